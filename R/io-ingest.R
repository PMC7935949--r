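# Readers for annotation/alignment files and construction of P-site
# coverage profiles in transcript coordinates. Internally everything is
# 0-based half-open; GTF (1-based inclusive) is converted at the boundary.

#' Read transcript models from annotation
#'
#' Supports two dialects: a transcript-space GTF (parsed with rtracklayer;
#' transcript length from `exon` features, CDS bounds from `CDS` features)
#' and a TSV with explicit columns (`transcript_id`, `gene_id`, `length`,
#' `cds_start` 0-based, `cds_end` exclusive). Transcripts lacking a CDS, or
#' whose CDS length is not a multiple of 3, are excluded with a warning.
#'
#' @param path Annotation file.
#' @param dialect `"gtf"`, `"tsv"`, or `"auto"` (by file extension).
#' @return Data frame of transcript models, one row per transcript.
#' @export
read_annotation <- function(path, dialect = c("auto", "gtf", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE))
      "gtf" else "tsv"
  }
  if (dialect == "gtf") {
    gr <- as.data.frame(rtracklayer::import(path, format = "gtf"))
    if (!"transcript_id" %in% names(gr))
      stop("GTF rows lack transcript_id attribute")
    exons <- gr[gr$type == "exon", ]
    cds <- gr[gr$type == "CDS", ]
    if (!nrow(exons)) stop("no exon features in GTF")
    len <- tapply(exons$end, exons$transcript_id, max)
    models <- data.frame(transcript_id = names(len),
                         length = as.integer(len),
                         stringsAsFactors = FALSE)
    gid <- exons$gene_id[match(models$transcript_id, exons$transcript_id)]
    models$gene_id <- if (is.null(gid)) models$transcript_id else gid
    cs <- tapply(cds$start, cds$transcript_id, min)  # 1-based inclusive
    ce <- tapply(cds$end, cds$transcript_id, max)
    models$cds_start <- as.integer(cs[models$transcript_id]) - 1L
    models$cds_end <- as.integer(ce[models$transcript_id])
    no_cds <- is.na(models$cds_start)
    if (any(no_cds)) {
      warning(sum(no_cds), " transcript(s) lack a CDS and were excluded")
      models <- models[!no_cds, ]
    }
    models <- models[, c("transcript_id", "gene_id", "length", "cds_start",
                         "cds_end")]
  } else {
    models <- utils::read.delim(path, stringsAsFactors = FALSE)
    needed <- c("transcript_id", "length", "cds_start", "cds_end")
    missing <- setdiff(needed, names(models))
    if (length(missing))
      stop("TSV annotation lacks column(s): ", paste(missing, collapse = ", "))
    if (!"gene_id" %in% names(models)) models$gene_id <- models$transcript_id
    models <- models[, c("transcript_id", "gene_id", "length", "cds_start",
                         "cds_end")]
  }
  if (anyDuplicated(models$transcript_id))
    stop("duplicate transcript_id in annotation: ",
         models$transcript_id[duplicated(models$transcript_id)][1])
  bad_bounds <- with(models, cds_start < 0 | cds_start >= cds_end |
                       cds_end > length)
  if (any(bad_bounds))
    stop("CDS bounds outside transcript for: ",
         paste(models$transcript_id[bad_bounds], collapse = ", "))
  frame_ok <- (models$cds_end - models$cds_start) %% 3L == 0L
  if (any(!frame_ok)) {
    warning(sum(!frame_ok),
            " transcript(s) with CDS length not a multiple of 3 excluded: ",
            paste(models$transcript_id[!frame_ok], collapse = ", "))
    models <- models[frame_ok, ]
  }
  rownames(models) <- NULL
  models
}

parse_cigar_len <- function(cigar) {
  # aligned read length on the reference: sum of M/=/X/D/N operations
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)
  vapply(seq_along(cigar), function(i) {
    m <- regmatches(cigar[i], ops[i])[[1]]
    if (!length(m)) return(NA_integer_)
    n <- as.integer(sub("[MIDNSHP=X]", "", m))
    op <- sub("\\d+", "", m)
    sum(n[op %in% c("M", "=", "X", "D", "N")])
  }, integer(1))
}

#' Read single-end alignments from a SAM file
#'
#' Keeps forward-strand mapped records only, then filters on mapping
#' quality (default minimum 5) and, in RPF mode, on read length (default
#' 26-32 nt). The mapping-location count is taken from the `NH` tag when
#' present, otherwise from the multiplicity of the read id within the file
#' (bowtie `-a` emits one line per location). Records on references absent
#' from `models` are skipped and tallied.
#'
#' @param path SAM file (text).
#' @param models Optional transcript models; when given, records on unknown
#'   references are dropped (tallied as `unknown_reference`).
#' @param min_mapq Minimum mapping quality (records below are dropped).
#' @param length_range Two integers or `NULL` (no length filter; mRNA mode).
#' @return Data frame of alignment records with a `tally` attribute
#'   (named counts of records removed per filter).
#' @export
read_alignments <- function(path, models = NULL, min_mapq = 5,
                            length_range = c(26L, 32L)) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "@"))
  tally <- c(unmapped = 0L, reverse_strand = 0L, mapq = 0L, length = 0L,
             unknown_reference = 0L)
  empty <- data.frame(read_id = character(), transcript_id = character(),
                      pos5 = integer(), read_length = integer(),
                      n_locations = integer(), mapq = integer(),
                      stringsAsFactors = FALSE)
  if (!length(body_idx)) {
    attr(empty, "tally") <- tally
    return(empty)
  }
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11))
    stop("malformed SAM line ", body_idx[which(nf < 11)[1]],
         ": fewer than 11 fields")
  qname <- vapply(fields, `[[`, "", 1L)
  flag <- as.integer(vapply(fields, `[[`, "", 2L))
  rname <- vapply(fields, `[[`, "", 3L)
  pos <- as.integer(vapply(fields, `[[`, "", 4L))
  mapq <- as.integer(vapply(fields, `[[`, "", 5L))
  cigar <- vapply(fields, `[[`, "", 6L)
  if (anyNA(flag) || anyNA(pos) || anyNA(mapq))
    stop("malformed SAM line ",
         body_idx[which(is.na(flag) | is.na(pos) | is.na(mapq))[1]])
  seqf <- vapply(fields, `[[`, "", 10L)
  rl <- ifelse(seqf == "*", parse_cigar_len(cigar), nchar(seqf))
  nh <- vapply(fields, function(f) {
    tag <- grep("^NH:i:", f[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("NH:i:", "", tag[1])) else NA_integer_
  }, integer(1))
  # fallback: count read-id multiplicity within the file
  if (anyNA(nh)) {
    mult <- table(qname)
    nh[is.na(nh)] <- as.integer(mult[qname[is.na(nh)]])
  }
  keep <- rep(TRUE, length(qname))
  drop_count <- function(cond) sum(keep & cond)
  unmapped <- bitwAnd(flag, 4L) != 0L
  tally["unmapped"] <- drop_count(unmapped); keep <- keep & !unmapped
  rev <- bitwAnd(flag, 16L) != 0L
  tally["reverse_strand"] <- drop_count(rev); keep <- keep & !rev
  low_mapq <- mapq < min_mapq
  tally["mapq"] <- drop_count(low_mapq); keep <- keep & !low_mapq
  if (!is.null(length_range)) {
    bad_len <- rl < length_range[1] | rl > length_range[2]
    tally["length"] <- drop_count(bad_len); keep <- keep & !bad_len
  }
  if (!is.null(models)) {
    unknown <- !(rname %in% models$transcript_id)
    tally["unknown_reference"] <- drop_count(unknown); keep <- keep & !unknown
  }
  rec <- data.frame(read_id = qname[keep], transcript_id = rname[keep],
                    pos5 = pos[keep] - 1L, read_length = as.integer(rl[keep]),
                    n_locations = nh[keep], mapq = mapq[keep],
                    stringsAsFactors = FALSE)
  attr(rec, "tally") <- tally
  rec
}

#' Resolve a record's multimapping weight
#'
#' Unique reads weigh 1; reads mapping to `k <= max_locations` locations
#' weigh `1/k` at each location; reads exceeding the cap are dropped
#' (weight 0). With `weight_by_locations = FALSE` multi-mapped reads below
#' the cap also weigh 1.
#' @noRd
location_weight <- function(n_locations, weight_by_locations = TRUE,
                            max_locations = 3L) {
  w <- if (weight_by_locations) 1 / n_locations
       else rep(1, length(n_locations))
  w[n_locations > max_locations] <- 0
  w
}

#' Build P-site coverage profiles
#'
#' Each record contributes weight `w` at transcript position
#' `pos5 + offset(read_length)`: `w = 1` for unique reads, `1/k` for reads
#' at `k <= max_locations` locations, and 0 (dropped) beyond the cap.
#' Records whose P-site falls outside `[0, L)` are dropped and tallied.
#'
#' @param records Alignment data frame (see [read_alignments()]).
#' @param models Transcript models.
#' @param offsets A [psite_offsets()] table, a single number (fixed
#'   offset), or a named numeric vector by read length.
#' @param weight_by_locations Weight multi-mapped reads by `1/k`?
#' @param max_locations Reads mapping to more locations are dropped.
#' @return Named list of per-transcript numeric coverage vectors (class
#'   `ribo_coverage`), with attributes `tally` (dropped weight by reason)
#'   and `total_weight` (sum of input read weights).
#' @export
build_coverage <- function(records, models, offsets = 14,
                           weight_by_locations = TRUE, max_locations = 3L) {
  off <- offset_lookup(offsets, records$read_length)
  w <- location_weight(records$n_locations, weight_by_locations,
                       max_locations)
  psite <- records$pos5 + off
  L <- models$length[match(records$transcript_id, models$transcript_id)]
  known <- !is.na(L)
  inside <- known & psite >= 0 & psite < L
  profiles <- lapply(seq_len(nrow(models)), function(i) {
    numeric(models$length[i])
  })
  names(profiles) <- models$transcript_id
  use <- which(inside & w > 0)
  if (length(use)) {
    by_tx <- split(use, records$transcript_id[use])
    for (tx in names(by_tx)) {
      idx <- by_tx[[tx]]
      v <- profiles[[tx]]
      acc <- tapply(w[idx], psite[idx], sum)
      v[as.integer(names(acc)) + 1L] <- v[as.integer(names(acc)) + 1L] + acc
      profiles[[tx]] <- v
    }
  }
  tally <- c(unknown_reference = sum(w[!known]),
             outside = sum(w[known & !inside]),
             excess_locations = sum(records$n_locations > max_locations))
  structure(profiles, class = "ribo_coverage", tally = tally,
            total_weight = sum(w[known & inside]))
}

#' Export coverage profiles as bedGraph
#'
#' 0-based half-open intervals; runs of equal value are merged and zero
#' runs omitted.
#'
#' @param profiles A `ribo_coverage` (named list of coverage vectors).
#' @param path Output path.
#' @param track_name Optional track line name (omitted when `NULL`).
#' @return Invisibly, `path`.
#' @export
export_bedgraph <- function(profiles, path, track_name = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(track_name))
    writeLines(sprintf('track type=bedGraph name="%s"', track_name), con)
  for (tx in names(profiles)) {
    v <- profiles[[tx]]
    if (!length(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    nz <- r$values != 0
    if (any(nz)) {
      writeLines(sprintf("%s\t%d\t%d\t%s", tx, starts[nz], ends[nz],
                         format(r$values[nz], trim = TRUE, digits = 15)),
                 con)
    }
  }
  invisible(path)
}

#' Re-import a bedGraph written by [export_bedgraph()]
#'
#' @param path bedGraph file.
#' @param models Transcript models (for vector lengths).
#' @return Named list of coverage vectors.
#' @export
read_bedgraph <- function(path, models) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "track") & nzchar(lines)]
  profiles <- lapply(models$length, numeric)
  names(profiles) <- models$transcript_id
  if (length(lines)) {
    f <- strsplit(lines, "\t", fixed = TRUE)
    tx <- vapply(f, `[[`, "", 1L)
    s <- as.integer(vapply(f, `[[`, "", 2L))
    e <- as.integer(vapply(f, `[[`, "", 3L))
    val <- as.numeric(vapply(f, `[[`, "", 4L))
    for (i in seq_along(tx)) {
      if (!tx[i] %in% names(profiles)) next
      profiles[[tx[i]]][(s[i] + 1L):e[i]] <- val[i]
    }
  }
  profiles
}
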