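# Synthetic-data generator: transcriptomes, Ribo-Seq/RNA-Seq alignments,
# count matrices and UV traces with known ground truth, so every downstream
# stage can be validated against planted signal.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator with validation.
#' Defaults emulate a cycloheximide-arrested ribosome-profiling library:
#' 26-32 nt ribosome-protected fragments (RPFs) with length-dependent
#' 5' end to P-site offsets, strong but imperfect triplet periodicity, and
#' a small multi-mapping fraction.
#'
#' @param seed Integer seed; the same configuration and seed give
#'   byte-identical outputs.
#' @param n_transcripts Number of transcripts to simulate.
#' @param cds_length_range Two integers, range of CDS lengths in nt
#'   (rounded down to multiples of 3, start and stop codon included).
#' @param utr5_length_range,utr3_length_range UTR length ranges in nt; the
#'   5' UTR minimum must be at least 60 nt so metagene windows upstream of
#'   the start codon fit.
#' @param planted_offsets Named numeric vector mapping read length to the
#'   5' end to P-site offset in nt. Offsets must lie in `[10, 16]`.
#' @param frame0_fraction Probability that a simulated P-site falls in
#'   frame 0 of its codon (the remainder split equally between frames 1/2).
#' @param depth Mean reads per transcript (Poisson-distributed unless
#'   `depth_exact = TRUE`).
#' @param depth_exact If `TRUE`, every transcript receives exactly `depth`
#'   reads (useful for noise-free calibration checks).
#' @param init_peak_fold Weight multiplier on the initiator codon,
#'   emulating the start-codon ribosome accumulation seen in
#'   cycloheximide-arrested libraries; this is the spike metagene offset
#'   calibration locks onto.
#' @param pause_spec Data frame with columns `transcript_id`,
#'   `codon_index` (0-based within the CDS) and `fold` (> 1): planted
#'   single-codon pauses.
#' @param skew_spec Optional named list mapping genotype to a named numeric
#'   vector of per-transcript geometric decay rates (see
#'   [skew_rate_for_rho()]); rate < 1 skews density 5', rate > 1 skews 3'.
#' @param multimap_fraction Probability a read is emitted at k in {2,3,4}
#'   locations.
#' @param nb_dispersion Negative-binomial dispersion for count-matrix
#'   simulation (> 0).
#' @param category_spec Data frame with columns `category`, `n`, `fold`
#'   used by [simulate_count_matrix()].
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_transcripts = 20L,
                       cds_length_range = c(300L, 900L),
                       utr5_length_range = c(60L, 120L),
                       utr3_length_range = c(30L, 90L),
                       planted_offsets = c(`26` = 12, `27` = 13, `28` = 13,
                                           `29` = 14, `30` = 15, `31` = 15,
                                           `32` = 16),
                       frame0_fraction = 0.9,
                       depth = 1000,
                       depth_exact = FALSE,
                       init_peak_fold = 10,
                       pause_spec = NULL,
                       skew_spec = NULL,
                       multimap_fraction = 0.05,
                       nb_dispersion = 0.1,
                       category_spec = NULL) {
  if (n_transcripts < 1) stop("n_transcripts must be >= 1")
  if (length(cds_length_range) != 2 || any(cds_length_range < 9) ||
      cds_length_range[1] > cds_length_range[2])
    stop("invalid cds_length_range")
  if (utr5_length_range[1] < 60)
    stop("5' UTR must be at least 60 nt to leave room for metagene windows")
  if (frame0_fraction < 0 || frame0_fraction > 1)
    stop("frame0_fraction must lie in [0, 1]")
  if (is.null(names(planted_offsets)) || any(names(planted_offsets) == ""))
    stop("planted_offsets must be named by read length")
  if (any(planted_offsets < 10 | planted_offsets > 16))
    stop("planted offsets must lie in [10, 16]")
  if (multimap_fraction < 0 || multimap_fraction > 1)
    stop("multimap_fraction must lie in [0, 1]")
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (depth < 0) stop("depth must be >= 0")
  if (init_peak_fold < 1) stop("init_peak_fold must be >= 1")
  if (!is.null(pause_spec)) {
    stopifnot(is.data.frame(pause_spec),
              all(c("transcript_id", "codon_index", "fold") %in%
                    names(pause_spec)))
    if (any(pause_spec$fold <= 1)) stop("pause folds must be > 1")
  }
  structure(list(seed = as.integer(seed),
                 n_transcripts = as.integer(n_transcripts),
                 cds_length_range = as.integer(cds_length_range),
                 utr5_length_range = as.integer(utr5_length_range),
                 utr3_length_range = as.integer(utr3_length_range),
                 planted_offsets = planted_offsets,
                 frame0_fraction = frame0_fraction,
                 depth = depth,
                 depth_exact = isTRUE(depth_exact),
                 init_peak_fold = init_peak_fold,
                 pause_spec = pause_spec,
                 skew_spec = skew_spec,
                 multimap_fraction = multimap_fraction,
                 nb_dispersion = nb_dispersion,
                 category_spec = category_spec),
            class = "sim_config")
}

# sample() treats a scalar first argument as 1:x; guard against it
resample <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]

random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_cds <- function(len) {
  # len includes start + stop; interior codons drawn from the 61 sense codons
  n_codons <- len / 3L
  sense <- setdiff(apply(expand.grid(c("A", "C", "G", "T"),
                                     c("A", "C", "G", "T"),
                                     c("A", "C", "G", "T")), 1, paste,
                         collapse = ""), STOP_CODONS)
  inner <- sample(sense, n_codons - 2L, replace = TRUE)
  paste0("ATG", paste(inner, collapse = ""), sample(STOP_CODONS, 1L))
}

#' Generate a synthetic transcriptome bundle
#'
#' Each transcript carries a 5' UTR of at least 60 nt, a CDS that starts
#' with ATG and ends with a stop codon (length a multiple of 3), and a
#' 3' UTR. One gene per transcript (`gene_id = g_<i>` for `tx_<i>`).
#'
#' @param config A [sim_config()].
#' @return A list of class `ribo_bundle` with elements `models` (data frame
#'   with `transcript_id`, `gene_id`, `length`, `cds_start` 0-based,
#'   `cds_end` exclusive) and `sequences` (named character vector).
#' @export
generate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_transcripts
    utr5 <- resample(seq(config$utr5_length_range[1],
                         config$utr5_length_range[2]), n)
    utr3 <- resample(seq(config$utr3_length_range[1],
                         config$utr3_length_range[2]), n)
    cds_len <- resample(seq(config$cds_length_range[1],
                            config$cds_length_range[2]), n)
    cds_len <- (cds_len %/% 3L) * 3L
    seqs <- character(n)
    for (i in seq_len(n)) {
      seqs[i] <- paste0(random_nt(utr5[i]), random_cds(cds_len[i]),
                        random_nt(utr3[i]))
    }
    ids <- sprintf("tx_%04d", seq_len(n))
    names(seqs) <- ids
    models <- data.frame(transcript_id = ids,
                         gene_id = sprintf("g_%04d", seq_len(n)),
                         length = utr5 + cds_len + utr3,
                         cds_start = utr5,
                         cds_end = utr5 + cds_len,
                         stringsAsFactors = FALSE)
    structure(list(models = models, sequences = seqs), class = "ribo_bundle")
  })
}

#' Solve the geometric skew rate that yields a target center of density
#'
#' Per-codon sampling weights proportional to `rate^codon_index` place the
#' median of the footprint mass at a predictable relative position; this
#' inverts that relation numerically so simulations can plant a known
#' center-of-density shift.
#'
#' @param target_rho Desired center of density in (0, 1).
#' @param n_codons Number of CDS codons.
#' @return The decay rate (1 means uniform; < 1 skews 5').
#' @export
skew_rate_for_rho <- function(target_rho, n_codons) {
  stopifnot(target_rho > 0, target_rho < 1, n_codons >= 2)
  if (abs(target_rho - 0.5) < 1e-9) return(1)
  # continuous-density median of w(x) = r^x on [0, n]: solve in log-rate
  f <- function(loga) {
    if (abs(loga) < 1e-12) return(0.5 - target_rho)
    a <- loga * n_codons
    # median m/n with density prop to exp(loga * x)
    m <- log1p((exp(a) - 1) / 2) / a
    m - target_rho
  }
  exp(stats::uniroot(f, c(-2, 2), tol = 1e-12)$root)
}

codon_weights <- function(n_codons, rate = 1, pauses = NULL,
                          init_peak_fold = 1) {
  w <- if (rate == 1) rep(1, n_codons) else rate^(seq_len(n_codons) - 1)
  w[1] <- w[1] * init_peak_fold
  if (!is.null(pauses) && nrow(pauses)) {
    idx <- pauses$codon_index + 1L
    if (any(idx < 1L | idx > n_codons))
      stop("pause position outside CDS")
    w[idx] <- w[idx] * pauses$fold
  }
  w / sum(w)
}

#' Simulate a Ribo-Seq library in transcript space
#'
#' P-sites are drawn per transcript from per-codon weights (uniform times
#' planted pause folds times geometric skew), a within-codon frame is drawn
#' with probability `frame0_fraction` of frame 0, a read length is drawn
#' uniformly from the configured lengths, and the read 5' end is placed at
#' P-site minus the planted offset for that length. A configurable fraction
#' of reads is additionally emitted at 2-4 locations on other transcripts
#' (all copies carrying the same `n_locations`, MAPQ 1), mimicking
#' `bowtie -a` reporting. Candidate P-sites whose read would run past a
#' transcript end are never emitted.
#'
#' @param bundle A `ribo_bundle` from [generate_transcriptome()].
#' @param config A [sim_config()].
#' @param sample_id Sample label written into the truth table.
#' @param genotype Which entry of `config$skew_spec` supplies per-transcript
#'   skew rates (ignored when `skew_spec` is `NULL`).
#' @param seed Optional override of `config$seed` (so replicates differ).
#' @return List with `records` (alignment data frame: `read_id`,
#'   `transcript_id`, `pos5` 0-based, `read_length`, `n_locations`, `mapq`)
#'   and `truth` (per-read true P-site and per-config planted values).
#' @export
simulate_riboseq <- function(bundle, config, sample_id = "ribo_1",
                             genotype = NULL, seed = NULL) {
  stopifnot(inherits(bundle, "ribo_bundle"), inherits(config, "sim_config"))
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  models <- bundle$models
  offs <- config$planted_offsets
  lens <- as.integer(names(offs))
  skew <- NULL
  if (!is.null(config$skew_spec) && !is.null(genotype)) {
    skew <- config$skew_spec[[genotype]]
    if (is.null(skew)) stop("genotype '", genotype, "' not in skew_spec")
  }
  withr::with_seed(seed, {
    out <- vector("list", nrow(models))
    truth_reads <- vector("list", nrow(models))
    read_counter <- 0L
    for (i in seq_len(nrow(models))) {
      m <- models[i, ]
      n_codons <- (m$cds_end - m$cds_start) %/% 3L
      pauses <- config$pause_spec
      if (!is.null(pauses))
        pauses <- pauses[pauses$transcript_id == m$transcript_id, ,
                         drop = FALSE]
      rate <- 1
      if (!is.null(skew) && m$transcript_id %in% names(skew))
        rate <- skew[[m$transcript_id]]
      w <- codon_weights(n_codons, rate, pauses, config$init_peak_fold)
      n_reads <- if (config$depth_exact) as.integer(config$depth)
                 else stats::rpois(1L, config$depth)
      if (n_reads == 0L) next
      codon <- sample.int(n_codons, n_reads, replace = TRUE, prob = w) - 1L
      in_frame <- stats::runif(n_reads) < config$frame0_fraction
      frame <- ifelse(in_frame, 0L, sample(c(1L, 2L), n_reads, replace = TRUE))
      psite <- m$cds_start + 3L * codon + frame
      rl <- lens[sample.int(length(lens), n_reads, replace = TRUE)]
      pos5 <- psite - as.integer(offs[as.character(rl)])
      ok <- pos5 >= 0L & (pos5 + rl) <= m$length
      if (!any(ok)) next
      codon <- codon[ok]; psite <- psite[ok]; rl <- rl[ok]; pos5 <- pos5[ok]
      n_ok <- sum(ok)
      ids <- sprintf("%s_r%07d", sample_id, read_counter + seq_len(n_ok))
      read_counter <- read_counter + n_ok
      multi <- stats::runif(n_ok) < config$multimap_fraction
      k <- rep(1L, n_ok)
      if (any(multi) && nrow(models) > 1)
        k[multi] <- sample(2:4, sum(multi), replace = TRUE)
      rec <- data.frame(read_id = ids, transcript_id = m$transcript_id,
                        pos5 = pos5, read_length = rl,
                        n_locations = k,
                        mapq = ifelse(k == 1L, 255L, 1L),
                        stringsAsFactors = FALSE)
      # extra copies on other transcripts, uniform positions
      extra <- NULL
      if (any(k > 1L)) {
        who <- which(k > 1L)
        ex <- vector("list", length(who))
        for (j in seq_along(who)) {
          r <- who[j]
          alt <- sample(setdiff(seq_len(nrow(models)), i),
                        k[r] - 1L, replace = nrow(models) - 1 < k[r] - 1L)
          alt_len <- models$length[alt]
          ex[[j]] <- data.frame(read_id = ids[r],
                                transcript_id = models$transcript_id[alt],
                                pos5 = floor(stats::runif(length(alt)) *
                                               (alt_len - rl[r] + 1L)),
                                read_length = rl[r],
                                n_locations = k[r], mapq = 1L,
                                stringsAsFactors = FALSE)
        }
        extra <- do.call(rbind, ex)
      }
      out[[i]] <- rbind(rec, extra)
      truth_reads[[i]] <- data.frame(read_id = ids,
                                     transcript_id = m$transcript_id,
                                     true_psite = psite,
                                     codon_index = codon,
                                     read_length = rl,
                                     n_locations = k,
                                     stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
    if (is.null(records))
      records <- data.frame(read_id = character(), transcript_id = character(),
                            pos5 = integer(), read_length = integer(),
                            n_locations = integer(), mapq = integer())
    rownames(records) <- NULL
    truth <- list(sample_id = sample_id,
                  offsets = offs,
                  pause_spec = config$pause_spec,
                  skew = skew,
                  reads = do.call(rbind,
                                  truth_reads[!vapply(truth_reads, is.null,
                                                      TRUE)]))
    list(records = records, truth = truth)
  })
}

#' Simulate a matched RNA-Seq library
#'
#' Reads are placed uniformly over the whole transcript (no CDS preference,
#' no periodicity); read lengths need not lie in the RPF range.
#'
#' @inheritParams simulate_riboseq
#' @param read_length Fixed RNA read length in nt.
#' @return List with `records` as in [simulate_riboseq()].
#' @export
simulate_rnaseq <- function(bundle, config, sample_id = "rna_1",
                            read_length = 50L, seed = NULL) {
  stopifnot(inherits(bundle, "ribo_bundle"))
  if (nrow(bundle$models) == 0) stop("empty bundle")
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  models <- bundle$models
  withr::with_seed(seed, {
    out <- vector("list", nrow(models))
    counter <- 0L
    for (i in seq_len(nrow(models))) {
      m <- models[i, ]
      rl <- min(read_length, m$length)
      n_reads <- if (config$depth_exact) as.integer(config$depth)
                 else stats::rpois(1L, config$depth)
      if (n_reads == 0L) next
      pos5 <- floor(stats::runif(n_reads) * (m$length - rl + 1L))
      ids <- sprintf("%s_r%07d", sample_id, counter + seq_len(n_reads))
      counter <- counter + n_reads
      out[[i]] <- data.frame(read_id = ids, transcript_id = m$transcript_id,
                             pos5 = as.integer(pos5),
                             read_length = as.integer(rl),
                             n_locations = 1L, mapq = 255L,
                             stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
    if (is.null(records))
      records <- data.frame(read_id = character(), transcript_id = character(),
                            pos5 = integer(), read_length = integer(),
                            n_locations = integer(), mapq = integer())
    rownames(records) <- NULL
    list(records = records)
  })
}

#' Simulate RPF and mRNA count matrices with planted translational effects
#'
#' Per-gene baseline means are log-normal; counts are negative-binomial
#' with the given dispersion, three replicates per condition by default.
#' Category effects are applied multiplicatively to the case-condition
#' means: `rpf_up_mrna_same` multiplies the RPF mean by `fold`,
#' `rpf_same_mrna_down` divides the mRNA mean, and so on; `both_up` /
#' `both_down` move both sources together. Genes without a planted effect
#' are labeled `unchanged`.
#'
#' @param n_genes Number of genes.
#' @param n_rep Replicates per condition.
#' @param dispersion NB dispersion (> 0); variance = mu + dispersion * mu^2.
#' @param category_spec Data frame with columns `category`
#'   (one of the six changed categories), `n` and `fold` (> 1, linear).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-gene baseline mean.
#' @param seed Integer seed.
#' @return List with matrices `rpf` and `mrna` (columns `ctrl_*`, `case_*`)
#'   and `truth` data frame (`gene_id`, `category`, `fold`).
#' @export
simulate_count_matrix <- function(n_genes = 2000L, n_rep = 3L,
                                  dispersion = 0.1,
                                  category_spec = NULL,
                                  baseline_meanlog = log(150),
                                  baseline_sdlog = 0.6,
                                  seed = 1L) {
  if (dispersion <= 0) stop("dispersion must be > 0")
  cats <- c("rpf_up_mrna_same", "rpf_same_mrna_down", "rpf_down_mrna_same",
            "rpf_same_mrna_up", "both_up", "both_down")
  if (!is.null(category_spec)) {
    stopifnot(all(c("category", "n", "fold") %in% names(category_spec)),
              all(category_spec$category %in% cats),
              all(category_spec$fold > 1),
              sum(category_spec$n) <= n_genes)
  }
  withr::with_seed(seed, {
    genes <- sprintf("g_%05d", seq_len(n_genes))
    label <- rep("unchanged", n_genes)
    fold <- rep(1, n_genes)
    if (!is.null(category_spec) && nrow(category_spec)) {
      planted <- sample.int(n_genes, sum(category_spec$n))
      label[planted] <- rep(category_spec$category, category_spec$n)
      fold[planted] <- rep(category_spec$fold, category_spec$n)
    }
    base <- stats::rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
    rpf_fac <- ifelse(label %in% c("rpf_up_mrna_same", "both_up"), fold,
                      ifelse(label %in% c("rpf_down_mrna_same", "both_down"),
                             1 / fold, 1))
    mrna_fac <- ifelse(label %in% c("rpf_same_mrna_up", "both_up"), fold,
                       ifelse(label %in% c("rpf_same_mrna_down", "both_down"),
                              1 / fold, 1))
    nb <- function(mu) {
      matrix(stats::rnbinom(length(mu) * n_rep, mu = rep(mu, n_rep),
                            size = 1 / dispersion),
             nrow = length(mu), ncol = n_rep)
    }
    rpf <- cbind(nb(base), nb(base * rpf_fac))
    mrna <- cbind(nb(base), nb(base * mrna_fac))
    cn <- c(sprintf("ctrl_%d", seq_len(n_rep)),
            sprintf("case_%d", seq_len(n_rep)))
    dimnames(rpf) <- dimnames(mrna) <- list(genes, cn)
    list(rpf = rpf, mrna = mrna,
         truth = data.frame(gene_id = genes, category = label, fold = fold,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a polysome-profile UV trace
#'
#' The trace is a sum of Gaussian peaks plus a linear baseline plus white
#' noise; the analytic area of each peak (`amplitude * sigma * sqrt(2*pi)`)
#' is returned as ground truth.
#'
#' @param peaks Data frame with columns `center`, `sigma` (> 0),
#'   `amplitude`.
#' @param positions Strictly increasing gradient-depth grid.
#' @param baseline_slope Slope of the linear baseline (intercept 0).
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return List of class `uv_trace` with `positions`, `absorbance`, and
#'   `truth_areas` (one per peak row).
#' @export
simulate_uv_trace <- function(peaks,
                              positions = seq(0, 10, length.out = 1001),
                              baseline_slope = 0, noise_sd = 0, seed = 1L) {
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  if (!is.null(peaks) && nrow(peaks)) {
    stopifnot(all(c("center", "sigma", "amplitude") %in% names(peaks)))
    if (any(peaks$sigma <= 0)) stop("peak sigma must be > 0")
    if (any(peaks$center < min(positions) | peaks$center > max(positions)))
      stop("peak centers must lie within the position domain")
  }
  y <- baseline_slope * positions
  areas <- numeric(0)
  if (!is.null(peaks) && nrow(peaks)) {
    for (i in seq_len(nrow(peaks))) {
      y <- y + peaks$amplitude[i] *
        exp(-(positions - peaks$center[i])^2 / (2 * peaks$sigma[i]^2))
    }
    areas <- peaks$amplitude * peaks$sigma * sqrt(2 * pi)
  }
  if (noise_sd > 0) {
    y <- y + withr::with_seed(seed,
                              stats::rnorm(length(positions), 0, noise_sd))
  }
  structure(list(positions = positions, absorbance = y, truth_areas = areas),
            class = "uv_trace")
}

#' Write a bundle's annotation and sequences to disk
#'
#' Emits a FASTA of transcript sequences plus both annotation dialects: a
#' transcript-space GTF (features `exon` and `CDS`, 1-based inclusive,
#' attributes `transcript_id`/`gene_id`) and a TSV
#' (`transcript_id`, `gene_id`, `length`, `cds_start` 0-based, `cds_end`
#' exclusive).
#'
#' @param bundle A `ribo_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ribo_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- bundle$models
  fasta <- file.path(dir, "transcripts.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(bundle$sequences),
                              fasta)
  gtf <- file.path(dir, "annotation.gtf")
  attr_str <- sprintf('gene_id "%s"; transcript_id "%s";', m$gene_id,
                      m$transcript_id)
  lines <- c(
    sprintf("%s\tribostall\texon\t1\t%d\t.\t+\t.\t%s", m$transcript_id,
            m$length, attr_str),
    sprintf("%s\tribostall\tCDS\t%d\t%d\t.\t+\t.\t%s", m$transcript_id,
            m$cds_start + 1L, m$cds_end, attr_str))
  writeLines(lines, gtf)
  tsv <- file.path(dir, "annotation.tsv")
  utils::write.table(m, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, gtf = gtf, tsv = tsv))
}

#' Write alignment records as a minimal SAM file
#'
#' Header carries one `@SQ` line per transcript; records are single-end,
#' FLAG 0, CIGAR `<len>M`, with the mapping-location count in the `NH` tag
#' (MAPQ 255 for unique reads, 1 for multi-mapped, mirroring bowtie).
#'
#' @param records Alignment data frame (`read_id`, `transcript_id`, `pos5`
#'   0-based, `read_length`, `n_locations`, `mapq`).
#' @param models Transcript models (for `@SQ` lengths).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(records, models, path) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", models$transcript_id,
                      models$length))
  body <- character(0)
  if (nrow(records)) {
    body <- sprintf("%s\t0\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*\tNH:i:%d",
                    records$read_id, records$transcript_id,
                    records$pos5 + 1L, records$mapq, records$read_length,
                    records$n_locations)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a UV trace as a two-column CSV
#'
#' @param trace A `uv_trace` (or any list with `positions`/`absorbance`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_uv_trace <- function(trace, path) {
  utils::write.csv(data.frame(position = trace$positions,
                              absorbance = trace$absorbance),
                   path, row.names = FALSE)
  invisible(path)
}
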