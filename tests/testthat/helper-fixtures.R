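# Shared fixtures and independent oracles, all built in code.

# one-row transcript model
tx_model <- function(transcript_id = "tx1", gene_id = transcript_id,
                     length = 300L, cds_start = 60L, cds_end = 240L) {
  data.frame(transcript_id = transcript_id, gene_id = gene_id,
             length = length, cds_start = cds_start, cds_end = cds_end,
             stringsAsFactors = FALSE)
}

# alignment record rows
align_rec <- function(transcript_id, pos5, read_length = 29L,
                      n_locations = 1L, read_id = NULL,
                      mapq = ifelse(n_locations == 1L, 255L, 1L)) {
  n <- max(length(transcript_id), length(pos5))
  if (is.null(read_id)) read_id <- sprintf("r%04d", seq_len(n))
  data.frame(read_id = read_id, transcript_id = transcript_id,
             pos5 = as.integer(pos5), read_length = as.integer(read_length),
             n_locations = as.integer(n_locations), mapq = as.integer(mapq),
             stringsAsFactors = FALSE)
}

# brute-force P-site coverage accumulator (position-by-position loop),
# independent of build_coverage's vectorized path
brute_coverage <- function(records, models, offsets, max_locations = 3L) {
  profiles <- lapply(models$length, numeric)
  names(profiles) <- models$transcript_id
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    if (!r$transcript_id %in% names(profiles)) next
    if (r$n_locations > max_locations) next
    w <- if (r$n_locations == 1L) 1 else 1 / r$n_locations
    off <- if (length(offsets) == 1 && is.null(names(offsets))) offsets
           else offsets[[as.character(r$read_length)]]
    p <- r$pos5 + off
    L <- models$length[models$transcript_id == r$transcript_id]
    if (p >= 0 && p < L)
      profiles[[r$transcript_id]][p + 1L] <-
        profiles[[r$transcript_id]][p + 1L] + w
  }
  profiles
}

# brute-force per-read gene counting oracle (with per-gene read dedup)
brute_count_genes <- function(records, models, offset = 14,
                              source = "rpf", max_locations = 3L) {
  genes <- unique(models$gene_id)
  counts <- stats::setNames(numeric(length(genes)), genes)
  seen <- character(0)
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    m <- models[models$transcript_id == r$transcript_id, ]
    if (!nrow(m)) next
    if (r$n_locations > max_locations) next
    w <- if (r$n_locations == 1L) 1 else 1 / r$n_locations
    hit <- if (source == "rpf") {
      p <- r$pos5 + offset
      p >= m$cds_start && p < m$cds_end
    } else {
      r$pos5 >= 0 && r$pos5 < m$length
    }
    if (!hit) next
    key <- paste(r$read_id, m$gene_id)
    if (key %in% seen) next
    seen <- c(seen, key)
    counts[m$gene_id] <- counts[m$gene_id] + w
  }
  counts
}

# brute-force BH step-up: q_i = min_{j >= rank(i)} p_(j) * m / j
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(o == i)
    q[i] <- min(pmin(p[o][rank_i:m] * m / (rank_i:m), 1))
  }
  q
}

# closed-form OLS via normal equations
brute_ols <- function(x, y) {
  X <- cbind(1, x)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# write records to a temporary SAM and return the path
temp_sam <- function(records, models) {
  path <- tempfile(fileext = ".sam")
  write_sam(records, models, path)
  path
}
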