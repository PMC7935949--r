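# Gene-level weighted counting (RPF over CDS, mRNA over the whole
# transcript) and TMM-log2 normalization.

#' Count reads per gene
#'
#' RPF mode counts a read if and only if its P-site (`pos5 + offset`) lies
#' within `[cds_start, cds_end)`; mRNA mode counts a read if its 5' end
#' lies within the transcript. Weights follow the exon-union convention of
#' the ingest layer: 1 for unique reads, `1/k` for reads at
#' `k <= max_locations` locations, 0 beyond the cap. A read hitting several
#' isoforms of one gene contributes once to that gene (the collapsed weight
#' is tallied as `gene_dedup`).
#'
#' @param records Alignment data frame.
#' @param models Transcript models carrying `gene_id`.
#' @param offsets Offset table / value (RPF mode only).
#' @param source `"rpf"` or `"mrna"`.
#' @param weight_by_locations Weight multi-mapped reads by `1/k`?
#' @param max_locations Cap beyond which reads are dropped.
#' @return Named numeric vector of per-gene counts (every gene in `models`
#'   present), with a `tally` attribute of dropped/collapsed weight.
#' @export
count_genes <- function(records, models, offsets = 14,
                        source = c("rpf", "mrna"),
                        weight_by_locations = TRUE, max_locations = 3L) {
  source <- match.arg(source)
  genes <- unique(models$gene_id)
  counts <- stats::setNames(numeric(length(genes)), genes)
  mi <- match(records$transcript_id, models$transcript_id)
  known <- !is.na(mi)
  w <- location_weight(records$n_locations, weight_by_locations,
                       max_locations)
  if (source == "rpf") {
    off <- offset_lookup(offsets, records$read_length)
    pos <- records$pos5 + off
    inside <- known & pos >= models$cds_start[mi] & pos < models$cds_end[mi]
  } else {
    inside <- known & records$pos5 >= 0 & records$pos5 < models$length[mi]
  }
  use <- which(inside & w > 0)
  dedup_weight <- 0
  if (length(use)) {
    gid <- models$gene_id[mi[use]]
    key <- paste(records$read_id[use], gid, sep = "\r")
    dup <- duplicated(key)
    dedup_weight <- sum(w[use][dup])
    use <- use[!dup]
    gid <- gid[!dup]
    acc <- tapply(w[use], gid, sum)
    counts[names(acc)] <- acc
  }
  tally <- c(unknown_reference = sum(w[!known]),
             outside = sum(w[known & !inside]),
             excess_locations = sum(records$n_locations > max_locations),
             gene_dedup = dedup_weight)
  attr(counts, "tally") <- tally
  counts
}

#' Assemble a gene-by-sample count matrix
#'
#' @param record_list Named list of alignment data frames, one per sample.
#' @param models Transcript models.
#' @param ... Passed to [count_genes()].
#' @return Numeric matrix, genes x samples.
#' @export
count_matrix <- function(record_list, models, ...) {
  cols <- lapply(record_list, count_genes, models = models, ...)
  mat <- do.call(cbind, cols)
  colnames(mat) <- names(record_list)
  mat
}

#' TMM normalization with log2-CPM transform
#'
#' Scaling factors follow the trimmed-mean-of-M-values definition (30% trim
#' on M, 5% on A, precision weighting, reference column with upper quartile
#' closest to the mean upper quartile), computed by edgeR and rescaled to
#' geometric mean 1. The normalized value is
#' `log2((count + pseudo) / (library_size * factor) * 1e6)`.
#'
#' @param counts Gene-by-sample matrix of (possibly fractional) counts.
#' @param trim_M,trim_A Trim fractions for log-ratios and abundances.
#' @param pseudo Pseudocount added before the log transform.
#' @return List of class `tmm_norm`: `factors`, `lib_sizes`, `normalized`
#'   (log2 matrix).
#' @export
tmm_normalize <- function(counts, trim_M = 0.30, trim_A = 0.05,
                          pseudo = 0.5) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("TMM requires at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("all-zero column(s): ",
                          paste(colnames(counts)[lib == 0], collapse = ", "))
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = trim_M, sumTrim = trim_A)
  f <- f / exp(mean(log(f)))  # geometric mean 1 (edgeR already ensures this)
  eff <- lib * f
  norm <- log2(sweep(counts + pseudo, 2, eff, "/") * 1e6)
  structure(list(factors = stats::setNames(f, colnames(counts)),
                 lib_sizes = lib, normalized = norm),
            class = "tmm_norm")
}

#' Change in ribosome occupancy (RPF/mRNA ratio) between conditions
#'
#' Translational efficiency per group is the mean normalized RPF signal
#' minus the mean normalized mRNA signal; the output is the case-minus-
#' control difference, i.e. the log2 fold change of the RPF/mRNA ratio.
#'
#' @param rpf_norm,mrna_norm Normalized (log2) gene-by-sample matrices with
#'   matching gene sets (genes missing from one matrix are dropped and
#'   tallied).
#' @param groups Named list with character vectors `case` and `control`
#'   selecting columns of each matrix (the same names are used for both).
#' @return Named numeric vector of per-gene delta log2(RPF/mRNA), with
#'   attribute `n_dropped`.
#' @export
occupancy_log2fc <- function(rpf_norm, mrna_norm, groups) {
  stopifnot(all(c("case", "control") %in% names(groups)))
  common <- intersect(rownames(rpf_norm), rownames(mrna_norm))
  dropped <- length(union(rownames(rpf_norm), rownames(mrna_norm))) -
    length(common)
  te <- function(mat, cols) rowMeans(mat[common, cols, drop = FALSE])
  d_case <- te(rpf_norm, groups$case) - te(mrna_norm, groups$case)
  d_ctrl <- te(rpf_norm, groups$control) - te(mrna_norm, groups$control)
  out <- d_case - d_ctrl
  attr(out, "n_dropped") <- dropped
  out
}
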