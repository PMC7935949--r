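# Per-gene testing of RPF, mRNA and mRNA-adjusted translation changes,
# Benjamini-Hochberg correction, and six-category classification of
# translational control.

TC_CATEGORIES <- c("rpf_up_mrna_same", "rpf_same_mrna_down",
                   "rpf_down_mrna_same", "rpf_same_mrna_up",
                   "both_up", "both_down")

# pooled-variance two-sample t-test, vectorized over matrix rows
row_t_test <- function(mat, case_cols, control_cols) {
  x <- mat[, case_cols, drop = FALSE]
  y <- mat[, control_cols, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1, stats::var); v2 <- apply(y, 1, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(abs(tstat), df = n1 + n2 - 2, lower.tail = FALSE)
  p[se == 0 & m1 == m2] <- 1
  flag <- se == 0 & m1 != m2
  p[flag] <- NA_real_
  list(effect = m1 - m2, p = p, flagged = flag)
}

#' Per-gene analysis of RPF, mRNA and mRNA-adjusted translation
#'
#' For each gene, `p_rpf` and `p_mrna` come from pooled two-sample t-tests
#' on the normalized (TMM-log2) values. `p_translation` comes from a
#' per-gene analysis of covariance: normalized RPF regressed on normalized
#' mRNA plus a group indicator, testing the group coefficient — the change
#' in ribosome occupancy not explained by the mRNA change. Effects are on
#' the log2 scale. Genes with zero within-group variance are flagged (`NA`
#' p-value), never silently assigned 0.
#'
#' @param rpf_norm,mrna_norm Normalized log2 matrices (same genes, same
#'   column layout).
#' @param groups Named list with `case` and `control` column-name vectors.
#' @return Data frame with one row per gene: effects, p-values and a
#'   `flagged` indicator.
#' @export
apv_test <- function(rpf_norm, mrna_norm, groups) {
  stopifnot(identical(rownames(rpf_norm), rownames(mrna_norm)))
  case_cols <- groups$case; control_cols <- groups$control
  if (length(case_cols) < 2 || length(control_cols) < 2)
    stop("at least 2 replicates per condition are required")
  t_rpf <- row_t_test(rpf_norm, case_cols, control_cols)
  t_mrna <- row_t_test(mrna_norm, case_cols, control_cols)
  cols <- c(control_cols, case_cols)
  g <- rep(c(0, 1), c(length(control_cols), length(case_cols)))
  n <- length(cols)
  p_tr <- effect_tr <- rep(NA_real_, nrow(rpf_norm))
  flagged_tr <- logical(nrow(rpf_norm))
  for (i in seq_len(nrow(rpf_norm))) {
    y <- rpf_norm[i, cols]
    x <- mrna_norm[i, cols]
    X <- cbind(1, x, g)
    if (qr(X)$rank < 3 || stats::var(y) == 0) {
      # degenerate covariate (e.g. constant mRNA): drop it, plain t-model
      X2 <- cbind(1, g)
      fit <- stats::lm.fit(X2, y)
      rss <- sum(fit$residuals^2)
      df <- n - 2
      if (df <= 0 || rss == 0) { flagged_tr[i] <- TRUE; next }
      XtXi <- chol2inv(chol(crossprod(X2)))
      se <- sqrt(rss / df * XtXi[2, 2])
      effect_tr[i] <- fit$coefficients[2]
      p_tr[i] <- 2 * stats::pt(abs(fit$coefficients[2] / se), df,
                               lower.tail = FALSE)
      next
    }
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    df <- n - 3
    if (df <= 0 || rss == 0) { flagged_tr[i] <- TRUE; next }
    XtXi <- chol2inv(chol(crossprod(X)))
    se <- sqrt(rss / df * XtXi[3, 3])
    effect_tr[i] <- fit$coefficients[3]
    p_tr[i] <- 2 * stats::pt(abs(fit$coefficients[3] / se), df,
                             lower.tail = FALSE)
  }
  data.frame(gene = rownames(rpf_norm),
             log2FC_RPF = t_rpf$effect, p_rpf = t_rpf$p,
             log2FC_mRNA = t_mrna$effect, p_mrna = t_mrna$p,
             log2FC_TE = effect_tr, p_translation = p_tr,
             flagged = t_rpf$flagged | t_mrna$flagged | flagged_tr,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_i = min over j >= rank(i) of p_(j) * m / j`, capped at 1; undefined
#' entries (`NA`) are excluded from the ranking and reinserted as `NA`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Vector of q-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Classify genes into six translational-control categories
#'
#' An axis (RPF or mRNA) is called changed when
#' `|log2FC| > log2(fc_min)` and `p < p_max` and `q <= fdr_max`
#' (defaults: fold change > 2, nominal P < 0.05, FDR 0.15). The sign
#' pattern of the changed axes maps to: RPF up with mRNA unchanged,
#' mRNA down with RPF unchanged, RPF down with mRNA unchanged, mRNA up
#' with RPF unchanged, both up, both down; anything else is `unchanged`.
#' Significant axes with opposite signs are not among the six categories;
#' they stay `unchanged` with `discordant = TRUE`.
#'
#' @param records Data frame from [apv_test()]; q-value columns (`q_rpf`,
#'   `q_mrna`, `q_translation`) are added via [bh_adjust()] when absent.
#' @param fc_min Linear fold-change threshold (> 1).
#' @param p_max Nominal p-value ceiling.
#' @param fdr_max q-value ceiling.
#' @return The input with `q_*` columns, `category` and `discordant`
#'   columns; genes with missing statistics get category `NA` and are
#'   counted in the `n_unclassified` attribute.
#' @export
classify_genes <- function(records, fc_min = 2, p_max = 0.05,
                           fdr_max = 0.15) {
  stopifnot(fc_min > 1, p_max > 0, fdr_max > 0)
  if (!"q_rpf" %in% names(records))
    records$q_rpf <- bh_adjust(records$p_rpf)
  if (!"q_mrna" %in% names(records))
    records$q_mrna <- bh_adjust(records$p_mrna)
  if (!"q_translation" %in% names(records) &&
      "p_translation" %in% names(records))
    records$q_translation <- bh_adjust(records$p_translation)
  lfc <- log2(fc_min)
  changed <- function(effect, p, q) {
    !is.na(effect) & !is.na(p) & !is.na(q) &
      abs(effect) > lfc & p < p_max & q <= fdr_max
  }
  rpf_ch <- changed(records$log2FC_RPF, records$p_rpf, records$q_rpf)
  mrna_ch <- changed(records$log2FC_mRNA, records$p_mrna, records$q_mrna)
  rpf_sign <- ifelse(rpf_ch, sign(records$log2FC_RPF), 0)
  mrna_sign <- ifelse(mrna_ch, sign(records$log2FC_mRNA), 0)
  cat_out <- rep("unchanged", nrow(records))
  cat_out[rpf_sign == 1 & mrna_sign == 0] <- "rpf_up_mrna_same"
  cat_out[rpf_sign == 0 & mrna_sign == -1] <- "rpf_same_mrna_down"
  cat_out[rpf_sign == -1 & mrna_sign == 0] <- "rpf_down_mrna_same"
  cat_out[rpf_sign == 0 & mrna_sign == 1] <- "rpf_same_mrna_up"
  cat_out[rpf_sign == 1 & mrna_sign == 1] <- "both_up"
  cat_out[rpf_sign == -1 & mrna_sign == -1] <- "both_down"
  discordant <- (rpf_sign * mrna_sign) == -1
  missing_stat <- is.na(records$p_rpf) | is.na(records$p_mrna)
  cat_out[missing_stat] <- NA_character_
  records$category <- cat_out
  records$discordant <- discordant & !missing_stat
  attr(records, "n_unclassified") <- sum(missing_stat)
  records
}
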