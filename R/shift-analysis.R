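# Center-of-ribosome-density per transcript and regression-based
# classification of 5' versus 3' occupancy shifts between conditions.

#' Center of ribosome density
#'
#' Treats the mass at each nucleotide `j` as uniform over `[j, j+1)` and
#' returns the CDS-relative position `x*/L` at which the interpolated
#' cumulative mass reaches half of the total. When the half-mass point
#' falls on a zero-coverage plateau (the median is non-unique) the plateau
#' midpoint is used, which makes the measure exactly antisymmetric under
#' profile reversal. 0.5 means balanced coverage; values below 0.5
#' indicate 5'-accumulated ribosomes.
#'
#' @param profile Full-transcript coverage vector.
#' @param model One-row transcript model.
#' @param min_mass Minimum total mass in the region; below it the center is
#'   undefined (`NA`).
#' @param region `"cds"` (default; translating ribosomes) or
#'   `"transcript"`.
#' @return The center of density in `[0, 1]`, or `NA`.
#' @export
center_of_density <- function(profile, model, min_mass = 10,
                              region = c("cds", "transcript")) {
  region <- match.arg(region)
  v <- if (region == "cds")
    profile[(model$cds_start + 1L):model$cds_end] else profile
  total <- sum(v)
  if (total < min_mass) return(NA_real_)
  half <- total / 2
  cs <- cumsum(v)
  j <- which(cs >= half)[1]                 # 1-based index
  before <- if (j > 1) cs[j - 1] else 0
  x <- (j - 1) + (half - before) / v[j]
  if (cs[j] == half) {
    # median plateau [j, k-1]: take its midpoint
    k <- which(cs > half)[1]
    x <- (j + (k - 1)) / 2
  }
  x / length(v)
}

#' Per-transcript, per-sample center-of-density table
#'
#' @param profile_list Named list of coverage sets (one `ribo_coverage`
#'   per sample).
#' @param models Transcript models.
#' @param ... Passed to [center_of_density()].
#' @return Data frame with `transcript_id`, `sample_id`, `rho`,
#'   `total_mass`.
#' @export
center_density_table <- function(profile_list, models, ...) {
  out <- list()
  for (s in names(profile_list)) {
    profiles <- profile_list[[s]]
    rho <- vapply(seq_len(nrow(models)), function(i) {
      v <- profiles[[models$transcript_id[i]]]
      if (is.null(v)) return(NA_real_)
      center_of_density(v, models[i, ], ...)
    }, numeric(1))
    mass <- vapply(seq_len(nrow(models)), function(i) {
      v <- profiles[[models$transcript_id[i]]]
      if (is.null(v)) return(0)
      sum(v[(models$cds_start[i] + 1L):models$cds_end[i]])
    }, numeric(1))
    out[[s]] <- data.frame(transcript_id = models$transcript_id,
                           sample_id = s, rho = rho, total_mass = mass,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Case-versus-control regression of mean centers of density
#'
#' Ordinary least squares of the case-condition mean center of density on
#' the control mean across transcripts; per-transcript residuals feed the
#' shift classification. Transcripts with an undefined mean in either
#' condition are excluded.
#'
#' @param rho_case,rho_control Named numeric vectors of replicate-mean
#'   centers of density (names are transcript ids).
#' @return List of class `shift_fit`: `coefficients` (intercept, slope),
#'   `data` (transcript, rho_control, rho_case, residual), `n`.
#' @export
shift_regression <- function(rho_case, rho_control) {
  common <- intersect(names(rho_case), names(rho_control))
  x <- rho_control[common]; y <- rho_case[common]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3)
    stop("need >= 3 transcripts with defined centers in both conditions")
  if (stats::var(x) == 0)
    stop("degenerate regression: all control centers are equal")
  fit <- stats::lm(y ~ x)
  structure(list(coefficients = stats::setNames(stats::coef(fit),
                                                c("intercept", "slope")),
                 data = data.frame(transcript_id = names(x),
                                   rho_control = unname(x),
                                   rho_case = unname(y),
                                   residual = unname(stats::resid(fit)),
                                   stringsAsFactors = FALSE),
                 n = length(x)),
            class = "shift_fit")
}

#' Classify 5'/3' density shifts from regression residuals
#'
#' A transcript whose residual lies below `-k_sd` residual standard
#' deviations is labeled `shift5` (density moved toward the 5' end in the
#' case condition), above `+k_sd` is `shift3`, otherwise `none`.
#'
#' @param fit A `shift_fit` from [shift_regression()].
#' @param k_sd Residual-SD multiplier for the decision boundary.
#' @return The fit's `data` with a `label` column.
#' @export
classify_shift <- function(fit, k_sd = 2) {
  stopifnot(inherits(fit, "shift_fit"))
  d <- fit$data
  if (nrow(d) < 3) stop("need >= 3 residuals")
  s <- stats::sd(d$residual)
  d$label <- "none"
  # guard against labeling pure floating-point noise around a perfect fit
  if (s > 1e-9) {
    d$label[d$residual < -k_sd * s] <- "shift5"
    d$label[d$residual > k_sd * s] <- "shift3"
  }
  d
}
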