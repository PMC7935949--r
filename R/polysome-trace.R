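# Quantification of polysome-profile UV (A254) traces: baseline
# correction, region integration, polysome/monosome (PS/MS) ratios, and
# harringtonine run-off time-course comparison.

#' Read a UV trace from CSV
#'
#' Expects two columns, position (gradient depth) and absorbance (A254).
#'
#' @param path CSV file.
#' @param sample_id,timepoint Optional metadata carried on the object.
#' @return List of class `uv_trace`.
#' @export
read_uv_trace <- function(path, sample_id = NA_character_,
                          timepoint = NA_real_) {
  d <- utils::read.csv(path)
  if (ncol(d) < 2) stop("trace CSV needs two columns (position, absorbance)")
  trace <- list(positions = d[[1]], absorbance = d[[2]],
                sample_id = sample_id, timepoint = timepoint)
  validate_trace(trace)
  structure(trace, class = "uv_trace")
}

validate_trace <- function(trace) {
  if (length(trace$positions) != length(trace$absorbance))
    stop("positions and absorbance differ in length")
  if (any(diff(trace$positions) <= 0))
    stop("positions must be strictly increasing")
  if (any(!is.finite(trace$absorbance)))
    stop("absorbance values must be finite")
  invisible(trace)
}

#' Baseline-correct a UV trace
#'
#' `linear` mode subtracts the straight line through the mean levels of
#' the first and last 2% of the trace (the signal-free gradient edges);
#' `rolling_min` subtracts a windowed running minimum. Negative residuals
#' are clipped to zero.
#'
#' @param trace A `uv_trace`.
#' @param mode `"linear"` or `"rolling_min"`.
#' @param window Window width (points) for `rolling_min`.
#' @return The corrected `uv_trace`.
#' @export
baseline_correct <- function(trace, mode = c("linear", "rolling_min"),
                             window = 101L) {
  mode <- match.arg(mode)
  validate_trace(trace)
  n <- length(trace$positions)
  if (n < 10) stop("trace too short for baseline correction (< 10 points)")
  x <- trace$positions; y <- trace$absorbance
  if (mode == "linear") {
    edge <- max(2L, ceiling(0.02 * n))
    lo <- seq_len(edge); hi <- seq(n - edge + 1L, n)
    x1 <- mean(x[lo]); y1 <- mean(y[lo])
    x2 <- mean(x[hi]); y2 <- mean(y[hi])
    slope <- (y2 - y1) / (x2 - x1)
    base <- y1 + slope * (x - x1)
  } else {
    half <- window %/% 2L
    base <- vapply(seq_len(n), function(i) {
      min(y[max(1L, i - half):min(n, i + half)])
    }, numeric(1))
  }
  trace$absorbance <- pmax(y - base, 0)
  trace
}

#' Integrate monosome and polysome regions of a trace
#'
#' Trapezoidal integration of the (baseline-corrected) trace over the
#' monosome (80S, MS) and polysome (PS) regions, and their PS/MS ratio —
#' the standard readout of polysome loading.
#'
#' @param trace A `uv_trace` (already baseline-corrected, or pass
#'   `baseline` to correct here).
#' @param ms,ps Two-element numeric vectors `[a, b]` / `[c, d]` with
#'   `a < b <= c < d`, in trace position units.
#' @param baseline Optional baseline mode forwarded to
#'   [baseline_correct()] (`NULL` = trace used as is).
#' @return List of class `region_areas`: `ms_area`, `ps_area`, `ratio`
#'   (`NA` and `defined = FALSE` when the MS area is 0), `boundaries`.
#' @export
integrate_regions <- function(trace, ms, ps, baseline = NULL) {
  validate_trace(trace)
  if (!is.null(baseline)) trace <- baseline_correct(trace, baseline)
  rng <- range(trace$positions)
  if (ms[1] >= ms[2] || ps[1] >= ps[2] || ms[2] > ps[1])
    stop("regions must satisfy ms[1] < ms[2] <= ps[1] < ps[2]")
  if (ms[1] < rng[1] || ps[2] > rng[2])
    stop("region boundaries outside the trace domain")
  area <- function(a, b) {
    sel <- trace$positions >= a & trace$positions <= b
    pracma::trapz(trace$positions[sel], trace$absorbance[sel])
  }
  ms_area <- area(ms[1], ms[2])
  ps_area <- area(ps[1], ps[2])
  structure(list(ms_area = ms_area, ps_area = ps_area,
                 ratio = if (ms_area > 0) ps_area / ms_area else NA_real_,
                 defined = ms_area > 0,
                 boundaries = list(ms = ms, ps = ps)),
            class = "region_areas")
}

#' Suggest MS/PS boundaries at the valley between labeled peaks
#'
#' Convenience helper: given approximate MS and PS peak positions, returns
#' region boundaries split at the local minimum between them (the
#' boundaries the operator would draw by eye).
#'
#' @param trace A baseline-corrected `uv_trace`.
#' @param ms_peak,ps_peak Approximate peak positions.
#' @return List with `ms` and `ps` boundary pairs.
#' @export
suggest_boundaries <- function(trace, ms_peak, ps_peak) {
  validate_trace(trace)
  stopifnot(ms_peak < ps_peak)
  between <- trace$positions > ms_peak & trace$positions < ps_peak
  valley <- trace$positions[between][which.min(trace$absorbance[between])]
  rng <- range(trace$positions)
  list(ms = c(rng[1], valley), ps = c(valley, rng[2]))
}

#' Compare PS/MS ratios across a run-off time course
#'
#' Tabulates PS/MS by condition and timepoint, reports the case-minus-
#' control ratio contrast per timepoint (omitted with a flag when a
#' timepoint is missing on one side), and checks whether each condition's
#' ratio declines monotonically over time — the expected signature of a
#' harringtonine run-off, where elongating ribosomes complete and
#' polysomes collapse into monosomes.
#'
#' @param areas Data frame with columns `condition`, `timepoint`, `ratio`
#'   (e.g. assembled from [integrate_regions()] results).
#' @param case,control Condition labels to contrast (defaults: first two
#'   conditions in order of appearance).
#' @return List of class `runoff_comparison`: `table` (condition x
#'   timepoint ratios), `contrasts` (per-timepoint case - control, NA where
#'   missing), `monotone_decline` (named logical per condition),
#'   `missing_timepoints`.
#' @export
runoff_compare <- function(areas, case = NULL, control = NULL) {
  stopifnot(all(c("condition", "timepoint", "ratio") %in% names(areas)))
  conds <- unique(areas$condition)
  tps <- sort(unique(areas$timepoint))
  if (length(tps) < 2) stop("need >= 2 timepoints")
  tab <- matrix(NA_real_, length(conds), length(tps),
                dimnames = list(conds, as.character(tps)))
  for (i in seq_len(nrow(areas)))
    tab[areas$condition[i], as.character(areas$timepoint[i])] <-
      areas$ratio[i]
  mono <- apply(tab, 1, function(r) {
    r <- r[!is.na(r)]
    length(r) >= 2 && all(diff(r) < 0)
  })
  contrasts <- NULL
  missing_tp <- character(0)
  if (!is.null(case) || length(conds) >= 2) {
    if (is.null(case)) case <- conds[2]
    if (is.null(control)) control <- conds[1]
    contrasts <- tab[case, ] - tab[control, ]
    missing_tp <- names(contrasts)[is.na(contrasts)]
  }
  structure(list(table = tab, contrasts = contrasts,
                 monotone_decline = mono,
                 missing_timepoints = missing_tp),
            class = "runoff_comparison")
}
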