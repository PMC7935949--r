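# Windowed single-codon pause scoring on P-site coverage profiles,
# replicate-consensus and genotype-exclusive pause sets, and the
# relative-position distribution of paused codons.

#' Per-position pause scores
#'
#' For each position `i`, the background is the mean count over the
#' `window`-nt window centered at `i` (the position itself included;
#' windows are clipped at the transcript ends and the clipped window's true
#' length is used — no zero padding). The score is
#' `count(i) / background(i)` (0 where the background is 0), and the window
#' coverage is the fraction of window positions with at least one read.
#'
#' @param profile Numeric P-site coverage vector for one transcript.
#' @param window Window size in nt (default 1000; must be >= 3).
#' @return Data frame with columns `position` (0-based), `count`, `score`,
#'   `window_coverage`.
#' @export
pause_scores <- function(profile, window = 1000L) {
  if (window < 3) stop("window must be >= 3 nt")
  L <- length(profile)
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window - 1L - half_lo
  pos <- seq_len(L) - 1L
  lo <- pmax(pos - half_lo, 0L)
  hi <- pmin(pos + half_hi, L - 1L)
  cs <- c(0, cumsum(profile))
  wlen <- hi - lo + 1L
  bg <- (cs[hi + 2L] - cs[lo + 1L]) / wlen
  cz <- c(0, cumsum(profile > 0))
  cov <- (cz[hi + 2L] - cz[lo + 1L]) / wlen
  score <- ifelse(bg > 0, profile / bg, 0)
  data.frame(position = pos, count = profile, score = score,
             window_coverage = cov)
}

#' Call single-codon pauses on one transcript profile
#'
#' Positions with `score >= fold_min` (threshold inclusive), window
#' coverage at least `min_window_coverage`, and lying within the CDS become
#' calls; within each codon only the maximal-score nucleotide is retained,
#' so there is at most one call per codon. When the transcript sequence is
#' supplied, each call carries its codon 3-mer.
#'
#' @param profile Coverage vector, or precomputed [pause_scores()] output.
#' @param model One-row transcript model.
#' @param fold_min Minimum fold over background (default 5).
#' @param min_window_coverage Minimum fraction of covered window positions
#'   (default 0.05, i.e. 5%).
#' @param sequence Optional transcript nucleotide string.
#' @param sample_id Sample label carried into the calls.
#' @param window Window size (used when `profile` is a coverage vector).
#' @return Data frame of pause calls: `transcript_id`, `sample_id`,
#'   `nt_position` (0-based), `codon_index` (0-based), `codon`, `score`,
#'   `window_coverage`, `count`.
#' @export
call_pauses <- function(profile, model, fold_min = 5,
                        min_window_coverage = 0.05, sequence = NULL,
                        sample_id = NA_character_, window = 1000L) {
  scores <- if (is.data.frame(profile)) profile
            else pause_scores(profile, window)
  in_cds <- scores$position >= model$cds_start &
    scores$position < model$cds_end
  hit <- in_cds & scores$score >= fold_min &
    scores$window_coverage >= min_window_coverage
  empty <- data.frame(transcript_id = character(), sample_id = character(),
                      nt_position = integer(), codon_index = integer(),
                      codon = character(), score = numeric(),
                      window_coverage = numeric(), count = numeric(),
                      stringsAsFactors = FALSE)
  if (!any(hit)) return(empty)
  h <- scores[hit, ]
  h$codon_index <- (h$position - model$cds_start) %/% 3L
  # one call per codon: maximal score, ties to the 5'-most nucleotide
  h <- h[order(h$codon_index, -h$score, h$position), ]
  h <- h[!duplicated(h$codon_index), ]
  codon <- rep(NA_character_, nrow(h))
  if (!is.null(sequence)) {
    start <- model$cds_start + 3L * h$codon_index + 1L
    codon <- substring(sequence, start, start + 2L)
  }
  data.frame(transcript_id = model$transcript_id, sample_id = sample_id,
             nt_position = h$position, codon_index = h$codon_index,
             codon = codon, score = h$score,
             window_coverage = h$window_coverage, count = h$count,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call pauses over a whole coverage set
#'
#' @param profiles A `ribo_coverage` (named list of coverage vectors).
#' @param models Transcript models.
#' @param sequences Optional named vector of transcript sequences.
#' @param ... Passed to [call_pauses()].
#' @return Row-bound pause calls across transcripts.
#' @export
call_pauses_all <- function(profiles, models, sequences = NULL, ...) {
  out <- lapply(seq_len(nrow(models)), function(i) {
    tx <- models$transcript_id[i]
    v <- profiles[[tx]]
    if (is.null(v)) return(NULL)
    call_pauses(v, models[i, ],
                sequence = if (!is.null(sequences)) sequences[[tx]], ...)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out))
    out <- call_pauses(numeric(3), data.frame(transcript_id = "x",
                                              cds_start = 0, cds_end = 3))
  rownames(out) <- NULL
  out
}

pause_keys <- function(calls) {
  if (!nrow(calls)) return(character(0))
  unique(paste(calls$transcript_id, calls$codon_index, sep = "\r"))
}

keys_to_df <- function(keys) {
  if (!length(keys))
    return(data.frame(transcript_id = character(), codon_index = integer(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(transcript_id = vapply(parts, `[[`, "", 1L),
             codon_index = as.integer(vapply(parts, `[[`, "", 2L)),
             stringsAsFactors = FALSE)
}

#' Replicate-consensus pause set
#'
#' Returns the (transcript, codon) pairs called in at least `k` of the
#' supplied replicates; by default `k` equals the number of replicates, so
#' a codon must pause in every replicate to be retained.
#'
#' @param call_list List of per-replicate pause-call data frames.
#' @param k Minimum number of replicates supporting a codon.
#' @return Data frame with `transcript_id`, `codon_index`, `n_replicates`.
#' @export
consensus_pauses <- function(call_list, k = length(call_list)) {
  stopifnot(length(call_list) >= 1, k >= 1, k <= length(call_list))
  keys <- unlist(lapply(call_list, pause_keys))
  if (!length(keys)) {
    out <- keys_to_df(character(0)); out$n_replicates <- integer(0)
    return(out)
  }
  tab <- table(keys)
  keep <- names(tab)[tab >= k]
  out <- keys_to_df(keep)
  out$n_replicates <- as.integer(tab[keep])
  out <- out[order(out$transcript_id, out$codon_index), ]
  rownames(out) <- NULL
  out
}

#' Genotype-exclusive pause set
#'
#' Removes from a case consensus set every (transcript, codon) pair called
#' in any control replicate (union over controls).
#'
#' @param case_common Consensus data frame from [consensus_pauses()].
#' @param control_calls List of per-replicate control pause-call data
#'   frames (or a single data frame).
#' @return Subset of `case_common` absent from all control replicates.
#' @export
exclusive_pauses <- function(case_common, control_calls) {
  if (is.data.frame(control_calls)) control_calls <- list(control_calls)
  ctrl_keys <- unique(unlist(lapply(control_calls, pause_keys)))
  case_keys <- paste(case_common$transcript_id, case_common$codon_index,
                     sep = "\r")
  out <- case_common[!(case_keys %in% ctrl_keys), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Relative-position distribution of paused codons
#'
#' Each pause is placed at `(codon_index + 0.5) / n_codons` of its CDS
#' (midpoint of the codon, in codon units), giving values in (0, 1); the
#' mean summarizes whether pauses concentrate 5' (< 0.5) or 3' (> 0.5).
#'
#' @param calls Pause calls (or consensus set) with `transcript_id` and
#'   `codon_index`.
#' @param models Transcript models.
#' @return List of class `pause_positions`: `relative_position` vector,
#'   `mean` (NA and `defined = FALSE` when empty).
#' @export
pause_position_distribution <- function(calls, models) {
  mi <- match(calls$transcript_id, models$transcript_id)
  n_codons <- (models$cds_end[mi] - models$cds_start[mi]) %/% 3L
  rel <- (calls$codon_index + 0.5) / n_codons
  structure(list(relative_position = rel,
                 mean = if (length(rel)) mean(rel) else NA_real_,
                 defined = length(rel) > 0),
            class = "pause_positions")
}
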