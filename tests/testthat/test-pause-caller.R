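test_that("pause scores reproduce the centered-window arithmetic", {
  # uniform positive profile: score 1 everywhere, full coverage
  u <- pause_scores(rep(3, 50), window = 10)
  expect_true(all(abs(u$score - 1) < 1e-12))
  expect_true(all(u$window_coverage == 1))
  # background 2 with one spike of 20, window fully inside:
  # score = 20 / ((999*2 + 20)/1000) = 9.911
  prof <- rep(2, 3000); prof[1501] <- 20
  s <- pause_scores(prof, window = 1000)
  expect_equal(s$score[1501], 20 / ((999 * 2 + 20) / 1000),
               tolerance = 1e-12)
  expect_equal(round(s$score[1501], 3), 9.911)
  # all-zero profile: scores and coverage all 0
  z <- pause_scores(numeric(100), window = 10)
  expect_true(all(z$score == 0))
  expect_true(all(z$window_coverage == 0))
  expect_error(pause_scores(rep(1, 10), window = 2), ">= 3")
})

test_that("window clipping uses the truncated window's true length", {
  prof <- c(10, rep(1, 99))
  s <- pause_scores(prof, window = 11)
  # position 0: window [0, 5], mean = (10 + 5)/6
  expect_equal(s$score[1], 10 / (15 / 6), tolerance = 1e-12)
  expect_equal(s$window_coverage[1], 1)
})

test_that("scores are invariant to profile scaling", {
  set.seed(4)
  prof <- rpois(500, 2)
  s1 <- pause_scores(prof, 100)
  s2 <- pause_scores(prof * 7.3, 100)
  expect_equal(s1$score, s2$score, tolerance = 1e-12)
})

test_that("pause calls gate on fold, coverage and CDS membership", {
  model <- tx_model("tx1", length = 2100L, cds_start = 60L,
                    cds_end = 2040L)
  prof <- rep(2, 2100)
  prof[1001] <- 30
  calls <- call_pauses(prof, model, window = 1000)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$nt_position, 1000)
  expect_equal(calls$codon_index, (1000 - 60) %/% 3)
  # score exactly at the threshold is called (inclusive boundary rule);
  # feed precomputed scores so the boundary value is exact
  s2 <- data.frame(position = 0:2099, count = 1,
                   score = 1, window_coverage = 1)
  s2$score[1001] <- 5
  expect_equal(nrow(call_pauses(s2, model)), 1)
  s2$score[1001] <- 5 - 1e-9
  expect_equal(nrow(call_pauses(s2, model)), 0)
  # high score but sparse window -> rejected on coverage
  sparse <- numeric(2100)
  sparse[1001] <- 50
  sparse[seq(1, 2100, by = 200)] <- 1  # ~1% of window covered
  s3 <- pause_scores(sparse, 1000)
  expect_gt(s3$score[1001], 5)
  expect_lt(s3$window_coverage[1001], 0.05)
  expect_equal(nrow(call_pauses(sparse, model, window = 1000)), 0)
  # spike outside the CDS is never a call
  prof3 <- rep(2, 2100)
  prof3[30] <- 40
  got3 <- call_pauses(prof3, model, window = 1000)
  expect_false(30 %in% (got3$nt_position + 1))
})

test_that("one call per codon, with the codon identity from the sequence", {
  model <- tx_model("tx1", length = 300L, cds_start = 60L, cds_end = 240L)
  seqs <- paste(rep("A", 300), collapse = "")
  substr(seqs, 61, 63) <- "ATG"
  substr(seqs, 64, 66) <- "GAG"
  prof <- rep(1, 300)
  prof[64] <- 40  # codon 1, nt offsets 63..65 (0-based)
  prof[65] <- 35
  calls <- call_pauses(prof, model, sequence = seqs, window = 100)
  one <- calls[calls$codon_index == 1, ]
  expect_equal(nrow(one), 1)
  expect_equal(one$nt_position, 63)  # maximal-score nt retained
  expect_equal(one$codon, "GAG")
})

test_that("consensus and exclusive sets match exhaustive set algebra", {
  # enumerate random per-replicate call sets over <= 10 codons and compare
  # against a direct set-algebra oracle
  set.seed(42)
  mk_calls <- function(keys) {
    if (!length(keys))
      return(data.frame(transcript_id = character(),
                        codon_index = integer()))
    data.frame(transcript_id = sub("@.*", "", keys),
               codon_index = as.integer(sub(".*@", "", keys)),
               stringsAsFactors = FALSE)
  }
  universe <- as.vector(outer(c("txA", "txB"), 0:4, paste, sep = "@"))
  for (trial in 1:30) {
    case <- lapply(1:3, function(i)
      mk_calls(sample(universe, rbinom(1, 10, 0.4))))
    ctrl <- lapply(1:3, function(i)
      mk_calls(sample(universe, rbinom(1, 10, 0.3))))
    key_of <- function(df) paste(df$transcript_id, df$codon_index,
                                 sep = "@")
    common <- consensus_pauses(case)
    oracle_common <- Reduce(intersect, lapply(case, key_of))
    expect_setequal(key_of(common), oracle_common)
    # k-of-n variant
    common2 <- consensus_pauses(case, k = 2)
    tab <- table(unlist(lapply(case, function(d) unique(key_of(d)))))
    expect_setequal(key_of(common2), names(tab)[tab >= 2])
    excl <- exclusive_pauses(common, ctrl)
    oracle_excl <- setdiff(oracle_common,
                           Reduce(union, lapply(ctrl, key_of)))
    expect_setequal(key_of(excl), oracle_excl)
    # containment: exclusive <= common <= union of replicate calls
    expect_true(all(key_of(excl) %in% key_of(common)))
    expect_true(all(key_of(common) %in%
                      unlist(lapply(case, key_of))))
  }
  # empty inputs give empty sets
  empty <- consensus_pauses(list(mk_calls(character(0)),
                                 mk_calls(character(0))))
  expect_equal(nrow(empty), 0)
  expect_equal(nrow(exclusive_pauses(empty, mk_calls(universe))), 0)
})

test_that("relative pause positions follow the codon-midpoint formula", {
  model <- tx_model("tx1", length = 400L, cds_start = 50L, cds_end = 350L)
  # 100-codon CDS, pause at the first codon -> 0.005
  calls <- data.frame(transcript_id = "tx1", codon_index = 0L)
  d <- pause_position_distribution(calls, model)
  expect_equal(d$relative_position, 0.005)
  expect_equal(d$mean, 0.005)
  # uniform pauses -> mean near 0.5
  calls2 <- data.frame(transcript_id = "tx1", codon_index = 0:99)
  d2 <- pause_position_distribution(calls2, model)
  expect_equal(d2$mean, 0.5, tolerance = 1e-12)
  # empty set: undefined, flagged
  d0 <- pause_position_distribution(calls[0, ], model)
  expect_false(d0$defined)
  expect_true(is.na(d0$mean))
})

test_that("planted pauses are detected and null profiles stay silent", {
  hits <- 0L
  for (seed in 1:25) {
    cfg <- sim_config(seed = seed, n_transcripts = 1, depth = 1e4,
                      cds_length_range = c(900L, 900L),
                      frame0_fraction = 1, multimap_fraction = 0,
                      init_peak_fold = 1,
                      planted_offsets = c(`29` = 14),
                      pause_spec = data.frame(transcript_id = "tx_0001",
                                              codon_index = 150,
                                              fold = 10))
    b <- generate_transcriptome(cfg)
    sim <- simulate_riboseq(b, cfg, "s1")
    cov <- build_coverage(sim$records, b$models, 14)
    calls <- call_pauses(cov$tx_0001, b$models[1, ], window = 1000)
    if (150 %in% calls$codon_index) hits <- hits + 1L
  }
  expect_gte(hits, 24)  # >= 95% sensitivity
  # matched nulls: uniform background (reads spread over all frames so the
  # per-nt profile is flat), no planted pause
  false_calls <- vapply(1:10, function(seed) {
    cfg <- sim_config(seed = 1000 + seed, n_transcripts = 1, depth = 1e4,
                      cds_length_range = c(900L, 900L),
                      frame0_fraction = 1 / 3,
                      multimap_fraction = 0, init_peak_fold = 1,
                      planted_offsets = c(`29` = 14))
    b <- generate_transcriptome(cfg)
    sim <- simulate_riboseq(b, cfg, "s1")
    cov <- build_coverage(sim$records, b$models, 14)
    as.numeric(nrow(call_pauses(cov$tx_0001, b$models[1, ],
                                window = 1000)))
  }, numeric(1))
  expect_lt(mean(false_calls), 1)
})

test_that("detection rate is non-decreasing in the planted fold", {
  rate_at_fold <- function(fold) {
    hits <- vapply(1:12, function(seed) {
      cfg <- sim_config(seed = 300 + seed, n_transcripts = 1, depth = 3000,
                        cds_length_range = c(900L, 900L),
                        frame0_fraction = 1, multimap_fraction = 0,
                        init_peak_fold = 1,
                        planted_offsets = c(`29` = 14),
                        pause_spec = data.frame(transcript_id = "tx_0001",
                                                codon_index = 150,
                                                fold = fold))
      b <- generate_transcriptome(cfg)
      sim <- simulate_riboseq(b, cfg, "s1")
      cov <- build_coverage(sim$records, b$models, 14)
      150 %in% call_pauses(cov$tx_0001, b$models[1, ],
                           window = 1000)$codon_index
    }, logical(1))
    mean(hits)
  }
  rates <- vapply(c(5, 10, 20), rate_at_fold, numeric(1))
  expect_true(all(diff(rates) >= 0))
})
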