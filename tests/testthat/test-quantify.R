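test_that("RPF counting uses P-site CDS membership with weight rules", {
  models <- tx_model("tx1", gene_id = "g1", length = 400L, cds_start = 60L,
                     cds_end = 360L)
  # P-site exactly at cds_start is counted (boundary inclusive)
  rec <- align_rec("tx1", 60 - 14)
  expect_equal(unname(count_genes(rec, models, 14, "rpf")["g1"]), 1)
  # P-site at cds_end is excluded (half-open interval)
  rec_end <- align_rec("tx1", 360 - 14)
  expect_equal(unname(count_genes(rec_end, models, 14, "rpf")["g1"]), 0)
  # 4-location read contributes nothing under the cap of 3
  rec4 <- align_rec("tx1", 100, n_locations = 4L)
  expect_equal(unname(count_genes(rec4, models, 14, "rpf")["g1"]), 0)
  # 3-location read contributes 1/3
  rec3 <- align_rec("tx1", 100, n_locations = 3L)
  expect_equal(unname(count_genes(rec3, models, 14, "rpf")["g1"]), 1 / 3)
  # mRNA mode counts by 5' end over the whole transcript
  rec_utr <- align_rec("tx1", 5)
  expect_equal(unname(count_genes(rec_utr, models, source = "mrna")["g1"]),
               1)
  expect_equal(unname(count_genes(rec_utr, models, 14, "rpf")["g1"]), 0)
})

test_that("a read hitting two isoforms of one gene counts once", {
  models <- rbind(tx_model("iso1", gene_id = "g1", length = 400L,
                           cds_start = 60L, cds_end = 360L),
                  tx_model("iso2", gene_id = "g1", length = 400L,
                           cds_start = 60L, cds_end = 360L))
  rec <- align_rec(c("iso1", "iso2"), c(100, 100), read_id = c("m", "m"),
                   n_locations = 2L)
  got <- count_genes(rec, models, 14, "rpf")
  expect_equal(unname(got["g1"]), 0.5)
  expect_equal(unname(attr(got, "tally")["gene_dedup"]), 0.5)
})

test_that("gene counting matches the brute-force per-read oracle", {
  set.seed(99)
  models <- rbind(tx_model("tx1", gene_id = "g1", length = 500L,
                           cds_start = 90L, cds_end = 390L),
                  tx_model("tx2", gene_id = "g1", length = 450L,
                           cds_start = 60L, cds_end = 420L),
                  tx_model("tx3", gene_id = "g2", length = 380L,
                           cds_start = 60L, cds_end = 300L))
  n <- 200
  rec <- align_rec(sample(models$transcript_id, n, replace = TRUE),
                   sample(0:340, n, replace = TRUE),
                   read_length = 29L,
                   n_locations = sample(1:4, n, replace = TRUE),
                   read_id = sprintf("r%03d", sample(120, n, replace = TRUE)))
  for (src in c("rpf", "mrna")) {
    got <- count_genes(rec, models, 14, src)
    oracle <- brute_count_genes(rec, models, 14, src)
    expect_equal(got[sort(names(got))], oracle[sort(names(oracle))],
                 ignore_attr = TRUE, tolerance = 1e-12)
    # conservation: counted + dropped + dedup-collapsed = input weight
    tally <- attr(got, "tally")
    w <- ifelse(rec$n_locations > 3, 0, 1 / rec$n_locations)
    expect_equal(sum(got) + sum(tally[c("outside", "unknown_reference",
                                        "gene_dedup")]),
                 sum(w), tolerance = 1e-9)
  }
})

test_that("TMM on identical columns gives unit factors", {
  set.seed(1)
  counts <- matrix(rpois(400, 50), ncol = 4,
                   dimnames = list(sprintf("g%d", 1:100),
                                   sprintf("s%d", 1:4)))
  counts[, 2] <- counts[, 1]
  counts[, 3] <- counts[, 1]
  counts[, 4] <- counts[, 1]
  n <- tmm_normalize(counts)
  expect_true(all(abs(n$factors - 1) < 1e-9))
  expect_true(all(abs(n$normalized[, 1] - n$normalized[, 2]) < 1e-12))
  expect_equal(unname(n$lib_sizes), unname(colSums(counts)))
  expect_equal(exp(mean(log(n$factors))), 1, tolerance = 1e-6)
})

test_that("a uniformly scaled library normalizes back onto the others", {
  set.seed(2)
  base <- rpois(500, 100)
  counts <- cbind(s1 = base, s2 = base * 2L)
  rownames(counts) <- sprintf("g%d", seq_along(base))
  n <- tmm_normalize(counts)
  dev <- abs(n$normalized[, 1] - n$normalized[, 2])
  expect_lt(max(dev), 0.01)
  expect_error(tmm_normalize(cbind(a = rep(0, 5), b = rpois(5, 10))),
               "all-zero")
  expect_error(tmm_normalize(matrix(1:5, ncol = 1)), "2 samples")
})

test_that("TMM is scale-invariant in the no-DE case", {
  # deep libraries so the fixed pseudocount is negligible
  set.seed(3)
  base <- matrix(rnbinom(300 * 4, mu = 2000, size = 50), ncol = 4,
                 dimnames = list(sprintf("g%d", 1:300),
                                 sprintf("s%d", 1:4)))
  n1 <- tmm_normalize(base)
  scaled <- base
  scaled[, 2] <- base[, 2] * 3
  n2 <- tmm_normalize(scaled)
  expect_lt(max(abs(n1$normalized - n2$normalized)), 1e-3)
})

test_that("genes absent from the TMM reference do not move the scaling", {
  # rows zero in one column are excluded from the trimmed M/A sets, so
  # between-sample contrasts of normalized values are unaffected by
  # appending such rows (absolute values shift only through library size)
  set.seed(4)
  counts <- matrix(rpois(200 * 2, 2000), ncol = 2,
                   dimnames = list(sprintf("g%d", 1:200), c("a", "b")))
  n1 <- tmm_normalize(counts)$normalized
  extra <- matrix(c(rep(0, 20), rpois(20, 2000)), ncol = 2,
                  dimnames = list(sprintf("z%d", 1:20), c("a", "b")))
  n2 <- tmm_normalize(rbind(counts, extra))$normalized
  d1 <- n1[, "b"] - n1[, "a"]
  d2 <- n2[rownames(n1), "b"] - n2[rownames(n1), "a"]
  expect_lt(max(abs(d1 - d2)), 1e-3)
})

test_that("occupancy log2FC has the expected closed-form behavior", {
  rpf <- matrix(c(1, 1, 2, 2), nrow = 1,
                dimnames = list("g1", c("c1", "c2", "t1", "t2")))
  mrna <- matrix(c(1, 1, 1, 1), nrow = 1,
                 dimnames = list("g1", c("c1", "c2", "t1", "t2")))
  groups <- list(case = c("t1", "t2"), control = c("c1", "c2"))
  # RPF doubles (on log2 scale +1), mRNA flat -> +1
  expect_equal(as.numeric(occupancy_log2fc(rpf, mrna, groups)), 1)
  # both double -> 0
  expect_equal(as.numeric(occupancy_log2fc(rpf, rpf, groups)), 0)
  # antisymmetry under case/control swap
  set.seed(6)
  r <- matrix(rnorm(40), 10, 4,
              dimnames = list(sprintf("g%d", 1:10),
                              c("c1", "c2", "t1", "t2")))
  m <- matrix(rnorm(40), 10, 4, dimnames = dimnames(r))
  fwd <- occupancy_log2fc(r, m, groups)
  rev <- occupancy_log2fc(r, m, list(case = groups$control,
                                     control = groups$case))
  expect_equal(as.numeric(fwd), as.numeric(-rev))
})

test_that("planted TE changes are recovered through the count pipeline", {
  cs <- data.frame(category = "rpf_up_mrna_same", n = 400, fold = 4)
  sim <- simulate_count_matrix(n_genes = 2000, dispersion = 0.05,
                               category_spec = cs, seed = 71)
  groups <- list(case = sprintf("case_%d", 1:3),
                 control = sprintf("ctrl_%d", 1:3))
  d <- occupancy_log2fc(tmm_normalize(sim$rpf)$normalized,
                        tmm_normalize(sim$mrna)$normalized, groups)
  planted <- sim$truth$category == "rpf_up_mrna_same"
  expect_lt(abs(mean(d[planted]) - 2), 0.3)
  expect_lt(abs(mean(d[!planted])), 0.2)
})
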