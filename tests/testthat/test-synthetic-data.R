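test_that("transcriptome generation enforces structure and determinism", {
  cfg <- sim_config(seed = 11, n_transcripts = 50)
  b <- generate_transcriptome(cfg)
  expect_equal(nrow(b$models), 50)
  expect_setequal(names(b$sequences), b$models$transcript_id)
  for (i in seq_len(nrow(b$models))) {
    m <- b$models[i, ]
    s <- b$sequences[[m$transcript_id]]
    expect_gte(m$cds_start, 60)
    expect_equal((m$cds_end - m$cds_start) %% 3, 0)
    expect_equal(substr(s, m$cds_start + 1, m$cds_start + 3), "ATG")
    expect_true(substr(s, m$cds_end - 2, m$cds_end) %in%
                  c("TAA", "TAG", "TGA"))
    expect_equal(nchar(s), m$length)
  }
  # byte-identical regeneration, including written files
  b2 <- generate_transcriptome(cfg)
  expect_identical(b, b2)
  d1 <- tempfile(); d2 <- tempfile()
  write_bundle(b, d1); write_bundle(b2, d2)
  for (f in c("transcripts.fa", "annotation.gtf", "annotation.tsv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("single-transcript config honors requested CDS length", {
  cfg <- sim_config(seed = 2, n_transcripts = 1,
                    cds_length_range = c(300L, 300L))
  b <- generate_transcriptome(cfg)
  expect_equal(b$models$cds_end - b$models$cds_start, 300)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_transcripts = 0), "n_transcripts")
  expect_error(sim_config(frame0_fraction = 1.5), "frame0_fraction")
  expect_error(sim_config(planted_offsets = c(`29` = 20)), "offsets")
  expect_error(sim_config(nb_dispersion = 0), "dispersion")
  expect_error(sim_config(pause_spec = data.frame(
    transcript_id = "tx", codon_index = 1, fold = 0.5)), "fold")
  expect_error(sim_config(cds_length_range = c(500, 100)),
               "cds_length_range")
})

test_that("simulated RPF reads obey the read-placement identity", {
  cfg <- sim_config(seed = 21, n_transcripts = 15, depth = 400,
                    multimap_fraction = 0.2)
  b <- generate_transcriptome(cfg)
  sim <- simulate_riboseq(b, cfg, "s1")
  tr <- sim$truth$reads
  origin <- sim$records[match(tr$read_id, sim$records$read_id), ]
  off <- cfg$planted_offsets[as.character(origin$read_length)]
  expect_true(all(origin$pos5 + off == tr$true_psite))
  # reads never straddle the transcript end
  L <- b$models$length[match(sim$records$transcript_id,
                             b$models$transcript_id)]
  expect_true(all(sim$records$pos5 >= 0))
  expect_true(all(sim$records$pos5 + sim$records$read_length <= L))
  # multimapped reads appear once per location with shared n_locations
  multi <- sim$records[sim$records$n_locations > 1, ]
  if (nrow(multi)) {
    per_read <- table(multi$read_id)
    k <- multi$n_locations[match(names(per_read), multi$read_id)]
    expect_equal(as.integer(per_read), as.integer(k))
    expect_true(all(multi$mapq == 1))
  }
  expect_true(all(sim$records$mapq[sim$records$n_locations == 1] == 255))
})

test_that("frame0_fraction = 1 forces perfect frame-0 placement", {
  cfg <- sim_config(seed = 3, n_transcripts = 5, depth = 300,
                    frame0_fraction = 1, multimap_fraction = 0,
                    planted_offsets = c(`29` = 14))
  b <- generate_transcriptome(cfg)
  sim <- simulate_riboseq(b, cfg, "s1")
  cds_start <- b$models$cds_start[match(sim$records$transcript_id,
                                        b$models$transcript_id)]
  expect_true(all((sim$records$pos5 + 14 - cds_start) %% 3 == 0))
})

test_that("multimap_fraction = 0 yields only unique records", {
  cfg <- sim_config(seed = 4, n_transcripts = 5, depth = 100,
                    multimap_fraction = 0)
  b <- generate_transcriptome(cfg)
  sim <- simulate_riboseq(b, cfg, "s1")
  expect_true(all(sim$records$n_locations == 1))
})

test_that("planted pause enrichment matches its fold at depth 1e4", {
  # uniform weights apart from the pause, so observed/expected is clean
  folds_ok <- vapply(1:20, function(seed) {
    cfg <- sim_config(seed = seed, n_transcripts = 1, depth = 1e4,
                      cds_length_range = c(600L, 600L),
                      frame0_fraction = 1, multimap_fraction = 0,
                      init_peak_fold = 1,
                      planted_offsets = c(`29` = 14),
                      pause_spec = data.frame(transcript_id = "tx_0001",
                                              codon_index = 50, fold = 10))
    b <- generate_transcriptome(cfg)
    sim <- simulate_riboseq(b, cfg, "s1")
    counts <- table(sim$truth$reads$codon_index)
    n_codons <- 200
    expected_per_codon <- nrow(sim$truth$reads) / (n_codons - 1 + 10)
    obs <- counts[["50"]] / expected_per_codon
    obs >= 7 && obs <= 13
  }, logical(1))
  expect_true(all(folds_ok))
})

test_that("pause outside the CDS is a configuration error", {
  cfg <- sim_config(seed = 1, n_transcripts = 1,
                    cds_length_range = c(300L, 300L),
                    pause_spec = data.frame(transcript_id = "tx_0001",
                                            codon_index = 150, fold = 5))
  b <- generate_transcriptome(cfg)
  expect_error(simulate_riboseq(b, cfg), "outside CDS")
})

test_that("RNA-Seq simulation is uniform and seed-stable", {
  cfg <- sim_config(seed = 9, n_transcripts = 3, depth = 3000)
  b <- generate_transcriptome(cfg)
  s1 <- simulate_rnaseq(b, cfg, read_length = 50)
  s2 <- simulate_rnaseq(b, cfg, read_length = 50)
  expect_identical(s1, s2)
  # Poisson moment check on per-nt coverage of one transcript
  m <- b$models[1, ]
  rec <- s1$records[s1$records$transcript_id == m$transcript_id, ]
  cov <- numeric(m$length)
  for (i in seq_len(nrow(rec))) {
    idx <- (rec$pos5[i] + 1):(rec$pos5[i] + rec$read_length[i])
    cov[idx] <- cov[idx] + 1
  }
  expected <- nrow(rec) * 50 / m$length
  expect_lt(abs(mean(cov) - expected), 3 * sqrt(expected))
  # zero depth still yields a valid empty record set and SAM
  cfg0 <- sim_config(seed = 9, n_transcripts = 3, depth = 0,
                     depth_exact = TRUE)
  s0 <- simulate_rnaseq(b, cfg0)
  expect_equal(nrow(s0$records), 0)
  sam <- temp_sam(s0$records, b$models)
  expect_true(all(startsWith(readLines(sam), "@")))
})

test_that("count-matrix simulation plants NB effects where labeled", {
  cs <- data.frame(category = c("rpf_up_mrna_same", "both_down"),
                   n = c(300, 300), fold = 4)
  sim <- simulate_count_matrix(n_genes = 2000, dispersion = 0.05,
                               category_spec = cs, seed = 42)
  expect_identical(sim, simulate_count_matrix(n_genes = 2000,
                                              dispersion = 0.05,
                                              category_spec = cs,
                                              seed = 42))
  up <- sim$truth$category == "rpf_up_mrna_same"
  ratio <- function(mat, rows) {
    mean(rowMeans(mat[rows, 4:6])) / mean(rowMeans(mat[rows, 1:3]))
  }
  # planted fold recovered in the group mean (3 SE slack at n=300)
  expect_lt(abs(ratio(sim$rpf, up) - 4) / 4, 0.15)
  expect_lt(abs(ratio(sim$mrna, up) - 1), 0.15)
  dn <- sim$truth$category == "both_down"
  expect_lt(abs(ratio(sim$rpf, dn) - 0.25) / 0.25, 0.15)
  expect_lt(abs(ratio(sim$mrna, dn) - 0.25) / 0.25, 0.15)
  # no planted effects -> all genes unchanged
  null_sim <- simulate_count_matrix(n_genes = 50, seed = 1)
  expect_true(all(null_sim$truth$category == "unchanged"))
  expect_error(simulate_count_matrix(dispersion = -1), "dispersion")
})

test_that("UV trace simulation matches analytic Gaussian areas", {
  tr <- simulate_uv_trace(data.frame(center = 5, sigma = 0.1,
                                     amplitude = 1))
  sel <- abs(tr$positions - 5) <= 0.6
  num <- pracma::trapz(tr$positions[sel], tr$absorbance[sel])
  expect_lt(abs(num - 0.2506628) / 0.2506628, 0.001)
  expect_equal(tr$truth_areas, 0.1 * sqrt(2 * pi))
  # flat config -> all-zero trace
  flat <- simulate_uv_trace(NULL)
  expect_true(all(flat$absorbance == 0))
  # symmetric peaks -> equal truth areas
  two <- simulate_uv_trace(data.frame(center = c(3, 7), sigma = 0.2,
                                      amplitude = 0.8))
  expect_equal(two$truth_areas[1], two$truth_areas[2])
  expect_error(simulate_uv_trace(data.frame(center = 5, sigma = -1,
                                            amplitude = 1)), "sigma")
  expect_error(simulate_uv_trace(NULL, positions = c(1, 1, 2)),
               "increasing")
})
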