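# Build a complete on-disk synthetic study (annotation, FASTA, Ribo/RNA
# SAMs for 3+3 replicates, two run-off traces) and its run configuration.
make_study <- function(dir, seed = 101, n_transcripts = 20, depth = 400) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim_config(seed = seed, n_transcripts = n_transcripts,
                    depth = depth, multimap_fraction = 0.05,
                    pause_spec = data.frame(transcript_id = "tx_0001",
                                            codon_index = 40, fold = 12))
  b <- generate_transcriptome(cfg)
  paths <- write_bundle(b, dir)
  samples <- list()
  for (cond in c("control", "case")) {
    for (rep_i in 1:3) {
      for (assay in c("ribo", "rna")) {
        sid <- sprintf("%s_%s_%d", assay, cond, rep_i)
        s <- seed + 10 * rep_i + ifelse(cond == "case", 100, 0) +
          ifelse(assay == "ribo", 0, 1000)
        sim <- if (assay == "ribo")
          simulate_riboseq(b, cfg, sid, seed = s)
        else simulate_rnaseq(b, cfg, sid, seed = s)
        sam <- file.path(dir, paste0(sid, ".sam"))
        write_sam(sim$records, b$models, sam)
        samples[[length(samples) + 1]] <-
          list(sample_id = sid, condition = cond, replicate = rep_i,
               assay = assay, sam = sam)
      }
    }
  }
  traces <- list()
  for (tp in c(0, 2)) {
    for (cond in c("control", "case")) {
      amp_ps <- if (cond == "case") 2 else 2 * exp(-0.3 * tp)
      tr <- simulate_uv_trace(data.frame(center = c(3, 7), sigma = 0.3,
                                         amplitude = c(1, amp_ps)),
                              noise_sd = 0.004,
                              seed = seed + tp + nchar(cond))
      p <- file.path(dir, sprintf("trace_%s_t%d.csv", cond, tp))
      write_uv_trace(tr, p)
      traces[[length(traces) + 1]] <-
        list(path = p, condition = cond, timepoint = tp)
    }
  }
  list(annotation = paths[["gtf"]], fasta = paths[["fasta"]],
       samples = samples, traces = traces,
       case_condition = "case", control_condition = "control",
       output_dir = file.path(dir, "out"), seed = seed,
       parameters = list(trace_ms = c(1, 5), trace_ps = c(5, 9),
                         metagene_min_reads = 50))
}
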