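# Configuration validation and end-to-end orchestration:
# ingest -> calibrate -> count -> normalize -> occupancy -> pauses ->
# shift (-> traces), with per-stage TSV outputs and a JSON summary.

default_parameters <- function() {
  list(min_mapq = 5, length_range = c(26L, 32L), max_locations = 3L,
       offset_mode = "fixed", fixed_offset = 14,
       metagene_window = c(-40L, 20L), metagene_min_reads = 100,
       pause_fold = 5, pause_window = 1000L, pause_coverage = 0.05,
       consensus_k = NULL,
       fc_min = 2, p_max = 0.05, fdr_max = 0.15,
       k_sd = 2, min_mass = 10,
       trace_baseline = "linear", trace_ms = NULL, trace_ps = NULL)
}

check_range <- function(errors, value, key, lo, hi, lo_open = FALSE,
                        hi_open = FALSE) {
  bad <- (lo_open && value <= lo) || (!lo_open && value < lo) ||
    (hi_open && value >= hi) || (!hi_open && value > hi)
  if (any(bad))
    errors <- c(errors, sprintf("'%s' out of range: %s", key,
                                paste(value, collapse = ", ")))
  errors
}

#' Validate a run configuration
#'
#' Reads a YAML file (or takes an equivalent list), fills defaults, and
#' checks every path, sample-sheet entry and parameter range. All
#' violations are collected and reported together. Unknown keys raise an
#' error with a closest-match suggestion.
#'
#' Default stage parameters mirror the standard analysis: fixed P-site
#' offset 14 nt for counting, per-length metagene offsets for pause
#' calling, RPF lengths 26-32 nt, MAPQ >= 5, multimap cap 3, pause fold 5
#' over a 1000-nt window with 5% window coverage, and classification at
#' fold change > 2, nominal P < 0.05, FDR 0.15.
#'
#' @param config Path to a YAML file, or a list with the same structure:
#'   `annotation`, optional `fasta`, `samples` (list of records with
#'   `sample_id`, `condition`, `replicate`, `assay` in `{ribo, rna}`,
#'   `sam`), optional `traces` (records with `path`, `condition`,
#'   `timepoint`), `case_condition`, `control_condition`, `output_dir`,
#'   `seed`, and a `parameters` block.
#' @return Validated config list of class `run_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  known <- c("annotation", "fasta", "samples", "traces", "case_condition",
             "control_condition", "output_dir", "seed", "parameters")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    sugg <- vapply(unknown, function(k) {
      hit <- known[agrepl(k, known, max.distance = 0.3)]
      if (length(hit)) paste0(" (did you mean '", hit[1], "'?)") else ""
    }, "")
    stop("unknown config key(s): ",
         paste0("'", unknown, "'", sugg, collapse = ", "))
  }
  errors <- character(0)
  if (is.null(config$annotation)) {
    errors <- c(errors, "'annotation' is required")
  } else if (!file.exists(config$annotation)) {
    errors <- c(errors, paste0("annotation file not found: ",
                               config$annotation))
  }
  if (!is.null(config$fasta) && !file.exists(config$fasta))
    errors <- c(errors, paste0("fasta file not found: ", config$fasta))
  if (is.null(config$samples) || !length(config$samples)) {
    errors <- c(errors, "'samples' must list at least one sample")
    sheet <- NULL
  } else {
    sheet <- do.call(rbind, lapply(config$samples, function(s) {
      data.frame(sample_id = s$sample_id %||% NA_character_,
                 condition = s$condition %||% NA_character_,
                 replicate = s$replicate %||% NA_integer_,
                 assay = s$assay %||% NA_character_,
                 sam = s$sam %||% NA_character_,
                 stringsAsFactors = FALSE)
    }))
    if (anyNA(sheet))
      errors <- c(errors, paste("sample sheet rows need sample_id,",
                                "condition, replicate, assay, sam"))
    bad_assay <- !sheet$assay %in% c("ribo", "rna")
    if (any(bad_assay, na.rm = TRUE))
      errors <- c(errors, paste0("assay must be 'ribo' or 'rna' for: ",
                                 paste(sheet$sample_id[bad_assay],
                                       collapse = ", ")))
    missing_sam <- !is.na(sheet$sam) & !file.exists(sheet$sam)
    if (any(missing_sam))
      errors <- c(errors, paste0("SAM file not found: ",
                                 paste(sheet$sam[missing_sam],
                                       collapse = ", ")))
    if (anyDuplicated(sheet$sample_id))
      errors <- c(errors, "duplicate sample_id in sample sheet")
  }
  params <- default_parameters()
  if (!is.null(config$parameters)) {
    unknown_p <- setdiff(names(config$parameters), names(params))
    if (length(unknown_p)) {
      sugg <- vapply(unknown_p, function(k) {
        hit <- names(params)[agrepl(k, names(params), max.distance = 0.3)]
        if (length(hit)) paste0(" (did you mean '", hit[1], "'?)") else ""
      }, "")
      stop("unknown parameter key(s): ",
           paste0("'", unknown_p, "'", sugg, collapse = ", "))
    }
    params[names(config$parameters)] <- config$parameters
  }
  errors <- check_range(errors, params$pause_fold, "pause_fold", 1, Inf)
  errors <- check_range(errors, params$fdr_max, "fdr_max", 0, 1,
                        lo_open = TRUE)
  errors <- check_range(errors, params$p_max, "p_max", 0, 1, lo_open = TRUE)
  errors <- check_range(errors, params$fc_min, "fc_min", 1, Inf,
                        lo_open = TRUE)
  errors <- check_range(errors, params$pause_coverage, "pause_coverage", 0, 1)
  errors <- check_range(errors, params$min_mapq, "min_mapq", 0, Inf)
  errors <- check_range(errors, params$max_locations, "max_locations", 1,
                        Inf)
  errors <- check_range(errors, params$pause_window, "pause_window", 3, Inf)
  if (!params$offset_mode %in% c("fixed", "metagene"))
    errors <- c(errors, "'offset_mode' must be 'fixed' or 'metagene'")
  if (length(errors))
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "))
  structure(list(annotation = config$annotation, fasta = config$fasta,
                 samples = sheet, traces = config$traces,
                 case_condition = config$case_condition,
                 control_condition = config$control_condition,
                 output_dir = config$output_dir %||% "ribostall_out",
                 seed = as.integer(config$seed %||% 1L),
                 parameters = params),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_stage <- function(df, dir, name) {
  path <- file.path(dir, paste0(name, ".tsv"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes ingest, offset calibration, periodicity QC, gene counting, TMM
#' normalization, occupancy testing and classification, pause calling with
#' consensus/exclusive sets, center-of-density shift analysis, and (when
#' traces are configured) polysome-trace quantification. Every stage
#' writes a TSV into the output directory; a JSON summary records stage
#' outputs, filter tallies, timings and md5 checksums. The run is
#' deterministic given the same configuration.
#'
#' @param config A `run_config` from [validate_config()] (or a path/list
#'   accepted by it).
#' @return Invisibly, a list of in-memory stage results plus the summary.
#' @export
run_all <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  p <- config$parameters
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  tallies <- list()
  timings <- c()
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    say("[%s] done in %.2f s", name, timings[[name]])
    res
  }

  models <- stage("annotation", read_annotation(config$annotation))
  sequences <- NULL
  if (!is.null(config$fasta)) {
    ss <- Biostrings::readDNAStringSet(config$fasta)
    sequences <- stats::setNames(as.character(ss),
                                 sub("\\s.*", "", names(ss)))
  }
  sheet <- config$samples
  ribo <- sheet[sheet$assay == "ribo", ]
  rna <- sheet[sheet$assay == "rna", ]

  records <- stage("ingest", {
    recs <- list()
    for (i in seq_len(nrow(sheet))) {
      s <- sheet[i, ]
      lr <- if (s$assay == "ribo") p$length_range else NULL
      r <- read_alignments(s$sam, models, min_mapq = p$min_mapq,
                           length_range = lr)
      tallies[[s$sample_id]] <- as.list(attr(r, "tally"))
      recs[[s$sample_id]] <- r
    }
    recs
  })

  calib <- stage("calibrate", {
    pooled <- do.call(rbind, records[ribo$sample_id])
    mg <- metagene_matrix(pooled, models, window = p$metagene_window)
    pause_offsets <- calibrate_offsets(mg, mode = "metagene",
                                       fixed_offset = p$fixed_offset,
                                       min_reads = p$metagene_min_reads)
    count_offsets <- if (p$offset_mode == "fixed")
      psite_offsets(p$fixed_offset, "fixed") else pause_offsets
    utils::write.table(as.data.frame.matrix(unclass(mg)),
                       file.path(config$output_dir, "metagene_matrix.tsv"),
                       sep = "\t", quote = FALSE)
    outputs <- c(outputs, write_offsets(
      pause_offsets, file.path(config$output_dir, "psite_offsets.tsv")),
      file.path(config$output_dir, "metagene_matrix.tsv"))
    list(metagene = mg, pause_offsets = pause_offsets,
         count_offsets = count_offsets)
  })

  coverage <- stage("coverage", {
    cov <- lapply(ribo$sample_id, function(s) {
      build_coverage(records[[s]], models, calib$pause_offsets,
                     max_locations = p$max_locations)
    })
    names(cov) <- ribo$sample_id
    for (s in ribo$sample_id) {
      bg <- file.path(config$output_dir, paste0("coverage_", s, ".bedgraph"))
      export_bedgraph(cov[[s]], bg)
      outputs <- c(outputs, bg)
    }
    cov
  })

  qc <- stage("periodicity", {
    fr <- lapply(coverage, frame_periodicity, models = models)
    df <- do.call(rbind, lapply(names(fr), function(s) {
      data.frame(sample_id = s, frame0 = fr[[s]]$fractions[1],
                 frame1 = fr[[s]]$fractions[2],
                 frame2 = fr[[s]]$fractions[3],
                 total_mass = fr[[s]]$total_mass)
    }))
    outputs <- c(outputs, write_stage(df, config$output_dir,
                                       "frame_report"))
    fr
  })

  counts <- stage("count", {
    rpf <- count_matrix(records[ribo$sample_id], models,
                        offsets = calib$count_offsets, source = "rpf",
                        max_locations = p$max_locations)
    mrna <- if (nrow(rna))
      count_matrix(records[rna$sample_id], models, source = "mrna",
                   max_locations = p$max_locations) else NULL
    outputs <- c(outputs,
                  write_stage(data.frame(gene_id = rownames(rpf), rpf,
                                         check.names = FALSE),
                              config$output_dir, "counts_rpf"))
    if (!is.null(mrna))
      outputs <- c(outputs,
                    write_stage(data.frame(gene_id = rownames(mrna), mrna,
                                           check.names = FALSE),
                                config$output_dir, "counts_mrna"))
    list(rpf = rpf, mrna = mrna)
  })

  case_cond <- config$case_condition %||% setdiff(unique(sheet$condition),
                                                  sheet$condition[1])[1]
  ctrl_cond <- config$control_condition %||% sheet$condition[1]

  norm <- stage("normalize", {
    n <- list(rpf = tmm_normalize(counts$rpf))
    if (!is.null(counts$mrna)) n$mrna <- tmm_normalize(counts$mrna)
    fdf <- data.frame(sample_id = names(n$rpf$factors),
                      source = "rpf", factor = n$rpf$factors,
                      lib_size = n$rpf$lib_sizes)
    if (!is.null(n$mrna))
      fdf <- rbind(fdf, data.frame(sample_id = names(n$mrna$factors),
                                   source = "mrna",
                                   factor = n$mrna$factors,
                                   lib_size = n$mrna$lib_sizes))
    outputs <- c(outputs, write_stage(fdf, config$output_dir,
                                       "tmm_factors"))
    n
  })

  occupancy <- NULL
  ribo_case <- ribo$sample_id[ribo$condition == case_cond]
  ribo_ctrl <- ribo$sample_id[ribo$condition == ctrl_cond]
  rna_case <- rna$sample_id[rna$condition == case_cond]
  rna_ctrl <- rna$sample_id[rna$condition == ctrl_cond]
  if (!is.null(norm$mrna) && length(ribo_case) >= 2 &&
      length(ribo_ctrl) >= 2 && length(rna_case) >= 2 &&
      length(rna_ctrl) >= 2) {
    occupancy <- stage("occupancy", {
      # align mRNA columns with RPF replicate order (condition/replicate)
      rpf_cols <- c(ribo_ctrl, ribo_case)
      rna_cols <- c(rna_ctrl, rna_case)
      rpf_n <- norm$rpf$normalized[, rpf_cols]
      rna_n <- norm$mrna$normalized[, rna_cols]
      colnames(rna_n) <- colnames(rpf_n)
      res <- apv_test(rpf_n, rna_n,
                      list(case = ribo_case, control = ribo_ctrl))
      res <- classify_genes(res, fc_min = p$fc_min, p_max = p$p_max,
                            fdr_max = p$fdr_max)
      outputs <- c(outputs, write_stage(res, config$output_dir,
                                         "occupancy"))
      summ <- as.data.frame(table(category = res$category),
                            responseName = "n_genes")
      outputs <- c(outputs, write_stage(summ, config$output_dir,
                                         "occupancy_summary"))
      res
    })
  } else {
    say("[occupancy] skipped: needs mRNA data and >= 2 replicates per condition")
  }

  pauses <- stage("pauses", {
    per_rep <- lapply(ribo$sample_id, function(s) {
      call_pauses_all(coverage[[s]], models, sequences,
                      fold_min = p$pause_fold,
                      min_window_coverage = p$pause_coverage,
                      sample_id = s, window = p$pause_window)
    })
    names(per_rep) <- ribo$sample_id
    all_calls <- do.call(rbind, per_rep)
    outputs <- c(outputs, write_stage(all_calls, config$output_dir,
                                       "pause_calls"))
    res <- list(per_replicate = per_rep, calls = all_calls)
    if (length(ribo_case) >= 2 && length(ribo_ctrl) >= 1) {
      k <- p$consensus_k %||% length(ribo_case)
      common <- consensus_pauses(per_rep[ribo_case], k = k)
      excl <- exclusive_pauses(common, per_rep[ribo_ctrl])
      dist <- pause_position_distribution(excl, models)
      outputs <- c(outputs,
                    write_stage(common, config$output_dir, "pause_common"),
                    write_stage(excl, config$output_dir, "pause_exclusive"))
      res$common <- common; res$exclusive <- excl; res$distribution <- dist
      say("[pauses] %d common, %d exclusive; mean relative position %s",
          nrow(common), nrow(excl),
          if (dist$defined) sprintf("%.3f", dist$mean) else "undefined")
    }
    res
  })

  shift <- NULL
  if (length(ribo_case) >= 1 && length(ribo_ctrl) >= 1) {
    shift <- stage("shift", {
      rho_tab <- center_density_table(coverage, models,
                                      min_mass = p$min_mass)
      outputs <- c(outputs, write_stage(rho_tab, config$output_dir,
                                         "center_density"))
      mean_rho <- function(samples) {
        sub <- rho_tab[rho_tab$sample_id %in% samples, ]
        tapply(sub$rho, sub$transcript_id, function(v) {
          v <- v[!is.na(v)]
          if (length(v)) mean(v) else NA_real_
        })
      }
      res <- tryCatch({
        fit <- shift_regression(mean_rho(ribo_case), mean_rho(ribo_ctrl))
        calls <- classify_shift(fit, k_sd = p$k_sd)
        outputs <- c(outputs, write_stage(calls, config$output_dir,
                                           "shift_calls"))
        say("[shift] %d shift5, %d shift3 of %d transcripts",
            sum(calls$label == "shift5"), sum(calls$label == "shift3"),
            nrow(calls))
        list(fit = fit, calls = calls, rho = rho_tab)
      }, error = function(e) {
        say("[shift] not performed: %s", conditionMessage(e))
        list(rho = rho_tab)
      })
      res
    })
  }

  trace_res <- NULL
  if (!is.null(config$traces) && length(config$traces)) {
    trace_res <- stage("traces", {
      if (is.null(p$trace_ms) || is.null(p$trace_ps))
        stop("trace_ms and trace_ps boundaries must be configured")
      rows <- lapply(config$traces, function(tr) {
        trace <- read_uv_trace(tr$path, sample_id = tr$condition,
                               timepoint = tr$timepoint %||% NA_real_)
        ra <- integrate_regions(trace, unlist(p$trace_ms),
                                unlist(p$trace_ps),
                                baseline = p$trace_baseline)
        data.frame(condition = tr$condition,
                   timepoint = tr$timepoint %||% NA_real_,
                   ms_area = ra$ms_area, ps_area = ra$ps_area,
                   ratio = ra$ratio)
      })
      areas <- do.call(rbind, rows)
      outputs <- c(outputs, write_stage(areas, config$output_dir,
                                         "trace_areas"))
      res <- list(areas = areas)
      if (length(unique(areas$timepoint[!is.na(areas$timepoint)])) >= 2) {
        cmp <- runoff_compare(areas, case = config$case_condition,
                              control = config$control_condition)
        outputs <- c(outputs,
                      write_stage(as.data.frame(cmp$table),
                                  config$output_dir, "runoff_table"))
        res$comparison <- cmp
      }
      res
    })
  } else {
    say("[traces] skipped: no traces configured")
  }

  summary <- list(
    seed = config$seed,
    case_condition = case_cond, control_condition = ctrl_cond,
    stages = names(timings), timings_s = as.list(timings),
    filter_tallies = tallies,
    outputs = basename(outputs),
    checksums = as.list(tools::md5sum(sort(unique(outputs)))))
  summary_path <- file.path(config$output_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(config$output_dir, "run.log"))
  say("[done] %d outputs in %s", length(outputs), config$output_dir)
  invisible(list(models = models, records = records, calibration = calib,
                 coverage = coverage, periodicity = qc, counts = counts,
                 normalized = norm, occupancy = occupancy, pauses = pauses,
                 shift = shift, traces = trace_res, summary = summary))
}
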