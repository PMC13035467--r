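#' Run the full evaluation pipeline
#'
#' Orchestrates generate (or load) -> apply workflows -> summarise ->
#' compare -> report as one reproducible run. One global seed feeds named
#' substreams (generation: `seed`; panel provider: `seed + 1`; bootstrap:
#' `seed + 2`; power: `seed + 3`) so stages can be re-run independently.
#'
#' Outputs written to `out_dir`: the generated cohort (`cohort.csv`),
#' per-workflow episode decisions (`outcomes_<name>.csv`), a summary table
#' of all workflows (`summary.csv`), gated comparison verdicts for the
#' combination workflows (`gated_comparisons.json`), a workload table with
#' savings under 1-3 arbiters (`workload.csv`), a run manifest
#' (`manifest.json`) and a structured per-stage log (`run.log`). Any stage
#' error aborts with the stage name; partial outputs are retained next to a
#' `FAILED` marker file.
#'
#' @param config named list (or path to a YAML file) with optional entries:
#'   `generator` (arguments to [generator_config()]) or `cohort_path`
#'   (exactly one), `thresholds` (named OP list, else calibrated),
#'   `workflows` (names from [workflow_catalogue()]; default all 17 plus
#'   routine), `inference` (arguments to [inference_config()]),
#'   `run_gating` (default TRUE), `power` (arguments to [power_design()],
#'   optional), `seed`, `out_dir`.
#' @return The run directory, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% tempfile("screenflow_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(stage, ...) {
    cat(sprintf("[%s] %s\n", stage, paste0(...)), file = log_path,
        append = TRUE)
  }
  stage <- "setup"
  on_fail <- function(e) {
    writeLines(paste("FAILED at stage:", stage), file.path(out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    if (!is.null(config$generator) && !is.null(config$cohort_path)) {
      stop("supply exactly one of generator config and cohort_path")
    }
    gen_args <- config$generator %||% list()
    gen_args$seed <- gen_args$seed %||% seed
    gcfg <- do.call(generator_config, gen_args)

    stage <- "operating_points"
    ops <- if (!is.null(config$thresholds)) {
      do.call(operating_points, as.list(config$thresholds))
    } else calibrate_thresholds(gcfg)
    log_line(stage, paste(names(ops), round(unname(ops), 5), collapse = ", "))

    stage <- "cohort"
    if (!is.null(config$cohort_path)) {
      cohort <- read_cohort(config$cohort_path)
    } else {
      cohort <- generate_cohort(gcfg, ops)
      write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    }
    log_line(stage, nrow(cohort), " episodes, ", sum(cohort$cancer),
             " cancers")

    stage <- "workflows"
    n_arb <- as.integer(config$n_arbiters %||% 1L)
    catalogue <- workflow_catalogue(n_arbiters = n_arb)
    catalogue$routine <- workflow_spec("routine", n_arbiters = n_arb)
    wanted <- config$workflows %||% names(catalogue)
    unknown <- setdiff(wanted, names(catalogue))
    if (length(unknown)) stop("unknown workflow(s): ",
                              paste(unknown, collapse = ", "))
    panel <- make_panel_provider(gcfg$panel_recall_given_cancer,
                                 gcfg$panel_recall_given_benign,
                                 seed = seed + 1L)
    results <- lapply(catalogue[wanted], function(sp)
      apply_workflow(cohort, sp, ops, panel))
    baseline <- results$routine %||%
      apply_workflow(cohort, workflow_spec("routine"), ops)
    for (nm in names(results)) {
      utils::write.csv(results[[nm]]$outcomes,
                       file.path(out_dir, paste0("outcomes_", nm, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
    log_line(stage, length(results), " workflows applied")

    stage <- "summaries"
    summaries <- lapply(results, summary, baseline = baseline)
    sum_tab <- do.call(rbind, lapply(names(summaries), function(nm) {
      s <- summaries[[nm]]
      data.frame(workflow = nm, n = s$n, recalls = s$recalls,
                 detected_cancers = s$detected_cancers,
                 cdr_per_1000 = s$estimates$cdr_per_1000,
                 cdr_lo = s$ci$cdr_per_1000[[1]], cdr_hi = s$ci$cdr_per_1000[[2]],
                 recall_rate = s$estimates$recall_rate,
                 recall_lo = s$ci$recall_rate[[1]], recall_hi = s$ci$recall_rate[[2]],
                 sensitivity = s$estimates$sensitivity,
                 specificity = s$estimates$specificity,
                 ppv = s$estimates$ppv, total_reads = s$total_reads,
                 workload_savings = s$workload_savings_vs_routine,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(sum_tab, file.path(out_dir, "summary.csv"),
                     row.names = FALSE, quote = FALSE)
    log_line(stage, nrow(sum_tab), " workflow summaries written")

    stage <- "workload"
    wl <- do.call(rbind, lapply(names(results), function(nm) {
      sp <- catalogue[[nm]]
      do.call(rbind, lapply(1:3, function(k) {
        spk <- sp; spk$n_arbiters <- k
        resk <- if (identical(sp$mode, "routine")) results[[nm]] else
          apply_workflow(cohort, spk, ops, panel)
        reads <- resk$counts$reads_by_role
        data.frame(workflow = nm, n_arbiters = k,
                   reads_r1 = reads[["r1"]], reads_r2 = reads[["r2"]],
                   reads_arbitration = reads[["arbitration"]],
                   reads_additional_arbitration = reads[["additional_arbitration"]],
                   total_reads = resk$counts$total_reads,
                   savings = workload_savings(resk, baseline),
                   stringsAsFactors = FALSE)
      }))
    }))
    utils::write.csv(wl, file.path(out_dir, "workload.csv"),
                     row.names = FALSE, quote = FALSE)

    stage <- "gated_comparisons"
    gated <- list()
    if (!isFALSE(config$run_gating)) {
      inf_args <- config$inference %||% list()
      inf_args$seed <- inf_args$seed %||% (seed + 2L)
      icfg <- do.call(inference_config, inf_args)
      gt <- gating_table()
      for (nm in intersect(wanted, names(gt))) {
        gc <- run_gated_comparison(cohort, catalogue[[nm]], gt, icfg, ops,
                                   panel)
        gated[[nm]] <- gc$table
      }
      jsonlite::write_json(gated, file.path(out_dir, "gated_comparisons.json"),
                           dataframe = "rows", auto_unbox = TRUE, digits = NA)
      log_line(stage, length(gated), " gated comparisons")
    }

    stage <- "power"
    if (!is.null(config$power)) {
      p_args <- config$power
      p_args$seed <- p_args$seed %||% (seed + 3L)
      pw <- simulate_power(do.call(power_design, p_args))
      jsonlite::write_json(list(power = pw$power, se = pw$se,
                                n_sim = pw$n_sim),
                           file.path(out_dir, "power.json"),
                           auto_unbox = TRUE, digits = NA)
      log_line(stage, sprintf("power %.3f (se %.3f)", pw$power, pw$se))
    }

    stage <- "manifest"
    manifest <- list(package_version = as.character(utils::packageVersion("screenflow")),
                     seed = seed,
                     thresholds = as.list(unclass(ops)),
                     n_episodes = nrow(cohort),
                     workflows = wanted,
                     generated = is.null(config$cohort_path))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }, error = on_fail)
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
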