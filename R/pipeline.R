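#' Load and validate a pipeline configuration
#'
#' Configurations are YAML (see the packaged default at
#' `system.file("extdata", "default_config.yaml", package = "bioensig")`).
#' `overrides` are merged recursively on top of the file.
#'
#' @param path YAML file; `NULL` loads the packaged default.
#' @param overrides Named list merged over the file contents.
#' @return Validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, overrides = list()) {
  if (is.null(path))
    path <- system.file("extdata", "default_config.yaml",
                        package = "bioensig", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  # named sub-lists merge recursively; unnamed lists (task arrays) replace
  merge_cfg <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(over[[nm]]) && !is.null(names(over[[nm]])) &&
          is.list(base[[nm]]) && !is.null(names(base[[nm]])))
        base[[nm]] <- merge_cfg(base[[nm]], over[[nm]])
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  if (length(overrides) > 0L) cfg <- merge_cfg(cfg, overrides)
  need <- c("seed", "control_label", "layout", "stats", "clustering_tasks")
  absent <- setdiff(need, names(cfg))
  if (length(absent) > 0L)
    stop("pipeline config lacks field(s): ", paste(absent, collapse = ", "))
  all_groups <- names(reference_groups())
  groups <- if (is.null(cfg$groups)) all_groups else unlist(cfg$groups)
  if (!cfg$control_label %in% groups)
    stop("configuration error: control group '", cfg$control_label,
         "' is not among the simulated groups")
  bad <- setdiff(groups, all_groups)
  if (length(bad) > 0L)
    stop("configuration error: unknown group(s) ", paste(bad, collapse = ", "))
  cfg$groups <- groups
  cfg$classifier_targets <- unlist(cfg$classifier_targets)
  cfg$clustering_tasks <- lapply(cfg$clustering_tasks, function(task) {
    if (!all(c("name", "groups", "markers", "k") %in% names(task)))
      stop("clustering task must declare name, groups, markers, k")
    task$groups <- unlist(task$groups)
    task$markers <- unlist(task$markers)
    if (!all(task$groups %in% groups))
      stop("clustering task '", task$name, "' references unsimulated groups")
    task
  })
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> array printing -> quantification -> fold-of-control
#' normalization -> signature ratios -> group statistics -> clustering tasks
#' -> interval-rule classification, writing every intermediate as CSV (plus
#' Newick dendrograms) when `outdir` is given and returning a reproducible
#' run report.  Identical configuration and seed give an identical report.
#'
#' @param config A [pipeline_config()] (default: packaged configuration).
#' @param outdir Optional output directory (created if needed).
#' @param quiet Suppress per-stage progress messages.
#' @return Run report: nested list with seeds, a configuration hash, stage
#'   sample counts, the mean array CV, the marker statistics table, per-task
#'   clustering performance and per-disease classification results.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         quiet = FALSE) {
  if (!inherits(config, "pipeline_config"))
    stop("'config' must be a pipeline_config object")
  say <- function(...) if (!quiet) message(...)
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  emit <- function(obj, name, writer) {
    if (!is.null(outdir)) writer(obj, file.path(outdir, name))
  }
  seeds <- withr::with_seed(config$seed,
                            as.list(stats::setNames(sample.int(2147483647L, 3),
                                                    c("cohort", "array", "stats"))))

  # 1. cohort (assayed proteins only; ratios are computed downstream)
  gspecs <- reference_groups(config$groups)
  spec <- cohort_spec(gspecs, seed = seeds$cohort,
                      value_floor = config$value_floor %||% 0)
  expr_true <- simulate_cohort(spec, markers = marker_panel()$name)
  say("simulated cohort: ", nrow(expr_true), " samples x ",
      length(expr_markers(expr_true)), " markers")
  emit(expr_true, "expression_true.csv", write_expression_csv)

  # 2. array printing + quantification
  layout <- array_layout(
    replicates_per_sample = config$layout$replicates_per_sample,
    standard_concentrations = unlist(config$layout$standard_concentrations),
    n_blank_spots = config$layout$n_blank_spots,
    technical_cv_percent = config$layout$technical_cv_percent,
    seed = seeds$array
  )
  spots <- simulate_spot_table(expr_true, layout)
  say("printed ", nrow(spots), " spots")
  emit(spots, "spots.csv", write_spot_csv)
  quant <- quantify_table(spots)
  expr_cal <- as_expression_matrix(quant)
  say("quantified ", nrow(expr_cal), " samples; mean array CV ",
      sprintf("%.2f%%", quant$array_scv_percent))
  emit(expr_cal, "expression_quantified.csv", write_expression_csv)

  # 3. normalization + signatures
  expr_sig <- add_signatures(expr_cal)
  expr_foc <- fold_of_control(expr_sig, config$control_label)
  emit(expr_foc, "expression_fold_of_control.csv", write_expression_csv)

  # 4. statistics
  stats_tab <- test_markers(expr_foc, config$control_label,
                            method = config$stats$method %||% "dunnett",
                            mc_draws = config$stats$mc_draws %||% 2e4,
                            seed = seeds$stats)
  say("statistics: ", nrow(stats_tab), " marker x group comparisons")
  emit(stats_tab, "stats.csv",
       function(obj, p) utils::write.csv(obj, p, row.names = FALSE))

  # 5. clustering tasks
  cluster_reports <- lapply(config$clustering_tasks, function(task) {
    sub <- expr_foc[expr_foc$class_label %in% task$groups, , drop = FALSE]
    lr <- log2_relative(sub, config$control_label,
                        floor = config$log2_floor %||% 0.01)
    lk <- wpgma_linkage(euclidean_distances(lr, task$markers))
    perf <- cluster_performance(cut_tree(lk, task$k), sub$class_label,
                                config$control_label)
    if (!is.null(outdir))
      write_newick(lk, file.path(outdir, paste0("tree_", task$name, ".nwk")))
    say("clustering '", task$name, "': pooled sensitivity ",
        sprintf("%.1f%%", perf$pooled_sensitivity_percent),
        ", control specificity ",
        sprintf("%.1f%%", perf$pooled_specificity_percent))
    list(name = task$name, markers = task$markers, k = task$k,
         n = nrow(sub), per_class = perf$per_class,
         specificity_percent = perf$specificity_percent,
         pooled_sensitivity_percent = perf$pooled_sensitivity_percent,
         pooled_specificity_percent = perf$pooled_specificity_percent)
  })

  # 6. interval-rule classification
  rules <- diagnostic_rules()
  targets <- intersect(config$classifier_targets %||% names(rules),
                       config$groups)
  classifier_reports <- lapply(targets, function(dz) {
    res <- evaluate_panel(expr_foc, rules[[dz]], dz,
                          control_label = config$control_label)
    say("rule '", dz, "': sensitivity ",
        sprintf("%.1f%%", res$sensitivity_percent))
    c(list(disease = dz), res)
  })

  report <- list(
    package_version = as.character(utils::packageVersion("bioensig")),
    r_version = R.version.string,
    seed = config$seed, stage_seeds = seeds,
    config_hash = rlang::hash(unclass(config)),
    n_samples = nrow(expr_true),
    array_scv_percent = quant$array_scv_percent,
    statistics = stats_tab,
    clustering = cluster_reports,
    classification = classifier_reports
  )
  if (!is.null(outdir))
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
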