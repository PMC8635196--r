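# End-to-end pipeline: simulate (or read) -> preprocess -> univariate
# summaries -> rDCV classification per requested class pair, with every
# output regenerated from the logged configuration and seed alone.

#' Pipeline configuration
#'
#' Assembles and validates the configuration consumed by [run_pipeline()].
#' Exactly one input source must be given: a synthetic-data block
#' (`synthetic`), or paths to a concentration CSV and a metadata CSV
#' written in the package's dialect (`input`).
#'
#' @param synthetic A [synthetic_config()] (or argument list for one);
#'   mutually exclusive with `input`.
#' @param input A list with `concentrations`, `mdls` and `metadata` CSV
#'   paths; mutually exclusive with `synthetic`.
#' @param class_pairs A list of length-2 character vectors: the class pairs
#'   to model, as values of `class_var`.
#' @param class_var Metadata column holding the class labels: `"region"`,
#'   `"macro_area"`, `"cultivar"` or `"production"`.
#' @param detection_threshold Minimum detected fraction for an element to
#'   enter a model (computed on the samples of the two compared classes);
#'   default 0.70.
#' @param alpha Significance level for the univariate tests; default 0.05.
#' @param include_dpph Include DPPH% as an additional predictor next to the
#'   retained elements (default `TRUE`).
#' @param rdcv An [rdcv_config()] (or argument list for one).
#' @param seed Integer seed forwarded to the synthetic generator and the
#'   rDCV splits.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, input = NULL,
                            class_pairs = list(),
                            class_var = c("region", "macro_area",
                                          "cultivar", "production"),
                            detection_threshold = 0.70, alpha = 0.05,
                            include_dpph = TRUE, rdcv = NULL, seed = 1L) {
  class_var <- match.arg(class_var)
  if (is.null(synthetic) == is.null(input)) {
    abort("exactly one of `synthetic` and `input` must be given")
  }
  if (!is.null(synthetic) && !inherits(synthetic, "synthetic_config")) {
    synthetic$seed <- synthetic$seed %||% seed
    synthetic <- do.call(synthetic_config, synthetic)
  }
  if (!is.null(input)) {
    stopifnot(all(c("concentrations", "metadata") %in% names(input)))
  }
  if (is.null(rdcv)) {
    rdcv <- rdcv_config(seed = seed)
  } else if (!inherits(rdcv, "rdcv_config")) {
    rdcv$seed <- rdcv$seed %||% seed
    rdcv <- do.call(rdcv_config, rdcv)
  }
  class_pairs <- lapply(class_pairs, function(p) {
    p <- as.character(unlist(p))
    if (length(p) != 2) abort("each class pair must have exactly 2 labels")
    p
  })
  structure(
    list(synthetic = synthetic, input = input, class_pairs = class_pairs,
         class_var = class_var, detection_threshold = detection_threshold,
         alpha = alpha, include_dpph = isTRUE(include_dpph), rdcv = rdcv,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path A `.yaml`/`.yml` or `.json` file whose top-level keys are
#'   [pipeline_config()] arguments.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("the yaml package is required to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$class_pairs) && is.matrix(raw$class_pairs)) {
    raw$class_pairs <- asplit(raw$class_pairs, 1)
  }
  do.call(pipeline_config, raw)
}

#' Run the full authentication pipeline
#'
#' Executes simulate (or load) -> impute -> average replicates ->
#' summarise -> compare -> DPPH correlation -> MRL screen -> rDCV
#' classification for each configured class pair, and writes the report
#' bundle to `out_dir`: survey-style element summary, per-group comparison
#' table, correlation and MRL reports, a figures-of-merit table with one row
#' per class pair (mean +/- SD over runs), per-sample score-interval data
#' and flagged-variable tables per pair, plus the serialized configuration
#' and a run log (package version, seed, timings).
#'
#' @param config A [pipeline_config()] (or a path understood by
#'   [read_pipeline_config()]).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the in-memory results: `summary`,
#'   `comparison`, `dpph_correlation`, `mrl`, and one `rdcv_result` per
#'   class pair (`classification`).
#' @export
run_pipeline <- function(config, out_dir = "oliveauth-report") {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) {
    cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  }
  cat("", file = log_path) # truncate
  log_line("oliveauth %s | seed %d | %s",
           as.character(utils::packageVersion("oliveauth")), config$seed,
           format(Sys.time(), "%Y-%m-%d %H:%M:%S"))

  # ---- input stage -------------------------------------------------------
  if (!is.null(config$synthetic)) {
    ds <- generate_dataset(config$synthetic)
    conc_raw <- ds$concentrations
    metadata <- ds$metadata
    jsonlite::write_json(ds$truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_line("simulated %d samples x %d elements",
             nrow(metadata), length(unique(conc_raw$element)))
  } else {
    conc_raw <- read_concentrations(
      config$input$concentrations,
      config$input$mdls %||% sub("\\.csv$", "_mdl.csv",
                                 config$input$concentrations))
    metadata <- readr::read_csv(config$input$metadata,
                                col_types = readr::cols())
    log_line("loaded %d samples x %d elements",
             nrow(metadata), length(unique(conc_raw$element)))
  }
  # fail early if a requested class is too small for the outer loop
  class_col <- metadata[[config$class_var]]
  for (pair in config$class_pairs) {
    for (cl in pair) {
      n_cl <- sum(class_col == cl)
      if (n_cl < config$rdcv$n_outer) {
        abort(sprintf(
          "class '%s' has %d sample(s) but the outer loop needs >= %d",
          cl, n_cl, config$rdcv$n_outer))
      }
    }
  }

  # ---- preprocess --------------------------------------------------------
  conc <- average_replicates(substitute_censored(conc_raw))
  write_concentrations(conc_raw, file.path(out_dir, "concentrations.csv"))
  readr::write_csv(metadata, file.path(out_dir, "metadata.csv"))

  # ---- univariate reports ------------------------------------------------
  summary_tbl <- summarize_elements(conc)
  readr::write_csv(summary_tbl, file.path(out_dir, "element_summary.csv"))

  wide <- pivot_concentrations(conc)
  stopifnot(identical(wide$sample_id, metadata$sample_id))
  groups <- metadata[[config$class_var]]
  comparison <- compare_elements(wide, groups, alpha = config$alpha)
  readr::write_csv(comparison, file.path(out_dir, "group_comparison.csv"))

  dpph_cor <- correlate_with_dpph(wide, metadata$dpph_percent,
                                  alpha = config$alpha)
  readr::write_csv(dpph_cor, file.path(out_dir, "dpph_correlation.csv"))

  mrl <- check_mrl(conc)
  readr::write_csv(mrl, file.path(out_dir, "mrl_report.csv"))
  log_line("univariate stage: %d elements summarised, %d significant at %g",
           nrow(summary_tbl), sum(comparison$significant), config$alpha)

  # ---- classification ----------------------------------------------------
  classification <- list()
  fom_rows <- list()
  for (pair in config$class_pairs) {
    key <- paste(gsub("\\s+", "_", pair), collapse = "_vs_")
    in_pair <- class_col %in% pair
    sub_meta <- metadata[in_pair, ]
    sub_conc <- dplyr::semi_join(conc, sub_meta, by = "sample_id")
    sub_conc <- filter_by_detection(sub_conc, config$detection_threshold)
    sub_wide <- pivot_concentrations(sub_conc)
    stopifnot(identical(sub_wide$sample_id, sub_meta$sample_id))
    if (config$include_dpph) {
      sub_wide$DPPH <- sub_meta$dpph_percent
    }
    y <- factor(sub_meta[[config$class_var]], levels = pair)
    res <- run_rdcv(sub_wide, y, config$rdcv)
    classification[[key]] <- res
    fom_rows[[key]] <- glance(res)
    readr::write_csv(score_interval_plot_data(res),
                     file.path(out_dir, paste0("scores_", key, ".csv")))
    readr::write_csv(significant_variables(res),
                     file.path(out_dir, paste0("variables_", key, ".csv")))
    log_line("rDCV %s: accuracy %.1f +/- %.1f%%", key,
             fom_rows[[key]]$accuracy_mean, fom_rows[[key]]$accuracy_sd)
  }
  if (length(fom_rows) > 0) {
    readr::write_csv(dplyr::bind_rows(fom_rows),
                     file.path(out_dir, "figures_of_merit.csv"))
  }

  # ---- provenance --------------------------------------------------------
  cfg_out <- config
  cfg_out$rdcv <- unclass(cfg_out$rdcv)
  if (!is.null(cfg_out$synthetic)) {
    cfg_out$synthetic <- lapply(unclass(cfg_out$synthetic), function(x) {
      if (is.data.frame(x)) as.list(x) else x
    })
  }
  jsonlite::write_json(unclass(cfg_out), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  log_line("done: %d classification model(s)", length(classification))

  invisible(list(
    summary = summary_tbl, comparison = comparison,
    dpph_correlation = dpph_cor, mrl = mrl,
    classification = classification,
    out_dir = out_dir
  ))
}
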