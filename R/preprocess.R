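# Preprocessing of replicate-level, left-censored concentration tables.
#
# Concentration tables are long tibbles with one row per measurement:
# sample_id, (optional) replicate, element, value (ug/kg, NA while
# censored and not yet imputed), censored (logical), mdl (ug/kg).

.check_conc <- function(data, call = rlang::caller_env()) {
  need <- c("sample_id", "element", "value", "censored", "mdl")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(paste0("concentration table lacks column(s): ",
                 paste(missing, collapse = ", ")), call = call)
  }
  invisible(data)
}

#' Substitute censored cells at half the detection limit
#'
#' Replaces the value of every censored cell by exactly `mdl / 2` for its
#' element (the conventional MDL/2 substitution for left-censored trace
#' element data). Detected cells are untouched and the censoring mask is
#' preserved for provenance, which also makes the operation idempotent.
#'
#' @param data A long concentration tibble (columns `sample_id`, `element`,
#'   `value`, `censored`, `mdl`).
#' @return The same tibble with censored `value`s set to `mdl / 2`.
#' @examples
#' tbl <- tibble::tibble(sample_id = "S1", element = "Tl",
#'                       value = NA_real_, censored = TRUE, mdl = 0.06)
#' substitute_censored(tbl)$value # 0.03
#' @export
substitute_censored <- function(data) {
  .check_conc(data)
  if (any(data$censored & is.na(data$mdl))) {
    abort("censored cells found for element(s) without an MDL")
  }
  dplyr::mutate(data,
                value = ifelse(.data$censored, .data$mdl / 2, .data$value))
}

#' Average analytical replicates
#'
#' Collapses replicate measurements to one row per sample and element, the
#' value being the arithmetic mean of the replicate values. A cell is
#' censored in the output only if all of its replicates were censored.
#' Censored replicates must already be imputed (see [substitute_censored()])
#' unless all replicates of a cell are censored.
#'
#' @param data A long concentration tibble with a `replicate` column. A table
#'   without one is returned unchanged.
#' @return A long concentration tibble with one row per sample and element
#'   and no `replicate` column.
#' @examples
#' tbl <- tibble::tibble(sample_id = "S1", replicate = 1:2, element = "Fe",
#'                       value = c(10, 12), censored = FALSE, mdl = 12)
#' average_replicates(tbl)$value # 11
#' @export
average_replicates <- function(data) {
  .check_conc(data)
  if (!"replicate" %in% names(data)) {
    return(data)
  }
  mixed <- dplyr::summarise(
    dplyr::group_by(data, .data$sample_id, .data$element),
    bad = any(is.na(.data$value)) && !all(is.na(.data$value)),
    none = dplyr::n() == 0,
    .groups = "drop"
  )
  if (any(mixed$bad)) {
    abort(paste0(
      "cells with a mix of censored (unimputed) and detected replicates; ",
      "run substitute_censored() before averaging"
    ))
  }
  out <- dplyr::summarise(
    dplyr::group_by(data, .data$sample_id, .data$element),
    value = mean(.data$value),
    censored = all(.data$censored),
    mdl = .data$mdl[1],
    .groups = "drop"
  )
  dplyr::arrange(out, match(.data$sample_id, unique(data$sample_id)),
                 match(.data$element, unique(data$element)))
}

#' Filter elements by detection rate
#'
#' Retains exactly the elements whose fraction of detected (above-MDL)
#' measurements over the samples in `data` is at least `threshold` — the
#' boundary is inclusive, so an element detected in exactly 70% of samples
#' survives the default filter. The kept and dropped element lists are
#' attached as attributes `kept_elements` and `dropped_elements`.
#'
#' @param data A long concentration tibble.
#' @param threshold Minimum detected fraction in (0, 1]; default 0.70.
#' @return The filtered tibble (rows of dropped elements removed).
#' @export
filter_by_detection <- function(data, threshold = 0.70) {
  .check_conc(data)
  if (nrow(data) == 0) abort("empty concentration table")
  if (threshold <= 0 || threshold > 1) {
    abort("threshold must be in (0, 1]")
  }
  rates <- dplyr::summarise(
    dplyr::group_by(data, .data$element),
    detected = mean(!.data$censored),
    .groups = "drop"
  )
  kept <- rates$element[rates$detected >= threshold]
  dropped <- setdiff(rates$element, kept)
  out <- dplyr::filter(data, .data$element %in% kept)
  attr(out, "kept_elements") <- kept
  attr(out, "dropped_elements") <- dropped
  out
}

#' Pivot a concentration table to the wide analysis form
#'
#' Returns one row per sample with one numeric column per element, the form
#' consumed by the classification functions. Replicates must be averaged
#' first.
#'
#' @param data A long concentration tibble with one row per sample/element.
#' @return A wide tibble: `sample_id` plus one column per element.
#' @export
pivot_concentrations <- function(data) {
  .check_conc(data)
  if ("replicate" %in% names(data) &&
      length(unique(data$replicate)) > 1) {
    abort("multiple replicates present; run average_replicates() first")
  }
  elements <- unique(data$element)
  wide <- tidyr::pivot_wider(
    dplyr::select(data, "sample_id", "element", "value"),
    names_from = "element", values_from = "value"
  )
  dplyr::select(wide, "sample_id", dplyr::all_of(elements))
}

#' Fit autoscaling (mean/SD) parameters on a training set
#'
#' Computes per-column mean and sample standard deviation (n - 1 denominator)
#' on the training rows only. Apply the parameters to any matrix with
#' [apply_autoscale()]; training columns then have mean 0 and SD 1.
#'
#' @param data A wide tibble or numeric matrix of training rows (a
#'   `sample_id` column, if present, is ignored).
#' @return An object of class `autoscale_params` (list with `center`,
#'   `scale`, `elements`).
#' @export
fit_autoscale <- function(data) {
  x <- .as_feature_matrix(data)
  if (nrow(x) < 2) abort("autoscaling needs at least 2 training samples")
  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  if (any(scale == 0 | !is.finite(scale))) {
    bad <- colnames(x)[scale == 0 | !is.finite(scale)]
    abort(paste0("constant column(s), cannot autoscale: ",
                 paste(bad, collapse = ", ")))
  }
  structure(list(center = center, scale = scale, elements = colnames(x)),
            class = "autoscale_params")
}

#' Apply autoscaling parameters
#'
#' @param data A wide tibble or numeric matrix with (at least) the columns
#'   the parameters were fitted on.
#' @param params An `autoscale_params` object from [fit_autoscale()].
#' @return A numeric matrix of scaled values, columns in training order.
#' @export
apply_autoscale <- function(data, params) {
  stopifnot(inherits(params, "autoscale_params"))
  x <- .as_feature_matrix(data)
  missing <- setdiff(params$elements, colnames(x))
  if (length(missing) > 0) {
    abort(paste0("data lacks element(s) the scaling was fitted on: ",
                 paste(missing, collapse = ", ")))
  }
  x <- x[, params$elements, drop = FALSE]
  scale(x, center = params$center, scale = params$scale)[, , drop = FALSE]
}

# Coerce a wide tibble / data frame / matrix to a plain numeric matrix,
# dropping a sample_id column and using it for rownames when present.
.as_feature_matrix <- function(data) {
  if (is.matrix(data)) {
    storage.mode(data) <- "double"
    return(data)
  }
  data <- as.data.frame(data)
  rn <- NULL
  if ("sample_id" %in% names(data)) {
    rn <- as.character(data$sample_id)
    data$sample_id <- NULL
  }
  num <- vapply(data, is.numeric, logical(1))
  if (!all(num)) {
    data <- data[, num, drop = FALSE]
  }
  x <- as.matrix(data)
  if (!is.null(rn)) rownames(x) <- rn
  x
}

#' Write / read a concentration table as CSV
#'
#' `write_concentrations()` renders the table in the wide survey dialect:
#' one row per sample and replicate, one column per element, censored cells
#' written as the literal `"<MDL"`. The numeric MDLs live in a side table
#' keyed by element (written next to the main file). `read_concentrations()`
#' inverts the dialect exactly: censored cells come back as `NA` values with
#' the censoring mask set.
#'
#' @param data A long concentration tibble.
#' @param path Output CSV path for the measurements.
#' @param mdl_path CSV path for the element/MDL side table; defaults to
#'   `path` with an `_mdl.csv` suffix.
#' @return `write_concentrations()`: `path`, invisibly;
#'   `read_concentrations()`: a long concentration tibble.
#' @export
write_concentrations <- function(data, path,
                                 mdl_path = sub("\\.csv$", "_mdl.csv", path)) {
  .check_conc(data)
  has_rep <- "replicate" %in% names(data)
  if (!has_rep) data$replicate <- 1L
  elements <- unique(data$element)
  cells <- dplyr::mutate(
    data,
    cell = ifelse(.data$censored, "<MDL",
                  formatC(.data$value, digits = 17, format = "g"))
  )
  wide <- tidyr::pivot_wider(
    dplyr::select(cells, "sample_id", "replicate", "element", "cell"),
    names_from = "element", values_from = "cell"
  )
  wide <- dplyr::select(wide, "sample_id", "replicate",
                        dplyr::all_of(elements))
  if (!has_rep) wide$replicate <- NULL
  readr::write_csv(wide, path)
  mdls <- dplyr::distinct(data, .data$element, .data$mdl)
  mdls$mdl <- formatC(mdls$mdl, digits = 17, format = "g")
  readr::write_csv(mdls, mdl_path)
  invisible(path)
}

#' @rdname write_concentrations
#' @export
read_concentrations <- function(path,
                                mdl_path = sub("\\.csv$", "_mdl.csv", path)) {
  wide <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()
  ))
  mdls <- readr::read_csv(mdl_path, col_types = "cd")
  id_cols <- intersect(c("sample_id", "replicate"), names(wide))
  long <- tidyr::pivot_longer(wide, cols = -dplyr::all_of(id_cols),
                              names_to = "element", values_to = "cell")
  long$censored <- long$cell == "<MDL"
  long$value <- NA_real_
  long$value[!long$censored] <- as.numeric(long$cell[!long$censored])
  long$cell <- NULL
  if ("replicate" %in% id_cols) long$replicate <- as.integer(long$replicate)
  out <- dplyr::left_join(long, mdls, by = "element")
  if (any(is.na(out$mdl))) {
    abort("MDL side table does not cover every element in the data")
  }
  cols <- c("sample_id", intersect("replicate", id_cols), "element",
            "value", "censored", "mdl")
  dplyr::select(tibble::as_tibble(out), dplyr::all_of(cols))
}
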