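# Shared fixture builders; everything is generated in code.

# Minimal long concentration tibble from a wide value matrix and mask.
make_conc <- function(values, censored = NULL, mdls = NULL,
                      replicate = NULL) {
  p <- ncol(values)
  n <- nrow(values)
  elements <- colnames(values) %||% paste0("E", seq_len(p))
  mdls <- mdls %||% rep(1e-6, p)
  censored <- censored %||% matrix(FALSE, n, p)
  tb <- tidyr::expand_grid(i = seq_len(n), j = seq_len(p))
  out <- tibble::tibble(
    sample_id = sprintf("S%03d", tb$i),
    element = elements[tb$j],
    value = values[cbind(tb$i, tb$j)],
    censored = censored[cbind(tb$i, tb$j)],
    mdl = mdls[tb$j]
  )
  if (!is.null(replicate)) out$replicate <- replicate
  out
}

`%||%` <- rlang::`%||%`

# Small synthetic config: `p` elements with full detection, two or more
# classes, optional log-scale shifts on the first `n_shift` elements for the
# first class.
small_config <- function(n_per_class = 30, n_classes = 2, p = 20,
                         n_shift = 0, shift_sd = 3, log_sd = 0.4,
                         replicate_cv = 0.03, seed = 1) {
  elements <- sprintf("El%02d", seq_len(p))
  panel <- tibble::tibble(
    element = elements,
    mdl = 0.01,            # far below the simulated range: full detection
    log_mean = 3,
    log_sd = log_sd
  )
  classes <- tibble::tibble(
    label = paste0("class", seq_len(n_classes)),
    n = as.integer(n_per_class)
  )
  effects <- if (n_shift > 0) {
    tibble::tibble(
      element = elements[seq_len(n_shift)],
      class = "class1",
      shift = shift_sd * log_sd
    )
  } else {
    tibble::tibble(element = character(), class = character(),
                   shift = numeric())
  }
  synthetic_config(
    panel = panel, classes = classes, effects = effects,
    replicate_cv = replicate_cv,
    dpph_links = tibble::tibble(element = elements[1], weight = 0.5),
    dpph_noise_sd = 0.5, seed = seed
  )
}

# Preprocess a generated dataset to the wide analysis table.
to_wide <- function(ds) {
  conc <- average_replicates(substitute_censored(ds$concentrations))
  pivot_concentrations(conc)
}
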