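# Synthetic multielement EVOO data with the statistical structure the
# analysis pipeline assumes: per-element log-normal concentrations, class-
# dependent shifts on the log scale, duplicate analytical replicates with
# multiplicative noise, left-censoring at element-specific MDLs, and a
# bounded DPPH% antioxidant index tied to selected elements.

# Deterministic per-stage substream seed so that adding an element (or any
# other keyed stage) never perturbs the draws of unrelated stages.
.substream_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key))) %% 104729L
  as.integer((abs(as.integer(seed)) %% 1000003L) * 2048L + h)
}

#' Default class-effect specification
#'
#' Additive log-scale concentration shifts that emulate the regional
#' structure reported for Italian EVOO: northern regions are enriched in Fe,
#' Pr, Na, P, Cs and U relative to the centre and south, and Lazio oils
#' carry higher Cd, La and Rb than neighbouring regions.
#'
#' @return A tibble with columns `element`, `class` and `shift` (log scale).
#' @export
default_effects <- function() {
  north <- c("Trentino Alto Adige", "Liguria", "Lombardy", "Veneto",
             "Emilia Romagna")
  north_shifts <- tibble::tribble(
    ~element, ~shift,
    "Fe", 0.80,
    "Pr", 0.80,
    "Na", 0.25,
    "P",  0.13,
    "Cs", 0.55,
    "U",  0.50
  )
  north_fx <- tidyr::crossing(north_shifts, class = north)
  lazio_fx <- tibble::tibble(
    element = c("Cd", "La", "Rb", "Na", "Mg", "Ti"),
    class = "Lazio",
    shift = c(0.90, 1.10, 1.00, 0.50, 0.35, 0.40)
  )
  dplyr::bind_rows(
    dplyr::select(north_fx, "element", "class", "shift"),
    lazio_fx
  )
}

#' Default element-DPPH link weights
#'
#' Weights of the latent antioxidant signal: elements reported to correlate
#' positively with DPPH radical-scavenging activity (Al, Ca, Fe, V, Zr
#' moderately; Ba and Ni weakly) contribute to the latent score from which
#' DPPH% is generated.
#'
#' @return A tibble with columns `element` and `weight`.
#' @export
default_dpph_links <- function() {
  tibble::tibble(
    element = c("Al", "Ca", "Fe", "V", "Zr", "Ba", "Ni"),
    weight = c(0.40, 0.40, 0.50, 0.50, 0.40, 0.15, 0.15)
  )
}

#' Configuration of the synthetic EVOO data generator
#'
#' Bundles and validates everything [generate_dataset()] needs: the element
#' panel (names, MDLs, log-normal parameters), per-class sample counts,
#' class-dependent log-scale mean shifts, the analytical replicate noise, the
#' element-DPPH link weights, and the random seed.
#'
#' @param panel Element panel as returned by [default_panel()]: columns
#'   `element`, `mdl` (ug/kg, > 0), `log_mean`, `log_sd` (>= 0).
#' @param classes Data frame with columns `label` and `n` (>= 1): one row per
#'   class. Defaults to the 15-region survey counts ([region_counts()]).
#' @param class_var Metadata column the classes populate: `"region"` or
#'   `"cultivar"`.
#' @param effects Data frame with columns `element`, `class`, `shift`:
#'   additive offsets applied to `log_mean` for samples of that class.
#' @param replicate_cv Relative standard deviation of the two analytical
#'   replicates around the true concentration (>= 0).
#' @param dpph_links Data frame with columns `element`, `weight` defining the
#'   latent antioxidant signal.
#' @param dpph_noise_sd Standard deviation of the noise added to the latent
#'   antioxidant signal (logit scale).
#' @param seed Integer seed; a fixed seed makes the generated dataset fully
#'   reproducible.
#' @return A list of class `synthetic_config`.
#' @examples
#' cfg <- synthetic_config(seed = 42)
#' names(cfg)
#' @export
synthetic_config <- function(panel = default_panel(),
                             classes = region_counts(),
                             class_var = c("region", "cultivar"),
                             effects = default_effects(),
                             replicate_cv = 0.05,
                             dpph_links = default_dpph_links(),
                             dpph_noise_sd = 0.8,
                             seed = 1L) {
  class_var <- match.arg(class_var)
  panel <- tibble::as_tibble(panel)
  stopifnot(all(c("element", "mdl", "log_mean", "log_sd") %in% names(panel)))
  if (anyDuplicated(panel$element)) {
    abort("element names must be unique within the panel")
  }
  if (any(panel$mdl <= 0)) abort("every MDL must be strictly positive")
  if (any(panel$log_sd < 0)) abort("log_sd must be non-negative")
  classes <- tibble::as_tibble(classes)
  stopifnot(all(c("label", "n") %in% names(classes)))
  if (any(classes$n < 1)) abort("every class needs at least one sample")
  effects <- tibble::as_tibble(effects)
  if (nrow(effects) > 0) {
    stopifnot(all(c("element", "class", "shift") %in% names(effects)))
    bad <- setdiff(effects$element, panel$element)
    if (length(bad) > 0) {
      abort(paste0("effects reference unknown elements: ",
                   paste(bad, collapse = ", ")))
    }
  }
  dpph_links <- tibble::as_tibble(dpph_links)
  if (nrow(dpph_links) > 0) {
    stopifnot(all(c("element", "weight") %in% names(dpph_links)))
    bad <- setdiff(dpph_links$element, panel$element)
    if (length(bad) > 0) {
      abort(paste0("dpph_links reference unknown elements: ",
                   paste(bad, collapse = ", ")))
    }
  }
  if (replicate_cv < 0) abort("replicate_cv must be >= 0")
  if (dpph_noise_sd < 0) abort("dpph_noise_sd must be >= 0")
  structure(
    list(panel = panel, classes = classes, class_var = class_var,
         effects = effects, replicate_cv = replicate_cv,
         dpph_links = dpph_links, dpph_noise_sd = dpph_noise_sd,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Generate a synthetic multielement EVOO dataset
#'
#' Draws, for every sample and element, a true concentration from a
#' log-normal law with the class shift applied on the log scale, then two
#' analytical replicate measurements with multiplicative (log-normal)
#' noise of relative SD `replicate_cv`. A measurement below the element's
#' MDL is flagged censored and its numeric value withheld (`NA`). DPPH% is a
#' logistic transform (bounded in 0-100) of the weighted latent element
#' signal plus noise. Each element and the DPPH stage consume independent
#' RNG substreams derived from the single configured seed.
#'
#' @param config A [synthetic_config()] object.
#' @return A list of class `synthetic_dataset` with components
#'   `concentrations` (long tibble: `sample_id`, `replicate`, `element`,
#'   `value`, `censored`, `mdl`), `metadata` (tibble: `sample_id`, `region`,
#'   `macro_area`, `cultivar`, `production`, `dpph_percent`), `truth` (the
#'   effects and DPPH links actually used) and `config`.
#' @examples
#' ds <- generate_dataset(synthetic_config(seed = 7))
#' dplyr::count(ds$concentrations, replicate)
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    config <- do.call(synthetic_config, config)
  }
  classes <- config$classes
  labels <- rep(classes$label, classes$n)
  n <- length(labels)
  sample_ids <- sprintf("S%03d", seq_len(n))

  panel <- config$panel
  effects <- config$effects
  link_elements <- unique(config$dpph_links$element)
  log_true_links <- matrix(0, nrow = n, ncol = length(link_elements),
                           dimnames = list(NULL, link_elements))

  per_element <- vector("list", nrow(panel))
  for (i in seq_len(nrow(panel))) {
    el <- panel$element[i]
    set.seed(.substream_seed(config$seed, paste0("element:", el)))
    shift <- rep(0, n)
    fx <- effects[effects$element == el, , drop = FALSE]
    if (nrow(fx) > 0) {
      m <- match(labels, fx$class)
      shift <- ifelse(is.na(m), 0, fx$shift[m])
    }
    log_true <- panel$log_mean[i] + shift + panel$log_sd[i] * rnorm(n)
    if (el %in% link_elements) log_true_links[, el] <- log_true
    true <- exp(log_true)
    reps <- lapply(1:2, function(r) {
      meas <- if (config$replicate_cv > 0) {
        true * exp(rnorm(n, 0, config$replicate_cv))
      } else {
        true
      }
      censored <- meas < panel$mdl[i]
      tibble::tibble(
        sample_id = sample_ids, replicate = r, element = el,
        value = ifelse(censored, NA_real_, meas),
        censored = censored, mdl = panel$mdl[i]
      )
    })
    per_element[[i]] <- dplyr::bind_rows(reps)
  }
  conc <- dplyr::bind_rows(per_element)
  conc <- dplyr::arrange(
    conc,
    match(.data$sample_id, sample_ids), .data$replicate,
    match(.data$element, panel$element)
  )

  # latent antioxidant signal: weighted z-scores of the (true) log
  # concentrations of the linked elements, logistic-squashed into (0, 100)
  set.seed(.substream_seed(config$seed, "dpph"))
  latent <- rep(0, n)
  if (length(link_elements) > 0) {
    for (el in link_elements) {
      idx <- match(el, panel$element)
      w <- config$dpph_links$weight[match(el, config$dpph_links$element)]
      z <- (log_true_links[, el] - panel$log_mean[idx]) /
        max(panel$log_sd[idx], 1e-8)
      latent <- latent + w * z
    }
  }
  noise <- if (config$dpph_noise_sd > 0) rnorm(n, 0, config$dpph_noise_sd)
           else rep(0, n)
  dpph <- 100 * plogis(qlogis(0.35) + latent + noise)

  set.seed(.substream_seed(config$seed, "production"))
  production <- sample(c("organic", "non-organic", "not-reported"), n,
                       replace = TRUE, prob = c(0.27, 0.60, 0.13))

  metadata <- tibble::tibble(
    sample_id = sample_ids,
    region = if (config$class_var == "region") labels else "not-reported",
    cultivar = if (config$class_var == "cultivar") labels else "Blend",
    production = production,
    dpph_percent = dpph
  )
  metadata$macro_area <- assign_macro_area(metadata$region)
  metadata <- dplyr::select(
    metadata, "sample_id", "region", "macro_area", "cultivar",
    "production", "dpph_percent"
  )

  structure(
    list(
      concentrations = conc,
      metadata = metadata,
      truth = list(effects = effects, dpph_links = config$dpph_links),
      config = config
    ),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  n <- nrow(x$metadata)
  p <- length(unique(x$concentrations$element))
  cat(sprintf(
    "<synthetic_dataset> %d samples x %d elements (2 replicates), %d classes\n",
    n, p, nrow(x$config$classes)
  ))
  invisible(x)
}
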