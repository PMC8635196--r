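# Reference element panel for Italian EVOO multielement surveys.
#
# The summary table below reproduces the published country-wide survey
# statistics for 45 elements in extra-virgin olive oil (all units ug/kg):
# method detection limit (mdl), percentage of samples detected above the MDL,
# and the median/min/max of the measured concentrations. Summary cells that
# fall below the MDL are not quantifiable and are stored as NA.
.evoo_survey_summary <- function() {
  tibble::tribble(
    ~element, ~mdl,   ~pct_detected, ~median, ~min,  ~max,
    "Ag",     0.06,   27,            NA,      NA,    0.86,
    "Al",     9,      85,            34,      NA,    1300,
    "As",     0.3,    28,            NA,      NA,    4.0,
    "B",      20,     16,            NA,      NA,    770,
    "Ba",     0.7,    49,            NA,      NA,    175,
    "Be",     0.004,  43,            NA,      NA,    0.431,
    "Bi",     0.1,    23,            NA,      NA,    1.0,
    "Ca",     510,    100,           4090,    1230,  35700,
    "Cd",     0.07,   67,            0.09,    NA,    0.97,
    "Ce",     0.1,    65,            0.2,     0.1,   3.5,
    "Co",     0.05,   70,            0.12,    NA,    2.16,
    "Cr",     0.3,    100,           5,       0.4,   839,
    "Cs",     0.007,  55,            0.008,   NA,    0.101,
    "Cu",     0.6,    99,            3.2,     NA,    41.6,
    "Dy",     0.005,  19,            NA,      NA,    0.055,
    "Fe",     12,     99,            77,      NA,    582,
    "Ga",     0.06,   15,            NA,      NA,    0.69,
    "K",      40,     24,            NA,      NA,    939,
    "La",     0.05,   70,            0.10,    NA,    0.79,
    "Li",     0.06,   32,            NA,      NA,    6.07,
    "Mg",     10,     100,           91,      21,    723,
    "Mn",     0.5,    100,           2.4,     1.1,   43.5,
    "Mo",     0.3,    20,            NA,      NA,    2.0,
    "Na",     25,     98,            110,     NA,    585,
    "Nb",     0.04,   7,             NA,      NA,    0.11,
    "Nd",     0.03,   52,            0.03,    NA,    13.8,
    "Ni",     0.5,    100,           5.6,     2.1,   49.7,
    "P",      60,     100,           272,     127,   650,
    "Pb",     0.3,    99,            0.9,     NA,    22.1,
    "Pr",     0.008,  40,            NA,      NA,    1.65,
    "Rb",     0.06,   99,            0.24,    NA,    1.77,
    "Sb",     0.02,   16,            NA,      NA,    0.37,
    "Se",     0.6,    48,            NA,      NA,    7.8,
    "Si",     270,    1,             NA,      NA,    3340,
    "Sn",     0.06,   63,            0.08,    NA,    1.94,
    "Sr",     1,      65,            3,       1,     58,
    "Tb",     0.006,  19,            NA,      NA,    1.28,
    "Te",     0.03,   3,             NA,      NA,    0.06,
    "Ti",     0.4,    100,           1.9,     0.8,   10.7,
    "Tl",     0.06,   0,             NA,      NA,    NA,
    "U",      0.005,  30,            NA,      NA,    0.050,
    "V",      0.08,   98,            0.53,    NA,    1.40,
    "W",      0.3,    38,            NA,      NA,    5.1,
    "Zn",     20,     100,           111,     54,    749,
    "Zr",     0.1,    57,            NA,      NA,    2.3
  )
}

#' Default 45-element EVOO panel
#'
#' Builds the default element panel used by the synthetic data generator: one
#' row per element with its method detection limit (MDL, ug/kg) and the
#' location (`log_mean`) and scale (`log_sd`) of a log-normal concentration
#' law on the natural-log scale. The log-normal parameters are derived from
#' published survey summaries (median, detection percentage, maximum at
#' n = 237) so that simulated panels reproduce the detection rates and
#' concentration ranges of real multielement EVOO data:
#'
#' * detected median `m` fixes `log_mean = log(m)`;
#' * the detected fraction `p` fixes the censoring quantile,
#'   `log_mean = log(mdl) + log_sd * qnorm(p)`, which is solved for `log_sd`;
#' * for fully detected elements the observed maximum (expected extreme of
#'   237 log-normal draws, roughly 2.8 SD above the median) bounds `log_sd`;
#' * for elements whose median is below the MDL the two constraints
#'   (detection quantile, observed maximum) are solved jointly;
#' * fully censored elements are placed 3 SD below their MDL.
#'
#' @param summary A data frame with columns `element`, `mdl`, `pct_detected`,
#'   `median`, `min`, `max` (ug/kg; `NA` where below the MDL). Defaults to the
#'   built-in 45-element survey summary.
#' @return A tibble with columns `element`, `mdl`, `log_mean`, `log_sd`.
#' @examples
#' panel <- default_panel()
#' nrow(panel) # 45
#' @export
default_panel <- function(summary = .evoo_survey_summary()) {
  stopifnot(all(c("element", "mdl", "pct_detected", "median", "max") %in%
                  names(summary)))
  if (any(summary$mdl <= 0)) {
    abort("all MDLs must be strictly positive")
  }
  # z-score of the expected maximum of ~237 iid normal draws
  z_max <- qnorm(1 - 1 / (237 + 1))
  rows <- purrr::pmap(summary, function(element, mdl, pct_detected, median,
                                        min, max, ...) {
    p <- base::min(base::max(pct_detected / 100, 0.005), 0.995)
    if (pct_detected == 0 || (is.na(median) && is.na(max))) {
      log_sd <- 0.5
      log_mean <- log(mdl) - 3 * log_sd
    } else if (!is.na(median)) {
      log_mean <- log(median)
      if (pct_detected >= 100) {
        cand <- (log(max) - log_mean) / z_max
        cand <- base::min(cand, (log_mean - log(mdl)) / qnorm(0.995))
        log_sd <- base::max(cand, 0.2)
      } else {
        log_sd <- base::max((log_mean - log(mdl)) / qnorm(p), 0.05)
      }
    } else {
      # median below MDL: match the detection fraction and the observed max
      log_sd <- (log(max) - log(mdl)) / (z_max - qnorm(p))
      log_sd <- base::max(log_sd, 0.05)
      log_mean <- log(mdl) + log_sd * qnorm(p)
    }
    tibble::tibble(element = element, mdl = mdl,
                   log_mean = log_mean, log_sd = log_sd)
  })
  dplyr::bind_rows(rows)
}

# Region -> macro-area grouping used throughout the Italian EVOO survey.
.macro_area_map <- function() {
  list(
    north   = c("emilia romagna", "liguria", "lombardy", "trentino alto adige",
                "veneto"),
    central = c("abruzzo", "lazio", "marche", "tuscany", "toscany", "toscana",
                "umbria"),
    south   = c("apulia", "calabria", "campania", "sardinia", "sicily")
  )
}

#' Map an Italian region to its macro-area
#'
#' Groups the 15 production regions into north / central / south Italy.
#' Matching is case-insensitive and ignores accents and surrounding
#' whitespace; a region outside the three lists maps to `"unknown"`.
#'
#' @param region Character vector of region names.
#' @return Character vector with values `"north"`, `"central"`, `"south"` or
#'   `"unknown"`.
#' @examples
#' assign_macro_area(c("Lazio", "Sicily", "Veneto", "Bavaria"))
#' @export
assign_macro_area <- function(region) {
  norm <- tolower(trimws(as.character(region)))
  norm <- iconv(norm, to = "ASCII//TRANSLIT")
  map <- .macro_area_map()
  out <- rep("unknown", length(norm))
  out[norm %in% map$north] <- "north"
  out[norm %in% map$central] <- "central"
  out[norm %in% map$south] <- "south"
  out
}

#' Default per-region sample counts
#'
#' The number of EVOO samples per Italian production region in the reference
#' survey (237 samples across 15 regions), used as the default class sizes of
#' the synthetic data generator so that realistic class unbalance (e.g. 79
#' Tuscany samples vs 1 from Emilia Romagna) is represented.
#'
#' @return A tibble with columns `label` (region) and `n`.
#' @export
region_counts <- function() {
  tibble::tribble(
    ~label,                 ~n,
    "Trentino Alto Adige",   7L,
    "Liguria",               6L,
    "Lombardy",              3L,
    "Veneto",                3L,
    "Emilia Romagna",        1L,
    "Abruzzo",              14L,
    "Lazio",                24L,
    "Marche",                7L,
    "Tuscany",              79L,
    "Umbria",                8L,
    "Apulia",               33L,
    "Calabria",             12L,
    "Campania",              7L,
    "Sardinia",             12L,
    "Sicily",               21L
  )
}

#' Regulatory maximum residue levels for olive oil
#'
#' International Olive Council maximum residue levels (MRLs) for trace metals
#' in olive and olive-pomace oils: 100 ug/kg for As, Cu and Pb, and
#' 3000 ug/kg for Fe.
#'
#' @return A tibble with columns `element` and `limit` (ug/kg).
#' @export
mrl_limits <- function() {
  tibble::tibble(
    element = c("As", "Cu", "Pb", "Fe"),
    limit = c(100, 100, 100, 3000)
  )
}
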