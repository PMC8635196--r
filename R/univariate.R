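# Censoring-aware descriptive summaries, nonparametric group comparison,
# DPPH% antioxidant index, element-DPPH correlation, and MRL compliance.

#' Summarise element concentrations
#'
#' Per-element detection percentage and median/min/max on the imputed scale,
#' mirroring the layout of published multielement survey tables. Order
#' statistics falling below the element's MDL are rendered as `"<MDL"` in the
#' label columns while the numeric columns keep the imputed values.
#'
#' @param data A long concentration tibble, already imputed (see
#'   [substitute_censored()]) and replicate-averaged.
#' @return A tibble with columns `element`, `n`, `pct_detected`, `median`,
#'   `min`, `max` and rendered `median_label`, `min_label`, `max_label`.
#' @export
summarize_elements <- function(data) {
  .check_conc(data)
  if (nrow(data) == 0) abort("empty concentration table")
  if (any(is.na(data$value))) {
    abort("censored cells are unimputed; run substitute_censored() first")
  }
  lab <- function(v, mdl) {
    ifelse(v < mdl, paste0("<", format(mdl, trim = TRUE)),
           format(signif(v, 3), trim = TRUE))
  }
  dplyr::summarise(
    dplyr::group_by(data, .data$element),
    n = dplyr::n(),
    pct_detected = 100 * mean(!.data$censored),
    median = median(.data$value),
    min = min(.data$value),
    max = max(.data$value),
    median_label = lab(.data$median[1], .data$mdl[1]),
    min_label = lab(.data$min[1], .data$mdl[1]),
    max_label = lab(.data$max[1], .data$mdl[1]),
    .groups = "drop"
  )
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H with the chi-square approximation on
#' k - 1 degrees of freedom (via [stats::kruskal.test()]). The MDL/2
#' imputation creates heavy ties, which the tie correction handles. When all
#' pooled values are identical the test is degenerate and `p = 1`, `H = 0`
#' by convention.
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping vector of the same length (>= 2 groups, each
#'   nonempty).
#' @param alpha Significance level; default 0.05.
#' @return A one-row tibble: `statistic` (H), `df`, `p_value`, `significant`.
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6, 7, 8, 9), rep(1:3, each = 3))
#' @export
kruskal_wallis <- function(values, groups, alpha = 0.05) {
  stopifnot(length(values) == length(groups))
  groups <- factor(groups)
  if (nlevels(groups) < 2) abort("need at least 2 groups")
  if (any(table(groups) == 0)) abort("every group needs at least one value")
  if (length(unique(values)) == 1) {
    return(tibble::tibble(statistic = 0, df = nlevels(groups) - 1L,
                          p_value = 1, significant = FALSE))
  }
  kt <- kruskal.test(values, groups)
  tibble::tibble(
    statistic = unname(kt$statistic),
    df = unname(kt$parameter),
    p_value = unname(kt$p.value),
    significant = unname(kt$p.value) < alpha
  )
}

#' Dunn's pairwise post-hoc test
#'
#' Pairwise z-tests on the joint ranks following a Kruskal-Wallis test
#' (Dunn's test), with tie correction and Bonferroni adjustment across the
#' k(k-1)/2 pairs by default.
#'
#' @inheritParams kruskal_wallis
#' @param p_adjust Multiplicity adjustment passed to [stats::p.adjust()];
#'   default `"bonferroni"`.
#' @return A tibble with one row per pair: `group1`, `group2`, `z`,
#'   `p_value` (raw), `p_adjusted`, `significant`.
#' @export
pairwise_posthoc <- function(values, groups, alpha = 0.05,
                             p_adjust = "bonferroni") {
  stopifnot(length(values) == length(groups))
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2) abort("need at least 2 groups")
  n <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  ng <- tapply(r, groups, length)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  v0 <- n * (n + 1) / 12 - tie_corr
  pairs <- utils::combn(levels(groups), 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]
    g2 <- pairs[2, j]
    se <- sqrt(v0 * (1 / ng[[g1]] + 1 / ng[[g2]]))
    z <- if (se > 0) (rbar[[g1]] - rbar[[g2]]) / se else 0
    tibble::tibble(group1 = g1, group2 = g2, z = z,
                   p_value = 2 * pnorm(-abs(z)))
  })
  res$p_adjusted <- p.adjust(res$p_value, method = p_adjust)
  res$significant <- res$p_adjusted < alpha
  res
}

#' Per-element group comparison
#'
#' Runs the Kruskal-Wallis test (and optionally Dunn's post-hoc) for every
#' element column of a wide analysis table against a grouping vector — the
#' workhorse behind region/macro-area comparison tables.
#'
#' @param data Wide analysis tibble (`sample_id` plus element columns).
#' @param groups Grouping vector aligned with the rows of `data`.
#' @param alpha Significance level; default 0.05.
#' @param posthoc If `TRUE`, attach Dunn's pairwise results as a list-column.
#' @return A tibble with one row per element: `element`, `statistic`, `df`,
#'   `p_value`, `significant` (and `posthoc` list-column if requested).
#' @export
compare_elements <- function(data, groups, alpha = 0.05, posthoc = FALSE) {
  x <- .as_feature_matrix(data)
  stopifnot(nrow(x) == length(groups))
  out <- purrr::map_dfr(colnames(x), function(el) {
    kw <- kruskal_wallis(x[, el], groups, alpha = alpha)
    dplyr::bind_cols(tibble::tibble(element = el), kw)
  })
  if (posthoc) {
    out$posthoc <- purrr::map(out$element, function(el) {
      pairwise_posthoc(x[, el], groups, alpha = alpha)
    })
  }
  out
}

#' DPPH radical-scavenging percentage
#'
#' Percentage reduction of the DPPH radical's absorbance at 517 nm:
#' `(a0 - a_s) / a0 * 100`, where `a0` is the blank absorbance and `a_s` the
#' sample absorbance. The result is strictly decreasing in `a_s` and
#' invariant to a common rescaling of both absorbances. A sample absorbance
#' above the blank yields a negative percentage, reported with a warning
#' rather than clipped, since it flags an assay failure.
#'
#' @param a0 Blank absorbance(s), > 0 (AU).
#' @param a_s Sample absorbance(s), >= 0 (AU); recycled against `a0`.
#' @return Numeric vector of DPPH percentages.
#' @examples
#' dpph_percent(0.80, 0.40) # 50
#' @export
dpph_percent <- function(a0, a_s) {
  if (any(a0 <= 0)) abort("blank absorbance a0 must be strictly positive")
  if (any(a_s < 0)) abort("sample absorbance a_s must be non-negative")
  out <- (a0 - a_s) / a0 * 100
  if (any(out < 0)) {
    warn("sample absorbance exceeds the blank: negative DPPH% reported")
  }
  out
}

#' Correlate element concentrations with DPPH%
#'
#' Per-element rank (Spearman, default) or Pearson correlation with the
#' antioxidant index, with a two-sided p-value. Correlations are classified
#' as `"low"` (|r| < 0.4), `"moderate"` (0.4 <= |r| <= 0.768) or `"high"`
#' following the conventional reading of element-antioxidant associations
#' in EVOO surveys. Constant element columns have no defined correlation and
#' are reported as `NA`.
#'
#' @param data Wide analysis tibble (`sample_id` plus element columns).
#' @param dpph Numeric vector of DPPH percentages aligned with the rows.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param alpha Significance level; default 0.05.
#' @return Tibble: `element`, `r`, `p_value`, `significant`, `strength`.
#' @export
correlate_with_dpph <- function(data, dpph,
                                method = c("spearman", "pearson"),
                                alpha = 0.05) {
  method <- match.arg(method)
  x <- .as_feature_matrix(data)
  stopifnot(nrow(x) == length(dpph))
  if (nrow(x) < 3) abort("need at least 3 paired observations")
  purrr::map_dfr(colnames(x), function(el) {
    v <- x[, el]
    if (sd(v) == 0 || sd(dpph) == 0) {
      return(tibble::tibble(element = el, r = NA_real_, p_value = NA_real_,
                            significant = NA, strength = NA_character_))
    }
    ct <- suppressWarnings(cor.test(v, dpph, method = method, exact = FALSE))
    r <- unname(ct$estimate)
    tibble::tibble(
      element = el, r = r, p_value = unname(ct$p.value),
      significant = unname(ct$p.value) < alpha,
      strength = dplyr::case_when(
        abs(r) < 0.4 ~ "low",
        abs(r) <= 0.768 ~ "moderate",
        TRUE ~ "high"
      )
    )
  })
}

#' Check concentrations against regulatory maximum residue levels
#'
#' Compares each element's measured concentrations against its maximum
#' residue level (MRL). Censored cells trivially comply (an MDL/2 value is
#' below any MRL of interest); a value exactly at the limit is compliant
#' (`<=` convention). Per-sample exceedances are attached as the
#' `violations` attribute.
#'
#' @param data A long concentration tibble.
#' @param limits Data frame with columns `element`, `limit` (ug/kg);
#'   defaults to the olive-oil MRLs ([mrl_limits()]).
#' @return Tibble: `element`, `limit`, `max_observed`, `n_exceeding`,
#'   `compliant`; attribute `violations` holds a tibble of offending
#'   sample/element pairs.
#' @export
check_mrl <- function(data, limits = mrl_limits()) {
  .check_conc(data)
  stopifnot(all(c("element", "limit") %in% names(limits)))
  if (any(limits$limit <= 0)) abort("MRL limits must be positive")
  report <- purrr::map_dfr(seq_len(nrow(limits)), function(i) {
    el <- limits$element[i]
    lim <- limits$limit[i]
    rows <- data[data$element == el & !data$censored & !is.na(data$value), ]
    mx <- if (nrow(rows) > 0) max(rows$value) else NA_real_
    n_exc <- sum(rows$value > lim)
    tibble::tibble(element = el, limit = lim, max_observed = mx,
                   n_exceeding = n_exc,
                   compliant = is.na(mx) || mx <= lim)
  })
  viol <- dplyr::inner_join(
    dplyr::filter(data, !.data$censored & !is.na(.data$value)),
    tibble::as_tibble(limits), by = "element"
  )
  viol <- dplyr::filter(viol, .data$value > .data$limit)
  attr(report, "violations") <-
    dplyr::select(viol, "sample_id", "element", "value", "limit")
  report
}
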