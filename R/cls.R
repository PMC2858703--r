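#' Survival fractions from a colony-forming-unit series
#'
#' Converts a CFU time series for one strain and condition into survival
#' fractions relative to a reference day:
#' `fraction(d) = cfu(d) * dilution(d) / (cfu(ref) * dilution(ref))`.
#' The result is invariant to uniform rescaling of all CFU values.
#'
#' @param series Tibble with columns `day`, `cfu` (colonies counted per
#'   volume plated, >= 0) and optionally `dilution` (dilution factor,
#'   defaults to 1); days must be strictly increasing.
#' @param reference_day Day with fraction 1; defaults to the first day.
#' @return Tibble `day`, `fraction` with `fraction[reference_day] == 1`.
#' @export
#' @examples
#' s <- tibble::tibble(day = c(1, 9, 21), cfu = c(400, 200, 100))
#' survival_curve(s)
survival_curve <- function(series, reference_day = min(series$day)) {
  assert_columns(series, c("day", "cfu"), "`series`")
  if (is.unsorted(series$day, strictly = TRUE)) {
    stop_clscreen("`series$day` must be strictly increasing", "bad_input")
  }
  if (any(series$cfu < 0)) {
    stop_clscreen("CFU counts must be >= 0", "bad_input")
  }
  dilution <- if ("dilution" %in% names(series)) series$dilution else rep(1, nrow(series))
  ref <- which(series$day == reference_day)
  if (length(ref) != 1) {
    stop_clscreen("`reference_day` must appear exactly once in the series", "bad_input")
  }
  ref_count <- series$cfu[ref] * dilution[ref]
  if (ref_count <= 0) {
    stop_clscreen("reference-day CFU must be > 0", "zero_reference")
  }
  tibble(day = series$day, fraction = series$cfu * dilution / ref_count)
}

#' Classify a strain's chronological lifespan against wild type
#'
#' Compares two survival curves on their shared days by the time-averaged
#' difference of log10 survival (the area under the log10-survival
#' difference divided by the shared day span). A strain surviving uniformly
#' 10x better than wild type scores +1; `|score| <= margin` is `"normal"`,
#' a positive score beyond the margin `"long"`, negative `"short"`. Curves
#' that cross with equal area score 0 and classify `"normal"`.
#'
#' @param strain_curve,wt_curve Survival-curve tibbles from
#'   [survival_curve()] (columns `day`, `fraction`).
#' @param margin Classification margin in average log10 survival units
#'   (default 0.5, calibrated so replicate wild-type-vs-wild-type assays
#'   classify `"normal"` at least 95\% of the time under plating noise).
#' @param strain_id,wt_id Optional labels stored in the verdict.
#' @param floor Detection floor: survival fractions are floored at this
#'   value before taking log10, so days with zero colonies stay comparable
#'   and sub-detection counts (0 vs 1 colony) cannot dominate the score.
#'   The default 1e-3 is roughly the dynamic range of a quantitative CFU
#'   assay.
#' @return A one-row tibble of class `lifespan_verdict`: `strain`,
#'   `reference`, `class`, `statistic` (average log10 survival difference),
#'   `margin`, `n_days`.
#' @export
classify_lifespan <- function(strain_curve, wt_curve, margin = 0.5,
                              strain_id = "strain", wt_id = "WT",
                              floor = 1e-3) {
  assert_columns(strain_curve, c("day", "fraction"), "`strain_curve`")
  assert_columns(wt_curve, c("day", "fraction"), "`wt_curve`")
  shared <- intersect(strain_curve$day, wt_curve$day)
  if (length(shared) < 2) {
    stop_clscreen("fewer than 2 shared days between the curves", "bad_input")
  }
  shared <- sort(shared)
  ls <- log10(pmax(strain_curve$fraction[match(shared, strain_curve$day)], floor))
  lw <- log10(pmax(wt_curve$fraction[match(shared, wt_curve$day)], floor))
  diffs <- ls - lw
  # trapezoidal area of the log10 difference, normalised by the day span
  span <- diff(range(shared))
  auc <- sum(diff(shared) * (utils::head(diffs, -1) + utils::tail(diffs, -1)) / 2)
  statistic <- auc / span
  cls <- if (abs(statistic) <= margin) "normal" else if (statistic > 0) "long" else "short"
  out <- tibble(
    strain = strain_id, reference = wt_id, class = cls,
    statistic = statistic, margin = margin, n_days = length(shared)
  )
  structure(out, class = c("lifespan_verdict", class(out)))
}

#' @rdname classify_lifespan
#' @param x A `lifespan_verdict`.
#' @param ... Unused.
#' @method tidy lifespan_verdict
#' @export
tidy.lifespan_verdict <- function(x, ...) {
  as_tibble(unclass(x))
}

#' Percent survival after an acute challenge
#'
#' `100 * cfu_treated / cfu_untreated`, elementwise over replicates; values
#' above 100 are legitimate (treated sample outgrowing the untreated one).
#'
#' @param cfu_treated,cfu_untreated Equal-length numeric vectors of CFU
#'   counts per replicate; untreated counts must be > 0.
#' @return One-row tibble: `n`, `mean_percent`, `sd_percent` (NA for a
#'   single replicate), plus the per-replicate percentages as a list column
#'   `percent`.
#' @export
#' @examples
#' percent_survival(50, 200)
percent_survival <- function(cfu_treated, cfu_untreated) {
  if (length(cfu_treated) != length(cfu_untreated)) {
    stop_clscreen("treated and untreated vectors must have equal length", "bad_input")
  }
  if (any(cfu_untreated <= 0)) {
    stop_clscreen("untreated CFU must be > 0", "zero_untreated")
  }
  pct <- 100 * cfu_treated / cfu_untreated
  tibble(
    n = length(pct),
    mean_percent = mean(pct),
    sd_percent = if (length(pct) > 1) stats::sd(pct) else NA_real_,
    percent = list(pct)
  )
}

#' Confirmation rate of retested candidates
#'
#' `100 * n_confirmed / n_tested`, rounded half away from zero to one
#' decimal — the convention of printed screen-validation percentages
#' (13 of 16 gives 81.3).
#'
#' @param n_confirmed,n_tested Non-negative counts with
#'   `n_confirmed <= n_tested` and `n_tested > 0`.
#' @return A single percentage rounded to one decimal.
#' @export
#' @examples
#' confirmation_rate(13, 16)
confirmation_rate <- function(n_confirmed, n_tested) {
  if (any(n_tested <= 0)) {
    stop_clscreen("`n_tested` must be > 0", "bad_input")
  }
  if (any(n_confirmed < 0) || any(n_confirmed > n_tested)) {
    stop_clscreen("`n_confirmed` must be between 0 and `n_tested`", "bad_input")
  }
  round_half_up(100 * n_confirmed / n_tested, 1)
}

#' Overlap between two gene sets
#'
#' @param set_a,set_b Character vectors of gene ids; `set_a` must be
#'   non-empty.
#' @return One-row tibble: `n_a`, `n_b`, `n_shared` and `percent_of_a`
#'   (`100 * |A intersect B| / |A|`, rounded half away from zero to one
#'   decimal).
#' @export
#' @examples
#' gene_set_overlap(letters[1:4], letters[3:6])
gene_set_overlap <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (length(set_a) == 0) {
    stop_clscreen("`set_a` is empty", "bad_input")
  }
  shared <- length(intersect(set_a, set_b))
  tibble(
    n_a = length(set_a), n_b = length(set_b), n_shared = shared,
    percent_of_a = round_half_up(100 * shared / length(set_a), 1)
  )
}

#' Simulate a colony-forming-unit series from a Weibull survival truth
#'
#' Generates the CFU counts an individual-strain chronological lifespan
#' assay would produce for a strain with known survival kinetics: at each
#' day the expected number of colonies is
#' `cells_plated * S(d) / dilution`, observed with Poisson counting noise.
#'
#' @param tau,shape_k Weibull survival parameters.
#' @param days Sampling days.
#' @param cells_plated Viable-equivalent cells plated at full survival.
#' @param dilution Dilution factor (scalar or per day).
#' @param seed Integer seed.
#' @return Tibble `day`, `cfu`, `dilution`.
#' @export
simulate_cfu_series <- function(tau, shape_k, days = c(1, 9, 21, 33),
                                cells_plated = 2e5, dilution = 100, seed = 1) {
  set.seed(derive_seed(seed, "cfu"))
  dilution <- rep(dilution, length.out = length(days))
  expected <- cells_plated * weibull_survival(days, tau, shape_k) / dilution
  tibble(day = days, cfu = stats::rpois(length(days), expected), dilution = dilution)
}
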