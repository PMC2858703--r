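#' Configuration for the synthetic pooled-screen simulator
#'
#' Bundles every tunable parameter of the simulator: the sampling design
#' (days, conditions, plating depth), the survival model (Weibull shape,
#' class-specific characteristic lifetimes, the calorie-restriction boost),
#' the measurement model (tag efficiencies, log-normal intensity noise,
#' nonspecific-hybridization background) and the adaptive-regrowth model.
#'
#' Defaults emulate a pooled screen of the yeast knockout collection aged in
#' stationary phase: samples at days 1 (reference), 9, 21 and 33 under
#' non-restricted (NR, 2\% glucose) and calorie-restricted (CR, 0.5\% glucose)
#' media; a characteristic NR survival time of 11 days for phenotypically
#' normal deletion strains with Weibull shape 2 (a die-off shoulder); and a
#' 1.5-fold CR extension of survival time for CR-responsive strains.
#'
#' @param sample_days Integer vector of sampling days, strictly increasing;
#'   the first element is the reference day.
#' @param conditions Character vector of growth conditions.
#' @param plating_depth Number of cells recovered per plating (one multinomial
#'   draw per condition and day).
#' @param pool_size Total viable cells in the culture at the reference scale;
#'   only sets the absolute scale of expected viable-cell trajectories.
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   intensity noise applied independently to every probe measurement.
#' @param background_mean,background_cv Mean and CV of the additive
#'   nonspecific-hybridization intensity (fluorescence a.u.).
#' @param tau_base Median characteristic survival time (days) of a
#'   phenotypically normal mutant under NR.
#' @param shape_k Weibull shape parameter (> 0), shared by all mutants.
#' @param short_factor,long_factor Multipliers applied to `tau_base` for the
#'   planted short-lived and long-lived classes.
#' @param class_sdlog Named numeric vector of log-normal spreads (sdlog) of
#'   the characteristic survival time within each lifespan class.
#' @param cr_boost Multiplier taking `tau_nr` to `tau_cr` for CR-responsive
#'   mutants; CR-unresponsive mutants keep `tau_cr = tau_nr`.
#' @param regrowth_prob Per-timecourse (gene x condition) probability of an
#'   adaptive-regrowth event.
#' @param regrowth_factor Multiplicative jump applied to the viable count from
#'   the regrowth day onward.
#' @param missing_tag_prob Probability that a given tag of a mutant is absent
#'   from the array (no usable probe).
#' @param tag_eff_range Range of the per-gene, per-tag hybridization
#'   efficiency, drawn uniformly.
#' @param abundance_sdlog Log-normal spread of initial pool fractions across
#'   non-essential mutants (fractions are renormalised to sum to 1).
#' @param n_essential Number of essential-gene probes appended to the array;
#'   these have no mutant in the pool and receive background signal only.
#' @param seed Master integer seed; all random sub-streams derive from it.
#'
#' @return A list of class `pool_config`.
#' @export
#' @examples
#' cfg <- pool_config(plating_depth = 1e6, n_essential = 50)
#' cfg$sample_days
pool_config <- function(sample_days = c(1L, 9L, 21L, 33L),
                        conditions = c("NR", "CR"),
                        plating_depth = 2e8,
                        pool_size = 1e10,
                        noise_cv = 0.1,
                        background_mean = 50,
                        background_cv = 0.3,
                        tau_base = 11,
                        shape_k = 2,
                        short_factor = 1 / 3,
                        long_factor = 3,
                        class_sdlog = c(short = 0.30, normal = 0.05,
                                        long = 0.20, cr_unresponsive = 0.05),
                        cr_boost = 1.5,
                        regrowth_prob = 0.005,
                        regrowth_factor = 25,
                        missing_tag_prob = 0.01,
                        tag_eff_range = c(0.4, 1),
                        abundance_sdlog = 0.2,
                        n_essential = 1000,
                        seed = 1L) {
  sample_days <- as.integer(sample_days)
  if (length(sample_days) < 2 || is.unsorted(sample_days, strictly = TRUE)) {
    stop_clscreen("`sample_days` must be strictly increasing with >= 2 days", "bad_config")
  }
  if (plating_depth <= 0) {
    stop_clscreen("`plating_depth` must be > 0", "bad_config")
  }
  if (noise_cv < 0 || background_cv < 0) {
    stop_clscreen("coefficients of variation must be >= 0", "bad_config")
  }
  if (shape_k <= 0 || tau_base <= 0) {
    stop_clscreen("`shape_k` and `tau_base` must be > 0", "bad_config")
  }
  needed <- c("short", "normal", "long", "cr_unresponsive")
  if (!all(needed %in% names(class_sdlog))) {
    stop_clscreen("`class_sdlog` must name all four lifespan classes", "bad_config")
  }
  structure(
    list(
      sample_days = sample_days,
      conditions = conditions,
      plating_depth = plating_depth,
      pool_size = pool_size,
      noise_cv = noise_cv,
      background_mean = background_mean,
      background_cv = background_cv,
      tau_base = tau_base,
      shape_k = shape_k,
      short_factor = short_factor,
      long_factor = long_factor,
      class_sdlog = class_sdlog,
      cr_boost = cr_boost,
      regrowth_prob = regrowth_prob,
      regrowth_factor = regrowth_factor,
      missing_tag_prob = missing_tag_prob,
      tag_eff_range = tag_eff_range,
      abundance_sdlog = abundance_sdlog,
      n_essential = n_essential,
      seed = as.integer(seed)
    ),
    class = "pool_config"
  )
}

# Largest-remainder apportionment of n among classes, so realised counts are
# within rounding of the requested fractions.
apportion_classes <- function(n, fractions) {
  quota <- n * fractions
  counts <- floor(quota)
  left <- n - sum(counts)
  if (left > 0) {
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(left)]
    counts[extra] <- counts[extra] + 1
  }
  counts
}

#' Build a synthetic pool of deletion-mutant profiles
#'
#' Constructs one profile per mutant: lifespan class, characteristic Weibull
#' survival times under NR and CR, initial pool fraction, per-tag
#' hybridization efficiencies and missing-tag flags. A configurable number of
#' essential-gene "probe-only" entries is appended; these carry zero pool
#' abundance and model array probes with no corresponding viable mutant.
#'
#' Class survival times are drawn log-normally around class medians:
#' `tau_base` for normal and CR-unresponsive mutants, `tau_base * short_factor`
#' for short-lived and `tau_base * long_factor` for long-lived mutants, with
#' class-specific spreads (`class_sdlog`). CR multiplies `tau_nr` by
#' `cr_boost`, except for CR-unresponsive mutants where `tau_cr = tau_nr`.
#'
#' @param n_mutants Number of non-essential (viable) mutants, >= 1.
#' @param class_fractions Named fractions over
#'   `c("short", "normal", "long", "cr_unresponsive")` (missing names mean 0);
#'   must sum to 1 within 1e-9.
#' @param config A [pool_config()].
#' @param seed Integer seed; defaults to `config$seed`. A fixed seed makes the
#'   pool fully reproducible.
#'
#' @return A tibble with one row per mutant (non-essential first, then
#'   essential probes) and columns `gene_id`, `essential`, `true_class`,
#'   `tau_nr`, `tau_cr`, `shape_k`, `initial_abundance`, `uptag_eff`,
#'   `dntag_eff`, `uptag_missing`, `dntag_missing`.
#' @export
#' @examples
#' pool <- build_pool(100, c(normal = 1), pool_config(n_essential = 10), seed = 1)
#' table(pool$true_class)
build_pool <- function(n_mutants,
                       class_fractions = c(short = 0.05, normal = 0.85,
                                           long = 0.05, cr_unresponsive = 0.05),
                       config = pool_config(),
                       seed = config$seed) {
  if (n_mutants < 1) {
    stop_clscreen("`n_mutants` must be >= 1", "bad_input")
  }
  classes <- c("short", "normal", "long", "cr_unresponsive")
  frac <- stats::setNames(rep(0, length(classes)), classes)
  if (!all(names(class_fractions) %in% classes)) {
    stop_clscreen("unknown class name in `class_fractions`", "bad_input")
  }
  frac[names(class_fractions)] <- class_fractions
  if (abs(sum(frac) - 1) > 1e-9) {
    stop_clscreen("`class_fractions` must sum to 1 (within 1e-9)", "bad_input")
  }

  set.seed(derive_seed(seed, "build_pool"))

  counts <- apportion_classes(n_mutants, frac)
  true_class <- sample(rep(classes, counts))

  median_tau <- config$tau_base * c(
    short = config$short_factor, normal = 1,
    long = config$long_factor, cr_unresponsive = 1
  )
  tau_nr <- stats::rlnorm(
    n_mutants,
    meanlog = log(median_tau[true_class]),
    sdlog = config$class_sdlog[true_class]
  )
  boost <- ifelse(true_class == "cr_unresponsive", 1, config$cr_boost)
  tau_cr <- tau_nr * boost

  abundance <- rlnorm_cv(n_mutants, mean = 1, cv = sqrt(exp(config$abundance_sdlog^2) - 1))
  abundance <- abundance / sum(abundance)

  eff <- function(n) stats::runif(n, config$tag_eff_range[1], config$tag_eff_range[2])

  mutants <- tibble(
    gene_id = sprintf("YSM%04dW", seq_len(n_mutants)),
    essential = FALSE,
    true_class = true_class,
    tau_nr = tau_nr,
    tau_cr = tau_cr,
    shape_k = config$shape_k,
    initial_abundance = abundance,
    uptag_eff = eff(n_mutants),
    dntag_eff = eff(n_mutants),
    uptag_missing = stats::runif(n_mutants) < config$missing_tag_prob,
    dntag_missing = stats::runif(n_mutants) < config$missing_tag_prob
  )

  if (config$n_essential > 0) {
    n_ess <- config$n_essential
    essentials <- tibble(
      gene_id = sprintf("YSE%04dC", seq_len(n_ess)),
      essential = TRUE,
      true_class = NA_character_,
      tau_nr = NA_real_,
      tau_cr = NA_real_,
      shape_k = config$shape_k,
      initial_abundance = 0,
      uptag_eff = eff(n_ess),
      dntag_eff = eff(n_ess),
      uptag_missing = stats::runif(n_ess) < config$missing_tag_prob,
      dntag_missing = stats::runif(n_ess) < config$missing_tag_prob
    )
    mutants <- dplyr::bind_rows(mutants, essentials)
  }
  mutants
}
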