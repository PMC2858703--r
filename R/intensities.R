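#' Synthesize two-channel tag intensities from plated counts
#'
#' Models PCR amplification, fluorescent labeling and hybridization of the
#' UPTAG/DNTAG barcodes for one array (one condition and later day
#' co-hybridized against the reference day). The expected intensity of a
#' probe is `count * tag_efficiency + background`; the realised intensity
#' multiplies the count term by independent multiplicative log-normal noise
#' (CV `noise_cv`) and adds a log-normal background draw (mean
#' `background_mean`, CV `background_cv`). Essential probes (no mutant in the
#' pool) receive background only; missing tags get empty (`NA`) intensities.
#'
#' @param counts_ref_day,counts_day_d Count tibbles from [sample_survivors()]
#'   for the reference day and a later day, over the same gene set and
#'   condition(s).
#' @param profiles Pool tibble from [build_pool()] (provides tag efficiencies
#'   and flags).
#' @param config A [pool_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#'
#' @return A tag-intensity tibble with columns `gene_id`, `tag` (`"UP"` or
#'   `"DN"`), `condition`, `day`, `intensity_ref`, `intensity_day`; strictly
#'   positive where present.
#' @export
synthesize_intensities <- function(counts_ref_day, counts_day_d, profiles, config,
                                   seed = config$seed) {
  assert_columns(counts_ref_day, c("gene_id", "condition", "day", "count"), "`counts_ref_day`")
  assert_columns(counts_day_d, c("gene_id", "condition", "day", "count"), "`counts_day_d`")
  if (any(counts_ref_day$count < 0) || any(counts_day_d$count < 0)) {
    stop_clscreen("counts must be non-negative", "bad_input")
  }
  key_ref <- paste(counts_ref_day$gene_id, counts_ref_day$condition)
  key_d <- paste(counts_day_d$gene_id, counts_day_d$condition)
  if (!setequal(counts_ref_day$gene_id, counts_day_d$gene_id)) {
    stop_clscreen("count tables must cover the same gene set", "bad_input")
  }

  day_d <- unique(counts_day_d$day)
  set.seed(derive_seed(seed, paste0("intensities_d", day_d[1], "_",
                                    paste(unique(counts_day_d$condition), collapse = ""))))

  merged <- dplyr::inner_join(
    dplyr::rename(counts_ref_day, count_ref = "count", day_ref = "day"),
    dplyr::rename(counts_day_d, count_day = "count"),
    by = c("gene_id", "condition")
  )
  merged <- dplyr::left_join(
    merged,
    profiles[, c("gene_id", "essential", "uptag_eff", "dntag_eff",
                 "uptag_missing", "dntag_missing")],
    by = "gene_id"
  )

  long <- tidyr::pivot_longer(
    merged,
    cols = c("uptag_eff", "dntag_eff"),
    names_to = "tag", values_to = "efficiency"
  )
  long$tag <- ifelse(long$tag == "uptag_eff", "UP", "DN")
  long$missing <- ifelse(long$tag == "UP", long$uptag_missing, long$dntag_missing)
  # essential probes: no template in the pool, background signal only
  long$count_ref[long$essential] <- 0
  long$count_day[long$essential] <- 0

  n <- nrow(long)
  one_channel <- function(count, eff) {
    count * eff * rlnorm_cv(n, 1, config$noise_cv) +
      rlnorm_cv(n, config$background_mean, config$background_cv)
  }
  intensity_ref <- one_channel(long$count_ref, long$efficiency)
  intensity_day <- one_channel(long$count_day, long$efficiency)
  intensity_ref[long$missing] <- NA_real_
  intensity_day[long$missing] <- NA_real_

  tibble(
    gene_id = long$gene_id,
    tag = long$tag,
    condition = long$condition,
    day = long$day,
    intensity_ref = intensity_ref,
    intensity_day = intensity_day
  )
}

#' Simulate a complete pooled lifespan screen
#'
#' Convenience wrapper chaining [build_pool()], [simulate_pool_aging()],
#' [sample_survivors()] at every sampling day, and
#' [synthesize_intensities()] for every later day against the reference day,
#' in both conditions. Everything derives deterministically from `seed`.
#'
#' @param n_mutants Number of non-essential mutants in the pool.
#' @param class_fractions Named lifespan-class fractions, see [build_pool()].
#' @param config A [pool_config()].
#' @param seed Master integer seed; defaults to `config$seed`.
#' @param profiles Optional pre-built pool tibble; when supplied,
#'   `n_mutants`/`class_fractions` are ignored.
#'
#' @return A list of class `screen_sim` with elements `intensities` (the full
#'   tag-intensity table), `truth` (per gene: `true_class`, `tau_nr`,
#'   `tau_cr`, realised survival fractions and regrowth days), `profiles`
#'   and `config`.
#' @export
#' @examples
#' sim <- simulate_screen(n_mutants = 60, config = pool_config(
#'   plating_depth = 1e5, n_essential = 10))
#' dplyr::count(sim$intensities, condition, day)
simulate_screen <- function(n_mutants = 4800,
                            class_fractions = c(short = 0.05, normal = 0.85,
                                                long = 0.05, cr_unresponsive = 0.05),
                            config = pool_config(),
                            seed = config$seed,
                            profiles = NULL) {
  if (is.null(profiles)) {
    profiles <- build_pool(n_mutants, class_fractions, config, seed = seed)
  }
  traj <- simulate_pool_aging(profiles, config, seed = seed)
  days <- config$sample_days
  ref_day <- days[1]

  counts <- lapply(days, function(d) {
    sample_survivors(traj, d, config$plating_depth, seed = derive_seed(seed, paste0("day", d)))
  })
  names(counts) <- as.character(days)

  intensities <- dplyr::bind_rows(lapply(days[-1], function(d) {
    synthesize_intensities(counts[[as.character(ref_day)]], counts[[as.character(d)]],
                           profiles, config, seed = seed)
  }))

  regrowth <- attr(traj, "regrowth")
  surv_wide <- tidyr::pivot_wider(
    as_tibble(traj)[, c("gene_id", "condition", "day", "survival")],
    names_from = c("condition", "day"), values_from = "survival",
    names_glue = "surv_{condition}_d{day}"
  )
  truth <- dplyr::left_join(
    profiles[, c("gene_id", "essential", "true_class", "tau_nr", "tau_cr")],
    surv_wide,
    by = "gene_id"
  )
  for (cond in config$conditions) {
    rg <- regrowth[regrowth$condition == cond, c("gene_id", "regrowth_day")]
    names(rg)[2] <- paste0("regrowth_day_", tolower(cond))
    truth <- dplyr::left_join(truth, rg, by = "gene_id")
  }

  structure(
    list(intensities = intensities, truth = truth, profiles = profiles, config = config),
    class = "screen_sim"
  )
}

#' @export
print.screen_sim <- function(x, ...) {
  cat("Simulated pooled lifespan screen\n")
  cat(sprintf("  mutants: %d non-essential + %d essential probes\n",
              sum(!x$profiles$essential), sum(x$profiles$essential)))
  cat(sprintf("  conditions: %s; days: %s\n",
              paste(x$config$conditions, collapse = ", "),
              paste(x$config$sample_days, collapse = ", ")))
  cat(sprintf("  intensity records: %d\n", nrow(x$intensities)))
  invisible(x)
}
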