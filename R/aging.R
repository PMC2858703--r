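#' Weibull stationary-phase survival fraction
#'
#' `S(d) = exp(-(d / tau)^k)`: the fraction of a mutant's population still
#' viable at day `d` given characteristic survival time `tau` (days) and shape
#' `k`. `k > 1` gives the die-off shoulder typical of chronologically aging
#' yeast cultures; `tau = Inf` is the zero-death limit (`S = 1`).
#'
#' @param day Day(s) at which to evaluate survival.
#' @param tau Characteristic survival time in days (> 0, may be `Inf`).
#' @param shape_k Weibull shape (> 0).
#' @return Survival fraction(s) in (0, 1].
#' @export
#' @examples
#' weibull_survival(c(1, 9, 21, 33), tau = 11, shape_k = 2)
weibull_survival <- function(day, tau, shape_k) {
  out <- exp(-(day / tau)^shape_k)
  out[is.infinite(tau)] <- 1
  out
}

#' Simulate viability decay of the pooled population
#'
#' Computes each mutant's expected viable-cell trajectory over the sampling
#' days in every condition: `initial_abundance * S(d) * pool_size`, with
#' Weibull survival evaluated at the condition's characteristic time
#' (`tau_nr` or `tau_cr`). Adaptive regrowth ("gasping") fires as a Bernoulli
#' event per timecourse (gene x condition); when it fires, a day is chosen
#' uniformly among the sampling days after the reference day and the viable
#' count is multiplied by `regrowth_factor` from that day onward. Essential
#' probes have no mutant in the pool and stay at zero.
#'
#' @param profiles Pool tibble from [build_pool()].
#' @param config A [pool_config()].
#' @param seed Integer seed for the regrowth events; defaults to
#'   `config$seed`.
#'
#' @return A tibble of class `pool_trajectories` with columns `gene_id`,
#'   `condition`, `day`, `survival` (realised survival fraction including any
#'   regrowth jump) and `viable` (expected viable cells). The realised
#'   regrowth days are attached as attribute `regrowth` (tibble `gene_id`,
#'   `condition`, `regrowth_day`).
#' @export
#' @examples
#' cfg <- pool_config(n_essential = 5, regrowth_prob = 0)
#' pool <- build_pool(20, c(normal = 1), cfg)
#' traj <- simulate_pool_aging(pool, cfg)
#' head(traj)
simulate_pool_aging <- function(profiles, config, seed = config$seed) {
  if (nrow(profiles) == 0) {
    stop_clscreen("`profiles` is empty", "bad_input")
  }
  assert_columns(
    profiles,
    c("gene_id", "essential", "tau_nr", "tau_cr", "shape_k", "initial_abundance"),
    "`profiles`"
  )
  set.seed(derive_seed(seed, "aging"))

  days <- config$sample_days
  ref_day <- days[1]
  later_days <- days[-1]

  grid <- tidyr::expand_grid(
    gene_id = profiles$gene_id,
    condition = config$conditions
  )
  grid <- dplyr::left_join(grid, profiles, by = "gene_id")

  # one regrowth event at most per gene x condition timecourse
  fires <- stats::runif(nrow(grid)) < config$regrowth_prob & !grid$essential
  grid$regrowth_day <- NA_integer_
  if (any(fires)) {
    grid$regrowth_day[fires] <- sample(later_days, sum(fires), replace = TRUE)
  }

  traj <- tidyr::expand_grid(idx = seq_len(nrow(grid)), day = days)
  traj <- dplyr::bind_cols(grid[traj$idx, ], traj["day"])
  tau <- ifelse(traj$condition == "CR", traj$tau_cr, traj$tau_nr)
  surv <- weibull_survival(traj$day, tau, traj$shape_k)
  surv[traj$essential] <- 0
  jump <- !is.na(traj$regrowth_day) & traj$day >= traj$regrowth_day
  surv[jump] <- surv[jump] * config$regrowth_factor

  out <- tibble(
    gene_id = traj$gene_id,
    condition = traj$condition,
    day = traj$day,
    survival = surv,
    viable = traj$initial_abundance * surv * config$pool_size
  )
  out <- structure(out, class = c("pool_trajectories", class(out)))
  attr(out, "regrowth") <- grid[!is.na(grid$regrowth_day),
                                c("gene_id", "condition", "regrowth_day")]
  attr(out, "ref_day") <- ref_day
  out
}

#' Sample surviving cells recovered by plating
#'
#' Models spreading an aliquot of the aged culture on rich plates: a
#' multinomial draw of `plating_depth` recovered cells with per-mutant
#' probabilities proportional to viable counts at the requested day, drawn
#' independently within each condition present in `trajectories`.
#'
#' @param trajectories Output of [simulate_pool_aging()].
#' @param day One of the simulated sampling days.
#' @param plating_depth Total cells recovered per plating (> 0).
#' @param seed Integer seed.
#'
#' @return Tibble with columns `gene_id`, `condition`, `day`, `count`; counts
#'   within a condition sum to `plating_depth` exactly.
#' @export
sample_survivors <- function(trajectories, day, plating_depth, seed) {
  assert_columns(trajectories, c("gene_id", "condition", "day", "viable"), "`trajectories`")
  if (!day %in% trajectories$day) {
    stop_clscreen(sprintf("day %s was not simulated", day), "bad_day")
  }
  if (plating_depth > .Machine$integer.max) {
    stop_clscreen("`plating_depth` exceeds the maximum supported draw size", "bad_config")
  }
  set.seed(derive_seed(seed, paste0("plating_d", day)))
  slice <- trajectories[trajectories$day == day, ]
  out <- lapply(split(slice, slice$condition), function(x) {
    if (all(x$viable <= 0)) {
      stop_clscreen(
        sprintf("pool extinct: no viable cells at day %s in condition %s", day, x$condition[1]),
        "pool_extinct"
      )
    }
    counts <- as.vector(stats::rmultinom(1, size = plating_depth, prob = x$viable))
    tibble(gene_id = x$gene_id, condition = x$condition, day = day, count = counts)
  })
  dplyr::bind_rows(out[order(names(out))])
}
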