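# Shared fixture builders. Everything is generated in code at test time;
# small pools keep the default run fast.

small_config <- function(seed = 1L, ...) {
  pool_config(plating_depth = 1e6, n_essential = 50, seed = as.integer(seed), ...)
}

# One small simulated screen, cached per (seed) within a test run.
.sim_cache <- new.env(parent = emptyenv())
small_sim <- function(seed = 1L, n_mutants = 300,
                      fractions = c(short = 0.1, normal = 0.8, long = 0.1)) {
  key <- paste0("s", seed, "_n", n_mutants, "_", paste(fractions, collapse = "_"))
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_screen(n_mutants, fractions,
                                         small_config(seed), seed = as.integer(seed))
  }
  .sim_cache[[key]]
}

# Processed slices (ratios, universe, NR ranks) for a small simulation.
small_analysis <- function(seed = 1L, ...) {
  sim <- small_sim(seed, ...)
  ratios <- compute_ratio_table(sim$intensities)
  essentials <- sim$profiles$gene_id[sim$profiles$essential]
  background <- estimate_background(sim$intensities, essentials, "ref_intensity")
  universe <- filter_gene_universe(sim$intensities, background, essentials,
                                   "ref_intensity")
  nr_ranks <- compute_rank_table(ratios[ratios$condition == "NR", ], universe)
  list(sim = sim, ratios = ratios, essentials = essentials,
       background = background, universe = universe, nr_ranks = nr_ranks)
}

# Hand-built dual-tag NR ratio table from a named list gene -> c(d9, d21, d33),
# identical values for both tags unless `jitter_dn` shifts the DN tag.
manual_ratio_table <- function(values, condition = "NR", jitter_dn = 0) {
  rows <- purrr::imap_dfr(values, function(v, g) {
    tidyr::expand_grid(tag = c("UP", "DN"), day = c(9L, 21L, 33L)) |>
      dplyr::mutate(
        gene_id = g, condition = condition,
        ratio = rep(v, 2) + rep(c(0, jitter_dn), each = 3)
      )
  })
  rows$log_ratio <- log2(rows$ratio)
  rows[, c("gene_id", "tag", "condition", "day", "ratio", "log_ratio")]
}

# Independent competition-ranking oracle: rank by counting strictly smaller
# (or larger) values, one gene at a time.
oracle_competition_rank <- function(x, direction = "ascending") {
  vapply(x, function(xi) {
    if (direction == "ascending") sum(x < xi) + 1L else sum(x > xi) + 1L
  }, integer(1))
}

# Independent type-7 quantile oracle: sort-based linear interpolation.
oracle_quantile7 <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Exact rational half-up rounding oracle for 100*c/t at one decimal.
oracle_rate_1dp <- function(confirmed, tested) {
  q <- (1000 * confirmed) %/% tested
  r <- (1000 * confirmed) %% tested
  if (2 * r >= tested) q <- q + 1
  q / 10
}
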