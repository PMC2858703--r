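#' Scale a published rank threshold to a different universe size
#'
#' The published rank cuts (bottom 200, top 500) were defined on a pool of
#' roughly 4,800 viable deletion mutants. On a smaller simulated pool the
#' cuts are rescaled proportionally to the analysed universe size:
#' `round(cut * universe_size / reference_size)`, floored at 1.
#'
#' @param cut Published rank cut.
#' @param universe_size Size of the analysed (dual-tag) universe.
#' @param reference_size Pool size the published cut refers to (4800).
#' @return Integer rank cut.
#' @export
#' @examples
#' scale_rank_cut(200, 2000)
scale_rank_cut <- function(cut, universe_size, reference_size = 4800) {
  max(1L, as.integer(round(cut * universe_size / reference_size)))
}

#' End-to-end parameter recovery of planted lifespan classes
#'
#' Simulates a pooled screen with planted short-lived (`tau/3`) and
#' long-lived (`3 tau`) mutants, runs the full analysis (ratios, essential
#' background, universe filtering, ranking, calling with proportionally
#' scaled rank cuts) and scores the called sets against the simulator's
#' ground truth. One row per seed and class.
#'
#' @param seeds Integer vector of master seeds, one simulation per seed.
#' @param n_mutants Number of non-essential mutants (default 2000).
#' @param frac_short,frac_long Planted class fractions (default 5\% each;
#'   the rest are normal).
#' @param config Base [pool_config()]; its seed is replaced per run.
#' @param mode Background metric mode used to filter the universe (default
#'   `"ref_intensity"`; see the vignette for why the intensity mode is the
#'   right one on simulated data).
#'
#' @return Tibble with columns `seed`, `class`, `n_true`, `n_called`, `tp`,
#'   `fp`, `fn`, `precision`, `recall`, `rank_cut`.
#' @export
evaluate_parameter_recovery <- function(seeds = 1:5, n_mutants = 2000,
                                        frac_short = 0.05, frac_long = 0.05,
                                        config = pool_config(n_essential = 200),
                                        mode = "ref_intensity") {
  fractions <- c(short = frac_short, normal = 1 - frac_short - frac_long,
                 long = frac_long)
  purrr::map_dfr(seeds, function(sd) {
    cfg <- config
    cfg$seed <- as.integer(sd)
    sim <- simulate_screen(n_mutants, fractions, cfg, seed = cfg$seed)
    ratios <- compute_ratio_table(sim$intensities)
    metric_table <- if (mode == "ratio") ratios else sim$intensities
    essentials <- sim$profiles$gene_id[sim$profiles$essential]
    background <- estimate_background(metric_table, essentials, mode)
    universe <- filter_gene_universe(metric_table, background, essentials, mode)
    nr_ranks <- compute_rank_table(ratios[ratios$condition == "NR", ], universe)

    # published cuts were defined on a ~4800-mutant pool; rescale to this pool
    short_cut <- scale_rank_cut(200, n_mutants)
    long_cut <- scale_rank_cut(500, n_mutants)
    calls <- list(
      short = call_short_lived(ratios, nr_ranks, rank_cut = short_cut),
      long = call_long_lived(ratios, nr_ranks, rank_cut = long_cut)
    )
    cuts <- c(short = short_cut, long = long_cut)
    purrr::map_dfr(c("short", "long"), function(cls) {
      planted <- sim$truth$gene_id[!is.na(sim$truth$true_class) &
                                     sim$truth$true_class == cls]
      # recall is over analysable planted genes: every criterion requires both
      # tags, so planted genes absent from the dual-tag universe cannot be
      # called by construction
      pos <- intersect(planted, universe$dual)
      ct <- cross_tabulate_calls(calls[[cls]], pos)
      dplyr::bind_cols(
        tibble(seed = sd, class = cls, n_planted = length(planted),
               n_analysable = length(pos), n_called = nrow(calls[[cls]])),
        ct[, c("tp", "fp", "fn", "precision", "recall")],
        tibble(rank_cut = cuts[[cls]])
      )
    })
  })
}
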