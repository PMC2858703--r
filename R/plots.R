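#' Box plots of abundance ratios across the aging population
#'
#' The per-day box plot of mutant abundance ratios within a universe,
#' faceted by condition — the standard population-level view of a pooled
#' lifespan screen (ratios drift downward as the population ages, and sit
#' higher under calorie restriction).
#'
#' @param ratios Ratio tibble from [compute_ratio_table()].
#' @param universe Character vector of gene ids or a `gene_universe` (its
#'   dual set is used).
#' @param log2_scale Plot log2 ratios instead of raw ratios (default TRUE;
#'   raw ratio distributions are heavily right-skewed).
#' @return A ggplot object.
#' @export
plot_ratio_distribution <- function(ratios, universe, log2_scale = TRUE) {
  if (inherits(universe, "gene_universe")) {
    universe <- universe$dual
  }
  x <- ratios[ratios$gene_id %in% universe, ]
  x$day_f <- factor(x$day, levels = sort(unique(x$day)))
  y <- if (log2_scale) "log_ratio" else "ratio"
  ggplot2::ggplot(x, ggplot2::aes(x = .data$day_f, y = .data[[y]])) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(
      x = "day",
      y = if (log2_scale) "log2 abundance ratio (day / reference)" else
        "abundance ratio (day / reference)"
    ) +
    ggplot2::theme_bw()
}

#' Plot chronological-lifespan survival curves
#'
#' @param curves Named list of survival-curve tibbles ([survival_curve()]),
#'   or one tibble with a `strain` column.
#' @return A ggplot object (log10 survival over days).
#' @export
plot_survival_curves <- function(curves) {
  if (is.data.frame(curves)) {
    assert_columns(curves, c("strain", "day", "fraction"), "`curves`")
    x <- curves
  } else {
    x <- purrr::imap_dfr(curves, function(cv, nm) {
      cv$strain <- nm
      cv
    })
  }
  ggplot2::ggplot(x, ggplot2::aes(x = .data$day, y = .data$fraction,
                                  colour = .data$strain)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "day", y = "surviving fraction", colour = NULL) +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the justification values of a call set
#'
#' For rank/ratio criteria, scatter of the two tags' clause values with the
#' thresholds drawn; for the CR-unresponsiveness criterion, fractional
#' difference against t-test p-value.
#'
#' @param object A `candidate_calls` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot candidate_calls
#' @export
autoplot.candidate_calls <- function(object, ...) {
  ev <- tidy(object)
  th <- attr(object, "thresholds")
  criterion <- attr(object, "criterion")
  if (criterion == "cr_unresponsive") {
    ev <- ev[!is.na(ev$p_value), ]
    p <- ggplot2::ggplot(ev, ggplot2::aes(x = .data$max_frac_diff, y = .data$p_value,
                                          colour = .data$called)) +
      ggplot2::geom_point(size = 0.6) +
      ggplot2::geom_vline(xintercept = th$frac_cut, linetype = 2) +
      ggplot2::geom_hline(yintercept = th$alpha, linetype = 2) +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "max |fractional difference| of NR vs CR mean log ratios",
                    y = "Welch t-test p-value")
  } else {
    rank_cols <- grep("^rank_", names(ev), value = TRUE)
    p <- ggplot2::ggplot(ev, ggplot2::aes(x = .data[[rank_cols[1]]],
                                          y = .data[[rank_cols[2]]],
                                          colour = .data$called)) +
      ggplot2::geom_point(size = 0.6) +
      ggplot2::geom_vline(xintercept = th$rank_cut, linetype = 2) +
      ggplot2::geom_hline(yintercept = th$rank_cut, linetype = 2) +
      ggplot2::labs(x = paste("UPTAG", rank_cols[1]), y = paste("DNTAG", rank_cols[2]))
  }
  p + ggplot2::theme_bw() + ggplot2::ggtitle(criterion)
}
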