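#' Compute abundance ratios from two-channel tag intensities
#'
#' For every (gene, tag, condition, day) record, the abundance ratio is the
#' later-day channel intensity divided by the reference-day channel intensity
#' (e.g. day 9 / day 1). Records with a missing or non-positive reference
#' channel, or a missing later-day channel, are dropped (never imputed) and
#' counted in the attached processing report. The base-2 log ratio is
#' attached, the standard two-channel microarray convention.
#'
#' @param intensities Tag-intensity tibble with columns `gene_id`, `tag`,
#'   `condition`, `day`, `intensity_ref`, `intensity_day`.
#'
#' @return A ratio tibble (`gene_id`, `tag`, `condition`, `day`, `ratio`,
#'   `log_ratio`) with attribute `report`: a list with `records_read`,
#'   `records_kept`, `dropped_missing_ref`, `dropped_missing_day`.
#' @export
#' @examples
#' x <- tibble::tibble(gene_id = "g1", tag = "UP", condition = "NR", day = 9,
#'                     intensity_ref = 4, intensity_day = 2)
#' compute_ratio_table(x)
compute_ratio_table <- function(intensities) {
  assert_columns(
    intensities,
    c("gene_id", "tag", "condition", "day", "intensity_ref", "intensity_day"),
    "`intensities`"
  )
  if (nrow(intensities) == 0) {
    stop_clscreen("`intensities` is empty", "bad_input")
  }
  bad_ref <- is.na(intensities$intensity_ref) | intensities$intensity_ref <= 0
  bad_day <- is.na(intensities$intensity_day)
  keep <- !bad_ref & !bad_day
  if (!any(keep)) {
    stop_clscreen("no record has both channels present", "bad_input")
  }
  kept <- intensities[keep, ]
  out <- tibble(
    gene_id = kept$gene_id,
    tag = kept$tag,
    condition = kept$condition,
    day = kept$day,
    ratio = kept$intensity_day / kept$intensity_ref
  )
  out$log_ratio <- log2(out$ratio)
  attr(out, "report") <- list(
    records_read = nrow(intensities),
    records_kept = nrow(out),
    dropped_missing_ref = sum(bad_ref),
    dropped_missing_day = sum(bad_day & !bad_ref)
  )
  out
}

#' Estimate nonspecific-hybridization background from essential-gene probes
#'
#' Essential genes have no viable deletion mutant in the pool, so their array
#' probes measure nonspecific hybridization only. The background value per
#' tag is the arithmetic mean, over essential-gene records, of the configured
#' metric:
#'
#' * `mode = "ratio"` (default): the mean essential-gene abundance ratio, the
#'   rule as printed in the original analysis.
#' * `mode = "ref_intensity"`: the mean essential-gene reference-channel
#'   intensity, the intensity-based alternative that directly expresses
#'   "a tag has signal" (used by default on simulated data, where
#'   essential-gene ratios are close to 1 by construction).
#'
#' @param x A ratio tibble ([compute_ratio_table()]) for `mode = "ratio"`, or
#'   a tag-intensity tibble for `mode = "ref_intensity"`.
#' @param essential_ids Character vector of essential gene ids present in `x`.
#' @param mode Background metric, `"ratio"` or `"ref_intensity"`.
#'
#' @return A tibble with columns `tag`, `background`, `n_essential_records`
#'   and attribute `mode`.
#' @export
estimate_background <- function(x, essential_ids, mode = c("ratio", "ref_intensity")) {
  mode <- match.arg(mode)
  if (length(essential_ids) == 0) {
    stop_clscreen("`essential_ids` is empty", "no_essentials")
  }
  metric_col <- if (mode == "ratio") "ratio" else "intensity_ref"
  assert_columns(x, c("gene_id", "tag", metric_col), "`x`")
  ess <- x[x$gene_id %in% essential_ids & !is.na(x[[metric_col]]), ]
  if (nrow(ess) == 0) {
    stop_clscreen("no essential-gene records found in the table", "no_essentials")
  }
  out <- dplyr::summarise(
    dplyr::group_by(ess, .data$tag),
    background = mean(.data[[metric_col]]),
    n_essential_records = dplyr::n(),
    .groups = "drop"
  )
  missing_tags <- setdiff(unique(x$tag), out$tag)
  if (length(missing_tags) > 0) {
    stop_clscreen(
      sprintf("no essential-gene records for tag(s): %s", paste(missing_tags, collapse = ", ")),
      "no_essentials"
    )
  }
  attr(out, "mode") <- mode
  out
}

#' Filter the analysable gene universe against the background
#'
#' Retains, per tag, the non-essential genes whose background metric (mean
#' ratio or mean reference intensity per gene and tag, matching the mode the
#' background was estimated with) is at least the tag's background value.
#' The dual-tag universe is the intersection of the two per-tag lists —
#' genes with signal from both tags; the per-tag lists are also reported.
#' Essential genes are never admitted.
#'
#' @param x The same kind of table the background was estimated from: a ratio
#'   tibble for mode `"ratio"`, a tag-intensity tibble for
#'   `"ref_intensity"`.
#' @param background Output of [estimate_background()] (carries its mode).
#' @param essential_ids Character vector of essential gene ids.
#' @param mode Metric mode; must match the background's mode, otherwise a
#'   `metric-mode mismatch` error is raised.
#'
#' @return A list of class `gene_universe`: `up`, `dn` (per-tag retained gene
#'   ids), `dual` (both tags), `background` (the background tibble), `mode`.
#' @export
filter_gene_universe <- function(x, background, essential_ids,
                                 mode = attr(background, "mode")) {
  bg_mode <- attr(background, "mode")
  if (is.null(bg_mode) || !identical(mode, bg_mode)) {
    stop_clscreen("metric-mode mismatch between `background` and `mode`", "mode_mismatch")
  }
  metric_col <- if (mode == "ratio") "ratio" else "intensity_ref"
  assert_columns(x, c("gene_id", "tag", metric_col), "`x`")

  noness <- x[!(x$gene_id %in% essential_ids) & !is.na(x[[metric_col]]), ]
  per_gene <- dplyr::summarise(
    dplyr::group_by(noness, .data$gene_id, .data$tag),
    metric = mean(.data[[metric_col]]),
    .groups = "drop"
  )
  per_gene <- dplyr::left_join(per_gene, background, by = "tag")
  kept <- per_gene[per_gene$metric >= per_gene$background, ]

  tag_sets <- split(kept$gene_id, kept$tag)
  up <- sort(tag_sets[["UP"]] %||% character())
  dn <- sort(tag_sets[["DN"]] %||% character())
  structure(
    list(
      up = up,
      dn = dn,
      dual = intersect(up, dn),
      background = background,
      mode = mode
    ),
    class = "gene_universe"
  )
}

#' @export
print.gene_universe <- function(x, ...) {
  cat("Gene universe (background mode: ", x$mode, ")\n", sep = "")
  cat(sprintf("  UPTAG list: %d genes\n", length(x$up)))
  cat(sprintf("  DNTAG list: %d genes\n", length(x$dn)))
  cat(sprintf("  dual-tag universe: %d genes\n", length(x$dual)))
  invisible(x)
}

#' Five-number summary of the aging population's abundance ratios
#'
#' The population summary behind per-day box plots of mutant abundance
#' ratios: minimum, lower quartile, median, upper quartile, maximum and mean
#' of the ratios of genes in the given universe at one day and condition.
#' Quartiles use linear interpolation (R's default type-7 rule).
#'
#' @param ratios Ratio tibble from [compute_ratio_table()].
#' @param universe Character vector of gene ids (e.g. a component of
#'   [filter_gene_universe()] output), or a `gene_universe` (its dual set is
#'   used).
#' @param day,condition The slice to summarise.
#'
#' @return One-row tibble: `condition`, `day`, `n`, `min`, `q1`, `median`,
#'   `q3`, `max`, `mean`.
#' @export
population_summary <- function(ratios, universe, day, condition) {
  if (inherits(universe, "gene_universe")) {
    universe <- universe$dual
  }
  assert_columns(ratios, c("gene_id", "condition", "day", "ratio"), "`ratios`")
  if (!day %in% ratios$day) {
    stop_clscreen(sprintf("day %s not present in the ratio table", day), "bad_day")
  }
  x <- ratios$ratio[ratios$gene_id %in% universe &
                      ratios$day == day & ratios$condition == condition]
  if (length(x) == 0) {
    stop_clscreen("empty universe for the requested slice", "empty_universe")
  }
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble(
    condition = condition, day = day, n = length(x),
    min = min(x), q1 = q[1], median = q[2], q3 = q[3], max = max(x),
    mean = mean(x)
  )
}
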