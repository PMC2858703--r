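#' Competition-rank mutants by abundance ratio
#'
#' Ranks genes within each tag's own universe at one day and condition,
#' using competition ("min") ranking: tied values share the minimum rank and
#' the next distinct value skips accordingly — the semantics of a
#' spreadsheet RANK() function. Direction `"ascending"` gives rank 1 to the
#' lowest ratio (most depleted mutant), `"descending"` to the highest.
#'
#' @param ratios Ratio tibble from [compute_ratio_table()].
#' @param universe A `gene_universe` from [filter_gene_universe()] (per-tag
#'   lists are used), or a character vector applied to both tags.
#' @param day,condition Slice to rank.
#' @param direction `"ascending"` or `"descending"`.
#'
#' @return Tibble `gene_id`, `tag`, `condition`, `day`, `ratio`, `rank`.
#' @export
#' @examples
#' r <- tibble::tibble(gene_id = c("a", "b", "c"), tag = "UP", condition = "NR",
#'                     day = 9, ratio = c(0.2, 0.2, 0.7), log_ratio = log2(ratio))
#' rank_mutants(r, c("a", "b", "c"), 9, "NR", "ascending")$rank
rank_mutants <- function(ratios, universe, day, condition,
                         direction = c("ascending", "descending")) {
  direction <- match.arg(direction)
  assert_columns(ratios, c("gene_id", "tag", "condition", "day", "ratio"), "`ratios`")
  tag_universe <- function(tag) {
    if (inherits(universe, "gene_universe")) {
      if (tag == "UP") universe$up else universe$dn
    } else {
      universe
    }
  }
  slice <- ratios[ratios$day == day & ratios$condition == condition, ]
  if (nrow(slice) == 0) {
    stop_clscreen(sprintf("no records for day %s in condition %s", day, condition), "bad_day")
  }
  out <- lapply(unique(slice$tag), function(tg) {
    u <- tag_universe(tg)
    x <- slice[slice$tag == tg & slice$gene_id %in% u, ]
    if (nrow(x) == 0) {
      return(NULL)
    }
    key <- if (direction == "ascending") x$ratio else -x$ratio
    tibble(
      gene_id = x$gene_id, tag = tg, condition = condition, day = day,
      ratio = x$ratio, rank = rank(key, ties.method = "min")
    )
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    stop_clscreen("universe is empty for every tag at this slice", "empty_universe")
  }
  out
}

#' Full rank table over days, conditions and both directions
#'
#' Applies [rank_mutants()] to every (condition, day) slice of the ratio
#' table, attaching both the ascending rank (1 = lowest ratio) and the
#' descending rank (1 = highest ratio).
#'
#' @inheritParams rank_mutants
#' @return Tibble `gene_id`, `tag`, `condition`, `day`, `ratio`, `rank_asc`,
#'   `rank_desc`, with the universe stored in attribute `universe`.
#' @export
compute_rank_table <- function(ratios, universe) {
  slices <- unique(ratios[, c("condition", "day")])
  out <- purrr::pmap(slices, function(condition, day) {
    asc <- rank_mutants(ratios, universe, day, condition, "ascending")
    desc <- rank_mutants(ratios, universe, day, condition, "descending")
    asc$rank_asc <- asc$rank
    asc$rank <- NULL
    asc$rank_desc <- desc$rank[match(
      paste(asc$gene_id, asc$tag),
      paste(desc$gene_id, desc$tag)
    )]
    asc
  })
  out <- dplyr::bind_rows(out)
  attr(out, "universe") <- universe
  out
}
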