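new_candidate_calls <- function(called, evaluation, criterion, thresholds, universe) {
  structure(
    called,
    evaluation = evaluation,
    criterion = criterion,
    thresholds = thresholds,
    universe = universe,
    class = c("candidate_calls", class(called))
  )
}

#' @export
print.candidate_calls <- function(x, ...) {
  cat(sprintf("Candidate call set: %s (%d genes called of %d in universe)\n",
              attr(x, "criterion"), nrow(x), length(attr(x, "universe"))))
  th <- attr(x, "thresholds")
  cat("  thresholds:", paste(names(th), unlist(th), sep = "=", collapse = ", "), "\n")
  NextMethod()
}

# Dual-tag wide slice of ranks/ratios for one day: one row per gene with
# both tags present, fixed column order (gene_id, up, dn).
dual_tag_slice <- function(ranks, day, value_col) {
  x <- ranks[ranks$day == day, c("gene_id", "tag", value_col)]
  names(x)[3] <- "value"
  wide <- tidyr::pivot_wider(x, names_from = "tag", values_from = "value")
  for (tg in c("UP", "DN")) {
    if (!tg %in% names(wide)) wide[[tg]] <- NA_real_
  }
  stats::na.omit(tibble(gene_id = wide$gene_id, up = wide$UP, dn = wide$DN))
}

#' Call short-lived candidate mutants
#'
#' A gene is called short-lived when, in the non-restricted (NR) condition,
#' its day-9 abundance ratio ranks in the bottom `rank_cut` for **both**
#' tags (ascending competition rank `<= rank_cut`) **and** its day-21
#' abundance ratio is strictly less than `ratio_cut` for both tags. Day-33
#' ratios are never consulted: by then most of the aging population is dead.
#' Genes missing either tag at these days cannot satisfy "both tags" and are
#' excluded; they are listed in the evaluation table ([tidy()]).
#'
#' @param ratios Ratio tibble from [compute_ratio_table()].
#' @param ranks Rank table from [compute_rank_table()], built on the NR
#'   ratios and the filtered universe.
#' @param rank_cut Inclusive bottom-rank threshold at day 9 (default 200).
#' @param ratio_cut Strict day-21 ratio upper bound (default 0.3).
#' @param condition Condition to call in (default `"NR"`).
#' @param day_rank,day_ratio Days used by the rank clause and the ratio
#'   clause.
#'
#' @return A `candidate_calls` tibble (one row per called gene with the
#'   justifying ranks and ratios); the full per-gene evaluation is available
#'   via [generics::tidy()], thresholds via [generics::glance()].
#' @export
call_short_lived <- function(ratios, ranks, rank_cut = 200, ratio_cut = 0.3,
                             condition = "NR", day_rank = 9, day_ratio = 21) {
  ranks <- ranks[ranks$condition == condition, ]
  for (d in c(day_rank, day_ratio)) {
    if (!d %in% ranks$day) {
      stop_clscreen(sprintf("day %s missing from the rank table (%s)", d, condition),
                    "missing_day")
    }
  }
  r9 <- dual_tag_slice(ranks, day_rank, "rank_asc")
  r21 <- dual_tag_slice(ranks, day_ratio, "ratio")
  ev <- dplyr::inner_join(r9, r21, by = "gene_id")
  names(ev) <- c("gene_id",
                 paste0("rank_up_d", day_rank), paste0("rank_dn_d", day_rank),
                 paste0("ratio_up_d", day_ratio), paste0("ratio_dn_d", day_ratio))
  ev$called <- ev[[2]] <= rank_cut & ev[[3]] <= rank_cut &
    ev[[4]] < ratio_cut & ev[[5]] < ratio_cut

  universe <- ev$gene_id
  called <- dplyr::select(ev[ev$called, ], -"called")
  new_candidate_calls(
    called, ev, "short_lived",
    list(rank_cut = rank_cut, ratio_cut = ratio_cut, condition = condition,
         day_rank = day_rank, day_ratio = day_ratio),
    universe
  )
}

#' Call long-lived candidate mutants
#'
#' A gene is called long-lived when its day-33 abundance ratio is in the top
#' `rank_cut` for **both** tags (descending competition rank `<= rank_cut`)
#' **and** its day-21 abundance ratio is strictly greater than `ratio_cut`
#' for both tags, in the NR condition.
#'
#' @inheritParams call_short_lived
#' @param rank_cut Inclusive top-rank threshold at day 33 (default 500).
#' @param ratio_cut Strict day-21 ratio lower bound (default 1.0).
#' @param day_rank,day_ratio Days used by the rank clause and the ratio
#'   clause.
#' @return A `candidate_calls` tibble; see [call_short_lived()].
#' @export
call_long_lived <- function(ratios, ranks, rank_cut = 500, ratio_cut = 1.0,
                            condition = "NR", day_rank = 33, day_ratio = 21) {
  ranks <- ranks[ranks$condition == condition, ]
  for (d in c(day_rank, day_ratio)) {
    if (!d %in% ranks$day) {
      stop_clscreen(sprintf("day %s missing from the rank table (%s)", d, condition),
                    "missing_day")
    }
  }
  r33 <- dual_tag_slice(ranks, day_rank, "rank_desc")
  r21 <- dual_tag_slice(ranks, day_ratio, "ratio")
  ev <- dplyr::inner_join(r33, r21, by = "gene_id")
  names(ev) <- c("gene_id",
                 paste0("rank_up_d", day_rank), paste0("rank_dn_d", day_rank),
                 paste0("ratio_up_d", day_ratio), paste0("ratio_dn_d", day_ratio))
  ev$called <- ev[[2]] <= rank_cut & ev[[3]] <= rank_cut &
    ev[[4]] > ratio_cut & ev[[5]] > ratio_cut

  called <- dplyr::select(ev[ev$called, ], -"called")
  new_candidate_calls(
    called, ev, "long_lived",
    list(rank_cut = rank_cut, ratio_cut = ratio_cut, condition = condition,
         day_rank = day_rank, day_ratio = day_ratio),
    ev$gene_id
  )
}

#' Call calorie-restriction-unresponsive candidate mutants
#'
#' Identifies mutants whose NR and CR abundance-ratio trajectories are
#' indistinguishable, i.e. whose lifespan is not extended by calorie
#' restriction. Two clauses, both required:
#'
#' 1. At **every** time point, the absolute fractional difference between the
#'    mean NR and mean CR log2 ratios — `|m_NR - m_CR| / ((m_NR + m_CR)/2)`
#'    taken in absolute value, where each mean pools the gene's available
#'    tags at that day — is strictly less than `frac_cut`.
#' 2. A two-sided Welch t-test comparing the gene's NR and CR log2-ratio
#'    observations (all tags and days pooled) passes the `p_rule`:
#'    `"p_lt_alpha"` requires `p < alpha` (the rule as printed in the
#'    original analysis, kept as the default for reproducibility) and
#'    `"p_ge_alpha"` requires `p >= alpha` (the statistically coherent
#'    reading of "means are not significantly different").
#'
#' Genes whose fractional difference is undefined at some day (mean log
#' ratios summing to ~0) or with fewer than two observations in either
#' condition are excluded and recorded in the evaluation table with a
#' reason.
#'
#' @param ratios Ratio tibble containing both conditions.
#' @param universe Character vector of gene ids (dual-tag universe) or a
#'   `gene_universe`.
#' @param frac_cut Strict upper bound on the absolute fractional difference
#'   (default 0.1, i.e. "within 10\%").
#' @param alpha t-test significance level (default 0.05).
#' @param p_rule `"p_lt_alpha"` or `"p_ge_alpha"`.
#'
#' @return A `candidate_calls` tibble with per-gene `max_frac_diff` and
#'   `p_value`.
#' @export
call_cr_unresponsive <- function(ratios, universe, frac_cut = 0.1, alpha = 0.05,
                                 p_rule = c("p_lt_alpha", "p_ge_alpha")) {
  p_rule <- match.arg(p_rule)
  if (inherits(universe, "gene_universe")) {
    universe <- universe$dual
  }
  assert_columns(ratios, c("gene_id", "tag", "condition", "day", "log_ratio"), "`ratios`")
  x <- ratios[ratios$gene_id %in% universe, ]
  conds <- unique(x$condition)
  if (length(conds) < 2) {
    stop_clscreen("both NR and CR records are required", "missing_condition")
  }

  per_day <- dplyr::summarise(
    dplyr::group_by(x, .data$gene_id, .data$condition, .data$day),
    m = mean(.data$log_ratio), .groups = "drop"
  )
  wide <- tidyr::pivot_wider(per_day, names_from = "condition", values_from = "m")
  wide <- stats::na.omit(wide)
  denom <- (wide$NR + wide$CR) / 2
  wide$frac_diff <- abs((wide$NR - wide$CR) / denom)
  wide$undefined <- abs(denom) < 1e-12

  by_gene <- dplyr::summarise(
    dplyr::group_by(wide, .data$gene_id),
    n_days = dplyr::n(),
    max_frac_diff = max(.data$frac_diff),
    any_undefined = any(.data$undefined),
    .groups = "drop"
  )

  tt <- dplyr::summarise(
    dplyr::group_by(x, .data$gene_id),
    n_nr = sum(.data$condition == "NR"),
    n_cr = sum(.data$condition == "CR"),
    p_value = if (sum(.data$condition == "NR") >= 2 && sum(.data$condition == "CR") >= 2) {
      # constant observations make the Welch statistic undefined
      tryCatch(
        stats::t.test(
          .data$log_ratio[.data$condition == "NR"],
          .data$log_ratio[.data$condition == "CR"],
          var.equal = FALSE
        )$p.value,
        error = function(e) NaN
      )
    } else {
      NA_real_
    },
    .groups = "drop"
  )

  ev <- dplyr::left_join(by_gene, tt, by = "gene_id")
  ev$excluded_reason <- dplyr::case_when(
    ev$any_undefined ~ "undefined fractional difference",
    is.nan(ev$p_value) ~ "degenerate t-test (constant observations)",
    is.na(ev$p_value) ~ "fewer than 2 observations per condition",
    TRUE ~ NA_character_
  )
  clause1 <- !ev$any_undefined & ev$max_frac_diff < frac_cut
  clause2 <- if (p_rule == "p_lt_alpha") ev$p_value < alpha else ev$p_value >= alpha
  ev$clause_frac <- clause1
  ev$clause_ttest <- clause2
  ev$called <- is.na(ev$excluded_reason) & clause1 & clause2

  called <- ev[ev$called, c("gene_id", "max_frac_diff", "p_value")]
  new_candidate_calls(
    called, ev, "cr_unresponsive",
    list(frac_cut = frac_cut, alpha = alpha, p_rule = p_rule),
    unique(x$gene_id)
  )
}

#' Re-evaluate every recorded clause of a call set against a ratio table
#'
#' Self-consistency audit: recomputes ranks and ratios from `ratios` with the
#' call set's stored thresholds and universe, and verifies that every called
#' gene still satisfies every clause.
#'
#' @param calls A `candidate_calls` object for the short- or long-lived
#'   criterion.
#' @param ratios The ratio tibble the calls were made from.
#' @param universe The universe the ranks were computed in (a
#'   `gene_universe` or character vector).
#' @return `TRUE` invisibly if the audit passes; otherwise an error naming
#'   the offending genes.
#' @export
audit_calls <- function(calls, ratios, universe = attr(calls, "universe")) {
  th <- attr(calls, "thresholds")
  criterion <- attr(calls, "criterion")
  ranks <- compute_rank_table(ratios[ratios$condition == th$condition, ], universe)
  redo <- switch(
    criterion,
    short_lived = call_short_lived(ratios, ranks, th$rank_cut, th$ratio_cut,
                                   th$condition, th$day_rank, th$day_ratio),
    long_lived = call_long_lived(ratios, ranks, th$rank_cut, th$ratio_cut,
                                 th$condition, th$day_rank, th$day_ratio),
    stop_clscreen("audit supports the rank/ratio criteria only", "bad_input")
  )
  missing <- setdiff(calls$gene_id, redo$gene_id)
  extra <- setdiff(redo$gene_id, calls$gene_id)
  if (length(missing) > 0 || length(extra) > 0) {
    stop_clscreen(
      sprintf("audit failed for criterion %s: %d recorded calls no longer pass, %d new",
              criterion, length(missing), length(extra)),
      "audit_failed"
    )
  }
  invisible(TRUE)
}

#' Audit stored long-lived candidate rows against the calling clauses
#'
#' Re-evaluates the long-lived clauses directly from stored per-tag rank and
#' ratio columns (as published candidate tables record them): day-33
#' descending rank `<= rank_cut` for both tags and day-21 ratio
#' `> ratio_cut` for both tags.
#'
#' @param candidates Tibble with columns `up_rank_d33`, `up_ratio_d21`,
#'   `dn_rank_d33`, `dn_ratio_d21` (and any id columns).
#' @param rank_cut,ratio_cut Thresholds (defaults 500 and 1.0).
#' @return The input with logical columns `pass_rank`, `pass_ratio`, `pass`.
#' @export
audit_long_lived_rows <- function(candidates, rank_cut = 500, ratio_cut = 1.0) {
  assert_columns(candidates,
                 c("up_rank_d33", "up_ratio_d21", "dn_rank_d33", "dn_ratio_d21"),
                 "`candidates`")
  candidates$pass_rank <- candidates$up_rank_d33 <= rank_cut &
    candidates$dn_rank_d33 <= rank_cut
  candidates$pass_ratio <- candidates$up_ratio_d21 > ratio_cut &
    candidates$dn_ratio_d21 > ratio_cut
  candidates$pass <- candidates$pass_rank & candidates$pass_ratio
  candidates
}

#' Published long-lived candidate table bundled with the package
#'
#' The 40-row published table of long-lived candidate mutants from a pooled
#' knockout-collection TAG-array screen, with each candidate's UPTAG/DNTAG
#' day-33 descending ranks, day-21 abundance ratios and the individually
#' retested lifespan verdict (L = long, S = short, N = normal,
#' UN = untested). Used to validate the long-lived calling clauses against
#' stored justification values.
#'
#' @return Tibble with columns `orf`, `gene`, `up_rank_d33`, `up_ratio_d21`,
#'   `dn_rank_d33`, `dn_ratio_d21`, `verdict`.
#' @export
published_long_lived_candidates <- function() {
  path <- system.file("extdata", "long_lived_candidates.tsv", package = "clscreen",
                      mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    orf = "c", gene = "c", up_rank_d33 = "i", up_ratio_d21 = "d",
    dn_rank_d33 = "i", dn_ratio_d21 = "d", verdict = "c"
  ))
}

#' Confusion counts of a call set against truth labels
#'
#' @param calls A `candidate_calls` object or character vector of called
#'   gene ids.
#' @param truth Character vector of gene ids truly in the positive class.
#' @param universe Optional character vector of evaluated gene ids (defaults
#'   to the call set's universe) used to count true negatives.
#' @return One-row tibble `tp`, `fp`, `fn`, `tn`, `precision`, `recall`.
#' @export
cross_tabulate_calls <- function(calls, truth, universe = NULL) {
  if (inherits(calls, "candidate_calls")) {
    universe <- universe %||% attr(calls, "universe")
    calls <- calls$gene_id
  }
  tp <- length(intersect(calls, truth))
  fp <- length(setdiff(calls, truth))
  fn <- length(setdiff(truth, calls))
  tn <- if (is.null(universe)) NA_integer_ else {
    length(setdiff(universe, union(calls, truth)))
  }
  tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-gene evaluation underlying a call set
#'
#' @param x A `candidate_calls` object.
#' @param ... Unused.
#' @return Tibble with one row per evaluated gene: the clause values
#'   (ranks/ratios or fractional differences and p-values) and the `called`
#'   flag.
#' @method tidy candidate_calls
#' @export
tidy.candidate_calls <- function(x, ...) {
  as_tibble(attr(x, "evaluation"))
}

#' One-row summary of a call set
#'
#' @param x A `candidate_calls` object.
#' @param ... Unused.
#' @return One-row tibble: criterion, thresholds, universe size and number
#'   of called genes.
#' @method glance candidate_calls
#' @export
glance.candidate_calls <- function(x, ...) {
  th <- attr(x, "thresholds")
  dplyr::bind_cols(
    tibble(criterion = attr(x, "criterion")),
    as_tibble(th[!vapply(th, is.null, logical(1))]),
    tibble(n_universe = length(attr(x, "universe")), n_called = nrow(x))
  )
}
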