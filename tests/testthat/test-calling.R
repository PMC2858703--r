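# A hand-built NR universe where every clause outcome is known by
# construction. Ratios identical across tags.
calling_fixture <- function() {
  vals <- list(
    dead1 = c(0.01, 0.10, 0.01),  # bottom ranks at d9, d21 < 0.3 -> short
    dead2 = c(0.02, 0.20, 0.01),  # short
    edge = c(0.03, 0.30, 0.01),   # d21 exactly 0.30: NOT short (strict)
    mid1 = c(0.50, 0.40, 0.02),
    mid2 = c(0.60, 0.50, 0.03),
    live1 = c(1.10, 1.50, 5.00),  # top d33 ranks, d21 > 1 -> long
    live2 = c(1.20, 2.00, 8.00),  # long
    edge2 = c(1.00, 1.00, 9.00)   # d21 exactly 1.0: NOT long (strict)
  )
  ratios <- manual_ratio_table(vals)
  universe <- names(vals)
  ranks <- compute_rank_table(ratios, universe)
  list(ratios = ratios, ranks = ranks, universe = universe)
}

test_that("short-lived calling applies both clauses with a strict ratio cut", {
  fx <- calling_fixture()
  calls <- call_short_lived(fx$ratios, fx$ranks, rank_cut = 3, ratio_cut = 0.3)
  expect_setequal(calls$gene_id, c("dead1", "dead2"))
  ev <- tidy(calls)
  expect_false(ev$called[ev$gene_id == "edge"]) # boundary: 0.30 is not < 0.3
  # day-33 values are never consulted: perturbing them changes nothing
  r2 <- fx$ratios
  r2$ratio[r2$day == 33] <- 999
  r2$log_ratio <- log2(r2$ratio)
  rk2 <- compute_rank_table(r2, fx$universe)
  calls2 <- call_short_lived(r2, rk2, rank_cut = 3, ratio_cut = 0.3)
  expect_setequal(calls2$gene_id, calls$gene_id)
  expect_error(call_short_lived(fx$ratios, fx$ranks[fx$ranks$day != 9, ]),
               class = "clscreen_missing_day")
})

test_that("long-lived calling requires top day-33 ranks and day-21 ratio above 1", {
  fx <- calling_fixture()
  calls <- call_long_lived(fx$ratios, fx$ranks, rank_cut = 3, ratio_cut = 1.0)
  expect_setequal(calls$gene_id, c("live1", "live2"))
  ev <- tidy(calls)
  expect_false(ev$called[ev$gene_id == "edge2"]) # boundary: 1.00 is not > 1.0
  # a candidate with day-33 descending ranks (3, 7) and day-21 ratios
  # (6.91, 5.47) must be called at the published thresholds
  stored <- tibble::tibble(orf = "YER056C", up_rank_d33 = 3L, up_ratio_d21 = 6.91,
                           dn_rank_d33 = 7L, dn_ratio_d21 = 5.47)
  expect_true(audit_long_lived_rows(stored)$pass)
})

test_that("published long-lived candidate table audits as stored", {
  tbl <- published_long_lived_candidates()
  expect_equal(nrow(tbl), 40)
  audit <- audit_long_lived_rows(tbl)
  # every row satisfies the day-21 ratio clause
  expect_true(all(audit$pass_ratio))
  # one stored row (a DNTAG day-33 rank of 501) violates the rank clause;
  # all other 39 rows satisfy both clauses as stored
  failures <- audit[!audit$pass, ]
  expect_equal(nrow(failures), 1)
  expect_equal(failures$gene, "RPL29")
  expect_equal(failures$dn_rank_d33, 501L)
  expect_true(audit$pass[audit$gene == "FCY2"])
})

test_that("missing-tag genes are excluded from dual-tag criteria", {
  fx <- calling_fixture()
  # drop the DN tag of dead1 at day 9
  r <- fx$ratios[!(fx$ratios$gene_id == "dead1" & fx$ratios$tag == "DN" &
                     fx$ratios$day == 9), ]
  rk <- compute_rank_table(r, fx$universe)
  calls <- call_short_lived(r, rk, rank_cut = 3, ratio_cut = 0.3)
  expect_false("dead1" %in% calls$gene_id)
  expect_false("dead1" %in% tidy(calls)$gene_id) # not evaluated at all
})

test_that("CR-unresponsiveness clause 1: identity and doubled-mean hand oracles", {
  nr <- manual_ratio_table(list(g1 = c(0.8, 0.6, 0.4)), condition = "NR")
  cr_same <- manual_ratio_table(list(g1 = c(0.8, 0.6, 0.4)), condition = "CR")
  calls <- call_cr_unresponsive(rbind(nr, cr_same), "g1", p_rule = "p_ge_alpha")
  ev <- tidy(calls)
  expect_equal(ev$max_frac_diff, 0)
  expect_true(ev$clause_frac)

  # CR log ratios exactly 2x NR: fractional difference |x - 2x| / (1.5x) = 2/3
  nr2 <- manual_ratio_table(list(g1 = c(0.8, 0.6, 0.4)), condition = "NR")
  cr2 <- nr2
  cr2$condition <- "CR"
  cr2$log_ratio <- 2 * nr2$log_ratio
  cr2$ratio <- 2^cr2$log_ratio
  calls2 <- call_cr_unresponsive(rbind(nr2, cr2), "g1")
  ev2 <- tidy(calls2)
  expect_equal(ev2$max_frac_diff, 2 / 3, tolerance = 1e-12)
  expect_false(ev2$clause_frac)
})

test_that("CR-unresponsiveness t-test clause follows the selected p rule", {
  set.seed(5)
  mk <- function(gene, cond, vals) {
    tibble::tibble(gene_id = gene, tag = rep(c("UP", "DN"), 3),
                   condition = cond, day = rep(c(9L, 21L, 33L), each = 2),
                   ratio = 2^vals, log_ratio = vals)
  }
  # near-identical trajectories: p large
  same <- rbind(mk("g1", "NR", c(-1, -1.01, -2, -2.02, -3, -2.98)),
                mk("g1", "CR", c(-1.01, -1, -2.01, -2, -2.99, -3.01)))
  got_ge <- call_cr_unresponsive(same, "g1", p_rule = "p_ge_alpha")
  expect_true("g1" %in% got_ge$gene_id)
  got_lt <- call_cr_unresponsive(same, "g1", p_rule = "p_lt_alpha")
  expect_false("g1" %in% got_lt$gene_id)
  # the p-value matches a direct Welch t-test
  ev <- tidy(got_ge)
  direct <- stats::t.test(c(-1, -1.01, -2, -2.02, -3, -2.98),
                          c(-1.01, -1, -2.01, -2, -2.99, -3.01))$p.value
  expect_equal(ev$p_value, direct)
})

test_that("CR-unresponsiveness exclusions: zero denominator and too few observations", {
  nr <- manual_ratio_table(list(g1 = c(2, 2, 2)), condition = "NR")   # log ratio 1
  cr <- manual_ratio_table(list(g1 = c(0.5, 0.5, 0.5)), condition = "CR") # log ratio -1
  ev <- tidy(call_cr_unresponsive(rbind(nr, cr), "g1"))
  expect_true(ev$any_undefined)
  expect_equal(ev$excluded_reason, "undefined fractional difference")

  # constant observations in both conditions: the Welch statistic is
  # undefined, the gene is excluded with a named reason (when the
  # fractional difference itself is defined)
  nrc <- manual_ratio_table(list(g1 = c(2, 2, 2)), condition = "NR")
  crc <- manual_ratio_table(list(g1 = c(2.2, 2.2, 2.2)), condition = "CR")
  evc <- tidy(call_cr_unresponsive(rbind(nrc, crc), "g1"))
  expect_equal(evc$excluded_reason, "degenerate t-test (constant observations)")

  few <- rbind(nrc[1, ], crc[1, ])
  ev2 <- tidy(call_cr_unresponsive(few, "g1"))
  expect_equal(ev2$excluded_reason, "fewer than 2 observations per condition")
  expect_error(call_cr_unresponsive(nr, "g1"), class = "clscreen_missing_condition")
})

test_that("tightening any threshold never enlarges a call set", {
  an <- small_analysis(1)
  short_sets <- lapply(c(50, 30, 15), function(rc) {
    call_short_lived(an$ratios, an$nr_ranks, rank_cut = rc, ratio_cut = 0.3)$gene_id
  })
  expect_true(all(short_sets[[2]] %in% short_sets[[1]]))
  expect_true(all(short_sets[[3]] %in% short_sets[[2]]))
  ratio_sets <- lapply(c(0.3, 0.1, 0.05), function(qc) {
    call_short_lived(an$ratios, an$nr_ranks, rank_cut = 50, ratio_cut = qc)$gene_id
  })
  expect_true(all(ratio_sets[[2]] %in% ratio_sets[[1]]))
  expect_true(all(ratio_sets[[3]] %in% ratio_sets[[2]]))
  long_sets <- lapply(c(80, 40, 10), function(rc) {
    call_long_lived(an$ratios, an$nr_ranks, rank_cut = rc)$gene_id
  })
  expect_true(all(long_sets[[2]] %in% long_sets[[1]]))
  expect_true(all(long_sets[[3]] %in% long_sets[[2]]))
  long_ratio <- lapply(c(1, 1.5, 2), function(qc) {
    call_long_lived(an$ratios, an$nr_ranks, rank_cut = 80, ratio_cut = qc)$gene_id
  })
  expect_true(all(long_ratio[[2]] %in% long_ratio[[1]]))
  expect_true(all(long_ratio[[3]] %in% long_ratio[[2]]))
  frac_sets <- lapply(c(0.2, 0.1, 0.05), function(fc) {
    call_cr_unresponsive(an$ratios, an$universe, frac_cut = fc,
                         p_rule = "p_ge_alpha")$gene_id
  })
  expect_true(all(frac_sets[[2]] %in% frac_sets[[1]]))
  expect_true(all(frac_sets[[3]] %in% frac_sets[[2]]))
  # a zero rank cut empties the rank-based sets
  expect_equal(nrow(call_short_lived(an$ratios, an$nr_ranks, rank_cut = 0)), 0)
  expect_equal(nrow(call_long_lived(an$ratios, an$nr_ranks, rank_cut = 0)), 0)
})

test_that("call sets contain only dual-universe genes and never essentials", {
  an <- small_analysis(1)
  calls <- list(
    call_short_lived(an$ratios, an$nr_ranks, rank_cut = 30),
    call_long_lived(an$ratios, an$nr_ranks, rank_cut = 30),
    call_cr_unresponsive(an$ratios, an$universe, p_rule = "p_ge_alpha")
  )
  for (cs in calls) {
    expect_true(all(cs$gene_id %in% an$universe$dual))
    expect_false(any(cs$gene_id %in% an$essentials))
  }
})

test_that("the self-consistency audit passes on fresh calls and catches tampering", {
  an <- small_analysis(1)
  calls <- call_short_lived(an$ratios, an$nr_ranks, rank_cut = 30)
  expect_true(audit_calls(calls, an$ratios, an$universe))
  tampered <- an$ratios
  swap <- tampered$gene_id %in% calls$gene_id & tampered$day == 21
  tampered$ratio[swap] <- 10
  expect_error(audit_calls(calls, tampered, an$universe),
               class = "clscreen_audit_failed")
})

test_that("confusion counts: perfect, disjoint and permutation-null cases", {
  perfect <- cross_tabulate_calls(c("a", "b"), c("a", "b"))
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  disjoint <- cross_tabulate_calls(c("a", "b"), c("c", "d"))
  expect_equal(disjoint$tp, 0)

  # random label permutation: recall ~ called fraction (hypergeometric oracle)
  set.seed(31)
  universe <- paste0("g", 1:1000)
  called <- sample(universe, 200)
  recalls <- replicate(40, {
    truth <- sample(universe, 100)
    cross_tabulate_calls(called, truth)$recall
  })
  expected <- 200 / 1000
  se <- sqrt(expected * (1 - expected) / 100) # per-replicate binomial-scale SE
  expect_lt(abs(mean(recalls) - expected), 3 * se / sqrt(40))
})

test_that("tidy and glance expose the evaluation and thresholds", {
  fx <- calling_fixture()
  calls <- call_short_lived(fx$ratios, fx$ranks, rank_cut = 3, ratio_cut = 0.3)
  ev <- tidy(calls)
  expect_true(all(c("gene_id", "rank_up_d9", "rank_dn_d9", "ratio_up_d21",
                    "ratio_dn_d21", "called") %in% names(ev)))
  g <- glance(calls)
  expect_equal(g$criterion, "short_lived")
  expect_equal(g$rank_cut, 3)
  expect_equal(g$n_called, nrow(calls))
  p <- ggplot2::autoplot(calls)
  expect_s3_class(p, "ggplot")
})
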