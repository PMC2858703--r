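test_that("ratio arithmetic: identity and simple division", {
  x <- tidyr::expand_grid(gene_id = c("g1", "g2"), tag = c("UP", "DN"),
                          condition = "NR", day = c(9L, 21L))
  x$intensity_ref <- 100
  x$intensity_day <- 100
  r <- compute_ratio_table(x)
  expect_true(all(r$ratio == 1))
  expect_true(all(r$log_ratio == 0))

  y <- tibble::tibble(gene_id = "g", tag = "UP", condition = "NR", day = 9L,
                      intensity_ref = 4, intensity_day = 2)
  r2 <- compute_ratio_table(y)
  expect_equal(r2$ratio, 0.5)
  expect_equal(r2$log_ratio, -1)
})

test_that("records with missing or zero reference channel are dropped and counted", {
  x <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"), tag = "UP", condition = "NR", day = 9L,
    intensity_ref = c(10, 0, NA, 10), intensity_day = c(5, 5, 5, NA)
  )
  r <- compute_ratio_table(x)
  expect_equal(r$gene_id, "a")
  rep <- attr(r, "report")
  expect_equal(rep$records_read, 4)
  expect_equal(rep$records_kept, 1)
  expect_equal(rep$dropped_missing_ref, 2)
  expect_equal(rep$dropped_missing_day, 1)
  expect_error(compute_ratio_table(x[0, ]), class = "clscreen_bad_input")
  x$intensity_ref <- NA_real_
  expect_error(compute_ratio_table(x), class = "clscreen_bad_input")
})

test_that("ratios are invariant to rescaling both channels", {
  sim <- small_sim(1)
  r1 <- compute_ratio_table(sim$intensities)
  scaled <- sim$intensities
  scaled$intensity_ref <- scaled$intensity_ref * 7.3
  scaled$intensity_day <- scaled$intensity_day * 7.3
  r2 <- compute_ratio_table(scaled)
  expect_equal(r1$ratio, r2$ratio)
})

test_that("day-33 ratios correlate negatively with planted death rate", {
  # full plating depth so late-day signals stay count-driven
  sim <- simulate_screen(300, c(short = 0.1, normal = 0.8, long = 0.1),
                         pool_config(n_essential = 50, seed = 21), seed = 21)
  ratios <- compute_ratio_table(sim$intensities)
  # oracle: recompute ratios by direct division, independent of the pipeline
  x <- sim$intensities
  x <- x[x$day == 33 & x$condition == "NR" & x$tag == "UP" &
           !is.na(x$intensity_ref) & x$intensity_ref > 0, ]
  direct <- x$intensity_day / x$intensity_ref
  via_pkg <- ratios[ratios$day == 33 & ratios$condition == "NR" &
                      ratios$tag == "UP", ]
  expect_equal(via_pkg$ratio[match(x$gene_id, via_pkg$gene_id)], direct)

  truth <- sim$truth
  death_rate <- 1 / truth$tau_nr[match(x$gene_id, truth$gene_id)]
  keep <- !is.na(death_rate)
  rho <- stats::cor(direct[keep], death_rate[keep], method = "spearman")
  expect_lt(rho, -0.5)
})

test_that("background estimation: constant and simple-mean cases", {
  r <- tibble::tibble(
    gene_id = c("e1", "e1", "e2", "g1"), tag = c("UP", "UP", "UP", "UP"),
    condition = "NR", day = 9L,
    ratio = c(1, 2, 3, 9), log_ratio = log2(c(1, 2, 3, 9))
  )
  b <- estimate_background(r, c("e1", "e2"), "ratio")
  expect_equal(b$background, 2)
  r$ratio <- c(5, 5, 5, 9)
  expect_equal(estimate_background(r, c("e1", "e2"), "ratio")$background, 5)
  expect_error(estimate_background(r, character(), "ratio"),
               class = "clscreen_no_essentials")
  expect_error(estimate_background(r, "absent_gene", "ratio"),
               class = "clscreen_no_essentials")
})

test_that("reference-intensity background recovers the simulator's parameter", {
  an <- small_analysis(1)
  cfg <- an$sim$config
  for (tg in c("UP", "DN")) {
    b <- an$background$background[an$background$tag == tg]
    n <- an$background$n_essential_records[an$background$tag == tg]
    se <- cfg$background_mean * cfg$background_cv / sqrt(n)
    expect_lt(abs(b - cfg$background_mean), 3 * se)
  }
})

test_that("universe filtering keeps dual-signal genes and never admits essentials", {
  r <- tibble::tibble(
    gene_id = rep(c("keep", "lowup", "ess1"), each = 2),
    tag = rep(c("UP", "DN"), 3),
    condition = "NR", day = 9L,
    ratio = c(5, 5, 0.1, 5, 1, 1),
    log_ratio = log2(c(5, 5, 0.1, 5, 1, 1))
  )
  b <- estimate_background(r, "ess1", "ratio")
  u <- filter_gene_universe(r, b, "ess1", "ratio")
  expect_true("keep" %in% u$dual)
  expect_false("lowup" %in% u$dual)
  expect_true("lowup" %in% u$dn) # still present in the DNTAG-only list
  expect_false("ess1" %in% c(u$up, u$dn, u$dual))
  expect_error(filter_gene_universe(r, b, "ess1", "ref_intensity"),
               class = "clscreen_mode_mismatch")
})

test_that("raising the background never grows a universe (monotonicity)", {
  an <- small_analysis(1)
  b1 <- an$background
  b2 <- b1
  b2$background <- b2$background * 10
  attr(b2, "mode") <- attr(b1, "mode")
  u1 <- filter_gene_universe(an$sim$intensities, b1, an$essentials, "ref_intensity")
  u2 <- filter_gene_universe(an$sim$intensities, b2, an$essentials, "ref_intensity")
  expect_true(all(u2$up %in% u1$up))
  expect_true(all(u2$dn %in% u1$dn))
  expect_true(all(u2$dual %in% u1$dual))
  expect_true(all(!an$essentials %in% u1$dual))
})

test_that("population summary matches hand and sort-based quantile oracles", {
  r <- manual_ratio_table(list(a = c(1, 1, 1), b = c(1, 1, 1), c = c(1, 1, 1)))
  s <- population_summary(r, c("a", "b", "c"), 9, "NR")
  expect_equal(unlist(s[, c("min", "q1", "median", "q3", "max", "mean")]),
               c(min = 1, q1 = 1, median = 1, q3 = 1, max = 1, mean = 1))

  r5 <- tibble::tibble(gene_id = letters[1:5], tag = "UP", condition = "NR",
                       day = 9L, ratio = c(0, 1, 2, 3, 4), log_ratio = NA_real_)
  s5 <- population_summary(r5, letters[1:5], 9, "NR")
  expect_equal(s5$q1, 1)
  expect_equal(s5$median, 2)
  expect_equal(s5$q3, 3)

  set.seed(123)
  for (n in c(1, 2, 3, 7, 20, 50)) {
    x <- stats::runif(n)
    rr <- tibble::tibble(gene_id = paste0("g", seq_len(n)), tag = "UP",
                         condition = "NR", day = 9L, ratio = x, log_ratio = NA_real_)
    ss <- population_summary(rr, rr$gene_id, 9, "NR")
    expect_equal(ss$q1, oracle_quantile7(x, 0.25))
    expect_equal(ss$median, oracle_quantile7(x, 0.5))
    expect_equal(ss$q3, oracle_quantile7(x, 0.75))
  }
  expect_error(population_summary(r5, character(), 9, "NR"),
               class = "clscreen_empty_universe")
})

test_that("CR day-33 population median exceeds NR (direction of the CR viability boost)", {
  an <- small_analysis(1)
  nr <- population_summary(an$ratios, an$universe, 33, "NR")
  cr <- population_summary(an$ratios, an$universe, 33, "CR")
  expect_gt(cr$median, nr$median)
})

test_that("ratio tables round-trip through TSV bit-identically", {
  an <- small_analysis(1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ratio_tsv(an$ratios, path)
  back <- read_ratio_tsv(path)
  for (col in names(back)) {
    expect_identical(back[[col]], an$ratios[[col]])
  }
})
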