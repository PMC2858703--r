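pkg_version <- function() {
  as.character(utils::packageVersion("clscreen"))
}

write_manifest <- function(out_dir, stage, inputs, config = NULL, seed = NULL,
                           counts = list()) {
  manifest <- list(
    stage = stage,
    tool_version = pkg_version(),
    seed = seed,
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    config = if (!is.null(config)) unclass(config) else NULL,
    counts = counts,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

ensure_out_dir <- function(out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) {
      stop_clscreen(sprintf("cannot create output directory %s", out_dir), "unwritable")
    }
  }
  invisible(out_dir)
}

#' Pipeline stage: simulate a screen to files
#'
#' Runs the full simulator and writes `intensities.tsv`, `truth.tsv`,
#' `essential_genes.txt`, a config snapshot (`config.yaml`) and a run
#' manifest into `out_dir`.
#'
#' @param config A [pool_config()] or path to its YAML file.
#' @param out_dir Output directory (created if needed).
#' @param n_mutants,class_fractions Pool composition, see [build_pool()].
#' @return Invisibly, a named list of the written file paths.
#' @export
screen_simulate <- function(config, out_dir, n_mutants = 4800,
                            class_fractions = c(short = 0.05, normal = 0.85,
                                                long = 0.05, cr_unresponsive = 0.05)) {
  if (is.character(config)) {
    config <- read_config_yaml(config)
  }
  ensure_out_dir(out_dir)
  sim <- simulate_screen(n_mutants, class_fractions, config)
  paths <- list(
    intensities = file.path(out_dir, "intensities.tsv"),
    truth = file.path(out_dir, "truth.tsv"),
    essentials = file.path(out_dir, "essential_genes.txt"),
    config = file.path(out_dir, "config.yaml")
  )
  write_intensity_tsv(sim$intensities, paths$intensities)
  write_truth_tsv(sim$truth, paths$truth)
  readr::write_lines(sim$profiles$gene_id[sim$profiles$essential], paths$essentials)
  write_config_yaml(config, paths$config)
  write_manifest(out_dir, "simulate", paths, config = config, seed = config$seed,
                 counts = list(
                   n_mutants = sum(!sim$profiles$essential),
                   n_essential = sum(sim$profiles$essential),
                   intensity_records = nrow(sim$intensities)
                 ))
  invisible(paths)
}

#' Pipeline stage: intensities to ratios, background and universe
#'
#' Chains [compute_ratio_table()], [estimate_background()] and
#' [filter_gene_universe()], writing `ratios.tsv`, `universe.json` and a
#' processing report (`ratio_report.json`) plus a manifest.
#'
#' @param intensity_path Intensity TSV written by [screen_simulate()] (or
#'   any table in that dialect).
#' @param essentials_path Essential-gene list file.
#' @param out_dir Output directory.
#' @param mode Background metric mode, `"ratio"` (as in the published
#'   analysis) or `"ref_intensity"`.
#' @return Invisibly, a list with the ratio table, the universe and file
#'   paths.
#' @export
screen_ratios <- function(intensity_path, essentials_path, out_dir,
                          mode = c("ratio", "ref_intensity")) {
  mode <- match.arg(mode)
  ensure_out_dir(out_dir)
  intensities <- read_intensity_tsv(intensity_path)
  essentials <- read_essential_genes(essentials_path)
  ratios <- compute_ratio_table(intensities)
  metric_table <- if (mode == "ratio") ratios else intensities
  background <- estimate_background(metric_table, essentials, mode)
  universe <- filter_gene_universe(metric_table, background, essentials, mode)

  paths <- list(
    ratios = file.path(out_dir, "ratios.tsv"),
    universe = file.path(out_dir, "universe.json"),
    report = file.path(out_dir, "ratio_report.json")
  )
  write_ratio_tsv(ratios, paths$ratios)
  jsonlite::write_json(
    list(mode = mode, up = universe$up, dn = universe$dn, dual = universe$dual,
         background = background),
    paths$universe, auto_unbox = TRUE, digits = NA
  )
  report <- attr(ratios, "report")
  report$universe_up <- length(universe$up)
  report$universe_dn <- length(universe$dn)
  report$universe_dual <- length(universe$dual)
  report$background <- stats::setNames(as.list(background$background), background$tag)
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(out_dir, "ratios", list(intensities = intensity_path,
                                         essentials = essentials_path),
                 counts = report[c("records_read", "records_kept",
                                   "universe_up", "universe_dn", "universe_dual")])
  invisible(list(ratios = ratios, universe = universe, paths = paths))
}

read_universe_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  bg <- as_tibble(raw$background)
  attr(bg, "mode") <- raw$mode
  structure(
    list(up = raw$up, dn = raw$dn, dual = raw$dual, background = bg, mode = raw$mode),
    class = "gene_universe"
  )
}

#' Pipeline stage: call candidate mutants
#'
#' Runs the three calling criteria on a ratio table and universe, audits the
#' rank/ratio call sets against the ratio table, and writes one TSV per
#' criterion plus a JSON sidecar with thresholds and input checksums.
#'
#' @param ratio_path Ratio TSV from [screen_ratios()].
#' @param universe_path `universe.json` from [screen_ratios()].
#' @param out_dir Output directory.
#' @param short_rank_cut,short_ratio_cut,long_rank_cut,long_ratio_cut,frac_cut,alpha,p_rule
#'   Calling thresholds; defaults are the published values (200, 0.3, 500,
#'   1.0, 0.1, 0.05, `"p_lt_alpha"`).
#' @return Invisibly, a named list of `candidate_calls` objects.
#' @export
screen_call <- function(ratio_path, universe_path, out_dir,
                        short_rank_cut = 200, short_ratio_cut = 0.3,
                        long_rank_cut = 500, long_ratio_cut = 1.0,
                        frac_cut = 0.1, alpha = 0.05, p_rule = "p_lt_alpha") {
  ensure_out_dir(out_dir)
  ratios <- read_ratio_tsv(ratio_path)
  universe <- read_universe_json(universe_path)
  nr_ranks <- compute_rank_table(ratios[ratios$condition == "NR", ], universe)

  calls <- list(
    short_lived = call_short_lived(ratios, nr_ranks, short_rank_cut, short_ratio_cut),
    long_lived = call_long_lived(ratios, nr_ranks, long_rank_cut, long_ratio_cut)
  )
  if (all(c("NR", "CR") %in% ratios$condition)) {
    calls$cr_unresponsive <- call_cr_unresponsive(ratios, universe, frac_cut, alpha,
                                                  p_rule)
  }
  audit_calls(calls$short_lived, ratios, universe)
  audit_calls(calls$long_lived, ratios, universe)

  for (nm in names(calls)) {
    readr::write_tsv(as_tibble(calls[[nm]]), file.path(out_dir, paste0("calls_", nm, ".tsv")))
  }
  sidecar <- list(
    thresholds = list(short_rank_cut = short_rank_cut, short_ratio_cut = short_ratio_cut,
                      long_rank_cut = long_rank_cut, long_ratio_cut = long_ratio_cut,
                      frac_cut = frac_cut, alpha = alpha, p_rule = p_rule),
    universe_sizes = list(up = length(universe$up), dn = length(universe$dn),
                          dual = length(universe$dual)),
    n_called = lapply(calls, nrow),
    input_checksums = list(ratios = unname(tools::md5sum(ratio_path)),
                           universe = unname(tools::md5sum(universe_path)))
  )
  jsonlite::write_json(sidecar, file.path(out_dir, "calls_meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(out_dir, "call", list(ratios = ratio_path, universe = universe_path),
                 counts = sidecar$n_called)
  invisible(calls)
}

#' Pipeline stage: validation summaries
#'
#' Cross-tabulates call sets against truth labels (when a truth file is
#' given), computes confirmation rates and external-list overlaps, and
#' writes `report.json`.
#'
#' @param calls Named list of `candidate_calls` (from [screen_call()]).
#' @param out_dir Output directory.
#' @param truth Optional truth tibble (or path to `truth.tsv`) with
#'   `gene_id` and `true_class`.
#' @param external_lists Optional named list of character vectors; each is
#'   overlapped against each call set.
#' @param retests Optional tibble with columns `criterion`, `n_confirmed`,
#'   `n_tested` of individual retest outcomes.
#' @return Invisibly, the report list.
#' @export
screen_report <- function(calls, out_dir, truth = NULL, external_lists = NULL,
                          retests = NULL) {
  ensure_out_dir(out_dir)
  report <- list()
  if (is.character(truth)) {
    truth <- read_truth_tsv(truth)
  }
  if (!is.null(truth)) {
    class_map <- c(short_lived = "short", long_lived = "long",
                   cr_unresponsive = "cr_unresponsive")
    report$confusion <- lapply(names(calls), function(nm) {
      pos <- truth$gene_id[!is.na(truth$true_class) &
                             truth$true_class == class_map[[nm]]]
      ct <- cross_tabulate_calls(calls[[nm]], pos)
      c(list(criterion = nm), as.list(ct))
    })
  }
  if (!is.null(external_lists)) {
    if (any(lengths(external_lists) == 0)) {
      warning("empty external list supplied; overlap section omitted for it")
      external_lists <- external_lists[lengths(external_lists) > 0]
    }
    report$overlap <- lapply(names(external_lists), function(enm) {
      lapply(names(calls), function(nm) {
        ov <- gene_set_overlap(calls[[nm]]$gene_id, external_lists[[enm]])
        c(list(criterion = nm, external = enm), as.list(ov))
      })
    })
  }
  if (!is.null(retests)) {
    report$confirmation <- lapply(seq_len(nrow(retests)), function(i) {
      list(criterion = retests$criterion[i],
           n_confirmed = retests$n_confirmed[i],
           n_tested = retests$n_tested[i],
           rate_percent = confirmation_rate(retests$n_confirmed[i], retests$n_tested[i]))
    })
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(out_dir, "report", list(), counts = list(sections = length(report)))
  invisible(report)
}

#' Run the full pipeline: simulate, ratios, call, report
#'
#' Chains the four stages on one output directory with the simulator's
#' configuration, using the `"ref_intensity"` background mode appropriate to
#' simulated data (see the package vignette).
#'
#' @param config A [pool_config()].
#' @param out_dir Output directory.
#' @param n_mutants,class_fractions Pool composition.
#' @param mode Background metric mode for universe filtering.
#' @return Invisibly, a list with calls and the report.
#' @export
run_screen_pipeline <- function(config = pool_config(), out_dir,
                                n_mutants = 4800,
                                class_fractions = c(short = 0.05, normal = 0.85,
                                                    long = 0.05, cr_unresponsive = 0.05),
                                mode = "ref_intensity") {
  paths <- screen_simulate(config, out_dir, n_mutants, class_fractions)
  rat <- screen_ratios(paths$intensities, paths$essentials, out_dir, mode = mode)
  calls <- screen_call(rat$paths$ratios, rat$paths$universe, out_dir)
  truth <- read_truth_tsv(paths$truth)
  report <- screen_report(calls, out_dir, truth = truth)
  invisible(list(paths = paths, calls = calls, report = report))
}
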