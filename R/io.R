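#' Read and write screen tables as TSV
#'
#' Tab-separated dialects used throughout the pipeline. Numeric values are
#' written with readr's shortest round-trippable representation, so writing
#' then reading a table reproduces it bit-identically. Missing tag
#' intensities are emitted as empty fields.
#'
#' @param x Table to write.
#' @param path File path.
#' @return `read_*` return tibbles; `write_*` return `path` invisibly.
#' @name screen_io
NULL

# %.17g uniquely identifies a double, so parsing the text recovers the
# exact value; readr's own writer keeps fewer digits.
format_double_cols <- function(x) {
  for (col in names(x)) {
    v <- x[[col]]
    if (is.double(v)) {
      x[[col]] <- ifelse(is.na(v), NA_character_, sprintf("%.17g", v))
    }
  }
  x
}

#' @rdname screen_io
#' @export
write_intensity_tsv <- function(x, path) {
  assert_columns(x, c("gene_id", "tag", "condition", "day",
                      "intensity_ref", "intensity_day"), "`x`")
  readr::write_tsv(format_double_cols(x), path, na = "")
  invisible(path)
}

# Parse double columns from text with strtod (via as.numeric), which rounds
# correctly to the nearest double; together with the %.17g writer this makes
# the TSV round trip bit-exact.
parse_double_cols <- function(x, cols) {
  for (col in cols) {
    x[[col]] <- as.numeric(x[[col]])
  }
  x
}

#' @rdname screen_io
#' @export
read_intensity_tsv <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", tag = "c", condition = "c", day = "i",
    intensity_ref = "c", intensity_day = "c"
  ), na = "")
  parse_double_cols(x, c("intensity_ref", "intensity_day"))
}

#' @rdname screen_io
#' @export
write_ratio_tsv <- function(x, path) {
  assert_columns(x, c("gene_id", "tag", "condition", "day", "ratio", "log_ratio"), "`x`")
  readr::write_tsv(format_double_cols(x), path, na = "")
  invisible(path)
}

#' @rdname screen_io
#' @export
read_ratio_tsv <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", tag = "c", condition = "c", day = "i",
    ratio = "c", log_ratio = "c"
  ), na = "")
  parse_double_cols(x, c("ratio", "log_ratio"))
}

#' @rdname screen_io
#' @export
write_truth_tsv <- function(x, path) {
  assert_columns(x, c("gene_id", "true_class", "tau_nr", "tau_cr"), "`x`")
  readr::write_tsv(format_double_cols(x), path, na = "")
  invisible(path)
}

#' @rdname screen_io
#' @export
read_truth_tsv <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", true_class = "c", tau_nr = "c", tau_cr = "c",
    .default = readr::col_guess()
  ), na = "")
  parse_double_cols(x, c("tau_nr", "tau_cr"))
}

#' Read an essential-gene list
#'
#' Accepts either a plain list (one ORF per line) or a two-column
#' tab-separated table `gene_id<TAB>essential_flag`, in which case ids with
#' a true flag (`TRUE`/`1`/`yes`) are returned. Lines starting with `#` are
#' ignored.
#'
#' @param path File path.
#' @return Character vector of essential gene ids.
#' @export
read_essential_genes <- function(path) {
  lines <- readr::read_lines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    stop_clscreen("essential-gene list is empty", "no_essentials")
  }
  parts <- strsplit(lines, "\t")
  if (all(lengths(parts) >= 2)) {
    flag <- tolower(vapply(parts, `[[`, character(1), 2))
    ids <- vapply(parts, `[[`, character(1), 1)
    ids[flag %in% c("true", "1", "yes", "y", "essential")]
  } else {
    vapply(parts, `[[`, character(1), 1)
  }
}

#' Read a supplementary ratio workbook export via a YAML column map
#'
#' Ingests a published per-gene ratio table (one row per gene, wide columns
#' of per-tag, per-condition, per-day ratios) into the long ratio format,
#' without hard-coding the sheet layout. The column map is a YAML file:
#'
#' ```yaml
#' gene_id: ORF
#' ratios:
#'   - {column: "UP D9 NR", tag: UP, condition: NR, day: 9}
#'   - {column: "DN D9 NR", tag: DN, condition: NR, day: 9}
#' ```
#'
#' Binary spreadsheet formats are not parsed; export the first sheet as
#' TSV/CSV first. An `.xls`/`.xlsx` path raises an
#' `clscreen_unsupported_workbook` error so callers can report the
#' replication as blocked rather than silently skipping it.
#'
#' @param path TSV or CSV export of the workbook's first sheet.
#' @param column_map_path Path to the YAML column map.
#' @return A ratio tibble (`gene_id`, `tag`, `condition`, `day`, `ratio`,
#'   `log_ratio`).
#' @export
read_ratio_workbook <- function(path, column_map_path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xls", "xlsx")) {
    stop_clscreen(
      "binary spreadsheet workbooks are not supported; export the first sheet as TSV/CSV",
      "unsupported_workbook"
    )
  }
  map <- yaml::read_yaml(column_map_path)
  if (is.null(map$gene_id) || is.null(map$ratios)) {
    stop_clscreen("column map must define `gene_id` and `ratios`", "bad_column_map")
  }
  raw <- if (ext == "csv") {
    readr::read_csv(path, col_types = readr::cols(.default = "c"))
  } else {
    readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  }
  needed <- c(map$gene_id, vapply(map$ratios, `[[`, character(1), "column"))
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    stop_clscreen(
      sprintf("workbook layout defeats the column map; missing column(s): %s",
              paste(missing, collapse = ", ")),
      "bad_column_map"
    )
  }
  long <- purrr::map_dfr(map$ratios, function(m) {
    tibble(
      gene_id = raw[[map$gene_id]],
      tag = m$tag,
      condition = m$condition,
      day = as.integer(m$day),
      ratio = suppressWarnings(as.numeric(raw[[m$column]]))
    )
  })
  long <- long[!is.na(long$ratio), ]
  long$log_ratio <- log2(long$ratio)
  long
}

#' Write or read a simulator configuration as a flat YAML file
#'
#' @param config A [pool_config()].
#' @param path YAML file path.
#' @return `read_config_yaml` returns a `pool_config`;
#'   `write_config_yaml` returns `path` invisibly.
#' @export
write_config_yaml <- function(config, path) {
  flat <- unclass(config)
  flat$class_sdlog <- as.list(flat$class_sdlog)
  yaml::write_yaml(flat, path, precision = 15)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(pool_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    stop_clscreen(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
                  "bad_config")
  }
  missing <- setdiff(allowed, names(raw))
  if (length(missing) > 0) {
    stop_clscreen(sprintf("missing config key(s): %s", paste(missing, collapse = ", ")),
                  "bad_config")
  }
  raw$class_sdlog <- unlist(raw$class_sdlog)
  do.call(pool_config, raw)
}
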