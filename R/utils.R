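#' @importFrom rlang abort .data :=
#' @importFrom tibble tibble as_tibble
NULL

# Round half away from zero (spreadsheet-style), the convention used for all
# printed percentages. base::round() rounds half to even and would give
# e.g. 81.2 for 13/16.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Derive a deterministic 31-bit sub-stream seed from one master seed, so the
# whole simulation is a pure function of (profiles, config, seed).
derive_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

stop_clscreen <- function(message, class) {
  abort(message, class = c(paste0("clscreen_", class), "clscreen_error"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Log-normal draws parameterised by mean and coefficient of variation.
rlnorm_cv <- function(n, mean = 1, cv = 0) {
  if (cv <= 0) {
    return(rep(mean, n))
  }
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

assert_columns <- function(x, cols, what) {
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    stop_clscreen(
      sprintf("%s is missing required column(s): %s", what, paste(missing, collapse = ", ")),
      "bad_input"
    )
  }
  invisible(x)
}
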