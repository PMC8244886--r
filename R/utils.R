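#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @keywords internal
"_PACKAGE"

# Round half away from zero (diversity-table presentation rounding).
# base::round() rounds half to even, which would print 0.345 -> 0.34.
round_half_away <- function(x, digits = 2) {
  scaled <- x * 10^digits
  # small epsilon so decimal halves stored just below .5 in binary
  # (e.g. 0.345 * 100) still round up
  sign(scaled) * floor(abs(scaled) + 0.5 + 1e-9) / 10^digits
}

# Format a metric for the rounded report view: always 2 decimals, NA -> "NA".
format_2dp <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%.2f", round_half_away(x, 2)))
}

stop_hapnet <- function(message, class, ...) {
  abort(message, class = c(paste0("hapnetdiv_", class), "hapnetdiv_error"), ...)
}

is_count_vector <- function(x) {
  is.numeric(x) && length(x) >= 1 && all(is.finite(x)) &&
    all(x == as.integer(x)) && all(x >= 1)
}
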