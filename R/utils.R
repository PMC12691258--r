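# Internal validation and formatting helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  invisible(x)
}

assert_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    stop(sprintf("`%s` must be a single nonnegative number", name), call. = FALSE)
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}

# Half-up decimal rounding (display convention of the aggregated tables).
round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

# Posterior percentage formatting: 6 decimals, widening to 9 for percentages
# below 0.001% (where 6 decimals would lose all significant digits).
format_pct <- function(p) {
  pct <- 100 * p
  vapply(pct, function(v) {
    if (is.na(v)) return(NA_character_)
    if (v != 0 && abs(v) < 1e-3) sprintf("%.9f%%", v) else sprintf("%.6f%%", v)
  }, character(1))
}

format_count <- function(x, digits = 2) {
  vapply(x, function(v) {
    if (is.na(v)) NA_character_
    else formatC(round_half_up(v, digits), format = "f", digits = digits, big.mark = ",")
  }, character(1))
}

# Full-precision decimal string: round-trips a double exactly through text.
format_full <- function(x) {
  vapply(x, function(v) if (is.na(v)) NA_character_ else sprintf("%.17g", v),
         character(1))
}
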