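#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map2 map_dbl map_int map_chr pmap imap
#' @importFrom tidyr pivot_wider pivot_longer unnest
NULL

# log(exp(a) + exp(b)) without overflow; a, b may be -Inf
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

#' Half-away-from-zero rounding
#'
#' The rounding convention of the dating report tables: ties round away
#' from zero (1.25 -> 1.3, -1.25 -> -1.3), unlike base R's banker's
#' rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# significance stars at the report thresholds
p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p <= 0.001 ~ "***",
    p <= 0.01 ~ "**",
    p <= 0.02 ~ "*",
    TRUE ~ ""
  )
}

# run `expr` under a fixed seed when `seed` is given, else in the current
# RNG state
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
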