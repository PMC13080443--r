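#' Round half away from zero
#'
#' Reported counts of people and tonnages are rounded half-up (0.5 always
#' rounds away from zero), the convention the worked country-crop tables
#' follow, rather than the IEC 60559 half-to-even rule of [round()]. All
#' internal arithmetic carries full double precision; rounding happens only
#' at report time.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(0.5)        # 1, where round(0.5) gives 0
#' round_half_up(349249.35)  # 349249
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# format a number for table rendering: half-up rounding then thousands commas
fmt_num <- function(x, digits = 0) {
  digits <- rep_len(digits, length(x))
  vapply(seq_along(x), function(i) {
    if (is.na(x[i])) return("")
    formatC(round_half_up(x[i], digits[i]), format = "f", digits = digits[i],
            big.mark = ",")
  }, character(1))
}

# collapse a character vector of flags for printing
fmt_flags <- function(flags) {
  if (length(flags) == 0) "none" else paste(flags, collapse = "; ")
}
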