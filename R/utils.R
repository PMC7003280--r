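#' Round half away from zero
#'
#' Fixed-precision rounding where exact .5 cases go up (for positive input),
#' matching how the pipeline's reported tables are rounded. Base [round()]
#' uses round-half-even, which disagrees on values such as 0.125.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up at `digits` decimals.
#' @examples
#' round_half_up(0.125, 2) # 0.13, where round(0.125, 2) gives 0.12
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # tiny nudge guards against representation error just below .5 (e.g. 51.505
  # stored as 51.50499999...); it is far below the precision of any reported value
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# normalize a lookup key: trim outer whitespace, case-fold
normalize_key <- function(x) {
  tolower(trimws(x))
}

# split a ;-separated field into a trimmed character vector (empty -> character(0))
split_field <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character(0))
  out <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  out[nzchar(out)]
}

stop_herbminer <- function(message, class, ...) {
  abort(message, class = c(class, "herbminer_error"), ...)
}
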