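#' Round half away from zero
#'
#' Rounds to a fixed number of decimals with ties going away from zero,
#' the convention used when comparing computed values against published
#' tables (base [round()] rounds ties to even). A tiny relative guard is
#' applied before taking the floor so that values that are exact halves
#' in decimal but sit an ulp below in binary still round up.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return `x` rounded half away from zero at `digits` decimals.
#' @examples
#' round_half_up(0.5)      # 1, not 0
#' round_half_up(123.227, 2)
#' @export
round_half_up <- function(x, digits = 0) {
  z <- abs(x) * 10^digits
  sign(x) * floor(z * (1 + 8 * .Machine$double.eps) + 0.5) / 10^digits
}

# stop() with call.=FALSE, sprintf-style
.fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_numeric <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || anyNA(x))
    .fail("'%s' must be numeric with no missing values", name)
  bad <- if (strict_min) any(x <= min) else any(x < min)
  if (bad)
    .fail("'%s' must be %s %g", name, if (strict_min) ">" else ">=", min)
  invisible(x)
}

.check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    .fail("%s is missing required column(s): %s", what,
          paste(miss, collapse = ", "))
  invisible(df)
}
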