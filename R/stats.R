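#' Pearson correlation with R-squared and two-sided p-value
#'
#' Product-moment correlation between two variables with the usual
#' t-test p-value, `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees
#' of freedom (computed via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with `r`, `r_squared`, `p_two_sided`, `n`.
#' @export
pearson <- function(x, y) {
  .check_numeric(x, "x"); .check_numeric(y, "y")
  if (length(x) != length(y)) .fail("'x' and 'y' must have equal length")
  if (length(x) < 3) .fail("at least 3 paired observations are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    .fail("zero variance in 'x' or 'y'")
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  list(r = r, r_squared = r^2, p_two_sided = ct$p.value, n = length(x))
}

#' Ordinary least squares with adjusted R-squared
#'
#' Linear model of a response on one or more numeric predictors, with an
#' optional categorical factor (reference-level dummy coding; reference
#' is the alphabetically first level) added either additively or
#' interacting with the predictors. Reports the coefficient table, the
#' adjusted R-squared `1 - (1 - R^2)(n - 1)/(n - p - 1)` and the overall
#' F-test p-value.
#'
#' @param y numeric response.
#' @param predictors numeric vector, matrix or data.frame of predictors.
#' @param factor optional vector of group labels (e.g. species).
#' @param interaction logical; if TRUE the factor interacts with each
#'   predictor instead of entering additively.
#' @return List with `coefficients` (matrix from `summary.lm`),
#'   `r_squared`, `adjusted_r_squared`, `model_p`, `n`.
#' @export
ols_adj_r2 <- function(y, predictors, factor = NULL, interaction = FALSE) {
  .check_numeric(y, "y")
  X <- as.data.frame(predictors)
  if (is.null(dim(predictors)) || is.null(colnames(predictors)))
    names(X) <- paste0("x", seq_along(X))
  if (nrow(X) != length(y)) .fail("'y' and 'predictors' sizes differ")
  dat <- cbind(data.frame(.y = y), X)
  rhs <- paste(names(X), collapse = " + ")
  if (!is.null(factor)) {
    dat$.group <- base::factor(factor)
    rhs <- if (interaction)
      paste0("(", rhs, ") * .group") else paste(rhs, "+ .group")
  }
  fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = dat)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    .fail("rank-deficient design; collinear term(s): %s",
          paste(bad, collapse = ", "))
  }
  s <- summary(fit)
  if (s$df[2] < 1) .fail("not enough observations for the model size")
  fstat <- s$fstatistic
  list(coefficients = s$coefficients,
       r_squared = s$r.squared,
       adjusted_r_squared = s$adj.r.squared,
       model_p = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                  lower.tail = FALSE)),
       n = length(y))
}

#' Mean and sample standard deviation
#'
#' @param values numeric vector, length >= 1. The SD uses the sample
#'   (n - 1) convention and is NA (with a warning) for a single value.
#' @return List with `mean`, `sd`, `n`.
#' @export
mean_sd <- function(values) {
  if (length(values) == 0) .fail("empty vector")
  .check_numeric(values, "values")
  s <- if (length(values) < 2) {
    warning("sample SD undefined for n = 1", call. = FALSE)
    NA_real_
  } else stats::sd(values)
  list(mean = mean(values), sd = s, n = length(values))
}
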