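# Box-Cox symmetrisation and standardisation of landscape metrics.

#' Box-Cox transform and standardise a metric
#'
#' Shifts non-positive vectors by `1 - min(x)`, picks the Box-Cox exponent
#' on the grid `lambda in [-2, 2]` (step 0.05) maximising the profile
#' normal log-likelihood, applies the transform, and centers/scales to mean
#' 0 and sd 1.
#'
#' @param x Numeric vector (n >= 3, not constant).
#' @return List with `x` (transformed, standardised vector) and `spec`
#'   (list `lambda, shift, mean, sd` needed to transform new data).
#' @export
boxcox_standardize <- function(x) {
  if (length(x) < 3L) abort("need at least 3 observations")
  if (anyNA(x)) abort("missing values in metric")
  if (sd(x) == 0) abort("constant metric cannot be transformed")
  shift <- if (min(x) <= 0) 1 - min(x) else 0
  xs <- x + shift
  grid <- seq(-2, 2, by = 0.05)
  n <- length(xs)
  slx <- sum(log(xs))
  ll <- vapply(grid, function(lambda) {
    y <- if (abs(lambda) < 1e-12) log(xs) else (xs^lambda - 1) / lambda
    -n / 2 * log(max(mean((y - mean(y))^2), 1e-300)) + (lambda - 1) * slx
  }, numeric(1))
  lambda <- grid[which.max(ll)]
  y <- if (abs(lambda) < 1e-12) log(xs) else (xs^lambda - 1) / lambda
  mu <- mean(y); s <- sd(y)
  if (s == 0) abort("metric is constant after transformation")
  list(
    x = (y - mu) / s,
    spec = list(lambda = lambda, shift = shift, mean = mu, sd = s)
  )
}

#' Apply a stored transform spec to new data
#'
#' @param x Numeric vector.
#' @param spec A `spec` from [boxcox_standardize()].
#' @return Transformed, standardised vector.
#' @export
apply_transform <- function(x, spec) {
  xs <- x + spec$shift
  y <- if (abs(spec$lambda) < 1e-12) log(xs) else (xs^spec$lambda - 1) / spec$lambda
  (y - spec$mean) / spec$sd
}

#' Box-Cox standardise a table of metrics
#'
#' Applies [boxcox_standardize()] column-wise; constant columns are dropped
#' with a warning and listed in the result.
#'
#' @param data A data frame.
#' @param metrics Character vector of column names to transform.
#' @return List with `data` (transformed copy), `specs` (named list) and
#'   `dropped` (character vector of constant metrics).
#' @export
standardize_metrics <- function(data, metrics) {
  specs <- list(); dropped <- character(0)
  for (m in metrics) {
    x <- data[[m]]
    ok <- !is.na(x)
    if (sd(x[ok]) == 0 || sum(ok) < 3L) {
      dropped <- c(dropped, m)
      warn(paste0("metric ", m, " is constant or too short; dropped"))
      next
    }
    bc <- boxcox_standardize(x[ok])
    data[[m]][ok] <- bc$x
    specs[[m]] <- bc$spec
  }
  list(data = data, specs = specs, dropped = dropped)
}
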