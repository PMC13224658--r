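# Gaussian linear mixed models with a patch random intercept, wrapping
# lme4::lmer behind the same tidy surface as the zero-inflated fits.
# ML fits drive model selection; REML refits produce the reported
# coefficients.

#' Fit a random-intercept Gaussian linear mixed model
#'
#' @param formula Fixed-effects formula, e.g. `a_r ~ MAIZE + I(MAIZE^2)`;
#'   the random intercept `(1 | group)` is appended automatically.
#' @param data Data frame.
#' @param group Grouping column (default `"patch_id"`).
#' @param method `"ML"` (for selection) or `"REML"` (for reporting).
#' @return Object of class `pollenscape_lmm`: `coefficients` (tibble
#'   `component, term, estimate, se, z, p` with Wald t p-values on
#'   residual df `n - k_fixed`), `sigma_u` (random-intercept SD),
#'   `sigma` (residual SD), `logLik`, `k`, `n`, `AICc`, `singular`.
#' @export
fit_lmm <- function(formula, data, group = "patch_id", method = c("ML", "REML")) {
  method <- match.arg(method)
  full <- stats::as.formula(
    paste(deparse(formula), "+ (1 |", group, ")"),
    env = environment(formula) %||% parent.frame()
  )
  fit <- suppressMessages(lme4::lmer(
    full, data = data, REML = method == "REML",
    control = lme4::lmerControl(check.conv.singular = "ignore")
  ))
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  n <- stats::nobs(fit)
  p <- length(fe)
  df <- n - p
  tval <- fe / se
  coefs <- tibble(
    component = "cond", term = names(fe), estimate = as.numeric(fe),
    se = as.numeric(se), z = as.numeric(tval),
    p = 2 * stats::pt(-abs(as.numeric(tval)), df = df)
  )
  vc <- lme4::VarCorr(fit)
  sigma_u <- attr(vc[[1]], "stddev")[[1]]
  ll <- as.numeric(logLik(fit))
  k <- p + 2L  # fixed effects + random-intercept variance + residual variance
  out <- list(
    coefficients = coefs, sigma_u = as.numeric(sigma_u),
    sigma = stats::sigma(fit), logLik = ll, k = k, n = n,
    AICc = .aicc(ll, k, n),
    singular = lme4::isSingular(fit), converged = TRUE,
    method = method, fit = fit,
    spec = list(formula = formula, group = group)
  )
  class(out) <- "pollenscape_lmm"
  out
}

#' @export
print.pollenscape_lmm <- function(x, ...) {
  cat(sprintf("Linear mixed model (%s), n = %d, logLik = %.3f, AICc = %.3f\n",
              x$method, x$n, x$logLik, x$AICc))
  if (x$singular) cat("  note: singular fit (random-intercept variance at 0)\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.pollenscape_lmm <- function(x, ...) x$coefficients

#' @export
glance.pollenscape_lmm <- function(x, ...) {
  tibble(logLik = x$logLik, AICc = x$AICc, k = x$k, n = x$n,
         sigma_u = x$sigma_u, sigma = x$sigma, singular = x$singular)
}
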