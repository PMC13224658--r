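# Zero-inflated Poisson / binomial mixed models with independent random
# intercepts (one per forest patch) in both the conditional and the
# zero-inflation component. The marginal likelihood integrates the two
# random effects per group by adaptive 2-D Gauss-Hermite quadrature.

# Internal model frame shared by the fitter and the likelihood evaluator.
.zi_frame <- function(data, response, cond, zi, family, trials, group) {
  family <- match.arg(family, c("poisson", "binomial"))
  y <- data[[response]]
  if (is.null(y)) abort(paste0("response column '", response, "' not found"))
  if (any(y < 0) || any(y != floor(y))) abort("response must be non-negative counts")
  size <- NULL
  if (family == "binomial") {
    if (is.null(trials)) abort("binomial family needs a 'trials' column")
    size <- data[[trials]]
    if (any(y > size)) abort("successes exceed trials")
  }
  X <- model.matrix(cond, data)
  Z <- model.matrix(zi, data)
  g <- as.factor(data[[group]])
  if (nlevels(g) < 2L) abort("need >= 2 groups for random intercepts")
  list(y = as.numeric(y), size = as.numeric(size), X = X, Z = Z,
       g = as.integer(g), levels = levels(g), family = family,
       n = length(y), p = ncol(X), q = ncol(Z))
}

# log f(y | eta + u) and its derivative d/d eta for the conditional family.
.cond_logpdf <- function(y, eta, size, family) {
  if (family == "poisson") dpois(y, exp(eta), log = TRUE)
  else dbinom(y, size, plogis(eta), log = TRUE)
}
.cond_score <- function(y, eta, size, family) {
  if (family == "poisson") y - exp(eta)
  else y - size * plogis(eta)
}

# Joint log-density h(u, v) of one group's data and random effects, plus
# its analytic gradient. eta0/zeta0 are the fixed-effect linear predictors.
.group_h <- function(u, v, y, eta0, zeta0, size, family, su, sv) {
  eta <- eta0 + u; zeta <- zeta0 + v
  lpi <- plogis(zeta, log.p = TRUE)
  l1m <- plogis(-zeta, log.p = TRUE)
  lf <- .cond_logpdf(y, eta, size, family)
  lm <- ifelse(y == 0, pmax(lpi, l1m + lf) +
                 log1p(exp(-abs(lpi - (l1m + lf)))), l1m + lf)
  sum(lm) - u^2 / (2 * su^2) - v^2 / (2 * sv^2) -
    log(2 * pi) - log(su) - log(sv)
}

.group_h_grad <- function(u, v, y, eta0, zeta0, size, family, su, sv) {
  eta <- eta0 + u; zeta <- zeta0 + v
  pi_ <- plogis(zeta)
  lpi <- plogis(zeta, log.p = TRUE)
  l1m <- plogis(-zeta, log.p = TRUE)
  lf <- .cond_logpdf(y, eta, size, family)
  lm <- ifelse(y == 0, pmax(lpi, l1m + lf) +
                 log1p(exp(-abs(lpi - (l1m + lf)))), l1m + lf)
  w_nz <- exp(l1m + lf - lm)          # posterior weight of the count component
  w_nz[!is.finite(w_nz)] <- 0
  s_z <- ifelse(y == 0, exp(lpi - lm), 0)
  s_z[!is.finite(s_z)] <- 0
  du <- sum(w_nz * .cond_score(y, eta, size, family)) - u / su^2
  dv <- sum(ifelse(y == 0, s_z * (1 - pi_) - w_nz * pi_, -pi_)) - v / sv^2
  c(du, dv)
}

# Newton mode-finding for one group; returns mode and negative Hessian.
.group_mode <- function(y, eta0, zeta0, size, family, su, sv, start = c(0, 0)) {
  uv <- start
  negH <- diag(c(1 / su^2, 1 / sv^2))  # prior curvature fallback
  for (it in 1:15) {
    gr <- .group_h_grad(uv[1], uv[2], y, eta0, zeta0, size, family, su, sv)
    if (!all(is.finite(gr))) break
    eps <- 1e-5
    g1 <- .group_h_grad(uv[1] + eps, uv[2], y, eta0, zeta0, size, family, su, sv)
    g2 <- .group_h_grad(uv[1], uv[2] + eps, y, eta0, zeta0, size, family, su, sv)
    H <- cbind((g1 - gr) / eps, (g2 - gr) / eps)
    H <- (H + t(H)) / 2
    negH <- -H
    # regularise to PD (closed-form 2x2 eigenvalue bound)
    tr <- negH[1, 1] + negH[2, 2]
    dt <- negH[1, 1] * negH[2, 2] - negH[1, 2] * negH[2, 1]
    ev_min <- tr / 2 - sqrt(max(tr^2 / 4 - dt, 0))
    if (!is.finite(ev_min)) break
    if (ev_min < 1e-8) negH <- negH + diag(1e-8 - ev_min, 2)
    dt <- negH[1, 1] * negH[2, 2] - negH[1, 2] * negH[2, 1]
    step <- c(negH[2, 2] * gr[1] - negH[1, 2] * gr[2],
              negH[1, 1] * gr[2] - negH[2, 1] * gr[1]) / dt
    slen <- sqrt(sum(step^2))
    if (!all(is.finite(step))) break
    if (slen > 10) step <- step * 10 / slen
    # damped step
    f0 <- .group_h(uv[1], uv[2], y, eta0, zeta0, size, family, su, sv)
    alpha <- 1
    repeat {
      cand <- uv + alpha * step
      f1 <- .group_h(cand[1], cand[2], y, eta0, zeta0, size, family, su, sv)
      if (is.finite(f1) && f1 >= f0 - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-6) { cand <- uv; break }
    }
    moved <- sqrt(sum((cand - uv)^2))
    uv <- cand
    if (max(abs(gr)) < 1e-8 || moved < 1e-10) break
  }
  list(mode = uv, negH = negH)
}

# Adaptive 2-D Gauss-Hermite log marginal likelihood of one group.
# The joint density is evaluated at all nodes in one vectorised pass.
.group_logLik <- function(y, eta0, zeta0, size, family, su, sv, rule,
                          start = c(0, 0), grad = FALSE) {
  md <- .group_mode(y, eta0, zeta0, size, family, su, sv, start)
  R <- tryCatch(chol(md$negH), error = function(e) NULL)
  if (is.null(R)) {  # fall back to prior-scaled quadrature
    A <- diag(c(su, sv))
    mode <- c(0, 0)
  } else {
    A <- backsolve(R, diag(2))
    mode <- md$mode
  }
  z <- rule$nodes; lw <- log(rule$weights)
  nn <- length(z)
  zu <- rep(z, times = nn); zv <- rep(z, each = nn)
  lws <- rep(lw, times = nn) + rep(lw, each = nn)
  u <- mode[1] + sqrt(2) * (A[1, 1] * zu + A[1, 2] * zv)
  v <- mode[2] + sqrt(2) * (A[2, 1] * zu + A[2, 2] * zv)
  n <- length(y); m <- length(u)
  eta <- matrix(eta0, n, m) + matrix(u, n, m, byrow = TRUE)
  zeta <- matrix(zeta0, n, m) + matrix(v, n, m, byrow = TRUE)
  lf <- if (family == "poisson") dpois(y, exp(eta), log = TRUE)
        else dbinom(y, size, plogis(eta), log = TRUE)
  l1m <- plogis(-zeta, log.p = TRUE)
  lm <- l1m + lf
  iz <- which(y == 0)
  if (length(iz)) {
    lpi <- plogis(zeta[iz, , drop = FALSE], log.p = TRUE)
    lb <- lm[iz, , drop = FALSE]
    lm[iz, ] <- pmax(lpi, lb) + log1p(exp(-abs(lpi - lb)))
  }
  hvals <- colSums(lm) - u^2 / (2 * su^2) - v^2 / (2 * sv^2) -
    log(2 * pi) - log(su) - log(sv)
  logint <- hvals + zu^2 + zv^2 + lws
  ll <- log(2) + log(abs(det(A))) + .logsumexp(logint)
  out <- list(ll = ll, mode = mode)
  if (grad) {
    pw <- exp(logint - max(logint)); pw <- pw / sum(pw)  # posterior node weights
    s <- if (family == "poisson") y - exp(eta) else y - size * plogis(eta)
    w_nz <- exp(l1m + lf - lm)
    pi_ <- plogis(zeta)
    q <- -pi_
    if (length(iz)) {
      s_z <- exp(lpi - lm[iz, , drop = FALSE])
      q[iz, ] <- s_z * (1 - pi_[iz, , drop = FALSE]) -
        w_nz[iz, , drop = FALSE] * pi_[iz, , drop = FALSE]
    }
    out$score_eta <- as.numeric((w_nz * s) %*% pw)   # per-obs cond score
    out$score_zeta <- as.numeric(q %*% pw)           # per-obs zi score
    out$score_logsu <- sum(pw * (u^2 / su^2 - 1))
    out$score_logsv <- sum(pw * (v^2 / sv^2 - 1))
  }
  out
}

#' Marginal log-likelihood of a zero-inflated GLMM at fixed parameters
#'
#' Evaluates, by adaptive 2-D Gauss-Hermite quadrature, the marginal
#' log-likelihood of the zero-inflated mixed model with independent
#' conditional and zero-inflation random intercepts per group.
#'
#' @param data Data frame.
#' @param response Name of the count response column.
#' @param cond,zi One-sided formulas for the conditional (log or logit
#'   link) and zero-inflation (logit link) fixed effects.
#' @param family `"poisson"` or `"binomial"`.
#' @param trials Name of the trials column (binomial only).
#' @param group Name of the grouping (forest patch) column.
#' @param beta,gamma Fixed-effect coefficient vectors (cond, zi), in
#'   `model.matrix` column order.
#' @param sigma_u,sigma_v Random-intercept standard deviations (cond, zi).
#' @param gh_nodes Quadrature nodes per dimension (default 9).
#' @return Log-likelihood (scalar).
#' @export
zi_glmm_marginal_loglik <- function(data, response, cond, zi,
                                    family = "poisson", trials = NULL,
                                    group = "patch_id",
                                    beta, gamma, sigma_u, sigma_v,
                                    gh_nodes = 9L) {
  fr <- .zi_frame(data, response, cond, zi, family, trials, group)
  rule <- .gh_rule(gh_nodes)
  eta0 <- as.numeric(fr$X %*% beta)
  zeta0 <- as.numeric(fr$Z %*% gamma)
  ll <- 0
  for (g in seq_along(fr$levels)) {
    ix <- fr$g == g
    res <- .group_logLik(fr$y[ix], eta0[ix], zeta0[ix], fr$size[ix],
                         fr$family, sigma_u, sigma_v, rule)
    ll <- ll + res$ll
  }
  ll
}

#' Fit a zero-inflated Poisson or binomial mixed model
#'
#' Maximises the adaptive Gauss-Hermite marginal likelihood over the
#' conditional coefficients, zero-inflation coefficients and the two
#' random-intercept standard deviations (one independent intercept per
#' group in each component). Standard errors come from the numerical
#' Hessian at the optimum. In the zero-inflation component a positive
#' coefficient means a higher probability of a structural zero.
#'
#' @inheritParams zi_glmm_marginal_loglik
#' @param gh_nodes Quadrature nodes per dimension (default 9).
#' @param max_starts Maximum optimiser starts (1 informed + random
#'   restarts, used only while unconverged; default 3).
#' @param seed Seed for restart jitter (default 1).
#' @return Object of class `pollenscape_ziglmm` with `coefficients`
#'   (tibble `component, term, estimate, se, z, p`), `sigma_u`, `sigma_v`,
#'   `logLik`, `k`, `n`, `AICc`, `converged`.
#' @export
fit_zi_glmm <- function(data, response, cond = ~1, zi = ~1,
                        family = "poisson", trials = NULL,
                        group = "patch_id", gh_nodes = 9L,
                        max_starts = 3L, seed = 1L) {
  fr <- .zi_frame(data, response, cond, zi, family, trials, group)
  rule <- .gh_rule(gh_nodes)
  G <- length(fr$levels)
  mode_cache <- matrix(0, G, 2)

  gix <- lapply(seq_len(G), function(g) which(fr$g == g))
  cache <- new.env(parent = emptyenv())

  eval_nll <- function(theta) {
    key <- paste(theta, collapse = ",")
    if (identical(cache$key, key)) return(cache$val)
    beta <- theta[seq_len(fr$p)]
    gamma <- theta[fr$p + seq_len(fr$q)]
    su <- exp(theta[fr$p + fr$q + 1L])
    sv <- exp(theta[fr$p + fr$q + 2L])
    eta0 <- as.numeric(fr$X %*% beta)
    zeta0 <- as.numeric(fr$Z %*% gamma)
    ll <- 0
    gr <- numeric(length(theta))
    for (g in seq_len(G)) {
      ix <- gix[[g]]
      res <- .group_logLik(fr$y[ix], eta0[ix], zeta0[ix], fr$size[ix],
                           fr$family, su, sv, rule, start = mode_cache[g, ],
                           grad = TRUE)
      mode_cache[g, ] <<- res$mode
      ll <- ll + res$ll
      gr[seq_len(fr$p)] <- gr[seq_len(fr$p)] +
        as.numeric(crossprod(fr$X[ix, , drop = FALSE], res$score_eta))
      gr[fr$p + seq_len(fr$q)] <- gr[fr$p + seq_len(fr$q)] +
        as.numeric(crossprod(fr$Z[ix, , drop = FALSE], res$score_zeta))
      gr[fr$p + fr$q + 1L] <- gr[fr$p + fr$q + 1L] + res$score_logsu
      gr[fr$p + fr$q + 2L] <- gr[fr$p + fr$q + 2L] + res$score_logsv
    }
    bad <- !is.finite(ll)
    cache$key <- key
    cache$val <- list(value = if (bad) 1e10 else -ll,
                      grad = if (bad) numeric(length(theta)) else -gr)
    cache$val
  }
  nll <- function(theta) eval_nll(theta)$value
  nll_grad <- function(theta) eval_nll(theta)$grad

  # informed start: ordinary GLM for the conditional part
  start_beta <- tryCatch({
    if (fr$family == "poisson") {
      coef(stats::glm.fit(fr$X, fr$y, family = stats::poisson()))
    } else {
      coef(stats::glm.fit(fr$X, fr$y / pmax(fr$size, 1),
                          weights = pmax(fr$size, 1),
                          family = stats::binomial()))
    }
  }, error = function(e) rep(0, fr$p))
  start_beta[!is.finite(start_beta)] <- 0
  p0 <- min(max(mean(fr$y == 0), 0.02), 0.98)
  start_gamma <- c(qlogis(p0), rep(0, fr$q - 1L))
  starts <- list(c(start_beta, start_gamma, log(0.3), log(0.3)))
  set.seed(.sub_seed(seed, "model"))
  for (s in seq_len(max_starts - 1L)) {
    starts[[s + 1L]] <- starts[[1L]] + rnorm(fr$p + fr$q + 2L, sd = 0.5)
  }

  lower <- c(rep(-20, fr$p + fr$q), -7, -7)
  upper <- c(rep(20, fr$p + fr$q), 3, 3)
  best <- NULL
  for (s in seq_len(max_starts)) {
    fit <- tryCatch(
      optim(starts[[s]], nll, nll_grad, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = 500, factr = 1e8)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    if (!is.null(best) && best$convergence == 0) break
  }
  if (is.null(best)) abort("zero-inflated GLMM optimisation failed")

  theta <- best$par
  # Hessian by central differences of the analytic gradient
  np <- length(theta)
  H <- matrix(0, np, np)
  hstep <- 1e-5 * (1 + abs(theta))
  for (i in seq_len(np)) {
    tp <- theta; tp[i] <- tp[i] + hstep[i]
    tm <- theta; tm[i] <- tm[i] - hstep[i]
    H[i, ] <- (nll_grad(tp) - nll_grad(tm)) / (2 * hstep[i])
  }
  H <- (H + t(H)) / 2
  vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, length(theta), length(theta)))
  se_all <- suppressWarnings(sqrt(pmax(diag(vc), 0)))
  se_all[!is.finite(se_all)] <- NA_real_

  est <- unname(theta[seq_len(fr$p + fr$q)])
  se <- se_all[seq_len(fr$p + fr$q)]
  zstat <- est / se
  coefs <- tibble(
    component = c(rep("cond", fr$p), rep("zi", fr$q)),
    term = c(colnames(fr$X), colnames(fr$Z)),
    estimate = est, se = se, z = zstat, p = 2 * pnorm(-abs(zstat))
  )
  k <- fr$p + fr$q + 2L
  ll <- -best$value
  out <- list(
    coefficients = coefs,
    sigma_u = exp(theta[fr$p + fr$q + 1L]),
    sigma_v = exp(theta[fr$p + fr$q + 2L]),
    logLik = ll, k = k, n = fr$n, AICc = .aicc(ll, k, fr$n),
    converged = best$convergence == 0,
    family = fr$family, theta = theta, vcov = vc,
    spec = list(response = response, cond = cond, zi = zi, trials = trials,
                group = group, gh_nodes = gh_nodes)
  )
  class(out) <- "pollenscape_ziglmm"
  out
}

#' @export
print.pollenscape_ziglmm <- function(x, ...) {
  cat(sprintf("Zero-inflated %s mixed model (adaptive GH, %d nodes/dim)\n",
              x$family, x$spec$gh_nodes))
  cat(sprintf("  n = %d, logLik = %.3f, AICc = %.3f, converged: %s\n",
              x$n, x$logLik, x$AICc, x$converged))
  cat(sprintf("  random-intercept SDs: cond %.3f, zi %.3f\n", x$sigma_u, x$sigma_v))
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.pollenscape_ziglmm <- function(x, ...) x$coefficients

#' @export
glance.pollenscape_ziglmm <- function(x, ...) {
  tibble(logLik = x$logLik, AICc = x$AICc, k = x$k, n = x$n,
         sigma_u = x$sigma_u, sigma_v = x$sigma_v, converged = x$converged)
}
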