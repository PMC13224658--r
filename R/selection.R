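# The three-step inference procedure over landscape metrics:
# (1) single-metric screening (p <= 0.15 per component, quadratic probe for
#     area metrics by AICc, orientation-interaction probe for linear
#     metrics), (2) collinearity filtering (|r| > 0.7 mutually exclusive),
# (3) all-subsets AICc selection (delta <= 2) with conditional model
#     averaging and unconditional standard errors.

#' Response/model specification for the selection machinery
#'
#' @param type `"zipoisson"` (counts), `"zibinomial"` (successes/trials) or
#'   `"lmm"` (Gaussian).
#' @param response Response column name.
#' @param trials Trials column (zibinomial only).
#' @param group Grouping column for random intercepts.
#' @param gh_nodes Quadrature nodes for the zero-inflated fits.
#' @return List of class `model_spec`.
#' @export
model_spec <- function(type = c("zipoisson", "zibinomial", "lmm"),
                       response, trials = NULL, group = "patch_id",
                       gh_nodes = 9L) {
  type <- match.arg(type)
  if (type == "zibinomial" && is.null(trials)) abort("zibinomial needs 'trials'")
  structure(list(type = type, response = response, trials = trials,
                 group = group, gh_nodes = as.integer(gh_nodes)),
            class = "model_spec")
}

.reformulate_rhs <- function(terms) {
  if (length(terms) == 0L) ~1 else stats::as.formula(paste("~", paste(terms, collapse = " + ")))
}

# Fit one candidate model; unified surface over the three families.
.fit_candidate <- function(data, spec, cond_terms, zi_terms = character(0),
                           method = "ML") {
  if (spec$type == "lmm") {
    f <- stats::as.formula(paste(spec$response, "~",
                                 if (length(cond_terms)) paste(cond_terms, collapse = " + ") else "1"))
    fit <- tryCatch(fit_lmm(f, data, group = spec$group, method = method),
                    error = function(e) NULL)
  } else {
    fam <- if (spec$type == "zipoisson") "poisson" else "binomial"
    fit <- tryCatch(
      fit_zi_glmm(data, spec$response,
                  cond = .reformulate_rhs(cond_terms),
                  zi = .reformulate_rhs(zi_terms),
                  family = fam, trials = spec$trials, group = spec$group,
                  gh_nodes = spec$gh_nodes),
      error = function(e) NULL
    )
  }
  if (is.null(fit) || !isTRUE(fit$converged)) return(NULL)
  fit
}

# p-value of a term in a given component of a fitted candidate.
.term_p <- function(fit, component, term) {
  cc <- fit$coefficients
  row <- cc[cc$component == component & cc$term == term, ]
  if (nrow(row) == 0L) return(NA_real_)
  row$p[1]
}

#' Single-metric screening of landscape metrics
#'
#' Fits one model per metric (and, for zero-inflated families, separately
#' per component) and retains metrics whose Wald p-value is at most
#' `alpha`. Area-based metrics are additionally probed with a quadratic
#' term, kept when it lowers the AICc; linear-element metrics are probed
#' for an interaction with the orthogonal-to-parallel ratio of their own
#' type (kept at p <= `alpha`).
#'
#' @param data Data frame of transformed, standardised metrics plus the
#'   response columns.
#' @param metrics Character vector of metric columns to screen.
#' @param spec A [model_spec()].
#' @param alpha Retention threshold on the Wald p-value (default 0.15).
#' @param area_metrics Subset of `metrics` probed for quadratic terms.
#' @param op_map Named character vector mapping a linear-element metric to
#'   its orientation-ratio column (e.g. `c(L_WATER = "OP_WATER")`).
#' @return Tibble `metric, component, term, term_type, p, delta_aicc,
#'   keep`; skipped (non-convergent) metrics appear with `keep = NA`.
#' @export
screen_metrics <- function(data, metrics, spec, alpha = 0.15,
                           area_metrics = character(0), op_map = NULL) {
  components <- if (spec$type == "lmm") "cond" else c("cond", "zi")
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- tibble(...)
  for (m in metrics) {
    for (comp in components) {
      ct <- if (comp == "cond") m else character(0)
      zt <- if (comp == "zi") m else character(0)
      f1 <- .fit_candidate(data, spec, ct, zt)
      if (is.null(f1)) {
        add(metric = m, component = comp, term = m, term_type = "linear",
            p = NA_real_, delta_aicc = NA_real_, keep = NA)
        next
      }
      p1 <- .term_p(f1, comp, m)
      add(metric = m, component = comp, term = m, term_type = "linear",
          p = p1, delta_aicc = NA_real_, keep = !is.na(p1) && p1 <= alpha)
      if (m %in% area_metrics) {
        q <- paste0("I(", m, "^2)")
        f2 <- .fit_candidate(data, spec,
                             if (comp == "cond") c(m, q) else character(0),
                             if (comp == "zi") c(m, q) else character(0))
        if (!is.null(f2)) {
          d <- f2$AICc - f1$AICc
          add(metric = m, component = comp, term = q, term_type = "quadratic",
              p = .term_p(f2, comp, q), delta_aicc = d, keep = d < 0)
        }
      }
      if (!is.null(op_map) && m %in% names(op_map)) {
        op <- op_map[[m]]
        if (op %in% names(data) && isTRUE(sd(data[[op]], na.rm = TRUE) > 0)) {
          int <- paste0(m, ":", op)
          terms3 <- c(m, op, int)
          dd <- data[!is.na(data[[op]]), , drop = FALSE]
          f3 <- .fit_candidate(dd, spec,
                               if (comp == "cond") terms3 else character(0),
                               if (comp == "zi") terms3 else character(0))
          if (!is.null(f3)) {
            p3 <- .term_p(f3, comp, int)
            add(metric = m, component = comp, term = int, term_type = "interaction",
                p = p3, delta_aicc = NA_real_, keep = !is.na(p3) && p3 <= alpha)
          }
        }
      }
    }
  }
  bind_rows(rows)
}

#' Pairwise collinearity constraints among candidate metrics
#'
#' @param data Data frame of transformed metrics.
#' @param candidates Character vector of metric columns.
#' @param r_max Absolute Pearson correlation above which two metrics may
#'   not enter the same model (default 0.7).
#' @return Tibble `metric1, metric2, r, excluded`.
#' @export
collinearity_filter <- function(data, candidates, r_max = 0.7) {
  if (length(candidates) < 2L) {
    return(tibble(metric1 = character(), metric2 = character(),
                  r = numeric(), excluded = logical()))
  }
  cm <- stats::cor(data[, candidates], use = "pairwise.complete.obs")
  out <- list()
  for (i in seq_len(length(candidates) - 1L)) {
    for (j in (i + 1L):length(candidates)) {
      r <- cm[i, j]
      out[[length(out) + 1L]] <- tibble(
        metric1 = candidates[i], metric2 = candidates[j],
        r = r, excluded = is.finite(r) && abs(r) > r_max
      )
    }
  }
  bind_rows(out)
}

# Build the toggleable model units from a screening result.
.build_units <- function(screen) {
  kept <- screen[!is.na(screen$keep) & screen$keep, ]
  units <- list()
  for (i in seq_len(nrow(kept))) {
    row <- kept[i, ]
    requires <- switch(row$term_type,
      linear = character(0),
      quadratic = row$metric,
      interaction = {
        mains <- strsplit(row$term, ":", fixed = TRUE)[[1]]
        mains
      }
    )
    units[[length(units) + 1L]] <- list(
      component = row$component, term = row$term, metric = row$metric,
      term_type = row$term_type, requires = requires
    )
  }
  # interaction terms need their O:P main effect available as a unit
  have <- vapply(units, function(u) paste(u$component, u$term), character(1))
  for (u in units) {
    if (u$term_type == "interaction") {
      for (req in u$requires) {
        key <- paste(u$component, req)
        if (!key %in% have) {
          units[[length(units) + 1L]] <- list(
            component = u$component, term = req, metric = req,
            term_type = "linear", requires = character(0)
          )
          have <- c(have, key)
        }
      }
    }
  }
  units
}

#' All-subsets AICc selection and conditional model averaging
#'
#' Enumerates every subset of the candidate terms that respects marginality
#' (quadratic and interaction terms only with their main effects, within
#' the same component) and the collinearity exclusions, fits each by
#' maximum likelihood, keeps models with `AICc - min(AICc) <= delta_max`,
#' forms Akaike weights over the kept set, and conditionally averages each
#' term over the kept models containing it with unconditional standard
#' errors (Burnham-Anderson). Gaussian mixed models are refitted by REML
#' before averaging.
#'
#' @param data Data frame.
#' @param spec A [model_spec()].
#' @param screen Output of [screen_metrics()] (or a compatible tibble of
#'   kept terms).
#' @param exclusions Output of [collinearity_filter()] (may be empty).
#' @param delta_max AICc window for the candidate set (default 2).
#' @param max_units Guard on the number of toggleable terms (default 12).
#' @return Object of class `pollenscape_avg`: `selection` (per-model
#'   tibble `model_id, terms, logLik, k, AICc, delta, weight, kept`) and
#'   `coefficients` (tibble `component, term, estimate, se, ci_low,
#'   ci_high, n_models`).
#' @export
all_subsets_average <- function(data, spec, screen, exclusions = NULL,
                                delta_max = 2, max_units = 12L) {
  units <- .build_units(screen)
  if (length(units) > max_units) {
    abort(sprintf("%d candidate terms exceed the max_units guard (%d)",
                  length(units), max_units))
  }
  excl_pairs <- if (!is.null(exclusions) && nrow(exclusions)) {
    ex <- exclusions[exclusions$excluded, , drop = FALSE]
    lapply(seq_len(nrow(ex)), function(i) c(ex$metric1[i], ex$metric2[i]))
  } else list()

  n_units <- length(units)
  unit_comp <- vapply(units, `[[`, character(1), "component")
  unit_term <- vapply(units, `[[`, character(1), "term")
  unit_metric <- vapply(units, `[[`, character(1), "metric")

  admissible <- function(sel) {
    if (!any(sel)) return(TRUE)
    for (i in which(sel)) {
      req <- units[[i]]$requires
      if (length(req)) {
        ok <- vapply(req, function(r) {
          any(sel & unit_comp == unit_comp[i] & unit_term == r)
        }, logical(1))
        if (!all(ok)) return(FALSE)
      }
    }
    metrics_in <- unique(unit_metric[sel])
    for (pr in excl_pairs) {
      if (all(pr %in% metrics_in)) return(FALSE)
    }
    TRUE
  }

  subsets <- list()
  for (mask in 0:(2^n_units - 1)) {
    sel <- as.logical(bitwAnd(mask, bitwShiftL(1L, seq_len(n_units) - 1L)) > 0)
    if (length(sel) == 0L) sel <- logical(0)
    if (admissible(sel)) subsets[[length(subsets) + 1L]] <- sel
  }

  fits <- list(); rows <- list()
  for (mid in seq_along(subsets)) {
    sel <- subsets[[mid]]
    ct <- unit_term[sel & unit_comp == "cond"]
    zt <- unit_term[sel & unit_comp == "zi"]
    fit <- .fit_candidate(data, spec, ct, zt, method = "ML")
    if (is.null(fit)) next
    fits[[length(fits) + 1L]] <- list(sel = sel, fit = fit, ct = ct, zt = zt)
    rows[[length(rows) + 1L]] <- tibble(
      model_id = length(fits),
      terms = paste(c(if (length(ct)) paste0("cond:", ct),
                      if (length(zt)) paste0("zi:", zt)), collapse = " + "),
      logLik = fit$logLik, k = fit$k, AICc = fit$AICc
    )
  }
  if (length(fits) == 0L) abort("no candidate model converged")
  selection <- bind_rows(rows)
  selection$delta <- selection$AICc - min(selection$AICc)
  selection$kept <- selection$delta <= delta_max
  w <- exp(-selection$delta / 2) * selection$kept
  selection$weight <- ifelse(selection$kept, w / sum(w), 0)

  kept_ids <- selection$model_id[selection$kept]
  kept_fits <- fits[kept_ids]
  kept_w <- selection$weight[selection$kept]
  if (spec$type == "lmm") {
    kept_fits <- lapply(kept_fits, function(f) {
      refit <- .fit_candidate(data, spec, f$ct, f$zt, method = "REML")
      if (!is.null(refit)) f$fit <- refit
      f
    })
  }

  all_terms <- distinct(bind_rows(lapply(kept_fits, function(f) {
    f$fit$coefficients[, c("component", "term")]
  })))
  avg <- lapply(seq_len(nrow(all_terms)), function(i) {
    comp <- all_terms$component[i]; trm <- all_terms$term[i]
    est <- c(); ses <- c(); ws <- c()
    for (j in seq_along(kept_fits)) {
      cc <- kept_fits[[j]]$fit$coefficients
      row <- cc[cc$component == comp & cc$term == trm, ]
      if (nrow(row)) {
        est <- c(est, row$estimate[1]); ses <- c(ses, row$se[1]); ws <- c(ws, kept_w[j])
      }
    }
    wn <- ws / sum(ws)
    b <- sum(wn * est)
    se_u <- sum(wn * sqrt(ses^2 + (est - b)^2))
    tibble(component = comp, term = trm, estimate = b, se = se_u,
           ci_low = b - 1.96 * se_u, ci_high = b + 1.96 * se_u,
           n_models = length(est))
  })
  out <- list(selection = selection, coefficients = bind_rows(avg),
              spec = spec, delta_max = delta_max)
  class(out) <- "pollenscape_avg"
  out
}

#' @export
print.pollenscape_avg <- function(x, ...) {
  cat(sprintf("Conditional model average over %d of %d candidate models (dAICc <= %g)\n",
              sum(x$selection$kept), nrow(x$selection), x$delta_max))
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.pollenscape_avg <- function(x, ...) x$coefficients

#' @export
glance.pollenscape_avg <- function(x, ...) {
  tibble(n_models = nrow(x$selection), n_kept = sum(x$selection$kept),
         best_aicc = min(x$selection$AICc), delta_max = x$delta_max)
}
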