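# Error-tolerant Mendelian paternity: per-patch candidate sets, annealed
# stochastic configuration search, multi-run consensus.

#' Paternity-search configuration
#'
#' @param error_rate Per-locus genotyping error probability (default 0.012,
#'   matching per-locus error rates of up to ~1.2% typical of repeat-based
#'   genotyping).
#' @param p_sampled Prior probability that an offspring's true father is in
#'   the candidate set (spread uniformly over candidates); default 0.5.
#' @param n_runs Number of independent search runs (default 5).
#' @param min_support Minimum number of runs in which an offspring-donor
#'   pair must appear to be accepted (default 2).
#' @param n_sweeps,t0,cooling Annealing schedule: number of sweeps, initial
#'   temperature and geometric cooling factor per sweep.
#' @param selfing_allowed If `FALSE` (default), a candidate whose MLG equals
#'   the mother's (including the mother herself) is excluded.
#' @param max_mismatch Mother-offspring mismatch tolerance passed to
#'   [resolve_mother_mismatches()].
#' @param seed Master seed; run r uses `seed + r - 1`.
#' @return A list of class `paternity_config`.
#' @export
paternity_config <- function(error_rate = 0.012, p_sampled = 0.5,
                             n_runs = 5L, min_support = 2L,
                             n_sweeps = 200L, t0 = 2.0, cooling = 0.95,
                             selfing_allowed = FALSE, max_mismatch = 1L,
                             seed = 1L) {
  stopifnot(error_rate >= 0, error_rate < 0.5, p_sampled > 0, p_sampled < 1,
            min_support <= n_runs, n_sweeps >= 1, t0 > 0, cooling > 0, cooling <= 1)
  structure(
    list(error_rate = error_rate, p_sampled = p_sampled, n_runs = as.integer(n_runs),
         min_support = as.integer(min_support), n_sweeps = as.integer(n_sweeps),
         t0 = t0, cooling = cooling, selfing_allowed = selfing_allowed,
         max_mismatch = as.integer(max_mismatch), seed = as.integer(seed)),
    class = "paternity_config"
  )
}

#' Mendelian transmission probability at one locus
#'
#' Probability of the offspring's unordered allele pair given one allele
#' drawn uniformly from each parent.
#'
#' @param g_off,g_mother,g_father Length-2 vectors of allele codes (> 0).
#' @return Probability in \[0, 1\].
#' @export
transmission_prob <- function(g_off, g_mother, g_father) {
  o1 <- min(g_off); o2 <- max(g_off)
  p <- 0
  for (m in g_mother) for (f in g_father) {
    if (min(m, f) == o1 && max(m, f) == o2) p <- p + 0.25
  }
  p
}

#' Offspring likelihood with an unsampled father
#'
#' The paternal allele is integrated over Hardy-Weinberg population allele
#' frequencies: sum over maternal alleles m (probability 1/2 each) of the
#' frequency of the paternal allele required to complete the offspring pair.
#'
#' @param g_off,g_mother Length-2 allele vectors.
#' @param freqs Named numeric vector of allele frequencies at the locus
#'   (names = allele codes).
#' @return Probability in \[0, 1\].
#' @export
offspring_lik_unsampled <- function(g_off, g_mother, freqs) {
  o1 <- min(g_off); o2 <- max(g_off)
  p <- 0
  for (m in g_mother) {
    if (m == o1) {
      p <- p + 0.5 * (freqs[as.character(o2)] %||% 0)
    } else if (m == o2) {
      p <- p + 0.5 * (freqs[as.character(o1)] %||% 0)
    }
  }
  as.numeric(ifelse(is.na(p), 0, p))
}

# Hardy-Weinberg genotype probability of an unordered pair.
.p_hwe <- function(g_off, freqs) {
  p1 <- freqs[as.character(g_off[1])] %||% 0
  p2 <- freqs[as.character(g_off[2])] %||% 0
  p1 <- ifelse(is.na(p1), 0, p1); p2 <- ifelse(is.na(p2), 0, p2)
  as.numeric(if (g_off[1] == g_off[2]) p1^2 else 2 * p1 * p2)
}

#' Trio log-likelihood over loci with a genotyping-error mixture
#'
#' Per typed locus the likelihood is `(1 - e) * T + e * P_HWE(g_off)` where
#' `T` is the Mendelian transmission probability (father given) or the
#' HWE-integrated offspring likelihood (father unsampled); loci missing in
#' any participant are skipped. `-Inf` is returned for configurations that
#' are impossible at `e = 0`.
#'
#' @param offspring,mother One-row allele tables (or rows of one).
#' @param father One-row allele table, or `NULL` for an unsampled father.
#' @param freqs Allele frequencies as returned by [allele_frequencies()].
#' @param error_rate Per-locus genotyping error probability.
#' @return Log-likelihood (may be `-Inf`).
#' @export
pair_loglik <- function(offspring, mother, father, freqs, error_rate = 0.012) {
  loci <- locus_names(offspring)
  fl <- .freq_list(freqs)
  ll <- 0
  for (loc in loci) {
    o <- as.numeric(offspring[1, paste0(loc, c("_1", "_2"))])
    m <- as.numeric(mother[1, paste0(loc, c("_1", "_2"))])
    if (any(o == 0) || any(m == 0)) next
    f <- fl[[loc]]
    if (is.null(father)) {
      t_prob <- offspring_lik_unsampled(o, m, f)
    } else {
      fa <- as.numeric(father[1, paste0(loc, c("_1", "_2"))])
      if (any(fa == 0)) next
      t_prob <- transmission_prob(o, m, fa)
    }
    ll <- ll + log((1 - error_rate) * t_prob + error_rate * .p_hwe(o, f))
  }
  ll
}

# Frequency lookup with a floor for alleles unseen at the locus (half the
# smallest observed frequency), so immigrant paternal alleles keep the
# unsampled-father likelihood finite.
.freq_floor <- function(fv) min(fv) / 2

.lookup_freq <- function(fv, alleles, floor_val = .freq_floor(fv)) {
  p <- fv[as.character(alleles)]
  p[is.na(p)] <- floor_val
  as.numeric(p)
}

# Log-likelihood matrix for one patch: rows = offspring, columns = candidates
# plus a final UNSAMPLED column. Vectorised over candidates per locus.
.loglik_matrix <- function(off_gs, mother_rows, cand_gs, freqs, cfg) {
  loci <- locus_names(off_gs)
  fl <- .freq_list(freqs)
  n_off <- nrow(off_gs); n_cand <- nrow(cand_gs)
  e <- cfg$error_rate
  ll <- matrix(0, n_off, n_cand + 1L)
  for (loc in loci) {
    om <- .locus_mat(off_gs, loc)
    mm <- .locus_mat(mother_rows, loc)
    cm <- if (n_cand) .locus_mat(cand_gs, loc) else matrix(0, 0, 2)
    f <- fl[[loc]]
    fa1 <- cm[, 1]; fa2 <- cm[, 2]
    cand_typed <- fa1 > 0 & fa2 > 0
    for (i in seq_len(n_off)) {
      o <- om[i, ]; m <- mm[i, ]
      if (any(o == 0) || any(m == 0)) next
      o1 <- min(o); o2 <- max(o)
      floor_val <- .freq_floor(f)
      p1 <- .lookup_freq(f, o1, floor_val); p2 <- .lookup_freq(f, o2, floor_val)
      phwe <- if (o1 == o2) p1^2 else 2 * p1 * p2
      if (n_cand) {
        # w(a) = 0.5 * sum_m I({m, a} == {o1, o2}); T = 0.5 * (w(f1) + w(f2))
        wfun <- function(a) {
          0.5 * ((pmin(m[1], a) == o1 & pmax(m[1], a) == o2) +
                 (pmin(m[2], a) == o1 & pmax(m[2], a) == o2))
        }
        t_vec <- 0.5 * (wfun(fa1) + wfun(fa2))
        contrib <- log((1 - e) * t_vec + e * phwe)
        contrib[!cand_typed] <- 0  # locus skipped for untyped candidates
        ll[i, seq_len(n_cand)] <- ll[i, seq_len(n_cand)] + contrib
      }
      t_un <- 0
      if (m[1] %in% c(o1, o2)) t_un <- t_un + 0.5 * .lookup_freq(f, o1 + o2 - m[1], floor_val)
      if (m[2] %in% c(o1, o2)) t_un <- t_un + 0.5 * .lookup_freq(f, o1 + o2 - m[2], floor_val)
      ll[i, n_cand + 1L] <- ll[i, n_cand + 1L] + log((1 - e) * t_un + e * phwe)
    }
  }
  if (!cfg$selfing_allowed && n_cand) {
    mother_keys <- mlg_key(mother_rows)
    cand_keys <- mlg_key(cand_gs)
    for (i in seq_len(n_off)) {
      selfing <- cand_keys == mother_keys[i] | cand_gs$sample_id == mother_rows$sample_id[i]
      ll[i, which(selfing)] <- -Inf
    }
  }
  ll
}

# Log-posterior matrix: adds the sampled-father prior (p_sampled spread
# uniformly over candidates) and log(1 - p_sampled) on the UNSAMPLED column.
.logpost_matrix <- function(ll, cfg) {
  n_cand <- ncol(ll) - 1L
  lp <- ll
  if (n_cand > 0L) lp[, seq_len(n_cand)] <- lp[, seq_len(n_cand)] + log(cfg$p_sampled / n_cand)
  lp[, n_cand + 1L] <- lp[, n_cand + 1L] + log(1 - cfg$p_sampled)
  lp
}

# Annealed heat-bath search over per-offspring father labels. Each sweep
# redraws every label from its tempered conditional posterior (a proposal
# from the conditional posterior is always accepted under Metropolis);
# the best joint configuration visited is returned.
.anneal_core <- function(logpost, cfg, seed) {
  set.seed(seed)
  n_off <- nrow(logpost); n_lab <- ncol(logpost)
  if (n_off == 0L) return(list(labels = integer(0), loglik = 0))
  labels <- max.col(logpost + matrix(-log(-log(runif(n_off * n_lab))), n_off, n_lab),
                    ties.method = "first")
  score <- sum(logpost[cbind(seq_len(n_off), labels)])
  best_labels <- labels; best_score <- score
  temp <- cfg$t0
  for (s in seq_len(cfg$n_sweeps)) {
    gumbel <- matrix(-log(-log(runif(n_off * n_lab))), n_off, n_lab)
    labels <- max.col(logpost / temp + gumbel, ties.method = "first")
    score <- sum(logpost[cbind(seq_len(n_off), labels)])
    if (score > best_score) { best_score <- score; best_labels <- labels }
    temp <- temp * cfg$cooling
  }
  list(labels = best_labels, loglik = best_score)
}

#' One stochastic paternity search run for a patch
#'
#' Maximises the joint posterior over per-offspring father labels (each
#' candidate of the patch, or UNSAMPLED) by simulated annealing with
#' heat-bath updates drawn from each offspring's tempered conditional
#' posterior. Deterministic given `seed`.
#'
#' @param offspring Allele-table rows of the patch's offspring (mothers
#'   already resolved via [resolve_mother_mismatches()]).
#' @param mothers Allele-table rows aligned with `offspring` (row i is the
#'   mother of offspring i).
#' @param candidates Allele-table rows of the patch's candidate donors.
#' @param freqs Allele frequencies ([allele_frequencies()] output).
#' @param config A [paternity_config()].
#' @param seed Integer seed for this run.
#' @return List with `seed`, `assignment` (tibble `offspring_id, donor_id`
#'   with `NA` = UNASSIGNED) and `loglik` of the best configuration.
#' @export
anneal_run <- function(offspring, mothers, candidates, freqs, config, seed) {
  ll <- .loglik_matrix(offspring, mothers, candidates, freqs, config)
  lp <- .logpost_matrix(ll, config)
  res <- .anneal_core(lp, config, seed)
  n_cand <- nrow(candidates)
  donor <- ifelse(res$labels > n_cand, NA_character_, candidates$sample_id[res$labels])
  list(
    seed = seed,
    assignment = tibble(offspring_id = offspring$sample_id, donor_id = donor),
    loglik = res$loglik
  )
}

#' Consensus over repeated paternity runs
#'
#' An offspring-donor pair is accepted when it appears in at least
#' `min_support` runs and has strictly maximal support among that
#' offspring's donors; ties yield UNASSIGNED.
#'
#' @param runs List of run results from [anneal_run()].
#' @param config A [paternity_config()] (supplies `n_runs`, `min_support`).
#' @return Tibble `offspring_id, donor_id, support, status` with status
#'   `assigned`, `unassigned` or `tie`.
#' @export
consensus_paternity <- function(runs, config) {
  if (length(runs) != config$n_runs) {
    abort(sprintf("expected %d runs, got %d", config$n_runs, length(runs)))
  }
  all_runs <- bind_rows(lapply(seq_along(runs), function(r) {
    mutate(runs[[r]]$assignment, run = r)
  }))
  per_off <- split(all_runs, all_runs$offspring_id)
  out <- lapply(per_off, function(d) {
    donors <- d$donor_id[!is.na(d$donor_id)]
    n_un <- sum(is.na(d$donor_id))
    if (length(donors) == 0L) {
      return(tibble(offspring_id = d$offspring_id[1], donor_id = NA_character_,
                    support = n_un, status = "unassigned"))
    }
    tb <- sort(table(donors), decreasing = TRUE)
    top <- as.integer(tb[1])
    if (top < config$min_support) {
      return(tibble(offspring_id = d$offspring_id[1], donor_id = NA_character_,
                    support = n_un, status = "unassigned"))
    }
    if (sum(tb == top) > 1L) {
      return(tibble(offspring_id = d$offspring_id[1], donor_id = NA_character_,
                    support = top, status = "tie"))
    }
    tibble(offspring_id = d$offspring_id[1], donor_id = names(tb)[1],
           support = top, status = "assigned")
  })
  arrange(bind_rows(out), .data$offspring_id)
}

#' Consensus paternity assignment for a whole study
#'
#' Runs the full per-patch procedure: mother-offspring mismatch resolution,
#' per-patch candidate sets (all adults of the patch, receptors included),
#' per-patch allele frequencies, `n_runs` annealed searches with seeds
#' `seed + 0 .. n_runs - 1`, and the >= `min_support` consensus rule.
#' Offspring flagged incompatible with their mother are excluded and
#' reported with status `incompatible`.
#'
#' @param genotypes A deduplicated allele table.
#' @param config A [paternity_config()].
#' @return List of class `paternity_result`: `consensus` (tibble
#'   `offspring_id, patch_id, mother_id, donor_id, support, status`),
#'   `runs` (per-patch list of run summaries), `mismatch_log`.
#' @export
assign_paternity <- function(genotypes, config = paternity_config()) {
  res <- resolve_mother_mismatches(genotypes, config$max_mismatch)
  gs <- res$genotypes
  incompat <- res$log$offspring_id[res$log$status == "incompatible"]
  # study-wide adult frequencies: the HWE background for unsampled fathers,
  # which includes immigrant pollen sources outside the focal patch
  freqs <- allele_frequencies(filter(gs, .data$role != "offspring"))
  out <- list(); run_log <- list()
  for (patch in sort(unique(gs$patch_id[gs$role == "offspring"]))) {
    off <- filter(gs, .data$role == "offspring", .data$patch_id == patch,
                  !.data$sample_id %in% incompat)
    if (nrow(off) == 0L) next
    cands <- filter(gs, .data$role != "offspring", .data$patch_id == patch)
    mothers <- gs[match(off$mother_id, gs$sample_id), ]
    if (nrow(cands) == 0L) {
      out[[patch]] <- tibble(offspring_id = off$sample_id, patch_id = patch,
                             mother_id = off$mother_id, donor_id = NA_character_,
                             support = config$n_runs, status = "unassigned")
      next
    }
    runs <- lapply(seq_len(config$n_runs) - 1L, function(r) {
      anneal_run(off, mothers, cands, freqs, config, seed = config$seed + r)
    })
    run_log[[patch]] <- tibble(
      patch_id = patch,
      run = seq_len(config$n_runs),
      seed = vapply(runs, function(x) x$seed, numeric(1)),
      loglik = vapply(runs, function(x) x$loglik, numeric(1))
    )
    cons <- consensus_paternity(runs, config)
    out[[patch]] <- cons %>%
      mutate(patch_id = patch,
             mother_id = off$mother_id[match(.data$offspring_id, off$sample_id)]) %>%
      select("offspring_id", "patch_id", "mother_id", "donor_id", "support", "status")
  }
  empty <- tibble(offspring_id = character(), patch_id = character(),
                  mother_id = character(), donor_id = character(),
                  support = integer(), status = character())
  consensus <- bind_rows(c(list(empty), unname(out)))
  if (length(incompat)) {
    inc_rows <- gs[match(incompat, gs$sample_id), ]
    consensus <- bind_rows(consensus, tibble(
      offspring_id = incompat, patch_id = inc_rows$patch_id,
      mother_id = inc_rows$mother_id, donor_id = NA_character_,
      support = 0L, status = "incompatible"
    ))
  }
  structure(
    list(consensus = arrange(consensus, .data$patch_id, .data$offspring_id),
         runs = run_log, mismatch_log = res$log, config = config),
    class = "paternity_result"
  )
}

#' @export
print.paternity_result <- function(x, ...) {
  cat("Consensus paternity:", nrow(x$consensus), "offspring;",
      sum(x$consensus$status == "assigned"), "assigned,",
      sum(x$consensus$status != "assigned"), "unassigned\n")
  invisible(x)
}

#' @export
tidy.paternity_result <- function(x, ...) x$consensus

#' @export
glance.paternity_result <- function(x, ...) {
  tibble(
    n_offspring = nrow(x$consensus),
    n_assigned = sum(x$consensus$status == "assigned"),
    prop_assigned = mean(x$consensus$status == "assigned"),
    n_incompatible = sum(x$consensus$status == "incompatible"),
    n_patches = length(unique(x$consensus$patch_id))
  )
}
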