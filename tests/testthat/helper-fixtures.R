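# Shared fixture builders: everything is generated in code at test time.

# Build an allele-table row list for tibble construction.
gt_row <- function(sample_id, role, patch = "F01", cluster = NA, mother = NA,
                   x = NA_real_, y = NA_real_, ...) {
  geno <- list(...)
  c(list(sample_id = sample_id, role = role, patch_id = patch,
         cluster_id = cluster, mother_id = mother, x = x, y = y), geno)
}

# Tiny two-locus allele table used across the genotype tests.
toy_genotypes <- function() {
  tibble::tibble(
    sample_id = c("A1", "A2", "R1", "R2", "O1", "O2"),
    role = c("donor", "donor", "receptor", "receptor", "offspring", "offspring"),
    patch_id = "F01",
    cluster_id = c("C1", "C2", "C3", "C4", NA, NA),
    mother_id = c(NA, NA, NA, NA, "R1", "R1"),
    x = c(0, 10, 20, 30, NA, NA), y = c(0, 0, 0, 0, NA, NA),
    LA_1 = c(101L, 101L, 103L, 101L, 101L, 103L),
    LA_2 = c(103L, 103L, 105L, 105L, 103L, 105L),
    LB_1 = c(200L, 200L, 202L, 204L, 200L, 202L),
    LB_2 = c(202L, 202L, 204L, 206L, 202L, 204L)
  )
}

# Random allele table of adults for MLG property tests; duplicates are
# created by copying rows, missing loci injected at the given rate.
random_genotype_set <- function(n, n_loci = 3, n_alleles = 4, dup_frac = 0.2,
                                missing_rate = 0, seed = 1) {
  set.seed(seed)
  base <- tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    role = sample(c("donor", "receptor"), n, replace = TRUE, prob = c(0.8, 0.2)),
    patch_id = "F01",
    cluster_id = sprintf("C%03d", seq_len(n)),
    mother_id = NA_character_, x = runif(n), y = runif(n)
  )
  for (l in seq_len(n_loci)) {
    a <- sample(100L + 2L * seq_len(n_alleles), 2 * n, replace = TRUE)
    m <- matrix(a, n, 2)
    base[[sprintf("L%02d_1", l)]] <- pmin(m[, 1], m[, 2])
    base[[sprintf("L%02d_2", l)]] <- pmax(m[, 1], m[, 2])
  }
  n_dup <- floor(n * dup_frac)
  if (n_dup > 0) {
    src <- sample(n, n_dup, replace = TRUE)
    for (k in seq_along(src)) {
      i <- src[k]
      base[n - n_dup + k, -1] <- base[i, -1]
      base$cluster_id[n - n_dup + k] <- sprintf("C%03d", n - n_dup + k)
    }
  }
  if (missing_rate > 0) {
    for (l in seq_len(n_loci)) {
      hit <- runif(n) < missing_rate
      base[[sprintf("L%02d_1", l)]][hit] <- 0L
      base[[sprintf("L%02d_2", l)]][hit] <- 0L
    }
  }
  base
}

# Brute-force O(n^2) repeated-MLG oracle over pairwise comparisons.
oracle_repeated_groups <- function(gs, policy = "strict") {
  loci <- locus_names(gs)
  n <- nrow(gs)
  pair_mat <- lapply(loci, function(l) {
    cbind(gs[[paste0(l, "_1")]], gs[[paste0(l, "_2")]])
  })
  match_fun <- function(i, j) {
    any_shared <- FALSE
    for (m in pair_mat) {
      ti <- all(m[i, ] > 0); tj <- all(m[j, ] > 0)
      pi <- sort(m[i, ]); pj <- sort(m[j, ])
      if (policy == "strict") {
        if (!identical(pi, pj)) return(FALSE)
      } else {
        if (ti && tj) {
          if (!identical(pi, pj)) return(FALSE)
          any_shared <- TRUE
        }
      }
    }
    if (policy == "tolerant") any_shared else TRUE
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (match_fun(i, j)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  grp <- split(gs$sample_id, roots)
  grp <- grp[lengths(grp) >= 2]
  unname(lapply(grp, sort))
}

# Small random paternity instance: n_off offspring, n_cand candidates,
# 2 loci with n_alleles alleles; returns the pieces anneal_run needs.
random_paternity_instance <- function(seed, n_off = 10, n_cand = 4, n_alleles = 6) {
  set.seed(seed)
  alleles <- 100L + 2L * seq_len(n_alleles)
  geno <- function() sort(sample(alleles, 2, replace = TRUE))
  mk <- function(id, role, mother = NA, patch = "F01") {
    g1 <- geno(); g2 <- geno()
    tibble::as_tibble(c(gt_row(id, role, patch = patch, mother = mother,
                               LA_1 = g1[1], LA_2 = g1[2], LB_1 = g2[1], LB_2 = g2[2])))
  }
  mothers_pool <- dplyr::bind_rows(lapply(1:2, function(i) mk(paste0("M", i), "receptor")))
  cands <- dplyr::bind_rows(lapply(seq_len(n_cand), function(i) mk(paste0("C", i), "donor")))
  offs <- list(); moms <- list()
  for (i in seq_len(n_off)) {
    mi <- sample(1:2, 1)
    mom <- mothers_pool[mi, ]
    # father: candidate or random outsider
    if (runif(1) < 0.6 && n_cand > 0) dad <- cands[sample(n_cand, 1), ] else dad <- mk("X", "donor")
    g <- lapply(c("LA", "LB"), function(loc) {
      ma <- c(mom[[paste0(loc, "_1")]], mom[[paste0(loc, "_2")]])
      fa <- c(dad[[paste0(loc, "_1")]], dad[[paste0(loc, "_2")]])
      sort(c(sample(ma, 1), sample(fa, 1)))
    })
    off <- tibble::as_tibble(c(gt_row(sprintf("O%02d", i), "offspring", mother = mom$sample_id,
                                      LA_1 = g[[1]][1], LA_2 = g[[1]][2],
                                      LB_1 = g[[2]][1], LB_2 = g[[2]][2])))
    offs[[i]] <- off; moms[[i]] <- mom
  }
  all_adults <- dplyr::bind_rows(mothers_pool, cands)
  list(off = dplyr::bind_rows(offs), moms = dplyr::bind_rows(moms),
       cands = cands, freqs = allele_frequencies(all_adults))
}

# Small study configuration keeping simulation-based tests fast.
small_sim_config <- function(...) {
  defaults <- list(
    n_clusters_range = c(12L, 30L), receptors_per_patch = c(3L, 5L),
    offspring_nb = c(size = 1.2, mu = 8, max = 20),
    clonality_subsample = 15L, max_routes = 5000L
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Simulated ZI-Poisson dataset at the reference parameters.
gen_zipois_data <- function(seed, G = 9, nper = 10,
                            beta = c(0.5, 1, -0.5), gamma = c(-1, 0.8),
                            sigma_u = 0.5, sigma_v = 0.5) {
  set.seed(seed)
  d <- tidyr::expand_grid(g = seq_len(G), i = seq_len(nper))
  d$x1 <- rnorm(nrow(d)); d$x2 <- rnorm(nrow(d)); d$z1 <- rnorm(nrow(d))
  u <- rnorm(G, 0, sigma_u); v <- rnorm(G, 0, sigma_v)
  eta <- beta[1] + beta[2] * d$x1 + beta[3] * d$x2 + u[d$g]
  pz <- plogis(gamma[1] + gamma[2] * d$z1 + v[d$g])
  d$y <- ifelse(runif(nrow(d)) < pz, 0L, rpois(nrow(d), exp(eta)))
  d$g <- factor(d$g)
  d
}
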