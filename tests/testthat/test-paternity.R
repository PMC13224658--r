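test_that("transmission probabilities follow Mendelian segregation", {
  expect_equal(transmission_prob(c(1, 1), c(1, 1), c(1, 1)), 1)
  expect_equal(transmission_prob(c(1, 3), c(1, 2), c(3, 4)), 0.25)
  expect_equal(transmission_prob(c(1, 1), c(1, 2), c(2, 3)), 0)
  # normalisation over all unordered offspring pairs, a few parental pairs
  alleles <- 1:4
  pairs <- expand.grid(a = alleles, b = alleles)
  pairs <- pairs[pairs$a <= pairs$b, ]
  for (m in list(c(1, 1), c(1, 2), c(3, 4))) {
    for (f in list(c(1, 1), c(2, 3), c(1, 4))) {
      tot <- sum(mapply(function(a, b) transmission_prob(c(a, b), m, f),
                        pairs$a, pairs$b))
      expect_equal(tot, 1, tolerance = 1e-12)
    }
  }
})

test_that("unsampled-father likelihood integrates over HWE frequencies", {
  freqs <- c(`1` = 0.5, `2` = 0.3, `3` = 0.2)
  expect_equal(offspring_lik_unsampled(c(1, 3), c(1, 2), freqs), 0.1)
  expect_equal(offspring_lik_unsampled(c(1, 1), c(1, 1), freqs), 0.5)
  # sums to 1 over all possible offspring genotypes
  pairs <- expand.grid(a = 1:3, b = 1:3)
  pairs <- pairs[pairs$a <= pairs$b, ]
  for (m in list(c(1, 1), c(1, 2), c(2, 3))) {
    tot <- sum(mapply(function(a, b) offspring_lik_unsampled(c(a, b), m, freqs),
                      pairs$a, pairs$b))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

make_trio <- function(off, mom, dad) {
  mk <- function(id, role, mother, g) {
    tibble::as_tibble(c(gt_row(id, role, mother = mother,
                               LA_1 = g[1], LA_2 = g[2], LB_1 = g[3], LB_2 = g[4])))
  }
  list(off = mk("O", "offspring", "M", off),
       mom = mk("M", "receptor", NA, mom),
       dad = mk("D", "donor", NA, dad))
}

test_that("trio log-likelihood mixes Mendelian and error terms per locus", {
  freqs <- tibble::tibble(locus = rep(c("LA", "LB"), each = 2),
                          allele = c(101L, 103L, 200L, 202L),
                          count = c(2L, 2L, 2L, 2L),
                          freq = c(0.5, 0.5, 0.5, 0.5))
  # incompatible at LB (offspring 202/202, father 200/200, mother 200/200)
  tr <- make_trio(c(101L, 101L, 202L, 202L), c(101L, 101L, 200L, 202L),
                  c(101L, 101L, 200L, 200L))
  expect_identical(pair_loglik(tr$off, tr$mom, tr$dad, freqs, error_rate = 0), -Inf)
  e <- 0.01
  ll <- pair_loglik(tr$off, tr$mom, tr$dad, freqs, error_rate = e)
  # locus LA: T = 1, LB: T = 0 with P_HWE(202/202) = 0.25
  expect_equal(ll, log((1 - e) * 1 + e * 0.25) + log(e * 0.25), tolerance = 1e-12)
  # monotone non-decreasing in e for the incompatible trio
  lls <- vapply(c(0.001, 0.01, 0.05, 0.1), function(ee) {
    pair_loglik(tr$off, tr$mom, tr$dad, freqs, error_rate = ee)
  }, numeric(1))
  expect_true(all(diff(lls) > 0))
  # permutation invariance in locus order
  swap <- function(d) d[, c("sample_id", "role", "patch_id", "cluster_id",
                            "mother_id", "x", "y", "LB_1", "LB_2", "LA_1", "LA_2")]
  expect_equal(pair_loglik(swap(tr$off), swap(tr$mom), swap(tr$dad), freqs, e), ll)
})

# Exhaustive joint-configuration oracle over all (n_cand + 1)^n_off labelings.
exhaustive_map <- function(inst, cfg) {
  ns <- asNamespace("pollenscape")
  ll <- ns$.loglik_matrix(inst$off, inst$moms, inst$cands, inst$freqs, cfg)
  lp <- ns$.logpost_matrix(ll, cfg)
  n_off <- nrow(lp); n_lab <- ncol(lp)
  labels <- rep(1L, n_off)
  best <- -Inf; best_labels <- labels
  total <- n_lab^n_off
  for (k in seq_len(total) - 1L) {
    lab <- (k %/% n_lab^(seq_len(n_off) - 1L)) %% n_lab + 1L
    sc <- sum(lp[cbind(seq_len(n_off), lab)])
    if (sc > best) { best <- sc; best_labels <- lab }
  }
  list(labels = best_labels, score = best)
}

test_that("annealed search equals the exhaustive oracle on tiny instances", {
  cfg <- paternity_config(error_rate = 0.01, seed = 1)
  for (seed in 1:20) {
    inst <- random_paternity_instance(seed, n_off = 5, n_cand = 3)
    want <- exhaustive_map(inst, cfg)
    run <- anneal_run(inst$off, inst$moms, inst$cands, inst$freqs, cfg, seed = seed)
    # the best visited configuration attains the exhaustive optimum
    expect_equal(run$loglik, want$score, tolerance = 1e-9)
  }
})

test_that("annealed search is reproducible and handles forced cases", {
  cfg <- paternity_config(error_rate = 0, seed = 5)
  inst <- random_paternity_instance(3, n_off = 4, n_cand = 3)
  r1 <- anneal_run(inst$off, inst$moms, inst$cands, inst$freqs, cfg, seed = 11)
  r2 <- anneal_run(inst$off, inst$moms, inst$cands, inst$freqs, cfg, seed = 11)
  expect_identical(r1, r2)

  # single informative candidate that is the true father, e = 0
  mom <- tibble::as_tibble(c(gt_row("M", "receptor", LA_1 = 101L, LA_2 = 101L, LB_1 = 200L, LB_2 = 200L)))
  dad <- tibble::as_tibble(c(gt_row("D", "donor", LA_1 = 111L, LA_2 = 111L, LB_1 = 210L, LB_2 = 210L)))
  off <- tibble::as_tibble(c(gt_row("O", "offspring", mother = "M",
                                    LA_1 = 101L, LA_2 = 111L, LB_1 = 200L, LB_2 = 210L)))
  freqs <- allele_frequencies(dplyr::bind_rows(mom, dad))
  run <- anneal_run(off, mom, dad, freqs, paternity_config(error_rate = 0), seed = 1)
  expect_equal(run$assignment$donor_id, "D")

  # zero candidates: everything UNASSIGNED
  none <- dad[0, ]
  run0 <- anneal_run(off, mom, none, freqs, paternity_config(error_rate = 0), seed = 1)
  expect_true(is.na(run0$assignment$donor_id))
})

test_that("consensus applies the at-least-two-of-five support rule with ties unassigned", {
  cfg <- paternity_config(n_runs = 5, min_support = 2)
  mk_run <- function(donors) {
    list(seed = 1, loglik = 0,
         assignment = tibble::tibble(offspring_id = names(donors),
                                     donor_id = unname(donors)))
  }
  runs <- list(
    mk_run(c(O1 = "D1", O2 = "D1", O3 = "D1")),
    mk_run(c(O1 = NA, O2 = "D2", O3 = "D2")),
    mk_run(c(O1 = "D1", O2 = "D2", O3 = NA)),
    mk_run(c(O1 = NA, O2 = "D1", O3 = "D2")),
    mk_run(c(O1 = NA, O2 = NA, O3 = NA))
  )
  cons <- consensus_paternity(runs, cfg)
  # O1: D1 in runs 1 and 3 -> accepted with support 2
  expect_equal(cons$donor_id[cons$offspring_id == "O1"], "D1")
  expect_equal(cons$support[cons$offspring_id == "O1"], 2L)
  # O2: D1 twice, D2 twice -> tie -> UNASSIGNED
  expect_true(is.na(cons$donor_id[cons$offspring_id == "O2"]))
  expect_equal(cons$status[cons$offspring_id == "O2"], "tie")
  # O3: D2 in 2 runs wins over D1 in 1
  expect_equal(cons$donor_id[cons$offspring_id == "O3"], "D2")

  # a pair in only one run stays unassigned
  runs1 <- list(mk_run(c(O1 = "D1")), mk_run(c(O1 = NA)), mk_run(c(O1 = NA)),
                mk_run(c(O1 = NA)), mk_run(c(O1 = NA)))
  cons1 <- consensus_paternity(runs1, cfg)
  expect_equal(cons1$status, "unassigned")
})

test_that("self-incompatibility excludes donors sharing the receptor's MLG", {
  # receptor's clone-mate is a candidate; a distinct true father also exists
  mom <- tibble::as_tibble(c(gt_row("M", "receptor", cluster = "C1",
                                    LA_1 = 101L, LA_2 = 103L, LB_1 = 200L, LB_2 = 202L)))
  clone <- tibble::as_tibble(c(gt_row("K", "donor", cluster = "C2",
                                      LA_1 = 101L, LA_2 = 103L, LB_1 = 200L, LB_2 = 202L)))
  dad <- tibble::as_tibble(c(gt_row("D", "donor", cluster = "C3",
                                    LA_1 = 111L, LA_2 = 113L, LB_1 = 210L, LB_2 = 212L)))
  off <- tibble::as_tibble(c(gt_row("O1", "offspring", mother = "M",
                                    LA_1 = 101L, LA_2 = 111L, LB_1 = 200L, LB_2 = 210L)))
  gs <- dplyr::bind_rows(mom, clone, dad, off)
  res <- assign_paternity(gs, paternity_config(error_rate = 0.001, seed = 2))
  expect_equal(res$consensus$donor_id, "D")
  # offspring that only the clone could explain must stay unassigned
  off2 <- tibble::as_tibble(c(gt_row("O2", "offspring", mother = "M",
                                     LA_1 = 101L, LA_2 = 103L, LB_1 = 200L, LB_2 = 202L)))
  gs2 <- dplyr::bind_rows(mom, clone, off2)
  res2 <- assign_paternity(gs2, paternity_config(error_rate = 0.001, seed = 2))
  expect_true(all(res2$consensus$status != "assigned" |
                    res2$consensus$donor_id != "K"))
})

test_that("incompatible offspring are excluded and reported", {
  mom <- tibble::as_tibble(c(gt_row("M", "receptor",
                                    LA_1 = 101L, LA_2 = 103L, LB_1 = 200L, LB_2 = 202L,
                                    LC_1 = 300L, LC_2 = 302L)))
  dad <- tibble::as_tibble(c(gt_row("D", "donor",
                                    LA_1 = 101L, LA_2 = 103L, LB_1 = 200L, LB_2 = 202L,
                                    LC_1 = 300L, LC_2 = 304L)))
  bad <- tibble::as_tibble(c(gt_row("O", "offspring", mother = "M",
                                    LA_1 = 111L, LA_2 = 113L, LB_1 = 210L, LB_2 = 212L,
                                    LC_1 = 310L, LC_2 = 312L)))
  gs <- dplyr::bind_rows(mom, dad, bad)
  res <- assign_paternity(gs, paternity_config(seed = 1))
  expect_equal(res$consensus$status, "incompatible")
  expect_true(is.na(res$consensus$donor_id))
})
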