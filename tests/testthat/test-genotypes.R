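test_that("allele tables round-trip through CSV with validation", {
  gs <- toy_genotypes()
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(gs, path, row.names = FALSE)
  back <- read_allele_table(path)
  expect_equal(nrow(back), 6L)
  expect_equal(locus_names(back), c("LA", "LB"))
  expect_equal(back$sample_id, gs$sample_id)

  # malformed allele is rejected with the row number
  bad <- gs
  bad$LA_1[2] <- -1L
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_allele_table(path), "row 2")

  # a table without offspring is valid and paternity returns nothing
  adults <- dplyr::filter(gs, role != "offspring")
  write.csv(adults, path, row.names = FALSE)
  ok <- read_allele_table(path)
  res <- assign_paternity(ok, paternity_config(seed = 1))
  expect_equal(nrow(res$consensus), 0L)
})

test_that("allele table validation catches structural errors", {
  gs <- toy_genotypes()
  expect_error(validate_allele_table(dplyr::mutate(gs, role = replace(role, 1, "adult"))),
               "unknown role")
  expect_error(validate_allele_table(dplyr::mutate(gs, sample_id = replace(sample_id, 2, "A1"))),
               "duplicate sample_id")
  expect_error(validate_allele_table(dplyr::mutate(gs, mother_id = replace(mother_id, 5, NA))),
               "without mother_id")
  half <- gs; half$LA_1[1] <- 0L
  expect_error(validate_allele_table(half), "half-missing")
})

test_that("MLG keys are order-independent within a locus and strict on missing data", {
  a <- tibble::as_tibble(c(gt_row("s1", "donor", LA_1 = 101L, LA_2 = 103L, LB_1 = 200L, LB_2 = 200L)))
  b <- tibble::as_tibble(c(gt_row("s2", "donor", LA_1 = 103L, LA_2 = 101L, LB_1 = 200L, LB_2 = 200L)))
  d <- tibble::as_tibble(c(gt_row("s3", "donor", LA_1 = 101L, LA_2 = 105L, LB_1 = 200L, LB_2 = 200L)))
  expect_identical(mlg_key(a), mlg_key(b))
  expect_false(mlg_key(a) == mlg_key(d))

  # policy truth table: a missing locus never matches a typed one under
  # strict, but matches anything under tolerant when the other loci agree
  full <- tibble::as_tibble(c(gt_row("f", "donor", LA_1 = 101L, LA_2 = 103L, LB_1 = 200L, LB_2 = 202L)))
  part <- tibble::as_tibble(c(gt_row("p", "donor", LA_1 = 101L, LA_2 = 103L, LB_1 = 0L, LB_2 = 0L)))
  both <- dplyr::bind_rows(full, part)
  expect_equal(nrow(find_repeated_mlgs(both, policy = "strict")), 0L)
  tol <- find_repeated_mlgs(both, policy = "tolerant")
  expect_equal(nrow(tol), 1L)
  expect_setequal(tol$sample_ids[[1]], c("f", "p"))

  # all-missing sample is an error
  miss <- part
  miss$LA_1 <- 0L; miss$LA_2 <- 0L
  expect_error(mlg_key(miss), "all loci missing")
})

test_that("repeated-MLG grouping matches the pairwise brute-force oracle", {
  for (seed in 1:4) {
    gs <- random_genotype_set(100, n_loci = 3, n_alleles = 3, dup_frac = 0.3,
                              missing_rate = if (seed > 2) 0.15 else 0, seed = seed)
    for (policy in c("strict", "tolerant")) {
      got <- find_repeated_mlgs(gs, policy = policy)
      want <- oracle_repeated_groups(gs, policy = policy)
      got_sets <- lapply(got$sample_ids, sort)
      expect_setequal(vapply(got_sets, paste, character(1), collapse = ","),
                      vapply(want, paste, character(1), collapse = ","))
    }
  }
})

test_that("deduplication keeps receptors, collapses twins and retains parent-offspring repeats", {
  base <- toy_genotypes()
  # adult duplicate of a receptor, a twin pair, and an offspring matching
  # its mother's MLG
  gs <- dplyr::bind_rows(
    base,
    tibble::as_tibble(c(gt_row("A9", "donor", cluster = "C9",
                               LA_1 = 103L, LA_2 = 105L, LB_1 = 202L, LB_2 = 204L))),  # same MLG as R1
    tibble::as_tibble(c(gt_row("O3", "offspring", mother = "R1",
                               LA_1 = 101L, LA_2 = 103L, LB_1 = 200L, LB_2 = 202L))),  # twin of O1
    tibble::as_tibble(c(gt_row("O4", "offspring", mother = "R2",
                               LA_1 = 103L, LA_2 = 105L, LB_1 = 202L, LB_2 = 204L)))   # matches mother R1? no: mother R2
  )
  out <- deduplicate_genotypes(gs)
  expect_true(all(c("R1", "R2") %in% out$genotypes$sample_id))
  expect_false("A9" %in% out$genotypes$sample_id)
  expect_equal(out$removal_log$reason[out$removal_log$sample_id == "A9"],
               "duplicate_of_receptor")
  # twins O1/O3 collapse to the lexicographically smallest
  expect_true("O1" %in% out$genotypes$sample_id)
  expect_false("O3" %in% out$genotypes$sample_id)
  expect_equal(out$removal_log$kept_twin_of[out$removal_log$sample_id == "O3"], "O1")
  # O4 shares R1's MLG but has a different mother: retained
  expect_true("O4" %in% out$genotypes$sample_id)
  # bookkeeping and idempotence
  expect_equal(nrow(out$genotypes) + nrow(out$removal_log), nrow(gs))
  again <- deduplicate_genotypes(out$genotypes)
  expect_equal(nrow(again$removal_log), 0L)
})

test_that("donor-only duplicate groups keep the smallest sample id", {
  gs <- dplyr::bind_rows(
    tibble::as_tibble(c(gt_row("D2", "donor", cluster = "C1", LA_1 = 101L, LA_2 = 101L, LB_1 = 200L, LB_2 = 200L))),
    tibble::as_tibble(c(gt_row("D1", "donor", cluster = "C2", LA_1 = 101L, LA_2 = 101L, LB_1 = 200L, LB_2 = 200L))),
    tibble::as_tibble(c(gt_row("D3", "donor", cluster = "C3", LA_1 = 101L, LA_2 = 103L, LB_1 = 200L, LB_2 = 200L)))
  )
  out <- deduplicate_genotypes(gs)
  expect_setequal(out$genotypes$sample_id, c("D1", "D3"))
  # second pass removes nothing (idempotent)
  expect_equal(nrow(deduplicate_genotypes(out$genotypes)$removal_log), 0L)
})

test_that("clonality report classifies clusters and excludes singletons", {
  mk <- function(id, cluster, a1, a2) {
    tibble::as_tibble(c(gt_row(id, "donor", cluster = cluster,
                               LA_1 = a1, LA_2 = a2, LB_1 = 200L, LB_2 = 200L)))
  }
  gs <- dplyr::bind_rows(
    mk("s1", "C1", 101L, 101L), mk("s2", "C1", 101L, 101L),     # monoclonal
    mk("s3", "C2", 101L, 103L), mk("s4", "C2", 101L, 103L),     # monoclonal
    mk("s5", "C3", 101L, 103L), mk("s6", "C3", 105L, 105L),     # 2 MLGs
    mk("s7", "C4", 101L, 101L)                                   # singleton, excluded
  )
  shoots <- tibble::tibble(cluster_id = c("C1", "C2", "C3", "C4"),
                           n_shoots = c(3L, 10L, 25L, 2L))
  rep <- clonality_report(gs, shoots)
  expect_equal(rep$overall_monoclonal_fraction, 2 / 3)
  expect_equal(rep$n_singleton_excluded, 1L)
  by <- rep$by_size_class
  expect_equal(by$prop_monoclonal[by$size_class == "<5"], 1)
  expect_equal(by$prop_monoclonal[by$size_class == ">20"], 0)
})

test_that("clonality recovery matches generator truth within the binomial band", {
  # 200 clusters per size class with known monoclonal rates, full sampling
  set.seed(99)
  probs <- c(`<5` = 0.62, `5-20` = 0.46, `>20` = 0.28)
  shoots_for <- c(`<5` = 3L, `5-20` = 10L, `>20` = 25L)
  rows <- list(); shoot_rows <- list()
  for (cls in names(probs)) {
    for (k in 1:200) {
      cl <- sprintf("%s_%03d", gsub("[<>-]", "", cls), k)
      mono <- runif(1) < probs[[cls]]
      n_sampled <- 4L
      geno <- matrix(sample(c(101L, 103L, 105L, 107L), 2 * n_sampled, TRUE), ncol = 2)
      if (mono) geno <- matrix(rep(geno[1, ], n_sampled), ncol = 2, byrow = TRUE)
      else geno[2, ] <- c(109L, 111L)  # force a second MLG
      for (s in seq_len(n_sampled)) {
        rows[[length(rows) + 1L]] <- tibble::as_tibble(c(gt_row(
          paste0(cl, "_S", s), "donor", cluster = cl,
          LA_1 = min(geno[s, ]), LA_2 = max(geno[s, ]), LB_1 = 200L, LB_2 = 200L
        )))
      }
      shoot_rows[[length(shoot_rows) + 1L]] <- tibble::tibble(
        cluster_id = cl, n_shoots = shoots_for[[cls]]
      )
    }
  }
  rep <- clonality_report(dplyr::bind_rows(rows), dplyr::bind_rows(shoot_rows))
  by <- rep$by_size_class
  for (cls in names(probs)) {
    p_hat <- by$prop_monoclonal[by$size_class == cls]
    band <- 1.96 * sqrt(probs[[cls]] * (1 - probs[[cls]]) / 200)
    expect_lt(abs(p_hat - probs[[cls]]), band + 1e-9)
  }
})

test_that("allele frequencies count typed copies and sum to one", {
  one <- tibble::as_tibble(c(gt_row("s1", "donor", LA_1 = 101L, LA_2 = 101L)))
  f1 <- allele_frequencies(one)
  expect_equal(f1$freq, 1)
  two <- dplyr::bind_rows(one,
    tibble::as_tibble(c(gt_row("s2", "donor", LA_1 = 101L, LA_2 = 103L))))
  f2 <- allele_frequencies(two)
  expect_equal(f2$freq[f2$allele == 101], 0.75)
  expect_equal(f2$freq[f2$allele == 103], 0.25)

  gs <- random_genotype_set(60, n_loci = 3, n_alleles = 5, missing_rate = 0.1, seed = 7)
  f <- allele_frequencies(gs)
  # counting oracle
  for (loc in locus_names(gs)) {
    a <- c(gs[[paste0(loc, "_1")]], gs[[paste0(loc, "_2")]])
    a <- a[a > 0]
    tb <- table(a)
    sub <- f[f$locus == loc, ]
    expect_equal(setNames(sub$freq, sub$allele),
                 setNames(as.numeric(tb) / length(a), names(tb)))
    expect_equal(sum(sub$freq), 1, tolerance = 1e-12)
  }
  # invariant under sample reordering
  shuf <- gs[sample(nrow(gs)), ]
  expect_equal(dplyr::arrange(allele_frequencies(shuf), locus, allele),
               dplyr::arrange(f, locus, allele))
})

test_that("mother-offspring mismatches are reset up to the tolerance, then flagged", {
  gs <- dplyr::bind_rows(
    tibble::as_tibble(c(gt_row("R1", "receptor", cluster = "C1",
                               LA_1 = 101L, LA_2 = 103L, LB_1 = 200L, LB_2 = 202L,
                               LC_1 = 300L, LC_2 = 302L))),
    tibble::as_tibble(c(gt_row("O1", "offspring", mother = "R1",
                               LA_1 = 105L, LA_2 = 107L, LB_1 = 200L, LB_2 = 204L,
                               LC_1 = 300L, LC_2 = 304L))),  # 1 mismatch (LA)
    tibble::as_tibble(c(gt_row("O2", "offspring", mother = "R1",
                               LA_1 = 101L, LA_2 = 105L, LB_1 = 202L, LB_2 = 206L,
                               LC_1 = 302L, LC_2 = 306L))),  # fully compatible
    tibble::as_tibble(c(gt_row("O3", "offspring", mother = "R1",
                               LA_1 = 105L, LA_2 = 107L, LB_1 = 206L, LB_2 = 208L,
                               LC_1 = 304L, LC_2 = 306L)))   # 3 mismatches
  )
  res <- resolve_mother_mismatches(gs, max_mismatch = 1)
  log <- res$log
  expect_equal(log$status[log$offspring_id == "O1"], "resolved")
  o1 <- dplyr::filter(res$genotypes, sample_id == "O1")
  expect_equal(c(o1$LA_1, o1$LA_2), c(0L, 0L))
  expect_equal(log$status[log$offspring_id == "O2"], "ok")
  expect_identical(dplyr::filter(res$genotypes, sample_id == "O2"),
                   dplyr::filter(gs, sample_id == "O2"))
  expect_equal(log$status[log$offspring_id == "O3"], "incompatible")

  # invariant: resolved offspring are Mendelian-compatible with the mother
  # at every locus still typed
  out <- res$genotypes
  mother <- dplyr::filter(out, sample_id == "R1")
  for (oid in c("O1", "O2")) {
    off <- dplyr::filter(out, sample_id == oid)
    for (loc in locus_names(out)) {
      o <- c(off[[paste0(loc, "_1")]], off[[paste0(loc, "_2")]])
      m <- c(mother[[paste0(loc, "_1")]], mother[[paste0(loc, "_2")]])
      if (all(o > 0) && all(m > 0)) expect_true(any(o %in% m))
    }
  }
})

test_that("repeated-MLG counts expose all three counting conventions", {
  gs <- random_genotype_set(50, dup_frac = 0.3, seed = 3)
  counts <- repeated_mlg_counts(gs)
  groups <- find_repeated_mlgs(gs)
  expect_equal(counts$n_groups, nrow(groups))
  expect_equal(counts$n_samples_involved, sum(groups$n))
  expect_equal(counts$n_redundant, sum(groups$n) - nrow(groups))
})
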