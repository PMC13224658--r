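# Pollen-flow measures per receptor and per donor: within-patch pollination
# proportion, immigration rate, rarefied allelic richness, donor statistics.

#' Rarefied allelic richness of a set of offspring genotypes
#'
#' Expected number of distinct alleles per locus in a random subsample of
#' `g = 2 * g_individuals` gene copies, by the exact hypergeometric formula
#' `A_r(l) = sum_i [1 - C(N_l - N_li, g) / C(N_l, g)]` (no resampling).
#' Missing slots are excluded from the `N_l` typed copies; when a locus has
#' fewer than `g` typed copies the rarefaction depth is reduced to `N_l`.
#'
#' @param offspring Allele-table rows of one receptor's offspring.
#' @param g_individuals Rarefaction depth in diploid individuals (default 5,
#'   i.e. 10 gene copies).
#' @return List with `per_locus` (tibble `locus, n_copies, g, a_r`),
#'   `mean` (mean over loci, the default summary) and `sum` (sum over loci).
#' @export
rarefied_allelic_richness <- function(offspring, g_individuals = 5L) {
  loci <- locus_names(offspring)
  if (nrow(offspring) < g_individuals) {
    abort(sprintf("need >= %d offspring, got %d", g_individuals, nrow(offspring)))
  }
  g_copies <- 2L * g_individuals
  per <- lapply(loci, function(loc) {
    m <- .locus_mat(offspring, loc)
    a <- c(m[, 1], m[, 2]); a <- a[a > 0]
    n_l <- length(a)
    if (n_l == 0L) return(tibble(locus = loc, n_copies = 0L, g = 0L, a_r = NA_real_))
    g <- min(g_copies, n_l)
    counts <- table(a)
    a_r <- sum(1 - exp(lchoose(n_l - counts, g) - lchoose(n_l, g)))
    tibble(locus = loc, n_copies = n_l, g = as.integer(g), a_r = a_r)
  })
  per <- bind_rows(per)
  list(per_locus = per,
       mean = mean(per$a_r, na.rm = TRUE),
       sum = sum(per$a_r, na.rm = TRUE))
}

#' Per-receptor pollen-flow summary
#'
#' For each pollen receptor: the number of genotyped offspring, the number
#' assigned to a donor of the receptor's own forest patch (`n_within`), the
#' within-patch pollination proportion `pf_within = n_within / n_offspring`,
#' the pollen immigration rate `1 - pf_within` (UNASSIGNED offspring count
#' as immigrant pollen), and the rarefied allelic richness of the offspring.
#' Receptors with fewer than `min_offspring` genotyped offspring get `NA`
#' allelic richness and are flagged `excluded` for downstream modelling.
#'
#' @param paternity A `paternity_result` from [assign_paternity()], or its
#'   consensus tibble.
#' @param genotypes The allele table the assignment was computed from.
#' @param g_individuals Rarefaction depth in individuals (default 5).
#' @param min_offspring Minimum offspring for allelic richness and model
#'   inclusion (default 5).
#' @return Tibble, one row per receptor: `receptor_id, patch_id,
#'   n_offspring, n_within, pf_within, immigration_rate, a_r, a_r_sum,
#'   excluded`.
#' @export
receptor_summaries <- function(paternity, genotypes, g_individuals = 5L,
                               min_offspring = 5L) {
  cons <- if (inherits(paternity, "paternity_result")) paternity$consensus else paternity
  offspring <- filter(genotypes, .data$role == "offspring")
  receptors <- filter(genotypes, .data$role == "receptor")
  out <- lapply(seq_len(nrow(receptors)), function(i) {
    rid <- receptors$sample_id[i]
    off <- filter(offspring, .data$mother_id == rid)
    n_off <- nrow(off)
    if (n_off == 0L) {
      return(tibble(receptor_id = rid, patch_id = receptors$patch_id[i],
                    n_offspring = 0L, n_within = NA_integer_,
                    pf_within = NA_real_, immigration_rate = NA_real_,
                    a_r = NA_real_, a_r_sum = NA_real_, excluded = TRUE))
    }
    cc <- filter(cons, .data$offspring_id %in% off$sample_id)
    n_within <- sum(cc$status == "assigned")
    pf <- n_within / n_off
    excl <- n_off < min_offspring
    ar <- if (!excl) rarefied_allelic_richness(off, g_individuals) else NULL
    tibble(receptor_id = rid, patch_id = receptors$patch_id[i],
           n_offspring = n_off, n_within = as.integer(n_within),
           pf_within = pf, immigration_rate = 1 - pf,
           a_r = if (is.null(ar)) NA_real_ else ar$mean,
           a_r_sum = if (is.null(ar)) NA_real_ else ar$sum,
           excluded = excl)
  })
  arrange(bind_rows(out), .data$patch_id, .data$receptor_id)
}

#' Per-donor statistics and within-patch mating aggregate
#'
#' Summarises effective pollen donors (shoot clusters whose sampled genotype
#' sired at least one assigned offspring): offspring count, shoot-cluster
#' size, Euclidean donor-receptor distances and the distance from the donor
#' cluster to the nearest point of its patch boundary.
#'
#' @param paternity A `paternity_result` or consensus tibble.
#' @param genotypes The allele table.
#' @param clusters Tibble `cluster_id, patch_id, x, y, n_shoots`.
#' @param patches Optional tibble `patch_id, geometry` (list-column of ring
#'   matrices) for edge distances; `NULL` skips them.
#' @return List with `donors` (tibble, one row per effective donor) and
#'   `aggregate` (one-row tibble: `n_effective_donors,
#'   fraction_clusters_donating, median_offspring_per_donor,
#'   median_donor_receptor_distance, median_distance_to_edge`).
#' @export
donor_statistics <- function(paternity, genotypes, clusters, patches = NULL) {
  cons <- if (inherits(paternity, "paternity_result")) paternity$consensus else paternity
  assigned <- filter(cons, .data$status == "assigned")
  adults <- filter(genotypes, .data$role != "offspring")
  receptors <- filter(genotypes, .data$role == "receptor")
  clusters <- as_tibble(clusters)

  donors <- assigned %>%
    group_by(donor_id = .data$donor_id) %>%
    summarise(n_assigned_offspring = n(),
              receptor_ids = list(unique(.data$mother_id)), .groups = "drop")
  ai <- match(donors$donor_id, adults$sample_id)
  donors$cluster_id <- adults$cluster_id[ai]
  donors$patch_id <- adults$patch_id[ai]
  donors$x <- adults$x[ai]
  donors$y <- adults$y[ai]
  ci <- match(donors$cluster_id, clusters$cluster_id)
  donors$shoot_count <- clusters$n_shoots[ci]

  dr_dist <- vapply(seq_len(nrow(donors)), function(i) {
    recs <- receptors[match(donors$receptor_ids[[i]], receptors$sample_id), ]
    if (is.na(donors$x[i]) || all(is.na(recs$x))) return(NA_real_)
    median(sqrt((recs$x - donors$x[i])^2 + (recs$y - donors$y[i])^2), na.rm = TRUE)
  }, numeric(1))
  donors$median_receptor_distance <- dr_dist

  if (!is.null(patches)) {
    donors$distance_to_edge <- vapply(seq_len(nrow(donors)), function(i) {
      if (is.na(donors$x[i])) return(NA_real_)
      ring <- patches$geometry[[match(donors$patch_id[i], patches$patch_id)]]
      if (is.null(ring)) return(NA_real_)
      point_polygon_boundary_distance(c(donors$x[i], donors$y[i]), ring)
    }, numeric(1))
  } else {
    donors$distance_to_edge <- NA_real_
  }
  donors$flagged_missing_coords <- is.na(donors$x)

  all_dr <- unlist(lapply(seq_len(nrow(donors)), function(i) {
    recs <- receptors[match(donors$receptor_ids[[i]], receptors$sample_id), ]
    if (is.na(donors$x[i])) return(numeric(0))
    sqrt((recs$x - donors$x[i])^2 + (recs$y - donors$y[i])^2)
  }))
  aggregate <- tibble(
    n_effective_donors = nrow(donors),
    fraction_clusters_donating = dplyr::n_distinct(donors$cluster_id) / nrow(clusters),
    median_offspring_per_donor = median(donors$n_assigned_offspring),
    median_donor_receptor_distance = median(all_dr, na.rm = TRUE),
    median_distance_to_edge = median(donors$distance_to_edge, na.rm = TRUE)
  )
  list(donors = select(donors, -"receptor_ids"), aggregate = aggregate)
}
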