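# Synthetic two-generation studies with full ground truth: landscape,
# clonal populations, HWE genotypes, trapline-driven self-incompatible
# mating with pollen carryover, and genotyping error.

#' Synthetic-study configuration
#'
#' Defaults emulate the sampling design of a 5 km x 5 km agricultural
#' landscape window: nine forest patches, heavy-tailed shoot-cluster sizes
#' (~85% of clusters under 10 shoots), size-dependent clonality
#' (monoclonal fractions 0.62 / 0.46 / 0.28 for the <5 / 5-20 / >20 shoot
#' classes), seven microsatellite loci totalling 97 alleles, per-locus
#' genotyping error 1.2%, 6-14 pollen receptors per patch with 1-41
#' genotyped offspring each (mean ~9.6), and bumblebee traplines of 10-30
#' flower visits with geometric pollen carryover.
#'
#' @param window Side of the square landscape window (m).
#' @param n_patches Number of forest patches (placed on a jittered 3x3
#'   grid; currently must be <= 9).
#' @param n_clusters_range Range of shoot-cluster counts per patch;
#'   counts are drawn log-uniformly.
#' @param cluster_size_nb `c(size, mu)` of the zero-truncated negative
#'   binomial for shoots per cluster.
#' @param monoclonal_probs Probability that a multi-shoot cluster is
#'   monoclonal, per size class `<5`, `5-20`, `>20`.
#' @param alleles_per_locus Integer vector, one entry per locus.
#' @param error_rate Per-allele-slot genotyping error probability.
#' @param receptors_per_patch Range of receptors per patch.
#' @param offspring_nb `c(size, mu, max)` of the zero-truncated negative
#'   binomial for genotyped offspring per receptor.
#' @param route_length Range of flower visits per foraging route.
#' @param p_switch Per-visit probability of switching to another patch.
#' @param carryover Geometric pollen-carryover decay (kappa); the donor of
#'   a deposition is a previously visited genet with weight `kappa^age`
#'   (age 0 = the immediately preceding visit).
#' @param k_nearest Within-patch moves go to one of the `k_nearest`
#'   closest clusters.
#' @param clonality_subsample Number of clusters sampled with multiple
#'   shoots (for the clonality assessment).
#' @param landuse_fractions Named fractions for `MAIZE`, `SEMNATGRASS`,
#'   `RAPESEED` (remainder is `OTHER`).
#' @param n_elements_per_type Linear landscape elements per type.
#' @param element_orientation `"random"`, `"parallel"` (elements point at
#'   the nearest patch center) or `"orthogonal"`.
#' @param si_slocus Enable a gametophytic S-locus on top of the default
#'   MLG-identity rejection.
#' @param n_s_alleles Number of S-alleles when `si_slocus` is on.
#' @param apply_error Apply genotyping error in [simulate_study()].
#' @param repeat_routes Reuse a fixed set of routes instead of drawing a
#'   fresh route per foraging bout.
#' @param max_routes Route budget before receptors are left short.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(window = 5000, n_patches = 9L,
                       n_clusters_range = c(24L, 689L),
                       cluster_size_nb = c(size = 0.30, mu = 2.5),
                       monoclonal_probs = c(`<5` = 0.62, `5-20` = 0.46, `>20` = 0.28),
                       alleles_per_locus = c(14L, 14L, 14L, 14L, 14L, 14L, 13L),
                       error_rate = 0.012,
                       receptors_per_patch = c(6L, 14L),
                       offspring_nb = c(size = 1.2, mu = 9.5, max = 41),
                       route_length = c(10L, 30L),
                       p_switch = 0.3, carryover = 0.5, k_nearest = 5L,
                       clonality_subsample = 59L,
                       landuse_fractions = c(MAIZE = 0.40, SEMNATGRASS = 0.08, RAPESEED = 0.12),
                       n_elements_per_type = 25L,
                       element_orientation = c("random", "parallel", "orthogonal"),
                       si_slocus = FALSE, n_s_alleles = 10L,
                       apply_error = TRUE, repeat_routes = FALSE,
                       max_routes = 20000L) {
  element_orientation <- match.arg(element_orientation)
  stopifnot(p_switch >= 0, p_switch <= 1, carryover >= 0, carryover <= 1,
            route_length[1] >= 2, sum(landuse_fractions) <= 1,
            all(monoclonal_probs >= 0), all(monoclonal_probs <= 1),
            n_patches <= 9L)
  structure(as.list(environment()), class = "sim_config")
}

#' Scenario presets
#'
#' @param name One of `within_only` (no patch switching), `trapline_mixed`
#'   (the default mixed-foraging scenario), `high_carryover`,
#'   `orientation_parallel`, `orientation_orthogonal`.
#' @param ... Overrides passed to [sim_config()].
#' @return A [sim_config()].
#' @export
scenario_config <- function(name = c("trapline_mixed", "within_only",
                                     "high_carryover", "orientation_parallel",
                                     "orientation_orthogonal"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    trapline_mixed = list(),
    within_only = list(p_switch = 0),
    high_carryover = list(carryover = 0.9),
    orientation_parallel = list(element_orientation = "parallel"),
    orientation_orthogonal = list(element_orientation = "orthogonal")
  )
  do.call(sim_config, utils::modifyList(args, list(...)))
}

#' Generate the synthetic landscape
#'
#' Forest-patch rectangles on a jittered 3x3 grid, a land-use grid tiling
#' the window with the configured class fractions, linear landscape
#' elements with controlled orientation, and the population layer (patches
#' flagged occupied).
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return List with `patches`, `landuse`, `elements`, `populations` layer
#'   tibbles (each with `geometry_type` and `geometry` columns).
#' @export
gen_landscape <- function(cfg, seed = 1L) {
  set.seed(.sub_seed(seed, "landscape"))
  w <- cfg$window
  cell <- w / 3
  centers <- tidyr::expand_grid(i = 0:2, j = 0:2)
  centers <- centers[seq_len(cfg$n_patches), ]
  patches <- lapply(seq_len(nrow(centers)), function(k) {
    cx <- (centers$i[k] + 0.5) * cell + runif(1, -300, 300)
    cy <- (centers$j[k] + 0.5) * cell + runif(1, -300, 300)
    hx <- runif(1, 150, 350); hy <- runif(1, 150, 350)
    ring <- rbind(c(cx - hx, cy - hy), c(cx + hx, cy - hy),
                  c(cx + hx, cy + hy), c(cx - hx, cy + hy))
    tibble(patch_id = sprintf("F%02d", k), occupied = TRUE,
           cx = cx, cy = cy, geometry_type = "Polygon", geometry = list(ring))
  })
  patches <- bind_rows(patches)

  fr <- cfg$landuse_fractions
  classes <- c(names(fr), "OTHER")
  probs <- c(fr, OTHER = 1 - sum(fr))
  gcell <- 250
  ng <- w / gcell
  grid <- tidyr::expand_grid(i = seq_len(ng) - 1L, j = seq_len(ng) - 1L)
  cls <- sample(classes, nrow(grid), replace = TRUE, prob = probs)
  landuse <- tibble(
    class = cls, geometry_type = "Polygon",
    geometry = lapply(seq_len(nrow(grid)), function(k) {
      x0 <- grid$i[k] * gcell; y0 <- grid$j[k] * gcell
      rbind(c(x0, y0), c(x0 + gcell, y0), c(x0 + gcell, y0 + gcell), c(x0, y0 + gcell))
    })
  )

  elements <- lapply(.linear_types, function(typ) {
    lapply(seq_len(cfg$n_elements_per_type), function(k) {
      anchor <- runif(2, 0, w)
      len <- runif(1, 200, 1500)
      ang <- switch(cfg$element_orientation,
        random = runif(1, 0, 2 * pi),
        parallel = ,
        orthogonal = {
          d2 <- (patches$cx - anchor[1])^2 + (patches$cy - anchor[2])^2
          pk <- which.min(d2)
          a <- atan2(anchor[2] - patches$cy[pk], anchor[1] - patches$cx[pk])
          if (cfg$element_orientation == "orthogonal") a + pi / 2 else a
        }
      )
      d <- c(cos(ang), sin(ang)) * len / 2
      tibble(type = typ, geometry_type = "LineString",
             geometry = list(rbind(anchor - d, anchor + d)))
    })
  })
  elements <- bind_rows(unlist(elements, recursive = FALSE))

  populations <- patches[, c("patch_id", "occupied", "geometry_type", "geometry")]
  list(patches = select(patches, -"cx", -"cy"), landuse = landuse,
       elements = elements, populations = populations)
}

# Dirichlet(1) allele frequencies per locus.
.gen_locus_panel <- function(cfg) {
  loci <- sprintf("L%02d", seq_along(cfg$alleles_per_locus))
  freqs <- lapply(seq_along(loci), function(i) {
    k <- cfg$alleles_per_locus[i]
    g <- stats::rgamma(k, 1)
    tibble(locus = loci[i], allele = 100L + 2L * seq_len(k), freq = g / sum(g))
  })
  bind_rows(freqs)
}

# Draw HWE genotypes: n x 2 allele matrix for one locus.
.draw_geno <- function(n, alleles, freq) {
  cbind(sample(alleles, n, replace = TRUE, prob = freq),
        sample(alleles, n, replace = TRUE, prob = freq))
}

#' Generate clonal populations, genets and the sampled allele table
#'
#' Shoot clusters are placed inside the forest patches with zero-truncated
#' negative-binomial shoot counts; each multi-shoot cluster is monoclonal
#' with its size-class probability, otherwise it holds 2-4 genets; genets
#' receive Hardy-Weinberg genotypes at the configured allele frequencies.
#' One shoot per cluster is sampled (plus multi-shoot subsamples of
#' `clonality_subsample` clusters), and 6-14 clusters per patch are
#' selected as pollen receptors.
#'
#' @param cfg A [sim_config()].
#' @param landscape Output of [gen_landscape()].
#' @param seed Integer seed.
#' @return List: `genotypes` (adult allele table incl. receptor roles),
#'   `clusters` (tibble `cluster_id, patch_id, x, y, n_shoots`), `genets`
#'   (internal truth: genotypes of every genet incl. unsampled ones),
#'   `receptors` (tibble with per-receptor offspring targets), `freqs`
#'   (configured allele frequencies).
#' @export
gen_populations <- function(cfg, landscape, seed = 1L) {
  set.seed(.sub_seed(seed, "genets"))
  panel <- .gen_locus_panel(cfg)
  loci <- unique(panel$locus)
  patches <- landscape$patches

  clusters <- list(); genets <- list()
  for (pi in seq_len(nrow(patches))) {
    pid <- patches$patch_id[pi]
    ring <- patches$geometry[[pi]]
    n_cl <- round(exp(runif(1, log(cfg$n_clusters_range[1]), log(cfg$n_clusters_range[2]))))
    xr <- range(ring[, 1]); yr <- range(ring[, 2])
    cx <- runif(n_cl, xr[1], xr[2]); cy <- runif(n_cl, yr[1], yr[2])
    n_shoots <- .rztnb(n_cl, cfg$cluster_size_nb[["size"]], cfg$cluster_size_nb[["mu"]], max = 300)
    cl <- tibble(
      cluster_id = sprintf("%s_C%04d", pid, seq_len(n_cl)),
      patch_id = pid, x = cx, y = cy, n_shoots = as.integer(n_shoots)
    )
    clusters[[pi]] <- cl
    size_class <- cut(cl$n_shoots, c(-Inf, 4.5, 20.5, Inf), labels = c("<5", "5-20", ">20"))
    p_mono <- cfg$monoclonal_probs[as.character(size_class)]
    n_genets <- ifelse(cl$n_shoots == 1L, 1L,
                       ifelse(runif(n_cl) < p_mono, 1L, 2L + rbinom(n_cl, 2L, 0.4)))
    for (ci in seq_len(n_cl)) {
      k <- n_genets[ci]
      # each genet holds at least one shoot; remaining shoots split uniformly
      extra <- if (cl$n_shoots[ci] > k) {
        as.integer(stats::rmultinom(1, cl$n_shoots[ci] - k, rep(1 / k, k)))
      } else rep(0L, k)
      shoots_per_genet <- pmin(rep(1L, k) + extra, cl$n_shoots[ci])
      genets[[length(genets) + 1L]] <- tibble(
        genet_id = sprintf("%s_G%d", cl$cluster_id[ci], seq_len(k)),
        cluster_id = cl$cluster_id[ci], patch_id = pid,
        n_shoots_genet = shoots_per_genet
      )
    }
  }
  clusters <- bind_rows(clusters)
  genets <- bind_rows(genets)

  for (loc in loci) {
    f <- panel[panel$locus == loc, ]
    gm <- .draw_geno(nrow(genets), f$allele, f$freq)
    genets[[paste0(loc, "_1")]] <- as.integer(pmin(gm[, 1], gm[, 2]))
    genets[[paste0(loc, "_2")]] <- as.integer(pmax(gm[, 1], gm[, 2]))
  }
  if (cfg$si_slocus) {
    s_alleles <- seq_len(cfg$n_s_alleles)
    genets$s1 <- sample(s_alleles, nrow(genets), replace = TRUE)
    genets$s2 <- sample(s_alleles, nrow(genets), replace = TRUE)
  }

  # one sampled shoot per cluster; the sampled genet is drawn by shoot share
  sample_genet <- function(cl_id) {
    g <- genets[genets$cluster_id == cl_id, ]
    if (nrow(g) == 1L) return(g$genet_id)
    sample(g$genet_id, 1L, prob = g$n_shoots_genet)
  }
  primary <- vapply(clusters$cluster_id, sample_genet, character(1))
  adult_rows <- tibble(
    sample_id = paste0(clusters$cluster_id, "_S1"),
    role = "donor", patch_id = clusters$patch_id,
    cluster_id = clusters$cluster_id, mother_id = NA_character_,
    x = clusters$x, y = clusters$y, genet_id = primary
  )

  # multi-shoot clonality subsample: extra sampled shoots on some clusters
  multi <- clusters$cluster_id[clusters$n_shoots >= 2L]
  sub <- sample(multi, min(cfg$clonality_subsample, length(multi)))
  extra_rows <- list()
  for (cl_id in sub) {
    n_sh <- clusters$n_shoots[clusters$cluster_id == cl_id]
    n_extra <- min(n_sh, if (n_sh <= 3L) n_sh else 6L) - 1L
    if (n_extra <= 0L) next
    g <- genets[genets$cluster_id == cl_id, ]
    gid <- if (nrow(g) == 1L) rep(g$genet_id, n_extra) else {
      sample(g$genet_id, n_extra, replace = TRUE, prob = g$n_shoots_genet)
    }
    extra_rows[[length(extra_rows) + 1L]] <- tibble(
      sample_id = sprintf("%s_S%d", cl_id, 1L + seq_len(n_extra)),
      role = "donor", patch_id = clusters$patch_id[clusters$cluster_id == cl_id],
      cluster_id = cl_id, mother_id = NA_character_,
      x = clusters$x[clusters$cluster_id == cl_id],
      y = clusters$y[clusters$cluster_id == cl_id],
      genet_id = gid
    )
  }
  adults <- bind_rows(adult_rows, bind_rows(extra_rows))

  # receptors: per patch, 6-14 clusters among those with a sampled adult
  set.seed(.sub_seed(seed, "receptors"))
  receptors <- list()
  for (pid in unique(clusters$patch_id)) {
    cl_ids <- clusters$cluster_id[clusters$patch_id == pid]
    n_rec <- sample(seq(cfg$receptors_per_patch[1], cfg$receptors_per_patch[2]), 1L)
    n_rec <- min(n_rec, length(cl_ids))
    rec_cl <- sample(cl_ids, n_rec)
    rec_sid <- paste0(rec_cl, "_S1")
    adults$role[adults$sample_id %in% rec_sid] <- "receptor"
    receptors[[length(receptors) + 1L]] <- tibble(
      sample_id = rec_sid, cluster_id = rec_cl, patch_id = pid,
      genet_id = adults$genet_id[match(rec_sid, adults$sample_id)],
      target_offspring = as.integer(.rztnb(n_rec, cfg$offspring_nb[["size"]],
                                           cfg$offspring_nb[["mu"]],
                                           max = cfg$offspring_nb[["max"]]))
    )
  }
  receptors <- bind_rows(receptors)

  genotypes <- adults
  for (loc in loci) {
    gi <- match(genotypes$genet_id, genets$genet_id)
    genotypes[[paste0(loc, "_1")]] <- genets[[paste0(loc, "_1")]][gi]
    genotypes[[paste0(loc, "_2")]] <- genets[[paste0(loc, "_2")]][gi]
  }
  genotypes <- select(genotypes, -"genet_id")

  list(genotypes = genotypes, clusters = clusters, genets = genets,
       receptors = receptors, freqs = panel, sample_genets = adults$genet_id,
       adult_sample_ids = adults$sample_id)
}

#' Simulate trapline-driven self-incompatible mating
#'
#' Foraging routes of 10-30 flower visits move among shoot clusters
#' (within-patch to one of the nearest clusters, or switching patch with
#' probability `p_switch`). Each visit adds the visited cluster's genet to
#' the forager's pollen load; a visit to a receptor cluster that still
#' needs offspring draws a donor from the load with geometric carryover
#' weights `kappa^age` and sires one ovule iff the self-incompatibility
#' check passes (donor MLG differs from the receptor's; optionally no
#' shared S-allele). Offspring genotypes are Mendelian draws.
#'
#' @param cfg A [sim_config()].
#' @param pops Output of [gen_populations()].
#' @param seed Integer seed.
#' @return List: `offspring` (allele-table rows), `truth` (tibble
#'   `offspring_id, receptor_id, receptor_patch, father_genet,
#'   father_cluster, father_patch, father_sampled, immigrant`),
#'   `shortfall` (receptors left short of their target), `event_log`
#'   (per-offspring route position of mother and donor).
#' @export
simulate_mating <- function(cfg, pops, seed = 1L) {
  set.seed(.sub_seed(seed, "routes"))
  clusters <- pops$clusters
  genets <- pops$genets
  receptors <- pops$receptors
  loci <- unique(pops$freqs$locus)
  n_cl <- nrow(clusters)

  # per-cluster genet lists and shoot-share weights
  gsplit <- split(seq_len(nrow(genets)), genets$cluster_id)
  cl_patch <- clusters$patch_id
  names(cl_patch) <- clusters$cluster_id

  # k-nearest within-patch neighbours
  nn <- vector("list", n_cl)
  for (pid in unique(clusters$patch_id)) {
    ix <- which(clusters$patch_id == pid)
    if (length(ix) == 1L) { nn[[ix]] <- ix; next }
    dm <- as.matrix(dist(cbind(clusters$x[ix], clusters$y[ix])))
    for (a in seq_along(ix)) {
      ord <- order(dm[a, ])[-1]
      nn[[ix[a]]] <- ix[head(ord, cfg$k_nearest)]
    }
  }
  patch_clusters <- split(seq_len(n_cl), clusters$patch_id)
  patch_ids <- names(patch_clusters)

  mlg_of <- function(gi) {
    paste(unlist(genets[gi, paste0(rep(loci, each = 2), c("_1", "_2"))]), collapse = "/")
  }
  genet_mlg <- vapply(seq_len(nrow(genets)), mlg_of, character(1))

  demand <- setNames(receptors$target_offspring, receptors$cluster_id)
  rec_by_cluster <- split(seq_len(nrow(receptors)), receptors$cluster_id)
  rec_genet_row <- match(receptors$genet_id, genets$genet_id)

  draw_route_seq <- function() {
    len <- sample(seq(cfg$route_length[1], cfg$route_length[2]), 1L)
    seq_out <- integer(len)
    cur <- sample.int(n_cl, 1L)
    seq_out[1] <- cur
    for (v in 2:len) {
      if (runif(1) < cfg$p_switch && length(patch_ids) > 1L) {
        other <- setdiff(patch_ids, cl_patch[[cur]])
        pid <- sample(other, 1L)
        cur <- sample(patch_clusters[[pid]], 1L)
      } else {
        cur <- if (length(nn[[cur]]) == 1L) nn[[cur]] else sample(nn[[cur]], 1L)
      }
      seq_out[v] <- cur
    }
    seq_out
  }

  fixed_routes <- if (cfg$repeat_routes) replicate(50, draw_route_seq(), simplify = FALSE)

  offspring <- list(); truth <- list(); events <- list()
  route_count <- 0L
  off_counter <- setNames(integer(nrow(receptors)), receptors$sample_id)
  while (any(demand > 0) && route_count < cfg$max_routes) {
    route_count <- route_count + 1L
    route <- if (cfg$repeat_routes) {
      fixed_routes[[(route_count - 1L) %% length(fixed_routes) + 1L]]
    } else draw_route_seq()
    load <- integer(0)  # genet row indices, most recent last
    for (v in seq_along(route)) {
      ci <- route[v]
      cl_id <- clusters$cluster_id[ci]
      # the flower visited belongs to one genet of the cluster (shoot share)
      rows <- gsplit[[cl_id]]
      gi <- if (length(rows) == 1L) rows else {
        sample(rows, 1L, prob = genets$n_shoots_genet[rows])
      }
      ri <- rec_by_cluster[[cl_id]]
      if (!is.null(ri) && demand[[cl_id]] > 0 && length(load) > 0) {
        ri <- ri[1]
        mother_row <- rec_genet_row[ri]
        ages <- rev(seq_along(load)) - 1L  # age 0 = most recent
        wts <- cfg$carryover^ages
        pos <- if (length(load) == 1L) 1L else sample(seq_along(load), 1L, prob = wts)
        donor_row <- load[pos]
        donor_age <- ages[pos]
        compatible <- genet_mlg[donor_row] != genet_mlg[mother_row]
        if (compatible && cfg$si_slocus) {
          pollen_s <- sample(c(genets$s1[donor_row], genets$s2[donor_row]), 1L)
          compatible <- !pollen_s %in% c(genets$s1[mother_row], genets$s2[mother_row])
        }
        if (compatible) {
          demand[[cl_id]] <- demand[[cl_id]] - 1L
          rid <- receptors$sample_id[ri]
          off_counter[[rid]] <- off_counter[[rid]] + 1L
          oid <- sprintf("%s_O%02d", rid, off_counter[[rid]])
          geno <- lapply(loci, function(loc) {
            ma <- c(genets[[paste0(loc, "_1")]][mother_row], genets[[paste0(loc, "_2")]][mother_row])
            fa <- c(genets[[paste0(loc, "_1")]][donor_row], genets[[paste0(loc, "_2")]][donor_row])
            a <- c(ma[sample.int(2L, 1L)], fa[sample.int(2L, 1L)])
            c(min(a), max(a))
          })
          row <- tibble(sample_id = oid, role = "offspring",
                        patch_id = receptors$patch_id[ri],
                        cluster_id = NA_character_, mother_id = rid,
                        x = NA_real_, y = NA_real_)
          for (li in seq_along(loci)) {
            row[[paste0(loci[li], "_1")]] <- as.integer(geno[[li]][1])
            row[[paste0(loci[li], "_2")]] <- as.integer(geno[[li]][2])
          }
          offspring[[length(offspring) + 1L]] <- row
          donor_gid <- genets$genet_id[donor_row]
          sampled_sid <- pops$adult_sample_ids[match(donor_gid, pops$sample_genets)]
          truth[[length(truth) + 1L]] <- tibble(
            offspring_id = oid, receptor_id = rid,
            receptor_patch = receptors$patch_id[ri],
            father_genet = donor_gid,
            father_cluster = genets$cluster_id[donor_row],
            father_patch = genets$patch_id[donor_row],
            father_sampled = !is.na(sampled_sid),
            father_sample_id = sampled_sid,
            immigrant = genets$patch_id[donor_row] != receptors$patch_id[ri]
          )
          events[[length(events) + 1L]] <- tibble(
            offspring_id = oid, route = route_count, visit = v,
            donor_age = donor_age
          )
        }
      }
      load <- c(load, gi)
    }
  }
  shortfall <- receptors[demand[receptors$cluster_id] > 0, c("sample_id", "cluster_id")]
  shortfall$remaining <- as.integer(demand[shortfall$cluster_id])
  list(
    offspring = if (length(offspring)) bind_rows(offspring) else NULL,
    truth = if (length(truth)) bind_rows(truth) else NULL,
    shortfall = shortfall,
    event_log = if (length(events)) bind_rows(events) else NULL,
    n_routes = route_count
  )
}

#' Apply genotyping error to an allele table
#'
#' Each typed allele slot is independently replaced, with probability
#' `error_rate`, by a random allele drawn from the locus allele
#' frequencies. Deterministic given `seed`.
#'
#' @param genotypes An allele table.
#' @param error_rate Per-slot error probability.
#' @param freqs Allele frequencies (tibble `locus, allele, freq`).
#' @param seed Integer seed.
#' @return Modified copy of `genotypes`.
#' @export
apply_genotyping_error <- function(genotypes, error_rate, freqs, seed = 1L) {
  set.seed(.sub_seed(seed, "errors"))
  if (error_rate == 0) return(genotypes)
  for (loc in unique(freqs$locus)) {
    f <- freqs[freqs$locus == loc, ]
    for (slot in c("_1", "_2")) {
      col <- paste0(loc, slot)
      v <- genotypes[[col]]
      typed <- which(v > 0)
      hit <- typed[runif(length(typed)) < error_rate]
      if (length(hit)) {
        v[hit] <- as.integer(sample(f$allele, length(hit), replace = TRUE, prob = f$freq))
        genotypes[[col]] <- v
      }
    }
  }
  genotypes
}

#' Simulate a complete synthetic study
#'
#' Chains [gen_landscape()], [gen_populations()], [simulate_mating()] and
#' (optionally) [apply_genotyping_error()], and assembles the combined
#' allele table. All stage seeds derive from the one master seed through
#' named substreams, so stages can be regenerated independently.
#'
#' @param cfg A [sim_config()].
#' @param seed Master seed.
#' @return List of class `sim_study`: `genotypes` (adults + offspring,
#'   with error applied when configured), `clusters`, `landscape`,
#'   `truth`, `receptors`, `freqs`, `genets`, `shortfall`, `event_log`.
#' @export
simulate_study <- function(cfg = sim_config(), seed = 1L) {
  land <- gen_landscape(cfg, seed)
  pops <- gen_populations(cfg, land, seed)
  mat <- simulate_mating(cfg, pops, seed)
  genotypes <- bind_rows(pops$genotypes, mat$offspring)
  if (cfg$apply_error && cfg$error_rate > 0) {
    genotypes <- apply_genotyping_error(genotypes, cfg$error_rate, pops$freqs, seed)
  }
  structure(
    list(genotypes = genotypes, clusters = pops$clusters, landscape = land,
         truth = mat$truth, receptors = pops$receptors, freqs = pops$freqs,
         genets = pops$genets, shortfall = mat$shortfall,
         event_log = mat$event_log, config = cfg, seed = seed),
    class = "sim_study"
  )
}

#' Per-receptor ground-truth pollen-flow proportions
#'
#' @param study A `sim_study` (or its `truth` tibble).
#' @return Tibble `receptor_id, n_offspring, true_within, true_immigrant`
#'   where `true_within + true_immigrant = 1` exactly.
#' @export
truth_receptor_summary <- function(study) {
  truth <- if (inherits(study, "sim_study")) study$truth else study
  truth %>%
    group_by(receptor_id = .data$receptor_id) %>%
    summarise(n_offspring = n(),
              true_within = mean(!.data$immigrant),
              true_immigrant = mean(.data$immigrant), .groups = "drop")
}

#' Write a synthetic study in the pipeline's input formats
#'
#' @param study A `sim_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$genotypes, file.path(dir, "allele_table.csv"), row.names = FALSE)
  utils::write.csv(study$clusters, file.path(dir, "clusters.csv"), row.names = FALSE)
  if (!is.null(study$truth)) {
    utils::write.csv(study$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  write_geojson(study$landscape$landuse, file.path(dir, "landuse.geojson"))
  write_geojson(study$landscape$elements, file.path(dir, "elements.geojson"))
  write_geojson(study$landscape$populations, file.path(dir, "populations.geojson"))
  invisible(dir)
}
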