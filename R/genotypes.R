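# Allele-table I/O, multilocus genotypes (MLGs), clone deduplication,
# clonality statistics, allele frequencies, mother-offspring compatibility.

#' Read and validate a microsatellite allele table
#'
#' The table has one row per sample with columns
#' `sample_id, role, patch_id, cluster_id, mother_id, x, y` followed by two
#' integer columns per locus (`<locus>_1`, `<locus>_2`; missing allele = 0).
#' Roles are `donor`, `receptor` (adults) and `offspring`; every offspring
#' must carry the `sample_id` of its maternal (receptor) plant in
#' `mother_id`.
#'
#' @param path Path to a CSV file.
#' @param loci Optional character vector naming the expected loci; defaults
#'   to all paired `<locus>_1`/`<locus>_2` columns found.
#' @return A validated tibble (the "allele table") with one row per sample.
#' @export
read_allele_table <- function(path, loci = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(sample_id = "character"))
  validate_allele_table(as_tibble(raw), loci = loci)
}

#' Validate an in-memory allele table
#'
#' @param genotypes A data frame shaped like [read_allele_table()] output.
#' @inheritParams read_allele_table
#' @return The validated tibble.
#' @export
validate_allele_table <- function(genotypes, loci = NULL) {
  gs <- as_tibble(genotypes)
  need <- c("sample_id", "role", "patch_id")
  miss <- setdiff(need, names(gs))
  if (length(miss)) abort(paste0("allele table lacks column(s): ", paste(miss, collapse = ", ")))
  if (!"cluster_id" %in% names(gs)) gs$cluster_id <- NA_character_
  if (!"mother_id" %in% names(gs)) gs$mother_id <- NA_character_
  if (!"x" %in% names(gs)) gs$x <- NA_real_
  if (!"y" %in% names(gs)) gs$y <- NA_real_
  gs$sample_id <- as.character(gs$sample_id)
  gs$mother_id <- as.character(gs$mother_id)
  gs$cluster_id <- as.character(gs$cluster_id)
  gs$patch_id <- as.character(gs$patch_id)
  gs$mother_id[!is.na(gs$mother_id) & gs$mother_id == ""] <- NA_character_

  found <- locus_names(gs)
  if (is.null(loci)) loci <- found else {
    missing_loci <- setdiff(loci, found)
    if (length(missing_loci)) abort(paste0("locus column(s) absent: ", paste(missing_loci, collapse = ", ")))
  }
  gs <- gs[, c(.reserved_cols, as.vector(rbind(paste0(loci, "_1"), paste0(loci, "_2"))))]

  bad_role <- which(!gs$role %in% .roles)
  if (length(bad_role)) {
    abort(paste0("unknown role '", gs$role[bad_role[1]], "' in row ", bad_role[1]))
  }
  dup <- gs$sample_id[duplicated(gs$sample_id)]
  if (length(dup)) abort(paste0("duplicate sample_id: ", paste(unique(dup), collapse = ", ")))
  no_mother <- which(gs$role == "offspring" & (is.na(gs$mother_id)))
  if (length(no_mother)) {
    abort(paste0("offspring without mother_id in row(s): ", paste(no_mother, collapse = ", ")))
  }
  known_mother <- gs$mother_id %in% gs$sample_id[gs$role == "receptor"]
  orphan <- which(gs$role == "offspring" & !known_mother)
  if (length(orphan)) {
    abort(paste0("offspring mother_id not a receptor sample_id in row(s): ",
                 paste(orphan, collapse = ", ")))
  }
  for (loc in loci) {
    m <- .locus_mat(gs, loc)
    if (!is.numeric(m)) abort(paste0("non-numeric alleles at locus ", loc))
    bad <- which(rowSums(m < 0 | m != floor(m)) > 0)
    if (length(bad)) {
      abort(paste0("malformed allele at locus ", loc, " in row ", bad[1],
                   " (sample ", gs$sample_id[bad[1]], ")"))
    }
    half <- which(xor(m[, 1] == 0, m[, 2] == 0))
    if (length(half)) {
      abort(paste0("half-missing genotype at locus ", loc, " in row ", half[1],
                   " (one allele 0, the other typed)"))
    }
  }
  gs
}

#' Canonical MLG keys
#'
#' Returns, per sample, a deterministic multilocus-genotype key: the per-locus
#' allele pair sorted within each locus and concatenated in panel order.
#' Under the strict missing-data policy (the default throughout the package)
#' a sample with a missing locus never shares a key with a fully typed
#' sample.
#'
#' @param genotypes An allele table.
#' @param loci Loci to use (default: all).
#' @return Character vector of MLG keys, one per row of `genotypes`.
#' @export
mlg_key <- function(genotypes, loci = locus_names(genotypes)) {
  parts <- lapply(loci, function(loc) {
    m <- .locus_mat(genotypes, loc)
    paste0(pmin(m[, 1], m[, 2]), "/", pmax(m[, 1], m[, 2]))
  })
  all_missing <- Reduce(`&`, lapply(loci, function(loc) {
    m <- .locus_mat(genotypes, loc)
    m[, 1] == 0 & m[, 2] == 0
  }))
  if (any(all_missing)) {
    abort(paste0("sample(s) with all loci missing: ",
                 paste(genotypes$sample_id[all_missing], collapse = ", ")))
  }
  do.call(paste, c(parts, sep = ";"))
}

# TRUE iff samples i and j match under the tolerant policy: equal sorted
# pairs at every locus typed in both, with at least one such locus.
.mlg_match_tolerant <- function(keys_split, typed) {
  n <- nrow(typed)
  pairs <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- typed[i, ] & typed[j, ]
      if (any(both) && all(keys_split[i, both] == keys_split[j, both])) {
        pairs[[length(pairs) + 1L]] <- c(i, j)
      }
    }
  }
  pairs
}

#' Find repeated multilocus genotypes
#'
#' Groups samples sharing an identical MLG. Under `policy = "strict"`
#' (default) two samples match iff their full keys are byte-equal, so a
#' missing locus never matches a typed one. Under `policy = "tolerant"`
#' samples match when they agree at every locus typed in both, and groups
#' are formed by single linkage over pairwise matches.
#'
#' @param genotypes An allele table.
#' @param policy `"strict"` or `"tolerant"` missing-data policy.
#' @return Tibble with one row per repeated-MLG group (>= 2 members):
#'   `mlg_key`, `n`, and a list-column `sample_ids`.
#' @export
find_repeated_mlgs <- function(genotypes, policy = c("strict", "tolerant")) {
  policy <- match.arg(policy)
  loci <- locus_names(genotypes)
  keys <- mlg_key(genotypes, loci)
  if (policy == "strict") {
    grp <- split(genotypes$sample_id, keys)
    grp <- grp[lengths(grp) >= 2L]
    out <- tibble(
      mlg_key = names(grp),
      n = lengths(grp),
      sample_ids = lapply(unname(grp), sort)
    )
    return(arrange(out, dplyr::desc(.data$n), .data$mlg_key))
  }
  # tolerant: union-find over pairwise matches
  n <- nrow(genotypes)
  keys_split <- do.call(rbind, strsplit(keys, ";", fixed = TRUE))
  typed <- do.call(cbind, lapply(loci, function(loc) {
    m <- .locus_mat(genotypes, loc)
    m[, 1] > 0 & m[, 2] > 0
  }))
  parent <- seq_len(n)
  findp <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (p in .mlg_match_tolerant(keys_split, typed)) {
    ri <- findp(p[1]); rj <- findp(p[2])
    if (ri != rj) parent[rj] <- ri
  }
  roots <- vapply(seq_len(n), findp, integer(1))
  grp <- split(seq_len(n), roots)
  grp <- grp[lengths(grp) >= 2L]
  out <- tibble(
    mlg_key = vapply(grp, function(ix) keys[ix[1]], character(1)),
    n = lengths(grp),
    sample_ids = lapply(unname(grp), function(ix) sort(genotypes$sample_id[ix]))
  )
  arrange(out, dplyr::desc(.data$n), .data$mlg_key)
}

#' Repeated-MLG counts under the three counting conventions
#'
#' The number of "repeated MLGs" in a data set is ambiguous; this reports
#' all three readings: the number of groups sharing a key, the number of
#' samples involved in any group, and the number of redundant copies
#' (samples minus groups).
#'
#' @inheritParams find_repeated_mlgs
#' @return One-row tibble: `n_groups`, `n_samples_involved`, `n_redundant`.
#' @export
repeated_mlg_counts <- function(genotypes, policy = c("strict", "tolerant")) {
  g <- find_repeated_mlgs(genotypes, policy)
  tibble(
    n_groups = nrow(g),
    n_samples_involved = sum(g$n),
    n_redundant = sum(g$n) - nrow(g)
  )
}

#' Remove clonal duplicates from an allele table
#'
#' Within each repeated-MLG group, adults that are not pollen receptors are
#' removed first (receptors are always kept); when a group contains only
#' non-receptor adults, the lexicographically smallest `sample_id` is kept.
#' Offspring are removed only as "apparent twins": several offspring of the
#' same mother sharing one MLG collapse to the smallest `sample_id`.
#' Offspring sharing an MLG with an adult (for example their own mother) are
#' retained, so the output may legitimately still contain repeated MLGs in
#' parent-offspring pairs.
#'
#' @inheritParams find_repeated_mlgs
#' @return List with `genotypes` (deduplicated tibble) and `removal_log`
#'   (tibble `sample_id, reason, kept_twin_of`).
#' @export
deduplicate_genotypes <- function(genotypes, policy = c("strict", "tolerant")) {
  policy <- match.arg(policy)
  groups <- find_repeated_mlgs(genotypes, policy)
  role <- setNames(genotypes$role, genotypes$sample_id)
  mother <- setNames(genotypes$mother_id, genotypes$sample_id)
  log <- list()
  for (ids in groups$sample_ids) {
    adults <- ids[role[ids] != "offspring"]
    if (length(adults) >= 2L) {
      receptors <- adults[role[adults] == "receptor"]
      donors <- sort(adults[role[adults] == "donor"])
      if (length(receptors) > 0L) {
        keep <- sort(receptors)[1]
        drop <- donors
        reason <- "duplicate_of_receptor"
      } else {
        keep <- donors[1]
        drop <- donors[-1]
        reason <- "duplicate_mlg"
      }
      if (length(drop)) {
        log[[length(log) + 1L]] <- tibble(sample_id = drop, reason = reason, kept_twin_of = keep)
      }
    }
    offs <- ids[role[ids] == "offspring"]
    if (length(offs) >= 2L) {
      by_mother <- split(offs, mother[offs])
      for (twin_set in by_mother) {
        if (length(twin_set) >= 2L) {
          twin_set <- sort(twin_set)
          log[[length(log) + 1L]] <- tibble(
            sample_id = twin_set[-1], reason = "apparent_twin", kept_twin_of = twin_set[1]
          )
        }
      }
    }
  }
  removal_log <- if (length(log)) bind_rows(log) else {
    tibble(sample_id = character(), reason = character(), kept_twin_of = character())
  }
  list(
    genotypes = filter(genotypes, !.data$sample_id %in% removal_log$sample_id),
    removal_log = removal_log
  )
}

#' Clonality of shoot clusters
#'
#' A cluster is monoclonal iff all its sampled shoots share one MLG.
#' Clusters are binned by shoot count into the size classes `<5`, `5-20`
#' and `>20`; clusters with a single sampled shoot carry no information on
#' clonality and are excluded from all denominators (their number is
#' reported).
#'
#' @param genotypes An allele table; only adult rows are used.
#' @param shoots_per_cluster Tibble/data frame with columns `cluster_id`,
#'   `n_shoots`.
#' @return Object of class `clonality_report`: a list with
#'   `overall_monoclonal_fraction`, `by_size_class` (tibble), `n_clusters`
#'   and `n_singleton_excluded`.
#' @export
clonality_report <- function(genotypes, shoots_per_cluster) {
  adults <- filter(genotypes, .data$role != "offspring", !is.na(.data$cluster_id))
  if (nrow(adults) == 0L) abort("no adult samples with cluster_id")
  keys <- mlg_key(adults)
  per <- tibble(cluster_id = adults$cluster_id, key = keys) %>%
    group_by(.data$cluster_id) %>%
    summarise(n_sampled = n(), monoclonal = dplyr::n_distinct(.data$key) == 1L, .groups = "drop")
  singletons <- sum(per$n_sampled < 2L)
  per <- filter(per, .data$n_sampled >= 2L)
  if (nrow(per) == 0L) abort("no cluster with >= 2 genotyped shoots")
  shoots <- as_tibble(shoots_per_cluster)
  per <- left_join(per, shoots[, c("cluster_id", "n_shoots")], by = "cluster_id")
  if (anyNA(per$n_shoots)) abort("shoot count missing for some clusters")
  per$size_class <- cut(per$n_shoots, breaks = c(-Inf, 4.5, 20.5, Inf),
                        labels = c("<5", "5-20", ">20"))
  by_class <- per %>%
    group_by(size_class = as.character(.data$size_class)) %>%
    summarise(n_clusters = n(), n_monoclonal = sum(.data$monoclonal),
              prop_monoclonal = mean(.data$monoclonal), .groups = "drop")
  out <- list(
    overall_monoclonal_fraction = mean(per$monoclonal),
    by_size_class = by_class,
    n_clusters = nrow(per),
    n_singleton_excluded = singletons,
    clusters = per
  )
  class(out) <- "clonality_report"
  out
}

#' @export
print.clonality_report <- function(x, ...) {
  cat("Clonality report:", x$n_clusters, "clusters with >= 2 sampled shoots",
      sprintf("(%d single-shoot clusters excluded)\n", x$n_singleton_excluded))
  cat(sprintf("  overall monoclonal fraction: %.3f\n", x$overall_monoclonal_fraction))
  print(x$by_size_class)
  invisible(x)
}

#' @export
tidy.clonality_report <- function(x, ...) {
  bind_rows(
    x$by_size_class,
    tibble(size_class = "overall", n_clusters = x$n_clusters,
           n_monoclonal = sum(x$by_size_class$n_monoclonal),
           prop_monoclonal = x$overall_monoclonal_fraction)
  )
}

#' Per-locus allele frequencies
#'
#' Relative allele frequencies per locus over the typed gene copies of the
#' given samples; missing slots (0) are excluded from the counts.
#'
#' @param genotypes An allele table (pre-filter rows to choose the subset).
#' @param loci Loci to tabulate (default: all).
#' @return Tibble `locus, allele, count, freq`; frequencies sum to 1 within
#'   each locus.
#' @export
allele_frequencies <- function(genotypes, loci = locus_names(genotypes)) {
  out <- lapply(loci, function(loc) {
    m <- .locus_mat(genotypes, loc)
    a <- c(m[, 1], m[, 2])
    a <- a[a > 0]
    if (length(a) == 0L) abort(paste0("locus ", loc, " has no typed samples"))
    tb <- table(a)
    tibble(locus = loc, allele = as.integer(names(tb)),
           count = as.integer(tb), freq = as.numeric(tb) / length(a))
  })
  bind_rows(out)
}

# Named list of per-locus frequency vectors (names = allele codes).
.freq_list <- function(freqs) {
  lapply(split(freqs, freqs$locus), function(d) setNames(d$freq, d$allele))
}

#' Enforce mother-offspring Mendelian compatibility
#'
#' For every offspring, loci where it shares no allele with its mother are
#' reset to missing ("0 0"), up to `max_mismatch` loci; offspring exceeding
#' the threshold are flagged `incompatible` and should be excluded from
#' paternity assignment.
#'
#' @param genotypes An allele table containing offspring and their mothers.
#' @param max_mismatch Maximum number of mismatching loci that are reset
#'   (default 1).
#' @return List with `genotypes` (modified copy) and `log` (tibble
#'   `offspring_id, mother_id, n_mismatch, loci_reset, status` with status
#'   `ok`, `resolved` or `incompatible`).
#' @export
resolve_mother_mismatches <- function(genotypes, max_mismatch = 1L) {
  loci <- locus_names(genotypes)
  gs <- genotypes
  off_idx <- which(gs$role == "offspring")
  mother_row <- match(gs$mother_id[off_idx], gs$sample_id)
  if (anyNA(mother_row)) abort("offspring with unknown mother_id")
  logs <- vector("list", length(off_idx))
  for (k in seq_along(off_idx)) {
    i <- off_idx[k]; m <- mother_row[k]
    mism <- character(0)
    for (loc in loci) {
      o <- c(gs[[paste0(loc, "_1")]][i], gs[[paste0(loc, "_2")]][i])
      mo <- c(gs[[paste0(loc, "_1")]][m], gs[[paste0(loc, "_2")]][m])
      if (all(o > 0) && all(mo > 0) && !any(o %in% mo)) mism <- c(mism, loc)
    }
    n_mism <- length(mism)
    if (n_mism == 0L) {
      status <- "ok"; reset <- character(0)
    } else if (n_mism <= max_mismatch) {
      status <- "resolved"; reset <- mism
      for (loc in mism) {
        gs[[paste0(loc, "_1")]][i] <- 0L
        gs[[paste0(loc, "_2")]][i] <- 0L
      }
    } else {
      status <- "incompatible"; reset <- character(0)
    }
    logs[[k]] <- tibble(
      offspring_id = gs$sample_id[i], mother_id = gs$sample_id[m],
      n_mismatch = n_mism, loci_reset = paste(reset, collapse = ";"),
      status = status
    )
  }
  log <- if (length(logs)) bind_rows(logs) else {
    tibble(offspring_id = character(), mother_id = character(),
           n_mismatch = integer(), loci_reset = character(), status = character())
  }
  list(genotypes = gs, log = log)
}
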