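# Stage orchestration: simulate -> qc -> assign -> metrics -> landscape ->
# model, behind one entry point with a YAML run configuration, a manifest
# and atomic, deterministic outputs.

.stages <- c("simulate", "qc", "assign", "metrics", "landscape", "model")

#' Default run configuration
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param seed Master seed.
#' @param sim Named list of [sim_config()] overrides.
#' @param paternity Named list of [paternity_config()] overrides.
#' @param rarefaction_g Rarefaction depth in individuals.
#' @param min_offspring Receptor exclusion threshold.
#' @param radii Buffer radii.
#' @param screen_alpha,collinearity_r,delta_aicc,gh_nodes Model settings.
#' @return Named list, the run configuration.
#' @export
run_config <- function(out_dir = "pollenscape_run", seed = 1L,
                       sim = list(), paternity = list(),
                       rarefaction_g = 5L, min_offspring = 5L,
                       radii = c(50, 250, 1000),
                       screen_alpha = 0.15, collinearity_r = 0.7,
                       delta_aicc = 2.0, gh_nodes = 9L) {
  list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
       paternity = paternity, rarefaction_g = as.integer(rarefaction_g),
       min_offspring = as.integer(min_offspring), radii = radii,
       screen_alpha = screen_alpha, collinearity_r = collinearity_r,
       delta_aicc = delta_aicc, gh_nodes = as.integer(gh_nodes))
}

#' Read a YAML run configuration
#'
#' @param path YAML file; keys as in [run_config()].
#' @return A run configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  cfg <- yaml::read_yaml(path)
  do.call(run_config, utils::modifyList(
    list(), cfg[intersect(names(cfg), names(formals(run_config)))]
  ))
}

# Atomic CSV/JSON writers: write to a temp file in the same directory,
# then rename.
.write_atomic <- function(write_fun, path) {
  tmp <- paste0(path, ".tmp")
  write_fun(tmp)
  file.rename(tmp, path)
  invisible(path)
}

.write_csv_atomic <- function(df, path) {
  .write_atomic(function(p) utils::write.csv(df, p, row.names = FALSE), path)
}

.write_json_atomic <- function(x, path) {
  .write_atomic(function(p) jsonlite::write_json(x, p, auto_unbox = TRUE,
                                                 digits = NA, pretty = TRUE), path)
}

# Update the run manifest with a stage record.
.update_manifest <- function(cfg, stage, counts) {
  path <- file.path(cfg$out_dir, "manifest.json")
  manifest <- if (file.exists(path)) jsonlite::read_json(path) else list()
  cfg_path <- file.path(cfg$out_dir, "run_config.yaml")
  .write_atomic(function(p) yaml::write_yaml(cfg, p), cfg_path)
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))
  manifest$seed <- cfg$seed
  manifest$package_version <- as.character(utils::packageVersion("pollenscape"))
  manifest$stages[[stage]] <- list(rows = counts)
  .write_json_atomic(manifest, path)
}

.need_artifact <- function(cfg, file, stage, wanted_by) {
  path <- file.path(cfg$out_dir, file)
  if (!file.exists(path)) {
    abort(sprintf("stage '%s' needs artifact '%s' (run stage '%s' first)",
                  wanted_by, file, stage))
  }
  path
}

#' Run one pipeline stage (or all)
#'
#' Stages: `simulate` (synthetic study in the pipeline's input formats),
#' `qc` (validation, deduplication, clonality, MLG counts), `assign`
#' (consensus paternity), `metrics` (receptor and donor pollen-flow
#' summaries), `landscape` (metric table in the configured buffers),
#' `model` (screening, collinearity filter, all-subsets AICc averaging for
#' the three response families), `all` (chains everything). Outputs are
#' written atomically; `manifest.json` records the config hash, seed,
#' package version and per-stage row counts.
#'
#' @param stage Stage name.
#' @param config A run configuration ([run_config()] /
#'   [read_run_config()]) or a path to a YAML file.
#' @return Invisible named list of artifact paths written by the stage.
#' @export
run_stage <- function(stage = c("all", .stages), config = run_config()) {
  stage <- match.arg(stage)
  cfg <- if (is.character(config)) read_run_config(config) else config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (stage == "all") {
    out <- list()
    for (s in .stages) out <- c(out, run_stage(s, cfg))
    return(invisible(out))
  }
  switch(stage,
    simulate = .stage_simulate(cfg),
    qc = .stage_qc(cfg),
    assign = .stage_assign(cfg),
    metrics = .stage_metrics(cfg),
    landscape = .stage_landscape(cfg),
    model = .stage_model(cfg)
  )
}

.stage_simulate <- function(cfg) {
  sc <- do.call(sim_config, cfg$sim)
  study <- simulate_study(sc, seed = cfg$seed)
  d <- cfg$out_dir
  .write_csv_atomic(study$genotypes, file.path(d, "allele_table.csv"))
  .write_csv_atomic(study$clusters, file.path(d, "clusters.csv"))
  .write_csv_atomic(study$truth, file.path(d, "truth.csv"))
  write_geojson(study$landscape$landuse, file.path(d, "landuse.geojson"))
  write_geojson(study$landscape$elements, file.path(d, "elements.geojson"))
  write_geojson(study$landscape$populations, file.path(d, "populations.geojson"))
  patches <- study$landscape$patches
  .write_csv_atomic(
    tibble(patch_id = patches$patch_id,
           ring = vapply(patches$geometry, function(g) {
             paste(apply(.close_ring(g), 1, paste, collapse = " "), collapse = ";")
           }, character(1))),
    file.path(d, "patches.csv")
  )
  .update_manifest(cfg, "simulate",
                   list(samples = nrow(study$genotypes), clusters = nrow(study$clusters),
                        offspring = sum(study$genotypes$role == "offspring")))
  invisible(list(allele_table = file.path(d, "allele_table.csv")))
}

.read_patches_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble(
    patch_id = d$patch_id, occupied = TRUE, geometry_type = "Polygon",
    geometry = lapply(d$ring, function(s) {
      do.call(rbind, lapply(strsplit(s, ";")[[1]], function(p) as.numeric(strsplit(p, " ")[[1]])))
    })
  )
}

.stage_qc <- function(cfg) {
  at <- .need_artifact(cfg, "allele_table.csv", "simulate", "qc")
  cl <- .need_artifact(cfg, "clusters.csv", "simulate", "qc")
  gs <- read_allele_table(at)
  clusters <- as_tibble(utils::read.csv(cl, stringsAsFactors = FALSE))
  dedup <- deduplicate_genotypes(gs)
  counts <- repeated_mlg_counts(gs)
  clon <- clonality_report(gs, clusters)
  d <- cfg$out_dir
  .write_csv_atomic(dedup$genotypes, file.path(d, "genotypes_qc.csv"))
  .write_csv_atomic(dedup$removal_log, file.path(d, "removal_log.csv"))
  .write_json_atomic(list(
    repeated_mlgs = as.list(counts),
    clonality = list(
      overall_monoclonal_fraction = clon$overall_monoclonal_fraction,
      by_size_class = clon$by_size_class,
      n_clusters = clon$n_clusters,
      n_singleton_excluded = clon$n_singleton_excluded
    )
  ), file.path(d, "qc_report.json"))
  .update_manifest(cfg, "qc", list(kept = nrow(dedup$genotypes),
                                   removed = nrow(dedup$removal_log)))
  invisible(list(genotypes_qc = file.path(d, "genotypes_qc.csv")))
}

.stage_assign <- function(cfg) {
  gq <- .need_artifact(cfg, "genotypes_qc.csv", "qc", "assign")
  gs <- read_allele_table(gq)
  pc <- do.call(paternity_config, utils::modifyList(list(seed = cfg$seed), cfg$paternity))
  res <- assign_paternity(gs, pc)
  d <- cfg$out_dir
  .write_csv_atomic(res$consensus, file.path(d, "assignments.csv"))
  if (length(res$runs)) {
    .write_csv_atomic(bind_rows(res$runs), file.path(d, "assignment_runs.csv"))
  }
  .write_atomic(function(p) yaml::write_yaml(unclass(pc), p),
                file.path(d, "paternity_config.yaml"))
  .update_manifest(cfg, "assign",
                   list(offspring = nrow(res$consensus),
                        assigned = sum(res$consensus$status == "assigned")))
  invisible(list(assignments = file.path(d, "assignments.csv")))
}

.stage_metrics <- function(cfg) {
  as_path <- .need_artifact(cfg, "assignments.csv", "assign", "metrics")
  gq <- .need_artifact(cfg, "genotypes_qc.csv", "qc", "metrics")
  cl <- .need_artifact(cfg, "clusters.csv", "simulate", "metrics")
  cons <- as_tibble(utils::read.csv(as_path, stringsAsFactors = FALSE))
  gs <- read_allele_table(gq)
  clusters <- as_tibble(utils::read.csv(cl, stringsAsFactors = FALSE))
  patches_path <- file.path(cfg$out_dir, "patches.csv")
  patches <- if (file.exists(patches_path)) .read_patches_csv(patches_path) else NULL
  rs <- receptor_summaries(cons, gs, g_individuals = cfg$rarefaction_g,
                           min_offspring = cfg$min_offspring)
  ds <- donor_statistics(cons, gs, clusters, patches)
  d <- cfg$out_dir
  .write_csv_atomic(rs, file.path(d, "receptor_summary.csv"))
  .write_csv_atomic(ds$donors, file.path(d, "donor_summary.csv"))
  .write_json_atomic(as.list(ds$aggregate), file.path(d, "geneflow_aggregate.json"))
  .update_manifest(cfg, "metrics", list(receptors = nrow(rs), donors = nrow(ds$donors)))
  invisible(list(receptor_summary = file.path(d, "receptor_summary.csv")))
}

.stage_landscape <- function(cfg) {
  rs_path <- .need_artifact(cfg, "receptor_summary.csv", "metrics", "landscape")
  gq <- .need_artifact(cfg, "genotypes_qc.csv", "qc", "landscape")
  lu <- .need_artifact(cfg, "landuse.geojson", "simulate", "landscape")
  el <- .need_artifact(cfg, "elements.geojson", "simulate", "landscape")
  pp <- .need_artifact(cfg, "populations.geojson", "simulate", "landscape")
  rs <- as_tibble(utils::read.csv(rs_path, stringsAsFactors = FALSE))
  gs <- read_allele_table(gq)
  rec <- filter(gs, .data$role == "receptor", .data$sample_id %in% rs$receptor_id)
  receptors <- tibble(receptor_id = rec$sample_id, patch_id = rec$patch_id,
                      x = rec$x, y = rec$y)
  lmt <- landscape_metric_table(receptors, read_geojson(lu), read_geojson(el),
                                read_geojson(pp), radii = cfg$radii)
  .write_csv_atomic(lmt, file.path(cfg$out_dir, "landscape_metrics.csv"))
  .update_manifest(cfg, "landscape", list(rows = nrow(lmt)))
  invisible(list(landscape_metrics = file.path(cfg$out_dir, "landscape_metrics.csv")))
}

# Model stage: PF_within (ZI-binomial) and A_r (LMM) against the landscape
# metrics per radius; within-patch donation (ZI-Poisson) against cluster
# size and edge distance.
.stage_model <- function(cfg) {
  rs_path <- .need_artifact(cfg, "receptor_summary.csv", "metrics", "model")
  lm_path <- .need_artifact(cfg, "landscape_metrics.csv", "landscape", "model")
  rs <- as_tibble(utils::read.csv(rs_path, stringsAsFactors = FALSE))
  lmt <- as_tibble(utils::read.csv(lm_path, stringsAsFactors = FALSE))
  d <- cfg$out_dir
  reports <- list(); sel_tables <- list()
  for (radius in cfg$radii) {
    metrics_r <- filter(lmt, .data$radius == !!radius)
    data <- left_join(filter(rs, !.data$excluded), metrics_r, by = "receptor_id")
    metric_cols <- intersect(
      c("SEMNATGRASS", "RAPESEED", "MAIZE", "L_ROAD", "L_WATER", "L_WOOD", "N_P"),
      names(metrics_r)
    )
    metric_cols <- metric_cols[vapply(metric_cols, function(m) {
      v <- data[[m]]
      sum(!is.na(v)) >= 3 && sd(v, na.rm = TRUE) > 0
    }, logical(1))]
    if (length(metric_cols) == 0L || nrow(data) < 10L) next
    std <- standardize_metrics(data, metric_cols)
    data <- std$data
    metric_cols <- setdiff(metric_cols, std$dropped)
    op_map <- c(L_ROAD = "OP_ROAD", L_WATER = "OP_WATER", L_WOOD = "OP_WOOD")
    op_map <- op_map[names(op_map) %in% metric_cols]
    area <- intersect(c("SEMNATGRASS", "RAPESEED", "MAIZE"), metric_cols)
    for (resp in c("pf_within", "a_r")) {
      spec <- if (resp == "pf_within") {
        model_spec("zibinomial", response = "n_within", trials = "n_offspring",
                   gh_nodes = cfg$gh_nodes)
      } else {
        model_spec("lmm", response = "a_r")
      }
      fit_data <- data[complete.cases(data[, c(spec$response, metric_cols)]), ]
      if (nrow(fit_data) < 10L) next
      # orientation ratios with missing values cannot enter interactions
      # without changing the common sample, so they are only offered when
      # complete
      op_ok <- op_map[vapply(op_map, function(cl) {
        cl %in% names(fit_data) && !anyNA(fit_data[[cl]])
      }, logical(1))]
      scr <- screen_metrics(fit_data, metric_cols, spec, alpha = cfg$screen_alpha,
                            area_metrics = area, op_map = op_ok)
      kept_metrics <- unique(scr$metric[!is.na(scr$keep) & scr$keep])
      excl <- collinearity_filter(fit_data, kept_metrics, r_max = cfg$collinearity_r)
      avg <- tryCatch(
        all_subsets_average(fit_data, spec, scr, excl, delta_max = cfg$delta_aicc),
        error = function(e) NULL
      )
      if (is.null(avg)) next
      reports[[length(reports) + 1L]] <- mutate(avg$coefficients,
                                                response = resp, radius = radius)
      sel_tables[[length(sel_tables) + 1L]] <- mutate(avg$selection,
                                                      response = resp, radius = radius)
    }
  }
  if (length(reports)) {
    .write_csv_atomic(bind_rows(reports), file.path(d, "model_report.csv"))
    .write_csv_atomic(bind_rows(sel_tables), file.path(d, "selection_table.csv"))
  } else {
    .write_csv_atomic(tibble(), file.path(d, "model_report.csv"))
    .write_csv_atomic(tibble(), file.path(d, "selection_table.csv"))
  }
  .update_manifest(cfg, "model", list(reports = length(reports)))
  invisible(list(model_report = file.path(d, "model_report.csv")))
}
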