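# Landscape composition metrics in circular buffers around pollen
# receptors: percent cover, linear-element lengths, orthogonal-to-parallel
# ratios, population counts.

.landuse_classes <- c("SEMNATGRASS", "RAPESEED", "MAIZE", "OTHER")
.linear_types <- c("L_ROAD", "L_WATER", "L_WOOD")
.buffer_radii <- c(50, 250, 1000)

# Table-style radius availability per metric.
.metric_radii <- list(
  SEMNATGRASS = 1000, RAPESEED = 1000, MAIZE = c(50, 250, 1000),
  L_ROAD = c(50, 250, 1000), L_WATER = c(50, 250, 1000), L_WOOD = c(250, 1000),
  OP_ROAD = c(50, 250, 1000), OP_WATER = c(50, 250, 1000), OP_WOOD = c(250, 1000),
  N_P = c(250, 1000)
)

.check_radius <- function(metric, radius, allow_custom = FALSE) {
  if (allow_custom) return(invisible(TRUE))
  ok <- .metric_radii[[metric]]
  if (!is.null(ok) && !radius %in% ok) {
    abort(sprintf("metric %s is not defined at a %g m radius (available: %s)",
                  metric, radius, paste(ok, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Read a GeoJSON FeatureCollection of polygons or polylines
#'
#' Minimal reader for planar (pre-projected, metric) GeoJSON as produced by
#' [write_geojson()] and typical GIS exports: `Polygon` features (outer
#' ring only) and `LineString` features, with scalar properties.
#'
#' @param path Path to a GeoJSON file.
#' @return Tibble with one row per feature: the feature properties plus a
#'   `geometry` list-column of n x 2 coordinate matrices and a
#'   `geometry_type` column.
#' @export
read_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) abort("not a GeoJSON FeatureCollection")
  rows <- lapply(gj$features, function(f) {
    typ <- f$geometry$type
    coords <- f$geometry$coordinates
    mat <- switch(typ,
      Polygon = do.call(rbind, lapply(coords[[1]], function(p) unlist(p))),
      LineString = do.call(rbind, lapply(coords, function(p) unlist(p))),
      Point = matrix(unlist(coords), 1, 2),
      abort(paste0("unsupported geometry type: ", typ))
    )
    props <- lapply(f$properties, function(x) if (is.null(x)) NA else x)
    c(props, list(geometry_type = typ, geometry = list(mat)))
  })
  bind_rows(lapply(rows, function(r) as_tibble(r)))
}

#' Write a layer tibble to GeoJSON
#'
#' @param layer Tibble with a `geometry` list-column (n x 2 matrices), a
#'   `geometry_type` column (`Polygon`, `LineString` or `Point`) and any
#'   further property columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(layer, path) {
  props <- setdiff(names(layer), c("geometry", "geometry_type"))
  features <- lapply(seq_len(nrow(layer)), function(i) {
    mat <- layer$geometry[[i]]
    typ <- layer$geometry_type[i]
    coords <- switch(typ,
      Polygon = {
        ring <- .close_ring(mat)
        list(lapply(seq_len(nrow(ring)), function(j) as.numeric(ring[j, ])))
      },
      LineString = lapply(seq_len(nrow(mat)), function(j) as.numeric(mat[j, ])),
      Point = as.numeric(mat[1, ]),
      abort(paste0("unsupported geometry type: ", typ))
    )
    list(
      type = "Feature",
      properties = as.list(layer[i, props, drop = FALSE]),
      geometry = list(type = typ, coordinates = coords)
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA, pretty = FALSE
  )
  invisible(path)
}

#' Percent cover of a land-use class in a buffer
#'
#' `100 * area(buffer intersect class polygons) / area(buffer)`. Map area
#' not covered by any polygon counts as `OTHER`, which is therefore
#' computed as the remainder over the explicit classes.
#'
#' @param landuse Land-use layer tibble (`class`, `geometry` columns).
#' @param center Length-2 numeric: buffer center (receptor position).
#' @param radius Buffer radius in meters.
#' @param class One of `SEMNATGRASS`, `RAPESEED`, `MAIZE`, `OTHER`.
#' @param allow_custom Skip the radius-availability check (default FALSE).
#' @return Percent in \[0, 100\].
#' @export
percent_cover <- function(landuse, center, radius, class, allow_custom = FALSE) {
  class <- match.arg(class, .landuse_classes)
  if (class != "OTHER") .check_radius(class, radius, allow_custom)
  buffer_area <- pi * radius^2
  cover_of <- function(cls) {
    polys <- landuse$geometry[landuse$class == cls]
    if (length(polys) == 0L) return(0)
    sum(vapply(polys, circle_polygon_area, numeric(1), center = center, radius = radius))
  }
  if (class == "OTHER") {
    known <- sum(vapply(setdiff(.landuse_classes, "OTHER"), cover_of, numeric(1)))
    return(max(0, 100 * (1 - known / buffer_area)))
  }
  100 * cover_of(class) / buffer_area
}

#' Total clipped length of linear elements in a buffer
#'
#' @param elements Linear-element layer tibble (`type`, `geometry`).
#' @inheritParams percent_cover
#' @param type One of `L_ROAD`, `L_WATER`, `L_WOOD`.
#' @return Length in meters.
#' @export
linear_length <- function(elements, center, radius, type, allow_custom = FALSE) {
  type <- match.arg(type, .linear_types)
  .check_radius(type, radius, allow_custom)
  lines <- elements$geometry[elements$type == type]
  if (length(lines) == 0L) return(0)
  sum(vapply(lines, function(coords) {
    pieces <- clip_polyline_to_circle(coords, center, radius)
    sum(vapply(pieces, .polyline_length, numeric(1)))
  }, numeric(1)))
}

#' Orthogonal-to-parallel length ratio of linear elements in a buffer
#'
#' Elements of the given type are clipped to the buffer; each connected
#' clipped piece gets its own reference axis (receptor to the piece's
#' half-arc-length midpoint; see [op_components()]) and the ratio is formed
#' from the pooled sums: `sum(orthogonal) / sum(parallel)`. When the pooled
#' parallel component is below `eps` the ratio is capped at `ratio_max`.
#'
#' @inheritParams linear_length
#' @param ratio_max Cap for a vanishing parallel component (default 1e3).
#' @param eps Parallel-length guard in meters (default 1e-9).
#' @return The ratio, or `NA` when no element of the type intersects the
#'   buffer (metric missing, not 0).
#' @export
op_ratio <- function(elements, center, radius, type, ratio_max = 1e3,
                     eps = 1e-9, allow_custom = FALSE) {
  type <- match.arg(type, .linear_types)
  .check_radius(paste0("OP_", sub("^L_", "", type)), radius, allow_custom)
  lines <- elements$geometry[elements$type == type]
  par_sum <- 0; orth_sum <- 0; any_piece <- FALSE
  for (coords in lines) {
    for (piece in clip_polyline_to_circle(coords, center, radius)) {
      comp <- op_components(piece, center)
      if (anyNA(comp)) {
        warn("element midpoint coincides with the receptor; element skipped")
        next
      }
      any_piece <- TRUE
      par_sum <- par_sum + comp[["parallel"]]
      orth_sum <- orth_sum + comp[["orthogonal"]]
    }
  }
  if (!any_piece) return(NA_real_)
  if (par_sum < eps) return(ratio_max)
  min(orth_sum / par_sum, ratio_max)
}

#' Number of occupied populations in a buffer
#'
#' Counts occupied population polygons (or points) intersecting the buffer,
#' excluding the receptor's own population.
#'
#' @param populations Tibble with `patch_id`, `occupied` and `geometry`
#'   columns (polygon rings or points).
#' @inheritParams percent_cover
#' @param own_patch_id The receptor's own `patch_id` (excluded).
#' @return Integer count.
#' @export
count_populations <- function(populations, center, radius, own_patch_id,
                              allow_custom = FALSE) {
  .check_radius("N_P", radius, allow_custom)
  pops <- filter(populations, .data$occupied, .data$patch_id != own_patch_id)
  if (nrow(pops) == 0L) return(0L)
  hit <- vapply(pops$geometry, function(g) {
    if (nrow(g) == 1L) {
      sqrt(sum((g[1, ] - center)^2)) <= radius
    } else {
      .point_polygon_distance(center, g) <= radius
    }
  }, logical(1))
  sum(hit)
}

#' Landscape metric table for a set of receptors
#'
#' Computes, per receptor and buffer radius, the full metric panel:
#' percent cover of `SEMNATGRASS`, `RAPESEED`, `MAIZE`; lengths of
#' `L_ROAD`, `L_WATER`, `L_WOOD`; their orthogonal-to-parallel ratios
#' `OP_ROAD`, `OP_WATER`, `OP_WOOD`; and the population count `N_P`.
#' Metrics not defined at a radius are `NA`.
#'
#' @param receptors Tibble `receptor_id, patch_id, x, y`.
#' @param landuse Land-use layer tibble.
#' @param elements Linear-element layer tibble.
#' @param populations Population layer tibble.
#' @param radii Buffer radii (default 50/250/1000 m).
#' @param ratio_max Cap passed to [op_ratio()].
#' @return Tibble, one row per receptor x radius.
#' @export
landscape_metric_table <- function(receptors, landuse, elements, populations,
                                   radii = .buffer_radii, ratio_max = 1e3) {
  grid <- tidyr::expand_grid(
    receptor_id = receptors$receptor_id, radius = radii
  )
  grid <- left_join(grid, as_tibble(receptors), by = "receptor_id")
  one <- function(rid, radius, patch, x, y) {
    ctr <- c(x, y)
    avail <- function(m) radius %in% .metric_radii[[m]]
    row <- list(receptor_id = rid, radius = radius)
    for (cls in c("SEMNATGRASS", "RAPESEED", "MAIZE")) {
      row[[cls]] <- if (avail(cls)) percent_cover(landuse, ctr, radius, cls) else NA_real_
    }
    for (typ in .linear_types) {
      nm_l <- typ; nm_op <- paste0("OP_", sub("^L_", "", typ))
      row[[nm_l]] <- if (avail(nm_l)) linear_length(elements, ctr, radius, typ) else NA_real_
      row[[nm_op]] <- if (avail(nm_op)) {
        op_ratio(elements, ctr, radius, typ, ratio_max = ratio_max)
      } else NA_real_
    }
    row[["N_P"]] <- if (avail("N_P")) {
      as.integer(count_populations(populations, ctr, radius, patch))
    } else NA_integer_
    as_tibble(row)
  }
  bind_rows(purrr::pmap(
    list(grid$receptor_id, grid$radius, grid$patch_id, grid$x, grid$y), one
  ))
}
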