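# Build a scene: land-use polygons, linear elements, populations.
square_ring <- function(x0, y0, side) {
  rbind(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side), c(x0, y0 + side))
}

rotate_scene <- function(coords, theta, pivot = c(0, 0)) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  sweep(sweep(coords, 2, pivot) %*% t(R), 2, pivot, `+`)
}

test_that("percent cover matches analytic half-disc and containment cases", {
  # buffer entirely inside one maize polygon
  landuse <- tibble::tibble(class = "MAIZE", geometry_type = "Polygon",
                            geometry = list(square_ring(-2000, -2000, 4000)))
  expect_equal(percent_cover(landuse, c(0, 0), 250, "MAIZE"), 100, tolerance = 1e-9)
  expect_equal(percent_cover(landuse, c(0, 0), 1000, "RAPESEED"), 0)
  # half-plane boundary through the buffer center: 50%
  half <- tibble::tibble(class = "MAIZE", geometry_type = "Polygon",
                         geometry = list(rbind(c(-1e5, -1e5), c(0, -1e5), c(0, 1e5), c(-1e5, 1e5))))
  expect_equal(percent_cover(half, c(0, 0), 250, "MAIZE"), 50, tolerance = 0.1)
  # covers including OTHER sum to 100
  mixed <- tibble::tibble(
    class = c("MAIZE", "SEMNATGRASS", "RAPESEED"),
    geometry_type = "Polygon",
    geometry = list(square_ring(-500, -500, 700), square_ring(200, -500, 600),
                    square_ring(-500, 200, 800))
  )
  total <- sum(vapply(c("MAIZE", "SEMNATGRASS", "RAPESEED", "OTHER"), function(cl) {
    percent_cover(mixed, c(0, 0), 1000, cl)
  }, numeric(1)))
  expect_equal(total, 100, tolerance = 0.01)
})

test_that("metric availability respects the buffer-radius matrix", {
  landuse <- tibble::tibble(class = "SEMNATGRASS", geometry_type = "Polygon",
                            geometry = list(square_ring(-500, -500, 1000)))
  expect_error(percent_cover(landuse, c(0, 0), 50, "SEMNATGRASS"), "not defined")
  expect_error(percent_cover(landuse, c(0, 0), 250, "RAPESEED"), "not defined")
  elems <- tibble::tibble(type = "L_WOOD", geometry_type = "LineString",
                          geometry = list(rbind(c(-100, 0), c(100, 0))))
  expect_error(linear_length(elems, c(0, 0), 50, "L_WOOD"), "not defined")
  expect_silent(linear_length(elems, c(0, 0), 250, "L_WOOD"))
  pops <- tibble::tibble(patch_id = "F02", occupied = TRUE,
                         geometry = list(square_ring(100, 100, 50)))
  expect_error(count_populations(pops, c(0, 0), 50, "F01"), "not defined")
})

test_that("linear lengths equal forced geometry and a dense-sampling oracle", {
  r <- 250
  chord <- tibble::tibble(type = "L_ROAD", geometry_type = "LineString",
                          geometry = list(rbind(c(-1000, 0), c(1000, 0))))
  expect_equal(linear_length(chord, c(0, 0), r, "L_ROAD"), 2 * r, tolerance = 1e-9)
  outside <- tibble::tibble(type = "L_ROAD", geometry_type = "LineString",
                            geometry = list(rbind(c(500, 500), c(900, 500))))
  expect_equal(linear_length(outside, c(0, 0), r, "L_ROAD"), 0)

  # random polylines vs 1 cm sampling oracle
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(3:6, 1)
    coords <- cbind(runif(n, -600, 600), runif(n, -600, 600))
    elems <- tibble::tibble(type = "L_WATER", geometry_type = "LineString",
                            geometry = list(coords))
    got <- linear_length(elems, c(0, 0), r, "L_WATER")
    want <- 0
    for (i in seq_len(n - 1)) {
      seg_len <- sqrt(sum((coords[i + 1, ] - coords[i, ])^2))
      k <- max(2L, ceiling(seg_len / 0.01))
      t_mid <- (seq_len(k) - 0.5) / k
      pts <- cbind(coords[i, 1] + t_mid * (coords[i + 1, 1] - coords[i, 1]),
                   coords[i, 2] + t_mid * (coords[i + 1, 2] - coords[i, 2]))
      inside <- rowSums(pts^2) <= r^2
      want <- want + seg_len * mean(inside)
    }
    expect_equal(got, want, tolerance = max(1e-3 * want, 1e-6))
  }
})

test_that("orientation components match closed forms", {
  ctr <- c(0, 0)
  # straight element collinear with the receptor-midpoint axis
  collinear <- rbind(c(50, 0), c(150, 0))
  expect_equal(op_components(collinear, ctr),
               c(parallel = 100, orthogonal = 0), tolerance = 1e-12)
  # perpendicular through its midpoint
  perp <- rbind(c(100, -50), c(100, 50))
  expect_equal(op_components(perp, ctr),
               c(parallel = 0, orthogonal = 100), tolerance = 1e-12)
  # 100 m segment at 45 degrees to the axis through its midpoint
  u <- c(1, 0); d45 <- c(cos(pi / 4), sin(pi / 4))
  mid <- c(100, 0)
  seg45 <- rbind(mid - 50 * d45, mid + 50 * d45)
  expect_equal(op_components(seg45, ctr),
               c(parallel = 100 / sqrt(2), orthogonal = 100 / sqrt(2)),
               tolerance = 1e-9)
  # component-sum bounds: |v.u| + |v.n| within [L, L*sqrt(2)]
  set.seed(13)
  for (rep in 1:20) {
    coords <- cbind(runif(4, 20, 300), runif(4, -300, 300))
    comp <- op_components(coords, ctr)
    len <- sum(sqrt(rowSums(diff(coords)^2)))
    expect_gte(sum(comp) + 1e-9, len)
    expect_lte(sum(comp), len * sqrt(2) + 1e-9)
  }
})

test_that("orthogonal-to-parallel ratios pool components and guard zero division", {
  ctr <- c(0, 0)
  radial <- tibble::tibble(type = "L_ROAD", geometry_type = "LineString",
                           geometry = list(rbind(c(50, 0), c(150, 0)),
                                           rbind(c(0, 30), c(0, 200))))
  expect_equal(op_ratio(radial, ctr, 250, "L_ROAD"), 0)
  tangent <- tibble::tibble(type = "L_ROAD", geometry_type = "LineString",
                            geometry = list(rbind(c(100, -40), c(100, 40))))
  expect_equal(op_ratio(tangent, ctr, 250, "L_ROAD"), 1e3)
  # mixed set equals recomputation from op_components
  set.seed(8)
  geoms <- lapply(1:4, function(i) cbind(runif(3, 30, 240), runif(3, -240, 240)))
  mixed <- tibble::tibble(type = "L_WATER", geometry_type = "LineString",
                          geometry = geoms)
  par_sum <- 0; orth_sum <- 0
  for (g in geoms) {
    for (piece in clip_polyline_to_circle(g, ctr, 250)) {
      comp <- op_components(piece, ctr)
      par_sum <- par_sum + comp[["parallel"]]
      orth_sum <- orth_sum + comp[["orthogonal"]]
    }
  }
  expect_equal(op_ratio(mixed, ctr, 250, "L_WATER"), orth_sum / par_sum)
  # absent type: missing, not zero
  expect_true(is.na(op_ratio(mixed, ctr, 250, "L_ROAD")))
})

test_that("population counts exclude the focal patch and match brute force", {
  set.seed(4)
  pops <- tibble::tibble(
    patch_id = sprintf("F%02d", 1:15), occupied = rep(c(TRUE, TRUE, FALSE), 5),
    geometry = lapply(1:15, function(i) square_ring(runif(1, -1500, 1500),
                                                    runif(1, -1500, 1500), 100))
  )
  ctr <- c(0, 0)
  got <- count_populations(pops, ctr, 1000, "F01")
  ns <- asNamespace("pollenscape")
  want <- sum(vapply(seq_len(nrow(pops)), function(i) {
    if (!pops$occupied[i] || pops$patch_id[i] == "F01") return(FALSE)
    ns$.point_polygon_distance(ctr, pops$geometry[[i]]) <= 1000
  }, logical(1)))
  expect_equal(got, want)
  none <- tibble::tibble(patch_id = "F09", occupied = TRUE,
                         geometry = list(square_ring(5000, 5000, 100)))
  expect_equal(count_populations(none, ctr, 1000, "F01"), 0L)
})

test_that("all metrics are invariant under whole-scene rotation", {
  set.seed(21)
  ctr <- c(300, -200)
  landuse <- tibble::tibble(
    class = c("MAIZE", "SEMNATGRASS"), geometry_type = "Polygon",
    geometry = list(square_ring(-200, -600, 700), square_ring(100, 100, 900))
  )
  elems <- tibble::tibble(
    type = c("L_ROAD", "L_WATER"), geometry_type = "LineString",
    geometry = list(cbind(runif(4, -800, 800), runif(4, -800, 800)),
                    cbind(runif(3, -800, 800), runif(3, -800, 800)))
  )
  pops <- tibble::tibble(patch_id = c("F01", "F02"), occupied = TRUE,
                         geometry = list(square_ring(600, 300, 200),
                                         square_ring(-900, -900, 300)))
  theta <- 0.77; pivot <- c(-50, 120)
  rot <- function(layer) {
    layer$geometry <- lapply(layer$geometry, rotate_scene, theta = theta, pivot = pivot)
    layer
  }
  ctr_r <- as.numeric(rotate_scene(matrix(ctr, 1), theta, pivot))
  for (radius in c(250, 1000)) {
    expect_equal(percent_cover(rot(landuse), ctr_r, radius, "MAIZE", allow_custom = TRUE),
                 percent_cover(landuse, ctr, radius, "MAIZE", allow_custom = TRUE),
                 tolerance = 1e-6)
    expect_equal(linear_length(rot(elems), ctr_r, radius, "L_ROAD"),
                 linear_length(elems, ctr, radius, "L_ROAD"), tolerance = 1e-6)
    expect_equal(op_ratio(rot(elems), ctr_r, radius, "L_WATER"),
                 op_ratio(elems, ctr, radius, "L_WATER"), tolerance = 1e-6)
    expect_equal(count_populations(rot(pops), ctr_r, radius, "F99"),
                 count_populations(pops, ctr, radius, "F99"))
  }
})

test_that("the landscape metric table honours the availability matrix", {
  landuse <- tibble::tibble(class = "MAIZE", geometry_type = "Polygon",
                            geometry = list(square_ring(-3000, -3000, 6000)))
  elems <- tibble::tibble(type = c("L_ROAD", "L_WOOD"), geometry_type = "LineString",
                          geometry = list(rbind(c(-500, 10), c(500, 10)),
                                          rbind(c(-500, -300), c(500, -300))))
  pops <- tibble::tibble(patch_id = c("F01", "F02"), occupied = TRUE,
                         geometry = list(square_ring(-50, -50, 100),
                                         square_ring(400, 400, 100)))
  receptors <- tibble::tibble(receptor_id = "R1", patch_id = "F01", x = 0, y = 0)
  tab <- landscape_metric_table(receptors, landuse, elems, pops)
  expect_equal(nrow(tab), 3L)
  r50 <- tab[tab$radius == 50, ]
  expect_true(is.na(r50$SEMNATGRASS) && is.na(r50$RAPESEED) &&
                is.na(r50$L_WOOD) && is.na(r50$N_P))
  expect_equal(r50$MAIZE, 100, tolerance = 1e-9)
  r1000 <- tab[tab$radius == 1000, ]
  expect_equal(r1000$N_P, 1L)
  expect_equal(r1000$L_ROAD, 1000)
  expect_false(is.na(r1000$OP_WOOD))
})

test_that("GeoJSON layers round-trip through write and read", {
  layer <- tibble::tibble(
    class = c("MAIZE", "OTHER"), geometry_type = "Polygon",
    geometry = list(square_ring(0, 0, 100), square_ring(200, 0, 50))
  )
  path <- withr::local_tempfile(fileext = ".geojson")
  write_geojson(layer, path)
  back <- read_geojson(path)
  expect_equal(back$class, layer$class)
  # ring is closed on write; same vertex set
  expect_equal(back$geometry[[1]][1:4, ], layer$geometry[[1]], ignore_attr = TRUE)
  lines <- tibble::tibble(type = "L_ROAD", geometry_type = "LineString",
                          geometry = list(rbind(c(0.5, 1.25), c(100.75, 50))))
  write_geojson(lines, path)
  back2 <- read_geojson(path)
  expect_equal(back2$geometry[[1]], lines$geometry[[1]], ignore_attr = TRUE)
})
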