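make_single_helix_structure <- function(origin = c(4, 0, -15), n_res = 21,
                                        direction = c(0, 0, 1), ...) {
  h <- make_ideal_helix(n_res, origin = origin, direction = direction, ...)
  tm <- tm_annotation(data.frame(helix_id = c(1, 2, 3), chain = c("A", "B", "B"),
                                 start = c(1, 1, 50), end = c(n_res, 10, 60)))
  list(structure = h, tm = tm[1, , drop = FALSE])
}

test_that("windowed helix centers track the helix axis", {
  hs <- make_single_helix_structure(origin = c(4, 0, -15))
  tm <- tm_annotation(data.frame(helix_id = 1, chain = "A", start = 1,
                                 end = 21))
  zq <- seq(-12, 12, by = 1)
  centers <- t(vapply(zq, function(z)
    helix_center_at_z(hs$structure, tm, 1, z, window = 2), numeric(2)))
  err <- sqrt((centers[, 1] - 4)^2 + centers[, 2]^2)
  # the +/- 2 A window holds 2-3 of the 3.6 residues per turn, so the plain
  # mean wobbles about the axis by up to ~0.65 * ca_radius
  expect_lt(mean(err), 0.6)
  expect_lt(max(err), 1.5)
  # a window covering a full turn tightens the estimate
  centers_ft <- t(vapply(zq, function(z)
    helix_center_at_z(hs$structure, tm, 1, z, window = 2.7), numeric(2)))
  err_ft <- sqrt((centers_ft[, 1] - 4)^2 + centers_ft[, 2]^2)
  expect_lt(mean(err_ft), 0.45)
})

test_that("nearest-point fallback returns the end Calpha beyond the span", {
  hs <- make_single_helix_structure(origin = c(4, 0, -15))
  tm <- tm_annotation(data.frame(helix_id = 1, chain = "A", start = 1,
                                 end = 21))
  ca <- hs$structure$atoms[hs$structure$atoms$elety == "CA", ]
  top <- ca[which.max(ca$z), ]
  got <- helix_center_at_z(hs$structure, tm, 1, z = 100, window = 2)
  expect_identical(got, c(top$x, top$y))
  # fallback continuity: center just beyond the end stays near the last
  # windowed center
  z_end <- max(ca$z)
  inside <- helix_center_at_z(hs$structure, tm, 1, z_end, window = 2)
  outside <- helix_center_at_z(hs$structure, tm, 1, z_end + 2.2, window = 2)
  expect_lt(sqrt(sum((inside - outside)^2)), 2 * 2.3)
})

test_that("a tilted helix's centers trace the expected slope in x vs z", {
  dir <- c(sin(20 * pi / 180), 0, cos(20 * pi / 180))
  h <- make_ideal_helix(25, origin = c(0, 0, -18), direction = dir)
  tm <- tm_annotation(data.frame(helix_id = 1, chain = "A", start = 1,
                                 end = 25))
  zq <- seq(-10, 10, by = 2)
  centers <- t(vapply(zq, function(z) helix_center_at_z(h, tm, 1, z, 2),
                      numeric(2)))
  slope <- stats::coef(stats::lm(centers[, 1] ~ zq))[2]
  expect_equal(unname(slope), tan(20 * pi / 180), tolerance = 0.05)
})

test_that("helix with no Calpha atoms raises an annotation error", {
  hs <- make_single_helix_structure()
  tm <- tm_annotation(data.frame(helix_id = 9, chain = "Q", start = 1,
                                 end = 21))
  expect_error(helix_center_at_z(hs$structure, tm, 9, 0, 2),
               class = "pf_annotation_error")
})

test_that("lateral polygons of the default bundle are near-regular heptagons", {
  b <- make_bundle(bundle_spec())
  zl <- seq(-10, 10, by = 1)
  sp <- lateral_polygons(b$structure, b$tm, zl)
  expect_equal(length(sp$vertices), length(zl))
  for (v in sp$vertices) {
    expect_equal(nrow(v), 7)
    expect_false(any(is.na(v)))
    ctr <- colMeans(v)
    r <- sqrt(rowSums(sweep(v, 2, ctr)^2))
    # each vertex wobbles about the true axis by at most ~0.65 * ca_radius
    # (the 2-atom window case); the centroid adds a little on top
    expect_true(all(abs(r - 12) < 1.7))
    expect_true(all(sqrt(rowSums((v - b$truth$axis_xy)^2)) < 1.5))
  }
  # angular ordering gives the same cycle as index ordering for a bundle
  # laid out sequentially around the circle
  sp2 <- lateral_polygons(b$structure, b$tm, zl, order = "angular")
  start <- which(sp2$helix_ids == 1)
  cyc <- sp2$helix_ids[c(start:7, seq_len(start - 1))]
  expect_equal(cyc, sp$helix_ids)
})

test_that("3-helix bundles give triangles with the analytic area", {
  b <- make_bundle(bundle_spec(n_helices = 3, bundle_radius = 14))
  sp <- lateral_polygons(b$structure, b$tm, 0)
  v <- sp$vertices[[1]]
  expect_equal(nrow(v), 3)
  analytic <- shoelace_area(b$truth$axis_xy)
  expect_equal(shoelace_area(v), analytic, tolerance = 0.02)
  # orientation is consistent across levels after canonicalization
  sp <- lateral_polygons(b$structure, b$tm, seq(-8, 8, 2))
  areas <- vapply(sp$vertices,
                  function(r) polygon_area(canonicalize_ring(r)), numeric(1))
  expect_true(all(areas > 0))
})

test_that("fewer than 3 helices is a geometry error", {
  b <- make_bundle(bundle_spec())
  expect_error(lateral_polygons(b$structure, b$tm[1:2, ], 0),
               class = "pf_geometry_error")
})

test_that("pocket bounds come from the toggle Calpha and the TM tops", {
  b <- make_bundle(bundle_spec())
  bounds <- pocket_z_bounds(b$structure, b$tm, b$bw)
  expect_equal(bounds$z_lower, b$truth$toggle$z, tolerance = 1e-9)
  expect_equal(bounds$z_upper, b$truth$z_upper, tolerance = 1e-9)
  # missing 6.48 residue
  bw_bad <- bw_map(data.frame(chain = "R", resno = 99999, bw = "6.48"))
  expect_error(pocket_z_bounds(b$structure, b$tm, bw_bad),
               class = "pf_annotation_error")
})

test_that("boundary construction is translation-equivariant", {
  b <- make_bundle(bundle_spec())
  tz <- identity_transform(); tz$translation <- c(3, -2, 5)
  moved <- apply_transform(b$structure, tz)
  b0 <- pocket_z_bounds(b$structure, b$tm, b$bw)
  b1 <- pocket_z_bounds(moved, b$tm, b$bw)
  expect_equal(b1$z_lower, b0$z_lower + 5)
  expect_equal(b1$z_upper, b0$z_upper + 5)
  sp0 <- lateral_polygons(b$structure, b$tm, c(-2, 0, 2))
  sp1 <- lateral_polygons(moved, b$tm, c(-2, 0, 2) + 5)
  for (i in seq_along(sp0$vertices))
    expect_equal(sp1$vertices[[i]],
                 sweep(sp0$vertices[[i]], 2, c(3, -2), "+"),
                 tolerance = 1e-9)
})
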