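# Mesh geometry: volumes, keyframe blending, branch splitting,
# cross-section slicing and centerline curvature.

test_that("tetrahedral volumes are exact on simple meshes", {
  cube <- unit_cube_tets()
  mesh <- time_resolved_mesh(cube$tets, list(cube$nodes), 0)
  expect_equal(mesh_volume(mesh), 1.0, tolerance = 1e-14)

  # two disjoint unit tets of volume 1/6 each
  t1 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  nodes <- rbind(t1, t1 + 5)
  mesh2 <- time_resolved_mesh(rbind(1:4, 5:8), list(nodes), 0)
  expect_equal(mesh_volume(mesh2), 1 / 3, tolerance = 1e-14)
})

test_that("cylinder mesh volume approaches pi R^2 L at 1.2 mm elements", {
  fx <- poiseuille_fixture()
  expect_equal(mesh_volume(fx$mesh), pi * 10, tolerance = 0.02 * pi * 10)
})

test_that("keyframe blending reproduces keyframes and analytic mid-volume", {
  ct <- coarse_tube()
  n1 <- ct$mesh$nodes_per_frame[[1]]
  n2 <- cbind(n1[, 1] * 1.2, n1[, 2] * 1.2, n1[, 3])
  m_min <- time_resolved_mesh(ct$mesh$connectivity, list(n1), 0)
  m_max <- time_resolved_mesh(ct$mesh$connectivity, list(n2), 0)
  mi <- interpolate_keyframes(m_min, m_max, c(0, 0.25, 0.5),
                              alpha = c(0, 0.5, 1))
  expect_identical(mi$nodes_per_frame[[1]], n1)
  expect_identical(mi$nodes_per_frame[[3]], n2)
  # radius 1.0 -> 1.2 at alpha 0.5 gives radius 1.1
  v_mid <- mesh_volume(mi, 2)
  expect_equal(v_mid, pi * 1.1^2 * 5, tolerance = 0.02 * pi * 1.1^2 * 5)

  one_tet <- time_resolved_mesh(
    rbind(1:4),
    list(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))), 0)
  expect_error(interpolate_keyframes(m_min, one_tet, 0),
               "connectivity|node")
})

test_that("blended volume is monotone in alpha for a dilating cylinder", {
  ct <- coarse_tube()
  n1 <- ct$mesh$nodes_per_frame[[1]]
  n2 <- cbind(n1[, 1] * 1.3, n1[, 2] * 1.3, n1[, 3])
  m_min <- time_resolved_mesh(ct$mesh$connectivity, list(n1), 0)
  m_max <- time_resolved_mesh(ct$mesh$connectivity, list(n2), 0)
  alphas <- seq(0, 1, 0.1)
  mi <- interpolate_keyframes(m_min, m_max, seq_along(alphas) / 20,
                              alpha = alphas)
  vols <- vapply(seq_along(alphas), function(f) mesh_volume(mi, f),
                 numeric(1))
  expect_true(all(diff(vols) > 0))
  # default cosine schedule hits the keyframes exactly
  mi2 <- interpolate_keyframes(m_min, m_max, c(0, 0.1, 0.2, 0.3),
                               t_min = 0, t_max = 0.2)
  expect_equal(mi2$nodes_per_frame[[1]], n1)
  expect_equal(mi2$nodes_per_frame[[3]], n2)
})

test_that("a single straight tube forms one branch with no bifurcation", {
  ct <- coarse_tube()
  regions <- split_branches(ct$mesh, ct$centerlines)
  expect_equal(length(regions$branch$MPA), nrow(ct$mesh$connectivity))
  expect_length(regions$bifurcation, 0)
})

test_that("Y-junction branches are disjoint, exhaustive and cap-adjacent", {
  spec <- phantom_spec("y_junction", R = 1, L = 8, element_size = 0.25)
  ph <- make_y_junction(spec)
  regions <- split_branches(ph$mesh, ph$centerlines)
  all_el <- sort(unname(c(unlist(regions$branch), regions$bifurcation)))
  expect_identical(all_el, seq_len(nrow(ph$mesh$connectivity)))
  expect_length(intersect(regions$branch$MPA, regions$branch$LPA), 0)
  expect_length(intersect(regions$branch$LPA, regions$branch$RPA), 0)
  # elements adjacent to each cap belong to that branch
  cen <- element_centroids(ph$mesh)
  mpa_cap <- which(cen[, 3] < -3.8)
  expect_true(all(mpa_cap %in% regions$branch$MPA))
  # volume additivity is exact
  v_parts <- sum(vapply(regions$branch, function(el)
    mesh_volume(ph$mesh, 1, el), numeric(1))) +
    mesh_volume(ph$mesh, 1, regions$bifurcation)
  expect_equal(v_parts, mesh_volume(ph$mesh), tolerance = 1e-12)

  far_cl <- centerline_set(list(MPA = cbind(100, 100, c(0, 1, 2, 3))))
  expect_error(split_branches(ph$mesh, far_cl), "outside the mesh")
})

test_that("mid-tube slice has area pi R^2 and sits at the right height", {
  ct <- coarse_tube()
  cl <- ct$centerlines$branches$MPA
  sl <- slice_at_fraction(ct$mesh, cl, 0.5)
  expect_equal(sl$area, pi, tolerance = 0.02 * pi)
  expect_equal(sl$origin[3], 2.5, tolerance = 1e-9)
  expect_true(all(abs((sl$vertices - rep(sl$origin, each = nrow(sl$vertices)))
                      %*% sl$normal) < 1e-6))
  sl10 <- slice_at_fraction(ct$mesh, cl, 0.1)
  expect_equal(sl10$origin[3], 0.5, tolerance = 1e-9)
  expect_error(slice_at_fraction(ct$mesh, cl, 1.5), "fraction")
  expect_error(slice_at_fraction(ct$mesh, cl, 0), "fraction")
})

test_that("slice area is invariant to rigid rotation of the scene", {
  ct <- coarse_tube()
  n1 <- ct$mesh$nodes_per_frame[[1]]
  ang <- 0.7
  Rz <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(0.5), 0, sin(0.5), 0, 1, 0, -sin(0.5), 0, cos(0.5)),
               3, 3, byrow = TRUE)
  Rm <- Ry %*% Rz
  mR <- time_resolved_mesh(ct$mesh$connectivity, list(n1 %*% t(Rm)), 0)
  clR <- ct$centerlines$branches$MPA %*% t(Rm)
  a0 <- slice_at_fraction(ct$mesh, ct$centerlines$branches$MPA, 0.5)$area
  aR <- slice_at_fraction(mR, clR, 0.5)$area
  expect_equal(aR, a0, tolerance = 0.005 * a0)
})

test_that("centerline curvature recovers circles, helices and lines", {
  line <- cbind(0, 0, seq(0, 10, length.out = 20))
  expect_identical(centerline_curvature(line, 0.5), Inf)

  th <- seq(0, pi / 2, length.out = 200)
  circ <- cbind(5 * cos(th), 5 * sin(th), 0)
  expect_equal(centerline_curvature(circ, 0.5), 5, tolerance = 0.01 * 5)

  tt <- seq(0, 4 * pi, length.out = 400)
  helix <- cbind(2 * cos(tt), 2 * sin(tt), tt)   # a = 2, b = 1
  expect_equal(centerline_curvature(helix, 0.5), (4 + 1) / 2,
               tolerance = 0.02 * 2.5)

  expect_error(centerline_curvature(cbind(0, 0, 0:3), 0.5), "5 points")
})

test_that("curved phantom tube reports its torus radius as curvature", {
  spec <- phantom_spec("poiseuille", R = 1, L = 7, Rc = 5,
                       element_size = 0.3)
  ph <- make_tube(spec)
  expect_equal(centerline_curvature(ph$centerlines$branches$MPA, 0.5), 5,
               tolerance = 0.01 * 5)
  # Pappus: bent volume equals straight-tube volume
  expect_equal(mesh_volume(ph$mesh), pi * 7, tolerance = 0.02 * pi * 7)
  expect_error(phantom_spec("poiseuille", R = 2, Rc = 1.5),
               "self-intersecting")
})
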