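# Differential operators: resampling exactness, gradients, vorticity,
# Q-criterion, vortex regions, and their invariances.

test_that("trilinear resampling is exact for constant and affine fields", {
  ct <- coarse_tube()
  const <- field_from_function(function(p)
    cbind(rep(10, nrow(p)), 0, 0))
  nf <- resample_to_mesh(const, ct$mesh)
  expect_equal(nf$values,
               cbind(rep(10, nrow(nf$values)), 0, 0), tolerance = 1e-12)

  A <- matrix(c(0.5, -1, 2, 1.5, 0.3, -0.7, 0, 2, 1), 3, 3)
  b <- c(1, -2, 3)
  affine <- field_from_function(function(p)
    sweep(p %*% t(A), 2, -b))
  nf <- resample_to_mesh(affine, ct$mesh)
  exact <- sweep(ct$mesh$nodes_per_frame[[1]] %*% t(A), 2, -b)
  expect_equal(nf$values, exact, tolerance = 1e-9)
})

test_that("Poiseuille resampling error stays under 2% of peak velocity", {
  fx <- poiseuille_fixture()
  nodes <- fx$mesh$nodes_per_frame[[1]]
  exact <- 40 * (1 - (nodes[, 1]^2 + nodes[, 2]^2))
  expect_lt(max(abs(fx$nf$values[, 3] - exact)), 0.02 * 40)
})

test_that("nodes outside the grid follow the fill policy", {
  ct <- coarse_tube()
  small <- field_from_function(function(p) cbind(p[, 1], 0, 0),
                               lo = c(-2, -2, 1), hi = c(2, 2, 2))
  expect_warning(resample_to_mesh(small, ct$mesh, outside = "zero"),
                 "outside")
  expect_error(resample_to_mesh(small, ct$mesh, outside = "error"),
               "outside")
})

test_that("gradient, curl and Q are exact for affine fields", {
  ct <- coarse_tube()
  # solid-body rotation, Omega = 2: omega = (0, 0, 4), Q = Omega^2
  sb <- field_from_function(function(p) cbind(-2 * p[, 2], 2 * p[, 1], 0))
  gf <- velocity_gradient(resample_to_mesh(sb, ct$mesh), ct$mesh)
  expect_lt(max(abs(gf$vorticity[, 3] - 4)), 4e-10)
  expect_lt(max(abs(gf$vorticity[, 1:2])), 1e-10)
  expect_lt(max(abs(gf$Q - 4)), 4e-10)

  # simple shear, gamma = 3: omega = (0, 0, -3), Q = 0
  sh <- field_from_function(function(p) cbind(3 * p[, 2], 0, 0))
  gf <- velocity_gradient(resample_to_mesh(sh, ct$mesh), ct$mesh)
  expect_lt(max(abs(gf$vorticity[, 3] + 3)), 3e-10)
  expect_lt(max(abs(gf$Q)), 1e-10)

  # constant field: zero gradient
  cf <- field_from_function(function(p) cbind(rep(5, nrow(p)), -3, 2))
  gf <- velocity_gradient(resample_to_mesh(cf, ct$mesh), ct$mesh)
  expect_lt(max(abs(gf$G)), 1e-11)
})

test_that("gradient-derived quantities are objective under uniform translation", {
  ct <- coarse_tube()
  gf0 <- velocity_gradient(resample_to_mesh(ct$field, ct$mesh), ct$mesh)
  shifted <- ct$field
  shifted$velocities <- sweep(shifted$velocities, 5, c(7, -4, 11), "+")
  gf1 <- velocity_gradient(resample_to_mesh(shifted, ct$mesh), ct$mesh)
  expect_equal(gf1$vorticity, gf0$vorticity, tolerance = 1e-10)
  expect_equal(gf1$Q, gf0$Q, tolerance = 1e-10)
})

test_that("rotation tensor stays consistent with the curl", {
  fx <- poiseuille_fixture()
  G <- fx$gf$G
  W21 <- (G[, 2, 1] - G[, 1, 2]) / 2
  expect_equal(fx$gf$vorticity[, 3], 2 * W21, tolerance = 1e-12)
})

test_that("branch vorticity: both averaging modes on analytic flows", {
  ct <- coarse_tube()
  sb <- field_from_function(function(p) cbind(-2 * p[, 2], 2 * p[, 1], 0))
  gf <- velocity_gradient(resample_to_mesh(sb, ct$mesh), ct$mesh)
  expect_equal(branch_vorticity(gf, mode = "vector-mean"), 4,
               tolerance = 1e-9)
  expect_equal(branch_vorticity(gf, mode = "magnitude-mean"), 4,
               tolerance = 1e-9)

  zero <- field_from_function(function(p) matrix(0, nrow(p), 3))
  gfz <- velocity_gradient(resample_to_mesh(zero, ct$mesh), ct$mesh)
  expect_equal(branch_vorticity(gfz, mode = "magnitude-mean"), 0)
  expect_error(branch_vorticity(gf, elements = integer(0)), "empty branch")
})

test_that("Poiseuille vorticity: magnitude mean 4u/3R, vector mean cancels", {
  fx <- poiseuille_fixture()
  wm <- branch_vorticity(fx$gf, mode = "magnitude-mean")
  wv <- branch_vorticity(fx$gf, mode = "vector-mean")
  expect_equal(wm, 4 * 40 / 3, tolerance = 0.03 * 4 * 40 / 3)
  expect_lt(wv, 0.05 * wm)
  # quadrature oracle agrees with the closed form
  expect_equal(fx$gt$vorticity_magmean, 4 * 40 / 3,
               tolerance = 1e-3 * 4 * 40 / 3)
})

test_that("magnitude-mean vorticity error shrinks under mesh refinement", {
  errs <- vapply(c(0.24, 0.12), function(h) {
    sp <- phantom_spec("poiseuille", R = 1, L = 5, u_max = 40,
                       element_size = h, spacing = 0.05)
    ph <- make_tube(sp)
    f <- make_field(sp)
    gf <- velocity_gradient(resample_to_mesh(f, ph$mesh), ph$mesh)
    abs(branch_vorticity(gf, mode = "magnitude-mean") - 4 * 40 / 3)
  }, numeric(1))
  expect_gt(errs[1] / errs[2], 1.4)  # at least first-order improvement
})

test_that("Q-criterion separates rotation from shear", {
  ct <- coarse_tube()
  sb <- field_from_function(function(p) cbind(-2 * p[, 2], 2 * p[, 1], 0))
  gf <- velocity_gradient(resample_to_mesh(sb, ct$mesh), ct$mesh)
  expect_equal(unname(range(q_criterion(gf))), c(4, 4), tolerance = 1e-10)

  # locally pure shear (Poiseuille): Q = 0 everywhere
  fx <- poiseuille_fixture()
  expect_lt(max(abs(q_criterion(fx$gf))), 1e-10)
})

test_that("vortex regions: slow solid-body core detected, Poiseuille empty", {
  sp <- phantom_spec("solid_body", R = 1, L = 4, Omega = 2,
                     element_size = 0.3)
  ph <- make_tube(sp)
  f <- make_field(sp)
  nf <- resample_to_mesh(f, ph$mesh)
  gf <- velocity_gradient(nf, ph$mesh)
  # speeds Omega * r <= 2 cm/s << 30: the whole tube is one slow vortex
  vr <- detect_vortex_regions(gf, nf, ph$mesh, speed_threshold = 30)
  expect_equal(nrow(vr$regions), 1)
  expect_equal(sum(vr$labels > 0), nrow(ph$mesh$connectivity))
  expect_equal(vr$regions$volume_cm3[1], mesh_volume(ph$mesh),
               tolerance = 1e-9)
  # zero threshold removes everything
  vr0 <- detect_vortex_regions(gf, nf, ph$mesh, speed_threshold = 0)
  expect_equal(nrow(vr0$regions), 0)

  fx <- poiseuille_fixture()
  vrp <- detect_vortex_regions(fx$gf, fx$nf, fx$mesh, 30)
  expect_equal(nrow(vrp$regions), 0)
})
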