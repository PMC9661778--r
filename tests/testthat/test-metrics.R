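# Hemodynamic metric operations against hand arithmetic and analytic
# profiles.

test_that("flow rate: plug flow, Poiseuille, and sign under normal flip", {
  ct <- coarse_tube()
  plug <- field_from_function(function(p) cbind(0, 0, rep(10, nrow(p))))
  sl <- slice_at_fraction(ct$mesh, ct$centerlines$branches$MPA, 0.5,
                          field = plug)
  q <- flow_rate(sl)
  expect_equal(q$cm3_s, 10 * sl$area, tolerance = 1e-9)
  expect_equal(q$L_min, q$cm3_s * 0.06, tolerance = 1e-12)

  fx <- poiseuille_fixture()
  sl10 <- slice_at_fraction(fx$mesh, fx$centerlines$branches$MPA, 0.10,
                            field = fx$field)
  expect_equal(flow_rate(sl10)$cm3_s, 40 * pi / 2,
               tolerance = 0.02 * 40 * pi / 2)

  flipped <- sl
  flipped$normal <- -sl$normal
  expect_equal(flow_rate(flipped)$cm3_s, -q$cm3_s, tolerance = 1e-12)
})

test_that("flux orientation picks the forward flow direction", {
  ct <- coarse_tube()
  downward <- field_from_function(function(p) cbind(0, 0, rep(-10, nrow(p))))
  sl <- slice_at_fraction(ct$mesh, ct$centerlines$branches$MPA, 0.5,
                          field = downward)
  expect_gt(flow_rate(sl)$cm3_s, 0)   # normal flipped against the tangent
  expect_equal(sl$normal[3], -1, tolerance = 1e-12)
})

test_that("conservation error arithmetic and QC threshold", {
  r <- conservation_error(5.0, 2.4, 2.4)
  expect_equal(r$error, 0.04, tolerance = 1e-12)
  expect_true(r$pass)
  expect_equal(conservation_error(3, 1.5, 1.5)$error, 0)
  r2 <- conservation_error(5.0, 2.0, 1.9)
  expect_equal(r2$error, 0.22, tolerance = 1e-12)
  expect_false(r2$pass)
  expect_error(conservation_error(0, 1, 1), "positive")
})

test_that("centerline velocity reads the core, not an off-center annulus", {
  fx <- poiseuille_fixture()
  sl50 <- slice_at_fraction(fx$mesh, fx$centerlines$branches$MPA, 0.50,
                            field = fx$field)
  expect_equal(centerline_velocity(sl50), 40, tolerance = 0.02 * 40)

  # annular profile peaking at r = 0.5 R with value 50; value 30 at 0.3 R:
  # the center-region max must report ~30, not the global 50
  ct <- coarse_tube()
  annular <- field_from_function(function(p) {
    r <- sqrt(p[, 1]^2 + p[, 2]^2)
    cbind(0, 0, pmax(0, 50 - 500 * (r - 0.5)^2))
  }, spacing = 0.05)
  sl <- slice_at_fraction(ct$mesh, ct$centerlines$branches$MPA, 0.5,
                          field = annular)
  v <- centerline_velocity(sl)
  expect_equal(v, 30, tolerance = 0.05 * 30)
  expect_lt(v, 40)

  zero <- field_from_function(function(p) matrix(0, nrow(p), 3))
  slz <- slice_at_fraction(ct$mesh, ct$centerlines$branches$MPA, 0.5,
                           field = zero)
  expect_equal(centerline_velocity(slz), 0)
})

test_that("acceleration time ratio follows the systolic peak position", {
  wf <- waveform(c(0, 0.10, 0.30, 0.50), c(0, 50, 5, 0), 0.8)
  win <- cardiac_windows(0, 0.30, 0.8)
  expect_warning(atr <- acceleration_time_ratio(wf, win), "boundary")
  expect_equal(atr, 1 / 3, tolerance = 1e-9)

  # peak at end-diastole
  wf2 <- waveform(c(0, 0.1, 0.2, 0.4), c(50, 20, 10, 0), 0.8)
  expect_warning(expect_equal(
    acceleration_time_ratio(wf2, cardiac_windows(0, 0.4, 0.8)), 0))

  # symmetric triangle in systole peaks halfway
  wf3 <- waveform(c(0, 0.1, 0.2, 0.3, 0.4), c(0, 25, 50, 25, 0), 0.8)
  expect_equal(acceleration_time_ratio(wf3, cardiac_windows(0, 0.4, 0.8)),
               0.5, tolerance = 1e-9)
  expect_error(acceleration_time_ratio(wf3, cardiac_windows(0.62, 0.64, 0.8)),
               "systolic window")
})

test_that("reverse-flow fraction counts non-forward area", {
  ct <- coarse_tube()
  # antisymmetric (odd in x) through-plane flow: half forward, half
  # reverse by mirror symmetry of the tube
  half <- field_from_function(function(p) cbind(0, 0, 10 * p[, 1]))
  sl <- slice_at_fraction(ct$mesh, ct$centerlines$branches$MPA, 0.5,
                          field = half, orient = "tangent")
  expect_equal(reverse_flow_fraction(sl), 0.5, tolerance = 0.05)

  fx <- poiseuille_fixture()
  sl50 <- slice_at_fraction(fx$mesh, fx$centerlines$branches$MPA, 0.50,
                            field = fx$field)
  expect_equal(reverse_flow_fraction(sl50), 0)

  # purely in-plane velocity: u . n = 0 everywhere counts as reverse
  inplane <- field_from_function(function(p) cbind(rep(5, nrow(p)), 0, 0))
  sli <- slice_at_fraction(ct$mesh, ct$centerlines$branches$MPA, 0.5,
                           field = inplane, orient = "tangent")
  expect_equal(reverse_flow_fraction(sli), 1.0)
})

test_that("helicity: helical field H_d, fraction positive and HFI", {
  fx <- helical_fixture()
  hel <- helicity_metrics(fx$nf, fx$gf, fx$mesh)
  expect_equal(unname(range(hel$H_d)), c(2, 2), tolerance = 0.01 * 2)
  expect_equal(hel$fraction_positive, 1)
  expect_equal(hel$HFI, 2 * (sqrt(2) - 1),
               tolerance = 0.01 * 2 * (sqrt(2) - 1))
  # quadrature oracle matches the closed form independently
  expect_equal(fx$gt$HFI, fx$gt$HFI_closed_form, tolerance = 1e-4)
})

test_that("Dean-pair helicity is mirror-balanced and HFI mirror-invariant", {
  spec <- phantom_spec("dean_pair", R = 1, L = 4, u_max = 20, dean_A = 10,
                       element_size = 0.15)
  ph <- make_tube(spec)
  f <- make_field(spec)
  nf <- resample_to_mesh(f, ph$mesh)
  gf <- velocity_gradient(nf, ph$mesh)
  hel <- helicity_metrics(nf, gf, ph$mesh)
  expect_equal(hel$fraction_positive, 0.5, tolerance = 0.02)

  fm <- pa4dflow:::mirror_field_y(f)
  mm <- pa4dflow:::mirror_mesh_y(ph$mesh)
  nfm <- resample_to_mesh(fm, mm)
  helm <- helicity_metrics(nfm, velocity_gradient(nfm, mm), mm)
  expect_equal(helm$HFI, hel$HFI, tolerance = 1e-3)
  expect_equal(helm$fraction_positive, 1 - hel$fraction_positive,
               tolerance = 0.02)
})

test_that("velocity scaling acts on metrics with the right powers", {
  spec <- phantom_spec("dean_pair", R = 1, L = 4, u_max = 20, dean_A = 10,
                       element_size = 0.25)
  ph <- make_tube(spec)
  f1 <- make_field(spec)
  k <- 3
  f2 <- f1
  f2$velocities <- f1$velocities * k
  cl <- ph$centerlines$branches$MPA
  m <- function(f) {
    nf <- resample_to_mesh(f, ph$mesh)
    gf <- velocity_gradient(nf, ph$mesh)
    sl <- slice_at_fraction(ph$mesh, cl, 0.5, field = f)
    hel <- helicity_metrics(nf, gf, ph$mesh)
    list(q = flow_rate(sl)$cm3_s, cv = centerline_velocity(sl),
         wm = branch_vorticity(gf, mode = "magnitude-mean"),
         rf = reverse_flow_fraction(sl), hfi = hel$HFI,
         fp = hel$fraction_positive, hd = hel$H_d)
  }
  m1 <- m(f1); m2 <- m(f2)
  expect_equal(m2$q, k * m1$q, tolerance = 1e-9)
  expect_equal(m2$cv, k * m1$cv, tolerance = 1e-9)
  expect_equal(m2$wm, k * m1$wm, tolerance = 1e-9)
  expect_equal(m2$hd, k^2 * m1$hd, tolerance = 1e-9)
  expect_equal(m2$rf, m1$rf)
  expect_equal(m2$hfi, m1$hfi, tolerance = 1e-9)
  expect_equal(m2$fp, m1$fp)
})

test_that("HFI and fractions stay within their ranges", {
  for (case in c("poiseuille", "helical", "dean_pair")) {
    spec <- phantom_spec(case, R = 1, L = 3, element_size = 0.3)
    ph <- make_tube(spec)
    f <- make_field(spec)
    nf <- resample_to_mesh(f, ph$mesh)
    hel <- helicity_metrics(nf, velocity_gradient(nf, ph$mesh), ph$mesh)
    expect_gte(hel$HFI, 0); expect_lte(hel$HFI, 1)
    expect_gte(hel$fraction_positive, 0)
    expect_lte(hel$fraction_positive, 1)
  }
})

test_that("Dean number formula, straight-vessel and zero-flow limits", {
  # u_bar = 50 cm/s through a plug-flow tube slice, Rc = 5 cm
  ct <- coarse_tube()
  plug <- field_from_function(function(p) cbind(0, 0, rep(50, nrow(p))))
  slp <- slice_at_fraction(ct$mesh, ct$centerlines$branches$MPA, 0.5,
                           field = plug)
  de <- dean_number(slp, Rc = 5)
  D <- 2 * sqrt(slp$area / pi)
  expect_equal(de, 1.06 * 50 * D / 0.04 * sqrt(D / 10), tolerance = 1e-9)
  # against the printed example at exactly D = 2
  expect_equal(1.06 * 50 * 2 / 0.04 * sqrt(2 / 10), 1185.116,
               tolerance = 0.001 * 1185.1)
  expect_equal(dean_number(slp, Rc = Inf), 0)
  zero <- field_from_function(function(p) matrix(0, nrow(p), 3))
  slz <- slice_at_fraction(ct$mesh, ct$centerlines$branches$MPA, 0.5,
                           field = zero)
  expect_equal(dean_number(slz, Rc = 5), 0)
  expect_error(dean_number(slp, Rc = -1), "positive")
})

test_that("stiffness indices match hand arithmetic", {
  awf <- waveform(c(0, 0.2, 0.4, 0.6), c(4, 5, 4.5, 4.2), 0.8, "area")
  st <- area_stiffness_metrics(awf, SPAP = 25, DPAP = 15)
  expect_equal(st$RAC, 0.25, tolerance = 1e-12)
  expect_equal(st$compliance, 0.10, tolerance = 1e-12)
  expect_equal(st$distensibility, 2.5, tolerance = 1e-12)

  flat <- waveform(c(0, 0.2, 0.4, 0.6), rep(4, 4), 0.8)
  st0 <- area_stiffness_metrics(flat, 25, 15)
  expect_equal(st0$RAC, 0)
  expect_equal(st0$compliance, 0)
  expect_error(area_stiffness_metrics(awf, 20, 20), "SPAP")
  neg <- waveform(c(0, 0.2, 0.4, 0.6), c(-1, 5, 4, 4), 0.8)
  expect_error(area_stiffness_metrics(neg), "area")
})

test_that("percent-predicted RV normalization and reference constants", {
  k <- predicted_rv_constants()
  expect_equal(k$RVEF[c("a", "b", "c")],
               list(a = 0.0706, b = -0.00771, c = -0.0782))
  expect_equal(k$RVSV$m_female, 21.12)
  # measured == predicted -> exactly 100%
  pred <- k$RVEDV$m_male * 50^k$RVEDV$a * 180^k$RVEDV$b * 80^k$RVEDV$c
  expect_equal(percent_predicted_rv(pred, "RVEDV", "M", 50, 180, 80), 100,
               tolerance = 1e-12)
  # independent arithmetic for the RVEF example
  pred_ef <- 71.52 * 60^0.0706 * 170^-0.00771 * 75^-0.0782
  expect_equal(percent_predicted_rv(55, "RVEF", "M", 60, 170, 75),
               100 * 55 / pred_ef, tolerance = 1e-12)
  expect_error(percent_predicted_rv(55, "LVEF", "M", 60, 170, 75),
               "unknown")
  expect_error(percent_predicted_rv(55, "RVEF", "M", 60, 170, -75),
               "positive")
})

test_that("waveform summaries are time-weighted over half-open windows", {
  wf <- waveform(c(0, 0.2, 0.4, 0.6), c(0, 10, 20, 10), 0.8)
  sm <- summarize_waveform(wf, cardiac_windows(0, 0.4, 0.8))
  get <- function(w, s) sm$value[sm$window == w & sm$statistic == s]
  expect_equal(get("systole", "mean"), 10, tolerance = 1e-12)
  expect_equal(get("systole", "max"), 10)    # sample at 0.4 is excluded
  expect_equal(get("cycle", "max"), 20)
  expect_equal(get("cycle", "min"), 0)
  expect_equal(get("diastole", "mean"), 10, tolerance = 1e-12)

  const <- waveform(c(0, 0.2, 0.4, 0.6), rep(7, 4), 0.8)
  smc <- summarize_waveform(const, cardiac_windows(0.1, 0.5, 0.8))
  expect_true(all(abs(smc$value - 7) < 1e-12))

  # no samples inside a sliver window -> error
  expect_error(summarize_waveform(wf, cardiac_windows(0.65, 0.79, 0.8)),
               "no waveform samples")
  expect_error(cardiac_windows(0.5, 0.4, 0.8), "t_ED")
})

test_that("windows derived from a flow waveform bracket the upstroke", {
  t <- seq(0, 0.76, by = 0.04)
  v <- pmax(0, sin(pi * t / 0.4)) * 60
  wf <- waveform(t, v, 0.8)
  win <- windows_from_flow(wf)
  expect_lt(win$t_ED, 0.1)
  expect_gte(win$t_ES, 0.36)
  expect_lt(win$t_ES, 0.56)
})
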