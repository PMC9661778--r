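# Shared fixtures, memoized so heavy phantoms are built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# Poiseuille tube at the standard 1.2 mm element size (acceptance suite)
poiseuille_fixture <- function() fixture("poiseuille_fine", function() {
  spec <- phantom_spec("poiseuille", R = 1, L = 10, u_max = 40,
                       element_size = 0.12)
  ph <- make_tube(spec)
  field <- make_field(spec)
  nf <- resample_to_mesh(field, ph$mesh)
  gf <- velocity_gradient(nf, ph$mesh)
  list(spec = spec, mesh = ph$mesh, centerlines = ph$centerlines,
       field = field, nf = nf, gf = gf, gt = ground_truth(spec))
})

helical_fixture <- function() fixture("helical_fine", function() {
  spec <- phantom_spec("helical", R = 1, L = 10, Omega = 1, W = 1,
                       element_size = 0.12)
  ph <- make_tube(spec)
  field <- make_field(spec)
  nf <- resample_to_mesh(field, ph$mesh)
  gf <- velocity_gradient(nf, ph$mesh)
  list(spec = spec, mesh = ph$mesh, field = field, nf = nf, gf = gf,
       gt = ground_truth(spec))
})

# small coarse tube for cheap unit tests
coarse_tube <- function() fixture("coarse_tube", function() {
  spec <- phantom_spec("poiseuille", R = 1, L = 5, u_max = 40,
                       element_size = 0.25)
  ph <- make_tube(spec)
  list(spec = spec, mesh = ph$mesh, centerlines = ph$centerlines,
       field = make_field(spec))
})

# analytic velocity field object built directly from a function of (x,y,z)
field_from_function <- function(fun, lo = c(-1.3, -1.3, -0.3),
                                hi = c(1.3, 1.3, 5.3), spacing = 0.1,
                                frames = 1L, period = 1) {
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  ax <- lapply(1:3, function(d) lo[d] + spacing * (seq_len(dims[d]) - 1L))
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  u <- fun(pts)
  vel <- array(0, c(frames, dims, 3L))
  for (f in seq_len(frames)) for (comp in 1:3)
    vel[f, , , , comp] <- array(u[, comp], dims)
  velocity_field4d(vel, lo, rep(spacing, 3),
                   seq(0, period, length.out = frames + 1L)[seq_len(frames)],
                   period)
}

# one positively oriented unit-cube tetrahedralization (6-tet Kuhn split)
unit_cube_tets <- function() {
  corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))  # binary order
  idx <- function(x, y, z) as.integer(1L + x + 2L * y + 4L * z)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  tets <- t(vapply(perms, function(p) {
    v <- c(0, 0, 0)
    path <- integer(4)
    path[1] <- idx(0, 0, 0)
    for (k in 1:3) {
      v[p[k]] <- 1
      path[k + 1] <- idx(v[1], v[2], v[3])
    }
    path
  }, integer(4)))
  v <- tet_volumes(corners, tets)
  tets[v < 0, c(3, 4)] <- tets[v < 0, c(4, 3)]
  list(nodes = corners, tets = tets)
}
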