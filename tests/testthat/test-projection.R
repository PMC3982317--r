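# Patch tracing, boundary pinning and the Tutte-type projection.

test_that("patch tracing on a 3x3 quad grid finds the border loop", {
  g <- grid_quad_mesh(2, 2)
  corners <- c(which(g$uv[, 1] == 0 & g$uv[, 2] == 0),
               which(g$uv[, 1] == 2 & g$uv[, 2] == 0),
               which(g$uv[, 1] == 2 & g$uv[, 2] == 2),
               which(g$uv[, 1] == 0 & g$uv[, 2] == 2))
  centre <- which(g$uv[, 1] == 1 & g$uv[, 2] == 1)
  spec <- trace_patch(g$surface, corners, inside = centre)
  expect_setequal(spec$loop, g$border)
  expect_equal(spec$interior, centre)
  expect_error(trace_patch(g$surface, c(corners[1], corners[1], corners[3],
                                        corners[4])),
               class = "parasurf_bad_anchors")
})

test_that("traced boundary paths are shortest paths (BFS oracle)", {
  ph <- make_bumpy_hemisphere(radius = 8, bump_amplitude = 0.8,
                              bump_frequency = 3, spacing = 1)
  s <- extract_boundary_quads(ph$volume, 100)
  anch <- pick_nearest_vertices(s, phantom_equator_points(ph))
  spec <- trace_patch(s, anch)
  for (k in 1:4) {
    p <- spec$boundary_paths[[k]]
    d <- bfs_distances(s$adjacency, p[1L])
    # hop count equals the unweighted shortest-path distance
    expect_equal(length(p) - 1L, d[p[length(p)]])
  }
})

test_that("boundary pinning equidistributes path vertices on domain edges", {
  # open sheet: 4 x 2 grid of quads; anchors at its corners
  g <- grid_quad_mesh(4, 2)
  corners <- c(which(g$uv[, 1] == 0 & g$uv[, 2] == 0),
               which(g$uv[, 1] == 4 & g$uv[, 2] == 0),
               which(g$uv[, 1] == 4 & g$uv[, 2] == 2),
               which(g$uv[, 1] == 0 & g$uv[, 2] == 2))
  spec <- trace_patch(g$surface, corners,
                      inside = which(g$uv[, 1] == 2 & g$uv[, 2] == 1))
  # the 5-vertex path along v = 0 must get u = 0, .25, .5, .75, 1
  pin <- pin_boundary(spec, c(0, 1, 0, 1))
  p1 <- spec$boundary_paths[[1L]]
  got <- pin[match(p1[-length(p1)], pin$vertex), ]
  expect_equal(got$u, c(0, 0.25, 0.5, 0.75))
  expect_equal(got$v, rep(0, 4))
  u_last <- pin[match(p1[length(p1)], pin$vertex), ]
  expect_equal(unlist(u_last[c("u", "v")]), c(u = 1, v = 0))

  # the parametric axis extent is arbitrary: scaling the domain scales
  # the assignment
  pin100 <- pin_boundary(spec, c(0, 100, 0, 100))
  expect_equal(pin100$u, pin$u * 100)
  expect_equal(pin100$v, pin$v * 100)
})

test_that("projection satisfies the neighbour-mean stationarity", {
  # 1 interior vertex adjacent to 4 pinned corners -> the mean
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0), c(0.5, 0.5, 0))
  s <- build_connectivity(v, rbind(c(1, 2, 5), c(2, 3, 5), c(3, 4, 5),
                                   c(4, 1, 5)))
  pin <- data.frame(vertex = 1:4, u = c(0, 1, 1, 0), v = c(0, 0, 1, 1))
  pm <- solve_projection(s, pin, c(0, 1, 0, 1))
  expect_equal(pm$uv[5L, ], c(0.5, 0.5), tolerance = 1e-9)

  # 3x3 grid with uniformly pinned border: interior vertex at the centre
  g <- grid_quad_mesh(2, 2)
  pinb <- data.frame(vertex = g$border,
                     u = g$uv[g$border, 1] / 2, v = g$uv[g$border, 2] / 2)
  pm2 <- solve_projection(g$surface, pinb, c(0, 1, 0, 1))
  centre <- which(g$uv[, 1] == 1 & g$uv[, 2] == 1)
  expect_equal(pm2$uv[centre, ], c(0.5, 0.5), tolerance = 1e-9)
  expect_lt(max(stationarity_residual(pm2)), 1e-8)
})

test_that("the reduced projection system is symmetric and diagonally dominant", {
  g <- grid_quad_mesh(3, 3, jitter = 0)
  free <- setdiff(seq_len(nrow(g$uv)), g$border)
  deg <- lengths(g$surface$adjacency)
  # assemble the reduced matrix the way the solver sees it
  A <- matrix(0, length(free), length(free))
  for (i in seq_along(free)) {
    A[i, i] <- deg[free[i]]
    for (w in g$surface$adjacency[[free[i]]]) {
      j <- match(w, free)
      if (!is.na(j)) A[i, j] <- -1
    }
  }
  expect_equal(A, t(A))
  expect_true(all(diag(A) >= rowSums(abs(A)) - diag(A)))
  expect_true(all(eigen(A, symmetric = TRUE, only.values = TRUE)$values > 0))
})

test_that("projection equals the brute-force minimizer of the objective", {
  g2 <- grid_quad_mesh(4, 4)
  # non-uniform boundary spacing so the minimizer is non-trivial
  warp <- function(t) t^1.5
  pin2 <- data.frame(vertex = g2$border,
                     u = ifelse(g2$uv[g2$border, 1] %in% c(0, 4),
                                g2$uv[g2$border, 1] / 4,
                                warp(g2$uv[g2$border, 1] / 4)),
                     v = g2$uv[g2$border, 2] / 4)
  pm <- solve_projection(g2$surface, pin2, c(0, 1, 0, 1))
  free <- setdiff(seq_len(nrow(g2$uv)), g2$border)
  theta <- function(x) {
    uv <- pm$uv
    uv[free, ] <- matrix(x, ncol = 2L)
    tot <- 0
    for (nn in seq_len(nrow(uv))) {
      nb <- g2$surface$adjacency[[nn]]
      tot <- tot + sum((uv[nn, 1] - uv[nb, 1])^2 + (uv[nn, 2] - uv[nb, 2])^2)
    }
    tot
  }
  op <- stats::optim(rep(0.5, 2 * length(free)), theta, method = "BFGS",
                     control = list(maxit = 2000, reltol = 1e-15))
  expect_equal(as.vector(pm$uv[free, ]), op$par, tolerance = 1e-6)
})

test_that("phantom patch projections are one-to-one", {
  for (seed_ph in list(
    make_bumpy_hemisphere(radius = 8, bump_amplitude = 0.8,
                          bump_frequency = 3, spacing = 1),
    make_papillary_phantom(radius = 8, protrusion_length = 4,
                           protrusion_radius = 2, spacing = 1))) {
    pr <- project_phantom(seed_ph, domain = c(0, 1, 0, 1))
    expect_equal(flipped_elements(pr$pmesh), 0L)
    expect_lt(max(stationarity_residual(pr$pmesh)), 1e-8)
  }
})

test_that("collision repair fixes crossings and fuses parallel edges", {
  # identity on a clean mesh
  g <- grid_quad_mesh(2, 2)
  pm <- parametric_mesh(g$surface, g$uv / 2, g$border, c(0, 1, 0, 1))
  out <- repair_collisions(pm)
  expect_equal(out$uv, pm$uv)
  expect_length(attr(out, "modified"), 0L)

  # two crossing non-adjacent segments: both near endpoints moved to the
  # crossing point
  v <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(0, 2, 0),
             c(0.9, 0.9, 0), c(1.1, 1.1, 0), c(1.1, 0.9, 0), c(0.9, 1.1, 0))
  f <- rbind(c(1, 2, 6, 5), c(2, 3, 8, 7), c(3, 4, 5, 6), c(4, 1, 7, 8))
  s <- build_connectivity(v, f)
  uv <- v[, 1:2]
  pm2 <- parametric_mesh(s, uv, integer(0), c(0, 2, 0, 2))
  out2 <- repair_collisions(pm2, fuse_angle_tol = 0)
  # segments 5-6 and 7-8 cross at (1, 1): the near endpoints of both
  # segments are moved onto the crossing point
  moved <- attr(out2, "modified")
  expect_true(length(moved) >= 2L)
  at_crossing <- apply(out2$uv[moved, , drop = FALSE], 1L,
                       function(r) all(abs(r - 1) < 1e-9))
  expect_true(sum(at_crossing) >= 2L)

  # nearly parallel edges at a shared vertex get fused, adjacency stays
  # symmetric
  v3 <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 0.0001, 0), c(1, 1, 0))
  f3 <- rbind(c(1, 2, 3), c(1, 3, 4))
  s3 <- build_connectivity(v3, f3)
  pm3 <- parametric_mesh(s3, v3[, 1:2], integer(0), c(0, 2, 0, 1))
  out3 <- repair_collisions(pm3, fuse_angle_tol = 1e-3)
  expect_equal(attr(out3, "fused"), 1L)
  expect_lt(nrow(out3$uv), nrow(pm3$uv))
  adj <- out3$surface$adjacency
  sym_ok <- vapply(seq_along(adj), function(i) {
    all(vapply(adj[[i]], function(j) i %in% adj[[j]], logical(1L)))
  }, logical(1L))
  expect_true(all(sym_ok))
})
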