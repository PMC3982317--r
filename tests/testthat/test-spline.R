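# Cubic B-spline basis, surface evaluation, fitting, clamping, I/O.

test_that("1D basis: knot values, partition of unity, C2 support border", {
  n <- 6L
  # the three basis functions overlapping a knot carry 1/6, 2/3, 1/6
  u_knot <- 2 / n
  vals <- vapply(1:(n + 3L), function(j) basis_1d(u_knot, j, n), numeric(1L))
  expect_equal(sort(vals[vals > 1e-14]), c(1 / 6, 1 / 6, 2 / 3),
               tolerance = 1e-12)

  # partition of unity at random interior points
  u <- with_seed_local(5, stats::runif(50))
  tot <- Reduce(`+`, lapply(1:(n + 3L), function(j) basis_1d(u, j, n)))
  expect_equal(tot, rep(1, 50), tolerance = 1e-12)

  # value and first two derivatives vanish at the support border
  j <- 5L                       # support on elements 2..5, border 5/6
  expect_equal(basis_1d(5 / n, j, n, deriv = 0L), 0, tolerance = 1e-12)
  expect_equal(basis_1d(5 / n, j, n, deriv = 1L), 0, tolerance = 1e-12)
  expect_equal(basis_1d(5 / n, j, n, deriv = 2L), 0, tolerance = 1e-12)
  expect_equal(basis_1d(0.99, j, n), 0)  # zero outside the support
})

test_that("1D basis agrees with an independent de Boor recursion", {
  n <- 5L
  u <- with_seed_local(9, stats::runif(40, 0, 0.999))
  for (j in c(1L, 3L, 6L, n + 3L)) {
    expect_equal(basis_1d(u, j, n), deboor_basis(u, j, n, 0, 1),
                 tolerance = 1e-12)
  }
})

test_that("2D basis is separable with correct mixed derivatives", {
  pts <- with_seed_local(2, matrix(stats::runif(200), ncol = 2L))
  b2 <- basis_2d(pts[, 1], pts[, 2], 4L, 5L, 5L, 5L)
  expect_equal(b2, basis_1d(pts[, 1], 4L, 5L) * basis_1d(pts[, 2], 5L, 5L))
  # zero outside the 4x4 element window of coefficient (1,1)
  expect_equal(basis_2d(0.9, 0.9, 1L, 1L, 5L, 5L), 0)

  h <- 1e-5
  fd <- (basis_2d(0.41 + h, 0.33 + h, 4L, 5L, 5L, 5L) -
           basis_2d(0.41 + h, 0.33 - h, 4L, 5L, 5L, 5L) -
           basis_2d(0.41 - h, 0.33 + h, 4L, 5L, 5L, 5L) +
           basis_2d(0.41 - h, 0.33 - h, 4L, 5L, 5L, 5L)) / (4 * h^2)
  expect_equal(basis_2d(0.41, 0.33, 4L, 5L, 5L, 5L, du = 1L, dv = 1L), fd,
               tolerance = 1e-5)
})

test_that("evaluation is exact for constant coefficients and C2 at knots", {
  cf <- list(x = matrix(2.5, 8, 8), y = matrix(-1, 8, 8), z = matrix(0, 8, 8))
  surf <- spline_surface(5L, 5L, c(0, 1, 0, 1), cf)
  pts <- with_seed_local(4, matrix(stats::runif(40), ncol = 2L))
  ev <- evaluate_surface(surf, pts[, 1], pts[, 2])
  expect_equal(ev[, 1], rep(2.5, 20), tolerance = 1e-12)
  expect_equal(ev[, 2], rep(-1, 20), tolerance = 1e-12)

  # C2 across knot lines: one-sided evaluations from the two adjoining
  # elements agree exactly in the local weights
  for (d in 0:2) {
    wl <- bspline_weights(1, d)    # right end of element k
    wr <- bspline_weights(0, d)    # left end of element k + 1
    # coefficient k+m from the left = coefficient (k+1)+(m-1) from the
    # right: shift and compare
    expect_equal(unname(wl[1, ]), unname(c(0, wr[1, 1:3])), tolerance = 1e-12)
  }
  # and numerically on a random surface
  surf2 <- random_spline_surface(5L, 5L, seed = 10)
  eps <- 1e-9
  for (d in list(c(0, 0), c(1, 0), c(0, 1), c(2, 0), c(1, 1), c(0, 2))) {
    a <- evaluate_surface(surf2, 0.4 - eps, 0.77, d[1], d[2])
    b <- evaluate_surface(surf2, 0.4 + eps, 0.77, d[1], d[2])
    expect_equal(a, b, tolerance = 1e-6)
  }
  expect_error(evaluate_surface(surf2, 1.2, 0.5),
               class = "parasurf_out_of_domain")
})

test_that("lambda = 0 fit reproduces a surface in the spline space", {
  surf <- random_spline_surface(9L, 9L, seed = 20, bump = 1)
  gg <- expand.grid(u = seq(0, 1, length.out = 50),
                    v = seq(0, 1, length.out = 50))
  xyz <- evaluate_surface(surf, gg$u, gg$v)
  fit <- fit_surface(list(uv = as.matrix(gg), xyz = xyz, domain = c(0, 1, 0, 1)),
                     9L, 9L, lambda = 0)
  for (cc in c("x", "y", "z")) {
    expect_lt(max(abs(fit$coeffs[[cc]] - surf$coeffs[[cc]])) /
                max(abs(surf$coeffs[[cc]])), 1e-8)
  }
})

test_that("a plane stays a plane for any stiffness and fit is translation-equivariant", {
  gg <- with_seed_local(3, matrix(stats::runif(600), ncol = 2L))
  xyz <- cbind(2 * gg[, 1] - 1, 3 * gg[, 2], 0)
  for (lam in c(0, 0.3, 0.8)) {
    fit <- fit_surface(list(uv = gg, xyz = xyz, domain = c(0, 1, 0, 1)),
                       4L, 4L, lambda = lam)
    pts <- with_seed_local(8, matrix(stats::runif(60), ncol = 2L))
    expect_equal(max(abs(evaluate_surface(fit, pts[, 1], pts[, 2])[, 3])), 0,
                 tolerance = 1e-8)
    for (d in list(c(2, 0), c(1, 1), c(0, 2))) {
      dd <- evaluate_surface(fit, pts[, 1], pts[, 2], d[1], d[2])
      expect_equal(max(abs(dd)), 0, tolerance = 1e-6)
    }
  }
  # translation of the data translates the fit
  t3 <- c(10, -4, 2.5)
  f0 <- fit_surface(list(uv = gg, xyz = xyz, domain = c(0, 1, 0, 1)),
                    4L, 4L, lambda = 0.2)
  f1 <- fit_surface(list(uv = gg, xyz = sweep(xyz, 2L, -t3),
                         domain = c(0, 1, 0, 1)), 4L, 4L, lambda = 0.2)
  pts <- matrix(c(0.2, 0.8, 0.5, 0.5), ncol = 2L)
  expect_equal(evaluate_surface(f1, pts[, 1], pts[, 2]),
               sweep(evaluate_surface(f0, pts[, 1], pts[, 2]), 2L, -t3),
               tolerance = 1e-10)
})

test_that("curvature energy is non-increasing in lambda", {
  # wavy data not in the spline space
  gg <- as.matrix(expand.grid(u = seq(0, 1, length.out = 40),
                              v = seq(0, 1, length.out = 40)))
  xyz <- cbind(gg[, 1], gg[, 2],
               0.3 * sin(6 * pi * gg[, 1]) * cos(4 * pi * gg[, 2]))
  S <- parasurf:::stiffness_matrix(5L, 5L, c(0, 1, 0, 1))
  bend <- function(fit) {
    z <- as.vector(fit$coeffs$z)
    x <- as.vector(fit$coeffs$x)
    y <- as.vector(fit$coeffs$y)
    sum(vapply(list(x, y, z), function(w) as.numeric(t(w) %*% (S %*% w)),
               numeric(1L)))
  }
  energies <- vapply(seq(0, 0.9, by = 0.1), function(lam) {
    bend(fit_surface(list(uv = gg, xyz = xyz, domain = c(0, 1, 0, 1)),
                     5L, 5L, lambda = lam))
  }, numeric(1L))
  expect_true(all(diff(energies) <= 1e-8 * max(abs(energies))))
})

test_that("rank-deficient lambda = 0 fits raise the advisory error", {
  gg <- matrix(stats::runif(40, 0, 0.4), ncol = 2L)  # leaves elements empty
  xyz <- cbind(gg, 0)
  expect_error(fit_surface(list(uv = gg, xyz = xyz, domain = c(0, 1, 0, 1)),
                           5L, 5L, lambda = 0),
               class = "parasurf_singular_fit")
  expect_error(fit_surface(list(uv = gg, xyz = xyz, domain = c(0, 1, 0, 1)),
                           5L, 5L, lambda = 1),
               class = "parasurf_bad_config")
})

test_that("curve fitting: straight line exactly, circle to 1%", {
  s <- seq(0, 1, length.out = 80)
  seg <- cbind(1 + 2 * s, -3 + s, 0.5 - 0.5 * s)
  fc <- fit_curve(s, seg, n_b = 6L, domain = c(0, 1), lambda = 0)
  ev <- evaluate_curve(fc, s)
  expect_lt(max(abs(ev - seg)), 1e-10)

  th <- seq(0, 2 * pi, length.out = 200)
  circ <- cbind(cos(th), sin(th), 0)
  fcirc <- fit_curve(th / (2 * pi), circ, n_b = 9L, domain = c(0, 1),
                     lambda = 0)
  dense <- evaluate_curve(fcirc, seq(0.02, 0.98, length.out = 500))
  radial <- abs(sqrt(dense[, 1]^2 + dense[, 2]^2) - 1)
  expect_lt(max(radial), 0.01)
})

test_that("edge clamping matches the curve exactly and composes patches", {
  # clamp to a straight line; fit noisy data elsewhere
  line <- spline_curve(5L, c(0, 1),
                       list(x = seq(0, 2, length.out = 8L),
                            y = rep(0, 8L), z = rep(0, 8L)))
  gg <- with_seed_local(6, matrix(stats::runif(800), ncol = 2L))
  xyz <- cbind(2 * gg[, 1], gg[, 2],
               with_seed_local(7, stats::rnorm(400, sd = 0.1)))
  fit <- fit_surface(list(uv = gg, xyz = xyz, domain = c(0, 1, 0, 1)),
                     5L, 5L, lambda = 0.1,
                     clamp = list(edge = "vmin", curve = line))
  us <- seq(0, 1, length.out = 200)
  edge <- evaluate_surface(fit, us, rep(0, 200))
  expect_lt(max(abs(edge - evaluate_curve(line, us))), 1e-10)

  # clamp curve = restriction of a known surface; lambda = 0 fit recovers
  # the full surface through the constraint
  surf <- random_spline_surface(5L, 5L, seed = 30, bump = 0.5)
  gg2 <- as.matrix(expand.grid(u = seq(0, 1, length.out = 30),
                               v = seq(0, 1, length.out = 30)))
  xyz2 <- evaluate_surface(surf, gg2[, 1], gg2[, 2])
  crv <- edge_curve(surf, "vmin")
  fit2 <- fit_surface(list(uv = gg2, xyz = xyz2, domain = c(0, 1, 0, 1)),
                      5L, 5L, lambda = 0,
                      clamp = list(edge = "vmin", curve = crv))
  for (cc in c("x", "y", "z")) {
    expect_lt(max(abs(fit2$coeffs[[cc]] - surf$coeffs[[cc]])), 1e-7)
  }

  # two patches clamped to the same curve join with a C0 seam
  fit3 <- fit_surface(list(uv = gg2, xyz = xyz2 + 0.2, domain = c(0, 1, 0, 1)),
                      5L, 5L, lambda = 0.05,
                      clamp = list(edge = "vmax", curve = crv))
  gap <- evaluate_surface(fit2, us, rep(0, 200)) -
    evaluate_surface(fit3, us, rep(1, 200))
  expect_lt(max(abs(gap)), 1e-9)

  # element-count mismatch is rejected with both values quoted
  bad <- spline_curve(4L, c(0, 1), list(x = rep(0, 7), y = rep(0, 7),
                                        z = rep(0, 7)))
  err <- expect_error(
    fit_surface(list(uv = gg2, xyz = xyz2, domain = c(0, 1, 0, 1)), 5L, 5L,
                lambda = 0.1, clamp = list(edge = "vmin", curve = bad)),
    class = "parasurf_bad_config")
  expect_equal(err$data$curve_n, 4L)
  expect_equal(err$data$axis_n, 5L)
})

test_that("GMRES and direct solvers agree", {
  gg <- as.matrix(expand.grid(u = seq(0, 1, length.out = 25),
                              v = seq(0, 1, length.out = 25)))
  xyz <- cbind(gg[, 1], gg[, 2], sin(2 * pi * gg[, 1]))
  fd <- fit_surface(list(uv = gg, xyz = xyz, domain = c(0, 1, 0, 1)),
                    4L, 4L, lambda = 0.1, solver = "direct")
  fg <- fit_surface(list(uv = gg, xyz = xyz, domain = c(0, 1, 0, 1)),
                    4L, 4L, lambda = 0.1, solver = "gmres", tol = 1e-12)
  expect_equal(fg$coeffs$z, fd$coeffs$z, tolerance = 1e-6)
})

test_that("JSON serialization round-trips and tessellation exports", {
  surf <- random_spline_surface(4L, 6L, seed = 40)
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "s.json")
  write_spline_json(surf, p1)
  back <- read_spline_json(p1)
  expect_equal(back$coeffs, surf$coeffs, tolerance = 1e-13)
  expect_equal(back$domain, surf$domain)
  # write/read/write is byte-identical on the decimal representation
  p2 <- file.path(dir, "s2.json")
  write_spline_json(back, p2)
  expect_identical(readLines(p1), readLines(p2))

  tess <- tessellate_surface(surf, 12L, 10L)
  expect_equal(nrow(tess$vertices), 120L)
  expect_equal(nrow(tess$faces), 11L * 9L)
})
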