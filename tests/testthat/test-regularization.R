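# Element Jacobians, the deformation energy, and the regularizer.

ref_unit <- reference_map("quad", scale = 1)
unit_square <- rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1))

make_pmesh <- function(uv, faces, fixed = integer(0)) {
  s <- build_connectivity(cbind(uv, 0), faces)
  dom <- c(min(uv[, 1]), max(uv[, 1]), min(uv[, 2]), max(uv[, 2]))
  parametric_mesh(s, uv, fixed, dom)
}

test_that("element Jacobian: translation, scaling, finite differences", {
  J <- element_jacobian(unit_square + 3, 0.3, -0.7, ref_unit)
  expect_equal(J, diag(2), tolerance = 1e-12)
  expect_equal(det(J), 1, tolerance = 1e-12)

  Js <- element_jacobian(2.5 * unit_square, -0.2, 0.4, ref_unit)
  expect_equal(Js, 2.5 * diag(2), tolerance = 1e-12)

  # bilinearly warped quad vs central finite differences of the map
  warp <- rbind(c(-1.2, -0.9), c(1.1, -1.3), c(0.8, 1.4), c(-1.4, 0.7))
  shape <- function(xi, eta) {
    N <- c((1 - xi) * (1 - eta), (1 + xi) * (1 - eta),
           (1 + xi) * (1 + eta), (1 - xi) * (1 + eta)) / 4
    as.vector(t(warp) %*% N)
  }
  h <- 1e-6
  for (pt in list(c(-1, -1) / sqrt(3), c(1, 1) / sqrt(3))) {
    Jw <- element_jacobian(warp, pt[1], pt[2], ref_unit)
    fd <- cbind((shape(pt[1] + h, pt[2]) - shape(pt[1] - h, pt[2])) / (2 * h),
                (shape(pt[1], pt[2] + h) - shape(pt[1], pt[2] - h)) / (2 * h))
    expect_equal(Jw, fd, tolerance = 1e-6)
  }
})

test_that("deformation energy has its closed-form values", {
  # a uniform grid of reference-sized squares: zero energy, zero gradient
  g <- grid_quad_mesh(3, 3)
  pm <- make_pmesh(2 * g$uv, g$surface$faces)
  obj <- regularization_objective(pm, ref_unit)
  expect_equal(obj$energy, 0, tolerance = 1e-20)
  expect_equal(max(abs(obj$gradient)), 0, tolerance = 1e-12)

  # single element scaled by s = 2: energy = A_ref * 2 * (s - 1/s)^2
  pm2 <- make_pmesh(2 * unit_square + 5, matrix(1:4, 1L))
  e2 <- regularization_objective(pm2, ref_unit)$energy
  expect_equal(e2, 4 * 2 * (2 - 0.5)^2, tolerance = 1e-12)

  # rotation leaves the energy unchanged (rotation changes neither area
  # nor edge length)
  th <- 73 * pi / 180
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  pm3 <- make_pmesh(unit_square %*% t(Rm), matrix(1:4, 1L))
  expect_equal(regularization_objective(pm3, ref_unit)$energy, 0,
               tolerance = 1e-20)
})

test_that("analytic gradient matches central finite differences", {
  g <- grid_quad_mesh(3, 3)
  uv <- g$uv
  inner <- setdiff(seq_len(nrow(uv)), g$border)
  uv[inner, ] <- uv[inner, ] +
    with_seed_local(42, matrix(stats::runif(2 * length(inner), -0.25, 0.25),
                               ncol = 2L))
  pm <- make_pmesh(uv, g$surface$faces)
  ref <- reference_map("quad", sqrt(mean(abs(element_signed_areas(pm)))) / 2)
  obj <- regularization_objective(pm, ref)
  h <- 1e-6
  for (vi in inner) for (cc in 1:2) {
    up <- uv; up[vi, cc] <- up[vi, cc] + h
    dn <- uv; dn[vi, cc] <- dn[vi, cc] - h
    fd <- (regularization_objective(make_pmesh(up, g$surface$faces), ref)$energy -
             regularization_objective(make_pmesh(dn, g$surface$faces), ref)$energy) / (2 * h)
    expect_equal(obj$gradient[vi, cc], fd, tolerance = 1e-5)
  }
})

test_that("degenerate elements trigger the penalty branch", {
  uv <- unit_square
  uv[3L, ] <- c(-2, -2)   # inverted quad
  pm <- make_pmesh(rbind(uv, c(5, 5)), matrix(1:4, 1L))
  obj <- regularization_objective(pm, ref_unit)
  expect_equal(obj$energy, Inf)
  expect_lt(obj$min_det, 0)
})

test_that("regularization equalizes a perturbed grid and fixes the boundary", {
  g <- grid_quad_mesh(5, 5)
  uv <- g$uv
  inner <- setdiff(seq_len(nrow(uv)), g$border)
  uv[inner, ] <- uv[inner, ] +
    with_seed_local(7, matrix(stats::runif(2 * length(inner), -0.35, 0.35),
                              ncol = 2L))
  pm <- make_pmesh(uv, g$surface$faces, g$border)
  reg <- regularize(pm, max_iters = 100)
  info <- attr(reg, "regularization")
  expect_identical(reg$uv[g$border, ], pm$uv[g$border, ])
  expect_true(all(diff(info$energy_trace) <= 0))
  expect_lt(tail(info$energy_trace, 1L), info$energy_trace[1L])
  expect_equal(flipped_elements(reg), 0L)
  expect_lt(area_cv(reg), area_cv(pm))

  # an already-regular grid returns unchanged
  pm0 <- make_pmesh(g$uv, g$surface$faces, g$border)
  reg0 <- regularize(pm0)
  expect_equal(reg0$uv, pm0$uv, tolerance = 1e-12)
  expect_equal(attr(reg0, "regularization")$iterations, 0L)
})

test_that("final energy matches a black-box minimizer on a small mesh", {
  # irregular pinned boundary so the optimum energy is nonzero
  g <- grid_quad_mesh(4, 4)
  uv <- g$uv
  warp <- function(t) 4 * (t / 4)^1.6
  uv[g$border, 1] <- ifelse(uv[g$border, 2] %in% c(0, 4),
                            warp(uv[g$border, 1]), uv[g$border, 1])
  inner <- setdiff(seq_len(nrow(uv)), g$border)
  uv[inner, 1] <- warp(uv[inner, 1])
  pm <- make_pmesh(uv, g$surface$faces, g$border)
  sig <- sqrt(mean(abs(element_signed_areas(pm)))) / 2
  reg <- regularize(pm, epsilon = 1e-12, max_iters = 500,
                    reference_scale = sig)
  e_ours <- tail(attr(reg, "regularization")$energy_trace, 1L)

  ref <- reference_map("quad", sig)
  obj_at <- function(x) {
    pm2 <- pm
    pm2$uv[inner, ] <- matrix(x, ncol = 2L)
    regularization_objective(pm2, ref)
  }
  fn <- function(x) {
    o <- obj_at(x)
    if (!is.finite(o$energy)) 1e12 else o$energy
  }
  gr <- function(x) {
    o <- obj_at(x)
    if (is.null(o$gradient)) return(numeric(2L * length(inner)))
    as.vector(o$gradient[inner, ])
  }
  op <- stats::optim(as.vector(uv[inner, ]), fn, gr, method = "BFGS",
                     control = list(maxit = 3000, reltol = 1e-14))
  expect_lt(abs(e_ours - op$value) / op$value, 0.01)
})

test_that("triangle meshes are regularized with the same machinery", {
  # split a jittered quad grid into triangles
  g <- grid_quad_mesh(4, 4)
  f4 <- g$surface$faces
  f3 <- rbind(f4[, c(1, 2, 3)], f4[, c(1, 3, 4)])
  uv <- g$uv
  inner <- setdiff(seq_len(nrow(uv)), g$border)
  uv[inner, ] <- uv[inner, ] +
    with_seed_local(3, matrix(stats::runif(2 * length(inner), -0.3, 0.3),
                              ncol = 2L))
  pm <- make_pmesh(uv, f3, g$border)
  reg <- regularize(pm, max_iters = 80)
  info <- attr(reg, "regularization")
  expect_true(all(diff(info$energy_trace) <= 0))
  expect_equal(flipped_elements(reg), 0L)
  expect_lt(area_cv(reg), area_cv(pm))
})
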