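# Closest point-to-surface distances: quintic roots, candidate search,
# Newton refinement, reports.

test_that("companion-matrix roots match an independent polynomial solver", {
  maxerr <- 0
  mismatches <- 0L
  with_seed_local(13, {
    for (i in 1:150) {
      co <- stats::rnorm(6)
      if (i %% 3 == 0) co[6] <- 0          # quintic degenerates to quartic
      if (i %% 7 == 0) co[5:6] <- 0        # ... and to a cubic
      r1 <- sort(polynomial_real_roots(co))
      pr <- polyroot(co[seq_len(max(which(abs(co) > 0)))])
      r2 <- sort(Re(pr)[abs(Im(pr)) < 1e-8 * (1 + abs(Re(pr)))])
      if (length(r1) != length(r2)) mismatches <- mismatches + 1L
      else if (length(r1)) maxerr <- max(maxerr, max(abs(r1 - r2)))
    }
  })
  expect_equal(mismatches, 0L)
  expect_lt(maxerr, 1e-9)
})

test_that("coordinate-line candidates find the perpendicular foot on a plane", {
  # plane z = 0 parameterized isometrically on [0,1]^2
  k <- seq(0, 1, length.out = 8)  # Greville-like linear coefficients
  cf <- list(x = outer(seq(-1 / 5, 1 + 1 / 5, length.out = 8), rep(1, 8)),
             y = outer(rep(1, 8), seq(-1 / 5, 1 + 1 / 5, length.out = 8)),
             z = matrix(0, 8, 8))
  surf <- spline_surface(5L, 5L, c(0, 1, 0, 1), cf)
  # with this coefficient layout X(u, v) = (u, v, 0) exactly
  expect_equal(evaluate_surface(surf, 0.3, 0.6)[1, ], c(x = 0.3, y = 0.6, z = 0),
               tolerance = 1e-12)
  cand <- coordinate_line_candidates(surf, c(0.3, 0.6, 1), c(2L, 4L))
  # the in-element root of the quintic along the line v = 0.6 is u = 0.3
  on_line <- cand[abs(cand[, "v"] - 0.6) < 1e-12, , drop = FALSE]
  expect_true(any(abs(on_line[, "u"] - 0.3) < 1e-9))
  # all candidates stay inside the closed element
  expect_true(all(cand[, "u"] >= 0.2 - 1e-9 & cand[, "u"] <= 0.4 + 1e-9))
  expect_true(all(cand[, "v"] >= 0.6 - 1e-9 & cand[, "v"] <= 0.8 + 1e-9))

  b <- point_surface_distance(surf, c(0.3, 0.6, 1))
  expect_equal(b$distance, 1, tolerance = 1e-10)
  expect_equal(c(b$u, b$v), c(0.3, 0.6), tolerance = 1e-8)
})

test_that("refinement is monotone and exact at a minimum", {
  surf <- random_spline_surface(5L, 5L, seed = 17)
  p0 <- evaluate_surface(surf, 0.43, 0.61)[1L, ]
  # start at the true minimum: returned unchanged
  at_min <- refine_minimum(surf, p0, c(0.43, 0.61))
  expect_equal(c(at_min$u, at_min$v), c(0.43, 0.61), tolerance = 1e-7)
  expect_lt(at_min$distance, 1e-9)

  # refinement never increases the distance
  with_seed_local(21, {
    for (i in 1:20) {
      pt <- c(stats::runif(1, 0, 3), stats::runif(1, 0, 3),
              stats::rnorm(1, sd = 0.6))
      start <- stats::runif(2, 0.05, 0.95)
      d0 <- sqrt(sum((evaluate_surface(surf, start[1], start[2])[1L, ] - pt)^2))
      refd <- refine_minimum(surf, pt, start)
      expect_lte(refd$distance, d0 + 1e-12)
    }
  })
})

test_that("distances match the dense-sampling oracle and respect symmetry", {
  surf <- random_spline_surface(4L, 4L, seed = 23)
  diag_phys <- {
    bb <- apply(do.call(rbind, lapply(surf$coeffs, range)), 2L, range)
    sqrt(sum((vapply(surf$coeffs, function(m) diff(range(m)), numeric(1L)))^2))
  }
  with_seed_local(29, {
    for (i in 1:12) {
      pt <- c(stats::runif(1, -0.5, 3.5), stats::runif(1, -0.5, 3.5),
              stats::rnorm(1, sd = 0.8))
      fast <- point_surface_distance(surf, pt)$distance
      oracle <- dense_distance_oracle(surf, pt, n_grid = 300L)
      expect_lt(abs(fast - oracle), 1e-5 * diag_phys)
    }
  })

  # reflecting surface and point through the plane x = 0 preserves distance
  refl <- surf
  refl$coeffs$x <- -refl$coeffs$x
  refl <- spline_surface(surf$n_bx, surf$n_by, surf$domain, refl$coeffs)
  pt <- c(1.3, 0.7, 0.9)
  d1 <- point_surface_distance(surf, pt)$distance
  d2 <- point_surface_distance(refl, pt * c(-1, 1, 1))$distance
  expect_equal(d1, d2, tolerance = 1e-10)
})

test_that("distance reports are consistent and serialize to CSV", {
  surf <- random_spline_surface(4L, 4L, seed = 31)
  gg <- with_seed_local(33, matrix(stats::runif(30, 0.05, 0.95), ncol = 2L))
  on_surface <- evaluate_surface(surf, gg[, 1], gg[, 2])
  rep0 <- distance_report(surf, on_surface)
  expect_lt(rep0$summary[["max"]], 1e-8)
  expect_lt(rep0$summary[["variance"]], 1e-16)

  # points offset along the surface normal: mean ~ offset, variance ~ 0
  Xu <- evaluate_surface(surf, gg[, 1], gg[, 2], 1L, 0L)
  Xv <- evaluate_surface(surf, gg[, 1], gg[, 2], 0L, 1L)
  nrm <- cbind(Xu[, 2] * Xv[, 3] - Xu[, 3] * Xv[, 2],
               Xu[, 3] * Xv[, 1] - Xu[, 1] * Xv[, 3],
               Xu[, 1] * Xv[, 2] - Xu[, 2] * Xv[, 1])
  nrm <- nrm / sqrt(rowSums(nrm^2))
  off <- distance_report(surf, on_surface + 0.04 * nrm)
  expect_equal(off$summary[["mean"]], 0.04, tolerance = 1e-4)
  expect_lt(off$summary[["variance"]], 1e-8)

  # summary consistent with per-point values
  d <- off$per_point$distance
  expect_equal(off$summary[["min"]], min(d), tolerance = 1e-12)
  expect_equal(off$summary[["max"]], max(d), tolerance = 1e-12)
  expect_equal(off$summary[["mean"]], mean(d), tolerance = 1e-12)
  expect_equal(off$summary[["variance"]], mean((d - mean(d))^2),
               tolerance = 1e-12)

  path <- withr::local_tempfile(fileext = ".csv")
  write_distance_csv(off, path)
  got <- utils::read.csv(path)
  expect_equal(nrow(got), nrow(off$per_point) + 4L)
  expect_equal(got$point_id[nrow(got) - 3L], "min")
  expect_error(distance_report(surf, matrix(numeric(0), 0L, 3L)),
               class = "parasurf_empty_points")
})
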