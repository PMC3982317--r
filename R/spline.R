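# Tensor-product cubic B-spline surfaces on a uniformly subdivided
# rectangular parametric domain.
#
# The parametric plane is split into n_bx x n_by equal elements; each
# axis carries n + 3 coefficients (the interior junction control points
# plus one extra row/column at each end so border elements have full
# degrees of freedom).  The basis is the uniform cubic B-spline: each
# 1D basis spans 4 knot segments, its value and first two derivatives
# vanish at the support border, the overlapping basis functions sum to 1
# everywhere (partition of unity), and any coefficient combination is C2
# across knot lines.  2D basis functions are tensor products b(u) b(v),
# indexed u-fastest ("boolean order, u-coordinate first").

# cubic B-spline weights of the 4 active coefficients on one element,
# local coordinate t in [0, 1]; deriv is the derivative order wrt t
bspline_weights <- function(t, deriv = 0L) {
  switch(as.character(deriv),
    "0" = cbind((1 - t)^3 / 6,
                (3 * t^3 - 6 * t^2 + 4) / 6,
                (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
                t^3 / 6),
    "1" = cbind(-(1 - t)^2 / 2,
                (9 * t^2 - 12 * t) / 6,
                (-9 * t^2 + 6 * t + 3) / 6,
                t^2 / 2),
    "2" = cbind(1 - t,
                3 * t - 2,
                -3 * t + 1,
                t),
    stop("derivative order must be 0, 1 or 2"))
}

# element index and local coordinate for points u on an n-element axis
locate_elements <- function(u, lo, hi, n) {
  h <- (hi - lo) / n
  tolr <- 1e-9 * (hi - lo)
  if (any(u < lo - tolr | u > hi + tolr)) {
    psf_stop("parametric coordinate outside the domain (no extrapolation)",
             "out_of_domain", list(range = c(lo, hi)))
  }
  k <- pmin(pmax(floor((u - lo) / h) + 1L, 1L), n)
  t <- (u - lo) / h - (k - 1L)
  list(k = as.integer(k), t = pmin(pmax(t, 0), 1), h = h)
}

#' Elementary 1D cubic B-spline basis
#'
#' Value (and derivatives) of the basis function attached to coefficient
#' `j` (1-based, `j = 1..n + 3`) of a uniform cubic B-spline axis with
#' `n` equal elements on `[lo, hi]`.  The support spans the 4 knot
#' segments `j - 3 .. j` (clipped to the axis); the function and its
#' first two derivatives vanish at the support border, and all basis
#' functions overlapping a point sum to exactly 1.
#'
#' @param u evaluation points (vector).
#' @param j coefficient index in `1..n + 3`.
#' @param n number of elements.
#' @param lo,hi axis domain.
#' @param deriv derivative order, 0..2.
#' @return numeric vector of basis values (derivatives are with respect
#'   to `u`, i.e. scaled by the knot spacing).
#' @export
basis_1d <- function(u, j, n, lo = 0, hi = 1, deriv = 0L) {
  le <- locate_elements(u, lo, hi, n)
  m <- j - le$k            # position of coefficient j within the element
  out <- numeric(length(u))
  act <- m >= 0L & m <= 3L
  if (any(act)) {
    w <- bspline_weights(le$t[act], deriv)
    out[act] <- w[cbind(seq_len(sum(act)), m[act] + 1L)] / le$h^deriv
  }
  out
}

#' Tensor-product 2D basis function
#'
#' `B_s(u, v) = b(u) b(v)` for the coefficient with u-index `ju` and
#' v-index `jv` of a [spline_surface()] geometry; supports all derivative
#' pairs up to order 2 (e.g. the mixed `B_uv` used by the stiffness
#' penalty).
#'
#' @param u,v evaluation points.
#' @param ju,jv coefficient indices (`1..n + 3` on each axis).
#' @param n_bx,n_by element counts.
#' @param domain `c(umin, umax, vmin, vmax)`.
#' @param du,dv derivative orders along u and v.
#' @return numeric vector.
#' @export
basis_2d <- function(u, v, ju, jv, n_bx, n_by, domain = c(0, 1, 0, 1),
                     du = 0L, dv = 0L) {
  basis_1d(u, ju, n_bx, domain[1], domain[2], du) *
    basis_1d(v, jv, n_by, domain[3], domain[4], dv)
}

#' Construct a spline surface
#'
#' @param n_bx,n_by element counts along u and v.
#' @param domain `c(umin, umax, vmin, vmax)`.
#' @param coeffs list with numeric `(n_bx + 3) x (n_by + 3)` matrices
#'   `x`, `y`, `z` (rows index the u direction).
#' @return object of class `spline_surface`.
#' @export
spline_surface <- function(n_bx, n_by, domain, coeffs) {
  n_bx <- as.integer(n_bx); n_by <- as.integer(n_by)
  stopifnot(n_bx >= 1L, n_by >= 1L, length(domain) == 4L,
            domain[2] > domain[1], domain[4] > domain[3])
  if (!all(c("x", "y", "z") %in% names(coeffs))) {
    psf_stop("coeffs must contain matrices x, y, z", "bad_spline")
  }
  for (nm in c("x", "y", "z")) {
    cm <- coeffs[[nm]]
    if (!is.matrix(cm) || !identical(dim(cm), c(n_bx + 3L, n_by + 3L))) {
      psf_stop(sprintf("coeffs$%s must be (n_bx+3) x (n_by+3)", nm),
               "bad_spline")
    }
  }
  structure(list(n_bx = n_bx, n_by = n_by, domain = as.numeric(domain),
                 coeffs = lapply(coeffs[c("x", "y", "z")], unname),
                 cache = new.env(parent = emptyenv())),
            class = "spline_surface")
}

#' @export
print.spline_surface <- function(x, ...) {
  cat(sprintf("<spline_surface> %d x %d elements, %d x %d coefficients per coordinate, domain [%g,%g]x[%g,%g]\n",
              x$n_bx, x$n_by, x$n_bx + 3L, x$n_by + 3L,
              x$domain[1], x$domain[2], x$domain[3], x$domain[4]))
  invisible(x)
}

#' Evaluate a spline surface
#'
#' Evaluates position or any derivative up to second order at parametric
#' points; evaluation is exact on the closed domain and errors outside it
#' (no extrapolation).  Values and first/second derivatives are
#' continuous across every knot line (the C2 property of the cubic
#' B-spline basis).
#'
#' @param surface a `spline_surface`.
#' @param u,v parametric coordinates (vectors of equal length).
#' @param du,dv derivative orders (0..2 each).
#' @return numeric `length(u) x 3` matrix.
#' @export
evaluate_surface <- function(surface, u, v, du = 0L, dv = 0L) {
  stopifnot(length(u) == length(v), du %in% 0:2, dv %in% 0:2)
  dom <- surface$domain
  lu <- locate_elements(u, dom[1], dom[2], surface$n_bx)
  lv <- locate_elements(v, dom[3], dom[4], surface$n_by)
  wu <- bspline_weights(lu$t, du) / lu$h^du
  wv <- bspline_weights(lv$t, dv) / lv$h^dv
  out <- matrix(0, length(u), 3L)
  for (ci in 1:3) {
    C <- surface$coeffs[[ci]]
    acc <- numeric(length(u))
    for (m in 0:3) for (nn in 0:3) {
      acc <- acc + wu[, m + 1L] * wv[, nn + 1L] *
        C[cbind(lu$k + m, lv$k + nn)]
    }
    out[, ci] <- acc
  }
  colnames(out) <- c("x", "y", "z")
  out
}

#' Construct a spline curve
#'
#' 1D analog of [spline_surface()]: a 3D curve with `n_b + 3`
#' coefficients per coordinate over `n_b` equal elements.
#'
#' @param n_b element count.
#' @param domain `c(lo, hi)`.
#' @param coeffs list with numeric length-`n_b + 3` vectors `x`, `y`, `z`.
#' @return object of class `spline_curve`.
#' @export
spline_curve <- function(n_b, domain, coeffs) {
  n_b <- as.integer(n_b)
  stopifnot(n_b >= 1L, length(domain) == 2L, domain[2] > domain[1])
  for (nm in c("x", "y", "z")) {
    if (length(coeffs[[nm]]) != n_b + 3L) {
      psf_stop(sprintf("coeffs$%s must have length n_b + 3", nm), "bad_spline")
    }
  }
  structure(list(n_b = n_b, domain = as.numeric(domain),
                 coeffs = lapply(coeffs[c("x", "y", "z")], unname)),
            class = "spline_curve")
}

#' Evaluate a spline curve
#' @param curve a `spline_curve`.
#' @param s parameter values.
#' @param deriv derivative order (0..2).
#' @return numeric `length(s) x 3` matrix.
#' @export
evaluate_curve <- function(curve, s, deriv = 0L) {
  le <- locate_elements(s, curve$domain[1], curve$domain[2], curve$n_b)
  w <- bspline_weights(le$t, deriv) / le$h^deriv
  out <- matrix(0, length(s), 3L)
  for (ci in 1:3) {
    co <- curve$coeffs[[ci]]
    acc <- numeric(length(s))
    for (m in 0:3) acc <- acc + w[, m + 1L] * co[le$k + m]
    out[, ci] <- acc
  }
  colnames(out) <- c("x", "y", "z")
  out
}

# 1D Gram matrices int b_i^(a) b_j^(a) du for a = 0, 1, 2, by 4-point
# Gauss-Legendre per element (exact: integrands are degree <= 6)
gram_1d <- function(n, lo, hi, deriv) {
  h <- (hi - lo) / n
  gp <- c(-0.861136311594053, -0.339981043584856,
          0.339981043584856, 0.861136311594053)
  gw <- c(0.347854845137454, 0.652145154862546,
          0.652145154862546, 0.347854845137454)
  tq <- (gp + 1) / 2           # element-local coordinates
  wq <- gw / 2 * h             # du = h dt
  W <- bspline_weights(tq, deriv) / h^deriv   # 4 qp x 4 basis
  G <- matrix(0, n + 3L, n + 3L)
  block <- matrix(0, 4L, 4L)
  for (a in 1:4) for (b in 1:4) block[a, b] <- sum(wq * W[, a] * W[, b])
  for (k in seq_len(n)) {
    idx <- k:(k + 3L)
    G[idx, idx] <- G[idx, idx] + block
  }
  G
}

# sparse design matrix: rows = data points, cols = coefficients
# (column-major over the (n_bx+3) x (n_by+3) grid, u index fastest)
design_matrix <- function(u, v, n_bx, n_by, domain) {
  lu <- locate_elements(u, domain[1], domain[2], n_bx)
  lv <- locate_elements(v, domain[3], domain[4], n_by)
  wu <- bspline_weights(lu$t, 0L)
  wv <- bspline_weights(lv$t, 0L)
  npt <- length(u)
  nrow_u <- n_bx + 3L
  ii <- jj <- xx <- vector("list", 16L)
  slot <- 0L
  for (m in 0:3) for (nn in 0:3) {
    slot <- slot + 1L
    ii[[slot]] <- seq_len(npt)
    jj[[slot]] <- (lu$k + m) + nrow_u * (lv$k + nn - 1L)
    xx[[slot]] <- wu[, m + 1L] * wv[, nn + 1L]
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(npt, nrow_u * (n_by + 3L)))
}

# curvature/twist stiffness matrix: the quadratic form of
# int (X_uu^2 + 2 X_uv^2 + X_vv^2) dOmega over the coefficient vector
stiffness_matrix <- function(n_bx, n_by, domain) {
  Gu0 <- Matrix::Matrix(gram_1d(n_bx, domain[1], domain[2], 0L), sparse = TRUE)
  Gu1 <- Matrix::Matrix(gram_1d(n_bx, domain[1], domain[2], 1L), sparse = TRUE)
  Gu2 <- Matrix::Matrix(gram_1d(n_bx, domain[1], domain[2], 2L), sparse = TRUE)
  Gv0 <- Matrix::Matrix(gram_1d(n_by, domain[3], domain[4], 0L), sparse = TRUE)
  Gv1 <- Matrix::Matrix(gram_1d(n_by, domain[3], domain[4], 1L), sparse = TRUE)
  Gv2 <- Matrix::Matrix(gram_1d(n_by, domain[3], domain[4], 2L), sparse = TRUE)
  Matrix::kronecker(Gv0, Gu2) + 2 * Matrix::kronecker(Gv1, Gu1) +
    Matrix::kronecker(Gv2, Gu0)
}

# simple restarted GMRES for sparse symmetric-positive systems; kept as
# an alternative solver mirroring the iterative option
gmres_solve <- function(A, b, tol = 1e-10, restart = 50L, max_cycles = 200L) {
  n <- length(b)
  x <- numeric(n)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(x)
  for (cycle in seq_len(max_cycles)) {
    r <- b - as.vector(A %*% x)
    beta <- sqrt(sum(r^2))
    if (beta / bnorm <= tol) return(x)
    m <- restart
    Q <- matrix(0, n, m + 1L)
    H <- matrix(0, m + 1L, m)
    Q[, 1L] <- r / beta
    for (j in seq_len(m)) {
      w <- as.vector(A %*% Q[, j])
      for (i in seq_len(j)) {
        H[i, j] <- sum(w * Q[, i])
        w <- w - H[i, j] * Q[, i]
      }
      H[j + 1L, j] <- sqrt(sum(w^2))
      if (H[j + 1L, j] > 1e-300) Q[, j + 1L] <- w / H[j + 1L, j]
      e1 <- c(beta, numeric(j))
      y <- qr.solve(H[seq_len(j + 1L), seq_len(j), drop = FALSE], e1)
      res <- sqrt(sum((H[seq_len(j + 1L), seq_len(j), drop = FALSE] %*% y - e1)^2))
      if (res / bnorm <= tol || j == m) {
        x <- x + Q[, seq_len(j), drop = FALSE] %*% y
        break
      }
    }
  }
  x
}

# clamp elimination: express the full coefficient vector as P z + q where
# the ghost row/column along the clamped edge is reconstructed from the
# curve coefficients gamma via ghost = 6 gamma - 4 edge - inner
clamp_constraints <- function(n_bx, n_by, edge, gamma) {
  nu <- n_bx + 3L; nv <- n_by + 3L
  K <- nu * nv
  idx <- function(i, j) i + nu * (j - 1L)
  ghost <- switch(edge,
    vmin = idx(seq_len(nu), 1L),
    vmax = idx(seq_len(nu), nv),
    umin = idx(1L, seq_len(nv)),
    umax = idx(nu, seq_len(nv)))
  edge_ids <- switch(edge,
    vmin = idx(seq_len(nu), 2L),
    vmax = idx(seq_len(nu), nv - 1L),
    umin = idx(2L, seq_len(nv)),
    umax = idx(nu - 1L, seq_len(nv)))
  inner_ids <- switch(edge,
    vmin = idx(seq_len(nu), 3L),
    vmax = idx(seq_len(nu), nv - 2L),
    umin = idx(3L, seq_len(nv)),
    umax = idx(nu - 2L, seq_len(nv)))
  free <- setdiff(seq_len(K), ghost)
  col_of <- integer(K)
  col_of[free] <- seq_along(free)
  ii <- c(free, ghost, ghost)
  jj <- c(col_of[free], col_of[edge_ids], col_of[inner_ids])
  xx <- c(rep(1, length(free)), rep(-4, length(ghost)), rep(-1, length(ghost)))
  P <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(K, length(free)))
  q <- numeric(K)
  q[ghost] <- 6 * gamma
  list(P = P, q = q, free = free)
}

#' Fit a spline surface to parametrized 3D data
#'
#' Solves the three independent penalized least-squares problems (one per
#' physical coordinate) for the control coefficients: the objective is
#' `(1 - lambda) * sum ||data - X(u_i, v_i)||^2 +
#'  lambda * int (X_uu^2 + 2 X_uv^2 + X_vv^2) dOmega`,
#' with `lambda = 0` a pure least-squares fit and increasing `lambda`
#' stiffening the surface against curvature and twist.  An optional clamp
#' constrains one domain edge to coincide exactly with a given spline
#' curve by algebraic elimination of the ghost coefficients along that
#' edge.
#'
#' @param pmesh a `parametric_mesh` whose surface vertices supply the
#'   `(x, y, z)` data and whose `uv` supply the parametric coordinates;
#'   alternatively a list with fields `uv` (`n x 2`) and `xyz` (`n x 3`)
#'   and `domain`.
#' @param n_bx,n_by element counts.
#' @param lambda stiffness weight in `[0, 1)`.
#' @param clamp optional `list(edge = "vmin"|"vmax"|"umin"|"umax",
#'   curve = spline_curve)`; the curve must have the same element count
#'   and parametric segment length as the surface axis along the clamp.
#' @param solver `"direct"` (sparse Cholesky) or `"gmres"`.
#' @param tol solver tolerance for the iterative solver.
#' @return A [spline_surface()]; attribute `fit` records residuals and
#'   solver details.
#' @export
fit_surface <- function(pmesh, n_bx = 9L, n_by = 9L, lambda = 0.2,
                        clamp = NULL, solver = c("direct", "gmres"),
                        tol = 1e-10) {
  solver <- match.arg(solver)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda >= 1) {
    psf_stop("lambda must lie in [0, 1): lambda = 1 would drop the data term",
             "bad_config", list(lambda = lambda))
  }
  if (inherits(pmesh, "parametric_mesh")) {
    uv <- pmesh$uv
    xyz <- pmesh$surface$vertices
    domain <- pmesh$domain
  } else {
    uv <- pmesh$uv; xyz <- pmesh$xyz; domain <- pmesh$domain
  }
  stopifnot(nrow(uv) == nrow(xyz))

  if (lambda == 0) {
    lu <- locate_elements(uv[, 1], domain[1], domain[2], n_bx)
    lv <- locate_elements(uv[, 2], domain[3], domain[4], n_by)
    occ <- table(factor(lu$k, levels = seq_len(n_bx)),
                 factor(lv$k, levels = seq_len(n_by)))
    if (any(occ == 0L)) {
      psf_stop(paste("with lambda = 0 every spline element needs at least one",
                     "data point; empty elements found - increase lambda > 0",
                     "or reduce the element counts"),
               "singular_fit", list(empty = which(occ == 0L, arr.ind = TRUE)))
    }
  }

  Phi <- design_matrix(uv[, 1], uv[, 2], n_bx, n_by, domain)
  S <- stiffness_matrix(n_bx, n_by, domain)
  M <- (1 - lambda) * Matrix::crossprod(Phi) + lambda * S

  cl <- NULL
  if (!is.null(clamp)) {
    cl <- validate_clamp(clamp, n_bx, n_by, domain)
  }

  nu <- n_bx + 3L; nv <- n_by + 3L
  coeffs <- list()
  resid <- numeric(3)
  for (ci in 1:3) {
    rhs <- (1 - lambda) * as.vector(Matrix::crossprod(Phi, xyz[, ci]))
    if (is.null(cl)) {
      zeta <- solve_linear(M, rhs, solver, tol)
      resid[ci] <- sqrt(sum((as.vector(M %*% zeta) - rhs)^2)) /
        max(sqrt(sum(rhs^2)), 1e-300)
    } else {
      gamma <- cl$curve$coeffs[[ci]]
      cc <- clamp_constraints(n_bx, n_by, cl$edge, gamma)
      Mq <- as.vector(M %*% cc$q)
      Mr <- Matrix::t(cc$P) %*% (M %*% cc$P)
      rr <- as.vector(Matrix::t(cc$P) %*% (rhs - Mq))
      zf <- solve_linear(Mr, rr, solver, tol)
      zeta <- as.vector(cc$P %*% zf) + cc$q
      resid[ci] <- sqrt(sum((as.vector(Mr %*% zf) - rr)^2)) /
        max(sqrt(sum(rr^2)), 1e-300)
    }
    coeffs[[c("x", "y", "z")[ci]]] <- matrix(zeta, nu, nv)
  }
  out <- spline_surface(n_bx, n_by, domain, coeffs)
  pred <- evaluate_surface(out, uv[, 1], uv[, 2])
  attr(out, "fit") <- list(
    lambda = lambda, solver = solver, n_points = nrow(uv),
    rms_residual = sqrt(mean(rowSums((xyz - pred)^2))),
    normal_relres = resid, clamped = if (is.null(cl)) NULL else cl$edge)
  out
}

solve_linear <- function(M, rhs, solver, tol) {
  if (solver == "direct") {
    as.vector(Matrix::solve(M, rhs))
  } else {
    as.vector(gmres_solve(M, rhs, tol = tol))
  }
}

validate_clamp <- function(clamp, n_bx, n_by, domain) {
  if (!is.list(clamp) || is.null(clamp$edge) || is.null(clamp$curve)) {
    psf_stop("clamp must be list(edge=, curve=)", "bad_config")
  }
  edge <- match.arg(clamp$edge, c("vmin", "vmax", "umin", "umax"))
  curve <- clamp$curve
  stopifnot(inherits(curve, "spline_curve"))
  along_u <- edge %in% c("vmin", "vmax")
  n_axis <- if (along_u) n_bx else n_by
  axis_dom <- if (along_u) domain[1:2] else domain[3:4]
  if (curve$n_b != n_axis) {
    psf_stop(sprintf(
      "clamp curve has %d elements but the surface axis has %d: counts must match",
      curve$n_b, n_axis), "bad_config",
      list(curve_n = curve$n_b, axis_n = n_axis))
  }
  seg_curve <- diff(curve$domain) / curve$n_b
  seg_axis <- diff(axis_dom) / n_axis
  if (abs(seg_curve - seg_axis) > 1e-9 * seg_axis ||
      any(abs(curve$domain - axis_dom) > 1e-9 * seg_axis)) {
    psf_stop(sprintf(
      "clamp curve parametric segments (%g on [%g,%g]) must equal the surface axis segments (%g on [%g,%g])",
      seg_curve, curve$domain[1], curve$domain[2],
      seg_axis, axis_dom[1], axis_dom[2]), "bad_config",
      list(curve_domain = curve$domain, axis_domain = axis_dom))
  }
  list(edge = edge, curve = curve)
}

#' Fit a spline curve to parametrized 3D points
#'
#' 1D analog of [fit_surface()]: per-coordinate penalized least squares
#' with the curvature penalty `int (c'')^2`.
#'
#' @param s parameter values.
#' @param xyz `n x 3` data points.
#' @param n_b element count.
#' @param domain `c(lo, hi)`.
#' @param lambda stiffness in `[0, 1)`.
#' @return A [spline_curve()].
#' @export
fit_curve <- function(s, xyz, n_b, domain = range(s), lambda = 0) {
  if (lambda < 0 || lambda >= 1) {
    psf_stop("lambda must lie in [0, 1)", "bad_config", list(lambda = lambda))
  }
  xyz <- as.matrix(xyz)
  le <- locate_elements(s, domain[1], domain[2], n_b)
  if (lambda == 0) {
    occ <- tabulate(le$k, n_b)
    if (any(occ == 0L)) {
      psf_stop("with lambda = 0 every curve element needs a data point; increase lambda",
               "singular_fit")
    }
  }
  w <- bspline_weights(le$t, 0L)
  npt <- length(s)
  ii <- rep(seq_len(npt), 4L)
  jj <- as.vector(vapply(0:3, function(m) le$k + m, integer(npt)))
  Phi <- Matrix::sparseMatrix(i = ii, j = jj, x = as.vector(w),
                              dims = c(npt, n_b + 3L))
  G2 <- Matrix::Matrix(gram_1d(n_b, domain[1], domain[2], 2L), sparse = TRUE)
  M <- (1 - lambda) * Matrix::crossprod(Phi) + lambda * G2
  coeffs <- list()
  for (ci in 1:3) {
    rhs <- (1 - lambda) * as.vector(Matrix::crossprod(Phi, xyz[, ci]))
    coeffs[[c("x", "y", "z")[ci]]] <- as.vector(Matrix::solve(M, rhs))
  }
  spline_curve(n_b, domain, coeffs)
}

#' Restrict a spline surface to one of its domain edges
#'
#' Returns the codimension-1 spline curve traced by the surface along the
#' given edge (same element count and knot spacing as the corresponding
#' surface axis), useful for building clamp curves that join adjacent
#' patches exactly.
#'
#' @param surface a `spline_surface`.
#' @param edge `"vmin"`, `"vmax"`, `"umin"` or `"umax"`.
#' @return A [spline_curve()].
#' @export
edge_curve <- function(surface, edge = c("vmin", "vmax", "umin", "umax")) {
  edge <- match.arg(edge)
  cf <- surface$coeffs
  take <- function(C) switch(edge,
    vmin = (C[, 1] + 4 * C[, 2] + C[, 3]) / 6,
    vmax = (C[, ncol(C)] + 4 * C[, ncol(C) - 1] + C[, ncol(C) - 2]) / 6,
    umin = (C[1, ] + 4 * C[2, ] + C[3, ]) / 6,
    umax = (C[nrow(C), ] + 4 * C[nrow(C) - 1, ] + C[nrow(C) - 2, ]) / 6)
  along_u <- edge %in% c("vmin", "vmax")
  n_b <- if (along_u) surface$n_bx else surface$n_by
  dom <- if (along_u) surface$domain[1:2] else surface$domain[3:4]
  spline_curve(n_b, dom, lapply(cf, take))
}

#' Serialize a spline surface to JSON
#'
#' Schema: `format` ("parasurf-spline"), `version` (1), `n_bx`, `n_by`,
#' `domain`, `basis` ("uniform-cubic-partition-of-unity"), `order`
#' ("u-fastest"), `coeffs` with row-major coefficient grids `x`, `y`,
#' `z` (rows = u index).  Numbers are written at full precision so a
#' write/read/write round trip is byte-identical.
#'
#' @param surface a `spline_surface`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_spline_json <- function(surface, path) {
  obj <- list(
    format = "parasurf-spline", version = 1L,
    n_bx = surface$n_bx, n_by = surface$n_by,
    domain = surface$domain,
    basis = "uniform-cubic-partition-of-unity",
    order = "u-fastest",
    coeffs = lapply(surface$coeffs, function(m) unname(as.matrix(m))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a spline surface from JSON
#' @param path file written by [write_spline_json()].
#' @return a `spline_surface`.
#' @export
read_spline_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "parasurf-spline")) {
    psf_stop(sprintf("'%s' is not a parasurf spline file", path), "io")
  }
  spline_surface(obj$n_bx, obj$n_by, obj$domain,
                 lapply(obj$coeffs, as.matrix))
}

#' Tessellate a spline surface into a polygonal mesh
#'
#' Samples the surface on a regular parametric grid and builds a quad or
#' triangle mesh for visualization export (OBJ/PLY/VTK).
#'
#' @param surface a `spline_surface`.
#' @param n_u,n_v sample counts per axis (vertices).
#' @param kind `"quad"` or `"tri"`.
#' @return a `poly_surface`.
#' @export
tessellate_surface <- function(surface, n_u = 60L, n_v = 60L,
                               kind = c("quad", "tri")) {
  kind <- match.arg(kind)
  dom <- surface$domain
  us <- seq(dom[1], dom[2], length.out = n_u)
  vs <- seq(dom[3], dom[4], length.out = n_v)
  gg <- expand.grid(u = us, v = vs)
  verts <- evaluate_surface(surface, gg$u, gg$v)
  id <- function(i, j) i + n_u * (j - 1L)
  fq <- vector("list", (n_u - 1L) * (n_v - 1L))
  slot <- 0L
  for (j in seq_len(n_v - 1L)) for (i in seq_len(n_u - 1L)) {
    slot <- slot + 1L
    fq[[slot]] <- c(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L), id(i, j + 1L))
  }
  faces <- do.call(rbind, fq)
  if (kind == "tri") {
    faces <- rbind(faces[, c(1, 2, 3)], faces[, c(1, 3, 4)])
  }
  build_connectivity(verts, faces)
}
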