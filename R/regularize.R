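# Mesh regularization for polygon area and edge length.
#
# Each parametric element is compared with a scaled reference element
# through the Jacobian (deformation gradient) J of the isoparametric map
# reference -> element.  The energy integrates the squared entries of
# J - Adj(J)/|J| over the reference domain and sums over elements, with
# the adjugate taken as the cofactor matrix so that the subtracted term
# is J^{-T}.  In singular values, || J - J^{-T} ||_F^2 =
# sum_i (s_i - 1/s_i)^2: the measure vanishes when the element is a
# rigid translate or rotation of the reference, grows with scaling and
# shear, and is exactly invariant under rotation (rotation changes
# neither area nor edge length, which is what regularization must
# preserve).  Minimizing it with the boundary pinned equalizes polygon
# areas and edge lengths.  The minimization is a Levenberg-Marquardt / Gauss-Newton
# iteration with backtracking; steps are shrunk until no element
# determinant turns non-positive, which preserves the one-to-one map.

#' Reference element for mesh regularization
#'
#' Builds the shape-function and quadrature tables for the reference
#' element: the square `[-1, 1]^2` with bilinear shape functions and
#' tensor Gauss quadrature for quads, or an equilateral triangle of equal
#' domain area with linear shape functions and a 3-point rule.  `scale`
#' multiplies the reference element so that an element of area
#' `4 * scale^2` (the mean element area when `scale` comes from
#' [regularize()]) has Jacobian exactly the identity.
#'
#' @param kind `"quad"` or `"tri"`.
#' @param scale reference scale factor sigma.
#' @param quadrature_order Gauss order per axis for quads (1 or 2).
#' @return A `reference_map` list: `kind`, `scale`, `qp` (list of
#'   quadrature points, each with weight `w` and shape gradient matrix
#'   `dN`), `corner_dN` (shape gradients at corners, for exact flip
#'   checks), `domain_area`.
#' @export
reference_map <- function(kind = c("quad", "tri"), scale = 1,
                          quadrature_order = 2L) {
  kind <- match.arg(kind)
  stopifnot(scale > 0)
  if (kind == "quad") {
    quad_dN <- function(xi, eta) {
      sx <- c(-1, 1, 1, -1); sy <- c(-1, -1, 1, 1)
      cbind(sx * (1 + sy * eta), sy * (1 + sx * xi)) / 4
    }
    gp <- if (quadrature_order <= 1L) 0 else c(-1, 1) / sqrt(3)
    wp <- if (quadrature_order <= 1L) 2 else c(1, 1)
    qp <- list()
    for (i in seq_along(gp)) for (j in seq_along(gp)) {
      qp[[length(qp) + 1L]] <- list(w = wp[i] * wp[j],
                                    dN = quad_dN(gp[i], gp[j]),
                                    xi = gp[i], eta = gp[j])
    }
    corner_dN <- lapply(1:4, function(k) {
      quad_dN(c(-1, 1, 1, -1)[k], c(-1, -1, 1, 1)[k])
    })
    structure(list(kind = kind, scale = scale, qp = qp,
                   corner_dN = corner_dN, domain_area = 4,
                   shape_dN = quad_dN),
              class = "reference_map")
  } else {
    # equilateral triangle with domain area 4
    L <- sqrt(16 / sqrt(3))
    corners <- rbind(c(0, 0), c(L, 0), c(L / 2, L * sqrt(3) / 2))
    C <- solve(cbind(1, corners))          # linear shape coefficients
    dN <- t(C[2:3, , drop = FALSE])        # constant gradients, 3 x 2
    mids <- (corners[c(1, 2, 3), ] + corners[c(2, 3, 1), ]) / 2
    qp <- lapply(1:3, function(i) list(w = 4 / 3, dN = dN,
                                       xi = mids[i, 1], eta = mids[i, 2]))
    structure(list(kind = kind, scale = scale, qp = qp,
                   corner_dN = rep(list(dN), 3L), domain_area = 4,
                   shape_dN = function(xi, eta) dN, corners = corners),
              class = "reference_map")
  }
}

#' Element deformation gradient
#'
#' Jacobian of the isoparametric map from the scaled reference element to
#' an element of the parametric plane, evaluated at reference coordinates
#' `(xi, eta)`.  For a quad that is a pure translate of the scaled
#' reference square the result is the identity.
#'
#' @param corners `nc x 2` matrix of element corner `(u, v)` coordinates,
#'   counterclockwise.
#' @param xi,eta reference coordinates.
#' @param ref a [reference_map()].
#' @return 2 x 2 Jacobian matrix `[[U_xi, U_eta], [V_xi, V_eta]]`.
#' @export
element_jacobian <- function(corners, xi, eta, ref) {
  dN <- ref$shape_dN(xi, eta)
  (t(as.matrix(corners)) %*% dN) / ref$scale
}

# per-quadrature-point Jacobian entry vectors for all elements at once
all_jacobians <- function(U, V, dN, sigma) {
  list(a = as.vector(U %*% dN[, 1]) / sigma,
       b = as.vector(U %*% dN[, 2]) / sigma,
       c = as.vector(V %*% dN[, 1]) / sigma,
       d = as.vector(V %*% dN[, 2]) / sigma)
}

#' Regularization energy and gradient
#'
#' Evaluates the deformation energy
#' `sum_e int_Omega_e || J_e - Adj(J_e)/|J_e| ||_F^2` by quadrature
#' (adjugate = cofactor matrix, so the subtracted term is the inverse
#' transpose and the measure is exactly rotation invariant), together
#' with its analytic gradient with respect to the free vertex parametric
#' coordinates (zero rows for pinned vertices).  If any element is
#' degenerate (non-positive Jacobian determinant at a quadrature point)
#' the element is flagged through an infinite energy (penalty branch)
#' and the gradient is `NULL`.  Note that positivity at the 2 x 2 Gauss
#' points implies a positive element area, because the bilinear
#' determinant is integrated exactly by that rule.
#'
#' @param pmesh a `parametric_mesh`.
#' @param ref a [reference_map()] whose `kind` matches the mesh faces.
#' @return list: `energy`, `gradient` (`n x 2`), `min_det` (minimum
#'   quadrature-point determinant over elements), `element_energy`
#'   (per-element energies).
#' @export
regularization_objective <- function(pmesh, ref) {
  f <- pmesh$surface$faces
  nc <- ncol(f)
  stopifnot((nc == 4L) == (ref$kind == "quad"))
  min_det <- min(qp_determinants(pmesh$uv, f, ref))
  if (min_det <= 0) {
    return(list(energy = Inf, gradient = NULL, min_det = min_det,
                element_energy = NULL))
  }
  res <- regularized_energy(pmesh$uv, f, ref, delta = 0)
  res$gradient[pmesh$fixed, ] <- 0
  list(energy = res$energy, gradient = res$gradient, min_det = min_det,
       element_energy = res$element_energy)
}

#' Regularize a parametric mesh
#'
#' Minimizes the deformation energy of [regularization_objective()] over
#' the free vertices with the pinned boundary fixed, using a
#' Gauss-Newton/Levenberg-Marquardt iteration with backtracking step
#' control that keeps every element determinant positive.  Terminates
#' when the gradient 2-norm drops below `epsilon` or after `max_iters`
#' iterations.
#'
#' @param pmesh a one-to-one `parametric_mesh`.
#' @param epsilon gradient-norm termination threshold; default
#'   `1e-4 * ||g0||` where `g0` is the initial gradient.
#' @param max_iters iteration cap.
#' @param quadrature_order Gauss order for quads.
#' @param reference_scale reference scale sigma; default
#'   `sqrt(mean element area) / 2`, which makes the mean-sized element
#'   energy-free.
#' @return The regularized `parametric_mesh`; attribute `regularization`
#'   holds `energy_trace`, `gnorm`, `iterations`, `converged`, `status`.
#' @export
regularize <- function(pmesh, epsilon = NULL, max_iters = 200L,
                       quadrature_order = 2L, reference_scale = NULL) {
  if (is.null(reference_scale)) {
    areas <- abs(element_signed_areas(pmesh))
    reference_scale <- sqrt(mean(areas)) / 2
  }
  f <- pmesh$surface$faces
  nc <- ncol(f)
  kind <- if (nc == 4L) "quad" else "tri"
  # the map's global orientation depends on the anchor loop direction;
  # normalize to counterclockwise by reversing the winding if needed
  if (sum(sign(signed_areas_uv(pmesh$uv, f))) < 0) {
    f <- f[, rev(seq_len(nc)), drop = FALSE]
    pmesh$surface$faces <- f
  }
  ref <- reference_map(kind, reference_scale, quadrature_order)
  n <- nrow(pmesh$uv)
  free <- setdiff(seq_len(n), pmesh$fixed)
  nF <- length(free)
  if (nF == 0L) return(pmesh)
  fidx <- integer(n)
  fidx[free] <- seq_len(nF)

  # global dof ids per element corner (0 = pinned)
  gdof <- cbind(matrix(fidx[f], ncol = nc),
                matrix(ifelse(fidx[f] > 0L, fidx[f] + nF, 0L), ncol = nc))

  uv <- pmesh$uv
  untangle_info <- NULL
  dets <- qp_determinants(uv, f, ref)
  dscale <- mean(dets[dets > 0])
  if (min(dets) <= 0) {
    # Tutte projections of convoluted patches routinely contain strongly
    # non-convex or collapsed quads; untangle first
    res <- untangle_mesh(uv, f, ref, gdof, nF, free, pmesh)
    uv <- res$uv
    untangle_info <- res$info
    if (res$info$min_det < -1e-3 * dscale) {
      psf_stop("mesh untangling failed: degenerate elements remain",
               "degenerate_mesh", list(min_det = res$info$min_det))
    }
  }
  # delta = 0 gives the exact energy with its natural barrier at det = 0;
  # a residual numerically-collapsed element (|det| ~ 0 after untangling,
  # e.g. a bowtie quad the local optimizer cannot untwist) gets a tiny
  # determinant floor instead, which perturbs healthy-element energies by
  # O((delta/det)^2) ~ 1e-12 relative
  mind <- min(qp_determinants(uv, f, ref))
  delta_reg <- if (mind > 1e-6 * dscale) 0 else
    max(10 * abs(min(0, mind)), 1e-6 * dscale)
  energy_of <- function(uv_) regularized_energy(uv_, f, ref, delta_reg)
  flip_count <- function(uv_) {
    aa <- signed_areas_uv(uv_, f)
    s <- sign(sum(sign(aa)))
    if (s == 0) s <- 1
    sum(aa * s <= 0)
  }
  # numerically collapsed elements surviving untangling are driven out by
  # the floored energy; steps may never increase the flipped count
  cur_flips <- flip_count(uv)

  cur <- energy_of(uv)
  cur$gradient[pmesh$fixed, ] <- 0
  g0norm <- sqrt(sum(cur$gradient[free, ]^2))
  epsilon <- epsilon %||% max(1e-4 * g0norm, 1e-12)
  trace <- cur$energy
  mu <- 1e-6
  status <- "max_iters"
  it <- 0L
  while (it < max_iters) {
    it <- it + 1L
    gvec <- c(cur$gradient[free, 1], cur$gradient[free, 2])
    gnorm <- sqrt(sum(gvec^2))
    if (gnorm < epsilon) { status <- "converged"; it <- it - 1L; break }
    H <- gn_normal_matrix_reg(uv, f, ref, gdof, nF, delta_reg)
    accepted <- FALSE
    for (bump in 1:10) {
      delta <- tryCatch(
        as.vector(Matrix::solve(H + mu * Matrix::Diagonal(2L * nF), -gvec)),
        error = function(e) NULL)
      if (!is.null(delta)) {
        t_step <- 1
        for (halve in 1:25) {
          uv_try <- uv
          uv_try[free, 1] <- uv[free, 1] + t_step * delta[seq_len(nF)]
          uv_try[free, 2] <- uv[free, 2] + t_step * delta[nF + seq_len(nF)]
          cand <- energy_of(uv_try)
          if (is.finite(cand$energy) &&
              cand$energy <= cur$energy + 1e-4 * t_step * sum(gvec * delta) &&
              cand$energy < cur$energy) {
            fc <- flip_count(uv_try)
            if (fc <= cur_flips) {
              uv <- uv_try; cur <- cand; cur_flips <- fc; accepted <- TRUE
              break
            }
          }
          t_step <- t_step / 2
        }
      }
      if (accepted) {
        cur$gradient[pmesh$fixed, ] <- 0
        mu <- max(mu / 3, 1e-12)
        break
      }
      mu <- mu * 10
    }
    if (!accepted) { status <- "no_descent"; break }
    trace <- c(trace, cur$energy)
  }
  if (status == "no_descent") {
    psf_log("regularization stopped: no descent step found", level = "warn")
  }
  if (cur_flips > 0L) {
    psf_log(sprintf("regularized mesh still has %d flipped element(s)",
                    cur_flips), level = "warn")
  }
  out <- parametric_mesh(pmesh$surface, uv, pmesh$fixed, pmesh$domain)
  attr(out, "regularization") <- list(
    energy_trace = trace,
    gnorm = sqrt(sum(cur$gradient[free, ]^2)),
    iterations = it, epsilon = epsilon,
    converged = status == "converged", status = status,
    reference_scale = reference_scale, untangle = untangle_info,
    delta = delta_reg, flipped = cur_flips)
  out
}

# shoelace signed areas straight from a uv matrix
signed_areas_uv <- function(uv, f) {
  nc <- ncol(f)
  u <- matrix(uv[f, 1], ncol = nc)
  v <- matrix(uv[f, 2], ncol = nc)
  a <- 0
  for (s in seq_len(nc)) {
    s2 <- if (s == nc) 1L else s + 1L
    a <- a + u[, s] * v[, s2] - u[, s2] * v[, s]
  }
  a / 2
}

# corner determinants of all elements: ne x ncorners matrix
corner_determinants <- function(uv, f, ref) {
  nc <- ncol(f)
  U <- matrix(uv[f, 1], ncol = nc)
  V <- matrix(uv[f, 2], ncol = nc)
  dets <- matrix(0, nrow(f), length(ref$corner_dN))
  for (k in seq_along(ref$corner_dN)) {
    J <- all_jacobians(U, V, ref$corner_dN[[k]], ref$scale)
    dets[, k] <- J$a * J$d - J$b * J$c
  }
  dets
}

# quadrature-point determinants of all elements: ne x nqp matrix
qp_determinants <- function(uv, f, ref) {
  nc <- ncol(f)
  U <- matrix(uv[f, 1], ncol = nc)
  V <- matrix(uv[f, 2], ncol = nc)
  dets <- matrix(0, nrow(f), length(ref$qp))
  for (k in seq_along(ref$qp)) {
    J <- all_jacobians(U, V, ref$qp[[k]]$dN, ref$scale)
    dets[, k] <- J$a * J$d - J$b * J$c
  }
  dets
}

# Untangling phase: minimizes the same deformation energy but with the
# element determinant replaced by the smooth regularization
# h(det) = (det + sqrt(det^2 + delta^2)) / 2, evaluated at the quadrature
# points and the element corners.  h stays positive for inverted
# elements, so the energy is finite everywhere and its minimization
# drives negative corner determinants positive; delta is shrunk over a
# few rounds.  (Phase 1 only finds a feasible one-to-one start; the
# reported energy trace belongs to the exact phase-2 objective.)
untangle_mesh <- function(uv, f, ref, gdof, nF, free, pmesh,
                          max_iters = 40L) {
  dets0 <- qp_determinants(uv, f, ref)
  dscale <- mean(dets0[dets0 > 0])
  margin <- 1e-3 * dscale
  it_total <- 0L
  for (delta in dscale * 0.5 * 5^-(0:7)) {
    mind_now <- min(qp_determinants(uv, f, ref))
    # a strictly positive margin is ideal; a residual |det| ~ 0 element is
    # handled by the determinant floor of the main phase
    if (mind_now > margin || (delta < 0.01 * dscale && mind_now > -1e-5 * dscale)) break
    cur <- regularized_energy(uv, f, ref, delta)
    mu <- 1e-6
    for (it in seq_len(max_iters)) {
      it_total <- it_total + 1L
      gvec <- c(cur$gradient[free, 1], cur$gradient[free, 2])
      H <- gn_normal_matrix_reg(uv, f, ref, gdof, nF, delta)
      accepted <- FALSE
      for (bump in 1:8) {
        delta_x <- tryCatch(
          as.vector(Matrix::solve(H + mu * Matrix::Diagonal(2L * nF), -gvec)),
          error = function(e) NULL)
        if (!is.null(delta_x)) {
          t_step <- 1
          for (halve in 1:20) {
            uv_try <- uv
            uv_try[free, 1] <- uv[free, 1] + t_step * delta_x[seq_len(nF)]
            uv_try[free, 2] <- uv[free, 2] + t_step * delta_x[nF + seq_len(nF)]
            cand <- regularized_energy(uv_try, f, ref, delta)
            if (cand$energy < cur$energy) {
              uv <- uv_try; cur <- cand; accepted <- TRUE
              break
            }
            t_step <- t_step / 2
          }
        }
        if (accepted) { mu <- max(mu / 3, 1e-12); break }
        mu <- mu * 10
      }
      if (!accepted) break
      if (min(qp_determinants(uv, f, ref)) > margin) break
    }
  }
  mind <- min(qp_determinants(uv, f, ref))
  psf_log(sprintf("untangling: %d iterations, min quadrature det %.3g",
                  it_total, mind))
  list(uv = uv, info = list(iterations = it_total, min_det = mind))
}

# Gauss-Newton normal matrix for the delta-regularized residuals
# sqrt(w) * vec(J - Adj(J)/h(det)) at the quadrature points
gn_normal_matrix_reg <- function(uv, f, ref, gdof, nF, delta) {
  nc <- ncol(f)
  ndof <- 2L * nc
  ne <- nrow(f)
  sigma <- ref$scale
  U <- matrix(uv[f, 1], ncol = nc)
  V <- matrix(uv[f, 2], ncol = nc)
  Hkl <- vector("list", ndof * ndof)
  for (p in seq_len(ndof * ndof)) Hkl[[p]] <- numeric(ne)

  for (q in ref$qp) {
    J <- all_jacobians(U, V, q$dN, sigma)
    a <- J$a; b <- J$b; c <- J$c; d <- J$d
    det <- a * d - b * c
    sq <- sqrt(det^2 + delta^2)
    h <- (det + sq) / 2
    hp <- (1 + det / sq) / 2
    D <- vector("list", ndof)
    for (k in seq_len(nc)) {
      al <- q$dN[k, 1] / sigma; be <- q$dN[k, 2] / sigma
      k1 <- hp * (d * al - c * be) / h^2
      k2 <- hp * (a * be - b * al) / h^2
      D[[k]] <- list(d11 = al + d * k1, d12 = be - c * k1,
                     d21 = be / h - b * k1, d22 = -al / h + a * k1)
      D[[nc + k]] <- list(d11 = -be / h + d * k2, d12 = al / h - c * k2,
                          d21 = al - b * k2, d22 = be + a * k2)
    }
    for (k in seq_len(ndof)) for (l in k:ndof) {
      v <- q$w * (D[[k]]$d11 * D[[l]]$d11 + D[[k]]$d12 * D[[l]]$d12 +
                    D[[k]]$d21 * D[[l]]$d21 + D[[k]]$d22 * D[[l]]$d22)
      p <- (k - 1L) * ndof + l
      Hkl[[p]] <- Hkl[[p]] + v
    }
  }
  ii <- jj <- xx <- vector("list", ndof * (ndof + 1L) / 2L)
  slot <- 0L
  for (k in seq_len(ndof)) for (l in k:ndof) {
    p <- (k - 1L) * ndof + l
    rows <- gdof[, k]; cols <- gdof[, l]
    sel <- rows > 0L & cols > 0L
    if (!any(sel)) next
    slot <- slot + 1L
    if (k == l) {
      ii[[slot]] <- rows[sel]; jj[[slot]] <- cols[sel]; xx[[slot]] <- Hkl[[p]][sel]
    } else {
      ii[[slot]] <- c(rows[sel], cols[sel])
      jj[[slot]] <- c(cols[sel], rows[sel])
      xx[[slot]] <- c(Hkl[[p]][sel], Hkl[[p]][sel])
    }
  }
  Matrix::sparseMatrix(i = unlist(ii[seq_len(slot)]),
                       j = unlist(jj[seq_len(slot)]),
                       x = 2 * unlist(xx[seq_len(slot)]),
                       dims = c(2L * nF, 2L * nF))
}

# delta-regularized deformation energy and analytic gradient at the
# quadrature points (optionally also the element corners)
regularized_energy <- function(uv, f, ref, delta, include_corners = FALSE) {
  nc <- ncol(f)
  sigma <- ref$scale
  U <- matrix(uv[f, 1], ncol = nc)
  V <- matrix(uv[f, 2], ncol = nc)
  pts <- ref$qp
  if (include_corners) {
    pts <- c(pts, lapply(ref$corner_dN, function(dn) list(w = 1, dN = dn)))
  }
  gu <- matrix(0, nrow(f), nc)
  gv <- matrix(0, nrow(f), nc)
  elem_e <- numeric(nrow(f))
  for (q in pts) {
    J <- all_jacobians(U, V, q$dN, sigma)
    a <- J$a; b <- J$b; c <- J$c; d <- J$d
    det <- a * d - b * c
    sq <- sqrt(det^2 + delta^2)
    h <- (det + sq) / 2
    hp <- (1 + det / sq) / 2
    R11 <- a - d / h; R12 <- b + c / h; R21 <- c + b / h; R22 <- d - a / h
    elem_e <- elem_e + q$w * (R11^2 + R12^2 + R21^2 + R22^2)
    S <- R11 * d - R12 * c - R21 * b + R22 * a
    for (k in seq_len(nc)) {
      al <- q$dN[k, 1] / sigma; be <- q$dN[k, 2] / sigma
      gu[, k] <- gu[, k] + 2 * q$w *
        (R11 * al + R12 * be + (R21 * be - R22 * al) / h +
           S * hp * (d * al - c * be) / h^2)
      gv[, k] <- gv[, k] + 2 * q$w *
        (R21 * al + R22 * be + (-R11 * be + R12 * al) / h +
           S * hp * (a * be - b * al) / h^2)
    }
  }
  energy <- sum(elem_e)
  n <- nrow(uv)
  gradient <- matrix(0, n, 2L)
  idx <- as.vector(f)
  agg_u <- rowsum(as.vector(gu), idx)
  agg_v <- rowsum(as.vector(gv), idx)
  gradient[as.integer(rownames(agg_u)), 1] <- agg_u[, 1L]
  gradient[as.integer(rownames(agg_v)), 2] <- agg_v[, 1L]
  list(energy = energy, gradient = gradient, element_energy = elem_e)
}

# cheap internal clone with replaced uv (skips validation inside hot loop)
parametric_mesh_raw <- function(pmesh, uv) {
  out <- pmesh
  out$uv <- uv
  out
}


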