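# Closest point-to-surface distances.
#
# Inside one spline element the surface is a bicubic polynomial, so the
# derivative of the squared distance D^2 along a u = const or v = const
# coordinate line is a quintic polynomial.  Candidate minima are its real
# roots on 4 lines per direction per element (the element borders plus
# two interior lines) and the element corners; roots come from the
# eigenvalues of the quintic's companion matrix (balanced Hessenberg QR,
# as provided by LAPACK through eigen()).  The best candidate is refined
# by a damped Newton fixed-point iteration on the local quadratic model
# of D^2, stopping at convergence or when the step would cross an
# element edge (the neighbouring element's own candidates cover the
# rest).  The global distance is the minimum over elements, with
# elements pruned by the distance to their control-point bounding box
# (the surface piece lies in the convex hull of its 16 control points).

# power-basis matrix of the cubic B-spline weights: w_m(t) = sum_a
# M[a, m] t^(a-1)
bspline_power_matrix <- matrix(c(
  1, -3, 3, -1,
  4, 0, -6, 3,
  1, 3, 3, -3,
  0, 0, 0, 1) / 6, 4L, 4L)

# per-element bicubic monomial coefficients and control-point bounding
# boxes; cached on the surface object
surface_pp <- function(surface) {
  cache <- surface$cache
  if (!is.null(cache$pp)) return(cache$pp)
  nu <- surface$n_bx; nv <- surface$n_by
  M <- bspline_power_matrix
  pp <- lapply(1:3, function(ci) array(0, c(nu, nv, 4L, 4L)))
  bb <- array(0, c(nu, nv, 3L, 2L))
  for (k in seq_len(nu)) for (l in seq_len(nv)) {
    for (ci in 1:3) {
      zl <- surface$coeffs[[ci]][k:(k + 3L), l:(l + 3L)]
      pp[[ci]][k, l, , ] <- M %*% zl %*% t(M)
      bb[k, l, ci, ] <- range(zl)
    }
  }
  h <- c((surface$domain[2] - surface$domain[1]) / nu,
         (surface$domain[4] - surface$domain[3]) / nv)
  out <- list(pp = pp, bbox = bb, h = h,
              u0 = surface$domain[1], v0 = surface$domain[3],
              nu = nu, nv = nv)
  cache$pp <- out
  out
}

# ascending-coefficient polynomial product
poly_mult <- function(p, q) {
  out <- numeric(length(p) + length(q) - 1L)
  for (i in seq_along(p)) {
    out[i:(i + length(q) - 1L)] <- out[i:(i + length(q) - 1L)] + p[i] * q
  }
  out
}

poly_deriv <- function(p) {
  if (length(p) <= 1L) return(0)
  p[-1L] * seq_len(length(p) - 1L)
}

poly_eval <- function(p, x) {
  out <- numeric(length(x))
  for (i in rev(seq_along(p))) out <- out * x + p[i]
  out
}

#' Real roots of a polynomial via its companion matrix
#'
#' Ascending coefficients; leading coefficients that are numerically zero
#' are trimmed so degree-degenerate cases (e.g. a quintic collapsing to a
#' cubic) are handled without spurious roots.  The companion matrix is
#' balanced and reduced by the LAPACK Hessenberg QR eigenvalue solver
#' underlying [eigen()]; eigenvalues with `|Im| <= 1e-8 * (1 + |Re|)` are
#' accepted as real.
#'
#' @param coefs ascending polynomial coefficients `c0, c1, ...`.
#' @return numeric vector of real roots (possibly empty).
#' @export
polynomial_real_roots <- function(coefs) {
  scale <- max(abs(coefs))
  if (scale == 0) return(numeric(0))
  keep <- which(abs(coefs) > 1e-13 * scale)
  if (length(keep) == 0L) return(numeric(0))
  d <- max(keep) - 1L
  coefs <- coefs[seq_len(d + 1L)]
  if (d == 0L) return(numeric(0))
  if (d == 1L) return(-coefs[1L] / coefs[2L])
  Cm <- matrix(0, d, d)
  Cm[cbind(2:d, 1:(d - 1L))] <- 1
  Cm[, d] <- -coefs[1:d] / coefs[d + 1L]
  ev <- eigen(Cm, symmetric = FALSE, only.values = TRUE)$values
  re <- Re(ev)
  re[abs(Im(ev)) <= 1e-8 * (1 + abs(re))]
}

#' Closest-distance candidates on the coordinate lines of one element
#'
#' For the element `(k, l)` of the surface, returns the stationary points
#' of the squared distance to `point` along the 4 `v = const` and 4
#' `u = const` coordinate lines of that element (borders plus interior
#' lines at the given offsets), together with the 4 element corners.
#' Only candidates inside the closed element are returned.
#'
#' @param surface a `spline_surface`.
#' @param point length-3 physical point.
#' @param element integer pair `c(k, l)`, 1-based element indices.
#' @param offsets line positions in element-local coordinates.
#' @return matrix with columns `u`, `v` of candidate parametric points.
#' @export
coordinate_line_candidates <- function(surface, point, element,
                                       offsets = c(0, 1 / 3, 2 / 3, 1)) {
  ppc <- surface_pp(surface)
  k <- element[1L]; l <- element[2L]
  stopifnot(k >= 1L, k <= ppc$nu, l >= 1L, l <= ppc$nv)
  P <- lapply(1:3, function(ci) ppc$pp[[ci]][k, l, , ])
  cand_t <- matrix(numeric(0), 0L, 2L)
  tpow <- function(s) s^(0:3)
  for (s0 in offsets) {
    # v = const line: cubic in local t_u
    co <- vapply(1:3, function(ci) as.vector(P[[ci]] %*% tpow(s0)), numeric(4L))
    d2 <- numeric(7L)
    for (ci in 1:3) {
      pc <- co[, ci]; pc[1L] <- pc[1L] - point[ci]
      d2 <- d2 + poly_mult(pc, pc)
    }
    r <- polynomial_real_roots(poly_deriv(d2))
    r <- r[r >= -1e-9 & r <= 1 + 1e-9]
    if (length(r)) cand_t <- rbind(cand_t, cbind(pmin(pmax(r, 0), 1), s0))
    # u = const line: cubic in local t_v
    co <- vapply(1:3, function(ci) as.vector(tpow(s0) %*% P[[ci]]), numeric(4L))
    d2 <- numeric(7L)
    for (ci in 1:3) {
      pc <- co[, ci]; pc[1L] <- pc[1L] - point[ci]
      d2 <- d2 + poly_mult(pc, pc)
    }
    r <- polynomial_real_roots(poly_deriv(d2))
    r <- r[r >= -1e-9 & r <= 1 + 1e-9]
    if (length(r)) cand_t <- rbind(cand_t, cbind(s0, pmin(pmax(r, 0), 1)))
  }
  cand_t <- rbind(cand_t, cbind(c(0, 1, 0, 1), c(0, 0, 1, 1)))
  cbind(u = ppc$u0 + (k - 1L + cand_t[, 1L]) * ppc$h[1L],
        v = ppc$v0 + (l - 1L + cand_t[, 2L]) * ppc$h[2L])
}

# squared distance and its (u, v) gradient/Hessian at a parametric
# point; one fused gather of the 16 active coefficients per coordinate
d2_model <- function(surface, point, u, v) {
  dom <- surface$domain
  nu <- surface$n_bx; nv <- surface$n_by
  hu <- (dom[2] - dom[1]) / nu
  hv <- (dom[4] - dom[3]) / nv
  k <- min(max(floor((u - dom[1]) / hu) + 1, 1), nu)
  l <- min(max(floor((v - dom[3]) / hv) + 1, 1), nv)
  tu <- min(max((u - dom[1]) / hu - (k - 1), 0), 1)
  tv <- min(max((v - dom[3]) / hv - (l - 1), 0), 1)
  wu <- bspline_weights(tu, 0L)[1L, ]
  wu1 <- bspline_weights(tu, 1L)[1L, ] / hu
  wu2 <- bspline_weights(tu, 2L)[1L, ] / hu^2
  wv <- bspline_weights(tv, 0L)[1L, ]
  wv1 <- bspline_weights(tv, 1L)[1L, ] / hv
  wv2 <- bspline_weights(tv, 2L)[1L, ] / hv^2
  X <- Xu <- Xv <- Xuu <- Xuv <- Xvv <- numeric(3L)
  for (ci in 1:3) {
    Z <- surface$coeffs[[ci]][k:(k + 3L), l:(l + 3L)]
    Zv <- Z %*% wv; Zv1 <- Z %*% wv1; Zv2 <- Z %*% wv2
    X[ci] <- sum(wu * Zv)
    Xu[ci] <- sum(wu1 * Zv)
    Xv[ci] <- sum(wu * Zv1)
    Xuu[ci] <- sum(wu2 * Zv)
    Xuv[ci] <- sum(wu1 * Zv1)
    Xvv[ci] <- sum(wu * Zv2)
  }
  X <- X - point
  g <- 2 * c(sum(X * Xu), sum(X * Xv))
  off <- sum(Xu * Xv) + sum(X * Xuv)
  H <- 2 * matrix(c(sum(Xu * Xu) + sum(X * Xuu), off, off,
                    sum(Xv * Xv) + sum(X * Xvv)), 2L, 2L)
  list(f = sum(X * X), g = g, H = H)
}

#' Refine a closest-point candidate by a Newton fixed-point iteration
#'
#' Starting inside an element, repeatedly minimizes the local quadratic
#' model of the squared distance (Hessian and gradient evaluated at the
#' current point).  The iteration stops when the gradient norm falls
#' below `eps`, when the update segment would cross an element edge (the
#' neighbouring element's candidate set covers the remainder - the
#' global search over elements makes this safe), or after `max_iter`
#' steps; an indefinite Hessian falls back to a gradient step.  The
#' returned distance never exceeds the starting distance.
#'
#' @param surface a `spline_surface`.
#' @param point length-3 physical point.
#' @param start length-2 `(u, v)` start inside the domain.
#' @param eps gradient-norm threshold; default scales with the squared
#'   bounding-box diagonal of the surface control points.
#' @param max_iter iteration cap.
#' @param max_hops number of element transitions allowed before the
#'   edge-crossing stop triggers: a strictly descending step into the
#'   adjacent element may proceed this many times, which catches minima
#'   sitting right next to a knot line.
#' @return list: `u`, `v`, `distance`, `iterations`, `converged`.
#' @export
refine_minimum <- function(surface, point, start, eps = NULL, max_iter = 50L,
                           max_hops = 3L) {
  ppc <- surface_pp(surface)
  diag2 <- sum((apply(ppc$bbox[, , , 2L, drop = FALSE], 3L, max) -
                  apply(ppc$bbox[, , , 1L, drop = FALSE], 3L, min))^2)
  eps <- eps %||% (1e-10 * max(diag2, 1))
  dom <- surface$domain
  u <- unname(start[1L]); v <- unname(start[2L])
  cur <- d2_model(surface, point, u, v)
  elem <- function(u, v) {
    c(min(max(floor((u - ppc$u0) / ppc$h[1L]) + 1L, 1L), ppc$nu),
      min(max(floor((v - ppc$v0) / ppc$h[2L]) + 1L, 1L), ppc$nv))
  }
  e0 <- elem(u, v)
  converged <- FALSE
  hops <- 0L
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    if (sqrt(sum(cur$g^2)) < eps) { converged <- TRUE; break }
    detH <- cur$H[1L, 1L] * cur$H[2L, 2L] - cur$H[1L, 2L]^2
    if (cur$H[1L, 1L] > 0 && detH > 1e-14 * sum(cur$H^2)) {
      step <- c(cur$H[2L, 2L] * cur$g[1L] - cur$H[1L, 2L] * cur$g[2L],
                cur$H[1L, 1L] * cur$g[2L] - cur$H[1L, 2L] * cur$g[1L]) / -detH
    } else {
      # indefinite quadratic model: plain gradient descent step
      psf_log("indefinite Hessian in distance refinement; gradient step")
      step <- -cur$g / max(sqrt(sum(cur$g^2)), 1e-300) * min(ppc$h) * 0.1
    }
    crossed <- FALSE
    accepted <- FALSE
    for (halve in 1:30) {
      un <- u + step[1L]; vn <- v + step[2L]
      un <- min(max(un, dom[1]), dom[2])
      vn <- min(max(vn, dom[3]), dom[4])
      en <- elem(un, vn)
      if (any(en != e0)) {
        cand <- d2_model(surface, point, un, vn)
        if (hops < max_hops && cand$f < cur$f) {
          u <- un; v <- vn; cur <- cand; e0 <- en
          hops <- hops + 1L
          accepted <- TRUE
        } else crossed <- TRUE
        break
      }
      cand <- d2_model(surface, point, un, vn)
      if (cand$f < cur$f) {
        u <- un; v <- vn; cur <- cand; accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (crossed || !accepted) break
  }
  list(u = u, v = v, distance = sqrt(cur$f), iterations = it,
       converged = converged)
}

#' Closest distance from a point to the spline surface
#'
#' The global minimum over all elements of the refined coordinate-line
#' candidates; elements are visited in order of the distance from the
#' point to their control-point bounding box and skipped once that lower
#' bound exceeds the best distance found.
#'
#' @param surface a `spline_surface`.
#' @param point length-3 physical point.
#' @param offsets coordinate-line offsets per element direction.
#' @return list: `distance`, `u`, `v`.
#' @export
point_surface_distance <- function(surface, point,
                                   offsets = c(0, 1 / 3, 2 / 3, 1)) {
  ppc <- surface_pp(surface)
  point <- as.numeric(point)
  # lower bound: distance to control-point bounding box per element
  lb2 <- matrix(0, ppc$nu, ppc$nv)
  for (ci in 1:3) {
    lo <- ppc$bbox[, , ci, 1L]; hi <- ppc$bbox[, , ci, 2L]
    d <- pmax(lo - point[ci], 0, point[ci] - hi)
    lb2 <- lb2 + d * d
  }
  ord <- order(lb2)
  # pass 1: unrefined candidate minima per element; the running best
  # candidate tightens the bounding-box pruning before any refinement
  cand_best <- vector("list", length(ord))
  best_d2 <- Inf
  for (ei in ord) {
    if (lb2[ei] >= best_d2) break
    k <- ((ei - 1L) %% ppc$nu) + 1L
    l <- ((ei - 1L) %/% ppc$nu) + 1L
    cand <- coordinate_line_candidates(surface, point, c(k, l), offsets)
    xyz <- evaluate_surface(surface, cand[, 1L], cand[, 2L])
    d2 <- rowSums(sweep(xyz, 2L, point)^2)
    # keep the best few well-separated candidates of the element: a
    # single start can slide into a neighbouring basin and miss a
    # minimum sitting between coordinate lines
    ord_c <- order(d2)
    keep <- ord_c[1L]
    for (ci in ord_c[-1L]) {
      if (length(keep) >= 3L) break
      sep <- min(abs(cand[ci, 1L] - cand[keep, 1L]) / ppc$h[1L] +
                   abs(cand[ci, 2L] - cand[keep, 2L]) / ppc$h[2L])
      if (sep > 0.15) keep <- c(keep, ci)
    }
    cand_best[[ei]] <- cbind(d2[keep], cand[keep, , drop = FALSE])
    best_d2 <- min(best_d2, d2[ord_c[1L]])
  }
  # pass 2: Newton-refine in order of candidate quality; refinement only
  # decreases distances, so elements whose box bound exceeds the current
  # best cannot contain the minimum
  seen <- which(!vapply(cand_best, is.null, logical(1L)))
  seen <- seen[order(vapply(cand_best[seen], function(m) m[1L, 1L],
                            numeric(1L)))]
  best <- list(distance = Inf, u = NA_real_, v = NA_real_)
  for (ei in seen) {
    if (lb2[ei] >= best$distance^2) next
    for (r in seq_len(nrow(cand_best[[ei]]))) {
      ref <- refine_minimum(surface, point, cand_best[[ei]][r, 2:3])
      if (ref$distance < best$distance) {
        best <- list(distance = ref$distance, u = ref$u, v = ref$v)
      }
    }
  }
  best
}

#' Distance report between data points and a fitted surface
#'
#' Computes the closest distance (and its parametric argmin) from every
#' data point to the surface plus the summary statistics: minimal,
#' maximal and average distance and the population variance, all in the
#' physical units of the data.
#'
#' @param surface a `spline_surface`.
#' @param points `n x 3` matrix of data points.
#' @param offsets coordinate-line offsets passed to the candidate search.
#' @return A `distance_report`: list with `per_point` (data.frame
#'   `point_id`, `u`, `v`, `distance`) and `summary` (named vector
#'   `min`, `max`, `mean`, `variance`).
#' @export
distance_report <- function(surface, points,
                            offsets = c(0, 1 / 3, 2 / 3, 1)) {
  points <- as.matrix(points)
  if (nrow(points) == 0L) {
    psf_stop("distance report needs a non-empty point set", "empty_points")
  }
  res <- vapply(seq_len(nrow(points)), function(i) {
    b <- point_surface_distance(surface, points[i, ], offsets)
    c(b$u, b$v, b$distance)
  }, numeric(3L))
  per_point <- data.frame(point_id = seq_len(nrow(points)),
                          u = res[1L, ], v = res[2L, ], distance = res[3L, ])
  d <- per_point$distance
  summary <- c(min = min(d), max = max(d), mean = mean(d),
               variance = mean((d - mean(d))^2))
  structure(list(per_point = per_point, summary = summary),
            class = "distance_report")
}

#' @export
print.distance_report <- function(x, ...) {
  cat(sprintf("<distance_report> %d points; min %.4g, max %.4g, mean %.4g, variance %.4g\n",
              nrow(x$per_point), x$summary["min"], x$summary["max"],
              x$summary["mean"], x$summary["variance"]))
  invisible(x)
}

#' Write a distance report as CSV
#'
#' Per-point rows `point_id, u, v, distance` followed by footer rows
#' carrying the summary statistics.
#'
#' @param report a `distance_report`.
#' @param path output CSV path.
#' @export
write_distance_csv <- function(report, path) {
  df <- report$per_point
  footer <- data.frame(point_id = c("min", "max", "avg", "variance"),
                       u = "", v = "",
                       distance = unname(report$summary))
  df$point_id <- as.character(df$point_id)
  utils::write.csv(rbind(df, footer), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
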