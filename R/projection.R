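# One-to-one projection of a surface patch onto the parametric plane.
#
# Interior parametric coordinates minimize the sum over vertices of the
# squared distances to their graph neighbours with the boundary pinned:
# the stationarity condition makes every free vertex the arithmetic mean
# of its neighbours (a Tutte-type embedding with uniform weights), which
# yields a one-to-one map for a triangulated disk with convex pinned
# boundary and behaves equally well in practice for quad patches.

#' Construct a parametric mesh
#'
#' @param surface the source `poly_surface` (connectivity is shared).
#' @param uv numeric `n x 2` matrix of per-vertex parametric coordinates.
#' @param fixed integer indices of pinned (boundary) vertices.
#' @param domain `c(umin, umax, vmin, vmax)`.
#' @return object of class `parametric_mesh`.
#' @export
parametric_mesh <- function(surface, uv, fixed, domain) {
  uv <- as.matrix(uv)
  if (nrow(uv) != nrow(surface$vertices) || ncol(uv) != 2L) {
    psf_stop("uv must be one (u,v) pair per surface vertex", "bad_pmesh")
  }
  tol <- 1e-9 * max(domain[2] - domain[1], domain[4] - domain[3])
  inside <- uv[, 1] >= domain[1] - tol & uv[, 1] <= domain[2] + tol &
    uv[, 2] >= domain[3] - tol & uv[, 2] <= domain[4] + tol
  if (!all(inside)) psf_stop("uv coordinates outside the closed domain",
                             "bad_pmesh", list(outside = which(!inside)))
  on_border <- abs(uv[fixed, 1] - domain[1]) <= tol |
    abs(uv[fixed, 1] - domain[2]) <= tol |
    abs(uv[fixed, 2] - domain[3]) <= tol |
    abs(uv[fixed, 2] - domain[4]) <= tol
  if (!all(on_border)) psf_stop("pinned vertices must lie on the domain border",
                                "bad_pmesh")
  structure(list(surface = surface, uv = uv, fixed = sort(as.integer(fixed)),
                 domain = as.numeric(domain)),
            class = "parametric_mesh")
}

#' @export
print.parametric_mesh <- function(x, ...) {
  cat(sprintf("<parametric_mesh> %d vertices (%d pinned), domain [%g,%g]x[%g,%g]\n",
              nrow(x$uv), length(x$fixed), x$domain[1], x$domain[2],
              x$domain[3], x$domain[4]))
  invisible(x)
}

# conjugate gradient for SPD sparse systems; relative residual tolerance
cg_solve <- function(A, b, tol = 1e-10, max_iter = NULL, x0 = NULL) {
  n <- length(b)
  max_iter <- max_iter %||% (10L * n)
  x <- x0 %||% numeric(n)
  r <- b - as.vector(A %*% x)
  p <- r
  rs <- sum(r * r)
  bnorm <- sqrt(sum(b * b))
  if (bnorm == 0) return(list(x = numeric(n), iters = 0L, relres = 0))
  for (it in seq_len(max_iter)) {
    Ap <- as.vector(A %*% p)
    alpha <- rs / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r * r)
    if (sqrt(rs_new) / bnorm <= tol) {
      return(list(x = x, iters = it, relres = sqrt(rs_new) / bnorm))
    }
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  list(x = x, iters = max_iter, relres = sqrt(rs) / bnorm)
}

#' Project a patch onto the parametric plane
#'
#' Solves the reduced sparse linear systems for the interior `u` and `v`
#' coordinates (diagonal = vertex degree, off-diagonal -1 per neighbour;
#' symmetric and diagonally dominant, hence positive definite) with an
#' unpreconditioned conjugate gradient.
#'
#' @param surface the patch `poly_surface` (all its vertices participate).
#' @param pinned data.frame with columns `vertex`, `u`, `v`: the fixed
#'   boundary assignment from [pin_boundary()] (indices into `surface`).
#' @param domain `c(umin, umax, vmin, vmax)`.
#' @param tol conjugate-gradient relative residual tolerance.
#' @param max_iter iteration cap (default `10 * n`).
#' @return A `parametric_mesh` with attributes `cg` (iterations/residual
#'   per coordinate).
#' @export
solve_projection <- function(surface, pinned, domain = c(0, 1, 0, 1),
                             tol = 1e-10, max_iter = NULL) {
  n <- nrow(surface$vertices)
  fixed <- as.integer(pinned$vertex)
  free <- setdiff(seq_len(n), fixed)
  deg <- lengths(surface$adjacency)
  if (any(deg[free] == 0L)) {
    psf_stop(sprintf("vertex %d is disconnected from the patch",
                     free[which(deg[free] == 0L)[1L]]),
             "disconnected_vertex")
  }
  uv <- matrix(0, n, 2L)
  uv[fixed, 1] <- pinned$u
  uv[fixed, 2] <- pinned$v
  if (length(free)) {
    idx <- integer(n)
    idx[free] <- seq_along(free)
    # assemble reduced system A_hat x_hat = c_hat
    ii <- rep(seq_along(free), times = deg[free])
    nbr <- unlist(surface$adjacency[free])
    is_free_nbr <- idx[nbr] > 0L
    trip_i <- c(seq_along(free), ii[is_free_nbr])
    trip_j <- c(seq_along(free), idx[nbr[is_free_nbr]])
    trip_x <- c(deg[free], rep(-1, sum(is_free_nbr)))
    A <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                              dims = c(length(free), length(free)))
    # rhs: sum of pinned neighbour coordinates
    pin_i <- ii[!is_free_nbr]
    pin_v <- nbr[!is_free_nbr]
    cg_info <- list()
    for (coord in 1:2) {
      b <- numeric(length(free))
      if (length(pin_i)) {
        agg <- rowsum(uv[pin_v, coord], pin_i)
        b[as.integer(rownames(agg))] <- agg[, 1L]
      }
      sol <- cg_solve(A, b, tol = tol, max_iter = max_iter)
      if (sol$relres > tol) {
        psf_stop(sprintf(
          "conjugate gradient did not converge (relative residual %.3e after %d iterations)",
          sol$relres, sol$iters), "no_convergence",
          list(relres = sol$relres, iters = sol$iters))
      }
      uv[free, coord] <- sol$x
      cg_info[[coord]] <- sol[c("iters", "relres")]
    }
  } else cg_info <- list()
  pm <- parametric_mesh(surface, uv, fixed, domain)
  attr(pm, "cg") <- cg_info
  pm
}

#' Signed parametric areas of the mesh elements
#'
#' Shoelace area of each face in the `(u, v)` plane.  A one-to-one map has
#' all areas of one sign.
#'
#' @param pmesh a `parametric_mesh`.
#' @return numeric vector, one signed area per face.
#' @export
element_signed_areas <- function(pmesh) {
  f <- pmesh$surface$faces
  nc <- ncol(f)
  u <- matrix(pmesh$uv[f, 1], ncol = nc)
  v <- matrix(pmesh$uv[f, 2], ncol = nc)
  a <- 0
  for (s in seq_len(nc)) {
    s2 <- if (s == nc) 1L else s + 1L
    a <- a + u[, s] * v[, s2] - u[, s2] * v[, s]
  }
  a / 2
}

#' Count flipped parametric elements
#'
#' Elements whose signed area disagrees with the majority orientation (or
#' is zero) are counted as flipped.
#'
#' @param pmesh a `parametric_mesh`.
#' @return integer count.
#' @export
flipped_elements <- function(pmesh) {
  a <- element_signed_areas(pmesh)
  sgn <- sign(sum(sign(a)))
  if (sgn == 0) sgn <- 1
  sum(a * sgn <= 0)
}

#' Neighbour-mean stationarity residual
#'
#' Maximum over free vertices of `|M_n * u_n - sum of neighbour u|`
#' (same for v): the first-order optimality condition of the projection
#' objective.
#'
#' @param pmesh a `parametric_mesh`.
#' @return numeric length-2, max residual for u and v.
#' @export
stationarity_residual <- function(pmesh) {
  n <- nrow(pmesh$uv)
  free <- setdiff(seq_len(n), pmesh$fixed)
  if (!length(free)) return(c(u = 0, v = 0))
  adj <- pmesh$surface$adjacency[free]
  deg <- lengths(adj)
  idx <- rep(seq_along(free), times = deg)
  nbr <- unlist(adj)
  res <- vapply(1:2, function(coord) {
    s <- rowsum(pmesh$uv[nbr, coord], idx, reorder = TRUE)
    max(abs(deg * pmesh$uv[free, coord] - as.vector(s)))
  }, numeric(1L))
  c(u = res[1], v = res[2])
}
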