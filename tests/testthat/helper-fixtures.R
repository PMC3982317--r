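# Shared fixtures and independent oracles, all built in code.

# regular (optionally jittered) quad grid in the z = 0 plane:
# (nx+1) x (ny+1) vertices on [0, nx] x [0, ny]
grid_quad_mesh <- function(nx, ny, jitter = 0, seed = 1) {
  gg <- as.matrix(expand.grid(u = 0:nx, v = 0:ny))
  if (jitter > 0) {
    gg <- gg + with_seed_local(seed, matrix(stats::runif(length(gg), -jitter, jitter),
                                            ncol = 2L))
  }
  id <- function(i, j) i + 1L + (nx + 1L) * j
  faces <- NULL
  for (j in 0:(ny - 1L)) for (i in 0:(nx - 1L)) {
    faces <- rbind(faces, c(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L),
                            id(i, j + 1L)))
  }
  border <- which(gg[, 1] %in% c(0, nx) | gg[, 2] %in% c(0, ny))
  list(surface = build_connectivity(cbind(gg, 0), faces),
       uv = gg, border = border, nx = nx, ny = ny)
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# independent Cox-de Boor recursion on the uniform clamped-free knot
# vector matching the package's coefficient indexing: coefficient j has
# knots tau[j .. j+4] with tau[i] = lo + (i - 4) * h
deboor_basis <- function(u, j, n, lo, hi, order = 4L) {
  h <- (hi - lo) / n
  tau <- lo + ((1:(n + 7L)) - 4L) * h
  N <- function(i, k, x) {
    if (k == 1L) return(as.numeric(x >= tau[i] & x < tau[i + 1L]))
    a <- (x - tau[i]) / (tau[i + k - 1L] - tau[i])
    b <- (tau[i + k] - x) / (tau[i + k] - tau[i + 1L])
    a * N(i, k - 1L, x) + b * N(i + 1L, k - 1L, x)
  }
  N(j, order, u)
}

# unweighted BFS distances from a source vertex over an adjacency list
bfs_distances <- function(adjacency, from) {
  n <- length(adjacency)
  dist <- rep(NA_integer_, n)
  dist[from] <- 0L
  queue <- from
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    for (w in adjacency[[v]]) {
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
  }
  dist
}

# dense-sampling + local-refinement closest-distance oracle
dense_distance_oracle <- function(surface, point, n_grid = 400L) {
  dom <- surface$domain
  us <- seq(dom[1], dom[2], length.out = n_grid)
  vs <- seq(dom[3], dom[4], length.out = n_grid)
  gg <- expand.grid(u = us, v = vs)
  xyz <- evaluate_surface(surface, gg$u, gg$v)
  d2 <- (xyz[, 1] - point[1])^2 + (xyz[, 2] - point[2])^2 +
    (xyz[, 3] - point[3])^2
  i0 <- which.min(d2)
  f <- function(p) {
    x <- evaluate_surface(surface, p[1], p[2])[1L, ]
    sum((x - point)^2)
  }
  op <- stats::optim(c(gg$u[i0], gg$v[i0]), f, method = "L-BFGS-B",
                     lower = dom[c(1, 3)], upper = dom[c(2, 4)],
                     control = list(factr = 1e3))
  sqrt(op$value)
}

# a smooth random spline surface with a dominant planar trend, for
# distance tests
random_spline_surface <- function(n_bx = 5L, n_by = 5L, seed = 1,
                                  bump = 0.25) {
  with_seed_local(seed, {
    base_u <- seq(0, 3, length.out = n_bx + 3L)
    base_v <- seq(0, 3, length.out = n_by + 3L)
    cf <- list(
      x = outer(base_u, rep(1, n_by + 3L)) +
        matrix(stats::rnorm((n_bx + 3L) * (n_by + 3L), sd = bump / 2), n_bx + 3L),
      y = outer(rep(1, n_bx + 3L), base_v) +
        matrix(stats::rnorm((n_bx + 3L) * (n_by + 3L), sd = bump / 2), n_bx + 3L),
      z = matrix(stats::rnorm((n_bx + 3L) * (n_by + 3L), sd = bump), n_bx + 3L))
    spline_surface(n_bx, n_by, c(0, 1, 0, 1), cf)
  })
}

# small voxel ball volume with a smooth intensity ramp near the surface,
# so isosurface interpolation recovers the sphere accurately
ramp_ball_volume <- function(radius, n, spacing = 1, centre = NULL) {
  if (is.null(centre)) centre <- rep(n * spacing / 2, 3L)
  g <- (seq_len(n) - 0.5) * spacing
  X <- array(rep(g, times = n * n), c(n, n, n))
  Y <- array(rep(rep(g, each = n), times = n), c(n, n, n))
  Z <- array(rep(g, each = n * n), c(n, n, n))
  r <- sqrt((X - centre[1])^2 + (Y - centre[2])^2 + (Z - centre[3])^2)
  arr <- pmin(pmax(127.5 + (radius - r) * 60, 0), 255)
  voxel_volume(arr, spacing)
}

# full patch pipeline on a phantom: extract quads, trace the equator
# patch, project
project_phantom <- function(phantom, domain = c(0, 100, 0, 100)) {
  s <- extract_boundary_quads(phantom$volume, 100)
  anch <- pick_nearest_vertices(s, phantom_equator_points(phantom))
  spec <- trace_patch(s, anch)
  pin <- pin_boundary(spec, domain)
  pt <- extract_patch(s, spec)
  pin$vertex <- match(pin$vertex, pt$index_map)
  pm <- solve_projection(pt$surface, pin, domain)
  list(pmesh = pm, patch = pt, spec = spec, surface = s)
}

area_cv <- function(pmesh) {
  a <- abs(element_signed_areas(pmesh))
  stats::sd(a) / mean(a)
}
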