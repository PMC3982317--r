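# Voxelized analytic phantoms.
#
# The phantoms stand in for segmented tomographic data: binary volumes
# (intensity 255 inside the solid, 0 outside, so the standard threshold of
# 100 separates them) together with the exact analytic implicit function
# of the solid for ground-truth checks.  The bumpy hemisphere and the
# papillary phantom emulate the smooth-but-convoluted open surfaces the
# fitting method targets (an endocardial wall with ridges and a
# finger-like papillary protrusion).

new_phantom <- function(volume, sdf, description) {
  structure(list(volume = volume, sdf = sdf, description = description),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s; dims %s, spacing %g\n",
              x$description$type,
              paste(x$volume$dims, collapse = "x"), x$volume$spacing[1]))
  invisible(x)
}

# voxel-centre coordinate grids for a dims/spacing/origin triple
centre_grid <- function(dims, spacing, origin) {
  gx <- origin[1] + (seq_len(dims[1]) - 0.5) * spacing[1]
  gy <- origin[2] + (seq_len(dims[2]) - 0.5) * spacing[2]
  gz <- origin[3] + (seq_len(dims[3]) - 0.5) * spacing[3]
  list(x = gx, y = gy, z = gz)
}

binary_volume_from_implicit <- function(f, dims, spacing, origin, blur_sigma = 0) {
  g <- centre_grid(dims, rep(spacing, 3L), origin)
  X <- array(rep(g$x, times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(g$y, each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(g$z, each = dims[1] * dims[2]), dims)
  inside <- f(cbind(as.vector(X), as.vector(Y), as.vector(Z))) <= 0
  arr <- array(ifelse(inside, 255, 0), dims)
  if (blur_sigma > 0) arr <- gaussian_blur3(arr, blur_sigma / spacing)
  voxel_volume(arr, spacing, origin)
}

# separable 3D Gaussian blur, sigma in voxel units; emulates
# partial-volume softness at the solid boundary
gaussian_blur3 <- function(arr, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv_axis <- function(a, axis) {
    d <- dim(a)
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- matrix(ap, nrow = dp[1])
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (o in -r:r) {
      src <- pmin(pmax(seq_len(n) + o, 1L), n)  # clamped border
      out <- out + k[o + r + 1L] * m[src, , drop = FALSE]
    }
    aperm(array(out, dp), order(perm))
  }
  for (ax in 1:3) arr <- conv_axis(arr, ax)
  arr
}

#' Solid ball phantom
#'
#' Binary voxelization of a solid sphere, centred in its grid, with the
#' exact signed distance function.
#'
#' @param radius sphere radius (physical units).
#' @param spacing voxel edge length.
#' @param margin empty border around the sphere, physical units; must be
#'   at least 2 voxels.
#' @param blur_sigma optional Gaussian blur (physical units) applied to
#'   the binary volume to mimic partial-volume softness.
#' @return A `phantom`: `volume` ([voxel_volume()]), `sdf` (vectorized
#'   over `n x 3` point matrices), `description`.
#' @export
make_ball <- function(radius = 20, spacing = 1, margin = 4, blur_sigma = 0) {
  if (radius <= 2 * spacing) psf_stop("radius must exceed 2 * spacing", "bad_phantom")
  if (margin < 2 * spacing) {
    psf_stop("margin must be at least 2 voxels for a clean boundary",
             "bad_phantom", list(margin = margin, spacing = spacing))
  }
  half <- radius + margin
  n <- ceiling(2 * half / spacing)
  centre <- rep(n * spacing / 2, 3L)
  sdf <- function(p) sqrt(row_norms2(sweep(matrix(p, ncol = 3L), 2L, centre))) - radius
  vol <- binary_volume_from_implicit(sdf, rep(n, 3L), spacing, c(0, 0, 0),
                                     blur_sigma)
  new_phantom(vol, sdf, list(type = "ball", radius = radius, spacing = spacing,
                             margin = margin, centre = centre,
                             blur_sigma = blur_sigma))
}

# polar angle from +z and azimuth of points relative to a centre
sph_angles <- function(p, centre) {
  q <- sweep(p, 2L, centre)
  rho <- sqrt(row_norms2(q))
  theta <- acos(pmin(pmax(ifelse(rho > 0, q[, 3] / rho, 1), -1), 1))
  phi <- atan2(q[, 2], q[, 1])
  list(rho = rho, theta = theta, phi = phi)
}

#' Bumpy hemisphere phantom
#'
#' An open hemispherical shell (dome pointing +z, flat face on the equator
#' plane) whose radius is modulated by a smooth angular perturbation
#' `r(theta, phi) = R + A * sin(k * theta + p1) * sin(k * phi + p2)`.
#' With `seed = NULL` the phases `p1, p2` are zero; a seed draws them
#' reproducibly, so the phantom is deterministic given
#' `(parameters, seed)`.
#'
#' @param radius mean dome radius R.
#' @param bump_amplitude perturbation amplitude A; must be `< 0.3 * R`.
#' @param bump_frequency integer angular frequency k.
#' @param spacing voxel edge length.
#' @param seed optional integer seed for the perturbation phases.
#' @param margin empty border, physical units.
#' @param blur_sigma optional Gaussian blur (physical units).
#' @return A `phantom`; the implicit function is negative inside the
#'   solid dome.
#' @export
make_bumpy_hemisphere <- function(radius = 20, bump_amplitude = 2,
                                  bump_frequency = 3, spacing = 1,
                                  seed = NULL, margin = 4, blur_sigma = 0) {
  if (bump_amplitude >= 0.3 * radius) {
    psf_stop("bump_amplitude must be < 0.3 * radius", "bad_phantom",
             list(amplitude = bump_amplitude, radius = radius))
  }
  phases <- c(0, 0)
  if (!is.null(seed)) phases <- with_seed(seed, stats::runif(2, 0, 2 * pi))
  rmax <- radius + bump_amplitude
  half <- rmax + margin
  nxy <- ceiling(2 * half / spacing)
  nz <- ceiling((rmax + 2 * margin) / spacing)
  centre <- c(nxy * spacing / 2, nxy * spacing / 2, margin)
  rfun <- function(theta, phi) {
    radius + bump_amplitude * sin(bump_frequency * theta + phases[1]) *
      sin(bump_frequency * phi + phases[2])
  }
  sdf <- function(p) {
    p <- matrix(p, ncol = 3L)
    a <- sph_angles(p, centre)
    pmax(a$rho - rfun(a$theta, a$phi), centre[3] - p[, 3])
  }
  vol <- binary_volume_from_implicit(sdf, c(nxy, nxy, nz), spacing, c(0, 0, 0),
                                     blur_sigma)
  new_phantom(vol, sdf, list(
    type = "bumpy_hemisphere", radius = radius,
    bump_amplitude = bump_amplitude, bump_frequency = bump_frequency,
    spacing = spacing, seed = seed, phases = phases, margin = margin,
    centre = centre, radial_fun = rfun, blur_sigma = blur_sigma))
}

#' Papillary phantom: hemisphere with a finger-like protrusion
#'
#' A solid hemisphere (dome pointing +z) unioned with a capsule whose axis
#' points radially outwards at 30 degrees from the pole; the capsule tip
#' reaches `radius + protrusion_length` from the dome centre.  The
#' boundary patch above the equator is a smooth dome carrying a
#' papillary-muscle-like protrusion, the hardest feature class for
#' low-degree-of-freedom surface fits.  `protrusion_length = 0` retracts
#' the capsule inside the ball, recovering the plain hemisphere.
#'
#' @param radius dome radius R.
#' @param protrusion_length length of the finger beyond the dome surface.
#' @param protrusion_radius capsule radius; must be `< radius / 2`.
#' @param spacing voxel edge length.
#' @param margin empty border, physical units.
#' @param blur_sigma optional Gaussian blur (physical units).
#' @return A `phantom`; `description$tip` holds the analytic tip point.
#' @export
make_papillary_phantom <- function(radius = 20, protrusion_length = 10,
                                   protrusion_radius = 5, spacing = 1,
                                   margin = 4, blur_sigma = 0) {
  if (protrusion_radius >= radius / 2) {
    psf_stop("protrusion_radius must be < radius / 2", "bad_phantom")
  }
  if (protrusion_length < 0 || protrusion_length > 2 * radius) {
    psf_stop("protrusion_length must be in [0, 2 * radius]", "bad_phantom")
  }
  dirv <- c(sin(pi / 6) * cos(pi / 4), sin(pi / 6) * sin(pi / 4), cos(pi / 6))
  reach <- radius + protrusion_length
  half <- reach + margin
  nxy <- ceiling(2 * half / spacing)
  nz <- ceiling((reach + 2 * margin) / spacing)
  centre <- c(nxy * spacing / 2, nxy * spacing / 2, margin)
  seg_a <- centre + 0.5 * radius * dirv
  seg_b <- centre + (radius - protrusion_radius + protrusion_length) * dirv
  tip <- centre + reach * dirv
  sdf <- function(p) {
    p <- matrix(p, ncol = 3L)
    d_ball <- sqrt(row_norms2(sweep(p, 2L, centre))) - radius
    ab <- seg_b - seg_a
    pa <- sweep(p, 2L, seg_a)
    t <- pmin(pmax(as.vector(pa %*% ab) / sum(ab * ab), 0), 1)
    diff <- pa - cbind(t * ab[1], t * ab[2], t * ab[3])
    d_cap <- sqrt(row_norms2(diff)) - protrusion_radius
    pmax(pmin(d_ball, d_cap), centre[3] - p[, 3])
  }
  vol <- binary_volume_from_implicit(sdf, c(nxy, nxy, nz), spacing, c(0, 0, 0),
                                     blur_sigma)
  new_phantom(vol, sdf, list(
    type = "papillary", radius = radius,
    protrusion_length = protrusion_length,
    protrusion_radius = protrusion_radius, spacing = spacing,
    margin = margin, centre = centre, direction = dirv, tip = tip,
    blur_sigma = blur_sigma))
}

#' Equatorial anchor points of a hemispherical phantom
#'
#' Analytic positions of 4 equally spaced points on the phantom's equator
#' rim, for use with [pick_nearest_vertices()] and [trace_patch()].
#'
#' @param phantom a hemispherical `phantom`.
#' @return a `4 x 3` matrix of physical points.
#' @export
phantom_equator_points <- function(phantom) {
  d <- phantom$description
  if (!d$type %in% c("bumpy_hemisphere", "papillary")) {
    psf_stop("equator anchors are defined for hemispherical phantoms only",
             "bad_phantom")
  }
  az <- c(0, 0.5, 1, 1.5) * pi
  r <- if (d$type == "papillary") d$radius
       else d$radial_fun(pi / 2, az)
  cbind(d$centre[1] + r * cos(az), d$centre[2] + r * sin(az),
        rep(d$centre[3], 4L))
}
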