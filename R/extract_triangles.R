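# Triangulated isosurface extraction on the voxel-centre grid.
#
# The extractor walks the cubes of the voxel-centre lattice and
# triangulates the iso-level crossing inside each cube.  Each cube is
# decomposed into 6 tetrahedra sharing the main diagonal (the Freudenthal
# decomposition); because the decomposition is translation-invariant the
# induced face diagonals agree between neighbouring cubes, so the output
# is a consistent oriented surface with no ambiguous configurations.
# Iso-vertices are obtained by linear interpolation along lattice edges
# and deduplicated by lattice edge, which makes the surface watertight
# wherever the labelled region does not touch the volume border.

# offsets of the 8 cube corners (0-based), bit order x, y, z
cube_corners <- rbind(
  c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
  c(0, 0, 1), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1)
)

# parity of a permutation of 1..4 (+1 even, -1 odd)
perm_sign <- function(p) {
  s <- 1L
  for (i in 1:3) for (j in (i + 1):4) if (p[i] > p[j]) s <- -s
  s
}

# 6 positively oriented Freudenthal tetrahedra, as rows of cube-corner
# indices (1..8 into cube_corners)
freudenthal_tets <- local({
  corner_index <- function(v) 1L + v[1] + 2L * v[2] + 4L * v[3]
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  tets <- matrix(0L, 6L, 4L)
  for (r in 1:6) {
    ax <- perms[r, ]
    e <- diag(3)
    p <- rbind(c(0, 0, 0), e[ax[1], ], e[ax[1], ] + e[ax[2], ], c(1, 1, 1))
    if (det(rbind(p[2, ] - p[1, ], p[3, ] - p[1, ], p[4, ] - p[1, ])) < 0) {
      p <- p[c(1, 2, 4, 3), ]
    }
    tets[r, ] <- apply(p, 1L, corner_index)
  }
  tets
})

# For each inside-mask code (1..14) of a positively oriented tetrahedron,
# the oriented triangles as pairs of local corner positions (edges).
# Derived from the canonical cases by even-permutation relabelling so that
# triangle normals point from the inside (>= threshold) region outwards.
tet_case_table <- local({
  canon <- function(order) {
    # order = (i, j, k, l): an even permutation of 1:4
    if (perm_sign(order) < 0) order[c(1, 2, 4, 3)] else order
  }
  others <- function(i) setdiff(1:4, i)
  table <- vector("list", 15L)
  for (code in 1:14) {
    inside <- which(bitwAnd(code, c(1L, 2L, 4L, 8L)) > 0L)
    tris <- NULL
    if (length(inside) == 1L) {
      o <- canon(c(inside, others(inside)))
      i <- o[1]; j <- o[2]; k <- o[3]; l <- o[4]
      tris <- list(rbind(c(i, j), c(i, k), c(i, l)))
    } else if (length(inside) == 3L) {
      out <- setdiff(1:4, inside)
      o <- canon(c(out, others(out)))
      i <- o[1]; j <- o[2]; k <- o[3]; l <- o[4]
      tris <- list(rbind(c(i, j), c(i, l), c(i, k)))
    } else if (length(inside) == 2L) {
      i <- inside[1]; j <- inside[2]
      kl <- setdiff(1:4, inside)
      o <- c(i, j, kl)
      if (perm_sign(o) < 0) o <- c(i, j, kl[2:1])
      i <- o[1]; j <- o[2]; k <- o[3]; l <- o[4]
      tris <- list(rbind(c(i, k), c(i, l), c(j, l)),
                   rbind(c(i, k), c(j, l), c(j, k)))
    }
    table[[code]] <- tris
  }
  table
})

#' Extract a triangulated isosurface
#'
#' Extracts the iso-level surface `intensity = threshold` as a triangle
#' mesh from the trilinear field sampled at voxel centres, using a
#' tetrahedral cube decomposition (a table-free, topologically consistent
#' marching-cubes variant).  Vertex positions are in physical units;
#' triangle winding is counterclockwise seen from the above-threshold
#' side.
#'
#' @inheritParams extract_boundary_quads
#' @return A `poly_surface` of triangles with connectivity tables.
#' @export
extract_isosurface_triangles <- function(volume, threshold,
                                         keep = c("largest", "all")) {
  keep <- match.arg(keep)
  stopifnot(inherits(volume, "voxel_volume"))
  d <- volume$dims
  if (any(d < 2L)) psf_stop("volume must be at least 2 voxels per axis",
                            "bad_volume")
  vals <- as.vector(volume$intensities)
  # nudge samples sitting exactly on the level so every crossing is proper
  eps <- 1e-9 * max(1, abs(threshold), max(abs(vals)))
  vals[vals == threshold] <- threshold + eps
  inside_all <- vals >= threshold
  if (!any(inside_all) || all(inside_all)) {
    psf_stop(sprintf("iso-level %g does not cross the volume: empty surface",
                     threshold), "empty_surface", list(threshold = threshold))
  }

  gid <- function(x, y, z) x + d[1] * (y + d[2] * z)  # 0-based grid id
  NG <- prod(d)

  # active cubes: any corner sign differs from corner 1
  dim(inside_all) <- d
  low_in <- inside_all[1:(d[1] - 1), 1:(d[2] - 1), 1:(d[3] - 1), drop = FALSE]
  mixed <- array(FALSE, d - 1L)
  for (c8 in 2:8) {
    off <- cube_corners[c8, ]
    blk <- inside_all[(1 + off[1]):(d[1] - 1 + off[1]),
                      (1 + off[2]):(d[2] - 1 + off[2]),
                      (1 + off[3]):(d[3] - 1 + off[3]), drop = FALSE]
    mixed <- mixed | (blk != low_in)
  }
  act <- which(mixed, arr.ind = TRUE)
  if (nrow(act) == 0L) {
    psf_stop(sprintf("iso-level %g does not cross the volume: empty surface",
                     threshold), "empty_surface", list(threshold = threshold))
  }
  low <- act - 1L  # 0-based low-corner grid coords of active cubes

  # global ids of the 8 corners of every active cube
  cg <- matrix(0, nrow(low), 8L)
  for (c8 in 1:8) {
    off <- cube_corners[c8, ]
    cg[, c8] <- gid(low[, 1] + off[1], low[, 2] + off[2], low[, 3] + off[3])
  }

  tri_keys <- vector("list", 6L * 14L)
  slot <- 0L
  for (t6 in 1:6) {
    tc <- freudenthal_tets[t6, ]
    g4 <- cg[, tc, drop = FALSE]           # n x 4 global corner ids
    ins <- matrix(inside_all[g4 + 1L], ncol = 4L)
    code <- ins[, 1] + 2L * ins[, 2] + 4L * ins[, 3] + 8L * ins[, 4]
    for (cc in 1:14) {
      rows <- which(code == cc)
      if (length(rows) == 0L) next
      for (tri in tet_case_table[[cc]]) {
        ka <- edge_key(g4[rows, tri[1, 1]], g4[rows, tri[1, 2]], NG)
        kb <- edge_key(g4[rows, tri[2, 1]], g4[rows, tri[2, 2]], NG)
        kc <- edge_key(g4[rows, tri[3, 1]], g4[rows, tri[3, 2]], NG)
        slot <- slot + 1L
        tri_keys[[slot]] <- cbind(ka, kb, kc)
      }
    }
  }
  keys <- do.call(rbind, tri_keys[seq_len(slot)])
  ukeys <- sort(unique(as.vector(keys)))
  faces <- matrix(match(as.vector(keys), ukeys), ncol = 3L)

  # decode lattice edges and interpolate crossing positions
  ga <- floor(ukeys / NG)
  gb <- ukeys - ga * NG
  fa <- vals[ga + 1L]; fb <- vals[gb + 1L]
  t <- (threshold - fa) / (fb - fa)
  pa <- decode_grid(ga, d, volume)
  pb <- decode_grid(gb, d, volume)
  vertices <- pa * (1 - t) + pb * t

  if (keep == "largest") {
    comp <- keep_largest_component(vertices, faces)
    vertices <- comp$vertices
    faces <- comp$faces
  }
  build_connectivity(vertices, faces)
}

# undirected lattice-edge key as a double (< 2^53)
edge_key <- function(ga, gb, NG) pmin(ga, gb) * NG + pmax(ga, gb)

# physical coordinates of voxel centres with 0-based grid ids
decode_grid <- function(g, d, volume) {
  x <- g %% d[1]
  y <- (g %/% d[1]) %% d[2]
  z <- g %/% (d[1] * d[2])
  p <- (cbind(x, y, z) + 0.5) * rep(volume$spacing, each = length(g))
  sweep(p, 2L, volume$origin, "+")
}
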