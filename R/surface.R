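# Polygonal surfaces: vertices + quad/triangle connectivity and the
# derived tables (vertex adjacency graph, inverse vertex->face table).

#' Build a polygonal surface with full connectivity tables
#'
#' Given vertices and faces, populates the vertex adjacency graph (for each
#' vertex, the sorted indices of vertices sharing a face edge with it) and
#' the inverse connectivity (for each vertex, the indices of incident
#' faces).  The adjacency is symmetric by construction and each row length
#' equals the vertex's topological degree.
#'
#' @param vertices numeric `n x 3` matrix of positions in physical units.
#' @param faces integer `m x 4` (quads) or `m x 3` (triangles) matrix of
#'   1-based vertex indices; each face must reference distinct, in-range
#'   vertices.
#' @return An object of class `poly_surface` with fields `vertices`,
#'   `faces`, `kind` (`"quad"` or `"tri"`), `adjacency` (list), `inverse`
#'   (list).
#' @export
build_connectivity <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) psf_stop("vertices must be n x 3", "bad_surface")
  nc <- ncol(faces)
  if (!nc %in% c(3L, 4L)) psf_stop("faces must be m x 3 or m x 4", "bad_surface")
  n <- nrow(vertices)
  bad <- which(faces < 1L | faces > n, arr.ind = TRUE)
  if (length(bad)) {
    f <- unname(bad[1L, 1L])
    psf_stop(sprintf("face %d references out-of-range vertex index %d (n = %d)",
                     f, faces[bad[1L, 1L], bad[1L, 2L]], n),
             "bad_face_index", list(face = f))
  }
  dup <- which(apply(faces, 1L, anyDuplicated) > 0L)
  if (length(dup)) {
    psf_stop(sprintf("face %d has repeated vertex indices", dup[1L]),
             "bad_face_index", list(face = dup[1L]))
  }

  # face edges: consecutive corners, cyclic
  from <- as.vector(faces)
  to <- as.vector(faces[, c(2:nc, 1L)])
  a <- pmin(from, to); b <- pmax(from, to)
  adjacency <- split_sorted_unique(c(a, b), c(b, a), n)
  inverse <- split_sorted_unique(as.vector(faces),
                                 rep(seq_len(nrow(faces)), times = nc), n)
  structure(
    list(vertices = vertices, faces = faces,
         kind = if (nc == 4L) "quad" else "tri",
         adjacency = adjacency, inverse = inverse),
    class = "poly_surface"
  )
}

# group `values` by `keys` in 1..n, sort+dedup each group; empty groups kept
split_sorted_unique <- function(keys, values, n) {
  grp <- split(values, factor(keys, levels = seq_len(n)))
  lapply(grp, function(v) sort(unique(v)))
}

#' @export
print.poly_surface <- function(x, ...) {
  cat(sprintf("<poly_surface> %d vertices, %d %s faces\n",
              nrow(x$vertices), nrow(x$faces),
              if (x$kind == "quad") "quad" else "triangle"))
  invisible(x)
}

#' Total surface area of a polygonal surface
#'
#' Quads are split along a diagonal into two triangles for the area
#' computation (exact for the planar quads produced by voxel-face
#' extraction).
#'
#' @param surface a `poly_surface`.
#' @return total area, physical units squared.
#' @export
surface_area <- function(surface) {
  v <- surface$vertices
  f <- surface$faces
  tri_area <- function(i, j, k) {
    u <- v[j, , drop = FALSE] - v[i, , drop = FALSE]
    w <- v[k, , drop = FALSE] - v[i, , drop = FALSE]
    cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
    cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
    cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
    0.5 * sqrt(cx^2 + cy^2 + cz^2)
  }
  if (surface$kind == "tri") {
    sum(tri_area(f[, 1], f[, 2], f[, 3]))
  } else {
    sum(tri_area(f[, 1], f[, 2], f[, 3])) + sum(tri_area(f[, 1], f[, 3], f[, 4]))
  }
}

# table of undirected face edges: columns a < b, face id
face_edges <- function(surface) {
  f <- surface$faces
  nc <- ncol(f)
  from <- as.vector(f)
  to <- as.vector(f[, c(2:nc, 1L)])
  data.frame(a = pmin(from, to), b = pmax(from, to),
             face = rep(seq_len(nrow(f)), times = nc))
}

# number of faces sharing each undirected edge
edge_face_counts <- function(surface) {
  e <- face_edges(surface)
  key <- paste(e$a, e$b)
  tab <- table(key)
  as.integer(tab)
}

# connected components over the vertex adjacency graph; returns membership
surface_components <- function(surface) {
  g <- igraph::graph_from_adj_list(surface$adjacency, mode = "all")
  igraph::components(g)$membership
}

# keep the largest connected component by face count; drop unused vertices
keep_largest_component <- function(vertices, faces) {
  n <- nrow(vertices)
  nc <- ncol(faces)
  from <- as.vector(faces)
  to <- as.vector(faces[, c(2:nc, 1L)])
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  memb <- igraph::components(g)$membership
  fc <- memb[faces[, 1L]]
  counts <- table(fc)
  if (length(counts) > 1L) {
    psf_log(sprintf("surface has %d connected components; keeping largest (%s faces of %d)",
                    length(counts), max(counts), nrow(faces)), level = "warn")
  }
  best <- as.integer(names(counts)[which.max(counts)])
  faces <- faces[fc == best, , drop = FALSE]
  used <- sort(unique(as.vector(faces)))
  remap <- integer(n)
  remap[used] <- seq_along(used)
  list(vertices = vertices[used, , drop = FALSE],
       faces = matrix(remap[faces], ncol = nc),
       kept_vertices = used)
}

#' Find the surface vertices nearest to given physical points
#'
#' Convenience helper, e.g. to turn analytically known anchor locations on
#' a phantom into concrete vertex indices.
#'
#' @param surface a `poly_surface`.
#' @param points numeric `k x 3` matrix of query points.
#' @return integer vector of `k` vertex indices.
#' @export
pick_nearest_vertices <- function(surface, points) {
  points <- matrix(as.numeric(points), ncol = 3L)
  v <- surface$vertices
  vapply(seq_len(nrow(points)), function(i) {
    d2 <- (v[, 1] - points[i, 1])^2 + (v[, 2] - points[i, 2])^2 +
      (v[, 3] - points[i, 3])^2
    which.min(d2)
  }, integer(1L))
}

#' Propose 4 extremal anchor vertices
#'
#' Projects the vertices on their first two principal axes and returns the
#' vertices nearest the two extremes of each axis, in cyclic order
#' (+PC1, +PC2, -PC1, -PC2).  A scriptable stand-in for interactive anchor
#' picking; works well for roughly convex patches.
#'
#' @param surface a `poly_surface`.
#' @return integer vector of 4 distinct vertex indices.
#' @export
suggest_anchors <- function(surface) {
  v <- surface$vertices
  ctr <- colMeans(v)
  vc <- sweep(v, 2L, ctr)
  pc <- svd(vc, nu = 0L, nv = 2L)$v
  s1 <- vc %*% pc[, 1L]
  s2 <- vc %*% pc[, 2L]
  idx <- c(which.max(s1), which.max(s2), which.min(s1), which.min(s2))
  if (anyDuplicated(idx)) {
    psf_stop("could not find 4 distinct extremal vertices", "bad_anchors")
  }
  as.integer(idx)
}
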