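# Post-processing of the parametric map for very dense point clouds:
# crossing segments are collapsed onto their intersection point, and
# nearly parallel segments sharing a vertex are fused.

# proper intersection point of segments p1-p2 and p3-p4, or NULL
segment_intersection <- function(p1, p2, p3, p4) {
  d1 <- p2 - p1
  d2 <- p4 - p3
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(den) < 1e-300) return(NULL)
  t <- ((p3[1] - p1[1]) * d2[2] - (p3[2] - p1[2]) * d2[1]) / den
  s <- ((p3[1] - p1[1]) * d1[2] - (p3[2] - p1[2]) * d1[1]) / den
  if (t <= 0 || t >= 1 || s <= 0 || s >= 1) return(NULL)
  list(point = p1 + t * d1, t = t, s = s)
}

# candidate edge pairs with overlapping bounding boxes, found by binning
# edge boxes on a uniform grid
bbox_candidate_pairs <- function(uv, edges) {
  xmin <- pmin(uv[edges[, 1], 1], uv[edges[, 2], 1])
  xmax <- pmax(uv[edges[, 1], 1], uv[edges[, 2], 1])
  ymin <- pmin(uv[edges[, 1], 2], uv[edges[, 2], 2])
  ymax <- pmax(uv[edges[, 1], 2], uv[edges[, 2], 2])
  cell <- max(stats::median(xmax - xmin), stats::median(ymax - ymin), 1e-12) * 2
  cx0 <- floor(xmin / cell); cx1 <- floor(xmax / cell)
  cy0 <- floor(ymin / cell); cy1 <- floor(ymax / cell)
  buckets <- new.env(hash = TRUE)
  for (e in seq_len(nrow(edges))) {
    for (cx in cx0[e]:cx1[e]) for (cy in cy0[e]:cy1[e]) {
      key <- paste(cx, cy)
      buckets[[key]] <- c(buckets[[key]], e)
    }
  }
  pairs <- list()
  for (key in ls(buckets)) {
    es <- buckets[[key]]
    if (length(es) > 1L) {
      cmb <- utils::combn(es, 2L)
      pairs[[length(pairs) + 1L]] <- t(cmb)
    }
  }
  if (!length(pairs)) return(matrix(integer(0), 0L, 2L))
  pr <- unique(do.call(rbind, pairs))
  ok <- xmin[pr[, 1]] <= xmax[pr[, 2]] & xmin[pr[, 2]] <= xmax[pr[, 1]] &
    ymin[pr[, 1]] <= ymax[pr[, 2]] & ymin[pr[, 2]] <= ymax[pr[, 1]]
  pr[ok, , drop = FALSE]
}

#' Repair vertex collisions in a parametric mesh
#'
#' Best-effort post-processing of a dense parametric map: when two
#' non-adjacent edges properly cross in the `(u, v)` plane, the endpoint
#' of each edge closest to the crossing is moved onto the crossing point;
#' when two edges sharing a vertex are nearly parallel (angle below
#' `fuse_angle_tol`), their outer endpoints are fused into one vertex and
#' the connectivity is updated.  Runs up to `max_passes` passes and always
#' returns; a warning is logged if crossings remain.
#'
#' Pinned boundary vertices are never moved or fused away.
#'
#' @param pmesh a `parametric_mesh`.
#' @param fuse_angle_tol radians; edges at a common vertex closer in
#'   direction than this are fused.
#' @param max_passes maximum number of repair sweeps.
#' @return A `parametric_mesh`; attribute `modified` lists the vertex
#'   indices (in the returned mesh) that were moved or produced by a
#'   fusion, attribute `fused` counts fusions.
#' @export
repair_collisions <- function(pmesh, fuse_angle_tol = 1e-3, max_passes = 5L) {
  uv <- pmesh$uv
  surface <- pmesh$surface
  fixed <- pmesh$fixed
  modified <- integer(0)
  fused_total <- 0L

  for (pass in seq_len(max_passes)) {
    changed <- FALSE
    edges <- unique_edges(surface)
    pr <- bbox_candidate_pairs(uv, edges)
    if (nrow(pr)) {
      for (r in seq_len(nrow(pr))) {
        e1 <- edges[pr[r, 1], ]; e2 <- edges[pr[r, 2], ]
        if (length(intersect(e1, e2))) next  # adjacent edges: fuse rule instead
        isec <- segment_intersection(uv[e1[1], ], uv[e1[2], ],
                                     uv[e2[1], ], uv[e2[2], ])
        if (is.null(isec)) next
        # endpoint of each segment closest to the crossing
        m1 <- if (isec$t <= 0.5) e1[1] else e1[2]
        m2 <- if (isec$s <= 0.5) e2[1] else e2[2]
        for (mv in c(m1, m2)) {
          if (!mv %in% fixed) {
            uv[mv, ] <- isec$point
            modified <- union(modified, mv)
            changed <- TRUE
          }
        }
      }
    }

    # fuse nearly parallel edge pairs at a shared vertex
    fuse <- find_fuse_pair(uv, surface, fixed, fuse_angle_tol)
    if (!is.null(fuse)) {
      res <- fuse_vertices(uv, surface, fixed, fuse[1], fuse[2])
      uv <- res$uv; surface <- res$surface; fixed <- res$fixed
      modified <- union(res$remap[modified], res$kept)
      modified <- modified[!is.na(modified)]
      fused_total <- fused_total + 1L
      changed <- TRUE
    }
    if (!changed) break
  }

  if (pass == max_passes) {
    psf_log("collision repair reached the pass cap; crossings may remain",
            level = "warn")
  }
  out <- parametric_mesh(surface, uv, fixed, pmesh$domain)
  attr(out, "modified") <- sort(modified)
  attr(out, "fused") <- fused_total
  out
}

# first pair of outer endpoints (b, c) of nearly parallel edges a-b, a-c
find_fuse_pair <- function(uv, surface, fixed, tol) {
  for (a in seq_len(nrow(uv))) {
    nb <- surface$adjacency[[a]]
    if (length(nb) < 2L) next
    dirs <- uv[nb, , drop = FALSE] - matrix(uv[a, ], length(nb), 2L, byrow = TRUE)
    nrm <- sqrt(rowSums(dirs^2))
    ok <- nrm > 0
    if (sum(ok) < 2L) next
    dirs <- dirs[ok, , drop = FALSE] / nrm[ok]
    nbok <- nb[ok]
    for (i in seq_len(nrow(dirs) - 1L)) for (j in (i + 1L):nrow(dirs)) {
      ang <- acos(pmin(pmax(sum(dirs[i, ] * dirs[j, ]), -1), 1))
      b <- nbok[i]; cc <- nbok[j]
      if (ang < tol && !(b %in% fixed && cc %in% fixed)) {
        return(c(b, cc))
      }
    }
  }
  NULL
}

# merge vertex `drop` into vertex `keep`; uv of the merged vertex is the
# midpoint unless one of the two is pinned
fuse_vertices <- function(uv, surface, fixed, keep, drop) {
  if (drop %in% fixed && !(keep %in% fixed)) { tmp <- keep; keep <- drop; drop <- tmp }
  n <- nrow(uv)
  if (!keep %in% fixed) uv[keep, ] <- (uv[keep, ] + uv[drop, ]) / 2
  remap <- seq_len(n)
  remap[drop] <- keep
  f <- matrix(remap[surface$faces], ncol = ncol(surface$faces))
  degenerate <- apply(f, 1L, anyDuplicated) > 0L
  f <- f[!degenerate, , drop = FALSE]
  live <- sort(unique(as.vector(f)))
  newid <- integer(n)
  newid[live] <- seq_along(live)
  out_surface <- build_connectivity(surface$vertices[live, , drop = FALSE],
                                    matrix(newid[f], ncol = ncol(f)))
  full_remap <- newid[remap]          # old vertex -> new index (0 if gone)
  full_remap[full_remap == 0L] <- NA_integer_
  list(uv = uv[live, , drop = FALSE], surface = out_surface,
       fixed = sort(unique(full_remap[fixed])),
       remap = full_remap, kept = newid[keep])
}
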