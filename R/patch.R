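# Patch delimitation: 4 anchors joined by shortest boundary paths on the
# surface graph, plus the pinned-boundary parametric assignment.

#' Delimit a surface patch by 4 anchor vertices
#'
#' Traces the 4 boundary segments joining consecutive anchors as shortest
#' paths on the surface edge graph (hop count, with physical edge length
#' as tie-breaker), verifies that they form a simple closed loop, and
#' collects the patch interior.
#'
#' @param surface a `poly_surface`.
#' @param anchors integer vector of 4 distinct vertex indices, in cyclic
#'   order around the desired patch.
#' @param inside optional hint selecting which side of the loop is the
#'   patch interior: a vertex index, or a physical point (length-3) whose
#'   nearest vertex is used.  By default the side containing the vertex
#'   graph-farthest from the loop is taken (for a dome bounded by its rim
#'   this is the dome).
#' @return A `patch_spec`: `anchors` (possibly adjusted, see Details),
#'   `boundary_paths` (4 vertex index sequences, each including both end
#'   anchors), `loop` (the closed loop, no repeats), `interior` (vertex
#'   indices strictly inside).
#'
#' @details On digitized staircase rims the traced loop occasionally runs
#' along every edge of a single face ("ear"); pinning all corners of such
#' a face onto the domain border would degenerate or invert its
#' parametric image.  The loop is therefore post-processed: each ear is
#' rerouted through the face's remaining edge, which releases the run's
#' middle vertices into the interior.  If an anchor sits on a released
#' vertex the anchor label moves to the run endpoint, so always read the
#' anchors actually used from the returned spec.
#' @export
trace_patch <- function(surface, anchors, inside = NULL) {
  anchors <- as.integer(anchors)
  if (length(anchors) != 4L || anyDuplicated(anchors)) {
    psf_stop("anchors must be 4 distinct vertex indices", "bad_anchors",
             list(anchors = anchors))
  }
  n <- nrow(surface$vertices)
  if (any(anchors < 1L | anchors > n)) {
    psf_stop("anchor index out of range", "bad_anchors", list(anchors = anchors))
  }
  el <- unique_edges(surface)
  len <- sqrt(row_norms2(surface$vertices[el[, 1], , drop = FALSE] -
                           surface$vertices[el[, 2], , drop = FALSE]))
  # hop count dominates; physical length only breaks ties
  w <- 1 + len * (1e-9 / max(len))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::E(g)$weight <- w

  igraph::V(g)$name <- as.character(seq_len(n))

  # trace the 4 segments sequentially, removing the vertices already used
  # by earlier segments (anchors excepted) so the loop is simple
  paths <- vector("list", 4L)
  used <- integer(0)
  for (s in 1:4) {
    from <- anchors[s]
    to <- anchors[if (s == 4L) 1L else s + 1L]
    forbidden <- setdiff(used, c(from, to))
    gs <- if (length(forbidden)) {
      igraph::delete_vertices(g, as.character(forbidden))
    } else g
    sp <- suppressWarnings(igraph::shortest_paths(gs, as.character(from),
                                                  as.character(to),
                                                  output = "vpath"))
    vp <- as.integer(names(sp$vpath[[1L]]))
    if (length(vp) < 2L) {
      psf_stop(sprintf(
        "anchors %d and %d cannot be joined without crossing earlier segments",
        from, to), "anchors_disconnected", list(pair = c(from, to)))
    }
    paths[[s]] <- vp
    used <- union(used, vp)
  }
  loop <- unlist(lapply(paths, function(p) p[-length(p)]))
  if (anyDuplicated(loop)) {
    dupv <- loop[duplicated(loop)][1L]
    psf_stop(sprintf("boundary loop self-intersects at vertex %d", dupv),
             "loop_not_simple", list(vertex = dupv))
  }

  rerouted <- reroute_loop_ears(loop, anchors, surface)
  loop <- rerouted$loop
  anchors <- rerouted$anchors
  paths <- split_loop_at_anchors(loop, anchors)

  interior <- patch_interior(g, loop, surface, inside)
  structure(list(anchors = anchors, boundary_paths = paths, loop = loop,
                 interior = interior),
            class = "patch_spec")
}

# Remove "ears": faces whose corners form a consecutive run covering the
# whole face along the loop.  The loop is rerouted through the face's
# remaining edge; released middle vertices leave the loop.  Anchor labels
# sitting on released vertices move to the run endpoint.
reroute_loop_ears <- function(loop, anchors, surface, max_passes = 50L) {
  f <- surface$faces
  nc <- ncol(f)
  for (pass in seq_len(max_passes)) {
    L <- length(loop)
    pos <- integer(nrow(surface$vertices))
    pos[loop] <- seq_len(L)
    pf <- matrix(pos[f], nrow = nrow(f))
    cand <- which(rowSums(pf > 0L) == nc)
    ear <- NULL
    for (fi in cand) {
      p <- sort(pf[fi, ])
      run <- NULL
      if (all(diff(p) == 1L)) run <- p
      else if (p[1] == 1L && p[nc] == L) {
        # cyclic wrap: rotate positions below the gap to the end
        gap <- which(diff(p) != 1L)
        if (length(gap) == 1L) run <- c(p[(gap + 1L):nc], p[1:gap] + L)
      }
      if (!is.null(run)) {
        # run endpoints must be joined by the remaining face edge
        ends <- loop[((run[c(1L, length(run))] - 1L) %% L) + 1L]
        if (ends[2L] %in% surface$adjacency[[ends[1L]]]) { ear <- run; break }
      }
    }
    if (is.null(ear)) return(list(loop = loop, anchors = anchors))
    drop_pos <- ((ear[-c(1L, length(ear))] - 1L) %% L) + 1L
    dropped <- loop[drop_pos]
    endpts <- loop[((ear[c(1L, length(ear))] - 1L) %% L) + 1L]
    for (a in intersect(dropped, anchors)) {
      repl <- setdiff(endpts, anchors)
      if (!length(repl)) {
        psf_log("cannot relocate anchor off a loop ear; keeping loop as is",
                level = "warn")
        return(list(loop = loop, anchors = anchors))
      }
      anchors[anchors == a] <- repl[1L]
      psf_log(sprintf("anchor %d released by ear reroute; moved to %d",
                      a, repl[1L]), level = "warn")
    }
    loop <- loop[-drop_pos]
  }
  psf_log("ear rerouting pass cap reached", level = "warn")
  list(loop = loop, anchors = anchors)
}

# split a cyclic loop into the 4 anchor-to-anchor paths (anchors must lie
# on the loop in cyclic order)
split_loop_at_anchors <- function(loop, anchors) {
  L <- length(loop)
  pos <- match(anchors, loop)
  if (any(is.na(pos))) psf_stop("anchor missing from loop", "bad_anchors")
  # rotate so anchor 1 is first
  loop <- loop[((pos[1L] - 1L + seq_len(L) - 1L) %% L) + 1L]
  pos <- match(anchors, loop)
  ord <- order(pos)
  if (!identical(anchors[ord], anchors) && !identical(anchors[ord], anchors[c(1, 4, 3, 2)])) {
    # anchors must appear in cyclic order (either direction)
    psf_stop("anchors are not in cyclic order along the loop", "bad_anchors")
  }
  if (identical(anchors[ord], anchors[c(1, 4, 3, 2)])) {
    loop <- c(loop[1L], rev(loop[-1L]))  # reverse traversal direction
    pos <- match(anchors, loop)
  }
  paths <- vector("list", 4L)
  bounds <- c(pos, L + 1L)
  for (s in 1:4) {
    idx <- bounds[s]:(bounds[s + 1L])
    idx[idx > L] <- idx[idx > L] - L
    paths[[s]] <- loop[c(idx[-length(idx)], idx[length(idx)])]
  }
  # close each path with the next anchor
  for (s in 1:4) {
    nxt <- anchors[if (s == 4L) 1L else s + 1L]
    p <- paths[[s]]
    if (p[length(p)] != nxt) paths[[s]] <- c(p, nxt)
  }
  paths
}

unique_edges <- function(surface) {
  e <- face_edges(surface)
  as.matrix(unique(e[, c("a", "b")]))
}

patch_interior <- function(g, loop, surface, inside) {
  n <- nrow(surface$vertices)
  g2 <- igraph::delete_vertices(g, loop)
  keep <- setdiff(seq_len(n), loop)
  memb <- igraph::components(g2)$membership
  if (is.null(inside)) {
    # multi-source BFS distance from the loop; take the component of the
    # farthest vertex
    dmat <- igraph::distances(g, v = loop, to = keep, weights = NA)
    seed_pos <- which.max(apply(dmat, 2L, min))
  } else {
    seed_v <- if (length(inside) == 3L && !is.integer(inside)) {
      pick_nearest_vertices(surface, matrix(inside, 1L))
    } else as.integer(inside)
    if (seed_v %in% loop) {
      psf_stop("interior seed vertex lies on the boundary loop", "bad_anchors")
    }
    seed_pos <- match(seed_v, keep)
  }
  keep[memb == memb[seed_pos]]
}

#' @export
print.patch_spec <- function(x, ...) {
  cat(sprintf("<patch_spec> anchors (%s); loop %d vertices, interior %d vertices\n",
              paste(x$anchors, collapse = ", "), length(x$loop),
              length(x$interior)))
  invisible(x)
}

#' Pin the patch boundary onto the border of the parametric domain
#'
#' Anchors map to the domain corners in cyclic order
#' `(umin,vmin) -> (umax,vmin) -> (umax,vmax) -> (umin,vmax)`; the
#' vertices of each boundary segment are distributed along their domain
#' edge, equally spaced by vertex count (default) or proportionally to
#' cumulative physical arc length.
#'
#' @param spec a `patch_spec`.
#' @param domain `c(umin, umax, vmin, vmax)`.
#' @param spacing_mode `"count"` (equidistributed by vertex count) or
#'   `"arclength"`.
#' @param surface required for `"arclength"` spacing: the `poly_surface`
#'   the patch lives on.
#' @return data.frame with columns `vertex`, `u`, `v`: the fixed boundary
#'   assignment (index set g).
#' @export
pin_boundary <- function(spec, domain = c(0, 1, 0, 1),
                         spacing_mode = c("count", "arclength"),
                         surface = NULL) {
  spacing_mode <- match.arg(spacing_mode)
  stopifnot(inherits(spec, "patch_spec"), length(domain) == 4L)
  umin <- domain[1]; umax <- domain[2]; vmin <- domain[3]; vmax <- domain[4]
  if (umax <= umin || vmax <= vmin) psf_stop("degenerate domain", "bad_domain")
  corners <- rbind(c(umin, vmin), c(umax, vmin), c(umax, vmax), c(umin, vmax))

  rows <- vector("list", 4L)
  for (s in 1:4) {
    p <- spec$boundary_paths[[s]]
    c0 <- corners[s, ]
    c1 <- corners[if (s == 4L) 1L else s + 1L, ]
    if (spacing_mode == "count" || length(p) == 2L) {
      t <- seq(0, 1, length.out = length(p))
    } else {
      if (is.null(surface)) psf_stop("arclength spacing needs `surface`", "bad_domain")
      seg <- sqrt(row_norms2(surface$vertices[p[-1L], , drop = FALSE] -
                               surface$vertices[p[-length(p)], , drop = FALSE]))
      t <- c(0, cumsum(seg)) / sum(seg)
    }
    # drop the closing vertex: it is the first vertex of the next path
    keep <- seq_len(length(p) - 1L)
    rows[[s]] <- data.frame(vertex = p[keep],
                            u = c0[1] + t[keep] * (c1[1] - c0[1]),
                            v = c0[2] + t[keep] * (c1[2] - c0[2]))
  }
  do.call(rbind, rows)
}

#' Extract the patch submesh delimited by a patch_spec
#'
#' Restricts the surface to the patch vertices (interior plus loop) and
#' the faces entirely inside the patch, renumbering vertices.
#'
#' @param surface a `poly_surface`.
#' @param spec a `patch_spec` traced on `surface`.
#' @return list: `surface` (the patch `poly_surface`), `index_map`
#'   (original index per new vertex), `loop`, `interior` (new indices).
#' @export
extract_patch <- function(surface, spec) {
  keep <- sort(c(spec$loop, spec$interior))
  remap <- integer(nrow(surface$vertices))
  remap[keep] <- seq_along(keep)
  f <- surface$faces
  infaces <- rowSums(matrix(remap[f] > 0L, nrow = nrow(f))) == ncol(f)
  sub <- build_connectivity(surface$vertices[keep, , drop = FALSE],
                            matrix(remap[f[infaces, , drop = FALSE]],
                                   ncol = ncol(f)))
  list(surface = sub, index_map = keep,
       loop = remap[spec$loop], interior = remap[spec$interior])
}
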