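# Boundary quad extraction: external faces of voxels crossing a
# threshold intensity.

#' Extract the boundary quad surface of thresholded voxels
#'
#' All voxels crossing the threshold intensity are labelled edge voxels;
#' the external faces of these voxels (the quads not shared with another
#' labelled voxel) form the polygonal surface.  Quad vertices are voxel
#' cube corners in physical units; shared corners are deduplicated by
#' their exact integer grid coordinates.  Quads are wound counterclockwise
#' seen from outside the labelled region.
#'
#' @param volume a [voxel_volume()].
#' @param threshold intensity threshold; voxels with intensity
#'   `>= threshold` (or `> threshold` with `comparison = "gt"`) are
#'   labelled.
#' @param comparison `">="` (default) or `">"`; how "crossing the
#'   threshold" is read.
#' @param keep `"largest"` keeps only the largest connected surface
#'   component (by face count, others are logged); `"all"` keeps every
#'   component.
#' @return A [build_connectivity()] `poly_surface` of quads.
#' @export
extract_boundary_quads <- function(volume, threshold,
                                   comparison = c(">=", ">"),
                                   keep = c("largest", "all")) {
  comparison <- match.arg(comparison)
  keep <- match.arg(keep)
  stopifnot(inherits(volume, "voxel_volume"))
  mask <- if (comparison == ">=") volume$intensities >= threshold
          else volume$intensities > threshold
  if (!any(mask)) {
    psf_stop(sprintf("no voxel crosses threshold %g: empty surface", threshold),
             "empty_surface", list(threshold = threshold))
  }
  d <- volume$dims

  # padded mask makes out-of-bounds neighbours FALSE
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE]
  shift <- function(dx, dy, dz) {
    pad[(2 + dx):(d[1] + 1 + dx), (2 + dy):(d[2] + 1 + dy),
        (2 + dz):(d[3] + 1 + dz), drop = FALSE]
  }

  # for each face direction: corner offsets (rows = 4 corners, cols = xyz
  # corner grid offsets relative to the voxel low corner), CCW from outside
  face_defs <- list(
    `+x` = list(dir = c(1, 0, 0),
                corners = rbind(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1), c(1, 0, 1))),
    `-x` = list(dir = c(-1, 0, 0),
                corners = rbind(c(0, 0, 0), c(0, 0, 1), c(0, 1, 1), c(0, 1, 0))),
    `+y` = list(dir = c(0, 1, 0),
                corners = rbind(c(0, 1, 0), c(0, 1, 1), c(1, 1, 1), c(1, 1, 0))),
    `-y` = list(dir = c(0, -1, 0),
                corners = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 1), c(0, 0, 1))),
    `+z` = list(dir = c(0, 0, 1),
                corners = rbind(c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))),
    `-z` = list(dir = c(0, 0, -1),
                corners = rbind(c(0, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, 0, 0)))
  )

  ncx <- d[1] + 1L; ncy <- d[2] + 1L
  corner_id <- function(cx, cy, cz) 1 + cx + ncx * (cy + ncy * cz)

  all_ids <- vector("list", length(face_defs))
  for (fi in seq_along(face_defs)) {
    fd <- face_defs[[fi]]
    open <- core & !shift(fd$dir[1], fd$dir[2], fd$dir[3])
    vox <- which(open, arr.ind = TRUE)  # 1-based voxel indices
    if (nrow(vox) == 0L) { all_ids[[fi]] <- NULL; next }
    low <- vox - 1L  # low corner grid coords (0-based)
    ids <- matrix(0, nrow(vox), 4L)
    for (cidx in 1:4) {
      co <- fd$corners[cidx, ]
      ids[, cidx] <- corner_id(low[, 1] + co[1], low[, 2] + co[2], low[, 3] + co[3])
    }
    all_ids[[fi]] <- ids
  }
  ids <- do.call(rbind, all_ids)

  uids <- sort(unique(as.vector(ids)))
  faces <- matrix(match(as.vector(ids), uids), ncol = 4L)
  # decode corner grid coords from ids
  u0 <- uids - 1
  cx <- u0 %% ncx
  cy <- (u0 %/% ncx) %% ncy
  cz <- u0 %/% (ncx * ncy)
  vertices <- cbind(cx, cy, cz) * rep(volume$spacing, each = length(uids))
  vertices <- sweep(vertices, 2L, volume$origin, "+")

  if (keep == "largest") {
    comp <- keep_largest_component(vertices, faces)
    vertices <- comp$vertices
    faces <- comp$faces
  }
  build_connectivity(vertices, faces)
}
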