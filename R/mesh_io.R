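# ASCII mesh writers (OBJ, PLY, legacy VTK polydata) and an OBJ reader.

fmt_num <- function(x) formatC(x, format = "g", digits = 15)

#' Write a polygonal surface as Wavefront OBJ
#' @param surface a `poly_surface`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_obj <- function(surface, path) {
  v <- surface$vertices
  f <- surface$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# parasurf OBJ export", con)
  writeLines(paste("v", fmt_num(v[, 1]), fmt_num(v[, 2]), fmt_num(v[, 3])), con)
  writeLines(paste("f", apply(f, 1L, paste, collapse = " ")), con)
  invisible(path)
}

#' Read a Wavefront OBJ mesh
#'
#' Supports plain `v`/`f` records with uniform face arity (all triangles or
#' all quads); `v/vt/vn` slash syntax is accepted, only the vertex index is
#' used.
#'
#' @param path OBJ file path.
#' @return a `poly_surface`.
#' @export
read_obj <- function(path) {
  if (!file.exists(path)) psf_stop(sprintf("cannot read '%s'", path), "io")
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (!length(vl) || !length(fl)) {
    psf_stop(sprintf("'%s' has no vertices or no faces", path), "io")
  }
  v <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p) {
    as.numeric(p[2:4])
  }))
  fparts <- strsplit(trimws(fl), "\\s+")
  arity <- unique(lengths(fparts)) - 1L
  if (length(arity) != 1L || !arity %in% c(3L, 4L)) {
    psf_stop("OBJ faces must be uniformly triangles or quads", "io")
  }
  f <- do.call(rbind, lapply(fparts, function(p) {
    as.integer(vapply(p[-1L], function(tok) strsplit(tok, "/")[[1L]][1L], ""))
  }))
  build_connectivity(v, f)
}

#' Write a polygonal surface as ASCII PLY
#' @inheritParams write_obj
#' @export
write_ply <- function(surface, path) {
  v <- surface$vertices
  f <- surface$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0", "comment parasurf export",
    sprintf("element vertex %d", nrow(v)),
    "property double x", "property double y", "property double z",
    sprintf("element face %d", nrow(f)),
    "property list uchar int vertex_indices", "end_header"
  ), con)
  writeLines(paste(fmt_num(v[, 1]), fmt_num(v[, 2]), fmt_num(v[, 3])), con)
  writeLines(paste(ncol(f), apply(f - 1L, 1L, paste, collapse = " ")), con)
  invisible(path)
}

#' Write a polygonal surface as legacy VTK polydata
#' @inheritParams write_obj
#' @export
write_vtk <- function(surface, path) {
  v <- surface$vertices
  f <- surface$faces
  nc <- ncol(f)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "parasurf surface", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", nrow(v))), con)
  writeLines(paste(fmt_num(v[, 1]), fmt_num(v[, 2]), fmt_num(v[, 3])), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(f), nrow(f) * (nc + 1L)), con)
  writeLines(paste(nc, apply(f - 1L, 1L, paste, collapse = " ")), con)
  invisible(path)
}

#' Write a parametric mesh as a vertex/u/v sidecar table
#'
#' CSV with columns `vertex`, `u`, `v`, `fixed`; the standard on-disk form
#' of a projection or regularization result.
#'
#' @param pmesh a `parametric_mesh`.
#' @param path output CSV path.
#' @export
write_uv_table <- function(pmesh, path) {
  df <- data.frame(vertex = seq_len(nrow(pmesh$uv)),
                   u = pmesh$uv[, 1], v = pmesh$uv[, 2],
                   fixed = seq_len(nrow(pmesh$uv)) %in% pmesh$fixed)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a vertex/u/v sidecar table written by [write_uv_table()]
#' @param path CSV path.
#' @param surface the `poly_surface` the table refers to.
#' @param domain parametric domain `c(umin, umax, vmin, vmax)`.
#' @return a `parametric_mesh`.
#' @export
read_uv_table <- function(path, surface, domain) {
  df <- utils::read.csv(path)
  uv <- cbind(df$u, df$v)[order(df$vertex), , drop = FALSE]
  parametric_mesh(surface, uv, which(df$fixed[order(df$vertex)]), domain)
}
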