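# Voxel volumes: construction, slice-stack I/O.

#' Construct a voxel volume
#'
#' A `voxel_volume` is a 3D scalar intensity grid with a physical voxel
#' spacing per axis.  Array index `[i, j, k]` addresses the voxel occupying
#' the axis-aligned cube `[i-1, i] x [j-1, j] x [k-1, k]` in index space,
#' scaled by `spacing` and offset by `origin` (the physical coordinate of
#' the low corner of voxel `[1, 1, 1]`).
#'
#' @param intensities numeric 3D array, finite values (conventionally in
#'   `[0, 255]` for 8-bit image stacks).
#' @param spacing numeric length-1 or length-3, physical edge length of a
#'   voxel along each axis; must be positive.
#' @param origin numeric length-3, physical position of the low corner of
#'   the first voxel.  Defaults to the coordinate origin.
#' @return An object of class `voxel_volume` with fields `intensities`,
#'   `dims`, `spacing`, `origin`.
#' @export
voxel_volume <- function(intensities, spacing = 1, origin = c(0, 0, 0)) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L) {
    psf_stop("`intensities` must be a 3D array", "bad_volume")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    psf_stop("`spacing` must be positive and finite on every axis", "bad_volume",
             list(spacing = spacing))
  }
  if (any(!is.finite(intensities))) {
    psf_stop("intensity values must all be finite", "bad_volume")
  }
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3L)
  structure(
    list(intensities = intensities, dims = dim(intensities),
         spacing = spacing, origin = origin),
    class = "voxel_volume"
  )
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("<voxel_volume> dims %s, spacing %s, intensity range [%g, %g]\n",
              paste(x$dims, collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

read_slice_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path, all = FALSE),
    psf_stop(sprintf("unsupported slice format '%s' (use PNG or TIFF)", ext),
             "io", list(path = path))
  )
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # first channel of RGB(A)
  img * 255
}

# natural numeric sort of slice file names (slice_2 before slice_10)
sort_slice_files <- function(files) {
  nums <- suppressWarnings(as.numeric(gsub("\\D", "", basename(files))))
  if (any(is.na(nums))) return(sort(files))
  files[order(nums, basename(files))]
}

#' Load a volume from an image stack
#'
#' Reads a stack of 2D grayscale slices into a [voxel_volume()].  Accepted
#' sources: a directory of numerically sorted PNG/TIFF slices, a single
#' multi-page TIFF, a single-slice image file, or an in-memory 3D array.
#' Slices are stacked along the third (z) axis in sorted order; within a
#' slice, image columns map to x and image rows to y.
#'
#' @param source directory path, file path, or 3D numeric array.
#' @param spacing physical voxel spacing (scalar or length-3).
#' @param origin physical coordinate of the low corner of the first voxel.
#' @return A [voxel_volume()]; intensities are rescaled to `[0, 255]` when
#'   read from 8/16-bit image files.
#' @export
load_volume <- function(source, spacing = 1, origin = c(0, 0, 0)) {
  if (is.array(source) && length(dim(source)) == 3L) {
    return(voxel_volume(source, spacing, origin))
  }
  if (!is.character(source) || length(source) != 1L) {
    psf_stop("`source` must be a path or a 3D array", "io")
  }
  if (!file.exists(source)) {
    psf_stop(sprintf("volume source '%s' does not exist", source), "io",
             list(path = source))
  }
  if (dir.exists(source)) {
    files <- list.files(source, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (length(files) == 0L) {
      psf_stop(sprintf("no PNG/TIFF slices found in '%s'", source), "io",
               list(path = source))
    }
    files <- sort_slice_files(files)
    slices <- lapply(files, read_slice_file)
  } else {
    ext <- tolower(tools::file_ext(source))
    if (ext %in% c("tif", "tiff")) {
      pages <- tiff::readTIFF(source, all = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      slices <- lapply(pages, function(img) {
        if (length(dim(img)) == 3L) img <- img[, , 1L]
        img * 255
      })
      files <- sprintf("%s[page %d]", source, seq_along(slices))
    } else {
      slices <- list(read_slice_file(source))
      files <- source
    }
  }
  d1 <- dim(slices[[1L]])
  for (s in seq_along(slices)) {
    if (!identical(dim(slices[[s]]), d1)) {
      psf_stop(sprintf(
        "slice %d ('%s') is %dx%d but slice 1 is %dx%d",
        s, basename(files[s]), dim(slices[[s]])[1L], dim(slices[[s]])[2L],
        d1[1L], d1[2L]),
        "slice_mismatch",
        list(slice = s, file = files[s], dim = dim(slices[[s]]), expected = d1))
    }
  }
  # slice matrix is [row = y, col = x]; volume array is [x, y, z]
  arr <- array(0, dim = c(d1[2L], d1[1L], length(slices)))
  for (s in seq_along(slices)) arr[, , s] <- t(slices[[s]])
  voxel_volume(arr, spacing, origin)
}

#' Write a volume as a stack of grayscale slice images
#'
#' One image per z-plane, named `slice_0001.png`, ... so that
#' [load_volume()] round-trips the stack.  Intensities are quantized to
#' 8 bits (exact for the binary phantom volumes).
#'
#' @param volume a [voxel_volume()].
#' @param dir output directory (created if missing).
#' @param format `"png"` or `"tiff"`.
#' @return Invisibly, the written file paths.
#' @export
write_volume_stack <- function(volume, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  stopifnot(inherits(volume, "voxel_volume"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nz <- volume$dims[3L]
  paths <- character(nz)
  for (k in seq_len(nz)) {
    img <- t(volume$intensities[, , k]) / 255
    img <- pmin(pmax(img, 0), 1)
    p <- file.path(dir, sprintf("slice_%04d.%s", k,
                                if (format == "png") "png" else "tif"))
    if (format == "png") png::writePNG(img, p) else tiff::writeTIFF(img, p)
    paths[k] <- p
  }
  invisible(paths)
}
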