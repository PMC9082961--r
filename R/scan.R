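#' Render a flatbed-scanner image of a specimen
#'
#' Rasterises the specimen silhouette at a given resolution, emulating a
#' flattened leaf scanned on a white background. The specimen is placed at a
#' seeded random sub-pixel offset and in-plane rotation (both overridable),
#' and each pixel is classified by a centre-in-silhouette test (`binary`
#' mode, no anti-aliasing) or by supersampled area coverage converted to a
#' green-channel intensity (`grayscale` mode, which exercises the
#' threshold-segmentation path).
#'
#' @param s a [leaf_specimen()].
#' @param dpi scan resolution in dots per inch, in `[50, 2400]`.
#' @param seed integer seed for the random placement (ignored when both
#'   `rotation` and `offset` are supplied).
#' @param rotation in-plane rotation in radians; default drawn uniformly on
#'   `[0, pi)`.
#' @param offset sub-pixel offset as a fraction of one pixel, length 2 in
#'   `[0, 1)`; default drawn uniformly.
#' @param mode `"binary"` (default) or `"grayscale"`.
#' @param canvas optional scanner bed size `c(width, height)` in mm; the
#'   rotated specimen must fit or an error is raised. `NULL` (default) sizes
#'   the canvas to the specimen.
#' @param leaf_green green-channel intensity of leaf tissue on a white
#'   (1.0) background, used in grayscale mode.
#' @param supersample subsamples per pixel edge in grayscale mode.
#' @return an object of class `scan_image` with fields `pixels` (matrix,
#'   rows = y; foreground mask in binary mode, green-channel image in
#'   grayscale mode), `dpi`, `mode`, `specimen_id` and `placement`.
#' @examples
#' sq <- leaf_specimen(leaf_shape(25.4, 25.4, width_exponent = 0,
#'                                thickness = c(0.3, 0.25, 0.2)))
#' sc <- render_scan(sq, dpi = 200, rotation = 0, offset = c(0, 0))
#' sum(sc$pixels)  # 200^2 pixels per square inch -> 40000
#' @export
render_scan <- function(s, dpi, seed = NULL, rotation = NULL, offset = NULL,
                        mode = c("binary", "grayscale"), canvas = NULL,
                        leaf_green = 0.35, supersample = 4L) {
  stopifnot(inherits(s, "leaf_specimen"), dpi >= 50, dpi <= 2400)
  mode <- match.arg(mode)
  pl <- draw_placement(s, dpi, seed, rotation, offset, canvas)
  ss <- if (mode == "binary") 1L else as.integer(supersample)
  cov <- .silhouette_coverage(pl$nx, pl$ny, pl$pitch, pl$origin[1], pl$origin[2],
                              cos(pl$rotation), sin(pl$rotation),
                              s$interval[1], s$interval[2],
                              s$shape$length, s$shape$max_width,
                              s$shape$width_exponent, ss)
  pixels <- if (mode == "binary") cov else 1 - cov * (1 - leaf_green)
  structure(list(pixels = pixels, dpi = dpi, mode = mode,
                 specimen_id = s$id, placement = pl),
            class = "scan_image")
}

#' @export
print.scan_image <- function(x, ...) {
  cat(sprintf("Scan of '%s': %d x %d px at %g dpi (%s)\n",
              x$specimen_id, ncol(x$pixels), nrow(x$pixels), x$dpi, x$mode))
  invisible(x)
}

# Seeded placement of a specimen on the pixel lattice. The leaf-frame basal
# axis point maps to scanner coordinate `origin`; origins are snapped so
# that with zero offset the basal point lies on a pixel boundary (whole-
# pixel margins do not change the foreground count).
draw_placement <- function(s, dpi, seed = NULL, rotation = NULL,
                           offset = NULL, canvas = NULL, margin_px = 2L) {
  pitch <- 25.4 / dpi
  if (is.null(rotation) || is.null(offset)) {
    drawn <- with_seed(seed, list(rot = runif(1, 0, pi), off = runif(2, 0, 1)))
    if (is.null(rotation)) rotation <- drawn$rot
    if (is.null(offset)) offset <- drawn$off
  }
  stopifnot(length(offset) == 2, all(offset >= 0), all(offset < 1))
  # rotated extent of the piece bounding box (leaf frame, relative to base)
  hw <- s$shape$max_width / 2
  us <- c(0, diff(s$interval))
  corners <- rbind(c(us[1], -hw), c(us[1], hw), c(us[2], -hw), c(us[2], hw))
  rot <- matrix(c(cos(rotation), sin(rotation),
                  -sin(rotation), cos(rotation)), 2, 2)
  sc <- corners %*% t(rot)
  ext <- c(diff(range(sc[, 1])), diff(range(sc[, 2])))
  if (!is.null(canvas)) {
    if (any(ext + 2 * margin_px * pitch > canvas)) {
      stop(sprintf("specimen (%.0f x %.0f mm rotated extent) exceeds the %g x %g mm canvas",
                   ext[1], ext[2], canvas[1], canvas[2]))
    }
  }
  shift_px <- ceiling(-apply(sc, 2, min) / pitch) + margin_px
  origin <- shift_px * pitch + offset * pitch
  n_px <- ceiling((origin + apply(sc, 2, max)) / pitch) + margin_px
  list(pitch = pitch, rotation = rotation, offset = offset,
       origin = origin, nx = as.integer(n_px[1]), ny = as.integer(n_px[2]))
}

#' Read a scanned leaf image from a PNG or TIFF file
#'
#' Loads a raster as a grayscale `scan_image` for [segment_pixels()]. For
#' RGB(A) images the green channel is kept — the channel with the
#' strongest leaf/background contrast. The resolution is taken from the
#' image metadata (PNG pHYs chunk / TIFF resolution tags) unless
#' overridden.
#'
#' @param path a `.png`, `.tif` or `.tiff` file.
#' @param dpi resolution override; required when the file carries none.
#' @param specimen_id identifier to attach (default: file name).
#' @return a `scan_image` in grayscale mode.
#' @export
read_scan <- function(path, dpi = NULL, specimen_id = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    meta_dpi <- attr(img, "info")$dpi[1]
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    res <- attr(img, "x.resolution")
    unit <- attr(img, "resolution.unit")
    meta_dpi <- if (is.null(res)) NULL
                else if (identical(unit, "cm")) res * 2.54 else res
  } else {
    stop("unsupported image format: ", ext)
  }
  dpi <- dpi %||% meta_dpi
  if (is.null(dpi) || !is.finite(dpi)) {
    stop("no resolution in image metadata; supply dpi explicitly")
  }
  # PNG stores pixels per metre, so nominal integer dpi come back a hair
  # off (300 -> 299.9994); snap within the quantisation error
  if (abs(dpi - round(dpi)) < 0.01) dpi <- round(dpi)
  green <- if (length(dim(img)) == 3) img[, , min(2, dim(img)[3])] else img
  structure(list(pixels = green, dpi = as.numeric(dpi), mode = "grayscale",
                 specimen_id = specimen_id %||% basename(path),
                 placement = NULL),
            class = "scan_image")
}

#' Write a scan image to a PNG file
#'
#' The image is written white-background with the leaf rendered at its
#' green-channel intensity; the dpi is stored in the PNG metadata and
#' appended to the file name (`<id>_<dpi>dpi.png`) when `path` is a
#' directory.
#'
#' @param scan a [render_scan()] result.
#' @param path output file, or an existing directory.
#' @param leaf_green leaf intensity used to display binary masks.
#' @return the path written, invisibly.
#' @export
write_scan <- function(scan, path, leaf_green = 0.35) {
  stopifnot(inherits(scan, "scan_image"))
  if (dir.exists(path)) {
    path <- file.path(path, sprintf("%s_%ddpi.png", scan$specimen_id,
                                    as.integer(scan$dpi)))
  }
  img <- if (scan$mode == "binary") 1 - scan$pixels * (1 - leaf_green) else scan$pixels
  png::writePNG(img, target = path, dpi = scan$dpi)
  invisible(path)
}
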