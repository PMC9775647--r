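#' Construct a specimen image
#'
#' Bundles an 8-bit RGB raster with its tissue mask, optional cancer /
#' noncancer annotation mask and metadata. All rasters share the convention
#' `[row, col]`, 1-based, origin top-left; channels are red, green, blue.
#'
#' @param pixels integer array `H x W x 3`, values 0..255.
#' @param tissue_mask logical matrix `H x W`; `TRUE` marks tissue. When
#'   `NULL` it is derived with [compute_tissue_mask()].
#' @param annotation_mask optional integer matrix `H x W` with values
#'   0 = unlabeled, 1 = noncancer, 2 = cancer; labels may only occur inside
#'   the tissue mask.
#' @param specimen_id identifier used in tables and file names.
#' @param resolution micrometres per pixel (metadata only; slide scans in
#'   the motivating study were acquired at 0.441).
#' @return An object of class `specimen_image`.
#' @export
specimen_image <- function(pixels, tissue_mask = NULL, annotation_mask = NULL,
                           specimen_id = "specimen", resolution = 0.441) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L)
    abort_data("pixels must be an H x W x 3 array (specimen '%s')", specimen_id)
  storage.mode(pixels) <- "integer"
  if (any(pixels < 0L | pixels > 255L))
    abort_data("pixels must be 8-bit (0..255); refusing to rescale silently")
  if (is.null(tissue_mask)) tissue_mask <- compute_tissue_mask(pixels)
  if (!identical(dim(tissue_mask), d[1:2]))
    abort_data("tissue mask shape %s does not match image %s",
               paste(dim(tissue_mask), collapse = "x"),
               paste(d[1:2], collapse = "x"))
  tissue_mask <- matrix(as.logical(tissue_mask), d[1], d[2])
  if (!is.null(annotation_mask)) {
    if (!identical(dim(annotation_mask), d[1:2]))
      abort_data("annotation mask shape does not match image")
    storage.mode(annotation_mask) <- "integer"
    if (!all(annotation_mask %in% 0:2))
      abort_data("annotation mask values must be 0 (unlabeled), 1 (noncancer) or 2 (cancer)")
    if (any(annotation_mask > 0L & !tissue_mask))
      abort_data("annotation labels occur outside the tissue mask")
  }
  structure(list(pixels = pixels, tissue_mask = tissue_mask,
                 annotation_mask = annotation_mask,
                 specimen_id = as.character(specimen_id),
                 resolution = resolution),
            class = "specimen_image")
}

#' @export
print.specimen_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<specimen_image> '%s' %dx%d px, %.0f tissue px%s\n",
              x$specimen_id, d[1], d[2], sum(x$tissue_mask),
              if (is.null(x$annotation_mask)) "" else ", annotated"))
  invisible(x)
}

#' Compute a tissue mask from near-white background
#'
#' H&E background is near-white, so a pixel is tissue when its darkest
#' channel is at or below `white_threshold`. Connected components smaller
#' than `min_object_size` are removed and enclosed holes smaller than
#' `min_object_size` are filled (4-connectivity).
#'
#' @param pixels integer array `H x W x 3`, 0..255.
#' @param white_threshold gray level; default 230.
#' @param min_object_size pixels; default 64.
#' @return logical matrix `H x W`.
#' @export
compute_tissue_mask <- function(pixels, white_threshold = 230,
                                min_object_size = 64) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L) abort_data("pixels must be H x W x 3")
  mask <- pmin(pixels[, , 1], pixels[, , 2], pixels[, , 3]) <= white_threshold
  if (min_object_size > 1 && any(mask)) {
    lab <- label_components_cpp(mask)
    sizes <- tabulate(lab)
    small <- which(sizes < min_object_size)
    if (length(small)) mask[lab %in% small] <- FALSE
    # fill small enclosed holes: background components not touching a border
    if (any(!mask)) {
      bg <- label_components_cpp(!mask)
      border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
      bsz <- tabulate(bg)
      holes <- setdiff(which(bsz < min_object_size), border)
      if (length(holes)) mask[bg %in% holes] <- TRUE
    }
  }
  mask
}

#' Load a specimen from PNG files
#'
#' @param image_path path to an 8-bit RGB PNG.
#' @param tissue_mask_path optional 0/255 mask PNG; when absent the mask is
#'   computed with [compute_tissue_mask()] at its defaults.
#' @param annotation_mask_path optional PNG with values 0/1/2
#'   (unlabeled / noncancer / cancer).
#' @param specimen_id defaults to the image file name without extension.
#' @inheritParams specimen_image
#' @return A [specimen_image()].
#' @export
load_specimen <- function(image_path, tissue_mask_path = NULL,
                          annotation_mask_path = NULL,
                          specimen_id = NULL, resolution = 0.441) {
  px <- read_png(image_path)
  if (is.matrix(px) || dim(px)[3] < 3L)
    abort_data("'%s' is not an RGB image", image_path)
  if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]  # drop alpha
  tm <- if (!is.null(tissue_mask_path)) read_mask_png(tissue_mask_path)
  am <- if (!is.null(annotation_mask_path)) {
    a <- read_png(annotation_mask_path)
    if (!is.matrix(a)) abort_data("annotation mask must be single-channel")
    a
  }
  if (is.null(specimen_id))
    specimen_id <- tools::file_path_sans_ext(basename(image_path))
  specimen_image(px, tissue_mask = tm, annotation_mask = am,
                 specimen_id = specimen_id, resolution = resolution)
}

#' Write a specimen's rasters as PNG files
#'
#' @param specimen a [specimen_image()].
#' @param dir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
write_specimen <- function(specimen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- specimen$specimen_id
  paths <- c(image = file.path(dir, paste0(id, ".png")),
             tissue = file.path(dir, paste0(id, "_tissue.png")))
  write_png(specimen$pixels, paths[["image"]])
  write_mask_png(specimen$tissue_mask, paths[["tissue"]])
  if (!is.null(specimen$annotation_mask)) {
    paths[["annotation"]] <- file.path(dir, paste0(id, "_annotation.png"))
    write_png(specimen$annotation_mask, paths[["annotation"]])
  }
  invisible(paths)
}

#' Split a specimen into non-overlapping grid tiles
#'
#' Tiles are laid out on a regular grid from the top-left corner; edge tiles
#' may be smaller so that the grid covers the full raster. Tiles whose
#' tissue fraction falls below `min_tissue_fraction` are dropped from the
#' result (they are returned in the `"dropped"` attribute so the tiling is
#' auditable).
#'
#' @param specimen a [specimen_image()].
#' @param tile_size tile edge length in pixels; a value larger than the
#'   image yields a single whole-image tile.
#' @param min_tissue_fraction tiles with `mean(tissue) <` this are dropped.
#' @return list of `specimen_image` tiles, each with attributes
#'   `row_offset` / `col_offset` (1-based origin of the tile in the parent).
#' @export
tile_image <- function(specimen, tile_size, min_tissue_fraction = 0) {
  if (tile_size < 1) abort_config("tile_size must be >= 1")
  d <- dim(specimen$pixels)
  row_starts <- seq(1L, d[1], by = tile_size)
  col_starts <- seq(1L, d[2], by = tile_size)
  kept <- list(); dropped <- list()
  for (r0 in row_starts) for (c0 in col_starts) {
    r1 <- min(r0 + tile_size - 1L, d[1]); c1 <- min(c0 + tile_size - 1L, d[2])
    tm <- specimen$tissue_mask[r0:r1, c0:c1, drop = FALSE]
    am <- if (!is.null(specimen$annotation_mask))
      specimen$annotation_mask[r0:r1, c0:c1, drop = FALSE]
    tile <- specimen_image(specimen$pixels[r0:r1, c0:c1, , drop = FALSE],
                           tissue_mask = tm, annotation_mask = am,
                           specimen_id = sprintf("%s_r%d_c%d",
                                                 specimen$specimen_id, r0, c0),
                           resolution = specimen$resolution)
    attr(tile, "row_offset") <- r0
    attr(tile, "col_offset") <- c0
    if (mean(tm) >= min_tissue_fraction) kept[[length(kept) + 1L]] <- tile
    else dropped[[length(dropped) + 1L]] <- tile
  }
  attr(kept, "dropped") <- dropped
  kept
}
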