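#' Local entropy configuration
#'
#' Per-pixel Shannon entropy of the gray-value distribution inside the
#' `(2k+1) x (2k+1)` window centred on the pixel. The motivating study used
#' a window radius of k = 20 on raw 8-bit channels; entropy is reported in
#' bits (log base 2) by default.
#'
#' @param k window radius in pixels (>= 1).
#' @param log_base logarithm base; 2 gives bits.
#' @param levels number of gray levels (8-bit rasters: 256).
#' @param border `"clipped"` normalises border windows by their actual pixel
#'   count so edge tissue pixels still receive values; `"interior"` leaves
#'   pixels within `k` of the raster border undefined.
#' @param multiplicity evaluate the window sum over pixel coordinates
#'   (each value weighted by its occurrence count) instead of the standard
#'   entropy over distinct values. Off by default; provided for audit.
#' @return An object of class `entropy_config`.
#' @export
entropy_config <- function(k = 20, log_base = 2, levels = 256,
                           border = c("clipped", "interior"),
                           multiplicity = FALSE) {
  if (k < 1) abort_config("window radius k must be >= 1")
  if (levels < 2) abort_config("levels must be >= 2")
  structure(list(k = as.integer(k), log_base = log_base,
                 levels = as.integer(levels),
                 border = match.arg(border),
                 multiplicity = multiplicity),
            class = "entropy_config")
}

#' Local entropy at a single pixel
#'
#' Direct (histogram of the one clipped window) evaluation; the map
#' computation uses an incremental sliding histogram and must agree with
#' this definitional form exactly.
#'
#' @param channel_raster integer matrix of 8-bit values.
#' @param i,j 1-based pixel coordinates.
#' @param config an [entropy_config()].
#' @return entropy in units of `log_base`.
#' @export
entropy_at <- function(channel_raster, i, j, config = entropy_config()) {
  H <- nrow(channel_raster); W <- ncol(channel_raster)
  if (i < 1 || i > H || j < 1 || j > W)
    abort_data("pixel (%d, %d) outside a %d x %d raster", i, j, H, W)
  k <- config$k
  win <- channel_raster[max(1, i - k):min(H, i + k),
                        max(1, j - k):min(W, j + k)]
  counts <- tabulate(as.integer(win) + 1L, nbins = config$levels)
  p <- counts[counts > 0] / length(win)
  w <- if (config$multiplicity) counts[counts > 0] else 1
  -sum(w * p * log(p)) / log(config$log_base)
}

#' Per-channel local entropy maps of a specimen
#'
#' Evaluates [entropy_at()] (via a sliding-window histogram) at every tissue
#' pixel of each RGB channel.
#'
#' @param specimen a [specimen_image()].
#' @param config an [entropy_config()].
#' @return An object of class `entropy_map`: list with `values` (named list
#'   of `H x W` numeric matrices, `NA` outside the valid mask, for channels
#'   red/green/blue), `valid_mask` (tissue mask, intersected with the
#'   interior in `border = "interior"` mode) and the config.
#' @export
local_entropy_map <- function(specimen, config = entropy_config()) {
  stopifnot(inherits(specimen, "specimen_image"),
            inherits(config, "entropy_config"))
  mask <- specimen$tissue_mask
  if (!any(mask))
    warning(sprintf("specimen '%s' has an empty tissue mask",
                    specimen$specimen_id))
  valid <- mask
  if (config$border == "interior") {
    d <- dim(mask); k <- config$k
    interior <- matrix(FALSE, d[1], d[2])
    if (d[1] > 2 * k && d[2] > 2 * k)
      interior[(k + 1):(d[1] - k), (k + 1):(d[2] - k)] <- TRUE
    valid <- valid & interior
  }
  vals <- lapply(setNames(1:3, c("red", "green", "blue")), function(ch) {
    m <- local_entropy_sliding(specimen$pixels[, , ch], config$k,
                               config$multiplicity, config$log_base)
    m[!valid] <- NA_real_
    m
  })
  structure(list(values = vals, valid_mask = valid, config = config,
                 specimen_id = specimen$specimen_id),
            class = "entropy_map")
}

#' Flatten entropy maps to long-format per-pixel records
#'
#' One row per valid pixel and channel, carrying the region label used by
#' the cohort statistics. Region labels come either from the specimen's
#' annotation mask (`regions = "annotation"`) or from a caller-supplied
#' ternary matrix (0 unlabeled / 1 noncancer / 2 cancer), e.g. one derived
#' from cluster maps via [regions_from_clusters()].
#'
#' @param emap an `entropy_map` from [local_entropy_map()].
#' @param specimen the matching [specimen_image()].
#' @param regions `"annotation"` or an integer matrix.
#' @return data.frame with columns specimen_id, row, col, channel, entropy,
#'   region_class (`"cancer"`, `"noncancer"`, or `NA` when unlabeled).
#' @export
entropy_records <- function(emap, specimen, regions = "annotation") {
  stopifnot(inherits(emap, "entropy_map"))
  reg <- if (is.matrix(regions)) regions
  else if (identical(regions, "annotation")) {
    if (is.null(specimen$annotation_mask))
      abort_data("specimen '%s' has no annotation mask", specimen$specimen_id)
    specimen$annotation_mask
  } else abort_config("regions must be \"annotation\" or a matrix")
  idx <- which(emap$valid_mask, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  lin <- idx[, 1L] + (idx[, 2L] - 1L) * nrow(emap$valid_mask)
  lab <- c(NA, "noncancer", "cancer")[reg[lin] + 1L]
  do.call(rbind, lapply(names(emap$values), function(ch) {
    data.frame(specimen_id = emap$specimen_id,
               row = idx[, 1L], col = idx[, 2L], channel = ch,
               entropy = emap$values[[ch]][lin],
               region_class = lab, stringsAsFactors = FALSE)
  }))
}

#' Derive a ternary region mask from a cluster map
#'
#' Implements the transfer path in which cancer / noncancer region labels
#' for an unannotated cohort come from clusters selected by composition
#' ratio: pixels in `cancer_clusters` are labelled cancer, pixels in
#' `noncancer_clusters` noncancer, all other tissue pixels stay unlabeled.
#'
#' @param cluster_map a `cluster_map` from [predict_clusters()].
#' @param cancer_clusters,noncancer_clusters integer cluster IDs.
#' @return integer matrix with values 0/1/2.
#' @export
regions_from_clusters <- function(cluster_map, cancer_clusters,
                                  noncancer_clusters) {
  ids <- cluster_map$ids
  if (length(intersect(cancer_clusters, noncancer_clusters)))
    abort_config("cancer and noncancer cluster lists overlap")
  reg <- matrix(0L, nrow(ids), ncol(ids))
  reg[ids %in% noncancer_clusters] <- 1L
  reg[ids %in% cancer_clusters] <- 2L
  reg
}
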