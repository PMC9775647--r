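#' Multiscale basic feature configuration
#'
#' Per-pixel features for clustering: at every smoothing scale sigma and
#' every channel, the Gaussian-smoothed intensity, the Gaussian-gradient
#' magnitude (edges), and the two eigenvalues of the Gaussian-smoothed
#' Hessian (texture). Defaults mirror the configuration used in the
#' motivating study (intensity on, edges off, sigma 3..7, multichannel);
#' that study's parameter table is silent on the texture flag, so texture
#' is on by default and configurable.
#'
#' @param intensity include Gaussian-smoothed intensity features.
#' @param edges include gradient-magnitude features.
#' @param texture include the two Hessian eigenvalue features.
#' @param sigma_min,sigma_max smoothing-scale bounds in pixels.
#' @param multichannel compute features per RGB channel; when `FALSE` the
#'   image is collapsed to a single gray channel (channel mean).
#' @param standardize z-score each feature column over the tissue pixels
#'   (off by default: features are used raw).
#' @return An object of class `mbf_config`.
#' @export
mbf_config <- function(intensity = TRUE, edges = FALSE, texture = TRUE,
                       sigma_min = 3, sigma_max = 7, multichannel = TRUE,
                       standardize = FALSE) {
  if (!(sigma_min > 0 && sigma_min <= sigma_max))
    abort_config("need 0 < sigma_min <= sigma_max (got %s, %s)",
                 sigma_min, sigma_max)
  if (!any(intensity, edges, texture))
    abort_config("at least one of intensity/edges/texture must be enabled")
  structure(list(intensity = intensity, edges = edges, texture = texture,
                 sigma_min = sigma_min, sigma_max = sigma_max,
                 multichannel = multichannel, standardize = standardize),
            class = "mbf_config")
}

#' Geometric sigma ladder
#'
#' Log-evenly spaced scales from `sigma_min` to `sigma_max` inclusive, with
#' `floor(log2(sigma_max / sigma_min)) + 1` rungs (base-2 ladder, so e.g.
#' (1, 8) gives 1, 2, 4, 8 and (3, 7) gives 3, 7).
#'
#' @inheritParams mbf_config
#' @return numeric vector of sigmas.
#' @export
sigma_ladder <- function(sigma_min, sigma_max) {
  if (!(sigma_min > 0 && sigma_min <= sigma_max))
    abort_config("need 0 < sigma_min <= sigma_max")
  n <- floor(log2(sigma_max / sigma_min)) + 1
  if (n == 1) return(sigma_min)
  sigma_min * (sigma_max / sigma_min)^((seq_len(n) - 1) / (n - 1))
}

# sampled Gaussian kernel (order 0) or its 1st/2nd analytic derivative,
# truncated at 4 sigma; the order-0 kernel is normalised to sum 1
gaussian_kernel <- function(sigma, order = 0L) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  switch(as.character(order),
         "0" = g,
         "1" = -x / sigma^2 * g,  # antisymmetric: sums to zero exactly
         "2" = {
           k <- (x^2 - sigma^2) / sigma^4 * g
           k - sum(k) / length(k)  # truncation correction: constants vanish
         },
         abort_config("unsupported derivative order %s", order))
}

# Band matrix M such that M %*% v convolves v with `kernel` under
# symmetric (reflect, edge repeated) boundary handling.
conv_matrix <- function(kernel, n) {
  r <- (length(kernel) - 1L) %/% 2L
  M <- matrix(0, n, n)
  i <- seq_len(n)
  for (o in -r:r) {
    j <- i + o
    # reflect repeatedly (kernels can exceed tiny images)
    repeat {
      out_lo <- j < 1L; out_hi <- j > n
      if (!any(out_lo | out_hi)) break
      j[out_lo] <- 1L - j[out_lo]
      j[out_hi] <- 2L * n + 1L - j[out_hi]
    }
    idx <- cbind(i, j)
    M[idx] <- M[idx] + kernel[o + r + 1L]
  }
  M
}

# separable filtering: kernel of order `order_v` down columns,
# `order_h` along rows
gaussian_filter2d <- function(img, sigma, order_v = 0L, order_h = 0L) {
  kv <- conv_matrix(gaussian_kernel(sigma, order_v), nrow(img))
  kh <- conv_matrix(gaussian_kernel(sigma, order_h), ncol(img))
  kv %*% img %*% t(kh)
}

#' Extract multiscale basic features for tissue pixels
#'
#' @param specimen a [specimen_image()].
#' @param config an [mbf_config()].
#' @return An object of class `mbf_features`: list with `values`
#'   (tissue-pixels x features matrix), `pixel_index` (matrix of 1-based
#'   `(row, col)` in raster-scan order, i.e. row by row, left to right),
#'   `feature_names`, and the config. An empty tissue mask yields a
#'   0-row matrix with a warning.
#' @export
extract_mbf <- function(specimen, config = mbf_config()) {
  stopifnot(inherits(specimen, "specimen_image"),
            inherits(config, "mbf_config"))
  mask <- specimen$tissue_mask
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx)) idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  colnames(idx) <- c("row", "col")

  chans <- if (config$multichannel) {
    list(red = specimen$pixels[, , 1L] + 0,
         green = specimen$pixels[, , 2L] + 0,
         blue = specimen$pixels[, , 3L] + 0)
  } else {
    list(gray = (specimen$pixels[, , 1L] + specimen$pixels[, , 2L] +
                   specimen$pixels[, , 3L]) / 3)
  }
  sigmas <- sigma_ladder(config$sigma_min, config$sigma_max)
  lin <- idx[, "row"] + (idx[, "col"] - 1L) * nrow(mask)  # column-major offset

  cols <- list(); names_out <- character(0)
  for (ch in names(chans)) {
    img <- chans[[ch]]
    for (s in sigmas) {
      if (config$intensity) {
        cols[[length(cols) + 1L]] <- gaussian_filter2d(img, s)[lin]
        names_out <- c(names_out, sprintf("%s_s%g_intensity", ch, s))
      }
      if (config$edges) {
        gx <- gaussian_filter2d(img, s, 0L, 1L)
        gy <- gaussian_filter2d(img, s, 1L, 0L)
        cols[[length(cols) + 1L]] <- sqrt(gx^2 + gy^2)[lin]
        names_out <- c(names_out, sprintf("%s_s%g_edge", ch, s))
      }
      if (config$texture) {
        hxx <- gaussian_filter2d(img, s, 0L, 2L)
        hyy <- gaussian_filter2d(img, s, 2L, 0L)
        hxy <- gaussian_filter2d(img, s, 1L, 1L)
        disc <- sqrt(((hxx - hyy) / 2)^2 + hxy^2)
        mid <- (hxx + hyy) / 2
        cols[[length(cols) + 1L]] <- (mid + disc)[lin]
        cols[[length(cols) + 1L]] <- (mid - disc)[lin]
        names_out <- c(names_out,
                       sprintf("%s_s%g_hessian1", ch, s),
                       sprintf("%s_s%g_hessian2", ch, s))
      }
    }
  }
  values <- if (length(cols)) do.call(cbind, cols) else
    matrix(0, 0L, 0L)
  colnames(values) <- names_out
  if (nrow(idx) == 0L)
    warning(sprintf("specimen '%s' has an empty tissue mask; returning 0 rows",
                    specimen$specimen_id))
  if (config$standardize && nrow(values) > 1L) {
    mu <- colMeans(values)
    sdv <- apply(values, 2L, sd)
    sdv[sdv == 0] <- 1
    values <- sweep(sweep(values, 2L, mu), 2L, sdv, "/")
  }
  structure(list(values = values, pixel_index = idx,
                 feature_names = names_out, config = config,
                 specimen_id = specimen$specimen_id,
                 dim = dim(mask)),
            class = "mbf_features")
}
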