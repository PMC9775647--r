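#' Clustering configuration
#'
#' KMeans over pooled per-pixel feature vectors. The motivating study used
#' 30 clusters; initialisation and restart counts were unstated there, so
#' the defaults below (k-means++ with 10 restarts, 300 Lloyd iterations)
#' follow common practice and are fully seed-reproducible.
#'
#' @param n_clusters number of clusters (>= 1).
#' @param seed integer seed driving initialisation and subsampling.
#' @param n_init number of k-means++ restarts; best inertia kept.
#' @param max_iter Lloyd iteration cap per restart.
#' @param noise_clusters integer IDs excluded from composition ratios
#'   (the study excluded, by visual inspection, clusters consisting only of
#'   tissue edges; the list is authoritative configuration here, with
#'   [flag_edge_clusters()] as an optional heuristic).
#' @param max_pixels_per_image training subsample cap per image (seeded
#'   uniform sampling); pooling every pixel of large cohorts is
#'   memory-prohibitive.
#' @return An object of class `cluster_config`.
#' @export
cluster_config <- function(n_clusters = 30, seed = 1, n_init = 10,
                           max_iter = 300, noise_clusters = integer(0),
                           max_pixels_per_image = 200000) {
  if (n_clusters < 1) abort_config("n_clusters must be >= 1")
  if (length(noise_clusters) &&
      !all(noise_clusters %in% seq_len(n_clusters)))
    abort_config("noise_clusters must be cluster IDs in 1..n_clusters")
  structure(list(n_clusters = as.integer(n_clusters), seed = as.integer(seed),
                 n_init = as.integer(n_init), max_iter = as.integer(max_iter),
                 noise_clusters = as.integer(noise_clusters),
                 max_pixels_per_image = as.integer(max_pixels_per_image)),
            class = "cluster_config")
}

# squared Euclidean distances, n x k, via the expansion trick
dist2_to_centers <- function(X, C) {
  d <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * X %*% t(C)
  d[d < 0] <- 0
  d
}

# nearest-centroid assignment; ties broken by lowest cluster ID
assign_nearest <- function(X, C) {
  max.col(-dist2_to_centers(X, C), ties.method = "first")
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  pick <- sample.int(n, 1L)
  centers[1L, ] <- X[pick, ]
  if (k > 1L) {
    d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
    for (c in 2L:k) {
      pick <- if (sum(d2) > 0) sample.int(n, 1L, prob = d2)
      else sample.int(n, 1L)
      centers[c, ] <- X[pick, ]
      d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[c, ])^2))
    }
  }
  centers
}

# Lloyd's algorithm; empty clusters retain their previous centroid
lloyd_kmeans <- function(X, centers, max_iter) {
  assign <- assign_nearest(X, centers)
  for (it in seq_len(max_iter)) {
    sums <- rowsum(X, assign)
    counts <- tabulate(assign, nbins = nrow(centers))
    present <- counts > 0L
    centers[present, ] <- sums[as.character(which(present)), , drop = FALSE] /
      counts[present]
    new_assign <- assign_nearest(X, centers)
    if (identical(new_assign, assign)) break
    assign <- new_assign
  }
  inertia <- sum((X - centers[assign, , drop = FALSE])^2)
  list(centers = centers, assign = assign, inertia = inertia)
}

#' Fit a KMeans cluster model on pooled pixel features
#'
#' k-means++ initialisation with `n_init` restarts of Lloyd's algorithm;
#' the restart with the lowest inertia wins. Fully determined by
#' `config$seed`.
#'
#' @param feature_matrices an `mbf_features` object or list of them (one
#'   per training specimen); pixels beyond `max_pixels_per_image` per image
#'   are subsampled uniformly under the seed.
#' @param config a [cluster_config()].
#' @param training_cohort label stored in the model for provenance.
#' @return An object of class `cluster_model` with fields `centroids`
#'   (`n_clusters x features`), `mbf_config`, `cluster_config`,
#'   `feature_names`, `training_cohort`, `inertia`, and `assignments`
#'   (fit-time labels of the pooled training pixels).
#' @export
fit_cluster_model <- function(feature_matrices, config = cluster_config(),
                              training_cohort = "training") {
  if (inherits(feature_matrices, "mbf_features"))
    feature_matrices <- list(feature_matrices)
  stopifnot(all(vapply(feature_matrices, inherits, TRUE, "mbf_features")))
  fnames <- feature_matrices[[1L]]$feature_names
  mbf_cfg <- feature_matrices[[1L]]$config

  with_seed(config$seed, {
    pooled <- do.call(rbind, lapply(feature_matrices, function(fm) {
      if (!identical(fm$feature_names, fnames))
        abort_data("feature matrices have inconsistent feature sets")
      v <- fm$values
      if (nrow(v) > config$max_pixels_per_image)
        v <- v[sort(sample.int(nrow(v), config$max_pixels_per_image)), ,
               drop = FALSE]
      v
    }))
    if (nrow(pooled) < config$n_clusters)
      abort_config("pooled pixel count (%d) is below n_clusters (%d)",
                   nrow(pooled), config$n_clusters)
    best <- NULL
    for (r in seq_len(config$n_init)) {
      fit <- lloyd_kmeans(pooled, kmeanspp_init(pooled, config$n_clusters),
                          config$max_iter)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
    structure(list(centroids = best$centers, mbf_config = mbf_cfg,
                   cluster_config = config, feature_names = fnames,
                   training_cohort = training_cohort,
                   inertia = best$inertia, assignments = best$assign),
              class = "cluster_model")
  })
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> %d clusters x %d features, trained on '%s'\n",
              nrow(x$centroids), ncol(x$centroids), x$training_cohort))
  invisible(x)
}

#' Assign every tissue pixel of a specimen to its nearest centroid
#'
#' Features are extracted with the model's own feature configuration;
#' Euclidean metric, ties broken by lowest cluster ID.
#'
#' @param model a [fit_cluster_model()] result.
#' @param specimen a [specimen_image()].
#' @return An object of class `cluster_map`: `ids` (integer raster, 0
#'   outside tissue, 1..n_clusters inside) plus `specimen_id`.
#' @export
predict_clusters <- function(model, specimen) {
  stopifnot(inherits(model, "cluster_model"))
  fm <- extract_mbf(specimen, model$mbf_config)
  if (ncol(fm$values) != ncol(model$centroids))
    abort_data("feature dimension %d does not match model (%d)",
               ncol(fm$values), ncol(model$centroids))
  ids <- matrix(0L, fm$dim[1L], fm$dim[2L])
  if (nrow(fm$values))
    ids[fm$pixel_index] <- assign_nearest(fm$values, model$centroids)
  structure(list(ids = ids, specimen_id = specimen$specimen_id),
            class = "cluster_map")
}

#' Cluster composition ratio
#'
#' Fraction of tissue pixels (pooled over the supplied maps, noise clusters
#' excluded) assigned to each cluster; ratios over the non-noise clusters
#' sum to one.
#'
#' @param maps a `cluster_map` or list of them.
#' @param noise_clusters integer IDs dropped from numerator and denominator.
#' @param n_clusters total clusters in the model; defaults to the largest
#'   observed ID.
#' @return named numeric vector (names are cluster IDs) over the non-noise
#'   clusters.
#' @export
cluster_composition <- function(maps, noise_clusters = integer(0),
                                n_clusters = NULL) {
  if (inherits(maps, "cluster_map")) maps <- list(maps)
  ids <- unlist(lapply(maps, function(m) m$ids[m$ids > 0L]), use.names = FALSE)
  if (is.null(n_clusters)) n_clusters <- if (length(ids)) max(ids) else 0L
  counts <- tabulate(ids, nbins = n_clusters)
  keep <- setdiff(seq_len(n_clusters), noise_clusters)
  total <- sum(counts[keep])
  if (total == 0L)
    abort_data("all tissue pixels fall in noise clusters; composition undefined")
  setNames(counts[keep] / total, keep)
}

#' Cancerous / noncancerous composition per cluster
#'
#' For each cluster, among its pixels carrying an annotation label, the
#' fraction annotated cancer and noncancer. Unlabeled pixels are excluded
#' from the denominator; a cluster with no labeled pixels is reported as
#' undefined (`NA` fractions, `defined = FALSE`), not as zero.
#'
#' @param maps list of `cluster_map`s.
#' @param annotations aligned list of ternary annotation matrices
#'   (0 unlabeled / 1 noncancer / 2 cancer), e.g.
#'   `lapply(specimens, `[[`, "annotation_mask")`.
#' @param n_clusters total clusters; defaults to largest observed ID.
#' @return data.frame with columns cluster, n_labeled, cancer_fraction,
#'   noncancer_fraction, defined.
#' @export
cancer_fraction_per_cluster <- function(maps, annotations, n_clusters = NULL) {
  if (inherits(maps, "cluster_map")) maps <- list(maps)
  if (length(maps) != length(annotations))
    abort_data("need one annotation mask per cluster map")
  ids <- integer(0); lab <- integer(0)
  for (i in seq_along(maps)) {
    if (is.null(annotations[[i]]))
      abort_data("map %d has no annotation mask", i)
    sel <- maps[[i]]$ids > 0L & annotations[[i]] > 0L
    ids <- c(ids, maps[[i]]$ids[sel])
    lab <- c(lab, annotations[[i]][sel])
  }
  if (is.null(n_clusters))
    n_clusters <- max(c(1L, unlist(lapply(maps, function(m) max(m$ids)))))
  n_lab <- tabulate(ids, nbins = n_clusters)
  n_can <- tabulate(ids[lab == 2L], nbins = n_clusters)
  out <- data.frame(cluster = seq_len(n_clusters), n_labeled = n_lab,
                    cancer_fraction = ifelse(n_lab > 0, n_can / n_lab, NA_real_),
                    noncancer_fraction = ifelse(n_lab > 0,
                                                1 - n_can / n_lab, NA_real_),
                    defined = n_lab > 0)
  out
}

#' Clusters with the largest and smallest composition ratios
#'
#' Clusters are sorted by ratio, descending, ties broken by lower cluster
#' ID first; the first `top_k` and last `bottom_k` are returned.
#'
#' @param composition named ratio vector from [cluster_composition()].
#' @param top_k,bottom_k how many clusters from each end.
#' @return list with integer vectors `top` and `bottom`.
#' @export
select_extreme_clusters <- function(composition, top_k = 3, bottom_k = 3) {
  ids <- as.integer(names(composition))
  if (length(composition) < top_k + bottom_k)
    abort_config("composition has %d clusters; need >= top_k + bottom_k = %d",
                 length(composition), top_k + bottom_k)
  ord <- order(-composition, ids)
  sorted_ids <- ids[ord]
  list(top = utils::head(sorted_ids, top_k),
       bottom = utils::tail(sorted_ids, bottom_k))
}

# one step of binary erosion with a 3x3 cross
erode_once <- function(m) {
  n <- nrow(m); p <- ncol(m)
  m & rbind(FALSE, m[-n, , drop = FALSE]) &
    rbind(m[-1, , drop = FALSE], FALSE) &
    cbind(FALSE, m[, -p, drop = FALSE]) &
    cbind(m[, -1, drop = FALSE], FALSE)
}

#' Heuristic flagging of tissue-edge ("noise") clusters
#'
#' The motivating study excluded, by visual inspection, clusters consisting
#' only of tissue edges. This helper flags clusters whose pixels lie mostly
#' within a morphological edge band of the tissue mask; the configured
#' `noise_clusters` list remains authoritative.
#'
#' @param maps list of `cluster_map`s.
#' @param tissue_masks aligned list of logical tissue masks.
#' @param band_width band thickness in pixels (erosion steps).
#' @param min_fraction flag clusters with at least this fraction of their
#'   pixels inside the band.
#' @return integer vector of flagged cluster IDs.
#' @export
flag_edge_clusters <- function(maps, tissue_masks, band_width = 3,
                               min_fraction = 0.6) {
  if (inherits(maps, "cluster_map")) maps <- list(maps)
  n_clusters <- max(unlist(lapply(maps, function(m) max(m$ids))))
  in_band <- total <- numeric(n_clusters)
  for (i in seq_along(maps)) {
    core <- tissue_masks[[i]]
    for (b in seq_len(band_width)) core <- erode_once(core)
    band <- tissue_masks[[i]] & !core
    ids <- maps[[i]]$ids
    total <- total + tabulate(ids[ids > 0L], nbins = n_clusters)
    in_band <- in_band + tabulate(ids[ids > 0L & band], nbins = n_clusters)
  }
  which(total > 0 & in_band / pmax(total, 1) >= min_fraction)
}

#' Persist / restore a cluster model as a versioned JSON archive
#'
#' @param model a `cluster_model`.
#' @param path destination file.
#' @return `path` invisibly; `read_cluster_model()` returns the model.
#' @export
write_cluster_model <- function(model, path) {
  stopifnot(inherits(model, "cluster_model"))
  payload <- list(schema = "pixelhe-cluster-model/1",
                  training_cohort = model$training_cohort,
                  feature_names = model$feature_names,
                  mbf_config = unclass(model$mbf_config),
                  cluster_config = unclass(model$cluster_config),
                  inertia = model$inertia,
                  centroids = model$centroids)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_cluster_model
#' @export
read_cluster_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$schema, "pixelhe-cluster-model/1"))
    abort_data("'%s' is not a recognised cluster-model archive", path)
  structure(list(centroids = p$centroids,
                 mbf_config = structure(as.list(p$mbf_config),
                                        class = "mbf_config"),
                 cluster_config = structure(as.list(p$cluster_config),
                                            class = "cluster_config"),
                 feature_names = p$feature_names,
                 training_cohort = p$training_cohort,
                 inertia = p$inertia, assignments = NULL),
            class = "cluster_model")
}
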