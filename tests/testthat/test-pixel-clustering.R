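# minimal feature-matrix stand-in for clustering unit tests
make_fm <- function(values, dim = c(10, 10)) {
  colnames(values) <- paste0("f", seq_len(ncol(values)))
  n <- nrow(values)
  structure(list(values = values,
                 pixel_index = cbind(row = rep(1L, n), col = seq_len(n)),
                 feature_names = colnames(values), config = mbf_config(),
                 specimen_id = "fake", dim = dim),
            class = "mbf_features")
}

test_that("two well-separated masses are recovered exactly (ARI = 1)", {
  set.seed(11)
  lab <- rep(1:2, each = 100)
  X <- matrix(rnorm(400, sd = 0.2), 200, 2) + cbind(10 * (lab == 2), 0)
  m <- fit_cluster_model(make_fm(X), cluster_config(2, seed = 1, n_init = 3))
  expect_equal(adjusted_rand_index(m$assignments, lab), 1)
})

test_that("degenerate fit: identical pixels, one cluster", {
  X <- matrix(2.5, 50, 3)
  m <- fit_cluster_model(make_fm(X), cluster_config(1, seed = 1, n_init = 1))
  expect_equal(m$inertia, 0)
  expect_equal(unname(m$centroids[1, ]), rep(2.5, 3))
})

test_that("fit is deterministic under the seed and errors when overfull", {
  set.seed(12)
  X <- matrix(rnorm(300), 100, 3)
  cfg <- cluster_config(5, seed = 7, n_init = 2)
  m1 <- fit_cluster_model(make_fm(X), cfg)
  m2 <- fit_cluster_model(make_fm(X), cfg)
  expect_identical(m1$centroids, m2$centroids)
  expect_error(fit_cluster_model(make_fm(X[1:3, , drop = FALSE]), cfg),
               class = "pixelhe_config_error")
})

test_that("predict on a training specimen reproduces fit-time labels", {
  sp <- small_specimen()
  fm <- extract_mbf(sp)
  cfg <- cluster_config(6, seed = 3, n_init = 2,
                        max_pixels_per_image = 1e6)  # no subsampling
  m <- fit_cluster_model(fm, cfg)
  cm <- predict_clusters(m, sp)
  expect_identical(cm$ids[fm$pixel_index], m$assignments)
  expect_true(all(cm$ids[!sp$tissue_mask] == 0L))
  expect_true(all(cm$ids[sp$tissue_mask] >= 1L))
})

test_that("nearest-centroid assignment matches a brute-force oracle", {
  set.seed(13)
  C <- matrix(rnorm(30 * 18), 30, 18)
  X <- matrix(rnorm(1000 * 18), 1000, 18)
  got <- pixelhe:::assign_nearest(X, C)
  oracle <- apply(X, 1, function(x) {
    d <- colSums((t(C) - x)^2)
    which(d == min(d))[1]  # lowest ID on ties
  })
  expect_identical(got, unname(oracle))
  # a pixel exactly equal to a centroid is assigned to it
  expect_identical(pixelhe:::assign_nearest(C[17, , drop = FALSE], C), 17L)
})

test_that("composition ratios: counting, noise exclusion, oracle", {
  ids <- matrix(0L, 10, 10)
  ids[1:6, 1:10] <- 1L   # 60 px
  ids[7:10, 1:10] <- 2L  # 40 px
  cm <- structure(list(ids = ids, specimen_id = "x"), class = "cluster_map")
  expect_equal(cluster_composition(cm), c("1" = 0.6, "2" = 0.4))
  expect_equal(cluster_composition(cm, noise_clusters = 2, n_clusters = 2),
               c("1" = 1.0))
  expect_error(cluster_composition(cm, noise_clusters = 1:2, n_clusters = 2),
               class = "pixelhe_data_error")

  set.seed(14)
  rnd <- matrix(sample(0:5, 400, TRUE), 20, 20)
  cmr <- structure(list(ids = rnd, specimen_id = "r"), class = "cluster_map")
  comp <- cluster_composition(cmr, n_clusters = 5)
  counts <- table(factor(rnd[rnd > 0], levels = 1:5))
  expect_equal(unname(as.numeric(comp)),
               unname(as.numeric(counts / sum(counts))))
})

test_that("cancer fractions per cluster; zero-labeled clusters flagged", {
  ids <- matrix(0L, 4, 4); ids[1, ] <- 1L; ids[2, ] <- 2L; ids[3, ] <- 3L
  ann <- matrix(0L, 4, 4)
  ann[1, ] <- 2L                 # cluster 1 all cancer
  ann[2, 1:3] <- 1L; ann[2, 4] <- 2L  # cluster 2: 1 cancer / 3 noncancer
  # cluster 3 unlabeled
  cm <- structure(list(ids = ids, specimen_id = "x"), class = "cluster_map")
  cf <- cancer_fraction_per_cluster(list(cm), list(ann), n_clusters = 3)
  expect_equal(cf$cancer_fraction[1], 1)
  expect_equal(cf$noncancer_fraction[1], 0)
  expect_equal(cf$cancer_fraction[2], 0.25)
  expect_true(is.na(cf$cancer_fraction[3]) && !cf$defined[3])
})

test_that("extreme-cluster selection: order, ties, oracle", {
  comp <- c("1" = 0.5, "2" = 0.3, "3" = 0.2)
  sel <- select_extreme_clusters(comp, 2, 1)
  expect_identical(sel$top, c(1L, 2L))
  expect_identical(sel$bottom, 3L)

  tied <- setNames(rep(0.25, 4), c("4", "2", "3", "1"))
  sel2 <- select_extreme_clusters(tied, 2, 2)
  expect_identical(sel2$top, c(1L, 2L))   # ID ascending on ties
  expect_identical(sel2$bottom, c(3L, 4L))

  set.seed(15)
  comp3 <- setNames(runif(10), as.character(sample(10)))
  sel3 <- select_extreme_clusters(comp3, 3, 3)
  ord <- as.integer(names(sort(-comp3)))
  expect_identical(sel3$top, ord[1:3])
  expect_identical(sel3$bottom, ord[8:10])
  expect_error(select_extreme_clusters(comp, 2, 2),
               class = "pixelhe_config_error")
})

test_that("model archive round-trips and is byte-stable", {
  sp <- small_specimen()
  m <- fit_cluster_model(extract_mbf(sp), cluster_config(4, seed = 2,
                                                         n_init = 1))
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_cluster_model(m, f1); write_cluster_model(m, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  re <- read_cluster_model(f1)
  expect_equal(re$centroids, unname(m$centroids))
  expect_identical(re$feature_names, m$feature_names)
  expect_equal(re$cluster_config$n_clusters, 4L)
  # prediction with the restored model matches the original
  expect_identical(predict_clusters(re, sp)$ids, predict_clusters(m, sp)$ids)
})

test_that("edge-cluster heuristic flags a boundary-band cluster", {
  ids <- matrix(0L, 40, 40)
  tissue <- matrix(FALSE, 40, 40); tissue[5:36, 5:36] <- TRUE
  ids[tissue] <- 2L
  core <- tissue; for (i in 1:3) core <- pixelhe:::erode_once(core)
  ids[tissue & !core] <- 1L  # cluster 1 = pure edge band
  cm <- structure(list(ids = ids, specimen_id = "x"), class = "cluster_map")
  expect_identical(flag_edge_clusters(list(cm), list(tissue)), 1L)
})
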