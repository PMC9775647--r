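test_that("constant windows give zero entropy", {
  m <- matrix(128L, 30, 30)
  expect_identical(entropy_at(m, 15, 15, entropy_config(k = 5)), 0)
  sp <- specimen_image(array(128L, dim = c(30, 30, 3)),
                       tissue_mask = matrix(TRUE, 30, 30))
  em <- local_entropy_map(sp, entropy_config(k = 5))
  for (ch in em$values) expect_equal(max(abs(ch)), 0)
})

test_that("k=1 window of three equiprobable values gives log2(3)", {
  m <- matrix(c(0L, 0L, 0L, 85L, 85L, 85L, 170L, 170L, 170L), 3, 3)
  expect_equal(entropy_at(m, 2, 2, entropy_config(k = 1)), log2(3),
               tolerance = 1e-12)
})

test_that("entropy_at equals the integral-image oracle on random patches", {
  set.seed(6)
  for (rep in 1:3) {
    patch <- matrix(sample(0:255, 41 * 41, TRUE), 41, 41)
    for (k in c(1, 5)) {
      oracle <- oracle_entropy_map(patch, k)
      probe <- cbind(sample(41, 20, TRUE), sample(41, 20, TRUE))
      for (r in seq_len(nrow(probe)))
        expect_equal(entropy_at(patch, probe[r, 1], probe[r, 2],
                                entropy_config(k = k)),
                     oracle[probe[r, 1], probe[r, 2]], tolerance = 1e-9)
    }
  }
})

test_that("sliding map equals entropy_at looped over all pixels", {
  set.seed(7)
  px <- array(sample(0:255, 64 * 64 * 3, TRUE), dim = c(64, 64, 3))
  sp <- specimen_image(px, tissue_mask = matrix(TRUE, 64, 64))
  cfg <- entropy_config(k = 5)
  em <- local_entropy_map(sp, cfg)
  direct <- matrix(0, 64, 64)
  for (i in 1:64) for (j in 1:64)
    direct[i, j] <- entropy_at(px[, , 2], i, j, cfg)
  expect_equal(em$values$green, direct, tolerance = 1e-12)
})

test_that("bijective gray remapping leaves the map unchanged", {
  sp <- small_specimen()
  cfg <- entropy_config(k = 6)
  set.seed(10)
  perm <- sample(0:255)  # value permutation: histogram-preserving
  px2 <- sp$pixels
  px2[, , 1] <- matrix(perm[px2[, , 1] + 1L], nrow(px2), ncol(px2))
  sp2 <- specimen_image(px2, tissue_mask = sp$tissue_mask,
                        annotation_mask = sp$annotation_mask,
                        specimen_id = sp$specimen_id)
  e1 <- local_entropy_map(sp, cfg)$values$red
  e2 <- local_entropy_map(sp2, cfg)$values$red
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("values respect the per-pixel log2(window size) bound", {
  set.seed(8)
  px <- array(sample(0:255, 48 * 48 * 3, TRUE), dim = c(48, 48, 3))
  sp <- specimen_image(px, tissue_mask = matrix(TRUE, 48, 48))
  k <- 3
  em <- local_entropy_map(sp, entropy_config(k = k))
  rc <- pmin(1:48 + k, 48) - pmax(1:48 - k, 1) + 1
  nwin <- outer(rc, rc)
  bound <- log2(pmin(256, nwin))
  for (ch in em$values) expect_true(all(ch <= bound + 1e-12))
})

test_that("interior border mode drops pixels within k of the border", {
  sp <- small_specimen()
  k <- 8
  em <- local_entropy_map(sp, entropy_config(k = k, border = "interior"))
  expect_false(any(em$valid_mask[1:k, ]))
  expect_false(any(em$valid_mask[, 1:k]))
  expect_true(all(is.na(em$values$red[!em$valid_mask])))
  inner <- em$valid_mask
  expect_true(all(!is.na(em$values$red[inner])))
})

test_that("multiplicity mode matches the literal coordinate double sum", {
  set.seed(9)
  patch <- matrix(sample(0:8 * 30, 15 * 15, TRUE), 15, 15)
  k <- 2
  lit <- function(i, j) {
    win <- as.vector(patch[max(1, i - k):min(15, i + k),
                           max(1, j - k):min(15, j + k)])
    p <- vapply(win, function(v) mean(win == v), numeric(1))
    -sum(p * log2(p))  # one term per coordinate (l, m)
  }
  cfg <- entropy_config(k = k, multiplicity = TRUE)
  for (pt in list(c(3, 3), c(8, 8), c(1, 15)))
    expect_equal(entropy_at(patch, pt[1], pt[2], cfg), lit(pt[1], pt[2]),
                 tolerance = 1e-12)
  # and the sliding path agrees with entropy_at in this mode too
  sp <- specimen_image(array(rep(patch, 3), dim = c(15, 15, 3)),
                       tissue_mask = matrix(TRUE, 15, 15))
  em <- local_entropy_map(sp, cfg)
  expect_equal(em$values$red[8, 8], entropy_at(patch, 8, 8, cfg),
               tolerance = 1e-12)
})

test_that("entropy records carry region labels and skip unlabeled pixels", {
  sp <- small_specimen()
  em <- local_entropy_map(sp, entropy_config(k = 5))
  rec <- entropy_records(em, sp)
  expect_setequal(unique(rec$channel), c("red", "green", "blue"))
  expect_identical(nrow(rec), 3L * sum(sp$tissue_mask))
  expect_false(any(is.na(rec$region_class)))  # generator labels all tissue
  expect_error(entropy_records(em, specimen_image(sp$pixels,
                                                  tissue_mask = sp$tissue_mask)),
               class = "pixelhe_data_error")
})

test_that("out-of-raster queries and invalid configs error", {
  m <- matrix(0L, 5, 5)
  expect_error(entropy_at(m, 6, 1), class = "pixelhe_data_error")
  expect_error(entropy_config(k = 0), class = "pixelhe_config_error")
  expect_error(entropy_config(levels = 1), class = "pixelhe_config_error")
})
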