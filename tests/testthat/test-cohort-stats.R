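test_that("TNM triplets map through the configured stage table", {
  expect_identical(map_tnm_to_stage("T1", "N0", "M0"), "I")
  expect_identical(map_tnm_to_stage("T2", "N0", "M0"), "II")
  expect_identical(map_tnm_to_stage("T3", "N0", "M0"), "III")
  expect_identical(map_tnm_to_stage("T4", "N0", "M0"), "IV-A")
  expect_identical(map_tnm_to_stage("T1", "N1", "M0"), "IV-A")
  expect_identical(map_tnm_to_stage("T2", "N1", "M1"), "IV-B")  # M1 dominates
  expect_identical(map_tnm_to_stage(NA, "N0", "M0"), "Unknown")
  expect_identical(map_tnm_to_stage("T9", "N0", "M0"), "Unknown")
  # a swapped-in site-specific table is honoured
  custom <- data.frame(T = "T1", N = "N0", M = "M0", stage = "0")
  expect_identical(map_tnm_to_stage("T1", "N0", "M0", custom), "0")
  expect_identical(map_tnm_to_stage("T2", "N0", "M0", custom), "Unknown")
})

test_that("Welch t-test: closed forms and antisymmetry", {
  x <- c(5, 6, 7, 8)
  w0 <- welch_t_test(x, x)
  expect_equal(w0$t, 0)
  expect_equal(w0$p_value, 1)

  # hand-derived: a = 1,2,3 (mean 2, var 1), b = 2,4,6 (mean 4, var 4):
  # t = -2 / sqrt(1/3 + 4/3) = -1.549, df = (5/3)^2 / (17/18) = 50/17 = 2.941
  w <- welch_t_test(c(1, 2, 3), c(2, 4, 6))
  expect_equal(w$t, -1.549, tolerance = 5e-4)
  expect_equal(w$df, 2.941, tolerance = 5e-4)

  w_ba <- welch_t_test(c(2, 4, 6), c(1, 2, 3))
  expect_equal(w_ba$t, -w$t)
  expect_equal(w_ba$df, w$df)
  expect_error(welch_t_test(1, c(1, 2)), class = "pixelhe_data_error")
})

test_that("Welch agrees with the reference implementation on 100 pairs", {
  set.seed(16)
  for (i in 1:100) {
    a <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
    w <- welch_t_test(a, b)
    ref <- t.test(a, b)  # Welch by default
    expect_equal(w$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-9)
    expect_equal(w$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("entropy histogram: point mass, uniform midpoints, oracle", {
  edges <- seq(0, 8, length.out = 5)
  h1 <- entropy_histogram(rep(3.3, 10), edges)
  expect_equal(as.numeric(h1), c(0, 1, 0, 0))

  mids <- c(1, 3, 5, 7)
  h2 <- entropy_histogram(rep(mids, 25), edges)
  expect_equal(as.numeric(h2), rep(0.25, 4))
  expect_equal(sum(h2), 1, tolerance = 1e-9)

  set.seed(17)
  x <- runif(500, 0, 8)
  h3 <- entropy_histogram(x, edges)
  oracle <- as.numeric(table(cut(x, edges, include.lowest = TRUE))) / 500
  expect_equal(as.numeric(h3), oracle)

  expect_error(entropy_histogram(numeric(0)), class = "pixelhe_data_error")
  expect_message(h4 <- entropy_histogram(c(1, 9.5), edges), "clipped")
  expect_identical(attr(h4, "n_clipped"), 1L)
})

test_that("Jensen-Shannon divergence: identities and closed form", {
  expect_equal(jensen_shannon_divergence(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(jensen_shannon_divergence(c(1, 0), c(0, 1)), 1)
  # P = (1/2, 1/2), Q = (1, 0): M = (3/4, 1/4),
  # KL(P||M) = 0.20752, KL(Q||M) = 0.41504, JSD = 0.31128 bits
  expect_equal(jensen_shannon_divergence(c(0.5, 0.5), c(1, 0)), 0.31128,
               tolerance = 1e-5)
  expect_error(jensen_shannon_divergence(c(1, 0), c(0.5, 0.5, 0)),
               class = "pixelhe_data_error")
  expect_error(jensen_shannon_divergence(c(0.7, 0.7), c(1, 0)),
               class = "pixelhe_data_error")
})

test_that("JSD is symmetric, bounded, and zero iff P = Q", {
  set.seed(18)
  for (i in 1:25) {
    P <- runif(16); P <- P / sum(P)
    Q <- runif(16); Q <- Q / sum(Q)
    j1 <- jensen_shannon_divergence(P, Q)
    expect_equal(j1, jensen_shannon_divergence(Q, P), tolerance = 1e-12)
    expect_gte(j1, 0); expect_lte(j1, 1)
    expect_gt(j1, 1e-12)  # random P != Q
  }
})

# synthetic records with two specimens whose region areas differ 2:1
two_specimen_records <- function(area_a = 100, area_b = 200) {
  rec <- data.frame(
    specimen_id = rep(c("a", "b"), c(2 * area_a, 2 * area_b)),
    row = 1L, col = 1L,
    channel = "red",
    entropy = c(rep(1, area_a), rep(2, area_a), rep(3, area_b), rep(4, area_b)),
    region_class = c(rep("cancer", area_a), rep("noncancer", area_a),
                     rep("cancer", area_b), rep("noncancer", area_b)),
    stringsAsFactors = FALSE)
  cohort <- data.frame(specimen_id = c("a", "b"), cohort = "t",
                       T = "T1", N = "N0", M = "M0", stage = "I",
                       tissue_area_cancer = c(area_a, area_b),
                       tissue_area_noncancer = c(area_a, area_b),
                       stringsAsFactors = FALSE)
  list(rec = rec, cohort = cohort)
}

test_that("inverse-area weights equalise specimen contributions", {
  d <- two_specimen_records()
  rs <- area_weighted_resample(d$rec, d$cohort, n_draws = 10000, seed = 4)
  for (cl in c("cancer", "noncancer")) {
    frac_a <- mean(rs$specimen_id[rs$region_class == cl] == "a")
    se <- sqrt(0.25 / 10000)
    expect_lt(abs(frac_a - 0.5), 3 * se)
  }
})

test_that("resampling is seed-deterministic; n_draws = 0 gives empty set", {
  d <- two_specimen_records()
  r1 <- area_weighted_resample(d$rec, d$cohort, 500, seed = 9)
  r2 <- area_weighted_resample(d$rec, d$cohort, 500, seed = 9)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  r3 <- area_weighted_resample(d$rec, d$cohort, 500, seed = 10)
  expect_false(identical(r1$entropy, r3$entropy))
  r0 <- area_weighted_resample(d$rec, d$cohort, 0, seed = 9)
  expect_identical(nrow(r0), 0L)
})

test_that("empty strata and missing specimens are named errors", {
  d <- two_specimen_records()
  rec_no_cancer <- d$rec[d$rec$region_class != "cancer", ]
  expect_error(area_weighted_resample(rec_no_cancer, d$cohort, 10, seed = 1),
               "cancer", class = "pixelhe_data_error")
  rec_alien <- d$rec; rec_alien$specimen_id[1] <- "ghost"
  expect_error(area_weighted_resample(rec_alien, d$cohort, 10, seed = 1),
               "ghost", class = "pixelhe_data_error")
})

test_that("stage stratification drops Unknown and keeps strata exact", {
  d <- two_specimen_records()
  d$cohort$stage <- c("I", "Unknown")
  rs <- area_weighted_resample(d$rec, d$cohort, 300, seed = 2,
                               group_by = "stage")
  expect_true(all(rs$specimen_id == "a"))
  expect_identical(nrow(rs), 2L * 300L)  # 1 stage x 1 channel x 2 classes
})

test_that("stratum mean converges to the specimen-balanced mean", {
  d <- two_specimen_records()
  # balanced population mean of cancer entropies: (1 + 3) / 2 = 2
  r5 <- area_weighted_resample(d$rec, d$cohort, 1e5, seed = 3)
  x <- r5$entropy[r5$region_class == "cancer"]
  expect_lt(abs(mean(x) - 2), 4 * sd(x) / sqrt(length(x)))
  r3 <- area_weighted_resample(d$rec, d$cohort, 1e3, seed = 3)
  x3 <- r3$entropy[r3$region_class == "cancer"]
  expect_lt(abs(mean(x3) - 2), 4 * sd(x3) / sqrt(length(x3)))
})

test_that("per-specimen-stratified mode allocates draws equally", {
  d <- two_specimen_records()
  rs <- area_weighted_resample(d$rec, d$cohort, 1000, seed = 5,
                               per_specimen_stratified = TRUE)
  frac_a <- mean(rs$specimen_id[rs$region_class == "cancer"] == "a")
  expect_equal(frac_a, 0.5)
})

test_that("compare_regions reports all groups and flags incomplete ones", {
  d <- two_specimen_records()
  rs <- area_weighted_resample(d$rec, d$cohort, 400, seed = 6)
  rep1 <- compare_regions(rs, "none")
  expect_identical(nrow(rep1), 1L)
  expect_false(rep1$flagged)
  expect_true(rep1$t < 0)  # cancer entropies {1,3} < noncancer {2,4}

  # a group missing one class is flagged; the other group still reported
  df <- as.data.frame(rs)
  df$stage <- "I"
  extra <- df[df$region_class == "cancer", ][1:10, ]
  extra$stage <- "IV-B"
  rep2 <- compare_regions(rbind(df, extra), "stage")
  expect_identical(nrow(rep2), 2L)
  expect_true(rep2$flagged[rep2$group == "IV-B"])
  expect_false(rep2$flagged[rep2$group == "I"])
})
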