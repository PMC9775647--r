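# Independent oracles and shared fixtures for the test suite.

# Local-entropy oracle via integral-image counting: for each gray value v,
# a summed-area table of the indicator image gives the exact window count
# at every pixel; entropy follows from the 256 count planes. Entirely
# different algorithm from the sliding-histogram implementation.
oracle_entropy_map <- function(img, k, log_base = 2) {
  H <- nrow(img); W <- ncol(img)
  i_mat <- row(matrix(0, H, W)); j_mat <- col(matrix(0, H, W))
  r0 <- pmax(i_mat - k, 1); r1 <- pmin(i_mat + k, H)
  c0 <- pmax(j_mat - k, 1); c1 <- pmin(j_mat + k, W)
  nwin <- (r1 - r0 + 1) * (c1 - c0 + 1)
  at <- function(S, r, c) S[cbind(as.vector(r), as.vector(c))]
  Lr <- matrix(as.numeric(row(diag(H)) >= col(diag(H))), H, H)
  Lc <- matrix(as.numeric(row(diag(W)) >= col(diag(W))), W, W)
  acc <- numeric(H * W)
  for (v in sort(unique(as.vector(img)))) {
    ind <- matrix(as.numeric(img == v), H, W)
    S <- matrix(0, H + 1, W + 1)
    S[-1, -1] <- Lr %*% ind %*% t(Lc)  # summed-area table by matmul
    cnt <- at(S, r1 + 1, c1 + 1) - at(S, r0, c1 + 1) -
      at(S, r1 + 1, c0) + at(S, r0, c0)
    p <- cnt / as.vector(nwin)
    nz <- p > 0
    acc[nz] <- acc[nz] - p[nz] * log(p[nz])
  }
  matrix(acc / log(log_base), H, W)
}

# adjusted Rand index from the contingency table (closed form)
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  s_ij <- sum(comb2(tab))
  s_a <- sum(comb2(rowSums(tab)))
  s_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- s_a * s_b / n2
  (s_ij - expected) / ((s_a + s_b) / 2 - expected)
}

# memoised fixtures shared across test files
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

small_specimen <- function() fixture("small_specimen", function() {
  generate_specimen(synthetic_spec(image_size = c(96, 96), seed = 42),
                    specimen_id = "fix96")
})

# small two-cohort world for statistics tests: strong entropy contrast,
# annotated ground truth, stages I and IV-B
stats_cohort <- function() fixture("stats_cohort", function() {
  generate_cohort(
    6, c(I = 0.5, `IV-B` = 0.5), cohort_label = "stats", seed = 77,
    base_spec = synthetic_spec(image_size = c(128, 128),
                               cancer_fraction = 0.5))
})

cohort_entropy_records <- function() fixture("cohort_entropy_records", function() {
  co <- stats_cohort()
  do.call(rbind, lapply(co$specimens, function(sp) {
    entropy_records(local_entropy_map(sp, entropy_config(k = 10)), sp)
  }))
})
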