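#' Default TNM-to-stage table (UICC 7th edition, intrahepatic bile duct)
#'
#' The stage table is configuration, not code: site-specific rules differ,
#' so any data.frame with columns `T`, `N`, `M`, `stage` can replace it.
#' The default enumerates all (T1..T4) x (N0, N1) x (M0, M1) combinations
#' under the rules: M1 is stage IV-B; otherwise T4 or N1 is IV-A; otherwise
#' T3 is III, T2 is II, T1 is I.
#'
#' @return data.frame with columns T, N, M, stage.
#' @export
default_stage_table <- function() {
  g <- expand.grid(T = paste0("T", 1:4), N = c("N0", "N1"),
                   M = c("M0", "M1"), stringsAsFactors = FALSE)
  g$stage <- ifelse(g$M == "M1", "IV-B",
                    ifelse(g$T == "T4" | g$N == "N1", "IV-A",
                           ifelse(g$T == "T3", "III",
                                  ifelse(g$T == "T2", "II", "I"))))
  g
}

#' Map TNM triplets to a cancer stage
#'
#' Exact lookup in the stage table; any missing or unrecognised component
#' yields `"Unknown"` (never an error), matching the handling of
#' unlabelled microarray specimens.
#'
#' @param T,N,M character vectors (recycled to common length); `NA` allowed.
#' @param stage_table see [default_stage_table()].
#' @return character vector of stages.
#' @export
map_tnm_to_stage <- function(T, N, M, stage_table = default_stage_table()) {
  n <- max(length(T), length(N), length(M))
  T <- rep_len(as.character(T), n)
  N <- rep_len(as.character(N), n)
  M <- rep_len(as.character(M), n)
  key <- paste(T, N, M, sep = "|")
  tab <- setNames(stage_table$stage,
                  paste(stage_table$T, stage_table$N, stage_table$M,
                        sep = "|"))
  out <- unname(tab[key])
  out[is.na(out)] <- "Unknown"
  out
}

#' Area-weighted resampling of per-pixel entropies
#'
#' Tissue-slice areas differ between specimens, so pixel entropies are
#' resampled with replacement using the inverse of the specimen's region
#' area as the weight: each specimen's region then contributes equal
#' expected total weight to its stratum. A stratum is a region class
#' (cancer / noncancer) by channel combination, additionally split by stage
#' when `group_by = "stage"`; each stratum receives exactly `n_draws`
#' draws. Specimens with stage "Unknown" are excluded from stage-stratified
#' sets.
#'
#' @param entropy_records long-format records from [entropy_records()]
#'   (rows with `NA` region class are ignored).
#' @param cohort cohort metadata data.frame with columns specimen_id,
#'   stage, tissue_area_cancer, tissue_area_noncancer.
#' @param n_draws draws per stratum (the motivating study used 100,000).
#' @param seed integer seed; same seed reproduces the draws exactly.
#' @param group_by `"none"` (pool all stages) or `"stage"`.
#' @param per_specimen_stratified alternative interpretation of "resampled
#'   equally from each specimen": allocate `n_draws` equally across the
#'   stratum's specimens and sample uniformly within each. Coincides in
#'   expectation with the weighted pool (the default).
#' @return An object of class `resampled_entropy`: data.frame with columns
#'   entropy, channel, region_class, stage, specimen_id, plus attributes
#'   `n_draws`, `seed`, `group_by`.
#' @export
area_weighted_resample <- function(entropy_records, cohort,
                                   n_draws = 100000, seed = 1,
                                   group_by = c("none", "stage"),
                                   per_specimen_stratified = FALSE) {
  group_by <- match.arg(group_by)
  rec <- entropy_records[!is.na(entropy_records$region_class), , drop = FALSE]
  miss <- setdiff(unique(rec$specimen_id), cohort$specimen_id)
  if (length(miss))
    abort_data("specimens missing from the cohort table: %s",
               paste(miss, collapse = ", "))
  ci <- match(rec$specimen_id, cohort$specimen_id)
  rec$stage <- cohort$stage[ci]
  area <- ifelse(rec$region_class == "cancer",
                 cohort$tissue_area_cancer[ci],
                 cohort$tissue_area_noncancer[ci])
  if (any(area <= 0))
    abort_data("specimen region with labelled pixels but non-positive area")
  rec$weight <- 1 / area
  if (group_by == "stage") rec <- rec[rec$stage != "Unknown", , drop = FALSE]

  groups <- if (group_by == "stage") sort(unique(rec$stage)) else "all"
  channels <- sort(unique(rec$channel))
  classes <- c("cancer", "noncancer")
  out <- list()
  with_seed(seed, {
    for (g in groups) for (ch in channels) for (cl in classes) {
      sel <- which(rec$channel == ch & rec$region_class == cl &
                     (group_by == "none" | rec$stage == g))
      if (n_draws == 0) next
      if (!length(sel))
        abort_data("no eligible pixels in stratum (%s, %s, %s)", g, ch, cl)
      sub <- rec[sel, , drop = FALSE]
      draw <- if (per_specimen_stratified) {
        ids <- sort(unique(sub$specimen_id))
        per <- rep(n_draws %/% length(ids), length(ids))
        add <- n_draws - sum(per)
        if (add > 0) per[seq_len(add)] <- per[seq_len(add)] + 1
        unlist(lapply(seq_along(ids), function(k) {
          pool <- which(sub$specimen_id == ids[k])
          pool[sample.int(length(pool), per[k], replace = TRUE)]
        }))
      } else {
        sample.int(nrow(sub), n_draws, replace = TRUE, prob = sub$weight)
      }
      out[[length(out) + 1L]] <-
        data.frame(entropy = sub$entropy[draw], channel = ch,
                   region_class = cl, stage = if (group_by == "stage") g
                   else sub$stage[draw],
                   specimen_id = sub$specimen_id[draw],
                   stringsAsFactors = FALSE)
    }
  })
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(entropy = numeric(0), channel = character(0),
               region_class = character(0), stage = character(0),
               specimen_id = character(0))
  structure(res, class = c("resampled_entropy", "data.frame"),
            n_draws = n_draws, seed = seed, group_by = group_by)
}

#' Welch's two-sample t-test
#'
#' `t = (mean_a - mean_b) / sqrt(s2_a/n_a + s2_b/n_b)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value from the
#' t distribution. Implemented directly (and cross-checked against
#' `stats::t.test` in the test suite) because it is the comparison the
#' entropy analysis reports.
#'
#' @param sample_a,sample_b numeric vectors with at least 2 values each.
#' @return list with `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
welch_t_test <- function(sample_a, sample_b) {
  na <- length(sample_a); nb <- length(sample_b)
  if (na < 2 || nb < 2)
    abort_data("both samples need >= 2 values (got %d and %d)", na, nb)
  va <- stats::var(sample_a); vb <- stats::var(sample_b)
  ma <- mean(sample_a); mb <- mean(sample_b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    t <- if (ma == mb) 0 else sign(ma - mb) * Inf
    df <- na + nb - 2
  } else {
    t <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  list(t = t, df = df, p_value = 2 * pt(-abs(t), df),
       mean_a = ma, mean_b = mb)
}

#' Normalised histogram of entropy draws
#'
#' @param draws numeric vector (non-empty).
#' @param bin_edges strictly increasing edges; values outside are clipped
#'   into the end bins and the clipped count recorded in the `n_clipped`
#'   attribute.
#' @return probability vector of length `length(bin_edges) - 1`, summing
#'   to 1.
#' @export
entropy_histogram <- function(draws, bin_edges = seq(0, 8, length.out = 65)) {
  if (!length(draws)) abort_data("cannot build a histogram from zero draws")
  if (any(diff(bin_edges) <= 0))
    abort_config("bin_edges must be strictly increasing")
  lo <- bin_edges[1L]; hi <- bin_edges[length(bin_edges)]
  n_clipped <- sum(draws < lo | draws > hi)
  x <- pmin(pmax(draws, lo), hi)
  bin <- findInterval(x, bin_edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(bin, nbins = length(bin_edges) - 1L)
  if (n_clipped > 0)
    message(sprintf("entropy_histogram: %d draws outside [%g, %g] clipped",
                    n_clipped, lo, hi))
  structure(counts / length(draws), n_clipped = n_clipped)
}

#' Jensen-Shannon divergence between two probability vectors
#'
#' `JSD = KL(P||M)/2 + KL(Q||M)/2` with `M = (P + Q)/2`, log base 2 and
#' `0 log 0 := 0`, so the result lies in `[0, 1]` bits: near zero for
#' similar distributions, 1 for disjoint supports.
#'
#' @param P,Q nonnegative vectors of equal length, each summing to 1
#'   (tolerance 1e-9).
#' @return divergence in bits.
#' @export
jensen_shannon_divergence <- function(P, Q) {
  if (length(P) != length(Q))
    abort_data("P and Q must have the same length")
  if (any(P < 0) || any(Q < 0) ||
      abs(sum(P) - 1) > 1e-9 || abs(sum(Q) - 1) > 1e-9)
    abort_data("P and Q must be probability vectors summing to 1")
  M <- (P + Q) / 2
  kl <- function(A) {
    nz <- A > 0
    sum(A[nz] * log2(A[nz] / M[nz]))
  }
  max(0, (kl(P) + kl(Q)) / 2)
}

#' Compare entropy distributions of cancer vs noncancer regions
#'
#' Per channel (and per stage when grouped): Welch test of cancer minus
#' noncancer, both normalised histograms, and the Jensen-Shannon
#' divergence between them. A group missing one region class is flagged
#' (`flagged = TRUE`, `NA` statistics); the remaining groups are still
#' reported.
#'
#' @param resampled a [area_weighted_resample()] result (or any data.frame
#'   with entropy, channel, region_class, stage columns).
#' @param group_by `"none"` or `"stage"`.
#' @param bin_edges histogram binning shared by both distributions; JSD
#'   magnitudes depend on it, so it is exposed rather than hidden.
#' @return data.frame with columns group, channel, n_cancer, n_noncancer,
#'   mean_cancer, mean_noncancer, t, df, p, jsd, flagged; the per-group
#'   histograms are attached as the `"histograms"` attribute.
#' @export
compare_regions <- function(resampled, group_by = c("none", "stage"),
                            bin_edges = seq(0, 8, length.out = 65)) {
  group_by <- match.arg(group_by)
  df <- as.data.frame(resampled)
  df$group <- if (group_by == "stage") df$stage else "all"
  rows <- list(); hists <- list()
  for (g in sort(unique(df$group))) for (ch in sort(unique(df$channel))) {
    ca <- df$entropy[df$group == g & df$channel == ch &
                       df$region_class == "cancer"]
    nc <- df$entropy[df$group == g & df$channel == ch &
                       df$region_class == "noncancer"]
    if (length(ca) < 2 || length(nc) < 2) {
      rows[[length(rows) + 1L]] <-
        data.frame(group = g, channel = ch, n_cancer = length(ca),
                   n_noncancer = length(nc), mean_cancer = NA_real_,
                   mean_noncancer = NA_real_, t = NA_real_, df = NA_real_,
                   p = NA_real_, jsd = NA_real_, flagged = TRUE,
                   stringsAsFactors = FALSE)
      next
    }
    w <- welch_t_test(ca, nc)
    h_ca <- entropy_histogram(ca, bin_edges)
    h_nc <- entropy_histogram(nc, bin_edges)
    hists[[paste(g, ch, sep = ".")]] <-
      list(cancer = h_ca, noncancer = h_nc, bin_edges = bin_edges)
    rows[[length(rows) + 1L]] <-
      data.frame(group = g, channel = ch, n_cancer = length(ca),
                 n_noncancer = length(nc), mean_cancer = w$mean_a,
                 mean_noncancer = w$mean_b, t = w$t, df = w$df,
                 p = w$p_value,
                 jsd = jensen_shannon_divergence(as.numeric(h_ca),
                                                 as.numeric(h_nc)),
                 flagged = FALSE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "histograms") <- hists
  out
}
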