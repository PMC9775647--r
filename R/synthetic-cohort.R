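#' Specification for one synthetic H&E-like specimen
#'
#' The generator paints an irregular tissue blob on a near-white background
#' and splits it into a cancer-like and a noncancer-like region, each
#' textured by smoothed per-channel Gaussian noise added to an H&E-like
#' base colour. Local entropy responds directly to local value diversity,
#' so the amplitude gap between the two regions controls the entropy
#' contrast every downstream stage is tested against.
#'
#' @param image_size `c(height, width)` in pixels.
#' @param cancer_fraction fraction of the tissue area carrying the
#'   cancer-like texture, in `[0, 1]`.
#' @param texture_amplitude_cancer,texture_amplitude_noncancer noise
#'   standard deviation in gray levels (after smoothing, renormalised).
#' @param texture_scale_cancer,texture_scale_noncancer smoothing sigma of
#'   the texture noise in pixels (>= 1); finer scale = busier texture.
#' @param base_color_cancer RGB triplet, hematoxylin-dense dark purple.
#' @param base_color_noncancer RGB triplet, eosin-dominant stroma pink.
#' @param background_color RGB triplet, near-white.
#' @param macro_amplitude amplitude (gray levels) of a shared macro-scale
#'   staining-heterogeneity field added to both region classes. Real tissue
#'   varies smoothly in stain uptake; without this shared component the
#'   whole noncancer class collapses into a single tight feature-space
#'   cloud, which no stained section does. The field is near-constant
#'   within a local-entropy window, so it leaves the entropy contrast to
#'   the fine-texture amplitudes.
#' @param macro_scale smoothing sigma of that field; default
#'   `min(image_size) / 5`.
#' @param tnm character vector `c(T, N, M)`; `NA`s mean missing.
#' @param seed integer; identical spec + seed gives bit-identical output.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(image_size = c(256, 256), cancer_fraction = 0.5,
                           texture_amplitude_cancer = 60,
                           texture_amplitude_noncancer = 10,
                           texture_scale_cancer = 1.5,
                           texture_scale_noncancer = 3,
                           base_color_cancer = c(110, 70, 150),
                           base_color_noncancer = c(230, 170, 195),
                           background_color = c(247, 245, 246),
                           macro_amplitude = 18, macro_scale = NULL,
                           tnm = c(NA, NA, NA), seed = 1) {
  if (!is.numeric(cancer_fraction) || cancer_fraction < 0 ||
      cancer_fraction > 1)
    abort_config("cancer_fraction must lie in [0, 1]")
  if (texture_amplitude_cancer < 0 || texture_amplitude_noncancer < 0)
    abort_config("texture amplitudes must be >= 0")
  if (texture_scale_cancer < 1 || texture_scale_noncancer < 1)
    abort_config("texture scales must be >= 1 pixel")
  structure(list(image_size = as.integer(image_size),
                 cancer_fraction = cancer_fraction,
                 texture_amplitude_cancer = texture_amplitude_cancer,
                 texture_amplitude_noncancer = texture_amplitude_noncancer,
                 texture_scale_cancer = texture_scale_cancer,
                 texture_scale_noncancer = texture_scale_noncancer,
                 base_color_cancer = base_color_cancer,
                 base_color_noncancer = base_color_noncancer,
                 background_color = background_color,
                 macro_amplitude = macro_amplitude,
                 macro_scale = if (is.null(macro_scale))
                   min(image_size) / 5 else macro_scale,
                 tnm = as.character(tnm), seed = as.integer(seed)),
            class = "synthetic_spec")
}

# unit-variance smoothed Gaussian noise field
smooth_noise_field <- function(h, w, scale) {
  f <- gaussian_filter2d(matrix(rnorm(h * w), h, w), scale)
  f / sd(f)
}

#' Generate one synthetic specimen
#'
#' Geometry: the tissue blob thresholds a radial-bias-plus-smoothed-noise
#' field (irregular margins, no straight edges); the cancer subregion
#' thresholds a second field seeded at a random interior point at exactly
#' the `cancer_fraction` quantile of tissue pixels, so masks are ground
#' truth by construction.
#'
#' @param spec a [synthetic_spec()].
#' @param specimen_id identifier for the result.
#' @return A [specimen_image()] with exact tissue and annotation masks.
#' @export
generate_specimen <- function(spec, specimen_id = "synthetic") {
  stopifnot(inherits(spec, "synthetic_spec"))
  h <- spec$image_size[1L]; w <- spec$image_size[2L]
  with_seed(spec$seed, {
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    radial <- sqrt(((rows - (h + 1) / 2) / h)^2 +
                     ((cols - (w + 1) / 2) / w)^2)
    blob_field <- radial / max(radial) +
      0.12 * smooth_noise_field(h, w, max(2, min(h, w) / 6))
    tissue <- blob_field <= quantile(blob_field, 0.72)

    tiss_idx <- which(tissue, arr.ind = TRUE)
    seed_px <- tiss_idx[sample.int(nrow(tiss_idx), 1L), ]
    gfield <- sqrt(((rows - seed_px[1L]) / h)^2 +
                     ((cols - seed_px[2L]) / w)^2) +
      0.12 * smooth_noise_field(h, w, max(2, min(h, w) / 6))
    cf <- spec$cancer_fraction
    cancer <- if (cf == 0) tissue & FALSE
    else if (cf == 1) tissue
    else tissue & gfield <= quantile(gfield[tissue], cf)

    annotation <- matrix(0L, h, w)
    annotation[tissue] <- 1L
    annotation[cancer] <- 2L

    px <- array(0, dim = c(h, w, 3L))
    for (ch in 1:3) {
      layer <- matrix(spec$background_color[ch], h, w) +
        1.5 * smooth_noise_field(h, w, 2)
      nc_tex <- smooth_noise_field(h, w, spec$texture_scale_noncancer)
      ca_tex <- smooth_noise_field(h, w, spec$texture_scale_cancer)
      macro <- if (spec$macro_amplitude > 0)
        spec$macro_amplitude * smooth_noise_field(h, w, spec$macro_scale)
      else matrix(0, h, w)
      layer[tissue] <- spec$base_color_noncancer[ch] + macro[tissue] +
        spec$texture_amplitude_noncancer * nc_tex[tissue]
      layer[cancer] <- spec$base_color_cancer[ch] + macro[cancer] +
        spec$texture_amplitude_cancer * ca_tex[cancer]
      px[, , ch] <- pmin(pmax(round(layer), 0), 255)
    }
    specimen_image(px, tissue_mask = tissue, annotation_mask = annotation,
                   specimen_id = specimen_id)
  })
}

# largest-remainder apportionment of n among proportions p (ties: earlier
# entries first)
apportion_counts <- function(p, n) {
  raw <- p * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(-(raw - base), seq_along(p))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a synthetic cohort with TNM metadata
#'
#' Produces `n_specimens` specimens whose TNM triplets realise the
#' requested stage distribution as closely as integer counts allow
#' (largest-remainder apportionment), plus an exact
#' `round(n * unknown_fraction)` specimens with missing TNM (stage
#' "Unknown"). For each staged specimen a TNM triplet is drawn uniformly
#' from the stage table rows mapping to its stage, and specimen order is
#' shuffled, so different seeds give different TNM orderings but identical
#' stage counts.
#'
#' @param n_specimens cohort size (>= 1).
#' @param stage_distribution named proportions over stages (must sum to 1);
#'   names from `I, II, III, IV-A, IV-B`.
#' @param cohort_label label recorded in the metadata (e.g. `"mouse"`).
#' @param seed integer master seed; per-specimen seeds derive from it.
#' @param unknown_fraction fraction of specimens given missing TNM.
#' @param base_spec a [synthetic_spec()] used as template for every
#'   specimen (its `seed` and `tnm` are overridden).
#' @param noncancer_amplitude_by_stage optional named numeric vector
#'   overriding the noncancer texture amplitude per stage; lets late-stage
#'   noncancer entropy distributions be shifted relative to early stages.
#' @param stage_table mapping used to pick TNM triplets; see
#'   [default_stage_table()].
#' @return list with `specimens` (list of [specimen_image()]) and `table`
#'   (data.frame: specimen_id, cohort, T, N, M, stage,
#'   tissue_area_cancer, tissue_area_noncancer).
#' @export
generate_cohort <- function(n_specimens,
                            stage_distribution = c(I = 0.3, II = 0.25,
                                                   III = 0.2, `IV-A` = 0.15,
                                                   `IV-B` = 0.1),
                            cohort_label = "cohort", seed = 1,
                            unknown_fraction = 0,
                            base_spec = synthetic_spec(),
                            noncancer_amplitude_by_stage = NULL,
                            stage_table = default_stage_table()) {
  if (n_specimens < 1) abort_config("n_specimens must be >= 1")
  if (abs(sum(stage_distribution) - 1) > 1e-9)
    abort_config("stage_distribution proportions must sum to 1")
  n_unknown <- round(n_specimens * unknown_fraction)
  n_staged <- n_specimens - n_unknown
  counts <- apportion_counts(stage_distribution, n_staged)

  with_seed(seed, {
    stages <- c(rep(names(stage_distribution), counts),
                rep("Unknown", n_unknown))
    stages <- sample(stages)  # shuffle specimen order
    tnm <- t(vapply(stages, function(s) {
      if (s == "Unknown") return(c(NA_character_, NA_character_,
                                   NA_character_))
      rows <- stage_table[stage_table$stage == s, , drop = FALSE]
      if (!nrow(rows))
        abort_config("stage '%s' has no TNM triplet in the stage table", s)
      r <- rows[sample.int(nrow(rows), 1L), ]
      c(r$T, r$N, r$M)
    }, character(3)))

    specimens <- vector("list", n_specimens)
    meta <- vector("list", n_specimens)
    for (i in seq_len(n_specimens)) {
      sp <- base_spec
      sp$seed <- derive_seed(seed, i)
      sp$tnm <- tnm[i, ]
      if (!is.null(noncancer_amplitude_by_stage) &&
          stages[i] %in% names(noncancer_amplitude_by_stage))
        sp$texture_amplitude_noncancer <-
          noncancer_amplitude_by_stage[[stages[i]]]
      id <- sprintf("%s_%02d", cohort_label, i)
      specimens[[i]] <- generate_specimen(sp, specimen_id = id)
      am <- specimens[[i]]$annotation_mask
      meta[[i]] <- data.frame(specimen_id = id, cohort = cohort_label,
                              T = tnm[i, 1L], N = tnm[i, 2L], M = tnm[i, 3L],
                              stage = stages[i],
                              tissue_area_cancer = sum(am == 2L),
                              tissue_area_noncancer = sum(am == 1L),
                              stringsAsFactors = FALSE)
    }
    list(specimens = specimens, table = do.call(rbind, meta))
  })
}

#' Write a cohort's images, masks and metadata to disk
#'
#' Images as 8-bit RGB PNG, tissue masks as 0/255 PNG, annotation masks as
#' 0/1/2 PNG, metadata as CSV.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory.
#' @return the metadata CSV path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in cohort$specimens) write_specimen(sp, dir)
  csv <- file.path(dir, "cohort.csv")
  write.csv(cohort$table, csv, row.names = FALSE)
  invisible(csv)
}
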