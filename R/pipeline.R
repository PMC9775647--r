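#' End-to-end run configuration
#'
#' One object drives the whole pipeline: synthetic cohort generation (or
#' loading pre-existing PNG cohorts), feature extraction, model fitting on
#' the training cohort, transfer to the second cohort, composition and
#' extreme-cluster selection, entropy maps, area-weighted resampling and
#' the region comparison report. A single global seed deterministically
#' derives every stage seed.
#'
#' @param output_dir run directory (created on demand).
#' @param seed global integer seed.
#' @param n_train,n_transfer synthetic cohort sizes (the demo emulates a
#'   small training cohort and a larger transfer cohort).
#' @param image_size synthetic image size.
#' @param stage_distribution,unknown_fraction passed to [generate_cohort()].
#' @param base_spec template [synthetic_spec()].
#' @param noncancer_amplitude_by_stage see [generate_cohort()].
#' @param train_dir,transfer_dir when set, cohorts are loaded from these
#'   directories (PNG images + `cohort.csv`) instead of being generated.
#' @param mbf an [mbf_config()].
#' @param clustering a [cluster_config()].
#' @param entropy an [entropy_config()].
#' @param n_draws resampling draws per stratum.
#' @param top_k,bottom_k extreme-cluster selection counts.
#' @param bin_edges histogram bins for the divergence report.
#' @return An object of class `run_config`.
#' @export
run_config <- function(output_dir, seed = 1, n_train = 5, n_transfer = 20,
                       image_size = c(256, 256),
                       stage_distribution = c(I = 0.3, II = 0.25, III = 0.2,
                                              `IV-A` = 0.15, `IV-B` = 0.1),
                       unknown_fraction = 0,
                       base_spec = synthetic_spec(image_size = image_size),
                       noncancer_amplitude_by_stage = NULL,
                       train_dir = NULL, transfer_dir = NULL,
                       mbf = mbf_config(), clustering = cluster_config(),
                       entropy = entropy_config(), n_draws = 10000,
                       top_k = 3, bottom_k = 3,
                       bin_edges = seq(0, 8, length.out = 65)) {
  if (missing(output_dir)) abort_config("output_dir is required")
  structure(as.list(environment()), class = "run_config")
}

read_cohort_dir <- function(dir) {
  csv <- file.path(dir, "cohort.csv")
  if (!file.exists(csv))
    abort_data("cohort metadata '%s' not found", csv)
  tab <- read.csv(csv, stringsAsFactors = FALSE,
                  colClasses = c(T = "character", N = "character",
                                 M = "character"))
  specimens <- lapply(tab$specimen_id, function(id) {
    img <- file.path(dir, paste0(id, ".png"))
    if (!file.exists(img)) abort_data("image for specimen '%s' missing", id)
    tm <- file.path(dir, paste0(id, "_tissue.png"))
    am <- file.path(dir, paste0(id, "_annotation.png"))
    load_specimen(img,
                  tissue_mask_path = if (file.exists(tm)) tm,
                  annotation_mask_path = if (file.exists(am)) am,
                  specimen_id = id)
  })
  list(specimens = specimens, table = tab)
}

pipeline_stages <- c("generate", "features", "fit", "predict", "compose",
                     "entropy", "stats")

#' Run the pixel-level analysis pipeline
#'
#' Stages, in order: `generate` (or load) both cohorts; `features`
#' (training-cohort feature matrices); `fit` (cluster model archive);
#' `predict` (cluster maps for both cohorts as PNG); `compose`
#' (composition tables, extreme-cluster selection, per-cluster cancer
#' fractions); `entropy` (per-pixel entropy records); `stats`
#' (area-weighted resampling plus the cancer-vs-noncancer comparison
#' report, pooled and per stage). Each stage consumes only files emitted
#' by earlier stages, so deleting downstream outputs and rerunning
#' reproduces them; completed stages are skipped unless `force = TRUE`.
#'
#' @param config a [run_config()].
#' @param stages subset of stages to run (prerequisites must exist).
#' @param force rerun stages whose outputs already exist.
#' @return the run directory, invisibly.
#' @export
run_pipeline <- function(config, stages = pipeline_stages, force = FALSE) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  # provenance: serialised config + content hash + seed
  cfg_path <- file.path(out, "run_config.json")
  ser <- list(seed = config$seed, n_train = config$n_train,
              n_transfer = config$n_transfer,
              image_size = config$image_size,
              stage_distribution = as.list(config$stage_distribution),
              unknown_fraction = config$unknown_fraction,
              mbf = unclass(config$mbf),
              clustering = unclass(config$clustering),
              entropy = unclass(config$entropy),
              n_draws = config$n_draws, top_k = config$top_k,
              bottom_k = config$bottom_k, bin_edges = config$bin_edges)
  jsonlite::write_json(ser, cfg_path, digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(list(config_md5 = unname(tools::md5sum(cfg_path)),
                            seed = config$seed),
                       file.path(out, "provenance.json"), auto_unbox = TRUE)

  run_stage <- function(name, outputs, fun) {
    if (!name %in% stages) return(invisible(NULL))
    if (!force && all(file.exists(outputs))) {
      message(sprintf("[%s] outputs present, skipping", name))
      return(invisible(NULL))
    }
    t0 <- Sys.time()
    tryCatch(fun(), error = function(e) {
      abort_data("stage '%s' failed: %s", name, conditionMessage(e))
    })
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
  }

  train_dir <- file.path(out, "cohort_train")
  transfer_dir <- file.path(out, "cohort_transfer")

  run_stage("generate",
            file.path(c(train_dir, transfer_dir), "cohort.csv"), function() {
    if (!is.null(config$train_dir)) {
      if (!dir.exists(config$train_dir) ||
          !length(list.files(config$train_dir)))
        abort_data("input image directory '%s' is missing or empty",
                   config$train_dir)
      dir.create(train_dir, showWarnings = FALSE)
      dir.create(transfer_dir, showWarnings = FALSE)
      file.copy(list.files(config$train_dir, full.names = TRUE), train_dir,
                overwrite = TRUE)
      file.copy(list.files(config$transfer_dir, full.names = TRUE),
                transfer_dir, overwrite = TRUE)
    } else {
      tr <- generate_cohort(config$n_train, config$stage_distribution,
                            cohort_label = "train",
                            seed = derive_seed(config$seed, 101),
                            unknown_fraction = config$unknown_fraction,
                            base_spec = config$base_spec,
                            noncancer_amplitude_by_stage =
                              config$noncancer_amplitude_by_stage)
      te <- generate_cohort(config$n_transfer, config$stage_distribution,
                            cohort_label = "transfer",
                            seed = derive_seed(config$seed, 202),
                            unknown_fraction = config$unknown_fraction,
                            base_spec = config$base_spec,
                            noncancer_amplitude_by_stage =
                              config$noncancer_amplitude_by_stage)
      write_cohort(tr, train_dir)
      write_cohort(te, transfer_dir)
    }
  })

  feat_dir <- file.path(out, "features")
  run_stage("features", file.path(feat_dir, "features_done.json"), function() {
    dir.create(feat_dir, showWarnings = FALSE)
    co <- read_cohort_dir(train_dir)
    for (sp in co$specimens) {
      fm <- extract_mbf(sp, config$mbf)
      write.csv(cbind(as.data.frame(fm$pixel_index),
                      as.data.frame(fm$values)),
                file.path(feat_dir, paste0(sp$specimen_id, "_mbf.csv")),
                row.names = FALSE)
    }
    jsonlite::write_json(list(specimens = co$table$specimen_id,
                              feature_names =
                                extract_mbf(co$specimens[[1]],
                                            config$mbf)$feature_names),
                         file.path(feat_dir, "features_done.json"),
                         auto_unbox = TRUE)
  })

  model_path <- file.path(out, "cluster_model.json")
  run_stage("fit", model_path, function() {
    co <- read_cohort_dir(train_dir)
    fms <- lapply(co$specimens, extract_mbf, config = config$mbf)
    cc <- config$clustering
    cc$seed <- derive_seed(config$seed, 303)
    model <- fit_cluster_model(fms, cc, training_cohort = "train")
    write_cluster_model(model, model_path)
  })

  maps_dir <- file.path(out, "cluster_maps")
  run_stage("predict", file.path(maps_dir, "maps_done.json"), function() {
    dir.create(maps_dir, showWarnings = FALSE)
    model <- read_cluster_model(model_path)
    done <- list()
    for (d in c(train_dir, transfer_dir)) {
      co <- read_cohort_dir(d)
      for (sp in co$specimens) {
        cm <- predict_clusters(model, sp)
        write_png(matrix(as.integer(cm$ids), nrow(cm$ids), ncol(cm$ids)),
                  file.path(maps_dir, paste0(sp$specimen_id, "_clusters.png")))
        done[[length(done) + 1L]] <- sp$specimen_id
      }
    }
    jsonlite::write_json(list(specimens = unlist(done)),
                         file.path(maps_dir, "maps_done.json"),
                         auto_unbox = TRUE)
  })

  compose_path <- file.path(out, "composition.csv")
  selection_path <- file.path(out, "extreme_clusters.json")
  run_stage("compose", c(compose_path, selection_path), function() {
    model <- read_cluster_model(model_path)
    noise <- model$cluster_config$noise_clusters
    read_maps <- function(d) {
      co <- read_cohort_dir(d)
      maps <- lapply(co$specimens, function(sp) {
        ids <- read_png(file.path(maps_dir,
                                  paste0(sp$specimen_id, "_clusters.png")))
        structure(list(ids = ids, specimen_id = sp$specimen_id),
                  class = "cluster_map")
      })
      list(cohort = co, maps = maps)
    }
    tr <- read_maps(train_dir); te <- read_maps(transfer_dir)
    nclust <- nrow(model$centroids)
    comp_tr <- cluster_composition(tr$maps, noise, nclust)
    comp_te <- cluster_composition(te$maps, noise, nclust)
    cf <- cancer_fraction_per_cluster(
      tr$maps, lapply(tr$cohort$specimens, `[[`, "annotation_mask"), nclust)
    tab <- data.frame(cluster = as.integer(names(comp_tr)),
                      ratio_train = as.numeric(comp_tr),
                      ratio_transfer = as.numeric(comp_te))
    tab <- merge(tab, cf, by = "cluster")
    write.csv(tab, compose_path, row.names = FALSE)
    sel <- select_extreme_clusters(comp_te, config$top_k, config$bottom_k)
    jsonlite::write_json(sel, selection_path)
  })

  entropy_dir <- file.path(out, "entropy")
  run_stage("entropy", file.path(entropy_dir, "entropy_done.json"), function() {
    dir.create(entropy_dir, showWarnings = FALSE)
    sel <- jsonlite::read_json(selection_path, simplifyVector = TRUE)
    done <- list()
    for (d in c(train_dir, transfer_dir)) {
      co <- read_cohort_dir(d)
      for (sp in co$specimens) {
        emap <- local_entropy_map(sp, config$entropy)
        # region labels: expert annotation when present, else transfer the
        # extreme clusters selected by composition (both paths recorded)
        if (!is.null(sp$annotation_mask)) {
          rec <- entropy_records(emap, sp, regions = "annotation")
          rec$label_source <- "annotation"
        } else {
          ids <- read_png(file.path(maps_dir,
                                    paste0(sp$specimen_id, "_clusters.png")))
          cm <- structure(list(ids = ids, specimen_id = sp$specimen_id),
                          class = "cluster_map")
          rec <- entropy_records(emap, sp,
                                 regions = regions_from_clusters(
                                   cm, sel$top, sel$bottom))
          rec$label_source <- "clusters"
        }
        write.csv(rec,
                  file.path(entropy_dir,
                            paste0(sp$specimen_id, "_entropy.csv")),
                  row.names = FALSE)
        done[[length(done) + 1L]] <- sp$specimen_id
      }
    }
    jsonlite::write_json(list(specimens = unlist(done)),
                         file.path(entropy_dir, "entropy_done.json"),
                         auto_unbox = TRUE)
  })

  report_path <- file.path(out, "region_report.csv")
  run_stage("stats", report_path, function() {
    co <- read_cohort_dir(transfer_dir)
    rec <- do.call(rbind, lapply(co$table$specimen_id, function(id) {
      read.csv(file.path(entropy_dir, paste0(id, "_entropy.csv")),
               stringsAsFactors = FALSE)
    }))
    pooled <- area_weighted_resample(rec, co$table, config$n_draws,
                                     seed = derive_seed(config$seed, 404),
                                     group_by = "none")
    rep_all <- compare_regions(pooled, "none", config$bin_edges)
    staged <- tryCatch(
      area_weighted_resample(rec, co$table, config$n_draws,
                             seed = derive_seed(config$seed, 505),
                             group_by = "stage"),
      pixelhe_data_error = function(e) NULL)
    rep_stage <- if (!is.null(staged))
      compare_regions(staged, "stage", config$bin_edges)
    report <- rbind(rep_all, rep_stage)
    write.csv(report, report_path, row.names = FALSE)
  })

  invisible(out)
}
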