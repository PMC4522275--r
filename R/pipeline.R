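#' Pipeline configuration
#'
#' Defaults for every stage of the batch analysis: optical conversion,
#' segmentation, tile classification, threshold percentiles, the
#' 10-percent tissue QC rule, and the significance level of the region
#' comparisons.
#'
#' @param mode Acquisition mode of the inputs.
#' @param i0 White reference for brightfield OD conversion.
#' @param od_max OD ceiling.
#' @param segmentation Named list of [segment_nuclei()] parameters.
#' @param tile_size Tissue-classifier tile edge (px).
#' @param tissue_od_threshold Summed-OD cutoff defining tissue pixels.
#' @param background_cutoff Minimum tile tissue fraction before a tile is
#'   called background.
#' @param membrane_dilation_px Label expansion for per-cell quantification.
#' @param channel_map Roles (`lineage`, `tetraspanin`, `nuclear`) to
#'   endmember names.
#' @param percentile_tet,percentile_lineage,min_control Threshold
#'   derivation settings ([derive_thresholds()]).
#' @param control_region Region whose cells serve as negative controls.
#' @param qc_min_tissue Minimum tissue fraction an image must reach
#'   (default 0.10; strictly smaller fractions are discarded).
#' @param alpha Significance level (p <= alpha is significant).
#' @param plan Comparison plan data frame (`metric`, `region_a`,
#'   `region_b`).
#' @param seed Seed for the (only) stochastic step, scatter subsampling.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("brightfield", "fluorescence"),
                            i0 = 255, od_max = 3,
                            segmentation = list(smooth_sigma = 0.8,
                                                threshold_method = "otsu",
                                                min_area = 12, max_area = 400,
                                                min_peak_distance = 1,
                                                watershed_tolerance = 0.1),
                            tile_size = 8,
                            tissue_od_threshold = 0.05,
                            background_cutoff = 0.05,
                            membrane_dilation_px = 2,
                            channel_map = c(lineage = "warp_red",
                                            tetraspanin = "true_blue",
                                            nuclear = "nuclear_red"),
                            percentile_tet = 95, percentile_lineage = 99,
                            min_control = 50,
                            control_region = "other",
                            qc_min_tissue = 0.10,
                            alpha = 0.05,
                            plan = data.frame(
                              metric = c("pct_bright", "od_mean",
                                         "pct_bright_lineage_pos"),
                              region_a = "follicle", region_b = "stroma"),
                            seed = 1) {
  mode <- match.arg(mode)
  stopifnot(i0 > 0, od_max > 0, tile_size >= 4,
            qc_min_tissue >= 0, qc_min_tissue <= 1,
            alpha > 0, alpha <= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full batch analysis pipeline
#'
#' Executes, in order: library build/load, OD conversion (brightfield),
#' per-pixel unmixing, nuclear segmentation, tissue-region classification
#' (or ground-truth masks when provided), per-cell quantification,
#' image-level tissue QC, threshold derivation from control cells of the
#' kept images, four-class scoring, region summaries and the planned
#' two-group comparisons. All stage outputs are written under `out_dir`;
#' a manifest records the configuration hash and seed. Reruns with the
#' same inputs and config produce byte-identical `cells.csv` and
#' `stats.csv`.
#'
#' @param cubes Named list of [multispectral_cube] objects or TIFF paths
#'   (names are image ids; unnamed paths use their base name).
#' @param library A `spectral_library`, [endmember_set], library CSV path,
#'   or named list of single-stain cubes to build from.
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @param tissue_model Optional pre-trained [train_tissue_classifier()]
#'   model.
#' @param train Optional list with `cubes` and `masks` (ground-truth
#'   [region_mask]s) used to train the tissue model when none is given.
#' @param region_masks Optional named list of [region_mask]s to use
#'   directly instead of classification (e.g. ground truth).
#' @return Invisibly, a list with `cells`, `summaries`, `stats`, `qc`,
#'   `thresholds`, `tissue_model` and `out_dir`.
#' @export
run_pipeline <- function(cubes, library, out_dir,
                         config = pipeline_config(),
                         tissue_model = NULL, train = NULL,
                         region_masks = NULL) {
  stopifnot(inherits(config, "pipeline_config"), length(cubes) >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  logit <- function(...) log_lines <<- c(log_lines, sprintf(...))
  stage <- "setup"
  on_fail <- function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }

  tryCatch({
    stage <- "load-cubes"
    if (is.null(names(cubes)))
      names(cubes) <- vapply(cubes, function(x) {
        if (is.character(x)) tools::file_path_sans_ext(basename(x)) else "image"
      }, character(1))
    cubes <- lapply(names(cubes), function(id) {
      x <- cubes[[id]]
      if (is.character(x)) x <- read_cube(x)
      x$image_id <- id
      x
    })
    names(cubes) <- vapply(cubes, function(x) x$image_id, character(1))

    stage <- "build-library"
    lib <- if (inherits(library, "spectral_library")) {
      library
    } else if (inherits(library, "endmember_set")) {
      as_spectral_library(library)
    } else if (is.character(library)) {
      read_spectral_library(library)
    } else if (is.list(library)) {
      build_library(library, mode = config$mode, od_max = config$od_max)
    } else stop("unsupported library specification")
    write_spectral_library(lib, file.path(out_dir, "library.csv"))
    logit("library: %d endmembers (%s)", length(lib$endmembers$names),
          paste(lib$endmembers$names, collapse = ", "))

    stage <- "unmix"
    abmaps <- list(); odcubes <- list()
    for (id in names(cubes)) {
      x <- if (config$mode == "brightfield") {
        to_optical_density(cubes[[id]], I0 = cubes[[id]]$I0 %||% config$i0,
                           od_max = config$od_max)
      } else cubes[[id]]
      odcubes[[id]] <- x
      abmaps[[id]] <- withCallingHandlers(
        unmix_cube(x, lib),
        warning = function(w) {
          logit("unmix %s: %s", id, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      write_abundance_map(abmaps[[id]],
                          file.path(out_dir, paste0(id, "_abundance.tiff")))
    }

    stage <- "qc"
    fractions <- vapply(abmaps, compute_tissue_fraction,
                        numeric(1), tissue_od_threshold = config$tissue_od_threshold)
    qc <- qc_filter_images(fractions, min_fraction = config$qc_min_tissue)
    for (id in qc$dropped) logit("QC: dropped image %s (tissue fraction %.3f < %.2f)",
                                 id, fractions[[id]], config$qc_min_tissue)
    utils::write.csv(qc$qc, file.path(out_dir, "qc.csv"), row.names = FALSE)
    if (length(qc$kept) == 0) stop("all images failed tissue QC")

    stage <- "segment-cells"
    labelmaps <- list()
    for (id in qc$kept) {
      seg <- config$segmentation
      labelmaps[[id]] <- segment_nuclei(
        abmaps[[id]]$coefficients[, , config$channel_map[["nuclear"]]],
        smooth_sigma = seg$smooth_sigma,
        threshold_method = seg$threshold_method,
        min_area = seg$min_area, max_area = seg$max_area,
        min_peak_distance = seg$min_peak_distance,
        watershed_tolerance = seg$watershed_tolerance %||% 0.1)
      write_label_tiff(labelmaps[[id]]$labels,
                       file.path(out_dir, paste0(id, "_cells.tiff")))
      logit("segmentation %s: %d cells", id, nrow(labelmaps[[id]]$cells))
    }

    stage <- "segment-tissue"
    if (is.null(region_masks)) {
      if (is.null(tissue_model)) {
        if (is.null(train))
          stop("need a tissue_model, train data, or region_masks")
        feats <- list(); labs <- list()
        for (i in seq_along(train$cubes)) {
          tc <- train$cubes[[i]]
          if (is.character(tc)) tc <- read_cube(tc)
          tx <- if (config$mode == "brightfield")
            to_optical_density(tc, I0 = tc$I0 %||% config$i0,
                               od_max = config$od_max) else tc
          tab <- suppressWarnings(unmix_cube(tx, lib))
          tseg <- segment_nuclei(
            tab$coefficients[, , config$channel_map[["nuclear"]]],
            smooth_sigma = config$segmentation$smooth_sigma,
            threshold_method = config$segmentation$threshold_method,
            min_area = config$segmentation$min_area,
            max_area = config$segmentation$max_area,
            min_peak_distance = config$segmentation$min_peak_distance,
            watershed_tolerance = config$segmentation$watershed_tolerance %||% 0.1)
          f <- extract_tile_features(tab, tseg, tile_size = config$tile_size,
                                     tissue_od_threshold = config$tissue_od_threshold,
                                     channel_map = config$channel_map)
          feats[[i]] <- f
          labs[[i]] <- tile_labels_from_mask(f, train$masks[[i]])
        }
        all_f <- do.call(rbind, feats)
        attr(all_f, "feature_names") <- attr(feats[[1]], "feature_names")
        attr(all_f, "tile_size") <- config$tile_size
        tissue_model <- train_tissue_classifier(all_f, unlist(labs))
        logit("tissue model trained on %d images (%d tiles)",
              length(train$cubes), nrow(all_f))
      }
      region_masks <- list()
      for (id in qc$kept) {
        f <- extract_tile_features(abmaps[[id]], labelmaps[[id]],
                                   tile_size = config$tile_size,
                                   tissue_od_threshold = config$tissue_od_threshold,
                                   channel_map = config$channel_map)
        region_masks[[id]] <- classify_tissue(tissue_model, f,
                                              dim(abmaps[[id]]$residual),
                                              background_cutoff = config$background_cutoff)
      }
    }
    for (id in qc$kept) {
      write_region_mask(region_masks[[id]],
                        file.path(out_dir, paste0(id, "_regions.tiff")))
    }

    stage <- "quantify"
    records <- do.call(rbind, lapply(qc$kept, function(id) {
      quantify_cells(labelmaps[[id]], abmaps[[id]], region_masks[[id]],
                     channel_map = config$channel_map,
                     membrane_dilation_px = config$membrane_dilation_px,
                     image_id = id)
    }))

    stage <- "thresholds"
    thresholds <- derive_thresholds(
      records,
      control_selector = function(r) r$region == config$control_region,
      percentile_tet = config$percentile_tet,
      percentile_lineage = config$percentile_lineage,
      min_control = config$min_control)
    logit("thresholds: lineage >= %.4f, bright >= %.4f (%d control cells)",
          thresholds$lineage_positivity_od, thresholds$tet_dim_bright_od,
          thresholds$n_control)
    jsonlite::write_json(unclass(thresholds),
                         file.path(out_dir, "thresholds.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    stage <- "score"
    records <- score_cells(records, thresholds)
    write_cell_records(records, file.path(out_dir, "cells.csv"))

    stage <- "summaries"
    summaries <- withCallingHandlers(
      summarize_regions(records),
      warning = function(w) {
        logit("summaries: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    utils::write.csv(summaries, file.path(out_dir, "summaries.csv"),
                     row.names = FALSE)

    stage <- "stats"
    stats_df <- withCallingHandlers(
      run_comparisons(summaries, config$plan, alpha = config$alpha),
      warning = function(w) {
        logit("stats: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    utils::write.csv(stats_df, file.path(out_dir, "stats.csv"),
                     row.names = FALSE)

    stage <- "scatter"
    scatter <- sample_cells_for_scatter(records, n_max = 2000,
                                        seed = config$seed)
    write_cell_records(scatter, file.path(out_dir, "scatter.csv"))

    stage <- "manifest"
    cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                 digits = NA, force = TRUE)
    tf <- tempfile(); writeLines(cfg_json, tf)
    manifest <- list(
      package = "spectracyte",
      version = as.character(utils::packageVersion("spectracyte")),
      config_md5 = unname(tools::md5sum(tf)),
      seed = config$seed,
      images = names(cubes),
      kept = qc$kept, dropped = qc$dropped
    )
    unlink(tf)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "log.txt"))

    invisible(list(cells = records, summaries = summaries, stats = stats_df,
                   qc = qc$qc, thresholds = thresholds,
                   tissue_model = tissue_model, out_dir = out_dir))
  }, error = on_fail)
}
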