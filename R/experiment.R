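## End-to-end experiment orchestration over phantom data, mirroring the
## three study designs: a two-class comparison 24 h after the apoptotic
## insult, an early time course in cell cultures, and a time course in
## retinal explants with seeded ROI boxes.

#' Configure a phantom experiment
#'
#' Defaults mirror the study designs: `two_class_24h` compares a control
#' and a fully degenerated class (120 stacks each in 8 imaging-session
#' subsets); `timecourse_cells` images 6 timepoints at 10-minute intervals
#' from 10 to 60 min (28 stacks per timepoint, 6 subsets) with a saturating
#' degeneration schedule (the texture change is most dramatic in the first
#' half hour); `timecourse_explant` uses 13 retinas with 10 seeded ROI
#' boxes of 128 x 64 x 64 voxels each, 5 subsets. Sizes are configurable
#' for reduced-scale runs.
#'
#' @param design one of `"two_class_24h"`, `"timecourse_cells"`,
#'   `"timecourse_explant"`.
#' @param n_per_group stacks per class (two-class) or per timepoint
#'   (time courses).
#' @param n_subsets number of imaging-session subsets.
#' @param shape phantom stack shape `(z, y, x)`.
#' @param schedule degeneration schedule for time-course designs.
#' @param timepoints_min acquisition times in minutes for the schedule.
#' @param max_features cap on ranked features in the forward search.
#' @param boxes_per_retina seeded ROI boxes per explant (explant design
#'   only); each box has the configured `shape` and the boxes tile the
#'   retina volume along x.
#' @param phantom named list of [phantom_spec()] overrides.
#' @param seed integer master seed.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(design = c("two_class_24h", "timecourse_cells",
                                         "timecourse_explant"),
                              n_per_group = NULL, n_subsets = NULL,
                              shape = NULL, schedule = NULL,
                              timepoints_min = NULL, max_features = 10L,
                              boxes_per_retina = 10L,
                              phantom = list(), seed = 1L) {
  design <- match.arg(design)
  defaults <- switch(design,
    two_class_24h = list(n_per_group = 120L, n_subsets = 8L,
                         shape = c(128L, 64L, 64L),
                         schedule = NULL, timepoints_min = NULL),
    timecourse_cells = list(n_per_group = 28L, n_subsets = 6L,
                            shape = c(128L, 64L, 64L),
                            schedule = c(0, 0.3, 0.55, 0.75, 0.9, 1),
                            timepoints_min = seq(10, 60, by = 10)),
    timecourse_explant = list(n_per_group = 13L, n_subsets = 5L,
                              shape = c(128L, 64L, 64L),
                              schedule = c(0, 0.3, 0.55, 0.75, 0.9, 1),
                              timepoints_min = seq(10, 60, by = 10)))
  cfg <- list(design = design,
              n_per_group = if (is.null(n_per_group)) defaults$n_per_group
                            else as.integer(n_per_group),
              n_subsets = if (is.null(n_subsets)) defaults$n_subsets
                          else as.integer(n_subsets),
              shape = if (is.null(shape)) defaults$shape else as.integer(shape),
              schedule = if (is.null(schedule)) defaults$schedule else schedule,
              timepoints_min = if (is.null(timepoints_min))
                defaults$timepoints_min else timepoints_min,
              max_features = as.integer(max_features),
              boxes_per_retina = as.integer(boxes_per_retina),
              phantom = phantom, seed = as.integer(seed))
  if (!is.null(cfg$schedule) &&
      length(cfg$schedule) != length(cfg$timepoints_min))
    stop("schedule and timepoints_min lengths differ")
  class(cfg) <- "experiment_config"
  cfg
}

base_spec_for <- function(cfg, degeneration = 0, seed = 1L) {
  args <- modifyList(list(shape = cfg$shape, degeneration = degeneration,
                          seed = seed), cfg$phantom)
  do.call(phantom_spec, args)
}

#' Quality-control gate for a masked stack
#'
#' Automated stand-in for visual image rejection: a stack passes when its
#' in-ROI mean intensity and speckle contrast (sd/mean) fall inside the
#' configured bounds.
#'
#' @param stack an [image_stack()].
#' @param roi a `roi_mask`.
#' @param mean_bounds acceptable in-ROI mean intensity range.
#' @param contrast_bounds acceptable speckle contrast range.
#' @return Logical: TRUE when the stack passes.
#' @export
qc_check <- function(stack, roi, mean_bounds = c(5, 250),
                     contrast_bounds = c(0.1, 2)) {
  x <- as.numeric(stack$voxels[roi$mask])
  m <- mean(x)
  ct <- if (m > 0) sd(x) / m else Inf
  m >= mean_bounds[1] && m <= mean_bounds[2] &&
    ct >= contrast_bounds[1] && ct <= contrast_bounds[2]
}

#' Preprocess, mask and featurize one stack
#'
#' The per-stack chain shared by every experiment: preprocessing with
#' below-coverslip cropping, automatic ROI masking, in-ROI histogram
#' equalization, 65-feature extraction and the QC gate.
#'
#' @param stack an [image_stack()].
#' @param feature_config optional [extract_features()] config overrides.
#' @return A list: `features` (length-65 named vector), `qc` (logical),
#'   `report` (the `preprocess_report`).
#' @export
stack_to_features <- function(stack, feature_config = list()) {
  pp <- preprocess_stack(stack, crop_below_coverslip = TRUE)
  roi <- mask_roi_auto(pp$stack)
  eq <- equalize_in_roi(pp$stack, roi)
  list(features = extract_features(eq, roi, feature_config),
       qc = qc_check(eq, roi), report = pp$report)
}

# Explant workflow for one retina volume: preprocess, tile into seeded ROI
# boxes along x, refine each with the automatic masking, equalize and
# extract features per ROI.
explant_stack_to_features <- function(stack, n_boxes, feature_config = list()) {
  pp <- preprocess_stack(stack, crop_below_coverslip = TRUE)
  d <- dim(pp$stack$voxels)
  w <- d[3] %/% n_boxes
  boxes <- lapply(seq_len(n_boxes) - 1L, function(b)
    list(z0 = 0L, z1 = d[1], y0 = 0L, y1 = d[2],
         x0 = b * w, x1 = (b + 1L) * w))
  rois <- mask_roi_manual(pp$stack, boxes)
  lapply(rois, function(roi) {
    eq <- equalize_in_roi(pp$stack, roi)
    list(features = extract_features(eq, roi, feature_config),
         qc = qc_check(eq, roi))
  })
}

#' Run a phantom experiment end to end
#'
#' Executes the full chain (phantom generation, preprocessing, ROI
#' masking, in-ROI equalization, 65-feature extraction) and then the
#' design-appropriate analysis: nested feature selection plus
#' leave-one-subset-out cross-validation for `two_class_24h`; feature
#' selection (first vs last timepoint), class-conditional pairwise
#' distances, Sammon projection and a Texture Index series for the time
#' courses. All outputs are written under `out_dir` together with a
#' manifest (config, seed, package version, output checksums) sufficient
#' to reproduce the run bit-identically.
#'
#' @param cfg an [experiment_config()].
#' @param out_dir output directory (created if missing).
#' @param feature_config optional [extract_features()] config overrides.
#' @return A list with the in-memory results (`features`, plus `cv` and
#'   `selection`, or `ti` and `embedding`, depending on design).
#' @export
run_experiment <- function(cfg, out_dir, feature_config = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stacks <- list(); labels <- character(0)
  subsets <- character(0); tps <- numeric(0)
  if (cfg$design == "two_class_24h") {
    groups <- c(control = 0, apoptotic = 1)
    for (gi in seq_along(groups)) {
      g <- names(groups)[gi]
      base <- base_spec_for(cfg, groups[[g]], seed = cfg$seed + gi)
      batch <- generate_timecourse(base, groups[[g]], cfg$n_per_group)
      stacks <- c(stacks, batch)
      labels <- c(labels, rep(g, cfg$n_per_group))
      subsets <- c(subsets,
                   sprintf("s%02d", 1L + (seq_len(cfg$n_per_group) - 1L) %%
                             cfg$n_subsets))
      tps <- c(tps, rep(NA_real_, cfg$n_per_group))
    }
  } else {
    base <- base_spec_for(cfg, 0, seed = cfg$seed)
    if (cfg$design == "timecourse_explant") {
      # one retina volume per acquisition, tiled into seeded ROI boxes
      base$shape[3] <- base$shape[3] * cfg$boxes_per_retina
      class(base) <- "phantom_spec"
    }
    stacks <- generate_timecourse(base, cfg$schedule, cfg$n_per_group)
    for (t in seq_along(cfg$schedule)) {
      labels <- c(labels, rep(sprintf("t%02d", t), cfg$n_per_group))
      subsets <- c(subsets,
                   sprintf("s%02d", 1L + (seq_len(cfg$n_per_group) - 1L) %%
                             cfg$n_subsets))
      tps <- c(tps, rep(cfg$timepoints_min[t], cfg$n_per_group))
    }
  }

  if (cfg$design == "timecourse_explant") {
    rows <- list(); lab2 <- character(0); sub2 <- character(0); tp2 <- numeric(0)
    for (i in seq_along(stacks)) {
      per <- explant_stack_to_features(stacks[[i]], cfg$boxes_per_retina,
                                       feature_config)
      rows <- c(rows, per)
      lab2 <- c(lab2, rep(labels[i], length(per)))
      sub2 <- c(sub2, rep(subsets[i], length(per)))
      tp2 <- c(tp2, rep(tps[i], length(per)))
    }
    labels <- lab2; subsets <- sub2; tps <- tp2
  } else {
    rows <- lapply(stacks, stack_to_features, feature_config = feature_config)
  }
  keep <- vapply(rows, `[[`, logical(1), "qc")
  fm <- feature_matrix(lapply(rows[keep], `[[`, "features"),
                       labels[keep], subsets[keep],
                       if (all(is.na(tps))) NULL else tps[keep])
  write_feature_matrix(fm, file.path(out_dir, "features.csv"))

  out <- list(features = fm, n_rejected = sum(!keep))
  if (cfg$design == "two_class_24h") {
    red <- cross_validate_reduced(fm, max_features = cfg$max_features,
                                  seed = cfg$seed)
    out$cv <- red$cv
    out$selection <- red
    jsonlite::write_json(
      list(overall_accuracy = red$cv$overall_accuracy,
           per_fold = red$cv$per_fold,
           confusion = as.data.frame(red$cv$confusion),
           per_fold_sets = red$per_fold_sets,
           union_set = red$union_set),
      file.path(out_dir, "cv_report.json"), auto_unbox = TRUE, digits = NA)
  } else {
    # features that separate the first from the last timepoint, selected
    # per training fold and pooled by union (training data are limited)
    rng <- range(fm$timepoints)
    two <- fm$timepoints %in% rng
    Msel <- feature_matrix(fm$X[two, , drop = FALSE], fm$labels[two],
                           fm$subset_ids[two])
    sel <- cross_validate_reduced(Msel, max_features = cfg$max_features,
                                  seed = cfg$seed)
    feats <- sel$union_set
    # The embedding benefits from a richer space than the minimal
    # classifying set (the study's projections used ~15 features): enrich
    # up to 8 features by first-vs-last effect size, skipping features
    # nearly collinear (|r| > 0.9) with those already taken, so the class
    # metric is not dominated by one redundant family.
    min_embed <- 8L
    if (length(feats) < min_embed) {
      m0 <- colMeans(Msel$X[Msel$labels == sort(unique(Msel$labels))[1], ,
                            drop = FALSE])
      m1 <- colMeans(Msel$X[Msel$labels == sort(unique(Msel$labels))[2], ,
                            drop = FALSE])
      sdp <- apply(Msel$X, 2, sd)
      zf <- abs(m1 - m0) / ifelse(sdp > 0, sdp, Inf)
      for (f in colnames(Msel$X)[order(zf, decreasing = TRUE)]) {
        if (length(feats) >= min_embed) break
        if (f %in% feats) next
        cors <- abs(cor(Msel$X[, f], Msel$X[, feats, drop = FALSE]))
        if (all(is.na(cors)) || max(cors, na.rm = TRUE) < 0.9)
          feats <- c(feats, f)
      }
    }
    D <- pairwise_class_distances(fm$X[, feats, drop = FALSE], fm$labels)
    emb <- sammon_project(D, seed = cfg$seed)
    ti <- ti_series(emb, fm$timepoints)
    out$selection <- sel
    out$embedding <- emb
    out$ti <- ti
    write.csv(ti, file.path(out_dir, "ti_series.csv"), row.names = FALSE)
    write.csv(data.frame(mvp = mvp_coords(emb),
                         svp = as.numeric(sweep(emb$points, 2,
                                                colMeans(emb$points)) %*%
                                            emb$svp_axis),
                         timepoint = fm$timepoints, label = fm$labels),
              file.path(out_dir, "embedding.csv"), row.names = FALSE)
  }

  manifest <- list(design = cfg$design, seed = cfg$seed,
                   n_per_group = cfg$n_per_group, n_subsets = cfg$n_subsets,
                   shape = cfg$shape, schedule = cfg$schedule,
                   timepoints_min = cfg$timepoints_min,
                   max_features = cfg$max_features,
                   phantom_overrides = cfg$phantom,
                   n_rejected_qc = out$n_rejected,
                   package_version =
                     as.character(utils::packageVersion("speckletex")),
                   file_md5 = as.list(tools::md5sum(
                     list.files(out_dir, full.names = TRUE,
                                pattern = "\\.(csv|json)$"))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}
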