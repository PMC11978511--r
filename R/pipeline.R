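# Pipeline orchestration: load -> enhance -> segment -> mocap -> flow ->
# features -> graphs, with standard-format outputs and a JSON run manifest.

#' Pipeline configuration
#'
#' Every parameter affecting outputs lives here and is serialized verbatim
#' into the run manifest.
#'
#' @param dim_order_override,spacing_override,interval_override metadata
#'   overrides passed to [load_stack()].
#' @param channel 0-based channel to analyse (required iff the data have a
#'   channel axis).
#' @param t_start,t_end 0-based half-open frame range (default: all frames).
#' @param r_min_um,r_max_um target structure radius range for the
#'   multiscale filter (microns); defaults cover typical organelles in
#'   diffraction-limited light microscopy.
#' @param n_scales number of filter scales (default from the radius range).
#' @param min_size_um minimum organelle size (square/cubic microns; 0 drops
#'   only single-voxel specks).
#' @param threshold_method automatic semantic threshold: `"otsu"` (default)
#'   or the more sensitive `"minotri"`.
#' @param max_travel_um maximum marker travel per frame (microns).
#' @param weights cost-matrix block weights `(distance, stats, Hu)`.
#' @param agg_stats aggregation statistics for cross-level features.
#' @param save_enhanced also write the enhanced response as float32
#'   OME-TIFF.
#' @param seed RNG seed recorded in the manifest (the analysis itself is
#'   deterministic; the seed matters only for synthetic-scene generation).
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(dim_order_override = NULL, spacing_override = NULL,
                            interval_override = NULL, channel = NULL,
                            t_start = NULL, t_end = NULL,
                            r_min_um = 0.25, r_max_um = 1.0, n_scales = NULL,
                            min_size_um = 0, threshold_method = "otsu",
                            max_travel_um = 1.0,
                            weights = c(1, 1, 1),
                            agg_stats = c("mean", "std", "min", "max",
                                          "median", "sum"),
                            save_enhanced = FALSE, seed = 1L) {
  structure(as.list(environment()), class = "PipelineConfig")
}

numeric_feature_cols <- function(df, exclude = character()) {
  skip <- c("frame", "z", "y", "x", "node_id", "branch_id", "organelle_id",
            "marker_id", "graph_node_id", "is_junction", "is_tip",
            "traversal_index", exclude)
  names(df)[vapply(df, is.numeric, TRUE) & !(names(df) %in% skip)]
}

#' Run the full pipeline
#'
#' Executes enhancement, hierarchical segmentation, marker tracking, flow
#' interpolation and feature extraction per the configuration. Single-frame
#' inputs run morphology-only: tracking and motility stages are skipped.
#'
#' @param input a file path (TIFF/OME-TIFF) or an `ImageStack`.
#' @param config a `PipelineConfig`.
#' @param out_dir if non-NULL, all outputs are written there via
#'   [write_outputs()].
#' @param verbose log stage timings to stderr.
#' @return a `PipelineResult` list: per-frame hierarchies and enhanced
#'   frames, tracking, per-level feature tables, tracks, and the manifest
#'   (when written).
#' @export
run_pipeline <- function(input, config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t_all <- proc.time()[3]
  stack <- if (inherits(input, "ImageStack")) input else
    load_stack(input, config$dim_order_override, config$spacing_override,
               config$interval_override)
  if (length(dim(stack$data)) == 5 || !is.null(config$channel) ||
      !is.null(config$t_start) || !is.null(config$t_end))
    stack <- select_slices(stack, config$channel, config$t_start, config$t_end)
  nT <- n_frames(stack)
  dim3 <- stack_dim3(stack)
  spacing <- stack$spacing
  fi <- if (is.null(stack$frame_interval)) 1.0 else stack$frame_interval
  say("loaded stack: %d frame(s), %s", nT, paste(dim3, collapse = "x"))

  scales <- derive_scales(spacing, config$r_min_um, config$r_max_um,
                          config$n_scales)
  raw_frames <- lapply(seq_len(nT), function(t) frame_array(stack$data, t))
  t0 <- proc.time()[3]
  enh <- lapply(raw_frames, structure_enhance, scales = scales)
  say("enhanced %d frame(s) [%.1fs]", nT, proc.time()[3] - t0)
  t0 <- proc.time()[3]
  hier <- lapply(enh, segment_frame, spacing = spacing,
                 min_size_um = config$min_size_um,
                 threshold_method = config$threshold_method)
  say("segmented [%.1fs]", proc.time()[3] - t0)

  tracking <- NULL
  if (nT > 1) {
    t0 <- proc.time()[3]
    tracking <- track_markers(hier, raw_frames, enh, spacing,
                              config$max_travel_um, config$weights)
    say("tracked markers [%.1fs]", proc.time()[3] - t0)
  }

  # ---- feature tables -------------------------------------------------
  t0 <- proc.time()[3]
  if (nT > 1) {
    voxels <- voxel_motility_features(hier, raw_frames, enh, tracking, fi,
                                      config$max_travel_um)
  } else {
    h <- hier[[1]]
    vidx <- which(h$semantic)
    co <- coords_from_index(vidx, dim3)
    voxels <- data.frame(frame = 0L, z = co[, 1], y = co[, 2], x = co[, 3],
                         node_id = h$voxel_to_node[vidx],
                         branch_id = h$branch_labels[vidx],
                         organelle_id = h$organelle_labels[vidx],
                         intensity_raw = raw_frames[[1]][vidx],
                         intensity_enh = enh[[1]]$response[vidx])
  }
  vox_feats <- numeric_feature_cols(voxels)
  nodes_t <- branches_t <- organelles_t <- image_t <- list()
  for (t in seq_len(nT)) {
    h <- hier[[t]]
    if (!nrow(h$nodes)) next
    fv <- fn <- NULL
    if (nT > 1 && t < nT) {
      vidx <- which(h$semantic)
      covx <- coords_from_index(vidx, dim3)
      fv <- interpolate_flow(covx, tracking$links[[t]]$forward,
                             tracking$markers[[t]], spacing,
                             config$max_travel_um)$vectors_um
      fn <- interpolate_flow(as.matrix(h$nodes[, c("z", "y", "x")]),
                             tracking$links[[t]]$forward,
                             tracking$markers[[t]], spacing,
                             config$max_travel_um)$vectors_um
    }
    nd <- node_features(h, fv, fn)
    br <- branch_features(h)
    og <- organelle_features(h)
    vsub <- voxels[voxels$frame == t - 1L, , drop = FALSE]
    # each level gets aggregates of its children's intrinsic features, plus
    # voxel aggregates taken directly (nested re-aggregation of aggregate
    # columns stays available through aggregate_features itself)
    nd_intr <- intersect(c("thickness_um", "radius_um", "vergence"), names(nd))
    br_intr <- intersect(c("branch_length", "branch_radius",
                           "branch_tortuosity", "branch_aspect_ratio",
                           "volume"), names(br))
    og_intr <- intersect(c("volume", "extent", "solidity",
                           "inertia_tensor_eig_sorted_min",
                           "inertia_tensor_eig_sorted_mid",
                           "inertia_tensor_eig_sorted_max",
                           "major_axis_length", "minor_axis_length"),
                         names(og))
    add_vox <- function(tab, key) {
      if (!nrow(vsub) || !length(vox_feats)) return(tab)
      agg <- aggregate_features(vsub, key, vox_feats,
                                stats = config$agg_stats, child_level = "voxel")
      merge(tab, agg, by = key, all.x = TRUE, sort = TRUE)
    }
    nd <- add_vox(nd, "node_id")
    br <- add_vox(br, "branch_id")
    if (nrow(nd)) {
      agg <- aggregate_features(nd, "branch_id", nd_intr,
                                stats = config$agg_stats, child_level = "node")
      br <- merge(br, agg, by = "branch_id", all.x = TRUE, sort = TRUE)
    }
    og <- add_vox(og, "organelle_id")
    if (nrow(br)) {
      agg <- aggregate_features(br, "organelle_id", br_intr,
                                stats = config$agg_stats, child_level = "branch")
      og <- merge(og, agg, by = "organelle_id", all.x = TRUE, sort = TRUE)
    }
    im <- data.frame(frame = t - 1L, n_organelles = nrow(og),
                     n_branches = nrow(br), n_nodes = nrow(nd),
                     n_mask_voxels = sum(h$semantic))
    if (nrow(og)) {
      og2 <- og; og2$all <- 1L
      agg <- aggregate_features(og2, "all", og_intr,
                                stats = config$agg_stats,
                                child_level = "organelle")
      im <- cbind(im, agg[, -1, drop = FALSE])
    }
    if (nrow(vsub) && length(vox_feats)) {
      agg <- aggregate_features(cbind(vsub, all = 1L), "all", vox_feats,
                                stats = config$agg_stats, child_level = "voxel")
      im <- cbind(im, agg[, -1, drop = FALSE])
    }
    nd$frame <- br$frame <- og$frame <- t - 1L
    nodes_t[[t]] <- nd; branches_t[[t]] <- br; organelles_t[[t]] <- og
    image_t[[t]] <- im
  }
  rbind_fill <- function(lst) {
    lst <- lst[!vapply(lst, is.null, TRUE)]
    if (!length(lst)) return(NULL)
    cols <- unique(unlist(lapply(lst, names)))
    do.call(rbind, lapply(lst, function(df) {
      for (cn in setdiff(cols, names(df))) df[[cn]] <- NA
      df[, cols, drop = FALSE]
    }))
  }
  tables <- list(voxel = voxels, node = rbind_fill(nodes_t),
                 branch = rbind_fill(branches_t),
                 organelle = rbind_fill(organelles_t),
                 image = rbind_fill(image_t))
  say("features [%.1fs]", proc.time()[3] - t0)

  tracks <- NULL
  if (nT > 1 && nrow(hier[[1]]$nodes)) {
    seeds <- as.matrix(hier[[1]]$nodes[, c("z", "y", "x")])
    tracks <- propagate_tracks(seeds, tracking, dim3, spacing, t0 = 1,
                               max_travel_um = config$max_travel_um)
  }

  result <- structure(list(
    stack = stack, scales = scales, enhanced = enh, hierarchies = hier,
    tracking = tracking, tables = tables, tracks = tracks,
    config = config, frame_interval = fi), class = "PipelineResult")
  if (!is.null(out_dir)) result$manifest <- write_outputs(out_dir, result)
  say("pipeline done [%.1fs total]", proc.time()[3] - t_all)
  result
}

flatten_marker_table <- function(markers) {
  do.call(rbind, lapply(seq_along(markers), function(t) {
    mk <- markers[[t]]
    if (!nrow(mk)) return(NULL)
    out <- data.frame(frame = t - 1L, marker_id = mk$marker_id,
                      z = mk$z, y = mk$y, x = mk$x, radius_um = mk$radius_um)
    if (!is.null(mk$stats_vec)) {
      sv <- mk$stats_vec; colnames(sv) <- paste0("stats_", 0:3)
      hv <- mk$hu_vec; colnames(hv) <- paste0("hu_", seq_len(ncol(hv)) - 1L)
      out <- cbind(out, sv, hv)
    }
    out
  }))
}

flatten_link_table <- function(links) {
  do.call(rbind, lapply(seq_along(links), function(t) {
    res <- NULL
    for (dir in c("forward", "backward")) {
      lk <- links[[t]][[dir]]$links
      if (nrow(lk))
        res <- rbind(res, cbind(data.frame(frame = t - 1L, direction = dir),
                                lk))
    }
    res
  }))
}

#' Write all pipeline outputs to a run directory
#'
#' Label images (semantic, organelle, branch, node assignment) as OME-TIFF
#' with voxel-size metadata, markers/links/tracks and all per-level feature
#' tables as CSV, a generated data dictionary, and a JSON manifest listing
#' files, parameters and the package version. Writing is deterministic:
#' identical results produce byte-identical files.
#'
#' @param run_dir output directory (created if needed).
#' @param result a `PipelineResult`.
#' @return the manifest list, invisibly written to `manifest.json`.
#' @export
write_outputs <- function(run_dir, result) {
  if (!dir.exists(run_dir)) dir.create(run_dir, recursive = TRUE)
  if (file.access(run_dir, 2) != 0) stop("run directory not writable: ", run_dir)
  hier <- result$hierarchies
  nT <- length(hier)
  dim3 <- dim(hier[[1]]$semantic)
  spacing <- hier[[1]]$spacing
  fi <- result$frame_interval
  files <- character()
  stack4 <- function(get) {
    a <- array(0, c(nT, dim3))
    for (t in seq_len(nT)) a[t, , , ] <- get(hier[[t]])
    a
  }
  wr <- function(name, data, dtype) {
    p <- file.path(run_dir, name)
    write_ome_tiff(data, p, spacing, if (nT > 1) fi else NULL, dtype = dtype)
    files <<- c(files, name)
  }
  wr("labels_semantic.ome.tif", stack4(function(h) h$semantic * 1L), "uint8")
  wr("labels_organelle.ome.tif", stack4(function(h) h$organelle_labels), "uint32")
  wr("labels_branch.ome.tif", stack4(function(h) h$branch_labels), "uint32")
  wr("labels_node.ome.tif", stack4(function(h) h$voxel_to_node), "uint32")
  if (isTRUE(result$config$save_enhanced)) {
    a <- array(0, c(nT, dim3))
    for (t in seq_len(nT)) a[t, , , ] <- result$enhanced[[t]]$response
    wr("enhanced.ome.tif", a, "float32")
  }
  wcsv <- function(df, name) {
    if (is.null(df) || !nrow(df)) return(invisible(NULL))
    utils::write.csv(df, file.path(run_dir, name), row.names = FALSE)
    files <<- c(files, name)
  }
  for (lv in names(result$tables))
    wcsv(result$tables[[lv]], paste0("features_", lv, ".csv"))
  if (!is.null(result$tracking)) {
    wcsv(flatten_marker_table(result$tracking$markers), "markers.csv")
    wcsv(flatten_link_table(result$tracking$links), "links.csv")
  }
  wcsv(result$tracks, "tracks.csv")
  # data dictionary: columns of every table
  dict <- do.call(rbind, lapply(names(result$tables), function(lv) {
    df <- result$tables[[lv]]
    if (is.null(df)) return(NULL)
    data.frame(level = lv, column = names(df))
  }))
  wcsv(dict, "data_dictionary.csv")
  cfg <- result$config
  cfg <- lapply(unclass(cfg), function(x) if (is.null(x)) NA else x)
  manifest <- list(
    software = "organellometry",
    version = as.character(utils::packageVersion("organellometry")),
    n_frames = nT, dim_zyx = as.integer(dim3), spacing_um = spacing,
    frame_interval_s = if (nT > 1) fi else NA,
    parameters = cfg, files = sort(files))
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  invisible(manifest)
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat("PipelineResult:", length(x$hierarchies), "frame(s)\n")
  for (lv in names(x$tables)) {
    df <- x$tables[[lv]]
    cat(sprintf("  %-10s %s\n", lv,
                if (is.null(df)) "(empty)" else
                  paste(nrow(df), "rows x", ncol(df), "cols")))
  }
  invisible(x)
}
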