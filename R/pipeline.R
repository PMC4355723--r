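#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis: input (a labelled
#' NIfTI volume, a [phantom_spec()], or `NULL` for the default Latimeria
#' phantom), smoothing, axis-pairing strategy, torus parameters, sweep
#' scales, seed and output directory.
#'
#' @param input `NULL` (default phantom), a [phantom_spec()], or a path
#'   to a labelled NIfTI volume.
#' @param sac_label Label id of the rostral sac / medial cavity.
#' @param voxel_size Phantom voxel size, mm (ignored for file input).
#' @param jitter Apply seeded segmentation jitter to a generated phantom?
#' @param smoothing `"swd"` (default, matching the analysis this package
#'   models) or `"none"`.
#' @param swd_order SWD truncation `L = N` (5 or 7 are the published
#'   choices; any positive order is accepted).
#' @param strategy Dipole axis strategy, `"baseline"` (default; the
#'   tip-to-tip dipole moment of each rabbit-ears pair) or `"bisector"`.
#' @param torus_a,torus_b Shared torus hole/tube radii, mm; defaults from
#'   [latimeria_torus_defaults()].
#' @param sweep_scales Tube-radius scale factors for [gain_sweep()].
#' @param overlap_voxel Overlap grid spacing, mm.
#' @param clip `"anterior"` (default) restricts the balanced region to
#'   the half-space anterior of the forwardmost antenna centre (the
#'   ambient water in front of the head); `"none"` keeps the pure
#'   three-torus intersection.
#' @param strike_range_mm Behavioural strike-distance band, mm.
#' @param seed Integer seed for all stochastic elements.
#' @param out_dir Optional output directory for CSV/JSON/PLY/log files.
#' @param write_meshes Write PLY meshes of the tori and overlap when
#'   `out_dir` is set?
#' @param overwrite Allow writing into a non-empty `out_dir`?
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, sac_label = 7L, voxel_size = 1,
                            jitter = FALSE,
                            smoothing = c("swd", "none"), swd_order = 7L,
                            strategy = c("baseline", "bisector"),
                            torus_a = latimeria_torus_defaults()$a,
                            torus_b = latimeria_torus_defaults()$b,
                            sweep_scales = c(0.5, 1, 1.5, 2),
                            overlap_voxel = 2,
                            clip = c("anterior", "none"),
                            strike_range_mm = c(100, 200),
                            seed = 1L, out_dir = NULL,
                            write_meshes = !is.null(out_dir),
                            overwrite = FALSE) {
  smoothing <- match.arg(smoothing)
  strategy <- match.arg(strategy)
  clip <- match.arg(clip)
  stopifnot(voxel_size > 0, swd_order >= 1, torus_a >= 0, torus_b > 0,
            overlap_voxel > 0, length(sweep_scales) >= 2L,
            all(sweep_scales > 0), length(strike_range_mm) == 2L)
  structure(
    list(input = input, sac_label = as.integer(sac_label),
         voxel_size = voxel_size, jitter = jitter,
         smoothing = smoothing, swd_order = as.integer(swd_order),
         strategy = strategy, torus_a = torus_a, torus_b = torus_b,
         sweep_scales = sweep_scales, overlap_voxel = overlap_voxel,
         clip = clip, strike_range_mm = strike_range_mm,
         seed = as.integer(seed), out_dir = out_dir,
         write_meshes = isTRUE(write_meshes), overwrite = overwrite),
    class = "pipeline_config")
}

#' Pair tubule records into dipole antennas
#'
#' Groups records by structure (name stripped of its `_L`/`_R` suffix)
#' and builds one [pair_dipole()] per complete left/right pair. Warns
#' when the array does not consist of exactly three pairs, since the
#' balanced-sensitivity construction of the full rostral organ rests on
#' three tori.
#'
#' @param records Output of [tubule_morphometry()].
#' @param strategy Passed to [pair_dipole()].
#' @return List of [antenna_pair()] objects.
#' @export
build_antennas <- function(records, strategy = "baseline") {
  stem <- sub("_[LR]$", "", records$name)
  out <- list()
  for (s in unique(stem)) {
    rows <- records[stem == s, , drop = FALSE]
    li <- grep("_L$", rows$name)
    ri <- grep("_R$", rows$name)
    if (length(li) != 1L || length(ri) != 1L) {
      warning("structure '", s, "' lacks a complete left/right pair; skipped")
      next
    }
    out[[s]] <- pair_dipole(rows[li, ], rows[ri, ], strategy = strategy,
                            name = s)
  }
  if (length(out) != 3L)
    warning("array has ", length(out), " antenna pair(s); the published ",
            "three-torus construction is not matched")
  out
}

#' Structure-dimension and orientation report tables
#'
#' Builds the two standard report tables: per-structure volumes and
#' lengths with left/right mean and n-1 SD columns (plus the medial
#' cavity and whole-organ total), and per-tubule orientation angles.
#'
#' @param records Output of [tubule_morphometry()].
#' @param sac_volume Medial-cavity volume, mm^3 (or `NA`).
#' @param out_dir Optional directory; writes `dimensions.csv` and
#'   `orientations.csv` there.
#' @return List of two `data.frame`s: `dimensions`, `orientations`.
#' @export
report_tables <- function(records, sac_volume = NA_real_, out_dir = NULL) {
  dims <- data.frame(structure = character(), side = character(),
                     volume = numeric(), mean_volume = numeric(),
                     sd_volume = numeric(), length = numeric(),
                     mean_length = numeric(), sd_length = numeric())
  if (nrow(records)) {
    stem <- sub("_[LR]$", "", records$name)
    side <- ifelse(grepl("_L$", records$name), "L",
                   ifelse(grepl("_R$", records$name), "R", NA))
    for (s in unique(stem)) {
      sel <- which(stem == s)
      li <- sel[side[sel] == "L"][1]
      ri <- sel[side[sel] == "R"][1]
      if (is.na(li) || is.na(ri)) {
        warning("structure '", s, "' lacks a pair member; ",
                "mean/SD left blank")
        vs <- ls_ <- c(NA_real_, NA_real_)
      } else {
        vs <- unlist(pair_summary(records$volume[li],
                                  records$volume[ri])[c("mean", "sd")])
        ls_ <- unlist(pair_summary(records$length[li],
                                   records$length[ri])[c("mean", "sd")])
      }
      for (i in sel) {
        first <- i == sel[1]
        dims <- rbind(dims, data.frame(
          structure = s, side = side[i], volume = records$volume[i],
          mean_volume = if (first) vs[1] else NA_real_,
          sd_volume = if (first) vs[2] else NA_real_,
          length = records$length[i],
          mean_length = if (first) ls_[1] else NA_real_,
          sd_length = if (first) ls_[2] else NA_real_))
      }
    }
    dims <- rbind(dims,
      data.frame(structure = "medial_cavity", side = NA,
                 volume = sac_volume, mean_volume = NA, sd_volume = NA,
                 length = NA, mean_length = NA, sd_length = NA),
      data.frame(structure = "full_rostral_organ", side = NA,
                 volume = total_volume(c(records$volume,
                                         sac_volume[!is.na(sac_volume)])),
                 mean_volume = NA, sd_volume = NA, length = NA,
                 mean_length = NA, sd_length = NA))
  }
  orient <- records[, intersect(c("name", "alpha_v", "alpha_h",
                                  "axis_x", "axis_y", "axis_z"),
                                names(records)), drop = FALSE]
  rownames(dims) <- rownames(orient) <- NULL
  if (!is.null(out_dir)) {
    utils::write.csv(dims, file.path(out_dir, "dimensions.csv"),
                     row.names = FALSE)
    utils::write.csv(orient, file.path(out_dir, "orientations.csv"),
                     row.names = FALSE)
  }
  list(dimensions = dims, orientations = orient)
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Phantom generation (or volume loading), optional SWD smoothing,
#' per-tubule morphometry, report tables, antenna construction, the
#' three-torus balanced-sensitivity overlap, the gain-band sweep, and
#' the behavioural strike-range check. Fully deterministic under a fixed
#' seed. When `config$out_dir` is set, writes `dimensions.csv`,
#' `orientations.csv`, `overlap.json`, `sweep.csv`, `run.log` and
#' (optionally) PLY meshes; an existing non-empty directory is an error
#' unless `overwrite = TRUE`.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result`: `records`, `tables`,
#'   `antennas`, `tori`, `overlap`, `sweep`, `strike`, `truth` (for
#'   generated phantoms), `log`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- c(sprintf("seed: %d", config$seed),
           sprintf("smoothing: %s (L = N = %d)", config$smoothing,
                   config$swd_order),
           sprintf("strategy: %s", config$strategy),
           sprintf("torus: a = %g mm, b = %g mm", config$torus_a,
                   config$torus_b),
           sprintf("sweep scales: %s",
                   paste(config$sweep_scales, collapse = ", ")),
           sprintf("overlap grid: %g mm, clip: %s", config$overlap_voxel,
                   config$clip))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(list.files(out_dir)) &&
        !config$overwrite)
      stop("out_dir '", out_dir, "' is not empty; set overwrite = TRUE")
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  truth <- NULL
  mouth <- snout <- NULL
  vol <- pipeline_stage("input", {
    if (is.null(config$input) || inherits(config$input, "phantom_spec")) {
      spec <- if (is.null(config$input))
        latimeria_phantom_spec(voxel_size = config$voxel_size)
      else config$input
      ph <- make_head_phantom(spec, seed = config$seed,
                              jitter = config$jitter)
      truth <- ph$truth
      mouth <- spec$mouth_landmark
      snout <- spec$snout_landmark
      log <- c(log, sprintf("input: generated phantom (%s voxels at %g mm)",
                            paste(spec$grid_shape, collapse = "x"),
                            spec$voxel_size),
               sprintf("jitter: %s", config$jitter))
      ph$volume
    } else {
      log <- c(log, sprintf("input: %s", config$input))
      read_labeled_volume(config$input)
    }
  })
  records <- pipeline_stage("morphometry",
    tubule_morphometry(vol, sac_label = config$sac_label,
                       smoothing = if (config$smoothing == "swd") "swd"
                                   else "none",
                       L = config$swd_order, N = config$swd_order))
  sac_vol <- pipeline_stage("morphometry",
    label_volume(vol, config$sac_label))
  tables <- pipeline_stage("report",
    report_tables(records, sac_volume = sac_vol, out_dir = out_dir))
  antennas <- pipeline_stage("antenna",
    build_antennas(records, strategy = config$strategy))
  tori <- lapply(antennas, function(ant)
    torus(ant$center, ant$axis, config$torus_a, config$torus_b))
  clip_plane <- if (config$clip == "anterior") {
    xs <- vapply(antennas, function(a) a$center[1], numeric(1))
    list(point = c(max(xs), 0, 0), normal = c(1, 0, 0))
  }
  overlap <- pipeline_stage("overlap",
    overlap_region(tori, voxel_size = config$overlap_voxel,
                   mouth_landmark = mouth, clip_plane = clip_plane))
  sweep <- pipeline_stage("sweep",
    gain_sweep(antennas, config$sweep_scales, a = config$torus_a,
               b = config$torus_b, voxel_size = config$overlap_voxel,
               mouth_landmark = mouth, clip_plane = clip_plane))
  strike <- if (!overlap$empty && !is.null(snout))
    pipeline_stage("strike",
      calibrate_strike_range(overlap, snout,
                             range_mm = config$strike_range_mm))
  log <- c(log,
           sprintf("tubule records: %d", nrow(records)),
           sprintf("antennas: %d", length(antennas)),
           sprintf("overlap volume: %.1f mm^3", overlap$volume),
           if (!overlap$empty)
             sprintf("overlap centroid: (%.1f, %.1f, %.1f) mm",
                     overlap$centroid[1], overlap$centroid[2],
                     overlap$centroid[3]),
           if (!is.null(strike))
             sprintf("strike distance: %.1f mm (in range: %s)",
                     strike$distance, strike$in_range))
  if (!is.null(out_dir)) {
    ovj <- list(volume = overlap$volume, n_voxels = overlap$n_voxels,
                centroid = unname(overlap$centroid),
                equivalent_sphere_radius =
                  overlap$equivalent_sphere_radius,
                distance_to_mouth = overlap$distance_to_mouth,
                strike = strike)
    jsonlite::write_json(ovj, file.path(out_dir, "overlap.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    utils::write.csv(sweep, file.path(out_dir, "sweep.csv"),
                     row.names = FALSE)
    if (config$write_meshes) {
      for (nm in names(tori))
        write_ply(torus_mesh(tori[[nm]], voxel_size = 4),
                  file.path(out_dir, paste0("torus_", nm, ".ply")))
      if (!overlap$empty)
        write_ply(boundary_quad_mesh(overlap$mask, overlap$voxel_size,
                                     overlap$origin),
                  file.path(out_dir, "overlap.ply"))
    }
    writeLines(log, file.path(out_dir, "run.log"))
  }
  structure(list(records = records, tables = tables, antennas = antennas,
                 tori = tori, overlap = overlap, sweep = sweep,
                 strike = strike, truth = truth, log = log),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  cat(sprintf("  %d tubule records, %d antennas\n", nrow(x$records),
              length(x$antennas)))
  print(x$overlap)
  invisible(x)
}
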