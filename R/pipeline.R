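#' Build a phantom specification from a plain (YAML-style) list
#'
#' Converts the nested-list form used in configuration files into a
#' validated [phantom_spec()]. Tumor entries are lists with `center`,
#' `radius` and the optional [tumor_spec()] fields.
#'
#' @param pl plain list, e.g. from [yaml::read_yaml()].
#' @return a [phantom_spec()].
#' @export
as_phantom_spec <- function(pl) {
  if (inherits(pl, "phantom_spec")) return(pl)
  tumors <- lapply(pl$tumors, function(tm)
    tumor_spec(center = unlist(tm$center), radius = tm$radius,
               shape_irregularity = tm$shape_irregularity %||% 0,
               boundary_sharpness = tm$boundary_sharpness %||% "sharp",
               ramp_width = tm$ramp_width %||% 2))
  args <- list(
    grid_shape = unlist(pl$grid_shape %||% c(96, 96, 96)),
    voxel_size_um = pl$voxel_size_um %||% 13,
    n_vessels = pl$n_vessels %||% 6,
    vessel_radius = unlist(pl$vessel_radius %||% c(1, 2)),
    tumors = tumors,
    halo_thickness = unlist(pl$halo_thickness %||% 0),
    noise_sigma = pl$noise_sigma %||% 800,
    rng_seed = pl$rng_seed %||% 1,
    well_separated = pl$well_separated %||% FALSE)
  if (!is.null(pl$lung)) args$lung <- lapply(pl$lung, unlist)
  if (!is.null(pl$airway_tree)) args$airway_tree <-
      lapply(pl$airway_tree, unlist)
  if (!is.null(pl$intensity)) args$intensity <- pl$intensity
  do.call(phantom_spec, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and validate a pipeline run configuration
#'
#' A run configuration (YAML) names either a `phantom` spec or an input
#' `volume` path, the segmentation parameter groups (`lung`, `airways`,
#' `tumors`), an optional `slice` selection and the top-level `rng_seed`.
#' Referenced files must exist at validation time and every seed group must
#' carry parameters.
#'
#' @param path YAML file path, or an already-parsed list.
#' @return validated configuration list (class `lb_run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(cfg$phantom) && is.null(cfg$volume))
    stop("config needs either a 'phantom' spec or an input 'volume' path")
  if (!is.null(cfg$volume) && !file.exists(cfg$volume))
    stop("input volume does not exist: ", cfg$volume)
  if (!is.null(cfg$labels) && !file.exists(cfg$labels))
    stop("label volume does not exist: ", cfg$labels)
  if (is.null(cfg$lung) || is.null(cfg$lung$background_threshold))
    stop("seed group 'lung' needs a background_threshold")
  if (!is.null(cfg$airways) && is.null(cfg$airways$tolerance))
    stop("seed group 'airways' needs a tolerance")
  if (is.null(cfg$tumors) || is.null(cfg$tumors$tolerance))
    stop("seed group 'tumors' needs a tolerance")
  cfg$rng_seed <- cfg$rng_seed %||% 1L
  class(cfg) <- c("lb_run_config", "list")
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

log_stage <- function(quiet, ...) if (!quiet) message("[lungburden] ", ...)

#' Run the full phantom-to-report pipeline
#'
#' Executes scan-surrogate -> segmentation -> quantification: generates (or
#' loads) the volume, extracts the organ mask, optionally segments airways,
#' region-grows the tumors, and writes masks, the gray-value histogram
#' split, the Table-style burden report CSV, a full-precision report and a
#' provenance file into `out_dir`. All randomness flows from the single
#' top-level `rng_seed`; re-running an identical configuration reproduces
#' byte-identical outputs.
#'
#' @param config run configuration (path or list; see [read_run_config()]).
#' @param out_dir output directory (created if needed).
#' @param quiet suppress stage log messages.
#' @return invisibly, a list with the report and the written file paths.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  cfg <- stage("config", read_run_config(config))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- list()

  spec <- NULL
  if (!is.null(cfg$phantom)) {
    res <- stage("phantom", {
      spec <- as_phantom_spec(cfg$phantom)
      spec$rng_seed <- as.integer(cfg$rng_seed)
      ph <- generate_phantom(spec)
      write_phantom(ph, out_dir)
      ph
    })
    spec <- res$spec
    vol <- res$volume; labels <- res$labels
    paths$volume <- file.path(out_dir, "volume.tif")
    paths$labels <- file.path(out_dir, "labels.tif")
    log_stage(quiet, "phantom: ", prod(dim(vol)), " voxels, ",
              sum(labels == 2L), " tumor voxels (truth)")
  } else {
    vol <- stage("load", read_volume(cfg$volume,
                                     voxel_size_um = cfg$voxel_size_um))
    labels <- if (!is.null(cfg$labels))
      stage("load", read_labels(cfg$labels,
                                voxel_size_um = cfg$voxel_size_um))
    else NULL
    log_stage(quiet, "loaded volume: ", prod(dim(vol)), " voxels")
  }

  # optional denoising feeds the masks and growths; histogram stays raw
  work <- if ((cfg$presmooth_radius %||% 0) > 0)
    smooth_volume(vol, cfg$presmooth_radius) else vol

  lung <- stage("segment:lung", compute_lung_mask(
    work, cfg$lung$background_threshold,
    closing_radius = cfg$lung$closing_radius %||% 3,
    fill_airways = cfg$lung$fill_airways %||% TRUE))
  paths$lung_mask <- file.path(out_dir, "lung_mask.tif")
  write_mask(lung, paths$lung_mask)
  log_stage(quiet, "lung mask: ", sum(lung), " voxels")

  airway_mask <- NULL
  if (!is.null(cfg$airways)) {
    aw <- stage("segment:airways", {
      seed <- cfg$airways$seed
      if (is.null(seed)) {
        if (is.null(spec)) stop("airway seed required for non-phantom input")
        seed <- trachea_seed(spec)
      }
      segment_airways(work, unlist(seed),
                      region_grow_params(
                        cfg$airways$tolerance,
                        radius_um = cfg$airways$radius_um,
                        connectivity = cfg$airways$connectivity %||% 26),
                      lung)
    })
    airway_mask <- aw$mask
    paths$airway_mask <- file.path(out_dir, "airway_mask.tif")
    write_mask(airway_mask, paths$airway_mask)
    log_stage(quiet, "airways: ", aw$voxel_count, " voxels")
  }

  seg <- stage("segment:tumors", {
    seeds <- cfg$tumors$seeds
    if (identical(seeds, "centers") || is.null(seeds)) {
      if (is.null(spec))
        stop("tumor seeds required for non-phantom input")
      seeds <- lapply(spec$tumors, function(tm) as.integer(round(tm$center)))
    } else seeds <- lapply(seeds, unlist)
    segment_tumors(work, seeds,
                   region_grow_params(
                     cfg$tumors$tolerance,
                     radius_um = cfg$tumors$radius_um,
                     connectivity = cfg$tumors$connectivity %||% 26),
                   lung,
                   exclude = if (isTRUE(cfg$tumors$exclude_airways) &&
                                 !is.null(airway_mask)) airway_mask)
  })
  paths$tumor_mask <- file.path(out_dir, "tumor_mask.tif")
  write_mask(seg$mask, paths$tumor_mask)
  log_stage(quiet, "tumors: ", seg$voxel_count, " voxels from ",
            nrow(seg$seeds), " seed(s)")

  report <- stage("quantify", {
    axis <- cfg$slice$axis %||% 1
    idx <- cfg$slice$index %||% "central"
    if (identical(idx, "central")) {
      ext <- which(apply(lung, axis, any))
      idx <- ext[ceiling(length(ext) / 2)]
    }
    hs <- histogram_split(vol, lung, seg$mask,
                          n_bins = cfg$histogram_bins %||% 64)
    paths$histogram <- file.path(out_dir, "histogram.csv")
    write.csv(data.frame(bin_low = hs$bin_edges[-length(hs$bin_edges)],
                         bin_high = hs$bin_edges[-1],
                         count_total = hs$counts_total,
                         count_segmented = hs$counts_segmented),
              paths$histogram, row.names = FALSE, quote = FALSE)
    build_report(list(tumor = seg, lung = lung), labels = labels,
                 slice = list(axis = axis, index = idx),
                 sample_id = cfg$sample_id %||% "sample")
  })
  paths$report <- file.path(out_dir, "report.csv")
  write_burden_csv(report, paths$report)
  paths$report_full <- file.path(out_dir, "report_full.csv")
  write.csv(report, paths$report_full, row.names = FALSE, quote = FALSE)
  log_stage(quiet, sprintf(
    "burden: 3D %.2f %%, 2D slice %.2f %% (slice %d)",
    report$burden_3d_microct_percent, report$burden_2d_microct_percent,
    report$slice_index))

  prov <- list(package = "lungburden",
               version = as.character(utils::packageVersion("lungburden")),
               rng_seed = cfg$rng_seed,
               config = unclass(cfg))
  paths$provenance <- file.path(out_dir, "provenance.yaml")
  yaml::write_yaml(prov, paths$provenance)

  invisible(list(report = report, paths = paths))
}

#' Built-in demonstration configuration
#'
#' A self-contained 64-cube phantom run: three tumors (two sharp, one
#' diffuse), a bifurcating airway tree, moderate noise, airway segmentation
#' excluded from the tumor domain, and the central virtual slice for the 2D
#' columns.
#'
#' @param rng_seed top-level seed for the run.
#' @return configuration list accepted by [run_pipeline()].
#' @export
demo_config <- function(rng_seed = 1) {
  list(
    sample_id = "demo",
    rng_seed = as.integer(rng_seed),
    phantom = list(
      grid_shape = c(64, 64, 64),
      voxel_size_um = 13,
      n_vessels = 5,
      tumors = list(
        list(center = c(36, 24, 24), radius = 7),
        list(center = c(44, 40, 38), radius = 5,
             shape_irregularity = 0.25),
        list(center = c(28, 40, 26), radius = 6,
             boundary_sharpness = "diffuse", ramp_width = 2)),
      noise_sigma = 800,
      rng_seed = as.integer(rng_seed)),
    lung = list(background_threshold = 15500, closing_radius = 4),
    airways = list(tolerance = 8000),
    tumors = list(seeds = "centers", tolerance = 20000,
                  exclude_airways = TRUE),
    slice = list(axis = 1, index = "central"),
    histogram_bins = 64)
}
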