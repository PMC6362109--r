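#' Volumetric fraction of one mask within another
#'
#' The 3D tumor burden: the ratio of segmented voxels to all voxels of the
#' specimen, in percent. `part` is intersected with `whole` first.
#'
#' @param part logical mask of the structure of interest (e.g. tumors).
#' @param whole logical mask of the whole specimen.
#' @return percentage in `[0, 100]`.
#' @export
volume_fraction <- function(part, whole) {
  assert_mask(part, what = "part")
  assert_mask(whole, dim(part), "whole")
  w <- sum(whole)
  if (w == 0) stop("whole mask is empty")
  100 * sum(part & whole) / w
}

#' Gray-value histogram of the whole specimen and its segmented part
#'
#' Two aligned histograms over identical bin edges spanning the gray range
#' inside `whole`: one for every specimen voxel, one for the segmented
#' subset. This is the standard display for intensity-based burden
#' estimation: the segmented part re-expressed in terms of gray values.
#'
#' @param vol a [vox_volume()].
#' @param whole specimen mask.
#' @param part segmented mask (intersected with `whole`).
#' @param n_bins number of bins (`>= 2`).
#' @return `lb_histogram_split`: list with `bin_edges`, `counts_total`,
#'   `counts_segmented`, `segmented_fraction_percent`.
#' @export
histogram_split <- function(vol, whole, part, n_bins = 64) {
  if (!inherits(vol, "vox_volume")) vol <- vox_volume(vol)
  assert_mask(whole, dim(vol), "whole")
  assert_mask(part, dim(vol), "part")
  if (n_bins < 2) stop("n_bins must be >= 2")
  if (!any(whole)) stop("whole mask is empty")
  g_all <- as.vector(vol)[whole]
  g_seg <- as.vector(vol)[part & whole]
  rng <- range(g_all)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin_of <- function(g) findInterval(g, edges, rightmost.closed = TRUE,
                                     all.inside = TRUE)
  structure(list(
    bin_edges = edges,
    counts_total = tabulate(bin_of(g_all), nbins = n_bins),
    counts_segmented = tabulate(bin_of(g_seg), nbins = n_bins),
    segmented_fraction_percent = 100 * length(g_seg) / length(g_all)),
    class = "lb_histogram_split")
}

#' @export
print.lb_histogram_split <- function(x, ...) {
  cat(sprintf(paste0("<lb_histogram_split> %d bins over gray %.0f..%.0f, ",
                     "segmented fraction %.1f %%\n"),
              length(x$counts_total), min(x$bin_edges), max(x$bin_edges),
              x$segmented_fraction_percent))
  invisible(x)
}

#' Area fraction of one mask within another on a single virtual slice
#'
#' The 2D analogue of [volume_fraction()]: the cross-sectional tumor area
#' fraction on one plane of the volume, as measured on a histological
#' section or a virtual micro-CT slice.
#'
#' @param part,whole logical masks as in [volume_fraction()].
#' @param axis slicing axis (1 = z, the default virtual-slice axis).
#' @param index slice index along `axis` (1-based).
#' @return percentage in `[0, 100]`.
#' @export
slice_burden <- function(part, whole, axis = 1, index) {
  assert_mask(part, what = "part")
  assert_mask(whole, dim(part), "whole")
  d <- dim(part)
  if (!axis %in% 1:3) stop("axis must be 1, 2 or 3")
  if (index < 1 || index > d[axis])
    stop("slice index ", index, " outside axis ", axis, " extent 1..",
         d[axis])
  sl <- function(m) switch(axis, m[index, , ], m[, index, ], m[, , index])
  w <- sl(whole)
  if (!any(w)) stop("no lung tissue in slice ", index, " along axis ", axis)
  100 * sum(sl(part & whole)) / sum(w)
}

#' Burden report: 2D histology surrogate vs 2D and 3D micro-CT estimates
#'
#' Fills the three-method comparison for one sample: (1) the histology
#' surrogate - the ground-truth tumor label restricted to one slice, which
#' emulates a pathologist's annotation and deliberately excludes halo tissue;
#' (2) the segmentation-based area fraction on the same virtual slice; and
#' (3) the segmentation-based volume fraction over the whole organ. With
#' ground-truth labels also the true 3D burden and signed errors
#' (estimate - truth).
#'
#' @param masks list with logical masks `tumor` and `lung` (segmentation
#'   results or plain masks).
#' @param labels optional [label_volume()] ground truth (phantom runs).
#' @param slice list with `axis` and `index` selecting the virtual slice;
#'   required for the 2D columns.
#' @param sample_id sample identifier for the report row.
#' @return `lb_burden_report`: a one-row data frame with class attributes.
#' @export
build_report <- function(masks, labels = NULL, slice = list(axis = 1),
                         sample_id = "sample") {
  tumor <- if (inherits(masks$tumor, "lb_segmentation")) masks$tumor$mask
           else masks$tumor
  lung <- if (inherits(masks$lung, "lb_segmentation")) masks$lung$mask
          else masks$lung
  assert_mask(tumor, what = "tumor mask")
  assert_mask(lung, dim(tumor), "lung mask")
  if (is.null(slice$axis) || is.null(slice$index))
    stop("slice selection (axis + index) is required for the 2D columns")

  burden_3d <- volume_fraction(tumor, lung)
  burden_2d_ct <- slice_burden(tumor, lung, slice$axis, slice$index)

  burden_2d_truth <- NA_real_
  true_3d <- NA_real_
  if (!is.null(labels)) {
    if (!inherits(labels, "label_volume"))
      stop("labels must be a label_volume")
    l <- array(as.integer(labels), dim = dim(labels))
    truth_tumor <- l == 2L          # label 2 only: halo never counts
    truth_lung <- l != 0L
    burden_2d_truth <- slice_burden(truth_tumor, truth_lung, slice$axis,
                                    slice$index)
    true_3d <- true_burden(labels)
  }
  rep <- data.frame(
    sample = sample_id,
    burden_2d_truth_percent = burden_2d_truth,
    burden_2d_microct_percent = burden_2d_ct,
    burden_3d_microct_percent = burden_3d,
    true_3d_percent = true_3d,
    error_2d_microct = burden_2d_ct - true_3d,
    error_3d_microct = burden_3d - true_3d,
    slice_axis = slice$axis,
    slice_index = slice$index,
    stringsAsFactors = FALSE)
  class(rep) <- c("lb_burden_report", "data.frame")
  rep
}

#' @export
print.lb_burden_report <- function(x, ...) {
  cat("<lb_burden_report>\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a burden report as CSV with the three canonical method columns
#'
#' Columns: `sample`, `he_histological_slice` (histology surrogate, 2D),
#' `microct_virtual_slice` (2D micro-CT), `microct_volumetric_image`
#' (3D micro-CT). Percentages are rounded to one decimal place; the report
#' object retains full precision.
#'
#' @param report an `lb_burden_report` (possibly several rows).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_burden_csv <- function(report, path) {
  out <- data.frame(
    sample = report$sample,
    he_histological_slice = round(report$burden_2d_truth_percent, 1),
    microct_virtual_slice = round(report$burden_2d_microct_percent, 1),
    microct_volumetric_image = round(report$burden_3d_microct_percent, 1))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bias study: 2D and 3D burden estimators against phantom truth
#'
#' Replicates a phantom family over seeds, runs the full estimation chain on
#' each replicate (organ mask, tumor region growing seeded at the true tumor
#' centers - standing in for the operator's interactive clicks - and the
#' three-method report), and aggregates signed errors. This quantifies the
#' two bias mechanisms of intensity-based burden estimation: halo tissue
#' inflates the 3D estimate, and a single 2D slice misses out-of-plane
#' tumor mass.
#'
#' @param base_spec a [phantom_spec()]; replicate `i` re-uses it with
#'   `rng_seed = rng_seed + i`.
#' @param n_replicates number of phantom replicates (`>= 1`).
#' @param tolerance region-growing tolerance; default: the tumor-parenchyma
#'   gray gap of the spec's intensity model.
#' @param slice_rule `"central"` (middle slice of the organ's z extent) or
#'   `"random"` (uniform over slices containing lung tissue).
#' @param rng_seed base seed for replicate phantoms and random slices.
#' @param background_threshold organ-mask threshold; default midway between
#'   the background and parenchyma means.
#' @param closing_radius closing radius for [compute_lung_mask()]; default
#'   one voxel above the trachea radius, so the airway opening is sealed.
#' @param connectivity growth connectivity (default 26).
#' @param presmooth_radius box-mean half-width applied by [smooth_volume()]
#'   before masking and growing (0, the default, disables it). Smoothing
#'   suppresses noise-driven leakage into the vessel gray class but
#'   under-segments tumors clipped at the organ surface; it is therefore
#'   opt-in.
#' @return list with `reports` (one `lb_burden_report` row per replicate)
#'   and `summary` (mean/sd of the signed 3D error, mean absolute 3D error,
#'   mean signed single-slice 2D error vs the true 3D burden, and the share
#'   of replicates whose absolute 3D error is below 1 percentage point).
#' @export
bias_study <- function(base_spec, n_replicates, tolerance = NULL,
                       slice_rule = c("central", "random"), rng_seed = 1,
                       background_threshold = NULL, closing_radius = NULL,
                       connectivity = 26, presmooth_radius = 0) {
  slice_rule <- match.arg(slice_rule)
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  im <- base_spec$intensity
  if (is.null(tolerance)) tolerance <- im$tumor - im$parenchyma
  if (is.null(background_threshold))
    background_threshold <- (im$background + im$parenchyma) / 2
  if (is.null(closing_radius))
    closing_radius <- ceiling(base_spec$airway_tree$radius) + 1

  rows <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    spec <- base_spec
    spec$rng_seed <- as.integer(rng_seed + i)
    ph <- generate_phantom(spec)
    work <- if (presmooth_radius > 0)
      smooth_volume(ph$volume, presmooth_radius) else ph$volume
    lung <- compute_lung_mask(work, background_threshold, closing_radius)
    seeds <- lapply(spec$tumors, function(tm) as.integer(round(tm$center)))
    seg <- segment_tumors(work, seeds,
                          region_grow_params(tolerance,
                                             connectivity = connectivity),
                          lung)
    zext <- which(apply(lung, 1, any))
    idx <- if (slice_rule == "central") {
      zext[ceiling(length(zext) / 2)]
    } else {
      set.seed(as.integer(rng_seed + 7919L * i) %% .Machine$integer.max)
      sample(zext, 1)
    }
    rows[[i]] <- build_report(list(tumor = seg, lung = lung),
                              labels = ph$labels,
                              slice = list(axis = 1, index = idx),
                              sample_id = paste0("replicate_", i))
  }
  reports <- do.call(rbind, rows)
  class(reports) <- c("lb_burden_report", "data.frame")
  err3 <- reports$error_3d_microct
  err2 <- reports$burden_2d_truth_percent - reports$true_3d_percent
  list(reports = reports,
       summary = list(
         n = n_replicates,
         mean_signed_error_3d = mean(err3),
         sd_signed_error_3d = if (n_replicates > 1) sd(err3) else NA_real_,
         mean_abs_error_3d = mean(abs(err3)),
         mean_signed_error_2d_vs_true3d = mean(err2),
         share_within_1pp_3d = mean(abs(err3) < 1)))
}
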