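#' Voxel volume container
#'
#' A `vox_volume` is a 3D numeric array of gray values with unsigned 16-bit
#' semantics (values in `[0, 65535]`) plus the physical voxel edge length in
#' micrometers. Axis order is `(z, y, x)` with axis 1 (`z`) the slicing axis
#' for virtual slices; indices are 1-based as usual in R.
#'
#' @param data numeric 3D array of gray values in `[0, 65535]`.
#' @param voxel_size_um voxel edge length in micrometers (isotropic voxels;
#'   reconstructed micro-CT data of the kind targeted here have voxel sizes
#'   around 12-13 um).
#' @return object of class `vox_volume` (the array, carrying
#'   `voxel_size_um` as an attribute).
#' @export
vox_volume <- function(data, voxel_size_um = 13) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("a vox_volume needs a 3D array, got ", length(dim(data)), " dims")
  if (any(dim(data) < 1L))
    stop("all three axes must be non-degenerate")
  rng <- range(data)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 65535)
    stop("gray values must lie in [0, 65535] with no NAs (observed range ",
         rng[1], "..", rng[2], ")")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      voxel_size_um <= 0)
    stop("voxel_size_um must be a single positive number")
  structure(data, voxel_size_um = as.numeric(voxel_size_um),
            class = c("vox_volume", "array"))
}

#' Ground-truth label volume
#'
#' Integer tissue-class labels co-registered with a phantom gray volume:
#' 0 background (ethanol bath), 1 lung parenchyma, 2 tumor, 3 airway lumen
#' (air), 4 halo / abnormal tissue, 5 vessel or airway wall. Labels partition
#' the grid: every voxel carries exactly one class.
#'
#' @param labels integer 3D array with values in 0..5.
#' @param voxel_size_um voxel edge length in micrometers.
#' @return object of class `label_volume`.
#' @export
label_volume <- function(labels, voxel_size_um = 13) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L)
    stop("a label_volume needs a 3D array")
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || any(labels < 0L | labels > 5L))
    stop("labels must be integers in 0..5")
  structure(labels, voxel_size_um = as.numeric(voxel_size_um),
            class = c("label_volume", "array"))
}

#' Voxel edge length of a volume or label grid
#' @param x a `vox_volume` or `label_volume`.
#' @return voxel edge length in micrometers.
#' @export
voxel_size <- function(x) {
  vs <- attr(x, "voxel_size_um")
  if (is.null(vs)) stop("object carries no voxel_size_um attribute")
  vs
}

#' @export
print.vox_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<vox_volume> %d x %d x %d voxels (z,y,x), %.4g um/voxel\n",
              d[1], d[2], d[3], voxel_size(x)))
  cat(sprintf("  gray range %s..%s, mean %.1f\n",
              format(min(x)), format(max(x)), mean(x)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<label_volume> %d x %d x %d voxels (z,y,x), %.4g um/voxel\n",
              d[1], d[2], d[3], voxel_size(x)))
  cls <- c("background", "parenchyma", "tumor", "airway lumen", "halo",
           "vessel/wall")
  tab <- tabulate(as.integer(x) + 1L, nbins = 6L)
  for (i in seq_along(cls))
    if (tab[i] > 0) cat(sprintf("  %-13s %d\n", cls[i], tab[i]))
  invisible(x)
}

#' True volumetric tumor burden from ground-truth labels
#'
#' Percentage of lung voxels carrying the tumor label, with the whole organ
#' (parenchyma, tumor, halo, vessels and - by default - enclosed airway
#' lumina) as denominator. This is the quantity the 2D and 3D estimators are
#' judged against on phantoms.
#'
#' @param labels a `label_volume`.
#' @param include_airways logical; count airway lumina in the organ
#'   denominator (default `TRUE`, the whole-organ reading).
#' @return tumor burden in percent.
#' @export
true_burden <- function(labels, include_airways = TRUE) {
  l <- as.integer(labels)
  denom_classes <- if (include_airways) 1:5 else c(1:2, 4:5)
  denom <- sum(l %in% denom_classes)
  if (denom == 0) stop("label volume contains no lung tissue")
  100 * sum(l == 2L) / denom
}

#' Dice overlap between two masks
#' @param a,b logical arrays of identical shape.
#' @return Dice coefficient `2|A and B| / (|A| + |B|)` in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

# internal: check a logical mask compatible with a reference grid
assert_mask <- function(mask, dim_ref = NULL, what = "mask") {
  if (!is.logical(mask) || length(dim(mask)) != 3L)
    stop(what, " must be a logical 3D array")
  if (!is.null(dim_ref) && !identical(dim(mask), as.integer(dim_ref)))
    stop(what, " has dims (", paste(dim(mask), collapse = ","),
         "), expected (", paste(dim_ref, collapse = ","), ")")
  invisible(TRUE)
}
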