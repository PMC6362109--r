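#' Region-growing parameters
#'
#' Parameters of the static-mode seeded flood fill: a voxel is accepted when
#' its gray value differs from the seed voxel's value by no more than half
#' the tolerance. The reference is the seed's gray value, fixed for the whole
#' growth (not a running mean), which makes the result deterministic and
#' monotone in the tolerance. An optional radius confines the growth to a
#' sphere around the seed - useful to keep a tumor growth out of the trachea.
#'
#' @param tolerance full width of the accepted gray-value range (`>= 0`);
#'   a voxel `v` is accepted when `|gray(v) - gray(seed)| <= tolerance / 2`.
#' @param radius_um optional sphere radius in micrometers measured between
#'   voxel centers; `NULL` means unlimited.
#' @param connectivity 6 (faces), 18 (faces + edges) or 26 (full cube).
#' @param reference reference convention; only `"seed"` (the seed voxel's
#'   fixed gray value) is implemented.
#' @return a `region_grow_params` list.
#' @export
region_grow_params <- function(tolerance, radius_um = NULL,
                               connectivity = 26, reference = "seed") {
  if (!is.numeric(tolerance) || tolerance < 0)
    stop("tolerance must be >= 0, got ", tolerance)
  if (!is.null(radius_um) && radius_um <= 0)
    stop("radius_um must be positive when given")
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  reference <- match.arg(reference, "seed")
  structure(list(tolerance = as.numeric(tolerance),
                 radius_um = if (is.null(radius_um)) NULL
                             else as.numeric(radius_um),
                 connectivity = as.integer(connectivity),
                 reference = reference),
            class = "region_grow_params")
}

# seeds -> n x 3 integer matrix of c(z,y,x), validated against grid/domain
normalize_seeds <- function(seeds, dim_ref, domain = NULL) {
  if (is.null(seeds) || length(seeds) == 0)
    return(matrix(integer(), 0, 3))
  if (is.numeric(seeds) && is.null(dim(seeds))) seeds <- list(seeds)
  if (is.list(seeds)) seeds <- do.call(rbind, lapply(seeds, as.integer))
  seeds <- matrix(as.integer(seeds), ncol = 3)
  for (i in seq_len(nrow(seeds))) {
    s <- seeds[i, ]
    if (any(s < 1L) || any(s > dim_ref))
      stop("seed (", paste(s, collapse = ","), ") lies outside the grid (",
           paste(dim_ref, collapse = ","), ")")
    if (!is.null(domain) && !domain[s[1], s[2], s[3]])
      stop("seed (", paste(s, collapse = ","),
           ") lies outside the segmentation domain")
  }
  seeds
}

#' Seeded 3D region growing with a static gray-value criterion
#'
#' Grows, breadth-first and independently from each seed, the maximal
#' connected set in which every voxel's gray value differs from the seed
#' voxel's value by at most `tolerance / 2`, stays inside `domain`, and (if a
#' radius is set) lies within `radius_um` of the seed center. The per-seed
#' regions are unioned, so the result does not depend on seed order.
#'
#' @param vol a [vox_volume()].
#' @param seeds one `c(z, y, x)` coordinate, a list of them, or an n x 3
#'   matrix (1-based voxel indices).
#' @param params a [region_grow_params()].
#' @param domain optional logical mask restricting the growth (default:
#'   whole grid). Exclusions must be carved out of the domain here, not
#'   subtracted afterwards, so growth cannot tunnel through excluded voxels.
#' @return a `lb_segmentation`: list with `mask` (logical array), `seeds`,
#'   `params` and `voxel_count`.
#' @export
region_grow <- function(vol, seeds, params, domain = NULL) {
  if (!inherits(vol, "vox_volume")) vol <- vox_volume(vol)
  if (!inherits(params, "region_grow_params"))
    stop("params must be a region_grow_params object")
  d <- dim(vol)
  if (is.null(domain)) domain <- array(TRUE, dim = d)
  assert_mask(domain, d, "domain")
  seeds <- normalize_seeds(seeds, d, domain)
  if (nrow(seeds) == 0) {
    mask <- array(FALSE, dim = d)
  } else {
    rvox <- if (is.null(params$radius_um)) -1
            else params$radius_um / voxel_size(vol)
    mask <- cpp_region_grow(as.double(vol), d, seeds - 1L,
                            params$tolerance, rvox, params$connectivity,
                            domain)
    dim(mask) <- d
  }
  structure(list(mask = mask, seeds = seeds, params = params,
                 voxel_count = sum(mask)),
            class = "lb_segmentation")
}

#' @export
print.lb_segmentation <- function(x, ...) {
  cat(sprintf("<lb_segmentation> %d voxels from %d seed(s), tolerance %g%s\n",
              x$voxel_count, nrow(x$seeds),
              if (is.data.frame(x$params)) NA else x$params$tolerance,
              if (!is.data.frame(x$params) && !is.null(x$params$radius_um))
                sprintf(", radius %g um", x$params$radius_um) else ""))
  invisible(x)
}

#' Box-mean smoothing of a volume
#'
#' Separable box-mean filter (window `2 * radius + 1` per axis, edges
#' clamped), the standard light denoising step before intensity-based
#' thresholding and region growing: a 3-cube mean cuts the noise standard
#' deviation by about a factor of five while shifting a step boundary by
#' less than a voxel.
#'
#' @param vol a [vox_volume()].
#' @param radius half-width of the box window in voxels (`>= 1`).
#' @return a smoothed [vox_volume()] (non-integer gray values).
#' @export
smooth_volume <- function(vol, radius = 1) {
  if (!inherits(vol, "vox_volume")) vol <- vox_volume(vol)
  if (radius < 1) stop("radius must be >= 1")
  out <- cpp_box_filter(as.double(vol), dim(vol), as.integer(radius))
  dim(out) <- dim(vol)
  vox_volume(out, voxel_size(vol))
}

#' Extract the whole-organ (lung) mask
#'
#' Thresholds the volume above the background gray level, applies a
#' morphological closing with a ball of the given radius, keeps the largest
#' 26-connected component, and fills enclosed cavities so that air-filled
#' airway lumina count as part of the organ - the burden denominator is the
#' entire specimen. A closing radius at least the trachea radius seals the
#' airway opening at the organ surface so the lumina become enclosed.
#'
#' @param vol a [vox_volume()].
#' @param background_threshold gray value separating the specimen from the
#'   surrounding bath; voxels strictly above it are tissue candidates.
#' @param closing_radius ball radius in voxels for the morphological closing
#'   (0 disables it).
#' @param fill_airways fill enclosed cavities (airway lumina) into the organ
#'   mask (default `TRUE`, the whole-organ denominator).
#' @return logical organ mask.
#' @export
compute_lung_mask <- function(vol, background_threshold, closing_radius = 3,
                              fill_airways = TRUE) {
  if (!inherits(vol, "vox_volume")) vol <- vox_volume(vol)
  d <- dim(vol)
  m <- array(as.vector(vol) > background_threshold, dim = d)
  if (!any(m)) stop("no specimen found above gray value ",
                    background_threshold)
  if (closing_radius > 0) {
    m <- cpp_dilate_ball(m, d, closing_radius)
    m <- cpp_erode_ball(m, d, closing_radius)
  }
  lab <- cpp_label_components(m, d, 26L)
  if (max(lab) == 0) stop("no specimen found above gray value ",
                          background_threshold)
  counts <- tabulate(lab)
  m <- lab == which.max(counts)
  if (fill_airways) m <- cpp_fill_holes(m, d)
  dim(m) <- d
  m
}

#' Segment the airway tree from a trachea seed
#'
#' Region-grows over the dark, air-filled lumina starting from a seed placed
#' in the trachea, restricted to the organ mask. If the seed's gray value
#' looks too bright for air (heuristically, above the 25 % point of the gray
#' range inside the organ) a warning is issued and the growth proceeds.
#'
#' @param vol a [vox_volume()].
#' @param trachea_seed `c(z, y, x)` voxel inside an airway lumen.
#' @param params a [region_grow_params()] tuned to the air gray class.
#' @param lung_mask organ mask from [compute_lung_mask()].
#' @return a `lb_segmentation` of the reachable airway lumina.
#' @export
segment_airways <- function(vol, trachea_seed, params, lung_mask) {
  if (!inherits(vol, "vox_volume")) vol <- vox_volume(vol)
  assert_mask(lung_mask, dim(vol), "lung_mask")
  s <- normalize_seeds(trachea_seed, dim(vol), lung_mask)
  g <- vol[lung_mask]
  air_cut <- min(g) + 0.25 * (max(g) - min(g))
  if (vol[s[1, 1], s[1, 2], s[1, 3]] > air_cut)
    warning("trachea seed gray value ", vol[s[1, 1], s[1, 2], s[1, 3]],
            " is above the expected air range (heuristic cut ",
            round(air_cut), "); proceeding anyway")
  region_grow(vol, s, params, domain = lung_mask)
}

#' Segment tumors from per-tumor seeds
#'
#' Region-grows from each tumor seed within the organ mask, with optional
#' exclusion masks (e.g. the airway segmentation) removed from the growth
#' domain beforehand. Seeds may carry individual parameter overrides, since
#' different lesions typically need different tolerances or radii.
#'
#' @param vol a [vox_volume()].
#' @param tumor_seeds seeds as in [region_grow()], or a list whose elements
#'   are `list(coord = c(z,y,x), tolerance = ..., radius_um = ...)` with the
#'   overrides optional.
#' @param params default [region_grow_params()] for seeds without overrides.
#' @param lung_mask organ mask.
#' @param exclude optional logical mask (or list of masks) to carve out of
#'   the domain, e.g. segmented airways.
#' @return a `lb_segmentation`; `provenance` records each seed's effective
#'   parameters.
#' @export
segment_tumors <- function(vol, tumor_seeds, params, lung_mask,
                           exclude = NULL) {
  if (!inherits(vol, "vox_volume")) vol <- vox_volume(vol)
  d <- dim(vol)
  assert_mask(lung_mask, d, "lung_mask")
  domain <- lung_mask
  if (!is.null(exclude)) {
    if (is.logical(exclude)) exclude <- list(exclude)
    for (ex in exclude) {
      assert_mask(ex, d, "exclude")
      domain <- domain & !ex
    }
  }
  # split seeds into coordinates + per-seed effective parameters
  coords <- list(); tol <- c(); rad <- c()
  if (!is.null(tumor_seeds) && length(tumor_seeds) > 0) {
    if (is.numeric(tumor_seeds) && is.null(dim(tumor_seeds)))
      tumor_seeds <- list(tumor_seeds)
    if (is.matrix(tumor_seeds))
      tumor_seeds <- lapply(seq_len(nrow(tumor_seeds)),
                            function(i) tumor_seeds[i, ])
    for (sd in tumor_seeds) {
      if (is.list(sd)) {
        coords[[length(coords) + 1L]] <- sd$coord
        tol <- c(tol, if (is.null(sd$tolerance)) params$tolerance
                      else sd$tolerance)
        rad <- c(rad, if (!is.null(sd$radius_um)) sd$radius_um
                      else if (is.null(params$radius_um)) -1
                      else params$radius_um)
      } else {
        coords[[length(coords) + 1L]] <- sd
        tol <- c(tol, params$tolerance)
        rad <- c(rad, if (is.null(params$radius_um)) -1 else params$radius_um)
      }
    }
  }
  seeds <- normalize_seeds(coords, d, domain)
  if (nrow(seeds) == 0) {
    mask <- array(FALSE, dim = d)
    prov <- data.frame(z = integer(), y = integer(), x = integer(),
                       tolerance = numeric(), radius_um = numeric())
  } else {
    rvox <- ifelse(rad < 0, -1, rad / voxel_size(vol))
    mask <- cpp_region_grow(as.double(vol), d, seeds - 1L, tol, rvox,
                            params$connectivity, domain)
    dim(mask) <- d
    prov <- data.frame(z = seeds[, 1], y = seeds[, 2], x = seeds[, 3],
                       tolerance = tol,
                       radius_um = ifelse(rad < 0, NA_real_, rad))
  }
  structure(list(mask = mask, seeds = seeds, params = params,
                 provenance = prov, voxel_count = sum(mask)),
            class = "lb_segmentation")
}
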