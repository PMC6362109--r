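#' Tumor specification for a stained-lung phantom
#'
#' Describes one lesion: a (possibly irregular) sphere of bright, stained
#' tissue. Lesions may overlap, which merges them into one connected mass
#' with undefined internal boundaries, as seen in heavily diseased lungs.
#'
#' @param center tumor center, voxel coordinates `c(z, y, x)` (1-based).
#' @param radius nominal radius in voxels (`>= 2`).
#' @param shape_irregularity amplitude in `[0, 1]` of a smooth random radial
#'   perturbation of the surface; 0 gives an exact sphere.
#' @param boundary_sharpness `"sharp"` (step edge) or `"diffuse"` (linear
#'   intensity ramp between the tumor and parenchyma means).
#' @param ramp_width width in voxels of the diffuse intensity ramp; must be
#'   smaller than `radius`. Ignored for sharp boundaries. The ground-truth
#'   label boundary sits at the 50 % intensity point of the ramp.
#' @return a `tumor_spec` list.
#' @export
tumor_spec <- function(center, radius, shape_irregularity = 0,
                       boundary_sharpness = c("sharp", "diffuse"),
                       ramp_width = 2) {
  boundary_sharpness <- match.arg(boundary_sharpness)
  if (length(center) != 3L) stop("tumor center must be c(z, y, x)")
  if (radius < 2) stop("tumor radius must be >= 2 voxels, got ", radius)
  if (shape_irregularity < 0 || shape_irregularity > 1)
    stop("shape_irregularity must lie in [0, 1]")
  if (boundary_sharpness == "diffuse" && ramp_width >= radius)
    stop("diffuse ramp_width (", ramp_width,
         ") must be smaller than the tumor radius (", radius, ")")
  structure(list(center = as.numeric(center), radius = as.numeric(radius),
                 shape_irregularity = shape_irregularity,
                 boundary_sharpness = boundary_sharpness,
                 ramp_width = as.numeric(ramp_width)),
            class = "tumor_spec")
}

#' Phantom specification for a synthetic stained-lung micro-CT volume
#'
#' Defines the geometry, contrast model and noise of a synthetic
#' iodine-in-ethanol stained lung: an ellipsoidal organ immersed in an
#' ethanol bath, a deterministic bifurcating airway tree of air-filled lumina
#' with stain-enhanced walls, randomly placed vessels, bright tumors, and an
#' optional halo of abnormal tissue around each tumor whose gray value
#' defaults to the tumor mean - the non-specific staining that makes
#' inflamed/dead tissue indistinguishable from tumor by intensity.
#'
#' Default class mean gray values (16-bit scale) are free parameters of the
#' phantom, not measurements: air 2000 < ethanol background 9000 <
#' parenchyma 22000 < vessel/airway wall 30000 < tumor 42000.
#'
#' @param grid_shape voxel counts `c(nz, ny, nx)`, each `>= 32`.
#' @param voxel_size_um voxel edge length in micrometers (default 13).
#' @param lung list with `center` (voxel coords, default grid center) and
#'   `semi_axes` (ellipsoid semi-axes in voxels, default 40 % of each axis).
#' @param airway_tree list: `depth` (bifurcation generations), `radius`
#'   (trachea radius, voxels), `length` (trachea segment length, default
#'   40 % of the z semi-axis), `radius_decay`, `length_decay` (per-generation
#'   scale factors), `angle_deg` (branching half-angle).
#' @param n_vessels number of random vessel segments inside the lung.
#' @param vessel_radius range `c(min, max)` of vessel radii in voxels.
#' @param tumors list of [tumor_spec()] objects.
#' @param halo_thickness halo shell thickness in voxels per tumor (recycled);
#'   0 disables the halo.
#' @param intensity named list of class mean gray values: `background`,
#'   `air`, `parenchyma`, `vessel`, `tumor`, `halo`.
#' @param noise_sigma standard deviation of additive zero-mean Gaussian
#'   noise in gray units (clipped to the 16-bit range).
#' @param rng_seed integer seed driving all randomness in the phantom.
#' @param well_separated if `TRUE`, require every pair of tissue-class means
#'   present in the phantom to differ by at least `4 * noise_sigma`.
#' @return a validated `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 96), voxel_size_um = 13,
                         lung = list(), airway_tree = list(),
                         n_vessels = 6, vessel_radius = c(1, 2),
                         tumors = list(), halo_thickness = 0,
                         intensity = list(), noise_sigma = 800,
                         rng_seed = 1, well_separated = FALSE) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 32L))
    stop("grid_shape must be three voxel counts, each >= 32")

  lung_def <- list(center = (grid_shape + 1) / 2, semi_axes = 0.40 * grid_shape)
  lung <- modifyList(lung_def, lung)
  if (any(lung$semi_axes <= 0)) stop("lung semi-axes must be positive")

  at_def <- list(depth = 3L, radius = 2.5,
                 length = 0.4 * lung$semi_axes[1],
                 radius_decay = 0.7, length_decay = 0.7, angle_deg = 40,
                 entry = c(lung$center[1] - lung$semi_axes[1] + 1.5,
                           lung$center[2], lung$center[3]))
  airway_tree <- modifyList(at_def, airway_tree)

  int_def <- list(background = 9000, air = 2000, parenchyma = 22000,
                  vessel = 30000, tumor = 42000, halo = 42000)
  intensity <- modifyList(int_def, intensity)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")

  if (length(tumors) > 0 && inherits(tumors, "tumor_spec"))
    tumors <- list(tumors)
  for (tm in tumors) {
    if (!inherits(tm, "tumor_spec")) stop("tumors must be tumor_spec objects")
    d2 <- sum(((tm$center - lung$center) / lung$semi_axes)^2)
    if (d2 > 1)
      stop("tumor centered at (", paste(tm$center, collapse = ","),
           ") lies outside the lung ellipsoid")
  }
  halo_thickness <- as.numeric(halo_thickness)
  if (any(halo_thickness < 0)) stop("halo_thickness must be >= 0")

  if (well_separated) {
    classes <- c(background = intensity$background, air = intensity$air,
                 parenchyma = intensity$parenchyma, vessel = intensity$vessel)
    if (length(tumors) > 0) classes <- c(classes, tumor = intensity$tumor)
    if (length(tumors) > 0 && any(rep_len(halo_thickness,
                                          length(tumors)) > 0))
      classes <- c(classes, halo = intensity$halo)
    gaps <- abs(outer(classes, classes, "-"))
    bad <- which(gaps < 4 * noise_sigma & upper.tri(gaps), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop("well-separated contrast requested but classes '",
           names(classes)[bad[1, 1]], "' and '", names(classes)[bad[1, 2]],
           "' differ by less than 4 * noise_sigma")
  }

  structure(list(grid_shape = grid_shape, voxel_size_um = voxel_size_um,
                 lung = lung, airway_tree = airway_tree,
                 n_vessels = as.integer(n_vessels),
                 vessel_radius = as.numeric(vessel_radius),
                 tumors = tumors, halo_thickness = halo_thickness,
                 intensity = intensity, noise_sigma = noise_sigma,
                 rng_seed = as.integer(rng_seed),
                 well_separated = well_separated),
            class = "phantom_spec")
}

# coordinate arrays over an index box (zi, yi, xi), each shaped (lz, ly, lx)
box_coords <- function(zi, yi, xi) {
  lz <- length(zi); ly <- length(yi); lx <- length(xi)
  list(z = array(zi, dim = c(lz, ly, lx)),
       y = aperm(array(yi, dim = c(ly, lz, lx)), c(2, 1, 3)),
       x = aperm(array(xi, dim = c(lx, lz, ly)), c(2, 3, 1)))
}

# mark voxels within `radius` of the segment p0-p1 (coords (z,y,x), 1-based)
rasterize_capsule <- function(mask, p0, p1, radius) {
  d <- dim(mask)
  lo <- pmax(floor(pmin(p0, p1) - radius), 1)
  hi <- pmin(ceiling(pmax(p0, p1) + radius), d)
  if (any(lo > hi)) return(mask)
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  co <- box_coords(zi, yi, xi)
  v <- p1 - p0
  vv <- sum(v^2)
  wz <- co$z - p0[1]; wy <- co$y - p0[2]; wx <- co$x - p0[3]
  t <- if (vv == 0) 0 else pmin(pmax((wz * v[1] + wy * v[2] + wx * v[3]) / vv,
                                     0), 1)
  d2 <- (wz - t * v[1])^2 + (wy - t * v[2])^2 + (wx - t * v[3])^2
  sub <- mask[zi, yi, xi, drop = FALSE]
  sub[d2 <= radius^2] <- TRUE
  mask[zi, yi, xi] <- sub
  mask
}

# rotate 3D vector v by angle `a` (radians) in the coordinate plane (i, j)
rotate_in_plane <- function(v, i, j, a) {
  vi <- v[i] * cos(a) - v[j] * sin(a)
  vj <- v[i] * sin(a) + v[j] * cos(a)
  v[i] <- vi; v[j] <- vj
  v
}

# deterministic recursive bifurcation: list of branches (p0, p1, radius)
airway_branches <- function(at) {
  res <- list()
  recurse <- function(p0, dir, len, rad, gen) {
    p1 <- p0 + dir * len
    res[[length(res) + 1L]] <<- list(p0 = p0, p1 = p1, radius = rad)
    if (gen >= at$depth) return(invisible())
    a <- at$angle_deg * pi / 180
    plane <- if (gen %% 2 == 0) c(1, 2) else c(1, 3)  # alternate (z,y)/(z,x)
    for (sgn in c(-1, 1)) {
      d2 <- rotate_in_plane(dir, plane[1], plane[2], sgn * a)
      recurse(p1, d2 / sqrt(sum(d2^2)), len * at$length_decay,
              rad * at$radius_decay, gen + 1L)
    }
  }
  recurse(as.numeric(at$entry), c(1, 0, 0), at$length, at$radius, 0L)
  res
}

#' Recommended trachea seed voxel for a phantom
#'
#' A voxel a couple of steps down the trachea from its entry point, suitable
#' as the seed for [segment_airways()].
#'
#' @param spec a `phantom_spec`.
#' @return integer `c(z, y, x)` voxel coordinate.
#' @export
trachea_seed <- function(spec) {
  as.integer(round(spec$airway_tree$entry + c(3, 0, 0)))
}

#' Generate a synthetic stained-lung phantom
#'
#' Builds the gray-value volume and the exact co-registered ground-truth
#' labels for a [phantom_spec()]. Construction order: ellipsoidal parenchyma
#' in an ethanol background; air-filled airway lumina with 1-voxel
#' stain-enhanced walls; random vessels; tumors (overriding any other lung
#' class, so lesions may merge); halo shells (dilation of each tumor by its
#' halo thickness, clipped to the lung, never overwriting tumor). Intensities
#' map labels to class means, diffuse tumor boundaries are linearly ramped
#' (the label boundary is the 50 % intensity point), and zero-mean Gaussian
#' noise is added and clipped to `[0, 65535]`.
#'
#' Identical spec (including `rng_seed`) gives bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` ([vox_volume()]), `labels`
#'   ([label_volume()]) and `spec`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec")
  d <- spec$grid_shape
  n <- prod(d)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$rng_seed)

  ctr <- spec$lung$center; ax <- spec$lung$semi_axes
  ez2 <- ((seq_len(d[1]) - ctr[1]) / ax[1])^2
  ey2 <- ((seq_len(d[2]) - ctr[2]) / ax[2])^2
  ex2 <- ((seq_len(d[3]) - ctr[3]) / ax[3])^2
  lung <- outer(outer(ez2, ey2, "+"), ex2, "+") <= 1

  labels <- array(0L, dim = d)
  labels[lung] <- 1L

  # airway tree: lumen + 1-voxel stained wall
  lumen <- array(FALSE, dim = d)
  for (br in airway_branches(spec$airway_tree))
    lumen <- rasterize_capsule(lumen, br$p0, br$p1, br$radius)
  lumen <- lumen & lung
  wall <- cpp_dilate_ball(lumen, d, 1.5)
  dim(wall) <- d
  labels[wall & lung & labels == 1L] <- 5L
  labels[lumen] <- 3L

  # vessels: random segments between points inside the lung
  sample_in_lung <- function() {
    repeat {
      u <- runif(3, -1, 1)
      if (sum(u^2) <= 0.85) return(ctr + u * ax * 0.95)
    }
  }
  if (spec$n_vessels > 0) {
    vess <- array(FALSE, dim = d)
    for (i in seq_len(spec$n_vessels)) {
      p0 <- sample_in_lung(); p1 <- sample_in_lung()
      r <- runif(1, spec$vessel_radius[1], spec$vessel_radius[2])
      vess <- rasterize_capsule(vess, p0, p1, r)
    }
    labels[vess & labels == 1L] <- 5L
  }

  # tumors: irregular spheres; `frac` carries the diffuse intensity ramp
  frac <- array(0, dim = d)
  tumor_mask <- array(FALSE, dim = d)
  halo_th <- rep_len(spec$halo_thickness, max(length(spec$tumors), 1L))
  halo_mask <- array(FALSE, dim = d)
  for (k in seq_along(spec$tumors)) {
    tm <- spec$tumors[[k]]
    w <- rnorm(6)  # smooth radial perturbation coefficients (always drawn)
    wbound <- sum(abs(w[1:3])) + sum(abs(w[4:6])) / 2
    ramp <- if (tm$boundary_sharpness == "diffuse") tm$ramp_width else 0
    pad <- tm$radius * (1 + tm$shape_irregularity) + ramp / 2 + halo_th[k] + 2
    lo <- pmax(floor(tm$center - pad), 1)
    hi <- pmin(ceiling(tm$center + pad), d)
    co <- box_coords(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3])
    dz <- co$z - tm$center[1]; dy <- co$y - tm$center[2]
    dx <- co$x - tm$center[3]
    dist <- sqrt(dz^2 + dy^2 + dx^2)
    r_eff <- tm$radius
    if (tm$shape_irregularity > 0) {
      dn <- pmax(dist, 1e-9)
      uz <- dz / dn; uy <- dy / dn; ux <- dx / dn
      f <- (w[1] * uz + w[2] * uy + w[3] * ux +
            w[4] * uz * uy + w[5] * uz * ux + w[6] * uy * ux) / wbound
      r_eff <- pmax(tm$radius * (1 + tm$shape_irregularity * f), 2)
    }
    core <- dist <= r_eff
    fr <- if (ramp > 0)
      pmin(pmax((r_eff + ramp / 2 - dist) / ramp, 0), 1) else core * 1.0
    zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
    tumor_mask[zi, yi, xi] <- tumor_mask[zi, yi, xi, drop = FALSE] | core
    frac[zi, yi, xi] <- pmax(frac[zi, yi, xi, drop = FALSE], fr)
    if (halo_th[k] > 0) {
      core_full <- array(FALSE, dim = d)
      core_full[zi, yi, xi] <- core
      hk <- cpp_dilate_ball(core_full & lung, d, halo_th[k])
      dim(hk) <- d
      halo_mask <- halo_mask | hk
    }
  }
  tumor_mask <- tumor_mask & lung
  labels[tumor_mask] <- 2L
  labels[halo_mask & lung & (labels == 1L | labels == 5L)] <- 4L

  # intensities: class means, then diffuse ramps, then noise
  im <- spec$intensity
  means <- c(im$background, im$parenchyma, im$tumor, im$air, im$halo,
             im$vessel)
  vol <- means[as.integer(labels) + 1L]
  dim(vol) <- d
  blend <- (labels == 1L | labels == 2L) & frac > 0
  vol[blend] <- im$parenchyma + frac[blend] * (im$tumor - im$parenchyma)
  if (spec$noise_sigma > 0)
    vol <- vol + rnorm(n, 0, spec$noise_sigma)
  vol <- round(pmin(pmax(vol, 0), 65535))

  list(volume = vox_volume(vol, spec$voxel_size_um),
       labels = label_volume(labels, spec$voxel_size_um),
       spec = spec)
}
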