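#' Read a gray-value volume from TIFF
#'
#' Accepts either a multi-page 16-bit TIFF file or a directory of per-slice
#' TIFFs stacked in ascending numeric filename order. The voxel size is taken
#' from the YAML sidecar written by [write_volume()] (`<stem>.meta.yaml`),
#' or from `voxel_size_um` when no sidecar exists.
#'
#' @param path TIFF file or directory of slice TIFFs.
#' @param voxel_size_um override / fallback voxel size in micrometers.
#' @return a [vox_volume()].
#' @export
read_volume <- function(path, voxel_size_um = NULL) {
  pages <- read_tiff_pages(path)
  vol <- stack_pages(pages, path)
  vs <- voxel_size_um
  if (is.null(vs)) vs <- sidecar_read(path)$voxel_size_um
  if (is.null(vs))
    stop("no voxel size: ", sidecar_path(path),
         " not found and voxel_size_um not given")
  vox_volume(vol, vs)
}

#' Write a gray-value volume as multi-page 16-bit TIFF
#'
#' Values are stored losslessly as 16-bit unsigned integers; a YAML sidecar
#' `<stem>.meta.yaml` records the voxel size (TIFF tags are deliberately not
#' relied on, for portability across writers).
#'
#' @param vol a [vox_volume()].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!inherits(vol, "vox_volume")) vol <- vox_volume(vol)
  check_writable(path)
  pages <- lapply(seq_len(dim(vol)[1]),
                  function(z) matrix(vol[z, , ], dim(vol)[2], dim(vol)[3]) /
                    65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  sidecar_write(path, list(kind = "volume", voxel_size_um = voxel_size(vol)))
  invisible(path)
}

#' Read / write a boolean mask as 8-bit TIFF
#'
#' Masks are stored with 0 = background, 255 = foreground; any other stored
#' value is rejected on read.
#'
#' @param mask logical 3D array.
#' @param path `.tif` path.
#' @return `write_mask`: `path` invisibly; `read_mask`: logical 3D array.
#' @export
write_mask <- function(mask, path) {
  assert_mask(mask)
  check_writable(path)
  pages <- lapply(seq_len(dim(mask)[1]),
                  function(z) matrix(as.numeric(mask[z, , ]), dim(mask)[2],
                                     dim(mask)[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  sidecar_write(path, list(kind = "mask"))
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  pages <- read_tiff_pages(path)
  m <- stack_pages(pages, path)
  bad <- setdiff(unique(as.vector(m)), c(0, 255))
  if (length(bad) > 0)
    stop("mask file ", path, " contains values other than {0, 255}: ",
         paste(utils::head(bad, 5), collapse = ", "))
  array(m == 255, dim = dim(m))
}

#' Read / write ground-truth labels as 8-bit TIFF
#'
#' Tissue-class labels 0..5 stored directly as 8-bit values.
#'
#' @param labels a [label_volume()].
#' @param path `.tif` path.
#' @param voxel_size_um fallback voxel size when no sidecar exists.
#' @return `write_labels`: `path` invisibly; `read_labels`: a
#'   [label_volume()].
#' @export
write_labels <- function(labels, path) {
  if (!inherits(labels, "label_volume")) stop("labels must be a label_volume")
  check_writable(path)
  pages <- lapply(seq_len(dim(labels)[1]),
                  function(z) matrix(as.numeric(labels[z, , ]) / 255,
                                     dim(labels)[2], dim(labels)[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  sidecar_write(path, list(kind = "labels",
                           voxel_size_um = voxel_size(labels)))
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path, voxel_size_um = NULL) {
  pages <- read_tiff_pages(path)
  l <- stack_pages(pages, path)
  vs <- voxel_size_um
  if (is.null(vs)) vs <- sidecar_read(path)$voxel_size_um
  if (is.null(vs))
    stop("no voxel size: ", sidecar_path(path),
         " not found and voxel_size_um not given")
  label_volume(l, vs)
}

#' Write a phantom (volume + labels + metadata) to a directory
#'
#' @param phantom result of [generate_phantom()].
#' @param dir output directory (created if needed). Writes `volume.tif`,
#'   `labels.tif` and their sidecars; the volume sidecar echoes the spec.
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_volume(phantom$volume, file.path(dir, "volume.tif"))
  write_labels(phantom$labels, file.path(dir, "labels.tif"))
  sidecar_write(file.path(dir, "volume.tif"),
                list(kind = "volume",
                     voxel_size_um = voxel_size(phantom$volume),
                     phantom_spec = spec_to_list(phantom$spec)))
  invisible(dir)
}

# ---- internals -------------------------------------------------------------

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".meta.yaml")
}

sidecar_write <- function(path, meta) {
  yaml::write_yaml(meta, sidecar_path(path))
}

sidecar_read <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(list())
  yaml::read_yaml(sp)
}

check_writable <- function(path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write ", path, ": directory ", dir,
                             " does not exist")
  invisible(TRUE)
}

# list of page matrices from a multi-page file or a slice directory
read_tiff_pages <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                        ignore.case = TRUE)
    if (length(files) == 0) stop("no TIFF slices found in directory ", path)
    num <- suppressWarnings(
      as.numeric(gsub("\\D", "", basename(files))))
    ord <- order(ifelse(is.na(num), Inf, num), basename(files))
    files <- files[ord]
    pages <- lapply(files, function(f) {
      p <- tiff::readTIFF(f, all = TRUE, as.is = TRUE)
      names(p) <- rep(f, length(p))
      p
    })
    do.call(c, pages)
  } else {
    if (!file.exists(path)) stop("no such file: ", path)
    tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  }
}

stack_pages <- function(pages, path) {
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(shapes)) != 1L) {
    off <- which(shapes != shapes[1])[1]
    src <- names(pages)[off]
    stop("slice ", off, if (!is.null(src) && nzchar(src))
      paste0(" (", src, ")") else "", " has shape ", shapes[off],
      ", expected ", shapes[1])
  }
  d2 <- dim(pages[[1]])
  vol <- array(0, dim = c(length(pages), d2[1], d2[2]))
  for (z in seq_along(pages)) vol[z, , ] <- pages[[z]]
  vol
}

# phantom_spec -> plain list for YAML echo
spec_to_list <- function(spec) {
  s <- unclass(spec)
  s$tumors <- lapply(s$tumors, unclass)
  s
}
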