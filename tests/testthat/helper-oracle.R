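# Independent reference implementations used as oracles. These deliberately
# avoid the package's C++ path: plain-R set expansion over precomputed
# acceptance arrays.

conn_offsets_r <- function(connectivity) {
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  m <- rowSums(abs(offs))
  lim <- c("6" = 1, "18" = 2, "26" = 3)[as.character(connectivity)]
  offs[m > 0 & m <= lim, , drop = FALSE]
}

# exhaustive region growth: mark every voxel passing the acceptance rule,
# then keep the connected component containing the seed
oracle_region_grow <- function(vol, seed, tolerance, radius_vox = NULL,
                               connectivity = 26, domain = NULL) {
  d <- dim(vol)
  if (is.null(domain)) domain <- array(TRUE, dim = d)
  ref <- vol[seed[1], seed[2], seed[3]]
  accept <- abs(vol - ref) <= tolerance / 2 & domain
  if (!is.null(radius_vox)) {
    co <- which(array(TRUE, dim = d), arr.ind = TRUE)
    d2 <- (co[, 1] - seed[1])^2 + (co[, 2] - seed[2])^2 +
      (co[, 3] - seed[3])^2
    accept <- accept & array(d2 <= radius_vox^2, dim = d)
  }
  offs <- conn_offsets_r(connectivity)
  sel <- array(FALSE, dim = d)
  sel[seed[1], seed[2], seed[3]] <- TRUE
  repeat {
    cur <- which(sel, arr.ind = TRUE)
    added <- FALSE
    for (k in seq_len(nrow(offs))) {
      nb <- sweep(cur, 2, offs[k, ], "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      if (nrow(nb) == 0) next
      idx <- nb[, 1] + d[1] * ((nb[, 2] - 1) + d[2] * (nb[, 3] - 1))
      new <- accept[idx] & !sel[idx]
      if (any(new)) {
        sel[idx[new]] <- TRUE
        added <- TRUE
      }
    }
    if (!added) break
  }
  sel
}

# exhaustive scan of voxel centers within `radius` of `center`
brute_sphere_count <- function(center, radius, dim) {
  co <- as.matrix(expand.grid(z = seq_len(dim[1]), y = seq_len(dim[2]),
                              x = seq_len(dim[3])))
  sum((co[, 1] - center[1])^2 + (co[, 2] - center[2])^2 +
        (co[, 3] - center[3])^2 <= radius^2)
}
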