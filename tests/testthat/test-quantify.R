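test_that("volume_fraction handles the degenerate and exact cases", {
  d <- c(10, 10, 10)
  whole <- array(TRUE, dim = d)
  empty <- array(FALSE, dim = d)
  expect_equal(volume_fraction(empty, whole), 0)
  expect_equal(volume_fraction(whole, whole), 100)
  expect_error(volume_fraction(whole, empty), "empty")
})

test_that("volume_fraction of a phantom tumor matches direct label counts", {
  ph <- generate_phantom(small_spec())
  l <- label_array(ph$labels)
  vf <- volume_fraction(l == 2L, l != 0L)
  expect_equal(vf, 100 * sum(l == 2L) / sum(l != 0L))
  expect_equal(vf, true_burden(ph$labels))
  # invariant under a common axis permutation of both masks
  expect_equal(volume_fraction(aperm(l == 2L, c(3, 1, 2)),
                               aperm(l != 0L, c(3, 1, 2))), vf)
})

test_that("histogram split is internally consistent and conserves counts", {
  ph <- generate_phantom(small_spec(noise_sigma = 400, rng_seed = 5))
  l <- label_array(ph$labels)
  whole <- l != 0L
  part <- l == 2L
  hs <- histogram_split(ph$volume, whole, part, n_bins = 32)
  expect_true(all(hs$counts_segmented <= hs$counts_total))
  expect_equal(sum(hs$counts_total), sum(whole))
  expect_equal(hs$segmented_fraction_percent,
               volume_fraction(part, whole), tolerance = 1e-9)
  expect_equal(sum(hs$counts_total - hs$counts_segmented),
               sum(whole & !part))
  # part = whole collapses the two histograms
  hs2 <- histogram_split(ph$volume, whole, whole, n_bins = 32)
  expect_identical(hs2$counts_total, hs2$counts_segmented)
  expect_equal(hs2$segmented_fraction_percent, 100)
})

test_that("noise-free class histograms occupy only the tumor-class bins", {
  spec <- small_spec(noise_sigma = 0)
  ph <- generate_phantom(spec)
  l <- label_array(ph$labels)
  hs <- histogram_split(ph$volume, l != 0L, l == 2L, n_bins = 16)
  occupied <- which(hs$counts_segmented > 0)
  expect_length(occupied, 1)  # one gray value: the tumor mean
  expect_gte(hs$bin_edges[occupied], spec$intensity$parenchyma)
})

test_that("slice burden matches a 2D rasterization oracle", {
  # spherical tumor r = 10 centered in a cylindrical lung r = 30; the
  # equatorial slice has area fraction close to (10/30)^2
  d <- c(41, 101, 101)
  ctr <- c(21, 51, 51)
  co <- expand.grid(z = 1:d[1], y = 1:d[2], x = 1:d[3])
  lung <- array((co$y - ctr[2])^2 + (co$x - ctr[3])^2 <= 30^2, dim = d)
  tum <- array((co$z - ctr[1])^2 + (co$y - ctr[2])^2 +
                 (co$x - ctr[3])^2 <= 10^2, dim = d)
  got <- slice_burden(tum, lung, axis = 1, index = 21)
  # independent 2D pixel-count oracle on the equatorial plane
  px <- expand.grid(y = 1:d[2], x = 1:d[3])
  in_lung <- (px$y - ctr[2])^2 + (px$x - ctr[3])^2 <= 30^2
  in_tum <- (px$y - ctr[2])^2 + (px$x - ctr[3])^2 <= 10^2
  expect_equal(got, 100 * sum(in_tum) / sum(in_lung))
  expect_equal(got, 100 * (10 / 30)^2, tolerance = 0.02)
  # a slice with no tumor reports 0; a slice with no lung errors
  expect_equal(slice_burden(tum, lung, axis = 1, index = 1), 0)
  lung0 <- lung; lung0[5, , ] <- FALSE
  expect_error(slice_burden(tum, lung0, axis = 1, index = 5),
               "no lung tissue")
  expect_error(slice_burden(tum, lung, axis = 1, index = 999), "extent")
})

test_that("lung-area-weighted slice burdens average to the volume fraction", {
  ph <- generate_phantom(small_spec(tumors = list(
    tumor_spec(c(28, 20, 20), 5), tumor_spec(c(20, 28, 28), 4))))
  l <- label_array(ph$labels)
  part <- l == 2L; whole <- l != 0L
  zs <- which(apply(whole, 1, any))
  b <- vapply(zs, function(z) slice_burden(part, whole, 1, z), numeric(1))
  w <- vapply(zs, function(z) sum(whole[z, , ]), numeric(1))
  expect_equal(sum(b * w) / sum(w), volume_fraction(part, whole),
               tolerance = 1e-9)
})

test_that("a perfect segmentation reports zero error and matching slices", {
  ph <- generate_phantom(small_spec())
  l <- label_array(ph$labels)
  rep <- build_report(list(tumor = l == 2L, lung = l != 0L),
                      labels = ph$labels, slice = list(axis = 1, index = 28),
                      sample_id = "perfect")
  expect_equal(rep$error_3d_microct, 0)
  expect_equal(rep$burden_2d_microct_percent, rep$burden_2d_truth_percent)
  expect_equal(rep$burden_3d_microct_percent, rep$true_3d_percent)
})

test_that("halo inflates the 3D estimate above truth in the report", {
  spec <- small_spec(halo_thickness = 2)
  ph <- generate_phantom(spec)
  lung <- compute_lung_mask(ph$volume, 15500, closing_radius = 4)
  seg <- segment_tumors(ph$volume, list(c(28L, 20L, 20L)),
                        region_grow_params(10000), lung)
  rep <- build_report(list(tumor = seg, lung = lung), labels = ph$labels,
                      slice = list(axis = 1, index = 28))
  expect_gt(rep$burden_3d_microct_percent, rep$true_3d_percent)
})

test_that("burden CSV carries exactly the three method columns", {
  td <- withr::local_tempdir()
  ph <- generate_phantom(small_spec())
  l <- label_array(ph$labels)
  rep <- build_report(list(tumor = l == 2L, lung = l != 0L),
                      labels = ph$labels, slice = list(axis = 1, index = 28))
  p <- file.path(td, "report.csv")
  write_burden_csv(rep, p)
  csv <- read.csv(p)
  expect_identical(names(csv),
                   c("sample", "he_histological_slice",
                     "microct_virtual_slice", "microct_volumetric_image"))
  expect_equal(csv$microct_volumetric_image,
               round(rep$burden_3d_microct_percent, 1))
})

test_that("missing slice selection for the 2D columns is an error", {
  ph <- generate_phantom(small_spec())
  l <- label_array(ph$labels)
  expect_error(build_report(list(tumor = l == 2L, lung = l != 0L),
                            labels = ph$labels, slice = list(axis = 1)),
               "slice selection")
})

test_that("a central slice misses an off-center tumor entirely", {
  # single small tumor near the top of the lung: the central virtual slice
  # contains no tumor although the true 3D burden is positive
  spec <- small_spec(tumors = list(tumor_spec(c(14, 24, 24), 3)),
                     noise_sigma = 300, rng_seed = 9)
  bs <- bias_study(spec, n_replicates = 1, rng_seed = 100)
  expect_equal(bs$reports$burden_2d_truth_percent, 0)
  expect_gt(bs$reports$true_3d_percent, 0)
})

test_that("bias study aggregates signed errors over replicates", {
  spec <- small_spec(tumors = list(tumor_spec(c(28, 20, 20), 5),
                                   tumor_spec(c(20, 28, 28), 4)),
                     noise_sigma = 500)
  bs <- bias_study(spec, n_replicates = 3, rng_seed = 50)
  expect_equal(nrow(bs$reports), 3)
  expect_equal(bs$summary$n, 3)
  expect_equal(bs$summary$mean_signed_error_3d,
               mean(bs$reports$error_3d_microct))
  expect_true(all(bs$reports$burden_3d_microct_percent >= 0 &
                    bs$reports$burden_3d_microct_percent <= 100))
  # random-slice rule stays within the organ's z extent and is reproducible
  bs2 <- bias_study(spec, n_replicates = 2, slice_rule = "random",
                    rng_seed = 50)
  bs3 <- bias_study(spec, n_replicates = 2, slice_rule = "random",
                    rng_seed = 50)
  expect_identical(bs2$reports$slice_index, bs3$reports$slice_index)
})
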