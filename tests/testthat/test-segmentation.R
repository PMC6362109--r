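test_that("uniform volume floods the whole domain", {
  v <- vox_volume(array(500, dim = c(5, 6, 7)), 13)
  res <- region_grow(v, c(3, 3, 3), region_grow_params(10))
  expect_true(all(res$mask))
  expect_equal(res$voxel_count, prod(dim(v)))
})

test_that("an isolated seed stays isolated", {
  v <- array(1000, dim = c(5, 5, 5))
  v[3, 3, 3] <- 0   # neighbors differ by 1000 > tolerance/2
  res <- region_grow(vox_volume(v, 13), c(3, 3, 3), region_grow_params(100))
  expect_equal(sum(res$mask), 1)
  expect_true(res$mask[3, 3, 3])
})

test_that("region growth matches the exhaustive oracle on random volumes", {
  for (seed in 1:8) {
    v <- rand_volume(c(5, 5, 5), seed = seed)
    res <- region_grow(v, c(3, 3, 3), region_grow_params(40))
    expect_identical(res$mask,
                     oracle_region_grow(unclass(v), c(3, 3, 3), 40),
                     info = paste("seed", seed))
  }
})

test_that("a one-voxel radius confines growth to the seed's face neighbors", {
  v <- vox_volume(array(500, dim = c(5, 5, 5)), 13)
  res <- region_grow(v, c(3, 3, 3),
                     region_grow_params(10, radius_um = 13,
                                        connectivity = 6))
  allowed <- rbind(c(3, 3, 3), c(2, 3, 3), c(4, 3, 3), c(3, 2, 3),
                   c(3, 4, 3), c(3, 3, 2), c(3, 3, 4))
  got <- which(res$mask, arr.ind = TRUE)
  expect_true(all(apply(got, 1, function(r)
    any(colSums(t(allowed) == r) == 3))))
  expect_equal(nrow(got), 7)
})

test_that("growth is monotone in tolerance and nested in connectivity", {
  for (seed in 1:5) {
    v <- rand_volume(c(6, 6, 6), seed = seed)
    m1 <- region_grow(v, c(3, 3, 3), region_grow_params(20))$mask
    m2 <- region_grow(v, c(3, 3, 3), region_grow_params(60))$mask
    expect_true(all(m2[m1]), info = paste("tolerance, seed", seed))
    c6 <- region_grow(v, c(3, 3, 3),
                      region_grow_params(60, connectivity = 6))$mask
    c26 <- region_grow(v, c(3, 3, 3),
                       region_grow_params(60, connectivity = 26))$mask
    expect_true(all(c26[c6]), info = paste("connectivity, seed", seed))
  }
})

test_that("multi-seed masks are unions, independent of seed order", {
  v <- rand_volume(c(6, 6, 6), seed = 3)
  s1 <- c(2, 2, 2); s2 <- c(5, 5, 5)
  p <- region_grow_params(30)
  m12 <- region_grow(v, list(s1, s2), p)$mask
  m21 <- region_grow(v, list(s2, s1), p)$mask
  expect_identical(m12, m21)
  expect_identical(m12, region_grow(v, s1, p)$mask |
                     region_grow(v, s2, p)$mask)
})

test_that("seed and parameter validation errors are descriptive", {
  v <- rand_volume(c(5, 5, 5))
  expect_error(region_grow(v, c(9, 1, 1), region_grow_params(10)),
               "outside the grid")
  dom <- array(FALSE, dim = c(5, 5, 5)); dom[1, 1, 1] <- TRUE
  expect_error(region_grow(v, c(3, 3, 3), region_grow_params(10), dom),
               "outside the segmentation domain")
  expect_error(region_grow_params(-1), "tolerance")
  expect_error(region_grow_params(10, radius_um = 0), "radius_um")
  expect_error(region_grow_params(10, connectivity = 4), "connectivity")
})

test_that("box smoothing preserves flat regions and damps noise", {
  # constant volume is a fixed point
  v <- vox_volume(array(1234, dim = c(8, 9, 10)), 13)
  expect_equal(unclass(smooth_volume(v, 1)), unclass(v) + 0,
               ignore_attr = TRUE)
  # interior voxel = mean of its 3-cube, computed independently
  set.seed(6)
  a <- array(sample(0:1000, 6^3, replace = TRUE), dim = c(6, 6, 6))
  s <- smooth_volume(vox_volume(a, 13), 1)
  expect_equal(s[3, 4, 3], mean(a[2:4, 3:5, 2:4]))
  # noise variance shrinks by about the window size
  set.seed(7)
  n <- array(rnorm(20^3, 1000, 100), dim = c(20, 20, 20))
  n <- pmax(n, 0)
  sm <- smooth_volume(vox_volume(n, 13), 1)
  inner <- sm[5:16, 5:16, 5:16]
  expect_lt(sd(inner), 100 / 3)
})

test_that("lung mask equals the ground-truth organ on a clean phantom", {
  # background at gray 0, tissue classes >= 1000: threshold in between
  spec <- small_spec(intensity = list(background = 0))
  ph <- generate_phantom(spec)
  m <- compute_lung_mask(ph$volume, 500, closing_radius = 0)
  expect_identical(m, label_array(ph$labels) != 0L)
})

test_that("all-background volumes raise 'no specimen found'", {
  v <- vox_volume(array(100, dim = c(32, 32, 32)), 13)
  expect_error(compute_lung_mask(v, 500, closing_radius = 0), "no specimen")
  expect_error(compute_lung_mask(v, 1e6, closing_radius = 0), "no specimen")
})

test_that("lung mask of a noisy phantom overlaps truth at Dice >= 0.99", {
  ph <- generate_phantom(small_spec(noise_sigma = 50, rng_seed = 21))
  m <- compute_lung_mask(ph$volume, 15500, closing_radius = 4)
  expect_gte(dice(m, label_array(ph$labels) != 0L), 0.99)
})

test_that("airway segmentation recovers the labeled lumina", {
  spec <- small_spec()
  ph <- generate_phantom(spec)
  l <- label_array(ph$labels)
  # closing radius 6 seals the trachea opening: the full tree is in the organ
  lung <- compute_lung_mask(ph$volume, 15500, closing_radius = 6)
  aw <- segment_airways(ph$volume, trachea_seed(spec),
                        region_grow_params(8000), lung)
  expect_identical(aw$mask, l == 3L)
  # a parenchyma seed with tight tolerance grows almost nothing (noisy
  # grays are essentially unique), and the air heuristic warns
  phn <- generate_phantom(small_spec(noise_sigma = 500, rng_seed = 33))
  ln <- label_array(phn$labels)
  lungn <- compute_lung_mask(phn$volume, 15500, closing_radius = 4)
  pseed <- which(ln == 1L & lungn, arr.ind = TRUE)[1, ]
  expect_warning(
    aw2 <- segment_airways(phn$volume, pseed, region_grow_params(2), lungn),
    "air range")
  expect_lte(aw2$voxel_count, 27)
  # radius restriction gives a strict subset of the full tree
  awr <- segment_airways(ph$volume, trachea_seed(spec),
                         region_grow_params(8000, radius_um = 5 * 13), lung)
  expect_true(all(aw$mask[awr$mask]))
  expect_lt(awr$voxel_count, aw$voxel_count)
})

test_that("tumor segmentation is exact on a sharp noise-free phantom", {
  spec <- small_spec(tumors = list(tumor_spec(c(28, 20, 20), 5),
                                   tumor_spec(c(20, 28, 28), 4)))
  ph <- generate_phantom(spec)
  lung <- compute_lung_mask(ph$volume, 15500, closing_radius = 4)
  seg <- segment_tumors(ph$volume,
                        list(c(28L, 20L, 20L), c(20L, 28L, 28L)),
                        region_grow_params(10000), lung)
  expect_identical(seg$mask, label_array(ph$labels) == 2L)
  expect_equal(nrow(seg$provenance), 2)
  expect_equal(seg$provenance$tolerance, c(10000, 10000))
})

test_that("halo tissue at tumor gray value is swallowed by the growth", {
  spec <- small_spec(halo_thickness = 2)   # halo mean defaults to tumor mean
  ph <- generate_phantom(spec)
  l <- label_array(ph$labels)
  lung <- compute_lung_mask(ph$volume, 15500, closing_radius = 4)
  seg <- segment_tumors(ph$volume, list(c(28L, 20L, 20L)),
                        region_grow_params(10000), lung)
  expect_true(all(seg$mask[l == 2L]))        # contains all true tumor
  expect_gt(sum(seg$mask & l == 4L), 0)      # and overlaps the halo
})

test_that("zero tumor seeds give an empty segmentation", {
  ph <- generate_phantom(small_spec())
  lung <- compute_lung_mask(ph$volume, 15500, closing_radius = 4)
  seg <- segment_tumors(ph$volume, list(), region_grow_params(10000), lung)
  expect_equal(seg$voxel_count, 0)
})

test_that("exclusion masks restrict the domain before growth", {
  # tumor abutting the airway: without exclusion the growth may not enter
  # the excluded region even if gray values matched, because the domain is
  # carved out beforehand
  spec <- small_spec()
  ph <- generate_phantom(spec)
  l <- label_array(ph$labels)
  lung <- compute_lung_mask(ph$volume, 15500, closing_radius = 6)
  aw <- segment_airways(ph$volume, trachea_seed(spec),
                        region_grow_params(8000), lung)
  seg <- segment_tumors(ph$volume, list(c(28L, 20L, 20L)),
                        region_grow_params(10000), lung, exclude = aw$mask)
  expect_equal(sum(seg$mask & aw$mask), 0)
})
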