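# Voxel dose engine: convolution, DVH, statistics, engine equivalence.

make_tia <- function(arr, spacing = 2) {
  g <- VoxelGrid(dim(arr), spacing = spacing)
  new("TIAMap", grid = g, tia = arr, provenance = list())
}

test_that("a delta kernel scales the TIA map elementwise", {
  set.seed(1)
  arr <- array(runif(10^3), c(10, 10, 10))
  tia <- make_tia(arr)
  k <- new("DoseKernel", values = array(3e-4, c(1, 1, 1)),
           spacing = rep(2, 3), nuclide = "lu177", energyRetained = 1e-15)
  d <- convolveDose(tia, k)
  expect_equal(d@dose, arr * 3e-4, tolerance = 1e-12)
})

test_that("FFT convolution matches the direct-sum oracle", {
  set.seed(42)
  for (i in 1:3) {
    dims <- sample(12:24, 3, replace = TRUE)
    arr <- array(runif(prod(dims)), dims)
    k <- array(runif(5 * 3 * 5), c(5, 3, 5))
    f <- voxdose:::fftConvolve3d(arr, k)
    o <- direct_convolve(arr, k)
    expect_lt(max(abs(f - o)) / max(o), 1e-9)
  }
})

test_that("energy is conserved when nothing escapes the grid", {
  ph <- uniform_phantom("sphere", 4, conc = 1, spacing = 2, half_size = 30)
  tia <- voxelTiaMap(list(ph$image), ph$mask, mode = "voxelwise",
                     tailMode = "physical")
  k <- buildParametricKernel(2, localFraction = 0.4, betaRangeMm = 1.5,
                             photonFraction = 0, radiusVoxels = 4)
  d <- convolveDose(tia, k)
  m_vox_kg <- voxelVolumeMl(ph$grid) * 1e-3
  energy_in <- sum(tia@tia) * 1e6 * k@energyRetained
  energy_out <- sum(d@dose) * m_vox_kg
  expect_equal(energy_out, energy_in, tolerance = 1e-6)
})

test_that("dose is linear in the TIA map", {
  set.seed(3)
  arr <- array(runif(8^3), c(8, 8, 8))
  k <- buildParametricKernel(2, localFraction = 0.5, betaRangeMm = 1,
                             photonFraction = 0, radiusVoxels = 2)
  d1 <- convolveDose(make_tia(arr), k)@dose
  d3 <- convolveDose(make_tia(3 * arr), k)@dose
  expect_equal(d3, 3 * d1, tolerance = 1e-12)
})

test_that("kernel/grid spacing mismatch is an error", {
  arr <- array(1, c(8, 8, 8))
  k <- buildParametricKernel(4.8, radiusVoxels = 1)
  expect_error(convolveDose(make_tia(arr, spacing = 2), k),
               "does not match grid spacing")
})

test_that("masked convolution never exceeds the full field", {
  # with background activity present, masking before convolution removes
  # cross-irradiation: per-voxel dose can only drop
  ph <- uniform_phantom("ellipsoid", 14.8, conc = 1, spacing = 2)
  warm <- paintActivity(ph$mask, c(voi = 1), background = 0.2,
                        timePostInjection = 24)
  tia <- voxelTiaMap(list(warm), ph$mask, mode = "voxelwise",
                     tailMode = "physical")
  k <- buildParametricKernel(2, localFraction = 0.4, betaRangeMm = 2,
                             photonFraction = 0, radiusVoxels = 3)
  full <- convolveDose(tia, k, maskMode = "full_field")
  masked <- convolveDose(tia, k, mask = ph$mask, maskLabels = "voi",
                         maskMode = "mask_before")
  expect_true(all(masked@dose <= full@dose + 1e-12))
  expect_lt(mean(masked@dose[ph$mask@labels == 1L]),
            mean(full@dose[ph$mask@labels == 1L]))
})

test_that("equal-volume torus receives less mean dose than ellipsoid", {
  # surface-driven leakage: the less compact shape loses more energy
  mean_voi_dose <- function(kind) {
    ph <- uniform_phantom(kind, 9.7, conc = 1.53, spacing = 2)
    tia <- voxelTiaMap(list(ph$image), ph$mask, mode = "voxelwise",
                       tailMode = "physical")
    k <- buildParametricKernel(2, localFraction = 0.4, betaRangeMm = 2.5,
                               photonFraction = 0, radiusVoxels = 4)
    d <- convolveDose(tia, k, mask = ph$mask, maskMode = "mask_before")
    doseStats(d, ph$mask, "voi")$mean_gy
  }
  expect_lt(mean_voi_dose("torus"), mean_voi_dose("ellipsoid"))
})

test_that("DVH: step function for uniform dose, V(2 Gy) for two levels", {
  g <- VoxelGrid(c(6, 6, 6), spacing = 2)
  labels <- array(1L, c(6, 6, 6))
  nm <- c(voi = 1L)
  mask <- new("VoiMask", grid = g, labels = labels, labelNames = nm)

  uni <- new("DoseMap", grid = g, dose = array(2, c(6, 6, 6)))
  dvh <- computeDvh(uni, mask, "voi", nBins = 10)
  expect_equal(dvh$cum_fraction[dvh$dose_gy <= 2], rep(1, 11))
  expect_true(all(diff(dvh$cum_fraction) <= 0))

  two <- array(1, c(6, 6, 6)); two[1:3, , ] <- 3
  dm <- new("DoseMap", grid = g, dose = two)
  dvh2 <- computeDvh(dm, mask, "voi", nBins = 300)
  v2 <- dvh2$cum_fraction[which.min(abs(dvh2$dose_gy - 2))]
  expect_equal(v2, 0.5)

  # mean dose recovered from the DVH integral
  dvh3 <- computeDvh(dm, mask, "voi", nBins = 2000)
  mean_from_dvh <- pracma::trapz(dvh3$dose_gy, dvh3$cum_fraction)
  expect_equal(mean_from_dvh, mean(two), tolerance = 0.005)

  empty <- new("VoiMask", grid = g, labels = array(0L, c(6, 6, 6)),
               labelNames = integer(0))
  expect_error(computeDvh(uni, empty, 1L), "empty VOI")
})

test_that("dose statistics summarize in-mask voxels only", {
  g <- VoxelGrid(c(4, 4, 4), spacing = 2)
  labels <- array(0L, c(4, 4, 4)); labels[1:3] <- 1L
  mask <- new("VoiMask", grid = g, labels = labels, labelNames = c(voi = 1L))
  dose <- array(100, c(4, 4, 4)); dose[1:3] <- c(1, 2, 3)
  dm <- new("DoseMap", grid = g, dose = dose)
  st <- doseStats(dm, mask, "voi")
  expect_equal(st$mean_gy, 2)
  expect_equal(st$n_voxels, 3)
  expect_equal(st$volume_ml, 3 * voxelVolumeMl(g))

  uni <- new("DoseMap", grid = g, dose = array(5, c(4, 4, 4)))
  stu <- doseStats(uni, mask, "voi")
  expect_equal(stu$sd_gy, 0)
  expect_equal(stu$cv_pct, 0)
})

test_that("blur induces dose heterogeneity in a uniform cylinder", {
  ph <- uniform_phantom("cylinder", 14, conc = 1, spacing = 2)
  blurred <- simulateSpect(ph$image, psfFwhmMm = 8)
  k <- buildParametricKernel(2, localFraction = 1, photonFraction = 0,
                             radiusVoxels = 1)
  cv_of <- function(img) {
    tia <- voxelTiaMap(list(img), ph$mask, mode = "voxelwise",
                       tailMode = "physical")
    d <- convolveDose(tia, k)
    doseStats(d, ph$mask, "voi")$cv_pct
  }
  expect_equal(cv_of(ph$image), 0, tolerance = 1e-9)
  expect_gt(cv_of(blurred), 1)
})

test_that("voxel and organ engines agree for local deposition", {
  # uniform activity + local-deposition kernel: the voxel mean equals the
  # sphere-model dose for the same TIA and rasterized mass
  ph <- uniform_phantom("sphere", 28.73, conc = 1.53, spacing = 2)
  tia <- voxelTiaMap(list(ph$image), ph$mask, mode = "voxelwise",
                     tailMode = "physical")
  k <- buildParametricKernel(2, localFraction = 1, photonFraction = 0,
                             radiusVoxels = 1)
  d <- convolveDose(tia, k, mask = ph$mask, maskMode = "mask_before")
  st <- doseStats(d, ph$mask, "voi")
  organ <- sphereDose(sum(tia@tia[ph$mask@labels == 1L]), st$volume_ml)
  expect_equal(st$mean_gy, organ, tolerance = 1e-9)
})

test_that("sphere model bounds the voxel mean for spread kernels", {
  # edge leakage only lowers the voxel result; phi = 1 is the ceiling
  ph <- uniform_phantom("sphere", 9.7, conc = 1.53, spacing = 2)
  tia <- voxelTiaMap(list(ph$image), ph$mask, mode = "voxelwise",
                     tailMode = "physical")
  k <- buildParametricKernel(2, localFraction = 0.3, betaRangeMm = 3,
                             photonFraction = 0, radiusVoxels = 5)
  d <- convolveDose(tia, k, mask = ph$mask, maskMode = "mask_before")
  st <- doseStats(d, ph$mask, "voi")
  organ <- sphereDose(sum(tia@tia[ph$mask@labels == 1L]), st$volume_ml)
  expect_lt(st$mean_gy, organ)
})
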