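# Shape rasterization, activity painting and SPECT-like degradation.

test_that("rasterized volumes match the analytic target volume", {
  # sphere of diameter 38 mm: V = 4/3 pi 1.9^3 cm^3 = 28.73 ml
  g <- VoxelGrid(c(48, 48, 48), spacing = 1)
  m <- rasterizeShape(shapeSpec("sphere", 28.73), g, supersample = 3)
  expect_equal(sum(m@labels == 1L) * voxelVolumeMl(g), 28.73,
               tolerance = 0.01)

  # every insert geometry solves and rasterizes near its target volume;
  # binary masks quantize flat faces (cylinder, tube) and tight curvature
  # (torus) more coarsely than smooth convex surfaces
  tol <- c(ellipsoid = 0.01, pear = 0.01, torus = 0.03,
           cylinder = 0.05, tube = 0.05)
  for (kind in names(tol)) {
    ph <- uniform_phantom(kind, 28.5, spacing = 1, half_size = 45,
                          supersample = 3)
    vol <- sum(ph$mask@labels == 1L) * voxelVolumeMl(ph$grid)
    expect_equal(vol, 28.5, tolerance = tol[[kind]],
                 label = paste(kind, "rasterized volume"))
  }
})

test_that("torus parameters solve to the named equivalent diameter", {
  # target volume 9.7 ml -> d_eq = (6 V / pi)^(1/3) = 26.5 mm, the "26"
  # in the insert acronym
  spec <- shapeSpec("torus", 9.7)
  expect_equal(equivalentDiameterMm(spec), 26.46, tolerance = 0.001)
  sol <- voxdose:::solveShape(spec)
  R <- sol$params$major_radius_mm
  r <- sol$params$minor_radius_mm
  expect_equal(R / r, 3)                        # fixed aspect ratio
  expect_equal(2 * pi^2 * R * r^2 / 1000, 9.7)  # analytic volume
})

test_that("rasterization error decreases as the voxel size shrinks", {
  for (kind in c("sphere", "ellipsoid", "pear", "torus")) {
    errs <- vapply(c(4, 2, 1), function(sp) {
      ph <- uniform_phantom(kind, 28.5, spacing = sp, half_size = 48,
                            supersample = 2)
      abs(sum(ph$mask@labels == 1L) * voxelVolumeMl(ph$grid) - 28.5) / 28.5
    }, numeric(1))
    expect_true(all(diff(errs) < 0), label = paste(kind, "error sequence"))
  }
})

test_that("shapes exceeding grid bounds are rejected", {
  g <- VoxelGrid(c(10, 10, 10), spacing = 1)
  expect_error(rasterizeShape(shapeSpec("sphere", 28.73), g),
               "exceeds grid bounds")
})

test_that("surface-to-volume ordering: torus > ellipsoid > sphere", {
  # the geometric driver of organ-vs-voxel dose discrepancies: at equal
  # volume, the torus exposes the most surface, the sphere the least
  sv <- vapply(c("torus", "ellipsoid", "sphere"), function(kind) {
    ph <- uniform_phantom(kind, 28.5, spacing = 1, half_size = 35,
                          supersample = 2)
    maskSurfaceAreaMm2(ph$mask) /
      (sum(ph$mask@labels == 1L) * voxelVolumeMl(ph$grid) * 1000)
  }, numeric(1))
  expect_true(sv[["torus"]] > sv[["ellipsoid"]])
  expect_true(sv[["ellipsoid"]] > sv[["sphere"]])
})

test_that("painted activity equals concentration x volume per label", {
  ph <- uniform_phantom("ellipsoid", 14.8, conc = 1.53, spacing = 2)
  n_in <- sum(ph$mask@labels == 1L)
  expect_equal(totalActivityMBq(ph$image),
               1.53 * n_in * voxelVolumeMl(ph$grid))
  expect_true(all(ph$image@concentration[ph$mask@labels == 1L] == 1.53))
  expect_true(all(ph$image@concentration[ph$mask@labels == 0L] == 0))

  # warm background: organ-to-background contrast ratio as published
  warm <- paintActivity(ph$mask, c(voi = 0.53), background = 0.03)
  expect_equal(0.53 / 0.03, 17.67, tolerance = 0.001)
  expect_equal(totalActivityMBq(warm),
               (0.53 * n_in + 0.03 * (length(ph$mask@labels) - n_in)) *
                 voxelVolumeMl(ph$grid))

  # all-zero painting
  zero <- paintActivity(ph$mask, c(voi = 0), background = 0)
  expect_equal(totalActivityMBq(zero), 0)

  expect_error(paintActivity(ph$mask, c(nonexistent = 1)), "unknown label")
})

test_that("SPECT emulation: identity at zero FWHM, conservation, PVE", {
  ph <- uniform_phantom("sphere", 2.57, conc = 1.53, spacing = 2,
                        half_size = 40)  # d = 17 mm sphere, wide margins
  same <- simulateSpect(ph$image, psfFwhmMm = 0)
  expect_identical(same@concentration, ph$image@concentration)

  blurred <- simulateSpect(ph$image, psfFwhmMm = 10)
  expect_equal(totalActivityMBq(blurred), totalActivityMBq(ph$image),
               tolerance = 1e-3)
  # partial volume effect: a 17 mm sphere at 10 mm FWHM under-recovers
  expect_lt(max(blurred@concentration[ph$mask@labels == 1L]), 1.53)

  expect_error(simulateSpect(ph$image, psfFwhmMm = -1), ">= 0")
})

test_that("Poisson noise branch is reproducible under a fixed seed", {
  ph <- uniform_phantom("sphere", 28.73, spacing = 2)
  n1 <- simulateSpect(ph$image, 5, noiseSeed = 42)
  n2 <- simulateSpect(ph$image, 5, noiseSeed = 42)
  n3 <- simulateSpect(ph$image, 5, noiseSeed = 43)
  expect_identical(n1@concentration, n2@concentration)
  expect_false(identical(n1@concentration, n3@concentration))
})

test_that("patient TACs follow the imaging schedule and kinetics", {
  tacs <- simulatePatientTacs(3, seed = 11)
  expect_setequal(unique(tacs$time_h), c(1, 4, 24, 44, 72))
  expect_true(all(tacs$activity_MBq >= 0))

  # zero-variance kinetics make all patients identical
  kin <- list(kidneys = list(A0_MBq = 100, T_washout_h = 50, T_uptake_h = 1,
                             cv_A0 = 0, cv_rates = 0))
  t0 <- simulatePatientTacs(4, organs = "kidneys", kinetics = kin, seed = 1)
  by_pat <- split(t0$activity_MBq, t0$patient_id)
  for (p in by_pat) expect_equal(p, by_pat[[1]])

  # reproducibility under seed
  expect_identical(simulatePatientTacs(5, seed = 3),
                   simulatePatientTacs(5, seed = 3))

  expect_error(simulatePatientTacs(2, schedule = c(4, 1)),
               "strictly increasing")
})

test_that("washout rates never fall below physical decay", {
  kin <- list(kidneys = list(A0_MBq = 100, T_washout_h = 5000, T_uptake_h = 1,
                             cv_A0 = 0, cv_rates = 0))
  tt <- simulatePatientTacs(1, organs = "kidneys", kinetics = kin, seed = 1)
  # requested washout far slower than physics: curve must decay at least
  # as fast as the physical half-life between late samples
  a44 <- tt$activity_MBq[tt$time_h == 44]
  a72 <- tt$activity_MBq[tt$time_h == 72]
  expect_lte(a72 / a44, exp(-lu177$lambda_per_h * 28) * 1.001)
})
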