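test_that("attenuation lookup matches the table and rejects off-grid energies", {
  tab <- default_tissue_properties()
  p <- small_phantom()
  mu <- attenuation_volume(p, tab, 100L)
  # single-organ check: liver voxels carry exactly the liver entry
  liver_mu <- tab$mu_100[match(organ_ids()[["liver"]], tab$organ_id)]
  expect_true(all(mu[p$labels == organ_ids()[["liver"]]] == liver_mu))
  bg_mu <- tab$mu_100[match(0L, tab$organ_id)]
  expect_true(all(mu[p$labels == 0L] == bg_mu))
  expect_error(attenuation_volume(p, tab, 101L), "no interpolation")

  # monotone energy dependence of soft tissue in the shipped table
  mu90 <- attenuation_volume(p, tab, 90L)
  mu120 <- attenuation_volume(p, tab, 120L)
  soft <- p$labels == organ_ids()[["liver"]]
  expect_true(all(mu90[soft] >= mu120[soft]))
})

test_that("HU conversion hits the anchor points", {
  expect_equal(mu_to_hu(0.17, 0.17), 0)
  expect_equal(mu_to_hu(0, 0.17), -1000)
  expect_equal(mu_to_hu(2 * 0.17, 0.17), 1000)
  expect_error(mu_to_hu(array(0.1, c(2, 2, 2)), 0), "positive")
})

test_that("cone-beam FOV mask keeps a cylinder around the liver", {
  p <- small_phantom()
  ct <- simulate_ct(p, normalize = FALSE)
  liver <- extract_organ_mask(p, "liver")

  # radius covering the whole grid changes nothing
  huge <- apply_cbct_fov(ct, liver, fov_spec(radius_mm = 1e4))
  expect_equal(huge$intensities, ct$intensities)

  # tiny radius floors (almost) everything
  tiny <- apply_cbct_fov(ct, liver, fov_spec(radius_mm = 1e-3))
  expect_lte(mean(tiny$intensities != ct$window[1]), 2 / prod(dim(ct$intensities)))

  # retained fraction ~ cylinder area / slice area (analytic oracle)
  r <- 60
  masked <- apply_cbct_fov(ct, liver, fov_spec(radius_mm = r),
                           floor_value = -2000)
  kept <- mean(masked$intensities != -2000)
  d <- dim(ct$intensities)
  expected <- pi * r^2 / prod((d[1:2] - 1) * ct$spacing[1:2])
  expect_lt(abs(kept - expected) / expected, 0.1)

  expect_error(apply_cbct_fov(ct, array(FALSE, dim(liver))), "empty")
})

test_that("VIBE signal equation matches an independent evaluation", {
  # saturation limits
  expect_equal(vibe_signal(800, 34, 1, vibe_parameters(alpha = 0)), 0)
  p_sat <- vibe_parameters(TR = 1e6, TE = 1e-9, alpha = 30)
  expect_equal(vibe_signal(800, 34, 2, p_sat), 2 * sin(30 * pi / 180),
               tolerance = 1e-6)

  # independent scalar evaluation at liver-like parameters
  T1 <- 800; T2 <- 34; rho <- 1; TR <- 7.25; TE <- 4.54; a <- 10 * pi / 180
  e1 <- exp(-TR / T1)
  expected <- rho * sin(a) * (1 - e1) / (1 - cos(a) * e1) * exp(-TE / T2)
  expect_equal(vibe_signal(800, 34, 1, vibe_parameters(7.25, 4.54, 10)),
               expected)
  expect_gt(expected, 0)

  # monotone in rho and in T2 (fixed others), on grids
  p <- vibe_parameters()
  rhos <- seq(0.1, 1, by = 0.1)
  expect_true(all(diff(vibe_signal(800, 34, rhos, p)) > 0))
  T2s <- seq(20, 200, by = 20)
  expect_true(all(diff(vibe_signal(800, T2s, 1, p)) > 0))

  expect_error(vibe_signal(-1, 34, 1), "positive")
  expect_error(vibe_parameters(TR = 5, TE = 6))
})

test_that("MRI phantom jitter is bounded, seeded, and off when zero", {
  p <- small_phantom()
  tab <- default_tissue_properties()
  no_jit <- mri_phantom(p, tab, jitter_frac = 0, seed = 1)
  # jitter 0: organ intensities equal the plain signal of the table values
  liver_row <- match(organ_ids()[["liver"]], tab$organ_id)
  si <- vibe_signal(tab$T1_ms[liver_row], tab$T2_ms[liver_row],
                    tab$rho[liver_row])
  expect_equal(unique(no_jit$intensities[p$labels ==
                                           organ_ids()[["liver"]]]), si)

  a <- mri_phantom(p, tab, seed = 5)
  b <- mri_phantom(p, tab, seed = 5)
  expect_identical(a$intensities, b$intensities)
  expect_false(identical(a$intensities,
                         mri_phantom(p, tab, seed = 6)$intensities))

  # realized organ signal lies between the extremal jittered evaluations
  j <- 0.05
  vals <- expand.grid(t1 = c(1 - j, 1 + j), t2 = c(1 - j, 1 + j),
                      r = c(1 - j, 1 + j))
  extremes <- mapply(function(t1, t2, r)
    vibe_signal(tab$T1_ms[liver_row] * t1, tab$T2_ms[liver_row] * t2,
                tab$rho[liver_row] * r),
    vals$t1, vals$t2, vals$r)
  realized <- unique(a$intensities[p$labels == organ_ids()[["liver"]]])
  expect_gte(realized, min(extremes))
  expect_lte(realized, max(extremes))
})

test_that("windowing is affine with exact endpoints and clipping", {
  arr <- array(c(-2000, -1024, 238, 1500, 3000, 0), c(6, 1, 1))
  v <- modality_volume(arr, "CT", c(1, 1, 1))
  n <- window_and_normalize(v, c(-1024, 1500))
  expect_equal(n$intensities[2, 1, 1], -1)
  expect_equal(n$intensities[4, 1, 1], 1)
  expect_equal(n$intensities[1, 1, 1], -1)  # clipped below
  expect_equal(n$intensities[5, 1, 1], 1)   # clipped above
  expect_equal(n$intensities[3, 1, 1],
               (238 - (-1024)) / (1500 - (-1024)) * 2 - 1)  # affine oracle
  expect_true(n$normalized)

  # midpoint maps to zero
  m <- window_and_normalize(modality_volume(array(238, c(2, 2, 2)), "CT",
                                            c(1, 1, 1)), c(0, 476))
  expect_equal(unique(as.vector(m$intensities)), 0)

  # percentile windowing on a constant volume is an error
  const <- modality_volume(array(5, c(4, 4, 4)), "MRI", c(1, 1, 1))
  expect_error(window_and_normalize(const, "percentile"), "constant")
})

test_that("modalities from one phantom are co-registered by construction", {
  p <- small_phantom()
  ct <- simulate_ct(p)
  mri <- simulate_mri(p, seed = 2)
  liver <- extract_organ_mask(p, "liver")
  # anatomy agrees voxel-for-voxel: each modality is constant-per-organ,
  # so the liver region is exactly one intensity level in both
  expect_equal(length(unique(ct$intensities[liver])), 1L)
  expect_equal(length(unique(mri$intensities[liver])), 1L)
  expect_identical(dim(ct$intensities), dim(mri$intensities))
})

test_that("tissue tables round-trip through CSV and validate", {
  tab <- default_tissue_properties()
  path <- tempfile(fileext = ".csv")
  write_tissue_table(tab, path)
  back <- read_tissue_table(path)
  expect_equal(back$mu_100, tab$mu_100)
  expect_equal(water_attenuation(back, 100L), water_attenuation(tab, 100L))
  expect_error(water_attenuation(tab, 101L), "no interpolation")

  bad <- tab; bad$T1_ms[2] <- -5
  path2 <- tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(read_tissue_table(path2), "positive")
})

test_that("volume resampling preserves content at matched grids", {
  p <- small_phantom()
  ct <- simulate_ct(p)
  half <- resample_volume(ct, ct$spacing * 2)
  expect_equal(dim(half$intensities), c(24, 24, 24))
  # downsampled then compared at shared lattice points (every 2nd voxel)
  expect_equal(half$intensities[1:10, 1, 1],
               ct$intensities[seq(1, 19, 2), 1, 1])
  lab <- resample_volume(p, p$spacing * 2)
  expect_true(all(unique(as.vector(lab$labels)) %in% p$organ_catalog))
})
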