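test_that("Dice matches counting oracles and rejects empty input", {
  a <- array(FALSE, c(10, 10, 10)); a[1:4, 1:5, 1:5] <- TRUE  # 100 voxels
  b <- array(FALSE, c(10, 10, 10)); b[3:6, 1:5, 1:5] <- TRUE  # overlap 50
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, b), 0.5)
  disj <- array(FALSE, c(10, 10, 10)); disj[8:10, 8:10, 8:10] <- TRUE
  expect_equal(dice(a, disj), 0)
  expect_error(dice(a & FALSE, b & FALSE), "empty")
  expect_error(dice(a, array(FALSE, c(5, 5, 5))), "grid")
})

test_that("liver closing fills vessel holes, is idempotent and extensive", {
  liver <- array(FALSE, c(24, 24, 24))
  liver[6:19, 6:19, 6:19] <- TRUE
  vessel <- array(FALSE, c(24, 24, 24))
  vessel[12:13, 12:13, 8:16] <- TRUE       # cylindrical interior hole
  liver[vessel] <- FALSE

  closed <- close_liver_mask(liver, vessel, structuring_radius = 3)
  expect_true(all(closed[liver]))           # output contains the input
  expect_true(all(closed[vessel]))          # hole filled (voxel oracle)
  expect_equal(sum(closed), sum(liver) + sum(vessel))

  # closing without holes changes nothing for a small radius
  solid <- array(FALSE, c(24, 24, 24)); solid[6:19, 6:19, 6:19] <- TRUE
  expect_equal(close_liver_mask(solid, NULL, 2), solid)

  # idempotent
  twice <- close_liver_mask(closed, NULL, 3)
  expect_equal(twice, close_liver_mask(liver, vessel, 3))
})

test_that("mask propagation through a constant-displacement transform shifts", {
  d <- c(20, 20, 20); sp <- c(2, 2, 2)
  grid <- mmsynth:::bspline_grid(d, sp, c(0, 0, 0), delta = 20)
  coef <- array(0, c(grid$ncp, 3L))
  tr <- structure(list(coef = coef, grid = grid,
                       cfg = registration_config(),
                       fixed_meta = list(dim = d, spacing = sp,
                                         origin = c(0, 0, 0))),
                  class = "bspline_transform")
  mask <- array(FALSE, d); mask[8:12, 8:12, 8:12] <- TRUE
  expect_equal(propagate_mask(mask, tr), mask)   # identity transform

  # all-equal coefficients give a constant field (partition of unity):
  # +4 mm along x pulls the mask 2 voxels toward lower x
  coef[, , , 1] <- 4
  tr$coef <- coef
  shifted <- propagate_mask(mask, tr)
  expect_equal(which(shifted, arr.ind = TRUE)[, 1] + 2,
               which(mask, arr.ind = TRUE)[, 1])
  expect_type(shifted, "logical")
  expect_error(propagate_mask(array(FALSE, c(4, 4, 4)), tr), "grid")
})

test_that("registering a volume to itself stays near identity", {
  pair <- small_pair()
  ct <- simulate_ct(pair$exhaled)
  cfg <- registration_config("MS", 50, max_iterations = 10, shrink = 2)
  tr <- register_bspline(ct, ct, cfg)
  vec <- mmsynth:::bspline_displacement(tr, dim(ct$intensities),
                                        ct$spacing, ct$origin)
  expect_lt(mean(sqrt(vec[, , , 1]^2 + vec[, , , 2]^2 + vec[, , , 3]^2)),
            min(ct$spacing))   # mean displacement under one voxel
})

test_that("registration improves liver Dice and is deterministic", {
  pair <- small_pair()
  ct_ex <- simulate_ct(pair$exhaled)
  ct_in <- simulate_ct(pair$inhaled)
  masks <- closed_livers()
  pre <- dice(masks$moving, masks$fixed)
  cfg <- registration_config("MS", 50, max_iterations = 60, shrink = 1)
  tr <- register_bspline(ct_ex, ct_in, cfg)
  post <- dice(propagate_mask(masks$moving, tr), masks$fixed)
  expect_gt(post, pre)       # Dice comparison oracle

  tr2 <- register_bspline(ct_ex, ct_in, cfg)
  expect_identical(tr$coef, tr2$coef)  # bit-for-bit reproducible

  expect_error(
    register_bspline(ct_ex, simulate_mri(pair$inhaled, seed = 1),
                     registration_config("MS", 50)), "monomodal")
})

test_that("transforms serialize losslessly to JSON", {
  pair <- small_pair()
  ct <- simulate_ct(pair$exhaled)
  tr <- register_bspline(ct, ct,
                         registration_config("MS", 70, max_iterations = 3))
  path <- tempfile(fileext = ".json")
  write_transform(tr, path)
  back <- read_transform(path)
  expect_equal(back$coef, tr$coef)
  expect_equal(back$grid$ncp, tr$grid$ncp)
  expect_equal(back$cfg$metric, "MS")
})

test_that("sweep enumeration matches the benchmark design", {
  s <- enumerate_sweep_settings()
  expect_equal(sum(s$pair == "ct-ct"), 18)      # monomodal: 3 metrics x 6
  expect_equal(sum(s$pair == "cbct-ct"), 12)    # multimodal: 2 metrics x 6
  expect_equal(sum(s$pair == "mri-ct"), 12)
  expect_true(all(!("MS" %in% s$metric[!s$monomodal])))
  expect_equal(sort(unique(s$spacing_mm)), seq(50, 150, by = 20))

  d <- run_sweep(list(), dry_run = TRUE)
  expect_equal(nrow(d), 42)
})

test_that("run_sweep records one row per phantom and setting", {
  pair <- small_pair()
  masks <- closed_livers()
  inst <- list(id = "ph1",
               fixed_ct = simulate_ct(pair$exhaled),
               moving = list(ct = simulate_ct(pair$inhaled)),
               liver_fixed = extract_organ_mask(pair$exhaled, "liver"),
               vessel_fixed = extract_organ_mask(pair$exhaled,
                                                 "hepatic_vessel"),
               liver_moving = extract_organ_mask(pair$inhaled, "liver"),
               vessel_moving = extract_organ_mask(pair$inhaled,
                                                  "hepatic_vessel"))
  res <- run_sweep(list(inst), pairs = "ct-ct", spacings = c(50, 150),
                   cfg_base = registration_config(max_iterations = 5,
                                                  shrink = 2))
  expect_equal(nrow(res), 6)   # 3 metrics x 2 spacings
  expect_true(all(res$dice_pre == res$dice_pre[1]))  # pre precedes settings
  expect_true(all(res$dice_post >= 0 & res$dice_post <= 1))

  agg <- aggregate_sweep(res)
  expect_equal(nrow(agg), 6)
  expect_true(all(c("dice_post_p10", "dice_post_p90") %in% names(agg)))

  inst_bad <- inst; inst_bad$moving <- list()
  expect_error(run_sweep(list(inst_bad), pairs = "ct-ct"), "missing")
})
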