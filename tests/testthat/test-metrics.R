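test_that("MAE excludes background and matches brute force", {
  set.seed(1)
  a <- array(rnorm(64), c(4, 4, 4))
  b <- array(rnorm(64), c(4, 4, 4))
  expect_equal(mae(a, a), 0)
  bg <- array(FALSE, c(4, 4, 4)); bg[1, , ] <- TRUE
  expect_equal(mae(a, b, bg), mean(abs(a[-1, , ] - b[-1, , ])))  # oracle
  # constant foreground offset
  b2 <- a; b2[!bg] <- b2[!bg] + 3.5
  expect_equal(mae(a, b2, bg), 3.5)
  expect_error(mae(a, b, array(TRUE, c(4, 4, 4))), "background")
  expect_error(mae(a, array(0, c(3, 4, 4))), "shape")
})

test_that("SSIM is 1 on identity, symmetric, near 0 for independent noise", {
  set.seed(3)
  a <- array(rnorm(32 * 32 * 3), c(32, 32, 3))
  b <- array(rnorm(32 * 32 * 3), c(32, 32, 3))
  expect_equal(ssim(a, a), 1)
  expect_equal(ssim(a, b), ssim(b, a))
  expect_lt(abs(ssim(a, b)), 0.05)   # Monte-Carlo oracle: independence
})

test_that("FSIM is 1 on identity and degrades with distortion", {
  set.seed(4)
  base <- array(0, c(48, 48, 2))
  base[12:36, 12:36, ] <- 1
  base <- base + array(rnorm(length(base), 0, 0.05), dim(base))
  expect_equal(fsim(base, base), 1)
  blurred <- array(apply(base, 3, function(m)
    mmsynth:::filter2_gauss(m, 3)), dim(base))
  f_blur <- fsim(base, blurred)
  expect_lt(f_blur, 1)
  expect_gt(f_blur, 0)
})

test_that("edge ratios match exhaustive tallies on synthetic patterns", {
  img <- array(0, c(48, 48, 2))
  img[16:32, 16:32, ] <- 1
  expect_equal(unname(edge_ratios(img, img)), c(1, 0))
  expect_equal(unname(edge_ratios(img, img * 0)[1]), 0)
  expect_error(edge_ratios(img * 0, img), "no edges")

  # shifted pattern: ratios equal direct pixel tallies of the edge maps
  shifted <- array(0, c(48, 48, 2))
  shifted[24:40, 24:40, ] <- 1
  r <- edge_ratios(img, shifted)
  e_ref <- mmsynth:::canny_slice(img[, , 1])
  e_tst <- mmsynth:::canny_slice(shifted[, , 1])
  expect_equal(unname(r[1]), sum(e_ref & e_tst) / sum(e_ref))
  expect_equal(unname(r[2]), sum(e_tst & !e_ref) / sum(e_ref))
})

test_that("noise magnitude is the masked standard deviation", {
  set.seed(5)
  vol <- array(rnorm(20^3, 100, 7), c(20, 20, 20))
  mask <- array(FALSE, dim(vol)); mask[5:15, 5:15, 5:15] <- TRUE
  expect_equal(noise_magnitude(vol, mask), sd(vol[mask]))
  expect_equal(noise_magnitude(vol + 50, mask), noise_magnitude(vol, mask))
  expect_equal(noise_magnitude(array(3, c(4, 4, 4)),
                               array(TRUE, c(4, 4, 4))), 0)
  expect_error(noise_magnitude(vol, mask & FALSE), "empty")
})

test_that("histogram correlation behaves on identical/disjoint supports", {
  set.seed(6)
  a <- array(rnorm(4000), c(20, 20, 10))
  expect_equal(histogram_correlation(a, a), 1)
  # same distribution, different sample size: near 1 after normalization
  b <- array(rnorm(32000), c(40, 40, 20))
  expect_gt(histogram_correlation(a, b, bins = 24, range = c(-4, 4)), 0.9)
  # disjoint supports: direct Pearson on the count vectors
  lo <- array(runif(1000, 0, 1), c(10, 10, 10))
  hi <- array(runif(1000, 2, 3), c(10, 10, 10))
  r <- histogram_correlation(lo, hi, bins = 30, range = c(0, 3))
  expect_lt(r, 0)
  expect_error(histogram_correlation(array(1, c(4, 4, 4)),
                                     array(1, c(4, 4, 4)),
                                     range = c(0, 2)), "single occupied")
})

test_that("Gaussian MAE/NM ratio converges to sqrt(2/pi), scale-free", {
  r1 <- mae_nm_gaussian_ratio(2e5, sigma = 1, seed = 10)
  r2 <- mae_nm_gaussian_ratio(2e5, sigma = 250, seed = 10)
  expect_equal(r1, r2, tolerance = 1e-12)  # sigma cancels exactly
  # within 3 Monte-Carlo standard errors of the analytic limit
  se <- sqrt(1 - 2 / pi) / sqrt(2e5)
  expect_lt(abs(r1 - sqrt(2 / pi)), 3 * se)
  expect_error(mae_nm_gaussian_ratio(100))
})

test_that("metric report aggregates per modality with identity baselines", {
  pair <- small_pair()
  ct <- simulate_ct(pair$exhaled)
  liver <- extract_organ_mask(pair$exhaled, "liver")
  bg <- extract_organ_mask(pair$exhaled, 0L)
  noisy <- inject_textured_noise(ct, "ramp", 0.03, seed = 2)
  rep1 <- build_metric_report(
    synthetic = list(CT = list(noisy)),
    phantom = list(CT = list(ct)),
    reference = list(CT = list(noisy)),
    masks = list(CT = list(background = bg, liver = liver)),
    nps_patch = 8)
  expect_equal(nrow(rep1), 1)
  expect_equal(rep1$NCC_mean, 1)          # reference is the synthetic itself
  expect_equal(rep1$HistCC_mean, 1)
  expect_gt(rep1$SSIM_mean, 0.8)
  expect_equal(rep1$mae_nm_ratio,
               rep1$MAE_mean / rep1$NM_synthetic_mean)

  # identity all around: perfect scores, zero errors
  rep0 <- build_metric_report(
    synthetic = list(CT = list(ct)),
    phantom = list(CT = list(ct)),
    reference = list(CT = list(noisy)),
    masks = list(CT = list(background = bg, liver = liver)),
    nps_patch = 8)
  expect_equal(rep0$SSIM_mean, 1)
  expect_equal(rep0$FSIM_mean, 1)
  expect_equal(rep0$EPR_mean, 1)
  expect_equal(rep0$EGR_mean, 0)
  expect_equal(rep0$MAE_mean, 0)
})

test_that("published reference ratios reproduce the reported bookkeeping", {
  ref <- reference_quality_metrics()
  get <- function(mod, metric)
    ref$mean[ref$modality == mod & ref$metric == metric]
  ratios <- vapply(c("CBCT", "CT", "MRI"), function(m)
    mae_nm_ratio(get(m, "MAE"), get(m, "NM_synthetic")), numeric(1))
  expect_equal(unname(round(ratios, 1)), c(2.1, 1.3, 1.5))
})
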