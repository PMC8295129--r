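# Loss-function oracles: every formula checked against brute-force
# evaluation on hand-computable grids.

test_that("intensity loss matches hand evaluation and is symmetric", {
  x <- matrix(c(0, 1), 1, 2); Gx <- matrix(c(0.5, 0.5), 1, 2)
  y <- matrix(c(0.2, -0.3), 1, 2)
  expect_equal(intensity_loss(x, x, y, y), 0)
  # |0.5-0| + |0.5-1| = 1 under the sum convention, /2 pixels under mean
  expect_equal(intensity_loss(x, Gx, y, y, convention = "sum"), 1)
  expect_equal(intensity_loss(x, Gx, y, y, convention = "mean"), 0.5)
  # symmetric under swapping the (x, Gx) and (y, Fy) roles
  expect_equal(intensity_loss(x, Gx, y, y), intensity_loss(y, y, x, Gx))
  expect_error(intensity_loss(x, matrix(0, 2, 2), y, y), "shape")
})

test_that("gradient difference loss matches the 2x2 brute-force value", {
  x <- matrix(c(0, 0, 1, 1), 2, 2)   # rows (0,1) and (0,1)
  Gx <- matrix(0, 2, 2)
  expect_equal(gradient_difference_loss(x, x), 0)
  expect_equal(gradient_difference_loss(x, -x), 0)  # |grad| sign-invariant
  # brute force: vertical diffs are 0; both horizontal diffs are |1|,
  # G's are 0, giving (1-0)^2 twice -> 2 (sum), /4 terms (mean)
  expect_equal(gradient_difference_loss(x, Gx, convention = "sum"), 2)
  expect_equal(gradient_difference_loss(x, Gx, convention = "mean"), 0.5)
  expect_error(gradient_difference_loss(matrix(0, 1, 5), matrix(0, 1, 5)),
               ">= 2 px")
})

test_that("gdl gradient agrees with numerical differentiation", {
  set.seed(42)
  x <- matrix(rnorm(16), 4, 4)
  Gx <- matrix(rnorm(16), 4, 4)
  an <- mmsynth:::gdl_grad(x, Gx, "mean")
  eps <- 1e-6
  num <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    Gp <- Gx; Gp[i, j] <- Gp[i, j] + eps
    Gm <- Gx; Gm[i, j] <- Gm[i, j] - eps
    num[i, j] <- (gradient_difference_loss(x, Gp) -
                    gradient_difference_loss(x, Gm)) / (2 * eps)
  }
  expect_equal(an$dGx, num, tolerance = 1e-5)
})

test_that("cycle loss is zero iff cycles reconstruct, additive in deltas", {
  x <- matrix(rnorm(9), 3, 3); y <- matrix(rnorm(9), 3, 3)
  expect_equal(cycle_consistency_loss(x, x, y, y), 0)
  pert <- x; pert[2, 2] <- pert[2, 2] + 0.25
  expect_equal(cycle_consistency_loss(x, pert, y, y, convention = "sum"),
               0.25)
  # strictly increasing in the perturbation size
  l1 <- cycle_consistency_loss(x, pert, y, y)
  pert[2, 2] <- pert[2, 2] + 0.25
  expect_gt(cycle_consistency_loss(x, pert, y, y), l1)
})

test_that("LSGAN losses hit their closed-form values", {
  ones <- matrix(1, 2, 2); zeros <- matrix(0, 2, 2)
  r <- lsgan_losses(ones, zeros)
  expect_equal(r$discriminator, 0)
  expect_equal(r$generator, 1)
  expect_equal(lsgan_losses(ones, ones)$generator, 0)
  # constant scores s: quadratic closed forms
  s <- 0.3
  r2 <- lsgan_losses(matrix(s, 3, 3), matrix(s, 3, 3))
  expect_equal(r2$discriminator, (s - 1)^2 + s^2)
  expect_equal(r2$generator, (s - 1)^2)
})

test_that("total generator loss combines components with the preset weights", {
  w <- gan_loss_weights(preset = "ct")
  expect_equal(c(w$lambda_cyc, w$lambda_int, w$lambda_gdl), c(10, 10, 5))
  w_mri <- gan_loss_weights(preset = "mri")
  expect_equal(c(w_mri$lambda_cyc, w_mri$lambda_int, w_mri$lambda_gdl),
               c(10, 0.4, 0.4))
  expect_equal(total_generator_loss(0, 0, 0, 0, 0, w), 0)
  expect_equal(total_generator_loss(1, 1, 1, 1, 1, w), 31)  # 1+10+10+5*2
  w0 <- gan_loss_weights(lambda_cyc = 0, lambda_int = 0, lambda_gdl = 0)
  expect_equal(total_generator_loss(1.7, 5, 5, 5, 5, w0), 1.7)
})

test_that("total loss is affine in each weight with the component as slope", {
  comps <- c(adv = 0.9, cyc = 1.3, int_ = 0.4, gdl_x = 0.2, gdl_y = 0.7)
  base <- gan_loss_weights(lambda_cyc = 2, lambda_int = 3, lambda_gdl = 4)
  f <- function(w) do.call(total_generator_loss, c(as.list(comps),
                                                   list(w = w)))
  for (lam in c("lambda_cyc", "lambda_int", "lambda_gdl")) {
    w1 <- base; w1[[lam]] <- base[[lam]] + 1
    slope <- switch(lam, lambda_cyc = comps[["cyc"]],
                    lambda_int = comps[["int_"]],
                    lambda_gdl = comps[["gdl_x"]] + comps[["gdl_y"]])
    expect_equal(f(w1) - f(base), slope)
  }
})
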