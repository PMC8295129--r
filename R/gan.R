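# CycleGAN synthesis stage: pure loss functions (adversarial, cycle,
# intensity, gradient-difference), ResNet generator and 70x70 PatchGAN
# discriminator builders, patch sampling, the training loop and slice-wise
# volume synthesis. Image losses use the per-pixel mean by default so the
# loss weights are resolution-independent; the raw-sum variant is exposed
# for exact small-grid verification.

loss_norm <- function(n, convention) if (convention == "mean") n else 1

#' Loss weight presets
#'
#' Weight triples `lambda_cyc / lambda_int / lambda_gdl` used per modality:
#' 10/10/5 for CT and CBCT, 10/0.4/0.4 for MRI (lower over-regularization
#' thresholds hold for MRI).
#'
#' @param preset `"ct"`, `"cbct"` or `"mri"`, or `NULL` to pass explicit
#'   weights.
#' @param lambda_cyc,lambda_int,lambda_gdl explicit weights (>= 0).
#' @return A list of class `gan_loss_weights`.
#' @export
gan_loss_weights <- function(preset = NULL, lambda_cyc = 10,
                             lambda_int = 10, lambda_gdl = 5) {
  if (!is.null(preset)) {
    w <- switch(match.arg(tolower(preset), c("ct", "cbct", "mri")),
                ct = c(10, 10, 5), cbct = c(10, 10, 5),
                mri = c(10, 0.4, 0.4))
    lambda_cyc <- w[1]; lambda_int <- w[2]; lambda_gdl <- w[3]
  }
  stopifnot(lambda_cyc >= 0, lambda_int >= 0, lambda_gdl >= 0)
  structure(list(lambda_cyc = lambda_cyc, lambda_int = lambda_int,
                 lambda_gdl = lambda_gdl), class = "gan_loss_weights")
}

#' Intensity loss
#'
#' `L_int(G, F) = ||G(x) - x||_1 + ||F(y) - y||_1`: an L1 penalty keeping
#' each generator's output close to its input, preserving the organ
#' intensities assigned by the phantom (meaningful because the phantom is
#' initialized in the target modality's intensity range, making the
#' translation monomodal).
#'
#' @param x,Gx,y,Fy images (matrices/arrays); `Gx` must match `x`, `Fy`
#'   must match `y`.
#' @param convention `"mean"` (per-pixel mean, default) or `"sum"`.
#' @return Non-negative scalar.
#' @export
intensity_loss <- function(x, Gx, y, Fy, convention = c("mean", "sum")) {
  convention <- match.arg(convention)
  if (!identical(dim(x), dim(Gx)) || !identical(dim(y), dim(Fy)))
    stop("shape mismatch")
  sum(abs(Gx - x)) / loss_norm(length(x), convention) +
    sum(abs(Fy - y)) / loss_norm(length(y), convention)
}

#' Gradient difference loss
#'
#' Squared differences between the absolute forward-difference gradients of
#' `x` and `G(x)`, summed over both in-plane axes:
#' `sum_ij (|x_i,j - x_i-1,j| - |Gx_i,j - Gx_i-1,j|)^2 +
#'  (|x_i,j - x_i,j-1| - |Gx_i,j - Gx_i,j-1|)^2`.
#' Counteracts blurring by penalizing lost (or invented) edges.
#'
#' @param x,Gx images of identical shape, at least 2 px per axis.
#' @param convention `"mean"` or `"sum"` over the valid difference terms.
#' @return Non-negative scalar; 0 when the absolute gradients agree.
#' @export
gradient_difference_loss <- function(x, Gx, convention = c("mean", "sum")) {
  convention <- match.arg(convention)
  if (!identical(dim(x), dim(Gx))) stop("shape mismatch")
  x <- as.matrix(drop(x)); Gx <- as.matrix(drop(Gx))
  if (nrow(x) < 2 || ncol(x) < 2) stop("images must be >= 2 px per axis")
  dvx <- abs(x[-1, , drop = FALSE] - x[-nrow(x), , drop = FALSE])
  dvg <- abs(Gx[-1, , drop = FALSE] - Gx[-nrow(Gx), , drop = FALSE])
  dhx <- abs(x[, -1, drop = FALSE] - x[, -ncol(x), drop = FALSE])
  dhg <- abs(Gx[, -1, drop = FALSE] - Gx[, -ncol(Gx), drop = FALSE])
  n <- loss_norm(length(dvx) + length(dhx), convention)
  (sum((dvx - dvg)^2) + sum((dhx - dhg)^2)) / n
}

# loss + gradient wrt Gx, for training
gdl_grad <- function(x, Gx, convention = "mean") {
  x <- as.matrix(drop(x)); Gx <- as.matrix(drop(Gx))
  nr <- nrow(x); nc <- ncol(x)
  dvx <- abs(x[-1, , drop = FALSE] - x[-nr, , drop = FALSE])
  gv <- Gx[-1, , drop = FALSE] - Gx[-nr, , drop = FALSE]
  dhx <- abs(x[, -1, drop = FALSE] - x[, -nc, drop = FALSE])
  gh <- Gx[, -1, drop = FALSE] - Gx[, -nc, drop = FALSE]
  n <- loss_norm(length(dvx) + length(dhx), convention)
  loss <- (sum((dvx - abs(gv))^2) + sum((dhx - abs(gh))^2)) / n
  dv <- -2 * (dvx - abs(gv)) * sign(gv) / n
  dh <- -2 * (dhx - abs(gh)) * sign(gh) / n
  dG <- matrix(0, nr, nc)
  dG[-1, ] <- dG[-1, , drop = FALSE] + dv
  dG[-nr, ] <- dG[-nr, , drop = FALSE] - dv
  dG[, -1] <- dG[, -1, drop = FALSE] + dh
  dG[, -nc] <- dG[, -nc, drop = FALSE] - dh
  list(loss = loss, dGx = dG)
}

#' Cycle consistency loss
#'
#' L1 reconstruction penalty on both cycles, `||F(G(x)) - x||_1 +
#' ||G(F(y)) - y||_1`; zero iff both cycles reconstruct exactly.
#'
#' @param x,FGx,y,GFy images; `FGx` matches `x`, `GFy` matches `y`.
#' @param convention `"mean"` or `"sum"`.
#' @return Non-negative scalar.
#' @export
cycle_consistency_loss <- function(x, FGx, y, GFy,
                                   convention = c("mean", "sum")) {
  convention <- match.arg(convention)
  if (!identical(dim(x), dim(FGx)) || !identical(dim(y), dim(GFy)))
    stop("shape mismatch")
  sum(abs(FGx - x)) / loss_norm(length(x), convention) +
    sum(abs(GFy - y)) / loss_norm(length(y), convention)
}

#' Least-squares GAN losses
#'
#' Discriminator loss `mean((D(real) - 1)^2) + mean(D(fake)^2)` and the
#' generator adversarial term `mean((D(fake) - 1)^2)`, both over patch
#' score maps.
#'
#' @param D_real_scores,D_fake_scores real-valued score maps.
#' @return List with `discriminator` and `generator` loss values.
#' @export
lsgan_losses <- function(D_real_scores, D_fake_scores) {
  list(discriminator = mean((D_real_scores - 1)^2) +
         mean(D_fake_scores^2),
       generator = mean((D_fake_scores - 1)^2))
}

#' Total generator loss
#'
#' `L_gen = L_adv + lambda_cyc * L_cyc + lambda_int * L_int +
#'  lambda_gdl * (L_gdl(G, x) + L_gdl(F, y))`.
#'
#' @param adv adversarial generator term (both directions summed).
#' @param cyc,int_ cycle and intensity losses (>= 0).
#' @param gdl_x,gdl_y gradient difference losses of the two generators.
#' @param w a [gan_loss_weights()].
#' @return Scalar total loss.
#' @export
total_generator_loss <- function(adv, cyc, int_, gdl_x, gdl_y,
                                 w = gan_loss_weights()) {
  stopifnot(inherits(w, "gan_loss_weights"))
  adv + w$lambda_cyc * cyc + w$lambda_int * int_ +
    w$lambda_gdl * (gdl_x + gdl_y)
}

# ---- network builders ----------------------------------------------------

#' Build a ResNet generator
#'
#' Encoder (7x7 conv, two stride-2 3x3 convs), `n_blocks` residual blocks,
#' decoder (two nearest-neighbour upsample + 3x3 conv stages), and a final
#' 7x7 conv with tanh constraining the output to \[-1, 1\]. Reflection
#' padding throughout; instance normalization after every convolution
#' except the last.
#'
#' @param width base channel width (default 64; 16 for desk-scale work).
#' @param n_blocks number of residual blocks (default 9).
#' @param in_channels,out_channels image channels (default 1, grayscale).
#' @return A `generator` object (list of layers + config).
#' @export
build_generator <- function(width = 64, n_blocks = 9, in_channels = 1,
                            out_channels = 1) {
  stopifnot(width >= 1, n_blocks >= 1)
  w <- as.integer(width)
  res_block <- function(c) nn_res(list(
    nn_conv(c, c, 3, 1, 1, "reflect"), nn_inorm(c), nn_relu(),
    nn_conv(c, c, 3, 1, 1, "reflect"), nn_inorm(c)))
  layers <- c(
    list(nn_conv(in_channels, w, 7, 1, 3, "reflect"), nn_inorm(w),
         nn_relu(),
         nn_conv(w, 2 * w, 3, 2, 1, "zero"), nn_inorm(2 * w), nn_relu(),
         nn_conv(2 * w, 4 * w, 3, 2, 1, "zero"), nn_inorm(4 * w),
         nn_relu()),
    lapply(seq_len(n_blocks), function(i) res_block(4 * w)),
    list(nn_upsample(), nn_conv(4 * w, 2 * w, 3, 1, 1, "zero"),
         nn_inorm(2 * w), nn_relu(),
         nn_upsample(), nn_conv(2 * w, w, 3, 1, 1, "zero"),
         nn_inorm(w), nn_relu(),
         nn_conv(w, out_channels, 7, 1, 3, "reflect"), nn_tanh()))
  structure(list(type = "generator", layers = layers, width = w,
                 n_blocks = n_blocks), class = "gan_network")
}

#' Build a 70x70 PatchGAN discriminator
#'
#' Five 4x4 convolutions (strides 2, 2, 2, 1, 1) with leaky ReLU; the
#' effective receptive field of each output score is exactly 70x70 input
#' pixels (see [receptive_field()]). Fully convolutional: the score map
#' grows with the input.
#'
#' @param width base channel width (default 64).
#' @param in_channels image channels.
#' @return A `discriminator` object.
#' @export
build_discriminator <- function(width = 64, in_channels = 1) {
  stopifnot(width >= 1)
  w <- as.integer(width)
  layers <- list(
    nn_conv(in_channels, w, 4, 2, 1, "zero"), nn_lrelu(),
    nn_conv(w, 2 * w, 4, 2, 1, "zero"), nn_inorm(2 * w), nn_lrelu(),
    nn_conv(2 * w, 4 * w, 4, 2, 1, "zero"), nn_inorm(4 * w), nn_lrelu(),
    nn_conv(4 * w, 8 * w, 4, 1, 1, "zero"), nn_inorm(8 * w), nn_lrelu(),
    nn_conv(8 * w, 1, 4, 1, 1, "zero"))
  structure(list(type = "discriminator", layers = layers, width = w),
            class = "gan_network")
}

#' @export
print.gan_network <- function(x, ...) {
  cat(sprintf("%s: width %d, %d parameters, receptive field %g\n",
              x$type, x$width, param_count(x), receptive_field(x)))
  invisible(x)
}

# Apply a network (or plain function) to one 2D image.
apply_net <- function(net, img) {
  if (is.function(net)) return(net(img))
  x <- array(img, c(nrow(img), ncol(img), 1L))
  r <- net_forward(net$layers, x)
  list(out = r$out, cache = r$cache)
}

# ---- patch sampling ------------------------------------------------------

#' Sample one training patch per axial slice
#'
#' For each axial slice of the volume one square patch is extracted at a
#' position drawn uniformly over the valid offsets. Slices smaller than the
#' patch are reflect-padded first. Deterministic given `seed`.
#'
#' @param volume a normalized [modality_volume()] or 3D array in \[-1, 1\].
#' @param patch patch side length in pixels (training default 256).
#' @param seed integer seed.
#' @return List of `patch_sample` objects: `pixels` (matrix), `slice`,
#'   `offset`.
#' @export
sample_patches <- function(volume, patch = 256L, seed = 1L) {
  arr <- as_arr3(volume)
  d <- dim(arr)
  set.seed(as.integer(seed))
  patch <- as.integer(patch)
  lapply(seq_len(d[3]), function(k) {
    sl <- arr[, , k]
    if (nrow(sl) < patch) {
      pad <- patch - nrow(sl)
      sl <- sl[reflect_idx(nrow(sl), pad)[seq_len(nrow(sl) + pad)], ,
               drop = FALSE]
    }
    if (ncol(sl) < patch) {
      pad <- patch - ncol(sl)
      sl <- sl[, reflect_idx(ncol(sl), pad)[seq_len(ncol(sl) + pad)],
               drop = FALSE]
    }
    oi <- sample.int(nrow(sl) - patch + 1L, 1L)
    oj <- sample.int(ncol(sl) - patch + 1L, 1L)
    structure(list(pixels = sl[oi:(oi + patch - 1L), oj:(oj + patch - 1L)],
                   slice = k, offset = c(oi, oj)),
              class = "patch_sample")
  })
}

# ---- training ------------------------------------------------------------

l1_grad <- function(a, b, convention = "mean") {
  n <- loss_norm(length(a), convention)
  list(loss = sum(abs(a - b)) / n, da = sign(a - b) / n)
}

#' Train a CycleGAN at configurable scale
#'
#' Full objective: least-squares adversarial losses for both discriminators,
#' cycle consistency, intensity loss and gradient difference loss for both
#' generators, combined with the configured weights; Adam (beta1 = 0.5)
#' with constant learning rate. The defaults build desk-scale networks; the
#' full-scale recipe (width 64, 9 blocks, 256 px patches, 150000 steps)
#' is reachable through the same arguments.
#'
#' @param x_data,y_data lists of equally sized matrices in \[-1, 1\]
#'   (domain X = phantom-style, domain Y = target-style images).
#' @param w a [gan_loss_weights()].
#' @param steps number of optimizer steps (>= 1).
#' @param lr Adam learning rate (training recipe default 0.0002).
#' @param batch batch size (training recipe default 4).
#' @param seed integer seed; fixes initialization and data order.
#' @param width,n_blocks network scale (desk defaults 16 and 2).
#' @param convention loss normalization convention.
#' @return A `cyclegan` object: generators `G` (X to Y) and `F` (Y to X),
#'   discriminators `D_X`, `D_Y`, and a `log` data.frame with the five
#'   generator-loss components per step.
#' @export
train_cyclegan <- function(x_data, y_data, w = gan_loss_weights(),
                           steps = 200L, lr = 2e-4, batch = 4L, seed = 1L,
                           width = 16, n_blocks = 2,
                           convention = "mean") {
  stopifnot(length(x_data) > 0, length(y_data) > 0, steps >= 1)
  rng <- function(m) range(unlist(lapply(m, range)))
  if (any(abs(rng(x_data)) > 1 + 1e-9) || any(abs(rng(y_data)) > 1 + 1e-9))
    stop("domain images must be normalized to [-1, 1]")
  set.seed(as.integer(seed))
  G <- build_generator(width, n_blocks)
  F_ <- build_generator(width, n_blocks)
  D_X <- build_discriminator(width)
  D_Y <- build_discriminator(width)
  st <- list(G = adam_init(G$layers), F = adam_init(F_$layers),
             D_X = adam_init(D_X$layers), D_Y = adam_init(D_Y$layers))
  log <- vector("list", steps)

  as_img <- function(m) array(m, c(nrow(m), ncol(m), 1L))

  for (step in seq_len(steps)) {
    gG <- NULL; gF <- NULL; gDX <- NULL; gDY <- NULL
    comp <- c(adv = 0, cyc = 0, int = 0, gdl_x = 0, gdl_y = 0,
              d_x = 0, d_y = 0, id_mae = 0)
    for (bi in seq_len(batch)) {
      x <- as_img(x_data[[sample.int(length(x_data), 1L)]])
      y <- as_img(y_data[[sample.int(length(y_data), 1L)]])

      fG <- net_forward(G$layers, x);  Gx <- fG$out
      fF <- net_forward(F_$layers, y); Fy <- fF$out
      fFG <- net_forward(F_$layers, Gx); FGx <- fFG$out
      fGF <- net_forward(G$layers, Fy);  GFy <- fGF$out
      fDY <- net_forward(D_Y$layers, Gx); sY <- fDY$out
      fDX <- net_forward(D_X$layers, Fy); sX <- fDX$out

      # --- generator losses and output-space gradients
      adv <- mean((sY - 1)^2) + mean((sX - 1)^2)
      cy1 <- l1_grad(FGx, x, convention); cy2 <- l1_grad(GFy, y, convention)
      in1 <- l1_grad(Gx, x, convention);  in2 <- l1_grad(Fy, y, convention)
      gd1 <- gdl_grad(x[, , 1], Gx[, , 1], convention)
      gd2 <- gdl_grad(y[, , 1], Fy[, , 1], convention)

      comp <- comp + c(adv = adv, cyc = cy1$loss + cy2$loss,
                       int = in1$loss + in2$loss,
                       gdl_x = gd1$loss, gdl_y = gd2$loss,
                       d_x = 0, d_y = 0,
                       id_mae = mean(abs(Gx - x)))

      # d(adv)/d(Gx): through D_Y, discriminator params frozen
      bDY <- net_backward(D_Y$layers, fDY$cache, 2 * (sY - 1) / length(sY))
      bDX <- net_backward(D_X$layers, fDX$cache, 2 * (sX - 1) / length(sX))

      # cycle gradients flow through the second generator into the first
      bFG <- net_backward(F_$layers, fFG$cache, w$lambda_cyc * cy1$da)
      bGF <- net_backward(G$layers, fGF$cache, w$lambda_cyc * cy2$da)

      dGx <- bDY$dx + bFG$dx + w$lambda_int * in1$da +
        array(w$lambda_gdl * gd1$dGx, dim(Gx))
      dFy <- bDX$dx + bGF$dx + w$lambda_int * in2$da +
        array(w$lambda_gdl * gd2$dGx, dim(Fy))

      bG <- net_backward(G$layers, fG$cache, dGx)
      bF <- net_backward(F_$layers, fF$cache, dFy)

      gG <- grads_add(gG, grads_add(bG$grads, bGF$grads))
      gF <- grads_add(gF, grads_add(bF$grads, bFG$grads))

      # --- discriminator losses (fakes detached)
      fDYr <- net_forward(D_Y$layers, y); sYr <- fDYr$out
      fDYf <- net_forward(D_Y$layers, Gx); sYf <- fDYf$out
      comp[["d_y"]] <- comp[["d_y"]] + mean((sYr - 1)^2) + mean(sYf^2)
      bYr <- net_backward(D_Y$layers, fDYr$cache,
                          2 * (sYr - 1) / length(sYr))
      bYf <- net_backward(D_Y$layers, fDYf$cache, 2 * sYf / length(sYf))
      gDY <- grads_add(gDY, grads_add(bYr$grads, bYf$grads))

      fDXr <- net_forward(D_X$layers, x); sXr <- fDXr$out
      fDXf <- net_forward(D_X$layers, Fy); sXf <- fDXf$out
      comp[["d_x"]] <- comp[["d_x"]] + mean((sXr - 1)^2) + mean(sXf^2)
      bXr <- net_backward(D_X$layers, fDXr$cache,
                          2 * (sXr - 1) / length(sXr))
      bXf <- net_backward(D_X$layers, fDXf$cache, 2 * sXf / length(sXf))
      gDX <- grads_add(gDX, grads_add(bXr$grads, bXf$grads))
    }

    sc <- 1 / batch
    r <- adam_update(G$layers, grads_scale(gG, sc), st$G, lr, step)
    G$layers <- r$net; st$G <- r$state
    r <- adam_update(F_$layers, grads_scale(gF, sc), st$F, lr, step)
    F_$layers <- r$net; st$F <- r$state
    r <- adam_update(D_Y$layers, grads_scale(gDY, sc), st$D_Y, lr, step)
    D_Y$layers <- r$net; st$D_Y <- r$state
    r <- adam_update(D_X$layers, grads_scale(gDX, sc), st$D_X, lr, step)
    D_X$layers <- r$net; st$D_X <- r$state

    comp <- comp / batch
    log[[step]] <- data.frame(
      step = step, adv = comp[["adv"]], cyc = comp[["cyc"]],
      int = comp[["int"]], gdl_x = comp[["gdl_x"]], gdl_y = comp[["gdl_y"]],
      total = total_generator_loss(comp[["adv"]], comp[["cyc"]],
                                   comp[["int"]], comp[["gdl_x"]],
                                   comp[["gdl_y"]], w),
      d_x = comp[["d_x"]], d_y = comp[["d_y"]],
      identity_mae = comp[["id_mae"]])
  }
  structure(list(G = G, F = F_, D_X = D_X, D_Y = D_Y, weights = w,
                 log = do.call(rbind, log)),
            class = "cyclegan")
}

#' @export
print.cyclegan <- function(x, ...) {
  n <- nrow(x$log)
  cat(sprintf("cyclegan: %d steps trained, final total loss %.4f\n",
              n, x$log$total[n]))
  invisible(x)
}

#' Save / load a trained CycleGAN
#'
#' Checkpoints use R's native serialization; loss curves can be exported
#' with [write_loss_log()].
#'
#' @param model a `cyclegan` object.
#' @param path checkpoint path (`.rds`).
#' @return `path` / the restored model.
#' @export
save_cyclegan <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_cyclegan
#' @export
load_cyclegan <- function(path) readRDS(path)

#' @rdname save_cyclegan
#' @export
write_loss_log <- function(model, path) {
  utils::write.csv(model$log, path, row.names = FALSE)
  invisible(path)
}

#' Synthesize a volume slice-wise with a generator
#'
#' Applies the generator to every full axial slice of a normalized volume
#' (the generator is fully convolutional, so slices need not match the
#' training patch size).
#'
#' @param phantom_vol a normalized [modality_volume()].
#' @param G a generator from [train_cyclegan()] / [build_generator()], or a
#'   plain function mapping a matrix to a matrix (useful for testing).
#' @return A [modality_volume()] of the same shape, normalized.
#' @export
synthesize_volume <- function(phantom_vol, G) {
  stopifnot(inherits(phantom_vol, "modality_volume"))
  if (!phantom_vol$normalized)
    stop("input volume must be normalized to [-1, 1]")
  arr <- phantom_vol$intensities
  out <- array(0, dim(arr))
  for (k in seq_len(dim(arr)[3])) {
    r <- apply_net(G, arr[, , k])
    sl <- if (is.list(r)) r$out else r
    out[, , k] <- drop(sl)
  }
  phantom_vol$intensities <- pmin(pmax(out, -1), 1)
  phantom_vol
}
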