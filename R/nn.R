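# Minimal convolutional-network framework used by the CycleGAN stage.
# Tensors are (H, W, C) arrays for a single sample; convolutions run via
# im2col + BLAS matrix products; every layer implements a hand-derived
# backward pass. Deliberately small: exactly the layers the generator and
# PatchGAN discriminator need (conv, instance norm, ReLU/LeakyReLU/tanh,
# nearest-neighbour upsampling, residual blocks), plus Adam.

nn_init_weight <- function(dims, sd = 0.02) {
  array(stats::rnorm(prod(dims), 0, sd), dim = dims)
}

nn_conv <- function(cin, cout, k, stride = 1L, pad = 0L,
                    pad_type = c("zero", "reflect")) {
  list(type = "conv", W = nn_init_weight(c(k, k, cin, cout)),
       b = numeric(cout), k = as.integer(k), stride = as.integer(stride),
       pad = as.integer(pad), pad_type = match.arg(pad_type))
}
nn_inorm <- function(c, eps = 1e-5)
  list(type = "inorm", gamma = rep(1, c), beta = numeric(c), eps = eps)
nn_relu <- function() list(type = "relu")
nn_lrelu <- function(alpha = 0.2) list(type = "lrelu", alpha = alpha)
nn_tanh <- function() list(type = "tanh")
nn_upsample <- function() list(type = "upsample")
nn_res <- function(layers) list(type = "res", layers = layers)

reflect_idx <- function(n, pad) {
  idx <- (1 - pad):(n + pad)
  idx <- ifelse(idx < 1, 2 - idx, idx)
  ifelse(idx > n, 2 * n - idx, idx)
}

pad_input <- function(x, pad, pad_type) {
  if (pad == 0) return(x)
  d <- dim(x)
  if (pad_type == "reflect") {
    x[reflect_idx(d[1], pad), reflect_idx(d[2], pad), , drop = FALSE]
  } else {
    out <- array(0, c(d[1] + 2 * pad, d[2] + 2 * pad, d[3]))
    out[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
    out
  }
}

unpad_grad <- function(dxp, orig_dim, pad, pad_type) {
  if (pad == 0) return(dxp)
  if (pad_type == "zero") {
    return(dxp[pad + seq_len(orig_dim[1]), pad + seq_len(orig_dim[2]), ,
               drop = FALSE])
  }
  # reflect: fold padded-border gradients back onto their source voxels
  ih <- reflect_idx(orig_dim[1], pad)
  iw <- reflect_idx(orig_dim[2], pad)
  dp <- dim(dxp)
  m <- matrix(dxp, nrow = dp[1])
  m <- rowsum(m, group = ih)                       # (H, Wp*C)
  a <- array(m, c(orig_dim[1], dp[2], dp[3]))
  a <- aperm(a, c(2, 1, 3))
  m <- rowsum(matrix(a, nrow = dp[2]), group = iw) # (W, H*C)
  aperm(array(m, c(orig_dim[2], orig_dim[1], dp[3])), c(2, 1, 3))
}

conv_forward <- function(layer, x) {
  k <- layer$k; stride <- layer$stride
  xp <- pad_input(x, layer$pad, layer$pad_type)
  dp <- dim(xp); C <- dp[3]
  Ho <- (dp[1] - k) %/% stride + 1L
  Wo <- (dp[2] - k) %/% stride + 1L
  if (Ho < 1L || Wo < 1L)
    stop("input too small for this convolution (", dp[1], "x", dp[2],
         " after padding, kernel ", k, ")")
  r0 <- seq(1L, by = stride, length.out = Ho)
  c0 <- seq(1L, by = stride, length.out = Wo)
  A <- array(0, c(Ho, Wo, k * k, C))
  for (dx in seq_len(k)) for (dy in seq_len(k)) {
    A[, , dy + (dx - 1L) * k, ] <- xp[r0 + dy - 1L, c0 + dx - 1L, ]
  }
  mat <- matrix(A, Ho * Wo, k * k * C)
  out_mat <- mat %*% matrix(layer$W, k * k * C, dim(layer$W)[4])
  out_mat <- sweep(out_mat, 2L, layer$b, "+")
  list(out = array(out_mat, c(Ho, Wo, dim(layer$W)[4])),
       cache = list(mat = mat, xdim = dim(x), pdim = dp, r0 = r0, c0 = c0))
}

conv_backward <- function(layer, cache, dout) {
  k <- layer$k
  cout <- dim(layer$W)[4]
  dd <- dim(dout)
  dout_mat <- matrix(dout, dd[1] * dd[2], cout)
  dW <- array(crossprod(cache$mat, dout_mat), dim(layer$W))
  db <- colSums(dout_mat)
  dmat <- tcrossprod(dout_mat, matrix(layer$W, k * k * dim(layer$W)[3],
                                      cout))
  dA <- array(dmat, c(dd[1], dd[2], k * k, dim(layer$W)[3]))
  dxp <- array(0, cache$pdim)
  r0 <- cache$r0; c0 <- cache$c0
  for (dx in seq_len(k)) for (dy in seq_len(k)) {
    ri <- r0 + dy - 1L; ci <- c0 + dx - 1L
    dxp[ri, ci, ] <- dxp[ri, ci, ] + dA[, , dy + (dx - 1L) * k, ]
  }
  list(dx = unpad_grad(dxp, cache$xdim, layer$pad, layer$pad_type),
       grads = list(W = dW, b = db))
}

inorm_forward <- function(layer, x) {
  d <- dim(x); n <- d[1] * d[2]
  m <- matrix(x, n, d[3])
  mu <- colMeans(m)
  xc <- sweep(m, 2L, mu)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + layer$eps)
  xhat <- sweep(xc, 2L, istd, "*")
  out <- sweep(sweep(xhat, 2L, layer$gamma, "*"), 2L, layer$beta, "+")
  list(out = array(out, d),
       cache = list(xhat = xhat, istd = istd, d = d, n = n))
}

inorm_backward <- function(layer, cache, dout) {
  d <- cache$d; n <- cache$n
  dy <- matrix(dout, n, d[3])
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, layer$gamma, "*")
  # dx = istd/n * (n*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dx <- sweep(dxhat * n, 2L, s1) - sweep(cache$xhat, 2L, s2, "*")
  dx <- sweep(dx, 2L, cache$istd / n, "*")
  list(dx = array(dx, d), grads = list(gamma = dgamma, beta = dbeta))
}

upsample_forward <- function(x) {
  d <- dim(x)
  list(out = x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), ,
               drop = FALSE],
       cache = d)
}

upsample_backward <- function(cache, dout) {
  d <- cache
  odd_r <- seq(1L, 2L * d[1], by = 2L); odd_c <- seq(1L, 2L * d[2], by = 2L)
  dout[odd_r, odd_c, , drop = FALSE] +
    dout[odd_r + 1L, odd_c, , drop = FALSE] +
    dout[odd_r, odd_c + 1L, , drop = FALSE] +
    dout[odd_r + 1L, odd_c + 1L, , drop = FALSE]
}

layer_forward <- function(layer, x) {
  switch(layer$type,
         conv = conv_forward(layer, x),
         inorm = inorm_forward(layer, x),
         relu = list(out = pmax(x, 0), cache = x > 0),
         lrelu = list(out = ifelse(x > 0, x, layer$alpha * x),
                      cache = x > 0),
         tanh = { o <- tanh(x); list(out = o, cache = o) },
         upsample = upsample_forward(x),
         res = {
           sub <- net_forward(layer$layers, x)
           list(out = x + sub$out, cache = sub$cache)
         },
         stop("unknown layer type: ", layer$type))
}

layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
         conv = conv_backward(layer, cache, dout),
         inorm = inorm_backward(layer, cache, dout),
         relu = list(dx = dout * cache, grads = NULL),
         lrelu = list(dx = dout * ifelse(cache, 1, layer$alpha),
                      grads = NULL),
         tanh = list(dx = dout * (1 - cache^2), grads = NULL),
         upsample = list(dx = upsample_backward(cache, dout), grads = NULL),
         res = {
           sub <- net_backward(layer$layers, cache, dout)
           list(dx = dout + sub$dx, grads = sub$grads)
         })
}

# Forward through a list of layers; returns output and per-layer caches.
net_forward <- function(net, x) {
  caches <- vector("list", length(net))
  for (i in seq_along(net)) {
    r <- layer_forward(net[[i]], x)
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, cache = caches)
}

# Backward; returns gradient wrt input and per-layer parameter grads.
net_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net))
  for (i in rev(seq_along(net))) {
    r <- layer_backward(net[[i]], caches[[i]], dout)
    dout <- r$dx
    grads[i] <- list(r$grads)   # keep NULLs as placeholders
  }
  list(dx = dout, grads = grads)
}

# Elementwise sum of two parallel gradient structures (NULL-safe).
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  mapply(function(ga, gb) {
    if (is.null(ga)) return(gb)
    if (is.null(gb)) return(ga)
    if (is.list(ga) && !is.null(ga$W)) # conv
      list(W = ga$W + gb$W, b = ga$b + gb$b)
    else if (is.list(ga) && !is.null(ga$gamma))
      list(gamma = ga$gamma + gb$gamma, beta = ga$beta + gb$beta)
    else grads_add(ga, gb)            # nested (res)
  }, a, b, SIMPLIFY = FALSE)
}

grads_scale <- function(g, s) {
  lapply(g, function(gi) {
    if (is.null(gi)) return(NULL)
    if (!is.null(gi$W)) list(W = gi$W * s, b = gi$b * s)
    else if (!is.null(gi$gamma))
      list(gamma = gi$gamma * s, beta = gi$beta * s)
    else grads_scale(gi, s)
  })
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(net) {
  lapply(net, function(l) {
    switch(l$type,
           conv = list(mW = array(0, dim(l$W)), vW = array(0, dim(l$W)),
                       mb = numeric(length(l$b)), vb = numeric(length(l$b))),
           inorm = list(mg = numeric(length(l$gamma)),
                        vg = numeric(length(l$gamma)),
                        mb = numeric(length(l$beta)),
                        vb = numeric(length(l$beta))),
           res = adam_init(l$layers),
           NULL)
  })
}

adam_step_arr <- function(p, g, m, v, lr, b1, b2, eps, t) {
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  mh <- m / (1 - b1^t); vh <- v / (1 - b2^t)
  list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
}

adam_update <- function(net, grads, state, lr, t, b1 = 0.5, b2 = 0.999,
                        eps = 1e-8) {
  for (i in seq_along(net)) {
    l <- net[[i]]; g <- grads[[i]]; s <- state[[i]]
    if (is.null(g)) next
    if (l$type == "conv") {
      r <- adam_step_arr(l$W, g$W, s$mW, s$vW, lr, b1, b2, eps, t)
      l$W <- r$p; s$mW <- r$m; s$vW <- r$v
      r <- adam_step_arr(l$b, g$b, s$mb, s$vb, lr, b1, b2, eps, t)
      l$b <- r$p; s$mb <- r$m; s$vb <- r$v
    } else if (l$type == "inorm") {
      r <- adam_step_arr(l$gamma, g$gamma, s$mg, s$vg, lr, b1, b2, eps, t)
      l$gamma <- r$p; s$mg <- r$m; s$vg <- r$v
      r <- adam_step_arr(l$beta, g$beta, s$mb, s$vb, lr, b1, b2, eps, t)
      l$beta <- r$p; s$mb <- r$m; s$vb <- r$v
    } else if (l$type == "res") {
      r <- adam_update(l$layers, g, s, lr, t, b1, b2, eps)
      l$layers <- r$net; s <- r$state
    }
    net[[i]] <- l; state[[i]] <- s
  }
  list(net = net, state = state)
}

# ---- introspection -------------------------------------------------------

#' Number of trainable parameters of a network
#'
#' @param net a generator or discriminator built by [build_generator()] /
#'   [build_discriminator()], or a bare layer list.
#' @return Integer parameter count.
#' @export
param_count <- function(net) {
  layers <- if (is.list(net) && !is.null(net$layers)) net$layers else net
  sum(vapply(layers, function(l) {
    switch(l$type,
           conv = length(l$W) + length(l$b),
           inorm = length(l$gamma) + length(l$beta),
           res = param_count(l$layers),
           0L)
  }, numeric(1)))
}

# Flat sequence of (k, stride) conv specs, expanding residual blocks.
conv_specs <- function(layers) {
  out <- list()
  for (l in layers) {
    if (l$type == "conv")
      out[[length(out) + 1L]] <- c(k = l$k, stride = l$stride)
    else if (l$type == "res") out <- c(out, conv_specs(l$layers))
    else if (l$type == "upsample")
      out[[length(out) + 1L]] <- c(k = 1L, stride = 0.5)
  }
  out
}

#' Receptive field of a convolutional network
#'
#' Standard recursion `rf <- rf + (k - 1) * jump; jump <- jump * stride`
#' over the layer stack; for the 70x70 PatchGAN discriminator this returns
#' 70.
#'
#' @param net a network object or layer list.
#' @return Receptive field in input pixels per output score.
#' @export
receptive_field <- function(net) {
  layers <- if (!is.null(net$type) && net$type %in%
                c("generator", "discriminator")) net$layers else net
  rf <- 1; jump <- 1
  for (s in conv_specs(layers)) {
    rf <- rf + (s[["k"]] - 1) * jump
    jump <- jump * s[["stride"]]
  }
  rf
}
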