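# Deformable registration benchmark: B-spline free-form deformation
# optimized by step-adaptive gradient descent under one of three similarity
# metrics (Mattes mutual information, normalized correlation, mean
# squares), plus the harness that sweeps metric x control-point spacing and
# scores each setting by liver-mask Dice overlap against the phantom's
# ground truth.

#' Registration configuration
#'
#' @param metric `"MMI"` (Mattes mutual information), `"NC"` (normalized
#'   correlation) or `"MS"` (mean squares; monomodal pairs only).
#' @param grid_spacing_mm B-spline control-point spacing (the benchmark
#'   sweep uses 50 to 150 mm in steps of 20 mm).
#' @param learning_rate initial gradient-descent step length, mm.
#' @param max_iterations iteration cap.
#' @param mmi_bins histogram bins for MMI.
#' @param shrink integer shrink factor: the optimization runs on a
#'   volume downsampled by this factor (the transform applies at any
#'   resolution).
#' @param sampling fraction of voxels used by the metric (1 = all, the
#'   deterministic default); fractions < 1 draw a fixed subset from `seed`.
#' @param seed seed for stochastic sampling.
#' @return A list of class `registration_config`.
#' @export
registration_config <- function(metric = c("MMI", "NC", "MS"),
                                grid_spacing_mm = 50, learning_rate = 1,
                                max_iterations = 300, mmi_bins = 50,
                                shrink = 2, sampling = 1, seed = 1L) {
  metric <- match.arg(metric)
  stopifnot(grid_spacing_mm > 0, learning_rate > 0, max_iterations >= 1,
            mmi_bins >= 8, shrink >= 1, sampling > 0, sampling <= 1)
  structure(list(metric = metric, grid_spacing_mm = grid_spacing_mm,
                 learning_rate = learning_rate,
                 max_iterations = as.integer(max_iterations),
                 mmi_bins = as.integer(mmi_bins),
                 shrink = as.integer(shrink), sampling = sampling,
                 seed = as.integer(seed)),
            class = "registration_config")
}

# Cubic Parzen window and derivative (support (-2, 2)).
parzen3 <- function(u) {
  au <- abs(u)
  ifelse(au < 1, (4 - 6 * au^2 + 3 * au^3) / 6,
         ifelse(au < 2, (2 - au)^3 / 6, 0))
}
parzen3_deriv <- function(u) {
  au <- abs(u)
  s <- sign(u)
  ifelse(au < 1, s * (-12 * au + 9 * au^2) / 6,
         ifelse(au < 2, s * (-3 * (2 - au)^2) / 6, 0))
}

accum_vec <- function(idx, w, n) {
  r <- rowsum(w, idx)
  out <- numeric(n)
  out[as.integer(rownames(r))] <- r
  out
}

# Metric value (to minimize) and derivative wrt the warped moving
# intensities. f, m: vectors over the sampled voxels.
metric_value_grad <- function(metric, f, m, prep) {
  n <- length(f)
  if (metric == "MS") {
    d <- m - f
    return(list(value = mean(d^2), dm = 2 * d / n))
  }
  if (metric == "NC") {
    fc <- f - mean(f); mc <- m - mean(m)
    a <- sum(fc * mc); b <- sum(mc^2); c0 <- sum(fc^2)
    if (b == 0 || c0 == 0) return(list(value = 0, dm = numeric(n)))
    ncc <- a / sqrt(b * c0)
    dm <- fc / sqrt(b * c0) - a * mc / (b^1.5 * sqrt(c0))
    return(list(value = -ncc, dm = -dm))
  }
  # Mattes MI with zeroth-order fixed and cubic Parzen moving windows
  nb <- prep$nb
  bf <- prep$bf                       # precomputed fixed bins, 1..nb
  um <- (m - prep$mmin) / prep$mbw
  um <- pmin(pmax(um, 1), nb - 2 - 1e-9)
  j0 <- floor(um)                     # support bins j0-1 .. j0+2 (0-based)
  Pj <- numeric(nb * nb)
  for (k in (-1):2) {
    j <- j0 + k
    w <- parzen3(um - j)
    Pj <- Pj + accum_vec(bf + nb * j, w, nb * nb)
  }
  P <- matrix(Pj / n, nb, nb)         # rows: fixed bins, cols: moving bins
  Pf <- rowSums(P); Pm <- colSums(P)
  pos <- P > 0
  denom <- outer(Pf, Pm)
  mi <- sum(P[pos] * log(P[pos] / denom[pos]))
  # dMI/dm_i = 1/(n*bw) * sum_k parzen'(um - j) * log(P(bf, j) / Pm(j))
  Lterm <- matrix(0, nb, nb)
  okm <- Pm > 0
  Lterm[, okm] <- log(pmax(P[, okm, drop = FALSE], 1e-300) /
                        matrix(Pm[okm], nb, sum(okm), byrow = TRUE))
  Lterm[!pos] <- 0
  dm <- numeric(n)
  for (k in (-1):2) {
    j <- j0 + k
    dm <- dm + parzen3_deriv(um - j) * Lterm[bf + nb * j]
  }
  list(value = -mi, dm = -dm / (n * prep$mbw))
}

#' Deformable B-spline registration
#'
#' Optimizes a cubic B-spline free-form deformation mapping fixed-grid
#' points into the moving image, by step-adaptive gradient descent on the
#' chosen similarity metric: the step length starts at `learning_rate` mm,
#' grows by 10% after an improving step and halves after a worsening one
#' (the worsening step is rolled back), stopping at `max_iterations` or
#' when the step falls below 1/20 of its initial value. The optimization
#' runs on a `shrink`-downsampled copy; the returned transform evaluates at
#' any resolution. Fully deterministic (full voxel sampling by default).
#'
#' @param fixed,moving [modality_volume()]s sharing physical conventions.
#' @param cfg a [registration_config()].
#' @return A `bspline_transform`: control-point displacement coefficients
#'   (mm) with their grid, the metric trace, and iteration count.
#' @export
register_bspline <- function(fixed, moving, cfg = registration_config()) {
  stopifnot(inherits(fixed, "modality_volume"),
            inherits(moving, "modality_volume"),
            inherits(cfg, "registration_config"))
  if (cfg$metric == "MS" && !identical(fixed$modality, moving$modality))
    stop("MS metric is only suited for monomodal pairs (",
         fixed$modality, " vs ", moving$modality, ")")

  fx <- fixed; mv <- moving
  if (cfg$shrink > 1) {
    fx <- resample_volume(fx, fixed$spacing * cfg$shrink)
    mv <- resample_volume(mv, moving$spacing * cfg$shrink)
  }
  f_arr <- fx$intensities
  m_arr <- mv$intensities
  d <- dim(f_arr); sp <- fx$spacing
  grid <- bspline_grid(d, sp, fx$origin, cfg$grid_spacing_mm)

  # moving-image gradient (per mm), central differences
  m_grad <- lapply(1:3, function(a) {
    dm <- dim(m_arr)
    idx_p <- pmin(seq_len(dm[a]) + 1L, dm[a])
    idx_m <- pmax(seq_len(dm[a]) - 1L, 1L)
    sel <- function(i) switch(a, m_arr[i, , , drop = FALSE],
                              m_arr[, i, , drop = FALSE],
                              m_arr[, , i, drop = FALSE])
    array((sel(idx_p) - sel(idx_m)) / (2 * mv$spacing[a]), dm)
  })

  pts0 <- coord_grid(d)
  nvox <- nrow(pts0)
  sel <- if (cfg$sampling < 1) {
    set.seed(cfg$seed)
    sort(sample.int(nvox, max(1000L, round(cfg$sampling * nvox))))
  } else seq_len(nvox)
  f_vec <- as.vector(f_arr)[sel]

  prep <- NULL
  if (cfg$metric == "MMI") {
    nb <- cfg$mmi_bins
    frng <- range(f_vec); mrng <- range(m_arr)
    fbw <- diff(frng) / (nb - 1)
    if (fbw == 0) stop("fixed image is constant")
    prep <- list(nb = nb,
                 bf = pmin(pmax(floor((f_vec - frng[1]) / fbw), 0),
                           nb - 1) + 1L,
                 mmin = mrng[1],
                 mbw = max(diff(mrng) / (nb - 3), 1e-12))
  }

  coef <- array(0, c(grid$ncp, 3L))
  step <- cfg$learning_rate
  trace <- numeric(0)
  best <- Inf
  eval_metric <- function(coef, with_grad = TRUE) {
    dvec <- vapply(1:3, function(c3)
      as.vector(bspline_eval_component(grid, coef[, , , c3])),
      numeric(nvox))
    pts <- pts0 + sweep(dvec, 2L, sp, "/")
    pts_s <- pts[sel, , drop = FALSE]
    m_w <- sample_volume(m_arr, pts_s, "linear")
    mg <- metric_value_grad(cfg$metric, f_vec, m_w, prep)
    if (!with_grad) return(list(value = mg$value))
    g <- array(0, c(grid$ncp, 3L))
    force_full <- numeric(nvox)
    for (c3 in 1:3) {
      gm <- sample_volume(m_grad[[c3]], pts_s, "linear")
      force_full[] <- 0
      force_full[sel] <- mg$dm * gm
      g[, , , c3] <- bspline_project_component(grid, array(force_full, d))
    }
    list(value = mg$value, grad = g)
  }

  it <- 0L
  cur <- eval_metric(coef)
  best <- cur$value
  min_step <- cfg$learning_rate / 20
  while (it < cfg$max_iterations && step >= min_step) {
    it <- it + 1L
    gmax <- max(abs(cur$grad))
    if (gmax == 0) break
    cand <- coef - step * cur$grad / gmax
    nxt <- eval_metric(cand)
    if (nxt$value < best) {
      coef <- cand
      best <- nxt$value
      cur <- nxt
      step <- min(step * 1.1, 4 * cfg$learning_rate)
    } else {
      step <- step / 2
    }
    trace <- c(trace, best)
  }

  structure(list(coef = coef, grid = grid, cfg = cfg,
                 fixed_meta = list(dim = dim(fixed$intensities),
                                   spacing = fixed$spacing,
                                   origin = fixed$origin),
                 metric_trace = trace, iterations = it,
                 final_metric = best),
            class = "bspline_transform")
}

#' @export
print.bspline_transform <- function(x, ...) {
  cat(sprintf(
    "bspline_transform: %s metric, %g mm grid, %d iterations, metric %.5f\n",
    x$cfg$metric, x$cfg$grid_spacing_mm, x$iterations, x$final_metric))
  invisible(x)
}

#' Serialize a transform as JSON
#'
#' Control-point coefficients and grid geometry in a plain-text, lossless
#' form.
#'
#' @param transform a `bspline_transform`.
#' @param path output path.
#' @return `path` (write) or the restored transform (read).
#' @export
write_transform <- function(transform, path) {
  obj <- list(coef = as.vector(transform$coef),
              ncp = transform$grid$ncp,
              delta = transform$grid$delta,
              cp_origin = transform$grid$cp_origin,
              fixed_meta = transform$fixed_meta,
              metric = transform$cfg$metric,
              grid_spacing_mm = transform$cfg$grid_spacing_mm)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- list(ncp = obj$ncp, delta = obj$delta, cp_origin = obj$cp_origin,
               B = NULL)
  structure(list(coef = array(obj$coef, c(obj$ncp, 3L)), grid = grid,
                 cfg = registration_config(metric = obj$metric,
                                           grid_spacing_mm =
                                             obj$grid_spacing_mm),
                 fixed_meta = obj$fixed_meta,
                 metric_trace = numeric(0), iterations = NA_integer_,
                 final_metric = NA_real_),
            class = "bspline_transform")
}

#' Propagate a binary mask through a transform
#'
#' Nearest-neighbour resampling of the mask through the registration
#' transform, onto the fixed grid the transform was estimated on.
#'
#' @param mask logical 3D array on the moving grid (same grid as fixed).
#' @param transform a `bspline_transform`.
#' @return Logical 3D array.
#' @export
propagate_mask <- function(mask, transform) {
  meta <- transform$fixed_meta
  if (!identical(dim(mask), as.integer(meta$dim)))
    stop("mask grid does not match the transform's fixed grid")
  vec <- bspline_displacement(transform, dim(mask), meta$spacing,
                              meta$origin)
  pts <- coord_grid(dim(mask)) +
    sweep(matrix(vec, ncol = 3L), 2L, meta$spacing, "/")
  out <- sample_volume(mask + 0, pts, "nearest")
  array(out > 0.5, dim(mask))
}

#' Dice similarity coefficient
#'
#' `DSC = 2 |A & B| / (|A| + |B|)` for two binary masks on the same grid.
#'
#' @param a,b logical arrays of identical shape.
#' @return Scalar in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks must share a grid")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) stop("Dice undefined: both masks are empty")
  2 * sum(a & b) / (na + nb)
}

# ---- morphology ----------------------------------------------------------

ball_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  g[g$x^2 + g$y^2 + g$z^2 <= radius^2, , drop = FALSE]
}

shift3 <- function(m, o, fill = FALSE) {
  d <- dim(m)
  out <- array(fill, d)
  src <- lapply(1:3, function(a) {
    i <- seq_len(d[a]) - o[a]
    list(ok = i >= 1 & i <= d[a], idx = pmin(pmax(i, 1), d[a]))
  })
  out[src[[1]]$ok, src[[2]]$ok, src[[3]]$ok] <-
    m[src[[1]]$idx[src[[1]]$ok], src[[2]]$idx[src[[2]]$ok],
      src[[3]]$idx[src[[3]]$ok]]
  out
}

dilate3 <- function(m, offsets) {
  out <- array(FALSE, dim(m))
  for (i in seq_len(nrow(offsets)))
    out <- out | shift3(m, as.numeric(offsets[i, ]), FALSE)
  out
}

erode3 <- function(m, offsets) {
  out <- array(TRUE, dim(m))
  for (i in seq_len(nrow(offsets)))
    out <- out & shift3(m, as.numeric(offsets[i, ]), FALSE)
  out
}

#' Close the liver mask over its interior vessels
#'
#' Morphological closing (dilation then erosion with a ball structuring
#' element) of the union of the liver and intrahepatic vessel masks, so
#' that veins and arteries inside the liver count as liver when scoring
#' registration overlap. The result always contains the input liver mask.
#'
#' @param liver_mask,vessel_mask logical arrays on the same grid
#'   (`vessel_mask` may be `NULL`).
#' @param structuring_radius ball radius in voxels (default 3).
#' @return Logical array.
#' @export
close_liver_mask <- function(liver_mask, vessel_mask = NULL,
                             structuring_radius = 3) {
  m <- if (is.null(vessel_mask)) liver_mask else liver_mask | vessel_mask
  offs <- ball_offsets(structuring_radius)
  closed <- erode3(dilate3(m, offs), offs)
  closed | m
}

# ---- sweep ----------------------------------------------------------------

#' Enumerate the benchmark parameter settings
#'
#' Monomodal pairs (e.g. `"ct-ct"`) sweep all three metrics (MMI, NC, MS)
#' over the control-point spacings; multimodal pairs (e.g. `"cbct-ct"`,
#' `"mri-ct"`) sweep MMI and NC only. With the default six spacings this
#' yields 18 monomodal and 12 multimodal settings per pair.
#'
#' @param pairs character vector like `c("ct-ct", "cbct-ct", "mri-ct")`;
#'   `"<moving>-<fixed>"`.
#' @param spacings control-point spacings in mm.
#' @return `data.frame` with columns `pair`, `metric`, `spacing_mm`,
#'   `monomodal`.
#' @export
enumerate_sweep_settings <- function(pairs = c("ct-ct", "cbct-ct", "mri-ct"),
                                     spacings = seq(50, 150, by = 20)) {
  rows <- lapply(pairs, function(p) {
    mods <- strsplit(p, "-", fixed = TRUE)[[1]]
    if (length(mods) != 2) stop("pair must be '<moving>-<fixed>': ", p)
    mono <- identical(mods[1], mods[2])
    metrics <- if (mono) c("MMI", "NC", "MS") else c("MMI", "NC")
    expand.grid(pair = p, metric = metrics, spacing_mm = spacings,
                monomodal = mono, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the registration benchmark sweep
#'
#' For each phantom instance and each enumerated `(pair, metric, spacing)`
#' setting, registers the inhaled moving volume to the exhaled fixed CT,
#' propagates the inhaled (closed) liver mask through the transform, and
#' scores Dice overlap with the exhaled (closed) liver mask. The
#' pre-registration Dice between the unregistered masks is recorded once
#' per pair.
#'
#' @param dataset list of phantom instances; each a list with `fixed_ct`
#'   (exhaled [modality_volume()]), `moving` (named list of inhaled
#'   volumes, lowercase modality names), `liver_fixed` / `liver_moving`
#'   and optional `vessel_fixed` / `vessel_moving` logical masks, and
#'   optionally `id`.
#' @param pairs registration pairs, `"<moving>-<fixed>"` (fixed is CT).
#' @param spacings control-point spacings, mm.
#' @param cfg_base a [registration_config()] providing everything but
#'   metric and spacing.
#' @param dry_run if `TRUE`, only enumerate the settings (no optimization).
#' @param closing_radius structuring radius for [close_liver_mask()].
#' @return `data.frame` with columns `phantom_id`, `pair`, `metric`,
#'   `spacing_mm`, `dice_pre`, `dice_post`, `iterations` (the enumeration
#'   columns only under `dry_run`).
#' @export
run_sweep <- function(dataset, pairs = c("ct-ct", "cbct-ct", "mri-ct"),
                      spacings = seq(50, 150, by = 20),
                      cfg_base = registration_config(),
                      dry_run = FALSE, closing_radius = 3) {
  settings <- enumerate_sweep_settings(pairs, spacings)
  if (dry_run) return(settings)
  rows <- list()
  for (pi in seq_along(dataset)) {
    inst <- dataset[[pi]]
    id <- if (!is.null(inst$id)) inst$id else pi
    fixed_closed <- close_liver_mask(inst$liver_fixed, inst$vessel_fixed,
                                     closing_radius)
    moving_closed <- close_liver_mask(inst$liver_moving, inst$vessel_moving,
                                      closing_radius)
    for (p in pairs) {
      mov_name <- strsplit(p, "-", fixed = TRUE)[[1]][1]
      moving <- inst$moving[[mov_name]]
      if (is.null(moving))
        stop("dataset instance ", id, " is missing moving modality '",
             mov_name, "'")
      d_pre <- dice(moving_closed, fixed_closed)
      sub <- settings[settings$pair == p, , drop = FALSE]
      for (si in seq_len(nrow(sub))) {
        cfg <- cfg_base
        cfg$metric <- sub$metric[si]
        cfg$grid_spacing_mm <- sub$spacing_mm[si]
        tr <- register_bspline(inst$fixed_ct, moving, cfg)
        warped <- propagate_mask(moving_closed, tr)
        rows[[length(rows) + 1L]] <- data.frame(
          phantom_id = id, pair = p, metric = sub$metric[si],
          spacing_mm = sub$spacing_mm[si], dice_pre = d_pre,
          dice_post = dice(warped, fixed_closed),
          iterations = tr$iterations)
      }
    }
  }
  do.call(rbind, rows)
}

#' Aggregate sweep results
#'
#' Mean and 10th/90th percentile of the post-registration Dice per
#' `(pair, metric, spacing)` setting, plus the mean pre-registration Dice —
#' the numbers behind a box-plot-style summary of the sweep.
#'
#' @param results `data.frame` from [run_sweep()].
#' @return Aggregated `data.frame`, one row per setting.
#' @export
aggregate_sweep <- function(results) {
  key <- interaction(results$pair, results$metric, results$spacing_mm,
                     drop = TRUE)
  rows <- lapply(split(results, key), function(g) {
    data.frame(pair = g$pair[1], metric = g$metric[1],
               spacing_mm = g$spacing_mm[1],
               dice_pre_mean = mean(g$dice_pre),
               dice_post_mean = mean(g$dice_post),
               dice_post_p10 = unname(stats::quantile(g$dice_post, 0.1)),
               dice_post_p90 = unname(stats::quantile(g$dice_post, 0.9)),
               n = nrow(g))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$pair, out$metric, out$spacing_mm), ]
}
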