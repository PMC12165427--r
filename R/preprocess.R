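# MRI preprocessing chain: similarity metrics, demons-style deformable
# registration under an MSE + smoothness objective, z-score normalization
# with truncation, local noise estimation, bias correction hook, and
# crop/resample to the network grid.

#' Mean squared error between two grids
#' @param image_a,image_b Numeric arrays of identical shape.
#' @export
mse <- function(image_a, image_b) {
  if (!identical(dim(image_a) %||% length(image_a),
                 dim(image_b) %||% length(image_b)))
    stop("invalid input: image shapes differ", call. = FALSE)
  mean((image_a - image_b)^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' Returns `Inf` when the images are identical (zero MSE).
#' @param ref,test Numeric arrays of identical shape.
#' @param peak Peak intensity value (> 0); 1 after [0,1] normalization.
#' @export
psnr <- function(ref, test, peak = 1) {
  stopifnot(peak > 0)
  m <- mse(ref, test)
  if (m == 0) return(Inf)
  10 * log10(peak^2 / m)
}

# Shift an array by one voxel along `ax` (replicating the border), used for
# finite differences and Laplacians.
shift1 <- function(a, ax, by) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  i <- idx[[ax]] + by
  i[i < 1L] <- 1L
  i[i > d[ax]] <- d[ax]
  idx[[ax]] <- i
  do.call(`[`, c(list(a), idx))
}

#' Smoothness energy of a deformation field
#'
#' Discretized integral of the squared gradient magnitude: forward
#' differences of every displacement component along every axis, summed.
#' Zero exactly for constant fields; homogeneous of degree 2.
#'
#' @param field 4D array (x, y, z, component) of voxel displacements.
#' @export
regularization_energy <- function(field) {
  d <- dim(field)
  if (length(d) != 4L || d[4] != 3L)
    stop("field must be a (x, y, z, 3) array", call. = FALSE)
  if (!all(is.finite(field)))
    stop("field contains non-finite values", call. = FALSE)
  e <- 0
  for (cmp in 1:3) {
    f <- field[, , , cmp, drop = TRUE]
    dd <- dim(f)
    for (ax in 1:3) {
      n <- dd[ax]
      if (n < 2) next
      idx <- lapply(dd, seq_len)
      lo <- idx; hi <- idx
      lo[[ax]] <- seq_len(n - 1L)
      hi[[ax]] <- seq_len(n - 1L) + 1L
      df <- do.call(`[`, c(list(f), hi)) - do.call(`[`, c(list(f), lo))
      e <- e + sum(df^2)
    }
  }
  e
}

# Gradient of regularization_energy with respect to the field (same shape).
reg_energy_grad <- function(field) {
  g <- array(0, dim(field))
  for (cmp in 1:3) {
    f <- field[, , , cmp, drop = TRUE]
    acc <- array(0, dim(f))
    for (ax in 1:3) {
      fwd <- shift1(f, ax, 1L) - f   # (d_{i+1} - d_i), zero at far border
      bwd <- f - shift1(f, ax, -1L)  # (d_i - d_{i-1}), zero at near border
      acc <- acc + 2 * (bwd - fwd)
    }
    g[, , , cmp] <- acc
  }
  g
}

#' Registration configuration
#'
#' @param reg_weight Weight of the smoothness energy.
#' @param step_size Scale of the demons update (the per-voxel force is
#'   bounded by 1/2, so this is roughly the peak displacement per
#'   iteration, voxels); halved on backtracking.
#' @param max_iters Iteration cap.
#' @param tol Relative objective-change stopping threshold.
#' @param smooth_sigma Gaussian sigma (voxels) applied to the demons force
#'   each iteration.
#' @param field_sigma Gaussian sigma of the field smoothing applied to each
#'   candidate (diffusion regularization); a relaxation sub-step at half
#'   this sigma harmonically spreads displacement into gradient-free
#'   regions whenever it lowers the objective.
#' @export
registration_config <- function(reg_weight = 0.1, step_size = 2,
                                max_iters = 100L, tol = 1e-6,
                                smooth_sigma = 2, field_sigma = 3) {
  stopifnot(reg_weight >= 0, step_size > 0, max_iters >= 1, tol > 0,
            smooth_sigma >= 0, field_sigma >= 0)
  structure(list(reg_weight = reg_weight, step_size = step_size,
                 max_iters = as.integer(max_iters), tol = tol,
                 smooth_sigma = smooth_sigma, field_sigma = field_sigma),
            class = "registration_config")
}

gauss_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

smooth3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  d <- dim(a)
  array(cpp_sep_smooth3(as.vector(a), d, gauss_kernel1d(sigma)), d)
}

# Warp `moving` by displacement field d: warped(v) = moving(v - d(v)).
warp_volume <- function(moving, field) {
  d <- dim(moving)
  base <- cbind(
    rep(seq_len(d[1]) - 1, times = d[2] * d[3]),
    rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]),
    rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
  coords <- base - matrix(field, ncol = 3)
  array(cpp_sample_trilinear(as.vector(moving), d, coords), d)
}

minmax01 <- function(a) {
  r <- range(a)
  if (r[2] > r[1]) (a - r[1]) / (r[2] - r[1]) else a * 0
}

#' Deformable registration by gradient descent on MSE + smoothness
#'
#' Dense per-voxel displacement field, demons-style: the similarity gradient
#' is Gaussian-smoothed each iteration; step-size backtracking enforces a
#' non-increasing objective. The displacement convention is that `d` carries
#' content of `moving` onto `fixed`: `warped(v) = moving(v - d(v))`.
#' Intensities are min-max normalized internally so the objective is
#' insensitive to global scaling.
#'
#' @param moving,fixed 3D arrays of identical shape.
#' @param cfg A [registration_config()].
#' @return List: `field` (x, y, z, 3 displacement array, voxels), `warped`
#'   (moving resampled into fixed space, original intensities), `trace`
#'   (objective per iteration, non-increasing).
#' @export
register <- function(moving, fixed, cfg = registration_config()) {
  if (!identical(dim(moving), dim(fixed)))
    stop("invalid input: image shapes differ", call. = FALSE)
  if (!all(is.finite(moving)) || !all(is.finite(fixed)))
    stop("invalid input: non-finite intensities", call. = FALSE)
  d <- dim(moving)
  n <- prod(d)
  mv <- minmax01(moving)
  fx <- minmax01(fixed)
  field <- array(0, c(d, 3))
  objective <- function(f) {
    w <- warp_volume(mv, f)
    mse(w, fx) + cfg$reg_weight * regularization_energy(f) / n
  }
  obj <- objective(field)
  if (!is.finite(obj))
    stop("registration diverged at iteration 0", call. = FALSE)
  trace <- obj
  step <- cfg$step_size
  smooth_field <- function(f, sigma) {
    if (sigma <= 0) return(f)
    for (ax in 1:3) f[, , , ax] <- smooth3(f[, , , ax], sigma)
    f
  }
  for (it in seq_len(cfg$max_iters)) {
    obj_prev <- obj
    w <- warp_volume(mv, field)
    r <- w - fx
    gax <- lapply(1:3, function(ax)
      (shift1(w, ax, 1L) - shift1(w, ax, -1L)) / 2)
    # classic demons force: residual times image gradient, normalized per
    # voxel (bounded by 1/2), then Gaussian-smoothed. The warped image's
    # own gradient approximates the moving gradient at v - d.
    den <- gax[[1]]^2 + gax[[2]]^2 + gax[[3]]^2 + r^2
    den[den < 1e-12] <- Inf
    u <- array(0, c(d, 3))
    for (ax in 1:3)
      u[, , , ax] <- smooth3(r * gax[[ax]] / den, cfg$smooth_sigma)
    improved <- FALSE
    for (bt in 1:10) {
      cand <- smooth_field(field + step * u, cfg$field_sigma)
      obj_new <- objective(cand)
      if (!is.finite(obj_new))
        stop("registration diverged at iteration ", it, call. = FALSE)
      if (obj_new <= obj) {
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (improved) {
      field <- cand
      obj <- obj_new
      step <- min(step * 1.3, 1.5 * cfg$step_size)
    }
    # diffusion relaxation: spreads displacement into gradient-free regions
    # (harmonic fill); accepted only when it lowers the objective, so the
    # trace stays non-increasing by construction
    relax <- smooth_field(field, cfg$field_sigma / 2)
    obj_relax <- objective(relax)
    relaxed <- is.finite(obj_relax) && obj_relax <= obj
    if (relaxed) {
      field <- relax
      obj <- obj_relax
    }
    trace <- c(trace, obj)
    if (!improved && !relaxed) break
    if ((obj_prev - obj) / max(obj_prev, .Machine$double.eps) < cfg$tol)
      break
  }
  list(field = field, warped = warp_volume(moving, field), trace = trace)
}

#' Mean displacement of a field over a support mask
#'
#' @param field (x, y, z, 3) displacement array.
#' @param mask Logical array; default everywhere.
#' @return Length-3 mean displacement vector (voxels).
#' @export
mean_displacement <- function(field, mask = NULL) {
  d <- dim(field)[1:3]
  if (is.null(mask)) mask <- array(TRUE, d)
  vapply(1:3, function(cmp) mean(field[, , , cmp][mask]), numeric(1))
}

#' Z-score normalization with truncation to [0, 1]
#'
#' z = (x - mu) / sigma with statistics over the brain mask, clipped to
#' [-5, 5], then affinely mapped to [0, 1] (so the masked mean lands on 0.5).
#'
#' @param vol 3D numeric array.
#' @param brain_mask Logical array; statistics are restricted to it.
#' @export
zscore_normalize <- function(vol, brain_mask = NULL) {
  if (is.null(brain_mask)) brain_mask <- array(TRUE, dim(vol))
  if (sum(brain_mask) == 0)
    stop("degenerate input: empty brain mask", call. = FALSE)
  x <- vol[brain_mask]
  mu <- mean(x)
  sg <- stats::sd(x)
  if (!is.finite(sg) || sg == 0)
    stop("degenerate input: zero intensity variance over mask", call. = FALSE)
  z <- (vol - mu) / sg
  z <- pmin(pmax(z, -5), 5)
  out <- (z + 5) / 10
  dim(out) <- dim(vol)
  out
}

#' Noise-intensity estimate D = k * sigma^2
#'
#' sigma^2 is estimated from the variance of the 6-neighbour Laplacian
#' high-pass residual over (the interior of) the brain mask; for i.i.d.
#' Gaussian noise the Laplacian has variance 42 sigma^2.
#'
#' @param vol 3D array.
#' @param k Adjustment coefficient in [0.1, 10].
#' @param brain_mask Optional logical array.
#' @export
estimate_noise <- function(vol, k = 1, brain_mask = NULL) {
  if (k < 0.1 || k > 10)
    stop("invalid spec: k must lie in [0.1, 10]", call. = FALSE)
  d <- dim(vol)
  lap <- -6 * vol
  for (ax in 1:3) lap <- lap + shift1(vol, ax, 1L) + shift1(vol, ax, -1L)
  interior <- array(TRUE, d)
  interior[c(1, d[1]), , ] <- FALSE
  interior[, c(1, d[2]), ] <- FALSE
  interior[, , c(1, d[3])] <- FALSE
  if (!is.null(brain_mask)) interior <- interior & brain_mask
  if (sum(interior) < 2) stop("degenerate input: mask too small",
                              call. = FALSE)
  v <- stats::var(lap[interior]) / 42
  k * v
}

#' Brain mask from intensity support
#'
#' Voxels whose maximum raw intensity across channels exceeds `frac` of the
#' robust (99.5th percentile) maximum. A crude stand-in for the skull-stripped
#' brain mask the pipeline otherwise receives as input.
#'
#' @param vol `multimodal_volume` or 4D array.
#' @param frac Relative threshold.
#' @export
brain_mask_from <- function(vol, frac = 0.2) {
  a <- if (inherits(vol, "multimodal_volume")) vol$data else vol
  m <- apply(a, 1:3, max)
  thr <- frac * stats::quantile(m, 0.995, names = FALSE)
  m > thr
}

#' Divide out a fitted smooth bias field (N4-style hook)
#'
#' The built-in method fits a degree-2 polynomial field to the masked
#' intensities by least squares and divides by it (rescaled to mean 1). A
#' full N4 implementation can be supplied through `external_fn`.
#'
#' @param vol 3D array.
#' @param brain_mask Logical array of the same shape.
#' @param method `"poly2"` or `"external"`.
#' @param external_fn Function `(vol, brain_mask) -> vol` used when
#'   `method = "external"`.
#' @export
bias_correct <- function(vol, brain_mask = NULL,
                         method = c("poly2", "external"),
                         external_fn = NULL) {
  method <- match.arg(method)
  if (method == "external") {
    if (is.null(external_fn))
      stop("external bias correction requires external_fn", call. = FALSE)
    return(external_fn(vol, brain_mask))
  }
  d <- dim(vol)
  if (is.null(brain_mask)) brain_mask <- array(TRUE, d)
  u <- lapply(1:3, function(a) 2 * (seq_len(d[a]) - 1) / (d[a] - 1) - 1)
  U <- array(rep(u[[1]], times = d[2] * d[3]), d)
  V <- array(rep(rep(u[[2]], each = d[1]), times = d[3]), d)
  W <- array(rep(u[[3]], each = d[1] * d[2]), d)
  X <- cbind(1, as.vector(U), as.vector(V), as.vector(W), as.vector(U)^2,
             as.vector(V)^2, as.vector(W)^2, as.vector(U * V),
             as.vector(U * W), as.vector(V * W))
  # multiplicative bias is additive in the log domain; a few reweighted
  # iterations (Tukey biweight) suppress tissue outliers such as tumor
  # compartments, which would otherwise bend the polynomial
  sel <- as.vector(brain_mask) & as.vector(vol) > 0
  if (sum(sel) < ncol(X))
    stop("degenerate input: too few positive masked voxels", call. = FALSE)
  Xs <- X[sel, , drop = FALSE]
  ys <- log(as.vector(vol)[sel])
  wts <- rep(1, length(ys))
  for (it in 1:4) {
    beta <- stats::lm.wfit(Xs, ys, wts)$coefficients
    beta[is.na(beta)] <- 0
    resid <- ys - as.vector(Xs %*% beta)
    s <- stats::mad(resid)
    if (s <= 0) break
    u <- resid / (4.685 * s)
    wts <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  }
  fit <- array(exp(X %*% beta), d)
  fit <- fit / mean(fit[brain_mask])
  fit[fit < 0.2] <- 0.2  # guard against divide-by-near-zero off the brain
  vol / fit
}

nearest_index <- function(nin, nout) {
  s <- ((seq_len(nout) - 0.5) * nin / nout - 0.5)
  i <- as.integer(round(s)) + 1L
  pmin(pmax(i, 1L), nin)
}

#' Crop to the brain bounding box and resample to a target grid
#'
#' Crops both volumes to the (padded) bounding box of the brain mask, then
#' resamples: trilinear for intensities, nearest-neighbour for labels, so the
#' label set is preserved. The output spacing is taken as declared.
#'
#' @param vol A `multimodal_volume`.
#' @param labels Optional `label_volume` on the same grid.
#' @param target_shape Output grid (3 positive integers).
#' @param spacing Output voxel spacing (mm).
#' @param brain_mask Optional logical array; derived from intensities via
#'   [brain_mask_from()] when absent.
#' @param pad Symmetric padding of the bounding box, voxels.
#' @return List with resampled `volume` and (if given) `labels`.
#' @export
crop_resample <- function(vol, labels = NULL, target_shape = c(128, 128, 128),
                          spacing = c(1, 1, 1), brain_mask = NULL, pad = 2L) {
  stopifnot(inherits(vol, "multimodal_volume"), all(target_shape >= 1))
  target_shape <- as.integer(target_shape)
  d <- dim(vol$data)[1:3]
  if (is.null(brain_mask)) brain_mask <- brain_mask_from(vol)
  if (sum(brain_mask) == 0)
    stop("degenerate input: empty brain mask", call. = FALSE)
  idx <- which(brain_mask, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - pad, 1L)
  hi <- pmin(apply(idx, 2, max) + pad, d)
  crop <- vol$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], , drop = FALSE]
  cd <- dim(crop)[1:3]
  C <- dim(crop)[4]
  xm <- matrix(crop, ncol = C)             # N x C, tape layout
  out <- cpp_resize3(xm, cd, target_shape)
  vout <- array(out, c(target_shape, C))
  aff <- diag(c(spacing, 1))
  res <- list(volume = multimodal_volume(vout, spacing, aff,
                                         vol$modalities))
  if (!is.null(labels)) {
    stopifnot(inherits(labels, "label_volume"))
    lc <- labels$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    i1 <- nearest_index(cd[1], target_shape[1])
    i2 <- nearest_index(cd[2], target_shape[2])
    i3 <- nearest_index(cd[3], target_shape[3])
    res$labels <- label_volume(lc[i1, i2, i3, drop = FALSE], spacing, aff)
  }
  res
}

#' Normalize all channels of a multimodal volume
#'
#' Applies [zscore_normalize()] per channel with a shared brain mask.
#' @param vol A `multimodal_volume`.
#' @param brain_mask Optional logical array.
#' @return A `multimodal_volume` with intensities in [0, 1].
#' @export
normalize_volume <- function(vol, brain_mask = NULL) {
  stopifnot(inherits(vol, "multimodal_volume"))
  if (is.null(brain_mask)) brain_mask <- brain_mask_from(vol)
  out <- vol
  for (m in seq_len(dim(vol$data)[4]))
    out$data[, , , m] <- zscore_normalize(vol$data[, , , m, drop = TRUE],
                                          brain_mask)
  out
}
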