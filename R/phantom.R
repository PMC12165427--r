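# Synthetic multimodal glioma phantom.
#
# A phantom is a brain sphere containing three nested tumor ellipsoids with
# BraTS label semantics: the innermost compartment is the necrotic core
# (label 1), the middle shell the enhancing rim (label 4), and the outer
# shell peritumoral edema (label 2). Each modality channel is a per-tissue
# mean-intensity map modulated by a smooth multiplicative bias field plus
# additive Gaussian noise. It emulates the statistical structure of
# co-registered, skull-stripped, 1 mm isotropic glioma MRI; it makes no
# attempt at anatomical realism or MRI physics.

#' Construct a multimodal volume
#'
#' @param data 4D numeric array (x, y, z, channel).
#' @param spacing Voxel spacing in mm (length 3).
#' @param affine 4x4 voxel-to-world matrix (default diagonal of spacing).
#' @param modalities Channel names, fixed order `t1, t1c, t2, flair`.
#' @return A `multimodal_volume`.
#' @export
multimodal_volume <- function(data, spacing = c(1, 1, 1), affine = NULL,
                              modalities = c("t1", "t1c", "t2", "flair")) {
  stopifnot(length(dim(data)) == 4L, length(spacing) == 3L, all(spacing > 0))
  if (dim(data)[4] != length(modalities))
    stop("channel count does not match modalities", call. = FALSE)
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  structure(list(data = data, spacing = as.numeric(spacing), affine = affine,
                 modalities = modalities), class = "multimodal_volume")
}

#' Construct a label volume
#'
#' @param data 3D integer array with values in \{0, 1, 2, 4\}.
#' @inheritParams multimodal_volume
#' @return A `label_volume`.
#' @export
label_volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  stopifnot(length(dim(data)) == 3L, length(spacing) == 3L, all(spacing > 0))
  check_labels(data)
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  structure(list(data = array(as.integer(data), dim(data)),
                 spacing = as.numeric(spacing), affine = affine),
            class = "label_volume")
}

#' @export
print.multimodal_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<multimodal_volume %dx%dx%d, %d channels (%s), spacing %s mm>\n",
              d[1], d[2], d[3], d[4], paste(x$modalities, collapse = ","),
              paste(signif(x$spacing, 3), collapse = "x")))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$data)
  tb <- table(x$data)
  cat(sprintf("<label_volume %dx%dx%d: %s>\n", d[1], d[2], d[3],
              paste(sprintf("%s=%d", names(tb), as.integer(tb)),
                    collapse = " ")))
  invisible(x)
}

# Run code under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)))
  set.seed(seed)
  force(code)
}

# Default per-tissue mean intensities (rows: modality; columns: tissue).
# Chosen to mimic the canonical qualitative contrasts: necrosis dark on T1C,
# enhancing rim bright on T1C, edema brightest on FLAIR/T2.
default_contrasts <- function() {
  m <- rbind(t1    = c(brain = 0.60, net = 0.30, et = 0.45, ed = 0.50),
             t1c   = c(brain = 0.60, net = 0.25, et = 0.90, ed = 0.50),
             t2    = c(brain = 0.40, net = 0.70, et = 0.60, ed = 0.75),
             flair = c(brain = 0.45, net = 0.60, et = 0.70, ed = 0.90))
  m
}

#' Phantom specification
#'
#' @param grid_shape Grid size in voxels (each >= 16).
#' @param spacing_mm Voxel spacing (default 1 mm isotropic, as in BraTS).
#' @param brain_radius_vox Brain sphere radius in voxels.
#' @param tumor_center_vox Tumor center (0-based voxel coordinates); default
#'   slightly off the grid center.
#' @param r_net,r_et,r_ed Nested compartment radii in voxels (scalar sphere
#'   radius or length-3 ellipsoid semi-axes), `r_net <= r_et <= r_ed`;
#'   defaults scale with the grid (3/5/8 voxels on a 64-voxel grid).
#' @param noise_sigma Additive Gaussian noise s.d. (intensity units).
#' @param bias_amplitude Peak relative amplitude of the multiplicative bias
#'   field (fraction of the mean intensity).
#' @param modality_contrasts 4 x 4 matrix of per-modality, per-tissue mean
#'   intensities (rows t1/t1c/t2/flair, columns brain/net/et/ed).
#' @param seed Integer seed; identical spec + seed is bit-reproducible.
#' @return A `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64), spacing_mm = c(1, 1, 1),
                         brain_radius_vox = 0.42 * min(grid_shape),
                         tumor_center_vox = (grid_shape - 1) / 2 +
                           0.1 * min(grid_shape) * c(1, -1, 0),
                         r_net = 3 * min(grid_shape) / 64,
                         r_et = 5 * min(grid_shape) / 64,
                         r_ed = 8 * min(grid_shape) / 64,
                         noise_sigma = 0.03, bias_amplitude = 0.1,
                         modality_contrasts = default_contrasts(),
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  ex <- function(r) if (length(r) == 1L) rep(r, 3) else as.numeric(r)
  r_net <- ex(r_net); r_et <- ex(r_et); r_ed <- ex(r_ed)
  if (any(grid_shape < 16L))
    stop("invalid spec: grid_shape must be >= 16 in every axis", call. = FALSE)
  if (any(r_net < 0) || any(r_et < 0) || any(r_ed < 0))
    stop("invalid spec: radii must be non-negative", call. = FALSE)
  if (any(r_net > r_et) || any(r_et > r_ed))
    stop("invalid spec: radii must nest r_net <= r_et <= r_ed", call. = FALSE)
  if (noise_sigma < 0) stop("invalid spec: noise_sigma < 0", call. = FALSE)
  if (bias_amplitude < 0)
    stop("invalid spec: bias_amplitude < 0", call. = FALSE)
  ctr <- (grid_shape - 1) / 2
  if (sqrt(sum((tumor_center_vox - ctr)^2)) + max(r_ed) > brain_radius_vox &&
      any(r_ed > 0))
    stop("invalid spec: tumor does not fit inside the brain sphere",
         call. = FALSE)
  structure(list(grid_shape = grid_shape, spacing_mm = as.numeric(spacing_mm),
                 brain_radius_vox = brain_radius_vox,
                 tumor_center_vox = as.numeric(tumor_center_vox),
                 r_net = r_net, r_et = r_et, r_ed = r_ed,
                 noise_sigma = noise_sigma, bias_amplitude = bias_amplitude,
                 modality_contrasts = modality_contrasts,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Squared normalized ellipsoid distance field: <=1 inside.
ellipsoid_field <- function(grid, center, radii) {
  if (any(radii <= 0)) return(array(Inf, grid))
  ax <- lapply(1:3, function(a) ((seq_len(grid[a]) - 1) - center[a]) / radii[a])
  f <- array(0, grid)
  f <- f + array(rep(ax[[1]]^2, times = grid[2] * grid[3]), grid)
  f <- f + array(rep(rep(ax[[2]]^2, each = grid[1]), times = grid[3]), grid)
  f + array(rep(ax[[3]]^2, each = grid[1] * grid[2]), grid)
}

#' Generate a synthetic multimodal glioma phantom
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` (`multimodal_volume`), `labels`
#'   (`label_volume`), and `clean` (noise-free, bias-free 4D array, useful as
#'   a PSNR reference in tests).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid_shape
  ctr <- (g - 1) / 2
  brain <- ellipsoid_field(g, ctr, rep(spec$brain_radius_vox, 3)) <= 1
  f_net <- ellipsoid_field(g, spec$tumor_center_vox, spec$r_net)
  f_et <- ellipsoid_field(g, spec$tumor_center_vox, spec$r_et)
  f_ed <- ellipsoid_field(g, spec$tumor_center_vox, spec$r_ed)
  labels <- array(0L, g)
  labels[f_ed <= 1 & brain] <- 2L   # edema shell
  labels[f_et <= 1 & brain] <- 4L   # enhancing rim
  labels[f_net <= 1 & brain] <- 1L  # necrotic core
  cm <- spec$modality_contrasts
  clean <- array(0, c(g, 4))
  for (m in 1:4) {
    ch <- array(0, g)
    ch[brain] <- cm[m, "brain"]
    ch[labels == 1L] <- cm[m, "net"]
    ch[labels == 4L] <- cm[m, "et"]
    ch[labels == 2L] <- cm[m, "ed"]
    clean[, , , m] <- ch
  }
  data <- with_seed(spec$seed, {
    field <- bias_field_poly2(g, spec$bias_amplitude)
    noisy <- clean * as.vector(field) +
      array(stats::rnorm(length(clean), sd = spec$noise_sigma), dim(clean))
    noisy
  })
  aff <- diag(c(spec$spacing_mm, 1))
  list(volume = multimodal_volume(data, spec$spacing_mm, aff),
       labels = label_volume(labels, spec$spacing_mm, aff),
       clean = clean)
}

# Smooth degree-2 polynomial field in normalized coordinates, centered so its
# global mean is exactly 1 and scaled so it stays within [1-a, 1+a].
bias_field_poly2 <- function(grid, amplitude) {
  if (amplitude == 0) return(array(1, grid))
  u <- lapply(1:3, function(a) {
    s <- seq_len(grid[a]) - 1
    2 * s / max(s[length(s)], 1) - 1
  })
  U <- array(rep(u[[1]], times = grid[2] * grid[3]), grid)
  V <- array(rep(rep(u[[2]], each = grid[1]), times = grid[3]), grid)
  W <- array(rep(u[[3]], each = grid[1] * grid[2]), grid)
  cf <- stats::rnorm(9)
  f <- cf[1] * U + cf[2] * V + cf[3] * W + cf[4] * U^2 + cf[5] * V^2 +
    cf[6] * W^2 + cf[7] * U * V + cf[8] * U * W + cf[9] * V * W
  f <- f - mean(f)
  mx <- max(abs(f))
  if (mx > 0) f <- f / mx
  1 + amplitude * f
}

#' Apply a smooth multiplicative bias field to a volume
#'
#' @param vol A `multimodal_volume`.
#' @param amplitude Peak relative amplitude (>= 0); the field lies in
#'   `[1 - amplitude, 1 + amplitude]` and has global mean exactly 1.
#' @param seed Integer seed for the random polynomial coefficients.
#' @return A `multimodal_volume`; the applied field is attached as attribute
#'   `"bias_field"`.
#' @export
add_bias_field <- function(vol, amplitude, seed = 1L) {
  stopifnot(inherits(vol, "multimodal_volume"))
  if (amplitude < 0)
    stop("invalid spec: amplitude must be >= 0", call. = FALSE)
  g <- dim(vol$data)[1:3]
  field <- with_seed(seed, bias_field_poly2(g, amplitude))
  out <- vol
  out$data <- vol$data * as.vector(field)
  attr(out, "bias_field") <- field
  out
}

#' Export phantom cases as NIfTI files plus a JSON manifest
#'
#' Writes `<case>_{t1,t1c,t2,flair,seg}.nii.gz` per case and `manifest.json`.
#'
#' @param cases List of lists with elements `volume`, `labels`, and
#'   optionally `seed` (as returned by [generate_phantom()]).
#' @param dir Output directory (created if missing).
#' @param case_ids Optional character ids; default `case001`, ...
#' @param gzip Write gzip-compressed NIfTI (default TRUE).
#' @return The manifest (invisibly also written to `manifest.json`).
#' @export
export_dataset <- function(cases, dir, case_ids = NULL, gzip = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir, call. = FALSE)
  if (is.null(case_ids))
    case_ids <- sprintf("case%03d", seq_along(cases))
  ext <- if (gzip) ".nii.gz" else ".nii"
  manifest <- list(version = 1L, cases = list())
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    id <- case_ids[i]
    vol <- cs$volume
    paths <- list()
    for (m in seq_along(vol$modalities)) {
      p <- file.path(dir, paste0(id, "_", vol$modalities[m], ext))
      write_nifti(vol$data[, , , m, drop = TRUE], p, spacing = vol$spacing,
                  affine = vol$affine)
      paths[[vol$modalities[m]]] <- p
    }
    segp <- file.path(dir, paste0(id, "_seg", ext))
    write_nifti(cs$labels$data, segp, spacing = cs$labels$spacing,
                affine = cs$labels$affine, datatype = "int16")
    paths$seg <- segp
    manifest$cases[[id]] <- list(case_id = id, paths = paths,
                                 seed = cs$seed %||% NA,
                                 spacing = vol$spacing,
                                 shape = dim(vol$data)[1:3])
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Generate a seeded set of phantom training cases
#'
#' Varies tumor center and radii deterministically from the base seed.
#'
#' @param n Number of cases.
#' @param grid_shape Grid size per case.
#' @param seed Base seed; case i uses `seed + i`.
#' @param noise_sigma,bias_amplitude Passed to [phantom_spec()].
#' @return List of cases (`volume`, `labels`, `clean`, `seed`, `spec`).
#' @export
phantom_cases <- function(n, grid_shape = c(32, 32, 32), seed = 0L,
                          noise_sigma = 0.03, bias_amplitude = 0.1) {
  lapply(seq_len(n), function(i) {
    si <- as.integer(seed) + i
    pars <- with_seed(si * 1009L %% .Machine$integer.max, {
      sc <- min(grid_shape) / 32
      list(center = (grid_shape - 1) / 2 +
             stats::runif(3, -2, 2) * sc,
           r_ed = stats::runif(1, 6.5, 8.5) * sc)
    })
    r_ed <- pars$r_ed
    sp <- phantom_spec(grid_shape = grid_shape,
                       tumor_center_vox = pars$center,
                       r_net = 0.38 * r_ed, r_et = 0.62 * r_ed, r_ed = r_ed,
                       noise_sigma = noise_sigma,
                       bias_amplitude = bias_amplitude, seed = si)
    ph <- generate_phantom(sp)
    ph$seed <- si
    ph$spec <- sp
    ph
  })
}
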