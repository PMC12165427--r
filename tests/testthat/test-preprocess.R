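test_that("mse matches the closed forms and the loop oracle", {
  expect_equal(mse(array(1, c(2, 2, 2)), array(1, c(2, 2, 2))), 0)
  expect_equal(mse(c(0, 0), c(1, 1)), 1)
  set.seed(20)
  a <- array(rnorm(8^3), c(8, 8, 8))
  b <- array(rnorm(8^3), c(8, 8, 8))
  acc <- 0
  for (i in seq_along(a)) acc <- acc + (a[i] - b[i])^2
  expect_equal(mse(a, b), acc / length(a), tolerance = 1e-12)
  expect_equal(mse(a, b), mse(b, a))
  expect_error(mse(a, array(0, c(4, 4, 4))), "shapes differ")
})

test_that("psnr closed forms and sentinel", {
  a <- array(0.5, c(4, 4, 4))
  expect_equal(psnr(a, a), Inf)
  b <- a + 0.1  # MSE = 0.01
  expect_equal(psnr(a, b, peak = 1), 20, tolerance = 1e-9)
  set.seed(21)
  r <- array(runif(64), c(4, 4, 4))
  t2 <- array(runif(64), c(4, 4, 4))
  expect_equal(psnr(r, t2, 2), 10 * log10(4 / mean((r - t2)^2)))
})

test_that("regularization energy: zero, ramp oracle, homogeneity", {
  n <- 6L
  zero <- array(0.7, c(n, n, n, 3))   # constant field
  expect_equal(regularization_energy(zero), 0)
  ramp <- array(0, c(n, n, n, 3))
  for (i in seq_len(n)) ramp[i, , , 1] <- i - 1  # dx = x
  # loop oracle: forward differences over every component and axis
  oracle <- 0
  for (cmp in 1:3) for (ax in 1:3) {
    f <- ramp[, , , cmp]
    d <- dim(f)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      nb <- c(i, j, k); nb[ax] <- nb[ax] + 1
      if (nb[ax] <= d[ax])
        oracle <- oracle + (f[nb[1], nb[2], nb[3]] - f[i, j, k])^2
    }
  }
  expect_equal(regularization_energy(ramp), oracle)
  expect_equal(regularization_energy(2 * ramp),
               4 * regularization_energy(ramp))
})

test_that("registering an image to itself stays near zero", {
  set.seed(22)
  d <- c(16, 16, 16)
  ctr <- (d - 1) / 2
  blob <- array(0, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3])
    blob[i, j, k] <- exp(-sum((c(i, j, k) - 1 - ctr)^2) / (2 * 3^2))
  r <- register(blob, blob, registration_config(max_iters = 5))
  expect_lt(max(abs(r$field)), 0.05)
  expect_lt(r$trace[length(r$trace)], 1e-8)
  expect_true(all(diff(r$trace) <= 1e-12))
})

test_that("z-score normalization contract and brute-force oracle", {
  set.seed(23)
  v <- array(rnorm(8^3, mean = 3, sd = 2), c(8, 8, 8))
  mask <- random_mask(c(8, 8, 8), 0.7)
  out <- zscore_normalize(v, mask)
  expect_true(all(out >= 0 & out <= 1))
  mu <- mean(v[mask]); sg <- stats::sd(v[mask])
  oracle <- (pmin(pmax((v - mu) / sg, -5), 5) + 5) / 10
  expect_equal(out, oracle, tolerance = 1e-12)
  # a voxel holding exactly the masked mean maps to the midpoint 0.5, and
  # one beyond the truncation range (z = 7) saturates at 1
  mask[1:2, 1, 1] <- FALSE   # keep the probe voxels out of the statistics
  v2 <- v
  v2[1, 1, 1] <- mean(v2[mask])
  v2[2, 1, 1] <- mean(v2[mask]) + 7 * stats::sd(v2[mask])
  out2 <- zscore_normalize(v2, mask)
  expect_equal(out2[1, 1, 1], 0.5)
  expect_equal(out2[2, 1, 1], 1)
  expect_error(zscore_normalize(array(1, c(4, 4, 4))), "zero intensity")
})

test_that("noise estimation recovers injected variance and scales with k", {
  set.seed(24)
  d <- c(32, 32, 32)
  ax <- seq_len(d[1]) / d[1]
  smooth <- outer(outer(sin(2 * pi * ax), cos(2 * pi * ax)), ax)
  noisy <- smooth + array(rnorm(prod(d), sd = 2), d)   # sigma^2 = 4
  D1 <- estimate_noise(noisy, k = 1)
  expect_lt(abs(D1 - 4) / 4, 0.15)
  expect_equal(estimate_noise(noisy, k = 2), 2 * D1, tolerance = 1e-12)
  expect_equal(estimate_noise(array(5, c(8, 8, 8)), k = 1), 0)
  expect_error(estimate_noise(noisy, k = 0.01), "0.1")
})

test_that("crop_resample shape contract, label preservation, volume", {
  ph <- generate_phantom(phantom_spec(grid_shape = c(64, 64, 64), seed = 3))
  cr <- crop_resample(ph$volume, ph$labels, target_shape = c(32, 32, 32))
  expect_equal(dim(cr$volume$data), c(32, 32, 32, 4))
  expect_equal(dim(cr$labels$data), c(32, 32, 32))
  expect_true(all(as.vector(cr$labels$data) %in% c(0L, 1L, 2L, 4L)))
  # WT voxel *fraction* within the brain is approximately preserved
  wt0 <- sum(region_masks(ph$labels$data)$wt)
  wt1 <- sum(region_masks(cr$labels$data)$wt)
  mask0 <- brain_mask_from(ph$volume)
  frac0 <- wt0 / sum(mask0)
  frac1 <- wt1 / sum(brain_mask_from(cr$volume))
  expect_lt(abs(frac1 - frac0) / frac0, 0.05)
  expect_error(crop_resample(ph$volume,
                             brain_mask = array(FALSE, c(64, 64, 64))),
               "empty brain mask")
})

test_that("bias_correct flattens a known multiplicative field", {
  ph <- tiny_phantom(noise = 0.005, bias = 0)
  biased <- add_bias_field(ph$volume, 0.3, seed = 9)
  ch <- biased$data[, , , 1, drop = TRUE]
  mask <- brain_mask_from(ph$volume)
  fixed <- bias_correct(ch, mask)
  clean <- ph$volume$data[, , , 1, drop = TRUE]
  # residual inhomogeneity should shrink substantially
  err_before <- stats::sd((ch / clean)[mask & clean > 0.1])
  err_after <- stats::sd((fixed / clean)[mask & clean > 0.1])
  expect_lt(err_after, 0.5 * err_before)
})
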