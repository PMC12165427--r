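# Shared fixtures. Single-threaded BLAS: the conv gemms are small and thread
# oversubscription on constrained CPUs slows them badly.
Sys.setenv(OPENBLAS_NUM_THREADS = "1", OMP_NUM_THREADS = "1")

g3 <- asNamespace("glioseg3d")

tiny_phantom <- function(grid = c(24, 24, 24), seed = 7L,
                         r = c(2, 3.2, 5) * min(grid) / 24,
                         noise = 0.02, bias = 0.1) {
  sc <- min(grid) / 24
  generate_phantom(phantom_spec(grid_shape = grid,
                                brain_radius_vox = 0.42 * min(grid),
                                tumor_center_vox = (grid - 1) / 2 +
                                  c(2, -1, 0) * sc,
                                r_net = r[1], r_et = r[2], r_ed = r[3],
                                noise_sigma = noise, bias_amplitude = bias,
                                seed = seed))
}

random_mask <- function(dims, p = 0.3) array(stats::runif(prod(dims)) < p, dims)

random_labels <- function(dims, p_bg = 0.7) {
  array(sample(c(0L, 1L, 2L, 4L), prod(dims), replace = TRUE,
               prob = c(p_bg, rep((1 - p_bg) / 3, 3))), dims)
}

# Random probability field, N x B rows summing to 1 (tape layout).
random_probs <- function(n, B = 4L) {
  m <- matrix(stats::rexp(n * B), nrow = n)
  m / rowSums(m)
}

# Independent soft-Dice oracle (plain loops, no shared code with the
# package implementation).
oracle_soft_dice <- function(p_bn, g_bn, eps = 1e-6) {
  B <- nrow(p_bn)
  acc <- 0
  for (b in seq_len(B)) {
    tp <- 0; fn <- 0; fp <- 0
    for (n in seq_len(ncol(p_bn))) {
      tp <- tp + p_bn[b, n] * g_bn[b, n]
      fn <- fn + (1 - p_bn[b, n]) * g_bn[b, n]
      fp <- fp + p_bn[b, n] * (1 - g_bn[b, n])
    }
    acc <- acc + 2 * tp / (2 * tp + fn + fp + eps)
  }
  B - acc
}

# Brute-force evaluation of the combined objective as printed: Tversky-Dice
# sum over classes plus -(lambda/N) sum g (1-p)^2 log p.
oracle_combined <- function(p_bn, g_bn, alpha, beta, lambda, eps = 1e-6) {
  B <- nrow(p_bn); N <- ncol(p_bn)
  dice <- B
  for (b in seq_len(B)) {
    tp <- sum(p_bn[b, ] * g_bn[b, ])
    fn <- sum((1 - p_bn[b, ]) * g_bn[b, ])
    fp <- sum(p_bn[b, ] * (1 - g_bn[b, ]))
    dice <- dice - tp / (tp + alpha * fn + beta * fp + eps)
  }
  focal <- 0
  for (b in seq_len(B)) for (n in seq_len(N)) {
    pc <- min(max(p_bn[b, n], 1e-7), 1 - 1e-7)
    focal <- focal + g_bn[b, n] * (1 - p_bn[b, n])^2 * log(pc)
  }
  dice - lambda * focal / N
}
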