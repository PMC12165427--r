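test_that("soft counts match the brute-force voxel loop", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 4^3
    p <- t(random_probs(n))           # B x N public layout
    g <- onehot_labels(random_labels(c(4, 4, 4)))
    sc <- soft_counts(p, g)
    for (b in 1:4) {
      tp <- sum(vapply(seq_len(n), function(i) p[b, i] * g[b, i], 1))
      expect_equal(sc$tp[b], tp, tolerance = 1e-12)
      expect_equal(sc$fn[b], sum(g[b, ]) - tp, tolerance = 1e-10)
      expect_equal(sc$fp[b], sum(p[b, ]) - tp, tolerance = 1e-10)
    }
    # TP + FN = sum g, TP + FP = sum p (per class)
    expect_equal(sc$tp + sc$fn, rowSums(g), tolerance = 1e-10)
    expect_equal(sc$tp + sc$fp, rowSums(p), tolerance = 1e-10)
  }
})

test_that("perfect and uniform predictions give the closed-form counts", {
  g <- onehot_labels(random_labels(c(4, 4, 4)))
  sc <- soft_counts(g, g)
  expect_equal(sc$tp, rowSums(g))
  expect_equal(sc$fn, rep(0, 4))
  expect_equal(sc$fp, rep(0, 4))
  u <- matrix(0.25, nrow = 4, ncol = ncol(g))
  scu <- soft_counts(u, g)
  expect_equal(scu$tp, rowSums(g) / 4)
})

test_that("lambda = 0, alpha = beta = 0.5 reduces to soft Dice", {
  set.seed(1)
  cfg <- loss_config(alpha = 0.5, beta = 0.5, lambda = 0)
  for (rep in 1:10) {
    p <- t(random_probs(4^3))
    g <- onehot_labels(random_labels(c(4, 4, 4)))
    expect_equal(combined_loss(p, g, cfg), oracle_soft_dice(p, g),
                 tolerance = 1e-7)
  }
})

test_that("full objective matches the brute-force per-voxel oracle", {
  set.seed(2)
  for (rep in 1:10) {
    p <- t(random_probs(4^3))
    g <- onehot_labels(random_labels(c(4, 4, 4)))
    cfg <- loss_config(alpha = 0.7, beta = 0.3, lambda = 1.5)
    expect_equal(combined_loss(p, g, cfg),
                 oracle_combined(p, g, 0.7, 0.3, 1.5), tolerance = 1e-7)
  }
})

test_that("hand-computed single-voxel example reproduces", {
  g <- matrix(c(1, 0), nrow = 2)
  p <- matrix(c(0.5, 0.5), nrow = 2)
  cfg <- loss_config(alpha = 0.5, beta = 0.5, lambda = 1)
  # class 1: TP=0.5, FN=0.5, FP=0 -> 0.5/0.75; class 2: TP=0 -> term 0;
  # Dice part 2 - 2/3, Focal part 0.25 ln 2
  expected <- 4 / 3 + log(2) / 4
  expect_equal(combined_loss(p, g, cfg), expected, tolerance = 1e-5)
})

test_that("loss is non-negative, vanishes at the optimum, and is monotone", {
  cfg <- loss_config()
  g <- onehot_labels(random_labels(c(3, 3, 3)))
  expect_lt(combined_loss(pmin(pmax(g, 1e-7), 1 - 1e-7), g, cfg), 1e-4)
  set.seed(3)
  for (rep in 1:10) {
    p <- t(random_probs(27))
    expect_gte(combined_loss(p, g, cfg), 0)
  }
  # single voxel, two classes: L strictly decreasing in p(true class)
  ps <- seq(0.05, 0.95, by = 0.05)
  ls <- vapply(ps, function(q)
    combined_loss(matrix(c(q, 1 - q), nrow = 2), matrix(c(1, 0), nrow = 2),
                  cfg), 1)
  expect_true(all(diff(ls) < 0))
})

test_that("loss is invariant under voxel permutation", {
  set.seed(4)
  p <- t(random_probs(50))
  g <- onehot_labels(sample(c(0L, 1L, 2L, 4L), 50, TRUE))
  perm <- sample(50)
  expect_equal(combined_loss(p, g), combined_loss(p[, perm], g[, perm]),
               tolerance = 1e-12)
})

test_that("analytic gradient matches central finite differences", {
  set.seed(5)
  cfg <- loss_config(alpha = 0.6, beta = 0.4, lambda = 1.2)
  for (rep in 1:3) {
    n <- 3^3
    p <- random_probs(n)              # N x B tape layout
    g <- t(onehot_labels(random_labels(c(3, 3, 3))))
    tape <- g3$ad_tape()
    pn <- g3$ad_leaf(tape, p)
    ln <- g3$ad_dice_focal(tape, pn, g, cfg)
    g3$ad_backward(tape, ln)
    h <- 1e-6
    for (idx in sample(length(p), 8)) {
      pp <- p; pp[idx] <- pp[idx] + h
      pm <- p; pm[idx] <- pm[idx] - h
      fd <- (oracle_combined(t(pp), t(g), 0.6, 0.4, 1.2) -
               oracle_combined(t(pm), t(g), 0.6, 0.4, 1.2)) / (2 * h)
      expect_equal(pn$grad[idx], fd, tolerance = 1e-4)
    }
  }
})

test_that("invalid probability inputs are rejected", {
  g <- onehot_labels(c(0L, 1L))
  bad <- matrix(c(0.9, 0.3, 0.2, 0.1), nrow = 4, ncol = 2)
  expect_error(combined_loss(bad, g), "sum to 1")
  expect_error(soft_counts(t(random_probs(8)), onehot_labels(rep(0L, 9))),
               "disagree")
  expect_error(onehot_labels(c(0L, 3L)), "outside")
})
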