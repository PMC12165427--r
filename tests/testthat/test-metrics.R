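test_that("region decomposition follows the BraTS label semantics", {
  lab <- array(0L, c(6, 6, 6))
  lab[1:2, 1, 1] <- 1L         # 2 voxels NET
  lab[1:4, 2, 1] <- 2L         # 4 voxels ED
  lab[1, 3, 1] <- 4L           # 1 voxel ET
  m <- region_masks(lab)
  expect_equal(sum(m$wt), 7)
  expect_equal(sum(m$tc), 3)
  expect_equal(sum(m$et), 1)
  expect_error(region_masks(array(3L, c(2, 2, 2))), "unknown label")
  empty <- region_masks(array(0L, c(4, 4, 4)))
  expect_equal(sum(empty$wt) + sum(empty$tc) + sum(empty$et), 0)
})

test_that("overlap metrics match brute-force counting on random pairs", {
  set.seed(10)
  for (rep in 1:20) {
    G <- random_mask(c(8, 8, 8), p = stats::runif(1, 0.1, 0.6))
    O <- random_mask(c(8, 8, 8), p = stats::runif(1, 0.1, 0.6))
    inter <- sum(G & O)
    expect_equal(dsc(G, O), 2 * inter / (sum(G) + sum(O)))
    expect_equal(recall(G, O), inter / sum(G))
    expect_equal(precision(G, O), inter / sum(O))
    expect_equal(iou(G, O), inter / sum(G | O))
    # symmetry / duality / standard identities
    expect_equal(dsc(G, O), dsc(O, G))
    expect_equal(recall(G, O), precision(O, G))
    expect_equal(iou(G, O), dsc(G, O) / (2 - dsc(G, O)), tolerance = 1e-12)
    expect_lte(iou(G, O), dsc(G, O))
  }
})

test_that("empty-mask conventions and degenerate cases", {
  e <- array(FALSE, c(4, 4, 4))
  f <- e; f[1, 1, 1] <- TRUE
  expect_equal(dsc(e, e), 1)
  expect_equal(iou(e, e), 1)
  expect_equal(recall(e, f), 0)
  expect_equal(precision(f, e), 0)
  expect_equal(dsc(f, f), 1)
  expect_error(dsc(e, array(FALSE, c(3, 3, 3))), "shapes differ")
  expect_error(hd95(e, f), "empty")
})

test_that("hd95 equals the brute-force all-pairs oracle on small masks", {
  oracle_hd95 <- function(G, O, spacing) {
    bnd <- function(m) {
      d <- dim(m)
      out <- array(FALSE, d)
      for (i in which(m)) {
        ix <- arrayInd(i, d)
        interior <- TRUE
        for (ax in 1:3) for (s in c(-1L, 1L)) {
          j <- ix; j[ax] <- j[ax] + s
          if (j[ax] < 1 || j[ax] > d[ax] || !m[j[1], j[2], j[3]])
            interior <- FALSE
        }
        if (!interior) out[ix[1], ix[2], ix[3]] <- TRUE
      }
      out
    }
    a <- which(bnd(G), arr.ind = TRUE) %*% diag(spacing)
    b <- which(bnd(O), arr.ind = TRUE) %*% diag(spacing)
    dmat <- sqrt(pmax(outer(rowSums(a^2), rowSums(b^2), "+") -
                        2 * a %*% t(b), 0))
    pooled <- c(apply(dmat, 1, min), apply(dmat, 2, min))
    unname(stats::quantile(pooled, 0.95, type = 7))
  }
  # two unit cubes offset by 3 voxels
  G <- array(FALSE, c(8, 8, 8)); G[2:3, 2:3, 2:3] <- TRUE
  O <- array(FALSE, c(8, 8, 8)); O[5:6, 2:3, 2:3] <- TRUE
  expect_equal(hd95(G, O), oracle_hd95(G, O, c(1, 1, 1)), tolerance = 1e-9)
  set.seed(11)
  for (rep in 1:10) {
    G <- random_mask(c(7, 7, 7), 0.3)
    O <- random_mask(c(7, 7, 7), 0.3)
    if (sum(G) == 0 || sum(O) == 0) next
    sp <- stats::runif(3, 0.5, 2)
    expect_equal(hd95(G, O, sp), oracle_hd95(G, O, sp), tolerance = 1e-9)
  }
})

test_that("hd95 identities: coincidence and spacing homogeneity", {
  set.seed(12)
  G <- random_mask(c(8, 8, 8), 0.4)
  O <- random_mask(c(8, 8, 8), 0.4)
  expect_equal(hd95(G, G), 0)
  expect_equal(hd95(G, O, c(2, 2, 2)), 2 * hd95(G, O, c(1, 1, 1)),
               tolerance = 1e-12)
})

test_that("metrics_report aggregates per region with sane conventions", {
  ph <- tiny_phantom()
  rep0 <- metrics_report(ph$labels$data, ph$labels$data)
  expect_equal(rep0$dsc, rep(1, 3))
  expect_equal(rep0$hd95, rep(0, 3))
  # tumor-free ground truth vs tumor-free prediction: empty-mask convention
  z <- array(0L, c(8, 8, 8))
  repz <- metrics_report(z, z)
  expect_equal(repz$dsc, rep(1, 3))
  expect_true(all(is.na(repz$hd95)))
})
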