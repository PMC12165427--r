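# Minimal reverse-mode automatic differentiation on a linear tape.
#
# Feature maps are dense N x C matrices (voxels x channels) carrying a "sp"
# attribute with the 3D grid shape; row n is the column-major linear index
# of the grid, so each channel is a contiguous column — the layout the
# compiled im2col/resize kernels and BLAS favor. Channel statistics (pooled
# vectors) are plain numeric vectors. A node is an environment holding the
# forward value, the accumulated gradient, its parents, and a backward
# closure that maps the node's gradient to a list of parent gradients.

# grad = FALSE marks an inference-only tape: backward closures then
# recompute any large intermediate buffers instead of retaining them.
ad_tape <- function(grad = TRUE) {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp$n <- 0L
  tp$grad <- isTRUE(grad)
  tp
}

ad_node <- function(tape, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  if (tape$grad) {
    # the backward closure captures its defining environment (all op
    # locals); on an inference tape it is dropped immediately so those
    # buffers can be collected
    nd$parents <- parents
    nd$backward <- backward
    tape$n <- tape$n + 1L
    nd$id <- tape$n
    tape$nodes[[tape$n]] <- nd
  } else {
    # inference: the tape keeps no registry, so intermediate activations
    # die as soon as the network graph stops referencing them
    nd$parents <- list()
    nd$backward <- NULL
    nd$id <- NA_integer_
  }
  nd
}

# Leaf holding a trainable parameter (or a constant whose gradient the
# caller simply never reads).
ad_leaf <- function(tape, value) ad_node(tape, value)

ad_accumulate <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(node)
}

# Reverse sweep from `root` (gradient seeded with 1 for scalars).
ad_backward <- function(tape, root, seed = 1) {
  for (nd in tape$nodes) nd$grad <- NULL
  root$grad <- seed
  for (i in seq(root$id, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd$grad)
    for (j in seq_along(nd$parents)) {
      if (!is.null(gs[[j]])) ad_accumulate(nd$parents[[j]], gs[[j]])
    }
  }
  invisible(root)
}

sp_of <- function(v) attr(v, "sp")

fmap <- function(m, sp) {
  attr(m, "sp") <- as.integer(sp)
  m
}

# Broadcast a per-channel vector across the rows of an N x C matrix.
bychan <- function(v, n) rep(v, each = n)

# --- convolution ------------------------------------------------------------

# 3D convolution, kernel k in {1, 3}, "same" padding for stride 1; for
# stride 2 / k 3 the padding of 1 halves even dims. Weight w: C_out x
# (C_in * k^3); bias b: length C_out. The im2col buffer is kept alive in the
# backward closure, trading memory for FLOPs.
ad_conv3 <- function(tape, x, w, b, k = 3L, stride = 1L, dilation = 1L) {
  sp <- sp_of(x$value)
  pad <- as.integer(dilation * (k - 1L) %/% 2L)
  if (k == 1L && stride == 1L) {
    val <- tcrossprod(x$value, w$value)
    val <- fmap(val + bychan(b$value, nrow(val)), sp)
    return(ad_node(tape, val, list(x, w, b), function(g) {
      list(fmap(g %*% w$value, sp), crossprod(g, x$value), colSums(g))
    }))
  }
  col <- cpp_im2col(x$value, sp, k, stride, dilation, pad)
  osp <- (sp + 2L * pad - (dilation * (k - 1L) + 1L)) %/% stride + 1L
  val <- tcrossprod(col, w$value)
  val <- fmap(val + bychan(b$value, nrow(val)), osp)
  C_in <- ncol(x$value)
  if (!tape$grad) col <- NULL  # inference: free the buffer
  ad_node(tape, val, list(x, w, b), function(g) {
    if (is.null(col))
      col <- cpp_im2col(x$value, sp, k, stride, dilation, pad)
    dw <- crossprod(g, col)
    dx <- cpp_col2im(g %*% w$value, sp, C_in, k, stride, dilation, pad)
    list(fmap(dx, sp), dw, colSums(g))
  })
}

# --- normalization / activations -------------------------------------------

# Instance normalization: per-channel (column) statistics over all voxels,
# learned per-channel gain/shift.
ad_instance_norm <- function(tape, x, gamma, beta, eps = 1e-5) {
  v <- x$value
  sp <- sp_of(v)
  n <- nrow(v)
  mu <- colMeans(v)
  xc <- v - bychan(mu, n)
  va <- colMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xhat <- xc * bychan(istd, n)
  val <- fmap(xhat * bychan(gamma$value, n) + bychan(beta$value, n), sp)
  ad_node(tape, val, list(x, gamma, beta), function(g) {
    dxhat <- g * bychan(gamma$value, n)
    # per-column: dx = istd (dxhat - mean(dxhat) - xhat mean(dxhat xhat))
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * xhat)
    dx <- bychan(istd, n) * (dxhat - bychan(m1, n) - xhat * bychan(m2, n))
    list(fmap(dx, sp), colSums(g * xhat), colSums(g))
  })
}

ad_leaky_relu <- function(tape, x, slope = 0.01) {
  v <- x$value
  fac <- slope + (1 - slope) * (v > 0)
  val <- v * fac
  attributes(val) <- attributes(v)
  ad_node(tape, val, list(x), function(g) {
    dg <- g * fac
    attributes(dg) <- attributes(v)
    list(dg)
  })
}

ad_relu <- function(tape, x) {
  v <- x$value
  val <- pmax(v, 0)
  attributes(val) <- attributes(v)
  ad_node(tape, val, list(x), function(g) {
    dg <- g * (v > 0)
    attributes(dg) <- attributes(v)
    list(dg)
  })
}

ad_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  attributes(s) <- attributes(x$value)
  ad_node(tape, s, list(x), function(g) list(g * s * (1 - s)))
}

ad_add <- function(tape, a, b) {
  ad_node(tape, a$value + b$value, list(a, b), function(g) list(g, g))
}

# Multiply each channel (column) of feature map x by scale[c].
ad_scale_channels <- function(tape, x, scale) {
  v <- x$value
  n <- nrow(v)
  val <- v * bychan(scale$value, n)
  attributes(val) <- attributes(v)
  ad_node(tape, val, list(x, scale), function(g) {
    dx <- g * bychan(scale$value, n)
    attributes(dx) <- attributes(v)
    list(dx, colSums(g * v))
  })
}

ad_concat_channels <- function(tape, xs) {
  sp <- sp_of(xs[[1]]$value)
  cols <- vapply(xs, function(x) ncol(x$value), integer(1))
  val <- fmap(do.call(cbind, lapply(xs, function(x) x$value)), sp)
  ad_node(tape, val, xs, function(g) {
    out <- vector("list", length(xs))
    at <- 0L
    for (i in seq_along(xs)) {
      out[[i]] <- fmap(g[, at + seq_len(cols[i]), drop = FALSE], sp)
      at <- at + cols[i]
    }
    out
  })
}

# Global average pooling: N x C -> length-C vector.
ad_gap <- function(tape, x) {
  n <- nrow(x$value)
  sp <- sp_of(x$value)
  C <- ncol(x$value)
  ad_node(tape, colMeans(x$value), list(x), function(g) {
    list(fmap(matrix(bychan(g / n, n), nrow = n, ncol = C), sp))
  })
}

# Broadcast a length-C vector to a constant N x C feature map.
ad_broadcast <- function(tape, x, sp) {
  n <- prod(sp)
  C <- length(x$value)
  val <- fmap(matrix(bychan(x$value, n), nrow = n, ncol = C), sp)
  ad_node(tape, val, list(x), function(g) list(colSums(g)))
}

# Fully connected layer on a channel-statistics vector.
ad_fc <- function(tape, x, w, b) {
  val <- as.vector(w$value %*% x$value + b$value)
  ad_node(tape, val, list(x, w, b), function(g) {
    list(as.vector(crossprod(w$value, g)), outer(g, x$value), g)
  })
}

# Trilinear resize of a feature map to a new grid shape.
ad_resize <- function(tape, x, osp) {
  sp <- sp_of(x$value)
  osp <- as.integer(osp)
  if (identical(sp, osp)) return(x)
  val <- fmap(cpp_resize3(x$value, sp, osp), osp)
  ad_node(tape, val, list(x), function(g) {
    list(fmap(cpp_resize3_adj(g, sp, osp), sp))
  })
}

# Dropout with a caller-supplied 0/1 mask (so seeding stays explicit).
ad_dropout <- function(tape, x, rate, mask = NULL) {
  if (rate <= 0 || is.null(mask)) return(x)
  keep <- mask / (1 - rate)
  v <- x$value
  val <- v * keep
  attributes(val) <- attributes(v)
  ad_node(tape, val, list(x), function(g) {
    dg <- g * keep
    attributes(dg) <- attributes(v)
    list(dg)
  })
}

# Per-voxel softmax over classes (columns) of an N x B logit matrix.
ad_softmax_classes <- function(tape, x) {
  v <- x$value
  sp <- sp_of(v)
  B <- ncol(v)
  mx <- v[, 1]
  for (j in seq_len(B)[-1]) mx <- pmax(mx, v[, j])
  e <- exp(v - mx)
  p <- e / rowSums(e)
  p <- fmap(p, sp)
  ad_node(tape, p, list(x), function(g) {
    dots <- rowSums(g * p)
    dz <- p * (g - dots)
    attributes(dz) <- attributes(p)
    list(dz)
  })
}
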