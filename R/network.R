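# Improved 3D U-Net: residual encoder with strided downsampling, ASPP
# bottleneck, channel-attention fusion blocks (MFAB) on the skip
# connections, trilinear-upsampling decoder, and deep supervision heads
# summed at full resolution.
#
# Feature maps flow through the autodiff tape as C x N matrices; the public
# API speaks 4D arrays (x, y, z, channel).

#' Network configuration
#'
#' @param in_channels Input channels (4 MRI modalities).
#' @param num_classes Output classes including background (4).
#' @param base_channels Channels at full resolution; doubled per
#'   downsampling. 16 is a desk-scale default, 32 for full runs.
#' @param depth Number of 2x downsamplings (default 4: bottleneck 16x
#'   smaller per axis than the input).
#' @param aspp_rates Dilation rates of the parallel atrous branches.
#' @param dropout_rate Dropout after each downsampling, in [0, 1).
#' @param negative_slope Leaky ReLU slope.
#' @param se_reduction Bottleneck reduction ratio r of the attention FCs.
#' @param attention_bypass Force all channel-attention scales to 1
#'   (diagnostic bypass; the block reduces to its convolutional pathway).
#' @export
network_config <- function(in_channels = 4L, num_classes = 4L,
                           base_channels = 16L, depth = 4L,
                           aspp_rates = c(6L, 12L, 18L), dropout_rate = 0,
                           negative_slope = 0.01, se_reduction = 4L,
                           attention_bypass = FALSE) {
  stopifnot(num_classes >= 2L, depth >= 1L, base_channels >= 4L,
            dropout_rate >= 0, dropout_rate < 1, negative_slope >= 0)
  if (!length(aspp_rates))
    stop("invalid spec: aspp_rates must be non-empty", call. = FALSE)
  structure(list(in_channels = as.integer(in_channels),
                 num_classes = as.integer(num_classes),
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth),
                 aspp_rates = as.integer(aspp_rates),
                 dropout_rate = dropout_rate,
                 negative_slope = negative_slope,
                 se_reduction = as.integer(se_reduction),
                 attention_bypass = isTRUE(attention_bypass)),
            class = "network_config")
}

level_channels <- function(cfg) cfg$base_channels * 2L^(0:cfg$depth)

he_init <- function(nout, fan_in, slope = 0.01) {
  sd <- sqrt(2 / (fan_in * (1 + slope^2)))
  matrix(stats::rnorm(nout * fan_in, sd = sd), nrow = nout, ncol = fan_in)
}

new_conv <- function(P, name, cin, cout, k, slope) {
  P[[paste0(name, ".w")]] <- he_init(cout, cin * k^3, slope)
  P[[paste0(name, ".b")]] <- numeric(cout)
  P
}

new_in <- function(P, name, c) {
  P[[paste0(name, ".g")]] <- rep(1, c)
  P[[paste0(name, ".s")]] <- numeric(c)
  P
}

new_fc <- function(P, name, cin, cout) {
  P[[paste0(name, ".w")]] <- he_init(cout, cin, 0)
  P[[paste0(name, ".b")]] <- numeric(cout)
  P
}

new_resblock <- function(P, name, cin, cout, slope) {
  P <- new_conv(P, paste0(name, ".c1"), cin, cout, 3L, slope)
  P <- new_in(P, paste0(name, ".n1"), cout)
  P <- new_conv(P, paste0(name, ".c2"), cout, cout, 3L, slope)
  P <- new_in(P, paste0(name, ".n2"), cout)
  if (cin != cout) {
    P <- new_conv(P, paste0(name, ".sc"), cin, cout, 1L, slope)
    P <- new_in(P, paste0(name, ".sn"), cout)
  }
  P
}

#' Initialize network parameters
#'
#' He-style normal initialization scaled for Leaky ReLU; instance-norm gains
#' 1, shifts 0.
#'
#' @param cfg A [network_config()].
#' @param seed Integer seed.
#' @return Named list of parameter arrays.
#' @export
init_network_params <- function(cfg, seed = 0L) {
  with_seed(seed, {
    sl <- cfg$negative_slope
    ch <- level_channels(cfg)
    P <- list()
    P <- new_resblock(P, "enc0", cfg$in_channels, ch[1], sl)
    for (l in seq_len(cfg$depth)) {
      P <- new_conv(P, sprintf("down%d.c", l), ch[l], ch[l + 1], 3L, sl)
      P <- new_in(P, sprintf("down%d.n", l), ch[l + 1])
      P <- new_resblock(P, sprintf("enc%d", l), ch[l + 1], ch[l + 1], sl)
    }
    cb <- max(ch[cfg$depth + 1] %/% 4L, 4L)
    P <- new_conv(P, "aspp.b0", ch[cfg$depth + 1], cb, 1L, sl)
    P <- new_in(P, "aspp.n0", cb)
    for (i in seq_along(cfg$aspp_rates)) {
      P <- new_conv(P, sprintf("aspp.b%d", i), ch[cfg$depth + 1], cb, 3L, sl)
      P <- new_in(P, sprintf("aspp.n%d", i), cb)
    }
    P <- new_fc(P, "aspp.gap", ch[cfg$depth + 1], cb)
    P <- new_conv(P, "aspp.proj", cb * (2L + length(cfg$aspp_rates)),
                  ch[cfg$depth + 1], 1L, sl)
    P <- new_in(P, "aspp.pn", ch[cfg$depth + 1])
    for (l in seq_len(cfg$depth)) {
      lo <- ch[l]
      hi <- ch[l + 1]
      r <- max(lo %/% cfg$se_reduction, 2L)
      pre <- sprintf("mfab%d", l)
      P <- new_conv(P, paste0(pre, ".c1"), hi, lo, 1L, sl)
      P <- new_in(P, paste0(pre, ".n1"), lo)
      P <- new_conv(P, paste0(pre, ".c3"), lo, lo, 3L, sl)
      P <- new_in(P, paste0(pre, ".n3"), lo)
      P <- new_fc(P, paste0(pre, ".fl1"), lo, r)
      P <- new_fc(P, paste0(pre, ".fl2"), r, lo)
      P <- new_fc(P, paste0(pre, ".fh1"), lo, r)
      P <- new_fc(P, paste0(pre, ".fh2"), r, lo)
      P <- new_conv(P, paste0(pre, ".p1"), lo, lo, 3L, sl)
      P <- new_in(P, paste0(pre, ".pn1"), lo)
      P <- new_conv(P, paste0(pre, ".p2"), lo, lo, 3L, sl)
      P <- new_in(P, paste0(pre, ".pn2"), lo)
    }
    for (l in 0:(cfg$depth - 1L))
      P <- new_conv(P, sprintf("head%d", l), ch[l + 1], cfg$num_classes, 1L,
                    sl)
    P
  })
}

pnode <- function(pn, name) {
  nd <- pn[[name]]
  if (is.null(nd)) stop("unknown parameter: ", name, call. = FALSE)
  nd
}

conv_in_act <- function(tape, pn, name_c, name_n, x, k, cfg, stride = 1L,
                        dilation = 1L) {
  h <- ad_conv3(tape, x, pnode(pn, paste0(name_c, ".w")),
                pnode(pn, paste0(name_c, ".b")), k, stride, dilation)
  h <- ad_instance_norm(tape, h, pnode(pn, paste0(name_n, ".g")),
                        pnode(pn, paste0(name_n, ".s")))
  ad_leaky_relu(tape, h, cfg$negative_slope)
}

resblock_forward <- function(tape, pn, name, x, cfg) {
  h <- conv_in_act(tape, pn, paste0(name, ".c1"), paste0(name, ".n1"), x, 3L,
                   cfg)
  h <- ad_conv3(tape, h, pnode(pn, paste0(name, ".c2.w")),
                pnode(pn, paste0(name, ".c2.b")), 3L)
  h <- ad_instance_norm(tape, h, pnode(pn, paste0(name, ".n2.g")),
                        pnode(pn, paste0(name, ".n2.s")))
  sc <- if (!is.null(pn[[paste0(name, ".sc.w")]])) {
    s <- ad_conv3(tape, x, pnode(pn, paste0(name, ".sc.w")),
                  pnode(pn, paste0(name, ".sc.b")), 1L)
    ad_instance_norm(tape, s, pnode(pn, paste0(name, ".sn.g")),
                     pnode(pn, paste0(name, ".sn.s")))
  } else x
  ad_leaky_relu(tape, ad_add(tape, h, sc), cfg$negative_slope)
}

downsample_forward <- function(tape, pn, l, x, cfg, mask = NULL) {
  sp <- sp_of(x$value)
  odd <- which(sp %% 2L != 0L)
  if (length(odd))
    stop("invalid shape: axis ", odd[1], " has odd extent ", sp[odd[1]],
         " and cannot be halved", call. = FALSE)
  h <- conv_in_act(tape, pn, sprintf("down%d.c", l), sprintf("down%d.n", l),
                   x, 3L, cfg, stride = 2L)
  ad_dropout(tape, h, cfg$dropout_rate, mask)
}

aspp_forward <- function(tape, pn, x, cfg) {
  sp <- sp_of(x$value)
  branches <- list(conv_in_act(tape, pn, "aspp.b0", "aspp.n0", x, 1L, cfg))
  for (i in seq_along(cfg$aspp_rates))
    branches[[i + 1L]] <- conv_in_act(tape, pn, sprintf("aspp.b%d", i),
                                      sprintf("aspp.n%d", i), x, 3L, cfg,
                                      dilation = cfg$aspp_rates[i])
  g <- ad_gap(tape, x)
  g <- ad_fc(tape, g, pnode(pn, "aspp.gap.w"), pnode(pn, "aspp.gap.b"))
  g <- ad_leaky_relu(tape, g, cfg$negative_slope)
  branches[[length(branches) + 1L]] <- ad_broadcast(tape, g, sp)
  cat <- ad_concat_channels(tape, branches)
  conv_in_act(tape, pn, "aspp.proj", "aspp.pn", cat, 1L, cfg)
}

# Channel-attention fusion of a skip (low-level) map with the upsampled
# decoder (high-level) map. `x_high` must already be resized to the skip
# grid; its channels are halved by the 1x1-then-3x3 alignment transform.
mfab_forward <- function(tape, pn, l, x_low, x_high, cfg) {
  pre <- sprintf("mfab%d", l)
  xh <- conv_in_act(tape, pn, paste0(pre, ".c1"), paste0(pre, ".n1"), x_high,
                    1L, cfg)
  xh <- conv_in_act(tape, pn, paste0(pre, ".c3"), paste0(pre, ".n3"), xh, 3L,
                    cfg)
  if (ncol(xh$value) != ncol(x_low$value))
    stop("invalid shape: channel mismatch after alignment", call. = FALSE)
  merged <- if (cfg$attention_bypass) {
    ad_add(tape, x_low, xh)
  } else {
    s1 <- ad_gap(tape, x_low)
    s2 <- ad_gap(tape, xh)
    z1 <- ad_fc(tape, ad_relu(tape, ad_fc(tape, s1,
                                          pnode(pn, paste0(pre, ".fl1.w")),
                                          pnode(pn, paste0(pre, ".fl1.b")))),
                pnode(pn, paste0(pre, ".fl2.w")),
                pnode(pn, paste0(pre, ".fl2.b")))
    z2 <- ad_fc(tape, ad_relu(tape, ad_fc(tape, s2,
                                          pnode(pn, paste0(pre, ".fh1.w")),
                                          pnode(pn, paste0(pre, ".fh1.b")))),
                pnode(pn, paste0(pre, ".fh2.w")),
                pnode(pn, paste0(pre, ".fh2.b")))
    beta <- ad_sigmoid(tape, ad_add(tape, z1, z2))
    ad_add(tape, ad_scale_channels(tape, x_low, beta), xh)
  }
  h <- conv_in_act(tape, pn, paste0(pre, ".p1"), paste0(pre, ".pn1"), merged,
                   3L, cfg)
  conv_in_act(tape, pn, paste0(pre, ".p2"), paste0(pre, ".pn2"), h, 3L, cfg)
}

# Full forward pass on the tape. Returns list(prob = softmax node,
# logits = summed deep-supervision node, nodes = param nodes).
network_forward <- function(tape, pn, x, cfg, training = FALSE,
                            dropout_masks = NULL) {
  enc <- vector("list", cfg$depth + 1L)
  h <- resblock_forward(tape, pn, "enc0", x, cfg)
  enc[[1]] <- h
  for (l in seq_len(cfg$depth)) {
    mk <- if (training && cfg$dropout_rate > 0) dropout_masks[[l]] else NULL
    h <- downsample_forward(tape, pn, l, h, cfg, mk)
    h <- resblock_forward(tape, pn, sprintf("enc%d", l), h, cfg)
    enc[[l + 1]] <- h
  }
  h <- aspp_forward(tape, pn, h, cfg)
  dec <- vector("list", cfg$depth)
  for (l in rev(seq_len(cfg$depth))) {
    up <- ad_resize(tape, h, sp_of(enc[[l]]$value))
    h <- mfab_forward(tape, pn, l, enc[[l]], up, cfg)
    dec[[l]] <- h
  }
  full_sp <- sp_of(x$value)
  logits <- NULL
  for (l in seq_len(cfg$depth)) {  # dec[[1]] is full resolution
    hd <- ad_conv3(tape, dec[[l]],
                   pnode(pn, sprintf("head%d.w", l - 1L)),
                   pnode(pn, sprintf("head%d.b", l - 1L)), 1L)
    hd <- ad_resize(tape, hd, full_sp)
    logits <- if (is.null(logits)) hd else ad_add(tape, logits, hd)
  }
  list(prob = ad_softmax_classes(tape, logits), logits = logits)
}

as_input_matrix <- function(vol, cfg) {
  a <- if (inherits(vol, "multimodal_volume")) vol$data else vol
  d <- dim(a)
  if (length(d) != 4L || d[4] != cfg$in_channels)
    stop("invalid input: expected (x, y, z, ", cfg$in_channels, ") array",
         call. = FALSE)
  bad <- which(d[1:3] %% 2L^cfg$depth != 0L)
  if (length(bad))
    stop("invalid shape: axis ", bad[1], " extent ", d[bad[1]],
         " not divisible by 2^depth = ", 2L^cfg$depth, call. = FALSE)
  fmap(matrix(a, ncol = d[4]), d[1:3])
}

#' Forward pass: multimodal volume to per-class probabilities
#'
#' @param vol `multimodal_volume` or 4D array (x, y, z, 4), intensities
#'   normalized to [0, 1]; spatial dims divisible by `2^depth`.
#' @param params Parameter list from [init_network_params()] (or a trained
#'   checkpoint).
#' @param cfg A [network_config()].
#' @return 4D array (x, y, z, class) of probabilities summing to 1 per
#'   voxel; classes ordered as internal indices 0:3 (BraTS 0, 1, 2, 4).
#' @export
model_forward <- function(vol, params, cfg = network_config()) {
  tape <- ad_tape(grad = FALSE)
  pn <- lapply(params, function(v) ad_leaf(tape, v))
  x <- ad_leaf(tape, as_input_matrix(vol, cfg))
  out <- network_forward(tape, pn, x, cfg, training = FALSE)
  p <- out$prob$value
  array(p, c(sp_of(p), cfg$num_classes))
}

#' Segment a volume: forward pass, argmax, remap to BraTS labels
#'
#' @inheritParams model_forward
#' @param spacing Spacing recorded in the returned label volume.
#' @return A `label_volume` over \{0, 1, 2, 4\}.
#' @export
predict_labels <- function(vol, params, cfg = network_config(),
                           spacing = NULL) {
  if (is.null(spacing))
    spacing <- if (inherits(vol, "multimodal_volume")) vol$spacing else
      c(1, 1, 1)
  p <- model_forward(vol, params, cfg)
  d <- dim(p)
  cls <- max.col(matrix(p, ncol = d[4])) - 1L  # internal 0..B-1
  lab <- array(cls, d[1:3])
  label_volume(remap_labels(lab, "to_brats"), spacing)
}

#' Save a trained model checkpoint
#'
#' Single-file serialized weights + configuration + label remap table.
#' @param path Output file.
#' @param params Parameter list.
#' @param cfg The `network_config`.
#' @param extra Optional metadata list (seeds, training trace, ...).
#' @export
save_checkpoint <- function(path, params, cfg, extra = list()) {
  obj <- list(format = "glioseg3d-checkpoint-1", params = params, cfg = cfg,
              label_map = data.frame(internal = 0:3,
                                     brats = c(0L, 1L, 2L, 4L)),
              extra = extra)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#' @param path Checkpoint file.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "glioseg3d-checkpoint-1"))
    stop("not a glioseg3d checkpoint: ", path, call. = FALSE)
  obj
}
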