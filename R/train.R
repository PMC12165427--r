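# Optimization: Adam with decoupled-from-nothing L2 weight decay (the decay
# is added to the gradient, the usual Adam weight_decay), seeded data split,
# per-epoch tracing, checkpointing, and case evaluation.

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param weight_decay L2 weight decay added to gradients (default 1e-4).
#' @param steps Number of Adam updates (batch size 1; cases are cycled).
#' @param split_fraction Training fraction of the train/validation split.
#' @param seed Seed controlling initialization and ordering.
#' @param checkpoint_dir Directory for checkpoints (optional).
#' @export
train_config <- function(learning_rate = 1e-3, weight_decay = 1e-4,
                         steps = 200L, split_fraction = 0.8, seed = 0L,
                         checkpoint_dir = NULL) {
  stopifnot(learning_rate > 0, weight_decay >= 0, steps >= 1,
            split_fraction > 0, split_fraction < 1)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 steps = as.integer(steps), split_fraction = split_fraction,
                 seed = as.integer(seed), checkpoint_dir = checkpoint_dir),
            class = "train_config")
}

#' Deterministic seeded train/validation split
#'
#' @param cases List (or character vector of ids); >= 2 elements.
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with `train` and `val` (disjoint, exhaustive).
#' @export
split_dataset <- function(cases, fraction = 0.8, seed = 0L) {
  n <- length(cases)
  if (n < 2L) stop("need at least 2 cases to split", call. = FALSE)
  ntr <- round(fraction * n)
  if (ntr < 1L || ntr >= n)
    stop("invalid spec: fraction ", fraction, " yields an empty partition",
         call. = FALSE)
  perm <- with_seed(seed, sample.int(n))
  list(train = cases[sort(perm[seq_len(ntr)])],
       val = cases[sort(perm[-seq_len(ntr)])])
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Normalize a case and build network input + one-hot target.
prepare_case <- function(case, cfg) {
  mask <- brain_mask_from(case$volume)
  nv <- normalize_volume(case$volume, mask)
  list(x = as_input_matrix(nv$data, cfg),
       g = t(onehot_labels(case$labels$data)),  # N x B, tape layout
       labels = case$labels$data)
}

# One training step: forward, loss, backward, gradient collection.
loss_and_grads <- function(params, xg, net_cfg, loss_cfg, training = TRUE,
                           dropout_masks = NULL) {
  tape <- ad_tape()
  pn <- lapply(params, function(v) ad_leaf(tape, v))
  x <- ad_leaf(tape, xg$x)
  out <- network_forward(tape, pn, x, net_cfg, training, dropout_masks)
  loss <- ad_dice_focal(tape, out$prob, xg$g, loss_cfg)
  ad_backward(tape, loss)
  list(loss = loss$value, grads = lapply(pn, function(nd) nd$grad))
}

#' Train the segmentation network on a set of cases
#'
#' Adam, batch size 1, cases cycled in seeded order. Fully reproducible for
#' a given configuration and seed (dropout off by default).
#'
#' @param cases List of cases (`volume` + `labels`), e.g. from
#'   [phantom_cases()] or [read_case()].
#' @param net_cfg A [network_config()].
#' @param loss_cfg A [loss_config()].
#' @param train_cfg A [train_config()].
#' @param val_cases Optional held-out cases evaluated once per epoch.
#' @param verbose Print per-epoch progress.
#' @return List: `params` (trained weights), `trace` (data.frame with step,
#'   epoch, loss), `val_trace` (per-epoch validation loss and WT DSC, or
#'   NULL), `initial_loss`, `final_loss`.
#' @export
train_network <- function(cases, net_cfg = network_config(),
                          loss_cfg = loss_config(),
                          train_cfg = train_config(), val_cases = NULL,
                          verbose = FALSE) {
  stopifnot(length(cases) >= 1)
  params <- init_network_params(net_cfg, train_cfg$seed)
  state <- adam_init(params)
  prep <- lapply(cases, prepare_case, cfg = net_cfg)
  prep_val <- if (!is.null(val_cases))
    lapply(val_cases, prepare_case, cfg = net_cfg)
  n <- length(prep)
  order_seed <- train_cfg$seed + 1L
  losses <- numeric(train_cfg$steps)
  epochs <- integer(train_cfg$steps)
  val_rows <- list()
  ord <- integer(0)
  epoch <- 0L
  set.seed(order_seed)
  for (step in seq_len(train_cfg$steps)) {
    if (!length(ord)) {
      ord <- sample.int(n)
      epoch <- epoch + 1L
    }
    i <- ord[1]
    ord <- ord[-1]
    masks <- NULL
    if (net_cfg$dropout_rate > 0)
      masks <- lapply(seq_len(net_cfg$depth), function(l) NULL)
    lg <- loss_and_grads(params, prep[[i]], net_cfg, loss_cfg,
                         training = TRUE, dropout_masks = masks)
    if (!is.finite(lg$loss))
      stop("non-finite training loss at step ", step, " (epoch ", epoch,
           ")", call. = FALSE)
    up <- adam_step(params, lg$grads, state, train_cfg$learning_rate,
                    train_cfg$weight_decay)
    params <- up$params
    state <- up$state
    losses[step] <- lg$loss
    epochs[step] <- epoch
    end_of_epoch <- !length(ord)
    if (end_of_epoch && !is.null(prep_val)) {
      vl <- vapply(prep_val, function(xg) {
        tape <- ad_tape(grad = FALSE)
        pn <- lapply(params, function(v) ad_leaf(tape, v))
        out <- network_forward(tape, pn, ad_leaf(tape, xg$x), net_cfg)
        combined_loss(t(out$prob$value), t(xg$g), loss_cfg)
      }, numeric(1))
      vd <- vapply(seq_along(prep_val), function(j) {
        pred <- predict_labels(array(prep_val[[j]]$x,
                                     c(sp_of(prep_val[[j]]$x),
                                       net_cfg$in_channels)),
                               params, net_cfg)
        dsc(region_masks(val_cases[[j]]$labels$data)$wt,
            region_masks(pred$data)$wt)
      }, numeric(1))
      val_rows[[length(val_rows) + 1L]] <-
        data.frame(epoch = epoch, val_loss = mean(vl), val_wt_dsc = mean(vd))
    }
    if (verbose && (end_of_epoch || step == train_cfg$steps))
      message(sprintf("epoch %d step %d loss %.4f", epoch, step, lg$loss))
  }
  res <- list(params = params,
              trace = data.frame(step = seq_len(train_cfg$steps),
                                 epoch = epochs, loss = losses),
              val_trace = if (length(val_rows)) do.call(rbind, val_rows),
              initial_loss = losses[1], final_loss = losses[train_cfg$steps])
  if (!is.null(train_cfg$checkpoint_dir)) {
    dir.create(train_cfg$checkpoint_dir, showWarnings = FALSE,
               recursive = TRUE)
    ckpt <- file.path(train_cfg$checkpoint_dir, "checkpoint.rds")
    save_checkpoint(ckpt, params, net_cfg,
                    extra = list(train_cfg = train_cfg,
                                 final_loss = res$final_loss))
    res$checkpoint <- ckpt
  }
  res
}

#' Evaluate trained weights on labelled cases
#'
#' Runs the forward pass, argmax + label remap, and the full per-region
#' metrics report for every case; aggregates by mean.
#'
#' @param params Trained parameter list (or a checkpoint's `$params`).
#' @param net_cfg The matching [network_config()].
#' @param cases Labelled cases.
#' @return List: `per_case` (data.frame with case index + region metrics),
#'   `aggregate` (mean of each metric by region).
#' @export
evaluate_cases <- function(params, net_cfg, cases) {
  rows <- lapply(seq_along(cases), function(i) {
    xg <- prepare_case(cases[[i]], net_cfg)
    vol <- array(xg$x, c(sp_of(xg$x), net_cfg$in_channels))
    pred <- predict_labels(vol, params, net_cfg,
                           spacing = cases[[i]]$labels$spacing)
    rep <- metrics_report(cases[[i]]$labels$data, pred$data,
                          spacing = cases[[i]]$labels$spacing)
    cbind(case = i, rep)
  })
  per_case <- do.call(rbind, rows)
  agg <- stats::aggregate(per_case[c("dsc", "recall", "precision", "iou",
                                     "hd95")],
                          by = list(region = per_case$region), mean,
                          na.rm = TRUE)
  list(per_case = per_case, aggregate = agg)
}
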