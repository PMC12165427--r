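# Compound segmentation objective: Tversky-form soft-Dice plus Focal term.
#
# Probabilities and one-hot labels are handled as B x N matrices (classes x
# voxels); 4D arrays with the class on the last margin are accepted and
# flattened. The Dice part is
#   L_dice = B - sum_b TP_b / (TP_b + alpha FN_b + beta FP_b + eps)
# with soft counts TP = sum p g, FN = sum (1-p) g, FP = sum p (1-g), and the
# Focal part is  -(lambda/N) sum_b sum_n g (1-p)^2 log(p), which is >= 0.
# alpha = beta = 0.5 reduces the Tversky form to standard soft Dice.

#' Loss configuration
#'
#' @param alpha False-negative weight of the Tversky denominator (>= 0).
#' @param beta False-positive weight of the Tversky denominator (>= 0).
#' @param lambda Weight of the Focal term (>= 0).
#' @param eps Denominator guard.
#' @param log_base Base of the Focal logarithm, `"natural"` or `"10"`.
#' @return A `loss_config` list.
#' @export
loss_config <- function(alpha = 0.5, beta = 0.5, lambda = 1,
                        eps = 1e-6, log_base = c("natural", "10")) {
  log_base <- match.arg(log_base)
  stopifnot(alpha >= 0, beta >= 0, lambda >= 0, eps > 0)
  if (alpha + beta <= 0) stop("alpha + beta must be positive", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, lambda = lambda, eps = eps,
                 log_base = log_base), class = "loss_config")
}

as_class_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  d <- dim(x)
  if (is.null(d) || length(d) != 4L)
    stop("expected a B x N matrix or a 4D array with classes last",
         call. = FALSE)
  t(matrix(x, nrow = prod(d[1:3]), ncol = d[4]))
}

#' One-hot encode a label volume
#'
#' @param labels Integer array/vector of labels.
#' @param classes Class values in channel order (default BraTS `c(0,1,2,4)`).
#' @return B x N binary matrix, rows ordered as `classes`.
#' @export
onehot_labels <- function(labels, classes = c(0L, 1L, 2L, 4L)) {
  lv <- as.vector(labels)
  bad <- setdiff(unique(lv), classes)
  if (length(bad))
    stop("labels outside the class set: ", paste(sort(bad), collapse = ", "),
         call. = FALSE)
  out <- matrix(0, nrow = length(classes), ncol = length(lv))
  for (i in seq_along(classes)) out[i, lv == classes[i]] <- 1
  out
}

check_probs <- function(p, tol = 1e-4) {
  if (any(p < -tol) || any(p > 1 + tol))
    stop("probabilities outside [0, 1]", call. = FALSE)
  cs <- colSums(p)
  if (any(abs(cs - 1) > tol))
    stop("per-voxel class probabilities do not sum to 1", call. = FALSE)
  invisible(p)
}

#' Soft true-positive / false-negative / false-positive counts per class
#'
#' @param p Probability matrix/array (classes on rows / last margin).
#' @param g One-hot ground truth of identical layout.
#' @return List with numeric vectors `tp`, `fn`, `fp` (one entry per class).
#' @export
soft_counts <- function(p, g) {
  p <- as_class_matrix(p)
  g <- as_class_matrix(g)
  if (!all(dim(p) == dim(g)))
    stop("probability and label layouts disagree: ",
         paste(dim(p), collapse = "x"), " vs ",
         paste(dim(g), collapse = "x"), call. = FALSE)
  check_probs(p)
  list(tp = rowSums(p * g),
       fn = rowSums((1 - p) * g),
       fp = rowSums(p * (1 - g)))
}

focal_log <- function(p, cfg) {
  lp <- log(pmin(pmax(p, 1e-7), 1 - 1e-7))
  if (cfg$log_base == "10") lp <- lp / log(10) else lp
}

#' Combined Dice(Tversky) + Focal loss
#'
#' @param p Probability matrix/array.
#' @param g One-hot ground truth.
#' @param cfg A [loss_config()].
#' @return Non-negative scalar loss.
#' @export
combined_loss <- function(p, g, cfg = loss_config()) {
  p <- as_class_matrix(p)
  g <- as_class_matrix(g)
  sc <- soft_counts(p, g)
  B <- nrow(p)
  n <- ncol(p)
  dice <- B - sum(sc$tp / (sc$tp + cfg$alpha * sc$fn + cfg$beta * sc$fp +
                             cfg$eps))
  focal <- -cfg$lambda * sum(g * (1 - p)^2 * focal_log(p, cfg)) / n
  dice + focal
}

# Autodiff node: same quantity, with an analytic gradient with respect to p.
# Here p and g follow the tape layout: N x B (voxels x classes).
ad_dice_focal <- function(tape, p, g, cfg = loss_config()) {
  pv <- p$value
  n <- nrow(pv)
  B <- ncol(pv)
  tp <- colSums(pv * g)
  fn <- colSums((1 - pv) * g)
  fp <- colSums(pv * (1 - g))
  den <- tp + cfg$alpha * fn + cfg$beta * fp + cfg$eps
  pc <- pmin(pmax(pv, 1e-7), 1 - 1e-7)
  lp <- log(pc)
  if (cfg$log_base == "10") lp <- lp / log(10)
  lscale <- if (cfg$log_base == "10") log(10) else 1
  val <- (B - sum(tp / den)) - cfg$lambda * sum(g * (1 - pv)^2 * lp) / n
  ad_node(tape, val, list(p), function(g_out) {
    # d/dp of the Dice part, per class b (column-wise broadcasting)
    dden <- g * (1 - cfg$alpha) + cfg$beta * (1 - g)
    ddice <- -(g * bychan(den, n) - bychan(tp, n) * dden) / bychan(den^2, n)
    dfocal <- -cfg$lambda / n *
      (g * ((1 - pv)^2 / (pc * lscale) - 2 * (1 - pv) * lp))
    dp <- (ddice + dfocal) * g_out
    attributes(dp) <- attributes(pv)
    list(dp)
  })
}
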