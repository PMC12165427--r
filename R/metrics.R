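# Segmentation evaluation: overlap metrics and 95th-percentile Hausdorff
# distance over the standard BraTS regions
#   WT (whole tumor)     = labels {1, 2, 4}
#   TC (tumor core)      = labels {1, 4}
#   ET (enhancing tumor) = label {4}

BRATS_LABELS <- c(0L, 1L, 2L, 4L)

check_labels <- function(labels) {
  bad <- setdiff(unique(as.vector(labels)), BRATS_LABELS)
  if (length(bad))
    stop("unknown label values: ", paste(sort(bad), collapse = ", "),
         call. = FALSE)
  invisible(labels)
}

#' Decompose a BraTS label volume into WT/TC/ET region masks
#'
#' @param labels Integer array over \{0, 1, 2, 4\}.
#' @return List of logical arrays `wt`, `tc`, `et` with `et <= tc <= wt`.
#' @export
region_masks <- function(labels) {
  check_labels(labels)
  a <- array(as.integer(labels), dim = dim(labels) %||% length(labels))
  list(wt = a == 1L | a == 2L | a == 4L,
       tc = a == 1L | a == 4L,
       et = a == 4L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_pair <- function(G, O) {
  if (!identical(dim(G) %||% length(G), dim(O) %||% length(O)))
    stop("mask shapes differ", call. = FALSE)
}

#' Dice similarity coefficient 2|G∩O| / (|G|+|O|)
#'
#' Both masks empty scores 1 by convention.
#' @param G,O Logical/0-1 arrays of identical shape.
#' @export
dsc <- function(G, O) {
  check_pair(G, O)
  sg <- sum(G); so <- sum(O)
  if (sg + so == 0) return(1)
  2 * sum(G & O) / (sg + so)
}

#' Recall |G∩O| / |G|
#' @inheritParams dsc
#' @export
recall <- function(G, O) {
  check_pair(G, O)
  sg <- sum(G)
  if (sg == 0) return(if (sum(O) == 0) 1 else 0)
  sum(G & O) / sg
}

#' Precision |G∩O| / |O|
#' @inheritParams dsc
#' @export
precision <- function(G, O) {
  check_pair(G, O)
  so <- sum(O)
  if (so == 0) return(if (sum(G) == 0) 1 else 0)
  sum(G & O) / so
}

#' Jaccard intersection-over-union |G∩O| / |G∪O|
#' @inheritParams dsc
#' @export
iou <- function(G, O) {
  check_pair(G, O)
  u <- sum(G | O)
  if (u == 0) return(1)
  sum(G & O) / u
}

# Boundary voxels of a 3D mask: voxels in the mask with at least one
# 6-connected neighbour outside it (faces of the volume count as outside
# nothing, i.e. border voxels of the mask are boundary if padded by FALSE).
mask_boundary <- function(m) {
  m <- m != 0
  d <- dim(m)
  stopifnot(length(d) == 3L)
  shift <- function(ax, by) {
    out <- array(FALSE, d)
    idx <- lapply(d, seq_len)
    src <- idx
    n <- d[ax]
    if (by == 1L) { idx[[ax]] <- seq_len(n - 1L) + 1L; src[[ax]] <- seq_len(n - 1L) }
    else { idx[[ax]] <- seq_len(n - 1L); src[[ax]] <- seq_len(n - 1L) + 1L }
    out[idx[[1]], idx[[2]], idx[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  interior <- m
  for (ax in 1:3) for (by in c(-1L, 1L)) interior <- interior & shift(ax, by)
  m & !interior
}

#' 95th-percentile symmetric surface distance (HD95)
#'
#' Boundaries are extracted by 6-connectivity erosion difference; distances
#' from every boundary voxel of one mask to the nearest boundary voxel of
#' the other are pooled over both directions and the 95th percentile (linear
#' interpolation) is returned, in physical units.
#'
#' @param G,O Non-empty masks of identical shape.
#' @param spacing Voxel spacing in mm (length 3).
#' @return HD95 in mm.
#' @export
hd95 <- function(G, O, spacing = c(1, 1, 1)) {
  check_pair(G, O)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  if (sum(G) == 0 || sum(O) == 0)
    stop("hd95 is undefined for an empty mask", call. = FALSE)
  bg <- which(mask_boundary(G), arr.ind = TRUE)
  bo <- which(mask_boundary(O), arr.ind = TRUE)
  pg <- sweep(bg, 2, spacing, "*")
  po <- sweep(bo, 2, spacing, "*")
  d <- c(cpp_min_dists(pg, po), cpp_min_dists(po, pg))
  unname(stats::quantile(d, 0.95, type = 7))
}

#' Per-region metrics report for a prediction / ground-truth label pair
#'
#' @param gt,pred Label arrays over \{0, 1, 2, 4\}.
#' @param spacing Voxel spacing (mm) for HD95.
#' @param hd95_sentinel Value reported when HD95 is undefined because a
#'   region is empty in either volume (default `NA`).
#' @return data.frame with one row per region (wt/tc/et): dsc, recall,
#'   precision, iou, hd95, and voxel counts `n_gt`, `n_pred`.
#' @export
metrics_report <- function(gt, pred, spacing = c(1, 1, 1),
                           hd95_sentinel = NA_real_) {
  mg <- region_masks(gt)
  mp <- region_masks(pred)
  rows <- lapply(names(mg), function(rg) {
    G <- mg[[rg]]; O <- mp[[rg]]
    h <- if (sum(G) > 0 && sum(O) > 0) hd95(G, O, spacing) else hd95_sentinel
    data.frame(region = rg, dsc = dsc(G, O), recall = recall(G, O),
               precision = precision(G, O), iou = iou(G, O), hd95 = h,
               n_gt = sum(G), n_pred = sum(O), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
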