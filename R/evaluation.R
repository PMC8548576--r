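# Detection-accuracy metrics (precision, recall, AP at IoU 0.5, the
# precision = recall equilibrium point) and model-lightness metrics
# (trainable parameters, analytic FLOPs, wall-clock FPS).

#' Match detections to ground truth
#'
#' Greedy one-to-one matching in descending confidence: each detection is
#' matched to the unmatched ground-truth box of highest IoU provided that
#' IoU reaches the threshold (a true positive); otherwise it is a false
#' positive. Duplicate detections of an already-matched box are false
#' positives.
#'
#' @param dets Detection data frame (corner boxes + `confidence`).
#' @param gts Ground-truth corner-box data frame (or matrix).
#' @param iou_threshold Match threshold (0.5 by default).
#' @return List: `tp` logical vector over detections (in descending
#'   confidence order), counts `n_tp` / `n_fp`, `matched_gt` (ground-truth
#'   row per detection, NA for false positives), and `order` mapping back
#'   to the input rows.
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5) {
  ord <- order(-dets$confidence)
  n <- length(ord)
  gt <- as.matrix(as.data.frame(gts)[, c("x1", "y1", "x2", "y2")])
  tp <- logical(n)
  matched_gt <- rep(NA_integer_, n)
  used <- logical(nrow(gt))
  if (n && nrow(gt)) {
    bx <- as.matrix(dets[ord, c("x1", "y1", "x2", "y2")])
    ious <- box_iou(bx, gt)
    for (i in seq_len(n)) {
      cand <- which(!used & ious[i, ] >= iou_threshold)
      if (length(cand)) {
        best <- cand[which.max(ious[i, cand])]
        used[best] <- TRUE
        tp[i] <- TRUE
        matched_gt[i] <- best
      }
    }
  }
  list(tp = tp, n_tp = sum(tp), n_fp = sum(!tp), matched_gt = matched_gt,
       order = ord)
}

#' Precision and recall from a confusion count
#'
#' `P = TP / (TP + FP)`, `R = TP / GT`. With no detections at all precision
#' is 1 by convention (and a message notes it).
#'
#' @param tp,fp True/false positive counts.
#' @param gt Number of ground-truth objects (> 0).
#' @return List with `precision` and `recall`.
#' @export
precision_recall <- function(tp, fp, gt) {
  if (gt <= 0) stop("gt must be positive")
  p <- if (tp + fp == 0) {
    message("no detections: precision defined as 1 by convention")
    1
  } else tp / (tp + fp)
  list(precision = p, recall = tp / gt)
}

# Shared sweep: global descending-confidence TP flags across images.
# dets needs image, corner box, confidence; gts needs image + corner box.
pr_sweep <- function(dets, gts, iou_threshold) {
  n_gt <- nrow(gts)
  if (n_gt == 0) stop("no ground truth; metric undefined")
  if (!nrow(dets))
    return(list(conf = numeric(0), tp = logical(0), n_gt = n_gt))
  if (is.null(dets$image)) dets$image <- 0L
  if (is.null(gts$image)) gts$image <- 0L
  ord <- order(-dets$confidence)
  dets <- dets[ord, , drop = FALSE]
  tp <- logical(nrow(dets))
  for (img in unique(dets$image)) {
    di <- which(dets$image == img)
    gi <- gts[gts$image == img, , drop = FALSE]
    if (!nrow(gi)) next
    m <- match_detections(dets[di, , drop = FALSE], gi, iou_threshold)
    tp[di[m$order]] <- m$tp
  }
  list(conf = dets$confidence, tp = tp, n_gt = n_gt)
}

#' Average precision at a fixed IoU threshold
#'
#' Sweeps the detections in descending confidence, forms the
#' precision-recall curve, replaces precision by its right-to-left running
#' maximum (the envelope) and integrates it over recall in `[0, 1]`
#' (all-point interpolation).
#'
#' @param dets Scored detections across images: corner boxes, `confidence`,
#'   and an `image` column when evaluating multiple images.
#' @param gts Ground-truth boxes with matching `image` ids.
#' @param iou_threshold Match threshold.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(dets, gts, iou_threshold = 0.5) {
  s <- pr_sweep(dets, gts, iou_threshold)
  if (!length(s$tp)) return(0)
  ctp <- cumsum(s$tp)
  rec <- ctp / s$n_gt
  prec <- ctp / seq_along(ctp)
  env <- rev(cummax(rev(prec)))
  sum(diff(c(0, rec)) * env)
}

#' Precision-recall equilibrium point
#'
#' Sweeps the confidence threshold over the observed detection scores and
#' returns the threshold minimizing `|P - R|`, ties broken toward the
#' higher confidence.
#'
#' @inheritParams average_precision
#' @return List: `confidence`, `precision`, `recall` at the equilibrium.
#' @export
equilibrium_point <- function(dets, gts, iou_threshold = 0.5) {
  s <- pr_sweep(dets, gts, iou_threshold)
  if (!length(s$tp))
    return(list(confidence = NA_real_, precision = 1, recall = 0))
  ctp <- cumsum(s$tp)
  rec <- ctp / s$n_gt
  prec <- ctp / seq_along(ctp)
  i <- which.min(abs(prec - rec)) # first index = highest confidence on ties
  list(confidence = s$conf[i], precision = prec[i], recall = rec[i])
}

# Shape-mode walk of the full graph; returns profile rows, parameter
# shapes and the FLOP total.
profile_run <- function(cfg, input_size) {
  ctx <- ctx_new(cfg, mode = "shape")
  .lc_prof$active <- TRUE
  .lc_prof$flops <- 0
  on.exit(.lc_prof$active <- FALSE)
  forward_model_graph(ctx, ag_node(lc_shape(c(input_size, input_size, 3L, 1L))))
  list(rows = ctx$rows, pshapes = ctx$pshapes, flops = .lc_prof$flops)
}

#' Architecture profile
#'
#' Walks the network in shape-propagation mode (no arithmetic) and tabulates
#' every block with its filter description and input/output shapes, plus
#' parameter and FLOP totals. For the default configuration at input 416
#' this reproduces the backbone's internal architecture table row by row.
#'
#' @param cfg An [arch_config()] (or a model, whose config is used).
#' @param input_size Input resolution; defaults to the configuration's.
#' @return Data frame of class `lightcsp_profile` with columns `block`,
#'   `filters`, `in_h`, `in_w`, `in_c`, `out_h`, `out_w`, `out_c`;
#'   attributes `total_params` (count) and `total_flops`.
#' @export
profile_model <- function(cfg = arch_config(), input_size = NULL) {
  if (inherits(cfg, "lightcsp_model") || inherits(cfg, "lightcsp_backbone"))
    cfg <- cfg$cfg
  size <- as.integer(input_size %||% cfg$input_size)
  if (size %% 32L != 0L) stop("input_size must be divisible by 32")
  pr <- profile_run(cfg, size)
  df <- do.call(rbind, lapply(pr$rows, function(r)
    data.frame(block = r$block, filters = r$filters,
               in_h = r$in_h, in_w = r$in_w, in_c = r$in_c,
               out_h = r$out_h, out_w = r$out_w, out_c = r$out_c)))
  attr(df, "total_params") <- sum(vapply(pr$pshapes, prod, 0))
  attr(df, "total_flops") <- pr$flops
  attr(df, "param_shapes") <- pr$pshapes
  attr(df, "input_size") <- size
  class(df) <- c("lightcsp_profile", class(df))
  df
}

#' @export
print.lightcsp_profile <- function(x, ...) {
  cat(sprintf("Architecture profile (input %d):\n", attr(x, "input_size")))
  fmt <- function(h, w, c) sprintf("%d x %d x %d", h, w, c)
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-48s %-34s %-16s -> %s\n", x$block[i], x$filters[i],
                fmt(x$in_h[i], x$in_w[i], x$in_c[i]),
                fmt(x$out_h[i], x$out_w[i], x$out_c[i])))
  cat(sprintf("  total: %.2f M params, %.2f GFLOPs\n",
              attr(x, "total_params") / 1e6, attr(x, "total_flops") / 1e9))
  invisible(x)
}

#' Per-module parameter breakdown
#'
#' Groups the trainable-parameter count by architectural module (stem,
#' Light-CSP stages, fusion, heads).
#'
#' @inheritParams profile_model
#' @return Named numeric vector of parameter counts (units, not millions).
#' @export
param_breakdown <- function(cfg = arch_config(), input_size = NULL) {
  if (inherits(cfg, "lightcsp_model")) cfg <- cfg$cfg
  pr <- profile_run(cfg, as.integer(input_size %||% cfg$input_size))
  counts <- vapply(pr$pshapes, prod, 0)
  module <- sub("^(stem[0-9]+|stage[0-9]+|fuse[0-9]+|fpn|head)\\..*$", "\\1",
                names(counts))
  tapply(counts, module, sum)
}

#' Analytic FLOP count
#'
#' Counts floating-point operations for one forward pass at the given input
#' size by walking the graph in shape mode: convolutions cost
#' `2 * k^2 * Cin * Cout * Hout * Wout` (multiply-accumulate counted as two
#' operations), batch norm 2 per element, activations, additions, gates and
#' pooling comparisons 1 per element; resampling is free.
#'
#' @inheritParams profile_model
#' @return FLOPs in units of 1e9 (GFLOPs).
#' @export
count_flops <- function(cfg = arch_config(), input_size = NULL) {
  if (inherits(cfg, "lightcsp_model") || inherits(cfg, "lightcsp_backbone"))
    cfg <- cfg$cfg
  size <- as.integer(input_size %||% cfg$input_size)
  profile_run(cfg, size)$flops / 1e9
}

#' Measured detection throughput
#'
#' Runs the detector over a list of images, excluding `warmup` initial
#' passes from the timing, and reports frames per second `N / t_N`.
#' Hardware-dependent; informational only.
#'
#' @param model A model with anchors.
#' @param images List of `(H, W, 3)` arrays.
#' @param warmup Untimed warm-up passes (repeats of the first image).
#' @param ... Passed to [detect()].
#' @return FPS; attributes `seconds` and `n`.
#' @export
measure_fps <- function(model, images, warmup = 2L, ...) {
  if (!length(images)) stop("need at least one image")
  for (i in seq_len(warmup)) detect(model, images[[1]], ...)
  t0 <- Sys.time()
  for (img in images) detect(model, img, ...)
  dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  fps <- length(images) / dt
  attr(fps, "seconds") <- dt
  attr(fps, "n") <- length(images)
  fps
}

#' Full evaluation of a detector on a labelled dataset
#'
#' Runs detection on every image (at a low confidence floor so the PR sweep
#' is informative), computes AP at the given IoU threshold, the equilibrium
#' point, and precision/recall at the working confidence threshold.
#'
#' @param model Model with anchors.
#' @param samples List of samples, each `list(image =, boxes =)` with
#'   normalized label boxes.
#' @param iou_threshold Match threshold.
#' @param conf_threshold Working threshold for the reported P/R.
#' @param nms_iou NMS threshold.
#' @param input_size Optional inference size override.
#' @return List: `ap`, `precision`, `recall`, `equilibrium`, counts, and
#'   the pooled detection table.
#' @export
evaluate_detector <- function(model, samples, iou_threshold = 0.5,
                              conf_threshold = 0.25, nms_iou = 0.45,
                              input_size = NULL) {
  dets <- list(); gts <- list()
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    d <- detect(model, s$image, conf_threshold = 0.01, nms_iou = nms_iou,
                input_size = input_size)
    if (nrow(d)) { d$image <- i; dets[[length(dets) + 1L]] <- d }
    g <- label_to_corners(s$boxes, dim(s$image)[2], dim(s$image)[1])
    if (nrow(g)) { g$image <- i; gts[[length(gts) + 1L]] <- g }
  }
  dets <- if (length(dets)) do.call(rbind, dets) else
    data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
               y2 = numeric(0), confidence = numeric(0), image = integer(0))
  gts <- do.call(rbind, gts)
  ap <- average_precision(dets, gts, iou_threshold)
  eq <- equilibrium_point(dets, gts, iou_threshold)
  keep <- dets[dets$confidence >= conf_threshold, , drop = FALSE]
  s <- pr_sweep(keep, gts, iou_threshold)
  pr <- precision_recall(sum(s$tp), sum(!s$tp), nrow(gts))
  list(ap = ap, precision = pr$precision, recall = pr$recall,
       equilibrium = eq, n_gt = nrow(gts), n_det = nrow(keep), dets = dets)
}
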