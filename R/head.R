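# Anchor-based detection: k-means anchor clustering under a 1-IoU distance,
# box decoding, target assignment, the training loss, and greedy NMS.

# Pairwise shape IoU between co-centered (w, h) boxes, n x 2 vs m x 2.
shape_iou <- function(wh, cent) {
  iw <- outer(wh[, 1], cent[, 1], pmin)
  ih <- outer(wh[, 2], cent[, 2], pmin)
  inter <- iw * ih
  union <- outer(wh[, 1] * wh[, 2], cent[, 1] * cent[, 2], `+`) - inter
  inter / pmax(union, .Machine$double.eps)
}

#' Intersection-over-union of corner-form boxes
#'
#' Boxes are `(x1, y1, x2, y2)` with `x2 > x1`, `y2 > y1` (half-open pixel
#' convention). Two vectors give a scalar; two matrices (rows = boxes) give
#' the full pairwise IoU matrix. Zero-area boxes have IoU 0 by convention.
#'
#' @param a,b Length-4 vectors or `n x 4` / `m x 4` matrices.
#' @export
#' @examples
#' box_iou(c(0, 0, 2, 2), c(1, 1, 3, 3)) # 1/7
box_iou <- function(a, b) {
  av <- is.null(dim(a)); bv <- is.null(dim(b))
  if (av) a <- matrix(a, 1)
  if (bv) b <- matrix(b, 1)
  x1 <- outer(a[, 1], b[, 1], pmax); y1 <- outer(a[, 2], b[, 2], pmax)
  x2 <- outer(a[, 3], b[, 3], pmin); y2 <- outer(a[, 4], b[, 4], pmin)
  inter <- pmax(x2 - x1, 0) * pmax(y2 - y1, 0)
  aa <- pmax(a[, 3] - a[, 1], 0) * pmax(a[, 4] - a[, 2], 0)
  ab <- pmax(b[, 3] - b[, 1], 0) * pmax(b[, 4] - b[, 2], 0)
  un <- outer(aa, ab, `+`) - inter
  m <- ifelse(un > 0, inter / un, 0)
  if (av && bv) m[1, 1] else m
}

#' K-means anchor clustering under the 1 - IoU distance
#'
#' Clusters annotated box shapes into `k` anchor priors using the
#' co-centered shape-IoU distance `d = 1 - IoU(shape, centroid)`. Iterates
#' assignment and mean update to an assignment fixpoint (at most `max_iter`
#' rounds); assignment ties break toward the lower centroid index and empty
#' clusters are reseeded from the point farthest from its centroid.
#' Centroids are sorted by area and partitioned into consecutive triples,
#' smallest areas first, one triple per detection branch.
#'
#' @param boxes Data frame of normalized boxes with columns `w`, `h`
#'   (a label data frame from [read_label_file()] works directly).
#' @param k Number of anchors (default 9).
#' @param input_size Reference input size in pixels; anchors are expressed
#'   at this scale.
#' @param seed Seed for the initial centroid draws.
#' @param max_iter Assignment-update iteration cap per restart.
#' @param restarts Independent seeded initializations; the run with the
#'   lowest final objective is kept.
#' @return An object of class `lightcsp_anchors`: `anchors` (a `k x 2`
#'   matrix of pixel `(w, h)` pairs sorted by area), `branch_assignment`
#'   (list of index triples, small to large), `input_size`, and the
#'   `objective` trace (mean 1 - IoU after each assignment).
#' @export
cluster_anchors <- function(boxes, k = 9L, input_size = 416L, seed = 1L,
                            max_iter = 300L, restarts = 5L) {
  wh <- cbind(boxes$w, boxes$h) * input_size
  zero <- wh[, 1] <= 0 | wh[, 2] <= 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " zero-area box(es) before clustering")
    wh <- wh[!zero, , drop = FALSE]
  }
  if (nrow(wh) < k)
    stop("need at least k = ", k, " boxes to cluster, got ", nrow(wh))
  uniq <- unique(wh)
  if (nrow(uniq) < k)
    stop("need at least k = ", k, " distinct box shapes, got ", nrow(uniq))

  run_once <- function(s) {
    cent <- local_seed(s, uniq[sample(nrow(uniq), k), , drop = FALSE])
    assign_prev <- rep(0L, nrow(wh))
    objective <- numeric(0)
    for (it in seq_len(max_iter)) {
      siou <- shape_iou(wh, cent)
      asg <- max.col(siou, ties.method = "first")
      objective <- c(objective, mean(1 - siou[cbind(seq_len(nrow(wh)), asg)]))
      if (identical(asg, assign_prev)) break
      assign_prev <- asg
      for (c in seq_len(k)) {
        members <- asg == c
        if (!any(members)) {
          far <- which.min(siou[cbind(seq_len(nrow(wh)), asg)])
          cent[c, ] <- wh[far, ]
          next
        }
        # guarded update: among the member mean, geometric mean and
        # coordinate-wise median, adopt the candidate that most reduces the
        # cluster's mean 1 - IoU, and only if it improves on the current
        # centroid (no candidate is guaranteed to improve a non-Euclidean
        # distance; the guard keeps the objective monotone non-increasing)
        mwh <- wh[members, , drop = FALSE]
        cands <- rbind(colMeans(mwh), exp(colMeans(log(mwh))),
                       apply(mwh, 2, stats::median))
        d_old <- mean(1 - shape_iou(mwh, cent[c, , drop = FALSE]))
        d_new <- rowMeans(1 - t(shape_iou(mwh, cands)))
        j <- which.min(d_new)
        if (d_new[j] <= d_old) cent[c, ] <- cands[j, ]
      }
    }
    list(cent = cent, objective = objective)
  }

  best <- NULL
  for (r in seq_len(restarts)) {
    res <- run_once(derive_seed(seed, r - 1L))
    if (is.null(best) || tail(res$objective, 1) < tail(best$objective, 1))
      best <- res
  }
  cent <- best$cent
  ord <- order(cent[, 1] * cent[, 2])
  ba <- if (k >= 3L && k %% 3L == 0L)
    split(seq_len(k), rep(seq_len(k %/% 3L), each = 3L))
  else list(seq_len(k))
  structure(list(anchors = cent[ord, , drop = FALSE],
                 branch_assignment = ba,
                 input_size = as.integer(input_size),
                 objective = best$objective),
            class = "lightcsp_anchors")
}

#' @export
print.lightcsp_anchors <- function(x, ...) {
  cat("<lightcsp_anchors> reference input", x$input_size, "px\n")
  for (b in seq_along(x$branch_assignment)) {
    idx <- x$branch_assignment[[b]]
    cat(sprintf("  branch %d: %s\n", b, paste(
      sprintf("(%.1f, %.1f)", x$anchors[idx, 1], x$anchors[idx, 2]),
      collapse = " ")))
  }
  invisible(x)
}

# Scale an anchor set to a (possibly different) input size; returns the
# 9 x 2 pixel matrix.
anchors_at <- function(anchors, input_size)
  anchors$anchors * (input_size / anchors$input_size)

#' Decode raw head output into candidate detections
#'
#' Per grid cell and anchor: center `(sigmoid(tx) + cell) * stride`, size
#' `anchor * exp(tw, th)` (offsets clamped to +-4 to guard the
#' exponential), objectness and class scores through sigmoids, confidence =
#' objectness x best class score. Candidates below `conf_threshold` are
#' dropped.
#'
#' @param raw Raw head output `(H, W, 3*(5+nc))` for one image (or with a
#'   trailing singleton batch dim).
#' @param anchors A `3 x 2` matrix of pixel anchor shapes for this branch,
#'   at the current input size.
#' @param stride Branch stride in pixels.
#' @param conf_threshold Minimum confidence.
#' @param num_classes Number of classes `nc`.
#' @return Data frame of detections: corner-form pixel box, `objectness`,
#'   `class_id` (0-based), `class_score`, `confidence`.
#' @export
decode_predictions <- function(raw, anchors, stride, conf_threshold = 0.25,
                               num_classes = 1L) {
  d <- dim(raw)
  if (length(d) == 4L) {
    if (d[4] != 1L) stop("decode one image at a time")
    dim(raw) <- d[1:3]
    d <- dim(raw)
  }
  per <- 5L + num_classes
  if (d[3] != 3L * per)
    stop("raw has ", d[3], " channels; expected ", 3L * per)
  H <- d[1]; W <- d[2]
  cellx <- matrix(rep(seq_len(W) - 1L, each = H), H)
  celly <- matrix(rep(seq_len(H) - 1L, W), H)
  sig <- function(z) 1 / (1 + exp(-z))
  out <- vector("list", 3L)
  for (a in 1:3) {
    base <- (a - 1L) * per
    bx <- (sig(raw[, , base + 1L]) + cellx) * stride
    by <- (sig(raw[, , base + 2L]) + celly) * stride
    bw <- anchors[a, 1] * exp(pmin(pmax(raw[, , base + 3L], -4), 4))
    bh <- anchors[a, 2] * exp(pmin(pmax(raw[, , base + 4L], -4), 4))
    obj <- sig(raw[, , base + 5L])
    cls <- sig(array(raw[, , base + 5L + seq_len(num_classes)],
                     c(H, W, num_classes)))
    best <- if (num_classes == 1L) array(1L, c(H, W)) else
      apply(cls, c(1, 2), which.max)
    bscore <- array(cls, c(H * W, num_classes))[cbind(seq_len(H * W), as.vector(best))]
    conf <- as.vector(obj) * bscore
    keep <- conf >= conf_threshold
    if (!any(keep)) next
    out[[a]] <- data.frame(
      x1 = as.vector(bx)[keep] - as.vector(bw)[keep] / 2,
      y1 = as.vector(by)[keep] - as.vector(bh)[keep] / 2,
      x2 = as.vector(bx)[keep] + as.vector(bw)[keep] / 2,
      y2 = as.vector(by)[keep] + as.vector(bh)[keep] / 2,
      objectness = as.vector(obj)[keep],
      class_id = as.vector(best)[keep] - 1L,
      class_score = bscore[keep],
      confidence = conf[keep])
  }
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), objectness = numeric(0),
                      class_id = integer(0), class_score = numeric(0),
                      confidence = numeric(0))
  out
}

#' Assign ground-truth boxes to branches, cells and anchors
#'
#' Each box is assigned to the anchor of highest co-centered shape IoU
#' (hence to that anchor's branch) at the grid cell containing its center.
#' Anchors with shape IoU above 0.5 to a box that are not its best match
#' are marked "ignore": they incur no objectness penalty in the loss. Boxes
#' with zero width or height are rejected.
#'
#' @param boxes Data frame of normalized boxes (`class_id`, `cx`, `cy`,
#'   `w`, `h`).
#' @param anchors A [cluster_anchors()] result.
#' @param input_size Current input size in pixels (grids are
#'   `input_size / stride`).
#' @param strides Branch strides, highest resolution first.
#' @param num_classes Number of classes.
#' @param ignore_iou Shape-IoU threshold above which non-best anchors are
#'   ignored.
#' @return A `lightcsp_targets` object: per branch, the positive mask,
#'   ignore mask, regression targets and one-hot class targets on the
#'   `(grid, grid, 3)` lattice, plus the assignment table.
#' @export
encode_targets <- function(boxes, anchors, input_size,
                           strides = c(4L, 8L, 16L), num_classes = 1L,
                           ignore_iou = 0.5) {
  if (any(boxes$w <= 0 | boxes$h <= 0)) {
    bad <- which(boxes$w <= 0 | boxes$h <= 0)
    warning("rejecting ", length(bad), " box(es) with zero width/height")
    boxes <- boxes[-bad, , drop = FALSE]
  }
  gs <- as.integer(input_size / strides)
  A <- anchors_at(anchors, input_size)
  br <- lapply(gs, function(g) list(
    tmask = array(0, c(g, g, 3L)), ign = array(0, c(g, g, 3L)),
    tx = array(0, c(g, g, 3L)), ty = array(0, c(g, g, 3L)),
    tw = array(0, c(g, g, 3L)), th = array(0, c(g, g, 3L)),
    cls = array(0, c(g, g, 3L, num_classes))))
  asg <- NULL
  if (nrow(boxes)) {
    wh <- cbind(boxes$w, boxes$h) * input_size
    siou <- shape_iou(wh, A)
    branch_of <- rep(seq_along(anchors$branch_assignment),
                     lengths(anchors$branch_assignment))
    within <- unlist(lapply(anchors$branch_assignment, seq_along))
    for (i in seq_len(nrow(boxes))) {
      best <- which.max(siou[i, ])
      b <- branch_of[best]; a <- within[best]
      g <- gs[b]
      col <- min(max(floor(boxes$cx[i] * g), 0), g - 1L)
      row <- min(max(floor(boxes$cy[i] * g), 0), g - 1L)
      br[[b]]$tmask[row + 1L, col + 1L, a] <- 1
      br[[b]]$ign[row + 1L, col + 1L, a] <- 0
      br[[b]]$tx[row + 1L, col + 1L, a] <- boxes$cx[i] * g - col
      br[[b]]$ty[row + 1L, col + 1L, a] <- boxes$cy[i] * g - row
      br[[b]]$tw[row + 1L, col + 1L, a] <- log(wh[i, 1] / A[best, 1])
      br[[b]]$th[row + 1L, col + 1L, a] <- log(wh[i, 2] / A[best, 2])
      br[[b]]$cls[row + 1L, col + 1L, a, ] <- 0
      br[[b]]$cls[row + 1L, col + 1L, a, boxes$class_id[i] + 1L] <- 1
      for (j in which(siou[i, ] > ignore_iou)) {
        if (j == best) next
        bj <- branch_of[j]; aj <- within[j]; gj <- gs[bj]
        cj <- min(max(floor(boxes$cx[i] * gj), 0), gj - 1L)
        rj <- min(max(floor(boxes$cy[i] * gj), 0), gj - 1L)
        if (br[[bj]]$tmask[rj + 1L, cj + 1L, aj] == 0)
          br[[bj]]$ign[rj + 1L, cj + 1L, aj] <- 1
      }
      asg <- rbind(asg, data.frame(box = i, anchor = best, branch = b,
                                   row = row, col = col))
    }
  }
  structure(list(branches = br, grids = gs, strides = strides,
                 input_size = input_size, assignment = asg),
            class = "lightcsp_targets")
}

# Numerically stable binary cross-entropy with logits and its gradient.
bce_logits <- function(z, y) pmax(z, 0) - z * y + log1p(exp(-abs(z)))

# Core loss: raw branch arrays (H, W, 3*(5+nc), N) + per-image targets.
# Returns loss components and the gradient w.r.t. each raw array.
yolo_loss_core <- function(raws, targets, num_classes,
                           w_box = 5, w_obj = 1, w_noobj = 0.5, w_cls = 1) {
  per <- 5L + num_classes
  N <- dim(raws[[1]])[4]
  tot <- c(box = 0, obj = 0, cls = 0)
  grads <- lapply(raws, function(r) array(0, dim(r)))
  sig <- function(z) 1 / (1 + exp(-z))
  for (b in seq_along(raws)) {
    for (n in seq_len(N)) {
      tb <- targets[[n]]$branches[[b]]
      for (a in 1:3) {
        base <- (a - 1L) * per
        pos <- tb$tmask[, , a] == 1
        noobj <- !pos & tb$ign[, , a] == 0
        zo <- raws[[b]][, , base + 5L, n]
        so <- sig(zo)
        tot["obj"] <- tot["obj"] +
          w_obj * sum(bce_logits(zo[pos], 1)) +
          w_noobj * sum(bce_logits(zo[noobj], 0))
        go <- array(0, dim(zo))
        go[pos] <- w_obj * (so[pos] - 1)
        go[noobj] <- w_noobj * so[noobj]
        grads[[b]][, , base + 5L, n] <- go
        if (any(pos)) {
          for (j in 1:2) { # tx, ty through sigmoid
            z <- raws[[b]][, , base + j, n]
            s <- sig(z)
            tgt <- if (j == 1L) tb$tx[, , a] else tb$ty[, , a]
            dlt <- s[pos] - tgt[pos]
            tot["box"] <- tot["box"] + w_box * sum(dlt^2)
            g <- array(0, dim(z))
            g[pos] <- w_box * 2 * dlt * s[pos] * (1 - s[pos])
            grads[[b]][, , base + j, n] <- g
          }
          for (j in 3:4) { # tw, th raw
            z <- raws[[b]][, , base + j, n]
            tgt <- if (j == 3L) tb$tw[, , a] else tb$th[, , a]
            dlt <- z[pos] - tgt[pos]
            tot["box"] <- tot["box"] + w_box * sum(dlt^2)
            g <- array(0, dim(z))
            g[pos] <- w_box * 2 * dlt
            grads[[b]][, , base + j, n] <- g
          }
          for (c in seq_len(num_classes)) {
            z <- raws[[b]][, , base + 5L + c, n]
            y <- tb$cls[, , a, c]
            tot["cls"] <- tot["cls"] + w_cls * sum(bce_logits(z[pos], y[pos]))
            g <- array(0, dim(z))
            g[pos] <- w_cls * (sig(z[pos]) - y[pos])
            grads[[b]][, , base + 5L + c, n] <- g
          }
        }
      }
    }
  }
  tot <- tot / N
  grads <- lapply(grads, function(g) g / N)
  total <- sum(tot)
  if (!is.finite(total))
    stop("non-finite detection loss (box=", tot["box"], ", obj=", tot["obj"],
         ", cls=", tot["cls"], ")")
  list(total = total, box = unname(tot["box"]), obj = unname(tot["obj"]),
       cls = unname(tot["cls"]), grads = grads)
}

# Differentiation-graph wrapper around yolo_loss_core.
ag_yolo_loss <- function(raw_nodes, targets, num_classes, ...) {
  core <- yolo_loss_core(lapply(raw_nodes, function(n) n$value),
                         targets, num_classes, ...)
  node <- ag_node(core$total, raw_nodes,
                  function(g) lapply(core$grads, function(gr) g * gr))
  node$components <- core[c("box", "obj", "cls")]
  node
}

#' Detection training loss
#'
#' YOLO-style composite loss: binary cross-entropy on objectness (positives
#' weighted 1, background 0.5, ignored anchors skipped) and class scores,
#' squared error on the sigmoid-space center offsets and the raw log-size
#' offsets of positive anchors, summed over the three branches and averaged
#' over the batch.
#'
#' @param raws List of the three raw head outputs, each
#'   `(H, W, 3*(5+nc), N)` (an `(H, W, C)` array is treated as batch 1).
#' @param targets List of [encode_targets()] results, one per batch image
#'   (a single object is treated as batch 1).
#' @param num_classes Number of classes.
#' @param w_box,w_obj,w_noobj,w_cls Component weights.
#' @return List with `total` and the `box`, `obj`, `cls` components.
#' @export
detection_loss <- function(raws, targets, num_classes = 1L,
                           w_box = 5, w_obj = 1, w_noobj = 0.5, w_cls = 1) {
  raws <- lapply(raws, as_batch)
  if (inherits(targets, "lightcsp_targets")) targets <- list(targets)
  core <- yolo_loss_core(raws, targets, num_classes, w_box, w_obj, w_noobj,
                         w_cls)
  core[c("total", "box", "obj", "cls")]
}

#' Greedy non-maximum suppression
#'
#' Class-wise greedy suppression in descending confidence: a detection is
#' kept unless it overlaps an already-kept detection of the same class with
#' IoU at or above `iou_threshold`.
#'
#' @param dets Detection data frame (corner-form boxes, `confidence`,
#'   optional `class_id`).
#' @param iou_threshold Suppression overlap threshold.
#' @return The surviving subset, ordered by descending confidence.
#' @export
nms <- function(dets, iou_threshold = 0.45) {
  if (!nrow(dets)) return(dets)
  dets <- dets[order(-dets$confidence), , drop = FALSE]
  cls <- if ("class_id" %in% names(dets)) dets$class_id else rep(0L, nrow(dets))
  keep <- logical(nrow(dets))
  bx <- as.matrix(dets[, c("x1", "y1", "x2", "y2")])
  for (cl in unique(cls)) {
    idx <- which(cls == cl)
    alive <- rep(TRUE, length(idx))
    for (i in seq_along(idx)) {
      if (!alive[i]) next
      keep[idx[i]] <- TRUE
      if (i < length(idx)) {
        rest <- idx[(i + 1):length(idx)]
        ious <- box_iou(matrix(bx[idx[i], ], 1), bx[rest, , drop = FALSE])
        alive[(i + 1):length(idx)][ious[1, ] >= iou_threshold] <- FALSE
      }
    }
  }
  dets[keep, , drop = FALSE]
}

#' Run the detector on one image
#'
#' Resizes the image to the model's input size, runs the forward pass,
#' decodes all three branches, applies class-wise NMS, and maps boxes back
#' to the original pixel coordinates.
#'
#' @param model A [build_model()] result carrying an anchor set.
#' @param image `(H, W, 3)` array in `[0, 1]`.
#' @param conf_threshold,nms_iou Confidence and NMS thresholds.
#' @param input_size Override the model's input size (must be divisible
#'   by 32).
#' @return Detection data frame in original-image pixel coordinates.
#' @export
detect <- function(model, image, conf_threshold = 0.25, nms_iou = 0.45,
                   input_size = NULL) {
  if (is.null(model$anchors))
    stop("model has no anchor set; assign one (see cluster_anchors)")
  size <- as.integer(input_size %||% model$cfg$input_size)
  if (size %% 32L != 0L) stop("input_size must be divisible by 32")
  d <- dim(image)
  xi <- if (all(d[1:2] == size)) image else resize_bilinear_cpp(image, size, size)
  raws <- model_forward(model, xi)$raws
  A <- anchors_at(model$anchors, size)
  ba <- model$anchors$branch_assignment
  strides <- unname(model$strides)
  dets <- do.call(rbind, lapply(seq_along(raws), function(b)
    decode_predictions(raws[[b]], A[ba[[b]], , drop = FALSE], strides[b],
                       conf_threshold, model$cfg$num_classes)))
  dets <- nms(dets, nms_iou)
  sx <- d[2] / size; sy <- d[1] / size
  dets$x1 <- dets$x1 * sx; dets$x2 <- dets$x2 * sx
  dets$y1 <- dets$y1 * sy; dets$y2 <- dets$y2 * sy
  dets
}
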