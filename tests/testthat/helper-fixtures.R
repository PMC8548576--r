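# Shared fixtures: a width-reduced architecture (default widths / 8) so CPU
# tests stay fast, the matching synthetic-scene regime, and independent
# brute-force oracles for NMS, AP and anchor assignment.

tiny_arch <- function(input_size = 64L, seed = 1L, ...) {
  arch_config(input_size = input_size,
              stage_widths = list(c(8L, 4L), c(16L, 8L), c(32L, 16L),
                                  c(64L, 32L)),
              branch_channels = 32L, attention_reduction = 4L, seed = seed,
              ...)
}

# The overfit-study conditions: 16 small scenes with modest fruit counts.
overfit_scene_params <- function() {
  scene_params(image_size = 160L, fruit_count_range = c(3L, 6L),
               radius_range = c(6, 22), cluster_prob = 0.2,
               occluder_count_range = c(1L, 3L))
}

overfit_dataset <- function(n = 16L, base_seed = 11L) {
  p <- overfit_scene_params()
  lapply(seq_len(n), function(i) {
    s <- render_scene(p, lightcsp:::derive_seed(base_seed, i))
    list(image = s$image, boxes = s$boxes)
  })
}

random_boxes <- function(n, size = 100, seed = 1) {
  lightcsp:::local_seed(seed, {
    x1 <- runif(n, 0, size * 0.8); y1 <- runif(n, 0, size * 0.8)
    data.frame(x1 = x1, y1 = y1,
               x2 = x1 + runif(n, 2, size * 0.2),
               y2 = y1 + runif(n, 2, size * 0.2),
               confidence = runif(n), class_id = 0L)
  })
}

# O(n^2) reference NMS: double loop, no vectorized IoU.
naive_nms <- function(dets, thr) {
  dets <- dets[order(-dets$confidence), , drop = FALSE]
  keep <- rep(TRUE, nrow(dets))
  for (i in seq_len(nrow(dets))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(dets))) {
      if (j <= i || !keep[j]) next
      if (dets$class_id[j] != dets$class_id[i]) next
      iou <- box_iou(as.numeric(dets[i, c("x1", "y1", "x2", "y2")]),
                     as.numeric(dets[j, c("x1", "y1", "x2", "y2")]))
      if (iou >= thr) keep[j] <- FALSE
    }
  }
  dets[keep, , drop = FALSE]
}

# Brute-force AP: explicit threshold-by-threshold precision envelope and
# rectangle sum, independent of the cumulative-sweep implementation.
naive_ap <- function(tp_sorted, n_gt) {
  n <- length(tp_sorted)
  rec <- prec <- numeric(n)
  for (i in seq_len(n)) {
    rec[i] <- sum(tp_sorted[1:i]) / n_gt
    prec[i] <- sum(tp_sorted[1:i]) / i
  }
  env <- numeric(n)
  for (i in seq_len(n)) env[i] <- max(prec[i:n])
  ap <- 0
  prev <- 0
  for (i in seq_len(n)) {
    ap <- ap + (rec[i] - prev) * env[i]
    prev <- rec[i]
  }
  ap
}

# Exhaustive best-anchor search for one (w, h) pixel shape over 9 anchors.
naive_best_anchor <- function(wh, anchors_px) {
  best <- 1L; best_iou <- -1
  for (j in seq_len(nrow(anchors_px))) {
    iw <- min(wh[1], anchors_px[j, 1]); ih <- min(wh[2], anchors_px[j, 2])
    inter <- iw * ih
    iou <- inter / (wh[1] * wh[2] + anchors_px[j, 1] * anchors_px[j, 2] - inter)
    if (iou > best_iou) { best_iou <- iou; best <- j }
  }
  best
}

# Finite-difference gradient check of a node graph built by `build`, which
# takes a list of leaf nodes and returns an output node. The output is
# reduced to a scalar through a fixed random projection.
check_grad <- function(build, inputs, n_checks = 6, eps = 1e-5, seed = 42) {
  leaves <- lapply(inputs, lightcsp:::ag_node)
  out <- build(leaves)
  proj <- lightcsp:::local_seed(seed, array(rnorm(length(out$value)),
                                            dim(out$value) %||% length(out$value)))
  loss <- lightcsp:::ag_node(sum(out$value * proj), list(out),
                             function(g) list(g * proj))
  lightcsp:::ag_backward(loss)
  scalar_of <- function(vals) {
    nodes <- lapply(vals, lightcsp:::ag_node)
    sum(build(nodes)$value * proj)
  }
  max_rel <- 0
  set.seed(seed)
  for (k in seq_len(n_checks)) {
    which_in <- sample(length(inputs), 1)
    i <- sample(length(inputs[[which_in]]), 1)
    vp <- inputs; vp[[which_in]][i] <- vp[[which_in]][i] + eps
    vm <- inputs; vm[[which_in]][i] <- vm[[which_in]][i] - eps
    num <- (scalar_of(vp) - scalar_of(vm)) / (2 * eps)
    ana <- leaves[[which_in]]$grad[i]
    rel <- abs(num - ana) / max(abs(num), abs(ana), 1e-6)
    max_rel <- max(max_rel, rel)
  }
  max_rel
}

`%||%` <- function(a, b) if (is.null(a)) b else a
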