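# Training strategy: SGD with momentum and weight decay, multi-scale input
# sampling at regular intervals, mosaic augmentation, deterministic dataset
# splitting, and a resumable training loop.

#' Training configuration
#'
#' Defaults follow the reference recipe: SGD with momentum 0.9, weight
#' decay 5e-4, initial learning rate 0.01, batch size 8, 30,000 iterations,
#' input scales 320/416/512 drawn uniformly at a fixed iteration interval,
#' mosaic augmentation, and a 7:3 train/test split.
#'
#' @param lr Initial learning rate.
#' @param momentum SGD momentum.
#' @param weight_decay L2 decay, applied to convolution kernels only.
#' @param batch_size Images per iteration.
#' @param iterations Total training iterations.
#' @param scales Candidate input sizes (all divisible by 32).
#' @param scale_switch_interval Iterations between scale re-draws.
#' @param mosaic_prob Probability a sample is mosaic-augmented.
#' @param split_ratio Train fraction for [split_dataset()].
#' @param seed Master seed for all training randomness.
#' @param lr_schedule `"constant"` (default) or `"cosine"` decay.
#' @param warmup Iterations of linear learning-rate ramp-up before the
#'   schedule takes over; stabilizes the first SGD steps.
#' @param w_box,w_obj,w_noobj,w_cls Loss-component weights.
#' @param checkpoint_interval Iterations between checkpoints.
#' @return An object of class `lightcsp_train_cfg`.
#' @export
train_config <- function(lr = 0.01, momentum = 0.9, weight_decay = 5e-4,
                         batch_size = 8L, iterations = 30000L,
                         scales = c(320L, 416L, 512L),
                         scale_switch_interval = 10L, mosaic_prob = 1.0,
                         split_ratio = 0.7, seed = 1L,
                         lr_schedule = c("constant", "cosine"),
                         warmup = 100L,
                         w_box = 5, w_obj = 1, w_noobj = 0.5, w_cls = 1,
                         checkpoint_interval = 500L) {
  if (any(scales %% 32L != 0L)) stop("all scales must be divisible by 32")
  if (split_ratio <= 0 || split_ratio >= 1)
    stop("split_ratio must lie strictly between 0 and 1")
  structure(list(lr = lr, momentum = momentum, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 iterations = as.integer(iterations),
                 scales = as.integer(scales),
                 scale_switch_interval = as.integer(scale_switch_interval),
                 mosaic_prob = mosaic_prob, split_ratio = split_ratio,
                 seed = as.integer(seed),
                 lr_schedule = match.arg(lr_schedule),
                 warmup = as.integer(warmup),
                 w_box = w_box, w_obj = w_obj, w_noobj = w_noobj,
                 w_cls = w_cls,
                 checkpoint_interval = as.integer(checkpoint_interval)),
            class = "lightcsp_train_cfg")
}

#' Deterministic shuffled train/test split
#'
#' @param items Vector or list to split.
#' @param ratio Train fraction, strictly between 0 and 1.
#' @param seed Shuffle seed; the same seed always yields the same split.
#' @return List with `train` and `test`; disjoint and exhaustive, with
#'   `length(train) == round(ratio * n)` (clamped so neither side is
#'   empty).
#' @export
split_dataset <- function(items, ratio = 0.7, seed = 1L) {
  n <- length(items)
  if (n < 2L) stop("need at least 2 items to split")
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie strictly in (0, 1)")
  perm <- local_seed(seed, sample(n))
  k <- min(max(round(ratio * n), 1L), n - 1L)
  list(train = items[perm[seq_len(k)]],
       test = items[perm[(k + 1L):n]])
}

#' Mosaic augmentation
#'
#' Composites four samples onto one canvas split into quadrants by a random
#' center point. Each source is scaled to cover its quadrant (aspect
#' preserved) and randomly cropped; boxes are remapped, clipped to their
#' quadrant, and dropped when the clipped area falls below 25% of the
#' scaled original.
#'
#' @param samples List of exactly four `list(image =, boxes =)` samples.
#' @param out_size Canvas size in pixels.
#' @param seed Optional seed (otherwise the ambient RNG stream is used).
#' @param center Optional fixed `(x, y)` canvas split point in pixels.
#' @return `list(image =, boxes =)` with normalized boxes.
#' @export
mosaic_augment <- function(samples, out_size, seed = NULL, center = NULL) {
  if (length(samples) != 4L) stop("mosaic needs exactly 4 samples")
  local_seed(seed, {
    S <- as.integer(out_size)
    ctr <- center %||% round(runif(2, 0.3, 0.7) * S)
    cx <- min(max(as.integer(ctr[1]), 1L), S - 1L)
    cy <- min(max(as.integer(ctr[2]), 1L), S - 1L)
    canvas <- array(0, c(S, S, 3))
    quads <- list(c(0L, 0L, cy, cx), c(0L, cx, cy, S - cx),
                  c(cy, 0L, S - cy, cx), c(cy, cx, S - cy, S - cx))
    out_boxes <- list()
    for (q in 1:4) {
      r0 <- quads[[q]][1]; c0 <- quads[[q]][2]
      qh <- quads[[q]][3]; qw <- quads[[q]][4]
      src <- samples[[q]]
      sh <- dim(src$image)[1]; sw <- dim(src$image)[2]
      sc <- max(qh / sh, qw / sw)
      nh <- max(qh, as.integer(ceiling(sh * sc)))
      nw <- max(qw, as.integer(ceiling(sw * sc)))
      res <- resize_image(src$image, nh, nw)
      offr <- if (nh > qh) sample.int(nh - qh + 1L, 1L) - 1L else 0L
      offc <- if (nw > qw) sample.int(nw - qw + 1L, 1L) - 1L else 0L
      canvas[r0 + seq_len(qh), c0 + seq_len(qw), ] <-
        res[offr + seq_len(qh), offc + seq_len(qw), , drop = FALSE]
      b <- src$boxes
      if (!is.null(b) && nrow(b)) {
        x1 <- (b$cx - b$w / 2) * nw - offc; x2 <- (b$cx + b$w / 2) * nw - offc
        y1 <- (b$cy - b$h / 2) * nh - offr; y2 <- (b$cy + b$h / 2) * nh - offr
        area0 <- (x2 - x1) * (y2 - y1)
        cx1 <- pmin(pmax(x1, 0), qw); cx2 <- pmin(pmax(x2, 0), qw)
        cy1 <- pmin(pmax(y1, 0), qh); cy2 <- pmin(pmax(y2, 0), qh)
        area <- (cx2 - cx1) * (cy2 - cy1)
        keep <- area >= 0.25 * area0 & area > 0
        if (any(keep))
          out_boxes[[q]] <- data.frame(
            class_id = b$class_id[keep],
            cx = (c0 + (cx1 + cx2)[keep] / 2) / S,
            cy = (r0 + (cy1 + cy2)[keep] / 2) / S,
            w = (cx2 - cx1)[keep] / S,
            h = (cy2 - cy1)[keep] / S)
      }
    }
    boxes <- if (length(out_boxes)) do.call(rbind, out_boxes) else NULL
    if (is.null(boxes))
      boxes <- data.frame(class_id = integer(0), cx = numeric(0),
                          cy = numeric(0), w = numeric(0), h = numeric(0))
    list(image = canvas, boxes = boxes)
  })
}

#' Input scale for an iteration
#'
#' The scale is re-drawn uniformly from `cfg$scales` every
#' `cfg$scale_switch_interval` iterations (iterations are 0-based) and is a
#' pure function of `(cfg$seed, iteration)`.
#'
#' @param iteration 0-based iteration index.
#' @param cfg A [train_config()].
#' @return Input size in pixels.
#' @export
sample_scale <- function(iteration, cfg) {
  block <- as.integer(iteration) %/% cfg$scale_switch_interval
  local_seed(derive_seed(cfg$seed, block),
             cfg$scales[sample.int(length(cfg$scales), 1L)])
}

#' Train a detector
#'
#' SGD with momentum on the composite detection loss. Each iteration
#' derives its seed from `(cfg$seed, iteration)`, so runs are reproducible
#' and resumable mid-stream. Anchors are clustered from the training labels
#' if the model carries none. A non-finite loss aborts after writing a
#' last-good checkpoint (when a checkpoint directory is given).
#'
#' @param model A [build_model()] result.
#' @param data List of `list(image =, boxes =)` samples, or a dataset
#'   directory for [load_dataset()].
#' @param cfg A [train_config()].
#' @param checkpoint_dir Optional directory for periodic checkpoints.
#' @param resume Optional checkpoint path to continue from.
#' @param verbose Print a progress line every 50 iterations.
#' @return List: trained `model` (with anchors) and the per-iteration loss
#'   `log`.
#' @export
train_detector <- function(model, data, cfg = train_config(),
                           checkpoint_dir = NULL, resume = NULL,
                           verbose = FALSE) {
  if (is.character(data)) data <- load_dataset(data)
  n <- length(data)
  if (!n) stop("empty training set")
  classes <- unlist(lapply(data, function(s) s$boxes$class_id))
  if (length(classes) && max(classes) + 1L > model$cfg$num_classes)
    stop("dataset has class ids up to ", max(classes),
         " but the model expects ", model$cfg$num_classes, " class(es)")
  log <- NULL
  opt <- NULL
  start <- 0L
  if (!is.null(resume)) {
    ck <- load_checkpoint(resume)
    model <- ck$model
    log <- ck$log
    start <- ck$iteration
    opt <- attr(ck, "opt") %||% ck$opt
  }
  if (is.null(model$anchors)) {
    all_boxes <- do.call(rbind, lapply(data, `[[`, "boxes"))
    model$anchors <- cluster_anchors(all_boxes, 9L, model$cfg$input_size,
                                     seed = cfg$seed)
  }
  if (is.null(opt)) opt <- lapply(model$params, function(p) p * 0)
  decay_mask <- grepl("\\.w[0-9]*$", names(model$params))
  nc <- model$cfg$num_classes
  strides <- unname(model$strides)
  for (it in (start + 1L):cfg$iterations) {
    s <- sample_scale(it - 1L, cfg)
    step <- local_seed(derive_seed(cfg$seed, 100000L + it), {
      idx <- sample.int(n, cfg$batch_size, replace = cfg$batch_size > n)
      x <- array(0, c(s, s, 3L, cfg$batch_size))
      targets <- vector("list", cfg$batch_size)
      for (bi in seq_along(idx)) {
        if (runif(1) < cfg$mosaic_prob) {
          others <- sample.int(n, 3L, replace = n < 4L)
          smp <- mosaic_augment(data[c(idx[bi], others)], s)
        } else {
          src <- data[[idx[bi]]]
          img <- if (all(dim(src$image)[1:2] == s)) src$image else
            resize_image(src$image, s, s)
          smp <- list(image = img, boxes = src$boxes)
        }
        x[, , , bi] <- smp$image
        targets[[bi]] <- encode_targets(smp$boxes, model$anchors, s,
                                        strides, nc)
      }
      fw <- model_ctx_forward(model, x, training = TRUE)
      loss <- ag_yolo_loss(fw$out$raws, targets, nc, cfg$w_box, cfg$w_obj,
                           cfg$w_noobj, cfg$w_cls)
      list(fw = fw, loss = loss)
    })
    loss <- step$loss
    if (!is.finite(loss$value)) {
      if (!is.null(checkpoint_dir)) {
        dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
        save_checkpoint(model, cfg, it - 1L, log,
                        file.path(checkpoint_dir, "last_good.rds"))
      }
      stop("training diverged at iteration ", it, " (loss = ", loss$value, ")")
    }
    ag_backward(loss)
    lr_t <- if (cfg$lr_schedule == "cosine")
      cfg$lr * 0.5 * (1 + cos(pi * it / cfg$iterations)) else cfg$lr
    if (cfg$warmup > 0L && it <= cfg$warmup) lr_t <- lr_t * it / cfg$warmup
    ctx <- step$fw$ctx
    for (nm in names(model$params)) {
      node <- ctx$nodes[[nm]]
      g <- if (is.null(node) || is.null(node$grad)) 0 else node$grad
      if (decay_mask[match(nm, names(model$params))])
        g <- g + cfg$weight_decay * model$params[[nm]]
      opt[[nm]] <- cfg$momentum * opt[[nm]] + g
      model$params[[nm]] <- model$params[[nm]] - lr_t * opt[[nm]]
    }
    for (bn in names(model$buffers))
      model$buffers[[bn]] <- ctx$buffers[[bn]]
    log <- rbind(log, data.frame(iteration = it, scale = s,
                                 loss = loss$value,
                                 box = loss$components$box,
                                 obj = loss$components$obj,
                                 cls = loss$components$cls))
    if (verbose && it %% 50L == 0L)
      message(sprintf("[lightcsp] iter %d scale %d loss %.4f", it, s,
                      loss$value))
    if (!is.null(checkpoint_dir) && it %% cfg$checkpoint_interval == 0L) {
      dir.create(checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
      ck <- list(model = model, train_cfg = cfg, iteration = it, log = log,
                 opt = opt)
      saveRDS(ck, file.path(checkpoint_dir, sprintf("iter_%06d.rds", it)))
    }
  }
  list(model = model, log = log)
}
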