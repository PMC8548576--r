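# Anchor clustering, decoding, target assignment, loss and NMS.

make_anchor_set <- function(anchors_px, input_size = 416L) {
  structure(list(anchors = anchors_px,
                 branch_assignment = split(seq_len(nrow(anchors_px)),
                                           rep(1:3, each = 3)),
                 input_size = as.integer(input_size), objective = numeric(0)),
            class = "lightcsp_anchors")
}

test_that("anchor clustering recovers separable shape modes exactly", {
  shapes <- cbind(w = seq(0.02, 0.5, length.out = 9),
                  h = seq(0.5, 0.02, length.out = 9) + 0.05)
  boxes <- data.frame(w = rep(shapes[, 1], 10), h = rep(shapes[, 2], 10))
  an <- cluster_anchors(boxes, k = 9, input_size = 416, seed = 4)
  got <- an$anchors[order(an$anchors[, 1]), ]
  want <- (shapes * 416)[order(shapes[, 1] * 416), ]
  expect_equal(unname(got), unname(want), tolerance = 1e-9)
  # triples ordered by ascending area
  areas <- an$anchors[, 1] * an$anchors[, 2]
  expect_true(all(diff(areas) >= 0))

  two <- data.frame(w = rep(c(0.1, 0.4), each = 5), h = rep(c(0.1, 0.4), each = 5))
  for (s in 1:4) {
    a2 <- cluster_anchors(two, k = 2, input_size = 100, seed = s)
    expect_equal(sort(a2$anchors[, 1]), c(10, 40), tolerance = 1e-9)
  }
})

test_that("anchor clustering objective is non-increasing and beats the true modes", {
  modes <- matrix(c(0.05, 0.06, 0.15, 0.18, 0.4, 0.35), 3, 2, byrow = TRUE)
  boxes <- lightcsp:::local_seed(8, {
    m <- sample(3, 1000, TRUE)
    data.frame(w = pmin(modes[m, 1] * exp(rnorm(1000, 0, 0.15)), 1),
               h = pmin(modes[m, 2] * exp(rnorm(1000, 0, 0.15)), 1))
  })
  an <- cluster_anchors(boxes, k = 3, input_size = 416, seed = 1)
  expect_true(all(diff(an$objective) <= 1e-9))
  wh <- cbind(boxes$w, boxes$h) * 416
  mean_dist <- function(cent) {
    s <- lightcsp:::shape_iou(wh, cent)
    mean(1 - apply(s, 1, max))
  }
  expect_lte(mean_dist(an$anchors), mean_dist(modes * 416) + 1e-12)
})

test_that("degenerate anchor inputs are rejected or cleaned", {
  expect_error(cluster_anchors(data.frame(w = runif(5), h = runif(5)), k = 9),
               "at least k")
  b <- data.frame(w = c(runif(20, 0.1, 0.5), 0), h = c(runif(20, 0.1, 0.5), 0.2))
  expect_warning(cluster_anchors(b, k = 9, seed = 1), "zero-area")
})

test_that("head convolution emits anchors * (5 + classes) channels", {
  f <- array(rnorm(13 * 13 * 64), c(13, 13, 64))
  expect_equal(dim(head_conv(f, num_classes = 1))[3], 18)
  expect_equal(dim(head_conv(f, num_classes = 3))[3], 24)
  expect_equal(dim(head_conv(f, num_classes = 80))[3], 255)
})

test_that("decoding inverts the anchor-offset parameterization", {
  # zero offsets at cell (0, 0): center = stride/2 .. no: sigmoid(0) = 0.5
  raw <- array(-20, c(4, 4, 18))
  raw[1, 1, 1:4] <- 0   # tx, ty, tw, th
  raw[1, 1, 5] <- 20    # objectness ~ 1
  raw[1, 1, 6] <- 20
  anchors <- matrix(c(32, 32, 48, 48, 64, 64), 3, 2, byrow = TRUE)
  d <- decode_predictions(raw, anchors, stride = 8, conf_threshold = 0.25)
  expect_equal(nrow(d), 1)
  expect_equal(c((d$x1 + d$x2) / 2, (d$y1 + d$y2) / 2), c(4, 4))
  expect_equal(c(d$x2 - d$x1, d$y2 - d$y1), c(32, 32))

  # silent map decodes to nothing
  expect_equal(nrow(decode_predictions(array(-20, c(4, 4, 18)), anchors, 8)), 0)
})

test_that("encode and decode round-trip boxes representable on the grid", {
  an <- make_anchor_set(cbind(c(8, 16, 24, 40, 56, 80, 120, 160, 220),
                              c(10, 14, 28, 44, 52, 88, 110, 170, 200)), 416)
  set.seed(5)
  boxes <- data.frame(class_id = 0L,
                      cx = runif(20, 0.1, 0.9), cy = runif(20, 0.1, 0.9),
                      w = runif(20, 0.03, 0.5), h = runif(20, 0.03, 0.5))
  tg <- encode_targets(boxes, an, 416)
  # rebuild raw maps that invert the encoding
  qlogit <- function(p) log(p / (1 - p))
  raws <- lapply(tg$grids, function(g) array(-20, c(g, g, 18)))
  for (k in seq_len(nrow(tg$assignment))) {
    a <- tg$assignment[k, ]
    b <- tg$branches[[a$branch]]
    ai <- (match(a$anchor, an$branch_assignment[[a$branch]]) - 1L) * 6L
    r <- a$row + 1L; c <- a$col + 1L
    raws[[a$branch]][r, c, ai + 1L] <- qlogit(min(max(b$tx[r, c, ai / 6 + 1], 1e-9), 1 - 1e-9))
    raws[[a$branch]][r, c, ai + 2L] <- qlogit(min(max(b$ty[r, c, ai / 6 + 1], 1e-9), 1 - 1e-9))
    raws[[a$branch]][r, c, ai + 3L] <- b$tw[r, c, ai / 6 + 1]
    raws[[a$branch]][r, c, ai + 4L] <- b$th[r, c, ai / 6 + 1]
    raws[[a$branch]][r, c, ai + 5L] <- 20
    raws[[a$branch]][r, c, ai + 6L] <- 20
  }
  dec <- do.call(rbind, lapply(1:3, function(bi)
    decode_predictions(raws[[bi]], an$anchors[an$branch_assignment[[bi]], ],
                       c(4, 8, 16)[bi], conf_threshold = 0.5)))
  expect_equal(nrow(dec), nrow(boxes))
  got <- dec[order((dec$x1 + dec$x2) / 2), ]
  want <- label_to_corners(boxes, 416, 416)
  want <- want[order((want$x1 + want$x2) / 2), ]
  for (col in c("x1", "y1", "x2", "y2"))
    expect_lt(max(abs(got[[col]] - want[[col]])) / 416, 1e-6)
})

test_that("target assignment matches an exhaustive best-IoU search", {
  an <- make_anchor_set(cbind(c(8, 16, 24, 40, 56, 80, 120, 160, 220),
                              c(10, 14, 28, 44, 52, 88, 110, 170, 200)), 416)
  set.seed(6)
  boxes <- data.frame(class_id = 0L,
                      cx = runif(40, 0.05, 0.95), cy = runif(40, 0.05, 0.95),
                      w = runif(40, 0.02, 0.6), h = runif(40, 0.02, 0.6))
  tg <- encode_targets(boxes, an, 416)
  for (k in seq_len(nrow(tg$assignment))) {
    i <- tg$assignment$box[k]
    expect_equal(tg$assignment$anchor[k],
                 naive_best_anchor(c(boxes$w[i], boxes$h[i]) * 416, an$anchors))
  }
  # a GT exactly matching anchor 5 lands on anchor 5's branch and cell
  g <- encode_targets(data.frame(class_id = 0L, cx = 0.52, cy = 0.48,
                                 w = 56 / 416, h = 52 / 416), an, 416)
  expect_equal(g$assignment$anchor, 5L)
  expect_equal(g$assignment$branch, 2L)
  # two GTs in different cells yield two positive cells
  g2 <- encode_targets(data.frame(class_id = 0L, cx = c(0.2, 0.8),
                                  cy = c(0.2, 0.8), w = 0.1, h = 0.1), an, 416)
  expect_equal(sum(vapply(g2$branches, function(b) sum(b$tmask), 0)), 2)
  expect_warning(
    encode_targets(data.frame(class_id = 0L, cx = 0.5, cy = 0.5, w = 0, h = 0.1),
                   an, 416), "zero width/height")
})

test_that("the loss is near zero for perfect logits and pure background", {
  an <- make_anchor_set(cbind(c(8, 16, 24, 40, 56, 80, 120, 160, 220),
                              c(10, 14, 28, 44, 52, 88, 110, 170, 200)), 160)
  boxes <- data.frame(class_id = 0L, cx = 0.5, cy = 0.5, w = 0.3, h = 0.25)
  tg <- encode_targets(boxes, an, 160)
  qlogit <- function(p) log(p / (1 - p))
  raws <- lapply(tg$grids, function(g) array(-20, c(g, g, 18)))
  a <- tg$assignment[1, ]
  b <- tg$branches[[a$branch]]
  ai <- (match(a$anchor, an$branch_assignment[[a$branch]]) - 1L) * 6L
  r <- a$row + 1L; c <- a$col + 1L
  s <- ai / 6 + 1
  raws[[a$branch]][r, c, ai + 1:6] <-
    c(qlogit(pmin(pmax(b$tx[r, c, s], 1e-9), 1 - 1e-9)),
      qlogit(pmin(pmax(b$ty[r, c, s], 1e-9), 1 - 1e-9)),
      b$tw[r, c, s], b$th[r, c, s], 20, 20)
  l <- detection_loss(raws, tg)
  expect_lt(l$total, 1e-3)

  # empty image: objectness is the only term and is ~ 0 at strong negatives
  tg0 <- encode_targets(boxes[0, ], an, 160)
  l0 <- detection_loss(lapply(tg0$grids, function(g) array(-20, c(g, g, 18))), tg0)
  expect_equal(l0$box, 0)
  expect_equal(l0$cls, 0)
  expect_lt(l0$obj, 1e-4) # ~6300 cells x bce(sigmoid(-20), 0)
})

test_that("loss gradients match finite differences on a toy grid", {
  an <- make_anchor_set(cbind(c(4, 6, 8, 10, 12, 16, 20, 26, 30),
                              c(4, 6, 8, 10, 12, 16, 20, 26, 30)), 64)
  boxes <- data.frame(class_id = 0L, cx = c(0.3, 0.72), cy = c(0.4, 0.7),
                      w = c(0.2, 0.12), h = c(0.18, 0.3))
  tg <- encode_targets(boxes, an, 64)
  set.seed(7)
  raws <- lapply(tg$grids, function(g) array(rnorm(g * g * 18), c(g, g, 18, 1)))
  core <- lightcsp:::yolo_loss_core(raws, list(tg), 1)
  max_rel <- 0
  for (b in 1:3) {
    for (k in 1:6) {
      i <- sample(length(raws[[b]]), 1)
      eps <- 1e-6
      f <- function(v) {
        r2 <- raws; r2[[b]][i] <- v
        lightcsp:::yolo_loss_core(r2, list(tg), 1)$total
      }
      num <- (f(raws[[b]][i] + eps) - f(raws[[b]][i] - eps)) / (2 * eps)
      ana <- core$grads[[b]][i]
      if (abs(num) > 1e-10 || abs(ana) > 1e-10)
        max_rel <- max(max_rel, abs(num - ana) / max(abs(num), abs(ana)))
    }
  }
  expect_lt(max_rel, 1e-4)
})

test_that("IoU matches hand-computed overlaps", {
  expect_equal(box_iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1.0)
  expect_equal(box_iou(c(0, 0, 1, 1), c(2, 2, 3, 3)), 0.0)
  expect_equal(box_iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7)
  expect_equal(box_iou(c(0, 0, 0, 2), c(0, 0, 2, 2)), 0.0) # zero area
  m <- box_iou(matrix(c(0, 0, 2, 2, 4, 4, 6, 6), 2, byrow = TRUE),
               matrix(c(1, 1, 3, 3), 1))
  expect_equal(dim(m), c(2, 1))
  expect_equal(m[1, 1], 1 / 7)
  expect_equal(m[2, 1], 0)
})

test_that("NMS keeps the top duplicate, all disjoint boxes, and is idempotent", {
  two <- data.frame(x1 = 0, y1 = 0, x2 = 10, y2 = 10,
                    confidence = c(0.9, 0.8), class_id = 0L)
  expect_equal(nms(two, 0.45)$confidence, 0.9)
  far <- data.frame(x1 = c(0, 50), y1 = c(0, 50), x2 = c(10, 60),
                    y2 = c(10, 60), confidence = c(0.3, 0.9), class_id = 0L)
  expect_equal(nrow(nms(far, 0.45)), 2)
  # descending-confidence order and subset property on random boxes
  dets <- random_boxes(200, seed = 10)
  out <- nms(dets, 0.5)
  expect_true(all(diff(out$confidence) <= 0))
  expect_true(all(out$confidence %in% dets$confidence))
  expect_equal(nms(out, 0.5), out)
})

test_that("NMS equals the O(n^2) reference on random boxes", {
  for (s in c(10, 11, 12)) {
    dets <- random_boxes(200, seed = s)
    dets$class_id <- lightcsp:::local_seed(s, sample(0:1, 200, TRUE))
    a <- nms(dets, 0.5)
    b <- naive_nms(dets, 0.5)
    expect_equal(a[order(-a$confidence), ], b[order(-b$confidence), ],
                 ignore_attr = TRUE)
  }
})
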