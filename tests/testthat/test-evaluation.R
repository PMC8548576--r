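# Detection metrics and model-lightness accounting.

test_that("greedy matching follows the one-to-one duplicate rule", {
  gt <- data.frame(x1 = 0, y1 = 0, x2 = 10, y2 = 10)
  one <- data.frame(x1 = 0, y1 = 0, x2 = 10, y2 = 10, confidence = 0.9)
  m <- match_detections(one, gt)
  expect_equal(c(m$n_tp, m$n_fp), c(1, 0))
  dup <- rbind(one, data.frame(x1 = 1, y1 = 1, x2 = 11, y2 = 11,
                               confidence = 0.8))
  m2 <- match_detections(dup, gt)
  expect_equal(c(m2$n_tp, m2$n_fp), c(1, 1))
})

test_that("greedy matching equals an independent reference on random instances", {
  for (s in 1:5) {
    set.seed(100 + s)
    gt <- random_boxes(8, seed = 200 + s)[, c("x1", "y1", "x2", "y2")]
    dets <- random_boxes(15, seed = 300 + s)
    ref_tp <- 0
    d <- dets[order(-dets$confidence), ]
    used <- rep(FALSE, nrow(gt))
    tp_ref <- logical(nrow(d))
    for (i in seq_len(nrow(d))) {
      best <- 0; best_iou <- 0.5 - 1e-12
      for (j in seq_len(nrow(gt))) {
        if (used[j]) next
        iou <- box_iou(as.numeric(d[i, c("x1", "y1", "x2", "y2")]),
                       as.numeric(gt[j, ]))
        if (iou >= 0.5 && iou > best_iou) { best <- j; best_iou <- iou }
      }
      if (best > 0) { used[best] <- TRUE; tp_ref[i] <- TRUE; ref_tp <- ref_tp + 1 }
    }
    m <- match_detections(dets, gt, 0.5)
    expect_equal(m$tp, tp_ref)
  }
})

test_that("precision and recall arithmetic and conventions hold", {
  pr <- precision_recall(8, 2, 10)
  expect_equal(pr$precision, 0.8)
  expect_equal(pr$recall, 0.8)
  expect_message(pr0 <- precision_recall(0, 0, 5), "convention")
  expect_equal(pr0$precision, 1)
  expect_equal(pr0$recall, 0)
  expect_error(precision_recall(1, 1, 0), "positive")
})

test_that("average precision handles the perfect and empty extremes", {
  gt <- data.frame(x1 = c(0, 20), y1 = c(0, 20), x2 = c(10, 30),
                   y2 = c(10, 30))
  perfect <- data.frame(x1 = c(0, 20), y1 = c(0, 20), x2 = c(10, 30),
                        y2 = c(10, 30), confidence = c(0.9, 0.8))
  expect_equal(average_precision(perfect, gt), 1.0)
  expect_equal(average_precision(perfect[0, ], gt), 0.0)
  expect_error(average_precision(perfect, gt[0, ]), "no ground truth")
})

test_that("average precision equals the brute-force envelope sum", {
  set.seed(21)
  gt <- random_boxes(10, seed = 22)[, c("x1", "y1", "x2", "y2")]
  dets <- rbind(
    cbind(gt[1:6, ] + runif(6, -1, 1), confidence = runif(6, 0.5, 1)),
    random_boxes(14, seed = 23)[, c("x1", "y1", "x2", "y2", "confidence")])
  ap <- average_precision(dets, gt)
  s <- lightcsp:::pr_sweep(dets, gt, 0.5)
  expect_equal(ap, naive_ap(s$tp, nrow(gt)), tolerance = 1e-12)
})

test_that("AP is invariant to monotone confidence rescaling and responds correctly to extra detections", {
  set.seed(31)
  gt <- random_boxes(10, seed = 32)[, c("x1", "y1", "x2", "y2")]
  dets <- rbind(
    cbind(gt[1:7, ] + runif(7, -0.5, 0.5), confidence = runif(7, 0.3, 0.9)),
    random_boxes(10, seed = 33)[, c("x1", "y1", "x2", "y2", "confidence")])
  ap <- average_precision(dets, gt)
  resc <- dets
  resc$confidence <- plogis(5 * resc$confidence - 1) # strictly monotone
  expect_equal(average_precision(resc, gt), ap, tolerance = 1e-12)
  # a new true positive at top confidence cannot hurt
  extra_tp <- rbind(dets, cbind(gt[8, ], confidence = 1))
  expect_gte(average_precision(extra_tp, gt), ap - 1e-12)
  # a new false positive at top confidence cannot help
  extra_fp <- rbind(dets, data.frame(x1 = 900, y1 = 900, x2 = 910, y2 = 910,
                                     confidence = 1))
  expect_lte(average_precision(extra_fp, gt), ap + 1e-12)
})

test_that("the equilibrium point minimizes |P - R| over all observed thresholds", {
  set.seed(41)
  gt <- random_boxes(12, seed = 42)[, c("x1", "y1", "x2", "y2")]
  dets <- rbind(
    cbind(gt[1:9, ] + runif(9, -0.5, 0.5), confidence = runif(9, 0.2, 1)),
    random_boxes(8, seed = 43)[, c("x1", "y1", "x2", "y2", "confidence")])
  eq <- equilibrium_point(dets, gt)
  s <- lightcsp:::pr_sweep(dets, gt, 0.5)
  ctp <- cumsum(s$tp)
  gaps <- abs(ctp / seq_along(ctp) - ctp / nrow(gt))
  expect_equal(abs(eq$precision - eq$recall), min(gaps), tolerance = 1e-12)
  # tie-break toward higher confidence: the reported threshold is the first
  # index achieving the minimum
  expect_equal(eq$confidence, s$conf[which.min(gaps)])
})

test_that("parameter counting matches layer closed forms", {
  # 1x1 conv 3 -> 2 with batch norm: 6 kernel + 4 BN
  y <- conv_bn_act(array(runif(48), c(4, 4, 3)), 1, 2)
  expect_equal(count_params(attr(y, "params")) * 1e6, 6 + 4)
  # head conv adds a bias instead: 6 kernel + 2 bias
  h <- head_conv(array(runif(48), c(4, 4, 3)), num_classes = 1,
                 anchors_per_cell = 1)
  expect_equal(count_params(attr(h, "params")) * 1e6, 3 * 6 + 6)
  # an instantiated model agrees with the analytic shape walk
  cfg <- tiny_arch()
  m <- build_model(cfg)
  expect_equal(count_params(m) * 1e6, attr(profile_model(cfg), "total_params"))
})

test_that("FLOP accounting follows the convolution closed form and grows with input", {
  f320 <- count_flops(arch_config(), 320)
  f416 <- count_flops(arch_config(), 416)
  f512 <- count_flops(arch_config(), 512)
  expect_true(f320 < f416 && f416 < f512)
  # nearly everything scales with spatial area
  expect_gt(f416 / f320, (416 / 320)^2 * 0.95)
  expect_lt(f416 / f320, (416 / 320)^2 * 1.05)
  # the stem's first convolution alone: 2 * 9 * 3 * 32 * 208^2 inside the total
  expect_gt(f416 * 1e9, 2 * 9 * 3 * 32 * 208^2)
})

test_that("throughput measurement reports N over elapsed seconds", {
  m <- build_model(tiny_arch(input_size = 64))
  m$anchors <- cluster_anchors(
    data.frame(w = runif(20, 0.1, 0.5), h = runif(20, 0.1, 0.5)),
    input_size = 64, seed = 1)
  imgs <- lapply(1:2, function(i) array(runif(64 * 64 * 3), c(64, 64, 3)))
  fps <- measure_fps(m, imgs, warmup = 1)
  expect_true(fps > 0)
  expect_equal(as.numeric(fps), attr(fps, "n") / attr(fps, "seconds"))
  expect_error(measure_fps(m, list()), "at least one")
})
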