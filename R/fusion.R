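# Deep-shallow three-branch feature fusion and the multiscale-fusion
# dual-attention (MFDA) step, plus the plain FPN baseline used by the
# component-ablation toggles.
#
# Per branch the equal-scale backbone tap is merged with the next deeper tap
# (2x nearest up-sampled) and the next shallower tap (2x max-pooled); the two
# resampled maps pass a channel-attention gate, the three maps are
# concatenated, the concatenation passes a spatial-attention gate and a 1x1
# fusion convolution. The highest-resolution branch has no shallower
# neighbour and fuses only two maps.

# CBAM-style channel attention: average- and max-pooled channel descriptors
# through a shared two-layer bottleneck, summed and sigmoid-gated.
nn_channel_attention <- function(ctx, name, x, reduction = NULL) {
  r <- reduction %||% ctx$cfg$attention_reduction
  C <- vdim(x$value)[3]
  if (r >= C)
    stop("channel attention reduction (", r, ") must be smaller than the ",
         "channel count (", C, ")")
  if (C %% r != 0L)
    stop("channel count (", C, ") must be divisible by the reduction (", r, ")")
  hidden <- C %/% r
  w1 <- px_param(ctx, paste0(name, ".w1"), c(1L, 1L, C, hidden),
                 function(d) rnorm(prod(d), 0, sqrt(2 / C)))
  b1 <- px_param(ctx, paste0(name, ".b1"), hidden, function(d) rep(0, prod(d)))
  w2 <- px_param(ctx, paste0(name, ".w2"), c(1L, 1L, hidden, C),
                 function(d) rnorm(prod(d), 0, sqrt(2 / hidden)))
  b2 <- px_param(ctx, paste0(name, ".b2"), C, function(d) rep(0, prod(d)))
  bottleneck <- function(p)
    ag_bias(ag_conv2d(ag_relu(ag_bias(ag_conv2d(p, w1), b1)), w2), b2)
  gate <- ag_sigmoid(ag_add(bottleneck(ag_gap(x)), bottleneck(ag_gmp(x))))
  ag_scale_channels(x, gate)
}

# Spatial attention: per-pixel channel mean and max, concatenated, convolved
# (odd kernel, default 7) to one channel and sigmoid-gated.
nn_spatial_attention <- function(ctx, name, x, kernel = NULL) {
  k <- kernel %||% ctx$cfg$spatial_kernel
  if (k %% 2L == 0L) stop("spatial attention kernel must be odd")
  stat <- ag_concat(list(ag_chmean(x), ag_chmax(x)))
  w <- px_param(ctx, paste0(name, ".w"), c(k, k, 2L, 1L),
                function(d) rnorm(prod(d), 0, sqrt(2 / (k * k * 2))))
  b <- px_param(ctx, paste0(name, ".b"), 1L, function(d) rep(0, prod(d)))
  gate <- ag_sigmoid(ag_bias(ag_conv2d(stat, w), b))
  ag_scale_spatial(x, gate)
}

# One fusion branch. `large` may be NULL (highest-resolution branch).
# With mfda = FALSE attention is skipped and plain concatenation is used.
nn_fuse_branch <- function(ctx, name, equal, small, large, out_ch, mfda) {
  parts <- list(equal)
  if (mfda) {
    parts <- c(parts, list(nn_channel_attention(ctx, paste0(name, ".ca_small"), small)))
    if (!is.null(large))
      parts <- c(parts, list(nn_channel_attention(ctx, paste0(name, ".ca_large"), large)))
  } else {
    parts <- c(parts, list(small))
    if (!is.null(large)) parts <- c(parts, list(large))
  }
  y <- ag_concat(parts)
  if (mfda) y <- nn_spatial_attention(ctx, paste0(name, ".sa"), y)
  ins <- shape3(y)
  out <- nn_conv_bn_act(ctx, paste0(name, ".fuse"), y, 1L, out_ch)
  trace_row(ctx, paste0("Fusion branch ", sub("^fuse", "", name)),
            sprintf("1x1x%d", out_ch), ins, shape3(out))
  out
}

forward_deep_shallow <- function(ctx, taps) {
  fc <- ctx$cfg$branch_channels
  mfda <- ctx$cfg$toggles$mfda
  b26 <- nn_fuse_branch(ctx, "fuse26", taps$p4,
                        ag_upsample2(taps$p5), ag_maxpool2(taps$p3), fc, mfda)
  b52 <- nn_fuse_branch(ctx, "fuse52", taps$p3,
                        ag_upsample2(taps$p4), ag_maxpool2(taps$p2), fc, mfda)
  b104 <- nn_fuse_branch(ctx, "fuse104", taps$p2,
                         ag_upsample2(taps$p3), NULL, fc, mfda)
  list(b104 = b104, b52 = b52, b26 = b26)
}

# FPN baseline: 1x1 laterals, nearest 2x top-down, element-wise addition.
# When mfda is on, channel attention gates each up-sampled top-down map and
# spatial attention gates each merged map.
forward_fpn <- function(ctx, taps) {
  fc <- ctx$cfg$branch_channels
  mfda <- ctx$cfg$toggles$mfda
  lat <- function(name, t) nn_conv_bn_act(ctx, name, t, 1L, fc)
  merge <- function(name, lateral, deeper) {
    td <- ag_upsample2(deeper)
    if (mfda) td <- nn_channel_attention(ctx, paste0(name, ".ca"), td)
    m <- ag_add(lateral, td)
    if (mfda) m <- nn_spatial_attention(ctx, paste0(name, ".sa"), m)
    m
  }
  l5 <- lat("fpn.l5", taps$p5)
  m4 <- merge("fpn.m4", lat("fpn.l4", taps$p4), l5)
  m3 <- merge("fpn.m3", lat("fpn.l3", taps$p3), m4)
  m2 <- merge("fpn.m2", lat("fpn.l2", taps$p2), m3)
  for (nm in c("m2", "m3", "m4")) {
    b <- get(nm)
    trace_row(ctx, paste0("FPN branch ", nm), sprintf("1x1x%d", fc),
              shape3(b), shape3(b))
  }
  list(b104 = m2, b52 = m3, b26 = m4)
}

forward_fusion <- function(ctx, taps) {
  if (ctx$cfg$toggles$deep_shallow_fusion) forward_deep_shallow(ctx, taps)
  else forward_fpn(ctx, taps)
}

forward_heads <- function(ctx, branches) {
  cfg <- ctx$cfg
  a <- cfg$anchors_per_branch
  per <- 5L + cfg$num_classes
  obj <- (seq_len(a) - 1L) * per + 5L
  lapply(stats::setNames(names(branches), names(branches)), function(nm) {
    raw <- nn_conv_head(ctx, paste0("head.", nm), branches[[nm]], a * per, obj)
    trace_row(ctx, paste0("Detection head ", nm), sprintf("1x1x%d", a * per),
              shape3(branches[[nm]]), shape3(raw))
    raw
  })
}

forward_model_graph <- function(ctx, x) {
  taps <- forward_backbone(ctx, x)
  branches <- forward_fusion(ctx, taps)
  raws <- forward_heads(ctx, branches)
  list(taps = taps, branches = branches, raws = raws)
}
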