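#' Architecture configuration
#'
#' Describes a detector instance: input resolution, class count, the
#' channel widths of the four Light-CSP stages, the width of the fused
#' detection branches, and the three component toggles that realize the
#' ablation variants (plain versus cross-scale-fusion down-sampling, FPN
#' versus deep-shallow fusion, dual attention on or off).
#'
#' Stage widths are `(C1, C2)` pairs; each stage consumes `C1` channels and
#' emits `C1 + 2*C2`, so consecutive stages must chain
#' (`C1[k+1] = C1[k] + 2*C2[k]`). The defaults give the reference network:
#' stages (64,32), (128,64), (256,128), (512,256) with multi-scale taps of
#' 128, 256, 512 and 512 channels at strides 4, 8, 16 and 32 for a 416 input.
#'
#' @param input_size Reference input resolution in pixels; must be divisible
#'   by 32.
#' @param num_classes Number of object classes (single fruit class by default).
#' @param anchors_per_branch Anchor priors per detection branch.
#' @param stage_widths List of four `(C1, C2)` integer pairs.
#' @param branch_channels Channels emitted by each fusion branch's 1x1 merge.
#' @param mfda,proposed_downsampling,deep_shallow_fusion Component toggles.
#'   All off reproduces the baseline variant (conv stem + FPN); switching
#'   them on in that order reproduces variants 2-4 of the component ablation.
#' @param attention_reduction Channel-attention bottleneck reduction ratio.
#' @param spatial_kernel Spatial-attention convolution kernel (odd).
#' @param bn_epsilon,bn_momentum,leaky_slope Batch-norm and activation
#'   constants.
#' @param seed Seed for weight initialization in [build_model()].
#' @return An object of class `lightcsp_arch`.
#' @export
#' @examples
#' cfg <- arch_config(input_size = 320)
#' profile_model(cfg)
arch_config <- function(input_size = 416L,
                        num_classes = 1L,
                        anchors_per_branch = 3L,
                        stage_widths = list(c(64L, 32L), c(128L, 64L),
                                            c(256L, 128L), c(512L, 256L)),
                        branch_channels = 128L,
                        mfda = TRUE,
                        proposed_downsampling = TRUE,
                        deep_shallow_fusion = TRUE,
                        attention_reduction = 16L,
                        spatial_kernel = 7L,
                        bn_epsilon = 1e-5,
                        bn_momentum = 0.03,
                        leaky_slope = 0.1,
                        seed = 1L) {
  cfg <- structure(list(
    input_size = as.integer(input_size),
    num_classes = as.integer(num_classes),
    anchors_per_branch = as.integer(anchors_per_branch),
    stage_widths = lapply(stage_widths, as.integer),
    branch_channels = as.integer(branch_channels),
    toggles = list(mfda = isTRUE(mfda),
                   proposed_downsampling = isTRUE(proposed_downsampling),
                   deep_shallow_fusion = isTRUE(deep_shallow_fusion)),
    attention_reduction = as.integer(attention_reduction),
    spatial_kernel = as.integer(spatial_kernel),
    bn_epsilon = bn_epsilon,
    bn_momentum = bn_momentum,
    leaky_slope = leaky_slope,
    seed = as.integer(seed)), class = "lightcsp_arch")
  validate_arch(cfg)
  cfg
}

validate_arch <- function(cfg) {
  if (cfg$input_size %% 32L != 0L)
    stop("input_size must be divisible by 32, got ", cfg$input_size)
  if (length(cfg$stage_widths) != 4L)
    stop("stage_widths must list four (C1, C2) pairs")
  for (i in 1:4) {
    w <- cfg$stage_widths[[i]]
    if (length(w) != 2L || any(w < 1L)) stop("invalid stage width pair ", i)
    if (i < 4L) {
      nxt <- cfg$stage_widths[[i + 1L]][1]
      if (nxt != w[1] + 2L * w[2])
        stop("stage widths must chain: stage ", i + 1L, " expects C1 = ",
             w[1] + 2L * w[2], ", got ", nxt)
    }
  }
  if (cfg$stage_widths[[1]][1] %% 2L != 0L)
    stop("first stage C1 must be even (stem uses C1/2 then C1 channels)")
  if (cfg$num_classes < 1L) stop("num_classes must be at least 1")
  invisible(cfg)
}

#' Instantiate a detector
#'
#' Materializes all weights (He initialization, seeded from the
#' configuration), batch-norm statistics and layer bookkeeping by tracing
#' the forward graph once.
#'
#' @param cfg An [arch_config()].
#' @return An object of class `lightcsp_model`: the configuration, a named
#'   list of parameter arrays, batch-norm running statistics, detection
#'   strides, and (once assigned) an anchor set.
#' @export
build_model <- function(cfg = arch_config()) {
  validate_arch(cfg)
  ctx <- ctx_new(cfg, mode = "init")
  local_seed(cfg$seed, {
    x <- ag_node(array(0, c(64, 64, 3, 1)))
    forward_model_graph(ctx, x)
  })
  structure(list(cfg = cfg,
                 params = mget(ctx$order, envir = ctx$params),
                 buffers = mget(ctx$border, envir = ctx$buffers),
                 strides = c(b104 = 4L, b52 = 8L, b26 = 16L),
                 anchors = NULL),
            class = "lightcsp_model")
}

#' @export
print.lightcsp_model <- function(x, ...) {
  tg <- x$cfg$toggles
  cat("<lightcsp_model>\n")
  cat(sprintf("  input %dx%d, %d class(es), %s anchors\n",
              x$cfg$input_size, x$cfg$input_size, x$cfg$num_classes,
              if (is.null(x$anchors)) "no" else "9"))
  cat(sprintf("  toggles: mfda=%s, proposed_downsampling=%s, deep_shallow_fusion=%s\n",
              tg$mfda, tg$proposed_downsampling, tg$deep_shallow_fusion))
  cat(sprintf("  parameters: %.2f M (%d tensors)\n",
              count_params(x), length(x$params)))
  invisible(x)
}

# Run the full graph on a plain array. Returns node lists; internal.
model_ctx_forward <- function(model, x, training = FALSE) {
  ctx <- ctx_new(model$cfg, params = model$params, buffers = model$buffers,
                 mode = if (training) "train" else "eval")
  out <- forward_model_graph(ctx, as_node(as_batch(x)))
  list(ctx = ctx, out = out)
}

#' Forward pass of a detector
#'
#' @param model A [build_model()] result.
#' @param x Image array `(H, W, 3)` or batch `(H, W, 3, N)` with values in
#'   `[0, 1]`; spatial size divisible by 32.
#' @param taps Also return the four backbone feature taps.
#' @return List with `raws` (raw head outputs per branch, highest resolution
#'   first) and optionally `taps`.
#' @export
model_forward <- function(model, x, taps = FALSE) {
  r <- model_ctx_forward(model, x, training = FALSE)
  out <- list(raws = lapply(r$out$raws, function(n) n$value))
  if (taps) out$taps <- lapply(r$out$taps, function(n) n$value)
  out
}

#' Backbone-only network
#'
#' Builds just the feature-extraction trunk and exposes its four multi-scale
#' taps (strides 4, 8, 16, 32).
#'
#' @inheritParams build_model
#' @return An object of class `lightcsp_backbone`.
#' @export
build_backbone <- function(cfg = arch_config()) {
  validate_arch(cfg)
  ctx <- ctx_new(cfg, mode = "init")
  local_seed(cfg$seed, forward_backbone(ctx, ag_node(array(0, c(64, 64, 3, 1)))))
  structure(list(cfg = cfg,
                 params = mget(ctx$order, envir = ctx$params),
                 buffers = mget(ctx$border, envir = ctx$buffers)),
            class = "lightcsp_backbone")
}

#' Backbone feature taps for an input
#'
#' @param backbone A [build_backbone()] (or full [build_model()]) object.
#' @param x Image array `(H, W, 3)` or batch; spatial size divisible by 32.
#' @return Named list of arrays `p2` (stride 4), `p3` (stride 8),
#'   `p4` (stride 16), `p5` (stride 32).
#' @export
backbone_taps <- function(backbone, x) {
  ctx <- ctx_new(backbone$cfg, params = backbone$params,
                 buffers = backbone$buffers, mode = "eval")
  taps <- forward_backbone(ctx, as_node(as_batch(x)))
  lapply(taps, function(n) n$value)
}

## ---- functional single-operation wrappers ---------------------------------
# Each building block is also callable on a plain array, initializing its
# own (seeded) weights unless a parameter bundle from a previous call is
# passed back in. The bundle is attached to the result as attr "params".

wrap_op <- function(x, params, seed, fn, cfg = arch_config()) {
  squeeze <- length(dim(x)) == 3L
  mode <- if (is.null(params)) "init" else "eval"
  ctx <- ctx_new(cfg, params = params$params, buffers = params$buffers,
                 mode = mode)
  node <- local_seed(seed, fn(ctx, ag_node(as_batch(x))))
  finish_op(ctx, node, squeeze)
}

finish_op <- function(ctx, node, squeeze) {
  grab <- function(n) if (squeeze) array(n$value, dim(n$value)[1:3]) else n$value
  out <- if (is.list(node)) lapply(node, grab) else grab(node)
  pl <- if (length(ctx$order)) mget(ctx$order, envir = ctx$params)
        else as.list(ctx$params)
  attr(out, "params") <- list(
    params = pl,
    buffers = if (length(ctx$border)) mget(ctx$border, envir = ctx$buffers)
              else as.list(ctx$buffers))
  out
}

#' Convolution + batch norm + Leaky ReLU layer
#'
#' The standard layer of the network: a same-padded convolution (kernel 1 or
#' 3, stride 1 or 2) followed by batch normalization and Leaky ReLU
#' (slope 0.1). At stride 2 an even input halves exactly.
#'
#' @param x Feature-map array `(H, W, C)` or `(H, W, C, N)`.
#' @param kernel Kernel size, 1 or 3.
#' @param out_channels Output channels.
#' @param stride 1 or 2.
#' @param params Parameter bundle from a previous call (attr `"params"`), or
#'   `NULL` to initialize.
#' @param bn,act Disable normalization / activation (used by numeric
#'   fixtures).
#' @param seed Initialization seed when `params` is `NULL`.
#' @return Output feature map with the parameter bundle attached.
#' @export
#' @examples
#' y <- conv_bn_act(array(runif(416 * 416 * 3), c(416, 416, 3)), 3, 32, 2)
#' dim(y) # 208 208 32
conv_bn_act <- function(x, kernel, out_channels, stride = 1L, params = NULL,
                        bn = TRUE, act = TRUE, seed = 1L) {
  stopifnot(kernel %in% c(1L, 3L), stride %in% c(1L, 2L))
  wrap_op(x, params, seed, function(ctx, n)
    nn_conv_bn_act(ctx, "conv", n, as.integer(kernel),
                   as.integer(out_channels), as.integer(stride),
                   bn = bn, act = act))
}

#' Cross-scale-fusion down-sampling operator
#'
#' Two parallel stride-2 paths over the full input (3x3 and 1x1
#' convolutions), concatenated and merged by a 1x1 convolution; spatial size
#' halves, channel count becomes `out_channels`. Odd spatial dimensions are
#' an error rather than silently padded.
#'
#' @inheritParams conv_bn_act
#' @export
cross_scale_downsample <- function(x, out_channels, params = NULL, bn = TRUE,
                                   seed = 1L) {
  wrap_op(x, params, seed, function(ctx, n)
    nn_cross_scale(ctx, "down", n, as.integer(out_channels), bn = bn))
}

#' Light-CSP block
#'
#' The nested miniature cross-stage block: a 3x3 convolution to `C1`
#' channels whose output feeds both an identity branch and a nested pair of
#' 3x3 convolutions to `C2` channels; the nested outputs are concatenated,
#' passed through a 1x1 transition of `2*C2` filters, and re-joined with the
#' identity branch. Output has `C1 + 2*C2` channels at unchanged spatial
#' size.
#'
#' @inheritParams conv_bn_act
#' @param C1,C2 Stage channel widths; the input must carry `C1` channels.
#' @export
light_csp_block <- function(x, C1, C2, params = NULL, seed = 1L) {
  wrap_op(x, params, seed, function(ctx, n)
    nn_light_csp(ctx, "block", n, as.integer(C1), as.integer(C2)))
}

#' Channel attention gate
#'
#' Global average- and max-pooled channel descriptors pass a shared
#' two-layer bottleneck (reduction ratio `reduction`), are summed and
#' sigmoid-gated; the input is rescaled channel-wise. Shape preserved.
#'
#' @inheritParams conv_bn_act
#' @param reduction Bottleneck reduction ratio; must divide and be smaller
#'   than the channel count.
#' @export
channel_attention <- function(x, reduction = 16L, params = NULL, seed = 1L) {
  wrap_op(x, params, seed, function(ctx, n)
    nn_channel_attention(ctx, "ca", n, as.integer(reduction)))
}

#' Spatial attention gate
#'
#' Per-pixel channel mean and max maps are concatenated, convolved (odd
#' kernel) to a single channel and sigmoid-gated; the input is rescaled
#' pixel-wise. Shape preserved.
#'
#' @inheritParams conv_bn_act
#' @param kernel Odd convolution kernel size (default 7).
#' @export
spatial_attention <- function(x, kernel = 7L, params = NULL, seed = 1L) {
  wrap_op(x, params, seed, function(ctx, n)
    nn_spatial_attention(ctx, "sa", n, as.integer(kernel)))
}

#' Dual-attention multiscale fusion of one branch
#'
#' `x_small` (the deeper map, already 2x up-sampled) and optionally
#' `x_large` (the shallower map, already 2x down-sampled) are gated by
#' channel attention, concatenated with the equal-scale map, gated by
#' spatial attention and merged to `out_channels` by a 1x1 convolution.
#'
#' @param x_equal,x_small,x_large Aligned feature maps (equal spatial size);
#'   `x_large` may be `NULL` for the highest-resolution branch.
#' @param out_channels Output channels of the 1x1 merge.
#' @param reduction Channel-attention bottleneck reduction.
#' @inheritParams conv_bn_act
#' @export
mfda_fuse <- function(x_equal, x_small, x_large = NULL, out_channels = 128L,
                      reduction = 16L, params = NULL, seed = 1L) {
  d <- dim(x_equal)
  for (o in list(x_small, x_large))
    if (!is.null(o) && !identical(dim(o)[1:2], d[1:2]))
      stop("fusion inputs must share the equal-scale spatial size")
  squeeze <- length(d) == 3L
  mode <- if (is.null(params)) "init" else "eval"
  ctx <- ctx_new(arch_config(attention_reduction = reduction),
                 params = params$params, buffers = params$buffers,
                 mode = mode)
  node <- local_seed(seed, nn_fuse_branch(
    ctx, "fuse", ag_node(as_batch(x_equal)), ag_node(as_batch(x_small)),
    if (is.null(x_large)) NULL else ag_node(as_batch(x_large)),
    as.integer(out_channels), mfda = TRUE))
  finish_op(ctx, node, squeeze)
}

#' Deep-shallow fusion of the backbone taps
#'
#' Produces the three detection branches (strides 4, 8, 16). Branch
#' resolution r fuses the equal-scale tap with the next deeper tap
#' (up-sampled) and, where one exists, the next shallower tap
#' (down-sampled), honouring the `mfda` and `deep_shallow_fusion` toggles of
#' `cfg` (with deep-shallow fusion off this is the FPN baseline).
#'
#' @param taps Named list `p2`, `p3`, `p4`, `p5` of tap arrays, e.g. from
#'   [backbone_taps()].
#' @param cfg An [arch_config()].
#' @inheritParams conv_bn_act
#' @return List of three branch feature maps `b104`, `b52`, `b26` (highest
#'   resolution first), parameter bundle attached.
#' @export
deep_shallow_fuse <- function(taps, cfg = arch_config(), params = NULL,
                              seed = 1L) {
  squeeze <- length(dim(taps[[1]])) == 3L
  mode <- if (is.null(params)) "init" else "eval"
  ctx <- ctx_new(cfg, params = params$params, buffers = params$buffers,
                 mode = mode)
  nodes <- lapply(taps, function(t) ag_node(as_batch(t)))
  out <- local_seed(seed, forward_fusion(ctx, nodes))
  finish_op(ctx, out, squeeze)
}

#' FPN baseline fusion
#'
#' Standard top-down pathway: 1x1 lateral convolutions, nearest 2x
#' up-sampling and element-wise addition, emitting the same three branch
#' scales as [deep_shallow_fuse()]. Used as the ablation baseline.
#'
#' @inheritParams deep_shallow_fuse
#' @export
fpn_fuse <- function(taps, cfg = arch_config(), params = NULL, seed = 1L) {
  cfg$toggles$deep_shallow_fusion <- FALSE
  cfg$toggles$mfda <- FALSE
  deep_shallow_fuse(taps, cfg, params, seed)
}

#' Detection head convolution
#'
#' A 1x1 convolution with bias and no normalization or activation mapping a
#' branch feature map to `anchors_per_cell * (5 + num_classes)` channels
#' (four box offsets, objectness, class scores per anchor).
#'
#' @param branch Branch feature map array.
#' @param num_classes Number of classes.
#' @param anchors_per_cell Anchors per grid cell (3 by default).
#' @inheritParams conv_bn_act
#' @export
#' @examples
#' f <- array(rnorm(13 * 13 * 512), c(13, 13, 512))
#' dim(head_conv(f, num_classes = 1))[3] # 18
head_conv <- function(branch, num_classes, anchors_per_cell = 3L,
                      params = NULL, seed = 1L) {
  per <- 5L + as.integer(num_classes)
  obj <- (seq_len(anchors_per_cell) - 1L) * per + 5L
  wrap_op(branch, params, seed, function(ctx, n)
    nn_conv_head(ctx, "head", n, as.integer(anchors_per_cell) * per, obj))
}

#' Trainable-parameter total of a block or model
#'
#' Counts every trainable tensor (convolution kernels, biases, batch-norm
#' scale and shift); running statistics are excluded.
#'
#' @param x A `lightcsp_model`, `lightcsp_backbone`, or a parameter bundle
#'   attached to a functional-op result.
#' @return Parameter count in millions.
#' @export
count_params <- function(x) {
  pl <- if (!is.null(x$params)) x$params else x
  sum(vapply(pl, length, 0)) / 1e6
}

as_batch <- function(x) {
  d <- dim(x)
  if (is.null(d) || !length(d) %in% c(3L, 4L))
    stop("expected an (H, W, C) or (H, W, C, N) array")
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}
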