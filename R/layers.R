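# Forward-pass context and parameter provider.
#
# The same forward code serves four modes:
#   init  - parameters are materialized (He init) the first time a layer asks
#           for them; running a forward trace on a dummy input builds the model
#   train - parameters come from the model, batch norm uses batch statistics
#           and refreshes its running buffers
#   eval  - running statistics, no side effects
#   shape - values are dimension stubs; records parameter shapes, per-block
#           rows and FLOPs without computing anything
# Keeping a single code path guarantees the profiler can never drift from the
# network actually being trained.

ctx_new <- function(cfg, params = NULL, buffers = NULL,
                    mode = c("eval", "train", "init", "shape")) {
  mode <- match.arg(mode)
  ctx <- new.env(parent = emptyenv())
  ctx$cfg <- cfg
  ctx$mode <- mode
  ctx$training <- mode == "train"
  ctx$params <- new.env(parent = emptyenv())
  ctx$nodes <- new.env(parent = emptyenv())
  ctx$buffers <- new.env(parent = emptyenv())
  ctx$order <- character(0)
  ctx$border <- character(0)
  ctx$pshapes <- list()
  ctx$rows <- list()
  if (!is.null(params))
    for (nm in names(params)) assign(nm, params[[nm]], envir = ctx$params)
  if (!is.null(buffers))
    for (nm in names(buffers)) assign(nm, buffers[[nm]], envir = ctx$buffers)
  ctx
}

# Fetch (or create) a parameter leaf node.
px_param <- function(ctx, name, dims, init_fn) {
  if (ctx$mode == "shape") {
    ctx$pshapes[[name]] <- as.integer(dims)
    return(ag_node(lc_shape(dims)))
  }
  if (!is.null(ctx$nodes[[name]])) return(ctx$nodes[[name]])
  if (is.null(ctx$params[[name]])) {
    if (ctx$mode != "init") stop("missing parameter '", name, "'")
    v <- init_fn(dims)
    if (length(dims) > 1L) v <- array(v, dims)
    assign(name, v, envir = ctx$params)
    ctx$order <- c(ctx$order, name)
  }
  n <- ag_node(ctx$params[[name]])
  assign(name, n, envir = ctx$nodes)
  n
}

px_bn_buffers <- function(ctx, name, cout) {
  km <- paste0(name, ".rmean")
  if (is.null(ctx$buffers[[km]])) {
    if (ctx$mode != "init") stop("missing batch-norm buffer '", km, "'")
    assign(km, rep(0, cout), envir = ctx$buffers)
    assign(paste0(name, ".rvar"), rep(1, cout), envir = ctx$buffers)
    ctx$border <- c(ctx$border, km, paste0(name, ".rvar"))
  }
  invisible(NULL)
}

trace_row <- function(ctx, block, filters, ins, outs) {
  ctx$rows[[length(ctx$rows) + 1L]] <- list(
    block = block, filters = filters,
    in_h = ins[1], in_w = ins[2], in_c = ins[3],
    out_h = outs[1], out_w = outs[2], out_c = outs[3])
  invisible(NULL)
}

shape3 <- function(node) vdim(node$value)[1:3]

## ---- layer helpers ---------------------------------------------------------

# Convolution + batch norm + Leaky ReLU, the standard layer of the network.
nn_conv_bn_act <- function(ctx, name, x, k, cout, stride = 1L,
                           bn = TRUE, act = TRUE) {
  cin <- vdim(x$value)[3]
  w <- px_param(ctx, paste0(name, ".w"), c(k, k, cin, cout),
                function(d) rnorm(prod(d), 0, sqrt(2 / (k * k * cin))))
  y <- ag_conv2d(x, w, stride)
  if (bn) {
    g <- px_param(ctx, paste0(name, ".bn.gamma"), cout, function(d) rep(1, prod(d)))
    b <- px_param(ctx, paste0(name, ".bn.beta"), cout, function(d) rep(0, prod(d)))
    if (ctx$mode != "shape") px_bn_buffers(ctx, name, cout)
    y <- ag_bn(y, g, b, ctx$buffers, name,
               ctx$cfg$bn_epsilon, ctx$cfg$bn_momentum, ctx$training)
  }
  if (act) y <- ag_leaky(y, ctx$cfg$leaky_slope)
  y
}

# Bare 1x1 prediction convolution: bias, no norm, no activation. Objectness
# biases start at -4 so the untrained detector is near-silent (the standard
# prior-probability initialization for dense single-stage heads).
nn_conv_head <- function(ctx, name, x, cout, obj_channels = integer(0)) {
  cin <- vdim(x$value)[3]
  w <- px_param(ctx, paste0(name, ".w"), c(1L, 1L, cin, cout),
                function(d) rnorm(prod(d), 0, 0.01))
  b <- px_param(ctx, paste0(name, ".b"), cout, function(d) {
    v <- rep(0, prod(d))
    v[obj_channels] <- -4
    v
  })
  ag_bias(ag_conv2d(x, w, 1L), b)
}

# Cross-scale-fusion down-sampling: a 3x3 stride-2 path and a 1x1 stride-2
# path over the full input, concatenated and merged by a 1x1 convolution.
nn_cross_scale <- function(ctx, name, x, cout, bn = TRUE) {
  d <- vdim(x$value)
  if (d[1] %% 2L || d[2] %% 2L)
    stop("cross-scale down-sampling requires even spatial dims, got ",
         d[1], "x", d[2])
  a <- nn_conv_bn_act(ctx, paste0(name, ".a"), x, 3L, cout, 2L, bn = bn)
  b <- nn_conv_bn_act(ctx, paste0(name, ".b"), x, 1L, cout, 2L, bn = bn)
  nn_conv_bn_act(ctx, paste0(name, ".fuse"), ag_concat(list(b, a)), 1L, cout,
                 bn = bn)
}

# Light-CSP block. Duplicate-routing semantics: the full 3x3 output X feeds
# both the identity branch and the nested transform branch; the nested pair
# (Y, Z) is concatenated, passed through the 1x1 transition and re-joined
# with X, giving C1 + 2*C2 output channels. When `final`, the block stops at
# the 2*C2-channel concatenation (the deepest stage has no transition of its
# own; its listed transition is the single-scale detection head).
nn_light_csp <- function(ctx, name, x, C1, C2, final = FALSE) {
  cin <- vdim(x$value)[3]
  if (cin != C1)
    stop("Light-CSP block '", name, "' expects ", C1, " input channels, got ", cin)
  ins <- shape3(x)
  X <- nn_conv_bn_act(ctx, paste0(name, ".conv1"), x, 3L, C1)
  Y <- nn_conv_bn_act(ctx, paste0(name, ".conv2"), X, 3L, C2)
  Z <- nn_conv_bn_act(ctx, paste0(name, ".conv3"), Y, 3L, C2)
  Yt <- ag_concat(list(Y, Z))
  trace_row(ctx, "Light-CSP block",
            sprintf("3x3x%d 3x3x%d 3x3x%d", C1, C2, C2), ins, shape3(Yt))
  if (final) return(Yt)
  tr <- nn_conv_bn_act(ctx, paste0(name, ".trans"), Yt, 1L, 2L * C2)
  out <- ag_concat(list(X, tr))
  trace_row(ctx, "(Transition filter)", sprintf("1x1x%d", 2L * C2),
            shape3(Yt), shape3(out))
  out
}

# Backbone assembly: two low-rate down-sampling stages (cross-scale fusion
# when enabled, plain stride-2 convolutions otherwise), then four Light-CSP
# stages separated by 2x2 max-pooling at the high down-sampling rates.
forward_backbone <- function(ctx, x) {
  cfg <- ctx$cfg
  sw <- cfg$stage_widths
  c1 <- sw[[1]][1]
  stem_w <- c(c1 %/% 2L, c1)
  h <- x
  for (i in 1:2) {
    ins <- shape3(h)
    if (cfg$toggles$proposed_downsampling) {
      h <- nn_cross_scale(ctx, paste0("stem", i), h, stem_w[i])
      trace_row(ctx, "Down-sampling method based on cross-scale fusion",
                sprintf("1x1x%d 3x3x%d (Stride = 2) 1x1x%d",
                        stem_w[i], stem_w[i], stem_w[i]), ins, shape3(h))
    } else {
      h <- nn_conv_bn_act(ctx, paste0("stem", i), h, 3L, stem_w[i], 2L)
      trace_row(ctx, "Conv down-sampling",
                sprintf("3x3x%d (Stride = 2)", stem_w[i]), ins, shape3(h))
    }
  }
  taps <- vector("list", 4L)
  for (i in 1:4) {
    if (i > 1L) {
      ins <- shape3(h)
      h <- ag_maxpool2(h)
      trace_row(ctx, "Maxpool", "Stride = 2", ins, shape3(h))
    }
    h <- nn_light_csp(ctx, paste0("stage", i), h,
                      sw[[i]][1], sw[[i]][2], final = (i == 4L))
    taps[[i]] <- h
  }
  names(taps) <- c("p2", "p3", "p4", "p5")
  taps
}
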