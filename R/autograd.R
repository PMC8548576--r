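# Reverse-mode differentiation over (H, W, C, N) feature-map arrays.
#
# A node is an environment holding a value, its accumulated gradient, the
# parent nodes it was computed from, and a backward closure mapping the
# node's upstream gradient to per-parent gradients. backward() runs a
# topological sweep from a scalar loss node. Heavy kernels (convolution,
# batch norm, pooling, resampling) are compiled; elementwise math stays in R.
#
# Every op also supports a shape-propagation mode: when a node's value is an
# `lc_shape` stub (dimensions, no data) the op emits an output stub and, if
# profiling is active, adds its FLOP cost to the accumulator. This lets
# profile_model() and count_flops() walk the exact forward code path without
# touching any numbers.

lc_shape <- function(d) structure(list(dim = as.integer(d)), class = "lc_shape")
is_shape <- function(v) inherits(v, "lc_shape")
vdim <- function(v) if (is_shape(v)) v$dim else dim(v)
numel <- function(v) prod(vdim(v))

prof_add <- function(n) {
  if (.lc_prof$active) .lc_prof$flops <- .lc_prof$flops + n
  invisible(NULL)
}

ag_node <- function(value, parents = list(), backfn = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$parents <- parents
  n$backfn <- backfn
  class(n) <- "ag_node"
  n
}

as_node <- function(x) if (inherits(x, "ag_node")) x else ag_node(x)

# Topological order of the graph rooted at `root` (parents before children).
ag_topo <- function(root) {
  out <- vector("list", 256L)
  k <- 0L
  token <- new.env(parent = emptyenv())
  visit <- function(n) {
    if (identical(n$.seen, token)) return(invisible(NULL))
    n$.seen <- token
    for (p in n$parents) visit(p)
    k <<- k + 1L
    if (k > length(out)) length(out) <<- 2L * k
    out[[k]] <<- n
    invisible(NULL)
  }
  visit(root)
  out[seq_len(k)]
}

# Accumulate gradients into every node reachable from `root`. The root is
# seeded with 1 (scalar losses) unless an explicit gradient is supplied.
ag_backward <- function(root, grad = NULL) {
  topo <- ag_topo(root)
  for (n in topo) n$grad <- NULL
  root$grad <- if (is.null(grad)) {
    if (length(root$value) == 1L) 1 else array(1, dim(root$value))
  } else grad
  for (n in rev(topo)) {
    if (is.null(n$backfn) || is.null(n$grad)) next
    gs <- n$backfn(n$grad)
    for (i in seq_along(n$parents)) {
      g <- gs[[i]]
      if (is.null(g)) next
      p <- n$parents[[i]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(root)
}

## ---- primitive ops ---------------------------------------------------------

ag_conv2d <- function(x, w, stride = 1L) {
  x <- as_node(x); w <- as_node(w)
  if (is_shape(x$value)) {
    wd <- vdim(w$value); xd <- vdim(x$value)
    if (wd[3] != xd[3])
      stop("channel mismatch: input has ", xd[3], ", kernel expects ", wd[3])
    k <- wd[1]; pad <- k %/% 2L
    ho <- (xd[1] + 2L * pad - k) %/% stride + 1L
    wo <- (xd[2] + 2L * pad - k) %/% stride + 1L
    if (ho < 1L || wo < 1L) stop("non-positive output spatial size")
    prof_add(2 * k * k * xd[3] * wd[4] * ho * wo * xd[4])
    return(ag_node(lc_shape(c(ho, wo, wd[4], xd[4]))))
  }
  k <- dim(w$value)[1]
  pad <- k %/% 2L
  y <- conv2d_fwd_cpp(x$value, w$value, as.integer(stride), pad)
  ag_node(y, list(x, w), function(g) {
    b <- conv2d_bwd_cpp(x$value, w$value, g, as.integer(stride), pad)
    list(b$dx, b$dw)
  })
}

# Per-channel bias (head convolutions only; everything else is conv+BN).
ag_bias <- function(x, b) {
  x <- as_node(x); b <- as_node(b)
  if (is_shape(x$value)) {
    prof_add(numel(x$value))
    return(ag_node(x$value))
  }
  d <- dim(x$value)
  hw <- d[1] * d[2]
  y <- x$value + rep(rep(b$value, each = hw), d[4])
  ag_node(y, list(x, b), function(g) {
    cs <- colSums(matrix(g, hw))
    list(g, rowSums(matrix(cs, d[3], d[4])))
  })
}

# Batch norm; running-stat buffers live in `buffers` (an environment) under
# `<name>.rmean` / `<name>.rvar` and are refreshed as a forward side effect
# when training.
ag_bn <- function(x, gamma, beta, buffers, name, eps, momentum, training) {
  x <- as_node(x); gamma <- as_node(gamma); beta <- as_node(beta)
  if (is_shape(x$value)) {
    prof_add(2 * numel(x$value))
    return(ag_node(x$value))
  }
  km <- paste0(name, ".rmean"); kv <- paste0(name, ".rvar")
  r <- bn_fwd_cpp(x$value, gamma$value, beta$value,
                  buffers[[km]], buffers[[kv]], eps, momentum, training)
  if (training) {
    buffers[[km]] <- r$rmean
    buffers[[kv]] <- r$rvar
  }
  ag_node(r$y, list(x, gamma, beta), function(g) {
    b <- bn_bwd_cpp(x$value, gamma$value, r$mean, r$invstd, g, training)
    list(b$dx, b$dgamma, b$dbeta)
  })
}

ag_leaky <- function(x, slope = 0.1) {
  x <- as_node(x)
  if (is_shape(x$value)) {
    prof_add(numel(x$value))
    return(ag_node(x$value))
  }
  y <- leaky_fwd_cpp(x$value, slope)
  ag_node(y, list(x), function(g) list(leaky_bwd_cpp(x$value, g, slope)))
}

ag_relu <- function(x) {
  x <- as_node(x)
  if (is_shape(x$value)) {
    prof_add(numel(x$value))
    return(ag_node(x$value))
  }
  neg <- x$value < 0
  y <- x$value
  y[neg] <- 0
  ag_node(y, list(x), function(g) {
    dg <- g
    dg[neg] <- 0
    list(dg)
  })
}

ag_sigmoid <- function(x) {
  x <- as_node(x)
  if (is_shape(x$value)) {
    prof_add(numel(x$value))
    return(ag_node(x$value))
  }
  y <- 1 / (1 + exp(-x$value))
  ag_node(y, list(x), function(g) list(g * y * (1 - y)))
}

ag_maxpool2 <- function(x) {
  x <- as_node(x)
  if (is_shape(x$value)) {
    d <- vdim(x$value)
    if (d[1] %% 2L || d[2] %% 2L) stop("maxpool2 requires even spatial dims")
    prof_add(prod(d) %/% 4 * 3)
    return(ag_node(lc_shape(c(d[1] %/% 2L, d[2] %/% 2L, d[3], d[4]))))
  }
  r <- maxpool2_fwd_cpp(x$value)
  xd <- dim(x$value)
  ag_node(r$y, list(x), function(g) list(maxpool2_bwd_cpp(g, r$idx, xd)))
}

ag_upsample2 <- function(x) {
  x <- as_node(x)
  if (is_shape(x$value)) {
    d <- vdim(x$value)
    return(ag_node(lc_shape(c(2L * d[1], 2L * d[2], d[3], d[4]))))
  }
  ag_node(upsample2_fwd_cpp(x$value), list(x),
          function(g) list(upsample2_bwd_cpp(g)))
}

# Channel concatenation.
ag_concat <- function(xs) {
  xs <- lapply(xs, as_node)
  if (is_shape(xs[[1]]$value)) {
    ds <- lapply(xs, function(n) vdim(n$value))
    d1 <- ds[[1]]
    return(ag_node(lc_shape(c(d1[1], d1[2], sum(vapply(ds, `[`, 0L, 3L)), d1[4]))))
  }
  ds <- lapply(xs, function(n) dim(n$value))
  d1 <- ds[[1]]
  cc <- vapply(ds, `[`, 0L, 3L)
  for (d in ds)
    if (!identical(d[c(1, 2, 4)], d1[c(1, 2, 4)]))
      stop("concat: spatial/batch mismatch")
  y <- array(0, c(d1[1], d1[2], sum(cc), d1[4]))
  off <- 0L
  for (i in seq_along(xs)) {
    y[, , off + seq_len(cc[i]), ] <- xs[[i]]$value
    off <- off + cc[i]
  }
  ag_node(y, xs, function(g) {
    out <- vector("list", length(xs))
    off <- 0L
    for (i in seq_along(xs)) {
      out[[i]] <- g[, , off + seq_len(cc[i]), , drop = FALSE]
      off <- off + cc[i]
    }
    out
  })
}

ag_add <- function(x, y) {
  x <- as_node(x); y <- as_node(y)
  if (is_shape(x$value)) {
    prof_add(numel(x$value))
    return(ag_node(x$value))
  }
  ag_node(x$value + y$value, list(x, y), function(g) list(g, g))
}

# Global average / max pool over the spatial grid -> (1, 1, C, N).
ag_gap <- function(x) {
  x <- as_node(x)
  if (is_shape(x$value)) {
    d <- vdim(x$value)
    prof_add(prod(d))
    return(ag_node(lc_shape(c(1L, 1L, d[3], d[4]))))
  }
  d <- dim(x$value)
  hw <- d[1] * d[2]
  y <- array(colMeans(matrix(x$value, hw)), c(1, 1, d[3], d[4]))
  ag_node(y, list(x), function(g) {
    list(array(rep(as.vector(g) / hw, each = hw), d))
  })
}

ag_gmp <- function(x) {
  x <- as_node(x)
  if (is_shape(x$value)) {
    d <- vdim(x$value)
    prof_add(prod(d))
    return(ag_node(lc_shape(c(1L, 1L, d[3], d[4]))))
  }
  d <- dim(x$value)
  hw <- d[1] * d[2]
  m <- matrix(x$value, hw)
  wm <- apply(m, 2, which.max)
  y <- array(m[cbind(wm, seq_along(wm))], c(1, 1, d[3], d[4]))
  ag_node(y, list(x), function(g) {
    dm <- matrix(0, hw, ncol(m))
    dm[cbind(wm, seq_along(wm))] <- as.vector(g)
    list(array(dm, d))
  })
}

# Per-pixel statistics across channels -> (H, W, 1, N).
ag_chmean <- function(x) {
  x <- as_node(x)
  if (is_shape(x$value)) {
    d <- vdim(x$value)
    prof_add(prod(d))
    return(ag_node(lc_shape(c(d[1], d[2], 1L, d[4]))))
  }
  d <- dim(x$value)
  y <- chmean_fwd_cpp(x$value)
  ag_node(y, list(x), function(g) {
    list(g[, , rep(1L, d[3]), , drop = FALSE] / d[3])
  })
}

ag_chmax <- function(x) {
  x <- as_node(x)
  if (is_shape(x$value)) {
    d <- vdim(x$value)
    prof_add(prod(d))
    return(ag_node(lc_shape(c(d[1], d[2], 1L, d[4]))))
  }
  xd <- dim(x$value)
  r <- chmax_fwd_cpp(x$value)
  ag_node(r$y, list(x), function(g) list(chmax_bwd_cpp(g, r$idx, xd)))
}

# x * gate with gate of shape (1, 1, C, N): channel-wise rescaling.
ag_scale_channels <- function(x, gate) {
  x <- as_node(x); gate <- as_node(gate)
  if (is_shape(x$value)) {
    prof_add(numel(x$value))
    return(ag_node(x$value))
  }
  d <- dim(x$value)
  hw <- d[1] * d[2]
  ge <- rep(as.vector(gate$value), each = hw)
  y <- x$value * ge
  dim(y) <- d
  ag_node(y, list(x, gate), function(g) {
    dg <- colSums(matrix(g * x$value, hw))
    dx <- g * ge
    dim(dx) <- d
    dim(dg) <- c(1, 1, d[3], d[4])
    list(dx, dg)
  })
}

# x * gate with gate of shape (H, W, 1, N): pixel-wise rescaling.
ag_scale_spatial <- function(x, gate) {
  x <- as_node(x); gate <- as_node(gate)
  if (is_shape(x$value)) {
    prof_add(numel(x$value))
    return(ag_node(x$value))
  }
  y <- scale_spatial_fwd_cpp(x$value, gate$value)
  ag_node(y, list(x, gate), function(g) {
    b <- scale_spatial_bwd_cpp(x$value, gate$value, g)
    list(b$dx, b$dgate)
  })
}
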