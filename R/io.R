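# Label, anchor, image, configuration and checkpoint I/O.

#' Read a normalized label file
#'
#' One object per line: `class cx cy w h`, whitespace-separated, with
#' center/size normalized to `[0, 1]`. An empty (or absent-object) file is a
#' valid background image. Malformed lines and out-of-range values raise an
#' error naming the offending line numbers.
#'
#' @param path Label file path.
#' @return Data frame `class_id`, `cx`, `cy`, `w`, `h`.
#' @export
read_label_file <- function(path) {
  empty <- data.frame(class_id = integer(0), cx = numeric(0), cy = numeric(0),
                      w = numeric(0), h = numeric(0))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  nonempty <- which(nzchar(lines))
  if (!length(nonempty)) return(empty)
  parsed <- lapply(nonempty, function(i) {
    tok <- strsplit(lines[i], "[[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(tok))
    if (length(tok) != 5L || anyNA(vals)) return(i) # malformed marker
    vals
  })
  bad <- vapply(parsed, function(p) length(p) == 1L, TRUE)
  if (any(bad))
    stop("malformed label line(s) in ", path, ": ",
         paste(nonempty[bad], collapse = ", "))
  m <- do.call(rbind, parsed)
  out_of_range <- m[, 2] < 0 | m[, 2] > 1 | m[, 3] < 0 | m[, 3] > 1 |
    m[, 4] <= 0 | m[, 4] > 1 | m[, 5] <= 0 | m[, 5] > 1 | m[, 1] < 0
  if (any(out_of_range))
    stop("label value(s) outside [0, 1] in ", path, " at line(s): ",
         paste(nonempty[out_of_range], collapse = ", "))
  data.frame(class_id = as.integer(m[, 1]), cx = m[, 2], cy = m[, 3],
             w = m[, 4], h = m[, 5])
}

#' Write a normalized label file
#'
#' @param boxes Data frame `class_id`, `cx`, `cy`, `w`, `h`.
#' @param path Output path.
#' @export
write_label_file <- function(boxes, path) {
  lines <- sprintf("%d %.8f %.8f %.8f %.8f", boxes$class_id,
                   boxes$cx, boxes$cy, boxes$w, boxes$h)
  writeLines(lines, path)
  invisible(path)
}

#' Write an anchor file
#'
#' Plain text: a header comment recording the reference input size, then
#' nine `w,h` pixel pairs, one per line, small to large.
#'
#' @param anchors A [cluster_anchors()] result.
#' @param path Output path.
#' @export
write_anchor_file <- function(anchors, path) {
  lines <- c(sprintf("# reference input size: %d", anchors$input_size),
             sprintf("%.4f,%.4f", anchors$anchors[, 1], anchors$anchors[, 2]))
  writeLines(lines, path)
  invisible(path)
}

#' Read an anchor file
#'
#' @param path Anchor file path.
#' @return A `lightcsp_anchors` object.
#' @export
read_anchor_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  size <- if (length(hdr)) as.integer(gsub("[^0-9]", "", hdr[1])) else 416L
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  m <- do.call(rbind, lapply(strsplit(body, ","), as.numeric))
  k <- nrow(m)
  ba <- if (k >= 3L && k %% 3L == 0L)
    split(seq_len(k), rep(seq_len(k %/% 3L), each = 3L))
  else list(seq_len(k))
  structure(list(anchors = m,
                 branch_assignment = ba,
                 input_size = size, objective = numeric(0)),
            class = "lightcsp_anchors")
}

#' Read a PNG image as an `(H, W, 3)` array in `[0, 1]`
#'
#' Grayscale images are expanded to three channels; an alpha channel is
#' dropped.
#'
#' @param path PNG path.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an `(H, W, 3)` array in `[0, 1]` as PNG
#'
#' @param image Image array.
#' @param path Output path.
#' @export
write_image <- function(image, path) {
  png::writePNG(clamp01(image), path)
  invisible(path)
}

#' Serialize / restore a run configuration as YAML
#'
#' The bundle holds the architecture config, training config, evaluation
#' thresholds, paths and seed, and round-trips identically.
#'
#' @param cfg Named list (typically `list(arch =, train =, eval =, paths =,
#'   seed =)`).
#' @param path YAML path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(prep_yaml(cfg), path)
  invisible(path)
}

prep_yaml <- function(x) {
  if (inherits(x, "lightcsp_arch")) x <- unclass(x)
  if (is.list(x)) return(lapply(x, prep_yaml))
  x
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$arch)) {
    a <- cfg$arch
    cfg$arch <- arch_config(
      input_size = a$input_size, num_classes = a$num_classes,
      anchors_per_branch = a$anchors_per_branch,
      stage_widths = a$stage_widths,
      branch_channels = a$branch_channels,
      mfda = a$toggles$mfda,
      proposed_downsampling = a$toggles$proposed_downsampling,
      deep_shallow_fusion = a$toggles$deep_shallow_fusion,
      attention_reduction = a$attention_reduction,
      spatial_kernel = a$spatial_kernel,
      bn_epsilon = a$bn_epsilon, bn_momentum = a$bn_momentum,
      leaky_slope = a$leaky_slope, seed = a$seed)
  }
  cfg
}

#' Save / load a training checkpoint
#'
#' A checkpoint bundles the model (weights, running statistics,
#' configuration, anchors), the training configuration, the iteration
#' counter and the loss log, so training is resumable.
#'
#' @param model A `lightcsp_model`.
#' @param train_cfg A [train_config()].
#' @param iteration Last completed iteration.
#' @param log Loss log data frame.
#' @param path Checkpoint path (`.rds`).
#' @export
save_checkpoint <- function(model, train_cfg, iteration, log, path) {
  saveRDS(list(model = model, train_cfg = train_cfg,
               iteration = iteration, log = log), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

# Short config fingerprint for run logs (not cryptographic).
config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  v <- as.integer(raw)
  h <- 5381
  for (chunk in split(v, ceiling(seq_along(v) / 4096)))
    h <- (h * 33 + sum(chunk * seq_along(chunk))) %% 2^31
  sprintf("%08x", as.integer(h))
}
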