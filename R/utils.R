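# Small shared helpers.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. A NULL seed runs the code with the ambient RNG.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Stable derived seeds that stay inside the 32-bit integer range.
derive_seed <- function(base, i)
  as.integer((as.numeric(base) * 1000003 + as.numeric(i) * 7919) %% 2147483629)

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Bilinear image resize
#'
#' @param image `(H, W, C)` array.
#' @param height,width Output size in pixels.
#' @export
resize_image <- function(image, height, width = height)
  resize_bilinear_cpp(image, as.integer(height), as.integer(width))

#' Convert normalized center-size labels to corner-form pixel boxes
#'
#' @param boxes Data frame with `cx`, `cy`, `w`, `h` in `[0, 1]`.
#' @param width,height Image size in pixels.
#' @return Data frame `x1`, `y1`, `x2`, `y2` (plus `class_id` if present).
#' @export
label_to_corners <- function(boxes, width, height) {
  out <- data.frame(x1 = (boxes$cx - boxes$w / 2) * width,
                    y1 = (boxes$cy - boxes$h / 2) * height,
                    x2 = (boxes$cx + boxes$w / 2) * width,
                    y2 = (boxes$cy + boxes$h / 2) * height)
  if (!is.null(boxes$class_id)) out$class_id <- boxes$class_id
  out
}

#' Convert corner-form pixel boxes to normalized center-size labels
#'
#' @param corners Data frame with `x1`, `y1`, `x2`, `y2` in pixels.
#' @param width,height Image size in pixels.
#' @export
corners_to_label <- function(corners, width, height) {
  out <- data.frame(
    class_id = if (!is.null(corners$class_id)) corners$class_id else 0L,
    cx = (corners$x1 + corners$x2) / 2 / width,
    cy = (corners$y1 + corners$y2) / 2 / height,
    w = (corners$x2 - corners$x1) / width,
    h = (corners$y2 - corners$y1) / height)
  out
}
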