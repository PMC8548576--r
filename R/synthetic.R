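# Seeded synthetic orchard scenes with exact annotations.
#
# Scenes emulate the regimes that make orchard fruit detection hard: many
# small round fruits (radii down to a few pixels, i.e. smaller than one
# stride-32 cell), fruit clusters with mutual occlusion (stacking), leaf-like
# occluders, and global lighting variation. They are deliberately not
# photorealistic; they exist so that detection, training and evaluation can
# be exercised end-to-end with exactly known labels.

#' Synthetic scene parameters
#'
#' @param image_size Square image size in pixels.
#' @param fruit_count_range `(min, max)` fruits attempted per scene.
#' @param radius_range Fruit radius range in pixels (min at least 2; the
#'   lower end exercises the small-target regime).
#' @param cluster_prob Probability that a placement spawns a cluster of 2-4
#'   overlapping fruits.
#' @param occluder_count_range `(min, max)` leaf-shaped occluders.
#' @param brightness_range Global lighting multiplier range.
#' @param fruit_hue_range Fruit hue range in degrees (default ripe-orange).
#' @param drop_visibility Labels are dropped when less than this fraction
#'   of the fruit remains visible (default 0.15: fruits more than 85%
#'   covered are unlabeled).
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(image_size = 416L,
                         fruit_count_range = c(4L, 18L),
                         radius_range = c(3, 40),
                         cluster_prob = 0.3,
                         occluder_count_range = c(2L, 8L),
                         brightness_range = c(0.65, 1.25),
                         fruit_hue_range = c(20, 40),
                         drop_visibility = 0.15) {
  stopifnot(radius_range[1] >= 2, radius_range[2] >= radius_range[1],
            fruit_count_range[1] >= 1,
            fruit_count_range[2] >= fruit_count_range[1],
            occluder_count_range[2] >= occluder_count_range[1],
            brightness_range[2] >= brightness_range[1])
  structure(list(image_size = as.integer(image_size),
                 fruit_count_range = as.integer(fruit_count_range),
                 radius_range = radius_range,
                 cluster_prob = cluster_prob,
                 occluder_count_range = as.integer(occluder_count_range),
                 brightness_range = brightness_range,
                 fruit_hue_range = fruit_hue_range,
                 drop_visibility = drop_visibility),
            class = "scene_params")
}

# Low-frequency value noise upscaled to the image grid.
value_noise <- function(size, cells = 13L) {
  coarse <- array(runif(cells * cells), c(cells, cells, 1L))
  resize_bilinear_cpp(coarse, size, size)[, , 1]
}

sample_int_range <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)

#' Render one synthetic orchard scene
#'
#' Deterministic per seed: a textured green background, shaded elliptical
#' fruits (radial gradient plus a specular highlight) placed singly or in
#' overlapping clusters, then leaf-shaped occluders drawn on top. Later
#' shapes occlude earlier ones; each fruit's visible fraction is tracked and
#' fruits below the visibility floor are dropped from the labels. Boxes are
#' exact ellipse bounding boxes clipped to the image, in the normalized
#' center-size convention.
#'
#' @param params A [scene_params()].
#' @param seed Scene seed.
#' @return List: `image` (`(H, W, 3)` in `[0, 1]`), `boxes` (label data
#'   frame), `visibility` (per labelled fruit), `n_attempted`.
#' @export
render_scene <- function(params = scene_params(), seed = 1L) {
  local_seed(seed, {
    S <- params$image_size
    # background: two coarse fields mixed into a leafy green
    v1 <- value_noise(S); v2 <- value_noise(S, 29L)
    base <- 0.25 + 0.35 * v1 + 0.12 * v2 + 0.04 * matrix(runif(S * S), S)
    img <- array(0, c(S, S, 3))
    img[, , 1] <- base * (0.35 + 0.15 * v2)
    img[, , 2] <- base * (0.85 + 0.15 * v1)
    img[, , 3] <- base * (0.30 + 0.10 * v1)

    n_target <- sample_int_range(params$fruit_count_range)
    rmin <- params$radius_range[1]
    rmax <- min(params$radius_range[2], S / 2 - 2)
    fruits <- list()
    while (length(fruits) < n_target) {
      r <- exp(runif(1, log(rmin), log(rmax)))
      ok <- FALSE
      for (try in 1:20) {
        cx <- runif(1, r + 1, S - r - 1)
        cy <- runif(1, r + 1, S - r - 1)
        ok <- TRUE
        break
      }
      if (!ok) { message("placement failed; rendering fewer fruits"); break }
      members <- list(c(cx, cy, r))
      if (runif(1) < params$cluster_prob) {
        extra <- sample(1:3, 1L)
        for (e in seq_len(extra)) {
          if (length(fruits) + length(members) >= n_target) break
          re <- r * runif(1, 0.7, 1.1)
          ang <- runif(1, 0, 2 * pi)
          dist <- (r + re) * runif(1, 0.45, 0.8) # forced overlap: stacking
          ex <- min(max(cx + dist * cos(ang), re + 1), S - re - 1)
          ey <- min(max(cy + dist * sin(ang), re + 1), S - re - 1)
          members <- c(members, list(c(ex, ey, re)))
        }
      }
      fruits <- c(fruits, members)
    }
    nf <- length(fruits)
    owner <- matrix(0L, S, S)
    total_px <- numeric(nf)
    geom <- matrix(0, nf, 4) # cx, cy, rx, ry
    for (i in seq_len(nf)) {
      f <- fruits[[i]]
      cx <- f[1]; cy <- f[2]; r <- f[3]
      rx <- r * runif(1, 0.85, 1.18); ry <- r * runif(1, 0.85, 1.18)
      geom[i, ] <- c(cx, cy, rx, ry)
      hue <- runif(1, params$fruit_hue_range[1], params$fruit_hue_range[2]) / 360
      sat <- runif(1, 0.75, 0.95)
      rgb <- as.vector(grDevices::col2rgb(grDevices::hsv(hue, sat, 1))) / 255
      rows <- max(1L, floor(cy - ry)):min(S, ceiling(cy + ry))
      cols <- max(1L, floor(cx - rx)):min(S, ceiling(cx + rx))
      dy <- (rows - cy) / ry
      dx <- (cols - cx) / rx
      d2 <- outer(dy^2, dx^2, `+`)
      mask <- d2 <= 1
      if (!any(mask)) next
      shade <- 0.55 + 0.45 * (1 - d2)
      spot <- exp(-(outer((rows - (cy - 0.35 * ry))^2,
                          (cols - (cx - 0.35 * rx))^2, `+`)) / (0.35 * r)^2)
      for (ch in 1:3) {
        plane <- img[rows, cols, ch]
        plane[mask] <- clamp01(rgb[ch] * shade[mask] + 0.3 * spot[mask])
        img[rows, cols, ch] <- plane
      }
      om <- owner[rows, cols]
      om[mask] <- i
      owner[rows, cols] <- om
      total_px[i] <- sum(mask)
    }

    n_occ <- sample_int_range(params$occluder_count_range)
    if (nf > 0) for (o in seq_len(n_occ)) {
      j <- sample(nf, 1L)
      r <- mean(geom[j, 3:4])
      a <- r * runif(1, 0.7, 1.1)          # leaf half-length
      b <- a * runif(1, 0.35, 0.5)         # elongated
      theta <- runif(1, 0, pi)
      ox <- geom[j, 1] + runif(1, -1, 1) * 0.9 * r
      oy <- geom[j, 2] + runif(1, -1, 1) * 0.9 * r
      rows <- max(1L, floor(oy - a)):min(S, ceiling(oy + a))
      cols <- max(1L, floor(ox - a)):min(S, ceiling(ox + a))
      dy <- matrix(rows - oy, length(rows), length(cols))
      dx <- matrix(cols - ox, length(rows), length(cols), byrow = TRUE)
      u <- (dx * cos(theta) + dy * sin(theta)) / a
      w <- (-dx * sin(theta) + dy * cos(theta)) / b
      mask <- u^2 + w^2 <= 1
      if (!any(mask)) next
      g <- 0.35 + 0.25 * (1 - abs(u))
      leaf <- c(0.18, 0.55, 0.20)
      for (ch in 1:3) {
        plane <- img[rows, cols, ch]
        plane[mask] <- clamp01(leaf[ch] * g[mask] * 1.6)
        img[rows, cols, ch] <- plane
      }
      om <- owner[rows, cols]
      om[mask] <- -1L
      owner[rows, cols] <- om
    }

    bright <- runif(1, params$brightness_range[1], params$brightness_range[2])
    img <- clamp01(img * bright)

    visible <- tabulate(owner[owner > 0L], nbins = nf)
    keep <- which(total_px > 0 & visible / total_px >= params$drop_visibility)
    boxes <- data.frame(class_id = integer(0), cx = numeric(0),
                        cy = numeric(0), w = numeric(0), h = numeric(0))
    if (length(keep)) {
      x1 <- pmax(geom[keep, 1] - geom[keep, 3], 0)
      x2 <- pmin(geom[keep, 1] + geom[keep, 3], S)
      y1 <- pmax(geom[keep, 2] - geom[keep, 4], 0)
      y2 <- pmin(geom[keep, 2] + geom[keep, 4], S)
      boxes <- data.frame(class_id = 0L,
                          cx = (x1 + x2) / 2 / S, cy = (y1 + y2) / 2 / S,
                          w = (x2 - x1) / S, h = (y2 - y1) / S)
    }
    list(image = img, boxes = boxes,
         visibility = if (length(keep)) visible[keep] / total_px[keep] else numeric(0),
         n_attempted = nf)
  })
}

#' Generate a labelled dataset on disk
#'
#' Writes `images/scene_%03d.png` and `labels/scene_%03d.txt` (normalized
#' `class cx cy w h` lines) plus a `manifest.csv` recording each scene's
#' derived seed. Deterministic for a given `seed`.
#'
#' @param n Number of scenes.
#' @param params A [scene_params()].
#' @param seed Base seed; scene i uses a seed derived from `(seed, i)`.
#' @param out_dir Output directory.
#' @param force Overwrite a non-empty `out_dir`.
#' @return Invisibly, the manifest data frame.
#' @export
generate_dataset <- function(n, params = scene_params(), seed = 1L,
                             out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force)
    stop("output directory ", out_dir, " is not empty (use force = TRUE)")
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "labels"), recursive = TRUE, showWarnings = FALSE)
  manifest <- data.frame(file = character(n), seed = integer(n),
                         n_boxes = integer(n))
  for (i in seq_len(n)) {
    si <- derive_seed(seed, i)
    sc <- render_scene(params, si)
    stem <- sprintf("scene_%03d", i)
    png::writePNG(aperm(sc$image, c(1, 2, 3)),
                  file.path(out_dir, "images", paste0(stem, ".png")))
    write_label_file(sc$boxes, file.path(out_dir, "labels", paste0(stem, ".txt")))
    manifest[i, ] <- list(stem, si, nrow(sc$boxes))
  }
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Load a dataset written by [generate_dataset()]
#'
#' @param dir Dataset directory with `images/` and `labels/`.
#' @return List of samples `list(image, boxes, name)`.
#' @export
load_dataset <- function(dir) {
  imgs <- sort(dir(file.path(dir, "images"), pattern = "\\.png$"))
  if (!length(imgs)) stop("no PNG images under ", file.path(dir, "images"))
  lapply(imgs, function(f) {
    stem <- sub("\\.png$", "", f)
    list(image = read_image(file.path(dir, "images", f)),
         boxes = read_label_file(file.path(dir, "labels", paste0(stem, ".txt"))),
         name = stem)
  })
}
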