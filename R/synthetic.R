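#' Synthetic aerial-survey scene configuration
#'
#' The generator emulates the statistical regime of low-resolution aerial
#' survey tiles: objects only about 5 x 5 pixels, heterogeneous backgrounds,
#' illumination gradients, per-image counts spanning the density levels L0
#' (empty) through L4 (1000+), including pure-background images.  Objects
#' are rendered as anisotropy-jittered Gaussian-profile blobs: this
#' preserves the counting problem's statistics (size, contrast, crowding)
#' without modelling species appearance.
#'
#' @param image_size `c(height, width)` in pixels (default 448 x 448, the
#'   survey tiling convention).
#' @param n_objects Number of objects, or a level name `"L0"`..`"L4"` in
#'   which case a count is drawn uniformly from that level's band
#'   (0, 1-100, 101-500, 501-1000, 1001-2000).
#' @param object_size Nominal object diameter in pixels (default 5).
#' @param object_contrast Mean intensity delta of objects over background
#'   (default 0.35).
#' @param background `"flat"`, `"textured"` (smoothed noise clutter) or
#'   `"illumination-gradient"`.
#' @param min_spacing Minimum centre-to-centre spacing in pixels
#'   (default 2: near-touching objects, as in dense colonies).
#' @param seed Integer seed; every draw is derived from it.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(image_size = c(448L, 448L), n_objects = 50L,
                         object_size = 5, object_contrast = 0.35,
                         background = c("textured", "flat",
                                        "illumination-gradient"),
                         min_spacing = 2, seed = 1L) {
  background <- match.arg(background)
  if (object_size < 2) stop("config-error: object_size must be >= 2")
  if (is.character(n_objects)) {
    stopifnot(n_objects %in% paste0("L", 0:4))
  } else if (n_objects < 0) stop("config-error: n_objects must be >= 0")
  structure(list(image_size = as.integer(image_size),
                 n_objects = n_objects, object_size = object_size,
                 object_contrast = object_contrast, background = background,
                 min_spacing = min_spacing, seed = as.integer(seed)),
            class = "scene_config")
}

level_band <- function(level) {
  switch(level, L0 = c(0L, 0L), L1 = c(1L, 100L), L2 = c(101L, 500L),
         L3 = c(501L, 1000L), L4 = c(1001L, 2000L),
         stop("unknown level ", level))
}

# grid-free rejection sampler for point positions with a minimum spacing
sample_positions <- function(n, h, w, min_spacing, margin = 1) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  cap <- ((h - 2 * margin) / max(min_spacing, 1)) *
         ((w - 2 * margin) / max(min_spacing, 1))
  if (n > 0.7 * cap)
    stop("config-error: cannot place ", n, " points with min_spacing ",
         min_spacing, " in ", h, " x ", w)
  cell <- min_spacing / sqrt(2)
  nx <- max(1L, as.integer(ceiling(w / cell)))
  ny <- max(1L, as.integer(ceiling(h / cell)))
  grid <- matrix(0L, ny, nx)  # 0 = empty, else point index
  px <- numeric(n); py <- numeric(n)
  placed <- 0L; attempts <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > 200L * n + 1000L)
      stop("config-error: spacing constraint infeasible")
    x <- runif(1, margin, w - 1 - margin)
    y <- runif(1, margin, h - 1 - margin)
    gi <- as.integer(y / cell) + 1L; gj <- as.integer(x / cell) + 1L
    ok <- TRUE
    for (di in -2:2) for (dj in -2:2) {
      ii <- gi + di; jj <- gj + dj
      if (ii < 1L || ii > ny || jj < 1L || jj > nx) next
      p <- grid[ii, jj]
      if (p > 0L && (px[p] - x)^2 + (py[p] - y)^2 < min_spacing^2) {
        ok <- FALSE; break
      }
    }
    if (!ok) next
    placed <- placed + 1L
    px[placed] <- x; py[placed] <- y
    grid[gi, gj] <- placed
  }
  cbind(x = px, y = py)
}

render_background <- function(h, w, kind) {
  base <- switch(kind,
    "flat" = matrix(0.35, h, w),
    "textured" = {
      noise <- matrix(runif(h * w, 0, 1), h, w)
      sm <- smooth_map(noise, 5L)
      0.25 + 0.3 * (sm - min(sm)) / max(diff(range(sm)), 1e-12)
    },
    "illumination-gradient" = {
      gx <- matrix(rep(seq(0, 1, length.out = w), each = h), h, w)
      gy <- matrix(rep(seq(0, 1, length.out = h), w), h, w)
      a <- runif(1, -0.2, 0.2); b <- runif(1, -0.2, 0.2)
      0.35 + a * gx + b * gy
    })
  pmin(pmax(base + matrix(rnorm(h * w, sd = 0.02), h, w), 0), 1)
}

# separable box blur, replicated edges
smooth_map <- function(m, k) {
  pad <- (k - 1L) %/% 2L
  kern <- rep(1 / k, k)
  t(apply(apply(m, 2L, running_mean, k = k), 1L, running_mean, k = k))
}

running_mean <- function(v, k) {
  pad <- (k - 1L) %/% 2L
  vp <- c(rep(v[[1]], pad), v, rep(v[[length(v)]], pad))
  as.numeric(stats::filter(vp, rep(1 / k, k), sides = 2L))[(pad + 1L):(pad + length(v))]
}

#' Render one synthetic survey scene
#'
#' Draws object positions by rejection sampling with a minimum spacing,
#' renders each object as a small elliptical Gaussian-profile blob with
#' per-object shape and intensity jitter on the configured background, and
#' returns the image with the object-centre point annotations.  Fully
#' deterministic given `cfg$seed`.
#'
#' @param cfg A [scene_config()].
#' @param image_id Identifier stored in the annotation set.
#' @return A list with `image` (`H x W x 3` array in `[0, 1]`) and `ann`
#'   (a [point_annotations()]).
#' @export
generate_scene <- function(cfg = scene_config(), image_id = "scene") {
  stopifnot(inherits(cfg, "scene_config"))
  set.seed(cfg$seed)
  h <- cfg$image_size[[1]]; w <- cfg$image_size[[2]]
  n <- cfg$n_objects
  if (is.character(n)) {
    band <- level_band(n)
    n <- if (band[[2]] == 0L) 0L else
      as.integer(floor(runif(1, band[[1]], band[[2]] + 1)))
  }
  bg <- render_background(h, w, cfg$background)
  pos <- sample_positions(n, h, w, cfg$min_spacing,
                          margin = ceiling(cfg$object_size / 2))
  img <- bg
  if (n > 0L) {
    r <- cfg$object_size / 2
    for (i in seq_len(n)) {
      sx <- r / 2 * runif(1, 0.8, 1.25)   # ~object_size px footprint
      sy <- r / 2 * runif(1, 0.8, 1.25)
      th <- runif(1, 0, pi)
      amp <- cfg$object_contrast * runif(1, 0.7, 1.3)
      ext <- ceiling(2.5 * max(sx, sy))
      cx <- pos[i, "x"]; cy <- pos[i, "y"]
      ix <- max(0, floor(cx - ext)):min(w - 1, ceiling(cx + ext))
      iy <- max(0, floor(cy - ext)):min(h - 1, ceiling(cy + ext))
      dx <- outer(rep(1, length(iy)), ix - cx)
      dy <- outer(iy - cy, rep(1, length(ix)))
      u <- cos(th) * dx + sin(th) * dy
      v <- -sin(th) * dx + cos(th) * dy
      blob <- amp * exp(-(u^2 / (2 * sx^2) + v^2 / (2 * sy^2)))
      img[iy + 1L, ix + 1L] <- img[iy + 1L, ix + 1L] + blob
    }
    img <- pmin(img, 1)
  }
  # mild per-channel tint so the RGB channels are not identical
  tint <- c(1, 0.97, 0.92)
  rgb <- array(0, c(h, w, 3L))
  for (c in 1:3) rgb[, , c] <- pmin(img * tint[[c]], 1)
  ann <- point_annotations(image_id,
                           data.frame(x = pos[, "x"], y = pos[, "y"]),
                           c(h, w))
  list(image = rgb, ann = ann)
}

#' Generate a synthetic dataset with a prescribed density-level mix
#'
#' Assigns each image a density level according to `level_mix`, draws its
#' count uniformly within the level's band, renders the scenes, and (when
#' `dir` is given) writes PNG images, the annotation CSV and a JSON
#' manifest.  Deterministic given `seed`.
#'
#' @param n_images Number of images.
#' @param level_mix Proportions over levels L0..L4 (summing to 1).  The
#'   default mirrors a colony survey archive: many empty or sparse tiles,
#'   few very dense ones.
#' @param seed Integer seed.
#' @param image_size,background,object_size,object_contrast,min_spacing
#'   Passed to [scene_config()].
#' @param dir Optional output directory; when `NULL` nothing is written.
#' @return A list with `manifest` (tibble: `image_id`, `height`, `width`,
#'   `level`, `count`), `scenes` (list of `generate_scene` results) and,
#'   when written, `paths`.
#' @export
generate_dataset <- function(n_images, level_mix = c(0.26, 0.32, 0.31, 0.07, 0.04),
                             seed = 1L, image_size = c(448L, 448L),
                             background = "textured", object_size = 5,
                             object_contrast = 0.35, min_spacing = 2,
                             dir = NULL) {
  stopifnot(length(level_mix) == 5L, abs(sum(level_mix) - 1) < 1e-8)
  set.seed(seed)
  levels <- paste0("L", 0:4)
  n_per <- floor(level_mix * n_images)
  rem <- n_images - sum(n_per)
  if (rem > 0) {
    extra <- order(level_mix * n_images - n_per, decreasing = TRUE)[seq_len(rem)]
    n_per[extra] <- n_per[extra] + 1L
  }
  assigned <- sample(rep(levels, times = n_per))
  scenes <- vector("list", n_images)
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    id <- sprintf("img_%04d", i)
    cfg <- scene_config(image_size = image_size, n_objects = assigned[[i]],
                        object_size = object_size,
                        object_contrast = object_contrast,
                        background = background, min_spacing = min_spacing,
                        seed = as.integer((seed * 10007L + i) %% .Machine$integer.max))
    scenes[[i]] <- generate_scene(cfg, image_id = id)
    rows[[i]] <- tibble::tibble(image_id = id,
                                height = image_size[[1]],
                                width = image_size[[2]],
                                level = assigned[[i]],
                                count = n_points(scenes[[i]]$ann))
  }
  manifest <- dplyr::bind_rows(rows)
  out <- list(manifest = manifest, scenes = scenes)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    img_paths <- character(n_images)
    for (i in seq_len(n_images)) {
      img_paths[[i]] <- file.path(dir, paste0(manifest$image_id[[i]], ".png"))
      png::writePNG(scenes[[i]]$image, img_paths[[i]])
    }
    ann_path <- file.path(dir, "annotations.csv")
    write_annotations(lapply(scenes, `[[`, "ann"), ann_path)
    man_path <- file.path(dir, "manifest.json")
    jsonlite::write_json(manifest, man_path, dataframe = "rows")
    out$paths <- list(images = img_paths, annotations = ann_path,
                      manifest = man_path)
  }
  out
}
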