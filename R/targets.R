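#' Density-target generation settings
#'
#' @param sigma Gaussian bandwidth in pixels used to smooth each point
#'   annotation into a unit-mass kernel.  Default 4, matched to objects a few
#'   pixels across in ortho-rectified survey imagery.
#' @param truncation_radius Kernel support half-width, in multiples of
#'   `sigma`.  The kernel is evaluated on a
#'   `(2 * truncation_radius * sigma + 1)^2` pixel window and normalised to
#'   unit mass over that window.
#' @param downsample_factor Integer block size for sum-pooling the
#'   full-resolution density map to the network's output resolution
#'   (default 8).
#' @param seg_epsilon Density threshold above which a target cell counts as
#'   foreground when deriving the binary segmentation target (default 1e-3).
#' @param adaptive Use a per-point bandwidth proportional to the mean
#'   distance to the `adaptive_k` nearest neighbours instead of the fixed
#'   `sigma`.  Off by default; the fixed bandwidth is appropriate when all
#'   objects have near-identical size on the ground.
#' @param adaptive_beta,adaptive_k Scale factor and neighbour count for the
#'   adaptive mode.
#' @return A list of class `gen_config`.
#' @export
gen_config <- function(sigma = 4, truncation_radius = 4, downsample_factor = 8L,
                       seg_epsilon = 1e-3, adaptive = FALSE,
                       adaptive_beta = 0.3, adaptive_k = 3L) {
  if (sigma <= 0) stop("config-error: sigma must be positive")
  if (truncation_radius < 3) stop("config-error: truncation_radius must be >= 3")
  if (downsample_factor < 1) stop("config-error: downsample_factor must be >= 1")
  if (seg_epsilon <= 0) stop("config-error: seg_epsilon must be positive")
  structure(list(sigma = sigma, truncation_radius = truncation_radius,
                 downsample_factor = as.integer(downsample_factor),
                 seg_epsilon = seg_epsilon, adaptive = adaptive,
                 adaptive_beta = adaptive_beta,
                 adaptive_k = as.integer(adaptive_k)),
            class = "gen_config")
}

#' Density map container
#'
#' A density map is a non-negative 2-D grid whose integral (sum) over any
#' region is the expected object count in that region.  `resolution_divisor`
#' records the ratio of the source image resolution to the grid resolution
#' (1 for full-resolution ground truth, 8 for network-scale targets).
#'
#' @param values Numeric matrix of non-negative densities.
#' @param resolution_divisor Integer resolution divisor.
#' @return An object of class `density_map` (a matrix with attributes).
#' @export
density_map <- function(values, resolution_divisor = 1L) {
  stopifnot(is.matrix(values))
  if (any(values < 0)) stop("density map values must be non-negative")
  structure(values, resolution_divisor = as.integer(resolution_divisor),
            class = c("density_map", "matrix", "array"))
}

#' @rdname density_map
#' @param d A density map (or plain matrix).
#' @export
density_mass <- function(d) sum(unclass(d))

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %d x %d (1/%d resolution), mass %.4f\n",
              nrow(x), ncol(x), attr(x, "resolution_divisor"), density_mass(x)))
  invisible(x)
}

# evaluate one truncated, window-normalised Gaussian kernel into `acc`
add_kernel <- function(acc, x, y, sigma, radius_px) {
  h <- nrow(acc); w <- ncol(acc)
  cx <- round(x); cy <- round(y)
  ix <- (cx - radius_px):(cx + radius_px)   # 0-based columns
  iy <- (cy - radius_px):(cy + radius_px)   # 0-based rows
  g <- exp(-outer((iy - y)^2, (ix - x)^2, "+") / (2 * sigma^2))
  g <- g / sum(g)  # unit mass over the full (possibly off-image) window
  keep_r <- iy >= 0 & iy <= h - 1
  keep_c <- ix >= 0 & ix <= w - 1
  rr <- iy[keep_r] + 1L
  cc <- ix[keep_c] + 1L
  acc[rr, cc] <- acc[rr, cc] + g[keep_r, keep_c, drop = FALSE]
  acc
}

#' Generate a ground-truth density map from point annotations
#'
#' Each annotated point contributes a discretely normalised, truncated
#' isotropic Gaussian centred at its (possibly fractional) coordinates: the
#' kernel is evaluated at pixel centres on a finite window and divided by the
#' window sum, so a point whose window lies fully inside the image adds
#' exactly one unit of mass.  Kernels overlapping the image border are
#' clipped without renormalisation — the mass falling outside the frame is
#' legitimately lost, which is what makes counts additive across tiles cut
#' from a larger scene.
#'
#' @param ann A [point_annotations()] object.
#' @param cfg A [gen_config()].
#' @return A full-resolution [density_map()] of the annotated image's size.
#' @examples
#' ann <- point_annotations("a", data.frame(x = 32, y = 32), c(64, 64))
#' d <- generate_density_map(ann, gen_config())
#' density_mass(d)  # 1
#' @export
generate_density_map <- function(ann, cfg = gen_config()) {
  stopifnot(inherits(ann, "point_annotations"), inherits(cfg, "gen_config"))
  h <- ann$image_size[["height"]]; w <- ann$image_size[["width"]]
  acc <- matrix(0, h, w)
  pts <- ann$points
  if (nrow(pts) > 0L) {
    sigmas <- rep(cfg$sigma, nrow(pts))
    if (cfg$adaptive && nrow(pts) > 1L) {
      dm <- as.matrix(stats::dist(cbind(pts$x, pts$y)))
      diag(dm) <- Inf
      k <- min(cfg$adaptive_k, nrow(pts) - 1L)
      nnd <- apply(dm, 1L, function(r) mean(sort(r)[seq_len(k)]))
      sigmas <- pmax(cfg$adaptive_beta * nnd, .Machine$double.eps)
    }
    for (i in seq_len(nrow(pts))) {
      radius_px <- ceiling(cfg$truncation_radius * sigmas[[i]])
      acc <- add_kernel(acc, pts$x[[i]], pts$y[[i]], sigmas[[i]], radius_px)
    }
  }
  density_map(acc, 1L)
}

#' Sum-pool a density map to a coarser grid
#'
#' Aggregates non-overlapping `factor x factor` blocks by summation, so the
#' total mass — and hence the count — is preserved exactly.  Dimensions not
#' divisible by `factor` are zero-padded on the bottom/right first.
#'
#' @param d A full-resolution [density_map()] or matrix.
#' @param factor Integer block size (default 8).
#' @return A [density_map()] with `resolution_divisor` multiplied by
#'   `factor`.
#' @export
downsample_density <- function(d, factor = 8L) {
  if (factor < 1) stop("config-error: factor must be >= 1")
  factor <- as.integer(factor)
  rd <- if (inherits(d, "density_map")) attr(d, "resolution_divisor") else 1L
  m <- unclass(d)
  attributes(m) <- list(dim = dim(m))
  hp <- ceiling(nrow(m) / factor) * factor
  wp <- ceiling(ncol(m) / factor) * factor
  if (hp != nrow(m) || wp != ncol(m)) {
    mp <- matrix(0, hp, wp)
    mp[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    m <- mp
  }
  out <- block_sum(m, factor)
  density_map(out, rd * factor)
}

# exact block sum via dimension folding (no floating point rearrangement
# beyond the summation itself)
block_sum <- function(m, k) {
  h <- nrow(m); w <- ncol(m)
  dim(m) <- c(k, h / k, k, w / k)
  colSums(colSums(aperm(m, c(1, 3, 2, 4))))  # sums over the two k axes
}

#' Segmentation maps
#'
#' @param values Numeric matrix; binary mode requires every value to be
#'   exactly 0 or 1, probability mode requires values in `[0, 1]`.
#' @param mode `"binary"` (ground-truth targets) or `"probability"`
#'   (network predictions).
#' @return An object of class `segmentation_map`.
#' @export
segmentation_map <- function(values, mode = c("binary", "probability")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(values))
  if (mode == "binary" && !all(values %in% c(0, 1)))
    stop("binary segmentation map must contain only 0 and 1")
  if (mode == "probability" && (any(values < 0) || any(values > 1)))
    stop("probability segmentation map must lie in [0, 1]")
  structure(values, mode = mode,
            class = c("segmentation_map", "matrix", "array"))
}

#' Derive the binary segmentation target from a density target
#'
#' A cell is foreground iff its density strictly exceeds the threshold:
#' `S = 1(D > epsilon)`.  Applied to the network-scale density target, this
#' marks the locations that carry non-negligible count mass.
#'
#' @param dt Density target (matrix or [density_map()]).
#' @param epsilon Strictly positive density threshold (default 1e-3).
#' @return A binary [segmentation_map()] of the same shape.
#' @export
make_segmentation_target <- function(dt, epsilon = 1e-3) {
  if (epsilon <= 0) stop("config-error: epsilon must be positive")
  m <- unclass(dt)
  attributes(m) <- list(dim = dim(m))
  segmentation_map((m > epsilon) * 1, "binary")
}

#' Cut a large scene into fixed-size tiles with fractional-mass density tiles
#'
#' Survey mosaics are far larger than what a network ingests, so scenes are
#' cut into `tile_size` tiles (the last row/column is zero-padded).  The
#' density tiles are cropped from the *full-scene* density map, so an object
#' straddling a tile border contributes fractional mass to both tiles and the
#' tile masses still sum to the scene mass.  Each point annotation is
#' assigned to exactly the tile containing its centre.
#'
#' @param image Numeric array `H x W` or `H x W x C` (values in `[0, 1]`).
#' @param ann A [point_annotations()] for the scene.
#' @param tile_size Tile edge in pixels (>= 16); the survey convention is
#'   448.
#' @param cfg A [gen_config()] used to build the full-scene density map.
#' @return A list of tiles, each a list with `image`, `ann`
#'   (a [point_annotations()] with tile-local coordinates), `density`
#'   (the cropped full-resolution [density_map()]), and `offset`
#'   (`c(row0, col0)`, 0-based position of the tile in the scene).
#' @export
tile_scene <- function(image, ann, tile_size = 448L, cfg = gen_config()) {
  if (tile_size < 16) stop("config-error: tile_size must be >= 16")
  tile_size <- as.integer(tile_size)
  dims <- dim(image)
  h <- dims[[1]]; w <- dims[[2]]
  if (tile_size > h || tile_size > w)
    warning("tile_size exceeds scene size; returning a single padded tile")
  full <- generate_density_map(ann, cfg)
  nr <- max(1L, as.integer(ceiling(h / tile_size)))
  nc <- max(1L, as.integer(ceiling(w / tile_size)))
  tiles <- vector("list", nr * nc)
  idx <- 1L
  for (ti in seq_len(nr) - 1L) {
    for (tj in seq_len(nc) - 1L) {
      r0 <- ti * tile_size; c0 <- tj * tile_size          # 0-based offsets
      rr <- (r0 + 1L):min(r0 + tile_size, h)
      cc <- (c0 + 1L):min(c0 + tile_size, w)
      img_t <- array(0, c(tile_size, tile_size,
                          if (length(dims) == 3L) dims[[3]] else 1L))
      if (length(dims) == 3L) {
        img_t[seq_along(rr), seq_along(cc), ] <- image[rr, cc, , drop = FALSE]
      } else {
        img_t[seq_along(rr), seq_along(cc), 1L] <- image[rr, cc]
      }
      if (length(dims) != 3L) img_t <- img_t[, , 1L]
      den_t <- matrix(0, tile_size, tile_size)
      den_t[seq_along(rr), seq_along(cc)] <- unclass(full)[rr, cc]
      pts <- ann$points
      insel <- floor(pts$y / tile_size) == ti & floor(pts$x / tile_size) == tj
      ann_t <- point_annotations(
        sprintf("%s_r%dc%d", ann$image_id, ti, tj),
        data.frame(x = pts$x[insel] - c0, y = pts$y[insel] - r0),
        c(tile_size, tile_size))
      tiles[[idx]] <- list(image = img_t, ann = ann_t,
                           density = density_map(den_t, 1L),
                           offset = c(row0 = r0, col0 = c0))
      idx <- idx + 1L
    }
  }
  tiles
}
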