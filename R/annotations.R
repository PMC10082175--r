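#' Point annotation sets
#'
#' A point annotation set holds the object-centre coordinates for one image:
#' the only supervision the density-map approach needs.  Coordinates are
#' 0-based with `x` the pixel column and `y` the pixel row; pixel centres sit
#' at integer coordinates.  An empty set (zero points) is valid: survey
#' archives contain pure-background images.
#'
#' @param image_id Character scalar identifying the image.
#' @param points A data frame (or tibble) with numeric columns `x` and `y`,
#'   one row per annotated object; may have zero rows.
#' @param image_size Integer vector `c(height, width)` in pixels.
#'
#' @return An object of class `point_annotations`: a list with fields
#'   `image_id`, `points` (tibble with columns `x`, `y`) and `image_size`.
#' @examples
#' ann <- point_annotations("tile_001",
#'                          data.frame(x = c(10.5, 30), y = c(12, 40)),
#'                          image_size = c(64, 64))
#' n_points(ann)
#' @export
point_annotations <- function(image_id, points = NULL,
                              image_size = c(448L, 448L)) {
  stopifnot(is.character(image_id), length(image_id) == 1L,
            length(image_size) == 2L, all(image_size >= 1))
  if (is.null(points) || nrow(points) == 0L) {
    pts <- tibble::tibble(x = numeric(0), y = numeric(0))
  } else {
    pts <- tibble::as_tibble(points[, c("x", "y")])
  }
  h <- image_size[[1]]; w <- image_size[[2]]
  if (nrow(pts) > 0L &&
      (any(pts$x < 0) || any(pts$x >= w) || any(pts$y < 0) || any(pts$y >= h))) {
    stop("annotation-error: point outside image bounds [0, width) x [0, height)")
  }
  structure(list(image_id = image_id, points = pts,
                 image_size = c(height = as.integer(h), width = as.integer(w))),
            class = "point_annotations")
}

#' @rdname point_annotations
#' @param ann A `point_annotations` object.
#' @export
n_points <- function(ann) nrow(ann$points)

#' @export
print.point_annotations <- function(x, ...) {
  cat(sprintf("<point_annotations> image '%s' (%d x %d px), %d point(s)\n",
              x$image_id, x$image_size[["height"]], x$image_size[["width"]],
              n_points(x)))
  invisible(x)
}

#' Read and write annotation tables
#'
#' Annotations for a whole dataset are stored as a CSV with header
#' `image_id,x,y` (one row per point) together with a manifest listing every
#' image id and its size, so that images with zero points are represented.
#'
#' @param path Path to the annotation CSV.
#' @param manifest A data frame with columns `image_id`, `height`, `width`
#'   (one row per image).  For `read_annotations` it supplies the images with
#'   no annotation rows.
#' @return `read_annotations` returns a named list of [point_annotations()]
#'   objects, one per manifest row.
#' @export
read_annotations <- function(path, manifest) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("image_id", "x", "y") %in% names(df)))
  out <- lapply(seq_len(nrow(manifest)), function(i) {
    id <- manifest$image_id[[i]]
    point_annotations(id, df[df$image_id == id, c("x", "y")],
                      c(manifest$height[[i]], manifest$width[[i]]))
  })
  stats::setNames(out, manifest$image_id)
}

#' @rdname read_annotations
#' @param anns A list of `point_annotations` objects.
#' @export
write_annotations <- function(anns, path) {
  rows <- lapply(anns, function(a) {
    if (n_points(a) == 0L) return(NULL)
    data.frame(image_id = a$image_id, x = a$points$x, y = a$points$y)
  })
  df <- do.call(rbind, c(rows, list(data.frame(image_id = character(0),
                                               x = numeric(0),
                                               y = numeric(0)))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
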