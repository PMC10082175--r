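#' Counting error metrics
#'
#' `count_mae` is the mean absolute difference between predicted and
#' ground-truth per-image counts; `count_rmse` is the root mean squared
#' difference.  RMSE weights large errors more heavily and always satisfies
#' `rmse >= mae`.  Predicted counts are real-valued density integrals and
#' are not rounded.
#'
#' @param pred,gt Equal-length nonzero-length numeric vectors of per-image
#'   counts.
#' @return A scalar.
#' @examples
#' count_mae(c(0, 3, 5), c(1, 1, 5))   # 1
#' count_rmse(c(0, 3, 5), c(1, 1, 5))  # sqrt(5/3)
#' @export
count_mae <- function(pred, gt) {
  check_pair(pred, gt)
  mean(abs(pred - gt))
}

#' @rdname count_mae
#' @export
count_rmse <- function(pred, gt) {
  check_pair(pred, gt)
  sqrt(mean((pred - gt)^2))
}

check_pair <- function(pred, gt) {
  if (length(pred) != length(gt) || length(pred) == 0L)
    stop("contract-error: pred and gt must have equal nonzero length")
  invisible(TRUE)
}

#' Density level of a ground-truth count
#'
#' Images are stratified by their true count into five bands: L0 (0),
#' L1 (1-100), L2 (101-500), L3 (501-1000), L4 (1000+).
#'
#' @param count Non-negative integer ground-truth count (vectorised).
#' @return Character vector of levels `"L0"`..`"L4"`.
#' @examples
#' level_of(c(0, 100, 101, 500, 501, 1000, 1001))
#' @export
level_of <- function(count) {
  if (any(count < 0)) stop("contract-error: counts must be non-negative")
  cut(count, breaks = c(-Inf, 0, 100, 500, 1000, Inf),
      labels = paste0("L", 0:4)) |> as.character()
}

#' Evaluate predicted counts against ground truth
#'
#' Produces overall MAE/RMSE, the per-density-level breakdown (levels
#' assigned from the ground-truth counts), and the signed dataset-level
#' count error `sum(pred) - sum(gt)`, also as a percentage of the true
#' total.  Empty levels report `n_images = 0` with `NA` metrics.
#'
#' @param counts A data frame with numeric columns `pred` and `gt`, one row
#'   per image (extra columns are ignored).  Alternatively pass two vectors
#'   via `pred` and `gt`.
#' @param pred,gt Used when `counts` is missing.
#' @return An object of class `eval_report`: a list with `overall_mae`,
#'   `overall_rmse`, `per_level` (tibble: level, n_images, mae, rmse),
#'   `dataset_count_error` and `dataset_count_error_pct` (`NA` when the true
#'   total is 0), plus `n_images`.
#' @examples
#' evaluate_counts(pred = c(5, 0), gt = c(4, 0))
#' @export
evaluate_counts <- function(counts = NULL, pred = NULL, gt = NULL) {
  if (is.null(counts)) counts <- tibble::tibble(pred = pred, gt = gt)
  counts <- tibble::as_tibble(counts)
  if (nrow(counts) == 0L) stop("contract-error: no count pairs supplied")
  check_pair(counts$pred, counts$gt)
  counts$level <- level_of(counts$gt)
  per_level <- dplyr::bind_rows(lapply(paste0("L", 0:4), function(lv) {
    sub <- counts[counts$level == lv, ]
    tibble::tibble(level = lv, n_images = nrow(sub),
                   mae = if (nrow(sub)) count_mae(sub$pred, sub$gt) else NA_real_,
                   rmse = if (nrow(sub)) count_rmse(sub$pred, sub$gt) else NA_real_)
  }))
  err <- sum(counts$pred) - sum(counts$gt)
  pct <- if (sum(counts$gt) > 0) 100 * err / sum(counts$gt) else NA_real_
  structure(list(overall_mae = count_mae(counts$pred, counts$gt),
                 overall_rmse = count_rmse(counts$pred, counts$gt),
                 per_level = per_level,
                 dataset_count_error = err,
                 dataset_count_error_pct = pct,
                 n_images = nrow(counts)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d images | MAE %.2f  RMSE %.2f | dataset error %+.1f (%s)\n",
              x$n_images, x$overall_mae, x$overall_rmse,
              x$dataset_count_error,
              if (is.na(x$dataset_count_error_pct)) "n/a"
              else sprintf("%+.1f%%", x$dataset_count_error_pct)))
  print(x$per_level)
  invisible(x)
}

#' Tidiers for evaluation reports
#'
#' `tidy()` returns the per-level breakdown with the overall row appended;
#' `glance()` returns the one-row dataset summary.
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.eval_report <- function(x, ...) {
  dplyr::bind_rows(x$per_level,
                   tibble::tibble(level = "overall", n_images = x$n_images,
                                  mae = x$overall_mae, rmse = x$overall_rmse))
}

#' @rdname tidy.eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(n_images = x$n_images, mae = x$overall_mae,
                 rmse = x$overall_rmse,
                 dataset_count_error = x$dataset_count_error,
                 dataset_count_error_pct = x$dataset_count_error_pct)
}

#' Plot an evaluation report
#'
#' Per-level MAE and RMSE bars.
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  d <- object$per_level[!is.na(object$per_level$mae), ]
  long <- dplyr::bind_rows(
    tibble::tibble(level = d$level, metric = "MAE", value = d$mae),
    tibble::tibble(level = d$level, metric = "RMSE", value = d$rmse))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$level, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "density level (by true count)", y = "count error") +
    ggplot2::theme_minimal()
}
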