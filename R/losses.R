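#' Loss configuration
#'
#' Settings for the supervision objective: a segmentation-masked multi-scale
#' structural similarity loss on the density branch plus a class-balanced
#' binary cross-entropy on the segmentation branch.
#'
#' @param c1,c2 Additive stabilising constants of the structural similarity
#'   index (defaults 0.01 and 0.03).
#' @param n_levels Number of average-pooling scales in the structural loss
#'   (default 3); level `i` pools by a factor `2^(i-1)`, so level 1 is the
#'   map itself.
#' @param h Weight on the negative (background) class in the cross-entropy,
#'   in `(0, 1]` (default 0.5): background cells vastly outnumber foreground
#'   ones in survey imagery.
#' @param lambda_seg Weight of the cross-entropy term in the total loss
#'   (default 0.1; density regression is the main task).
#' @param prob_clamp Predicted probabilities are clamped to
#'   `[prob_clamp, 1 - prob_clamp]` before taking logs (default 1e-7).
#' @return A list of class `loss_config`.
#' @export
loss_config <- function(c1 = 0.01, c2 = 0.03, n_levels = 3L, h = 0.5,
                        lambda_seg = 0.1, prob_clamp = 1e-7) {
  if (c1 <= 0 || c2 <= 0) stop("config-error: c1 and c2 must be positive")
  if (n_levels < 1) stop("config-error: n_levels must be >= 1")
  if (h <= 0 || h > 1) stop("config-error: h must lie in (0, 1]")
  if (lambda_seg < 0) stop("config-error: lambda_seg must be >= 0")
  if (prob_clamp <= 0 || prob_clamp >= 0.01)
    stop("config-error: prob_clamp must lie in (0, 0.01)")
  structure(list(c1 = c1, c2 = c2, n_levels = as.integer(n_levels), h = h,
                 lambda_seg = lambda_seg, prob_clamp = prob_clamp),
            class = "loss_config")
}

as_plain_matrix <- function(x) {
  m <- unclass(x)
  attributes(m) <- list(dim = dim(m))
  m
}

#' Structural similarity index of two maps (whole-map statistics)
#'
#' Computes the similarity
#' `(2 mu_x mu_y + c1)(2 cov_xy + c2) / ((mu_x^2 + mu_y^2 + c1)(var_x + var_y + c2))`
#' from whole-map means, variances and covariance (1/M normalisation).  The
#' index is 1 exactly when the maps are identical and is symmetric in its
#' arguments.  A sliding-window variant (`window`) averaging local SSIM over
#' `window x window` patches is available but off by default.
#'
#' @param x,y Numeric matrices of identical shape.
#' @param cfg A [loss_config()].
#' @param window Optional odd window size for local statistics; `NULL`
#'   (default) uses whole-map statistics.
#' @return A scalar similarity, at most 1.
#' @export
ssim_index <- function(x, y, cfg = loss_config(), window = NULL) {
  x <- as_plain_matrix(x); y <- as_plain_matrix(y)
  if (!all(dim(x) == dim(y))) stop("contract-error: shape mismatch")
  if (is.null(window)) return(ssim_stat(x, y, cfg$c1, cfg$c2)$value)
  stopifnot(window %% 2 == 1)
  # local mode: mean of per-window indices at each valid centre
  vals <- c()
  k <- (window - 1L) / 2L
  for (i in (1 + k):(nrow(x) - k)) for (j in (1 + k):(ncol(x) - k)) {
    px <- x[(i - k):(i + k), (j - k):(j + k)]
    py <- y[(i - k):(i + k), (j - k):(j + k)]
    vals <- c(vals, ssim_stat(px, py, cfg$c1, cfg$c2)$value)
  }
  mean(vals)
}

# value + the statistics needed for the analytic gradient
ssim_stat <- function(x, y, c1, c2) {
  M <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2) / M
  vy <- sum((y - my)^2) / M
  cxy <- sum((x - mx) * (y - my)) / M
  a1 <- 2 * mx * my + c1
  a2 <- 2 * cxy + c2
  b1 <- mx^2 + my^2 + c1
  b2 <- vx + vy + c2
  list(value = (a1 * a2) / (b1 * b2), mx = mx, my = my, a1 = a1, a2 = a2,
       b1 = b1, b2 = b2, M = M)
}

# d ssim(x, y) / d x, whole-map statistics
ssim_grad_x <- function(x, y, cfg) {
  s <- ssim_stat(x, y, cfg$c1, cfg$c2)
  with(s, {
    dx <- x - mx; dy <- y - my
    (2 / (M * b1^2 * b2^2)) *
      (my * a2 * b1 * b2 + dy * a1 * b1 * b2 -
       mx * a1 * a2 * b2 - dx * a1 * a2 * b1)
  })
}

#' Multi-scale structural loss between predicted and target density maps
#'
#' `SL = mean_i (1 - SSIM(Pool_i(pred), Pool_i(target)))` over `n_levels`
#' average-pooling scales with kernel and stride `2^(i-1)` (level 1 is the
#' identity).  Zero exactly when the maps are identical; always
#' non-negative for maps bounded by the index's maximum of 1.  If the map is
#' too small for the requested number of levels the level count is reduced
#' with a warning.
#'
#' @param dpred,dtarget Numeric matrices (predicted and target density) of
#'   identical shape.
#' @param cfg A [loss_config()].
#' @return Scalar loss.
#' @export
structural_loss <- function(dpred, dtarget, cfg = loss_config()) {
  sl_core(as_plain_matrix(dpred), as_plain_matrix(dtarget), cfg,
          grad = FALSE)$value
}

sl_core <- function(x, y, cfg, grad = FALSE) {
  if (!all(dim(x) == dim(y))) stop("contract-error: shape mismatch")
  n <- cfg$n_levels
  max_k <- 2^(n - 1)
  if (min(dim(x)) < max_k) {
    n <- max(1L, floor(log2(min(dim(x)))) + 1L)
    warning(sprintf("map smaller than 2^(n_levels-1); reducing levels to %d", n))
  }
  total <- 0
  g <- if (grad) matrix(0, nrow(x), ncol(x)) else NULL
  for (i in seq_len(n)) {
    k <- 2^(i - 1)
    px <- if (k == 1) x else cpp_avgpool(x, k)
    py <- if (k == 1) y else cpp_avgpool(y, k)
    total <- total + (1 - ssim_stat(px, py, cfg$c1, cfg$c2)$value)
    if (grad) {
      gi <- -ssim_grad_x(px, py, cfg)
      g <- g + if (k == 1) gi else cpp_avgpool_bwd(gi, k, nrow(x), ncol(x))
    }
  }
  list(value = total / n, grad = if (grad) g / n else NULL)
}

#' Masked structural loss
#'
#' The structural loss applied after masking both maps by the binary
#' ground-truth segmentation (`pred * mask` vs `target * mask`, then pool).
#' Cells carrying negligible density are thereby excluded, focusing the
#' regression on the high-density cells that dominate the count.  Reduces to
#' [structural_loss()] under an all-ones mask and to 0 under an all-zeros
#' mask.
#'
#' @param dpred,dtarget Numeric matrices of identical shape.
#' @param sgt Binary mask (matrix or binary [segmentation_map()]), same shape.
#' @param cfg A [loss_config()].
#' @return Scalar loss.
#' @export
masked_structural_loss <- function(dpred, dtarget, sgt, cfg = loss_config()) {
  msl_core(as_plain_matrix(dpred), as_plain_matrix(dtarget),
           as_plain_matrix(sgt), cfg, grad = FALSE)$value
}

msl_core <- function(x, y, m, cfg, grad = FALSE) {
  if (!all(m %in% c(0, 1))) stop("contract-error: mask must be binary")
  if (!all(dim(m) == dim(x))) stop("contract-error: shape mismatch")
  res <- sl_core(x * m, y * m, cfg, grad = grad)
  if (grad) res$grad <- res$grad * m
  res
}

#' Class-balanced binary cross-entropy for the segmentation branch
#'
#' `CE = mean_m -( y_m log p_m + h (1 - y_m) log(1 - p_m) )` with the
#' background term down-weighted by `h`.  Probabilities are clamped to
#' `[prob_clamp, 1 - prob_clamp]` before the logs.
#'
#' @param spred Predicted probability map (matrix or probability
#'   [segmentation_map()]).
#' @param sgt Binary target map, same shape.
#' @param cfg A [loss_config()].
#' @return Scalar loss, non-negative.
#' @export
weighted_cross_entropy <- function(spred, sgt, cfg = loss_config()) {
  ce_core(as_plain_matrix(spred), as_plain_matrix(sgt), cfg, grad = FALSE)$value
}

ce_core <- function(p, y, cfg, grad = FALSE) {
  if (!all(dim(p) == dim(y))) stop("contract-error: shape mismatch")
  eps <- cfg$prob_clamp
  pc <- pmin(pmax(p, eps), 1 - eps)
  M <- length(p)
  val <- -sum(y * log(pc) + cfg$h * (1 - y) * log(1 - pc)) / M
  g <- NULL
  if (grad) {
    g <- (-(y / pc) + cfg$h * (1 - y) / (1 - pc)) / M
    g[p < eps | p > 1 - eps] <- 0  # clamped region: flat
  }
  list(value = val, grad = g)
}

#' Total training loss
#'
#' `Loss = SL* + lambda * CE`: the masked structural loss on the density
#' branch plus the weighted cross-entropy on the segmentation branch, with
#' `lambda = 0.1` by default since density regression is the main task.
#'
#' @param sl_star Masked structural loss value.
#' @param ce Weighted cross-entropy value.
#' @param cfg A [loss_config()].
#' @return Scalar total loss.
#' @export
total_loss <- function(sl_star, ce, cfg = loss_config()) {
  stopifnot(is.finite(sl_star), is.finite(ce))
  sl_star + cfg$lambda_seg * ce
}
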