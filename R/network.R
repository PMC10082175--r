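#' Model configuration
#'
#' The model is a truncated VGG-19-style backbone (four stride-2 max-pooling
#' stages, so features at 1/16 input resolution), bilinearly upsampled by 2
#' to 1/8 resolution, feeding two branches: a segmentation branch (sigmoid
#' head) and a density regression branch (ReLU head) that sees the shared
#' features dampened by a mask built from the predicted segmentation.
#'
#' @param backbone `"vgg19-truncated"` (the full-size model: all sixteen
#'   3x3 convolution layers of VGG-19 with the final max-pool and classifier
#'   removed) or `"tiny"`, a reduced-width backbone with the identical
#'   downsampling structure used for desk-scale experiments and tests.
#' @param use_pretrained_backbone Initialise the backbone from externally
#'   supplied weights (see `pretrained_weights`).  Off by default; nothing in
#'   the package requires a download.
#' @param pretrained_weights Path to an `.rds` file with a named list of
#'   backbone weight matrices, required when `use_pretrained_backbone` is on.
#' @param alpha Dampening factor applied to features at locations the
#'   segmentation branch calls background, in `(0, 1)` (default 0.1).
#' @param branch_channels Channel widths of the two 3x3 convolutions in each
#'   branch (the final 1x1 convolution always maps to 1 channel).  `NULL`
#'   picks `c(256, 64)` for the full backbone and `c(32, 16)` for the tiny
#'   one.
#' @param pad_multiple Inputs are zero-padded so both sides are divisible by
#'   this (16: four pooling stages), ensuring no pixel dropout.
#' @param norm_mean,norm_sd Per-channel input normalisation constants
#'   (scalars are recycled over channels).
#' @return A list of class `model_config`.
#' @export
model_config <- function(backbone = c("tiny", "vgg19-truncated"),
                         use_pretrained_backbone = FALSE,
                         pretrained_weights = NULL,
                         alpha = 0.1, branch_channels = NULL,
                         pad_multiple = 16L, norm_mean = 0.5, norm_sd = 0.25) {
  backbone <- match.arg(backbone)
  if (alpha <= 0 || alpha >= 1) stop("config-error: alpha must lie in (0, 1)")
  if (pad_multiple != 16L) stop("config-error: pad_multiple must be 16")
  if (is.null(branch_channels)) {
    branch_channels <- if (backbone == "vgg19-truncated") c(256L, 64L)
                       else c(32L, 16L)
  }
  structure(list(backbone = backbone,
                 use_pretrained_backbone = use_pretrained_backbone,
                 pretrained_weights = pretrained_weights,
                 alpha = alpha,
                 branch_channels = as.integer(branch_channels),
                 pad_multiple = as.integer(pad_multiple),
                 output_divisor = as.integer(pad_multiple / 2L),
                 norm_mean = norm_mean, norm_sd = norm_sd),
            class = "model_config")
}

backbone_plan <- function(backbone) {
  # per block: conv widths; a 2x2 max-pool follows every block but the last
  switch(backbone,
    "vgg19-truncated" = list(c(64, 64), c(128, 128), c(256, 256, 256, 256),
                             c(512, 512, 512, 512), c(512, 512, 512, 512)),
    "tiny" = list(8, 16, 32, 64, 64),
    stop("config-error: unknown backbone '", backbone, "'"))
}

# He initialisation for from-scratch backbone convs; N(0, 0.01) for the
# branch layers as in the training recipe
init_conv <- function(cin, cout, k, scheme = c("he", "gauss001")) {
  scheme <- match.arg(scheme)
  fan_in <- k * k * cin
  sd <- if (scheme == "he") sqrt(2 / fan_in) else 0.01
  list(W = matrix(stats::rnorm(fan_in * cout, sd = sd), fan_in, cout),
       b = rep(0, cout), k = k, cin = cin, cout = cout)
}

#' Build the two-branch counting network
#'
#' Constructs the backbone (four stride-2 pooling stages), the x2 bilinear
#' upsampler and the two branches.  Each branch is
#' `conv3x3 -> ReLU -> conv3x3 -> ReLU -> conv1x1`, shrinking the channel
#' count from the backbone width down to 1.  Branch and head weights are
#' drawn from a zero-mean Gaussian with standard deviation 0.01; the
#' backbone uses He initialisation unless pretrained weights are supplied.
#'
#' @param cfg A [model_config()].
#' @param seed Optional integer seed for the weight draw (uses the current
#'   RNG state when `NULL`).
#' @return An object of class `densicount_network`.
#' @export
build_network <- function(cfg = model_config(), seed = NULL) {
  stopifnot(inherits(cfg, "model_config"))
  if (!is.null(seed)) set.seed(seed)
  plan <- backbone_plan(cfg$backbone)
  backbone <- list()
  cin <- 3L
  for (bi in seq_along(plan)) {
    for (width in plan[[bi]]) {
      backbone[[length(backbone) + 1L]] <-
        c(init_conv(cin, width, 3L, "he"), list(pool_after = FALSE))
      cin <- width
    }
    if (bi < length(plan)) backbone[[length(backbone)]]$pool_after <- TRUE
  }
  if (isTRUE(cfg$use_pretrained_backbone)) {
    if (is.null(cfg$pretrained_weights))
      stop("config-error: use_pretrained_backbone requires pretrained_weights")
    pre <- readRDS(cfg$pretrained_weights)
    for (i in seq_along(backbone)) {
      backbone[[i]]$W <- pre[[i]]$W
      backbone[[i]]$b <- pre[[i]]$b
    }
  }
  bc <- cfg$branch_channels
  make_branch <- function() list(
    init_conv(cin, bc[[1]], 3L, "gauss001"),
    init_conv(bc[[1]], bc[[2]], 3L, "gauss001"),
    init_conv(bc[[2]], 1L, 1L, "gauss001"))
  structure(list(cfg = cfg, backbone = backbone,
                 seg = make_branch(), den = make_branch()),
            class = "densicount_network")
}

#' @export
print.densicount_network <- function(x, ...) {
  np <- sum(vapply(collect_tensors(x), length, 1L))
  cat(sprintf("<densicount_network> backbone '%s', %d backbone convs, %d parameters\n",
              x$cfg$backbone, length(x$backbone), np))
  invisible(x)
}

#' Pad an image so both sides are divisible by a given multiple
#'
#' Zero-fill on the bottom/right; the original size is recorded so outputs
#' can be related back to the unpadded frame.
#'
#' @param image `H x W` or `H x W x C` numeric array.
#' @param multiple Positive integer (16 for this model's four pooling
#'   stages).
#' @return A list with `image` (padded array) and `original_size`
#'   (`c(height, width)`).
#' @export
pad_to_multiple <- function(image, multiple = 16L) {
  stopifnot(multiple >= 1)
  dims <- dim(image)
  h <- dims[[1]]; w <- dims[[2]]
  hp <- as.integer(ceiling(h / multiple) * multiple)
  wp <- as.integer(ceiling(w / multiple) * multiple)
  if (hp != h || wp != w) {
    if (length(dims) == 3L) {
      out <- array(0, c(hp, wp, dims[[3]]))
      out[seq_len(h), seq_len(w), ] <- image
    } else {
      out <- matrix(0, hp, wp)
      out[seq_len(h), seq_len(w)] <- image
    }
    image <- out
  }
  list(image = image, original_size = c(height = h, width = w))
}

#' Segmentation-guided feature mask
#'
#' `M = 1(S >= 0.5) + alpha * 1(S < 0.5)`: locations the segmentation branch
#' calls foreground keep weight 1, background locations are dampened to
#' `alpha`.  The mask multiplies the shared features point-wise (broadcast
#' over channels) before the density branch, and is treated as a constant in
#' the backward pass.
#'
#' @param spred Probability map (matrix or probability [segmentation_map()]).
#' @param alpha Dampening factor in `(0, 1)`.
#' @return Numeric matrix of mask weights.
#' @export
make_feature_mask <- function(spred, alpha = 0.1) {
  p <- as_plain_matrix(spred)
  (p >= 0.5) * 1 + alpha * (p < 0.5)
}

as_input_cube <- function(image, cfg) {
  dims <- dim(image)
  if (length(dims) == 2L) image <- array(rep(image, 3L), c(dims, 3L))
  if (dim(image)[[3]] != 3L) stop("input-error: expected 3 image channels")
  mean3 <- rep(cfg$norm_mean, length.out = 3L)
  sd3 <- rep(cfg$norm_sd, length.out = 3L)
  for (c in 1:3) image[, , c] <- (image[, , c] - mean3[[c]]) / sd3[[c]]
  image
}

run_branch <- function(branch, x, cache = FALSE) {
  caches <- list()
  for (li in seq_along(branch)) {
    lay <- branch[[li]]
    pre <- cpp_conv2d_fwd(x, lay$W, lay$b, lay$k)
    if (li < length(branch)) {
      post <- pre * (pre > 0)  # ReLU on hidden layers
      if (cache) caches[[li]] <- list(x = x, relu = pre > 0)
      x <- post
    } else {
      if (cache) caches[[li]] <- list(x = x)
      x <- pre
    }
  }
  list(out = x[, , 1L], caches = caches)
}

branch_backward <- function(branch, caches, gout) {
  g <- array(gout, c(dim(gout), 1L))
  grads <- vector("list", length(branch))
  for (li in rev(seq_along(branch))) {
    lay <- branch[[li]]
    cc <- caches[[li]]
    if (li < length(branch)) g <- g * cc$relu
    bw <- cpp_conv2d_bwd(cc$x, lay$W, g, lay$k)
    grads[[li]] <- list(W = bw$gW, b = as.numeric(bw$gb))
    g <- bw$gx
  }
  list(grads = grads, gx = g)
}

# Full forward pass.  With cache = TRUE every intermediate needed by
# nn_backward is retained.
nn_forward <- function(net, image, cache = FALSE) {
  cfg <- net$cfg
  x <- as_input_cube(image, cfg)
  if (any(dim(x)[1:2] %% cfg$pad_multiple != 0))
    stop("input-error: image must be padded to a multiple of pad_multiple")
  bb_cache <- list()
  for (li in seq_along(net$backbone)) {
    lay <- net$backbone[[li]]
    pre <- cpp_conv2d_fwd(x, lay$W, lay$b, lay$k)
    post <- pre * (pre > 0)
    entry <- list(x = x, relu = pre > 0)
    if (lay$pool_after) {
      mp <- cpp_maxpool2_fwd(post)
      entry$pool_idx <- mp$idx
      entry$pool_in_dim <- dim(post)[1:2]
      post <- mp$y
    }
    if (cache) bb_cache[[li]] <- entry
    x <- post
  }
  f16_dim <- dim(x)[1:2]
  f8 <- cpp_upsample2_fwd(x)
  segr <- run_branch(net$seg, f8, cache = cache)
  spred <- 1 / (1 + exp(-segr$out))
  mask <- make_feature_mask(spred, cfg$alpha)
  fm <- f8 * as.vector(mask)  # broadcast over channels
  denr <- run_branch(net$den, fm, cache = cache)
  dpred <- denr$out * (denr$out > 0)
  out <- list(density = dpred, segmentation = spred)
  if (cache) {
    out$cache <- list(bb = bb_cache, f16_dim = f16_dim, f8 = f8,
                      seg = segr$caches, den = denr$caches,
                      den_relu = denr$out > 0, spred = spred, mask = mask)
  }
  out
}

# Backward pass from gradients w.r.t. dpred and spred down to all weights.
# The feature mask is a constant (no gradient through the indicator).
nn_backward <- function(net, cache, g_dpred, g_spred) {
  g_den_out <- g_dpred * cache$den_relu
  den_bw <- branch_backward(net$den, cache$den, g_den_out)
  g_f8_d <- den_bw$gx * as.vector(cache$mask)
  g_logit <- g_spred * cache$spred * (1 - cache$spred)
  seg_bw <- branch_backward(net$seg, cache$seg, g_logit)
  g_f8 <- g_f8_d + seg_bw$gx
  g <- cpp_upsample2_bwd(g_f8, cache$f16_dim[[1]], cache$f16_dim[[2]])
  bb_grads <- vector("list", length(net$backbone))
  for (li in rev(seq_along(net$backbone))) {
    lay <- net$backbone[[li]]
    cc <- cache$bb[[li]]
    if (lay$pool_after)
      g <- cpp_maxpool2_bwd(cc$pool_idx, g, cc$pool_in_dim[[1]],
                            cc$pool_in_dim[[2]])
    g <- g * cc$relu
    bw <- cpp_conv2d_bwd(cc$x, lay$W, g, lay$k)
    bb_grads[[li]] <- list(W = bw$gW, b = as.numeric(bw$gb))
    g <- bw$gx
  }
  list(backbone = bb_grads, seg = seg_bw$grads, den = den_bw$grads)
}

# flat named list of all weight tensors, for the optimizer and checkpoints
collect_tensors <- function(net) {
  out <- list()
  for (grp in c("backbone", "seg", "den"))
    for (li in seq_along(net[[grp]])) {
      out[[paste0(grp, li, ".W")]] <- net[[grp]][[li]]$W
      out[[paste0(grp, li, ".b")]] <- net[[grp]][[li]]$b
    }
  out
}

set_tensors <- function(net, tensors) {
  for (grp in c("backbone", "seg", "den"))
    for (li in seq_along(net[[grp]])) {
      net[[grp]][[li]]$W <- tensors[[paste0(grp, li, ".W")]]
      net[[grp]][[li]]$b <- tensors[[paste0(grp, li, ".b")]]
    }
  net
}

grads_to_tensors <- function(grads) {
  out <- list()
  for (grp in c("backbone", "seg", "den"))
    for (li in seq_along(grads[[grp]])) {
      out[[paste0(grp, li, ".W")]] <- grads[[grp]][[li]]$W
      out[[paste0(grp, li, ".b")]] <- grads[[grp]][[li]]$b
    }
  out
}

#' Run the network on a padded image
#'
#' @param net A [build_network()] model.
#' @param image Padded `H x W x 3` array (both sides divisible by 16),
#'   values on the `[0, 1]` image scale.
#' @return A list of class `network_output` with `density` (non-negative
#'   matrix) and `segmentation` (probability matrix), both at 1/8 of the
#'   padded input size.
#' @export
forward <- function(net, image) {
  out <- nn_forward(net, image, cache = FALSE)
  structure(list(density = out$density, segmentation = out$segmentation),
            class = "network_output")
}

#' Fuse the two branches into the output density map
#'
#' `D_out = D_pred * 1(S_pred >= 0.5)`: predicted density is zeroed wherever
#' the segmentation branch assigns background probability, discarding the
#' regressor's residual response on empty terrain.
#'
#' @param out A `network_output` (or a list with `density` and
#'   `segmentation` matrices).
#' @return A [density_map()] at the network output resolution.
#' @export
fuse_inference <- function(out) {
  d <- as_plain_matrix(out$density)
  s <- as_plain_matrix(out$segmentation)
  if (!all(dim(d) == dim(s))) stop("contract-error: shape mismatch")
  density_map(d * (s >= 0.5), 8L)
}

#' Predict the object count for an arbitrary-size image
#'
#' Pads the image to a multiple of 16, runs the network, fuses the branches
#' and integrates the fused map.  The count is the total mass of the fused
#' output over the padded frame (so it is identical whether or not the
#' caller pre-padded the image); the unpadded size is recorded on the
#' returned map as attribute `original_size`.
#'
#' @param net A [build_network()] model.
#' @param image `H x W` or `H x W x 3` numeric array on the `[0, 1]` scale.
#' @return A list with `count` (non-negative scalar), `density` (fused
#'   [density_map()]) and `segmentation` (probability map).
#' @export
predict_count <- function(net, image) {
  p <- pad_to_multiple(image, net$cfg$pad_multiple)
  out <- forward(net, p$image)
  fused <- fuse_inference(out)
  attr(fused, "original_size") <- p$original_size
  list(count = density_mass(fused), density = fused,
       segmentation = segmentation_map(out$segmentation, "probability"))
}

#' Save / load model checkpoints
#'
#' Checkpoints embed the model configuration alongside the weights, so a
#' saved model is self-describing.
#'
#' @param net A `densicount_network`.
#' @param path File path (`.rds`).
#' @param extra Optional list stored verbatim (e.g. training history).
#' @export
save_checkpoint <- function(net, path, extra = NULL) {
  saveRDS(list(cfg = net$cfg, tensors = collect_tensors(net), extra = extra),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  net <- build_network(ck$cfg, seed = 0L)
  net <- set_tensors(net, ck$tensors)
  attr(net, "extra") <- ck$extra
  net
}
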