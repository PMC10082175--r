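#' Training configuration
#'
#' Defaults follow the survey-counting recipe: 256-pixel random crops with
#' random horizontal flipping, Adam at a fixed learning rate of 1e-5 with
#' weight decay 1e-4, batch size 16, 600 epochs, validation starting after
#' epoch 100, and checkpoint selection by the lowest validation MAE + RMSE.
#'
#' @param crop_size Square crop edge in pixels, divisible by 16
#'   (default 256).
#' @param flip_prob Probability of a horizontal flip (default 0.5).
#' @param epochs Number of passes over the training list (default 600).
#' @param batch_size Images per optimizer step (default 16).
#' @param learning_rate Fixed Adam learning rate (default 1e-5, tuned for a
#'   pretrained full-size backbone; use ~1e-3 when training the tiny
#'   backbone from scratch).
#' @param weight_decay L2 penalty added to the gradients (default 1e-4).
#' @param validate_after_epoch First epoch after which validation runs
#'   (default 100).
#' @param seed Integer seed governing shuffling, cropping and flipping.
#' @return A list of class `train_config`.
#' @export
train_config <- function(crop_size = 256L, flip_prob = 0.5, epochs = 600L,
                         batch_size = 16L, learning_rate = 1e-5,
                         weight_decay = 1e-4, validate_after_epoch = 100L,
                         seed = 1L) {
  if (crop_size %% 16 != 0) stop("config-error: crop_size must be divisible by 16")
  if (epochs < 1) stop("config-error: epochs must be >= 1")
  if (batch_size < 1) stop("config-error: batch_size must be >= 1")
  structure(list(crop_size = as.integer(crop_size), flip_prob = flip_prob,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 validate_after_epoch = as.integer(validate_after_epoch),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Split image ids into train / validation / test sets (3:1:1)
#'
#' A seeded random shuffle followed by a 3:1:1 partition; the validation and
#' test sizes are floored and the remainder goes to the training split.
#'
#' @param ids Character or integer vector of at least 5 items.
#' @param seed Integer seed.
#' @return A list with `train`, `val`, `test` (disjoint, exhaustive).
#' @export
split_dataset <- function(ids, seed = 1L) {
  n <- length(ids)
  if (n < 5L) stop("config-error: need at least 5 items for a 3:1:1 split")
  set.seed(seed)
  shuffled <- sample(ids)
  n_val <- floor(n / 5)
  n_test <- floor(n / 5)
  n_train <- n - n_val - n_test
  list(train = shuffled[seq_len(n_train)],
       val = shuffled[n_train + seq_len(n_val)],
       test = shuffled[n_train + n_val + seq_len(n_test)])
}

#' Random crop + horizontal flip applied jointly to image and density map
#'
#' The same crop window and flip decision are applied to the image and to
#' its precomputed full-resolution density map, so the cropped density mass
#' equals the mass of the crop window in the source map (objects straddling
#' the window border contribute fractional mass).  Images smaller than the
#' crop are zero-padded bottom/right first.
#'
#' @param image `H x W x C` array.
#' @param density Full-resolution density map (matrix), same `H x W`.
#' @param cfg A [train_config()] (supplies `crop_size` and `flip_prob`).
#' @return A list with `image` and `density`, both `crop_size` square.
#' @export
augment <- function(image, density, cfg = train_config()) {
  cs <- cfg$crop_size
  dims <- dim(image)
  den <- as_plain_matrix(density)
  if (dims[[1]] < cs || dims[[2]] < cs) {
    hp <- max(dims[[1]], cs); wp <- max(dims[[2]], cs)
    imp <- array(0, c(hp, wp, if (length(dims) == 3L) dims[[3]] else 1L))
    if (length(dims) == 3L) imp[seq_len(dims[[1]]), seq_len(dims[[2]]), ] <- image
    else imp[seq_len(dims[[1]]), seq_len(dims[[2]]), 1L] <- image
    dnp <- matrix(0, hp, wp)
    dnp[seq_len(dims[[1]]), seq_len(dims[[2]])] <- den
    image <- imp; den <- dnp; dims <- dim(image)
  }
  r0 <- if (dims[[1]] == cs) 0L else sample.int(dims[[1]] - cs + 1L, 1L) - 1L
  c0 <- if (dims[[2]] == cs) 0L else sample.int(dims[[2]] - cs + 1L, 1L) - 1L
  rr <- r0 + seq_len(cs); cc <- c0 + seq_len(cs)
  img <- if (length(dims) == 3L) image[rr, cc, , drop = FALSE]
         else array(image[rr, cc], c(cs, cs, 1L))
  dcrop <- den[rr, cc]
  if (runif(1) < cfg$flip_prob) {           # flip columns: x -> width-1-x
    img <- img[, rev(seq_len(cs)), , drop = FALSE]
    dcrop <- dcrop[, rev(seq_len(cs))]
  }
  list(image = img, density = dcrop)
}

adam_init <- function(tensors) {
  list(m = lapply(tensors, function(t) t * 0),
       v = lapply(tensors, function(t) t * 0), t = 0L)
}

adam_step <- function(tensors, grads, state, lr, wd, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(tensors)) {
    g <- grads[[nm]] + wd * tensors[[nm]]   # L2 penalty folded into the gradient
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    tensors[[nm]] <- tensors[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(tensors = tensors, state = state)
}

# loss + weight gradients for one (image crop, full-res density crop) pair
step_gradients <- function(net, image, density_crop, gcfg, lcfg) {
  dt <- as_plain_matrix(downsample_density(density_crop, gcfg$downsample_factor))
  sgt <- as_plain_matrix(make_segmentation_target(dt, gcfg$seg_epsilon))
  fw <- nn_forward(net, image, cache = TRUE)
  sl <- msl_core(fw$density, dt, sgt, lcfg, grad = TRUE)
  ce <- ce_core(fw$segmentation, sgt, lcfg, grad = TRUE)
  loss <- total_loss(sl$value, ce$value, lcfg)
  grads <- nn_backward(net, fw$cache, sl$grad, lcfg$lambda_seg * ce$grad)
  list(loss = loss, grads = grads_to_tensors(grads))
}

validate_model <- function(net, val_items) {
  pred <- vapply(val_items, function(it) predict_count(net, it$image)$count, 0)
  gt <- vapply(val_items, function(it) n_points(it$ann), 0L)
  c(mae = count_mae(pred, gt), rmse = count_rmse(pred, gt))
}

#' Train the counting network
#'
#' One epoch is one pass over the training image list with one random crop
#' per image; crops are batched and each batch takes one Adam step on the
#' mean of the per-image gradients of `SL* + lambda * CE`.  After
#' `validate_after_epoch`, every epoch is validated on the full
#' (uncropped) validation images through the fused inference pathway, and
#' the checkpoint with the lowest validation MAE + RMSE is returned (ties
#' resolved to the earliest epoch).  Fully deterministic given
#' `train_cfg$seed`; aborts with a diagnostic if the loss becomes
#' non-finite.
#'
#' @param net A [build_network()] model (its weights are the starting
#'   point).
#' @param train_items,val_items Lists of items, each a list with `image`
#'   (`H x W x 3` array), `ann` ([point_annotations()]) and `density`
#'   (full-resolution [density_map()], precomputed once).
#' @param train_cfg A [train_config()].
#' @param loss_cfg A [loss_config()].
#' @param gen_cfg A [gen_config()] (supplies the downsampling factor and
#'   segmentation threshold used to build per-crop targets on the fly).
#' @param resume Optional result of a previous `train_model` call whose
#'   optimizer state and epoch counter should be continued.
#' @param verbose Print one line per epoch.
#' @return A list of class `densicount_fit`: `net` (best model), `best`
#'   (tibble row: epoch, val_mae, val_rmse, selection_score), `history`
#'   (tibble: epoch, loss, val_mae, val_rmse, selection_score), `final_net`
#'   (weights after the last epoch) and `state` (optimizer state, for
#'   resuming).
#' @export
train_model <- function(net, train_items, val_items,
                        train_cfg = train_config(), loss_cfg = loss_config(),
                        gen_cfg = gen_config(), resume = NULL,
                        verbose = FALSE) {
  set.seed(train_cfg$seed)
  tensors <- collect_tensors(if (is.null(resume)) net else resume$final_net)
  state <- if (is.null(resume)) adam_init(tensors) else resume$state
  epoch0 <- if (is.null(resume)) 0L else max(resume$history$epoch)
  history <- if (is.null(resume)) NULL else resume$history
  best_tensors <- NULL
  best_score <- Inf; best_row <- NULL
  if (!is.null(history) && any(is.finite(history$selection_score))) {
    bi <- which.min(history$selection_score)
    best_score <- history$selection_score[[bi]]
    best_tensors <- resume$best_tensors
    best_row <- history[bi, ]
  }
  n_train <- length(train_items)
  for (ep in (epoch0 + 1L):(epoch0 + train_cfg$epochs)) {
    ord <- sample.int(n_train)
    ep_loss <- 0; n_batches <- 0L
    for (b0 in seq(1L, n_train, by = train_cfg$batch_size)) {
      idx <- ord[b0:min(b0 + train_cfg$batch_size - 1L, n_train)]
      net_cur <- set_tensors(net, tensors)
      acc <- NULL; bloss <- 0
      for (i in idx) {
        it <- train_items[[i]]
        aug <- augment(it$image, it$density, train_cfg)
        sg <- step_gradients(net_cur, aug$image, aug$density, gen_cfg,
                             loss_cfg)
        bloss <- bloss + sg$loss
        acc <- if (is.null(acc)) sg$grads
               else Map(`+`, acc, sg$grads)
      }
      acc <- lapply(acc, function(g) g / length(idx))
      bloss <- bloss / length(idx)
      if (!is.finite(bloss))
        stop("divergence: non-finite training loss at epoch ", ep)
      upd <- adam_step(tensors, acc, state, train_cfg$learning_rate,
                       train_cfg$weight_decay)
      tensors <- upd$tensors; state <- upd$state
      ep_loss <- ep_loss + bloss; n_batches <- n_batches + 1L
    }
    ep_loss <- ep_loss / n_batches
    val_mae <- NA_real_; val_rmse <- NA_real_; score <- NA_real_
    if (ep > train_cfg$validate_after_epoch && length(val_items) > 0L) {
      vm <- validate_model(set_tensors(net, tensors), val_items)
      val_mae <- vm[["mae"]]; val_rmse <- vm[["rmse"]]
      score <- val_mae + val_rmse
      if (score < best_score) {  # strict: ties keep the earliest epoch
        best_score <- score
        best_tensors <- tensors
        best_row <- tibble::tibble(epoch = ep, val_mae = val_mae,
                                   val_rmse = val_rmse,
                                   selection_score = score)
      }
    }
    history <- dplyr::bind_rows(history,
      tibble::tibble(epoch = ep, loss = ep_loss, val_mae = val_mae,
                     val_rmse = val_rmse, selection_score = score))
    if (verbose)
      message(sprintf("epoch %d  loss %.5f  val_mae %s", ep, ep_loss,
                      ifelse(is.na(val_mae), "-", sprintf("%.3f", val_mae))))
  }
  if (is.null(best_tensors)) {  # no validation epochs ran
    best_tensors <- tensors
    best_row <- tibble::tibble(epoch = max(history$epoch), val_mae = NA_real_,
                               val_rmse = NA_real_, selection_score = NA_real_)
  }
  structure(list(net = set_tensors(net, best_tensors), best = best_row,
                 history = history, final_net = set_tensors(net, tensors),
                 state = state, best_tensors = best_tensors),
            class = "densicount_fit")
}

#' Checkpoint selection rule
#'
#' Given a history of validation records, returns the row with the lowest
#' `val_mae + val_rmse` (earliest epoch on ties) — the rule used to pick the
#' reported model.
#'
#' @param history A data frame with columns `epoch`, `val_mae`, `val_rmse`.
#' @return A one-row tibble with `epoch`, `val_mae`, `val_rmse`,
#'   `selection_score`.
#' @export
select_checkpoint <- function(history) {
  h <- tibble::as_tibble(history)
  h$selection_score <- h$val_mae + h$val_rmse
  h <- h[is.finite(h$selection_score), ]
  if (nrow(h) == 0L) stop("contract-error: no finite validation records")
  h[which.min(h$selection_score),
    c("epoch", "val_mae", "val_rmse", "selection_score")]
}

#' @export
print.densicount_fit <- function(x, ...) {
  cat(sprintf("<densicount_fit> %d epoch(s); best epoch %s (val MAE %.3f, RMSE %.3f)\n",
              max(x$history$epoch), x$best$epoch,
              x$best$val_mae, x$best$val_rmse))
  invisible(x)
}

#' Prepare training items from generated scenes
#'
#' Precomputes the full-resolution density map for each scene once, so
#' training crops can reuse it.
#'
#' @param scenes List of `generate_scene()` results.
#' @param gen_cfg A [gen_config()].
#' @return A list of items suitable for [train_model()].
#' @export
prepare_items <- function(scenes, gen_cfg = gen_config()) {
  lapply(scenes, function(s)
    list(image = s$image, ann = s$ann,
         density = generate_density_map(s$ann, gen_cfg)))
}

#' broom-style tidiers for fitted counting models
#'
#' `tidy()` returns the per-epoch training history; `glance()` returns a
#' one-row summary of the selected checkpoint.
#'
#' @param x A `densicount_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @importFrom generics tidy glance
#' @export
tidy.densicount_fit <- function(x, ...) x$history

#' @rdname tidy.densicount_fit
#' @export
glance.densicount_fit <- function(x, ...) {
  tibble::tibble(epochs = max(x$history$epoch),
                 best_epoch = x$best$epoch,
                 val_mae = x$best$val_mae,
                 val_rmse = x$best$val_rmse,
                 selection_score = x$best$selection_score,
                 final_loss = x$history$loss[[nrow(x$history)]])
}

#' Plot a training history
#'
#' Loss per epoch with validation MAE/RMSE overlaid once validation starts.
#'
#' @param object A `densicount_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.densicount_fit <- function(object, ...) {
  h <- object$history
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$loss, colour = "training loss")) +
    ggplot2::geom_line(data = h[is.finite(h$val_mae), ],
                       ggplot2::aes(y = .data$val_mae, colour = "val MAE")) +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
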