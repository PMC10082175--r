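test_that("3:1:1 split is disjoint, exhaustive and seeded", {
  ids <- sprintf("im%03d", 1:100)
  sp <- split_dataset(ids, seed = 3)
  expect_length(sp$train, 60)
  expect_length(sp$val, 20)
  expect_length(sp$test, 20)
  expect_setequal(c(sp$train, sp$val, sp$test), ids)
  expect_identical(sp, split_dataset(ids, seed = 3))
  expect_false(identical(sp$train, split_dataset(ids, seed = 4)$train))

  # remainder goes to the training split
  sp7 <- split_dataset(letters[1:7], seed = 1)
  expect_equal(lengths(sp7[c("train", "val", "test")]),
               c(train = 5L, val = 1L, test = 1L))
  expect_error(split_dataset(1:4), "config-error")
})

test_that("augmentation crops image and density jointly and flips involute", {
  set.seed(17)
  scene <- generate_scene(scene_config(image_size = c(96L, 96L),
                                       n_objects = 12L, seed = 17L), "a")
  den <- generate_density_map(scene$ann)
  cfg_noflip <- train_config(crop_size = 64L, flip_prob = 0, epochs = 1)
  a <- augment(scene$image, den, cfg_noflip)
  expect_equal(dim(a$image), c(64, 64, 3))
  expect_equal(dim(a$density), c(64, 64))

  # all-zero density stays zero under any crop
  z <- augment(scene$image, matrix(0, 96, 96), cfg_noflip)
  expect_identical(sum(z$density), 0)

  # forced flip applied twice recovers the original crop
  cfg_flip <- train_config(crop_size = 96L, flip_prob = 1, epochs = 1)
  f1 <- augment(scene$image, den, cfg_flip)
  f2 <- augment(f1$image, f1$density, cfg_flip)
  expect_equal(f2$image, scene$image, tolerance = 1e-12)
  expect_equal(f2$density, unclass(den), tolerance = 1e-12,
               ignore_attr = TRUE)
  # flip preserves mass
  expect_equal(sum(f1$density), density_mass(den), tolerance = 1e-12)
})

test_that("mean cropped mass matches the window-area expectation", {
  set.seed(23)
  scene <- generate_scene(scene_config(image_size = c(128L, 128L),
                                       n_objects = 60L, seed = 23L,
                                       min_spacing = 3), "mc")
  den <- generate_density_map(scene$ann)
  cfg <- train_config(crop_size = 64L, flip_prob = 0.5, epochs = 1)
  masses <- vapply(1:1000, function(i) sum(augment(scene$image, den, cfg)$density), 0)
  # expected mass of a uniform crop window = mean over all window positions
  pos <- 128 - 64 + 1
  expected <- mean(vapply(seq_len(pos), function(r0) {
    sum(vapply(seq_len(pos), function(c0) {
      sum(unclass(den)[r0:(r0 + 63), c0:(c0 + 63)])
    }, 0))
  }, 0)) / pos
  expect_equal(mean(masses), expected, tolerance = 0.05)
})

test_that("checkpoint selection picks the lowest MAE + RMSE, earliest on ties", {
  h <- tibble::tibble(epoch = 1:3, val_mae = c(5, 3, 4), val_rmse = c(7, 10, 4))
  best <- select_checkpoint(h)
  expect_identical(best$epoch, 3L)
  expect_identical(best$selection_score, 8)

  ht <- tibble::tibble(epoch = 1:3, val_mae = c(4, 2, 3), val_rmse = c(2, 4, 3))
  expect_identical(select_checkpoint(ht)$epoch, 1L)  # all score 6: earliest
  expect_error(select_checkpoint(tibble::tibble(epoch = 1, val_mae = NA_real_,
                                                val_rmse = NA_real_)),
               "contract-error")
})

make_smoke_items <- function(n, seed, size = 64L) {
  gcfg <- gen_config()
  lapply(seq_len(n), function(i) {
    sc <- generate_scene(scene_config(image_size = c(size, size),
                                      n_objects = sample(0:25, 1),
                                      seed = seed * 1000L + i), sprintf("s%d", i))
    list(image = sc$image, ann = sc$ann,
         density = generate_density_map(sc$ann, gcfg))
  })
}

test_that("a short seeded run reduces the training loss and is reproducible", {
  set.seed(71)
  items <- make_smoke_items(8, seed = 71)
  tcfg <- train_config(crop_size = 48L, epochs = 6L, batch_size = 4L,
                       learning_rate = 1e-3, validate_after_epoch = 3L,
                       seed = 5L)
  run <- function() {
    net <- tiny_net(seed = 31)
    train_model(net, items[1:6], items[7:8], tcfg, loss_config(), gen_config())
  }
  f1 <- run()
  expect_lt(f1$history$loss[[6]], f1$history$loss[[1]])
  # selection rule agrees with a brute-force scan of the history
  expect_equal(f1$best$epoch, select_checkpoint(f1$history)$epoch)
  expect_equal(f1$best$selection_score,
               min(f1$history$selection_score, na.rm = TRUE))

  f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(f1$best, f2$best)

  # tidiers expose the history and summary
  expect_identical(tidy(f1), f1$history)
  g <- glance(f1)
  expect_identical(g$best_epoch, f1$best$epoch)
})

test_that("training resumes from a previous state seamlessly", {
  set.seed(91)
  items <- make_smoke_items(6, seed = 91, size = 48L)
  tcfg2 <- train_config(crop_size = 48L, epochs = 2L, batch_size = 3L,
                        learning_rate = 1e-3, validate_after_epoch = 1L,
                        seed = 9L)
  net <- tiny_net(seed = 13)
  f1 <- train_model(net, items[1:4], items[5:6], tcfg2, loss_config(),
                    gen_config())
  f2 <- train_model(net, items[1:4], items[5:6], tcfg2, loss_config(),
                    gen_config(), resume = f1)
  expect_equal(max(f2$history$epoch), 4L)
  expect_identical(f2$history$epoch, 1:4)
})

test_that("overfitting a fixed tiny batch drives the loss far down", {
  # train on two fixed images with full-image crops: the loss should fall
  # below 10% of its initial value well within the step budget
  set.seed(37)
  items <- make_smoke_items(2, seed = 37, size = 48L)
  tcfg <- train_config(crop_size = 48L, epochs = 120L, batch_size = 2L,
                       learning_rate = 2e-3, flip_prob = 0,
                       validate_after_epoch = 1e6L, seed = 3L)
  fit <- train_model(tiny_net(seed = 8), items, list(), tcfg, loss_config(),
                     gen_config())
  expect_lt(min(fit$history$loss), 0.10 * fit$history$loss[[1]])
})
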