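test_that("padding rounds sizes up to the next multiple of 16", {
  p1 <- pad_to_multiple(random_rgb(448, 448), 16)
  expect_equal(dim(p1$image)[1:2], c(448, 448))
  p2 <- pad_to_multiple(random_rgb(450, 300), 16)
  expect_equal(dim(p2$image)[1:2], c(464, 304))
  expect_equal(unname(p2$original_size), c(450, 300))
  p3 <- pad_to_multiple(matrix(1, 1, 1), 16)
  expect_equal(dim(p3$image), c(16, 16))
  # padding is zero-fill bottom/right
  expect_true(all(p2$image[451:464, , ] == 0))
  expect_true(all(p2$image[, 301:304, ] == 0))
})

test_that("network construction follows the branch design", {
  net <- tiny_net(seed = 1)
  expect_gt(sum(vapply(net$backbone, function(l) length(l$W), 0)), 0)
  # branches: kernel sizes 3, 3, 1; channels shrink to 1
  for (br in list(net$seg, net$den)) {
    expect_equal(vapply(br, `[[`, 0L, "k"), c(3L, 3L, 1L))
    expect_identical(br[[3]]$cout, 1L)
  }
  # four pooling stages in the backbone
  expect_identical(sum(vapply(net$backbone, `[[`, TRUE, "pool_after")), 4L)

  # seeded determinism of initial weights
  n1 <- tiny_net(seed = 42)
  n2 <- tiny_net(seed = 42)
  expect_identical(n1$backbone[[1]]$W, n2$backbone[[1]]$W)
  expect_identical(n1$den[[2]]$W, n2$den[[2]]$W)

  expect_error(model_config("resnet"), "arg")
  expect_error(model_config(alpha = 1.5), "config-error")
})

test_that("feature mask keeps foreground at 1 and dampens background", {
  expect_equal(make_feature_mask(matrix(0.9, 3, 3)), matrix(1, 3, 3))
  expect_equal(make_feature_mask(matrix(0.2, 3, 3), alpha = 0.1),
               matrix(0.1, 3, 3))
  # threshold is inclusive at 0.5
  m <- make_feature_mask(matrix(c(0.5, 0.49), 1, 2), alpha = 0.1)
  expect_equal(as.numeric(m), c(1, 0.1))

  set.seed(6)
  p <- matrix(runif(64), 8, 8)
  expect_equal(make_feature_mask(p, 0.3),
               ifelse(p >= 0.5, 1, 0.3), ignore_attr = TRUE)
})

test_that("forward obeys the 1/8 output-shape contract and head ranges", {
  net <- tiny_net(seed = 2)
  out <- forward(net, random_rgb(256, 256))
  expect_equal(dim(out$density), c(32, 32))
  expect_equal(dim(out$segmentation), c(32, 32))
  out2 <- forward(net, random_rgb(448, 448))
  expect_equal(dim(out2$density), c(56, 56))
  expect_true(all(out2$density >= 0))
  expect_true(all(out2$segmentation >= 0 & out2$segmentation <= 1))
  expect_error(forward(net, array(1, c(64, 64, 2))), "input-error")
  expect_error(forward(net, random_rgb(50, 64)), "input-error")
})

test_that("fusion zeroes density where segmentation is background", {
  set.seed(10)
  d <- random_density_matrix(6, 6)
  lo <- matrix(0.3, 6, 6)
  hi <- matrix(0.8, 6, 6)
  expect_equal(density_mass(fuse_inference(list(density = d, segmentation = lo))), 0)
  expect_equal(unclass(fuse_inference(list(density = d, segmentation = hi))),
               d, ignore_attr = TRUE)
  for (i in 1:30) {
    s <- matrix(runif(36), 6, 6)
    fused <- fuse_inference(list(density = d, segmentation = s))
    expect_equal(unclass(fused), d * (s >= 0.5), ignore_attr = TRUE)
    expect_lte(density_mass(fused), sum(d))
  }
  expect_error(fuse_inference(list(density = d, segmentation = matrix(0.5, 3, 3))),
               "contract-error")
})

test_that("predicted counts are padding-invariant, non-negative and equal the fused mass", {
  net <- tiny_net(seed = 3)
  img <- random_rgb(150, 150)
  a <- predict_count(net, img)
  pre <- pad_to_multiple(img, 16)$image
  b <- predict_count(net, pre)
  expect_equal(a$count, b$count, tolerance = 1e-9)
  expect_gte(a$count, 0)
  expect_equal(a$count, density_mass(a$density), tolerance = 1e-12)

  # zeroed density head forces a zero count
  net0 <- net
  net0$den[[3]]$W[] <- 0
  net0$den[[3]]$b[] <- 0
  expect_equal(predict_count(net0, img)$count, 0)
})

test_that("output dimensions follow ceil(H/16)*16/8 for random sizes", {
  net <- tiny_net(seed = 4)
  set.seed(44)
  for (i in 1:8) {
    h <- sample(17:120, 1); w <- sample(17:120, 1)
    res <- predict_count(net, random_rgb(h, w))
    expect_equal(dim(res$density),
                 c(ceiling(h / 16) * 16 / 8, ceiling(w / 16) * 16 / 8))
  }
})

test_that("inference is deterministic for a fixed seed and input", {
  img <- random_rgb(64, 64)
  r1 <- predict_count(tiny_net(seed = 11), img)
  r2 <- predict_count(tiny_net(seed = 11), img)
  expect_identical(r1$count, r2$count)
  expect_identical(unclass(r1$density), unclass(r2$density))
})

test_that("network weight gradients agree with finite differences", {
  dc <- asNamespace("densicount")
  set.seed(55)
  net <- tiny_net(seed = 9)
  net$seg[[3]]$b <- 0.8   # keep spred clear of the 0.5 mask threshold
  net$den[[3]]$b <- 0.05
  img <- random_rgb(32, 32)
  ann <- point_annotations("g", data.frame(x = c(10, 25), y = c(8, 26)),
                           c(32, 32))
  gcfg <- gen_config(); lcfg <- loss_config()
  den <- generate_density_map(ann, gcfg)
  loss_of <- function(nn) {
    dt <- unclass(downsample_density(den, 8))
    attributes(dt) <- list(dim = dim(dt))
    sgt <- (dt > gcfg$seg_epsilon) * 1
    fw <- dc$nn_forward(nn, img, cache = TRUE)
    sl <- dc$msl_core(fw$density, dt, sgt, lcfg, grad = TRUE)
    ce <- dc$ce_core(fw$segmentation, sgt, lcfg, grad = TRUE)
    list(loss = total_loss(sl$value, ce$value, lcfg),
         grads = dc$grads_to_tensors(
           dc$nn_backward(nn, fw$cache, sl$grad, lcfg$lambda_seg * ce$grad)))
  }
  base <- loss_of(net)
  tensors <- dc$collect_tensors(net)
  eps <- 1e-6
  for (nm in c("backbone1.W", "backbone3.W", "backbone5.b", "seg1.W",
               "seg3.W", "den1.W", "den2.b", "den3.W")) {
    for (ix in sample(length(tensors[[nm]]), 2)) {
      tp <- tensors; tp[[nm]][ix] <- tp[[nm]][ix] + eps
      tm <- tensors; tm[[nm]][ix] <- tm[[nm]][ix] - eps
      num <- (loss_of(dc$set_tensors(net, tp))$loss -
              loss_of(dc$set_tensors(net, tm))$loss) / (2 * eps)
      ana <- base$grads[[nm]][ix]
      expect_lt(abs(num - ana) / max(abs(num) + abs(ana), 1e-6), 1e-3)
    }
  }
})

test_that("checkpoints round-trip weights and config", {
  net <- tiny_net(seed = 20)
  img <- random_rgb(48, 48)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(net, path, extra = list(note = "test"))
  back <- load_checkpoint(path)
  expect_identical(predict_count(back, img)$count, predict_count(net, img)$count)
  expect_identical(attr(back, "extra")$note, "test")
})
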