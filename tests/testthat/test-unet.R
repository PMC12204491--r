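test_that("receptive field follows (k - 1) d + 1", {
  expect_equal(receptive_field(3, 1), 3)
  expect_equal(receptive_field(3, 3), 7)
  expect_equal(receptive_field(5, 2), 9)
  expect_error(receptive_field(3, 0), "d >= 1")
})

impulse_support <- function(dilations, k = 3, n = 63) {
  # push an impulse through all-positive dilated conv layers and measure the
  # support of the response
  x <- array(0, c(n, n, 1, 1))
  x[(n + 1) / 2, (n + 1) / 2, 1, 1] <- 1
  for (d in dilations) {
    W <- array(1, c(k, k, 1, 1))
    x <- aaastress:::cpp_conv_fwd(x, W, 0, as.integer(d))
  }
  rows <- which(apply(x[, , 1, 1], 1, max) > 0)
  max(rows) - min(rows) + 1L
}

test_that("measured impulse support matches the receptive-field formula", {
  for (d in c(1, 2, 3)) {
    expect_equal(impulse_support(d), receptive_field(3, d))
  }
  # the stacked encoder schedule: 1 + sum (k-1) d
  sched <- c(1, 2, 3, 1)
  expect_equal(impulse_support(sched), 1 + sum(2 * sched)) # = 15
})

test_that("patch grids tile, pad, and invert correctly", {
  g <- patch_grid(c(64, 64), 32, 32)
  expect_equal(nrow(g), 4L)
  img <- matrix(rnorm(64 * 64), 64)
  p <- extract_patches(img, g)
  expect_equal(dim(p), c(32, 32, 4))
  expect_equal(stitch_patches(p, g), img) # exact at stride == patch
  # patch == image size
  g1 <- patch_grid(c(64, 64), 64, 64)
  p1 <- extract_patches(img, g1)
  expect_equal(p1[, , 1], img)
  # overlapped: 16 patches; constants reconstruct exactly
  g2 <- patch_grid(c(64, 64), 32, 16)
  expect_equal(nrow(g2), 16L)
  cimg <- matrix(pi, 64, 64)
  expect_equal(stitch_patches(extract_patches(cimg, g2), g2), cimg)
  # zero-padded ragged edge
  g3 <- patch_grid(c(50, 70), 32, 32)
  expect_equal(nrow(g3), ceiling(50 / 32) * ceiling(70 / 32))
  img3 <- matrix(runif(50 * 70), 50)
  expect_equal(stitch_patches(extract_patches(img3, g3), g3), img3)
  expect_error(patch_grid(c(64, 64), 32, 0), "positive")
  expect_error(stitch_patches(p, g2), "inconsistent")
})

test_that("combined loss behaves at its anchor points", {
  t <- matrix(c(1, 0, 1, 0), 2)
  expect_lt(combined_loss(pmin(pmax(t, 1e-7), 1 - 1e-7), t), 1e-3)
  expect_gt(combined_loss(pmin(pmax(1 - t, 1e-7), 1 - 1e-7), t), 5)
  # uniform 0.5 prediction, half-foreground 2x2 target, eps = 1:
  # BCE = ln 2; soft dice = (2*1 + 1) / (2 + 2 + 1) = 3/5
  p <- matrix(0.5, 2, 2)
  expect_equal(combined_loss(p, t), log(2) + (1 - 3 / 5), tolerance = 1e-12)
  expect_error(combined_loss(matrix(0.5, 2, 3), t), "shapes differ")
  # non-negativity over random inputs
  set.seed(8)
  for (i in 1:5) {
    pr <- matrix(runif(16, 0.01, 0.99), 4)
    tg <- matrix(rbinom(16, 1, 0.5), 4)
    expect_gte(combined_loss(pr, tg), 0)
  }
})

test_that("augmentation is seeded, paired, and involutive for flips", {
  img <- matrix(runif(32 * 32), 32)
  msk <- disk_slice(32, 8)
  off <- augmentation_spec(hflip = FALSE, vflip = FALSE, rotation = 0,
                           zoom = c(1, 1), intensity = c(1, 1), seed = 1)
  a <- augment_pair(img, msk, off)
  expect_identical(a$image, img)
  expect_identical(a$mask, msk)

  sp <- augmentation_spec(seed = 99)
  a1 <- augment_pair(img, msk, sp)
  a2 <- augment_pair(img, msk, sp)
  expect_identical(a1, a2) # bitwise reproducible
  expect_true(all(a1$mask %in% c(0, 1))) # mask stays binary

  # horizontal flip twice is the identity
  flip <- img[, rev(seq_len(ncol(img)))]
  expect_identical(flip[, rev(seq_len(ncol(flip)))], img)
})

test_that("the network forward pass has the contracted shape and range", {
  model <- build_unet(base_channels = 4, seed = 2)
  x <- array(runif(64 * 64), c(64, 64, 1))
  p <- unet_forward(model, x)
  expect_equal(dim(p), c(64, 64, 1, 1))
  expect_true(all(p > 0 & p < 1))
  x2 <- array(runif(32 * 32 * 3), c(32, 32, 3)) # batch of 3
  p2 <- unet_forward(model, x2)
  expect_equal(dim(p2), c(32, 32, 1, 3))
  expect_error(unet_forward(model, array(0, c(30, 30, 1))), "divisible by 8")
  expect_error(build_unet(dilations = c(1, 2)), "four rates")
  expect_gt(n_parameters(model), 0)
})

test_that("backpropagation matches numerical gradients", {
  set.seed(3)
  model <- build_unet(base_channels = 2, seed = 5)
  x <- array(runif(16 * 16 * 2), c(16, 16, 2))
  y <- array(rbinom(16 * 16 * 2, 1, 0.4), c(16, 16, 2))
  cache <- unet_forward(model, x, cache = TRUE)
  gl <- array(
    aaastress:::combined_loss_grad_logits(cache$probs, aaastress:::as_batch(y)),
    dim(cache$probs)
  )
  grads <- aaastress:::unet_backward(model, cache, gl)
  lossfun <- function(m) combined_loss(unet_forward(m, x), aaastress:::as_batch(y))
  base_loss <- lossfun(model)
  for (nm in c("e1c1", "d2c2", "out")) {
    for (rep in 1:2) {
      i <- sample(length(model$layers[[nm]]$W), 1)
      m2 <- model
      eps <- 1e-6
      m2$layers[[nm]]$W[i] <- m2$layers[[nm]]$W[i] + eps
      num <- (lossfun(m2) - base_loss) / eps
      expect_equal(grads[[nm]]$gW[i], num, tolerance = 1e-3)
    }
  }
})

test_that("prediction needs spacing and thresholds monotonically", {
  model <- build_unet(base_channels = 2, seed = 4)
  vol <- array(runif(2 * 64 * 64), c(2, 64, 64))
  expect_error(predict_volume(model, vol), "spacing")
  m_lo <- predict_volume(model, vol, c(1, 1), 1, threshold = 0.3)
  m_hi <- predict_volume(model, vol, c(1, 1), 1, threshold = 0.7)
  expect_true(all(m_hi$voxels <= m_lo$voxels)) # raising threshold never grows
  # a head biased to +inf predicts everything
  sat <- model
  sat$layers$out$b[] <- 50
  m_all <- predict_volume(sat, vol, c(1, 1), 1)
  expect_equal(sum(m_all$voxels), length(m_all$voxels))
})

test_that("checkpoints save and restore the exact model", {
  model <- build_unet(base_channels = 2, seed = 6)
  f <- tempfile(fileext = ".rds")
  save_unet(model, f)
  m2 <- load_unet(f)
  expect_identical(unclass(m2), unclass(model))
  x <- array(runif(16 * 16), c(16, 16, 1))
  expect_identical(unet_forward(m2, x), unet_forward(model, x))
})

test_that("a short training run is reproducible under a fixed seed", {
  ds <- phantom_dataset(16, patch_size = 32, seed = 21, n_phantoms = 2)
  run <- function() {
    model <- build_unet(base_channels = 4, seed = 21)
    model <- train_unet(model, ds$x, ds$y, epochs = 1, batch_size = 8, seed = 21)
    model$history$loss
  }
  l1 <- run(); l2 <- run()
  expect_equal(l1, l2, tolerance = 1e-4)
})
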