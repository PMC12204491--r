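#' Receptive field of a dilated convolution
#'
#' A single dilated convolution with kernel size `k` and dilation rate `d`
#' sees `RF = (k - 1) * d + 1` pixels: the taps are spread `d` pixels apart,
#' enlarging context without extra parameters. Stacked layers add their
#' `(k - 1) * d` increments.
#'
#' @param k kernel size in pixels (>= 1).
#' @param d dilation rate (>= 1).
#' @return receptive field in pixels.
#' @examples
#' receptive_field(3, 1) # 3
#' receptive_field(3, 3) # 7
#' @export
receptive_field <- function(k, d) {
  if (any(k < 1) || any(d < 1)) abort("need k >= 1 and d >= 1")
  (k - 1) * d + 1
}

#' Patch grid over an image
#'
#' Row-major tiling with `ceiling(H / stride) * ceiling(W / stride)` patches;
#' patches hanging over the image edge are zero-padded. `stride` may be
#' smaller than `patch_size` for overlapped inference.
#'
#' @param source_shape `c(H, W)` of the source image.
#' @param patch_size patch edge, px.
#' @param stride step between patch origins, px (`<= patch_size`).
#' @return object of class `patch_grid` (tibble of 0-based origins `row0`,
#'   `col0` with the geometry in attributes).
#' @export
patch_grid <- function(source_shape, patch_size, stride = patch_size) {
  if (stride <= 0) abort("stride must be positive")
  if (stride > patch_size) abort("stride must not exceed patch_size (gaps)")
  H <- source_shape[1]; W <- source_shape[2]
  nr <- ceiling(H / stride); nc <- ceiling(W / stride)
  origins <- tidyr::expand_grid(
    row0 = (seq_len(nr) - 1L) * stride,
    col0 = (seq_len(nc) - 1L) * stride
  )
  structure(
    origins,
    class = c("patch_grid", class(origins)),
    patch_size = as.integer(patch_size), stride = as.integer(stride),
    source_shape = as.integer(c(H, W))
  )
}

#' Extract / stitch image patches
#'
#' `extract_patches()` cuts the grid's patches (zero-padded at the edges) in
#' row-major order; `stitch_patches()` reassembles them, averaging overlapped
#' pixels. At `stride == patch_size` the round trip is exact for any image;
#' with overlap it is exact on constant images.
#'
#' @param image 2D numeric matrix.
#' @param grid a [patch_grid()].
#' @return `extract_patches()`: array `(patch_size, patch_size, n_patches)`.
#' @export
extract_patches <- function(image, grid) {
  ps <- attr(grid, "patch_size")
  ss <- attr(grid, "source_shape")
  if (!identical(as.integer(dim(image)), ss)) abort("image shape does not match grid")
  out <- array(0, c(ps, ps, nrow(grid)))
  for (i in seq_len(nrow(grid))) {
    r <- grid$row0[i]; c2 <- grid$col0[i]
    rr <- (r + 1L):min(r + ps, ss[1])
    cc <- (c2 + 1L):min(c2 + ps, ss[2])
    out[seq_along(rr), seq_along(cc), i] <- image[rr, cc]
  }
  out
}

#' @rdname extract_patches
#' @param patches array from `extract_patches()` (possibly model output of
#'   the same shape).
#' @export
stitch_patches <- function(patches, grid) {
  ps <- attr(grid, "patch_size")
  ss <- attr(grid, "source_shape")
  if (!identical(as.integer(dim(patches)), c(ps, ps, nrow(grid)))) {
    abort("patch stack inconsistent with grid")
  }
  acc <- matrix(0, ss[1], ss[2])
  cnt <- matrix(0, ss[1], ss[2])
  for (i in seq_len(nrow(grid))) {
    r <- grid$row0[i]; c2 <- grid$col0[i]
    rr <- (r + 1L):min(r + ps, ss[1])
    cc <- (c2 + 1L):min(c2 + ps, ss[2])
    acc[rr, cc] <- acc[rr, cc] + patches[seq_along(rr), seq_along(cc), i]
    cnt[rr, cc] <- cnt[rr, cc] + 1
  }
  acc / cnt
}

#' Combined Dice + binary cross-entropy segmentation loss
#'
#' `BCE + (1 - softDice)` with equal weighting by default; the soft Dice term
#' uses smoothing `eps = 1` in numerator and denominator so empty targets are
#' well-behaved. BCE confidence and Dice overlap complement each other for
#' boundary delineation.
#'
#' @param pred predicted probabilities in (0, 1), any array shape.
#' @param target binary mask of the same shape.
#' @param eps Dice smoothing constant.
#' @param bce_weight,dice_weight term weights (default 1:1).
#' @return scalar loss.
#' @export
combined_loss <- function(pred, target, eps = 1, bce_weight = 1,
                          dice_weight = 1) {
  if (!identical(dim(pred) %||% length(pred),
                 dim(target) %||% length(target))) {
    abort("pred and target shapes differ")
  }
  p <- pmin(pmax(pred, 1e-7), 1 - 1e-7)
  bce <- -mean(target * log(p) + (1 - target) * log(1 - p))
  dice <- (2 * sum(p * target) + eps) / (sum(p) + sum(target) + eps)
  bce_weight * bce + dice_weight * (1 - dice)
}

#' Augmentation settings for image/mask pairs
#'
#' Geometric transforms (flips, rotation, zoom) are applied identically to
#' image and mask (image bilinear, mask nearest-neighbour re-binarized);
#' intensity scaling touches the image only. Given the same seed the output
#' is bitwise reproducible.
#'
#' @param hflip,vflip allow horizontal / vertical flips (p = 0.5 each).
#' @param rotation max |rotation| in degrees (uniform; 0 disables).
#' @param zoom zoom factor range `c(lo, hi)` (`c(1, 1)` disables).
#' @param intensity multiplicative intensity range for the image.
#' @param seed integer seed.
#' @return an `augmentation_spec` list.
#' @export
augmentation_spec <- function(hflip = TRUE, vflip = TRUE, rotation = 15,
                              zoom = c(0.9, 1.1), intensity = c(0.9, 1.1),
                              seed = 1L) {
  structure(
    list(hflip = hflip, vflip = vflip, rotation = rotation,
         zoom = rep_len(zoom, 2L), intensity = rep_len(intensity, 2L),
         seed = as.integer(seed)),
    class = "augmentation_spec"
  )
}

affine_sample <- function(img, angle, zoom, bilinear = TRUE) {
  h <- nrow(img); w <- ncol(img)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  co <- cos(angle); si <- sin(angle)
  r <- row(img) - cy; c2 <- col(img) - cx
  # inverse map: rotate by -angle, scale by 1/zoom
  sr <- (co * r + si * c2) / zoom + cy
  sc <- (-si * r + co * c2) / zoom + cx
  if (bilinear) {
    r0 <- floor(sr); c0 <- floor(sc)
    fr <- sr - r0; fc <- sc - c0
    gv <- function(ri, ci) {
      ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
      out <- matrix(0, h, w)
      out[ok] <- img[cbind(ri[ok], ci[ok])]
      out
    }
    gv(r0, c0) * (1 - fr) * (1 - fc) + gv(r0 + 1, c0) * fr * (1 - fc) +
      gv(r0, c0 + 1) * (1 - fr) * fc + gv(r0 + 1, c0 + 1) * fr * fc
  } else {
    ri <- round(sr); ci <- round(sc)
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    out <- matrix(0, h, w)
    out[ok] <- img[cbind(ri[ok], ci[ok])]
    out
  }
}

#' Apply a seeded augmentation to an image/mask pair
#'
#' @param image numeric matrix.
#' @param mask binary matrix of the same shape.
#' @param spec an [augmentation_spec()].
#' @return list `image`, `mask` (mask still binary).
#' @export
augment_pair <- function(image, mask, spec) {
  stopifnot(inherits(spec, "augmentation_spec"))
  if (!identical(dim(image), dim(mask))) abort("image and mask shapes differ")
  set.seed(spec$seed)
  do_h <- isTRUE(spec$hflip) && runif(1) < 0.5
  do_v <- isTRUE(spec$vflip) && runif(1) < 0.5
  angle <- if (spec$rotation > 0) runif(1, -spec$rotation, spec$rotation) * pi / 180 else 0
  zoom <- if (diff(spec$zoom) > 0 || spec$zoom[1] != 1) runif(1, spec$zoom[1], spec$zoom[2]) else 1
  gain <- if (diff(spec$intensity) > 0 || spec$intensity[1] != 1) {
    runif(1, spec$intensity[1], spec$intensity[2])
  } else 1
  if (do_h) { image <- image[, rev(seq_len(ncol(image)))]; mask <- mask[, rev(seq_len(ncol(mask)))] }
  if (do_v) { image <- image[rev(seq_len(nrow(image))), ]; mask <- mask[rev(seq_len(nrow(mask))), ] }
  if (angle != 0 || zoom != 1) {
    image <- affine_sample(image, angle, zoom, bilinear = TRUE)
    mask <- (affine_sample(mask, angle, zoom, bilinear = FALSE) > 0.5) * 1
  }
  list(image = image * gain, mask = mask)
}

# ---- network --------------------------------------------------------------

he_init <- function(k, cin, cout, rng) {
  array(rng(k * k * cin * cout) * sqrt(2 / (k * k * cin)), c(k, k, cin, cout))
}

#' Build the patch-based dilated U-Net
#'
#' A compact encoder-decoder with skip connections: four encoder blocks (two
#' 3x3 convolutions + ReLU each) carrying the dilation schedule — rate 1,
#' then 2, then 3, then back to 1 — 2x2 max-pooling between blocks, a mirror
#' decoder with nearest-neighbour upsampling and skip concatenation, and a
#' 1x1 sigmoid output head. Channel widths double per level from
#' `base_channels`.
#'
#' @param base_channels channels of the first block (default 16).
#' @param dilations dilation rates of the four encoder blocks (default
#'   `c(1, 2, 3, 1)`).
#' @param in_channels input image channels (default 1).
#' @param seed seed for He-initialized weights.
#' @return object of class `unet_model`; see [n_parameters()],
#'   [train_unet()], [unet_forward()].
#' @export
build_unet <- function(base_channels = 16, dilations = c(1, 2, 3, 1),
                       in_channels = 1, seed = 1L) {
  if (length(dilations) != 4 || any(dilations < 1)) {
    abort("dilations must be four rates >= 1")
  }
  if (base_channels < 1) abort("invalid channel configuration")
  set.seed(seed)
  rng <- function(n) rnorm(n)
  cb <- base_channels
  ch <- c(cb, 2 * cb, 4 * cb, 8 * cb)
  conv <- function(cin, cout, d, k = 3) {
    list(W = he_init(k, cin, cout, rng), b = numeric(cout), d = as.integer(d))
  }
  layers <- list(
    e1c1 = conv(in_channels, ch[1], dilations[1]),
    e1c2 = conv(ch[1], ch[1], dilations[1]),
    e2c1 = conv(ch[1], ch[2], dilations[2]),
    e2c2 = conv(ch[2], ch[2], dilations[2]),
    e3c1 = conv(ch[2], ch[3], dilations[3]),
    e3c2 = conv(ch[3], ch[3], dilations[3]),
    bc1 = conv(ch[3], ch[4], dilations[4]),
    bc2 = conv(ch[4], ch[4], dilations[4]),
    d3c1 = conv(ch[4], ch[3], 1),
    d3c2 = conv(2 * ch[3], ch[3], 1),
    d2c1 = conv(ch[3], ch[2], 1),
    d2c2 = conv(2 * ch[2], ch[2], 1),
    d1c1 = conv(ch[2], ch[1], 1),
    d1c2 = conv(2 * ch[1], ch[1], 1),
    out = conv(ch[1], 1, 1, k = 1)
  )
  structure(
    list(layers = layers, dilations = as.integer(dilations),
         base_channels = as.integer(base_channels),
         in_channels = as.integer(in_channels)),
    class = "unet_model"
  )
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf(
    "<unet_model> dilations (%s), base %d channels, %d parameters\n",
    paste(x$dilations, collapse = ", "), x$base_channels, n_parameters(x)
  ))
  invisible(x)
}

#' Total trainable parameter count of a network
#' @param model a `unet_model`.
#' @return integer.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$layers, function(l) length(l$W) + length(l$b), 0))
}

as_batch <- function(x) {
  # accept (H, W), (H, W, N) -> (H, W, 1, N)
  d <- dim(x)
  if (length(d) == 2L) x <- array(x, c(d, 1L, 1L))
  else if (length(d) == 3L) x <- array(x, c(d[1], d[2], 1L, d[3]))
  x
}

conv_fwd <- function(x, layer) cpp_conv_fwd(x, layer$W, layer$b, layer$d)

relu <- function(x) { x[x < 0] <- 0; x }

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , , drop = FALSE]
}

downsample2_sum <- function(g) {
  # adjoint of nearest-neighbour upsample: sum over each 2x2 block
  d <- dim(g)
  g[seq(1, d[1], 2), seq(1, d[2], 2), , , drop = FALSE] +
    g[seq(2, d[1], 2), seq(1, d[2], 2), , , drop = FALSE] +
    g[seq(1, d[1], 2), seq(2, d[2], 2), , , drop = FALSE] +
    g[seq(2, d[1], 2), seq(2, d[2], 2), , , drop = FALSE]
}

cat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

#' Forward pass of the U-Net
#'
#' @param model a `unet_model`.
#' @param x input batch: matrix `(H, W)`, array `(H, W, N)` or
#'   `(H, W, C, N)`; `H` and `W` must be divisible by 8 (three poolings).
#' @param cache keep intermediate activations for backprop (internal).
#' @return probabilities in (0, 1) with shape `(H, W, 1, N)` (plus a cache
#'   attribute when requested).
#' @export
unet_forward <- function(model, x, cache = FALSE) {
  x <- as_batch(x)
  d <- dim(x)
  if (d[1] %% 8 != 0 || d[2] %% 8 != 0) {
    abort("input height and width must be divisible by 8")
  }
  L <- model$layers
  cc <- list(x = x)
  z <- list(); a <- list()
  fwd <- function(name, input) {
    zz <- conv_fwd(input, L[[name]])
    z[[name]] <<- zz
    relu(zz)
  }
  a1 <- fwd("e1c2", fwd("e1c1", x))
  p1 <- cpp_maxpool_fwd(a1)
  a2 <- fwd("e2c2", fwd("e2c1", p1$y))
  p2 <- cpp_maxpool_fwd(a2)
  a3 <- fwd("e3c2", fwd("e3c1", p2$y))
  p3 <- cpp_maxpool_fwd(a3)
  bb <- fwd("bc2", fwd("bc1", p3$y))
  u3 <- fwd("d3c1", upsample2(bb))
  m3 <- fwd("d3c2", cat_ch(u3, a3))
  u2 <- fwd("d2c1", upsample2(m3))
  m2 <- fwd("d2c2", cat_ch(u2, a2))
  u1 <- fwd("d1c1", upsample2(m2))
  m1 <- fwd("d1c2", cat_ch(u1, a1))
  logits <- conv_fwd(m1, L$out)
  probs <- 1 / (1 + exp(-logits))
  if (!cache) return(probs)
  list(
    probs = probs, z = z,
    a1 = a1, a2 = a2, a3 = a3, p1 = p1, p2 = p2, p3 = p3,
    bb = bb, u3 = u3, m3 = m3, u2 = u2, m2 = m2, u1 = u1, m1 = m1, x = x
  )
}

# gradient of combined loss w.r.t. logits, given probs and targets
combined_loss_grad_logits <- function(p, t, eps = 1) {
  n <- length(p)
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  g_bce <- (pc - t) / n
  sp <- sum(p); st <- sum(t); spt <- sum(p * t)
  den <- sp + st + eps
  # d(1 - dice)/dp, then chain through sigmoid p(1-p)
  ddice_dp <- -(2 * t * den - (2 * spt + eps)) / den^2
  g_bce + ddice_dp * p * (1 - p)
}

unet_backward <- function(model, cache, gl) {
  L <- model$layers
  grads <- list()
  bwd <- function(name, input, gout) {
    # gout is gradient at the ReLU output; mask by z > 0 (no ReLU for "out")
    if (name != "out") gout <- gout * (cache$z[[name]] > 0)
    r <- cpp_conv_bwd(input, L[[name]]$W, gout, L[[name]]$d)
    grads[[name]] <<- list(gW = r$gW, gb = r$gb)
    r$gx
  }
  g_m1 <- bwd("out", cache$m1, gl)
  g_cat1 <- bwd("d1c2", cat_ch(cache$u1, cache$a1), g_m1)
  nc1 <- dim(cache$u1)[3]
  g_u1 <- g_cat1[, , seq_len(nc1), , drop = FALSE]
  g_a1_skip <- g_cat1[, , nc1 + seq_len(nc1), , drop = FALSE]
  g_m2 <- downsample2_sum(bwd("d1c1", upsample2(cache$m2), g_u1))
  g_cat2 <- bwd("d2c2", cat_ch(cache$u2, cache$a2), g_m2)
  nc2 <- dim(cache$u2)[3]
  g_u2 <- g_cat2[, , seq_len(nc2), , drop = FALSE]
  g_a2_skip <- g_cat2[, , nc2 + seq_len(nc2), , drop = FALSE]
  g_m3 <- downsample2_sum(bwd("d2c1", upsample2(cache$m3), g_u2))
  g_cat3 <- bwd("d3c2", cat_ch(cache$u3, cache$a3), g_m3)
  nc3 <- dim(cache$u3)[3]
  g_u3 <- g_cat3[, , seq_len(nc3), , drop = FALSE]
  g_a3_skip <- g_cat3[, , nc3 + seq_len(nc3), , drop = FALSE]
  g_bb <- downsample2_sum(bwd("d3c1", upsample2(cache$bb), g_u3))
  g_p3 <- bwd("bc1", cache$p3$y, bwd("bc2", relu(cache$z$bc1), g_bb))
  g_a3 <- cpp_maxpool_bwd(g_p3, cache$p3$idx, dim(cache$a3)) + g_a3_skip
  g_p2 <- bwd("e3c1", cache$p2$y, bwd("e3c2", relu(cache$z$e3c1), g_a3))
  g_a2 <- cpp_maxpool_bwd(g_p2, cache$p2$idx, dim(cache$a2)) + g_a2_skip
  g_p1 <- bwd("e2c1", cache$p1$y, bwd("e2c2", relu(cache$z$e2c1), g_a2))
  g_a1 <- cpp_maxpool_bwd(g_p1, cache$p1$idx, dim(cache$a1)) + g_a1_skip
  bwd("e1c1", cache$x, bwd("e1c2", relu(cache$z$e1c1), g_a1))
  grads
}

#' Train the U-Net on patch pairs
#'
#' Adam on the combined Dice + BCE loss, mini-batches reshuffled each epoch
#' under the given seed; optionally evaluates a held-out set each epoch and
#' stops early once its Dice coefficient reaches `target_dice`.
#'
#' @param model a `unet_model` from [build_unet()].
#' @param x,y training patches and masks, arrays `(H, W, N)`.
#' @param epochs maximum epochs (default 30).
#' @param batch_size mini-batch size (default 8).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed shuffling seed.
#' @param val optional list with `x`, `y` held-out arrays.
#' @param target_dice early-stop threshold on held-out Dice (default 0.98).
#' @param verbose print a line per epoch.
#' @return the trained model with a `history` tibble (epoch, mean loss,
#'   holdout dice) attached.
#' @export
train_unet <- function(model, x, y, epochs = 30, batch_size = 8, lr = 1e-3,
                       seed = 1L, val = NULL, target_dice = 0.98,
                       verbose = FALSE) {
  x <- as_batch(x); y <- as_batch(y)
  n <- dim(x)[4]
  set.seed(seed)
  mstate <- purrr::map(model$layers, function(l) {
    list(mW = array(0, dim(l$W)), vW = array(0, dim(l$W)),
         mb = numeric(length(l$b)), vb = numeric(length(l$b)))
  })
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  history <- list()
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (s in seq(1, n, by = batch_size)) {
      idx <- ord[s:min(s + batch_size - 1L, n)]
      xb <- x[, , , idx, drop = FALSE]
      yb <- y[, , , idx, drop = FALSE]
      cache <- unet_forward(model, xb, cache = TRUE)
      losses <- c(losses, combined_loss(cache$probs, yb))
      gl <- array(combined_loss_grad_logits(cache$probs, yb), dim(cache$probs))
      grads <- unet_backward(model, cache, gl)
      step <- step + 1L
      for (nm in names(model$layers)) {
        g <- grads[[nm]]
        st <- mstate[[nm]]
        st$mW <- b1 * st$mW + (1 - b1) * g$gW
        st$vW <- b2 * st$vW + (1 - b2) * g$gW^2
        st$mb <- b1 * st$mb + (1 - b1) * g$gb
        st$vb <- b2 * st$vb + (1 - b2) * g$gb^2
        mhW <- st$mW / (1 - b1^step); vhW <- st$vW / (1 - b2^step)
        mhb <- st$mb / (1 - b1^step); vhb <- st$vb / (1 - b2^step)
        model$layers[[nm]]$W <- model$layers[[nm]]$W - lr * mhW / (sqrt(vhW) + eps)
        model$layers[[nm]]$b <- model$layers[[nm]]$b - lr * mhb / (sqrt(vhb) + eps)
        mstate[[nm]] <- st
      }
    }
    vd <- NA_real_
    if (!is.null(val)) {
      pv <- unet_forward(model, val$x)
      vd <- dice_coefficient((pv > 0.5) * 1, as_batch(val$y))
    }
    history[[ep]] <- tibble(epoch = ep, loss = mean(losses), val_dice = vd)
    if (isTRUE(verbose)) {
      cat(sprintf("epoch %d: loss %.4f, holdout dice %.4f\n", ep, mean(losses), vd))
    }
    if (!is.na(vd) && vd >= target_dice) break
  }
  model$history <- dplyr::bind_rows(history)
  model
}

#' Hard Dice coefficient between binary arrays
#' @param a,b binary arrays of equal shape.
#' @return Dice similarity in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  2 * sum(a * b) / (sum(a) + sum(b))
}

#' Segment a grayscale volume with a trained model
#'
#' Per slice: patch extraction on the grid, batched inference, overlap-average
#' stitching, then thresholding into a [mask_volume()] carrying the input
#' spacing metadata.
#'
#' @param model a trained `unet_model`.
#' @param volume 3D numeric array (slice, row, col), intensities on the scale
#'   the model was trained on (`[0, 1]`).
#' @param pixel_size,slice_spacing spacing metadata (mm); required.
#' @param patch_size,stride inference tiling (default 64 / 32 overlap).
#' @param threshold probability cut for the binary mask (default 0.5).
#' @return a [mask_volume()].
#' @export
predict_volume <- function(model, volume, pixel_size, slice_spacing,
                           patch_size = 64, stride = 32, threshold = 0.5) {
  if (missing(pixel_size) || missing(slice_spacing) ||
      is.null(pixel_size) || is.null(slice_spacing)) {
    abort("spacing metadata (pixel_size, slice_spacing) is required")
  }
  if (is.matrix(volume)) volume <- array(volume, c(1L, dim(volume)))
  d <- dim(volume)
  grid <- patch_grid(d[2:3], patch_size, stride)
  vox <- array(0L, d)
  for (k in seq_len(d[1])) {
    patches <- extract_patches(volume[k, , ], grid)
    probs <- unet_forward(model, patches)
    probs <- array(probs, dim(patches))
    stitched <- stitch_patches(probs, grid)
    vox[k, , ] <- (stitched > threshold) * 1L
  }
  mask_volume(vox, pixel_size, slice_spacing)
}

#' Save / load network checkpoints
#'
#' Plain RDS of the weight list plus architecture fields.
#' @param model a `unet_model`.
#' @param path checkpoint file (`.rds`).
#' @export
save_unet <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  structure(readRDS(path), class = "unet_model")
}
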