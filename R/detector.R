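# Optional keypoint detector: an encoder-decoder ("hourglass") network that
# maps a grayscale frame to the seven binary annotation channels. The rest
# of the pipeline runs without this module (decode_stack accepts any
# channel stack). The network is a fixed topology: 25 convolutions (all 3x3,
# zero padding, stride 1, ReLU except a sigmoid output), four 2x2 max
# poolings down to a 1/16-scale latent map, six stacked bottleneck
# convolutions, four 2x2 upsamplings each followed by a skip concatenation
# from the encoder. Filter counts follow a doubling schedule from
# `base_filters` (16 -> 256 at the bottleneck for the default).

#' Specification of the keypoint-detector network
#'
#' @param input_shape \code{c(H, W, 1)}; H and W must be divisible by 16
#'   (four 2x2 poolings). The 640 x 400 frame convention gives a 40 x 25
#'   latent map.
#' @param n_channels_out Number of output channels (default 7).
#' @param base_filters Filters of the first stage; doubled at each encoder
#'   stage (default 16).
#' @return An object of class \code{net_spec} with the layer sequence.
#' @export
net_spec <- function(input_shape = c(400, 640, 1), n_channels_out = 7,
                     base_filters = 16) {
  H <- input_shape[1]; W <- input_shape[2]
  if (H %% 16 != 0 || W %% 16 != 0) {
    stop_pigtrackr("input H and W must be divisible by 16 (got ", H, "x", W, ")")
  }
  f <- base_filters
  ops <- list()
  add <- function(...) ops[[length(ops) + 1]] <<- list(...)
  add(op = "conv", cin = input_shape[3], cout = f, act = "relu")   # stem
  cin <- f
  enc_f <- c(f, 2 * f, 4 * f, 8 * f)
  for (i in 1:4) {
    add(op = "conv", cin = cin, cout = enc_f[i], act = "relu")
    add(op = "conv", cin = enc_f[i], cout = enc_f[i], act = "relu")
    add(op = "save_skip", slot = i)
    add(op = "pool")
    cin <- enc_f[i]
  }
  for (j in 1:6) {                                                 # bottleneck
    add(op = "conv", cin = cin, cout = 16 * f, act = "relu")
    cin <- 16 * f
  }
  for (i in 4:1) {
    add(op = "upsample")
    add(op = "concat", slot = i)
    add(op = "conv", cin = cin + enc_f[i], cout = enc_f[i], act = "relu")
    add(op = "conv", cin = enc_f[i], cout = enc_f[i], act = "relu")
    cin <- enc_f[i]
  }
  add(op = "conv", cin = cin, cout = f, act = "relu")              # head
  add(op = "conv", cin = f, cout = n_channels_out, act = "sigmoid")
  structure(list(input_shape = input_shape, n_channels_out = n_channels_out,
                 base_filters = base_filters, ops = ops),
            class = "net_spec")
}

#' Build (initialise) the keypoint-detector network
#'
#' He-normal weight initialisation, seeded.
#'
#' @param spec A \code{\link{net_spec}}.
#' @param seed Integer seed for the initialisation.
#' @return An object of class \code{pig_detector} holding the specification
#'   and the parameter list.
#' @export
build_detector <- function(spec = net_spec(), seed = 1L) {
  stopifnot(inherits(spec, "net_spec"))
  params <- with_seed(seed, {
    lapply(spec$ops, function(o) {
      if (o$op != "conv") return(NULL)
      k <- 3
      sd <- sqrt(2 / (k * k * o$cin))
      list(W = matrix(rnorm(k * k * o$cin * o$cout, sd = sd),
                      k * k * o$cin, o$cout),
           b = numeric(o$cout))
    })
  })
  structure(list(spec = spec, params = params, adam = NULL, step = 0L),
            class = "pig_detector")
}

#' Audit the network architecture
#'
#' @param model A \code{pig_detector} (or a \code{net_spec}).
#' @return List: \code{n_conv}, \code{n_pool}, \code{n_upsample},
#'   \code{n_concat}, \code{latent_shape}, \code{latent_scale},
#'   \code{n_bottleneck_conv}, \code{out_channels}, \code{out_activation}.
#' @export
network_audit <- function(model) {
  spec <- if (inherits(model, "pig_detector")) model$spec else model
  ops <- vapply(spec$ops, `[[`, "", "op")
  n_pool <- sum(ops == "pool")
  convs <- which(ops == "conv")
  # bottleneck = consecutive convs between the last pool and first upsample
  lp <- max(which(ops == "pool")); fu <- min(which(ops == "upsample"))
  list(n_conv = length(convs),
       n_pool = n_pool,
       n_upsample = sum(ops == "upsample"),
       n_concat = sum(ops == "concat"),
       latent_shape = spec$input_shape[1:2] / 2^n_pool,
       latent_scale = 1 / 2^n_pool,
       n_bottleneck_conv = sum(ops[lp:fu] == "conv"),
       out_channels = spec$ops[[max(convs)]]$cout,
       out_activation = spec$ops[[max(convs)]]$act)
}

detector_forward <- function(model, x, keep_cache = FALSE) {
  skips <- list(); caches <- list(); sizes <- list()
  h <- x
  for (li in seq_along(model$spec$ops)) {
    o <- model$spec$ops[[li]]
    if (o$op == "conv") {
      fw <- nn_conv_fwd(h, model$params[[li]]$W, model$params[[li]]$b)
      pre <- fw$out
      h <- if (o$act == "relu") pmax(pre, 0) else nn_sigmoid(pre)
      if (keep_cache) caches[[li]] <- list(cols = fw$cols, act_in = pre,
                                           in_dim = dim(fw$out)[1:2])
    } else if (o$op == "save_skip") {
      skips[[o$slot]] <- h
    } else if (o$op == "pool") {
      sizes[[li]] <- dim(h)[1:2]
      pw <- nn_pool_fwd(h)
      h <- pw$out
      if (keep_cache) caches[[li]] <- pw$mask
    } else if (o$op == "upsample") {
      h <- nn_upsample_fwd(h)
    } else if (o$op == "concat") {
      sk <- skips[[o$slot]]
      if (keep_cache) caches[[li]] <- list(c1 = dim(h)[3], c2 = dim(sk)[3])
      hh <- array(0, c(dim(h)[1], dim(h)[2], dim(h)[3] + dim(sk)[3]))
      hh[, , seq_len(dim(h)[3])] <- h
      hh[, , dim(h)[3] + seq_len(dim(sk)[3])] <- sk
      h <- hh
    }
  }
  list(out = h, caches = caches, sizes = sizes)
}

detector_backward <- function(model, fwd, y) {
  ops <- model$spec$ops
  p <- fwd$out
  pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  # d(mean BCE)/d(logit) for the sigmoid output layer
  dh <- (pc - y) / length(y)
  grads <- vector("list", length(ops))
  dskips <- list()
  for (li in rev(seq_along(ops))) {
    o <- ops[[li]]
    if (o$op == "conv") {
      cache <- fwd$caches[[li]]
      if (o$act == "relu") dh <- dh * (cache$act_in > 0)
      d <- nn_conv_bwd(dh, cache$cols, model$params[[li]]$W,
                       dim(dh)[1], dim(dh)[2], o$cin)
      grads[[li]] <- list(dW = d$dW, db = d$db)
      dh <- d$dx
    } else if (o$op == "save_skip") {
      if (!is.null(dskips[[as.character(o$slot)]])) {
        dh <- dh + dskips[[as.character(o$slot)]]
      }
    } else if (o$op == "pool") {
      sz <- fwd$sizes[[li]]
      dh <- nn_pool_bwd(dh, fwd$caches[[li]], sz[1], sz[2])
    } else if (o$op == "upsample") {
      dh <- nn_upsample_bwd(dh)
    } else if (o$op == "concat") {
      cc <- fwd$caches[[li]]
      dskips[[as.character(o$slot)]] <- dh[, , cc$c1 + seq_len(cc$c2), drop = FALSE]
      dh <- dh[, , seq_len(cc$c1), drop = FALSE]
    }
  }
  grads
}

adam_step <- function(model, grads, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  if (is.null(model$adam)) {
    model$adam <- lapply(model$params, function(p) {
      if (is.null(p)) return(NULL)
      list(mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0)
    })
  }
  model$step <- model$step + 1L
  t <- model$step
  for (li in seq_along(model$params)) {
    if (is.null(model$params[[li]])) next
    g <- grads[[li]]; a <- model$adam[[li]]
    a$mW <- beta1 * a$mW + (1 - beta1) * g$dW
    a$vW <- beta2 * a$vW + (1 - beta2) * g$dW^2
    a$mb <- beta1 * a$mb + (1 - beta1) * g$db
    a$vb <- beta2 * a$vb + (1 - beta2) * g$db^2
    mhW <- a$mW / (1 - beta1^t); vhW <- a$vW / (1 - beta2^t)
    mhb <- a$mb / (1 - beta1^t); vhb <- a$vb / (1 - beta2^t)
    model$params[[li]]$W <- model$params[[li]]$W - lr * mhW / (sqrt(vhW) + eps)
    model$params[[li]]$b <- model$params[[li]]$b - lr * mhb / (sqrt(vhb) + eps)
    model$adam[[li]] <- a
  }
  model
}

#' Forward-pass a frame through the detector
#'
#' @param model A trained or untrained \code{pig_detector}.
#' @param image Grayscale matrix in \[0, 1\] with the spec's input dims.
#' @return A real-valued \code{channel_stack} (sigmoid outputs in (0, 1)),
#'   ready for \code{\link{decode_stack}}.
#' @export
predict_stack <- function(model, image) {
  x <- array(image, c(nrow(image), ncol(image), 1))
  out <- detector_forward(model, x)$out
  dimnames(out) <- list(NULL, NULL, CHANNEL_NAMES[seq_len(dim(out)[3])])
  structure(out, class = "channel_stack")
}

#' Toy-scale training loop for the detector
#'
#' Trains with Adam on mean binary cross-entropy, sample by sample, with a
#' seeded 90/10 train/validation split and per-epoch loss logging. Intended
#' for small crops and synthetic frames; a NaN loss aborts with diagnostics.
#'
#' @param model A \code{pig_detector}.
#' @param images List of grayscale matrices.
#' @param stacks List of matching \code{channel_stack}s (binary targets).
#' @param epochs Number of epochs (0 returns the model untouched with an
#'   empty history).
#' @param validation_split Fraction held out for validation (default 0.1).
#' @param lr Adam learning rate.
#' @param seed Seed for the split and shuffling.
#' @return List: \code{model} (trained), \code{history} (data frame epoch,
#'   train_loss, val_loss).
#' @export
train_toy <- function(model, images, stacks, epochs = 10,
                      validation_split = 0.1, lr = 1e-3, seed = 1L) {
  stopifnot(length(images) == length(stacks))
  n <- length(images)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  if (epochs == 0) return(list(model = model, history = history))
  if (n < 2) stop_pigtrackr("need at least 2 training pairs")
  xs <- lapply(images, function(im) array(im, c(nrow(im), ncol(im), 1)))
  ys <- lapply(stacks, unclass)
  with_seed(seed, {
    perm <- sample(n)
    n_val <- max(1, round(validation_split * n))
    val <- perm[seq_len(n_val)]
    trn <- setdiff(perm, val)
    for (ep in seq_len(epochs)) {
      ord <- sample(trn)
      tl <- 0
      for (i in ord) {
        fwd <- detector_forward(model, xs[[i]], keep_cache = TRUE)
        loss <- nn_bce(fwd$out, ys[[i]])
        if (!is.finite(loss)) {
          stop_pigtrackr("training diverged (loss = ", loss, ") at epoch ",
                         ep, ", sample ", i)
        }
        tl <- tl + loss
        grads <- detector_backward(model, fwd, ys[[i]])
        model <- adam_step(model, grads, lr)
      }
      vl <- mean(vapply(val, function(i)
        nn_bce(detector_forward(model, xs[[i]])$out, ys[[i]]), 1))
      history <- rbind(history, data.frame(epoch = ep,
                                           train_loss = tl / length(ord),
                                           val_loss = vl))
    }
  })
  list(model = model, history = history)
}

#' @export
print.pig_detector <- function(x, ...) {
  a <- network_audit(x)
  cat("Keypoint detector:", a$n_conv, "conv layers,", a$n_pool, "poolings,",
      a$n_upsample, "upsamplings,", a$n_concat, "skip concatenations\n")
  cat("  input", paste(x$spec$input_shape, collapse = "x"),
      "-> latent", paste(a$latent_shape, collapse = "x"),
      "-> output", a$out_channels, "channels (", a$out_activation, ")\n")
  invisible(x)
}

# nearest-neighbour resampling under an inverse coordinate map
transform_nn <- function(mat, inv) {
  H <- nrow(mat); W <- ncol(mat)
  gx <- rep(0:(W - 1), each = H)
  gy <- rep(0:(H - 1), times = W)
  src <- inv(gx, gy)
  xi <- round(src$x); yi <- round(src$y)
  ok <- xi >= 0 & xi < W & yi >= 0 & yi < H
  out <- matrix(0, H, W)
  out[cbind(gy[ok] + 1, gx[ok] + 1)] <- mat[cbind(yi[ok] + 1, xi[ok] + 1)]
  out
}

#' Jointly augment a frame and its annotation stack
#'
#' Applies each requested geometric operation to the image and all seven
#' annotation channels identically (nearest-neighbour resampling, zero
#' fill), returning the original pair plus one transformed pair per
#' operation: \code{1 + length(ops)} pairs in total. Shift sign and
#' rotation sign are drawn from the seed; magnitudes are configurable.
#'
#' @param image Grayscale matrix.
#' @param stack Matching \code{channel_stack}.
#' @param ops Subset of \code{c("vshift", "hshift", "shrink", "rotate")}.
#' @param seed Seed for the random signs.
#' @param shift_frac Shift magnitude as a fraction of the dimension
#'   (default 0.1).
#' @param shrink_factor Shrink scale (default 0.9).
#' @param rotate_deg Rotation magnitude in degrees (default 15).
#' @return List of \code{list(image, stack, op)} pairs, original first.
#' @export
augment_pair <- function(image, stack,
                         ops = c("vshift", "hshift", "shrink", "rotate"),
                         seed = 1L, shift_frac = 0.1, shrink_factor = 0.9,
                         rotate_deg = 15) {
  if (length(ops)) ops <- match.arg(ops, several.ok = TRUE)
  stopifnot(all(dim(image) == dim(unclass(stack))[1:2]))
  H <- nrow(image); W <- ncol(image)
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  signs <- with_seed(seed, sample(c(-1, 1), length(ops), replace = TRUE))
  out <- list(list(image = image, stack = stack, op = "original"))
  for (k in seq_along(ops)) {
    op <- ops[k]; s <- signs[k]
    inv <- switch(op,
      vshift = { dy <- s * round(shift_frac * H)
                 function(x, y) list(x = x, y = y - dy) },
      hshift = { dx <- s * round(shift_frac * W)
                 function(x, y) list(x = x - dx, y = y) },
      shrink = function(x, y) list(x = cx + (x - cx) / shrink_factor,
                                   y = cy + (y - cy) / shrink_factor),
      rotate = { a <- s * rotate_deg * pi / 180
                 function(x, y) list(x = cx + cos(a) * (x - cx) - sin(a) * (y - cy),
                                     y = cy + sin(a) * (x - cx) + cos(a) * (y - cy)) })
    img_t <- transform_nn(image, inv)
    st <- unclass(stack)
    st_t <- array(0, dim(st), dimnames = dimnames(st))
    for (ch in seq_len(dim(st)[3])) st_t[, , ch] <- transform_nn(st[, , ch], inv)
    out[[length(out) + 1]] <- list(image = img_t,
                                   stack = structure(st_t, class = "channel_stack"),
                                   op = op)
  }
  out
}

#' Preprocess a raw frame to the working format
#'
#' Converts RGB to grayscale (Rec. 601 luma), rescales intensities to
#' \[0, 1\], and bilinearly resizes to the working resolution (default
#' 640 x 400).
#'
#' @param frame Matrix (grayscale) or H x W x 3 array (RGB); values in
#'   \[0, 1\] or \[0, 255\].
#' @param width,height Target dimensions.
#' @param frame_index Used in error messages only.
#' @return Grayscale matrix \code{height x width} in \[0, 1\].
#' @export
preprocess_frame <- function(frame, width = 640, height = 400,
                             frame_index = NA) {
  if (!is.numeric(frame) || length(dim(frame) %||% 1) < 2) {
    stop_pigtrackr("unreadable frame", if (!is.na(frame_index))
      paste0(" at index ", frame_index) else "")
  }
  if (length(dim(frame)) == 3) {
    if (dim(frame)[3] >= 3) {
      frame <- 0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
    } else {
      frame <- frame[, , 1]
    }
  }
  if (max(frame, na.rm = TRUE) > 1) frame <- frame / 255
  if (nrow(frame) == height && ncol(frame) == width) return(frame)
  img <- EBImage::Image(t(frame))            # EBImage: first dim = x
  res <- EBImage::resize(img, w = width, h = height)
  t(EBImage::imageData(res))
}
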