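# Training recipe: binary cross-entropy on logits, Adam with weight decay,
# per-iteration poly learning-rate schedule, random rotation augmentation.

#' Training configuration
#'
#' Defaults are the published recipe: Adam, learning rate 6e-4, batch size 2,
#' weight decay 1e-4, poly schedule with power 0.9, rotation augmentation in
#' [-10, 10] degrees applied only during training.
#'
#' @param epochs number of epochs (50 for 304px-scale data, 300 for
#'   512px-scale in the original recipe; choose per dataset).
#' @param lr base learning rate.
#' @param weight_decay L2 coefficient added to the gradients.
#' @param batch_size images per optimization step.
#' @param poly_power exponent of the poly decay.
#' @param rotation_deg augmentation angle range `c(lo, hi)` in degrees.
#' @param augment enable rotation augmentation.
#' @param seed root seed for shuffling, augmentation and initialisation.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 50L, lr = 6e-4, weight_decay = 1e-4,
                         batch_size = 2L, poly_power = 0.9,
                         rotation_deg = c(-10, 10), augment = TRUE,
                         seed = 1L) {
  stopifnot(lr > 0, epochs >= 1, batch_size >= 1)
  structure(list(epochs = as.integer(epochs), lr = lr,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 poly_power = poly_power, rotation_deg = rotation_deg,
                 augment = augment, seed = as.integer(seed)),
            class = "train_config")
}

#' Mean binary cross-entropy from logits
#'
#' Computed in the numerically stable form
#' `max(z, 0) - z y + log(1 + exp(-|z|))`, averaged over all pixels.
#'
#' @param logits real array of logits.
#' @param target_mask binary array of the same shape.
#' @return scalar loss.
#' @export
bce_loss <- function(logits, target_mask) {
  if (anyNA(logits) || any(!is.finite(logits))) {
    stop("bce_loss: non-finite logits")
  }
  z <- as.vector(logits); y <- as.vector(target_mask)
  if (length(z) != length(y)) stop("bce_loss: shape mismatch")
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

#' Poly learning-rate schedule
#'
#' `base_lr * (1 - step / max_steps)^power`; steps beyond `max_steps` clamp
#' to zero.
#'
#' @param base_lr base learning rate.
#' @param step current iteration (0-based).
#' @param max_steps total iterations.
#' @param power poly exponent.
#' @return learning rate for this step.
#' @export
poly_lr <- function(base_lr, step, max_steps, power = 0.9) {
  frac <- 1 - step / max_steps
  if (frac <= 0) return(0)
  base_lr * frac^power
}

rotate_grid <- function(m, angle_deg, binary = FALSE) {
  if (angle_deg == 0) return(m)
  H <- nrow(m); W <- ncol(m)
  th <- angle_deg * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  rr <- matrix(seq_len(H), H, W) - cy
  cc <- matrix(rep(seq_len(W), each = H), H, W) - cx
  # inverse map: output pixel samples the source at rotation by -angle
  sr <- cos(th) * rr - sin(th) * cc + cy
  sc <- sin(th) * rr + cos(th) * cc + cx
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  getpix <- function(r, c) {
    inside <- r >= 1 & r <= H & c >= 1 & c <= W
    v <- numeric(length(r))
    v[inside] <- m[cbind(r[inside], c[inside])]
    v
  }
  v <- (1 - fr) * (1 - fc) * getpix(r0, c0) +
    (1 - fr) * fc * getpix(r0, c0 + 1) +
    fr * (1 - fc) * getpix(r0 + 1, c0) +
    fr * fc * getpix(r0 + 1, c0 + 1)
  out <- matrix(v, H, W)
  if (binary) out <- (out >= 0.5) + 0L
  out
}

#' Rotate a sample for augmentation
#'
#' Draws one angle uniformly from `range_deg` (or uses `angle` if given) and
#' applies it to the image and every mask in the sample; masks are
#' re-binarized at 0.5 after interpolation. An angle of zero is pixel-exact.
#'
#' @param sample list with `image` and any of `pixel_mask`,
#'   `centerline_mask`.
#' @param range_deg angle range in degrees.
#' @param angle fixed angle (bypasses the draw).
#' @return the rotated sample with an `angle` field recording the draw.
#' @export
augment_rotation <- function(sample, range_deg = c(-10, 10), angle = NULL) {
  if (is.null(angle)) angle <- stats::runif(1L, range_deg[1L], range_deg[2L])
  out <- sample
  out$image <- rotate_grid(sample$image, angle)
  for (f in c("pixel_mask", "centerline_mask")) {
    if (!is.null(sample[[f]])) {
      out[[f]] <- rotate_grid(sample[[f]], angle, binary = TRUE)
    }
  }
  out$angle <- angle
  out
}

# --- Adam ------------------------------------------------------------------

adam_step <- function(params, grads, state, lr, wd, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  rec <- function(p, g, path) {
    if (is.list(p)) {
      for (nm in names(p)) p[[nm]] <- rec(p[[nm]], g[[nm]], paste(path, nm))
      return(p)
    }
    grad <- g + wd * p
    s <- state[[path]]
    if (is.null(s)) s <- list(m = 0 * p, v = 0 * p)
    m <- beta1 * s$m + (1 - beta1) * grad
    v <- beta2 * s$v + (1 - beta2) * grad * grad
    state[[path]] <- list(m = m, v = v)
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    p - lr * mhat / (sqrt(vhat) + eps)
  }
  rec(params, grads, "p")
}

stack_batch <- function(samples) {
  H <- nrow(samples[[1L]]$image); W <- ncol(samples[[1L]]$image)
  N <- length(samples)
  x <- array(0, c(H, W, 1L, N))
  y <- array(0, c(H, W, 1L, N))
  for (n in seq_len(N)) {
    x[, , 1L, n] <- samples[[n]]$image
    y[, , 1L, n] <- samples[[n]]$pixel_mask
  }
  list(x = x, y = y)
}

#' Train a model
#'
#' Adam with the configured hyperparameters, poly schedule stepped per
#' iteration, BCE loss on logits, optional rotation augmentation. Training is
#' fully determined by `cfg$seed`. Aborts with a diagnostic if the loss goes
#' non-finite.
#'
#' @param model an `octafuse_model`.
#' @param dataset list of samples, each `list(image, pixel_mask)`.
#' @param cfg a [train_config()].
#' @param stop_dice optional early-stop target: training halts once the
#'   training-set Dice (evaluated every `check_every` epochs) reaches it.
#' @param check_every epoch interval for Dice evaluation when `stop_dice` is
#'   set (also recorded in the history).
#' @param verbose print per-epoch losses.
#' @return list `model` (trained), `history` (data frame of epoch, loss,
#'   lr, and Dice where evaluated).
#' @export
train_model <- function(model, dataset, cfg, stop_dice = NULL,
                        check_every = 10L, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  if (length(dataset) == 0L) stop("train_model: empty dataset")
  set.seed(cfg$seed)
  n <- length(dataset)
  steps_per_epoch <- ceiling(n / cfg$batch_size)
  max_steps <- cfg$epochs * steps_per_epoch
  state <- new.env()
  step <- 0L
  hist <- list()
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (b in seq_len(steps_per_epoch)) {
      idx <- ord[((b - 1L) * cfg$batch_size + 1L):min(b * cfg$batch_size, n)]
      batch <- dataset[idx]
      if (cfg$augment) {
        batch <- lapply(batch, augment_rotation, range_deg = cfg$rotation_deg)
      }
      sb <- stack_batch(batch)
      lr <- poly_lr(cfg$lr, step, max_steps, cfg$poly_power)
      fw <- net_forward(model, sb$x, training = TRUE)
      loss <- bce_loss(fw$logits, sb$y)
      if (!is.finite(loss)) {
        stop("train_model: non-finite loss at epoch ", epoch,
             " step ", step, " (lr ", lr, "); training aborted")
      }
      dlogits <- (sigmoid(fw$logits) - sb$y) / length(sb$y)
      grads <- net_backward(model, fw, dlogits)
      step <- step + 1L
      model$params <- adam_step(model$params, grads, state, lr,
                                cfg$weight_decay, step)
      losses <- c(losses, loss)
    }
    drow <- list(epoch = epoch, loss = mean(losses),
                 lr = poly_lr(cfg$lr, step - 1L, max_steps, cfg$poly_power),
                 dice = NA_real_)
    if (!is.null(stop_dice) && (epoch %% check_every == 0L ||
                                epoch == cfg$epochs)) {
      preds <- lapply(dataset, function(s) predict_vessels(model, s$image))
      gts <- lapply(dataset, function(s) s$pixel_mask)
      mr <- evaluate_dataset(preds, gts)
      drow$dice <- mr$dice[nrow(mr)]
    }
    hist[[epoch]] <- drow
    if (verbose) {
      message(sprintf("epoch %d loss %.4f dice %s", epoch, drow$loss,
                      format(drow$dice)))
    }
    if (!is.null(stop_dice) && !is.na(drow$dice) && drow$dice >= stop_dice) {
      break
    }
  }
  history <- do.call(rbind, lapply(hist, as.data.frame))
  list(model = model, history = history)
}

reflect_pad_to8 <- function(img) {
  H <- nrow(img); W <- ncol(img)
  Hp <- ceiling(H / 8) * 8; Wp <- ceiling(W / 8) * 8
  if (Hp == H && Wp == W) return(list(img = img, H = H, W = W))
  ridx <- c(seq_len(H), seq.int(H - 1L, by = -1L,
                                length.out = Hp - H))
  cidx <- c(seq_len(W), seq.int(W - 1L, by = -1L,
                                length.out = Wp - W))
  list(img = img[ridx, cidx], H = H, W = W)
}

#' Predict a vessel probability map
#'
#' Runs the network in evaluation mode and applies a sigmoid. Images whose
#' size is not divisible by 8 are reflect-padded and the output cropped back.
#'
#' @param model an `octafuse_model` (trained or not).
#' @param image 2-D grayscale image in `[0, 1]`.
#' @return probability matrix in `[0, 1]` at the input resolution.
#' @export
predict_vessels <- function(model, image) {
  image <- as.matrix(image)
  pp <- reflect_pad_to8(image)
  fw <- net_forward(model, pp$img, training = FALSE)
  probs <- sigmoid(fw$logits[, , 1L, 1L])
  matrix(probs[seq_len(pp$H), seq_len(pp$W)], pp$H, pp$W)
}

#' Save a model checkpoint
#'
#' Single-file checkpoint embedding the configuration, weights and
#' batch-norm running statistics.
#'
#' @param model an `octafuse_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = model$config, params = model$params,
               buffers = as.list(model$buffers)), path)
  invisible(path)
}

#' Restore a model from a checkpoint
#'
#' @param path file written by [save_checkpoint()].
#' @return an `octafuse_model`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  bf <- new.env()
  for (nm in names(ck$buffers)) bf[[nm]] <- ck$buffers[[nm]]
  structure(list(config = ck$config, params = ck$params, buffers = bf),
            class = "octafuse_model")
}
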