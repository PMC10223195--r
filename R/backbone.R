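# U-shaped encoder/decoder backbone and assembly of the four network
# variants: base (plain U-Net wiring), base+ECT, base+ECCA, full.
#
# The network has four resolution levels; the deepest encoder output acts as
# the start of the decoding path, so all four encoder scales provide skip
# connections. Downsampling is 2x2 max-pooling, upsampling is bilinear x2
# followed by a 3x3 convolution. Convolutions feeding a batch-norm layer
# carry no bias term (it would be exactly cancelled by the normalization).

#' Attention configuration for the cross-fusion transformer
#'
#' @param num_heads number of attention heads (default 4).
#' @param reduction_factor factor by which each spatial axis of the input
#'   image is shrunk to form the shared token grid; the token count is
#'   `k = (H / r) * (W / r)`. One of 4, 8 or 16 in the ablation grid.
#' @param reduction_mode `"bilinear"` (interpolation) or `"maxpool"`.
#' @param target_hw optional fixed token-grid size `c(h, w)` overriding the
#'   factor-derived grid (used to hold `k` constant across image sizes).
#' @return an `attention_config` list.
#' @export
attention_config <- function(num_heads = 4L, reduction_factor = 16L,
                             reduction_mode = c("bilinear", "maxpool"),
                             target_hw = NULL) {
  reduction_mode <- match.arg(reduction_mode)
  stopifnot(num_heads >= 1L, reduction_factor >= 1L)
  structure(list(num_heads = as.integer(num_heads),
                 reduction_factor = as.integer(reduction_factor),
                 reduction_mode = reduction_mode,
                 target_hw = target_hw),
            class = "attention_config")
}

#' Model configuration
#'
#' @param variant one of `"base"` (plain U-Net wiring), `"ect"` (transformer
#'   skip fusion), `"ecca"` (channel-gated skips), `"full"` (both modules).
#' @param in_channels input image channels (1 for grayscale angiograms).
#' @param num_classes output channels (1: vessel probability).
#' @param base_width channel count of the first encoder level.
#' @param channel_widths the four encoder widths C1..C4; defaults to
#'   `base_width * c(1, 2, 4, 8)`. Must be strictly increasing and divisible
#'   by `num_heads`.
#' @param attention an [attention_config()].
#' @return a `model_config` list.
#' @export
model_config <- function(variant = c("full", "base", "ect", "ecca"),
                         in_channels = 1L, num_classes = 1L, base_width = 32L,
                         channel_widths = NULL,
                         attention = attention_config()) {
  variant <- match.arg(variant)
  if (is.null(channel_widths)) channel_widths <- base_width * c(1L, 2L, 4L, 8L)
  channel_widths <- as.integer(channel_widths)
  if (length(channel_widths) != 4L) stop("channel_widths must have length 4")
  if (any(diff(channel_widths) <= 0L)) {
    stop("channel_widths must be strictly increasing")
  }
  if (any(channel_widths %% attention$num_heads != 0L)) {
    stop("channel widths must be divisible by the number of attention heads")
  }
  structure(list(variant = variant,
                 in_channels = as.integer(in_channels),
                 num_classes = as.integer(num_classes),
                 base_width = as.integer(base_width),
                 channel_widths = channel_widths,
                 attention = attention),
            class = "model_config")
}

#' Reference configuration of the full network
#'
#' Channel widths are calibrated — approximately 1.64x the 32/64/128/256
#' default ladder, rounded to head-divisible integers with the third level
#' nudged one head-width — so that the full variant totals 14.1 M trainable
#' parameters for single-channel input.
#'
#' @param variant network variant, defaulting to the full model.
#' @return a `model_config`.
#' @export
reference_config <- function(variant = "full") {
  model_config(variant = variant, in_channels = 1L, num_classes = 1L,
               base_width = 52L, channel_widths = c(52L, 104L, 212L, 416L),
               attention = attention_config(num_heads = 4L,
                                            reduction_factor = 16L))
}

use_ect <- function(cfg) cfg$variant %in% c("ect", "full")
use_ecca <- function(cfg) cfg$variant %in% c("ecca", "full")

init_block <- function(cin, cout) {
  list(conv1 = list(W = init_conv3x3(cin, cout)),
       bn1 = list(gamma = rep(1, cout), beta = numeric(cout)),
       conv2 = list(W = init_conv3x3(cout, cout)),
       bn2 = list(gamma = rep(1, cout), beta = numeric(cout)))
}

init_ect_scale <- function(ci) {
  list(ln = list(gamma = rep(1, ci), beta = numeric(ci)),
       q = list(W = init_conv1x1(ci, ci), b = numeric(ci)),
       k = list(W = init_conv1x1(ci, ci), b = numeric(ci)),
       v = list(W = init_conv1x1(ci, ci), b = numeric(ci)),
       merge = list(W = init_linear(ci, ci), b = numeric(ci)),
       recon = list(W = init_conv1x1(ci, ci), b = numeric(ci)),
       rbn = list(gamma = rep(1, ci), beta = numeric(ci)),
       rconv = list(W = init_conv3x3(ci, ci), b = numeric(ci)))
}

init_ecca_scale <- function(ci) {
  list(L1 = init_linear(ci, ci), L2 = init_linear(ci, ci))
}

#' Build a network from a configuration
#'
#' @param config a [model_config()].
#' @param seed integer seed for weight initialisation.
#' @return an `octafuse_model`: config, nested parameter list, and an
#'   environment of batch-norm running statistics.
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  set.seed(seed)
  cw <- config$channel_widths
  params <- list()
  params$enc <- list(
    l1 = init_block(config$in_channels, cw[1L]),
    l2 = init_block(cw[1L], cw[2L]),
    l3 = init_block(cw[2L], cw[3L]),
    l4 = init_block(cw[3L], cw[4L]))
  if (use_ect(config)) {
    params$ect <- list(s1 = init_ect_scale(cw[1L]), s2 = init_ect_scale(cw[2L]),
                       s3 = init_ect_scale(cw[3L]), s4 = init_ect_scale(cw[4L]))
  }
  if (use_ecca(config)) {
    params$ecca <- list(s1 = init_ecca_scale(cw[1L]), s2 = init_ecca_scale(cw[2L]),
                        s3 = init_ecca_scale(cw[3L]), s4 = init_ecca_scale(cw[4L]))
  }
  params$dec <- list(
    fuse4 = init_block(2L * cw[4L], cw[4L]),
    up3 = list(conv = list(W = init_conv3x3(cw[4L], cw[3L])),
               bn = list(gamma = rep(1, cw[3L]), beta = numeric(cw[3L]))),
    fuse3 = init_block(2L * cw[3L], cw[3L]),
    up2 = list(conv = list(W = init_conv3x3(cw[3L], cw[2L])),
               bn = list(gamma = rep(1, cw[2L]), beta = numeric(cw[2L]))),
    fuse2 = init_block(2L * cw[2L], cw[2L]),
    up1 = list(conv = list(W = init_conv3x3(cw[2L], cw[1L])),
               bn = list(gamma = rep(1, cw[1L]), beta = numeric(cw[1L]))),
    fuse1 = init_block(2L * cw[1L], cw[1L]),
    head = list(W = init_conv1x1(cw[1L], config$num_classes),
                b = numeric(config$num_classes)))
  structure(list(config = config, params = params, buffers = new.env()),
            class = "octafuse_model")
}

#' Count trainable parameters
#'
#' Sums the lengths of every weight array in the model (batch-norm running
#' statistics are buffers, not parameters, and are excluded).
#'
#' @param model an `octafuse_model`, or a bare nested parameter list.
#' @return integer count of trainable scalars.
#' @export
count_parameters <- function(model) {
  p <- if (inherits(model, "octafuse_model")) model$params else model
  if (length(p) == 0L) return(0L)
  sum(rapply(p, length, how = "unlist"))
}

# --- double conv block -----------------------------------------------------

block_fwd <- function(x, p, buffers, key, training) {
  c1 <- conv3x3_fwd(x, p$conv1$W)
  b1 <- bn_fwd(c1$out, p$bn1$gamma, p$bn1$beta, buffers, paste0(key, ".bn1"),
               training)
  r1 <- relu_fwd(b1$out)
  c2 <- conv3x3_fwd(r1$out, p$conv2$W)
  b2 <- bn_fwd(c2$out, p$bn2$gamma, p$bn2$beta, buffers, paste0(key, ".bn2"),
               training)
  r2 <- relu_fwd(b2$out)
  list(out = r2$out, cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                                  c2 = c2$cache, b2 = b2$cache, r2 = r2$cache))
}

block_bwd <- function(dy, cache, p) {
  dy <- relu_bwd(dy, cache$r2)
  b2 <- bn_bwd(dy, cache$b2, p$bn2$gamma)
  c2 <- conv3x3_bwd(b2$dx, cache$c2, p$conv2$W)
  dmid <- relu_bwd(c2$dx, cache$r1)
  b1 <- bn_bwd(dmid, cache$b1, p$bn1$gamma)
  c1 <- conv3x3_bwd(b1$dx, cache$c1, p$conv1$W)
  list(dx = c1$dx,
       grads = list(conv1 = list(W = c1$dW),
                    bn1 = list(gamma = b1$dgamma, beta = b1$dbeta),
                    conv2 = list(W = c2$dW),
                    bn2 = list(gamma = b2$dgamma, beta = b2$dbeta)))
}

up_fwd <- function(x, p, buffers, key, training) {
  d <- dim(x)
  rs <- bilinear_resize_fwd(x, 2L * d[1L], 2L * d[2L])
  cv <- conv3x3_fwd(rs$out, p$conv$W)
  bn <- bn_fwd(cv$out, p$bn$gamma, p$bn$beta, buffers, paste0(key, ".bn"),
               training)
  rl <- relu_fwd(bn$out)
  list(out = rl$out,
       cache = list(rs = rs$cache, cv = cv$cache, bn = bn$cache, rl = rl$cache))
}

up_bwd <- function(dy, cache, p) {
  dy <- relu_bwd(dy, cache$rl)
  bn <- bn_bwd(dy, cache$bn, p$bn$gamma)
  cv <- conv3x3_bwd(bn$dx, cache$cv, p$conv$W)
  dx <- bilinear_resize_bwd(cv$dx, cache$rs)
  list(dx = dx,
       grads = list(conv = list(W = cv$dW),
                    bn = list(gamma = bn$dgamma, beta = bn$dbeta)))
}

concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  if (any(da[c(1L, 2L, 4L)] != db[c(1L, 2L, 4L)])) {
    stop("concat: spatial/batch mismatch between decoder feature and skip")
  }
  out <- array(0, c(da[1L], da[2L], da[3L] + db[3L], da[4L]))
  out[, , seq_len(da[3L]), ] <- a
  out[, , da[3L] + seq_len(db[3L]), ] <- b
  out
}

split_c <- function(d, c_first) {
  list(a = d[, , seq_len(c_first), , drop = FALSE],
       b = d[, , -seq_len(c_first), , drop = FALSE])
}

# --- encoder ---------------------------------------------------------------

encode_fwd <- function(model, x, training) {
  p <- model$params$enc
  bf <- model$buffers
  l1 <- block_fwd(x, p$l1, bf, "enc.l1", training)
  m1 <- maxpool2_fwd(l1$out)
  l2 <- block_fwd(m1$out, p$l2, bf, "enc.l2", training)
  m2 <- maxpool2_fwd(l2$out)
  l3 <- block_fwd(m2$out, p$l3, bf, "enc.l3", training)
  m3 <- maxpool2_fwd(l3$out)
  l4 <- block_fwd(m3$out, p$l4, bf, "enc.l4", training)
  list(ms = list(x1 = l1$out, x2 = l2$out, x3 = l3$out, x4 = l4$out),
       cache = list(l1 = l1$cache, m1 = m1$cache, l2 = l2$cache, m2 = m2$cache,
                    l3 = l3$cache, m3 = m3$cache, l4 = l4$cache))
}

encode_bwd <- function(dms, cache, p) {
  g4 <- block_bwd(dms$x4, cache$l4, p$l4)
  da3 <- dms$x3 + maxpool2_bwd(g4$dx, cache$m3)
  g3 <- block_bwd(da3, cache$l3, p$l3)
  da2 <- dms$x2 + maxpool2_bwd(g3$dx, cache$m2)
  g2 <- block_bwd(da2, cache$l2, p$l2)
  da1 <- dms$x1 + maxpool2_bwd(g2$dx, cache$m1)
  g1 <- block_bwd(da1, cache$l1, p$l1)
  list(dx = g1$dx,
       grads = list(l1 = g1$grads, l2 = g2$grads, l3 = g3$grads, l4 = g4$grads))
}

#' Encode an image into the four-scale feature pyramid
#'
#' @param model an `octafuse_model`.
#' @param image array coercible by [as_feature_map()]; spatial size must be
#'   divisible by 8.
#' @return list `x1..x4` of feature maps at full, 1/2, 1/4 and 1/8 resolution.
#' @export
encode <- function(model, image) {
  x <- as_feature_map(image)
  d <- dim(x)
  if (d[1L] %% 8L != 0L || d[2L] %% 8L != 0L) {
    stop("encode: spatial size must be divisible by 8 (three halvings); ",
         "use predict_vessels() for automatic reflect-padding")
  }
  encode_fwd(model, x, training = FALSE)$ms
}

# --- decoder ---------------------------------------------------------------

# skips: list s1..s4 (raw encoder features or ECT outputs, by variant);
# decoder features D4..D1 are x4 and the three up-convolution outputs.
decode_fwd <- function(model, ms, skips, training) {
  p <- model$params$dec
  pe <- model$params$ecca
  bf <- model$buffers
  gated <- use_ecca(model$config)
  cw <- model$config$channel_widths
  cache <- list(gated = gated)

  fuse_stage <- function(dfeat, skip, pscale, fuse_p, fuse_key) {
    if (gated) {
      g <- ecca_fwd(skip, dfeat, pscale)
      skip_in <- g$out
    } else {
      g <- NULL
      skip_in <- skip
    }
    f <- block_fwd(concat_c(dfeat, skip_in), fuse_p, bf, fuse_key, training)
    list(out = f$out, gate = g, fuse = f$cache)
  }

  s4 <- fuse_stage(ms$x4, skips[[4L]], pe$s4, p$fuse4, "dec.fuse4")
  u3 <- up_fwd(s4$out, p$up3, bf, "dec.up3", training)
  s3 <- fuse_stage(u3$out, skips[[3L]], pe$s3, p$fuse3, "dec.fuse3")
  u2 <- up_fwd(s3$out, p$up2, bf, "dec.up2", training)
  s2 <- fuse_stage(u2$out, skips[[2L]], pe$s2, p$fuse2, "dec.fuse2")
  u1 <- up_fwd(s2$out, p$up1, bf, "dec.up1", training)
  s1 <- fuse_stage(u1$out, skips[[1L]], pe$s1, p$fuse1, "dec.fuse1")
  hd <- conv1x1_fwd(s1$out, p$head$W, p$head$b)

  cache$s4 <- s4; cache$u3 <- u3$cache; cache$s3 <- s3; cache$u2 <- u2$cache
  cache$s2 <- s2; cache$u1 <- u1$cache; cache$s1 <- s1; cache$hd <- hd$cache
  cache$cw <- cw
  list(logits = hd$out, cache = cache)
}

decode_bwd <- function(dlogits, cache, model) {
  p <- model$params$dec
  pe <- model$params$ecca
  gated <- cache$gated
  cw <- cache$cw
  grads <- list()
  dskips <- vector("list", 4L)
  decca <- if (gated) list() else NULL

  hd <- conv1x1_bwd(dlogits, cache$hd, p$head$W)
  grads$head <- list(W = hd$dW, b = hd$db)

  stage_bwd <- function(dy, st, ci, fuse_p, pscale) {
    f <- block_bwd(dy, st$fuse, fuse_p)
    sp <- split_c(f$dx, ci)
    dd <- sp$a
    if (gated) {
      gb <- ecca_bwd(sp$b, st$gate$cache, pscale)
      dskip <- gb$de
      dd <- dd + gb$dd
      list(dd = dd, dskip = dskip, fuse_g = f$grads, ecca_g = gb$grads)
    } else {
      list(dd = dd, dskip = sp$b, fuse_g = f$grads, ecca_g = NULL)
    }
  }

  b1 <- stage_bwd(hd$dx, cache$s1, cw[1L], p$fuse1, pe$s1)
  grads$fuse1 <- b1$fuse_g; dskips[[1L]] <- b1$dskip
  if (gated) decca$s1 <- b1$ecca_g
  q1 <- up_bwd(b1$dd, cache$u1, p$up1)
  grads$up1 <- q1$grads

  b2 <- stage_bwd(q1$dx, cache$s2, cw[2L], p$fuse2, pe$s2)
  grads$fuse2 <- b2$fuse_g; dskips[[2L]] <- b2$dskip
  if (gated) decca$s2 <- b2$ecca_g
  q2 <- up_bwd(b2$dd, cache$u2, p$up2)
  grads$up2 <- q2$grads

  b3 <- stage_bwd(q2$dx, cache$s3, cw[3L], p$fuse3, pe$s3)
  grads$fuse3 <- b3$fuse_g; dskips[[3L]] <- b3$dskip
  if (gated) decca$s3 <- b3$ecca_g
  q3 <- up_bwd(b3$dd, cache$u3, p$up3)
  grads$up3 <- q3$grads

  b4 <- stage_bwd(q3$dx, cache$s4, cw[4L], p$fuse4, pe$s4)
  grads$fuse4 <- b4$fuse_g; dskips[[4L]] <- b4$dskip
  if (gated) decca$s4 <- b4$ecca_g

  list(dskips = dskips, dd4 = b4$dd, dec_grads = grads, ecca_grads = decca)
}

#' Decode a feature pyramid into segmentation logits
#'
#' Runs the variant's skip path (raw, transformer-fused, and/or channel-gated)
#' and the upsampling decoder in evaluation mode.
#'
#' @param model an `octafuse_model`.
#' @param ms a list `x1..x4` as returned by [encode()].
#' @return logits feature map with `num_classes` channels at full resolution.
#' @export
decode <- function(model, ms) {
  skips <- if (use_ect(model$config)) {
    ect_fwd(ms, model$params$ect, model$config$attention, model$buffers,
            training = FALSE)$e
  } else {
    list(ms$x1, ms$x2, ms$x3, ms$x4)
  }
  decode_fwd(model, ms, skips, training = FALSE)$logits
}

# --- full network ----------------------------------------------------------

net_forward <- function(model, x, training = FALSE) {
  x <- as_feature_map(x)
  d <- dim(x)
  if (d[1L] %% 8L != 0L || d[2L] %% 8L != 0L) {
    stop("net_forward: spatial size must be divisible by 8")
  }
  enc <- encode_fwd(model, x, training)
  if (use_ect(model$config)) {
    ec <- ect_fwd(enc$ms, model$params$ect, model$config$attention,
                  model$buffers, training)
    skips <- ec$e
    ect_cache <- ec$cache
  } else {
    skips <- list(enc$ms$x1, enc$ms$x2, enc$ms$x3, enc$ms$x4)
    ect_cache <- NULL
  }
  dec <- decode_fwd(model, enc$ms, skips, training)
  list(logits = dec$logits,
       cache = list(enc = enc, ect = ect_cache, dec = dec$cache))
}

net_backward <- function(model, fw, dlogits) {
  cache <- fw$cache
  db <- decode_bwd(dlogits, cache$dec, model)
  grads <- list()
  if (use_ect(model$config)) {
    eb <- ect_bwd(db$dskips, cache$ect, model$params$ect)
    dms <- eb$dms
    grads$ect <- eb$grads
  } else {
    dms <- list(x1 = db$dskips[[1L]], x2 = db$dskips[[2L]],
                x3 = db$dskips[[3L]], x4 = db$dskips[[4L]])
  }
  dms$x4 <- dms$x4 + db$dd4
  enc <- encode_bwd(dms, cache$enc$cache, model$params$enc)
  grads$enc <- enc$grads
  grads$dec <- db$dec_grads
  if (use_ecca(model$config)) grads$ecca <- db$ecca_grads
  grads[names(model$params)]
}
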