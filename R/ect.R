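# Efficient cross-fusion transformer (ECT) replacing the skip connections.
#
# Pipeline per forward pass: layer-normalize each encoder scale, project to
# Q/K/V with 1x1 convolutions, shrink every projection to a shared h x w
# token grid (k = h*w tokens), concatenate the four K and V along the
# embedding axis, run multi-head cross-attention per scale (the score matrix
# lives on the channel axes, d_i x d_sigma per head, so cost is independent
# of image size once k is fixed), merge heads linearly, restore tokens to the
# scale's resolution (bilinear upsample + 1x1 convolution), and refine with a
# residual conv block: E_i = s + Conv(ReLU(BN(s))), s = X_i + A_hat_i.

softmax_rows <- function(s) {
  m <- apply(s, 1L, max)
  e <- exp(s - m)
  e / rowSums(e)
}

# tokens: flatten an (h, w, C, N) map to (k, C, N), k = h*w, row-major in the
# sense that token index runs down rows first (column-major array order).
map_to_tokens <- function(x) {
  d <- dim(x)
  array(x, c(d[1L] * d[2L], d[3L], d[4L]))
}

tokens_to_map <- function(tk, h, w) {
  d <- dim(tk)
  array(tk, c(h, w, d[2L], d[3L]))
}

# --- grouped max-pool reduction (non-divisible sizes allowed) --------------

groupmax_fwd <- function(x, h, w) {
  d <- dim(x)
  rgrp <- ceiling(seq_len(d[1L]) * h / d[1L])
  cgrp <- ceiling(seq_len(d[2L]) * w / d[2L])
  y <- array(0, c(h, w, d[3L], d[4L]))
  am <- vector("list", h * w)
  for (gi in seq_len(h)) {
    rows <- which(rgrp == gi)
    for (gj in seq_len(w)) {
      cols <- which(cgrp == gj)
      sub <- x[rows, cols, , , drop = FALSE]
      y[gi, gj, , ] <- apply(sub, c(3L, 4L), max)
      am[[(gj - 1L) * h + gi]] <-
        list(rows = rows, cols = cols, idx = apply(sub, c(3L, 4L), which.max))
    }
  }
  list(out = y, cache = list(am = am, dims = d, h = h, w = w))
}

groupmax_bwd <- function(dy, cache) {
  d <- cache$dims
  dx <- array(0, d)
  for (gi in seq_len(cache$h)) {
    for (gj in seq_len(cache$w)) {
      cell <- cache$am[[(gj - 1L) * cache$h + gi]]
      nr <- length(cell$rows)
      for (n in seq_len(d[4L])) {
        for (c in seq_len(d[3L])) {
          idx <- cell$idx[c, n]
          ri <- (idx - 1L) %% nr + 1L
          ci <- (idx - 1L) %/% nr + 1L
          dx[cell$rows[ri], cell$cols[ci], c, n] <-
            dx[cell$rows[ri], cell$cols[ci], c, n] + dy[gi, gj, c, n]
        }
      }
    }
  }
  dx
}

resize_tokens_fwd <- function(x, h, w, mode) {
  if (mode == "maxpool") groupmax_fwd(x, h, w) else bilinear_resize_fwd(x, h, w)
}

resize_tokens_bwd <- function(dy, cache, mode) {
  if (mode == "maxpool") groupmax_bwd(dy, cache) else bilinear_resize_bwd(dy, cache)
}

# --- exported elementary operations ----------------------------------------

#' Per-token layer normalization of an encoder scale
#'
#' Normalizes each spatial position's channel vector to zero mean and unit
#' variance, then applies the affine terms.
#'
#' @param x feature map (any shape accepted by [as_feature_map()]).
#' @param gamma,beta optional per-channel affine parameters (default 1 and 0).
#' @return normalized feature map of the same shape.
#' @export
normalize_scale <- function(x, gamma = NULL, beta = NULL) {
  x <- as_feature_map(x)
  C <- dim(x)[3L]
  if (is.null(gamma)) gamma <- rep(1, C)
  if (is.null(beta)) beta <- numeric(C)
  ln_fwd(x, gamma, beta)$out
}

#' Project a normalized scale into query, key and value maps
#'
#' Three independent 1x1 convolutions, preserving spatial size.
#'
#' @param x normalized feature map.
#' @param wq,wk,wv `Cin x Cout` projection matrices.
#' @param bq,bk,bv optional bias vectors.
#' @return list with elements `q`, `k`, `v`.
#' @export
project_qkv <- function(x, wq, wk, wv, bq = NULL, bk = NULL, bv = NULL) {
  x <- as_feature_map(x)
  list(q = conv1x1_fwd(x, wq, bq)$out,
       k = conv1x1_fwd(x, wk, bk)$out,
       v = conv1x1_fwd(x, wv, bv)$out)
}

#' Reduce a feature map to a token matrix
#'
#' Shrinks the spatial grid to `target_hw` (bilinear interpolation or grouped
#' max-pooling) and flattens it to `k = h * w` tokens.
#'
#' @param map feature map; batch size must be 1 for the matrix form.
#' @param reduction_mode `"bilinear"` or `"maxpool"`.
#' @param target_hw integer vector `c(h, w)`; must not exceed the source size.
#' @return a `k x C` token matrix.
#' @export
reduce_tokens <- function(map, reduction_mode = c("bilinear", "maxpool"),
                          target_hw) {
  reduction_mode <- match.arg(reduction_mode)
  map <- as_feature_map(map)
  d <- dim(map)
  h <- as.integer(target_hw[1L]); w <- as.integer(target_hw[2L])
  if (h > d[1L] || w > d[2L]) {
    stop("reduce_tokens: target grid exceeds the source size")
  }
  if (d[4L] != 1L) stop("reduce_tokens: expects a single sample")
  tk <- map_to_tokens(resize_tokens_fwd(map, h, w, reduction_mode)$out)
  matrix(tk, h * w, d[3L])
}

#' Efficient multi-head cross-attention over token matrices
#'
#' Per head, scores are `t(Q) %*% K / sqrt(d_sigma)` (a `d_q x d_kv` matrix on
#' the embedding axes), soft-maxed over the key axis, and applied to the
#' values: `out = t(A %*% t(V))`. Head outputs are concatenated; the linear
#' head merge of the full module is applied separately.
#'
#' @param q `k x d_q` query token matrix.
#' @param k_cat,v_cat `k x d_kv` concatenated key/value token matrices.
#' @param num_heads number of heads; must divide both `d_q` and `d_kv`.
#' @return `k x d_q` token matrix.
#' @export
efficient_cross_attention <- function(q, k_cat, v_cat, num_heads = 1L) {
  stopifnot(is.matrix(q), is.matrix(k_cat), is.matrix(v_cat))
  if (nrow(q) != nrow(k_cat) || nrow(q) != nrow(v_cat)) {
    stop("efficient_cross_attention: token counts of Q, K, V must agree")
  }
  if (!identical(dim(k_cat), dim(v_cat))) {
    stop("efficient_cross_attention: K and V must share shape")
  }
  dq <- ncol(q); dkv <- ncol(k_cat)
  if (dq %% num_heads != 0L || dkv %% num_heads != 0L) {
    stop("efficient_cross_attention: head count must divide embedding widths")
  }
  hq <- dq %/% num_heads; hkv <- dkv %/% num_heads
  out <- matrix(0, nrow(q), dq)
  for (hh in seq_len(num_heads)) {
    qc <- (hh - 1L) * hq + seq_len(hq)
    kc <- (hh - 1L) * hkv + seq_len(hkv)
    S <- crossprod(q[, qc, drop = FALSE], k_cat[, kc, drop = FALSE]) / sqrt(hkv)
    A <- softmax_rows(S)
    out[, qc] <- t(tcrossprod(A, v_cat[, kc, drop = FALSE]))
  }
  out
}

#' Residual refinement of one scale (token restoration + conv block)
#'
#' Restores the attention tokens to the scale's resolution (reshape to the
#' token grid, bilinear upsample, 1x1 projection), then applies the residual
#' refinement `E = s + Conv(ReLU(BN(s)))` with `s = x + A_hat`.
#'
#' @param x the scale's feature map (single sample).
#' @param eca `k x d` attention token matrix for this scale.
#' @param token_hw the token grid `c(h, w)`.
#' @param weights list with `recon = list(W, b)`, `rbn = list(gamma, beta)`,
#'   `rconv = list(W, b)`.
#' @return feature map with the shape of `x`.
#' @export
ect_layer <- function(x, eca, token_hw, weights) {
  x <- as_feature_map(x)
  d <- dim(x)
  tk <- array(eca, c(nrow(eca), ncol(eca), 1L))
  up <- bilinear_resize_fwd(tokens_to_map(tk, token_hw[1L], token_hw[2L]),
                            d[1L], d[2L])$out
  a_hat <- conv1x1_fwd(up, weights$recon$W, weights$recon$b)$out
  if (!identical(dim(a_hat), d)) stop("ect_layer: restored shape mismatch")
  s <- x + a_hat
  bf <- new.env()
  bn <- bn_fwd(s, weights$rbn$gamma, weights$rbn$beta, bf, "bn", training = TRUE)
  rl <- relu_fwd(bn$out)
  cv <- conv3x3_fwd(rl$out, weights$rconv$W, weights$rconv$b)
  s + cv$out
}

# --- full module forward/backward ------------------------------------------

head_columns <- function(cw, num_heads) {
  offs <- c(0L, cumsum(cw))
  lapply(seq_len(num_heads), function(hh) {
    unlist(lapply(seq_along(cw), function(j) {
      dh <- cw[j] %/% num_heads
      offs[j] + (hh - 1L) * dh + seq_len(dh)
    }))
  })
}

token_grid <- function(cfg, H, W) {
  if (!is.null(cfg$target_hw)) {
    as.integer(cfg$target_hw)
  } else {
    c(max(1L, H %/% cfg$reduction_factor), max(1L, W %/% cfg$reduction_factor))
  }
}

ect_fwd <- function(ms, p, cfg, buffers, training) {
  xs <- list(ms$x1, ms$x2, ms$x3, ms$x4)
  cw <- vapply(xs, function(x) dim(x)[3L], 1L)
  N <- dim(xs[[1L]])[4L]
  nh <- cfg$num_heads
  hw <- token_grid(cfg, dim(xs[[1L]])[1L], dim(xs[[1L]])[2L])
  h <- hw[1L]; w <- hw[2L]; k <- h * w
  hc <- head_columns(cw, nh)
  dsig <- length(hc[[1L]])

  sc <- vector("list", 4L)   # per-scale caches
  qtok <- vector("list", 4L)
  ktok <- vector("list", 4L)
  vtok <- vector("list", 4L)
  for (i in 1:4) {
    pi <- p[[i]]
    ln <- ln_fwd(xs[[i]], pi$ln$gamma, pi$ln$beta)
    qp <- conv1x1_fwd(ln$out, pi$q$W, pi$q$b)
    kp <- conv1x1_fwd(ln$out, pi$k$W, pi$k$b)
    vp <- conv1x1_fwd(ln$out, pi$v$W, pi$v$b)
    # deep scales can be smaller than the shared grid for small reduction
    # factors; the resize then interpolates up so k stays shared
    qr <- resize_tokens_fwd(qp$out, h, w, cfg$reduction_mode)
    kr <- resize_tokens_fwd(kp$out, h, w, cfg$reduction_mode)
    vr <- resize_tokens_fwd(vp$out, h, w, cfg$reduction_mode)
    qtok[[i]] <- map_to_tokens(qr$out)
    ktok[[i]] <- map_to_tokens(kr$out)
    vtok[[i]] <- map_to_tokens(vr$out)
    sc[[i]] <- list(ln = ln$cache, qp = qp$cache, kp = kp$cache, vp = vp$cache,
                    qr = qr$cache, kr = kr$cache, vr = vr$cache)
  }
  kcat <- array(0, c(k, sum(cw), N))
  vcat <- array(0, c(k, sum(cw), N))
  offs <- c(0L, cumsum(cw))
  for (j in 1:4) {
    kcat[, offs[j] + seq_len(cw[j]), ] <- ktok[[j]]
    vcat[, offs[j] + seq_len(cw[j]), ] <- vtok[[j]]
  }

  es <- vector("list", 4L)
  for (i in 1:4) {
    pi <- p[[i]]
    dhi <- cw[i] %/% nh
    attn <- vector("list", N)
    otok <- array(0, c(k, cw[i], N))
    for (n in seq_len(N)) {
      heads <- vector("list", nh)
      for (hh in seq_len(nh)) {
        qc <- (hh - 1L) * dhi + seq_len(dhi)
        Q <- matrix(qtok[[i]][, qc, n], k, dhi)
        K <- matrix(kcat[, hc[[hh]], n], k, dsig)
        V <- matrix(vcat[, hc[[hh]], n], k, dsig)
        S <- crossprod(Q, K) / sqrt(dsig)
        A <- softmax_rows(S)
        otok[, qc, n] <- t(tcrossprod(A, V))
        heads[[hh]] <- list(Q = Q, K = K, V = V, A = A)
      }
      attn[[n]] <- heads
    }
    # head merge: one linear map on the concatenated head outputs
    mtok <- array(0, c(k, cw[i], N))
    for (n in seq_len(N)) {
      mtok[, , n] <- otok[, , n] %*% pi$merge$W +
        matrix(pi$merge$b, k, cw[i], byrow = TRUE)
    }
    di <- dim(xs[[i]])
    up <- bilinear_resize_fwd(tokens_to_map(mtok, h, w), di[1L], di[2L])
    rc <- conv1x1_fwd(up$out, pi$recon$W, pi$recon$b)
    s <- xs[[i]] + rc$out
    bn <- bn_fwd(s, pi$rbn$gamma, pi$rbn$beta, buffers,
                 paste0("ect.s", i, ".rbn"), training)
    rl <- relu_fwd(bn$out)
    cv <- conv3x3_fwd(rl$out, pi$rconv$W, pi$rconv$b)
    es[[i]] <- s + cv$out
    sc[[i]]$attn <- attn
    sc[[i]]$otok <- otok
    sc[[i]]$up <- up$cache
    sc[[i]]$rc <- rc$cache
    sc[[i]]$bn <- bn$cache
    sc[[i]]$rl <- rl$cache
    sc[[i]]$cv <- cv$cache
  }
  info <- list(k = k, token_hw = c(h, w), num_heads = nh, d_sigma = dsig,
               score_dims = lapply(1:4, function(i) c(cw[i] %/% nh, dsig)))
  list(e = es,
       cache = list(sc = sc, cw = cw, hc = hc, dsig = dsig, hw = c(h, w),
                    N = N, nh = nh, mode = cfg$reduction_mode, info = info))
}

ect_bwd <- function(des, cache, p) {
  sc <- cache$sc
  cw <- cache$cw
  hc <- cache$hc
  dsig <- cache$dsig
  h <- cache$hw[1L]; w <- cache$hw[2L]
  k <- h * w
  N <- cache$N
  nh <- cache$nh
  offs <- c(0L, cumsum(cw))
  dkcat <- array(0, c(k, sum(cw), N))
  dvcat <- array(0, c(k, sum(cw), N))
  dqtok <- lapply(1:4, function(i) array(0, c(k, cw[i], N)))
  dx <- vector("list", 4L)
  grads <- vector("list", 4L)
  names(grads) <- paste0("s", 1:4)

  for (i in 1:4) {
    pi <- p[[i]]
    ci <- sc[[i]]
    dE <- des[[i]]
    # E = s + Conv(ReLU(BN(s)))
    cv <- conv3x3_bwd(dE, ci$cv, pi$rconv$W)
    drl <- relu_bwd(cv$dx, ci$rl)
    bn <- bn_bwd(drl, ci$bn, pi$rbn$gamma)
    ds <- dE + bn$dx
    # s = x + recon(upsample(tokens))
    rc <- conv1x1_bwd(ds, ci$rc, pi$recon$W)
    dup <- bilinear_resize_bwd(rc$dx, ci$up)
    dmtok <- map_to_tokens(dup)
    dhi <- cw[i] %/% nh
    dWm <- matrix(0, cw[i], cw[i])
    dbm <- numeric(cw[i])
    dotok <- array(0, c(k, cw[i], N))
    for (n in seq_len(N)) {
      dm <- matrix(dmtok[, , n], k, cw[i])
      ot <- matrix(ci$otok[, , n], k, cw[i])
      dWm <- dWm + crossprod(ot, dm)
      dbm <- dbm + colSums(dm)
      dotok[, , n] <- tcrossprod(dm, pi$merge$W)
    }
    for (n in seq_len(N)) {
      for (hh in seq_len(nh)) {
        hd <- ci$attn[[n]][[hh]]
        qc <- (hh - 1L) * dhi + seq_len(dhi)
        dO <- matrix(dotok[, qc, n], k, dhi)
        dB <- t(dO)                            # B = A %*% t(V), O = t(B)
        dA <- dB %*% hd$V
        dvcat[, hc[[hh]], n] <- dvcat[, hc[[hh]], n] + crossprod(dB, hd$A)
        dS <- hd$A * (dA - rowSums(dA * hd$A))
        dS <- dS / sqrt(dsig)
        dqtok[[i]][, qc, n] <- dqtok[[i]][, qc, n] + hd$K %*% t(dS)
        dkcat[, hc[[hh]], n] <- dkcat[, hc[[hh]], n] + hd$Q %*% dS
      }
    }
    grads[[i]] <- list(merge = list(W = dWm, b = dbm),
                       recon = list(W = rc$dW, b = rc$db),
                       rbn = list(gamma = bn$dgamma, beta = bn$dbeta),
                       rconv = list(W = cv$dW, b = cv$db))
    dx[[i]] <- ds
  }

  for (j in 1:4) {
    pj <- p[[j]]
    cj <- sc[[j]]
    dq_map <- resize_tokens_bwd(tokens_to_map(dqtok[[j]], h, w), cj$qr,
                                cache$mode)
    dk_map <- resize_tokens_bwd(
      tokens_to_map(dkcat[, offs[j] + seq_len(cw[j]), , drop = FALSE], h, w),
      cj$kr, cache$mode)
    dv_map <- resize_tokens_bwd(
      tokens_to_map(dvcat[, offs[j] + seq_len(cw[j]), , drop = FALSE], h, w),
      cj$vr, cache$mode)
    qp <- conv1x1_bwd(dq_map, cj$qp, pj$q$W)
    kp <- conv1x1_bwd(dk_map, cj$kp, pj$k$W)
    vp <- conv1x1_bwd(dv_map, cj$vp, pj$v$W)
    dln_out <- qp$dx + kp$dx + vp$dx
    ln <- ln_bwd(dln_out, cj$ln, pj$ln$gamma)
    dx[[j]] <- dx[[j]] + ln$dx
    grads[[j]]$ln <- list(gamma = ln$dgamma, beta = ln$dbeta)
    grads[[j]]$q <- list(W = qp$dW, b = qp$db)
    grads[[j]]$k <- list(W = kp$dW, b = kp$db)
    grads[[j]]$v <- list(W = vp$dW, b = vp$db)
    # keep gradient list ordered like the parameter list
    grads[[j]] <- grads[[j]][names(p[[j]])]
  }
  list(dms = list(x1 = dx[[1L]], x2 = dx[[2L]], x3 = dx[[3L]], x4 = dx[[4L]]),
       grads = grads)
}

#' Transformer-fused skip outputs for an image
#'
#' Runs the encoder and the cross-fusion transformer in evaluation mode and
#' returns the four fused skip features, with attention bookkeeping (token
#' count, per-scale score-matrix dimensions) attached as the
#' `"attention_info"` attribute.
#'
#' @param model an `octafuse_model` whose variant includes the transformer.
#' @param image input image.
#' @return list `e1..e4` of fused feature maps.
#' @export
ect_outputs <- function(model, image) {
  if (!use_ect(model$config)) {
    stop("ect_outputs: model variant has no cross-fusion transformer")
  }
  ms <- encode(model, image)
  fw <- ect_fwd(ms, model$params$ect, model$config$attention, model$buffers,
                training = FALSE)
  structure(fw$e, attention_info = fw$cache$info)
}
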