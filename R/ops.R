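# Low-level differentiable tensor operations.
#
# Feature maps are dense double arrays with dim c(H, W, C, N): rows, columns,
# channels, batch. Every op returns list(out, cache); the matching *_bwd takes
# the upstream gradient plus the cache and returns gradients with respect to
# its inputs and parameters. All convolutions are stride-1 with "same" padding.

#' Coerce an array to the canonical 4-D feature-map layout
#'
#' 2-D input is treated as a single-channel, single-sample map; 3-D input as a
#' single-sample multi-channel map.
#'
#' @param x numeric array of 2, 3 or 4 dimensions.
#' @return double array with dim c(H, W, C, N).
#' @export
as_feature_map <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("input must be a matrix or array, not a bare vector")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("feature maps must have 2, 3 or 4 axes")
  storage.mode(x) <- "double"
  x
}

# (H,W,C,N) -> (H*W*N, C) matrix of per-position channel vectors
to_cmat <- function(x) {
  d <- dim(x)
  m <- aperm(x, c(1L, 2L, 4L, 3L))
  dim(m) <- c(d[1L] * d[2L] * d[4L], d[3L])
  m
}

# inverse of to_cmat
from_cmat <- function(m, H, W, C, N) {
  dim(m) <- c(H, W, N, C)
  aperm(m, c(1L, 2L, 4L, 3L))
}

# --- im2col 3x3 convolution ------------------------------------------------

im2col3 <- function(x) {
  d <- dim(x)
  H <- d[1L]; W <- d[2L]; C <- d[3L]; N <- d[4L]
  xp <- array(0, c(H + 2L, W + 2L, C, N))
  xp[2:(H + 1L), 2:(W + 1L), , ] <- x
  M <- matrix(0, H * W * N, 9L * C)
  for (c in seq_len(C)) {
    for (k in 1:9) {
      di <- (k - 1L) %% 3L
      dj <- (k - 1L) %/% 3L
      M[, (c - 1L) * 9L + k] <- as.vector(xp[di + seq_len(H), dj + seq_len(W), c, ])
    }
  }
  M
}

col2im3 <- function(dM, H, W, C, N) {
  dxp <- array(0, c(H + 2L, W + 2L, C, N))
  for (c in seq_len(C)) {
    for (k in 1:9) {
      di <- (k - 1L) %% 3L
      dj <- (k - 1L) %/% 3L
      idx_i <- di + seq_len(H); idx_j <- dj + seq_len(W)
      dxp[idx_i, idx_j, c, ] <- dxp[idx_i, idx_j, c, ] +
        array(dM[, (c - 1L) * 9L + k], c(H, W, N))
    }
  }
  dxp[2:(H + 1L), 2:(W + 1L), , , drop = FALSE]
}

# W: (9*Cin) x Cout matrix, rows ordered (offset within channel) fastest;
# b: length-Cout vector or NULL.
conv3x3_fwd <- function(x, W, b = NULL) {
  d <- dim(x)
  if (length(d) != 4L) stop("conv3x3: input must be a 4-axis feature map")
  if (d[1L] < 3L || d[2L] < 3L) stop("conv3x3: spatial size must be at least 3x3")
  M <- im2col3(x)
  y <- M %*% W
  if (!is.null(b)) y <- sweep(y, 2L, b, "+")
  out <- from_cmat(y, d[1L], d[2L], ncol(W), d[4L])
  list(out = out, cache = list(M = M, dims = d, has_b = !is.null(b)))
}

conv3x3_bwd <- function(dy, cache, W) {
  d <- cache$dims
  dyM <- to_cmat(dy)
  dW <- crossprod(cache$M, dyM)
  db <- if (cache$has_b) colSums(dyM) else NULL
  dM <- tcrossprod(dyM, W)
  dx <- col2im3(dM, d[1L], d[2L], d[3L], d[4L])
  list(dx = dx, dW = dW, db = db)
}

# 1x1 convolution: W is Cin x Cout
conv1x1_fwd <- function(x, W, b = NULL) {
  d <- dim(x)
  m <- to_cmat(x)
  y <- m %*% W
  if (!is.null(b)) y <- sweep(y, 2L, b, "+")
  list(out = from_cmat(y, d[1L], d[2L], ncol(W), d[4L]),
       cache = list(m = m, dims = d, has_b = !is.null(b)))
}

conv1x1_bwd <- function(dy, cache, W) {
  d <- cache$dims
  dyM <- to_cmat(dy)
  list(dx = from_cmat(tcrossprod(dyM, W), d[1L], d[2L], d[3L], d[4L]),
       dW = crossprod(cache$m, dyM),
       db = if (cache$has_b) colSums(dyM) else NULL)
}

# --- activations -----------------------------------------------------------

relu_fwd <- function(x) {
  mask <- x > 0
  x[!mask] <- 0
  list(out = x, cache = mask)
}

relu_bwd <- function(dy, mask) {
  dy[!mask] <- 0
  dy
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# --- 2x2 max pooling -------------------------------------------------------

maxpool2_fwd <- function(x) {
  d <- dim(x)
  H <- d[1L]; W <- d[2L]
  if (H %% 2L != 0L || W %% 2L != 0L) stop("maxpool2: spatial size must be even")
  io <- seq(1L, H, by = 2L); jo <- seq(1L, W, by = 2L)
  a1 <- x[io, jo, , , drop = FALSE]
  a2 <- x[io + 1L, jo, , , drop = FALSE]
  a3 <- x[io, jo + 1L, , , drop = FALSE]
  a4 <- x[io + 1L, jo + 1L, , , drop = FALSE]
  y <- pmax(a1, a2, a3, a4)
  # first-match argmax so tied maxima route gradient to a single source pixel
  arg <- array(4L, dim(y))
  arg[a3 == y] <- 3L
  arg[a2 == y] <- 2L
  arg[a1 == y] <- 1L
  list(out = y, cache = list(arg = arg, dims = d))
}

maxpool2_bwd <- function(dy, cache) {
  d <- cache$dims
  dx <- array(0, d)
  io <- seq(1L, d[1L], by = 2L); jo <- seq(1L, d[2L], by = 2L)
  arg <- cache$arg
  g <- dy; g[arg != 1L] <- 0; dx[io, jo, , ] <- g
  g <- dy; g[arg != 2L] <- 0; dx[io + 1L, jo, , ] <- g
  g <- dy; g[arg != 3L] <- 0; dx[io, jo + 1L, , ] <- g
  g <- dy; g[arg != 4L] <- 0; dx[io + 1L, jo + 1L, , ] <- g
  dx
}

# --- bilinear resize -------------------------------------------------------

# Interpolation weight matrix mapping n_in samples to n_out (half-pixel
# centers, edges clamped). Rows sum to 1 so constants are preserved.
interp_matrix <- function(n_out, n_in) {
  if (n_out == n_in) return(diag(n_in))
  Wm <- matrix(0, n_out, n_in)
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    s <- (i - 0.5) * scale + 0.5
    lo <- floor(s)
    fr <- s - lo
    if (lo < 1L) { lo <- 1L; fr <- 0 }
    hi <- min(lo + 1L, n_in)
    if (lo > n_in) { lo <- n_in; hi <- n_in; fr <- 0 }
    Wm[i, lo] <- Wm[i, lo] + (1 - fr)
    Wm[i, hi] <- Wm[i, hi] + fr
  }
  Wm
}

apply_rowcol <- function(x, Rm, Cm) {
  d <- dim(x)
  H <- d[1L]; W <- d[2L]; C <- d[3L]; N <- d[4L]
  ho <- nrow(Rm); wo <- nrow(Cm)
  tmp <- Rm %*% matrix(x, H, W * C * N)           # (ho, W*C*N)
  tmp <- array(tmp, c(ho, W, C, N))
  tmp <- aperm(tmp, c(2L, 1L, 3L, 4L))            # (W, ho, C, N)
  tmp <- Cm %*% matrix(tmp, W, ho * C * N)        # (wo, ho*C*N)
  tmp <- array(tmp, c(wo, ho, C, N))
  aperm(tmp, c(2L, 1L, 3L, 4L))
}

bilinear_resize_fwd <- function(x, h_out, w_out) {
  d <- dim(x)
  Rm <- interp_matrix(h_out, d[1L])
  Cm <- interp_matrix(w_out, d[2L])
  list(out = apply_rowcol(x, Rm, Cm), cache = list(Rm = Rm, Cm = Cm))
}

bilinear_resize_bwd <- function(dy, cache) {
  apply_rowcol(dy, t(cache$Rm), t(cache$Cm))
}

# --- batch normalization ---------------------------------------------------

# gamma/beta: length-C vectors. Running statistics live in `buffers`, an
# environment keyed by `key` holding list(mean, var); training mode updates
# them with exponential `momentum`. Population variance over (H, W, N).
bn_fwd <- function(x, gamma, beta, buffers, key, training, momentum = 0.1,
                   eps = 1e-5) {
  d <- dim(x)
  m <- to_cmat(x)
  if (is.null(buffers[[key]])) {
    buffers[[key]] <- list(mean = numeric(d[3L]), var = rep(1, d[3L]))
  }
  if (training) {
    mu <- colMeans(m)
    ctr <- sweep(m, 2L, mu, "-")
    va <- colMeans(ctr * ctr)
    b <- buffers[[key]]
    buffers[[key]] <- list(mean = (1 - momentum) * b$mean + momentum * mu,
                           var = (1 - momentum) * b$var + momentum * va)
  } else {
    mu <- buffers[[key]]$mean
    va <- buffers[[key]]$var
    ctr <- sweep(m, 2L, mu, "-")
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- sweep(ctr, 2L, invstd, "*")
  y <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(out = from_cmat(y, d[1L], d[2L], d[3L], d[4L]),
       cache = list(xhat = xhat, invstd = invstd, dims = d, training = training))
}

bn_bwd <- function(dy, cache, gamma) {
  d <- cache$dims
  dyM <- to_cmat(dy)
  dgamma <- colSums(dyM * cache$xhat)
  dbeta <- colSums(dyM)
  dxhat <- sweep(dyM, 2L, gamma, "*")
  if (cache$training) {
    n <- nrow(dyM)
    t1 <- sweep(dxhat, 2L, colMeans(dxhat), "-")
    t2 <- sweep(cache$xhat, 2L, colMeans(dxhat * cache$xhat), "*")
    dxM <- sweep(t1 - t2, 2L, cache$invstd, "*")
  } else {
    dxM <- sweep(dxhat, 2L, cache$invstd, "*")
  }
  list(dx = from_cmat(dxM, d[1L], d[2L], d[3L], d[4L]),
       dgamma = dgamma, dbeta = dbeta)
}

# --- layer normalization (per spatial position, over channels) -------------

ln_fwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  m <- to_cmat(x)
  mu <- rowMeans(m)
  ctr <- m - mu
  va <- rowMeans(ctr * ctr)
  invstd <- 1 / sqrt(va + eps)
  xhat <- ctr * invstd
  y <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(out = from_cmat(y, d[1L], d[2L], d[3L], d[4L]),
       cache = list(xhat = xhat, invstd = invstd, dims = d))
}

ln_bwd <- function(dy, cache, gamma) {
  d <- cache$dims
  dyM <- to_cmat(dy)
  dgamma <- colSums(dyM * cache$xhat)
  dbeta <- colSums(dyM)
  dxhat <- sweep(dyM, 2L, gamma, "*")
  dxM <- cache$invstd *
    (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dx = from_cmat(dxM, d[1L], d[2L], d[3L], d[4L]),
       dgamma = dgamma, dbeta = dbeta)
}

# --- parameter initialisation ----------------------------------------------

init_conv3x3 <- function(cin, cout) {
  matrix(stats::rnorm(9L * cin * cout, sd = sqrt(2 / (9 * cin))), 9L * cin, cout)
}

init_conv1x1 <- function(cin, cout) {
  matrix(stats::rnorm(cin * cout, sd = sqrt(2 / cin)), cin, cout)
}

init_linear <- function(cin, cout) {
  matrix(stats::rnorm(cin * cout, sd = sqrt(1 / cin)), cin, cout)
}
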