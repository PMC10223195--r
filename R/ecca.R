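# Efficient channel cross-attention (ECCA): gates each skip feature E_i with
# a channel descriptor built jointly from E_i and the decoder feature D_i.
#
#   M(E) = sigmoid(AvgPool(E));  M(D) = sigmoid(AvgPool(D))
#   N    = L1 %*% M(E) + L2 %*% M(D)
#   E'   = sigmoid(N) * E          (gate broadcast over spatial positions)
#
# Both sigmoids are intentional: the descriptors are squashed before the
# linear maps and the fused score is squashed again to form the gate. An
# optional mode adds a max-pool descriptor to the average-pool one before the
# squash.

#' Channel descriptor of a feature map
#'
#' Global average pool per channel followed by a sigmoid; with
#' `add_maxpool = TRUE` the per-channel spatial maximum is added to the mean
#' before the squash.
#'
#' @param x feature map.
#' @param add_maxpool also aggregate with a global max pool (off by default).
#' @return `C x N` matrix of descriptor values in (0, 1).
#' @export
channel_descriptor <- function(x, add_maxpool = FALSE) {
  x <- as_feature_map(x)
  d <- dim(x)
  m <- array(x, c(d[1L] * d[2L], d[3L], d[4L]))
  pooled <- apply(m, c(2L, 3L), mean)
  if (add_maxpool) pooled <- pooled + apply(m, c(2L, 3L), max)
  sigmoid(matrix(pooled, d[3L], d[4L]))
}

#' Fuse skip and decoder channel descriptors
#'
#' Returns the pre-sigmoid fused score `N = L1 %*% mE + L2 %*% mD`.
#'
#' @param m_e,m_d `C x N` descriptor matrices (columns are samples).
#' @param L1,L2 `C x C` weight matrices of the two linear layers.
#' @return `C x N` matrix of fused scores.
#' @export
fuse_descriptors <- function(m_e, m_d, L1, L2) {
  m_e <- as.matrix(m_e); m_d <- as.matrix(m_d)
  if (nrow(m_e) != nrow(m_d) || nrow(m_e) != ncol(L1) || nrow(m_e) != ncol(L2)) {
    stop("fuse_descriptors: channel count mismatch")
  }
  L1 %*% m_e + L2 %*% m_d
}

#' Gate a skip feature by a fused channel score
#'
#' @param e feature map to gate.
#' @param n `C x N` pre-sigmoid fused score (or length-C vector).
#' @return gated feature map `sigmoid(n) * e`.
#' @export
gate_features <- function(e, n) {
  e <- as_feature_map(e)
  d <- dim(e)
  n <- if (is.matrix(n)) n else matrix(n, d[3L], d[4L])
  if (nrow(n) != d[3L]) stop("gate_features: channel count mismatch")
  g <- sigmoid(n)
  gx <- aperm(array(g, c(d[3L], d[4L], d[1L], d[2L])), c(3L, 4L, 1L, 2L))
  e * gx
}

# --- module forward/backward (used inside the decoder) ---------------------

ecca_fwd <- function(e, dfeat, p) {
  de <- dim(e)
  hw <- de[1L] * de[2L]
  em <- array(e, c(hw, de[3L], de[4L]))
  dm <- array(dfeat, c(hw, de[3L], de[4L]))
  pe <- matrix(apply(em, c(2L, 3L), mean), de[3L], de[4L])
  pd <- matrix(apply(dm, c(2L, 3L), mean), de[3L], de[4L])
  m_e <- sigmoid(pe)
  m_d <- sigmoid(pd)
  nmat <- p$L1 %*% m_e + p$L2 %*% m_d
  g <- sigmoid(nmat)
  gx <- aperm(array(g, c(de[3L], de[4L], de[1L], de[2L])), c(3L, 4L, 1L, 2L))
  list(out = e * gx,
       cache = list(e = e, g = g, gx = gx, m_e = m_e, m_d = m_d, dims = de))
}

ecca_bwd <- function(dy, cache, p) {
  de <- cache$dims
  hw <- de[1L] * de[2L]
  # gate branch
  prod_sum <- array(dy * cache$e, c(hw, de[3L], de[4L]))
  dg <- matrix(apply(prod_sum, c(2L, 3L), sum), de[3L], de[4L])
  dn <- dg * cache$g * (1 - cache$g)
  dL1 <- tcrossprod(dn, cache$m_e)
  dL2 <- tcrossprod(dn, cache$m_d)
  dm_e <- crossprod(p$L1, dn) * cache$m_e * (1 - cache$m_e)
  dm_d <- crossprod(p$L2, dn) * cache$m_d * (1 - cache$m_d)
  # average pool spreads gradient uniformly
  de_pool <- aperm(array(dm_e / hw, c(de[3L], de[4L], de[1L], de[2L])),
                   c(3L, 4L, 1L, 2L))
  dd_pool <- aperm(array(dm_d / hw, c(de[3L], de[4L], de[1L], de[2L])),
                   c(3L, 4L, 1L, 2L))
  list(de = dy * cache$gx + de_pool,
       dd = dd_pool,
       grads = list(L1 = dL1, L2 = dL2))
}
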