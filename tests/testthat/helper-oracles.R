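# Independent brute-force oracles and tiny fixtures shared across tests.

# Dense explicit-loop cross-attention: per head, scores t(Q) %*% K scaled by
# 1/sqrt(head key width), softmax over keys, applied to the values. Written
# with scalar loops on purpose: it is the reference the vectorized
# implementation is checked against.
dense_attention_oracle <- function(Q, K, V) {
  k <- nrow(Q); dq <- ncol(Q); dkv <- ncol(K)
  S <- matrix(0, dq, dkv)
  for (a in seq_len(dq)) {
    for (b in seq_len(dkv)) {
      acc <- 0
      for (t in seq_len(k)) acc <- acc + Q[t, a] * K[t, b]
      S[a, b] <- acc / sqrt(dkv)
    }
  }
  A <- matrix(0, dq, dkv)
  for (a in seq_len(dq)) {
    e <- exp(S[a, ] - max(S[a, ]))
    A[a, ] <- e / sum(e)
  }
  out <- matrix(0, k, dq)
  for (t in seq_len(k)) {
    for (a in seq_len(dq)) {
      acc <- 0
      for (b in seq_len(dkv)) acc <- acc + A[a, b] * V[t, b]
      out[t, a] <- acc
    }
  }
  out
}

# Explicit double-loop confusion tally.
loop_confusion <- function(pred, gt) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      if (pred[i, j] == 1 && gt[i, j] == 1) tp <- tp + 1L
      else if (pred[i, j] == 1 && gt[i, j] == 0) fp <- fp + 1L
      else if (pred[i, j] == 0 && gt[i, j] == 0) tn <- tn + 1L
      else fn <- fn + 1L
    }
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# All-pairs AUC with half credit for ties.
loop_auc <- function(scores, gt) {
  s <- as.vector(scores); g <- as.vector(gt)
  pos <- s[g == 1]; neg <- s[g == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  acc <- 0
  for (a in pos) {
    for (b in neg) {
      acc <- acc + if (a > b) 1 else if (a == b) 0.5 else 0
    }
  }
  acc / (length(pos) * length(neg))
}

# Standard Cohen's kappa from marginal probabilities (independent form).
cohen_kappa_standard <- function(cc) {
  n <- cc$tp + cc$fp + cc$tn + cc$fn
  po <- (cc$tp + cc$tn) / n
  p_yes_t <- (cc$tp + cc$fn) / n
  p_yes_p <- (cc$tp + cc$fp) / n
  pe <- p_yes_t * p_yes_p + (1 - p_yes_t) * (1 - p_yes_p)
  (po - pe) / (1 - pe)
}

# Elementwise BCE loop.
loop_bce <- function(logits, y) {
  p <- 1 / (1 + exp(-as.vector(logits)))
  y <- as.vector(y)
  acc <- 0
  for (i in seq_along(p)) {
    acc <- acc - (y[i] * log(p[i]) + (1 - y[i]) * log(1 - p[i]))
  }
  acc / length(p)
}

# Small model configuration used wherever full-scale widths are unnecessary.
micro_config <- function(variant = "full", heads = 2L, reduction = 4L) {
  model_config(variant = variant, base_width = 4L,
               channel_widths = c(4L, 8L, 12L, 16L),
               attention = attention_config(num_heads = heads,
                                            reduction_factor = reduction))
}

random_image_batch <- function(H, W, N = 2L, seed = 1L) {
  set.seed(seed)
  list(x = array(stats::runif(H * W * N), c(H, W, 1L, N)),
       y = array((stats::runif(H * W * N) > 0.8) + 0, c(H, W, 1L, N)))
}

flatten_params <- function(p) rapply(p, function(a) a, how = "unlist")

fixture_training_set <- function(n = 8L, seed = 100L,
                                 params = vessel_tree_params()) {
  lapply(seq_len(n), function(i) synthetic_sample(params, seed + i))
}
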