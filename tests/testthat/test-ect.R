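# Cross-fusion transformer: normalization, projections, token reduction,
# attention algebra against the dense loop oracle, residual refinement,
# and cross-scale information flow.

test_that("per-token normalization removes mean and fixes variance", {
  cst <- array(4.2, c(5, 5, 6, 1))
  out <- normalize_scale(cst)
  expect_equal(max(abs(out)), 0, tolerance = 1e-3)  # eps-regularized

  set.seed(8)
  x <- array(rnorm(8 * 8 * 6 * 2, mean = 2, sd = 3), c(8, 8, 6, 2))
  y <- normalize_scale(x)
  expect_identical(dim(y), dim(x))
  m <- to_cmat(y)
  expect_equal(max(abs(rowMeans(m))), 0, tolerance = 1e-6)
  expect_equal(rowMeans(m * m), rep(1, nrow(m)), tolerance = 1e-3)
})

test_that("Q/K/V projection keeps spatial size and separates weights", {
  set.seed(3)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4, 1))
  wq <- init_conv1x1(4L, 6L); wk <- init_conv1x1(4L, 6L)
  wv <- init_conv1x1(4L, 6L)
  p <- project_qkv(x, wq, wk, wv)
  for (nm in c("q", "k", "v")) expect_identical(dim(p[[nm]]), c(8L, 8L, 6L, 1L))
  expect_gt(max(abs(p$q - p$k)), 0.1)
  z <- project_qkv(array(0, c(8, 8, 4, 1)), wq, wk, wv)
  expect_equal(max(abs(unlist(z))), 0)
})

test_that("token reduction flattens to the expected count and preserves constants", {
  set.seed(5)
  x <- array(rnorm(32 * 32 * 3), c(32, 32, 3, 1))
  tk <- reduce_tokens(x, "bilinear", c(8, 8))
  expect_identical(dim(tk), c(64L, 3L))

  cst <- array(1.25, c(16, 16, 2, 1))
  tkc <- reduce_tokens(cst, "bilinear", c(4, 4))
  expect_equal(max(abs(tkc - 1.25)), 0, tolerance = 1e-12)

  # factor 1 is identity flattening
  tid <- reduce_tokens(x, "bilinear", c(32, 32))
  expect_equal(tid, matrix(x, 32 * 32, 3))

  expect_error(reduce_tokens(x, "bilinear", c(64, 8)), "exceeds")
})

test_that("cross-attention matches closed-form degenerate cases", {
  set.seed(6)
  k <- 10L
  # single key/value column: softmax over a singleton is exactly 1
  q <- matrix(rnorm(k * 3), k, 3)
  v1 <- matrix(rnorm(k), k, 1)
  out <- efficient_cross_attention(q, matrix(rnorm(k), k, 1), v1)
  expect_equal(out, matrix(v1, k, 3), tolerance = 1e-12)

  # identical key columns: uniform weights, output is the value row-mean
  kc <- matrix(rep(rnorm(k), 4), k, 4)
  vc <- matrix(rnorm(k * 4), k, 4)
  out2 <- efficient_cross_attention(q, kc, vc)
  expect_equal(out2, matrix(rowMeans(vc), k, 3), tolerance = 1e-12)
})

test_that("vectorized attention equals the dense loop oracle", {
  set.seed(7)
  for (rep in 1:10) {
    x <- array(rnorm(6 * 6 * 4), c(6, 6, 4, 1))
    wq <- init_conv1x1(4L, 4L); wk <- init_conv1x1(4L, 4L)
    wv <- init_conv1x1(4L, 4L)
    p <- project_qkv(normalize_scale(x), wq, wk, wv)
    q <- reduce_tokens(p$q, "bilinear", c(6, 6))
    kk <- reduce_tokens(p$k, "bilinear", c(6, 6))
    v <- reduce_tokens(p$v, "bilinear", c(6, 6))
    fast <- efficient_cross_attention(q, kk, v, num_heads = 1L)
    slow <- dense_attention_oracle(q, kk, v)
    expect_lt(max(abs(fast - slow)), 1e-5)
  }
})

test_that("attention rows are probability distributions", {
  m <- build_model(micro_config("full", heads = 2L, reduction = 8L), seed = 4)
  batch <- random_image_batch(32L, 32L, N = 2L, seed = 3)
  fw <- net_forward(m, batch$x, training = TRUE)
  for (sc in fw$cache$ect$sc) {
    for (heads in sc$attn) {
      for (hd in heads) {
        expect_equal(rowSums(hd$A), rep(1, nrow(hd$A)), tolerance = 1e-6)
      }
    }
  }
})

test_that("residual refinement is exact identity at zero attention", {
  set.seed(9)
  x <- array(rnorm(12 * 12 * 4), c(12, 12, 4, 1))
  w <- list(recon = list(W = init_conv1x1(4L, 4L), b = numeric(4)),
            rbn = list(gamma = rep(1, 4), beta = numeric(4)),
            rconv = list(W = matrix(0, 36, 4), b = numeric(4)))
  eca <- matrix(0, 9, 4)   # 3x3 token grid, all-zero attention output
  e <- ect_layer(x, eca, c(3, 3), w)
  expect_identical(dim(e), dim(x))
  expect_equal(e, x, tolerance = 1e-12)

  # general weights keep outputs finite across random draws
  for (r in 1:20) {
    w$rconv$W <- init_conv3x3(4L, 4L)
    eca_r <- matrix(rnorm(36), 9, 4)
    expect_true(all(is.finite(ect_layer(x, eca_r, c(3, 3), w))))
  }
})

test_that("fused outputs match encoder scales and mix information across them", {
  m <- build_model(micro_config("ect", heads = 2L, reduction = 8L), seed = 12)
  img <- matrix(runif(64 * 64), 64, 64)
  e <- ect_outputs(m, img)
  ms <- encode(m, img)
  for (i in 1:4) expect_identical(dim(e[[i]]), dim(ms[[i]]))
  info <- attr(e, "attention_info")
  expect_identical(info$k, 64L)   # (64/8)^2 tokens

  # zeroing one encoder scale changes every other fused output
  ms0 <- ms
  ms0$x3 <- ms0$x3 * 0
  e0 <- ect_fwd(ms0, m$params$ect, m$config$attention, m$buffers,
                training = FALSE)$e
  for (i in c(1L, 2L, 4L)) expect_gt(max(abs(e0[[i]] - e[[i]])), 1e-8)
})

test_that("attention matrix size depends only on the token grid, not image size", {
  cfgA <- model_config(variant = "ect", base_width = 4L,
                       channel_widths = c(4L, 8L, 12L, 16L),
                       attention = attention_config(num_heads = 2L,
                                                    target_hw = c(4L, 4L)))
  m <- build_model(cfgA, seed = 6)
  i64 <- attr(ect_outputs(m, matrix(runif(64^2), 64, 64)), "attention_info")
  i128 <- attr(ect_outputs(m, matrix(runif(128^2), 128, 128)), "attention_info")
  expect_identical(i64$k, 16L)
  expect_identical(i128$k, 16L)
  expect_identical(i64$score_dims, i128$score_dims)
  expect_identical(i64$d_sigma, i128$d_sigma)
})
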