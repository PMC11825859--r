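# The zero-query / identity cross-attention initialization and its
# closed form: at init the attention map is uniform, every output row
# is the mean detail token, and the output carries no information about
# the context input -- yet the query pathway remains trainable.

# independent brute-force evaluation of softmax(Q K' / sqrt(dk)) V W_P
brute_force_cross_attention <- function(ctx, det, w) {
  n <- nrow(det); d <- ncol(det)
  Q <- matrix(0, n, d); K <- matrix(0, n, d); V <- matrix(0, n, d)
  for (i in 1:n) for (j in 1:d) {
    for (k in 1:d) {
      Q[i, j] <- Q[i, j] + ctx[i, k] * w$W_Q[k, j]
      K[i, j] <- K[i, j] + det[i, k] * w$W_K[k, j]
      V[i, j] <- V[i, j] + det[i, k] * w$W_V[k, j]
    }
    Q[i, j] <- Q[i, j] + w$b_Q[j]
    K[i, j] <- K[i, j] + w$b_K[j]
    V[i, j] <- V[i, j] + w$b_V[j]
  }
  A <- matrix(0, n, n)
  for (i in 1:n) {
    row <- numeric(n)
    for (j in 1:n) row[j] <- sum(Q[i, ] * K[j, ]) / sqrt(w$d_k)
    e <- exp(row - max(row))
    A[i, ] <- e / sum(e)
  }
  AV <- matrix(0, n, d)
  for (i in 1:n) for (j in 1:d) {
    for (k in 1:n) AV[i, j] <- AV[i, j] + A[i, k] * V[k, j]
  }
  res <- matrix(0, n, d)
  for (i in 1:n) for (j in 1:d) {
    for (k in 1:d) res[i, j] <- res[i, j] + AV[i, k] * w$W_P[k, j]
    res[i, j] <- res[i, j] + w$b_P[j]
  }
  res
}

test_that("init_weights builds the zero-query / identity weight set", {
  w <- init_weights(3)
  expect_true(all(w$W_Q == 0))
  expect_equal(w$W_K, diag(3))
  expect_equal(w$W_V, diag(3))
  expect_equal(w$W_P, diag(3))
  expect_equal(mean(w$W_Q), 0)
  expect_equal(mean(w$W_K), 1 / 3)
  expect_true(all(c(w$b_Q, w$b_K, w$b_V, w$b_P) == 0))
  expect_identical(init_weights(3), init_weights(3))
  expect_error(init_weights(0), "positive")
})

test_that("at init the output rows are the mean detail token", {
  det <- matrix(c(1, 3, 2, 4), 2, 2)  # tokens [[1,2],[3,4]]
  ctx <- matrix(rnorm(4), 2, 2)
  out <- cross_attention(ctx, det, init_weights(2))
  expect_equal(out, matrix(c(2, 2, 3, 3), 2, 2), tolerance = 1e-14)
  for (trial in 1:5) {
    n <- sample(2:8, 1); d <- sample(2:8, 1)
    det <- matrix(rnorm(n * d), n, d)
    out <- cross_attention(matrix(rnorm(n * d), n, d), det, init_weights(d))
    expect_lt(max(abs(sweep(out, 2, colMeans(det)))), 1e-12)
  }
})

test_that("at init the output is independent of the context input", {
  set.seed(5)
  det <- matrix(rnorm(12), 4, 3)
  w <- init_weights(3)
  o1 <- cross_attention(matrix(rnorm(12), 4, 3), det, w)
  o2 <- cross_attention(matrix(rnorm(12, sd = 50), 4, 3), det, w)
  expect_identical(o1, o2)
})

test_that("cross attention matches the brute-force formula on random weights", {
  set.seed(6)
  for (trial in 1:50) {
    n <- sample(2:6, 1); d <- sample(2:4, 1)
    w <- init_weights(d)
    w$W_Q <- matrix(rnorm(d * d), d, d)
    w$W_K <- matrix(rnorm(d * d), d, d)
    w$W_V <- matrix(rnorm(d * d), d, d)
    w$W_P <- matrix(rnorm(d * d), d, d)
    w$b_Q <- rnorm(d); w$b_K <- rnorm(d); w$b_V <- rnorm(d); w$b_P <- rnorm(d)
    ctx <- matrix(rnorm(n * d), n, d)
    det <- matrix(rnorm(n * d), n, d)
    expect_equal(cross_attention(ctx, det, w),
                 brute_force_cross_attention(ctx, det, w), tolerance = 1e-10)
  }
})

test_that("uniform_softmax_matrix equals softmax of a zero matrix", {
  expect_equal(uniform_softmax_matrix(4), matrix(0.25, 4, 4))
  for (n in c(1, 3, 7)) {
    M <- uniform_softmax_matrix(n)
    expect_equal(rowSums(M), rep(1, n))
    ad_begin()
    expect_equal(M, ad_softmax_rows(ad_leaf(matrix(0, n, n)))$v,
                 tolerance = 1e-15)
  }
  expect_error(uniform_softmax_matrix(0), "positive")
})

test_that("token/map conversion is a row-major bijection", {
  fm <- array(c(1, 3, 2, 4), c(2, 2, 1))  # [[a,b],[c,d]] = [[1,2],[3,4]]
  tt <- tokens_from_map(fm)
  expect_equal(as.numeric(tt$tokens), c(1, 2, 3, 4))
  set.seed(7)
  fm2 <- array(rnorm(7 * 5 * 3), c(7, 5, 3))
  expect_equal(map_from_tokens(tokens_from_map(fm2)), fm2)
  expect_error(token_tensor(matrix(0, 6, 2), c(2, 2)), "spatial_shape")
})

test_that("the zero-initialized query pathway is inert but trainable", {
  set.seed(8)
  m <- cgsnet:::new_model_env()
  cgsnet:::reg_mca_stage(m, "s", 4L, 3L)
  det <- matrix(rnorm(6 * 4), 6, 4)
  run <- function(ctxv, track = FALSE) {
    ad_begin()
    P <- cgsnet:::make_param_provider(m, track = track)
    out <- cgsnet:::fw_mca_stage(P, "s", ad_leaf(ctxv, track = FALSE),
                                 ad_leaf(det, track = FALSE), 4L)
    list(out = out, P = P)
  }
  ctx <- matrix(rnorm(24), 6, 4)
  base <- run(ctx)$out$v
  # finite-difference sensitivity to the context values is zero
  for (k in 1:5) {
    ctx2 <- ctx; ctx2[sample(24, 1)] <- ctx2[sample(24, 1)] + 1e-3
    expect_lt(max(abs(run(ctx2)$out$v - base)), 1e-8)
  }
  # but the loss gradient with respect to W_Q is generically nonzero
  r <- run(ctx, track = TRUE)
  loss <- ad_sum(ad_mul(r$out, ad_leaf(matrix(rnorm(24), 6, 4), track = FALSE)))
  ad_backward(loss)
  g <- cgsnet:::collect_grads(r$P)
  expect_gt(max(abs(g[["s.wq"]])), 0)
})
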