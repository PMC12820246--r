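# Attention and fusion: printed-equation contracts, brute-force oracle
# equivalence, softmax normalization, permutation invariance, masking.

# Independent loop-based oracle for scaled dot-product attention.
attn_oracle <- function(Q, K, V, d_k) {
  tq <- nrow(Q); tk <- nrow(K)
  A <- matrix(0, tq, tk)
  for (i in seq_len(tq)) {
    logits <- numeric(tk)
    for (j in seq_len(tk)) logits[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d_k)
    e <- exp(logits - max(logits))
    A[i, ] <- e / sum(e)
  }
  O <- matrix(0, tq, ncol(V))
  for (i in seq_len(tq)) for (j in seq_len(tk))
    O[i, ] <- O[i, ] + A[i, j] * V[j, ]
  list(A = A, O = O)
}

test_that("self-attention handles degenerate token sets per the equations", {
  p <- attention_params(dim = 3, d_k = 2, seed = 1)
  one <- self_attention(matrix(c(1, 2, 3), 1, 3), p)
  expect_equal(one$A, matrix(1, 1, 1))
  expect_all_equal(one$O, matrix(c(1, 2, 3), 1, 3) %*% p$Wv, tol = 1e-12)
  # identical tokens -> identical keys -> uniform attention rows
  two <- self_attention(rbind(c(1, 0, 2), c(1, 0, 2)), p)
  expect_all_equal(two$A, matrix(0.5, 2, 2), tol = 1e-12)
})

test_that("self- and cross-attention match the brute-force oracle on 100 random instances", {
  set.seed(123)
  for (trial in 1:100) {
    tq <- sample(1:5, 1); tk <- sample(1:5, 1)
    d <- sample(2:4, 1); dk <- sample(1:4, 1)
    Xq <- matrix(stats::rnorm(tq * d), tq, d)
    Xk <- matrix(stats::rnorm(tk * d), tk, d)
    p <- attention_params(d, dk, seed = trial)
    sa <- self_attention(Xq, p)
    ora <- attn_oracle(Xq %*% p$Wq, Xq %*% p$Wk, Xq %*% p$Wv, dk)
    expect_all_equal(sa$A, ora$A, tol = 1e-6)
    expect_all_equal(sa$O, ora$O, tol = 1e-6)
    ca <- cross_attention(Xq, Xk, p)
    orc <- attn_oracle(Xq %*% p$Wq, Xk %*% p$Wk, Xk %*% p$Wv, dk)
    expect_all_equal(ca$A, orc$A, tol = 1e-6)
    expect_all_equal(ca$C, orc$O, tol = 1e-6)
  }
})

test_that("hand-set integer cases with d_k = 1 match the oracle", {
  p <- list(Wq = diag(1), Wk = diag(1), Wv = diag(1), d_k = 1)
  toks <- matrix(c(1, 2, 0), 3, 1)
  sa <- self_attention(toks, p)
  ora <- attn_oracle(toks, toks, toks, 1)
  expect_all_equal(sa$O, ora$O, tol = 1e-6)
  q2 <- matrix(c(1, 0), 2, 1); k3 <- matrix(c(2, 1, 3), 3, 1)
  ca <- cross_attention(q2, k3, p)
  orc <- attn_oracle(q2, k3, k3, 1)
  expect_all_equal(ca$C, orc$O, tol = 1e-6)
})

test_that("attention rows are normalized and nonnegative on 100 random inputs", {
  set.seed(77)
  for (trial in 1:100) {
    t <- sample(1:6, 1); d <- sample(2:5, 1)
    p <- attention_params(d, d_k = sample(1:4, 1), seed = trial + 500)
    A <- self_attention(matrix(stats::rnorm(t * d, sd = 3), t, d), p)$A
    expect_true(all(A >= 0))
    expect_all_equal(rowSums(A), rep(1, t), tol = 1e-6)
  }
})

test_that("cross-attention is convex over values and permutation-invariant over keys", {
  set.seed(5)
  d <- 4
  p <- attention_params(d, 3, seed = 9)
  Xq <- matrix(stats::rnorm(2 * d), 2, d)
  # identical value rows: every output row equals that value projection
  Xk_same <- matrix(rep(stats::rnorm(d), 3), 3, d, byrow = TRUE)
  ca <- cross_attention(Xq, Xk_same, p)
  v <- (Xk_same %*% p$Wv)[1, ]
  expect_all_equal(ca$C, rbind(v, v), tol = 1e-9)
  # zero logits (zero queries): uniform weights -> column mean of V
  ca0 <- cross_attention(matrix(0, 2, d), Xk <- matrix(stats::rnorm(3 * d), 3, d), p)
  expect_all_equal(ca0$C, rbind(colMeans(Xk %*% p$Wv), colMeans(Xk %*% p$Wv)),
                   tol = 1e-9)
  # permuting key/value tokens leaves outputs unchanged
  perm <- c(3, 1, 2)
  ca1 <- cross_attention(Xq, Xk, p)
  ca2 <- cross_attention(Xq, Xk[perm, ], p)
  expect_all_equal(ca1$C, ca2$C, tol = 1e-9)
  expect_error(cross_attention(Xq, Xk[0, , drop = FALSE], p), "empty key")
})

test_that("fusion sums follow the printed identities under masking", {
  O <- c(1, 1); C1 <- c(2, 0); C2 <- c(0, 3)
  f <- fuse_modalities(O, O, O, C1, C2, c(0, 0))
  expect_equal(as.vector(f$F_S), c(3, 4))     # O + C_SM + C_SE
  # all cross terms zero: F equals the self-attended outputs
  z <- c(0, 0)
  f0 <- fuse_modalities(O, O, O, z, z, z)
  expect_equal(as.vector(f0$F_S), O)
  expect_equal(as.vector(f0$F_M), O)
  # SNP-only mask: cross terms dropped, F_S = O_S; other modalities zero
  fs <- fuse_modalities(O, O, O, C1, C2, c(5, 5),
                        mask = c(TRUE, FALSE, FALSE))
  expect_equal(as.vector(fs$F_S), O)
  expect_equal(as.vector(fs$F_M), z)
  expect_equal(as.vector(fs$F_E), z)
})

test_that("masking a modality equals zeroing its tokens in the model", {
  inputs <- tiny_inputs(n = 3)
  cfg <- tiny_config()
  mod <- nf_model(inputs, cfg, seed = 3)
  masked <- inputs
  masked$mask[2, "EEG"] <- FALSE
  zeroed <- inputs
  zeroed$eeg[2, ] <- 0
  # zeroed tokens: EEG branch biases still fire, so compare against the
  # model contract that masked tokens are zeroed post-encoder
  lm_masked <- nf_forward(mod, masked)$logits
  zeroed$mask[2, "EEG"] <- FALSE
  lm_zeroed <- nf_forward(mod, zeroed)$logits
  expect_all_equal(lm_masked, lm_zeroed, tol = 1e-12)
})

test_that("fusion head is the printed dense + dropout + LN/GLU/residual stack", {
  hp <- fusion_head_params(fusion_dim = 3, width = 4, seed = 2)
  Fv <- lapply(1:3, function(i) stats::rnorm(3))
  # deterministic in evaluation mode
  a <- fusion_head(Fv[[1]], Fv[[2]], Fv[[3]], hp, dropout_rate = 0.5,
                   training = FALSE)
  b <- fusion_head(Fv[[1]], Fv[[2]], Fv[[3]], hp, dropout_rate = 0.5,
                   training = FALSE)
  expect_identical(a$logits, b$logits)
  expect_identical(a$Z, a$Z_drop)            # no dropout at eval
  # affine degenerate: zero projection weight gives Z = b_F
  hp0 <- hp; hp0$W_F <- hp$W_F * 0; hp0$b_F <- c(1, -1, 2, 0)
  z <- fusion_head(Fv[[1]], Fv[[2]], Fv[[3]], hp0)$Z
  expect_equal(as.vector(z), c(1, -1, 2, 0))
  # GLU gate saturated open (huge gate bias): refinement adds the linear
  # half of the GLU on top of the residual
  hpg <- hp
  hpg$b_g <- c(rep(0, 4), rep(50, 4))        # sigmoid(gate) -> 1
  r <- fusion_head(Fv[[1]], Fv[[2]], Fv[[3]], hpg)
  ln <- layernorm_fwd(r$Z_drop, hpg$gamma, hpg$beta)
  lin_half <- ln$out %*% hpg$W_g[, 1:4]      # + zero bias
  expect_all_equal(r$refined, r$Z_drop + lin_half, tol = 1e-8)
  expect_error(fusion_head(Fv[[1]], Fv[[2]], Fv[[3]], hp, dropout_rate = 1),
               "dropout_rate")
})
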