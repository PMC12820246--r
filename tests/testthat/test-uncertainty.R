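# MC-dropout posterior, uncertainty decomposition, calibration, and the
# composite objective.

test_that("uncertainty decomposition reproduces the hand-evaluated identities", {
  # all passes identical one-hot: perfectly certain
  u0 <- decompose_uncertainty(matrix(rep(c(1, 0, 0), 4), 4, 3, byrow = TRUE))
  expect_equal(u0$epistemic, 0)
  expect_equal(u0$aleatoric, 0)
  expect_equal(u0$U_final, 0)
  # identical uniform: no epistemic spread, aleatoric 3 * (1/3)(2/3) = 2/3
  uu <- decompose_uncertainty(matrix(1 / 3, 5, 3))
  expect_equal(uu$epistemic, 0)
  expect_equal(uu$aleatoric, 2 / 3, tolerance = 1e-12)
  # two opposite one-hot passes: mu = (0.5, 0.5), per-class var 0.25,
  # epistemic = class mean 0.25, aleatoric 0, U = 0.25
  u2 <- decompose_uncertainty(rbind(c(1, 0), c(0, 1)))
  expect_equal(u2$mu, c(0.5, 0.5))
  expect_equal(unname(u2$var_per_class), c(0.25, 0.25))
  expect_equal(u2$epistemic, 0.25)
  expect_equal(u2$aleatoric, 0)
  expect_equal(u2$U_final, 0.25)
  # T = 1: population variance with divisor T gives 0
  u1 <- decompose_uncertainty(matrix(c(0.6, 0.4), 1))
  expect_equal(u1$epistemic, 0)
  # decomposition identity holds always
  set.seed(3)
  S <- row_softmax(matrix(stats::rnorm(30), 10, 3))
  ud <- decompose_uncertainty(S)
  expect_equal(ud$epistemic + ud$aleatoric, ud$U_final)
  expect_error(decompose_uncertainty(matrix(c(0.9, 0.5), 1)), "probability")
})

test_that("MC prediction is seeded, and collapses to the deterministic pass at dropout 0", {
  inputs <- tiny_inputs(n = 3)
  mod <- nf_model(inputs, tiny_config(), seed = 3)    # all dropout rates 0
  mc <- mc_config(num_passes = 7, seed = 5)
  pr <- mc_predict(mod, inputs, mc = mc)
  expect_true(all(pr$epistemic == 0))                 # sigma^2 = 0 exactly
  det <- calibrated_softmax(nf_forward(mod, inputs)$logits, 1)
  expect_all_equal(pr$mu, det, tol = 1e-12)
  # with dropout active, replaying the same seed reproduces the samples
  cfg <- tiny_config(); cfg$head_dropout <- 0.4
  mod2 <- nf_model(inputs, cfg, seed = 3)
  a <- mc_predict(mod2, inputs, mc = mc)
  b <- mc_predict(mod2, inputs, mc = mc)
  expect_identical(a$samples, b$samples)
  expect_gt(mean(a$epistemic), 0)
  expect_error(mc_config(num_passes = 0), "num_passes")
})

test_that("calibrated softmax obeys closed forms and limits", {
  expect_equal(calibrated_softmax(c(0, 0, 0), 17), rep(1 / 3, 3))
  expect_equal(calibrated_softmax(c(log(2), 0), 1), c(2 / 3, 1 / 3),
               tolerance = 1e-12)
  # closed form at temperature 1000: exp(0.005) / (exp(0.005) + 2) etc.,
  # which sits 1.1e-3 from uniform
  expect_all_equal(calibrated_softmax(c(5, 0, 0), 1000),
                   c(exp(0.005), 1, 1) / (exp(0.005) + 2), tol = 1e-12)
  expect_all_equal(calibrated_softmax(c(5, 0, 0), 1e6), rep(1 / 3, 3),
                   tol = 1e-5)
  expect_error(calibrated_softmax(c(1, 2), 0), "temperature")
})

test_that("temperature fitting recovers the generating scale", {
  set.seed(11)
  n <- 4000
  true_p <- row_softmax(matrix(stats::rnorm(n * 3), n, 3))
  y <- vapply(seq_len(n), function(i) sample(3, 1, prob = true_p[i, ]), 0L)
  logits <- log(true_p)                       # perfectly calibrated
  t1 <- fit_temperature(logits, y)
  expect_lt(abs(t1 - 1), 0.05)
  t2 <- fit_temperature(2 * logits, y)        # two times over-sharpened
  expect_lt(abs(t2 - 2), 0.1)
  nll <- function(lg, temp) {
    p <- calibrated_softmax(lg, temp)
    -mean(log(p[cbind(seq_len(n), y)]))
  }
  for (sc in c(0.5, 1, 3)) {
    tf <- fit_temperature(sc * logits, y)
    expect_lte(nll(sc * logits, tf), nll(sc * logits, 1) + 1e-12)
  }
  expect_error(fit_temperature(logits, rep(1L, n)), "classes")
})

test_that("cross-entropy and focal loss match closed forms", {
  expect_equal(cross_entropy(c(1, 0, 0), c(1, 0, 0)), 0, tolerance = 1e-9)
  expect_equal(cross_entropy(rep(1 / 3, 3), c(0, 1, 0)), log(3),
               tolerance = 1e-9)
  expect_equal(cross_entropy(c(0.5, 0.25, 0.25), c(1, 0, 0)), log(2),
               tolerance = 1e-9)
  expect_error(cross_entropy(c(0.5, 0.5), c(0.7, 0.3)), "one-hot")
  expect_equal(focal_loss(c(1, 0), c(1, 0), gamma = 3), 0, tolerance = 1e-9)
  expect_equal(focal_loss(c(0.5, 0.5), c(1, 0), gamma = 2),
               0.25 * log(2), tolerance = 1e-9)
  # gamma = 0 with unit weights reduces to cross-entropy (100 random cases)
  set.seed(21)
  P <- row_softmax(matrix(stats::rnorm(300), 100, 3))
  Y <- one_hot_labels(factor(CLASS_LEVELS[sample(3, 100, TRUE)],
                             CLASS_LEVELS))
  expect_all_equal(focal_loss(P, Y, gamma = 0), cross_entropy(P, Y),
                   tol = 1e-9)
  # monotone non-increasing in the true-class probability
  ps <- seq(0.05, 0.95, by = 0.05)
  fl <- vapply(ps, function(p) focal_loss(c(p, 1 - p), c(1, 0), 2), 0)
  expect_true(all(diff(fl) < 0))
  expect_error(focal_loss(c(0.5, 0.5), c(1, 0), gamma = -1), "gamma")
})

test_that("composite loss decomposes exactly and reduces term by term", {
  set.seed(31)
  P <- row_softmax(matrix(stats::rnorm(24), 8, 3))
  Y <- one_hot_labels(factor(CLASS_LEVELS[sample(3, 8, TRUE)], CLASS_LEVELS))
  W <- list(h_WF = matrix(c(2, -1), 1), s_Wemb = matrix(0.5, 2, 2),
            h_bF = c(1, 1))
  lt <- total_loss(list(P), Y, W, lambda_l2 = 0.1, alpha_l1 = 0.01,
                   kl_coef = 0.2, u_coef = 1, focal_gamma = 2,
                   head_dropout = 0.5)
  # single weight 2 contributes 0.1 * 4 to the squared-norm penalty
  expect_equal(lt$l2_term, 0.1 * (4 + 1 + 4 * 0.25), tolerance = 1e-12)
  expect_equal(lt$l1_term, 0.01 * (3 + 4 * 0.5), tolerance = 1e-12)
  expect_equal(lt$D_KL, 0.2 * 0.5 * 0.5 * 5, tolerance = 1e-12)
  expect_equal(lt$L_final,
               lt$L_CE + lt$U_term + lt$l2_term + lt$l1_term + lt$D_KL +
                 lt$L_focal, tolerance = 1e-12)
  expect_equal(lt$L_total, lt$L_CE + lt$U_term, tolerance = 1e-12)
  # zero coefficients and zero weights remove exactly those terms
  lt0 <- total_loss(list(P), Y, lapply(W, function(w) w * 0),
                    lambda_l2 = 0.1, alpha_l1 = 0.01, kl_coef = 0.2)
  expect_equal(lt0$l2_term, 0); expect_equal(lt0$l1_term, 0)
  expect_equal(lt0$D_KL, 0)
  ltc <- total_loss(list(P), Y, W, lambda_l2 = 0, alpha_l1 = 0, kl_coef = 0,
                    u_coef = 0, focal_coef = 0)
  expect_equal(ltc$L_final, ltc$L_CE, tolerance = 1e-9)
  expect_true(all(unlist(lt[1:6]) >= 0))
  expect_gte(lt$L_final, lt$L_CE)
  expect_error(total_loss(list(P), Y, W, lambda_l2 = -1), "coefficients")
})

test_that("single-pass mean agrees with a high-pass MC mean within Monte-Carlo error", {
  inputs <- tiny_inputs(n = 2)
  cfg <- tiny_config(); cfg$head_dropout <- 0.3
  mod <- nf_model(inputs, cfg, seed = 3)
  a <- mc_predict(mod, inputs, idx = 1, mc = mc_config(num_passes = 30, seed = 1))
  b <- mc_predict(mod, inputs, idx = 1, mc = mc_config(num_passes = 300, seed = 2))
  se <- sqrt(mean(a$estimates[[1]]$var_per_class) / 30)
  expect_lt(max(abs(a$mu - b$mu)), 3 * se + 3 * sqrt(mean(b$estimates[[1]]$var_per_class) / 300))
})

test_that("loss gradient w.r.t. logits matches numerical differentiation", {
  set.seed(41)
  n <- 5; C <- 3; Tn <- 3
  logits <- lapply(seq_len(Tn), function(t) matrix(stats::rnorm(n * C), n, C))
  Y <- one_hot_labels(factor(CLASS_LEVELS[sample(3, n, TRUE)], CLASS_LEVELS))
  cw <- c(1.2, 0.9, 0.9)
  lossval <- function(lgs) {
    probs <- lapply(lgs, row_softmax)
    lt <- total_loss(probs, Y, NULL, u_coef = 0.7, focal_gamma = 2,
                     focal_coef = 1.3, class_weights = cw)
    lt$L_CE + lt$U_term * 1 + lt$L_focal
  }
  # note: U_term inside total_loss uses u_coef already
  probs <- lapply(logits, row_softmax)
  dl <- dloss_dlogits(probs, Y, u_coef = 0.7, focal_gamma = 2,
                      focal_coef = 1.3, class_weights = cw)
  eps <- 1e-6
  worst <- 0
  for (t in seq_len(Tn)) for (j in sample(n * C, 6)) {
    lp <- logits; lp[[t]][j] <- lp[[t]][j] + eps
    lm <- logits; lm[[t]][j] <- lm[[t]][j] - eps
    g <- (lossval(lp) - lossval(lm)) / (2 * eps)
    worst <- max(worst, abs(g - dl[[t]][j]))
  }
  expect_lt(worst, 1e-6)
})
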