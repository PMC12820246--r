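# Model assembly: exact backprop (numerical check), evaluation-mode
# determinism, partial-modality behavior, and a short optimization run.

test_that("analytic gradients match numerical differentiation end to end", {
  inputs <- tiny_inputs(n = 3, mask = cbind(SNP = c(TRUE, TRUE, FALSE),
                                            MRI = c(TRUE, FALSE, TRUE),
                                            EEG = c(TRUE, TRUE, TRUE)))
  mod <- nf_model(inputs, tiny_config(), seed = 3)
  tgt <- matrix(stats::rnorm(9), 3)
  fw <- nf_forward(mod, inputs)
  bw <- nf_backward(mod, inputs, fw$cache, tgt, input_grads = TRUE)
  lossf <- function(params) {
    m2 <- mod; m2$params <- params
    sum(nf_forward(m2, inputs)$logits * tgt)
  }
  eps <- 1e-5
  set.seed(1)
  for (nm in names(mod$params)) {
    sel <- sample(length(mod$params[[nm]]), min(3, length(mod$params[[nm]])))
    for (j in sel) {
      pp <- mod$params; pp[[nm]][j] <- pp[[nm]][j] + eps
      pm <- mod$params; pm[[nm]][j] <- pm[[nm]][j] - eps
      g <- (lossf(pp) - lossf(pm)) / (2 * eps)
      expect_lt(abs(g - bw$grads[[nm]][j]) / max(1, abs(g)), 1e-6)
    }
  }
  # input gradients (saliency path)
  for (j in sample(length(inputs$snp), 3)) {
    ip <- inputs; ip$snp[j] <- ip$snp[j] + eps
    im <- inputs; im$snp[j] <- im$snp[j] - eps
    g <- (sum(nf_forward(mod, ip)$logits * tgt) -
            sum(nf_forward(mod, im)$logits * tgt)) / (2 * eps)
    expect_lt(abs(g - bw$input_grads$snp[j]), 1e-6)
  }
})

test_that("precomputed conv gather reproduces the direct path exactly", {
  inputs <- tiny_inputs(n = 4)
  mod <- nf_model(inputs, tiny_config(), seed = 3)
  prep <- prep_conv(mod, inputs)
  direct <- nf_forward(mod, inputs, c(2, 4))
  fast <- nf_forward(mod, inputs, c(2, 4), prep = prep)
  expect_identical(direct$logits, fast$logits)
})

test_that("no-attention configuration concatenates pooled encoder outputs", {
  inputs <- tiny_inputs(n = 3)
  cfg <- tiny_config(); cfg$use_attention <- FALSE
  mod <- nf_model(inputs, cfg, seed = 5)
  expect_false(any(grepl("^a_", names(mod$params))))   # no attention params
  fw <- nf_forward(mod, inputs)
  # fused vectors equal token means
  tk <- fw$cache$tok$S
  expect_all_equal(fw$cache$FS,
                   t(vapply(1:3, function(i)
                     colMeans(matrix(tk[i, , ], ncol = cfg$fusion_dim)),
                     numeric(cfg$fusion_dim))))
})

test_that("gradient clipping bounds the global norm at the configured ceiling", {
  p <- list(w = matrix(5, 2, 2))
  g <- list(w = matrix(100, 2, 2))
  st <- adam_init(p)
  up <- adam_step(p, g, st, lr = 0.1, clip = 1.0)
  expect_gt(up$gnorm, 1)
  # re-deriving the clipped gradient: norm after scaling <= 1 + eps
  gnorm <- sqrt(sum(g$w^2))
  clipped <- g$w * (1 / gnorm)
  expect_lte(sqrt(sum(clipped^2)), 1 + 1e-6)
})

test_that("training reduces the loss on a learnable toy problem", {
  # 1-stage schedule on a small separable cohort: logged training loss at
  # the final epoch is below the first epoch in most seeds
  sp <- small_spec(n = 45, seed = 1, frac_complete = 1)
  co <- generate_cohort(sp)
  wins <- 0
  for (s in 1:5) {
    split <- make_splits(co, seed = s)
    cfg <- tiny_config(head_dropout = 0.1)
    cfg$pca_cap <- 8
    fitstats <- preprocess_fit(co, cfg, split$train)
    inputs <- build_model_inputs(co, fitstats)
    model <- nf_model(inputs, cfg, seed = s)
    model <- train_model(model, inputs, split$train, split$val,
                         data.frame(stage = 1, lr = 1e-3, batch_size = 16,
                                    epochs = 4),
                         seed = s)
    lg <- model$log
    if (utils::tail(lg$L_final, 1) < lg$L_final[1]) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("the full tuning schedule prints the documented 10 stages in order", {
  sch <- full_schedule()
  expect_equal(nrow(sch), 10)
  expect_equal(sch$lr[c(1, 10)], c(0.001, 0.00001))
  expect_true(all(diff(sch$lr) <= 0))
  expect_equal(sch$batch_size[c(1, 10)], c(32, 16))
  expect_equal(sch$dropout[c(1, 10)], c(0.5, 0.2))
  expect_equal(sch$epochs[c(1, 10)], c(10, 50))
  expect_equal(sch$filters[c(1, 10)], c(64, 256))
  expect_equal(sch$kernel[c(1, 10)], c(3, 5))
})

test_that("raw-signal EEG path produces segment tokens with exact gradients", {
  set.seed(11)
  n <- 3; ch <- 3; Tn <- 40
  inputs <- tiny_inputs(n = n)
  inputs$eeg <- matrix(stats::rnorm(n * Tn * ch), n)
  inputs$geometry$eeg_channels <- ch
  inputs$geometry$eeg_T <- Tn
  cfg <- tiny_config(eeg_input = "raw")
  mod <- nf_model(inputs, cfg, seed = 3)
  tgt <- matrix(stats::rnorm(n * 3), n)
  fw <- nf_forward(mod, inputs)
  expect_equal(dim(fw$cache$tok$E), c(n, 4L, cfg$fusion_dim))  # 4 segments
  bw <- nf_backward(mod, inputs, fw$cache, tgt, input_grads = TRUE)
  lossf <- function(params) {
    m2 <- mod; m2$params <- params
    sum(nf_forward(m2, inputs)$logits * tgt)
  }
  eps <- 1e-5
  for (nm in c("e_W1", "e_Wtok")) {
    for (j in sample(length(mod$params[[nm]]), 3)) {
      pp <- mod$params; pp[[nm]][j] <- pp[[nm]][j] + eps
      pm <- mod$params; pm[[nm]][j] <- pm[[nm]][j] - eps
      g <- (lossf(pp) - lossf(pm)) / (2 * eps)
      expect_lt(abs(g - bw$grads[[nm]][j]) / max(1, abs(g)), 1e-6)
    }
  }
  sal <- eeg_saliency(mod, inputs, 1, "AD")
  expect_equal(dim(sal), c(ch, Tn))      # channel x time saliency grid
})

test_that("modality dropout never removes the last live modality", {
  inputs <- tiny_inputs(n = 6, mask = cbind(SNP = c(TRUE, rep(FALSE, 5)),
                                            MRI = rep(FALSE, 6),
                                            EEG = c(TRUE, rep(TRUE, 5))))
  cfg <- tiny_config(); cfg$modality_dropout <- 0.9
  mod <- nf_model(inputs, cfg, seed = 2)
  for (rep in 1:10) {
    fw <- with_seed(rep, nf_forward(mod, inputs, dropout = TRUE,
                                    mod_drop = TRUE))
    expect_true(all(rowSums(fw$cache$mask) >= 1))
  }
})
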