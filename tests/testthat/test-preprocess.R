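# Preprocessing contracts: scaling, clipping, encoding, PCA, filtering,
# band powers, volume normalization, bias correction, patch extraction.

test_that("min-max scaling maps documented examples and is idempotent", {
  expect_equal(unname(minmax_scale_columns(cbind(c(2, 4, 6)))[, 1]),
               c(0, 0.5, 1))
  expect_equal(unname(minmax_scale_columns(cbind(c(-1, 0, 3)))[, 1]),
               c(0, 0.25, 1))
  expect_true(all(minmax_scale_columns(cbind(c(5, 5, 5))) == 0))
  X <- matrix(stats::rnorm(60), 20, 3)
  once <- minmax_scale_columns(X)
  expect_all_equal(minmax_scale_columns(once), once)
  # fitted parameters reapply to held-out data without refitting
  pars <- attr(once, "minmax_params")
  held <- minmax_scale_columns(matrix(stats::rnorm(30), 10, 3), params = pars)
  expect_true(all(held >= 0 & held <= 1))
  expect_error(minmax_scale_columns(cbind(c(1, NA))), "missing")
})

test_that("z-score clipping bounds outputs at the oracle boundary and is idempotent", {
  x <- cbind(c(rep(0, 30), 100))
  bound <- mean(x) + 3 * stats::sd(x)      # independent closed-form oracle
  cl <- clip_outliers_zscore(x)
  expect_equal(cl[31, 1], bound)
  expect_true(all(cl <= bound + 1e-12))
  expect_equal(cl[1:30, 1], x[1:30, 1])    # non-outliers unchanged
  inl <- matrix(stats::rnorm(100, sd = 0.1), 50, 2)
  expect_all_equal(clip_outliers_zscore(inl, threshold = 10), inl)
  expect_all_equal(clip_outliers_zscore(inl, threshold = Inf), inl)
  same <- clip_outliers_zscore(x)
  expect_all_equal(clip_outliers_zscore(same, params = attr(same, "clip_params")),
                   same)
  const <- cbind(rep(5, 4))
  expect_all_equal(clip_outliers_zscore(const), const)
  expect_error(clip_outliers_zscore(x, threshold = 0), "threshold")
})

test_that("one-hot expansion is AA/AG/GG ordered with row sums p", {
  expect_equal(unname(one_hot_genotypes(matrix(0, 1, 1))[1, ]), c(1L, 0L, 0L))
  expect_equal(unname(one_hot_genotypes(matrix(1, 1, 1))[1, ]), c(0L, 1L, 0L))
  G <- matrix(2L, 2, 2)
  oh <- one_hot_genotypes(G)
  expect_equal(dim(oh), c(2L, 6L))
  expect_equal(rowSums(oh), c(2, 2))
  expect_error(one_hot_genotypes(matrix(3, 1, 1)), "locus 1")
  # mode imputation completes missing entries before encoding
  Gm <- rbind(c(0L, NA), c(0L, 2L), c(1L, 2L))
  imp <- impute_genotypes_mode(Gm)
  expect_equal(imp[1, 2], 2L)
})

test_that("PCA keeps the smallest k reaching the variance target", {
  r1 <- outer(stats::rnorm(50), stats::rnorm(5))
  f1 <- pca_reduce(r1)
  expect_equal(f1$k, 1L)
  expect_equal(sum(f1$explained), 1, tolerance = 1e-9)
  # isotropic noise: all 10 directions needed for 95%
  set.seed(2)
  X <- matrix(stats::rnorm(5000 * 10), 5000, 10)
  expect_equal(pca_reduce(X, 0.95)$k, 10L)
  expect_equal(pca_reduce(X, 1.0)$k, qr(X)$rank)
  # loadings orthonormal; apply reproduces training scores
  f <- pca_reduce(X, 0.95)
  expect_all_equal(crossprod(f$loadings), diag(f$k), tol = 1e-8)
  expect_all_equal(pca_apply(X, f), f$scores, tol = 1e-8)
  expect_equal(pca_reduce(X, 0.95, max_components = 3)$k, 3L)
  expect_error(pca_reduce(X, 1.5), "variance_target")
})

test_that("bandpass preserves passband tones and rejects stopband tones", {
  fs <- 200
  tt <- seq_len(2000) / fs
  tone10 <- cbind(sin(2 * pi * 10 * tt))
  out <- bandpass_filter(tone10, 0.5, 40, fs)
  mid <- 500:1500
  ratio <- sqrt(mean(out[mid]^2) / mean(tone10[mid]^2))
  expect_gt(ratio, 0.95); expect_lt(ratio, 1.05)
  fs2 <- 250
  tt2 <- seq_len(2500) / fs2
  tone90 <- cbind(sin(2 * pi * 90 * tt2))
  out2 <- bandpass_filter(tone90, 0.5, 40, fs2)
  expect_lt(sqrt(mean(out2^2) / mean(tone90^2)), 0.1)   # >= 20 dB down
  expect_all_equal(bandpass_filter(cbind(rep(0, 500)), 0.5, 40, fs),
                   cbind(rep(0, 500)))
  expect_error(bandpass_filter(tone10, 0.5, 120, fs), "Nyquist")
})

test_that("band powers isolate a pure alpha tone and z-score exactly", {
  fs <- 128
  tt <- seq_len(fs * 8) / fs
  rec <- cbind(sin(2 * pi * 10 * tt))
  bp <- exp(band_psd_features(list(rec), fs, zscore = FALSE)[1, ])
  expect_gt(bp["ch01_alpha"] / sum(bp), 0.9)
  # identical recordings give identical feature rows
  two <- band_psd_features(list(rec, rec), fs, zscore = FALSE)
  expect_identical(two[1, ], two[2, ])
  # z-scored training columns have mean 0, sd 1
  set.seed(8)
  recs <- lapply(1:12, function(i) matrix(stats::rnorm(fs * 4 * 2), ncol = 2))
  fz <- band_psd_features(recs, fs)
  expect_lt(max(abs(colMeans(fz))), 1e-9)
  expect_lt(max(abs(apply(fz, 2, stats::sd) - 1)), 1e-9)
  expect_error(band_psd_features(list(matrix(0, 10, 1)), fs), "Welch")
})

test_that("volume normalization maps to [0,1] with degenerate conventions", {
  v <- array(stats::runif(4^3, 10, 20), c(4, 4, 4))
  nv <- normalize_volume(v)
  expect_equal(min(nv), 0); expect_equal(max(nv), 1)
  expect_all_equal(nv, (v - min(v)) / (max(v) - min(v)))
  expect_true(all(normalize_volume(array(7, c(3, 3, 3))) == 0))
  v01 <- array(c(0, stats::runif(25), 1), c(3, 3, 3))
  expect_all_equal(normalize_volume(v01), v01)
})

test_that("polynomial bias correction removes a planted field by >= 50%", {
  # generator-default 32^3 grid: the texture fit error is well below 1%
  sp <- cohort_spec(n_subjects = 2, n_timesteps = 200, n_channels = 2,
                    n_snps = 10, n_risk_loci = 2, frac_complete = 1,
                    seed = 3, bias_amplitude = 0, noise_sd = 0.03)
  co <- generate_cohort(sp)
  V <- co[[1]]$volume
  Vb <- plant_bias_field(V, 0.3, seed = 11)
  attr(Vb, "bias_field") <- NULL
  Vc <- correct_bias_field(Vb)
  tis <- V > 0.3
  expect_lt(stats::sd(Vc[tis] / V[tis]), 0.5 * stats::sd(Vb[tis] / V[tis]))
  # nothing to remove: an unbiased volume (flat tissue + voxel noise) passes
  # through within 1% RMS, and amplitude-0 planting is consistent with it
  set.seed(2)
  flat <- array(0.75 * (1 + 0.03 * stats::rnorm(24^3)), c(24, 24, 24))
  Vc0 <- correct_bias_field(flat)
  expect_lt(sqrt(mean((Vc0 - flat)^2) / mean(flat^2)), 0.01)
  Vc1 <- correct_bias_field(plant_bias_field(flat, 0, seed = 1))
  expect_lt(sqrt(mean((Vc1 - flat)^2) / mean(flat^2)), 0.01)
  expect_warning(correct_bias_field(array(0, c(4, 4, 4))), "all-zero")
})

test_that("patch extraction follows the clamped half-open window rule", {
  pg <- extract_patches(array(0, c(64, 64, 64)), rep(32, 3), rep(32, 3))
  expect_equal(nrow(pg$starts), 8L)
  one <- extract_patches(array(stats::runif(8^3), c(8, 8, 8)), rep(8, 3))
  expect_equal(nrow(one$starts), 1L)
  expect_equal(dim(one$patches), c(1L, 8L, 8L, 8L))
  # 70^3 with 32^3 patches at stride 32: 3 per axis, last clamped to [39, 70]
  pg2 <- extract_patches(array(0, c(70, 70, 70)), rep(32, 3), rep(32, 3))
  expect_equal(nrow(pg2$starts), 27L)
  expect_equal(sort(unique(pg2$starts[, 1])), c(1L, 33L, 39L))
  expect_error(extract_patches(array(0, c(8, 8, 8)), rep(16, 3)), "patch")
  # coverage: every voxel appears in >= 1 patch at stride <= patch size
  v <- array(seq_len(10^3), c(10, 10, 10))
  pg3 <- extract_patches(v, rep(4, 3), rep(3, 3))
  seen <- array(FALSE, dim(v))
  for (i in seq_len(nrow(pg3$starts))) {
    s <- pg3$starts[i, ]
    seen[s[1]:(s[1] + 3), s[2]:(s[2] + 3), s[3]:(s[3] + 3)] <- TRUE
  }
  expect_true(all(seen))
})

test_that("preprocessing fit statistics freeze on training subjects only", {
  co <- small_cohort()
  cfg <- nf_config(pca_cap = 8)
  fit_tr <- preprocess_fit(co, cfg, train_idx = 1:16)
  inputs <- build_model_inputs(co, fit_tr)
  # transforming held-out subjects must not change the fitted statistics
  fit_before <- unserialize(serialize(fit_tr, NULL))
  inputs2 <- build_model_inputs(co[17:24], fit_tr)
  expect_identical(fit_tr, fit_before)
  # held-out rows computed with train statistics differ from a refit
  fit_all <- preprocess_fit(co, cfg, train_idx = seq_along(co))
  expect_false(isTRUE(all.equal(fit_tr$pca$center, fit_all$pca$center)))
})
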