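# Splitting, leakage guards, aggregation, metrics oracles, and the
# closed-form statistical tests.

test_that("splits are stratified 70/15/15 at subject level and deterministic", {
  labs <- factor(rep(c("AD", "PD", "HC"), c(40, 30, 30)), CLASS_LEVELS)
  sp <- make_splits(labs, seed = 3)
  expect_equal(length(sp$train), 70)
  expect_equal(length(sp$val), 15)
  expect_equal(length(sp$test), 15)
  # disjoint partitions covering everyone
  expect_equal(sort(c(sp$train, sp$val, sp$test)), 1:100)
  # per-partition class counts within one subject of global proportions
  for (part in list(sp$train, sp$val, sp$test)) {
    frac <- table(labs[part]) / length(part)
    expect_true(all(abs(frac - c(0.4, 0.3, 0.3)) <= 1 / length(part) + 1e-9))
  }
  expect_identical(sp, make_splits(labs, seed = 3))
  expect_false(identical(sp$train, make_splits(labs, seed = 4)$train))
  # k folds partition the non-test pool exactly once per subject
  pool <- sort(c(sp$train, sp$val))
  expect_equal(sort(as.integer(names(sp$folds))), pool)
  expect_equal(sort(unique(sp$folds)), 1:5)
  expect_error(make_splits(factor(rep(c("AD", "PD", "HC"), c(3, 30, 30)),
                                  CLASS_LEVELS), k = 5), "fewer than k")
})

test_that("all of a multi-scan subject's data stays in one partition", {
  sp <- small_spec(n = 30, seed = 9, frac_complete = 1)
  sp$scans_per_subject <- 3L
  co <- generate_cohort(sp)
  expect_length(co[[1]]$volumes, 3)
  plan <- make_splits(co, seed = 2)
  # scans live inside the subject sample, so partition membership is unique
  member <- integer(length(co))
  member[plan$train] <- 1; member[plan$val] <- 2; member[plan$test] <- 3
  expect_true(all(member %in% 1:3))
  ids <- vapply(co, `[[`, "", "subject_id")
  expect_equal(anyDuplicated(ids), 0L)
})

test_that("subject aggregation averages calibrated probabilities, ties to AD", {
  probs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0.2, 0.2, 0.6))
  agg <- aggregate_subject_predictions(probs, c("a", "a", "b"))
  expect_equal(unname(agg$probs["a", ]), c(0.5, 0.5, 0))
  expect_equal(as.character(agg$label[agg$subject_id == "a"]), "AD") # tie rule
  expect_equal(as.character(agg$label[agg$subject_id == "b"]), "HC")
  one <- aggregate_subject_predictions(matrix(c(0.1, 0.7, 0.2), 1), "x")
  expect_equal(unname(one$probs[1, ]), c(0.1, 0.7, 0.2))
  # three known vectors -> hand-computed mean
  three <- aggregate_subject_predictions(
    rbind(c(0.6, 0.3, 0.1), c(0.2, 0.5, 0.3), c(0.1, 0.1, 0.8)),
    rep("s", 3))
  expect_equal(unname(three$probs[1, ]), c(0.3, 0.3, 0.4), tolerance = 1e-12)
  expect_error(aggregate_subject_predictions(probs, c("a", "a")), "length")
})

test_that("metrics match a naive counting oracle on small inputs", {
  # perfect predictions
  truth <- factor(rep(CLASS_LEVELS, each = 10), CLASS_LEVELS)
  probs <- one_hot_labels(truth)
  probs <- probs * 0.9 + 0.05
  probs <- probs / rowSums(probs)
  m <- compute_metrics(probs, truth)
  expect_equal(m$accuracy, 1)
  expect_true(all(m$per_class$f1 == 1))
  expect_equal(unname(diag(m$confusion)), c(10, 10, 10))
  # binary-style reduction with known confusion counts: [[8,2],[1,9]]
  tr <- factor(rep(c("AD", "PD"), c(10, 10)), CLASS_LEVELS)
  pd <- c(rep("AD", 8), rep("PD", 2), rep("AD", 1), rep("PD", 9))
  pp <- one_hot_labels(factor(pd, CLASS_LEVELS)) * 0.8 + 0.1
  pp <- pp / rowSums(pp)
  m2 <- compute_metrics(pp, tr)
  ad <- m2$per_class[m2$per_class$class == "AD", ]
  expect_equal(ad$sensitivity, 0.8)
  expect_equal(ad$specificity, 0.9)
  prec <- 8 / 9
  expect_equal(ad$f1, 2 * prec * 0.8 / (prec + 0.8), tolerance = 1e-12)
  # confusion-matrix row sums equal per-class test counts
  expect_equal(unname(rowSums(m2$confusion)), c(10, 10, 0))
  expect_error(compute_metrics(matrix(c(0.9, 0.9, 0.1), 1), factor("AD", CLASS_LEVELS)),
               "sum to 1")
})

test_that("rank-based AUROC agrees with pROC and is ~0.5 under random scores", {
  skip_if_not_installed("pROC")
  set.seed(17)
  truth <- factor(sample(CLASS_LEVELS, 120, TRUE), CLASS_LEVELS)
  probs <- row_softmax(matrix(stats::rnorm(360), 120, 3))
  m <- compute_metrics(probs, truth)
  for (ci in 1:3) {
    ref <- suppressMessages(
      pROC::auc(pROC::roc(truth == CLASS_LEVELS[ci], probs[, ci],
                          quiet = TRUE, direction = "<")))
    expect_equal(m$per_class$auroc[ci], as.numeric(ref), tolerance = 1e-9)
  }
  # random predictions on balanced classes: AUROC within 0.5 +/- 0.07
  truth2 <- factor(rep(CLASS_LEVELS, each = 200), CLASS_LEVELS)
  probs2 <- row_softmax(matrix(stats::rnorm(1800), 600, 3))
  m2 <- compute_metrics(probs2, truth2)
  expect_true(all(abs(m2$per_class$auroc - 0.5) < 0.07))
})

test_that("McNemar closed forms and fallbacks match hand calculations", {
  # b = c = 10: chi-square (|0| - 1)^2 / 20 = 0.05 -> p > 0.8
  c1 <- c(rep(TRUE, 10), rep(FALSE, 10), rep(TRUE, 20))
  c2 <- c(rep(FALSE, 10), rep(TRUE, 10), rep(TRUE, 20))
  r <- mcnemar_test(c1, c2, exact_below = 0)
  expect_equal(r$statistic, 0.05)
  expect_gt(r$p.value, 0.8)
  # b = 10, c = 2: chi-square 49/12, p < 0.05 (with continuity correction)
  c1 <- c(rep(TRUE, 10), rep(FALSE, 2), rep(TRUE, 30))
  c2 <- c(rep(FALSE, 10), rep(TRUE, 2), rep(TRUE, 30))
  r2 <- mcnemar_test(c1, c2, exact_below = 0)
  expect_equal(r2$statistic, 49 / 12, tolerance = 1e-12)
  expect_equal(r2$p.value, stats::pchisq(49 / 12, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(r2$p.value, 0.05)
  # below threshold the exact binomial is used
  r3 <- mcnemar_test(c1, c2)   # b + c = 12 < 25
  expect_equal(r3$method, "exact binomial")
  expect_equal(r3$p.value, stats::binom.test(10, 12, 0.5)$p.value)
  # identical models: degenerate, p = 1
  expect_warning(r4 <- mcnemar_test(c1, c1), "discordant")
  expect_equal(r4$p.value, 1)
})

test_that("paired t test matches the closed form and its symmetries", {
  d <- c(0.02, 0.03, 0.01, 0.02, 0.02)
  r <- paired_t_test(d)
  expect_equal(r$t, mean(d) / (stats::sd(d) / sqrt(5)), tolerance = 1e-12)
  expect_equal(r$p.value, 2 * stats::pt(-abs(r$t), 4), tolerance = 1e-12)
  # agrees with stats::t.test as an independent oracle
  tt <- stats::t.test(d)
  expect_equal(r$t, unname(tt$statistic), tolerance = 1e-9)
  expect_equal(r$p.value, tt$p.value, tolerance = 1e-9)
  # sign flip: same |t|, same p
  rf <- paired_t_test(-d)
  expect_equal(abs(rf$t), abs(r$t)); expect_equal(rf$p.value, r$p.value)
  # exact ties
  expect_warning(rz <- paired_t_test(rep(0.5, 4), rep(0.5, 4)), "ties")
  expect_equal(rz$p.value, 1)
})

test_that("cross-validation trains on fold complements and reports per-fold metrics", {
  co <- generate_cohort(cohort_spec(n_subjects = 36, volume_shape = c(10, 10, 10),
                                    n_timesteps = 600, n_snps = 30,
                                    n_risk_loci = 6, frac_complete = 1,
                                    seed = 4))
  cfg <- tiny_config(pca_cap = 6)
  cv <- cross_validate(co, cfg,
                       schedule = data.frame(stage = 1, lr = 1e-3,
                                             batch_size = 16, epochs = 2),
                       k = 3, seed = 2)
  expect_equal(nrow(cv$per_fold), 3)
  expect_equal(cv$per_fold$fold, 1:3)
  expect_true(all(cv$per_fold$accuracy >= 0 & cv$per_fold$accuracy <= 1))
  expect_equal(unname(cv$summary["mean", "accuracy"]),
               mean(cv$per_fold$accuracy))
})

test_that("ablation harness validates tags and evaluates each exactly once", {
  expect_error(run_ablation(small_cohort(), character(0)), "non-empty")
  expect_error(run_ablation(small_cohort(), c("S", "S")), "unique")
  expect_error(run_ablation(small_cohort(), "S+Q"), "unknown tag")
})
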