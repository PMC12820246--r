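# Subject-level splitting, staged training with early stopping, subject
# prediction aggregation, metrics, significance tests, cross-validation and
# the ablation harness.

#' Stratified subject-level train/validation/test split with k folds
#'
#' Subjects are partitioned by ID (all of a subject's scans/recordings stay
#' together), stratified by class using largest-remainder allocation so
#' per-partition class proportions are within one subject of the global
#' proportions.  The non-test pool is additionally partitioned into `k`
#' stratified cross-validation folds.
#'
#' @param cohort An `nf_cohort` (or factor of labels).
#' @param ratios Train/validation/test fractions summing to 1.
#' @param k Number of CV folds over the non-test pool (default 5).
#' @param seed Integer seed (deterministic assignments).
#' @return List of class `split_plan`: `train`, `val`, `test` (integer
#'   subject indices), `folds` (fold id per non-test subject, named by
#'   index), `labels`.
#' @export
make_splits <- function(cohort, ratios = c(0.70, 0.15, 0.15), k = 5, seed = 1) {
  labels <- if (is.factor(cohort)) cohort else cohort_labels(cohort)
  if (abs(sum(ratios) - 1) > 1e-9)
    stop_invalid("ratios", "must sum to 1")
  counts <- table(labels)
  if (any(counts < k))
    stop_invalid("k", sprintf("class '%s' has fewer than k=%d subjects",
                              names(counts)[which.min(counts)], k))
  with_seed(seed, {
    train <- val <- test <- integer(0)
    for (cl in levels(labels)) {
      ids <- which(labels == cl)
      ids <- ids[sample.int(length(ids))]
      sizes <- largest_remainder(length(ids), ratios,
                                 rotate = match(cl, levels(labels)) - 1)
      train <- c(train, ids[seq_len(sizes[1])])
      val <- c(val, ids[sizes[1] + seq_len(sizes[2])])
      test <- c(test, ids[sizes[1] + sizes[2] + seq_len(sizes[3])])
    }
    pool <- sort(c(train, val))
    folds <- integer(length(pool))
    names(folds) <- pool
    for (cl in levels(labels)) {
      ids <- pool[labels[pool] == cl]
      ids <- ids[sample.int(length(ids))]
      folds[as.character(ids)] <- rep_len(seq_len(k), length(ids))
    }
    structure(list(train = sort(train), val = sort(val), test = sort(test),
                   folds = folds, labels = labels, k = k),
              class = "split_plan")
  })
}

one_hot_labels <- function(labels, C = 3) {
  Y <- matrix(0, length(labels), C)
  Y[cbind(seq_along(labels), as.integer(labels))] <- 1
  Y
}

#' Train the multimodal model on a staged schedule
#'
#' Executes the schedule stages in order, carrying weights across stages.
#' Each step runs `train_passes` stochastic passes so the uncertainty term
#' is differentiated in-graph, applies the analytic gradients of the L2/L1/
#' KL penalties, clips the global gradient norm, and takes an Adam step.
#' Early stopping monitors validation cross-entropy with the configured
#' patience and minimum delta; the best-validation weights are restored.
#'
#' @param model An [nf_model()].
#' @param inputs An [build_model_inputs()] object.
#' @param train_idx,val_idx Subject rows used for fitting and validation.
#' @param schedule Data frame of stages (see [desk_schedule()] /
#'   [full_schedule()]); columns `lr`, `batch_size`, `epochs`, and
#'   optionally `dropout`.
#' @param seed Integer seed controlling batching and dropout.
#' @param verbose Print per-epoch progress.
#' @return The trained model with a `log` data frame (stage, epoch, loss
#'   terms, validation loss/accuracy) attached.
#' @export
train_model <- function(model, inputs, train_idx, val_idx,
                        schedule = desk_schedule(), seed = 1,
                        verbose = FALSE) {
  cfg <- model$config
  if (nrow(schedule) < 1) stop_invalid("schedule", "must have >= 1 stage")
  Y_all <- one_hot_labels(inputs$labels, cfg$n_classes)
  cw <- as.numeric(1 / pmax(table(inputs$labels[train_idx]), 1))
  cw <- cw * length(cw) / sum(cw)            # inverse-frequency, mean 1
  opt <- adam_init(model$params)
  prep <- attr(inputs, "nf_prep") %||% prep_conv(model, inputs)
  log_rows <- list()
  best <- list(val = Inf, params = model$params)
  wait <- 0
  Tn <- cfg$train_passes
  step <- 0
  for (st in seq_len(nrow(schedule))) {
    lr <- schedule$lr[st]
    bs <- schedule$batch_size[st]
    drop_rate <- if ("dropout" %in% names(schedule)) schedule$dropout[st] else NULL
    for (ep in seq_len(schedule$epochs[st])) {
      ord <- with_seed(seed + 1000 * st + ep, sample(train_idx))
      batches <- split(ord, ceiling(seq_along(ord) / bs))
      ep_terms <- NULL
      for (b in batches) {
        step <- step + 1
        Yb <- Y_all[b, , drop = FALSE]
        res <- with_seed(seed * 7 + step, {
          grads <- NULL
          pass_probs <- vector("list", Tn)
          caches <- vector("list", Tn)
          for (t in seq_len(Tn)) {
            fw <- nf_forward(model, inputs, b, dropout = TRUE,
                             mod_drop = TRUE, dropout_override = drop_rate,
                             prep = prep)
            pass_probs[[t]] <- row_softmax(fw$logits)
            caches[[t]] <- fw$cache
          }
          dl <- dloss_dlogits(pass_probs, Yb, cfg$u_coef, cfg$focal_gamma,
                              cfg$focal_coef, cw)
          for (t in seq_len(Tn)) {
            bwd <- nf_backward(model, inputs, caches[[t]], dl[[t]])
            grads <- if (is.null(grads)) bwd$grads
                     else mapply(`+`, grads, bwd$grads, SIMPLIFY = FALSE)
          }
          list(grads = grads, pass_probs = pass_probs)
        })
        grads <- res$grads
        # analytic penalty gradients
        pw_names <- names(penalized_weights(model$params))
        for (nm in pw_names) {
          g <- 2 * cfg$lambda_l2 * model$params[[nm]] +
            cfg$alpha_l1 * sign(model$params[[nm]])
          if (nm == "h_WF")
            g <- g + cfg$kl_coef * (1 - cfg$head_dropout) * model$params[[nm]]
          grads[[nm]] <- grads[[nm]] + g
        }
        upd <- adam_step(model$params, grads, opt, lr, clip = cfg$grad_clip)
        model$params <- upd$params
        opt <- upd$state
        lt <- total_loss(res$pass_probs, Yb, model$params,
                         cfg$lambda_l2, cfg$alpha_l1, cfg$kl_coef,
                         cfg$u_coef, cfg$focal_gamma, cfg$focal_coef,
                         cw, cfg$head_dropout)
        if (!is.finite(lt$L_final))
          stop(sprintf("training diverged (non-finite loss) at stage %d epoch %d",
                       st, ep), call. = FALSE)
        ep_terms <- rbind(ep_terms, unlist(lt[c("L_CE", "U_term", "l2_term",
                                                "l1_term", "D_KL", "L_focal",
                                                "L_final")]))
      }
      # validation: deterministic eval-mode cross-entropy
      vfw <- nf_forward(model, inputs, val_idx, prep = prep)
      vp <- row_softmax(vfw$logits)
      vloss <- mean(cross_entropy(vp, Y_all[val_idx, , drop = FALSE]))
      vacc <- mean(max.col(vp) == as.integer(inputs$labels[val_idx]))
      log_rows[[length(log_rows) + 1]] <- data.frame(
        stage = st, epoch = ep, t(colMeans(ep_terms)),
        val_loss = vloss, val_acc = vacc)
      if (verbose)
        message(sprintf("stage %d epoch %2d  train L=%.4f  val CE=%.4f acc=%.3f",
                        st, ep, mean(ep_terms[, "L_final"]), vloss, vacc))
      if (vloss < best$val - cfg$min_delta) {
        best$val <- vloss; best$params <- model$params; wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= cfg$patience) break
      }
    }
  }
  model$params <- best$params
  model$log <- do.call(rbind, log_rows)
  model
}

#' Calibrated subject probabilities in evaluation mode
#'
#' @param model Trained [nf_model()].
#' @param inputs An [build_model_inputs()] object.
#' @param idx Subject rows (default all).
#' @return n x C matrix of calibrated class probabilities.
#' @export
predict_subjects <- function(model, inputs, idx = NULL) {
  fw <- nf_forward(model, inputs, idx)
  calibrated_softmax(fw$logits, model$temperature)
}

#' Aggregate per-sample predictions to subject level
#'
#' The subject probability is the arithmetic mean of its samples'
#' calibrated probability vectors; argmax decides the class with ties
#' broken in class order (AD, PD, HC).
#'
#' @param probs n_samples x C probability matrix.
#' @param subject_ids Character vector mapping each row to a subject.
#' @return List with `subject_id`, `probs` (subjects x C), `label`
#'   (factor).
#' @export
aggregate_subject_predictions <- function(probs, subject_ids) {
  if (length(subject_ids) != nrow(probs))
    stop_invalid("subject_ids", "length must match rows of probs")
  if (any(!nzchar(subject_ids)))
    stop_invalid("subject_ids", "empty subject id")
  uid <- unique(subject_ids)
  agg <- t(vapply(uid, function(u)
    colMeans(probs[subject_ids == u, , drop = FALSE]), numeric(ncol(probs))))
  lab <- factor(CLASS_LEVELS[max.col(agg, ties.method = "first")],
                levels = CLASS_LEVELS)
  list(subject_id = uid, probs = agg, label = lab)
}

auroc_binary <- function(scores, pos) {
  npos <- sum(pos); nneg <- sum(!pos)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg)
}

auprc_binary <- function(scores, pos) {
  npos <- sum(pos)
  if (npos == 0) return(NA_real_)
  ord <- order(-scores)
  tp <- cumsum(pos[ord])
  prec <- tp / seq_along(tp)
  rec <- tp / npos
  sum(diff(c(0, rec)) * prec)
}

#' Classification metrics report
#'
#' One-vs-rest sensitivity, specificity, precision, NPV, F1, AUROC (rank
#' based) and AUPRC (step-integrated precision-recall) per class, macro
#' averages, overall accuracy, and the confusion matrix.
#'
#' @param probs n x C matrix of class probabilities (rows sum to 1).
#' @param truth Factor of true labels (levels AD, PD, HC).
#' @return List of class `metrics_report`: `accuracy`, `per_class` (data
#'   frame), `macro` (named vector), `confusion` (C x C matrix,
#'   rows = truth).
#' @export
compute_metrics <- function(probs, truth) {
  probs <- as.matrix(probs)
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop_invalid("probs", "rows must sum to 1")
  truth <- factor(truth, levels = CLASS_LEVELS)
  pred <- factor(CLASS_LEVELS[max.col(probs, ties.method = "first")],
                 levels = CLASS_LEVELS)
  conf <- table(truth = truth, pred = pred)
  acc <- mean(pred == truth)
  per <- lapply(seq_along(CLASS_LEVELS), function(ci) {
    cl <- CLASS_LEVELS[ci]
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    tn <- sum(pred != cl & truth != cl)
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
      2 * prec * sens / (prec + sens) else 0
    data.frame(class = cl, sensitivity = sens, specificity = spec,
               precision = prec, npv = npv, f1 = f1,
               auroc = auroc_binary(probs[, ci], truth == cl),
               auprc = auprc_binary(probs[, ci], truth == cl))
  })
  per <- do.call(rbind, per)
  macro <- colMeans(per[, -1], na.rm = TRUE)
  structure(list(accuracy = acc, per_class = per, macro = macro,
                 confusion = unclass(conf)),
            class = "metrics_report")
}

#' @method print metrics_report
#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.3f | macro F1 %.3f | macro AUROC %.3f\n",
              x$accuracy, x$macro["f1"], x$macro["auroc"]))
  print(round(x$per_class[, -1], 3))
  invisible(x)
}

#' McNemar's test for paired classifier accuracy
#'
#' Counts discordant pairs b (model 1 right, model 2 wrong) and c (the
#' reverse).  Uses the continuity-corrected chi-square
#' `(|b - c| - 1)^2 / (b + c)` with 1 df, or the exact binomial test when
#' `b + c < 25`.
#'
#' @param correct1,correct2 Logical vectors of per-subject correctness on
#'   identical subjects.
#' @param exact_below Threshold on `b + c` below which the exact test is
#'   used (default 25).
#' @return List with `statistic`, `p.value`, `b`, `c`, `method`.
#' @export
mcnemar_test <- function(correct1, correct2, exact_below = 25) {
  if (length(correct1) != length(correct2))
    stop_invalid("correct2", "length mismatch")
  b <- sum(correct1 & !correct2)
  cc <- sum(!correct1 & correct2)
  if (b + cc == 0) {
    warning("no discordant pairs; p = 1")
    return(list(statistic = NA_real_, p.value = 1, b = b, c = cc,
                method = "degenerate"))
  }
  if (b + cc < exact_below) {
    p <- stats::binom.test(b, b + cc, 0.5)$p.value
    list(statistic = NA_real_, p.value = p, b = b, c = cc,
         method = "exact binomial")
  } else {
    stat <- (abs(b - cc) - 1)^2 / (b + cc)
    list(statistic = stat,
         p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         b = b, c = cc, method = "continuity-corrected chi-square")
  }
}

#' Paired t test on per-fold metric pairs
#'
#' @param x,y Paired metric vectors (e.g. per-fold F1 of two models); or
#'   pass differences via `x` with `y = NULL`.
#' @return List with `t`, `df`, `p.value`, `mean_diff`.
#' @export
paired_t_test <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  n <- length(d)
  if (n < 2) stop_invalid("x", "need >= 2 paired values")
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    warning("zero-variance differences (exact ties)")
    p <- if (mean(d) == 0) 1 else 0
    return(list(t = if (mean(d) == 0) 0 else Inf, df = n - 1, p.value = p,
                mean_diff = mean(d)))
  }
  tstat <- mean(d) / (sd_d / sqrt(n))
  list(t = tstat, df = n - 1,
       p.value = 2 * stats::pt(-abs(tstat), df = n - 1),
       mean_diff = mean(d))
}

## ---- end-to-end harness ----

#' Train and evaluate one configuration on a cohort
#'
#' Runs the complete pipeline: preprocessing fit on training subjects,
#' model training on the staged schedule, temperature calibration on the
#' validation split, and test-set evaluation with MC-dropout uncertainty.
#'
#' @param cohort An `nf_cohort`.
#' @param config An [nf_config()].
#' @param split A [make_splits()] plan (created with `seed` if `NULL`).
#' @param schedule Stage table (default [desk_schedule()]).
#' @param seed Integer seed.
#' @param mc An [mc_config()] for test-time uncertainty (NULL to skip).
#' @param inputs Optional precomputed [build_model_inputs()] object (its
#'   preprocessing must have been fitted on this split's training subjects);
#'   used by the ablation harness to share preprocessing across
#'   configurations.
#' @return List of class `nf_fit`: `model`, `metrics`
#'   ([compute_metrics()]), `probs`, `truth`, `correct`, `uncertainty`
#'   ([mc_predict()] output or NULL), `split`, `fitstats`.
#' @export
fit_evaluate <- function(cohort, config = nf_config(), split = NULL,
                         schedule = desk_schedule(), seed = 1,
                         mc = mc_config(seed = seed), inputs = NULL) {
  if (is.null(split)) split <- make_splits(cohort, seed = seed)
  if (is.null(inputs)) {
    fitstats <- preprocess_fit(cohort, config, split$train)
    inputs <- build_model_inputs(cohort, fitstats)
  } else {
    fitstats <- attr(inputs, "fitstats")
  }
  model <- nf_model(inputs, config, seed = seed)
  model <- train_model(model, inputs, split$train, split$val, schedule,
                       seed = seed)
  vl <- nf_forward(model, inputs, split$val)$logits
  model$temperature <- tryCatch(
    fit_temperature(vl, inputs$labels[split$val]), error = function(e) 1)
  probs <- predict_subjects(model, inputs, split$test)
  truth <- inputs$labels[split$test]
  unc <- if (!is.null(mc)) mc_predict(model, inputs, split$test, mc) else NULL
  structure(list(model = model,
                 metrics = compute_metrics(probs, truth),
                 probs = probs, truth = truth,
                 correct = max.col(probs, ties.method = "first") ==
                   as.integer(truth),
                 uncertainty = unc, split = split, fitstats = fitstats),
            class = "nf_fit")
}

#' k-fold cross-validation over the non-test pool
#'
#' @param cohort An `nf_cohort`.
#' @param config An [nf_config()].
#' @param schedule Stage table.
#' @param k Folds (default 5).
#' @param seed Integer seed.
#' @return List with `per_fold` (data frame of accuracy/F1/AUROC per fold)
#'   and `summary` (mean and sd).
#' @export
cross_validate <- function(cohort, config = nf_config(),
                           schedule = desk_schedule(), k = 5, seed = 1) {
  split <- make_splits(cohort, k = k, seed = seed)
  pool <- as.integer(names(split$folds))
  rows <- list()
  for (fd in seq_len(k)) {
    hold <- pool[split$folds == fd]
    tr <- setdiff(pool, hold)
    # small validation share carved from the training side, stratified
    vs <- make_splits(factor(split$labels[tr], CLASS_LEVELS),
                      ratios = c(0.85, 0.15, 0), k = 2, seed = seed + fd)
    fitstats <- preprocess_fit(cohort, config, tr[vs$train])
    inputs <- build_model_inputs(cohort, fitstats)
    model <- nf_model(inputs, config, seed = seed + fd)
    model <- train_model(model, inputs, tr[vs$train], tr[vs$val], schedule,
                         seed = seed + fd)
    probs <- predict_subjects(model, inputs, hold)
    met <- compute_metrics(probs, inputs$labels[hold])
    rows[[fd]] <- data.frame(fold = fd, accuracy = met$accuracy,
                             f1 = met$macro["f1"],
                             auroc = met$macro["auroc"],
                             sensitivity = met$macro["sensitivity"])
  }
  per_fold <- do.call(rbind, rows)
  list(per_fold = per_fold,
       summary = rbind(mean = colMeans(per_fold[, -1]),
                       sd = apply(per_fold[, -1], 2, stats::sd)))
}

#' Ablation harness over modality subsets and attention on/off
#'
#' Trains every requested configuration on identical splits and seeds and
#' reports test metrics sorted by accuracy.  Tags are `"S"`, `"M"`, `"E"`,
#' `"M+E"`, `"M+S"`, `"S+E"`, `"S+M+E"`, optionally suffixed
#' `":no-attention"` (plain concatenation fusion).
#'
#' @param cohort An `nf_cohort`.
#' @param configurations Character vector of tags.
#' @param config Base [nf_config()].
#' @param schedule Stage table.
#' @param seed Integer seed (same splits for every configuration).
#' @return List of class `ablation_result`: `table` (one row per tag) and
#'   `fits` (named list of `nf_fit` objects).
#' @export
run_ablation <- function(cohort, configurations, config = nf_config(),
                         schedule = desk_schedule(), seed = 1) {
  if (length(configurations) == 0)
    stop_invalid("configurations", "must be non-empty")
  if (anyDuplicated(configurations))
    stop_invalid("configurations", "tags must be unique")
  mod_map <- c(S = "SNP", M = "MRI", E = "EEG")
  split <- make_splits(cohort, seed = seed)
  # preprocessing depends only on the training subjects, not the modality
  # subset or attention flag: fit once, share across configurations
  fitstats <- preprocess_fit(cohort, config, split$train)
  inputs <- build_model_inputs(cohort, fitstats)
  attr(inputs, "fitstats") <- fitstats
  if ("MRI" %in% config$modalities) {
    probe <- nf_model(inputs, config, seed = seed)
    attr(inputs, "nf_prep") <- prep_conv(probe, inputs)
  }
  fits <- list()
  rows <- list()
  for (tag in configurations) {
    parts <- strsplit(tag, ":", fixed = TRUE)[[1]]
    mods <- strsplit(parts[1], "+", fixed = TRUE)[[1]]
    if (!all(mods %in% names(mod_map)))
      stop_invalid("configurations", sprintf("unknown tag '%s'", tag))
    attn <- !(length(parts) > 1 && parts[2] == "no-attention")
    cfg <- config
    cfg$modalities <- unname(mod_map[mods])
    cfg$use_attention <- attn
    fit <- fit_evaluate(cohort, cfg, split = split, schedule = schedule,
                        seed = seed, mc = NULL, inputs = inputs)
    fits[[tag]] <- fit
    rows[[tag]] <- data.frame(tag = tag,
                              accuracy = fit$metrics$accuracy,
                              f1 = fit$metrics$macro[["f1"]],
                              auroc = fit$metrics$macro[["auroc"]])
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$accuracy), ]
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits, seed = seed),
            class = "ablation_result")
}
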