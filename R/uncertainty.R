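# Monte-Carlo-dropout predictive posterior, epistemic/aleatoric
# decomposition, calibrated softmax, and the composite objective:
#   L_final = L_CE + U_final + lambda*||W||_2^2 + alpha*|W| + D_KL + L_focal
# The MC posterior over T stochastic passes gives mu = mean(y_t) and the
# per-class population variance sigma^2 = mean((y_t - mu)^2); epistemic
# uncertainty is the class-mean of sigma^2, aleatoric uncertainty the mean
# per-pass predictive variance sum_c y_tc (1 - y_tc), and
# U_final = epistemic + aleatoric.

#' Monte-Carlo dropout configuration
#'
#' @param num_passes Stochastic forward passes at inference (default 30).
#' @param training_passes In-graph passes for the differentiable
#'   uncertainty term during training (default 5).
#' @param seed Base seed; pass `t` uses `seed + t`.
#' @return List of class `mc_config`.
#' @export
mc_config <- function(num_passes = 30, training_passes = 5, seed = 1) {
  num_passes <- check_count(num_passes, "num_passes")
  training_passes <- check_count(training_passes, "training_passes")
  structure(list(num_passes = num_passes, training_passes = training_passes,
                 seed = as.integer(seed)), class = "mc_config")
}

#' Decompose MC-dropout samples into epistemic and aleatoric uncertainty
#'
#' @param samples T x C matrix of per-pass class-probability vectors for one
#'   subject (rows sum to 1).
#' @return List of class `uncertainty_estimate`: `samples`, `mu` (mean
#'   prediction), `var_per_class` (population variance, divisor T),
#'   `epistemic` (class mean of the per-class variances), `aleatoric` (mean
#'   over passes of `sum_c y_c (1 - y_c)`), `U_final = epistemic +
#'   aleatoric`.
#' @export
decompose_uncertainty <- function(samples) {
  samples <- as.matrix(samples)
  if (any(samples < -1e-9) || any(abs(rowSums(samples) - 1) > 1e-6))
    stop_invalid("samples", "rows must be probability vectors")
  T_mc <- nrow(samples)
  mu <- colMeans(samples)
  v <- colMeans(sweep(samples, 2, mu)^2)      # population variance, divisor T
  epistemic <- mean(v)
  aleatoric <- mean(rowSums(samples * (1 - samples)))
  structure(list(samples = samples, mu = mu, var_per_class = v,
                 epistemic = epistemic, aleatoric = aleatoric,
                 U_final = epistemic + aleatoric, num_passes = T_mc),
            class = "uncertainty_estimate")
}

#' MC-dropout prediction with uncertainty
#'
#' Runs `mc$num_passes` stochastic forward passes with dropout active
#' (pass `t` seeded `mc$seed + t` for replayability) and summarizes the
#' sample set per subject.
#'
#' @param model An [nf_model()] (trained).
#' @param inputs An [build_model_inputs()] object.
#' @param idx Subject rows to predict (default all).
#' @param mc An [mc_config()].
#' @return List with `samples` (T x n x C array), `mu` (n x C), `epistemic`,
#'   `aleatoric`, `U_final` (length-n vectors), and `estimates` (per-subject
#'   [decompose_uncertainty()] objects).
#' @export
mc_predict <- function(model, inputs, idx = NULL, mc = mc_config()) {
  if (!inherits(mc, "mc_config")) stop_invalid("mc", "need an mc_config")
  if (is.null(idx)) idx <- seq_len(nrow(inputs$mask))
  n <- length(idx)
  C <- model$config$n_classes
  samples <- array(0, dim = c(mc$num_passes, n, C))
  for (t in seq_len(mc$num_passes)) {
    probs <- with_seed(mc$seed + t, {
      fw <- nf_forward(model, inputs, idx, dropout = TRUE)
      calibrated_softmax(fw$logits, model$temperature)
    })
    samples[t, , ] <- probs
  }
  ests <- lapply(seq_len(n), function(i)
    decompose_uncertainty(matrix(samples[, i, ], ncol = C)))
  list(samples = samples,
       mu = t(vapply(ests, `[[`, numeric(C), "mu")),
       epistemic = vapply(ests, `[[`, 0, "epistemic"),
       aleatoric = vapply(ests, `[[`, 0, "aleatoric"),
       U_final = vapply(ests, `[[`, 0, "U_final"),
       estimates = ests)
}

#' Temperature-calibrated softmax
#'
#' `softmax(logits / temperature)`; temperature 1 is the plain softmax and
#' large temperatures approach the uniform distribution.
#'
#' @param logits Numeric vector or n x C matrix.
#' @param temperature Positive scalar.
#' @return Probability vector/matrix (rows sum to 1).
#' @export
calibrated_softmax <- function(logits, temperature = 1) {
  if (!is.numeric(temperature) || temperature <= 0)
    stop_invalid("temperature", "must be > 0")
  vec <- !is.matrix(logits)
  Z <- if (vec) matrix(logits, nrow = 1) else logits
  out <- row_softmax(Z / temperature)
  if (vec) out[1, ] else out
}

#' Fit a calibration temperature on validation logits
#'
#' One-dimensional search for the temperature minimizing validation
#' negative log-likelihood.  The fitted NLL never exceeds the NLL at
#' temperature 1.
#'
#' @param logits n x C validation logits.
#' @param labels Factor or integer class index (1-based) per row.
#' @return Fitted temperature (scalar).
#' @export
fit_temperature <- function(logits, labels) {
  logits <- as.matrix(logits)
  yi <- if (is.factor(labels)) as.integer(labels) else as.integer(labels)
  if (length(unique(yi)) < 2)
    stop_invalid("labels", "need at least 2 classes represented")
  nll <- function(logT) {
    p <- calibrated_softmax(logits, exp(logT))
    -mean(log(pmax(p[cbind(seq_len(nrow(p)), yi)], 1e-12)))
  }
  opt <- stats::optimize(nll, interval = c(log(0.05), log(20)))
  temp <- exp(opt$minimum)
  if (nll(log(temp)) <= nll(0)) temp else 1
}

#' Cross-entropy loss
#'
#' `-sum_i y_i log(yhat_i)` with predictions clipped to `[1e-12, 1 - 1e-12]`.
#'
#' @param yhat Probability vector (or n x C matrix).
#' @param y One-hot vector (or matrix) of the same shape.
#' @return Scalar (vector input) or per-row vector (matrix input).
#' @export
cross_entropy <- function(yhat, y) {
  vec <- !is.matrix(yhat)
  P <- if (vec) matrix(yhat, nrow = 1) else yhat
  Y <- if (vec) matrix(y, nrow = 1) else y
  if (any(Y != 0 & Y != 1) || any(abs(rowSums(Y) - 1) > 1e-9))
    stop_invalid("y", "must be one-hot")
  P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
  out <- -rowSums(Y * log(P))
  if (vec) out[1] else out
}

#' Focal loss
#'
#' `-w_c (1 - yhat_c)^gamma log(yhat_c)` on the true class c.  With
#' `gamma = 0` and unit weights this equals the cross-entropy.
#'
#' @param yhat Probability vector or n x C matrix.
#' @param y One-hot vector or matrix.
#' @param gamma Focusing parameter, `>= 0`.
#' @param class_weights Length-C weights (default all 1).
#' @return Scalar or per-row vector.
#' @export
focal_loss <- function(yhat, y, gamma = 2, class_weights = NULL) {
  if (gamma < 0) stop_invalid("gamma", "must be >= 0")
  vec <- !is.matrix(yhat)
  P <- if (vec) matrix(yhat, nrow = 1) else yhat
  Y <- if (vec) matrix(y, nrow = 1) else y
  if (any(Y != 0 & Y != 1) || any(abs(rowSums(Y) - 1) > 1e-9))
    stop_invalid("y", "must be one-hot")
  C <- ncol(P)
  if (is.null(class_weights)) class_weights <- rep(1, C)
  ci <- max.col(Y, ties.method = "first")
  pc <- pmin(pmax(P[cbind(seq_len(nrow(P)), ci)], 1e-12), 1 - 1e-12)
  out <- -class_weights[ci] * (1 - pc)^gamma * log(pc)
  if (vec) out[1] else out
}

# Weight matrices included in the norm penalties (biases and LayerNorm
# parameters excluded, as in weight decay convention).
penalized_weights <- function(params) {
  nm <- names(params)
  keep <- grepl("W", nm) & !grepl("^h_gamma|^h_beta", nm)
  params[keep]
}

#' Composite training objective
#'
#' Evaluates every term of the final loss on a set of stochastic-pass
#' predictions: the cross-entropy (mean over passes and batch), the
#' uncertainty term (batch-mean `U_final` of the pass samples), the L2 and
#' L1 weight penalties, the MC-dropout variational KL surrogate (scaled
#' squared-norm of the dropout-adjacent head weights), and the focal loss.
#' Zeroing any coefficient removes exactly that term.
#'
#' @param pass_probs List of n x C probability matrices, one per stochastic
#'   pass (a single matrix is treated as one pass).
#' @param Y n x C one-hot label matrix.
#' @param weights Model parameter list (for the norm penalties); may be
#'   `NULL` for data-terms-only evaluation.
#' @param lambda_l2,alpha_l1,kl_coef,u_coef,focal_gamma,focal_coef
#'   Coefficients; all must be `>= 0`.
#' @param class_weights Length-C focal class weights.
#' @param head_dropout Dropout rate at the penalized head layer (enters the
#'   KL surrogate scale).
#' @return List of class `loss_terms`: `L_CE`, `U_term`, `l2_term`,
#'   `l1_term`, `D_KL`, `L_focal`, `L_total` (= `L_CE + U_term`), `L_final`.
#' @export
total_loss <- function(pass_probs, Y, weights = NULL,
                       lambda_l2 = 1e-5, alpha_l1 = 1e-6, kl_coef = 1e-5,
                       u_coef = 1, focal_gamma = 2, focal_coef = 1,
                       class_weights = NULL, head_dropout = 0.2) {
  for (cf in c(lambda_l2, alpha_l1, kl_coef, u_coef, focal_gamma, focal_coef))
    if (cf < 0) stop_invalid("coefficients", "must be >= 0")
  if (is.matrix(pass_probs)) pass_probs <- list(pass_probs)
  n <- nrow(Y)
  L_CE <- mean(vapply(pass_probs, function(P) mean(cross_entropy(P, Y)), 0))
  L_foc <- mean(vapply(pass_probs, function(P)
    mean(focal_loss(P, Y, focal_gamma, class_weights)), 0))
  U <- vapply(seq_len(n), function(i) {
    S <- do.call(rbind, lapply(pass_probs, function(P) P[i, ]))
    decompose_uncertainty(S)$U_final
  }, 0)
  U_term <- u_coef * mean(U)
  l2 <- l1 <- kl <- 0
  if (!is.null(weights)) {
    pw <- penalized_weights(weights)
    l2 <- lambda_l2 * sum(vapply(pw, function(w) sum(w^2), 0))
    l1 <- alpha_l1 * sum(vapply(pw, function(w) sum(abs(w)), 0))
    if (!is.null(weights$h_WF))
      kl <- kl_coef * 0.5 * (1 - head_dropout) * sum(weights$h_WF^2)
  }
  L_final <- L_CE + U_term + l2 + l1 + kl + focal_coef * L_foc
  structure(list(L_CE = L_CE, U_term = U_term, l2_term = l2, l1_term = l1,
                 D_KL = kl, L_focal = focal_coef * L_foc,
                 L_total = L_CE + U_term, L_final = L_final),
            class = "loss_terms")
}

## ---- gradients of the data terms w.r.t. logits (internal) ----

# Softmax jacobian: given dL/dprobs, return dL/dlogits.
softmax_jac <- function(probs, dprobs) {
  probs * (dprobs - rowSums(dprobs * probs))
}

# Per-pass logits gradient of (CE + focal + u_coef * U) with means over
# passes and batch.  pass_probs: list of n x C; returns list of n x C.
dloss_dlogits <- function(pass_probs, Y, u_coef, focal_gamma, focal_coef,
                          class_weights) {
  Tn <- length(pass_probs)
  n <- nrow(Y)
  C <- ncol(Y)
  mu <- Reduce(`+`, pass_probs) / Tn
  ci <- max.col(Y, ties.method = "first")
  lapply(pass_probs, function(P) {
    # CE: softmax shortcut
    d <- (P - Y) / (Tn * n)
    # focal on the true class
    pc <- pmin(pmax(P[cbind(seq_len(n), ci)], 1e-12), 1 - 1e-12)
    w <- if (is.null(class_weights)) rep(1, C) else class_weights
    dfoc_dp <- w[ci] * (focal_gamma * (1 - pc)^pmax(focal_gamma - 1, 0) *
                          log(pc) - (1 - pc)^focal_gamma / pc)
    dP <- matrix(0, n, C)
    dP[cbind(seq_len(n), ci)] <- focal_coef * dfoc_dp / (Tn * n)
    # uncertainty: epistemic (class mean) + aleatoric
    if (u_coef > 0) {
      dU <- (2 * (P - mu) / (C * Tn) + (1 - 2 * P) / Tn) * (u_coef / n)
      dP <- dP + dU
    }
    d + softmax_jac(P, dP)
  })
}
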