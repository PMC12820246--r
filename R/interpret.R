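# Gradient-based interpretation: voxel saliency for volumes, channel/band
# saliency for EEG features, and the uncertainty separation report.

normalize_saliency <- function(x) {
  m <- max(x)
  if (m > 0) x / m else x
}

#' Input-gradient saliency over a subject's volume
#'
#' Absolute gradient of the target-class logit with respect to each input
#' voxel, evaluated in deterministic evaluation mode and max-normalized to
#' \[0, 1\].  Gradients of overlapping patches are accumulated on the voxel
#' grid.
#'
#' @param model Trained [nf_model()].
#' @param inputs An [build_model_inputs()] object.
#' @param subject Row index of the subject.
#' @param target_class Class name or index (1 = AD, 2 = PD, 3 = HC).
#' @return 3-D saliency array (volume shape), attribute `target_class`.
#' @export
volume_saliency <- function(model, inputs, subject, target_class) {
  if (is.character(target_class))
    target_class <- match(target_class, CLASS_LEVELS)
  if (is.na(target_class) || target_class < 1 ||
      target_class > model$config$n_classes)
    stop_invalid("target_class", "out of range")
  fw <- nf_forward(model, inputs, subject)
  dlogits <- matrix(0, 1, model$config$n_classes)
  dlogits[1, target_class] <- 1
  bw <- nf_backward(model, inputs, fw$cache, dlogits, input_grads = TRUE)
  g <- bw$input_grads$mri            # 1 x patches x voxels
  shp <- inputs$geometry$volume_shape
  patch <- inputs$geometry$patch
  starts <- inputs$geometry$patch_starts
  sal <- array(0, dim = shp)
  for (k in seq_len(dim(g)[2])) {
    s <- starts[k, ]
    sl <- list(s[1]:(s[1] + patch[1] - 1), s[2]:(s[2] + patch[2] - 1),
               s[3]:(s[3] + patch[3] - 1))
    sal[sl[[1]], sl[[2]], sl[[3]]] <- sal[sl[[1]], sl[[2]], sl[[3]]] +
      array(g[1, k, ], dim = patch)
  }
  sal <- normalize_saliency(abs(sal))
  attr(sal, "target_class") <- CLASS_LEVELS[target_class]
  sal
}

#' Channel-by-band saliency over EEG features
#'
#' Absolute input gradient of the target-class logit with respect to the
#' band-power features, reshaped to a 4 x channels (band x channel) grid and
#' max-normalized.
#'
#' @inheritParams volume_saliency
#' @return 4 x channels matrix (rows delta, theta, alpha, beta), attribute
#'   `target_class`.
#' @export
eeg_saliency <- function(model, inputs, subject, target_class) {
  if (is.character(target_class))
    target_class <- match(target_class, CLASS_LEVELS)
  if (is.na(target_class) || target_class < 1 ||
      target_class > model$config$n_classes)
    stop_invalid("target_class", "out of range")
  fw <- nf_forward(model, inputs, subject)
  dlogits <- matrix(0, 1, model$config$n_classes)
  dlogits[1, target_class] <- 1
  bw <- nf_backward(model, inputs, fw$cache, dlogits, input_grads = TRUE)
  g <- abs(as.vector(bw$input_grads$eeg))
  if (!is.null(inputs$geometry$eeg_T)) {
    # raw-signal path: channel x time saliency
    sal <- matrix(g, nrow = inputs$geometry$eeg_channels)
    rownames(sal) <- sprintf("ch%02d", seq_len(nrow(sal)))
    sal <- normalize_saliency(sal)
    attr(sal, "target_class") <- CLASS_LEVELS[target_class]
    return(sal)
  }
  sal <- matrix(g, nrow = 4)          # band-fastest layout
  rownames(sal) <- names(band_edges())
  colnames(sal) <- sprintf("ch%02d", seq_len(ncol(sal)))
  sal <- normalize_saliency(sal)
  attr(sal, "target_class") <- CLASS_LEVELS[target_class]
  sal
}

#' Uncertainty separation report: correct vs incorrect predictions
#'
#' Summarizes epistemic, aleatoric and total uncertainty by correctness
#' group and tests whether misclassified subjects carry higher total
#' uncertainty (one-sided Mann-Whitney / Wilcoxon rank-sum).
#'
#' @param U_final,epistemic,aleatoric Per-subject uncertainty vectors (e.g.
#'   from [mc_predict()]).
#' @param correct Logical vector of per-subject correctness.
#' @return List of class `uncertainty_report`: `summary` (per-group
#'   mean/median/IQR for each component), `p_value` (one-sided, incorrect >
#'   correct; `NA` with `test_skipped = TRUE` if a group is empty).
#' @export
uncertainty_report <- function(U_final, epistemic = NULL, aleatoric = NULL,
                               correct) {
  grp <- factor(ifelse(correct, "correct", "incorrect"),
                levels = c("correct", "incorrect"))
  comp <- list(U_final = U_final)
  if (!is.null(epistemic)) comp$epistemic <- epistemic
  if (!is.null(aleatoric)) comp$aleatoric <- aleatoric
  rows <- list()
  for (nm in names(comp)) {
    for (g in levels(grp)) {
      v <- comp[[nm]][grp == g]
      rows[[paste(nm, g)]] <- data.frame(
        component = nm, group = g, n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        median = if (length(v)) stats::median(v) else NA_real_,
        iqr = if (length(v)) stats::IQR(v) else NA_real_)
    }
  }
  skipped <- any(table(grp) == 0)
  p <- NA_real_
  if (!skipped) {
    p <- stats::wilcox.test(U_final[grp == "incorrect"],
                            U_final[grp == "correct"],
                            alternative = "greater", exact = FALSE)$p.value
  }
  structure(list(summary = do.call(rbind, rows), p_value = p,
                 test_skipped = skipped),
            class = "uncertainty_report")
}

#' @method print uncertainty_report
#' @export
print.uncertainty_report <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  if (x$test_skipped) cat("rank-sum test skipped (empty group)\n")
  else cat(sprintf("one-sided Mann-Whitney p (incorrect > correct): %.4g\n",
                   x$p_value))
  invisible(x)
}
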