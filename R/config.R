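# Experiment configuration: architecture, preprocessing, fusion,
# uncertainty, and training-schedule settings in one validated list.

#' Experiment configuration
#'
#' Collects every tunable of the pipeline.  Defaults are the desk-scale
#' study conditions; `full_schedule()` exposes the 10-stage progressive
#' tuning table used at full scale.
#'
#' @param fusion_dim Shared fused-vector length per modality.
#' @param d_k Attention key/query dimension.
#' @param embed_m SNP dense-embedding width (split into tokens).
#' @param token_width Width of each SNP embedding token fed to the BiLSTM;
#'   must divide `embed_m`.
#' @param lstm_units Hidden units per BiLSTM direction (128 at full scale).
#' @param conv3d_filters Integer vector of 3-D conv filters per block.
#' @param conv3d_kernel Cubic kernel edge for the volume branch.
#' @param conv1d_filters Filters for the EEG branch.
#' @param conv1d_kernel Kernel length for the EEG branch.
#' @param pool Max-pool window between 3-D conv blocks.
#' @param head_width Dense width of the fusion head (256 at full scale).
#' @param head_dropout,conv_dropout Dropout rates at the head and after conv
#'   blocks.
#' @param modality_dropout Probability of dropping one present modality per
#'   subject per training batch (robustness to partial data).
#' @param use_attention If `FALSE`, the attention block is replaced by plain
#'   concatenation of pooled encoder outputs (ablation configuration).
#' @param modalities Character subset of `c("SNP", "MRI", "EEG")` to use.
#' @param eeg_input `"psd"` (band-power features, the default) or `"raw"`
#'   (bandpassed signal windows).
#' @param patch,patch_stride Patch shape and stride for volumes (`NULL`
#'   patch = whole volume as a single patch).
#' @param bandpass `c(low, high)` EEG filter edges in Hz.
#' @param pca_variance,pca_cap PCA explained-variance target and component
#'   cap for the one-hot SNP matrix.
#' @param clip_sd Z-score clipping threshold for tabular features.
#' @param lambda_l2,alpha_l1,kl_coef,u_coef,focal_gamma,focal_coef Loss
#'   coefficients: L2 (weight decay), L1, KL surrogate, uncertainty term,
#'   focal focusing parameter and weight.
#' @param mc_passes Monte-Carlo dropout passes at inference (30, matching
#'   the evaluation protocol).
#' @param train_passes In-graph stochastic passes per training step used for
#'   the differentiable uncertainty term.
#' @param grad_clip Global gradient-norm ceiling.
#' @param weight_decay Adam weight decay (applied through `lambda_l2`).
#' @param patience,min_delta Early-stopping patience (epochs) and minimum
#'   validation-loss improvement.
#' @param n_classes Number of classes (3: AD, PD, HC).
#' @return A list of class `nf_config`.
#' @export
nf_config <- function(fusion_dim = 16,
                      d_k = 64,
                      embed_m = 32,
                      token_width = 8,
                      lstm_units = 8,
                      conv3d_filters = c(4, 8),
                      conv3d_kernel = 3,
                      conv1d_filters = 8,
                      conv1d_kernel = 3,
                      pool = 2,
                      head_width = 32,
                      head_dropout = 0.2,
                      conv_dropout = 0.2,
                      modality_dropout = 0.1,
                      use_attention = TRUE,
                      modalities = c("SNP", "MRI", "EEG"),
                      eeg_input = c("psd", "raw"),
                      patch = NULL,
                      patch_stride = NULL,
                      bandpass = c(0.5, 40),
                      pca_variance = 0.95,
                      pca_cap = 200,
                      clip_sd = 3,
                      lambda_l2 = 1e-5,
                      alpha_l1 = 1e-6,
                      kl_coef = 1e-5,
                      u_coef = 1,
                      focal_gamma = 2,
                      focal_coef = 1,
                      mc_passes = 30,
                      train_passes = 2,
                      grad_clip = 1.0,
                      weight_decay = 1e-5,
                      patience = 5,
                      min_delta = 1e-4,
                      n_classes = 3) {
  if (embed_m %% token_width != 0)
    stop_invalid("token_width", "must divide embed_m")
  modalities <- match.arg(modalities, c("SNP", "MRI", "EEG"),
                          several.ok = TRUE)
  eeg_input <- match.arg(eeg_input)
  if (head_dropout < 0 || head_dropout >= 1)
    stop_invalid("head_dropout", "must be in [0, 1)")
  cfg <- as.list(environment())
  structure(cfg, class = "nf_config")
}

#' The full-scale 10-stage progressive tuning schedule
#'
#' Learning rate decays 0.001 to 0.00001, batch size drops 32 to 16, CNN
#' dropout 0.5 to 0.2, epochs grow 10 to 50, kernels widen 3 to 5 and
#' filters 64 to 256 across stages.
#'
#' @return Data frame with one row per stage (columns `stage`, `lr`,
#'   `batch_size`, `epochs`, `dropout`, `kernel`, `filters`, `lstm_units`,
#'   `fc_units`).
#' @export
full_schedule <- function() {
  data.frame(
    stage = 1:10,
    lr = c(0.001, 0.001, 0.0005, 0.0005, 0.0005, 0.0001, 0.0001, 0.0001,
           0.00001, 0.00001),
    batch_size = c(32, 32, 32, 16, 16, 16, 16, 16, 16, 16),
    epochs = c(10, 20, 30, 40, 50, 50, 50, 50, 50, 50),
    dropout = c(0.5, 0.4, 0.4, 0.3, 0.3, 0.2, 0.2, 0.2, 0.2, 0.2),
    kernel = c(3, 3, 3, 5, 5, 5, 5, 5, 5, 5),
    filters = c(64, 64, 128, 128, 128, 128, 128, 256, 256, 256),
    lstm_units = c(128, 128, 128, 128, 256, 256, 256, 256, 256, 256),
    fc_units = rep(256, 10))
}

#' Desk-scale 3-stage compression of the tuning schedule
#'
#' @param epochs Integer vector of epochs per stage.
#' @param batch_size Batch size used throughout.
#' @return Data frame with columns `stage`, `lr`, `batch_size`, `epochs`,
#'   `dropout`.
#' @export
desk_schedule <- function(epochs = c(10, 8, 4), batch_size = 32) {
  data.frame(stage = seq_along(epochs),
             lr = c(1e-3, 1e-4, 1e-5)[seq_along(epochs)],
             batch_size = batch_size,
             epochs = epochs,
             dropout = c(0.3, 0.2, 0.2)[seq_along(epochs)])
}

#' Print all configuration defaults
#'
#' @param config An [nf_config()] (default: the package defaults).
#' @return The config, invisibly.
#' @export
show_config <- function(config = nf_config()) {
  for (nm in names(config)) {
    v <- config[[nm]]
    cat(sprintf("%-18s %s\n", nm,
                if (is.null(v)) "NULL" else paste(format(v), collapse = ", ")))
  }
  invisible(config)
}
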