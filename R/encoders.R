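# Public modality-encoder operations.  These expose the three branches as
# standalone functions over explicit parameter lists; nf_model() composes
# the same primitives with backprop for training.

#' Linear SNP embedding
#'
#' `Z_S = W_S S' + b_S` with `W_S` an m x p matrix; exactly affine in the
#' scaled SNP input.
#'
#' @param S_scaled Length-p vector or n x p matrix of scaled SNP features.
#' @param params List with `W_S` (m x p) and `b_S` (length m).
#' @return Length-m vector or n x m matrix of embeddings.
#' @export
embed_snp <- function(S_scaled, params) {
  W <- params$W_S; b <- params$b_S
  vec <- !is.matrix(S_scaled)
  S <- if (vec) matrix(S_scaled, nrow = 1) else S_scaled
  if (ncol(S) != ncol(W))
    stop(sprintf("SNP feature length %d does not match expected p = %d",
                 ncol(S), ncol(W)), call. = FALSE)
  Z <- S %*% t(W) + rep(b, each = nrow(S))
  if (vec) Z[1, ] else Z
}

#' Initialize BiLSTM parameters for the SNP sequence encoder
#'
#' @param token_width Input width per token.
#' @param hidden_units Hidden units per direction.
#' @param seed Integer seed.
#' @param shared If `TRUE` both directions share one weight set (useful for
#'   symmetry checks).
#' @return List with forward/backward LSTM weights.
#' @export
snp_sequence_params <- function(token_width, hidden_units, seed = 1,
                                shared = FALSE) {
  with_seed(seed, {
    f <- lstm_init(token_width, hidden_units)
    b <- if (shared) f else lstm_init(token_width, hidden_units)
    list(Wf = f$W, bf = f$b, Wb = b$W, bb = b$b,
         hidden_units = hidden_units, token_width = token_width)
  })
}

#' Bidirectional LSTM over SNP embedding tokens
#'
#' The flat embedding is chunked into tokens of `params$token_width`
#' columns; a forward and a backward LSTM pass produce a sequence-aware
#' output of `2 * hidden_units` per token (forward || backward).
#'
#' @param Z_S Length-m embedding vector or n x m matrix; `m` must be a
#'   multiple of the token width.
#' @param params A [snp_sequence_params()] list.
#' @return Array n x tokens x (2 * hidden_units) (drops to a matrix for a
#'   single subject).
#' @export
encode_snp_sequence <- function(Z_S, params) {
  vec <- !is.matrix(Z_S)
  Z <- if (vec) matrix(Z_S, nrow = 1) else Z_S
  tw <- params$token_width
  if (ncol(Z) %% tw != 0)
    stop_invalid("Z_S", "embedding length must be a multiple of token_width")
  ts <- ncol(Z) %/% tw
  if (ts < 1) stop_invalid("Z_S", "empty token sequence")
  X <- aperm(array(Z, dim = c(nrow(Z), tw, ts)), c(1, 3, 2))
  H <- bilstm_fwd(X, params$Wf, params$bf, params$Wb, params$bb)$out
  if (vec) matrix(H[1, , ], ncol = 2 * params$hidden_units) else H
}

#' Initialize the volumetric (3-D CNN) encoder
#'
#' Two convolution blocks (cubic kernels, max pooling between them), global
#' mean pooling per patch, and a dense projection to the fusion dimension.
#'
#' @param patch Integer 3-vector patch shape.
#' @param filters Length-2 integer vector of filters per block.
#' @param kernel Cubic kernel edge.
#' @param pool Pooling window.
#' @param fusion_dim Output token dimension.
#' @param seed Integer seed.
#' @return Parameter/geometry list for [encode_volume()].
#' @export
volume_encoder_params <- function(patch, filters = c(4, 8), kernel = 3,
                                  pool = 2, fusion_dim = 16, seed = 1) {
  g1 <- conv_geom(patch, 1, kernel)
  pg1 <- pool_geom(g1$out_shape, filters[1], pool)
  g2 <- conv_geom(pg1$out_shape, filters[1], kernel)
  with_seed(seed, list(
    W1 = he_init(g1$cols, filters[1]), b1 = rep(0, filters[1]),
    W2 = he_init(g2$cols, filters[2]), b2 = rep(0, filters[2]),
    Wtok = xavier_init(filters[2], fusion_dim), btok = rep(0, fusion_dim),
    g1 = g1, pg1 = pg1, g2 = g2, filters = filters, patch = patch))
}

#' Volumetric encoder: patches to feature tokens
#'
#' @param x A [extract_patches()] grid, a k x ph x pw x pd patch array, or a
#'   single 3-D volume (treated as one patch; must match the configured
#'   patch shape).  Values are expected in \[0, 1\].
#' @param params A [volume_encoder_params()] list.
#' @return List with `tokens` (patches x fusion_dim matrix `F_M`) and
#'   `flat` (concatenated flattened vector `F_M'`).
#' @export
encode_volume <- function(x, params) {
  if (inherits(x, "patch_grid")) x <- x$patches
  if (length(dim(x)) == 3) x <- array(x, dim = c(1, dim(x)))
  if (!all(dim(x)[-1] == params$patch))
    stop(sprintf("patch shape (%s) does not match encoder (%s)",
                 paste(dim(x)[-1], collapse = "x"),
                 paste(params$patch, collapse = "x")), call. = FALSE)
  k <- dim(x)[1]
  X <- matrix(x, k)
  c1 <- conv_fwd(X, params$W1, params$b1, params$g1)
  r1 <- relu_fwd(c1$out)
  p1 <- pool_fwd(r1$out, params$pg1)
  c2 <- conv_fwd(p1$out, params$W2, params$b2, params$g2)
  r2 <- relu_fwd(c2$out)
  f2 <- params$filters[2]
  npos <- params$g2$n_pos
  gmp <- matrix(0, k, f2)
  for (p in seq_len(npos))
    gmp <- gmp + r2$out[, (p - 1) * f2 + seq_len(f2), drop = FALSE]
  gmp <- gmp / npos
  tokens <- gmp %*% params$Wtok + rep(params$btok, each = k)
  list(tokens = tokens, flat = as.vector(t(tokens)))
}

#' Initialize the EEG (1-D CNN) encoder
#'
#' @param channels Number of EEG channels (sequence positions; the four
#'   band powers are the input channels).
#' @param filters Number of filters.
#' @param kernel Kernel length.
#' @param fusion_dim Output token dimension.
#' @param seed Integer seed.
#' @return Parameter/geometry list for [encode_timeseries()].
#' @export
eeg_encoder_params <- function(channels, filters = 8, kernel = 3,
                               fusion_dim = 16, seed = 1) {
  ge <- conv_geom(channels, 4, kernel)
  with_seed(seed, list(
    W1 = he_init(ge$cols, filters), b1 = rep(0, filters),
    Wtok = xavier_init(filters, fusion_dim), btok = rep(0, fusion_dim),
    ge = ge, filters = filters, channels = channels))
}

#' EEG encoder: band-power features to feature tokens
#'
#' @param feats Length-4c vector or n x 4c matrix of band-power features
#'   (band-fastest per channel, as produced by [band_psd_features()]).
#' @param params An [eeg_encoder_params()] list.
#' @return For one subject: list with `tokens` ((channels - kernel + 1) x
#'   fusion_dim, `F_E`) and `flat` (`F_E'`); for a matrix input, a list of
#'   token arrays.
#' @export
encode_timeseries <- function(feats, params) {
  vec <- !is.matrix(feats)
  X <- if (vec) matrix(feats, nrow = 1) else feats
  ce <- conv_fwd(X, params$W1, params$b1, params$ge)
  re <- relu_fwd(ce$out)
  n <- nrow(X)
  tE <- params$ge$n_pos
  f <- params$filters
  toks <- lapply(seq_len(n), function(i) {
    m <- t(matrix(re$out[i, ], f, tE))
    m %*% params$Wtok + rep(params$btok, each = tE)
  })
  if (vec) list(tokens = toks[[1]], flat = as.vector(t(toks[[1]])))
  else toks
}

#' Realized architecture description
#'
#' Prints the layer stack and parameter count of a model.
#'
#' @param model An [nf_model()].
#' @return Parameter count, invisibly.
#' @export
describe_model <- function(model) {
  cfg <- model$config
  np <- sum(vapply(model$params, length, 0L))
  cat("neurofuse model\n")
  cat(sprintf("  modalities: %s | attention: %s\n",
              paste(cfg$modalities, collapse = "+"), cfg$use_attention))
  if ("SNP" %in% cfg$modalities)
    cat(sprintf("  SNP: dense %d->%d, %d tokens of %d, BiLSTM %d units -> %d\n",
                nrow(model$params$s_Wemb), cfg$embed_m,
                cfg$embed_m %/% cfg$token_width, cfg$token_width,
                cfg$lstm_units, cfg$fusion_dim))
  if ("MRI" %in% cfg$modalities)
    cat(sprintf("  MRI: conv3d %d @%d^3 -> pool %d -> conv3d %d @%d^3 -> GAP -> %d (patches: %d)\n",
                cfg$conv3d_filters[1], cfg$conv3d_kernel, cfg$pool,
                cfg$conv3d_filters[2], cfg$conv3d_kernel, cfg$fusion_dim,
                model$geoms$mri$n_patch))
  if ("EEG" %in% cfg$modalities)
    cat(sprintf("  EEG: conv1d %d @%d over %d channels x 4 bands -> %d\n",
                cfg$conv1d_filters, cfg$conv1d_kernel,
                model$geoms$eeg$channels, cfg$fusion_dim))
  cat(sprintf("  head: dense %d -> %d, LayerNorm -> GLU -> residual -> %d classes\n",
              3 * cfg$fusion_dim, cfg$head_width, cfg$n_classes))
  cat(sprintf("  parameters: %d\n", np))
  invisible(np)
}
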