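# Attention fusion: per-modality self-attention, directed cross-modality
# attention (SNP->MRI, SNP->EEG, MRI->EEG), pooled fusion sums, and the
# dense + dropout + LayerNorm/GLU/residual head.
#
# Attention is single-head scaled dot-product: A = softmax(Q K' / sqrt(d_k)),
# O = A V.  Attended outputs are mean-pooled over their token axis and
# linearly projected to the shared fusion dimension before the per-modality
# sums, which is the only reading under which the sums are well-typed when
# the token counts differ across modalities.

#' Create attention projection parameters
#'
#' @param dim Token feature dimension.
#' @param d_k Key/query dimension (default 64).
#' @param seed Integer seed for initialization.
#' @return List with `Wq`, `Wk` (`dim x d_k`), `Wv` (`dim x dim`), `d_k`.
#' @export
attention_params <- function(dim, d_k = 64, seed = 1) {
  if (d_k < 1) stop_invalid("d_k", "must be >= 1")
  with_seed(seed, list(Wq = xavier_init(dim, d_k),
                       Wk = xavier_init(dim, d_k),
                       Wv = xavier_init(dim, dim),
                       d_k = d_k))
}

# Core scaled dot-product attention on already-projected matrices.
attn_core <- function(Q, K, V, d_k) {
  if (ncol(Q) != ncol(K)) stop("d_k mismatch between Q and K", call. = FALSE)
  if (nrow(K) == 0) stop_invalid("keys", "empty key set (undefined softmax)")
  A <- row_softmax(Q %*% t(K) / sqrt(d_k))
  list(A = A, O = A %*% V)
}

#' Single-modality self-attention
#'
#' Computes `Q = X Wq`, `K = X Wk`, `V = X Wv`, attention weights
#' `A = softmax(Q K' / sqrt(d_k))` and output `O = A V` over one modality's
#' token set.
#'
#' @param tokens t x dim matrix of tokens.
#' @param params An [attention_params()] list.
#' @return List with `A` (t x t, rows sum to 1) and `O` (t x dim).
#' @export
self_attention <- function(tokens, params) {
  tokens <- as.matrix(tokens)
  if (nrow(tokens) < 1) stop_invalid("tokens", "need at least one token")
  Q <- tokens %*% params$Wq
  K <- tokens %*% params$Wk
  V <- tokens %*% params$Wv
  attn_core(Q, K, V, params$d_k)
}

#' Cross-modality attention
#'
#' Queries come from modality X and keys/values from modality Y:
#' `C_XY = softmax(Q_X K_Y' / sqrt(d_k)) V_Y`.  Output row count equals the
#' query token count; each output row is a convex combination of the value
#' rows.
#'
#' @param query_tokens t_q x dim matrix (modality X).
#' @param key_value_tokens t_k x dim matrix (modality Y).
#' @param params List with `Wq` (query side), `Wk`, `Wv` (key/value side),
#'   and `d_k`.
#' @return List with `A` (t_q x t_k) and `C` (t_q x dim).
#' @export
cross_attention <- function(query_tokens, key_value_tokens, params) {
  query_tokens <- as.matrix(query_tokens)
  key_value_tokens <- as.matrix(key_value_tokens)
  if (nrow(key_value_tokens) == 0)
    stop_invalid("key_value_tokens", "empty key set (undefined softmax)")
  Q <- query_tokens %*% params$Wq
  K <- key_value_tokens %*% params$Wk
  V <- key_value_tokens %*% params$Wv
  r <- attn_core(Q, K, V, params$d_k)
  list(A = r$A, C = r$O)
}

#' Combine self- and cross-attended outputs per modality
#'
#' Computes the pooled fusion sums `F_S = O_S + C_SM + C_SE`,
#' `F_M = O_M + C_SM + C_ME`, `F_E = O_E + C_SE + C_ME`.  Terms involving a
#' masked-out modality contribute zero (equivalently, are dropped from the
#' sum); a modality that is itself absent yields a zero vector.
#'
#' @param O_S,O_M,O_E Pooled self-attended outputs (length-d vectors or
#'   n x d matrices).
#' @param C_SM,C_SE,C_ME Pooled cross-attended outputs, same shape.
#' @param mask Logical 3-vector (SNP, MRI, EEG) or n x 3 matrix.
#' @return List with `F_S`, `F_M`, `F_E`.
#' @export
fuse_modalities <- function(O_S, O_M, O_E, C_SM, C_SE, C_ME,
                            mask = c(SNP = TRUE, MRI = TRUE, EEG = TRUE)) {
  vecs <- list(O_S = O_S, O_M = O_M, O_E = O_E,
               C_SM = C_SM, C_SE = C_SE, C_ME = C_ME)
  vecs <- lapply(vecs, function(v) if (is.matrix(v)) v else matrix(v, nrow = 1))
  n <- nrow(vecs$O_S)
  if (!is.matrix(mask)) mask <- matrix(mask, n, 3, byrow = TRUE)
  s <- mask[, 1]; m <- mask[, 2]; e <- mask[, 3]
  fuse1 <- function(self, self_on, t1, t1_on, t2, t2_on) {
    (vecs[[self]] * self_on + vecs[[t1]] * t1_on + vecs[[t2]] * t2_on) *
      as.numeric(self_on)
  }
  list(F_S = fuse1("O_S", s, "C_SM", s & m, "C_SE", s & e),
       F_M = fuse1("O_M", m, "C_SM", s & m, "C_ME", m & e),
       F_E = fuse1("O_E", e, "C_SE", s & e, "C_ME", m & e))
}

#' Create fusion-head parameters
#'
#' @param fusion_dim Shared per-modality fused vector length.
#' @param width Dense layer width (256 at full scale).
#' @param n_classes Number of output classes (default 3).
#' @param seed Integer seed.
#' @return Named list of head weights: `W_F`, `b_F` (dense on the
#'   concatenation), `gamma`, `beta` (LayerNorm), `W_g`, `b_g` (GLU),
#'   `W_out`, `b_out` (class logits).
#' @export
fusion_head_params <- function(fusion_dim, width = 256, n_classes = 3,
                               seed = 1) {
  with_seed(seed, list(
    W_F = he_init(3 * fusion_dim, width), b_F = rep(0, width),
    gamma = rep(1, width), beta = rep(0, width),
    W_g = xavier_init(width, 2 * width), b_g = rep(0, 2 * width),
    W_out = xavier_init(width, n_classes), b_out = rep(0, n_classes)))
}

#' Fusion head: concatenation, dense projection, dropout, refinement, logits
#'
#' `F_concat = [F_S || F_M || F_E]`, `Z = W_F' F_concat + b_F`,
#' `Z_drop = Dropout(Z)` (active only when `training = TRUE`), then the
#' refinement block LayerNorm -> GLU -> residual add, and a final dense map
#' to class logits.
#'
#' @param F_S,F_M,F_E Fused per-modality vectors (length-d or n x d).
#' @param head_params A [fusion_head_params()] list.
#' @param dropout_rate Dropout probability in \[0, 1).
#' @param training Whether dropout is sampled (training / MC mode).
#' @return List with `logits` (n x n_classes), `Z`, `Z_drop`, and
#'   `refined`.
#' @export
fusion_head <- function(F_S, F_M, F_E, head_params, dropout_rate = 0,
                        training = FALSE) {
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop_invalid("dropout_rate", "must be in [0, 1)")
  as_mat <- function(v) if (is.matrix(v)) v else matrix(v, nrow = 1)
  Fc <- cbind(as_mat(F_S), as_mat(F_M), as_mat(F_E))
  d <- dense_fwd(Fc, head_params$W_F, head_params$b_F)
  dr <- dropout_fwd(d$out, dropout_rate, training)
  ln <- layernorm_fwd(dr$out, head_params$gamma, head_params$beta)
  gl <- glu_fwd(ln$out, head_params$W_g, head_params$b_g)
  refined <- dr$out + gl$out
  lo <- dense_fwd(refined, head_params$W_out, head_params$b_out)
  list(logits = lo$out, Z = d$out, Z_drop = dr$out, refined = refined)
}
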