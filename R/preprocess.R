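# Per-modality preprocessing: column min-max scaling, z-score outlier
# clipping, genotype imputation + one-hot encoding + PCA, EEG bandpass
# filtering and Welch band-power features, volume normalization, simplified
# polynomial bias-field correction, and patch extraction.
#
# Every fit-then-apply transform returns its fitted statistics so held-out
# subjects are transformed with training-set parameters only (leakage guard).

#' Column-wise min-max scaling to \[0, 1\]
#'
#' Each column's minimum maps to 0 and maximum to 1.  Constant columns map
#' to all zeros (the 0/0 case is defined as 0 to keep the \[0, 1\] contract).
#'
#' @param X Numeric matrix (subjects x features) with no missing values.
#' @param params Optional fitted parameters (from a previous call) to apply
#'   instead of refitting; scaled values are then clamped to \[0, 1\].
#' @return Scaled matrix with attribute `"minmax_params"` (list of `min`,
#'   `range` per column).
#' @export
minmax_scale_columns <- function(X, params = NULL) {
  X <- as.matrix(X)
  if (anyNA(X))
    stop("X contains missing values; impute before scaling", call. = FALSE)
  if (is.null(params)) {
    mins <- apply(X, 2, min)
    rng <- apply(X, 2, max) - mins
    params <- list(min = mins, range = rng)
  }
  rng <- ifelse(params$range == 0, 1, params$range)
  out <- sweep(sweep(X, 2, params$min), 2, rng, "/")
  out[, params$range == 0] <- 0
  out <- pmin(pmax(out, 0), 1)
  attr(out, "minmax_params") <- params
  out
}

#' Clip column outliers at mean +/- threshold * SD
#'
#' Values beyond the per-column boundaries are replaced by the boundary;
#' zero-variance columns are returned unchanged.
#'
#' @param X Numeric matrix.
#' @param threshold Positive number of standard deviations (default 3).
#' @param params Optional fitted boundaries to apply.
#' @return Clipped matrix with attribute `"clip_params"`.
#' @export
clip_outliers_zscore <- function(X, threshold = 3, params = NULL) {
  if (threshold <= 0) stop_invalid("threshold", "must be > 0")
  X <- as.matrix(X)
  if (is.null(params)) {
    mu <- colMeans(X)
    sd_ <- apply(X, 2, stats::sd)
    lo <- ifelse(sd_ == 0 | !is.finite(threshold), -Inf, mu - threshold * sd_)
    hi <- ifelse(sd_ == 0 | !is.finite(threshold), Inf, mu + threshold * sd_)
    params <- list(lo = lo, hi = hi)
  }
  out <- pmin(pmax(X, rep(params$lo, each = nrow(X))),
              rep(params$hi, each = nrow(X)))
  attr(out, "clip_params") <- params
  out
}

#' Impute missing genotypes by per-locus mode
#'
#' @param G Subjects x SNP matrix of 0/1/2 counts with possible `NA`s.
#' @param params Optional fitted per-locus modes to apply.
#' @return Completed integer matrix with attribute `"impute_params"`.
#' @export
impute_genotypes_mode <- function(G, params = NULL) {
  G <- as.matrix(G)
  if (is.null(params)) {
    modes <- apply(G, 2, function(g) {
      g <- g[!is.na(g)]
      if (!length(g)) return(0L)
      tab <- tabulate(g + 1L, 3L)
      as.integer(which.max(tab) - 1L)   # ties -> smaller count
    })
    params <- list(mode = modes)
  }
  idx <- which(is.na(G), arr.ind = TRUE)
  if (nrow(idx)) G[idx] <- params$mode[idx[, 2]]
  storage.mode(G) <- "integer"
  attr(G, "impute_params") <- params
  G
}

#' One-hot encode genotype counts
#'
#' Each locus expands to three columns in fixed order AA, AG, GG (counts
#' 0, 1, 2 of the minor/ALT allele).
#'
#' @param G Subjects x p matrix with entries in `{0, 1, 2}` (impute first).
#' @return n x 3p binary matrix; each row sums to p.
#' @export
one_hot_genotypes <- function(G) {
  G <- as.matrix(G)
  bad <- which(!(G %in% c(0, 1, 2)), arr.ind = FALSE)
  if (length(bad)) {
    loc <- arrayInd(bad[1], dim(G))
    stop(sprintf("genotype out of range {0,1,2} at subject %d, locus %d",
                 loc[1], loc[2]), call. = FALSE)
  }
  n <- nrow(G); p <- ncol(G)
  out <- matrix(0L, n, 3L * p)
  for (a in 0:2)
    out[, seq(a + 1L, by = 3L, length.out = p)][G == a] <- 1L
  cn <- colnames(G) %||% sprintf("snp%d", seq_len(p))
  colnames(out) <- paste0(rep(cn, each = 3), "_", c("AA", "AG", "GG"))
  out
}

#' PCA dimensionality reduction by explained-variance target
#'
#' Keeps the smallest number of components whose cumulative explained
#' variance reaches `variance_target`, then applies `max_components` as a
#' hard cap.
#'
#' @param X Numeric matrix (subjects x features), no missing values.
#' @param variance_target Fraction of total variance to retain, in (0, 1\].
#' @param max_components Hard cap on retained components (default 200).
#' @return List with `scores` (n x k), `loadings` (features x k,
#'   orthonormal), `explained` (per-component variance fractions), `center`,
#'   and `k`.
#' @export
pca_reduce <- function(X, variance_target = 0.95, max_components = 200) {
  if (variance_target <= 0 || variance_target > 1)
    stop_invalid("variance_target", "must be in (0, 1]")
  X <- as.matrix(X)
  if (nrow(X) < 2) stop_invalid("X", "need at least 2 rows")
  if (!all(is.finite(X))) stop_invalid("X", "must be finite")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  frac <- ev / sum(ev)
  k <- which(cumsum(frac) >= variance_target - 1e-12)[1]
  if (is.na(k)) k <- length(frac)
  k <- min(k, max_components, ncol(pc$rotation))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       explained = frac[seq_len(k)],
       center = pc$center,
       k = k)
}

#' Project new data onto fitted principal components
#'
#' @param X New data matrix with the same feature columns used in
#'   [pca_reduce()].
#' @param fit The list returned by [pca_reduce()].
#' @return n x k score matrix.
#' @export
pca_apply <- function(X, fit) {
  sweep(as.matrix(X), 2, fit$center) %*% fit$loadings
}

#' Zero-phase Butterworth bandpass filter
#'
#' Order-4 Butterworth applied forward-backward (`signal::filtfilt`) so the
#' passband is phase-neutral.
#'
#' @param E T x c matrix (one recording) or n x T x c array.
#' @param low,high Passband edges in Hz; `0 < low < high < sample_rate / 2`.
#' @param sample_rate Sampling rate in Hz.
#' @param order Filter order (default 4).
#' @return Filtered object of the same shape.
#' @export
bandpass_filter <- function(E, low = 0.5, high = 40, sample_rate, order = 4) {
  if (low <= 0 || high <= low) stop_invalid("low/high", "need 0 < low < high")
  if (high >= sample_rate / 2)
    stop_invalid("high", "must be below the Nyquist frequency")
  bf <- signal::butter(order, c(low, high) / (sample_rate / 2), type = "pass")
  filt1 <- function(x) signal::filtfilt(bf, x)
  if (is.matrix(E)) {
    apply(E, 2, filt1)
  } else if (length(dim(E)) == 3) {
    out <- E
    for (i in seq_len(dim(E)[1])) out[i, , ] <- apply(E[i, , ], 2, filt1)
    out
  } else {
    filt1(as.numeric(E))
  }
}

# Welch PSD estimate for one signal: Hann segments with 50% overlap.
# Returns data.frame(freq, psd) with one-sided density scaling.
welch_psd <- function(x, sample_rate, window_sec = 2) {
  nwin <- round(window_sec * sample_rate)
  n <- length(x)
  if (n < nwin)
    stop("recording shorter than one Welch window", call. = FALSE)
  step <- max(1L, floor(nwin / 2))
  starts <- seq(1L, n - nwin + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nwin) / (nwin + 1))  # Hann
  u <- sum(w^2)
  acc <- numeric(floor(nwin / 2) + 1)
  for (s in starts) {
    seg <- x[s:(s + nwin - 1)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg))^2
    acc <- acc + sp[seq_along(acc)]
  }
  psd <- acc / (length(starts) * u * sample_rate)
  psd[c(-1, -length(psd))] <- 2 * psd[c(-1, -length(psd))]   # one-sided
  data.frame(freq = (seq_along(psd) - 1) * sample_rate / nwin, psd = psd)
}

#' Band power features from multichannel recordings
#'
#' Welch-estimates the PSD per channel (2 s Hann windows, 50% overlap),
#' integrates power over the delta/theta/alpha/beta bands of
#' [band_edges()], log-transforms, and z-scores each (channel, band) column
#' across subjects.  Fitted z-score statistics are returned for reuse on
#' held-out data.
#'
#' @param recordings List of T x c matrices, or a single matrix.
#' @param sample_rate Sampling rate in Hz.
#' @param zscore Whether to z-score columns (default TRUE).
#' @param params Optional fitted z-score parameters to apply.
#' @return n x (4c) matrix, columns ordered channel-major then band
#'   (delta, theta, alpha, beta), with attribute `"zscore_params"`.
#' @export
band_psd_features <- function(recordings, sample_rate, zscore = TRUE,
                              params = NULL) {
  if (is.matrix(recordings)) recordings <- list(recordings)
  edges <- band_edges()
  feat1 <- function(rec) {
    out <- numeric(0)
    for (ch in seq_len(ncol(rec))) {
      ps <- welch_psd(rec[, ch], sample_rate)
      df <- ps$freq[2] - ps$freq[1]
      bp <- vapply(edges, function(e)
        sum(ps$psd[ps$freq >= e[1] & ps$freq < e[2]]) * df, 0)
      out <- c(out, bp)
    }
    out
  }
  feats <- t(vapply(recordings, feat1,
                    numeric(4 * ncol(recordings[[1]]))))
  feats <- log(pmax(feats, 1e-20))
  colnames(feats) <- paste0(
    rep(sprintf("ch%02d", seq_len(ncol(recordings[[1]]))), each = 4), "_",
    rep(names(edges), ncol(recordings[[1]])))
  if (!zscore) return(feats)
  if (is.null(params)) {
    mu <- colMeans(feats)
    sd_ <- apply(feats, 2, stats::sd)
    sd_[sd_ == 0 | is.na(sd_)] <- 1
    params <- list(mean = mu, sd = sd_)
  }
  out <- sweep(sweep(feats, 2, params$mean), 2, params$sd, "/")
  attr(out, "zscore_params") <- params
  out
}

#' Min-max normalize a volume to \[0, 1\]
#'
#' @param V 3-D numeric array (finite).
#' @return Array with minimum 0 and maximum 1; constant volumes map to all
#'   zeros.
#' @export
normalize_volume <- function(V) {
  if (!all(is.finite(V))) stop_invalid("V", "must be finite")
  rng <- max(V) - min(V)
  if (rng == 0) return(array(0, dim = dim(V)))
  (V - min(V)) / rng
}

#' Simplified polynomial bias-field correction
#'
#' Fits an order-`poly_order` polynomial in the voxel coordinates to the
#' log-intensity of tissue voxels (intensity above `tissue_quantile` of the
#' volume), exponentiates the fit into a multiplicative field normalized to
#' mean 1 over tissue, and divides it out.  A documented simplification of
#' full N4 bias correction; `n4_hook` may supply an external corrector
#' `function(V) -> V` which is used instead.
#'
#' @param V 3-D array, positive where tissue is present.
#' @param poly_order Polynomial order (default 2).
#' @param tissue_frac Fraction of the maximum intensity above which a voxel
#'   counts as tissue for the fit (default 0.2, separating tissue from the
#'   near-zero background).
#' @param n4_hook Optional external correction function.
#' @return Corrected array with the estimated field as attribute
#'   `"estimated_field"`.
#' @export
correct_bias_field <- function(V, poly_order = 2, tissue_frac = 0.2,
                               n4_hook = NULL) {
  if (!is.null(n4_hook)) return(n4_hook(V))
  if (all(V == 0)) {
    warning("all-zero volume; returning unchanged")
    return(V)
  }
  shp <- dim(V)
  tissue <- which(V > tissue_frac * max(V))
  idx <- arrayInd(tissue, shp)
  x <- (idx[, 1] - 0.5) / shp[1] * 2 - 1
  y <- (idx[, 2] - 0.5) / shp[2] * 2 - 1
  z <- (idx[, 3] - 0.5) / shp[3] * 2 - 1
  basis <- function(x, y, z) {
    cols <- list(rep(1, length(x)))
    for (total in seq_len(poly_order))
      for (i in 0:total) for (j in 0:(total - i))
        cols[[length(cols) + 1]] <- x^i * y^j * z^(total - i - j)
    do.call(cbind, cols)
  }
  B <- basis(x, y, z)
  co <- stats::lm.fit(B, log(V[tissue]))$coefficients
  co[is.na(co)] <- 0
  # evaluate fitted log-field everywhere
  all_idx <- arrayInd(seq_along(V), shp)
  Ba <- basis((all_idx[, 1] - 0.5) / shp[1] * 2 - 1,
              (all_idx[, 2] - 0.5) / shp[2] * 2 - 1,
              (all_idx[, 3] - 0.5) / shp[3] * 2 - 1)
  lf <- Ba %*% co
  lf <- lf - mean(lf[tissue])              # mean-preserving over tissue
  field <- array(exp(lf), dim = shp)
  out <- V / field
  attr(out, "estimated_field") <- field
  out
}

#' Extract a 3-D patch grid
#'
#' Windows are half-open `[i * s, i * s + p)` per axis; the final window is
#' clamped to the end of the volume so the last voxel is always covered.
#' Patch count per axis is `ceiling((L - p) / s) + 1`.
#'
#' @param V 3-D array.
#' @param patch Integer 3-vector of patch shape.
#' @param stride Integer 3-vector of strides (default = patch).
#' @return List of class `patch_grid`: `patches` (4-D array
#'   `k x p_h x p_w x p_d`), `starts` (k x 3 matrix of 1-based start
#'   indices), `patch`, `stride`, `volume_shape`.
#' @export
extract_patches <- function(V, patch, stride = patch) {
  shp <- dim(V)
  patch <- as.integer(patch); stride <- as.integer(stride)
  if (any(patch > shp))
    stop_invalid("patch", "patch exceeds volume shape")
  if (any(stride < 1)) stop_invalid("stride", "must be >= 1")
  ax_starts <- function(L, p, s) {
    n <- ceiling((L - p) / s) + 1
    st <- (seq_len(n) - 1) * s + 1
    pmin(st, L - p + 1)
  }
  sx <- ax_starts(shp[1], patch[1], stride[1])
  sy <- ax_starts(shp[2], patch[2], stride[2])
  sz <- ax_starts(shp[3], patch[3], stride[3])
  starts <- as.matrix(expand.grid(x = sx, y = sy, z = sz))
  k <- nrow(starts)
  patches <- array(0, dim = c(k, patch))
  for (i in seq_len(k)) {
    s <- starts[i, ]
    patches[i, , , ] <- V[s[1]:(s[1] + patch[1] - 1),
                          s[2]:(s[2] + patch[2] - 1),
                          s[3]:(s[3] + patch[3] - 1)]
  }
  structure(list(patches = patches, starts = starts, patch = patch,
                 stride = stride, volume_shape = shp),
            class = "patch_grid")
}
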