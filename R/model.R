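# Model assembly: preprocessing fit/apply, parameter initialization, and the
# full forward/backward pass through the three encoder branches, the
# attention fusion block, and the head.
#
# Layout conventions (see nn-core.R): per-item flattened tensors are
# channel-fastest; token arrays are (n, tokens, dim).

MODALITIES <- c("SNP", "MRI", "EEG")

#' Fit preprocessing statistics on training subjects
#'
#' Fits, on the given subjects only, the SNP pipeline (mode imputation,
#' one-hot, PCA to the explained-variance target, z-clip, min-max scaling)
#' and the EEG pipeline (bandpass, Welch band powers, log, z-score, z-clip).
#' The returned object transforms any subject with these frozen statistics;
#' nothing is ever re-estimated at apply time.
#'
#' @param cohort An `nf_cohort`.
#' @param config An [nf_config()].
#' @param train_idx Integer indices of training subjects.
#' @return An opaque fit object for [build_model_inputs()].
#' @export
preprocess_fit <- function(cohort, config, train_idx = seq_along(cohort)) {
  spec <- attr(cohort, "spec")
  fit <- list(config = config, sample_rate = spec$sample_rate)
  if ("SNP" %in% config$modalities) {
    tr <- cohort[train_idx]
    has <- vapply(tr, function(s) s$modality_mask[["SNP"]], TRUE)
    G <- do.call(rbind, lapply(tr[has], `[[`, "genotypes"))
    imp <- impute_genotypes_mode(G)
    fit$impute <- attr(imp, "impute_params")
    oh <- one_hot_genotypes(imp)
    fit$pca <- pca_reduce(oh, config$pca_variance, config$pca_cap)
    sc <- pca_apply(oh, fit$pca)
    cl <- clip_outliers_zscore(sc, config$clip_sd)
    fit$clip_snp <- attr(cl, "clip_params")
    mm <- minmax_scale_columns(cl)
    fit$minmax_snp <- attr(mm, "minmax_params")
  }
  if ("EEG" %in% config$modalities) {
    tr <- cohort[train_idx]
    has <- vapply(tr, function(s) s$modality_mask[["EEG"]], TRUE)
    recs <- lapply(tr[has], function(s)
      bandpass_filter(s$recording, config$bandpass[1], config$bandpass[2],
                      spec$sample_rate))
    fe <- band_psd_features(recs, spec$sample_rate)
    fit$zscore_eeg <- attr(fe, "zscore_params")
    cl <- clip_outliers_zscore(fe, config$clip_sd)
    fit$clip_eeg <- attr(cl, "clip_params")
  }
  fit
}

snp_features <- function(cohort, fit) {
  config <- fit$config
  n <- length(cohort)
  p <- fit$pca$k
  out <- matrix(0, n, p)
  for (i in seq_len(n)) {
    s <- cohort[[i]]
    if (!s$modality_mask[["SNP"]] || is.null(s$genotypes)) next
    g <- matrix(s$genotypes, nrow = 1)
    g <- impute_genotypes_mode(g, fit$impute)
    oh <- one_hot_genotypes(g)
    sc <- pca_apply(oh, fit$pca)
    sc <- clip_outliers_zscore(sc, config$clip_sd, params = fit$clip_snp)
    out[i, ] <- minmax_scale_columns(sc, params = fit$minmax_snp)
  }
  out
}

mri_patches <- function(cohort, fit) {
  config <- fit$config
  n <- length(cohort)
  first <- NULL
  for (s in cohort) if (s$modality_mask[["MRI"]]) { first <- s; break }
  shp <- dim(first$volume)
  patch <- config$patch %||% shp
  stride <- config$patch_stride %||% patch
  pg0 <- extract_patches(array(0, shp), patch, stride)
  np <- nrow(pg0$starts)
  len <- prod(patch)
  out <- array(0, dim = c(n, np, len))
  for (i in seq_len(n)) {
    s <- cohort[[i]]
    if (!s$modality_mask[["MRI"]] || is.null(s$volume)) next
    v <- normalize_volume(correct_bias_field(s$volume))
    pg <- extract_patches(v, patch, stride)
    out[i, , ] <- matrix(pg$patches, np, len)
  }
  list(patches = out, patch = patch, stride = stride, starts = pg0$starts,
       volume_shape = shp)
}

eeg_features <- function(cohort, fit) {
  config <- fit$config
  n <- length(cohort)
  p <- length(fit$zscore_eeg$mean)
  out <- matrix(0, n, p)
  for (i in seq_len(n)) {
    s <- cohort[[i]]
    if (!s$modality_mask[["EEG"]] || is.null(s$recording)) next
    rec <- bandpass_filter(s$recording, config$bandpass[1],
                           config$bandpass[2], fit$sample_rate)
    fe <- band_psd_features(list(rec), fit$sample_rate,
                            params = fit$zscore_eeg)
    out[i, ] <- clip_outliers_zscore(fe, config$clip_sd,
                                     params = fit$clip_eeg)
  }
  out
}

#' Assemble model-ready inputs for a cohort
#'
#' Applies the frozen preprocessing fit to every subject and packs the
#' result into the dense arrays consumed by the network.  Subjects missing
#' a modality get zero rows; the mask records availability.
#'
#' @param cohort An `nf_cohort`.
#' @param fit Object from [preprocess_fit()].
#' @return List of class `nf_inputs`: `snp` (n x p), `mri` (n x patches x
#'   voxels), `eeg` (n x 4c), `mask` (n x 3), `labels`, `subject_ids`,
#'   `geometry`.
#' @export
build_model_inputs <- function(cohort, fit) {
  config <- fit$config
  n <- length(cohort)
  mask <- t(vapply(cohort, function(s) s$modality_mask, logical(3)))
  colnames(mask) <- MODALITIES
  mask[, setdiff(MODALITIES, config$modalities)] <- FALSE
  out <- list(mask = mask,
              labels = cohort_labels(cohort),
              subject_ids = vapply(cohort, `[[`, "", "subject_id"))
  geometry <- list()
  if ("SNP" %in% config$modalities) {
    out$snp <- snp_features(cohort, fit)
    geometry$p_snp <- ncol(out$snp)
  }
  if ("MRI" %in% config$modalities) {
    mp <- mri_patches(cohort, fit)
    out$mri <- mp$patches
    geometry$patch <- mp$patch
    geometry$n_patch <- dim(mp$patches)[2]
    geometry$patch_starts <- mp$starts
    geometry$volume_shape <- mp$volume_shape
  }
  if ("EEG" %in% config$modalities) {
    if (config$eeg_input == "raw") {
      spec <- attr(cohort, "spec")
      first <- NULL
      for (s in cohort) if (s$modality_mask[["EEG"]]) { first <- s; break }
      Tn <- nrow(first$recording); nc <- ncol(first$recording)
      out$eeg <- matrix(0, n, Tn * nc)
      for (i in seq_len(n)) {
        s <- cohort[[i]]
        if (!s$modality_mask[["EEG"]] || is.null(s$recording)) next
        rec <- bandpass_filter(s$recording, config$bandpass[1],
                               config$bandpass[2], fit$sample_rate)
        out$eeg[i, ] <- as.vector(t(rec))     # channel-fastest per time step
      }
      geometry$eeg_T <- Tn
      geometry$eeg_channels <- nc
    } else {
      out$eeg <- eeg_features(cohort, fit)
      geometry$eeg_channels <- ncol(out$eeg) / 4
    }
  }
  out$geometry <- geometry
  structure(out, class = "nf_inputs")
}

#' Initialize the multimodal model
#'
#' Builds all parameter matrices (SNP embedding + BiLSTM, 3-D and 1-D conv
#' branches, attention projections, fusion head) for the geometry of the
#' supplied inputs.
#'
#' @param inputs An [build_model_inputs()] object (geometry source).
#' @param config An [nf_config()].
#' @param seed Integer seed for weight initialization.
#' @return List of class `nf_model` with elements `params`, `config`,
#'   `geoms`, `classes`, `temperature`.
#' @export
nf_model <- function(inputs, config = nf_config(), seed = 1) {
  g <- inputs$geometry
  fu <- config$fusion_dim
  with_seed(seed, {
    params <- list()
    geoms <- list()
    if ("SNP" %in% config$modalities) {
      m <- config$embed_m; tw <- config$token_width; h <- config$lstm_units
      params$s_Wemb <- xavier_init(g$p_snp, m)
      params$s_bemb <- rep(0, m)
      lf <- lstm_init(tw, h); lb <- lstm_init(tw, h)
      params$s_lfW <- lf$W; params$s_lfb <- lf$b
      params$s_lbW <- lb$W; params$s_lbb <- lb$b
      params$s_Wtok <- xavier_init(2 * h, fu)
      params$s_btok <- rep(0, fu)
      geoms$snp <- list(ts = m %/% tw, tw = tw, h = h)
    }
    if ("MRI" %in% config$modalities) {
      k <- config$conv3d_kernel
      f1 <- config$conv3d_filters[1]; f2 <- config$conv3d_filters[2]
      g1 <- conv_geom(g$patch, 1, k)
      pg1 <- pool_geom(g1$out_shape, f1, config$pool)
      g2 <- conv_geom(pg1$out_shape, f1, k)
      geoms$mri <- list(g1 = g1, sc1 = conv_scatter(g1), pg1 = pg1,
                        g2 = g2, sc2 = conv_scatter(g2),
                        f1 = f1, f2 = f2, n_patch = g$n_patch,
                        patch = g$patch)
      params$m_W1 <- he_init(g1$cols, f1); params$m_b1 <- rep(0, f1)
      params$m_W2 <- he_init(g2$cols, f2); params$m_b2 <- rep(0, f2)
      params$m_Wtok <- xavier_init(f2, fu); params$m_btok <- rep(0, fu)
    }
    if ("EEG" %in% config$modalities) {
      f <- config$conv1d_filters; k <- config$conv1d_kernel
      if (config$eeg_input == "raw") {
        # raw path: convolve over time with the channels as input channels,
        # then mean-pool positions into a few segment tokens
        ge <- conv_geom(g$eeg_T, g$eeg_channels, k)
        n_seg <- 4L
        seg_id <- as.integer(cut(seq_len(ge$n_pos), n_seg, labels = FALSE))
        geoms$eeg <- list(ge = ge, sce = conv_scatter(ge), f = f,
                          channels = g$eeg_channels, raw = TRUE,
                          n_seg = n_seg, seg_id = seg_id)
      } else {
        ge <- conv_geom(g$eeg_channels, 4, k)
        geoms$eeg <- list(ge = ge, sce = conv_scatter(ge), f = f,
                          channels = g$eeg_channels, raw = FALSE)
      }
      params$e_W1 <- he_init(ge$cols, f); params$e_b1 <- rep(0, f)
      params$e_Wtok <- xavier_init(f, fu); params$e_btok <- rep(0, fu)
    }
    if (config$use_attention) {
      dk <- config$d_k
      for (mo in c(S = "S", M = "M", E = "E")[c("SNP", "MRI", "EEG") %in%
                                              config$modalities]) {
        params[[paste0("a_", mo, "_Wq")]] <- xavier_init(fu, dk)
        params[[paste0("a_", mo, "_Wk")]] <- xavier_init(fu, dk)
        params[[paste0("a_", mo, "_Wv")]] <- xavier_init(fu, fu)
        # output projections start at zero so the block enters training as
        # its residual (token-mean) path and the attention terms grow in
        params[[paste0("p_O", mo)]] <- matrix(0, fu, fu)
        params[[paste0("b_O", mo)]] <- rep(0, fu)
      }
      pairs <- c("SM", "SE", "ME")
      have <- c(SM = all(c("SNP", "MRI") %in% config$modalities),
                SE = all(c("SNP", "EEG") %in% config$modalities),
                ME = all(c("MRI", "EEG") %in% config$modalities))
      for (pr in pairs[have]) {
        params[[paste0("p_C", pr)]] <- matrix(0, fu, fu)
        params[[paste0("b_C", pr)]] <- rep(0, fu)
      }
    }
    hw <- config$head_width
    params$h_WF <- he_init(3 * fu, hw); params$h_bF <- rep(0, hw)
    params$h_gamma <- rep(1, hw); params$h_beta <- rep(0, hw)
    params$h_Wg <- xavier_init(hw, 2 * hw); params$h_bg <- rep(0, 2 * hw)
    params$h_Wout <- xavier_init(hw, config$n_classes)
    params$h_bout <- rep(0, config$n_classes)
    structure(list(params = params, config = config, geoms = geoms,
                   classes = CLASS_LEVELS, temperature = 1),
              class = "nf_model")
  })
}

zero_grads <- function(params) lapply(params, function(p) p * 0)

# zero the tokens of subjects lacking the modality (no-op when all present)
mask_tokens <- function(tk, mv) {
  if (all(mv == 1)) tk else tk * array(mv, dim = dim(tk))
}

## ---- forward ----

# Precompute the im2col gather of the (fixed) first-layer MRI input so
# training epochs skip the expensive reshape.
prep_conv <- function(model, inputs) {
  prep <- list()
  if ("MRI" %in% model$config$modalities) {
    gm <- model$geoms$mri
    n_all <- dim(inputs$mri)[1]
    Xm_all <- matrix(inputs$mri, n_all * gm$n_patch)
    prep$mri_A <- conv_im2col(Xm_all, gm$g1)
    prep$mri_n <- n_all
  }
  prep
}

mri_prep_rows <- function(prep, idx, np, n_pos) {
  gitems <- as.vector(outer(idx, (seq_len(np) - 1) * prep$mri_n, `+`))
  N <- prep$mri_n * np
  as.vector(outer(gitems, (seq_len(n_pos) - 1) * N, `+`))
}

# idx: subject rows of `inputs` in the batch.  dropout: sample dropout masks
# (training or MC mode).  mod_drop: apply modality dropout (training only).
nf_forward <- function(model, inputs, idx = NULL, dropout = FALSE,
                       mod_drop = FALSE, dropout_override = NULL,
                       prep = NULL) {
  cfg <- model$config
  pr <- model$params
  if (is.null(idx)) idx <- seq_len(nrow(inputs$mask))
  n <- length(idx)
  fu <- cfg$fusion_dim
  head_rate <- dropout_override %||% cfg$head_dropout
  conv_rate <- dropout_override %||% cfg$conv_dropout
  cache <- list(idx = idx, n = n)

  mask <- inputs$mask[idx, , drop = FALSE] * 1
  if (mod_drop && cfg$modality_dropout > 0) {
    for (i in seq_len(n)) {
      live <- which(mask[i, ] > 0)
      if (length(live) > 1 && stats::runif(1) < cfg$modality_dropout)
        mask[i, sample(live, 1)] <- 0
    }
  }
  cache$mask <- mask
  use <- list(S = "SNP" %in% cfg$modalities,
              M = "MRI" %in% cfg$modalities,
              E = "EEG" %in% cfg$modalities)

  tok <- list()
  # SNP branch: dense embed -> token chunks -> BiLSTM -> per-token dense
  if (use$S) {
    gs <- model$geoms$snp
    Xs <- inputs$snp[idx, , drop = FALSE]
    emb <- dense_fwd(Xs, pr$s_Wemb, pr$s_bemb)
    Zt <- aperm(array(emb$out, dim = c(n, gs$tw, gs$ts)), c(1, 3, 2))
    bl <- bilstm_fwd(Zt, pr$s_lfW, pr$s_lfb, pr$s_lbW, pr$s_lbb)
    Hf <- matrix(aperm(bl$out, c(1, 2, 3)), n * gs$ts, 2 * gs$h)
    td <- dense_fwd(Hf, pr$s_Wtok, pr$s_btok)
    tokS <- array(td$out, dim = c(n, gs$ts, fu))
    tokS <- mask_tokens(tokS, mask[, "SNP"])
    cache$snp <- list(emb = emb, bl = bl, td = td, gs = gs)
    tok$S <- tokS
  }
  # MRI branch: shared conv stack per patch -> global mean pool -> dense
  if (use$M) {
    gm <- model$geoms$mri
    np <- gm$n_patch
    if (!is.null(prep$mri_A)) {
      A1 <- prep$mri_A[mri_prep_rows(prep, idx, np, gm$g1$n_pos), ,
                       drop = FALSE]
      c1 <- conv_fwd(NULL, pr$m_W1, pr$m_b1, gm$g1, A = A1)
    } else {
      Xm <- matrix(inputs$mri[idx, , , drop = FALSE], n * np)
      c1 <- conv_fwd(Xm, pr$m_W1, pr$m_b1, gm$g1)
    }
    r1 <- relu_fwd(c1$out)
    d1 <- dropout_fwd(r1$out, conv_rate, dropout)
    p1 <- pool_fwd(d1$out, gm$pg1)
    c2 <- conv_fwd(p1$out, pr$m_W2, pr$m_b2, gm$g2)
    r2 <- relu_fwd(c2$out)
    d2 <- dropout_fwd(r2$out, conv_rate, dropout)
    npos2 <- gm$g2$n_pos
    gmp <- matrix(0, n * np, gm$f2)
    for (p in seq_len(npos2))
      gmp <- gmp + d2$out[, (p - 1) * gm$f2 + seq_len(gm$f2), drop = FALSE]
    gmp <- gmp / npos2
    tdm <- dense_fwd(gmp, pr$m_Wtok, pr$m_btok)
    tokM <- array(tdm$out, dim = c(n, np, fu))
    tokM <- mask_tokens(tokM, mask[, "MRI"])
    cache$mri <- list(c1 = c1, r1 = r1, d1 = d1, p1 = p1, c2 = c2, r2 = r2,
                      d2 = d2, tdm = tdm, np = np, npos2 = npos2)
    tok$M <- tokM
  }
  # EEG branch: 1-D conv -> dense per token.  PSD path convolves over the
  # channel axis (band powers as input channels, one token per position);
  # raw path convolves over time and mean-pools positions into segments.
  if (use$E) {
    gee <- model$geoms$eeg
    Xe <- inputs$eeg[idx, , drop = FALSE]
    ce <- conv_fwd(Xe, pr$e_W1, pr$e_b1, gee$ge)
    re <- relu_fwd(ce$out)
    de <- dropout_fwd(re$out, conv_rate, dropout)
    if (isTRUE(gee$raw)) {
      tE <- gee$n_seg
      segn <- tabulate(gee$seg_id, tE)
      Ee <- matrix(0, n * tE, gee$f)
      for (p in seq_len(gee$ge$n_pos)) {
        s <- gee$seg_id[p]
        rr <- (s - 1L) * n + seq_len(n)
        Ee[rr, ] <- Ee[rr, , drop = FALSE] +
          de$out[, (p - 1L) * gee$f + seq_len(gee$f), drop = FALSE]
      }
      Ee <- Ee / rep(segn, each = n)
    } else {
      tE <- gee$ge$n_pos
      Ee <- matrix(aperm(array(de$out, dim = c(n, gee$f, tE)), c(1, 3, 2)),
                   n * tE, gee$f)
    }
    tde <- dense_fwd(Ee, pr$e_Wtok, pr$e_btok)
    tokE <- array(tde$out, dim = c(n, tE, fu))
    tokE <- mask_tokens(tokE, mask[, "EEG"])
    cache$eeg <- list(ce = ce, re = re, de = de, tde = tde, tE = tE)
    tok$E <- tokE
  }
  cache$tok <- tok

  zero <- matrix(0, n, fu)
  if (cfg$use_attention) {
    # project Q/K/V for every modality in one matmul over all subjects;
    # the per-subject loop then only does the (tiny) softmax mixing
    mos <- c("S", "M", "E")[unlist(use)]
    tokmat <- qb <- kb <- vb <- tcount <- list()
    for (mo in mos) {
      tk <- tok[[mo]]
      tcount[[mo]] <- dim(tk)[2]
      tokmat[[mo]] <- matrix(tk, n * dim(tk)[2], fu)
      qb[[mo]] <- tokmat[[mo]] %*% pr[[paste0("a_", mo, "_Wq")]]
      kb[[mo]] <- tokmat[[mo]] %*% pr[[paste0("a_", mo, "_Wk")]]
      vb[[mo]] <- tokmat[[mo]] %*% pr[[paste0("a_", mo, "_Wv")]]
    }
    tags <- list(OS = c("S", "S"), OM = c("M", "M"), OE = c("E", "E"),
                 CSM = c("S", "M"), CSE = c("S", "E"), CME = c("M", "E"))
    live_tags <- names(tags)[vapply(tags, function(p)
      all(p %in% mos), TRUE)]
    # batched attention: rows of the big projection matrices are ordered
    # subject-fastest (row = i + (token-1) * n), so per-token slices are
    # vectorized over the whole batch
    A_caches <- list()
    pools <- list(OS = zero, OM = zero, OE = zero,
                  CSM = zero, CSE = zero, CME = zero)
    sdk <- sqrt(cfg$d_k)
    rows_tok <- function(mo, a) (a - 1L) * n + seq_len(n)
    for (tg in live_tags) {
      qm <- tags[[tg]][1]; km <- tags[[tg]][2]
      tq <- tcount[[qm]]; tk <- tcount[[km]]
      # logits L[(i,a), b] = <Q_ia, K_ib> / sqrt(d_k)
      L <- matrix(0, n * tq, tk)
      for (a in seq_len(tq)) {
        Qa <- qb[[qm]][rows_tok(qm, a), , drop = FALSE]
        for (b in seq_len(tk))
          L[rows_tok(qm, a), b] <-
            rowSums(Qa * kb[[km]][rows_tok(km, b), , drop = FALSE])
      }
      A <- row_softmax(L / sdk)
      O <- matrix(0, n * tq, fu)
      i_rep <- rep(seq_len(n), tq)
      for (b in seq_len(tk))
        O <- O + A[, b] * vb[[km]][(b - 1L) * n + i_rep, , drop = FALSE]
      pl <- matrix(0, n, fu)
      for (a in seq_len(tq)) pl <- pl + O[rows_tok(qm, a), , drop = FALSE]
      pools[[tg]] <- pl / tq
      A_caches[[tg]] <- A
    }
    cache$att <- list(tokmat = tokmat, qb = qb, kb = kb, vb = vb,
                      tcount = tcount, A = A_caches, tags = tags,
                      live_tags = live_tags, mos = mos)
    proj <- list()
    for (nm in c("OS", "OM", "OE")) {
      mo <- substr(nm, 2, 2)
      if (!use[[c(S = "S", M = "M", E = "E")[mo]]]) { proj[[nm]] <- zero; next }
      proj[[nm]] <- dense_fwd(pools[[nm]], pr[[paste0("p_O", mo)]],
                              pr[[paste0("b_O", mo)]])
    }
    for (nm in c("CSM", "CSE", "CME")) {
      pr_nm <- paste0("p_C", substr(nm, 2, 3))
      if (is.null(pr[[pr_nm]])) { proj[[nm]] <- zero; next }
      proj[[nm]] <- dense_fwd(pools[[nm]], pr[[pr_nm]],
                              pr[[paste0("b_C", substr(nm, 2, 3))]])
    }
    cache$proj <- proj
    # residual path: the pooled self-attended representation is the token
    # mean plus the projected attention output (standard attention-block
    # residual; keeps early training well-conditioned)
    tokmean <- function(tk) if (is.null(tk)) zero else
      matrix(colMeans(aperm(tk, c(2, 1, 3))), nrow = n)
    rS <- tokmean(tok$S); rM <- tokmean(tok$M); rE <- tokmean(tok$E)
    cache$resid <- list(S = rS, M = rM, E = rE)
    gv <- function(x) if (is.list(x)) x$out else x
    s <- mask[, "SNP"]; m <- mask[, "MRI"]; e <- mask[, "EEG"]
    FS <- ((gv(proj$OS) + rS) * s + gv(proj$CSM) * (s * m) +
             gv(proj$CSE) * (s * e)) * s
    FM <- ((gv(proj$OM) + rM) * m + gv(proj$CSM) * (s * m) +
             gv(proj$CME) * (m * e)) * m
    FE <- ((gv(proj$OE) + rE) * e + gv(proj$CSE) * (s * e) +
             gv(proj$CME) * (m * e)) * e
  } else {
    # concatenation-only fusion: token means per modality
    tokmean <- function(tk) if (is.null(tk)) zero else
      matrix(colMeans(aperm(tk, c(2, 1, 3))), nrow = n)
    FS <- tokmean(tok$S); FM <- tokmean(tok$M); FE <- tokmean(tok$E)
  }
  cache$FS <- FS; cache$FM <- FM; cache$FE <- FE

  Fc <- cbind(FS, FM, FE)
  hd <- dense_fwd(Fc, pr$h_WF, pr$h_bF)
  hdr <- dropout_fwd(hd$out, head_rate, dropout)
  ln <- layernorm_fwd(hdr$out, pr$h_gamma, pr$h_beta)
  gl <- glu_fwd(ln$out, pr$h_Wg, pr$h_bg)
  refined <- hdr$out + gl$out
  lo <- dense_fwd(refined, pr$h_Wout, pr$h_bout)
  cache$head <- list(hd = hd, hdr = hdr, ln = ln, gl = gl)
  list(logits = lo$out, cache = cache)
}

## ---- backward ----

# dlogits: n x n_classes.  Returns grads (same names as params) and, when
# input_grads = TRUE, gradients w.r.t. the raw inputs (for saliency).
nf_backward <- function(model, inputs, cache, dlogits, input_grads = FALSE) {
  cfg <- model$config
  pr <- model$params
  n <- cache$n
  fu <- cfg$fusion_dim
  gr <- zero_grads(pr)
  use <- list(S = "SNP" %in% cfg$modalities,
              M = "MRI" %in% cfg$modalities,
              E = "EEG" %in% cfg$modalities)
  mask <- cache$mask
  hd <- cache$head

  bo <- dense_bwd(dlogits, list(X = hd$hdr$out + hd$gl$out), pr$h_Wout)
  gr$h_Wout <- gr$h_Wout + bo$dW; gr$h_bout <- gr$h_bout + bo$db
  drefined <- bo$dX
  bg <- glu_bwd(drefined, hd$gl, pr$h_Wg)
  gr$h_Wg <- gr$h_Wg + bg$dW; gr$h_bg <- gr$h_bg + bg$db
  bl_ <- layernorm_bwd(bg$dX, hd$ln, pr$h_gamma)
  gr$h_gamma <- gr$h_gamma + bl_$dgamma; gr$h_beta <- gr$h_beta + bl_$dbeta
  dZdrop <- drefined + bl_$dX
  dZ <- dropout_bwd(dZdrop, hd$hdr)
  bF <- dense_bwd(dZ, hd$hd, pr$h_WF)
  gr$h_WF <- gr$h_WF + bF$dW; gr$h_bF <- gr$h_bF + bF$db
  dFS <- bF$dX[, seq_len(fu), drop = FALSE]
  dFM <- bF$dX[, fu + seq_len(fu), drop = FALSE]
  dFE <- bF$dX[, 2 * fu + seq_len(fu), drop = FALSE]

  dtok <- list(S = if (use$S) array(0, dim = dim(cache$tok$S)),
               M = if (use$M) array(0, dim = dim(cache$tok$M)),
               E = if (use$E) array(0, dim = dim(cache$tok$E)))

  if (cfg$use_attention) {
    s <- mask[, "SNP"]; m <- mask[, "MRI"]; e <- mask[, "EEG"]
    dproj <- list(
      OS = dFS * s, OM = dFM * m, OE = dFE * e,
      CSM = (dFS * s + dFM * m) * (s * m),
      CSE = (dFS * s + dFE * e) * (s * e),
      CME = (dFM * m + dFE * e) * (m * e))
    # residual (token-mean) path of the pooled self-attended outputs
    spread_add <- function(dtk, dF) {
      tcount <- dim(dtk)[2]
      for (tix in seq_len(tcount)) dtk[, tix, ] <- dtk[, tix, ] + dF / tcount
      dtk
    }
    if (use$S) dtok$S <- spread_add(dtok$S, dproj$OS)
    if (use$M) dtok$M <- spread_add(dtok$M, dproj$OM)
    if (use$E) dtok$E <- spread_add(dtok$E, dproj$OE)
    dpool <- list()
    for (nm in c("OS", "OM", "OE")) {
      mo <- substr(nm, 2, 2)
      key <- paste0("p_O", mo)
      if (is.null(pr[[key]]) || !is.list(cache$proj[[nm]])) {
        dpool[[nm]] <- NULL; next
      }
      bb <- dense_bwd(dproj[[nm]], cache$proj[[nm]], pr[[key]])
      gr[[key]] <- gr[[key]] + bb$dW
      gr[[paste0("b_O", mo)]] <- gr[[paste0("b_O", mo)]] + bb$db
      dpool[[nm]] <- bb$dX
    }
    for (nm in c("CSM", "CSE", "CME")) {
      key <- paste0("p_C", substr(nm, 2, 3))
      if (is.null(pr[[key]]) || !is.list(cache$proj[[nm]])) {
        dpool[[nm]] <- NULL; next
      }
      bb <- dense_bwd(dproj[[nm]], cache$proj[[nm]], pr[[key]])
      gr[[key]] <- gr[[key]] + bb$dW
      gr[[paste0("b_C", substr(nm, 2, 3))]] <- gr[[paste0("b_C", substr(nm, 2, 3))]] + bb$db
      dpool[[nm]] <- bb$dX
    }
    at <- cache$att
    dqb <- dkb <- dvb <- list()
    for (mo in at$mos) {
      dqb[[mo]] <- at$qb[[mo]] * 0
      dkb[[mo]] <- at$kb[[mo]] * 0
      dvb[[mo]] <- at$vb[[mo]] * 0
    }
    sdk <- sqrt(cfg$d_k)
    for (tg in at$live_tags) {
      dp <- dpool[[tg]]
      if (is.null(dp)) next
      qm <- at$tags[[tg]][1]; km <- at$tags[[tg]][2]
      tq <- at$tcount[[qm]]; tk <- at$tcount[[km]]
      A <- at$A[[tg]]                       # (n*tq) x tk
      i_rep <- rep(seq_len(n), tq)
      dO <- (dp / tq)[i_rep, , drop = FALSE]
      # value gradients: dV_(i,b) = sum_a A[(i,a),b] dO_(i,a)
      for (b in seq_len(tk)) {
        contrib <- A[, b] * dO
        acc <- matrix(0, n, ncol(dO))
        for (a in seq_len(tq))
          acc <- acc + contrib[(a - 1L) * n + seq_len(n), , drop = FALSE]
        rb <- (b - 1L) * n + seq_len(n)
        dvb[[km]][rb, ] <- dvb[[km]][rb, , drop = FALSE] + acc
      }
      # attention-weight gradients and softmax backward (1/sqrt(d_k) folded)
      dA <- matrix(0, n * tq, tk)
      for (b in seq_len(tk))
        dA[, b] <- rowSums(dO * at$vb[[km]][(b - 1L) * n + i_rep, ,
                                            drop = FALSE])
      dL <- A * (dA - rowSums(dA * A)) / sdk
      # query gradients: dQ_(i,a) = sum_b dL[(i,a),b] K_(i,b)
      dQ <- dqb[[qm]] * 0
      for (b in seq_len(tk))
        dQ <- dQ + dL[, b] * at$kb[[km]][(b - 1L) * n + i_rep, , drop = FALSE]
      dqb[[qm]] <- dqb[[qm]] + dQ
      # key gradients: dK_(i,b) = sum_a dL[(i,a),b] Q_(i,a)
      for (b in seq_len(tk)) {
        acc <- matrix(0, n, ncol(dkb[[km]]))
        for (a in seq_len(tq)) {
          ra <- (a - 1L) * n + seq_len(n)
          acc <- acc + dL[ra, b] * at$qb[[qm]][ra, , drop = FALSE]
        }
        rb <- (b - 1L) * n + seq_len(n)
        dkb[[km]][rb, ] <- dkb[[km]][rb, , drop = FALSE] + acc
      }
    }
    for (mo in at$mos) {
      gr[[paste0("a_", mo, "_Wq")]] <- gr[[paste0("a_", mo, "_Wq")]] +
        crossprod(at$tokmat[[mo]], dqb[[mo]])
      gr[[paste0("a_", mo, "_Wk")]] <- gr[[paste0("a_", mo, "_Wk")]] +
        crossprod(at$tokmat[[mo]], dkb[[mo]])
      gr[[paste0("a_", mo, "_Wv")]] <- gr[[paste0("a_", mo, "_Wv")]] +
        crossprod(at$tokmat[[mo]], dvb[[mo]])
      dtm <- dqb[[mo]] %*% t(pr[[paste0("a_", mo, "_Wq")]]) +
        dkb[[mo]] %*% t(pr[[paste0("a_", mo, "_Wk")]]) +
        dvb[[mo]] %*% t(pr[[paste0("a_", mo, "_Wv")]])
      dtok[[mo]] <- dtok[[mo]] + array(dtm, dim = dim(dtok[[mo]]))
    }
  } else {
    spread <- function(dF, tk) {
      tcount <- dim(tk)[2]
      out <- array(0, dim = dim(tk))
      for (tix in seq_len(tcount)) out[, tix, ] <- dF / tcount
      out
    }
    if (use$S) dtok$S <- spread(dFS, cache$tok$S)
    if (use$M) dtok$M <- spread(dFM, cache$tok$M)
    if (use$E) dtok$E <- spread(dFE, cache$tok$E)
  }

  igr <- list()
  # branch backward: chain through the mask multiply first
  if (use$S) {
    gs <- cache$snp$gs
    dS <- mask_tokens(dtok$S, mask[, "SNP"])
    dH <- matrix(dS, n * gs$ts, fu)
    bt <- dense_bwd(dH, cache$snp$td, pr$s_Wtok)
    gr$s_Wtok <- gr$s_Wtok + bt$dW; gr$s_btok <- gr$s_btok + bt$db
    dHs <- array(bt$dX, dim = c(n, gs$ts, 2 * gs$h))
    bb <- bilstm_bwd(dHs, cache$snp$bl, pr$s_lfW, pr$s_lbW)
    gr$s_lfW <- gr$s_lfW + bb$dWf; gr$s_lfb <- gr$s_lfb + bb$dbf
    gr$s_lbW <- gr$s_lbW + bb$dWb; gr$s_lbb <- gr$s_lbb + bb$dbb
    dZt <- matrix(aperm(bb$dX, c(1, 3, 2)), n, gs$tw * gs$ts)
    be <- dense_bwd(dZt, cache$snp$emb, pr$s_Wemb)
    gr$s_Wemb <- gr$s_Wemb + be$dW; gr$s_bemb <- gr$s_bemb + be$db
    if (input_grads) igr$snp <- be$dX
  }
  if (use$M) {
    gm <- model$geoms$mri
    cm <- cache$mri
    dM <- mask_tokens(dtok$M, mask[, "MRI"])
    dtm <- matrix(dM, n * cm$np, fu)
    bt <- dense_bwd(dtm, cm$tdm, pr$m_Wtok)
    gr$m_Wtok <- gr$m_Wtok + bt$dW; gr$m_btok <- gr$m_btok + bt$db
    dgmp <- bt$dX / cm$npos2
    dD2 <- matrix(0, n * cm$np, gm$f2 * cm$npos2)
    for (p in seq_len(cm$npos2))
      dD2[, (p - 1) * gm$f2 + seq_len(gm$f2)] <- dgmp
    dR2 <- dropout_bwd(dD2, cm$d2)
    dC2 <- relu_bwd(dR2, cm$r2)
    b2 <- conv_bwd(dC2, cm$c2, pr$m_W2, gm$g2, gm$sc2)
    gr$m_W2 <- gr$m_W2 + b2$dW; gr$m_b2 <- gr$m_b2 + b2$db
    dP1 <- pool_bwd(b2$dX, cm$p1, gm$pg1, n * cm$np, gm$pg1$in_len)
    dD1 <- dropout_bwd(dP1, cm$d1)
    dC1 <- relu_bwd(dD1, cm$r1)
    b1 <- conv_bwd(dC1, cm$c1, pr$m_W1, gm$g1, gm$sc1, need_dX = input_grads)
    gr$m_W1 <- gr$m_W1 + b1$dW; gr$m_b1 <- gr$m_b1 + b1$db
    if (input_grads) igr$mri <- array(b1$dX, dim = c(n, cm$np, ncol(b1$dX)))
  }
  if (use$E) {
    gee <- model$geoms$eeg
    cee <- cache$eeg
    dE <- mask_tokens(dtok$E, mask[, "EEG"])
    dte <- matrix(dE, n * cee$tE, fu)
    bt <- dense_bwd(dte, cee$tde, pr$e_Wtok)
    gr$e_Wtok <- gr$e_Wtok + bt$dW; gr$e_btok <- gr$e_btok + bt$db
    if (isTRUE(gee$raw)) {
      segn <- tabulate(gee$seg_id, gee$n_seg)
      dSeg <- bt$dX / rep(segn, each = n)
      dEe <- matrix(0, n, gee$f * gee$ge$n_pos)
      for (p in seq_len(gee$ge$n_pos)) {
        s <- gee$seg_id[p]
        dEe[, (p - 1L) * gee$f + seq_len(gee$f)] <-
          dSeg[(s - 1L) * n + seq_len(n), , drop = FALSE]
      }
    } else {
      dEe <- matrix(aperm(array(bt$dX, dim = c(n, cee$tE, gee$f)),
                          c(1, 3, 2)), n, gee$f * cee$tE)
    }
    dDe <- dropout_bwd(dEe, cee$de)
    dCe <- relu_bwd(dDe, cee$re)
    be <- conv_bwd(dCe, cee$ce, pr$e_W1, gee$ge, gee$sce,
                   need_dX = input_grads)
    gr$e_W1 <- gr$e_W1 + be$dW; gr$e_b1 <- gr$e_b1 + be$db
    if (input_grads) igr$eeg <- be$dX
  }
  list(grads = gr, input_grads = igr)
}
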