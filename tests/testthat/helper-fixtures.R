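# Shared fixtures: small cohorts and model inputs built in code.

small_spec <- function(n = 24, seed = 7, ...) {
  cohort_spec(n_subjects = n, volume_shape = c(12, 12, 12),
              n_timesteps = 600, n_channels = 6, sample_rate = 100,
              n_snps = 40, n_risk_loci = 8, seed = seed, ...)
}

# cached small complete cohort shared across tests
small_cohort <- local({
  co <- NULL
  function() {
    if (is.null(co)) co <<- generate_cohort(small_spec(frac_complete = 1))
    co
  }
})

tiny_config <- function(...) {
  defaults <- list(fusion_dim = 5, d_k = 4, embed_m = 8, token_width = 4,
                   lstm_units = 3, conv3d_filters = c(2, 3),
                   conv1d_filters = 3, head_width = 6, head_dropout = 0,
                   conv_dropout = 0, modality_dropout = 0)
  do.call(nf_config, utils::modifyList(defaults, list(...)))
}

# hand-built inputs object that skips preprocessing (for model-level tests)
tiny_inputs <- function(n = 4, p_snp = 6, patch = c(8, 8, 8), np = 2,
                        ch = 6, seed = 9,
                        mask = cbind(SNP = rep(TRUE, n), MRI = rep(TRUE, n),
                                     EEG = rep(TRUE, n))) {
  set.seed(seed)
  structure(list(
    snp = matrix(stats::rnorm(n * p_snp), n),
    mri = array(stats::runif(n * np * prod(patch)), c(n, np, prod(patch))),
    eeg = matrix(stats::rnorm(n * 4 * ch), n),
    mask = mask,
    labels = factor(rep_len(c("AD", "PD", "HC"), n),
                    levels = c("AD", "PD", "HC")),
    subject_ids = sprintf("S%02d", seq_len(n)),
    geometry = list(p_snp = p_snp, patch = patch, n_patch = np,
                    eeg_channels = ch,
                    # patches tile a volume stacked along the third axis
                    volume_shape = c(patch[1], patch[2], patch[3] * np),
                    patch_starts = cbind(1, 1, (seq_len(np) - 1) * patch[3] + 1))),
    class = "nf_inputs")
}

expect_all_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a - b)), tol)
}
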