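# Synthetic tri-modal cohort generator.
#
# Generates subjects with three modalities carrying planted, class-dependent
# signal: volumetric "MRI" arrays with reduced intensity mass in a designated
# atrophy region (AD) or motor region (PD), multichannel "EEG" built from
# band-limited sinusoid mixtures plus pink noise with class-dependent band
# power offsets (delta/theta elevated in AD, alpha/beta in PD), and SNP
# genotype vectors with class-enriched allele frequencies at designated risk
# loci.  A fraction of subjects is complete tri-modal; the rest keep a random
# non-empty proper subset of modalities.

#' Specify a synthetic tri-modal cohort
#'
#' Builds and validates the parameter set consumed by [generate_cohort()].
#' Defaults are desk-scale: 32^3 volumes, 8-channel 20 s recordings at
#' 100 Hz, 200 SNPs of which 20 are designated risk loci.
#'
#' @param n_subjects Number of subjects.
#' @param class_proportions Length-3 vector of AD, PD, HC proportions summing
#'   to 1; class counts follow largest-remainder rounding with ties broken in
#'   class order (AD, PD, HC).
#' @param volume_shape Integer 3-vector (h, w, d) of the volume grid.
#' @param n_channels,n_timesteps,sample_rate EEG geometry: channels, time
#'   steps, and sampling rate in Hz.
#' @param n_snps Number of SNP loci.
#' @param n_risk_loci Number of designated risk loci (half enriched in AD,
#'   half in PD); must be even and `<= n_snps`.
#' @param atrophy_effect Fractional intensity-mass reduction in the atrophy
#'   region for AD subjects, in \[0, 1\].
#' @param motor_effect Fractional reduction in the motor region for PD.
#' @param band_shift_db 3x4 matrix of per-class band-power offsets in dB;
#'   rows AD, PD, HC; columns delta, theta, alpha, beta.
#' @param risk_allele_freqs `n_risk_loci` x 3 matrix of per-class minor-allele
#'   frequencies at the risk loci (columns AD, PD, HC); all entries in
#'   \[0, 1\].  The default enriches the first half in AD (0.45 vs 0.15) and
#'   the second half in PD.
#' @param n_shift_channels Number of channels carrying the class band-power
#'   shift; 0 (the default) applies it to every channel.  A positive value
#'   plants a localized abnormality on a random per-subject channel subset,
#'   so channel relevance varies across subjects.
#' @param frac_complete Fraction of subjects with all three modalities.
#' @param bias_amplitude Peak deviation of the multiplicative intensity bias
#'   field planted on each volume (see [plant_bias_field()]).
#' @param noise_sd Additive noise scale (voxel noise SD; EEG pink-noise RMS
#'   is `10 * noise_sd`).
#' @param scans_per_subject Number of MRI scans generated per subject with
#'   the MRI modality (all carry the same class effect, independent noise).
#' @param signal_mode `"marginal"` plants independent per-modality class
#'   signal (the default study condition); `"xor"` plants a cross-modal
#'   SNP-by-EEG interaction: disease subjects carry risk burden in one of two
#'   disjoint risk-locus sets and one of two band-shift profiles, and the
#'   AD/PD label is their XOR, so no single modality separates AD from PD.
#' @param seed Integer seed; identical spec + seed reproduces the cohort
#'   bit-exactly.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 100,
                        class_proportions = c(AD = 1 / 3, PD = 1 / 3, HC = 1 / 3),
                        volume_shape = c(32L, 32L, 32L),
                        n_channels = 8,
                        n_timesteps = 2000,
                        sample_rate = 100,
                        n_snps = 200,
                        n_risk_loci = 20,
                        atrophy_effect = 0.2,
                        motor_effect = 0.2,
                        band_shift_db = rbind(AD = c(3, 3, 0, 0),
                                              PD = c(0, 0, 3, 3),
                                              HC = c(0, 0, 0, 0)),
                        risk_allele_freqs = NULL,
                        n_shift_channels = 0,
                        frac_complete = 0.6,
                        bias_amplitude = 0.2,
                        noise_sd = 0.05,
                        scans_per_subject = 1,
                        signal_mode = c("marginal", "xor"),
                        seed = 1L) {
  n_subjects <- check_count(n_subjects, "n_subjects")
  if (length(class_proportions) != 3 || any(class_proportions < 0))
    stop_invalid("class_proportions", "must be 3 nonnegative numbers")
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop_invalid("class_proportions", "must sum to 1")
  if (length(volume_shape) != 3 || any(volume_shape < 4))
    stop_invalid("volume_shape", "must be 3 integers >= 4")
  volume_shape <- vapply(volume_shape, check_count, integer(1), field = "volume_shape")
  n_channels <- check_count(n_channels, "n_channels")
  n_timesteps <- check_count(n_timesteps, "n_timesteps")
  if (sample_rate <= 0) stop_invalid("sample_rate", "must be positive")
  n_snps <- check_count(n_snps, "n_snps")
  n_risk_loci <- check_count(n_risk_loci, "n_risk_loci", min = 2L)
  if (n_risk_loci %% 2 != 0 || n_risk_loci > n_snps)
    stop_invalid("n_risk_loci", "must be even and <= n_snps")
  atrophy_effect <- check_fraction(atrophy_effect, "atrophy_effect")
  motor_effect <- check_fraction(motor_effect, "motor_effect")
  band_shift_db <- as.matrix(band_shift_db)
  if (!all(dim(band_shift_db) == c(3, 4)))
    stop_invalid("band_shift_db", "must be a 3x4 matrix (classes x bands)")
  if (is.null(risk_allele_freqs)) {
    half <- n_risk_loci / 2
    risk_allele_freqs <- cbind(
      AD = c(rep(0.45, half), rep(0.15, half)),
      PD = c(rep(0.15, half), rep(0.45, half)),
      HC = rep(0.15, n_risk_loci))
  }
  risk_allele_freqs <- as.matrix(risk_allele_freqs)
  if (nrow(risk_allele_freqs) != n_risk_loci || ncol(risk_allele_freqs) != 3)
    stop_invalid("risk_allele_freqs", "must be n_risk_loci x 3 (AD, PD, HC)")
  if (any(risk_allele_freqs < 0 | risk_allele_freqs > 1))
    stop_invalid("risk_allele_freqs", "frequencies must lie in [0, 1]")
  n_shift_channels <- check_count(n_shift_channels, "n_shift_channels",
                                  min = 0L)
  if (n_shift_channels > n_channels)
    stop_invalid("n_shift_channels", "must be <= n_channels")
  frac_complete <- check_fraction(frac_complete, "frac_complete")
  if (bias_amplitude < 0) stop_invalid("bias_amplitude", "must be >= 0")
  if (noise_sd < 0) stop_invalid("noise_sd", "must be >= 0")
  scans_per_subject <- check_count(scans_per_subject, "scans_per_subject")
  signal_mode <- match.arg(signal_mode)
  structure(list(
    n_subjects = n_subjects, class_proportions = class_proportions,
    volume_shape = volume_shape, n_channels = n_channels,
    n_timesteps = n_timesteps, sample_rate = sample_rate,
    n_snps = n_snps, n_risk_loci = n_risk_loci,
    atrophy_effect = atrophy_effect, motor_effect = motor_effect,
    band_shift_db = band_shift_db, risk_allele_freqs = risk_allele_freqs,
    n_shift_channels = n_shift_channels,
    frac_complete = frac_complete, bias_amplitude = bias_amplitude,
    noise_sd = noise_sd, scans_per_subject = scans_per_subject,
    signal_mode = signal_mode, seed = as.integer(seed)),
    class = "cohort_spec")
}

# Canonical frequency-band edges in Hz (half-open intervals).
#' Frequency band edges used throughout the package
#'
#' Delta \[0.5, 4), theta \[4, 8), alpha \[8, 13), beta \[13, 30) Hz.
#' @return Named list of `c(lo, hi)` pairs.
#' @export
band_edges <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
}

# Ellipsoidal region masks.  These are fixed *designated* regions of the
# synthetic grid, standing in for hippocampal / motor anatomy; they make the
# planted effect exactly recoverable but claim nothing anatomical.
region_mask <- function(shape, center, semi) {
  x <- (seq_len(shape[1]) - 0.5) / shape[1]
  y <- (seq_len(shape[2]) - 0.5) / shape[2]
  z <- (seq_len(shape[3]) - 0.5) / shape[3]
  dx <- (x - center[1]) / semi[1]
  dy <- (y - center[2]) / semi[2]
  dz <- (z - center[3]) / semi[3]
  outer(outer(dx^2, dy^2, `+`), dz^2, `+`) <= 1
}

#' Designated region masks on the synthetic volume grid
#'
#' Fixed ellipsoids (in normalized coordinates) in which the generator
#' reduces intensity mass for AD (`atrophy_region_mask`) and PD
#' (`motor_region_mask`).
#'
#' @param shape Integer 3-vector of the volume grid.
#' @return Logical array of the given shape.
#' @export
atrophy_region_mask <- function(shape) {
  region_mask(shape, center = c(0.35, 0.40, 0.50), semi = c(0.13, 0.13, 0.13))
}

#' @rdname atrophy_region_mask
#' @export
motor_region_mask <- function(shape) {
  region_mask(shape, center = c(0.68, 0.62, 0.55), semi = c(0.13, 0.13, 0.13))
}

#' Multiplicative low-order polynomial bias field
#'
#' Builds a smooth order-2 polynomial field with mean exactly 1 and peak
#' deviation equal to `amplitude`, emulating scanner intensity
#' inhomogeneity.
#'
#' @param shape Integer 3-vector.
#' @param amplitude Peak absolute deviation from 1; must be `>= 0`.
#' @param seed Integer seed; the same seed yields the identical field.
#' @return Array of the given shape.
#' @export
make_bias_field <- function(shape, amplitude, seed) {
  if (amplitude < 0) stop_invalid("amplitude", "must be >= 0")
  if (amplitude == 0) return(array(1, dim = shape))
  with_seed(seed, {
    co <- stats::rnorm(9)
    x <- seq(-1, 1, length.out = shape[1])
    y <- seq(-1, 1, length.out = shape[2])
    z <- seq(-1, 1, length.out = shape[3])
    g <- expand.grid(x = x, y = y, z = z)
    f <- with(g, co[1] * x + co[2] * y + co[3] * z +
                 co[4] * x^2 + co[5] * y^2 + co[6] * z^2 +
                 co[7] * x * y + co[8] * x * z + co[9] * y * z)
    f <- f - mean(f)
    f <- f * (amplitude / max(abs(f)))
    array(1 + f, dim = shape)
  })
}

#' Plant a multiplicative bias field on a volume
#'
#' Multiplies the volume voxel-wise by a smooth order-2 polynomial field with
#' mean 1 and peak deviation `<= amplitude` (see [make_bias_field()]).
#' `amplitude = 0` returns the input unchanged.
#'
#' @param volume 3-D numeric array.
#' @param amplitude Peak field deviation, `>= 0`.
#' @param seed Integer seed.
#' @return The biased volume, with the field attached as attribute
#'   `"bias_field"`.
#' @export
plant_bias_field <- function(volume, amplitude, seed) {
  if (amplitude < 0) stop_invalid("amplitude", "must be >= 0")
  if (amplitude == 0) return(volume)
  field <- make_bias_field(dim(volume), amplitude, seed)
  out <- volume * field
  attr(out, "bias_field") <- field
  out
}

# One synthetic volume: near-constant tissue inside an ellipsoidal "head",
# small smooth texture, additive voxel noise, class-dependent regional
# intensity reduction, then the multiplicative bias field.
make_volume <- function(spec, label, bias_seed) {
  shp <- spec$volume_shape
  head_mask <- region_mask(shp, c(0.5, 0.5, 0.5), c(0.46, 0.46, 0.46))
  x <- (seq_len(shp[1]) - 0.5) / shp[1]
  y <- (seq_len(shp[2]) - 0.5) / shp[2]
  z <- (seq_len(shp[3]) - 0.5) / shp[3]
  ph <- stats::runif(3, 0, 2 * pi)
  tex <- 0.05 * (outer(outer(cos(2 * pi * 2 * x + ph[1]),
                             cos(2 * pi * 2 * y + ph[2]), `+`),
                       cos(2 * pi * 2 * z + ph[3]), `+`) / 3)
  v <- array(0.02, dim = shp)
  v[head_mask] <- 0.75 + tex[head_mask]
  if (spec$signal_mode == "xor") {
    # generic disease effect: both diseases lose mass in the atrophy region
    if (label %in% c("AD", "PD"))
      v[atrophy_region_mask(shp)] <- v[atrophy_region_mask(shp)] * (1 - spec$atrophy_effect)
  } else {
    if (label == "AD")
      v[atrophy_region_mask(shp)] <- v[atrophy_region_mask(shp)] * (1 - spec$atrophy_effect)
    if (label == "PD")
      v[motor_region_mask(shp)] <- v[motor_region_mask(shp)] * (1 - spec$motor_effect)
  }
  v <- v + array(stats::rnorm(prod(shp), sd = spec$noise_sd), dim = shp)
  v <- plant_bias_field(v, spec$bias_amplitude, seed = bias_seed)
  attr(v, "bias_field") <- NULL
  pmax(v, 0)
}

# Pink (1/f) noise via frequency-domain shaping.
pink_noise <- function(n, rms) {
  w <- stats::rnorm(n)
  sp <- stats::fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)          # two-sided frequency index
  sp <- sp / sqrt(f)
  x <- Re(stats::fft(sp, inverse = TRUE)) / n
  x <- x - mean(x)
  x * (rms / stats::sd(x))
}

# One multichannel recording with band-power offsets in dB (power domain).
# `shift_db` is a length-4 vector applied to all channels, or a c x 4 matrix
# of per-channel offsets (localized abnormalities).
make_recording <- function(spec, shift_db) {
  edges <- band_edges()
  base_power <- c(delta = 1.0, theta = 0.8, alpha = 1.0, beta = 0.6)
  tt <- (seq_len(spec$n_timesteps) - 1) / spec$sample_rate
  rec <- matrix(0, nrow = spec$n_timesteps, ncol = spec$n_channels)
  if (!is.matrix(shift_db))
    shift_db <- matrix(shift_db, spec$n_channels, 4, byrow = TRUE)
  for (ch in seq_len(spec$n_channels)) {
    sig <- numeric(spec$n_timesteps)
    for (b in seq_along(edges)) {
      p <- base_power[b] * 10^(shift_db[ch, b] / 10)
      freq <- stats::runif(1, edges[[b]][1], min(edges[[b]][2], spec$sample_rate / 2 - 1))
      phase <- stats::runif(1, 0, 2 * pi)
      sig <- sig + sqrt(2 * p) * sin(2 * pi * freq * tt + phase)
    }
    rec[, ch] <- sig + pink_noise(spec$n_timesteps, rms = 10 * spec$noise_sd)
  }
  rec
}

#' Generate a synthetic tri-modal cohort
#'
#' Draws `spec$n_subjects` subjects with class counts fixed by
#' largest-remainder rounding of `class_proportions`, plants the per-modality
#' class signal described in [cohort_spec()], and assigns each subject a
#' modality-availability mask with `round(n * frac_complete)` complete
#' tri-modal subjects; partial subjects drop each modality independently at
#' random with at least one retained.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `nf_cohort`; each element is a `cohort_sample`
#'   list with fields `subject_id`, `label`, `genotypes` (0/1/2 counts or
#'   `NULL`), `volume` (3-D array or `NULL`), `volumes` (list of all scans),
#'   `recording` (T x c matrix or `NULL`), and `modality_mask` (named logical
#'   3-vector, order SNP, MRI, EEG).  Attributes: `spec`, `risk_loci`
#'   (designated locus indices), `snp_ids`, `background_freqs`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_subjects
    counts <- largest_remainder(n, spec$class_proportions)
    labels <- rep(CLASS_LEVELS, counts)
    labels <- labels[sample.int(n)]         # shuffle subject order

    n_complete <- round(n * spec$frac_complete)
    complete <- rep(FALSE, n)
    complete[sample.int(n, n_complete)] <- TRUE
    masks <- matrix(TRUE, nrow = n, ncol = 3,
                    dimnames = list(NULL, c("SNP", "MRI", "EEG")))
    for (i in which(!complete)) {
      repeat {
        keep <- stats::runif(3) < 0.5
        if (any(keep) && !all(keep)) break
      }
      masks[i, ] <- keep
    }

    risk_loci <- seq_len(spec$n_risk_loci)
    bg_freq <- stats::runif(spec$n_snps, 0.05, 0.5)
    snp_ids <- sprintf("rs%05d", seq_len(spec$n_snps))
    half <- spec$n_risk_loci / 2
    set1 <- risk_loci[seq_len(half)]
    set2 <- risk_loci[half + seq_len(half)]

    samples <- vector("list", n)
    for (i in seq_len(n)) {
      lab <- labels[i]
      diseased <- lab != "HC"
      # latent cross-modal factors (xor mode only)
      G <- if (spec$signal_mode == "xor" && diseased) stats::rbinom(1, 1, 0.5) else NA
      genotypes <- NULL
      if (masks[i, "SNP"]) {
        freq <- bg_freq
        if (spec$signal_mode == "xor") {
          if (diseased) {
            freq[set1] <- 0.15; freq[set2] <- 0.15
            if (G == 0) freq[set1] <- 0.45 else freq[set2] <- 0.45
          } else freq[risk_loci] <- 0.15
        } else {
          freq[risk_loci] <- spec$risk_allele_freqs[, lab]
        }
        genotypes <- stats::rbinom(spec$n_snps, 2, freq)
        names(genotypes) <- snp_ids
      }
      volume <- NULL; volumes <- list()
      if (masks[i, "MRI"]) {
        volumes <- lapply(seq_len(spec$scans_per_subject), function(k)
          make_volume(spec, lab, bias_seed = spec$seed + i * 131L + k))
        volume <- volumes[[1]]
      }
      recording <- NULL
      if (masks[i, "EEG"]) {
        if (spec$signal_mode == "xor") {
          profile <- if (!diseased) "HC" else {
            B <- if (lab == "AD") G else 1 - G
            if (B == 0) "AD" else "PD"       # AD row = delta/theta, PD row = alpha/beta
          }
          shift <- spec$band_shift_db[profile, ]
        } else {
          shift <- spec$band_shift_db[lab, ]
        }
        if (spec$n_shift_channels > 0 && any(shift != 0)) {
          # localized abnormality: only a random channel subset shifted
          active <- sample.int(spec$n_channels, spec$n_shift_channels)
          shift_mat <- matrix(0, spec$n_channels, 4)
          shift_mat[active, ] <- matrix(shift, spec$n_shift_channels, 4,
                                        byrow = TRUE)
          shift <- shift_mat
        }
        recording <- make_recording(spec, shift)
      }
      samples[[i]] <- structure(list(
        subject_id = sprintf("S%04d", i),
        label = lab,
        genotypes = genotypes,
        volume = volume,
        volumes = volumes,
        recording = recording,
        modality_mask = masks[i, ]),
        class = "cohort_sample")
    }
    structure(samples, class = "nf_cohort",
              spec = spec, risk_loci = risk_loci,
              snp_ids = snp_ids, background_freqs = bg_freq)
  })
}

#' @method print nf_cohort
#' @export
print.nf_cohort <- function(x, ...) {
  labs <- vapply(x, `[[`, "", "label")
  cat(sprintf("<nf_cohort> %d subjects (%s); %d complete tri-modal\n",
              length(x),
              paste(sprintf("%s=%d", CLASS_LEVELS, table(factor(labs, CLASS_LEVELS))),
                    collapse = ", "),
              sum(vapply(x, function(s) all(s$modality_mask), TRUE))))
  invisible(x)
}

#' Study conditions for the cross-modal interaction cohort
#'
#' The desk-scale cohort used to probe whether fusion recovers a planted
#' SNP-by-EEG interaction: disease subjects carry risk burden in one of two
#' disjoint 10-locus sets (minor-allele frequency 0.5 versus background
#' 0.1) and one of two band-shift profiles (+4 dB delta/theta or +4 dB
#' alpha/beta) expressed on a random 3-channel subset of the 8 channels
#' (a localized abnormality, so channel relevance varies by subject), with
#' AD versus PD defined by the XOR of the two latent factors; no single
#' modality separates the two diseases, and MRI carries a generic
#' disease-versus-control atrophy signal only.  Volumes are 12^3,
#' recordings 10 s at 100 Hz.
#'
#' @param n_subjects Number of subjects (default 300).
#' @param seed Integer seed.
#' @return A [cohort_spec()].
#' @export
interaction_cohort_spec <- function(n_subjects = 300, seed = 1) {
  cohort_spec(
    n_subjects = n_subjects, volume_shape = c(12L, 12L, 12L),
    n_timesteps = 1000, n_channels = 8, sample_rate = 100,
    n_snps = 60, n_risk_loci = 20,
    risk_allele_freqs = cbind(AD = c(rep(0.5, 10), rep(0.1, 10)),
                              PD = c(rep(0.1, 10), rep(0.5, 10)),
                              HC = rep(0.1, 20)),
    band_shift_db = rbind(AD = c(4, 4, 0, 0), PD = c(0, 0, 4, 4),
                          HC = c(0, 0, 0, 0)),
    n_shift_channels = 3,
    frac_complete = 1, signal_mode = "xor", atrophy_effect = 0.25,
    seed = seed)
}

#' Desk-scale model settings and schedule for the interaction study
#'
#' Configuration used with [interaction_cohort_spec()]: compact branches,
#' SNP principal components capped at 12, dropout 0.3, one in-graph
#' stochastic pass, and a single 45-epoch stage at learning rate 2e-3 with
#' early-stopping patience 15 (the interaction is typically picked up
#' between epochs 15 and 35).
#'
#' @return List with elements `config` ([nf_config()]) and `schedule`.
#' @export
interaction_study_settings <- function() {
  list(config = nf_config(d_k = 16, train_passes = 1, modality_dropout = 0,
                          pca_cap = 12, head_dropout = 0.3, patience = 15),
       schedule = data.frame(stage = 1, lr = 2e-3, batch_size = 32,
                             epochs = 45, dropout = 0.3))
}

#' Cohort labels as a factor
#' @param cohort An `nf_cohort`.
#' @return Factor with levels AD, PD, HC.
#' @export
cohort_labels <- function(cohort) {
  factor(vapply(cohort, `[[`, "", "label"), levels = CLASS_LEVELS)
}
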