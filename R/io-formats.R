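# Readers and writers for the on-disk formats the framework touches:
# NIfTI volumes (via RNifti), EDF recordings (minimal EDF subset implemented
# here: no R EDF package is available), VCF v4.2 genotypes (read via vcfR,
# written as plain biallelic text), CSV genotype-count tables, and the
# cohort manifest.

#' Read a NIfTI volume
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return 3-D numeric array with attribute `voxel_size` (mm per axis).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3)
    stop(sprintf("expected a 3-D volume, got %d dimensions", length(dim(img))),
         call. = FALSE)
  v <- array(as.numeric(img), dim = dim(img))
  if (!all(is.finite(v))) stop("volume contains non-finite values", call. = FALSE)
  attr(v, "voxel_size") <- RNifti::pixdim(img)
  v
}

#' Write a volume as NIfTI
#'
#' @param volume 3-D numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size Numeric 3-vector of voxel edge lengths in mm.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, voxel_size = c(1, 1, 1)) {
  stopifnot(length(dim(volume)) == 3)
  volume <- array(as.numeric(volume), dim = dim(volume))
  attr(volume, "pixdim") <- voxel_size
  RNifti::writeNifti(RNifti::asNifti(volume), path, datatype = "double")
  invisible(path)
}

pad_field <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a multichannel recording as EDF
#'
#' Writes a minimal EDF file (one data record spanning the full recording,
#' 16-bit samples, per-channel physical scaling).  All channels share one
#' sample rate.
#'
#' @param recording T x c numeric matrix (time steps x channels).
#' @param path Output path.
#' @param sample_rate Sampling rate in Hz.
#' @param channel_labels Optional character vector of channel names.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, sample_rate,
                      channel_labels = NULL) {
  recording <- as.matrix(recording)
  nt <- nrow(recording); nc <- ncol(recording)
  if (is.null(channel_labels))
    channel_labels <- sprintf("CH%02d", seq_len(nc))
  stopifnot(length(channel_labels) == nc)
  duration <- nt / sample_rate
  pmin <- apply(recording, 2, min); pmax <- apply(recording, 2, max)
  flat <- pmax - pmin < 1e-12       # constant channels: avoid zero span
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),                       # version
    pad_field("X X X X", 80),                # patient id
    pad_field("Startdate X X X X", 80),      # recording id
    pad_field("01.01.26", 8), pad_field("00.00.00", 8),
    pad_field(256 * (nc + 1), 8),            # header bytes
    pad_field("", 44),                       # reserved
    pad_field(1, 8),                         # number of data records
    pad_field(format(duration, digits = 7), 8),
    pad_field(nc, 4))
  writeChar(hdr, con, eos = NULL)
  per <- function(vals, width)
    writeChar(paste0(vapply(vals, pad_field, "", width = width), collapse = ""),
              con, eos = NULL)
  per(channel_labels, 16)
  per(rep("", nc), 80)                       # transducer
  per(rep("uV", nc), 8)                      # physical dimension
  per(formatC(pmin, digits = 7, format = "g"), 8)
  per(formatC(pmax, digits = 7, format = "g"), 8)
  per(rep(dmin, nc), 8)
  per(rep(dmax, nc), 8)
  per(rep("", nc), 80)                       # prefiltering
  per(rep(nt, nc), 8)                        # samples per record
  per(rep("", nc), 32)                       # reserved
  # data record: channel-blocked int16
  for (ch in seq_len(nc)) {
    dig <- round((recording[, ch] - pmin[ch]) / (pmax[ch] - pmin[ch]) *
                   (dmax - dmin) + dmin)
    writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

read_edf_header_num <- function(con, width) {
  as.numeric(trimws(readChar(con, width)))
}

#' Read an EDF recording
#'
#' Supports the EDF subset written by [write_edf()] plus multi-record files
#' with a uniform sample rate across channels.
#'
#' @param path Path to an `.edf` file.
#' @return T x c numeric matrix with attributes `sample_rate` and
#'   `channel_labels`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 8)                            # version
  readChar(con, 80); readChar(con, 80)        # patient / recording id
  readChar(con, 8); readChar(con, 8)          # date / time
  readChar(con, 8)                            # header bytes
  readChar(con, 44)
  n_rec <- read_edf_header_num(con, 8)
  rec_dur <- read_edf_header_num(con, 8)
  nc <- as.integer(read_edf_header_num(con, 4))
  labels <- trimws(vapply(seq_len(nc), function(i) readChar(con, 16), ""))
  for (i in seq_len(nc)) readChar(con, 80)    # transducer
  for (i in seq_len(nc)) readChar(con, 8)     # physical dim
  pmin <- vapply(seq_len(nc), function(i) read_edf_header_num(con, 8), 0)
  pmax <- vapply(seq_len(nc), function(i) read_edf_header_num(con, 8), 0)
  dmin <- vapply(seq_len(nc), function(i) read_edf_header_num(con, 8), 0)
  dmax <- vapply(seq_len(nc), function(i) read_edf_header_num(con, 8), 0)
  for (i in seq_len(nc)) readChar(con, 80)    # prefiltering
  spr <- vapply(seq_len(nc), function(i) read_edf_header_num(con, 8), 0)
  for (i in seq_len(nc)) readChar(con, 32)
  if (length(unique(spr)) != 1)
    stop("unsupported EDF: channels have mixed sample rates", call. = FALSE)
  spr <- spr[1]
  fs <- spr / rec_dur
  out <- matrix(0, nrow = spr * n_rec, ncol = nc)
  for (r in seq_len(n_rec)) {
    rows <- (r - 1) * spr + seq_len(spr)
    for (ch in seq_len(nc)) {
      dig <- readBin(con, integer(), n = spr, size = 2, endian = "little",
                     signed = TRUE)
      out[rows, ch] <- pmin[ch] + (dig - dmin[ch]) *
        (pmax[ch] - pmin[ch]) / (dmax[ch] - dmin[ch])
    }
  }
  attr(out, "sample_rate") <- fs
  attr(out, "channel_labels") <- labels
  out
}

#' Write a cohort genotype matrix as VCF v4.2
#'
#' Biallelic sites only; genotype counts are minor (ALT) allele counts, so
#' 0 -> `0/0` (AA), 1 -> `0/1` (AG), 2 -> `1/1` (GG).
#'
#' @param G Subjects x SNP matrix of 0/1/2 counts (`NA` allowed, written as
#'   `./.`); rownames are subject IDs, colnames SNP IDs.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, path) {
  G <- as.matrix(G)
  ids <- colnames(G) %||% sprintf("rs%05d", seq_len(ncol(G)))
  subj <- rownames(G) %||% sprintf("S%04d", seq_len(nrow(G)))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", subj), collapse = "\t"))
  body <- vapply(seq_len(ncol(G)), function(j) {
    g <- G[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    paste(c("1", j, ids[j], "A", "G", ".", "PASS", ".", "GT", gt),
          collapse = "\t")
  }, "")
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a genotype matrix
#'
#' @param path Path to a VCF (v4.2, biallelic) or a CSV count table whose
#'   first column is `subject_id` and remaining columns are SNP IDs with
#'   values 0/1/2 (or empty/NA for missing).
#' @param format `"vcf"` or `"table"`.
#' @param strict If `TRUE`, multiallelic VCF sites or out-of-range table
#'   cells raise an error; otherwise multiallelic sites are skipped with a
#'   warning.
#' @return Subjects x SNP integer matrix (entries 0/1/2 or `NA`), rownames
#'   subject IDs, colnames SNP IDs.
#' @export
read_genotypes <- function(path, format = c("vcf", "table"), strict = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
    if (any(multi)) {
      if (strict)
        stop(sprintf("multiallelic site(s) at %s",
                     paste(fix[multi, "ID"], collapse = ", ")), call. = FALSE)
      warning(sprintf("skipping %d multiallelic site(s)", sum(multi)))
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gt[!multi, , drop = FALSE]
    ids <- unname(fix[!multi, "ID"])
    counts <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt),
                     dimnames = list(colnames(gt), ids))
    clean <- gsub("|", "/", gt, fixed = TRUE)
    map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
    for (j in seq_len(nrow(gt)))
      counts[, j] <- unname(map[clean[j, ]])
    counts
  } else {
    tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (names(tab)[1] != "subject_id")
      stop("genotype table must have 'subject_id' as first column", call. = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(m) <- "numeric"
    bad <- !is.na(m) & !m %in% c(0, 1, 2)
    if (any(bad)) {
      if (strict)
        stop(sprintf("genotype table contains non-{0,1,2} value at [%d, %d]",
                     which(bad, arr.ind = TRUE)[1, 1],
                     which(bad, arr.ind = TRUE)[1, 2]), call. = FALSE)
      m[bad] <- NA
    }
    storage.mode(m) <- "integer"
    rownames(m) <- tab$subject_id
    m
  }
}

mask_to_string <- function(mask) paste(as.integer(mask), collapse = "")
string_to_mask <- function(s) {
  m <- as.integer(strsplit(s, "")[[1]]) == 1L
  names(m) <- c("SNP", "MRI", "EEG")
  m
}

#' Write cohort fixtures to disk
#'
#' Writes each subject's volume as NIfTI and recording as EDF, the cohort
#' genotype matrix as both VCF and a CSV count table, and a manifest CSV
#' with columns `subject_id,label,snp_path,mri_path,eeg_path,mask` (mask is
#' a 3-character 0/1 string in SNP, MRI, EEG order).  Missing modalities get
#' empty path cells.
#'
#' @param cohort An `nf_cohort`.
#' @param out_dir Output directory (created if needed).
#' @return Path to the manifest CSV, invisibly.
#' @export
write_fixtures <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  spec <- attr(cohort, "spec")
  snp_ids <- attr(cohort, "snp_ids")

  has_snp <- vapply(cohort, function(s) s$modality_mask[["SNP"]], TRUE)
  snp_path <- vcf_path <- ""
  if (any(has_snp)) {
    G <- do.call(rbind, lapply(cohort[has_snp], `[[`, "genotypes"))
    rownames(G) <- vapply(cohort[has_snp], `[[`, "", "subject_id")
    colnames(G) <- snp_ids %||% colnames(G)
    snp_path <- file.path(out_dir, "genotypes.csv")
    utils::write.csv(data.frame(subject_id = rownames(G), G,
                                check.names = FALSE),
                     snp_path, row.names = FALSE)
    vcf_path <- file.path(out_dir, "genotypes.vcf")
    write_vcf(G, vcf_path)
  }

  rows <- lapply(cohort, function(s) {
    mri_path <- eeg_path <- ""
    if (s$modality_mask[["MRI"]]) {
      mri_path <- file.path(out_dir, paste0(s$subject_id, ".nii"))
      write_volume(s$volume, mri_path)
    }
    if (s$modality_mask[["EEG"]]) {
      eeg_path <- file.path(out_dir, paste0(s$subject_id, ".edf"))
      write_edf(s$recording, eeg_path,
                sample_rate = if (is.null(spec)) 100 else spec$sample_rate)
    }
    data.frame(subject_id = s$subject_id, label = s$label,
               snp_path = if (s$modality_mask[["SNP"]]) snp_path else "",
               mri_path = mri_path, eeg_path = eeg_path,
               mask = mask_to_string(s$modality_mask),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read and validate a cohort manifest
#'
#' @param path Manifest CSV written by [write_fixtures()] (columns
#'   `subject_id,label,snp_path,mri_path,eeg_path,mask`).
#' @return A data.frame with a parsed logical `mask` column replaced by
#'   columns `has_snp`, `has_mri`, `has_eeg`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(mask = "character"))
  need <- c("subject_id", "label", "snp_path", "mri_path", "eeg_path", "mask")
  if (!all(need %in% names(m)))
    stop("manifest missing columns: ",
         paste(setdiff(need, names(m)), collapse = ", "), call. = FALSE)
  if (anyDuplicated(m$subject_id))
    stop("duplicate subject IDs in manifest", call. = FALSE)
  check_label(m$label)
  masks <- t(vapply(m$mask, string_to_mask, logical(3)))
  for (col in c("snp_path", "mri_path", "eeg_path")) {
    p <- as.character(m[[col]])
    p[is.na(p)] <- ""
    m[[col]] <- p
    missing <- nzchar(p) & !file.exists(p)
    if (any(missing))
      stop("manifest lists nonexistent file(s): ",
           paste(utils::head(p[missing], 3), collapse = ", "), call. = FALSE)
  }
  m$has_snp <- masks[, "SNP"]; m$has_mri <- masks[, "MRI"]
  m$has_eeg <- masks[, "EEG"]
  m
}
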