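# PSM collapse and equal-loading median normalization.

#' Collapse PSMs to peptide ions
#'
#' A peptide ion is a (peptide_sequence, modifications, charge) combination.
#' When an ion is measured by several PSMs in a sample, only the maximum
#' intensity is kept; the kept value is then log2-transformed.  Zero and
#' missing intensities are treated as missing (log2 of zero is undefined).
#'
#' @param psms a `psm_table` (see [read_psm_table()]).
#' @param keep_shared if `FALSE` (default) an ion mapped to more than one
#'   protein accession across its PSM rows raises an ambiguity error; if
#'   `TRUE` such ions are kept with their accessions joined by `";"` and
#'   flagged, to be excluded from protein summarization.
#' @return a `peptide_matrix`: list with `log2` (ion-by-sample numeric
#'   matrix), `features` (data.frame of ion annotations, including a
#'   `shared` flag), and `normalized` (logical).
#' @export
collapse_psms <- function(psms, keep_shared = FALSE) {
  stopifnot(inherits(psms, "psm_table") || is.data.frame(psms))
  sample_cols <- setdiff(names(psms), PSM_KEY_COLS)
  if (length(sample_cols) == 0) stop("PSM table has no intensity columns")

  ion_id <- paste(psms$peptide_sequence, psms$modifications, psms$charge,
                  sep = "\r")
  ions <- !duplicated(ion_id)
  ion_levels <- ion_id[ions]

  # protein mapping must be unique per ion (unless shared handling is on)
  acc_by_ion <- tapply(psms$protein_accession, factor(ion_id, ion_levels),
                       function(a) sort(unique(a)), simplify = FALSE)
  n_acc <- vapply(acc_by_ion, length, integer(1))
  if (any(n_acc > 1) && !keep_shared) {
    first_bad <- ion_levels[which(n_acc > 1)[1]]
    stop("peptide ion '", gsub("\r", "/", first_bad),
         "' maps to multiple protein accessions; ",
         "enable keep_shared to retain shared peptides")
  }
  accession <- vapply(acc_by_ion, paste, character(1), collapse = ";")
  shared <- n_acc > 1 | grepl(";", accession, fixed = TRUE)

  f <- factor(ion_id, ion_levels)
  log2m <- matrix(NA_real_, length(ion_levels), length(sample_cols),
                  dimnames = list(NULL, sample_cols))
  for (s in sample_cols) {
    v <- psms[[s]]
    v[!is.na(v) & v <= 0] <- NA  # zeros are missing
    mx <- suppressWarnings(tapply(v, f, max, na.rm = TRUE))
    mx[!is.finite(mx)] <- NA
    log2m[, s] <- log2(as.numeric(mx))
  }

  features <- data.frame(
    peptide_sequence = psms$peptide_sequence[ions],
    modifications = psms$modifications[ions],
    charge = psms$charge[ions],
    protein_accession = as.character(accession),
    shared = as.logical(shared),
    stringsAsFactors = FALSE)
  rownames(log2m) <- paste(features$peptide_sequence, features$modifications,
                           features$charge, sep = "_")

  structure(list(log2 = log2m, features = features, normalized = FALSE),
            class = "peptide_matrix")
}

#' Median-normalize a peptide matrix under the equal-loading assumption
#'
#' Aligns every sample's median log2 intensity to the global target median,
#' defined as the median of the per-sample medians.  Missing cells are left
#' untouched.  The operation is idempotent and removes any per-sample
#' additive (log2) loading offset exactly.
#'
#' @param m a `peptide_matrix` from [collapse_psms()].
#' @return the normalized `peptide_matrix` (with `normalized = TRUE`).
#' @export
median_normalize <- function(m) {
  stopifnot(inherits(m, "peptide_matrix"))
  x <- m$log2
  n_obs <- colSums(!is.na(x))
  if (any(n_obs == 0)) {
    stop("sample(s) with no observed intensities: ",
         paste(colnames(x)[n_obs == 0], collapse = ", "))
  }
  sample_medians <- apply(x, 2, stats::median, na.rm = TRUE)
  target <- stats::median(sample_medians)
  m$log2 <- sweep(x, 2, sample_medians - target)
  m$normalized <- TRUE
  m
}

#' @export
print.peptide_matrix <- function(x, ...) {
  cat("peptide_matrix: ", nrow(x$log2), " peptide ions x ", ncol(x$log2),
      " samples; ", sum(x$features$shared), " shared; ",
      if (x$normalized) "normalized" else "not normalized", "\n", sep = "")
  invisible(x)
}
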