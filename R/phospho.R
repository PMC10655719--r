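# Phospho-to-protein fold-change normalization and counting of regulated
# phosphopeptides.  Subtracting the parent protein's log2FC from a
# phosphopeptide's log2FC separates site-level regulation from a change in
# total protein abundance.

#' Normalize phosphopeptide fold changes to their parent protein
#'
#' Matches each phosphopeptide record to the protein record with the same
#' (`protein_accession`, `contrast`) and subtracts the protein's log2FC.
#' Phosphopeptides whose parent protein was not quantified are retained
#' unadjusted and flagged `unmatched` (their parent may simply not have been
#' identified in the global proteome).  Peptides mapping to more than one
#' protein are flagged `ambiguous` and not adjusted.
#'
#' @param phospho data.frame of phosphopeptide differential records with
#'   columns `feature_id`, `protein_accession`, `contrast`, `log2fc`.
#' @param proteins data.frame of protein differential records with columns
#'   `feature_id`, `contrast`, `log2fc`.
#' @return data.frame with `peptide_id`, `protein_accession`, `contrast`,
#'   `raw_log2fc`, `protein_log2fc`, `adjusted_log2fc`, `status`.
#' @export
adjust_phospho <- function(phospho, proteins) {
  for (col in c("feature_id", "protein_accession", "contrast", "log2fc")) {
    if (!col %in% names(phospho)) {
      stop("phospho records are missing column '", col, "'")
    }
  }
  for (col in c("feature_id", "contrast", "log2fc")) {
    if (!col %in% names(proteins)) {
      stop("protein records are missing column '", col, "'")
    }
  }
  missing_contrasts <- setdiff(unique(phospho$contrast),
                               unique(proteins$contrast))
  if (length(missing_contrasts) > 0) {
    stop("contrast(s) present in phospho but absent in proteins: ",
         paste(missing_contrasts, collapse = ", "))
  }

  key <- paste(proteins$feature_id, proteins$contrast, sep = "\r")
  prot_fc <- stats::setNames(proteins$log2fc, key)

  ambiguous <- grepl(";", phospho$protein_accession, fixed = TRUE)
  match_key <- paste(phospho$protein_accession, phospho$contrast, sep = "\r")
  pfc <- unname(prot_fc[match_key])
  status <- ifelse(ambiguous, "ambiguous",
                   ifelse(is.na(pfc), "unmatched", "adjusted"))
  adjusted <- ifelse(status == "adjusted", phospho$log2fc - pfc,
                     phospho$log2fc)
  data.frame(peptide_id = phospho$feature_id,
             protein_accession = phospho$protein_accession,
             contrast = phospho$contrast,
             raw_log2fc = phospho$log2fc,
             protein_log2fc = ifelse(status == "adjusted", pfc, NA_real_),
             adjusted_log2fc = adjusted,
             status = status,
             stringsAsFactors = FALSE)
}

#' Count phosphopeptides with at least a threshold-fold adjusted change
#'
#' The default threshold of 1 on the absolute adjusted log2FC counts
#' peptides with at least a twofold increase or decrease in phosphorylation
#' after protein-level normalization.  The boundary is inclusive.
#'
#' @param records output of [adjust_phospho()].
#' @param threshold positive absolute log2FC cutoff.
#' @param drop_unmatched if `TRUE`, records with status `unmatched` (and
#'   `ambiguous`) are excluded before counting.
#' @return data.frame per contrast with `n_total`, `n_changed`, `n_up`,
#'   `n_down`.
#' @export
count_changed <- function(records, threshold = 1.0, drop_unmatched = FALSE) {
  if (threshold <= 0) stop("threshold must be positive")
  if (nrow(records) == 0) {
    return(data.frame(contrast = character(0), n_total = integer(0),
                      n_changed = integer(0), n_up = integer(0),
                      n_down = integer(0), stringsAsFactors = FALSE))
  }
  if (drop_unmatched) {
    records <- records[records$status == "adjusted", , drop = FALSE]
  }
  contrasts <- unique(records$contrast)
  out <- lapply(contrasts, function(cc) {
    r <- records[records$contrast == cc, , drop = FALSE]
    up <- sum(r$adjusted_log2fc >= threshold, na.rm = TRUE)
    down <- sum(r$adjusted_log2fc <= -threshold, na.rm = TRUE)
    data.frame(contrast = cc, n_total = nrow(r), n_changed = up + down,
               n_up = up, n_down = down, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
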