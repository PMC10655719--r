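#' Construct and validate a sample design
#'
#' A sample design maps TMT channels to biological samples and carries the
#' experimental factors (cell line, treatment, timepoint, replicate) from
#' which condition labels are derived.  Exactly one condition must be marked
#' as the reference; every contrast downstream is taken against it.
#'
#' @param df data.frame with columns `sample_id`, `channel`, `cell_line`,
#'   `treatment`, `timepoint_h`, `replicate`, `is_reference`.
#' @return A `sample_design` data.frame with a derived `condition` column and
#'   a `"reference"` attribute naming the reference condition.
#' @examples
#' des <- default_16plex_design()
#' reference_condition(des)
#' @export
sample_design <- function(df) {
  required <- c("sample_id", "channel", "cell_line", "treatment",
                "timepoint_h", "replicate", "is_reference")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("design is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$sample_id <- as.character(df$sample_id)
  df$channel <- as.character(df$channel)
  df$cell_line <- as.character(df$cell_line)
  df$treatment <- as.character(df$treatment)
  df$timepoint_h <- as.numeric(df$timepoint_h)
  df$replicate <- as.integer(df$replicate)
  df$is_reference <- as.logical(df$is_reference)

  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in design: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  if (anyDuplicated(df$channel)) {
    stop("duplicate channel in design: ",
         paste(unique(df$channel[duplicated(df$channel)]), collapse = ", "))
  }
  if (any(is.na(df$timepoint_h)) || any(df$timepoint_h < 0)) {
    stop("timepoint_h must be non-negative numbers")
  }
  if (any(is.na(df$replicate)) || any(df$replicate < 1)) {
    stop("replicate must be positive integers")
  }
  df$condition <- condition_label(df$cell_line, df$treatment, df$timepoint_h)

  ref_conditions <- unique(df$condition[df$is_reference])
  if (length(ref_conditions) == 0) {
    stop("design must mark exactly one reference condition; none found")
  }
  if (length(ref_conditions) > 1) {
    stop("design marks more than one reference condition: ",
         paste(ref_conditions, collapse = ", "))
  }
  # the reference flag must be consistent within its condition
  in_ref <- df$condition == ref_conditions
  if (any(in_ref & !df$is_reference)) {
    stop("all samples of the reference condition must have is_reference = TRUE")
  }
  attr(df, "reference") <- ref_conditions
  class(df) <- c("sample_design", "data.frame")
  df
}

#' Derive a condition label from experimental factors
#'
#' Pure function of (cell_line, treatment, timepoint_h); replicate does not
#' enter the label.  Timepoints are printed without trailing zeros so that
#' `14` and `14.0` give the same label.
#'
#' @param cell_line,treatment character vectors.
#' @param timepoint_h numeric vector of hours.
#' @return character vector of labels like `"iDUX4_dox_14h"`.
#' @export
condition_label <- function(cell_line, treatment, timepoint_h) {
  tp <- vapply(as.numeric(timepoint_h), function(x) {
    format(x, trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
  }, character(1))
  paste0(cell_line, "_", treatment, "_", tp, "h")
}

#' @rdname sample_design
#' @param design a `sample_design`.
#' @export
reference_condition <- function(design) {
  ref <- attr(design, "reference")
  if (is.null(ref)) stop("not a validated sample_design (no reference attribute)")
  ref
}

#' Read a sample design from a tab-separated file
#'
#' Expects columns `sample_id`, `channel`, `cell_line`, `treatment`,
#' `timepoint_h`, `replicate`, `is_reference` (TRUE/FALSE).
#'
#' @param path path to the TSV file.
#' @return a validated [sample_design()].
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  sample_design(df)
}

#' Write a sample design to a tab-separated file
#' @param design a `sample_design`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  out <- as.data.frame(design)
  out$condition <- NULL
  write_tsv_impl(out, path)
}

#' The default single-batch 16-plex design
#'
#' Two cell lines (WT and iDUX4, the doxycycline-inducible DUX4 myoblast
#' line) crossed with four treatments (DMSO for 14 h; doxycycline for 2, 6
#' and 14 h) at two replicates per condition fill one TMTpro 16-plex.
#' DMSO-treated iDUX4 myoblasts are the reference condition.
#'
#' @return a [sample_design()] with 16 samples.
#' @export
default_16plex_design <- function() {
  channels <- c("126", "127N", "127C", "128N", "128C", "129N", "129C",
                "130N", "130C", "131N", "131C", "132N", "132C", "133N",
                "133C", "134N")
  grid <- expand.grid(replicate = 1:2,
                      timepoint_h = c(14, 2, 6, 14),
                      treatment = c("DMSO", "dox"),
                      cell_line = c("iDUX4", "WT"),
                      stringsAsFactors = FALSE)
  # DMSO arm exists only at 14 h: drop the DMSO rows at 2 and 6 h
  grid <- grid[!(grid$treatment == "DMSO" & grid$timepoint_h != 14), ]
  grid <- grid[!duplicated(grid[c("cell_line", "treatment", "timepoint_h",
                                  "replicate")]), ]
  grid <- grid[order(grid$cell_line, grid$treatment, grid$timepoint_h,
                     grid$replicate), ]
  n <- nrow(grid)
  stopifnot(n == 16L)
  df <- data.frame(
    sample_id = sprintf("%s_%s_%sh_r%d", grid$cell_line, grid$treatment,
                        format(grid$timepoint_h, trim = TRUE,
                               drop0trailing = TRUE),
                        grid$replicate),
    channel = channels[seq_len(n)],
    cell_line = grid$cell_line,
    treatment = grid$treatment,
    timepoint_h = grid$timepoint_h,
    replicate = grid$replicate,
    is_reference = grid$cell_line == "iDUX4" & grid$treatment == "DMSO",
    stringsAsFactors = FALSE
  )
  sample_design(df)
}

#' Significance thresholds used for classification and splicing counting
#'
#' Defaults follow the conventions of inducible-DUX4 multi-omic studies:
#' RNA calls need FDR < 0.05 and |log2FC| > 1, protein calls FDR < 0.1 and
#' |log2FC| > 1 (both strict), phosphopeptides need at least a twofold
#' adjusted change (inclusive), and a splicing event is significant when the
#' posterior probability of a >= 20% PSI change exceeds 0.95 (strict).
#'
#' @param rna_fdr,protein_fdr FDR gates for RNA and protein calls.
#' @param rna_abs_log2fc,protein_abs_log2fc,phospho_abs_log2fc absolute
#'   log2 fold-change gates.
#' @param dpsi_threshold minimum |delta PSI| defining a splicing change.
#' @param dpsi_confidence posterior-probability gate for splicing calls.
#' @return a named list of class `significance_thresholds`.
#' @export
significance_thresholds <- function(rna_fdr = 0.05, rna_abs_log2fc = 1,
                                    protein_fdr = 0.1, protein_abs_log2fc = 1,
                                    phospho_abs_log2fc = 1,
                                    dpsi_threshold = 0.20,
                                    dpsi_confidence = 0.95) {
  th <- list(rna_fdr = rna_fdr, rna_abs_log2fc = rna_abs_log2fc,
             protein_fdr = protein_fdr, protein_abs_log2fc = protein_abs_log2fc,
             phospho_abs_log2fc = phospho_abs_log2fc,
             dpsi_threshold = dpsi_threshold,
             dpsi_confidence = dpsi_confidence)
  for (nm in c("rna_fdr", "protein_fdr", "dpsi_threshold", "dpsi_confidence")) {
    v <- th[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0 || v > 1) {
      stop(nm, " must be a single number in (0, 1]")
    }
  }
  for (nm in c("rna_abs_log2fc", "protein_abs_log2fc", "phospho_abs_log2fc")) {
    v <- th[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0) {
      stop(nm, " must be a single positive number")
    }
  }
  class(th) <- "significance_thresholds"
  th
}
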