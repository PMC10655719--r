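# Tabular input/output shared by every stage.  All files are plain
# tab-separated text; numeric columns are written with enough significant
# digits that read(write(x)) round-trips losslessly in practice.

PSM_KEY_COLS <- c("peptide_sequence", "modifications", "charge",
                  "protein_accession")

#' Read a PSM-level reporter-intensity table
#'
#' The file must be tab-separated with the four identification columns
#' (`peptide_sequence`, `modifications`, `charge`, `protein_accession`)
#' followed by one intensity column per designed sample.  Empty cells are
#' missing values; zeros are kept here and treated as missing at collapse
#' time (log2 of zero is undefined).
#'
#' @param path path to the TSV file.
#' @param design a [sample_design()]; every `sample_id` must appear as a
#'   column in the file.
#' @return a `psm_table` data.frame.
#' @export
read_psm_table <- function(path, design) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = NA)
  missing_cols <- setdiff(PSM_KEY_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop("PSM table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("peptide_sequence", "modifications", "protein_accession")) {
    v <- as.character(df[[col]])
    v[is.na(v)] <- ""   # an empty modifications field means unmodified
    df[[col]] <- v
  }
  absent <- setdiff(design$sample_id, names(df))
  if (length(absent) > 0) {
    stop("PSM table has no intensity column for designed sample(s): ",
         paste(absent, collapse = ", "))
  }
  for (s in design$sample_id) {
    v <- df[[s]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- !is.na(v) & v != "" & is.na(vn)
      if (any(bad)) {
        stop("non-numeric intensity in column '", s, "' at row ",
             which(bad)[1])
      }
      v <- vn
    }
    if (any(v < 0, na.rm = TRUE)) {
      stop("negative intensity in column '", s, "' at row ",
           which(v < 0)[1])
    }
    df[[s]] <- v
  }
  psm_table(df[c(PSM_KEY_COLS, design$sample_id)])
}

#' @rdname read_psm_table
#' @param df a data.frame holding PSM rows.
#' @export
psm_table <- function(df) {
  missing_cols <- setdiff(PSM_KEY_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop("PSM table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$charge <- as.integer(df$charge)
  if (any(is.na(df$charge)) || any(df$charge < 1)) {
    stop("charge must be a positive integer")
  }
  sample_cols <- setdiff(names(df), PSM_KEY_COLS)
  for (s in sample_cols) {
    if (any(df[[s]] < 0, na.rm = TRUE)) {
      stop("negative intensity in column '", s, "'")
    }
  }
  class(df) <- c("psm_table", "data.frame")
  df
}

#' Write a PSM table to a tab-separated file
#' @param psms a `psm_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  write_tsv_impl(psms, path)
}

# Shared TSV writer: missing values as empty fields, no quoting, numbers at
# full precision (15 significant digits).
write_tsv_impl <- function(df, path) {
  out <- as.data.frame(df, stringsAsFactors = FALSE)
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      v <- sprintf("%.15g", out[[j]])
      v[is.na(out[[j]])] <- NA_character_
      out[[j]] <- v
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Write / read a feature-by-sample log2 intensity matrix
#'
#' The first column holds the feature identifier; remaining columns are
#' samples.  Used for both protein matrices and flattened peptide matrices.
#'
#' @param m numeric matrix with feature rownames and sample colnames.
#' @param path file path.
#' @param id_col name for the identifier column.
#' @return `write_matrix_tsv` returns `path` invisibly; `read_matrix_tsv`
#'   returns a numeric matrix.
#' @export
write_matrix_tsv <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv_impl(df, path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  m <- as.matrix(df[-1])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Write / read a differential-result table
#'
#' Columns: `feature_id`, `contrast`, `log2fc`, `se`, `t`, `df`, `p`, `q`,
#' plus any extra annotation columns (e.g. `protein_accession` for
#' peptide-level results).
#'
#' @param records a data.frame of differential records.
#' @param path file path.
#' @return `write_differential_table` returns `path` invisibly;
#'   `read_differential_table` returns the data.frame.
#' @export
write_differential_table <- function(records, path) {
  write_tsv_impl(records, path)
}

#' @rdname write_differential_table
#' @export
read_differential_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  needed <- c("feature_id", "contrast", "log2fc")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("differential table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df
}
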