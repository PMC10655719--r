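# Tukey median polish and peptide-to-protein summarization.

#' Tukey median polish of a two-way table
#'
#' Decomposes `y[i, j] ~ overall + row[i] + col[j] + residual[i, j]` by
#' alternately sweeping out row medians then column medians (rows first),
#' with medians taken over observed entries only.  Iteration stops when the
#' change in the sum of absolute residuals is at most `tol`, or after
#' `max_iter` sweeps.  Effects are centered so that the median of the row
#' effects and of the column effects is absorbed into the overall term.
#'
#' @param y numeric matrix; `NA`s allowed but no all-missing row or column.
#' @param tol convergence tolerance on the change in sum(|residual|).
#' @param max_iter maximum number of row+column sweep iterations.
#' @return list of class `median_polish` with `overall`, `row_effects`,
#'   `column_effects`, `residuals`, `n_iterations`, `converged`.
#' @examples
#' fit <- median_polish(matrix(c(1, 3, 4, 6), 2, 2))
#' fit$overall + fit$column_effects  # per-column summary
#' @export
median_polish <- function(y, tol = 1e-4, max_iter = 20L) {
  y <- as.matrix(y)
  storage.mode(y) <- "double"
  if (nrow(y) < 1 || ncol(y) < 1) stop("matrix must have >= 1 row and column")
  row_missing <- rowSums(!is.na(y)) == 0
  if (any(row_missing)) {
    stop("all-missing row(s): ",
         paste(if (is.null(rownames(y))) which(row_missing)
               else rownames(y)[row_missing], collapse = ", "))
  }
  col_missing <- colSums(!is.na(y)) == 0
  if (any(col_missing)) {
    stop("all-missing column(s): ",
         paste(if (is.null(colnames(y))) which(col_missing)
               else colnames(y)[col_missing], collapse = ", "))
  }

  z <- y
  row_eff <- rep(0, nrow(y))
  col_eff <- rep(0, ncol(y))
  overall <- 0
  oldsum <- sum(abs(z), na.rm = TRUE)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    rdelta <- apply(z, 1, stats::median, na.rm = TRUE)
    z <- z - rdelta
    row_eff <- row_eff + rdelta
    cmed <- stats::median(col_eff)
    overall <- overall + cmed
    col_eff <- col_eff - cmed

    cdelta <- apply(z, 2, stats::median, na.rm = TRUE)
    z <- sweep(z, 2, cdelta)
    col_eff <- col_eff + cdelta
    rmed <- stats::median(row_eff)
    overall <- overall + rmed
    row_eff <- row_eff - rmed

    newsum <- sum(abs(z), na.rm = TRUE)
    if (abs(oldsum - newsum) <= tol) {
      converged <- TRUE
      break
    }
    oldsum <- newsum
  }
  # final centering: medians of effects absorbed into the overall term
  rmed <- stats::median(row_eff)
  overall <- overall + rmed
  row_eff <- row_eff - rmed
  cmed <- stats::median(col_eff)
  overall <- overall + cmed
  col_eff <- col_eff - cmed
  names(row_eff) <- rownames(y)
  names(col_eff) <- colnames(y)
  dimnames(z) <- dimnames(y)

  structure(list(overall = overall, row_effects = row_eff,
                 column_effects = col_eff, residuals = z,
                 n_iterations = iter, converged = converged),
            class = "median_polish")
}

#' @export
print.median_polish <- function(x, ...) {
  cat("median polish: overall ", format(x$overall), ", ",
      length(x$row_effects), " rows x ", length(x$column_effects),
      " columns, ", x$n_iterations, " iterations",
      if (x$converged) " (converged)" else " (max_iter reached)", "\n",
      sep = "")
  invisible(x)
}

#' Summarize peptide ions to protein log2 intensities
#'
#' For each protein, runs [median_polish()] on its peptide-by-sample log2
#' submatrix; the protein's summary in a sample is `overall + column
#' effect`, so constant per-peptide ionization offsets are absorbed into row
#' effects and do not move the summary.  Single-peptide proteins pass
#' through unchanged.  Samples in which none of a protein's peptides were
#' observed get a missing summary.  Shared peptide ions are excluded unless
#' `include_shared = TRUE`.
#'
#' @param m a normalized `peptide_matrix` (see [median_normalize()]).
#' @param tol,max_iter passed to [median_polish()].
#' @param include_shared include peptide ions mapped to multiple proteins
#'   (each such ion is used for every protein it maps to).
#' @return numeric protein-by-sample matrix of log2 summaries.
#' @export
summarize_proteins <- function(m, tol = 1e-4, max_iter = 20L,
                               include_shared = FALSE) {
  stopifnot(inherits(m, "peptide_matrix"))
  if (!isTRUE(m$normalized)) {
    stop("peptide matrix must be median-normalized before summarization")
  }
  feats <- m$features
  x <- m$log2
  if (include_shared) {
    # expand shared ions: one copy per mapped protein
    acc_list <- strsplit(feats$protein_accession, ";", fixed = TRUE)
    idx <- rep(seq_len(nrow(feats)), lengths(acc_list))
    acc <- unlist(acc_list)
  } else {
    keep <- !feats$shared
    idx <- which(keep)
    acc <- feats$protein_accession[keep]
  }
  proteins <- unique(acc)
  out <- matrix(NA_real_, length(proteins), ncol(x),
                dimnames = list(proteins, colnames(x)))
  rows_by_protein <- split(idx, factor(acc, levels = proteins))
  for (p in proteins) {
    sub <- x[rows_by_protein[[p]], , drop = FALSE]
    if (nrow(sub) == 1) {
      out[p, ] <- sub[1, ]
      next
    }
    observed_col <- colSums(!is.na(sub)) > 0
    observed_row <- rowSums(!is.na(sub[, observed_col, drop = FALSE])) > 0
    sub2 <- sub[observed_row, observed_col, drop = FALSE]
    if (nrow(sub2) == 0 || ncol(sub2) == 0) next
    if (nrow(sub2) == 1) {
      out[p, observed_col] <- sub2[1, ]
      next
    }
    fit <- median_polish(sub2, tol = tol, max_iter = max_iter)
    out[p, observed_col] <- fit$overall + fit$column_effects
  }
  out
}
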