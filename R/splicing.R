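# Counting of significant local splice variations (LSVs) from VOILA-style
# delta-PSI tables.  The module consumes posterior probabilities as
# provided by the upstream splicing tool; it does not recompute them.

LSV_COLS <- c("gene_id", "lsv_id", "event_kind", "exon_skip", "e_dpsi",
              "p_ge_threshold")

#' Read a VOILA-style LSV event table
#'
#' Tab-separated with columns `gene_id`, `lsv_id`, `event_kind` (`junction`
#' or `intron_retention`), `exon_skip` (TRUE when a junction bypasses at
#' least one annotated exon), `e_dpsi` (expected delta PSI, in \[-1, 1\])
#' and `p_ge_threshold` (posterior probability that |delta PSI| exceeds the
#' PSI-change threshold, in \[0, 1\]).
#'
#' @param path path to the TSV file.
#' @return validated data.frame of LSV events.
#' @export
parse_lsv_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  validate_lsv_events(df)
}

#' @rdname parse_lsv_table
#' @param events a data.frame of LSV events to validate in place.
#' @export
validate_lsv_events <- function(events) {
  missing_cols <- setdiff(LSV_COLS, names(events))
  if (length(missing_cols) > 0) {
    stop("LSV table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  events$exon_skip <- as.logical(events$exon_skip)
  bad_kind <- !events$event_kind %in% c("junction", "intron_retention")
  if (any(bad_kind)) {
    stop("unknown event_kind at row ", which(bad_kind)[1], ": '",
         events$event_kind[which(bad_kind)[1]], "'")
  }
  bad_p <- is.na(events$p_ge_threshold) | events$p_ge_threshold < 0 |
    events$p_ge_threshold > 1
  if (any(bad_p)) {
    stop("p_ge_threshold outside [0, 1] at row ", which(bad_p)[1])
  }
  bad_d <- is.na(events$e_dpsi) | abs(events$e_dpsi) > 1
  if (any(bad_d)) {
    stop("e_dpsi outside [-1, 1] at row ", which(bad_d)[1])
  }
  events
}

#' Write an LSV event table
#' @param events data.frame of LSV events.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lsv_table <- function(events, path) {
  write_tsv_impl(events, path)
}

#' Flag significant splicing events
#'
#' An event is significant when its posterior probability of at least a
#' `dpsi_threshold` change in PSI strictly exceeds `dpsi_confidence`
#' (default: > 0.95 confidence of a >= 20% change).  Direction is the sign
#' of the expected delta PSI.
#'
#' @param events validated LSV events (see [parse_lsv_table()]).
#' @param thresholds a [significance_thresholds()].
#' @return `events` with added logical `significant` and integer
#'   `direction` (+1 / -1 / 0) columns.
#' @export
significant_events <- function(events, thresholds = significance_thresholds()) {
  events <- validate_lsv_events(events)
  events$significant <- events$p_ge_threshold > thresholds$dpsi_confidence
  events$direction <- sign(events$e_dpsi)
  events
}

#' Summarize significant splicing changes per comparison
#'
#' An LSV is significant if at least one of its events is significant; a
#' gene is counted once however many of its LSVs change.  Exon-skipping
#' tallies count significant junction events that bypass an annotated exon;
#' intron-retention tallies count significant intron events; both are split
#' by the sign of the expected delta PSI.
#'
#' @param events LSV events, optionally with a `comparison` column (one
#'   summary row per comparison; otherwise a single row labelled "all").
#' @param thresholds a [significance_thresholds()].
#' @return data.frame per comparison with `n_events`, `n_significant_events`,
#'   `n_significant_lsvs`, `n_genes_with_significant_lsv`, `exon_skip_up`,
#'   `exon_skip_down`, `intron_retention_up`, `intron_retention_down`.
#' @export
summarize_splicing <- function(events, thresholds = significance_thresholds()) {
  ev <- significant_events(events, thresholds)
  if (!"comparison" %in% names(ev)) ev$comparison <- "all"
  out <- lapply(unique(ev$comparison), function(cmp) {
    e <- ev[ev$comparison == cmp, , drop = FALSE]
    sig <- e[e$significant, , drop = FALSE]
    skip <- sig$event_kind == "junction" & sig$exon_skip
    ir <- sig$event_kind == "intron_retention"
    data.frame(
      comparison = cmp,
      n_events = nrow(e),
      n_significant_events = nrow(sig),
      n_significant_lsvs = length(unique(sig$lsv_id)),
      n_genes_with_significant_lsv = length(unique(sig$gene_id)),
      exon_skip_up = sum(skip & sig$direction > 0),
      exon_skip_down = sum(skip & sig$direction < 0),
      intron_retention_up = sum(ir & sig$direction > 0),
      intron_retention_down = sum(ir & sig$direction < 0),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
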