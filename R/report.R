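# Threshold classification of differential tables and the one-call
# pipeline driver.

#' Classify differential records as up / down / unchanged
#'
#' RNA and protein records are gated on both the FDR and the log2
#' fold-change (strict inequalities: q < fdr AND log2fc > cutoff for "up",
#' q < fdr AND log2fc < -cutoff for "down").  Phosphopeptide records use
#' only the adjusted fold change, with an inclusive twofold rule
#' (|adjusted log2FC| >= cutoff), since adjusted values are point estimates
#' that are thresholded, not re-tested.
#'
#' @param records for `rna`/`protein`: a data.frame with `contrast`,
#'   `log2fc`, `q`; for `phospho`: the output of [adjust_phospho()].
#' @param data_type one of `"rna"`, `"protein"`, `"phospho"`.
#' @param thresholds a [significance_thresholds()].
#' @return data.frame per contrast with `data_type`, `n_total`, `n_up`,
#'   `n_down`, `pct_up`, `pct_down` (percentages to one decimal).
#' @export
classify_features <- function(records, data_type,
                              thresholds = significance_thresholds()) {
  if (!data_type %in% c("rna", "protein", "phospho")) {
    stop("unknown data_type '", data_type, "'")
  }
  if (data_type == "phospho") {
    fc <- records$adjusted_log2fc
    if (is.null(fc)) fc <- records$log2fc
    cut <- thresholds$phospho_abs_log2fc
    up <- !is.na(fc) & fc >= cut
    down <- !is.na(fc) & fc <= -cut
  } else {
    fdr <- if (data_type == "rna") thresholds$rna_fdr else thresholds$protein_fdr
    cut <- if (data_type == "rna") thresholds$rna_abs_log2fc
           else thresholds$protein_abs_log2fc
    ok <- !is.na(records$q) & !is.na(records$log2fc)
    up <- ok & records$q < fdr & records$log2fc > cut
    down <- ok & records$q < fdr & records$log2fc < -cut
  }
  contrasts <- unique(records$contrast)
  out <- lapply(contrasts, function(cc) {
    sel <- records$contrast == cc
    n <- sum(sel)
    nu <- sum(up & sel)
    nd <- sum(down & sel)
    data.frame(data_type = data_type, contrast = cc, n_total = n,
               n_up = nu, n_down = nd,
               pct_up = round(100 * nu / n, 1),
               pct_down = round(100 * nd / n, 1),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (field in c("design", "output_dir")) {
    if (is.null(cfg[[field]])) {
      stop("pipeline config is missing required field '", field, "'")
    }
  }
  cfg
}

run_stage <- function(stage, input, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed",
         if (!is.null(input)) paste0(" on input '", input, "'"), ": ",
         conditionMessage(e), call. = FALSE)
  })
}

#' Run the full differential-abundance pipeline from a config file
#'
#' The YAML config names the inputs and outputs:
#' \preformatted{
#' design: design.tsv          # required
#' psm: psm.tsv                # global-proteome PSM table (optional)
#' phospho_psm: phospho.tsv    # phosphopeptide PSM table (optional)
#' rna: rna_de.tsv             # precomputed RNA differential table (optional)
#' lsv: lsv.tsv                # LSV event table (optional)
#' output_dir: out/            # required
#' thresholds:                 # optional overrides, see
#'   protein_fdr: 0.1          #   significance_thresholds()
#' phospho_threshold: 1.0      # |adjusted log2FC| cutoff for counting
#' drop_unmatched: false       # drop unmatched phosphopeptides before counting
#' keep_shared_peptides: false
#' medpolish_tol: 1.0e-4
#' medpolish_max_iter: 20
#' }
#'
#' Stages executed (when their inputs are present): PSM collapse ->
#' median normalization -> median-polish protein summarization -> protein
#' differential tests; phospho PSM collapse -> normalization -> peptide-wise
#' differential tests -> phospho-to-protein adjustment -> counting; RNA /
#' protein / phospho threshold classification; LSV splicing summary.  All
#' result tables are written to `output_dir` along with a plain-text run
#' log; reruns with the same config produce byte-identical outputs.
#'
#' @param config_path path to the YAML config file.
#' @return invisibly, a named list of the in-memory results.
#' @export
run_pipeline <- function(config_path) {
  cfg <- read_pipeline_config(config_path)
  out_dir <- cfg$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  th_args <- if (is.null(cfg$thresholds)) list() else cfg$thresholds
  thresholds <- do.call(significance_thresholds, th_args)
  keep_shared <- isTRUE(cfg$keep_shared_peptides)
  tol <- if (is.null(cfg$medpolish_tol)) 1e-4 else cfg$medpolish_tol
  max_iter <- if (is.null(cfg$medpolish_max_iter)) 20L
              else as.integer(cfg$medpolish_max_iter)

  log_lines <- c(
    paste0("tmtpolish ", as.character(utils::packageVersion("tmtpolish"))),
    paste0("config: ", normalizePath(config_path)),
    paste0("thresholds: ",
           paste(names(unclass(thresholds)), unlist(unclass(thresholds)),
                 sep = "=", collapse = " ")),
    paste0("medpolish: tol=", tol, " max_iter=", max_iter))

  design <- run_stage("read_design", cfg$design, read_design(cfg$design))
  log_lines <- c(log_lines,
                 paste0("design: ", nrow(design), " samples, reference ",
                        reference_condition(design)))
  results <- list(design = design, thresholds = thresholds)
  classifications <- list()

  protein_de <- NULL
  if (!is.null(cfg$psm)) {
    psms <- run_stage("read_psm", cfg$psm, read_psm_table(cfg$psm, design))
    pep <- run_stage("collapse", cfg$psm,
                     collapse_psms(psms, keep_shared = keep_shared))
    pep <- run_stage("normalize", cfg$psm, median_normalize(pep))
    prot <- run_stage("summarize", cfg$psm,
                      summarize_proteins(pep, tol = tol,
                                         max_iter = max_iter))
    write_matrix_tsv(prot, file.path(out_dir, "protein_matrix.tsv"),
                     id_col = "protein_accession")
    protein_de <- run_stage("test_proteins", cfg$psm,
                            differential_test(prot, design))
    write_differential_table(protein_de,
                             file.path(out_dir, "protein_differential.tsv"))
    classifications$protein <- classify_features(protein_de, "protein",
                                                 thresholds)
    results$protein_matrix <- prot
    results$protein_de <- protein_de
    log_lines <- c(log_lines,
                   paste0("proteins: ", nrow(prot), " summarized from ",
                          nrow(pep$log2), " peptide ions (",
                          nrow(psms), " PSMs)"))
  }

  if (!is.null(cfg$phospho_psm)) {
    if (is.null(protein_de)) {
      stop("pipeline stage 'adjust_phospho' requires a global-proteome ",
           "'psm' input to provide protein fold changes")
    }
    ph_psms <- run_stage("read_phospho_psm", cfg$phospho_psm,
                         read_psm_table(cfg$phospho_psm, design))
    ph_pep <- run_stage("collapse_phospho", cfg$phospho_psm,
                        collapse_psms(ph_psms, keep_shared = TRUE))
    ph_pep <- run_stage("normalize_phospho", cfg$phospho_psm,
                        median_normalize(ph_pep))
    ph_de <- run_stage("test_phospho", cfg$phospho_psm,
                       differential_test(
                         ph_pep$log2, design,
                         feature_annotation =
                           ph_pep$features["protein_accession"]))
    prot_for_adjust <- protein_de
    adj <- run_stage("adjust_phospho", cfg$phospho_psm,
                     adjust_phospho(ph_de, prot_for_adjust))
    write_differential_table(ph_de,
                             file.path(out_dir, "phospho_differential.tsv"))
    write_tsv_impl(adj, file.path(out_dir, "phospho_adjusted.tsv"))
    ph_threshold <- if (is.null(cfg$phospho_threshold))
      thresholds$phospho_abs_log2fc else cfg$phospho_threshold
    counts <- count_changed(adj, threshold = ph_threshold,
                            drop_unmatched = isTRUE(cfg$drop_unmatched))
    write_tsv_impl(counts, file.path(out_dir, "phospho_counts.tsv"))
    classifications$phospho <- classify_features(adj, "phospho", thresholds)
    results$phospho_de <- ph_de
    results$phospho_adjusted <- adj
    results$phospho_counts <- counts
    log_lines <- c(log_lines,
                   paste0("phospho: ", nrow(ph_pep$log2), " peptide ions; ",
                          sum(adj$status == "unmatched"), " unmatched, ",
                          sum(adj$status == "ambiguous"), " ambiguous"))
  }

  if (!is.null(cfg$rna)) {
    rna_de <- run_stage("read_rna", cfg$rna,
                        read_differential_table(cfg$rna))
    classifications$rna <- classify_features(rna_de, "rna", thresholds)
    results$rna_de <- rna_de
  }

  if (length(classifications) > 0) {
    cls <- do.call(rbind, classifications)
    rownames(cls) <- NULL
    write_tsv_impl(cls, file.path(out_dir, "classification_summary.tsv"))
    results$classification <- cls
  }

  if (!is.null(cfg$lsv)) {
    lsv <- run_stage("read_lsv", cfg$lsv, parse_lsv_table(cfg$lsv))
    splicing <- run_stage("splice_count", cfg$lsv,
                          summarize_splicing(lsv, thresholds))
    write_tsv_impl(splicing, file.path(out_dir, "splicing_summary.tsv"))
    results$splicing <- splicing
    log_lines <- c(log_lines,
                   paste0("splicing: ", nrow(lsv), " events, ",
                          sum(splicing$n_genes_with_significant_lsv),
                          " genes with significant LSVs"))
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(results)
}
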