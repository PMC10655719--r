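# Fixture builders and independent oracles shared across the suite.

# Two-condition design: DMSO-treated reference vs dox-treated, same cell line.
two_condition_design <- function(n_ref = 3, n_trt = 3) {
  sample_design(data.frame(
    sample_id = c(paste0("ref_r", seq_len(n_ref)),
                  paste0("trt_r", seq_len(n_trt))),
    channel = as.character(seq_len(n_ref + n_trt)),
    cell_line = "iDUX4",
    treatment = c(rep("DMSO", n_ref), rep("dox", n_trt)),
    timepoint_h = c(rep(14, n_ref), rep(2, n_trt)),
    replicate = c(seq_len(n_ref), seq_len(n_trt)),
    is_reference = c(rep(TRUE, n_ref), rep(FALSE, n_trt)),
    stringsAsFactors = FALSE))
}

# Build a PSM table from a compact row list: each element is
# list(seq, mods, charge, acc, intensities-named-by-sample).
make_psms <- function(rows, sample_ids) {
  df <- do.call(rbind, lapply(rows, function(r) {
    ints <- stats::setNames(rep(NA_real_, length(sample_ids)), sample_ids)
    ints[names(r$int)] <- r$int
    data.frame(peptide_sequence = r$seq,
               modifications = if (is.null(r$mods)) "" else r$mods,
               charge = if (is.null(r$charge)) 2L else r$charge,
               protein_accession = r$acc,
               as.data.frame(as.list(ints), check.names = FALSE),
               check.names = FALSE, stringsAsFactors = FALSE)
  }))
  psm_table(df)
}

# Independent reference median polish: plain double-loop sweeps, rows first,
# medians over observed entries, effect medians folded into the overall term.
# Returns the per-column protein summary (overall + column effects).
ref_medpolish_summary <- function(y, tol = 1e-4, max_iter = 20) {
  nr <- nrow(y); nc <- ncol(y)
  overall <- 0
  r <- numeric(nr)
  cfx <- numeric(nc)
  z <- y
  old <- sum(abs(z), na.rm = TRUE)
  for (it in seq_len(max_iter)) {
    for (i in seq_len(nr)) {
      m <- stats::median(z[i, ], na.rm = TRUE)
      z[i, ] <- z[i, ] - m
      r[i] <- r[i] + m
    }
    m <- stats::median(cfx)
    overall <- overall + m
    cfx <- cfx - m
    for (j in seq_len(nc)) {
      m <- stats::median(z[, j], na.rm = TRUE)
      z[, j] <- z[, j] - m
      cfx[j] <- cfx[j] + m
    }
    m <- stats::median(r)
    overall <- overall + m
    r <- r - m
    new <- sum(abs(z), na.rm = TRUE)
    if (abs(old - new) <= tol) break
    old <- new
  }
  m <- stats::median(r)
  overall <- overall + m
  m <- stats::median(cfx)
  overall <- overall + m
  cfx <- cfx - m
  overall + cfx
}

# Random matrix with a given fraction of missing cells (never a whole row or
# column).
random_matrix_with_missing <- function(nr, nc, frac_missing = 0.1) {
  y <- matrix(stats::rnorm(nr * nc), nr, nc)
  n_miss <- floor(frac_missing * nr * nc)
  if (n_miss > 0) {
    repeat {
      idx <- sample(nr * nc, n_miss)
      y2 <- y
      y2[idx] <- NA
      ok <- all(rowSums(!is.na(y2)) > 0) && all(colSums(!is.na(y2)) > 0)
      if (ok) return(y2)
    }
  }
  y
}

# Simulated full-study inputs plus a pipeline config, written to `dir`.
make_pipeline_inputs <- function(dir, noise_sd = 0, seed = 19) {
  des <- default_16plex_design()
  spec <- effect_spec(n_proteins = 40, frac_proteins_changed = 0.1,
                      protein_log2fc = 2, n_phosphopeptides = 60,
                      frac_phospho_changed = 0.2, phospho_log2fc = 1.5,
                      noise_sd_log2 = noise_sd,
                      loading_offsets_log2 = if (noise_sd == 0) 0 else NULL,
                      seed = seed)
  sim <- simulate_psm_table(des, spec)
  ph <- simulate_phospho_psm_table(des, spec, sim$truth)
  lsv <- simulate_lsv_table(n_genes = 80, frac_significant = 0.25, seed = seed)
  write_design(des, file.path(dir, "design.tsv"))
  write_psm_table(sim$psms, file.path(dir, "psm.tsv"))
  write_psm_table(ph$psms, file.path(dir, "phospho.tsv"))
  write_lsv_table(lsv$events, file.path(dir, "lsv.tsv"))
  cfg <- list(design = file.path(dir, "design.tsv"),
              psm = file.path(dir, "psm.tsv"),
              phospho_psm = file.path(dir, "phospho.tsv"),
              lsv = file.path(dir, "lsv.tsv"),
              output_dir = file.path(dir, "out"))
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  list(config = cfg_path, sim = sim, ph = ph, lsv = lsv, spec = spec,
       design = des)
}
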