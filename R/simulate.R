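# Synthetic-data generator with known ground truth.
#
# The measurement model mirrors what the quantification pipeline assumes:
# each PSM intensity is 2^(protein baseline + peptide ionization offset +
# planted condition effect + per-sample loading offset + Gaussian log2
# noise).  Loading offsets are per-sample constants -- exactly the artifact
# the global-median normalization is supposed to remove -- and planted
# effects are attached to the doxycycline-induced iDUX4 conditions so that
# contrasts against the DMSO reference recover them.

#' Specify the effect structure of a simulated experiment
#'
#' @param n_proteins number of simulated proteins.
#' @param peptides_per_protein integer range (length-2) of peptide ions per
#'   protein; sampled uniformly.
#' @param psms_per_peptide integer range of PSM observations per peptide ion
#'   per sample.
#' @param frac_proteins_changed fraction of proteins given a non-zero
#'   abundance effect in the affected conditions.
#' @param protein_log2fc magnitude of the planted protein effect; each
#'   changed protein gets +magnitude or -magnitude with equal probability.
#' @param n_phosphopeptides number of simulated phosphopeptides.
#' @param frac_phospho_changed fraction of phosphopeptides given a site-level
#'   effect on top of their parent protein's effect.
#' @param phospho_log2fc magnitude of the planted site-level effect.
#' @param noise_sd_log2 SD of Gaussian measurement noise on the log2 scale.
#' @param ionization_spread_sd_log2 SD of the per-peptide ionization offset.
#' @param loading_offsets_log2 per-sample log2 loading offsets: a single
#'   number recycled to all samples, a named/ordered vector, or `NULL` to
#'   draw offsets from N(0, 0.3) at simulation time.
#' @param affected_conditions condition labels that receive planted effects;
#'   `NULL` selects the doxycycline-treated iDUX4 conditions of the design
#'   (falling back to all non-reference conditions if the design has none).
#' @param shared_peptide_frac fraction of peptide ions mapped to two
#'   proteins, to exercise the ambiguous-match path (default 0: off).
#' @param seed integer seed governing all randomness of the generator.
#' @return a list of class `effect_spec`.
#' @export
effect_spec <- function(n_proteins = 200,
                        peptides_per_protein = c(2, 8),
                        psms_per_peptide = c(1, 3),
                        frac_proteins_changed = 0.05,
                        protein_log2fc = 2,
                        n_phosphopeptides = 500,
                        frac_phospho_changed = 0.1,
                        phospho_log2fc = 1.5,
                        noise_sd_log2 = 0.3,
                        ionization_spread_sd_log2 = 1,
                        loading_offsets_log2 = NULL,
                        affected_conditions = NULL,
                        shared_peptide_frac = 0,
                        seed = 1L) {
  spec <- list(n_proteins = as.integer(n_proteins),
               peptides_per_protein = as.integer(rep_len(peptides_per_protein, 2)),
               psms_per_peptide = as.integer(rep_len(psms_per_peptide, 2)),
               frac_proteins_changed = frac_proteins_changed,
               protein_log2fc = protein_log2fc,
               n_phosphopeptides = as.integer(n_phosphopeptides),
               frac_phospho_changed = frac_phospho_changed,
               phospho_log2fc = phospho_log2fc,
               noise_sd_log2 = noise_sd_log2,
               ionization_spread_sd_log2 = ionization_spread_sd_log2,
               loading_offsets_log2 = loading_offsets_log2,
               affected_conditions = affected_conditions,
               shared_peptide_frac = shared_peptide_frac,
               seed = as.integer(seed))
  stopifnot(spec$n_proteins >= 1, spec$n_phosphopeptides >= 0,
            all(spec$peptides_per_protein >= 1),
            all(spec$psms_per_peptide >= 1),
            spec$noise_sd_log2 >= 0, spec$ionization_spread_sd_log2 >= 0,
            spec$shared_peptide_frac >= 0, spec$shared_peptide_frac <= 1)
  for (f in c("frac_proteins_changed", "frac_phospho_changed")) {
    if (spec[[f]] < 0 || spec[[f]] > 1) stop(f, " must be in [0, 1]")
  }
  class(spec) <- "effect_spec"
  spec
}

# Resolve which conditions carry planted effects.
affected_conditions_of <- function(design, spec) {
  if (!is.null(spec$affected_conditions)) return(spec$affected_conditions)
  cond <- unique(design$condition[design$cell_line == "iDUX4" &
                                    design$treatment == "dox"])
  if (length(cond) == 0) {
    cond <- setdiff(unique(design$condition), reference_condition(design))
  }
  cond
}

resolve_loading <- function(design, spec) {
  lo <- spec$loading_offsets_log2
  if (is.null(lo)) {
    lo <- stats::rnorm(nrow(design), 0, 0.3)
  } else if (length(lo) == 1) {
    lo <- rep(lo, nrow(design))
  } else if (!is.null(names(lo))) {
    lo <- lo[design$sample_id]
  }
  if (length(lo) != nrow(design) || any(is.na(lo))) {
    stop("loading_offsets_log2 must give one offset per designed sample")
  }
  stats::setNames(as.numeric(lo), design$sample_id)
}

random_peptide <- function(n, len_range = c(8, 20)) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    paste(sample(aa, sample(len_range[1]:len_range[2], 1), replace = TRUE),
          collapse = "")
  }, character(1))
}

#' Simulate a PSM-level reporter-intensity table with known ground truth
#'
#' @param design a [sample_design()].
#' @param spec an [effect_spec()].
#' @return list with elements `psms` (a `psm_table`), `truth` (data.frame
#'   `protein_accession`, `condition`, `true_log2fc` over all non-reference
#'   conditions), and `loading` (the per-sample log2 offsets used).
#' @export
simulate_psm_table <- function(design, spec) {
  set.seed(spec$seed)
  ref <- reference_condition(design)
  affected <- affected_conditions_of(design, spec)
  loading <- resolve_loading(design, spec)
  conditions <- unique(design$condition)
  nonref <- setdiff(conditions, ref)

  accessions <- sprintf("PROT%04d", seq_len(spec$n_proteins))
  n_changed <- round(spec$frac_proteins_changed * spec$n_proteins)
  changed <- accessions[seq_len(n_changed)]
  sign_fc <- stats::setNames(sample(c(-1, 1), n_changed, replace = TRUE),
                             changed)

  # long-format ground truth over non-reference conditions
  truth <- expand.grid(protein_accession = accessions, condition = nonref,
                       stringsAsFactors = FALSE)
  truth$true_log2fc <- 0
  hit <- truth$protein_accession %in% changed & truth$condition %in% affected
  truth$true_log2fc[hit] <-
    spec$protein_log2fc * sign_fc[truth$protein_accession[hit]]

  effect_matrix <- matrix(0, spec$n_proteins, length(conditions),
                          dimnames = list(accessions, conditions))
  effect_matrix[cbind(truth$protein_accession, truth$condition)] <-
    truth$true_log2fc

  n_pep <- sample(spec$peptides_per_protein[1]:spec$peptides_per_protein[2],
                  spec$n_proteins, replace = TRUE)
  base_protein <- stats::rnorm(spec$n_proteins, 16, 1.5)

  rows <- vector("list", spec$n_proteins)
  n_samples <- nrow(design)
  cond_of_sample <- design$condition
  for (i in seq_len(spec$n_proteins)) {
    np <- n_pep[i]
    seqs <- random_peptide(np)
    pep_offset <- stats::rnorm(np, 0, spec$ionization_spread_sd_log2)
    charge <- sample(2:4, np, replace = TRUE)
    n_psm <- sample(spec$psms_per_peptide[1]:spec$psms_per_peptide[2], np,
                    replace = TRUE)
    acc <- accessions[i]
    if (spec$shared_peptide_frac > 0 &&
        stats::runif(1) < spec$shared_peptide_frac && spec$n_proteins > 1) {
      other <- sample(setdiff(accessions, acc), 1)
      acc_pep <- c(paste(acc, other, sep = ";"), rep(acc, np - 1))
    } else {
      acc_pep <- rep(acc, np)
    }
    pep_rows <- vector("list", np)
    for (j in seq_len(np)) {
      k <- n_psm[j]
      mu <- base_protein[i] + pep_offset[j] +
        effect_matrix[i, cond_of_sample] + loading
      log2_int <- matrix(mu, nrow = k, ncol = n_samples, byrow = TRUE) +
        matrix(stats::rnorm(k * n_samples, 0, spec$noise_sd_log2),
               nrow = k)
      intens <- 2^log2_int
      colnames(intens) <- design$sample_id
      pep_rows[[j]] <- data.frame(
        peptide_sequence = seqs[j], modifications = "", charge = charge[j],
        protein_accession = acc_pep[j],
        as.data.frame(intens, check.names = FALSE),
        check.names = FALSE, stringsAsFactors = FALSE)
    }
    rows[[i]] <- do.call(rbind, pep_rows)
  }
  psms <- do.call(rbind, rows)
  rownames(psms) <- NULL
  list(psms = psm_table(psms), truth = truth, loading = loading)
}

#' Simulate a phosphopeptide PSM table on top of protein-level ground truth
#'
#' Each phosphopeptide's true total log2 fold change is its parent protein's
#' effect plus a site-level effect; the site effect is drawn only for the
#' changed fraction.  After phospho-to-protein adjustment the recovered
#' value should therefore equal the site effect alone.
#'
#' @param design a [sample_design()].
#' @param spec an [effect_spec()].
#' @param truth the protein ground-truth data.frame from
#'   [simulate_psm_table()]; parent proteins are drawn from it.
#' @return list with `psms` (a `psm_table` of phosphopeptide ions) and
#'   `truth` (data.frame `peptide_id`, `protein_accession`, `condition`,
#'   `site_log2fc`, `total_log2fc`).
#' @export
simulate_phospho_psm_table <- function(design, spec, truth) {
  set.seed(spec$seed + 1L)
  ref <- reference_condition(design)
  affected <- affected_conditions_of(design, spec)
  loading <- resolve_loading(design, spec)
  conditions <- unique(design$condition)
  nonref <- setdiff(conditions, ref)

  accessions <- unique(truth$protein_accession)
  if (length(accessions) == 0) stop("protein ground truth is empty")
  npp <- spec$n_phosphopeptides
  parent <- sample(accessions, npp, replace = TRUE)
  n_changed <- round(spec$frac_phospho_changed * npp)
  site_sign <- sample(c(-1, 1), n_changed, replace = TRUE)

  prot_fc <- matrix(0, length(accessions), length(conditions),
                    dimnames = list(accessions, conditions))
  prot_fc[cbind(truth$protein_accession, truth$condition)] <- truth$true_log2fc

  seqs <- random_peptide(npp)
  site_pos <- sample(2:15, npp, replace = TRUE)
  mods <- sprintf("1xPhospho [S%d]", site_pos)
  charge <- sample(2:4, npp, replace = TRUE)
  base_pep <- stats::rnorm(npp, 14, spec$ionization_spread_sd_log2 + 0.5)

  site_fc <- matrix(0, npp, length(conditions),
                    dimnames = list(NULL, conditions))
  if (n_changed > 0 && length(affected) > 0) {
    site_fc[seq_len(n_changed), affected] <-
      site_sign * spec$phospho_log2fc
  }
  total_fc <- prot_fc[parent, , drop = FALSE] + site_fc

  peptide_id <- sprintf("%s_%s_%d", seqs, mods, charge)
  ph_truth <- expand.grid(idx = seq_len(npp), condition = nonref,
                          stringsAsFactors = FALSE)
  cond_idx <- match(ph_truth$condition, conditions)
  ph_truth <- data.frame(peptide_id = peptide_id[ph_truth$idx],
                         protein_accession = parent[ph_truth$idx],
                         condition = ph_truth$condition,
                         site_log2fc = site_fc[cbind(ph_truth$idx, cond_idx)],
                         total_log2fc = total_fc[cbind(ph_truth$idx, cond_idx)],
                         stringsAsFactors = FALSE)

  n_samples <- nrow(design)
  n_psm <- sample(spec$psms_per_peptide[1]:spec$psms_per_peptide[2], npp,
                  replace = TRUE)
  rows <- vector("list", npp)
  for (i in seq_len(npp)) {
    k <- n_psm[i]
    mu <- base_pep[i] + total_fc[i, design$condition] + loading
    log2_int <- matrix(mu, nrow = k, ncol = n_samples, byrow = TRUE) +
      matrix(stats::rnorm(k * n_samples, 0, spec$noise_sd_log2), nrow = k)
    intens <- 2^log2_int
    colnames(intens) <- design$sample_id
    rows[[i]] <- data.frame(
      peptide_sequence = seqs[i], modifications = mods[i], charge = charge[i],
      protein_accession = parent[i],
      as.data.frame(intens, check.names = FALSE),
      check.names = FALSE, stringsAsFactors = FALSE)
  }
  psms <- do.call(rbind, rows)
  rownames(psms) <- NULL
  list(psms = psm_table(psms), truth = ph_truth)
}

#' Simulate a VOILA-style LSV table with planted significant genes
#'
#' Generates local splice variations (LSVs) with per-event expected delta
#' PSI and posterior probability that |delta PSI| >= 0.2.  Exactly
#' `round(frac_significant * n_genes)` genes carry at least one event with
#' posterior probability above 0.95; all events of the remaining genes stay
#' at or below 0.95.
#'
#' @param n_genes number of genes.
#' @param frac_significant fraction of genes planted as significant.
#' @param seed integer seed.
#' @param lsvs_per_gene integer range of LSVs per gene.
#' @param events_per_lsv integer range of events per LSV.
#' @return list with `events` (data.frame `gene_id`, `lsv_id`, `event_kind`,
#'   `exon_skip`, `e_dpsi`, `p_ge_threshold`) and `truth` (data.frame
#'   `gene_id`, `significant`).
#' @export
simulate_lsv_table <- function(n_genes, frac_significant, seed = 1L,
                               lsvs_per_gene = c(1, 3),
                               events_per_lsv = c(2, 4)) {
  if (frac_significant < 0 || frac_significant > 1) {
    stop("frac_significant must be in [0, 1]")
  }
  set.seed(seed)
  genes <- sprintf("GENE%05d", seq_len(n_genes))
  n_sig <- round(frac_significant * n_genes)
  sig_genes <- genes[seq_len(n_sig)]

  out <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    n_lsv <- sample(lsvs_per_gene[1]:lsvs_per_gene[2], 1)
    lsv_rows <- vector("list", n_lsv)
    for (l in seq_len(n_lsv)) {
      n_ev <- sample(events_per_lsv[1]:events_per_lsv[2], 1)
      kind <- sample(c("junction", "intron_retention"), n_ev, replace = TRUE,
                     prob = c(0.75, 0.25))
      skip <- kind == "junction" & stats::runif(n_ev) < 0.5
      e_dpsi <- round(stats::runif(n_ev, -0.15, 0.15), 4)
      p <- round(stats::runif(n_ev, 0, 0.95), 4)
      lsv_rows[[l]] <- data.frame(
        gene_id = genes[g],
        lsv_id = sprintf("%s:s:%d", genes[g], l),
        event_kind = kind, exon_skip = skip, e_dpsi = e_dpsi,
        p_ge_threshold = p, stringsAsFactors = FALSE)
    }
    gene_df <- do.call(rbind, lsv_rows)
    if (genes[g] %in% sig_genes) {
      # plant one clearly significant event in the gene's first LSV
      i <- 1L
      gene_df$p_ge_threshold[i] <- round(stats::runif(1, 0.96, 0.999), 4)
      gene_df$e_dpsi[i] <- round(sample(c(-1, 1), 1) *
                                   stats::runif(1, 0.2, 0.6), 4)
    }
    out[[g]] <- gene_df
  }
  events <- do.call(rbind, out)
  rownames(events) <- NULL
  list(events = events,
       truth = data.frame(gene_id = genes, significant = genes %in% sig_genes,
                          stringsAsFactors = FALSE))
}
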