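---
title: "TMT differential abundance, phospho normalization and splicing counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TMT differential abundance, phospho normalization and splicing counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmtpolish)
```

## The problem

Doxycycline-inducible DUX4 (iDUX4) myoblast experiments ask how a toxic
transcription factor reshapes the proteome, the phosphoproteome and the
transcript isoform repertoire over a time course. A single TMTpro 16-plex
carries every sample of the time course (two cell lines, WT and iDUX4; DMSO
for 14 h or doxycycline for 2, 6 and 14 h), so all quantification is
relative, within one batch, against reporter-ion intensities. DMSO-treated
iDUX4 myoblasts are the reference condition for every contrast.

`tmtpolish` implements the quantification chain from PSM-level reporter
intensities to classified differential calls, the phospho-to-protein
fold-change normalization that separates site-level regulation from protein
abundance change, and the counting of significant local splice variations
(LSVs) from delta-PSI posterior tables. A synthetic-data generator with
known ground truth stands in for raw mass-spectrometry and RNA-seq data, so
every stage is testable offline.

## The quantification model

Each PSM (peptide-spectrum match) contributes one reporter intensity per
channel. The chain is:

1. **Collapse.** A peptide ion is a (sequence, modifications, charge)
   triple. When an ion is measured by several PSMs in a sample, only the
   maximum intensity is kept, then log2-transformed. Zero intensities are
   treated as missing: log2 of zero is undefined, and a zero reporter value
   indicates absence of signal, not an abundance of one.
2. **Equal-loading normalization.** Each sample's median log2 intensity is
   aligned to the global target median (the median of the per-sample
   medians). This removes per-channel loading differences under the
   assumption that most features do not change. The target choice preserves
   the intensity scale instead of centering at zero.
3. **Median-polish summarization.** Per protein, Tukey's median polish
   decomposes the peptide-by-sample table into
   `overall + peptide effect + sample effect + residual` by alternating
   row-then-column median sweeps over observed entries. The protein's
   summary in a sample is `overall + sample effect`; per-peptide ionization
   offsets are absorbed into row effects and never move the summary. The
   sweep stops when the sum of absolute residuals changes by at most `tol`
   (default `1e-4`) or after `max_iter` (default 20) iterations; both are
   exposed. Effects are centered so that the medians of the row and column
   effects sit in the overall term.
4. **Feature-wise linear model.** For each protein (or phosphopeptide ion)
   the normalized log2 intensity in sample *s* of condition *t* is modeled
   as an intercept plus a fixed condition effect with i.i.d. Gaussian error.
   One model spans *all* conditions, so the residual variance is pooled
   across the full plex (larger degrees of freedom than per-pair testing;
   with two replicates per each of the 8 conditions the pooled fit has 8
   residual df instead of 2). A contrast against the reference is then a
   pooled-variance t-test: `log2FC = mean(condition) - mean(reference)`,
   `se = sqrt(s2 * (1/n_c + 1/n_r))`, two-sided Student-t p-value. No
   empirical-Bayes moderation is applied: the model is plain feature-wise
   OLS, and moderation would change the p-values away from the described
   estimator.
5. **Multiple testing.** Benjamini–Hochberg is applied separately per
   contrast and per data type, matching how each contrast is reported
   against the common reference.

### Degenerate inputs

Zero residual variance with a non-zero fold change (possible with few
replicates at zero measurement noise) yields `p = 0` and a `degenerate`
flag; zero variance with zero fold change yields `t = 0, p = 1`. A feature
observed once per condition has no residual degrees of freedom: the fit is
flagged and its contrasts carry missing p-values rather than a fabricated
one. A protein whose peptides are all missing in one sample gets a missing
summary there, which simply propagates.

## Phospho-to-protein normalization

Phosphopeptide fold changes confound site-level regulation with changes in
total protein abundance. Each phosphopeptide's log2FC is therefore
normalized by subtracting its parent protein's log2FC for the same
contrast: `adjusted = raw - protein`. Phosphopeptides whose parent protein
was not quantified in the global proteome are *retained* unadjusted and
flagged `unmatched` — dropping them would hide regulation on proteins the
proteome run missed — and peptides mapping to several proteins are flagged
`ambiguous` and left unadjusted. Counting of regulated phosphopeptides uses
an inclusive twofold rule, `|adjusted log2FC| >= 1`, with no FDR gate:
adjusted values are point estimates that are thresholded, not re-tested, so
no protein-estimate uncertainty is propagated into an adjusted SE.

## Threshold classification

RNA calls require FDR < 0.05 and |log2FC| > 1; protein calls FDR < 0.1 and
|log2FC| > 1 — both gates strict, reflecting the "greater than" phrasing
conventional for these cutoffs. The phospho rule ("at least twofold") is
inclusive. Percentages are reported to one decimal over all records of the
contrast. All thresholds live in one `significance_thresholds()` object; no
stage hard-codes them.

## Splicing counts

An LSV groups the splicing and intron-retention events sharing a source or
target exon. The upstream tool reports, per event, the expected delta PSI
(percent spliced in) and the posterior probability that |delta PSI| is at
least 0.2. An event is significant when that probability *strictly* exceeds
0.95; an LSV is significant when at least one of its events is; genes are
counted once regardless of how many of their LSVs change. Because an LSV
can contain both a significant intron-retention and a significant
exon-skipping event, event-type tallies (split by the sign of delta PSI)
are reported separately from the LSV and gene counts rather than forced to
partition them. Exon-skipping status is taken from an explicit column of
the input, as exported by the upstream annotator; no coordinate-based
classification is attempted, and posteriors are consumed, never recomputed.

## The synthetic-data generator

`simulate_psm_table()` draws, per protein, a baseline log2 abundance
(N(16, 1.5)), per-peptide ionization offsets (N(0, 1) by default — peptides
of one protein genuinely span orders of magnitude), and per-PSM intensities
`2^(baseline + peptide offset + planted effect + loading offset + noise)`
with Gaussian log2 noise (default SD 0.3, a typical TMT reporter spread).
Loading offsets are per-sample constants — exactly the artifact the median
normalization must remove, which makes normalization testable. Planted
protein effects go to a sparse changed fraction (default 5%) in the
doxycycline-treated iDUX4 conditions, with random sign.
`simulate_phospho_psm_table()` plants site-level effects *on top of* parent
protein effects, so a phosphopeptide's true total fold change is the sum,
and the adjusted value should recover the site effect alone — protein and
site regulation are decoupled by construction, mirroring the observed
decoupling of transcript, protein and phosphorylation responses.
`simulate_lsv_table()` plants an exact number of significant genes.

The default design fills the 16-plex with two replicates for each of the
eight conditions. (A 3-replicate iDUX4 / 2-replicate WT layout would need
20 channels; two-per-condition is the configuration that fits a single
16-plex while keeping every condition testable.)

What the generator does **not** emulate: co-isolation interference and the
resulting ratio compression (TMT fold changes in real data are attenuated
toward zero), peptide-specific digestion or labeling efficiency,
intensity-dependent missingness, and correlated (batch-structured) noise.
Passing tests therefore demonstrate correctness of the estimator chain
under its own model assumptions, not immunity to those real-data artifacts.

## Identifiability of fold changes under median normalization

Global median normalization estimates each sample's loading from its median
feature. When planted (or real) effects move an appreciable fraction of
features in one direction, they also move that sample's median slightly, so
every fold change in the affected contrast shifts by a single small
constant (about 0.1 log2 units with 10% of features changed by 2). Fold
changes are thus identified only up to this per-contrast intercept; it
shrinks toward zero as the changed fraction becomes sparse or
sign-balanced. The test suite asserts *exact* recovery (to 1e-9) of planted
effects after removing that one intercept per contrast, bounds the
intercept itself, and additionally asserts strict 1e-12 exactness on
fixtures constructed so that no sample median can move (all changed
features above the middle ranks). This is a property of the normalization
estimator, and any analysis using global median alignment inherits it.

## Numerical and design choices

* Median of an even count is the mean of the two middle values throughout.
* Collapse-then-normalize order: normalization operates on the collapsed
  peptide ions, the matrix the downstream models consume.
* Shared (multi-protein) peptides are excluded from protein summarization
  by default to avoid double counting; an option retains them, and the
  phospho path keeps them (flagged `ambiguous`, never adjusted).
* Whether peptide-wise phospho models should pool variance across WT and
  iDUX4 jointly is open in principle; the joint model is used, consistent
  with the single-model-across-all-conditions design, and gains residual
  df.
* BH is delegated to `stats::p.adjust(method = "BH")` behind a validating
  wrapper; the median polish is implemented in the package because its
  convergence rule (absolute tolerance on the change in sum of absolute
  residuals) and centering conventions are part of the package contract,
  and it is cross-checked in the tests against both an independently
  written naive sweep and `stats::medpolish`.
* Tests and the acceptance script run at reduced problem sizes (hundreds of
  proteins, 50 null replicates) chosen so the whole suite completes in
  about a minute while keeping binomial/recovery checks well-powered.

## Worked example

```{r example}
design <- default_16plex_design()
spec <- effect_spec(n_proteins = 100, frac_proteins_changed = 0.1,
                    protein_log2fc = 2, n_phosphopeptides = 150,
                    frac_phospho_changed = 0.2, noise_sd_log2 = 0.3,
                    seed = 1)
sim <- simulate_psm_table(design, spec)
ph  <- simulate_phospho_psm_table(design, spec, sim$truth)

peptides <- median_normalize(collapse_psms(sim$psms))
proteins <- summarize_proteins(peptides)
protein_de <- differential_test(proteins, design)

ph_pep <- median_normalize(collapse_psms(ph$psms, keep_shared = TRUE))
ph_de <- differential_test(ph_pep$log2, design,
                           feature_annotation =
                             ph_pep$features["protein_accession"])
adjusted <- adjust_phospho(ph_de, protein_de)
count_changed(adjusted, threshold = 1)
```

```{r classify}
classify_features(protein_de, "protein", significance_thresholds())
```

```{r splicing}
lsv <- simulate_lsv_table(n_genes = 200, frac_significant = 0.1, seed = 1)
summarize_splicing(lsv$events)
```

## Limitations

Single-plex only: no reference-channel bridging across plexes, no
between-plex batch terms, and no mixed-effects handling of technical
replicates. RNA differential tables are consumed, not fitted. Ratio
compression is neither modeled nor corrected, so real-TMT fold changes will
be conservative relative to the planted-truth behavior shown here.
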