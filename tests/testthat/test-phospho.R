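phospho_records <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(feature_id = r[[1]], protein_accession = r[[2]],
               contrast = r[[3]], log2fc = as.numeric(r[[4]]),
               stringsAsFactors = FALSE)
  }))
}

protein_records <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(feature_id = r[[1]], contrast = r[[2]],
               log2fc = as.numeric(r[[3]]), stringsAsFactors = FALSE)
  }))
}

test_that("adjustment subtracts the parent protein's fold change", {
  ph <- phospho_records(list("pep1", "P1", "c1", 2.0),
                        list("pep2", "P1", "c1", 1.0),
                        list("pep3", "P2", "c1", 1.0))
  pr <- protein_records(list("P1", "c1", 0.5), list("P2", "c1", 1.0))
  adj <- adjust_phospho(ph, pr)
  expect_equal(adj$adjusted_log2fc, c(1.5, 0.5, 0))
  expect_equal(adj$status, rep("adjusted", 3))
  expect_equal(adj$protein_log2fc, c(0.5, 0.5, 1.0))
  # the adjustment inverts: raw = adjusted + protein
  expect_equal(adj$raw_log2fc, adj$adjusted_log2fc + adj$protein_log2fc)
})

test_that("unmatched and ambiguous phosphopeptides pass through flagged", {
  ph <- phospho_records(list("pep1", "P9", "c1", 1.0),
                        list("pep2", "P1;P2", "c1", 2.0))
  pr <- protein_records(list("P1", "c1", 0.5), list("P2", "c1", 0.1))
  adj <- adjust_phospho(ph, pr)
  expect_equal(adj$status, c("unmatched", "ambiguous"))
  expect_equal(adj$adjusted_log2fc, c(1.0, 2.0))
  expect_true(all(is.na(adj$protein_log2fc)))
})

test_that("a phospho contrast absent from the protein set is an error", {
  ph <- phospho_records(list("pep1", "P1", "c2", 1.0))
  pr <- protein_records(list("P1", "c1", 0.5))
  expect_error(adjust_phospho(ph, pr), "c2")
})

test_that("counting is inclusive at the twofold boundary", {
  ph <- phospho_records(list("a", "P1", "c1", 1.0),
                        list("b", "P2", "c1", -1.2),
                        list("c", "P3", "c1", 0.9))
  pr <- protein_records(list("P1", "c1", 0), list("P2", "c1", 0),
                        list("P3", "c1", 0))
  counts <- count_changed(adjust_phospho(ph, pr), threshold = 1)
  expect_equal(counts$n_changed, 2)
  expect_equal(counts$n_up, 1)
  expect_equal(counts$n_down, 1)
  expect_equal(counts$n_total, 3)

  empty <- count_changed(adjust_phospho(ph, pr)[0, ])
  expect_equal(nrow(empty), 0)
  expect_error(count_changed(adjust_phospho(ph, pr), threshold = 0),
               "positive")
})

test_that("drop_unmatched restricts counting to adjusted records", {
  ph <- phospho_records(list("a", "P1", "c1", 2.0),
                        list("b", "P9", "c1", 2.0))
  pr <- protein_records(list("P1", "c1", 0))
  keep <- count_changed(adjust_phospho(ph, pr), drop_unmatched = FALSE)
  drop <- count_changed(adjust_phospho(ph, pr), drop_unmatched = TRUE)
  expect_equal(keep$n_changed, 2)
  expect_equal(drop$n_changed, 1)
})

test_that("pure abundance changes are driven to adjusted zero at no noise", {
  des <- two_condition_design(2, 2)
  spec <- effect_spec(n_proteins = 10, frac_proteins_changed = 0.5,
                      protein_log2fc = 1, n_phosphopeptides = 30,
                      frac_phospho_changed = 0,  # no site effects at all
                      noise_sd_log2 = 0, loading_offsets_log2 = 0, seed = 6)
  sim <- simulate_psm_table(des, spec)
  prot <- summarize_proteins(median_normalize(collapse_psms(sim$psms)))
  prot_de <- differential_test(prot, des)

  ph <- simulate_phospho_psm_table(des, spec, sim$truth)
  pep <- median_normalize(collapse_psms(ph$psms, keep_shared = TRUE))
  ph_de <- differential_test(pep$log2, des,
                             feature_annotation =
                               pep$features["protein_accession"])
  adj <- adjust_phospho(ph_de, prot_de)
  expect_true(all(adj$status == "adjusted"))
  # median normalization identifies fold changes up to a per-contrast
  # intercept (planted effects contaminate the sample medians); at zero
  # noise the adjusted values collapse to that single constant, near zero
  offset <- median(adj$adjusted_log2fc)
  expect_lt(max(abs(adj$adjusted_log2fc - offset)), 1e-9)
  expect_lt(abs(offset), 0.15)
})

test_that("adjusted log2FC is exactly zero when medians are effect-free", {
  # hand-built pure-abundance scenario: the changed protein's ions sit above
  # the upper middle ranks in every sample, so no sample median moves and
  # the equal-loading assumption holds exactly
  des <- two_condition_design(2, 2)
  flat <- function(v_ref, v_trt = v_ref) {
    c(ref_r1 = 2^v_ref, ref_r2 = 2^v_ref, trt_r1 = 2^v_trt, trt_r2 = 2^v_trt)
  }
  prot_psms <- make_psms(list(
    list(seq = "HIGHAK", acc = "P1", int = flat(10, 11)),      # +1 planted
    list(seq = "HIGHBK", acc = "P1", int = flat(10.5, 11.5)),  # +1 planted
    list(seq = "AAK", acc = "P2", int = flat(5)),
    list(seq = "ABK", acc = "P2", int = flat(5.2)),
    list(seq = "BAK", acc = "P3", int = flat(6)),
    list(seq = "BBK", acc = "P3", int = flat(6.1)),
    list(seq = "CAK", acc = "P4", int = flat(7)),
    list(seq = "CBK", acc = "P4", int = flat(7.3))
  ), des$sample_id)
  ph_psms <- make_psms(list(
    list(seq = "SPHOSK", mods = "1xPhospho [S2]", acc = "P1",
         int = flat(12, 13)),                                  # pure abundance
    list(seq = "TPHOSK", mods = "1xPhospho [T1]", acc = "P2", int = flat(6)),
    list(seq = "YPHOSK", mods = "1xPhospho [Y3]", acc = "P3", int = flat(7)),
    list(seq = "SPHOTK", mods = "1xPhospho [S5]", acc = "P4", int = flat(5))
  ), des$sample_id)

  prot_de <- differential_test(
    summarize_proteins(median_normalize(collapse_psms(prot_psms))), des)
  expect_equal(prot_de$log2fc[prot_de$feature_id == "P1"], 1,
               tolerance = 1e-12)
  pep <- median_normalize(collapse_psms(ph_psms, keep_shared = TRUE))
  ph_de <- differential_test(pep$log2, des,
                             feature_annotation =
                               pep$features["protein_accession"])
  adj <- adjust_phospho(ph_de, prot_de)
  expect_true(all(adj$status == "adjusted"))
  expect_equal(adj$adjusted_log2fc, rep(0, 4), tolerance = 1e-12)
})

test_that("planted site effects are counted exactly at zero noise", {
  des <- two_condition_design(2, 2)
  spec <- effect_spec(n_proteins = 10, frac_proteins_changed = 0.3,
                      protein_log2fc = 1, n_phosphopeptides = 100,
                      frac_phospho_changed = 0.25, phospho_log2fc = 1.5,
                      noise_sd_log2 = 0, loading_offsets_log2 = 0, seed = 14)
  sim <- simulate_psm_table(des, spec)
  prot_de <- differential_test(
    summarize_proteins(median_normalize(collapse_psms(sim$psms))), des)
  ph <- simulate_phospho_psm_table(des, spec, sim$truth)
  pep <- median_normalize(collapse_psms(ph$psms, keep_shared = TRUE))
  ph_de <- differential_test(pep$log2, des,
                             feature_annotation =
                               pep$features["protein_accession"])
  adj <- adjust_phospho(ph_de, prot_de)
  counts <- count_changed(adj, threshold = 1)
  # 25 planted site effects of |log2fc| = 1.5 >= the twofold threshold
  expect_equal(counts$n_changed, 25)
  expect_equal(counts$n_up + counts$n_down, 25)
})
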