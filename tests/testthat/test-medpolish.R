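test_that("median polish solves small tables exactly", {
  # constant table
  fit <- median_polish(matrix(5, 2, 2))
  expect_equal(fit$overall, 5)
  expect_equal(unname(fit$row_effects), c(0, 0))
  expect_equal(unname(fit$column_effects), c(0, 0))
  expect_equal(unname(fit$residuals), matrix(0, 2, 2))

  # hand-iterated 2x2: rows [1,4] and [3,6]
  y <- matrix(c(1, 3, 4, 6), 2, 2)
  fit <- median_polish(y)
  expect_equal(fit$overall, 3.5)
  expect_equal(unname(fit$row_effects), c(-1, 1))
  expect_equal(unname(fit$column_effects), c(-1.5, 1.5))
  expect_equal(unname(fit$residuals), matrix(0, 2, 2), tolerance = 1e-12)
  expect_equal(unname(fit$overall + fit$column_effects), c(2, 5))
  expect_true(fit$converged)
})

test_that("any exactly additive table is a fixed point (zero residuals)", {
  set.seed(101)
  for (rep in 1:10) {
    r <- rnorm(5); cc <- rnorm(7); a <- rnorm(1)
    y <- a + outer(r, rep(1, 7)) + outer(rep(1, 5), cc)
    fit <- median_polish(y)
    expect_lt(max(abs(fit$residuals)), 1e-9)
    # decomposition reconstructs the input
    recon <- fit$overall + outer(fit$row_effects, rep(1, 7)) +
      outer(rep(1, 5), fit$column_effects) + fit$residuals
    expect_equal(unname(recon), unname(y), tolerance = 1e-9)
  }
})

test_that("decomposition reconstructs observed cells and centers effects", {
  set.seed(77)
  y <- random_matrix_with_missing(6, 8, 0.1)
  fit <- median_polish(y, tol = 1e-10, max_iter = 100)
  recon <- fit$overall + outer(fit$row_effects, rep(1, 8)) +
    outer(rep(1, 6), fit$column_effects) + fit$residuals
  obs <- !is.na(y)
  expect_equal(recon[obs], y[obs], tolerance = 1e-9)
  expect_equal(median(fit$row_effects), 0, tolerance = 1e-9)
  expect_equal(median(fit$column_effects), 0, tolerance = 1e-9)
})

test_that("polish matches the independent reference sweep on random tables", {
  set.seed(20240917)
  for (rep in 1:25) {
    y <- random_matrix_with_missing(6, 8, 0.1)
    fit <- median_polish(y)
    expect_equal(unname(fit$overall + fit$column_effects),
                 ref_medpolish_summary(y), tolerance = 1e-9)
  }
})

test_that("polish agrees with stats::medpolish on complete tables", {
  set.seed(5)
  for (rep in 1:10) {
    y <- matrix(rnorm(48), 6, 8)
    mine <- median_polish(y, tol = 1e-12, max_iter = 200)
    ref <- stats::medpolish(y, eps = 1e-13, maxiter = 200,
                            trace.iter = FALSE)
    expect_equal(unname(mine$overall + mine$column_effects),
                 unname(ref$overall + ref$col), tolerance = 1e-8)
  }
})

test_that("all-missing rows and columns are rejected with identification", {
  y <- matrix(rnorm(12), 3, 4,
              dimnames = list(paste0("pep", 1:3), paste0("s", 1:4)))
  y["pep2", ] <- NA
  expect_error(median_polish(y), "pep2")
  y2 <- matrix(rnorm(12), 3, 4,
               dimnames = list(paste0("pep", 1:3), paste0("s", 1:4)))
  y2[, "s3"] <- NA
  expect_error(median_polish(y2), "s3")
})

test_that("protein summarization passes single peptides through unchanged", {
  des <- two_condition_design(2, 2)
  psms <- make_psms(list(
    list(seq = "AK", acc = "P1",
         int = c(ref_r1 = 8, ref_r2 = 8, trt_r1 = 16, trt_r2 = 16))
  ), des$sample_id)
  pep <- collapse_psms(psms)
  pep$normalized <- TRUE   # bypass normalization for the identity check
  prot <- summarize_proteins(pep)
  expect_equal(prot["P1", ], pep$log2[1, ])
})

test_that("summaries ignore constant per-peptide ionization offsets", {
  des <- two_condition_design(2, 2)
  x <- c(ref_r1 = 1, ref_r2 = 1.2, trt_r1 = 3, trt_r2 = 3.1)
  # first peptide at 2^x, second offset by a constant +4 in log2
  psms <- make_psms(list(
    list(seq = "AK", acc = "P1", int = 2^x),
    list(seq = "CK", acc = "P1", int = 2^(x + 4))
  ), des$sample_id)
  pep <- collapse_psms(psms)
  pep$normalized <- TRUE
  prot <- summarize_proteins(pep)
  # offset absorbed into row effects: summary equals midpoint profile + 2
  expect_equal(unname(prot["P1", ]), unname(x + 2), tolerance = 1e-9)

  # shifting one peptide row never changes the summary shape across samples
  psms2 <- make_psms(list(
    list(seq = "AK", acc = "P1", int = 2^x),
    list(seq = "CK", acc = "P1", int = 2^(x + 9))
  ), des$sample_id)
  pep2 <- collapse_psms(psms2)
  pep2$normalized <- TRUE
  prot2 <- summarize_proteins(pep2)
  expect_equal(unname(prot2["P1", ] - prot["P1", ]), rep(2.5, 4),
               tolerance = 1e-9)
})

test_that("sample column permutation permutes summaries identically", {
  des <- two_condition_design(3, 3)
  spec <- effect_spec(n_proteins = 6, seed = 33)
  sim <- simulate_psm_table(des, spec)
  pep <- median_normalize(collapse_psms(sim$psms))
  prot <- summarize_proteins(pep)
  perm <- rev(seq_len(ncol(pep$log2)))
  pep_perm <- pep
  pep_perm$log2 <- pep_perm$log2[, perm]
  prot_perm <- summarize_proteins(pep_perm)
  expect_equal(prot_perm, prot[, perm])
})

test_that("an all-missing sample within one protein yields NA, not an error", {
  des <- two_condition_design(2, 2)
  psms <- make_psms(list(
    list(seq = "AK", acc = "P1", int = c(ref_r1 = 4, ref_r2 = 4, trt_r1 = 8)),
    list(seq = "CK", acc = "P1", int = c(ref_r1 = 6, ref_r2 = 7, trt_r1 = 9)),
    list(seq = "DK", acc = "P2",
         int = c(ref_r1 = 2, ref_r2 = 2, trt_r1 = 2, trt_r2 = 2))
  ), des$sample_id)
  pep <- collapse_psms(psms)
  pep$normalized <- TRUE
  prot <- summarize_proteins(pep)
  expect_true(is.na(prot["P1", "trt_r2"]))
  expect_false(anyNA(prot["P2", ]))
})

test_that("summarization requires a normalized matrix and excludes shared ions", {
  des <- two_condition_design(1, 1)
  psms <- make_psms(list(
    list(seq = "AK", acc = "P1", int = c(ref_r1 = 4, trt_r1 = 8)),
    list(seq = "CK", acc = "P1;P2", int = c(ref_r1 = 2, trt_r1 = 2))
  ), des$sample_id)
  pep <- collapse_psms(psms, keep_shared = TRUE)
  expect_error(summarize_proteins(pep), "normalized")
  pep$normalized <- TRUE
  prot <- summarize_proteins(pep)
  expect_equal(rownames(prot), "P1")
  prot_all <- summarize_proteins(pep, include_shared = TRUE)
  expect_setequal(rownames(prot_all), c("P1", "P2"))
})
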