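# Feature-wise fixed-effects linear models, contrasts against the
# reference condition, and Benjamini-Hochberg FDR control.
#
# The model for one feature (protein or phosphopeptide ion) is
#   y_st = beta0 + beta_condition(t) + eps_st,   eps ~ N(0, sigma^2)
# i.e. a one-way fixed-effects fit across ALL conditions of the design,
# with the residual variance pooled over every condition.  A contrast
# between a condition and the reference is then the familiar pooled-
# variance t-test, but with the larger pooled degrees of freedom.

#' Fit the feature-wise one-way linear model
#'
#' @param values named numeric vector of (normalized log2) intensities, one
#'   per sample; names must be design sample_ids.  Missing values are
#'   dropped.
#' @param design a [sample_design()].
#' @return list of class `feature_fit` with `condition_means`,
#'   `n_per_condition`, `residual_variance`, `residual_df`, and `flagged`
#'   (TRUE when no residual degrees of freedom remain).
#' @export
fit_feature <- function(values, design) {
  if (is.null(names(values))) stop("values must be named by sample_id")
  unknown <- setdiff(names(values), design$sample_id)
  if (length(unknown) > 0) {
    stop("values for sample(s) not in design: ",
         paste(unknown, collapse = ", "))
  }
  cond <- design$condition[match(names(values), design$sample_id)]
  keep <- !is.na(values)
  v <- as.numeric(values[keep])
  g <- cond[keep]
  conditions <- unique(g)
  if (length(conditions) < 2) {
    stop("need observations in at least two conditions to fit")
  }
  means <- tapply(v, factor(g, conditions), mean)
  n_per <- tapply(v, factor(g, conditions), length)
  rss <- sum((v - means[g])^2)
  df <- length(v) - length(conditions)
  fit <- list(condition_means = stats::setNames(as.numeric(means), conditions),
              n_per_condition = stats::setNames(as.integer(n_per), conditions),
              residual_variance = if (df > 0) rss / df else NA_real_,
              residual_df = as.integer(df),
              flagged = df == 0L)
  class(fit) <- "feature_fit"
  fit
}

#' Test a contrast between a condition and the reference
#'
#' log2FC is the difference of condition means; its standard error uses the
#' pooled residual variance of the full model.  The p-value is two-sided
#' Student-t on the model's residual degrees of freedom.
#'
#' Degenerate cases: with zero residual variance and a non-zero log2FC the
#' p-value is set to 0 and the record is flagged degenerate; with zero
#' variance and zero log2FC, t = 0 and p = 1.  With zero residual df the
#' p-value is missing.
#'
#' @param fit a `feature_fit` from [fit_feature()].
#' @param condition,reference condition labels present in the fit.
#' @return one-row data.frame with `contrast`, `log2fc`, `se`, `t`, `df`,
#'   `p`, `degenerate`.
#' @export
test_contrast <- function(fit, condition, reference) {
  stopifnot(inherits(fit, "feature_fit"))
  for (cc in c(condition, reference)) {
    if (!cc %in% names(fit$condition_means)) {
      stop("condition '", cc, "' not present in fit")
    }
  }
  fc <- unname(fit$condition_means[condition] - fit$condition_means[reference])
  s2 <- fit$residual_variance
  nc <- fit$n_per_condition[condition]
  nr <- fit$n_per_condition[reference]
  degenerate <- FALSE
  if (fit$flagged || is.na(s2)) {
    se <- NA_real_; tstat <- NA_real_; p <- NA_real_
  } else if (s2 == 0) {
    se <- 0
    if (fc == 0) {
      tstat <- 0; p <- 1
    } else {
      tstat <- Inf * sign(fc); p <- 0; degenerate <- TRUE
    }
  } else {
    se <- sqrt(s2 * (1 / nc + 1 / nr))
    tstat <- fc / se
    p <- 2 * stats::pt(-abs(tstat), df = fit$residual_df)
  }
  data.frame(contrast = paste0(condition, "_vs_", reference),
             log2fc = fc, se = se, t = tstat, df = fit$residual_df,
             p = p, degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Thin validating wrapper around `stats::p.adjust(method = "BH")`, applied
#' per contrast across all features of one data type.  `NA` p-values give
#' `NA` q-values and do not enter the number of tests.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values, same order as `p`.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Differential testing of every feature in a matrix
#'
#' Fits the one-way model per feature (matrix row) and tests each requested
#' condition against the design's reference, then applies Benjamini-Hochberg
#' FDR separately within each contrast.
#'
#' @param m numeric feature-by-sample matrix (log2 scale); colnames are
#'   sample_ids.
#' @param design a [sample_design()].
#' @param conditions conditions to contrast against the reference; default
#'   all non-reference conditions of the design.
#' @param feature_annotation optional data.frame of per-feature columns
#'   (e.g. `protein_accession`), row-aligned with `m`, carried into the
#'   output.
#' @return data.frame with columns `feature_id`, `contrast`, `log2fc`, `se`,
#'   `t`, `df`, `p`, `q`, `degenerate`, plus any annotation columns.
#' @export
differential_test <- function(m, design, conditions = NULL,
                              feature_annotation = NULL) {
  ref <- reference_condition(design)
  if (is.null(conditions)) {
    conditions <- setdiff(unique(design$condition), ref)
  }
  m <- m[, colnames(m) %in% design$sample_id, drop = FALSE]
  if (ncol(m) == 0) stop("matrix has no columns matching the design")
  if (!is.null(feature_annotation) &&
      nrow(feature_annotation) != nrow(m)) {
    stop("feature_annotation must have one row per matrix row")
  }

  res <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    fit <- tryCatch(fit_feature(m[i, ], design), error = function(e) NULL)
    if (is.null(fit)) next
    rows <- lapply(conditions, function(cc) {
      if (!cc %in% names(fit$condition_means)) return(NULL)
      test_contrast(fit, cc, ref)
    })
    rows <- do.call(rbind, rows)
    if (is.null(rows) || nrow(rows) == 0) next
    rows <- data.frame(feature_id = rownames(m)[i], rows,
                       stringsAsFactors = FALSE)
    if (!is.null(feature_annotation)) {
      rows <- cbind(rows, feature_annotation[rep(i, nrow(rows)), ,
                                             drop = FALSE])
      rownames(rows) <- NULL
    }
    res[[i]] <- rows
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    stop("no feature could be fitted against the design")
  }
  out$q <- NA_real_
  for (cc in unique(out$contrast)) {
    sel <- out$contrast == cc
    out$q[sel] <- adjust_bh(out$p[sel])
  }
  rownames(out) <- NULL
  out
}
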