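#' TAMPOR-style median polish of ratios to reference channels
#'
#' Two-way iterative normalization for multiplexed (TMT) proteomics: on the
#' log2 scale, the procedure alternates (1) subtracting, per feature and
#' per batch, the feature's median over that batch's reference (GIS)
#' samples — the log-scale equivalent of taking the ratio to the pooled
#' internal standard — and (2) subtracting, per sample, the sample's median
#' over features.  Iteration continues until the largest absolute
#' adjustment falls below `tol` or `max_iter` is reached.  After
#' convergence, every sample's median log2 ratio is ~0 and every feature's
#' per-batch reference median is ~0, which removes batch- and
#' loading-driven offsets while leaving biological contrasts intact.
#'
#' @param matrix Numeric matrix, features x samples, log2 scale, `NA`
#'   allowed.
#' @param batch Batch label per sample column.
#' @param is_reference Logical per sample column; `TRUE` marks GIS
#'   reference channels.  Every batch must contain at least one.
#' @param max_iter Maximum sweeps (default 250).
#' @param tol Convergence tolerance on the largest absolute adjustment
#'   (default 1e-8).
#' @return List with `matrix` (normalized), `trace` (per-iteration largest
#'   adjustment) and `converged`.
#' @export
tampor_normalize <- function(matrix, batch, is_reference,
                             max_iter = 250, tol = 1e-8) {
  assert_matrix(matrix)
  if (length(batch) != ncol(matrix) || length(is_reference) != ncol(matrix))
    stopf("'batch' and 'is_reference' must have one entry per sample column")
  batch <- as.character(batch)
  for (b in unique(batch))
    if (!any(is_reference[batch == b]))
      stopf("batch '%s' has no reference (GIS) sample", b)
  x <- matrix
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (b in unique(batch)) {
      in_b <- batch == b
      ref_med <- apply(x[, in_b & is_reference, drop = FALSE], 1, median,
                       na.rm = TRUE)
      ref_med[is.na(ref_med)] <- 0
      x[, in_b] <- x[, in_b, drop = FALSE] - ref_med
      delta <- max(delta, max(abs(ref_med), na.rm = TRUE))
    }
    samp_med <- apply(x, 2, median, na.rm = TRUE)
    samp_med[is.na(samp_med)] <- 0
    x <- sweep(x, 2, samp_med)
    delta <- max(delta, max(abs(samp_med), na.rm = TRUE))
    trace <- c(trace, delta)
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("TAMPOR did not converge in %d iterations (last adjustment %.3g)",
                    max_iter, trace[length(trace)]))
  list(matrix = x, trace = trace, converged = converged)
}

#' Remove features with excessive missingness
#'
#' Drops features absent in `max_missing_fraction` of samples or more
#' (default: missing in 50% of cases or greater), leaving the remaining
#' values untouched.
#'
#' @param matrix Numeric matrix, features x samples.
#' @param max_missing_fraction Removal threshold in (0, 1]; a feature is
#'   removed when `missing fraction >= max_missing_fraction`.
#' @return The filtered matrix, with `attr(., "n_removed")`.
#' @export
filter_missingness <- function(matrix, max_missing_fraction = 0.5) {
  assert_matrix(matrix)
  if (max_missing_fraction <= 0 || max_missing_fraction > 1)
    stopf("'max_missing_fraction' must be in (0, 1]")
  frac <- rowMeans(is.na(matrix))
  keep <- frac < max_missing_fraction
  message(sprintf("filter_missingness: removed %d of %d features (threshold %.0f%%)",
                  sum(!keep), nrow(matrix), 100 * max_missing_fraction))
  out <- matrix[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Iterative network-connectivity outlier detection
#'
#' Flags outlier samples by low mean inter-sample correlation: each
#' sample's mean Pearson correlation to all other samples is standardized,
#' samples with z below `z_threshold` are removed, and the procedure
#' repeats on the remaining samples until no sample is flagged or
#' `max_rounds` is reached.
#'
#' @param matrix Numeric matrix, features x samples (>= 4 samples).
#' @param z_threshold Flagging threshold on the connectivity z-score
#'   (default -3).
#' @param max_rounds Maximum removal rounds (default 5).
#' @return List with `outliers` (sample ids in removal order) and `rounds`
#'   (per-round data frame of sample, mean correlation, z).
#' @export
detect_outliers <- function(matrix, z_threshold = -3, max_rounds = 5) {
  assert_matrix(matrix)
  if (ncol(matrix) < 4) stopf("outlier detection needs >= 4 samples")
  keep <- colnames(matrix)
  if (is.null(keep)) keep <- as.character(seq_len(ncol(matrix)))
  colnames(matrix) <- keep
  outliers <- character(0)
  rounds <- list()
  for (round in seq_len(max_rounds)) {
    x <- matrix[, keep, drop = FALSE]
    cc <- cor(x, use = "pairwise.complete.obs")
    diag(cc) <- NA
    mean_cor <- rowMeans(cc, na.rm = TRUE)
    z <- (mean_cor - mean(mean_cor)) / sd(mean_cor)
    rounds[[round]] <- data.frame(round = round, sample = names(mean_cor),
                                  mean_cor = mean_cor, z = z,
                                  row.names = NULL)
    flagged <- names(z)[z < z_threshold]
    if (length(flagged) == 0) break
    if (length(flagged) >= length(keep))
      stopf("all samples flagged as outliers; matrix is degenerate")
    outliers <- c(outliers, flagged)
    keep <- setdiff(keep, flagged)
  }
  list(outliers = outliers, rounds = do.call(rbind, rounds))
}

#' Bootstrap regression of nuisance covariates
#'
#' Removes variation attributable to nuisance covariates (default: age,
#' sex, PMI, batch) from each feature while preserving the protected
#' biological terms (default: diagnosis group).  Per feature, ordinary
#' least squares is fit to `abundance ~ protected + covariates` on `n_boot`
#' bootstrap resamples of the samples; covariate coefficients are
#' aggregated as the median over resamples, and the covariate design
#' (column-centered, so the grand mean is retained) times those
#' coefficients is subtracted from the data.  Missing values stay missing.
#'
#' @param matrix Numeric matrix, features x samples.
#' @param pheno Data frame of per-sample variables (rows aligned with the
#'   sample columns).
#' @param covariates Names of nuisance columns of `pheno` to regress out.
#' @param protected Names of columns whose contribution must be preserved.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed (mandatory; the resampling is the only source
#'   of randomness).
#' @return The adjusted matrix, with `attr(., "coefficients")` holding the
#'   median covariate coefficients (covariate design columns x features).
#' @export
regress_covariates <- function(matrix, pheno,
                               covariates = c("age", "sex", "pmi", "batch"),
                               protected = "group",
                               n_boot = 1000, seed) {
  assert_matrix(matrix)
  if (missing(seed)) stopf("'seed' is required")
  if (n_boot < 1) stopf("'n_boot' must be >= 1")
  if (nrow(pheno) != ncol(matrix))
    stopf("'pheno' must have one row per sample column")
  vars <- c(protected, covariates)
  missing_vars <- setdiff(vars, colnames(pheno))
  if (length(missing_vars) > 0)
    stopf("variables not in 'pheno': %s", paste(missing_vars, collapse = ", "))
  if (anyNA(pheno[, vars])) stopf("covariates must be present for all samples")
  form <- stats::as.formula(paste("~", paste(vars, collapse = " + ")))
  X <- model.matrix(form, data = pheno)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stopf("design is rank deficient; collinear columns: %s",
          paste(drop_cols, collapse = ", "))
  }
  term_of <- attr(X, "assign")
  term_labels <- attr(stats::terms(form), "term.labels")
  cov_cols <- which(term_of > 0)
  cov_cols <- cov_cols[term_labels[term_of[cov_cols]] %in% covariates]
  n <- ncol(matrix)
  Y <- t(matrix)                       # samples x features
  set.seed(seed)
  coef_boot <- array(NA_real_, dim = c(n_boot, length(cov_cols), nrow(matrix)))
  complete_feat <- !apply(is.na(Y), 2, any)
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      Xb <- X[idx, , drop = FALSE]
      if (qr(Xb)$rank == ncol(X)) break
    }
    XtXi <- chol2inv(chol(crossprod(Xb)))
    if (any(complete_feat)) {
      beta <- XtXi %*% crossprod(Xb, Y[idx, complete_feat, drop = FALSE])
      coef_boot[b, , complete_feat] <- beta[cov_cols, , drop = FALSE]
    }
    for (f in which(!complete_feat)) {
      yb <- Y[idx, f]
      ok <- !is.na(yb)
      if (sum(ok) <= ncol(X)) next
      Xf <- Xb[ok, , drop = FALSE]
      if (qr(Xf)$rank < ncol(X)) next
      fit <- .lm.fit(Xf, yb[ok])
      coef_boot[b, , f] <- fit$coefficients[cov_cols]
    }
  }
  med_coef <- apply(coef_boot, c(2, 3), median, na.rm = TRUE)
  rownames(med_coef) <- colnames(X)[cov_cols]
  colnames(med_coef) <- rownames(matrix)
  X_cov <- X[, cov_cols, drop = FALSE]
  X_cov <- sweep(X_cov, 2, colMeans(X_cov))   # keep the grand mean
  adj <- Y - X_cov %*% med_coef
  out <- t(adj)
  dimnames(out) <- dimnames(matrix)
  attr(out, "coefficients") <- med_coef
  out
}

#' Floor imputation for an immunoassay trait
#'
#' Replaces missing (below-detection) trait values with a fixed floor —
#' for pTDP-43, 0.1, roughly half of the lowest detected level.  Observed
#' entries are unchanged.
#'
#' @param trait_values Numeric vector with `NA` for below-detection.
#' @param floor Positive imputation value (default 0.1).
#' @return The vector with `NA` replaced by `floor`.
#' @export
impute_trait_floor <- function(trait_values, floor = 0.1) {
  if (floor <= 0) stopf("'floor' must be positive")
  trait_values[is.na(trait_values)] <- floor
  trait_values
}
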