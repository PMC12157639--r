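#' Biweight midcorrelation
#'
#' Robust correlation built from Tukey biweights: observations are weighted
#' by `w = (1 - u^2)^2` with `u = (x - median(x)) / (9 * MAD(x))` (unscaled
#' median absolute deviation) and weights of zero beyond `|u| >= 1`, so a
#' handful of outlying values cannot dominate the coefficient the way they
#' do for Pearson correlation.  Pairs with a missing value in either vector
#' are dropped before medians and MADs are computed (pairwise-complete).
#' When either vector has `MAD == 0` on the complete pairs (more than half
#' its values tied), the coefficient falls back to Pearson for that pair and
#' the result is tagged accordingly.
#'
#' @param x,y Numeric vectors of equal length; `NA` allowed.
#' @return A single correlation in `[-1, 1]` with attributes `n_used`
#'   (number of complete pairs) and `method` (`"bicor"` or `"pearson"`).
#' @examples
#' set.seed(1)
#' x <- rnorm(30); y <- x + rnorm(30, sd = 0.5)
#' bicor(x, y)
#' @export
bicor <- function(x, y) {
  if (length(x) != length(y)) stopf("'x' and 'y' must have equal length")
  res <- bicor_cross_cpp(cbind(as.numeric(x)), cbind(as.numeric(y)), min_n = 3L)
  n <- res$n[1, 1]
  if (n < 3) stopf("bicor needs >= 3 pairwise-complete observations, got %d", n)
  r <- res$r[1, 1]
  structure(r, n_used = n,
            method = if (res$method[1, 1] == 1L) "pearson" else "bicor")
}

# Internal: bicor of all columns of X (samples x features) against all
# columns of Y, pairwise-complete.  Returns list(r, n, method).
# Complete data admits a fast path: the per-pair subset is then the full
# column, so each column is biweight-transformed once and the coefficient
# matrix is a single cross-product.
bicor_matrix <- function(x, y = NULL, min_n = 3L) {
  if (!anyNA(x) && (is.null(y) || !anyNA(y)) && nrow(x) >= min_n) {
    tx <- biweight_columns(x)
    ty <- if (is.null(y)) tx else biweight_columns(y)
    if (!any(tx$pearson) && !any(ty$pearson)) {
      r <- crossprod(tx$a, ty$a)
      r <- pmin(pmax(r, -1), 1)
      if (is.null(y)) diag(r) <- 1
      n <- base::matrix(nrow(x), nrow(r), ncol(r))
      method <- base::matrix(0L, nrow(r), ncol(r))
      return(list(r = r, n = n, method = method))
    }
  }
  if (is.null(y)) bicor_self_cpp(x, min_n) else bicor_cross_cpp(x, y, min_n)
}

# Internal: unit-normalized biweight transform of each column (Pearson
# centering where MAD = 0), mirroring the per-pair C++ kernel.
biweight_columns <- function(x) {
  p <- ncol(x)
  a <- base::matrix(0, nrow(x), p)
  pearson <- logical(p)
  med <- apply(x, 2, median)
  madv <- apply(abs(sweep(x, 2, med)), 2, median)
  for (j in seq_len(p)) {
    if (madv[j] == 0) {
      pearson[j] <- TRUE
      v <- x[, j] - mean(x[, j])
    } else {
      u <- (x[, j] - med[j]) / (9 * madv[j])
      w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
      v <- (x[, j] - med[j]) * w
    }
    nv <- sqrt(sum(v^2))
    a[, j] <- if (nv > 0) v / nv else 0
  }
  list(a = a, pearson = pearson)
}

#' Correlate every feature against every target with bicor
#'
#' Computes the full feature x target grid of biweight midcorrelations over
#' the shared samples (pairwise-complete per pair), with two-sided p-values
#' from the Student t approximation `t = r * sqrt((n - 2) / (1 - r^2))` on
#' `n_used - 2` degrees of freedom, Benjamini-Hochberg q-values across the
#' grid, and significance stars at 0.05 / 0.01 / 0.001.
#'
#' @param features_matrix Numeric matrix, features x samples.
#' @param targets_matrix Numeric matrix, targets x samples (a single target
#'   may be given as a named numeric vector over samples).
#' @return A data frame with columns `feature`, `target`, `estimate`,
#'   `n_used`, `method`, `p`, `q`, `stars`.
#' @export
correlate_grid <- function(features_matrix, targets_matrix) {
  assert_matrix(features_matrix, "features_matrix")
  if (is.vector(targets_matrix))
    targets_matrix <- matrix(targets_matrix, nrow = 1,
                             dimnames = list("target", names(targets_matrix)))
  shared <- intersect(colnames(features_matrix), colnames(targets_matrix))
  if (length(shared) == 0) stopf("no shared sample ids between features and targets")
  fx <- t(features_matrix[, shared, drop = FALSE])
  tx <- t(targets_matrix[, shared, drop = FALSE])
  res <- bicor_matrix(fx, tx)
  grid <- expand.grid(feature = rownames(features_matrix),
                      target = rownames(targets_matrix),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$estimate <- as.vector(res$r)
  grid$n_used <- as.vector(res$n)
  grid$method <- c("bicor", "pearson")[as.vector(res$method) + 1L]
  grid$p <- cor_p_value(grid$estimate, grid$n_used)
  grid$q <- p.adjust(grid$p, method = "BH")
  grid$stars <- p_stars(grid$p)
  grid
}

#' One-way ANOVA per feature with Benjamini-Hochberg correction
#'
#' Vectorized one-way F tests across groups for every row of an abundance
#' matrix.  For each feature, only groups with at least two non-missing
#' values enter the test; features with fewer than two such groups are
#' reported untested (`NA` statistics) and excluded from the BH family.
#'
#' @param matrix Numeric matrix, features x samples.
#' @param groups Factor or character vector of group labels, one per sample.
#' @return Data frame with per-group means (`mean_<group>`), `F`, `df1`,
#'   `df2`, `p`, `q` and `tested`.
#' @export
anova_bh <- function(matrix, groups) {
  assert_matrix(matrix)
  groups <- as.factor(groups)
  if (length(groups) != ncol(matrix))
    stopf("'groups' must have one label per sample column")
  if (nlevels(droplevels(groups)) < 2) stopf("ANOVA requires >= 2 groups")
  lev <- levels(droplevels(groups))
  G <- length(lev)
  nf <- nrow(matrix)
  ng <- mg <- vg <- base::matrix(0, nf, G, dimnames = list(rownames(matrix), lev))
  for (g in seq_along(lev)) {
    xg <- matrix[, groups == lev[g], drop = FALSE]
    ng[, g] <- rowSums(!is.na(xg))
    sg <- rowSums(xg, na.rm = TRUE)
    mg[, g] <- ifelse(ng[, g] > 0, sg / ng[, g], NA_real_)
    ssg <- rowSums(xg^2, na.rm = TRUE)
    vg[, g] <- ifelse(ng[, g] > 1, (ssg - sg^2 / pmax(ng[, g], 1)) / (ng[, g] - 1), NA_real_)
  }
  use <- ng >= 2
  k <- rowSums(use)
  tested <- k >= 2
  Fv <- p <- rep(NA_real_, nf)
  df1 <- df2 <- rep(NA_real_, nf)
  if (any(tested)) {
    nU <- ng * use
    N <- rowSums(nU)
    grand <- rowSums(ifelse(use, mg * ng, 0)) / N
    ssb <- rowSums(ifelse(use, ng * (mg - grand)^2, 0))
    ssw <- rowSums(ifelse(use, (ng - 1) * vg, 0))
    df1 <- k - 1
    df2 <- N - k
    msb <- ssb / df1
    msw <- ssw / df2
    Fv <- ifelse(tested & msw > 0, msb / msw, ifelse(tested & ssb == 0, 0, NA_real_))
    Fv[tested & !is.na(msw) & msw == 0 & ssb == 0] <- 0
    p[tested] <- pf(Fv[tested], df1[tested], df2[tested], lower.tail = FALSE)
    p[tested & !is.na(Fv) & Fv == 0] <- 1
  }
  q <- rep(NA_real_, nf)
  q[tested] <- p.adjust(p[tested], method = "BH")
  feat <- rownames(matrix)
  if (is.null(feat)) feat <- as.character(seq_len(nf))
  out <- data.frame(feature = feat, stringsAsFactors = FALSE)
  for (g in seq_along(lev)) out[[paste0("mean_", lev[g])]] <- mg[, g]
  out$F <- Fv; out$df1 <- ifelse(tested, df1, NA_real_)
  out$df2 <- ifelse(tested, df2, NA_real_)
  out$p <- p; out$q <- q; out$tested <- tested
  out
}

#' Two-group contrast (volcano table) per feature
#'
#' Welch t-test of `group_a` against `group_b` for every feature, with the
#' log2 fold change reported as the difference of group means of log2
#' abundance (`group_a - group_b`), BH q-values, and a significance class
#' (`increased` / `decreased` / `ns`) at `q < alpha`.
#'
#' @param matrix Numeric matrix, features x samples (log2 scale).
#' @param groups Group label per sample column.
#' @param group_a,group_b Labels to contrast; positive `log2fc` means higher
#'   in `group_a`.
#' @param alpha Significance level applied to BH q (default 0.05).
#' @param var_equal Pool the variances (classical two-sample t; default
#'   `FALSE` = Welch).
#' @return Data frame with `feature`, `mean_a`, `mean_b`, `log2fc`, `t`,
#'   `df`, `p`, `q`, `class`.
#' @export
group_contrast <- function(matrix, groups, group_a, group_b, alpha = 0.05,
                           var_equal = FALSE) {
  assert_matrix(matrix)
  groups <- as.character(groups)
  ia <- which(groups == group_a)
  ib <- which(groups == group_b)
  if (length(ia) == 0 || length(ib) == 0)
    stopf("both contrast groups must be nonempty")
  if (length(ia) < 2 || length(ib) < 2)
    stopf("each contrast group needs >= 2 samples")
  welch <- welch_rows(matrix[, ia, drop = FALSE], matrix[, ib, drop = FALSE],
                      var_equal = var_equal)
  q <- rep(NA_real_, nrow(matrix))
  q[welch$tested] <- p.adjust(welch$p[welch$tested], method = "BH")
  cls <- rep("ns", nrow(matrix))
  cls[!is.na(q) & q < alpha & welch$delta > 0] <- "increased"
  cls[!is.na(q) & q < alpha & welch$delta < 0] <- "decreased"
  data.frame(feature = rownames(matrix),
             mean_a = welch$m1, mean_b = welch$m2, log2fc = welch$delta,
             t = welch$t, df = welch$df, p = welch$p, q = q, class = cls,
             stringsAsFactors = FALSE)
}

# Internal: row-wise two-sample t of x1 vs x2 (features x samples each);
# Welch by default, pooled when var_equal.
welch_rows <- function(x1, x2, var_equal = FALSE) {
  n1 <- rowSums(!is.na(x1)); n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE); m2 <- rowMeans(x2, na.rm = TRUE)
  v1 <- rowSums((x1 - m1)^2, na.rm = TRUE) / pmax(n1 - 1, 1)
  v2 <- rowSums((x2 - m2)^2, na.rm = TRUE) / pmax(n2 - 1, 1)
  tested <- n1 >= 2 & n2 >= 2
  if (var_equal) {
    vp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- vp * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  }
  tt <- (m1 - m2) / sqrt(se2)
  p <- 2 * pt(abs(tt), df, lower.tail = FALSE)
  zerovar <- tested & !is.na(se2) & se2 == 0
  tt[zerovar] <- 0; p[zerovar] <- 1; df[zerovar] <- n1[zerovar] + n2[zerovar] - 2
  tt[!tested] <- NA_real_; p[!tested] <- NA_real_; df[!tested] <- NA_real_
  list(m1 = m1, m2 = m2, delta = m1 - m2, t = tt, df = df, p = p,
       tested = tested & !is.na(p))
}

#' Spearman correlation of every feature with the CE Burden Score
#'
#' Per-feature Spearman rank correlation against the cumulative CE Burden
#' Score (pairwise-complete), with t-approximation p-values and BH q-values.
#' Constant features have undefined rho and are reported missing (excluded
#' from the BH family).
#'
#' @param matrix Numeric matrix, features x samples.
#' @param burden_score Named numeric vector of burden scores covering the
#'   sample columns.
#' @return Data frame with `feature`, `rho`, `n_used`, `p`, `q`.
#' @export
spearman_burden <- function(matrix, burden_score) {
  assert_matrix(matrix)
  if (is.null(names(burden_score))) {
    if (length(burden_score) != ncol(matrix))
      stopf("'burden_score' must be named or match the sample columns")
    names(burden_score) <- colnames(matrix)
  }
  shared <- intersect(colnames(matrix), names(burden_score))
  if (length(shared) < 3) stopf("burden score must cover >= 3 samples with feature data")
  x <- matrix[, shared, drop = FALSE]
  b <- burden_score[shared]
  rho <- n_used <- rep(NA_real_, nrow(x))
  for (i in seq_len(nrow(x))) {
    ok <- !is.na(x[i, ]) & !is.na(b)
    n_used[i] <- sum(ok)
    if (n_used[i] >= 3 && sd(x[i, ok]) > 0 && sd(b[ok]) > 0)
      rho[i] <- cor(rank(x[i, ok]), rank(b[ok]))
  }
  p <- cor_p_value(rho, n_used)
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- p.adjust(p[!is.na(p)], method = "BH")
  data.frame(feature = rownames(x), rho = rho, n_used = n_used, p = p, q = q,
             stringsAsFactors = FALSE)
}

#' Directional bias of CE-transcript proteins along the burden axis
#'
#' Among proteins whose transcripts are predicted to harbor cryptic exons,
#' counts how many are significantly negatively vs positively correlated
#' with the CE Burden Score, and tests the split against symmetry with an
#' exact binomial sign test.  A strong negative excess is the expected
#' signature of CE-containing transcripts being degraded (e.g. by NMD) and
#' their protein products depleted.
#'
#' @param spearman_result Output of [spearman_burden()].
#' @param ce_gene_list Character vector of CE-transcript gene symbols.
#' @param alpha Significance cutoff (default 0.05).
#' @param use `"q"` (BH-adjusted, default) or `"p"` (nominal).
#' @return List with `n_negative`, `n_positive`, `p_value` (two-sided exact
#'   binomial against 0.5), and the significant CE-gene subtable.
#' @export
ce_gene_bias <- function(spearman_result, ce_gene_list, alpha = 0.05,
                         use = c("q", "p")) {
  use <- match.arg(use)
  hit <- spearman_result$feature %in% ce_gene_list
  if (!any(hit)) stopf("no CE-transcript genes found among the features")
  sub <- spearman_result[hit, , drop = FALSE]
  crit <- sub[[use]]
  sig <- !is.na(crit) & crit < alpha & !is.na(sub$rho)
  n_neg <- sum(sig & sub$rho < 0)
  n_pos <- sum(sig & sub$rho > 0)
  pv <- if (n_neg + n_pos == 0) 1 else
    binom.test(n_neg, n_neg + n_pos, p = 0.5)$p.value
  list(n_negative = n_neg, n_positive = n_pos, p_value = pv,
       significant = sub[sig, , drop = FALSE])
}
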