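#' Average technical replicates per biological sample
#'
#' Collapses replicate columns to their biological sample by the
#' available-case mean (missing replicates ignored; all replicates missing
#' leaves the cell missing).
#'
#' @param matrix Numeric matrix, features x replicate columns.
#' @param replicate_map Named character vector mapping every column name to
#'   its biological sample id.
#' @return Features x samples matrix, one column per unique sample id (in
#'   first-appearance order).
#' @export
average_technical_replicates <- function(matrix, replicate_map) {
  assert_matrix(matrix)
  unmapped <- setdiff(colnames(matrix), names(replicate_map))
  if (length(unmapped) > 0)
    stopf("columns without a replicate mapping: %s",
          paste(unmapped, collapse = ", "))
  samples <- unique(unname(replicate_map[colnames(matrix)]))
  out <- base::matrix(NA_real_, nrow(matrix), length(samples),
                      dimnames = list(rownames(matrix), samples))
  for (s in samples) {
    cols <- colnames(matrix)[replicate_map[colnames(matrix)] == s]
    out[, s] <- rowMeans(matrix[, cols, drop = FALSE], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' Perseus-style downshifted-normal imputation of missing values
#'
#' Per sample column, missing entries are drawn from a normal distribution
#' with mean `mean_s - downshift * sd_s` and standard deviation
#' `width * sd_s`, where `mean_s` and `sd_s` come from that column's
#' observed values.  This encodes the assumption that missing label-free
#' intensities are predominantly below the detection limit (missing not at
#' random), so imputed values populate the lower tail.  Observed entries
#' are never altered.
#'
#' @param matrix Numeric matrix, features x samples.
#' @param width SD of the imputation distribution as a fraction of the
#'   observed SD (default 0.3).
#' @param downshift Mean shift in observed-SD units (default 1.8).
#' @param seed Integer seed (mandatory).
#' @return The matrix with missing cells imputed, plus
#'   `attr(., "n_imputed")`.
#' @export
perseus_impute <- function(matrix, width = 0.3, downshift = 1.8, seed) {
  assert_matrix(matrix)
  if (missing(seed)) stopf("'seed' is required")
  set.seed(seed)
  out <- matrix
  n_imp <- 0L
  for (j in seq_len(ncol(matrix))) {
    obs <- matrix[, j][!is.na(matrix[, j])]
    mis <- which(is.na(matrix[, j]))
    if (length(obs) < 3)
      stopf("column %s has fewer than 3 observed values; moments unreliable",
            if (!is.null(colnames(matrix))) colnames(matrix)[j] else j)
    if (length(mis) > 0) {
      out[mis, j] <- rnorm(length(mis),
                           mean = mean(obs) - downshift * sd(obs),
                           sd = width * sd(obs))
      n_imp <- n_imp + length(mis)
    }
  }
  attr(out, "n_imputed") <- n_imp
  out
}

#' Knockdown-vs-control differential abundance
#'
#' Per-protein Welch t-tests of the TDP-43 knockdown group against
#' control, with log2 fold change reported as knockdown minus control, BH
#' correction, and a class (`increased` / `decreased` / `ns`) at
#' `q < alpha`.
#'
#' @param matrix Numeric matrix, features x samples (imputed log2 scale).
#' @param groups Two-group label per sample column.
#' @param kd,control The knockdown and control labels (defaults `"KD"`,
#'   `"Control"`).
#' @param alpha Class threshold on BH q (default 0.05).
#' @return Data frame: `feature`, `mean_kd`, `mean_control`, `log2fc`,
#'   `t`, `df`, `p`, `q`, `class`.
#' @export
kd_differential <- function(matrix, groups, kd = "KD", control = "Control",
                            alpha = 0.05) {
  groups <- as.character(groups)
  extra <- setdiff(unique(groups), c(kd, control))
  if (length(extra) > 0)
    stopf("the knockdown arm is two-group by design; unexpected groups: %s",
          paste(extra, collapse = ", "))
  res <- group_contrast(matrix, groups, group_a = kd, group_b = control,
                        alpha = alpha)
  names(res)[names(res) == "mean_a"] <- "mean_kd"
  names(res)[names(res) == "mean_b"] <- "mean_control"
  res
}

#' Classify cross-modal concordance of proteome changes
#'
#' Links the tissue arm (per-protein Spearman correlation with the CE
#' Burden Score) to the knockdown arm (per-protein log2FC in TDP-43
#' knockdown neurons).  Proteins significant in BOTH datasets at
#' `q < alpha` (default FDR 0.1) are `concordant_down` when both effects
#' are negative, `concordant_up` when both are positive, and `discordant`
#' when the signs differ; everything else is `ns`.
#'
#' @param kd_result Output of [kd_differential()].
#' @param burden_corr Output of [spearman_burden()] on the tissue matrix.
#' @param alpha Two-sided FDR threshold applied in each dataset (default
#'   0.1).
#' @param use `"q"` (BH-adjusted, default) or `"p"` (nominal).
#' @param ce_gene_list Optional character vector; flags CE-transcript
#'   features in the output.
#' @return List of class `concordance_result`: `table` (per shared
#'   feature: `rho`, `tissue_q`, `log2fc`, `kd_q`, `class`, `ce_gene`) and
#'   `counts` (named vector over the four classes).
#' @export
classify_concordance <- function(kd_result, burden_corr, alpha = 0.1,
                                 use = c("q", "p"), ce_gene_list = NULL) {
  use <- match.arg(use)
  shared <- intersect(kd_result$feature, burden_corr$feature)
  if (length(shared) == 0) stopf("no shared features between the two datasets")
  kd <- kd_result[match(shared, kd_result$feature), ]
  ts <- burden_corr[match(shared, burden_corr$feature), ]
  kd_crit <- kd[[use]]
  ts_crit <- ts[[use]]
  sig_both <- !is.na(kd_crit) & kd_crit < alpha &
              !is.na(ts_crit) & ts_crit < alpha &
              !is.na(kd$log2fc) & !is.na(ts$rho)
  cls <- rep("ns", length(shared))
  cls[sig_both & kd$log2fc > 0 & ts$rho > 0] <- "concordant_up"
  cls[sig_both & kd$log2fc < 0 & ts$rho < 0] <- "concordant_down"
  cls[sig_both & sign(kd$log2fc) * sign(ts$rho) < 0 &
        kd$log2fc != 0 & ts$rho != 0] <- "discordant"
  tab <- data.frame(feature = shared, rho = ts$rho, tissue_q = ts_crit,
                    log2fc = kd$log2fc, kd_q = kd_crit, class = cls,
                    stringsAsFactors = FALSE)
  if (!is.null(ce_gene_list)) tab$ce_gene <- shared %in% ce_gene_list
  counts <- table(factor(cls, levels = c("concordant_up", "concordant_down",
                                         "discordant", "ns")))
  structure(list(table = tab, counts = c(counts)), class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("cross-modal concordance over %d shared proteins:\n",
              nrow(x$table)))
  print(x$counts)
  invisible(x)
}

#' Module overlap of concordant protein sets
#'
#' One-tailed Fisher's exact tests of the concordantly increased and
#' concordantly decreased protein sets against each co-expression module,
#' with the shared feature universe as background and BH correction across
#' the full grid.
#'
#' @param concordance A [classify_concordance()] result.
#' @param labels Named module labels for the tissue features.
#' @return Enrichment table (one row per direction x module) with `q` and
#'   `stars`.
#' @export
concordant_module_overlap <- function(concordance, labels) {
  if (!inherits(concordance, "concordance_result"))
    stopf("'concordance' must be a classify_concordance() result")
  tab <- concordance$table
  background <- intersect(tab$feature, names(labels))
  mods <- sort(unique(labels[labels > 0]))
  rows <- list()
  for (direction in c("concordant_up", "concordant_down")) {
    qset <- tab$feature[tab$class == direction]
    for (m in mods) {
      members <- names(labels)[labels == m]
      rows[[length(rows) + 1]] <-
        fisher_enrichment(qset, members, background,
                          query_name = direction, set_name = paste0("M", m))
    }
  }
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$stars <- p_stars(out$p)
  out
}
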