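#' Construct a qPCR Ct table
#'
#' Bundles a subjects x assays matrix of raw cycle-threshold (Ct) values
#' with the partition of assays into cryptic-exon targets and housekeeping
#' normalizers (default RPLP0, GAPDH, CYC1).  All Ct values must be finite
#' and positive where present; housekeeping Cts must be complete for every
#' subject because they form the per-subject normalization denominator.
#'
#' @param ct Numeric matrix, subjects (rows) x assays (columns), with
#'   dimnames.
#' @param ce_assays Character vector of CE assay column names.
#' @param hk_assays Character vector of housekeeping assay column names.
#' @return An object of class `ct_table`.
#' @export
ct_table <- function(ct, ce_assays,
                     hk_assays = c("RPLP0", "GAPDH", "CYC1")) {
  assert_matrix(ct, "ct")
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stopf("'ct' must have subject rownames and assay colnames")
  if (anyDuplicated(rownames(ct))) stopf("subject ids must be unique")
  if (length(intersect(ce_assays, hk_assays)) > 0)
    stopf("CE and housekeeping assay sets must be disjoint")
  missing_cols <- setdiff(c(ce_assays, hk_assays), colnames(ct))
  if (length(missing_cols) > 0)
    stopf("assays not present in the Ct matrix: %s",
          paste(missing_cols, collapse = ", "))
  bad <- which(!is.na(ct) & ct <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stopf("nonpositive Ct value for subject '%s', assay '%s'",
          rownames(ct)[bad[1, 1]], colnames(ct)[bad[1, 2]])
  structure(list(ct = ct, ce_assays = ce_assays, hk_assays = hk_assays),
            class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf("qPCR Ct table: %d subjects, %d CE assays, %d housekeeping assays\n",
              nrow(x$ct), length(x$ce_assays), length(x$hk_assays)))
  invisible(x)
}

#' Housekeeping-normalized delta-Ct
#'
#' Subtracts the geometric mean of the housekeeping Ct values (taken over
#' the raw Ct values themselves) from each cryptic-exon Ct, per subject:
#' `dCt[i, c] = ct[i, c] - geomean(ct[i, housekeeping])`.
#'
#' @param x A [ct_table()].
#' @return Numeric matrix, subjects x CE assays, of delta-Ct values.
#'   Missing CE Cts propagate as `NA`.
#' @export
delta_ct <- function(x) {
  if (!inherits(x, "ct_table")) stopf("'x' must be a ct_table")
  hk <- x$ct[, x$hk_assays, drop = FALSE]
  if (anyNA(hk)) {
    bad <- which(is.na(hk), arr.ind = TRUE)
    stopf("missing housekeeping Ct for subject '%s', assay '%s'",
          rownames(hk)[bad[1, 1]], colnames(hk)[bad[1, 2]])
  }
  geo <- exp(rowMeans(log(hk)))
  x$ct[, x$ce_assays, drop = FALSE] - geo
}

#' Log2 relative CE expression (-ddCt) centered on controls
#'
#' Centers each CE's delta-Ct on the mean delta-Ct of the control subjects
#' (`ddCt = dCt - mean(dCt[controls])`) and returns the negative
#' (`-ddCt = log2(2^-ddCt)`), so that higher CE expression is numerically
#' larger.  By construction the control-column means of the result are zero.
#'
#' @param delta_ct_matrix Subjects x CE matrix from [delta_ct()].
#' @param control_ids Character vector of control subject ids (nonempty
#'   subset of the rownames).
#' @return Subjects x CE matrix of log2 relative expression, with
#'   `attr(., "control_ids")` recording the centering set.
#' @export
relative_log2_expression <- function(delta_ct_matrix, control_ids) {
  assert_matrix(delta_ct_matrix, "delta_ct_matrix")
  if (length(control_ids) == 0) stopf("control set must be nonempty")
  missing_ids <- setdiff(control_ids, rownames(delta_ct_matrix))
  if (length(missing_ids) > 0)
    stopf("control ids not in the delta-Ct matrix: %s",
          paste(missing_ids, collapse = ", "))
  ctrl_mean <- colMeans(delta_ct_matrix[control_ids, , drop = FALSE], na.rm = TRUE)
  out <- -(sweep(delta_ct_matrix, 2, ctrl_mean))
  attr(out, "control_ids") <- control_ids
  out
}

#' Full Ct-to-CE-expression quantification
#'
#' Convenience wrapper: [delta_ct()] followed by
#' [relative_log2_expression()].
#'
#' @inheritParams delta_ct
#' @inheritParams relative_log2_expression
#' @return Subjects x CE matrix of log2 relative expression.
#' @export
ce_quantify <- function(x, control_ids) {
  relative_log2_expression(delta_ct(x), control_ids)
}

#' Read a Ct table from tab-separated text
#'
#' @param path TSV file with subjects in rows (first column = subject id)
#'   and assays in columns.
#' @inheritParams ct_table
#' @return A [ct_table()].
#' @export
read_ct_table <- function(path, ce_assays,
                          hk_assays = c("RPLP0", "GAPDH", "CYC1")) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  ct_table(m, ce_assays = ce_assays, hk_assays = hk_assays)
}
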