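#' Read a GMT gene-set collection
#'
#' Parses the standard tab-delimited GMT format (set name, description,
#' then member gene symbols).  Member symbols are upper-cased, empty
#' fields dropped and duplicates within a set collapsed; a line with fewer
#' than three fields is a format error reported with its line number.
#'
#' @param path Path to a GMT file.
#' @return A list of class `gene_set_collection`: `sets` (named list of
#'   character vectors), `descriptions`, `source`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stopf("malformed GMT line %d: expected >= 3 tab-separated fields, got %d",
            i, length(fields))
    nm <- fields[1]
    if (nm %in% names(sets)) stopf("duplicate gene-set name '%s' (line %d)", nm, i)
    members <- unique(toupper(fields[-(1:2)]))
    members <- members[nzchar(members)]
    if (length(members) == 0) stopf("gene set '%s' (line %d) has no members", nm, i)
    sets[[nm]] <- members
    desc[nm] <- fields[2]
  }
  structure(list(sets = sets, descriptions = desc, source = path),
            class = "gene_set_collection")
}

#' One-tailed Fisher's exact enrichment of a query set in a gene set
#'
#' Builds the 2x2 table of query membership against gene-set membership,
#' restricted to the background universe, and computes the enrichment
#' (upper) hypergeometric tail `P(X >= overlap)` together with the sample
#' odds ratio (0.5 Haldane correction applied only when a cell is zero).
#' The background should be the set of detectable features (the analyzed
#' proteome), so enrichment conditions on detectability.
#'
#' @param query_genes Character vector (intersected with the background).
#' @param gene_set Character vector of set members.
#' @param background Character vector, the universe (nonempty).
#' @param query_name,set_name Labels carried into the output row.
#' @return One-row data frame: `query`, `set`, `overlap`, `query_size`,
#'   `set_size`, `background_size`, `odds_ratio`, `p`,
#'   `overlap_genes` (comma-separated).
#' @export
fisher_enrichment <- function(query_genes, gene_set, background,
                              query_name = "query", set_name = "set") {
  background <- unique(toupper(background))
  if (length(background) == 0) stopf("background must be nonempty")
  q <- intersect(unique(toupper(query_genes)), background)
  s <- intersect(unique(toupper(gene_set)), background)
  ov <- intersect(q, s)
  a <- length(ov)
  b <- length(q) - a
  cc <- length(s) - a
  d <- length(background) - a - b - cc
  p <- phyper(a - 1, length(s), length(background) - length(s), length(q),
              lower.tail = FALSE)
  cells <- c(a, b, cc, d)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  data.frame(query = query_name, set = set_name, overlap = a,
             query_size = length(q), set_size = length(s),
             background_size = length(background), odds_ratio = or, p = p,
             overlap_genes = paste(sort(ov), collapse = ","),
             stringsAsFactors = FALSE)
}

#' Enrich every module against every gene set
#'
#' Runs [fisher_enrichment()] for each module (features sharing a label)
#' against each set in the collection, with BH correction across the full
#' module x set grid and star annotation.  The default background is every
#' labeled feature including the unassigned ones.
#'
#' @param labels Named module labels (features; 0 = unassigned).
#' @param collection A [read_gmt()] collection, or a named list of
#'   character vectors.
#' @param background Character vector; default `names(labels)`.
#' @return Data frame of one row per module x set with `q` and `stars`
#'   added.
#' @export
enrich_modules <- function(labels, collection, background = names(labels)) {
  sets <- if (inherits(collection, "gene_set_collection")) collection$sets
          else collection
  if (is.null(names(labels))) stopf("'labels' must be named by feature")
  mods <- sort(unique(labels[labels > 0]))
  rows <- list()
  for (m in mods) {
    members <- names(labels)[labels == m]
    for (s in names(sets)) {
      rows[[length(rows) + 1]] <-
        fisher_enrichment(members, sets[[s]], background,
                          query_name = paste0("M", m), set_name = s)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$stars <- p_stars(out$p)
  out
}
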