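#' Signed soft-threshold adjacency from biweight midcorrelations
#'
#' Builds the signed weighted network adjacency
#' `a_ij = ((1 + bicor_ij) / 2) ^ beta`, mapping correlation -1 to 0, 0 to
#' `2^-beta`, and 1 to 1.  The soft power sharpens the contrast between
#' correlated and uncorrelated feature pairs without a hard cutoff; the
#' non-integer default 24.5 is well defined because the base is
#' nonnegative.  Features missing in more than `max_missing` of samples
#' are excluded (pairwise-complete bicor handles the rest).
#'
#' @param expr Numeric matrix, features x samples.
#' @param beta Soft threshold power (> 0; default 24.5).
#' @param max_missing Maximum tolerated per-feature missing fraction
#'   (default 0.25); features above it are dropped with a warning.
#' @return Symmetric features x features adjacency matrix in `[0, 1]` with
#'   unit diagonal and `attr(., "beta")`.
#' @export
soft_adjacency <- function(expr, beta = 24.5, max_missing = 0.25) {
  assert_matrix(expr, "expr")
  if (beta <= 0) stopf("'beta' must be > 0")
  frac <- rowMeans(is.na(expr))
  if (any(frac > max_missing)) {
    warning(sprintf("excluding %d features with > %.0f%% missing values from the network",
                    sum(frac > max_missing), 100 * max_missing))
    expr <- expr[frac <= max_missing, , drop = FALSE]
  }
  r <- bicor_matrix(t(expr))$r
  a <- ((1 + r) / 2)^beta
  diag(a) <- 1
  dimnames(a) <- list(rownames(expr), rownames(expr))
  attr(a, "beta") <- beta
  a
}

#' Topological overlap matrix
#'
#' Converts an adjacency into the topological overlap measure
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j`, with connectivity `k_i = sum_{u != i} a_iu` and `TOM_ii = 1`.
#' Two features share high topological overlap when they are strongly
#' connected to the same neighborhood, which makes module detection robust
#' to individual spurious correlations.
#'
#' @param adjacency Symmetric features x features matrix in `[0, 1]`.
#' @return The TOM, same shape, unit diagonal.  Use `1 - TOM` as the
#'   clustering dissimilarity.
#' @export
topological_overlap <- function(adjacency) {
  assert_matrix(adjacency, "adjacency")
  if (nrow(adjacency) != ncol(adjacency))
    stopf("'adjacency' must be square")
  if (max(abs(adjacency - t(adjacency))) > 1e-10)
    stopf("'adjacency' must be symmetric")
  a <- adjacency
  diag(a) <- 0
  k <- colSums(a)
  num <- a %*% a + a
  kmin <- outer(k, k, pmin)
  tom <- num / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect co-expression modules by dynamic tree cut with a PAM stage
#'
#' Average-linkage hierarchical clustering on the TOM dissimilarity,
#' followed by an adaptive tree cut: a static cut near the top of the
#' dendrogram (`cut_fraction` of the merge-height range) defines initial
#' branches, each branch is then recursively split wherever the gap between
#' a node's merge height and its subtrees' internal heights is large
#' relative to the tree (the `deep_split` level 0-4 lowers the required
#' gap, producing more, smaller modules), and branches smaller than
#' `min_module_size` are left unassigned (label 0).  A
#' partitioning-around-medoids-like stage then iteratively reassigns
#' assigned features to the module with the smallest mean dissimilarity.
#' Modules are numbered by decreasing size (M1 largest).
#'
#' @param diss_tom Square symmetric dissimilarity (1 - TOM), zero diagonal.
#' @param deep_split Split aggressiveness, integer 0-4 (default 2).
#' @param min_module_size Smallest allowed module (default 15).
#' @param pam Run the medoid reassignment stage (default `TRUE`).
#' @param cut_fraction Static cut position as a fraction of the merge
#'   height range.  The default (`NULL`) scans a ladder of candidate cuts
#'   between 0.95 and 0.999 of the range and keeps the one yielding the
#'   most clusters of at least `min_module_size` (ties broken by the
#'   number of features they cover); supply a value to fix the cut.
#' @return Named integer vector of module labels (0 = unassigned), with
#'   attributes `hclust` (the feature dendrogram), `cut_height` and
#'   `sizes`.
#' @export
detect_modules <- function(diss_tom, deep_split = 2, min_module_size = 15,
                           pam = TRUE, cut_fraction = NULL) {
  assert_matrix(diss_tom, "diss_tom")
  if (nrow(diss_tom) != ncol(diss_tom)) stopf("'diss_tom' must be square")
  if (!deep_split %in% 0:4) stopf("'deep_split' must be an integer in 0..4")
  ids <- rownames(diss_tom)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(diss_tom)))
  hc <- hclust(as.dist(diss_tom), method = "average")
  h <- hc$height
  fractions <- if (is.null(cut_fraction))
    c(0.95, 0.96, 0.97, 0.98, 0.985, 0.99, 0.993, 0.995, 0.997, 0.999, 1)
  else cut_fraction
  best <- NULL
  h_cut <- NA_real_
  for (f in fractions) {
    hc_f <- min(h) + f * (max(h) - min(h))
    cand <- cutree(hc, h = hc_f)
    tab <- table(cand)
    n_valid <- sum(tab >= min_module_size)
    covered <- sum(tab[tab >= min_module_size])
    score <- c(n_valid, covered)
    if (is.null(best) || n_valid > best[1] ||
        (n_valid == best[1] && covered > best[2])) {
      best <- score
      branches <- cand
      h_cut <- hc_f
    }
  }
  # Required merge-height gap (as a fraction of the height range) for a
  # branch to split: smaller at deeper split levels.
  gap_frac <- c(0.20, 0.10, 0.05, 0.025, 0.0125)[deep_split + 1]
  gap <- gap_frac * (max(h) - min(h))
  labels <- integer(length(branches))
  next_label <- 1L
  for (b in unique(branches)) {
    members <- which(branches == b)
    if (length(members) < min_module_size) next
    parts <- split_branch(hc, members, diss_tom, gap, min_module_size)
    for (p in parts) {
      labels[p] <- next_label
      next_label <- next_label + 1L
    }
  }
  if (pam && max(labels) >= 1) labels <- pam_stage(labels, diss_tom)
  sizes <- table(labels[labels > 0])
  labels[labels %in% as.integer(names(sizes)[sizes < min_module_size])] <- 0L
  labels <- renumber_by_size(labels)
  names(labels) <- ids
  attr(labels, "hclust") <- hc
  attr(labels, "cut_height") <- h_cut
  attr(labels, "sizes") <- table(labels[labels > 0])
  labels
}

# Recursively split a branch (given as member indices) at dendrogram nodes
# whose merge-height gap over both subtrees exceeds `gap`, provided both
# halves keep >= min_size members.  Returns a list of index vectors.
split_branch <- function(hc, members, diss, gap, min_size) {
  n <- length(hc$order) # number of leaves
  if (length(members) < 2 * min_size) return(list(members))
  # Find the node at which this member set is joined: cut the subtree at
  # successively lower heights until it falls apart into >= 2 clusters.
  sub_heights <- sort(unique(merge_heights_within(hc, members)), decreasing = TRUE)
  if (length(sub_heights) < 2) return(list(members))
  top <- sub_heights[1]
  inner <- sub_heights[sub_heights < top]
  if (top - max(inner) < gap) return(list(members))
  # Split just below the top merge of this branch.
  h_split <- (top + max(inner)) / 2
  cl <- cutree(hc, h = h_split)[members]
  parts <- split(members, cl)
  if (length(parts) < 2) return(list(members))
  sizes <- lengths(parts)
  if (sum(sizes >= min_size) < 2) return(list(members))
  out <- list()
  for (p in parts) {
    if (length(p) >= min_size)
      out <- c(out, split_branch(hc, p, diss, gap, min_size))
    else
      out <- c(out, list(p))  # runt: absorbed below
  }
  # Absorb runts (< min_size) into the closest resulting large part.
  large <- out[vapply(out, length, 1L) >= min_size]
  small <- out[vapply(out, length, 1L) < min_size]
  if (length(large) == 0) return(list(members))
  for (s in small) {
    d_to <- vapply(large, function(m) mean(diss[s, m, drop = FALSE]), 1)
    j <- which.min(d_to)
    large[[j]] <- c(large[[j]], s)
  }
  large
}

# Heights of all merges internal to a member set: a merge is internal when
# both merged clusters consist only of members.
merge_heights_within <- function(hc, members) {
  n <- length(hc$order)
  in_set <- logical(n)
  in_set[members] <- TRUE
  node_in <- logical(nrow(hc$merge))
  hts <- numeric(0)
  for (i in seq_len(nrow(hc$merge))) {
    a <- hc$merge[i, 1]; b <- hc$merge[i, 2]
    a_in <- if (a < 0) in_set[-a] else node_in[a]
    b_in <- if (b < 0) in_set[-b] else node_in[b]
    node_in[i] <- a_in && b_in
    if (node_in[i]) hts <- c(hts, hc$height[i])
  }
  hts
}

# Medoid-style refinement.  Three actions per sweep: (1) move each
# assigned feature to the module with the smallest mean dissimilarity;
# (2) release members whose dissimilarity to their own module approaches
# the background level (branch cutting sweeps loosely attached features
# into modules; a genuine member sits well below the typical inter-feature
# dissimilarity); (3) attach an unassigned feature to its nearest module
# when it lies within that module's own radius (the 90th percentile of
# members' mean dissimilarity to co-members).  Iterate to a fixed point.
pam_stage <- function(labels, diss, max_iter = 10) {
  mods <- sort(unique(labels[labels > 0]))
  if (length(mods) == 0) return(labels)
  d_bg <- median(diss[upper.tri(diss)])
  for (it in seq_len(max_iter)) {
    d_mod <- vapply(mods, function(m) {
      members <- labels == m
      rowSums(diss[, members, drop = FALSE]) / sum(members)
    }, numeric(length(labels)))
    new_labels <- labels
    # (1) reassign to the nearest module
    best <- max.col(-d_mod)
    nearest <- mods[best]
    move <- labels > 0 & nearest != labels
    new_labels[move] <- nearest[move]
    # (2) release members sitting too close to the background dissimilarity
    radius <- rep(NA_real_, length(mods))
    for (j in seq_along(mods)) {
      members <- which(new_labels == mods[j])
      if (length(members) < 2) next
      n_m <- length(members)
      d_self <- (d_mod[members, j] * n_m) / (n_m - 1)
      core <- as.numeric(quantile(d_self, 0.25))   # robust to noise-heavy branches
      # a member is released when it sits much closer to the background
      # dissimilarity than the module core does; the MAD guard keeps the
      # rule inert when module and background scales coincide
      thr <- max(core + 3 * mad(d_self), d_bg - 0.25 * (d_bg - core))
      new_labels[members[d_self > thr]] <- 0L
      kept <- members[d_self <= thr]
      if (length(kept) >= 2)
        radius[j] <- as.numeric(quantile(d_self[d_self <= thr], 0.9))
    }
    # (3) attach unassigned features within a module's own radius
    d_best <- d_mod[cbind(seq_along(labels), best)]
    attach <- new_labels == 0 & !is.na(radius[best]) & d_best <= radius[best]
    new_labels[attach] <- nearest[attach]
    if (all(new_labels == labels)) break
    labels <- new_labels
  }
  labels
}

# Renumber modules 1..k by decreasing size (ties by first appearance).
renumber_by_size <- function(labels) {
  tab <- table(labels[labels > 0])
  if (length(tab) == 0) return(labels)
  ord <- names(sort(tab, decreasing = TRUE))
  map <- setNames(seq_along(ord), ord)
  out <- labels
  out[labels > 0] <- map[as.character(labels[labels > 0])]
  out
}

#' Module eigenproteins, variance explained and kME
#'
#' The eigenprotein of a module is the first principal component of the
#' module's standardized abundance over samples (unit-normalized,
#' sign-aligned so its correlation with the module's mean standardized
#' profile is nonnegative).  kME is the biweight midcorrelation of every
#' feature with every module eigenprotein (module membership strength).
#'
#' @param expr Numeric matrix, features x samples.
#' @param labels Module labels from [detect_modules()] (0 ignored).
#' @return List of class `eigenprotein_set`: `eigenproteins` (samples x
#'   modules matrix, columns `M1`, `M2`, ...), `variance_explained`, `kME`
#'   (features x modules).
#' @export
module_eigenproteins <- function(expr, labels) {
  assert_matrix(expr, "expr")
  mods <- sort(unique(labels[labels > 0]))
  if (length(mods) == 0) stopf("no named modules in 'labels'")
  eps <- base::matrix(NA_real_, ncol(expr), length(mods),
                      dimnames = list(colnames(expr), paste0("M", mods)))
  ve <- setNames(numeric(length(mods)), paste0("M", mods))
  for (j in seq_along(mods)) {
    members <- which(labels == mods[j])
    if (length(members) < 2)
      stopf("module M%d has fewer than 2 features", mods[j])
    xm <- t(expr[members, , drop = FALSE])        # samples x features
    xm <- base::scale(xm)
    xm[is.na(xm)] <- 0                            # mean-impute post-scaling
    sv <- svd(xm, nu = 1, nv = 0)
    ep <- sv$u[, 1]
    avg <- rowMeans(xm)
    if (cor(ep, avg) < 0) ep <- -ep
    eps[, j] <- ep
    ve[j] <- sv$d[1]^2 / sum(sv$d^2)
  }
  kme <- bicor_matrix(t(expr), eps)$r
  dimnames(kme) <- list(rownames(expr), colnames(eps))
  structure(list(eigenproteins = eps, variance_explained = ve, kME = kme),
            class = "eigenprotein_set")
}

#' Merge modules with closely related eigenproteins
#'
#' Clusters module eigenproteins by `1 - cor` dissimilarity and merges any
#' modules closer than `cut_height` (default 0.07, i.e. eigenprotein
#' correlation above 0.93), recomputing eigenproteins and iterating to a
#' fixed point.  The final eigenprotein relatedness dendrogram is retained
#' for reporting.
#'
#' @param expr Numeric matrix, features x samples.
#' @param labels Module labels (0 = unassigned, preserved).
#' @param cut_height Merge threshold on `1 - cor(eigenproteins)` (default
#'   0.07).
#' @param min_kme Module-membership floor: after merging, features whose
#'   kME to their own module's eigenprotein falls below this are released
#'   to unassigned (default 0.3, the conventional stay-in-module cutoff;
#'   0 disables).  This trims weakly attached features that the tree cut
#'   swept into a branch.
#' @return Named integer labels renumbered by decreasing size, with
#'   attributes `eigenproteins` (final [module_eigenproteins()] result) and
#'   `dendrogram` (hclust of the final eigenproteins; `NULL` when fewer
#'   than 3 modules remain).
#' @export
merge_modules <- function(expr, labels, cut_height = 0.07, min_kme = 0.3) {
  lab <- as.integer(labels)
  names(lab) <- names(labels)
  if (is.null(names(lab))) names(lab) <- rownames(expr)
  repeat {
    mods <- sort(unique(lab[lab > 0]))
    if (length(mods) < 2) break
    eset <- module_eigenproteins(expr, lab)
    d <- 1 - cor(eset$eigenproteins)
    hc_ep <- hclust(as.dist(d), method = "average")
    grp <- cutree(hc_ep, h = cut_height)
    if (max(grp) == length(mods)) break          # nothing close enough
    map <- setNames(mods[match(grp, grp)], paste0("M", mods))
    # All modules in a merge group collapse onto the group's first module.
    for (g in unique(grp)) {
      members_g <- mods[grp == g]
      lab[lab %in% members_g] <- members_g[1]
    }
  }
  if (min_kme > 0 && any(lab > 0)) {
    eset <- module_eigenproteins(expr, lab)
    mods <- sort(unique(lab[lab > 0]))
    own_kme <- eset$kME[cbind(seq_along(lab),
                              match(paste0("M", lab), colnames(eset$kME)))]
    release <- lab > 0 & (is.na(own_kme) | own_kme < min_kme)
    lab[release] <- 0L
    sizes <- table(lab[lab > 0])
    lab[lab %in% as.integer(names(sizes)[sizes < 2])] <- 0L
  }
  lab <- renumber_by_size(lab)
  eset <- if (any(lab > 0)) module_eigenproteins(expr, lab) else NULL
  dend <- NULL
  if (!is.null(eset) && ncol(eset$eigenproteins) >= 3)
    dend <- hclust(as.dist(1 - cor(eset$eigenproteins)), method = "average")
  attr(lab, "eigenproteins") <- eset
  attr(lab, "dendrogram") <- dend
  lab
}

#' Module-trait and module-disease associations
#'
#' Associates each module eigenprotein with continuous traits (pTDP-43,
#' pTau ratio, Abeta42, CE levels, burden score) by biweight
#' midcorrelation over all samples, and with disease type by restricting
#' to control plus one disease group at a time, encoding membership 0/1,
#' and correlating that indicator with the eigenprotein (each
#' disease-control combination separately).  p-values use the Student t
#' approximation; cells whose contrast group has fewer than 3 samples are
#' reported missing.
#'
#' @param eigenproteins Samples x modules matrix (or an
#'   `eigenprotein_set`).
#' @param traits Data frame or matrix of continuous traits, rows aligned
#'   with samples (or named).
#' @param meta Data frame with a `group` column for the disease contrasts;
#'   `NULL` to skip.
#' @param control_group Label of the control group (default `"Control"`).
#' @return Long data frame: `module`, `trait`, `estimate`, `n_used`, `p`,
#'   `q`, `stars`.  Disease contrasts appear as trait `"<group> vs
#'   control"`.
#' @export
module_trait_association <- function(eigenproteins, traits = NULL, meta = NULL,
                                     control_group = "Control") {
  if (inherits(eigenproteins, "eigenprotein_set"))
    eigenproteins <- eigenproteins$eigenproteins
  assert_matrix(eigenproteins, "eigenproteins")
  rows <- list()
  if (!is.null(traits)) {
    tm <- as.matrix(as.data.frame(traits))
    if (nrow(tm) != nrow(eigenproteins))
      stopf("'traits' must have one row per sample")
    for (tr in colnames(tm)) {
      for (m in colnames(eigenproteins)) {
        ok <- !is.na(tm[, tr]) & !is.na(eigenproteins[, m])
        if (sum(ok) < 3) {
          rows[[length(rows) + 1]] <- data.frame(module = m, trait = tr,
                                                 estimate = NA_real_,
                                                 n_used = sum(ok), p = NA_real_)
          next
        }
        r <- bicor(eigenproteins[ok, m], tm[ok, tr])
        rows[[length(rows) + 1]] <- data.frame(
          module = m, trait = tr, estimate = as.numeric(r),
          n_used = attr(r, "n_used"),
          p = cor_p_value(as.numeric(r), attr(r, "n_used")))
      }
    }
  }
  if (!is.null(meta)) {
    grp <- as.character(meta$group)
    for (dz in setdiff(unique(grp), control_group)) {
      sel <- grp %in% c(control_group, dz)
      indicator <- as.numeric(grp[sel] == dz)
      for (m in colnames(eigenproteins)) {
        ep <- eigenproteins[sel, m]
        ok <- !is.na(ep)
        trait_name <- paste(dz, "vs control")
        if (sum(indicator[ok]) < 3 || sum(1 - indicator[ok]) < 3) {
          rows[[length(rows) + 1]] <- data.frame(module = m, trait = trait_name,
                                                 estimate = NA_real_,
                                                 n_used = sum(ok), p = NA_real_)
          next
        }
        r <- bicor(ep[ok], indicator[ok])
        rows[[length(rows) + 1]] <- data.frame(
          module = m, trait = trait_name, estimate = as.numeric(r),
          n_used = attr(r, "n_used"),
          p = cor_p_value(as.numeric(r), attr(r, "n_used")))
      }
    }
  }
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$stars <- p_stars(out$p)
  out
}

#' One-way ANOVA of module eigenproteins across CE subtypes
#'
#' Tests each module eigenprotein for differences across the molecular
#' subtypes (low / intermediate / high) with a one-way F test, BH
#' correction across modules, and pairwise Welch t-test annotations.
#'
#' @param eigenproteins Samples x modules matrix (or an
#'   `eigenprotein_set`).
#' @param subtype_labels Factor of subtype labels per sample.
#' @return List with `anova` (per-module F, p, q) and `pairwise` (long
#'   data frame of pairwise Welch t p-values).
#' @export
eigenprotein_anova <- function(eigenproteins, subtype_labels) {
  if (inherits(eigenproteins, "eigenprotein_set"))
    eigenproteins <- eigenproteins$eigenproteins
  assert_matrix(eigenproteins, "eigenproteins")
  subtype_labels <- as.factor(subtype_labels)
  if (nlevels(droplevels(subtype_labels)) < 2)
    stopf("need >= 2 subtypes for ANOVA")
  em <- t(eigenproteins)               # modules x samples
  res <- anova_bh(em, subtype_labels)
  names(res)[1] <- "module"
  lev <- levels(droplevels(subtype_labels))
  pw <- list()
  for (i in seq_len(length(lev) - 1)) for (j in (i + 1):length(lev)) {
    ct <- group_contrast(em, subtype_labels, lev[j], lev[i])
    pw[[length(pw) + 1]] <- data.frame(module = ct$feature,
                                       contrast = paste(lev[j], "vs", lev[i]),
                                       delta = ct$log2fc, t = ct$t, p = ct$p,
                                       stars = p_stars(ct$p))
  }
  list(anova = res, pairwise = do.call(rbind, pw))
}
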