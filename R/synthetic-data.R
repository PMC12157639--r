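#' Default CE qPCR assay parameters
#'
#' Forward-model parameters for the qPCR readout of the eight cryptic
#' exons measured in hippocampus (STMN2, UNC13A, ELAVL3, KALRN, ARHGAP32,
#' CAMK2B, PFKP, SYT7) against the three housekeeping normalizers (RPLP0,
#' GAPDH, CYC1).  `loadings` give each CE's Ct decrease per unit of latent
#' burden (more burden, more CE template, lower Ct); `input_sd` is the
#' per-subject RNA-input spread shared by all assays.
#'
#' @param ce_assays,hk_assays Assay names.
#' @param loadings Per-CE loading on latent burden (named or in
#'   `ce_assays` order).
#' @param ce_base Baseline Ct of each CE assay at zero burden.
#' @param noise_sd Per-well CE Ct noise SD.
#' @param hk_means Baseline Ct of each housekeeping assay.
#' @param hk_sd Per-well housekeeping Ct noise SD.
#' @param input_sd SD of the per-subject RNA-input offset (cycles).
#' @return List of assay parameters for [generate_ct_table()].
#' @export
ce_assay_params <- function(ce_assays = c("STMN2", "UNC13A", "ELAVL3", "KALRN",
                                          "ARHGAP32", "CAMK2B", "PFKP", "SYT7"),
                            loadings = c(1.2, 1.1, 1.0, 1.0, 0.9, 0.9, 0.8, 0.8),
                            ce_base = 30,
                            noise_sd = 0.3,
                            hk_assays = c("RPLP0", "GAPDH", "CYC1"),
                            hk_means = c(18, 19, 22),
                            hk_sd = 0.15,
                            input_sd = 0.4) {
  if (length(loadings) != length(ce_assays))
    stopf("'loadings' must give one value per CE assay")
  if (length(hk_means) != length(hk_assays))
    stopf("'hk_means' must give one value per housekeeping assay")
  if (noise_sd < 0 || hk_sd < 0 || input_sd < 0)
    stopf("noise SDs must be nonnegative")
  list(ce_assays = ce_assays, loadings = setNames(loadings, ce_assays),
       ce_base = rep_len(ce_base, length(ce_assays)),
       noise_sd = noise_sd, hk_assays = hk_assays,
       hk_means = setNames(hk_means, hk_assays), hk_sd = hk_sd,
       input_sd = input_sd)
}

#' Simulate a postmortem cohort with latent CE burden
#'
#' Draws a cohort of subjects across the four pathology groups (Control,
#' LATE, AD, AD+LATE) with a per-subject latent cryptic-exon burden from a
#' three-component Gaussian mixture.  The component a subject is drawn
#' from is the planted low / intermediate / high subtype; mixture weights
#' depend on group (Control and AD mostly low, AD+LATE skewed high, LATE
#' mixed), component means are separated by `separation` within-component
#' SDs.  Traits follow the burden and pathology: pTDP-43 increases with
#' burden (values below the detection limit of 0.2 are returned missing,
#' for floor imputation at 0.1), pTau ratio and Abeta42 are elevated in
#' AD-containing groups independent of burden, and MMSE declines linearly
#' with burden plus noise.
#'
#' @param n_subjects Number of subjects (>= 12; default 90).
#' @param group_proportions Named proportions over the four groups,
#'   summing to 1.  Default mirrors a 21 / 10 / 24 / 35 composition of
#'   Control / LATE / AD / AD+LATE out of 90.
#' @param separation Distance between adjacent mixture component means in
#'   within-component SDs (default 2).
#' @param component_sd Within-component SD of latent burden (default 1).
#' @param ptdp_burden_cor Correlation between latent burden and
#'   log pTDP-43 (default 0.6; the two are related but not co-dependent).
#' @param n_batches Number of TMT batches subjects are randomized into
#'   (default 6).
#' @param seed Integer seed (mandatory).
#' @return List with `meta` (subject metadata), `traits` (pTDP-43, pTau
#'   ratio, Abeta42) and `truth` (latent burden, planted subtype,
#'   component parameters).
#' @export
generate_cohort <- function(n_subjects = 90,
                            group_proportions = c(Control = 21, LATE = 10,
                                                  AD = 24, `AD+LATE` = 35) / 90,
                            separation = 2,
                            component_sd = 1,
                            ptdp_burden_cor = 0.6,
                            n_batches = 6,
                            seed) {
  if (missing(seed)) stopf("'seed' is required")
  if (n_subjects < 12) stopf("'n_subjects' must be >= 12")
  allowed <- c("Control", "LATE", "AD", "AD+LATE")
  if (is.null(names(group_proportions)))
    names(group_proportions) <- allowed[seq_along(group_proportions)]
  if (!all(names(group_proportions) %in% allowed))
    stopf("group proportions must be named from {%s}", paste(allowed, collapse = ", "))
  if (any(group_proportions < 0) || abs(sum(group_proportions) - 1) > 1e-6)
    stopf("group proportions must be nonnegative and sum to 1")
  if (abs(ptdp_burden_cor) > 1) stopf("'ptdp_burden_cor' must be in [-1, 1]")
  set.seed(seed)
  groups <- sample(names(group_proportions), n_subjects, replace = TRUE,
                   prob = group_proportions)
  # mixture weights over (low, intermediate, high) per group
  w <- rbind(Control    = c(0.85, 0.15, 0.00),
             AD         = c(0.70, 0.25, 0.05),
             LATE       = c(0.25, 0.40, 0.35),
             `AD+LATE`  = c(0.10, 0.40, 0.50))
  comp_means <- c(0, separation, 2 * separation) * component_sd
  comp <- vapply(groups, function(g) sample.int(3, 1, prob = w[g, ]), 1L)
  burden <- rnorm(n_subjects, mean = comp_means[comp], sd = component_sd)
  ids <- sprintf("S%03d", seq_len(n_subjects))
  age <- pmin(95, pmax(55, round(rnorm(n_subjects, 75, 8))))
  sex <- sample(c("F", "M"), n_subjects, replace = TRUE)
  pmi <- round(exp(rnorm(n_subjects, log(8), 0.45)), 1)
  batch <- paste0("b", rep_len(seq_len(n_batches), n_subjects)[sample.int(n_subjects)])
  channel <- stats::ave(seq_len(n_subjects), batch, FUN = seq_along)
  mmse <- pmin(30, pmax(0, round(29 - 1.6 * burden + rnorm(n_subjects, 0, 2))))
  b_std <- as.numeric(base::scale(burden))
  ptdp_log <- ptdp_burden_cor * b_std +
    sqrt(1 - ptdp_burden_cor^2) * rnorm(n_subjects)
  ptdp43 <- round(exp(ptdp_log), 3)
  ptdp43[ptdp43 < 0.2] <- NA              # below immunoassay detection
  ad <- as.numeric(groups %in% c("AD", "AD+LATE"))
  ptau_ratio <- round(-1 + 1.2 * ad + rnorm(n_subjects, 0, 0.5), 3)
  abeta42 <- round(10 + 1.0 * ad + rnorm(n_subjects, 0, 0.7), 3)
  meta <- data.frame(subject_id = ids, group = groups, age = age, sex = sex,
                     pmi = pmi, batch = batch,
                     channel = paste0("ch", channel), mmse = mmse,
                     stringsAsFactors = FALSE)
  traits <- data.frame(subject_id = ids, ptdp43 = ptdp43,
                       ptau_ratio = ptau_ratio, abeta42 = abeta42,
                       stringsAsFactors = FALSE)
  # planted subtype: deterministic banding of the realized latent burden at
  # the midpoints between adjacent component means
  thresholds <- (comp_means[-1] + comp_means[-3]) / 2
  bands <- cut(burden, c(-Inf, thresholds, Inf),
               labels = c("low", "intermediate", "high"))
  truth <- list(latent_burden = setNames(burden, ids),
                true_subtype = setNames(bands, ids),
                component = setNames(c("low", "intermediate", "high")[comp], ids),
                subtype_thresholds = thresholds,
                component_means = comp_means, component_sd = component_sd)
  list(meta = meta, traits = traits, truth = truth)
}

#' Simulate the qPCR Ct table from a cohort
#'
#' Forward model of the ddCt readout: each subject carries an RNA-input
#' offset shared by all assays; housekeeping Cts are that offset around
#' the assay baseline (independent of burden); each CE's Ct decreases with
#' latent burden by its loading (lower Ct = more template):
#' `Ct[i, c] = base_c + input_i - loading_c * burden_i + noise`.
#' A round trip through [ce_quantify()] therefore recovers log2 relative
#' CE expression correlated with the latent burden.
#'
#' @param meta,truth From [generate_cohort()].
#' @param assay_params From [ce_assay_params()].
#' @param seed Integer seed (mandatory).
#' @return A [ct_table()].
#' @export
generate_ct_table <- function(meta, truth, assay_params = ce_assay_params(),
                              seed) {
  if (missing(seed)) stopf("'seed' is required")
  ap <- assay_params
  if (ap$noise_sd < 0 || ap$hk_sd < 0 || ap$input_sd < 0)
    stopf("noise SDs must be nonnegative")
  set.seed(seed)
  n <- nrow(meta)
  ids <- meta$subject_id
  burden <- truth$latent_burden[ids]
  input <- rnorm(n, 0, ap$input_sd)
  ct <- base::matrix(NA_real_, n, length(ap$ce_assays) + length(ap$hk_assays),
                     dimnames = list(ids, c(ap$ce_assays, ap$hk_assays)))
  for (a in ap$hk_assays)
    ct[, a] <- ap$hk_means[a] + input + rnorm(n, 0, ap$hk_sd)
  for (k in seq_along(ap$ce_assays)) {
    a <- ap$ce_assays[k]
    ct[, a] <- ap$ce_base[k] + input - ap$loadings[a] * burden +
      rnorm(n, 0, ap$noise_sd)
  }
  ct_table(ct, ce_assays = ap$ce_assays, hk_assays = ap$hk_assays)
}

#' Default proteome simulation parameters
#'
#' Factor-model specification for the simulated TMT proteome: six planted
#' co-expression modules (sizes 100-30) plus one runt block of 10 features
#' (below the minimum module size, expected to stay unassigned), an
#' intra-module factor loading of 0.6, per-module association of the
#' module factor with latent burden (two strongly positive / negative, two
#' moderate, one null, one weak), 35 CE-transcript features of which 30
#' carry negative and 5 positive direct burden loadings, small random
#' covariate effects, batch and sample offsets removable by TAMPOR, and
#' 5% MCAR plus ~5% intensity-dependent MNAR missingness.
#'
#' @param n_features Total features (default 1500).
#' @param module_sizes Planted module sizes (default 100, 80, 60, 50, 40,
#'   30).
#' @param runt_size Size of the below-minimum planted block (default 10;
#'   0 disables).
#' @param loading Intra-module factor loading (default 0.6).
#' @param burden_assoc Per-module correlation of the module factor with
#'   standardized latent burden.
#' @param n_ce_genes,ce_gene_neg Number of CE-transcript features and how
#'   many of them load negatively on burden (default 35 and 30).
#' @param ce_gene_loading Magnitude of the CE-gene burden loading (default
#'   0.5).
#' @param concordant_min_loading Smallest |burden loading| recorded as a
#'   planted concordant effect (default 0.3).
#' @param age_effect_sd,sex_effect_sd,pmi_effect_sd,batch_effect_sd SDs of
#'   per-feature nuisance coefficients (subject samples only; the batch
#'   term here is *not* shared with the reference channels, so it is the
#'   part covariate regression must remove).
#' @param planted_batch_offset Optional named vector (batch -> offset)
#'   added to every feature in those batches (subject samples only).
#' @param planted_age_slope Optional scalar age slope added to every
#'   feature.
#' @param planted_group_offset Optional named vector (group -> offset)
#'   added to every feature for subjects in those groups (a protected
#'   effect regression must preserve).
#' @param sample_offset_sd SD of per-sample loading offsets (default 0.3;
#'   TAMPOR-removable).
#' @param batch_shift_sd SD of per-feature-per-batch shifts shared with
#'   the GIS channels (default 0.5; TAMPOR-removable).
#' @param noise_sd Residual feature noise scale (default 1; module
#'   features use `sqrt(1 - loading^2)` of it to keep unit variance).
#' @param base_mean,base_sd Distribution of feature baseline log2
#'   abundance (defaults 20, 2).
#' @param mcar,mnar Missingness rates (defaults 0.05 each).
#' @param n_gis_per_batch Reference (GIS) channels per batch (default 2).
#' @return Parameter list for [generate_proteome()].
#' @export
proteome_spec <- function(n_features = 1500,
                          module_sizes = c(100, 80, 60, 50, 40, 30),
                          runt_size = 10,
                          loading = 0.6,
                          burden_assoc = c(0.8, -0.8, 0.5, -0.7, 0, 0.3),
                          n_ce_genes = 35, ce_gene_neg = 30,
                          ce_gene_loading = 0.5,
                          concordant_min_loading = 0.3,
                          age_effect_sd = 0.005, sex_effect_sd = 0.1,
                          pmi_effect_sd = 0.01, batch_effect_sd = 0.2,
                          planted_batch_offset = NULL,
                          planted_age_slope = NULL,
                          planted_group_offset = NULL,
                          sample_offset_sd = 0.3,
                          batch_shift_sd = 0.5,
                          noise_sd = 1,
                          base_mean = 20, base_sd = 2,
                          mcar = 0.05, mnar = 0.05,
                          n_gis_per_batch = 2) {
  if (length(burden_assoc) != length(module_sizes))
    stopf("'burden_assoc' must give one value per module")
  if (ce_gene_neg > n_ce_genes) stopf("'ce_gene_neg' cannot exceed 'n_ce_genes'")
  if (sum(module_sizes) + runt_size + n_ce_genes > n_features)
    stopf("module sizes (%d) + runt (%d) + CE genes (%d) exceed n_features (%d)",
          sum(module_sizes), runt_size, n_ce_genes, n_features)
  as.list(environment())
}

#' Simulate the hippocampal TMT proteome with planted structure
#'
#' Builds a features x samples log2 abundance matrix from the factor model
#' in [proteome_spec()]: module features share a per-sample latent factor
#' tied to the subject's burden, CE-transcript features carry
#' predominantly negative direct burden loadings, nuisance covariates
#' (age, sex, PMI, batch) act through planted per-feature coefficients,
#' per-sample loading offsets and per-feature batch shifts emulate what
#' TAMPOR removes, and each batch carries reference (GIS) channels that
#' track feature baselines plus the batch shift.  Missingness is MCAR plus
#' intensity-dependent MNAR.  All planted quantities are returned as
#' ground truth.
#'
#' @param meta,truth From [generate_cohort()].
#' @param spec From [proteome_spec()].
#' @param seed Integer seed (mandatory).
#' @return List with `abundance` (features x samples), `annot` (per-sample
#'   data frame: sample_id, subject_id, group, batch, is_reference) and
#'   `truth` (module_membership, runt_module, ce_gene_flags,
#'   burden_loadings, concordant_set, covariate coefficient matrices).
#' @export
generate_proteome <- function(meta, truth, spec = proteome_spec(), seed) {
  if (missing(seed)) stopf("'seed' is required")
  set.seed(seed)
  sp <- spec
  n_sub <- nrow(meta)
  ids <- meta$subject_id
  batches <- sort(unique(meta$batch))
  gis_ids <- as.vector(t(outer(batches, seq_len(sp$n_gis_per_batch),
                               function(b, k) sprintf("GIS_%s_%d", b, k))))
  gis_batch <- rep(batches, each = sp$n_gis_per_batch)
  sample_ids <- c(ids, gis_ids)
  n_col <- length(sample_ids)
  feats <- sprintf("P%04d", seq_len(sp$n_features))
  n_mod <- length(sp$module_sizes)

  # feature layout: modules, runt block, CE genes, background
  membership <- integer(sp$n_features)
  pos <- 1
  for (m in seq_len(n_mod)) {
    membership[pos:(pos + sp$module_sizes[m] - 1)] <- m
    pos <- pos + sp$module_sizes[m]
  }
  runt_module <- 0L
  if (sp$runt_size > 0) {
    runt_module <- n_mod + 1L
    membership[pos:(pos + sp$runt_size - 1)] <- runt_module
    pos <- pos + sp$runt_size
  }
  ce_idx <- if (sp$n_ce_genes > 0) seq(pos, length.out = sp$n_ce_genes)
            else integer(0)
  ce_flags <- setNames(logical(sp$n_features), feats)
  ce_flags[ce_idx] <- TRUE
  names(membership) <- feats

  b_std <- as.numeric(base::scale(truth$latent_burden[ids]))
  assoc <- c(sp$burden_assoc, if (runt_module > 0) 0)
  # per-sample module factors (subjects only)
  factors <- vapply(seq_along(assoc), function(m) {
    assoc[m] * b_std + sqrt(1 - assoc[m]^2) * rnorm(n_sub)
  }, numeric(n_sub))

  base_f <- rnorm(sp$n_features, sp$base_mean, sp$base_sd)
  burden_loadings <- setNames(numeric(sp$n_features), feats)
  ce_sign <- c(rep(-1, sp$ce_gene_neg), rep(1, sp$n_ce_genes - sp$ce_gene_neg))

  x <- base::matrix(0, sp$n_features, n_sub, dimnames = list(feats, ids))
  resid_scale <- sp$noise_sd * sqrt(1 - sp$loading^2)
  for (f in seq_len(sp$n_features)) {
    m <- membership[f]
    if (m > 0) {
      x[f, ] <- sp$loading * factors[, m] + resid_scale * rnorm(n_sub)
      burden_loadings[f] <- sp$loading * assoc[m]
    } else if (ce_flags[f]) {
      s <- ce_sign[match(f, ce_idx)]
      cl <- sp$ce_gene_loading
      x[f, ] <- s * cl * b_std + sp$noise_sd * sqrt(1 - cl^2) * rnorm(n_sub)
      burden_loadings[f] <- s * cl
    } else {
      x[f, ] <- sp$noise_sd * rnorm(n_sub)
    }
  }

  # nuisance covariates (subject samples only)
  age_c <- meta$age - mean(meta$age)
  pmi_c <- meta$pmi - mean(meta$pmi)
  sex_m <- as.numeric(meta$sex == "M")
  age_coef <- rnorm(sp$n_features, 0, sp$age_effect_sd) +
    (sp$planted_age_slope %||% 0)
  sex_coef <- rnorm(sp$n_features, 0, sp$sex_effect_sd)
  pmi_coef <- rnorm(sp$n_features, 0, sp$pmi_effect_sd)
  batch_coef <- base::matrix(rnorm(sp$n_features * length(batches), 0,
                                   sp$batch_effect_sd),
                             sp$n_features, length(batches),
                             dimnames = list(feats, batches))
  if (!is.null(sp$planted_batch_offset))
    for (b in names(sp$planted_batch_offset))
      batch_coef[, b] <- batch_coef[, b] + sp$planted_batch_offset[[b]]
  group_off <- setNames(numeric(n_sub), ids)
  if (!is.null(sp$planted_group_offset))
    for (g in names(sp$planted_group_offset))
      group_off[meta$group == g] <- sp$planted_group_offset[[g]]
  x <- x + outer(age_coef, age_c) + outer(sex_coef, sex_m) +
    outer(pmi_coef, pmi_c) + batch_coef[, meta$batch]
  x <- sweep(x, 2, group_off, "+")

  # assemble full matrix with baselines, TAMPOR-removable terms, GIS columns
  batch_shift <- base::matrix(rnorm(sp$n_features * length(batches), 0,
                                    sp$batch_shift_sd),
                              sp$n_features, length(batches),
                              dimnames = list(feats, batches))
  full <- base::matrix(NA_real_, sp$n_features, n_col,
                       dimnames = list(feats, sample_ids))
  full[, ids] <- base_f + x + batch_shift[, meta$batch]
  full[, gis_ids] <- base_f + batch_shift[, gis_batch] +
    rnorm(sp$n_features * length(gis_ids), 0, 0.05)
  sample_offset <- rnorm(n_col, 0, sp$sample_offset_sd)
  full <- sweep(full, 2, sample_offset, "+")

  # missingness: MCAR + intensity-dependent MNAR (subject samples)
  if (sp$mcar > 0 || sp$mnar > 0) {
    vals <- full[, ids]
    p_miss <- sp$mcar
    if (sp$mnar > 0) {
      ctr <- quantile(vals, 0.10, na.rm = TRUE)
      p_miss <- p_miss + 2 * sp$mnar * stats::plogis((ctr - vals) / 1.5)
    }
    drop <- base::matrix(runif(length(vals)) < p_miss, nrow(vals))
    vals[drop] <- NA_real_
    full[, ids] <- vals
  }

  concordant <- setNames(rep("none", sp$n_features), feats)
  concordant[burden_loadings >= sp$concordant_min_loading] <- "up"
  concordant[burden_loadings <= -sp$concordant_min_loading] <- "down"

  annot <- data.frame(
    sample_id = sample_ids,
    subject_id = c(ids, rep(NA_character_, length(gis_ids))),
    group = c(meta$group, rep(NA_character_, length(gis_ids))),
    batch = c(meta$batch, gis_batch),
    is_reference = c(rep(FALSE, n_sub), rep(TRUE, length(gis_ids))),
    stringsAsFactors = FALSE)

  list(abundance = full, annot = annot,
       truth = list(module_membership = membership, runt_module = runt_module,
                    ce_gene_flags = ce_flags,
                    burden_loadings = burden_loadings,
                    concordant_set = concordant,
                    age_coef = age_coef, sex_coef = sex_coef,
                    pmi_coef = pmi_coef, batch_coef = batch_coef))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default knockdown-proteome effect parameters
#'
#' @param effect_size Magnitude of the planted knockdown log2FC on
#'   concordant features (sign follows the recorded direction; default
#'   2).
#' @param noise_sd Per-sample noise SD (default 0.3).
#' @param missing_rate Target missingness rate, intensity-dependent
#'   (default 0.1).
#' @param base_mean,base_sd Feature baseline distribution (defaults 20,
#'   2).
#' @param log2fc Optional named per-feature log2FC overriding the
#'   concordant-set defaults entirely.
#' @return Parameter list for [generate_kd_proteome()].
#' @export
kd_effect_spec <- function(effect_size = 2, noise_sd = 0.3,
                           missing_rate = 0.1, base_mean = 20, base_sd = 2,
                           log2fc = NULL) {
  if (noise_sd < 0) stopf("'noise_sd' must be nonnegative")
  as.list(environment())
}

#' Simulate the TDP-43 knockdown iNeuron proteome
#'
#' Two-group (control vs TDP-43 knockdown) log2 abundance matrix over the
#' same feature universe as the tissue proteome.  Features in the planted
#' concordant set receive a knockdown log2FC of the recorded sign (down:
#' reduced in knockdown, matching their negative tissue burden loading);
#' all other features have no effect.  Intensity-dependent missing values
#' are introduced for imputation testing.
#'
#' @param truth The `truth` element of [generate_proteome()] (needs
#'   `concordant_set`), or a character vector of directions.
#' @param effect_spec From [kd_effect_spec()].
#' @param n_per_group Samples per group (>= 2; default 4).
#' @param seed Integer seed (mandatory).
#' @return List with `abundance` (features x samples), `groups` (per
#'   column, `"Control"` / `"KD"`) and `log2fc` (planted per-feature
#'   effects).
#' @export
generate_kd_proteome <- function(truth, effect_spec = kd_effect_spec(),
                                 n_per_group = 4, seed) {
  if (missing(seed)) stopf("'seed' is required")
  if (n_per_group < 2) stopf("'n_per_group' must be >= 2 (t-test undefined)")
  es <- effect_spec
  concordant <- if (is.list(truth)) truth$concordant_set else truth
  feats <- names(concordant)
  if (is.null(feats)) stopf("'truth' concordant set must be named by feature")
  set.seed(seed)
  lfc <- setNames(numeric(length(feats)), feats)
  lfc[concordant == "up"] <- es$effect_size
  lfc[concordant == "down"] <- -es$effect_size
  if (!is.null(es$log2fc)) {
    lfc[] <- 0
    lfc[names(es$log2fc)] <- es$log2fc
  }
  cols <- c(sprintf("Control_%d", seq_len(n_per_group)),
            sprintf("KD_%d", seq_len(n_per_group)))
  groups <- rep(c("Control", "KD"), each = n_per_group)
  base_f <- rnorm(length(feats), es$base_mean, es$base_sd)
  x <- base_f + outer(lfc, as.numeric(groups == "KD")) +
    base::matrix(rnorm(length(feats) * length(cols), 0, es$noise_sd),
                 length(feats), length(cols))
  dimnames(x) <- list(feats, cols)
  if (es$missing_rate > 0) {
    # purely intensity-dependent (MNAR): cells near the low-abundance tail
    # go missing, emulating label-free detection limits
    ctr <- quantile(x, 0.05)
    p_miss <- pmin(1, 4 * es$missing_rate * stats::plogis((ctr - x) / 0.7))
    drop <- base::matrix(runif(length(x)) < p_miss, nrow(x))
    # keep at least 3 observed per column for imputation moments
    for (j in seq_len(ncol(x))) {
      obs <- which(!drop[, j])
      if (length(obs) < 3)
        drop[sample(which(drop[, j]), 3 - length(obs)), j] <- FALSE
    }
    x[drop] <- NA_real_
  }
  list(abundance = x, groups = setNames(groups, cols), log2fc = lfc)
}

#' Simulate every pipeline input at the study conditions
#'
#' Convenience orchestrator: cohort, qPCR Ct table, tissue proteome and
#' knockdown proteome from one master seed (sub-generators receive
#' deterministic offsets of it).
#'
#' @param n_subjects Cohort size (default 90).
#' @param separation Burden mixture separation in SDs (default 2).
#' @param spec Proteome specification (default [proteome_spec()]).
#' @param assay_params qPCR parameters (default [ce_assay_params()]).
#' @param effect_spec Knockdown parameters (default [kd_effect_spec()]).
#' @param seed Master integer seed (kept small; offsets stay below 2^31).
#' @return List with `cohort`, `ct`, `proteome`, `kd`.
#' @export
simulate_study <- function(n_subjects = 90, separation = 2,
                           spec = proteome_spec(),
                           assay_params = ce_assay_params(),
                           effect_spec = kd_effect_spec(), seed) {
  if (missing(seed)) stopf("'seed' is required")
  cohort <- generate_cohort(n_subjects = n_subjects, separation = separation,
                            seed = seed)
  ct <- generate_ct_table(cohort$meta, cohort$truth,
                          assay_params = assay_params, seed = seed + 1L)
  prot <- generate_proteome(cohort$meta, cohort$truth, spec = spec,
                            seed = seed + 2L)
  kd <- generate_kd_proteome(prot$truth, effect_spec = effect_spec,
                             seed = seed + 3L)
  list(cohort = cohort, ct = ct, proteome = prot, kd = kd)
}
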