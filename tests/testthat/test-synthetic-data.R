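test_that("generators are bit-identical under a fixed seed", {
  a <- generate_cohort(n_subjects = 30, seed = 11)
  b <- generate_cohort(n_subjects = 30, seed = 11)
  expect_identical(a, b)
  cta <- generate_ct_table(a$meta, a$truth, seed = 12)
  ctb <- generate_ct_table(b$meta, b$truth, seed = 12)
  expect_identical(cta, ctb)
  sp <- proteome_spec(n_features = 120, module_sizes = c(20, 20), runt_size = 0,
                      n_ce_genes = 10, ce_gene_neg = 8,
                      burden_assoc = c(0.8, -0.8))
  pa <- generate_proteome(a$meta, a$truth, spec = sp, seed = 13)
  pb <- generate_proteome(b$meta, b$truth, spec = sp, seed = 13)
  expect_identical(pa, pb)
  ka <- generate_kd_proteome(pa$truth, seed = 14)
  kb <- generate_kd_proteome(pb$truth, seed = 14)
  expect_identical(ka, kb)
})

test_that("invalid generator arguments fail with the named constraint", {
  expect_error(generate_cohort(n_subjects = 30,
                               group_proportions = c(0.5, 0.5, 0.1, 0.1),
                               seed = 1), "sum to 1")
  expect_error(generate_cohort(n_subjects = 5, seed = 1), ">= 12")
  expect_error(generate_cohort(n_subjects = 30, seed = 1,
                               group_proportions = c(bad = 1)), "named")
  co <- generate_cohort(n_subjects = 20, seed = 1)
  expect_error(generate_ct_table(co$meta, co$truth,
                                 ce_assay_params(noise_sd = -1), seed = 2),
               "nonnegative")
  expect_error(generate_kd_proteome(setNames("down", "P1"), n_per_group = 1,
                                    seed = 3), "t-test undefined")
  expect_error(proteome_spec(n_features = 50, module_sizes = c(40, 40),
                             burden_assoc = c(0, 0)), "exceed")
})

test_that("cohort structure follows the group-dependent burden mixture", {
  co <- generate_cohort(n_subjects = 90, seed = 5)
  expect_equal(nrow(co$meta), 90)
  expect_true(all(co$meta$group %in% c("Control", "LATE", "AD", "AD+LATE")))
  expect_false(anyDuplicated(co$meta$subject_id) > 0)
  expect_setequal(levels(co$truth$true_subtype),
                  c("low", "intermediate", "high"))
  # every batch is populated
  expect_true(all(table(co$meta$batch) >= 1))

  # an all-Control cohort draws from the low end of the mixture: its mean
  # burden sits well below a mixed cohort of the same size
  ctrl <- generate_cohort(n_subjects = 500,
                          group_proportions = c(Control = 1, LATE = 0,
                                                AD = 0, `AD+LATE` = 0),
                          seed = 6)
  mixed <- generate_cohort(n_subjects = 500, seed = 6)
  expect_lt(mean(ctrl$truth$latent_burden), mean(mixed$truth$latent_burden))
})

test_that("traits track burden and pathology as specified", {
  co <- generate_cohort(n_subjects = 400, seed = 8)
  tr <- co$traits
  obs <- !is.na(tr$ptdp43)
  expect_gt(cor(log(tr$ptdp43[obs]), co$truth$latent_burden[obs]), 0.3)
  ad <- co$meta$group %in% c("AD", "AD+LATE")
  expect_gt(mean(tr$ptau_ratio[ad]), mean(tr$ptau_ratio[!ad]))
  expect_gt(mean(tr$abeta42[ad]), mean(tr$abeta42[!ad]))
  expect_lt(cor(co$meta$mmse, co$truth$latent_burden), -0.3)
})

test_that("Ct forward model round-trips through ce_quantify", {
  co <- generate_cohort(n_subjects = 30, seed = 21)
  controls <- co$meta$subject_id[co$meta$group == "Control"]
  # zero loadings, zero noise: all subjects identical -ddCt = 0
  ap0 <- ce_assay_params(loadings = rep(0, 8), noise_sd = 0, hk_sd = 0,
                         input_sd = 0)
  ct0 <- generate_ct_table(co$meta, co$truth, ap0, seed = 22)
  expect_lt(max(abs(ce_quantify(ct0, controls))), 1e-12)

  # unit loading, zero noise: output equals burden centered on controls
  ap1 <- ce_assay_params(loadings = rep(1, 8), noise_sd = 0, hk_sd = 0,
                         input_sd = 0)
  ct1 <- generate_ct_table(co$meta, co$truth, ap1, seed = 23)
  ce1 <- ce_quantify(ct1, controls)
  expected <- co$truth$latent_burden -
    mean(co$truth$latent_burden[controls])
  for (j in seq_len(ncol(ce1)))
    expect_equal(unname(ce1[, j]), unname(expected), tolerance = 1e-10)
})

test_that("proteome planting shows up in raw sample means", {
  co <- generate_cohort(n_subjects = 36, seed = 31)
  sp <- proteome_spec(n_features = 200, module_sizes = c(30, 30),
                      runt_size = 0, n_ce_genes = 10, ce_gene_neg = 8,
                      burden_assoc = c(0.8, -0.8), mcar = 0, mnar = 0,
                      batch_shift_sd = 0, sample_offset_sd = 0,
                      planted_batch_offset = c(b2 = 1.5))
  pr <- generate_proteome(co$meta, co$truth, spec = sp, seed = 32)
  expect_false(anyNA(pr$abundance))
  subj <- co$meta$subject_id
  b2 <- subj[co$meta$batch == "b2"]
  b1 <- subj[co$meta$batch == "b1"]
  delta <- mean(pr$abundance[, b2]) - mean(pr$abundance[, b1])
  expect_equal(delta, 1.5, tolerance = 0.15)

  # zero noise, one module, loading 1: module rows perfectly correlated
  sp1 <- proteome_spec(n_features = 30, module_sizes = 20, runt_size = 0,
                       n_ce_genes = 0, ce_gene_neg = 0, burden_assoc = 0.5,
                       loading = 1, noise_sd = 0, mcar = 0, mnar = 0,
                       age_effect_sd = 0, sex_effect_sd = 0, pmi_effect_sd = 0,
                       batch_effect_sd = 0, batch_shift_sd = 0,
                       sample_offset_sd = 0)
  pr1 <- generate_proteome(co$meta, co$truth, spec = sp1, seed = 33)
  mod <- names(pr1$truth$module_membership)[pr1$truth$module_membership == 1]
  cc <- cor(t(pr1$abundance[mod, subj]))
  expect_lt(max(abs(cc - 1)), 1e-8)
})

test_that("null knockdown effects give calibrated t-test p-values", {
  tr <- setNames(rep("none", 2000), sprintf("P%04d", 1:2000))
  kd <- generate_kd_proteome(tr, kd_effect_spec(missing_rate = 0),
                             n_per_group = 10, seed = 41)
  res <- kd_differential(kd$abundance, kd$groups)
  frac <- mean(res$p < 0.05)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("a strongly decreased feature is recovered from the KD arm", {
  tr <- setNames(rep("none", 50), sprintf("P%04d", 1:50))
  es <- kd_effect_spec(noise_sd = 0.1, missing_rate = 0,
                       log2fc = c(P0001 = -3))
  kd <- generate_kd_proteome(tr, es, n_per_group = 4, seed = 42)
  res <- kd_differential(kd$abundance, kd$groups)
  expect_equal(res$class[res$feature == "P0001"], "decreased")
  expect_equal(res$log2fc[res$feature == "P0001"], -3, tolerance = 0.3)
})

test_that("stronger planted CE loadings never weaken the recovered signal", {
  recovered <- vapply(c(0.25, 0.5, 1), function(l) {
    co <- generate_cohort(n_subjects = 60, seed = 55)
    ap <- ce_assay_params(loadings = rep(l, 8))
    ct <- generate_ct_table(co$meta, co$truth, ap, seed = 56)
    ce <- ce_quantify(ct, co$meta$subject_id[co$meta$group == "Control"])
    cor(rowMeans(ce), co$truth$latent_burden)
  }, 1)
  expect_true(all(diff(recovered) >= 0))
})
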