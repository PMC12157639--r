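test_that("bicor handles perfect correlation, anticorrelation and fallback", {
  set.seed(1)
  x <- rnorm(30)
  expect_equal(as.numeric(bicor(x, x)), 1)
  expect_equal(as.numeric(bicor(x, -x)), -1)
  expect_equal(attr(bicor(x, x), "method"), "bicor")
  # > half ties gives MAD 0: Pearson fallback, tagged
  y <- c(rep(0, 20), rnorm(10))
  r <- bicor(y, x)
  expect_equal(attr(r, "method"), "pearson")
  expect_error(bicor(1:2, 1:2), ">= 3")
})

test_that("bicor matches the independent formula oracle with missingness", {
  set.seed(2)
  for (i in 1:100) {
    n <- sample(20:60, 1)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    if (i %% 2 == 0) {
      x[sample(n, 3)] <- NA
      y[sample(n, 3)] <- NA
    }
    expect_equal(as.numeric(bicor(x, y)), bicor_oracle(x, y),
                 tolerance = 1e-10)
  }
})

test_that("bicor is symmetric, bounded and shift/scale invariant", {
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(40); y <- rnorm(40) + 0.3 * x
    r <- as.numeric(bicor(x, y))
    expect_lte(abs(r), 1)
    expect_equal(as.numeric(bicor(y, x)), r, tolerance = 1e-12)
    expect_equal(as.numeric(bicor(2.5 * x + 7, 0.1 * y - 3)), r,
                 tolerance = 1e-12)
  }
})

test_that("bicor shrugs off a single extreme outlier where Pearson breaks", {
  set.seed(4)
  x <- rnorm(50); y <- 0.8 * x + rnorm(50, 0, 0.6)
  r0_b <- as.numeric(bicor(x, y)); r0_p <- cor(x, y)
  x2 <- x; y2 <- y
  x2[1] <- 100; y2[1] <- -100
  expect_lt(abs(as.numeric(bicor(x2, y2)) - r0_b), 0.05)
  expect_gt(abs(cor(x2, y2) - r0_p), 0.3)
})

test_that("correlation grid tracks pairwise-complete df and annotates stars", {
  set.seed(5)
  f <- matrix(rnorm(4 * 40), 4, 40,
              dimnames = list(paste0("P", 1:4), paste0("s", 1:40)))
  f[1, 1:10] <- NA
  tmat <- matrix(f[2, ], 1, 40, dimnames = list("T1", colnames(f)))
  g <- correlate_grid(f, tmat)
  expect_equal(g$n_used[g$feature == "P1"], 30)
  expect_equal(g$n_used[g$feature == "P3"], 40)
  # the feature equal to the target has r = 1 at the numerical floor
  self <- g[g$feature == "P2", ]
  expect_equal(self$estimate, 1)
  expect_lt(self$p, 1e-12)
  # df follows the complete subset: same r/p as the subset computed directly
  sub <- bicor(f[1, 11:40], tmat[1, 11:40])
  expect_equal(g$estimate[g$feature == "P1"], as.numeric(sub),
               tolerance = 1e-12)
  expect_error(correlate_grid(f, matrix(1, 1, 2,
                                        dimnames = list("T", c("z1", "z2")))),
               "shared")
})

test_that("row-wise ANOVA matches aov and handles untestable features", {
  set.seed(6)
  x <- matrix(rnorm(5 * 24), 5, 24,
              dimnames = list(paste0("P", 1:5), NULL))
  g <- rep(c("a", "b", "c"), each = 8)
  x[3, 1:7] <- NA                       # group a has 1 value: drops out
  res <- anova_bh(x, g)
  for (i in c(1, 2, 4, 5)) {
    fit <- summary(aov(x[i, ] ~ factor(g)))[[1]]
    expect_equal(res$F[i], fit$`F value`[1], tolerance = 1e-10)
    expect_equal(res$p[i], fit$`Pr(>F)`[1], tolerance = 1e-10)
  }
  # feature 3 tested on the two groups that keep >= 2 values
  fit3 <- summary(aov(x[3, 9:24] ~ factor(g[9:24])))[[1]]
  expect_equal(res$F[3], fit3$`F value`[1], tolerance = 1e-10)
  # identical groups: F = 0, p = 1
  y <- matrix(rep(rnorm(12), 2), 1, 24)
  res0 <- anova_bh(y, rep(c("a", "b"), each = 12))
  expect_equal(res0$F, 0)
  expect_equal(res0$p, 1)
  expect_error(anova_bh(x, rep("a", 24)), ">= 2 groups")
})

test_that("BH correction equals the brute-force step-up everywhere", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  set.seed(7)
  for (i in 1:10) {
    p <- runif(sample(5:50, 1))^2
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("group contrasts behave as volcano tables", {
  set.seed(8)
  x <- matrix(rnorm(100 * 30, sd = 0.2), 100, 30,
              dimnames = list(sprintf("P%03d", 1:100), NULL))
  g <- rep(c("hi", "lo"), each = 15)
  x[1, g == "hi"] <- x[1, g == "hi"] + 1
  res <- group_contrast(x, g, "hi", "lo")
  expect_equal(res$class[1], "increased")
  expect_equal(res$log2fc[1], 1, tolerance = 0.25)
  # swapping the groups negates the fold change, p unchanged
  swp <- group_contrast(x, g, "lo", "hi")
  expect_equal(swp$log2fc, -res$log2fc)
  expect_equal(swp$p, res$p)
  # identical groups: zero fold change, ns
  y <- matrix(rep(rnorm(10), each = 6), 10, 6, byrow = TRUE,
              dimnames = list(paste0("P", 1:10), NULL))
  res0 <- group_contrast(y, rep(c("a", "b"), 3), "a", "b")
  expect_true(all(res0$log2fc == 0))
  expect_true(all(res0$class == "ns"))
  expect_error(group_contrast(x, g, "hi", "absent"), "nonempty")
})

test_that("pooled two-group t squares to the one-way F", {
  set.seed(9)
  x <- matrix(rnorm(20 * 16), 20, 16,
              dimnames = list(paste0("P", 1:20), NULL))
  g <- rep(c("a", "b"), each = 8)
  tt <- group_contrast(x, g, "a", "b", var_equal = TRUE)
  ff <- anova_bh(x, g)
  expect_equal(tt$t^2, ff$F, tolerance = 1e-10)
  expect_equal(tt$p, ff$p, tolerance = 1e-10)
})

test_that("Spearman against burden equals the rank-then-Pearson oracle", {
  set.seed(10)
  x <- matrix(rnorm(100 * 30), 100, 30,
              dimnames = list(sprintf("P%03d", 1:100), sprintf("s%02d", 1:30)))
  b <- setNames(rnorm(30), colnames(x))
  res <- spearman_burden(x, b)
  for (i in seq_len(50)) {
    expect_equal(res$rho[i], cor(rank(x[i, ]), rank(b)), tolerance = 1e-12)
  }
  # exact extremes and the constant-feature case
  x2 <- rbind(eq = unname(b), neg = -unname(b), flat = rep(1, 30))
  colnames(x2) <- names(b)
  r2 <- spearman_burden(x2, b)
  expect_equal(r2$rho[1:2], c(1, -1))
  expect_true(is.na(r2$rho[3]))
})

test_that("CE-transcript bias test counts signed significant correlations", {
  sp <- data.frame(feature = sprintf("G%02d", 1:40),
                   rho = c(rep(-0.6, 15), rep(0.6, 5), rep(0.01, 20)),
                   n_used = 90,
                   p = c(rep(1e-6, 20), rep(0.9, 20)),
                   q = c(rep(1e-5, 20), rep(0.95, 20)))
  res <- ce_gene_bias(sp, sprintf("G%02d", 1:30))
  expect_equal(res$n_negative, 15)
  expect_equal(res$n_positive, 5)
  expect_equal(res$p_value, binom.test(15, 20)$p.value)
  # nothing significant: (0, 0) with p = 1
  res0 <- ce_gene_bias(sp[21:40, ], sprintf("G%02d", 21:40))
  expect_equal(c(res0$n_negative, res0$n_positive, res0$p_value), c(0, 0, 1))
  expect_error(ce_gene_bias(sp, "absent"), "no CE")
})

test_that("symmetric planted effects rarely fake a directional bias", {
  pvals <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 60
    b <- setNames(rnorm(n), paste0("s", 1:n))
    x <- t(sapply(1:40, function(i) {
      sign <- if (i <= 20) 1 else -1
      sign * 0.5 * b + rnorm(n, 0, 0.8)
    }))
    dimnames(x) <- list(paste0("G", 1:40), names(b))
    ce_gene_bias(spearman_burden(x, b), paste0("G", 1:40))$p_value
  }, 1)
  expect_gte(mean(pvals > 0.05), 0.9)
})
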