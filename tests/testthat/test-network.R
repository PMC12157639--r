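# Small planted-module expression fixture: features x samples.
make_module_expr <- function(sizes = c(30, 30), n_noise = 20, n = 90,
                             loading = 0.85, assoc = NULL, seed = 1) {
  set.seed(seed)
  k <- length(sizes)
  factors <- matrix(rnorm(n * k), n, k)
  rows <- list()
  labels <- integer(0)
  for (m in seq_len(k)) {
    block <- sapply(seq_len(sizes[m]), function(i)
      loading * factors[, m] + sqrt(1 - loading^2) * rnorm(n))
    rows[[m]] <- t(block)
    labels <- c(labels, rep(m, sizes[m]))
  }
  noise <- matrix(rnorm(n_noise * n), n_noise, n)
  x <- rbind(do.call(rbind, rows), noise)
  labels <- c(labels, rep(0, n_noise))
  dimnames(x) <- list(sprintf("P%03d", seq_len(nrow(x))),
                      sprintf("s%02d", seq_len(n)))
  list(x = x, labels = setNames(labels, rownames(x)))
}

test_that("signed adjacency applies the closed-form bicor mapping", {
  set.seed(1)
  x <- matrix(rnorm(6 * 30), 6, 30,
              dimnames = list(paste0("P", 1:6), paste0("s", 1:30)))
  x[2, ] <- x[1, ] * 2          # bicor +1
  x[3, ] <- -x[1, ]             # bicor -1
  a <- soft_adjacency(x, beta = 24.5)
  expect_equal(a["P1", "P2"], 1, tolerance = 1e-12)
  expect_equal(a["P1", "P3"], 0, tolerance = 1e-12)
  # generic entries equal ((1 + r)/2)^beta
  r <- as.numeric(bicor(x[4, ], x[5, ]))
  expect_equal(a["P4", "P5"], ((1 + r) / 2)^24.5, tolerance = 1e-12)
  expect_error(soft_adjacency(x, beta = 0), "> 0")
})

test_that("raising beta shrinks every off-diagonal adjacency in (0,1)", {
  set.seed(2)
  x <- matrix(rnorm(8 * 40), 8, 40,
              dimnames = list(paste0("P", 1:8), paste0("s", 1:40)))
  a1 <- soft_adjacency(x, beta = 6)
  a2 <- soft_adjacency(x, beta = 12)
  off <- upper.tri(a1)
  expect_true(all(a2[off] < a1[off]))
})

test_that("TOM matches hand arithmetic and the brute-force oracle", {
  a <- matrix(0.5, 3, 3); diag(a) <- 1
  tom <- topological_overlap(a)
  expect_equal(tom[1, 2], 0.5, tolerance = 1e-12)  # (0.25+0.5)/(1+1-0.5)
  # disconnected adjacency: zero off-diagonal overlap
  expect_true(all(topological_overlap(diag(4))[upper.tri(diag(4))] == 0))
  set.seed(3)
  for (i in 1:30) {
    p <- 20
    a <- matrix(runif(p * p), p, p)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    expect_lt(max(abs(topological_overlap(a) - tom_oracle(a))), 1e-12)
  }
  expect_error(topological_overlap(matrix(runif(9), 3, 3)), "symmetric")
})

test_that("planted blocks are detected; undersized blocks stay unassigned", {
  me <- make_module_expr(sizes = c(40, 40, 40), n_noise = 60, seed = 4)
  tom <- topological_overlap(soft_adjacency(me$x, beta = 12))
  lab <- detect_modules(1 - tom, min_module_size = 15)
  assigned <- lab > 0
  expect_gte(ari(lab[assigned], me$labels[assigned]), 0.9)
  # a size-10 block below the minimum is never reported as a module
  me2 <- make_module_expr(sizes = c(40, 10), n_noise = 60, seed = 5)
  tom2 <- topological_overlap(soft_adjacency(me2$x, beta = 12))
  lab2 <- detect_modules(1 - tom2, min_module_size = 15)
  small <- names(me2$labels)[me2$labels == 2]
  expect_true(all(lab2[small] == 0))
  expect_error(detect_modules((1 - tom2)[, 1:10]), "square")
})

test_that("a single homogeneous block forms one all-member module", {
  me <- make_module_expr(sizes = 40, n_noise = 0, loading = 0.95, seed = 6)
  tom <- topological_overlap(soft_adjacency(me$x, beta = 12))
  lab <- detect_modules(1 - tom, min_module_size = 15)
  expect_equal(max(lab), 1)
  expect_true(all(lab == 1))
})

test_that("eigenproteins summarize modules with the declared conventions", {
  set.seed(7)
  profile <- rnorm(50)
  x <- matrix(rep(profile, each = 6), 6, 50,
              dimnames = list(paste0("P", 1:6), paste0("s", 1:50)))
  labels <- setNames(rep(1L, 6), rownames(x))
  es <- module_eigenproteins(x, labels)
  expect_equal(es$variance_explained[["M1"]], 1, tolerance = 1e-10)
  expect_true(all(abs(es$kME[, "M1"] - 1) < 1e-10))
  expect_gte(cor(es$eigenproteins[, "M1"], profile), 0)
  expect_equal(sqrt(sum(es$eigenproteins[, 1]^2)), 1, tolerance = 1e-10)
  # two orthogonal half-modules forced together: PC1 carries about half
  set.seed(8)
  f1 <- rnorm(60); f2 <- rnorm(60)
  y <- rbind(t(sapply(1:10, function(i) f1 + rnorm(60, 0, 0.1))),
             t(sapply(1:10, function(i) f2 + rnorm(60, 0, 0.1))))
  dimnames(y) <- list(paste0("P", 1:20), paste0("s", 1:60))
  es2 <- module_eigenproteins(y, setNames(rep(1L, 20), rownames(y)))
  expect_equal(es2$variance_explained[["M1"]], 0.5, tolerance = 0.15)
  expect_error(module_eigenproteins(y, setNames(c(1L, rep(0L, 19)),
                                                rownames(y))),
               "fewer than 2")
})

test_that("eigenprotein sign always aligns with the module mean profile", {
  for (s in 1:10) {
    me <- make_module_expr(sizes = c(20, 20), n_noise = 0, seed = s + 20)
    es <- module_eigenproteins(me$x, me$labels)
    for (m in colnames(es$eigenproteins)) {
      members <- names(me$labels)[paste0("M", me$labels) == m]
      avg <- rowMeans(scale(t(me$x[members, ])))
      expect_gte(cor(es$eigenproteins[, m], avg), 0)
    }
  }
})

test_that("near-identical modules merge below the cut height, others do not", {
  set.seed(9)
  f <- rnorm(80)
  x <- rbind(t(sapply(1:20, function(i) f + rnorm(80, 0, 0.02))),
             t(sapply(1:20, function(i) f + rnorm(80, 0, 0.02))),
             t(sapply(1:20, function(i) rnorm(80))))
  dimnames(x) <- list(paste0("P", 1:60), paste0("s", 1:80))
  labels <- setNames(c(rep(1L, 20), rep(2L, 20), rep(3L, 20)), rownames(x))
  merged <- merge_modules(x, labels, min_kme = 0)
  expect_equal(unname(merged[1]), unname(merged[21]))   # 0.99-correlated pair
  expect_false(unname(merged[1]) == unname(merged[41])) # unrelated module
  # idempotence
  again <- merge_modules(x, merged, min_kme = 0)
  expect_equal(unname(again), unname(merged))
})

test_that("module-trait grid recovers planted associations", {
  me <- make_module_expr(sizes = c(25, 25), n_noise = 0, seed = 10)
  es <- module_eigenproteins(me$x, me$labels)
  tr <- data.frame(t1 = es$eigenproteins[, "M1"],
                   t2 = rnorm(ncol(me$x)))
  grid <- module_trait_association(es, traits = tr)
  self <- grid[grid$module == "M1" & grid$trait == "t1", ]
  expect_equal(self$estimate, 1, tolerance = 1e-10)
  expect_lt(self$p, 1e-10)
  # disease contrast with an (almost) empty group -> missing cell, no crash
  meta <- data.frame(group = c(rep("Control", ncol(me$x) - 2), "LATE", "LATE"))
  grid2 <- module_trait_association(es, meta = meta)
  expect_true(all(is.na(grid2$estimate[grid2$trait == "LATE vs control"])))
})

test_that("eigenprotein ANOVA is invariant within subtype and finds signal", {
  set.seed(11)
  n <- 60
  lab <- factor(rep(c("low", "intermediate", "high"), each = n / 3),
                levels = c("low", "intermediate", "high"))
  eps <- cbind(M1 = as.numeric(lab) + rnorm(n, 0, 0.3),
               M2 = rnorm(n))
  rownames(eps) <- paste0("s", 1:n)
  res <- eigenprotein_anova(eps, lab)
  expect_lt(res$anova$p[res$anova$module == "M1"], 0.01)
  expect_gt(res$anova$p[res$anova$module == "M2"], 0.01)
  # permuting samples within each subtype leaves the result unchanged
  idx <- unlist(lapply(split(seq_len(n), lab), sample))
  res2 <- eigenprotein_anova(eps[idx, ], lab[idx])
  expect_equal(res2$anova$F, res$anova$F, tolerance = 1e-12)
  expect_error(eigenprotein_anova(eps, factor(rep("low", n))), ">= 2")
})
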