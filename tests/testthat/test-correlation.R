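test_that("log2 transform maps values through log2(x + pseudocount) and is idempotent", {
  m <- matrix(c(0, 7, 1, 3), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  ds <- expression_dataset("toy", m, "linear")
  tr <- log2_transform(ds, pseudocount = 1)
  expect_equal(tr$values[1, 1], 0)   # log2(0 + 1)
  expect_equal(tr$values[2, 1], 3)   # log2(7 + 1)
  expect_identical(tr$scale, "log2")
  expect_identical(log2_transform(tr, 1), tr)  # no-op on log2 data
  ds$values[1, 1] <- -2
  expect_error(log2_transform(ds, 1), "negative")
})

test_that("pearson_r matches the hand sum-form oracle and exact (anti)linearity", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1)
  # sum-form by hand: n*Sxy - Sx*Sy = 116 - 100 = 16; denominators 20 each
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_r(c(1, NA), c(1, 2)), "fewer than 3")
})

test_that("pearson_r is symmetric and invariant to positive affine rescaling", {
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(15)
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    expect_equal(pearson_r(x, y), pearson_r(y, x))
    expect_equal(pearson_r(a * x + b, y), pearson_r(x, y))
    expect_equal(pearson_r(-a * x + b, y), -pearson_r(x, y))
  }
})

test_that("correlation significance reproduces the quadrature oracle at r = 0.5, n = 27", {
  res <- correlation_significance(0.5, 27)
  # frozen from direct numerical integration of the t density with 25 df
  expect_equal(res$t, 2.8867513459, tolerance = 1e-9)
  expect_equal(res$p, 0.007912738358, tolerance = 1e-8)
})

test_that("correlation significance: null case, monotonicity in n, |r| = 1 sentinel", {
  res0 <- correlation_significance(0, 50)
  expect_equal(res0$t, 0)
  expect_equal(res0$p, 1)
  ps <- vapply(c(5, 10, 20, 40, 80),
               function(n) correlation_significance(0.4, n)$p, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_warning(res1 <- correlation_significance(1, 10), "smallest positive")
  expect_true(res1$p > 0 && res1$p < 1e-300)
  expect_error(correlation_significance(0.5, 2), "at least 3")
  expect_error(correlation_significance(1.2, 10), "-1, 1")
})

test_that("t-approximation significance calls agree in rank with exact permutation at tiny n", {
  # permute one vector at n = 6; exact permutation p from the correlation
  # magnitude, compared as significance ranks, not equality
  x <- c(0.3, 1.1, 2.0, 2.9, 4.2, 5.1)
  y <- c(0.1, 0.9, 2.2, 3.4, 3.9, 5.5)  # strongly correlated
  y2 <- c(2.2, 0.1, 3.9, 0.9, 5.5, 3.4) # scrambled
  perm_p <- function(x, y) {
    r_obs <- abs(pearson_r(x, y))
    # enumerate all 720 orderings of y
    idx <- expand.grid(rep(list(1:6), 6))
    idx <- idx[apply(idx, 1, function(v) !any(duplicated(v))), ]
    rs <- apply(idx, 1, function(v) abs(cor(x, y[unlist(v)])))
    mean(rs >= r_obs - 1e-12)
  }
  p_exact_strong <- perm_p(x, y)
  p_exact_weak <- perm_p(x, y2)
  p_t_strong <- correlation_significance(pearson_r(x, y), 6)$p
  p_t_weak <- correlation_significance(pearson_r(x, y2), 6)$p
  expect_lt(p_t_strong, 0.05)
  expect_lt(p_exact_strong, 0.05)
  expect_gt(p_t_weak, 0.05)
  expect_gt(p_exact_weak, 0.05)
})

test_that("anchor correlation: completeness, perfect-copy gene, skipped genes", {
  set.seed(7)
  n <- 30
  vals <- rbind(anchor = rnorm(n, 8), copy = NA, noise = rnorm(n, 8),
                flat = rep(5, n))
  vals["copy", ] <- vals["anchor", ]
  colnames(vals) <- sprintf("s%02d", 1:n)
  ds <- expression_dataset("toy", vals, "log2")
  rec <- correlate_anchor_gene(ds, "anchor")
  expect_equal(nrow(rec) + length(attr(rec, "skipped")),
               nrow(vals) - 1L)  # one record or skip per non-anchor gene
  expect_identical(attr(rec, "skipped"), "flat")
  cp <- rec[rec$gene == "copy", ]
  expect_equal(cp$r, 1)
  expect_identical(cp$sign, "+")
  expect_error(correlate_anchor_gene(ds, "nope"), "not present")
  ds$values["anchor", ] <- 1
  expect_error(correlate_anchor_gene(ds, "anchor"), "constant")
})

test_that("status correlation is point-biserial: direction, encoding symmetry", {
  ds <- status_dataset(n = 60)
  rec <- correlate_binary_status(ds, "er")
  up <- rec[rec$gene == "up", ]
  expect_gt(up$r, 0.7)          # near-indicator gene, strong positive r
  expect_identical(up$sign, "+")
  # swapping the status coding flips r, leaves p unchanged
  ds_sw <- ds
  ds_sw$clinical$er <- ifelse(ds$clinical$er == "positive",
                              "negative", "positive")
  rec_sw <- correlate_binary_status(ds_sw, "er")
  expect_equal(rec_sw$r, -rec$r)
  expect_equal(rec_sw$p, rec$p)
  # a status class below 2 samples errors by name
  ds2 <- ds
  ds2$clinical$er <- c("negative", rep("positive", 59))
  expect_error(correlate_binary_status(ds2, "er"), "negative")
})

test_that("status-permutation null yields ~alpha significant calls and uniform p", {
  set.seed(123)
  n <- 120
  er <- rep(c("positive", "negative"), each = n / 2)
  n_genes <- 1000
  vals <- matrix(rnorm(n_genes * n, 8, 1), n_genes, n,
                 dimnames = list(sprintf("g%04d", 1:n_genes),
                                 sprintf("s%03d", 1:n)))
  ds <- expression_dataset("null", vals, "log2",
                           clinical = clinical_table(colnames(vals),
                                                     er = sample(er)))
  rec <- correlate_binary_status(ds, "er")
  frac_sig <- mean(rec$p < 0.05)
  se <- sqrt(0.05 * 0.95 / n_genes)
  expect_lt(abs(frac_sig - 0.05), 3 * se)
  ks <- suppressWarnings(ks.test(rec$p, "punif"))
  expect_gt(ks$p.value, 0.001)  # coarse uniformity check
})

test_that("Kruskal-Wallis matches the hand midrank formula and exact permutation", {
  res <- kruskal_wallis(c(1, 2, 3, 4, 5, 6),
                        rep(c("a", "b"), each = 3))
  # H by hand midrank formula on ranks 1..6 with R1 = 6, R2 = 15
  expect_equal(res$statistic, 27 / 7, tolerance = 1e-10)
  expect_equal(res$df, 1)
  # exact permutation over all 20 assignments (frozen oracle): p = 0.10
  vals <- 1:6
  p_perm <- perm_pvalue(vals, 3, function(idx) {
    rks <- rank(vals)
    R1 <- sum(rks[idx]); R2 <- sum(rks[-idx])
    12 / 42 * (R1^2 / 3 + R2^2 / 3) - 21
  })
  expect_equal(p_perm, 0.10)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "2 groups")
})

test_that("Kruskal-Wallis: identical groups give H = 0 and shifts leave H unchanged", {
  v <- c(3, 1, 4, 3, 1, 4)
  g <- rep(c("a", "b"), each = 3)
  expect_equal(kruskal_wallis(v, g)$statistic, 0, tolerance = 1e-12)
  set.seed(9)
  v2 <- rnorm(20); g2 <- rep(c("a", "b", "c", "d"), 5)
  expect_equal(kruskal_wallis(v2 + 100, g2)$statistic,
               kruskal_wallis(v2, g2)$statistic)
})

test_that("Welch ANOVA matches the hand formula, F = t^2 for two groups", {
  x1 <- c(1, 2, 3, 4); x2 <- c(2, 4, 6, 8, 10); x3 <- c(5, 5, 6, 7)
  res <- welch_anova(c(x1, x2, x3),
                     rep(c("a", "b", "c"), c(4, 5, 4)))
  # frozen from a hand evaluation of the Welch F formula
  expect_equal(res$statistic, 7.8163505219, tolerance = 1e-9)
  expect_equal(unname(res$df), c(2, 6.3590665614), tolerance = 1e-8)
  # two groups: omnibus F equals squared Welch t
  res2 <- welch_anova(c(x1, x2), rep(c("a", "b"), c(4, 5)))
  tt <- t.test(x2, x1, var.equal = FALSE)
  expect_equal(res2$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res2$p, tt$p.value, tolerance = 1e-10)
  expect_error(welch_anova(c(1, 1, 2, 3), rep(c("a", "b"), each = 2)),
               "zero-variance")
})

test_that("Welch ANOVA null rejection rate is ~alpha and post-hoc targets the reference", {
  set.seed(77)
  reps <- 1000
  rej <- logical(reps)
  for (i in seq_len(reps)) {
    v <- rnorm(30)
    rej[i] <- welch_anova(v, rep(c("a", "b", "c"), each = 10))$p < 0.05
  }
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(mean(rej) - 0.05), 3 * se)
  res <- welch_anova(c(rnorm(10), rnorm(10, 3), rnorm(10)),
                     rep(c("basal", "lum", "her2"), each = 10),
                     reference = "basal")
  expect_setequal(res$posthoc$group, c("lum", "her2"))
  expect_true(all(res$posthoc$p_adj >= res$posthoc$p))
})
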