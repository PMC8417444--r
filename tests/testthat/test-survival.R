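test_that("KM estimate matches the hand product-limit computation", {
  tr <- survival_track(time = c(1, 2, 3), event = c(1, 1, 1))
  km <- km_estimate(tr)
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  # all censored: S stays at 1
  trc <- survival_track(time = c(1, 2, 3), event = c(0, 0, 0))
  expect_true(all(km_estimate(trc)$survival == 1))
  # duplicating every subject leaves the curve unchanged
  tr2 <- survival_track(time = rep(c(1, 2, 3), 2), event = rep(c(1, 1, 1), 2))
  expect_equal(km_estimate(tr2)$survival, km$survival)
  # censoring in the middle: hand product-limit 4 subjects, censor at 2
  tr3 <- survival_track(time = c(1, 2, 3, 4), event = c(1, 0, 1, 1))
  expect_equal(km_estimate(tr3)$survival, c(3 / 4, 3 / 4, 3 / 8, 0))
  expect_error(survival_track(time = c(0, 1), event = c(1, 1)), "positive")
})

test_that("logrank: identical groups give chi2 ~ 0; hand O-E-V example reproduces", {
  t0 <- c(1, 2, 3, 4, 5)
  tr <- survival_track(time = rep(t0, 2), event = rep(c(1, 1, 0, 1, 1), 2),
                       group = rep(c("a", "b"), each = 5))
  lt <- logrank_test(tr)
  expect_lt(lt$chi2, 1e-10)
  expect_gt(lt$p, 0.999)
  # hand-computed: A = (1,3) events, B = (2 event, 4 censored)
  # O_A = 2, E_A = 4/3, V = 13/18 -> chi2 = 8/13
  tr2 <- survival_track(time = c(1, 3, 2, 4), event = c(1, 1, 1, 0),
                        group = c("a", "a", "b", "b"))
  expect_equal(logrank_test(tr2)$chi2, 8 / 13, tolerance = 1e-10)
  expect_error(logrank_test(survival_track(1:3, c(1, 1, 1))), "2 non-empty")
  expect_error(logrank_test(survival_track(1:4, rep(0, 4),
                                           group = c("a", "a", "b", "b"))),
               "no events")
})

test_that("logrank chi2 is invariant to group relabeling and matches permutation on a tiny case", {
  set.seed(31)
  tr <- survival_track(time = rexp(12) + 0.1, event = rbinom(12, 1, 0.8),
                       group = rep(c("a", "b"), 6))
  tr_re <- tr
  tr_re$group <- ifelse(tr$group == "a", "x", "w")
  expect_equal(logrank_test(tr_re)$chi2, logrank_test(tr)$chi2)
  # exact permutation oracle on a small example: the chi-square p and the
  # permutation p of the logrank statistic agree coarsely
  time <- c(1, 2, 4, 5, 6, 8)
  event <- c(1, 1, 1, 1, 0, 1)
  chi_of <- function(idx) {
    g <- rep("b", 6); g[idx] <- "a"
    logrank_test(survival_track(time, event, group = g))$chi2
  }
  p_perm <- perm_pvalue(seq_along(time), 3, chi_of)
  p_chi <- logrank_test(survival_track(time, event,
                                       group = rep(c("a", "b"), each = 3)))$p
  expect_lt(abs(p_perm - p_chi), 0.25)
})

test_that("internal scan logrank agrees with survdiff at matched splits", {
  set.seed(17)
  n <- 40
  expr <- rnorm(n)
  tr <- survival_track(time = rexp(n, 0.2), event = rbinom(n, 1, 0.7))
  ks <- kaplan_scan(expr, tr, run_config(kaplan_min_group = 5))
  for (i in sample(nrow(ks$profile), 5)) {
    cut <- ks$profile$cutoff[i]
    g <- ifelse(expr > cut, "high", "low")
    ref <- logrank_test(survival_track(tr$time, tr$event, group = g))
    expect_equal(ks$profile$chi2[i], ref$chi2, tolerance = 1e-8)
    expect_equal(ks$profile$p[i], ref$p, tolerance = 1e-8)
  }
})

test_that("kaplan scan: minimal p, group-size bounds, median-split dominance, ties", {
  set.seed(4)
  n <- 100
  expr <- rnorm(n)
  tr <- survival_track(time = rexp(n, 0.1), event = rbinom(n, 1, 0.6))
  cfg <- run_config(kaplan_min_group = 8)
  ks <- kaplan_scan(expr, tr, cfg)
  expect_equal(ks$p_raw, min(ks$profile$p))
  expect_true(all(ks$profile$n_low >= 8 & ks$profile$n_high >= 8))
  expect_gte(ks$p_adjusted, ks$p_raw)
  # the median split's p can never beat the scanned minimum
  med_i <- which.min(abs(ks$profile$n_low - n / 2))
  expect_gte(ks$profile$p[med_i], ks$p_raw)
  # shrinking the minimum group enlarges the search space: p_raw cannot rise
  ks2 <- kaplan_scan(expr, tr, run_config(kaplan_min_group = 4))
  expect_lte(ks2$p_raw, ks$p_raw)
  expect_error(kaplan_scan(rep(1, n), tr, cfg), "constant")
})

test_that("kaplan scan recovers a planted 3-fold hazard difference between separated supports", {
  set.seed(1234)
  n <- 200
  grp <- rep(c("lowexpr", "highexpr"), each = n / 2)
  expr <- c(runif(n / 2, 0, 1), runif(n / 2, 2, 3))  # disjoint supports
  rate <- ifelse(grp == "highexpr", 0.3, 0.1)
  t_ev <- rexp(n, rate)
  t_cs <- runif(n, 0, 20)
  tr <- survival_track(pmin(t_ev, t_cs), as.integer(t_ev <= t_cs))
  ks <- kaplan_scan(expr, tr, run_config(kaplan_min_group = 8))
  # recovery is judged by the induced grouping: the scanned minimum drifts a
  # few boundary samples past the gap by chance, so the cutoff recovers the
  # planted split up to a small misclassified fraction
  planted_high <- grp == "highexpr"
  agreement <- mean((expr > ks$cutoff) == planted_high)
  expect_gte(agreement, 0.95)
  expect_lt(ks$p_adjusted, 0.01)
})

test_that("scan multiplicity: raw minimum is anti-conservative, adjusted p is not", {
  set.seed(55)
  reps <- 400
  n <- 60
  raw_rej <- adj_rej <- logical(reps)
  cfg <- run_config(kaplan_min_group = 10)
  for (i in seq_len(reps)) {
    expr <- rnorm(n)
    t_ev <- rexp(n, 0.15)
    t_cs <- runif(n, 0, 15)
    tr <- survival_track(pmin(t_ev, t_cs), as.integer(t_ev <= t_cs))
    ks <- kaplan_scan(expr, tr, cfg)
    raw_rej[i] <- ks$p_raw < 0.05
    adj_rej[i] <- ks$p_adjusted < 0.05
  }
  se <- sqrt(0.05 * 0.95 / reps)
  expect_gt(mean(raw_rej), 0.05 + 3 * se)   # empirically anti-conservative
  expect_lte(mean(adj_rej), 0.05 + 3 * se)  # Bonferroni-style control
})

test_that("combined tracks form four groups with expected sizes and degenerate guards", {
  set.seed(8)
  n <- 400
  samples <- sprintf("s%03d", 1:n)
  a <- setNames(sample(c("high", "low"), n, replace = TRUE), samples)
  b <- setNames(sample(c("high", "low"), n, replace = TRUE), samples)
  comb <- combine_tracks(a, b)
  sizes <- table(comb)
  expect_length(sizes, 4L)
  # independent fair tracks: each group ~ n/4 within 3 binomial sd
  sd3 <- 3 * sqrt(n * 0.25 * 0.75)
  expect_true(all(abs(sizes - n / 4) < sd3))
  # constant second track degenerates
  b_const <- setNames(rep("high", n), samples)
  expect_error(combine_tracks(a, b_const), "constant")
  expect_error(combine_tracks(a, setNames(b, sprintf("x%03d", 1:n))),
               "no samples")
  # samples missing from one track are dropped with a message
  expect_message(comb2 <- combine_tracks(a[1:300], b[101:400]), "dropping")
  expect_length(comb2, 200L)
})

test_that("worst planted combined group has the lowest KM curve; pairwise logrank flags it", {
  set.seed(777)
  n <- 400
  samples <- sprintf("s%03d", 1:n)
  a <- setNames(sample(c("high", "low"), n, replace = TRUE), samples)
  b <- setNames(sample(c("high", "low"), n, replace = TRUE), samples)
  worst <- a == "high" & b == "low"
  rate <- ifelse(worst, 0.4, 0.08)
  t_ev <- rexp(n, rate)
  t_cs <- runif(n, 0, 25)
  comb <- combine_tracks(a, b)
  tr <- survival_track(pmin(t_ev, t_cs), as.integer(t_ev <= t_cs),
                       group = as.character(comb))
  # KM at median follow-up: worst group lowest
  med_t <- median(tr$time)
  surv_at <- function(g) {
    km <- km_estimate(tr, group = g)
    s <- c(1, km$survival)[findInterval(med_t, c(0, km$time)) ]
    s
  }
  svals <- vapply(levels(comb), surv_at, numeric(1))
  expect_equal(names(which.min(svals)), "A-high/B-low")
  lt <- logrank_test(tr)
  expect_lt(lt$p, 1e-6)
  pw <- pairwise_logrank(tr)
  expect_equal(nrow(pw), 6L)
  inv <- pw[pw$group1 == "A-high/B-low" | pw$group2 == "A-high/B-low", ]
  expect_true(all(inv$p_adj < 0.01))
})
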