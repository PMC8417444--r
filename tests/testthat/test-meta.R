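# Build a correlation_records data frame directly from vote patterns: a
# character vector per gene, one element per dataset, "+" = significant
# positive, "-" = significant negative, "." = not significant, NA = gene
# absent from that dataset.
records_from_votes <- function(votes, alpha = 0.05) {
  recs <- do.call(rbind, lapply(names(votes), function(g) {
    v <- votes[[g]]
    ds <- sprintf("d%02d", seq_along(v))
    keep <- !is.na(v)
    data.frame(gene = g, dataset = ds[keep],
               r = ifelse(v[keep] == "-", -0.5,
                          ifelse(v[keep] == "+", 0.5, 0.01)),
               n = 100,
               t = 0, p = ifelse(v[keep] == ".", 0.5, 0.001),
               sign = ifelse(v[keep] == ".", "none", v[keep]),
               stringsAsFactors = FALSE)
  }))
  structure(recs, class = c("correlation_records", "data.frame"))
}

test_that("vote filter implements the K-of-D rule with the cancel penalty", {
  votes <- list(
    pass6 = c(rep("+", 6), rep(".", 6)),        # 6 of 12 positive -> passes
    fail5 = c(rep("+", 5), rep(".", 7)),        # below threshold
    conflict = c(rep("+", 7), rep("-", 2), rep(".", 3)),  # net 5 -> fails
    strong_neg = c(rep("-", 9), rep(".", 3)),   # passes negative
    tie = c(rep("+", 6), rep("-", 6))           # tie -> no consensus
  )
  calls <- aggregate_votes(records_from_votes(votes), run_config(min_votes = 6))
  row <- function(g) calls[calls$gene == g, ]
  expect_true(row("pass6")$passes)
  expect_identical(row("pass6")$consensus_sign, "+")
  expect_false(row("fail5")$passes)
  expect_false(row("conflict")$passes)
  expect_equal(row("conflict")$net_votes, 5L)
  expect_true(row("strong_neg")$passes)
  expect_identical(row("strong_neg")$consensus_sign, "-")
  expect_false(row("tie")$passes)
  expect_identical(row("tie")$consensus_sign, "none")
})

test_that("strict penalty disqualifies any conflicted gene", {
  votes <- list(clean = c(rep("+", 7), rep(".", 5)),
                conflicted = c(rep("+", 8), "-", rep(".", 3)))
  cfg <- run_config(min_votes = 6, vote_penalty = "strict")
  calls <- aggregate_votes(records_from_votes(votes), cfg)
  expect_true(calls[calls$gene == "clean", "passes"])
  expect_false(calls[calls$gene == "conflicted", "passes"])
  # the same gene passes under the default cancel penalty (net 7)
  calls_c <- aggregate_votes(records_from_votes(votes), run_config(min_votes = 6))
  expect_true(calls_c[calls_c$gene == "conflicted", "passes"])
})

test_that("genes absent from some datasets contribute no vote and are audited, not dropped", {
  votes <- list(partial = c("+", "+", "+", NA, NA, NA, NA, NA, NA, NA, NA, NA))
  calls <- aggregate_votes(records_from_votes(votes), run_config(min_votes = 6))
  expect_equal(calls$n_datasets_tested, 3L)
  expect_false(calls$passes)     # tested in < min_votes datasets: cannot pass
  expect_equal(nrow(calls), 1L)  # still reported
})

test_that("duplicate gene records within one dataset are rejected", {
  recs <- records_from_votes(list(g1 = c("+", "+")))
  recs$dataset <- c("d01", "d01")
  expect_error(aggregate_votes(recs, run_config()), "within one dataset")
})

test_that("vote aggregation is invariant to dataset order and monotone in support", {
  votes <- list(a = c("+", "+", "+", "+", "+", "-", ".", "+"),
                b = c("-", "-", ".", "-", "-", "-", "-", "."))
  recs <- records_from_votes(votes)
  cfg <- run_config(min_votes = 5)
  base <- aggregate_votes(recs, cfg)
  set.seed(1)
  shuf <- recs[sample(nrow(recs)), ]
  expect_equal(as.data.frame(aggregate_votes(shuf, cfg)), as.data.frame(base))
  # adding one more significant same-sign dataset never un-passes a gene
  for (g in names(votes)) {
    sgn <- base[base$gene == g, "consensus_sign"]
    extra <- records_from_votes(setNames(list(c(votes[[g]], sgn)), g))
    extra$dataset[nrow(extra)] <- "d99"
    more <- aggregate_votes(extra, cfg)
    if (base[base$gene == g, "passes"]) expect_true(more$passes)
    expect_gte(more$net_votes, base[base$gene == g, "net_votes"])
  }
})

test_that("with one dataset and min_votes 1 the filter reduces to the per-dataset call", {
  set.seed(21)
  ds <- status_dataset(n = 80)
  rec <- correlate_binary_status(ds, "er")
  calls <- aggregate_votes(rec, run_config(min_votes = 1))
  merged <- merge(as.data.frame(rec), as.data.frame(calls), by = "gene")
  expect_identical(merged$passes, merged$p < 0.05)
})

test_that("signed gene lists partition the passing genes disjointly", {
  votes <- list(up = rep("+", 7), down = rep("-", 7), ns = rep(".", 7),
                weak = c("+", "+", rep(".", 5)))
  calls <- aggregate_votes(records_from_votes(votes), run_config(min_votes = 6))
  sl <- signed_gene_list(calls)
  expect_identical(sl$pos, "up")
  expect_identical(sl$neg, "down")
  expect_length(intersect(sl$pos, sl$neg), 0L)
  expect_setequal(c(sl$pos, sl$neg), calls$gene[calls$passes])
  # all-failing calls give two empty sets
  none <- aggregate_votes(records_from_votes(list(x = rep(".", 7))),
                          run_config(min_votes = 6))
  sl0 <- signed_gene_list(none)
  expect_length(sl0$pos, 0L)
  expect_length(sl0$neg, 0L)
})
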