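# Small fixtures built in code.

toy_matrix <- function(n_genes = 3, n_samples = 4, seed = 11) {
  set.seed(seed)
  matrix(round(rnorm(n_genes * n_samples, 8, 1), 3), n_genes, n_samples,
         dimnames = list(sprintf("g%d", seq_len(n_genes)),
                         sprintf("s%d", seq_len(n_samples))))
}

toy_dataset <- function(n_genes = 3, n_samples = 4, seed = 11,
                        scale = "log2") {
  expression_dataset("toy", toy_matrix(n_genes, n_samples, seed),
                     scale = scale)
}

toy_clinical <- function(samples, er = "positive") {
  clinical_table(sample = samples, er = rep_len(er, length(samples)))
}

# dataset with a planted status effect: gene "up" higher in ER-positive
status_dataset <- function(n = 60, seed = 5, shift = 2) {
  set.seed(seed)
  er <- rep(c("positive", "negative"), each = n / 2)
  vals <- rbind(
    up = 8 + shift * (er == "positive") + rnorm(n, 0, 0.5),
    flat = rnorm(n, 8, 0.5)
  )
  colnames(vals) <- sprintf("s%03d", seq_len(n))
  expression_dataset("status_toy", vals, scale = "log2",
                     clinical = clinical_table(colnames(vals), er = er))
}

# exact permutation p-value of a statistic over all assignments of
# `size1` labels to positions (used as an independent oracle at tiny n)
perm_pvalue <- function(values, size1, stat_fn) {
  idx <- utils::combn(length(values), size1)
  obs <- stat_fn(seq_len(size1))
  stats <- apply(idx, 2, stat_fn)
  mean(stats >= obs - 1e-12)
}

expect_tsv_roundtrip <- function(ds) {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(ds, path)
  back <- read_expression_matrix(path, ds$name)
  expect_identical(back$values, ds$values)
  expect_identical(back$scale, ds$scale)
}
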