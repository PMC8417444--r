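# Per-cohort correlation of every gene with an anchor gene or a binary
# clinical status, with t-based significance on n-2 degrees of freedom.

#' Log2-transform a linear-scale expression dataset
#'
#' Replaces every value by `log2(value + pseudocount)` and flags the dataset
#' as log2 scale. Datasets already on log2 scale are returned unchanged, so
#' the operation is idempotent.
#'
#' @param dataset an [expression_dataset()].
#' @param pseudocount non-negative offset added before taking logs.
#' @return The transformed dataset.
#' @examples
#' m <- matrix(c(0, 7, 1, 3), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' log2_transform(expression_dataset("toy", m, "linear"), pseudocount = 1)$values
#' @export
log2_transform <- function(dataset, pseudocount = 1) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (dataset$scale == "log2") return(dataset)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0)
    stop("`pseudocount` must be a single non-negative number")
  if (any(dataset$values < 0))
    stop("negative values in linear-scale data; cannot log2-transform")
  if (any(dataset$values + pseudocount <= 0))
    stop("zero values require a positive pseudocount")
  dataset$values <- log2(dataset$values + pseudocount)
  dataset$scale <- "log2"
  dataset
}

#' Pearson product-moment correlation with pairwise-complete deletion
#'
#' Pairs with a missing value in either vector are removed first. At least 3
#' complete pairs are required and both vectors must be non-constant on the
#' complete pairs; violations are errors, never silently reported as 0.
#'
#' @param x,y numeric vectors of equal length.
#' @return The correlation coefficient, a single number in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L)
    stop("fewer than 3 complete pairs; correlation undefined")
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant vector; correlation undefined")
  as.numeric(stats::cor(x, y))
}

#' Significance of a correlation coefficient
#'
#' Computes `t = r * sqrt((n - 2) / (1 - r^2))` and the two-sided tail
#' probability of the Student t distribution with `n - 2` degrees of
#' freedom. Vectorised over `r` and `n`.
#'
#' @param r correlation coefficient(s), |r| <= 1.
#' @param n number(s) of samples used, >= 3.
#' @return A list with numeric components `t` and `p`. For |r| = 1 the test
#'   is degenerate: `t` is infinite and `p` is reported as the smallest
#'   positive double, with a warning.
#' @examples
#' correlation_significance(0.5, 27)
#' @export
correlation_significance <- function(r, n) {
  if (any(is.na(r)) || any(abs(r) > 1))
    stop("`r` must lie in [-1, 1] with no missing values")
  if (any(n < 3L)) stop("`n` must be at least 3")
  df <- n - 2
  t <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), df)
  perfect <- abs(r) == 1
  if (any(perfect)) {
    warning("|r| = 1: p-value reported as smallest positive double")
    t[perfect] <- sign(r[perfect]) * Inf
    p[perfect] <- .Machine$double.xmin
  }
  list(t = t, p = p)
}

# Correlate each row of a genes x samples matrix against a numeric target
# vector; pairwise-complete per gene. Returns the records data frame plus
# the genes skipped (constant or < 3 complete pairs).
.correlate_matrix <- function(values, target, dataset_name, alpha) {
  n_samp <- ncol(values)
  stopifnot(length(target) == n_samp)
  genes <- rownames(values)
  t_ok <- !is.na(target)
  if (!anyNA(values) && all(t_ok)) {
    n <- rep(n_samp, nrow(values))
    sds <- apply(values, 1L, stats::sd)
    usable <- sds > 0 & n >= 3L
    r <- rep(NA_real_, nrow(values))
    if (any(usable))
      r[usable] <- as.numeric(stats::cor(t(values[usable, , drop = FALSE]), target))
  } else {
    n <- integer(nrow(values))
    r <- rep(NA_real_, nrow(values))
    usable <- logical(nrow(values))
    for (i in seq_len(nrow(values))) {
      ok <- t_ok & !is.na(values[i, ])
      n[i] <- sum(ok)
      if (n[i] >= 3L && stats::sd(values[i, ok]) > 0 && stats::sd(target[ok]) > 0) {
        usable[i] <- TRUE
        r[i] <- as.numeric(stats::cor(values[i, ok], target[ok]))
      }
    }
  }
  skipped <- genes[!usable]
  genes <- genes[usable]
  r <- r[usable]; n <- n[usable]
  sig <- suppressWarnings(correlation_significance(r, n))
  sgn <- ifelse(sig$p < alpha, ifelse(r > 0, "+", "-"), "none")
  rec <- data.frame(gene = genes, dataset = dataset_name,
                    r = r, n = n, t = sig$t, p = sig$p, sign = sgn,
                    stringsAsFactors = FALSE)
  rownames(rec) <- NULL
  list(records = rec, skipped = skipped)
}

.prepare_scale <- function(dataset, config) {
  switch(config$log_transform,
         auto = if (dataset$scale == "linear")
           log2_transform(dataset, config$pseudocount) else dataset,
         force = log2_transform(dataset, config$pseudocount),
         never = dataset)
}

#' Correlate every gene with an anchor gene in one cohort
#'
#' Computes, for each non-anchor gene, the Pearson correlation with the
#' anchor gene's expression on log2 scale (linear cohorts are transformed
#' according to `config$log_transform`), the pairwise-complete sample count,
#' and the t-based significance. Genes with constant expression or fewer
#' than 3 complete pairs are skipped and listed in the `"skipped"`
#' attribute rather than reported with r = 0.
#'
#' @param dataset an [expression_dataset()] containing the anchor.
#' @param anchor gene identifier of the anchor gene.
#' @param config a [run_config()]; `alpha` sets the significance call.
#' @return A data frame of class `correlation_records` with columns
#'   `gene, dataset, r, n, t, p, sign` (`sign` is `"+"`, `"-"` or `"none"`),
#'   one row per usable non-anchor gene. Attributes: `target`, `skipped`.
#' @export
correlate_anchor_gene <- function(dataset, anchor, config = run_config()) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!anchor %in% rownames(dataset$values))
    stop(sprintf("anchor gene '%s' not present in dataset '%s'",
                 anchor, dataset$name))
  dataset <- .prepare_scale(dataset, config)
  target <- dataset$values[anchor, ]
  if (stats::sd(target, na.rm = TRUE) == 0)
    stop("anchor gene is constant across samples")
  vals <- dataset$values[setdiff(rownames(dataset$values), anchor), ,
                         drop = FALSE]
  res <- .correlate_matrix(vals, target, dataset$name, config$alpha)
  structure(res$records,
            class = c("correlation_records", "data.frame"),
            target = list(type = "gene", value = anchor),
            skipped = res$skipped,
            alpha = config$alpha)
}

#' Correlate every gene with a binary clinical status in one cohort
#'
#' The status is coded negative = 0, positive = 1 and correlated with each
#' gene using the same Pearson machinery as gene-gene correlation (the
#' point-biserial correlation). A negative sign therefore means higher
#' expression in status-negative samples. Samples with missing status are
#' dropped; both classes must retain at least 2 samples.
#'
#' @param dataset an [expression_dataset()] with clinical annotation.
#' @param status_field one of `"er"`, `"pr"`, `"her2"`.
#' @param config a [run_config()].
#' @return A `correlation_records` data frame as in
#'   [correlate_anchor_gene()].
#' @export
correlate_binary_status <- function(dataset, status_field = c("er", "pr", "her2"),
                                    config = run_config()) {
  status_field <- match.arg(status_field)
  stopifnot(inherits(dataset, "expression_dataset"))
  if (is.null(dataset$clinical))
    stop("dataset has no clinical annotation; use attach_clinical()")
  dataset <- .prepare_scale(dataset, config)
  status <- dataset$clinical[[status_field]]
  keep <- !is.na(status)
  counts <- table(factor(status[keep], levels = .status_levels))
  if (any(counts < 2L))
    stop(sprintf("status class '%s' has %d sample(s); need at least 2",
                 names(counts)[which.min(counts)], min(counts)))
  target <- as.numeric(status[keep] == "positive")
  vals <- dataset$values[, keep, drop = FALSE]
  res <- .correlate_matrix(vals, target, dataset$name, config$alpha)
  structure(res$records,
            class = c("correlation_records", "data.frame"),
            target = list(type = "status", value = status_field),
            skipped = res$skipped,
            alpha = config$alpha)
}

#' Write correlation records to TSV
#'
#' @param records a `correlation_records` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_correlation_records <- function(records, path) {
  utils::write.table(as.data.frame(records), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

.group_summaries <- function(values, groups) {
  do.call(rbind, lapply(split(values, groups), function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(n = length(v), q1 = q[1], median = q[2], q3 = q[3])
  }))
}

#' Kruskal-Wallis rank test across groups
#'
#' Midrank handling of ties with the standard tie correction; the H
#' statistic is referred to a chi-square distribution with g - 1 degrees of
#' freedom.
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length as `values`.
#' @return A list of class `group_test` with `statistic`, `df`, `p`,
#'   `method` and per-group `group_summaries` (n, quartiles).
#' @export
kruskal_wallis <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  ht <- stats::kruskal.test(values, groups)
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p = ht$p.value,
                 method = "Kruskal-Wallis",
                 group_summaries = .group_summaries(values, groups)),
            class = "group_test")
}

#' Welch's heteroscedastic one-way ANOVA with post-hoc comparisons
#'
#' The omnibus test is Welch's F with Welch-Satterthwaite denominator
#' degrees of freedom. Post-hoc comparisons are pairwise Welch t-tests of
#' every other group against `reference` (default: the first factor level),
#' Holm-adjusted.
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length as `values`; every group needs at
#'   least 2 observations and positive variance.
#' @param reference group treated as the baseline for post-hoc contrasts.
#' @param p_adjust multiplicity adjustment passed to [stats::p.adjust()].
#' @return A list of class `group_test` with the omnibus `statistic`, `df`
#'   (numerator, denominator), `p`, `group_summaries`, and a `posthoc` data
#'   frame (group, t, df, p, p_adj).
#' @export
welch_anova <- function(values, groups, reference = NULL, p_adjust = "holm") {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  ns <- tapply(values, groups, length)
  if (any(ns < 2L)) stop("every group needs at least 2 observations")
  vars <- tapply(values, groups, stats::var)
  if (any(vars == 0))
    stop("zero-variance group(s): ",
         paste(names(vars)[vars == 0], collapse = ", "))
  ht <- stats::oneway.test(values ~ groups, var.equal = FALSE)
  if (is.null(reference)) reference <- levels(groups)[1L]
  if (!reference %in% levels(groups))
    stop("reference group '", reference, "' not found")
  others <- setdiff(levels(groups), reference)
  ph <- do.call(rbind, lapply(others, function(g) {
    tt <- stats::t.test(values[groups == g], values[groups == reference],
                        var.equal = FALSE)
    data.frame(group = g, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               stringsAsFactors = FALSE)
  }))
  ph$p_adj <- stats::p.adjust(ph$p, method = p_adjust)
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p = ht$p.value,
                 method = "Welch ANOVA",
                 reference = reference,
                 posthoc = ph,
                 group_summaries = .group_summaries(values, groups)),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n",
              x$method, x$statistic,
              paste(signif(x$df, 4), collapse = ", "), x$p))
  if (!is.null(x$posthoc)) {
    cat(sprintf("Post-hoc (Welch t vs '%s', Holm-adjusted):\n", x$reference))
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}
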