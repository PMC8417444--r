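#' Construct an expression dataset (one cohort)
#'
#' A cohort is a genes x samples numeric matrix with unique row (gene) and
#' column (sample) identifiers, a declared expression scale, and optionally
#' a clinical annotation table covering the same samples.
#'
#' @param name cohort label.
#' @param values numeric matrix, genes in rows, samples in columns; rownames
#'   and colnames are required and must be unique. No missing values are
#'   allowed: impute or drop upstream.
#' @param scale `"linear"` or `"log2"`, the scale of `values` as provided.
#' @param clinical optional [clinical_table()] for the same samples; joined
#'   with [attach_clinical()].
#' @return An object of class `expression_dataset`.
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' ds <- expression_dataset("toy", m, scale = "linear")
#' dim(ds$values)
#' @export
expression_dataset <- function(name, values, scale = c("log2", "linear"),
                               clinical = NULL) {
  scale <- match.arg(scale)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("`name` must be a non-empty string")
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples))
    stop("`values` must have rownames (genes) and colnames (samples)")
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (anyDuplicated(samples))
    stop("duplicate sample identifiers: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (anyNA(values))
    stop("missing values in expression matrix; impute or drop before loading")
  ds <- structure(
    list(name = name, values = values, scale = scale, clinical = NULL),
    class = "expression_dataset"
  )
  if (!is.null(clinical)) ds <- attach_clinical(ds, clinical)
  ds
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("Expression dataset '%s': %d genes x %d samples (%s scale)\n",
              x$name, nrow(x$values), ncol(x$values), x$scale))
  if (!is.null(x$clinical)) {
    cat(sprintf("  clinical annotation: %d samples, fields: %s\n",
                nrow(x$clinical),
                paste(setdiff(names(x$clinical), "sample"), collapse = ", ")))
  }
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

.status_levels <- c("positive", "negative")

#' Construct a per-sample clinical annotation table
#'
#' @param sample character vector of unique sample identifiers.
#' @param er,pr,her2 receptor status: `"positive"`, `"negative"` or `NA`.
#' @param subtype molecular subtype label or `NA`.
#' @param surv_time non-negative survival/follow-up time or `NA`.
#' @param surv_event 1 = event, 0 = censored, `NA`; must be present exactly
#'   when `surv_time` is.
#' @return A data frame of class `clinical_table`.
#' @export
clinical_table <- function(sample,
                           er = NA, pr = NA, her2 = NA,
                           subtype = NA_character_,
                           surv_time = NA_real_, surv_event = NA_integer_) {
  n <- length(sample)
  if (anyDuplicated(sample))
    stop("duplicate sample identifiers in clinical table")
  rec <- function(x, len = n) {
    if (length(x) == 1L) rep(x, len) else x
  }
  tab <- data.frame(
    sample = as.character(sample),
    er = .check_status(rec(er), "er"),
    pr = .check_status(rec(pr), "pr"),
    her2 = .check_status(rec(her2), "her2"),
    subtype = as.character(rec(subtype)),
    surv_time = as.numeric(rec(surv_time)),
    surv_event = as.integer(rec(surv_event)),
    stringsAsFactors = FALSE
  )
  bad <- xor(is.na(tab$surv_time), is.na(tab$surv_event))
  if (any(bad))
    stop("survival time and event indicator must be present together; ",
         "offending samples: ", paste(tab$sample[bad], collapse = ", "))
  if (any(tab$surv_time < 0, na.rm = TRUE))
    stop("negative survival times")
  if (!all(tab$surv_event %in% c(0L, 1L, NA)))
    stop("survival event indicator must be 0, 1 or missing")
  class(tab) <- c("clinical_table", "data.frame")
  tab
}

.check_status <- function(x, field) {
  x <- as.character(x)
  ok <- is.na(x) | x %in% .status_levels
  if (!all(ok))
    stop(sprintf("invalid %s status value(s): %s", field,
                 paste(unique(x[!ok]), collapse = ", ")))
  x
}

#' Attach a clinical table to an expression dataset
#'
#' Performs an explicit inner join on sample identifiers. Samples present in
#' only one of the two inputs are dropped and reported via `message()`.
#'
#' @param dataset an [expression_dataset()].
#' @param clinical a [clinical_table()].
#' @return The dataset restricted to the common samples, with `clinical` set
#'   in the matching order.
#' @export
attach_clinical <- function(dataset, clinical) {
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(clinical, "clinical_table"))
  common <- intersect(colnames(dataset$values), clinical$sample)
  if (length(common) == 0L)
    stop("no samples shared between expression matrix and clinical table")
  drop_expr <- setdiff(colnames(dataset$values), common)
  drop_clin <- setdiff(clinical$sample, common)
  if (length(drop_expr))
    message(sprintf("[%s] dropping %d expression sample(s) without clinical annotation: %s",
                    dataset$name, length(drop_expr),
                    paste(utils::head(drop_expr, 5L), collapse = ", ")))
  if (length(drop_clin))
    message(sprintf("[%s] dropping %d clinical row(s) without expression data: %s",
                    dataset$name, length(drop_clin),
                    paste(utils::head(drop_clin, 5L), collapse = ", ")))
  dataset$values <- dataset$values[, common, drop = FALSE]
  clin <- clinical[match(common, clinical$sample), , drop = FALSE]
  rownames(clin) <- NULL
  class(clin) <- c("clinical_table", "data.frame")
  dataset$clinical <- clin
  dataset
}
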