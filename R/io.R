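# Text-format readers/writers: expression TSV, clinical TSV, GMT gene sets.
# Parsing is strict by design: ragged rows, malformed numbers and duplicate
# identifiers are hard errors that name the offending cell.

#' Read a genes x samples expression matrix from TSV
#'
#' Expected layout: optional leading metadata comment lines of the form
#' `# key: value` (recognised key: `scale`), then a header row of sample
#' identifiers, then one row per gene: gene id followed by one numeric value
#' per sample. `NA` is not permitted in the body.
#'
#' @param path path to the tab-separated file.
#' @param name cohort label for the resulting dataset.
#' @param scale declared expression scale; overridden by a `# scale:` header
#'   line if present.
#' @return An [expression_dataset()] with `clinical` unset.
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path, name, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  lines <- readLines(path)
  meta <- grep("^#", lines)
  for (i in meta) {
    m <- regmatches(lines[i], regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(\\S+)", lines[i]))[[1]]
    if (length(m) == 3L && m[2] == "scale") {
      if (!m[3] %in% c("linear", "log2"))
        stop("unknown scale declaration in header: ", m[3])
      scale <- m[3]
    }
  }
  if (length(meta)) lines <- lines[-meta]
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("expression file needs a header row and at least one gene row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  samples <- if (nzchar(header[1]) && length(fields[[2]]) == length(header) + 1L)
    header else header[-1]
  # header may or may not carry a leading corner label; infer from body width
  width <- length(samples) + 1L
  body <- fields[-1]
  for (i in seq_along(body)) {
    if (length(body[[i]]) != width)
      stop(sprintf("parse error: row %d has %d fields, expected %d",
                   i + 1L, length(body[[i]]), width))
  }
  genes <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  vals <- matrix(NA_real_, length(genes), length(samples),
                 dimnames = list(genes, samples))
  for (i in seq_along(body)) {
    raw <- body[[i]][-1]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("parse error: non-numeric value '%s' at gene '%s' (row %d), sample '%s' (column %d)",
                   raw[bad[1]], genes[i], i + 1L, samples[bad[1]], bad[1] + 1L))
    vals[i, ] <- v
  }
  expression_dataset(name, vals, scale = scale)
}

#' Write an expression dataset to TSV
#'
#' Values are serialised at full double precision (17 significant digits) so
#' a write/read round trip reproduces the matrix bitwise. A `# scale:` header
#' line records the expression scale.
#'
#' @param dataset an [expression_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(dataset, path) {
  stopifnot(inherits(dataset, "expression_dataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# scale: ", dataset$scale), con)
  writeLines(paste(c("gene", colnames(dataset$values)), collapse = "\t"), con)
  body <- apply(dataset$values, 1L, function(v)
    paste(formatC(v, digits = 17, format = "g"), collapse = "\t"))
  writeLines(paste(rownames(dataset$values), body, sep = "\t"), con)
  invisible(path)
}

.status_synonyms <- c(
  "pos" = "positive", "positive" = "positive", "+" = "positive", "1" = "positive",
  "neg" = "negative", "negative" = "negative", "-" = "negative", "0" = "negative"
)
.missing_tokens <- c("na", "", "n.d.", "nd", "missing")

.map_status <- function(x, field) {
  x <- trimws(tolower(as.character(x)))
  out <- rep(NA_character_, length(x))
  miss <- is.na(x) | x %in% .missing_tokens
  known <- !miss & x %in% names(.status_synonyms)
  out[known] <- .status_synonyms[x[known]]
  bad <- !miss & !known
  if (any(bad))
    stop(sprintf("unknown %s status token(s): %s", field,
                 paste(unique(x[bad]), collapse = ", ")))
  out
}

#' Read a per-sample clinical annotation table from TSV
#'
#' The file must have a header including `sample`; recognised further
#' columns are `er`, `pr`, `her2`, `subtype`, `surv_time`, `surv_event` (any
#' subset may be absent). Receptor statuses accept the synonyms
#' `pos/neg`, `+/-`, `1/0`, `positive/negative` case-insensitively; `NA`,
#' `n.d.` and empty cells are missing.
#'
#' @param path path to the tab-separated file.
#' @return A [clinical_table()].
#' @export
read_clinical_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL)
  if (!"sample" %in% names(raw))
    stop("clinical table must have a 'sample' column")
  known <- c("sample", "er", "pr", "her2", "subtype", "surv_time", "surv_event")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown clinical column(s): ", paste(extra, collapse = ", "))
  get <- function(col) if (col %in% names(raw)) raw[[col]] else NA
  num <- function(col) {
    if (!col %in% names(raw)) return(NA_real_)
    x <- trimws(raw[[col]])
    x[tolower(x) %in% .missing_tokens] <- NA
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric %s value '%s' for sample '%s'",
                   col, x[bad[1]], raw$sample[bad[1]]))
    v
  }
  subtype <- if ("subtype" %in% names(raw)) {
    s <- trimws(raw$subtype)
    s[tolower(s) %in% .missing_tokens] <- NA
    s
  } else NA_character_
  clinical_table(
    sample = raw$sample,
    er = .map_status(get("er"), "er"),
    pr = .map_status(get("pr"), "pr"),
    her2 = .map_status(get("her2"), "her2"),
    subtype = subtype,
    surv_time = num("surv_time"),
    surv_event = as.integer(num("surv_event"))
  )
}

#' Write a clinical table to TSV
#'
#' @param clinical a [clinical_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(clinical, path) {
  stopifnot(inherits(clinical, "clinical_table"))
  out <- as.data.frame(clinical)
  out$surv_time <- ifelse(is.na(out$surv_time), NA,
                          formatC(out$surv_time, digits = 17, format = "g"))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: term id, description, then member genes, tab-separated.
#'
#' @param path path to the GMT file.
#' @return An object of class `gene_set_collection`: a list with `sets`
#'   (named list of character vectors) and `descriptions` (named character).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(sprintf("parse error: GMT line %d has %d field(s), need at least 3 (term, description, genes)",
                 short[1], length(fields[[short[1]]])))
  terms <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(terms))
    stop("duplicate term id(s): ",
         paste(unique(terms[duplicated(terms)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- terms
  descriptions <- vapply(fields, `[[`, character(1), 2L)
  names(descriptions) <- terms
  structure(list(sets = sets, descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("Gene set collection: %d terms, set sizes %d-%d\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' Drop cohorts below the minimum sample size
#'
#' Mirrors the study inclusion rule that excluded datasets with fewer than
#' 100 tumour samples. Order of the retained cohorts is preserved and each
#' exclusion is reported via `message()`.
#'
#' @param datasets list of [expression_dataset()] objects.
#' @param config a [run_config()]; `min_dataset_size` is the threshold.
#' @return The retained datasets, in input order.
#' @export
filter_datasets <- function(datasets, config = run_config()) {
  stopifnot(is.list(datasets),
            all(vapply(datasets, inherits, logical(1), "expression_dataset")))
  sizes <- vapply(datasets, function(d) ncol(d$values), integer(1))
  keep <- sizes >= config$min_dataset_size
  for (i in which(!keep))
    message(sprintf("excluding dataset '%s': %d samples < minimum %d",
                    datasets[[i]]$name, sizes[i], config$min_dataset_size))
  if (!any(keep))
    stop("no dataset meets the minimum sample size (",
         config$min_dataset_size, "); lower `min_dataset_size`")
  datasets[keep]
}
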