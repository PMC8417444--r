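# Gene-set over-representation: one-sided Fisher exact (hypergeometric
# upper tail) per term, BH FDR across terms.

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement, mapped back to the
#' input order.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(pvalues, method = "BH")
}

#' Gene-set over-representation by Fisher's exact test
#'
#' For each term, tests over-representation of the query genes among the
#' term's genes within the universe using the hypergeometric upper tail
#' (equivalently a one-sided Fisher exact test on the 2x2 table). Term sets
#' are intersected with the universe first; terms left empty are dropped.
#' The odds ratio is computed from the 2x2 table, with a 0.5 continuity
#' correction applied when any cell is zero. BH FDR is applied across the
#' tested terms.
#'
#' @param query character vector of genes of interest; must be a subset of
#'   `universe`.
#' @param collection a [read_gmt()] `gene_set_collection` (or a named list
#'   of character vectors).
#' @param universe character vector: all genes eligible to be in `query`.
#' @return A data frame of class `enrichment_result` with columns `term,
#'   description, k, K, n, N, odds_ratio, p, q`, ordered by p-value. `k` is
#'   the query/term overlap, `K` the term size in the universe, `n` the
#'   query size and `N` the universe size.
#' @examples
#' sets <- list(sets = list(T1 = paste0("g", 1:5)),
#'              descriptions = c(T1 = "toy"))
#' class(sets) <- "gene_set_collection"
#' fisher_enrichment(paste0("g", 1:4), sets, paste0("g", 1:20))
#' @export
fisher_enrichment <- function(query, collection, universe) {
  if (inherits(collection, "gene_set_collection")) {
    sets <- collection$sets
    desc <- collection$descriptions
  } else {
    sets <- collection
    desc <- stats::setNames(rep(NA_character_, length(sets)), names(sets))
  }
  universe <- unique(universe)
  query <- unique(query)
  if (length(universe) == 0L) stop("empty universe")
  if (length(query) == 0L) stop("empty query")
  if (!all(query %in% universe))
    stop("query contains genes outside the universe: ",
         paste(utils::head(setdiff(query, universe), 5L), collapse = ", "))
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(term) {
    tset <- intersect(sets[[term]], universe)
    K <- length(tset)
    if (K == 0L) return(NULL)
    k <- length(intersect(query, tset))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    a <- k; b <- K - k; cc <- n - k; d <- N - K - n + k
    if (min(a, b, cc, d) == 0) { a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5 }
    data.frame(term = term, description = unname(desc[term]),
               k = k, K = K, n = n, N = N,
               odds_ratio = (a * d) / (b * cc), p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    stop("no term overlaps the universe")
  res <- do.call(rbind, rows)
  res$q <- bh_fdr(res$p)
  res <- res[order(res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("enrichment_result", "data.frame"))
}

#' Write enrichment results to TSV, with a significance flag
#'
#' @param result an `enrichment_result` data frame.
#' @param path output path.
#' @param q_cutoff FDR threshold for the `significant` flag column.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(result, path, q_cutoff = 0.05) {
  out <- as.data.frame(result)
  out$significant <- out$q < q_cutoff
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
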