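# Cross-cohort aggregation: the sign-consistency vote filter. A gene is
# retained when it is significantly correlated with a consistent sign in at
# least `min_votes` cohorts, with conflicting-sign cohorts penalising the
# count.

#' Aggregate per-cohort correlation records into vote-filtered gene calls
#'
#' For each gene, counts the cohorts where it was significantly (p < alpha)
#' positively or negatively correlated with the target. Under the default
#' `"cancel"` penalty each conflicting-sign cohort cancels one supporting
#' cohort: `net_votes = |n_sig_pos - n_sig_neg|`, the consensus sign is the
#' majority sign (ties give no consensus), and a gene passes when
#' `net_votes >= min_votes`. Under `"strict"` any conflicting cohort
#' disqualifies the gene. Genes absent from a cohort (unmeasured or skipped
#' there) simply contribute no vote; genes measured in fewer than
#' `min_votes` cohorts can never pass but are reported with
#' `passes = FALSE` for auditability.
#'
#' @param records one `correlation_records` data frame or a list of them
#'   (one per cohort), all computed against the same target. Two records for
#'   one gene from the same cohort are an error.
#' @param config a [run_config()]; uses `alpha`, `min_votes`, `vote_penalty`.
#' @return A data frame of class `meta_calls` with columns `gene,
#'   n_datasets_tested, n_sig_pos, n_sig_neg, net_votes, consensus_sign,
#'   passes`, ordered by gene identifier.
#' @export
aggregate_votes <- function(records, config = run_config()) {
  if (is.data.frame(records)) records <- list(records)
  recs <- do.call(rbind, lapply(records, as.data.frame))
  need <- c("gene", "dataset", "r", "p")
  if (!all(need %in% names(recs)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  dup <- duplicated(recs[c("gene", "dataset")])
  if (any(dup))
    stop("multiple records for gene(s) ",
         paste(unique(recs$gene[dup]), collapse = ", "),
         " within one dataset")
  sig <- recs$p < config$alpha
  gene <- factor(recs$gene, levels = sort(unique(recs$gene)))
  tested <- as.integer(table(gene))
  pos <- as.integer(tapply(sig & recs$r > 0, gene, sum))
  neg <- as.integer(tapply(sig & recs$r < 0, gene, sum))
  net <- abs(pos - neg)
  consensus <- ifelse(pos > neg, "+", ifelse(neg > pos, "-", "none"))
  passes <- consensus != "none" & net >= config$min_votes
  if (config$vote_penalty == "strict")
    passes <- passes & (pos == 0L | neg == 0L)
  calls <- data.frame(gene = levels(gene),
                      n_datasets_tested = tested,
                      n_sig_pos = pos, n_sig_neg = neg,
                      net_votes = net, consensus_sign = consensus,
                      passes = passes, stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  structure(calls, class = c("meta_calls", "data.frame"),
            alpha = config$alpha, min_votes = config$min_votes,
            vote_penalty = config$vote_penalty,
            n_datasets = length(unique(recs$dataset)))
}

#' @export
print.meta_calls <- function(x, ...) {
  cat(sprintf(
    "Vote-filtered gene calls: %d genes over %d dataset(s); alpha = %g, min_votes = %d (%s penalty)\n",
    nrow(x), attr(x, "n_datasets"), attr(x, "alpha"),
    attr(x, "min_votes"), attr(x, "vote_penalty")))
  cat(sprintf("  passing: %d (+: %d, -: %d)\n", sum(x$passes),
              sum(x$passes & x$consensus_sign == "+"),
              sum(x$passes & x$consensus_sign == "-")))
  invisible(x)
}

#' @export
summary.meta_calls <- function(object, ...) {
  print(object)
  cat("Net-vote distribution among passing genes:\n")
  print(table(object$net_votes[object$passes]))
  invisible(object)
}

#' Split passing vote-filtered calls into signed gene lists
#'
#' Partitions the genes that pass the vote filter by consensus sign; the two
#' sets are disjoint and their union is exactly the passing genes.
#'
#' @param calls a `meta_calls` data frame from [aggregate_votes()].
#' @return A list of class `signed_gene_list` with character vectors `pos`
#'   and `neg`.
#' @export
signed_gene_list <- function(calls) {
  stopifnot(inherits(calls, "meta_calls"))
  structure(
    list(pos = calls$gene[calls$passes & calls$consensus_sign == "+"],
         neg = calls$gene[calls$passes & calls$consensus_sign == "-"]),
    class = "signed_gene_list"
  )
}

#' @export
print.signed_gene_list <- function(x, ...) {
  cat(sprintf("Signed gene list: %d positive, %d negative\n",
              length(x$pos), length(x$neg)))
  invisible(x)
}

#' Write vote-filtered calls to TSV
#'
#' @param calls a `meta_calls` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_meta_calls <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
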