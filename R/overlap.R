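# Signed-list overlap (Venn) statistics. A shared gene is "inverse" when
# its sign with respect to the anchor gene differs from its sign with
# respect to the clinical status; the inverse fraction is the quantity of
# interest for an antagonism signature.

#' Build an overlap summary from raw Venn counts
#'
#' Constructor used both by [classify_overlap()] and directly when the
#' counts come from an external table. `n_concordant` defaults to
#' `n_shared - n_inverse_ap_sn - n_inverse_an_sp`.
#'
#' @param n_anchor_pos,n_anchor_neg signed totals of the anchor-correlated
#'   list.
#' @param n_status_pos,n_status_neg signed totals of the status-correlated
#'   list.
#' @param n_shared genes present in both lists.
#' @param n_inverse_ap_sn shared genes positive to the anchor, negative to
#'   the status.
#' @param n_inverse_an_sp shared genes negative to the anchor, positive to
#'   the status.
#' @param n_concordant shared genes with equal signs in both lists.
#' @return An object of class `overlap_summary` (counts only; add
#'   percentages with [summarize_overlap()]).
#' @export
overlap_counts <- function(n_anchor_pos, n_anchor_neg,
                           n_status_pos, n_status_neg,
                           n_shared, n_inverse_ap_sn, n_inverse_an_sp,
                           n_concordant = n_shared - n_inverse_ap_sn - n_inverse_an_sp) {
  cnt <- list(n_anchor = n_anchor_pos + n_anchor_neg,
              n_anchor_pos = n_anchor_pos, n_anchor_neg = n_anchor_neg,
              n_status = n_status_pos + n_status_neg,
              n_status_pos = n_status_pos, n_status_neg = n_status_neg,
              n_shared = n_shared,
              n_inverse_ap_sn = n_inverse_ap_sn,
              n_inverse_an_sp = n_inverse_an_sp,
              n_concordant = n_concordant)
  if (any(vapply(cnt, function(v) v < 0 || v != round(v), logical(1))))
    stop("counts must be non-negative integers")
  if (cnt$n_shared != cnt$n_inverse_ap_sn + cnt$n_inverse_an_sp + cnt$n_concordant)
    stop("count conservation violated: shared != inverse classes + concordant")
  if (cnt$n_shared > min(cnt$n_anchor, cnt$n_status))
    stop("shared count exceeds a list total")
  structure(cnt, class = "overlap_summary")
}

#' Classify the overlap between two signed gene lists
#'
#' Intersects the anchor-correlated and status-correlated signed lists and
#' classifies every shared gene as inverse (opposite signs in the two lists)
#' or concordant (same sign).
#'
#' @param anchor_list,status_list [signed_gene_list()] objects (or plain
#'   lists with disjoint character vectors `pos` and `neg`).
#' @return An `overlap_summary` with counts and, as attributes, the gene
#'   identifiers in each shared class (`genes_inverse_ap_sn`,
#'   `genes_inverse_an_sp`, `genes_concordant`).
#' @export
classify_overlap <- function(anchor_list, status_list) {
  for (lst in list(anchor_list, status_list)) {
    if (!all(c("pos", "neg") %in% names(lst)))
      stop("signed lists need `pos` and `neg` components")
    if (length(intersect(lst$pos, lst$neg)))
      stop("signed sets within one list overlap: ",
           paste(intersect(lst$pos, lst$neg), collapse = ", "))
  }
  ap_sn <- intersect(anchor_list$pos, status_list$neg)
  an_sp <- intersect(anchor_list$neg, status_list$pos)
  conc <- c(intersect(anchor_list$pos, status_list$pos),
            intersect(anchor_list$neg, status_list$neg))
  out <- overlap_counts(
    n_anchor_pos = length(anchor_list$pos),
    n_anchor_neg = length(anchor_list$neg),
    n_status_pos = length(status_list$pos),
    n_status_neg = length(status_list$neg),
    n_shared = length(ap_sn) + length(an_sp) + length(conc),
    n_inverse_ap_sn = length(ap_sn),
    n_inverse_an_sp = length(an_sp),
    n_concordant = length(conc)
  )
  attr(out, "genes_inverse_ap_sn") <- ap_sn
  attr(out, "genes_inverse_an_sp") <- an_sp
  attr(out, "genes_concordant") <- conc
  out
}

#' Add overlap percentages to an overlap summary
#'
#' Percentages are computed at full precision on the 0-100 scale:
#' the inverse fraction of the shared genes and of each full list, and each
#' inverse class as a fraction of the shared genes and of its own signed
#' list totals. When `n_shared` is 0 the shared-based percentages are
#' undefined and reported as `NA`, not 0.
#'
#' @param counts an `overlap_summary` from [classify_overlap()] or
#'   [overlap_counts()].
#' @return The summary with percentage fields added (`pct_*`).
#' @export
summarize_overlap <- function(counts) {
  stopifnot(inherits(counts, "overlap_summary"))
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  inv <- counts$n_inverse_ap_sn + counts$n_inverse_an_sp
  counts$pct_inverse_of_shared <- pct(inv, counts$n_shared)
  counts$pct_concordant_of_shared <- pct(counts$n_concordant, counts$n_shared)
  counts$pct_ap_sn_of_shared <- pct(counts$n_inverse_ap_sn, counts$n_shared)
  counts$pct_an_sp_of_shared <- pct(counts$n_inverse_an_sp, counts$n_shared)
  counts$pct_inverse_of_anchor <- pct(inv, counts$n_anchor)
  counts$pct_inverse_of_status <- pct(inv, counts$n_status)
  counts$pct_ap_sn_of_anchor_pos <- pct(counts$n_inverse_ap_sn, counts$n_anchor_pos)
  counts$pct_ap_sn_of_status_neg <- pct(counts$n_inverse_ap_sn, counts$n_status_neg)
  counts$pct_an_sp_of_anchor_neg <- pct(counts$n_inverse_an_sp, counts$n_anchor_neg)
  counts$pct_an_sp_of_status_pos <- pct(counts$n_inverse_an_sp, counts$n_status_pos)
  counts
}

#' @export
print.overlap_summary <- function(x, digits = 2, ...) {
  cat("Signed-list overlap summary\n")
  cat(sprintf("  anchor list:  %d genes (+: %d, -: %d)\n",
              x$n_anchor, x$n_anchor_pos, x$n_anchor_neg))
  cat(sprintf("  status list:  %d genes (+: %d, -: %d)\n",
              x$n_status, x$n_status_pos, x$n_status_neg))
  cat(sprintf("  shared:       %d  (anchor+/status-: %d, anchor-/status+: %d, concordant: %d)\n",
              x$n_shared, x$n_inverse_ap_sn, x$n_inverse_an_sp, x$n_concordant))
  if (!is.null(x$pct_inverse_of_shared)) {
    fmt <- function(v) if (is.na(v)) "NA" else formatC(v, digits = digits, format = "f")
    cat(sprintf("  inverse: %s%% of shared (%s%% / %s%% by class), %s%% of anchor list, %s%% of status list\n",
                fmt(x$pct_inverse_of_shared), fmt(x$pct_ap_sn_of_shared),
                fmt(x$pct_an_sp_of_shared), fmt(x$pct_inverse_of_anchor),
                fmt(x$pct_inverse_of_status)))
    cat(sprintf("  anchor+/status- class: %s%% of anchor+, %s%% of status-\n",
                fmt(x$pct_ap_sn_of_anchor_pos), fmt(x$pct_ap_sn_of_status_neg)))
    cat(sprintf("  anchor-/status+ class: %s%% of anchor-, %s%% of status+\n",
                fmt(x$pct_an_sp_of_anchor_neg), fmt(x$pct_an_sp_of_status_pos)))
  }
  invisible(x)
}

#' Serialise an overlap summary
#'
#' Writes the counts and percentages as JSON (round-trippable) and, when
#' `tsv` is given, as a two-column TSV; returns the human-readable report
#' lines. Percentages are rendered at both 1 and 2 decimals in the report.
#'
#' @param summary an `overlap_summary`, usually from [summarize_overlap()].
#' @param json,tsv optional output paths.
#' @return Character vector of report lines, invisibly.
#' @export
venn_report <- function(summary, json = NULL, tsv = NULL) {
  stopifnot(inherits(summary, "overlap_summary"))
  vals <- unclass(summary)
  if (!is.null(json))
    jsonlite::write_json(vals, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  if (!is.null(tsv)) {
    df <- data.frame(field = names(vals),
                     value = vapply(vals, function(v)
                       formatC(v, digits = 15, format = "g"), character(1)))
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  lines <- c(
    sprintf("anchor list total\t%d", vals$n_anchor),
    sprintf("anchor list split\t+%d / -%d", vals$n_anchor_pos, vals$n_anchor_neg),
    sprintf("status list total\t%d", vals$n_status),
    sprintf("status list split\t+%d / -%d", vals$n_status_pos, vals$n_status_neg),
    sprintf("shared genes\t%d", vals$n_shared),
    sprintf("inverse anchor+/status-\t%d", vals$n_inverse_ap_sn),
    sprintf("inverse anchor-/status+\t%d", vals$n_inverse_an_sp),
    sprintf("concordant\t%d", vals$n_concordant)
  )
  pcts <- vals[startsWith(names(vals), "pct_")]
  for (nm in names(pcts)) {
    v <- pcts[[nm]]
    lines <- c(lines, sprintf("%s\t%s\t%s", nm,
                              ifelse(is.na(v), "NA", formatC(v, digits = 1, format = "f")),
                              ifelse(is.na(v), "NA", formatC(v, digits = 2, format = "f"))))
  }
  invisible(lines)
}
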