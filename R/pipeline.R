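# End-to-end orchestration: size filter -> log2 -> per-cohort correlations
# (anchor gene and binary status) -> vote aggregation per target -> signed
# lists -> overlap -> optional enrichment -> optional survival analyses.

#' Run the full cross-cohort antagonism analysis
#'
#' Executes, deterministically given the inputs and configuration: the
#' cohort size filter, log2 transformation, per-cohort correlation of every
#' gene with the anchor gene and with the binary status, the K-of-D vote
#' filter for each target separately, the signed-list overlap, Fisher/FDR
#' enrichment of each signed list (when `gene_sets` is supplied; the
#' universe is every gene tested in at least one cohort), and, when survival
#' columns are present, a per-cohort Kaplan scan on the anchor (and on
#' `second_gene` if given) followed by the 4-group combined-track logrank
#' with pairwise comparisons.
#'
#' @param datasets list of [expression_dataset()] objects with clinical
#'   tables attached.
#' @param anchor anchor gene identifier. Cohorts lacking the anchor are
#'   skipped for the anchor analysis with a warning; if no cohort has it,
#'   an error.
#' @param status_field binary clinical status to correlate against.
#' @param config a [run_config()].
#' @param gene_sets optional `gene_set_collection` for enrichment.
#' @param second_gene optional gene whose Kaplan-scan track is crossed with
#'   the anchor's for the 4-group survival analysis.
#' @param out_dir optional directory; when given, all intermediates are
#'   written there as TSV/JSON.
#' @return An object of class `corvote_report`.
#' @export
run_pipeline <- function(datasets, anchor, status_field = "er",
                         config = run_config(), gene_sets = NULL,
                         second_gene = NULL, out_dir = NULL) {
  datasets <- filter_datasets(datasets, config)
  datasets <- lapply(datasets, .prepare_scale, config = config)
  have_anchor <- vapply(datasets, function(d)
    anchor %in% rownames(d$values), logical(1))
  if (!any(have_anchor))
    stop("anchor gene '", anchor, "' absent from every dataset")
  for (d in datasets[!have_anchor])
    warning("anchor gene '", anchor, "' absent from dataset '", d$name,
            "'; skipped for the anchor analysis")
  anchor_recs <- lapply(datasets[have_anchor], correlate_anchor_gene,
                        anchor = anchor, config = config)
  status_recs <- lapply(datasets, correlate_binary_status,
                        status_field = status_field, config = config)
  anchor_calls <- aggregate_votes(anchor_recs, config)
  status_calls <- aggregate_votes(status_recs, config)
  anchor_list <- signed_gene_list(anchor_calls)
  status_list <- signed_gene_list(status_calls)
  overlap <- summarize_overlap(classify_overlap(anchor_list, status_list))

  enrichment <- NULL
  if (!is.null(gene_sets)) {
    universe <- sort(unique(c(anchor_calls$gene, status_calls$gene)))
    enr_one <- function(genes) {
      if (length(genes) == 0L) return(NULL)
      fisher_enrichment(genes, gene_sets, universe)
    }
    enrichment <- list(
      anchor_pos_status_neg = enr_one(attr(overlap, "genes_inverse_ap_sn")),
      anchor_neg_status_pos = enr_one(attr(overlap, "genes_inverse_an_sp"))
    )
  }

  surv <- NULL
  has_surv <- vapply(datasets, function(d)
    !is.null(d$clinical) && any(!is.na(d$clinical$surv_time)), logical(1))
  if (any(has_surv)) {
    surv <- lapply(datasets[has_surv], function(d) {
      keep <- !is.na(d$clinical$surv_time)
      track <- survival_track(d$clinical$surv_time[keep],
                              d$clinical$surv_event[keep],
                              sample = d$clinical$sample[keep])
      one_scan <- function(gene) {
        if (!gene %in% rownames(d$values)) return(NULL)
        ks <- kaplan_scan(d$values[gene, keep], track, config)
        names(ks$groups) <- d$clinical$sample[keep]
        ks
      }
      scan_a <- one_scan(anchor)
      out <- list(dataset = d$name, scan_anchor = scan_a)
      if (!is.null(second_gene)) {
        scan_b <- one_scan(second_gene)
        out$scan_second <- scan_b
        if (!is.null(scan_a) && !is.null(scan_b)) {
          comb <- combine_tracks(scan_a$groups, scan_b$groups,
                                 name_a = anchor, name_b = second_gene)
          ctrack <- survival_track(track$time, track$event,
                                   group = as.character(comb[track$sample]),
                                   sample = track$sample)
          out$four_group <- logrank_test(ctrack)
          out$pairwise <- pairwise_logrank(ctrack)
          out$combined_track <- ctrack
        }
      }
      out
    })
    names(surv) <- vapply(datasets[has_surv], `[[`, character(1), "name")
  }

  report <- structure(list(
    anchor = anchor,
    status_field = status_field,
    datasets = vapply(datasets, `[[`, character(1), "name"),
    correlations = list(anchor = anchor_recs, status = status_recs),
    meta = list(anchor = anchor_calls, status = status_calls),
    signed_lists = list(anchor = anchor_list, status = status_list),
    overlap = overlap,
    enrichment = enrichment,
    survival = surv,
    provenance = list(
      package = "corvote",
      version = as.character(utils::packageVersion("corvote")),
      config = unclass(config),
      r_version = paste(R.version$major, R.version$minor, sep = ".")
    )
  ), class = "corvote_report")
  if (!is.null(out_dir)) .write_report(report, out_dir)
  report
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (tgt in c("anchor", "status")) {
    for (rec in report$correlations[[tgt]])
      write_correlation_records(
        rec, file.path(out_dir, sprintf("correlations_%s_%s.tsv",
                                        rec$dataset[1], tgt)))
    write_meta_calls(report$meta[[tgt]],
                     file.path(out_dir, sprintf("meta_%s.tsv", tgt)))
  }
  venn_report(report$overlap,
              json = file.path(out_dir, "overlap.json"),
              tsv = file.path(out_dir, "overlap.tsv"))
  if (!is.null(report$enrichment)) {
    for (nm in names(report$enrichment))
      if (!is.null(report$enrichment[[nm]]))
        write_enrichment(report$enrichment[[nm]],
                         file.path(out_dir, sprintf("enrichment_%s.tsv", nm)))
  }
  if (!is.null(report$survival)) {
    prof <- do.call(rbind, lapply(report$survival, function(s) {
      if (is.null(s$scan_anchor)) return(NULL)
      data.frame(dataset = s$dataset, cutoff = s$scan_anchor$cutoff,
                 p_raw = s$scan_anchor$p_raw,
                 p_adjusted = s$scan_anchor$p_adjusted)
    }))
    if (!is.null(prof))
      utils::write.table(prof, file.path(out_dir, "kaplan_scan_anchor.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(report$provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.corvote_report <- function(x, ...) {
  cat(sprintf("Cross-cohort antagonism report: anchor '%s' vs %s status over %d cohort(s)\n",
              x$anchor, x$status_field, length(x$datasets)))
  cat(sprintf("  anchor list: %d genes pass (+%d / -%d)\n",
              sum(x$meta$anchor$passes), length(x$signed_lists$anchor$pos),
              length(x$signed_lists$anchor$neg)))
  cat(sprintf("  status list: %d genes pass (+%d / -%d)\n",
              sum(x$meta$status$passes), length(x$signed_lists$status$pos),
              length(x$signed_lists$status$neg)))
  cat(sprintf("  shared: %d, inverse: %s%% of shared\n",
              x$overlap$n_shared,
              ifelse(is.na(x$overlap$pct_inverse_of_shared), "NA",
                     formatC(x$overlap$pct_inverse_of_shared,
                             digits = 2, format = "f"))))
  if (!is.null(x$survival))
    cat(sprintf("  survival analysed in %d cohort(s)\n", length(x$survival)))
  invisible(x)
}

#' @export
summary.corvote_report <- function(object, ...) {
  print(object)
  cat("\nOverlap detail:\n")
  print(object$overlap)
  invisible(object)
}

#' Five-number summary with 1.5 IQR outlier fences
#'
#' Quartiles use linear interpolation (type 7). Outliers are observations
#' outside `[q1 - 1.5 IQR, q3 + 1.5 IQR]`.
#'
#' @param x numeric vector.
#' @return A list with `min, q1, median, q3, max` and the `outliers` values.
#' @export
five_number <- function(x) {
  x <- x[!is.na(x)]
  q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
  iqr <- q[4] - q[2]
  out <- x[x < q[2] - 1.5 * iqr | x > q[4] + 1.5 * iqr]
  list(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
       outliers = out)
}

#' Anchor-gene expression across molecular subtypes, per cohort
#'
#' For every cohort with subtype annotation, tests whether anchor expression
#' differs across subtypes with the Kruskal-Wallis test and Welch's ANOVA
#' (the latter with pairwise Welch t post-hoc contrasts against
#' `reference`), on both the stored scale and, for linear cohorts, after
#' log2 transformation. Per-subtype box-plot statistics (five-number summary
#' with 1.5 IQR outlier flagging) are returned alongside.
#'
#' @param datasets list of [expression_dataset()] with subtype annotation.
#' @param anchor anchor gene identifier.
#' @param config a [run_config()].
#' @param reference subtype used as the post-hoc baseline (default
#'   `"basal"`, falling back to the first subtype present).
#' @return A list of class `subtype_association`: per cohort, the
#'   `kruskal_wallis` and `welch_anova` results plus `boxstats`.
#' @export
subtype_association <- function(datasets, anchor, config = run_config(),
                                reference = "basal") {
  res <- lapply(datasets, function(d) {
    if (!anchor %in% rownames(d$values)) return(NULL)
    if (is.null(d$clinical) || all(is.na(d$clinical$subtype))) return(NULL)
    keep <- !is.na(d$clinical$subtype)
    groups <- d$clinical$subtype[keep]
    if (length(unique(groups)) < 2L)
      stop("dataset '", d$name, "' has fewer than 2 subtypes")
    dl <- .prepare_scale(d, config)
    vals <- dl$values[anchor, keep]
    ref <- if (reference %in% groups) reference else sort(unique(groups))[1]
    list(dataset = d$name,
         kruskal = kruskal_wallis(vals, groups),
         welch = welch_anova(vals, groups, reference = ref),
         boxstats = lapply(split(vals, groups), five_number))
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L)
    stop("no dataset has both the anchor gene and subtype annotation")
  names(res) <- vapply(res, `[[`, character(1), "dataset")
  structure(res, class = "subtype_association")
}

#' @export
print.subtype_association <- function(x, ...) {
  cat("Anchor expression vs molecular subtype:\n")
  for (r in x)
    cat(sprintf("  %s: Kruskal-Wallis p = %.3g; Welch ANOVA p = %.3g\n",
                r$dataset, r$kruskal$p, r$welch$p))
  invisible(x)
}
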