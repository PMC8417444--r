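# Kaplan-Meier estimation, logrank testing, the optimal-expression-cutoff
# ("Kaplan scan") search, and 4-group survival from two combined binary
# high/low expression tracks. KM and the k-group logrank go through the
# survival package; the cutoff scan uses an internal incremental 2-group
# logrank so that scanning all cutoffs stays O(samples x event times).

#' Construct a survival track
#'
#' @param time positive follow-up times.
#' @param event event indicator: 1 = event, 0 = censored.
#' @param group optional group labels.
#' @param sample optional sample identifiers.
#' @return A data frame of class `survival_track`.
#' @export
survival_track <- function(time, event, group = NULL, sample = NULL) {
  if (any(is.na(time)) || any(time <= 0))
    stop("survival times must be positive and non-missing")
  if (!all(event %in% c(0, 1)))
    stop("event indicator must be 0 or 1")
  tr <- data.frame(time = as.numeric(time), event = as.integer(event),
                   stringsAsFactors = FALSE)
  tr$group <- if (is.null(group)) "all" else as.character(group)
  if (!is.null(sample)) tr$sample <- as.character(sample)
  class(tr) <- c("survival_track", "data.frame")
  tr
}

#' Kaplan-Meier product-limit estimate
#'
#' @param track a [survival_track()].
#' @param group optional single group label to restrict to.
#' @return A data frame of class `km_curve` with columns `time, n_risk,
#'   n_event, n_censor, survival` — the right-continuous step function
#'   S(t), with S(0) = 1 implied.
#' @export
km_estimate <- function(track, group = NULL) {
  stopifnot(inherits(track, "survival_track"))
  if (!is.null(group)) {
    track <- track[track$group == group, , drop = FALSE]
    if (nrow(track) == 0L) stop("no samples in group '", group, "'")
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = as.data.frame(track))
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    survival = fit$surv)
  structure(out, class = c("km_curve", "data.frame"),
            group = if (is.null(group)) "all" else group,
            n = nrow(track))
}

#' @export
plot.km_curve <- function(x, xlab = "Time", ylab = "Survival probability",
                          main = NULL, ...) {
  tt <- c(0, rep(x$time, each = 2))
  ss <- c(1, 1, rep(x$survival, each = 2)[-(2 * nrow(x))])
  graphics::plot(tt, ss, type = "l", ylim = c(0, 1),
                 xlab = xlab, ylab = ylab,
                 main = if (is.null(main)) paste("KM curve,", attr(x, "group")) else main,
                 ...)
  invisible(x)
}

#' Logrank test across k groups
#'
#' Standard (unweighted) logrank chi-square with ties pooled at each
#' distinct event time, via [survival::survdiff()].
#'
#' @param track a [survival_track()] with at least 2 non-empty groups and at
#'   least one event.
#' @return A list of class `logrank_test` with `chi2`, `df`, `p` and
#'   per-group sizes.
#' @export
logrank_test <- function(track) {
  stopifnot(inherits(track, "survival_track"))
  groups <- factor(track$group)
  if (nlevels(groups) < 2L) stop("need at least 2 non-empty groups")
  if (sum(track$event) == 0L) stop("no events observed")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                           data = as.data.frame(track))
  df <- nlevels(groups) - 1L
  structure(list(chi2 = unname(sd$chisq), df = df,
                 p = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
                 n = as.integer(table(groups)),
                 groups = levels(groups)),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Logrank test: chi2 = %.4g on %d df, p = %.4g\n",
              x$chi2, x$df, x$p))
  cat("  groups:", paste(sprintf("%s (n=%d)", x$groups, x$n), collapse = ", "), "\n")
  invisible(x)
}

# Incremental 2-group logrank over all admissible expression cutoffs.
# Samples sorted by expression; moving the cutoff up transfers one sample
# from the high group to the low group, so per-event-time risk/event counts
# of the high group are updated in O(#event times).
.logrank_scan <- function(expr, time, event, min_group) {
  n <- length(expr)
  ord <- order(expr)
  expr_s <- expr[ord]; time_s <- time[ord]; event_s <- event[ord]
  ut <- sort(unique(time_s[event_s == 1L]))
  if (length(ut) == 0L) stop("no events observed")
  d_tot <- vapply(ut, function(u) sum(time_s == u & event_s == 1L), numeric(1))
  n_tot <- vapply(ut, function(u) sum(time_s >= u), numeric(1))
  # start with everything in the high group
  n_hi <- n_tot
  d_hi <- d_tot
  ks <- integer(0); chi2s <- numeric(0)
  for (k in seq_len(n - 1L)) {
    # sample ord[k] moves high -> low
    n_hi <- n_hi - (time_s[k] >= ut)
    d_hi <- d_hi - (time_s[k] == ut & event_s[k] == 1L)
    if (k < min_group || (n - k) < min_group) next
    if (expr_s[k] == expr_s[k + 1L]) next  # not a valid cut between distinct values
    keep <- n_tot > 1
    O <- sum(d_hi)
    E <- sum(d_tot * n_hi / n_tot)
    V <- sum((d_tot * (n_hi / n_tot) * (1 - n_hi / n_tot) *
                (n_tot - d_tot) / (n_tot - 1))[keep])
    chi2 <- if (V > 0) (O - E)^2 / V else 0
    ks <- c(ks, k); chi2s <- c(chi2s, chi2)
  }
  if (length(ks) == 0L)
    stop("no valid cutoff: expression constant or too few samples per side")
  cutoffs <- (expr_s[ks] + expr_s[ks + 1L]) / 2
  p <- stats::pchisq(chi2s, 1L, lower.tail = FALSE)
  data.frame(cutoff = cutoffs, n_low = ks, n_high = n - ks,
             chi2 = chi2s, p = p)
}

#' Optimal expression cutoff by logrank scanning ("Kaplan scan")
#'
#' Scans every cut between consecutive distinct sorted expression values
#' that leaves at least `kaplan_min_group` samples on each side, computes
#' the 2-group logrank p-value for each split, and returns the split with
#' the minimal p (ties broken toward the more balanced split). Because the
#' minimum over many tests is anti-conservative, a Bonferroni-style adjusted
#' p (`p_raw` times the number of scanned cutoffs, capped at 1) is reported
#' alongside the raw minimum.
#'
#' @param expression numeric vector of per-sample expression values.
#' @param track a [survival_track()] for the same samples, in the same
#'   order.
#' @param config a [run_config()]; `kaplan_min_group` bounds the group
#'   sizes.
#' @return An object of class `kaplan_scan`: `cutoff`, `n_low`, `n_high`,
#'   `logrank_chi2`, `p_raw`, `p_adjusted`, `n_cutoffs`, the full `profile`
#'   data frame, and a `groups` factor (`"low"`/`"high"`) for downstream
#'   use.
#' @export
kaplan_scan <- function(expression, track, config = run_config()) {
  stopifnot(inherits(track, "survival_track"))
  if (length(expression) != nrow(track))
    stop("expression vector and survival track differ in length")
  ok <- !is.na(expression)
  expression <- expression[ok]
  track <- track[ok, , drop = FALSE]
  if (length(unique(expression)) < 2L)
    stop("no valid cutoff: expression is constant")
  if (length(expression) < 2L * config$kaplan_min_group)
    stop("need at least 2 * kaplan_min_group samples with survival data")
  prof <- .logrank_scan(expression, track$time, track$event,
                        config$kaplan_min_group)
  best_p <- min(prof$p)
  cand <- which(prof$p == best_p)
  if (length(cand) > 1L)
    cand <- cand[which.min(abs(prof$n_high[cand] - prof$n_low[cand]))]
  best <- prof[cand, ]
  groups <- factor(ifelse(expression > best$cutoff, "high", "low"),
                   levels = c("low", "high"))
  structure(list(cutoff = best$cutoff,
                 n_low = best$n_low, n_high = best$n_high,
                 logrank_chi2 = best$chi2,
                 p_raw = best$p,
                 p_adjusted = min(1, best$p * nrow(prof)),
                 n_cutoffs = nrow(prof),
                 profile = prof,
                 groups = groups),
            class = "kaplan_scan")
}

#' @export
print.kaplan_scan <- function(x, ...) {
  cat(sprintf("Kaplan scan: optimal cutoff %.4g (low n=%d, high n=%d)\n",
              x$cutoff, x$n_low, x$n_high))
  cat(sprintf("  logrank chi2 = %.4g, raw p = %.4g, adjusted p (x%d cutoffs) = %.4g\n",
              x$logrank_chi2, x$p_raw, x$n_cutoffs, x$p_adjusted))
  invisible(x)
}

#' @export
plot.kaplan_scan <- function(x, ...) {
  graphics::plot(x$profile$cutoff, -log10(x$profile$p), type = "l",
                 xlab = "Expression cutoff", ylab = "-log10 logrank p",
                 main = "Kaplan scan profile", ...)
  graphics::abline(v = x$cutoff, lty = 2)
  invisible(x)
}

#' Combine two binary high/low tracks into a 4-level track
#'
#' Crosses two binary expression tracks (e.g. the high/low groups from two
#' Kaplan scans) into the four combinations. Samples missing from either
#' track are dropped with a message; a track that is constant on the common
#' samples is an error because the combination would degenerate to two
#' groups.
#'
#' @param track_a,track_b named vectors/factors with values `"high"` or
#'   `"low"`; names are sample identifiers.
#' @param name_a,name_b labels used in the combined level names.
#' @return A named factor on the common samples with levels like
#'   `"A-high/B-low"`.
#' @export
combine_tracks <- function(track_a, track_b, name_a = "A", name_b = "B") {
  a <- as.character(track_a); names(a) <- names(track_a)
  b <- as.character(track_b); names(b) <- names(track_b)
  if (is.null(names(a)) || is.null(names(b)))
    stop("tracks must be named by sample identifier")
  if (!all(a %in% c("high", "low")) || !all(b %in% c("high", "low")))
    stop("track values must be 'high' or 'low'")
  common <- intersect(names(a), names(b))
  if (length(common) == 0L) stop("tracks share no samples")
  dropped <- length(union(names(a), names(b))) - length(common)
  if (dropped > 0L)
    message(sprintf("combine_tracks: dropping %d sample(s) missing from one track", dropped))
  a <- a[common]; b <- b[common]
  if (length(unique(a)) < 2L)
    stop("track '", name_a, "' is constant on the common samples")
  if (length(unique(b)) < 2L)
    stop("track '", name_b, "' is constant on the common samples")
  lv <- c(paste0(name_a, "-high/", name_b, "-high"),
          paste0(name_a, "-high/", name_b, "-low"),
          paste0(name_a, "-low/", name_b, "-high"),
          paste0(name_a, "-low/", name_b, "-low"))
  lab <- paste0(name_a, "-", a, "/", name_b, "-", b)
  stats::setNames(factor(lab, levels = lv), common)
}

#' All pairwise logrank comparisons between groups of a track
#'
#' @param track a [survival_track()] with k >= 2 groups.
#' @param p_adjust multiplicity adjustment for the pairwise p-values.
#' @return Data frame with columns `group1, group2, chi2, p, p_adj`.
#' @export
pairwise_logrank <- function(track, p_adjust = "holm") {
  stopifnot(inherits(track, "survival_track"))
  gs <- unique(track$group)
  if (length(gs) < 2L) stop("need at least 2 groups")
  pairs <- utils::combn(gs, 2L)
  res <- apply(pairs, 2L, function(pr) {
    sub <- track[track$group %in% pr, , drop = FALSE]
    lt <- logrank_test(sub)
    data.frame(group1 = pr[1], group2 = pr[2], chi2 = lt$chi2, p = lt$p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adj <- stats::p.adjust(res$p, method = p_adjust)
  rownames(res) <- NULL
  res
}

#' Export a KM curve as TSV
#'
#' @param curve a `km_curve` from [km_estimate()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_km_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
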