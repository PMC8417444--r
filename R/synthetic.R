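# Seeded synthetic multi-cohort generator. Emulates the statistical
# structure the meta-analysis assumes: a binary clinical status, an anchor
# gene elevated in status-negative samples, gene modules coupled positively
# or negatively to the anchor (and hence inversely to the status), subtype
# labels enriched for basal among status-negative tumours, and exponential
# survival whose hazard depends on the anchor-high x status group.

#' Configuration for the synthetic multi-cohort generator
#'
#' Defaults describe the benchmark conditions: 12 cohorts of 100-500
#' samples, 2,000 genes, 70% status-positive samples (the approximate
#' prevalence of ER-positive breast tumours), an anchor gene shifted up by
#' 1.5 log2 units in status-negative samples, and two 100-gene modules
#' coupled to the anchor at |r| = 0.5.
#'
#' @param n_datasets number of cohorts.
#' @param samples_per_dataset integer, or length-2 range to draw cohort
#'   sizes from uniformly.
#' @param n_genes total genes per cohort (modules + background + the anchor
#'   and a status-driven receptor-like gene).
#' @param frac_status_positive expected fraction of status-positive samples.
#' @param anchor_shift mean log2 increase of the anchor gene in
#'   status-negative samples.
#' @param module_sizes length-2 integer vector: genes positively /
#'   negatively coupled to the anchor.
#' @param coupling_strength target |Pearson correlation| of module genes
#'   with the anchor, in (0, 1); 0 plants no coupling.
#' @param noise_sd per-gene Gaussian noise standard deviation on log2 scale.
#' @param baseline_hazard exponential event hazard of the reference
#'   (anchor-low, status-positive) group.
#' @param hazard_multipliers named multipliers for the four anchor x status
#'   groups: `hi_neg`, `hi_pos`, `lo_neg`, `lo_pos`.
#' @param censor_max censoring times are uniform on (0, `censor_max`).
#' @param subtype_confusion probability a sample's subtype disagrees with
#'   its status-driven default (basal for status-negative, luminal/HER2 mix
#'   otherwise).
#' @param seed master seed; each cohort derives a child seed from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_datasets = 12L,
                       samples_per_dataset = c(100L, 500L),
                       n_genes = 2000L,
                       frac_status_positive = 0.7,
                       anchor_shift = 1.5,
                       module_sizes = c(pos = 100L, neg = 100L),
                       coupling_strength = 0.5,
                       noise_sd = 1,
                       baseline_hazard = 0.05,
                       hazard_multipliers = c(hi_neg = 3, hi_pos = 2,
                                              lo_neg = 1.5, lo_pos = 1),
                       censor_max = 40,
                       subtype_confusion = 0.15,
                       seed = 1L) {
  stopifnot(n_datasets >= 1L, n_genes >= 4L,
            frac_status_positive > 0, frac_status_positive < 1,
            noise_sd > 0, baseline_hazard > 0, censor_max > 0,
            subtype_confusion >= 0, subtype_confusion < 1)
  if (coupling_strength < 0 || coupling_strength >= 1)
    stop("infeasible coupling: |correlation| target must lie in [0, 1)")
  if (length(module_sizes) != 2L)
    stop("`module_sizes` must give positive- and negative-module sizes")
  if (sum(module_sizes) + 2L > n_genes)
    stop("module sizes plus anchor and receptor gene exceed n_genes")
  if (length(samples_per_dataset) == 1L)
    samples_per_dataset <- rep(samples_per_dataset, 2L)
  if (!all(c("hi_neg", "hi_pos", "lo_neg", "lo_pos") %in% names(hazard_multipliers)))
    stop("hazard_multipliers needs names hi_neg, hi_pos, lo_neg, lo_pos")
  structure(list(
    n_datasets = as.integer(n_datasets),
    samples_per_dataset = as.integer(samples_per_dataset),
    n_genes = as.integer(n_genes),
    frac_status_positive = frac_status_positive,
    anchor_shift = anchor_shift,
    module_sizes = stats::setNames(as.integer(module_sizes), c("pos", "neg")),
    coupling_strength = coupling_strength,
    noise_sd = noise_sd,
    baseline_hazard = baseline_hazard,
    hazard_multipliers = hazard_multipliers,
    censor_max = censor_max,
    subtype_confusion = subtype_confusion,
    seed = as.integer(seed)
  ), class = "sim_config")
}

.child_seed <- function(seed, i) as.integer((seed * 1009L + i * 7919L) %% 2147483647L)

#' Generate synthetic cohorts with planted antagonistic modules
#'
#' Per cohort (on log2 scale, baseline mean 8): the binary status is drawn
#' with `frac_status_positive`; the anchor gene is Gaussian with a
#' `+anchor_shift` mean in status-negative samples; each module gene is
#' `rho * z + sqrt(1 - rho^2) * noise` around the standardised anchor signal
#' `z` (sign per module), so its expected correlation with the anchor is
#' `+/-rho`; a receptor-like gene `ESR1L` is shifted up in status-positive
#' samples; background genes are independent noise. Positive-module genes
#' therefore correlate positively with the anchor and negatively with the
#' status, and vice versa — the planted antagonism. Subtypes default to
#' basal for status-negative samples and a luminal/HER2 mix otherwise,
#' flipped with probability `subtype_confusion`; the anchor is additionally
#' the highest in basal samples by construction. Survival is exponential
#' with group hazards over (anchor high/low) x status and uniform censoring.
#'
#' @param config a [sim_config()].
#' @return A list with `datasets` (list of [expression_dataset()] with
#'   clinical tables) and `manifest` (class `sim_manifest`): the planted
#'   module memberships and signs, per-cohort seeds and sizes, the anchor
#'   high/low threshold and the hazard table.
#' @examples
#' sim <- generate_cohorts(sim_config(n_datasets = 2,
#'   samples_per_dataset = 60, n_genes = 50,
#'   module_sizes = c(pos = 5, neg = 5), seed = 42))
#' length(sim$datasets)
#' @export
generate_cohorts <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  m_pos <- config$module_sizes[["pos"]]
  m_neg <- config$module_sizes[["neg"]]
  n_bg <- config$n_genes - m_pos - m_neg - 2L
  genes <- c("ANCHOR", "ESR1L",
             if (m_pos) sprintf("MPOS%04d", seq_len(m_pos)),
             if (m_neg) sprintf("MNEG%04d", seq_len(m_neg)),
             if (n_bg) sprintf("BG%05d", seq_len(n_bg)))
  base_mu <- 8
  anchor_threshold <- base_mu + config$anchor_shift / 2
  datasets <- vector("list", config$n_datasets)
  cohort_meta <- vector("list", config$n_datasets)
  for (i in seq_len(config$n_datasets)) {
    cs <- .child_seed(config$seed, i)
    set.seed(cs)
    rng <- config$samples_per_dataset
    n <- if (rng[1] == rng[2]) rng[1] else
      sample(seq(rng[1], rng[2]), 1L)
    # guarantee both status classes are represented
    repeat {
      status_pos <- stats::rbinom(n, 1L, config$frac_status_positive)
      if (sum(status_pos) >= 2L && sum(1L - status_pos) >= 2L) break
    }
    status <- ifelse(status_pos == 1L, "positive", "negative")
    anchor <- base_mu + config$anchor_shift * (status_pos == 0L) +
      stats::rnorm(n, 0, config$noise_sd)
    esr1l <- base_mu + config$anchor_shift * (status_pos == 1L) +
      stats::rnorm(n, 0, config$noise_sd)
    z <- as.numeric(scale(anchor))
    rho <- config$coupling_strength
    module_gene <- function(sign) {
      g <- sign * rho * z + sqrt(1 - rho^2) * stats::rnorm(n)
      base_mu + config$noise_sd * g
    }
    vals <- matrix(NA_real_, length(genes), n,
                   dimnames = list(genes, sprintf("c%02d_s%04d", i, seq_len(n))))
    vals["ANCHOR", ] <- anchor
    vals["ESR1L", ] <- esr1l
    for (j in seq_len(m_pos)) vals[2L + j, ] <- module_gene(+1)
    for (j in seq_len(m_neg)) vals[2L + m_pos + j, ] <- module_gene(-1)
    if (n_bg)
      vals[(2L + m_pos + m_neg + 1L):length(genes), ] <-
        base_mu + config$noise_sd * stats::rnorm(n_bg * n)
    # subtype: basal for status-negative, luminal/HER2 mix otherwise,
    # flipped with probability subtype_confusion
    others <- c("Lum-A", "Lum-B", "Her2")
    flip <- stats::runif(n) < config$subtype_confusion
    subtype <- ifelse(xor(status_pos == 0L, flip), "basal",
                      sample(others, n, replace = TRUE,
                             prob = c(0.45, 0.35, 0.2)))
    # survival: exponential with group hazard, uniform censoring
    anchor_high <- anchor > anchor_threshold
    grp <- paste0(ifelse(anchor_high, "hi", "lo"),
                  "_", ifelse(status_pos == 1L, "pos", "neg"))
    hz <- config$baseline_hazard * config$hazard_multipliers[grp]
    t_event <- stats::rexp(n, rate = hz)
    t_cens <- stats::runif(n, 0, config$censor_max)
    surv_time <- pmin(t_event, t_cens)
    surv_event <- as.integer(t_event <= t_cens)
    pr <- ifelse(stats::runif(n) < 0.1,
                 ifelse(status == "positive", "negative", "positive"), status)
    her2 <- ifelse(stats::runif(n) < 0.2, "positive", "negative")
    clin <- clinical_table(sample = colnames(vals), er = status, pr = pr,
                           her2 = her2, subtype = subtype,
                           surv_time = surv_time, surv_event = surv_event)
    datasets[[i]] <- expression_dataset(sprintf("cohort%02d", i), vals,
                                        scale = "log2", clinical = clin)
    cohort_meta[[i]] <- list(name = sprintf("cohort%02d", i), n = n, seed = cs)
  }
  manifest <- structure(list(
    genes = genes,
    anchor = "ANCHOR",
    receptor_gene = "ESR1L",
    module_pos = genes[seq_len(m_pos) + 2L],
    module_neg = c("ESR1L", genes[seq_len(m_neg) + 2L + m_pos]),
    anchor_threshold = anchor_threshold,
    base_mu = base_mu,
    cohorts = cohort_meta,
    config = config
  ), class = "sim_manifest")
  list(datasets = datasets, manifest = manifest)
}

#' @export
print.sim_manifest <- function(x, ...) {
  cat(sprintf(
    "Synthetic manifest: %d cohorts, %d genes (modules +%d / -%d incl. receptor gene), seed %d\n",
    length(x$cohorts), length(x$genes), length(x$module_pos),
    length(x$module_neg), x$config$seed))
  invisible(x)
}

#' Compare vote-filtered calls against the planted ground truth
#'
#' Scores the passing calls against the planted module memberships:
#' sensitivity (fraction of planted genes passing), specificity (fraction of
#' non-planted genes not passing) and sign accuracy (fraction of passing
#' planted genes whose consensus sign matches the planted sign). For
#' `target = "anchor"` the expected signs are the module signs and the
#' anchor gene itself is outside the call universe; for `target = "status"`
#' the expected signs are flipped (positive-module genes are elevated with
#' the anchor, hence in status-negative samples).
#'
#' @param manifest the `sim_manifest` from [generate_cohorts()].
#' @param calls a `meta_calls` data frame from [aggregate_votes()].
#' @param target `"anchor"` or `"status"`: which correlation target the
#'   calls were computed against.
#' @return A list with `sensitivity`, `specificity`, `sign_accuracy` and the
#'   underlying `confusion` counts.
#' @export
truth_vs_calls <- function(manifest, calls, target = c("anchor", "status")) {
  target <- match.arg(target)
  stopifnot(inherits(manifest, "sim_manifest"), inherits(calls, "meta_calls"))
  expected_universe <- if (target == "anchor")
    setdiff(manifest$genes, manifest$anchor) else manifest$genes
  if (!setequal(calls$gene, expected_universe))
    stop("gene universe mismatch between manifest and calls")
  pos_set <- manifest$module_pos
  neg_set <- manifest$module_neg
  truth_sign <- rep("none", nrow(calls))
  truth_sign[calls$gene %in% pos_set] <- if (target == "anchor") "+" else "-"
  truth_sign[calls$gene %in% neg_set] <- if (target == "anchor") "-" else "+"
  planted <- truth_sign != "none"
  tp <- sum(planted & calls$passes)
  fn <- sum(planted & !calls$passes)
  fp <- sum(!planted & calls$passes)
  tn <- sum(!planted & !calls$passes)
  sign_ok <- sum(planted & calls$passes & calls$consensus_sign == truth_sign)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       sign_accuracy = if (tp > 0) sign_ok / tp else NA_real_,
       confusion = c(tp = tp, fp = fp, fn = fn, tn = tn))
}

#' Write a synthetic run to disk in the standard text formats
#'
#' Writes one expression TSV and one clinical TSV per cohort plus a JSON
#' ground-truth manifest.
#'
#' @param sim the list returned by [generate_cohorts()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohorts <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ds in sim$datasets) {
    write_expression_matrix(ds, file.path(dir, paste0(ds$name, "_expr.tsv")))
    write_clinical_table(ds$clinical, file.path(dir, paste0(ds$name, "_clinical.tsv")))
  }
  man <- sim$manifest
  man$config <- unclass(man$config)
  jsonlite::write_json(unclass(man), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
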