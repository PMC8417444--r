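#' Analysis run configuration
#'
#' Bundles the tuning parameters shared by the pipeline stages. Defaults
#' mirror the published analysis: per-test significance at `alpha = 0.05`,
#' a gene is retained when supported by at least `min_votes = 6` cohorts,
#' and cohorts with fewer than `min_dataset_size = 100` tumour samples are
#' excluded up front.
#'
#' @param alpha per-test significance level, in (0, 1).
#' @param min_votes minimum net number of supporting cohorts (K of the
#'   "K of D" vote filter).
#' @param min_dataset_size minimum samples per cohort; smaller cohorts are
#'   dropped by [filter_datasets()].
#' @param log_transform `"auto"` (log2-transform linear-scale cohorts,
#'   leave log2 cohorts alone), `"force"`, or `"never"`.
#' @param pseudocount non-negative value added before log2 transform of
#'   linear data.
#' @param kaplan_min_group minimum samples on each side of a candidate
#'   Kaplan-scan cutoff.
#' @param vote_penalty `"cancel"`: each conflicting-sign cohort cancels one
#'   supporting cohort (net votes = |pos - neg|); `"strict"`: any
#'   conflicting cohort disqualifies the gene.
#' @param seed integer seed for stochastic operations.
#'
#' @return An object of class `run_config` (a validated list).
#' @examples
#' cfg <- run_config(alpha = 0.05, min_votes = 6)
#' cfg$min_dataset_size
#' @export
run_config <- function(alpha = 0.05,
                       min_votes = 6L,
                       min_dataset_size = 100L,
                       log_transform = c("auto", "force", "never"),
                       pseudocount = 1,
                       kaplan_min_group = 8L,
                       vote_penalty = c("cancel", "strict"),
                       seed = 1L) {
  log_transform <- match.arg(log_transform)
  vote_penalty <- match.arg(vote_penalty)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("`alpha` must be a single value in (0, 1)")
  min_votes <- as.integer(min_votes)
  if (is.na(min_votes) || min_votes < 1L)
    stop("`min_votes` must be a positive integer")
  min_dataset_size <- as.integer(min_dataset_size)
  if (is.na(min_dataset_size) || min_dataset_size < 1L)
    stop("`min_dataset_size` must be a positive integer")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount < 0)
    stop("`pseudocount` must be a single non-negative number")
  kaplan_min_group <- as.integer(kaplan_min_group)
  if (is.na(kaplan_min_group) || kaplan_min_group < 2L)
    stop("`kaplan_min_group` must be an integer >= 2")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("`seed` must be an integer")
  structure(
    list(alpha = alpha, min_votes = min_votes,
         min_dataset_size = min_dataset_size, log_transform = log_transform,
         pseudocount = pseudocount, kaplan_min_group = kaplan_min_group,
         vote_penalty = vote_penalty, seed = seed),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys fall back to the [run_config()]
#' defaults.
#'
#' @param path path to a YAML file whose keys mirror [run_config()] arguments.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop("config file must contain a YAML mapping")
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration:\n")
  for (nm in names(x))
    cat(sprintf("  %-17s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
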