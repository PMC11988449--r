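#' Plan replicate simulations for representative poses
#'
#' One job per (pose, replicate, condition) with a deterministic unique
#' seed, so the screen is reproducible and trivially parallel. The
#' full-scale preset is 20 poses x 3 replicates x 2 force-field
#' conditions = 120 trajectories of 150 ns.
#'
#' @param n_poses number of representative poses.
#' @param n_replicates replicates per condition.
#' @param conditions character vector of condition labels (e.g. force
#'   fields), or a count.
#' @param length trajectory length per job (time units or steps).
#' @param seed root integer seed.
#' @return object of class `screen_plan`: data frame `job`, `pose`,
#'   `replicate`, `condition`, `length`, `seed`.
#' @export
plan_screen <- function(n_poses, n_replicates, conditions, length,
                        seed = 1L) {
  if (is.numeric(conditions) && length(conditions) == 1L)
    conditions <- paste0("cond", seq_len(conditions))
  if (n_poses < 1 || n_replicates < 1 || length(conditions) < 1)
    stopf("all counts must be >= 1")
  jobs <- expand.grid(condition = conditions,
                      replicate = seq_len(n_replicates),
                      pose = seq_len(n_poses),
                      stringsAsFactors = FALSE)[, 3:1]
  jobs <- jobs[order(jobs$pose, jobs$replicate, jobs$condition), ]
  jobs$job <- seq_len(nrow(jobs))
  jobs$length <- length
  jobs$seed <- vapply(jobs$job, function(j)
    child_seed(seed, sprintf("screen-job-%d", j)), 1L)
  rownames(jobs) <- NULL
  structure(jobs[, c("job", "pose", "replicate", "condition", "length",
                     "seed")],
            class = c("screen_plan", "data.frame"))
}

#' Ligand-stability verdict from COM-RMSD traces
#'
#' A replicate passes when its ligand centre-of-mass RMSD stays strictly
#' below `threshold` at every stored frame ("throughout"); a pose passes
#' when at least `min_pass` of its replicates pass. The full-scale rule is
#' a 15 Angstrom threshold with at least 5 of 6 replicates passing.
#' Missing replicates (NULL traces) count as failing, with a warning.
#'
#' @param traces list of numeric COM-RMSD traces (Angstrom), one per
#'   replicate of a single pose.
#' @param threshold COM-RMSD threshold (Angstrom).
#' @param min_pass minimum number of passing replicates.
#' @return object of class `stability_verdict`: `pass` (logical),
#'   `replicate_pass` (logical vector), `max_rmsd` (per replicate),
#'   `threshold`, `min_pass`.
#' @export
stability_filter <- function(traces, threshold = 15, min_pass = 5) {
  if (length(traces) == 0L) stopf("at least one trace is required")
  missing <- vapply(traces, is.null, logical(1))
  if (any(missing))
    warnf("%d missing replicate(s) counted as failing", sum(missing))
  max_rmsd <- vapply(traces, function(tr) {
    if (is.null(tr)) return(Inf)
    if (any(!is.finite(tr))) stopf("traces must be finite")
    max(tr)
  }, numeric(1))
  rep_pass <- max_rmsd < threshold
  structure(list(pass = sum(rep_pass) >= min_pass,
                 replicate_pass = rep_pass, max_rmsd = max_rmsd,
                 threshold = threshold, min_pass = min_pass),
            class = "stability_verdict")
}

#' @export
print.stability_verdict <- function(x, ...) {
  cat(sprintf("stability_verdict: %s (%d/%d replicates < %g A; need >= %d)\n",
              if (x$pass) "PASS" else "FAIL", sum(x$replicate_pass),
              length(x$replicate_pass), x$threshold, x$min_pass))
  invisible(x)
}

#' Contact profiles of poses that survived the stability filter
#'
#' Concatenates each pose's stable replicates into one pooled ensemble,
#' computes per-residue ligand contact frequencies
#' ([contact_frequency()]), and reports the high-contact set (frequency
#' strictly above the configured threshold).
#'
#' @param ensembles named list (one entry per passing pose) of
#'   [conformation_ensemble()]s pooled over that pose's stable replicates.
#' @param ligand_selection ligand atom indices (shared atom table).
#' @param config a [contact_config()].
#' @return list with `tables` (per-pose contact data frames) and
#'   `high_contact` (per-pose data frames of residues above threshold).
#' @export
profile_contacts <- function(ensembles, ligand_selection,
                             config = contact_config()) {
  if (length(ensembles) == 0L) stopf("no passing poses to profile")
  tables <- lapply(ensembles, contact_frequency, ligand_selection, config)
  high <- lapply(tables, function(tb)
    tb[tb$frequency > config$threshold, , drop = FALSE])
  list(tables = tables, high_contact = high)
}

#' Converged ligand displacement from the docked pose
#'
#' Mean and SD of the RMSD-from-docked-pose trace over the final `window`
#' frames, averaged across stable replicates: the "converged pose"
#' displacement after early reorientation.
#'
#' @param traces list of numeric RMSD-from-docked traces (stable
#'   replicates of one pose).
#' @param window number of final frames to average (shorter than each
#'   trace).
#' @return list `mean`, `sd` (Angstrom), `window`.
#' @export
pose_convergence <- function(traces, window) {
  if (any(vapply(traces, length, 1L) <= window))
    stopf("'window' must be shorter than every trace")
  tails <- lapply(traces, function(tr) tr[(length(tr) - window + 1):length(tr)])
  per_rep <- vapply(tails, mean, numeric(1))
  list(mean = mean(per_rep),
       sd = sd(unlist(tails)), window = window)
}
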