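#' Reweighting configuration for ensemble docking
#'
#' @param kT thermal energy in kcal/mol; the default 0.596 corresponds to
#'   the 300 K simulation temperature.
#' @param mode `"effective-free-energy"` ranks by
#'   \eqn{G_i = g_i - kT \ln \hat\pi_i}; `"linear-expectation"` ranks by
#'   the linear population-weighted score \eqn{\hat\pi_i g_i}. Both are
#'   recorded in output metadata.
#' @param top_k poses kept after ranking (100 in the full-scale preset).
#' @return object of class `reweight_config`.
#' @export
reweight_config <- function(kT = 0.596,
                            mode = c("effective-free-energy",
                                     "linear-expectation"),
                            top_k = 100) {
  assert_scalar_num(kT, "kT", positive = TRUE)
  if (top_k < 1) stopf("'top_k' must be >= 1")
  structure(list(kT = kT, mode = match.arg(mode), top_k = as.integer(top_k)),
            class = "reweight_config")
}

#' Reweight docking scores by MSM stationary probabilities
#'
#' Each pose (one best-scored pose per protein conformation) carries a raw
#' docking score `g_i` and maps, through its conformation, to an MSM
#' microstate. The microstate's stationary probability is split uniformly
#' among the poses assigned to it (`pi_share`), so state probability is
#' never double-counted, and the default effective score is
#' \deqn{G_i = g_i - kT \ln \hat\pi_i,}
#' ranked ascending (low = strongly scored *and* thermodynamically
#' accessible). The macroscopic binding constant
#' \eqn{K = \sum_i \hat\pi_i e^{-g_i/kT}} is attached as an attribute.
#' Poses whose state falls outside the model's active set (or has zero
#' probability) are dropped with a warning.
#'
#' @param poses data frame with columns `conformation`, `state` (microstate
#'   label in the original state numbering) and `score` (kcal/mol).
#' @param model a `markov_model` (see [build_msm()]).
#' @param config a [reweight_config()].
#' @return `ranked_poses` data frame (`conformation`, `state`, `score`,
#'   `pi_share`, `effective`, `rank`), best first, with attributes
#'   `K` and `mode`.
#' @export
reweight_poses <- function(poses, model, config = reweight_config()) {
  need <- c("conformation", "state", "score")
  if (!all(need %in% names(poses)))
    stopf("'poses' must contain columns %s", paste(need, collapse = ", "))
  if (any(!is.finite(poses$score))) stopf("scores must be finite")
  pos <- match(poses$state, model$active_set)
  ok <- !is.na(pos) & model$pi[ifelse(is.na(pos), 1L, pos)] > 0
  if (!all(ok)) {
    warnf("%d pose(s) outside the active set or in zero-probability states; dropped",
          sum(!ok))
    poses <- poses[ok, , drop = FALSE]
    pos <- pos[ok]
  }
  if (nrow(poses) == 0L) stopf("no pose maps to the active set")
  n_in_state <- table(pos)
  pi_share <- model$pi[pos] / as.numeric(n_in_state[as.character(pos)])
  effective <- switch(config$mode,
    "effective-free-energy" = poses$score - config$kT * log(pi_share),
    "linear-expectation" = pi_share * poses$score)
  out <- data.frame(conformation = poses$conformation, state = poses$state,
                    score = poses$score, pi_share = pi_share,
                    effective = effective)
  ord <- order(out$effective, out$score, out$conformation)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "K") <- sum(pi_share * exp(-poses$score / config$kT))
  attr(out, "mode") <- config$mode
  class(out) <- c("ranked_poses", class(out))
  out
}

#' Keep the K best reweighted poses
#'
#' @param ranked a [reweight_poses()] table.
#' @param K number of poses to keep; if `K` exceeds the pose count, all
#'   poses are returned with a warning.
#' @return the top rows, re-ranked 1..K.
#' @export
select_top <- function(ranked, K) {
  if (K > nrow(ranked)) {
    warnf("K = %d exceeds pose count %d; returning all", K, nrow(ranked))
    K <- nrow(ranked)
  }
  out <- ranked[seq_len(K), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# symmetric ligand-RMSD matrix between poses (shared atom correspondence,
# shared receptor frame -> no superposition)
pose_rmsd_matrix <- function(coords) {
  n <- length(coords)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- coords[[i]] - coords[[j]]
    D[i, j] <- D[j, i] <- sqrt(mean(rowSums(d^2)))
  }
  D
}

#' Quality-threshold clustering of ligand poses by RMSD
#'
#' Repeatedly takes the pose with the most neighbours within `cutoff`
#' ligand-atom RMSD as a cluster representative, removes the cluster, and
#' repeats until no pose remains. Deterministic: ties go to the lowest
#' pose id. Every member lies within `cutoff` of its representative and
#' clusters are disjoint. The full-scale preset clusters the 100 best
#' poses at 2.5 Angstrom.
#'
#' @param coords list of ligand coordinate matrices (identical atom
#'   ordering across poses), one per pose.
#' @param cutoff RMSD cutoff (Angstrom).
#' @param ids optional pose identifiers (default `1:n`).
#' @return object of class `pose_clusters`: list with `clusters` (each
#'   `representative`, `members`), `cutoff`; ordered by decreasing size.
#' @export
cluster_poses <- function(coords, cutoff = 2.5, ids = NULL) {
  if (length(coords) == 0L) stopf("at least one pose is required")
  ids <- ids %||% seq_along(coords)
  D <- pose_rmsd_matrix(coords)
  remaining <- seq_along(coords)
  clusters <- list()
  while (length(remaining) > 0L) {
    sub <- D[remaining, remaining, drop = FALSE]
    nn <- rowSums(sub <= cutoff) # self included; constant offset
    pick <- remaining[which.max(nn)] # which.max takes first (lowest id) tie
    members <- remaining[sub[match(pick, remaining), ] <= cutoff]
    clusters[[length(clusters) + 1]] <-
      list(representative = ids[pick], members = ids[members],
           size = length(members))
    remaining <- setdiff(remaining, members)
  }
  sizes <- vapply(clusters, `[[`, 1, "size")
  reps <- vapply(clusters, function(cl) cl$representative[1], ids[1])
  clusters <- clusters[order(-sizes, reps)]
  structure(list(clusters = clusters, cutoff = cutoff),
            class = "pose_clusters")
}

#' @export
print.pose_clusters <- function(x, ...) {
  cat(sprintf("pose_clusters: %d cluster(s) at %.2f A cutoff; sizes %s\n",
              length(x$clusters), x$cutoff,
              paste(vapply(x$clusters, `[[`, 1, "size"), collapse = ", ")))
  invisible(x)
}

#' Representative poses for downstream simulation
#'
#' Up to `n_max` cluster representatives, largest clusters first (20 in
#' the full-scale preset).
#'
#' @param clusters a [cluster_poses()] result.
#' @param n_max maximum representatives (>= 1).
#' @return vector of representative pose ids.
#' @export
representative_poses <- function(clusters, n_max = 20) {
  if (n_max < 1) stopf("'n_max' must be >= 1")
  reps <- vapply(clusters$clusters, function(cl) cl$representative[1],
                 clusters$clusters[[1]]$representative[1])
  head(reps, n_max)
}

#' Emit a docking grid-box specification
#'
#' Written as a JSON artifact for external docking engines; the
#' full-scale preset uses a 24 x 22 x 25 Angstrom box at the candidate
#' site.
#'
#' @param center box centre (length 3, Angstrom).
#' @param dims box edge lengths (length 3, Angstrom).
#' @param file output JSON path.
#' @return `file`, invisibly.
#' @export
write_grid_box <- function(center, dims = c(24, 22, 25), file) {
  if (length(center) != 3L || length(dims) != 3L)
    stopf("'center' and 'dims' must have length 3")
  jsonlite::write_json(list(center = center, dims = dims), file,
                       auto_unbox = FALSE, digits = NA)
  invisible(file)
}
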