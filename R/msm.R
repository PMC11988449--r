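#' Discretize feature space into microstates by k-means
#'
#' k-means++ seeding followed by Lloyd iterations (via [stats::kmeans()]),
#' repeated over `restarts` initializations with the lowest within-cluster
#' sum of squares kept. Deterministic for a given seed. The workflow's
#' full-scale preset uses 1000 microstates; toy systems use fewer.
#'
#' @param features numeric matrix (frames x features) or `feature_matrix`.
#' @param k number of microstates (<= frames).
#' @param seed integer seed.
#' @param restarts independent initializations.
#' @return object of class `msm_discretization`: `centers`, `labels`
#'   (per-frame state, 1-based), `k`, `inertia`, `seed`.
#' @export
kmeans_discretize <- function(features, k, seed = 1L, restarts = 10L) {
  X <- unclass(rbind(features))
  if (k > nrow(X)) stopf("k (%d) exceeds number of frames (%d)", k, nrow(X))
  best <- NULL
  with_seed(as.integer(seed), {
    for (r in seq_len(restarts)) {
      init <- kmeanspp_init(X, k)
      km <- suppressWarnings(
        stats::kmeans(X, centers = init, iter.max = 100, algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  labels <- assign_to_centers(X, best$centers)
  structure(list(centers = best$centers, labels = labels, k = as.integer(k),
                 inertia = best$tot.withinss, seed = as.integer(seed)),
            class = "msm_discretization")
}

# k-means++ initial centres (uses current RNG stream)
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(X, 2, X[idx[1], ])^2)
  for (j in seq_len(k - 1L)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx[j + 1L] <- sample.int(n, 1L, prob = p)
    d2 <- pmin(d2, rowSums(sweep(X, 2, X[idx[j + 1L], ])^2))
  }
  X[idx, , drop = FALSE]
}

#' Assign frames to the nearest cluster centre
#'
#' @param features numeric matrix (frames x features).
#' @param centers cluster-centre matrix.
#' @return integer state labels (1-based).
#' @export
assign_to_centers <- function(features, centers) {
  X <- unclass(rbind(features))
  d2 <- outer(rowSums(X^2), rowSums(centers^2), `+`) -
    2 * tcrossprod(X, centers)
  max.col(-d2, ties.method = "first")
}

#' Lagged transition counts
#'
#' Sliding-window counting: every ordered pair of frames `(t, t + tau)`
#' within one trajectory contributes one count; counting never crosses
#' trajectory boundaries. Trajectories shorter than `tau + 1` frames are
#' skipped with a warning.
#'
#' @param labels integer state labels (1-based), a vector or a list of
#'   vectors (one per trajectory).
#' @param tau lag in frames (>= 1).
#' @param n_states number of states (default: maximum label).
#' @return `n_states x n_states` count matrix `C[i, j]`.
#' @export
count_transitions <- function(labels, tau, n_states = NULL) {
  if (!is.list(labels)) labels <- list(labels)
  if (tau < 1) stopf("'tau' must be >= 1")
  n <- n_states %||% max(unlist(labels))
  C <- matrix(0, n, n)
  for (lab in labels) {
    len <- length(lab)
    if (len < tau + 1) {
      warnf("trajectory of %d frames shorter than tau + 1 = %d; skipped",
            len, tau + 1)
      next
    }
    from <- lab[seq_len(len - tau)]
    to <- lab[seq_len(len - tau) + tau]
    tab <- table(factor(from, levels = seq_len(n)),
                 factor(to, levels = seq_len(n)))
    C <- C + unclass(tab)
  }
  unname(C)
}

#' Largest strongly connected set of the transition-count graph
#'
#' MSM estimation requires an irreducible chain; counts are trimmed to the
#' largest strongly connected component of the directed graph with an edge
#' `i -> j` wherever `C[i, j] > 0` (ties broken by the smallest member
#' state).
#'
#' @param counts transition-count matrix.
#' @return sorted integer vector of active states.
#' @export
largest_connected_set <- function(counts) {
  if (nrow(counts) == 0L) stopf("empty count matrix")
  g <- igraph::graph_from_adjacency_matrix((counts > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- comp$csize
  cand <- which(sizes == max(sizes))
  mins <- vapply(cand, function(cc) min(which(comp$membership == cc)), 1L)
  sort(which(comp$membership == cand[which.min(mins)]))
}

#' Reversible maximum-likelihood transition matrix
#'
#' Estimates the transition probability matrix that maximizes the
#' multinomial likelihood of the observed counts under a detailed-balance
#' constraint (the "maximum likelihood symmetrization"), using the
#' standard self-consistent fixed-point iteration on the unnormalized
#' symmetric flux matrix
#' \deqn{x_{ij} \leftarrow \frac{c_{ij} + c_{ji}}{c_i/x_i + c_j/x_j}.}
#' The stationary distribution is \eqn{\pi_i = x_i / \sum_k x_k} and
#' \eqn{T_{ij} = x_{ij} / x_i}. The log-likelihood is non-decreasing
#' across sweeps; iteration stops when the largest elementwise change
#' falls below `tol`.
#'
#' @param counts count matrix restricted to a strongly connected set (see
#'   [largest_connected_set()]); rows must each contain at least one count.
#' @param tol convergence tolerance on `max |delta x|` (normalized flux).
#' @param max_iter sweep cap.
#' @param lag lag time associated with the counts (stored, default 1).
#' @return object of class `markov_model`: `counts`, `T`, `pi`,
#'   `active_set`, `lag`, `log_likelihood`, `n_iter`.
#' @export
estimate_reversible_tpm <- function(counts, tol = 1e-10, max_iter = 1e6,
                                    lag = 1) {
  counts <- unname(as.matrix(counts))
  n <- nrow(counts)
  if (any(rowSums(counts) == 0))
    stopf("every state needs at least one outgoing count; trim first")
  ci <- rowSums(counts)
  x <- counts + t(counts)
  x <- x / sum(x)
  ll_old <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    xi <- rowSums(x)
    denom <- outer(ci / xi, ci / xi, `+`)
    x_new <- (counts + t(counts)) / denom
    x_new[counts + t(counts) == 0] <- 0
    x_new <- x_new / sum(x_new)
    delta <- max(abs(x_new - x))
    x <- x_new
    if (delta < tol || iter >= max_iter) break
  }
  xi <- rowSums(x)
  T <- x / xi
  ll <- reversible_loglik(counts, T)
  if (iter >= max_iter && delta >= tol)
    stopf("reversible MLE did not converge: last update %.3g > tol %.3g",
          delta, tol)
  pi <- xi / sum(xi)
  structure(list(counts = counts, T = T, pi = pi,
                 active_set = seq_len(n), lag = lag,
                 log_likelihood = ll, n_iter = iter),
            class = "markov_model")
}

reversible_loglik <- function(counts, T) {
  sel <- counts > 0 & T > 0
  sum(counts[sel] * log(T[sel]))
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("markov_model: %d states, lag %g, logL %.4f (%d sweeps)\n",
              nrow(x$T), x$lag, x$log_likelihood, x$n_iter))
  cat("pi:", format(head(x$pi, 8), digits = 4),
      if (length(x$pi) > 8) "..." else "", "\n")
  invisible(x)
}

#' Build a Markov state model from state labels
#'
#' Counts lagged transitions, trims to the largest strongly connected set,
#' and fits the reversible maximum-likelihood transition matrix. The
#' model's `active_set` records which original states survived trimming.
#'
#' @inheritParams count_transitions
#' @return a `markov_model` whose `active_set` maps its states back to the
#'   input labels.
#' @export
build_msm <- function(labels, tau, n_states = NULL) {
  C <- count_transitions(labels, tau, n_states)
  act <- largest_connected_set(C)
  m <- estimate_reversible_tpm(C[act, act, drop = FALSE], lag = tau)
  m$active_set <- act
  m
}

#' Stationary distribution of a transition matrix
#'
#' Leading left eigenvector of a row-stochastic irreducible matrix,
#' normalized to a probability vector.
#'
#' @param T row-stochastic transition matrix.
#' @return stationary probabilities `pi` with `pi %*% T = pi`.
#' @export
stationary_distribution <- function(T) {
  T <- unname(as.matrix(T))
  if (max(abs(rowSums(T) - 1)) > 1e-8) stopf("'T' must be row-stochastic")
  if (length(largest_connected_set(T)) != nrow(T))
    stopf("'T' is reducible; no unique stationary distribution")
  e <- eigen(t(T))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-10)) stopf("negative stationary entries; T malformed")
  pmax(v, 0) / sum(pmax(v, 0))
}

# eigenvalues of a reversible T via the pi-symmetrized similar matrix
reversible_eigen <- function(T, pi) {
  s <- sqrt(pi)
  S <- (s %o% (1 / s)) * T
  S <- (S + t(S)) / 2
  eigen(S, symmetric = TRUE, only.values = TRUE)$values
}

#' Implied timescales across lag times
#'
#' For each lag, builds a reversible MSM and reports
#' \eqn{t_k = -\tau / \ln \lambda_k} for the non-stationary eigenvalues
#' sorted in decreasing order. Eigenvalues `<= 0` give an undefined
#' timescale, flagged rather than propagated as NaN. Lag-independence of
#' the slow timescales indicates Markovian behaviour and guides the lag
#' choice.
#'
#' @param labels state labels (vector or list of trajectories).
#' @param taus lags in frames.
#' @param n_timescales how many slow timescales to report.
#' @param n_states number of states (default: maximum label).
#' @return data frame `lag`, `k`, `eigenvalue`, `timescale` (frames; `NA`
#'   when undefined), `defined`.
#' @export
implied_timescales <- function(labels, taus, n_timescales = 3,
                               n_states = NULL) {
  out <- list()
  for (tau in taus) {
    m <- build_msm(labels, tau, n_states)
    lam <- sort(reversible_eigen(m$T, m$pi), decreasing = TRUE)
    lam <- lam[-1] # drop the stationary eigenvalue
    kk <- seq_len(min(n_timescales, length(lam)))
    lam <- lam[kk]
    ts <- ifelse(lam > 0 & lam < 1, -tau / log(lam), NA_real_)
    out[[length(out) + 1]] <- data.frame(
      lag = tau, k = kk + 1L, eigenvalue = lam, timescale = ts,
      defined = lam > 0 & lam < 1)
  }
  do.call(rbind, out)
}

#' Sample a trajectory from a known Markov chain
#'
#' Generates a synthetic state sequence from an explicit transition
#' matrix -- the ground-truth data source for validating MSM estimators
#' against analytic stationary distributions and timescales.
#'
#' @param T row-stochastic transition matrix.
#' @param n_steps number of transitions.
#' @param seed integer seed.
#' @param start initial state (1-based).
#' @return integer state sequence of length `n_steps + 1`.
#' @export
sample_chain <- function(T, n_steps, seed = 1L, start = 1L) {
  T <- unname(as.matrix(T))
  if (max(abs(rowSums(T) - 1)) > 1e-8) stopf("'T' must be row-stochastic")
  with_seed(as.integer(seed),
            sample_markov_chain(T, as.integer(n_steps),
                                as.integer(start) - 1L)) + 1L
}
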