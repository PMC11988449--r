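#' Time-lagged independent component analysis
#'
#' Finds the linear projections of the feature space X(t) with maximal
#' autocorrelation at lag tau by solving the symmetrized generalized
#' eigenproblem \eqn{C(\tau) v = \lambda C(0) v}, where
#' \eqn{C(\tau) = \langle X(t) X^T(t+\tau)\rangle} is the lagged
#' autocovariance of the mean-free features (estimates symmetrized over
#' the forward and reverse windows, so eigenvalues are real and bounded by
#' 1 up to statistical error). Components are ordered by decreasing
#' eigenvalue; the slowest coordinates come first. Eigenvectors are
#' normalized to unit instantaneous variance (`v' C(0) v = 1`), so
#' projections of the training data are whitened.
#'
#' A singular instantaneous covariance is ridge-regularized
#' (`epsilon = 1e-8`) with a warning.
#'
#' @param features numeric matrix (frames x features) or list of such
#'   matrices (one per trajectory; lagged pairs never cross boundaries).
#' @param lag lag time in frames (>= 1).
#' @return object of class `tica_model`: `mean`, `eigenvalues`,
#'   `eigenvectors` (columns), `lag`.
#' @export
tica_fit <- function(features, lag) {
  if (!is.list(features)) features <- list(features)
  features <- lapply(features, function(f) unclass(rbind(f)))
  if (lag < 1) stopf("'lag' must be >= 1")
  usable <- vapply(features, nrow, 1L) >= lag + 2L
  if (!any(usable)) stopf("need at least lag + 2 frames in some trajectory")
  features <- features[usable]
  mu <- colMeans(do.call(rbind, features))
  d <- length(mu)
  C0 <- matrix(0, d, d); Ct <- matrix(0, d, d); n <- 0
  for (f in features) {
    Xc <- sweep(f, 2, mu)
    X1 <- Xc[seq_len(nrow(Xc) - lag), , drop = FALSE]
    X2 <- Xc[seq_len(nrow(Xc) - lag) + lag, , drop = FALSE]
    C0 <- C0 + crossprod(X1) + crossprod(X2)
    Ct <- Ct + crossprod(X1, X2) + crossprod(X2, X1)
    n <- n + 2 * nrow(X1)
  }
  C0 <- C0 / n; Ct <- Ct / n
  ev0 <- eigen(C0, symmetric = TRUE)
  if (min(ev0$values) < 1e-10) {
    warnf("singular instantaneous covariance; ridge-regularized (1e-8)")
    C0 <- C0 + diag(1e-8, d)
    ev0 <- eigen(C0, symmetric = TRUE)
  }
  W <- ev0$vectors %*% diag(1 / sqrt(ev0$values), d) %*% t(ev0$vectors)
  es <- eigen(W %*% Ct %*% W, symmetric = TRUE)
  structure(list(mean = mu, eigenvalues = es$values,
                 eigenvectors = W %*% es$vectors, lag = lag),
            class = "tica_model")
}

#' @export
print.tica_model <- function(x, ...) {
  cat(sprintf("tica_model: %d components at lag %g\n",
              length(x$eigenvalues), x$lag))
  cat("eigenvalues:", format(head(x$eigenvalues, 6), digits = 4), "\n")
  invisible(x)
}

#' Project features onto tICA components
#'
#' @param model a [tica_fit()] result.
#' @param features frames x features matrix.
#' @param n_components number of leading components (default 2).
#' @return frames x n_components projection matrix.
#' @export
tica_project <- function(model, features, n_components = 2) {
  X <- sweep(unclass(rbind(features)), 2, model$mean)
  X %*% model$eigenvectors[, seq_len(n_components), drop = FALSE]
}

#' VAMP-2 score of a tICA model
#'
#' \eqn{1 + \sum_{k \le n} \lambda_k^2}: the variational score of the
#' projection including the constant function. Non-decreasing in `n` on
#' training data; used to choose how many slow components are worth
#' retaining (four, in the full-scale preset).
#'
#' @param model a [tica_fit()] result.
#' @param n_components number of components scored (0 gives 1.0).
#' @return VAMP-2 score.
#' @export
vamp2_score <- function(model, n_components) {
  if (n_components > length(model$eigenvalues))
    stopf("n_components exceeds available components")
  if (n_components == 0) return(1.0)
  1 + sum(model$eigenvalues[seq_len(n_components)]^2)
}

#' Free-energy surface on the first two tICA components
#'
#' Projects frames onto (tIC1, tIC2), histograms them, and converts the
#' normalized density to free energies \eqn{F = -kT \ln \rho}, shifted so
#' the global minimum is zero. Empty bins are `Inf` (flagged), never zero.
#'
#' @param features frames x features matrix.
#' @param model a [tica_fit()] result with >= 2 components.
#' @param kT thermal energy (sets the free-energy unit).
#' @param bins number of bins per axis.
#' @return object of class `free_energy_surface`: `F` (matrix), `xmids`,
#'   `ymids`, `kT`.
#' @export
project_fes <- function(features, model, kT = 1, bins = 32) {
  if (length(model$eigenvalues) < 2) stopf("model needs >= 2 components")
  P <- tica_project(model, features, 2)
  xe <- seq(min(P[, 1]), max(P[, 1]), length.out = bins + 1)
  ye <- seq(min(P[, 2]), max(P[, 2]), length.out = bins + 1)
  ix <- pmin(pmax(findInterval(P[, 1], xe, all.inside = TRUE), 1), bins)
  iy <- pmin(pmax(findInterval(P[, 2], ye, all.inside = TRUE), 1), bins)
  H <- matrix(0, bins, bins)
  for (i in seq_along(ix)) H[ix[i], iy[i]] <- H[ix[i], iy[i]] + 1
  if (sum(H > 0) == 1) warnf("degenerate surface: all frames in one bin")
  p <- H / sum(H)
  F <- -kT * log(p)
  F <- F - min(F[is.finite(F)])
  structure(list(F = F, xmids = (xe[-1] + xe[-length(xe)]) / 2,
                 ymids = (ye[-1] + ye[-length(ye)]) / 2, kT = kT),
            class = "free_energy_surface")
}

#' Count local minima (metastable basins) of a free-energy surface
#'
#' A basin is a finite bin whose free energy is the unique minimum of its
#' `halo`-bin neighbourhood, lies within `fmax` of the global minimum
#' (discarding noise minima in barely populated regions), and is
#' surrounded by bins at least `depth` higher. Used to check that a
#' projected landscape resolves the expected number of metastable states.
#'
#' @param fes a [project_fes()] result.
#' @param halo neighbourhood half-width in bins.
#' @param depth required prominence (free-energy units).
#' @param fmax only bins within `fmax` of the global minimum are basin
#'   candidates.
#' @return number of detected basins.
#' @export
count_fes_basins <- function(fes, halo = 2, depth = 0.5, fmax = Inf) {
  F <- fes$F
  nb <- dim(F)
  n_min <- 0
  for (i in seq_len(nb[1])) for (j in seq_len(nb[2])) {
    if (!is.finite(F[i, j]) || F[i, j] > fmax) next
    ii <- max(1, i - halo):min(nb[1], i + halo)
    jj <- max(1, j - halo):min(nb[2], j + halo)
    nbh <- F[ii, jj]
    nbh <- nbh[is.finite(nbh)]
    if (F[i, j] == min(nbh) && sum(nbh == min(nbh)) == 1 &&
        any(nbh >= F[i, j] + depth))
      n_min <- n_min + 1
  }
  n_min
}
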