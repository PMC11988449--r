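# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: brute-force enumeration, quadrature and
# closed forms only.

# Boltzmann weights of a toy potential on a regular 2D grid
quadrature_weights <- function(potential, xlim, ylim, h = 0.02, kT = 1) {
  g <- as.matrix(expand.grid(x = seq(xlim[1], xlim[2], by = h),
                             y = seq(ylim[1], ylim[2], by = h)))
  list(points = g, w = exp(-potential_energy(potential, g) / kT))
}

# brute-force strongly connected components by repeated reachability
brute_scc <- function(adj) {
  n <- nrow(adj)
  reach <- function(start) {
    seen <- rep(FALSE, n); seen[start] <- TRUE
    repeat {
      new <- seen | (colSums(adj[seen, , drop = FALSE]) > 0)
      if (all(new == seen)) return(seen)
      seen <- new
    }
  }
  fwd <- t(sapply(seq_len(n), reach))
  comp <- rep(NA_integer_, n); cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    comp[which(fwd[i, ] & fwd[, i])] <- cid
  }
  comp
}

# maximum-likelihood reversible TPM by direct constrained optimization of
# the symmetric flux parameterization (log-coordinates, generic optimizer)
oracle_reversible_mle <- function(C) {
  n <- nrow(C)
  up <- which(upper.tri(C, diag = TRUE))
  sym <- C + t(C)
  nll <- function(theta) {
    x <- matrix(0, n, n)
    x[up] <- exp(theta)
    x <- x + t(x) - diag(diag(x))
    x[sym == 0] <- 0
    Tm <- x / rowSums(x)
    sel <- C > 0
    if (any(Tm[sel] <= 0)) return(1e10)
    -sum(C[sel] * log(Tm[sel]))
  }
  theta0 <- log(pmax(sym[up], 0.5))
  opt <- optim(theta0, nll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  x <- matrix(0, n, n); x[up] <- exp(opt$par)
  x <- x + t(x) - diag(diag(x)); x[sym == 0] <- 0
  list(T = x / rowSums(x), logLik = -opt$value)
}

# naive estimator projected to reversibility: row-normalized counts, then
# pi-symmetrized flux re-normalized
naive_reversible_projection <- function(C) {
  Tn <- C / rowSums(C)
  e <- eigen(t(Tn))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  piv <- v / sum(v)
  x <- (piv * Tn + t(piv * Tn)) / 2
  x / rowSums(x)
}

# exhaustive widest-path bottleneck on a small clearance grid: scan the
# clearance levels from high to low, test start/boundary connectivity
# with igraph on the thresholded voxel graph
oracle_widest_bottleneck <- function(clearance, dims, start, targets) {
  n <- prod(dims)
  coord <- cbind(i = (seq_len(n) - 1) %% dims[1],
                 j = ((seq_len(n) - 1) %/% dims[1]) %% dims[2],
                 k = (seq_len(n) - 1) %/% (dims[1] * dims[2]))
  edges <- NULL
  for (d in 1:3) {
    ok <- coord[, d] < dims[d] - 1
    stride <- c(1, dims[1], dims[1] * dims[2])[d]
    edges <- rbind(edges, cbind(which(ok), which(ok) + stride))
  }
  levels <- sort(unique(clearance[clearance > 0]), decreasing = TRUE)
  for (thr in levels) {
    keep <- clearance >= thr
    e <- edges[keep[edges[, 1]] & keep[edges[, 2]], , drop = FALSE]
    g <- igraph::graph_from_edgelist(cbind(as.character(e[, 1]),
                                           as.character(e[, 2])),
                                     directed = FALSE)
    g <- g + igraph::vertices(setdiff(as.character(which(keep)),
                                      igraph::V(g)$name))
    memb <- igraph::components(g)$membership
    sm <- memb[as.character(start)]
    tg <- memb[as.character(intersect(which(targets), which(keep)))]
    if (!is.na(sm) && length(tg) > 0 && any(tg == sm)) return(thr)
  }
  0
}

# random reversible row-stochastic matrix with known structure
random_reversible_T <- function(n, seed) {
  set.seed(seed)
  X <- matrix(runif(n * n), n, n)
  X <- X + t(X)
  diag(X) <- diag(X) + n / 2
  X / rowSums(X)
}

# random connected count matrix (all pairs observed at least once)
random_connected_counts <- function(n, seed, lambda = 6) {
  set.seed(seed)
  matrix(rpois(n * n, lambda) + 1L, n, n)
}
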