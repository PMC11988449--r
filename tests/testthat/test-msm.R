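test_that("k-means discretization honours limits and separable blobs", {
  set.seed(2)
  X <- rbind(matrix(rnorm(60, 0, 0.5), 30, 2),
             matrix(rnorm(60, 8, 0.5), 30, 2))
  expect_error(kmeans_discretize(X, k = 100), "exceeds")
  d1 <- kmeans_discretize(X, k = 1)
  expect_true(all(d1$labels == 1))
  dn <- kmeans_discretize(X[1:10, ], k = 10)
  expect_equal(sort(dn$labels), 1:10)
  d2 <- kmeans_discretize(X, k = 2, seed = 7)
  blob <- rep(1:2, each = 30)
  # labels must match blob identity up to permutation
  agree <- max(mean(d2$labels == blob), mean(d2$labels == 3 - blob))
  expect_equal(agree, 1.0)
  expect_identical(d2$labels, kmeans_discretize(X, k = 2, seed = 7)$labels)
})

test_that("transition counting enumerates lagged pairs exactly", {
  expect_equal(count_transitions(c(1, 1, 2, 2), 1),
               matrix(c(1, 1, 0, 1), 2, 2, byrow = TRUE))
  expect_equal(count_transitions(c(1, 1, 2, 2), 3),
               matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE))
  set.seed(5)
  lab <- sample(1:4, 200, replace = TRUE)
  tau <- 3
  brute <- matrix(0, 4, 4)
  for (t in seq_len(200 - tau))
    brute[lab[t], lab[t + tau]] <- brute[lab[t], lab[t + tau]] + 1
  expect_equal(count_transitions(lab, tau), brute)
  # never crosses trajectory boundaries
  split2 <- count_transitions(list(lab[1:100], lab[101:200]), tau)
  expect_equal(sum(split2), sum(brute) - tau)
  expect_warning(count_transitions(list(lab, lab[1:2]), tau), "skipped")
})

test_that("largest strongly connected set matches a brute-force oracle", {
  blockC <- rbind(c(1, 1, 0, 0, 0), c(1, 1, 0, 0, 0),
                  c(0, 0, 2, 1, 1), c(0, 0, 1, 2, 1), c(0, 0, 1, 1, 2))
  expect_equal(largest_connected_set(blockC), 3:5)
  full <- matrix(1, 4, 4)
  expect_equal(largest_connected_set(full), 1:4)
  set.seed(29)
  for (rep in 1:5) {
    adj <- matrix(rbinom(49, 1, 0.25), 7, 7)
    comp <- brute_scc(adj > 0)
    sizes <- table(comp)
    big <- as.integer(names(sizes)[sizes == max(sizes)])
    oracle_sets <- lapply(big, function(b) which(comp == b))
    got <- largest_connected_set(adj)
    expect_true(any(vapply(oracle_sets, identical, logical(1), got)))
  }
})

test_that("2-state reversible MLE equals row-normalized counts", {
  for (seed in 1:5) {
    set.seed(seed)
    C <- matrix(rpois(4, 10) + 1, 2, 2)
    m <- estimate_reversible_tpm(C)
    expect_equal(m$T, C / rowSums(C), tolerance = 1e-8)
  }
})

test_that("symmetric counts are their own reversible MLE", {
  # constant row sums: kernel symmetric, pi uniform
  Cu <- matrix(c(4, 2, 2, 2, 4, 2, 2, 2, 4), 3, 3)
  mu <- estimate_reversible_tpm(Cu)
  expect_equal(mu$T, t(mu$T), tolerance = 1e-8)
  expect_equal(mu$pi, rep(1 / 3, 3), tolerance = 1e-8)
  # general symmetric counts: T is row-normalized counts, pi tracks
  # row sums, and the stationary flux is symmetric
  C <- matrix(c(4, 2, 1, 2, 4, 2, 1, 2, 4), 3, 3)
  m <- estimate_reversible_tpm(C)
  expect_equal(m$T, C / rowSums(C), tolerance = 1e-8)
  expect_equal(m$pi, rowSums(C) / sum(C), tolerance = 1e-8)
  flux <- m$pi * m$T
  expect_equal(flux, t(flux), tolerance = 1e-10)
})

test_that("reversible MLE satisfies detailed balance and beats projection", {
  for (seed in 1:6) {
    C <- random_connected_counts(4, seed)
    m <- estimate_reversible_tpm(C)
    flux <- m$pi * m$T
    expect_lt(max(abs(flux - t(flux))), 1e-8)
    expect_equal(rowSums(m$T), rep(1, 4), tolerance = 1e-10)
    ll <- function(T) sum(C[C > 0] * log(T[C > 0]))
    expect_gte(m$log_likelihood, ll(naive_reversible_projection(C)) - 1e-9)
  }
})

test_that("reversible MLE agrees with a direct constrained optimizer", {
  for (seed in c(2, 8)) {
    C <- random_connected_counts(4, seed)
    m <- estimate_reversible_tpm(C)
    orc <- oracle_reversible_mle(C)
    expect_equal(m$log_likelihood, orc$logLik, tolerance = 1e-6)
    expect_equal(m$T, orc$T, tolerance = 1e-3)
  }
})

test_that("stationary distribution solves pi T = pi", {
  T2 <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  expect_equal(stationary_distribution(T2), c(2 / 3, 1 / 3))
  Tsym <- matrix(c(0.5, 0.25, 0.25, 0.25, 0.5, 0.25, 0.25, 0.25, 0.5),
                 3, 3)
  expect_equal(stationary_distribution(Tsym), rep(1 / 3, 3))
  T5 <- random_reversible_T(5, 77)
  piv <- stationary_distribution(T5)
  # power-iteration oracle
  p <- rep(1 / 5, 5)
  for (i in 1:10000) p <- as.numeric(p %*% T5)
  expect_equal(piv, p, tolerance = 1e-10)
  expect_equal(as.numeric(piv %*% T5), piv, tolerance = 1e-12)
  Tred <- diag(2)
  expect_error(stationary_distribution(Tred), "reducible")
})

test_that("implied timescales reproduce the -tau/log(lambda) formula", {
  # a 2-state chain whose 5-step kernel has lambda2 = 0.7: the timescale
  # reported at lag 5 must be -5/log(0.7) ~ 14.02
  lam_step <- 0.7^(1 / 5)
  p <- (1 - lam_step) / 2
  T2 <- matrix(c(1 - p, p, p, 1 - p), 2, 2, byrow = TRUE)
  lab <- sample_chain(T2, 2e5, seed = 3)
  its <- implied_timescales(lab, taus = 5, n_timescales = 1)
  expect_equal(-5 / log(0.7), 14.02, tolerance = 0.001)
  expect_equal(its$timescale, 14.02, tolerance = 0.1)
})

test_that("timescales from an exact chain are lag-independent", {
  T3 <- random_reversible_T(3, 55)
  lab <- sample_chain(T3, 2e5, seed = 12)
  its <- implied_timescales(lab, taus = c(1, 2, 4), n_timescales = 1)
  lam2 <- sort(Re(eigen(T3, only.values = TRUE)$values),
               decreasing = TRUE)[2]
  analytic <- -1 / log(lam2)
  expect_true(all(abs(its$timescale - analytic) / analytic < 0.15))
})

test_that("undefined timescales are flagged, not NaN", {
  # period-2 flips give a negative second eigenvalue
  lab <- rep(c(1, 2), 500)
  its <- implied_timescales(lab, taus = 1, n_timescales = 1)
  expect_false(its$defined)
  expect_true(is.na(its$timescale))
})

test_that("a known 5-state chain is recovered from a finite trajectory", {
  T5 <- random_reversible_T(5, 42)
  pi_true <- stationary_distribution(T5)
  lam <- sort(Re(eigen(T5, only.values = TRUE)$values), decreasing = TRUE)
  lab <- sample_chain(T5, 1e5, seed = 11)
  m <- build_msm(lab, tau = 1, n_states = 5)
  expect_equal(length(m$active_set), 5)
  expect_lt(sum(abs(m$pi - pi_true)), 0.02)
  its <- implied_timescales(lab, taus = 1, n_timescales = 1)
  expect_lt(abs(its$timescale - (-1 / log(lam[2]))) / (-1 / log(lam[2])),
            0.10)
})
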