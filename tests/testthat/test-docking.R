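two_state_model <- function(pi) {
  structure(list(T = diag(2), pi = pi, active_set = 1:2, lag = 1),
            class = "markov_model")
}

test_that("uniform stationary probabilities reduce to raw-score ranking", {
  set.seed(14)
  n <- 20
  model <- structure(list(T = matrix(0.25, 4, 4), pi = rep(0.25, 4),
                          active_set = 1:4, lag = 1),
                     class = "markov_model")
  poses <- data.frame(conformation = 1:n,
                      state = rep(1:4, each = 5),
                      score = rnorm(n, -6))
  rk <- reweight_poses(poses, model, reweight_config())
  expect_equal(rk$conformation, poses$conformation[order(poses$score)])
})

test_that("the two-pose worked example evaluates exactly", {
  model <- two_state_model(c(0.99, 0.01))
  poses <- data.frame(conformation = 1:2, state = 1:2, score = c(-6, -7))
  rk <- reweight_poses(poses, model, reweight_config(kT = 0.596))
  # hand evaluation of G_i = g_i - kT ln(pi_i):
  # G1 = -6 - 0.596 ln(0.99) = -5.994, G2 = -7 - 0.596 ln(0.01) = -4.255
  g1 <- -6 - 0.596 * log(0.99)
  g2 <- -7 - 0.596 * log(0.01)
  expect_equal(rk$effective[rk$conformation == 1], g1, tolerance = 1e-9)
  expect_equal(rk$effective[rk$conformation == 2], g2, tolerance = 1e-9)
  expect_equal(g1, -5.994, tolerance = 1e-3)
  expect_equal(g2, -4.255, tolerance = 1e-3)
  expect_equal(rk$conformation[1], 1) # pose 1 outranks pose 2
})

test_that("a single pose in a single state gives K = exp(-g/kT)", {
  model <- structure(list(T = matrix(1), pi = 1, active_set = 1L, lag = 1),
                     class = "markov_model")
  poses <- data.frame(conformation = 1, state = 1, score = -5)
  rk <- reweight_poses(poses, model, reweight_config(kT = 0.596))
  expect_equal(attr(rk, "K"), exp(5 / 0.596))
})

test_that("state probability is conserved when poses are duplicated", {
  model <- two_state_model(c(0.7, 0.3))
  poses <- data.frame(conformation = 1:2, state = 1:2, score = c(-6, -5))
  K1 <- attr(reweight_poses(poses, model), "K")
  # split state 1 into three poses with the same score
  poses3 <- data.frame(conformation = 1:4, state = c(1, 1, 1, 2),
                       score = c(-6, -6, -6, -5))
  K3 <- attr(reweight_poses(poses3, model), "K")
  expect_equal(K1, K3, tolerance = 1e-12)
})

test_that("poses outside the active set are dropped with a warning", {
  model <- two_state_model(c(0.5, 0.5))
  poses <- data.frame(conformation = 1:3, state = c(1, 2, 9),
                      score = c(-6, -5, -10))
  expect_warning(rk <- reweight_poses(poses, model), "dropped")
  expect_equal(nrow(rk), 2)
})

test_that("select_top matches a full-sort oracle", {
  set.seed(24)
  model <- structure(list(T = diag(5), pi = runif(5), active_set = 1:5,
                          lag = 1), class = "markov_model")
  model$pi <- model$pi / sum(model$pi)
  poses <- data.frame(conformation = 1:40,
                      state = sample(1:5, 40, replace = TRUE),
                      score = rnorm(40, -6))
  rk <- reweight_poses(poses, model)
  expect_equal(select_top(rk, 1)$effective, min(rk$effective))
  expect_equal(nrow(select_top(rk, nrow(rk))), nrow(rk))
  oracle <- rk$conformation[order(rk$effective, rk$score,
                                  rk$conformation)][1:7]
  expect_equal(select_top(rk, 7)$conformation, oracle)
  expect_warning(all_back <- select_top(rk, 999), "exceeds")
  expect_equal(nrow(all_back), nrow(rk))
})

test_that("quality-threshold clustering recovers planted pose blobs", {
  single <- cluster_poses(list(matrix(0, 3, 3)), cutoff = 2.5)
  expect_equal(length(single$clusters), 1)
  two <- cluster_poses(list(matrix(0, 2, 3),
                            matrix(10, 2, 3)), cutoff = 2.5)
  expect_equal(length(two$clusters), 2)
  set.seed(34)
  blobs <- lapply(1:12, function(i) {
    ctr <- c(0, 20, 40)[(i - 1) %% 3 + 1]
    matrix(ctr, 4, 3) + matrix(rnorm(12, 0, 0.3), 4, 3)
  })
  cl <- cluster_poses(blobs, cutoff = 2.5)
  expect_equal(length(cl$clusters), 3)
  memb <- lapply(cl$clusters, function(x) sort(x$members))
  planted <- lapply(1:3, function(b) seq(b, 12, by = 3))
  expect_setequal(
    vapply(memb, paste, "", collapse = ","),
    vapply(planted, paste, "", collapse = ","))
  # every member within cutoff of its representative
  for (x in cl$clusters) {
    repc <- blobs[[x$representative]]
    for (mm in x$members)
      expect_lt(sqrt(mean(rowSums((blobs[[mm]] - repc)^2))), 2.5)
  }
})

test_that("clustering is invariant to input order via deterministic ties", {
  set.seed(44)
  blobs <- lapply(1:9, function(i)
    matrix(c(0, 15, 30)[(i - 1) %/% 3 + 1], 2, 3) +
      matrix(rnorm(6, 0, 0.2), 2, 3))
  cl1 <- cluster_poses(blobs, cutoff = 2.5, ids = 1:9)
  perm <- c(5, 2, 9, 1, 7, 3, 8, 6, 4)
  cl2 <- cluster_poses(blobs[perm], cutoff = 2.5, ids = perm)
  sets1 <- sort(vapply(cl1$clusters,
                       function(x) paste(sort(x$members), collapse = ","), ""))
  sets2 <- sort(vapply(cl2$clusters,
                       function(x) paste(sort(x$members), collapse = ","), ""))
  expect_equal(sets1, sets2)
})

test_that("representative selection respects cluster size and the cap", {
  set.seed(54)
  blobs <- lapply(1:25, function(i) matrix(7 * i, 1, 3))
  cl <- cluster_poses(blobs, cutoff = 2.5)
  expect_equal(length(representative_poses(cl, 20)), 20)
  three <- cluster_poses(lapply(c(0, 0, 0, 20, 20, 40),
                                function(z) matrix(z, 1, 3)), 2.5)
  reps <- representative_poses(three, 20)
  expect_equal(length(reps), 3)
  # largest blob's representative comes first
  expect_true(reps[1] %in% 1:3)
})

test_that("grid-box specifications round-trip through JSON", {
  f <- tempfile(fileext = ".json")
  write_grid_box(c(1, 2, 3), c(24, 22, 25), f)
  gb <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(gb$dims, c(24, 22, 25))
  expect_equal(gb$center, c(1, 2, 3))
})
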