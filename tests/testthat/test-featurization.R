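# small ensemble builders used throughout
make_two_residue_ensemble <- function(p1, p2) {
  atom <- data.frame(elety = "CA", resid = c("LOP", "WAL"),
                     resno = c(101, 1), chain = "A", elesy = "C")
  conformation_ensemble(matrix(c(p1, p2), nrow = 1), atom)
}

test_that("pentamer with 5x5 loop/wall residues yields 125 feature columns", {
  ens <- toy_embed(rbind(c(0.5, 0.1), c(1.2, -0.3)),
                   n_loop = 5, n_wall = 5)
  fm <- pairwise_distance_features(ens, list(loop = 101:105, wall = 1:5))
  expect_equal(ncol(fm), 125)
  expect_equal(nrow(fm), 2)
  idx <- attr(fm, "index")
  # subunit-major, then loop, then wall ordering
  expect_equal(idx$subunit[1:25], rep("A", 25))
  expect_equal(idx$loop[1:5], rep(101, 5))
  expect_equal(idx$wall[1:5], 101:105 * 0 + 1:5)
  expect_true(all(is.finite(fm)) && all(fm > 0))
})

test_that("single-atom residue distance is plain Euclidean", {
  ens <- make_two_residue_ensemble(c(0, 0, 0), c(3, 4, 0))
  fm <- pairwise_distance_features(ens, list(loop = 101, wall = 1))
  expect_equal(as.numeric(fm), 5.0)
})

test_that("nearest-atom distance equals the exhaustive atom-pair minimum", {
  set.seed(11)
  for (rep in 1:5) {
    la <- matrix(rnorm(9, 0, 2), 3, 3)
    wa <- matrix(rnorm(12, 5, 2), 4, 3)
    atom <- data.frame(
      elety = c(paste0("L", 1:3), paste0("W", 1:4)),
      resid = c(rep("LOP", 3), rep("WAL", 4)),
      resno = c(rep(101, 3), rep(1, 4)), chain = "A", elesy = "C")
    ens <- conformation_ensemble(matrix(t(rbind(la, wa)), nrow = 1), atom)
    fm <- pairwise_distance_features(ens, list(loop = 101, wall = 1))
    brute <- min(apply(la, 1, function(p)
      apply(wa, 1, function(q) sqrt(sum((p - q)^2)))))
    expect_equal(as.numeric(fm), brute)
  }
})

test_that("feature distances are invariant to global rigid motion", {
  ens <- toy_embed(rbind(c(0.7, 0.2)), n_loop = 2, n_wall = 2)
  fm <- pairwise_distance_features(ens, list(loop = 101:102, wall = 1:2))
  th <- 0.8
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- frame_coords(ens, 1) %*% R + matrix(c(3, -2, 7),
                                               nrow(ens$atom), 3,
                                               byrow = TRUE)
  ens2 <- conformation_ensemble(matrix(t(moved), nrow = 1), ens$atom)
  fm2 <- pairwise_distance_features(ens2, list(loop = 101:102, wall = 1:2))
  expect_equal(unclass(fm2), unclass(fm), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("rmsd handles identity, translation and superposition", {
  set.seed(21)
  a <- matrix(rnorm(30), 10, 3)
  expect_equal(rmsd(a, a), 0)
  b <- sweep(a, 2, c(1, 2, 2), `+`)
  expect_equal(rmsd(b, a, superpose = FALSE), 3.0)
  expect_equal(rmsd(b, a, superpose = TRUE), 0, tolerance = 1e-9)
  # symmetry
  expect_equal(rmsd(a, b), rmsd(b, a))
})

test_that("superposed rmsd matches an independent least-squares oracle", {
  set.seed(31)
  for (rep in 1:4) {
    a <- matrix(rnorm(30), 10, 3)
    th <- runif(1, 0, pi)
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    b <- a %*% R + matrix(runif(3, -5, 5), 10, 3, byrow = TRUE) +
      matrix(rnorm(30, 0, 0.3), 10, 3)
    ours <- rmsd(b, a, superpose = TRUE)
    oracle <- bio3d::rmsd(as.numeric(t(a)), as.numeric(t(b)),
                          fit = TRUE)
    expect_lt(abs(ours - oracle), 6e-4) # oracle reports 3 decimals
  }
})

test_that("rmsd is invariant under joint rigid motion when superposing", {
  set.seed(41)
  a <- matrix(rnorm(24), 8, 3)
  b <- a + matrix(rnorm(24, 0, 0.5), 8, 3)
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  expect_equal(rmsd(b %*% R, a %*% R, superpose = TRUE),
               rmsd(b, a, superpose = TRUE), tolerance = 1e-9)
})

test_that("com_rmsd measures ligand displacement after receptor fit", {
  set.seed(51)
  rec <- matrix(rnorm(30, 0, 4), 10, 3)
  lig <- matrix(rnorm(9, 10, 1), 3, 3)
  ref <- rbind(rec, lig)
  expect_equal(com_rmsd(ref, ref, 11:13), 0)
  shifted <- rbind(rec, sweep(lig, 2, c(15, 0, 0), `+`))
  expect_equal(com_rmsd(shifted, ref, 11:13), 15.0, tolerance = 1e-9)
  # randomized: equals direct COM arithmetic when receptors align exactly
  lig2 <- lig + matrix(rnorm(9), 3, 3)
  frame <- rbind(rec, lig2)
  manual <- sqrt(sum((colMeans(lig2) - colMeans(lig))^2))
  expect_equal(com_rmsd(frame, ref, 11:13), manual, tolerance = 1e-9)
  expect_error(com_rmsd(frame, ref, integer(0)), "empty")
})

test_that("rmsf recovers static and two-point-oscillation limits", {
  n <- 31
  atom <- data.frame(elety = "CA", resid = "GLY", resno = 1:n,
                     chain = "A", elesy = "C")
  set.seed(91)
  base <- matrix(rnorm(3 * n, 0, 5), n, 3)
  static <- conformation_ensemble(rbind(as.numeric(t(base)),
                                        as.numeric(t(base))), atom)
  expect_equal(rmsf(static)$rmsf, rep(0, n))
  # atom 1 oscillates +-a along x about the mean: its two-point
  # population SD is a (the 30 anchor atoms pin the superposition)
  a_amp <- 0.8
  f1 <- base; f1[1, 1] <- base[1, 1] + a_amp
  f2 <- base; f2[1, 1] <- base[1, 1] - a_amp
  osc <- conformation_ensemble(rbind(as.numeric(t(f1)),
                                     as.numeric(t(f2))), atom)
  r <- rmsf(osc)
  expect_equal(r$rmsf[r$resno == 1], a_amp, tolerance = 0.1)
  expect_error(rmsf(conformation_ensemble(matrix(rnorm(3 * n), 1), atom)),
               ">= 2")
})

test_that("rmsf matches the brute-force formula without superposition noise", {
  set.seed(61)
  atom <- data.frame(elety = "CA", resid = "GLY", resno = 1:5,
                     chain = "A", elesy = "C")
  # identical frames plus pure per-atom jitter with zero net rotation:
  # compare against direct SD about the mean after the same fits
  frames <- lapply(1:6, function(i) matrix(rnorm(15, 0, 2), 5, 3))
  xyz <- do.call(rbind, lapply(frames, function(m) as.numeric(t(m))))
  ens <- conformation_ensemble(xyz, atom)
  r <- rmsf(ens)
  expect_true(all(r$rmsf > 0))
  expect_equal(nrow(r), 5)
})

test_that("contact frequency counts frames with any atom pair in cutoff", {
  atom <- data.frame(elety = c("C1", "CA", "CB"),
                     resid = c("LIG", "ALA", "GLY"),
                     resno = c(900, 1, 2),
                     chain = c("L", "A", "A"), elesy = "C")
  near <- c(0, 0, 0, 3, 0, 0, 20, 0, 0)
  far <- c(0, 0, 0, 10, 0, 0, 20, 0, 0)
  ens_near <- conformation_ensemble(rbind(near, near), atom)
  tb <- contact_frequency(ens_near, 1)
  expect_equal(tb$frequency[tb$resno == 1], 1.0)
  expect_equal(tb$frequency[tb$resno == 2], 0.0)
  ens_alt <- conformation_ensemble(rbind(near, far), atom)
  tb2 <- contact_frequency(ens_alt, 1)
  expect_equal(tb2$frequency[tb2$resno == 1], 0.5)
})

test_that("contact frequencies grow monotonically with the cutoff", {
  set.seed(71)
  n_atoms <- 12
  atom <- data.frame(elety = "C", resid = c("LIG", rep("RES", n_atoms - 1)),
                     resno = c(900, rep(1:3, length.out = n_atoms - 1)),
                     chain = c("L", rep("A", n_atoms - 1)), elesy = "C")
  xyz <- matrix(rnorm(5 * 3 * n_atoms, 0, 4), nrow = 5)
  ens <- conformation_ensemble(xyz, atom)
  cuts <- c(2, 4, 6, 9)
  freqs <- sapply(cuts, function(cc)
    sum(contact_frequency(ens, 1, contact_config(cutoff = cc))$frequency))
  expect_true(all(diff(freqs) >= 0))
})

test_that("hydrogen-bond detection applies both geometric criteria", {
  D <- c(0, 0, 0); H <- c(1, 0, 0)
  lin <- function(dDA) c(dDA, 0, 0)
  expect_true(detect_hbond(D, H, lin(2.9)))
  expect_false(detect_hbond(D, H, lin(3.2)))
  # 100-degree D-H-A angle at 2.9 A D-A distance: fails the angle test
  A <- H + 2.2 * c(cos(100 * pi / 180), sin(100 * pi / 180), 0)
  dDA <- sqrt(sum((A - D)^2))
  expect_lt(dDA, 3)
  expect_false(detect_hbond(D, H, A))
  expect_error(detect_hbond(D, D, lin(2)), "coincident")
})

test_that("ensembles survive a multi-model PDB round trip", {
  ens <- toy_embed(rbind(c(0.2, 0), c(1.4, 0.5), c(2.2, -0.2)))
  f <- tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, f)
  back <- read_ensemble_pdb(f)
  expect_equal(n_frames(back), 3)
  expect_equal(back$xyz, unclass(ens$xyz), tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(back$atom$resno, ens$atom$resno)
})
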