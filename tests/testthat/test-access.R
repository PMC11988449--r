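# a slab of atoms filling a box with a cylindrical channel of given
# radius along z: dense atom packing everywhere except the channel tube
slab_with_channel <- function(channel_radius, atom_radius = 1.0,
                              half_w = 7, thick = 4) {
  g <- expand.grid(x = seq(-half_w, half_w, by = 1.4),
                   y = seq(-half_w, half_w, by = 1.4),
                   z = seq(-thick, thick, by = 1.4))
  keep <- sqrt(g$x^2 + g$y^2) > channel_radius + atom_radius
  data.frame(x = g$x[keep], y = g$y[keep], z = g$z[keep],
             radius = atom_radius)
}

test_that("clearance equals distance to the nearest atom surface", {
  one <- data.frame(x = 0, y = 0, z = 0, radius = 2)
  grid <- build_grid(one, spacing = 0.5, padding = 4)
  vi <- crypticsite:::voxel_index(grid, c(5, 0, 0))
  expect_equal(grid$clearance[vi], 3.0, tolerance = 1e-9)
  vc <- crypticsite:::voxel_index(grid, c(0, 0, 0))
  expect_equal(grid$clearance[vc], -2.0, tolerance = 1e-9)
  expect_error(build_grid(one[0, ], spacing = 0.5), "empty")
  expect_error(build_grid(one, spacing = 3), "spacing")
})

test_that("clearance matches a brute-force minimum at random voxels", {
  set.seed(94)
  atoms <- data.frame(x = rnorm(50, 0, 5), y = rnorm(50, 0, 5),
                      z = rnorm(50, 0, 5),
                      radius = runif(50, 1, 2))
  grid <- build_grid(atoms, spacing = 0.7, padding = 3)
  n <- prod(grid$dims)
  idx <- sample(n, 100)
  pts <- crypticsite:::voxel_coords(grid, idx)
  brute <- vapply(seq_len(100), function(i)
    min(sqrt((pts[i, 1] - atoms$x)^2 + (pts[i, 2] - atoms$y)^2 +
               (pts[i, 3] - atoms$z)^2) - atoms$radius), 1)
  expect_equal(grid$clearance[idx], brute, tolerance = 1e-9)
})

test_that("a cylindrical channel's bottleneck is recovered to grid accuracy", {
  slab <- slab_with_channel(3.0)
  grid <- build_grid(slab, spacing = 0.5, padding = 3)
  tun <- find_tunnels(grid, c(0, 0, 0))
  expect_gt(length(tun), 0)
  best <- tun[[1]]
  expect_equal(best$bottleneck, 3.0, tolerance = 0.5)
  expect_true(best$exit_face %in% c("z-", "z+"))
  # bottleneck is the min clearance along the reported path
  path_idx <- apply(best$path, 1, function(p)
    crypticsite:::voxel_index(grid, p))
  expect_gte(min(grid$clearance[path_idx]), best$bottleneck - 1e-9)
})

test_that("a sealed cavity yields no tunnel and is classified buried", {
  rec <- build_sphere_receptor(list(list(center = c(0, 0, 0),
                                         channel_radius = 0)),
                               shell_radius = 6)
  grid <- build_grid(rec, spacing = 0.5)
  tun <- find_tunnels(grid, c(0, 0, 0))
  expect_equal(length(tun), 0)
  expect_equal(classify_site(tun)$label, "buried")
  # start inside an atom errors
  a1 <- rec$atoms[1, ]
  expect_error(find_tunnels(grid, c(a1$x, a1$y, a1$z)), "inside an atom")
})

test_that("an isolated start in open space is trivially open", {
  lone <- data.frame(x = 30, y = 30, z = 30, radius = 1)
  grid <- build_grid(lone, spacing = 1, padding = 6)
  tun <- find_tunnels(grid, c(30, 30, 24))
  expect_gt(length(tun), 0)
  expect_equal(classify_site(tun)$label, "open")
})

test_that("bottlenecks equal the exhaustive widest-path oracle", {
  set.seed(104)
  for (rep in 1:3) {
    atoms <- data.frame(x = rnorm(12, 0, 3), y = rnorm(12, 0, 3),
                        z = rnorm(12, 0, 3), radius = runif(12, 1.2, 2.5))
    grid <- build_grid(atoms, spacing = 1.0, padding = 2)
    # quantize the clearance field so the oracle's level scan stays small;
    # both methods then see the identical field
    grid$clearance <- round(grid$clearance, 1)
    expect_lte(max(grid$dims), 30)
    start_pt <- c(6, 6, 6)
    sv <- crypticsite:::voxel_index(grid, start_pt)
    if (grid$clearance[sv] <= 0) next
    bnd <- crypticsite:::boundary_mask(grid)
    oracle <- oracle_widest_bottleneck(grid$clearance, grid$dims, sv, bnd)
    tun <- find_tunnels(grid, start_pt)
    got <- if (length(tun) == 0) 0 else tun[[1]]$bottleneck
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("bottlenecks shrink when atom radii dilate", {
  slab <- slab_with_channel(2.5)
  g1 <- build_grid(slab, spacing = 0.5, padding = 3)
  b1 <- find_tunnels(g1, c(0, 0, 0))[[1]]$bottleneck
  slab2 <- slab; slab2$radius <- slab2$radius + 0.5
  g2 <- build_grid(slab2, spacing = 0.5, padding = 3)
  b2 <- find_tunnels(g2, c(0, 0, 0))[[1]]$bottleneck
  expect_lte(b2, b1)
})

test_that("classification thresholds are honoured, with indeterminate gap", {
  cfg <- accessibility_config()
  mk <- function(b) list(structure(list(bottleneck = b, path = NULL,
                                        length = 0, exit_face = "z+"),
                                   class = "tunnel_result"))
  expect_equal(classify_site(mk(3.0), cfg)$label, "open")
  expect_equal(classify_site(mk(1.2), cfg)$label, "buried")
  expect_equal(classify_site(mk(1.7), cfg)$label, "indeterminate")
  expect_error(accessibility_config(open = 1, buried = 2), ">=")
  # threshold monotonicity: raising 'open' never converts buried -> open
  for (b in c(0.5, 1.6, 2.4)) {
    l1 <- classify_site(mk(b), accessibility_config(2.0, 1.5))$label
    l2 <- classify_site(mk(b), accessibility_config(3.0, 1.5))$label
    expect_false(l1 == "buried" && l2 == "open")
    if (l1 == "buried") expect_equal(l2, "buried")
  }
})

test_that("pocket volumes approximate analytic cavity volumes", {
  # hollow cube: walls of small atoms enclosing a 10 A void
  s <- 1.0
  w <- expand.grid(x = seq(-6, 6, by = 1.2), y = seq(-6, 6, by = 1.2),
                   z = seq(-6, 6, by = 1.2))
  inner <- abs(w$x) < 5 & abs(w$y) < 5 & abs(w$z) < 5
  shelled <- w[!inner & abs(w$x) <= 6 & abs(w$y) <= 6 & abs(w$z) <= 6, ]
  walls <- data.frame(shelled, radius = s)
  grid <- build_grid(walls, spacing = 0.5, padding = 3)
  vol <- pocket_volume(grid, c(0, 0, 0), region_radius = 9,
                       probe_radius = 0.5)
  # interior clear of the probe: roughly an 8.6^3 box after wall standoff
  expect_gt(vol, 450)
  expect_lt(vol, 1100)
  # solid region -> zero volume
  solid <- data.frame(x = 0, y = 0, z = 0, radius = 4)
  gs <- build_grid(solid, spacing = 0.5, padding = 3)
  expect_equal(pocket_volume(gs, c(0, 0, 0), 2, 0.3), 0)
})

test_that("sphere-cavity volume matches quadrature and the r^3 law", {
  rec <- build_sphere_receptor(list(list(center = c(0, 0, 0),
                                         channel_radius = 0)),
                               shell_radius = 6, shell_spacing = 2.0)
  grid <- build_grid(rec, spacing = 0.5)
  vol <- pocket_volume(grid, c(0, 0, 0), region_radius = 8,
                       probe_radius = 0)
  # fine-lattice quadrature of the accessible cavity: direct min-over-atom
  # arithmetic at 0.25 A, no grid machinery
  h <- 0.25
  pts <- as.matrix(expand.grid(x = seq(-6, 6, by = h),
                               y = seq(-6, 6, by = h),
                               z = seq(-6, 6, by = h)))
  pts <- pts[rowSums(pts^2) <= 6^2, ]
  A <- as.matrix(rec$atoms[, c("x", "y", "z")])
  inside <- vapply(seq_len(nrow(pts)), function(i)
    min(sqrt(colSums((t(A) - pts[i, ])^2)) - rec$atom_radius) >= 0,
    logical(1))
  quad_vol <- sum(inside) * h^3
  expect_equal(vol, quad_vol, tolerance = 0.05)
  # nominal cavity radius = shell radius - atom radius; lattice gaps make
  # the accessible cavity slightly larger than the ideal sphere
  expect_equal(vol, 4 / 3 * pi * (6 - rec$atom_radius)^3, tolerance = 0.2)
})

test_that("batch curation reports planted open/buried compositions", {
  mk <- function(ch) build_sphere_receptor(
    list(list(center = c(0, 0, 0), channel_radius = ch)),
    shell_radius = 7, channel_length = 3)
  pair <- list(mk(3.0), mk(0))
  rep2 <- curate_reference_check(pair, list(c(0, 0, 0), c(0, 0, 0)),
                                 spacing = 0.6)
  expect_equal(rep2$label, c("open", "buried"))
  empty <- curate_reference_check(list(), list())
  expect_null(empty)
  bad <- suppressWarnings(
    curate_reference_check(list(mk(3.0), "no/such/file.pdb"),
                           list(c(0, 0, 0), c(0, 0, 0)), spacing = 0.6))
  expect_equal(bad$ok, c(TRUE, FALSE))
})
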