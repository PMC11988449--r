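#' Frozen van der Waals radii (Angstrom)
#'
#' Bondi-type radii for the elements the sphere models and bead systems
#' use. Bundled as fixed values so synthetic structures are bit-exact.
#'
#' @return named numeric vector of radii.
#' @export
vdw_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, Cl = 1.75, Br = 1.85)
}

# Near-uniform points on a sphere (Fibonacci lattice), radius r, n points.
fibonacci_sphere <- function(n, r = 1) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = r * sin(phi) * cos(theta),
        y = r * sin(phi) * sin(theta),
        z = r * cos(phi))
}

#' Build a sphere-model receptor with planted sub-pockets
#'
#' Constructs a bead ("one sphere per atom") receptor from one shell per
#' requested site: a densely packed spherical wall enclosing a cavity, with
#' an optional tunnel of controlled radius drilled to the exterior. The
#' tunnel is lined by stacked rings of wall atoms whose inner surface sits
#' exactly `channel_radius` from the tunnel axis, so the planted ground
#' truth -- the bottleneck radius from the cavity to bulk solvent -- is
#' known by construction. `channel_radius = 0` leaves the cavity fully
#' sealed (bottleneck 0, buried).
#'
#' @param sites list of site specifications; each a list with elements
#'   `center` (length-3, Angstrom), `channel_radius` (Angstrom, 0 = sealed),
#'   and optionally `direction` (tunnel axis, default +z), `label`
#'   ("open"/"buried"; defaults to "open" iff `channel_radius >= 2`).
#' @param shell_radius cavity radius of each shell (Angstrom).
#' @param atom_radius wall-atom radius (Angstrom); default carbon vdW.
#' @param shell_spacing target spacing of wall atoms on the shell
#'   (Angstrom); must leave inter-atom gaps narrower than any planted
#'   bottleneck so the drilled tunnel is the only passage.
#' @param channel_length tunnel length beyond the shell (Angstrom).
#' @param seed integer seed (reserved for optional jitter).
#' @param jitter_sd SD of Gaussian positional jitter applied to wall atoms
#'   (Angstrom, default 0 = deterministic).
#' @return object of class `sphere_receptor`: `atoms` data frame
#'   (`x,y,z,radius,subunit,role`), `sites` ground-truth data frame
#'   (`site,cx,cy,cz,bottleneck,label`), and the construction parameters.
#' @export
build_sphere_receptor <- function(sites, shell_radius = 8,
                                  atom_radius = unname(vdw_radii()["C"]),
                                  shell_spacing = 2.2, channel_length = 5,
                                  seed = 1L, jitter_sd = 0) {
  if (!is.list(sites) || length(sites) == 0L)
    stopf("'sites' must be a non-empty list of site specifications")
  assert_scalar_num(shell_radius, "shell_radius", positive = TRUE)
  assert_scalar_num(atom_radius, "atom_radius", positive = TRUE)
  atoms <- list()
  truth <- list()
  for (s in seq_along(sites)) {
    spec <- sites[[s]]
    ctr <- as.numeric(spec$center)
    if (length(ctr) != 3L) stopf("site %d: 'center' must have length 3", s)
    ch <- spec$channel_radius %||% 0
    if (ch < 0) stopf("site %d: channel_radius must be >= 0", s)
    if (ch > 0 && ch + 2 * atom_radius >= shell_radius)
      stopf(paste("site %d: infeasible geometry - channel radius %.2f plus",
                  "tunnel walls does not fit inside a shell of radius %.2f"),
            s, ch, shell_radius)
    dir <- spec$direction %||% c(0, 0, 1)
    dir <- dir / sqrt(sum(dir^2))
    subunit <- LETTERS[(s - 1L) %% 26L + 1L]

    n_shell <- ceiling(4 * pi * shell_radius^2 / shell_spacing^2)
    shell <- fibonacci_sphere(n_shell, shell_radius)
    role <- rep("shell", nrow(shell))
    if (ch > 0) {
      # drill: drop shell atoms inside the tunnel footprint (+dir side)
      t_ax <- drop(shell %*% dir)
      perp <- sqrt(pmax(rowSums(shell^2) - t_ax^2, 0))
      keep <- !(t_ax > 0 & perp < ch + 2.2 * atom_radius)
      shell <- shell[keep, , drop = FALSE]
      role <- role[keep]
      # line the tunnel with staggered atom rings of inner radius ch
      rho <- ch + atom_radius
      m <- max(6L, ceiling(2 * pi * rho / 1.2))
      e1 <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- e1 - sum(e1 * dir) * dir; e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(dir[2] * e1[3] - dir[3] * e1[2],
              dir[3] * e1[1] - dir[1] * e1[3],
              dir[1] * e1[2] - dir[2] * e1[1])
      t_vals <- seq(shell_radius - 2 * atom_radius,
                    shell_radius + channel_length, by = 1.0)
      for (i in seq_along(t_vals)) {
        ang <- 2 * pi * (seq_len(m) - 1) / m + (i %% 2) * pi / m
        ring <- t_vals[i] * matrix(dir, m, 3, byrow = TRUE) +
          rho * (cos(ang) %o% e1 + sin(ang) %o% e2)
        shell <- rbind(shell, ring)
        role <- c(role, rep("channel", m))
      }
    }
    shell <- sweep(shell, 2, ctr, `+`)
    atoms[[s]] <- data.frame(x = shell[, 1], y = shell[, 2], z = shell[, 3],
                             radius = atom_radius, subunit = subunit,
                             role = role, stringsAsFactors = FALSE)
    truth[[s]] <- data.frame(
      site = s, cx = ctr[1], cy = ctr[2], cz = ctr[3], bottleneck = ch,
      label = spec$label %||% (if (ch >= 2) "open" else "buried"),
      stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, atoms)
  if (jitter_sd > 0) {
    jit <- with_seed(as.integer(seed),
                     matrix(rnorm(3 * nrow(atoms), 0, jitter_sd),
                            ncol = 3))
    atoms[, c("x", "y", "z")] <- atoms[, c("x", "y", "z")] + jit
  }
  structure(list(atoms = atoms, sites = do.call(rbind, truth),
                 shell_radius = shell_radius, atom_radius = atom_radius,
                 channel_length = channel_length, seed = as.integer(seed)),
            class = "sphere_receptor")
}

#' @export
print.sphere_receptor <- function(x, ...) {
  cat(sprintf("sphere_receptor: %d atoms, %d planted site(s)\n",
              nrow(x$atoms), nrow(x$sites)))
  print(x$sites, row.names = FALSE)
  invisible(x)
}

#' Ground-truth annotations of a sphere receptor
#'
#' @param receptor a [build_sphere_receptor()] result.
#' @return data frame with site centres, planted bottleneck radii and
#'   open/buried labels.
#' @export
receptor_ground_truth <- function(receptor) receptor$sites

#' Write a sphere receptor as PDB
#'
#' One HETATM sphere per wall atom; subunits map to chain identifiers.
#'
#' @param receptor a [build_sphere_receptor()] result.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_receptor_pdb <- function(receptor, file) {
  a <- receptor$atoms
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("HETATM", nrow(a)),
                   resno = seq_len(nrow(a)),
                   resid = rep("SPH", nrow(a)),
                   chain = a$subunit,
                   elety = rep("C", nrow(a)),
                   elesy = rep("C", nrow(a)))
  invisible(file)
}

#' Write ground-truth site annotations as JSON
#'
#' @param receptor a [build_sphere_receptor()] result.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_ground_truth_json <- function(receptor, file) {
  jsonlite::write_json(receptor$sites, file, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(file)
}
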