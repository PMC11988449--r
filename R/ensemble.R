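#' Conformational ensemble container
#'
#' Holds a multi-frame bead or atomic model: coordinates as a frames x 3N
#' matrix (bio3d xyz convention, Angstrom) plus a per-atom table. All
#' featurization and screening operations take this container.
#'
#' @param xyz numeric matrix, one frame per row, columns x1,y1,z1,x2,...
#' @param atom data frame with one row per atom; must contain `elety`
#'   (atom name), `resid`, `resno`, `chain`; optional `elesy` (element).
#' @return object of class `conformation_ensemble`.
#' @export
conformation_ensemble <- function(xyz, atom) {
  xyz <- rbind(xyz)
  if (!is.numeric(xyz) || any(!is.finite(xyz)))
    stopf("'xyz' must be a finite numeric matrix")
  need <- c("elety", "resid", "resno", "chain")
  if (!all(need %in% names(atom)))
    stopf("'atom' must contain columns %s", paste(need, collapse = ", "))
  if (ncol(xyz) != 3L * nrow(atom))
    stopf("'xyz' has %d columns but 'atom' describes %d atoms",
          ncol(xyz), nrow(atom))
  if (is.null(atom$elesy))
    atom$elesy <- toupper(substr(gsub("^[0-9]", "", atom$elety), 1, 1))
  structure(list(xyz = xyz, atom = atom), class = "conformation_ensemble")
}

#' @export
print.conformation_ensemble <- function(x, ...) {
  cat(sprintf("conformation_ensemble: %d frames x %d atoms (%d chains)\n",
              nrow(x$xyz), nrow(x$atom), length(unique(x$atom$chain))))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble a [conformation_ensemble()].
#' @return integer frame count.
#' @export
n_frames <- function(ensemble) nrow(ensemble$xyz)

#' Coordinates of one frame
#' @param ensemble a [conformation_ensemble()].
#' @param i frame index.
#' @return N x 3 coordinate matrix.
#' @export
frame_coords <- function(ensemble, i) {
  matrix(ensemble$xyz[i, ], ncol = 3, byrow = TRUE,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Select atom indices by chain, residue and element
#'
#' @param ensemble a [conformation_ensemble()].
#' @param chain,resno,resid optional filters (vectors; `NULL` = no filter).
#' @param heavy drop hydrogens (element H)?
#' @return integer atom indices.
#' @export
select_atoms <- function(ensemble, chain = NULL, resno = NULL, resid = NULL,
                         heavy = FALSE) {
  a <- ensemble$atom
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (heavy) keep <- keep & a$elesy != "H"
  which(keep)
}

#' Read a (multi-model) PDB file as an ensemble
#'
#' @param file PDB path; MODEL records become frames.
#' @return a [conformation_ensemble()].
#' @export
read_ensemble_pdb <- function(file) {
  pdb <- bio3d::read.pdb(file, multi = TRUE)
  xyz <- pdb$xyz
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  conformation_ensemble(unclass(xyz),
                        pdb$atom[, c("elety", "resid", "resno", "chain",
                                     "elesy")])
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param ensemble a [conformation_ensemble()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, file) {
  a <- ensemble$atom
  bio3d::write.pdb(file = file, xyz = ensemble$xyz,
                   resno = a$resno, resid = a$resid, chain = a$chain,
                   elety = a$elety, elesy = a$elesy)
  invisible(file)
}

#' Map toy-trajectory coordinates onto a pentameric bead model
#'
#' Embeds 2D toy dynamics into 3D bead coordinates mimicking a pentamer
#' whose loop beads move radially outward as the slow coordinate grows:
#' five (by default) subunits sit on a ring; each carries `n_wall` fixed
#' wall beads and `n_loop` loop beads displaced outward by
#' `base_distance + x`, with the fast toy coordinate mapped to a small
#' tangential displacement. Loop-wall nearest-atom distances therefore
#' track `base_distance + x`, mirroring how omega-loop-to-beta-strand
#' distances report pocket opening.
#'
#' @param xyz toy coordinates: matrix with >= 1 column (column 1 is the
#'   slow "opening" coordinate), or a `toy_trajectory`.
#' @param n_subunits number of subunits.
#' @param n_loop,n_wall beads per loop / wall per subunit.
#' @param base_distance closed-state loop-wall distance (Angstrom).
#' @param ring_radius pentamer ring radius (Angstrom).
#' @return a [conformation_ensemble()]; loop beads are residues `LOP`
#'   (resno 101...), wall beads `WAL` (resno 1...), chains A, B, ...
#' @export
toy_embed <- function(xyz, n_subunits = 5, n_loop = 1, n_wall = 1,
                      base_distance = 4, ring_radius = 10) {
  if (inherits(xyz, "toy_trajectory")) xyz <- xyz$xyz
  xyz <- rbind(xyz)
  xcoord <- xyz[, 1]
  ycoord <- if (ncol(xyz) >= 2) xyz[, 2] else rep(0, nrow(xyz))
  nf <- nrow(xyz)
  atom <- list(); cols <- list()
  for (s in seq_len(n_subunits)) {
    th <- 2 * pi * (s - 1) / n_subunits
    u <- c(cos(th), sin(th), 0)   # radial
    tv <- c(-sin(th), cos(th), 0) # tangential
    for (w in seq_len(n_wall)) {
      off <- (w - (n_wall + 1) / 2) * 1.5
      pos <- matrix(ring_radius * u + off * tv + c(0, 0, 0.5 * (w - 1)),
                    nf, 3, byrow = TRUE)
      atom[[length(atom) + 1]] <- data.frame(
        elety = "CA", resid = "WAL", resno = w,
        chain = LETTERS[s], elesy = "C")
      cols[[length(cols) + 1]] <- pos
    }
    for (l in seq_len(n_loop)) {
      off <- (l - (n_loop + 1) / 2) * 1.5
      r <- ring_radius + base_distance + xcoord
      pos <- cbind(r * u[1] + (off + 0.3 * ycoord) * tv[1],
                   r * u[2] + (off + 0.3 * ycoord) * tv[2],
                   0.5 * (l - 1))
      atom[[length(atom) + 1]] <- data.frame(
        elety = "CA", resid = "LOP", resno = 100 + l,
        chain = LETTERS[s], elesy = "C")
      cols[[length(cols) + 1]] <- pos
    }
  }
  xyzm <- do.call(cbind, lapply(cols, function(p) p))
  # interleave into frames x 3N (each element of cols is nf x 3)
  conformation_ensemble(xyzm, do.call(rbind, atom))
}
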