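#' Contact-analysis configuration
#'
#' Defaults follow the convention used throughout the workflow: a contact
#' is counted when any two atoms of ligand and residue are within 4
#' Angstrom, and a residue is "interacting" when its contact frequency
#' exceeds 50%.
#'
#' @param cutoff atom-atom distance cutoff (Angstrom, > 0).
#' @param threshold contact-frequency threshold in `[0, 1]`.
#' @return object of class `contact_config`.
#' @export
contact_config <- function(cutoff = 4.0, threshold = 0.5) {
  assert_scalar_num(cutoff, "cutoff", positive = TRUE)
  if (threshold < 0 || threshold > 1) stopf("'threshold' must be in [0,1]")
  structure(list(cutoff = cutoff, threshold = threshold),
            class = "contact_config")
}

#' Hydrogen-bond geometric criteria
#'
#' A hydrogen bond requires donor-acceptor distance below `dist_cutoff`
#' and a donor-hydrogen-acceptor angle above `angle_cutoff`.
#'
#' @param dist_cutoff D-A distance cutoff (Angstrom, default 3.0).
#' @param angle_cutoff D-H-A angle cutoff (degrees, default 120).
#' @return object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(dist_cutoff = 3.0, angle_cutoff = 120) {
  assert_scalar_num(dist_cutoff, "dist_cutoff", positive = TRUE)
  if (angle_cutoff <= 0 || angle_cutoff > 180)
    stopf("'angle_cutoff' must be in (0, 180]")
  structure(list(dist_cutoff = dist_cutoff, angle_cutoff = angle_cutoff),
            class = "hbond_criteria")
}

#' Nearest-atom pairwise distance features
#'
#' For every subunit and every (loop residue, wall residue) combination,
#' the feature is the minimum Euclidean distance between any atom of the
#' loop residue and any atom of the wall residue -- nearest atoms rather
#' than C-alpha, so side-chain reorientation registers. Column order is
#' deterministic: subunit-major, then loop index, then wall index.
#'
#' @param ensemble a [conformation_ensemble()].
#' @param pair_spec list with `loop` and `wall` residue-number vectors
#'   (applied within each chain), and optionally `chains` (default: all
#'   chains, sorted).
#' @param heavy use heavy atoms only (default TRUE).
#' @return a `feature_matrix`: frames x features numeric matrix with an
#'   `index` attribute mapping columns to (subunit, loop, wall).
#' @export
pairwise_distance_features <- function(ensemble, pair_spec, heavy = TRUE) {
  if (n_frames(ensemble) < 1L) stopf("empty frame set")
  chains <- pair_spec$chains %||% sort(unique(ensemble$atom$chain))
  idx <- expand.grid(wall = pair_spec$wall, loop = pair_spec$loop,
                     subunit = chains, stringsAsFactors = FALSE)
  idx <- idx[order(match(idx$subunit, chains),
                   match(idx$loop, pair_spec$loop),
                   match(idx$wall, pair_spec$wall)), c("subunit", "loop", "wall")]
  rownames(idx) <- NULL
  nf <- n_frames(ensemble)
  out <- matrix(NA_real_, nf, nrow(idx))
  xs <- ensemble$xyz[, seq(1, ncol(ensemble$xyz), by = 3), drop = FALSE]
  ys <- ensemble$xyz[, seq(2, ncol(ensemble$xyz), by = 3), drop = FALSE]
  zs <- ensemble$xyz[, seq(3, ncol(ensemble$xyz), by = 3), drop = FALSE]
  for (p in seq_len(nrow(idx))) {
    li <- select_atoms(ensemble, chain = idx$subunit[p],
                       resno = idx$loop[p], heavy = heavy)
    wi <- select_atoms(ensemble, chain = idx$subunit[p],
                       resno = idx$wall[p], heavy = heavy)
    if (length(li) == 0L)
      stopf("missing residue %s in subunit %s", idx$loop[p], idx$subunit[p])
    if (length(wi) == 0L)
      stopf("missing residue %s in subunit %s", idx$wall[p], idx$subunit[p])
    best <- rep(Inf, nf)
    for (a in li) for (b in wi) {
      d <- sqrt((xs[, a] - xs[, b])^2 + (ys[, a] - ys[, b])^2 +
                  (zs[, a] - zs[, b])^2)
      best <- pmin(best, d)
    }
    out[, p] <- best
  }
  colnames(out) <- paste0(idx$subunit, ":", idx$loop, "-", idx$wall)
  structure(out, index = idx, class = c("feature_matrix", class(out)))
}

# Optimal rigid-body superposition (Kabsch, via SVD). Returns the rotation
# and translation mapping `mobile` onto `target` in least-squares sense.
kabsch <- function(mobile, target) {
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  s <- svd(crossprod(A, B))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(R = R, t = as.numeric(ct - R %*% cm))
}

apply_fit <- function(coords, fit) {
  sweep(coords %*% t(fit$R), 2, fit$t, `+`)
}

#' Root-mean-square deviation between two conformations
#'
#' With `superpose = TRUE` the frame is first fitted onto the reference by
#' optimal least-squares rigid-body superposition over `fit_selection`
#' (default: the RMSD selection itself), then the RMSD is computed over
#' `selection`. With `superpose = FALSE` raw coordinates are compared.
#'
#' @param frame,reference N x 3 coordinate matrices (or
#'   [conformation_ensemble()]s with a single frame).
#' @param selection integer atom indices (default: all atoms).
#' @param superpose fit before measuring?
#' @param fit_selection atoms used for the superposition fit.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(frame, reference, selection = NULL, superpose = FALSE,
                 fit_selection = NULL) {
  frame <- as_coords(frame); reference <- as_coords(reference)
  if (!all(dim(frame) == dim(reference)))
    stopf("mismatched atom counts: %d vs %d", nrow(frame), nrow(reference))
  selection <- selection %||% seq_len(nrow(frame))
  if (superpose) {
    fs <- fit_selection %||% selection
    fit <- kabsch(frame[fs, , drop = FALSE], reference[fs, , drop = FALSE])
    frame <- apply_fit(frame, fit)
  }
  d <- frame[selection, , drop = FALSE] - reference[selection, , drop = FALSE]
  sqrt(mean(rowSums(d^2)))
}

as_coords <- function(x) {
  if (inherits(x, "conformation_ensemble")) {
    if (n_frames(x) != 1L) stopf("expected a single-frame ensemble")
    return(frame_coords(x, 1))
  }
  m <- rbind(x)
  if (ncol(m) != 3L) stopf("coordinates must be an N x 3 matrix")
  m
}

#' Ligand center-of-mass displacement after receptor superposition
#'
#' Superposes the frame onto the reference over the receptor selection,
#' then reports the Euclidean distance between the ligand centers of mass.
#' This is the ligand-stability metric used by the screening filter
#' (threshold 15 Angstrom).
#'
#' @param frame,reference N x 3 coordinate matrices.
#' @param ligand_selection integer indices of ligand atoms.
#' @param receptor_selection indices used for the superposition (default:
#'   all non-ligand atoms).
#' @param superpose fit receptors first (default TRUE).
#' @return COM displacement in Angstrom.
#' @export
com_rmsd <- function(frame, reference, ligand_selection,
                     receptor_selection = NULL, superpose = TRUE) {
  frame <- as_coords(frame); reference <- as_coords(reference)
  if (length(ligand_selection) == 0L) stopf("empty ligand selection")
  receptor_selection <- receptor_selection %||%
    setdiff(seq_len(nrow(frame)), ligand_selection)
  if (superpose && length(receptor_selection) >= 3L) {
    fit <- kabsch(frame[receptor_selection, , drop = FALSE],
                  reference[receptor_selection, , drop = FALSE])
    frame <- apply_fit(frame, fit)
  }
  sqrt(sum((colMeans(frame[ligand_selection, , drop = FALSE]) -
              colMeans(reference[ligand_selection, , drop = FALSE]))^2))
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are superposed onto the ensemble mean (one fit pass against the
#' first frame, then against the resulting mean), the per-atom SD about
#' the mean position is computed, and atoms are averaged within residues.
#'
#' @param ensemble a [conformation_ensemble()] with >= 2 frames.
#' @param selection atom indices (default all).
#' @return data frame `chain`, `resno`, `rmsf` (Angstrom).
#' @export
rmsf <- function(ensemble, selection = NULL) {
  if (n_frames(ensemble) < 2L) stopf("RMSF requires >= 2 frames")
  selection <- selection %||% seq_len(nrow(ensemble$atom))
  nf <- n_frames(ensemble)
  coords <- lapply(seq_len(nf), function(i)
    frame_coords(ensemble, i)[selection, , drop = FALSE])
  ref <- coords[[1]]
  coords <- lapply(coords, function(m) apply_fit(m, kabsch(m, ref)))
  mean1 <- Reduce(`+`, coords) / nf
  coords <- lapply(coords, function(m) apply_fit(m, kabsch(m, mean1)))
  mu <- Reduce(`+`, coords) / nf
  msf <- Reduce(`+`, lapply(coords, function(m) rowSums((m - mu)^2))) / nf
  atom <- ensemble$atom[selection, ]
  out <- aggregate(sqrt(msf), by = list(chain = atom$chain,
                                        resno = atom$resno), FUN = mean)
  names(out)[3] <- "rmsf"
  out[order(out$chain, out$resno), ]
}

#' Ligand-residue contact frequencies over an ensemble
#'
#' A residue is in contact in a frame when any of its atoms lies within
#' `config$cutoff` of any ligand atom; the frequency is the fraction of
#' frames in contact.
#'
#' @param ensemble a [conformation_ensemble()].
#' @param ligand_selection integer indices of ligand atoms.
#' @param config a [contact_config()].
#' @return data frame `chain`, `resno`, `resid`, `frequency`, sorted by
#'   decreasing frequency.
#' @export
contact_frequency <- function(ensemble, ligand_selection,
                              config = contact_config()) {
  if (length(ligand_selection) == 0L) stopf("empty ligand selection")
  atom <- ensemble$atom
  rec <- setdiff(seq_len(nrow(atom)), ligand_selection)
  key <- paste(atom$chain[rec], atom$resno[rec], sep = ":")
  groups <- split(rec, key)
  nf <- n_frames(ensemble)
  hits <- setNames(numeric(length(groups)), names(groups))
  for (f in seq_len(nf)) {
    m <- frame_coords(ensemble, f)
    lig <- m[ligand_selection, , drop = FALSE]
    # distance of every receptor atom to its nearest ligand atom
    dmin <- rep(Inf, length(rec))
    for (l in seq_len(nrow(lig))) {
      d <- sqrt(rowSums(sweep(m[rec, , drop = FALSE], 2, lig[l, ])^2))
      dmin <- pmin(dmin, d)
    }
    contact <- vapply(groups, function(g)
      any(dmin[match(g, rec)] < config$cutoff), logical(1))
    hits <- hits + contact
  }
  info <- atom[vapply(groups, `[`, integer(1), 1), ]
  out <- data.frame(chain = info$chain, resno = info$resno,
                    resid = info$resid, frequency = unname(hits) / nf)
  out[order(-out$frequency, out$chain, out$resno), ]
}

#' Hydrogen-bond test from donor, hydrogen and acceptor coordinates
#'
#' True when the donor-acceptor distance is below the distance cutoff and
#' the D-H-A angle exceeds the angle cutoff.
#'
#' @param donor,hydrogen,acceptor length-3 coordinates (Angstrom).
#' @param criteria a [hbond_criteria()].
#' @return logical.
#' @export
detect_hbond <- function(donor, hydrogen, acceptor,
                         criteria = hbond_criteria()) {
  pts <- rbind(donor, hydrogen, acceptor)
  if (any(dist(pts) < 1e-9)) stopf("coincident points")
  da <- sqrt(sum((donor - acceptor)^2))
  v1 <- donor - hydrogen; v2 <- acceptor - hydrogen
  ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                             sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
  da < criteria$dist_cutoff && ang > criteria$angle_cutoff
}

#' Write a feature matrix as CSV
#'
#' @param features a `feature_matrix` from [pairwise_distance_features()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_feature_csv <- function(features, file) {
  write.csv(as.data.frame(unclass(features)), file, row.names = FALSE)
  invisible(file)
}
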