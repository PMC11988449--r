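#' Accessibility decision thresholds
#'
#' A site is called open when the best tunnel bottleneck is at least
#' `open` (solvent-accessible pockets in reference apo/holo complexes are
#' reachable via tunnels of at least 2 Angstrom radius) and buried when it
#' is below `buried` (no entry pathway wider than 1.5 Angstrom); anything
#' between is reported as indeterminate, never silently resolved.
#'
#' @param open open threshold (Angstrom).
#' @param buried buried threshold (Angstrom); `open >= buried > 0`.
#' @return object of class `accessibility_config`.
#' @export
accessibility_config <- function(open = 2.0, buried = 1.5) {
  assert_scalar_num(open, "open", positive = TRUE)
  assert_scalar_num(buried, "buried", positive = TRUE)
  if (open < buried) stopf("'open' must be >= 'buried'")
  structure(list(open = open, buried = buried),
            class = "accessibility_config")
}

# normalize structure input to a data frame x, y, z, radius
as_atom_spheres <- function(structure) {
  if (inherits(structure, "sphere_receptor")) return(structure$atoms)
  if (is.character(structure) && length(structure) == 1L) {
    pdb <- bio3d::read.pdb(structure)
    rad <- vdw_radii()
    r <- unname(rad[pdb$atom$elesy])
    r[is.na(r)] <- rad["C"]
    return(data.frame(x = pdb$atom$x, y = pdb$atom$y, z = pdb$atom$z,
                      radius = r))
  }
  structure <- as.data.frame(structure)
  if (!all(c("x", "y", "z", "radius") %in% names(structure)))
    stopf("structure must provide x, y, z, radius")
  structure
}

#' Build a clearance grid around a structure
#'
#' Regular voxel grid whose value at each voxel centre is the clearance:
#' the distance to the nearest atom *surface* (negative inside an atom).
#' The bounding box pads the structure so bulk solvent surrounds it.
#'
#' @param structure a [build_sphere_receptor()] result, a PDB path, or a
#'   data frame with `x`, `y`, `z`, `radius` (Angstrom).
#' @param spacing voxel edge (Angstrom, in (0.1, 2]).
#' @param padding box padding beyond the atom surfaces (Angstrom, at
#'   least a probe diameter).
#' @return object of class `occupancy_grid`: `clearance` (vector in x-
#'   fastest order), `dims`, `origin`, `spacing`.
#' @export
build_grid <- function(structure, spacing = 0.5, padding = 4) {
  atoms <- as_atom_spheres(structure)
  if (nrow(atoms) == 0L) stopf("empty structure")
  if (spacing <= 0.1 || spacing > 2) stopf("'spacing' must be in (0.1, 2]")
  lo <- c(min(atoms$x - atoms$radius), min(atoms$y - atoms$radius),
          min(atoms$z - atoms$radius)) - padding
  hi <- c(max(atoms$x + atoms$radius), max(atoms$y + atoms$radius),
          max(atoms$z + atoms$radius)) + padding
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  clearance <- grid_clearance_cpp(as.matrix(atoms[, c("x", "y", "z")]),
                                  atoms$radius, lo, dims, spacing)
  structure(list(clearance = clearance, dims = dims, origin = lo,
                 spacing = spacing), class = "occupancy_grid")
}

#' @export
print.occupancy_grid <- function(x, ...) {
  cat(sprintf("occupancy_grid: %d x %d x %d voxels at %.2f A\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing))
  invisible(x)
}

# nearest voxel (1-based linear index, x fastest) for a point
voxel_index <- function(grid, point) {
  ijk <- round((as.numeric(point) - grid$origin) / grid$spacing)
  if (any(ijk < 0) || any(ijk > grid$dims - 1L))
    stopf("point outside the grid")
  as.integer(1 + ijk[1] + grid$dims[1] * (ijk[2] + grid$dims[2] * ijk[3]))
}

# coordinates of voxel centres for 1-based linear indices
voxel_coords <- function(grid, idx) {
  idx0 <- idx - 1L
  i <- idx0 %% grid$dims[1]
  j <- (idx0 %/% grid$dims[1]) %% grid$dims[2]
  k <- idx0 %/% (grid$dims[1] * grid$dims[2])
  cbind(x = grid$origin[1] + i * grid$spacing,
        y = grid$origin[2] + j * grid$spacing,
        z = grid$origin[3] + k * grid$spacing)
}

boundary_mask <- function(grid) {
  d <- grid$dims
  n <- prod(d)
  idx0 <- seq_len(n) - 1L
  i <- idx0 %% d[1]
  j <- (idx0 %/% d[1]) %% d[2]
  k <- idx0 %/% (d[1] * d[2])
  i == 0L | i == d[1] - 1L | j == 0L | j == d[2] - 1L |
    k == 0L | k == d[3] - 1L
}

# largest clearance threshold at which `start` reaches any TRUE voxel of
# `targets`, searched over the sorted unique clearance levels; 6-connected
# flood fill at each candidate level. Returns 0 if unreachable at every
# positive level.
widest_threshold <- function(grid, start, targets) {
  cl <- grid$clearance
  levels <- sort(unique(cl[cl > 0 & cl <= cl[start]]))
  if (length(levels) == 0L) return(0)
  reaches <- function(thr) {
    seen <- grid_flood_cpp(cl, grid$dims, thr, as.integer(start - 1L))
    any(seen & targets)
  }
  lo <- 1L; hi <- length(levels)
  if (!reaches(levels[lo])) return(0)
  while (lo < hi) { # invariant: reaches(levels[lo]), maybe more
    mid <- (lo + hi + 1L) %/% 2L
    if (reaches(levels[mid])) lo <- mid else hi <- mid - 1L
  }
  levels[lo]
}

#' Widest-path tunnel search from a site to bulk solvent
#'
#' Finds, for each exit face of the padded bounding box, the path from the
#' start point to the box boundary that maximizes the minimum clearance
#' along the path (the bottleneck radius), via threshold search over the
#' clearance levels with 6-connected flood fills. The globally best
#' tunnel comes first. Bottlenecks are accurate to about one grid
#' spacing.
#'
#' @param grid an [build_grid()] result.
#' @param start site coordinates (typically the ligand centre of mass).
#' @param config an [accessibility_config()] (carried into results).
#' @param n_paths maximum number of distinct-exit tunnels returned.
#' @return list of `tunnel_result`s (possibly empty if the start is
#'   sealed off): each has `bottleneck` (Angstrom), `path` (voxel-centre
#'   coordinates), `length` (Angstrom), `exit_face`.
#' @export
find_tunnels <- function(grid, start, config = accessibility_config(),
                         n_paths = 6) {
  sv <- voxel_index(grid, start)
  if (grid$clearance[sv] <= 0)
    stopf("start point lies inside an atom (clearance %.2f)",
          grid$clearance[sv])
  d <- grid$dims
  n <- prod(d)
  idx0 <- seq_len(n) - 1L
  i <- idx0 %% d[1]; j <- (idx0 %/% d[1]) %% d[2]; k <- idx0 %/% (d[1] * d[2])
  faces <- list(`x-` = i == 0L, `x+` = i == d[1] - 1L,
                `y-` = j == 0L, `y+` = j == d[2] - 1L,
                `z-` = k == 0L, `z+` = k == d[3] - 1L)
  out <- list()
  for (f in names(faces)) {
    thr <- widest_threshold(grid, sv, faces[[f]])
    if (thr <= 0) next
    path_idx <- grid_bfs_path_cpp(grid$clearance, d, thr,
                                  as.integer(sv - 1L), faces[[f]]) + 1L
    if (length(path_idx) == 0L) next
    out[[length(out) + 1]] <- structure(
      list(bottleneck = thr, path = voxel_coords(grid, path_idx),
           length = (length(path_idx) - 1L) * grid$spacing,
           exit_face = f, spacing = grid$spacing),
      class = "tunnel_result")
  }
  out[order(-vapply(out, `[[`, 1, "bottleneck"))][seq_len(min(n_paths,
                                                              length(out)))]
}

#' Classify a site as open, buried or indeterminate
#'
#' Open when the best bottleneck is at least the open threshold; buried
#' when it is below the buried threshold; indeterminate in between (left
#' visible to the caller rather than silently resolved).
#'
#' @param tunnels a [find_tunnels()] result (empty list = sealed, best
#'   bottleneck 0).
#' @param config an [accessibility_config()].
#' @return list `label` ("open"/"buried"/"indeterminate") and
#'   `bottleneck` (Angstrom).
#' @export
classify_site <- function(tunnels, config = accessibility_config()) {
  best <- if (length(tunnels) == 0L) 0 else
    max(vapply(tunnels, `[[`, 1, "bottleneck"))
  label <- if (best >= config$open) "open"
    else if (best < config$buried) "buried"
    else "indeterminate"
  list(label = label, bottleneck = best)
}

#' Grid-based pocket volume
#'
#' Volume of the voxels inside a spherical query region that clear a probe
#' of the given radius and are *bounded* -- not part of bulk solvent, as
#' decided by a flood fill of probe-accessible space from the box
#' boundary.
#'
#' @param grid an [build_grid()] result.
#' @param center query-region centre.
#' @param region_radius query-region radius (Angstrom).
#' @param probe_radius probe radius (Angstrom, >= 0).
#' @return volume in cubic Angstrom.
#' @export
pocket_volume <- function(grid, center, region_radius, probe_radius = 0) {
  voxel_index(grid, center) # validates the region lies within the grid
  xyz <- voxel_coords(grid, seq_along(grid$clearance))
  in_region <- rowSums(sweep(xyz, 2, as.numeric(center))^2) <=
    region_radius^2
  bnd <- which(boundary_mask(grid))
  bulk <- grid_flood_cpp(grid$clearance, grid$dims,
                         max(probe_radius, .Machine$double.eps),
                         as.integer(bnd - 1L))
  ok <- in_region & grid$clearance >= probe_radius & !bulk
  sum(ok) * grid$spacing^3
}

#' Batch accessibility report over candidate structures
#'
#' Runs grid construction, tunnel search and classification for each
#' (structure, site) pair -- e.g. a curated set of ligand-bound complexes
#' -- and tabulates labels. Unreadable structures are skipped and logged
#' in the report.
#'
#' @param structures list of structures ([build_sphere_receptor()]
#'   results, PDB paths, or sphere data frames).
#' @param sites list of site centres (length-3 vectors), one per
#'   structure.
#' @param spacing grid spacing (Angstrom).
#' @param config an [accessibility_config()].
#' @return data frame `structure`, `bottleneck`, `label`, `ok`.
#' @export
curate_reference_check <- function(structures, sites, spacing = 0.5,
                                   config = accessibility_config()) {
  if (length(structures) != length(sites))
    stopf("'structures' and 'sites' lengths differ")
  rows <- lapply(seq_along(structures), function(i) {
    res <- tryCatch({
      grid <- build_grid(structures[[i]], spacing = spacing)
      cls <- classify_site(find_tunnels(grid, sites[[i]], config), config)
      data.frame(structure = i, bottleneck = cls$bottleneck,
                 label = cls$label, ok = TRUE)
    }, error = function(e) {
      warnf("structure %d skipped: %s", i, conditionMessage(e))
      data.frame(structure = i, bottleneck = NA_real_,
                 label = NA_character_, ok = FALSE)
    })
    res
  })
  do.call(rbind, rows)
}

#' Write a tunnel path as a PDB pseudo-atom trace
#'
#' @param tunnel a `tunnel_result`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_tunnel_pdb <- function(tunnel, file) {
  p <- tunnel$path
  bio3d::write.pdb(file = file, xyz = as.numeric(t(p)),
                   type = rep("HETATM", nrow(p)),
                   resno = seq_len(nrow(p)), resid = rep("TUN", nrow(p)),
                   chain = rep("T", nrow(p)), elety = rep("O", nrow(p)),
                   elesy = rep("O", nrow(p)))
  invisible(file)
}
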