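#' Construct a toy multi-well potential
#'
#' Defines the energy landscape used by the synthetic Brownian-dynamics
#' engine: a sum of inverted Gaussian wells on a quadratic confinement,
#' \deqn{U(x) = \tfrac12 k_c |x|^2 - \sum_j A_j \exp(-|x-c_j|^2 / 2w_j^2).}
#' The form is bounded below and its Boltzmann weight is integrable, so the
#' stationary distribution of overdamped dynamics on it is known exactly up
#' to a quadrature constant. Well depths are in kT units when `kT = 1`.
#'
#' @param centers numeric matrix, one well centre per row (nm).
#' @param depths positive numeric vector, well depths `A_j` (kT units).
#' @param widths positive numeric vector, Gaussian widths `w_j` (nm).
#' @param k_confine confinement spring constant (kT/nm^2).
#' @param open_well index of the well designated as the "open-pocket" basin
#'   (the slow, goal state of adaptive sampling), or `NA`.
#' @return object of class `toy_potential`.
#' @seealso [three_well_potential()], [simulate_brownian()]
#' @export
toy_potential <- function(centers, depths, widths, k_confine = 0.05,
                          open_well = NA_integer_) {
  centers <- rbind(centers)
  storage.mode(centers) <- "double"
  if (nrow(centers) < 1L) stopf("at least one well is required")
  if (length(depths) != nrow(centers) || length(widths) != nrow(centers))
    stopf("'depths' and 'widths' must have one entry per well")
  if (any(!is.finite(centers)) || any(!is.finite(depths)) ||
      any(!is.finite(widths)))
    stopf("well parameters must be finite")
  if (any(depths <= 0) || any(widths <= 0))
    stopf("well depths and widths must be > 0")
  assert_scalar_num(k_confine, "k_confine")
  if (k_confine < 0) stopf("'k_confine' must be >= 0")
  structure(
    list(dim = ncol(centers), centers = centers,
         depths = as.numeric(depths), widths = as.numeric(widths),
         k_confine = k_confine, open_well = open_well),
    class = "toy_potential")
}

#' Default three-basin pocket-opening landscape
#'
#' A 2D landscape with three metastable basins along a slow x coordinate:
#' closed (x = 0), intermediate (x = 2) and open-pocket (x = 4). Adjacent
#' basins are separated by barriers well above 3 kT, so spontaneous opening
#' is a rare event at kT = 1 and pocket opening is a genuinely slow
#' transition that adaptive sampling has to earn.
#'
#' @param depth_closed,depth_mid,depth_open well depths (kT).
#' @param width Gaussian width shared by the wells (nm).
#' @return a [toy_potential()].
#' @export
three_well_potential <- function(depth_closed = 9, depth_mid = 8,
                                 depth_open = 9, width = 0.55) {
  toy_potential(
    centers = rbind(c(0, 0), c(2, 0), c(4, 0)),
    depths = c(depth_closed, depth_mid, depth_open),
    widths = rep(width, 3), k_confine = 0.05, open_well = 3L)
}

#' Potential energy at given coordinates
#'
#' @param potential a [toy_potential()].
#' @param x numeric vector (one point) or matrix (points in rows).
#' @return numeric vector of energies (kT units at kT = 1).
#' @export
potential_energy <- function(potential, x) {
  x <- rbind(x)
  if (ncol(x) != potential$dim) stopf("'x' must have %d columns", potential$dim)
  u <- 0.5 * potential$k_confine * rowSums(x^2)
  for (j in seq_len(nrow(potential$centers))) {
    d2 <- rowSums(sweep(x, 2, potential$centers[j, ])^2)
    u <- u - potential$depths[j] * exp(-d2 / (2 * potential$widths[j]^2))
  }
  u
}

#' Force (negative gradient) of a toy potential
#'
#' @inheritParams potential_energy
#' @return matrix of forces, one row per input point.
#' @export
potential_force <- function(potential, x) {
  x <- rbind(x)
  f <- -potential$k_confine * x
  for (j in seq_len(nrow(potential$centers))) {
    dx <- sweep(x, 2, potential$centers[j, ])
    w2 <- potential$widths[j]^2
    g <- potential$depths[j] * exp(-rowSums(dx^2) / (2 * w2)) / w2
    f <- f - dx * g
  }
  f
}

#' @export
print.toy_potential <- function(x, ...) {
  cat(sprintf("toy_potential: %d wells in %dD, k_confine = %g\n",
              nrow(x$centers), x$dim, x$k_confine))
  for (j in seq_len(nrow(x$centers)))
    cat(sprintf("  well %d: centre (%s), depth %.2f kT, width %.2f%s\n", j,
                paste(format(x$centers[j, ]), collapse = ", "),
                x$depths[j], x$widths[j],
                if (identical(j, as.integer(x$open_well))) "  [open-pocket]"
                else ""))
  invisible(x)
}
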