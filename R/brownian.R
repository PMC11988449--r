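#' Simulate overdamped Brownian dynamics on a toy potential
#'
#' Euler-Maruyama integration of the overdamped Langevin equation
#' \deqn{x_{t+1} = x_t + F(x_t)\,\Delta t + \sqrt{2 kT \Delta t}\,\eta_t}
#' with unit friction and mobility, so the long-run empirical density
#' converges to the Boltzmann distribution `exp(-U/kT)`. Identical seed and
#' inputs reproduce the trajectory bit-exactly.
#'
#' The timestep must keep the single-step noise displacement small relative
#' to the well geometry; a guard refuses timesteps whose per-coordinate
#' displacement SD exceeds 0.2 times the minimum well separation.
#'
#' @param potential a [toy_potential()].
#' @param n_steps number of integration steps (>= 1).
#' @param timestep integration timestep (reduced units).
#' @param kT thermal energy (reduced units).
#' @param seed integer seed.
#' @param x0 starting coordinates; defaults to the first well centre.
#' @return object of class `toy_trajectory`: list with `xyz` (matrix,
#'   `n_steps + 1` rows), `timestep`, `kT`, `seed`.
#' @export
simulate_brownian <- function(potential, n_steps, timestep = 0.01, kT = 1,
                              seed = 1L, x0 = NULL) {
  if (!inherits(potential, "toy_potential")) stopf("'potential' must be a toy_potential")
  if (n_steps < 1) stopf("'n_steps' must be >= 1")
  assert_scalar_num(timestep, "timestep", positive = TRUE)
  assert_scalar_num(kT, "kT", positive = TRUE)
  if (is.null(x0)) x0 <- potential$centers[1, ]
  if (length(x0) != potential$dim) stopf("'x0' must have length %d", potential$dim)
  if (nrow(potential$centers) > 1L) {
    seps <- dist(potential$centers)
    min_sep <- min(seps[seps > 0], Inf)
    if (is.finite(min_sep) && sqrt(2 * kT * timestep) > 0.2 * min_sep)
      stopf(paste("timestep too large: single-step displacement SD %.3g",
                  "exceeds 0.2 x minimum well separation %.3g"),
            sqrt(2 * kT * timestep), min_sep)
  }
  xyz <- with_seed(as.integer(seed), {
    bd_integrate(potential$centers, potential$depths, potential$widths,
                 potential$k_confine, as.numeric(x0), as.integer(n_steps),
                 timestep, kT)
  })
  structure(list(xyz = xyz, timestep = timestep, kT = kT,
                 seed = as.integer(seed)),
            class = "toy_trajectory")
}

#' @export
print.toy_trajectory <- function(x, ...) {
  cat(sprintf("toy_trajectory: %d frames in %dD, dt = %g, kT = %g, seed = %d\n",
              nrow(x$xyz), ncol(x$xyz), x$timestep, x$kT, x$seed))
  invisible(x)
}

#' Assign toy-trajectory frames to potential wells
#'
#' A frame belongs to the well whose centre is nearest, provided it lies
#' within `capture` widths of that centre; otherwise it is in transit
#' (state 0). Used to define basin occupancy and first-passage events.
#'
#' @param potential a [toy_potential()].
#' @param xyz coordinate matrix (frames in rows).
#' @param capture capture radius in units of the well width.
#' @return integer vector of well indices (0 = no well).
#' @export
assign_wells <- function(potential, xyz, capture = 2) {
  xyz <- rbind(xyz)
  d2 <- sapply(seq_len(nrow(potential$centers)), function(j)
    rowSums(sweep(xyz, 2, potential$centers[j, ])^2))
  d2 <- rbind(d2)
  best <- max.col(-d2, ties.method = "first")
  r <- sqrt(d2[cbind(seq_len(nrow(xyz)), best)])
  ifelse(r <= capture * potential$widths[best], best, 0L)
}
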