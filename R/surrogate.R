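#' Surrogate docking-score model
#'
#' Emulates a docking engine that returns one best-scored pose per protein
#' conformation: the raw score is linear in a per-frame pocket-openness
#' coordinate plus Gaussian noise,
#' \deqn{g_i = g_0 - \mathrm{slope}\cdot\mathrm{openness}_i + \epsilon_i,
#'   \quad \epsilon_i \sim N(0, \mathrm{sd}).}
#' More-open conformations therefore receive, in expectation, more
#' favourable (lower) scores.
#'
#' @param g0 baseline score (kcal/mol).
#' @param slope openness coupling (kcal/mol per openness unit, >= 0 for a
#'   pocket that favours the ligand when open).
#' @param noise_sd score noise SD (kcal/mol, >= 0).
#' @param seed integer seed.
#' @return object of class `surrogate_score_model`.
#' @export
surrogate_score_model <- function(g0 = -4, slope = 1, noise_sd = 0.5,
                                  seed = 1L) {
  assert_scalar_num(g0, "g0"); assert_scalar_num(slope, "slope")
  assert_scalar_num(noise_sd, "noise_sd")
  if (noise_sd < 0) stopf("'noise_sd' must be >= 0")
  structure(list(g0 = g0, slope = slope, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "surrogate_score_model")
}

#' Generate surrogate docking scores from an openness series
#'
#' @param openness numeric vector, per-frame pocket openness.
#' @param model a [surrogate_score_model()].
#' @return data frame `conformation`, `openness`, `score` (kcal/mol);
#'   CSV-writable, one row per conformation.
#' @export
surrogate_scores <- function(openness, model) {
  if (!inherits(model, "surrogate_score_model"))
    stopf("'model' must be a surrogate_score_model")
  if (any(!is.finite(openness))) stopf("'openness' must be finite")
  eps <- if (model$noise_sd > 0)
    with_seed(model$seed, rnorm(length(openness), 0, model$noise_sd))
  else rep(0, length(openness))
  data.frame(conformation = seq_along(openness),
             openness = as.numeric(openness),
             score = model$g0 - model$slope * openness + eps)
}

#' Evaluate the Hill concentration-response equation
#'
#' \deqn{Y = R_{basal} + \frac{R_{max} - R_{basal}}
#'   {1 + 10^{(\log_{10} EC_{50} - \log_{10} X)\, n_H}}}
#'
#' @param x concentrations (> 0).
#' @param ec50 half-maximal effective concentration (> 0).
#' @param nH Hill coefficient.
#' @param r_basal,r_max baseline and maximal responses.
#' @return responses at `x`.
#' @export
hill_response <- function(x, ec50, nH, r_basal = 0, r_max = 1) {
  assert_scalar_num(ec50, "ec50", positive = TRUE)
  if (any(x <= 0)) stopf("concentrations must be > 0")
  r_basal + (r_max - r_basal) / (1 + 10^((log10(ec50) - log10(x)) * nH))
}

#' Synthesize a noisy concentration-response table
#'
#' Hill-equation responses ([hill_response()]) with additive Gaussian
#' noise, the data-generating process for testing the dose-response fitter.
#'
#' @inheritParams hill_response
#' @param concentrations agonist concentrations (> 0).
#' @param noise_sd additive response noise SD (>= 0).
#' @param seed integer seed.
#' @param replicates independent noisy replicates per concentration.
#' @return data frame `replicate`, `concentration`, `response`.
#' @export
synth_dose_response <- function(ec50, nH, r_basal, r_max, concentrations,
                                noise_sd = 0, seed = 1L, replicates = 1L) {
  if (r_max < r_basal) stopf("'r_max' must be >= 'r_basal'")
  if (noise_sd < 0) stopf("'noise_sd' must be >= 0")
  y0 <- hill_response(concentrations, ec50, nH, r_basal, r_max)
  n <- length(concentrations)
  eps <- if (noise_sd > 0)
    with_seed(as.integer(seed), rnorm(n * replicates, 0, noise_sd))
  else rep(0, n * replicates)
  data.frame(replicate = rep(seq_len(replicates), each = n),
             concentration = rep(concentrations, replicates),
             response = rep(y0, replicates) + eps)
}

#' Simulate a ligand center-of-mass displacement trace
#'
#' Toy replicate trajectories for exercising the stability filter: a
#' stable ligand diffuses in a bounded (Ornstein-Uhlenbeck) well around
#' its docked position, while an unstable one drifts away and escapes far
#' beyond the 15-Angstrom stability threshold.
#'
#' @param n_steps trace length.
#' @param stable bounded diffusion (TRUE) or escaping drift (FALSE).
#' @param seed integer seed.
#' @param sd stationary displacement SD of the stable trace (Angstrom).
#' @param escape_rate outward drift of the unstable trace
#'   (Angstrom/step).
#' @return numeric COM-displacement trace (Angstrom, >= 0).
#' @export
simulate_ligand_trace <- function(n_steps, stable = TRUE, seed = 1L,
                                  sd = 1.5, escape_rate = 0.25) {
  if (n_steps < 1) stopf("'n_steps' must be >= 1")
  with_seed(as.integer(seed), {
    if (stable) {
      # OU in 3D, theta dt = 0.1: stationary per-axis SD = sd/sqrt(3)
      ax <- sd / sqrt(3)
      x <- matrix(0, n_steps, 3)
      prev <- rnorm(3, 0, ax)
      noise_sd <- ax * sqrt(1 - 0.9^2)
      for (t in seq_len(n_steps)) {
        prev <- 0.9 * prev + rnorm(3, 0, noise_sd)
        x[t, ] <- prev
      }
      sqrt(rowSums(x^2))
    } else {
      drift <- cumsum(rep(escape_rate, n_steps))
      pmax(drift + cumsum(rnorm(n_steps, 0, 0.3)), 0)
    }
  })
}
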