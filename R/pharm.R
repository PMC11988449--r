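#' Fit the Hill concentration-response equation
#'
#' Nonlinear least squares on
#' \deqn{Y = R_{basal} + \frac{R_{max} - R_{basal}}
#'   {1 + 10^{(\log_{10}EC_{50} - \log_{10}X)\,n_H}}}
#' parameterized in `logEC50` for stability, with multi-start
#' initialization (a grid of `logEC50` values across the data range
#' crossed with Hill coefficients 0.5, 1, 2, 4) and Levenberg-Marquardt
#' optimization; the lowest-residual converged start wins.
#'
#' @param concentrations agonist concentrations (> 0; >= 4 distinct
#'   values required).
#' @param responses measured responses, same length.
#' @param weights optional per-point weights.
#' @return object of class `dose_response_fit`: `r_basal`, `r_max`,
#'   `ec50`, `log_ec50`, `nH`, `se` (named vector of parameter SEs),
#'   `rss`, `converged`, and the fitted [stats::nls] object as `fit`.
#' @export
fit_hill <- function(concentrations, responses, weights = NULL) {
  if (length(concentrations) != length(responses))
    stopf("lengths of concentrations and responses differ")
  if (any(concentrations <= 0)) stopf("concentrations must be > 0")
  if (any(!is.finite(responses))) stopf("responses must be finite")
  if (length(unique(concentrations)) < 4L)
    stopf("need >= 4 distinct concentrations")
  df <- data.frame(lx = log10(concentrations), y = responses)
  w <- weights %||% rep(1, nrow(df))
  starts <- expand.grid(
    log_ec50 = seq(min(df$lx), max(df$lx), length.out = 5),
    nH = c(0.5, 1, 2, 4))
  ry <- range(responses)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ r_basal + (r_max - r_basal) / (1 + 10^((log_ec50 - lx) * nH)),
        data = df, weights = w,
        start = list(r_basal = ry[1], r_max = ry[2],
                     log_ec50 = starts$log_ec50[s], nH = starts$nH[s]),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stopf("Hill fit failed to converge from any start")
  cf <- coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 4), names(cf)))
  structure(list(r_basal = unname(cf["r_basal"]),
                 r_max = unname(cf["r_max"]),
                 log_ec50 = unname(cf["log_ec50"]),
                 ec50 = unname(10^cf["log_ec50"]),
                 nH = unname(cf["nH"]), se = se, rss = best$rss,
                 converged = TRUE, fit = best$fit),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf(paste0("dose_response_fit: EC50 = %.4g, nH = %.3f, ",
                     "R_basal = %.4g, R_max = %.4g (RSS %.3g)\n"),
              x$ec50, x$nH, x$r_basal, x$r_max, x$rss))
  invisible(x)
}

#' Concentration giving a chosen fraction of the maximal effect
#'
#' Inverts the Hill equation:
#' \eqn{X = EC_{50}\,(f/(1-f))^{1/n_H}}. `fraction = 0.2` gives the EC20
#' used for submaximal agonist pulses; `fraction = 0.5` returns EC50
#' exactly.
#'
#' @param fit a [fit_hill()] result (or any list with `ec50` and `nH`).
#' @param fraction target effect fraction in (0, 1).
#' @return concentration in the units of the fitted data.
#' @export
ec_fraction <- function(fit, fraction) {
  if (fraction <= 0 || fraction >= 1) stopf("'fraction' must be in (0, 1)")
  fit$ec50 * (fraction / (1 - fraction))^(1 / fit$nH)
}

#' Percent modulation of a submaximal agonist response
#'
#' \eqn{\%\,\mathrm{modulation} = (R_A - R_0)/R_0 \times 100}, where
#' `R0` is the response to the EC20 agonist pulse alone and `RA` the
#' response to agonist plus modulator.
#'
#' @param R0 control response (> 0).
#' @param RA response with modulator.
#' @return percent modulation (positive = potentiation).
#' @export
percent_modulation <- function(R0, RA) {
  if (any(R0 <= 0)) stopf("'R0' must be > 0")
  (RA - R0) / R0 * 100
}

#' Per-concentration comparison of two response groups
#'
#' Mean +/- SEM per group and an unpaired two-sided Student's t test
#' (equal variances) at each concentration; p-values are reported
#' unadjusted. Degenerate (zero-variance) concentrations are flagged with
#' `NA` statistics rather than dropped.
#'
#' @param wt,mutant data frames with columns `concentration` and
#'   `response` (>= 2 records per group per concentration).
#' @return data frame `concentration`, `mean_wt`, `sem_wt`, `mean_mut`,
#'   `sem_mut`, `t`, `p`, `significant` (p < 0.05).
#' @export
compare_groups <- function(wt, mutant) {
  concs <- sort(unique(c(wt$concentration, mutant$concentration)))
  rows <- lapply(concs, function(cc) {
    a <- wt$response[wt$concentration == cc]
    b <- mutant$response[mutant$concentration == cc]
    if (length(a) < 2L || length(b) < 2L)
      stopf("need >= 2 records per group at concentration %g", cc)
    tt <- if (var(a) + var(b) == 0) NULL else
      t.test(a, b, var.equal = TRUE)
    data.frame(concentration = cc,
               mean_wt = mean(a), sem_wt = sd(a) / sqrt(length(a)),
               mean_mut = mean(b), sem_mut = sd(b) / sqrt(length(b)),
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p = if (is.null(tt)) NA_real_ else tt$p.value,
               significant = if (is.null(tt)) NA else tt$p.value < 0.05)
  })
  do.call(rbind, rows)
}

#' Normalize responses within an experiment
#'
#' Divides each experiment's responses by its maximum recorded response
#' (I / I_max), the per-cell normalization applied before pooling
#' recordings.
#'
#' @param data data frame with columns `experiment` and `response`.
#' @return the data frame with a `response_norm` column added.
#' @export
normalize_by_max <- function(data) {
  mx <- tapply(data$response, data$experiment, max)
  data$response_norm <- data$response / as.numeric(mx[as.character(data$experiment)])
  data
}
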