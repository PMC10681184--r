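## Power analysis for fully-crossed participant-by-stimulus designs via
## variance partitioning coefficients, plus effect-size conversions and a
## repeated-measures ANOVA sensitivity solver.

#' Variance partitioning coefficients for a crossed design
#'
#' @param participant_intercept,stimulus_intercept,participant_slope,stimulus_slope,participant_stimulus,residual
#'   shares of total outcome variance; must be non-negative and sum to 1.
#' @return named numeric vector of class `vpc`.
#' @export
vpc_spec <- function(participant_intercept = 0.1, stimulus_intercept = 0.1,
                     participant_slope = 0.2, stimulus_slope = 0,
                     participant_stimulus = 0, residual = 0.6) {
  v <- c(participant_intercept = participant_intercept,
         stimulus_intercept = stimulus_intercept,
         participant_slope = participant_slope,
         stimulus_slope = stimulus_slope,
         participant_stimulus = participant_stimulus,
         residual = residual)
  stopifnot(all(v >= 0))
  if (abs(sum(v) - 1) > 1e-9) stop("VPC components must sum to 1")
  structure(v, class = c("vpc", "numeric"))
}

# variance components of the condition-effect estimate and their df
crossed_components <- function(p, q, vpc, design) {
  ve <- vpc[["residual"]] + vpc[["participant_stimulus"]]
  if (design == "counterbalanced") {
    # each stimulus serves both conditions, so intercepts cancel
    comp <- c(2 * vpc[["participant_slope"]] / p,
              2 * vpc[["stimulus_slope"]] / q,
              4 * ve / (p * q))
    dfs <- c(p - 1, q - 1, (p - 1) * (q - 1))
  } else {
    # stimuli nested within condition: stimulus intercept (and slope,
    # confounded with it) variance does not cancel
    comp <- c(2 * vpc[["participant_slope"]] / p,
              4 * (vpc[["stimulus_intercept"]] + vpc[["stimulus_slope"]]) / q,
              4 * ve / (p * q))
    dfs <- c(p - 1, q - 2, (p - 1) * (q - 2))
  }
  keep <- comp > 0
  if (!any(keep)) stop("all variance components of the effect are zero")
  list(comp = comp[keep], dfs = dfs[keep])
}

#' Power for a fully-crossed participant-by-stimulus design
#'
#' Analytic power for the condition contrast of a crossed linear
#' mixed-effects design, in the variance-partitioning formulation: the
#' noncentrality is d over the square root of the design-weighted variance
#' components (for the counterbalanced design,
#' 2*V_pslope/p + 2*V_sslope/q + 4*V_resid/(p*q); intercept components
#' cancel because every stimulus serves both conditions).  The test is a
#' two-tailed noncentral t with Satterthwaite-type effective degrees of
#' freedom combining the per-component df.
#'
#' @param d standardized effect size (Cohen's d).
#' @param p number of participants.
#' @param q number of stimuli.
#' @param vpc a [vpc_spec()] (or named vector with the same components).
#' @param alpha two-tailed significance level.
#' @param design `"counterbalanced"` (each stimulus appears in both
#'   conditions) or `"stimuli_within_condition"`.
#' @return power in (0, 1); equals `alpha` at `d = 0`.
#' @export
crossed_power <- function(d, p, q, vpc = vpc_spec(), alpha = 0.05,
                          design = c("counterbalanced",
                                     "stimuli_within_condition")) {
  design <- match.arg(design)
  stopifnot(p >= 2, q >= 2, alpha > 0, alpha < 1)
  cc <- crossed_components(p, q, vpc, design)
  v <- sum(cc$comp)
  ncp <- d / sqrt(v)
  df <- v^2 / sum(cc$comp^2 / cc$dfs)
  crit <- qt(1 - alpha / 2, df)
  pt(-crit, df, ncp) + 1 - pt(crit, df, ncp)
}

#' Minimal detectable effect size of a crossed design
#'
#' Inverts [crossed_power()] in d (bisection to 1e-6), giving the lower
#' bound of the effect sizes detectable at `target_power`.
#'
#' @inheritParams crossed_power
#' @param target_power desired power, in (alpha, 1).
#' @return Cohen's d.
#' @export
minimal_detectable_effect <- function(p, q, vpc = vpc_spec(), alpha = 0.05,
                                      target_power = 0.8,
                                      design = "counterbalanced") {
  stopifnot(target_power > alpha, target_power < 1)
  f <- function(d) crossed_power(d, p, q, vpc, alpha, design) - target_power
  if (f(50) < 0) stop("target power unattainable for this design")
  uniroot(f, c(1e-10, 50), tol = 1e-9)$root
}

#' Convert between effect-size metrics
#'
#' For a two-level contrast, f = d/2 and partial eta squared =
#' f^2 / (1 + f^2); conversions are exact inverses on their domains
#' (non-negative d and f, eta_p2 in \[0, 1)).
#'
#' @param value effect size in the source metric.
#' @param from,to one of `"d"`, `"f"`, `"eta_p2"`.
#' @return converted effect size.
#' @export
effect_size_convert <- function(value, from = c("d", "f", "eta_p2"),
                                to = c("d", "f", "eta_p2")) {
  from <- match.arg(from); to <- match.arg(to)
  if (value < 0) stop("effect sizes must be non-negative")
  if (from == "eta_p2" && value >= 1) stop("eta_p2 must be below 1")
  f <- switch(from,
              d = value / 2,
              f = value,
              eta_p2 = sqrt(value / (1 - value)))
  switch(to,
         d = 2 * f,
         f = f,
         eta_p2 = f^2 / (1 + f^2))
}

#' Sensitivity analysis for a repeated-measures ANOVA effect
#'
#' Solves for the effect size f at which a within-subject F test reaches the
#' target power, with df1 = m - 1, df2 = (m - 1)(n - 1) and noncentrality
#' lambda = f^2 * n * m / (1 - rho), rho being the correlation among
#' repeated measures (larger rho shrinks the detectable f).
#'
#' @param n number of participants (>= 2).
#' @param m number of repeated measurements (>= 2).
#' @param rho correlation among repeated measures, in \[0, 1).
#' @param alpha significance level.
#' @param target_power desired power.
#' @return effect size f (Cohen's d for a two-level contrast is 2f).
#' @export
rm_anova_sensitivity <- function(n, m, rho = 0.75, alpha = 0.05,
                                 target_power = 0.8) {
  stopifnot(n >= 2, m >= 2, rho >= 0, rho < 1,
            target_power > alpha, target_power < 1)
  df1 <- m - 1
  df2 <- (m - 1) * (n - 1)
  pow <- function(f) {
    lam <- f^2 * n * m / (1 - rho)
    1 - pf(qf(1 - alpha, df1, df2), df1, df2, ncp = lam)
  }
  if (pow(50) < target_power) stop("target power unattainable")
  uniroot(function(f) pow(f) - target_power, c(1e-10, 50), tol = 1e-9)$root
}
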