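## Belief tracker: three-level binary Hierarchical Gaussian Filter and the
## trial-wise probability predictors built from it.

#' Parameters of the binary Hierarchical Gaussian Filter
#'
#' Level 2 tracks the logit-scale tendency of the observed binary event;
#' level 3 tracks its log-volatility, giving the filter a dynamic learning
#' rate (a Bayesian analogue of Rescorla-Wagner learning whose rate adapts to
#' environmental volatility).
#'
#' @param kappa coupling of level 3 onto level-2 volatility (> 0).
#' @param omega tonic level-2 log-volatility.
#' @param theta level-3 innovation variance (>= 0); 0 freezes the
#'   learning-rate dynamics.  The default, exp(-6), is the conventional
#'   weakly-volatile regime: large values destabilize the variational
#'   update (the level-3 precision can turn negative on long sequences).
#' @param mu2_0,sigma2_0 level-2 prior mean and variance (`sigma2_0` > 0).
#'   `mu2_0 = 0` makes the first-trial prediction exactly 0.5.
#' @param mu3_0,sigma3_0 level-3 prior mean and variance (`sigma3_0` > 0).
#' @return list of class `hgf_params`.
#' @export
hgf_params <- function(kappa = 1, omega = -2, theta = exp(-6),
                       mu2_0 = 0, sigma2_0 = 1, mu3_0 = 1, sigma3_0 = 1) {
  stopifnot(kappa > 0, theta >= 0, sigma2_0 > 0, sigma3_0 > 0)
  structure(list(kappa = kappa, omega = omega, theta = theta,
                 mu2_0 = mu2_0, sigma2_0 = sigma2_0,
                 mu3_0 = mu3_0, sigma3_0 = sigma3_0),
            class = "hgf_params")
}

#' Single HGF update step
#'
#' Pure-R transcription of the variational mean-field update for one binary
#' observation: the level-2 belief moves by the level-1 prediction error times
#' the posterior level-2 variance (the effective learning rate), and level 3
#' moves by the precision-weighted volatility prediction error.
#'
#' @param state list with `mu2`, `sigma2`, `mu3`, `sigma3`, `trial_count`
#'   (use [hgf_init()] for the prior state).
#' @param u binary observation (0 or 1).
#' @param params an [hgf_params()] object.
#' @return updated state list.
#' @export
hgf_update <- function(state, u, params) {
  stopifnot(u %in% c(0, 1), state$sigma2 > 0, state$sigma3 > 0)
  p <- sigmoid(state$mu2)
  d1 <- u - p
  e <- exp(params$kappa * state$mu3 + params$omega)
  v <- state$sigma2 + e
  pi2 <- 1 / v + p * (1 - p)
  sigma2_new <- 1 / pi2
  mu2_new <- state$mu2 + sigma2_new * d1
  d2 <- (sigma2_new + (mu2_new - state$mu2)^2) / v - 1
  pihat3 <- 1 / (state$sigma3 + params$theta)
  w2 <- e / v
  r2 <- (e - state$sigma2) / v
  pi3 <- pihat3 + 0.5 * params$kappa^2 * w2 * (w2 + r2 * d2)
  if (pi3 <= 0)
    stop("level-3 precision became non-positive; check kappa/omega/theta")
  list(mu2 = mu2_new, sigma2 = sigma2_new,
       mu3 = state$mu3 + 0.5 * params$kappa * (w2 / pi3) * d2,
       sigma3 = 1 / pi3,
       trial_count = state$trial_count + 1L)
}

#' @rdname hgf_update
#' @export
hgf_init <- function(params) {
  list(mu2 = params$mu2_0, sigma2 = params$sigma2_0,
       mu3 = params$mu3_0, sigma3 = params$sigma3_0, trial_count = 0L)
}

#' Track a binary sequence with the HGF
#'
#' Runs the filter over a binary sequence and returns the one-step-ahead
#' predicted probability for every trial: element k is the belief held before
#' observing trial k (the prediction for trial 1 is the prior,
#' `sigmoid(mu2_0)`).
#'
#' @param inputs binary vector (0/1), non-empty.
#' @param params an [hgf_params()] object.
#' @param full if TRUE return the full trajectory (predictions plus posterior
#'   means/variances at both levels) instead of the prediction vector.
#' @return numeric vector of predicted probabilities, or a data frame when
#'   `full = TRUE`.
#' @export
track_binary_sequence <- function(inputs, params = hgf_params(),
                                  full = FALSE) {
  stopifnot(length(inputs) >= 1, all(inputs %in% c(0, 1)))
  res <- hgf_filter_cpp(as.integer(inputs), params$kappa, params$omega,
                        params$theta, params$mu2_0, params$sigma2_0,
                        params$mu3_0, params$sigma3_0)
  if (full) as.data.frame(res) else res$pred_prob
}

# filter a subsequence and return logit-scale predictors aligned to it
track_logit <- function(inputs, params, timing = "prediction") {
  res <- hgf_filter_cpp(as.integer(inputs), params$kappa, params$omega,
                        params$theta, params$mu2_0, params$sigma2_0,
                        params$mu3_0, params$sigma3_0)
  if (timing == "prediction") res$pred_logit
  else res$mu2   # posterior belief after the trial's own update
}

#' Trial-wise probability predictors for a trial list
#'
#' Computes the five probability predictors of the design from evolving
#' beliefs instead of block-wise constants, since a participant cannot know a
#' block's probabilities at its first trials:
#' \describe{
#'   \item{lwpc}{one tracker over the congruency sequence of all trials.}
#'   \item{ispc}{four trackers, one per location, each updated only on trials
#'     at its location; the predictor is the current location's belief before
#'     that trial's update.}
#'   \item{prs}{per location, four one-vs-rest binary trackers over direction
#'     identity; the predictor is the prediction for the direction actually
#'     shown (the response-given-location contingency).}
#'   \item{pr}{four one-vs-rest direction trackers over all trials.}
#'   \item{pl}{four one-vs-rest location trackers over all trials.}
#' }
#' All predictors are one-step-ahead predictions by default and are returned
#' on the natural-log-odds (logit) scale together with probability-scale
#' twins.
#'
#' @param trial_list a `trial_list`.
#' @param params an [hgf_params()] object.
#' @param timing `"prediction"` (belief before the trial, the default: a
#'   participant's expectation about trial k cannot use trial k's outcome) or
#'   `"posterior"` (belief after the trial's update).
#' @return data frame of class `belief_table`, row-aligned with
#'   `trial_list`, with columns `lwpc_logit`, `ispc_logit`, `prs_logit`,
#'   `pr_logit`, `pl_logit` and probability-scale `*_prob` twins.
#' @export
trialwise_predictors <- function(trial_list, params = hgf_params(),
                                 timing = c("prediction", "posterior")) {
  timing <- match.arg(timing)
  n <- nrow(trial_list)
  loc <- match(trial_list$location, corners())
  dir <- match(trial_list$direction, corners())
  cong <- trial_list$congruency

  lwpc <- track_logit(cong, params, timing)

  ispc <- numeric(n)
  prs <- numeric(n)
  for (l in 1:4) {
    idx <- which(loc == l)
    if (!length(idx)) next
    ispc[idx] <- track_logit(cong[idx], params, timing)
    # one-vs-rest direction trackers at this location
    for (d in 1:4) {
      hit <- which(dir[idx] == d)
      if (!length(hit)) next
      pred <- track_logit(as.integer(dir[idx] == d), params, timing)
      prs[idx[hit]] <- pred[hit]
    }
  }

  pr <- numeric(n)
  pl <- numeric(n)
  for (d in 1:4) {
    pred <- track_logit(as.integer(dir == d), params, timing)
    pr[dir == d] <- pred[dir == d]
    predl <- track_logit(as.integer(loc == d), params, timing)
    pl[loc == d] <- predl[loc == d]
  }

  out <- data.frame(
    lwpc_logit = lwpc, ispc_logit = ispc, prs_logit = prs,
    pr_logit = pr, pl_logit = pl,
    lwpc_prob = sigmoid(lwpc), ispc_prob = sigmoid(ispc),
    prs_prob = sigmoid(prs), pr_prob = sigmoid(pr), pl_prob = sigmoid(pl)
  )
  attr(out, "params") <- params
  attr(out, "timing") <- timing
  class(out) <- c("belief_table", "data.frame")
  out
}

#' Renormalize one-vs-rest probabilities into a proper distribution
#'
#' Four one-vs-rest trackers give four marginal probabilities that need not
#' sum to one; dividing by their sum yields a proper categorical
#' distribution.
#'
#' @param p numeric vector of one-vs-rest probabilities (> 0).
#' @return vector summing to exactly 1.
#' @export
renormalize_ovr <- function(p) {
  stopifnot(all(p > 0))
  p / sum(p)
}

#' Plot trial-wise LWPC beliefs against the block-wise proportions
#'
#' Diagnostic companion of the design: the evolving filtered belief (solid
#' line) lags and smooths the piecewise-constant block LWPC (step line).
#'
#' @param x a `belief_table`.
#' @param trial_list the trial list it was computed from.
#' @param design the block design (for the block-wise proportions).
#' @param ... passed to [plot()].
#' @export
plot.belief_table <- function(x, trial_list = NULL, design = NULL, ...) {
  plot(x$lwpc_prob, type = "l", col = "blue", ylim = c(0, 1),
       xlab = "trial", ylab = "P(congruent)", ...)
  if (!is.null(trial_list) && !is.null(design)) {
    pr <- design_probabilities(design)
    bw <- vapply(pr, `[[`, numeric(1), "lwpc")[trial_list$block]
    lines(bw, col = "orange", lwd = 2)
  }
  invisible(x)
}

#' Write a belief table row-aligned with its trial-list CSV
#'
#' @param beliefs a `belief_table`.
#' @param path file path.
#' @export
write_belief_table <- function(beliefs, path) {
  write.csv(as.data.frame(beliefs), path, row.names = FALSE)
  invisible(path)
}
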