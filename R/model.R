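## Linear mixed model with crossed participant/image random effects:
## fitting, backward elimination, residual-outlier refit, R2 decomposition.

#' Model formulas for the Stroop analysis
#'
#' The full model contains all experimental terms (Congruency x LWPC x
#' Emotion and Congruency x ISPC x Emotion with their lower-order terms), the
#' confound predictors (trial rank, preceding iRT, PRS, PR, PL, position and
#' direction codes), by-image random intercepts and by-participant correlated
#' random intercepts and slopes for both three-way interactions and all their
#' lower-order terms (12 correlated terms).  The final model keeps the same
#' fixed part but drops every Emotion-related random slope (6 correlated
#' terms), the structure retained by backward elimination in the reference
#' analysis.
#'
#' @param type `"full"` or `"final"`.
#' @param fixed_only drop the random part (returns the fixed formula only).
#' @return a model formula in lme4 notation.
#' @export
stroop_formula <- function(type = c("final", "full"), fixed_only = FALSE) {
  type <- match.arg(type)
  fixed <- paste(
    "irt ~ trial + prec_irt + prs + pr + pl + hpos + vpos + hdir + vdir +",
    "congruency * lwpc * emotion + congruency * ispc * emotion")
  if (fixed_only) return(as.formula(fixed))
  ran <- if (type == "full")
    "(congruency * lwpc * emotion + congruency * ispc * emotion | participant)"
  else
    "(congruency * lwpc + congruency * ispc | participant)"
  as.formula(paste(fixed, "+", ran, "+ (1 | image)"))
}

#' Fit the crossed-random-effects linear mixed model
#'
#' Gaussian LMM with crossed grouping factors (participants and prime
#' images), estimated by (restricted) maximum likelihood through lme4.
#' Satterthwaite degrees of freedom and p-values come from lmerTest when
#' `ddf = "satterthwaite"`; `ddf = "none"` uses the normal approximation
#' (flagged in the output) and is considerably faster on large fits.
#'
#' @param formula model formula (e.g. [stroop_formula()]).
#' @param data analysis table from [build_design_matrix()].
#' @param method `"REML"` or `"ML"`.
#' @param ddf `"satterthwaite"` or `"none"`.
#' @param conf_level confidence level for the Wald intervals.
#' @param control an [lme4::lmerControl()]; the default turns off the
#'   (expensive) finite-difference convergence checks for `ddf = "none"`.
#' @return object of class `stroop_fit`: the lme4 fit plus an estimates
#'   table (estimate, SE, df, CI, p), convergence/singularity flags and the
#'   data used.
#' @export
fit_mixed_model <- function(formula, data, method = c("REML", "ML"),
                            ddf = c("satterthwaite", "none"),
                            conf_level = 0.95, control = NULL) {
  method <- match.arg(method)
  ddf <- match.arg(ddf)
  stopifnot(nrow(data) > 0)
  reml <- method == "REML"
  if (is.null(control))
    control <- lme4::lmerControl(
      optimizer = "bobyqa",
      calc.derivs = (ddf == "satterthwaite"),
      check.conv.singular = lme4::.makeCC(action = "message", tol = 1e-4))

  # do.call keeps evaluated arguments in the stored call so that update()
  # inside downstream tools (lmerTest::step, refits) works in any frame
  if (ddf == "satterthwaite") {
    model <- do.call(lmerTest::lmer, list(formula, data = data, REML = reml,
                                          control = control))
    ct <- as.data.frame(coef(summary(model)))
    names(ct) <- c("estimate", "se", "df", "t", "p")
  } else {
    model <- do.call(lme4::lmer, list(formula, data = data, REML = reml,
                                      control = control))
    ct <- as.data.frame(coef(summary(model)))
    names(ct) <- c("estimate", "se", "t")
    ct$df <- Inf
    ct$p <- 2 * pnorm(-abs(ct$t))
  }
  alpha <- 1 - conf_level
  crit <- qt(1 - alpha / 2, pmax(ct$df, 1))
  est <- data.frame(term = rownames(ct), estimate = ct$estimate, se = ct$se,
                    df = ct$df, ci_lower = ct$estimate - crit * ct$se,
                    ci_upper = ct$estimate + crit * ct$se,
                    t = ct$t, p = ct$p, row.names = NULL)

  conv <- model@optinfo$conv$opt == 0 &&
    length(model@optinfo$conv$lme4$messages) == 0
  fit <- structure(list(
    model = model, formula = formula, method = method, ddf = ddf,
    estimates = est, converged = conv,
    singular = lme4::isSingular(model, tol = 1e-4),
    optinfo = model@optinfo, data = data, conf_level = conf_level
  ), class = "stroop_fit")
  fit$r2 <- variance_explained(fit)
  fit
}

#' @export
print.stroop_fit <- function(x, ...) {
  cat("Linear mixed model (", x$method, ", df: ", x$ddf, ")\n", sep = "")
  cat(deparse(x$formula, width.cutoff = 500), sep = "\n")
  cat(sprintf("Observations: %d; converged: %s; singular: %s\n",
              nrow(x$data), x$converged, x$singular))
  cat(sprintf("Marginal R2 = %.3f, Conditional R2 = %.3f\n",
              x$r2[["marginal_r2"]], x$r2[["conditional_r2"]]))
  print(x$estimates, digits = 3)
  invisible(x)
}

#' @export
summary.stroop_fit <- function(object, ...) {
  structure(list(estimates = object$estimates,
                 varcorr = lme4::VarCorr(object$model),
                 r2 = object$r2, method = object$method,
                 formula = object$formula,
                 converged = object$converged,
                 singular = object$singular,
                 logLik = as.numeric(logLik(object$model)),
                 REMLcrit = if (object$method == "REML")
                   lme4::REMLcrit(object$model) else NA_real_),
            class = "summary.stroop_fit")
}

#' @export
print.summary.stroop_fit <- function(x, ...) {
  cat("Fixed effects:\n"); print(x$estimates, digits = 3)
  cat("\nRandom effects:\n"); print(x$varcorr, comp = "Std.Dev.")
  cat(sprintf("\nMarginal R2 = %.3f, Conditional R2 = %.3f\n",
              x$r2[["marginal_r2"]], x$r2[["conditional_r2"]]))
  invisible(x)
}

#' @export
coef.stroop_fit <- function(object, ...) lme4::fixef(object$model)

#' @export
vcov.stroop_fit <- function(object, ...) as.matrix(vcov(object$model))

#' @export
predict.stroop_fit <- function(object, newdata = NULL, re.form = NULL, ...)
  predict(object$model, newdata = newdata, re.form = re.form, ...)

#' @export
residuals.stroop_fit <- function(object, ...) residuals(object$model, ...)

#' @export
logLik.stroop_fit <- function(object, ...) logLik(object$model, ...)

#' @export
plot.stroop_fit <- function(x, ...) {
  r <- residuals(x) / sigma(x$model)
  stats::qqnorm(r, main = "Standardized conditional residuals", ...)
  stats::qqline(r)
  invisible(x)
}

#' Backward elimination of non-significant random and fixed effects
#'
#' Wraps the standard stepwise procedure (lmerTest's `step`): random-effect
#' terms are removed first via pairwise likelihood-ratio tests at
#' `alpha_random`, then fixed effects via t/F tests at `alpha_fixed`, never
#' removing a term contained in a retained interaction.  Also reports the
#' likelihood-ratio test between the full and the final model (ML scale).
#'
#' @param formula full-model formula.
#' @param data analysis table.
#' @param alpha_random,alpha_fixed elimination thresholds.
#' @param control optional [lme4::lmerControl()].
#' @return list with `final_formula`, `fit` (a `stroop_fit` REML refit of
#'   the final model), `log` (the elimination tables), and `comparison`
#'   (`chi_square`, `df`, `p_value` of full vs final).
#' @export
backward_eliminate <- function(formula, data, alpha_random = 0.1,
                               alpha_fixed = 0.05, control = NULL) {
  if (is.null(control))
    control <- lme4::lmerControl(
      optimizer = "bobyqa",
      check.conv.singular = lme4::.makeCC(action = "message", tol = 1e-4))
  full <- do.call(lmerTest::lmer, list(formula, data = data, REML = TRUE,
                                       control = control))
  st <- lmerTest::step(full, reduce.fixed = TRUE, reduce.random = TRUE,
                       alpha.random = alpha_random, alpha.fixed = alpha_fixed)
  final <- lmerTest::get_model(st)
  final_formula <- formula(final, fixed.only = FALSE)

  if (identical(deparse(final_formula), deparse(formula(full)))) {
    comparison <- list(chi_square = 0, df = 0L, p_value = 1)
  } else {
    an <- suppressMessages(anova(final, full, refit = TRUE))
    comparison <- list(chi_square = an$Chisq[2], df = an$Df[2],
                       p_value = an$`Pr(>Chisq)`[2])
  }
  fit <- fit_mixed_model(final_formula, data, method = "REML",
                         ddf = "satterthwaite")
  list(final_formula = final_formula, fit = fit, log = st,
       comparison = comparison)
}

#' Remove residual outliers and refit once
#'
#' Trials with absolute standardized conditional residuals above `threshold`
#' (in residual-SD units) are removed and the model is refitted a single
#' time, the usual post-selection cleanup for mildly skewed RT residuals.
#' Under Gaussian residuals the expected removed fraction at 2.5 SD is about
#' 2 * pnorm(-2.5), i.e. 1.24%.
#'
#' @param fit a `stroop_fit`.
#' @param threshold residual cut in SD units (default 2.5).
#' @return list with `fit` (the refit) and `fraction_removed`.
#' @export
outlier_refit <- function(fit, threshold = 2.5) {
  std <- residuals(fit$model) / sigma(fit$model)
  keep <- abs(std) <= threshold
  frac <- mean(!keep)
  if (frac == 0) return(list(fit = fit, fraction_removed = 0))
  refit <- fit_mixed_model(fit$formula, fit$data[keep, , drop = FALSE],
                           method = fit$method, ddf = fit$ddf,
                           conf_level = fit$conf_level)
  list(fit = refit, fraction_removed = frac)
}

#' Marginal and conditional R-squared of a mixed model
#'
#' Variance decomposition in the Nakagawa style: the marginal R2 is the
#' variance of the fixed-effect linear predictor over the total (fixed +
#' summed random + residual) variance; the conditional R2 adds the random
#' variances to the numerator.  Random-slope terms contribute the average
#' row-wise quadratic form of their covariance matrix.
#'
#' @param fit a `stroop_fit` (or lme4 fit).
#' @return named vector `c(marginal_r2, conditional_r2)`.
#' @export
variance_explained <- function(fit) {
  model <- if (inherits(fit, "stroop_fit")) fit$model else fit
  X <- lme4::getME(model, "X")
  var_fixed <- var(drop(X %*% lme4::fixef(model)))
  vc <- lme4::VarCorr(model)
  bars <- lme4::findbars(formula(model))
  fr <- model@frame
  var_random <- 0
  for (i in seq_along(vc)) {
    Sigma <- as.matrix(vc[[i]])
    cn <- rownames(Sigma)
    grp <- sub("\\.\\d+$", "", names(vc)[i])
    Xr <- NULL
    for (b in bars) {
      if (deparse(b[[3]]) != grp) next
      mm <- model.matrix(stats::reformulate(deparse(b[[2]])), fr)
      if (identical(colnames(mm), cn)) { Xr <- mm; break }
    }
    if (is.null(Xr))
      stop("could not reconstruct the design of random term for '",
           grp, "'")
    var_random <- var_random + mean(rowSums((Xr %*% Sigma) * Xr))
  }
  var_resid <- sigma(model)^2
  tot <- var_fixed + var_random + var_resid
  c(marginal_r2 = var_fixed / tot,
    conditional_r2 = (var_fixed + var_random) / tot)
}

#' Serialize a fit to JSON
#'
#' Writes estimates, confidence intervals, p-values, random-effect standard
#' deviations, R2 decomposition and convergence information.
#'
#' @param fit a `stroop_fit`.
#' @param path output path.
#' @export
write_fit_json <- function(fit, path) {
  vc <- lme4::VarCorr(fit$model)
  ran <- lapply(seq_along(vc), function(i)
    list(group = names(vc)[i],
         sd = as.list(setNames(attr(vc[[i]], "stddev"),
                               rownames(vc[[i]])))))
  out <- list(
    formula = deparse(fit$formula, width.cutoff = 500),
    method = fit$method, ddf = fit$ddf,
    converged = fit$converged, singular = fit$singular,
    n_obs = nrow(fit$data),
    estimates = fit$estimates,
    random_effects = ran,
    residual_sd = sigma(fit$model),
    marginal_r2 = fit$r2[["marginal_r2"]],
    conditional_r2 = fit$r2[["conditional_r2"]],
    logLik = as.numeric(logLik(fit$model))
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
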