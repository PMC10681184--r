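## Post-hoc contrasts: simple slopes and marginal means at chosen predictor
## values, as exact linear functions of the fixed effects, with Tukey
## adjustment.

# value of a model term (product of its variables) at a named cell;
# variables absent from the cell take 0 (their centered mean), the
# intercept takes 1
term_value <- function(term, cell) {
  if (term == "(Intercept)") return(1)
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  prod(vapply(parts, function(v)
    if (!is.null(cell[[v]])) cell[[v]] else 0, numeric(1)))
}

# derivative of a term with respect to `modifier` at a cell
term_slope <- function(term, modifier, cell) {
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  hits <- sum(parts == modifier)
  if (hits == 0) return(0)
  others <- parts[parts != modifier]
  hits * prod(vapply(others, function(v)
    if (!is.null(cell[[v]])) cell[[v]] else 0, numeric(1)))
}

cell_grid <- function(by) {
  g <- expand.grid(by, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(g)), function(i) as.list(g[i, , drop = FALSE]))
}

# rows = cells, columns = model terms (robust to single-term models)
build_L <- function(cells, terms, fun) {
  m <- vapply(cells, function(cell)
    vapply(terms, fun, numeric(1), cell = cell), numeric(length(terms)))
  if (length(terms) == 1) matrix(m, ncol = 1)
  else t(m)
}

#' Simple slopes of a continuous predictor by factor cells
#'
#' Linear-combination estimates of the change in predicted iRT per unit of
#' `modifier` within each cell of `by` (e.g. the LWPC slope in every Emotion
#' by Congruency cell), with delta-method standard errors from the
#' fixed-effect covariance matrix.
#'
#' @param fit a `stroop_fit`.
#' @param modifier name of a continuous fixed term (e.g. `"lwpc"`).
#' @param by named list of factor levels defining the cells, e.g.
#'   `list(congruency = c(-1, 1), emotion = c(-1, 1))`.
#' @return data frame with one row per cell: the cell values, `slope`, `se`,
#'   `z`; the contrast matrix is attached as attribute `L`.
#' @export
estimate_slopes <- function(fit, modifier = "lwpc",
                            by = list(congruency = c(-1, 1),
                                      emotion = c(-1, 1))) {
  beta <- coef(fit)
  if (!modifier %in% unlist(strsplit(names(beta), ":", fixed = TRUE)))
    stop("term '", modifier, "' is not in the model")
  V <- vcov(fit)
  cells <- cell_grid(by)
  L <- build_L(cells, names(beta), function(term, cell)
    term_slope(term, modifier, cell))
  est <- drop(L %*% beta)
  se <- sqrt(rowSums((L %*% V) * L))
  out <- cbind(expand.grid(by, KEEP.OUT.ATTRS = FALSE),
               data.frame(slope = est, se = se, z = est / se))
  attr(out, "L") <- L
  attr(out, "modifier") <- modifier
  out
}

#' Default slope-contrast family
#'
#' Contrasts the `modifier` slopes between Emotion levels within each
#' Congruency level and between Congruency levels within each Emotion level
#' (four contrasts), Tukey-adjusted for the family size `k`.
#'
#' @inheritParams estimate_slopes
#' @param k family size for the Tukey adjustment (default 4).
#' @return data frame of contrasts with estimate, se, z, p and adjusted p.
#' @export
slope_contrasts <- function(fit, modifier = "lwpc", k = 4) {
  sl <- estimate_slopes(fit, modifier,
                        by = list(congruency = c(-1, 1),
                                  emotion = c(-1, 1)))
  L <- attr(sl, "L")
  # rows of sl: (C-1,E-1), (C+1,E-1), (C-1,E+1), (C+1,E+1)
  D <- rbind(
    "sad - neutral | congruent"    = c(-1, 0, 1, 0),
    "sad - neutral | incongruent"  = c(0, -1, 0, 1),
    "incongruent - congruent | neutral" = c(-1, 1, 0, 0),
    "incongruent - congruent | sad"     = c(0, 0, -1, 1)
  )
  Lc <- D %*% L
  beta <- coef(fit)
  V <- vcov(fit)
  est <- drop(Lc %*% beta)
  se <- sqrt(rowSums((Lc %*% V) * Lc))
  z <- est / se
  data.frame(contrast = rownames(D), estimate = est, se = se, z = z,
             p = 2 * pnorm(-abs(z)), p_adj = tukey_adjust(z, k),
             k = k, row.names = NULL)
}

#' Model-implied marginal iRT at chosen LWPC values
#'
#' Predicted iRT at the given values of a continuous predictor (by default
#' the observed extremes of trial-wise LWPC) in every Emotion by Congruency
#' cell, all other continuous predictors held at 0 (their centered mean).
#' Two predictor values and the 2x2 cells give 8 means.
#'
#' @param fit a `stroop_fit`.
#' @param lwpc_values numeric values of the modifier; defaults to the
#'   observed min and max in the analysis sample (values outside the
#'   observed range trigger a warning).
#' @param modifier the continuous predictor (default `"lwpc"`).
#' @param by named list of factor cells.
#' @return data frame of means with SEs; linear-combination matrix in
#'   attribute `L`.
#' @export
marginal_means_at <- function(fit, lwpc_values = NULL, modifier = "lwpc",
                              by = list(congruency = c(-1, 1),
                                        emotion = c(-1, 1))) {
  obs <- fit$data[[modifier]]
  if (is.null(lwpc_values)) lwpc_values <- range(obs)
  if (!is.null(obs) &&
      (min(lwpc_values) < min(obs) || max(lwpc_values) > max(obs)))
    warning("requested ", modifier,
            " values extrapolate beyond the observed range")
  beta <- coef(fit)
  V <- vcov(fit)
  grid <- c(by, setNames(list(lwpc_values), modifier))
  cells <- cell_grid(grid)
  L <- build_L(cells, names(beta), term_value)
  est <- drop(L %*% beta)
  se <- sqrt(rowSums((L %*% V) * L))
  out <- cbind(expand.grid(grid, KEEP.OUT.ATTRS = FALSE),
               data.frame(mean = est, se = se))
  attr(out, "L") <- L
  out
}

#' All pairwise contrasts among estimated marginal means
#'
#' @param means output of [marginal_means_at()].
#' @param fit the `stroop_fit` the means came from.
#' @param k Tukey family size; defaults to the number of pairs (8 means give
#'   28 comparisons).
#' @return data frame of pairwise contrasts with Tukey-adjusted p-values.
#' @export
pairwise_contrasts <- function(means, fit, k = NULL) {
  L <- attr(means, "L")
  n <- nrow(L)
  pairs <- utils::combn(n, 2)
  if (is.null(k)) k <- ncol(pairs)
  beta <- coef(fit)
  V <- vcov(fit)
  lab <- apply(means[, setdiff(names(means), c("mean", "se")), drop = FALSE],
               1, function(r) paste(r, collapse = ","))
  Lc <- t(apply(pairs, 2, function(ij) L[ij[1], ] - L[ij[2], ]))
  est <- drop(Lc %*% beta)
  se <- sqrt(rowSums((Lc %*% V) * Lc))
  z <- est / se
  data.frame(contrast = paste0("(", lab[pairs[1, ]], ") - (",
                               lab[pairs[2, ]], ")"),
             estimate = est, se = se, z = z,
             p = 2 * pnorm(-abs(z)), p_adj = tukey_adjust(z, k), k = k,
             row.names = NULL)
}

#' Tukey adjustment for a family of k simultaneous comparisons
#'
#' Adjusted p-values from the studentized-range distribution: a family of k
#' pairwise comparisons corresponds to m means with choose(m, 2) >= k (m
#' exactly recovers k when k is a triangular number), and the adjusted p for
#' a statistic z is P(range of m independent standard normals >
#' sqrt(2)|z|).  `k = 1` returns the unadjusted two-sided p.
#'
#' @param statistics z (or t) statistics.
#' @param k family size, at least the number of statistics supplied (or 1).
#' @param df error degrees of freedom (Inf for the normal case).
#' @return adjusted p-values, always >= the unadjusted ones.
#' @export
tukey_adjust <- function(statistics, k, df = Inf) {
  stopifnot(k >= 1)
  if (k < length(statistics))
    stop("family size k must be at least the number of statistics")
  if (k == 1) return(2 * pt(-abs(statistics), df))
  m <- 2
  while (choose(m, 2) < k) m <- m + 1
  pmin(1, 1 - ptukey(sqrt(2) * abs(statistics), m, df))
}
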