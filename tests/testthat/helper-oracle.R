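# Independent line-by-line transcription of the three-level binary HGF
# update equations, used as the oracle against the package's filter.
# Deliberately written as a direct equation dump, not sharing code with
# the implementation.

oracle_hgf_step <- function(st, u, kappa, omega, theta) {
  sig <- function(x) 1 / (1 + exp(-x))
  phat <- sig(st$mu2)
  del1 <- u - phat
  expo <- exp(kappa * st$mu3 + omega)
  vhat <- st$sigma2 + expo
  pi2 <- 1 / vhat + phat * (1 - phat)
  s2 <- 1 / pi2
  m2 <- st$mu2 + s2 * del1
  del2 <- (s2 + (m2 - st$mu2)^2) / vhat - 1
  pih3 <- 1 / (st$sigma3 + theta)
  w2 <- expo / vhat
  r2 <- (expo - st$sigma2) / vhat
  pi3 <- pih3 + kappa^2 / 2 * w2 * (w2 + r2 * del2)
  stopifnot(pi3 > 0)
  list(mu2 = m2, sigma2 = s2,
       mu3 = st$mu3 + kappa / 2 * (1 / pi3) * w2 * del2,
       sigma3 = 1 / pi3)
}

oracle_hgf_track <- function(u, p) {
  st <- list(mu2 = p$mu2_0, sigma2 = p$sigma2_0,
             mu3 = p$mu3_0, sigma3 = p$sigma3_0)
  out <- matrix(NA_real_, length(u), 6,
                dimnames = list(NULL, c("pred_logit", "pred_prob", "mu2",
                                        "sigma2", "mu3", "sigma3")))
  for (k in seq_along(u)) {
    out[k, "pred_logit"] <- st$mu2
    out[k, "pred_prob"] <- 1 / (1 + exp(-st$mu2))
    st <- oracle_hgf_step(st, u[k], p$kappa, p$omega, p$theta)
    out[k, 3:6] <- c(st$mu2, st$sigma2, st$mu3, st$sigma3)
  }
  out
}
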