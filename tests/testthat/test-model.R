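# small balanced dataset with crossed random intercepts
toy_lmm_data <- function(seed = 1, n_part = 8, n_img = 6, reps = 4,
                         sd_part = 0.5, sd_img = 0.3, sd_e = 1) {
  set.seed(seed)
  g <- expand.grid(participant = factor(seq_len(n_part)),
                   image = factor(seq_len(n_img)),
                   rep = seq_len(reps))
  bp <- rnorm(n_part, 0, sd_part)
  bi <- rnorm(n_img, 0, sd_img)
  g$congruency <- rep(c(-1, 1), length.out = nrow(g))
  g$irt <- -2 + bp[g$participant] + bi[g$image] + rnorm(nrow(g), 0, sd_e)
  g
}

test_that("intercept-only fit recovers the grand mean on balanced data", {
  d <- toy_lmm_data(2)
  fit <- fit_mixed_model(irt ~ 1 + (1 | participant) + (1 | image), d)
  expect_equal(unname(coef(fit)["(Intercept)"]), mean(d$irt),
               tolerance = 1e-6)
  expect_s3_class(fit, "stroop_fit")
  # CI brackets the estimate
  expect_true(all(fit$estimates$ci_lower <= fit$estimates$estimate &
                    fit$estimates$estimate <= fit$estimates$ci_upper))
})

test_that("data without group structure give boundary variance estimates", {
  d <- toy_lmm_data(3, n_part = 20, n_img = 10, reps = 10,
                    sd_part = 0, sd_img = 0)
  fit <- suppressMessages(
    fit_mixed_model(irt ~ 1 + (1 | participant) + (1 | image), d))
  vc <- lme4::VarCorr(fit$model)
  resid_var <- sigma(fit$model)^2
  for (i in seq_along(vc))
    expect_lt(as.numeric(vc[[i]][1]), 0.01 * resid_var)
  expect_true(fit$singular)
})

test_that("REML matches the closed-form one-way ANOVA estimators", {
  set.seed(4)
  k <- 6; n <- 10
  a <- rnorm(k, 0, 2)
  g <- factor(rep(seq_len(k), each = n))
  y <- 1 + a[g] + rnorm(k * n, 0, 1)
  d <- data.frame(participant = g, irt = y)
  fit <- fit_mixed_model(irt ~ 1 + (1 | participant), d)
  msb <- n * var(tapply(y, g, mean))
  msw <- sum((y - ave(y, g))^2) / (k * (n - 1))
  vc <- lme4::VarCorr(fit$model)
  expect_equal(as.numeric(vc$participant[1]), (msb - msw) / n,
               tolerance = 1e-6)
  expect_equal(sigma(fit$model)^2, msw, tolerance = 1e-6)
})

test_that("fixed-effect estimates are invariant to row order", {
  d <- toy_lmm_data(5)
  d$x <- rnorm(nrow(d))
  f <- irt ~ x + congruency + (1 | participant) + (1 | image)
  fit1 <- fit_mixed_model(f, d)
  set.seed(9); perm <- sample(nrow(d))
  fit2 <- fit_mixed_model(f, d[perm, ])
  expect_equal(coef(fit1), coef(fit2), tolerance = 1e-8)
})

test_that("methods on the fit object behave like a classic model object", {
  d <- toy_lmm_data(6)
  fit <- fit_mixed_model(irt ~ congruency + (1 | participant) + (1 | image), d)
  expect_output(print(fit), "Linear mixed model")
  s <- summary(fit)
  expect_s3_class(s, "summary.stroop_fit")
  expect_named(coef(fit), c("(Intercept)", "congruency"))
  expect_length(residuals(fit), nrow(d))
  expect_equal(dim(vcov(fit)), c(2, 2))
  p <- predict(fit, newdata = d[1:5, ], re.form = NA)
  expect_length(p, 5)
})

test_that("outlier refit removes the Gaussian tail fraction once", {
  d <- toy_lmm_data(7, n_part = 12, n_img = 8, reps = 6)
  fit <- fit_mixed_model(irt ~ 1 + (1 | participant) + (1 | image), d)

  same <- outlier_refit(fit, threshold = Inf)
  expect_identical(same$fit, fit)
  expect_equal(same$fraction_removed, 0)

  o <- outlier_refit(fit, threshold = 2.5)
  expect_gt(o$fraction_removed, 0.002)
  expect_lt(o$fraction_removed, 0.03)
  # second pass takes no more than the first
  o2 <- outlier_refit(o$fit, threshold = 2.5)
  expect_lte(o2$fraction_removed, o$fraction_removed)
})

test_that("variance decomposition orders and degenerates correctly", {
  d <- toy_lmm_data(8)
  d$x <- rnorm(nrow(d))
  fit <- fit_mixed_model(irt ~ x + (1 | participant) + (1 | image), d)
  r2 <- variance_explained(fit)
  expect_gte(r2[["conditional_r2"]], r2[["marginal_r2"]])
  expect_true(all(r2 >= 0 & r2 <= 1))

  # intercept-only model explains no fixed variance
  fit0 <- fit_mixed_model(irt ~ 1 + (1 | participant) + (1 | image), d)
  expect_lt(variance_explained(fit0)[["marginal_r2"]], 1e-10)

  # without group variance, marginal and conditional coincide
  d0 <- toy_lmm_data(9, sd_part = 0, sd_img = 0)
  d0$x <- rnorm(nrow(d0))
  fit00 <- suppressMessages(
    fit_mixed_model(irt ~ x + (1 | participant) + (1 | image), d0))
  r200 <- variance_explained(fit00)
  expect_equal(r200[["marginal_r2"]], r200[["conditional_r2"]],
               tolerance = 1e-3)
})

test_that("fixed effects are recovered from generated mini cohorts", {
  setup <- mini_setup(14)
  p <- mini_gen(12)
  dat <- simulate_dataset(p, master_seed = 21, trial_list = setup$trial_list,
                          beliefs = setup$beliefs)
  dm <- build_design_matrix(apply_exclusions(dat)$data)
  form <- update(stroop_formula("final", fixed_only = TRUE),
                 . ~ . + (1 + congruency | participant) + (1 | image))
  fit <- suppressMessages(fit_mixed_model(form, dm, ddf = "none"))
  # congruency slope SD .2 across 12 participants: keep a 3-sigma-ish band
  expect_lt(abs(coef(fit)[["congruency"]] - 0.225), 0.2)
  expect_lt(abs(coef(fit)[["(Intercept)"]] - (-2.329)), 0.25)
  # residual-scale terms are tightly identified even in a mini cohort
  expect_lt(abs(coef(fit)[["congruency:lwpc"]] - 0.054), 0.05)
  expect_lt(abs(coef(fit)[["prec_irt"]] - 0.086), 0.05)
})

test_that("backward elimination drops absent Emotion random effects", {
  dropped <- logical(3)
  for (s in 1:3) {
    setup <- mini_setup(20 + s)
    p <- mini_gen(10)
    dat <- simulate_dataset(p, master_seed = 50 + s,
                            trial_list = setup$trial_list,
                            beliefs = setup$beliefs)
    dm <- build_design_matrix(apply_exclusions(dat)$data)
    form <- irt ~ congruency * emotion + lwpc + prec_irt + trial +
      (congruency * emotion | participant) + (1 | image)
    el <- suppressMessages(suppressWarnings(backward_eliminate(form, dm)))
    re_terms <- deparse(el$final_formula, width.cutoff = 500)
    ran <- regmatches(re_terms, gregexpr("\\([^)]*\\|[^)]*\\)", re_terms))[[1]]
    part_ran <- grep("participant", ran, value = TRUE)
    dropped[s] <- length(part_ran) == 0 || !grepl("emotion", part_ran)
    expect_gte(el$comparison$chi_square, 0)
    expect_true(el$comparison$df >= 0)
  }
  expect_gte(sum(dropped), 2)
})

test_that("elimination never orphans a retained interaction", {
  d <- toy_lmm_data(10, n_part = 10, n_img = 6, reps = 6)
  set.seed(11)
  d$x <- rnorm(nrow(d))
  # strong interaction, weak main effect: the main must survive marginality
  d$irt <- d$irt + 0.01 * d$x + 0.5 * d$x * d$congruency
  el <- suppressMessages(suppressWarnings(backward_eliminate(
    irt ~ x * congruency + (1 | participant) + (1 | image), d)))
  fixed_terms <- attr(terms(el$final_formula), "term.labels")
  if ("x:congruency" %in% fixed_terms) {
    expect_true(all(c("x", "congruency") %in% fixed_terms))
  }
  # final model cannot beat the full model on ML likelihood
  full_ml <- lme4::lmer(irt ~ x * congruency + (1 | participant) + (1 | image),
                        d, REML = FALSE)
  final_ml <- lme4::lmer(el$final_formula, d, REML = FALSE)
  expect_lte(as.numeric(logLik(final_ml)), as.numeric(logLik(full_ml)) + 1e-6)
})
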