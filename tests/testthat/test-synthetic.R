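test_that("prime assignment balances emotion within block by congruency", {
  d <- default_block_design()
  tl <- assign_primes(pseudorandomize(d, seed = 31), seed = 5)
  for (b in 1:6) for (cg in 0:1) {
    idx <- tl$block == b & tl$congruency == cg
    n_sad <- sum(tl$emotion[idx] == "sad")
    expect_lte(abs(n_sad - sum(idx) / 2), 0.5)
  }
  # block 2 has 48 congruent trials: exactly 24 sad among them
  idx <- tl$block == 2 & tl$congruency == 1
  expect_equal(sum(idx), 48)
  expect_equal(sum(tl$emotion[idx] == "sad"), 24)

  # image ids consistent with emotion, no immediate repeats, deterministic
  expect_true(all(tl$prime_image[tl$emotion == "sad"] %in% 1:20))
  expect_true(all(tl$prime_image[tl$emotion == "neutral"] %in% 21:40))
  expect_false(any(diff(tl$prime_image) == 0))
  tl2 <- assign_primes(pseudorandomize(d, seed = 31), seed = 5)
  expect_identical(tl, tl2)
})

test_that("the noiseless generator reproduces the intercept arithmetic", {
  setup <- mini_setup(6)
  # intercept-only fixed effects, vanishing random variation
  fx <- generative_params()$fixed
  fx[] <- 0
  fx["(Intercept)"] <- -2.329
  p <- generative_params(fixed = fx, total_var = 1e-12,
                         error_rate_congruent = 0,
                         error_rate_incongruent = 0, n_participants = 1)
  rows <- simulate_participant(setup$trial_list, setup$beliefs, p,
                               participant_seed = 1)
  expect_equal(rows$rt, rep(1000 / 2.329, nrow(rows)), tolerance = 1e-3)
  expect_true(all(rows$accuracy == 1))
})

test_that("the congruency coefficient produces the coded iRT difference", {
  setup <- mini_setup(7)
  fx <- generative_params()$fixed
  fx[] <- 0
  fx["(Intercept)"] <- -2.329
  fx["congruency"] <- 0.225
  p <- generative_params(fixed = fx, total_var = 1e-12,
                         error_rate_congruent = 0,
                         error_rate_incongruent = 0, n_participants = 1)
  rows <- simulate_participant(setup$trial_list, setup$beliefs, p,
                               participant_seed = 1)
  irt <- -1000 / rows$rt
  diff_irt <- mean(irt[rows$congruency == 0]) - mean(irt[rows$congruency == 1])
  expect_equal(diff_irt, 2 * 0.225, tolerance = 1e-6)
})

test_that("dataset assembly is sized, deterministic and metadata-complete", {
  setup <- mini_setup(8)
  p <- mini_gen(n_participants = 2)
  d1 <- simulate_dataset(p, master_seed = 9, trial_list = setup$trial_list,
                         beliefs = setup$beliefs)
  expect_equal(nrow(d1), 2 * nrow(setup$trial_list))
  d2 <- simulate_dataset(p, master_seed = 9, trial_list = setup$trial_list,
                         beliefs = setup$beliefs)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  d3 <- simulate_dataset(p, master_seed = 10, trial_list = setup$trial_list,
                         beliefs = setup$beliefs)
  expect_false(identical(d1$rt, d3$rt))

  f <- tempfile(fileext = ".csv")
  write_behavioral_dataset(d1, f)
  expect_true(file.exists(f) && file.exists(paste0(f, ".json")))
  meta <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(meta$master_seed, 9)
  expect_equal(meta$n_participants, 2)

  # rt missing only at timeouts; otherwise within bounds
  ok <- !is.na(d1$rt)
  expect_true(all(d1$rt[ok] >= p$rt_bounds[1] & d1$rt[ok] <= p$rt_bounds[2]))
  expect_true(all(d1$accuracy[!ok] == 0))
})

test_that("zero error rates give all-correct responses", {
  setup <- mini_setup(9)
  p <- mini_gen(n_participants = 2, error_rate_congruent = 0,
                error_rate_incongruent = 0)
  d <- simulate_dataset(p, master_seed = 3, trial_list = setup$trial_list,
                        beliefs = setup$beliefs)
  expect_true(all(d$accuracy[!is.na(d$rt)] == 1))
})

test_that("grand mean RT of correct trials stays in the plausible band", {
  d <- default_block_design()
  tl <- assign_primes(pseudorandomize(d, seed = 77), seed = 78)
  bt <- trialwise_predictors(tl)
  for (s in 1:5) {
    dat <- simulate_dataset(mini_gen(n_participants = 3), master_seed = s,
                            trial_list = tl, beliefs = bt)
    m <- mean(dat$rt[dat$accuracy == 1], na.rm = TRUE)
    expect_gt(m, 350)
    expect_lt(m, 550)
  }
})

test_that("larger residual variance widens the simulated iRT distribution", {
  setup <- mini_setup(10)
  v_lo <- v_hi <- numeric(3)
  for (s in 1:3) {
    lo <- simulate_dataset(mini_gen(2, total_var = 0.1), master_seed = s,
                           trial_list = setup$trial_list,
                           beliefs = setup$beliefs)
    hi <- simulate_dataset(mini_gen(2, total_var = 0.5), master_seed = s,
                           trial_list = setup$trial_list,
                           beliefs = setup$beliefs)
    v_lo[s] <- var(-1000 / lo$rt, na.rm = TRUE)
    v_hi[s] <- var(-1000 / hi$rt, na.rm = TRUE)
  }
  expect_true(all(v_hi > v_lo))
})

test_that("generator and preprocessing build the same design matrix", {
  setup <- mini_setup(11)
  p <- mini_gen(2, error_rate_congruent = 0, error_rate_incongruent = 0)
  dat <- simulate_dataset(p, master_seed = 4, trial_list = setup$trial_list,
                          beliefs = setup$beliefs)
  ex <- apply_exclusions(dat)
  # reuse the generator's standardization constants (full trial list)
  rows <- cbind(as.data.frame(setup$trial_list),
                as.data.frame(setup$beliefs))
  gen_coded <- pcstroop:::code_predictors(rows)
  constants <- attr(gen_coded, "constants")
  dm <- build_design_matrix(ex$data, constants = constants)
  for (col in c("congruency", "emotion", "hpos", "vpos", "hdir", "vdir",
                "lwpc", "ispc", "prs", "pr", "pl", "trial")) {
    expect_equal(dm[[col]], gen_coded[[col]][ex$data$trial_index],
                 tolerance = 1e-12, label = col)
  }
})
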