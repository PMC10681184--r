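# Small two-block design for fast tests: 8 trials per location per block,
# LWPC .5 and .25, mild ISPC offsets.
mini_design <- function() {
  b1 <- synthesize_block_counts(0.5, c(5, 5, 3, 3) / 8, 8)
  b2 <- synthesize_block_counts(0.25, c(3, 2, 2, 1) / 8, 8)
  block_design(list(b1, b2))
}

# Pseudorandomized mini trial list with primes and beliefs attached.
mini_setup <- function(seed = 1) {
  d <- mini_design()
  tl <- assign_primes(pseudorandomize(d, seed = seed), seed = seed + 1)
  list(design = d, trial_list = tl, beliefs = trialwise_predictors(tl))
}

# Quick generative parameters with small cohorts for tests.
mini_gen <- function(n_participants = 4, ...) {
  generative_params(n_participants = n_participants, ...)
}

# Moderately sized fit with interactions for the contrast machinery.
contrast_fit <- function(seed = 30) {
  setup <- mini_setup(seed)
  dat <- simulate_dataset(mini_gen(8), master_seed = seed,
                          trial_list = setup$trial_list,
                          beliefs = setup$beliefs)
  dm <- build_design_matrix(apply_exclusions(dat)$data)
  suppressMessages(fit_mixed_model(
    irt ~ prec_irt + trial + congruency * lwpc * emotion +
      (1 | participant) + (1 | image),
    dm, ddf = "none"))
}
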