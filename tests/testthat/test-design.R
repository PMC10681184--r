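test_that("synthesize_block_counts realizes proportion targets", {
  # all-congruent block
  m <- synthesize_block_counts(1, c(1, 1, 1, 1), 10)
  expect_equal(unname(diag(m)), rep(10L, 4))
  expect_equal(sum(diag(m)) / sum(m), 1)

  # uniform quarter-congruent block
  m <- synthesize_block_counts(0.25, rep(0.25, 4), 20)
  expect_equal(unname(diag(m)), rep(5L, 4))
  expect_equal(unname(rowSums(m)), rep(20, 4))
  expect_equal(sum(diag(m)) / sum(m), 0.25)

  # graded ISPC block (integer arithmetic at trials_per_location = 24)
  m <- synthesize_block_counts(0.75, c(.875, .833, .667, .625), 24)
  expect_equal(unname(diag(m)), c(21L, 20L, 16L, 15L))
  expect_equal(unname(rowSums(m)), rep(24, 4))
  expect_equal(sum(diag(m)) / sum(m), 72 / 96)
})

test_that("synthesize_block_counts rejects infeasible targets", {
  expect_error(synthesize_block_counts(0.9, rep(0.25, 4), 20), "infeasible")
  expect_error(synthesize_block_counts(0.5, c(1.2, 0.3, 0.3, 0.2), 20))
})

test_that("design_probabilities returns exact rationals", {
  ident <- diag(4) * 10
  pr <- design_probabilities(list(ident))[[1]]
  expect_equal(pr$lwpc, 1)
  expect_equal(unname(pr$ispc), rep(1, 4))
  expect_equal(unname(diag(pr$prs)), rep(1, 4))

  unif <- matrix(3, 4, 4)
  pr <- design_probabilities(list(unif))[[1]]
  expect_equal(pr$lwpc, 0.25)
  expect_equal(unname(pr$ispc), rep(0.25, 4))
  expect_true(all(pr$prs == 0.25))

  m <- synthesize_block_counts(0.75, c(.875, .833, .667, .625), 24)
  pr <- design_probabilities(list(m))[[1]]
  expect_equal(unname(pr$ispc), c(21, 20, 16, 15) / 24, tolerance = 1e-12)
  # per-location PRS rows are proper distributions
  expect_equal(unname(rowSums(pr$prs)), rep(1, 4))

  expect_error(design_probabilities(list(matrix(0, 4, 4))), "zero row sum")
})

test_that("row-sum-weighted mean ISPC equals LWPC on every default block", {
  d <- default_block_design()
  for (pr in design_probabilities(d)) {
    expect_equal(mean(pr$ispc), pr$lwpc, tolerance = 1e-12)
  }
})

test_that("default design has the documented block structure", {
  d <- default_block_design()
  expect_length(d$blocks, 6)
  lw <- vapply(design_probabilities(d), `[[`, numeric(1), "lwpc")
  expect_equal(lw, c(.25, .5, .75, .5, .25, .75))
  expect_equal(lw[c(1, 2, 3)], lw[c(5, 4, 6)])
  expect_true(all(vapply(d$blocks, function(m)
    all(rowSums(m) == 24), logical(1))))
  # ten lower-left trials pointing upper-left in block 1
  expect_equal(d$blocks[[1]]["lower-left", "upper-left"], 10L)
})

test_that("block_design validates inputs", {
  expect_error(block_design(list(matrix(1, 3, 3))), "4x4")
  uneven <- matrix(c(2, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1), 4, 4)
  expect_error(block_design(list(uneven)), "row sums")
  bad_mirror <- default_block_design()$blocks
  bad_mirror[[5]] <- bad_mirror[[3]]
  expect_error(block_design(bad_mirror), "LWPC")
})

test_that("pseudorandomization satisfies all sequencing constraints", {
  d <- mini_design()
  tl <- pseudorandomize(d, seed = 7)
  expect_s3_class(tl, "trial_list")
  expect_equal(nrow(tl), sum(vapply(d$blocks, sum, numeric(1))))
  expect_identical(validate_trial_list(tl, d), TRUE)
  expect_equal(attr(tl, "break_position"), nrow(tl) %/% 2L)

  # independent re-check of the constraints, not via the validator
  n <- nrow(tl)
  expect_false(any(tl$location[-1] == tl$location[-n]))
  expect_false(any(tl$direction[-1] == tl$direction[-n]))
  expect_lte(max(rle(tl$congruency)$lengths), 5)
  expect_equal(tl$congruency,
               as.integer(tl$location == tl$direction))
  # response keys are the fixed direction bijection
  keymap <- c("upper-left" = "E", "upper-right" = "O",
              "lower-right" = "K", "lower-left" = "D")
  expect_equal(tl$response_key, unname(keymap[tl$direction]))
})

test_that("pseudorandomization is deterministic and detects infeasibility", {
  d <- mini_design()
  expect_identical(pseudorandomize(d, seed = 3), pseudorandomize(d, seed = 3))
  expect_false(identical(pseudorandomize(d, seed = 3)$location,
                         pseudorandomize(d, seed = 4)$location))

  # two trials at the same location force a consecutive repeat
  m <- matrix(0L, 4, 4); m[1, 2] <- 1L; m[1, 3] <- 1L
  expect_error(pseudorandomize(list(m), seed = 1), "infeasible")
})

test_that("candidate generation is reproducible and multiset-preserving", {
  d <- mini_design()
  cands <- generate_candidates(d, n = 5, seed = 11)
  expect_length(cands, 5)
  for (tl in cands) expect_identical(validate_trial_list(tl, d), TRUE)
  cands2 <- generate_candidates(d, n = 5, seed = 11)
  expect_identical(cands, cands2)
  one <- generate_candidates(d, n = 1, seed = 2)
  expect_length(one, 1)
})

test_that("shared_variance is a squared correlation with its invariances", {
  x <- c(1, 2, 3, 4)
  expect_equal(shared_variance(x, x), 1)
  expect_equal(shared_variance(x, c(1, -1, -1, 1)), 0)
  y <- c(2, 1, 4, 3)
  expect_equal(shared_variance(x, y), shared_variance(y, x))
  expect_equal(shared_variance(x, y), shared_variance(3 - 2 * x, y),
               tolerance = 1e-12)
  expect_error(shared_variance(x, rep(1, 4)), "zero-variance")
  expect_error(shared_variance(1:2, 1:2))
})

test_that("trial-list selection minimizes ISPC-PRS shared variance", {
  setup <- mini_setup(5)
  d <- setup$design
  cands <- generate_candidates(d, n = 6, seed = 21)
  tabs <- lapply(cands, trialwise_predictors)
  sel <- select_trial_list(cands, tabs)
  crit <- vapply(tabs, function(bt)
    shared_variance(bt$ispc_logit, bt$prs_logit), numeric(1))
  expect_equal(sel$report$shared_variance_ispc_prs, min(crit))
  expect_true(all(sel$report$shared_variance_ispc_prs <= crit))
  expect_equal(sel$report$selected_index, which.min(crit))
  expect_equal(sel$report$n_candidates, 6)

  # permutation invariance of the winner (up to index bookkeeping)
  perm <- c(4, 1, 6, 3, 2, 5)
  sel2 <- select_trial_list(cands[perm], tabs[perm])
  expect_equal(as.data.frame(sel2$trial_list),
               as.data.frame(sel$trial_list))

  one <- select_trial_list(cands[1], tabs[1])
  expect_equal(one$report$selected_index, 1)
  expect_error(select_trial_list(list(), list()), "empty")
})

test_that("trial lists and designs round-trip through CSV/YAML", {
  setup <- mini_setup(2)
  f <- tempfile(fileext = ".csv")
  write_trial_list(setup$trial_list, f)
  back <- read_trial_list(f)
  expect_equal(back$location, setup$trial_list$location)
  expect_equal(back$congruency, setup$trial_list$congruency)

  y <- tempfile(fileext = ".yaml")
  write_block_design_yaml(setup$design, y)
  d2 <- read_block_design_yaml(y)
  expect_equal(d2$blocks, setup$design$blocks)
})
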