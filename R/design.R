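## Design engine: dual proportion-congruency block designs, constrained
## pseudorandomization, candidate generation and trial-list selection.

#' Synthesize a block count matrix from proportion-congruency targets
#'
#' Builds a 4x4 integer matrix of trial counts indexed by (target location,
#' target direction) realizing a list-wide proportion congruency (LWPC) and
#' per-location item-specific proportions (ISPC).  Diagonal cells (location
#' equal to direction) are the congruent trials.  All four locations receive
#' the same number of trials, so each target location is equally probable.
#'
#' @param target_lwpc desired proportion of congruent trials in the block.
#' @param target_ispc length-4 vector of desired congruent proportions per
#'   location, in the order [corners()]; its mean must match `target_lwpc`.
#' @param trials_per_location number of trials at each location (>= 4).
#' @param prs_weights optional 4x4 non-negative weight matrix steering how
#'   each row's incongruent trials are spread over the three off-diagonal
#'   directions (diagonal entries are ignored); default spreads them evenly.
#'   Varying these weights decorrelates the response-given-location
#'   contingency (PRS) from the congruency proportions.
#' @return 4x4 integer matrix with `corners()` dimnames and equal row sums.
#' @export
synthesize_block_counts <- function(target_lwpc, target_ispc,
                                    trials_per_location,
                                    prs_weights = NULL) {
  stopifnot(length(target_ispc) == 4, trials_per_location >= 4,
            all(target_ispc >= 0), all(target_ispc <= 1),
            target_lwpc >= 0, target_lwpc <= 1)
  tpl <- as.integer(trials_per_location)
  if (abs(mean(target_ispc) - target_lwpc) > 1 / tpl)
    stop("infeasible targets: mean(target_ispc) must match target_lwpc ",
         "(difference exceeds 1/trials_per_location)")
  diagonal <- round(target_ispc * tpl)
  if (any(diagonal > tpl))
    stop("infeasible targets: a diagonal count exceeds trials_per_location")

  m <- matrix(0L, 4, 4, dimnames = list(location = corners(),
                                        direction = corners()))
  if (is.null(prs_weights)) prs_weights <- matrix(1, 4, 4)
  stopifnot(all(dim(prs_weights) == c(4, 4)), all(prs_weights >= 0))

  for (i in 1:4) {
    m[i, i] <- diagonal[i]
    rest <- tpl - diagonal[i]
    off <- setdiff(1:4, i)
    w <- prs_weights[i, off]
    if (sum(w) == 0) w <- rep(1, 3)
    m[i, off] <- largest_remainder(rest * w / sum(w), rest)
  }

  achieved <- sum(diag(m)) / sum(m)
  if (abs(achieved - target_lwpc) > 1 / sum(m))
    stop("infeasible targets: rounding the ISPC diagonal gives LWPC ",
         signif(achieved, 4), ", more than 1/total away from ", target_lwpc)
  storage.mode(m) <- "integer"
  m
}

# integer apportionment with fixed total (largest-remainder rule)
largest_remainder <- function(x, total) {
  fl <- floor(x)
  rem <- as.integer(total) - sum(fl)
  if (rem > 0) {
    ord <- order(x - fl, decreasing = TRUE)
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  }
  as.integer(fl)
}

#' Construct a block design
#'
#' Bundles an ordered list of 4x4 location-by-direction count matrices into a
#' validated `block_design` object.  Within each block all location row sums
#' must be equal (equally probable target locations).  For six-block designs
#' the list-wide proportions must mirror across blocks 1&5, 2&4 and 3&6, the
#' balanced presentation order of low and high LWPC blocks.
#'
#' @param blocks list of 4x4 non-negative integer matrices (rows: location,
#'   columns: direction, both in [corners()] order).
#' @param check_mirror enforce the mirrored-LWPC rule when there are exactly
#'   six blocks (default TRUE).
#' @return object of class `block_design`.
#' @export
block_design <- function(blocks, check_mirror = TRUE) {
  stopifnot(is.list(blocks), length(blocks) >= 1)
  blocks <- lapply(seq_along(blocks), function(b) {
    m <- blocks[[b]]
    if (!is.matrix(m) || any(dim(m) != c(4, 4)))
      stop("block ", b, " is not a 4x4 matrix")
    if (any(m < 0) || any(m != round(m)))
      stop("block ", b, " has negative or non-integer counts")
    storage.mode(m) <- "integer"
    dimnames(m) <- list(location = corners(), direction = corners())
    if (length(unique(rowSums(m))) != 1)
      stop("block ", b, ": location row sums are unequal; every target ",
           "location must be equally probable")
    m
  })
  if (check_mirror && length(blocks) == 6) {
    lw <- vapply(blocks, function(m) sum(diag(m)) / sum(m), numeric(1))
    pairs <- list(c(1, 5), c(2, 4), c(3, 6))
    for (p in pairs)
      if (abs(lw[p[1]] - lw[p[2]]) > 1e-12)
        stop("blocks ", p[1], " and ", p[2], " must share the same LWPC")
  }
  structure(list(blocks = blocks), class = "block_design")
}

#' @export
print.block_design <- function(x, ...) {
  pr <- design_probabilities(x)
  cat("Block design:", length(x$blocks), "blocks,",
      sum(vapply(x$blocks, sum, numeric(1))), "trials\n")
  cat("LWPC per block:",
      paste(sprintf("%.3f", vapply(pr, `[[`, numeric(1), "lwpc")),
            collapse = " "), "\n")
  invisible(x)
}

#' Default six-block dual proportion-congruency design
#'
#' Six blocks of 96 trials (24 per location).  LWPC levels are .25/.50/.75,
#' mirrored over blocks 1&5, 2&4 and 3&6.  Within each block, per-location
#' ISPC values offset the block LWPC by (+.125, +.083, -.083, -.125) --
#' e.g. diagonal counts (21, 20, 16, 15) in the .75 blocks -- with the
#' location assignment reversed in the mirror blocks, so the item-specific
#' and list-wide congruency series decouple.  Block 1 contains ten trials at
#' the lower-left location pointing upper-left.
#'
#' @return a [block_design()] object.
#' @export
default_block_design <- function() {
  # Off-diagonal allocations come from a deterministic design-time search
  # that zeroes the block-level (count-weighted, probability-scale)
  # correlations of PRS with both ISPC and LWPC, the orthogonalization the
  # dual-PC construction requires so that contingency learning cannot mimic
  # the congruency-proportion effects.
  spec <- list(
    #           diag counts           off-diagonal weights (by row)
    list(lw = .25, d = c(9, 8, 4, 3),
         w = rbind(c(0, 14, 1, 0), c(14, 0, 1, 1),
                   c(3, 3, 0, 14), c(10, 6, 5, 0))),
    list(lw = .50, d = c(15, 14, 10, 9),
         w = rbind(c(0, 3, 3, 3), c(4, 0, 3, 3),
                   c(14, 0, 0, 0), c(1, 14, 0, 0))),
    list(lw = .75, d = c(21, 20, 16, 15),
         w = rbind(c(0, 1, 1, 1), c(2, 0, 1, 1),
                   c(3, 3, 0, 2), c(3, 3, 3, 0))),
    list(lw = .50, d = c(9, 10, 14, 15),
         w = rbind(c(0, 14, 1, 0), c(14, 0, 0, 0),
                   c(4, 3, 0, 3), c(3, 3, 3, 0))),
    list(lw = .25, d = c(3, 4, 8, 9),
         w = rbind(c(0, 14, 4, 3), c(14, 0, 3, 3),
                   c(14, 1, 0, 1), c(1, 14, 0, 0))),
    list(lw = .75, d = c(15, 16, 20, 21),
         w = rbind(c(0, 3, 3, 3), c(3, 0, 3, 2),
                   c(2, 1, 0, 1), c(1, 1, 1, 0)))
  )
  blocks <- lapply(spec, function(s)
    synthesize_block_counts(s$lw, s$d / 24, 24, prs_weights = s$w))
  block_design(blocks)
}

#' Exact block-wise probabilities of a design
#'
#' Returns, for every block, the list-wide proportion congruency (`lwpc`,
#' trace over total), the item-specific proportion congruency per location
#' (`ispc`, diagonal over row sum) and the response-given-location
#' contingency matrix (`prs`, rows normalized to sum to one).
#'
#' @param design a [block_design()] or list of 4x4 count matrices.
#' @return list with one element per block: `list(lwpc, ispc, prs)`.
#' @export
design_probabilities <- function(design) {
  blocks <- if (inherits(design, "block_design")) design$blocks else design
  lapply(blocks, function(m) {
    rs <- rowSums(m)
    if (any(rs == 0)) stop("zero row sum in block count matrix")
    list(lwpc = sum(diag(m)) / sum(m),
         ispc = setNames(diag(m) / rs, corners()),
         prs  = m / rs)
  })
}

#' Pseudorandomize a block design into a trial list
#'
#' Orders the trials of each block (blocks concatenated 1..n) under the
#' experiment's sequencing constraints: at most `max_congruency_run`
#' consecutive trials of the same congruency, and no two consecutive trials
#' sharing the target location or the target direction (direction determines
#' the response key, so this also forbids response repetitions and first-order
#' priming).  Constraints are enforced across block boundaries as well.
#' Sampling is a weighted greedy draw with bounded restarts; the result is
#' deterministic given `seed`.
#'
#' @param design a [block_design()] or list of 4x4 count matrices.
#' @param seed integer seed.
#' @param max_congruency_run maximal run length of a congruency level.
#' @param max_restarts restarts allowed per block before giving up.
#' @return a `trial_list` data frame with columns block, trial_index,
#'   location, direction, congruency (1 = congruent), response_key, and
#'   attributes `break_position` (index after which the mid-task break falls,
#'   floor(total/2)) and `seed`.
#' @export
pseudorandomize <- function(design, seed, max_congruency_run = 5,
                            max_restarts = 1000) {
  blocks <- if (inherits(design, "block_design")) design$blocks else design
  locf <- rep(1:4, times = 4)   # row index of flat cell (column-major)
  dirf <- rep(1:4, each = 4)
  congf <- as.integer(locf == dirf)

  check_block_feasible(blocks, max_congruency_run)

  with_seed(seed, {
    out_loc <- integer(0); out_dir <- integer(0); out_blk <- integer(0)
    prev_loc <- 0L; prev_dir <- 0L; prev_cong <- -1L; run <- 0L
    for (b in seq_along(blocks)) {
      cnt0 <- as.vector(blocks[[b]])
      nb <- sum(cnt0)
      done <- FALSE
      for (attempt in seq_len(max_restarts)) {
        cnt <- cnt0
        loc_seq <- integer(nb); dir_seq <- integer(nb)
        pl <- prev_loc; pd <- prev_dir; pc <- prev_cong; r <- run
        ok_all <- TRUE
        for (t in seq_len(nb)) {
          w <- cnt
          w[locf == pl | dirf == pd] <- 0
          if (r >= max_congruency_run) w[congf == pc] <- 0
          # one-step feasibility lookahead: after a pick, no location or
          # direction class may exceed the alternation bound on the
          # remaining trials (a class equal to the previous pick can fill
          # at most floor(R/2) of the R remaining slots, any other class
          # at most ceil(R/2))
          if (any(w > 0)) {
            rem <- nb - t
            loc_cnt <- vapply(1:4, function(k) sum(cnt[locf == k]), 0L)
            dir_cnt <- vapply(1:4, function(k) sum(cnt[dirf == k]), 0L)
            for (cell_i in which(w > 0)) {
              lx <- locf[cell_i]; dx <- dirf[cell_i]
              lc <- loc_cnt; lc[lx] <- lc[lx] - 1L
              dc <- dir_cnt; dc[dx] <- dc[dx] - 1L
              bound_l <- (rem + as.integer(1:4 != lx)) %/% 2L
              bound_d <- (rem + as.integer(1:4 != dx)) %/% 2L
              if (any(lc > bound_l) || any(dc > bound_d)) w[cell_i] <- 0
            }
          }
          s <- sum(w)
          if (s == 0) { ok_all <- FALSE; break }
          cell <- sample.int(16L, 1L, prob = w)
          cnt[cell] <- cnt[cell] - 1L
          loc_seq[t] <- locf[cell]; dir_seq[t] <- dirf[cell]
          cg <- congf[cell]
          r <- if (cg == pc) r + 1L else 1L
          pc <- cg; pl <- locf[cell]; pd <- dirf[cell]
        }
        if (ok_all) {
          out_loc <- c(out_loc, loc_seq); out_dir <- c(out_dir, dir_seq)
          out_blk <- c(out_blk, rep(b, nb))
          prev_loc <- pl; prev_dir <- pd; prev_cong <- pc; run <- r
          done <- TRUE
          break
        }
      }
      if (!done)
        stop("pseudorandomization failed for block ", b, " after ",
             max_restarts, " restarts (sequencing constraints unsatisfiable)")
    }
    n <- length(out_loc)
    tl <- data.frame(
      block = out_blk,
      trial_index = seq_len(n),
      location = corners()[out_loc],
      direction = corners()[out_dir],
      congruency = as.integer(out_loc == out_dir),
      response_key = unname(.response_keys[corners()[out_dir]]),
      stringsAsFactors = FALSE
    )
    attr(tl, "break_position") <- n %/% 2L
    attr(tl, "seed") <- seed
    class(tl) <- c("trial_list", "data.frame")
    tl
  })
}

# Fast necessary-condition check: a location (or direction) present on more
# than half the trials of a block forces a consecutive repetition.
check_block_feasible <- function(blocks, max_congruency_run) {
  for (b in seq_along(blocks)) {
    m <- blocks[[b]]
    tot <- sum(m)
    if (tot == 0) next
    if (max(rowSums(m)) > ceiling(tot / 2))
      stop("block ", b, " infeasible: a target location occurs on more than ",
           "half the trials, so consecutive location repetitions are ",
           "unavoidable")
    if (max(colSums(m)) > ceiling(tot / 2))
      stop("block ", b, " infeasible: a target direction occurs on more ",
           "than half the trials, so consecutive response repetitions are ",
           "unavoidable")
    ncong <- sum(diag(m)); ninc <- tot - ncong
    need <- max(ncong, ninc)
    other <- tot - need
    if (ceiling(need / max_congruency_run) - 1 > other)
      stop("block ", b, " infeasible: congruency run-length limit of ",
           max_congruency_run, " cannot be met")
  }
  invisible(TRUE)
}

#' Validate a trial list against its design and sequencing constraints
#'
#' @param trial_list a `trial_list` data frame.
#' @param design optional design whose per-block (location, direction)
#'   multisets the list must reproduce.
#' @param max_congruency_run maximal permitted congruency run length.
#' @return TRUE invisibly; stops with a message on the first violation.
#' @export
validate_trial_list <- function(trial_list, design = NULL,
                                max_congruency_run = 5) {
  n <- nrow(trial_list)
  if (n > 1) {
    same_loc <- trial_list$location[-1] == trial_list$location[-n]
    same_dir <- trial_list$direction[-1] == trial_list$direction[-n]
    if (any(same_loc)) stop("consecutive trials share a location at index ",
                            which(same_loc)[1] + 1)
    if (any(same_dir)) stop("consecutive trials share a direction at index ",
                            which(same_dir)[1] + 1)
    r <- rle(trial_list$congruency)
    if (max(r$lengths) > max_congruency_run)
      stop("congruency run length ", max(r$lengths), " exceeds ",
           max_congruency_run)
  }
  if (!is.null(design)) {
    blocks <- if (inherits(design, "block_design")) design$blocks else design
    for (b in seq_along(blocks)) {
      sub <- trial_list[trial_list$block == b, ]
      got <- table(factor(sub$location, corners()),
                   factor(sub$direction, corners()))
      if (any(got != blocks[[b]]))
        stop("block ", b, ": trial multiset does not match the design counts")
    }
  }
  invisible(TRUE)
}

#' Generate constraint-satisfying candidate trial lists
#'
#' Draws `n` pseudorandomized trial lists from the same design, each with a
#' distinct child seed derived from `seed`, so the whole collection is
#' reproducible from the master seed.
#'
#' @inheritParams pseudorandomize
#' @param n number of candidates (the study generated 1000).
#' @return list of `trial_list` objects.
#' @export
generate_candidates <- function(design, n = 1000, seed,
                                max_congruency_run = 5, max_restarts = 1000) {
  stopifnot(n >= 1)
  seeds <- derive_seeds(seed, n)
  lapply(seeds, function(s)
    pseudorandomize(design, s, max_congruency_run, max_restarts))
}

#' Shared variance of two numeric series
#'
#' Squared Pearson correlation, the proportion of variance two trial-wise
#' predictor series share.  Symmetric and invariant under affine rescaling of
#' either argument.
#'
#' @param x,y numeric vectors of equal length (>= 3) with nonzero variance.
#' @return proportion in \[0, 1\].
#' @export
shared_variance <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0)
    stop("shared_variance undefined for a zero-variance series")
  cor(x, y)^2
}

#' Select the trial list decorrelating item-specific congruency and contingency
#'
#' Among candidate trial lists, picks the one whose trial-wise ISPC and PRS
#' predictor series (logit scale) share the least variance, so that the
#' item-specific proportion-congruency effect cannot be mimicked by
#' associative contingency learning.  Ties break towards the lowest candidate
#' index.
#'
#' @param candidates list of `trial_list` objects.
#' @param belief_tables list of [trialwise_predictors()] tables, one per
#'   candidate.
#' @return list with elements `trial_list`, `beliefs` (the winner's belief
#'   table) and `report` (n_candidates, the winner's three pairwise shared
#'   variances, selected_index).
#' @export
select_trial_list <- function(candidates, belief_tables) {
  if (length(candidates) == 0) stop("empty candidate set")
  stopifnot(length(candidates) == length(belief_tables))
  crit <- vapply(belief_tables, function(bt)
    shared_variance(bt$ispc_logit, bt$prs_logit), numeric(1))
  idx <- which.min(crit)   # which.min takes the first minimum: lowest index
  bt <- belief_tables[[idx]]
  report <- list(
    n_candidates = length(candidates),
    shared_variance_ispc_prs = crit[idx],
    shared_variance_lwpc_prs = shared_variance(bt$lwpc_logit, bt$prs_logit),
    shared_variance_lwpc_ispc = shared_variance(bt$lwpc_logit, bt$ispc_logit),
    selected_index = idx
  )
  list(trial_list = candidates[[idx]], beliefs = bt, report = report)
}

#' Read/write a trial list as CSV
#'
#' @param trial_list a `trial_list`.
#' @param path file path.
#' @return `read_trial_list()` returns a `trial_list` data frame.
#' @export
write_trial_list <- function(trial_list, path) {
  write.csv(as.data.frame(trial_list), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_list
#' @export
read_trial_list <- function(path) {
  tl <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("block", "trial_index", "location", "direction", "congruency")
  miss <- setdiff(need, names(tl))
  if (length(miss)) stop("trial list is missing columns: ",
                         paste(miss, collapse = ", "))
  attr(tl, "break_position") <- nrow(tl) %/% 2L
  class(tl) <- c("trial_list", "data.frame")
  tl
}

#' Read/write a block design as YAML
#'
#' The YAML file holds one 4x4 integer matrix per block (list of rows),
#' locations as rows and directions as columns, both in [corners()] order.
#'
#' @param design a [block_design()].
#' @param path file path.
#' @export
write_block_design_yaml <- function(design, path) {
  blocks <- lapply(design$blocks, function(m)
    lapply(seq_len(nrow(m)), function(i) as.integer(m[i, ])))
  yaml::write_yaml(list(blocks = blocks), path)
  invisible(path)
}

#' @rdname write_block_design_yaml
#' @export
read_block_design_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$blocks)) stop("design YAML must have a top-level 'blocks'")
  blocks <- lapply(raw$blocks, function(b)
    do.call(rbind, lapply(b, as.integer)))
  block_design(blocks)
}
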