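## Synthetic behavioral data with the statistical structure the analysis
## assumes: crossed participant/image random effects, effect-coded factors,
## standardized trial-wise probability predictors, lag-1 dependence through
## the preceding-iRT term, congruency-dependent errors and timeouts.

#' Generative parameters for synthetic spatial-Stroop data
#'
#' Defaults reproduce the fitted final mixed model of the reference study on
#' the inverse-RT scale (iRT = -1000/RT): fixed-effect coefficients for the
#' experimental terms (Congruency, trial-wise LWPC/ISPC, prime Emotion and
#' their interactions) and the confound terms (trial rank, preceding iRT,
#' PRS, PR, PL, horizontal/vertical position and direction codes).  Random
#' variation follows the study's variance partitioning: with total
#' random-plus-residual variance `total_var`, the by-participant intercept,
#' by-image intercept, by-participant congruency slope and residual take .1,
#' .1, .2 and .6 of it.
#'
#' @param fixed named coefficient vector on the iRT scale; names follow the
#'   design-matrix columns (`congruency`, `lwpc`, `congruency:lwpc`, ...).
#' @param total_var total random-plus-residual iRT variance apportioned by
#'   `vpc`.
#' @param vpc named variance shares (participant intercept, image intercept,
#'   participant congruency slope, residual).
#' @param cor_participant correlation between by-participant intercept and
#'   congruency slope.
#' @param error_rate_congruent,error_rate_incongruent Bernoulli response
#'   error probabilities (accuracy is near ceiling on congruent trials).
#' @param n_participants number of simulated participants.
#' @param rt_bounds c(floor, timeout) in ms; responses slower than the
#'   timeout are recorded as missing.
#' @param irt_center,irt_scale fixed constants standardizing the preceding
#'   simulated iRT inside the generator (approximately the marginal mean and
#'   SD of iRT under the defaults).
#' @return list of class `generative_params`.
#' @export
generative_params <- function(
    fixed = c("(Intercept)" = -2.329, trial = -0.103, prec_irt = 0.086,
              prs = -0.05, pr = -0.102, pl = -0.138,
              hpos = -0.013, vpos = 0.021, hdir = -0.006, vdir = -0.074,
              congruency = 0.225, lwpc = 0.058, emotion = 0, ispc = -0.01,
              "congruency:lwpc" = 0.054, "congruency:emotion" = -0.003,
              "lwpc:emotion" = 0.013, "congruency:ispc" = -0.005,
              "emotion:ispc" = -0.007, "congruency:lwpc:emotion" = -0.008,
              "congruency:emotion:ispc" = 0.001),
    total_var = 0.2,
    vpc = c(participant_intercept = 0.1, image_intercept = 0.1,
            participant_slope = 0.2, residual = 0.6),
    cor_participant = 0,
    error_rate_congruent = 0.01, error_rate_incongruent = 0.03,
    n_participants = 74,
    rt_bounds = c(150, 2000),
    irt_center = -2.329, irt_scale = 0.56) {
  stopifnot(total_var > 0, all(vpc >= 0), abs(sum(vpc) - 1) < 1e-9,
            error_rate_congruent >= 0, error_rate_congruent <= 1,
            error_rate_incongruent >= 0, error_rate_incongruent <= 1,
            abs(cor_participant) <= 1, rt_bounds[1] > 0,
            rt_bounds[2] > rt_bounds[1])
  structure(list(
    fixed = fixed,
    sd_participant_intercept = sqrt(vpc[["participant_intercept"]] * total_var),
    sd_participant_slope = sqrt(vpc[["participant_slope"]] * total_var),
    sd_image = sqrt(vpc[["image_intercept"]] * total_var),
    residual_sd = sqrt(vpc[["residual"]] * total_var),
    cor_participant = cor_participant,
    error_rate_congruent = error_rate_congruent,
    error_rate_incongruent = error_rate_incongruent,
    n_participants = as.integer(n_participants),
    rt_bounds = rt_bounds,
    irt_center = irt_center, irt_scale = irt_scale,
    total_var = total_var, vpc = vpc
  ), class = "generative_params")
}

#' Assign prime emotions and images to a trial list
#'
#' Emotion (sad vs neutral face prime) is balanced 50/50 within every block
#' by congruency cell; odd cells round alternately so the imbalance never
#' accumulates.  The prime image is drawn uniformly from the 20 images of the
#' assigned emotion (ids 1-20 sad, 21-40 neutral) with no immediate image
#' repetition.  Deterministic given `seed`.
#'
#' @param trial_list a `trial_list`.
#' @param seed integer seed.
#' @return the trial list with `emotion` ("sad"/"neutral") and `prime_image`
#'   columns filled.
#' @export
assign_primes <- function(trial_list, seed) {
  n <- nrow(trial_list)
  with_seed(seed, {
    emotion <- character(n)
    extra_sad <- TRUE   # alternating rounding for odd cells
    for (b in sort(unique(trial_list$block))) {
      for (cg in c(1, 0)) {
        idx <- which(trial_list$block == b & trial_list$congruency == cg)
        m <- length(idx)
        if (!m) next
        ns <- m %/% 2
        if (m %% 2 == 1) {
          if (extra_sad) ns <- ns + 1
          extra_sad <- !extra_sad
        }
        sad_idx <- if (ns > 0) sample(idx, ns) else integer(0)
        emotion[idx] <- "neutral"
        emotion[sad_idx] <- "sad"
      }
    }
    img <- integer(n)
    prev <- 0L
    for (i in seq_len(n)) {
      pool <- if (emotion[i] == "sad") 1:20 else 21:40
      pool <- setdiff(pool, prev)
      img[i] <- pool[sample.int(length(pool), 1)]
      prev <- img[i]
    }
    trial_list$emotion <- emotion
    trial_list$prime_image <- img
    trial_list
  })
}

# Effect codes and standardized continuous predictors shared by the
# generator and the preprocessing stage (coding: congruent = -1,
# incongruent = +1; neutral = -1, sad = +1; left/lower = -1, right/upper
# = +1).  `constants` fixes the standardization centers/scales; when NULL
# they are computed from the rows supplied and returned as an attribute.
code_predictors <- function(rows, constants = NULL) {
  right <- c("upper-right", "lower-right")
  upper <- c("upper-left", "upper-right")
  out <- data.frame(
    congruency = ifelse(rows$congruency == 1, -1, 1),
    emotion = ifelse(rows$emotion == "sad", 1, -1),
    hpos = ifelse(rows$location %in% right, 1, -1),
    vpos = ifelse(rows$location %in% upper, 1, -1),
    hdir = ifelse(rows$direction %in% right, 1, -1),
    vdir = ifelse(rows$direction %in% upper, 1, -1)
  )
  cont <- c(lwpc = "lwpc_logit", ispc = "ispc_logit", prs = "prs_logit",
            pr = "pr_logit", pl = "pl_logit", trial = "trial_index")
  if (is.null(constants)) {
    constants <- lapply(cont, function(cn)
      list(center = mean(rows[[cn]]), scale = sd(rows[[cn]])))
    names(constants) <- names(cont)
  }
  for (nm in names(cont)) {
    out[[nm]] <- standardize(rows[[cont[[nm]]]],
                             constants[[nm]]$center, constants[[nm]]$scale)
  }
  attr(out, "constants") <- constants
  out
}

# fixed-effect linear predictor matrix for the full factorial structure
design_matrix_fixed <- function(coded) {
  stats::model.matrix(~ trial + prs + pr + pl + hpos + vpos + hdir + vdir +
                        congruency * lwpc * emotion +
                        congruency * ispc * emotion,
                      data = coded)
}

#' Simulate one participant's trial sequence
#'
#' Draws the participant's correlated random intercept and congruency slope,
#' then walks the trial list: the iRT mean is the fixed linear predictor plus
#' random contributions plus the preceding-iRT coefficient times the
#' standardized previous simulated iRT (giving true lag-1 dependence); a
#' Gaussian residual is added (resampled, and counted, in the rare case the
#' implied iRT is non-negative), RT = -1000/iRT is clipped at the floor and
#' censored at the timeout, and response errors are drawn at the
#' congruency-specific rate.
#'
#' @param trial_list a `trial_list` with emotion/prime_image assigned.
#' @param beliefs matching [trialwise_predictors()] table.
#' @param params a [generative_params()] object.
#' @param participant_seed integer seed for this participant.
#' @param image_effects length-40 vector of by-image intercepts (shared
#'   across participants); zeros if NULL.
#' @param participant_id id stored in the output rows.
#' @return data frame of per-trial rows (rt in ms, NA at timeouts).
#' @export
simulate_participant <- function(trial_list, beliefs, params,
                                 participant_seed, image_effects = NULL,
                                 participant_id = 1L) {
  stopifnot(nrow(trial_list) == nrow(beliefs))
  if (is.null(image_effects)) image_effects <- numeric(40)
  rows <- cbind(as.data.frame(trial_list), as.data.frame(beliefs))
  coded <- code_predictors(rows)
  X <- design_matrix_fixed(coded)
  beta <- params$fixed
  miss <- setdiff(colnames(X), names(beta))
  if (length(miss)) stop("generative fixed effects missing terms: ",
                         paste(miss, collapse = ", "))
  b_prec <- beta[["prec_irt"]]
  eta_static <- drop(X %*% beta[colnames(X)])

  with_seed(participant_seed, {
    # correlated intercept/slope draw
    z <- rnorm(2)
    b0 <- params$sd_participant_intercept * z[1]
    b1 <- params$sd_participant_slope *
      (params$cor_participant * z[1] +
         sqrt(1 - params$cor_participant^2) * z[2])

    n <- nrow(rows)
    irt <- numeric(n); rt <- numeric(n); acc <- integer(n)
    resamples <- 0L
    zprev <- rnorm(1)   # marginal draw for the first trial's lag term
    err_rate <- ifelse(coded$congruency == -1,
                       params$error_rate_congruent,
                       params$error_rate_incongruent)
    for (t in seq_len(n)) {
      mu <- eta_static[t] + b_prec * zprev + b0 + b1 * coded$congruency[t] +
        image_effects[rows$prime_image[t]]
      val <- mu + rnorm(1, 0, params$residual_sd)
      tries <- 0L
      while (val >= 0 && tries < 100L) {
        val <- mu + rnorm(1, 0, params$residual_sd)
        tries <- tries + 1L
        resamples <- resamples + 1L
      }
      if (val >= 0) val <- -1e-3   # pathological configuration guard
      irt[t] <- val
      r <- -1000 / val
      if (r < params$rt_bounds[1]) {
        r <- params$rt_bounds[1]
        irt[t] <- -1000 / r
      }
      timeout <- r > params$rt_bounds[2]
      rt[t] <- if (timeout) NA_real_ else r
      acc[t] <- if (timeout) 0L else 1L - rbinom(1, 1, err_rate[t])
      zprev <- (irt[t] - params$irt_center) / params$irt_scale
    }
    out <- data.frame(participant = participant_id,
                      image = rows$prime_image,
                      rows[c("block", "trial_index", "location", "direction",
                             "congruency", "emotion")],
                      rows[c("lwpc_logit", "ispc_logit", "prs_logit",
                             "pr_logit", "pl_logit")],
                      rt = rt, accuracy = acc)
    attr(out, "residual_resamples") <- resamples
    out
  })
}

#' Simulate a complete behavioral dataset
#'
#' All participants run through the same trial list (as in the study, where a
#' single selected list was administered to everyone); by-image random
#' intercepts are drawn once and shared across participants.  If no trial
#' list is supplied, a small candidate set is generated from the design and
#' the minimum ISPC-PRS list selected.
#'
#' @param params a [generative_params()] object.
#' @param design a [block_design()]; default [default_block_design()].
#' @param master_seed integer; every random element (list selection, prime
#'   assignment, image effects, participants) derives from it.
#' @param trial_list,beliefs optional pre-selected list and belief table
#'   (e.g. from [select_trial_list()]); computed from `design` when NULL.
#' @param n_candidates candidate count used only when `trial_list` is NULL.
#' @param hgf HGF parameters used when `beliefs` is NULL.
#' @return data frame of class `behavioral_dataset` with one row per
#'   participant-trial; metadata (seeds, params, selection report) in
#'   attributes.
#' @export
simulate_dataset <- function(params = generative_params(),
                             design = default_block_design(),
                             master_seed = 1L,
                             trial_list = NULL, beliefs = NULL,
                             n_candidates = 10, hgf = hgf_params()) {
  seeds <- derive_seeds(master_seed, 3L + params$n_participants)
  sel_report <- NULL
  if (is.null(trial_list)) {
    cands <- generate_candidates(design, n = n_candidates, seed = seeds[1])
    tabs <- lapply(cands, trialwise_predictors, params = hgf)
    sel <- select_trial_list(cands, tabs)
    trial_list <- sel$trial_list
    beliefs <- sel$beliefs
    sel_report <- sel$report
  }
  if (is.null(beliefs)) beliefs <- trialwise_predictors(trial_list, hgf)
  if (is.null(trial_list$emotion) || all(is.na(trial_list$emotion)))
    trial_list <- assign_primes(trial_list, seeds[2])

  image_effects <- with_seed(seeds[3], rnorm(40, 0, params$sd_image))
  parts <- lapply(seq_len(params$n_participants), function(i)
    simulate_participant(trial_list, beliefs, params,
                         participant_seed = seeds[3L + i],
                         image_effects = image_effects,
                         participant_id = i))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  attr(out, "params") <- params
  attr(out, "master_seed") <- master_seed
  attr(out, "break_position") <- attr(trial_list, "break_position")
  attr(out, "selection_report") <- sel_report
  attr(out, "trial_list") <- trial_list
  class(out) <- c("behavioral_dataset", "data.frame")
  out
}

#' Write a behavioral dataset as CSV with a JSON metadata sidecar
#'
#' @param data a `behavioral_dataset`.
#' @param path CSV path; metadata goes to `<path>.json` (seeds, generative
#'   parameters, package version).
#' @export
write_behavioral_dataset <- function(data, path) {
  write.csv(as.data.frame(data), path, row.names = FALSE)
  p <- attr(data, "params")
  meta <- list(master_seed = attr(data, "master_seed"),
               break_position = attr(data, "break_position"),
               n_participants = p$n_participants,
               fixed = as.list(p$fixed),
               sd_participant_intercept = p$sd_participant_intercept,
               sd_participant_slope = p$sd_participant_slope,
               sd_image = p$sd_image, residual_sd = p$residual_sd,
               package_version = as.character(packageVersion("pcstroop")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
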