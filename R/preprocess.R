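## Preprocessing: exclusion rules, inverse-RT transform, coded and
## standardized design matrix.

#' Inverse reaction-time transform
#'
#' iRT = -1000/RT (RT in ms), the standard normalization of positively
#' skewed RT distributions; strictly increasing in RT and always negative.
#'
#' @param rt_ms positive reaction time(s) in milliseconds.
#' @return iRT value(s).
#' @export
inverse_rt <- function(rt_ms) {
  if (any(!is.na(rt_ms) & rt_ms <= 0)) stop("RT must be positive")
  -1000 / rt_ms
}

#' Apply the trial exclusion rules
#'
#' Removes, per participant: the first trial of the task, the first trial
#' after the mid-task break, error trials (incorrect or missing responses,
#' timeouts counting as missing), and the trial immediately following each
#' error.  Retained rows additionally require a defined preceding iRT — the
#' iRT of the immediately preceding presented trial, whether or not that
#' trial is itself retained — which is attached as `prec_irt_raw` along with
#' `irt`.
#'
#' @param data a `behavioral_dataset` (or any long table with participant,
#'   trial_index, rt, accuracy), ordered by participant then trial index.
#' @param break_position trial index after which the break occurred; taken
#'   from the data's attribute when NULL, and skipped if absent.
#' @return list with `data` (retained rows) and `report` (per-participant
#'   and overall exclusion percentages, counts by reason).
#' @export
apply_exclusions <- function(data, break_position = NULL) {
  if (is.null(break_position)) break_position <- attr(data, "break_position")
  df <- as.data.frame(data)
  ord <- order(df$participant, df$trial_index)
  if (any(ord != seq_len(nrow(df))))
    stop("rows must be ordered by participant then trial index")

  df$irt <- inverse_rt(df$rt)
  err <- df$accuracy == 0 | is.na(df$rt)

  new_part <- c(TRUE, df$participant[-1] != df$participant[-nrow(df)])
  if (is.null(df$prec_irt_raw)) {
    # preceding presented trial's iRT; kept as-is on re-application so the
    # operator stays idempotent after rows have been removed
    prec <- c(NA_real_, df$irt[-nrow(df)])
    prec[new_part] <- NA_real_
    df$prec_irt_raw <- prec
  }
  prec <- df$prec_irt_raw
  post_err <- c(FALSE, err[-length(err)])
  post_err[new_part] <- FALSE

  first <- df$trial_index == 1
  after_break <- if (is.null(break_position)) rep(FALSE, nrow(df))
                 else df$trial_index == break_position + 1
  no_prec <- is.na(prec)
  drop <- first | after_break | err | post_err | no_prec
  retained <- df[!drop, , drop = FALSE]

  per_part <- tapply(drop, df$participant, mean) * 100
  report <- list(
    n_input = nrow(df),
    n_retained = nrow(retained),
    overall_pct_excluded = mean(drop) * 100,
    mean_participant_pct_excluded = mean(per_part),
    sd_participant_pct_excluded = sd(per_part),
    per_participant_pct = per_part,
    n_by_reason = c(first_trial = sum(first),
                    after_break = sum(after_break & !first),
                    error = sum(err & !first & !after_break),
                    post_error = sum(post_err & !err & !first & !after_break),
                    missing_preceding = sum(no_prec & !first & !after_break &
                                              !err & !post_err))
  )
  attrs <- attributes(data)
  for (a in setdiff(names(attrs), c("names", "row.names", "class")))
    attr(retained, a) <- attrs[[a]]
  list(data = retained, report = report)
}

#' Build the coded, standardized analysis design matrix
#'
#' Effect-codes the two-level factors (congruent = -1 / incongruent = +1;
#' neutral = -1 / sad = +1; left = -1 / right = +1 and lower = -1 / upper =
#' +1 for target position and direction), keeps the probability predictors
#' on the natural-log-odds scale and standardizes them, and standardizes the
#' trial rank and the preceding iRT.  Standardization constants default to
#' the analysis sample (mean 0, SD 1 over retained rows) and can be fixed via
#' `constants` — e.g. to reuse the generator's constants in a
#' generative/analysis round trip.
#'
#' @param retained retained rows from [apply_exclusions()] (must carry the
#'   belief predictor columns `lwpc_logit`, ..., `pl_logit`, plus `irt` and
#'   `prec_irt_raw`).
#' @param constants optional list of `list(center, scale)` per continuous
#'   predictor (`lwpc`, `ispc`, `prs`, `pr`, `pl`, `trial`, `prec_irt`).
#' @return data frame with columns participant, image, irt, congruency,
#'   emotion, hpos, vpos, hdir, vdir, lwpc, ispc, prs, pr, pl, trial,
#'   prec_irt; the constants used are attached as attribute `constants`.
#' @export
build_design_matrix <- function(retained, constants = NULL) {
  need <- c("lwpc_logit", "ispc_logit", "prs_logit", "pr_logit", "pl_logit")
  miss <- setdiff(need, names(retained))
  if (length(miss)) stop("missing belief predictor columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(retained$irt)) retained$irt <- inverse_rt(retained$rt)
  if (is.null(retained$prec_irt_raw))
    stop("run apply_exclusions() first: prec_irt_raw column is required")

  coded <- code_predictors(retained, constants = constants)
  constants <- attr(coded, "constants")
  if (is.null(constants$prec_irt))
    constants$prec_irt <- list(center = mean(retained$prec_irt_raw),
                               scale = sd(retained$prec_irt_raw))
  out <- data.frame(
    participant = factor(retained$participant),
    image = factor(retained$image),
    irt = retained$irt,
    coded[c("congruency", "emotion", "hpos", "vpos", "hdir", "vdir",
            "lwpc", "ispc", "prs", "pr", "pl", "trial")],
    prec_irt = standardize(retained$prec_irt_raw,
                           constants$prec_irt$center,
                           constants$prec_irt$scale)
  )
  attr(out, "constants") <- constants
  out
}
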