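## Pipeline orchestration: design -> tracking -> simulation -> preprocessing
## -> fitting -> contrasts, with config, artifact serialization and a
## reproducibility manifest.  Plus the two study-level convenience drivers
## (trial-list selection and parameter recovery) used to reproduce the
## reference conditions.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "pcstroop-run",
    design_yaml = NULL,        # path to a design YAML; default design if NULL
    n_candidates = 50,
    hgf = list(),              # overrides for hgf_params()
    generative = list(),       # overrides for generative_params()
    model = list(formula = NULL, type = "final", eliminate = FALSE,
                 outlier_sd = 2.5, ddf = "none"),
    contrasts = TRUE
  )
}

#' Run the full analysis pipeline
#'
#' Executes design construction, candidate generation, belief tracking,
#' trial-list selection, prime assignment, data simulation, preprocessing,
#' model fitting (optionally with backward elimination and residual-outlier
#' refit) and post-hoc contrasts, writing every intermediate artifact to
#' `out_dir` together with a manifest of file hashes and seeds.  Re-running
#' with the same config reproduces identical artifacts.
#'
#' @param config a named list (merged over the defaults) or path to a YAML
#'   file with entries seed, out_dir, design_yaml, n_candidates, hgf,
#'   generative, model (formula/type/eliminate/outlier_sd/ddf), contrasts.
#' @return the manifest (invisibly written to `manifest.json`).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(pipeline_defaults(), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  save <- function(name) artifacts <<- c(artifacts, file.path(cfg$out_dir, name))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  design <- stage("design", {
    d <- if (!is.null(cfg$design_yaml)) read_block_design_yaml(cfg$design_yaml)
         else default_block_design()
    write_block_design_yaml(d, file.path(cfg$out_dir, "design.yaml"))
    save("design.yaml")
    d
  })

  hgf <- do.call(hgf_params, cfg$hgf)
  seeds <- derive_seeds(cfg$seed, 3L)

  sel <- stage("select", {
    cands <- generate_candidates(design, n = cfg$n_candidates,
                                 seed = seeds[1])
    tabs <- lapply(cands, trialwise_predictors, params = hgf)
    s <- select_trial_list(cands, tabs)
    write_trial_list(s$trial_list, file.path(cfg$out_dir, "trial_list.csv"))
    write_belief_table(s$beliefs, file.path(cfg$out_dir, "beliefs.csv"))
    jsonlite::write_json(s$report, file.path(cfg$out_dir, "selection.json"),
                         auto_unbox = TRUE, digits = NA)
    save("trial_list.csv"); save("beliefs.csv"); save("selection.json")
    s
  })

  gen <- do.call(generative_params, cfg$generative)
  data <- stage("simulate", {
    d <- simulate_dataset(gen, design, master_seed = seeds[2],
                          trial_list = sel$trial_list, beliefs = sel$beliefs)
    write_behavioral_dataset(d, file.path(cfg$out_dir, "dataset.csv"))
    save("dataset.csv"); save("dataset.csv.json")
    d
  })

  analysis <- stage("preprocess", {
    ex <- apply_exclusions(data)
    jsonlite::write_json(ex$report[c("n_input", "n_retained",
                                     "overall_pct_excluded",
                                     "mean_participant_pct_excluded",
                                     "n_by_reason")],
                         file.path(cfg$out_dir, "exclusion_report.json"),
                         auto_unbox = TRUE, digits = NA)
    dm <- build_design_matrix(ex$data)
    write.csv(dm, file.path(cfg$out_dir, "analysis_data.csv"),
              row.names = FALSE)
    save("exclusion_report.json"); save("analysis_data.csv")
    dm
  })

  fit <- stage("fit", {
    form <- if (!is.null(cfg$model$formula)) as.formula(cfg$model$formula)
            else stroop_formula(cfg$model$type)
    f <- if (isTRUE(cfg$model$eliminate)) {
      el <- backward_eliminate(form, analysis)
      jsonlite::write_json(el$comparison,
                           file.path(cfg$out_dir, "elimination.json"),
                           auto_unbox = TRUE, digits = NA)
      save("elimination.json")
      el$fit
    } else {
      fit_mixed_model(form, analysis, method = "REML", ddf = cfg$model$ddf)
    }
    if (is.finite(cfg$model$outlier_sd)) {
      o <- outlier_refit(f, cfg$model$outlier_sd)
      f <- o$fit
      attr(f, "outlier_fraction") <- o$fraction_removed
    }
    write_fit_json(f, file.path(cfg$out_dir, "fit.json"))
    save("fit.json")
    f
  })

  if (isTRUE(cfg$contrasts)) stage("contrasts", {
    sc <- slope_contrasts(fit, "lwpc", k = 4)
    mm <- marginal_means_at(fit)
    pc <- pairwise_contrasts(mm, fit)
    write.csv(sc, file.path(cfg$out_dir, "slope_contrasts.csv"),
              row.names = FALSE)
    write.csv(as.data.frame(mm), file.path(cfg$out_dir, "marginal_means.csv"),
              row.names = FALSE)
    write.csv(pc, file.path(cfg$out_dir, "marginal_contrasts.csv"),
              row.names = FALSE)
    save("slope_contrasts.csv"); save("marginal_means.csv")
    save("marginal_contrasts.csv")
  })

  manifest <- list(
    seed = cfg$seed, derived_seeds = as.list(seeds),
    config = cfg[setdiff(names(cfg), "out_dir")],
    files = lapply(setNames(nm = basename(artifacts)), function(f)
      unname(tools::md5sum(file.path(cfg$out_dir, f))))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Validate a pipeline input file
#'
#' Schema checks for trial-list CSVs, behavioral dataset CSVs and design
#' YAMLs with row/column diagnostics.
#'
#' @param path readable file.
#' @param type `"trial_list"`, `"dataset"`, `"design"` or `"auto"` (guessed
#'   from the extension and columns).
#' @return list with `valid` (logical) and `issues` (character vector,
#'   empty when valid).
#' @export
validate_inputs <- function(path, type = c("auto", "trial_list", "dataset",
                                           "design")) {
  type <- match.arg(type)
  if (!file.exists(path)) return(list(valid = FALSE,
                                      issues = paste("file not found:", path)))
  issues <- character(0)
  add <- function(msg) issues <<- c(issues, msg)

  if (type == "design" ||
      (type == "auto" && grepl("\\.ya?ml$", path, ignore.case = TRUE))) {
    tryCatch(read_block_design_yaml(path), error = function(e)
      add(conditionMessage(e)))
    return(list(valid = length(issues) == 0, issues = issues))
  }

  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) { add(conditionMessage(e)); NULL })
  if (is.null(df)) return(list(valid = FALSE, issues = issues))

  if (type == "auto")
    type <- if ("rt" %in% names(df)) "dataset" else "trial_list"

  need <- if (type == "dataset")
    c("participant", "block", "trial_index", "location", "direction",
      "congruency", "emotion", "rt", "accuracy")
  else c("block", "trial_index", "location", "direction", "congruency")
  for (col in setdiff(need, names(df))) add(paste("missing column:", col))
  if (!length(issues)) {
    bad_loc <- which(!df$location %in% corners())
    if (length(bad_loc)) add(paste("invalid location at rows:",
                                   paste(head(bad_loc, 5), collapse = ", ")))
    bad_dir <- which(!df$direction %in% corners())
    if (length(bad_dir)) add(paste("invalid direction at rows:",
                                   paste(head(bad_dir, 5), collapse = ", ")))
    if (!all(df$congruency %in% c(0, 1)))
      add("congruency must be 0/1")
    if (type == "dataset") {
      bad_rt <- which(!is.na(df$rt) & df$rt <= 0)
      if (length(bad_rt)) add(paste("non-positive RT at rows:",
                                    paste(head(bad_rt, 5), collapse = ", ")))
      if (!all(df$accuracy %in% c(0, 1))) add("accuracy must be 0/1")
    }
  }
  list(valid = length(issues) == 0, issues = issues)
}

#' Reproduce the trial-list selection procedure
#'
#' Generates `n_candidates` pseudorandomized lists from the default
#' six-block design, computes trial-wise LWPC/ISPC/PRS beliefs for each, and
#' selects the list with minimal ISPC-PRS shared variance (the study's list
#' construction, which used 1000 candidates).
#'
#' @param n_candidates number of candidate lists.
#' @param seed master seed.
#' @param design a [block_design()]; the default design if NULL.
#' @param hgf an [hgf_params()] object.
#' @return the [select_trial_list()] result (trial_list, beliefs, report).
#' @export
selection_study <- function(n_candidates = 1000, seed = 1L, design = NULL,
                            hgf = hgf_params()) {
  if (is.null(design)) design <- default_block_design()
  cands <- generate_candidates(design, n = n_candidates, seed = seed)
  tabs <- lapply(cands, trialwise_predictors, params = hgf)
  select_trial_list(cands, tabs)
}

#' Parameter-recovery study on the selected trial list
#'
#' Simulates `n_rep` independent cohorts from the generative model, runs
#' each through exclusions, the inverse-RT transform and the REML fit of the
#' final mixed model, and summarizes every fixed effect by its mean recovered
#' estimate and between-replicate SE.
#'
#' @param trial_list,beliefs a selected list and its belief table (e.g. from
#'   [selection_study()]).
#' @param n_rep number of replicate cohorts.
#' @param seed master seed (one child seed per replicate).
#' @param params a [generative_params()] object.
#' @return list with `estimates` (matrix, replicates x terms), `mean`,
#'   `se` (between-replicate SE of the mean) and `fits` metadata.
#' @export
recovery_study <- function(trial_list, beliefs, n_rep = 5, seed = 1L,
                           params = generative_params()) {
  seeds <- derive_seeds(seed, n_rep)
  est <- NULL
  singular <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    data <- simulate_dataset(params, master_seed = seeds[r],
                             trial_list = trial_list, beliefs = beliefs)
    ex <- apply_exclusions(data)
    dm <- build_design_matrix(ex$data)
    fit <- fit_mixed_model(stroop_formula("final"), dm,
                           method = "REML", ddf = "none")
    b <- coef(fit)
    if (is.null(est)) est <- matrix(NA_real_, n_rep, length(b),
                                    dimnames = list(NULL, names(b)))
    est[r, ] <- b
    singular[r] <- fit$singular
  }
  list(estimates = est,
       mean = colMeans(est),
       se = apply(est, 2, sd) / sqrt(n_rep),
       singular = singular,
       n_participants = params$n_participants,
       seeds = seeds)
}
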