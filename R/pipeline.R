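#' Default pipeline configuration
#'
#' All tunable settings of the end-to-end synthetic study in one list. The
#' defaults mirror the study's shape (34 participants, two training methods
#' between subjects, two sessions within subjects, 8 repetitions of each of
#' the 24 discriminations) with iteration counts scaled for interactive
#' use; `n_iter = 10000` reproduces the full Monte-Carlo setting.
#'
#' @param n_participants Cohort size.
#' @param regime Generative regime for inference behaviour.
#' @param kappa True engagement parameter.
#' @param n_iter Monte-Carlo iterations per model fit.
#' @param n_boot Bootstrap resamples for the model comparison.
#' @param v Voxels per simulated region.
#' @param noise_sd BOLD noise SD.
#' @param lambda Distance-decay constant of the injected structural
#'   similarity.
#' @param nuisance_iter Iterations of the decomposition-nuisance simulation.
#' @param seed Global seed; per-stage substreams derive from it.
#'
#' @return A named list (class `ti_config`).
#' @export
pipeline_config <- function(n_participants = 34L, regime = "OR", kappa = 0.9,
                            n_iter = 1000L, n_boot = 2000L, v = 50L,
                            noise_sd = 1, lambda = 2, nuisance_iter = 50L,
                            seed = 1L) {
  structure(
    list(n_participants = n_participants, regime = regime, kappa = kappa,
         n_iter = n_iter, n_boot = n_boot, v = v, noise_sd = noise_sd,
         lambda = lambda, nuisance_iter = nuisance_iter, seed = seed),
    class = "ti_config"
  )
}

#' Run the end-to-end synthetic study
#'
#' Orchestrates every stage on synthetic data: task design (both training
#' schedules and the in-scanner trial list), behavioural cohort simulation,
#' AND/OR model fitting and comparison, the accuracy GLMM, and a
#' single-"ROI" representational similarity analysis (ground-truth patterns
#' with injected distance structure, per-participant similarity, nuisance
#' predictors, mixed-model fit and outlier rule).
#'
#' @param config A [pipeline_config()] list.
#'
#' @return A list of stage outputs: `schedules`, `scan_trials`, `cohort`
#'   (trial-level data), `fits`, `comparison`, `glmm`, `rsa`, plus a
#'   `summary` tibble of headline numbers (median fitted kappa per model,
#'   mean cross-entropies, preferred model, GLMM interaction estimate, RSA
#'   distance coefficient).
#' @export
run_study_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "ti_config"))
  seed <- config$seed
  schedules <- list(
    interleaved = generate_interleaved_schedule(seed),
    progressive = generate_progressive_schedule(seed)
  )
  scan_trials <- generate_scan_trials(seed)

  profiles <- participant_profiles(
    n = config$n_participants, regime = config$regime, kappa = config$kappa,
    seed = seed
  )
  cohort <- simulate_cohort(profiles, seed = seed)

  fits <- fit_cohort_models(cohort, n_iter = config$n_iter, seed = seed)
  comparison <- compare_models(fits, n_boot = config$n_boot, seed = seed)

  glmm <- fit_glmm(build_accuracy_design(cohort, seed = seed),
                   random = "intercept")

  counts <- summarise_counts(resample_missing(cohort, seed = seed))
  sims <- lapply(seq_len(config$n_participants), function(p) {
    pat <- simulate_patterns(
      v = config$v, lambda = config$lambda,
      seed = (seed * 3001L + p) %% .Machine$integer.max
    )
    noisy <- pat + matrix(
      withr::with_seed((seed * 4001L + p) %% .Machine$integer.max,
                       stats::rnorm(length(pat), sd = config$noise_sd)),
      nrow = nrow(pat)
    )
    dplyr::mutate(
      pattern_similarity(noisy, scope = "within"),
      participant = p,
      method = profiles$method[match(p, profiles$participant)],
      .before = 1
    )
  })
  rsa_table <- build_rsa_table(dplyr::bind_rows(sims), counts)
  rsa <- fit_rsa_lmm(rsa_table, predictors = "full")

  by_model <- comparison$by_fit |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(kappa_median = stats::median(.data$kappa),
                     H_mean = mean(.data$H), .groups = "drop")
  summary <- tibble::tibble(
    preferred_model = by_model$model[which.min(by_model$H_mean)],
    kappa_median_AND = by_model$kappa_median[by_model$model == "AND"],
    kappa_median_OR = by_model$kappa_median[by_model$model == "OR"],
    H_mean_AND = by_model$H_mean[by_model$model == "AND"],
    H_mean_OR = by_model$H_mean[by_model$model == "OR"],
    glmm_method_x_type = glmm$coef$estimate[glmm$coef$term == "tt:mm"],
    rsa_distance = rsa$coef$estimate[rsa$coef$term == "distance_c"],
    rsa_prop_excluded = rsa$prop_excluded
  )
  list(schedules = schedules, scan_trials = scan_trials, cohort = cohort,
       fits = fits, comparison = comparison, glmm = glmm, rsa = rsa,
       summary = summary, config = config)
}
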