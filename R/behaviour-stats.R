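#' Resample missing responses as fair guesses
#'
#' Replaces every missing response with a Bernoulli(1/2) draw, the rule the
#' behavioural regressions use to avoid biases from failures to respond.
#' Latencies of missing trials stay missing (the latency analysis uses
#' correct, answered trials only).
#'
#' @param dataset Trial-level behavioural tibble with `missing` and
#'   `correct` columns.
#' @param seed Integer seed.
#' @return The dataset with missing `correct` values filled in and
#'   `missing` reset to `FALSE` for accuracy purposes (a `resampled`
#'   column records which rows were filled).
#' @export
resample_missing <- function(dataset, seed = 1L) {
  miss <- which(is.na(dataset$correct))
  dataset$resampled <- FALSE
  if (length(miss) > 0) {
    withr::with_seed(seed, {
      dataset$correct[miss] <- stats::rbinom(length(miss), 1, 0.5)
    })
    dataset$resampled[miss] <- TRUE
  }
  dataset
}

#' Per-participant transitive slope
#'
#' The simple Pearson correlation between transitive distance and accuracy
#' over the inferred discriminations, computed per participant and session.
#' Positive slopes (accuracy improves with distance) are the behavioural
#' signature of encoding-based generalisation; negative slopes of
#' retrieval-based generalisation. Slices with zero accuracy variance have
#' an undefined slope and are returned as `NA` with `defined = FALSE`.
#'
#' @param counts Per-discrimination counts (see [summarise_counts()]).
#' @return A tibble with `participant`, `session`, `slope`, `defined`.
#' @export
transitive_slope <- function(counts) {
  counts |>
    dplyr::filter(.data$trial_type == "inferred") |>
    dplyr::group_by(.data$participant, .data$session) |>
    dplyr::summarise(
      slope = if (stats::sd(.data$k / .data$n) == 0) NA_real_ else
        stats::cor(.data$distance, .data$k / .data$n),
      .groups = "drop"
    ) |>
    dplyr::mutate(defined = !is.na(.data$slope))
}

# shared +/-0.5 contrast coding; main effects are then interpretable at the
# grand mean. Distance is mean-centred over its support (inference rows) and
# held at the centred baseline (0) on premise rows.
code_design_columns <- function(df) {
  dmean <- mean(df$distance[df$trial_type == "inferred"])
  df |>
    dplyr::mutate(
      tt = ifelse(.data$trial_type == "inferred", 0.5, -0.5),
      mm = ifelse(.data$method == "progressive", 0.5, -0.5),
      ss = ifelse(.data$session == "remote", 0.5, -0.5),
      dd = ifelse(.data$trial_type == "inferred", .data$distance - dmean, 0)
    )
}

glmm_fixed_formula <- function(lhs) {
  stats::as.formula(paste(
    lhs, "~ tt * mm * ss + dd + dd:mm + dd:ss + dd:mm:ss"
  ))
}

#' Build the accuracy regression design
#'
#' Assembles the binomial accuracy design: outcome = correct count of the 8
#' repetitions per discrimination; fixed effects = trial type, training
#' method and session (all coded +/-0.5), mean-centred transitive distance
#' (inference rows only; premise rows at the centred baseline 0), and all
#' their interactions — 12 coefficients including the intercept. The
#' random-effect specification (within-subject intercepts and slopes by
#' participant, intercepts by discrimination) is attached as metadata for
#' the solver.
#'
#' @param dataset Trial-level behavioural tibble; missing responses are
#'   resampled as fair guesses first.
#' @param seed Seed for the missing-response resampling.
#'
#' @return An object of class `ti_design`: list with `data` (the model
#'   frame), `fixed` (formula), `random` (character vector of random-effect
#'   terms), `family`, `outcome`.
#' @export
build_accuracy_design <- function(dataset, seed = 1L) {
  stopifnot(all(c("participant", "method", "session", "pair", "trial_type",
                  "distance", "correct") %in% names(dataset)))
  if (!all(dataset$method %in% c("interleaved", "progressive")) ||
      !all(dataset$session %in% session_levels())) {
    stop("unknown condition labels in `dataset`")
  }
  counts <- summarise_counts(resample_missing(dataset, seed = seed))
  data <- code_design_columns(counts) |>
    dplyr::mutate(discrimination = paste(.data$session, .data$pair))
  structure(
    list(
      data = data,
      fixed = glmm_fixed_formula("cbind(k, n - k)"),
      random = c("(1 + tt + ss + dd | participant)", "(1 | discrimination)"),
      family = "binomial",
      outcome = "accuracy"
    ),
    class = "ti_design"
  )
}

#' Build the latency regression design
#'
#' Same fixed- and random-effect structure as the accuracy design, but the
#' outcome is the response latency of correct, answered trials, modelled
#' with a gamma distribution and log link.
#'
#' @inheritParams build_accuracy_design
#' @return A `ti_design` object (one row per correct trial).
#' @export
build_latency_design <- function(dataset, seed = 1L) {
  if (!all(dataset$method %in% c("interleaved", "progressive")) ||
      !all(dataset$session %in% session_levels())) {
    stop("unknown condition labels in `dataset`")
  }
  rows <- dataset |>
    dplyr::filter(!is.na(.data$correct), .data$correct == 1,
                  !is.na(.data$latency))
  if (any(rows$latency <= 0)) stop("latencies must be positive")
  data <- code_design_columns(rows) |>
    dplyr::mutate(discrimination = paste(.data$session, .data$pair))
  structure(
    list(
      data = data,
      fixed = glmm_fixed_formula("latency"),
      random = c("(1 + tt + ss + dd | participant)", "(1 | discrimination)"),
      family = "Gamma(log)",
      outcome = "latency"
    ),
    class = "ti_design"
  )
}

#' @export
print.ti_design <- function(x, ...) {
  cat("<ti_design> outcome:", x$outcome, "| family:", x$family, "\n")
  cat("  fixed: ", deparse(x$fixed), "\n")
  cat("  random:", paste(x$random, collapse = " + "), "\n")
  cat("  rows:  ", nrow(x$data), "\n")
  invisible(x)
}

#' Number of fixed-effect columns a design implies
#' @param design A `ti_design` object.
#' @return Integer count including the intercept.
#' @export
n_fixed_effects <- function(design) {
  ncol(stats::model.matrix(design$fixed[-2], data = design$data))
}

#' Fit a behavioural mixed model
#'
#' Delegates estimation to lme4: `glmer` with a binomial logit or gamma log
#' family according to the design. If the mixed solver fails or does not
#' converge, the fit downgrades to a fixed-effects-only GLM and flags the
#' downgrade rather than failing.
#'
#' @param design A `ti_design` from [build_accuracy_design()] or
#'   [build_latency_design()].
#' @param random Random-effect structure: `"full"` uses the design's
#'   specification, `"intercept"` keeps participant intercepts only (faster,
#'   used by the calibration simulations), `"none"` forces the GLM route.
#' @param ... Passed to [lme4::glmer()].
#'
#' @return An object of class `ti_glmm`: list with `coef` (tibble of
#'   estimates, SEs, t values and p values), `fit` (the underlying model
#'   object), `downgraded`, `converged`, `design`.
#' @export
fit_glmm <- function(design, random = c("full", "intercept", "none"), ...) {
  stopifnot(inherits(design, "ti_design"))
  random <- match.arg(random)
  fam <- if (design$family == "binomial") stats::binomial() else
    stats::Gamma(link = "log")
  re_terms <- switch(random,
    full = design$random,
    intercept = "(1 | participant)",
    none = character(0)
  )
  fit <- NULL
  downgraded <- FALSE
  converged <- TRUE
  if (length(re_terms) > 0) {
    form <- stats::as.formula(paste(
      deparse(design$fixed[[2]]), "~",
      deparse(design$fixed[[3]]), "+", paste(re_terms, collapse = " + ")
    ))
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::glmer(form, data = design$data, family = fam, ...)
      )),
      error = function(e) NULL
    )
    if (!is.null(fit) && length(fit@optinfo$conv$lme4) > 0) converged <- FALSE
  }
  if (is.null(fit)) {
    downgraded <- TRUE
    fit <- stats::glm(design$fixed, data = design$data, family = fam)
  }
  coefs <- if (inherits(fit, "glmerMod")) {
    s <- summary(fit)$coefficients
    tibble::tibble(
      term = rownames(s), estimate = s[, 1], std_error = s[, 2],
      statistic = s[, 3], p_value = 2 * stats::pnorm(-abs(s[, 3]))
    )
  } else {
    s <- summary(fit)$coefficients
    tibble::tibble(
      term = rownames(s), estimate = s[, 1], std_error = s[, 2],
      statistic = s[, 3], p_value = s[, 4]
    )
  }
  structure(
    list(coef = coefs, fit = fit, downgraded = downgraded,
         converged = converged, design = design),
    class = "ti_glmm"
  )
}

#' @export
print.ti_glmm <- function(x, ...) {
  cat("<ti_glmm> outcome:", x$design$outcome,
      if (x$downgraded) "[downgraded to GLM]" else "",
      if (!x$converged) "[convergence warning]" else "", "\n")
  print(x$coef)
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.ti_glmm <- function(x, ...) x$coef

#' @rdname tidiers
#' @export
glance.ti_glmm <- function(x, ...) {
  tibble::tibble(
    outcome = x$design$outcome, family = x$design$family,
    n = nrow(x$design$data), downgraded = x$downgraded,
    converged = x$converged
  )
}
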