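#' Assemble the long-format RSA table
#'
#' Joins per-participant pattern similarities with the behavioural
#' covariates and nuisance predictors, producing the table the RSA mixed
#' models are fitted to. Distance enters as a mean-centred continuous
#' predictor; inference accuracy and transitive slope are mean-centred over
#' participants; both nuisance predictors are attached by texture pair. No
#' interaction between inference accuracy and transitive slope is formed at
#' any stage.
#'
#' @param similarities A tibble of [pattern_similarity()] rows with
#'   `participant` and `method` columns added (one block per participant).
#' @param counts Per-discrimination behavioural counts
#'   ([summarise_counts()]) used to derive inference accuracy and
#'   transitive slope per participant and session.
#' @param nuisance_sim Optional [simulation_nuisance()] tibble; when `NULL`
#'   the predictor is set to 0 (noiseless designs do not need it).
#'
#' @return A tibble ready for [fit_rsa_lmm()], with coded columns
#'   `distance_c`, `mm` (method, +/-0.5), `ss` (session, +/-0.5, within
#'   scope only), `accuracy_c`, `slope_c`, `nuisance_copres`,
#'   `nuisance_sim` and the outcome `z`.
#' @export
build_rsa_table <- function(similarities, counts, nuisance_sim = NULL) {
  scope <- unique(similarities$scope)
  stopifnot(length(scope) == 1)
  copres <- copresentation_nuisance(scope = scope)
  behav <- counts |>
    dplyr::filter(.data$trial_type == "inferred") |>
    dplyr::group_by(.data$participant, .data$session) |>
    dplyr::summarise(accuracy = sum(.data$k) / sum(.data$n), .groups = "drop")
  slopes <- transitive_slope(counts)
  behav <- dplyr::left_join(behav, slopes, by = c("participant", "session"))

  tab <- similarities |>
    dplyr::filter(.data$defined) |>
    dplyr::left_join(copres,
                     by = c("texture_1", "texture_2", "session_1", "session_2",
                            "scope", "distance"))
  if (!is.null(nuisance_sim)) {
    tab <- dplyr::left_join(
      tab, nuisance_sim[, c("texture_1", "texture_2", "session_1", "session_2",
                            "nuisance_sim")],
      by = c("texture_1", "texture_2", "session_1", "session_2")
    )
  } else {
    tab$nuisance_sim <- 0
  }

  if (scope == "within") {
    tab$session <- tab$session_1
    tab <- dplyr::left_join(tab, behav, by = c("participant", "session"))
  } else {
    behav_p <- behav |>
      dplyr::group_by(.data$participant) |>
      dplyr::summarise(accuracy = mean(.data$accuracy),
                       slope = mean(.data$slope, na.rm = TRUE),
                       .groups = "drop")
    tab <- dplyr::left_join(tab, behav_p, by = "participant")
  }
  dropped <- !is.finite(tab$slope) | !is.finite(tab$accuracy)
  if (any(dropped)) {
    message(sum(dropped), " rows dropped for missing behavioural covariates")
    tab <- tab[!dropped, ]
  }
  tab |>
    dplyr::mutate(
      distance_c = .data$distance - mean(.data$distance),
      mm = ifelse(.data$method == "progressive", 0.5, -0.5),
      ss = if (scope[[1]] == "within")
        ifelse(.data$session == "remote", 0.5, -0.5) else 0,
      accuracy_c = .data$accuracy - mean(.data$accuracy),
      slope_c = .data$slope - mean(.data$slope)
    )
}

rsa_formula <- function(scope, predictors = c("full", "distance"),
                        nuisance = TRUE) {
  predictors <- match.arg(predictors)
  if (predictors == "distance") {
    rhs <- "distance_c"
  } else {
    vars <- if (scope == "within") c("mm", "ss", "dd", "acc", "slp") else
      c("mm", "dd", "acc", "slp")
    subsets <- unlist(lapply(seq_along(vars), function(k) {
      utils::combn(vars, k, simplify = FALSE)
    }), recursive = FALSE)
    # the accuracy x slope interaction (at any order) is never included
    subsets <- Filter(function(s) !all(c("acc", "slp") %in% s), subsets)
    terms <- vapply(subsets, paste, "", collapse = ":")
    map <- c(mm = "mm", ss = "ss", dd = "distance_c", acc = "accuracy_c",
             slp = "slope_c")
    terms <- vapply(strsplit(terms, ":"), function(s) {
      paste(map[s], collapse = ":")
    }, "")
    rhs <- paste(terms, collapse = " + ")
  }
  if (nuisance) rhs <- paste(rhs, "+ nuisance_copres + nuisance_sim")
  stats::as.formula(paste("z ~", rhs))
}

#' Fit the RSA linear mixed model
#'
#' Fits the Fisher-z similarity table with an identity-link LMM (maximum
#' likelihood via lme4), with participant-level random intercepts and
#' distance slopes. After the initial fit, a single outlier pass excludes
#' observations whose absolute standardised residual exceeds
#' [outlier_threshold()] evaluated at the model's sample size, and refits.
#' If the mixed solver fails, the fit downgrades to a fixed-effects linear
#' model with a flag.
#'
#' @param table A [build_rsa_table()] tibble.
#' @param predictors `"full"` (all condition/behaviour predictors and their
#'   admissible interactions) or `"distance"` (distance plus nuisances
#'   only; used by reduced simulations).
#' @param exclude_outliers Apply the residual-outlier pass (default TRUE).
#'
#' @return An object of class `ti_rsa`: list with `coef` (tibble), `fit`,
#'   `n_excluded`, `prop_excluded`, `threshold`, `downgraded`, `scope`,
#'   `formula`, `table`.
#' @export
fit_rsa_lmm <- function(table, predictors = c("full", "distance"),
                        exclude_outliers = TRUE) {
  predictors <- match.arg(predictors)
  scope <- unique(table$scope)
  form <- rsa_formula(scope, predictors)
  fit_once <- function(dat) {
    f <- stats::update(form, . ~ . + (1 + distance_c | participant))
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(f, data = dat, REML = FALSE)
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) list(fit = stats::lm(form, data = dat), downgraded = TRUE)
    else list(fit = fit, downgraded = FALSE)
  }
  first <- fit_once(table)
  n_excluded <- 0L
  thr <- outlier_threshold(nrow(table))
  dat <- table
  if (exclude_outliers) {
    res <- if (inherits(first$fit, "lmerMod")) {
      stats::resid(first$fit, scaled = TRUE)
    } else {
      stats::rstandard(first$fit)
    }
    keep <- abs(res) <= thr
    n_excluded <- sum(!keep)
    if (n_excluded > 0) {
      dat <- table[keep, ]
      first <- fit_once(dat)
    }
  }
  fit <- first$fit
  coefs <- if (inherits(fit, "lmerMod")) {
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
    list(coef = coefs, fit = fit, n_excluded = n_excluded,
         prop_excluded = n_excluded / nrow(table), threshold = thr,
         downgraded = first$downgraded, scope = scope, formula = form,
         table = dat),
    class = "ti_rsa"
  )
}

#' @export
print.ti_rsa <- function(x, ...) {
  cat("<ti_rsa> scope:", x$scope,
      "| outliers excluded:", x$n_excluded,
      sprintf("(%.3f%%, threshold %.2f)", 100 * x$prop_excluded, x$threshold),
      if (x$downgraded) "[downgraded to LM]" else "", "\n")
  print(x$coef)
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.ti_rsa <- function(x, ...) x$coef

#' @rdname tidiers
#' @export
glance.ti_rsa <- function(x, ...) {
  tibble::tibble(
    scope = x$scope, n = nrow(x$table), n_excluded = x$n_excluded,
    prop_excluded = x$prop_excluded, threshold = x$threshold,
    downgraded = x$downgraded
  )
}

#' Refit the RSA excluding directly-trained pairs
#'
#' Sensitivity analysis guarding against distance effects driven solely by
#' elevated similarity of textures shown together in a premise pair: refits
#' the within-hierarchy model on rows with transitive distance >= 2
#' (dropping the four distance-1 pairs per session).
#'
#' @inheritParams fit_rsa_lmm
#' @return A `ti_rsa` object fitted to the reduced table.
#' @export
delta1_sensitivity <- function(table, predictors = c("full", "distance"),
                               exclude_outliers = TRUE) {
  reduced <- dplyr::filter(table, .data$distance >= 2) |>
    dplyr::mutate(distance_c = .data$distance - mean(.data$distance))
  fit_rsa_lmm(reduced, predictors = predictors,
              exclude_outliers = exclude_outliers)
}

#' Broom-style tidiers for transitr fits
#'
#' `tidy()` returns per-term or per-inference tibbles; `glance()` returns
#' one-row model summaries.
#'
#' @param x A fitted object (`ti_fit`, `ti_glmm` or `ti_rsa`).
#' @param ... Unused.
#' @name tidiers
NULL

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
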