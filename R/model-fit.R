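#' Generalisation probability under the AND or OR model
#'
#' Both descriptive models turn sampled premise retrieval probabilities into
#' the probability `g` of a memory-guided correct inference. The
#' retrieval-based AND model requires every mediating contingency:
#' \eqn{g^{and} = \kappa \prod_{r_p \in A} r_p}. The encoding-based OR model
#' requires either end contingency (prefer the high stimulus or avoid the
#' low one): \eqn{g^{or} = \kappa (1 - \prod_{r_p \in O} (1 - r_p))}.
#' `kappa` in `[0, 1]` is the probability of engaging memory-guided
#' generalisation at all, rather than guessing.
#'
#' @param model `"AND"` or `"OR"`.
#' @param kappa Generalisation-engagement probability in `[0, 1]`.
#' @param samples Numeric vector of sampled retrieval probabilities: the
#'   full mediating set for AND, the end premises for OR.
#'
#' @return The generalisation probability `g` in `[0, 1]`.
#'
#' @examples
#' generalisation_prob("AND", 0.9, c(0.9, 0.8))
#' generalisation_prob("OR", 0.9, c(0.9, 0.8))
#' @export
generalisation_prob <- function(model = c("AND", "OR"), kappa, samples) {
  model <- match.arg(model)
  if (kappa < 0 || kappa > 1) stop("`kappa` must lie in [0, 1]")
  if (length(samples) == 0) stop("`samples` must be non-empty")
  if (model == "AND") kappa * prod(samples) else kappa * (1 - prod(1 - samples))
}

#' Probability of k correct inference responses
#'
#' Identical two-stage form as [premise_prob()] with the generalisation
#' probability `g` in place of the retrieval probability: with probability
#' `g` the inference is made from memory (correct), otherwise the response
#' is a guess.
#'
#' @inheritParams premise_prob
#' @param g Generalisation probability in `[0, 1]`.
#' @return Probabilities, recycled over `k` and `g`.
#' @export
inference_prob <- function(k, n = 8L, g) {
  premise_prob(k, n, g)
}

# closed binomial form, used internally where speed matters (the Monte-Carlo
# objective evaluates this millions of times)
.resp_prob <- function(k, n, g) {
  choose(n, k) * ((1 + g) / 2)^k * ((1 - g) / 2)^(n - k)
}

#' Fit the AND or OR model to one participant/condition
#'
#' For one participant and training condition, premise performance (`k_p`
#' correct of `n` per premise pair) defines a normalised likelihood over
#' each pair's retrieval probability. The fitter repeatedly samples
#' retrieval probabilities from those likelihoods by inverse-transform
#' sampling (`n_iter` iterations, common random numbers across `kappa`
#' evaluations), converts each draw into a generalisation probability for
#' every inferred pair under the chosen model, and averages the response
#' probabilities \eqn{\Pr(k_i \mid n, g_i)} over iterations. The engagement
#' parameter `kappa` is then chosen to minimise the cross-entropy
#' \deqn{H = -\frac{1}{I} \sum_{i=1}^{I} \log \widehat{\Pr}(k_i \mid n, g_i),}
#' the mean negative log probability of the observed inference counts, by
#' bounded scalar minimisation on `[0, 1]` with endpoint checks.
#'
#' @param premise_counts Named numeric vector: correct counts for the six
#'   premise pairs (names `"A>B"` ... `"F>G"`).
#' @param inference_counts Named numeric vector: correct counts for the
#'   inferred pairs (names like `"B>D"`).
#' @param model `"AND"` or `"OR"`.
#' @param n Trials per discrimination (default 8).
#' @param n_iter Monte-Carlo iterations (default 10000).
#' @param seed Integer seed for the contingency samples.
#'
#' @return An object of class `ti_fit`: list with `model`, `kappa`, `H`
#'   (cross-entropy, nats, per inference), `prob` (tibble of per-inference
#'   averaged probabilities and expected correct counts), `n_iter`, `seed`,
#'   `convergence` (optimiser diagnostic, 0 = clean).
#'
#' @examples
#' prem <- stats::setNames(c(8, 8, 7, 8, 8, 8), paste0(LETTERS[1:6], ">", LETTERS[2:7]))
#' infr <- stats::setNames(c(8, 7, 8, 6, 8, 7), c("B>D", "C>E", "D>F", "B>E", "C>F", "B>F"))
#' fit_inference_model(prem, infr, model = "OR", n_iter = 500, seed = 1)
#' @export
fit_inference_model <- function(premise_counts, inference_counts,
                                model = c("AND", "OR"), n = 8L,
                                n_iter = 10000L, seed = 1L) {
  model <- match.arg(model)
  stopifnot(length(premise_counts) == 6, !is.null(names(premise_counts)),
            !is.null(names(inference_counts)))
  sets <- mediating_sets(names(inference_counts))

  # one likelihood per premise pair; common random draws across kappa values
  liks <- lapply(premise_counts, build_likelihood, n = n)
  r_draws <- withr::with_seed(seed, {
    u <- matrix(stats::runif(6L * n_iter), nrow = n_iter)
    vapply(1:6, function(p) sample_r(liks[[p]], u[, p]), numeric(n_iter))
  })
  colnames(r_draws) <- names(premise_counts)

  # per-iteration model-specific kernels: g = kappa * kern
  kerns <- vapply(sets, function(s) {
    if (model == "AND") {
      apply(r_draws[, s$all, drop = FALSE], 1, prod)
    } else {
      1 - apply(1 - r_draws[, s$ends, drop = FALSE], 1, prod)
    }
  }, numeric(n_iter))

  k_i <- inference_counts
  avg_prob <- function(kappa) {
    vapply(seq_along(k_i), function(i) {
      mean(.resp_prob(k_i[i], n, kappa * kerns[, i]))
    }, numeric(1))
  }
  objective <- function(kappa) -mean(log(avg_prob(kappa)))

  opt <- stats::optimize(objective, interval = c(0, 1), tol = 1e-6)
  # guard against flat or edge-favouring objectives
  cand <- c(opt$minimum, 0, 0.5, 1)
  vals <- vapply(cand, objective, numeric(1))
  kappa_hat <- cand[which.min(vals)]
  H <- min(vals)

  p_hat <- avg_prob(kappa_hat)
  g_bar <- vapply(seq_along(k_i), function(i) mean(kappa_hat * kerns[, i]),
                  numeric(1))
  prob <- tibble::tibble(
    pair = names(k_i),
    distance = lengths(lapply(sets, `[[`, "all")),
    k = as.numeric(k_i),
    prob = p_hat,
    g_mean = g_bar,
    expected_k = n * (1 + g_bar) / 2
  )
  structure(
    list(model = model, kappa = kappa_hat, H = H, prob = prob, n = n,
         n_iter = n_iter, seed = seed,
         convergence = if (is.finite(H)) 0L else 1L),
    class = "ti_fit"
  )
}

#' @export
print.ti_fit <- function(x, ...) {
  cat("<ti_fit> ", x$model, " model: kappa = ", round(x$kappa, 4),
      ", H = ", round(x$H, 4), " (", x$n_iter, " iterations)\n", sep = "")
  print(x$prob)
  invisible(x)
}

#' Expected correct counts under a fitted model
#'
#' For a generalisation probability `g`, the expected number of correct
#' responses to `n` trials is `n * (1 + g) / 2` (memory-guided successes
#' plus half of the guesses); the fit averages this over Monte-Carlo
#' iterations.
#'
#' @param fit A `ti_fit` object.
#' @return A tibble with `pair`, observed `k` and `expected_k`.
#' @export
expected_correct <- function(fit) {
  stopifnot(inherits(fit, "ti_fit"))
  fit$prob[, c("pair", "k", "expected_k")]
}

#' @rdname tidiers
#' @export
tidy.ti_fit <- function(x, ...) {
  dplyr::mutate(x$prob, model = x$model, .before = 1)
}

#' @rdname tidiers
#' @export
glance.ti_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, kappa = x$kappa, H = x$H,
    n_inferences = nrow(x$prob), n_iter = x$n_iter, seed = x$seed
  )
}

#' Compare AND and OR fits across a cohort
#'
#' Takes per-participant/condition fits of both models and summarises the
#' model comparison: the cross-entropy of each fit, the Spearman rank
#' correlation between observed and model-expected correct counts over the
#' inferred discriminations, and a bootstrapped paired t statistic on the
#' participant-level difference in Spearman correlations (OR minus AND).
#' Participants whose expected counts are constant under a model (Spearman
#' undefined) are flagged and excluded from the correlation contrast.
#'
#' @param fits A tibble with columns `participant`, `session` (or any other
#'   grouping columns), `model` and a list-column `fit` of `ti_fit` objects;
#'   the output of [fit_cohort_models()] has this shape.
#' @param n_boot Bootstrap resamples for the paired t statistic.
#' @param seed Seed for the bootstrap.
#'
#' @return A list with `by_fit` (per-fit H, kappa and Spearman rho),
#'   `contrast` (per participant mean rho under each model and their
#'   difference) and `bootstrap` (mean difference, bootstrap SE, t statistic
#'   and number of participants).
#' @export
compare_models <- function(fits, n_boot = 10000L, seed = 1L) {
  stopifnot(all(c("participant", "model", "fit") %in% names(fits)))
  by_fit <- fits |>
    dplyr::mutate(
      kappa = purrr::map_dbl(.data$fit, "kappa"),
      H = purrr::map_dbl(.data$fit, "H"),
      rho = purrr::map_dbl(.data$fit, function(f) {
        ek <- f$prob$expected_k
        if (stats::sd(ek) == 0 || stats::sd(f$prob$k) == 0) return(NA_real_)
        stats::cor(f$prob$k, ek, method = "spearman")
      })
    ) |>
    dplyr::select(-"fit")

  contrast <- by_fit |>
    dplyr::group_by(.data$participant, .data$model) |>
    dplyr::summarise(rho = mean(.data$rho, na.rm = TRUE), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "model", values_from = "rho") |>
    dplyr::mutate(diff = .data$OR - .data$AND) |>
    dplyr::filter(is.finite(.data$diff))

  d <- contrast$diff
  boot_t <- withr::with_seed(seed, {
    means <- vapply(seq_len(n_boot), function(b) mean(sample(d, replace = TRUE)),
                    numeric(1))
    se <- stats::sd(means)
    if (se == 0) 0 else mean(d) / se
  })
  list(
    by_fit = by_fit,
    contrast = contrast,
    bootstrap = tibble::tibble(
      mean_diff = mean(d),
      se = if (length(d) > 1) stats::sd(d) / sqrt(length(d)) else NA_real_,
      t = boot_t, n = length(d), n_boot = n_boot
    )
  )
}

#' Fit both models to every participant/condition in a cohort
#'
#' Convenience wrapper: collapses a trial-level dataset to counts (after
#' resampling missing responses as fair guesses, the same rule used by the
#' behavioural regressions), then fits the AND and OR models to each
#' participant x session slice.
#'
#' @param dataset Trial-level behavioural tibble (see [simulate_cohort()]).
#' @param models Character vector of models to fit.
#' @param n_iter Monte-Carlo iterations per fit.
#' @param seed Integer seed; per-fit substreams are derived from it.
#'
#' @return A tibble with `participant`, `method`, `session`, `model` and a
#'   list-column `fit` of `ti_fit` objects.
#' @export
fit_cohort_models <- function(dataset, models = c("AND", "OR"),
                              n_iter = 10000L, seed = 1L) {
  counts <- summarise_counts(resample_missing(dataset, seed = seed))
  slices <- dplyr::distinct(counts, .data$participant, .data$method, .data$session)
  out <- tidyr::expand_grid(slices, model = models)
  out$fit <- purrr::pmap(out, function(participant, method, session, model) {
    sl <- dplyr::filter(counts, .data$participant == !!participant,
                        .data$session == !!session)
    prem <- sl[sl$trial_type == "premise", ]
    infr <- sl[sl$trial_type == "inferred", ]
    sub_seed <- (seed * 7919L + participant * 13L +
                   ifelse(session == "recent", 0L, 1L) +
                   ifelse(model == "AND", 0L, 5L)) %% .Machine$integer.max
    fit_inference_model(
      stats::setNames(prem$k, prem$pair),
      stats::setNames(infr$k, infr$pair),
      model = model, n = max(sl$n), n_iter = n_iter, seed = sub_seed
    )
  })
  out
}
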