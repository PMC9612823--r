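#' Build a synthetic participant cohort
#'
#' Creates ground-truth participant profiles mirroring the study's shape:
#' `n` participants split evenly between interleaved and progressive
#' training (between-subjects), each with two within-subject sessions
#' (recent/remote). Every participant carries a true retrieval probability
#' for each of the six premise pairs per session, drawn from a Beta
#' distribution whose default, `Beta(8, 2)` (mean 0.8), mimics the
#' near-ceiling premise performance typical of well-trained cohorts; a
#' generative regime (`"AND"` retrieval-based or `"OR"` encoding-based); an
#' engagement parameter `kappa_true`; a missing-response rate (default
#' 0.0181, i.e. 1.81% of trials); and gamma latency parameters.
#'
#' @param n Number of participants (default 34).
#' @param regime Generative regime for inference responses, `"OR"` or
#'   `"AND"`; recycled over participants.
#' @param kappa True engagement probability; recycled.
#' @param beta_shape1,beta_shape2 Beta parameters for retrieval
#'   probabilities.
#' @param miss_rate Probability a response is missing.
#' @param latency_shape Gamma shape of response latencies.
#' @param latency_mean Mean latency (seconds) on premise trials.
#' @param inferred_mult Multiplicative latency effect of inferred trials
#'   (log-link scale > 1 means slower inferences).
#' @param seed Integer seed.
#'
#' @return A tibble with one row per participant x session, carrying
#'   `participant`, `method`, `session`, `regime`, `kappa_true`,
#'   `miss_rate`, latency parameters and a list-column `retrieval` (named
#'   vector of six true retrieval probabilities).
#' @export
participant_profiles <- function(n = 34L, regime = "OR", kappa = 0.9,
                                 beta_shape1 = 8, beta_shape2 = 2,
                                 miss_rate = 0.0181,
                                 latency_shape = 8, latency_mean = 1.2,
                                 inferred_mult = 1.15, seed = 1L) {
  labs <- texture_labels()
  pairs <- paste0(labs[1:6], ">", labs[2:7])
  grid <- tidyr::expand_grid(
    participant = seq_len(n),
    session = session_levels()
  )
  withr::with_seed(seed, {
    grid$retrieval <- lapply(seq_len(nrow(grid)), function(i) {
      stats::setNames(stats::rbeta(6, beta_shape1, beta_shape2), pairs)
    })
  })
  grid |>
    dplyr::mutate(
      method = ifelse(.data$participant %% 2 == 1, "interleaved", "progressive"),
      regime = rep_len(regime, dplyr::n()),
      kappa_true = rep_len(kappa, dplyr::n()),
      miss_rate = miss_rate,
      latency_shape = latency_shape,
      latency_mean = latency_mean,
      inferred_mult = inferred_mult
    ) |>
    dplyr::relocate("participant", "method", "session", "regime", "kappa_true")
}

#' Simulate correct counts for a premise discrimination
#'
#' Generative inverse of the two-stage response process behind
#' [premise_prob()]: on each of `n` trials the contingency is retrieved with
#' probability `r` (correct), otherwise the response is a coin-flip guess.
#'
#' @param r Retrieval probability in `[0, 1]` (vectorised: one count is
#'   returned per element).
#' @param n Trials per discrimination (default 8).
#' @param seed Integer seed.
#'
#' @return Integer vector of correct counts, one per element of `r`.
#' @export
simulate_premise_responses <- function(r, n = 8L, seed = 1L) {
  if (any(r < 0 | r > 1)) stop("`r` must lie in [0, 1]")
  withr::with_seed(seed, {
    vapply(r, function(ri) {
      sum(stats::rbinom(n, 1, (1 + ri) / 2))
    }, integer(1))
  })
}

#' Simulate correct counts for inferred discriminations
#'
#' Computes the true generalisation probability for each inferred pair from
#' a profile's regime, `kappa_true` and true retrieval probabilities
#' (AND: product over all mediating premises; OR: either end premise), then
#' draws responses through the same generalise-then-guess process.
#'
#' @param retrieval Named vector of six true retrieval probabilities.
#' @param regime `"AND"` or `"OR"`.
#' @param kappa True engagement probability.
#' @param n Trials per discrimination.
#' @param seed Integer seed.
#'
#' @return A tibble with `pair`, `distance`, `g_true` and the simulated
#'   correct count `k` for the six inferred pairs.
#' @export
simulate_inference_responses <- function(retrieval, regime = c("OR", "AND"),
                                         kappa = 0.9, n = 8L, seed = 1L) {
  regime <- match.arg(regime)
  inferred <- dplyr::filter(build_hierarchy("recent"), .data$trial_type == "inferred")
  sets <- mediating_sets(inferred$pair)
  g <- vapply(sets, function(s) {
    generalisation_prob(regime, kappa,
                        retrieval[if (regime == "AND") s$all else s$ends])
  }, numeric(1))
  k <- withr::with_seed(seed, {
    vapply(g, function(gi) sum(stats::rbinom(n, 1, (1 + gi) / 2)), integer(1))
  })
  tibble::tibble(pair = inferred$pair, distance = inferred$distance,
                 g_true = unname(g), k = unname(k))
}

#' Simulate a full behavioural cohort
#'
#' Expands participant profiles into a trial-level behavioural dataset for
#' the in-scanner task: 8 trials per discrimination, 24 discriminations per
#' participant (6 premise + 6 inferred in each of two sessions), with
#' per-trial correctness from the generative retrieval/generalisation
#' process, missing responses, and gamma latencies for answered trials.
#'
#' @param profiles Output of [participant_profiles()].
#' @param n Trials per discrimination (default 8).
#' @param seed Integer seed; per-participant substreams are derived from it.
#'
#' @return A tibble with one row per trial: `participant`, `method`,
#'   `session`, `pair`, `trial_type`, `distance`, `trial` (1..8), `correct`
#'   (0/1, `NA` when missing), `missing`, `latency` (seconds, `NA` when
#'   missing).
#' @export
simulate_cohort <- function(profiles, n = 8L, seed = 1L) {
  hier <- build_hierarchy("recent")[, c("pair", "trial_type", "distance")]
  rows <- purrr::pmap(profiles, function(participant, method, session, regime,
                                         kappa_true, retrieval, miss_rate,
                                         latency_shape, latency_mean,
                                         inferred_mult, ...) {
    sub_seed <- (seed * 10007L + participant * 101L +
                   ifelse(session == "recent", 0L, 1L)) %% .Machine$integer.max
    withr::with_seed(sub_seed, {
      # success probability per discrimination
      sets <- mediating_sets(hier$pair[hier$trial_type == "inferred"])
      p_succ <- vapply(seq_len(nrow(hier)), function(i) {
        if (hier$trial_type[i] == "premise") {
          retrieval[[hier$pair[i]]]
        } else {
          s <- sets[[hier$pair[i]]]
          generalisation_prob(regime, kappa_true,
                              retrieval[if (regime == "AND") s$all else s$ends])
        }
      }, numeric(1))
      df <- hier[rep(seq_len(nrow(hier)), each = n), ]
      df$trial <- rep(seq_len(n), times = nrow(hier))
      p <- rep(p_succ, each = n)
      df$correct <- stats::rbinom(nrow(df), 1, (1 + p) / 2)
      df$missing <- stats::runif(nrow(df)) < miss_rate
      df$correct[df$missing] <- NA_integer_
      mult <- ifelse(df$trial_type == "inferred", inferred_mult, 1)
      lat <- stats::rgamma(nrow(df), shape = latency_shape,
                           scale = latency_mean * mult / latency_shape)
      df$latency <- pmin(lat, 3)
      df$latency[df$missing] <- NA_real_
      dplyr::mutate(df, participant = participant, method = method,
                    session = session, .before = 1)
    })
  })
  dplyr::bind_rows(rows)
}

#' Flag trials as missing at random
#'
#' Independently flags each trial missing with probability `miss_rate`
#' (default 0.0181, the average non-response rate the analysis assumes);
#' missing trials lose their response and latency.
#'
#' @param dataset A trial-level behavioural tibble.
#' @param miss_rate Missingness probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return The dataset with updated `missing`, `correct`, `latency`.
#' @export
simulate_missingness <- function(dataset, miss_rate = 0.0181, seed = 1L) {
  if (miss_rate < 0 || miss_rate >= 1) stop("`miss_rate` must lie in [0, 1)")
  withr::with_seed(seed, {
    miss <- stats::runif(nrow(dataset)) < miss_rate
  })
  dataset$missing <- miss
  dataset$correct[miss] <- NA_integer_
  if ("latency" %in% names(dataset)) dataset$latency[miss] <- NA_real_
  dataset
}

#' Draw gamma latencies for answered trials
#'
#' Latencies follow a gamma distribution whose mean is scaled
#' multiplicatively by condition effects (matching the log link used in the
#' latency analysis) and truncated at the 3-second response window.
#'
#' @param dataset Trial-level tibble with `trial_type` and `missing`.
#' @param shape Gamma shape (> 0).
#' @param mean_premise Mean latency on premise trials (seconds, > 0).
#' @param inferred_mult Multiplier on the mean for inferred trials.
#' @param seed Integer seed.
#' @return The dataset with a `latency` column (`NA` on missing trials).
#' @export
simulate_latencies <- function(dataset, shape = 8, mean_premise = 1.2,
                               inferred_mult = 1.15, seed = 1L) {
  if (shape <= 0 || mean_premise <= 0) stop("gamma parameters must be positive")
  mult <- ifelse(dataset$trial_type == "inferred", inferred_mult, 1)
  withr::with_seed(seed, {
    lat <- stats::rgamma(nrow(dataset), shape = shape,
                         scale = mean_premise * mult / shape)
  })
  dataset$latency <- pmin(lat, 3)
  dataset$latency[dataset$missing] <- NA_real_
  dataset
}

#' Collapse a trial-level dataset to per-discrimination counts
#'
#' @param dataset Trial-level behavioural tibble.
#' @return A tibble with one row per participant x session x discrimination:
#'   correct count `k` (missing trials excluded), trials answered
#'   `n_answered`, total trials `n`, and mean latency on correct trials.
#' @export
summarise_counts <- function(dataset) {
  dataset |>
    dplyr::group_by(.data$participant, .data$method, .data$session,
                    .data$pair, .data$trial_type, .data$distance) |>
    dplyr::summarise(
      k = sum(.data$correct, na.rm = TRUE),
      n_answered = sum(!is.na(.data$correct)),
      n = dplyr::n(),
      latency = mean(.data$latency[.data$correct == 1], na.rm = TRUE),
      .groups = "drop"
    )
}
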