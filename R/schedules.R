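#' Default per-epoch trial counts for progressive training
#'
#' Progressive training runs in six epochs that introduce the premise
#' discriminations one by one: epoch 1 presents only `A>B` (17 trials);
#' epoch 2 adds `B>C` (20 of its 34 trials, ~59%); and so on down the
#' hierarchy. Once introduced, a discrimination appears in every subsequent
#' epoch with strictly decreasing counts, and every discrimination totals 60
#' trials by the end (360 trials overall). The counts for later epochs are
#' under-determined by those constraints; this default satisfies all of them
#' and can be replaced via the `counts` argument of
#' [generate_progressive_schedule()].
#'
#' @return A 6 x 6 integer matrix, rows = premise pairs `A>B` ... `F>G`,
#'   columns = epochs 1-6; `NA` before a pair is introduced.
#' @export
progressive_counts <- function() {
  m <- rbind(
    c(17, 14, 11,  8,  6,  4),
    c(NA, 20, 14, 11,  8,  7),
    c(NA, NA, 20, 16, 13, 11),
    c(NA, NA, NA, 22, 20, 18),
    c(NA, NA, NA, NA, 31, 29),
    c(NA, NA, NA, NA, NA, 60)
  )
  labs <- texture_labels()
  dimnames(m) <- list(paste0(labs[1:6], ">", labs[2:7]), paste0("epoch", 1:6))
  storage.mode(m) <- "integer"
  m
}

validate_progressive_counts <- function(counts) {
  if (!is.matrix(counts) || !all(dim(counts) == c(6, 6))) {
    stop("`counts` must be a 6 x 6 matrix (pairs x epochs)")
  }
  for (j in 1:6) {
    row <- counts[j, ]
    if (any(!is.na(row[seq_len(j - 1)]))) {
      stop("discrimination ", j, " must not appear before epoch ", j)
    }
    active <- row[j:6]
    if (any(is.na(active)) || any(active <= 0)) {
      stop("discrimination ", j, " must appear in epoch ", j,
           " and every later epoch")
    }
    if (length(active) > 1 && any(diff(active) >= 0)) {
      stop("per-epoch counts for discrimination ", j,
           " must strictly decrease after introduction")
    }
    if (sum(active) != 60) {
      stop("discrimination ", j, " must total 60 trials, got ", sum(active))
    }
  }
  invisible(counts)
}

# Balanced left/right placement: exactly half of each pair's trials show the
# higher-valued texture on the left, in a seeded random arrangement.
balanced_sides <- function(n_per_pair) {
  stopifnot(n_per_pair %% 2 == 0)
  sample(rep(c(TRUE, FALSE), n_per_pair / 2))
}

schedule_tibble <- function(pairs, epoch, high_on_left, condition) {
  hier <- build_hierarchy("recent")
  idx <- match(pairs, hier$pair)
  tibble::tibble(
    trial = seq_along(pairs),
    epoch = epoch,
    pair = pairs,
    high = hier$high[idx],
    low = hier$low[idx],
    high_on_left = high_on_left,
    left_stimulus = ifelse(high_on_left, hier$high[idx], hier$low[idx]),
    right_stimulus = ifelse(high_on_left, hier$low[idx], hier$high[idx]),
    condition = condition
  )
}

#' Generate an interleaved training schedule
#'
#' All six premise discriminations are presented in a pseudorandom order with
#' a uniform marginal probability (1/6) of encountering any one of them on a
#' given trial, realised as a seeded shuffle of the exactly balanced multiset
#' (60 copies of each pair, 360 trials). The higher-valued texture appears on
#' the left in exactly 30 of each pair's 60 trials.
#'
#' @param seed Integer seed; schedules are reproducible given the seed.
#'
#' @return A tibble with 360 rows and columns `trial`, `epoch` (all `NA` for
#'   interleaved training), `pair`, `high`, `low`, `high_on_left`,
#'   `left_stimulus`, `right_stimulus`, `condition`.
#'
#' @examples
#' sched <- generate_interleaved_schedule(seed = 1)
#' table(sched$pair)
#' @export
generate_interleaved_schedule <- function(seed = 1L) {
  labs <- texture_labels()
  pairs <- paste0(labs[1:6], ">", labs[2:7])
  withr::with_seed(seed, {
    order <- sample(rep(pairs, each = 60))
    sides <- logical(360)
    for (p in pairs) sides[order == p] <- balanced_sides(60)
  })
  schedule_tibble(order, NA_integer_, sides, "interleaved")
}

#' Generate a progressive training schedule
#'
#' Six epochs of different lengths gradually introduce the premise
#' discriminations one by one, from the top of the hierarchy down (see
#' [progressive_counts()]). Trial order is shuffled within each epoch;
#' left/right placement is balanced 30/30 per pair over the whole schedule.
#'
#' @param seed Integer seed.
#' @param counts Per-epoch count matrix as returned by
#'   [progressive_counts()]; validated against the introduction, monotonicity
#'   and per-pair total constraints before use.
#'
#' @return A tibble as in [generate_interleaved_schedule()], with `epoch`
#'   filled in.
#' @export
generate_progressive_schedule <- function(seed = 1L, counts = progressive_counts()) {
  validate_progressive_counts(counts)
  pairs <- rownames(counts)
  withr::with_seed(seed, {
    order <- character(0)
    epoch <- integer(0)
    for (e in 1:6) {
      block <- rep(pairs, times = ifelse(is.na(counts[, e]), 0L, counts[, e]))
      block <- sample(block)
      order <- c(order, block)
      epoch <- c(epoch, rep(e, length(block)))
    }
    sides <- logical(length(order))
    for (p in pairs) sides[order == p] <- balanced_sides(60)
  })
  schedule_tibble(order, epoch, sides, "progressive")
}

#' Count chained runs of overlapping discriminations
#'
#' A "chain" is a maximal run of consecutive trials in which each successive
#' discrimination shares a wall texture with the previous one (e.g. `B>C`
#' followed by `C>D`). In directional mode the successor must additionally
#' sit exactly one step lower in the hierarchy (shared texture = previous
#' pair's low texture and the next pair descends from it), so `C>D` followed
#' by `B>C` breaks a directional chain but continues a non-directional one.
#'
#' @param schedule A schedule tibble with a `pair` column.
#' @param directional If `TRUE`, count descending chains only.
#'
#' @return A tibble with columns `length` (run length, >= 2) and `n` (number
#'   of maximal runs of that length); zero rows when no chains occur.
#'
#' @examples
#' sched <- generate_interleaved_schedule(seed = 1)
#' count_chains(sched)
#' @export
count_chains <- function(schedule, directional = FALSE) {
  stopifnot(nrow(schedule) > 0)
  labs <- texture_labels()
  hi <- match(schedule$high, labs)
  lo <- match(schedule$low, labs)
  n <- nrow(schedule)
  if (n == 1) return(tibble::tibble(length = integer(0), n = integer(0)))
  linked <- if (directional) {
    hi[-1] == lo[-n]
  } else {
    hi[-1] == hi[-n] | hi[-1] == lo[-n] | lo[-1] == hi[-n] | lo[-1] == lo[-n]
  }
  # identical consecutive pairs are repetitions, not chains
  linked <- linked & !(hi[-1] == hi[-n] & lo[-1] == lo[-n])
  runs <- rle(linked)
  lens <- runs$lengths[runs$values] + 1L
  if (length(lens) == 0) return(tibble::tibble(length = integer(0), n = integer(0)))
  tab <- table(lens)
  tibble::tibble(length = as.integer(names(tab)), n = as.integer(tab))
}

#' Generate the in-scanner trial list
#'
#' The in-scanner task tests each of the 24 discriminations (6 premise + 6
#' inferred, from each of the two sessions) 8 times, giving 192 trials, plus
#' 16 null events used to estimate a resting baseline. Each trial shows the
#' two buildings for a 3-second response window followed by 3.5 s of
#' fixation; null events last 6.5 s; onsets accumulate accordingly. Per
#' discrimination, the higher-valued texture is on the left in exactly 4 of
#' its 8 trials. Order is a seeded pseudorandom shuffle.
#'
#' @param seed Integer seed.
#'
#' @return A tibble with 208 rows: `trial`, `session`, `pair`, `trial_type`
#'   (`"premise"`, `"inferred"` or `"null"`), `distance`, `high`, `low`,
#'   `high_on_left`, `onset` (seconds), `duration` (stimulus duration:
#'   3 s for discrimination trials, 6.5 s for nulls).
#'
#' @examples
#' scan <- generate_scan_trials(seed = 1)
#' sum(scan$trial_type != "null")
#' @export
generate_scan_trials <- function(seed = 1L) {
  hiers <- dplyr::bind_rows(build_hierarchy("recent"), build_hierarchy("remote"))
  trials <- hiers[rep(seq_len(nrow(hiers)), each = 8), ]
  nulls <- tibble::tibble(
    session = NA_character_, pair = NA_character_, high = NA_character_,
    low = NA_character_, trial_type = "null", distance = NA_integer_
  )[rep(1, 16), ]
  withr::with_seed(seed, {
    sides <- logical(nrow(trials))
    for (p in unique(paste(trials$session, trials$pair))) {
      sides[paste(trials$session, trials$pair) == p] <- balanced_sides(8)
    }
    trials$high_on_left <- sides
    nulls$high_on_left <- NA
    all_trials <- dplyr::bind_rows(trials, nulls)
    all_trials <- all_trials[sample(nrow(all_trials)), ]
  })
  all_trials |>
    dplyr::mutate(
      duration = ifelse(.data$trial_type == "null", 6.5, 3),
      # every event occupies 6.5 s: 3 s response window + 3.5 s fixation,
      # or a 6.5 s null
      onset = (dplyr::row_number() - 1) * 6.5,
      trial = dplyr::row_number()
    ) |>
    dplyr::relocate("trial", "session", "pair", "trial_type", "distance",
                    "high", "low", "high_on_left", "onset", "duration")
}

#' Validate a training schedule against its design constraints
#'
#' Checks trial count (360), per-pair counts (60 each), left/right balance
#' (30/30 per pair) and, for progressive schedules, the epoch introduction
#' and monotonicity constraints.
#'
#' @param schedule A schedule tibble.
#' @return `TRUE` invisibly, or an error describing the violated constraint.
#' @export
validate_schedule <- function(schedule) {
  if (nrow(schedule) != 360) stop("schedule must have 360 trials")
  counts <- table(schedule$pair)
  if (length(counts) != 6 || any(counts != 60)) {
    stop("each premise pair must occur exactly 60 times")
  }
  lr <- tapply(schedule$high_on_left, schedule$pair, sum)
  if (any(lr != 30)) stop("left/right placement must be balanced 30/30 per pair")
  if (schedule$condition[1] == "progressive") {
    m <- with(schedule, table(pair, epoch))
    m <- ifelse(m == 0, NA_integer_, m)
    validate_progressive_counts(m[rownames(progressive_counts()), , drop = FALSE])
  }
  invisible(TRUE)
}
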