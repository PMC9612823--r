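#' Texture labels of a seven-item transitive hierarchy
#'
#' Each training session teaches six pairwise "premise" discriminations over
#' seven wall textures, labelled `A` (highest reward value) through `G`
#' (lowest). The pairs jointly imply the one-dimensional hierarchy
#' `A > B > C > D > E > F > G`.
#'
#' @keywords internal
#' @noRd
texture_labels <- function() LETTERS[1:7]

#' Valid session labels
#' @noRd
session_levels <- function() c("recent", "remote")

#' Build the discrimination set of one hierarchy
#'
#' Returns the six premise discriminations (adjacent pairs, transitive
#' distance 1) and the six inferred discriminations (distances 2-4) for one
#' training session. Inferred discriminations never contain the terminal
#' textures `A` or `G`, because those can be solved by a simple featural
#' policy ("always pick A" / "always avoid G") without generalisation.
#'
#' @param session `"recent"` or `"remote"`.
#'
#' @return A tibble with one row per discrimination and columns
#'   `session`, `high` (the rewarded, higher-ranked texture), `low`,
#'   `pair` (e.g. `"B>E"`), `trial_type` (`"premise"` or `"inferred"`) and
#'   `distance` (hierarchy separation, 1-4).
#'
#' @examples
#' build_hierarchy("recent")
#' @export
build_hierarchy <- function(session = c("recent", "remote")) {
  session <- match.arg(session)
  labs <- texture_labels()
  premise <- tibble::tibble(
    high = labs[1:6],
    low  = labs[2:7],
    trial_type = "premise",
    distance = 1L
  )
  inner <- labs[2:6] # B..F: inferred pairs avoid the hierarchy ends
  inferred <- tidyr::expand_grid(high = inner, low = inner) |>
    dplyr::filter(match(.data$low, labs) - match(.data$high, labs) >= 2) |>
    dplyr::mutate(
      trial_type = "inferred",
      distance = match(.data$low, labs) - match(.data$high, labs)
    )
  dplyr::bind_rows(premise, inferred) |>
    dplyr::mutate(
      session = session,
      pair = paste0(.data$high, ">", .data$low),
      distance = as.integer(.data$distance),
      .before = 1
    ) |>
    dplyr::relocate("session", "pair", "high", "low", "trial_type", "distance")
}

#' Premise discriminations mediating an inferred discrimination
#'
#' An inferred pair such as `B>E` spans a chain of adjacent premise pairs
#' (`B>C`, `C>D`, `D>E`), the "mediating contingencies". The retrieval-based
#' AND model requires all of them; the encoding-based OR model requires only
#' the two end premises — the one naming the stimulus to prefer (`B>C`) and
#' the one naming the stimulus to avoid (`D>E`). At distance 2 the two sets
#' coincide.
#'
#' @param pair An inferred pair label such as `"B>E"`, or a vector of them.
#'
#' @return A named list (one element per input pair) with components
#'   `all` (character vector of all mediating premise pairs, length =
#'   transitive distance) and `ends` (the first and last premise of the
#'   chain, deduplicated).
#'
#' @examples
#' mediating_sets("B>E")
#' @export
mediating_sets <- function(pair) {
  labs <- texture_labels()
  out <- lapply(pair, function(p) {
    hl <- strsplit(p, ">", fixed = TRUE)[[1]]
    i <- match(hl[1], labs)
    j <- match(hl[2], labs)
    if (is.na(i) || is.na(j) || j - i < 2) {
      stop("`pair` must be an inferred discrimination (distance >= 2), got: ", p)
    }
    chain <- paste0(labs[i:(j - 1)], ">", labs[(i + 1):j])
    list(all = chain, ends = unique(chain[c(1, length(chain))]))
  })
  names(out) <- pair
  out
}
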