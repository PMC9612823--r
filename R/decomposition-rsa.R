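#' Build the texture-occurrence decomposition design
#'
#' The 24 discrimination-level beta patterns are linear mixtures of
#' texture-level patterns: each discrimination presents exactly two textures
#' from one session. The occurrence design `X` (24 x 15) has unit entries
#' for each discrimination's two textures (columns 1-7: recent A-G, columns
#' 8-14: remote A-G) and a final trial-type contrast column (+/-0.5,
#' inferred positive) that absorbs overall BOLD differences between premise
#' and inferred trials. Its pseudoinverse `T = (X'X)^{-1} X'` maps
#' discrimination betas to texture patterns.
#'
#' @return An object of class `occurrence_design`: list with `X` (24 x 15),
#'   `T` (15 x 24) and the row/column names.
#' @export
build_occurrence_design <- function() {
  labs <- texture_labels()
  disc <- dplyr::bind_rows(build_hierarchy("recent"), build_hierarchy("remote"))
  cols <- c(paste0("recent_", labs), paste0("remote_", labs), "trial_type")
  X <- matrix(0, nrow = 24, ncol = 15,
              dimnames = list(paste(disc$session, disc$pair), cols))
  for (i in seq_len(24)) {
    X[i, paste0(disc$session[i], "_", disc$high[i])] <- 1
    X[i, paste0(disc$session[i], "_", disc$low[i])] <- 1
    X[i, "trial_type"] <- if (disc$trial_type[i] == "inferred") 0.5 else -0.5
  }
  if (qr(X)$rank < 15) {
    stop("occurrence design is rank deficient; check the trial-type coding")
  }
  Tm <- solve(crossprod(X), t(X))
  structure(list(X = X, T = Tm), class = "occurrence_design")
}

#' @export
print.occurrence_design <- function(x, ...) {
  cat("<occurrence_design> X:", nrow(x$X), "x", ncol(x$X),
      "| rank", qr(x$X)$rank, "\n")
  invisible(x)
}

#' Decompose discrimination betas into texture patterns
#'
#' Applies the pseudoinverse transformation `T` to a 24 x V beta matrix,
#' returning the 15 x V decomposition: rows 1-14 are voxel-wise
#' representations of the individual wall textures (recent then remote),
#' row 15 is the premise-vs-inferred nuisance component, which downstream
#' similarity analyses discard.
#'
#' @param betas 24 x V matrix from [lss_estimate()] (row order: recent
#'   hierarchy then remote hierarchy).
#' @param design An [build_occurrence_design()] object.
#'
#' @return A 15 x V matrix with texture rownames plus `trial_type`.
#' @export
decompose_patterns <- function(betas, design = build_occurrence_design()) {
  if (!is.matrix(betas) || nrow(betas) != 24) {
    stop("`betas` must be a 24 x V matrix")
  }
  if (!all(is.finite(betas))) stop("`betas` must be finite")
  out <- design$T %*% betas
  rownames(out) <- colnames(design$X)
  out
}

fisher_z <- function(r, clip = 1 - 1e-12) {
  clipped <- abs(r) > clip
  if (any(clipped)) {
    warning("|r| = 1 clipped before Fisher transform")
    r <- pmin(pmax(r, -clip), clip)
  }
  atanh(r)
}

#' Pairwise Fisher-z pattern similarities
#'
#' Correlates decomposed texture patterns across voxels and
#' Fisher-transforms the coefficients. Similarities involving the terminal
#' textures `A` and `G` are excluded (those stimuli only ever appeared in
#' premise trials, so their patterns can differ for trivial reasons),
#' leaving textures B-F. Within-hierarchy scope pairs textures from the
#' same session (10 pairs per session, distances 1-4); across-hierarchy
#' scope pairs textures from different sessions (25 pairs, distances 0-4).
#'
#' @param patterns 15 x V (or 14 x V) matrix of texture patterns; the
#'   `trial_type` row, if present, is dropped.
#' @param scope `"within"` or `"across"`.
#'
#' @return A tibble with `texture_1`, `texture_2`, `session_1`,
#'   `session_2`, `scope`, `distance`, `r`, `z`; degenerate (zero-variance)
#'   patterns yield flagged `NA` rows via the `defined` column.
#' @export
pattern_similarity <- function(patterns, scope = c("within", "across")) {
  scope <- match.arg(scope)
  if (ncol(patterns) < 3) stop("need at least 3 voxels")
  keep <- rownames(patterns)[grepl("_(B|C|D|E|F)$", rownames(patterns))]
  p <- patterns[keep, , drop = FALSE]
  info <- tibble::tibble(
    name = keep,
    session = sub("_.*", "", keep),
    texture = sub(".*_", "", keep),
    pos = match(sub(".*_", "", keep), texture_labels())
  )
  pairs <- tidyr::expand_grid(i = seq_len(nrow(info)), j = seq_len(nrow(info)))
  pairs <- if (scope == "within") {
    dplyr::filter(pairs, .data$i < .data$j,
                  info$session[.data$i] == info$session[.data$j])
  } else {
    dplyr::filter(pairs, info$session[.data$i] == "recent",
                  info$session[.data$j] == "remote")
  }
  sds <- apply(p, 1, stats::sd)
  purrr::pmap(pairs, function(i, j) {
    defined <- sds[i] > 0 && sds[j] > 0
    r <- if (defined) stats::cor(p[i, ], p[j, ]) else NA_real_
    tibble::tibble(
      texture_1 = info$texture[i], texture_2 = info$texture[j],
      session_1 = info$session[i], session_2 = info$session[j],
      scope = scope,
      distance = abs(info$pos[j] - info$pos[i]),
      r = r,
      z = if (defined) fisher_z(r) else NA_real_,
      defined = defined
    )
  }) |>
    dplyr::bind_rows()
}

#' Co-presentation nuisance predictor
#'
#' Trivial similarity between co-presented textures: textures shown in the
#' same trials share noise sources. For each admissible texture pair the
#' predictor is the Fisher-transformed Pearson correlation between binary
#' vectors encoding each texture's presence across all in-scanner trials
#' (with equal repetition counts, the 24-discrimination and 192-trial
#' computations coincide).
#'
#' @param scope `"within"` or `"across"`.
#' @return A tibble with the pair identifiers and `nuisance_copres` (the
#'   Fisher z).
#' @export
copresentation_nuisance <- function(scope = c("within", "across")) {
  scope <- match.arg(scope)
  design <- build_occurrence_design()
  X <- design$X[, 1:14]
  # presence vectors over the 24 discriminations
  keep <- colnames(X)[grepl("_(B|C|D|E|F)$", colnames(X))]
  info <- tibble::tibble(
    name = keep,
    session = sub("_.*", "", keep),
    texture = sub(".*_", "", keep),
    pos = match(sub(".*_", "", keep), texture_labels())
  )
  pairs <- tidyr::expand_grid(i = seq_len(nrow(info)), j = seq_len(nrow(info)))
  pairs <- if (scope == "within") {
    dplyr::filter(pairs, .data$i < .data$j,
                  info$session[.data$i] == info$session[.data$j])
  } else {
    dplyr::filter(pairs, info$session[.data$i] == "recent",
                  info$session[.data$j] == "remote")
  }
  purrr::pmap(pairs, function(i, j) {
    r <- stats::cor(X[, info$name[i]], X[, info$name[j]])
    tibble::tibble(
      texture_1 = info$texture[i], texture_2 = info$texture[j],
      session_1 = info$session[i], session_2 = info$session[j],
      scope = scope,
      distance = abs(info$pos[j] - info$pos[i]),
      nuisance_copres = fisher_z(r)
    )
  }) |>
    dplyr::bind_rows()
}

#' Decomposition/timing nuisance predictor via simulation
#'
#' Estimates the spurious pattern correlations induced by trial timing,
#' repetition suppression and the least-squares-separate decomposition
#' itself: on each iteration, independent normal texture patterns are
#' simulated, mixed into a BOLD time series according to the trial list,
#' re-estimated with [lss_estimate()], decomposed, and correlated. The
#' predictor is the across-iteration mean Fisher z per texture pair.
#'
#' @param trial_list Scan trial list (one per "subject"; the same list is
#'   reused across iterations).
#' @param n_iter Number of iterations (a warning is raised below 50, where
#'   the mean is unstable).
#' @param v Number of simulated voxels.
#' @param noise_sd,ar_rho Noise settings passed to [simulate_scan()].
#' @param scope `"within"` or `"across"`.
#' @param seed Integer seed.
#'
#' @return A tibble with pair identifiers, `nuisance_sim` (mean Fisher z)
#'   and `se` (Monte-Carlo standard error).
#' @export
simulation_nuisance <- function(trial_list, n_iter = 100L, v = 50L,
                                noise_sd = 1, ar_rho = 0.3,
                                scope = c("within", "across"), seed = 1L) {
  scope <- match.arg(scope)
  if (n_iter < 50) warning("n_iter < 50: nuisance estimate may be unstable")
  zs <- lapply(seq_len(n_iter), function(it) {
    pat <- simulate_patterns(v = v, lambda = NULL,
                             seed = (seed * 1009L + it) %% .Machine$integer.max)
    scan <- simulate_scan(pat, trial_list, noise_sd = noise_sd,
                          ar_rho = ar_rho,
                          seed = (seed * 2003L + it) %% .Machine$integer.max)
    betas <- lss_estimate(scan)
    dec <- decompose_patterns(betas)
    pattern_similarity(dec, scope = scope)
  })
  template <- zs[[1]][, c("texture_1", "texture_2", "session_1", "session_2",
                          "scope", "distance")]
  zmat <- vapply(zs, function(d) d$z, numeric(nrow(template)))
  template |>
    dplyr::mutate(
      nuisance_sim = rowMeans(zmat),
      se = apply(zmat, 1, stats::sd) / sqrt(n_iter)
    )
}

#' Sample-size-dependent residual-outlier threshold
#'
#' The absolute standardised-residual cut-off
#' \deqn{z = \left|\Phi^{-1}\!\left(\tfrac{1}{2}\,(1 - 2^{-1/n})\right)\right|}
#' is the bound of a standard normal that contains all `n` normally
#' distributed residuals of a random sample 50% of the time, so the
#' exclusion rule adapts to the model's sample size instead of using a
#' fixed heuristic (about 2.7 at n = 100 and 3.4 at n = 1000).
#'
#' @param n Sample size (number of observations in the model), >= 1.
#' @return The threshold in standard-deviation units (vectorised over `n`).
#'
#' @examples
#' outlier_threshold(c(100, 1000))
#' @export
outlier_threshold <- function(n) {
  if (any(n < 1)) stop("`n` must be >= 1")
  abs(stats::qnorm(0.5 * (1 - 2^(-1 / n))))
}
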