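#' Probability of k correct responses given a retrieval probability
#'
#' Responses to a discrimination tested `n` times arise from a two-stage
#' process: on each trial the relevant contingency is retrieved with
#' probability `r` (yielding a correct response), and otherwise the
#' participant guesses, succeeding with probability 1/2. The probability of
#' observing `k` correct responses is the sum over the number of trials `m`
#' answered via retrieval,
#' \deqn{\Pr(k \mid n, r) = \sum_{m=0}^{k}
#'   \frac{n!}{m!\,(k-m)!\,(n-k)!}\; r^m (1-r)^{n-m} (1/2)^{n-m},}
#' which collapses to the binomial form
#' \eqn{\binom{n}{k} ((1+r)/2)^k ((1-r)/2)^{n-k}}.
#' The explicit sum is evaluated here; the closed form serves as an
#' independent check in the test suite.
#'
#' @param k Number of correct responses, `0 <= k <= n` (vectorised).
#' @param n Number of trials (default 8, the in-scanner repetition count).
#' @param r Retrieval probability in `[0, 1]` (vectorised).
#'
#' @return Probabilities, recycled over `k` and `r`.
#'
#' @examples
#' premise_prob(6, 8, 0.6)
#' @export
premise_prob <- function(k, n = 8L, r) {
  if (any(r < 0 | r > 1)) stop("`r` must lie in [0, 1]")
  if (any(k < 0 | k > n | k != round(k))) stop("`k` must be an integer in 0..n")
  len <- max(length(k), length(r))
  k <- rep_len(k, len); r <- rep_len(r, len)
  out <- numeric(len)
  for (ii in seq_len(len)) {
    m <- 0:k[ii]
    terms <- exp(
      lfactorial(n) - lfactorial(m) - lfactorial(k[ii] - m) - lfactorial(n - k[ii])
    ) * r[ii]^m * (1 - r[ii])^(n - m) * 0.5^(n - m)
    out[ii] <- sum(terms)
  }
  out
}

#' Normalised likelihood of the retrieval probability for one premise
#'
#' Given `k` correct responses out of `n` trials, the likelihood of the
#' retrieval probability `r` is \eqn{L(r \mid k, n) = \Pr(k \mid n, r) / c(k
#' \mid n)}, where the normalising constant \eqn{c(k \mid n) = \int_0^1
#' \Pr(k \mid n, r)\,dr} is computed by trapezoid quadrature on a dense grid.
#' The cumulative form of `L` supports inverse-transform sampling of
#' plausible `r` values (see [sample_r()]).
#'
#' @param k Correct count.
#' @param n Trial count (default 8).
#' @param grid_n Number of grid points on `[0, 1]` (default 2001).
#'
#' @return An object of class `premise_likelihood`: a list with `k`, `n`,
#'   `r` (grid), `pr` (unnormalised probabilities), `c` (normalising
#'   constant), `L` (normalised likelihood) and `cdf` (cumulative likelihood,
#'   0 at r = 0, 1 at r = 1).
#'
#' @examples
#' lik <- build_likelihood(k = 8, n = 8)
#' lik$c
#' @export
build_likelihood <- function(k, n = 8L, grid_n = 2001L) {
  r <- seq(0, 1, length.out = grid_n)
  pr <- premise_prob(k, n, r)
  dr <- r[2] - r[1]
  cons <- sum((pr[-1] + pr[-grid_n]) / 2) * dr
  L <- pr / cons
  cdf <- c(0, cumsum((L[-1] + L[-grid_n]) / 2) * dr)
  cdf <- cdf / cdf[grid_n] # absorb O(dr^2) quadrature residue
  structure(
    list(k = k, n = n, r = r, pr = pr, c = cons, L = L, cdf = cdf),
    class = "premise_likelihood"
  )
}

#' @export
print.premise_likelihood <- function(x, ...) {
  cat("<premise_likelihood> k =", x$k, "of n =", x$n,
      "| normalising constant c =", signif(x$c, 5), "\n")
  invisible(x)
}

#' Inverse-transform sample from a premise likelihood
#'
#' Maps uniform variates through the inverse cumulative likelihood: the
#' returned `r` satisfies `cdf(r) = u`, linearly interpolated on the grid.
#' Feeding `u ~ U(0, 1)` therefore yields draws distributed as the
#' normalised likelihood itself.
#'
#' @param likelihood A [build_likelihood()] object.
#' @param u Uniform variates in `[0, 1]` (vectorised).
#'
#' @return Sampled retrieval probabilities in `[0, 1]`.
#'
#' @examples
#' lik <- build_likelihood(8, 8)
#' sample_r(lik, 0.5)
#' @export
sample_r <- function(likelihood, u) {
  stopifnot(inherits(likelihood, "premise_likelihood"))
  if (any(u < 0 | u > 1)) stop("`u` must lie in [0, 1]")
  stats::approx(likelihood$cdf, likelihood$r, xout = u, ties = "ordered",
                rule = 2)$y
}
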