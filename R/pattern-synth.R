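#' Calibrate the exponential repetition-suppression model
#'
#' Repeated stimulus presentations evoke an attenuated BOLD response that
#' recovers exponentially with time since the last presentation:
#' attenuation(dt) = `a * exp(-dt / tau)`. The two free parameters are
#' solved exactly from the two parahippocampal adaptation anchors reported
#' by Fritsche et al. (2020): 23% attenuation after a 0.1-second delay and
#' 10% after a 1-second delay, giving `tau = 0.9 / log(2.3)` (~1.08 s) and
#' `a = 0.23 * 2.3^(1/9)` (~0.252).
#'
#' @return An object of class `adaptation_model`: list with `a`, `tau`, and
#'   a function `attenuation(dt)`.
#'
#' @examples
#' m <- calibrate_adaptation()
#' m$attenuation(0.1) # 0.23
#' m$attenuation(1.0) # 0.10
#' @export
calibrate_adaptation <- function() {
  anchors <- c(t1 = 0.1, t2 = 1.0, f1 = 0.23, f2 = 0.10)
  tau <- (anchors["t2"] - anchors["t1"]) / log(anchors["f1"] / anchors["f2"])
  a <- anchors["f1"] * exp(anchors["t1"] / tau)
  tau <- unname(tau); a <- unname(a)
  structure(
    list(a = a, tau = tau,
         attenuation = function(dt) a * exp(-dt / tau)),
    class = "adaptation_model"
  )
}

#' @export
print.adaptation_model <- function(x, ...) {
  cat("<adaptation_model> a =", signif(x$a, 5), "| tau =", signif(x$tau, 5),
      "s\n")
  invisible(x)
}

#' Apply repetition suppression to trial amplitudes
#'
#' Scales each presentation's amplitude by `1 - attenuation(dt)`, where `dt`
#' is the time since the *same texture* was last presented (suppression is
#' keyed to stimulus repetitions, not discrimination repetitions). First
#' presentations are unscaled.
#'
#' @param amplitudes Numeric vector, one amplitude per presentation.
#' @param onsets Presentation onsets in seconds (same length).
#' @param texture Texture identity per presentation (same length).
#' @param model An [calibrate_adaptation()] model.
#' @param strength Multiplier on the attenuation (1 = as calibrated; 0
#'   disables suppression; larger values stress-test the nuisance
#'   simulation).
#'
#' @return The scaled amplitude vector.
#' @export
apply_repetition_suppression <- function(amplitudes, onsets, texture,
                                         model = calibrate_adaptation(),
                                         strength = 1) {
  stopifnot(length(amplitudes) == length(onsets),
            length(onsets) == length(texture))
  ord <- order(onsets)
  scaled <- amplitudes
  last_seen <- list()
  for (i in ord) {
    tx <- as.character(texture[i])
    if (!is.null(last_seen[[tx]])) {
      dt <- onsets[i] - last_seen[[tx]]
      att <- pmin(strength * model$attenuation(dt), 1)
      scaled[i] <- amplitudes[i] * (1 - att)
    }
    last_seen[[tx]] <- onsets[i]
  }
  scaled
}

#' Canonical double-gamma haemodynamic response function
#'
#' Standard shape: response peak at 6 s, undershoot peaking at 16 s,
#' undershoot ratio 1/6, evaluated at times `t` (seconds) and scaled to a
#' peak of 1.
#'
#' @param t Time points in seconds.
#' @param peak,undershoot Gamma shape parameters (seconds to peak).
#' @param ratio Undershoot amplitude relative to the response.
#' @return The HRF evaluated at `t`.
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot, rate = 1)
  h[t < 0] <- 0
  if (max(abs(h)) > 0) h / max(h) else h
}

#' Random ground-truth texture patterns
#'
#' Draws one response-amplitude pattern per texture over `v` voxels. With
#' `lambda = NULL` (the nuisance-simulation setting) patterns are
#' independent standard normals. With a positive `lambda`, textures within
#' a session share structure so that the expected pattern correlation
#' decays as `exp(-distance / lambda)` with hierarchical distance — the
#' structural-representation ground truth used by recovery tests.
#'
#' @param v Number of voxels (>= 20 recommended).
#' @param lambda Distance-decay constant of the injected similarity
#'   structure, or `NULL` for independent patterns.
#' @param seed Integer seed.
#'
#' @return A 14 x `v` matrix with rownames `recent_A` ... `remote_G`.
#' @export
simulate_patterns <- function(v = 50L, lambda = NULL, seed = 1L) {
  labs <- texture_labels()
  nm <- c(paste0("recent_", labs), paste0("remote_", labs))
  withr::with_seed(seed, {
    if (is.null(lambda)) {
      p <- matrix(stats::rnorm(14 * v), nrow = 14)
    } else {
      # per session: Gaussian process over hierarchy positions with
      # exponential correlation exp(-|i - j| / lambda)
      d <- abs(outer(1:7, 1:7, "-"))
      S <- exp(-d / lambda)
      Lc <- chol(S)
      p <- rbind(t(Lc) %*% matrix(stats::rnorm(7 * v), nrow = 7),
                 t(Lc) %*% matrix(stats::rnorm(7 * v), nrow = 7))
    }
    rownames(p) <- nm
    p
  })
}

# presentations of individual textures implied by a scan trial list
scan_presentations <- function(trial_list) {
  trials <- dplyr::filter(trial_list, .data$trial_type != "null")
  tibble::tibble(
    trial = rep(trials$trial, each = 2),
    onset = rep(trials$onset, each = 2),
    duration = rep(trials$duration, each = 2),
    texture = as.vector(rbind(paste0(trials$session, "_", trials$high),
                              paste0(trials$session, "_", trials$low)))
  )
}

#' Simulate a voxel-level BOLD scan of the in-scanner task
#'
#' Each discrimination trial presents two wall textures; their ground-truth
#' voxel amplitudes (attenuated by repetition suppression keyed to each
#' texture's last presentation) sum, the resulting event amplitudes are
#' convolved with a canonical double-gamma HRF on a fine time grid, sampled
#' at the scanner TR, and AR(1) Gaussian noise is added.
#'
#' @param patterns 14 x V ground-truth matrix from [simulate_patterns()].
#' @param trial_list Scan trial list from [generate_scan_trials()].
#' @param tr Repetition time in seconds (default 2.52).
#' @param noise_sd Marginal SD of the AR(1) noise (0 = noiseless).
#' @param ar_rho AR(1) autocorrelation (default 0.3).
#' @param adaptation Repetition-suppression model; `NULL` disables it.
#' @param suppression_strength Multiplier on the calibrated attenuation.
#' @param seed Integer seed.
#'
#' @return An object of class `ti_scan`: list with `y` (volumes x V data
#'   matrix), `trial_list`, `tr`, `n_volumes`, `seed` and the noise
#'   settings.
#' @export
simulate_scan <- function(patterns, trial_list, tr = 2.52, noise_sd = 1,
                          ar_rho = 0.3, adaptation = calibrate_adaptation(),
                          suppression_strength = 1, seed = 1L) {
  pres <- scan_presentations(trial_list)
  if (anyDuplicated(paste(pres$texture, pres$onset))) {
    stop("overlapping identical onsets for a texture")
  }
  total <- max(trial_list$onset) + 6.5 + 30 # tail for the HRF to settle
  n_vol <- ceiling(total / tr)
  v <- ncol(patterns)

  # repetition-suppression gain per presentation (same for every voxel)
  gain <- rep(1, nrow(pres))
  if (!is.null(adaptation) && suppression_strength > 0) {
    gain <- apply_repetition_suppression(
      rep(1, nrow(pres)), pres$onset, pres$texture,
      model = adaptation, strength = suppression_strength
    )
  }

  # neural amplitude time course on a fine grid, per texture, then mixed
  dt <- 0.1
  n_fine <- ceiling(total / dt)
  tgrid <- (seq_len(n_fine) - 1) * dt
  hrf <- hrf_double_gamma(seq(0, 32, by = dt))

  # build a trial-by-texture amplitude: event boxcar of the stimulus duration
  signal <- matrix(0, nrow = n_vol, ncol = v)
  stim <- matrix(0, nrow = n_fine, ncol = nrow(patterns),
                 dimnames = list(NULL, rownames(patterns)))
  for (i in seq_len(nrow(pres))) {
    idx <- which(tgrid >= pres$onset[i] & tgrid < pres$onset[i] + pres$duration[i])
    stim[idx, pres$texture[i]] <- stim[idx, pres$texture[i]] + gain[i]
  }
  conv_tex <- apply(stim, 2, function(s) {
    stats::convolve(s, rev(hrf), type = "open")[seq_len(n_fine)] * dt
  })
  vol_idx <- pmin(pmax(round(((seq_len(n_vol) - 1) * tr) / dt) + 1, 1), n_fine)
  design_tex <- conv_tex[vol_idx, , drop = FALSE]
  signal <- design_tex %*% patterns

  if (noise_sd > 0) {
    noise <- withr::with_seed(seed, {
      innov_sd <- noise_sd * sqrt(1 - ar_rho^2)
      apply(matrix(stats::rnorm(n_vol * v, sd = innov_sd), n_vol, v), 2,
            function(e) as.numeric(stats::filter(e, ar_rho, method = "recursive")))
    })
    signal <- signal + noise
  }
  structure(
    list(y = signal, trial_list = trial_list, tr = tr, n_volumes = n_vol,
         noise_sd = noise_sd, ar_rho = ar_rho, seed = seed,
         suppression_strength = suppression_strength),
    class = "ti_scan"
  )
}

#' @export
print.ti_scan <- function(x, ...) {
  cat("<ti_scan>", x$n_volumes, "volumes x", ncol(x$y), "voxels | TR =",
      x$tr, "s | noise SD =", x$noise_sd, "\n")
  invisible(x)
}

# cosine drift set implementing a high-pass filter (cutoff in seconds)
cosine_drift <- function(n_vol, tr, cutoff = 128) {
  t <- (seq_len(n_vol) - 0.5) / n_vol
  order <- floor(2 * n_vol * tr / cutoff)
  if (order < 1) return(matrix(1, n_vol, 1, dimnames = list(NULL, "const")))
  drift <- vapply(seq_len(order), function(k) cos(pi * k * t), numeric(n_vol))
  cbind(const = 1, drift)
}

# convolved regressor for a set of trials
convolved_regressor <- function(trials, n_vol, tr, dt = 0.1) {
  total <- n_vol * tr
  n_fine <- ceiling(total / dt)
  tgrid <- (seq_len(n_fine) - 1) * dt
  s <- numeric(n_fine)
  for (i in seq_len(nrow(trials))) {
    idx <- which(tgrid >= trials$onset[i] & tgrid < trials$onset[i] + trials$duration[i])
    s[idx] <- s[idx] + 1
  }
  hrf <- hrf_double_gamma(seq(0, 32, by = dt))
  conv <- stats::convolve(s, rev(hrf), type = "open")[seq_len(n_fine)] * dt
  vol_idx <- pmin(pmax(round(((seq_len(n_vol) - 1) * tr) / dt) + 1, 1), n_fine)
  conv[vol_idx]
}

#' Least-squares-separate beta estimation
#'
#' Estimates one beta pattern per discrimination: for each of the 24
#' discriminations a separate GLM is fitted with one regressor for that
#' discrimination's trials, one for all other discrimination trials, and a
#' cosine drift set implementing a 1/128 Hz high-pass filter (plus
#' intercept). The target regressor's coefficient per voxel is that
#' discrimination's beta.
#'
#' @param scan A `ti_scan` from [simulate_scan()].
#' @param hp_cutoff High-pass cutoff in seconds (default 128).
#'
#' @return A 24 x V beta matrix with rownames `"recent A>B"` etc., ordered
#'   as the two [build_hierarchy()] tables stacked (recent then remote).
#' @export
lss_estimate <- function(scan, hp_cutoff = 128) {
  stopifnot(inherits(scan, "ti_scan"))
  trial_list <- dplyr::filter(scan$trial_list, .data$trial_type != "null")
  n_vol <- scan$n_volumes
  drift <- cosine_drift(n_vol, scan$tr, hp_cutoff)
  disc <- dplyr::bind_rows(build_hierarchy("recent"),
                           build_hierarchy("remote"))[, c("session", "pair")]
  disc_id <- paste(trial_list$session, trial_list$pair)
  betas <- matrix(NA_real_, nrow = nrow(disc), ncol = ncol(scan$y),
                  dimnames = list(paste(disc$session, disc$pair), NULL))
  # one convolved regressor per discrimination; "all others" is the
  # difference from their sum
  regs <- vapply(seq_len(nrow(disc)), function(d) {
    id <- paste(disc$session[d], disc$pair[d])
    convolved_regressor(trial_list[disc_id == id, ], n_vol, scan$tr)
  }, numeric(n_vol))
  total <- rowSums(regs)
  for (d in seq_len(nrow(disc))) {
    target <- regs[, d]
    others <- total - target
    X <- cbind(target = target, others = others, drift)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      bad <- setdiff(colnames(X), colnames(X)[qrX$pivot[seq_len(qrX$rank)]])
      stop("rank-deficient LSS design; offending regressor(s): ",
           paste(bad, collapse = ", "))
    }
    betas[d, ] <- qr.coef(qrX, scan$y)["target", ]
  }
  betas
}
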