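test_that("the occurrence design has full rank and the stated structure", {
  d <- build_occurrence_design()
  expect_equal(dim(d$X), c(24, 15))
  expect_equal(qr(d$X)$rank, 15)
  expect_equal(d$T %*% d$X, diag(15), tolerance = 1e-10,
               ignore_attr = TRUE)
  row <- d$X["recent A>B", ]
  expect_equal(unname(row[c("recent_A", "recent_B")]), c(1, 1))
  expect_equal(sum(abs(row[setdiff(names(row), c("recent_A", "recent_B",
                                                 "trial_type"))])), 0)
  # terminal textures appear only in premise rows
  disc <- rbind(build_hierarchy("recent"), build_hierarchy("remote"))
  for (col in c("recent_A", "recent_G", "remote_A", "remote_G")) {
    expect_true(all(disc$trial_type[d$X[, col] != 0] == "premise"))
  }
})

test_that("decomposition inverts the mixing exactly and matches least squares", {
  d <- build_occurrence_design()
  set.seed(71)
  P <- matrix(rnorm(15 * 12), nrow = 15)
  expect_equal(decompose_patterns(d$X %*% P), P, tolerance = 1e-10,
               ignore_attr = TRUE)
  # generic least-squares oracle per voxel on noisy betas
  betas <- d$X %*% P + matrix(rnorm(24 * 12, sd = 0.3), 24)
  dec <- decompose_patterns(betas)
  oracle <- apply(betas, 2, function(y) qr.coef(qr(d$X), y))
  expect_equal(dec, oracle, tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(decompose_patterns(matrix(0, 10, 4)), "24 x V")
  expect_error(decompose_patterns(matrix(NA_real_, 24, 4)), "finite")
})

test_that("pattern similarity keeps the admissible pairs only", {
  set.seed(72)
  pat <- matrix(rnorm(15 * 40), nrow = 15,
                dimnames = list(colnames(build_occurrence_design()$X), NULL))
  within <- pattern_similarity(pat, "within")
  expect_equal(nrow(within), 20) # choose(5, 2) pairs x 2 sessions
  expect_true(all(within$session_1 == within$session_2))
  expect_true(all(within$distance %in% 1:4))
  across <- pattern_similarity(pat, "across")
  expect_equal(nrow(across), 25) # 5 x 5, distance 0 allowed
  expect_true(any(across$distance == 0))
  expect_false(any(c(within$texture_1, within$texture_2,
                     across$texture_1, across$texture_2) %in% c("A", "G")))
  expect_equal(within$z, atanh(within$r), tolerance = 1e-12)
})

test_that("degenerate patterns are flagged, duplicates clipped", {
  pat <- matrix(rnorm(15 * 10), nrow = 15,
                dimnames = list(colnames(build_occurrence_design()$X), NULL))
  pat["recent_C", ] <- 0 # zero variance
  out <- pattern_similarity(pat, "within")
  recent_c <- out$session_1 == "recent" &
    (out$texture_1 == "C" | out$texture_2 == "C")
  expect_true(all(!out$defined[recent_c]))
  expect_true(all(out$defined[!recent_c]))
  pat2 <- pat
  pat2["recent_C", ] <- pat2["recent_B", ] # perfect duplicate
  expect_warning(out2 <- pattern_similarity(pat2, "within"), "clipped")
  z_dup <- out2$z[out2$texture_1 == "B" & out2$texture_2 == "C" &
                    out2$session_1 == "recent"]
  expect_equal(z_dup, atanh(1 - 1e-12))
  expect_error(pattern_similarity(pat[, 1:2], "within"), "3 voxels")
})

test_that("the co-presentation nuisance matches the design's phi coefficients", {
  cn <- copresentation_nuisance("within")
  bc <- cn[cn$texture_1 == "B" & cn$texture_2 == "C" & cn$session_1 == "recent", ]
  phi <- (24 * 1 - 5 * 4) / sqrt(5 * 19 * 4 * 20)
  expect_equal(bc$nuisance_copres, atanh(phi), tolerance = 1e-12)
  ca <- copresentation_nuisance("across")
  bc_x <- ca[ca$texture_1 == "B" & ca$texture_2 == "C", ]
  expect_equal(bc_x$nuisance_copres, atanh(-20 / sqrt(5 * 19 * 4 * 20)),
               tolerance = 1e-12)
  # no self-pairs in either scope
  expect_false(any(cn$texture_1 == cn$texture_2 & cn$session_1 == cn$session_2))
})

test_that("the outlier threshold follows the probit rule", {
  expect_equal(round(outlier_threshold(100), 1), 2.7)
  expect_equal(round(outlier_threshold(1000), 1), 3.4)
  expect_equal(outlier_threshold(1), abs(qnorm(0.25)), tolerance = 1e-12)
  n <- c(1, 5, 10, 50, 100, 500, 1000, 5000)
  expect_true(all(diff(outlier_threshold(n)) > 0))
  expect_error(outlier_threshold(0), ">= 1")
})

test_that("the RSA table joins covariates and omits accuracy-by-slope terms", {
  cohort <- small_cohort(n = 6, seed = 73)
  counts <- summarise_counts(resample_missing(cohort, seed = 73))
  sims <- dplyr::bind_rows(lapply(1:6, function(p) {
    dplyr::mutate(
      pattern_similarity(structured_patterns(seed = 700 + p), "within"),
      participant = p,
      method = ifelse(p %% 2 == 1, "interleaved", "progressive"),
      .before = 1
    )
  }))
  tab <- build_rsa_table(sims, counts)
  expect_equal(nrow(tab), 6 * 20) # participants x (10 pairs x 2 sessions)
  expect_equal(mean(tab$distance_c), 0, tolerance = 1e-12)
  expect_true(all(c("nuisance_copres", "nuisance_sim", "accuracy_c",
                    "slope_c") %in% names(tab)))
  form <- attr(terms(fit_rsa_lmm(tab, predictors = "full",
                                 exclude_outliers = FALSE)$formula), "term.labels")
  expect_false(any(grepl("accuracy_c", form) & grepl("slope_c", form)))
})

test_that("across-hierarchy tables carry 25 pairs per participant", {
  cohort <- small_cohort(n = 4, seed = 74)
  counts <- summarise_counts(resample_missing(cohort, seed = 74))
  sims <- dplyr::bind_rows(lapply(1:4, function(p) {
    dplyr::mutate(
      pattern_similarity(structured_patterns(seed = 740 + p), "across"),
      participant = p, method = "interleaved", .before = 1
    )
  }))
  tab <- build_rsa_table(sims, counts)
  expect_equal(nrow(tab), 4 * 25)
  expect_true(all(tab$ss == 0))
})

test_that("the RSA mixed model recovers an injected distance effect", {
  cohort <- small_cohort(n = 10, seed = 75)
  counts <- summarise_counts(resample_missing(cohort, seed = 75))
  sims <- dplyr::bind_rows(lapply(1:10, function(p) {
    dplyr::mutate(
      pattern_similarity(structured_patterns(v = 50, lambda = 2,
                                             seed = 750 + p), "within"),
      participant = p,
      method = ifelse(p %% 2 == 1, "interleaved", "progressive"),
      .before = 1
    )
  }))
  tab <- build_rsa_table(sims, counts)
  fit <- fit_rsa_lmm(tab, predictors = "full")
  est <- fit$coef$estimate[fit$coef$term == "distance_c"]
  expect_lt(est, 0)
  # outlier pass stays within the expected envelope on typical data
  expect_lte(fit$prop_excluded, 0.01)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$n, nrow(fit$table))
})

test_that("excluding distance-1 pairs drops 8 rows per participant", {
  cohort <- small_cohort(n = 6, seed = 76)
  counts <- summarise_counts(resample_missing(cohort, seed = 76))
  sims <- dplyr::bind_rows(lapply(1:6, function(p) {
    dplyr::mutate(
      pattern_similarity(structured_patterns(seed = 760 + p), "within"),
      participant = p,
      method = ifelse(p %% 2 == 1, "interleaved", "progressive"),
      .before = 1
    )
  }))
  tab <- build_rsa_table(sims, counts)
  d1 <- delta1_sensitivity(tab, predictors = "distance",
                           exclude_outliers = FALSE)
  expect_equal(nrow(d1$table), nrow(tab) - 6 * 8)
  expect_true(all(d1$table$distance >= 2))
})

test_that("delta-1-only similarity boosts vanish in the sensitivity refit", {
  cohort <- small_cohort(n = 8, seed = 77)
  counts <- summarise_counts(resample_missing(cohort, seed = 77))
  # patterns with elevated similarity only for adjacent (distance-1) pairs
  sims <- dplyr::bind_rows(lapply(1:8, function(p) {
    set.seed(770 + p)
    v <- 60
    base <- matrix(rnorm(14 * v), nrow = 14,
                   dimnames = list(rownames(simulate_patterns(v = 2)), NULL))
    shared <- matrix(rnorm(12 * v), nrow = 12) # one latent per adjacent pair
    for (s in 0:1) for (i in 1:6) {
      latent <- shared[s * 6 + i, ]
      base[s * 7 + i, ] <- base[s * 7 + i, ] + latent
      base[s * 7 + i + 1, ] <- base[s * 7 + i + 1, ] + latent
    }
    dplyr::mutate(
      pattern_similarity(base, "within"),
      participant = p,
      method = ifelse(p %% 2 == 1, "interleaved", "progressive"),
      .before = 1
    )
  }))
  tab <- build_rsa_table(sims, counts)
  full <- fit_rsa_lmm(tab, predictors = "distance", exclude_outliers = FALSE)
  est_full <- full$coef$estimate[full$coef$term == "distance_c"]
  expect_lt(est_full, 0) # adjacency boost masquerades as a distance effect
  red <- delta1_sensitivity(tab, predictors = "distance",
                            exclude_outliers = FALSE)
  t_red <- red$coef$statistic[red$coef$term == "distance_c"]
  expect_lt(abs(t_red), 2.5) # effect gone once distance-1 pairs are removed
})
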