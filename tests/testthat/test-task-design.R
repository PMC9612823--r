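test_that("hierarchy contains the six premise and six inferred pairs", {
  for (sess in c("recent", "remote")) {
    h <- build_hierarchy(sess)
    prem <- h[h$trial_type == "premise", ]
    infr <- h[h$trial_type == "inferred", ]
    expect_equal(prem$pair, premise_pairs())
    expect_true(all(prem$distance == 1))
    expect_setequal(infr$pair, inferred_pairs())
    # distance histogram: three distance-2, two distance-3, one distance-4
    expect_equal(as.vector(table(infr$distance)), c(3, 2, 1))
    # terminal textures never appear in inferred pairs
    expect_false(any(c(infr$high, infr$low) %in% c("A", "G")))
    expect_true(all(match(h$high, LETTERS) < match(h$low, LETTERS)))
  }
})

test_that("interleaved schedules are balanced and seed-reproducible", {
  s1 <- generate_interleaved_schedule(seed = 1)
  expect_equal(nrow(s1), 360)
  expect_true(all(table(s1$pair) == 60))
  expect_true(all(tapply(s1$high_on_left, s1$pair, sum) == 30))
  expect_silent(validate_schedule(s1))
  expect_identical(s1, generate_interleaved_schedule(seed = 1))
  s2 <- generate_interleaved_schedule(seed = 2)
  expect_false(identical(s1$pair, s2$pair))
  expect_equal(table(s1$pair), table(s2$pair))
})

test_that("any pair is equally likely at a fixed schedule position", {
  n_seeds <- 1000
  first <- vapply(seq_len(n_seeds),
                  function(s) generate_interleaved_schedule(seed = s)$pair[1],
                  character(1))
  p_hat <- mean(first == "C>D")
  se <- sqrt((1 / 6) * (5 / 6) / n_seeds)
  expect_lt(abs(p_hat - 1 / 6), 3 * se)
})

test_that("progressive schedules honour the epoch structure", {
  p <- generate_progressive_schedule(seed = 1)
  expect_silent(validate_schedule(p))
  e1 <- p[p$epoch == 1, ]
  expect_equal(nrow(e1), 17)
  expect_true(all(e1$pair == "A>B"))
  e2 <- p[p$epoch == 2, ]
  expect_equal(mean(e2$pair == "B>C"), 20 / 34, tolerance = 1e-12)
  # introduced in the final epoch, F>G must supply all 60 trials there
  expect_equal(sum(p$pair == "F>G" & p$epoch == 6), 60)
  # per-epoch counts strictly decrease after introduction
  m <- table(p$pair, p$epoch)
  for (j in 1:5) {
    active <- m[premise_pairs()[j], j:6]
    expect_true(all(diff(active) < 0))
  }
})

test_that("invalid progressive count matrices are rejected", {
  bad <- progressive_counts()
  bad[1, 1] <- 16L # breaks the row total
  expect_error(generate_progressive_schedule(seed = 1, counts = bad), "total 60")
  bad2 <- progressive_counts()
  bad2[1, 2] <- 17L # not strictly decreasing
  bad2[1, 3] <- 8L
  expect_error(generate_progressive_schedule(seed = 1, counts = bad2),
               "strictly decrease")
})

test_that("chain counting matches the definition on worked cases", {
  mk <- function(pairs) {
    hl <- strsplit(pairs, ">")
    tibble::tibble(pair = pairs,
                   high = vapply(hl, `[`, "", 1),
                   low = vapply(hl, `[`, "", 2))
  }
  # A>B, B>C, C>D chain of three; the final A>B restarts
  expect_equal(count_chains(mk(c("A>B", "B>C", "C>D", "A>B"))),
               tibble::tibble(length = 3L, n = 1L))
  expect_equal(nrow(count_chains(mk(c("A>B", "D>E")))), 0)
  # C>D then B>C shares C but ascends: non-directional chain only
  expect_equal(nrow(count_chains(mk(c("C>D", "B>C")), directional = TRUE)), 0)
  expect_equal(count_chains(mk(c("C>D", "B>C")), directional = FALSE),
               tibble::tibble(length = 2L, n = 1L))
  # repeated identical pair is not a chain
  expect_equal(nrow(count_chains(mk(c("A>B", "A>B")))), 0)
})

test_that("chain runs never cover more trials than the schedule holds", {
  for (seed in 1:5) {
    s <- generate_interleaved_schedule(seed)
    ch <- count_chains(s)
    expect_lte(sum(ch$length * ch$n), nrow(s))
    expect_identical(ch, count_chains(s))
  }
})

test_that("the in-scanner trial list has the printed structure", {
  scan <- generate_scan_trials(seed = 1)
  expect_equal(sum(scan$trial_type != "null"), 192)
  nulls <- scan[scan$trial_type == "null", ]
  expect_equal(nrow(nulls), 16)
  expect_true(all(nulls$duration == 6.5))
  disc <- scan[scan$trial_type != "null", ]
  expect_true(all(table(disc$session, disc$pair) == 8))
  left <- tapply(disc$high_on_left, paste(disc$session, disc$pair), sum)
  expect_true(all(left == 4))
  # onsets accumulate in 6.5 s steps (3 s response + 3.5 s fixation / null)
  expect_equal(diff(scan$onset), rep(6.5, 207))
})
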