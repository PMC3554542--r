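test_that("covariate models validate their probability vectors", {
  spec <- worked_spec()
  m <- covariate_model(spec)
  expect_equal(unname(m$center), rep(1 / 3, 3))
  m2 <- covariate_model(spec, probs = list(gender = c(0.8, 0.2)))
  expect_equal(unname(m2$gender), c(0.8, 0.2))
  expect_error(covariate_model(spec, probs = list(age = c(0.5, 0.5))),
               "undeclared")
  expect_error(covariate_model(spec, probs = list(gender = c(0.5, 0.4))),
               "sum to one")
  expect_error(covariate_model(spec, probs = list(gender = c(1.2, -0.2))),
               "non-negative")
})

test_that("profile generation honours the covariate model", {
  spec <- worked_spec()
  degenerate <- covariate_model(spec, probs = list(
    gender = c(0, 1), center = c(0, 0, 1)))
  profs <- generate_profiles(spec, 50, degenerate)
  expect_true(all(profs$gender == "F" & profs$center == "Z"))

  set.seed(5)
  big <- generate_profiles(spec, 30000)
  freq <- table(big$center)
  se <- sqrt(30000 * (1 / 3) * (2 / 3))
  expect_true(all(abs(freq - 10000) < 3 * se))

  set.seed(9); a <- generate_profiles(spec, 100)
  set.seed(9); b <- generate_profiles(spec, 100)
  expect_identical(a, b)
})

test_that("max_run_length finds the longest constant block", {
  expect_identical(max_run_length(c("A", "A", "B", "B", "A")), 2L)
  expect_identical(max_run_length(c("A", "B", "A", "B")), 1L)
  expect_identical(max_run_length(c("A", "A", "A", "B", "A", "A")), 3L)
  expect_identical(max_run_length(1L), 1L)
  expect_error(max_run_length(integer(0)), "non-empty")
  # brute-force cross-check on random sequences
  set.seed(3)
  for (rep in 1:20) {
    x <- sample(1:2, 30, replace = TRUE)
    brute <- max(vapply(seq_along(x), function(s) {
      e <- s
      while (e < length(x) && x[e + 1L] == x[s]) e <- e + 1L
      e - s + 1L
    }, integer(1)))
    expect_identical(max_run_length(x), brute)
  }
})

test_that("all-zero weights reduce the simulator to simple randomization", {
  spec <- scenario_spec(4)
  sims <- simulate_trials(spec, 50, 1000, seed = 404)
  # every boundary is exactly 1/2
  expect_true(all(sims$p_first == 0.5))
  # pooled final-split histogram matches Binomial(50, 1/2) within 3 SE
  counts_a <- sims$overall[1, ]
  bins <- list(lo = 0:19, mid20 = 20:23, center = 24:26,
               mid27 = 27:30, hi = 31:50)
  for (b in bins) {
    p <- sum(stats::dbinom(b, 50, 0.5))
    expect_within_3se(sum(counts_a %in% b), 1000 * p, 1000)
  }
})

test_that("weight 10 without stratification gives an exact split almost always", {
  # in the quasi-deterministic block-of-two regime every consecutive
  # pair is balanced, so an even-sized 1:1 trial ends exactly even
  hard <- trial_spec(c("A", "B"), c(1, 1), list(),
                     weights = list(overall = 10))
  sims <- simulate_trials(hard, 50, 200, seed = 8)
  expect_gte(mean(sims$overall[1, ] == 25), 0.99)
})

test_that("summaries satisfy their conservation invariants", {
  spec <- scenario_spec(2)
  sims <- simulate_trials(spec, 50, 200, seed = 12)
  s <- summarize_trials(sims, checkpoint = 12)
  expect_identical(sum(s$final_split$trials), 200L)
  expect_identical(sum(s$checkpoint_split$trials), 200L)
  expect_identical(sum(s$max_runs$trials), 200L)
  expect_identical(sum(s$boundary_hist$count), 200L * 50L)
  expect_identical(sum(s$level_diffs$center$count), 3L * 200L)
  expect_identical(sum(s$level_diffs$gender$count), 2L * 200L)
  # checkpoint splits sum to the checkpoint
  expect_true(all(rowSums(s$checkpoint_split[, c("A", "B")]) == 12L))
  expect_error(summarize_trials(sims, checkpoint = 51), "exceed")
})

test_that("expected absolute imbalance decreases from no control to strong control", {
  mean_abs_diff <- numeric(4)
  for (sc in 1:4) {
    sims <- simulate_trials(scenario_spec(sc), 50, 1000, seed = 900 + sc)
    mean_abs_diff[sc] <- mean(abs(sims$overall[1, ] - sims$overall[2, ]))
  }
  # scenario 4 (simple) -> 3 (weak) -> 2 (medium) -> 1 (strong)
  expect_gt(mean_abs_diff[4], mean_abs_diff[3])
  expect_gt(mean_abs_diff[3], mean_abs_diff[2])
  expect_gt(mean_abs_diff[2], mean_abs_diff[1])
})

test_that("strong control buys balance at the price of predictability", {
  s1 <- simulate_trials(scenario_spec(1), 50, 300, seed = 21)
  s3 <- simulate_trials(scenario_spec(3), 50, 300, seed = 22)
  extreme <- function(s) mean(s$p_first <= 0.10 | s$p_first >= 0.90)
  expect_gt(extreme(s1), 0.5)   # well over half the boundaries are extreme
  expect_lt(extreme(s3), 0.05)  # almost none under weak control
  expect_gt(extreme(s1), extreme(s3))
})

test_that("replicates are reproducible from the master seed and in isolation", {
  spec <- scenario_spec(2)
  a <- simulate_trials(spec, 20, 50, seed = 77)
  b <- simulate_trials(spec, 20, 50, seed = 77)
  expect_identical(a$assignments, b$assignments)
  expect_identical(a$p_first, b$p_first)
  # replicate r alone is recoverable from its substream seed
  set.seed(77)
  sub <- sample.int(.Machine$integer.max, 50)
  solo <- simulate_trial(spec, 20, seed = sub[7])
  expect_identical(solo$assignments, a$assignments[, 7])
})

test_that("a fixed profile stream is honoured across replicates", {
  spec <- trial_spec(c("A", "B"), c(1, 1),
                     list(gender = c("M", "F")),
                     weights = list(overall = 0.1,
                                    variables = c(gender = 0.2),
                                    stratum = 0.5))
  stream <- data.frame(gender = c("M", "F", "M", "F", "M", "M"))
  sims <- simulate_trials(spec, 6, 10, seed = 14, profiles = stream)
  expect_identical(dim(sims$assignments), c(6L, 10L))
  solo <- simulate_trial(spec, 6, profiles = stream, seed = 1)
  expect_identical(solo$n, 6L)
  expect_error(simulate_trial(spec, 5, profiles = stream), "exactly n rows")
})
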