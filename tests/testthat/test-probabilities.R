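test_that("the logistic step maps imbalance to the worked probabilities", {
  expect_equal(probability_from_imbalance(2, 0), 2 / 3, tolerance = 1e-12)
  expect_equal(round(probability_from_imbalance(2, -1.1), 2), 0.40)
  expect_equal(round(probability_from_imbalance(2, -0.11), 2), 0.64)
  expect_identical(probability_from_imbalance(1, 0), 0.5)
  expect_equal(probability_from_imbalance(2, -11),
               2 * exp(-11) / (1 + 2 * exp(-11)), tolerance = 1e-12)
  expect_equal(signif(probability_from_imbalance(2, -11), 3), 3.34e-5)
})

test_that("the logistic step is strictly increasing and saturates cleanly", {
  a <- seq(-5, 5, by = 0.25)
  p <- vapply(a, function(x) probability_from_imbalance(2, x), numeric(1))
  expect_true(all(diff(p) > 0))
  expect_identical(probability_from_imbalance(2, -1e6), 0)
  expect_identical(probability_from_imbalance(2, 1e6), 1)
  expect_error(probability_from_imbalance(2, Inf), "finite")
  expect_error(probability_from_imbalance(0, 0), "positive")
})

test_that("two-group boundaries reproduce the worked example and the first draw", {
  gp <- group_probabilities(worked_profile, worked_state(), worked_spec())
  expect_equal(round(unname(gp$probabilities), 2), c(0.40, 0.60))
  expect_equal(sum(gp$probabilities), 1, tolerance = 1e-12)

  first <- group_probabilities(c(gender = "F", center = "Y"),
                               empty_state(worked_spec()), worked_spec())
  expect_equal(unname(first$probabilities), c(2 / 3, 1 / 3),
               tolerance = 1e-12)
})

test_that("probabilities normalize and match the base method over random states", {
  # random two-group states with unequal ratio: p_B must equal 1 - p_A,
  # and p_A must equal the independent four-step oracle
  spec <- worked_spec()
  set.seed(101)
  for (rep in 1:20) {
    sim <- simulate_trial(spec, sample(5:40, 1))
    state <- sim$state
    prof <- c(gender = sample(c("M", "F"), 1),
              center = sample(c("X", "Y", "Z"), 1))
    gp <- group_probabilities(prof, state, spec)
    expect_equal(sum(gp$probabilities), 1, tolerance = 1e-12)
    idx <- profile_indices(spec, prof)
    counts <- list(
      overall = unname(state$overall),
      vars = list(unname(state$variables$gender[idx[[1]], ]),
                  unname(state$variables$center[idx[[2]], ])),
      stratum = unname(state$strata[adaptrand:::stratum_index(spec, idx), ]))
    p_oracle <- oracle_p_first(counts, 2, 0.1, c(0.2, 0.2), 0.5)
    expect_equal(unname(gp$probabilities[[1]]), p_oracle, tolerance = 1e-12)
    expect_equal(unname(gp$probabilities[[2]]), 1 - p_oracle,
                 tolerance = 1e-12)
  }
})

test_that("multi-group probabilities normalize and honour the ratio at balance", {
  spec <- swad_spec()
  gp0 <- group_probabilities(
    c(center = "Oxford", cohort = "cohort1", suicidality = "none",
      ad_use = "no"), empty_state(spec), spec)
  expect_equal(unname(gp0$probabilities), c(0.4, 0.4, 0.2), tolerance = 1e-12)
  set.seed(7)
  for (rep in 1:10) {
    sim <- simulate_trial(spec, 30)
    prof <- generate_profiles(spec, 1)
    gp <- group_probabilities(unlist(prof[1, ]), sim$state, spec)
    expect_equal(sum(gp$probabilities), 1, tolerance = 1e-12)
    expect_true(all(gp$probabilities >= 0 & gp$probabilities <= 1))
    expect_true(all(diff(gp$cumulative) >= 0))
    expect_equal(gp$cumulative[[3]], 1, tolerance = 1e-12)
  }
})

test_that("with all weights zero every probability is the exact ratio proportion", {
  spec2 <- trial_spec(c("A", "B"), c(2, 1),
                      list(gender = c("M", "F")),
                      weights = list(overall = 0,
                                     variables = c(gender = 0), stratum = 0))
  spec3 <- trial_spec(c("A", "B", "C"), c(2, 2, 1),
                      list(gender = c("M", "F")),
                      weights = list(overall = 0,
                                     variables = c(gender = 0), stratum = 0))
  set.seed(11)
  for (spec in list(spec2, spec3)) {
    sim <- simulate_trial(spec, 40)
    gp <- group_probabilities(c(gender = "F"), sim$state, spec)
    expect_identical(unname(gp$probabilities),
                     spec$ratio / sum(spec$ratio))
  }
})

test_that("weight 10 on an unstratified 1:1 trial behaves like blocks of two", {
  spec <- trial_spec(c("A", "B"), c(1, 1), list(),
                     weights = list(overall = 10))
  st <- empty_state(spec)
  one_up <- adaptrand:::increment_state(st, spec, integer(0), 1L)
  gp <- group_probabilities(character(0), one_up, spec)
  expect_lt(gp$probabilities[[1]], 1e-4)

  sim <- simulate_trial(spec, 1000, seed = 5)
  pairs <- matrix(sim$assignments, nrow = 2)
  expect_true(all(colSums(pairs) == 3L))  # every pair holds one A and one B
})

test_that("allocating to a group never raises that group's next probability", {
  spec <- worked_spec()
  set.seed(23)
  for (rep in 1:20) {
    sim <- simulate_trial(spec, sample(1:30, 1))
    prof <- c(gender = sample(c("M", "F"), 1),
              center = sample(c("X", "Y", "Z"), 1))
    p_before <- group_probabilities(prof, sim$state, spec)$probabilities[[1]]
    idx <- profile_indices(spec, prof)
    bumped <- adaptrand:::increment_state(sim$state, spec, idx, 1L)
    p_after <- group_probabilities(prof, bumped, spec)$probabilities[[1]]
    expect_lte(p_after, p_before + 1e-12)
  }
})

test_that("draws are located by half-open lower-inclusive intervals", {
  expect_identical(draw_assignment(c(2 / 3, 1 / 3), 0.30), 1L)
  expect_identical(draw_assignment(c(2 / 3, 1 / 3), 0.90), 2L)
  expect_identical(draw_assignment(c(2 / 3, 1 / 3), 2 / 3), 2L)
  expect_identical(draw_assignment(c(2 / 3, 1 / 3), 0), 1L)
  expect_identical(draw_assignment(c(0.4, 0.4, 0.2), 0.79), 2L)
  expect_identical(draw_assignment(c(0.4, 0.4, 0.2), 0.80), 3L)
  expect_error(draw_assignment(c(0.5, 0.5), 1), "0, 1")
  expect_error(draw_assignment(c(0.5, 0.5), -0.1), "0, 1")
  expect_error(draw_assignment(c(0.5, 0.4), 0.2), "sum to one")
})

test_that("allocate_participant composes the steps without mutating its input", {
  spec <- worked_spec()
  st0 <- empty_state(spec)
  res <- allocate_participant(c(gender = "F", center = "Y"), st0, spec,
                              id = "P1", u = 0.5)
  expect_identical(res$record$group, "A")       # 0.5 < 2/3
  expect_identical(unname(res$state$overall), c(1L, 0L))
  expect_identical(unname(st0$overall), c(0L, 0L))  # input untouched
  expect_identical(st0$n, 0L)

  res13 <- allocate_participant(worked_profile, worked_state(), spec,
                                id = "P13", u = 0.55)
  expect_identical(res13$record$group, "B")     # 0.55 >= 0.40 boundary

  expect_error(
    allocate_participant(c(gender = "M", center = "X"), res$state, spec,
                         id = "P1", u = 0.1),
    "already been randomized")
})

test_that("a fixed seed reproduces an identical allocation sequence", {
  spec <- worked_spec()
  run <- function() {
    st <- empty_state(spec)
    profs <- generate_profiles(spec, 15)
    for (i in 1:15)
      st <- allocate_participant(unlist(profs[i, ]), st, spec,
                                 id = as.character(i))$state
    st
  }
  set.seed(99); a <- run()
  set.seed(99); b <- run()
  expect_identical(a$overall, b$overall)
  expect_identical(a$history[, setdiff(names(a$history), "timestamp")],
                   b$history[, setdiff(names(b$history), "timestamp")])
})
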