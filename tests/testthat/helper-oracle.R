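# Independent oracle for the two-group boundary calculation, written
# directly from the four-step definition and kept free of any package
# internals: counts are passed explicitly and the probability is the
# shifted logistic of the weighted signed squared imbalance sum.
#
# counts: list(overall = c(nA, nB),
#              vars    = list of c(nA, nB) at the participant's level,
#              stratum = c(nA, nB))
oracle_p_first <- function(counts, odds, w_overall, w_vars, w_stratum) {
  term <- function(w, nab) {
    q <- odds * nab[[2L]] - nab[[1L]]
    w * sign(q) * q * q / odds
  }
  a <- term(w_overall, counts$overall)
  for (v in seq_along(counts$vars)) a <- a + term(w_vars[[v]], counts$vars[[v]])
  a <- a + term(w_stratum, counts$stratum)
  z <- odds * exp(a)
  z / (1 + z)
}

# Exact final-split distribution for a two-group trial with one
# stratification variable and a fixed profile stream, by recursive
# enumeration of all 2^n allocation sequences, multiplying the step
# probabilities along each branch.  Returns P(final count in group 1 = j)
# for j = 0..n.
oracle_split_distribution <- function(levels_idx, odds,
                                      w_overall, w_var, w_stratum) {
  n <- length(levels_idx)
  n_lev <- max(levels_idx)
  dist <- numeric(n + 1L)
  recurse <- function(i, overall, lev_counts, prob) {
    if (i > n) {
      dist[overall[[1L]] + 1L] <<- dist[overall[[1L]] + 1L] + prob
      return(invisible())
    }
    li <- levels_idx[[i]]
    # with a single variable the stratum coincides with the level, but
    # both terms enter the sum with their own weights
    p <- oracle_p_first(
      list(overall = overall, vars = list(lev_counts[li, ]),
           stratum = lev_counts[li, ]),
      odds, w_overall, w_var, w_stratum)
    for (g in 1:2) {
      ov <- overall; ov[[g]] <- ov[[g]] + 1L
      lc <- lev_counts; lc[li, g] <- lc[li, g] + 1L
      recurse(i + 1L, ov, lc, prob * if (g == 1L) p else 1 - p)
    }
  }
  recurse(1L, c(0L, 0L), matrix(0L, n_lev, 2L), 1)
  dist
}

# shared fixtures -------------------------------------------------------

worked_spec <- function(scale = 1) example_spec_2to1(scale)

worked_state <- function(scale = 1)
  state_from_counts(worked_spec(scale), example_counts_12())

worked_profile <- c(gender = "F", center = "Z")

# |observed - expected| within 3 binomial standard errors, where the
# expected count arises from `total` draws at proportion expected/total
expect_within_3se <- function(observed, expected, total) {
  se <- sqrt(total * (expected / total) * (1 - expected / total))
  expect_lt(abs(observed - expected), 3 * se + 1e-9)
}
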