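#' Allocation odds from a pair of ratio entries
#'
#' The first step of the boundary calculation: for a target allocation
#' ratio A:B, the allocation odds are the plain quotient A/B.  A 2:1
#' ratio in favour of A gives odds 2; a 1:1 ratio gives odds 1.
#'
#' @param ratio_a,ratio_b Positive ratio entries for the two (pooled)
#'   sides of the comparison.
#' @return The odds `ratio_a / ratio_b` in full floating precision.
#' @export
allocation_odds <- function(ratio_a, ratio_b) {
  if (!is.numeric(ratio_a) || !is.numeric(ratio_b) ||
      length(ratio_a) != 1L || length(ratio_b) != 1L ||
      is.na(ratio_a) || is.na(ratio_b) || ratio_a <= 0 || ratio_b <= 0)
    stop("allocation-ratio entries must be single positive numbers",
         call. = FALSE)
  ratio_a / ratio_b
}

#' Signed allocation difference at one level
#'
#' The second step: at any level of the trial (overall, one level of one
#' stratification variable, or one stratum) with `n_a` participants in
#' group A and `n_b` in group B, the difference is
#' \deqn{d = (odds \times n_B - n_A) / odds.}
#' It is positive when A holds fewer allocations than the target ratio
#' warrants (A underrepresented) and zero at perfect ratio balance.
#'
#' @param n_a,n_b Non-negative allocation counts at this level.
#' @param odds Allocation odds from [allocation_odds()].
#' @return The signed difference `d`.
#' @export
level_difference <- function(n_a, n_b, odds) {
  check_counts(n_a, n_b, odds)
  (odds * n_b - n_a) / odds
}

#' Weighted signed squared imbalance term at one level
#'
#' The third step applies, level by level, the transformation
#' \deqn{w \times sign(odds \cdot n_B - n_A) \times
#'       (odds \cdot n_B - n_A)^2 / odds}
#' which equals \eqn{w \cdot sign(d) \cdot odds \cdot d^2} in terms of the
#' step-2 difference \eqn{d}.  The sum of these terms over all relevant
#' levels is the total imbalance fed to the logit.  Setting
#' `squaring = "difference"` instead squares the step-2 difference
#' directly (\eqn{w \cdot sign(d) \cdot d^2}); the two variants coincide
#' at odds 1 and the default is the variant whose arithmetic the
#' boundary probabilities of this engine are calibrated against (see the
#' methods vignette).
#'
#' @inheritParams level_difference
#' @param weight Non-negative weight attached to this level.
#' @param squaring `"odds_scaled"` (default) or `"difference"`.
#' @return The signed weighted term; zero iff `odds * n_b == n_a`.
#' @export
imbalance_term <- function(weight, n_a, n_b, odds,
                           squaring = c("odds_scaled", "difference")) {
  squaring <- match.arg(squaring)
  if (!is.numeric(weight) || length(weight) != 1L || is.na(weight) ||
      weight < 0)
    stop("'weight' must be a single non-negative number", call. = FALSE)
  check_counts(n_a, n_b, odds)
  q <- odds * n_b - n_a
  if (squaring == "odds_scaled") weight * sign(q) * q * q / odds
  else weight * sign(q) * (q / odds)^2
}

check_counts <- function(n_a, n_b, odds) {
  if (!is.numeric(n_a) || !is.numeric(n_b) || any(is.na(c(n_a, n_b))) ||
      any(c(n_a, n_b) < 0))
    stop("allocation counts must be non-negative numbers", call. = FALSE)
  if (!is.numeric(odds) || length(odds) != 1L || is.na(odds) || odds <= 0)
    stop("'odds' must be a single positive number", call. = FALSE)
  invisible(TRUE)
}

#' Total weighted imbalance for an arriving participant
#'
#' Accumulates the step-3 terms over every level relevant to the
#' arriving participant's profile: one overall term, one term per
#' stratification variable (at the participant's level of that
#' variable), and one term for the participant's stratum.  The total is
#' the quantity fed to the logit in [probability_from_imbalance()].
#'
#' For trials with more than two groups the comparison is one group
#' versus the rest: `group_pair` names the focal group A and the
#' remaining groups are pooled as B with odds
#' `ratio[A] / (sum(ratio) - ratio[A])`.
#'
#' @param profile Named character vector/list giving the participant's
#'   level of every stratification variable.
#' @param state An [empty_state()]-shaped `allocation_state`.
#' @param spec A [trial_spec()].
#' @param group_pair Integer vector of length 2: index of the focal group
#'   A and, for a two-group trial, the index of B.  For `k > 2` the
#'   second entry is ignored and all non-focal groups are pooled.
#' @param squaring Passed to [imbalance_term()].
#' @return An object of class `imbalance_breakdown`: a data frame with
#'   one row per level (`level`, `at`, `n_a`, `n_b`, `difference`,
#'   `term`) and attribute `total`, retrieved by [imbalance_total()]; the
#'   total equals the column sum of `term`.
#' @export
total_imbalance <- function(profile, state, spec, group_pair = c(1L, 2L),
                            squaring = c("odds_scaled", "difference")) {
  squaring <- match.arg(squaring)
  stopifnot(inherits(spec, "trial_spec"), inherits(state, "allocation_state"))
  ga <- group_pair[[1L]]
  idx <- profile_indices(spec, profile)
  k <- n_groups(spec)
  if (k == 2L) {
    gb <- group_pair[[2L]]
    odds <- allocation_odds(spec$ratio[[ga]], spec$ratio[[gb]])
    count_pair <- function(cnt) c(cnt[[ga]], cnt[[gb]])
  } else {
    odds <- allocation_odds(spec$ratio[[ga]], sum(spec$ratio) - spec$ratio[[ga]])
    count_pair <- function(cnt) c(cnt[[ga]], sum(cnt) - cnt[[ga]])
  }
  w <- spec$weights
  lv <- names(spec$variables)

  level <- c("overall", lv, if (length(lv)) "stratum")
  at <- c("", vapply(seq_along(lv), function(v)
    spec$variables[[v]][[idx[[v]]]], character(1L)),
    if (length(lv)) paste(vapply(seq_along(lv), function(v)
      spec$variables[[v]][[idx[[v]]]], character(1L)), collapse = "/"))
  wts <- c(w$overall, unname(w$variables), if (length(lv)) w$stratum)

  pairs <- matrix(0, nrow = length(level), ncol = 2L)
  pairs[1L, ] <- count_pair(state$overall)
  for (v in seq_along(lv))
    pairs[1L + v, ] <- count_pair(state$variables[[v]][idx[[v]], ])
  if (length(lv))
    pairs[length(level), ] <-
      count_pair(state$strata[stratum_index(spec, idx), ])

  diffs <- (odds * pairs[, 2L] - pairs[, 1L]) / odds
  terms <- vapply(seq_along(level), function(i)
    imbalance_term(wts[[i]], pairs[i, 1L], pairs[i, 2L], odds, squaring),
    numeric(1L))

  out <- data.frame(level = level, at = at, n_a = pairs[, 1L],
                    n_b = pairs[, 2L], weight = wts, difference = diffs,
                    term = terms, stringsAsFactors = FALSE)
  attr(out, "total") <- sum(terms)
  attr(out, "odds") <- odds
  class(out) <- c("imbalance_breakdown", class(out))
  out
}

#' Total of an imbalance breakdown
#' @param breakdown An `imbalance_breakdown` from [total_imbalance()].
#' @return The summed imbalance (the logit argument).
#' @export
imbalance_total <- function(breakdown) attr(breakdown, "total")
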