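#' Allocation probability from a total imbalance
#'
#' The fourth step maps the total weighted imbalance `a` through a
#' shifted logistic,
#' \deqn{p = \frac{odds \times e^{a}}{1 + odds \times e^{a}},}
#' giving the probability of assigning the arriving participant to the
#' focal group A.  At `a = 0` (perfect balance) this is
#' `odds / (1 + odds)`, i.e. the ratio proportion; it increases strictly
#' with `a`, so an underrepresented A (positive imbalance) is favoured.
#'
#' The exponent is clamped at +/- 700 before exponentiation so that
#' extreme imbalances saturate cleanly at probabilities 1 and 0 instead
#' of overflowing.
#'
#' @param odds Allocation odds (see [allocation_odds()]).
#' @param a Finite total imbalance from [total_imbalance()].
#' @return A probability in `[0, 1]`.
#' @examples
#' probability_from_imbalance(2, 0)     # 2/3 at perfect balance
#' probability_from_imbalance(2, -1.1)  # ~0.40, boundary shifted towards B
#' @export
probability_from_imbalance <- function(odds, a) {
  if (!is.numeric(odds) || length(odds) != 1L || is.na(odds) || odds <= 0)
    stop("'odds' must be a single positive number", call. = FALSE)
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a))
    stop("'a' must be a single finite number", call. = FALSE)
  if (a <= -700) return(0)
  if (a >= 700) return(1)
  z <- odds * exp(a)
  z / (1 + z)
}

#' Per-group allocation probabilities and cumulative boundaries
#'
#' Computes the probability of assigning the arriving participant to
#' each treatment group given the current allocation state, and the
#' cumulative boundaries that partition the unit interval in declared
#' group order for use with a uniform draw.
#'
#' For two groups this is exactly the four-step base calculation: odds
#' `ratio[1]/ratio[2]`, step-2 differences and step-3 weighted terms at
#' the overall, variable and stratum levels, step-4 logistic, and
#' probabilities `(p, 1 - p)`.  For `k > 2` groups each group's
#' probability is computed one-vs-rest -- group g against the pool of
#' all other groups with odds `ratio[g] / (sum(ratio) - ratio[g])` --
#' and the k one-vs-rest probabilities are renormalized to sum to one.
#' At `k = 2` the one-vs-rest construction is identical to the base
#' method (the two probabilities already sum to one), and at zero
#' imbalance every group receives exactly its ratio proportion.
#'
#' @inheritParams total_imbalance
#' @return An object of class `prob_boundaries`: list with
#'   `probabilities` (named numeric, one per group, summing to 1),
#'   `cumulative` (partition points of `[0, 1]`, ending at 1) and
#'   `breakdown` (list of `imbalance_breakdown`s, one per focal group).
#' @examples
#' spec <- trial_spec(c("A", "B"), c(2, 1),
#'   list(gender = c("M", "F"), center = c("X", "Y", "Z")),
#'   weights = list(overall = 0.1, variables = c(gender = 0.2, center = 0.2),
#'                  stratum = 0.5))
#' group_probabilities(c(gender = "F", center = "Y"), empty_state(spec), spec)
#' @export
group_probabilities <- function(profile, state, spec,
                                squaring = c("odds_scaled", "difference")) {
  squaring <- match.arg(squaring)
  k <- n_groups(spec)
  R <- sum(spec$ratio)
  if (k == 2L) {
    br <- total_imbalance(profile, state, spec, c(1L, 2L), squaring)
    a <- imbalance_total(br)
    # at exactly zero imbalance the logistic equals the ratio proportion
    # mathematically; return it directly so the balanced case is exact
    probs <- if (a == 0) spec$ratio / R
             else { p1 <- probability_from_imbalance(attr(br, "odds"), a)
                    c(p1, 1 - p1) }
    breakdown <- list(br)
  } else {
    breakdown <- lapply(seq_len(k), function(g)
      total_imbalance(profile, state, spec, c(g, 0L), squaring))
    totals <- vapply(breakdown, imbalance_total, numeric(1L))
    if (all(totals == 0)) {
      # the one-vs-rest probabilities are exactly ratio/R at balance and
      # already sum to one; skip the renormalization round-off
      probs <- spec$ratio / R
    } else {
      raw <- vapply(seq_len(k), function(g)
        probability_from_imbalance(attr(breakdown[[g]], "odds"),
                                   totals[[g]]), numeric(1L))
      if (sum(raw) == 0) raw <- spec$ratio / R
      probs <- raw / sum(raw)
    }
  }
  names(probs) <- spec$groups
  structure(list(probabilities = probs,
                 cumulative = cumsum(probs),
                 breakdown = breakdown),
            class = "prob_boundaries")
}

#' @export
print.prob_boundaries <- function(x, ...) {
  cat("Allocation probabilities:\n")
  print(round(x$probabilities, 4))
  cat("cumulative boundaries:",
      paste(format(x$cumulative, digits = 4), collapse = " | "), "\n")
  invisible(x)
}

#' Locate a uniform draw between the cumulative boundaries
#'
#' Assigns the group whose half-open interval
#' `[cumulative[g-1], cumulative[g])` contains the uniform draw; the
#' lower boundary is inclusive, so a draw below the first boundary
#' assigns the first declared group.
#'
#' @param boundaries A `prob_boundaries` from [group_probabilities()],
#'   or a bare numeric vector of probabilities summing to one.
#' @param u A uniform draw in `[0, 1)`.
#' @return The assigned group index (1-based).
#' @export
draw_assignment <- function(boundaries, u) {
  if (!is.numeric(u) || length(u) != 1L || is.na(u) || u < 0 || u >= 1)
    stop("'u' must be a single number in [0, 1)", call. = FALSE)
  cum <- if (inherits(boundaries, "prob_boundaries")) boundaries$cumulative
         else cumsum(boundaries)
  if (abs(cum[[length(cum)]] - 1) > 1e-9)
    stop("probabilities must sum to one", call. = FALSE)
  cum[[length(cum)]] <- 1  # guard the top interval against rounding
  which(u < cum)[[1L]]
}

#' Allocate one participant and update the state
#'
#' Composes [group_probabilities()] and [draw_assignment()]: recomputes
#' the boundaries for the arriving participant, locates the uniform draw,
#' and returns the allocation record together with a new state in which
#' the overall, variable-level and stratum counts of the assigned group
#' are incremented and the record is appended to the history.  The input
#' state is never modified, so callers keep a valid snapshot of the
#' pre-allocation state.
#'
#' @inheritParams group_probabilities
#' @param id Participant identifier recorded in the history; must not
#'   repeat an identifier already in the history.
#' @param u Optional uniform draw in `[0, 1)`; drawn from the session
#'   random-number generator when omitted (set a seed for reproducible
#'   allocation sequences).
#' @return List with `record` (one-row data frame: sequence number, id,
#'   profile, per-group probabilities, draw, assigned group, UTC
#'   timestamp) and `state` (the updated `allocation_state`).
#' @export
allocate_participant <- function(profile, state, spec,
                                 id = as.character(state$n + 1L), u = NULL,
                                 squaring = c("odds_scaled", "difference")) {
  squaring <- match.arg(squaring)
  if (id %in% state$history$id)
    stop("participant '", id, "' has already been randomized", call. = FALSE)
  if (is.null(u)) u <- stats::runif(1L)
  bounds <- group_probabilities(profile, state, spec, squaring)
  g <- draw_assignment(bounds, u)
  idx <- profile_indices(spec, profile)

  record <- data.frame(seq = state$n + 1L, id = id,
                       stringsAsFactors = FALSE, check.names = FALSE)
  for (v in names(spec$variables))
    record[[v]] <- spec$variables[[v]][[idx[[v]]]]
  for (gi in seq_along(spec$groups))
    record[[paste0("p_", spec$groups[[gi]])]] <-
      unname(bounds$probabilities[[gi]])
  record$u <- u
  record$group <- spec$groups[[g]]
  record$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

  new_state <- increment_state(state, spec, idx, g)
  new_state$history <- rbind(new_state$history, record)
  list(record = record, state = new_state)
}
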