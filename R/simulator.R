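#' Covariate model for synthetic participants
#'
#' Describes the joint distribution of the stratification profiles of
#' synthetic participants: one probability vector per declared variable,
#' sampled independently across variables.  The default is uniform over
#' each variable's levels.
#'
#' @param spec A [trial_spec()].
#' @param probs Optional named list overriding the level probabilities of
#'   some or all variables; each vector must be non-negative, match the
#'   variable's number of levels and sum to one (within 1e-12).
#' @return An object of class `covariate_model` (named list of
#'   probability vectors in declaration order).
#' @export
covariate_model <- function(spec, probs = NULL) {
  stopifnot(inherits(spec, "trial_spec"))
  model <- lapply(spec$variables, function(lv)
    stats::setNames(rep(1 / length(lv), length(lv)), lv))
  if (!is.null(probs)) {
    extra <- setdiff(names(probs), names(spec$variables))
    if (length(extra))
      stop("probabilities given for undeclared variable(s): ",
           paste(extra, collapse = ", "), call. = FALSE)
    for (v in names(probs)) {
      p <- probs[[v]]
      if (length(p) != length(spec$variables[[v]]))
        stop("probability vector for '", v, "' must have one entry per level",
             call. = FALSE)
      if (any(p < 0) || abs(sum(p) - 1) > 1e-12)
        stop("probabilities for '", v,
             "' must be non-negative and sum to one", call. = FALSE)
      model[[v]] <- stats::setNames(as.numeric(p), spec$variables[[v]])
    }
  }
  structure(model, class = "covariate_model")
}

#' Generate synthetic participant profiles
#'
#' Samples `n` profiles from a [covariate_model()], independently across
#' participants and across variables.  Sampling uses the session RNG, so
#' a fixed seed reproduces the identical profile stream.
#'
#' @param spec A [trial_spec()].
#' @param n Number of profiles.
#' @param model A [covariate_model()]; uniform by default.
#' @return Data frame with one character column per stratification
#'   variable and `n` rows; each row is a valid participant profile.
#' @export
generate_profiles <- function(spec, n, model = covariate_model(spec)) {
  idx <- generate_profile_indices(spec, n, model)
  out <- as.data.frame(lapply(seq_along(spec$variables), function(v)
    spec$variables[[v]][idx[, v]]), stringsAsFactors = FALSE,
    col.names = names(spec$variables))
  names(out) <- names(spec$variables)
  out
}

generate_profile_indices <- function(spec, n, model) {
  V <- length(spec$variables)
  idx <- matrix(1L, nrow = n, ncol = V)
  for (v in seq_len(V))
    idx[, v] <- sample.int(length(spec$variables[[v]]), n, replace = TRUE,
                           prob = model[[v]])
  idx
}

# sequential allocation engine on primitive arrays; prof_idx is an
# n-by-V integer matrix of level indices, u a vector of n uniforms.
# Returns assignments, the per-step probability vector of every group,
# and the final count matrices.
run_allocation <- function(spec, prof_idx, u, squaring = "odds_scaled") {
  n <- length(u)
  k <- n_groups(spec)
  V <- length(spec$variables)
  nlev <- lengths(spec$variables)
  ratio <- spec$ratio
  R <- sum(ratio)
  w0 <- spec$weights$overall
  wv <- unname(spec$weights$variables)
  ws <- spec$weights$stratum
  stride <- if (V) rev(cumprod(rev(c(nlev[-1L], 1L)))) else integer(0)

  overall <- numeric(k)
  varc <- lapply(nlev, function(L) matrix(0, L, k))
  n_strata <- if (V) prod(nlev) else 1L
  strat <- matrix(0, n_strata, k)

  assign <- integer(n)
  pmat <- matrix(0, n, k)

  if (k == 2L) {
    odds <- ratio[[1L]] / ratio[[2L]]
    denom <- if (squaring == "odds_scaled") odds else odds * odds
    for (i in seq_len(n)) {
      q <- odds * overall[[2L]] - overall[[1L]]
      a <- w0 * sign(q) * q * q / denom
      si <- 1L
      for (v in seq_len(V)) {
        li <- prof_idx[[i, v]]
        q <- odds * varc[[v]][[li, 2L]] - varc[[v]][[li, 1L]]
        a <- a + wv[[v]] * sign(q) * q * q / denom
        si <- si + (li - 1L) * stride[[v]]
      }
      if (V) {
        q <- odds * strat[[si, 2L]] - strat[[si, 1L]]
        a <- a + ws * sign(q) * q * q / denom
      }
      p1 <- if (a == 0) ratio[[1L]] / R
            else if (a <= -700) 0
            else if (a >= 700) 1
            else { z <- odds * exp(a); z / (1 + z) }
      g <- if (u[[i]] < p1) 1L else 2L
      pmat[[i, 1L]] <- p1
      pmat[[i, 2L]] <- 1 - p1
      assign[[i]] <- g
      overall[[g]] <- overall[[g]] + 1
      for (v in seq_len(V)) {
        li <- prof_idx[[i, v]]
        varc[[v]][[li, g]] <- varc[[v]][[li, g]] + 1
      }
      if (V) strat[[si, g]] <- strat[[si, g]] + 1
    }
  } else {
    odds_g <- ratio / (R - ratio)
    denom_g <- if (squaring == "odds_scaled") odds_g else odds_g * odds_g
    for (i in seq_len(n)) {
      si <- 1L
      if (V) for (v in seq_len(V))
        si <- si + (prof_idx[[i, v]] - 1L) * stride[[v]]
      tot <- sum(overall)
      avec <- numeric(k)
      raw <- numeric(k)
      for (g in seq_len(k)) {
        na <- overall[[g]]
        q <- odds_g[[g]] * (tot - na) - na
        a <- w0 * sign(q) * q * q / denom_g[[g]]
        for (v in seq_len(V)) {
          li <- prof_idx[[i, v]]
          na <- varc[[v]][[li, g]]
          nb <- sum(varc[[v]][li, ]) - na
          q <- odds_g[[g]] * nb - na
          a <- a + wv[[v]] * sign(q) * q * q / denom_g[[g]]
        }
        if (V) {
          na <- strat[[si, g]]
          nb <- sum(strat[si, ]) - na
          q <- odds_g[[g]] * nb - na
          a <- a + ws * sign(q) * q * q / denom_g[[g]]
        }
        avec[[g]] <- a
        raw[[g]] <- if (a <= -700) 0 else if (a >= 700) 1
                    else { z <- odds_g[[g]] * exp(a); z / (1 + z) }
      }
      if (all(avec == 0)) {
        p <- ratio / R    # exact ratio proportions at perfect balance
      } else {
        if (sum(raw) == 0) raw <- ratio / R
        p <- raw / sum(raw)
      }
      cum <- cumsum(p)
      cum[[k]] <- 1
      g <- which(u[[i]] < cum)[[1L]]
      pmat[i, ] <- p
      assign[[i]] <- g
      overall[[g]] <- overall[[g]] + 1
      for (v in seq_len(V)) {
        li <- prof_idx[[i, v]]
        varc[[v]][[li, g]] <- varc[[v]][[li, g]] + 1
      }
      if (V) strat[[si, g]] <- strat[[si, g]] + 1
    }
  }
  list(assignments = assign, pmat = pmat, overall = overall,
       varc = varc, strat = strat)
}

#' Simulate one sequential trial
#'
#' Allocates `n` synthetic participants sequentially through the
#' adaptive engine: for each arrival the probability boundaries are
#' recomputed from the current counts, a uniform draw decides the group,
#' and the counts are updated.  Profiles are sampled from the covariate
#' model unless an explicit profile stream is supplied.
#'
#' @inheritParams generate_profiles
#' @param n Number of participants (>= 1).
#' @param seed Optional integer seed for a reproducible trial.
#' @param profiles Optional data frame of `n` pre-specified profiles
#'   (one character column per variable), bypassing the covariate model.
#' @param squaring Passed through to the imbalance calculation; see
#'   [imbalance_term()].
#' @return An object of class `trial_sim`: list with `assignments`
#'   (integer group indices, length `n`), `groups` (the assigned group
#'   labels), `boundaries` (`n`-by-`k` matrix of the per-step allocation
#'   probabilities), `state` (the final `allocation_state`, counts only)
#'   and `spec`.
#' @export
simulate_trial <- function(spec, n, model = covariate_model(spec),
                           seed = NULL, profiles = NULL,
                           squaring = c("odds_scaled", "difference")) {
  squaring <- match.arg(squaring)
  stopifnot(inherits(spec, "trial_spec"))
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("'n' must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(profiles)) {
    prof_idx <- generate_profile_indices(spec, n, model)
  } else {
    if (nrow(profiles) != n)
      stop("'profiles' must supply exactly n rows", call. = FALSE)
    prof_idx <- profile_matrix(spec, profiles)
  }
  u <- stats::runif(n)
  res <- run_allocation(spec, prof_idx, u, squaring)
  state <- counts_to_state(spec, res)
  colnames(res$pmat) <- spec$groups
  structure(list(assignments = res$assignments,
                 groups = spec$groups[res$assignments],
                 boundaries = res$pmat,
                 u = u, profile_indices = prof_idx,
                 state = state, spec = spec, n = n),
            class = "trial_sim")
}

profile_matrix <- function(spec, profiles) {
  V <- length(spec$variables)
  idx <- matrix(1L, nrow(profiles), V)
  for (v in seq_len(V)) {
    vn <- names(spec$variables)[[v]]
    if (!vn %in% names(profiles))
      stop("'profiles' is missing variable '", vn, "'", call. = FALSE)
    m <- match(profiles[[vn]], spec$variables[[v]])
    if (anyNA(m))
      stop("undeclared level in profile stream for variable '", vn, "'",
           call. = FALSE)
    idx[, v] <- m
  }
  idx
}

counts_to_state <- function(spec, res) {
  state <- empty_state(spec)
  state$overall[] <- as.integer(res$overall)
  for (v in seq_along(spec$variables))
    state$variables[[v]][] <- as.integer(res$varc[[v]])
  state$strata[] <- as.integer(res$strat)
  state$n <- as.integer(sum(res$overall))
  state
}

#' Simulate replicated trials
#'
#' Runs `replicates` independent trials of `n` sequential allocations
#' each, seeding every replicate from its own substream spawned from the
#' master seed, so any single replicate can be reproduced in isolation.
#' The per-replicate results are kept in compact array form for
#' [summarize_trials()].
#'
#' @inheritParams simulate_trial
#' @param replicates Number of replicated trials.
#' @param seed Master seed for the replicate substreams.
#' @param profiles Optional data frame of `n` pre-specified profiles
#'   used identically in every replicate (the covariate model is then
#'   ignored and only the uniform draws vary across replicates).
#' @return An object of class `trial_sims`: list with `assignments`
#'   (`n`-by-`replicates` integer matrix), `p_first`
#'   (`n`-by-`replicates` matrix of the first group's allocation
#'   probability at every step), `overall` (`k`-by-`replicates` final
#'   count matrix), `var_diffs` (per variable, a levels-by-replicates
#'   matrix of final first-minus-second group count differences),
#'   `spec`, `n`, `replicates`, `seed`.
#' @export
simulate_trials <- function(spec, n, replicates,
                            model = covariate_model(spec), seed = NULL,
                            profiles = NULL,
                            squaring = c("odds_scaled", "difference")) {
  squaring <- match.arg(squaring)
  stopifnot(inherits(spec, "trial_spec"))
  k <- n_groups(spec)
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, replicates)
  fixed_idx <- if (!is.null(profiles)) profile_matrix(spec, profiles)
  assignments <- matrix(0L, n, replicates)
  p_first <- matrix(0, n, replicates)
  overall <- matrix(0L, k, replicates)
  var_diffs <- lapply(spec$variables, function(lv)
    matrix(0L, length(lv), replicates, dimnames = list(lv, NULL)))
  for (r in seq_len(replicates)) {
    set.seed(sub_seeds[[r]])
    prof_idx <- if (is.null(fixed_idx))
      generate_profile_indices(spec, n, model) else fixed_idx
    u <- stats::runif(n)
    res <- run_allocation(spec, prof_idx, u, squaring)
    assignments[, r] <- res$assignments
    p_first[, r] <- res$pmat[, 1L]
    overall[, r] <- as.integer(res$overall)
    for (v in seq_along(spec$variables))
      var_diffs[[v]][, r] <-
        as.integer(res$varc[[v]][, 1L] - res$varc[[v]][, 2L])
  }
  structure(list(assignments = assignments, p_first = p_first,
                 overall = overall, var_diffs = var_diffs,
                 spec = spec, n = n, replicates = replicates, seed = seed),
            class = "trial_sims")
}

#' Longest run of same-group allocations
#'
#' @param x Assignment sequence (group indices or labels).
#' @return Length of the longest constant block.
#' @examples
#' max_run_length(c("A", "A", "B", "B", "A"))  # 2
#' @export
max_run_length <- function(x) {
  if (length(x) == 0L)
    stop("assignment sequence must be non-empty", call. = FALSE)
  max(rle(as.vector(x))$lengths)
}

#' Boundary histogram intervals
#'
#' The canonical binning of computed allocation probabilities:
#' `[0, 0.05]`, then `(0.05, 0.15], (0.15, 0.25], ..., (0.85, 0.95]`,
#' and `(0.95, 1]` -- eleven intervals, closed on the right, with the
#' first also closed on the left.
#'
#' @return Numeric vector of break points of length 12.
#' @export
boundary_breaks <- function() c(0, seq(0.05, 0.95, by = 0.10), 1)

#' Summarize replicated trial simulations
#'
#' Computes the distributional diagnostics of a batch of replicated
#' trials: the histogram of final overall splits, the histogram of
#' end-of-trial within-level count differences for every stratification
#' variable, the histogram of each replicate's longest same-group run,
#' the histogram of every computed first-group allocation probability
#' over the [boundary_breaks()] intervals, and (optionally) the split
#' histogram at an interim checkpoint.
#'
#' @param sims A `trial_sims` object from [simulate_trials()].
#' @param checkpoint Optional number of allocations after which the
#'   interim split is recorded; must not exceed the trial size.
#' @return An object of class `sim_summary`: list of data frames
#'   `final_split` (columns: one count per group, `trials`),
#'   `level_diffs` (per variable: `difference`, `count`),
#'   `max_runs` (`max_run`, `trials`), `boundary_hist` (`interval`,
#'   `count`, `proportion`) and `checkpoint_split` (as `final_split`,
#'   or `NULL`).
#' @export
summarize_trials <- function(sims, checkpoint = NULL) {
  stopifnot(inherits(sims, "trial_sims"))
  spec <- sims$spec
  k <- n_groups(spec)
  R <- sims$replicates

  final_split <- split_histogram(sims$overall, spec)
  stopifnot(sum(final_split$trials) == R)

  level_diffs <- lapply(sims$var_diffs, function(m) {
    tab <- table(as.vector(m))
    out <- data.frame(difference = as.integer(names(tab)),
                      count = as.integer(tab))
    stopifnot(sum(out$count) == nrow(m) * R)
    out
  })

  runs <- apply(sims$assignments, 2L, max_run_length)
  tab <- table(runs)
  max_runs <- data.frame(max_run = as.integer(names(tab)),
                         trials = as.integer(tab))

  br <- boundary_breaks()
  cuts <- cut(as.vector(sims$p_first), breaks = br, include.lowest = TRUE)
  boundary_hist <- data.frame(interval = levels(cuts),
                              count = as.integer(table(cuts)))
  boundary_hist$proportion <- boundary_hist$count / sum(boundary_hist$count)
  stopifnot(sum(boundary_hist$count) == R * sims$n)

  checkpoint_split <- NULL
  if (!is.null(checkpoint)) {
    if (checkpoint > sims$n)
      stop("'checkpoint' cannot exceed the trial size", call. = FALSE)
    head_assign <- sims$assignments[seq_len(checkpoint), , drop = FALSE]
    interim <- matrix(0L, k, R)
    for (g in seq_len(k)) interim[g, ] <- colSums(head_assign == g)
    checkpoint_split <- split_histogram(interim, spec)
    stopifnot(sum(checkpoint_split$trials) == R)
  }

  structure(list(final_split = final_split, level_diffs = level_diffs,
                 max_runs = max_runs, boundary_hist = boundary_hist,
                 checkpoint_split = checkpoint_split,
                 replicates = R, n = sims$n, checkpoint = checkpoint),
            class = "sim_summary")
}

split_histogram <- function(overall, spec) {
  k <- n_groups(spec)
  key <- apply(overall, 2L, paste, collapse = ":")
  tab <- table(key)
  counts <- do.call(rbind, strsplit(names(tab), ":", fixed = TRUE))
  out <- as.data.frame(matrix(as.integer(counts), ncol = k),
                       col.names = spec$groups)
  names(out) <- spec$groups
  out$trials <- as.integer(tab)
  out[order(out[[1L]]), , drop = FALSE]
}

#' @export
print.sim_summary <- function(x, ...) {
  cat("Simulation summary:", x$replicates, "replicates x", x$n,
      "participants\n\nFinal overall splits:\n")
  print(x$final_split, row.names = FALSE)
  cat("\nLongest same-group runs:\n")
  print(x$max_runs, row.names = FALSE)
  cat("\nBoundary distribution:\n")
  print(transform(x$boundary_hist,
                  proportion = round(proportion, 4)), row.names = FALSE)
  if (!is.null(x$checkpoint_split)) {
    cat("\nSplits after", x$checkpoint, "participants:\n")
    print(x$checkpoint_split, row.names = FALSE)
  }
  invisible(x)
}
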