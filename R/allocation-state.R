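#' Create an empty allocation state
#'
#' The allocation state carries the running allocation counts at every
#' level the boundary calculation consults: the overall group totals, the
#' totals within each level of each stratification variable, and the
#' totals within each stratum (one cell of the full cross-classification
#' of all variables).  It also carries the ordered log of past allocation
#' records, from which the counts are always reconstructible (see
#' [replay_log()]).
#'
#' @param spec A [trial_spec()].
#' @return An object of class `allocation_state` with components
#'   `overall` (integer vector, one count per group), `variables` (list of
#'   levels-by-groups count matrices), `strata` (strata-by-groups count
#'   matrix), `n` (total allocations) and `history` (data frame of
#'   allocation records).
#' @export
empty_state <- function(spec) {
  stopifnot(inherits(spec, "trial_spec"))
  k <- n_groups(spec)
  vars <- lapply(spec$variables, function(lv)
    matrix(0L, nrow = length(lv), ncol = k,
           dimnames = list(lv, spec$groups)))
  n_strata <- if (length(spec$variables)) prod(lengths(spec$variables)) else 1L
  strata <- matrix(0L, nrow = n_strata, ncol = k,
                   dimnames = list(stratum_keys(spec), spec$groups))
  structure(
    list(overall = stats::setNames(integer(k), spec$groups),
         variables = vars, strata = strata, n = 0L,
         history = empty_history(spec)),
    class = "allocation_state")
}

empty_history <- function(spec) {
  cols <- c(list(seq = integer(0), id = character(0)),
            stats::setNames(rep(list(character(0)), length(spec$variables)),
                            names(spec$variables)),
            stats::setNames(rep(list(numeric(0)), n_groups(spec)),
                            paste0("p_", spec$groups)),
            list(u = numeric(0), group = character(0),
                 timestamp = character(0)))
  as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Build an allocation state from per-stratum counts
#'
#' Convenience constructor for states that are known only through a
#' cross-tabulation (one row per stratum, one count column per group)
#' rather than through an allocation-by-allocation log.  Variable-level
#' and overall counts are derived by aggregation, so the resulting state
#' satisfies the cross-tabulation consistency invariants by construction.
#' The state has no participant-level history; use [replay_log()] when an
#' allocation log is available.
#'
#' @param spec A [trial_spec()].
#' @param counts Data frame with one character column per stratification
#'   variable (named as declared) and one integer count column per group
#'   (named as the groups).  Strata omitted from the table are empty.
#' @return An `allocation_state`.
#' @examples
#' spec <- trial_spec(c("A", "B"), c(2, 1),
#'   list(gender = c("M", "F"), center = c("X", "Y", "Z")),
#'   weights = list(overall = 0.1, variables = c(gender = 0.2, center = 0.2),
#'                  stratum = 0.5))
#' tab <- data.frame(
#'   gender = c("M", "F", "M", "F", "M", "F"),
#'   center = c("X", "X", "Y", "Y", "Z", "Z"),
#'   A = c(1L, 1L, 2L, 1L, 1L, 2L),
#'   B = c(0L, 1L, 1L, 1L, 1L, 0L))
#' st <- state_from_counts(spec, tab)
#' st$overall
#' @export
state_from_counts <- function(spec, counts) {
  stopifnot(inherits(spec, "trial_spec"), is.data.frame(counts))
  vars <- names(spec$variables)
  need <- c(vars, spec$groups)
  missing <- setdiff(need, names(counts))
  if (length(missing))
    stop("'counts' is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  state <- empty_state(spec)
  for (r in seq_len(nrow(counts))) {
    prof <- if (length(vars))
      stats::setNames(as.character(unlist(counts[r, vars])), vars)
    else character(0)
    idx <- profile_indices(spec, prof)
    si <- stratum_index(spec, idx)
    for (g in seq_along(spec$groups)) {
      cnt <- counts[r, spec$groups[[g]]]
      if (is.na(cnt) || cnt < 0 || cnt != round(cnt))
        stop("counts must be non-negative integers", call. = FALSE)
      cnt <- as.integer(cnt)
      state$overall[[g]] <- state$overall[[g]] + cnt
      for (v in seq_along(vars))
        state$variables[[v]][idx[[v]], g] <-
          state$variables[[v]][idx[[v]], g] + cnt
      state$strata[si, g] <- state$strata[si, g] + cnt
    }
  }
  state$n <- as.integer(sum(state$overall))
  state
}

# increment all count levels for one assignment; returns the new state
# (copy semantics: the caller's state is untouched)
increment_state <- function(state, spec, level_idx, group_idx) {
  state$overall[[group_idx]] <- state$overall[[group_idx]] + 1L
  for (v in seq_along(level_idx))
    state$variables[[v]][level_idx[[v]], group_idx] <-
      state$variables[[v]][level_idx[[v]], group_idx] + 1L
  si <- stratum_index(spec, level_idx)
  state$strata[si, group_idx] <- state$strata[si, group_idx] + 1L
  state$n <- state$n + 1L
  state
}

#' Check the internal consistency of an allocation state
#'
#' Asserts the cross-tabulation invariants: for every group, the counts
#' at every stratification variable sum to the overall count, and the
#' stratum counts aggregate to the variable-level counts.
#'
#' @param state An `allocation_state`.
#' @param spec The matching [trial_spec()].
#' @return `TRUE` invisibly, or an error describing the inconsistency.
#' @export
validate_state <- function(state, spec) {
  stopifnot(inherits(state, "allocation_state"))
  k <- n_groups(spec)
  for (v in seq_along(spec$variables)) {
    if (!all(colSums(state$variables[[v]]) == state$overall))
      stop("variable '", names(spec$variables)[[v]],
           "' counts do not sum to the overall counts", call. = FALSE)
  }
  if (length(spec$variables)) {
    # stratum rows aggregated over each variable must give that
    # variable's level counts
    nlev <- lengths(spec$variables)
    keys <- strata_level_map(spec)
    for (v in seq_along(nlev)) {
      agg <- rowsum(state$strata, keys[, v])
      lev_counts <- state$variables[[v]]
      if (!all(agg[as.character(seq_len(nlev[[v]])), , drop = FALSE] ==
               lev_counts))
        stop("stratum counts do not aggregate to the level counts of ",
             "variable '", names(spec$variables)[[v]], "'", call. = FALSE)
    }
  }
  if (sum(state$overall) != state$n)
    stop("total allocation count is inconsistent", call. = FALSE)
  invisible(TRUE)
}

# matrix mapping stratum row -> level index of each variable
strata_level_map <- function(spec) {
  nlev <- lengths(spec$variables)
  n_strata <- prod(nlev)
  out <- matrix(0L, n_strata, length(nlev))
  stride <- rev(cumprod(rev(c(nlev[-1L], 1L))))
  for (v in seq_along(nlev))
    out[, v] <- ((seq_len(n_strata) - 1L) %/% stride[[v]]) %% nlev[[v]] + 1L
  out
}

#' @export
print.allocation_state <- function(x, ...) {
  cat("Allocation state:", x$n, "participants\n")
  cat("  overall:", paste(names(x$overall), x$overall, sep = "=",
                          collapse = "  "), "\n")
  for (v in names(x$variables)) {
    cat("  ", v, ":\n", sep = "")
    print(x$variables[[v]])
  }
  invisible(x)
}
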