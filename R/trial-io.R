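#' Read a trial configuration file
#'
#' The configuration is a YAML document with top-level keys `groups`,
#' `ratio`, `variables`, `weights` and optionally `seed`; any other key
#' is rejected so that a mistyped weight name cannot silently disappear.
#' `variables` maps each variable name to its list of levels; `weights`
#' holds `overall`, `stratum` and a `variables` mapping with one entry
#' per declared variable.  [write_trial_config()] emits the same layout,
#' and the two round-trip losslessly.
#'
#' @param path Path to a YAML configuration file.
#' @return A list with `spec` (a validated [trial_spec()]) and `seed`
#'   (integer or `NULL`).
#' @export
read_trial_config <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!is.list(doc)) stop("malformed configuration file", call. = FALSE)
  allowed <- c("groups", "ratio", "variables", "weights", "seed")
  unknown <- setdiff(names(doc), allowed)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (key in c("groups", "ratio", "weights"))
    if (is.null(doc[[key]]))
      stop("configuration is missing required key '", key, "'",
           call. = FALSE)
  vars <- doc$variables
  if (is.null(vars)) vars <- list()
  vars <- lapply(vars, function(lv) as.character(unlist(lv)))
  w <- doc$weights
  unknown_w <- setdiff(names(w), c("overall", "variables", "stratum"))
  if (length(unknown_w))
    stop("unknown weight key(s): ", paste(unknown_w, collapse = ", "),
         call. = FALSE)
  if (!is.null(w$variables)) w$variables <- unlist(w$variables)
  spec <- trial_spec(groups = as.character(unlist(doc$groups)),
                     ratio = unlist(doc$ratio),
                     variables = vars, weights = w)
  seed <- if (!is.null(doc$seed)) as.integer(doc$seed)
  list(spec = spec, seed = seed)
}

#' Write a trial configuration file
#'
#' @param spec A [trial_spec()].
#' @param path Output path for the YAML document.
#' @param seed Optional integer RNG seed stored alongside the
#'   specification.
#' @return `path`, invisibly.
#' @export
write_trial_config <- function(spec, path, seed = NULL) {
  stopifnot(inherits(spec, "trial_spec"))
  doc <- list(groups = as.list(spec$groups),
              ratio = as.list(spec$ratio),
              variables = lapply(spec$variables, as.list),
              weights = list(overall = spec$weights$overall,
                             variables = as.list(spec$weights$variables),
                             stratum = spec$weights$stratum))
  if (!is.null(seed)) doc$seed <- as.integer(seed)
  yaml::write_yaml(doc, path, precision = 17L)  # full double precision
  invisible(path)
}

#' Append an allocation record to a CSV log
#'
#' The allocation log is an append-only comma-separated table with a
#' header row: sequence number, participant id, one column per
#' stratification variable, the per-group probabilities at full
#' precision, the uniform draw, the assigned group and a UTC timestamp.
#' Replaying the log through [replay_log()] reconstructs the allocation
#' state exactly.
#'
#' @param record One-row data frame as produced by
#'   [allocate_participant()].
#' @param path Path to the log file; created with a header when absent.
#' @return `path`, invisibly.
#' @export
append_log <- function(record, path) {
  new <- !file.exists(path)
  fmt <- record
  num <- vapply(fmt, is.double, logical(1L))
  fmt[num] <- lapply(fmt[num], function(x) sprintf("%.17g", x))
  utils::write.table(fmt, path, sep = ",", row.names = FALSE,
                     col.names = new, append = !new, qmethod = "double")
  invisible(path)
}

#' Read an allocation log
#'
#' @param path Path to a CSV allocation log written by [append_log()].
#' @return Data frame of allocation records in sequence order.
#' @export
read_log <- function(path) {
  # read everything as character first: level labels like "F" or "T"
  # must never be type-guessed into logicals
  log <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE, colClasses = "character")
  log$seq <- as.integer(log$seq)
  for (col in c("u", grep("^p_", names(log), value = TRUE)))
    log[[col]] <- as.numeric(log[[col]])
  log
}

#' Rebuild an allocation state by replaying a log
#'
#' Replays the recorded allocations in sequence, recomputing the
#' probability boundaries from the reconstructed state at every step and
#' locating each recorded uniform draw between them.  With
#' `check = TRUE` (the default) the recomputed probabilities and the
#' recomputed assignment are verified against the recorded ones, so a
#' log edited by hand, truncated, or replayed against the wrong
#' specification is detected rather than silently accepted.  Duplicate
#' participant identifiers are always rejected: no participant can be
#' randomized twice.
#'
#' @param log Data frame of allocation records ([read_log()]), or a path
#'   to a log file.
#' @param spec The [trial_spec()] the log belongs to.
#' @param check Verify recorded probabilities (to 1e-9) and assignments
#'   against the replay.
#' @param squaring Passed through to [group_probabilities()].
#' @return The reconstructed `allocation_state`, including history.
#' @export
replay_log <- function(log, spec, check = TRUE,
                       squaring = c("odds_scaled", "difference")) {
  squaring <- match.arg(squaring)
  if (is.character(log)) log <- read_log(log)
  state <- empty_state(spec)
  if (!nrow(log)) return(state)
  if (anyDuplicated(log$id))
    stop("duplicate participant id in log: '",
         log$id[duplicated(log$id)][[1L]],
         "' -- no participant can be randomized twice", call. = FALSE)
  vars <- names(spec$variables)
  pcols <- paste0("p_", spec$groups)
  need <- c("seq", "id", vars, pcols, "u", "group")
  missing <- setdiff(need, names(log))
  if (length(missing))
    stop("log is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (r in seq_len(nrow(log))) {
    row <- log[r, , drop = FALSE]
    profile <- stats::setNames(as.character(unlist(row[vars])), vars)
    rec <- tryCatch(
      allocate_participant(profile, state, spec, id = row$id, u = row$u,
                           squaring = squaring),
      error = function(e)
        stop("log row ", r, ": ", conditionMessage(e), call. = FALSE))
    if (check) {
      if (rec$record$group != row$group)
        stop("log row ", r, ": recorded assignment '", row$group,
             "' disagrees with replayed assignment '", rec$record$group,
             "'", call. = FALSE)
      p_new <- unlist(rec$record[pcols])
      p_old <- unlist(row[pcols])
      if (any(abs(p_new - p_old) > 1e-9))
        stop("log row ", r, ": recorded probabilities disagree with replay",
             call. = FALSE)
    }
    state <- rec$state
  }
  # preserve original timestamps: replay equality excludes them
  state$history$timestamp <- if ("timestamp" %in% names(log))
    as.character(log$timestamp) else NA_character_
  validate_state(state, spec)
  state
}

#' Current allocation splits from a state
#'
#' Tabulates the current allocation counts overall, within every level
#' of every stratification variable, and within every non-empty stratum.
#'
#' @param state An `allocation_state`.
#' @param spec The matching [trial_spec()].
#' @return Data frame with columns `level`, `at` and one count column
#'   per group.
#' @export
allocation_report <- function(state, spec) {
  k <- n_groups(spec)
  rows <- list(data.frame(level = "overall", at = "",
                          t(state$overall), check.names = FALSE))
  for (v in names(spec$variables)) {
    m <- state$variables[[v]]
    rows[[length(rows) + 1L]] <-
      data.frame(level = v, at = rownames(m), m,
                 check.names = FALSE, row.names = NULL)
  }
  if (length(spec$variables)) {
    occupied <- rowSums(state$strata) > 0
    if (any(occupied))
      rows[[length(rows) + 1L]] <-
        data.frame(level = "stratum", at = rownames(state$strata)[occupied],
                   state$strata[occupied, , drop = FALSE],
                   check.names = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  names(out)[2L + seq_len(k)] <- spec$groups
  rownames(out) <- NULL
  out
}
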