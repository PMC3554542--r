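#' Define a trial specification
#'
#' A trial specification is the immutable definition of a randomization
#' set-up: the treatment groups, the target allocation ratio, the discrete
#' stratification variables with their levels, and the imbalance weights
#' that control how strongly the allocation boundaries react to imbalance
#' at each level of the trial (overall, within each stratification
#' variable, and within the stratum cross-classification).
#'
#' @param groups Character vector of unique treatment-group labels
#'   (length >= 2).
#' @param ratio Positive integer vector, one entry per group, giving the
#'   target allocation ratio (e.g. `c(2, 1)` for 2:1 in favour of the
#'   first group).  Defaults to equal allocation.
#' @param variables Named list of stratification variables; each element
#'   is a character vector of >= 2 unique level labels.  May be empty for
#'   an unstratified trial.
#' @param weights List with components `overall` (single non-negative
#'   number), `variables` (named non-negative numeric vector with exactly
#'   one entry per stratification variable) and `stratum` (single
#'   non-negative number).  `weights(spec)` retrieves them.  All-zero
#'   weights give simple randomization at the ratio proportions.
#'
#' @return An object of class `trial_spec`.
#' @examples
#' spec <- trial_spec(
#'   groups    = c("A", "B"),
#'   ratio     = c(2, 1),
#'   variables = list(gender = c("M", "F"), center = c("X", "Y", "Z")),
#'   weights   = list(overall = 0.1,
#'                    variables = c(gender = 0.2, center = 0.2),
#'                    stratum = 0.5)
#' )
#' spec
#' @export
trial_spec <- function(groups, ratio = rep(1L, length(groups)),
                       variables = list(), weights) {
  if (!is.character(groups) || length(groups) < 2L)
    stop("'groups' must be a character vector of at least two group labels",
         call. = FALSE)
  if (anyDuplicated(groups))
    stop("group labels must be unique", call. = FALSE)
  if (length(ratio) != length(groups))
    stop("'ratio' must have one entry per group", call. = FALSE)
  if (any(is.na(ratio)) || any(ratio < 1) || any(ratio != round(ratio)))
    stop("every allocation-ratio entry must be a positive integer",
         call. = FALSE)
  ratio <- as.integer(round(ratio))

  if (!is.list(variables))
    stop("'variables' must be a (possibly empty) named list of level vectors",
         call. = FALSE)
  if (length(variables) > 0L) {
    nm <- names(variables)
    if (is.null(nm) || any(!nzchar(nm)))
      stop("every stratification variable must be named", call. = FALSE)
    if (anyDuplicated(nm))
      stop("stratification-variable names must be unique", call. = FALSE)
    for (v in nm) {
      lv <- variables[[v]]
      if (!is.character(lv) || length(lv) < 2L)
        stop("variable '", v, "' must declare at least two level labels",
             call. = FALSE)
      if (anyDuplicated(lv))
        stop("levels of variable '", v, "' must be unique", call. = FALSE)
    }
  }

  weights <- validate_weights(weights, names(variables))

  structure(
    list(groups = groups, ratio = ratio,
         variables = variables, weights = weights),
    class = "trial_spec")
}

validate_weights <- function(weights, var_names) {
  if (!is.list(weights))
    stop("'weights' must be a list with components 'overall', 'variables' ",
         "and 'stratum'", call. = FALSE)
  unknown <- setdiff(names(weights), c("overall", "variables", "stratum"))
  if (length(unknown))
    stop("unknown weight component(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (comp in c("overall", "stratum")) {
    w <- weights[[comp]]
    if (is.null(w)) {
      if (comp == "stratum" && length(var_names) == 0L) {
        weights$stratum <- 0
        next
      }
      stop("weight component '", comp, "' is missing", call. = FALSE)
    }
    if (!is.numeric(w) || length(w) != 1L || is.na(w) || w < 0)
      stop("weight '", comp, "' must be a single non-negative number",
           call. = FALSE)
  }
  wv <- weights$variables
  if (length(var_names) == 0L) {
    weights$variables <- stats::setNames(numeric(0), character(0))
  } else {
    if (is.null(wv))
      stop("weight component 'variables' is missing", call. = FALSE)
    if (!is.numeric(wv) || is.null(names(wv)))
      stop("'weights$variables' must be a named numeric vector", call. = FALSE)
    missing <- setdiff(var_names, names(wv))
    if (length(missing))
      stop("no weight declared for variable(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    extra <- setdiff(names(wv), var_names)
    if (length(extra))
      stop("weight declared for undeclared variable(s): ",
           paste(extra, collapse = ", "), call. = FALSE)
    if (any(is.na(wv)) || any(wv < 0))
      stop("variable weights must be non-negative", call. = FALSE)
    weights$variables <- wv[var_names]   # canonical order
  }
  weights[c("overall", "variables", "stratum")]
}

#' @export
print.trial_spec <- function(x, ...) {
  cat("Trial specification\n")
  cat("  groups: ", paste(x$groups, collapse = ", "),
      "  (ratio ", paste(x$ratio, collapse = ":"), ")\n", sep = "")
  if (length(x$variables) == 0L) {
    cat("  no stratification variables\n")
  } else {
    for (v in names(x$variables))
      cat("  ", v, " [w=", format(x$weights$variables[[v]]), "]: ",
          paste(x$variables[[v]], collapse = ", "), "\n", sep = "")
  }
  cat("  weights: overall=", format(x$weights$overall),
      ", stratum=", format(x$weights$stratum), "\n", sep = "")
  invisible(x)
}

#' Number of treatment groups in a specification
#' @param spec A [trial_spec()].
#' @return Integer count of groups.
#' @export
n_groups <- function(spec) length(spec$groups)

#' Validate a participant profile against a specification
#'
#' A profile assigns to every declared stratification variable exactly one
#' of its declared levels.
#'
#' @param spec A [trial_spec()].
#' @param profile Named character vector or named list mapping every
#'   variable name to one of its levels.
#' @return Integer vector of level indices, one per declared variable (in
#'   declaration order); zero-length for an unstratified trial.
#' @export
profile_indices <- function(spec, profile) {
  vars <- names(spec$variables)
  if (length(vars) == 0L) return(integer(0))
  profile <- unlist(profile)
  if (is.null(names(profile)))
    stop("profile values must be named by stratification variable",
         call. = FALSE)
  missing <- setdiff(vars, names(profile))
  if (length(missing))
    stop("profile is missing variable(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(profile), vars)
  if (length(extra))
    stop("profile declares unknown variable(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  idx <- integer(length(vars))
  names(idx) <- vars
  for (v in vars) {
    i <- match(as.character(profile[[v]]), spec$variables[[v]])
    if (is.na(i))
      stop("'", profile[[v]], "' is not a declared level of variable '",
           v, "'", call. = FALSE)
    idx[[v]] <- i
  }
  idx
}

# row index of a stratum in the stratum count matrix; first declared
# variable varies slowest
stratum_index <- function(spec, level_idx) {
  nlev <- lengths(spec$variables)
  if (length(nlev) == 0L) return(1L)
  i <- 0L
  for (v in seq_along(nlev)) i <- i * nlev[[v]] + (level_idx[[v]] - 1L)
  i + 1L
}

stratum_keys <- function(spec) {
  if (length(spec$variables) == 0L) return("(all)")
  grids <- expand.grid(rev(spec$variables), stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  grids <- grids[, rev(seq_along(spec$variables)), drop = FALSE]
  apply(grids, 1L, paste, collapse = "/")
}
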