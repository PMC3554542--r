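#' Two-group demonstration trial with a 2:1 ratio
#'
#' The small worked-example set-up: groups A and B allocated 2:1,
#' stratified by gender (M, F) and center (X, Y, Z), with weights 0.1
#' overall, 0.2 per stratification variable and 0.5 for the stratum.
#'
#' @param weight_scale Multiplier applied to all four weights (e.g. 10
#'   for the strengthened and 0.1 for the weakened variant).
#' @return A [trial_spec()].
#' @export
example_spec_2to1 <- function(weight_scale = 1) {
  trial_spec(
    groups = c("A", "B"), ratio = c(2L, 1L),
    variables = list(gender = c("M", "F"), center = c("X", "Y", "Z")),
    weights = list(overall = 0.1 * weight_scale,
                   variables = c(gender = 0.2, center = 0.2) * weight_scale,
                   stratum = 0.5 * weight_scale))
}

#' Simulation-scenario specifications
#'
#' The four weighting regimes of the simulation study, all on a
#' two-group 1:1 trial stratified by center (X, Y, Z) and gender
#' (M, F): strong control (overall 1, center 2, gender 2, stratum 5),
#' medium (0.1, 0.2, 0.2, 0.5), weak (0.01, 0.02, 0.02, 0.05) and
#' simple randomization (all weights 0).
#'
#' @param scenario Integer 1-4 (strong, medium, weak, simple).
#' @return A [trial_spec()].
#' @export
scenario_spec <- function(scenario) {
  stopifnot(length(scenario) == 1L, scenario %in% 1:4)
  scale <- c(1, 0.1, 0.01, 0)[[scenario]]
  trial_spec(
    groups = c("A", "B"), ratio = c(1L, 1L),
    variables = list(center = c("X", "Y", "Z"), gender = c("M", "F")),
    weights = list(overall = 1 * scale,
                   variables = c(center = 2, gender = 2) * scale,
                   stratum = 5 * scale))
}

#' FolATED trial specification
#'
#' Two-group 1:1 placebo-controlled antidepressant-augmentation trial
#' (target 549 participants), stratified by center (3), gender (2),
#' patient type (4 levels: new and continuing patients crossed with
#' counselling history) and antidepressant type (2), with weights
#' overall 0.02, center 0.04, gender 0.04, patient type 0.02,
#' antidepressant 0.02 and stratum 0.05.
#'
#' @return A [trial_spec()].
#' @export
folated_spec <- function() {
  trial_spec(
    groups = c("folate", "placebo"), ratio = c(1L, 1L),
    variables = list(
      center = c("Bangor", "Swansea", "Wrexham"),
      gender = c("female", "male"),
      patient_type = c("new/counselling", "new/no-counselling",
                       "continuing/counselling", "continuing/no-counselling"),
      antidepressant = c("SSRI", "other")),
    weights = list(overall = 0.02,
                   variables = c(center = 0.04, gender = 0.04,
                                 patient_type = 0.02, antidepressant = 0.02),
                   stratum = 0.05))
}

#' EPIC trial specification
#'
#' Two-group 2:1 trial of an information pack for children and young
#' people with type 1 diabetes (target 252 participants, 168:84),
#' stratified by age band (3), gender (2), time since diagnosis (2) and
#' recruiting center, with weights 0.05 for overall, age, gender and
#' diagnosis, 0.1 for center and 0.2 for the stratum.  The number of
#' recruiting centers is a parameter: the source set-up does not pin it
#' down, so EPIC-derived quantities are soft checks only.
#'
#' @param n_centers Number of recruiting centers in the fixture.
#' @return A [trial_spec()].
#' @export
epic_spec <- function(n_centers = 4L) {
  stopifnot(n_centers >= 2L)
  trial_spec(
    groups = c("intervention", "control"), ratio = c(2L, 1L),
    variables = list(
      age = c("6-10", "11-15", "16-18"),
      gender = c("female", "male"),
      diagnosis = c("<2y", ">=2y"),
      center = paste0("C", seq_len(n_centers))),
    weights = list(overall = 0.05,
                   variables = c(age = 0.05, gender = 0.05,
                                 diagnosis = 0.05, center = 0.1),
                   stratum = 0.2))
}

#' SWAD trial specification
#'
#' Three-group 2:2:1 trial (mindfulness-based cognitive therapy + TAU,
#' cognitive psycho-education + TAU, TAU alone; target 375
#' participants), stratified by research center (2), recruitment cohort
#' (6), suicidality history (3) and antidepressant use (2), with
#' weights overall 0.05, center 0.1, cohort 0.1, suicidality 0.05,
#' antidepressant use 0.05 and stratum 0.25.  Cohorts recruit
#' sequentially in the real trial, which an i.i.d. covariate model does
#' not emulate, so SWAD-derived quantities are soft checks only.
#'
#' @return A [trial_spec()].
#' @export
swad_spec <- function() {
  trial_spec(
    groups = c("MBCT", "CPE", "TAU"), ratio = c(2L, 2L, 1L),
    variables = list(
      center = c("Oxford", "Bangor"),
      cohort = paste0("cohort", 1:6),
      suicidality = c("none", "ideation", "attempt"),
      ad_use = c("no", "yes")),
    weights = list(overall = 0.05,
                   variables = c(center = 0.1, cohort = 0.1,
                                 suicidality = 0.05, ad_use = 0.05),
                   stratum = 0.25))
}

#' Twelve-participant worked-example allocation table
#'
#' The cross-tabulated state after 12 allocations in the 2:1
#' demonstration trial: 8 in group A and 4 in group B, with the
#' per-stratum breakdown used by the worked boundary calculation for
#' the 13th participant.
#'
#' @return Data frame of per-stratum counts suitable for
#'   [state_from_counts()] with [example_spec_2to1()].
#' @export
example_counts_12 <- function() {
  data.frame(
    gender = c("M", "F", "M", "F", "M", "F"),
    center = c("X", "X", "Y", "Y", "Z", "Z"),
    A = c(1L, 1L, 2L, 1L, 1L, 2L),
    B = c(0L, 1L, 1L, 1L, 1L, 0L),
    stringsAsFactors = FALSE)
}
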