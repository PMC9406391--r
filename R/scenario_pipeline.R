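# End-to-end clinical scenario evaluator: joins a transportability verdict
# with the milestone effect calculator to produce per-patient adjuvant
# therapy recommendations, including sensitivity-grid handling for off-trial
# histologies and explicit "not estimable / external data needed" outcomes.

HISTOLOGIES <- c("clear cell", "papillary I", "papillary II", "chromophobe",
                 "other")

#' Describe a patient scenario for adjuvant-therapy evaluation
#'
#' Bundles what the decision pipeline needs: renal-cell-carcinoma histology,
#' trial-eligibility status, the externally supplied baseline milestone
#' disease-free-survival probability (e.g. from a prognostic nomogram; this
#' package never computes it), the milestone time, and a primary hazard ratio
#' and/or a sensitivity grid of hypothetical hazard ratios.
#'
#' @param id patient identifier.
#' @param histology one of `"clear cell"`, `"papillary I"`, `"papillary II"`,
#'   `"chromophobe"`, `"other"`.
#' @param eligible logical: does the patient meet the reference trial's entry
#'   criteria?
#' @param baseline_prob baseline milestone survival probability under
#'   surveillance, a fraction in (0, 1), or `NA` when no credible estimate
#'   exists.
#' @param milestone_months milestone time in months (> 0, default 24).
#' @param hr primary hazard ratio (trial estimate), or `NA`.
#' @param hr_grid optional numeric vector of hypothetical hazard ratios for
#'   sensitivity analysis.
#' @param notes free-text covariate notes (stage, grade, necrosis, ...).
#' @return Object of class `patient_scenario`.
#' @examples
#' patient_scenario("I", "clear cell", eligible = TRUE,
#'                  baseline_prob = 0.414, hr = 0.68)
#' @export
patient_scenario <- function(id, histology, eligible,
                             baseline_prob = NA_real_,
                             milestone_months = 24,
                             hr = NA_real_, hr_grid = NULL, notes = "") {
  if (!is_string(histology) || !histology %in% HISTOLOGIES)
    abort2(paste0("unknown histology '", histology, "'; expected one of: ",
                  paste(HISTOLOGIES, collapse = ", ")),
           "oncocausal_config_error")
  stopifnot(is.logical(eligible), length(eligible) == 1L)
  if (!is.na(baseline_prob)) check_fraction(baseline_prob, "baseline_prob")
  check_positive(milestone_months, "milestone_months")
  if (!is.na(hr)) check_positive(hr, "hr")
  if (!is.null(hr_grid)) {
    if (!length(hr_grid) || any(!is.finite(hr_grid)) || any(hr_grid <= 0))
      abort2("hr_grid must contain positive hazard ratios",
             "oncocausal_config_error")
  }
  structure(list(id = as.character(id), histology = histology,
                 eligible = eligible, baseline_prob = baseline_prob,
                 milestone_months = milestone_months, hr = hr,
                 hr_grid = hr_grid, notes = notes),
            class = "patient_scenario")
}

#' @export
print.patient_scenario <- function(x, ...) {
  cat(sprintf("Patient %s: %s RCC, %s\n", x$id, x$histology,
              if (x$eligible) "trial-eligible" else "not trial-eligible"))
  cat(sprintf("  baseline %d-month DFS: %s; HR: %s%s\n",
              x$milestone_months,
              if (is.na(x$baseline_prob)) "not estimable"
              else sprintf("%.1f%%", 100 * x$baseline_prob),
              if (is.na(x$hr)) "-" else format(x$hr),
              if (is.null(x$hr_grid)) ""
              else paste0("; sensitivity grid {",
                          paste(x$hr_grid, collapse = ", "), "}")))
  invisible(x)
}

#' Transport route for a patient scenario
#'
#' Classifies how (and whether) the reference-trial effect can be transported
#' to the patient, and verifies the corresponding selection-diagram
#' admissibility check:
#' * clear cell histology with a baseline estimate: the `additive` route —
#'   the general risk-plus-effect-modification diagram collapses to the
#'   additive risk diagram (fixture `6A`, adjustment `{Z}`);
#' * any other histology with a baseline estimate: the `effect_modified`
#'   route — the immune-microenvironment mediator makes histology a
#'   treatment-effect modifier (fixture `8A`, adjustment `{Z, B}`), so a
#'   hazard-ratio sensitivity grid is required downstream;
#' * no baseline estimate: `not_estimable` — external observational data are
#'   needed before any effect can be computed.
#'
#' The route is a pure function of (histology, baseline presence).
#'
#' @param scenario a [patient_scenario()].
#' @return List with elements `route` (one of `"additive"`,
#'   `"effect_modified"`, `"not_estimable"`), `figure` (fixture id used),
#'   `adjustment`, and `verdict` (the [s_admissible()] result, always
#'   admissible for the chosen adjustment).
#' @export
transport_route <- function(scenario) {
  stopifnot(inherits(scenario, "patient_scenario"))
  if (is.na(scenario$baseline_prob)) {
    route <- "not_estimable"; fig <- "6A"; adj <- "Z"
  } else if (scenario$histology == "clear cell") {
    route <- "additive"; fig <- "6A"; adj <- "Z"
  } else {
    route <- "effect_modified"; fig <- "8A"; adj <- c("Z", "B")
  }
  verdict <- s_admissible(figure_fixture(fig), "X", "Y", adjustment = adj)
  if (!verdict$admissible)
    abort2(sprintf("internal: fixture %s adjustment {%s} unexpectedly inadmissible",
                   fig, paste(adj, collapse = ", ")),
           "oncocausal_config_error")
  list(route = route, figure = fig, adjustment = adj, verdict = verdict)
}

#' Evaluate a patient scenario into a decision report
#'
#' Runs the transport route, applies the milestone calculator, and applies an
#' absolute-risk-reduction decision threshold (default 5 percentage points in
#' 24-month disease-free survival):
#' * `additive` route: the primary hazard ratio yields a single treated
#'   probability and ARR; recommend iff ARR >= threshold.
#' * `effect_modified` route: the effect is not formally estimable. The
#'   hazard-ratio sensitivity grid is evaluated; the *reported* figures use
#'   the most conservative (largest) grid value. If even that conservative
#'   ARR clears the threshold the verdict is "plausible under sensitivity";
#'   if even the most optimistic (smallest) hazard ratio fails the threshold,
#'   the treatment is not recommended under any considered scenario;
#'   otherwise the verdict stays "do not recommend".
#' * `not_estimable` route: no quantities are computed; external data flags
#'   are raised instead.
#'
#' External-data flags: observational studies are needed when no baseline
#' probability exists; experimental studies are needed for non-clear-cell
#' histologies (no trial covers their distinct immune microenvironment).
#'
#' @param scenario a [patient_scenario()].
#' @param threshold ARR decision threshold in percentage points (> 0,
#'   default 5).
#' @return Object of class `decision_report`.
#' @examples
#' p1 <- patient_scenario("I", "clear cell", TRUE, baseline_prob = 0.414,
#'                        hr = 0.68)
#' evaluate_scenario(p1)
#' @export
evaluate_scenario <- function(scenario, threshold = 5) {
  stopifnot(inherits(scenario, "patient_scenario"))
  check_positive(threshold, "threshold")
  rt <- transport_route(scenario)
  rep_base <- list(id = scenario$id, histology = scenario$histology,
                   eligible = scenario$eligible,
                   baseline_prob = scenario$baseline_prob,
                   milestone_months = scenario$milestone_months,
                   route = rt$route, figure = rt$figure,
                   threshold = threshold,
                   observational_needed = is.na(scenario$baseline_prob),
                   experimental_needed = scenario$histology != "clear cell")
  if (rt$route == "not_estimable") {
    rep_base$treated_prob <- NA_real_
    rep_base$arr <- NA_real_
    rep_base$hr_used <- NA_real_
    rep_base$recommendation <- "not estimable"
  } else if (rt$route == "additive") {
    if (is.na(scenario$hr))
      abort2(paste0("patient ", scenario$id,
                    ": additive route requires a primary hazard ratio"),
             "oncocausal_config_error")
    est <- treated_milestone(scenario$baseline_prob,
                             scenario$milestone_months, scenario$hr)
    rep_base$treated_prob <- est$treated
    rep_base$arr <- est$arr
    rep_base$hr_used <- scenario$hr
    rep_base$recommendation <-
      if (est$arr >= threshold) "recommend" else "do not recommend"
  } else {  # effect_modified
    if (is.null(scenario$hr_grid))
      abort2(paste0("patient ", scenario$id, ": effect-modified route needs ",
                    "an hr_grid sensitivity input (no trial estimate applies ",
                    "to this histology)"),
             "oncocausal_config_error")
    grid <- hr_sensitivity(scenario$baseline_prob, scenario$milestone_months,
                           sort(scenario$hr_grid))
    conservative <- grid[nrow(grid), ]   # largest HR: smallest effect
    optimistic <- grid[1L, ]             # smallest HR: best case
    rep_base$treated_prob <- conservative$treated
    rep_base$arr <- conservative$arr
    rep_base$hr_used <- conservative$hr
    rep_base$arr_best_case <- optimistic$arr
    rep_base$recommendation <-
      if (conservative$arr >= threshold) "plausible under sensitivity"
      else "do not recommend"
  }
  structure(rep_base, class = "decision_report")
}

#' @export
print.decision_report <- function(x, ...) {
  cat(sprintf("Patient %s (%s RCC) - route: %s [diagram %s]\n",
              x$id, x$histology, x$route, x$figure))
  if (is.na(x$arr)) {
    cat("  effect: not estimable\n")
  } else {
    qual <- if (x$route == "effect_modified")
      sprintf(" (not formally estimable; shown at HR %g)", x$hr_used) else ""
    cat(sprintf("  %d-month DFS: %.1f%% -> %.1f%%, ARR %.1f points%s\n",
                x$milestone_months, 100 * x$baseline_prob,
                100 * x$treated_prob, x$arr, qual))
  }
  cat(sprintf("  recommendation (ARR >= %g points): %s\n",
              x$threshold, x$recommendation))
  if (x$observational_needed)
    cat("  external observational studies needed\n")
  if (x$experimental_needed)
    cat("  external experimental studies needed\n")
  invisible(x)
}

# ---- report rendering -------------------------------------------------------

#' Render decision reports as a table
#'
#' @param reports non-empty list of [evaluate_scenario()] results.
#' @param format `"text"` (aligned table), `"csv"` or `"json"`. All formats
#'   render the same cell values; quantities that cannot be computed appear
#'   as the string `"Not estimable"`, never as blank cells.
#' @return For `"text"` and `"csv"`, a character vector of lines; for
#'   `"json"`, a JSON string. The underlying data frame is attached as
#'   attribute `"data"`.
#' @export
report_table <- function(reports, format = c("text", "csv", "json")) {
  format <- match.arg(format)
  if (!length(reports))
    abort2("no reports to render", "oncocausal_argument_error")
  ne <- "Not estimable"
  pct <- function(p) ifelse(is.na(p), ne, sprintf("%.1f%%", 100 * p))
  pts <- function(a) ifelse(is.na(a), ne, sprintf("%.1f", a))
  df <- do.call(rbind, lapply(reports, function(r) {
    data.frame(
      patient = r$id,
      histology = r$histology,
      eligible = ifelse(r$eligible, "Yes", "No"),
      route = r$route,
      baseline_dfs = pct(r$baseline_prob),
      treated_dfs = pct(r$treated_prob),
      arr = pts(r$arr),
      recommendation = r$recommendation,
      observational_needed = ifelse(r$observational_needed, "Yes", "No"),
      experimental_needed = ifelse(r$experimental_needed, "Yes", "No"),
      stringsAsFactors = FALSE)
  }))
  out <- switch(format,
    text = {
      m <- rbind(names(df), as.matrix(df))
      widths <- apply(nchar(m), 2L, max)
      lines <- apply(m, 1L, function(row)
        paste(mapply(formatC, row, width = widths, flag = "-"),
              collapse = "  "))
      trimws(lines, which = "right")
    },
    csv = {
      con <- textConnection("csv_out", "w", local = TRUE)
      utils::write.csv(df, con, row.names = FALSE)
      close(con)
      csv_out
    },
    json = jsonlite::toJSON(df, dataframe = "rows", auto_unbox = TRUE,
                            pretty = TRUE))
  attr(out, "data") <- df
  out
}

# ---- shipped patient fixtures ----------------------------------------------

parse_hr_grid <- function(x) {
  if (is.na(x) || !nzchar(x)) return(NULL)
  as.numeric(strsplit(x, ";", fixed = TRUE)[[1L]])
}

#' Read patient scenarios from a CSV or JSON file
#'
#' Expected columns/keys: `id`, `histology`, `eligible`, `baseline_prob`
#' (fraction or empty), `milestone_months`, `hr` (or empty), `hr_grid`
#' (semicolon-separated, or empty), `notes`.
#'
#' @param file path to a `.csv` or `.json` file.
#' @return List of [patient_scenario()] objects.
#' @export
read_patient_scenarios <- function(file) {
  df <- if (grepl("\\.json$", file, ignore.case = TRUE)) {
    jsonlite::fromJSON(file)
  } else {
    utils::read.csv(file, stringsAsFactors = FALSE,
                    colClasses = c(hr_grid = "character"))
  }
  need <- c("id", "histology", "eligible", "baseline_prob",
            "milestone_months", "hr", "hr_grid", "notes")
  missing <- setdiff(need, names(df))
  if (length(missing))
    abort2(paste0("scenario file lacks column(s): ",
                  paste(missing, collapse = ", ")),
           "oncocausal_config_error")
  lapply(seq_len(nrow(df)), function(i) {
    elig <- df$eligible[i]
    if (is.character(elig)) elig <- tolower(elig) %in% c("yes", "true", "1")
    patient_scenario(df$id[i], df$histology[i], as.logical(elig),
                     baseline_prob = df$baseline_prob[i],
                     milestone_months = df$milestone_months[i],
                     hr = df$hr[i],
                     hr_grid = parse_hr_grid(df$hr_grid[i]),
                     notes = df$notes[i] %||% "")
  })
}

#' The eight bundled renal-cell-carcinoma patient scenarios
#'
#' Loads the packaged scenarios built around the KEYNOTE-564 adjuvant
#' pembrolizumab trial (hazard ratio 0.68 for disease-free survival) and
#' Assure-nomogram baseline probabilities: trial-eligible and ineligible
#' clear cell patients, a patient whose M1-NED status no nomogram covers,
#' papillary type I/II and chromophobe patients evaluated through
#' hazard-ratio sensitivity bounds, and a patient whose nomogram output is
#' clinically implausible.
#'
#' @return List of eight [patient_scenario()] objects.
#' @examples
#' pats <- keynote564_patients()
#' report_table(lapply(pats, evaluate_scenario), format = "text")
#' @export
keynote564_patients <- function() {
  path <- system.file("extdata", "patients_keynote564.csv",
                      package = "oncocausal", mustWork = TRUE)
  read_patient_scenarios(path)
}
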