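#' Read a measurement table from CSV
#'
#' Reads and validates the long-format measurement table: one row per
#' (subject, observer, observation, method) with the basal-turn measurements
#' in mm. Expected columns: `subject_id`, `observer`, `observation`,
#' `method` (`"software-3d"` or `"2d-oblique"`), `A_mm`, `B_mm`; an optional
#' `ear` column is carried through. The 2D-oblique workflow measures only
#' the diameter, so `B_mm` may be empty for those rows only. All schema
#' violations are collected and reported together with their row numbers.
#'
#' @param path Path to a CSV file (comma-separated, header row, `.` decimal
#'   separator, units in the column names).
#' @return A validated tibble.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("subject_id", "observer", "observation", "method", "A_mm", "B_mm")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop(sprintf("schema error in %s: missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }

  problems <- character(0)
  note <- function(rows, what) {
    if (length(rows) > 0) {
      problems <<- c(problems, sprintf("%s (row%s %s)", what,
                                       if (length(rows) > 1) "s" else "",
                                       paste(rows, collapse = ", ")))
    }
  }

  A <- suppressWarnings(as.numeric(raw$A_mm))
  B <- suppressWarnings(as.numeric(raw$B_mm))
  note(which(is.na(A) & !is.na(raw$A_mm)), "non-numeric A_mm")
  note(which(is.na(raw$A_mm)), "missing A_mm")
  note(which(is.na(B) & !is.na(raw$B_mm)), "non-numeric B_mm")
  note(which(!is.na(A) & A <= 0), "non-positive A_mm")
  note(which(!is.na(B) & B <= 0), "non-positive B_mm")

  bad_method <- which(!raw$method %in% c("software-3d", "2d-oblique"))
  note(bad_method, "unknown method (expected software-3d or 2d-oblique)")
  # only the 2D-oblique workflow is allowed to omit the width
  note(which(raw$method == "software-3d" & is.na(raw$B_mm)),
       "B_mm missing for a software-3d row")

  key <- paste(raw$subject_id, raw$observer, raw$observation, raw$method)
  note(which(duplicated(key)),
       "duplicate (subject_id, observer, observation, method)")

  if (length(problems) > 0) {
    stop(sprintf("schema error in %s:\n  - %s", path,
                 paste(problems, collapse = "\n  - ")), call. = FALSE)
  }

  out <- tibble::tibble(
    subject_id = raw$subject_id,
    observer = as.integer(raw$observer),
    observation = as.integer(raw$observation),
    method = raw$method,
    A_mm = A,
    B_mm = B
  )
  if ("ear" %in% names(raw)) out$ear <- raw$ear
  if (any(!is.na(out$B_mm) & out$A_mm <= out$B_mm)) {
    warning(sprintf("%d row(s) have A_mm <= B_mm; A should be the longer axis",
                    sum(!is.na(out$B_mm) & out$A_mm <= out$B_mm)), call. = FALSE)
  }
  out
}

#' Write a measurement table to CSV
#'
#' @param data A measurement tibble (see [read_measurements()] for the schema).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_measurements <- function(data, path) {
  stopifnot(is.data.frame(data))
  readr::write_csv(data, path)
  invisible(path)
}

#' Run the full prediction-validation-agreement pipeline
#'
#' Ties the stages together: per-measurement insertion-depth predictions
#' under the requested model(s), per-subject prediction errors against the
#' observed postoperative depths, the per-model/per-observer error summary
#' table, cohort mean angles, observer-agreement statistics (Bland-Altman
#' and ICC on the predicted angle at C1), and the paired Wilcoxon comparison
#' of inter-observer disagreement between the two models. Rows that cannot
#' be predicted (missing B for the ECA, geometry outside a model's domain)
#' are reported by count and excluded from summaries, never silently
#' dropped. The pipeline is deterministic given its inputs.
#'
#' @param measurements Measurement tibble ([read_measurements()] schema or
#'   the `measurements` table of a [generate_cohort()] result).
#' @param observed Observed-insertion tibble with `subject_id`, optionally
#'   `observer`, and `actual_angular_c1_deg`.
#' @param model `"both"` (default), `"escude"`, or `"eca"`.
#' @param electrode An [electrode_spec()].
#' @param params A [cochlear_params()] object.
#' @param reference `"c1"` (default) or `"tip"`: reference point for errors.
#' @return A list of class `insertion_pipeline`: `predictions`, `errors`,
#'   `error_summary`, `cohort_angles`, `agreement` (one row per agreement
#'   analysis), `method_comparison`, `settings`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 8), seed = 42)
#' res <- run_pipeline(coh$measurements, coh$observed)
#' res$error_summary
#' @export
run_pipeline <- function(measurements, observed,
                         model = c("both", "escude", "eca"),
                         electrode = flex28(),
                         params = cochlear_params(),
                         reference = c("c1", "tip")) {
  model <- match.arg(model)
  reference <- match.arg(reference)
  stopifnot(is.data.frame(measurements), is.data.frame(observed))

  settings <- list(
    model = model, electrode = electrode, params = params,
    reference = reference,
    icc_form = "two-way random effects, absolute agreement, single measures",
    loa_multiplier = 2,
    param_hash = rlang::hash(list(electrode, params))
  )

  predictions <- predict_insertion(measurements, model = model,
                                   electrode = electrode, params = params)
  predictions$param_hash <- settings$param_hash
  n_failed <- sum(!is.finite(predictions$angular_c1_deg))

  errors <- prediction_error(predictions, observed,
                             reference = reference,
                             electrode = electrode, params = params)
  errors$param_hash <- settings$param_hash
  error_summary <- summarize_errors(errors)

  cohort_angles <- dplyr::bind_rows(
    dplyr::mutate(
      cohort_angle_summary(errors, .data$actual_angular_tip_deg, .data$model),
      quantity = "actual_tip"),
    dplyr::mutate(
      cohort_angle_summary(errors, .data$angular_tip_deg, .data$model),
      quantity = "predicted_tip")
  )

  agreement <- pipeline_agreement(predictions, settings)
  method_comparison <- pipeline_method_comparison(predictions)

  structure(
    list(predictions = predictions, errors = errors,
         error_summary = error_summary, cohort_angles = cohort_angles,
         agreement = agreement, method_comparison = method_comparison,
         n_unpredictable = n_failed, settings = settings),
    class = "insertion_pipeline"
  )
}

# Bland-Altman (intra- and inter-observer) and inter-observer ICC on the
# predicted angular depth at C1, per model; analyses that need structure the
# data lacks (a second observation, a second observer) are simply absent
pipeline_agreement <- function(predictions, settings) {
  out <- list()
  add_ba <- function(ba, model, kind, observer = NA_integer_) {
    dplyr::mutate(glance(ba), model = model, analysis = kind,
                  observer = observer, icc = NA_real_, icc_label = NA_character_,
                  .before = 1)
  }
  for (m in unique(predictions$model)) {
    pm <- dplyr::filter(predictions, .data$model == m,
                        is.finite(.data$angular_c1_deg))
    # intra-observer: observation 1 vs observation 2, per observer
    if ("observation" %in% names(pm)) {
      wide_obs <- tidyr::pivot_wider(
        pm[c("subject_id", "observer", "observation", "angular_c1_deg")],
        names_from = "observation", values_from = "angular_c1_deg",
        names_prefix = "obs_")
      if (all(c("obs_1", "obs_2") %in% names(wide_obs))) {
        for (o in sort(unique(wide_obs$observer))) {
          w <- dplyr::filter(wide_obs, .data$observer == o)
          if (sum(stats::complete.cases(w[c("obs_1", "obs_2")])) >= 2) {
            out[[length(out) + 1]] <- add_ba(
              bland_altman(w, .data$obs_1, .data$obs_2), m,
              "intra-observer angular C1", o)
          }
        }
      }
    }
    # inter-observer: first observation of observer 1 vs observer 2
    first_obs <- if ("observation" %in% names(pm)) {
      dplyr::filter(pm, .data$observation == 1)
    } else {
      pm
    }
    wide_rat <- tidyr::pivot_wider(
      first_obs[c("subject_id", "observer", "angular_c1_deg")],
      names_from = "observer", values_from = "angular_c1_deg",
      names_prefix = "rater_")
    if (all(c("rater_1", "rater_2") %in% names(wide_rat)) &&
        sum(stats::complete.cases(wide_rat[c("rater_1", "rater_2")])) >= 3) {
      ba <- bland_altman(wide_rat, .data$rater_1, .data$rater_2)
      icc <- icc_agreement(wide_rat, dplyr::all_of(c("rater_1", "rater_2")))
      row <- add_ba(ba, m, "inter-observer angular C1")
      row$icc <- icc$value
      row$icc_label <- icc$label
      out[[length(out) + 1]] <- row
    }
  }
  if (length(out) == 0) return(NULL)
  dplyr::bind_rows(out)
}

# paired Wilcoxon on per-subject |observer 1 - observer 2| of the predicted
# angle at C1, Escude vs ECA (first observations)
pipeline_method_comparison <- function(predictions) {
  if (!all(c("escude", "eca") %in% unique(predictions$model))) return(NULL)
  first_obs <- if ("observation" %in% names(predictions)) {
    dplyr::filter(predictions, .data$observation == 1)
  } else {
    predictions
  }
  disag <- tidyr::pivot_wider(
    first_obs[c("subject_id", "observer", "model", "angular_c1_deg")],
    names_from = "observer", values_from = "angular_c1_deg",
    names_prefix = "rater_")
  if (!all(c("rater_1", "rater_2") %in% names(disag))) return(NULL)
  disag$abs_diff <- abs(disag$rater_1 - disag$rater_2)
  wide <- tidyr::pivot_wider(disag[c("subject_id", "model", "abs_diff")],
                             names_from = "model", values_from = "abs_diff")
  wide <- wide[stats::complete.cases(wide), ]
  if (nrow(wide) < 5) return(NULL)
  res <- compare_method_variability(wide$escude, wide$eca)
  dplyr::mutate(res,
                comparison = "inter-observer |disagreement| of angular C1: escude vs eca",
                .before = 1)
}

#' @export
print.insertion_pipeline <- function(x, ...) {
  cat("Insertion-depth prediction pipeline\n")
  cat(sprintf("  model(s): %s; electrode: %s; errors at %s\n",
              x$settings$model, x$settings$electrode$name,
              toupper(x$settings$reference)))
  cat(sprintf("  ICC form: %s; limits of agreement at mean +/- %g SD\n",
              x$settings$icc_form, x$settings$loa_multiplier))
  if (x$n_unpredictable > 0) {
    cat(sprintf("  %d prediction row(s) unpredictable and excluded from summaries\n",
                x$n_unpredictable))
  }
  cat("\nError summary (absolute errors, actual - predicted):\n")
  print(x$error_summary)
  if (!is.null(x$method_comparison)) {
    cat(sprintf("\nMethod variability comparison: p = %0.4g (%s)\n",
                x$method_comparison$p_value, x$method_comparison$method))
  }
  invisible(x)
}
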