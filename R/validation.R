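#' Complete observed insertions with model-derived linear depths
#'
#' Postoperative imaging yields the *angular* insertion depth of the first
#' contact C1; the corresponding linear depth is obtained by evaluating the
#' chosen cochlear model forward at that angle with the subject's own
#' (A, B). The tip values follow by adding the tip-to-C1 offset to the linear
#' depth and inverting back to an angle.
#'
#' @param data A data frame with columns `A_mm`, `B_mm` (B may be `NA` for
#'   the Escude model), `model` (`"escude"` or `"eca"`), and
#'   `actual_angular_c1_deg`. Other columns are carried through.
#' @param electrode An [electrode_spec()]; FLEX28 by default.
#' @param params A [cochlear_params()] object.
#' @return The input tibble plus `actual_linear_c1_mm`,
#'   `actual_linear_tip_mm`, `actual_angular_tip_deg`. Rows whose conversion
#'   fails (missing geometry, angle outside the model domain) get `NA` with
#'   a warning count.
#' @export
complete_observed <- function(data, electrode = flex28(),
                              params = cochlear_params()) {
  stopifnot(is.data.frame(data))
  need <- c("A_mm", "model", "actual_angular_c1_deg")
  if (!all(need %in% names(data))) {
    stop(sprintf("`data` must have columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  if (!"B_mm" %in% names(data)) data$B_mm <- NA_real_

  res <- purrr::map(seq_len(nrow(data)), function(i) {
    A <- data$A_mm[i]; B <- data$B_mm[i]
    m <- data$model[i]; ang <- data$actual_angular_c1_deg[i]
    if (!is.finite(A) || !is.finite(ang) || (m == "eca" && !is.finite(B))) {
      return(NULL)
    }
    tryCatch({
      lin_c1 <- if (m == "escude") {
        cdl_escude(A, ang, params = params)
      } else {
        cdl_eca(A, B, ang, params = params)
      }
      lin_tip <- lin_c1 + electrode$tip_to_c1_mm
      ang_tip <- if (m == "escude") {
        angle_escude(A, lin_tip, params = params)
      } else {
        angle_eca(A, B, lin_tip, params = params)
      }
      list(lin_c1 = lin_c1, lin_tip = lin_tip, ang_tip = ang_tip)
    }, error = function(e) NULL)
  })
  failed <- vapply(res, is.null, logical(1))
  if (any(failed)) {
    warning(sprintf("%d observed row(s) could not be completed (missing geometry or angle outside the model domain)",
                    sum(failed)), call. = FALSE)
  }
  res[failed] <- list(list(lin_c1 = NA_real_, lin_tip = NA_real_, ang_tip = NA_real_))
  data$actual_linear_c1_mm <- vapply(res, `[[`, numeric(1), "lin_c1")
  data$actual_linear_tip_mm <- vapply(res, `[[`, numeric(1), "lin_tip")
  data$actual_angular_tip_deg <- vapply(res, `[[`, numeric(1), "ang_tip")
  tibble::as_tibble(data)
}

#' Per-subject prediction errors (actual minus predicted)
#'
#' Joins predictions to observed insertions and subtracts, in both the
#' angular and the linear domain, at a named reference point. The sign
#' convention is `actual - predicted`: a *negative* error means the
#' preoperative prediction overestimated the achieved insertion depth.
#'
#' @param predictions Output of [predict_insertion()]: one row per
#'   measurement row per model, with `angular_c1_deg`, `linear_c1_mm`,
#'   `angular_tip_deg`, `linear_tip_mm`.
#' @param observed A data frame of observed insertions with
#'   `actual_angular_c1_deg` (and, after [complete_observed()], the linear
#'   and tip columns). If the actual linear columns are absent they are
#'   derived here via [complete_observed()] using the prediction row's own
#'   geometry and model.
#' @param by Join keys; defaults to the intersection of
#'   `c("subject_id", "observer")` with the columns of `observed`.
#' @param reference `"c1"` (default) or `"tip"`: where the error is taken.
#' @param electrode,params Passed to [complete_observed()] when the linear
#'   actuals must be derived.
#' @return A tibble with the join keys, `model`, the predicted and actual
#'   depth columns at the chosen reference, and `angular_error_deg`,
#'   `linear_error_mm`.
#' @examples
#' meas <- tibble::tibble(subject_id = 1:2, A_mm = c(9.2, 8.7), B_mm = c(6.8, 6.5))
#' pred <- predict_insertion(meas, model = "eca")
#' obs <- tibble::tibble(subject_id = 1:2, actual_angular_c1_deg = c(520, 560))
#' prediction_error(pred, obs)
#' @export
prediction_error <- function(predictions, observed,
                             by = intersect(c("subject_id", "observer"),
                                            names(observed)),
                             reference = c("c1", "tip"),
                             electrode = flex28(),
                             params = cochlear_params()) {
  reference <- match.arg(reference)
  stopifnot(is.data.frame(predictions), is.data.frame(observed))
  if (!"model" %in% names(predictions)) {
    stop("`predictions` must carry a `model` column (see predict_insertion())",
         call. = FALSE)
  }
  if (!"actual_angular_c1_deg" %in% names(observed)) {
    stop("`observed` must have `actual_angular_c1_deg`", call. = FALSE)
  }
  if (length(by) == 0) {
    stop("no join keys shared between predictions and observed", call. = FALSE)
  }
  obs_cols <- intersect(c(by, "actual_angular_c1_deg", "actual_linear_c1_mm",
                          "actual_linear_tip_mm", "actual_angular_tip_deg"),
                        names(observed))
  joined <- dplyr::inner_join(predictions, observed[obs_cols], by = by,
                              relationship = "many-to-many")
  if (nrow(joined) == 0) {
    stop("predictions and observed share no rows under the join keys", call. = FALSE)
  }
  # derive the linear (and tip) actuals through the row's own model/geometry
  if (!all(c("actual_linear_c1_mm", "actual_linear_tip_mm",
             "actual_angular_tip_deg") %in% names(joined))) {
    joined <- complete_observed(joined, electrode = electrode, params = params)
  }
  if (reference == "c1") {
    joined$angular_error_deg <- joined$actual_angular_c1_deg - joined$angular_c1_deg
    joined$linear_error_mm <- joined$actual_linear_c1_mm - joined$linear_c1_mm
  } else {
    joined$angular_error_deg <- joined$actual_angular_tip_deg - joined$angular_tip_deg
    joined$linear_error_mm <- joined$actual_linear_tip_mm - joined$linear_tip_mm
  }
  joined$reference <- reference
  tibble::as_tibble(joined)
}

#' Summarise prediction errors per group
#'
#' Produces the per-model, per-observer error table: mean and sample
#' standard deviation (n - 1 denominator) of the *absolute* angular and
#' linear errors, plus the signed means that show the direction of
#' systematic misprediction (negative = overestimation).
#'
#' The absolute value is taken per record before averaging, so the reported
#' mean is a mean absolute error, not the absolute value of a mean.
#'
#' @param errors Output of [prediction_error()].
#' @param ... Grouping columns (tidy-select); defaults to `model` and, when
#'   present, `observer`.
#' @return A tibble with `n`, `mean_abs_angular_deg`, `sd_abs_angular_deg`,
#'   `mean_abs_linear_mm`, `sd_abs_linear_mm`, `mean_signed_angular_deg`,
#'   `mean_signed_linear_mm` per group. With a single record per group the
#'   sample SD is `NA`.
#' @export
summarize_errors <- function(errors, ...) {
  stopifnot(is.data.frame(errors))
  need <- c("angular_error_deg", "linear_error_mm")
  if (!all(need %in% names(errors))) {
    stop("`errors` must have angular_error_deg and linear_error_mm", call. = FALSE)
  }
  errors <- dplyr::filter(errors,
                          is.finite(.data$angular_error_deg),
                          is.finite(.data$linear_error_mm))
  if (nrow(errors) == 0) {
    stop("no finite error records to summarise", call. = FALSE)
  }
  groups <- rlang::enquos(...)
  if (length(groups) == 0) {
    default <- intersect(c("model", "observer"), names(errors))
    grouped <- dplyr::group_by(errors, dplyr::across(dplyr::all_of(default)))
  } else {
    grouped <- dplyr::group_by(errors, !!!groups)
  }
  out <- dplyr::summarise(
    grouped,
    n = dplyr::n(),
    mean_abs_angular_deg = mean(abs(.data$angular_error_deg)),
    sd_abs_angular_deg = stats::sd(abs(.data$angular_error_deg)),
    mean_abs_linear_mm = mean(abs(.data$linear_error_mm)),
    sd_abs_linear_mm = stats::sd(abs(.data$linear_error_mm)),
    mean_signed_angular_deg = mean(.data$angular_error_deg),
    mean_signed_linear_mm = mean(.data$linear_error_mm),
    .groups = "drop"
  )
  tibble::as_tibble(out)
}

#' Cohort mean angular insertion depth, in degrees and turns
#'
#' Arithmetic mean of an angular-depth column, optionally per group, with
#' the conventional conversion to cochlear turns (360 degrees = one turn).
#'
#' @param data A data frame.
#' @param angle Column of angular depths in degrees (tidy-select; unquoted).
#' @param ... Optional grouping columns (tidy-select).
#' @return A tibble with `n`, `mean_deg`, `turns` per group.
#' @examples
#' d <- tibble::tibble(angle = c(540, 580))
#' cohort_angle_summary(d, angle)  # 560 deg, 1.56 turns
#' @export
cohort_angle_summary <- function(data, angle, ...) {
  stopifnot(is.data.frame(data))
  angle <- rlang::enquo(angle)
  groups <- rlang::enquos(...)
  vals <- dplyr::pull(data, !!angle)
  if (sum(is.finite(vals)) == 0) {
    stop("no finite angles to average", call. = FALSE)
  }
  grouped <- if (length(groups) > 0) dplyr::group_by(data, !!!groups) else data
  out <- dplyr::summarise(
    grouped,
    n = sum(is.finite(!!angle)),
    mean_deg = mean(!!angle, na.rm = TRUE),
    turns = mean(!!angle, na.rm = TRUE) / 360,
    .groups = "drop"
  )
  tibble::as_tibble(out)
}

#' Exceedance of the predicted insertion depth
#'
#' For a set of signed linear prediction errors (actual minus predicted, mm),
#' reports how often the achieved insertion *exceeds* the prediction
#' (error > 0) and how often it exceeds it by more than a stated bound —
#' both as empirical fractions and under a normal model fitted to the signed
#' errors. The fixed one- and two-SD upper tail probabilities of that normal
#' model (about 15.9% and 2.3%) are reported alongside, since surgical
#' planning bounds are conventionally quoted at whole SD multiples.
#'
#' @param linear_errors Numeric vector of signed linear errors, mm.
#' @param bound Exceedance bound in mm; defaults to twice the mean absolute
#'   error of the input.
#' @return A one-row tibble: `n`, `bound_mm`, empirical `frac_exceed_0` and
#'   `frac_exceed_bound`, fitted `mean_signed_mm` and `sd_signed_mm`,
#'   model-based `p_exceed_0_normal` and `p_exceed_bound_normal`, and the
#'   fixed `p_one_sd_tail`, `p_two_sd_tail`.
#' @export
exceedance_report <- function(linear_errors, bound = NULL) {
  linear_errors <- linear_errors[is.finite(linear_errors)]
  if (length(linear_errors) == 0) {
    stop("no finite errors", call. = FALSE)
  }
  if (is.null(bound)) bound <- 2 * mean(abs(linear_errors))
  m <- mean(linear_errors)
  s <- stats::sd(linear_errors)
  tibble::tibble(
    n = length(linear_errors),
    bound_mm = bound,
    frac_exceed_0 = mean(linear_errors > 0),
    frac_exceed_bound = mean(linear_errors > bound),
    mean_signed_mm = m,
    sd_signed_mm = s,
    p_exceed_0_normal = if (is.na(s) || s == 0) as.numeric(m > 0)
                        else stats::pnorm(0, m, s, lower.tail = FALSE),
    p_exceed_bound_normal = if (is.na(s) || s == 0) as.numeric(m > bound)
                            else stats::pnorm(bound, m, s, lower.tail = FALSE),
    p_one_sd_tail = stats::pnorm(1, lower.tail = FALSE),
    p_two_sd_tail = stats::pnorm(2, lower.tail = FALSE)
  )
}
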