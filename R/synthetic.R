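#' Configuration for a synthetic measurement cohort
#'
#' Describes a simulated two-observer, two-observation CT measurement study:
#' the anatomical distribution of the basal-turn measurements (A, B), the
#' per-measurement observer noise, systematic between-observer biases, and
#' the mechanism that makes achieved insertions fall short of the nominal
#' full insertion (the stopper seats against the round-window niche short of
#' the round window itself, costing on the order of a millimetre of depth).
#'
#' Defaults describe the study design the package targets: 46 subjects, two
#' observers measuring twice each. Per-measurement noise SDs are the
#' reported intra-observer *difference* SDs divided by sqrt(2) (a difference
#' of two independent equally noisy measurements has sqrt(2) times the
#' per-measurement SD): A 0.47/0.53 mm and B 0.40/0.44 mm difference SDs for
#' observers 1 and 2.
#'
#' By default the per-measurement errors are independent across observers
#' and observations. Reported inter-observer difference SDs can be smaller
#' than intra-observer ones (0.27 vs 0.47 mm for A in the emulated design),
#' which is only possible if part of each measurement's deviation is shared
#' between the observers within an observation session (for instance, the
#' stored cochlear-view plane both read from). The optional `session_sd_*`
#' parameters inject such a component `u[subject, observation]` common to
#' both observers, with the observer-specific residual shrunk so each total
#' per-measurement SD is unchanged; solving the three difference-SD
#' equations `2*(su^2 + se_o^2) = intra_o^2` and `se_1^2 + se_2^2 = inter^2`
#' for the design's published values gives session SDs of about 0.298 mm
#' for A and 0.066 mm for B. Observer 2 reads A higher by 0.12 mm and B
#' higher by 0.10 mm (the reported inter-observer mean differences,
#' observer 1 minus observer 2).
#'
#' The insertion shortfall is truncated-normal with mean
#' 0.58 mm (the mean underestimation of achieved depth relative to a full
#' insertion) and SD 0.5 mm, keeping essentially all shortfalls inside the
#' 0-2 mm range attributed to stopper seating. The anatomical distribution
#' (A ~ 9.1 +/- 0.4 mm, B ~ 6.8 +/- 0.4 mm, correlation 0.5) and the
#' postoperative angle-reading noise (8 degrees SD) are package assumptions
#' chosen to span the clinical range; no published per-subject distribution
#' backs them (see the vignette).
#'
#' @param n_subjects Number of subjects.
#' @param n_observers,n_observations Observers and repeated observations per
#'   observer (the agreement analyses expect 2 and 2).
#' @param A_mean,A_sd,B_mean,B_sd Anatomical distribution of the true basal
#'   turn diameter and width, mm.
#' @param AB_correlation Correlation between true A and B.
#' @param A_range,B_range Truncation boxes for the true values, mm; draws
#'   outside (or with A <= B) are rejected and redrawn.
#' @param obs_noise_A,obs_noise_B Total per-measurement noise SD per
#'   observer, mm (length `n_observers`), inclusive of the session
#'   component.
#' @param session_sd_A,session_sd_B SD of the observation-session noise
#'   component shared across observers, mm; must not exceed any
#'   per-observer total SD. 0 (the default) means fully independent
#'   measurements.
#' @param inter_observer_bias_A,inter_observer_bias_B Additive bias per
#'   observer, mm (length `n_observers`; default biases observer 2 upward).
#' @param insertion_shortfall_mean,insertion_shortfall_sd Truncated-at-zero
#'   normal shortfall of the achieved linear depth at C1 below the nominal
#'   full insertion, mm.
#' @param actual_angle_noise_sd SD of the postoperative angle-reading noise,
#'   degrees.
#' @param generating_model `"eca"` or `"escude"`: the model treated as the
#'   true geometry-to-angle mapping when simulating achieved insertions.
#' @param electrode An [electrode_spec()].
#' @param params A [cochlear_params()] object.
#' @return A list of class `cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_subjects = 46,
                          n_observers = 2,
                          n_observations = 2,
                          A_mean = 9.1, A_sd = 0.4,
                          B_mean = 6.8, B_sd = 0.4,
                          AB_correlation = 0.5,
                          A_range = c(7, 11),
                          B_range = c(5, 8),
                          obs_noise_A = c(0.47, 0.53) / sqrt(2),
                          obs_noise_B = c(0.40, 0.44) / sqrt(2),
                          session_sd_A = 0,
                          session_sd_B = 0,
                          inter_observer_bias_A = c(0, 0.12),
                          inter_observer_bias_B = c(0, 0.10),
                          insertion_shortfall_mean = 0.58,
                          insertion_shortfall_sd = 0.5,
                          actual_angle_noise_sd = 8,
                          generating_model = c("eca", "escude"),
                          electrode = flex28(),
                          params = cochlear_params()) {
  generating_model <- match.arg(generating_model)
  stopifnot(n_subjects >= 1, n_observers >= 1, n_observations >= 1,
            A_sd >= 0, B_sd >= 0,
            AB_correlation >= -1, AB_correlation <= 1,
            length(obs_noise_A) == n_observers, all(obs_noise_A >= 0),
            length(obs_noise_B) == n_observers, all(obs_noise_B >= 0),
            session_sd_A >= 0, session_sd_B >= 0,
            length(inter_observer_bias_A) == n_observers,
            length(inter_observer_bias_B) == n_observers,
            insertion_shortfall_mean >= 0, insertion_shortfall_sd >= 0,
            actual_angle_noise_sd >= 0,
            inherits(electrode, "electrode_spec"),
            inherits(params, "cochlear_params"))
  if (session_sd_A > min(obs_noise_A) + 1e-12 ||
      session_sd_B > min(obs_noise_B) + 1e-12) {
    stop("session noise SD cannot exceed any observer's total per-measurement SD",
         call. = FALSE)
  }
  structure(
    list(n_subjects = n_subjects, n_observers = n_observers,
         n_observations = n_observations,
         A_mean = A_mean, A_sd = A_sd, B_mean = B_mean, B_sd = B_sd,
         AB_correlation = AB_correlation,
         A_range = A_range, B_range = B_range,
         obs_noise_A = obs_noise_A, obs_noise_B = obs_noise_B,
         session_sd_A = session_sd_A, session_sd_B = session_sd_B,
         inter_observer_bias_A = inter_observer_bias_A,
         inter_observer_bias_B = inter_observer_bias_B,
         insertion_shortfall_mean = insertion_shortfall_mean,
         insertion_shortfall_sd = insertion_shortfall_sd,
         actual_angle_noise_sd = actual_angle_noise_sd,
         generating_model = generating_model,
         electrode = electrode, params = params),
    class = "cohort_config"
  )
}

#' @rdname cohort_config
#' @export
default_study_config <- function() {
  cohort_config()
}

# correlated bivariate normal truncated to the anatomical box with A > B,
# by rejection (keeps the shape of the distribution, unlike clipping)
draw_geometry <- function(n, cfg, max_tries = 1000L) {
  out_A <- numeric(n); out_B <- numeric(n)
  filled <- 0L
  for (try in seq_len(max_tries)) {
    m <- max(2L * (n - filled), 10L)
    z1 <- stats::rnorm(m); z2 <- stats::rnorm(m)
    A <- cfg$A_mean + cfg$A_sd * z1
    B <- cfg$B_mean + cfg$B_sd * (cfg$AB_correlation * z1 +
                                    sqrt(1 - cfg$AB_correlation^2) * z2)
    ok <- A >= cfg$A_range[1] & A <= cfg$A_range[2] &
      B >= cfg$B_range[1] & B <= cfg$B_range[2] & A > B
    take <- min(sum(ok), n - filled)
    if (take > 0) {
      out_A[filled + seq_len(take)] <- A[ok][seq_len(take)]
      out_B[filled + seq_len(take)] <- B[ok][seq_len(take)]
      filled <- filled + take
    }
    if (filled == n) return(list(A = out_A, B = out_B))
  }
  stop("could not draw geometries inside the anatomical box; check the config",
       call. = FALSE)
}

# nonnegative shortfall: normal truncated at zero by rejection
draw_shortfall <- function(n, mean, sd, max_tries = 1000L) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  for (try in seq_len(max_tries)) {
    draw <- stats::rnorm(2L * n, mean, sd)
    out <- c(out, draw[draw >= 0])
    if (length(out) >= n) return(out[seq_len(n)])
  }
  stop("could not draw nonnegative shortfalls; check the config", call. = FALSE)
}

#' Generate a synthetic measurement cohort
#'
#' Simulates a full study under a [cohort_config()]: true cochlear
#' geometries, noisy per-observer measurements of A and B, and achieved
#' (postoperative) insertion depths. The achieved linear depth at C1 is the
#' nominal full insertion minus a nonnegative shortfall; the corresponding
#' angle is obtained by inverting the generating model at the subject's
#' *true* geometry, and each observer reads that angle with additive noise.
#' With every noise SD at zero the measurements equal the truth and the
#' achieved depth is exactly the nominal full insertion.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the cohort is reproducible given (config, seed).
#' @return A list of class `synthetic_cohort`:
#'   \describe{
#'     \item{truth}{per-subject `A_true_mm`, `B_true_mm`, `shortfall_mm`,
#'       `actual_linear_c1_mm`, `true_angular_c1_deg`, `true_angular_tip_deg`.}
#'     \item{measurements}{long tibble: `subject_id`, `observer`,
#'       `observation`, `method`, `A_mm`, `B_mm`.}
#'     \item{observed}{per subject x observer: `actual_angular_c1_deg`,
#'       `actual_angular_tip_deg`.}
#'   }
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 5), seed = 1)
#' coh$truth
#' @export
generate_cohort <- function(config = default_study_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  n <- config$n_subjects

  geom <- draw_geometry(n, config)
  shortfall <- draw_shortfall(n, config$insertion_shortfall_mean,
                              config$insertion_shortfall_sd)
  lin_c1 <- config$electrode$c1_to_stopper_mm - shortfall
  lin_tip <- lin_c1 + config$electrode$tip_to_c1_mm

  ang_at <- function(L) {
    if (config$generating_model == "escude") {
      angle_escude(geom$A, L, params = config$params)
    } else {
      angle_eca(geom$A, geom$B, L, params = config$params)
    }
  }
  true_ang_c1 <- ang_at(lin_c1)
  true_ang_tip <- ang_at(lin_tip)

  truth <- tibble::tibble(
    subject_id = seq_len(n),
    A_true_mm = geom$A, B_true_mm = geom$B,
    shortfall_mm = shortfall,
    actual_linear_c1_mm = lin_c1,
    true_angular_c1_deg = true_ang_c1,
    true_angular_tip_deg = true_ang_tip
  )

  # session (subject x observation) noise shared by the observers, plus an
  # observer-specific residual so that each observer's total per-measurement
  # SD equals obs_noise_* while the inter-observer difference stays tighter
  sessions <- tidyr::expand_grid(subject_id = seq_len(n),
                                 observation = seq_len(config$n_observations))
  sessions$u_A <- stats::rnorm(nrow(sessions), 0, config$session_sd_A)
  sessions$u_B <- stats::rnorm(nrow(sessions), 0, config$session_sd_B)

  resid_sd_A <- sqrt(pmax(config$obs_noise_A^2 - config$session_sd_A^2, 0))
  resid_sd_B <- sqrt(pmax(config$obs_noise_B^2 - config$session_sd_B^2, 0))

  grid <- tidyr::expand_grid(
    subject_id = seq_len(n),
    observer = seq_len(config$n_observers),
    observation = seq_len(config$n_observations)
  )
  measurements <- dplyr::mutate(
    dplyr::left_join(
      dplyr::left_join(grid, truth[c("subject_id", "A_true_mm", "B_true_mm")],
                       by = "subject_id"),
      sessions, by = c("subject_id", "observation")),
    method = "software-3d",
    A_mm = .data$A_true_mm + config$inter_observer_bias_A[.data$observer] +
      .data$u_A + stats::rnorm(dplyr::n(), 0, resid_sd_A[.data$observer]),
    B_mm = .data$B_true_mm + config$inter_observer_bias_B[.data$observer] +
      .data$u_B + stats::rnorm(dplyr::n(), 0, resid_sd_B[.data$observer])
  )
  measurements <- tibble::as_tibble(
    measurements[c("subject_id", "observer", "observation", "method",
                   "A_mm", "B_mm")]
  )

  obs_grid <- tidyr::expand_grid(subject_id = seq_len(n),
                                 observer = seq_len(config$n_observers))
  eps <- stats::rnorm(nrow(obs_grid), 0, config$actual_angle_noise_sd)
  observed <- dplyr::mutate(
    dplyr::left_join(obs_grid,
                     truth[c("subject_id", "true_angular_c1_deg",
                             "true_angular_tip_deg")],
                     by = "subject_id"),
    actual_angular_c1_deg = .data$true_angular_c1_deg + eps,
    actual_angular_tip_deg = .data$true_angular_tip_deg + eps
  )
  observed <- tibble::as_tibble(
    observed[c("subject_id", "observer", "actual_angular_c1_deg",
               "actual_angular_tip_deg")]
  )

  structure(
    list(truth = truth, measurements = measurements, observed = observed,
         config = config, seed = seed),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects, %d observers x %d observations (seed %d)\n",
              x$config$n_subjects, x$config$n_observers,
              x$config$n_observations, x$seed))
  cat(sprintf("  generating model: %s; electrode: %s\n",
              x$config$generating_model, x$config$electrode$name))
  cat(sprintf("  mean achieved linear depth at C1: %0.2f mm (nominal %g mm)\n",
              mean(x$truth$actual_linear_c1_mm),
              x$config$electrode$c1_to_stopper_mm))
  invisible(x)
}

#' Write / read a synthetic cohort as plain CSV
#'
#' `write_cohort()` writes the three cohort tables (measurements, observed,
#' truth) as CSV files named `<stem>_measurements.csv`, `<stem>_observed.csv`
#' and `<stem>_truth.csv`; the measurement table is the same long format
#' consumed by [read_measurements()].
#'
#' @param cohort A [generate_cohort()] result.
#' @param stem Path stem for the three files.
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, stem) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  paths <- paste0(stem, c("_measurements.csv", "_observed.csv", "_truth.csv"))
  readr::write_csv(cohort$measurements, paths[1])
  readr::write_csv(cohort$observed, paths[2])
  readr::write_csv(cohort$truth, paths[3])
  invisible(paths)
}
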