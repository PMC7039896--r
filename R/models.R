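#' Cochlear duct length at the electrode level, logarithmic-spiral model
#'
#' Evaluates the adopted Escude formula for the cochlear duct length along
#' the electrode path, `CDL_i(theta) = p1 * (A - 2*offset) * ln(1 + theta/p2)`,
#' where `A` is the basal-turn diameter measured on the cochlear view and
#' `offset` is the assumed distance between the lateral wall and a
#' lateral-wall electrode array (0.5 mm by default, so 1 mm total is
#' subtracted from the diameter).
#'
#' @param A Basal-turn diameter in mm (vectorised).
#' @param theta_deg Insertion angle in degrees, 0 at the round window,
#'   increasing apically (vectorised).
#' @param offset Lateral-wall-to-electrode distance in mm; defaults to the
#'   value in `params`.
#' @param params A [cochlear_params()] object.
#' @return Cochlear duct length at the electrode level in mm.
#' @seealso [angle_escude()] for the closed-form inversion, [cdl_eca()] for
#'   the two-parameter alternative.
#' @examples
#' cdl_escude(A = 9.0, theta_deg = 360)
#' # full basal turn for a larger cochlea is longer
#' cdl_escude(A = c(8.5, 9.5), theta_deg = 360)
#' @export
cdl_escude <- function(A, theta_deg, offset = params$escude_offset,
                       params = cochlear_params()) {
  check_geometry(A)
  check_theta(theta_deg, params)
  eff <- A - 2 * offset
  if (any(eff <= 0)) {
    bad <- A[eff <= 0][1]
    stop(sprintf("effective diameter A - 2*offset is not positive (A = %g mm, offset = %g mm)",
                 bad, offset), call. = FALSE)
  }
  params$p1 * eff * log1p(theta_deg / params$p2)
}

#' Insertion angle from linear depth, logarithmic-spiral model
#'
#' Closed-form inversion of [cdl_escude()]:
#' `theta = p2 * (exp(L / (p1 * (A - 2*offset))) - 1)`.
#'
#' @inheritParams cdl_escude
#' @param length_mm Linear insertion depth along the electrode path, mm.
#' @return Insertion angle in degrees. Errors if the required angle exceeds
#'   the model's valid domain (`params$theta_max`), i.e. the electrode is
#'   longer than the modelled duct.
#' @examples
#' angle_escude(A = 9.0, length_mm = 26.8)
#' # roundtrip identity
#' angle_escude(A = 9.0, length_mm = cdl_escude(A = 9.0, theta_deg = 360))
#' @export
angle_escude <- function(A, length_mm, offset = params$escude_offset,
                         params = cochlear_params()) {
  check_geometry(A)
  if (any(!is.finite(length_mm)) || any(length_mm < 0)) {
    stop("linear depth must be finite and non-negative", call. = FALSE)
  }
  eff <- A - 2 * offset
  if (any(eff <= 0)) {
    stop(sprintf("effective diameter A - 2*offset is not positive (A = %g mm, offset = %g mm)",
                 A[eff <= 0][1], offset), call. = FALSE)
  }
  theta <- params$p2 * expm1(length_mm / (params$p1 * eff))
  if (any(theta > params$theta_max)) {
    i <- which(theta > params$theta_max)[1]
    stop(sprintf(paste0("length %g mm needs %0.1f degrees, beyond the modelled duct ",
                        "(max %g degrees, %0.2f mm for A = %g mm)"),
                 length_mm[i], theta[i], params$theta_max,
                 cdl_escude(A[i], params$theta_max, offset = offset, params = params),
                 A[i]),
         call. = FALSE)
  }
  theta
}

#' Basal turn length at the electrode level (Elliptic-Circular Approximation)
#'
#' The ECA estimates the length of the first full cochlear turn at the
#' electrode level from both basal-turn measurements:
#' `BTL_i = 1.18*a + 2.69*b - sqrt(0.72*a*b)` with `a = A - 2*offset` and
#' `b = B - 2*offset`. The default offset of 0.35 mm reflects the assumption
#' that a lateral-wall electrode lies 0.35 mm inside the lateral wall.
#'
#' @inheritParams cdl_escude
#' @param B Basal-turn width in mm (perpendicular to A, through the
#'   helicotrema; vectorised).
#' @return Basal turn length at the electrode level, mm.
#' @examples
#' btl_eca(A = 9.2, B = 6.8)
#' @export
btl_eca <- function(A, B, offset = params$eca_offset,
                    params = cochlear_params()) {
  check_geometry(A, B)
  a <- A - 2 * offset
  b <- B - 2 * offset
  if (any(a < 0) || any(b < 0)) {
    i <- which(a < 0 | b < 0)[1]
    stop(sprintf("offset-corrected measurement is negative (A = %g, B = %g, offset = %g mm)",
                 A[i], B[i], offset), call. = FALSE)
  }
  1.18 * a + 2.69 * b - sqrt(0.72 * a * b)
}

#' Basal turn length percentage at an insertion angle
#'
#' The ECA maps an insertion angle to a percentage of the basal turn length
#' through a cubic fitted on micro-CT reconstructions:
#' `p_BTL(theta) = 8.3e-8*theta^3 - 2.4e-4*theta^2 + 0.34*theta + 3.7`
#' (in percent). The cubic is strictly increasing on the tabulated domain
#' 0-900 degrees. Note the intercept: `pbtl(0) = 3.7`, not 0 — a fit
#' artifact of the source polynomial, which this package preserves rather
#' than renormalises (see the package vignette).
#'
#' @inheritParams cdl_escude
#' @return Percentage of the basal turn length (vectorised over `theta_deg`).
#' @examples
#' pbtl(0)     # 3.7, the fit intercept
#' pbtl(360)   # about one full turn
#' @export
pbtl <- function(theta_deg, params = cochlear_params()) {
  check_theta(theta_deg, params)
  cf <- params$pbtl_coeffs
  cf[1] + cf[2] * theta_deg + cf[3] * theta_deg^2 + cf[4] * theta_deg^3
}

#' Cochlear duct length at the electrode level, Elliptic-Circular Approximation
#'
#' `CDL_i(theta) = p_BTL(theta)/100 * BTL_i`: the percentage polynomial
#' [pbtl()] applied to the basal turn length [btl_eca()]. The division by 100
#' converts the tabulated percentage to a fraction.
#'
#' @inheritParams btl_eca
#' @param theta_deg Insertion angle in degrees (vectorised).
#' @return Cochlear duct length at the electrode level, mm.
#' @examples
#' cdl_eca(A = 9.2, B = 6.8, theta_deg = 360)
#' @export
cdl_eca <- function(A, B, theta_deg, offset = params$eca_offset,
                    params = cochlear_params()) {
  (pbtl(theta_deg, params) / 100) * btl_eca(A, B, offset = offset, params = params)
}

#' Insertion angle from linear depth, Elliptic-Circular Approximation
#'
#' Numerical inversion of [cdl_eca()] by bracketed root-finding on the valid
#' angular domain `[0, theta_max]`. The objective is strictly monotone (a
#' positive constant times an increasing cubic), so bisection-grade root
#' finding is robust; the solver is run to an angular tolerance that
#' reproduces the requested length to well under 1e-6 mm.
#'
#' Because `pbtl(0) = 3.7` percent, the ECA length does not vanish at the
#' round window: lengths below `cdl_eca(A, B, 0)` have no angle in the valid
#' domain and raise an error rather than being clipped to 0.
#'
#' @inheritParams cdl_eca
#' @param length_mm Linear insertion depth along the electrode path, mm
#'   (vectorised together with `A` and `B`).
#' @return Insertion angle in degrees.
#' @examples
#' angle_eca(A = 9.2, B = 6.8, length_mm = 26.8)
#' @export
angle_eca <- function(A, B, length_mm, offset = params$eca_offset,
                      params = cochlear_params()) {
  check_geometry(A, B)
  if (any(!is.finite(length_mm)) || any(length_mm < 0)) {
    stop("linear depth must be finite and non-negative", call. = FALSE)
  }
  n <- max(length(A), length(B), length(length_mm))
  A <- rep_len(A, n); B <- rep_len(B, n); length_mm <- rep_len(length_mm, n)
  vapply(seq_len(n), function(i) {
    btl <- btl_eca(A[i], B[i], offset = offset, params = params)
    lo <- (pbtl(0, params) / 100) * btl
    hi <- (pbtl(params$theta_max, params) / 100) * btl
    L <- length_mm[i]
    if (L > hi) {
      stop(sprintf(paste0("length %g mm exceeds the modelled duct ",
                          "(max %0.2f mm at %g degrees for A = %g, B = %g mm)"),
                   L, hi, params$theta_max, A[i], B[i]), call. = FALSE)
    }
    if (L < lo) {
      stop(sprintf(paste0("length %g mm is below the model's value at 0 degrees ",
                          "(%0.3f mm): the percentage polynomial has a nonzero ",
                          "intercept, so depths shallower than this are outside ",
                          "the model's domain"), L, lo), call. = FALSE)
    }
    stats::uniroot(function(th) cdl_eca(A[i], B[i], th, offset = offset, params = params) - L,
                   interval = c(0, params$theta_max),
                   tol = 1e-10, maxiter = 1000L)$root
  }, numeric(1))
}

#' Tabulate the basal-turn-length percentage over 1-900 degrees
#'
#' Evaluates [pbtl()] on the full valid grid of insertion angles in 1-degree
#' steps, the tabulated form in which the percentage mapping is normally
#' published. Values are emitted at full floating precision, unrounded.
#'
#' @param params A [cochlear_params()] object.
#' @param file Optional path; if given, the table is also written as a
#'   two-column CSV (`theta_deg`, `pbtl_percent`) with a header row.
#' @return A tibble with 900 rows and columns `theta_deg`, `pbtl_percent`.
#' @examples
#' tab <- pbtl_table()
#' nrow(tab)
#' @export
pbtl_table <- function(params = cochlear_params(), file = NULL) {
  tab <- tibble::tibble(
    theta_deg = seq_len(params$theta_max),
    pbtl_percent = pbtl(seq_len(params$theta_max), params)
  )
  if (!is.null(file)) {
    readr::write_csv(tab, file)
  }
  tab
}
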