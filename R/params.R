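#' Analytical cochlear model parameters
#'
#' Bundles the constants of the two analytical cochlear models so that every
#' model function draws them from one place. The logarithmic-spiral (adopted
#' Escude) model uses the scale constant `p1` and angle constant `p2`; the
#' Elliptic-Circular Approximation (ECA) uses the cubic percentage polynomial
#' `pbtl_coeffs`. Each model assumes the electrode runs at a fixed distance
#' inside the bony lateral wall, so a per-model offset is subtracted from the
#' basal-turn measurements: 0.5 mm for the Escude model and 0.35 mm for the
#' ECA. Exposing the offsets as parameters makes sensitivity variants (for
#' example, running the Escude model with the ECA's 0.35 mm offset) a
#' parameter change rather than a code change.
#'
#' @param p1 Escude scale constant (applied to the offset-corrected diameter,
#'   per mm). Default 2.62.
#' @param p2 Escude angle constant in degrees. Default 235.
#' @param escude_offset Lateral-wall-to-electrode distance used by the Escude
#'   model, mm. Default 0.5.
#' @param eca_offset Lateral-wall-to-electrode distance used by the ECA, mm.
#'   Default 0.35.
#' @param pbtl_coeffs Coefficients of the basal-turn-length percentage cubic,
#'   in increasing powers of the angle (intercept first). The percentage at
#'   angle theta (degrees) is
#'   `c0 + c1*theta + c2*theta^2 + c3*theta^3`.
#' @param theta_max Upper end of the valid angular domain, degrees. The
#'   percentage polynomial is a fit tabulated over 1-900 degrees; requests
#'   outside `[0, theta_max]` raise an error rather than extrapolate.
#'
#' @return A list of class `cochlear_params`.
#' @examples
#' p <- cochlear_params()
#' p$p1
#' # sensitivity variant: Escude model with the ECA offset
#' cochlear_params(escude_offset = 0.35)
#' @export
cochlear_params <- function(p1 = 2.62,
                            p2 = 235,
                            escude_offset = 0.5,
                            eca_offset = 0.35,
                            pbtl_coeffs = c(3.7, 3.4e-1, -2.4e-4, 8.3e-8),
                            theta_max = 900) {
  stopifnot(p1 > 0, p2 > 0, escude_offset >= 0, eca_offset >= 0,
            length(pbtl_coeffs) == 4, theta_max > 0)
  structure(
    list(p1 = p1, p2 = p2,
         escude_offset = escude_offset, eca_offset = eca_offset,
         pbtl_coeffs = pbtl_coeffs, theta_max = theta_max),
    class = "cochlear_params"
  )
}

#' @export
print.cochlear_params <- function(x, ...) {
  cat("Cochlear model parameters\n")
  cat(sprintf("  Escude:  p1 = %g, p2 = %g deg, lateral-wall offset = %g mm\n",
              x$p1, x$p2, x$escude_offset))
  cat(sprintf("  ECA:     lateral-wall offset = %g mm\n", x$eca_offset))
  cat(sprintf("  p_BTL(theta) = %g %+g*theta %+g*theta^2 %+g*theta^3  [percent]\n",
              x$pbtl_coeffs[1], x$pbtl_coeffs[2], x$pbtl_coeffs[3], x$pbtl_coeffs[4]))
  cat(sprintf("  valid angular domain: [0, %g] deg\n", x$theta_max))
  invisible(x)
}

# shared argument checks -------------------------------------------------

check_theta <- function(theta_deg, params, allow_zero = TRUE) {
  if (any(!is.finite(theta_deg))) {
    stop("insertion angle must be finite", call. = FALSE)
  }
  if (any(theta_deg < 0) || any(theta_deg > params$theta_max)) {
    stop(sprintf("insertion angle must lie in [0, %g] degrees; got %s",
                 params$theta_max,
                 paste(signif(theta_deg[theta_deg < 0 | theta_deg > params$theta_max], 6),
                       collapse = ", ")),
         call. = FALSE)
  }
  invisible(theta_deg)
}

check_geometry <- function(A, B = NULL, warn_AB = TRUE) {
  if (any(!is.finite(A)) || any(A <= 0)) {
    stop("basal-turn diameter A must be finite and positive", call. = FALSE)
  }
  if (!is.null(B)) {
    if (any(!is.finite(B)) || any(B <= 0)) {
      stop("basal-turn width B must be finite and positive", call. = FALSE)
    }
    # A is the long axis by definition; measurement noise can flip the order
    # on real data, so warn rather than refuse
    if (warn_AB && any(A <= B)) {
      warning(sprintf("%d measurement(s) have A <= B; A should be the longer axis",
                      sum(A <= B)), call. = FALSE)
    }
  }
  invisible(NULL)
}
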