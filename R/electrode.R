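#' Electrode array geometry
#'
#' Describes a lateral-wall electrode array by the three lengths the
#' prediction needs: total length from the silicone tip to the stopper, the
#' distance from the first (most apical) contact C1 to the stopper, and the
#' tip-to-C1 distance. The three are redundant (`total = c1_to_stopper +
#' tip_to_c1`), so the constructor takes the first two and derives the third.
#'
#' C1 is the reference point for postoperative validation because the bare
#' silicone tip is not visible on postoperative CT; predictions are made at
#' both C1 and the tip.
#'
#' @param name Label for the array.
#' @param total_length_mm Tip-to-stopper length, mm.
#' @param c1_to_stopper_mm First-contact-to-stopper length, mm.
#' @return A list of class `electrode_spec` with fields `name`,
#'   `total_length_mm`, `c1_to_stopper_mm`, `tip_to_c1_mm`.
#' @seealso [flex28()] for the built-in FLEX28 geometry.
#' @examples
#' electrode_spec("custom", total_length_mm = 20.9, c1_to_stopper_mm = 19.7)
#' @export
electrode_spec <- function(name, total_length_mm, c1_to_stopper_mm) {
  stopifnot(is.character(name), length(name) == 1,
            is.numeric(total_length_mm), total_length_mm > 0,
            is.numeric(c1_to_stopper_mm), c1_to_stopper_mm > 0)
  if (c1_to_stopper_mm >= total_length_mm) {
    stop("c1_to_stopper_mm must be smaller than total_length_mm", call. = FALSE)
  }
  structure(
    list(name = name,
         total_length_mm = total_length_mm,
         c1_to_stopper_mm = c1_to_stopper_mm,
         tip_to_c1_mm = total_length_mm - c1_to_stopper_mm),
    class = "electrode_spec"
  )
}

#' @export
print.electrode_spec <- function(x, ...) {
  cat(sprintf("Electrode array: %s\n", x$name))
  cat(sprintf("  tip to stopper: %g mm\n", x$total_length_mm))
  cat(sprintf("  C1 to stopper:  %g mm\n", x$c1_to_stopper_mm))
  cat(sprintf("  tip to C1:      %g mm\n", x$tip_to_c1_mm))
  invisible(x)
}

#' FLEX28 electrode array geometry
#'
#' The flexible 28 mm lateral-wall array: 28 mm from the silicone tip to the
#' stopper, with the first contact C1 located 26.8 mm from the stopper
#' (1.2 mm from the tip). The linear insertion depth at C1 under an assumed
#' full insertion is therefore 26.8 mm.
#'
#' @return An [electrode_spec()] object.
#' @examples
#' flex28()
#' @export
flex28 <- function() {
  electrode_spec("FLEX28", total_length_mm = 28.0, c1_to_stopper_mm = 26.8)
}

#' Read an electrode spec from a key-value config file
#'
#' Reads a small plain-text file of `key: value` lines with keys `name`,
#' `total_length_mm`, `c1_to_stopper_mm` (order free, `#` comments allowed).
#'
#' @param path Path to the config file.
#' @return An [electrode_spec()] object.
#' @export
read_electrode_spec <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) {
    stop(sprintf("malformed line(s) in %s: %s", path,
                 paste(lines[bad], collapse = "; ")), call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  need <- c("name", "total_length_mm", "c1_to_stopper_mm")
  if (!all(need %in% keys)) {
    stop(sprintf("missing key(s) in %s: %s", path,
                 paste(setdiff(need, keys), collapse = ", ")), call. = FALSE)
  }
  electrode_spec(vals[["name"]],
                 as.numeric(vals[["total_length_mm"]]),
                 as.numeric(vals[["c1_to_stopper_mm"]]))
}

#' Linear depth at the silicone tip from the depth at C1
#'
#' The tip sits `tip_to_c1_mm` (1.2 mm on the FLEX28) apical of the first
#' contact, so the linear insertion depth at the tip is the depth at C1 plus
#' that offset.
#'
#' @param linear_c1_mm Linear insertion depth at C1, mm (vectorised).
#' @param electrode An [electrode_spec()]; FLEX28 by default.
#' @return Linear insertion depth at the tip, mm.
#' @examples
#' actual_tip_from_c1(26.8)  # 28 mm: full insertion
#' @export
actual_tip_from_c1 <- function(linear_c1_mm, electrode = flex28()) {
  stopifnot(inherits(electrode, "electrode_spec"))
  if (any(!is.finite(linear_c1_mm)) || any(linear_c1_mm < 0)) {
    stop("linear depth at C1 must be finite and non-negative", call. = FALSE)
  }
  linear_c1_mm + electrode$tip_to_c1_mm
}

# single-geometry prediction; errors propagate from the inversions
predict_one <- function(A, B, model, electrode, params) {
  lin_c1 <- electrode$c1_to_stopper_mm
  lin_tip <- electrode$total_length_mm
  if (model == "escude") {
    ang_c1 <- angle_escude(A, lin_c1, params = params)
    ang_tip <- angle_escude(A, lin_tip, params = params)
  } else {
    ang_c1 <- angle_eca(A, B, lin_c1, params = params)
    ang_tip <- angle_eca(A, B, lin_tip, params = params)
  }
  list(linear_c1_mm = lin_c1, angular_c1_deg = ang_c1,
       linear_tip_mm = lin_tip, angular_tip_deg = ang_tip)
}

#' Predict insertion depth at C1 and at the tip for measured cochleae
#'
#' For each measurement row, projects the electrode array onto the estimated
#' cochlear duct under one or both analytical models, assuming a full
#' insertion with the stopper at the round window. The predicted linear depth
#' at C1 is the array's C1-to-stopper length; the corresponding angular depth
#' is the model inversion of that length for the row's (A, B); tip values use
#' the full tip-to-stopper length.
#'
#' Rows whose geometry cannot accommodate the full array within the model's
#' valid angular domain (or, for the ECA, rows with missing B) yield `NA`
#' predictions and a warning with the count; they are never silently dropped.
#'
#' @param data A data frame with numeric columns `A_mm` and (for the ECA)
#'   `B_mm`; all other columns are carried through.
#' @param model `"escude"`, `"eca"`, or `"both"` (default): which model(s) to
#'   run. With `"both"` the output is stacked long with one row per
#'   measurement row per model.
#' @param electrode An [electrode_spec()]; FLEX28 by default.
#' @param params A [cochlear_params()] object (use it to change the
#'   lateral-wall offsets).
#' @return A tibble: the input columns plus `model`, `linear_c1_mm`,
#'   `angular_c1_deg`, `linear_tip_mm`, `angular_tip_deg`.
#' @examples
#' meas <- tibble::tibble(subject_id = 1:2, A_mm = c(9.2, 8.7), B_mm = c(6.8, 6.5))
#' predict_insertion(meas, model = "both")
#' @export
predict_insertion <- function(data, model = c("both", "escude", "eca"),
                              electrode = flex28(),
                              params = cochlear_params()) {
  model <- match.arg(model)
  stopifnot(is.data.frame(data), inherits(electrode, "electrode_spec"))
  if (!"A_mm" %in% names(data)) {
    stop("`data` must have a numeric column `A_mm`", call. = FALSE)
  }
  models <- if (model == "both") c("escude", "eca") else model
  if ("eca" %in% models && !"B_mm" %in% names(data)) {
    if (identical(models, "eca")) {
      stop("ECA predictions need a `B_mm` column", call. = FALSE)
    }
    data$B_mm <- NA_real_
  }

  out <- purrr::map_dfr(models, function(m) {
    res <- purrr::map(seq_len(nrow(data)), function(i) {
      A <- data$A_mm[i]
      B <- if ("B_mm" %in% names(data)) data$B_mm[i] else NA_real_
      if (!is.finite(A) || (m == "eca" && !is.finite(B))) {
        return(NULL)
      }
      tryCatch(predict_one(A, B, m, electrode, params),
               error = function(e) NULL)
    })
    failed <- vapply(res, is.null, logical(1))
    if (any(failed)) {
      warning(sprintf("%d row(s) not predictable under the %s model (missing or out-of-range geometry); predictions set to NA",
                      sum(failed), m), call. = FALSE)
    }
    res[failed] <- list(list(linear_c1_mm = NA_real_, angular_c1_deg = NA_real_,
                             linear_tip_mm = NA_real_, angular_tip_deg = NA_real_))
    dplyr::bind_cols(
      data,
      tibble::tibble(
        model = m,
        linear_c1_mm = vapply(res, `[[`, numeric(1), "linear_c1_mm"),
        angular_c1_deg = vapply(res, `[[`, numeric(1), "angular_c1_deg"),
        linear_tip_mm = vapply(res, `[[`, numeric(1), "linear_tip_mm"),
        angular_tip_deg = vapply(res, `[[`, numeric(1), "angular_tip_deg")
      )
    )
  })
  tibble::as_tibble(out)
}
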