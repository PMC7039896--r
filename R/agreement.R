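#' Bland-Altman agreement analysis
#'
#' Agreement between two measurements of the same quantity (two observations
#' of one observer, or two observers' observations) via per-pair differences
#' against per-pair averages. Limits of agreement are placed at the mean
#' difference plus/minus exactly twice the sample SD of the differences
#' (2*SD, not 1.96*SD).
#'
#' @param data A data frame with one row per paired measurement.
#' @param value_1,value_2 Columns holding the two measurements (unquoted).
#' @return An object of class `bland_altman`: use [glance()] for the
#'   one-row statistics (`n`, `mean_diff`, `sd_diff`, `loa_low`, `loa_high`),
#'   [tidy()] for the per-pair averages and differences, and
#'   [ggplot2::autoplot()] for the standard plot.
#' @examples
#' d <- tibble::tibble(first = c(9.1, 9.4, 8.8), second = c(9.0, 9.5, 8.9))
#' ba <- bland_altman(d, first, second)
#' glance(ba)
#' @export
bland_altman <- function(data, value_1, value_2) {
  stopifnot(is.data.frame(data))
  v1 <- dplyr::pull(data, {{ value_1 }})
  v2 <- dplyr::pull(data, {{ value_2 }})
  keep <- is.finite(v1) & is.finite(v2)
  v1 <- v1[keep]; v2 <- v2[keep]
  if (length(v1) < 2) {
    stop("Bland-Altman needs at least 2 complete pairs", call. = FALSE)
  }
  diffs <- v1 - v2
  avgs <- (v1 + v2) / 2
  mean_diff <- mean(diffs)
  sd_diff <- stats::sd(diffs)
  structure(
    list(
      pairs = tibble::tibble(average = avgs, difference = diffs),
      n = length(diffs),
      mean_diff = mean_diff,
      sd_diff = sd_diff,
      loa_low = mean_diff - 2 * sd_diff,
      loa_high = mean_diff + 2 * sd_diff
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (n = %d pairs)\n", x$n))
  cat(sprintf("  mean difference: %0.4g\n", x$mean_diff))
  cat(sprintf("  SD of differences: %0.4g\n", x$sd_diff))
  cat(sprintf("  limits of agreement (mean +/- 2 SD): [%0.4g, %0.4g]\n",
              x$loa_low, x$loa_high))
  invisible(x)
}

#' @rdname bland_altman
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @method tidy bland_altman
#' @export
tidy.bland_altman <- function(x, ...) {
  x$pairs
}

#' @rdname bland_altman
#' @method glance bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(n = x$n, mean_diff = x$mean_diff, sd_diff = x$sd_diff,
                 loa_low = x$loa_low, loa_high = x$loa_high)
}

#' Qualitative interpretation of an agreement coefficient
#'
#' Maps a reliability/agreement coefficient to the conventional
#' Landis-Koch bands: below 0 "poor", up to 0.20 "slight", 0.21-0.40
#' "fair", 0.41-0.60 "moderate", 0.61-0.80 "substantial", above 0.80
#' "almost perfect".
#'
#' @param value Numeric coefficient(s), at most 1.
#' @return Character vector of labels.
#' @examples
#' agreement_label(c(0.58, 0.74, 0.90))
#' @export
agreement_label <- function(value) {
  if (any(value > 1 + 1e-12, na.rm = TRUE)) {
    stop("agreement coefficients cannot exceed 1", call. = FALSE)
  }
  cut(value,
      breaks = c(-Inf, 0, 0.20, 0.40, 0.60, 0.80, 1),
      labels = c("poor", "slight", "fair", "moderate", "substantial",
                 "almost perfect"),
      right = TRUE) |> as.character()
}

#' Intraclass correlation for observer agreement
#'
#' Two-way random-effects, absolute-agreement intraclass correlation from
#' the mean squares of the subjects-by-raters ANOVA. The default form is
#' single measures (commonly written ICC(2,1)): observers are treated as a
#' random sample of raters and the clinical question is absolute agreement
#' of a single measurement. Average-measures (ICC(2,k)) is available via
#' `form`.
#'
#' Writing `MSR`, `MSC`, `MSE` for the subject, rater and residual mean
#' squares of the two-way ANOVA with `n` subjects and `k` raters:
#' \deqn{ICC(2,1) = \frac{MSR - MSE}{MSR + (k-1) MSE + \frac{k}{n}(MSC - MSE)}}
#' \deqn{ICC(2,k) = \frac{MSR - MSE}{MSR + \frac{MSC - MSE}{n}}}
#'
#' @param data A data frame, one row per subject.
#' @param ... Two or more rating columns (tidy-select), one per
#'   rater/observation.
#' @param form `"single"` (default) or `"average"` measures.
#' @return An object of class `icc_agreement` with the coefficient, its
#'   qualitative [agreement_label()], the form, and the ANOVA mean squares;
#'   [glance()] returns them as a one-row tibble.
#' @examples
#' d <- tibble::tibble(r1 = c(9.1, 8.6, 9.8, 9.0, 8.2),
#'                     r2 = c(9.0, 8.8, 9.7, 9.2, 8.4))
#' icc_agreement(d, r1, r2)
#' @export
icc_agreement <- function(data, ..., form = c("single", "average")) {
  form <- match.arg(form)
  stopifnot(is.data.frame(data))
  ratings <- dplyr::select(data, ...)
  if (ncol(ratings) < 2) {
    stop("need at least two rating columns", call. = FALSE)
  }
  ratings <- as.matrix(ratings)
  if (!is.numeric(ratings)) stop("rating columns must be numeric", call. = FALSE)
  ratings <- ratings[stats::complete.cases(ratings), , drop = FALSE]
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 3) stop("ICC needs at least 3 complete subjects", call. = FALSE)
  if (stats::var(as.vector(ratings)) == 0) {
    stop("all ratings identical: total variance is zero, ICC undefined",
         call. = FALSE)
  }

  long <- data.frame(
    y = as.vector(ratings),
    subject = factor(rep(seq_len(n), times = k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  # only the mean squares are used; anova()'s F-tests can warn on a perfect
  # fit (identical raters), which is irrelevant here
  ms <- suppressWarnings(
    stats::anova(stats::aov(y ~ subject + rater, data = long))[["Mean Sq"]]
  )
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]

  value <- if (form == "single") {
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  } else {
    (msr - mse) / (msr + (msc - mse) / n)
  }
  structure(
    list(value = value, label = agreement_label(value),
         form = form, n = n, k = k,
         ms_subjects = msr, ms_raters = msc, ms_error = mse),
    class = "icc_agreement"
  )
}

#' @export
print.icc_agreement <- function(x, ...) {
  cat(sprintf("ICC (two-way random effects, absolute agreement, %s measures)\n",
              x$form))
  cat(sprintf("  n = %d subjects, k = %d raters\n", x$n, x$k))
  cat(sprintf("  ICC = %0.3f (%s agreement)\n", x$value, x$label))
  invisible(x)
}

#' @rdname icc_agreement
#' @param x An `icc_agreement` object.
#' @method glance icc_agreement
#' @export
glance.icc_agreement <- function(x, ...) {
  tibble::tibble(icc = x$value, label = x$label, form = x$form,
                 n = x$n, k = x$k,
                 ms_subjects = x$ms_subjects, ms_raters = x$ms_raters,
                 ms_error = x$ms_error)
}

# two-sided signed-rank p from an Edgeworth-refined normal approximation on
# the midrank moments: V is a sum of independent rank*Bernoulli(1/2) terms,
# so its skewness is 0 and its fourth cumulant is -sum(r^4)/8; the
# fourth-cumulant term plus a continuity correction keeps the approximation
# within a few thousandths of the exact distribution from about n = 8 up
signed_rank_p_approx <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- sum(r) / 2
  s2 <- sum(r^2) / 4
  k4 <- -sum(r^4) / 8
  cdf <- function(q) {
    z <- (q + 0.5 - mu) / sqrt(s2)
    stats::pnorm(z) - stats::dnorm(z) * (k4 / (24 * s2^2)) * (z^3 - 3 * z)
  }
  p <- if (v > mu) 2 * (1 - cdf(v - 1)) else 2 * cdf(v)
  list(statistic = v, p_value = min(max(p, 0), 1))
}

#' Paired comparison of per-subject disagreement between two methods
#'
#' Tests whether one prediction method yields systematically smaller
#' observer disagreement than another: the inputs are per-subject absolute
#' disagreement values (for example, |observer 1 - observer 2| of the
#' predicted angle) under each method, paired by subject, compared with a
#' two-sided Wilcoxon signed-rank test. By default the exact distribution is
#' used for 25 or fewer informative (non-zero, untied) pairs; larger or tied
#' samples use a fourth-cumulant Edgeworth refinement of the normal
#' approximation with continuity correction, accurate to a few thousandths
#' in p from about eight pairs upward.
#'
#' @param abs_diff_1,abs_diff_2 Equal-length numeric vectors of per-subject
#'   disagreement under methods 1 and 2, paired by position.
#' @param method `"auto"` (default), `"exact"`, or `"approximation"`.
#' @return A one-row tibble: `n`, `statistic` (V, the positive-rank sum),
#'   `p_value`, `method`.
#' @examples
#' set.seed(1)
#' d1 <- abs(rnorm(20, 0, 40)); d2 <- d1 * 0.5
#' compare_method_variability(d1, d2)
#' @export
compare_method_variability <- function(abs_diff_1, abs_diff_2,
                                       method = c("auto", "exact",
                                                  "approximation")) {
  method <- match.arg(method)
  if (length(abs_diff_1) != length(abs_diff_2)) {
    stop("inputs must be paired: equal lengths required", call. = FALSE)
  }
  keep <- is.finite(abs_diff_1) & is.finite(abs_diff_2)
  x <- abs_diff_1[keep]; y <- abs_diff_2[keep]
  if (length(x) < 5) {
    stop("need at least 5 complete pairs", call. = FALSE)
  }
  d <- x - y
  if (all(d == 0)) {
    warning("all paired differences are zero; the methods are indistinguishable",
            call. = FALSE)
    return(tibble::tibble(n = length(d), statistic = NA_real_, p_value = 1,
                          method = "Wilcoxon signed rank (degenerate)"))
  }
  d_nz <- d[d != 0]
  ties <- anyDuplicated(abs(d_nz)) > 0
  if (method == "auto") {
    method <- if (length(d_nz) <= 25 && !ties) "exact" else "approximation"
  }
  if (method == "exact") {
    if (ties) {
      stop("exact signed-rank p is unavailable with tied |differences|; use the approximation",
           call. = FALSE)
    }
    wt <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
    tibble::tibble(n = length(d), statistic = unname(wt$statistic),
                   p_value = wt$p.value,
                   method = "Wilcoxon signed rank, exact")
  } else {
    res <- signed_rank_p_approx(d)
    tibble::tibble(n = length(d), statistic = res$statistic,
                   p_value = res$p_value,
                   method = "Wilcoxon signed rank, Edgeworth-corrected normal approximation")
  }
}
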