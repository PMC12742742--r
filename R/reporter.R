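# Promoter-fusion reporter quantification: relative fluorescence rF,
# lacZ-normalized expression ratios, and the slope-test responsiveness
# criterion on porin-ratio flow data.

#' Assemble a reporter time course
#'
#' @param time sampling times (h), strictly increasing.
#' @param f_sample,f_blank fluorescence of the cell sample and the medium
#'   blank (a.u.).
#' @param od_sample,od_blank optical density (OD595) of sample and blank.
#' @return data.frame of class `reporter_series`.
#' @export
reporter_series <- function(time, f_sample, f_blank, od_sample, od_blank) {
  n <- length(time)
  if (any(lengths(list(f_sample, f_blank, od_sample, od_blank)) != n))
    stop_config("all reporter series columns must share the same length")
  if (n > 1L && any(diff(time) <= 0))
    stop_config("times must be strictly increasing")
  structure(data.frame(time = time, f_sample = f_sample, f_blank = f_blank,
                       od_sample = od_sample, od_blank = od_blank),
            class = c("reporter_series", "data.frame"))
}

#' Relative fluorescence rF
#'
#' Background-subtracted fluorescence divided by background-subtracted
#' optical density at each time point:
#' `rF(t) = (F_s - F_b) / (OD_s - OD_b)`.
#'
#' @param series a [reporter_series()].
#' @param t optional time(s) at which to evaluate; default all time points.
#' @return numeric vector of rF values (named by time).
#' @export
relative_fluorescence <- function(series, t = NULL) {
  s <- series
  if (!is.null(t)) {
    idx <- match(t, s$time)
    if (anyNA(idx)) stop_config("requested time(s) not in the series")
    s <- s[idx, , drop = FALSE]
  }
  dod <- s$od_sample - s$od_blank
  if (any(dod <= 0))
    stop_config("OD_sample - OD_blank must be > 0 at every evaluated time point")
  setNames((s$f_sample - s$f_blank) / dod, s$time)
}

#' Expression normalized to the lacZ control fusion
#'
#' Divides the rF of the porin-promoter fusion by the rF of the lacZ control
#' fusion measured in the same strain (conventionally at the 10 h endpoint).
#'
#' @param target_rf rF of the promoter of interest.
#' @param lacz_rf rF of the lacZ control (> 0).
#' @return the expression ratio.
#' @export
normalized_expression <- function(target_rf, lacz_rf) {
  if (any(!is.finite(lacz_rf)) || any(lacz_rf <= 0))
    stop_config("lacZ rF must be a positive finite value")
  target_rf / lacz_rf
}

#' Dose-response slope test on the porin expression ratio
#'
#' Fits an ordinary least-squares line of `log10(FITC_C / FITC_F)` against a
#' numeric stressor dose and tests the slope against zero with a two-sided
#' t-test (n - 2 df). The sensor is called responsive when the slope differs
#' significantly from zero.
#'
#' @param fitc_c,fitc_f mean FITC fluorescence of the ompC and ompF reporter
#'   strains at each dose (> 0).
#' @param doses numeric stressor doses; at least 3 distinct values.
#' @param alpha significance level for the responsiveness call (default 0.05).
#' @return list with `slope`, `intercept`, `p_value`, `responsive`, `n`.
#' @export
ratio_response_test <- function(fitc_c, fitc_f, doses, alpha = 0.05) {
  if (length(unique(doses)) < 3L)
    stop_config("at least 3 distinct doses are required for the slope test")
  if (any(fitc_c <= 0) || any(fitc_f <= 0))
    stop_config("FITC intensities must be positive")
  if (length(fitc_c) != length(doses) || length(fitc_f) != length(doses))
    stop_config("fitc_c, fitc_f and doses must have equal length")
  y <- log10(fitc_c / fitc_f)
  fit <- lm(y ~ doses)
  slope <- unname(coef(fit)[2L])
  n <- length(y)
  rss <- sum(resid(fit)^2)
  sxx <- sum((doses - mean(doses))^2)
  se <- sqrt(rss / (n - 2L) / sxx)
  if (se == 0) {
    # exact line: zero slope is a flat ratio, nonzero slope is unambiguous
    p <- if (slope == 0) 1 else 0
  } else {
    p <- 2 * pt(abs(slope / se), df = n - 2L, lower.tail = FALSE)
  }
  list(slope = slope, intercept = unname(coef(fit)[1L]),
       p_value = p, responsive = p < alpha, n = n)
}
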