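#' Fit post-anthesis SPAD decline and the chlorophyll degradation rate
#'
#' Fits the quadratic `SPAD(t) = a t^2 + b t + c` to flag-leaf SPAD
#' readings against days post-anthesis (typically measured at 7, 14, 21
#' and 28 d). The chlorophyll degradation rate is taken as `CDR = |2a|`,
#' the absolute slope of the first derivative `2 a t + b` — a curvature
#' measure (SPAD per day squared) that is invariant to adding a constant
#' or a linear trend to the series. The absolute slope of a simple linear
#' regression of SPAD on time is returned alongside as
#' `linear_decline_rate` (SPAD per day), an alternative senescence-rate
#' reading; downstream sensitivity analyses can use either via the
#' `cdr_mode` option of [run_analysis()].
#'
#' With exactly 3 distinct times the quadratic interpolates (`rss = 0`).
#' With fewer than 3 points the quadratic is unavailable: the linear rate
#' is still returned (or NA with 1 point) and the row is flagged.
#'
#' @param times days post-anthesis, distinct.
#' @param spad SPAD readings (unitless chlorophyll proxy, >= 0).
#' @return one-row [tibble::tibble]: quadratic coefficients `a`, `b`, `c`,
#'   `cdr`, `linear_decline_rate`, `rss`, `flag`.
#' @export
#' @examples
#' t <- c(7, 14, 21, 28)
#' fit_spad(t, 55 - 0.1 * t - 0.02 * t^2)
fit_spad <- function(times, spad) {
  stopifnot(is.numeric(times), is.numeric(spad), length(times) == length(spad))
  if (anyDuplicated(times)) stop("duplicate measurement times", call. = FALSE)
  n <- length(times)

  lin_rate <- if (n >= 2L) {
    abs(unname(stats::coef(stats::lm(spad ~ times))[2]))
  } else NA_real_

  if (n < 3L) {
    return(tibble::tibble(
      a = NA_real_, b = NA_real_, c = NA_real_, cdr = NA_real_,
      linear_decline_rate = lin_rate, rss = NA_real_,
      flag = "too_few_points_for_quadratic"))
  }

  fit <- stats::lm(spad ~ times + I(times^2))
  cf <- stats::coef(fit)
  tibble::tibble(
    a = unname(cf[3]), b = unname(cf[2]), c = unname(cf[1]),
    cdr = abs(2 * unname(cf[3])),
    linear_decline_rate = lin_rate,
    rss = sum(stats::resid(fit)^2),
    flag = "ok")
}
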