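#' Fit a linear-plus-plateau yield-N response
#'
#' Fits the continuity-constrained piecewise model
#' \deqn{GY(N) = b_0 + N_r \min(N, N_{cs})}
#' to replicate- or mean-level grain yields over fertilizer N rates. The
#' slope of the linear phase is the cultivar's N responsiveness (`n_r`),
#' the breakpoint is the critical N supply (`n_cs`, the minimum N rate at
#' which maximum yield is reached) and the plateau is `gy_max = intercept +
#' n_r * n_cs`.
#'
#' For each candidate breakpoint the conditional fit is an ordinary linear
#' regression on `min(N, c)`, solved in closed form; candidates are the
#' observed rates plus a uniform grid (default 1 kg N/ha step) over the
#' rate range, followed by golden-section refinement of the best bracket.
#' The search is deterministic. Among breakpoints with equal residual sum
#' of squares the smallest `n_cs` is kept, matching the definition of the
#' critical supply as a minimum.
#'
#' When the optimal breakpoint sits at the maximum observed rate the
#' response is still linear over the tested range and `plateau_observed`
#' is `FALSE`. Degenerate inputs are flagged, not hidden: identical yields
#' give `n_r = 0`, `n_cs = min(rate)`, `flag = "degenerate"`; a negative
#' fitted slope (N-depressed response) is returned with
#' `flag = "negative_slope"`.
#'
#' @param n_rates fertilizer N rates (kg N/ha, >= 0), one per yield value;
#'   at least 3 distinct rates.
#' @param yields grain yields (t/ha, > 0).
#' @param grid_step candidate-breakpoint spacing in kg N/ha.
#' @return a one-row [tibble::tibble]: `intercept`, `n_r`, `n_cs`,
#'   `gy_max`, `rss`, `plateau_observed`, `flag`.
#' @export
#' @examples
#' n <- c(0, 75, 150, 225)
#' fit_linear_plateau(n, 4 + 0.02 * pmin(n, 150))
fit_linear_plateau <- function(n_rates, yields, grid_step = 1) {
  stopifnot(is.numeric(n_rates), is.numeric(yields),
            length(n_rates) == length(yields), all(n_rates >= 0))
  if (length(unique(n_rates)) < 3L)
    stop("at least 3 distinct N rates are required", call. = FALSE)

  lo <- min(n_rates); hi <- max(n_rates)
  flag <- "ok"

  if (stats::sd(yields) == 0) {
    return(tibble::tibble(
      intercept = yields[1], n_r = 0, n_cs = lo, gy_max = yields[1],
      rss = 0, plateau_observed = FALSE, flag = "degenerate"))
  }

  # closed-form conditional least squares at breakpoint c
  rss_at <- function(c) {
    x <- pmin(n_rates, c)
    vx <- stats::var(x)
    if (vx == 0) {
      return(list(rss = sum((yields - mean(yields))^2),
                  b0 = mean(yields), b1 = 0))
    }
    b1 <- stats::cov(x, yields) / vx
    b0 <- mean(yields) - b1 * mean(x)
    list(rss = sum((yields - b0 - b1 * x)^2), b0 = b0, b1 = b1)
  }

  cand <- sort(unique(c(n_rates, seq(lo, hi, by = grid_step), hi)))
  cand <- cand[cand > lo]                    # breakpoint at min rate is degenerate
  rsses <- vapply(cand, function(c) rss_at(c)$rss, numeric(1))
  best_i <- which(rsses <= min(rsses) + 1e-12)[1]   # smallest n_cs among ties

  # golden-section refinement inside the bracketing interval
  gold <- (sqrt(5) - 1) / 2
  a <- cand[max(1L, best_i - 1L)]; b <- cand[min(length(cand), best_i + 1L)]
  x1 <- b - gold * (b - a); x2 <- a + gold * (b - a)
  f1 <- rss_at(x1)$rss; f2 <- rss_at(x2)$rss
  for (i in 1:60) {
    if (b - a < 1e-8) break
    if (f1 <= f2) { b <- x2; x2 <- x1; f2 <- f1; x1 <- b - gold * (b - a); f1 <- rss_at(x1)$rss }
    else          { a <- x1; x1 <- x2; f1 <- f2; x2 <- a + gold * (b - a); f2 <- rss_at(x2)$rss }
  }
  refined <- (a + b) / 2
  n_cs <- if (rss_at(refined)$rss < rsses[best_i] - 1e-12) refined else cand[best_i]
  sol <- rss_at(n_cs)

  if (sol$b1 < 0) flag <- "negative_slope"
  plateau_observed <- n_cs < hi - 1e-6

  tibble::tibble(
    intercept = sol$b0, n_r = sol$b1, n_cs = n_cs,
    gy_max = sol$b0 + sol$b1 * n_cs, rss = sol$rss,
    plateau_observed = plateau_observed, flag = flag)
}

#' Predict yield from a linear-plateau fit
#'
#' @param fit a one-row fit as returned by [fit_linear_plateau()] (or any
#'   list with `intercept`, `n_r`, `n_cs`).
#' @param n_rate N rate(s), kg N/ha, >= 0.
#' @return predicted grain yield (t/ha); equals `gy_max` for
#'   `n_rate >= n_cs`.
#' @export
predict_yield <- function(fit, n_rate) {
  stopifnot(all(n_rate >= 0))
  fit$intercept + fit$n_r * pmin(n_rate, fit$n_cs)
}
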