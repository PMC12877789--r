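#' Richards growth curve: grain weight at time t
#'
#' Evaluates the four-parameter Richards function
#' \deqn{W(t) = A (1 + B e^{-kt})^{-1/N}}
#' the standard asymmetric sigmoid used to describe post-anthesis grain
#' filling. `A` is the asymptotic final grain weight, `B` shifts the curve
#' along the time axis, `k` (per day) sets the intrinsic rate and `N`
#' controls the asymmetry (the logistic is the special case `N = 1`).
#'
#' @param params a list or named vector with elements `A`, `B`, `k`, `N`,
#'   all strictly positive (see [richards_params()]).
#' @param t days post-anthesis; any finite numeric vector.
#' @return grain weight, same units as `A`; strictly between 0 and `A` for
#'   finite `t` and non-decreasing in `t`. Large `k * t` safely saturates
#'   to `A` rather than overflowing.
#' @seealso [richards_rate()], [filling_traits()], [fit_richards()]
#' @export
#' @examples
#' richards_weight(richards_params(40, 20, 0.2, 1), c(0, 15, 36))
richards_weight <- function(params, t) {
  p <- richards_params(params)
  stopifnot(is.numeric(t), all(is.finite(t)))
  # log1p(B * exp(-k t)) computed via logspace addition is overflow-safe
  # even when -k*t is large and B*exp(-k*t) would overflow.
  z <- log(p$B) - p$k * t
  log_term <- ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))
  p$A * exp(-log_term / p$N)
}

#' Richards growth curve: instantaneous grain-filling rate
#'
#' First time-derivative of [richards_weight()]:
#' \deqn{dW/dt = \frac{A k B}{N} e^{-kt} (1 + B e^{-kt})^{-1/N - 1}}
#' The rate is positive for all finite `t` and vanishes in both tails.
#'
#' @inheritParams richards_weight
#' @return filling rate (weight units per day).
#' @export
richards_rate <- function(params, t) {
  p <- richards_params(params)
  stopifnot(is.numeric(t), all(is.finite(t)))
  z <- log(p$B) - p$k * t                       # log(B e^{-kt})
  log_term <- ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))
  exp(log(p$A * p$k / p$N) + z + (-1 / p$N - 1) * log_term)
}

#' Construct and validate Richards parameters
#'
#' @param A,B,k,N the four coefficients, all strictly positive. `A` carries
#'   the weight unit, `k` is per day, `B` and `N` are dimensionless.
#'   Alternatively pass a single list/named vector as `A`.
#' @return a named list of class `richards_params`.
#' @export
richards_params <- function(A, B = NULL, k = NULL, N = NULL) {
  if (is.list(A) || (is.numeric(A) && length(A) == 4L && !is.null(names(A)))) {
    p <- as.list(A)[c("A", "B", "k", "N")]
  } else {
    p <- list(A = A, B = B, k = k, N = N)
  }
  vals <- unlist(p)
  if (length(vals) != 4L || anyNA(vals) || any(!is.finite(vals)) || any(vals <= 0)) {
    stop("Richards parameters A, B, k, N must all be finite and strictly positive",
         call. = FALSE)
  }
  structure(lapply(p, unname), class = "richards_params")
}

#' Grain-filling phase traits from Richards parameters
#'
#' Derives, in closed form, the descriptors used to decompose grain filling:
#' the maximum rate `GFR_max = k A (N+1)^{-(N+1)/N}`, the mean rate
#' `GFR_mean = A k / (2 (N+2))`, the phase end-times
#' \deqn{T_1 = -\ln\!\big[(N^2+3N+N\sqrt{N^2+6N+5})/(2B)\big]/k}
#' \deqn{T_2 = -\ln\!\big[(N^2+3N-N\sqrt{N^2+6N+5})/(2B)\big]/k}
#' \deqn{T_3 = -\ln\!\big[((100/99)^N - 1)/B\big]/k}
#' and the phase durations `T_slow = T1`, `T_fast = T2 - T1`,
#' `T_slight = T3 - T2`. `T1` and `T2` are the zeros of the third
#' time-derivative of the weight curve (the inflection points of the rate),
#' delimiting the fast-increase period; `T3` is the time at which the grain
#' reaches 99% of its final weight `A`, so `W(T3) = 0.99 A` identically.
#'
#' `T_fast` depends only on `k` and `N`: changing `B` shifts `T1`, `T2` and
#' `T3` together by `ln(B)/k` but leaves every duration unchanged.
#'
#' A fit whose curve is already past the slow phase at anthesis (`T1 <= 0`)
#' is returned with `quality_flag = "nonpositive_T1"` rather than clamped;
#' downstream aggregation excludes flagged rows. If the parameter region
#' where `T3 <= T2` is hit (very large `N`), an error names the violated
#' inequality.
#'
#' @inheritParams richards_weight
#' @return a one-row [tibble::tibble] with columns `GFR_max`, `GFR_mean`,
#'   `T1`, `T2`, `T3`, `T_slow`, `T_fast`, `T_slight`, `quality_flag`
#'   (`"ok"` or `"nonpositive_T1"`).
#' @export
#' @examples
#' filling_traits(richards_params(40, 20, 0.2, 1))
filling_traits <- function(params) {
  p <- richards_params(params)
  N <- p$N; B <- p$B; k <- p$k; A <- p$A
  disc <- sqrt(N^2 + 6 * N + 5)
  u1 <- (N^2 + 3 * N + N * disc) / 2      # B e^{-k T1}
  u2 <- (N^2 + 3 * N - N * disc) / 2      # B e^{-k T2}
  u3 <- (100 / 99)^N - 1                  # B e^{-k T3}
  if (!(u3 < u2)) {
    stop(sprintf(
      "phase ordering violated: (100/99)^N - 1 = %.6g must be < (N^2+3N-N*sqrt(N^2+6N+5))/2 = %.6g for T3 > T2",
      u3, u2), call. = FALSE)
  }
  T1 <- -log(u1 / B) / k
  T2 <- -log(u2 / B) / k
  T3 <- -log(u3 / B) / k
  tibble::tibble(
    GFR_max  = k * A * (N + 1)^(-(N + 1) / N),
    GFR_mean = A * k / (2 * (N + 2)),
    T1 = T1, T2 = T2, T3 = T3,
    T_slow = T1, T_fast = T2 - T1, T_slight = T3 - T2,
    quality_flag = if (T1 <= 0) "nonpositive_T1" else "ok"
  )
}

#' Fit the Richards curve to a grain-weight time series
#'
#' Nonlinear least squares (Levenberg-Marquardt via
#' [minpack.lm::nlsLM()]) of `richards_weight` against observed grain
#' weights. Initialisation follows a logistic approximation: `A0 = 1.05 *
#' max(weight)`, `k0` from the slope of `logit(W / A0)` against time,
#' `N0 = 1`, and `B0` chosen so the starting curve passes through the first
#' observation. If the first attempt fails to converge or leaves
#' `r^2 < 0.98`, a deterministic 3 x 3 x 3 multi-start grid scaling
#' `(k0, N0, B0)` by \{0.5, 1, 2\} is tried and the best residual sum of
#' squares kept.
#'
#' Parameters are constrained to `A` in `(0, 3 * max(weight)]` and `B`,
#' `k`, `N` in `(1e-6, 1e3]` to keep the exponent numerically sane. The
#' fit is unweighted.
#'
#' @param times days post-anthesis, strictly increasing, `times[1] >= 0`.
#' @param weights observed grain weights (all positive, one per time; mg
#'   per grain or g per 1000 grains — any consistent unit).
#' @param max_restarts maximum number of grid restarts attempted after the
#'   default start (0-27).
#' @param r2_accept stop restarting once `r^2` reaches this value.
#' @return a list with `params` (a `richards_params`, or `NULL` on total
#'   failure) and `diagnostics`, a one-row tibble with `rss`, `r_squared`,
#'   `n_points`, `converged`, `n_restarts_used`. Non-convergence after all
#'   restarts is reported explicitly (`converged = FALSE`), never silently
#'   replaced.
#' @export
#' @examples
#' p <- richards_params(42, 18, 0.22, 0.9)
#' t <- seq(0, 36, by = 6)
#' fit <- fit_richards(t, richards_weight(p, t))
#' unlist(fit$params)
fit_richards <- function(times, weights, max_restarts = 27L, r2_accept = 0.98) {
  stopifnot(is.numeric(times), is.numeric(weights), length(times) == length(weights))
  if (length(times) < 5L)
    stop("at least 5 time points are required to fit 4 Richards parameters", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE) || times[1] < 0)
    stop("times must be strictly increasing and non-negative", call. = FALSE)
  if (any(weights <= 0)) stop("all weights must be positive", call. = FALSE)

  wmax <- max(weights)
  A0 <- 1.05 * wmax
  # logistic approximation: logit(W/A0) is ~ linear in t with slope k
  lg <- log(weights / A0) - log1p(-pmin(weights / A0, 1 - 1e-9))
  k0 <- unname(stats::coef(stats::lm(lg ~ times))[2])
  if (!is.finite(k0) || k0 <= 0) k0 <- 0.2
  N0 <- 1
  # B0: make the start curve pass through the first observation
  b_through_first <- function(A, k, N) {
    ((weights[1] / A)^(-N) - 1) * exp(k * times[1])
  }
  B0 <- b_through_first(A0, k0, N0)
  if (!is.finite(B0) || B0 <= 0) B0 <- 20

  lower <- c(A = 1e-8, B = 1e-6, k = 1e-6, N = 1e-6)
  upper <- c(A = 3 * wmax, B = 1e3, k = 1e3, N = 1e3)
  tss <- sum((weights - mean(weights))^2)
  df <- data.frame(t = times, w = weights)

  try_one <- function(start) {
    start <- pmin(pmax(start, lower * 1.0000001), upper)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        w ~ A * (1 + B * exp(-k * t))^(-1 / N),
        data = df, start = as.list(start),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) return(NULL)
    cf <- stats::coef(fit)
    list(coef = cf, rss = sum(stats::resid(fit)^2))
  }

  starts <- list(c(A = A0, B = B0, k = k0, N = N0))
  grid <- expand.grid(fk = c(0.5, 1, 2), fN = c(0.5, 1, 2), fB = c(0.5, 1, 2))
  for (i in seq_len(nrow(grid))) {
    ki <- k0 * grid$fk[i]; Ni <- N0 * grid$fN[i]
    Bi <- b_through_first(A0, ki, Ni)
    if (!is.finite(Bi) || Bi <= 0) Bi <- B0 * grid$fB[i]
    starts[[length(starts) + 1L]] <- c(A = A0, B = Bi * grid$fB[i], k = ki, N = Ni)
  }

  best <- NULL; n_used <- 0L
  for (i in seq_along(starts)) {
    if (i > 1L) {
      if (n_used >= max_restarts) break
      r2_so_far <- if (is.null(best)) -Inf else 1 - best$rss / tss
      if (r2_so_far >= r2_accept) break
      n_used <- n_used + 1L
    }
    res <- try_one(starts[[i]])
    if (!is.null(res) && (is.null(best) || res$rss < best$rss)) best <- res
  }

  if (is.null(best)) {
    return(list(
      params = NULL,
      diagnostics = tibble::tibble(
        rss = NA_real_, r_squared = NA_real_, n_points = length(times),
        converged = FALSE, n_restarts_used = n_used)))
  }
  list(
    params = richards_params(as.list(best$coef)),
    diagnostics = tibble::tibble(
      rss = best$rss,
      r_squared = if (tss > 0) 1 - best$rss / tss else NA_real_,
      n_points = length(times),
      converged = TRUE,
      n_restarts_used = n_used))
}
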