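# Independent oracles used across the suite. None of these call the
# package's closed-form trait algebra: derivatives come from base R's
# symbolic differentiator applied to the growth formula itself.

.w_expr <- quote(A * (1 + B * exp(-k * t))^(-1 / N))
.d1_expr <- D(.w_expr, "t")
.d3_expr <- D(D(D(.w_expr, "t"), "t"), "t")

oracle_weight <- function(A, B, k, N, t) {
  eval(.w_expr, list(A = A, B = B, k = k, N = N, t = t))
}

# zeros of the third time-derivative, located by scan + uniroot on the
# symbolically differentiated curve
oracle_d3_zeros <- function(A, B, k, N) {
  f <- function(t) eval(.d3_expr, list(A = A, B = B, k = k, N = N, t = t))
  tgrid <- seq(log(B / 1e4) / k, log(B / 1e-4) / k, length.out = 4001)
  v <- f(tgrid)
  s <- which(diff(sign(v)) != 0)
  vapply(s, function(i) {
    stats::uniroot(f, c(tgrid[i], tgrid[i + 1]), tol = 1e-12)$root
  }, numeric(1))
}

# numeric maximum of the filling rate from the symbolic first derivative
oracle_rate_max <- function(A, B, k, N) {
  f <- function(t) eval(.d1_expr, list(A = A, B = B, k = k, N = N, t = t))
  lo <- log(B / 1e4) / k; hi <- log(B / 1e-4) / k
  stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-10)
}

# random valid Richards parameter sets (log-uniform, filtered so that the
# slight-increase phase exists, i.e. T3 > T2)
random_richards <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n)
  got <- 0L
  while (got < n) {
    A <- exp(stats::runif(1, log(20), log(60)))
    B <- exp(stats::runif(1, log(1), log(50)))
    k <- exp(stats::runif(1, log(0.05), log(0.5)))
    N <- exp(stats::runif(1, log(0.2), log(5)))
    u2 <- (N^2 + 3 * N - N * sqrt(N^2 + 6 * N + 5)) / 2
    if ((100 / 99)^N - 1 < u2) {
      got <- got + 1L
      out[[got]] <- c(A = A, B = B, k = k, N = N)
    }
  }
  out
}

# exhaustive-grid linear-plateau oracle: conditional OLS at every
# candidate breakpoint on a fixed-resolution grid
oracle_plateau_rss <- function(n_rates, yields, step = 0.1) {
  rss_at <- function(cc) {
    x <- pmin(n_rates, cc)
    if (stats::var(x) == 0) return(sum((yields - mean(yields))^2))
    b1 <- stats::cov(x, yields) / stats::var(x)
    b0 <- mean(yields) - b1 * mean(x)
    sum((yields - b0 - b1 * x)^2)
  }
  cand <- seq(min(n_rates) + step, max(n_rates), by = step)
  rs <- vapply(cand, rss_at, numeric(1))
  list(n_cs = cand[which.min(rs)], rss = min(rs))
}
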