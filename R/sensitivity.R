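#' Sensitivity of a trait to N supply
#'
#' Ordinary least-squares line `trait = k * n_rate + b`; the slope `k`
#' (trait units per kg N/ha) quantifies how strongly the trait responds
#' to fertilizer N and is the per-cultivar "sensitivity" compared across
#' traits and cultivars.
#'
#' @param rates fertilizer N rates (kg N/ha); at least 3 distinct values.
#' @param values trait values, one per rate.
#' @return one-row [tibble::tibble]: `k`, `b`, `r_squared`.
#' @export
#' @examples
#' sensitivity_slope(c(0, 75, 150, 225), c(14, 15.5, 17, 18.2))
sensitivity_slope <- function(rates, values) {
  stopifnot(is.numeric(rates), is.numeric(values), length(rates) == length(values))
  if (length(unique(rates)) < 3L)
    stop("at least 3 distinct N rates are required", call. = FALSE)
  if (stats::var(rates) == 0) stop("zero variance in rates", call. = FALSE)
  fit <- stats::lm(values ~ rates)
  cf <- stats::coef(fit)
  tss <- sum((values - mean(values))^2)
  tibble::tibble(
    k = unname(cf[2]), b = unname(cf[1]),
    r_squared = if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else NA_real_)
}

#' Fraction of variance in y explained by x
#'
#' Squared Pearson correlation, the share of variation in one trait
#' accounted for by a straight-line dependence on another.
#'
#' @param x,y numeric vectors, >= 3 pairs, both with positive variance.
#' @return a number in \[0, 1\].
#' @export
variance_explained <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("variance_explained undefined for constant input", call. = FALSE)
  stats::cor(x, y)^2
}

#' Path analysis of yield components
#'
#' Decomposes the correlation of each predictor (e.g. grain weight GW,
#' grains per spike GPS, spikes per unit area SPUA) with a response
#' (grain yield GY) into a direct path coefficient and first-order
#' indirect contributions through the other predictors. On standardized
#' variables the direct coefficients solve the normal equations
#' `R_pred %*% p = r_resp` (they are the standardized multiple-regression
#' coefficients) and the indirect contribution of predictor i via j is
#' `r_ij * p_j`, so that for every predictor
#' `r(i, response) = direct_i + sum_j indirect_{i,j}` exactly, and the
#' regression R^2 equals `sum_i direct_i * r(i, response)`.
#'
#' @param data a data frame holding the response and predictor columns.
#' @param response name of the response column.
#' @param predictors character vector of predictor column names (>= 1);
#'   needs at least `length(predictors) + 2` rows and a nonsingular
#'   predictor correlation matrix.
#' @return a list with `direct` (named vector), `indirect` (matrix,
#'   `indirect[i, j]` = contribution of i via j, zero diagonal),
#'   `correlations` (predictor-response), `r_squared` (full model),
#'   `r_squared_single` (per-predictor squared correlations).
#' @export
#' @examples
#' d <- data.frame(gy = rnorm(50))
#' d$gw <- d$gy + rnorm(50); d$gps <- rnorm(50)
#' path_analysis(d, "gy", c("gw", "gps"))
path_analysis <- function(data, response, predictors) {
  stopifnot(response %in% names(data), all(predictors %in% names(data)),
            length(predictors) >= 1L)
  X <- as.matrix(data[predictors]); y <- data[[response]]
  if (nrow(X) < length(predictors) + 2L)
    stop("need at least predictors + 2 rows", call. = FALSE)
  R <- stats::cor(X)
  kappa_R <- kappa(R, exact = TRUE)
  if (!all(is.finite(R)) || kappa_R > 1e10)
    stop(sprintf("predictor correlation matrix is singular (condition number %.3g)",
                 kappa_R), call. = FALSE)
  r_resp <- drop(stats::cor(X, y))
  direct <- drop(solve(R, r_resp))
  names(direct) <- predictors
  indirect <- R * rep(direct, each = length(direct))   # indirect[i,j] = r_ij * direct_j
  diag(indirect) <- 0
  dimnames(indirect) <- list(predictors, predictors)
  list(direct = direct,
       indirect = indirect,
       correlations = stats::setNames(r_resp, predictors),
       r_squared = sum(direct * r_resp),
       r_squared_single = stats::setNames(r_resp^2, predictors))
}
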