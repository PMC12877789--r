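#' Default cultivar profiles for the synthetic trial
#'
#' Five winter-wheat cultivar profiles spanning a breeding-era gradient of
#' nitrogen responsiveness, from a low-responsive landrace-era type
#' (`BM1`) to a modern high-responsive cultivar (`JM22`). The profiles
#' encode the qualitative gradients the generator is meant to emulate:
#' monotonically increasing yield-N slope (`nr_true`), critical N supply
#' (`ncs_true`), final grain weight, fast-phase duration sensitivity
#' (`tfast_per_n`) and anthesis N-accumulation sensitivity (`naa_per_n`),
#' and monotonically decreasing chlorophyll degradation rate and
#' post-anthesis share of grain N.
#'
#' Columns (units):
#' * `a_base` (mg/grain) final grain weight at N0, `a_per_n` its response
#'   per kg N/ha up to `ncs_true`;
#' * `tfast_base` (d), `tfast_per_n` (d per kg N/ha) fast-increase phase
#'   duration and its N sensitivity;
#' * `n_shape`, `b_coef` Richards shape parameters held fixed per cultivar;
#' * `nr_true` (t/ha per kg N/ha), `ncs_true` (kg N/ha), `gy0` (t/ha)
#'   the generating linear-plateau yield response;
#' * `cdr_base` (SPAD/d^2), `cdr_per_n` SPAD-curve curvature and its N
#'   response;
#' * `naa_base`, `naa_per_n` (g/m2, g/m2 per kg N/ha) anthesis N
#'   accumulation;
#' * `post_uptake_frac` fraction of grain N from post-anthesis uptake.
#'
#' @return a [tibble::tibble], one row per cultivar.
#' @export
cultivar_profiles <- function() {
  tibble::tibble(
    name       = c("BM1", "JN2", "TS1", "JM26", "JM22"),
    a_base     = c(34,    36,    38,    40,     42),
    a_per_n    = c(0.016, 0.020, 0.024, 0.028,  0.032),
    tfast_base = c(12.0,  12.5,  13.0,  13.5,   14.0),
    tfast_per_n= c(0.006, 0.010, 0.014, 0.018,  0.024),
    n_shape    = c(0.85,  0.95,  1.00,  1.05,   1.10),
    b_coef     = c(18,    19,    20,    21,     22),
    nr_true    = c(0.012, 0.014, 0.016, 0.018,  0.021),
    ncs_true   = c(120,   130,   140,   145,    150),
    gy0        = c(3.2,   3.5,   3.8,   4.0,    4.3),
    cdr_base   = c(0.056, 0.052, 0.048, 0.044,  0.040),
    cdr_per_n  = c(-2e-5, -2.5e-5, -3e-5, -3.5e-5, -4e-5),
    naa_base   = c(8.0,   8.5,   9.0,   9.5,    10.0),
    naa_per_n  = c(0.020, 0.026, 0.032, 0.038,  0.046),
    post_uptake_frac = c(0.40, 0.36, 0.32, 0.28, 0.24))
}

#' Default synthetic trial design
#'
#' Mirrors a two-season split-plot wheat trial: 2 years x 4 N rates
#' (0/75/150/225 kg N/ha) x 5 cultivars x 3 replicates, grain weights
#' sampled every 6 d from anthesis to 36 d, SPAD at 7/14/21/28 d.
#'
#' @param years year labels.
#' @param n_rates fertilizer N rates (kg N/ha).
#' @param reps replicates per treatment.
#' @param sampling_days grain-sampling days post-anthesis.
#' @param spad_days SPAD measurement days post-anthesis.
#' @param grain_sigma,spad_sigma,yield_sigma Gaussian noise SD for grain
#'   weight (mg), SPAD units and yield (t/ha).
#' @param npool_cv coefficient of variation of organ N pools and biomass.
#' @param soil_n plant-available soil N (kg/ha) entering the effective
#'   supply `n_e = n_rate + soil_n`.
#' @param seed integer seed; expanded into independent per-table
#'   substreams so that adding a table does not perturb the others.
#' @return a list of class `trial_design`.
#' @export
trial_design <- function(years = c(2018L, 2019L),
                         n_rates = c(0, 75, 150, 225),
                         reps = 3L,
                         sampling_days = seq(0, 36, by = 6),
                         spad_days = c(7, 14, 21, 28),
                         grain_sigma = 0.5, spad_sigma = 0.8,
                         yield_sigma = 0.2, npool_cv = 0.05,
                         soil_n = 60, seed = 42L) {
  stopifnot(length(n_rates) == length(unique(n_rates)), all(n_rates >= 0),
            grain_sigma >= 0, spad_sigma >= 0, yield_sigma >= 0, npool_cv >= 0)
  structure(list(years = years, n_rates = n_rates, reps = as.integer(reps),
                 sampling_days = sampling_days, spad_days = spad_days,
                 grain_sigma = grain_sigma, spad_sigma = spad_sigma,
                 yield_sigma = yield_sigma, npool_cv = npool_cv,
                 soil_n = soil_n, seed = as.integer(seed)),
            class = "trial_design")
}

#' Richards parameters implied by a cultivar profile at an N rate
#'
#' Inverts the closed-form phase algebra: the fast-phase duration
#' `T_fast = ln(u1/u2) / k` depends only on `k` and the shape exponent
#' (`u1`, `u2` are the third-derivative roots of `B e^{-kt}`), so the rate
#' constant is solved from the profile's target
#' `T_fast(n) = tfast_base + tfast_per_n * n`; `B` is the profile's fixed
#' `b_coef` (it shifts phase onset but not durations) and the asymptote
#' follows the plateau rule `A = a_base + a_per_n * min(n, ncs_true)`.
#' Round trip: `filling_traits(derive_richards(p, n))$T_fast` equals the
#' target exactly.
#'
#' @param profile one row of [cultivar_profiles()] (list or 1-row data
#'   frame).
#' @param n_rate fertilizer N rate (kg N/ha).
#' @return a `richards_params` object.
#' @export
derive_richards <- function(profile, n_rate) {
  pr <- as.list(profile)
  tfast <- pr$tfast_base + pr$tfast_per_n * n_rate
  if (tfast <= 0) stop("target T_fast must be positive", call. = FALSE)
  N <- pr$n_shape
  disc <- sqrt(N^2 + 6 * N + 5)
  u1 <- (N^2 + 3 * N + N * disc) / 2
  u2 <- (N^2 + 3 * N - N * disc) / 2
  k <- log(u1 / u2) / tfast
  if (k <= 1e-6 || k > 1e3)
    stop(sprintf("infeasible T_fast target %.3g d: implied k = %.3g outside (1e-6, 1e3]",
                 tfast, k), call. = FALSE)
  A <- pr$a_base + pr$a_per_n * min(n_rate, pr$ncs_true)
  richards_params(A = A, B = pr$b_coef, k = k, N = N)
}

plot_key <- function(year, cultivar, n_rate, rep) {
  paste(year, cultivar, n_rate, rep, sep = "_")
}

#' Generate a complete synthetic field trial
#'
#' Builds the full plot-level table bundle the analysis pipeline consumes,
#' with known ground truth:
#' * `grain_series` — Richards-curve grain weights plus Gaussian noise
#'   (weights truncated at a 0.1 mg floor and flagged if hit);
#' * `spad_series` — concave quadratic SPAD decline whose curvature
#'   `|2a|` equals the profile's CDR at that N rate, plus noise;
#' * `yields` — linear-plateau grain yield `gy0 + nr_true * min(N, ncs)`
#'   plus noise, with consistent yield components (1000-grain weight from
#'   the Richards asymptote, grains per spike, spikes per m2);
#' * `organ_n` — anthesis and maturity organ biomass and N concentration
#'   satisfying the nitrogen mass balances `n_am = n_vtm + n_gm` and
#'   `n_gm = nta + post-anthesis uptake` exactly before noise;
#' * `truth` — the generating profile parameters for recovery tests.
#'
#' Output is deterministic for a given `design$seed`; each table draws
#' from its own seeded substream.
#'
#' @param profiles cultivar profile table ([cultivar_profiles()] format).
#' @param design a [trial_design()].
#' @return a list of class `trial_dataset` with elements `grain_series`,
#'   `spad_series`, `yields`, `organ_n`, `truth`, `design`.
#' @export
#' @examples
#' trial <- generate_trial(cultivar_profiles(), trial_design(seed = 1))
#' head(trial$grain_series)
generate_trial <- function(profiles, design = trial_design()) {
  stopifnot(inherits(design, "trial_design"))
  profiles <- tibble::as_tibble(profiles)

  plots <- tidyr::expand_grid(
    year = design$years, cultivar = profiles$name,
    n_rate_kg_ha = design$n_rates, rep = seq_len(design$reps)) |>
    dplyr::mutate(plot_id = plot_key(.data$year, .data$cultivar,
                                     .data$n_rate_kg_ha, .data$rep))
  prof_of <- function(cv) profiles[match(cv, profiles$name), ]

  ## --- grain series (substream 1) -----------------------------------
  set.seed(design$seed + 1L)
  grain <- plots |>
    dplyr::rowwise() |>
    dplyr::mutate(data = list({
      p <- derive_richards(prof_of(.data$cultivar), .data$n_rate_kg_ha)
      w <- richards_weight(p, design$sampling_days)
      tibble::tibble(day_post_anthesis = design$sampling_days, mu = w)
    })) |>
    dplyr::ungroup() |>
    tidyr::unnest("data")
  grain$grain_weight <- grain$mu + stats::rnorm(nrow(grain), 0, design$grain_sigma)
  grain$truncated <- grain$grain_weight < 0.1
  grain$grain_weight <- pmax(grain$grain_weight, 0.1)
  grain <- dplyr::select(grain, -"mu")

  ## --- SPAD series (substream 2) ------------------------------------
  set.seed(design$seed + 2L)
  spad <- tidyr::expand_grid(plots, day_post_anthesis = design$spad_days)
  pr <- prof_of(spad$cultivar)
  cdr <- pr$cdr_base + pr$cdr_per_n * spad$n_rate_kg_ha
  a <- -cdr / 2
  spad0 <- 46 + 0.03 * pmin(spad$n_rate_kg_ha, pr$ncs_true) +
    2 * (match(spad$cultivar, cultivar_order()) - 1) / 4
  spad$spad <- spad0 - 0.05 * spad$day_post_anthesis + a * spad$day_post_anthesis^2 +
    stats::rnorm(nrow(spad), 0, design$spad_sigma)

  ## --- yields and components (substream 3) --------------------------
  set.seed(design$seed + 3L)
  pr <- prof_of(plots$cultivar)
  gy_mu <- pr$gy0 + pr$nr_true * pmin(plots$n_rate_kg_ha, pr$ncs_true)
  year_eff <- 0.1 * (plots$year == design$years[1]) - 0.05
  gw_mu <- pr$a_base + pr$a_per_n * pmin(plots$n_rate_kg_ha, pr$ncs_true)
  yields <- plots
  yields$grain_yield_t_ha <- gy_mu + year_eff +
    stats::rnorm(nrow(plots), 0, design$yield_sigma)
  yields$gw_mg <- gw_mu + stats::rnorm(nrow(plots), 0, 0.8)
  yields$gps <- 28 + 0.03 * pmin(plots$n_rate_kg_ha, pr$ncs_true) +
    stats::rnorm(nrow(plots), 0, 1)
  # spikes per m2 closing the yield identity GY[t/ha] = SPUA*GPS*GW[mg]/1e5
  yields$spua <- yields$grain_yield_t_ha * 1e5 / (yields$gw_mg * yields$gps)

  ## --- organ N pools (substream 4) ----------------------------------
  set.seed(design$seed + 4L)
  n_aa <- pr$naa_base + pr$naa_per_n * plots$n_rate_kg_ha          # g/m2
  n_gm <- 0.022 * gy_mu * 100                                      # 2.2 % grain N
  nta <- (1 - pr$post_uptake_frac) * n_gm
  n_vtm <- pmax(n_aa - nta, 0.05)
  w_shoot_g_m2 <- 100 * (6.5 + 0.015 * pmin(plots$n_rate_kg_ha, pr$ncs_true) +
                           0.3 * (match(plots$cultivar, cultivar_order()) - 1) / 4)
  anth_split <- c(stem = 0.50, leaf = 0.35, chaff = 0.15)   # anthesis N split
  nta_split  <- c(stem = 0.45, leaf = 0.40, chaff = 0.15)   # organ shares of NTA
  bm_split_a <- c(stem = 0.58, leaf = 0.27, chaff = 0.15)   # anthesis biomass split
  bm_split_m <- c(stem = 0.60, leaf = 0.22, chaff = 0.18)   # maturity veg biomass

  organ_rows <- function(stage, org, n_amt, biomass) {
    dplyr::bind_cols(
      plots[c("year", "cultivar", "n_rate_kg_ha", "rep", "plot_id")],
      tibble::tibble(stage = stage, organ = org,
                     n_amount = n_amt, biomass = biomass))
  }
  rows <- list()
  for (org in names(anth_split)) {
    rows[[paste0("a_", org)]] <- organ_rows(
      "anthesis", org, n_aa * anth_split[[org]], w_shoot_g_m2 * bm_split_a[[org]])
  }
  veg_m_biomass <- 0.85 * w_shoot_g_m2    # leaf loss + respiration by maturity
  for (org in names(nta_split)) {
    n_m <- n_aa * anth_split[[org]] - nta * nta_split[[org]]
    rows[[paste0("m_", org)]] <- organ_rows(
      "maturity", org, pmax(n_m, 0.01), veg_m_biomass * bm_split_m[[org]])
  }
  rows$m_grain <- organ_rows("maturity", "grain", n_gm, gy_mu * 100)
  organ_n <- dplyr::bind_rows(rows)
  noise <- stats::rnorm(nrow(organ_n), 1, design$npool_cv)
  organ_n$n_amount <- organ_n$n_amount * pmax(noise, 0.5)
  organ_n$biomass_g_m2 <- organ_n$biomass *
    pmax(stats::rnorm(nrow(organ_n), 1, design$npool_cv), 0.5)
  organ_n$n_conc_pct <- 100 * organ_n$n_amount / organ_n$biomass_g_m2
  organ_n <- dplyr::select(organ_n, -"n_amount", -"biomass")

  truth <- profiles
  structure(list(grain_series = grain, spad_series = spad, yields = yields,
                 organ_n = organ_n, truth = truth, design = design),
            class = "trial_dataset")
}

cultivar_order <- function() c("BM1", "JN2", "TS1", "JM26", "JM22")

#' Write / read a trial dataset as CSV files
#'
#' `write_trial_csvs()` writes `grain_series.csv`, `spad_series.csv`,
#' `yields.csv`, `organ_n.csv` and `truth.csv` into `dir`;
#' `read_trial_csvs()` reads them back into a `trial_dataset` (without the
#' design object, which is not needed for analysis).
#'
#' @param trial a `trial_dataset` from [generate_trial()].
#' @param dir directory (created if missing).
#' @return `write_trial_csvs()` the directory, invisibly;
#'   `read_trial_csvs()` a `trial_dataset` list.
#' @export
write_trial_csvs <- function(trial, dir) {
  stopifnot(inherits(trial, "trial_dataset") || is.list(trial))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tab in c("grain_series", "spad_series", "yields", "organ_n", "truth")) {
    readr::write_csv(trial[[tab]], file.path(dir, paste0(tab, ".csv")))
  }
  invisible(dir)
}

#' @rdname write_trial_csvs
#' @export
read_trial_csvs <- function(dir) {
  tabs <- c("grain_series", "spad_series", "yields", "organ_n", "truth")
  out <- lapply(tabs, function(tab) {
    f <- file.path(dir, paste0(tab, ".csv"))
    if (!file.exists(f)) stop("missing input file: ", f, call. = FALSE)
    readr::read_csv(f, show_col_types = FALSE)
  })
  names(out) <- tabs
  structure(out, class = "trial_dataset")
}
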