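#' Analysis configuration
#'
#' Collects the options of [run_analysis()] in one validated object.
#'
#' @param fit_level `"plot"` (fit the Richards curve to every replicate
#'   plot, then average traits over replicates — the default) or `"mean"`
#'   (average the grain series over replicates first, then fit).
#' @param cdr_mode senescence-rate definition fed to the sensitivity
#'   analysis: `"quadratic"` uses `|2a|` from the quadratic SPAD fit,
#'   `"linear"` the absolute OLS slope of SPAD on time.
#' @param dilution_unit biomass unit of the critical dilution curve
#'   (see [critical_n_conc()]).
#' @param soil_n plant-available soil N (kg/ha) added to the fertilizer
#'   rate to form the effective supply `n_e`.
#' @param max_restarts,r2_accept passed to [fit_richards()].
#' @param max_failure_frac abort threshold: if more than this fraction of
#'   Richards fits fail, [run_analysis()] errors.
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(fit_level = c("plot", "mean"),
                            cdr_mode = c("quadratic", "linear"),
                            dilution_unit = c("t_ha", "kg_ha"),
                            soil_n = 60,
                            max_restarts = 27L, r2_accept = 0.98,
                            max_failure_frac = 0.2) {
  structure(list(fit_level = match.arg(fit_level),
                 cdr_mode = match.arg(cdr_mode),
                 dilution_unit = match.arg(dilution_unit),
                 soil_n = soil_n, max_restarts = max_restarts,
                 r2_accept = r2_accept, max_failure_frac = max_failure_frac),
            class = "analysis_config")
}

keys <- c("year", "cultivar", "n_rate_kg_ha", "rep", "plot_id")

#' Run the full N-responsiveness analysis pipeline
#'
#' End-to-end orchestration: Richards fits and filling traits per plot,
#' linear-plateau yield-N response per cultivar x year, SPAD senescence
#' fits, nitrogen budgets / efficiency indices / nutrition index per
#' plot, trait-to-N sensitivity slopes per cultivar x year, and a path
#' decomposition of yield components (GW, GPS, SPUA on GY) pooled across
#' the trial. Fits that fail or carry quality flags are excluded from the
#' aggregates and counted in the manifest; everything is deterministic
#' given the input tables and config.
#'
#' @param trial a `trial_dataset` (from [generate_trial()] or
#'   [read_trial_csvs()]).
#' @param config an [analysis_config()].
#' @return a list of class `result_bundle`: tibbles `richards_fits`,
#'   `n_response`, `senescence_fits`, `n_budget`, `efficiency`, `nni`,
#'   `sensitivity`, plus `path` (see [path_analysis()]) and `manifest`.
#' @export
#' @examples
#' trial <- generate_trial(cultivar_profiles(), trial_design(seed = 7))
#' res <- run_analysis(trial)
#' res$n_response
run_analysis <- function(trial, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  v <- validate_trial(trial)
  if (any(v$status == "fail")) {
    bad <- v[v$status == "fail", ]
    stop("input validation failed:\n",
         paste(sprintf("  [%s] %s: %s", bad$table, bad$check, bad$detail),
               collapse = "\n"), call. = FALSE)
  }

  ## ---- grain filling -------------------------------------------------
  gs <- trial$grain_series
  if (config$fit_level == "mean") {
    gs <- gs |>
      dplyr::group_by(.data$year, .data$cultivar, .data$n_rate_kg_ha,
                      .data$day_post_anthesis) |>
      dplyr::summarise(grain_weight = mean(.data$grain_weight), .groups = "drop") |>
      dplyr::mutate(rep = 0L,
                    plot_id = plot_key(.data$year, .data$cultivar,
                                       .data$n_rate_kg_ha, "mean"))
  }
  richards_fits <- gs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(function(d, g) {
      d <- d[order(d$day_post_anthesis), ]
      fit <- fit_richards(d$day_post_anthesis, d$grain_weight,
                          max_restarts = config$max_restarts,
                          r2_accept = config$r2_accept)
      if (is.null(fit$params)) {
        return(dplyr::bind_cols(
          tibble::tibble(A = NA_real_, B = NA_real_, k = NA_real_, N = NA_real_),
          fit$diagnostics,
          tibble::tibble(quality_flag = "fit_failed")))
      }
      traits <- tryCatch(filling_traits(fit$params),
                         error = function(e) tibble::tibble(quality_flag = "ordering_violation"))
      dplyr::bind_cols(tibble::as_tibble(unclass(fit$params)),
                       fit$diagnostics,
                       traits)
    }) |>
    dplyr::ungroup()

  n_failed <- sum(!richards_fits$converged)
  if (n_failed / nrow(richards_fits) > config$max_failure_frac)
    stop(sprintf("%d of %d Richards fits failed (> %.0f%% threshold)",
                 n_failed, nrow(richards_fits), 100 * config$max_failure_frac),
         call. = FALSE)

  ## ---- yield-N response ----------------------------------------------
  n_response <- trial$yields |>
    dplyr::group_by(.data$year, .data$cultivar) |>
    dplyr::group_modify(~ fit_linear_plateau(.x$n_rate_kg_ha, .x$grain_yield_t_ha)) |>
    dplyr::ungroup()

  ## ---- senescence -----------------------------------------------------
  senescence_fits <- trial$spad_series |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::group_modify(~ fit_spad(.x$day_post_anthesis, .x$spad)) |>
    dplyr::ungroup()

  ## ---- nitrogen budget, efficiency, NNI -------------------------------
  org <- trial$organ_n |>
    dplyr::mutate(n_amount = .data$biomass_g_m2 * .data$n_conc_pct / 100)
  pools <- org |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_aa = sum(.data$n_amount[.data$stage == "anthesis"]),
      n_gm = sum(.data$n_amount[.data$stage == "maturity" & .data$organ == "grain"]),
      n_vtm = sum(.data$n_amount[.data$stage == "maturity" & .data$organ != "grain"]),
      w_shoot_t_ha = sum(.data$biomass_g_m2[.data$stage == "anthesis"]) / 100,
      .groups = "drop")
  n_budget <- dplyr::bind_cols(
    pools[keys],
    translocation(pools$n_aa, pools$n_vtm, pools$n_gm),
    tibble::tibble(n_aa = pools$n_aa, n_vtm = pools$n_vtm, n_gm = pools$n_gm))

  yl <- trial$yields[c(keys, "grain_yield_t_ha")]
  eff_in <- dplyr::inner_join(
    dplyr::select(n_budget, dplyr::all_of(keys), "n_am"), yl, by = keys)
  efficiency <- dplyr::bind_cols(
    eff_in[keys],
    efficiency_indices(eff_in$grain_yield_t_ha, eff_in$n_am,
                       eff_in$n_rate_kg_ha + config$soil_n))

  nni_tbl <- dplyr::bind_cols(
    pools[keys],
    nni(nc_act = 100 * pools$n_aa / (100 * pools$w_shoot_t_ha),
        w_shoot = pools$w_shoot_t_ha, unit = config$dilution_unit))

  ## ---- sensitivity slopes ---------------------------------------------
  trait_tbl <- richards_fits |>
    dplyr::filter(.data$converged, .data$quality_flag == "ok") |>
    dplyr::select(dplyr::all_of(keys), "GFR_max", "GFR_mean",
                  "T_slow", "T_fast", "T_slight", "A")
  sen <- senescence_fits |>
    dplyr::mutate(cdr = if (config$cdr_mode == "quadratic") .data$cdr
                  else .data$linear_decline_rate) |>
    dplyr::select(dplyr::all_of(keys), "cdr")
  nb <- dplyr::select(n_budget, dplyr::all_of(keys), "nta", "n_aa")
  plot_traits <- trait_tbl |>
    dplyr::left_join(sen, by = keys) |>
    dplyr::left_join(nb, by = keys) |>
    tidyr::pivot_longer(-dplyr::all_of(keys),
                        names_to = "trait", values_to = "value")
  sensitivity <- plot_traits |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$trait, .data$cultivar, .data$year,
                    .data$n_rate_kg_ha) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    dplyr::group_by(.data$trait, .data$cultivar, .data$year) |>
    dplyr::group_modify(~ sensitivity_slope(.x$n_rate_kg_ha, .x$value)) |>
    dplyr::ungroup()

  ## ---- path analysis of yield components ------------------------------
  path <- path_analysis(as.data.frame(trial$yields),
                        response = "grain_yield_t_ha",
                        predictors = c("gw_mg", "gps", "spua"))

  manifest <- list(
    config = unclass(config),
    n_plots = length(unique(trial$yields$plot_id)),
    n_richards_fits = nrow(richards_fits),
    n_fit_failures = n_failed,
    n_flagged_fits = sum(richards_fits$quality_flag != "ok"),
    package_version = as.character(utils::packageVersion("wheatnr")))

  structure(list(richards_fits = richards_fits, n_response = n_response,
                 senescence_fits = senescence_fits, n_budget = n_budget,
                 efficiency = efficiency, nni = nni_tbl,
                 sensitivity = sensitivity, path = path, manifest = manifest),
            class = "result_bundle")
}

#' Validate a trial dataset against the expected schema
#'
#' Checks, per table: required columns, key uniqueness (one row per plot
#' and sampling day), positivity of weights/yields, non-negative N rates,
#' and duplicate organs within a plot/stage. Large drops in grain weight
#' between consecutive samples (> 3 sigma of the within-series
#' differences) are reported as warnings, not failures.
#'
#' @param trial a `trial_dataset` list.
#' @return a tibble with columns `table`, `check`, `status`
#'   (`"pass"`/`"warn"`/`"fail"`), `detail`.
#' @export
validate_trial <- function(trial) {
  out <- list()
  add <- function(table, check, ok, detail = "", warn = FALSE) {
    out[[length(out) + 1L]] <<- tibble::tibble(
      table = table, check = check,
      status = if (ok) "pass" else if (warn) "warn" else "fail",
      detail = if (ok) "" else detail)
  }
  need <- list(
    grain_series = c(keys, "day_post_anthesis", "grain_weight"),
    spad_series = c(keys, "day_post_anthesis", "spad"),
    yields = c(keys, "grain_yield_t_ha", "gw_mg", "gps", "spua"),
    organ_n = c(keys, "stage", "organ", "biomass_g_m2", "n_conc_pct"))
  for (tab in names(need)) {
    if (is.null(trial[[tab]])) { add(tab, "present", FALSE, "table missing"); next }
    miss <- setdiff(need[[tab]], names(trial[[tab]]))
    add(tab, "columns", length(miss) == 0,
        paste("missing columns:", paste(miss, collapse = ", ")))
  }
  if (!is.null(trial$grain_series) &&
      all(c("plot_id", "day_post_anthesis") %in% names(trial$grain_series))) {
    gs <- trial$grain_series
    dup <- anyDuplicated(gs[c("plot_id", "day_post_anthesis")])
    add("grain_series", "unique_plot_day", dup == 0,
        sprintf("duplicated (plot_id, day) at row %d", dup))
    if ("grain_weight" %in% names(gs)) {
      add("grain_series", "positive_weights", all(gs$grain_weight > 0),
          "non-positive grain weights")
      drops <- gs |>
        dplyr::arrange(.data$plot_id, .data$day_post_anthesis) |>
        dplyr::group_by(.data$plot_id) |>
        dplyr::mutate(d = c(NA, diff(.data$grain_weight))) |>
        dplyr::ungroup()
      sd_d <- stats::sd(drops$d, na.rm = TRUE)
      n_big <- sum(drops$d < -3 * sd_d, na.rm = TRUE)
      add("grain_series", "monotone_within_noise", n_big == 0,
          sprintf("%d weight drops exceeding 3 sigma between samples", n_big),
          warn = TRUE)
    }
  }
  if (!is.null(trial$yields) && "grain_yield_t_ha" %in% names(trial$yields)) {
    add("yields", "positive_yield", all(trial$yields$grain_yield_t_ha > 0),
        "non-positive yields")
    add("yields", "nonnegative_rates", all(trial$yields$n_rate_kg_ha >= 0),
        "negative N rates")
  }
  if (!is.null(trial$organ_n) &&
      all(c("plot_id", "stage", "organ") %in% names(trial$organ_n))) {
    dup <- anyDuplicated(trial$organ_n[c("plot_id", "stage", "organ")])
    add("organ_n", "unique_organ", dup == 0,
        sprintf("duplicated (plot, stage, organ) at row %d", dup))
    grain_at_anthesis <- with(trial$organ_n, any(stage == "anthesis" & organ == "grain"))
    add("organ_n", "grain_only_at_maturity", !grain_at_anthesis,
        "grain organ recorded at anthesis")
  }
  dplyr::bind_rows(out)
}

#' Write a result bundle as CSV files
#'
#' Writes `richards_fits.csv`, `n_response.csv`, `senescence_fits.csv`,
#' `n_budget.csv`, `efficiency.csv`, `nni.csv`, `sensitivity.csv`,
#' `path_analysis.csv` and a `manifest.yml`-style text manifest into
#' `dir`. Numbers are written at full precision.
#'
#' @param res a `result_bundle` from [run_analysis()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_results <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tab in c("richards_fits", "n_response", "senescence_fits",
                "n_budget", "efficiency", "nni", "sensitivity")) {
    readr::write_csv(res[[tab]], file.path(dir, paste0(tab, ".csv")))
  }
  p <- res$path
  path_tbl <- tibble::tibble(
    predictor = names(p$direct),
    correlation = unname(p$correlations),
    direct = unname(p$direct),
    r_squared_single = unname(p$r_squared_single))
  for (j in names(p$direct))
    path_tbl[[paste0("indirect_via_", j)]] <- unname(p$indirect[, j])
  readr::write_csv(path_tbl, file.path(dir, "path_analysis.csv"))
  m <- res$manifest
  writeLines(c(
    paste0("package_version: ", m$package_version),
    paste0("n_plots: ", m$n_plots),
    paste0("n_richards_fits: ", m$n_richards_fits),
    paste0("n_fit_failures: ", m$n_fit_failures),
    paste0("n_flagged_fits: ", m$n_flagged_fits),
    paste0("config: ", paste(names(m$config), unlist(m$config),
                             sep = "=", collapse = " "))),
    file.path(dir, "manifest.txt"))
  invisible(dir)
}
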