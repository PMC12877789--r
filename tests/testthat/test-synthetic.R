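noiseless <- function(seed = 1) {
  trial_design(grain_sigma = 0, spad_sigma = 0, yield_sigma = 0,
               npool_cv = 0, seed = seed)
}

test_that("derive_richards hits the target fast-phase duration exactly", {
  prof <- cultivar_profiles()[5, ]
  for (n in c(0, 75, 150, 225)) {
    p <- derive_richards(prof, n)
    target <- prof$tfast_base + prof$tfast_per_n * n
    expect_equal(filling_traits(p)$T_fast, target, tolerance = 1e-9)
  }
  # asymptote follows the plateau rule
  p225 <- derive_richards(prof, 225)
  pcs <- derive_richards(prof, prof$ncs_true)
  expect_equal(p225$A, pcs$A)
  expect_equal(p225$A, prof$a_base + prof$a_per_n * prof$ncs_true)
})

test_that("two T_fast targets with shared shape invert to the expected k ratio", {
  prof <- cultivar_profiles()[3, ]
  p1 <- derive_richards(dplyr::mutate(prof, tfast_base = 14, tfast_per_n = 0), 0)
  p2 <- derive_richards(dplyr::mutate(prof, tfast_base = 18, tfast_per_n = 0), 0)
  expect_equal(p1$k / p2$k, 18 / 14, tolerance = 1e-10)
  expect_equal(p1$B, p2$B)  # B untouched: it cannot change durations
})

test_that("infeasible fast-phase targets are rejected", {
  prof <- dplyr::mutate(cultivar_profiles()[1, ], tfast_base = -2, tfast_per_n = 0)
  expect_error(derive_richards(prof, 0), "positive")
})

test_that("generated tables have the design-implied shapes and keys", {
  des <- trial_design(seed = 5)
  trial <- generate_trial(cultivar_profiles(), des)
  n_plots <- 2 * 5 * 4 * 3
  expect_equal(nrow(trial$grain_series), n_plots * length(des$sampling_days))
  expect_equal(nrow(trial$spad_series), n_plots * length(des$spad_days))
  expect_equal(nrow(trial$yields), n_plots)
  expect_equal(nrow(trial$organ_n), n_plots * 7)  # 3 organs + 4 at maturity
  expect_equal(anyDuplicated(trial$grain_series[c("plot_id", "day_post_anthesis")]), 0)
  expect_true(all(trial$grain_series$grain_weight > 0))
})

test_that("a degenerate one-cultivar one-rate design still validates", {
  des <- trial_design(n_rates = 150, reps = 1L, seed = 2)
  trial <- generate_trial(cultivar_profiles()[5, ], des)
  v <- validate_trial(trial)
  expect_false(any(v$status == "fail"))
  expect_equal(nrow(trial$yields), 2)
})

test_that("identical seeds give byte-identical CSVs; different seeds differ", {
  d1 <- file.path(tempdir(), "trial_a"); d2 <- file.path(tempdir(), "trial_b")
  d3 <- file.path(tempdir(), "trial_c")
  write_trial_csvs(generate_trial(cultivar_profiles(), trial_design(seed = 9)), d1)
  write_trial_csvs(generate_trial(cultivar_profiles(), trial_design(seed = 9)), d2)
  write_trial_csvs(generate_trial(cultivar_profiles(), trial_design(seed = 10)), d3)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_false(identical(readLines(file.path(d1, "yields.csv")),
                         readLines(file.path(d3, "yields.csv"))))
  back <- read_trial_csvs(d1)
  expect_false(any(validate_trial(back)$status == "fail"))
})

test_that("noiseless organ pools satisfy the nitrogen mass balances exactly", {
  trial <- generate_trial(cultivar_profiles(), noiseless())
  org <- dplyr::mutate(trial$organ_n,
                       n_amount = biomass_g_m2 * n_conc_pct / 100)
  pools <- org |>
    dplyr::group_by(plot_id, cultivar, n_rate_kg_ha) |>
    dplyr::summarise(
      n_aa = sum(n_amount[stage == "anthesis"]),
      n_gm = sum(n_amount[stage == "maturity" & organ == "grain"]),
      n_vtm = sum(n_amount[stage == "maturity" & organ != "grain"]),
      .groups = "drop")
  prof <- cultivar_profiles()
  i <- match(pools$cultivar, prof$name)
  nta <- pools$n_aa - pools$n_vtm
  post <- prof$post_uptake_frac[i] * pools$n_gm
  # grain N = translocated N + post-anthesis uptake, exactly
  expect_equal(pools$n_gm, nta + post, tolerance = 1e-9)
  # anthesis accumulation follows the profile response
  expect_equal(pools$n_aa,
               prof$naa_base[i] + prof$naa_per_n[i] * pools$n_rate_kg_ha,
               tolerance = 1e-9)
})

test_that("noiseless generation lets the pipeline recover the ground truth", {
  trial <- generate_trial(cultivar_profiles(), noiseless())
  res <- run_analysis(trial)
  prof <- cultivar_profiles()

  # yield response: slope, breakpoint and plateau per cultivar and year
  nr <- dplyr::inner_join(res$n_response, prof, by = c(cultivar = "name"))
  expect_equal(nr$n_r, nr$nr_true, tolerance = 1e-6)
  expect_equal(nr$n_cs, nr$ncs_true, tolerance = 1e-3)

  # fast-phase duration per plot matches the generating target
  rf <- dplyr::inner_join(res$richards_fits, prof, by = c(cultivar = "name"))
  expect_true(all(rf$converged))
  tfast_true <- rf$tfast_base + rf$tfast_per_n * rf$n_rate_kg_ha
  expect_equal(rf$T_fast, tfast_true, tolerance = 1e-3)

  # SPAD curvature reproduces the profile CDR at each rate
  sf <- dplyr::inner_join(res$senescence_fits, prof, by = c(cultivar = "name"))
  expect_equal(sf$cdr, sf$cdr_base + sf$cdr_per_n * sf$n_rate_kg_ha,
               tolerance = 1e-9)

  # translocation recovered from organ snapshots
  nb <- dplyr::inner_join(res$n_budget, prof, by = c(cultivar = "name"))
  expect_equal(nb$cnta, 100 * (1 - nb$post_uptake_frac), tolerance = 1e-6)
})
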