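#' Total above-ground N accumulation at a stage
#'
#' Sums organ N amounts (`N_stem + N_leaf + N_chaff [+ N_grain]`) for one
#' plot at one stage. The grain term only exists at maturity; at anthesis
#' the shoot total is stems + leaves + chaff.
#'
#' @param organ organ labels; subset of `"stem"`, `"leaf"`, `"chaff"`,
#'   `"grain"`, no duplicates.
#' @param n_amount N mass per area (g/m2), one per organ, >= 0.
#' @param stage `"anthesis"` or `"maturity"`.
#' @return list with `total` (g/m2) and `flag` (`"ok"` or
#'   `"missing_organ"` when a required organ is absent).
#' @export
total_n <- function(organ, n_amount, stage = c("anthesis", "maturity")) {
  stage <- match.arg(stage)
  if (length(organ) == 0L) stop("no organ samples supplied", call. = FALSE)
  stopifnot(length(organ) == length(n_amount), all(n_amount >= 0))
  organ <- match.arg(organ, c("stem", "leaf", "chaff", "grain"), several.ok = TRUE)
  if (anyDuplicated(organ)) stop("duplicate organ in one plot/stage", call. = FALSE)
  if (stage == "anthesis" && "grain" %in% organ)
    stop("grain organ is only sampled at maturity", call. = FALSE)
  required <- if (stage == "anthesis") c("stem", "leaf", "chaff")
              else c("stem", "leaf", "chaff", "grain")
  list(total = sum(n_amount),
       flag = if (all(required %in% organ)) "ok" else "missing_organ")
}

#' Critical N concentration from the dilution curve
#'
#' The critical (just non-limiting) shoot N concentration declines with
#' crop mass following the allometric dilution curve
#' `NC_cri = 4.59 * W_shoot^(-0.41)` with `NC_cri` in % N and `W_shoot`
#' the above-ground biomass at anthesis in t/ha (Mg/ha) by default.
#' Dilution curves of this family are calibrated on biomass in t/ha; see
#' the methods vignette for the unit discussion and use `unit = "kg_ha"`
#' to evaluate the same power law on kg/ha directly.
#'
#' @param w_shoot shoot biomass at anthesis, > 0, in the unit given.
#' @param unit `"t_ha"` (default) or `"kg_ha"`.
#' @return critical N concentration (%).
#' @export
#' @examples
#' critical_n_conc(1)   # 4.59 % at 1 t/ha
critical_n_conc <- function(w_shoot, unit = c("t_ha", "kg_ha")) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(w_shoot), all(w_shoot > 0))
  4.59 * w_shoot^(-0.41)
}

#' Nitrogen nutrition index
#'
#' `NNI = NC_act / NC_cri`, the actual shoot N concentration divided by
#' the critical concentration from [critical_n_conc()] at the observed
#' biomass. `NNI ~ 1` indicates optimal N status; below 1, deficiency;
#' above 1, luxury uptake.
#'
#' @param nc_act actual shoot N concentration at anthesis (%), > 0.
#' @param w_shoot shoot biomass at anthesis (t/ha by default), > 0.
#' @inheritParams critical_n_conc
#' @return one-row [tibble::tibble]: `nc_act`, `nc_cri`, `w_shoot`, `nni`.
#' @export
nni <- function(nc_act, w_shoot, unit = c("t_ha", "kg_ha")) {
  unit <- match.arg(unit)
  stopifnot(all(nc_act > 0), all(w_shoot > 0))
  nc_cri <- critical_n_conc(w_shoot, unit)
  tibble::tibble(nc_act = nc_act, nc_cri = nc_cri,
                 w_shoot = w_shoot, nni = nc_act / nc_cri)
}

#' N use-efficiency indices
#'
#' Computes, on a common kg/ha basis,
#' * `nute` — N utilization efficiency, grain yield per unit plant N at
#'   maturity (kg grain per kg N),
#' * `nupe` — N uptake efficiency, plant N at maturity per unit effective
#'   N supply (kg/kg, dimensionless),
#' * `nue`  — N use efficiency, grain yield per unit effective N supply
#'   (kg grain per kg N), identically `nute * nupe`.
#'
#' Inputs arrive in the units they are measured in and are converted
#' internally: grain yield t/ha -> kg/ha (x1000), plant N g/m2 -> kg/ha
#' (x10). The effective supply `n_e` is fertilizer N plus plant-available
#' soil N (0-30 cm), already in kg/ha.
#'
#' @param gy grain yield (t/ha), > 0.
#' @param n_am above-ground N accumulation at maturity (g/m2), > 0.
#' @param n_e effective N supply (kg/ha), > 0.
#' @return one-row [tibble::tibble]: `nute`, `nupe`, `nue`, `n_e`.
#' @export
#' @examples
#' efficiency_indices(gy = 6, n_am = 18, n_e = 200)
efficiency_indices <- function(gy, n_am, n_e) {
  stopifnot(all(gy > 0), all(n_am > 0), all(n_e > 0))
  gy_kg <- gy * 1000          # t/ha -> kg/ha
  nam_kg <- n_am * 10         # g/m2 -> kg/ha
  tibble::tibble(
    nute = gy_kg / nam_kg,
    nupe = nam_kg / n_e,
    nue  = gy_kg / n_e,
    n_e  = n_e)
}

#' N translocation amount, efficiency and grain contribution
#'
#' From anthesis and maturity N pools computes
#' * `nta  = n_aa - n_vtm` — N translocated from vegetative tissue to the
#'   grain during filling (g/m2),
#' * `nte  = 100 * nta / n_aa` — translocation efficiency (% of anthesis
#'   N remobilized),
#' * `cnta = 100 * nta / n_gm` — contribution of translocated N to grain
#'   N (%); its complement `100 - cnta` is the post-anthesis-uptake share
#'   of grain N.
#'
#' `n_vtm > n_aa` (net post-anthesis gain of vegetative N) yields a
#' negative `nta` with `flag = "negative_nta"` rather than an error.
#'
#' @param n_aa above-ground N at anthesis (g/m2), > 0.
#' @param n_vtm vegetative-tissue N at maturity (g/m2), >= 0.
#' @param n_gm grain N at maturity (g/m2), > 0.
#' @return one-row [tibble::tibble]: `nta`, `nte`, `cnta`, `n_am`
#'   (= `n_vtm + n_gm`), `flag`.
#' @export
#' @examples
#' translocation(n_aa = 15, n_vtm = 5, n_gm = 12)
translocation <- function(n_aa, n_vtm, n_gm) {
  stopifnot(all(n_aa > 0), all(n_vtm >= 0), all(n_gm > 0))
  nta <- n_aa - n_vtm
  tibble::tibble(
    nta = nta,
    nte = 100 * nta / n_aa,
    cnta = 100 * nta / n_gm,
    n_am = n_vtm + n_gm,
    flag = ifelse(nta < 0, "negative_nta", "ok"))
}

#' Per-organ N translocation
#'
#' Applies the translocation definition organ-wise: for each vegetative
#' organ, N at anthesis minus N at maturity. Summed over
#' \{leaf, stem, chaff\} this equals the whole-shoot `nta`.
#'
#' @param organ vegetative organ labels (subset of stem/leaf/chaff), no
#'   duplicates.
#' @param n_anthesis,n_maturity organ N (g/m2) at the two stages, aligned
#'   with `organ`.
#' @return [tibble::tibble] with `organ` and `nta_organ` columns.
#' @export
translocation_by_organ <- function(organ, n_anthesis, n_maturity) {
  organ <- match.arg(organ, c("stem", "leaf", "chaff"), several.ok = TRUE)
  stopifnot(length(organ) == length(n_anthesis),
            length(organ) == length(n_maturity),
            !anyDuplicated(organ))
  tibble::tibble(organ = organ, nta_organ = n_anthesis - n_maturity)
}
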