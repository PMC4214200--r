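#' Default per-condition generator settings
#'
#' Joins the three carbonate media of [culture_media()] with the kinetic
#' parameters of the batch simulation: the logistic midpoint of acetate
#' consumption (which lags slightly as CO2 rises, emulating the small rate
#' decrease observed in tri-cultures under elevated CO2), the logistic rate,
#' and the quasi-steady H2 plateau (tens of Pa, decreasing with CO2 since
#' the syntrophs draw H2 lower when acetate oxidation is more constrained).
#'
#' @return A tibble: `condition`, `bicarbonate_added_m`,
#'   `co2_headspace_atm`, `ph`, `t_mid_days`, `rate_per_day`,
#'   `h2_plateau_pa`.
#' @examples
#' default_conditions()
#' @export
default_conditions <- function() {
  culture_media() |>
    mutate(
      t_mid_days = c(6, 6.75, 7.5),
      rate_per_day = 1,
      h2_plateau_pa = c(50, 28, 21)
    )
}

#' Batch tri-culture generator configuration
#'
#' Collects everything the synthetic time-course generator needs: the vial,
#' the per-condition media/kinetics table, initial acetate, the sampling
#' grid, replication, the noise model, and the CH4 yield per acetate
#' (1 mol/mol; the generator refuses super-stoichiometric yields).
#'
#' @param conditions Per-condition table as from [default_conditions()].
#' @param vial A [vial_spec()].
#' @param initial_acetate_m Initial acetate, mol/L.
#' @param duration_days,dt_days Sampling span and interval, days.
#' @param n_replicates Number of replicate cultures per condition.
#' @param noise_cv Relative SD of the multiplicative lognormal measurement
#'   noise applied to each analyte (mean-preserving).
#' @param ch4_yield mol CH4 produced per mol acetate consumed; must be in
#'   (0, 1].
#' @param h2_ramp_days Time constant of the initial H2 rise, days.
#' @param abundance_cv Relative SD of replicate noise in the 16S
#'   copy-number generator.
#' @return An object of class `generator_config` (a validated list).
#' @examples
#' generator_config(noise_cv = 0)
#' @export
generator_config <- function(conditions = default_conditions(),
                             vial = vial_spec(),
                             initial_acetate_m = 0.040,
                             duration_days = 15,
                             dt_days = 1,
                             n_replicates = 3,
                             noise_cv = 0.05,
                             ch4_yield = 1,
                             h2_ramp_days = 0.3,
                             abundance_cv = 0.1) {
  stopifnot(inherits(vial, "vial_spec"), is.data.frame(conditions))
  need <- c("condition", "bicarbonate_added_m", "co2_headspace_atm", "ph",
            "t_mid_days", "rate_per_day", "h2_plateau_pa")
  missing <- setdiff(need, names(conditions))
  if (length(missing))
    abort(paste0("`conditions` is missing columns: ",
                 paste(missing, collapse = ", ")))
  if (n_replicates < 1) abort("`n_replicates` must be >= 1.")
  if (noise_cv < 0 || abundance_cv < 0) abort("noise SDs must be >= 0.")
  if (initial_acetate_m <= 0) abort("`initial_acetate_m` must be > 0.")
  if (duration_days <= 0 || dt_days <= 0)
    abort("`duration_days` and `dt_days` must be > 0.")
  if (ch4_yield <= 0 || ch4_yield > 1)
    abort(paste0("`ch4_yield` must be in (0, 1]: more CH4 than acetate ",
                 "consumed is super-stoichiometric."))
  ## H2 plateaus must fall as total inorganic carbon rises (the observed
  ## condition ordering); validate against the speciation of each medium.
  sigma <- vapply(seq_len(nrow(conditions)), function(i) {
    med <- medium_spec(conditions$bicarbonate_added_m[i],
                       conditions$co2_headspace_atm[i],
                       ph = conditions$ph[i])
    speciate_closed_vial(vial, med)$total_inorganic_carbon_mm
  }, numeric(1))
  ord <- order(sigma)
  if (any(diff(conditions$h2_plateau_pa[ord]) >= 0))
    abort(paste0("`h2_plateau_pa` must be strictly decreasing with ",
                 "increasing initial total inorganic carbon."))
  structure(
    list(conditions = conditions, vial = vial,
         initial_acetate_m = initial_acetate_m,
         duration_days = duration_days, dt_days = dt_days,
         n_replicates = n_replicates, noise_cv = noise_cv,
         ch4_yield = ch4_yield, h2_ramp_days = h2_ramp_days,
         abundance_cv = abundance_cv,
         sigma_co2_mm = setNames(sigma, as.character(conditions$condition))),
    class = "generator_config"
  )
}

## Noise-free trajectory for one condition: logistic acetate decay,
## stoichiometric CH4 to the headspace, inorganic carbon re-speciated from
## the initial pool plus biogenic HCO3- (both routes net 1 HCO3- per
## acetate), and H2 ramping to a quasi-steady plateau then collapsing as
## acetate runs out.
condition_truth <- function(cond, config) {
  vial <- config$vial
  days <- seq(0, config$duration_days, by = config$dt_days)
  a0 <- config$initial_acetate_m /
    (1 + exp(cond$rate_per_day * (0 - cond$t_mid_days)))
  acetate_m <- config$initial_acetate_m /
    (1 + exp(cond$rate_per_day * (days - cond$t_mid_days)))
  consumed_mol <- (a0 - acetate_m) * vial$liquid_volume_l
  ch4_mol <- config$ch4_yield * consumed_mol
  p_ch4_atm <- ch4_mol * R_LATM * vial$temperature_k /
    vial$headspace_volume_l
  med <- medium_spec(cond$bicarbonate_added_m, cond$co2_headspace_atm,
                     ph = cond$ph)
  n0 <- cond$bicarbonate_added_m * vial$liquid_volume_l +
    cond$co2_headspace_atm * vial$headspace_volume_l /
      (R_LATM * vial$temperature_k)
  spec <- speciate_total_carbon(n0 + consumed_mol, vial, med)
  p_h2_pa <- cond$h2_plateau_pa *
    (1 - exp(-days / config$h2_ramp_days)) *
    acetate_m / (acetate_m + 0.005 * config$initial_acetate_m)
  tibble(
    condition = cond$condition,
    day = days,
    temperature_k = vial$temperature_k,
    ph = cond$ph,
    acetate_mm = acetate_m * 1000,
    bicarbonate_mm = spec$bicarbonate_m * 1000,
    p_ch4_atm = p_ch4_atm,
    p_h2_pa = p_h2_pa,
    p_co2_atm = spec$p_co2_atm,
    ch4_mol = ch4_mol,
    consumed_acetate_mol = consumed_mol
  )
}

## Mean-preserving multiplicative lognormal noise.
ln_noise <- function(x, cv, n) {
  if (cv == 0) return(x)
  sdlog <- sqrt(log(1 + cv^2))
  x * exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Simulate tri-culture batch time courses
#'
#' Generates replicate acetate / CH4 / H2 / bicarbonate trajectories for
#' each CO2 condition, with a retained noise-free ground-truth twin. The
#' noise-free twin satisfies exact mol-for-mol mass balance between acetate
#' consumed and CH4 produced (times the configured yield) and conserves
#' inorganic carbon through the closed-vial speciation. Replicates carry
#' independent multiplicative lognormal noise; the same seed reproduces the
#' output bit for bit.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed for the replicate noise.
#' @return A tibble of class `tri_culture_sim` with columns `condition`,
#'   `replicate`, `day`, `temperature_k`, `ph`, `acetate_mm`,
#'   `bicarbonate_mm`, `p_ch4_atm`, `p_h2_pa`. The noise-free twin is
#'   attached as attribute `"truth"` and available via [ground_truth()].
#' @examples
#' tc <- simulate_cultures(generator_config(noise_cv = 0), seed = 1)
#' head(tc)
#' @export
simulate_cultures <- function(config = generator_config(), seed = 1) {
  stopifnot(inherits(config, "generator_config"))
  truth <- bind_rows(lapply(seq_len(nrow(config$conditions)), function(i) {
    condition_truth(config$conditions[i, ], config)
  }))
  set.seed(seed)
  noisy <- bind_rows(lapply(seq_len(config$n_replicates), function(rep) {
    out <- truth[, c("condition", "day", "temperature_k", "ph",
                     "acetate_mm", "bicarbonate_mm", "p_ch4_atm", "p_h2_pa")]
    out$replicate <- rep
    n <- nrow(out)
    for (col in c("acetate_mm", "bicarbonate_mm", "p_ch4_atm", "p_h2_pa"))
      out[[col]] <- ln_noise(out[[col]], config$noise_cv, n)
    out
  }))
  noisy <- noisy |>
    select("condition", "replicate", "day", "temperature_k", "ph",
           "acetate_mm", "bicarbonate_mm", "p_ch4_atm", "p_h2_pa") |>
    arrange(.data$condition, .data$replicate, .data$day)
  structure(noisy,
            truth = truth,
            config = config,
            class = c("tri_culture_sim", class(noisy)))
}

#' Ground truth of a simulated time course
#'
#' @param x A `tri_culture_sim` object from [simulate_cultures()].
#' @return The noise-free twin tibble (per condition and day), including the
#'   cumulative CH4 and consumed acetate in mol.
#' @examples
#' ground_truth(simulate_cultures(seed = 1))
#' @export
ground_truth <- function(x) {
  truth <- attr(x, "truth")
  if (is.null(truth)) abort("`x` carries no ground-truth attribute.")
  truth
}

#' Default condition-wise suppression of the syntrophic partners
#'
#' Expected fold-change of each organism's 16S copy number relative to the
#' low-CO2 condition: the aceticlastic methanogen is unaffected while both
#' syntrophic partners decline as CO2 rises.
#'
#' @return A tibble: `organism`, `condition`, `factor`.
#' @examples
#' default_suppression()
#' @export
default_suppression <- function() {
  conds <- levels(culture_media()$condition)
  bind_rows(
    tibble(organism = "Methanosaeta_thermophila", condition = conds,
           factor = c(1, 1, 1)),
    tibble(organism = "Thermacetogenium_phaeum", condition = conds,
           factor = c(1, 0.6, 0.3)),
    tibble(organism = "Methanothermobacter_thermautotrophicus",
           condition = conds, factor = c(1, 0.6, 0.3))
  ) |>
    mutate(condition = factor(.data$condition, levels = conds))
}

#' Simulate 16S rRNA copy-number tables
#'
#' Emits copy numbers per organism x condition x replicate with lognormal
#' replicate noise, where each organism's condition-wise expectation is its
#' baseline times the given suppression factor (so the configured factor is
#' the ground-truth normalized abundance).
#'
#' @param config A [generator_config()] (supplies replicate count,
#'   abundance noise and condition labels).
#' @param suppression Tibble `organism`, `condition`, `factor` (> 0), as
#'   [default_suppression()].
#' @param seed Integer seed.
#' @param baseline Named baseline copy numbers per organism (copies/ml);
#'   organisms absent from it get 1e8.
#' @return A tibble: `organism`, `condition`, `replicate`, `copies`.
#' @examples
#' simulate_abundances(generator_config(), seed = 1)
#' @export
simulate_abundances <- function(config = generator_config(),
                                suppression = default_suppression(),
                                seed = 1,
                                baseline = c(
                                  Methanosaeta_thermophila = 2e8,
                                  Thermacetogenium_phaeum = 5e7,
                                  Methanothermobacter_thermautotrophicus = 1e8
                                )) {
  stopifnot(inherits(config, "generator_config"))
  if (any(suppression$factor <= 0)) abort("suppression factors must be > 0.")
  set.seed(seed)
  grid <- tidyr::crossing(suppression,
                          replicate = seq_len(config$n_replicates))
  base <- ifelse(grid$organism %in% names(baseline),
                 baseline[grid$organism], 1e8)
  grid$copies <- ln_noise(base * grid$factor, config$abundance_cv,
                          nrow(grid))
  grid |>
    select("organism", "condition", "replicate", "copies") |>
    arrange(.data$organism, .data$condition, .data$replicate)
}
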