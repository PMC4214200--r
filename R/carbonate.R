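#' Serum-vial geometry
#'
#' Describes the closed culture vessel: total capacity, liquid (medium)
#' volume, and incubation temperature. The default is the 68-ml serum vial
#' holding 20 ml of medium incubated at 55 degC (328.15 K) used for the
#' thermophilic tri-culture.
#'
#' @param total_volume_l Total vial capacity in liters.
#' @param liquid_volume_l Medium volume in liters; must be positive and
#'   strictly less than `total_volume_l`.
#' @param temperature_k Incubation temperature in kelvin.
#'
#' @return An object of class `vial_spec`: a list with the three fields plus
#'   the derived `headspace_volume_l`.
#' @examples
#' vial_spec()
#' @export
vial_spec <- function(total_volume_l = 0.068,
                      liquid_volume_l = 0.020,
                      temperature_k = 328.15) {
  if (!is.numeric(total_volume_l) || total_volume_l <= 0)
    abort("`total_volume_l` must be a positive number.")
  if (!is.numeric(liquid_volume_l) || liquid_volume_l <= 0 ||
      liquid_volume_l >= total_volume_l)
    abort("`liquid_volume_l` must satisfy 0 < liquid_volume_l < total_volume_l.")
  if (!is.numeric(temperature_k) || temperature_k <= 0)
    abort("`temperature_k` must be > 0.")
  structure(
    list(
      total_volume_l = total_volume_l,
      liquid_volume_l = liquid_volume_l,
      headspace_volume_l = total_volume_l - liquid_volume_l,
      temperature_k = temperature_k
    ),
    class = "vial_spec"
  )
}

#' Culture-medium carbonate configuration
#'
#' Amount of sodium bicarbonate added to the medium, the CO2 fraction of the
#' (1 atm total) headspace gas, the adjusted pH, and the two equilibrium
#' constants governing CO2 dissolution and the first carbonate dissociation.
#'
#' The Henry constant default is 0.019 mol/(L.atm), the value for CO2 at
#' 55 degC. The first dissociation constant defaults to 4.47e-7 mol/L
#' (pK1 ~ 6.35); it is a parameter so alternative conventions can be forced.
#'
#' @param bicarbonate_added_m NaHCO3 added, mol per liter of medium.
#' @param co2_headspace_atm CO2 partial pressure of the initial headspace in
#'   atm (a fraction of 1 atm total pressure, 0-1).
#' @param ph Medium pH (held fixed; the cultures are adjusted to 7.0 and
#'   drift less than 0.2 units).
#' @param henry_constant Henry constant for CO2, mol/(L.atm).
#' @param k1 First carbonate acid dissociation constant, mol/L.
#'
#' @return An object of class `medium_spec` (a validated list).
#' @examples
#' medium_spec(bicarbonate_added_m = 0.035, co2_headspace_atm = 0.2)
#' @export
medium_spec <- function(bicarbonate_added_m = 0,
                        co2_headspace_atm = 0,
                        ph = 7,
                        henry_constant = 0.019,
                        k1 = 4.47e-7) {
  stopifnot(is.numeric(bicarbonate_added_m), is.numeric(co2_headspace_atm),
            is.numeric(ph), is.numeric(henry_constant), is.numeric(k1))
  if (bicarbonate_added_m < 0) abort("`bicarbonate_added_m` must be >= 0.")
  if (co2_headspace_atm < 0 || co2_headspace_atm > 1)
    abort("`co2_headspace_atm` must lie in [0, 1] (fraction of 1 atm).")
  if (ph < 0 || ph > 14) abort("`ph` must lie in [0, 14].")
  if (henry_constant <= 0) abort("`henry_constant` must be > 0.")
  if (k1 <= 0) abort("`k1` must be > 0.")
  structure(
    list(
      bicarbonate_added_m = bicarbonate_added_m,
      co2_headspace_atm = co2_headspace_atm,
      ph = ph,
      henry_constant = henry_constant,
      k1 = k1
    ),
    class = "medium_spec"
  )
}

#' Dissolved CO2 from Henry's law
#'
#' `c_aq = k * p`: the aqueous CO2 concentration in equilibrium with a gas
#' phase at partial pressure `p_co2_atm`.
#'
#' @param p_co2_atm CO2 partial pressure, atm (>= 0).
#' @param henry_constant Henry constant, mol/(L.atm).
#' @return Dissolved CO2 concentration, mol/L.
#' @examples
#' dissolved_co2(0.2) # 3.8e-3 M
#' @export
dissolved_co2 <- function(p_co2_atm, henry_constant = 0.019) {
  if (any(p_co2_atm < 0)) abort("`p_co2_atm` must be >= 0.")
  if (any(henry_constant <= 0)) abort("`henry_constant` must be > 0.")
  henry_constant * p_co2_atm
}

#' Bicarbonate in equilibrium with dissolved CO2
#'
#' First carbonate dissociation (H2CO3* = H+ + HCO3-):
#' `[HCO3-] = K1 [CO2(aq)] / [H+]` with `[H+] = 10^-pH`.
#'
#' @param co2_aq Dissolved CO2, mol/L (>= 0).
#' @param ph Solution pH.
#' @param k1 First dissociation constant, mol/L.
#' @return Bicarbonate concentration, mol/L.
#' @examples
#' bicarbonate_at_equilibrium(0.019, ph = 7) # ~0.085 M
#' @export
bicarbonate_at_equilibrium <- function(co2_aq, ph, k1 = 4.47e-7) {
  if (any(co2_aq < 0)) abort("`co2_aq` must be >= 0.")
  if (any(k1 <= 0)) abort("`k1` must be > 0.")
  k1 * co2_aq / 10^(-ph)
}

## Distribute a known total amount of inorganic carbon (mol) over headspace
## CO2, aqueous CO2 and bicarbonate so that Henry's law and the K1
## equilibrium hold simultaneously at the medium pH.
##
## All three pools are proportional to the equilibrium CO2 partial pressure
## p, so the balance
##   n = p*Vh/(R*T) + k*p*Vl + K1*k*p/[H+] * Vl
## is linear in p and solved in closed form.
speciate_total_carbon <- function(n_total_mol, vial, medium) {
  stopifnot(inherits(vial, "vial_spec"), inherits(medium, "medium_spec"))
  if (any(n_total_mol < 0)) abort("total inorganic carbon must be >= 0.")
  h <- 10^(-medium$ph)
  gas_cap <- vial$headspace_volume_l / (R_LATM * vial$temperature_k)
  aq_cap  <- medium$henry_constant * vial$liquid_volume_l
  bic_cap <- medium$k1 * medium$henry_constant / h * vial$liquid_volume_l
  denom <- gas_cap + aq_cap + bic_cap
  p <- n_total_mol / denom
  if (any(!is.finite(p)))
    abort("carbonate balance failed to produce a finite partial pressure.")
  tibble(
    p_co2_atm = p,
    co2_aq_m = medium$henry_constant * p,
    bicarbonate_m = medium$k1 * medium$henry_constant * p / h,
    co2_gas_mol = p * gas_cap,
    total_inorganic_carbon_mm =
      n_total_mol / vial$liquid_volume_l * 1000
  )
}

#' Closed-vial inorganic carbon speciation
#'
#' Takes the carbon loaded into a sealed vial -- NaHCO3 dissolved in the
#' medium plus CO2 in the initial headspace (ideal gas at the vial
#' temperature) -- and partitions it across headspace CO2, dissolved CO2
#' (Henry's law) and bicarbonate (first dissociation at the stated pH).
#' Carbon is conserved by construction; the total is reported per liter of
#' medium, the field's usual convention for total inorganic carbon.
#'
#' @param vial A [vial_spec()].
#' @param medium A [medium_spec()].
#' @return A one-row tibble: `p_co2_atm`, `co2_aq_m`, `bicarbonate_m`,
#'   `co2_gas_mol`, `total_inorganic_carbon_mm` (mmol per liter of medium).
#' @examples
#' speciate_closed_vial(vial_spec(),
#'                      medium_spec(bicarbonate_added_m = 0.035,
#'                                  co2_headspace_atm = 0.2))
#' @export
speciate_closed_vial <- function(vial, medium) {
  stopifnot(inherits(vial, "vial_spec"), inherits(medium, "medium_spec"))
  n_bic <- medium$bicarbonate_added_m * vial$liquid_volume_l
  n_gas <- medium$co2_headspace_atm * vial$headspace_volume_l /
    (R_LATM * vial$temperature_k)
  speciate_total_carbon(n_bic + n_gas, vial, medium)
}

#' Default culture media for the three CO2 conditions
#'
#' The three closed-vial carbonate setups used throughout the package:
#' 5 mM NaHCO3 under CO2-free headspace ("low"), 35 mM NaHCO3 under
#' 0.2 atm CO2 ("mid"), and 35 mM NaHCO3 under 1 atm CO2 ("high").
#'
#' @param ph Medium pH applied to all three conditions.
#' @return A tibble with columns `condition`, `bicarbonate_added_m`,
#'   `co2_headspace_atm`.
#' @examples
#' culture_media()
#' @export
culture_media <- function(ph = 7) {
  tibble(
    condition = factor(c("low", "mid", "high"),
                       levels = c("low", "mid", "high")),
    bicarbonate_added_m = c(0.005, 0.035, 0.035),
    co2_headspace_atm = c(0, 0.2, 1),
    ph = ph
  )
}
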