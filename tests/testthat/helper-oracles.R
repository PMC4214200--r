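# Independent oracles, written before the implementation paths they check.
# They share no code with the package internals: formation arithmetic,
# reaction quotients, the speciation balance and the H2 inversion are all
# re-derived here by hand.

R_KJ_H <- 8.3145e-3
R_LATM_H <- 0.082057
ATM_PA_H <- 101325

# standard transformed energies summed by hand from the shipped constants
ORACLE_DG0 <- list(
  aceticlastic = (-50.75 + -586.85) - (-369.41 + -237.18),
  acetate_oxidation = (2 * -586.85 + 4 * 0 + -39.83) - (-369.41 + 4 * -237.18),
  hydrogenotrophic = (-50.75 + 3 * -237.18) - (4 * 0 + -586.85 + -39.83)
)

# term-by-term dG, one hard-coded formula per reaction (no shared Q routine)
oracle_dg <- function(reaction, st) {
  rt <- R_KJ_H * st$temperature_k
  ac <- st$acetate_mm / 1000
  bic <- st$bicarbonate_mm / 1000
  ch4 <- st$p_ch4_atm
  h2 <- st$p_h2_pa / ATM_PA_H
  hplus <- (7 - st$ph) * log(10)
  switch(reaction,
    aceticlastic =
      ORACLE_DG0$aceticlastic + rt * (log(ch4) + log(bic) - log(ac)),
    acetate_oxidation =
      ORACLE_DG0$acetate_oxidation +
        rt * (2 * log(bic) + 4 * log(h2) + hplus - log(ac)),
    hydrogenotrophic =
      ORACLE_DG0$hydrogenotrophic +
        rt * (log(ch4) - 4 * log(h2) - log(bic) - hplus),
    stop("unknown reaction")
  )
}

# bisection-style root finding for the H2 pressure at which dG = target
oracle_solve_h2 <- function(reaction, st, target) {
  f <- function(p_pa) {
    st$p_h2_pa <- p_pa
    oracle_dg(reaction, st) - target
  }
  stats::uniroot(f, c(1e-3, 1e5), tol = 1e-12)$root
}

# 1-D root finding over aqueous CO2 for the closed-vial carbon balance
oracle_speciate <- function(n_total_mol, vial, medium) {
  h <- 10^(-medium$ph)
  f <- function(c_aq) {
    p <- c_aq / medium$henry_constant
    bic <- medium$k1 * c_aq / h
    gas <- p * vial$headspace_volume_l / (R_LATM_H * vial$temperature_k)
    (c_aq + bic) * vial$liquid_volume_l + gas - n_total_mol
  }
  upper <- max(n_total_mol / vial$liquid_volume_l, 1e-12) * 10 + 1
  c_aq <- stats::uniroot(f, c(0, upper), tol = 1e-15)$root
  list(
    co2_aq_m = c_aq,
    bicarbonate_m = medium$k1 * c_aq / h,
    p_co2_atm = c_aq / medium$henry_constant,
    co2_gas_mol = c_aq / medium$henry_constant *
      vial$headspace_volume_l / (R_LATM_H * vial$temperature_k)
  )
}

# random but physically plausible culture states
random_states <- function(n, seed) {
  set.seed(seed)
  culture_state(
    acetate_mm = stats::runif(n, 0.5, 45),
    bicarbonate_mm = stats::runif(n, 0.5, 80),
    p_ch4_atm = stats::runif(n, 0.001, 0.5),
    p_h2_pa = stats::runif(n, 0.5, 200),
    ph = stats::runif(n, 6.3, 7.7),
    temperature_k = stats::runif(n, 300, 340)
  )
}

# build a deltag_series object directly (for toy aggregation tests)
toy_series <- function(df, threshold = -20) {
  structure(tibble::as_tibble(df), threshold = threshold,
            class = c("deltag_series", class(tibble::tibble())))
}
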