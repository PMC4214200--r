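#' Standard Gibbs free energies of formation (pH-7 "primed" convention)
#'
#' The chemical species appearing in the three catabolic reactions, their
#' phase (which fixes the activity convention used in reaction quotients),
#' and their standard Gibbs free energy of formation at 25 degC.
#'
#' Aqueous species are referred to a 1 M standard state, gases to 1 atm,
#' water has activity 1, and the proton is handled in the transformed
#' ("primed") convention: its entry is the pH-7 transformation term, so that
#' coefficient-weighted sums over a reaction directly give the standard
#' transformed free energy change at pH 7. The proton term is
#' -39.83 kJ/mol, the value implied by the classical compilation of
#' catabolic reaction energies that this table is chosen to reproduce to
#' 0.1 kJ/mol (the textbook 25 degC value RT ln 1e-7 = -39.96 kJ/mol gives
#' reaction energies about 0.1 kJ/mol away from the canonical ones).
#'
#' @return A tibble with columns `species`, `phase`
#'   (`aqueous`/`gas`/`water`/`proton`), `formation_kj_mol`.
#' @examples
#' formation_energies()
#' @export
formation_energies <- function() {
  tribble(
    ~species,      ~phase,    ~formation_kj_mol,
    "acetate",     "aqueous", -369.41,
    "bicarbonate", "aqueous", -586.85,
    "methane",     "gas",     -50.75,
    "hydrogen",    "gas",     0,
    "water",       "water",   -237.18,
    "proton",      "proton",  -39.83
  )
}

## Elemental composition and charge, for validating reaction balance.
species_composition <- function() {
  tribble(
    ~species,      ~C, ~H, ~O, ~charge,
    "acetate",      2,  3,  2, -1,
    "bicarbonate",  1,  1,  3, -1,
    "methane",      1,  4,  0,  0,
    "hydrogen",     0,  2,  0,  0,
    "water",        0,  2,  1,  0,
    "proton",       0,  1,  0,  1
  )
}

#' The three catabolic reactions of the consortium
#'
#' Signed stoichiometry (products positive, reactants negative) of:
#' * `aceticlastic`: CH3COO- + H2O -> CH4 + HCO3-
#'   (*Methanosaeta thermophila*)
#' * `acetate_oxidation`: CH3COO- + 4 H2O -> 2 HCO3- + 4 H2 + H+
#'   (*Thermacetogenium phaeum*, the syntrophic acetate oxidizer)
#' * `hydrogenotrophic`: 4 H2 + HCO3- + H+ -> CH4 + 3 H2O
#'   (*Methanothermobacter thermautotrophicus*)
#'
#' The sum of the last two is exactly the first, which is the stoichiometric
#' identity behind the additivity of their free energy changes.
#'
#' @return A tibble with columns `reaction`, `species`, `coefficient`.
#' @examples
#' catabolic_reactions()
#' @export
catabolic_reactions <- function() {
  tribble(
    ~reaction,            ~species,      ~coefficient,
    "aceticlastic",       "acetate",     -1,
    "aceticlastic",       "water",       -1,
    "aceticlastic",       "methane",      1,
    "aceticlastic",       "bicarbonate",  1,
    "acetate_oxidation",  "acetate",     -1,
    "acetate_oxidation",  "water",       -4,
    "acetate_oxidation",  "bicarbonate",  2,
    "acetate_oxidation",  "hydrogen",     4,
    "acetate_oxidation",  "proton",       1,
    "hydrogenotrophic",   "hydrogen",    -4,
    "hydrogenotrophic",   "bicarbonate", -1,
    "hydrogenotrophic",   "proton",      -1,
    "hydrogenotrophic",   "methane",      1,
    "hydrogenotrophic",   "water",        3
  )
}

#' Check elemental and charge balance of reactions
#'
#' Sums C, H, O and charge over each reaction's signed stoichiometry
#' (integer arithmetic); a balanced reaction sums to zero in every column.
#'
#' @param reactions A reaction table as from [catabolic_reactions()].
#' @return A tibble with one row per reaction and columns `C`, `H`, `O`,
#'   `charge` giving the (should-be-zero) imbalance.
#' @examples
#' reaction_balance(catabolic_reactions())
#' @export
reaction_balance <- function(reactions = catabolic_reactions()) {
  comp <- species_composition()
  missing <- setdiff(unique(reactions$species), comp$species)
  if (length(missing))
    abort(paste0("No elemental composition for species: ",
                 paste(missing, collapse = ", ")))
  reactions |>
    left_join(comp, by = "species") |>
    group_by(.data$reaction) |>
    summarise(
      C = sum(.data$coefficient * .data$C),
      H = sum(.data$coefficient * .data$H),
      O = sum(.data$coefficient * .data$O),
      charge = sum(.data$coefficient * .data$charge),
      .groups = "drop"
    )
}

#' Standard transformed free energy change of reactions
#'
#' Coefficient-weighted sum of standard formation energies over each
#' reaction, in the pH-7 primed convention of [formation_energies()].
#' Reproduces the canonical values for the three built-in reactions:
#' -31.0 (aceticlastic), +104.6 (acetate oxidation) and -135.6
#' (hydrogenotrophic) kJ per mol of reaction as written (per mol acetate
#' for the two acetate reactions).
#'
#' @param reactions Reaction table ([catabolic_reactions()] format).
#' @param formation Formation-energy table ([formation_energies()] format).
#' @return A tibble with columns `reaction`, `dg0_kj_mol`.
#' @examples
#' delta_g_standard()
#' @export
delta_g_standard <- function(reactions = catabolic_reactions(),
                             formation = formation_energies()) {
  if (nrow(reactions) == 0)
    return(tibble(reaction = character(), dg0_kj_mol = numeric()))
  missing <- setdiff(unique(reactions$species), formation$species)
  if (length(missing))
    abort(paste0("No formation energy for species: ",
                 paste(missing, collapse = ", ")))
  reactions |>
    left_join(formation[, c("species", "formation_kj_mol")], by = "species") |>
    group_by(.data$reaction) |>
    summarise(
      dg0_kj_mol = sum(.data$coefficient * .data$formation_kj_mol),
      .groups = "drop"
    )
}

#' Construct a table of culture states
#'
#' A culture state is one time point's chemistry: temperature, pH, acetate
#' and bicarbonate concentrations, and CH4/H2 partial pressures. All
#' free-energy evaluation functions take a data frame with these columns,
#' one row per state; this helper builds and validates one. Aqueous
#' concentrations are in mM, CH4 in atm and H2 in Pa, matching the tidy
#' interchange CSV (the interface converts to activity scales internally).
#'
#' @param acetate_mm Acetate concentration, mM.
#' @param bicarbonate_mm Bicarbonate concentration, mM.
#' @param p_ch4_atm CH4 partial pressure, atm.
#' @param p_h2_pa H2 partial pressure, Pa.
#' @param ph pH.
#' @param temperature_k Temperature, kelvin.
#' @param day Optional day label.
#' @return A tibble with the validated state columns.
#' @examples
#' culture_state(acetate_mm = 30, bicarbonate_mm = 1, p_ch4_atm = 0.1,
#'               p_h2_pa = 16.4)
#' @export
culture_state <- function(acetate_mm, bicarbonate_mm, p_ch4_atm, p_h2_pa,
                          ph = 7, temperature_k = 328.15, day = NA_real_) {
  out <- tibble(
    day = day,
    temperature_k = temperature_k,
    ph = ph,
    acetate_mm = acetate_mm,
    bicarbonate_mm = bicarbonate_mm,
    p_ch4_atm = p_ch4_atm,
    p_h2_pa = p_h2_pa
  )
  bad <- c("acetate_mm", "bicarbonate_mm", "p_ch4_atm", "p_h2_pa")[
    vapply(out[c("acetate_mm", "bicarbonate_mm", "p_ch4_atm", "p_h2_pa")],
           function(x) any(x < 0, na.rm = TRUE), logical(1))]
  if (length(bad))
    abort(paste0("Negative values not allowed in: ", paste(bad, collapse = ", ")))
  if (any(out$temperature_k <= 0)) abort("`temperature_k` must be > 0.")
  out
}

## Activity (on the standard-state scale) of one species in one or more
## states. Aqueous: mol/L vs 1 M; gas: atm vs 1 atm (H2 arrives in Pa);
## water: 1; proton: 10^(7 - pH) in the primed convention.
species_activity <- function(species, states) {
  switch(
    species,
    acetate     = states$acetate_mm / 1000,
    bicarbonate = states$bicarbonate_mm / 1000,
    methane     = states$p_ch4_atm,
    hydrogen    = states$p_h2_pa / ATM_PA,
    water       = rep(1, nrow(states)),
    proton      = 10^(7 - states$ph),
    abort(paste0("Unknown species `", species, "` in reaction."))
  )
}

state_cols <- c("temperature_k", "ph", "acetate_mm", "bicarbonate_mm",
                "p_ch4_atm", "p_h2_pa")

check_states <- function(states) {
  if (!is.data.frame(states)) abort("`states` must be a data frame.")
  missing <- setdiff(state_cols, names(states))
  if (length(missing))
    abort(paste0("`states` is missing required columns: ",
                 paste(missing, collapse = ", ")))
  invisible(states)
}

#' Log reaction quotient of a reaction in given culture states
#'
#' `ln Q = sum_i nu_i ln a_i` over the reaction's species, with the phase
#' conventions of [formation_energies()]: water contributes 0 and the proton
#' contributes `(7 - pH) ln 10` per unit coefficient. A species with nonzero
#' coefficient and zero activity is a domain error (the quotient diverges).
#'
#' @param states Data frame of culture states (see [culture_state()]).
#' @param reaction Reaction name in `reactions`.
#' @param reactions Reaction table.
#' @return Numeric vector, one `ln Q` per state row.
#' @examples
#' st <- culture_state(acetate_mm = 30, bicarbonate_mm = 1,
#'                     p_ch4_atm = 0.1, p_h2_pa = 20)
#' ln_reaction_quotient(st, "aceticlastic")
#' @export
ln_reaction_quotient <- function(states, reaction,
                                 reactions = catabolic_reactions()) {
  check_states(states)
  stoich <- reactions[reactions$reaction == reaction, ]
  if (nrow(stoich) == 0)
    abort(paste0("Unknown reaction `", reaction, "`."))
  lnq <- rep(0, nrow(states))
  for (i in seq_len(nrow(stoich))) {
    sp <- stoich$species[i]
    nu <- stoich$coefficient[i]
    if (sp == "water") next
    if (sp == "proton") {
      lnq <- lnq + nu * (7 - states$ph) * log(10)
      next
    }
    a <- species_activity(sp, states)
    if (any(a <= 0, na.rm = TRUE))
      abort(paste0("Zero or negative activity for species `", sp,
                   "` with nonzero coefficient."))
    lnq <- lnq + nu * log(a)
  }
  lnq
}

#' In-situ Gibbs free energy change of reactions
#'
#' `dG = dG0' + R T ln Q` with `R = 8.3145e-3` kJ/(mol.K) and the state's
#' temperature; the 25 degC standard values are combined with the
#' culture-temperature `RT ln Q` term (no van't Hoff enthalpy correction),
#' which reproduces the worked H2-shift arithmetic of the source system.
#' A reaction is flagged feasible when its dG does not exceed the energy-
#' conservation threshold (default -20 kJ/mol, the approximate minimum
#' catabolic energy quantum).
#'
#' @param states Data frame of culture states (see [culture_state()]);
#'   extra columns (condition, replicate, day, ...) are carried through.
#' @param reactions Reaction table; all reactions in it are evaluated
#'   against every state row.
#' @param threshold Feasibility threshold, kJ/mol.
#' @param formation Formation-energy table.
#' @return A tibble: the state rows crossed with reactions, with columns
#'   `reaction`, `dg0_kj_mol`, `dg_kj_mol`, `feasible` appended.
#' @examples
#' st <- culture_state(acetate_mm = 30, bicarbonate_mm = 1,
#'                     p_ch4_atm = 0.1, p_h2_pa = 20)
#' delta_g(st)
#' @export
delta_g <- function(states, reactions = catabolic_reactions(),
                    threshold = -20, formation = formation_energies()) {
  check_states(states)
  dg0 <- delta_g_standard(reactions, formation)
  out <- lapply(dg0$reaction, function(rx) {
    lnq <- ln_reaction_quotient(states, rx, reactions)
    g0 <- dg0$dg0_kj_mol[dg0$reaction == rx]
    dg <- g0 + R_KJ * states$temperature_k * lnq
    res <- as_tibble(states)
    res$reaction <- rx
    res$dg0_kj_mol <- g0
    res$dg_kj_mol <- dg
    res$feasible <- dg <= threshold
    res
  })
  bind_rows(out)
}

h2_coefficient <- function(reaction, reactions = catabolic_reactions()) {
  row <- reactions[reactions$reaction == reaction &
                     reactions$species == "hydrogen", ]
  if (nrow(row) == 0 || row$coefficient[1] == 0)
    abort(paste0("Reaction `", reaction, "` has no H2 term; ",
                 "an H2 shift or solve is meaningless for it."))
  row$coefficient[1]
}

#' Shift a free energy change to a different H2 partial pressure
#'
#' Counterfactual: keeps every activity except H2 fixed and moves the H2
#' partial pressure, so `dG` changes by `nu_H2 R T ln(p_to / p_from)`,
#' where `nu_H2` is the signed H2 stoichiometric coefficient (+4 for
#' acetate oxidation, -4 for hydrogenotrophic methanogenesis).
#'
#' @param dg Starting free energy change, kJ/mol.
#' @param reaction Reaction name (must involve H2).
#' @param p_h2_from_pa,p_h2_to_pa H2 partial pressures, Pa (> 0).
#' @param temperature_k Temperature, kelvin.
#' @param reactions Reaction table.
#' @return Shifted dG, kJ/mol.
#' @examples
#' # the worked example: -25.1 kJ/mol at 16.4 Pa moved to 10 Pa at 55 degC
#' shift_h2(-25.1, "hydrogenotrophic", 16.4, 10)
#' @export
shift_h2 <- function(dg, reaction, p_h2_from_pa, p_h2_to_pa,
                     temperature_k = 328.15,
                     reactions = catabolic_reactions()) {
  if (any(p_h2_from_pa <= 0) || any(p_h2_to_pa <= 0))
    abort("H2 partial pressures must be > 0.")
  nu <- h2_coefficient(reaction, reactions)
  dg + nu * R_KJ * temperature_k * log(p_h2_to_pa / p_h2_from_pa)
}

#' H2 partial pressure at which a reaction reaches a target free energy
#'
#' Closed-form inversion of `dG(p_H2) = target`: all activities other than
#' H2 are held at the state's values and the single exponential is solved
#' for the H2 partial pressure.
#'
#' @param reaction Reaction name (must involve H2).
#' @param states Data frame of culture states.
#' @param target_dg Target free energy change, kJ/mol.
#' @param reactions Reaction table.
#' @param formation Formation-energy table.
#' @return H2 partial pressure(s), Pa, one per state row.
#' @examples
#' st <- culture_state(acetate_mm = 30, bicarbonate_mm = 10,
#'                     p_ch4_atm = 0.1, p_h2_pa = 20)
#' solve_h2_for_target("hydrogenotrophic", st)
#' @export
solve_h2_for_target <- function(reaction, states, target_dg = -20,
                                reactions = catabolic_reactions(),
                                formation = formation_energies()) {
  check_states(states)
  nu <- h2_coefficient(reaction, reactions)
  dg0 <- delta_g_standard(reactions, formation)
  g0 <- dg0$dg0_kj_mol[dg0$reaction == reaction]
  ## ln Q with H2 at unit activity isolates the non-H2 terms
  ref <- states
  ref$p_h2_pa <- ATM_PA
  lnq_other <- ln_reaction_quotient(ref, reaction, reactions)
  rt <- R_KJ * states$temperature_k
  ln_a <- (target_dg - g0 - rt * lnq_other) / (nu * rt)
  ATM_PA * exp(ln_a)
}

#' H2 feasibility window for syntrophic acetate degradation
#'
#' Syntrophy requires both partners to clear the energy threshold at the
#' same H2 partial pressure: the hydrogenotroph sets the floor (below
#' `h2_min_pa` it cannot conserve energy) and the acetate oxidizer sets the
#' ceiling (above `h2_max_pa` oxidation is too endergonic). An empty window
#' (`h2_min_pa > h2_max_pa`) signals that syntrophy is infeasible at that
#' state, regardless of where H2 settles.
#'
#' @param states Data frame of culture states.
#' @param threshold Energy threshold, kJ/mol.
#' @param reactions Reaction table.
#' @param formation Formation-energy table.
#' @return A tibble with one row per state: `h2_min_pa`, `h2_max_pa`,
#'   `window_open` (logical).
#' @examples
#' st <- culture_state(acetate_mm = 30, bicarbonate_mm = 5,
#'                     p_ch4_atm = 0.1, p_h2_pa = 20)
#' feasibility_window(st)
#' @export
feasibility_window <- function(states, threshold = -20,
                               reactions = catabolic_reactions(),
                               formation = formation_energies()) {
  check_states(states)
  lo <- solve_h2_for_target("hydrogenotrophic", states, threshold,
                            reactions, formation)
  hi <- solve_h2_for_target("acetate_oxidation", states, threshold,
                            reactions, formation)
  tibble(h2_min_pa = lo, h2_max_pa = hi, window_open = lo <= hi)
}
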