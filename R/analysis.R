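#' Per-day, per-reaction free energy series from time courses
#'
#' Applies [delta_g()] to every replicate-day record of a tidy time-course
#' table and keeps the replicate-level values; use [generics::tidy()] on the
#' result for per-day mean/SD, or [logphase_summary()] for window averages.
#' A replicate-day missing any analyte a reaction needs is dropped from that
#' reaction's series and logged in the `"dropped"` attribute, never imputed.
#'
#' @param timecourses Tidy time-course tibble with columns `condition`,
#'   `replicate`, `day` and the state columns of [culture_state()].
#' @param reactions Reaction table; all its reactions are evaluated.
#' @param threshold Feasibility threshold, kJ/mol.
#' @return A tibble of class `deltag_series`: `condition`, `reaction`,
#'   `day`, `replicate`, `p_h2_pa`, `temperature_k`, `dg_kj_mol`,
#'   `feasible`; attribute `"dropped"` lists skipped records.
#' @examples
#' tc <- simulate_cultures(seed = 1)
#' series <- compute_dg_series(tc)
#' generics::tidy(series)
#' @export
compute_dg_series <- function(timecourses,
                              reactions = catabolic_reactions(),
                              threshold = -20) {
  need <- c("condition", "replicate", "day", state_cols)
  missing <- setdiff(need, names(timecourses))
  if (length(missing))
    abort(paste0("`timecourses` is missing columns: ",
                 paste(missing, collapse = ", ")))
  tc <- as_tibble(timecourses)[, need]

  ## which analytes each reaction needs, as state columns
  col_for <- c(acetate = "acetate_mm", bicarbonate = "bicarbonate_mm",
               methane = "p_ch4_atm", hydrogen = "p_h2_pa")
  series <- lapply(unique(reactions$reaction), function(rx) {
    sp <- reactions$species[reactions$reaction == rx]
    cols <- unname(col_for[intersect(sp, names(col_for))])
    usable <- stats::complete.cases(tc[, cols]) &
      rowSums(tc[, cols, drop = FALSE] <= 0) == 0
    ok <- tc[usable, ]
    dg <- delta_g(ok, reactions[reactions$reaction == rx, ],
                  threshold = threshold)
    dropped <- tc[!usable, c("condition", "replicate", "day")]
    if (nrow(dropped)) dropped$reaction <- rx
    list(dg = dg, dropped = dropped)
  })
  out <- bind_rows(lapply(series, `[[`, "dg")) |>
    select("condition", "reaction", "day", "replicate", "p_h2_pa",
           "temperature_k", "dg_kj_mol", "feasible") |>
    arrange(.data$condition, .data$reaction, .data$day, .data$replicate)
  structure(out,
            dropped = bind_rows(lapply(series, `[[`, "dropped")),
            threshold = threshold,
            class = c("deltag_series", class(out)))
}

#' @rdname compute_dg_series
#' @param x A `deltag_series`.
#' @param ... Unused.
#' @export
tidy.deltag_series <- function(x, ...) {
  threshold <- attr(x, "threshold")
  as_tibble(x) |>
    group_by(.data$condition, .data$reaction, .data$day) |>
    summarise(
      n = dplyr::n(),
      mean_dg_kj_mol = mean(.data$dg_kj_mol),
      sd_dg_kj_mol = if (dplyr::n() > 1) sd(.data$dg_kj_mol) else 0,
      .groups = "drop"
    ) |>
    mutate(feasible = .data$mean_dg_kj_mol <= threshold)
}

#' @rdname compute_dg_series
#' @export
glance.deltag_series <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$condition, .data$reaction) |>
    summarise(
      n_days = dplyr::n_distinct(.data$day),
      n_values = dplyr::n(),
      mean_dg_kj_mol = mean(.data$dg_kj_mol),
      min_dg_kj_mol = min(.data$dg_kj_mol),
      max_dg_kj_mol = max(.data$dg_kj_mol),
      .groups = "drop"
    )
}

#' Log-phase average free energy per condition and reaction
#'
#' Pools every replicate-day value whose day lies in the closed window
#' (default days 2-5, the exponential-growth phase of these batch cultures)
#' and reports mean, sample SD (n-1) and whether the mean exceeds the
#' energy-conservation threshold.
#'
#' @param series A `deltag_series` from [compute_dg_series()].
#' @param window Closed day window `c(first, last)`.
#' @param threshold Threshold, kJ/mol; defaults to the series' own.
#' @return A tibble: `condition`, `reaction`, `day_start`, `day_end`, `n`,
#'   `mean_dg_kj_mol`, `sd_dg_kj_mol`, `exceeds_threshold`.
#' @examples
#' tc <- simulate_cultures(seed = 1)
#' logphase_summary(compute_dg_series(tc))
#' @export
logphase_summary <- function(series, window = c(2, 5), threshold = NULL) {
  if (length(window) != 2 || window[1] > window[2])
    abort("`window` must be c(first_day, last_day) with first <= last.")
  if (is.null(threshold)) threshold <- attr(series, "threshold") %||% -20
  inside <- as_tibble(series) |>
    filter(.data$day >= window[1], .data$day <= window[2])
  if (nrow(inside) == 0)
    abort("`window` does not overlap any sampled day.")
  inside |>
    group_by(.data$condition, .data$reaction) |>
    summarise(
      day_start = window[1],
      day_end = window[2],
      n = dplyr::n(),
      mean_dg_kj_mol = mean(.data$dg_kj_mol),
      sd_dg_kj_mol = if (dplyr::n() > 1) sd(.data$dg_kj_mol) else 0,
      .groups = "drop"
    ) |>
    mutate(exceeds_threshold = .data$mean_dg_kj_mol > threshold)
}

#' Counterfactual H2 shift of a measured free energy series
#'
#' For each replicate at the given day, recomputes the chosen reaction's
#' free energy as if the H2 partial pressure had been `p_h2_to_pa` instead
#' of the measured value (all other activities unchanged), and summarizes
#' mean and SD before and after per condition.
#'
#' @param series A `deltag_series`.
#' @param day Sampled day to evaluate.
#' @param p_h2_to_pa Counterfactual H2 partial pressure, Pa.
#' @param reaction Reaction to shift (must involve H2).
#' @param reactions Reaction table.
#' @return A tibble per condition: `day`, `reaction`, `p_h2_to_pa`, `n`,
#'   `dg_before_mean`, `dg_before_sd`, `dg_after_mean`, `dg_after_sd`
#'   (kJ/mol).
#' @examples
#' tc <- simulate_cultures(seed = 1)
#' counterfactual_report(compute_dg_series(tc), day = 5, p_h2_to_pa = 10)
#' @export
counterfactual_report <- function(series, day, p_h2_to_pa,
                                  reaction = "hydrogenotrophic",
                                  reactions = catabolic_reactions()) {
  rx <- reaction
  at_day <- day
  to_pa <- p_h2_to_pa
  h2_coefficient(rx, reactions) # misuse guard: reaction must carry H2
  rows <- as_tibble(series) |>
    filter(.data$reaction == rx, .data$day == at_day)
  if (nrow(rows) == 0)
    abort(paste0("Day ", at_day, " is not sampled for reaction `",
                 rx, "`."))
  rows |>
    mutate(dg_after = shift_h2(.data$dg_kj_mol, rx,
                               p_h2_from_pa = .data$p_h2_pa,
                               p_h2_to_pa = to_pa,
                               temperature_k = .data$temperature_k,
                               reactions = reactions)) |>
    group_by(.data$condition) |>
    summarise(
      day = at_day,
      reaction = rx,
      p_h2_to_pa = to_pa,
      n = dplyr::n(),
      dg_before_mean = mean(.data$dg_kj_mol),
      dg_before_sd = if (dplyr::n() > 1) sd(.data$dg_kj_mol) else 0,
      dg_after_mean = mean(.data$dg_after),
      dg_after_sd = if (dplyr::n() > 1) sd(.data$dg_after) else 0,
      .groups = "drop"
    )
}

## Headspace CH4 partial pressure -> mol per liter of medium.
ch4_mol_per_l <- function(p_ch4_atm, vial) {
  p_ch4_atm * vial$headspace_volume_l /
    (R_LATM * vial$temperature_k * vial$liquid_volume_l)
}

#' Methanogenic rate from cumulative CH4
#'
#' Converts headspace CH4 partial pressure to mol per liter of medium via
#' the vial geometry and reports, per condition and replicate, the slope of
#' the least-squares line over the steepest contiguous 3-point window --
#' a robust maximum-rate estimate at the small n of batch samplings.
#'
#' @param timecourses Tidy time-course tibble (needs `condition`,
#'   `replicate`, `day`, `p_ch4_atm`).
#' @param vial The [vial_spec()] the pressures were measured in.
#' @return A tibble: `condition`, `replicate`, `rate_mol_l_day`,
#'   `window_start_day`, `window_end_day`.
#' @examples
#' tc <- simulate_cultures(seed = 1)
#' methanogenic_rate(tc)
#' @export
methanogenic_rate <- function(timecourses, vial = vial_spec()) {
  stopifnot(inherits(vial, "vial_spec"))
  as_tibble(timecourses) |>
    group_by(.data$condition, .data$replicate) |>
    group_modify(function(df, key) {
      df <- arrange(df, .data$day)
      if (nrow(df) < 3)
        abort("Rate estimation needs at least 3 time points per replicate.")
      ch4 <- ch4_mol_per_l(df$p_ch4_atm, vial)
      slopes <- vapply(seq_len(nrow(df) - 2), function(i) {
        idx <- i:(i + 2)
        unname(coef(lm(ch4[idx] ~ df$day[idx]))[2])
      }, numeric(1))
      best <- which.max(slopes)
      tibble(rate_mol_l_day = slopes[best],
             window_start_day = df$day[best],
             window_end_day = df$day[best + 2])
    }) |>
    ungroup()
}

#' Methanogenic rates relative to a reference condition
#'
#' Divides each condition's mean rate by the reference condition's mean
#' rate; the SD is propagated by the first-order delta method for a ratio
#' of means.
#'
#' @param rates Output of [methanogenic_rate()].
#' @param reference Reference condition label.
#' @return A tibble: `condition`, `n`, `relative_rate`, `sd`.
#' @examples
#' tc <- simulate_cultures(seed = 1)
#' relative_rate(methanogenic_rate(tc), reference = "low")
#' @export
relative_rate <- function(rates, reference = "low") {
  by_cond <- as_tibble(rates) |>
    group_by(.data$condition) |>
    summarise(n = dplyr::n(), mean_rate = mean(.data$rate_mol_l_day),
              sd_rate = if (dplyr::n() > 1) sd(.data$rate_mol_l_day) else 0,
              .groups = "drop")
  ref <- by_cond[as.character(by_cond$condition) == reference, ]
  if (nrow(ref) == 0)
    abort(paste0("Reference condition `", reference, "` not present."))
  if (ref$mean_rate == 0)
    abort("Reference condition has zero mean rate.")
  by_cond |>
    mutate(
      relative_rate = .data$mean_rate / ref$mean_rate,
      sd = .data$relative_rate *
        sqrt((.data$sd_rate / .data$mean_rate)^2 +
               (ref$sd_rate / ref$mean_rate)^2)
    ) |>
    select("condition", "n", "relative_rate", "sd")
}

#' Normalize 16S copy numbers against a reference condition
#'
#' Per organism, divides each condition's mean copy number by the reference
#' condition's mean; replicate scatter is propagated to the ratio by the
#' first-order delta method.
#'
#' @param copy_numbers Tibble `organism`, `condition`, `replicate`,
#'   `copies`.
#' @param reference Reference condition label.
#' @return A tibble: `organism`, `condition`, `n`, `relative_abundance`,
#'   `sd`.
#' @examples
#' ab <- simulate_abundances(generator_config(), seed = 1)
#' normalize_abundance(ab, reference = "low")
#' @export
normalize_abundance <- function(copy_numbers, reference = "low") {
  by_oc <- as_tibble(copy_numbers) |>
    group_by(.data$organism, .data$condition) |>
    summarise(n = dplyr::n(), mean_copies = mean(.data$copies),
              sd_copies = if (dplyr::n() > 1) sd(.data$copies) else 0,
              .groups = "drop")
  out <- by_oc |>
    group_by(.data$organism) |>
    group_modify(function(df, key) {
      ref <- df[as.character(df$condition) == reference, ]
      if (nrow(ref) == 0)
        abort(paste0("Reference condition `", reference,
                     "` missing for organism `", key$organism, "`."))
      if (ref$mean_copies == 0)
        abort(paste0("Zero reference mean for organism `",
                     key$organism, "`."))
      df |>
        mutate(
          relative_abundance = .data$mean_copies / ref$mean_copies,
          sd = .data$relative_abundance *
            sqrt((.data$sd_copies / .data$mean_copies)^2 +
                   (ref$sd_copies / ref$mean_copies)^2)
        )
    }) |>
    ungroup()
  out[, c("organism", "condition", "n", "relative_abundance", "sd")]
}

#' Molar ratio of CH4 produced to acetate consumed
#'
#' Compares, per condition and replicate, the CH4 accumulated in the
#' headspace between the first and last sampled day (converted to mol via
#' the vial geometry) with the acetate consumed in the medium over the same
#' span. Complete stoichiometric conversion gives 1.0.
#'
#' @param timecourses Tidy time-course tibble.
#' @param vial The [vial_spec()].
#' @return A tibble: `condition`, `replicate`, `acetate_consumed_mol`,
#'   `ch4_produced_mol`, `ratio`.
#' @examples
#' tc <- simulate_cultures(generator_config(noise_cv = 0), seed = 1)
#' stoichiometry_check(tc)
#' @export
stoichiometry_check <- function(timecourses, vial = vial_spec()) {
  stopifnot(inherits(vial, "vial_spec"))
  as_tibble(timecourses) |>
    group_by(.data$condition, .data$replicate) |>
    group_modify(function(df, key) {
      df <- arrange(df, .data$day)
      consumed <- (df$acetate_mm[1] - df$acetate_mm[nrow(df)]) / 1000 *
        vial$liquid_volume_l
      if (consumed <= 0)
        abort("No acetate consumption between first and last sample.")
      ch4 <- (df$p_ch4_atm[nrow(df)] - df$p_ch4_atm[1]) *
        vial$headspace_volume_l / (R_LATM * vial$temperature_k)
      tibble(acetate_consumed_mol = consumed, ch4_produced_mol = ch4,
             ratio = ch4 / consumed)
    }) |>
    ungroup()
}
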