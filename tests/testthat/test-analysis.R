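vial <- vial_spec()

# p_ch4 corresponding to a cumulative CH4 amount per liter of medium
p_from_molperl <- function(mol_per_l) {
  mol_per_l * R_LATM_H * vial$temperature_k * vial$liquid_volume_l /
    vial$headspace_volume_l
}

toy_timecourse <- function(days, acetate_mm, ch4_mol_per_l,
                           condition = "low", replicate = 1) {
  tibble::tibble(
    condition = condition, replicate = replicate, day = days,
    temperature_k = vial$temperature_k, ph = 7,
    acetate_mm = acetate_mm, bicarbonate_mm = 10,
    p_ch4_atm = p_from_molperl(ch4_mol_per_l), p_h2_pa = 20
  )
}

test_that("the free energy series is the composition of per-record
           delta_g calls", {
  tc <- simulate_cultures(seed = 2)
  tc <- dplyr::filter(tc, day > 0) # day 0 has zero CH4/H2 by construction
  series <- compute_dg_series(tc)
  direct <- delta_g(tc)
  joined <- dplyr::inner_join(
    as.data.frame(series),
    direct[, c("condition", "replicate", "day", "reaction", "dg_kj_mol")],
    by = c("condition", "replicate", "day", "reaction"),
    suffix = c("", "_direct"))
  expect_equal(nrow(joined), nrow(series))
  expect_equal(joined$dg_kj_mol, joined$dg_kj_mol_direct, tolerance = 1e-12)
  # identical replicates: per-day SD is zero
  tc0 <- simulate_cultures(generator_config(noise_cv = 0), seed = 1)
  s0 <- tidy(compute_dg_series(dplyr::filter(tc0, day > 0)))
  expect_equal(s0$sd_dg_kj_mol, rep(0, nrow(s0)))
})

test_that("records lacking an analyte are dropped for the reactions that
           need it and reported", {
  tc <- dplyr::bind_rows(
    toy_timecourse(1:4, c(40, 35, 25, 10), c(0, 0.005, 0.015, 0.03)),
    toy_timecourse(1:4, c(40, 36, 26, 11), c(0, 0.005, 0.014, 0.029),
                   replicate = 2))
  tc$p_h2_pa[tc$replicate == 2 & tc$day == 3] <- NA
  series <- compute_dg_series(tc)
  h2_rows <- dplyr::filter(as.data.frame(series),
                           reaction == "hydrogenotrophic", day == 3)
  expect_equal(nrow(h2_rows), 1) # replicate 2 dropped
  ac_rows <- dplyr::filter(as.data.frame(series),
                           reaction == "aceticlastic", day == 3)
  expect_equal(nrow(ac_rows), 2) # aceticlastic does not need H2
  dropped <- attr(series, "dropped")
  expect_true(any(dropped$replicate == 2 & dropped$day == 3 &
                    dropped$reaction == "hydrogenotrophic"))
})

test_that("replicate aggregation gives textbook two-point statistics", {
  s <- toy_series(tibble::tibble(
    condition = "low", reaction = "aceticlastic", day = 3,
    replicate = 1:2, p_h2_pa = 20, temperature_k = 328.15,
    dg_kj_mol = c(-22, -24), feasible = TRUE))
  t <- tidy(s)
  expect_equal(t$mean_dg_kj_mol, -23)
  expect_equal(t$sd_dg_kj_mol, sqrt(2))
  lp <- logphase_summary(s, window = c(2, 5))
  expect_equal(lp$mean_dg_kj_mol, -23)
  expect_equal(lp$sd_dg_kj_mol, sqrt(2))
  expect_false(lp$exceeds_threshold)
})

test_that("log-phase pooling matches a flat enumeration over the
           replicate-day grid", {
  set.seed(31)
  grid <- tidyr::crossing(replicate = 1:3, day = 1:7)
  grid$dg_kj_mol <- rnorm(nrow(grid), -25, 3)
  s <- toy_series(dplyr::mutate(grid, condition = "mid",
                                reaction = "hydrogenotrophic",
                                p_h2_pa = 20, temperature_k = 328.15,
                                feasible = TRUE))
  lp <- logphase_summary(s, window = c(2, 5))
  inside <- grid$dg_kj_mol[grid$day >= 2 & grid$day <= 5]
  expect_equal(lp$n, 12)
  expect_equal(lp$mean_dg_kj_mol, mean(inside))
  expect_equal(lp$sd_dg_kj_mol, sd(inside))
  # a one-day window reduces to that day's statistics
  lp1 <- logphase_summary(s, window = c(4, 4))
  day4 <- grid$dg_kj_mol[grid$day == 4]
  expect_equal(lp1$mean_dg_kj_mol, mean(day4))
  expect_equal(lp1$sd_dg_kj_mol, sd(day4))
  expect_error(logphase_summary(s, window = c(30, 40)), "overlap")
  expect_error(logphase_summary(s, window = c(5, 2)), "first <= last")
})

test_that("aggregation is invariant under replicate permutation", {
  tc <- simulate_cultures(seed = 8)
  tc <- dplyr::filter(tc, day > 0)
  shuffled <- tc[sample(nrow(tc)), ]
  shuffled$replicate <- dplyr::recode(shuffled$replicate,
                                      `1` = 3L, `2` = 1L, `3` = 2L)
  a <- logphase_summary(compute_dg_series(tc))
  b <- logphase_summary(compute_dg_series(shuffled))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("the H2 counterfactual reproduces the worked numbers and is
           reversible", {
  s <- toy_series(tibble::tibble(
    condition = "high", reaction = "hydrogenotrophic", day = 5,
    replicate = 1, p_h2_pa = 16.4, temperature_k = 328.15,
    dg_kj_mol = -25.1, feasible = TRUE))
  rep <- counterfactual_report(s, day = 5, p_h2_to_pa = 10)
  expect_equal(rep$dg_before_mean, -25.1)
  expect_equal(rep$dg_after_mean, -19.7, tolerance = 0.05 / 19.7)
  # shifting to the measured pressure changes nothing
  same <- counterfactual_report(s, day = 5, p_h2_to_pa = 16.4)
  expect_equal(same$dg_after_mean, same$dg_before_mean)
  # there and back
  back <- shift_h2(rep$dg_after_mean, "hydrogenotrophic", 10, 16.4)
  expect_equal(back, -25.1, tolerance = 1e-12)
  expect_error(counterfactual_report(s, day = 5, p_h2_to_pa = 10,
                                     reaction = "aceticlastic"),
               "no H2 term")
  expect_error(counterfactual_report(s, day = 9, p_h2_to_pa = 10),
               "not sampled")
})

test_that("methanogenic rate finds the steepest 3-point window", {
  # perfectly linear production at 2 mmol per liter per day
  lin <- toy_timecourse(0:5, seq(40, 15, by = -5), 0.002 * (0:5))
  r <- methanogenic_rate(lin)
  expect_equal(r$rate_mol_l_day, 0.002, tolerance = 1e-12)
  # flat series: zero rate
  flat <- toy_timecourse(0:4, rep(40, 5), rep(0, 5))
  expect_equal(methanogenic_rate(flat)$rate_mol_l_day, 0)
  # 5-point toy curve against exhaustive window enumeration
  ch4 <- c(0, 0.001, 0.004, 0.009, 0.011)
  toy <- toy_timecourse(0:4, seq(40, 20, by = -5), ch4)
  got <- methanogenic_rate(toy)
  slopes <- vapply(1:3, function(i) {
    idx <- i:(i + 2)
    unname(coef(lm(ch4[idx] ~ idx)))[2]
  }, numeric(1))
  expect_equal(got$rate_mol_l_day, max(slopes), tolerance = 1e-9)
  expect_equal(got$window_start_day, which.max(slopes) - 1)
  expect_error(methanogenic_rate(toy_timecourse(1:2, c(40, 30), c(0, 0.01))),
               "at least 3")
})

test_that("relative rates are ratios of condition means", {
  rates <- tibble::tibble(
    condition = rep(c("low", "high"), each = 2), replicate = c(1, 2, 1, 2),
    rate_mol_l_day = c(2e-3, 2e-3, 1e-3, 1e-3))
  rel <- relative_rate(rates, reference = "low")
  expect_equal(rel$relative_rate[as.character(rel$condition) == "low"], 1)
  expect_equal(rel$relative_rate[as.character(rel$condition) == "high"], 0.5)
  expect_error(relative_rate(rates, reference = "mid"), "not present")
  zero <- dplyr::mutate(rates, rate_mol_l_day = 0)
  expect_error(relative_rate(zero, reference = "low"), "zero mean rate")
})

test_that("a syntrophic co-culture configured to halve its rate under high
           CO2 reports a relative rate below one half", {
  conds <- default_conditions()
  # slower logistic rate at high CO2 emulates the co-culture susceptibility
  conds$rate_per_day <- c(1, 0.7, 0.35)
  cfg <- generator_config(conditions = conds)
  tc <- simulate_cultures(cfg, seed = 4)
  rel <- relative_rate(methanogenic_rate(tc, cfg$vial), reference = "low")
  expect_lt(rel$relative_rate[as.character(rel$condition) == "high"], 0.5)
})

test_that("abundance normalization is exact on constructed tables and
           recovers generator ground truth", {
  tbl <- tidyr::crossing(organism = c("a", "b"),
                         condition = c("low", "high"), replicate = 1:3)
  tbl$copies <- ifelse(tbl$condition == "low", 1e8,
                       ifelse(tbl$organism == "a", 2e8, 1e8))
  rel <- normalize_abundance(tbl, reference = "low")
  expect_equal(rel$relative_abundance[rel$organism == "a" &
                                        rel$condition == "high"], 2)
  expect_equal(rel$relative_abundance[rel$condition == "low"], c(1, 1))
  expect_equal(rel$sd[rel$condition == "low"], c(0, 0))
  expect_error(normalize_abundance(tbl, reference = "mid"), "missing")
  # generator round trip at suppression 0.5
  supp <- default_suppression()
  supp$factor[supp$organism == "Thermacetogenium_phaeum"] <- c(1, 0.7, 0.5)
  ab <- simulate_abundances(generator_config(), suppression = supp, seed = 14)
  rel2 <- normalize_abundance(ab, reference = "low")
  hit <- dplyr::filter(rel2, organism == "Thermacetogenium_phaeum",
                       as.character(condition) == "high")
  expect_lt(abs(hit$relative_abundance - 0.5), 2 * hit$sd)
})

test_that("stoichiometry ratios use the vial geometry correctly", {
  # 0.8 mmol acetate consumed, 0.4 mmol CH4 produced -> ratio 0.5
  days <- c(0, 10)
  acet <- c(40, 0) # 40 mM over 20 ml = 0.8 mmol
  p_ch4 <- c(0, 0.4e-3 * R_LATM_H * vial$temperature_k /
               vial$headspace_volume_l)
  toy <- tibble::tibble(condition = "low", replicate = 1, day = days,
                        temperature_k = vial$temperature_k, ph = 7,
                        acetate_mm = acet, bicarbonate_mm = 10,
                        p_ch4_atm = p_ch4, p_h2_pa = 20)
  expect_equal(stoichiometry_check(toy)$ratio, 0.5, tolerance = 1e-12)
  flat <- dplyr::mutate(toy, acetate_mm = 40)
  expect_error(stoichiometry_check(flat), "No acetate consumption")
})
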