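test_that("decay fraction is the proportion of marked groups lost", {
  expect_equal(decay_fraction(5, 0), 0)
  expect_equal(decay_fraction(20, 2), 0.1)   # pooled grassland winter trial
  expect_equal(decay_fraction(5, 5), 1)
  expect_error(decay_fraction(5, 6), "n_lost")
  expect_error(decay_fraction(0, 0), "n_placed")
})

test_that("decay correction follows pg_obs / (1 - r/2) with its bounds", {
  expect_equal(correct_pellet_count(10, 0), 10)
  expect_equal(correct_pellet_count(10, 0.2), 10 / 0.9)
  # at r = 0.3 the observed count is 85% of the corrected one
  expect_equal(correct_pellet_count(17, 0.3), 20)
  expect_equal(17 / correct_pellet_count(17, 0.3), 0.85)
  expect_error(correct_pellet_count(10, 1.2), "\\[0, 1\\]")
  expect_error(correct_pellet_count(-1, 0.5), "non-negative")
})

test_that("correction is monotone in r and bounded on [pg_obs, 2 pg_obs]", {
  r <- seq(0, 1, by = 0.01)
  pc <- correct_pellet_count(10, r)
  expect_true(all(diff(pc) > 0))
  expect_true(all(pc >= 10 & pc <= 20))
  # with r <= 0.3 the observed/corrected ratio stays in [0.85, 1]
  r2 <- seq(0, 0.3, by = 0.005)
  ratio <- 10 / correct_pellet_count(10, r2)
  expect_true(all(ratio >= 0.85 & ratio <= 1))
})

test_that("corrected counts are unbiased under uniform-deposition thinning", {
  # each deposited group survives to the count with probability 1 - r/2
  set.seed(401)
  r <- 0.3
  deposited <- 50
  obs <- rbinom(4000, deposited, 1 - r / 2)
  est <- correct_pellet_count(obs, r)
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - deposited), 4 * mc_se + 1e-9)
})

test_that("dung mass scales counts by group mass over plot area", {
  expect_equal(dung_mass_per_ha(1, 100, 225), 0.1 / 0.0225)
  expect_equal(dung_mass_per_ha(0, 57, 225), 0)
  expect_equal(dung_mass_per_ha(22.5, 225, 225), 225)
  expect_error(dung_mass_per_ha(1, 100, 0), "positive")
})

test_that("U subplots average pairwise and propagate missingness", {
  l <- list(habitat = "heathland", site = 1L, treatment = "U", period = 1L,
            pg_obs = 10, pg_cor = 11, mass_kg_ha = 100)
  r <- modifyList(l, list(pg_obs = 20, pg_cor = 21, mass_kg_ha = 200))
  out <- average_u_plots(l, r)
  expect_equal(out$pg_obs, 15)
  expect_equal(out$pg_cor, 16)
  expect_equal(out$mass_kg_ha, 150)
  same <- average_u_plots(l, l)
  expect_equal(same$mass_kg_ha, l$mass_kg_ha)
  # one side missing -> missing, not halved
  r_na <- modifyList(r, list(mass_kg_ha = NA_real_))
  expect_true(is.na(average_u_plots(l, r_na)$mass_kg_ha))
  # key mismatch
  r_bad <- modifyList(r, list(site = 2L))
  expect_error(average_u_plots(l, r_bad), "disagree")
  b <- modifyList(l, list(treatment = "B"))
  expect_error(average_u_plots(b, b), "U-treatment")
})

test_that("decay rates fall back from site trial to habitat mean to zero", {
  ds <- generate_survey(complete_config(), seed = 21)
  # drop the site-1 heathland trial of period 2
  dt <- ds$decay_trials
  drop <- dt$habitat == "heathland" & dt$site == 1 & dt$period == 2
  ds2 <- survey_dataset(ds$dung_counts, dt[!drop, ], ds$pellet_masses,
                        ds$concentrations, ds$forage)
  rr <- decay_rates(ds2)
  row <- rr[rr$habitat == "heathland" & rr$site == 1 & rr$period == 2, ]
  expect_identical(row$r_source, "habitat_mean")
  others <- dt[dt$habitat == "heathland" & dt$period == 2 & dt$site != 1, ]
  expect_equal(row$r, mean(others$n_lost / others$n_placed))
  # whole habitat-period without trials -> r = 0 with a warning
  drop_all <- dt$habitat == "heathland" & dt$period == 2
  ds3 <- survey_dataset(ds$dung_counts, dt[!drop_all, ], ds$pellet_masses,
                        ds$concentrations, ds$forage)
  expect_warning(rr3 <- decay_rates(ds3), "assuming")
  rows3 <- rr3[rr3$habitat == "heathland" & rr3$period == 2, ]
  expect_true(all(rows3$r == 0))
  expect_true(all(rows3$r_source == "assumed_zero"))
})

test_that("dung quantity table applies correction, mass and subplot averaging", {
  cfg <- noise_free_config()
  ds <- generate_survey(cfg, seed = 22)
  dq <- dung_quantities(ds)
  # r_true = 0: corrected equals observed, mass follows the fixed group mass
  expect_equal(dq$pg_cor, dq$pg_obs)
  m <- cfg$pellet_mass_mean[dq$habitat]
  expect_equal(dq$mass_kg_ha,
               unname(dq$pg_cor * (m / 1000) / (225 / 10000)))
})
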