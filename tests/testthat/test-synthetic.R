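test_that("the generator is deterministic given a seed", {
  ds1 <- generate_survey(synthetic_config(), seed = 61)
  ds2 <- generate_survey(synthetic_config(), seed = 61)
  for (tb in c("dung_counts", "decay_trials", "pellet_masses",
               "concentrations", "forage"))
    expect_identical(ds1[[tb]], ds2[[tb]], label = tb)
  ds3 <- generate_survey(synthetic_config(), seed = 62)
  expect_false(identical(ds1$dung_counts$pg_obs, ds3$dung_counts$pg_obs))
})

test_that("with no decay the observed counts equal the deposited counts", {
  cfg <- synthetic_config(
    r_true = rbind(heathland = rep(0, 5), grassland = rep(0, 5)),
    count_model = "fixed")
  ds <- generate_survey(cfg, seed = 63)
  mu <- cfg$deposition_mean[cbind(match(ds$dung_counts$habitat,
                                        rownames(cfg$deposition_mean)),
                                  ds$dung_counts$period)]
  expect_equal(ds$dung_counts$pg_obs, round(mu))
  expect_true(all(ds$decay_trials$n_lost == 0))
})

test_that("true budget is linear in its configured means", {
  cfg <- synthetic_config()
  tb <- true_budget(cfg)
  # zero deposition -> zero import, untouched export
  z <- rbind(heathland = rep(0, 5), grassland = rep(0, 5))
  tb0 <- true_budget(synthetic_config(deposition_mean = z))
  for (v in c("dung_mass", "faecal_N", "urinary_N", "total_N", "P_import"))
    expect_true(all(tb0$truth[tb0$variable == v] == 0), label = v)
  expect_equal(tb0$truth[tb0$variable == "export_N"],
               tb$truth[tb$variable == "export_N"])
  # doubling faecal concentrations doubles faecal imports
  dbl <- synthetic_config(
    faecal_conc_mean = list(N = c(heathland = 2 * 1.91, grassland = 2 * 2.73),
                            P = c(heathland = 2 * 0.24, grassland = 2 * 0.79)))
  tb2 <- true_budget(dbl)
  for (v in c("faecal_N", "P_import"))
    expect_equal(tb2$truth[tb2$variable == v],
                 2 * tb$truth[tb$variable == v], label = v)
  # doubling removal doubles exports
  tb3 <- true_budget(synthetic_config(removal_mean = 2 * cfg$removal_mean))
  for (v in c("export_N", "export_P"))
    expect_equal(tb3$truth[tb3$variable == v],
                 2 * tb$truth[tb$variable == v], label = v)
})

test_that("the noise-free pipeline reproduces the true budget exactly", {
  cfg <- noise_free_config()
  ds <- generate_survey(cfg, seed = 64)
  fit <- suppressWarnings(nutrient_budget(ds))
  tb <- true_budget(cfg)
  a <- fit$annual
  for (v in c("dung_mass", "faecal_N", "urinary_N", "total_N", "export_N",
              "P_import", "export_P")) {
    for (h in c("heathland", "grassland")) {
      est <- a$estimate[a$habitat == h & a$variable == v]
      tru <- tb$truth[tb$habitat == h & tb$variable == v]
      expect_equal(est, tru, tolerance = 1e-12,
                   label = paste(h, v, "estimate"))
    }
  }
  b <- fit$balance
  expect_equal(b$delta[b$habitat == "heathland" & b$nutrient == "N"],
               tb$truth[tb$habitat == "heathland" & tb$variable == "delta_N"],
               tolerance = 1e-12)
  # no sampling noise: propagated SEs collapse to zero
  expect_true(all(abs(a$se) < 1e-12))
})

test_that("estimated decay fractions are unbiased for the trial model", {
  # the generator draws n_lost ~ Binomial(n_placed, r_true); the estimator
  # is the sample fraction
  set.seed(65)
  for (r in c(0.05, 0.1, 0.3)) {
    rhat <- decay_fraction(5, rbinom(4000, 5, r))
    mc_se <- sd(rhat) / sqrt(length(rhat))
    expect_lt(abs(mean(rhat) - r), 4 * mc_se + 1e-9)
  }
})

test_that("configuration validation catches bad shapes and ranges", {
  expect_error(synthetic_config(deposition_mean = matrix(1, 2, 3)),
               "habitat x period")
  expect_error(
    synthetic_config(r_true = rbind(heathland = rep(2, 5),
                                    grassland = rep(0, 5))),
    "\\[0, 1\\]")
  expect_error(synthetic_config(dispersion = c(foo = 1, bar = 2)),
               "named by habitat")
  expect_error(synthetic_config(p_missing_forage = 1.5), "\\[0, 1\\]")
})

test_that("default configuration reproduces study-scale uncertainty", {
  # the propagated relative SEs of the annual imports on default synthetic
  # data should be of the same order as the published CI widths imply
  published <- utils::read.csv(
    system.file("extdata", "gta_annual_rates.csv", package = "deerflux"))
  rel_pub <- function(h, v) {
    r <- published[published$habitat == h & published$variable == v, ]
    ((r$upper - r$lower) / (2 * 1.96)) / r$estimate
  }
  fit <- suppressWarnings(
    nutrient_budget(generate_survey(synthetic_config(), seed = 66)))
  rel_sim <- function(h, v) {
    a <- annual_est(fit, h, v)
    a$se / a$estimate
  }
  pairs <- rbind(c("heathland", "faecal_N", "faecal_N_import"),
                 c("grassland", "faecal_N", "faecal_N_import"),
                 c("heathland", "P_import", "P_import"),
                 c("grassland", "P_import", "P_import"))
  for (i in seq_len(nrow(pairs))) {
    ratio <- rel_sim(pairs[i, 1], pairs[i, 2]) /
      rel_pub(pairs[i, 1], pairs[i, 3])
    expect_gt(ratio, 0.4, label = paste(pairs[i, 1], pairs[i, 2], "ratio"))
    expect_lt(ratio, 2.5, label = paste(pairs[i, 1], pairs[i, 2], "ratio"))
  }
})
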