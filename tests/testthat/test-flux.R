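test_that("urinary ratio matches hand evaluation of the allometric model", {
  # frozen values from direct evaluation of the ratio equation at w = 100
  expect_equal(urinary_ratio(0.01307), 0.6416545596, tolerance = 1e-9)
  expect_equal(urinary_ratio(0.01625), 0.8853267509, tolerance = 1e-9)
  # closed-form dilute-diet limit: c2 / (w^0.75 c5) = 0.03005 at w = 100
  expect_equal(urinary_ratio(1e-7), 0.004 / (100^0.75 * 0.00421),
               tolerance = 1e-4)
})

test_that("urinary ratio guards its units and domain", {
  expect_warning(urinary_ratio(1.3), "percent")
  expect_error(urinary_ratio(0), "positive")
  expect_error(urinary_ratio(-0.01), "positive")
  expect_error(urinary_params(w = -1), "positive")
})

test_that("urinary ratio is increasing in diet N and decreasing in body mass", {
  pn <- seq(0.005, 0.04, length.out = 60)
  u <- urinary_ratio(pn)
  expect_true(all(diff(u) > 0))
  for (pn0 in c(0.008, 0.013, 0.03)) {
    uw <- vapply(c(50, 100, 200, 400),
                 function(w) urinary_ratio(pn0, urinary_params(w = w)),
                 numeric(1))
    expect_true(all(diff(uw) < 0))
  }
})

test_that("import, export and total-N arithmetic is exact and guarded", {
  expect_equal(nutrient_import(100, 2), 2)
  expect_equal(nutrient_import(0, 2), 0)
  # annual heathland dung at its mean faecal N, consistency scale check
  expect_equal(nutrient_import(154.8, 1.91), 2.95668)
  expect_error(nutrient_import(100, 120), "\\(0, 100\\)")
  expect_error(nutrient_import(-1, 2), "non-negative")

  expect_equal(nutrient_export(1000, 1.625), 16.25)
  expect_equal(nutrient_export(0, 2), 0)
  expect_true(is.na(nutrient_export(NA, 2)))
  expect_error(nutrient_export(100, 0), "\\(0, 100\\)")

  expect_equal(total_n_import(2, 0), 2)
  expect_equal(total_n_import(2, 0.65), 3.3)
  expect_equal(total_n_import(0, 0.9), 0)
  expect_error(total_n_import(-1, 0.5), "non-negative")
})

test_that("flux arithmetic is linear over periods", {
  set.seed(41)
  mass <- runif(5, 0, 200); conc <- runif(5, 1, 3)
  expect_equal(sum(nutrient_import(mass, conc[1])),
               nutrient_import(sum(mass), conc[1]))
  rem <- runif(5, -100, 600)
  expect_equal(sum(nutrient_export(rem, conc[1])),
               nutrient_export(sum(rem), conc[1]))
})

test_that("flux table joins site-level faecal and plot-level plant data", {
  cfg <- noise_free_config()
  ds <- generate_survey(cfg, seed = 42)
  fx <- period_fluxes(ds)
  expect_equal(nrow(fx), 160)  # 80 plot-periods x 2 nutrients
  # P carries no urine
  fp <- fx[fx$nutrient == "P", ]
  expect_true(all(fp$urinary_import == 0, na.rm = TRUE))
  expect_equal(fp$total_import, fp$faecal_import)
  # N total equals faecal * (1 + U)
  fn <- fx[fx$nutrient == "N", ]
  expect_equal(fn$total_import, fn$faecal_import * (1 + fn$u_ratio))
  # structural forage gaps propagate to export as missing, never zero
  burnt <- fn$habitat == "heathland" & fn$treatment == "B" &
    fn$site %in% cfg$burnt_heath_forage_missing_sites
  expect_true(all(is.na(fn$export[burnt])))
  expect_true(all(!is.na(fn$export[!burnt])))
})

test_that("a noise-free mass balance closes exactly through the flux table", {
  cfg <- noise_free_config()
  ds <- generate_survey(cfg, seed = 43)
  fx <- period_fluxes(ds)
  per <- periods(ds$design)
  # reconstruct one cell by hand: heathland site 3, treatment U, period 4
  row <- fx[fx$habitat == "heathland" & fx$site == 3 & fx$treatment == "U" &
              fx$period == 4 & fx$nutrient == "N", ]
  conc_N <- mean(cfg$faecal_conc_mean$N["heathland", 4:5])
  mass <- cfg$deposition_mean[["heathland", 4]] *
    (cfg$pellet_mass_mean[["heathland"]] / 1000) / 0.0225
  expect_equal(row$faecal_import, mass * conc_N / 100)
  plant_N <- mean(cfg$plant_conc_mean$N["heathland", 4:5])
  expect_equal(row$export,
               cfg$removal_mean[["heathland", 4]] * plant_N / 100)
  expect_equal(row$u_ratio, urinary_ratio(plant_N / 100))
})
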