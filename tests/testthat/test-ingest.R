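test_that("survey dataset has the full study layout and 80 plot-period rows", {
  ds <- generate_survey(synthetic_config(), seed = 11)
  expect_s3_class(ds, "survey_dataset")
  # 16 vegetation plots, 24 dung plots (U counted twice), 5 periods
  expect_equal(nrow(ds$dung_counts), 24 * 5)
  dq <- dung_quantities(ds)
  expect_equal(nrow(dq), 80)
  expect_equal(nrow(unique(dq[c("habitat", "site", "treatment")])), 16)
})

test_that("read/write round trip reproduces every table including NA cells", {
  ds <- generate_survey(synthetic_config(), seed = 12)
  dir <- withr::local_tempdir()
  write_survey(ds, dir)
  ds2 <- read_survey(dir)
  for (tb in c("dung_counts", "decay_trials", "pellet_masses",
               "concentrations", "forage"))
    expect_equal(ds2[[tb]], ds[[tb]], ignore_attr = TRUE, label = tb)
  # missingness markers survive: faecal concentrations have NA cells
  expect_true(anyNA(ds$concentrations$value_pct))
  expect_identical(is.na(ds2$concentrations$value_pct),
                   is.na(ds$concentrations$value_pct))
})

test_that("validation rejects malformed or out-of-design records", {
  ds <- generate_survey(complete_config(), seed = 13)
  # empty dung-count table
  empty <- ds$dung_counts[0, ]
  expect_error(
    survey_dataset(empty, ds$decay_trials, ds$pellet_masses,
                   ds$concentrations, ds$forage),
    "no rows")
  # concentration out of (0, 100)
  cc <- ds$concentrations
  cc$value_pct[5] <- 150
  expect_error(
    survey_dataset(ds$dung_counts, ds$decay_trials, ds$pellet_masses, cc,
                   ds$forage),
    "value_pct outside \\(0, 100\\).*5")
  # key outside the declared design
  dc <- ds$dung_counts
  dc$site[1] <- 9L
  expect_error(
    survey_dataset(dc, ds$decay_trials, ds$pellet_masses,
                   ds$concentrations, ds$forage),
    "outside the declared design")
  # non-integer count
  dc <- ds$dung_counts
  dc$pg_obs[2] <- 3.5
  expect_error(
    survey_dataset(dc, ds$decay_trials, ds$pellet_masses,
                   ds$concentrations, ds$forage),
    "non-negative integers")
  # decay trial losing more than it placed
  dt <- ds$decay_trials
  dt$n_lost[1] <- dt$n_placed[1] + 1L
  expect_error(
    survey_dataset(ds$dung_counts, dt, ds$pellet_masses,
                   ds$concentrations, ds$forage),
    "n_lost > n_placed")
  # subplot label on a B-treatment dung plot
  dc <- ds$dung_counts
  i <- which(dc$treatment == "B")[1]
  dc$subplot[i] <- "left"
  expect_error(
    survey_dataset(dc, ds$decay_trials, ds$pellet_masses,
                   ds$concentrations, ds$forage),
    "subplot")
})

test_that("missingness report counts available observations, never zeros them", {
  ds <- generate_survey(complete_config(), seed = 14)
  rep0 <- missingness_report(ds)
  full <- rep0[!is.na(rep0$n_design), ]
  expect_true(all(full$n_available == full$n_design))

  # remove three faecal N samples at one date
  cc <- ds$concentrations
  idx <- which(cc$kind == "faecal" & cc$nutrient == "N" &
                 cc$date == ds$design$dates[3])[1:3]
  cc$value_pct[idx] <- NA
  ds2 <- survey_dataset(ds$dung_counts, ds$decay_trials, ds$pellet_masses,
                        cc, ds$forage)
  rep2 <- missingness_report(ds2)
  cell <- rep2[rep2$variable == "faecal_N" &
                 rep2$when == format(ds$design$dates[3]), ]
  expect_equal(cell$n_available, cell$n_design - 3L)

  # structurally missing burnt-heathland forage shows as reduced counts
  ds3 <- generate_survey(synthetic_config(), seed = 14)
  rep3 <- missingness_report(ds3)
  fo <- rep3[rep3$variable == "forage_removal", ]
  expect_true(all(fo$n_available == fo$n_design - 2L))
  expect_true(all(fo$n_available > 0))
})

test_that("read_survey reports missing files and parse problems by name", {
  dir <- withr::local_tempdir()
  expect_error(read_survey(dir), "file not found")
})

test_that("the command-line wrapper ships and parses", {
  cli <- system.file("cli", "deerflux.R", package = "deerflux")
  expect_true(nzchar(cli) && file.exists(cli))
  expect_no_error(parse(cli))
})
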