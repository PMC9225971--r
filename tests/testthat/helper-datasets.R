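# shared fixtures: all generated in code, no files on disk

# a fully observed, moderately sized synthetic dataset
complete_config <- function(...) {
  defaults <- list(p_missing_faecal_conc = 0, p_missing_plant_conc = 0,
                   burnt_heath_forage_missing_sites = integer(0),
                   first_date_plant_missing = FALSE)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

zero_h <- c(heathland = 0, grassland = 0)

# deterministic configuration: every random source switched off
noise_free_config <- function(...) {
  defaults <- list(
    r_true = rbind(heathland = rep(0, 5), grassland = rep(0, 5)),
    pellet_mass_cv = zero_h,
    plant_conc_sd = list(N = zero_h, P = zero_h),
    faecal_conc_sd = list(N = zero_h, P = zero_h),
    removal_sd = zero_h,
    p_missing_faecal_conc = 0, p_missing_plant_conc = 0,
    count_model = "fixed")
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

# named estimate lookup from a fitted budget's annual table
annual_est <- function(fit, habitat, variable) {
  a <- fit$annual
  a[a$habitat == habitat & a$variable == variable, ]
}
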