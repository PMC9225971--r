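#' Configuration for the synthetic survey generator
#'
#' Parameterises [generate_survey()] and the matching closed-form truth
#' [true_budget()]. The defaults emulate the one-year red deer survey the
#' package is built around: 2 habitats x 4 sites x 2 treatments, six dates
#' / five periods, winter-heavy dung deposition in heathland and
#' summer-heavy deposition in grassland, habitat-specific concentration
#' means at the reported study values, and the study's structural gaps
#' (no plant samples at the first date; no forage data for the burnt
#' heathland plots).
#'
#' Habitat-indexed arguments are named vectors (names = habitats); period
#' profiles are habitat x period matrices (rownames = habitats).
#'
#' @param design a [study_design()].
#' @param deposition_mean habitat x period matrix: true mean number of
#'   pellet groups deposited per dung plot per period.
#' @param dispersion named vector: negative-binomial size per habitat
#'   (larger = closer to Poisson); used when `count_model = "nbinom"`.
#' @param r_true habitat x period matrix of true decay fractions in
#'   \[0, 1\].
#' @param pellet_mass_mean,pellet_mass_cv named vectors: mean dry mass (g)
#'   of a pellet group and its coefficient of variation (lognormal).
#' @param plant_conc_mean,plant_conc_sd,faecal_conc_mean,faecal_conc_sd
#'   lists with elements `N` and `P`: concentration means and residual
#'   (non-seasonal) plot- or site-level SDs in % DM. A mean may be a named
#'   per-habitat vector — then it is the annual grand mean, modulated over
#'   dates by the corresponding seasonal profile — or a full habitat x date
#'   matrix.
#' @param plant_season,faecal_season seasonal multiplier profiles over the
#'   sampling dates (normalised internally to mean 1, so the configured
#'   grand means are preserved); defaults peak in spring for plant tissue
#'   and early summer for faeces, echoing the observed seasonal pattern.
#' @param removal_mean habitat x period matrix of mean forage removal per
#'   plot, kg DM/ha; `removal_sd` named per-habitat plot-level SD.
#' @param removal_sd named per-habitat SD of plot-level removal, kg DM/ha.
#' @param p_missing_faecal_conc,p_missing_plant_conc,p_missing_forage
#'   probabilities that an individual measured cell is missing.
#' @param burnt_heath_forage_missing_sites sites of the first habitat whose
#'   B-treatment plots have structurally missing forage data (no biomass
#'   calibration), as in the study; `integer(0)` disables.
#' @param first_date_plant_missing logical: omit plant concentrations at
#'   the first sampling date (they are substituted downstream by the final
#'   date's values).
#' @param n_placed pellet groups placed per site and period in the decay
#'   experiment.
#' @param n_mass_groups pellet groups collected per site and date for dry
#'   mass determination.
#' @param count_model `"nbinom"`, `"poisson"` or `"fixed"` (deposited
#'   counts equal the rounded mean — no sampling noise; used for
#'   noise-free identity checks).
#' @param seed default seed used by [generate_survey()] when none is given.
#' @return A validated list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(
    design = study_design(),
    deposition_mean = rbind(heathland = c(12, 14, 15, 16, 50),
                            grassland = c(16, 18, 20, 16, 3)),
    dispersion = c(heathland = 1.5, grassland = 40),
    r_true = rbind(heathland = c(0.05, 0.05, 0.10, 0.10, 0.05),
                   grassland = c(0.05, 0.10, 0.10, 0.10, 0.10)),
    pellet_mass_mean = c(heathland = 32.5, grassland = 30),
    pellet_mass_cv = c(heathland = 0.3, grassland = 0.3),
    plant_conc_mean = list(N = c(heathland = 1.307, grassland = 1.625),
                           P = c(heathland = 0.117, grassland = 0.216)),
    plant_season = c(1.25, 1.20, 1.00, 0.85, 0.80, 1.25),
    plant_conc_sd = list(N = c(heathland = 0.12, grassland = 0.20),
                         P = c(heathland = 0.015, grassland = 0.03)),
    faecal_conc_mean = list(N = c(heathland = 1.91, grassland = 2.73),
                            P = c(heathland = 0.24, grassland = 0.79)),
    faecal_season = c(1.10, 1.20, 1.15, 0.90, 0.80, 0.85),
    faecal_conc_sd = list(N = c(heathland = 0.20, grassland = 0.35),
                          P = c(heathland = 0.06, grassland = 0.15)),
    removal_mean = rbind(heathland = c(330, 180, 180, 200, 550),
                         grassland = c(560, 330, 340, 350, 540)),
    removal_sd = c(heathland = 380, grassland = 460),
    p_missing_faecal_conc = 0.15,
    p_missing_plant_conc = 0.05,
    p_missing_forage = 0,
    burnt_heath_forage_missing_sites = c(1L, 2L),
    first_date_plant_missing = TRUE,
    n_placed = 5L,
    n_mass_groups = 5L,
    count_model = c("nbinom", "poisson", "fixed"),
    seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  count_model <- match.arg(count_model)
  H <- design$habitats; P <- design$n_periods

  as_hp <- function(x, nm) {
    x <- as.matrix(x)
    if (!identical(dim(x), c(length(H), P)) ||
        !identical(rownames(x), H))
      stop("'", nm, "' must be a habitat x period matrix with rownames ",
           paste(H, collapse = ", "), call. = FALSE)
    if (any(x < 0)) stop("'", nm, "' must be non-negative", call. = FALSE)
    x
  }
  as_h <- function(x, nm) {
    if (!identical(sort(names(x)), sort(H)))
      stop("'", nm, "' must be named by habitat", call. = FALSE)
    if (any(x < 0)) stop("'", nm, "' must be non-negative", call. = FALSE)
    x[H]
  }
  as_conc <- function(x, nm) {
    stopifnot(all(c("N", "P") %in% names(x)))
    lapply(x[c("N", "P")], as_h, nm)
  }
  D <- length(design$dates)
  as_conc_mat <- function(x, season, nm) {
    stopifnot(all(c("N", "P") %in% names(x)))
    if (length(season) != D || any(season <= 0))
      stop("seasonal profile must be positive with one value per date",
           call. = FALSE)
    season <- season / mean(season)
    lapply(x[c("N", "P")], function(v) {
      if (is.matrix(v)) {
        if (!identical(dim(v), c(length(H), D)) ||
            !identical(rownames(v), H))
          stop("'", nm, "' matrix must be habitat x date", call. = FALSE)
        v
      } else {
        m <- outer(as_h(v, nm), season)
        colnames(m) <- NULL
        m
      }
    })
  }
  deposition_mean <- as_hp(deposition_mean, "deposition_mean")
  r_true <- as_hp(r_true, "r_true")
  if (any(r_true > 1)) stop("r_true must lie in [0, 1]", call. = FALSE)
  removal_mean <- as_hp(removal_mean, "removal_mean")
  for (p in c(p_missing_faecal_conc, p_missing_plant_conc, p_missing_forage))
    if (p < 0 || p > 1)
      stop("missingness probabilities must lie in [0, 1]", call. = FALSE)

  structure(list(
    design = design,
    deposition_mean = deposition_mean,
    dispersion = as_h(dispersion, "dispersion"),
    r_true = r_true,
    pellet_mass_mean = as_h(pellet_mass_mean, "pellet_mass_mean"),
    pellet_mass_cv = as_h(pellet_mass_cv, "pellet_mass_cv"),
    plant_conc_mean = as_conc_mat(plant_conc_mean, plant_season,
                                  "plant_conc_mean"),
    plant_conc_sd = as_conc(plant_conc_sd, "plant_conc_sd"),
    faecal_conc_mean = as_conc_mat(faecal_conc_mean, faecal_season,
                                   "faecal_conc_mean"),
    faecal_conc_sd = as_conc(faecal_conc_sd, "faecal_conc_sd"),
    removal_mean = removal_mean,
    removal_sd = as_h(removal_sd, "removal_sd"),
    p_missing_faecal_conc = p_missing_faecal_conc,
    p_missing_plant_conc = p_missing_plant_conc,
    p_missing_forage = p_missing_forage,
    burnt_heath_forage_missing_sites =
      as.integer(burnt_heath_forage_missing_sites),
    first_date_plant_missing = isTRUE(first_date_plant_missing),
    n_placed = as.integer(n_placed),
    n_mass_groups = as.integer(n_mass_groups),
    count_model = count_model,
    seed = as.integer(seed)),
    class = "synthetic_config")
}

hp_lookup <- function(mat, habitat, period)
  mat[cbind(match(habitat, rownames(mat)), period)]

# truncated-normal draw on (lo, hi) by resampling out-of-range values
rnorm_trunc <- function(n, mean, sd, lo = 0, hi = 100) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lo | x >= hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] <= lo | x[bad] >= hi]
  }
  x
}

#' Generate a synthetic survey dataset
#'
#' Draws a complete raw survey dataset with the statistical structure the
#' analysis assumes: pellet-group deposition is negative-binomial (Poisson,
#' or fixed at the mean) per dung plot and period; observed counts are
#' binomially thinned at detection probability `1 - r_true/2` (the uniform
#' deposition-time rationale behind the decay correction, which makes
#' [correct_pellet_count()] the matched estimator); decay trials are
#' binomial(`n_placed`, `r_true`); pellet masses lognormal; concentrations
#' normal truncated to (0, 100); forage removal normal; missingness applied
#' cell-wise at the configured probabilities plus the structural gaps.
#'
#' All draws come from one generator stream seeded once, in a fixed
#' documented order (counts, decay trials, masses, faecal concentrations,
#' plant concentrations, forage, missingness), so a given seed always
#' yields the identical dataset.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return A validated `"survey_dataset"`.
#' @examples
#' ds <- generate_survey(seed = 42)
#' nutrient_budget(ds)
#' @export
generate_survey <- function(config = synthetic_config(), seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  des <- config$design
  set.seed(seed)
  per <- periods(des)
  H <- des$habitats

  # 1. dung counts on the dung plots
  dp <- design_dung_plots(des)
  dc <- merge(dp, data.frame(period = per$period), by = NULL)
  mu <- hp_lookup(config$deposition_mean, dc$habitat, dc$period)
  size <- config$dispersion[dc$habitat]
  deposited <- switch(config$count_model,
    nbinom = stats::rnbinom(nrow(dc), mu = mu, size = size),
    poisson = stats::rpois(nrow(dc), lambda = mu),
    fixed = round(mu))
  detect_p <- 1 - hp_lookup(config$r_true, dc$habitat, dc$period) / 2
  dc$pg_obs <- if (all(detect_p == 1)) deposited else
    stats::rbinom(nrow(dc), size = deposited, prob = detect_p)
  dung_counts <- dc[c("habitat", "site", "treatment", "subplot",
                      "period", "pg_obs")]

  # 2. decay trials per site x period
  st <- expand.grid(habitat = H, site = des$sites,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  dt <- merge(st, data.frame(period = per$period), by = NULL)
  rt <- hp_lookup(config$r_true, dt$habitat, dt$period)
  dt$n_placed <- config$n_placed
  dt$n_lost <- if (all(rt == 0)) 0L else
    stats::rbinom(nrow(dt), size = dt$n_placed, prob = rt)
  decay_trials <- dt[c("habitat", "site", "period", "n_placed", "n_lost")]

  # 3. pellet masses at the period end (collection) dates
  pm <- merge(st, data.frame(date = per$end), by = NULL)
  pm <- pm[rep(seq_len(nrow(pm)), each = config$n_mass_groups), ]
  m <- config$pellet_mass_mean[pm$habitat]
  cv <- config$pellet_mass_cv[pm$habitat]
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(m) - sdlog^2 / 2
  pm$mass_g <- if (all(cv == 0)) m else
    stats::rlnorm(nrow(pm), meanlog = meanlog, sdlog = sdlog)
  pellet_masses <- pm[c("habitat", "site", "date", "mass_g")]

  # 4. faecal concentrations: site level, all dates
  draw_conc <- function(grid, means, sds) {
    out <- NULL
    for (nut in c("N", "P")) {
      g <- grid
      g$nutrient <- nut
      mu <- means[[nut]][cbind(match(g$habitat, H),
                               match(g$date, des$dates))]
      sd <- sds[[nut]][g$habitat]
      g$value_pct <- ifelse(sd == 0, mu, NA)
      idx <- which(sd > 0)
      if (length(idx))
        g$value_pct[idx] <- rnorm_trunc(length(idx), mu[idx], sd[idx])
      out <- rbind(out, g)
    }
    out
  }
  fgrid <- merge(st, data.frame(date = des$dates), by = NULL)
  fcc <- draw_conc(fgrid, config$faecal_conc_mean, config$faecal_conc_sd)
  fcc$kind <- "faecal"
  fcc$treatment <- NA_character_

  # 5. plant concentrations: plot level; first date omitted if configured
  pdates <- if (config$first_date_plant_missing) des$dates[-1L] else des$dates
  pgrid <- merge(design_plots(des), data.frame(date = pdates), by = NULL)
  pcc <- draw_conc(pgrid, config$plant_conc_mean, config$plant_conc_sd)
  pcc$kind <- "plant"
  cols <- c("kind", "habitat", "site", "treatment", "date", "nutrient",
            "value_pct")
  concentrations <- rbind(fcc[cols], pcc[cols])

  # 6. forage removal per plot x period
  fo <- merge(design_plots(des), data.frame(period = per$period), by = NULL)
  rmu <- hp_lookup(config$removal_mean, fo$habitat, fo$period)
  rsd <- config$removal_sd[fo$habitat]
  fo$removal_kg_ha <- ifelse(rsd == 0, rmu, NA)
  idx <- which(rsd > 0)
  if (length(idx))
    fo$removal_kg_ha[idx] <- stats::rnorm(length(idx), rmu[idx], rsd[idx])
  if (length(config$burnt_heath_forage_missing_sites)) {
    drop <- fo$habitat == H[1L] & fo$treatment == "B" &
      fo$site %in% config$burnt_heath_forage_missing_sites
    fo$removal_kg_ha[drop] <- NA_real_
  }
  forage <- fo[c("habitat", "site", "treatment", "period", "removal_kg_ha")]

  # 7. cell-wise missingness
  if (config$p_missing_faecal_conc > 0) {
    i <- concentrations$kind == "faecal"
    hit <- stats::runif(sum(i)) < config$p_missing_faecal_conc
    concentrations$value_pct[which(i)[hit]] <- NA_real_
  }
  if (config$p_missing_plant_conc > 0) {
    i <- concentrations$kind == "plant"
    hit <- stats::runif(sum(i)) < config$p_missing_plant_conc
    concentrations$value_pct[which(i)[hit]] <- NA_real_
  }
  if (config$p_missing_forage > 0) {
    hit <- stats::runif(nrow(forage)) < config$p_missing_forage
    forage$removal_kg_ha[hit] <- NA_real_
  }

  survey_dataset(dung_counts, decay_trials, pellet_masses, concentrations,
                 forage, design = des)
}

#' Closed-form true budget of a synthetic configuration
#'
#' Expected annual fluxes implied by a [synthetic_config()], computed
#' analytically from the configured means and independent of any random
#' draw: per period, expected dung mass per plot is
#' `deposition_mean * pellet_mass_mean / plot area`, imports multiply that
#' by the faecal concentration means, the urinary N fraction is the
#' allometric ratio evaluated at the configured plant N mean, exports
#' multiply the removal means by plant concentration means, and periods sum
#' to the year.
#'
#' @param config a [synthetic_config()].
#' @param urinary a [urinary_params()] object (must match the one used in
#'   the analysis for recovery comparisons).
#' @return Data frame `habitat, variable, truth` with variables
#'   `dung_mass`, `faecal_N`, `urinary_N`, `total_N`, `export_N`,
#'   `P_import`, `export_P`, `delta_N`, `delta_P` (kg/ha/a).
#' @export
true_budget <- function(config = synthetic_config(),
                        urinary = urinary_params()) {
  stopifnot(inherits(config, "synthetic_config"))
  des <- config$design
  area_ha <- des$plot_area_m2 / 10000
  D <- length(des$dates)
  # expected period-mean concentration: mean of the bounding date means,
  # honouring the final-date substitution for the first plant endpoint
  period_conc <- function(dates_mean, substitute_first) {
    if (substitute_first) dates_mean[1L] <- dates_mean[D]
    (dates_mean[-D] + dates_mean[-1L]) / 2
  }
  out <- list()
  for (h in des$habitats) {
    sub1 <- config$first_date_plant_missing
    plN <- period_conc(config$plant_conc_mean$N[h, ], sub1)
    plP <- period_conc(config$plant_conc_mean$P[h, ], sub1)
    faN <- period_conc(config$faecal_conc_mean$N[h, ], FALSE)
    faP <- period_conc(config$faecal_conc_mean$P[h, ], FALSE)
    mass_p <- config$deposition_mean[h, ] *
      (config$pellet_mass_mean[[h]] / 1000) / area_ha   # kg/ha per period
    fN <- mass_p * faN / 100
    fP <- mass_p * faP / 100
    u <- urinary_ratio(plN / 100, urinary)
    uN <- fN * u
    exN <- config$removal_mean[h, ] * plN / 100
    exP <- config$removal_mean[h, ] * plP / 100
    vals <- c(dung_mass = sum(mass_p), faecal_N = sum(fN),
              urinary_N = sum(uN), total_N = sum(fN + uN),
              export_N = sum(exN), P_import = sum(fP),
              export_P = sum(exP),
              delta_N = sum(fN + uN) - sum(exN),
              delta_P = sum(fP) - sum(exP))
    out[[h]] <- data.frame(habitat = h, variable = names(vals),
                           truth = unname(vals))
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
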