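#' Parameters of the urinary-to-faecal N excretion model
#'
#' The urinary fraction of N excretion by a ruminant is estimated from the
#' dietary N concentration and metabolic body mass via an empirical
#' allometric ratio model (see [urinary_ratio()]). The coefficients are
#' fixed empirical constants; only the body mass is ordinarily adjusted
#' (default 100 kg, an approximate average for red deer).
#'
#' @param w body mass in kg.
#' @param c1,c2,c3,c4,c5 model coefficients (defaults 11.56, 0.004, 0.078,
#'   0.05, 0.00421); override only to reproduce variant parameterisations.
#' @return A list of class `"urinary_params"`.
#' @export
urinary_params <- function(w = 100, c1 = 11.56, c2 = 0.004, c3 = 0.078,
                           c4 = 0.05, c5 = 0.00421) {
  if (!is.numeric(w) || length(w) != 1L || w <= 0)
    stop("body mass w must be a single positive number", call. = FALSE)
  structure(list(w = w, c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5),
            class = "urinary_params")
}

#' Ratio of urinary to faecal nitrogen excretion
#'
#' Empirical allometric model for the urinary:faecal N excretion ratio of a
#' ruminant as a function of dietary N concentration and body mass:
#' \deqn{U_{ratio} = \frac{11.56\,pN + 0.004/(pN\,w^{0.75}) + 0.078}
#'                        {0.05 + 0.00421/pN}}
#' where `pN` is the dietary N concentration as a **mass fraction of dry
#' matter** (e.g. 0.013, not 1.3) and `w` the body mass in kg. The ratio
#' increases with dietary N (richer diets shift excretion towards urine)
#' and decreases weakly with body mass. At red deer scale (w = 100 kg,
#' plant N 1.3–1.6% DM) it is roughly 0.6–0.9.
#'
#' @param plant_n dietary N concentration, fraction of dry matter ( > 0).
#'   Values above 0.1 trigger a warning: they almost certainly arrived in
#'   percent rather than fraction units.
#' @param params a [urinary_params()] object.
#' @return The dimensionless ratio, strictly positive. Vectorised over
#'   `plant_n`.
#' @examples
#' urinary_ratio(0.01307)  # heathland-scale diet: ~0.64
#' urinary_ratio(0.01625)  # grassland-scale diet: ~0.89
#' @export
urinary_ratio <- function(plant_n, params = urinary_params()) {
  stopifnot(inherits(params, "urinary_params"))
  if (any(plant_n <= 0, na.rm = TRUE))
    stop("plant_n must be positive (a fraction of dry matter)",
         call. = FALSE)
  if (any(plant_n > 0.1, na.rm = TRUE))
    warning("plant_n > 0.1: did you pass percent instead of fraction?",
            call. = FALSE)
  with(params,
       (c1 * plant_n + c2 / (plant_n * w^0.75) + c3) /
         (c4 + c5 / plant_n))
}

#' Faecal nutrient import
#'
#' Nutrient mass deposited with dung: the dung dry mass per hectare times
#' the faecal nutrient concentration.
#'
#' @param mass_kg_ha dung dry mass, kg DM per hectare (>= 0).
#' @param faecal_conc_pct faecal nutrient concentration, % of dry mass.
#' @return Import in kg per hectare. Vectorised.
#' @export
nutrient_import <- function(mass_kg_ha, faecal_conc_pct) {
  check_pct(faecal_conc_pct)
  if (any(mass_kg_ha < 0, na.rm = TRUE))
    stop("dung mass must be non-negative", call. = FALSE)
  mass_kg_ha * faecal_conc_pct / 100
}

#' Nutrient export through grazing
#'
#' Nutrient mass removed in grazed forage: removal times the plant nutrient
#' concentration. A missing removal yields a missing export — never zero.
#'
#' @param removal_kg_ha forage removal, kg DM per hectare (may be negative
#'   where a negative increment difference was retained).
#' @param plant_conc_pct plant nutrient concentration, % of dry mass.
#' @return Export in kg per hectare. Vectorised.
#' @export
nutrient_export <- function(removal_kg_ha, plant_conc_pct) {
  check_pct(plant_conc_pct)
  removal_kg_ha * plant_conc_pct / 100
}

#' Total N import including the urinary fraction
#'
#' Faecal N import scaled up by the urinary:faecal excretion ratio:
#' `N_total = faecal_N * (1 + U_ratio)`. Urine is assumed to be deposited
#' with the same spatial pattern as dung; urinary P is zero (P is excreted
#' almost exclusively in dung), so this applies to N only.
#'
#' @param faecal_n_import faecal N import, kg per hectare (>= 0).
#' @param u_ratio urinary-to-faecal N excretion ratio (>= 0).
#' @return Total N import, kg per hectare. Vectorised.
#' @export
total_n_import <- function(faecal_n_import, u_ratio) {
  if (any(faecal_n_import < 0, na.rm = TRUE) ||
      any(u_ratio < 0, na.rm = TRUE))
    stop("faecal import and U_ratio must be non-negative", call. = FALSE)
  faecal_n_import * (1 + u_ratio)
}

check_pct <- function(x) {
  if (any(!is.na(x) & (x <= 0 | x >= 100)))
    stop("concentration must lie in (0, 100) percent of dry mass",
         call. = FALSE)
  invisible(TRUE)
}

#' Per-plot, per-period nutrient fluxes
#'
#' The flux stage of the pipeline: combines dung quantities, period
#' concentrations and forage removal into one long table of per-plot,
#' per-period fluxes. Faecal import uses site-level faecal concentrations
#' broadcast to both plots of a site; export uses plot-level plant
#' concentrations; the urinary N ratio is evaluated per observation at the
#' plot's period-mean plant N (as a fraction).
#'
#' @param ds a `"survey_dataset"`.
#' @param urinary a [urinary_params()] object.
#' @return Data frame with one row per plot x period x nutrient:
#'   `habitat, site, treatment, period, nutrient, mass_kg_ha,
#'   faecal_import, u_ratio, urinary_import, total_import, removal_kg_ha,
#'   export, negative_removal`.
#' @export
period_fluxes <- function(ds, urinary = urinary_params()) {
  stopifnot(inherits(ds, "survey_dataset"))
  dq <- dung_quantities(ds)
  fc <- period_concentrations(ds, "faecal")
  pc <- period_concentrations(ds, "plant")
  plot_key <- function(x) paste(x$habitat, x$site, x$treatment, x$period)
  site_key <- function(x) paste(x$habitat, x$site, x$period)

  fo <- ds$forage
  rem <- fo$removal_kg_ha[match(plot_key(dq), plot_key(fo))]

  out <- NULL
  for (nut in c("N", "P")) {
    fcn <- fc[fc$nutrient == nut, ]
    pcn <- pc[pc$nutrient == nut, ]
    f_conc <- fcn$value_pct[match(site_key(dq), site_key(fcn))]
    p_conc <- pcn$value_pct[match(plot_key(dq), plot_key(pcn))]
    row <- data.frame(dq[c("habitat", "site", "treatment", "period")],
                      nutrient = nut, mass_kg_ha = dq$mass_kg_ha)
    row$faecal_import <- nutrient_import(dq$mass_kg_ha, f_conc)
    if (nut == "N") {
      pn <- pc[pc$nutrient == "N", ]
      plant_n_frac <- pn$value_pct[match(plot_key(dq), plot_key(pn))] / 100
      row$u_ratio <- ifelse(is.na(plant_n_frac), NA_real_,
                            urinary_ratio(plant_n_frac, urinary))
      row$urinary_import <- row$faecal_import * row$u_ratio
      row$total_import <- total_n_import(row$faecal_import,
                                         row$u_ratio)
    } else {
      row$u_ratio <- NA_real_
      row$urinary_import <- 0 * row$faecal_import   # NA where faecal is NA
      row$total_import <- row$faecal_import
    }
    row$removal_kg_ha <- rem
    row$export <- nutrient_export(rem, p_conc)
    row$negative_removal <- !is.na(rem) & rem < 0
    out <- rbind(out, row)
  }
  rownames(out) <- NULL
  out
}
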