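#' Decay fraction from a pellet-group persistence trial
#'
#' In the decay experiment, marked fresh pellet groups are placed at the
#' start of a sampling period and revisited at its end; a group counts as
#' decayed when fewer than six pellets are retrieved. The decay fraction is
#' simply the proportion lost.
#'
#' @param n_placed number of marked pellet groups placed (>= 1).
#' @param n_lost number of those that had disappeared by the next visit.
#' @return `n_lost / n_placed`, a fraction in \[0, 1\]. Vectorised.
#' @examples
#' decay_fraction(20, 2)  # pooled grassland winter trial: 0.1
#' @export
decay_fraction <- function(n_placed, n_lost) {
  if (any(n_placed < 1, na.rm = TRUE))
    stop("n_placed must be >= 1 (no trial without placed groups)",
         call. = FALSE)
  if (any(n_lost < 0 | n_lost > n_placed, na.rm = TRUE))
    stop("n_lost must lie in [0, n_placed]", call. = FALSE)
  n_lost / n_placed
}

#' Decay-correct an observed pellet-group count
#'
#' Pellet groups deposited during a period are exposed to decay for only
#' part of it: under uniform deposition times a group is exposed for half
#' the period on average, so the expected fraction still detectable at the
#' survey date is `1 - r/2` where `r` is the full-period decay fraction.
#' The corrected count is therefore
#' \deqn{pg_{cor} = \frac{pg_{obs}}{1 - r/2}}
#' which equals the observed count when nothing decayed and at most doubles
#' it at complete loss. `pg_cor` is kept as a real number: it feeds
#' continuous mass arithmetic downstream.
#'
#' @param pg_obs observed pellet-group count (>= 0).
#' @param r decay fraction in \[0, 1\] (see [decay_fraction()]).
#' @return Corrected count, in `[pg_obs, 2 * pg_obs]`. Vectorised.
#' @examples
#' correct_pellet_count(10, 0.2)  # 11.11
#' @export
correct_pellet_count <- function(pg_obs, r) {
  if (any(r < 0 | r > 1, na.rm = TRUE))
    stop("decay fraction r must lie in [0, 1]", call. = FALSE)
  if (any(pg_obs < 0, na.rm = TRUE))
    stop("pg_obs must be non-negative", call. = FALSE)
  pg_obs / (1 - r / 2)
}

#' Convert a pellet-group count to dung dry mass per hectare
#'
#' @param pg_cor (corrected) pellet-group count per plot.
#' @param mean_pg_mass_g average dry mass of one pellet group, g.
#' @param plot_area_m2 plot area in m2.
#' @return Dung dry mass in kg DM per hectare. Vectorised.
#' @examples
#' dung_mass_per_ha(1, 100, 225)  # 4.44 kg/ha
#' @export
dung_mass_per_ha <- function(pg_cor, mean_pg_mass_g, plot_area_m2) {
  if (any(plot_area_m2 <= 0, na.rm = TRUE))
    stop("plot_area_m2 must be positive", call. = FALSE)
  if (any(pg_cor < 0, na.rm = TRUE) || any(mean_pg_mass_g < 0, na.rm = TRUE))
    stop("counts and masses must be non-negative", call. = FALSE)
  pg_cor * (mean_pg_mass_g / 1000) / (plot_area_m2 / 10000)
}

#' Average the two dung subplots flanking an untreated plot
#'
#' U-treatment vegetation plots have one dung plot on each side; their
#' records are combined by the arithmetic mean so every vegetation plot
#' carries a single dung quantity. If either subplot's value is missing for
#' a period the mean is missing — averaging one side against unknown
#' exposure on the other would bias the mass.
#'
#' @param left,right single-row data frames (or lists) for the two subplots
#'   with fields `habitat`, `site`, `treatment`, `period` and the numeric
#'   quantities `pg_obs`, `pg_cor`, `mass_kg_ha`.
#' @return One combined row with each quantity replaced by the mean.
#' @export
average_u_plots <- function(left, right) {
  keys <- c("habitat", "site", "treatment", "period")
  for (k in keys)
    if (!identical(left[[k]], right[[k]]))
      stop("subplots disagree on '", k, "'", call. = FALSE)
  if (!identical(left$treatment, "U"))
    stop("subplot averaging applies to U-treatment dung plots only",
         call. = FALSE)
  out <- as.data.frame(left[keys])
  for (q in c("pg_obs", "pg_cor", "mass_kg_ha"))
    out[[q]] <- (left[[q]] + right[[q]]) / 2  # NA if either side missing
  out
}

#' Site- and period-specific decay fractions with fallback
#'
#' Estimates `r` per habitat x site x period from the decay trials. A
#' site-period with no trial falls back to the habitat x period mean of the
#' available sites; if none exists either, `r = 0` is used with a warning
#' (uncorrected counts, i.e. no-decay assumption).
#'
#' @param ds a `"survey_dataset"`.
#' @return Data frame `habitat, site, period, r, r_source` where `r_source`
#'   is one of `"site_trial"`, `"habitat_mean"`, `"assumed_zero"`.
#' @export
decay_rates <- function(ds) {
  stopifnot(inherits(ds, "survey_dataset"))
  des <- ds$design
  grid <- expand.grid(habitat = des$habitats, site = des$sites,
                      period = seq_len(des$n_periods),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  dt <- ds$decay_trials
  dt$r <- decay_fraction(dt$n_placed, dt$n_lost)
  out <- merge(grid, dt[c("habitat", "site", "period", "r")],
               by = c("habitat", "site", "period"), all.x = TRUE)
  out$r_source <- ifelse(is.na(out$r), NA_character_, "site_trial")
  # habitat x period mean fallback
  hp <- stats::aggregate(r ~ habitat + period, data = out, FUN = mean,
                         na.rm = TRUE, na.action = stats::na.pass)
  names(hp)[names(hp) == "r"] <- "r_hab"
  out <- merge(out, hp, by = c("habitat", "period"), all.x = TRUE)
  fill <- is.na(out$r) & !is.na(out$r_hab) & is.finite(out$r_hab)
  out$r[fill] <- out$r_hab[fill]
  out$r_source[fill] <- "habitat_mean"
  none <- is.na(out$r)
  if (any(none)) {
    warning("no decay trial for ", sum(none), " site-period(s); assuming ",
            "r = 0 (no decay correction) there", call. = FALSE)
    out$r[none] <- 0
    out$r_source[none] <- "assumed_zero"
  }
  out$r_hab <- NULL
  out[order(out$habitat, out$site, out$period), names(out)]
}

#' Site- and date-specific mean pellet-group dry mass with fallback
#'
#' Arithmetic mean of the collected pellet-group masses per site and
#' sampling date; a missing site-date falls back to the habitat x date mean.
#'
#' @param ds a `"survey_dataset"`.
#' @return Data frame `habitat, site, date, mean_mass_g, mass_source`.
#' @export
pellet_mass_means <- function(ds) {
  stopifnot(inherits(ds, "survey_dataset"))
  des <- ds$design
  grid <- expand.grid(habitat = des$habitats, site = des$sites,
                      date = des$dates,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pm <- ds$pellet_masses
  if (nrow(pm)) {
    m <- stats::aggregate(mass_g ~ habitat + site + date, data = pm,
                          FUN = mean, na.rm = TRUE)
    names(m)[names(m) == "mass_g"] <- "mean_mass_g"
  } else {
    m <- data.frame(habitat = character(), site = integer(),
                    date = as.Date(character()), mean_mass_g = numeric())
  }
  out <- merge(grid, m, by = c("habitat", "site", "date"), all.x = TRUE)
  out$mass_source <- ifelse(is.na(out$mean_mass_g), NA_character_,
                            "site_mean")
  hd <- stats::aggregate(mean_mass_g ~ habitat + date, data = out,
                         FUN = mean, na.rm = TRUE,
                         na.action = stats::na.pass)
  names(hd)[names(hd) == "mean_mass_g"] <- "m_hab"
  out <- merge(out, hd, by = c("habitat", "date"), all.x = TRUE)
  fill <- is.na(out$mean_mass_g) & is.finite(out$m_hab)
  out$mean_mass_g[fill] <- out$m_hab[fill]
  out$mass_source[fill] <- "habitat_mean"
  out$m_hab <- NULL
  out[order(out$habitat, out$site, out$date),
      c("habitat", "site", "date", "mean_mass_g", "mass_source")]
}

#' Per-plot, per-period dung quantities
#'
#' The dung accumulation stage of the pipeline: applies the decay
#' correction ([correct_pellet_count()]) with site x period decay fractions,
#' converts counts to dung dry mass per hectare using the site x date mean
#' pellet-group mass of the period's end (collection) date, and averages the
#' two U-treatment subplots so the result has one row per vegetation plot
#' and period.
#'
#' @param ds a `"survey_dataset"`.
#' @return Data frame `habitat, site, treatment, period, pg_obs, r, pg_cor,
#'   mass_kg_ha` (U rows: subplot means).
#' @export
dung_quantities <- function(ds) {
  stopifnot(inherits(ds, "survey_dataset"))
  des <- ds$design
  per <- periods(des)
  dq <- merge(ds$dung_counts, decay_rates(ds),
              by = c("habitat", "site", "period"), all.x = TRUE)
  dq$pg_cor <- correct_pellet_count(dq$pg_obs, dq$r)
  dq$date <- per$end[match(dq$period, per$period)]
  dq <- merge(dq, pellet_mass_means(ds), by = c("habitat", "site", "date"),
              all.x = TRUE)
  dq$mass_kg_ha <- dung_mass_per_ha(dq$pg_cor, dq$mean_mass_g,
                                    ds$plot_area_m2)
  # collapse subplots: mean over the dung plots attached to each
  # vegetation plot; NA if any expected subplot value is missing
  key <- interaction(dq$habitat, dq$site, dq$treatment, dq$period,
                     drop = TRUE)
  kf <- which(!duplicated(key))
  kf <- kf[order(key[kf])]                  # align with tapply level order
  out <- data.frame(habitat = dq$habitat[kf], site = dq$site[kf],
                    treatment = dq$treatment[kf], period = dq$period[kf])
  agg <- function(v)
    as.numeric(tapply(v, key, function(x) if (anyNA(x)) NA_real_ else mean(x)))
  out$pg_obs <- agg(dq$pg_obs)
  out$r <- as.numeric(tapply(dq$r, key, function(x) x[1]))
  out$pg_cor <- agg(dq$pg_cor)
  out$mass_kg_ha <- agg(dq$mass_kg_ha)
  # a U plot with only one subplot recorded is treated as missing
  n_seen <- as.integer(tapply(dq$pg_obs, key, length))
  short <- n_seen < ifelse(out$treatment == "U", 2L, 1L)
  if (any(short))
    out[short, c("pg_obs", "pg_cor", "mass_kg_ha")] <- NA_real_
  rownames(out) <- NULL
  out[order(out$habitat, out$site, out$treatment, out$period), ]
}
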