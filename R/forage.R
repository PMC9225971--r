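#' Calibrate compressed sward height against cut biomass
#'
#' Rising-plate meter readings (compressed sward height) are converted to
#' standing biomass through a least-squares calibration line fitted on
#' paired height/calibration-cut observations,
#' `biomass = a + b * height`.
#'
#' @param height rising-plate readings (any consistent unit).
#' @param biomass cut biomass at the same spots, kg DM per hectare.
#' @return An object of class `"sward_calibration"` wrapping the [lm()] fit
#'   with elements `intercept`, `slope`, `n`, `residual_sd`.
#' @examples
#' cal <- fit_calibration(c(0, 1, 2), c(0, 100, 200))
#' predict(cal, newdata = data.frame(height = 1.5))
#' @export
fit_calibration <- function(height, biomass) {
  ok <- !is.na(height) & !is.na(biomass)
  height <- height[ok]; biomass <- biomass[ok]
  if (length(height) < 3L)
    stop("calibration needs at least 3 paired observations", call. = FALSE)
  if (length(unique(height)) < 2L)
    stop("degenerate calibration: all heights equal", call. = FALSE)
  fit <- stats::lm(biomass ~ height, data = data.frame(height, biomass))
  structure(
    list(fit = fit,
         intercept = unname(stats::coef(fit)[1L]),
         slope = unname(stats::coef(fit)[2L]),
         n = length(height),
         residual_sd = summary(fit)$sigma),
    class = "sward_calibration")
}

#' @export
coef.sward_calibration <- function(object, ...)
  c(intercept = object$intercept, slope = object$slope)

#' @export
predict.sward_calibration <- function(object, newdata, ...) {
  if (!is.data.frame(newdata)) newdata <- data.frame(height = newdata)
  unname(stats::predict(object$fit, newdata = newdata))
}

#' @export
print.sward_calibration <- function(x, ...) {
  cat(sprintf(
    "Sward-height calibration: biomass = %.2f + %.2f * height (n = %d, residual SD = %.2f)\n",
    x$intercept, x$slope, x$n, x$residual_sd))
  invisible(x)
}

#' Forage removal from paired biomass increments
#'
#' Forage removal by grazing over a period is the difference between the
#' biomass increment under a movable exclusion cage (protected from
#' grazing) and the increment of the surrounding, continuously grazed
#' sward. Negative values — possible through measurement noise — are
#' retained, not truncated: truncation would bias annual export upward.
#' Users preferring the truncating convention can apply `pmax(x, 0)`.
#'
#' @param protected_increment biomass increment under the cage, kg DM/ha.
#' @param grazed_increment biomass increment on the grazed plot, kg DM/ha.
#' @return Removal in kg DM per hectare (`NA` if either increment is
#'   missing), with attribute `"negative"`: logical flag per element.
#'   Vectorised.
#' @export
forage_removal <- function(protected_increment, grazed_increment) {
  removal <- protected_increment - grazed_increment
  attr(removal, "negative") <- !is.na(removal) & removal < 0
  removal
}

#' Period-mean nutrient concentration with imputation
#'
#' Concentrations change over a sampling period, so flux arithmetic uses
#' the mean of the values measured at the period's start and end dates. A
#' missing endpoint is replaced by the habitat x date mean of the available
#' samples before averaging, so that a one-sided gap does not bias the
#' period value; a measured cell is never altered. The provenance of each
#' period value is recorded.
#'
#' @param start_value concentration at the period start date, % DM, or `NA`.
#' @param end_value concentration at the period end date, % DM, or `NA`.
#' @param fallback_start,fallback_end habitat x date mean used when the
#'   respective endpoint is missing (may be `NA` if unavailable).
#' @return A list with `value` (% DM) and `provenance`, one of
#'   `"measured_both_ends"`, `"imputed_one_end"`, `"missing"`. When one
#'   endpoint has neither a measurement nor a fallback, the other endpoint
#'   stands alone (provenance `"imputed_one_end"`); when neither endpoint
#'   can be determined the value is `NA` with a warning.
#' @export
period_concentration <- function(start_value, end_value,
                                 fallback_start = NA_real_,
                                 fallback_end = NA_real_) {
  imputed <- FALSE
  if (is.na(start_value) && !is.na(fallback_start)) {
    start_value <- fallback_start; imputed <- TRUE
  }
  if (is.na(end_value) && !is.na(fallback_end)) {
    end_value <- fallback_end; imputed <- TRUE
  }
  if (is.na(start_value) && is.na(end_value)) {
    warning("period concentration undefined: no endpoint and no fallback",
            call. = FALSE)
    return(list(value = NA_real_, provenance = "missing"))
  }
  # one endpoint unavailable even after fallback: use the other alone
  if (is.na(start_value) || is.na(end_value)) imputed <- TRUE
  list(value = mean(c(start_value, end_value), na.rm = TRUE),
       provenance = if (imputed) "imputed_one_end" else "measured_both_ends")
}

# Endpoint concentration table on the full design grid, with the first-date
# substitution for plant samples and habitat x date mean fill.
# level: "plot" (plant) or "site" (faecal).
endpoint_concentrations <- function(ds, kind) {
  des <- ds$design
  level <- if (kind == "plant") "plot" else "site"
  base <- if (level == "plot") design_plots(des) else
    expand.grid(habitat = des$habitats, site = des$sites,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- merge(base, expand.grid(date = des$dates, nutrient = c("N", "P"),
                                  KEEP.OUT.ATTRS = FALSE,
                                  stringsAsFactors = FALSE))
  cc <- ds$concentrations[ds$concentrations$kind == kind, ]
  keys <- c("habitat", "site", if (level == "plot") "treatment",
            "date", "nutrient")
  if (level == "site") cc$treatment <- NULL
  cc <- cc[c(keys, "value_pct")]
  # collapse duplicates (several samples per cell) by their mean
  if (nrow(cc))
    cc <- stats::aggregate(value_pct ~ ., data = cc, FUN = mean,
                           na.rm = TRUE, na.action = stats::na.pass)
  cc$value_pct[is.nan(cc$value_pct)] <- NA_real_
  out <- merge(grid, cc, by = keys, all.x = TRUE)
  out$provenance <- ifelse(is.na(out$value_pct), NA_character_, "measured")

  # plant samples are unavailable at the very first date by design: the
  # final date (same month, one year on) stands in for that endpoint
  if (kind == "plant") {
    first_idx <- which(out$date == des$dates[1L])
    last <- out[out$date == des$dates[length(des$dates)], ]
    ukey <- function(x) paste(x$habitat, x$site,
                              if (level == "plot") x$treatment else "",
                              x$nutrient)
    m <- match(ukey(out[first_idx, ]), ukey(last))
    need <- is.na(out$value_pct[first_idx])
    repl <- last$value_pct[m[need]]
    out$value_pct[first_idx[need]] <- repl
    out$provenance[first_idx[need][!is.na(repl)]] <- "substituted_final_date"
  }

  # habitat x date mean fallback
  hd <- stats::aggregate(value_pct ~ habitat + date + nutrient, data = out,
                         FUN = mean, na.rm = TRUE,
                         na.action = stats::na.pass)
  names(hd)[names(hd) == "value_pct"] <- "v_hab"
  out <- merge(out, hd, by = c("habitat", "date", "nutrient"), all.x = TRUE)
  fill <- is.na(out$value_pct) & is.finite(out$v_hab)
  out$value_pct[fill] <- out$v_hab[fill]
  out$provenance[fill] <- "imputed_habitat_mean"
  out$v_hab <- NULL
  out
}

#' Period-level plant and faecal nutrient concentrations
#'
#' Builds the full table of period-mean concentrations used by the flux
#' stage: plant concentrations at plot level, faecal concentrations at site
#' level (dung samples are collected per site and broadcast to both plots
#' downstream). Each period value is the mean of its start- and end-date
#' values after the imputation rules of [period_concentration()]; plant
#' values missing at the first sampling date are substituted by the final
#' date's values (the same calendar month one year later) before any mean
#' imputation.
#'
#' @param ds a `"survey_dataset"`.
#' @param kind `"plant"` or `"faecal"`.
#' @return Data frame `habitat, site, (treatment,) period, nutrient,
#'   value_pct, provenance` with provenance one of `measured_both_ends`,
#'   `substituted_final_date`, `imputed_one_end`, `missing`.
#' @export
period_concentrations <- function(ds, kind = c("plant", "faecal")) {
  stopifnot(inherits(ds, "survey_dataset"))
  kind <- match.arg(kind)
  des <- ds$design
  per <- periods(des)
  ep <- endpoint_concentrations(ds, kind)
  level_cols <- c("habitat", "site",
                  if (kind == "plant") "treatment", "nutrient")
  ukey <- function(x, d) do.call(paste, c(x[level_cols], list(format(d))))
  out_rows <- vector("list", nrow(per))
  units <- unique(ep[level_cols])
  for (p in per$period) {
    s_idx <- match(ukey(units, per$start[p]), ukey(ep, ep$date))
    e_idx <- match(ukey(units, per$end[p]), ukey(ep, ep$date))
    sv <- ep$value_pct[s_idx]; ev <- ep$value_pct[e_idx]
    sp <- ep$provenance[s_idx]; epv <- ep$provenance[e_idx]
    value <- rowMeans(cbind(sv, ev), na.rm = TRUE)
    value[is.nan(value)] <- NA_real_
    prov <- rep("measured_both_ends", nrow(units))
    prov[xor(is.na(sv), is.na(ev))] <- "imputed_one_end"
    prov[(!is.na(sp) & sp == "substituted_final_date") |
           (!is.na(epv) & epv == "substituted_final_date")] <-
      "substituted_final_date"
    prov[(!is.na(sp) & sp == "imputed_habitat_mean") |
           (!is.na(epv) & epv == "imputed_habitat_mean")] <-
      "imputed_one_end"
    prov[is.na(value)] <- "missing"
    out_rows[[p]] <- cbind(units, period = p, value_pct = value,
                           provenance = prov)
  }
  out <- do.call(rbind, out_rows)
  rownames(out) <- NULL
  if (any(out$provenance == "missing"))
    warning(sum(out$provenance == "missing"), " ", kind,
            " period concentration(s) could not be determined", call. = FALSE)
  out
}
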