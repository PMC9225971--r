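#' Define the survey design
#'
#' The design declares the factorial layout of the field survey: habitat
#' types, sampling sites within each habitat, vegetation-management
#' treatments, and the ordered sampling dates whose consecutive pairs form
#' the sampling periods. The shipped default is the layout of a one-year red
#' deer grazing survey on the Grafenwöhr training area: 2 habitats
#' (heathland, grassland) x 4 sites x 2 treatments (B = burnt, U =
#' untreated), six sampling dates from April 2015 to April 2016 giving five
#' periods that tile exactly one year. Dung is recorded on separate dung
#' plots: two subplots ("left", "right") flanking each U plot and one plot
#' adjoining each B plot.
#'
#' @param habitats character vector of habitat type names.
#' @param sites integer vector of site identifiers within each habitat.
#' @param treatments character vector of treatment codes.
#' @param dates ordered vector of sampling dates (coerced with [as.Date()]);
#'   `length(dates) - 1` sampling periods are derived from consecutive pairs.
#' @param period_labels optional character labels for the periods; defaults
#'   to "Mon1-Mon2" built from the month abbreviations of the bounding dates.
#' @param plot_area_m2 area of one survey plot in square metres.
#'
#' @return An object of class `"study_design"`: a list with elements
#'   `habitats`, `sites`, `treatments`, `dates`, `period_labels`,
#'   `n_periods`, `plot_area_m2`.
#' @examples
#' d <- study_design()
#' periods(d)
#' @export
study_design <- function(habitats = c("heathland", "grassland"),
                         sites = 1:4,
                         treatments = c("B", "U"),
                         dates = c("2015-04-15", "2015-05-15", "2015-06-15",
                                   "2015-08-15", "2015-10-15", "2016-04-15"),
                         period_labels = NULL,
                         plot_area_m2 = 225) {
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("'dates' contains unparseable dates", call. = FALSE)
  if (length(dates) < 2L) stop("need at least two sampling dates", call. = FALSE)
  if (is.unsorted(dates, strictly = TRUE))
    stop("'dates' must be strictly increasing", call. = FALSE)
  if (length(habitats) < 1L || anyDuplicated(habitats))
    stop("'habitats' must be distinct and non-empty", call. = FALSE)
  if (!is.numeric(sites) || anyDuplicated(sites))
    stop("'sites' must be distinct integers", call. = FALSE)
  if (anyDuplicated(treatments))
    stop("'treatments' must be distinct", call. = FALSE)
  if (!is.numeric(plot_area_m2) || length(plot_area_m2) != 1L || plot_area_m2 <= 0)
    stop("'plot_area_m2' must be a single positive number", call. = FALSE)
  n_periods <- length(dates) - 1L
  if (is.null(period_labels)) {
    mon <- months(dates, abbreviate = TRUE)
    period_labels <- paste0(mon[-length(mon)], "-", mon[-1L])
  }
  if (length(period_labels) != n_periods)
    stop("'period_labels' must have one label per period", call. = FALSE)
  structure(
    list(habitats = as.character(habitats),
         sites = as.integer(sites),
         treatments = as.character(treatments),
         dates = dates,
         period_labels = as.character(period_labels),
         n_periods = n_periods,
         plot_area_m2 = as.numeric(plot_area_m2)),
    class = "study_design")
}

#' Sampling periods of a design
#'
#' @param design a [study_design()] object.
#' @return A data frame with one row per sampling period: `period` (ordinal
#'   index), `label`, `start`, `end` (dates). Periods are consecutive and
#'   non-overlapping; period i ends where period i + 1 starts.
#' @export
periods <- function(design) {
  stopifnot(inherits(design, "study_design"))
  data.frame(period = seq_len(design$n_periods),
             label = design$period_labels,
             start = design$dates[-length(design$dates)],
             end = design$dates[-1L])
}

#' @export
print.study_design <- function(x, ...) {
  cat("Survey design:",
      length(x$habitats), "habitats x", length(x$sites), "sites x",
      length(x$treatments), "treatments;",
      length(x$dates), "sampling dates /", x$n_periods, "periods\n")
  cat("  habitats:  ", paste(x$habitats, collapse = ", "), "\n")
  cat("  treatments:", paste(x$treatments, collapse = ", "), "\n")
  cat("  dates:     ", paste(format(x$dates), collapse = ", "), "\n")
  cat("  plot area: ", x$plot_area_m2, "m2\n")
  invisible(x)
}

# all vegetation plots of a design (one per habitat x site x treatment)
design_plots <- function(design) {
  expand.grid(habitat = design$habitats, site = design$sites,
              treatment = design$treatments,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

# dung plots: U treatment has two subplots flanking the vegetation plot,
# every other treatment has a single adjoining plot (subplot NA)
design_dung_plots <- function(design) {
  pl <- design_plots(design)
  u <- pl$treatment == "U"
  rbind(
    cbind(pl[!u, , drop = FALSE], subplot = NA_character_),
    cbind(pl[u, , drop = FALSE], subplot = "left"),
    cbind(pl[u, , drop = FALSE], subplot = "right"))
}
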