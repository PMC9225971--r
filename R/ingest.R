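#' Assemble and validate a survey dataset
#'
#' Bundles the five raw record tables of a dung/vegetation survey into a
#' validated container used by every downstream stage. All tables are long
#' format; a missing value is an `NA` cell (never 0 — an absent measurement
#' and a measured zero mean different things throughout the pipeline).
#'
#' Required columns (extra columns are dropped):
#' \describe{
#'   \item{dung_counts}{`habitat, site, treatment, subplot, period, pg_obs` —
#'     observed pellet-group count per dung plot and period. `subplot` is
#'     "left"/"right" for U-treatment dung plots and `NA` otherwise.}
#'   \item{decay_trials}{`habitat, site, period, n_placed, n_lost` — marked
#'     fresh pellet groups placed at the period start and the number that had
#'     disappeared (fewer than six pellets retrieved) by its end.}
#'   \item{pellet_masses}{`habitat, site, date, mass_g` — one row per
#'     collected pellet group, oven-dry mass in grams.}
#'   \item{concentrations}{`kind, habitat, site, treatment, date, nutrient,
#'     value_pct` — N/P concentration in % of dry mass. `kind` is "plant"
#'     (plot level) or "faecal" (site level; `treatment` is `NA`).}
#'   \item{forage}{`habitat, site, treatment, period, removal_kg_ha` — forage
#'     removal by grazing, kg DM per hectare, possibly `NA`.}
#' }
#'
#' @param dung_counts,decay_trials,pellet_masses,concentrations,forage data
#'   frames as described above.
#' @param design a [study_design()]; defaults to the shipped study layout.
#' @param plot_area_m2 plot area in m2, defaulting to the design's.
#' @return An object of class `"survey_dataset"`: a list of the validated
#'   tables plus `design` and `plot_area_m2`.
#' @seealso [read_survey()], [missingness_report()], [nutrient_budget()]
#' @export
survey_dataset <- function(dung_counts, decay_trials, pellet_masses,
                           concentrations, forage,
                           design = study_design(),
                           plot_area_m2 = design$plot_area_m2) {
  stopifnot(inherits(design, "study_design"))
  dung_counts <- take_cols(dung_counts, "dung_counts",
    c("habitat", "site", "treatment", "subplot", "period", "pg_obs"))
  decay_trials <- take_cols(decay_trials, "decay_trials",
    c("habitat", "site", "period", "n_placed", "n_lost"))
  pellet_masses <- take_cols(pellet_masses, "pellet_masses",
    c("habitat", "site", "date", "mass_g"))
  concentrations <- take_cols(concentrations, "concentrations",
    c("kind", "habitat", "site", "treatment", "date", "nutrient", "value_pct"))
  forage <- take_cols(forage, "forage",
    c("habitat", "site", "treatment", "period", "removal_kg_ha"))

  if (nrow(dung_counts) == 0L)
    stop("validation error: dung_counts has no rows", call. = FALSE)

  for (tb in c("pellet_masses", "concentrations")) {
    x <- get(tb)
    x$date <- as.Date(x$date)
    assign(tb, x)
  }
  dung_counts$site <- as.integer(dung_counts$site)
  decay_trials$site <- as.integer(decay_trials$site)
  pellet_masses$site <- as.integer(pellet_masses$site)
  concentrations$site <- as.integer(concentrations$site)
  forage$site <- as.integer(forage$site)

  check_keys(dung_counts, "dung_counts", design, period = TRUE)
  check_keys(decay_trials, "decay_trials", design, period = TRUE,
             treatment = FALSE)
  check_keys(pellet_masses, "pellet_masses", design, treatment = FALSE,
             date = TRUE)
  check_keys(forage, "forage", design, period = TRUE)
  check_keys(concentrations, "concentrations", design, date = TRUE,
             treatment = FALSE)

  # dung plot identity: subplot left/right only with treatment U
  bad <- which(
    (dung_counts$treatment == "U" &
       !dung_counts$subplot %in% c("left", "right")) |
    (dung_counts$treatment != "U" & !is.na(dung_counts$subplot)))
  if (length(bad))
    stop("validation error in dung_counts: subplot must be left/right for U ",
         "plots and empty otherwise; offending rows: ",
         paste(bad, collapse = ", "), call. = FALSE)

  validate_count(dung_counts$pg_obs, "dung_counts$pg_obs")
  validate_count(decay_trials$n_placed, "decay_trials$n_placed",
                 allow_na = FALSE)
  validate_count(decay_trials$n_lost, "decay_trials$n_lost", allow_na = FALSE)
  bad <- which(decay_trials$n_lost > decay_trials$n_placed)
  if (length(bad))
    stop("validation error in decay_trials: n_lost > n_placed in rows ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(decay_trials$n_placed < 1L))
    stop("validation error in decay_trials: n_placed must be >= 1",
         call. = FALSE)

  if (any(pellet_masses$mass_g <= 0, na.rm = TRUE))
    stop("validation error in pellet_masses: non-positive mass_g",
         call. = FALSE)

  if (!all(concentrations$kind %in% c("plant", "faecal")))
    stop("validation error in concentrations: kind must be plant or faecal",
         call. = FALSE)
  if (!all(concentrations$nutrient %in% c("N", "P")))
    stop("validation error in concentrations: nutrient must be N or P",
         call. = FALSE)
  v <- concentrations$value_pct
  bad <- which(!is.na(v) & (v <= 0 | v >= 100))
  if (length(bad))
    stop("validation error in concentrations: value_pct outside (0, 100) in ",
         "rows ", paste(bad, collapse = ", "), call. = FALSE)

  structure(
    list(dung_counts = dung_counts, decay_trials = decay_trials,
         pellet_masses = pellet_masses, concentrations = concentrations,
         forage = forage, design = design,
         plot_area_m2 = as.numeric(plot_area_m2)),
    class = "survey_dataset")
}

take_cols <- function(x, name, cols) {
  if (!is.data.frame(x)) stop("'", name, "' must be a data frame", call. = FALSE)
  miss <- setdiff(cols, names(x))
  if (length(miss))
    stop("table '", name, "' lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  x <- as.data.frame(x)[cols]
  rownames(x) <- NULL
  x
}

check_keys <- function(x, name, design, period = FALSE, date = FALSE,
                       treatment = TRUE) {
  bad <- !x$habitat %in% design$habitats
  bad <- bad | !x$site %in% design$sites
  if (treatment) bad <- bad | !x$treatment %in% design$treatments
  if (period) bad <- bad | !x$period %in% seq_len(design$n_periods)
  if (date) bad <- bad | !x$date %in% design$dates
  if (any(bad))
    stop("validation error in ", name, ": key outside the declared design ",
         "in rows ", paste(which(bad), collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

validate_count <- function(x, what, allow_na = TRUE) {
  bad <- !is.na(x) & (x < 0 | x != round(x))
  if (!allow_na) bad <- bad | is.na(x)
  if (any(bad))
    stop("validation error: ", what, " must be non-negative integers",
         if (!allow_na) " (no missing values)",
         "; offending rows: ", paste(which(bad), collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("Survey dataset (", length(x$design$habitats), " habitats, ",
      length(x$design$sites), " sites, ", x$design$n_periods,
      " periods)\n", sep = "")
  for (tb in c("dung_counts", "decay_trials", "pellet_masses",
               "concentrations", "forage"))
    cat(sprintf("  %-15s %5d rows\n", tb, nrow(x[[tb]])))
  invisible(x)
}

#' Read a survey dataset from delimited text files
#'
#' Reads the five record tables from a directory (default file names
#' `dung_counts.csv`, `decay_trials.csv`, `pellet_masses.csv`,
#' `concentrations.csv`, `forage.csv`) or from a named list/vector of paths,
#' then validates them with [survey_dataset()]. Empty cells are read as
#' missing values.
#'
#' @param path directory containing the five files, or a named character
#'   vector/list with elements `dung_counts`, `decay_trials`,
#'   `pellet_masses`, `concentrations`, `forage`.
#' @param design a [study_design()].
#' @param sep field delimiter (default comma).
#' @return A validated `"survey_dataset"`.
#' @export
read_survey <- function(path, design = study_design(), sep = ",") {
  tables <- c("dung_counts", "decay_trials", "pellet_masses",
              "concentrations", "forage")
  if (is.character(path) && length(path) == 1L && dir.exists(path)) {
    files <- file.path(path, paste0(tables, ".csv"))
    names(files) <- tables
  } else {
    files <- unlist(path)
    miss <- setdiff(tables, names(files))
    if (length(miss))
      stop("no path given for table(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    files <- files[tables]
  }
  absent <- files[!file.exists(files)]
  if (length(absent))
    stop("file not found: ", paste(absent, collapse = ", "), call. = FALSE)
  read1 <- function(f) {
    out <- tryCatch(
      utils::read.table(f, header = TRUE, sep = sep, na.strings = "",
                        stringsAsFactors = FALSE, colClasses = NA),
      error = function(e)
        stop("parse error in ", f, ": ", conditionMessage(e), call. = FALSE))
    out
  }
  tabs <- lapply(files, read1)
  survey_dataset(tabs$dung_counts, tabs$decay_trials, tabs$pellet_masses,
                 tabs$concentrations, tabs$forage, design = design)
}

#' Write a survey dataset to delimited text files
#'
#' Inverse of [read_survey()]: writes the five record tables as headed CSV
#' files with empty cells for missing values, so that a read/write/read
#' round trip reproduces the dataset exactly.
#'
#' @param ds a `"survey_dataset"`.
#' @param dir output directory (created if needed).
#' @param sep field delimiter.
#' @return Invisibly, the named vector of files written.
#' @export
write_survey <- function(ds, dir, sep = ",") {
  stopifnot(inherits(ds, "survey_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- c("dung_counts", "decay_trials", "pellet_masses",
              "concentrations", "forage")
  files <- file.path(dir, paste0(tables, ".csv"))
  names(files) <- tables
  for (tb in tables)
    utils::write.table(ds[[tb]], files[[tb]], sep = sep, na = "",
                       row.names = FALSE, quote = FALSE)
  invisible(files)
}

#' Tabulate data availability per variable and date
#'
#' Counts non-missing observations per variable and sampling date (or
#' period, for period-indexed variables) against the design size, so that
#' gaps — missed faecal collections, structurally unavailable forage data —
#' are visible before any imputation happens.
#'
#' @param ds a `"survey_dataset"`.
#' @return A data frame with columns `variable`, `when` (date or period
#'   label), `n_available`, `n_design`.
#' @export
missingness_report <- function(ds) {
  stopifnot(inherits(ds, "survey_dataset"))
  des <- ds$design
  per <- periods(des)
  n_plots <- nrow(design_plots(des))
  n_dung <- nrow(design_dung_plots(des))
  n_sites <- length(des$habitats) * length(des$sites)
  out <- list()
  add <- function(variable, when, n_available, n_design)
    out[[length(out) + 1L]] <<- data.frame(
      variable = variable, when = as.character(when),
      n_available = as.integer(n_available), n_design = as.integer(n_design))

  for (p in per$period) {
    dc <- ds$dung_counts[ds$dung_counts$period == p, ]
    add("dung_count", per$label[p], sum(!is.na(dc$pg_obs)), n_dung)
    dt <- ds$decay_trials[ds$decay_trials$period == p, ]
    add("decay_trial", per$label[p], nrow(dt), n_sites)
    fo <- ds$forage[ds$forage$period == p, ]
    add("forage_removal", per$label[p], sum(!is.na(fo$removal_kg_ha)), n_plots)
  }
  for (d in format(des$dates)) {
    pm <- ds$pellet_masses[format(ds$pellet_masses$date) == d, ]
    add("pellet_mass", d, sum(!is.na(pm$mass_g)), NA)
    for (kind in c("plant", "faecal")) for (nut in c("N", "P")) {
      cc <- ds$concentrations
      cc <- cc[cc$kind == kind & cc$nutrient == nut &
                 format(cc$date) == d, ]
      add(paste0(kind, "_", nut), d, sum(!is.na(cc$value_pct)),
          if (kind == "plant") n_plots else n_sites)
    }
  }
  do.call(rbind, out)
}
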