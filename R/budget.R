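#' Summarise per-plot flux values for one habitat x period
#'
#' Arithmetic mean of the non-missing plot values with its standard error
#' (sample SD over the square root of the number of contributing plots).
#' Missing plots reduce `n`; they never enter as zero. A single
#' contributing plot yields SE 0 with a warning (no replication).
#'
#' @param values numeric vector of per-plot values, possibly with `NA`.
#' @return A list `mean`, `se`, `n`. With zero non-missing values, all
#'   three are `NA`/0 and a warning is raised.
#' @examples
#' summarize_period(c(2, 4))  # mean 3, se 1, n 2
#' @export
summarize_period <- function(values) {
  v <- values[!is.na(values)]
  n <- length(v)
  if (n == 0L) {
    warning("no non-missing observations in period summary", call. = FALSE)
    return(list(mean = NA_real_, se = NA_real_, n = 0L))
  }
  if (n == 1L) {
    warning("single observation in period summary; SE set to 0",
            call. = FALSE)
    return(list(mean = v, se = 0, n = 1L))
  }
  list(mean = mean(v), se = stats::sd(v) / sqrt(n), n = n)
}

#' Annual rate from period summaries by Gaussian error propagation
#'
#' The annual rate is the sum of the period means; because the period means
#' are treated as independent, its standard error is the square root of the
#' sum of squared period SEs, and the confidence interval is
#' `mean +/- z * se` with `z = 1.96` for a normal 95% interval.
#'
#' @param means per-period means (one per period, none missing).
#' @param ses per-period standard errors.
#' @param z normal quantile for the confidence interval.
#' @return A list `mean`, `se`, `lower`, `upper`.
#' @examples
#' annualize(rep(1, 5), c(3, 4, 0, 0, 0))  # se 5
#' @export
annualize <- function(means, ses, z = 1.96) {
  if (length(means) != length(ses))
    stop("means and ses must have equal length", call. = FALSE)
  if (anyNA(means) || anyNA(ses))
    stop("annual rate undefined: missing period summary", call. = FALSE)
  m <- sum(means)
  se <- sqrt(sum(ses^2))
  list(mean = m, se = se, lower = m - z * se, upper = m + z * se)
}

#' Net nutrient balance (import minus export)
#'
#' Difference between an annual import and an annual export rate, with its
#' SE combined in quadrature and a normal confidence interval. Negative
#' values mean the grazers remove more of the nutrient than their excreta
#' return.
#'
#' @param import,export lists with `mean` and `se` (as from [annualize()]).
#' @param z normal quantile for the confidence interval.
#' @return A list `mean`, `se`, `lower`, `upper`.
#' @examples
#' net_balance(list(mean = 4.91, se = 0), list(mean = 18.81, se = 0))$mean
#' @export
net_balance <- function(import, export, z = 1.96) {
  for (x in list(import, export))
    if (!is.list(x) || !all(c("mean", "se") %in% names(x)))
      stop("import and export must be lists with mean and se", call. = FALSE)
  d <- import$mean - export$mean
  se <- sqrt(import$se^2 + export$se^2)
  list(mean = d, se = se, lower = d - z * se, upper = d + z * se)
}

#' Ratio of net N export to net P export
#'
#' Magnitude ratio of the two net balances, conventionally reported to one
#' decimal. Comparable to the plant tissue N:P ratio: similarity of the two
#' suggests grazing does not shift the habitat's nutrient limitation.
#'
#' @param delta_n,delta_p net N and P balances, kg per hectare per year.
#' @param digits decimals for rounding (default 1; `NULL` for unrounded).
#' @return `|delta_n| / |delta_p|`, or `NA` with a warning when
#'   `delta_p == 0`.
#' @examples
#' np_export_ratio(-13.90, -1.08)  # 12.9
#' @export
np_export_ratio <- function(delta_n, delta_p, digits = 1) {
  if (any(delta_p == 0, na.rm = TRUE)) {
    warning("net P balance is zero: N:P export ratio undefined",
            call. = FALSE)
  }
  out <- ifelse(delta_p == 0, NA_real_, abs(delta_n) / abs(delta_p))
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Net nutrient input under an atmospheric deposition scenario
#'
#' Balances an atmospheric deposition rate against the grazer-mediated net
#' balance: `net_input = deposition + delta` (delta is negative when export
#' exceeds import). The conservative variant uses the upper confidence
#' limit of delta — the smallest net removal the data support — and is the
#' quantity to compare against a habitat's critical load.
#'
#' @param delta net balance as a list with `mean`, `lower`, `upper`
#'   (see [net_balance()]), kg per hectare per year.
#' @param deposition atmospheric deposition, kg per hectare per year (>= 0).
#' @return A list `deposition`, `net_input`, `conservative_net_input`.
#' @examples
#' deposition_scenario(list(mean = -13.9, lower = -22.87, upper = -4.93), 11)
#' @export
deposition_scenario <- function(delta, deposition) {
  if (any(deposition < 0, na.rm = TRUE))
    stop("deposition must be non-negative", call. = FALSE)
  if (!is.list(delta) || !all(c("mean", "upper") %in% names(delta)))
    stop("delta must be a list with at least mean and upper", call. = FALSE)
  list(deposition = deposition,
       net_input = deposition + delta$mean,
       conservative_net_input = deposition + delta$upper)
}

#' Net removal as a fraction of the nutrient in annual production
#'
#' Expresses the net nutrient removal relative to the nutrient pool bound
#' in annually produced aboveground biomass.
#'
#' @param net_removal net balance, kg per hectare per year (sign ignored).
#' @param production_pool nutrient in annual aboveground production, kg per
#'   hectare per year (> 0).
#' @return `|net_removal| / production_pool`, a fraction.
#' @examples
#' fraction_of_production(-10, 25)  # 0.4
#' @export
fraction_of_production <- function(net_removal, production_pool) {
  if (any(production_pool <= 0, na.rm = TRUE))
    stop("production_pool must be positive", call. = FALSE)
  abs(net_removal) / production_pool
}

# Period summaries for every habitat x period x variable of a flux table.
# Returns a data.frame habitat, period, variable, mean, se, n.
flux_period_summaries <- function(flux, design) {
  vars <- c(dung_mass = "mass_kg_ha", faecal_N = "faecal_import",
            urinary_N = "urinary_import", total_N = "total_import",
            export_N = "export", u_ratio = "u_ratio",
            P_import = "faecal_import", export_P = "export")
  nut_of <- c(dung_mass = "N", faecal_N = "N", urinary_N = "N",
              total_N = "N", export_N = "N", u_ratio = "N",
              P_import = "P", export_P = "P")
  out <- list()
  for (h in design$habitats) for (p in seq_len(design$n_periods)) {
    for (v in names(vars)) {
      rows <- flux[flux$habitat == h & flux$period == p &
                     flux$nutrient == nut_of[[v]], ]
      s <- suppressWarnings(summarize_period(rows[[vars[[v]]]]))
      out[[length(out) + 1L]] <- data.frame(
        habitat = h, period = p, variable = v,
        mean = s$mean, se = s$se, n = s$n)
    }
  }
  do.call(rbind, out)
}
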