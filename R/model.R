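#' Estimate annual nutrient import/export budgets from a survey dataset
#'
#' The package's front door: runs the whole accounting pipeline on a
#' validated survey dataset and returns the habitat-level annual N and P
#' budgets. The stages are (i) decay-corrected dung quantities
#' ([dung_quantities()]), (ii) period-mean concentrations with imputation
#' ([period_concentrations()]), (iii) per-plot, per-period fluxes including
#' the modelled urinary N fraction ([period_fluxes()]), and (iv) annual
#' aggregation: per habitat and period the plot values are averaged, the
#' period means are summed over the year and their SEs combined by Gaussian
#' error propagation ([annualize()]), net balances are import minus export
#' ([net_balance()]), and net balances are weighed against atmospheric
#' deposition ([deposition_scenario()]).
#'
#' @param data a `"survey_dataset"` (see [survey_dataset()],
#'   [read_survey()], [generate_survey()]).
#' @param deposition named numeric vector of atmospheric deposition rates
#'   in kg per hectare per year, by nutrient. Defaults to `c(N = 11,
#'   P = 0.3)` — the upper modelled N deposition for the study region and
#'   the European average P deposition.
#' @param z normal quantile for all confidence intervals (1.96 for 95%).
#' @param urinary a [urinary_params()] object (body mass etc.).
#' @return An object of class `"nutrient_budget"` with components
#'   `annual` (data frame: habitat, variable, nutrient, estimate, se,
#'   lower, upper, n_periods), `balance` (habitat x nutrient net balances),
#'   `scenarios`, `np_ratio`, `period_summaries`, `flux`, `dung`,
#'   `missingness`, plus the call and settings. Methods: [print()],
#'   [summary()], [coef()], [confint()], [plot()], [simulate()].
#' @examples
#' ds <- generate_survey(seed = 1)
#' fit <- nutrient_budget(ds)
#' fit
#' coef(fit)
#' @export
nutrient_budget <- function(data, deposition = c(N = 11, P = 0.3),
                            z = 1.96, urinary = urinary_params()) {
  stopifnot(inherits(data, "survey_dataset"))
  design <- data$design
  flux <- period_fluxes(data, urinary = urinary)
  dung <- dung_quantities(data)
  ps <- flux_period_summaries(flux, design)

  annual_vars <- c(dung_mass = "N", faecal_N = "N", urinary_N = "N",
                   total_N = "N", export_N = "N", P_import = "P",
                   export_P = "P")
  ann <- list()
  for (h in design$habitats) for (v in names(annual_vars)) {
    s <- ps[ps$habitat == h & ps$variable == v, ]
    s <- s[order(s$period), ]
    a <- annualize(s$mean, s$se, z = z)
    ann[[length(ann) + 1L]] <- data.frame(
      habitat = h, variable = v, nutrient = annual_vars[[v]],
      estimate = a$mean, se = a$se, lower = a$lower, upper = a$upper,
      n_periods = nrow(s))
  }
  annual <- do.call(rbind, ann)
  rownames(annual) <- NULL

  get_ann <- function(h, v) {
    r <- annual[annual$habitat == h & annual$variable == v, ]
    list(mean = r$estimate, se = r$se, lower = r$lower, upper = r$upper)
  }
  bal <- list()
  for (h in design$habitats) {
    dN <- net_balance(get_ann(h, "total_N"), get_ann(h, "export_N"), z = z)
    dP <- net_balance(get_ann(h, "P_import"), get_ann(h, "export_P"), z = z)
    bal[[length(bal) + 1L]] <- data.frame(
      habitat = h, nutrient = c("N", "P"),
      import = c(get_ann(h, "total_N")$mean, get_ann(h, "P_import")$mean),
      export = c(get_ann(h, "export_N")$mean, get_ann(h, "export_P")$mean),
      delta = c(dN$mean, dP$mean), se = c(dN$se, dP$se),
      lower = c(dN$lower, dP$lower), upper = c(dN$upper, dP$upper))
  }
  balance <- do.call(rbind, bal)
  rownames(balance) <- NULL

  scen <- list()
  for (h in design$habitats) for (nut in names(deposition)) {
    b <- balance[balance$habitat == h & balance$nutrient == nut, ]
    if (!nrow(b)) next
    sc <- deposition_scenario(list(mean = b$delta, lower = b$lower,
                                   upper = b$upper),
                              deposition[[nut]])
    scen[[length(scen) + 1L]] <- data.frame(
      habitat = h, nutrient = nut, deposition = sc$deposition,
      net_input = sc$net_input,
      conservative_net_input = sc$conservative_net_input)
  }
  scenarios <- if (length(scen)) do.call(rbind, scen) else NULL

  npr <- vapply(design$habitats, function(h) {
    b <- balance[balance$habitat == h, ]
    suppressWarnings(np_export_ratio(b$delta[b$nutrient == "N"],
                                     b$delta[b$nutrient == "P"]))
  }, numeric(1))

  structure(
    list(annual = annual, balance = balance, scenarios = scenarios,
         np_ratio = npr, period_summaries = ps, flux = flux, dung = dung,
         missingness = missingness_report(data), design = design,
         deposition = deposition, z = z, urinary = urinary,
         call = match.call()),
    class = "nutrient_budget")
}

#' @export
print.nutrient_budget <- function(x, digits = 2, ...) {
  cat("Annual nutrient budgets from red deer grazing survey\n")
  cat("(kg per hectare per year; CI at z =", x$z, ")\n\n")
  b <- x$balance
  for (h in unique(b$habitat)) {
    cat(h, ":\n", sep = "")
    bh <- b[b$habitat == h, ]
    for (i in seq_len(nrow(bh)))
      cat(sprintf(
        "  %s: import %.*f, export %.*f, net %+.*f [%.*f, %.*f]\n",
        bh$nutrient[i], digits, bh$import[i], digits, bh$export[i],
        digits, bh$delta[i], digits, bh$lower[i], digits, bh$upper[i]))
  }
  invisible(x)
}

#' @export
summary.nutrient_budget <- function(object, ...) {
  structure(list(annual = object$annual, balance = object$balance,
                 scenarios = object$scenarios, np_ratio = object$np_ratio,
                 z = object$z, deposition = object$deposition),
            class = "summary.nutrient_budget")
}

#' @export
print.summary.nutrient_budget <- function(x, digits = 2, ...) {
  fmt <- function(d) {
    d[] <- lapply(d, function(c) if (is.numeric(c)) round(c, digits) else c)
    d
  }
  cat("Annual rates (kg/ha/a):\n")
  print(fmt(x$annual), row.names = FALSE)
  cat("\nNet balances (import - export):\n")
  print(fmt(x$balance), row.names = FALSE)
  if (!is.null(x$scenarios)) {
    cat("\nDeposition scenarios:\n")
    print(fmt(x$scenarios), row.names = FALSE)
  }
  cat("\nNet N:P export ratio by habitat:\n")
  print(round(x$np_ratio, 1))
  invisible(x)
}

#' @export
coef.nutrient_budget <- function(object, ...) {
  a <- object$annual
  out <- a$estimate
  names(out) <- paste(a$habitat, a$variable, sep = ".")
  d <- object$balance
  dn <- d$delta
  names(dn) <- paste(d$habitat, "delta", d$nutrient, sep = ".")
  c(out, dn)
}

#' @export
confint.nutrient_budget <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  a <- object$annual
  est <- c(a$estimate, object$balance$delta)
  se <- c(a$se, object$balance$se)
  nm <- c(paste(a$habitat, a$variable, sep = "."),
          paste(object$balance$habitat, "delta", object$balance$nutrient,
                sep = "."))
  ci <- cbind(est - z * se, est + z * se)
  dimnames(ci) <- list(nm, paste0(100 * c((1 - level) / 2,
                                          1 - (1 - level) / 2), " %"))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Plot annual imports against exports
#'
#' Bar chart of annual import and export per habitat and nutrient with the
#' propagated 95% confidence intervals as error bars.
#'
#' @param x a `"nutrient_budget"`.
#' @param ... passed to [graphics::barplot()].
#' @return Invisibly, `x`.
#' @export
plot.nutrient_budget <- function(x, ...) {
  b <- x$balance
  a <- x$annual
  get <- function(h, v, f)
    a[[f]][a$habitat == h & a$variable == v]
  op <- graphics::par(mfrow = c(1, length(unique(b$habitat))),
                      mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  for (h in unique(b$habitat)) {
    vals <- rbind(import = c(N = get(h, "total_N", "estimate"),
                             P = get(h, "P_import", "estimate")),
                  export = c(N = get(h, "export_N", "estimate"),
                             P = get(h, "export_P", "estimate")))
    up <- rbind(c(get(h, "total_N", "upper"), get(h, "P_import", "upper")),
                c(get(h, "export_N", "upper"), get(h, "export_P", "upper")))
    lo <- rbind(c(get(h, "total_N", "lower"), get(h, "P_import", "lower")),
                c(get(h, "export_N", "lower"), get(h, "export_P", "lower")))
    bp <- graphics::barplot(vals, beside = TRUE, main = h,
                            ylab = "kg / ha / a",
                            ylim = c(0, max(up) * 1.1),
                            legend.text = rownames(vals), ...)
    graphics::arrows(bp, pmax(lo, 0), bp, up, angle = 90, code = 3,
                     length = 0.04)
  }
  invisible(x)
}

#' Simulate annual budget replicates from the fitted period summaries
#'
#' Parametric draws of the annual rates: each period mean is drawn from a
#' normal distribution with its estimated mean and SE (independently across
#' periods, mirroring the error-propagation assumption) and summed over the
#' year. The empirical SD of the replicates converges to the propagated
#' annual SE, which makes this a direct Monte-Carlo check of the
#' propagation.
#'
#' @param object a `"nutrient_budget"`.
#' @param nsim number of replicates.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A data frame with `nsim` rows per habitat x variable: columns
#'   `habitat`, `variable`, `replicate`, `annual`.
#' @export
simulate.nutrient_budget <- function(object, nsim = 1000, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ps <- object$period_summaries
  out <- list()
  for (h in unique(ps$habitat)) for (v in unique(ps$variable)) {
    s <- ps[ps$habitat == h & ps$variable == v, ]
    if (anyNA(s$mean) || anyNA(s$se)) next
    draws <- matrix(stats::rnorm(nsim * nrow(s), mean = rep(s$mean, each = nsim),
                                 sd = rep(s$se, each = nsim)),
                    nrow = nsim)
    out[[length(out) + 1L]] <- data.frame(
      habitat = h, variable = v, replicate = seq_len(nsim),
      annual = rowSums(draws))
  }
  do.call(rbind, out)
}
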