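#' Neutral ORF-disruption rate from inherited-pseudogene branches
#'
#' Estimates how often a neutrally evolving ORF acquires a disrupting
#' mutation, by counting disruption events on branches that were already
#' pseudogenized in their ancestor (`psi1` branches: neutral by
#' definition, so every lesion on them accrued free of selection) and
#' dividing by the summed exposure of those branches, in million years or
#' in synonymous-substitution units. Multi-gene inputs pool events and
#' exposures; supply row-bound tables with a `gene` column if provenance
#' matters.
#'
#' @param mapped_events Tibble from [map_events] (possibly several genes
#'   row-bound).
#' @param classes Branch classification tibble from [classify_branches]
#'   (row-bound in the same way, with a `gene` column when pooling).
#' @param exposures Tibble with columns `branch` and `exposure` (branch
#'   time in myr, or branch dS), plus `gene` when pooling; exposure must be
#'   available for every psi1 branch.
#' @param unit `"myr"` or `"dS"` (bookkeeping only).
#' @return A `rate_estimate`: `n_events`, `exposure`, `unit`, `rate`
#'   (events per unit), `mean_waiting` (unit per event), `waiting_se`
#'   (delta-method `mean_waiting / sqrt(n)`), and `ci` (exact Poisson 95%
#'   interval for the rate).
#' @export
neutral_disruption_rate <- function(mapped_events, classes, exposures,
                                    unit = c("myr", "dS")) {
  unit <- match.arg(unit)
  by <- intersect(c("gene", "branch"), intersect(names(classes),
                                                 names(exposures)))
  psi1 <- dplyr::filter(classes, .data$class == "psi1")
  psi1 <- dplyr::inner_join(psi1, exposures, by = by)
  if (nrow(psi1) < nrow(dplyr::filter(classes, .data$class == "psi1"))) {
    stop("exposure missing for some psi1 branches")
  }
  exposure <- sum(psi1$exposure)
  if (nrow(psi1) > 0L && exposure <= 0) stop("total psi1 exposure is zero")
  ev_by <- intersect(by, names(mapped_events))
  ev <- dplyr::semi_join(mapped_events, psi1, by = ev_by)
  n <- nrow(ev)
  if (exposure <= 0) stop("no psi1 branches: zero exposure")
  ci_count <- stats::poisson.test(n)$conf.int
  structure(list(
    n_events = n, exposure = exposure, unit = unit,
    rate = n / exposure,
    mean_waiting = if (n > 0) exposure / n else NA_real_,
    waiting_se = if (n > 0) (exposure / n) / sqrt(n) else NA_real_,
    ci = ci_count / exposure,
    events = ev
  ), class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat("<rate_estimate> ", x$n_events, " events over ",
      format(x$exposure, digits = 4), " ", x$unit, "\n", sep = "")
  if (x$n_events > 0) {
    cat("  one disruption every ", format(x$mean_waiting, digits = 3),
        " +/- ", format(x$waiting_se, digits = 3), " ", x$unit, "\n",
        sep = "")
  }
  cat("  rate ", format(x$rate, digits = 4), "/", x$unit,
      "  (95% CI ", format(x$ci[1], digits = 3), "-",
      format(x$ci[2], digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Probability that an ORF stays undisrupted for a given exposure
#'
#' Under the Poisson model, the chance of acquiring no disrupting mutation
#' over exposure `t` at rate `rate` is `exp(-rate * t)`.
#'
#' @param rate Disruption rate (per myr or per dS), >= 0.
#' @param t Exposure in the same unit, >= 0.
#' @return Probability in (0, 1].
#' @export
prob_intact <- function(rate, t) {
  if (any(rate < 0) || any(t < 0)) stop("rate and t must be >= 0")
  exp(-rate * t)
}
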