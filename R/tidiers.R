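#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted codon model
#'
#' @param x A `codon_fit`.
#' @param ... Unused.
#' @return Tibble of omega-class estimates (`class`, `estimate`, `fixed`,
#'   `flag`) with mixture proportions where the model has site classes.
#' @export
tidy.codon_fit <- function(x, ...) {
  out <- x$omega
  if (length(x$proportions) > 1L &&
      length(x$proportions) == nrow(out)) {
    out$proportion <- x$proportions
  }
  out
}

#' @rdname tidy.codon_fit
#' @return For `glance()`: one row with `lnL`, `np`, `AIC`, `kappa`,
#'   `n_sites`, `n_taxa`, `converged`.
#' @export
glance.codon_fit <- function(x, ...) {
  tibble::tibble(lnL = x$lnL, np = x$np, AIC = 2 * x$np - 2 * x$lnL,
                 kappa = x$kappa, n_sites = x$n_sites, n_taxa = x$n_taxa,
                 converged = any(x$convergence$converged))
}

#' Tidy a disruption-rate estimate
#' @param x A `rate_estimate`.
#' @param ... Unused.
#' @return One-row tibble with the count, exposure, rate, waiting time and
#'   exact Poisson interval.
#' @export
tidy.rate_estimate <- function(x, ...) {
  tibble::tibble(n_events = x$n_events, exposure = x$exposure,
                 unit = x$unit, rate = x$rate,
                 mean_waiting = x$mean_waiting, waiting_se = x$waiting_se,
                 ci_lower = x$ci[1], ci_upper = x$ci[2])
}

#' Tidy a neutral-decay simulation
#' @param x A `decay_sim`.
#' @param ... Unused.
#' @return Tibble histogram: `count`, `n_replicates`, `frequency`,
#'   `p_dis` (cumulative fraction of replicates at or below `count`).
#' @export
tidy.decay_sim <- function(x, ...) {
  tab <- table(x$counts)
  counts <- as.integer(names(tab))
  n <- as.integer(tab)
  tibble::tibble(count = counts, n_replicates = n,
                 frequency = n / length(x$counts),
                 p_dis = cumsum(n) / length(x$counts))
}

#' @rdname tidy.decay_sim
#' @export
glance.decay_sim <- function(x, ...) {
  tibble::tibble(n_reps = length(x$counts), L = x$config$L,
                 duration = x$config$duration,
                 mean_count = mean(x$counts),
                 expected_count = x$expected_count,
                 p_dis_0 = x$p_dis(0))
}

#' Tidy a paralog omega correlation
#' @param x A `correlation_result`.
#' @param ... Unused.
#' @return One-row tibble: `r_s`, `p_value`, `n_used`, `n_excluded`,
#'   `method`.
#' @export
tidy.correlation_result <- function(x, ...) {
  tibble::tibble(r_s = x$r_s, p_value = x$p_value, n_used = x$n_used,
                 n_excluded = nrow(x$excluded), method = x$method)
}

#' Histogram of simulated neutral disruption counts
#'
#' @param object A `decay_sim`.
#' @param observed Observed disruption count to highlight (default 0).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.decay_sim <- function(object, observed = 0L, ...) {
  df <- tidy.decay_sim(object)
  p0 <- object$p_dis(observed)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count,
                                   y = .data$frequency)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_vline(xintercept = observed + 0.5, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(
      x = "disrupting mutations per replicate",
      y = "fraction of replicates",
      title = sprintf("Neutral ORF decay: P(count <= %d) = %.2g",
                      observed, p0)) +
    ggplot2::theme_minimal()
}

#' Per-branch omega estimates from a free-ratio fit
#'
#' @param object A `codon_fit` from [free_ratio].
#' @param ... Unused.
#' @return A ggplot; branches with dS = 0 or dN = 0 sentinels are shown as
#'   open points at the panel edges.
#' @export
autoplot.codon_fit <- function(object, ...) {
  if (is.null(object$omega_by_branch)) {
    stop("autoplot is defined for free-ratio fits; see tidy() for others")
  }
  df <- object$omega_by_branch
  cap <- max(c(1, df$estimate[is.finite(df$estimate)]), na.rm = TRUE) * 1.2
  df$shown <- pmin(df$estimate, cap)
  df$sentinel <- df$flag != "ok"
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$label,
                                                      .data$shown),
                                   y = .data$shown,
                                   shape = .data$sentinel)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                guide = "none") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "dN/dS (free-ratio)") +
    ggplot2::theme_minimal()
}
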