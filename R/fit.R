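#' Fit a GY94 codon model by maximum likelihood
#'
#' Maximises the pruning log-likelihood over kappa, the model's free omega
#' and mixture parameters and (optionally) branch lengths, using BFGS on
#' log/logit-transformed parameters. Following standard practice the
#' optimisation is run from at least two initial omega values and the best
#' end point is kept; both end points are recorded so convergence to the
#' same optimum can be checked.
#'
#' @inheritParams codon_log_likelihood
#' @param model A `codon_model_spec` ([branch_model], [site_model],
#'   [branch_site_model]); default one-ratio.
#' @param estimate_branch_lengths Jointly estimate branch lengths (default
#'   `TRUE`); set `FALSE` to keep the input tree's lengths fixed.
#' @param estimate_kappa Estimate the transition/transversion ratio
#'   (default `TRUE`); set `FALSE` to pin it at `kappa`.
#' @param starts Initial omega values (one optimisation run each).
#' @param control Passed to [stats::optim] (method BFGS); sensible defaults
#'   are filled in.
#' @return A `codon_fit` object: `lnL`, `np`, `kappa`, `omega` (tibble of
#'   class estimates with dS=0/dN=0 sentinel flags), `proportions` (site
#'   mixtures), `branch_lengths`, `counts` (per-branch expected numbers of
#'   nonsynonymous and synonymous substitutions), `convergence` (one row
#'   per start) and the inputs needed for downstream posteriors.
#' @export
fit_codon_model <- function(aln, tree, model = one_ratio_model(),
                            pi = "F3X4", kappa = 2,
                            estimate_branch_lengths = TRUE,
                            estimate_kappa = TRUE,
                            starts = c(0.5, 2), control = list(),
                            code = genetic_code()) {
  if (length(alignment_taxa(aln)) < 2L) stop("need at least 2 taxa")
  data <- prepare_codon_data(aln, code)
  ts <- tree_structure(tree)
  pi <- resolve_pi(pi, aln, code)
  bl0 <- resolve_branch_lengths(tree, NULL)
  packed <- pack_spec(model, tree)
  children <- tree$edge[, 2L]
  n_edge <- length(children)
  n_omega <- packed$np_omega

  unpack_all <- function(theta) {
    off <- 0L
    if (estimate_kappa) {
      kap <- min(max(exp(theta[1L]), 1e-3), 999)
      off <- 1L
    } else {
      kap <- kappa
    }
    bl <- bl0
    if (estimate_branch_lengths) {
      bl[children] <- exp(theta[off + seq_len(n_edge)])
      off <- off + n_edge
    }
    mix <- packed$unpack(theta[off + seq_len(n_omega)])
    list(kappa = kap, bl = bl, mix = mix)
  }
  lik_cache <- new.env(parent = emptyenv())
  negll <- function(theta) {
    pr <- unpack_all(theta)
    if (!all(is.finite(pr$mix$p)) ||
        !all(is.finite(pr$mix$omega[, children]))) {
      return(1e10)  # degenerate corner of the transform; step back
    }
    cl <- class_site_likelihoods(data, ts, pi, pr$kappa, pr$bl,
                                 pr$mix$omega, pr$mix$p, code,
                                 cache = lik_cache)
    site_lik <- as.numeric(cl %*% pr$mix$p)
    -sum(data$weights * pmax(log(site_lik), -700))
  }

  ctrl <- utils::modifyList(list(maxit = 300L, reltol = 1e-10), control)
  runs <- lapply(starts, function(ws) {
    th0 <- c(if (estimate_kappa) log(kappa),
             if (estimate_branch_lengths)
               log(pmax(bl0[children], 1e-4)),
             packed$init(ws))
    opt <- stats::optim(th0, negll, method = "BFGS", control = ctrl)
    list(start = ws, opt = opt)
  })
  lnls <- vapply(runs, function(r) -r$opt$value, numeric(1))
  best <- runs[[which.max(lnls)]]
  conv <- tibble::tibble(
    start_omega = vapply(runs, function(r) r$start, numeric(1)),
    lnL = lnls,
    converged = vapply(runs, function(r) r$opt$convergence == 0L, logical(1)),
    evaluations = vapply(runs, function(r) r$opt$counts[["function"]],
                         numeric(1)))
  if (!any(conv$converged)) {
    warning("optimiser did not report convergence from any start")
  }

  pr <- unpack_all(best$opt$par)
  mix <- pr$mix
  np <- n_omega + (if (estimate_kappa) 1L else 0L) +
    (if (estimate_branch_lengths) n_edge else 0L)

  # per-branch expected N/S substitution counts at the estimates; in a
  # mixture, class k carries a share of substitutions proportional to
  # p_k times its relative rate under the common scale
  n_sites <- sum(data$weights)
  bt <- branch_table(tree)
  K <- nrow(mix$omega)
  t_e <- pr$bl[bt$branch]
  EN <- vapply(seq_len(nrow(bt)), function(i) {
    ch <- bt$branch[i]
    w_k <- mix$omega[, ch]
    fN_k <- vapply(w_k, function(w)
      gy94_nonsyn_fraction(pi, pr$kappa, w, code), numeric(1))
    if (K == 1L) {
      share <- 1
    } else {
      mu_k <- vapply(w_k, function(w)
        gy94_mean_rate(pi, pr$kappa, w, code), numeric(1))
      share <- mix$p * mu_k / sum(mix$p * mu_k)
    }
    t_e[i] * n_sites * sum(share * fN_k)
  }, numeric(1))
  ES <- t_e * n_sites - EN
  counts <- tibble::tibble(branch = bt$branch, label = bt$label,
                           length = t_e, EN = EN, ES = ES)

  omega_tbl <- omega_table(mix, packed, model)

  structure(list(
    lnL = -best$opt$value, np = np, kappa = pr$kappa, pi = pi,
    model = model, mix = mix, theta = best$opt$par,
    omega = omega_tbl,
    proportions = mix$p,
    branch_lengths = stats::setNames(t_e, bt$branch),
    estimate_branch_lengths = estimate_branch_lengths,
    counts = counts, convergence = conv,
    n_sites = n_sites, n_taxa = length(data$taxa),
    aln = aln, tree = tree, code = code, data = data
  ), class = "codon_fit")
}

# Tidy omega estimates with dS=0 / dN=0 sentinel flags. Estimates pinned at
# the omega bounds stand for branches without synonymous (omega -> Inf) or
# nonsynonymous (omega -> 0) change and must not leak into statistics.
omega_table <- function(mix, packed, model) {
  est <- mix$omega_by_class
  flag <- rep("ok", length(est))
  flag[est >= 500] <- "ds_zero"
  flag[est <= 1e-5 & grepl("^(w|b)", names(est))] <- "dn_zero"
  fixed_names <- names(model$fixed %||% numeric())
  tibble::tibble(class = names(est), estimate = unname(est),
                 fixed = names(est) %in% fixed_names, flag = flag)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.codon_fit <- function(x, ...) {
  cat("<codon_fit> lnL = ", format(x$lnL, nsmall = 4), ", np = ", x$np,
      ", kappa = ", format(x$kappa, digits = 4), "\n", sep = "")
  print(x$omega)
  invisible(x)
}

#' @export
logLik.codon_fit <- function(object, ...) {
  structure(object$lnL, df = object$np, class = "logLik")
}

#' Likelihood-ratio test of nested codon models
#'
#' @param fit_null,fit_alt `codon_fit` objects, the null nested in the
#'   alternative.
#' @return One-row tibble: `two_delta_lnL`, `df`, `p_value` (plain
#'   chi-squared reference distribution).
#' @export
lrt <- function(fit_null, fit_alt) {
  if (fit_alt$np <= fit_null$np) {
    stop("alternative must have more free parameters than the null")
  }
  stat <- 2 * (fit_alt$lnL - fit_null$lnL)
  if (stat < -0.05) {
    warning("2*delta lnL = ", format(stat, digits = 4),
            " is negative beyond optimizer tolerance; clamped to 0")
  }
  stat <- max(stat, 0)
  df <- fit_alt$np - fit_null$np
  tibble::tibble(two_delta_lnL = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Naive empirical Bayes site-class posteriors
#'
#' For a fitted site-class mixture, the posterior that site `s` belongs to
#' class `k` is proportional to the class proportion times the site's
#' class-conditional likelihood, normalised per site.
#'
#' @param fit A `codon_fit` with more than one site class.
#' @return Tibble with columns `site`, `class`, `omega`, `posterior`.
#' @export
site_posteriors <- function(fit) {
  mix <- fit$mix
  K <- length(mix$p)
  if (K < 2L) stop("site posteriors require a site-class mixture model")
  ts <- tree_structure(fit$tree)
  bl <- rep(NA_real_, length(fit$tree$tip.label) + fit$tree$Nnode)
  bl[as.integer(names(fit$branch_lengths))] <- fit$branch_lengths
  cl <- class_site_likelihoods(fit$data, ts, fit$pi, fit$kappa, bl,
                               mix$omega, mix$p, fit$code)
  post_pat <- sweep(cl, 2L, mix$p, `*`)
  post_pat <- post_pat / rowSums(post_pat)
  post <- post_pat[fit$data$pattern_of, , drop = FALSE]
  class_names <- pack_spec(fit$model, fit$tree)$class_labels
  if (length(class_names) != K) class_names <- paste0("class", seq_len(K))
  class_omega <- apply(mix$omega, 1L, function(z) stats::median(z, na.rm = TRUE))
  tibble::tibble(
    site = rep(seq_len(fit$data$n_sites), K),
    class = rep(class_names, each = fit$data$n_sites),
    omega = rep(class_omega, each = fit$data$n_sites),
    posterior = as.numeric(post))
}

#' Free-ratio model: one omega per branch
#'
#' @inheritParams fit_codon_model
#' @return A `codon_fit`; `$omega_by_branch` gives the per-branch tibble
#'   with `estimate`, `flag` (`ds_zero` branches are reported as infinite
#'   omega, `dn_zero` as zero, both excluded from downstream correlation),
#'   and expected N/S counts.
#' @export
free_ratio <- function(aln, tree, ...) {
  fit <- fit_codon_model(aln, tree, model = free_ratio_model(), ...)
  om <- fit$omega
  bt <- branch_table(tree)
  cls <- resolve_branch_classes(free_ratio_model(), tree)
  tbl <- tibble::tibble(branch = bt$branch, class = cls[bt$branch])
  tbl <- dplyr::left_join(tbl, om[, c("class", "estimate", "flag")],
                          by = "class")
  tbl <- dplyr::left_join(tbl, bt[, c("branch", "label")], by = "branch")
  tbl <- dplyr::left_join(tbl,
                          fit$counts[, c("branch", "EN", "ES", "length")],
                          by = "branch")
  tbl$class <- NULL
  tbl$estimate[tbl$flag == "ds_zero"] <- Inf
  tbl$estimate[tbl$flag == "dn_zero"] <- 0
  fit$omega_by_branch <- dplyr::arrange(tbl, .data$branch)
  fit
}

#' Fit the standard site-model ledger and its LRT pairs
#'
#' Fits M1a, M2a, M7 and M8 (optionally M0/M3) and performs the two
#' canonical positive-selection comparisons, M1a vs M2a and M7 vs M8 (df =
#' 2 each). A positive-selection call requires both a significant LRT and
#' an extra-class omega estimate above 1.
#'
#' @inheritParams fit_codon_model
#' @param models Site models to fit.
#' @param ncat Beta discretisation classes for M7/M8.
#' @param alpha Significance level for the positive-selection call.
#' @return List with `fits` (named list of `codon_fit`) and `tests`
#'   (tibble: comparison, two_delta_lnL, df, p_value, omega_extra,
#'   positive_selection).
#' @export
fit_site_models <- function(aln, tree, models = c("M1a", "M2a", "M7", "M8"),
                            ncat = 10L, alpha = 0.05, ...) {
  if (length(alignment_taxa(aln)) < 4L) {
    warning("fewer than 4 taxa: site-model tests will have little power")
  }
  fits <- lapply(stats::setNames(models, models), function(m) {
    fit_codon_model(aln, tree, model = site_model(m, ncat = ncat), ...)
  })
  pairs <- list(c("M1a", "M2a"), c("M7", "M8"))
  tests <- dplyr::bind_rows(lapply(pairs, function(pr) {
    if (!all(pr %in% models)) return(NULL)
    res <- lrt(fits[[pr[1L]]], fits[[pr[2L]]])
    extra <- fits[[pr[2L]]]$omega
    w_extra <- extra$estimate[extra$class %in% c("w2", "ws")]
    dplyr::mutate(res,
                  comparison = paste(pr, collapse = " vs "), .before = 1L,
                  omega_extra = w_extra,
                  positive_selection = .data$p_value < alpha & w_extra > 1)
  }))
  list(fits = fits, tests = tests)
}

#' Branch-site test of positive selection (test 2)
#'
#' Fits branch-site model A with free foreground omega2 and its null with
#' omega2 = 1 fixed, and compares them with a one-degree-of-freedom LRT.
#'
#' @inheritParams fit_codon_model
#' @param foreground Foreground branch ids (child node ids) or tip labels.
#' @return List with `alt`, `null` (`codon_fit`s) and `test` (LRT tibble).
#' @export
fit_branch_site_A <- function(aln, tree, foreground, ...) {
  alt <- fit_codon_model(aln, tree,
                         model = branch_site_model(foreground, null = FALSE),
                         ...)
  null <- fit_codon_model(aln, tree,
                          model = branch_site_model(foreground, null = TRUE),
                          ...)
  list(alt = alt, null = null, test = lrt(null, alt))
}
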