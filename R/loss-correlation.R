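#' Cross-tabulate pseudogene status of two paralogs over tree branches
#'
#' Each branch of the shared tree contributes one count to a 2x2 table:
#' pseudogenized in both genes (`a`), in gene A only (`b`), gene B only
#' (`c`), or neither (`d`). A branch counts as pseudogenized when its class
#' is `psi1` or `psi2`.
#'
#' @param classes_a,classes_b Branch classification tibbles from
#'   [classify_branches], on the same tree.
#' @param level `"branch"` (default: every branch counts) or `"species"`
#'   (terminal branches only).
#' @return A `loss_table`: list with `a`, `b`, `c`, `d` and the underlying
#'   per-branch tibble.
#' @export
categorize_branch_pairs <- function(classes_a, classes_b,
                                    level = c("branch", "species")) {
  level <- match.arg(level)
  if (!setequal(classes_a$branch, classes_b$branch)) {
    stop("branch sets differ between the two classifications; ",
         "classify both genes on the same shared tree")
  }
  tbl <- dplyr::inner_join(
    dplyr::select(classes_a, "branch", "label", class_a = "class"),
    dplyr::select(classes_b, "branch", class_b = "class"),
    by = "branch")
  if (level == "species") {
    tbl <- dplyr::filter(tbl, !startsWith(.data$label, "node"))
  }
  psi <- function(x) x %in% c("psi1", "psi2")
  tbl <- dplyr::mutate(tbl, pseudo_a = psi(.data$class_a),
                       pseudo_b = psi(.data$class_b))
  structure(list(
    a = sum(tbl$pseudo_a & tbl$pseudo_b),
    b = sum(tbl$pseudo_a & !tbl$pseudo_b),
    c = sum(!tbl$pseudo_a & tbl$pseudo_b),
    d = sum(!tbl$pseudo_a & !tbl$pseudo_b),
    branches = tbl
  ), class = "loss_table")
}

#' @export
print.loss_table <- function(x, ...) {
  cat("<loss_table> both:", x$a, " A-only:", x$b, " B-only:", x$c,
      " neither:", x$d, "\n")
  invisible(x)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric enumeration with the sum-of-smaller-probabilities
#' convention: the two-sided p-value adds the point probabilities of all
#' tables (with the observed margins) whose probability does not exceed
#' the observed table's, with a `1 + 1e-7` rounding guard.
#'
#' @param x A `loss_table`, a 2x2 matrix, or a length-4 vector `(a, b, c,
#'   d)`.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(x) {
  if (inherits(x, "loss_table")) x <- c(x$a, x$b, x$c, x$d)
  if (is.matrix(x)) x <- c(x[1, 1], x[1, 2], x[2, 1], x[2, 2])
  if (any(x < 0) || any(x != round(x))) {
    stop("cell counts must be non-negative integers")
  }
  a <- x[1]; b <- x[2]; cc <- x[3]; d <- x[4]
  m <- a + b          # margin of gene A pseudogenes
  n <- cc + d
  k <- a + cc         # margin of gene B pseudogenes
  if (m + n == 0) stop("empty table")
  support <- max(0, k - n):min(m, k)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Spearman correlation of per-branch omega between two paralogs
#'
#' Correlates free-ratio omega estimates branch by branch after applying
#' the standard exclusions: any branch where either gene has no synonymous
#' change (dS = 0, omega reported as infinite) or no nonsynonymous change
#' (dN = 0, omega reported as 0) is dropped. Ties receive average ranks.
#' The p-value uses the exact permutation distribution for n <= 9 (no
#' ties) and the t approximation otherwise.
#'
#' @param omega_a,omega_b Per-branch omega tables (`$omega_by_branch` of a
#'   [free_ratio] fit, or any tibble with columns `branch`, `estimate`,
#'   `flag`), indexed by the same branches.
#' @return A `correlation_result`: `r_s`, `p_value`, `n_used`, `excluded`
#'   (tibble of dropped branches with reasons).
#' @export
spearman_branch_omega <- function(omega_a, omega_b) {
  tbl <- dplyr::inner_join(
    dplyr::select(omega_a, "branch", est_a = "estimate", flag_a = "flag"),
    dplyr::select(omega_b, "branch", est_b = "estimate", flag_b = "flag"),
    by = "branch")
  if (nrow(tbl) != nrow(omega_a) || nrow(tbl) != nrow(omega_b)) {
    stop("omega tables are not indexed by the same branches")
  }
  bad <- tbl$flag_a != "ok" | tbl$flag_b != "ok"
  excluded <- dplyr::mutate(
    tbl[bad, ], reason = dplyr::case_when(
      .data$flag_a == "ds_zero" | .data$flag_b == "ds_zero" ~
        "dS = 0 (omega infinite)",
      TRUE ~ "dN = 0 (omega zero)"))
  use <- tbl[!bad, ]
  n <- nrow(use)
  if (n < 3L) stop("insufficient branches after exclusions (n = ", n, ")")
  no_ties <- !anyDuplicated(use$est_a) && !anyDuplicated(use$est_b)
  ct <- suppressWarnings(stats::cor.test(
    use$est_a, use$est_b, method = "spearman",
    exact = n <= 9L && no_ties))
  structure(list(
    r_s = unname(ct$estimate),
    p_value = ct$p.value,
    n_used = n,
    excluded = excluded,
    method = if (n <= 9L && no_ties) "exact permutation" else
      "t approximation"
  ), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat("<correlation_result> r_s = ", format(x$r_s, digits = 4),
      ", p = ", format(x$p_value, digits = 4), " (n = ", x$n_used,
      ", ", nrow(x$excluded), " branches excluded)\n", sep = "")
  invisible(x)
}
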