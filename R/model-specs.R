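#' Branch model with labelled omega classes
#'
#' Specifies a codon model in which every branch belongs to one omega class
#' (e.g. `intact`, `psi1`, `psi2`, or a foreground label), with some classes
#' estimated and others pinned to fixed values (typically 1 for a neutral
#' null).
#'
#' @param classes Branch classes: either a tibble with columns `branch`
#'   (child node id) and `class` (as returned by [classify_branches]), or a
#'   character vector indexed by child node id (as in `tree$branch.class`),
#'   or a single string to give every branch the same class (one-ratio
#'   model).
#' @param fixed Named numeric vector pinning class omegas, e.g.
#'   `c(psi1 = 1)`.
#' @return A `branch_model_spec`.
#' @export
branch_model <- function(classes = "all", fixed = numeric()) {
  structure(list(classes = classes, fixed = fixed),
            class = c("branch_model_spec", "codon_model_spec"))
}

#' One-ratio (M0) model
#' @export
one_ratio_model <- function() branch_model("all")

#' Free-ratio model specification (one omega per branch)
#' @export
free_ratio_model <- function() {
  structure(list(free_ratio = TRUE, fixed = numeric()),
            class = c("branch_model_spec", "codon_model_spec"))
}

#' Site models M0/M1a/M2a/M3/M7/M8
#'
#' Site-class mixtures in the PAML tradition: M1a (nearly neutral: omega0 <
#' 1 plus omega1 = 1), M2a (adds a class with omega >= 1), M3 (k free
#' discrete classes), M7 (beta-distributed omega), M8 (beta plus a class
#' with omega >= 1). Beta models are discretised into `ncat`
#' equal-probability classes represented by their class medians.
#'
#' @param name One of `"M0"`, `"M1a"`, `"M2a"`, `"M3"`, `"M7"`, `"M8"`.
#' @param k Number of discrete classes for M3.
#' @param ncat Number of discretisation classes for the beta in M7/M8.
#' @return A `site_model_spec`.
#' @export
site_model <- function(name = c("M0", "M1a", "M2a", "M3", "M7", "M8"),
                       k = 3L, ncat = 10L) {
  name <- match.arg(name)
  structure(list(name = name, k = as.integer(k), ncat = as.integer(ncat)),
            class = c("site_model_spec", "codon_model_spec"))
}

#' Branch-site model A (and its omega2 = 1 null)
#'
#' Four site classes: a proportion `p0` of sites under purifying selection
#' (omega0 < 1) everywhere, `p1` neutral (omega1 = 1) everywhere, and two
#' classes in which sites switch to omega2 on the foreground branches while
#' staying at omega0 (class 2a) or 1 (class 2b) on the background. The null
#' pins omega2 = 1 (one fewer parameter, LRT df = 1).
#'
#' @param foreground Integer vector of foreground branch ids (child node
#'   ids), or a character vector of tip labels whose terminal branches are
#'   foreground.
#' @param null Fix omega2 = 1?
#' @return A `branch_site_spec`.
#' @export
branch_site_model <- function(foreground, null = FALSE) {
  if (length(foreground) == 0L) stop("foreground branch set is empty")
  structure(list(foreground = foreground, null = null),
            class = c("branch_site_spec", "codon_model_spec"))
}

# ---- internal: resolve branch classes to a per-node character vector ----
resolve_branch_classes <- function(spec, tree) {
  n <- length(tree$tip.label) + tree$Nnode
  if (isTRUE(spec$free_ratio)) {
    cls <- paste0("b", seq_len(n))
    # the two root-child edges form one path under a reversible model
    # (pulley principle): only their combination is identifiable, so they
    # share one omega class
    root_children <- tree$edge[tree$edge[, 1] == tree_root(tree), 2]
    cls[root_children] <- paste0("b", min(root_children))
    cls[tree_root(tree)] <- NA
    return(cls)
  }
  classes <- spec$classes
  if (is.data.frame(classes)) {
    cls <- rep(NA_character_, n)
    cls[classes$branch] <- classes$class
  } else if (length(classes) == 1L && is.null(names(classes))) {
    cls <- rep(classes, n)
    cls[tree_root(tree)] <- NA
  } else {
    cls <- rep(NA_character_, n)
    cls[seq_along(classes)] <- classes
  }
  unl <- setdiff(tree$edge[, 2], which(!is.na(cls)))
  if (length(unl)) {
    stop("branches without a class label: ", paste(unl, collapse = ", "))
  }
  cls
}

resolve_foreground <- function(fg, tree) {
  if (is.character(fg)) {
    idx <- match(fg, tree$tip.label)
    if (anyNA(idx)) stop("foreground tips not in tree: ",
                         paste(fg[is.na(idx)], collapse = ", "))
    return(idx)
  }
  bad <- setdiff(as.integer(fg), tree$edge[, 2])
  if (length(bad)) stop("foreground branch ids not in tree: ",
                        paste(bad, collapse = ", "))
  as.integer(fg)
}

# ---- internal: parameter packing for each spec ----
# A packed spec provides: $np_omega (free omega/mixture parameter count),
# $init(omega_start) -> numeric theta, $unpack(theta) -> list(p = mixture
# proportions, omega = K x n_node matrix of class omegas by child node,
# class_label, omega_label) .

logit <- function(p) log(p / (1 - p))

# Medians of equal-probability beta classes; qbeta can return NaN (with a
# warning) for extreme shapes explored by the optimiser, so non-finite
# quantiles are floored into (0, 1).
beta_class_medians <- function(ncat, p, q) {
  w <- suppressWarnings(stats::qbeta((seq_len(ncat) - 0.5) / ncat, p, q))
  w[!is.finite(w)] <- 1e-8
  pmin(pmax(w, 1e-8), 1)
}
inv_logit <- function(x) 1 / (1 + exp(-x))
softmax <- function(x) { e <- exp(x - max(x)); e / sum(e) }
clamp_omega <- function(w) pmin(pmax(w, 1e-6), 999)

pack_spec <- function(spec, tree, ncat_override = NULL) {
  n_node <- length(tree$tip.label) + tree$Nnode
  if (inherits(spec, "branch_model_spec")) {
    cls <- resolve_branch_classes(spec, tree)
    labels <- sort(unique(stats::na.omit(cls)))
    free <- setdiff(labels, names(spec$fixed))
    fixed <- spec$fixed[names(spec$fixed) %in% labels]
    list(
      np_omega = length(free),
      class_labels = labels,
      init = function(omega_start) rep(log(omega_start), length(free)),
      unpack = function(theta) {
        w <- stats::setNames(numeric(length(labels)), labels)
        w[free] <- clamp_omega(exp(theta))
        w[names(fixed)] <- fixed
        omega <- matrix(NA_real_, 1L, n_node)
        omega[1L, ] <- w[cls]
        list(p = 1, omega = omega, class_label = "branch",
             omega_by_class = w, free = free)
      })
  } else if (inherits(spec, "site_model_spec")) {
    pack_site_spec(spec, n_node)
  } else if (inherits(spec, "branch_site_spec")) {
    fg <- resolve_foreground(spec$foreground, tree)
    is_fg <- seq_len(n_node) %in% fg
    null <- isTRUE(spec$null)
    list(
      np_omega = if (null) 3L else 4L,
      class_labels = c("2a_like_0", "2b_like_1", "fg_2a", "fg_2b"),
      init = function(omega_start) {
        th <- c(log(0.45 / 0.1), log(0.45 / 0.1), logit(min(omega_start, 0.9)))
        if (!null) th <- c(th, log(max(omega_start, 1.5) - 1))
        th
      },
      unpack = function(theta) {
        pr <- softmax(c(theta[1L], theta[2L], 0))
        p0 <- pr[1L]; p1 <- pr[2L]; p2 <- pr[3L]
        w0 <- inv_logit(theta[3L])
        w2 <- if (null) 1 else min(1 + exp(theta[4L]), 999)
        denom <- max(p0 + p1, 1e-12)
        p <- c(p0, p1, p2 * p0 / denom, p2 * p1 / denom)
        p <- p / sum(p)
        omega <- matrix(NA_real_, 4L, n_node)
        omega[1L, ] <- w0
        omega[2L, ] <- 1
        omega[3L, ] <- ifelse(is_fg, w2, w0)
        omega[4L, ] <- ifelse(is_fg, w2, 1)
        list(p = p, omega = omega, class_label = "branch-site",
             omega_by_class = c(w0 = w0, w1 = 1, w2 = w2),
             proportions = c(p0 = p[1], p1 = p[2], p2a = p[3], p2b = p[4]))
      })
  } else stop("unknown model specification")
}

pack_site_spec <- function(spec, n_node) {
  name <- spec$name
  const_omega <- function(w) {
    K <- length(w)
    omega <- matrix(rep(w, n_node), K, n_node)
    omega
  }
  if (name == "M0") {
    list(np_omega = 1L, class_labels = "w",
         init = function(ws) log(ws),
         unpack = function(theta) {
           w <- clamp_omega(exp(theta))
           list(p = 1, omega = const_omega(w), omega_by_class = c(w = w))
         })
  } else if (name == "M1a") {
    list(np_omega = 2L, class_labels = c("w0", "w1"),
         init = function(ws) c(logit(0.7), logit(min(ws, 0.9))),
         unpack = function(theta) {
           p0 <- inv_logit(theta[1L]); w0 <- inv_logit(theta[2L])
           list(p = c(p0, 1 - p0), omega = const_omega(c(w0, 1)),
                omega_by_class = c(w0 = w0, w1 = 1))
         })
  } else if (name == "M2a") {
    list(np_omega = 4L, class_labels = c("w0", "w1", "w2"),
         init = function(ws) c(log(0.6 / 0.1), log(0.3 / 0.1),
                               logit(min(ws, 0.9)), log(max(ws, 1.5) - 1)),
         unpack = function(theta) {
           p <- softmax(c(theta[1L], theta[2L], 0))
           w0 <- inv_logit(theta[3L])
           w2 <- min(1 + exp(theta[4L]), 999)
           list(p = p, omega = const_omega(c(w0, 1, w2)),
                omega_by_class = c(w0 = w0, w1 = 1, w2 = w2))
         })
  } else if (name == "M3") {
    k <- spec$k
    list(np_omega = 2L * k - 1L,
         class_labels = paste0("w", seq_len(k)),
         init = function(ws) c(rep(0, k - 1L),
                               log(ws * 2^(seq_len(k) - (k + 1) / 2))),
         unpack = function(theta) {
           p <- softmax(c(theta[seq_len(k - 1L)], 0))
           w <- clamp_omega(exp(theta[k:(2L * k - 1L)]))
           list(p = p, omega = const_omega(w),
                omega_by_class = stats::setNames(w, paste0("w", seq_len(k))))
         })
  } else if (name == "M7") {
    ncat <- spec$ncat
    list(np_omega = 2L, class_labels = paste0("beta", seq_len(ncat)),
         init = function(ws) c(log(1), log(2)),
         unpack = function(theta) {
           pq <- pmin(pmax(exp(theta[1:2]), 0.005), 99)
           w <- beta_class_medians(ncat, pq[1L], pq[2L])
           list(p = rep(1 / ncat, ncat), omega = const_omega(w),
                omega_by_class = c(p = pq[1L], q = pq[2L]))
         })
  } else if (name == "M8") {
    ncat <- spec$ncat
    list(np_omega = 4L,
         class_labels = c(paste0("beta", seq_len(ncat)), "ws"),
         init = function(ws) c(logit(0.9), log(1), log(2),
                               log(max(ws, 1.5) - 1)),
         unpack = function(theta) {
           p0 <- inv_logit(theta[1L])
           pq <- pmin(pmax(exp(theta[2:3]), 0.005), 99)
           wsel <- min(1 + exp(theta[4L]), 999)
           w <- c(beta_class_medians(ncat, pq[1L], pq[2L]), wsel)
           list(p = c(rep(p0 / ncat, ncat), 1 - p0),
                omega = const_omega(w),
                omega_by_class = c(p0 = p0, p = pq[1L], q = pq[2L],
                                   ws = wsel))
         })
  } else stop("unknown site model ", name)
}
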