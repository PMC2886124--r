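# Prepared codon data: integer states over sense codons, compressed to
# site patterns. State 0 = fully ambiguous (any gap/ambiguity in the
# codon); stop codons are refused with a pointer to sanitize_alignment().
prepare_codon_data <- function(aln, code = genetic_code()) {
  strs <- alignment_codon_strings(aln)
  taxa <- names(strs)
  sense <- code$sense
  states <- vapply(strs, function(cod) {
    s <- match(cod, sense)
    amb <- !grepl("^[ACGT]{3}$", cod)
    bad <- which(!amb & is.na(s))
    if (length(bad)) {
      stop("stop codon(s) in likelihood columns (reference codon ",
           paste(utils::head(bad, 3L), collapse = ", "),
           "); run sanitize_alignment() first")
    }
    s[amb] <- 0L
    s
  }, integer(aln$n_ref_codons))
  states <- t(states)  # taxa x sites
  key <- apply(states, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  pattern_of <- match(key, key[first])
  pat <- states[, first, drop = FALSE]
  w <- as.numeric(table(factor(pattern_of, levels = seq_len(sum(first)))))
  list(taxa = taxa, patterns = pat, weights = w, pattern_of = pattern_of,
       n_sites = aln$n_ref_codons)
}

tree_structure <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  list(edge = po$edge, n_tip = length(tree$tip.label),
       nnode = tree$Nnode, root = tree_root(tree),
       tip_label = tree$tip.label)
}

# Felsenstein pruning for one rate class. `tipstates` is a (ntip x npat)
# integer matrix in tree tip order; `P` a list of transition matrices
# indexed by child node id. Returns the 61 x npat root partial matrix.
prune_partials <- function(ts, tipstates, P) {
  npat <- ncol(tipstates)
  partial <- vector("list", ts$n_tip + ts$nnode)
  edge <- ts$edge
  for (e in seq_len(nrow(edge))) {
    parent <- edge[e, 1L]; child <- edge[e, 2L]
    if (child <= ts$n_tip) {
      s <- tipstates[child, ]
      if (all(s == 0L)) next  # fully missing tip contributes ones
      contrib <- P[[child]][, pmax(s, 1L), drop = FALSE]
      if (any(s == 0L)) contrib[, s == 0L] <- 1
    } else {
      contrib <- P[[child]] %*% partial[[child]]
    }
    partial[[parent]] <- if (is.null(partial[[parent]])) contrib
                         else partial[[parent]] * contrib
  }
  partial[[ts$root]]
}

# Per-class site likelihoods for a mixture model. Returns npat x K matrix.
# `bl` is a branch-length vector indexed by child node id; `omega` a K x
# n_node matrix of class omegas by child node; `p_mix` the mixture
# proportions. Single-class models use a generator normalised to mean rate
# one. Mixtures use one common normalisation per edge (the
# proportion-weighted mean rate over classes), so branch lengths are
# mixture-average substitutions per codon site and high-omega classes
# evolve proportionally faster -- the standard site-model convention.
# `cache`, when supplied, is an environment reused across optimiser
# evaluations: gradient steps perturb one parameter at a time, so most
# class columns are unchanged and can be reused.
class_site_likelihoods <- function(data, ts, pi, kappa, bl, omega,
                                   p_mix = NULL,
                                   code = genetic_code(), cache = NULL) {
  K <- nrow(omega)
  if (is.null(p_mix)) p_mix <- rep(1 / K, K)
  npat <- ncol(data$patterns)
  idx <- match(ts$tip_label, data$taxa)
  if (anyNA(idx)) {
    stop("tree tips missing from alignment: ",
         paste(setdiff(ts$tip_label, data$taxa), collapse = ", "))
  }
  tipstates <- data$patterns[idx, , drop = FALSE]
  children <- ts$edge[, 2L]

  # per-edge common scale for mixtures: t_eff = t / (sum_k p_k mu_k)
  scaled <- K == 1L
  if (scaled) {
    t_eff <- bl
  } else {
    uniq_w <- unique(as.vector(omega[, children]))
    mu_of <- vapply(uniq_w, function(w) gy94_mean_rate(pi, kappa, w, code),
                    numeric(1))
    mu_edge <- rep(NA_real_, length(bl))
    for (ch in children) {
      mu_edge[ch] <- sum(p_mix * mu_of[match(omega[, ch], uniq_w)])
    }
    t_eff <- bl / mu_edge
  }

  # eigendecompositions and class likelihood columns are cached in the
  # shared store when one is supplied (pi is constant within a fit, so
  # (kappa, omega) identifies the generator); this makes one-parameter
  # gradient perturbations cheap. Hash tables are used rather than
  # string-keyed environments because environment keys are interned as
  # permanent symbols and would grow the process for ever across fits;
  # both stores are additionally capped.
  if (!is.null(cache)) {
    if (is.null(cache$eig) || utils::numhash(cache$eig) > 200L) {
      cache$eig <- utils::hashtab()
    }
    if (is.null(cache$cols) || utils::numhash(cache$cols) > 2000L) {
      cache$cols <- utils::hashtab()
    }
    eig_cache <- cache$eig
    cols_cache <- cache$cols
  } else {
    eig_cache <- utils::hashtab()
    cols_cache <- NULL
  }
  p_cache <- utils::hashtab()
  out <- matrix(NA_real_, npat, K)
  for (k in seq_len(K)) {
    ckey <- if (!is.null(cols_cache)) {
      rlang::hash(list(kappa, omega[k, ], bl, if (!scaled) t_eff))
    }
    if (!is.null(ckey)) {
      hit <- utils::gethash(cols_cache, ckey)
      if (!is.null(hit)) {
        out[, k] <- hit
        next
      }
    }
    P <- vector("list", ts$n_tip + ts$nnode)
    for (e in seq_len(nrow(ts$edge))) {
      child <- ts$edge[e, 2L]
      w <- omega[k, child]
      pkey <- paste0(w, "|", t_eff[child])
      Pe <- utils::gethash(p_cache, pkey)
      if (is.null(Pe)) {
        wkey <- paste0(kappa, "|", w, "|", scaled)
        eg <- utils::gethash(eig_cache, wkey)
        if (is.null(eg)) {
          eg <- gy94_eigen(pi, kappa, w, code, scale = scaled)
          utils::sethash(eig_cache, wkey, eg)
        }
        Pe <- gy94_prob(eg, t_eff[child])
        utils::sethash(p_cache, pkey, Pe)
      }
      P[[child]] <- Pe
    }
    root_partial <- prune_partials(ts, tipstates, P)
    out[, k] <- as.numeric(crossprod(root_partial, pi))
    if (!is.null(ckey)) utils::sethash(cols_cache, ckey, out[, k])
  }
  out
}

resolve_pi <- function(pi, aln, code) {
  if (is.numeric(pi)) {
    stopifnot(length(pi) == length(code$sense))
    return(pi / sum(pi))
  }
  switch(match.arg(pi, c("F3X4", "equal")),
         F3X4 = f3x4_frequencies(aln, code),
         equal = equal_codon_frequencies(code))
}

resolve_branch_lengths <- function(tree, branch_lengths = NULL) {
  n_node <- length(tree$tip.label) + tree$Nnode
  bl <- rep(NA_real_, n_node)
  if (is.null(branch_lengths)) {
    if (is.null(tree$edge.length)) {
      stop("tree has no branch lengths and none were supplied")
    }
    bl[tree$edge[, 2L]] <- tree$edge.length
  } else if (!is.null(names(branch_lengths))) {
    bl[as.integer(names(branch_lengths))] <- branch_lengths
  } else {
    stopifnot(length(branch_lengths) == nrow(tree$edge))
    bl[tree$edge[, 2L]] <- branch_lengths
  }
  bl
}

#' Codon-model log-likelihood by Felsenstein pruning
#'
#' Computes the log-likelihood of a codon alignment on a rooted tree under
#' a GY94 model: a single omega, a labelled branch model, a site-class
#' mixture, or branch-site model A. Ambiguous codons (any gap or ambiguity
#' letter) contribute a marginal likelihood over all compatible states.
#'
#' @param aln A sanitized [codon_alignment] (stop codons are refused).
#' @param tree Rooted [ape::phylo] tree whose tips are alignment taxa.
#' @param omega Single dN/dS value (used when `model` is `NULL`).
#' @param kappa Transition/transversion ratio.
#' @param pi `"F3X4"`, `"equal"`, or a numeric vector of sense-codon
#'   frequencies.
#' @param model Optional `codon_model_spec` (see [branch_model],
#'   [site_model], [branch_site_model]).
#' @param model_theta Internal parameter vector for `model` (as produced by
#'   the fitting routines); when `NULL`, `omega` is used for every free
#'   class.
#' @param branch_lengths Optional replacement branch lengths (expected
#'   substitutions per codon site), named by child node id or in
#'   `tree$edge` order; defaults to `tree$edge.length`.
#' @param code A [genetic_code].
#' @return The log-likelihood (a scalar).
#' @export
codon_log_likelihood <- function(aln, tree, omega = 0.2, kappa = 2,
                                 pi = "F3X4", model = NULL,
                                 model_theta = NULL,
                                 branch_lengths = NULL,
                                 code = genetic_code()) {
  data <- prepare_codon_data(aln, code)
  ts <- tree_structure(tree)
  pi <- resolve_pi(pi, aln, code)
  bl <- resolve_branch_lengths(tree, branch_lengths)
  if (is.null(model)) model <- one_ratio_model()
  packed <- pack_spec(model, tree)
  theta <- if (is.null(model_theta)) packed$init(omega) else model_theta
  mix <- packed$unpack(theta)
  cl <- class_site_likelihoods(data, ts, pi, kappa, bl, mix$omega, mix$p,
                               code)
  site_lik <- as.numeric(cl %*% mix$p)
  sum(data$weights * pmax(log(site_lik), -700))
}
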