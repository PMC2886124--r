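#' Codon frequencies from position-specific nucleotide counts (F3X4)
#'
#' Builds stationary codon frequencies the way codeml's F3X4 option does:
#' empirical nucleotide frequencies are tallied separately at the three
#' codon positions, each sense codon gets the product of its positional
#' frequencies, stop codons get frequency zero, and the result is
#' renormalised over sense codons.
#'
#' @param aln A [codon_alignment], or a character vector of codon strings.
#' @param code A [genetic_code].
#' @return Numeric vector of frequencies over sense codons (named), summing
#'   to one.
#' @export
f3x4_frequencies <- function(aln, code = genetic_code()) {
  if (inherits(aln, "codon_alignment")) {
    codons <- unlist(alignment_codon_strings(aln))
  } else {
    codons <- toupper(chartr("U", "T", as.character(aln)))
  }
  codons <- codons[!is.na(codons) & grepl("^[ACGT]{3}$", codons)]
  if (length(codons) == 0L) stop("no unambiguous codons to tally")
  m <- do.call(rbind, strsplit(codons, ""))
  bases <- c("A", "C", "G", "T")
  fpos <- sapply(1:3, function(p) {
    tab <- table(factor(m[, p], levels = bases))
    # floor zero counts so no sense codon gets exactly zero frequency
    # (keeps the reversible decomposition well defined on sparse data)
    f <- pmax(as.numeric(tab), 1e-4)
    f / sum(f)
  })  # 4 x 3
  rownames(fpos) <- bases
  sense <- code$sense
  sm <- do.call(rbind, strsplit(sense, ""))
  pi <- fpos[sm[, 1], 1] * fpos[sm[, 2], 2] * fpos[sm[, 3], 3]
  pi <- pi / sum(pi)
  names(pi) <- sense
  pi
}

#' Equal sense-codon frequencies
#' @inheritParams f3x4_frequencies
#' @return Named numeric vector, 1/61 each under the standard code.
#' @export
equal_codon_frequencies <- function(code = genetic_code()) {
  sense <- code$sense
  stats::setNames(rep(1 / length(sense), length(sense)), sense)
}

#' Goldman-Yang codon instantaneous rate matrix
#'
#' Builds the GY94 rate matrix over sense codons: single-nucleotide changes
#' only, target-codon frequency `pi_j`, a factor `kappa` for transitions and
#' `omega` for nonsynonymous changes. The matrix is scaled so the expected
#' substitution rate at stationarity is one, i.e. branch lengths are in
#' expected substitutions per codon site.
#'
#' @param pi Stationary frequencies over sense codons (see
#'   [f3x4_frequencies]).
#' @param kappa Transition/transversion rate ratio, > 0.
#' @param omega Nonsynonymous/synonymous rate ratio (dN/dS), >= 0.
#' @param code A [genetic_code].
#' @param scale If `TRUE` (default), normalise the mean rate to one.
#' @return A 61 x 61 matrix with zero row sums.
#' @export
gy94_rate_matrix <- function(pi, kappa, omega, code = genetic_code(),
                             scale = TRUE) {
  if (omega < 0) stop("omega must be >= 0")
  if (kappa <= 0) stop("kappa must be > 0")
  cs <- codon_structure(code)
  stopifnot(length(pi) == cs$n)
  Q <- matrix(0, cs$n, cs$n, dimnames = list(cs$sense, cs$sense))
  rate <- ifelse(cs$is_ts, kappa, 1) * ifelse(cs$is_syn, 1, omega)
  Q[cbind(cs$i, cs$j)] <- rate * pi[cs$j]
  Q[cbind(cs$j, cs$i)] <- rate * pi[cs$i]
  diag(Q) <- -rowSums(Q)
  if (scale) {
    mu <- -sum(pi * diag(Q))
    if (mu > 0) Q <- Q / mu
  }
  Q
}

# Mean substitution rate of the *unscaled* GY94 generator at stationarity.
# Used to put site-class mixtures on a single common scale (one overall
# normalisation across classes, so branch lengths are mixture-average
# substitutions per codon site and high-omega classes evolve faster).
gy94_mean_rate <- function(pi, kappa, omega, code = genetic_code()) {
  cs <- codon_structure(code)
  rate <- ifelse(cs$is_ts, kappa, 1) * ifelse(cs$is_syn, 1, omega)
  2 * sum(rate * pi[cs$i] * pi[cs$j])
}

# Symmetric eigendecomposition of a reversible GY94 generator, for fast
# transition probabilities P(t) = exp(Qt). Returns a closure-friendly list.
gy94_eigen <- function(pi, kappa, omega, code = genetic_code(),
                       scale = TRUE) {
  Q <- gy94_rate_matrix(pi, kappa, omega, code, scale = scale)
  sq <- sqrt(pi)
  B <- (sq * Q) %*% diag(1 / sq)          # diag(sqrt(pi)) Q diag(1/sqrt(pi))
  B <- (B + t(B)) / 2                     # enforce symmetry numerically
  es <- eigen(B, symmetric = TRUE)
  list(values = es$values,
       U = es$vectors / sq,               # diag(1/sqrt(pi)) V
       Uinv = t(es$vectors * sq),         # V' diag(sqrt(pi))
       pi = pi)
}

# Transition probability matrix from a cached eigendecomposition.
gy94_prob <- function(eig, t) {
  if (t < 0) stop("branch length must be >= 0")
  P <- eig$U %*% (exp(eig$values * t) * eig$Uinv)
  P[P < 0] <- 0
  P
}

# Fraction of the (unit) substitution rate that is nonsynonymous under a
# normalised GY94 matrix; used for expected N/S substitution counts.
gy94_nonsyn_fraction <- function(pi, kappa, omega, code = genetic_code()) {
  cs <- codon_structure(code)
  Q <- gy94_rate_matrix(pi, kappa, omega, code)
  flux <- pi[cs$i] * Q[cbind(cs$i, cs$j)] + pi[cs$j] * Q[cbind(cs$j, cs$i)]
  tot <- sum(flux)
  if (tot <= 0) return(0)
  sum(flux[!cs$is_syn]) / tot
}
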