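#' Configuration for neutral ORF-decay simulation
#'
#' Describes a forward simulation of neutral sequence evolution over a
#' total lineage exposure: point substitutions arrive as a Poisson process
#' with a transition bias, indels as an independent Poisson process, and
#' disrupting mutations (new in-frame premature stop codons plus
#' frameshifting indels) are counted per replicate.
#'
#' @param L ORF length in nucleotides (multiple of 3).
#' @param sub_rate Substitutions per site per year.
#' @param indel_rate Indels per site per year.
#' @param duration Total lineage time in years (sum over the lineages
#'   simulated).
#' @param n_reps Number of replicates.
#' @param kappa Transition/transversion rate ratio for substitutions.
#' @param base_freq Nucleotide frequencies (A, C, G, T) for the random
#'   stop-free start ORF.
#' @param indel_length `"one_bp"` (every indel is 1 bp, hence
#'   frameshifting) or `"geometric"` (lengths 1 + Geom(`geom_prob`)).
#' @param geom_prob Success probability of the geometric length model.
#' @param seed Optional integer seed for reproducibility.
#' @param code A [genetic_code].
#' @return A `decay_sim_config` list.
#' @export
decay_sim_config <- function(L = 1044L, sub_rate = 1e-9, indel_rate = 1e-10,
                             duration = 55e6, n_reps = 10000L, kappa = 2,
                             base_freq = c(A = 0.25, C = 0.25,
                                           G = 0.25, T = 0.25),
                             indel_length = c("one_bp", "geometric"),
                             geom_prob = 0.5, seed = NULL,
                             code = genetic_code()) {
  indel_length <- match.arg(indel_length)
  if (L %% 3L != 0L) stop("L must be a multiple of 3")
  if (sub_rate < 0 || indel_rate < 0 || duration < 0) {
    stop("rates and duration must be >= 0")
  }
  if (n_reps < 1L) stop("n_reps must be >= 1")
  structure(list(L = as.integer(L), sub_rate = sub_rate,
                 indel_rate = indel_rate, duration = duration,
                 n_reps = as.integer(n_reps), kappa = kappa,
                 base_freq = base_freq / sum(base_freq),
                 indel_length = indel_length, geom_prob = geom_prob,
                 seed = seed, code = code),
            class = "decay_sim_config")
}

#' Random stop-free ORF
#'
#' Codons are drawn with probability proportional to the product of the
#' base frequencies, stop codons excluded.
#'
#' @param L Length in nucleotides (multiple of 3).
#' @param base_freq Named A/C/G/T frequencies.
#' @param code A [genetic_code].
#' @return Character vector of `L` bases.
#' @export
random_orf <- function(L, base_freq, code = genetic_code()) {
  sense <- code$sense
  sm <- do.call(rbind, strsplit(sense, ""))
  p <- base_freq[sm[, 1]] * base_freq[sm[, 2]] * base_freq[sm[, 3]]
  p <- p / sum(p)
  codons <- sample(sense, L %/% 3L, replace = TRUE, prob = p)
  unlist(strsplit(codons, ""), use.names = FALSE)
}

#' Simulate neutral ORF decay and the intact-frame tail probability
#'
#' Per replicate, `Poisson(sub_rate * L * duration)` substitutions are
#' placed uniformly over sites (transition with probability
#' `kappa / (kappa + 2)`, each transversion `1 / (kappa + 2)`), and
#' `Poisson(indel_rate * L * duration)` indels with lengths from the
#' configured model. The disruption count is the number of premature stop
#' codons in the mutated sequence (original reading frame) plus the number
#' of frameshifting indels. `p_dis(k)` is the fraction of replicates with
#' a count less than or equal to `k`; `p_dis(0)` is the probability that
#' an ORF this long would still be disruption-free after the exposure.
#'
#' Substitutions are applied as independent draws from the start sequence
#' (no multiple-hit bookkeeping), which is adequate at the low divergences
#' involved; the analytic cross-check `exp(-expected_count)` uses exactly
#' the same model.
#'
#' @param config A [decay_sim_config].
#' @param start_seq Optional start sequence (character vector of bases or a
#'   single string, length `L`, stop-free); default a random stop-free ORF.
#' @return A `decay_sim` object: `counts` (per-replicate disruption
#'   counts), `p_dis` (function of `k`), `expected_count` (analytic) and
#'   the config.
#' @export
simulate_decay <- function(config, start_seq = NULL) {
  stopifnot(inherits(config, "decay_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  code <- config$code
  L <- config$L
  if (is.null(start_seq)) {
    start_seq <- random_orf(L, config$base_freq, code)
  } else {
    if (length(start_seq) == 1L) start_seq <- strsplit(start_seq, "")[[1]]
    start_seq <- toupper(chartr("U", "T", start_seq))
    if (length(start_seq) != L) stop("start_seq length != L")
    cods <- apply(matrix(start_seq, nrow = 3L), 2L, paste, collapse = "")
    if (any(cods %in% code$stops)) stop("start_seq contains stop codons")
  }
  bases <- c("A", "C", "G", "T")
  transition <- c(A = "G", C = "T", G = "A", T = "C")
  tv1 <- c(A = "C", C = "A", G = "C", T = "A")
  tv2 <- c(A = "T", C = "G", G = "T", T = "G")
  p_ts <- config$kappa / (config$kappa + 2)
  stop_set <- code$stops

  mu_sub <- config$sub_rate * L * config$duration
  mu_ind <- config$indel_rate * L * config$duration
  n_sub <- stats::rpois(config$n_reps, mu_sub)
  n_ind <- stats::rpois(config$n_reps, mu_ind)

  # frameshifting indels per replicate
  fs_count <- if (config$indel_length == "one_bp") n_ind else {
    vapply(n_ind, function(n) {
      if (n == 0L) return(0L)
      len <- 1L + stats::rgeom(n, config$geom_prob)
      sum(len %% 3L != 0L)
    }, integer(1))
  }

  # new stops per replicate: only mutated codons can change status
  stop_count <- integer(config$n_reps)
  for (r in seq_len(config$n_reps)) {
    n <- n_sub[r]
    if (n == 0L) next
    pos <- sample.int(L, n, replace = TRUE)
    u <- stats::runif(n)
    old <- start_seq[pos]
    new <- ifelse(u < p_ts, transition[old],
                  ifelse(u < (1 + p_ts) / 2, tv1[old], tv2[old]))
    s <- start_seq
    s[pos] <- new
    ci <- unique((pos - 1L) %/% 3L)
    tri <- paste0(s[3L * ci + 1L], s[3L * ci + 2L], s[3L * ci + 3L])
    stop_count[r] <- sum(tri %in% stop_set)
  }
  counts <- stop_count + fs_count

  structure(list(
    counts = counts,
    p_dis = function(k) mean(counts <= k),
    expected_count = analytic_expected_count(config, start_seq),
    start_seq = start_seq,
    config = config
  ), class = "decay_sim")
}

#' @export
print.decay_sim <- function(x, ...) {
  cat("<decay_sim> ", length(x$counts), " replicates, L = ", x$config$L,
      " nt, exposure ", format(x$config$duration / 1e6, digits = 4),
      " myr\n  mean disruption count ", format(mean(x$counts), digits = 4),
      " (analytic ", format(x$expected_count, digits = 4), ")",
      "\n  P(no disruption) = ", format(x$p_dis(0), digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' Analytic expected number of disrupting mutations
#'
#' Closed-form companion to [simulate_decay]: the indel term is
#' `indel_rate * L * duration * Pr(length %% 3 != 0)`, the stop term is
#' `sub_rate * L * duration` times the exact fraction of single-nucleotide
#' substitutions of the start sequence that create a stop codon (weighted
#' by the transition bias).
#'
#' @inheritParams simulate_decay
#' @return Expected count (scalar).
#' @export
analytic_expected_count <- function(config, start_seq = NULL) {
  stopifnot(inherits(config, "decay_sim_config"))
  code <- config$code
  L <- config$L
  if (is.null(start_seq)) {
    # expectation of the stop fraction under the random-ORF codon law
    sense <- code$sense
    sm <- do.call(rbind, strsplit(sense, ""))
    pcod <- config$base_freq[sm[, 1]] * config$base_freq[sm[, 2]] *
      config$base_freq[sm[, 3]]
    pcod <- pcod / sum(pcod)
    frac <- sum(pcod * vapply(sense, codon_stop_fraction,
                              numeric(1), config$kappa, code))
  } else {
    if (length(start_seq) == 1L) start_seq <- strsplit(start_seq, "")[[1]]
    cods <- apply(matrix(start_seq, nrow = 3L), 2L, paste, collapse = "")
    frac <- mean(vapply(cods, codon_stop_fraction, numeric(1),
                        config$kappa, code))
  }
  p_fs <- if (config$indel_length == "one_bp") 1 else {
    # length = 1 + Geom(p): P(len %% 3 != 0)
    len <- 1L + 0:499
    pr <- stats::dgeom(0:499, config$geom_prob)
    sum(pr[len %% 3L != 0L]) / sum(pr)
  }
  config$indel_rate * L * config$duration * p_fs +
    config$sub_rate * L * config$duration * frac
}

# Probability that a substitution landing uniformly in this codon creates a
# stop, given the transition bias: average over the 3 sites of the
# weighted fraction of target bases yielding a stop.
codon_stop_fraction <- function(codon, kappa, code = genetic_code()) {
  bases <- c("A", "C", "G", "T")
  transition <- c(A = "G", C = "T", G = "A", T = "C")
  chars <- strsplit(codon, "")[[1]]
  tot <- 0
  for (p in 1:3) {
    for (b in setdiff(bases, chars[p])) {
      w <- if (transition[[chars[p]]] == b) kappa / (kappa + 2) else
        1 / (kappa + 2)
      mut <- chars
      mut[p] <- b
      if (paste(mut, collapse = "") %in% code$stops) tot <- tot + w
    }
  }
  tot / 3
}
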