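test_that("GY94 rate matrix is reversible, normalised and respects omega", {
  set.seed(1)
  gc <- genetic_code()
  cs <- orfdecay:::codon_structure(gc)
  for (pi in list(equal_codon_frequencies(),
                  { p <- stats::runif(61); p / sum(p) })) {
    names(pi) <- gc$sense
    Q <- gy94_rate_matrix(pi, kappa = 2.3, omega = 0.4)
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
    # detailed balance
    expect_lt(max(abs(pi[cs$i] * Q[cbind(cs$i, cs$j)] -
                        pi[cs$j] * Q[cbind(cs$j, cs$i)])), 1e-14)
    # multi-nucleotide changes have rate zero
    multi <- outer(seq_len(61), seq_len(61), function(i, j) {
      m <- matrix(TRUE, 61, 61)
      m[cbind(cs$i, cs$j)] <- FALSE
      m[cbind(cs$j, cs$i)] <- FALSE
      diag(m) <- FALSE
      m[cbind(i, j)]
    })
    expect_true(all(Q[multi] == 0))
  }
  # omega = 0 kills all nonsynonymous rates
  pi <- equal_codon_frequencies()
  Q0 <- gy94_rate_matrix(pi, 2, 0)
  expect_true(all(Q0[cbind(cs$i, cs$j)][!cs$is_syn] == 0))
  expect_error(gy94_rate_matrix(pi, 2, -0.1), ">= 0")
})

test_that("the chain run to stationarity returns the codon frequencies", {
  aln <- aln_from_strings(list(a = "ATGAAACCCGGGTTT",
                               b = "ATGAAGCCTGGCTTC"), "a")
  pi <- f3x4_frequencies(aln)
  expect_equal(sum(pi), 1)
  Q <- gy94_rate_matrix(pi, 2, 0.3)
  P_inf <- as.matrix(Matrix::expm(Q * 500))
  expect_equal(max(abs(sweep(P_inf, 2, pi))), 0, tolerance = 1e-8)
})

test_that("pruning equals exhaustive ancestral enumeration on small trees", {
  set.seed(21)
  for (i in 1:5) {
    n <- sample(2:4, 1)
    tr <- ape::rcoal(n)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.02, 0.5)
    sc <- sim_scenario(tr, L = 10, omega_intact = 0.4, seed = 300 + i)
    aln <- simulate_codon_alignment(sc)$alignment
    kappa <- stats::runif(1, 1, 4)
    omega <- stats::runif(1, 0.05, 2)
    pi <- equal_codon_frequencies()
    ll <- codon_log_likelihood(aln, tr, omega = omega, kappa = kappa,
                               pi = pi)
    oracle <- brute_force_loglik(aln, tr, omega, kappa, pi)
    expect_equal(ll, oracle, tolerance = 1e-8)
  }
})

test_that("rerooting a reversible model leaves the likelihood unchanged", {
  set.seed(22)
  tr <- ape::rcoal(5)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.4)
  sc <- sim_scenario(tr, L = 40, omega_intact = 0.3, seed = 9)
  aln <- simulate_codon_alignment(sc)$alignment
  ll <- codon_log_likelihood(aln, tr, omega = 0.3, kappa = 2, pi = "equal")
  for (og in tr$tip.label[2:4]) {
    tr2 <- ape::root(ape::unroot(tr), outgroup = og, resolve.root = TRUE)
    ll2 <- codon_log_likelihood(aln, tr2, omega = 0.3, kappa = 2,
                                pi = "equal")
    expect_equal(ll2, ll, tolerance = 1e-8)
  }
})

test_that("zero-length branches give the stationary log-likelihood", {
  aln <- aln_from_strings(list(a = "ATGAAACCC", b = "ATGAAACCC"), "a")
  tr <- ape::read.tree(text = "(a:0,b:0);")
  pi <- equal_codon_frequencies()
  ll <- codon_log_likelihood(aln, tr, omega = 0.5, kappa = 2, pi = pi)
  codons <- c("ATG", "AAA", "CCC")
  expect_equal(ll, sum(log(pi[codons])), tolerance = 1e-10)
})

test_that("fully ambiguous taxa marginalise out of the likelihood", {
  sc <- sim_scenario(random_scaled_tree(4), L = 30, seed = 13)
  aln <- simulate_codon_alignment(sc)$alignment
  tr <- sc$tree
  ll_full <- codon_log_likelihood(aln, tr, omega = 0.3, kappa = 2,
                                  pi = "equal")
  # replace one non-reference taxon by Ns: the likelihood must equal the
  # alignment with that tip fully missing
  tx <- setdiff(rownames(aln$mat), aln$reference)[1]
  aln2 <- aln
  aln2$mat[tx, ] <- "N"
  ll_mis <- codon_log_likelihood(aln2, tr, omega = 0.3, kappa = 2,
                                 pi = "equal")
  drop_tr <- ape::drop.tip(tr, tx)
  aln3 <- aln
  aln3$mat <- aln3$mat[setdiff(rownames(aln$mat), tx), , drop = FALSE]
  ll_drop <- codon_log_likelihood(aln3, drop_tr, omega = 0.3, kappa = 2,
                                  pi = "equal")
  expect_equal(ll_mis, ll_drop, tolerance = 1e-8)
  expect_false(isTRUE(all.equal(ll_full, ll_mis)))
})

test_that("stop codons in likelihood columns are refused with guidance", {
  aln <- aln_from_strings(list(a = "ATGAAACCC", b = "ATGTAACCC"), "a")
  tr <- ape::read.tree(text = "(a:0.1,b:0.1);")
  expect_error(codon_log_likelihood(aln, tr, pi = "equal"),
               "sanitize_alignment")
})
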