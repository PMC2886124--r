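test_that("one-ratio ML recovers the generating omega", {
  set.seed(31)
  hits <- 0L
  for (i in 1:10) {
    tr <- random_scaled_tree(10, depth = 0.5)
    sc <- sim_scenario(tr, L = 200, omega_intact = 0.2, seed = 400 + i)
    aln <- simulate_codon_alignment(sc)$alignment
    fit <- fit_codon_model(aln, tr, one_ratio_model(), pi = "F3X4",
                           estimate_branch_lengths = FALSE, starts = 1,
                           control = list(reltol = 1e-8))
    if (fit$omega$estimate >= 0.15 && fit$omega$estimate <= 0.25) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 8L)
})

test_that("fits record one optimisation run per start", {
  sc <- sim_scenario(random_scaled_tree(4), L = 60, seed = 2)
  aln <- simulate_codon_alignment(sc)$alignment
  fit <- fit_codon_model(aln, sc$tree, one_ratio_model(),
                         estimate_branch_lengths = FALSE)
  expect_equal(nrow(fit$convergence), 2L)
  expect_equal(fit$convergence$start_omega, c(0.5, 2))
  expect_true(any(fit$convergence$converged))
  # the two starts agree on the optimum
  expect_lt(diff(range(fit$convergence$lnL)), 1e-3)
})

test_that("model nesting is respected by the maximised likelihoods", {
  sc <- sim_scenario(random_scaled_tree(6), L = 80, seed = 3,
                     schedule = tibble::tibble(branch = 8L, at = 0.5))
  sim <- inject_pseudogenization(simulate_codon_alignment(sc), sc)
  cls <- classify_branches(sc$tree,
                           map_events(sc$tree, scan_alignment(sim$alignment)))
  san <- sanitize_alignment(sim$alignment)
  cls2 <- dplyr::mutate(cls, class = ifelse(class == "intact", "intact",
                                            "psi"))
  free <- fit_codon_model(san$alignment, sc$tree, branch_model(cls2),
                          estimate_branch_lengths = FALSE,
                          starts = c(0.5, 2))
  fixed <- fit_codon_model(san$alignment, sc$tree,
                           branch_model(cls2, fixed = c(psi = 1)),
                           estimate_branch_lengths = FALSE, starts = 1)
  expect_gte(free$lnL, fixed$lnL - 1e-4)
  expect_equal(free$np - fixed$np, 1L)
})

test_that("likelihood-ratio tests follow the chi-squared reference", {
  f0 <- structure(list(lnL = -100, np = 2L), class = "codon_fit")
  f1 <- structure(list(lnL = -100, np = 3L), class = "codon_fit")
  expect_equal(lrt(f0, f1)$p_value, 1)
  f2 <- structure(list(lnL = -100 + 3.8415 / 2, np = 3L),
                  class = "codon_fit")
  expect_equal(lrt(f0, f2)$p_value, 0.05, tolerance = 1e-4)
  expect_equal(lrt(f0, f2)$df, 1L)
  expect_error(lrt(f1, f0), "more free parameters")
  # small negative statistics are clamped to zero
  f3 <- structure(list(lnL = -100.001, np = 3L), class = "codon_fit")
  expect_equal(lrt(f0, f3)$two_delta_lnL, 0)
})

test_that("M3 with one class collapses to M0", {
  sc <- sim_scenario(random_scaled_tree(5), L = 80, seed = 5)
  aln <- simulate_codon_alignment(sc)$alignment
  f0 <- fit_codon_model(aln, sc$tree, site_model("M0"),
                        estimate_branch_lengths = FALSE, starts = 1)
  f3 <- fit_codon_model(aln, sc$tree, site_model("M3", k = 1),
                        estimate_branch_lengths = FALSE, starts = 1)
  expect_equal(f3$lnL, f0$lnL, tolerance = 1e-6)
})

test_that("free-ratio on two taxa equals the one-ratio estimate", {
  tr <- ape::read.tree(text = "(a:0.3,b:0.3);")
  sc <- sim_scenario(tr, L = 150, omega_intact = 0.3, seed = 4)
  aln <- simulate_codon_alignment(sc)$alignment
  f1 <- fit_codon_model(aln, tr, one_ratio_model(),
                        estimate_branch_lengths = FALSE, starts = 1)
  fr <- free_ratio(aln, tr, estimate_branch_lengths = FALSE, starts = 1)
  expect_equal(unique(fr$omega_by_branch$estimate), f1$omega$estimate,
               tolerance = 1e-4)
})

test_that("free-ratio flags dS = 0 and dN = 0 branches with sentinels", {
  # c differs from the (a,b) pair only nonsynonymously -> its branch has
  # dS = 0; d only synonymously -> dN = 0
  base <- c("ATG", "AAA", "CCC", "GGG", "TTT", "CTT", "GAT", "CAT",
            "AGA", "GCA")
  nonsyn <- base; nonsyn[c(2, 4, 6)] <- c("ACA", "GCG", "CCT")
  syn <- base; syn[c(3, 5, 7)] <- c("CCT", "TTC", "GAC")
  aln <- aln_from_strings(list(
    a = paste(base, collapse = ""), b = paste(base, collapse = ""),
    c = paste(nonsyn, collapse = ""), d = paste(syn, collapse = "")),
    "a")
  tr <- ape::read.tree(text = "((a:0.05,b:0.05):0.05,(c:0.2,d:0.2):0.05);")
  fr <- free_ratio(aln, tr, estimate_branch_lengths = FALSE, starts = 1)
  ob <- fr$omega_by_branch
  c_row <- ob[ob$label == "c", ]
  d_row <- ob[ob$label == "d", ]
  expect_equal(c_row$flag, "ds_zero")
  expect_identical(c_row$estimate, Inf)
  expect_equal(d_row$flag, "dn_zero")
  expect_identical(d_row$estimate, 0)
})

test_that("free-ratio finds the neutral branch among purifying ones", {
  set.seed(61)
  hits <- 0L
  for (i in 1:5) {
    tr <- random_scaled_tree(6, depth = 0.6)
    tip <- which.max(tr$edge.length[match(1:6, tr$edge[, 2])])
    sc <- sim_scenario(tr, L = 250, omega_intact = 0.15, seed = 500 + i,
                       schedule = tibble::tibble(branch = tip, at = 0))
    aln <- simulate_codon_alignment(sc)$alignment
    fr <- free_ratio(aln, tr, estimate_branch_lengths = FALSE, starts = 1,
                     control = list(reltol = 1e-8))
    ob <- fr$omega_by_branch[is.finite(fr$omega_by_branch$estimate), ]
    if (ob$branch[which.max(ob$estimate)] == tip) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})
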