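classes_tbl <- function(tree, psi_branches) {
  bt <- branch_table(tree)
  tibble::tibble(branch = bt$branch, label = bt$label,
                 class = ifelse(bt$branch %in% psi_branches, "psi2",
                                "intact"))
}

test_that("branch pairs are cross-tabulated correctly", {
  tr <- random_scaled_tree(5)
  a <- classes_tbl(tr, integer(0))
  b <- classes_tbl(tr, integer(0))
  tab <- categorize_branch_pairs(a, b)
  expect_equal(c(tab$a, tab$b, tab$c), c(0, 0, 0))
  expect_equal(tab$d, nrow(tr$edge))

  shared <- tr$edge[1, 2]
  tab2 <- categorize_branch_pairs(classes_tbl(tr, shared),
                                  classes_tbl(tr, shared))
  expect_equal(tab2$a, 1)
  expect_equal(tab2$d, nrow(tr$edge) - 1)

  # random status maps against a direct per-branch tally
  set.seed(17)
  for (i in 1:10) {
    tr2 <- random_scaled_tree(7)
    br <- tr2$edge[, 2]
    pa <- sample(br, sample(0:4, 1))
    pb <- sample(br, sample(0:4, 1))
    tab3 <- categorize_branch_pairs(classes_tbl(tr2, pa),
                                    classes_tbl(tr2, pb))
    expect_equal(tab3$a, sum(br %in% pa & br %in% pb))
    expect_equal(tab3$b, sum(br %in% pa & !br %in% pb))
    expect_equal(tab3$c, sum(!br %in% pa & br %in% pb))
    expect_equal(tab3$d, sum(!br %in% pa & !br %in% pb))
  }
  expect_error(categorize_branch_pairs(a, b[-1, ]), "branch sets")
})

test_that("Fisher enumeration reproduces the known exact values", {
  expect_equal(fisher_exact_2x2(c(3, 4, 1, 31)), 1155 / 82251,
               tolerance = 1e-12)
  expect_equal(round(fisher_exact_2x2(c(3, 4, 1, 31)), 4), 0.0140)
  expect_equal(fisher_exact_2x2(c(0, 0, 0, 10)), 1)
  expect_equal(fisher_exact_2x2(c(0, 2, 5, 30)), 1)
  expect_error(fisher_exact_2x2(c(-1, 1, 1, 1)), "non-negative")
})

test_that("Fisher point probabilities sum to one over each margin", {
  for (tab in list(c(2, 3, 1, 4), c(0, 5, 2, 2), c(3, 0, 0, 3))) {
    m <- tab[1] + tab[2]; n <- tab[3] + tab[4]; k <- tab[1] + tab[3]
    support <- max(0, k - n):min(m, k)
    expect_equal(sum(stats::dhyper(support, m, n, k)), 1,
                 tolerance = 1e-12)
  }
})

test_that("Fisher agrees with the independent reference implementation", {
  set.seed(33)
  for (i in 1:20) {
    tab <- stats::rpois(4, 4)
    if (sum(tab) == 0) tab <- c(1, 0, 0, 1)
    got <- fisher_exact_2x2(tab)
    ref <- stats::fisher.test(matrix(c(tab[1], tab[3], tab[2], tab[4]),
                                     2))$p.value
    expect_equal(got, ref, tolerance = 1e-9)
  }
})

test_that("Spearman correlation applies the dS/dN exclusion rules", {
  oa <- tibble::tibble(branch = 1:5, estimate = c(1, 2, 3, 4, 5),
                       flag = "ok")
  ob <- tibble::tibble(branch = 1:5, estimate = c(2, 4, 6, 8, 10),
                       flag = "ok")
  r <- spearman_branch_omega(oa, ob)
  expect_equal(r$r_s, 1)
  expect_equal(r$n_used, 5L)

  # hand-ranked n = 5 vectors against the textbook formula
  xa <- c(0.1, 0.4, 0.2, 0.9, 0.6)
  xb <- c(0.3, 0.2, 0.5, 0.8, 0.1)
  oa2 <- tibble::tibble(branch = 1:5, estimate = xa, flag = "ok")
  ob2 <- tibble::tibble(branch = 1:5, estimate = xb, flag = "ok")
  d <- rank(xa) - rank(xb)
  expect_equal(spearman_branch_omega(oa2, ob2)$r_s,
               1 - 6 * sum(d^2) / (5 * 24), tolerance = 1e-12)

  # a dS = 0 sentinel drops exactly that branch
  oa3 <- oa
  oa3$estimate[2] <- Inf
  oa3$flag[2] <- "ds_zero"
  r3 <- spearman_branch_omega(oa3, ob)
  expect_equal(r3$n_used, 4L)
  expect_equal(r3$excluded$branch, 2L)
  expect_match(r3$excluded$reason, "dS = 0")

  # monotone-transform invariance
  ob4 <- dplyr::mutate(ob, estimate = exp(estimate))
  expect_equal(spearman_branch_omega(oa2, ob4)$r_s,
               spearman_branch_omega(oa2, ob)$r_s)

  oa5 <- tibble::tibble(branch = 1:3, estimate = c(1, Inf, 2),
                        flag = c("ok", "ds_zero", "ok"))
  ob5 <- tibble::tibble(branch = 1:3, estimate = c(1, 2, 3), flag = "ok")
  expect_error(spearman_branch_omega(oa5, ob5), "insufficient")
})

test_that("independent losses give a calibrated Fisher rejection rate", {
  set.seed(44)
  tr <- random_scaled_tree(12)
  br <- tr$edge[, 2]
  rejections <- 0L
  n_sim <- 200
  for (i in seq_len(n_sim)) {
    pa <- br[stats::runif(length(br)) < 0.3]
    pb <- br[stats::runif(length(br)) < 0.3]
    p <- fisher_exact_2x2(categorize_branch_pairs(classes_tbl(tr, pa),
                                                  classes_tbl(tr, pb)))
    if (p < 0.05) rejections <- rejections + 1L
  }
  # Fisher is conservative on small discrete tables: at or below nominal
  expect_lte(rejections / n_sim, 0.05 + 2 * sqrt(0.05 * 0.95 / n_sim))
})
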