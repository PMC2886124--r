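test_that("reference row defines the codon coordinate map", {
  path <- write_temp_fasta(list(mouse = "ATGAAACCC", other = "ATGAAACCC"))
  aln <- read_codon_alignment(path, "mouse")
  expect_equal(aln$n_ref_codons, 3L)
  expect_equal(aln$coord_map, rep(1:3, each = 3))

  # a gapped block in the other taxon inside reference codon 2 still maps
  # those columns to codon 2
  path2 <- write_temp_fasta(list(mouse = "ATGAAACCC",
                                 other = "ATG---CCC"))
  aln2 <- read_codon_alignment(path2, "mouse")
  expect_equal(aln2$coord_map[4:6], rep(2L, 3))

  # columns gapped in the reference are insertions, anchored to the
  # preceding reference codon
  path3 <- write_temp_fasta(list(mouse = "ATG--AAACCC",
                                 other = "ATGGGAAACCC"))
  aln3 <- read_codon_alignment(path3, "mouse")
  expect_true(all(is.na(aln3$coord_map[4:5])))
  expect_equal(aln3$ins_anchor[4:5], c(1L, 1L))
  expect_equal(aln3$coord_map[6:8], rep(2L, 3))
})

test_that("malformed alignments are refused with informative errors", {
  path <- write_temp_fasta(list(mouse = "ATGAAACCCA", other = "ATGAAACCCA"))
  expect_error(read_codon_alignment(path, "mouse"), "remainder 1")
  path2 <- write_temp_fasta(list(mouse = "ATGAAA", other = "ATGAAA"))
  expect_error(read_codon_alignment(path2, "rat"), "rat")
  path3 <- write_temp_fasta(list(mouse = "ATGAAA", other = "ATGAAACCC"))
  expect_error(read_codon_alignment(path3, "mouse"), "unequal")
})

test_that("parsing is case-insensitive and maps U to T", {
  aln <- aln_from_strings(list(m = "atgaaaccc", o = "auguuuccc"), "m")
  expect_equal(paste(aln$mat["o", 1:6], collapse = ""), "ATGTTT")
})

test_that("alignment FASTA round-trips with an identical coordinate map", {
  sc <- sim_scenario(random_scaled_tree(5), L = 40, seed = 101)
  sim <- inject_pseudogenization(
    simulate_codon_alignment(sc), sc)
  path <- tempfile(fileext = ".fasta")
  write_codon_alignment(sim$alignment, path)
  back <- read_codon_alignment(path, sim$alignment$reference)
  expect_identical(back$coord_map, sim$alignment$coord_map)
  expect_identical(back$mat, sim$alignment$mat)
})

test_that("codons hit by stops or partial deletions are removed everywhere", {
  # taxon X has a 1-bp deletion inside reference codon 5
  seqs <- list(mouse = "ATGAAACCCGGGTTTAAA",
               x     = "ATGAAACCCGGGT-TAAA",
               y     = "ATGAAACCCGGGTTTAAA")
  aln <- aln_from_strings(seqs, "mouse")
  san <- sanitize_alignment(aln)
  expect_equal(san$alignment$n_ref_codons, 5L)
  expect_equal(san$log$ref_codon, 5L)
  expect_equal(san$log$reason, "partial_deletion")
  # removed across all rows
  expect_false(any(grepl("-", san$alignment$mat)))

  # a stop codon in one taxon removes that codon in all taxa
  seqs2 <- list(mouse = "ATGAAACCCGGG", z = "ATGTAACCCGGG")
  san2 <- sanitize_alignment(aln_from_strings(seqs2, "mouse"))
  expect_equal(san2$alignment$n_ref_codons, 3L)
  expect_equal(san2$log$reason, "stop")
  expect_equal(san2$log$taxon, "z")
})

test_that("intact alignments sanitize to themselves with an empty log", {
  sc <- sim_scenario(random_scaled_tree(6), L = 50, seed = 7)
  sim <- simulate_codon_alignment(sc)
  san <- sanitize_alignment(sim$alignment)
  expect_identical(san$alignment$mat, sim$alignment$mat)
  expect_equal(nrow(san$log), 0L)
})

test_that("sanitization is idempotent and its log is complete", {
  for (seed in c(11, 12, 13)) {
    tr <- random_scaled_tree(6)
    nodes <- (8):(6 + tr$Nnode)
    sc <- sim_scenario(tr, L = 60, seed = seed,
                       schedule = tibble::tibble(
                         branch = nodes[1], at = 0.4))
    sim <- inject_pseudogenization(simulate_codon_alignment(sc), sc)
    san1 <- sanitize_alignment(sim$alignment)
    san2 <- sanitize_alignment(san1$alignment)
    expect_identical(san2$alignment$mat, san1$alignment$mat)
    expect_equal(nrow(san2$log), 0L)
    # every ref-frame stop is gone, and the number of surviving codons
    # matches an independent column recount
    expect_equal(san1$alignment$n_ref_codons,
                 count_clean_codons(san1$alignment))
    # log completeness: removed codons == logged codons
    removed <- sim$alignment$n_ref_codons - san1$alignment$n_ref_codons
    expect_equal(removed,
                 length(unique(san1$log$ref_codon[
                   san1$log$reason != "frameshift_insertion"])))
  }
})
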