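test_that("intact sequences yield no disruption events", {
  aln <- aln_from_strings(list(mouse = "ATGAAACCCGGG",
                               other = "ATGAAGCCAGGG"), "mouse")
  expect_equal(nrow(detect_disruptions(aln, "other")), 0L)
  expect_error(detect_disruptions(aln, "absent"), "absent")
})

test_that("a 4-bp insertion followed by a 1-bp deletion gives two events", {
  # gibbon-style lesion pair: 4-bp insertion after codon 2, then a 1-bp
  # deletion in codon 4
  aln <- aln_from_strings(list(
    mouse  = "ATGAAA----CCCGGGTTT",
    gibbon = "ATGAAAGGGGCCCG-GTTT"), "mouse")
  ev <- detect_disruptions(aln, "gibbon")
  indels <- ev[ev$kind != "nonsense", ]
  expect_equal(indels$kind, c("insertion", "deletion"))
  expect_equal(indels$length_bp, c(4L, 1L))
  expect_equal(indels$ref_codon, c(2L, 4L))
})

test_that("in-frame indels are not disruptions", {
  aln <- aln_from_strings(list(
    mouse = "ATGAAA---CCCGGG",
    other = "ATGAAATTTCCCGGG"), "mouse")
  expect_equal(nrow(detect_disruptions(aln, "other")), 0L)
  aln2 <- aln_from_strings(list(
    mouse = "ATGAAACCCGGG",
    other = "ATG---CCCGGG"), "mouse")
  expect_equal(nrow(detect_disruptions(aln2, "other")), 0L)
})

test_that("premature stops are read in the running frame and respect the
           tail tolerance", {
  # direct in-frame stop
  aln <- aln_from_strings(list(mouse = "ATGAAACCCGGG",
                               x = "ATGTAACCCGGG"), "mouse")
  ev <- detect_disruptions(aln, "x")
  expect_equal(ev$kind, "nonsense")
  expect_equal(ev$ref_codon, 2L)
  expect_equal(ev$stop_codon, "TAA")
  # a 1-bp deletion shifts the frame; the downstream TAA read in the
  # shifted frame is reported
  aln2 <- aln_from_strings(list(mouse = "ATGAAATTAAGG",
                                x = "ATGAA-TTAAGG"), "mouse")
  ev2 <- detect_disruptions(aln2, "x")
  expect_setequal(ev2$kind, c("deletion", "nonsense"))
  # tail tolerance silences 3'-proximal stops
  ev3 <- detect_disruptions(aln, "x", tail_tolerance = 3L)
  expect_equal(nrow(ev3), 0L)
})

test_that("injected lesions are recovered exactly on clean backgrounds", {
  set.seed(42)
  for (i in 1:30) {
    tr <- random_scaled_tree(6)
    tips <- sample(6, 2)  # two disjoint terminal-branch lesions
    sc <- sim_scenario(tr, L = 50, seed = 1000 + i,
                       schedule = tibble::tibble(branch = tips, at = 0.5),
                       reference = setdiff(tr$tip.label,
                                           tr$tip.label[tips])[1])
    sim <- inject_pseudogenization(simulate_codon_alignment(sc), sc)
    truth <- sim$truth$events
    for (j in seq_len(nrow(truth))) {
      taxon <- truth$carriers[[j]][1]
      det <- detect_disruptions(sim$alignment, taxon)
      hit <- det[det$kind == truth$kind[j] &
                   det$ref_codon == truth$ref_codon[j], ]
      expect_equal(nrow(hit), 1L)
      expect_equal(hit$length_bp, truth$length_bp[j])
    }
  }
})

test_that("shared lesions map to a single origin under Dollo parsimony", {
  tr <- hcg_tree()
  shared <- tibble::tibble(
    taxon = c("human", "chimp", "gorilla"), kind = "deletion",
    ref_codon = 10L, length_bp = 2L, stop_codon = NA_character_)
  mp <- map_events(tr, shared)
  expect_equal(nrow(mp), 1L)
  expect_setequal(mp$carriers[[1]], c("human", "chimp", "gorilla"))
  # assigned to the branch above the hcg ancestor (node 6)
  expect_setequal(tree_tips_below_names(tr, mp$branch),
                  c("human", "chimp", "gorilla"))
  expect_equal(count_independent_events(mp), 1L)
})

test_that("the same lesion in non-sister taxa yields independent origins", {
  tr <- hcg_tree()
  # human and gorilla carry it, chimp (inside the span) does not:
  # poly-A-stretch style recurrence
  ev <- tibble::tibble(
    taxon = c("human", "gorilla"), kind = "insertion",
    ref_codon = 247L, length_bp = 1L, stop_codon = NA_character_)
  mp <- map_events(tr, ev)
  expect_equal(nrow(mp), 2L)
  expect_equal(count_independent_events(mp), 2L)
  expect_setequal(unlist(mp$carriers), c("human", "gorilla"))
  # single-taxon event goes to the terminal branch
  ev2 <- tibble::tibble(taxon = "macaque", kind = "nonsense",
                        ref_codon = 5L, length_bp = 0L, stop_codon = "TGA")
  mp2 <- map_events(tr, ev2)
  expect_equal(mp2$branch, match("macaque", tr$tip.label))
  expect_error(map_events(tr, dplyr::mutate(ev2, taxon = "yeti")), "yeti")
})

test_that("nonsense events at one codon with different stop triplets stay
           separate", {
  tr <- hcg_tree()
  ev <- tibble::tibble(
    taxon = c("human", "chimp"), kind = "nonsense",
    ref_codon = 7L, length_bp = 0L, stop_codon = c("TAA", "TGA"))
  mp <- map_events(tr, ev)
  expect_equal(nrow(mp), 2L)
})

test_that("branch classification marks founding and inherited pseudogenes", {
  tr <- hcg_tree()
  shared <- tibble::tibble(
    taxon = c("human", "chimp", "gorilla"), kind = "deletion",
    ref_codon = 10L, length_bp = 2L, stop_codon = NA_character_)
  cls <- classify_branches(tr, map_events(tr, shared))
  get <- function(lab) cls$class[cls$label == lab]
  expect_equal(get("human"), "psi1")
  expect_equal(get("chimp"), "psi1")
  expect_equal(get("gorilla"), "psi1")
  expect_equal(get("macaque"), "intact")
  # the hcg ancestor branch is psi2, the human-chimp ancestor psi1
  hcg_node <- which(sapply(cls$branch, function(b)
    setequal(tree_tips_below_names(tr, b), c("human", "chimp", "gorilla"))))
  hc_node <- which(sapply(cls$branch, function(b)
    setequal(tree_tips_below_names(tr, b), c("human", "chimp"))))
  expect_equal(cls$class[hcg_node], "psi2")
  expect_equal(cls$class[hc_node], "psi1")
  # no events: everything intact
  cls0 <- classify_branches(tr, map_events(tr, shared[0, ]))
  expect_true(all(cls0$class == "intact"))
})

test_that("classification equals a root-to-tip path-walking oracle", {
  set.seed(77)
  for (i in 1:20) {
    tr <- ape::rcoal(sample(5:12, 1))
    branches <- tr$edge[, 2]
    hit <- sample(branches, sample(0:3, 1))
    ev <- if (length(hit)) tibble::tibble(
      event_id = seq_along(hit), kind = "nonsense",
      ref_codon = seq_along(hit), length_bp = 0L,
      stop_codon = "TAA", branch = hit,
      carriers = lapply(hit, function(b) tree_tips_below_names(tr, b)),
      polymorphic = FALSE)
    else map_events(tr, tibble::tibble(
      taxon = character(), kind = character(), ref_codon = integer(),
      length_bp = integer(), stop_codon = character()))
    cls <- classify_branches(tr, ev)
    oracle <- classify_oracle(tr, hit)
    expect_equal(cls$class, oracle[cls$branch])
  }
})

test_that("polymorphic lesions are reported but do not found a pseudogene
           lineage by default", {
  tr <- hcg_tree()
  ev <- tibble::tibble(taxon = "human", kind = "nonsense", ref_codon = 3L,
                       length_bp = 0L, stop_codon = "TAA")
  mp <- map_events(tr, ev, polymorphic_taxa = "human")
  expect_true(mp$polymorphic)
  cls <- classify_branches(tr, mp)
  expect_true(all(cls$class == "intact"))
  cls2 <- classify_branches(tr, mp, include_polymorphic = TRUE)
  expect_equal(cls2$class[cls2$label == "human"], "psi2")
})
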