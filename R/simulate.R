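#' Define a synthetic codon-evolution scenario
#'
#' Describes the generative process used throughout testing: codon
#' sequences evolve along a rooted tree under GY94 with purifying selection
#' (`omega_intact`) on intact lineages; on each scheduled branch a
#' pseudogenization event occurs at a fractional position along the
#' branch, after which the lineage (and all its descendants) evolves
#' neutrally (omega = 1) and carries ORF-disrupting lesions. Each scheduled
#' event injects one guaranteed founding lesion; additional lesions can
#' accrue stochastically at the configured neutral rates when branch times
#' are supplied.
#'
#' @param tree Rooted [ape::phylo] with branch lengths in expected
#'   substitutions per codon site.
#' @param L Number of codons (>= 10).
#' @param omega_intact dN/dS on intact lineages.
#' @param kappa Transition/transversion ratio.
#' @param base_freq Nucleotide frequencies used to build the stationary
#'   codon distribution (position-independent product, stops excluded).
#' @param schedule Tibble with columns `branch` (child node id) and `at`
#'   (fraction in `[0, 1]` of the branch elapsed before the
#'   pseudogenization event); `NULL` for a fully intact scenario.
#' @param site_classes Optional tibble with columns `p` (proportions
#'   summing to 1) and `omega`, giving a site-class mixture on intact
#'   lineages; each site is assigned a class at random and the assignment
#'   is recorded in the truth. Overrides `omega_intact` on intact branches
#'   (pseudogene branches stay neutral).
#' @param times Optional per-branch times in years (named by child node
#'   id), enabling stochastic extra lesions on pseudogene branches.
#' @param sub_rate,indel_rate Neutral lesion rates per site per year (used
#'   only for stochastic extra lesions).
#' @param stochastic_lesions Draw extra Poisson lesions on pseudogene
#'   branch segments (requires `times`).
#' @param reference Reference taxon for coordinates (default: first tip
#'   not descending from any scheduled branch).
#' @param seed Optional integer seed.
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(tree, L = 300L, omega_intact = 0.2, kappa = 2,
                         base_freq = c(A = 0.25, C = 0.25, G = 0.25,
                                       T = 0.25),
                         schedule = NULL, site_classes = NULL,
                         times = NULL,
                         sub_rate = 1e-9, indel_rate = 1e-10,
                         stochastic_lesions = FALSE, reference = NULL,
                         seed = NULL) {
  if (L < 10L) stop("L must be >= 10 codons")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (!is.null(schedule)) {
    stopifnot(all(c("branch", "at") %in% names(schedule)))
    bad <- setdiff(schedule$branch, tree$edge[, 2])
    if (length(bad)) stop("scheduled branches not in tree: ",
                          paste(bad, collapse = ", "))
    if (any(schedule$at < 0 | schedule$at > 1)) {
      stop("schedule 'at' must lie in [0, 1]")
    }
  }
  if (stochastic_lesions && is.null(times)) {
    stop("stochastic lesions require per-branch times")
  }
  if (!is.null(site_classes)) {
    stopifnot(all(c("p", "omega") %in% names(site_classes)),
              abs(sum(site_classes$p) - 1) < 1e-8)
  }
  structure(list(tree = tree, L = as.integer(L),
                 omega_intact = omega_intact, kappa = kappa,
                 base_freq = base_freq / sum(base_freq),
                 schedule = schedule, site_classes = site_classes,
                 times = times,
                 sub_rate = sub_rate, indel_rate = indel_rate,
                 stochastic_lesions = stochastic_lesions,
                 reference = reference, seed = seed),
            class = "sim_scenario")
}

# Branch classes implied by the schedule: scheduled branches are psi2,
# branches below them psi1, the rest intact.
scenario_branch_classes <- function(scenario) {
  tree <- scenario$tree
  n <- length(tree$tip.label) + tree$Nnode
  cls <- rep("intact", n)
  cls[tree_root(tree)] <- NA
  if (!is.null(scenario$schedule)) {
    for (b in scenario$schedule$branch) {
      cls[b] <- "psi2"
      for (d in tree_descendants(tree, b)) cls[d] <- "psi1"
    }
  }
  cls
}

#' Simulate a codon alignment under a scenario
#'
#' Sequences evolve by transition-probability sampling along each branch
#' under that branch's omega regime; a scheduled (psi2) branch evolves
#' under `omega_intact` for the fraction `at` of its length and neutrally
#' for the remainder. Stop codons never arise (the state space is the
#' sense codons). No lesions are applied here; see
#' [inject_pseudogenization].
#'
#' @param scenario A [sim_scenario].
#' @param code A [genetic_code].
#' @return List with `alignment` (a gapless [codon_alignment]), and
#'   `truth` (list: `classes` tibble of per-branch class and omega,
#'   `root_seq`, `pi`).
#' @export
simulate_codon_alignment <- function(scenario, code = genetic_code()) {
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  tree <- scenario$tree
  L <- scenario$L
  sense <- code$sense
  sm <- do.call(rbind, strsplit(sense, ""))
  pi <- scenario$base_freq[sm[, 1]] * scenario$base_freq[sm[, 2]] *
    scenario$base_freq[sm[, 3]]
  pi <- pi / sum(pi)
  names(pi) <- sense

  cls <- scenario_branch_classes(scenario)
  at <- stats::setNames(rep(NA_real_, length(cls)), seq_along(cls))
  if (!is.null(scenario$schedule)) {
    at[scenario$schedule$branch] <- scenario$schedule$at
  }

  eig_cache <- new.env(parent = emptyenv())
  get_eig <- function(w) {
    key <- format(w, digits = 15)
    if (is.null(eig_cache[[key]])) {
      eig_cache[[key]] <- gy94_eigen(pi, scenario$kappa, w, code)
    }
    eig_cache[[key]]
  }
  evolve <- function(states, w, t) {
    if (t <= 0) return(states)
    P <- gy94_prob(get_eig(w), t)
    out <- integer(length(states))
    for (s in unique(states)) {
      idx <- which(states == s)
      out[idx] <- sample.int(length(sense), length(idx), replace = TRUE,
                             prob = P[s, ])
    }
    out
  }

  # per-site omega class on intact lineages; classes share one overall
  # rate normalisation (mixture-average), so high-omega classes evolve
  # proportionally faster, matching the likelihood convention
  if (!is.null(scenario$site_classes)) {
    site_class <- sample.int(nrow(scenario$site_classes), L, replace = TRUE,
                             prob = scenario$site_classes$p)
    class_omega <- scenario$site_classes$omega
    mu_k <- vapply(class_omega, function(w)
      gy94_mean_rate(pi, scenario$kappa, w, code), numeric(1))
    class_rate <- mu_k / sum(scenario$site_classes$p * mu_k)
  } else {
    site_class <- rep(1L, L)
    class_omega <- scenario$omega_intact
    class_rate <- 1
  }
  evolve_sites <- function(states, omega_per_class, t) {
    out <- states
    for (cl_k in unique(site_class)) {
      idx <- which(site_class == cl_k)
      out[idx] <- evolve(states[idx], omega_per_class[cl_k],
                         t * class_rate[cl_k])
    }
    out
  }

  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  seqs <- vector("list", n_node)
  root <- tree_root(tree)
  seqs[[root]] <- sample.int(length(sense), L, replace = TRUE, prob = pi)
  bl <- resolve_branch_lengths(tree, NULL)
  neutral <- rep(1, length(class_omega))
  # preorder: parents before children
  pre <- ape::reorder.phylo(tree, "postorder")$edge
  pre <- pre[rev(seq_len(nrow(pre))), , drop = FALSE]
  for (e in seq_len(nrow(pre))) {
    parent <- pre[e, 1L]; child <- pre[e, 2L]
    t_e <- bl[child]
    if (cls[child] == "psi2") {
      s <- evolve_sites(seqs[[parent]], class_omega, t_e * at[child])
      seqs[[child]] <- evolve(s, 1, t_e * (1 - at[child]))
    } else if (cls[child] == "psi1") {
      seqs[[child]] <- evolve(seqs[[parent]], 1, t_e)
    } else {
      seqs[[child]] <- evolve_sites(seqs[[parent]], class_omega, t_e)
    }
  }

  mat <- do.call(rbind, lapply(seq_len(n_tip), function(tip) {
    unlist(strsplit(sense[seqs[[tip]]], ""), use.names = FALSE)
  }))
  rownames(mat) <- tree$tip.label

  reference <- scenario$reference
  if (is.null(reference)) {
    intact_tips <- which(cls[seq_len(n_tip)] == "intact")
    if (!length(intact_tips)) stop("no intact tip available as reference")
    reference <- tree$tip.label[intact_tips[1L]]
  }
  bt <- branch_table(tree)
  truth_classes <- tibble::tibble(
    branch = bt$branch, label = bt$label, class = cls[bt$branch],
    omega = ifelse(cls[bt$branch] == "intact", scenario$omega_intact, 1),
    at = at[bt$branch])
  list(alignment = codon_alignment(mat, reference),
       truth = list(classes = truth_classes, site_class = site_class,
                    root_seq = sense[seqs[[root]]], pi = pi))
}

#' Inject pseudogenization lesions according to the schedule
#'
#' For each scheduled branch, one guaranteed founding lesion (frameshifting
#' insertion or deletion, or a nonsense mutation, chosen at random) is
#' written into every descendant tip at a random reference codon. With
#' `stochastic_lesions = TRUE` and branch times available, extra lesions
#' are drawn as Poisson counts at the configured neutral indel and
#' stop-creating substitution rates on each pseudogene branch segment and
#' applied to the tips below that segment. Lesion codon positions never
#' collide, so the injected set is exactly recoverable by
#' [detect_disruptions] on frameshift-free backgrounds.
#'
#' @param sim Result of [simulate_codon_alignment].
#' @param scenario The same [sim_scenario].
#' @param code A [genetic_code].
#' @return List as `sim`, with the lesioned `alignment` and
#'   `truth$events`: tibble (`kind`, `ref_codon`, `length_bp`,
#'   `stop_codon`, `branch`, `carriers` list column, `founding`).
#' @export
inject_pseudogenization <- function(sim, scenario, code = genetic_code()) {
  aln <- sim$alignment
  tree <- scenario$tree
  if (is.null(scenario$schedule) || nrow(scenario$schedule) == 0L) {
    sim$truth$events <- tibble::tibble(
      kind = character(), ref_codon = integer(), length_bp = integer(),
      stop_codon = character(), branch = integer(), carriers = list(),
      founding = logical())
    return(sim)
  }
  L3 <- aln$n_ref_codons
  used <- integer(0)
  events <- list()
  draw_codon <- function() {
    ok <- setdiff(seq(4L, L3 - 3L), c(used, used - 1L, used + 1L))
    if (!length(ok)) stop("no free codon positions left for lesions")
    sample(ok, 1L)
  }

  lesion_plan <- list()
  for (i in seq_len(nrow(scenario$schedule))) {
    b <- scenario$schedule$branch[i]
    lesion_plan[[length(lesion_plan) + 1L]] <-
      list(branch = b, founding = TRUE)
  }
  if (scenario$stochastic_lesions) {
    cls <- scenario_branch_classes(scenario)
    times <- scenario$times
    stop_frac <- mean(vapply(code$sense, codon_stop_fraction, numeric(1),
                             scenario$kappa, code))
    for (b in tree$edge[, 2L]) {
      if (is.na(cls[b]) || cls[b] == "intact") next
      t_b <- times[[as.character(b)]]
      if (is.null(t_b) || is.na(t_b)) next
      if (cls[b] == "psi2") {
        t_b <- t_b * (1 - scenario$schedule$at[
          match(b, scenario$schedule$branch)])
      }
      mu <- (scenario$indel_rate +
               scenario$sub_rate * stop_frac) * 3 * L3 * t_b
      n_extra <- stats::rpois(1L, mu)
      for (k in seq_len(n_extra)) {
        lesion_plan[[length(lesion_plan) + 1L]] <-
          list(branch = b, founding = FALSE)
      }
    }
  }

  for (pl in lesion_plan) {
    carriers <- tree$tip.label[tree_tips_below(tree, pl$branch)]
    if (aln$reference %in% carriers) {
      stop("reference taxon descends from a scheduled branch; ",
           "choose an intact reference")
    }
    kind <- sample(c("deletion", "insertion", "nonsense"), 1L)
    rc <- draw_codon()
    used <- c(used, rc)
    rows <- match(carriers, rownames(aln$mat))
    cols <- ref_codon_columns(aln)[[as.character(rc)]]
    if (kind == "deletion") {
      len <- sample(c(1L, 2L), 1L)
      aln$mat[rows, cols[seq_len(len)]] <- "-"
      ev <- tibble::tibble(kind = "deletion", ref_codon = rc,
                           length_bp = len, stop_codon = NA_character_)
    } else if (kind == "insertion") {
      len <- sample(c(1L, 2L), 1L)
      pos <- cols[3L]
      newcols <- matrix("-", nrow(aln$mat), len)
      newcols[rows, ] <- sample(c("A", "C", "G", "T"), length(rows) * len,
                                replace = TRUE)
      mat <- cbind(aln$mat[, seq_len(pos), drop = FALSE], newcols,
                   aln$mat[, -seq_len(pos), drop = FALSE])
      rownames(mat) <- rownames(aln$mat)
      aln <- codon_alignment(mat, aln$reference)
      ev <- tibble::tibble(kind = "insertion", ref_codon = rc,
                           length_bp = len, stop_codon = NA_character_)
    } else {
      stop_cod <- sample(code$stops, 1L)
      aln$mat[rows, cols] <- matrix(rep(strsplit(stop_cod, "")[[1]],
                                        each = length(rows)),
                                    nrow = length(rows))
      ev <- tibble::tibble(kind = "nonsense", ref_codon = rc,
                           length_bp = 0L, stop_codon = stop_cod)
    }
    events[[length(events) + 1L]] <- dplyr::mutate(
      ev, branch = pl$branch, carriers = list(carriers),
      founding = pl$founding)
  }
  sim$alignment <- aln
  sim$truth$events <- dplyr::bind_rows(events)
  sim
}
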