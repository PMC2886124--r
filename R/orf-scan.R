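#' Detect ORF-disrupting lesions in one aligned sequence
#'
#' Scans a taxon's row of a codon alignment against the reference frame and
#' reports, in reference-coordinate order: insertions and deletions relative
#' to the reference whose length is not a multiple of three (frameshifting
#' indels), and premature stop codons read in the taxon's *current* frame
#' (the frame is tracked through indels, so stops downstream of a frameshift
#' are reported in the shifted frame). In-frame indels are not disruptions.
#'
#' @param aln A [codon_alignment].
#' @param taxon Taxon to scan.
#' @param code A [genetic_code].
#' @param tail_tolerance Stops within this many codons of the reference 3'
#'   end are ignored (default 0: every premature stop counts).
#' @return Tibble with columns `taxon`, `kind` (`insertion`, `deletion`,
#'   `nonsense`), `ref_codon`, `length_bp` (0 for nonsense) and
#'   `stop_codon` (the stop triplet for nonsense events, else `NA`).
#' @export
detect_disruptions <- function(aln, taxon, code = genetic_code(),
                               tail_tolerance = 0L) {
  if (!taxon %in% alignment_taxa(aln)) {
    stop("taxon '", taxon, "' not present in alignment")
  }
  row <- aln$mat[taxon, ]
  is_ins_col <- is.na(aln$coord_map)
  events <- list()
  add <- function(kind, ref_codon, length_bp, stop_codon = NA_character_,
                  col = NA_integer_) {
    events[[length(events) + 1L]] <<- tibble::tibble(
      taxon = taxon, kind = kind, ref_codon = as.integer(ref_codon),
      length_bp = as.integer(length_bp), stop_codon = stop_codon, col = col)
  }

  # deletions: runs of taxon gaps over reference-base columns
  ref_cols <- which(!is_ins_col)
  gap <- row[ref_cols] == "-"
  if (any(gap)) {
    runs <- rle(gap)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      len <- runs$lengths[k]
      if (len %% 3L != 0L) {
        add("deletion", aln$coord_map[ref_cols[starts[k]]], len,
            col = ref_cols[starts[k]])
      }
    }
  }

  # insertions: runs of taxon bases over insertion columns, contiguous in
  # the full column sequence
  has_base <- is_ins_col & row != "-"
  if (any(has_base)) {
    runs <- rle(has_base)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      len <- runs$lengths[k]
      if (len %% 3L != 0L) {
        add("insertion", aln$ins_anchor[starts[k]], len, col = starts[k])
      }
    }
  }

  # premature stops in the taxon's own running frame: read the ungapped
  # sequence in triplets from its start; indels shift the parsing of
  # everything downstream automatically
  base_cols <- which(row != "-")
  if (length(base_cols) >= 3L) {
    n_tri <- length(base_cols) %/% 3L
    for (t in seq_len(n_tri)) {
      cols3 <- base_cols[(3L * t - 2L):(3L * t)]
      tri <- paste(row[cols3], collapse = "")
      if (tri %in% code$stops) {
        rc <- aln$coord_map[cols3[1L]]
        if (is.na(rc)) rc <- aln$ins_anchor[cols3[1L]]
        if (rc <= aln$n_ref_codons - tail_tolerance) {
          add("nonsense", rc, 0L, stop_codon = tri, col = cols3[1L])
        }
      }
    }
  }

  if (!length(events)) {
    return(tibble::tibble(taxon = character(), kind = character(),
                          ref_codon = integer(), length_bp = integer(),
                          stop_codon = character()))
  }
  out <- dplyr::bind_rows(events)
  out <- dplyr::select(dplyr::arrange(out, .data$col), -"col")
  out
}

#' Scan every taxon of an alignment for ORF disruptions
#'
#' @inheritParams detect_disruptions
#' @param taxa Taxa to scan (default: all except none; the reference is
#'   scanned too and should come back clean for an intact reference).
#' @return Tibble as in [detect_disruptions], rows for all taxa.
#' @export
scan_alignment <- function(aln, taxa = alignment_taxa(aln),
                           code = genetic_code(), tail_tolerance = 0L) {
  dplyr::bind_rows(lapply(taxa, function(tx) {
    detect_disruptions(aln, tx, code, tail_tolerance)
  }))
}

#' Map shared lesions onto tree branches under Dollo parsimony
#'
#' Lesions identical in kind, reference codon, length (and stop triplet for
#' nonsense lesions) across taxa are treated as a single mutation wherever a
#' single origin is consistent with the tree: the merged event is assigned
#' to the branch above the most recent common ancestor of its carriers
#' provided every tip below that ancestor carries it. Otherwise the carrier
#' set is split into maximal fully-carrying clades, each an independent
#' event. Each origin is one row of the result.
#'
#' @param tree Rooted [ape::phylo] tree whose tips cover all carrier taxa.
#' @param events Tibble from [scan_alignment]/[detect_disruptions].
#' @param polymorphic_taxa Taxa whose lesions are allele-polymorphic; their
#'   private events are flagged (`polymorphic = TRUE`) and excluded from
#'   branch classification by default.
#' @return Tibble with columns `event_id`, `kind`, `ref_codon`, `length_bp`,
#'   `stop_codon`, `branch` (child node id of the assigned branch),
#'   `carriers` (list column of taxon names) and `polymorphic`.
#' @export
map_events <- function(tree, events, polymorphic_taxa = character()) {
  if (nrow(events) == 0L) {
    return(tibble::tibble(event_id = integer(), kind = character(),
                          ref_codon = integer(), length_bp = integer(),
                          stop_codon = character(), branch = integer(),
                          carriers = list(), polymorphic = logical()))
  }
  missing <- setdiff(unique(events$taxon), tree$tip.label)
  if (length(missing)) {
    stop("carrier taxa not in tree: ", paste(missing, collapse = ", "))
  }
  n_tip <- length(tree$tip.label)
  keys <- dplyr::group_by(events, .data$kind, .data$ref_codon,
                          .data$length_bp, .data$stop_codon)
  groups <- dplyr::group_split(keys)
  out <- list()
  for (g in groups) {
    carriers <- unique(g$taxon)
    carry <- rep(FALSE, n_tip + tree$Nnode)
    carry[match(carriers, tree$tip.label)] <- TRUE
    carry[(n_tip + 1L):(n_tip + tree$Nnode)] <- TRUE
    # postorder: an internal node carries iff all its children carry
    po <- ape::reorder.phylo(tree, "postorder")$edge
    for (e in seq_len(nrow(po))) {
      carry[po[e, 1]] <- carry[po[e, 1]] && carry[po[e, 2]]
    }
    # maximal carrying nodes (origin branches)
    parent_of <- integer(n_tip + tree$Nnode)
    parent_of[tree$edge[, 2]] <- tree$edge[, 1]
    root <- tree_root(tree)
    origins <- which(vapply(seq_along(carry), function(node) {
      carry[node] && (node == root || !carry[parent_of[node]])
    }, logical(1)))
    for (node in origins) {
      tips <- tree_tips_below(tree, node)
      tips <- tree$tip.label[tips]
      tips <- intersect(tips, carriers)
      if (!length(tips)) next
      out[[length(out) + 1L]] <- tibble::tibble(
        kind = g$kind[1L], ref_codon = g$ref_codon[1L],
        length_bp = g$length_bp[1L], stop_codon = g$stop_codon[1L],
        branch = as.integer(node), carriers = list(tips),
        polymorphic = all(tips %in% polymorphic_taxa))
    }
  }
  out <- dplyr::bind_rows(out)
  out <- dplyr::arrange(out, .data$ref_codon, .data$kind)
  dplyr::mutate(out, event_id = dplyr::row_number(), .before = 1L)
}

#' Classify branches as intact / founding pseudogene / inherited pseudogene
#'
#' Walking each root-to-tip path, the first branch carrying a disruption
#' event is the founding pseudogene branch (`psi2`); every branch strictly
#' below a `psi2` branch is an inherited pseudogene branch (`psi1`, neutral
#' by definition); all other branches are `intact`. Pseudogene status is
#' hereditary and irreversible.
#'
#' @param tree Rooted [ape::phylo] tree.
#' @param mapped_events Tibble from [map_events].
#' @param include_polymorphic Count allele-polymorphic lesions as founding
#'   events (default `FALSE`).
#' @return Tibble with columns `branch` (child node id), `label` and
#'   `class` (`intact`, `psi2`, `psi1`).
#' @export
classify_branches <- function(tree, mapped_events,
                              include_polymorphic = FALSE) {
  ev <- mapped_events
  if (!include_polymorphic && nrow(ev)) {
    ev <- ev[!ev$polymorphic, , drop = FALSE]
  }
  hit <- unique(ev$branch)
  n_tip <- length(tree$tip.label)
  cls <- rep(NA_character_, n_tip + tree$Nnode)
  walk <- function(node, state) {
    for (child in tree$edge[tree$edge[, 1] == node, 2]) {
      st <- if (state != "intact") "psi1"
            else if (child %in% hit) "psi2" else "intact"
      cls[child] <<- st
      walk(child, st)
    }
  }
  walk(tree_root(tree), "intact")
  bt <- branch_table(tree)
  tibble::tibble(branch = bt$branch, label = bt$label,
                 class = cls[bt$branch])
}

#' Number of independent disruption origins
#'
#' @param mapped_events Tibble from [map_events].
#' @param include_polymorphic Count allele-polymorphic lesions.
#' @return Integer count of distinct (event, branch) origins.
#' @export
count_independent_events <- function(mapped_events,
                                     include_polymorphic = TRUE) {
  ev <- mapped_events
  if (!include_polymorphic && nrow(ev)) ev <- ev[!ev$polymorphic, , drop = FALSE]
  nrow(dplyr::distinct(ev, .data$event_id, .data$branch))
}
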