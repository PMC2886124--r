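# Shared fixtures and independent oracles used across the suite.

# A small ape tree with named hominoid-style tips; node ids (4 tips):
# root = 5, (human,chimp,gorilla) ancestor = 6, (human,chimp) ancestor = 7.
hcg_tree <- function() {
  read_species_tree("(((human:6,chimp:6):2,gorilla:8):24,macaque:32);")
}

random_scaled_tree <- function(n, depth = 0.5) {
  tr <- ape::rcoal(n)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr)) *
    depth
  tr
}

# Write an alignment matrix (list of named strings) to a temp FASTA file.
write_temp_fasta <- function(seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(seqs), function(n) {
    c(paste0(">", n), seqs[[n]])
  })), path)
  path
}

aln_from_strings <- function(seqs, reference) {
  mat <- do.call(rbind, strsplit(unlist(seqs), ""))
  rownames(mat) <- names(seqs)
  codon_alignment(mat, reference)
}

# Independent likelihood oracle: exhaustive enumeration over ancestral
# codon states at every internal node, with transition probabilities from
# Matrix::expm (a different exponentiation route than the package's
# eigendecomposition).
brute_force_loglik <- function(aln, tree, omega, kappa, pi) {
  code <- genetic_code()
  Q <- gy94_rate_matrix(pi, kappa, omega, code)
  P <- lapply(seq_len(nrow(tree$edge)), function(e) {
    as.matrix(Matrix::expm(Q * tree$edge.length[e]))
  })
  names(P) <- tree$edge[, 2]
  strs <- orfdecay:::alignment_codon_strings(aln)
  sense <- code$sense
  states <- do.call(rbind, lapply(strs, function(cod) {
    s <- match(cod, sense)
    s[!grepl("^[ACGT]{3}$", cod)] <- 0L
    s
  }))
  states <- states[match(tree$tip.label, rownames(states)), , drop = FALSE]
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  internals <- (n_tip + 1L):(n_tip + tree$Nnode)
  grid <- as.matrix(expand.grid(rep(list(seq_along(sense)),
                                    length(internals))))
  colnames(grid) <- internals
  total <- 0
  for (s in seq_len(ncol(states))) {
    lik <- pi[grid[, as.character(root)]]
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
      sp <- grid[, as.character(par)]
      Pe <- P[[as.character(ch)]]
      if (ch <= n_tip) {
        sc <- states[ch, s]
        lik <- lik * if (sc == 0L) 1 else Pe[cbind(sp, sc)]
      } else {
        lik <- lik * Pe[cbind(sp, grid[, as.character(ch)])]
      }
    }
    total <- total + log(sum(lik))
  }
  total
}

# Root-to-tip branch classification oracle: walk every path from the root
# and mark the first event branch psi2, everything below psi1.
classify_oracle <- function(tree, event_branches) {
  n_tip <- length(tree$tip.label)
  out <- rep(NA_character_, n_tip + tree$Nnode)
  recurse <- function(node, seen) {
    for (child in tree$edge[tree$edge[, 1] == node, 2]) {
      st <- if (seen) "psi1" else if (child %in% event_branches) "psi2"
            else "intact"
      out[child] <<- st
      recurse(child, seen || child %in% event_branches)
    }
  }
  recurse(length(tree$tip.label) + 1L, FALSE)
  out
}

# Surviving-codon oracle for sanitize_alignment: recount columns by brute
# force given the lesions known to have been injected.
count_clean_codons <- function(aln, code = genetic_code()) {
  cols <- orfdecay:::ref_codon_columns(aln)
  keep <- vapply(seq_along(cols), function(ci) {
    for (tx in rownames(aln$mat)) {
      tri <- aln$mat[tx, cols[[ci]]]
      if (paste(tri, collapse = "") %in% code$stops) return(FALSE)
    }
    TRUE
  }, logical(1))
  sum(keep)
}

tree_tips_below_names <- function(tree, node) {
  tree$tip.label[orfdecay:::tree_tips_below(tree, node)]
}
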