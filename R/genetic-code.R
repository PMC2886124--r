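#' Genetic code used for ORF scanning and codon models
#'
#' A light wrapper around a codon-to-amino-acid table. The default is the
#' standard nuclear code (stop codons TAA, TAG, TGA) taken from
#' [Biostrings::GENETIC_CODE].
#'
#' @param table Named character vector of length 64 mapping codons (e.g.
#'   `"ATG"`) to single-letter amino acids, with `"*"` marking stops.
#' @return An object of class `genetic_code` with elements `table`, `stops`
#'   (stop codons) and `sense` (the non-stop codons, in table order).
#' @examples
#' gc <- genetic_code()
#' gc$stops
#' @export
genetic_code <- function(table = NULL) {
  if (is.null(table)) {
    table <- as.character(Biostrings::GENETIC_CODE)
    names(table) <- names(Biostrings::GENETIC_CODE)
    # Biostrings uses T-alphabet codon names already
  }
  stopifnot(length(table) == 64L, !is.null(names(table)))
  names(table) <- toupper(chartr("U", "T", names(table)))
  stops <- names(table)[table == "*"]
  structure(
    list(table = table, stops = stops,
         sense = names(table)[table != "*"]),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("<genetic_code> ", length(x$sense), " sense codons, stops: ",
      paste(x$stops, collapse = ", "), "\n", sep = "")
  invisible(x)
}

is_stop_codon <- function(codon, code = genetic_code()) {
  codon %in% code$stops
}

# Cached pairwise structure of the sense-codon state space for one genetic
# code: single-nucleotide neighbours, transition/transversion status and
# synonymy. Keyed by the concatenated amino-acid table.
.codon_env <- new.env(parent = emptyenv())

codon_structure <- function(code = genetic_code()) {
  key <- paste(code$table, collapse = "")
  if (!is.null(.codon_env[[key]])) return(.codon_env[[key]])
  sense <- code$sense
  n <- length(sense)
  aa <- code$table[sense]
  split_mat <- do.call(rbind, strsplit(sense, ""))
  transitions <- c(A = "G", G = "A", C = "T", T = "C")
  ii <- integer(0); jj <- integer(0); pos <- integer(0)
  is_ts <- logical(0); is_syn <- logical(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      diff <- which(split_mat[i, ] != split_mat[j, ])
      if (length(diff) != 1L) next
      ii <- c(ii, i); jj <- c(jj, j); pos <- c(pos, diff)
      is_ts <- c(is_ts, transitions[[split_mat[i, diff]]] == split_mat[j, diff])
      is_syn <- c(is_syn, aa[[i]] == aa[[j]])
    }
  }
  out <- list(sense = sense, n = n, aa = aa, split = split_mat,
              i = ii, j = jj, pos = pos, is_ts = is_ts, is_syn = is_syn)
  .codon_env[[key]] <- out
  out
}
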