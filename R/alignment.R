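#' Codon-framed multiple alignment
#'
#' Container for an aligned set of nucleotide sequences with a designated
#' reference taxon whose gapless sequence defines the codon frame. Every
#' alignment column is mapped either to a 1-based reference codon index or
#' flagged as an insertion relative to the reference (coordinate `NA`, with
#' the anchoring reference codon recorded separately). Positions reported by
#' downstream ORF-scanning functions are always in reference codon
#' coordinates, matching the convention of annotating lesions by the codon
#' position of an intact ortholog.
#'
#' @param mat Character matrix, rows = taxa (rownames required), columns =
#'   alignment columns; entries in `A/C/G/T/-` plus ambiguity letters
#'   (anything not `A/C/G/T/-` is treated as fully ambiguous downstream).
#' @param reference Name of the reference taxon (must be a row).
#' @param frame_offset Number of leading reference bases before codon 1
#'   (default 0).
#' @return Object of class `codon_alignment` with elements `mat`,
#'   `reference`, `frame_offset`, `coord_map` (integer per column, `NA` on
#'   insertion columns), `ins_anchor` (reference codon each insertion column
#'   is anchored to) and `n_ref_codons`.
#' @export
codon_alignment <- function(mat, reference, frame_offset = 0L) {
  stopifnot(is.matrix(mat), is.character(mat))
  if (is.null(rownames(mat))) stop("alignment matrix must have taxon rownames")
  if (!reference %in% rownames(mat)) {
    stop("reference taxon '", reference, "' not present in alignment")
  }
  mat[] <- toupper(chartr("Uu", "TT", mat))
  ref <- mat[reference, ]
  ref_base <- ref != "-"
  n_ref_nt <- sum(ref_base) - frame_offset
  if (n_ref_nt %% 3L != 0L) {
    stop("reference sequence length not divisible by 3: remainder ",
         n_ref_nt %% 3L)
  }
  coord_map <- rep(NA_integer_, ncol(mat))
  idx <- which(ref_base)
  if (frame_offset > 0L) idx <- idx[-seq_len(frame_offset)]
  coord_map[idx] <- rep(seq_len(n_ref_nt %/% 3L), each = 3L)
  # insertion columns anchor to the most recent reference codon (0 if none)
  anchor <- rep(NA_integer_, ncol(mat))
  last <- 0L
  for (c in seq_len(ncol(mat))) {
    if (!is.na(coord_map[c])) last <- coord_map[c] else anchor[c] <- last
  }
  structure(
    list(mat = mat, reference = reference, frame_offset = as.integer(frame_offset),
         coord_map = coord_map, ins_anchor = anchor,
         n_ref_codons = n_ref_nt %/% 3L),
    class = "codon_alignment"
  )
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("<codon_alignment> ", nrow(x$mat), " taxa x ", ncol(x$mat),
      " columns; ", x$n_ref_codons, " reference codons (reference: ",
      x$reference, ")\n", sep = "")
  invisible(x)
}

#' @export
ntaxa <- function(aln) UseMethod("ntaxa")
#' @export
ntaxa.codon_alignment <- function(aln) nrow(aln$mat)

alignment_taxa <- function(aln) rownames(aln$mat)

# Columns belonging to each reference codon, as a list of integer triplets.
ref_codon_columns <- function(aln) {
  split(which(!is.na(aln$coord_map)), aln$coord_map[!is.na(aln$coord_map)])
}

# Per-taxon codon strings in reference frame: n_ref_codons entries, each the
# 3 aligned characters at that codon's columns pasted together.
alignment_codon_strings <- function(aln, taxa = alignment_taxa(aln)) {
  cols <- which(!is.na(aln$coord_map))
  lapply(stats::setNames(taxa, taxa), function(tx) {
    ch <- aln$mat[tx, cols]
    apply(matrix(ch, nrow = 3L), 2L, paste, collapse = "")
  })
}

#' Read a codon-framed alignment from aligned FASTA
#'
#' @param path Path to an aligned FASTA file (all records equal length).
#' @param reference Reference taxon name.
#' @param frame_offset Leading reference bases before codon 1.
#' @return A [codon_alignment].
#' @export
read_codon_alignment <- function(path, reference, frame_offset = 0L) {
  seqs <- Biostrings::readBStringSet(path)
  lens <- Biostrings::width(seqs)
  if (length(unique(lens)) != 1L) {
    stop("alignment rows have unequal lengths: ",
         paste(paste0(names(seqs), "=", lens), collapse = ", "))
  }
  nm <- sub("\\s.*$", "", names(seqs))
  mat <- do.call(rbind, strsplit(as.character(seqs), ""))
  rownames(mat) <- nm
  codon_alignment(mat, reference, frame_offset)
}

#' Write a codon alignment to aligned FASTA
#' @param aln A [codon_alignment].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_codon_alignment <- function(aln, path) {
  seqs <- Biostrings::BStringSet(apply(aln$mat, 1L, paste, collapse = ""))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Remove alignment codons incompatible with codon-model likelihoods
#'
#' Applies the standard pseudogene-alignment cleaning rules: (i) runs of
#' columns that are insertions relative to the reference are deleted when
#' the run length is not a multiple of three (frameshifting insertions;
#' in-frame insertions are retained but never enter likelihood columns);
#' (ii) any reference codon in which some taxon reads a stop codon, and
#' (iii) any reference codon left partially deleted by a frameshifting
#' deletion in some taxon, are deleted across all taxa. The removal log
#' records every removed codon with the triggering taxon and reason.
#'
#' Sanitization is idempotent and the log is complete: a codon is removed
#' if and only if it appears in the log.
#'
#' @param aln A [codon_alignment].
#' @param code A [genetic_code].
#' @return A list with elements `alignment` (sanitized [codon_alignment])
#'   and `log` (tibble with columns `ref_codon`, `reason`, `taxon`).
#' @export
sanitize_alignment <- function(aln, code = genetic_code()) {
  mat <- aln$mat
  drop_cols <- logical(ncol(mat))
  log <- list()

  # (i) frameshifting insertion runs
  ins <- is.na(aln$coord_map)
  if (any(ins)) {
    runs <- rle(ins)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      cols <- starts[k]:ends[k]
      if (length(cols) %% 3L != 0L) {
        drop_cols[cols] <- TRUE
        carriers <- rownames(mat)[apply(mat[, cols, drop = FALSE] != "-", 1L, any)]
        carriers <- setdiff(carriers, aln$reference)
        log[[length(log) + 1L]] <- tibble::tibble(
          ref_codon = aln$ins_anchor[cols[1L]],
          reason = "frameshift_insertion",
          taxon = paste(carriers, collapse = ","))
      }
    }
  }

  # (ii) stop codons and (iii) partial codons from frameshifting deletions
  codon_cols <- ref_codon_columns(aln)
  drop_codon <- logical(aln$n_ref_codons)
  ref_base_cols <- which(!is.na(aln$coord_map))
  for (tx in rownames(mat)) {
    row <- mat[tx, ]
    # stops read in the reference frame
    for (ci in seq_along(codon_cols)) {
      tri <- paste(row[codon_cols[[ci]]], collapse = "")
      if (tri %in% code$stops) {
        if (!drop_codon[ci]) {
          log[[length(log) + 1L]] <- tibble::tibble(
            ref_codon = ci, reason = "stop", taxon = tx)
        }
        drop_codon[ci] <- TRUE
      }
    }
    # frameshifting deletion runs over reference-base columns
    gap <- row[ref_base_cols] == "-"
    if (any(gap)) {
      runs <- rle(gap)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (k in which(runs$values)) {
        if (runs$lengths[k] %% 3L == 0L) next
        run_codons <- unique(aln$coord_map[ref_base_cols[starts[k]:ends[k]]])
        for (ci in run_codons) {
          chars <- row[codon_cols[[as.character(ci)]]]
          if (any(chars == "-") && any(chars != "-")) {
            if (!drop_codon[ci]) {
              log[[length(log) + 1L]] <- tibble::tibble(
                ref_codon = ci, reason = "partial_deletion", taxon = tx)
            }
            drop_codon[ci] <- TRUE
          }
        }
      }
    }
  }

  for (ci in which(drop_codon)) drop_cols[codon_cols[[as.character(ci)]]] <- TRUE
  log <- if (length(log)) {
    dplyr::distinct(dplyr::arrange(dplyr::bind_rows(log), .data$ref_codon))
  } else {
    tibble::tibble(ref_codon = integer(), reason = character(),
                   taxon = character())
  }
  keep <- !drop_cols
  if (!any(keep & !is.na(aln$coord_map))) {
    warning("sanitized alignment contains no reference codons")
  }
  out <- codon_alignment(mat[, keep, drop = FALSE], aln$reference,
                         aln$frame_offset)
  list(alignment = out, log = log)
}
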