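#' Read a rooted species tree with optional branch class labels
#'
#' Parses a Newick tree via [ape::read.tree] after extracting branch class
#' tags. Two label syntaxes are accepted: comment tags `[&class=psi1]`
#' attached to a tip or internal node (before or after the branch length),
#' and PAML-style suffix tags `#1` (this branch) or `$1` (this branch and
#' all its descendants). Classes are stored per branch, indexed by the
#' branch's child node, in the returned tree's `branch.class` element.
#'
#' @param path Path to a Newick file, or a Newick string containing `;`.
#' @return An [ape::phylo] object (rooted) with an extra `branch.class`
#'   character vector of length `Ntip + Nnode` (NA where unlabelled; the
#'   root entry is always NA).
#' @export
read_species_tree <- function(path) {
  txt <- if (grepl(";", path, fixed = TRUE)) path else {
    paste(readLines(path, warn = FALSE), collapse = "")
  }
  # move comment tags that follow a branch length to before the colon
  txt <- gsub(":([0-9.eE+\\-]+)\\[&class=([^]]+)\\]", "__CLS_\\2:\\1", txt)
  txt <- gsub("\\[&class=([^]]+)\\]", "__CLS_\\1", txt)
  txt <- gsub("\\s*#\\s*([0-9A-Za-z_.]+)", "__CLS_\\1", txt)
  txt <- gsub("\\s*\\$\\s*([0-9A-Za-z_.]+)", "__CLSALL_\\1", txt)
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("could not parse Newick input")
  if (!ape::is.rooted(tree)) {
    stop("tree is unrooted; please root it (binary root) before analysis")
  }
  n_tip <- length(tree$tip.label)
  cls <- rep(NA_character_, n_tip + tree$Nnode)
  clade <- rep(NA_character_, n_tip + tree$Nnode)
  extract <- function(labels, offset) {
    for (i in seq_along(labels)) {
      lab <- labels[i]
      if (is.na(lab) || lab == "") next
      m <- regmatches(lab, regexec("__CLSALL_([0-9A-Za-z_.]+)", lab))[[1]]
      if (length(m)) clade[offset + i] <<- m[2]
      m <- regmatches(lab, regexec("__CLS_([0-9A-Za-z_.]+)$", lab))[[1]]
      if (length(m)) cls[offset + i] <<- m[2]
      labels[i] <- sub("__CLS(ALL)?_[0-9A-Za-z_.]+$", "", lab)
    }
    labels
  }
  tree$tip.label <- extract(tree$tip.label, 0L)
  if (!is.null(tree$node.label)) {
    tree$node.label <- extract(tree$node.label, n_tip)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate taxon names in tree: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  # propagate clade ($) tags to all descendant branches
  for (node in which(!is.na(clade))) {
    for (d in tree_descendants(tree, node)) {
      if (is.na(cls[d])) cls[d] <- clade[node]
    }
    cls[node] <- clade[node]
  }
  tree$branch.class <- cls
  tree
}

#' Write a species tree with branch class labels
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output path (NULL returns the Newick string).
#' @param classes Character vector of branch classes indexed by child node
#'   (defaults to `tree$branch.class`).
#' @param style `"comment"` for `[&class=x]` tags, `"paml"` for `#x` tags.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_species_tree <- function(tree, path = NULL,
                               classes = tree$branch.class,
                               style = c("comment", "paml")) {
  style <- match.arg(style)
  tree2 <- tree
  tree2$branch.class <- NULL
  n_tip <- length(tree$tip.label)
  if (!is.null(classes)) {
    idx <- which(!is.na(classes))
    if (is.null(tree2$node.label)) tree2$node.label <- rep("", tree2$Nnode)
    for (node in idx) {
      tag <- paste0("__CLS_", classes[node])
      if (node <= n_tip) {
        tree2$tip.label[node] <- paste0(tree2$tip.label[node], tag)
      } else {
        tree2$node.label[node - n_tip] <- paste0(tree2$node.label[node - n_tip], tag)
      }
    }
  }
  txt <- ape::write.tree(tree2)
  txt <- if (style == "comment") {
    gsub("__CLS_([0-9A-Za-z_.]+)", "[&class=\\1]", txt)
  } else {
    gsub("__CLS_([0-9A-Za-z_.]+)", " #\\1", txt)
  }
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

# All descendant node ids of `node` (excluding the node itself).
tree_descendants <- function(tree, node) {
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  if (!length(kids)) return(integer(0))
  c(kids, unlist(lapply(kids, tree_descendants, tree = tree)))
}

# Tip ids below a node (the node itself if it is a tip).
tree_tips_below <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  d <- tree_descendants(tree, node)
  d[d <= n_tip]
}

tree_root <- function(tree) length(tree$tip.label) + 1L

#' Branch table of a species tree
#'
#' One row per branch (edge), identified by its child node id. Tip branches
#' carry the tip name as `label`.
#'
#' @param tree An [ape::phylo] tree.
#' @return Tibble with columns `branch` (child node id), `parent`, `label`,
#'   `length` and `class`.
#' @export
branch_table <- function(tree) {
  n_tip <- length(tree$tip.label)
  child <- tree$edge[, 2]
  lab <- ifelse(child <= n_tip, tree$tip.label[child],
                paste0("node", child))
  cls <- if (!is.null(tree$branch.class)) tree$branch.class[child] else NA_character_
  tibble::tibble(
    branch = child,
    parent = tree$edge[, 1],
    label = lab,
    length = if (!is.null(tree$edge.length)) tree$edge.length else NA_real_,
    class = cls
  )
}
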