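# Newick I/O and tree surgery. Trees are ape "phylo" objects throughout;
# internal node labels hold support values (bootstrap % or local posterior
# probability) and are parsed as numeric where they look numeric.

#' Parse a Newick string into a tree
#'
#' Internal node labels are kept verbatim in `$node.label`; when numeric they
#' are interpreted downstream as branch support. Leaf labels must be unique.
#'
#' @param text A single Newick string (terminated by `;`).
#' @return An object of class `phylo`.
#' @examples
#' tr <- parse_newick("((A:1,B:1)90:0.5,C:1.5);")
#' tr$node.label
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tr <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("malformed Newick string: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(tr)) {
    # ape signals some failures by returning NULL; locate first offender
    pos <- regexpr("[^(),:;[:alnum:]_. '-]", text)
    stop("malformed Newick string",
         if (pos > 0) paste0(" near character ", pos), call. = FALSE)
  }
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "),
         call. = FALSE)
  }
  tr
}

#' Read gene trees from a file (one Newick per line)
#'
#' @param path Path to a text file with one Newick string per line.
#' @return A list of `phylo` objects (class `multiPhylo`).
#' @export
read_newick_trees <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no trees in file: ", path, call. = FALSE)
  trees <- lapply(lines, parse_newick)
  class(trees) <- "multiPhylo"
  trees
}

#' Write a tree (or list of trees) as Newick
#'
#' @param tree A `phylo` or `multiPhylo` object.
#' @param path Optional file path; when `NULL` the Newick string(s) are
#'   returned invisibly-visible as a character vector.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

# numeric support values per internal node (NA where absent / non-numeric)
node_support <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

#' Root a tree on an outgroup
#'
#' The outgroup must be monophyletic in some rooting of the tree; the root is
#' placed on the branch separating it from all remaining taxa. Re-rooting
#' preserves total tree length and the unrooted bipartition set.
#'
#' @param tree A `phylo` object.
#' @param outgroup Character vector of outgroup taxa.
#' @return A rooted `phylo` object.
#' @export
root_at_outgroup <- function(tree, outgroup) {
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing)) {
    stop("outgroup taxa absent from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- tryCatch(
    ape::root(tree, outgroup = outgroup, resolve.root = TRUE),
    error = function(e) stop("outgroup {", paste(outgroup, collapse = ", "),
                             "} is not monophyletic in any rooting",
                             call. = FALSE)
  )
  out
}

#' Collapse weakly supported branches into polytomies
#'
#' Internal branches whose (numeric) support is less than or equal to
#' `threshold` are contracted; branches with missing or non-numeric labels are
#' kept. The leaf set and all retained branch lengths are unchanged, and the
#' operation is idempotent.
#'
#' @param tree A `phylo` object with support stored as internal node labels.
#' @param threshold Support value at or below which a branch is collapsed
#'   (the rule is `<=`).
#' @return A `phylo` object, possibly with polytomies.
#' @export
collapse_low_support <- function(tree, threshold) {
  stopifnot(inherits(tree, "phylo"), is.numeric(threshold))
  sup <- node_support(tree)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  nodes <- ntip + seq_len(tree$Nnode)
  drop <- nodes[!is.na(sup) & sup <= threshold & nodes != root]
  if (!length(drop)) return(tree)

  edge <- tree$edge
  len <- tree$edge.length
  has_len <- !is.null(len)
  children <- split(seq_len(nrow(edge)), edge[, 1L])

  # Emit Newick recursively, splicing the children of dropped nodes into
  # their parent (the contracted branch's length is discarded).
  # parts contributed by one child edge: a dropped child is spliced into its
  # parent, recursively through chains of dropped nodes
  parts_of <- function(i) {
    child <- edge[i, 2L]
    if (child %in% drop) {
      unlist(lapply(children[[as.character(child)]], parts_of))
    } else {
      emit(child, if (has_len) len[i] else NA_real_, has_len)
    }
  }
  emit <- function(node, blen, show_len) {
    if (node <= ntip) {
      lab <- tree$tip.label[node]
    } else {
      parts <- unlist(lapply(children[[as.character(node)]], parts_of))
      lab <- paste0("(", paste(parts, collapse = ","), ")",
                    if (!is.null(tree$node.label))
                      tree$node.label[node - ntip] else "")
    }
    if (show_len && !is.na(blen)) paste0(lab, ":", format(blen, digits = 15))
    else lab
  }
  parse_newick(paste0(emit(root, NA_real_, has_len), ";"))
}

#' Prune a tree to a taxon subset
#'
#' Returns the induced subtree on `keep`; degree-2 nodes created by pruning
#' are suppressed with their incident branch lengths summed, so patristic
#' distances among kept taxa are preserved.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of taxa to retain (at least 2).
#' @return A `phylo` object on the taxa in `keep`.
#' @export
prune_to_taxa <- function(tree, keep) {
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing)) {
    stop("taxa absent from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(keep) < 2L) stop("need at least 2 taxa to keep", call. = FALSE)
  if (setequal(keep, tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Nontrivial bipartitions of a tree
#'
#' One split per internal edge, encoded canonically as the side that excludes
#' the lexicographically smallest taxon, so split identity is invariant to
#' rooting. Trivial splits (one side with fewer than 2 taxa) are omitted.
#'
#' @param tree A `phylo` object.
#' @return A list of character vectors (sorted taxa), named by a `|`-joined
#'   key usable for set operations.
#' @export
tree_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip < 4L) return(structure(list(), names = character()))
  ref <- min(tree$tip.label)
  edge <- tree$edge
  # tips below each node, accumulated in postorder
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(po))) {
    below[[po[i, 1L]]] <- c(below[[po[i, 1L]]], below[[po[i, 2L]]])
  }
  splits <- list()
  for (i in seq_len(nrow(edge))) {
    child <- edge[i, 2L]
    if (child <= ntip) next
    side <- tree$tip.label[below[[child]]]
    if (length(side) < 2L || length(side) > ntip - 2L) next
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    side <- sort(side)
    splits[[paste(side, collapse = "|")]] <- side
  }
  splits
}
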