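# Fitch parsimony and reverse-constraint partitioned Bremer support: each
# locus's parsimony-step contribution to each node of a focal tree, measured
# against the best tree in which that node's bipartition is broken.

# DNA state bitmasks; gaps/N/? are full state sets (missing data)
state_bits <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
                R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
                B = 14L, D = 13L, H = 11L, V = 7L,
                N = 15L, `-` = 15L, `?` = 15L, X = 15L)

#' Build a character matrix for parsimony scoring
#'
#' @param aln A `locus_alignment` or character matrix (rows = taxa). IUPAC
#'   ambiguity codes become state sets; gaps and `N` are treated as missing
#'   (the full state set).
#' @return Integer bitmask matrix of class `character_matrix`.
#' @export
character_matrix <- function(aln) {
  m <- unclass(aln)
  attr(m, "mask") <- NULL
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  bits <- state_bits[toupper(m)]
  bits[is.na(bits)] <- 15L
  out <- matrix(as.integer(bits), nrow(m), ncol(m),
                dimnames = list(rownames(m), NULL))
  class(out) <- c("character_matrix", "matrix", "array")
  out
}

#' Fitch parsimony length of a tree
#'
#' Minimum number of state changes over all sites by the Fitch bottom-up pass
#' (exact on binary trees; polytomies are scored as-is by sequential state-set
#' combination).
#'
#' @param tree A `phylo` whose tip labels all occur in `matrix`.
#' @param matrix A `character_matrix` (or alignment coercible to one).
#' @return Integer parsimony length.
#' @export
fitch_length <- function(tree, matrix) {
  if (!inherits(matrix, "character_matrix")) {
    if (is.numeric(matrix) && !is.null(rownames(matrix))) {
      # already bitmask-encoded (e.g. a column subset of a character_matrix)
      storage.mode(matrix) <- "integer"
      class(matrix) <- c("character_matrix", "matrix", "array")
    } else {
      matrix <- character_matrix(matrix)
    }
  }
  missing <- setdiff(tree$tip.label, rownames(matrix))
  if (length(missing))
    stop("taxa absent from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  nsite <- ncol(matrix)
  states <- matrix(0L, nnode, nsite)
  states[seq_len(ntip), ] <- matrix[tree$tip.label, , drop = FALSE]
  changes <- 0L
  po <- ape::reorder.phylo(tree, "postorder")$edge
  seen <- logical(nnode)
  for (i in seq_len(nrow(po))) {
    par <- po[i, 1L]; child <- po[i, 2L]
    if (!seen[par]) {
      states[par, ] <- states[child, ]
      seen[par] <- TRUE
    } else {
      inter <- bitwAnd(states[par, ], states[child, ])
      empty <- inter == 0L
      changes <- changes + sum(empty)
      if (any(empty))
        inter[empty] <- bitwOr(states[par, empty], states[child, empty])
      states[par, ] <- inter
    }
  }
  changes
}

# does the tree contain this bipartition (canonical-key comparison)?
has_bipartition <- function(tree, side) {
  all_taxa <- tree$tip.label
  side <- sort(side)
  if (min(all_taxa) %in% side) side <- sort(setdiff(all_taxa, side))
  paste(side, collapse = "|") %in% names(tree_bipartitions(tree))
}

#' Best parsimony tree under a bipartition constraint
#'
#' Finds the best-scoring tree that contains (`"require"`) or lacks
#' (`"forbid"`) a given bipartition, either by exhaustive enumeration of all
#' unrooted binary topologies (exact; feasible to 9 taxa) or by seeded NNI
#' hill-climbing with restarts. Score ties are broken by lexicographic Newick
#' so results are deterministic.
#'
#' @param matrix A `character_matrix`.
#' @param split Character vector: one side of the bipartition.
#' @param constraint `"require"` or `"forbid"`.
#' @param search `"exhaustive"` or `"nni_hillclimb"`.
#' @param seed RNG seed (heuristic mode).
#' @param n_restarts Hill-climb restarts (default 5).
#' @return List with `tree` (a `phylo`) and `length`.
#' @export
best_tree_under_constraint <- function(matrix, split,
                                       constraint = c("forbid", "require"),
                                       search = c("exhaustive",
                                                  "nni_hillclimb"),
                                       seed = 1, n_restarts = 5) {
  constraint <- match.arg(constraint)
  search <- match.arg(search)
  taxa <- rownames(matrix)
  missing <- setdiff(split, taxa)
  if (length(missing))
    stop("constraint taxa not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  ok <- function(tr) {
    h <- has_bipartition(tr, split)
    if (constraint == "require") h else !h
  }
  if (search == "exhaustive") {
    if (length(taxa) > 9)
      stop("exhaustive search limited to 9 taxa", call. = FALSE)
    cands <- phangorn::allTrees(length(taxa), rooted = FALSE,
                                tip.label = taxa)
    cands <- lapply(seq_along(cands), function(i) cands[[i]])
    best <- NULL; best_len <- Inf; best_key <- ""
    for (tr in cands) {
      if (!ok(tr)) next
      len <- fitch_length(tr, matrix)
      key <- lexicographic_key(tr)
      if (len < best_len || (len == best_len && key < best_key)) {
        best <- tr; best_len <- len; best_key <- key
      }
    }
    if (is.null(best))
      stop("no topology satisfies the constraint", call. = FALSE)
    return(list(tree = best, length = best_len))
  }
  # seeded NNI hill-climb
  set.seed(seed)
  best <- NULL; best_len <- Inf; best_key <- ""
  consider <- function(tr, len) {
    key <- lexicographic_key(tr)
    if (len < best_len || (len == best_len && key < best_key)) {
      best <<- tr; best_len <<- len; best_key <<- key
      TRUE
    } else FALSE
  }
  for (r in seq_len(n_restarts)) {
    cur <- ape::rtopology(length(taxa), rooted = FALSE, tip.label = sample(taxa))
    cur <- ape::unroot(cur)
    if (!ok(cur)) next
    cur_len <- fitch_length(cur, matrix)
    plateau <- 5L
    repeat {
      nbs <- phangorn::nni(cur)
      nbs <- lapply(seq_along(nbs), function(i) nbs[[i]])
      nbs <- Filter(ok, nbs)
      if (!length(nbs)) break
      lens <- vapply(nbs, fitch_length, numeric(1), matrix = matrix)
      m <- min(lens)
      if (m < cur_len) {
        pick <- which(lens == m)[1]
        cur <- nbs[[pick]]; cur_len <- m
      } else if (m == cur_len && plateau > 0L) {
        # sideways move across a parsimony plateau
        plateau <- plateau - 1L
        cur <- nbs[[sample(which(lens == m), 1)]]
      } else break
    }
    consider(cur, cur_len)
  }
  if (is.null(best))
    stop("no restart produced a tree satisfying the constraint", call. = FALSE)
  list(tree = best, length = best_len)
}

# deterministic tie-break key: Newick with sorted ladderized labels
lexicographic_key <- function(tree) {
  tr <- ape::ladderize(ape::root(tree, outgroup = min(tree$tip.label),
                                 resolve.root = TRUE))
  ape::write.tree(tr)
}

#' Reverse-constraint partitioned Bremer support
#'
#' For each internal node of the focal tree, the best tree lacking that
#' node's bipartition is found on the combined matrix; each locus's value at
#' the node is its Fitch-length difference between that anti-constraint tree
#' and the focal tree. Per-locus values sum exactly to the node's overall
#' Bremer support.
#'
#' @param loci Named list of `character_matrix` objects (shared taxa).
#' @param focal The focal tree (e.g. the combined-matrix optimum).
#' @param search,seed,n_restarts Passed to [best_tree_under_constraint()].
#' @return An object of class `bremer_table`: list with `values` (node x
#'   locus integer matrix), `node_totals`, and `splits` (the node keys).
#' @export
partitioned_bremer <- function(loci, focal,
                               search = c("exhaustive", "nni_hillclimb"),
                               seed = 1, n_restarts = 5) {
  search <- match.arg(search)
  if (is.null(names(loci))) names(loci) <- sprintf("L%02d", seq_along(loci))
  loci <- lapply(loci, function(l)
    if (inherits(l, "character_matrix")) l else character_matrix(l))
  combined <- do.call(cbind, lapply(loci, function(l)
    l[rownames(loci[[1]]), , drop = FALSE]))
  class(combined) <- c("character_matrix", "matrix", "array")
  splits <- tree_bipartitions(focal)
  if (!length(splits)) stop("focal tree has no internal edges", call. = FALSE)
  focal_len <- vapply(loci, function(l) fitch_length(focal, l), integer(1))
  values <- matrix(NA_integer_, length(splits), length(loci),
                   dimnames = list(names(splits), names(loci)))
  for (s in seq_along(splits)) {
    anti <- tryCatch(
      best_tree_under_constraint(combined, splits[[s]], constraint = "forbid",
                                 search = search, seed = seed + s,
                                 n_restarts = n_restarts),
      error = function(e) NULL
    )
    if (is.null(anti)) next                     # node flagged by NA row
    values[s, ] <- vapply(loci, function(l) fitch_length(anti$tree, l),
                          integer(1)) - focal_len
  }
  structure(list(values = values, node_totals = rowSums(values),
                 splits = names(splits)), class = "bremer_table")
}

#' Per-locus and per-node Bremer summary statistics
#'
#' For each locus: number of nodes with positive values (supporting), number
#' with negative values (conflicting), their difference, and the sum of all
#' its values; the same four statistics per node over loci. The per-node sum
#' equals that node's overall Bremer support.
#'
#' @param table A `bremer_table`.
#' @return List of two data frames, `per_locus` and `per_node`.
#' @export
summarize_support <- function(table) {
  v <- table$values
  v <- v[!apply(v, 1, anyNA), , drop = FALSE]
  per_locus <- data.frame(
    locus = colnames(v),
    n_positive = colSums(v > 0), n_negative = colSums(v < 0),
    diff = colSums(v > 0) - colSums(v < 0), sum = colSums(v),
    row.names = NULL, stringsAsFactors = FALSE
  )
  per_node <- data.frame(
    node = rownames(v),
    n_positive = rowSums(v > 0), n_negative = rowSums(v < 0),
    diff = rowSums(v > 0) - rowSums(v < 0), sum = rowSums(v),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(per_locus = per_locus, per_node = per_node)
}
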