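# Shared fixture builders. Everything is generated in code under fixed seeds.

# random binary tree with branch lengths and unique labels
random_tree <- function(n, rooted = TRUE) {
  tr <- ape::rtree(n, rooted = rooted, tip.label = sprintf("t%02d", 1:n))
  tr
}

# a small alignment as locus_alignment from a named character vector
aln <- function(...) locus_alignment(c(...))

# same unrooted split sets?
same_splits <- function(a, b) {
  setequal(names(tree_bipartitions(a)), names(tree_bipartitions(b)))
}

# brute-force minimum parsimony length: enumerate all internal-node state
# assignments (states 1, 2, 4, 8) per site
brute_force_parsimony <- function(tree, cm) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  edge <- tree$edge
  tipstates <- cm[tree$tip.label, , drop = FALSE]
  total <- 0L
  for (site in seq_len(ncol(cm))) {
    combos <- as.matrix(expand.grid(rep(list(c(1L, 2L, 4L, 8L)), nnode)))
    best <- Inf
    for (r in seq_len(nrow(combos))) {
      assign <- combos[r, ]
      state_of <- function(v) {
        if (v <= ntip) tipstates[v, site] else assign[v - ntip]
      }
      ch <- 0L
      for (e in seq_len(nrow(edge))) {
        a <- state_of(edge[e, 1L]); b <- state_of(edge[e, 2L])
        if (bitwAnd(a, b) == 0L) ch <- ch + 1L
      }
      best <- min(best, ch)
    }
    total <- total + best
  }
  total
}

# independent quartet-topology oracle: prune to the 4 taxa and compare
# the cherry structure
quartet_topology_oracle <- function(tree, q) {
  if (!all(q %in% tree$tip.label)) return(NA_integer_)
  sub <- ape::unroot(prune_to_taxa(tree, q))
  sp <- tree_bipartitions(sub)
  if (!length(sp)) return(0L)
  side <- sp[[1]]
  pair <- sort(match(side, q))
  if (all(pair == c(1, 2)) || all(pair == c(3, 4))) return(1L)
  if (all(pair == c(1, 3)) || all(pair == c(2, 4))) return(2L)
  3L
}
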