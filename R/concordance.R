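# Per-locus concordance and clock metrics, "gene shopping" stratification,
# quartet concordance against the species tree, and dating-set export.

#' Proportion of gene-tree bipartitions shared with the species tree
#'
#' Both trees are restricted to their shared taxa before comparison. The
#' denominator is the gene tree's split count by default (the per-gene-tree
#' reading under which the retention threshold is applied), optionally the
#' species tree's.
#'
#' @param gene_tree,species_tree `phylo` objects with >= 4 shared taxa.
#' @param denominator `"gene"` (default) or `"species"`.
#' @return A proportion in `[0, 1]`.
#' @export
shared_bipartition_proportion <- function(gene_tree, species_tree,
                                          denominator = c("gene", "species")) {
  denominator <- match.arg(denominator)
  shared <- intersect(gene_tree$tip.label, species_tree$tip.label)
  if (length(shared) < 4L)
    stop("fewer than 4 shared taxa between gene and species tree",
         call. = FALSE)
  g <- prune_to_taxa(gene_tree, shared)
  s <- prune_to_taxa(species_tree, shared)
  gs <- names(tree_bipartitions(g))
  ss <- names(tree_bipartitions(s))
  denom <- if (denominator == "gene") length(gs) else length(ss)
  if (denom == 0L) return(NA_real_)
  length(intersect(gs, ss)) / denom
}

#' Root-to-tip variance of a rooted tree
#'
#' Sample variance (`n - 1` denominator) of the root-to-leaf path lengths; a
#' clock-likeness proxy that is 0 for ultrametric trees.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @return A nonnegative number.
#' @export
root_to_tip_variance <- function(tree) {
  if (!ape::is.rooted(tree))
    stop("tree must be rooted (root it on an outgroup first)", call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  var(depths)
}

#' Total tree length
#'
#' @param tree A `phylo` with branch lengths.
#' @return Sum of all branch lengths.
#' @export
tree_length <- function(tree) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree has missing branch lengths", call. = FALSE)
  sum(tree$edge.length)
}

#' Per-locus concordance and clock metrics
#'
#' @param gene_trees Named list of rooted gene trees (names = locus ids).
#' @param species_tree Rooted species tree.
#' @param denominator Passed to [shared_bipartition_proportion()].
#' @return A data frame with columns `locus`, `bipartition_proportion`,
#'   `root_to_tip_variance`, `tree_length`.
#' @export
locus_metrics <- function(gene_trees, species_tree,
                          denominator = c("gene", "species")) {
  denominator <- match.arg(denominator)
  if (is.null(names(gene_trees)))
    names(gene_trees) <- sprintf("L%03d", seq_along(gene_trees))
  data.frame(
    locus = names(gene_trees),
    bipartition_proportion = vapply(gene_trees, shared_bipartition_proportion,
                                    numeric(1), species_tree = species_tree,
                                    denominator = denominator),
    root_to_tip_variance = vapply(gene_trees, root_to_tip_variance, numeric(1)),
    tree_length = vapply(gene_trees, tree_length, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' "Gene shopping": filter by concordance, stratify by rate variance
#'
#' Loci whose shared-bipartition proportion is at least `min_bipartition` are
#' retained (the rule is `>=`), sorted by ascending root-to-tip variance
#' (ties by descending tree length, then locus id), and split into `n_sets`
#' contiguous rank-based groups; when divisible the groups are equal-sized and
#' otherwise differ by at most one (earlier sets take the remainder). `set1`
#' holds the lowest variances.
#'
#' @param metrics Data frame from [locus_metrics()].
#' @param min_bipartition Retention threshold (default 0.3).
#' @param n_sets Number of variance strata (default 3, i.e. terciles).
#' @return `metrics` with a `set_label` column (`set1`..`setN` or
#'   `excluded`), ordered as sorted; attribute `"manifest"` lists locus ids
#'   per set in concatenation order.
#' @export
gene_shop <- function(metrics, min_bipartition = 0.3, n_sets = 3) {
  stopifnot(all(c("locus", "bipartition_proportion", "root_to_tip_variance",
                  "tree_length") %in% names(metrics)))
  if (anyNA(metrics)) stop("metrics contain missing values", call. = FALSE)
  keep <- metrics$bipartition_proportion >= min_bipartition
  retained <- metrics[keep, , drop = FALSE]
  n <- nrow(retained)
  if (n < n_sets)
    stop("only ", n, " loci retained; need at least n_sets = ", n_sets,
         call. = FALSE)
  ord <- order(retained$root_to_tip_variance, -retained$tree_length,
               retained$locus)
  retained <- retained[ord, , drop = FALSE]
  sizes <- rep(n %/% n_sets, n_sets) + (seq_len(n_sets) <= n %% n_sets)
  retained$set_label <- rep(paste0("set", seq_len(n_sets)), sizes)
  excluded <- metrics[!keep, , drop = FALSE]
  if (nrow(excluded)) excluded$set_label <- "excluded"
  out <- rbind(retained, excluded)
  rownames(out) <- NULL
  attr(out, "manifest") <- split(retained$locus, retained$set_label)
  out
}

#' Most clock-like loci
#'
#' @param metrics Data frame with `locus` and `root_to_tip_variance`.
#' @param k How many loci (default 5).
#' @return Character vector of the `k` locus ids with the smallest
#'   root-to-tip variance (ties broken by id).
#' @export
lowest_variance_subset <- function(metrics, k = 5) {
  if (k > nrow(metrics))
    stop("k = ", k, " exceeds available loci (", nrow(metrics), ")",
         call. = FALSE)
  ord <- order(metrics$root_to_tip_variance, metrics$locus)
  metrics$locus[ord][seq_len(k)]
}

# --- quartet concordance -----------------------------------------------------

# split membership matrix: rows = nontrivial splits, columns = all taxa in
# `taxa`; NA for taxa absent from the tree
split_matrix <- function(tree, taxa) {
  sp <- tree_bipartitions(tree)
  m <- matrix(NA, length(sp), length(taxa), dimnames = list(NULL, taxa))
  present <- intersect(taxa, tree$tip.label)
  for (i in seq_along(sp)) {
    m[i, present] <- present %in% sp[[i]]
  }
  attr(m, "present") <- present
  m
}

# resolution of quartet (4 taxon names) in a tree's split matrix:
# 1 = q1q2|q3q4, 2 = q1q3|q2q4, 3 = q1q4|q2q3, 0 = unresolved, NA = missing
quartet_resolution <- function(sm, q) {
  present <- attr(sm, "present")
  if (!is.null(present) && !all(q %in% present)) return(NA_integer_)
  sub <- sm[, q, drop = FALSE]
  if (nrow(sub) && anyNA(sub[, 1])) return(NA_integer_)
  if (!nrow(sub)) return(0L)
  if (anyNA(sub)) return(NA_integer_)
  hit <- which(rowSums(sub) == 2L)
  if (!length(hit)) return(0L)
  r <- sub[hit[1], ]
  if (r[1] == r[2]) 1L else if (r[1] == r[3]) 2L else 3L
}

#' Quartet concordance between gene trees and a species tree
#'
#' The normalized score is the fraction of (quartet, gene tree) pairs, over
#' quartets resolved in the gene tree and with all four taxa present, that
#' match the species-tree resolution. Per-branch support draws quartets with
#' one leaf from each of the four subtrees adjacent to a species-tree internal
#' branch and reports the % matching that branch's resolution.
#'
#' @param species_tree Rooted binary species tree.
#' @param gene_trees List of gene trees (may miss taxa).
#' @param mode `"exhaustive"` (all quartets; feasible to ~25 taxa) or
#'   `"sampled"`.
#' @param n_samples_per_branch Quartets drawn per branch in sampled mode.
#' @param seed RNG seed for sampled mode.
#' @return A list with `score` (NA with `undefined = TRUE` when no quartet is
#'   resolved), `n_resolved`, `n_concordant`, and `branch_support`, a data
#'   frame of per-branch % concordant quartets keyed by the branch's split.
#' @export
quartet_scores <- function(species_tree, gene_trees,
                           mode = c("exhaustive", "sampled"),
                           n_samples_per_branch = 1000, seed = NULL) {
  mode <- match.arg(mode)
  if (mode == "sampled") {
    if (n_samples_per_branch <= 0)
      stop("n_samples_per_branch must be positive", call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
  }
  taxa <- sort(species_tree$tip.label)
  ssm <- split_matrix(species_tree, taxa)
  gsm <- lapply(gene_trees, split_matrix, taxa = taxa)

  quartets <- combn(taxa, 4, simplify = FALSE)
  sres <- vapply(quartets, function(q) quartet_resolution(ssm, q), integer(1))
  n_res <- 0L; n_con <- 0L
  for (sm in gsm) {
    for (i in seq_along(quartets)) {
      if (sres[i] %in% c(0L, NA_integer_)) next
      r <- quartet_resolution(sm, quartets[[i]])
      if (is.na(r) || r == 0L) next
      n_res <- n_res + 1L
      if (r == sres[i]) n_con <- n_con + 1L
    }
  }
  score <- if (n_res == 0L) NA_real_ else n_con / n_res

  bs <- branch_quartet_support(species_tree, gsm, mode, n_samples_per_branch)
  list(score = score, undefined = n_res == 0L,
       n_resolved = n_res, n_concordant = n_con, branch_support = bs)
}

# per-branch % concordant quartets, one leaf per adjacent subtree
branch_quartet_support <- function(species_tree, gsm, mode, n_samples) {
  tr <- species_tree
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  tipsets <- tips_below(tr)
  all_taxa <- tr$tip.label
  kids <- split(tr$edge[, 2L], tr$edge[, 1L])
  out <- list()
  seen <- character()
  for (e in seq_len(nrow(tr$edge))) {
    v <- tr$edge[e, 2L]; p <- tr$edge[e, 1L]
    if (v <= ntip) next
    ch <- kids[[as.character(v)]]
    if (length(ch) != 2L) next
    A <- all_taxa[tipsets[[ch[1]]]]
    B <- all_taxa[tipsets[[ch[2]]]]
    if (p == root && length(kids[[as.character(root)]]) == 2L) {
      sib <- setdiff(kids[[as.character(root)]], v)
      if (sib <= ntip) next                       # trivial split
      sch <- kids[[as.character(sib)]]
      if (length(sch) != 2L) next
      C <- all_taxa[tipsets[[sch[1]]]]
      D <- all_taxa[tipsets[[sch[2]]]]
    } else {
      C <- setdiff(all_taxa[tipsets[[p]]], all_taxa[tipsets[[v]]])
      D <- setdiff(all_taxa, all_taxa[tipsets[[p]]])
    }
    if (!length(C) || !length(D)) next
    side <- sort(c(A, B))
    key <- paste(side, collapse = "|")
    if (key %in% seen) next
    seen <- c(key, seen)
    combos <- if (mode == "exhaustive") {
      expand.grid(a = A, b = B, c = C, d = D, stringsAsFactors = FALSE)
    } else {
      data.frame(a = sample(A, n_samples, TRUE), b = sample(B, n_samples, TRUE),
                 c = sample(C, n_samples, TRUE), d = sample(D, n_samples, TRUE),
                 stringsAsFactors = FALSE)
    }
    nr <- 0L; nc <- 0L
    for (sm in gsm) {
      for (i in seq_len(nrow(combos))) {
        q <- as.character(combos[i, ])
        r <- quartet_resolution(sm, q)
        if (is.na(r) || r == 0L) next
        nr <- nr + 1L
        if (r == 1L) nc <- nc + 1L   # species resolution is ab|cd by design
      }
    }
    out[[key]] <- data.frame(split = key,
                             support_pct = if (nr) 100 * nc / nr else NA_real_,
                             n_resolved = nr, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(split = character(), support_pct = numeric(),
                      n_resolved = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# integer tip indices below each node
tips_below <- function(tree) {
  ntip <- length(tree$tip.label)
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(po)))
    below[[po[i, 1L]]] <- c(below[[po[i, 1L]]], below[[po[i, 2L]]])
  below
}

# --- dating-set export -------------------------------------------------------

#' Concatenate locus alignments into dating supermatrices
#'
#' Builds one supermatrix per manifest set plus a combined supermatrix whose
#' partition table has one 1-based inclusive column range per set. Taxa absent
#' from a locus are padded with gaps.
#'
#' @param alignments Named list of `locus_alignment`s (names = locus ids).
#' @param manifest Named list of character vectors of locus ids (set order =
#'   concatenation order), e.g. `attr(gene_shop(...), "manifest")`.
#' @return A list with `per_set` (named list of `locus_alignment`),
#'   `combined` (one `locus_alignment`), and `partitions` (data frame `set`,
#'   `start`, `end`).
#' @export
build_dating_sets <- function(alignments, manifest) {
  all_loci <- unlist(manifest, use.names = FALSE)
  missing <- setdiff(all_loci, names(alignments))
  if (length(missing))
    stop("manifest loci without alignments: ", paste(missing, collapse = ", "),
         call. = FALSE)
  taxa <- sort(unique(unlist(lapply(alignments[all_loci], rownames))))
  pad <- function(aln) {
    m <- unclass(aln); attr(m, "mask") <- NULL
    out <- matrix("-", length(taxa), ncol(m), dimnames = list(taxa, NULL))
    out[rownames(m), ] <- m
    out
  }
  per_set <- lapply(manifest, function(loci) {
    locus_alignment(do.call(cbind, lapply(alignments[loci], pad)))
  })
  widths <- vapply(per_set, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  combined <- locus_alignment(do.call(cbind, lapply(per_set, unclass)))
  list(per_set = per_set, combined = combined,
       partitions = data.frame(set = names(manifest), start = starts,
                               end = ends, row.names = NULL,
                               stringsAsFactors = FALSE))
}

#' Write a supermatrix and its partition table
#'
#' Writes relaxed PHYLIP and NEXUS (with a `sets` block) versions of the
#' combined supermatrix and a RAxML-style partition file
#' (`DNA, setN = a-b`).
#'
#' @param sets Result of [build_dating_sets()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the written file paths.
#' @export
write_dating_sets <- function(sets, dir, prefix = "dating") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  comb <- unclass(sets$combined); attr(comb, "mask") <- NULL
  paths <- character()
  # relaxed PHYLIP
  phy <- file.path(dir, paste0(prefix, "_concat.phy"))
  con <- file(phy, "w")
  writeLines(paste(nrow(comb), ncol(comb)), con)
  for (i in seq_len(nrow(comb)))
    writeLines(paste(rownames(comb)[i], paste(comb[i, ], collapse = "")), con)
  close(con)
  paths <- c(paths, phy)
  # NEXUS with sets block
  nex <- file.path(dir, paste0(prefix, "_concat.nex"))
  con <- file(nex, "w")
  writeLines(c("#NEXUS", "BEGIN DATA;",
               sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(comb), ncol(comb)),
               "  FORMAT DATATYPE=DNA MISSING=N GAP=-;", "  MATRIX"), con)
  for (i in seq_len(nrow(comb)))
    writeLines(sprintf("  %s  %s", rownames(comb)[i],
                       paste(comb[i, ], collapse = "")), con)
  writeLines(c("  ;", "END;", "BEGIN SETS;"), con)
  for (i in seq_len(nrow(sets$partitions)))
    writeLines(sprintf("  CHARSET %s = %d-%d;", sets$partitions$set[i],
                       sets$partitions$start[i], sets$partitions$end[i]), con)
  writeLines("END;", con)
  close(con)
  paths <- c(paths, nex)
  # RAxML-style partition file
  part <- file.path(dir, paste0(prefix, "_partitions.txt"))
  writeLines(sprintf("DNA, %s = %d-%d", sets$partitions$set,
                     sets$partitions$start, sets$partitions$end), part)
  paths <- c(paths, part)
  # per-set FASTA
  for (s in names(sets$per_set)) {
    p <- file.path(dir, paste0(prefix, "_", s, ".fasta"))
    write_fasta_alignment(sets$per_set[[s]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
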