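# Triplet enumeration and extraction of the triplet internal branch length t
# from gene trees rooted on a fixed outgroup. For a rooted tree the triplet
# topology is read off pairwise MRCA depths: the cherry is the pair whose MRCA
# differs from the MRCA of all three taxa, and t is the depth difference
# between the two coalescences.

#' Enumerate species triplets
#'
#' All unordered triples of the supplied (ingroup) taxa in deterministic
#' lexicographic order. The designated outgroup must be excluded beforehand.
#'
#' @param taxa Character vector of at least 3 ingroup taxa.
#' @return A list of sorted character triples; `C(n, 3)` of them.
#' @export
enumerate_triplets <- function(taxa) {
  taxa <- sort(unique(taxa))
  if (length(taxa) < 3L) stop("need at least 3 taxa", call. = FALSE)
  combn(taxa, 3, simplify = FALSE)
}

# topology + internal branch of one triplet on a rooted tree, given the
# pairwise MRCA node matrix and root-to-node depths.
# Returns list(odd = odd taxon name or NA, t = length) or status string.
triplet_from_depths <- function(trip, mrca_mat, depths) {
  m_ab <- mrca_mat[trip[1], trip[2]]
  m_ac <- mrca_mat[trip[1], trip[3]]
  m_bc <- mrca_mat[trip[2], trip[3]]
  ms <- c(m_ab, m_ac, m_bc)
  if (m_ab == m_ac && m_ab == m_bc) return("unresolved")
  # in a tree two of the three pairwise MRCAs coincide: that node is the
  # triplet MRCA; the remaining pair is the cherry
  if (m_ab == m_ac) { cherry <- 3L; anc <- m_ab }
  else if (m_ab == m_bc) { cherry <- 2L; anc <- m_ab }
  else { cherry <- 1L; anc <- m_ac }
  odd <- trip[c(3L, 2L, 1L)][cherry]       # taxon not in the cherry
  t <- depths[ms[cherry]] - depths[anc]
  list(odd = odd, t = t)
}

#' Extract one triplet observation from a gene tree
#'
#' The gene tree is rooted on `outgroup`; the two ingroup taxa forming a
#' cherry define the topology (named by the odd taxon out) and `t` is the
#' length of the internal edge separating the cherry from the third taxon on
#' the pruned 4-taxon tree (suppressed-node path sum).
#'
#' @param gene_tree A `phylo`.
#' @param triplet Character vector of 3 ingroup taxa.
#' @param outgroup Single outgroup taxon (not among the triplet).
#' @return A list `(triplet, odd, t)`, or the string `"missing"` (taxa
#'   absent) / `"unresolved"` (polytomy at the relevant node).
#' @export
extract_triplet <- function(gene_tree, triplet, outgroup) {
  stopifnot(length(triplet) == 3L, length(outgroup) == 1L)
  if (outgroup %in% triplet)
    stop("outgroup cannot be part of the triplet", call. = FALSE)
  if (!all(c(triplet, outgroup) %in% gene_tree$tip.label)) return("missing")
  sub <- prune_to_taxa(gene_tree, c(triplet, outgroup))
  sub <- root_at_outgroup(sub, outgroup)
  mm <- ape::mrca(sub)
  depths <- ape::node.depth.edgelength(sub)
  res <- triplet_from_depths(sort(triplet), mm, depths)
  if (is.character(res)) return(res)
  list(triplet = sort(triplet), odd = res$odd, t = res$t)
}

#' Tabulate triplet topologies and internal branch lengths over gene trees
#'
#' Gene trees missing the outgroup are skipped entirely; per triplet, trees
#' missing a taxon or unresolved at the triplet node go into the skipped
#' tally, so `n1 + n2 + n3 + skipped` equals the number of gene trees for
#' every triplet.
#'
#' @param gene_trees List of `phylo` objects sharing a taxon namespace.
#' @param triplets List of taxon triples from [enumerate_triplets()].
#' @param outgroup Single outgroup taxon used to root every tree.
#' @return A list with `observations` (long data frame: `locus`, `taxon1..3`,
#'   `odd_taxon`, `t`) and `summary` (per triplet: topology counts and
#'   skipped tally).
#' @export
tabulate_triplets <- function(gene_trees, triplets, outgroup) {
  if (!length(gene_trees)) stop("empty gene tree list", call. = FALSE)
  if (is.null(names(gene_trees)))
    names(gene_trees) <- sprintf("L%03d", seq_along(gene_trees))
  trip_mat <- do.call(rbind, lapply(triplets, sort))
  n_trip <- nrow(trip_mat)
  obs <- vector("list", length(gene_trees))
  skipped <- integer(n_trip)

  for (g in seq_along(gene_trees)) {
    tr <- gene_trees[[g]]
    if (!(outgroup %in% tr$tip.label)) {
      skipped <- skipped + 1L
      next
    }
    tr <- root_at_outgroup(tr, outgroup)
    mm <- ape::mrca(tr)
    depths <- ape::node.depth.edgelength(tr)
    labs <- tr$tip.label
    present <- matrix(trip_mat %in% labs, n_trip)
    ok <- rowSums(present) == 3L
    odd <- rep(NA_character_, n_trip)
    tval <- rep(NA_real_, n_trip)
    if (any(ok)) {
      idx <- matrix(match(trip_mat[ok, , drop = FALSE], labs), sum(ok))
      m_ab <- mm[cbind(idx[, 1], idx[, 2])]
      m_ac <- mm[cbind(idx[, 1], idx[, 3])]
      m_bc <- mm[cbind(idx[, 2], idx[, 3])]
      poly <- m_ab == m_ac & m_ab == m_bc
      cherry <- ifelse(m_ab == m_ac, 3L, ifelse(m_ab == m_bc, 2L, 1L))
      sub <- trip_mat[ok, , drop = FALSE]
      oddk <- sub[cbind(seq_len(nrow(sub)), c(3L, 2L, 1L)[cherry])]
      deep <- cbind(m_ab, m_ac, m_bc)[cbind(seq_along(cherry), cherry)]
      anc <- ifelse(cherry == 1L, m_ac, m_ab)
      tv <- depths[deep] - depths[anc]
      oddk[poly] <- NA_character_
      tv[poly] <- NA_real_
      odd[ok] <- oddk
      tval[ok] <- tv
    }
    skipped <- skipped + as.integer(is.na(odd))
    keep <- !is.na(odd)
    if (any(keep)) {
      obs[[g]] <- data.frame(
        locus = names(gene_trees)[g],
        taxon1 = trip_mat[keep, 1], taxon2 = trip_mat[keep, 2],
        taxon3 = trip_mat[keep, 3],
        odd_taxon = odd[keep], t = tval[keep],
        stringsAsFactors = FALSE
      )
    }
  }
  observations <- do.call(rbind, obs)
  if (is.null(observations)) {
    observations <- data.frame(locus = character(), taxon1 = character(),
                               taxon2 = character(), taxon3 = character(),
                               odd_taxon = character(), t = numeric(),
                               stringsAsFactors = FALSE)
  }
  rownames(observations) <- NULL

  key_all <- paste(trip_mat[, 1], trip_mat[, 2], trip_mat[, 3], sep = "|")
  key_obs <- paste(observations$taxon1, observations$taxon2,
                   observations$taxon3, sep = "|")
  counts <- matrix(0L, n_trip, 3,
                   dimnames = list(key_all, c("n1", "n2", "n3")))
  if (nrow(observations)) {
    ki <- match(key_obs, key_all)
    top <- 1L + (observations$odd_taxon == observations$taxon2) +
      2L * (observations$odd_taxon == observations$taxon3)
    tab <- tabulate(ki + (top - 1L) * n_trip, nbins = 3L * n_trip)
    counts[] <- tab
  }
  summary <- data.frame(
    taxon1 = trip_mat[, 1], taxon2 = trip_mat[, 2], taxon3 = trip_mat[, 3],
    n1 = counts[, 1], n2 = counts[, 2], n3 = counts[, 3],
    skipped = skipped, row.names = NULL, stringsAsFactors = FALSE
  )
  list(observations = observations, summary = summary)
}
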