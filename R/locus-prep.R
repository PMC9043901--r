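# Orthology clustering and alignment clean-up: k-mer shared distance,
# neighbour-joining clusters, the >50%-of-species cluster filter, and the
# good-site / window-masking / sparse-column trimming rules.

#' Construct a locus alignment
#'
#' A locus alignment is a character matrix (rows = sequences, uppercase, `-`
#' for gaps) with a logical mask matrix of the same shape attached.
#'
#' @param x A character matrix of single characters, or a character vector of
#'   equal-length sequence strings named by sequence id.
#' @return An object of class `locus_alignment`.
#' @export
locus_alignment <- function(x) {
  if (is.character(x) && !is.matrix(x)) return(aln_from_strings(x))
  stopifnot(is.matrix(x), is.character(x))
  x[] <- toupper(x)
  if (is.null(attr(x, "mask"))) {
    attr(x, "mask") <- matrix(FALSE, nrow(x), ncol(x))
  }
  class(x) <- c("locus_alignment", class(x))
  x
}

# helper: build from named character vector of strings
aln_from_strings <- function(seqs) {
  stopifnot(!is.null(names(seqs)))
  n <- nchar(seqs)
  if (length(unique(n)) > 1L)
    stop("aligned sequences must have equal length", call. = FALSE)
  m <- matrix("", length(seqs), n[1], dimnames = list(names(seqs), NULL))
  for (i in seq_along(seqs)) m[i, ] <- strsplit(toupper(seqs[[i]]), "")[[1]]
  locus_alignment(m)
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat("locus alignment:", nrow(x), "sequences x", ncol(x), "columns;",
      sum(attr(x, "mask")), "masked residues\n")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Lowercase residues are read as masked (and uppercased in the matrix).
#'
#' @param path FASTA file path.
#' @return A `locus_alignment`.
#' @export
read_fasta_alignment <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path, call. = FALSE)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, "", collapse = "")
  names(seqs) <- ids
  aln <- aln_from_strings(seqs)
  # recover mask from case of the raw residues
  raw <- matrix("", length(seqs), nchar(seqs[[1]]))
  for (i in seq_along(seqs)) raw[i, ] <- strsplit(seqs[[i]], "")[[1]]
  attr(aln, "mask") <- matrix(raw %in% letters, nrow(raw), ncol(raw))
  aln
}

#' Write an aligned FASTA file (masked residues lowercase)
#'
#' @param aln A `locus_alignment`.
#' @param path Output path.
#' @param mask_as_n Write masked residues as `N` instead of lowercase.
#' @param width Line wrap width.
#' @export
write_fasta_alignment <- function(aln, path, mask_as_n = FALSE, width = 80) {
  mask <- attr(aln, "mask")
  m <- unclass(aln)
  attr(m, "mask") <- NULL
  if (mask_as_n) m[mask & m != "-"] <- "N"
  else m[mask] <- tolower(m[mask])
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(m))) {
    writeLines(paste0(">", rownames(m)[i]), con)
    s <- paste(m[i, ], collapse = "")
    starts <- seq(1, max(nchar(s), 1), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' k-mer shared distance between two sequences
#'
#' The distance is `1 - |shared k-mers| / min(|K(a)|, |K(b)|)` over distinct
#' k-mers; k-mers containing characters outside `A/C/G/T` (gaps, `N`,
#' ambiguity codes) are excluded. With the `"union"` denominator the Jaccard
#' form is used instead.
#'
#' @param a,b Sequence strings (or single-row character vectors).
#' @param k k-mer size (default 20).
#' @param denominator `"min"` (default: a short fragment of a long sequence
#'   scores as similar) or `"union"`.
#' @return A distance in `[0, 1]`.
#' @export
kmer_shared_distance <- function(a, b, k = 20, denominator = c("min", "union")) {
  denominator <- match.arg(denominator)
  ka <- kmer_set(a, k)
  kb <- kmer_set(b, k)
  if (!length(ka) || !length(kb))
    stop("sequence shorter than k (or no valid k-mers)", call. = FALSE)
  shared <- length(intersect(ka, kb))
  denom <- if (denominator == "min") min(length(ka), length(kb))
           else length(union(ka, kb))
  1 - shared / denom
}

kmer_set <- function(x, k) {
  stopifnot(k >= 1)
  x <- toupper(paste(x, collapse = ""))
  x <- gsub("-", "", x, fixed = TRUE)  # gaps never form k-mers
  n <- nchar(x)
  if (n < k) return(character())
  mers <- substring(x, 1:(n - k + 1), k:n)
  unique(mers[grepl(sprintf("^[ACGT]{%d}$", k), mers)])
}

#' Pairwise k-mer distance matrix
#'
#' @param seqs Named character vector of sequences.
#' @inheritParams kmer_shared_distance
#' @return A symmetric matrix with zero diagonal.
#' @export
kmer_distance_matrix <- function(seqs, k = 20, denominator = c("min", "union")) {
  denominator <- match.arg(denominator)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  sets <- lapply(seqs, kmer_set, k = k)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    si <- sets[[i]]; sj <- sets[[j]]
    if (!length(si) || !length(sj))
      stop("sequence shorter than k: ", names(seqs)[if (!length(si)) i else j],
           call. = FALSE)
    shared <- length(intersect(si, sj))
    denom <- if (denominator == "min") min(length(si), length(sj))
             else length(union(si, sj))
    d[i, j] <- d[j, i] <- 1 - shared / denom
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' @param d Symmetric distance matrix with row/column names.
#' @return An unrooted `phylo`; additive input distances are reproduced
#'   exactly as patristic distances.
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d))
  if (nrow(d) < 3L) stop("need at least 3 sequences for NJ", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix not symmetric",
                                       call. = FALSE)
  ape::nj(as.dist(d))
}

#' Read clusters off an NJ tree by cutting long edges
#'
#' Removes every edge longer than `cut_length` and returns the tip sets of the
#' resulting connected components.
#'
#' @param tree A `phylo` with branch lengths.
#' @param cut_length Edges strictly longer than this are cut (`Inf` keeps a
#'   single cluster; `0` on all-positive edges isolates every tip).
#' @return A list of character vectors (cluster members).
#' @export
clusters_from_nj <- function(tree, cut_length) {
  if (cut_length < 0) stop("cut_length must be nonnegative", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths",
                                      call. = FALSE)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  keep <- tree$edge.length <= cut_length
  # union-find over nodes connected by retained edges
  parent <- seq_len(nnode)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (e in which(keep)) {
    a <- find(tree$edge[e, 1L]); b <- find(tree$edge[e, 2L])
    if (a != b) parent[a] <- b
  }
  comp <- vapply(seq_len(ntip), find, integer(1))
  unname(split(tree$tip.label, comp))
}

#' Filter clusters by species coverage
#'
#' Keeps clusters covering strictly more than `min_fraction` of the target
#' species (the rule is `>`, so exactly 50% of the species is dropped at the
#' default).
#'
#' @param clusters List of character vectors of sequence ids.
#' @param id_to_species Named character vector mapping sequence id to species.
#' @param n_target_species Number of species targeted.
#' @param min_fraction Coverage threshold (default 0.5).
#' @return The retained subset of `clusters`.
#' @export
filter_clusters <- function(clusters, id_to_species, n_target_species,
                            min_fraction = 0.5) {
  if (n_target_species <= 0) stop("n_target_species must be positive",
                                  call. = FALSE)
  keep <- vapply(clusters, function(cl) {
    sp <- unique(id_to_species[cl])
    length(sp[!is.na(sp)]) / n_target_species > min_fraction
  }, logical(1))
  clusters[keep]
}

#' Flag "good" alignment columns
#'
#' A column is good when its most prevalent non-gap, non-`N` state is shared
#' by strictly more than half of ALL rows (gaps count in the denominator but
#' never as the modal state).
#'
#' @param aln A `locus_alignment`.
#' @return Logical vector, one flag per column.
#' @export
mark_good_sites <- function(aln) {
  stopifnot(nrow(aln) > 0)
  n <- nrow(aln)
  apply(unclass(aln), 2, function(col) {
    col <- col[!(col %in% c("-", "N", "?"))]
    if (!length(col)) return(FALSE)
    max(table(col)) > n / 2
  })
}

#' Mask low-quality sequence regions
#'
#' For each sequence, windows of `window` consecutive non-gap positions are
#' slid along the sequence; every residue covered by at least one window
#' containing fewer than `min_good` good columns is mask-flagged. Masking
#' twice with the same good vector is a no-op.
#'
#' @param aln A `locus_alignment`.
#' @param good Logical per-column good flags from [mark_good_sites()]
#'   (computed once, from the unmasked alignment).
#' @param window Window length in residues (default 20).
#' @param min_good Minimum good columns a window must contain (default 15).
#' @return The alignment with updated mask flags.
#' @export
mask_low_quality_regions <- function(aln, good, window = 20, min_good = 15) {
  if (window <= 0) stop("window must be positive", call. = FALSE)
  stopifnot(length(good) == ncol(aln))
  mask <- attr(aln, "mask")
  m <- unclass(aln)
  for (i in seq_len(nrow(m))) {
    pos <- which(m[i, ] != "-")        # this sequence's residue coordinates
    np <- length(pos)
    if (np < window) next
    g <- as.integer(good[pos])
    cs <- c(0L, cumsum(g))
    starts <- 1:(np - window + 1)
    bad <- (cs[starts + window] - cs[starts]) < min_good
    if (!any(bad)) next
    covered <- logical(np)
    for (s in starts[bad]) covered[s:(s + window - 1)] <- TRUE
    mask[i, pos[covered]] <- TRUE
  }
  attr(aln, "mask") <- mask
  aln
}

#' Trim sparse alignment columns
#'
#' Columns with fewer than `min_unmasked` unmasked, non-gap residues are
#' removed; row order is preserved and the operation is idempotent.
#'
#' @param aln A `locus_alignment` with mask flags set (possibly none).
#' @param min_unmasked Minimum unmasked bases per retained column (default 56).
#' @return The trimmed alignment.
#' @export
trim_sparse_sites <- function(aln, min_unmasked = 56) {
  mask <- attr(aln, "mask")
  m <- unclass(aln)
  n_unmasked <- colSums(!mask & m != "-" & m != "N")
  keep <- n_unmasked >= min_unmasked
  out <- m[, keep, drop = FALSE]
  attr(out, "mask") <- mask[, keep, drop = FALSE]
  class(out) <- c("locus_alignment", "matrix", "array")
  out
}
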