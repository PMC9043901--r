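# Ground-truth generators: mixture-distributed branch lengths, multispecies
# coalescent gene trees (with optional introgression pulses), molecular-rate
# heterogeneity, and sequences evolved on the resulting trees.

#' Draw internal branch lengths from the two-component mixture
#'
#' With probability `pi` a draw is `Exp(mean = lambda)` (the ILS component),
#' otherwise `c + Exp(mean = lambda)` (the non-ILS component).
#'
#' @param n Number of draws.
#' @param pi ILS mixing weight in `[0, 1]`.
#' @param lambda Exponential mean (> 0).
#' @param c Shift of the non-ILS component (>= 0).
#' @param seed RNG seed.
#' @return Numeric vector of `n` nonnegative lengths.
#' @export
sample_mixture_lengths <- function(n, pi, lambda, c, seed = NULL) {
  if (n <= 0 || pi < 0 || pi > 1 || lambda <= 0 || c < 0)
    stop("invalid mixture parameters", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ils <- runif(n) < pi
  rexp(n, rate = 1 / lambda) + ifelse(ils, 0, c)
}

#' Species-tree model for coalescent simulation
#'
#' @param tree Rooted ultrametric `phylo` with branch lengths in coalescent
#'   units (2N generations).
#' @param events List of introgression pulses, each a list with `donor` and
#'   `recipient` (a tip name, or a vector of tips naming the branch above
#'   their MRCA), `time` (before present, within both branches), and `gamma`
#'   in `[0, 1]` (per-lineage probability that a recipient lineage traces
#'   back into the donor population at the pulse).
#' @return An object of class `species_tree_model`.
#' @export
species_tree_model <- function(tree, events = list()) {
  stopifnot(inherits(tree, "phylo"), ape::is.rooted(tree))
  depths <- ape::node.depth.edgelength(tree)
  height <- max(depths)
  age <- height - depths            # node times before present
  ntip <- length(tree$tip.label)
  branch_of <- function(taxa_sel) {
    tips <- match(taxa_sel, tree$tip.label)
    if (anyNA(tips)) stop("unknown taxa in event: ",
                          paste(taxa_sel[is.na(tips)], collapse = ", "),
                          call. = FALSE)
    node <- if (length(tips) == 1L) tips else ape::getMRCA(tree, tips)
    node
  }
  events <- lapply(events, function(ev) {
    stopifnot(!is.null(ev$donor), !is.null(ev$recipient),
              is.numeric(ev$time), is.numeric(ev$gamma))
    if (ev$gamma < 0 || ev$gamma > 1)
      stop("gamma must be in [0, 1]", call. = FALSE)
    ev$donor_node <- branch_of(ev$donor)
    ev$recipient_node <- branch_of(ev$recipient)
    for (nd in c(ev$donor_node, ev$recipient_node)) {
      if (nd == ntip + 1L) stop("root has no parent branch", call. = FALSE)
      lo <- age[nd]
      hi <- age[tree$edge[tree$edge[, 2L] == nd, 1L]]
      if (ev$time < lo || ev$time > hi)
        stop("event time ", ev$time, " outside branch interval [",
             round(lo, 4), ", ", round(hi, 4), "]", call. = FALSE)
    }
    ev
  })
  structure(list(tree = tree, events = events, age = age),
            class = "species_tree_model")
}

#' Simulate gene trees under the multispecies coalescent
#'
#' One haploid sample per species; lineages coalesce within species-tree
#' branches at rate `k(k-1)/2` (censored at each branch's top) and introgression
#' pulses move each recipient-branch lineage to the donor branch with
#' probability `gamma` at the event time. Branch lengths of the returned gene
#' trees are in coalescent units. With `gamma = 0` everywhere the event
#' machinery is a no-op.
#'
#' @param model A `species_tree_model`.
#' @param n_loci Number of gene trees.
#' @param seed RNG seed.
#' @return A `multiPhylo` list of rooted gene trees over all species.
#' @export
simulate_msc <- function(model, n_loci, seed = NULL) {
  stopifnot(inherits(model, "species_tree_model"), n_loci >= 1)
  if (!is.null(seed)) set.seed(seed)
  tree <- model$tree
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  age <- model$age
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]

  # timeline: population-merger times (internal node ages) + pulses.
  # Mergers sharing a time (zero-length internal branches) must be applied
  # child-before-parent; a postorder rank provides that ordering.
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  po_edge <- ape::reorder.phylo(tree, "postorder")$edge
  po_rank <- match(internal, po_edge[, 2L])       # NA for the root -> last
  po_rank[is.na(po_rank)] <- nrow(po_edge) + 1L
  mergers <- data.frame(time = age[internal], node = internal,
                        rank = po_rank)
  mergers <- mergers[order(mergers$time, mergers$rank), ]
  # gamma = 0 pulses are dropped before simulation so the event machinery is
  # an exact no-op (same RNG stream, bitwise-identical trees)
  pulses <- Filter(function(ev) ev$gamma > 0, model$events)
  ev_times <- sort(unique(c(mergers$time,
                            vapply(pulses, `[[`, numeric(1), "time"))))

  sim_locus <- function() {
    pop <- seq_len(ntip)          # branch (node id) holding each lineage
    nwk <- tree$tip.label
    top <- rep(0, ntip)
    alive <- rep(TRUE, ntip)
    pop_time <- rep(0, ntip + tree$Nnode)

    run_pop <- function(p, t_end) {
      repeat {
        members <- which(alive & pop == p)
        k <- length(members)
        if (k < 2L) {
          if (is.finite(t_end)) pop_time[p] <<- t_end
          return(invisible())
        }
        wait <- rexp(1, rate = k * (k - 1) / 2)
        tc <- pop_time[p] + wait
        if (tc > t_end) {
          pop_time[p] <<- t_end
          return(invisible())
        }
        pop_time[p] <<- tc
        pair <- if (k == 2L) members else sample(members, 2L)
        i <- pair[1]; j <- pair[2]
        nwk[i] <<- paste0("(", nwk[i], ":", format(tc - top[i], digits = 10),
                          ",", nwk[j], ":", format(tc - top[j], digits = 10),
                          ")")
        top[i] <<- tc
        alive[j] <<- FALSE
      }
    }

    t_prev <- 0
    for (te in c(ev_times, Inf)) {
      for (p in unique(pop[alive])) {
        pop_time[p] <- max(pop_time[p], t_prev)
        run_pop(p, te)
      }
      if (!is.finite(te)) break
      # pulses fire before mergers at the same instant
      for (ev in pulses) {
        if (ev$time != te) next
        for (i in which(alive & pop == ev$recipient_node)) {
          if (runif(1) < ev$gamma) pop[i] <- ev$donor_node
        }
      }
      sel <- mergers$time == te
      for (nd in mergers$node[sel]) {
        kids <- tree$edge[tree$edge[, 1L] == nd, 2L]
        pop[alive & pop %in% kids] <- nd
      }
      t_prev <- te
    }
    paste0(nwk[which(alive)], ";")
  }

  texts <- vapply(seq_len(n_loci), function(i) sim_locus(), character(1))
  trees <- ape::read.tree(text = paste(texts, collapse = "\n"))
  if (inherits(trees, "phylo")) trees <- structure(list(trees),
                                                   class = "multiPhylo")
  names(trees) <- sprintf("L%03d", seq_len(n_loci))
  trees
}

#' Simulation configuration
#'
#' @param n_loci Number of loci.
#' @param seed Master seed (mandatory; all randomness flows from it).
#' @param rate_meanlog,rate_sdlog Lognormal per-locus rate model.
#' @param branch_noise_shape Gamma shape of per-branch rate noise (mean 1);
#'   `Inf` disables the noise.
#' @param scale Substitutions/site per coalescent unit (default 0.01).
#' @param seq_length Alignment length for sequence simulation.
#' @param subst_model Substitution model (only `"JC69"`).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_loci = 150, seed, rate_meanlog = 0,
                       rate_sdlog = 0.5, branch_noise_shape = 10,
                       scale = 0.01, seq_length = 600,
                       subst_model = "JC69") {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_loci > 0, rate_sdlog >= 0, branch_noise_shape > 0, scale > 0,
            seq_length > 0, subst_model == "JC69")
  structure(list(n_loci = n_loci, seed = seed, rate_meanlog = rate_meanlog,
                 rate_sdlog = rate_sdlog,
                 branch_noise_shape = branch_noise_shape, scale = scale,
                 seq_length = seq_length, subst_model = subst_model),
            class = "sim_config")
}

#' Apply molecular-rate heterogeneity to coalescent-unit gene trees
#'
#' Every branch length is multiplied by `scale` x a per-locus lognormal rate
#' x per-branch Gamma(shape, shape) noise (mean 1), converting coalescent
#' units into substitutions/site. With `rate_sdlog = 0` and no branch noise,
#' all loci share one rate and ultrametric inputs stay ultrametric.
#'
#' @param gene_trees List of `phylo` in coalescent units.
#' @param config A `sim_config`.
#' @param seed RNG seed (defaults to `config$seed`).
#' @return List with `trees` (substitution-unit `multiPhylo`) and
#'   `locus_rates`.
#' @export
apply_rate_heterogeneity <- function(gene_trees, config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  rates <- rlnorm(length(gene_trees), config$rate_meanlog, config$rate_sdlog)
  out <- vector("list", length(gene_trees))
  for (i in seq_along(gene_trees)) {
    tr <- gene_trees[[i]]
    noise <- if (is.finite(config$branch_noise_shape)) {
      rgamma(length(tr$edge.length), shape = config$branch_noise_shape,
             rate = config$branch_noise_shape)
    } else 1
    tr$edge.length <- tr$edge.length * config$scale * rates[i] * noise
    out[[i]] <- tr
  }
  names(out) <- names(gene_trees)
  class(out) <- "multiPhylo"
  list(trees = out, locus_rates = rates)
}

#' Simulate a sequence alignment on a tree under JC69
#'
#' Root sequence uniform over `A/C/G/T`; states evolve along each branch with
#' the JC69 transition probabilities (branch lengths in substitutions/site).
#'
#' @param tree A `phylo` with branch lengths in substitutions/site.
#' @param length Number of sites.
#' @param seed RNG seed.
#' @return A `locus_alignment` over the tree's tips.
#' @export
simulate_sequences <- function(tree, length, seed = NULL) {
  if (length <= 0) stop("length must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sim <- phangorn::simSeq(tree, l = length, type = "DNA")
  m <- toupper(as.character(sim))
  rownames(m) <- names(sim)
  locus_alignment(m[tree$tip.label, , drop = FALSE])
}

#' Bundled toy study with known ground truth
#'
#' Nine groups ("subfamilies") of two taxa each plus one outgroup on a
#' coalescent-unit species tree; one planted introgression pulse
#' (`gamma = 0.15` by default) between two designated groups; simulated gene
#' trees, substitution-unit versions with rate heterogeneity, alignments for
#' the first loci, and the taxon-to-group map.
#'
#' @param seed Master seed.
#' @param n_loci Gene trees to simulate (default 150).
#' @param gamma Pulse strength (default 0.15; `0` disables the pulse).
#' @param n_alignments Loci to evolve sequences for (default 10).
#' @param dir Optional directory; when given, gene trees (Newick, one per
#'   line), species tree, alignments (FASTA), the taxon map (TSV) and a
#'   ground-truth manifest (YAML) are written there.
#' @return List with `model`, `species_tree`, `gene_trees` (coalescent
#'   units), `subst_trees`, `alignments`, `taxon_map`, `outgroup`,
#'   `planted_pair`, `config`.
#' @export
make_toy_study <- function(seed, n_loci = 150, gamma = 0.15,
                           n_alignments = 10, dir = NULL) {
  groups <- paste0("g", 1:9)
  taxa <- as.vector(t(outer(groups, c("a", "b"), paste, sep = "_")))
  # coalescent-unit species tree: two major clades (g1-g4, g5-g9) splitting
  # at 11, short internal ladders inside each clade (spans 1.5 coalescent
  # units, enough to leave visible ILS), within-group cherries at 2, the
  # outgroup at 16.
  cherry <- function(g, h) sprintf("(%s_a:%g,%s_b:%g)", g, h, g, h)
  ladder <- function(gs, heights) {
    nwk <- cherry(gs[1], 2)
    cur <- 2
    for (i in seq_along(heights)) {
      nwk <- sprintf("(%s:%g,%s:%g)", nwk, heights[i] - cur,
                     cherry(gs[i + 1], 2), heights[i] - 2)
      cur <- heights[i]
    }
    list(nwk = nwk, h = cur)
  }
  a <- ladder(groups[1:4], c(4, 5.5, 7))
  b <- ladder(groups[5:9], c(4, 5.5, 7, 8.5))
  nwk <- sprintf("((%s:%g,%s:%g):%g,out:16);", a$nwk, 11 - a$h, b$nwk,
                 11 - b$h, 16 - 11)
  sptree <- parse_newick(nwk)
  events <- if (gamma > 0) {
    list(list(donor = c("g2_a", "g2_b"), recipient = c("g7_a", "g7_b"),
              time = 3, gamma = gamma))
  } else list()
  model <- species_tree_model(sptree, events)
  config <- sim_config(n_loci = n_loci, seed = seed)
  gene_trees <- simulate_msc(model, n_loci, seed = seed)
  het <- apply_rate_heterogeneity(gene_trees, config, seed = seed + 1)
  alignments <- list()
  for (i in seq_len(min(n_alignments, n_loci))) {
    alignments[[names(gene_trees)[i]]] <-
      simulate_sequences(het$trees[[i]], config$seq_length, seed = seed + 1 + i)
  }
  taxon_map <- c(setNames(rep(groups, each = 2), taxa), out = "outgroup")
  out <- list(model = model, species_tree = sptree, gene_trees = gene_trees,
              subst_trees = het$trees, locus_rates = het$locus_rates,
              alignments = alignments, taxon_map = taxon_map,
              outgroup = "out", planted_pair = if (gamma > 0) c("g2", "g7"),
              config = config)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_newick(out$subst_trees, file.path(dir, "gene_trees.nwk"))
    write_newick(sptree, file.path(dir, "species_tree.nwk"))
    write.table(data.frame(taxon = names(taxon_map), group = taxon_map),
                file.path(dir, "taxon_map.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    for (nm in names(alignments))
      write_fasta_alignment(alignments[[nm]],
                            file.path(dir, paste0(nm, ".fasta")))
    yaml::write_yaml(list(seed = seed, n_loci = n_loci, gamma = gamma,
                          planted_donor = "g2", planted_recipient = "g7",
                          pulse_time = 3, scale = config$scale,
                          rate_sdlog = config$rate_sdlog,
                          branch_noise_shape = config$branch_noise_shape),
                     file.path(dir, "ground_truth.yaml"))
  }
  out
}
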