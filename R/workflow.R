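# End-to-end pipelines: discordance-source analysis and gene-shopping /
# dating-set preparation, with a YAML run configuration and TSV report
# writers. Per-stage item counts are logged via message() so the usual
# debugging surface of discordance pipelines (trees read, triplets skipped,
# non-converged fits) is visible.

run_config_keys <- c(
  "gene_trees", "species_tree", "alignments_dir", "taxon_map", "out_dir",
  "outgroup", "dbic_threshold", "n_min", "restarts", "seed",
  "collapse_support", "min_bipartition", "n_sets", "k_lowvar",
  "denominator", "value_tol"
)

#' Read and validate a run configuration
#'
#' A YAML file of paths and module parameters; unknown keys are rejected and
#' every random operation must receive a seed.
#'
#' @param path YAML file path.
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(cfg$seed)) stop("config must set a seed", call. = FALSE)
  structure(cfg, class = "run_config")
}

default_or <- function(x, default) if (is.null(x)) default else x

#' Run the discordance pipeline from a configuration file
#'
#' Thin dispatcher mapping `run_config` keys (paths, thresholds, seeds) onto
#' [run_discordance()] arguments.
#'
#' @param config A `run_config` from [read_run_config()], or a YAML path.
#' @return See [run_discordance()].
#' @export
run_discordance_config <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  run_discordance(
    gene_trees = config$gene_trees,
    species_tree = config$species_tree,
    outgroup = config$outgroup,
    taxon_map = config$taxon_map,
    dbic_threshold = default_or(config$dbic_threshold, 10),
    n_min = default_or(config$n_min, 5),
    restarts = default_or(config$restarts, 10),
    seed = config$seed,
    value_tol = default_or(config$value_tol, 1e-6),
    collapse_support = config$collapse_support,
    out_dir = config$out_dir
  )
}

#' Discordance-source analysis pipeline
#'
#' Stages, in order: prune gene trees to the analysis taxa, optionally
#' collapse weakly supported branches, tabulate triplet topologies and
#' internal branch lengths, fit both branch-length models per topology,
#' compare by BIC, classify against the species tree, and summarise
#' significant results into introgression/ILS events.
#'
#' @param gene_trees Named list of gene trees (or a path readable by
#'   [read_newick_trees()]).
#' @param species_tree Species tree (or Newick path), rooted on `outgroup`.
#' @param outgroup Single taxon used to root every tree and excluded from
#'   triplet enumeration.
#' @param taxon_map Named character vector taxon -> group, or a two-column
#'   TSV path (`taxon`, `group`).
#' @param dbic_threshold,n_min,restarts,seed,value_tol Model-stage settings.
#' @param fit_topologies Passed to [fit_triplet_models()]; `"discordant"`
#'   skips the (numerous) concordant topologies when only event summaries
#'   are needed.
#' @param collapse_support Collapse gene-tree branches with support at or
#'   below this value before tabulation (`NULL` to skip).
#' @param normalize_rates Divide every gene tree's branch lengths by its mean
#'   root-to-tip depth before extracting triplet branches (default `TRUE`).
#'   This per-locus clock correction removes among-locus substitution-rate
#'   variation, which otherwise smears the introgression lag `c` across loci
#'   and erodes the power of the mixture test; the exponential form of the
#'   ILS component is preserved under the rescaling. Set to `FALSE` to fit
#'   raw substitutions/site branch lengths.
#' @param out_dir When given, the triplet table, Table-1-shaped report and
#'   events file are written there.
#' @return List with `results` (per triplet-topology tests), `events`,
#'   `triplets` (the tabulation), and `counts` (per-stage tallies).
#' @export
run_discordance <- function(gene_trees, species_tree, outgroup, taxon_map,
                            dbic_threshold = 10, n_min = 5, restarts = 10,
                            seed = 1, value_tol = 1e-6,
                            collapse_support = NULL, normalize_rates = TRUE,
                            fit_topologies = c("all", "discordant"),
                            out_dir = NULL) {
  fit_topologies <- match.arg(fit_topologies)
  if (is.character(gene_trees)) {
    if (!file.exists(gene_trees))
      stop("gene tree file not found: ", gene_trees, call. = FALSE)
    gene_trees <- read_newick_trees(gene_trees)
  }
  if (!length(gene_trees)) stop("empty gene tree input", call. = FALSE)
  if (is.character(species_tree)) {
    species_tree <- read_newick_trees(species_tree)[[1]]
  }
  if (is.character(taxon_map) && length(taxon_map) == 1 &&
      file.exists(taxon_map)) {
    tm <- read.table(taxon_map, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    taxon_map <- setNames(tm$group, tm$taxon)
  }
  ingroup <- setdiff(names(taxon_map)[taxon_map != "outgroup"], outgroup)
  analysis_taxa <- c(ingroup, outgroup)
  message("run_discordance: ", length(gene_trees), " gene trees, ",
          length(ingroup), " ingroup taxa")

  sp <- prune_to_taxa(species_tree, intersect(species_tree$tip.label,
                                              analysis_taxa))
  sp <- root_at_outgroup(sp, outgroup)

  pruned <- lapply(gene_trees, function(tr) {
    keep <- intersect(tr$tip.label, analysis_taxa)
    if (length(keep) < 4L) return(NULL)
    prune_to_taxa(tr, keep)
  })
  dropped <- vapply(pruned, is.null, logical(1))
  pruned <- pruned[!dropped]
  if (!is.null(collapse_support)) {
    pruned <- lapply(pruned, collapse_low_support,
                     threshold = collapse_support)
  }
  if (normalize_rates) {
    pruned <- lapply(pruned, function(tr) {
      if (!(outgroup %in% tr$tip.label)) return(tr)
      rt <- root_at_outgroup(tr, outgroup)
      depth <- mean(ape::node.depth.edgelength(rt)[seq_along(rt$tip.label)])
      if (is.finite(depth) && depth > 0) rt$edge.length <- rt$edge.length / depth
      rt
    })
  }
  message("  pruned: ", length(pruned), " trees retained (",
          sum(dropped), " dropped with <4 analysis taxa)")

  triplets <- enumerate_triplets(ingroup)
  tab <- tabulate_triplets(pruned, triplets, outgroup)
  message("  tabulated: ", length(triplets), " triplets, ",
          nrow(tab$observations), " observations, ",
          sum(tab$summary$skipped), " skipped (tree x triplet)")

  results <- fit_triplet_models(tab, sp, dbic_threshold = dbic_threshold,
                                n_min = n_min, n_restarts = restarts,
                                seed = seed, fit_topologies = fit_topologies)
  message("  fitted: ", nrow(results), " triplet topologies (",
          sum(!results$converged), " non-converged)")
  events <- summarize_events(results, taxon_map, value_tol = value_tol)
  message("  events: ", nrow(events))

  out <- list(results = results, events = events, triplets = tab,
              counts = list(trees_in = length(gene_trees),
                            trees_used = length(pruned),
                            triplets = length(triplets),
                            observations = nrow(tab$observations),
                            skipped = sum(tab$summary$skipped),
                            topologies_tested = nrow(results),
                            non_converged = sum(!results$converged),
                            events = nrow(events)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(results, file.path(out_dir, "triplet_tests.tsv"))
    write.table(events, file.path(out_dir, "events.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.table(tab$summary, file.path(out_dir, "triplet_summary.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(tab$observations, file.path(out_dir, "triplet_obs.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  out
}

#' Gene-shopping / dating-set preparation pipeline
#'
#' Computes per-locus concordance and clock metrics, retains loci at the
#' bipartition threshold, stratifies them into variance terciles, selects the
#' most clock-like subset, and exports the five dating datasets (one
#' supermatrix per set, the combined partitioned supermatrix, and the
#' low-variance subset).
#'
#' @param gene_trees Named list of gene trees (or Newick path), one per
#'   locus, rooted or rootable on `outgroup`.
#' @param species_tree Species tree (or Newick path).
#' @param alignments Named list of `locus_alignment`s matching the locus ids
#'   (required for supermatrix export; `NULL` computes metrics only).
#' @param outgroup Taxon (vector) used to root trees.
#' @param min_bipartition Retention threshold (default 0.3).
#' @param n_sets Variance strata (default 3).
#' @param k_lowvar Size of the low-variance subset (default 5).
#' @param denominator Bipartition-proportion denominator (see
#'   [shared_bipartition_proportion()]).
#' @param out_dir When given, metrics/manifests TSVs and supermatrices are
#'   written there.
#' @return List with `metrics` (with set labels), `manifest`, `lowvar`,
#'   and (when alignments are given) `sets` from [build_dating_sets()].
#' @export
run_geneshop <- function(gene_trees, species_tree, alignments = NULL,
                         outgroup = NULL, min_bipartition = 0.3, n_sets = 3,
                         k_lowvar = 5, denominator = c("gene", "species"),
                         out_dir = NULL) {
  denominator <- match.arg(denominator)
  if (is.character(gene_trees)) gene_trees <- read_newick_trees(gene_trees)
  if (is.character(species_tree))
    species_tree <- read_newick_trees(species_tree)[[1]]
  if (!is.null(outgroup)) {
    gene_trees <- lapply(gene_trees, function(tr) {
      if (all(outgroup %in% tr$tip.label)) root_at_outgroup(tr, outgroup)
      else tr
    })
    if (all(outgroup %in% species_tree$tip.label))
      species_tree <- root_at_outgroup(species_tree, outgroup)
  }
  metrics <- locus_metrics(gene_trees, species_tree,
                           denominator = denominator)
  shopped <- gene_shop(metrics, min_bipartition = min_bipartition,
                       n_sets = n_sets)
  manifest <- attr(shopped, "manifest")
  retained <- shopped[shopped$set_label != "excluded", , drop = FALSE]
  lowvar <- lowest_variance_subset(retained, k = min(k_lowvar,
                                                     nrow(retained)))
  message("run_geneshop: ", nrow(metrics), " loci, ", nrow(retained),
          " retained at >= ", min_bipartition, "; sets of ",
          paste(lengths(manifest), collapse = "/"))
  out <- list(metrics = shopped, manifest = manifest, lowvar = lowvar)
  if (!is.null(alignments)) {
    have <- unlist(manifest) %in% names(alignments)
    if (!all(have))
      stop("retained loci without alignments: ",
           paste(setdiff(unlist(manifest), names(alignments)),
                 collapse = ", "), call. = FALSE)
    out$sets <- build_dating_sets(alignments, manifest)
    out$lowvar_set <- build_dating_sets(alignments, list(lowvar5 = lowvar))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(shopped, file.path(out_dir, "locus_metrics.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    mani_df <- data.frame(set = rep(names(manifest), lengths(manifest)),
                          locus = unlist(manifest), row.names = NULL)
    write.table(mani_df, file.path(out_dir, "set_manifest.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    writeLines(lowvar, file.path(out_dir, "lowvar_loci.txt"))
    if (!is.null(out$sets)) {
      write_dating_sets(out$sets, out_dir, prefix = "dating")
      write_dating_sets(out$lowvar_set, out_dir, prefix = "lowvar")
    }
  }
  out
}

#' Write the Table-1-shaped triplet test report
#'
#' Deterministic column order (`taxa_pair`, `group_pair` slot left to the
#' events file, fitted proportions, BICs, dBIC, decision, interpretation),
#' floats rounded to 2 decimals in the main file and written at full
#' precision in a `.full.tsv` sidecar.
#'
#' @param results Data frame from [fit_triplet_models()].
#' @param path Output TSV path.
#' @param format `"tsv"` or `"markdown"`.
#' @return Invisibly, `path`.
#' @export
write_report <- function(results, path, format = c("tsv", "markdown")) {
  format <- match.arg(format)
  cols <- data.frame(
    taxa_pair = paste(results$cherry1, results$cherry2, sep = "-"),
    triplet = paste(results$taxon1, results$taxon2, results$taxon3,
                    sep = "|"),
    odd_taxon = results$odd_taxon,
    ils_prop = results$ils_prop, nonils_prop = results$nonils_prop,
    bic2 = results$bic2, bic1 = results$bic1, dbic = results$dbic,
    total_nonils_pct = results$total_nonils_pct,
    preferred = results$preferred, interpretation = results$interpretation,
    stringsAsFactors = FALSE
  )
  rounded <- cols
  num <- vapply(rounded, is.numeric, logical(1))
  rounded[num] <- lapply(rounded[num], round, digits = 2)
  if (format == "tsv") {
    write.table(rounded, path, sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(cols, sub("\\.tsv$", ".full.tsv", path), sep = "\t",
                row.names = FALSE, quote = FALSE)
  } else {
    hdr <- paste0("| ", paste(names(rounded), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(rounded)), collapse = "|"), "|")
    body <- apply(rounded, 1, function(r)
      paste0("| ", paste(r, collapse = " | "), " |"))
    writeLines(c(hdr, sep, body), path)
  }
  invisible(path)
}
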