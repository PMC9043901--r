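# The core statistical stage: two competing models for the triplet internal
# branch length t.
#
# ILS only:        f1(t) = (1/lambda) exp(-t/lambda)
#   (internal branches of discordant coalescent gene trees are exponential
#   waiting times)
# ILS + non-ILS:   f2(t) = pi f1(t) + (1 - pi) (1/lambda) exp(-(t-c)/lambda),
#                  t >= c in the second component
#   (introgressed/speciation branches carry a fixed lag c from the event,
#   sharing the exponential scale lambda)
#
# Model selection by BIC = k ln(n) - 2 lnL (k = 1 vs 3), with |dBIC| > 10
# taken as decisive.

#' Prepare internal branch lengths for model fitting
#'
#' Zero (or negative) lengths break the log-density and are jittered to half
#' the smallest positive observation; the number jittered is recorded.
#'
#' @param t Numeric vector of internal branch lengths.
#' @return List with `t` (positive lengths) and `n_jittered`.
#' @export
prepare_lengths <- function(t) {
  t <- as.numeric(t)
  bad <- t <= 0
  if (any(bad)) {
    pos <- t[!bad]
    if (!length(pos)) stop("all branch lengths are zero", call. = FALSE)
    t[bad] <- min(pos) / 2
  }
  list(t = t, n_jittered = sum(bad))
}

#' Fit the ILS-only exponential model
#'
#' Closed-form MLE: `lambda = mean(t)`,
#' `lnL = -n (log lambda + 1)`, `BIC = log(n) - 2 lnL`.
#'
#' @param t Positive branch lengths.
#' @param n_min Minimum observations; below it the fit is flagged
#'   `insufficient` and excluded downstream.
#' @return An object of class `ils_fit` with `lambda`, `lnL`, `bic`, `n`.
#' @export
fit_ils_only <- function(t, n_min = 5) {
  t <- as.numeric(t)
  n <- length(t)
  if (n < n_min) {
    return(structure(list(lambda = NA_real_, lnL = NA_real_, bic = NA_real_,
                          n = n, insufficient = TRUE), class = "ils_fit"))
  }
  stopifnot(all(t > 0))
  lambda <- mean(t)
  lnL <- -n * (log(lambda) + 1)
  structure(list(lambda = lambda, lnL = lnL, bic = log(n) - 2 * lnL, n = n,
                 insufficient = FALSE), class = "ils_fit")
}

#' Fit the ILS + introgression mixture model
#'
#' EM with closed-form M-steps for the mixing weight `pi` and shared scale
#' `lambda`, and a bounded one-dimensional likelihood search on `[0, max(t))`
#' for the shift `c`, run from `n_restarts` seeded initializations
#' (`pi ~ U(0.05, 0.95)`, `c` uniform over the 10-90% data quantiles,
#' `lambda = mean(t)`); the best restart is returned. The observed
#' log-likelihood is non-decreasing across iterations and, at convergence, at
#' least that of the nested ILS-only model (attained at `pi = 1` or `c = 0`).
#'
#' @param t Positive branch lengths.
#' @param n_restarts Number of EM initializations (default 10).
#' @param seed RNG seed making the restarts deterministic.
#' @param tol Relative convergence tolerance on the log-likelihood
#'   (default 1e-8; convergence when `|dlnL| < tol * (|lnL| + 1)`).
#' @param max_iter Maximum EM iterations per restart (default 2000).
#' @param n_min As in [fit_ils_only()].
#' @return An object of class `mixture_fit` with `pi_ils`, `lambda`,
#'   `shift_c`, `lnL`, `bic` (k = 3), `n`, `converged`, `n_restarts`.
#' @export
fit_ils_plus_intro <- function(t, n_restarts = 10, seed = NULL, tol = 1e-8,
                               max_iter = 2000, n_min = 5) {
  t <- as.numeric(t)
  n <- length(t)
  if (n < n_min) {
    return(structure(list(pi_ils = NA_real_, lambda = NA_real_,
                          shift_c = NA_real_, lnL = NA_real_, bic = NA_real_,
                          n = n, converged = FALSE, n_restarts = 0L,
                          insufficient = TRUE), class = "mixture_fit"))
  }
  stopifnot(all(t > 0))
  if (!is.null(seed)) set.seed(seed)
  q <- quantile(t, c(0.1, 0.9), names = FALSE)
  lam0 <- mean(t)
  best <- NULL
  any_converged <- FALSE
  inits <- data.frame(
    pi = c(0.5, runif(max(n_restarts - 1, 0), 0.05, 0.95)),
    c = c(median(t), runif(max(n_restarts - 1, 0), q[1], q[2]))
  )[seq_len(n_restarts), , drop = FALSE]
  for (i in seq_len(n_restarts)) {
    fit <- em_shift_mix_cpp(t, inits$pi[i], lam0, inits$c[i], tol, max_iter)
    any_converged <- any_converged || fit$converged
    if (is.null(best) || fit$lnL > best$lnL) best <- fit
  }
  # the ILS-only model is nested (pi = 1): never report a worse likelihood
  ils <- fit_ils_only(t, n_min = n_min)
  if (best$lnL < ils$lnL) {
    best <- list(pi = 1 - 1e-9, lambda = ils$lambda, c = 0, lnL = ils$lnL,
                 converged = TRUE)
    any_converged <- TRUE
  }
  structure(list(pi_ils = min(max(best$pi, 0), 1), lambda = best$lambda,
                 shift_c = best$c, lnL = best$lnL,
                 bic = 3 * log(n) - 2 * best$lnL, n = n,
                 converged = any_converged, n_restarts = n_restarts,
                 insufficient = FALSE), class = "mixture_fit")
}

#' @export
print.ils_fit <- function(x, ...) {
  cat("ILS-only exponential fit: lambda =", format(x$lambda, digits = 4),
      " lnL =", format(x$lnL, digits = 6), " BIC =", format(x$bic, digits = 6),
      " (n =", x$n, ")\n")
  invisible(x)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("ILS + introgression mixture fit: pi_ils =",
      format(x$pi_ils, digits = 3), " lambda =", format(x$lambda, digits = 4),
      " c =", format(x$shift_c, digits = 4), " lnL =",
      format(x$lnL, digits = 6), " BIC =", format(x$bic, digits = 6),
      " (n =", x$n, ")\n")
  invisible(x)
}

#' Compare the two models by BIC
#'
#' `dbic = bic2 - bic1`; the mixture is preferred when `dbic < -threshold`,
#' ILS-only when `dbic > threshold`, otherwise the comparison is ambiguous.
#'
#' @param fit1 An `ils_fit`.
#' @param fit2 A `mixture_fit` on the same data.
#' @param threshold Decision threshold on |dBIC| (default 10).
#' @return List with `dbic` and `preferred` in
#'   `c("mixture", "ils_only", "ambiguous")`.
#' @export
compare_models <- function(fit1, fit2, threshold = 10) {
  if (!is.null(fit1$n) && !is.null(fit2$n) && fit1$n != fit2$n)
    stop("fits are on different data (n mismatch)", call. = FALSE)
  dbic <- fit2$bic - fit1$bic
  preferred <- if (dbic < -threshold) "mixture"
               else if (dbic > threshold) "ils_only"
               else "ambiguous"
  list(dbic = dbic, preferred = preferred)
}

#' Triplet topology of the species tree
#'
#' @param species_tree Rooted species tree containing the triplet taxa.
#' @param triplet Character vector of 3 taxa.
#' @return The odd-taxon-out under the species tree, or `NA` if the species
#'   tree is unresolved for this triplet.
#' @export
species_triplet_topology <- function(species_tree, triplet) {
  missing <- setdiff(triplet, species_tree$tip.label)
  if (length(missing))
    stop("triplet taxa absent from species tree: ",
         paste(missing, collapse = ", "), call. = FALSE)
  mm <- ape::mrca(species_tree)
  depths <- ape::node.depth.edgelength(species_tree)
  res <- triplet_from_depths(sort(triplet), mm, depths)
  if (is.character(res)) return(NA_character_)
  res$odd
}

#' Interpret a triplet-topology test against the species tree
#'
#' Discordant topology with the mixture preferred reads as introgression;
#' discordant with ILS-only preferred as ILS; a concordant topology's non-ILS
#' component reflects speciation (lineage sorting along the species tree),
#' never introgression; an ambiguous model choice stays ambiguous.
#'
#' @param concordant Logical: does the tested topology match the species tree?
#' @param preferred `"mixture"`, `"ils_only"` or `"ambiguous"` from
#'   [compare_models()].
#' @return One of `"introgression"`, `"ILS"`, `"speciation"`, `"ambiguous"`.
#' @export
classify_interpretation <- function(concordant, preferred) {
  if (preferred == "ambiguous") return("ambiguous")
  if (concordant) return("speciation")
  if (preferred == "mixture") "introgression" else "ILS"
}

#' Total non-ILS proportion as a percentage of all gene trees
#'
#' `100 * (1 - pi_ils) * n_topology / n_total_trees`: the fraction of ALL
#' analysed gene trees assigned to the non-ILS component of this topology.
#'
#' @param fit2 A `mixture_fit`.
#' @param n_topology Number of gene trees showing the tested topology.
#' @param n_total_trees Number of gene trees analysed.
#' @return A percentage.
#' @export
total_nonils_pct <- function(fit2, n_topology, n_total_trees) {
  if (n_topology <= 0 || n_total_trees <= 0)
    stop("counts must be positive", call. = FALSE)
  if (n_topology > n_total_trees)
    stop("n_topology exceeds n_total_trees", call. = FALSE)
  100 * (1 - fit2$pi_ils) * n_topology / n_total_trees
}

#' Run both models for every triplet topology in a tabulation
#'
#' For each triplet and each of its observed topologies with at least `n_min`
#' observations, fits the ILS-only and mixture models, compares them by BIC,
#' and classifies the result against the species tree.
#'
#' @param tab Result of [tabulate_triplets()].
#' @param species_tree Rooted species tree (pruned to the analysis taxa).
#' @param dbic_threshold Decision threshold (default 10).
#' @param n_min Minimum observations per topology (default 5).
#' @param n_restarts,seed,tol,max_iter Passed to [fit_ils_plus_intro()];
#'   per-topology seeds are derived deterministically from `seed`.
#' @param fit_topologies `"all"` (default) fits every topology;
#'   `"discordant"` restricts fitting to topologies that disagree with the
#'   species tree — sufficient for event summaries, since concordant
#'   topologies read as speciation regardless of the model choice.
#' @return A data frame, one row per tested triplet topology, with taxa,
#'   cherry pair, fitted parameters, `bic1`, `bic2`, `dbic`, `preferred`,
#'   `concordant`, `interpretation`, `total_nonils_pct`, `n`, `n_jittered`.
#' @export
fit_triplet_models <- function(tab, species_tree, dbic_threshold = 10,
                               n_min = 5, n_restarts = 10, seed = 1,
                               tol = 1e-8, max_iter = 2000,
                               fit_topologies = c("all", "discordant")) {
  fit_topologies <- match.arg(fit_topologies)
  obs <- tab$observations
  if (!nrow(obs)) stop("no triplet observations to fit", call. = FALSE)
  n_total <- max(rowSums(tab$summary[, c("n1", "n2", "n3", "skipped")]))
  key <- paste(obs$taxon1, obs$taxon2, obs$taxon3, obs$odd_taxon, sep = "|")
  groups <- split(seq_len(nrow(obs)), key)
  sp_cache <- new.env(parent = emptyenv())
  rows <- vector("list", length(groups))
  i <- 0L
  for (k in names(groups)) {
    idx <- groups[[k]]
    if (length(idx) < n_min) next
    first0 <- obs[idx[1], ]
    trip0 <- c(first0$taxon1, first0$taxon2, first0$taxon3)
    tkey <- paste(trip0, collapse = "|")
    if (is.null(sp_cache[[tkey]]))
      sp_cache[[tkey]] <- species_triplet_topology(species_tree, trip0)
    if (fit_topologies == "discordant" &&
        !is.na(sp_cache[[tkey]]) && sp_cache[[tkey]] == first0$odd_taxon)
      next
    i <- i + 1L
    first <- first0
    trip <- trip0
    prep <- prepare_lengths(obs$t[idx])
    f1 <- fit_ils_only(prep$t, n_min = n_min)
    f2 <- fit_ils_plus_intro(prep$t, n_restarts = n_restarts,
                             seed = seed + i, tol = tol, max_iter = max_iter,
                             n_min = n_min)
    cmp <- compare_models(f1, f2, threshold = dbic_threshold)
    sp_odd <- sp_cache[[paste(trip, collapse = "|")]]
    concordant <- !is.na(sp_odd) && sp_odd == first$odd_taxon
    cherry <- sort(setdiff(trip, first$odd_taxon))
    rows[[i]] <- data.frame(
      taxon1 = trip[1], taxon2 = trip[2], taxon3 = trip[3],
      odd_taxon = first$odd_taxon,
      cherry1 = cherry[1], cherry2 = cherry[2],
      n = length(idx), n_jittered = prep$n_jittered,
      ils_prop = f2$pi_ils, nonils_prop = 1 - f2$pi_ils,
      lambda = f2$lambda, shift_c = f2$shift_c,
      bic2 = f2$bic, bic1 = f1$bic, dbic = cmp$dbic,
      preferred = cmp$preferred, concordant = concordant,
      interpretation = classify_interpretation(concordant, cmp$preferred),
      total_nonils_pct = total_nonils_pct(f2, length(idx), n_total),
      converged = f2$converged, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[seq_len(i)])
  if (is.null(out)) stop("no topology reached n_min observations",
                         call. = FALSE)
  rownames(out) <- NULL
  attr(out, "n_total_trees") <- n_total
  out
}

#' Summarise significant triplet tests into events
#'
#' Significant discordant results (introgression or ILS interpretation) are
#' collapsed into events when they imply the same unordered group pair (the
#' groups of the two cherry taxa) and their fitted `(pi, lambda, c)` agree
#' within `value_tol` — triplets drawing different species from the same two
#' groups with equal fits reflect one ancestral event. Events with total
#' non-ILS above 1% are flagged strong.
#'
#' @param results Data frame from [fit_triplet_models()].
#' @param taxon_to_group Named character vector: taxon -> group (subfamily).
#' @param value_tol Equality tolerance on fitted values (default 1e-6).
#' @param strong_pct Strong/weak threshold on total non-ILS % (default 1).
#' @return A data frame, one row per event: `group_pair`, `event_type`,
#'   `n_triplets`, member taxa pairs, shared fitted values, and
#'   `total_nonils_pct` (the members' maximum), `strong`.
#' @export
summarize_events <- function(results, taxon_to_group, value_tol = 1e-6,
                             strong_pct = 1) {
  sig <- results[results$interpretation %in% c("introgression", "ILS"), ,
                 drop = FALSE]
  if (!nrow(sig)) {
    return(data.frame(group_pair = character(), event_type = character(),
                      n_triplets = integer(), taxa_pairs = character(),
                      ils_prop = numeric(), lambda = numeric(),
                      shift_c = numeric(), total_nonils_pct = numeric(),
                      strong = logical(), stringsAsFactors = FALSE))
  }
  unmapped <- setdiff(unique(c(sig$cherry1, sig$cherry2)),
                      names(taxon_to_group))
  if (length(unmapped))
    stop("taxa without a group mapping: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  g1 <- unname(taxon_to_group[sig$cherry1])
  g2 <- unname(taxon_to_group[sig$cherry2])
  sig$group_pair <- ifelse(g1 <= g2, paste(g1, g2, sep = "-"),
                           paste(g2, g1, sep = "-"))
  events <- list()
  for (gp in unique(sig$group_pair)) {
    for (ty in unique(sig$interpretation[sig$group_pair == gp])) {
      block <- sig[sig$group_pair == gp & sig$interpretation == ty, ,
                   drop = FALSE]
      block <- block[order(block$ils_prop, block$shift_c), , drop = FALSE]
      assigned <- rep(0L, nrow(block))
      ev <- 0L
      for (r in seq_len(nrow(block))) {
        placed <- FALSE
        for (e in seq_len(ev)) {
          rep_row <- block[match(e, assigned), ]
          if (abs(block$ils_prop[r] - rep_row$ils_prop) <= value_tol &&
              abs(block$lambda[r] - rep_row$lambda) <= value_tol &&
              abs(block$shift_c[r] - rep_row$shift_c) <= value_tol) {
            assigned[r] <- e
            placed <- TRUE
            break
          }
        }
        if (!placed) { ev <- ev + 1L; assigned[r] <- ev }
      }
      for (e in seq_len(ev)) {
        mem <- block[assigned == e, , drop = FALSE]
        pct <- max(mem$total_nonils_pct)
        events[[length(events) + 1L]] <- data.frame(
          group_pair = gp, event_type = ty, n_triplets = nrow(mem),
          taxa_pairs = paste(paste(mem$cherry1, mem$cherry2, sep = "-"),
                             collapse = ", "),
          ils_prop = mem$ils_prop[1], lambda = mem$lambda[1],
          shift_c = mem$shift_c[1], total_nonils_pct = pct,
          strong = pct > strong_pct, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}
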