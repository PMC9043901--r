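test_that("fit_ils_only is the closed-form exponential MLE", {
  f <- fit_ils_only(c(2, 2, 2, 2), n_min = 4)
  expect_equal(f$lambda, 2)
  expect_equal(f$lnL, 4 * (-log(2) - 1), tolerance = 1e-12)
  expect_equal(f$bic, log(4) - 2 * f$lnL, tolerance = 1e-12)

  f2 <- fit_ils_only(rep(3.5, 20))
  expect_equal(f2$lambda, 3.5)

  set.seed(77)
  big <- rexp(2000, rate = 1 / 3)
  expect_equal(fit_ils_only(big)$lambda, 3, tolerance = 0.15 / 3)

  small <- fit_ils_only(c(1, 2), n_min = 5)
  expect_true(small$insufficient)
})

test_that("zero lengths are jittered to half the smallest positive value", {
  p <- prepare_lengths(c(0, 1, 2, 0.5))
  expect_equal(p$n_jittered, 1)
  expect_equal(min(p$t), 0.25)
  expect_error(prepare_lengths(c(0, 0)), "all branch lengths")
})

test_that("the mixture EM recovers planted parameters", {
  t <- sample_mixture_lengths(2000, pi = 0.5, lambda = 1, c = 3, seed = 50)
  f <- fit_ils_plus_intro(t, seed = 51)
  expect_equal(f$pi_ils, 0.5, tolerance = 0.05 / 0.5)
  expect_equal(f$lambda, 1, tolerance = 0.1)
  expect_equal(f$shift_c, 3, tolerance = 0.15 / 3)
  expect_true(f$converged)
  expect_equal(f$bic, 3 * log(2000) - 2 * f$lnL, tolerance = 1e-9)
})

test_that("the mixture never reports a worse likelihood than the nested model", {
  set.seed(60)
  for (i in 1:15) {
    t <- rexp(sample(c(30, 100, 400), 1), rate = 1 / runif(1, 0.5, 4))
    f1 <- fit_ils_only(t)
    f2 <- fit_ils_plus_intro(t, n_restarts = 4, seed = i)
    expect_gte(f2$lnL, f1$lnL - 1e-6)
    # and the mixture is penalized on truly single-exponential data
    expect_gt(compare_models(f1, f2)$dbic, -10 - 1e-9 - 25)  # sanity bound
  }
})

test_that("EM started at the nested solution reproduces the ILS-only lnL", {
  set.seed(61)
  t <- rexp(200, 1)
  f1 <- fit_ils_only(t)
  em <- phylodisc:::em_shift_mix_cpp(t, 1 - 1e-9, mean(t), 0, 1e-10, 1)
  expect_equal(em$lnL, f1$lnL, tolerance = 1e-6)
})

test_that("EM improves the likelihood from any random start", {
  set.seed(62)
  for (i in 1:10) {
    t <- sample_mixture_lengths(300, runif(1, 0.2, 0.9), 1,
                                runif(1, 0.5, 3), seed = 100 + i)
    pi0 <- runif(1, 0.05, 0.95); c0 <- quantile(t, runif(1, 0.1, 0.9))
    ll0 <- phylodisc:::shift_mix_loglik_cpp(t, pi0, mean(t), c0)
    em <- phylodisc:::em_shift_mix_cpp(t, pi0, mean(t), c0, 1e-8, 2000)
    expect_gte(em$lnL, ll0 - 1e-9)
  }
})

test_that("compare_models applies the printed dBIC arithmetic and rule", {
  f1 <- structure(list(bic = -18.65, n = 10), class = "ils_fit")
  f2 <- structure(list(bic = -30.91, n = 10), class = "mixture_fit")
  cmp <- compare_models(f1, f2)
  expect_equal(cmp$dbic, -12.26)
  expect_equal(cmp$preferred, "mixture")

  f1b <- structure(list(bic = -256.52, n = 10), class = "ils_fit")
  f2b <- structure(list(bic = -246.36, n = 10), class = "mixture_fit")
  cmpb <- compare_models(f1b, f2b)
  expect_equal(cmpb$dbic, 10.16)
  expect_equal(cmpb$preferred, "ils_only")

  cmpc <- compare_models(structure(list(bic = -95, n = 5), class = "ils_fit"),
                         structure(list(bic = -100, n = 5),
                                   class = "mixture_fit"))
  expect_equal(cmpc$dbic, -5)
  expect_equal(cmpc$preferred, "ambiguous")

  expect_error(compare_models(structure(list(bic = 0, n = 5), class = "ils_fit"),
                              structure(list(bic = 0, n = 6),
                                        class = "mixture_fit")),
               "different data")
})

test_that("interpretation follows concordance and the preferred model", {
  expect_equal(classify_interpretation(FALSE, "mixture"), "introgression")
  expect_equal(classify_interpretation(FALSE, "ils_only"), "ILS")
  expect_equal(classify_interpretation(TRUE, "mixture"), "speciation")
  expect_equal(classify_interpretation(TRUE, "ils_only"), "speciation")
  expect_equal(classify_interpretation(FALSE, "ambiguous"), "ambiguous")
})

test_that("total_nonils_pct scales the non-ILS weight by topology frequency", {
  f <- structure(list(pi_ils = 0), class = "mixture_fit")
  expect_equal(total_nonils_pct(f, 4, 108), 100 * 4 / 108)
  expect_equal(round(total_nonils_pct(f, 4, 108), 2), 3.70)
  f1 <- structure(list(pi_ils = 1), class = "mixture_fit")
  expect_equal(total_nonils_pct(f1, 10, 100), 0)
  f5 <- structure(list(pi_ils = 0.5), class = "mixture_fit")
  expect_equal(total_nonils_pct(f5, 10, 100), 5.0)
  expect_error(total_nonils_pct(f5, 0, 100), "positive")
})

test_that("species_triplet_topology reads the species tree", {
  sp <- parse_newick("(((A:1,B:1):1,C:2):1,D:3);")
  expect_equal(species_triplet_topology(sp, c("A", "B", "C")), "C")
  expect_equal(species_triplet_topology(sp, c("A", "C", "D")), "D")
  poly <- parse_newick("((A:1,B:1,C:1):1,D:2);")
  expect_true(is.na(species_triplet_topology(poly, c("A", "B", "C"))))
  expect_error(species_triplet_topology(sp, c("A", "B", "Z")), "absent")
})

sig_row <- function(c1, c2, pi, lam, cc, interp, pct = 2) {
  data.frame(taxon1 = "x", taxon2 = "y", taxon3 = "z", odd_taxon = "z",
             cherry1 = c1, cherry2 = c2, n = 10, n_jittered = 0,
             ils_prop = pi, nonils_prop = 1 - pi, lambda = lam, shift_c = cc,
             bic2 = -20, bic1 = -5, dbic = -15, preferred = "mixture",
             concordant = FALSE, interpretation = interp,
             total_nonils_pct = pct, converged = TRUE,
             stringsAsFactors = FALSE)
}

test_that("summarize_events merges equal fits of the same group pair", {
  map <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  res <- rbind(sig_row("a1", "b1", 0.4, 1, 2, "introgression"),
               sig_row("a2", "b2", 0.4, 1, 2, "introgression"))
  ev <- summarize_events(res, map)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_triplets, 2)
  expect_equal(ev$group_pair, "A-B")

  res2 <- rbind(sig_row("a1", "b1", 0.4, 1, 2, "introgression"),
                sig_row("a2", "b2", 0.7, 1, 2, "introgression"))
  expect_equal(nrow(summarize_events(res2, map)), 2)

  empty <- summarize_events(res[0, ], map)
  expect_equal(nrow(empty), 0)

  expect_error(summarize_events(sig_row("a1", "q9", 0.4, 1, 2,
                                        "introgression"), map),
               "without a group")
})

test_that("events are flagged strong above 1% total non-ILS", {
  map <- c(a1 = "A", b1 = "B")
  strong <- summarize_events(sig_row("a1", "b1", 0.2, 1, 2, "introgression",
                                     pct = 3.7), map)
  weak <- summarize_events(sig_row("a1", "b1", 0.2, 1, 2, "introgression",
                                   pct = 0.93), map)
  expect_true(strong$strong)
  expect_false(weak$strong)
})

test_that("fit_triplet_models tests each topology against the species tree", {
  sp <- parse_newick("(((A:1,B:1):1,C:2):8,O:10);")
  model <- species_tree_model(sp)
  trees <- simulate_msc(model, 300, seed = 9)
  tab <- tabulate_triplets(trees, list(c("A", "B", "C")), "O")
  res <- fit_triplet_models(tab, sp, seed = 4, n_restarts = 3)
  expect_true(all(res$n >= 5))
  expect_setequal(unique(res$concordant), c(TRUE, FALSE))
  conc <- res[res$odd_taxon == "C", ]
  expect_equal(conc$interpretation[1],
               if (conc$preferred[1] == "ambiguous") "ambiguous" else "speciation")
  # conservation: tested topology counts never exceed the tree count
  expect_true(all(res$n <= 300))
  # discordant-only mode drops the concordant topology
  disc <- fit_triplet_models(tab, sp, seed = 4, n_restarts = 3,
                             fit_topologies = "discordant")
  expect_false("C" %in% disc$odd_taxon)
})
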