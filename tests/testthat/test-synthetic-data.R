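test_that("sample_mixture_lengths draws from the two-component law", {
  t1 <- sample_mixture_lengths(5000, pi = 1, lambda = 2, c = 5, seed = 1)
  expect_equal(mean(t1), 2, tolerance = 0.05)

  t2 <- sample_mixture_lengths(1e5, pi = 0.5, lambda = 1, c = 3, seed = 2)
  expect_equal(mean(t2), 2.5, tolerance = 0.03 / 2.5)
  expect_true(all(t2 >= 0))

  t3 <- sample_mixture_lengths(2000, pi = 0, lambda = 1, c = 3, seed = 3)
  expect_true(all(t3 >= 3))

  expect_error(sample_mixture_lengths(10, pi = 1.2, lambda = 1, c = 0),
               "invalid")
  expect_error(sample_mixture_lengths(10, pi = 0.5, lambda = -1, c = 0),
               "invalid")
})

test_that("species_tree_model validates events", {
  sp <- parse_newick("((A:1,B:1):1,C:2);")
  expect_s3_class(species_tree_model(sp), "species_tree_model")
  expect_error(species_tree_model(sp, list(list(donor = "A", recipient = "B",
                                                time = 1.5, gamma = 0.1))),
               "outside branch interval")
  expect_error(species_tree_model(sp, list(list(donor = "A", recipient = "B",
                                                time = 0.5, gamma = 1.3))),
               "gamma")
  ok <- species_tree_model(sp, list(list(donor = "A", recipient = "B",
                                         time = 0.5, gamma = 0.2)))
  expect_length(ok$events, 1)
})

test_that("simulate_msc matches the triplet closed forms", {
  freqs <- function(T, n = 4000, seed = 33) {
    sp <- parse_newick(sprintf("((A:1,B:1):%g,C:%g);", T, 1 + T))
    gt <- simulate_msc(species_tree_model(sp), n, seed = seed)
    odd <- vapply(gt, function(tr) {
      mm <- ape::mrca(tr); d <- ape::node.depth.edgelength(tr)
      r <- phylodisc:::triplet_from_depths(c("A", "B", "C"), mm, d)
      if (is.character(r)) NA_character_ else r$odd
    }, character(1))
    table(factor(odd, c("A", "B", "C"))) / n
  }
  f0 <- freqs(0)
  expect_equal(unname(f0[["A"]]), 1 / 3, tolerance = 0.1)
  expect_equal(unname(f0[["C"]]), 1 / 3, tolerance = 0.1)
  f5 <- freqs(5)
  expect_equal(unname(f5[["C"]]), 1 - 2 / 3 * exp(-5), tolerance = 0.01)
})

test_that("discordant internal branches are Exp(1) in coalescent units", {
  sp <- parse_newick("((A:1,B:1):1,C:2);")
  gt <- simulate_msc(species_tree_model(sp), 4000, seed = 14)
  res <- lapply(gt, function(tr) {
    mm <- ape::mrca(tr); d <- ape::node.depth.edgelength(tr)
    phylodisc:::triplet_from_depths(c("A", "B", "C"), mm, d)
  })
  odd <- vapply(res, function(r) if (is.character(r)) NA else r$odd, "")
  tv <- vapply(res, function(r) if (is.character(r)) NA_real_ else r$t, 0)
  disc <- tv[!is.na(odd) & odd != "C"]
  expect_gt(length(disc), 500)
  expect_gt(stats::ks.test(disc, "pexp", 1)$p.value, 0.01)
})

test_that("identical seeds give identical simulations; gamma 0 is a no-op", {
  sp <- parse_newick("(((A:1,B:1):1,C:2):1,D:3);")
  m0 <- species_tree_model(sp)
  mg <- species_tree_model(sp, list(list(donor = "A", recipient = "B",
                                         time = 0.5, gamma = 0)))
  a <- simulate_msc(m0, 25, seed = 5)
  b <- simulate_msc(m0, 25, seed = 5)
  g <- simulate_msc(mg, 25, seed = 5)
  expect_identical(write_newick(a), write_newick(b))
  expect_identical(write_newick(a), write_newick(g))
})

test_that("an introgression pulse raises the donor-recipient pairing rate", {
  sp <- parse_newick("(((A:1,B:1):4,C:5):5,D:10);")
  m0 <- species_tree_model(sp)
  mg <- species_tree_model(sp, list(list(donor = "C", recipient = "A",
                                         time = 0.5, gamma = 0.5)))
  pair_rate <- function(trees) {
    mean(vapply(trees, function(tr) {
      mm <- ape::mrca(tr); d <- ape::node.depth.edgelength(tr)
      r <- phylodisc:::triplet_from_depths(c("A", "B", "C"), mm, d)
      !is.character(r) && r$odd == "B"      # (A, C) cherry
    }, logical(1)))
  }
  t0 <- simulate_msc(m0, 600, seed = 8)
  tg <- simulate_msc(mg, 600, seed = 8)
  expect_gt(pair_rate(tg), pair_rate(t0) + 0.2)
})

test_that("rate heterogeneity scales and noises branches as configured", {
  sp <- parse_newick("(((A:1,B:1):1,C:2):1,D:3);")
  gt <- simulate_msc(species_tree_model(sp), 100, seed = 3)
  # no noise, no locus spread: ultrametric trees stay clock-like
  cfg0 <- sim_config(n_loci = 100, seed = 4, rate_sdlog = 0,
                     branch_noise_shape = Inf)
  het0 <- apply_rate_heterogeneity(gt, cfg0)
  rtv <- vapply(het0$trees, root_to_tip_variance, numeric(1))
  expect_true(all(rtv < 1e-20))
  expect_true(all(het0$locus_rates == het0$locus_rates[1]))
  # tree length scales linearly with the drawn locus rate
  cfg1 <- sim_config(n_loci = 100, seed = 5, rate_sdlog = 0.8,
                     branch_noise_shape = Inf)
  het1 <- apply_rate_heterogeneity(gt, cfg1)
  ratio <- vapply(seq_along(gt), function(i)
    tree_length(het1$trees[[i]]) /
      (tree_length(gt[[i]]) * het1$locus_rates[i]), numeric(1))
  expect_equal(ratio, rep(cfg1$scale, 100), tolerance = 1e-10)
  # stronger branch noise -> larger mean root-to-tip variance
  het_lo <- apply_rate_heterogeneity(gt, sim_config(n_loci = 100, seed = 6,
    rate_sdlog = 0, branch_noise_shape = 100))
  het_hi <- apply_rate_heterogeneity(gt, sim_config(n_loci = 100, seed = 6,
    rate_sdlog = 0, branch_noise_shape = 2))
  expect_gt(mean(vapply(het_hi$trees, root_to_tip_variance, numeric(1))),
            mean(vapply(het_lo$trees, root_to_tip_variance, numeric(1))))
})

test_that("simulated gene-shopping loci show increasing variance by tercile", {
  toy <- make_toy_study(seed = 31, n_loci = 60, gamma = 0, n_alignments = 0)
  metrics <- locus_metrics(lapply(toy$subst_trees, root_at_outgroup, "out"),
                           root_at_outgroup(toy$species_tree, "out"))
  shopped <- gene_shop(metrics, min_bipartition = 0)
  mv <- tapply(shopped$root_to_tip_variance[shopped$set_label != "excluded"],
               shopped$set_label[shopped$set_label != "excluded"], mean)
  expect_true(mv[["set1"]] < mv[["set2"]] &&
                mv[["set2"]] < mv[["set3"]])
})

test_that("simulate_sequences follows JC69", {
  two <- parse_newick("(A:0.15,B:0.15);")   # tip distance 0.3
  a <- simulate_sequences(two, 4000, seed = 9)
  p <- mean(unclass(a)["A", ] != unclass(a)["B", ])
  expect_equal(p, 3 / 4 * (1 - exp(-4 * 0.3 / 3)), tolerance = 0.1)

  zero <- parse_newick("((A:0,B:0):0,C:0);")
  z <- simulate_sequences(zero, 200, seed = 10)
  expect_true(all(unclass(z)["A", ] == unclass(z)["B", ]))
  expect_true(all(unclass(z)["A", ] == unclass(z)["C", ]))

  s1 <- simulate_sequences(two, 100, seed = 11)
  s2 <- simulate_sequences(two, 100, seed = 11)
  expect_identical(unclass(s1)[, ], unclass(s2)[, ])
  expect_error(simulate_sequences(two, 0), "positive")
})

test_that("make_toy_study bundles a coherent fixture", {
  d <- tempfile()
  toy <- make_toy_study(seed = 2, n_loci = 30, dir = d)
  expect_length(toy$gene_trees, 30)
  expect_equal(length(toy$species_tree$tip.label), 19)
  expect_equal(sort(unique(unname(toy$taxon_map))),
               sort(c(paste0("g", 1:9), "outgroup")))
  expect_equal(toy$planted_pair, c("g2", "g7"))
  expect_length(toy$alignments, 10)
  expect_true(file.exists(file.path(d, "gene_trees.nwk")))
  expect_true(file.exists(file.path(d, "ground_truth.yaml")))
  # every gene tree covers all 19 tips; tabulation conserves counts
  expect_true(all(vapply(toy$gene_trees, function(tr)
    setequal(tr$tip.label, c(names(toy$taxon_map))), logical(1))))
  tri <- enumerate_triplets(c("g1_a", "g2_a", "g3_a", "g4_a"))
  tab <- tabulate_triplets(toy$subst_trees, tri, "out")
  expect_true(all(rowSums(tab$summary[, c("n1", "n2", "n3", "skipped")])
                  == 30))
})
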