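test_that("shared_bipartition_proportion counts shared splits", {
  sp <- parse_newick("((((A:1,B:1):1,C:1):1,D:1):1,E:1);")
  expect_equal(shared_bipartition_proportion(sp, sp), 1.0)
  # gene tree swaps B and C: only {A,B,C} is shared, of 2 gene splits
  g <- parse_newick("((((A:1,C:1):1,B:1):1,D:1):1,E:1);")
  expect_equal(shared_bipartition_proportion(g, sp), 0.5)
  expect_error(shared_bipartition_proportion(parse_newick("(A:1,(B:1,C:1):1);"),
                                             sp), "4 shared")
})

test_that("totally incompatible 6-taxon trees score 0", {
  sp <- parse_newick("(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,F:1):1);")
  g <- parse_newick("(((A:1,C:1):1,(E:1,B:1):1):1,(D:1,F:1):1);")
  expect_equal(shared_bipartition_proportion(g, sp), 0)
})

test_that("root_to_tip_variance is the n-1 sample variance of tip depths", {
  ultra <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(root_to_tip_variance(ultra), 0)
  two <- parse_newick("(A:1,B:3);")
  expect_equal(root_to_tip_variance(two), 2.0)
  relab <- parse_newick("(B:1,A:3);")
  expect_equal(root_to_tip_variance(relab), 2.0)
  expect_error(root_to_tip_variance(ape::unroot(
    parse_newick("((A:1,B:1):1,C:1,D:2);"))), "rooted")
})

test_that("tree_length sums branches and is rooting-invariant", {
  expect_equal(tree_length(parse_newick("(A:1,B:2);")), 3.0)
  set.seed(13)
  for (i in 1:10) {
    tr <- random_tree(8)
    expect_equal(tree_length(tr), sum(tr$edge.length))
    rr <- root_at_outgroup(ape::unroot(tr), sample(tr$tip.label, 1))
    expect_equal(tree_length(rr), tree_length(tr), tolerance = 1e-10)
  }
})

make_metrics <- function(bip, var, len = NULL) {
  n <- length(bip)
  data.frame(locus = sprintf("L%03d", seq_len(n)),
             bipartition_proportion = bip,
             root_to_tip_variance = var,
             tree_length = if (is.null(len)) rep(1, n) else len,
             stringsAsFactors = FALSE)
}

test_that("gene_shop filters at >= 0.3 and cuts equal terciles", {
  # 123 passing loci -> 41/41/41
  set.seed(8)
  m <- make_metrics(rep(0.5, 123), runif(123))
  shopped <- gene_shop(m)
  expect_equal(unname(table(shopped$set_label)[c("set1", "set2", "set3")]),
               c(41L, 41L, 41L), ignore_attr = TRUE)
  mani <- attr(shopped, "manifest")
  expect_equal(lengths(mani)[c("set1", "set2", "set3")],
               c(set1 = 41L, set2 = 41L, set3 = 41L))
  # set1 holds the lowest variances
  v1 <- max(shopped$root_to_tip_variance[shopped$set_label == "set1"])
  v3 <- min(shopped$root_to_tip_variance[shopped$set_label == "set3"])
  expect_lt(v1, v3)

  # threshold is "at least": 0.3 itself is retained
  m2 <- make_metrics(c(0.2, 0.5, 0.9, 0.4, 0.1, 0.35), 1:6)
  s2 <- gene_shop(m2, n_sets = 2)
  expect_equal(sum(s2$set_label != "excluded"), 4)
  m3 <- make_metrics(c(0.3, 0.3, 0.3), 1:3)
  expect_equal(sum(gene_shop(m3, n_sets = 3)$set_label != "excluded"), 3)

  # 6 passing -> 2/2/2, lowest two variances in set1
  m6 <- make_metrics(rep(1, 6), c(5, 1, 4, 2, 3, 6))
  s6 <- gene_shop(m6)
  expect_equal(sort(s6$locus[s6$set_label == "set1"]),
               sort(m6$locus[order(m6$root_to_tip_variance)][1:2]))
  expect_error(gene_shop(make_metrics(c(0.5, 0.5), 1:2), n_sets = 3),
               "at least")
})

test_that("gene_shop set sizes differ by at most one and partition retained", {
  set.seed(21)
  for (n in c(7, 10, 100, 123)) {
    m <- make_metrics(rep(1, n), runif(n))
    s <- gene_shop(m)
    sizes <- lengths(attr(s, "manifest"))
    expect_lte(diff(range(sizes)), 1)
    expect_setequal(unlist(attr(s, "manifest")), m$locus)
  }
})

test_that("lowest_variance_subset picks the k smallest variances", {
  m <- make_metrics(rep(1, 5), c(5, 1, 4, 2, 3))
  expect_setequal(lowest_variance_subset(m, 2), c("L002", "L004"))
  expect_setequal(lowest_variance_subset(m, 5), m$locus)
  expect_error(lowest_variance_subset(m, 6), "exceeds")
  s <- gene_shop(m)
  retained <- s[s$set_label != "excluded", ]
  expect_true(all(lowest_variance_subset(retained, 3) %in% retained$locus))
})

test_that("quartet score is 1 for self-concordant gene trees", {
  sp <- parse_newick("(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,F:1):1);")
  qs <- quartet_scores(sp, list(sp, sp, sp), mode = "exhaustive")
  expect_equal(qs$score, 1.0)
  expect_true(all(qs$branch_support$support_pct == 100))
  expect_false(qs$undefined)
})

test_that("quartet score matches brute-force enumeration with an NNI tree", {
  sp <- parse_newick("((((A:1,B:1):1,C:1):1,D:1):1,E:1);")
  g1 <- sp
  g2 <- sp
  g3 <- parse_newick("((((A:1,C:1):1,B:1):1,D:1):1,E:1);")  # one NNI away
  trees <- list(g1, g2, g3)
  qs <- quartet_scores(sp, trees, mode = "exhaustive")
  # oracle: enumerate all 5 quartets x 3 trees independently via pruning
  taxa <- sort(sp$tip.label)
  quartets <- combn(taxa, 4, simplify = FALSE)
  nres <- 0; ncon <- 0
  for (q in quartets) {
    sq <- quartet_topology_oracle(sp, q)
    for (tr in trees) {
      gq <- quartet_topology_oracle(tr, q)
      if (is.na(gq) || gq == 0) next
      nres <- nres + 1
      if (gq == sq) ncon <- ncon + 1
    }
  }
  expect_equal(qs$score, ncon / nres)
  expect_equal(qs$n_resolved, nres)
})

test_that("star gene trees leave the quartet score undefined", {
  sp <- parse_newick("(((A:1,B:1):1,C:1):1,D:1);")
  star <- parse_newick("(A:1,B:1,C:1,D:1);")
  qs <- quartet_scores(sp, list(star), mode = "exhaustive")
  expect_true(qs$undefined)
  expect_true(is.na(qs$score))
})

test_that("sampled quartet support is reproducible given the seed", {
  set.seed(1)
  sp <- random_tree(8)
  gts <- lapply(1:4, function(i) random_tree(8))
  a <- quartet_scores(sp, gts, mode = "sampled", n_samples_per_branch = 50,
                      seed = 5)
  b <- quartet_scores(sp, gts, mode = "sampled", n_samples_per_branch = 50,
                      seed = 5)
  expect_identical(a$branch_support, b$branch_support)
  expect_error(quartet_scores(sp, gts, mode = "sampled",
                              n_samples_per_branch = 0), "positive")
})

test_that("build_dating_sets concatenates, pads and round-trips", {
  a1 <- locus_alignment(matrix("A", 3, 10,
        dimnames = list(c("t1", "t2", "t3"), NULL)))
  a2 <- locus_alignment(matrix("C", 2, 15,
        dimnames = list(c("t1", "t2"), NULL)))
  sets <- build_dating_sets(list(L1 = a1, L2 = a2),
                            list(set1 = "L1", set2 = "L2"))
  expect_equal(ncol(sets$combined), 25)
  expect_equal(sets$partitions$start, c(1L, 11L))
  expect_equal(sets$partitions$end, c(10L, 25L))
  # t3 missing from L2 -> gap padded over 11..25
  expect_true(all(unclass(sets$combined)["t3", 11:25] == "-"))
  # deconcatenation recovers the inputs
  part <- sets$partitions
  back1 <- unclass(sets$combined)[rownames(a1), part$start[1]:part$end[1]]
  expect_equal(unname(back1), unname(unclass(a1)[, ]))
  expect_error(build_dating_sets(list(L1 = a1), list(set1 = c("L1", "LX"))),
               "without alignments")
})

test_that("dating-set export writes phylip, nexus and partition files", {
  a1 <- locus_alignment(matrix("A", 2, 4, dimnames = list(c("t1", "t2"), NULL)))
  a2 <- locus_alignment(matrix("G", 2, 6, dimnames = list(c("t1", "t2"), NULL)))
  sets <- build_dating_sets(list(L1 = a1, L2 = a2),
                            list(set1 = "L1", set2 = "L2"))
  d <- tempfile()
  paths <- write_dating_sets(sets, d)
  expect_true(all(file.exists(paths)))
  part <- readLines(file.path(d, "dating_partitions.txt"))
  expect_equal(part, c("DNA, set1 = 1-4", "DNA, set2 = 5-10"))
  phy <- readLines(file.path(d, "dating_concat.phy"))
  expect_equal(phy[1], "2 10")
})
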