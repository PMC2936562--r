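test_that("alignment spec rejects inconsistent parameters", {
  expect_error(sim_alignment_spec(5, 10, n_fixed = 8, n_poly_a = 3),
               "exceed length")
  expect_error(sim_alignment_spec(5, 100, n_fixed = -1), ">= 0")
  expect_error(sim_alignment_spec(0, 100), "n_per_group")
  expect_error(sim_alignment_spec(5, 100, frame_offset = 3), "frame_offset")
})

test_that("a spec without injected variation yields identical sequences", {
  sim <- make_two_group_alignment(sim_alignment_spec(5, 100, seed = 7))
  expect_equal(nrow(sim$alignment), 10L)
  expect_equal(ncol(sim$alignment), 100L)
  expect_true(all(apply(sim$alignment, 2, function(c) length(unique(c)) == 1)))
})

test_that("a tiny hand-enumerable spec gives 3 disjoint variable sites", {
  sim <- make_two_group_alignment(
    sim_alignment_spec(2, 9, n_fixed = 1, n_poly_a = 1, n_poly_b = 1,
                       seed = 3))
  vs <- variable_sites(sim$alignment)
  expect_length(vs, 3L)
  truth_sites <- with(sim$truth, c(fixed_sites, poly_a_sites, poly_b_sites))
  expect_false(anyDuplicated(truth_sites) > 0)
  expect_setequal(vs, truth_sites)
  # exhaustive scan of the 9 columns agrees with the classifier
  bc <- brute_classify(sim$alignment, sim$partition)
  cls <- classify_sites(sim$alignment, sim$partition)
  expect_equal(stats::setNames(cls$category, cls$site), bc)
})

test_that("classifier recovers injected counts exactly for all seeds", {
  for (seed in 1:6) {
    set.seed(seed + 1000)
    n_fixed <- sample(0:30, 1); n_pa <- sample(0:10, 1); n_pb <- sample(0:10, 1)
    sim <- make_two_group_alignment(
      sim_alignment_spec(5, 400, n_fixed, n_pa, n_pb, seed = seed))
    cls <- classify_sites(sim$alignment, sim$partition)
    expect_equal(sum(cls$category == "fixed_difference"), n_fixed)
    expect_equal(sum(cls$category == "polymorphic_A"), n_pa)
    expect_equal(sum(cls$category == "polymorphic_B"), n_pb)
    expect_equal(sum(cls$category == "polymorphic_both"), 0L)
  }
})

test_that("codon-aware injection controls the coding effect of fixed sites", {
  eff <- rep(c("nonsynonymous", "synonymous"), c(7, 5))
  sim <- make_two_group_alignment(
    sim_alignment_spec(5, 300, n_fixed = 12, seed = 9), fixed_effects = eff)
  cls <- classify_sites(sim$alignment, sim$partition, frame_offset = 0)
  expect_equal(sum(cls$coding_effect == "nonsynonymous"), 7L)
  expect_equal(sum(cls$coding_effect == "synonymous"), 5L)
  expect_equal(cls$coding_effect[match(sim$truth$fixed_sites, cls$site)],
               sim$truth$effects)
})

test_that("same seed reproduces byte-identical simulations", {
  s <- sim_alignment_spec(5, 200, 4, 2, 1, seed = 42)
  expect_identical(make_two_group_alignment(s), make_two_group_alignment(s))
  ts <- tree_sim_spec(ape::rtree(5, br = 0.1), 100, seed = 11)
  expect_identical(evolve_on_tree(ts), evolve_on_tree(ts))
  tb <- sim_table_spec(10, seed = 5)
  expect_identical(make_genotype_table(tb), make_genotype_table(tb))
})

test_that("zero branch lengths evolve identical sequences", {
  tr <- ape::read.tree(text = "(a:0,b:0);")
  aln <- evolve_on_tree(tree_sim_spec(tr, 500, seed = 2))
  expect_identical(aln["a", ], aln["b", ])
})

test_that("infinite-sites simulations are homoplasy-free on their own tree", {
  tr <- ape::read.tree(text = "((a:0.05,b:0.08):0.04,(c:0.06,d:0.05):0.03);")
  for (seed in 1:5) {
    aln <- evolve_on_tree(tree_sim_spec(tr, 3000, seed = seed),
                          infinite_sites = TRUE)
    h <- detect_homoplasies(ancestral_changes(tr, aln, "parsimony"))
    expect_equal(attr(h, "total"), 0L)
  }
})

test_that("substitution fraction on a branch matches the model expectation", {
  b <- 0.1; L <- 100000L
  tr <- ape::read.tree(text = sprintf("(a:%f,b:0);", b))
  aln <- evolve_on_tree(tree_sim_spec(tr, L, kappa = 1, seed = 13))
  p_obs <- mean(aln["a", ] != aln["b", ])
  p_exp <- 3 / 4 * (1 - exp(-4 * b / 3))      # JC closed form (kappa = 1)
  se <- sqrt(p_exp * (1 - p_exp) / L)
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("genotype tables honour trivial edge cases and record truth", {
  all_n <- make_genotype_table(sim_table_spec(8, snp_rate = 6, n_rate = 1,
                                              diff_rate = 0.5, seed = 1))
  cnt <- count_differences_per_gene(all_n$table, "WSB", "PWD", all_n$genes)
  expect_true(all(cnt$n_differing == 0))

  no_diff <- make_genotype_table(sim_table_spec(8, snp_rate = 6, n_rate = 0.1,
                                                diff_rate = 0, seed = 2))
  cnt2 <- count_differences_per_gene(no_diff$table, "WSB", "PWD", no_diff$genes)
  expect_true(all(cnt2$n_differing == 0))

  sim <- make_genotype_table(sim_table_spec(10, snp_rate = 5, n_rate = 0.2,
                                            diff_rate = 0.3, seed = 11))
  cnt3 <- count_differences_per_gene(sim$table, "WSB", "PWD", sim$genes)
  expect_equal(cnt3$n_differing, sim$truth$n_differing)
})

test_that("the synthetic study fixture carries its designed structure", {
  st <- synthetic_study(seed = 4)
  expect_named(st$alignments, c("Vmn1r67", "Vmn1r71", "Abpa27"))
  expect_equal(ncol(st$alignments$Vmn1r67), 915L)
  expect_equal(ncol(st$alignments$Vmn1r71), 921L)
  expect_equal(ncol(st$alignments$Abpa27), 1185L)
  expect_equal(nrow(st$cross_taxon), 9L)
  expect_length(st$truth$homoplasy_sites, 19L)
  # same seed, same study
  expect_identical(synthetic_study(seed = 4), st)
})
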