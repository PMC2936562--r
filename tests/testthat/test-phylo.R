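test_that("F84 distance is zero for identical sequences", {
  aln <- random_alignment(2, 200, 1)
  expect_equal(f84_pairwise(aln[1, ], aln[1, ]), 0)
})

test_that("F84 reduces to the K80 and JC69 closed forms in their limits", {
  # engineered pair with exactly uniform pooled base composition:
  # balanced transition blocks (A<->G, C<->T) and transversion blocks
  # (A<->C, G<->T) on top of matched ACGT repeats
  block_same <- c("A", "C", "G", "T")
  block_ts <- rbind(c("A", "G", "C", "T"), c("G", "A", "T", "C"))
  block_tv <- rbind(c("A", "C", "G", "T"), c("C", "A", "T", "G"))
  x <- c(rep(block_same, 27), block_ts[1, ], block_tv[1, ], block_tv[1, ])
  y <- c(rep(block_same, 27), block_ts[2, ], block_tv[2, ], block_tv[2, ])
  # 120 sites, 4 transitions, 8 transversions: P = 1/30, Q = 1/15
  P <- 4 / 120; Q <- 8 / 120
  d <- f84_pairwise(x, y)
  expect_equal(d, k80_distance(P, Q), tolerance = 1e-12)
  # with transitions at one third of all differences this equals JC69
  expect_equal(d, jc_distance(P + Q), tolerance = 1e-12)
})

test_that("F84 agrees with an independent pairwise implementation", {
  for (seed in 1:4) {
    tr <- ape::read.tree(text = "(a:0.08,b:0.07);")
    aln <- evolve_on_tree(tree_sim_spec(tr, 3000, kappa = 3,
                                        base_freqs = c(0.3, 0.2, 0.3, 0.2),
                                        seed = seed))
    ours <- f84_pairwise(aln["a", ], aln["b", ])
    bin <- ape::as.DNAbin(list(a = tolower(aln["a", ]),
                               b = tolower(aln["b", ])))
    oracle <- as.numeric(ape::dist.dna(bin, model = "F84"))
    expect_equal(ours, oracle, tolerance = 1e-8)
  }
})

test_that("simulated divergence is re-estimated consistently", {
  tr <- ape::read.tree(text = "(a:0.1,b:0);")
  aln <- evolve_on_tree(tree_sim_spec(tr, 100000L, kappa = 2, seed = 17))
  d <- f84_pairwise(aln["a", ], aln["b", ])
  # delta-method standard error at d = 0.1 over 1e5 sites is ~1e-3
  expect_lt(abs(d - 0.1), 3 * 1.2e-3)
})

test_that("saturated pairs are flagged as Inf", {
  x <- rep(c("A", "C", "G", "T"), 25)
  y <- rep(c("C", "A", "T", "G"), 25)       # every site a transversion
  expect_warning(d <- f84_pairwise(x, y), "saturated")
  expect_equal(d, Inf)
})

test_that("three-taxon NJ branch lengths follow the closed form", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["a"]], 1)
  expect_equal(bl[["b"]], 2)
  expect_equal(bl[["c"]], 3)
})

test_that("NJ recovers tree and branch lengths from an additive matrix", {
  true <- ape::read.tree(text = "((a:2,b:3):1,((c:1.5,d:4):2,e:6):0.5);")
  D <- ape::cophenetic.phylo(true)
  nj <- neighbor_joining(D)
  expect_equal(phangorn::RF.dist(ape::unroot(nj), ape::unroot(true)), 0)
  # all pairwise path distances reproduced to 1e-9
  expect_equal(ape::cophenetic.phylo(nj)[rownames(D), colnames(D)], D,
               tolerance = 1e-9)
  # independent implementation agrees on the topology
  expect_equal(phangorn::RF.dist(ape::unroot(nj),
                                 ape::unroot(ape::nj(D))), 0)
})

test_that("taxon input order does not change the NJ topology", {
  true <- ape::read.tree(text = "((a:1,b:2):1,((c:2,d:1):1,e:3):1,f:4);")
  D <- ape::cophenetic.phylo(true)
  nj1 <- neighbor_joining(D)
  perm <- c("d", "a", "f", "b", "e", "c")
  nj2 <- neighbor_joining(D[perm, perm])
  expect_equal(phangorn::RF.dist(ape::unroot(nj1), ape::unroot(nj2)), 0)
})

test_that("non-symmetric distance input is rejected", {
  D <- matrix(c(0, 1, 2, 9, 0, 3, 2, 3, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_error(neighbor_joining(D), "symmetric")
})

test_that("negative branch estimates are clamped and flagged", {
  D <- matrix(c(0, 1, 6, 6, 1, 0, 6, 6, 6, 6, 0, 0.2, 6, 6, 0.2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(D)
  expect_true(all(tr$edge.length >= 0))
  expect_gte(attr(tr, "clamped"), 0)
})

test_that("bootstrap support behaves at its fixed points", {
  # strains b1 and b2 identical, all others at moderate divergence
  tr <- ape::read.tree(text = "((b1:0.06,c:0.05):0.04,(d:0.05,e:0.06):0.03);")
  base <- evolve_on_tree(tree_sim_spec(tr, 300, seed = 5))
  m <- rbind(unclass(base), b2 = base["b1", ])
  aln <- strain_alignment(m)
  bs <- bootstrap_support(aln, n_reps = 30, seed = 1)
  # bipartition keys are canonicalized to the side without the first tip
  key <- paste(sort(setdiff(rownames(aln), c("b1", "b2"))), collapse = "|")
  expect_true(key %in% names(bs$support))
  expect_equal(unname(bs$support[key]), 100)
  # single replicate: supports are 0 or 100
  bs1 <- bootstrap_support(aln, n_reps = 1, seed = 3)
  expect_true(all(bs1$support %in% c(0, 100)))
})

test_that("bootstrap is reproducible for a fixed seed", {
  tr <- ape::read.tree(text = "((a:0.05,b:0.05):0.05,(c:0.05,d:0.05):0.02,e:0.1);")
  aln <- evolve_on_tree(tree_sim_spec(tr, 600, seed = 8))
  b1 <- bootstrap_support(aln, n_reps = 100, seed = 42)
  b2 <- bootstrap_support(aln, n_reps = 100, seed = 42)
  expect_identical(b1$support, b2$support)
  expect_error(bootstrap_support(aln, n_reps = 10), "seed")
})
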