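two_group <- function(a_seqs, b_seqs) {
  names(a_seqs) <- paste0("a", seq_along(a_seqs))
  names(b_seqs) <- paste0("b", seq_along(b_seqs))
  list(aln = strain_alignment(c(a_seqs, b_seqs)),
       part = group_partition(A = names(a_seqs), B = names(b_seqs)))
}

test_that("identical sequences have no variable sites", {
  x <- two_group(rep("ACGTACGT", 2), rep("ACGTACGT", 2))
  expect_length(variable_sites(x$aln), 0L)
  expect_equal(nrow(classify_sites(x$aln, x$part)), 0L)
})

test_that("columns with N or gaps are excluded by complete deletion", {
  x <- two_group(c("ACGT", "ACGT"), c("NCTA", "AC-T"))
  # col 1 has N, col 3 has gap -> only cols 2 and 4 are included; col 4 varies
  expect_equal(included_sites(x$aln), c(2L, 4L))
  expect_equal(variable_sites(x$aln), 4L)
})

test_that("site categories partition the variable sites", {
  for (seed in 1:5) {
    aln <- random_alignment(8, 60, seed)
    part <- group_partition(A = paste0("s", 1:4), B = paste0("s", 5:8))
    cls <- classify_sites(aln, part)
    expect_setequal(cls$site, variable_sites(aln))
    expect_equal(anyDuplicated(cls$site), 0L)
    expect_equal(stats::setNames(cls$category, cls$site),
                 brute_classify(aln, part))
  }
})

test_that("relabeling groups swaps the polymorphic categories", {
  aln <- random_alignment(8, 80, 21)
  pAB <- group_partition(A = paste0("s", 1:4), B = paste0("s", 5:8))
  pBA <- group_partition(A = paste0("s", 5:8), B = paste0("s", 1:4))
  c1 <- classify_sites(aln, pAB)
  c2 <- classify_sites(aln, pBA)
  swap <- c(fixed_difference = "fixed_difference",
            polymorphic_A = "polymorphic_B", polymorphic_B = "polymorphic_A",
            polymorphic_both = "polymorphic_both")
  expect_equal(stats::setNames(unname(swap[c1$category]), c1$site),
               stats::setNames(c2$category, c2$site))
})

test_that("duplicating a sequence never creates a new fixed difference", {
  for (seed in 6:9) {
    aln <- random_alignment(6, 60, seed)
    part <- group_partition(A = paste0("s", 1:3), B = paste0("s", 4:6))
    fixed_before <- with(classify_sites(aln, part),
                         site[category == "fixed_difference"])
    m <- rbind(unclass(aln), dup = aln["s1", ])
    aln2 <- strain_alignment(m)
    part2 <- group_partition(stats::setNames(c(unclass(part), "A"),
                                             c(names(part), "dup")))
    fixed_after <- with(classify_sites(aln2, part2),
                        site[category == "fixed_difference"])
    expect_true(all(fixed_after %in% fixed_before))
  }
})

test_that("coding effect follows the standard genetic code", {
  # GGA -> GGG: 4-fold degenerate glycine, synonymous
  x <- two_group(c("GGAAAA", "GGAAAA"), c("GGGAAA", "GGGAAA"))
  expect_equal(coding_effect(x$aln, x$part, 3, 0), "synonymous")
  # ATG -> CTG: Met -> Leu, nonsynonymous
  y <- two_group(c("ATGAAA", "ATGAAA"), c("CTGAAA", "CTGAAA"))
  expect_equal(coding_effect(y$aln, y$part, 1, 0), "nonsynonymous")
})

test_that("truncated or ambiguous codons are not assessed", {
  # 7 bp: site 7 sits in an incomplete codon for frame 0
  x <- two_group(c("ATGAAAT", "ATGAAAT"), c("ATGAAAG", "ATGAAAG"))
  expect_equal(coding_effect(x$aln, x$part, 7, 0), "not_assessed")
  # frame 1 shifts site 2 ahead of the first complete codon
  y <- two_group(c("TATGAA", "TATGAA"), c("TCTGAA", "TCTGAA"))
  expect_equal(coding_effect(y$aln, y$part, 2, 1), "nonsynonymous")
  expect_equal(coding_effect(y$aln, y$part, 1, 1), "not_assessed")
  # N in the consensus codon
  z <- two_group(c("ANGAAA", "ANGAAA"), c("CNGAAA", "CNGAAA"))
  expect_equal(coding_effect(z$aln, z$part, 1, 0), "not_assessed")
})

test_that("joint codon comparison differs only for multi-hit codons", {
  # codon with two fixed differences: AAA (Lys) vs GAG (Glu)
  x <- two_group(c("AAA", "AAA"), c("GAG", "GAG"))
  # site-wise: AAA->GAA (Lys->Glu) nonsynonymous at position 1
  expect_equal(coding_effect(x$aln, x$part, 1, 0), "nonsynonymous")
  # site-wise at position 3: AAA->AAG is synonymous (Lys)
  expect_equal(coding_effect(x$aln, x$part, 3, 0), "synonymous")
  # joint: AAA vs GAG, Lys vs Glu, nonsynonymous at both sites
  expect_equal(coding_effect(x$aln, x$part, 3, 0, joint_codon = TRUE),
               "nonsynonymous")
})

test_that("diversity matches hand values and the brute-force oracle", {
  # monomorphic group
  x <- strain_alignment(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT"))
  d0 <- diversity(x)
  expect_equal(d0$S, 0L)
  expect_equal(d0$pi, 0)
  expect_equal(d0$theta_w, 0)
  # n = 2, one difference in 100 bp: pi = theta = 0.01 (a_1 = 1)
  y <- strain_alignment(c(a = paste(rep("A", 100), collapse = ""),
                          b = paste(c("C", rep("A", 99)), collapse = "")))
  dy <- diversity(y)
  expect_equal(dy$pi, 0.01)
  expect_equal(dy$theta_w, 0.01)
  # random alignments: brute-force pairwise enumeration to 1e-12
  for (seed in 1:5) {
    aln <- random_alignment(5, 50, seed + 50)
    dv <- diversity(aln)
    expect_equal(dv$pi, brute_pi(aln), tolerance = 1e-12)
    # integer recovery: theta_w * a_n * L_eff = S exactly
    expect_equal(dv$theta_w * dv$a_n * dv$L_eff, dv$S, tolerance = 1e-12)
  }
})

test_that("diversity input contracts are enforced", {
  x <- strain_alignment(c(a = "ACGT", b = "ACGT"))
  expect_error(diversity(x, "a"), "at least two")
  allN <- strain_alignment(c(a = "NNNN", b = "NNNN"))
  expect_error(diversity(allN), "L_eff = 0")
})
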