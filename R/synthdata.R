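# Synthetic-data generators: two-group alignments with injected fixed
# differences and private polymorphisms, sequences evolved on a tree under
# HKY (with an infinite-sites option), and Perlegen-style strain genotype
# tables with recorded ground truth.

#' Specification for a two-group alignment simulation
#'
#' @param n_per_group strains per group (the study design sampled 5
#'   wild-derived inbred strains per subspecies).
#' @param length alignment length in bp.
#' @param n_fixed number of inter-group fixed differences to inject.
#' @param n_poly_a,n_poly_b numbers of private polymorphisms within group A
#'   and group B respectively.
#' @param frame_offset reading-frame start (0, 1 or 2).
#' @param seed integer seed; same seed, same output.
#' @return list of class `sim_alignment_spec`.
#' @export
sim_alignment_spec <- function(n_per_group = 5L, length = 915L,
                               n_fixed = 0L, n_poly_a = 0L, n_poly_b = 0L,
                               frame_offset = 0L, seed = 1L) {
  if (n_per_group < 1L) stop("n_per_group must be >= 1")
  if (any(c(n_fixed, n_poly_a, n_poly_b) < 0)) stop("counts must be >= 0")
  if (n_fixed + n_poly_a + n_poly_b > length)
    stop("n_fixed + n_poly_a + n_poly_b must not exceed length")
  if (!frame_offset %in% 0:2) stop("frame_offset must be 0, 1 or 2")
  structure(list(n_per_group = as.integer(n_per_group),
                 length = as.integer(length), n_fixed = as.integer(n_fixed),
                 n_poly_a = as.integer(n_poly_a), n_poly_b = as.integer(n_poly_b),
                 frame_offset = as.integer(frame_offset),
                 seed = as.integer(seed)),
            class = "sim_alignment_spec")
}

# codon edits with a known coding effect, all avoiding stop codons:
# list of (group-A codon, codon position of the edit, group-B base)
SYN_EDITS <- list(c("GGA", 3, "G"), c("GCT", 3, "C"), c("CCA", 3, "G"),
                  c("ACC", 3, "T"), c("GTA", 3, "G"), c("CGT", 3, "C"))
NONSYN_EDITS <- list(c("ATG", 1, "C"), c("AAA", 2, "G"), c("GCA", 2, "A"),
                     c("TTT", 2, "G"), c("GAT", 1, "C"), c("CAT", 2, "G"))

#' Simulate a two-group multi-strain alignment with injected variants
#'
#' Generates `2 * n_per_group` equal-length haploid sequences over a random
#' background (uniform base composition by default) and injects, at
#' non-overlapping positions: `n_fixed` sites at which the two groups are
#' internally monomorphic for different nucleotides, and `n_poly_a` /
#' `n_poly_b` sites variable only within one group (singleton minor
#' alleles by default). With `fixed_effects` supplied, each fixed
#' difference is placed inside its own codon (relative to `frame_offset`)
#' engineered to be synonymous or nonsynonymous as requested.
#'
#' @param spec a [sim_alignment_spec()].
#' @param fixed_effects optional character vector of length `n_fixed` with
#'   values `"synonymous"` / `"nonsynonymous"` controlling the coding
#'   effect of each injected fixed difference.
#' @param minor_copies number of strains carrying the minor allele at
#'   injected polymorphic sites (default 1, a singleton).
#' @param strains optional vector of `2 * n_per_group` strain names
#'   (group A first); defaults to `A1..`, `B1..`.
#' @param base_freqs background base composition (default uniform).
#' @return list with elements `alignment` (a `strain_alignment`),
#'   `partition` (a `group_partition`) and `truth` (injected site indices
#'   and effects, for oracle testing).
#' @export
make_two_group_alignment <- function(spec, fixed_effects = NULL,
                                     minor_copies = 1L, strains = NULL,
                                     base_freqs = rep(0.25, 4)) {
  stopifnot(inherits(spec, "sim_alignment_spec"))
  if (!is.null(fixed_effects)) {
    if (length(fixed_effects) != spec$n_fixed)
      stop("fixed_effects must have length n_fixed")
    if (!all(fixed_effects %in% c("synonymous", "nonsynonymous")))
      stop("fixed_effects values must be 'synonymous' or 'nonsynonymous'")
  }
  if (minor_copies < 1L || minor_copies >= spec$n_per_group)
    if (spec$n_poly_a + spec$n_poly_b > 0)
      stop("minor_copies must be in [1, n_per_group - 1]")
  set.seed(spec$seed)
  n <- spec$n_per_group
  L <- spec$length
  if (is.null(strains))
    strains <- c(paste0("A", seq_len(n)), paste0("B", seq_len(n)))
  stopifnot(length(strains) == 2L * n)
  background <- sample(NUC, L, replace = TRUE, prob = base_freqs)
  m <- matrix(rep(background, each = 2L * n), nrow = 2L * n,
              dimnames = list(strains, NULL))
  a_rows <- seq_len(n); b_rows <- n + seq_len(n)

  if (is.null(fixed_effects)) {
    pos <- sample.int(L, spec$n_fixed + spec$n_poly_a + spec$n_poly_b)
    fixed_sites <- sort(pos[seq_len(spec$n_fixed)])
    poly_a_sites <- sort(pos[spec$n_fixed + seq_len(spec$n_poly_a)])
    poly_b_sites <- sort(pos[spec$n_fixed + spec$n_poly_a +
                               seq_len(spec$n_poly_b)])
    effects <- NULL
    for (s in fixed_sites) {
      ab <- sample(NUC, 2)
      m[a_rows, s] <- ab[1]; m[b_rows, s] <- ab[2]
    }
  } else {
    # codon-aware placement: each injected site gets its own codon
    n_codons <- (L - spec$frame_offset) %/% 3
    need <- spec$n_fixed + spec$n_poly_a + spec$n_poly_b
    if (need > n_codons)
      stop("not enough complete codons for codon-aware placement")
    codons <- sample.int(n_codons, need)
    codon_cols <- function(ci) spec$frame_offset + (ci - 1L) * 3L + 1:3
    fixed_sites <- integer(spec$n_fixed)
    for (i in seq_len(spec$n_fixed)) {
      edit_pool <- if (fixed_effects[i] == "synonymous") SYN_EDITS else NONSYN_EDITS
      e <- edit_pool[[sample.int(length(edit_pool), 1)]]
      cols <- codon_cols(codons[i])
      cod <- strsplit(e[[1]], "")[[1]]
      p <- as.integer(e[[2]])
      for (r in seq_len(2L * n)) m[r, cols] <- cod
      m[b_rows, cols[p]] <- e[[3]]
      fixed_sites[i] <- cols[p]
    }
    poly_cols <- unlist(lapply(codons[spec$n_fixed + seq_len(spec$n_poly_a +
                                                               spec$n_poly_b)],
                               codon_cols))
    poly_pick <- poly_cols[seq(2, by = 3,
                               length.out = spec$n_poly_a + spec$n_poly_b)]
    poly_a_sites <- sort(poly_pick[seq_len(spec$n_poly_a)])
    poly_b_sites <- sort(poly_pick[spec$n_poly_a + seq_len(spec$n_poly_b)])
    ord <- order(fixed_sites)
    effects <- fixed_effects[ord]
    fixed_sites <- fixed_sites[ord]
  }
  inject_poly <- function(m, sites, rows) {
    for (s in sites) {
      carriers <- rows[sample.int(length(rows), minor_copies)]
      alt <- sample(setdiff(NUC, m[rows[1], s]), 1)
      m[carriers, s] <- alt
    }
    m
  }
  m <- inject_poly(m, poly_a_sites, a_rows)
  m <- inject_poly(m, poly_b_sites, b_rows)
  list(alignment = strain_alignment(m),
       partition = group_partition(stats::setNames(rep(c("A", "B"), each = n),
                                                   strains)),
       truth = list(fixed_sites = fixed_sites, poly_a_sites = poly_a_sites,
                    poly_b_sites = poly_b_sites, effects = effects))
}

#' Specification for evolving sequences on a tree
#'
#' @param tree an ape `phylo` tree with branch lengths in expected
#'   substitutions per site (all >= 0).
#' @param length number of sites.
#' @param base_freqs stationary base frequencies (sum to 1 within 1e-9).
#' @param kappa HKY transition/transversion rate ratio.
#' @param seed integer seed.
#' @return list of class `tree_sim_spec`.
#' @export
tree_sim_spec <- function(tree, length, base_freqs = rep(0.25, 4),
                          kappa = 2, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L) stop("tree must have >= 2 leaves")
  if (length < 1L) stop("zero-length alignment request")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree must carry nonnegative branch lengths")
  if (abs(sum(base_freqs) - 1) > 1e-9) stop("base frequencies must sum to 1")
  structure(list(tree = tree, length = as.integer(length),
                 base_freqs = base_freqs, kappa = kappa,
                 seed = as.integer(seed)),
            class = "tree_sim_spec")
}

#' Evolve sequences along a tree
#'
#' Simulates independent sites under an HKY model down the supplied tree
#' (root sequence drawn from the stationary distribution). With
#' `infinite_sites = TRUE`, substitution events are drawn per branch as
#' Poisson(branch length x sites) and every event hits a previously
#' untouched site, so no recurrent changes can exist by construction.
#'
#' @param spec a [tree_sim_spec()].
#' @param infinite_sites logical, see above.
#' @return a `strain_alignment` with one row per tree leaf.
#' @export
evolve_on_tree <- function(spec, infinite_sites = FALSE) {
  stopifnot(inherits(spec, "tree_sim_spec"))
  set.seed(spec$seed)
  tree <- ape::reorder.phylo(spec$tree, "cladewise")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  L <- spec$length
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- sample(NUC, L, replace = TRUE, prob = spec$base_freqs)
  if (infinite_sites) {
    used <- logical(L)
    # mark ancestrally injected... only mutation events consume fresh sites
    for (k in seq_len(nrow(tree$edge))) {
      p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
      s <- seqs[[p]]
      n_mut <- stats::rpois(1, tree$edge.length[k] * L)
      if (n_mut > 0) {
        free <- which(!used)
        if (length(free) < n_mut)
          stop("infinite-sites simulation ran out of fresh sites; increase length")
        hit <- free[sample.int(length(free), n_mut)]
        used[hit] <- TRUE
        for (h in hit) s[h] <- sample(setdiff(NUC, s[h]), 1)
      }
      seqs[[ch]] <- s
    }
  } else {
    Q <- hky_rate_matrix(spec$base_freqs, spec$kappa)
    Pcache <- new.env()
    getP <- function(b) {
      key <- sprintf("%.12g", b)
      if (is.null(Pcache[[key]]))
        Pcache[[key]] <- hky_prob_matrix(b, spec$base_freqs, spec$kappa, Q = Q)
      Pcache[[key]]
    }
    for (k in seq_len(nrow(tree$edge))) {
      p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
      s <- seqs[[p]]
      P <- getP(tree$edge.length[k])
      out <- character(L)
      for (b in NUC) {
        idx <- which(s == b)
        if (length(idx))
          out[idx] <- sample(NUC, length(idx), replace = TRUE, prob = P[b, ])
      }
      seqs[[ch]] <- out
    }
  }
  m <- do.call(rbind, seqs[seq_len(ntip)])
  rownames(m) <- tree$tip.label
  strain_alignment(m)
}

#' Specification for a synthetic strain genotype table
#'
#' @param n_genes number of genes (>= 1).
#' @param snp_rate expected SNPs per gene (Poisson).
#' @param n_rate probability that any single genotype call is masked to
#'   `"N"` (ambiguous), independently per strain and SNP.
#' @param diff_rate probability that a SNP has differing underlying
#'   genotypes in the two focal strains.
#' @param seed integer seed.
#' @param strains strain (column) names; the first two are the focal pair.
#' @param pseudogene_rate probability a gene is flagged as a pseudogene.
#' @return list of class `sim_table_spec`.
#' @export
sim_table_spec <- function(n_genes, snp_rate = 5, n_rate = 0.2,
                           diff_rate = 0.3, seed = 1L,
                           strains = c("WSB", "PWD", "LEWES", "CZECHI"),
                           pseudogene_rate = 0.2) {
  if (n_genes < 1L) stop("n_genes must be >= 1")
  for (p in c(n_rate, diff_rate, pseudogene_rate))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  if (snp_rate < 0) stop("snp_rate must be >= 0")
  if (length(strains) < 2L) stop("need at least the two focal strains")
  structure(list(n_genes = as.integer(n_genes), snp_rate = snp_rate,
                 n_rate = n_rate, diff_rate = diff_rate,
                 seed = as.integer(seed), strains = strains,
                 pseudogene_rate = pseudogene_rate),
            class = "sim_table_spec")
}

#' Simulate a strain genotype table with gene intervals and ground truth
#'
#' Genes are laid out as disjoint 1 kb intervals (BED convention, 0-based
#' half-open) along one chromosome; each gene receives Poisson(`snp_rate`)
#' SNPs at distinct positions inside its interval. The focal pair's
#' genotypes differ with probability `diff_rate`; every call is then
#' independently masked to `"N"` with probability `n_rate`. The recorded
#' truth is the per-gene count of SNPs still countable by the screen
#' (both focal genotypes unmasked and unequal).
#'
#' @param spec a [sim_table_spec()].
#' @return list with elements `table` (a `genotype_table`), `genes`
#'   (interval data.frame as from [read_gene_bed()]) and `truth`
#'   (data.frame `gene_id`, `n_differing`).
#' @export
make_genotype_table <- function(spec) {
  stopifnot(inherits(spec, "sim_table_spec"))
  set.seed(spec$seed)
  ng <- spec$n_genes
  genes <- data.frame(
    gene_id = sprintf("gene%04d", seq_len(ng)), chrom = "chr7",
    start = (seq_len(ng) - 1L) * 2000L,
    end = (seq_len(ng) - 1L) * 2000L + 1000L,
    pseudogene = stats::runif(ng) < spec$pseudogene_rate,
    stringsAsFactors = FALSE)
  strains <- spec$strains
  rows <- vector("list", ng)
  truth_n <- integer(ng)
  for (i in seq_len(ng)) {
    k <- stats::rpois(1, spec$snp_rate)
    if (k == 0) next
    pos <- sort(genes$start[i] + sample.int(1000L, k))  # 1-based in interval
    g <- matrix("", k, length(strains), dimnames = list(NULL, strains))
    for (s in seq_len(k)) {
      ref <- sample(NUC, 1)
      alt <- sample(setdiff(NUC, ref), 1)
      differs <- stats::runif(1) < spec$diff_rate
      g[s, 1] <- ref
      g[s, 2] <- if (differs) alt else ref
      if (length(strains) > 2)
        g[s, 3:length(strains)] <- sample(c(ref, alt),
                                          length(strains) - 2L, replace = TRUE)
      mask <- stats::runif(length(strains)) < spec$n_rate
      g[s, mask] <- "N"
    }
    truth_n[i] <- sum(g[, 1] != "N" & g[, 2] != "N" & g[, 1] != g[, 2])
    rows[[i]] <- data.frame(chrom = "chr7", pos = pos, g,
                            check.names = FALSE, stringsAsFactors = FALSE)
  }
  tab <- if (any(lengths(rows) > 0)) do.call(rbind, rows[lengths(rows) > 0]) else
    data.frame(chrom = character(0), pos = integer(0),
               matrix(character(0), 0, length(strains),
                      dimnames = list(NULL, strains)), check.names = FALSE)
  list(table = genotype_table(tab),
       genes = genes,
       truth = data.frame(gene_id = genes$gene_id, n_differing = truth_n,
                          stringsAsFactors = FALSE))
}
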