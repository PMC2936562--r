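#' Synthetic stand-in for the three-gene, ten-strain study data
#'
#' Builds a fully synthetic data set with the structure of the study
#' design this package targets: two subspecies panels of five wild-derived
#' inbred strains each, three intron-less genes on one chromosome, and a
#' cross-taxon single-copy alignment with a gene history discordant from
#' the canonical species history. None of the sequences are real; every
#' paper-style quantity is *injected* so the pipeline's recovery of it can
#' be verified against the returned ground truth.
#'
#' The injected study conditions are:
#' \itemize{
#'   \item `Vmn1r67` (915 bp): 24 fixed inter-subspecies differences
#'     (15 nonsynonymous, 9 synonymous) plus 2 polymorphisms private to
#'     the domesticus panel (26 variable sites in total);
#'   \item `Vmn1r71` (921 bp): 35 variable sites, all polymorphisms
#'     (18 domesticus-private, 17 musculus-private), no fixed differences;
#'   \item `Abpa27` (1185 bp): 5 fixed inter-subspecies differences and no
#'     polymorphism, so it is in complete LD with the fixed sites of
#'     `Vmn1r67`;
#'   \item a nine-taxon cross-species `Vmn1r67` alignment in which the
#'     domesticus allele shares 19 derived states with M. spretus
#'     (14 at fixed nonsynonymous columns, 5 at fixed synonymous columns),
#'     so that ancestral reconstruction under the canonical species tree
#'     (subspecies polytomy) finds exactly 19 recurrent identical changes
#'     while the gene's own tree explains the data without homoplasy.
#' }
#'
#' @param seed integer seed controlling the random background, site
#'   placement and codon choices.
#' @return list of class `synthetic_study` with elements `alignments`
#'   (named list of three ten-strain `strain_alignment`s), `partition`,
#'   `cross_taxon` (nine-taxon `strain_alignment`), `species_tree`,
#'   `gene_tree` (the true discordant history, `phylo`), and `truth`
#'   (injected counts and site indices per gene).
#' @export
synthetic_study <- function(seed = 1L) {
  seed <- as.integer(seed)
  dom <- c("LEWES", "PERA", "TIRANO", "ZALENDE", "WSB")
  mus <- c("CZECHI", "CZECHII", "PWD", "PWK", "SKIVE")
  strains <- c(dom, mus)

  set.seed(seed)
  eff67 <- sample(rep(c("nonsynonymous", "synonymous"), c(15, 9)))
  effAbp <- sample(rep(c("nonsynonymous", "synonymous"), c(3, 2)))

  g67 <- make_two_group_alignment(
    sim_alignment_spec(5, 915, n_fixed = 24, n_poly_a = 2, n_poly_b = 0,
                       seed = seed + 101L),
    fixed_effects = eff67, strains = strains)
  g71 <- make_two_group_alignment(
    sim_alignment_spec(5, 921, n_fixed = 0, n_poly_a = 18, n_poly_b = 17,
                       seed = seed + 202L),
    strains = strains)
  gAbp <- make_two_group_alignment(
    sim_alignment_spec(5, 1185, n_fixed = 5, n_poly_a = 0, n_poly_b = 0,
                       seed = seed + 303L),
    fixed_effects = effAbp, strains = strains)

  taxa <- c("domesticus", "musculus", "castaneus", "spicilegus",
            "macedonicus", "spretus", "caroli", "pahari", "rat")
  species_tree <- ape::read.tree(text = paste0(
    "((((((domesticus,musculus,castaneus),(spicilegus,macedonicus)),",
    "spretus),caroli),pahari),rat);"))
  gene_tree <- ape::read.tree(text = paste0(
    "((((((musculus,castaneus),(spicilegus,macedonicus)),",
    "(domesticus,spretus)),caroli),pahari),rat);"))

  # cross-taxon alignment, column-coordinated with the Vmn1r67 stand-in
  aln67 <- g67$alignment
  fixed <- g67$truth$fixed_sites
  eff <- g67$truth$effects
  a_allele <- vapply(fixed, function(s) aln67[dom[1], s], "")
  b_allele <- vapply(fixed, function(s) aln67[mus[1], s], "")
  backbone <- group_consensus(aln67, dom, seq_len(ncol(aln67)))
  anc <- backbone
  anc[fixed] <- b_allele                 # ancestral state = musculus allele
  set.seed(seed + 404L)
  nonsyn_sites <- fixed[eff == "nonsynonymous"]
  syn_sites <- fixed[eff == "synonymous"]
  homoplasy_sites <- sort(c(sample(nonsyn_sites, 14), sample(syn_sites, 5)))

  m <- matrix(rep(anc, each = length(taxa)), nrow = length(taxa),
              dimnames = list(taxa, NULL))
  m["domesticus", fixed] <- a_allele                      # the diverged allele
  m["spretus", homoplasy_sites] <- a_allele[match(homoplasy_sites, fixed)]

  free <- setdiff(seq_len(915), fixed)
  draw_sites <- function(k) {
    s <- sample(free, k)
    free <<- setdiff(free, s)
    s
  }
  derive <- function(rows, sites) {
    for (s in sites) m[rows, s] <<- sample(setdiff(NUC, anc[s]), 1)
  }
  # synapomorphies on history edges shared by both trees (plus the gene
  # tree's cluster of the four non-domesticus Mus species)
  derive(c("spicilegus", "macedonicus"), draw_sites(6))
  derive(c("musculus", "castaneus", "spicilegus", "macedonicus"),
         draw_sites(6))
  derive(setdiff(taxa, c("caroli", "pahari", "rat")), draw_sites(6))
  derive(setdiff(taxa, c("pahari", "rat")), draw_sites(6))
  derive(setdiff(taxa, "rat"), draw_sites(6))
  for (t in taxa) derive(t, draw_sites(8))                # terminal branches

  out <- list(
    alignments = list(Vmn1r67 = g67$alignment, Vmn1r71 = g71$alignment,
                      Abpa27 = gAbp$alignment),
    partition = g67$partition,
    cross_taxon = strain_alignment(m),
    species_tree = species_tree,
    gene_tree = gene_tree,
    truth = list(
      Vmn1r67 = c(g67$truth, list(
        n_fixed = 24L, n_poly_a = 2L, n_poly_b = 0L,
        n_nonsyn = 15L, n_syn = 9L)),
      Vmn1r71 = c(g71$truth, list(n_fixed = 0L, n_poly_a = 18L,
                                  n_poly_b = 17L)),
      Abpa27 = c(gAbp$truth, list(n_fixed = 5L)),
      homoplasy_sites = homoplasy_sites,
      n_homoplasies_species_tree = 19L,
      n_homoplasies_gene_tree = 0L,
      n_homoplasies_at_fixed_nonsyn = 14L))
  class(out) <- "synthetic_study"
  out
}

#' Write the synthetic study to disk in the pipeline's input formats
#'
#' Writes each gene alignment as FASTA (`synthetic_<gene>.fasta`), the
#' strain-group mapping as TSV, both guide trees as Newick, and the ground
#' truth as a JSON sidecar, all prefixed `synthetic_` to mark them as
#' simulated stand-ins.
#'
#' @param study a [synthetic_study()] object.
#' @param dir output directory (created if needed).
#' @return named list of written file paths.
#' @export
write_synthetic_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (g in names(study$alignments)) {
    p <- file.path(dir, paste0("synthetic_", g, ".fasta"))
    write_alignment(study$alignments[[g]], p)
    paths[[g]] <- p
  }
  paths$cross_taxon <- file.path(dir, "synthetic_cross_taxon.fasta")
  write_alignment(study$cross_taxon, paths$cross_taxon)
  paths$groups <- file.path(dir, "synthetic_groups.tsv")
  utils::write.table(
    data.frame(strain = names(study$partition),
               group = as.vector(unclass(study$partition))),
    paths$groups, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  paths$species_tree <- file.path(dir, "synthetic_species_tree.nwk")
  ape::write.tree(study$species_tree, paths$species_tree)
  paths$gene_tree <- file.path(dir, "synthetic_gene_tree.nwk")
  ape::write.tree(study$gene_tree, paths$gene_tree)
  paths$truth <- file.path(dir, "synthetic_truth.json")
  jsonlite::write_json(study$truth, paths$truth, auto_unbox = TRUE)
  invisible(paths)
}
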