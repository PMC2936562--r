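#' Read a strain genotype table (TSV)
#'
#' The header row names the columns: `chrom`, `pos`, then one column per
#' strain. Positions are 1-based. Genotypes are single calls in
#' `A C G T N`; any other symbol is rejected.
#'
#' @param path TSV path.
#' @return data.frame of class `genotype_table`.
#' @export
read_genotype_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  if (!all(c("chrom", "pos") %in% names(d)[1:2]))
    stop("genotype table must start with columns 'chrom' and 'pos': ", path)
  d$pos <- as.integer(d$pos)
  genotype_table(d)
}

#' Construct/validate a genotype table
#' @param d data.frame with columns chrom, pos, then one column per strain.
#' @return data.frame of class `genotype_table`.
#' @export
genotype_table <- function(d) {
  strains <- setdiff(names(d), c("chrom", "pos"))
  if (!length(strains)) stop("genotype table has no strain columns")
  g <- toupper(as.matrix(d[, strains, drop = FALSE]))
  bad <- setdiff(unique(as.vector(g)), c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("invalid genotype symbols: ", paste(bad, collapse = " "),
         " (allowed: A C G T N)")
  d[, strains] <- g
  if (anyDuplicated(d[, c("chrom", "pos")]))
    stop("duplicate (chrom, pos) records in genotype table")
  class(d) <- c("genotype_table", "data.frame")
  d
}

#' Read gene intervals from a BED file (0-based, half-open)
#'
#' Columns: chrom, start, end, gene_id, and optionally a 5th column where a
#' value of `pseudogene` (or score 1) flags pseudogenes.
#'
#' @param path BED path.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `pseudogene`.
#' @export
read_gene_bed <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(d) < 4L) stop("BED file needs at least 4 columns: ", path)
  out <- data.frame(gene_id = as.character(d[[4]]), chrom = as.character(d[[1]]),
                    start = as.integer(d[[2]]), end = as.integer(d[[3]]),
                    pseudogene = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) >= 5L)
    out$pseudogene <- d[[5]] %in% c("pseudogene", "1", 1, TRUE)
  if (any(out$start >= out$end)) stop("gene intervals must satisfy start < end")
  out
}

#' Count focal-pair genotype differences per gene
#'
#' For each gene interval, counts the SNPs at which two focal strains both
#' have unambiguous genotypes (in `A C G T`) that are unequal; `N`
#' genotypes are conservatively never counted as differences. A SNP at
#' 1-based position `pos` belongs to a gene iff `pos - 1` lies in the
#' 0-based half-open interval `[start, end)` on the same chromosome; a SNP
#' overlapping two genes is counted in both (with a warning).
#'
#' @param table a `genotype_table`.
#' @param strain_a,strain_b focal strain names (columns of `table`).
#' @param genes data.frame of gene intervals (see [read_gene_bed()]).
#' @return data.frame with one row per gene: `gene_id`, `n_snps_in_gene`,
#'   `n_differing`, `pseudogene`.
#' @export
count_differences_per_gene <- function(table, strain_a, strain_b, genes) {
  for (s in c(strain_a, strain_b))
    if (!s %in% names(table)) stop("unknown strain name: ", s)
  ga <- table[[strain_a]]
  gb <- table[[strain_b]]
  ok <- ga %in% c("A", "C", "G", "T") & gb %in% c("A", "C", "G", "T")
  differs <- ok & ga != gb
  n_genes_per_snp <- integer(nrow(table))
  res <- genes[, c("gene_id", "pseudogene"), drop = FALSE]
  res$n_snps_in_gene <- 0L
  res$n_differing <- 0L
  for (i in seq_len(nrow(genes))) {
    in_gene <- table$chrom == genes$chrom[i] &
      table$pos - 1L >= genes$start[i] & table$pos - 1L < genes$end[i]
    n_genes_per_snp[in_gene] <- n_genes_per_snp[in_gene] + 1L
    res$n_snps_in_gene[i] <- sum(in_gene)
    res$n_differing[i] <- sum(differs & in_gene)
  }
  if (any(n_genes_per_snp > 1L))
    warning(sum(n_genes_per_snp > 1L),
            " SNP(s) overlap more than one gene; counted in each")
  res[, c("gene_id", "n_snps_in_gene", "n_differing", "pseudogene")]
}

#' Rank candidate genes by focal-pair difference count
#'
#' Descending by `n_differing`; ties broken by lexicographic `gene_id` so
#' the ranking is deterministic. Pseudogenes may be excluded first.
#'
#' @param counts output of [count_differences_per_gene()].
#' @param exclude_pseudogenes drop rows flagged as pseudogenes.
#' @param top_k number of genes to return (capped at the number available).
#' @return the top rows of `counts`, ranked.
#' @export
rank_candidates <- function(counts, exclude_pseudogenes = FALSE, top_k = 10L) {
  if (!nrow(counts)) stop("empty counts")
  if (top_k <= 0) stop("top_k must be positive")
  if (exclude_pseudogenes) counts <- counts[!counts$pseudogene, , drop = FALSE]
  ord <- order(-counts$n_differing, counts$gene_id)
  out <- counts[ord, , drop = FALSE][seq_len(min(top_k, nrow(counts))), ,
                                     drop = FALSE]
  rownames(out) <- NULL
  out
}
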