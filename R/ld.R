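#' Concatenate per-gene variable sites into a haplotype matrix
#'
#' Reduces each gene's alignment to its candidate variable columns (at
#' least two nucleotides among non-missing entries; `N` and gaps are kept
#' as missing) and concatenates them across genes in the supplied order,
#' annotating every column with its gene of origin and original position.
#' Columns with more than two alleles among non-missing entries are
#' excluded, with the count reported via a message.
#'
#' @param alignments named list of `strain_alignment` objects (identical
#'   strain sets; the first alignment's row order is used throughout).
#' @return a character matrix of class `haplotype_matrix` (rows = strains,
#'   columns = variable sites) with attributes `gene` and `position`
#'   (per-column provenance) and `n_multiallelic_dropped`.
#' @export
concatenate_haplotypes <- function(alignments) {
  if (!length(alignments)) stop("no alignments supplied")
  if (is.null(names(alignments)) || any(names(alignments) == ""))
    stop("alignments must be a named list (gene ids)")
  strains <- rownames(alignments[[1]])
  for (g in names(alignments)) {
    miss <- setdiff(strains, rownames(alignments[[g]]))
    extra <- setdiff(rownames(alignments[[g]]), strains)
    if (length(miss) || length(extra))
      stop("strain set mismatch in gene ", g, ": missing [",
           paste(miss, collapse = ", "), "], extra [",
           paste(extra, collapse = ", "), "]")
  }
  cols <- list(); gene <- character(0); pos <- integer(0); dropped <- 0L
  for (g in names(alignments)) {
    aln <- alignments[[g]][strains, , drop = FALSE]
    for (j in seq_len(ncol(aln))) {
      v <- aln[, j]
      alleles <- unique(v[v %in% NUC])
      if (length(alleles) < 2L) next
      if (length(alleles) > 2L) { dropped <- dropped + 1L; next }
      cols[[length(cols) + 1L]] <- v
      gene <- c(gene, g); pos <- c(pos, j)
    }
  }
  if (dropped > 0L)
    message("excluded ", dropped, " multi-allelic column(s)")
  if (!length(cols)) stop("no biallelic variable columns found")
  m <- do.call(cbind, cols)
  rownames(m) <- strains
  attr(m, "gene") <- gene
  attr(m, "position") <- pos
  attr(m, "n_multiallelic_dropped") <- dropped
  class(m) <- c("haplotype_matrix", class(m))
  m
}

r2_pair <- function(x, y) {
  ok <- x %in% NUC & y %in% NUC        # pairwise-complete rows
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L) return(NA_real_)
  ax <- names(sort(table(x), decreasing = TRUE))
  ay <- names(sort(table(y), decreasing = TRUE))
  if (length(ax) < 2L || length(ay) < 2L) return(NA_real_)  # monomorphic
  p_i <- mean(x == ax[1]); p_j <- mean(y == ay[1])
  p_ij <- mean(x == ax[1] & y == ay[1])
  D <- p_ij - p_i * p_j
  D^2 / (p_i * (1 - p_i) * p_j * (1 - p_j))
}

#' Pairwise r-squared linkage disequilibrium over a haplotype matrix
#'
#' For each pair of biallelic sites, computes
#' `r^2 = (p_ij - p_i p_j)^2 / (p_i (1 - p_i) p_j (1 - p_j))` with
#' major-allele frequencies taken over pairwise-complete rows. Pairs that
#' become monomorphic after missing-data removal are reported as `NA`
#' (undefined, distinct from 0). Gene-pair summaries (max and mean r^2
#' across site pairs) are attached.
#'
#' @param hap a `haplotype_matrix` from [concatenate_haplotypes()].
#' @return list of class `ld_matrix` with elements `r2` (symmetric matrix,
#'   unit diagonal for polymorphic sites), `gene` / `position` column
#'   annotations, and `gene_pairs` (data.frame `gene_i`, `gene_j`,
#'   `max_r2`, `mean_r2`, `n_pairs`).
#' @export
r2_matrix <- function(hap) {
  if (nrow(hap) < 2L) stop("need at least two haplotypes")
  S <- ncol(hap)
  r2 <- matrix(NA_real_, S, S)
  for (i in seq_len(S)) {
    r2[i, i] <- r2_pair(hap[, i], hap[, i])
    if (i < S) for (j in (i + 1):S)
      r2[i, j] <- r2[j, i] <- r2_pair(hap[, i], hap[, j])
  }
  gene <- attr(hap, "gene"); pos <- attr(hap, "position")
  colnames(r2) <- rownames(r2) <- paste(gene, pos, sep = ":")
  genes <- unique(gene)
  gp <- list()
  for (a in seq_along(genes)) for (b in a:length(genes)) {
    sub <- r2[gene == genes[a], gene == genes[b], drop = FALSE]
    if (a == b && ncol(sub) > 1L) sub <- sub[upper.tri(sub)]
    vals <- sub[!is.na(sub)]
    gp[[length(gp) + 1L]] <- data.frame(
      gene_i = genes[a], gene_j = genes[b],
      max_r2 = if (length(vals)) max(vals) else NA_real_,
      mean_r2 = if (length(vals)) mean(vals) else NA_real_,
      n_pairs = length(vals), stringsAsFactors = FALSE)
  }
  out <- list(r2 = r2, gene = gene, position = pos,
              gene_pairs = do.call(rbind, gp))
  class(out) <- "ld_matrix"
  out
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat("ld_matrix:", ncol(x$r2), "sites from",
      length(unique(x$gene)), "gene(s)\n")
  print.data.frame(x$gene_pairs, digits = 3)
  invisible(x)
}
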