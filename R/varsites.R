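#' Columns usable for site statistics (complete-deletion rule)
#'
#' Columns containing any `N` or gap are excluded from all site statistics,
#' mirroring the complete-deletion behaviour of standard polymorphism
#' software. Returns the 1-based indices of fully resolved columns.
#'
#' @param aln a `strain_alignment`.
#' @return integer vector of included column indices.
#' @export
included_sites <- function(aln) {
  ok <- colSums(aln == "N" | aln == "-") == 0L
  which(ok)
}

#' Variable sites of a multi-strain alignment
#'
#' A variable site is a fully resolved column (no `N`, no gap) at which at
#' least two distinct nucleotides occur.
#'
#' @param aln a `strain_alignment` with at least two sequences.
#' @return integer vector of 1-based variable column indices.
#' @export
variable_sites <- function(aln) {
  if (nrow(aln) < 2L) stop("need at least two sequences")
  inc <- included_sites(aln)
  if (!length(inc)) return(integer(0))
  nvar <- vapply(inc, function(j) length(unique(aln[, j])), 0L)
  inc[nvar > 1L]
}

#' Classify variable sites into fixed differences and polymorphisms
#'
#' Given a two-group partition of the strains, each variable column is
#' assigned to exactly one category: `fixed_difference` (both groups
#' internally monomorphic, with different nucleotides), `polymorphic_A` /
#' `polymorphic_B` (variable within exactly one group), or
#' `polymorphic_both`. If `frame_offset` is supplied, fixed differences are
#' additionally annotated as synonymous or nonsynonymous (see
#' [coding_effect()]); other sites are `not_assessed`.
#'
#' @param aln a `strain_alignment`.
#' @param partition a `group_partition` covering all strains in `aln`.
#' @param frame_offset optional reading-frame start (0, 1 or 2); `NULL`
#'   skips coding annotation.
#' @param joint_codon logical; passed to [coding_effect()].
#' @return a data.frame of class `site_classification` with columns
#'   `site`, `category`, `alleles_A`, `alleles_B`, `coding_effect`.
#' @export
classify_sites <- function(aln, partition, frame_offset = NULL,
                           joint_codon = FALSE) {
  partition <- check_partition(aln, partition)
  a_rows <- names(partition)[partition == "A"]
  b_rows <- names(partition)[partition == "B"]
  if (length(a_rows) == 1L || length(b_rows) == 1L)
    warning("a group of size 1 can never be scored polymorphic within itself")
  vs <- variable_sites(aln)
  cat_of <- function(j) {
    ua <- unique(aln[a_rows, j])
    ub <- unique(aln[b_rows, j])
    if (length(ua) == 1L && length(ub) == 1L && ua != ub) "fixed_difference"
    else if (length(ua) > 1L && length(ub) == 1L) "polymorphic_A"
    else if (length(ua) == 1L && length(ub) > 1L) "polymorphic_B"
    else "polymorphic_both"
  }
  res <- data.frame(
    site = vs,
    category = vapply(vs, cat_of, ""),
    alleles_A = vapply(vs, function(j)
      paste(sort(unique(aln[a_rows, j])), collapse = "/"), ""),
    alleles_B = vapply(vs, function(j)
      paste(sort(unique(aln[b_rows, j])), collapse = "/"), ""),
    coding_effect = rep("not_assessed", length(vs)),
    stringsAsFactors = FALSE
  )
  if (!is.null(frame_offset)) {
    fx <- which(res$category == "fixed_difference")
    for (i in fx) {
      res$coding_effect[i] <- coding_effect(aln, partition, res$site[i],
                                            frame_offset,
                                            joint_codon = joint_codon)
    }
  }
  class(res) <- c("site_classification", class(res))
  res
}

#' @export
print.site_classification <- function(x, ...) {
  tab <- table(factor(x$category,
                      levels = c("fixed_difference", "polymorphic_A",
                                 "polymorphic_B", "polymorphic_both")))
  cat("site_classification:", nrow(x), "variable sites\n")
  for (k in names(tab)) cat(sprintf("  %-18s %d\n", k, tab[[k]]))
  if (any(x$coding_effect != "not_assessed")) {
    eff <- table(x$coding_effect[x$category == "fixed_difference"])
    cat("  fixed-difference coding effects:",
        paste(names(eff), eff, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

group_consensus <- function(aln, rows, cols) {
  vapply(cols, function(j) {
    v <- aln[rows, j]
    v <- v[v %in% c("A", "C", "G", "T")]
    if (!length(v)) return("N")
    tab <- sort(table(v), decreasing = TRUE)
    if (length(tab) > 1L && tab[1] == tab[2]) return("N")  # ambiguous consensus
    names(tab)[1]
  }, "")
}

translate_codon <- function(codon) {
  seqinr::translate(tolower(codon))
}

#' Coding effect of a fixed inter-group difference
#'
#' Scores a fixed-difference site as synonymous or nonsynonymous. The
#' group-A consensus codon containing the site is compared against the
#' codon obtained by substituting group B's allele at that site only, the
#' other codon positions being held at the group-A consensus. With
#' `joint_codon = TRUE` the full group-B consensus codon is used instead,
#' so codons carrying several fixed differences are compared jointly.
#'
#' @param aln a `strain_alignment`.
#' @param partition a `group_partition`.
#' @param site 1-based column index of a fixed difference.
#' @param frame_offset reading-frame start: 0, 1 or 2.
#' @param joint_codon logical, see above.
#' @return `"synonymous"`, `"nonsynonymous"`, or `"not_assessed"` when the
#'   codon is truncated at the alignment edge or its consensus contains an
#'   unresolved base.
#' @export
coding_effect <- function(aln, partition, site, frame_offset = 0,
                          joint_codon = FALSE) {
  stopifnot(frame_offset %in% 0:2, length(site) == 1L)
  partition <- check_partition(aln, partition)
  a_rows <- names(partition)[partition == "A"]
  b_rows <- names(partition)[partition == "B"]
  if (site <= frame_offset) return("not_assessed")
  codon_idx <- (site - 1 - frame_offset) %/% 3
  cols <- frame_offset + codon_idx * 3 + 1:3
  if (cols[3] > ncol(aln)) return("not_assessed")
  cod_a <- group_consensus(aln, a_rows, cols)
  if (any(cod_a == "N")) return("not_assessed")
  b_allele <- unique(aln[b_rows, site])
  if (length(b_allele) != 1L || !b_allele %in% c("A", "C", "G", "T"))
    stop("site ", site, " is not a fixed difference (group B not monomorphic)")
  if (joint_codon) {
    cod_b <- group_consensus(aln, b_rows, cols)
    if (any(cod_b == "N")) return("not_assessed")
  } else {
    cod_b <- cod_a
    cod_b[cols == site] <- b_allele
  }
  if (identical(translate_codon(cod_a), translate_codon(cod_b)))
    "synonymous" else "nonsynonymous"
}

#' Nucleotide diversity and Watterson's theta for one group
#'
#' Computes per-site nucleotide diversity `pi` (mean pairwise difference
#' proportion) and Watterson's estimator `theta_w = S / (a_n * L_eff)` over
#' the fully resolved columns of the sub-alignment, where
#' `a_n = sum(1/i, i = 1..n-1)`.
#'
#' @param aln a `strain_alignment`.
#' @param strains optional character vector selecting a subset of rows
#'   (e.g. one group); default uses all sequences.
#' @return an object of class `diversity_stats`: a list with elements
#'   `n`, `L_eff`, `S`, `pi`, `theta_w`, `a_n`.
#' @export
diversity <- function(aln, strains = NULL) {
  if (!is.null(strains)) {
    missing <- setdiff(strains, rownames(aln))
    if (length(missing)) stop("unknown strains: ", paste(missing, collapse = ", "))
    aln <- strain_alignment(aln[strains, , drop = FALSE])
  }
  n <- nrow(aln)
  if (n < 2L) stop("need at least two sequences for diversity statistics")
  inc <- included_sites(aln)
  L_eff <- length(inc)
  if (L_eff == 0L) stop("no fully resolved columns (L_eff = 0)")
  npairs <- n * (n - 1) / 2
  # per-column heterozygosity from allele counts; sums to mean pairwise diffs
  h <- vapply(inc, function(j) {
    cnt <- table(aln[, j])
    1 - sum(cnt * (cnt - 1)) / (n * (n - 1))
  }, 0)
  S <- sum(h > 0)
  a_n <- sum(1 / seq_len(n - 1))
  out <- list(n = n, L_eff = L_eff, S = S,
              pi = sum(h) / L_eff,
              theta_w = S / (a_n * L_eff),
              a_n = a_n)
  class(out) <- "diversity_stats"
  out
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat(sprintf("diversity_stats: n=%d  L_eff=%d  S=%d  pi=%.6g  theta_w=%.6g\n",
              x$n, x$L_eff, x$S, x$pi, x$theta_w))
  invisible(x)
}
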