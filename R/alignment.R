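#' Multi-strain alignment container
#'
#' A `strain_alignment` is a character matrix with one row per (haploid)
#' strain and one column per alignment site, over the alphabet
#' `A C G T N -`. Wild-derived inbred strains are treated as single
#' haplotypes, so there are no heterozygote codes.
#'
#' @param x a named character vector of equal-length DNA strings, or a
#'   character matrix (rows = strains) of single characters.
#' @return an object of class `strain_alignment`.
#' @export
strain_alignment <- function(x) {
  if (is.character(x) && !is.matrix(x)) {
    if (is.null(names(x)) || anyDuplicated(names(x)))
      stop("sequences must carry unique strain names")
    lens <- nchar(x)
    if (length(unique(lens)) != 1L)
      stop("sequences must have equal length (got lengths ",
           paste(unique(lens), collapse = ", "), ")")
    if (lens[1] == 0L) stop("zero-length alignment")
    m <- do.call(rbind, strsplit(toupper(x), "", fixed = TRUE))
    rownames(m) <- names(x)
  } else if (is.matrix(x) && is.character(x)) {
    if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
      stop("alignment matrix must carry unique strain rownames")
    if (ncol(x) == 0L) stop("zero-length alignment")
    m <- x
    m[] <- toupper(m)
  } else stop("expected a named character vector or character matrix")
  bad <- setdiff(unique(as.vector(m)), c("A", "C", "G", "T", "N", "-"))
  if (length(bad))
    stop("invalid symbols in alignment: ", paste(bad, collapse = " "),
         " (allowed: A C G T N -)")
  class(m) <- c("strain_alignment", class(m))
  m
}

#' @export
print.strain_alignment <- function(x, ...) {
  cat("strain_alignment:", nrow(x), "strains x", ncol(x), "sites\n")
  n_show <- min(ncol(x), 60L)
  for (s in rownames(x)) {
    cat(sprintf("  %-12s %s%s\n", s,
                paste(x[s, seq_len(n_show)], collapse = ""),
                if (ncol(x) > n_show) "..." else ""))
  }
  invisible(x)
}

n_strains <- function(aln) nrow(aln)
aln_length <- function(aln) ncol(aln)

#' Read a FASTA alignment into a strain_alignment
#'
#' Record ids may carry a `|group` suffix (e.g. `WSB|A`); if every record
#' has one, the suffix is stripped into an attached group partition.
#'
#' @param path path to an uncompressed FASTA file.
#' @return a `strain_alignment`; if group suffixes were present, the
#'   partition is attached as attribute `"partition"`.
#' @export
read_alignment <- function(path) {
  dna <- ape::read.FASTA(path)
  if (length(dna) < 1L) stop("no sequences in ", path)
  chars <- as.character(dna)
  if (length(unique(lengths(chars))) != 1L)
    stop("sequences in ", path, " are not aligned (unequal lengths)")
  m <- toupper(do.call(rbind, chars))
  ids <- names(dna)
  part <- NULL
  if (all(grepl("|", ids, fixed = TRUE))) {
    sp <- strsplit(ids, "|", fixed = TRUE)
    ids <- vapply(sp, `[`, "", 1L)
    part <- vapply(sp, `[`, "", 2L)
    names(part) <- ids
  }
  rownames(m) <- ids
  aln <- strain_alignment(m)
  if (!is.null(part)) attr(aln, "partition") <- group_partition(part)
  aln
}

#' Write a strain_alignment as FASTA
#'
#' @param aln a `strain_alignment`.
#' @param path output path.
#' @param partition optional group partition; if given, record ids are
#'   written as `strain|group`.
#' @export
write_alignment <- function(aln, path, partition = NULL) {
  ids <- rownames(aln)
  if (!is.null(partition)) ids <- paste(ids, partition[rownames(aln)], sep = "|")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(paste0(">", ids[i]), con)
    writeLines(paste(aln[i, ], collapse = ""), con)
  }
  invisible(path)
}

#' Two-group strain partition
#'
#' @param x named character vector mapping strain name to group id
#'   (`"A"` or `"B"`), or the `A` / `B` arguments may be used instead.
#' @param A,B character vectors of strain names per group.
#' @return named character vector of class `group_partition`.
#' @export
group_partition <- function(x = NULL, A = NULL, B = NULL) {
  if (is.null(x)) {
    if (is.null(A) || is.null(B)) stop("supply x, or both A and B")
    x <- stats::setNames(rep(c("A", "B"), c(length(A), length(B))), c(A, B))
  }
  if (is.null(names(x)) || anyDuplicated(names(x)))
    stop("partition must be a named vector with unique strain names")
  if (!all(x %in% c("A", "B")))
    stop("group ids must be 'A' or 'B'")
  if (!all(c("A", "B") %in% x)) stop("both groups must be nonempty")
  class(x) <- "group_partition"
  x
}

#' Read a strain-to-group mapping from TSV (columns: strain, group)
#' @param path TSV path, no header required; a header line `strain\tgroup`
#'   is tolerated.
#' @return a `group_partition`.
#' @export
read_groups <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE, col.names = c("strain", "group"))
  if (tolower(d$strain[1]) == "strain") d <- d[-1, , drop = FALSE]
  group_partition(stats::setNames(d$group, d$strain))
}

check_partition <- function(aln, partition) {
  missing <- setdiff(rownames(aln), names(partition))
  if (length(missing))
    stop("strains missing from partition: ", paste(missing, collapse = ", "))
  partition[rownames(aln)]
}
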