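#' Pairwise F84 distance
#'
#' Maximum-likelihood pairwise distance under the F84 model (unequal base
#' frequencies, transition/transversion distinction). For a sequence pair,
#' with base frequencies pooled over the two sequences' shared resolved
#' columns, `piR = piA + piG`, `piY = piC + piT`,
#' `A = piC*piT/piY + piA*piG/piR`, `B = piC*piT + piA*piG`, `C = piR*piY`,
#' transition proportion `P` and transversion proportion `Q`:
#' \deqn{d = -2A \log(1 - P/(2A) - (A-B)Q/(2AC)) + 2(A-B-C)\log(1 - Q/(2C))}
#' Saturated pairs (non-positive log argument) are reported as `Inf` with a
#' warning.
#'
#' @param x,y character vectors of single nucleotides (rows of a
#'   `strain_alignment`); columns where either sequence is not in
#'   `A C G T` are dropped pairwise.
#' @return a single distance in expected substitutions per site.
#' @export
f84_pairwise <- function(x, y) {
  ok <- x %in% NUC & y %in% NUC
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 1L) stop("no shared resolved columns for this pair")
  freqs <- table(factor(c(x, y), levels = NUC)) / (2 * n)
  freqs <- as.numeric(freqs); names(freqs) <- NUC
  diff <- x != y
  transition <- diff & ((x %in% c("A", "G") & y %in% c("A", "G")) |
                          (x %in% c("C", "T") & y %in% c("C", "T")))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  piR <- freqs["A"] + freqs["G"]; piY <- freqs["C"] + freqs["T"]
  if (piR <= 0 || piY <= 0) {
    warning("degenerate base composition; distance undefined, reporting Inf")
    return(Inf)
  }
  A <- freqs["C"] * freqs["T"] / piY + freqs["A"] * freqs["G"] / piR
  B <- freqs["C"] * freqs["T"] + freqs["A"] * freqs["G"]
  C <- piR * piY
  arg1 <- 1 - P / (2 * A) - (A - B) * Q / (2 * A * C)
  arg2 <- 1 - Q / (2 * C)
  if (arg1 <= 0 || arg2 <= 0) {
    warning("saturated pair (log argument <= 0); reporting Inf")
    return(Inf)
  }
  d <- -2 * A * log(arg1) + 2 * (A - B - C) * log(arg2)
  unname(max(d, 0))
}

#' F84 distance matrix for an alignment
#'
#' @param aln a `strain_alignment` with at least two sequences.
#' @return symmetric numeric matrix (zero diagonal) with strain dimnames.
#' @export
f84_distance_matrix <- function(aln) {
  n <- nrow(aln)
  if (n < 2L) stop("need at least two sequences")
  D <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- f84_pairwise(aln[i, ], aln[j, ])
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration in the Studier-Keppler form. Ties in the
#' Q-criterion are broken deterministically towards the smallest
#' (row, column) index pair. Negative branch-length estimates are clamped
#' to zero; the number of clamped branches is attached as attribute
#' `"clamped"`.
#'
#' @param D symmetric numeric distance matrix with taxon dimnames
#'   (at least 3 taxa).
#' @return an unrooted `phylo` tree (trifurcating at the root node).
#' @export
neighbor_joining <- function(D) {
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix must be symmetric")
  taxa <- rownames(D)
  if (is.null(taxa)) stop("distance matrix must carry taxon names")
  if (any(!is.finite(D)))
    stop("distance matrix contains non-finite entries (saturated pairs?)")
  n <- length(taxa)
  if (n < 3L) stop("need at least 3 taxa")
  labels <- taxa                      # newick substring per active cluster
  d <- D
  clamped <- 0L
  fmt <- function(x) sprintf("%.15g", x)
  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    Qm <- (m - 2) * d - outer(r, r, `+`)
    diag(Qm) <- Inf
    # deterministic arg-min: smallest Q, ties to smallest (i, j), i < j
    best <- c(NA, NA); bestq <- Inf
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      if (Qm[i, j] < bestq - 1e-12) { bestq <- Qm[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- d[i, j] - vi
    if (vi < 0) { vi <- 0; clamped <- clamped + 1L }
    if (vj < 0) { vj <- 0; clamped <- clamped + 1L }
    new_lab <- paste0("(", labels[i], ":", fmt(vi), ",",
                      labels[j], ":", fmt(vj), ")")
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    labels <- c(labels[keep], new_lab)
  }
  # final three clusters: closed-form three-point branch lengths
  va <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  vb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  vc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  v <- c(va, vb, vc)
  clamped <- clamped + sum(v < 0)
  v[v < 0] <- 0
  nwk <- paste0("(", labels[1], ":", fmt(v[1]), ",",
                labels[2], ":", fmt(v[2]), ",",
                labels[3], ":", fmt(v[3]), ");")
  tr <- ape::read.tree(text = nwk)
  attr(tr, "clamped") <- clamped
  tr
}

# canonical key for the bipartition induced by removing an internal edge:
# the tip-name set on the side NOT containing the alphabetically first tip
bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  anchor <- tips[1]
  ntip <- length(tree$tip.label)
  internal <- tree$edge[tree$edge[, 2] > ntip, 2]
  keys <- character(0)
  for (node in internal) {
    below <- tree$tip.label[phangorn::Descendants(tree, node, "tips")[[1]]]
    side <- if (anchor %in% below) setdiff(tips, below) else below
    if (length(side) >= 2 && length(side) <= ntip - 2)
      keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Column-bootstrap support for the F84 + NJ gene tree
#'
#' Resamples alignment columns with replacement, rebuilds the F84 distance
#' and neighbor-joining tree per replicate, and reports the frequency (as a
#' percentage) with which each internal bipartition of the original tree
#' recurs. Replicate resamplings are drawn sequentially from one master
#' seed, so identical seeds give identical supports.
#'
#' @param aln a `strain_alignment` (at least 4 sequences for internal
#'   edges to exist).
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer master seed (required: the resampling is stochastic).
#' @return list with elements `tree` (the original NJ tree), `support`
#'   (named numeric vector, percent per bipartition key), `n_reps`.
#' @export
bootstrap_support <- function(aln, n_reps = 1000L, seed) {
  if (missing(seed) || is.null(seed))
    stop("bootstrap requires an explicit seed")
  if (n_reps < 1L) stop("n_reps must be >= 1")
  tree <- neighbor_joining(f84_distance_matrix(aln))
  orig <- bipartitions(tree)
  hits <- stats::setNames(numeric(length(orig)), orig)
  L <- ncol(aln)
  set.seed(as.integer(seed))
  for (b in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_aln <- strain_alignment(aln[, cols, drop = FALSE])
    rep_tree <- try(suppressWarnings(neighbor_joining(f84_distance_matrix(rep_aln))),
                    silent = TRUE)
    if (inherits(rep_tree, "try-error")) next
    rb <- bipartitions(rep_tree)
    hits[orig %in% rb] <- hits[orig %in% rb] + 1
  }
  list(tree = tree, support = 100 * hits / n_reps, n_reps = n_reps)
}
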