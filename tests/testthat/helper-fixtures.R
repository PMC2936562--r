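# shared helpers: tiny brute-force oracles kept independent of the
# implementation paths they check

random_alignment <- function(n, L, seed) {
  set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L,
              dimnames = list(paste0("s", seq_len(n)), NULL))
  strain_alignment(m)
}

# brute-force pi: average pairwise difference proportion over all pairs
brute_pi <- function(aln) {
  keep <- which(apply(aln, 2, function(c) all(c %in% c("A", "C", "G", "T"))))
  sub <- aln[, keep, drop = FALSE]
  n <- nrow(sub)
  total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    total <- total + sum(sub[i, ] != sub[j, ])
  total / choose(n, 2) / length(keep)
}

# brute-force per-column classification by direct scanning
brute_classify <- function(aln, partition) {
  a <- names(partition)[partition == "A"]
  b <- names(partition)[partition == "B"]
  out <- character(0)
  for (j in seq_len(ncol(aln))) {
    col <- aln[, j]
    if (any(!col %in% c("A", "C", "G", "T"))) next
    if (length(unique(col)) < 2) next
    ua <- unique(aln[a, j]); ub <- unique(aln[b, j])
    out[as.character(j)] <-
      if (length(ua) == 1 && length(ub) == 1) "fixed_difference"
      else if (length(ua) > 1 && length(ub) == 1) "polymorphic_A"
      else if (length(ua) == 1 && length(ub) > 1) "polymorphic_B"
      else "polymorphic_both"
  }
  out
}

# brute-force r^2 from the 2x2 haplotype table
brute_r2 <- function(x, y) {
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) != 2 || length(unique(y)) != 2) return(NA_real_)
  xi <- as.numeric(x == sort(unique(x))[1])
  yi <- as.numeric(y == sort(unique(y))[1])
  stats::cor(xi, yi)^2
}

# brute-force focal-pair SNP difference counting per gene interval
brute_screen <- function(table, a, b, genes) {
  sapply(seq_len(nrow(genes)), function(i) {
    n <- 0L
    for (r in seq_len(nrow(table))) {
      if (table$chrom[r] != genes$chrom[i]) next
      if (table$pos[r] - 1 < genes$start[i] ||
          table$pos[r] - 1 >= genes$end[i]) next
      ga <- table[[a]][r]; gb <- table[[b]][r]
      if (ga %in% c("A", "C", "G", "T") && gb %in% c("A", "C", "G", "T") &&
          ga != gb) n <- n + 1L
    }
    n
  })
}

k80_distance <- function(P, Q) -log(1 - 2 * P - Q) / 2 - log(1 - 2 * Q) / 4
jc_distance <- function(D) -3 / 4 * log(1 - 4 * D / 3)
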