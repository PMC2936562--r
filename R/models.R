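# Nucleotide substitution machinery shared by the simulator and the
# ancestral-state reconstruction: HKY rate matrix and transition
# probabilities, computed by symmetric eigendecomposition (the chain is
# reversible, so diag(sqrt(pi)) Q diag(1/sqrt(pi)) is symmetric).

NUC <- c("A", "C", "G", "T")

hky_rate_matrix <- function(freqs = rep(0.25, 4), kappa = 2) {
  stopifnot(length(freqs) == 4L, all(freqs > 0))
  if (abs(sum(freqs) - 1) > 1e-9) stop("base frequencies must sum to 1")
  names(freqs) <- NUC
  is_transition <- function(i, j)
    (NUC[i] %in% c("A", "G") && NUC[j] %in% c("A", "G")) ||
    (NUC[i] %in% c("C", "T") && NUC[j] %in% c("C", "T"))
  Q <- matrix(0, 4, 4, dimnames = list(NUC, NUC))
  for (i in 1:4) for (j in 1:4) if (i != j)
    Q[i, j] <- freqs[j] * if (is_transition(i, j)) kappa else 1
  diag(Q) <- -rowSums(Q)
  rate <- -sum(freqs * diag(Q))      # expected substitutions per unit time
  Q / rate                           # normalized: branch lengths in subs/site
}

hky_prob_matrix <- function(t, freqs = rep(0.25, 4), kappa = 2,
                            Q = NULL) {
  if (is.null(Q)) Q <- hky_rate_matrix(freqs, kappa)
  pi_sqrt <- sqrt(freqs); names(pi_sqrt) <- NUC
  B <- diag(pi_sqrt) %*% Q %*% diag(1 / pi_sqrt)
  B <- (B + t(B)) / 2                # enforce symmetry against rounding
  e <- eigen(B, symmetric = TRUE)
  P <- diag(1 / pi_sqrt) %*% e$vectors %*% diag(exp(t * e$values)) %*%
    t(e$vectors) %*% diag(pi_sqrt)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(NUC, NUC)
  P
}
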