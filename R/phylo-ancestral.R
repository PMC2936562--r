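# Ancestral-state reconstruction on a fixed (possibly multifurcating) guide
# tree, and the homoplasy census built on top of it.

node_names <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  c(tree$tip.label, paste0("node", ntip + seq_len(nnode)))
}

# Hartigan parsimony (exact on multifurcating trees) for one site.
# Returns per-node final states (indices into NUC), deterministic:
# minimal total changes, then alphabetical state order.
hartigan_site <- function(tree, tip_states, postorder_edge) {
  ntip <- length(tree$tip.label)
  nnodes <- ntip + tree$Nnode
  V <- matrix(0L, nnodes, 4)          # votes per state
  B <- matrix(FALSE, nnodes, 4)       # optimal state sets
  S2 <- matrix(FALSE, nnodes, 4)      # "second" sets (votes == max - 1)
  B[cbind(seq_len(ntip), tip_states)] <- TRUE
  parents <- postorder_edge[, 1]
  children <- postorder_edge[, 2]
  finalize <- function(v) {
    K <- max(v)
    list(B = v == K, S2 = v == K - 1)
  }
  for (k in seq_len(nrow(postorder_edge))) {
    ch <- children[k]
    if (ch > ntip) {
      # postorder: all of ch's child edges already absorbed into V[ch, ]
      f <- finalize(V[ch, ])
      B[ch, ] <- f$B; S2[ch, ] <- f$S2
    }
    V[parents[k], ] <- V[parents[k], ] + B[ch, ]
  }
  final <- integer(nnodes)
  root <- ntip + 1L
  f <- finalize(V[root, ])
  B[root, ] <- f$B; S2[root, ] <- f$S2
  final[root] <- which(B[root, ])[1]
  for (k in rev(seq_len(nrow(postorder_edge)))) {
    p <- parents[k]; ch <- children[k]
    F_ <- final[p]
    if (B[ch, F_]) final[ch] <- F_
    else {
      cand <- B[ch, ]
      if (S2[ch, F_]) cand[F_] <- TRUE
      final[ch] <- which(cand)[1]
    }
  }
  final
}

# joint maximum-likelihood reconstruction (Pupko et al. dynamic programme)
# for one site under precomputed per-edge log transition matrices
pupko_site <- function(tree, tip_states, postorder_edge, logP, log_freqs) {
  ntip <- length(tree$tip.label)
  nnodes <- ntip + tree$Nnode
  root <- ntip + 1L
  # Lmat[v, s]: best log-likelihood of v's subtree given parent state s
  Lmat <- matrix(0, nnodes, 4)
  Cmat <- matrix(0L, nnodes, 4)       # best child state given parent state
  M <- matrix(0, nnodes, 4)           # sum over children of Lmat, per own state
  parents <- postorder_edge[, 1]
  children <- postorder_edge[, 2]
  for (k in seq_len(nrow(postorder_edge))) {
    ch <- children[k]
    lp <- logP[[k]]
    if (ch <= ntip) {
      Lmat[ch, ] <- lp[, tip_states[ch]]
      Cmat[ch, ] <- tip_states[ch]
    } else {
      for (s in 1:4) {
        v <- lp[s, ] + M[ch, ]
        best <- which.max(v)          # first max = alphabetical tie-break
        Lmat[ch, s] <- v[best]
        Cmat[ch, s] <- best
      }
    }
    M[parents[k], ] <- M[parents[k], ] + Lmat[ch, ]
  }
  final <- integer(nnodes)
  vroot <- log_freqs + M[root, ]
  final[root] <- which.max(vroot)
  for (k in rev(seq_len(nrow(postorder_edge)))) {
    ch <- children[k]
    final[ch] <- Cmat[ch, final[parents[k]]]
  }
  final
}

#' Per-branch nucleotide changes under a guide tree
#'
#' Reconstructs ancestral states at every internal node of a supplied
#' (possibly multifurcating) guide tree and lists each (branch, site) where
#' the parent and child states differ. Two reconstruction methods are
#' available: exact Fitch/Hartigan parsimony with deterministic tie-breaks
#' (minimal total changes, then alphabetical state order), and joint
#' maximum likelihood under an HKY model on the fixed topology. Only
#' columns at which every tree taxon carries an unambiguous nucleotide are
#' reconstructed.
#'
#' @param tree a `phylo` guide tree; its tips must all be present in `aln`.
#'   For `method = "ml"` branch lengths are used if present, otherwise
#'   re-estimated from the data (parsimony change counts with a
#'   0.5-change pseudocount per branch).
#' @param aln a `strain_alignment`.
#' @param method `"parsimony"` or `"ml"`.
#' @param kappa HKY transition/transversion rate ratio for `method = "ml"`.
#' @return data.frame of class `branch_changes` with columns `branch`
#'   (`parent->child` using tip labels and `node<k>` ids), `parent`,
#'   `child`, `site` (1-based alignment column), `from`, `to`.
#' @export
ancestral_changes <- function(tree, aln, method = c("parsimony", "ml"),
                              kappa = 2) {
  method <- match.arg(method)
  missing <- setdiff(tree$tip.label, rownames(aln))
  if (length(missing))
    stop("tree leaves missing from alignment: ", paste(missing, collapse = ", "))
  sub <- aln[tree$tip.label, , drop = FALSE]
  resolved <- colSums(!matrix(sub %in% NUC, nrow(sub))) == 0L
  variable <- resolved &
    apply(sub, 2, function(col) length(unique(col)) > 1L)
  sites <- which(variable)
  tree <- ape::reorder.phylo(tree, "postorder")
  pe <- tree$edge
  ntip <- length(tree$tip.label)
  labels <- node_names(tree)
  states_at <- function(j) match(sub[, j], NUC)
  finals <- list()
  if (method == "parsimony") {
    for (j in sites) finals[[as.character(j)]] <-
        hartigan_site(tree, states_at(j), pe)
  } else {
    el <- tree$edge.length
    if (is.null(el)) {
      # branch lengths from parsimony change counts (+0.5 pseudocount)
      counts <- numeric(nrow(pe))
      n_used <- max(sum(resolved), 1L)
      for (j in sites) {
        f <- hartigan_site(tree, states_at(j), pe)
        counts <- counts + (f[pe[, 1]] != f[pe[, 2]])
      }
      el <- (counts + 0.5) / n_used
    }
    el <- pmax(el, 1e-8)
    freqs <- table(factor(sub[, resolved, drop = FALSE], levels = NUC))
    freqs <- as.numeric(freqs / sum(freqs))
    if (any(freqs == 0)) freqs <- (freqs + 1e-6) / sum(freqs + 1e-6)
    Q <- hky_rate_matrix(freqs, kappa)
    logP <- lapply(el, function(b) log(hky_prob_matrix(b, freqs, kappa, Q = Q)))
    for (j in sites) finals[[as.character(j)]] <-
        pupko_site(tree, states_at(j), pe, logP, log(freqs))
  }
  rows <- list()
  for (j in sites) {
    f <- finals[[as.character(j)]]
    chg <- which(f[pe[, 1]] != f[pe[, 2]])
    for (k in chg) {
      rows[[length(rows) + 1L]] <- data.frame(
        parent = labels[pe[k, 1]], child = labels[pe[k, 2]],
        site = j, from = NUC[f[pe[k, 1]]], to = NUC[f[pe[k, 2]]],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(parent = character(0), child = character(0),
               site = integer(0), from = character(0), to = character(0),
               stringsAsFactors = FALSE)
  out <- data.frame(branch = if (nrow(out)) paste0(out$parent, "->", out$child)
                    else character(0), out, stringsAsFactors = FALSE)
  attr(out, "method") <- method
  attr(out, "n_sites_reconstructed") <- length(sites)
  class(out) <- c("branch_changes", "data.frame")
  out
}

#' Census of homoplasies in a per-branch change list
#'
#' Groups inferred changes by (site, ancestral state, derived state); a
#' change-type occurring on two or more distinct branches is an apparent
#' homoplasy (a recurrent identical mutation). Optionally flags whether
#' each homoplastic column is one of a supplied set of fixed
#' nonsynonymous inter-group difference sites.
#'
#' @param changes a `branch_changes` data.frame from [ancestral_changes()].
#' @param fixed_nonsyn_sites optional integer vector of alignment columns
#'   carrying fixed nonsynonymous inter-group differences.
#' @return data.frame of class `homoplasy_report` with columns `site`,
#'   `from`, `to`, `n_branches`, `branches`, `fixed_nonsyn`; the total
#'   number of homoplastic change-types is attached as attribute `"total"`.
#' @export
detect_homoplasies <- function(changes, fixed_nonsyn_sites = NULL) {
  key <- paste(changes$site, changes$from, changes$to, sep = "_")
  grp <- split(changes, key)
  keep <- Filter(function(g) length(unique(g$branch)) >= 2L, grp)
  if (length(keep)) {
    out <- do.call(rbind, lapply(keep, function(g) data.frame(
      site = g$site[1], from = g$from[1], to = g$to[1],
      n_branches = length(unique(g$branch)),
      branches = paste(sort(unique(g$branch)), collapse = ";"),
      stringsAsFactors = FALSE)))
    out <- out[order(out$site, out$from, out$to), , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out <- data.frame(site = integer(0), from = character(0),
                      to = character(0), n_branches = integer(0),
                      branches = character(0), stringsAsFactors = FALSE)
  }
  out$fixed_nonsyn <- if (is.null(fixed_nonsyn_sites))
    rep(NA, nrow(out)) else out$site %in% fixed_nonsyn_sites
  attr(out, "total") <- nrow(out)
  class(out) <- c("homoplasy_report", "data.frame")
  out
}

#' @export
print.homoplasy_report <- function(x, ...) {
  cat("homoplasy_report:", attr(x, "total"), "homoplastic change-type(s)\n")
  if (nrow(x)) print.data.frame(x)
  invisible(x)
}
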