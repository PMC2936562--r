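#' Run the full subspecies-divergence pipeline from one configuration
#'
#' Executes, in dependency order, whichever stages the configuration
#' provides inputs for: the focal-pair SNP screen, per-gene site
#' classification and diversity, gene-tree construction with bootstrap and
#' homoplasy census under guide trees, and inter-gene LD. Partial
#' configurations run the remaining stages; a failing stage is recorded
#' and later independent stages still run.
#'
#' @param config a named list, or path to a YAML file, with any of:
#'   \describe{
#'     \item{genotype_table, gene_intervals, strain_pair}{screen inputs:
#'       TSV table path, BED path, character vector of two focal strains.}
#'     \item{alignments}{named list/vector of per-gene FASTA paths, in
#'       genomic order.}
#'     \item{groups}{strain-to-group TSV path.}
#'     \item{frame_offset}{reading-frame start for coding annotation
#'       (default 0).}
#'     \item{tree_gene}{name of the alignment used for tree building; a
#'       separate `tree_alignment` FASTA path may be given instead (e.g. a
#'       cross-taxon sequence set).}
#'     \item{guide_trees}{named list/vector of Newick paths for the
#'       homoplasy census (e.g. the canonical species tree).}
#'     \item{bootstrap_reps, seed}{bootstrap settings; `seed` is required
#'       whenever a stochastic stage runs (no hidden default).}
#'     \item{exclude_pseudogenes, top_k}{screen ranking options.}
#'     \item{outdir}{optional directory; stage outputs and the report are
#'       written there with provenance checksums.}
#'   }
#' @return an object of class `run_report`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config) || !length(config))
    stop("empty configuration: supply at least one of genotype_table+",
         "gene_intervals+strain_pair, alignments, tree_alignment")
  known_inputs <- c("genotype_table", "gene_intervals", "alignments",
                    "tree_alignment")
  if (!any(known_inputs %in% names(config)))
    stop("configuration provides no inputs; missing all of: ",
         paste(known_inputs, collapse = ", "))
  for (f in c(config$genotype_table, config$gene_intervals,
              unlist(config$alignments), config$groups,
              config$tree_alignment, unlist(config$guide_trees)))
    if (!file.exists(f)) stop("input file does not exist: ", f)

  report <- list(stages = list(), warnings = character(0))
  note <- function(w) report$warnings <<- c(report$warnings, w)
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- withCallingHandlers(
      tryCatch(fun(), error = function(e)
        structure(list(error = conditionMessage(e)), class = "stage_failure")),
      warning = function(w) {
        note(paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    report$stages[[name]] <<- list(
      result = res, failed = inherits(res, "stage_failure"),
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
  }

  # --- screen ---------------------------------------------------------
  if (!is.null(config$genotype_table)) {
    if (is.null(config$gene_intervals) || is.null(config$strain_pair))
      stop("screen stage needs genotype_table, gene_intervals and strain_pair")
    run_stage("screen", function() {
      tab <- read_genotype_table(config$genotype_table)
      genes <- read_gene_bed(config$gene_intervals)
      counts <- count_differences_per_gene(tab, config$strain_pair[1],
                                           config$strain_pair[2], genes)
      list(counts = counts,
           n_with_differences = sum(counts$n_differing > 0),
           n_without = sum(counts$n_differing == 0),
           top = rank_candidates(counts,
                                 isTRUE(config$exclude_pseudogenes),
                                 config$top_k %||% 10L))
    })
  }

  # --- classify + diversity ------------------------------------------
  alns <- NULL
  partition <- NULL
  if (!is.null(config$alignments)) {
    if (is.null(config$groups))
      stop("classification stage needs a groups mapping file")
    partition <- read_groups(config$groups)
    alns <- lapply(config$alignments, read_alignment)
    names(alns) <- names(config$alignments)
    frame <- config$frame_offset %||% 0L
    for (g in names(alns)) {
      run_stage(paste0("classify_", g), local({
        gg <- g
        function() {
          aln <- alns[[gg]]
          cls <- classify_sites(aln, partition, frame_offset = frame)
          a_strains <- names(partition)[partition == "A"]
          b_strains <- names(partition)[partition == "B"]
          list(classification = cls,
               n_variable = nrow(cls),
               n_fixed = sum(cls$category == "fixed_difference"),
               n_poly_a = sum(cls$category == "polymorphic_A"),
               n_poly_b = sum(cls$category == "polymorphic_B"),
               n_poly_both = sum(cls$category == "polymorphic_both"),
               n_nonsyn = sum(cls$coding_effect == "nonsynonymous"),
               n_syn = sum(cls$coding_effect == "synonymous"),
               diversity_A = diversity(aln, intersect(a_strains, rownames(aln))),
               diversity_B = diversity(aln, intersect(b_strains, rownames(aln))))
        }
      }))
    }
  }

  # --- gene tree + homoplasy census ----------------------------------
  tree_aln <- NULL
  if (!is.null(config$tree_alignment))
    tree_aln <- read_alignment(config$tree_alignment)
  else if (!is.null(config$tree_gene) && !is.null(alns))
    tree_aln <- alns[[config$tree_gene]]
  if (!is.null(tree_aln)) {
    run_stage("gene_tree", function() {
      reps <- config$bootstrap_reps %||% 0L
      if (reps > 0 && is.null(config$seed))
        stop("bootstrap is stochastic: config must set an explicit seed")
      nj <- neighbor_joining(f84_distance_matrix(tree_aln))
      bs <- if (reps > 0)
        bootstrap_support(tree_aln, n_reps = reps, seed = config$seed)
      list(tree = nj, bootstrap = bs,
           clamped_branches = attr(nj, "clamped"))
    })
    if (!is.null(config$guide_trees) &&
        !isTRUE(report$stages$gene_tree$failed)) {
      fixed_nonsyn <- NULL
      cls_stage <- report$stages[[paste0("classify_", config$tree_gene %||%
                                           names(alns)[1] %||% "")]]
      if (!is.null(cls_stage) && !cls_stage$failed) {
        cc <- cls_stage$result$classification
        fixed_nonsyn <- cc$site[cc$category == "fixed_difference" &
                                  cc$coding_effect == "nonsynonymous"]
      }
      guide <- lapply(config$guide_trees, ape::read.tree)
      names(guide) <- names(config$guide_trees)
      guide$nj_gene_tree <- report$stages$gene_tree$result$tree
      for (gt in names(guide)) {
        run_stage(paste0("homoplasy_", gt), local({
          tr <- guide[[gt]]
          function() {
            per_method <- lapply(c(parsimony = "parsimony", ml = "ml"),
                                 function(mm) {
              ch <- ancestral_changes(tr, tree_aln, method = mm)
              detect_homoplasies(ch, fixed_nonsyn_sites = fixed_nonsyn)
            })
            list(parsimony = per_method$parsimony, ml = per_method$ml,
                 n_parsimony = attr(per_method$parsimony, "total"),
                 n_ml = attr(per_method$ml, "total"),
                 rf_to_gene_tree = suppressMessages(phangorn::RF.dist(
                   ape::unroot(tr),
                   ape::unroot(report$stages$gene_tree$result$tree))))
          }
        }))
      }
    }
  }

  # --- linkage disequilibrium ----------------------------------------
  if (!is.null(alns) && length(alns) >= 2L) {
    run_stage("ld", function() {
      hap <- concatenate_haplotypes(alns)
      r2_matrix(hap)
    })
  }

  report$provenance <- list(
    package = as.character(utils::packageVersion("subspecscan")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    timestamp_format = "not recorded (reports are content-addressed)",
    input_checksums = {
      files <- unlist(config[c("genotype_table", "gene_intervals",
                               "alignments", "groups", "tree_alignment",
                               "guide_trees")], use.names = FALSE)
      if (length(files)) as.list(tools::md5sum(files)) else list()
    })
  class(report) <- "run_report"
  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run report (JSON summary plus per-stage TSV/Newick files)
#' @param report a `run_report`.
#' @param outdir output directory.
#' @return invisibly, the summary JSON path.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  summ <- summary(report)
  for (nm in names(report$stages)) {
    st <- report$stages[[nm]]
    if (st$failed) next
    res <- st$result
    if (!is.null(res$classification))
      utils::write.table(res$classification,
                         file.path(outdir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$counts))
      utils::write.table(res$counts, file.path(outdir, "screen_counts.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$tree))
      ape::write.tree(res$tree, file.path(outdir, "gene_tree.nwk"))
    if (inherits(res, "ld_matrix")) {
      utils::write.table(round(res$r2, 6),
                         file.path(outdir, "ld_r2.tsv"),
                         sep = "\t", quote = FALSE)
      utils::write.table(res$gene_pairs,
                         file.path(outdir, "ld_gene_pairs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(res$parsimony))
      utils::write.table(as.data.frame(res$parsimony),
                         file.path(outdir, paste0(nm, "_parsimony.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  path <- file.path(outdir, "report.json")
  jsonlite::write_json(summ, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
summary.run_report <- function(object, ...) {
  out <- list()
  for (nm in names(object$stages)) {
    st <- object$stages[[nm]]
    if (st$failed) {
      out[[nm]] <- list(failed = TRUE, error = st$result$error)
      next
    }
    res <- st$result
    keep <- res[vapply(res, function(x)
      is.numeric(x) && length(x) == 1L, TRUE)]
    if (!is.null(res$diversity_A))
      keep <- c(keep, list(pi_A = res$diversity_A$pi,
                           theta_A = res$diversity_A$theta_w,
                           pi_B = res$diversity_B$pi,
                           theta_B = res$diversity_B$theta_w))
    if (inherits(res, "ld_matrix"))
      keep <- list(gene_pairs = res$gene_pairs)
    # stage timings stay in print(); the JSON summary must be byte-identical
    # across reruns with the same config and seeds
    out[[nm]] <- keep
  }
  out$warnings <- object$warnings
  out$provenance <- object$provenance
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report with", length(x$stages), "stage(s):\n")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-24s %s (%.2fs)\n", nm,
                if (st$failed) paste("FAILED:", st$result$error) else "ok",
                st$seconds))
  }
  if (length(x$warnings))
    cat("warnings:\n", paste(" -", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}
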