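---
title: "Scanning multi-strain panels for subspecies-diagnostic divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning multi-strain panels for subspecies-diagnostic divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subspecscan)
```

## The problem

Two parapatric house-mouse subspecies, *M. m. domesticus* and
*M. m. musculus*, meet along a narrow European hybrid zone where selection
acts against hybrids. A candidate mechanism for assortative mating is a
receptor gene that has diverged so strongly between the subspecies that
each carries its own fixed allele. `subspecscan` implements the complete
analysis chain used to find and characterise such genes when each
subspecies is sampled as a panel of wild-derived inbred strains (single
haplotypes, no heterozygotes):

1. **Screen** a strain SNP genotype table for genes where two focal
   strains (one per subspecies) carry differing, unambiguous genotypes.
2. **Classify** every variable column of a two-group multi-strain
   alignment as a fixed inter-group difference or a (private or shared)
   polymorphism, and annotate fixed differences as synonymous or
   nonsynonymous.
3. **Summarise** within-group variation with nucleotide diversity
   ($\pi$) and Watterson's $\theta_W$.
4. **Build a gene tree** from F84 pairwise distances by neighbor-joining
   with column-bootstrap support, and compare it with the canonical
   species history.
5. **Census homoplasies**: reconstruct ancestral states on a guide tree
   and count identical nucleotide changes inferred on more than one
   branch. A diverged allele acquired by introgression produces many
   apparent homoplasies under the species tree and none under the gene's
   own tree.
6. **Quantify linkage disequilibrium** ($r^2$) between genes across
   concatenated variable sites, to distinguish functional association
   from residual physical linkage.

A synthetic-data generator produces every input with recorded ground
truth, so the whole pipeline is testable end to end without any external
download.

## Models and statistics

### Site classification

For a two-group partition, a fully resolved variable column is a *fixed
difference* when both groups are internally monomorphic with different
nucleotides, *private polymorphism* when variable within exactly one
group, and *shared polymorphism* otherwise. Columns containing `N` or a
gap are excluded from all site statistics (complete deletion, the default
behaviour of standard polymorphism software); this makes the segregating
site count $S$ unambiguous.

The coding effect of a fixed difference is scored per site: the group-A
consensus codon containing the site is compared with the codon obtained
by substituting group B's allele at that site only. When a codon carries
several fixed differences this choice is not unique; a joint
codon-comparison mode (`joint_codon = TRUE`) is provided, but the
site-wise convention is the default because it is deterministic, local,
and matches how individual sites are usually reported. Codons truncated
by the alignment edge or with unresolved consensus bases are
`not_assessed`.

### Diversity

For $n$ sequences and $L_\mathrm{eff}$ fully resolved columns,
$$\pi = \frac{2}{n(n-1)\,L_\mathrm{eff}} \sum_{i<j} d_{ij}, \qquad
\theta_W = \frac{S}{a_n L_\mathrm{eff}}, \qquad
a_n = \sum_{i=1}^{n-1} \tfrac1i,$$
with $d_{ij}$ the count of differing included columns. Both are reported
per site. $S = 0$ forces $\pi = \theta_W = 0$, and
$\theta_W a_n L_\mathrm{eff}$ recovers $S$ exactly (an invariant the test
suite asserts).

### F84 distances and neighbor-joining

Pairwise distances use the F84 model with base frequencies pooled over
the pair. With $\pi_R = \pi_A + \pi_G$, $\pi_Y = \pi_C + \pi_T$,
$A = \pi_C\pi_T/\pi_Y + \pi_A\pi_G/\pi_R$, $B = \pi_C\pi_T + \pi_A\pi_G$,
$C = \pi_R\pi_Y$, and transition/transversion proportions $P$ and $Q$:
$$d = -2A\,\ln\!\Big(1 - \frac{P}{2A} - \frac{(A-B)Q}{2AC}\Big)
      + 2(A-B-C)\,\ln\!\Big(1 - \frac{Q}{2C}\Big).$$
The implementation is validated against an independent implementation
(`ape::dist.dna`) and against the JC69 and K80 closed forms, to which the
expression reduces for uniform composition (the test suite constructs a
pair with exactly uniform pooled composition and transitions at one third
of all differences, where $d = -\tfrac34\ln(1-\tfrac43 D)$ must hold to
machine precision). Saturated pairs (non-positive logarithm argument) are
reported as `Inf` with a warning rather than silently truncated.

Neighbor-joining follows the Studier–Keppler formulation. Ties in the
$Q$-criterion are broken toward the smallest (row, column) pair so runs
are reproducible under taxon permutation (topology is permutation
invariant; the tie-break only fixes which of several equal-score joins is
taken first). Negative branch-length estimates are clamped to zero and
counted in the `clamped` attribute. On additive matrices the tree and all
path distances are recovered exactly; this is asserted to $10^{-9}$.

Bootstrap support resamples columns with replacement, rebuilds F84 + NJ
per replicate, and reports the recurrence frequency of each original
bipartition as a percentage. One master seed drives sequential
per-replicate draws, so a seed fixes the entire analysis; an omitted seed
is an error rather than a hidden default.

### Ancestral reconstruction and the homoplasy census

Two reconstructions are reported side by side:

* **Parsimony** uses Hartigan's generalisation of the Fitch algorithm,
  exact on multifurcating trees (needed because the canonical species
  history treats the three *M. musculus* subspecies as an unresolved
  polytomy). Ties are resolved toward minimal total changes, then
  alphabetical state order.
* **Joint maximum likelihood** uses the Pupko dynamic programme under an
  HKY model (empirical base frequencies, $\kappa = 2$ by default) on the
  fixed topology. When the guide tree carries no branch lengths they are
  estimated from per-branch parsimony change counts with a 0.5-change
  pseudocount, and floored at $10^{-8}$ so that forced changes across
  near-zero branches remain representable.

The original analysis this package re-implements reconstructed ancestors
under a codon model; reconstruction here is at nucleotide level, which is
why both methods are always reported and why agreement between them (a
property asserted for low-divergence simulations) matters.

A *homoplasy* is a (site, ancestral state, derived state) change-type
inferred on two or more branches. The census counts change-types, not
change instances; per-entry branch lists are retained so instance counts
can be recovered. The report can flag which homoplastic columns coincide
with fixed nonsynonymous inter-group differences — the signature that the
diverged allele itself, not background noise, drives the species-tree
incongruence.

### Linkage disequilibrium

Inbred strains are phased haploid haplotypes, so $r^2$ needs no EM
phasing. For biallelic sites with major-allele frequencies $p_i, p_j$ and
joint frequency $p_{ij}$ over pairwise-complete rows:
$$r^2 = \frac{(p_{ij} - p_i p_j)^2}{p_i(1-p_i)\,p_j(1-p_j)}.$$
Multi-allelic columns are excluded (with a logged count). Pairs that
become monomorphic after missing-data removal are *undefined* (`NA`),
deliberately distinct from $r^2 = 0$. Because a site-level heat map and a
gene-level claim are different things, gene pairs are summarised by both
the maximum and the mean $r^2$.

## The synthetic study data

`synthetic_study()` builds a coordinated stand-in for the study design:
ten strains (five per subspecies), three genes, and a nine-taxon
cross-species alignment. All sequences are simulated; the *structure* is
injected and the pipeline must recover it by computation:

* `Vmn1r67` (915 bp): 24 fixed differences (15 nonsynonymous,
  9 synonymous, each engineered inside its own codon) plus 2
  domesticus-private polymorphisms — 26 variable sites.
* `Vmn1r71` (921 bp): 35 polymorphisms (18 + 17 private to each group),
  no fixed differences. With singleton minor alleles this makes
  `Vmn1r71` roughly an order of magnitude more diverse than `Vmn1r67`,
  reproducing the qualitative ten-fold $\pi$/$\theta$ contrast.
* `Abpa27` (1185 bp): 5 fixed differences, no polymorphism, hence
  complete LD with the fixed sites of `Vmn1r67` and low LD with
  `Vmn1r71`.
* The cross-taxon alignment gives the domesticus allele a history
  discordant with the species tree: at 19 of the 24 fixed columns
  (14 nonsynonymous, 5 synonymous) *M. spretus* shares the derived
  domesticus state. Under the species tree (subspecies polytomy) every
  such column is reconstructed as the same change on two branches — 19
  apparent homoplasies, 14 of them at fixed nonsynonymous columns —
  while the gene's own NJ tree explains the data with zero homoplasies.
  All other injected sites are clade synapomorphies on edges shared by
  both histories, or terminal autapomorphies (8 per taxon), chosen so
  that every pattern has a unique most-parsimonious reconstruction and
  parsimony and ML therefore agree exactly.

What the generator does *not* emulate: coalescent genealogy and
recombination within genes, rate heterogeneity across sites, indels,
array-specific genotyping error (the `N` masking is plain Bernoulli), and
realistic allele-frequency spectra (injected polymorphisms are singletons
by default, configurable via `minor_copies`). Passing tests therefore
demonstrate correctness of the *computations* under the stated design,
not robustness to every property of real resequencing data.

Defaults were fixed once from the study design: 5 strains per group, gene
lengths 915/921/1185 bp, uniform base composition, $\kappa = 2$, frame
offset 0 (the genes are intron-less with coding lengths divisible by 3).

## Numerical and design choices

* Genotype tables carry 1-based positions; gene intervals are BED-style
  0-based half-open. A SNP at position $p$ belongs to a gene iff
  $p - 1 \in [\mathrm{start}, \mathrm{end})$; a SNP in two overlapping
  genes counts in both, with a warning.
* `N` genotypes never count as screen differences (conservative, matching
  the upstream data supplier's intent); candidate ranking breaks ties
  lexicographically.
* Ambiguity codes other than `N` are rejected at parse time.
* The JSON run report contains no timestamps or timings, so identical
  configurations and seeds give byte-identical reports; stage timings are
  shown only by `print()`.
* Problem sizes used by the packaged checks — 10–1,000 gene screen
  tables, 392 genes in the worked example (the size of the receptor-gene
  family that motivated the design), 1,000 bootstrap replicates, and
  $10^5$-site simulations for distance consistency — were chosen as the
  smallest sizes at which the statistical assertions are sharp.

## Known limitations

* The Perlegen-style screen logic is exact, but the published 165/392
  screen tally requires the external SNP release, which is not shipped;
  the screen is instead verified exactly against generator ground truth.
* Nucleotide-level reconstruction is a related but not identical model to
  codon-level reconstruction; homoplasy totals on real data can differ
  between the two even when both are internally consistent.
* No neutrality tests (e.g. Tajima's D), no D′, no significance testing
  for LD, no recombination-aware methods — all deliberately out of scope.

## A worked run

```{r, eval = FALSE}
st <- synthetic_study(seed = 1)
paths <- write_synthetic_study(st, "study")
report <- run_pipeline(list(
  alignments = list(Vmn1r67 = paths$Vmn1r67, Vmn1r71 = paths$Vmn1r71,
                    Abpa27 = paths$Abpa27),
  groups = paths$groups, frame_offset = 0,
  tree_alignment = paths$cross_taxon,
  guide_trees = list(species = paths$species_tree),
  bootstrap_reps = 1000, seed = 42, outdir = "study/out"))
print(report)
summary(report)$homoplasy_species
```
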