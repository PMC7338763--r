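---
title: "Detecting the molecular signatures of C4 gene recruitment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting the molecular signatures of C4 gene recruitment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(c4recruit)
```

## The scientific setting

C4 photosynthesis evolved repeatedly from C3 ancestors by recruiting
pre-existing housekeeping genes into new roles. A recruited gene typically
shows a recognizable bundle of changes relative to its C3 counterpart:
fixed amino-acid differences between C3 and C4 orthologs, occasionally a
lineage-specific insertion, new cis-regulatory elements in the promoter,
higher transcript abundance with shifted tissue and cell-type specificity
(root to leaf, bundle sheath to mesophyll), faster light induction, and -
sometimes, though not necessarily - a signal of positive selection in the
coding sequence. The genus *Flaveria*, which contains C3, C3-C4
intermediate, C4-like and C4 species in two clades, is the classic system
for ordering these events along a phylogeny; the
phosphoenolpyruvate/phosphate translocator (PPT) paralog pair is the
motivating example throughout this package.

`c4recruit` implements each of these signature detectors as a small,
separately testable stage, together with a synthetic-data module that
generates every input with known ("planted") truth. All results in this
vignette and in the test suite are computed from those generated inputs;
the package makes no claims about external datasets, which would require
genome assemblies and read data it does not ship.

## Consistent amino-acid modifications

A *consistent modification* is an alignment column fixed for one residue
in every C3 species and for a different residue in every C4 species.
Intermediate species never veto the call; they only inform where on the
tree the change arose. `classify_columns()` applies this definition
column by column; the origin of each modification is then mapped with
Fitch small parsimony (`map_origin_node()`).

Decisions the definition leaves open, and the defaults chosen here:

* **Which species are "C4"?** C4-like species are *excluded* from the C4
  group by default; callers can include them explicitly. Both choices are
  reported in the output.
* **Gaps.** A gap is a 21st character state; all-gap columns are skipped.
  Runs of two or more columns in which one group is entirely gapped are
  insertion spans and are routed to the repeat detector rather than
  counted as point modifications, mirroring how insertions are reported
  separately from amino-acid changes in comparative studies.
* **Fitch ambiguity.** Ties at the root resolve toward the ancestral
  (non-derived) state; below the root a node inherits its parent's state
  whenever the Fitch set allows it. When a derived state arises more than
  once, the origin covering the most derived tips is reported. All
  tie-breaks are deterministic.

```{r}
sim <- simulate_ortholog_set(sim_config(
  seed = 7, subst_rate = 0,
  planted_mods = data.frame(column = c(50, 120), anc = c("A", "K"),
                            derived = c("S", "T"), origin = "N7")))
classify_columns(sim$set$protein, c("Fcro", "Frob"),
                 c("Fkoc", "Faus", "Fbid", "Ftri"),
                 tree = sim$set$tree)[, 1:4]
```

## Tandem-repeat insertions and slipped-strand mispairing

The repeat stage is *alignment-anchored*: an insertion span is a maximal
run of columns gapped in some species (the non-carriers) and
residue-bearing in others. Within a span the repeat unit is found by
exhaustive enumeration over unit lengths and offsets - the span is tens
of residues, so exhaustive search is cheap and lets the tests compare
against an independent brute-force oracle. The decomposition covering
the most residues wins; ties go to the smallest unit. Each copy may
deviate from the copy consensus by `max_mismatch_per_copy` (default 2)
residues, reflecting that published repeat units vary at a handful of
sites across copies and species.

The slipped-strand-mispairing evidence has three parts:

1. `infer_ancestral_unit()` - the element at the N-terminal boundary of
   the insertion, present identically in *all* species and matching a
   suffix of the repeat unit; its edit relation to the unit (for the PPT1
   reconstruction: one missing N-terminal alanine) is reported.
2. `find_flanking_direct_repeats()` - the longest DNA word occurring at
   both the head and the tail of the slippage segment's CDS (capped at
   half the region to avoid degenerate self-overlap).
3. `nussinov_hairpin()` - the Nussinov maximum base-pairing dynamic
   program over Watson-Crick pairs plus, by default, G-T wobble (the DNA
   is treated as a transcript proxy; switchable). "Hairpin-capable" means
   the maximum pairing reaches `ceiling(length/6)` - an artifact
   convention chosen because no thermodynamic model is implied; the claim
   tested is the boolean capability, not a folding energy.

The bundled `ppt1_insertion_fixture()` is a synthetic reconstruction of
the published *Flaveria* PPT1 insertion region: a 13-aa unit
`AAASVPDSADGGY` with variants at unit positions 3, 8, 10 and 13, four
copies in one set of carriers and five in another, a conserved 12-aa
element upstream, a triplet alanine after it, and alanine codons pinned
to `GCG` so the 15-aa segment's CDS carries the `GCGGCG` direct repeat at
both ends. It is assembled from the published textual description, not
transcribed from sequence archives, and is labeled synthetic in its
documentation.

```{r}
fx <- ppt1_insertion_fixture()
ins <- detect_tandem_insertion(fx$set)[[1]]
c(unit = ins$unit_length_aa, copies_Ftri = unname(ins$copies["Ftri"]),
  copies_Fkoc = unname(ins$copies["Fkoc"]))
find_flanking_direct_repeats(fx$segment15_cds)
```

## Promoter submodules

Promoters are handled on the coding strand with the 3' end abutting the
start codon; positions are signed upstream offsets (offset -1 is the base
adjacent to the A of ATG), matching how promoter coordinates are printed
in the plant literature. Internally, coordinates are 0-based half-open
slices with a tested converter pair (`offset_to_index()` /
`index_to_offset()`).

`scan_motif()` reports every window matching an IUPAC motif with at most
`max_mismatch` substitutions; there is deliberately *no* enrichment
statistic - presence, counts and placement are what the comparative
argument uses, and a background model would suggest a rigor the data do
not support. The shipped library contains the MEM1 B-submodule core, the
15-mer `AAAACAAACAAAAAC`; a "submodule present" call requires two copies
within a 60 bp window (the published submodule is two tandem copies
within ~44 bp; the window is configurable). Only the two printed copies
and their tandem geometry are encoded - the full extent of the submodule
beyond the core is not modeled.

Promoter identity uses global Needleman-Wunsch alignment with match +1,
mismatch 0, linear gap -1, and deterministic tie-breaking
(diagonal > up > left). Published promoter-identity figures do not state
alignment parameters, so the defaults are documented, logged in every
output, and configurable. `find_conserved_blocks()` scores consecutive
50-column windows of the global alignment, merges windows at or above 70%
identity, and trims blocks to matched columns; an insertion in one
promoter therefore splits a conserved region into two reported blocks.

## Expression shifts

* `counts_to_tpm()` / `counts_to_fpkm()` implement the standard
  normalizations (TPM columns sum to one million by construction). The
  two units are never merged silently.
* `relative_abundance()` is the delta-Ct rule `2^-(Ct_target - Ct_ref)`
  against an ACTIN7-style reference.
* `stepwise_light_test()` compares each time point to the preceding one.
  The test is Welch's unequal-variance t-test, two-sided and unpaired by
  default: the variant is rarely stated in figure legends, so it is
  configurable and recorded. Tests run on raw relative abundances (a log
  option exists), matching common qRT-PCR practice; the star convention
  is `*` for p in [0.01, 0.05), `**` for [0.001, 0.01), `***` below
  0.001, with a separately reported marginal band up to 0.10 because
  marginal light responses are biologically discussed. When both groups
  are constant with equal means, p is 1 by convention. No multiple-testing
  correction is applied across intervals - the stepwise display is
  descriptive, not a family of confirmatory tests.
* `recruitment_switch()` flags the expression handover that accompanies
  recruitment: the paralog dominating the C3 leaf (and mesophyll) differs
  from the one dominating the C4 leaf (and mesophyll). C4-like species
  are not counted as C4 by default.

## The branch-site positive-selection test

The coding-sequence test is the standard branch-site ("model A")
likelihood-ratio test with uniform codon frequencies (1/61): four site
classes with background/foreground omega pairs (w0, w0), (1, 1),
(w0, w2), (1, w2) and proportions p0, p1, p2·p0/(p0+p1), p2·p1/(p0+p1).
The null model fixes w2 = 1; twice the log-likelihood difference is
referred to a chi-square distribution with one degree of freedom, and
p-values are Benjamini-Hochberg adjusted across genes at a 0.05
threshold.

Numerical choices:

* **Rate-matrix scaling.** The three class matrices share one scale - the
  mean rate of the background site-class mixture - so branch lengths are
  expected substitutions per codon and a positively selected class
  evolves *faster*, not merely with a different substitution composition.
  (Scaling each class to unit rate would silently discard most of the
  power of the test.) With uniform frequencies the generators are
  symmetric, so transition matrices come from symmetric
  eigendecompositions.
* **Pruning.** Felsenstein pruning over the 61 sense codons runs in
  compiled code with per-node rescaling; the two purely-background
  classes are single-omega prunings, and the two selection classes reuse
  all background subtree conditionals, recomputing only the path from the
  foreground branches to the root.
* **Optimization.** Nelder-Mead on transformed parameters (log kappa,
  logit w0, softmax class proportions, log(w2 - 1)). The null fit uses up
  to three documented starting points; the alternative is warm-started
  from the null solution, which guarantees the nesting inequality up to
  the boundary: when the optimizer ends below the null likelihood the
  boundary solution w2 = 1 (identical to the null model) is returned and
  the statistic is 0, the familiar point mass of the boundary LRT.
  Branch lengths are taken from the input tree; a global scale factor can
  be co-estimated under the null and is reused by the alternative.
* **Gaps and stops** are removed codon-column-wise before fitting.
* Convergence codes are carried through in every fit result, never
  silently dropped.

Because published selection scans rarely print their likelihoods, the
test's correctness is established by simulation instead: a null
calibration (200 replicates, 300 codons, 8 taxa; empirical size well
below the nominal 5%, as expected for a boundary test) and a power study
(w2 = 5, 500 codons; power above 0.8). The 8-taxon simulation tree uses
branch lengths of 0.1-0.3 expected substitutions per codon with a
0.3-length foreground stem and true parameters kappa = 2, w0 = 0.2,
p0 = 0.6, p1 = 0.2 - values in the range used by branch-site power
studies in the molecular-evolution literature. The simulation studies use
a single documented optimizer start per fit (the calibration tree and
parameters are fixed, making dispersed starts redundant there); user-facing
fits default to the multi-start strategy. Foreground branches follow the
`#1` Newick tag convention (`read_foreground_newick()`), and the two-clade
analysis style - testing with and without a second clade - is a loop over
foreground configurations, not special-cased code.

## The synthetic-data module

`simulate_ortholog_set()` evolves a root protein tip-ward with Poisson
substitutions under a uniform replacement kernel - the consistency
classifier is alphabet-agnostic, so an empirical exchange matrix would
add realism the downstream statistics never see - then overwrites planted
modifications below their origin node, applies the configured insertion
(gap columns elsewhere), and back-translates each tip with a
deterministic codon choice (lexicographically first codon, with per-amino
-acid overrides for pinned DNA such as `GCG` alanines). The default tree
is the 16-tip two-clade topology with the C4-like/C4 stem labeled `N7`
and branch lengths of 0.02-0.1; at the default substitution rate of
0.02/site this yields a realistic handful of incidental substitutions per
protein without overwhelming planted signal. Promoter, expression,
light-course and qPCR generators follow the same pattern: log-normal
noise around configured means, a 0/0.5/2/4 h light grid, three
replicates, and truth tables returned alongside every dataset.

What the generators deliberately do *not* emulate: indel evolution beyond
the single configured insertion, read-level RNA-seq noise, alignment
error, and correlated evolution among sites. Passing recovery tests on
these simulations therefore demonstrates that the detectors are correct
given clean orthology and alignment - not that they are robust to
upstream pipeline errors in real data.

## Problem sizes and limitations

The test suite and the demonstration pipeline run at desk scale: 400-site
proteins on 16 taxa for modification recovery (100 seeds), 300-500 codons
on 8 taxa for the selection calibration (200 null replicates, 40 power
replicates), 3 kb promoters, and 600 bp sequences for the conserved-block
false-positive check. These sizes were chosen so the full statistical
story - exact recovery, calibration, power - is reproducible in minutes
on a single core.

Known limitations: the consistency classifier is a fixed-difference
screen, not an ancestral-state model, and reports nothing about
intermediate lineages beyond origin placement; the repeat detector is
alignment-anchored and will not find insertions absent from the
alignment; hairpin capability is a pairing count, not a free-energy
statement; the branch-site implementation fixes codon frequencies at
1/61 (the uniform-frequency setting) and does not implement BEB site
identification or alternative frequency models.
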