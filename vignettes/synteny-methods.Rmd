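---
title: "Methods: synteny-based orthology and duplication-scenario parsimony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synteny-based orthology and duplication-scenario parsimony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralogon)
```

## Why synteny

Gene families that expanded in a rapid radiation — the oxytocin–vasotocin
(OT/VT) receptors being the motivating case — cannot be sorted into
orthologs and paralogs by sequence similarity alone: paralogs are often as
similar to each other as orthologs are across distant lineages, and local
alignment tools return partial hits that mislead naming. The conserved
gene neighbourhood of a locus, by contrast, is inherited through
speciation and through whole-genome duplication (WGD), and decays only
through rearrangement and gene loss. This package operationalises
neighbourhood evidence at three scales and couples it to an explicit
parsimony engine over genome-level mutational events.

Gene **order** is the primary axis throughout: every synteny operation
counts genes, not base pairs. Base-pair coordinates (0-based, half-open;
GFF3 input is converted on load) are optional and used only by the
bp-window operations (`territory()` in bp mode, `te_flank_scan()`).

## Microsynteny (ten-gene windows)

`window_profile()` records the family labels of the `k = 5` nearest
protein-coding genes on each side of a focus gene. Non-protein-coding
records are skipped by default — annotations interleave miRNAs and
pseudogenes inconsistently across species, and a flag (`include_noncoding`)
restores them. Unlabelled neighbours become anonymous singletons so they
can never produce a spurious match.

`shared_synteny_score()` counts distinct families present in both windows.
Matching is order-free by default because small inversions are pervasive
and do not bear on orthology; an order-aware longest-common-sublist length
is also reported. The score is symmetric and bounded by `2k`.

`assign_orthogroups()` groups candidates greedily against group consensus
windows (the union of families seen in at least two member species),
seeded from the best-annotated species, joining a group when at least
`min_shared = 3` of the up-to-10 window families match. The value 3
mirrors the chromosome-scale minimum-aligned-pairs setting applied at
window scale; it is exposed, not asserted as canonical. Within a species,
co-members of one group are suffixed `a`, `b`, ... by descending shared
synteny, ties broken by (chromosome, order index) — so a lineage-specific
duplicate is named after its weaker-syntenic copy.

`classify_locus()` separates three situations for a species lacking the
focus gene: at least `min_territory = 3` consensus families co-occurring
within a 10-gene span means the gene was deleted from a retained territory;
fewer means the territory itself is gone; partial evidence confined to a
scaffold shorter than the span is reported `unresolved` rather than
absent, since fragmented assemblies routinely truncate territories. The
threshold 3 is a design choice — the source analyses speak only of "a
larger block of genes" — and is configurable.

## Macrosynteny (chromosome scale)

`collinear_chains()` finds maximal runs of homologous gene pairs strictly
monotone on both genomes (anti-diagonal runs capture inversions),
consecutive pairs at most `max_gap = 20` genes apart on both axes, and at
least `min_pairs = 3` pairs long (2 is the recommended setting for very
distant comparisons). Chains are enumerated over *immediate* successor
links: any pair insertable between two chain members always shortens both
gaps, so maximal chains use only immediate links — this makes enumeration
exact and cheap. The implementation is verified against a brute-force
enumerate-and-filter oracle on randomized instances of up to 14 pairs.

`chromosome_hit_counts()` counts, per query chromosome, the *distinct*
reference genes participating in any chain — deduplicated, because the
downstream test uses the reference scaffold's gene count as its sample
size, and a gene hit twice is still one gene. `top2_test()` compares the
two best chromosomes with χ² = Σ(O−E)²/E on [h₁, n−h₁; h₂, n−h₂], df = 1,
two-sided, without continuity correction (none is specified by the method
being reproduced; the statistic equals the pooled two-proportion z², which
the tests assert to 1e-10). `density_normalize()` guards against the top
chromosome merely being gene-rich: hits-per-gene rates plus a Spearman
rank correlation between counts and totals, flagging rate/count
disagreement.

## Territories and paralogons

`territory()` collects genes within a 10-Mb window (or the 40 nearest
genes when coordinates are absent — the two specs are treated as
equivalent because a 10-Mb window typically captures more than 40 genes,
and they agree exactly on uniformly spaced fixtures). `territory_overlap()`
counts shared families between territories; family identity, not gene
identity, defines overlap, so WGD paralogons appear as strongly
overlapping territory pairs. `deleted_locus_anchor()` transfers the 10
flanking families of a donor species that retains a gene into a genome
that lost it; when the matched flanks split across chromosomes the fission
is reported — the signature seen at the mammalian *VTR2A* locus.

## Dollo reconstruction and scenarios

`dollo_reconstruct()` places a single gain at the MRCA of the lineages
carrying a gene and one loss on the branch above each maximal subtree that
contains absences but no presence. Cells coded `.` (never evolved there, or
unresolvable, as for the hagfish receptor subfamilies) are unconstrained.
The implementation is property-tested against exhaustive enumeration of
all single-gain labelings on trees of up to 8 leaves.

`apply_scenario()` replays branch-anchored event lists (the same `event()`
vocabulary the simulator uses) and `scenario_consistent()` checks the
predicted per-lineage repertoires and same-chromosome pairs against an
observation. `step_count()` prices a scenario with unit costs per
elementary event; a segmental duplication whose copy lands on another
chromosome decomposes into duplication + translocation (2 steps). This
decomposition is this package's declared event model: it is the minimal
explicit model under which both packaged hypotheses are well-defined, and
under it the one-WGD encoding costs 1 (tandem duplication) + 1 (WGD) +
2 + 2 (two translocated segmental duplications) = 6 steps, while the
two-WGD encoding costs 1 + 2 (two WGDs) + 2 (jawed-vertebrate-stem losses
of the never-observed fourth subfamily pair) + 4 (lamprey-stem losses of
the classes lampreys lack under that hypothesis) = 9. The five downstream
lineage-specific losses (*VTR2B* in tetrapods, *VTR2A* in mammals and in
teleosts, *VTR1B* in holosteans+teleosts, *VTR2C* in birds) are common to
both hypotheses; they ship as a separate suffix
(`append_lineage_losses()`) used for consistency checking, and are
excluded from both counts so the comparison isolates what distinguishes
the hypotheses. The hagfish lineage is scored only under the one-WGD
scenario (where its two-receptor repertoire emerges with no extra events,
if hagfish branched before the WGD) and left unresolved under the two-WGD
scenario, which would require additional uncounted losses — hence that
count is a lower bound.

`min_steps_search()` is an exhaustive branch-and-bound over loss/
duplication histories at gene-class granularity, kept deliberately at desk
scale (3-leaf trees, bounds ≤ 12): leaf branches are solved in closed form
(set differences), internal branches by canonical-order enumeration.

## The synthetic generator

`simulate_evolution()` plays events down a rooted species tree from an
ancestral gene order, supporting both explicit per-branch event lists
(so specific histories can be encoded exactly) and per-branch Poisson
rates (for property tests). Every gene carries a hidden locus label that
duplications extend deterministically (`/a`,`/b` for WGD copies — a WGD
*renames* a locus; `/t*`,`/s*` for tandem/segmental copies, which are new
loci), so ground-truth orthology falls out of the log. Tandem duplications
can leave a TE-TIR marker flanking the copy, surfacing later as a
repeat-track interval — emulating the cut-and-paste transposon footprint
proposed for the OT/VT duplication.

The packaged `h1_receptor_config()` is the generator's reference
condition: ten lineages (hagfish branching basally, which lets the
two-receptor hagfish repertoire arise with zero lineage-specific events),
a 62-gene receptor chromosome with zoned neighbourhoods plus three
background chromosomes, the 1R WGD on the vertebrate stem followed by
reciprocal near-zone gene losses (which is what differentiates the four
post-WGD receptor territories — the generator's stand-in for the massive
post-WGD gene loss real paralogons show), two translocated segmental
duplications creating *VTR1B* and *VTR2C* with two inherited plus eight
novel window families each, the ligand tandem duplication with TE-TIR
mark, the placental OT inversion, the teleost and holostean OT
translocations, the mammalian fission at the deleted *VTR2A* locus, and
the five lineage losses. Neighbourhood sizes were chosen once so that
distinct receptor windows share at most 2 families (below `min_shared`)
while WGD-paralogon territories share dozens.

What the generator does **not** emulate: nucleotide sequences and their
divergence (no substitution model — GC, intron and alignment analyses run
on separately constructed structures), unequal intergenic spacing
(synthetic coordinates are uniform), assembly errors beyond a simple
fission stand-in for scaffold fragmentation, and background gene turnover
outside the configured events. Green tests therefore demonstrate that the
inference chain is correct *given* annotated gene orders and homology
labels, not that those labels are easy to obtain from real assemblies.

## Encoded observations

The packaged presence/absence matrix encodes the observed repertoires at
lineage-group granularity. Two choices deviate from a literal reading of
the figure it mirrors: holosteans and teleosts are separate leaves (the
spotted gar retains *VTR2A* while teleosts lost it, so merging them would
hide an independent loss; the shared *VTR1B* loss still reconstructs as a
single event on their common stem), and the coelacanth is scored as
retaining *VTR2B* (required for the loss to reconstruct on the tetrapod
stem, and consistent with "fishes" including the coelacanth). Hagfish
cells for the six receptor orthogroups are `.`: its two receptors predate
the subfamily expansion and cannot be assigned.

## Numerical and degenerate-input choices

GC content excludes `N` from the denominator and errors on
non-nucleotide characters; an all-masked sequence yields `NA` with a
warning rather than a number. Intron comparisons align by rank and flag
count mismatches instead of failing. Orientation calls attribute the
inverted member of a non-tail-to-head pair by the majority strand of its
5-genes-per-side neighbourhood (window size reused from microsynteny; a
tie yields `none`, flagged). Homology-hit filtering keeps hits with bit
score strictly above 40 and E-value strictly below 1e-4, and is
idempotent. All tie-breaks (orthogroup seeding, chain ordering, suffix
assignment, WGD copy naming) are lexicographic and documented so replays
are bit-stable.

## Problem sizes

The test suite runs the full receptor panel (10 genomes, ~500 genes),
500 randomized chaining instances of ≤ 14 pairs, 200 random Dollo rows on
≤ 8-leaf trees, 20 seeds each for end-to-end orthology recovery and
post-WGD ranking, and 3-leaf scenario searches of ≤ 5 steps — sizes chosen
so every oracle comparison is exhaustive and the whole suite completes in
well under a minute.

## Limitations

Territory presence alone cannot distinguish "gene lost" from "gene never
evolved" — that distinction needs the species tree (Dollo) or the event
log, which is why `truth_orthogroups()` reports `never_evolved` but
`classify_locus()` cannot. Gene trees are consumed, never inferred, and
the tree-vs-synteny contradictions the concordance module reports (e.g.
lamprey receptors clustering as within-lineage pairs) are reported, not
adjudicated: both convergence and rapid radiation remain compatible
explanations. The χ² sample-size convention (reference scaffold gene
count for both proportions) follows the method being reproduced; it is a
convention, not an independence claim about chained gene hits.
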