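---
title: "WRKY family analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{WRKY family analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wrkykit)
```

wrkykit implements the standard genome-wide WRKY transcription-factor
family workflow as a tested pipeline: motif-grammar domain detection,
structural group/subgroup classification with phylogeny-assisted rescue,
duplication-mode typing with Ka/Ks selection screening, and a
fold-change intersection screen for candidate anthocyanin regulators.
This vignette records the models, the tunable parameters and their
defaults, the numerical conventions, and what the synthetic tests do and
do not demonstrate.

## Domain model and motif grammars

A WRKY domain is modeled as an ordered motif pair: a heptapeptide
(canonically `WRKYGQK`) followed within 60 residues by a zinc finger. The
zinc-finger grammars are

* C2H2: `C-X{4,5}-C-X{22,24}-H-X-H`
* C2HC: `C-X{7}-C-X{22,24}-H-X-C`

The classical family descriptions give 22–23 spacer residues for the
Group I C2H2 finger and 23 for the Group III C2HC finger; we widen the
Cys–His spacer to 22–24 on both to absorb annotation wobble, and fix the
inner H-X-H / H-X-C spacing at exactly one residue. Scanning is left to
right and non-overlapping; when several geometries share a start, the
shortest Cys–Cys spacer and then the shortest Cys–His spacer win. This
resolution is arbitrary but deterministic, which we value over completeness
of overlapping placements: annotation output must be reproducible across
runs and platforms.

Heptapeptide search is anchor-conditioned. Exact `WRKYGQK` occurrences are
always reported; degenerate variants (`WRKYGEK`, `WRKYGRK`, `WRQCRRK` and
the like) are only sought within the 60 residues upstream of a detected
zinc finger, must keep the `WR` prefix, and may differ from the canonical
motif at up to 4 positions — the smallest cap admitting `WRQCRRK`, whose
positionwise distance from `WRKYGQK` is 4. An unanchored fuzzy search at
this tolerance floods false positives, which is why variants require a
zinc-finger anchor while exact motifs do not. A terminal `WR`/`WRK` that
cannot be completed before the sequence ends is kept as a partial hit:
truncated second domains of Group I proteins are real annotations in
published family tables and must count toward the domain number.

Pairing assigns each zinc finger to the nearest upstream non-partial
heptapeptide within the 60-aa window (the only length statement available
for the domain). Unpaired heptapeptides survive as zinc-finger-absent
domains when they have at most one mismatch or are partial; unpaired fuzzy
variants at higher distance are discarded as anchor-search artifacts. A
protein with no domain at all is not a WRKY and is dropped rather than
labeled UC — family membership requires at least one WRKY signature.

## Classification ladder

`classify_structural()` applies a first-match-wins ladder: (1) two or more
domains with any C2H2 finger → I; (2) any C2HC → III; (3) no usable zinc
finger or only partial motifs → UC; (4) single C2H2 with a CX4C spacer →
IIc; (5) single C2H2 with a CX5C spacer → the subgroup signature on the 12
residues after the second cysteine (IIa `PVKKK(L/V)Q`, IIb `PVRKQVQ`, IId
`PARKHVE`, IIe `PARK(Q/M)V(E/D)`). Rule 1 deliberately requires only one
intact zinc finger: proteins whose second domain is truncated still belong
to Group I by domain count.

Signatures are matched exactly first; failing that, the minimum-Hamming
signature within `max_mismatch = 2` is used (ties broken by lexically
smallest subgroup). Real sequences drift and exact-only matching inflates
UC; two mismatches over a seven-residue signature is the loosest setting
that cannot confuse the signatures themselves, whose pairwise distances
exceed 4. The bound is an argument, not a constant.

UC proteins are resolved on a phylogeny by nearest-labeled-leaf transfer
under patristic distance (`ape`'s cophenetic distances), with ties broken
by majority label then lexical order. Published analyses do this step by
manual clade inspection; nearest-leaf transfer is the deterministic,
automatable counterpart, and a published reassignment map can be applied
directly (`apply_reassignment()`) so that reproducing a printed table does
not depend on reproducing its tree. Structurally classified proteins are
never relabeled by the tree.

The packaged azalea family table prints the four zinc-finger-lost genes
under their post-hoc clade labels; the package keeps the structural status
(`Lost`) in its own column and treats the printed group as the outcome of
the reassignment, which is how the two readings are reconciled.

## Duplication modes

Collinear blocks are detected by greedy chaining of homologous pairs over
per-chromosome gene ranks: pairs sorted by rank on one side, a chain
extended while both rank gaps stay within `max_rank_gap = 25` and the
other side progresses strictly monotonically in one direction, and chains
below `min_anchors = 5` discarded. These defaults mirror the common
defaults of collinearity tools; both are arguments. This is a simplified
stand-in for full synteny detection — it does not score alignments or
handle nested inversions — but it is sufficient to type desk-scale gene
families.

Pair modes follow a fixed rule order: block anchor → WGD; same chromosome
at rank distance exactly 1 → tandem (no intervening gene); rank distance ≤
`proximal_max = 10` → proximal; exactly one side occurring among block
anchors → transposed; otherwise dispersed. The transposed rule is an
approximation: the reference method identifies the ancestral locus using
outgroup genomes, which are out of scope here, so "one side has collinear
evidence" stands in for "one copy sits at an ancestral locus". Per-gene
modes take the highest-priority mode among a gene's pairs
(WGD > tandem > proximal > transposed > dispersed); genes with no pair are
simply absent from the output rather than labeled singleton.

## Ka/Ks (Nei–Gojobori 1986)

Synonymous site fractions are computed per codon by enumerating the nine
single-nucleotide neighbors; the counts of the two sequences are averaged.
Changes that would create a stop codon are counted as nonsynonymous rather
than excluded, so the invariant S + N = 3 × compared codons holds exactly
— the cost is a slightly conservative site count near stop-adjacent
codons. Codons differing at 2–3 positions are averaged over all orderings
of single steps, with pathways passing through stop codons excluded; if
every pathway hits a stop the codon is skipped (and excluded from the site
totals) with a log line. Proportions are corrected with Jukes–Cantor,
`d = -3/4·ln(1 - 4p/3)`, undefined at p ≥ 3/4.

Ks = 0 yields an undefined ratio, never infinity; undefined ratios pass
through the category call as `"undefined"` and are excluded from category
tallies, avoiding spurious positive-selection calls on identical or
synonymous-free pairs. The neutral category uses a band |Ka/Ks − 1| ≤ ε
with ε = 0.05 because exact equality to 1 is measure-zero; ε is an
argument. Only the standard genetic code is supported, and terminal stop
codons on a CDS are stripped with a log line.

NG86 was chosen over likelihood estimators (GY94 and the model-averaged
defaults of common calculator tools) because it is fully specifiable and
checkable against a brute-force pathway-enumeration oracle, which the test
suite does exhaustively for short alignments. Numerical identity with
model-averaged published values is therefore not claimed; the published
qualitative result this package checks as a property is that duplicate
families evolved under ω < 1 yield only ratios below 1.

## Expression screen

Fold changes are `log2((mean treatment FPKM + 1) / (mean baseline FPKM +
1))` on arithmetic replicate means. The pseudocount of 1 keeps all-zero
genes at fold change 0 and is configurable; means rather than per-replicate
statistics are used because the screen's DEG rule is threshold-only, with
no dispersion model. DEG thresholds are boundary-inclusive (|log2FC| ≥ 1,
i.e. |fold| ≥ 2). Candidates are the intersection of the two
colored-vs-white DEG sets of one floral stage: up in both → putative
anthocyanin promoter, down in both → putative suppressor.

ΔΔCt validation combines two reference genes by the arithmetic mean of
their Ct values (the geometric mean of expression), then
`fold = 2^-(mean dCt(group) - mean dCt(calibrator))`. Term enrichment uses
the one-sided hypergeometric upper tail (over-representation only) with
Bonferroni correction by the number of terms actually tested — not the
ontology size — since untested terms contribute no hypothesis.

## Synthetic data: what it emulates and what it does not

The generators produce the study conditions the pipeline is tested under:

* `gen_wrky_proteome()` plants canonical heptapeptide + subgroup-specific
  zinc fingers in random flanks; Group I proteins get two units; a
  configurable fraction is degraded by a variant heptapeptide or a lost
  zinc finger, with truth recorded. Flanks and spacers are drawn from an
  amino-acid alphabet without C, H and W, which makes accidental motif
  creation impossible by construction — planted truth is unambiguous
  without rejection sampling. Real proteomes obviously contain C/H/W-rich
  background, so scanner precision on real data is not established by
  these tests; the grammar-soundness tests against exhaustive enumeration
  on C/H-biased random sequences are the guard there.
* `gen_codon_pairs()` evolves an ancestral codon sequence along two
  branches with an accept/reject scheme: synonymous proposals always
  accepted, nonsynonymous with probability ω, stop-creating proposals
  rejected. `branch_length` is the proposal intensity per nucleotide site
  per branch, so realized divergence is lower whenever ω < 1 (at ω = 0.2 a
  proposal intensity of 0.4 per branch yields roughly 0.3 realized
  substitutions per site between the pair). This is not a full GY94
  process — no transition/transversion bias, no codon frequencies — which
  is precisely why NG86's unweighted counting recovers ω consistently on
  it; recovery tolerances (±0.1 on ω = 0.2 at 500 codons × 50 pairs) are
  set for this simulator, not for real data.
* `gen_duplicated_genome()` lays out background genes on six chromosomes
  and plants each mode so that features sit further apart than the default
  chaining gap: WGD chains of ≥ 5 consecutive anchors, tandem pairs at
  adjacent ranks, proximal pairs at gaps 2–10, transposed pairs linking a
  chain anchor to a distant locus, dispersed pairs on otherwise unused
  chromosomes. Real genomes interleave these signals; the planted layout
  tests the rules, not their robustness to interleaving.
* `gen_fpkm_table()` draws baseline FPKM from a lognormal (meanlog 3,
  sdlog 1), multiplies/divides planted candidates by an 8-fold effect in
  the two colored varieties, and applies lognormal replicate noise
  (σ = 0.25 on the log scale, 3 replicates) across the 3-variety ×
  2-stage design. The effect and noise levels are the screen's stated test
  conditions; genes with very low baseline expression can fail the
  down-regulation threshold arithmetic because of the pseudocount, which
  is a property of the screen itself, not of the generator.

Every generator is a pure function of its parameters and seed, restores
the caller's RNG state, and returns truth tables sufficient to score the
downstream stage.

## Problem sizes and numerical conventions

The test suite and the acceptance script run at desk scale: proteomes of
20 proteins per class over 3 seeds, 1000 random short alignments against
the NG86 oracle plus 50 pairs × 500 codons for ω recovery, genomes with
5–20 pairs per duplication mode over 3 seeds, and 20 seeded replicates of
the 100-gene expression screen. These sizes give stable recovery estimates
while keeping a full run in the tens of seconds.

Tie-breaks are deterministic everywhere: lexical gene order for equal gene
starts, shortest spacers for overlapping zinc-finger placements, closest-
to-anchor for equally mismatched heptapeptide candidates, majority-then-
lexical for equidistant tree neighbors, and lexically smallest subgroup
for equal-Hamming signatures. File readers reject malformed input (negative
FPKM, start > end, unknown strand, labels for absent leaves, duplicate
ids) rather than repairing it, so set-logic downstream never depends on an
imputation policy. Scaffold-placed genes are ordered lexically after the
numbered chromosomes when ranks are computed; published tables do not
state their convention for these, so this choice is documented rather than
validated.

## Known limitations

* The motif scanner is a grammar matcher, not a profile HMM; it does not
  score against PF03106 and cannot reproduce borderline judgement calls on
  nearly-degraded domains.
* Tree inference is out of scope; trees are inputs. Label transfer by
  nearest labeled leaf can differ from manual clade inspection on trees
  with long-branch artifacts.
* The transposed-duplication call approximates the outgroup-based
  ancestral-locus test, and block detection is a simplified chainer;
  replicating a specific published mode split from raw genome data is not
  claimed — the published split ships as a fixture tally instead.
* The screen has no dispersion model or p-value; it is faithful to the
  threshold-only DEG rule it implements, which also means it inherits that
  rule's sensitivity to low-expression genes.
* Published per-contrast DEG counts, cross-species ortholog counts and
  enriched-term lists depend on raw sequencing data or annotation sources
  that are not packaged; the printed downstream tallies are the packaged
  stand-ins.
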