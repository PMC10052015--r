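---
title: "Photolyase variants and UV survival: models and methods"
author: "phrscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photolyase variants and UV survival: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phrscan)
```

## The scientific question

Halophilic archaea repair UV-C-induced cyclobutane pyrimidine dimers (CPDs)
with a light-dependent DNA photolyase. The cyanobacterial-type enzyme binds
its DNA substrate together with two chromophores: catalytic FAD and the
8-hydroxy-5-deazaflavin (HDF) antenna. Strains isolated from sunlit surface
brines tend to photoreactivate well after UV exposure; strains from dark
subsurface halite often do not. phrscan formalizes the genotype side of that
comparison — which photolyase residues sit against the DNA, FAD or HDF, how
homologous strains differ at those positions, and what each substitution
does to local hydrogen bonding — and correlates a per-strain
photolyase-integrity score with dose-response UV survival.

## Contact shells

A protein residue belongs to the contact shell of a ligand group when the
minimum Euclidean distance between any heavy atom of the residue and any
atom of the group is at or below a threshold. Hydrogens are excluded
throughout: crystal structures at the relevant resolution do not resolve
them. The conventional proximity radius for this enzyme family is
approximate ("within about 2.8 Å"), so the threshold is a parameter
(default 2.8 Å) and `contactSweep()` calibrates it against a target residue
count over a 2.6–4.0 Å grid, reusing a single all-pairs distance
computation. Alternate locations are resolved to the highest-occupancy
conformer (alphabetical tie-break), waters and ions are excluded by
default, and nonstandard residue names for a CPD analog are declared in
configuration (`nucleicExtra`), never hard-coded.

All cross-strain positions are reported in the reference numbering of the
cyanobacterial photolyase, which excludes the initiator methionine; the
`numbering_offset` convention (1 when a FASTA sequence carries the Met, 0
otherwise) is applied at every sequence/structure boundary by the position
maps, so there is a single source of truth for numbering.

## Residue mapping and the variant table

Each homolog is aligned to the reference by Needleman–Wunsch global
alignment (BLOSUM62, affine gaps with opening 10 and extension 1, via
Biostrings). Pairwise alignment to one reference — rather than a full
multiple alignment — is deliberate: a position map to the reference is the
only alignment product the analysis consumes, and pairwise alignments are
exactly testable against exhaustive enumeration on short sequences. Percent
identity is defined as identical columns over aligned columns; published
identity percentages for this family rarely state their definition, so ours
is fixed and documented rather than tuned to match.

The variant table (rows: contact-shell positions; columns: strains) is the
computational twin of a published key-residue comparison, which ships as a
packaged TSV fixture with its provenance caveats in the header: the table
labels position 282 as DNA-interacting while the accompanying text
discusses it as FAD-binding, and one strain's residue at position 385
differs from the functional reference even though the text calls that
strain substitution-free. The package reports the literal table content and
carries both caveats; it does not guess author intent.

Two reference frames are explicit parameters everywhere: the *structural*
reference (the enzyme the crystal structure belongs to) anchors numbering
and variant flagging; the *functional* reference (the best-characterized
photorepair-proficient strain, NRC-1) anchors phenotype comparisons.

## Substitution modeling and hydrogen bonds

`substituteResidue()` keeps backbone atoms exactly and rebuilds the side
chain from packaged idealized internal coordinates (bond lengths, angles
and torsions per amino acid), copying each chi angle from the wild-type
residue when both residue types define it and setting the remainder to a
fixed default rotamer. There is no rotamer search, clash relief or energy
term: the construction is single-conformer and fully deterministic, which
is what makes verdicts reproducible and testable. The documented limitation
is that substitutions whose real side chain would rearrange chi angles can
yield different hydrogen-bond verdicts than a refined model would.

Hydrogen bonds are detected by a distance-only criterion between the
residue's polar side-chain atoms and ligand N/O/S atoms: strong for
donor–acceptor distances in [2.4, 3.3] Å, weak in (3.3, 3.6] Å, closer
pairs treated as clashes. No angle term is applied because the structures
carry no hydrogens; the windows are configurable. Donor/acceptor capability
comes from a packaged table for protein side chains (e.g. aspartate oxygens
accept only; lysine NZ donates; histidine nitrogens do both); ligand atoms
default to element-level rules (N donates and accepts, O accepts, S
accepts). That default misses ribityl-hydroxyl donation by cofactor
oxygens — a conscious simplification, since protonation assignment is out
of scope.

A substitution verdict is a pure function of the before/after bond sets,
evaluated per partner ligand at the best strength (strong beats weak):
loss, gain, weakened, strengthened, unchanged, or mixed when several
transition categories occur. "Weakened/strengthened" mean strong↔weak class
transitions only, never sub-Ångström distance deltas, which keeps verdicts
robust to coordinate noise.

## Survival curves and the genotype–phenotype correlation

Colony counts are dilution-corrected to titers, replicates averaged on the
linear scale, and survival expressed relative to the dose-0 titer per
strain and condition (doses default to 0/24/48/96/144 J/m² of 254 nm
UV-C). When every replicate at a dose yields zero colonies, survival is set
to a detection floor (half a colony at the deepest plated dilution) and
flagged censored so log-scale summaries stay finite. Summaries are the
log10-survival slope per J/m² from a least-squares fit, the dose at 10%
survival (flagged when extrapolated), the log-kill at the top dose, and the
photoreactivation benefit log10 S_light − log10 S_dark per dose.

The source study plots survival but prints no colony counts, so no numeric
survival value is "reproduced" here; all quantitative survival testing is
synthetic and property-based, with the published qualitative ordering
(surface strains photoreactivate best, the lake-sediment strain is
intermediate, subsurface strains worst) encoded as a rank assertion on the
paper-shaped preset.

The integrity score formalizes "how intact is this strain's photolyase" as
a weighted penalty sum, with the functional reference at 0 (best): one
penalty point per substitution relative to the functional reference, an
extra point for a non-conservative substitution at one of the six key
positions (50, 149, 282, 385, 398, 413), two points per hydrogen bond lost
and one per bond weakened when structural impacts are available, and a flat
gene-absent penalty (50) that ranks a missing photolyase below any variant
one. The per-substitution term is part of the default deliberately: scoring
only key-position changes would rank a strain with one key-position change
below a strain with three conservative changes, contradicting the observed
phenotype ordering this score is meant to track. Weights are fully
configurable, and the score is linear in them (doubling all weights doubles
every distance from the best score). Conservativeness uses a documented
six-class physicochemical partition ({AGVLIPM} {FWY} {ST} {CNQ} {DE}
{KRH}), chosen to reproduce the classifications the source analysis states
(T→S conservative; K→E, R→V, D→N non-conservative) and configurable like
everything else.

The genotype–phenotype link is Spearman rank correlation between integrity
scores and the survival ranking metric (default: light-condition survival
at the highest common dose), with a permutation p-value — exact by full
enumeration for up to eight strains, seeded Monte-Carlo above that, always
including the identity permutation so p is never zero.

## Phylogeny and synteny context

16S distances are p-distances or Jukes–Cantor (−(3/4)·ln(1 − 4p/3)) with
pairwise gap deletion; saturation (p ≥ 0.75) is an error, not an infinite
distance. Neighbor joining is authored in the package — the standard
Q-criterion and branch-length formulas with documented determinism: ties
broken by the lowest pair of node indices, negative branch-length estimates
clamped to zero and counted. The implementation recovers additive matrices
exactly and is cross-checked against an independent implementation (ape) in
the tests. Monophyly of habitat or taxonomic groups is assessed on the tree
rooted at a designated outgroup.

Gene-neighborhood comparison is label-based (functional-annotation
equivalence classes), matching how such figures are drawn; sequence-level
orthology is out of scope. The order-conservation score is the longest
common subsequence of (label, strand) tokens normalized by the longer
neighborhood, with a neighborhood and its reverse complement considered
equivalent. Coordinate-level indels between shared flanking genes use
declared homologous segments when present (each absent segment reports its
exact length; this is how a 1727 bp deletion and a 237 bp insertion can
coexist between one pair of flanks) and fall back to the net inter-flank
span difference otherwise.

## Synthetic data: what it emulates and what it does not

Every generator is seed-deterministic and writes a `.truth.json` sidecar
that the tests consume directly — tests never re-derive truth from outputs.

- `simStructure()` builds residues on an idealized extended backbone spaced
  14 Å apart (beyond any side-chain reach) and places pseudo-ligand atoms
  at exact requested distances along directions where the designated atom
  is provably nearest, erroring on infeasible requests. It emulates
  contact and hydrogen-bond geometry exactly; it does not emulate packing,
  crystallographic noise, or realistic ligand shapes.
- `simSequences()` plants substitutions at known reference-numbered
  positions; the `table2` preset reproduces the packaged key-residue table
  cell for cell and flags a gene-absent strain. No indels are simulated in
  protein sequences (substitutions only).
- `simSurvival()` draws counts around N0·exp(−k·dose) with lognormal noise
  (CV 0.2 by default, exact/unrounded at CV 0 so the noiseless limit is
  recoverable to machine precision). The paper-shaped preset fixes kill
  rates once per strain/condition to encode the published qualitative
  ordering: surface strains k_light ≈ 0.002–0.005, sediment 0.02,
  subsurface 0.055–0.07 per J/m², dark-condition rates around 0.05 (three
  to four logs of kill at 144 J/m²), with the dark-repair-proficient model
  strain at 0.015.
- `simTreeSequences()` evolves Jukes–Cantor sequences along a stated tree
  (three clades of three taxa plus a distant outgroup in the default
  preset, mirroring the three haloarchaeal orders).
- `simNeighborhoods()` plants the published narrative: the reference
  arrangement with the anchor adjacent to the superoxide-dismutase gene,
  one strain with two intervening hypothetical genes, two strains with a
  distinct arrangement lacking sod2, related subsurface strains with their
  own arrangement, and a gene-loss strain with the 1727/237 bp indel pair.

Passing tests on these generators demonstrate algorithmic correctness
against planted truth under idealized conditions; they do not demonstrate
robustness to real-structure artifacts (alternate conformers beyond
occupancy handling, missing atoms, modified residues) beyond what the
handling described above provides.

## Numerical and design choices

- Problem sizes in the tests and the acceptance script (70–413-residue
  synthetic structures, 100 simulated strains, 4–8-taxon trees, 1200 bp
  alignments, 10⁴ Monte-Carlo permutations) were chosen as the smallest
  sizes at which each property is convincingly exercised.
- Identity substitutions short-circuit: replacing a residue by itself
  returns the structure unchanged, byte for byte.
- The identity matrix aligns each pair in canonical (lexicographic) order
  so it is exactly permutation-equivariant.
- The pipeline reports every skipped stage by name with a reason, and its
  config hash covers semantic fields only (not output locations).
- Divalent ions are carried as an entity class but excluded from default
  hydrogen-bond partner sets.

## Known limitations

- Single-conformer substitution modeling (no repacking) can mis-call
  verdicts for substitutions requiring chi rearrangement; distance-only
  hydrogen bonds (no angles, no protonation) over-detect in rare
  geometries. Both are documented trade-offs for determinism.
- The contact-shell membership reproducible from literature is the residue
  *count*, not the identities: published analyses list counts and variant
  positions, not the full 59-residue roster.
- Percent-identity and survival percentages from the source study are
  reproduced only qualitatively (unstated aligner parameters; figure-only
  data) — by design, the package asserts orderings and properties there,
  not numbers.

## A worked run

```{r example}
vt <- table2Fixture()
diffCounts(vt, "BOL5-1", "NRC-1")$byInteraction

sv <- simSurvival(preset = "paper", seed = 7)
report <- runPipeline(list(survival = sv$records,
                           genePresent = list("BOL5-4" = FALSE),
                           seed = 7))
report$scores
head(report$ranking)
report$correlation[c("rho", "p", "method")]
```
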