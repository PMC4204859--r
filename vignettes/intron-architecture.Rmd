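---
title: "Comparing intron-exon architectures across orthologs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing intron-exon architectures across orthologs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intronarch)
```

## The problem

Spliceosomal introns are gained and lost over evolutionary time, and for a
deeply conserved single-copy gene the positions at which introns interrupt
the coding sequence are themselves heritable characters. When two species
carry an intron at the same position of the aligned protein, in the same
codon phase, the most parsimonious reading is common descent of the site;
when a whole order shows an exon layout shared by no other lineage, the
architecture itself marks that lineage. `intronarch` turns this style of
analysis — as applied, for instance, to the core
α1,6-fucosyltransferase (*fut8*) gene family across metazoa — into a
reusable pipeline: compute intron phases and exon notation from gene
models, project insertion sites onto a protein multiple alignment,
cluster and label homologous sites per lineage, detect *near intron
pairs*, reconstruct gain/loss histories by Dollo parsimony on a dated
species tree, and score translation-initiation contexts against a
frequency-derived consensus.

## Intron phases and exon notation

An intron's *phase* is the amount of coding sequence preceding it, modulo
3: phase 0 introns fall between two codons, phase 1 after the first
nucleotide of a codon, phase 2 between the second and the third. Phase is
the key invariant of site homology: a conserved insertion site conserves
its phase, so equal alignment column with unequal phase is treated as
non-homologous.

Structure diagrams write an exon as `u-c-d`, where `c` is the number of
codons having at least one nucleotide in the exon and the flanking
numbers are the nucleotides of the split boundary codons lying *inside*
the exon. An exon downstream of a phase-2 intron carries 1 nt of the
split codon, so it starts `1-…`; upstream of a phase-0 intron it ends
`…-0`. The nucleotide length follows as

```
L = u + 3 * (c - [u>0] - [d>0]) + d
```

Under this convention the notation algebra is exact: merging the two
exons flanking a lost intron gives `c_a + c_b` codons, minus one when the
boundary codon was split (it was counted in both exons), and
`notation_to_length()` is additive under `merge_exons()`. The classic
example is the lepidopteran exon pair `1-51-0` / `0-58-0` fusing into an
ancestral `1-109-0`:

```{r}
merge_exons(exon_notation(1, 51, 0), exon_notation(0, 58, 0))
```

`split_exon()` inverts the merge. Offsets that would cut inside a codon
already split by a flanking intron are rejected, because the middle
fragment of a doubly split codon cannot be written in `u-c-d` notation.

## Site projection and clustering

Sites live in CDS coordinates (`cds_offset`, 0-based nt of CDS upstream
of the intron). A site at offset `o` maps to residue `o div 3` with phase
`o mod 3`; a phase-0 site at residue *r* is taken to lie between residues
*r − 1* and *r*, phase 1/2 sites inside residue *r*'s codon. This
convention makes `3·Δresidue + Δphase` an exact nucleotide distance
between insertion points. Residues map to alignment columns by skipping
the gap columns of the species' own row.

Clustering is single linkage over columns with equal phase;
`column_tolerance` (default 0, exact column identity) exists for noisy
alignments, and the cluster count is non-increasing in it. Labels follow
the field's convention `i<number><lineage letter>` (`l` lepidoptera, `h`
hymenoptera, `c` chordata): all clusters containing any member of the
reference lineage are numbered jointly in 5′→3′ column order. Passing
the whole lineage rather than a single species matters when the primary
reference lacks a site the lineage has — a family-restricted site still
occupies its ordinal, which is how a formicid-specific site can be the
third of four hymenopteran sites while the honeybee carries sites 1, 2
and 4.

Codon-internal (phase 1/2) sites are assigned to the column of the
residue whose codon they interrupt; when flanking residues of different
species align to different columns, the distance fallback (below) flags
which species the measurement was taken on.

## Near intron pairs

Two distinct sites separated by only a few coding nucleotides — closer
than independent gain would plausibly place them — form a *near intron
pair*, the signature of intron sliding. Distance is measured on a
species carried by both clusters (preferring a designated scaffold
species) as the difference of `3·residue + phase` in that species' own
ungapped coordinates; clusters sharing no species fall back to
`3·Δcolumn + Δphase`. The default window is 32 nt: the only worked case
in the comparative *fut8* literature is a 24-nt lepidoptera/chordate
pair, and the concept implies "a handful of codons", so a round bound
covering that case is used and is configurable. Pairs at distance 0
sharing a member are the same site, not a pair.

## Dollo reconstruction and dating

Each site is modelled as gained exactly once and lost freely afterwards
(Dollo parsimony). The gain branch is the branch into the MRCA of all
carriers; losses are the maximal subtrees inside that clade containing
absences and no carrier, found by one bottom-up pass. This is provably
the minimum-loss single-gain explanation, and the test suite checks it
against an exhaustive oracle on all small trees. Unknown states
(5′-truncated genes) never force a loss and never change the inferred
events. Convergent gains of the same column in distant lineages violate
Dollo's premise; the package handles them by reconstructing per
lineage-specific label rather than relaxing the single-gain constraint —
a documented limitation, deliberate because relaxing Dollo makes the
reconstruction non-identifiable at these sample sizes.

Events are dated by the age of the branch's *parent* node — the
divergence that opens the branch — because published gain/loss dates
cite divergence times. The packaged `metazoa_*` fixtures encode a
schematic arrangement of one representative per lineage (not a resolved
phylogeny: the nesting of the dated consecutive losses cannot be
realised on the true insect topology, since lepidoptera retain several
of the sites lost later along the schematic backbone); node ages are the
published divergence dates, and the dated ledger reproduces the
published 855/783/372/300/265 MYA events.

## Distance trees

`p_distance()` counts differing residues per retained column; *complete
deletion* (default) removes every column with a gap or missing character
in any sequence, *pairwise deletion* only per pair. `nj_tree()` is a
standard neighbor-joining agglomeration with two fixed contracts: ties
in the Q criterion resolve to the lowest current index pair (making
degenerate inputs deterministic), and negative branch estimates are
clamped to zero with a warning. On additive matrices NJ recovers the
generating tree exactly; the suite verifies this on random trees with up
to 8 leaves, and cross-checks topologies against an independent NJ
implementation. Bootstrap support resamples columns with replacement and
reports, per internal bipartition of the original tree, the percentage
of replicate trees containing it — support is attached to the original
topology rather than a majority-rule consensus, which is simpler and
sufficient for annotating one tree. Any display threshold (e.g. showing
only supports above 75%) is presentation, not computation.

## Translation-initiation contexts

`build_pfm()` tabulates the 10 nt upstream of known start codons into
per-position percentages (U and T identified). `derive_consensus()`
keeps, per position, every nucleotide at or above a threshold; the
default 27% is the unique integer threshold that reproduces the
published Sf9 consensus row cell by cell (26% frequencies fall outside
the printed sets, 27% ones inside), and is configurable. Scoring is the
plain count of consensus matches over the 10 positions — that is what
published context tables encode by bolding — with a log-odds PWM score
offered as a secondary statistic only. `select_start()` scans AUGs
in-frame with the annotated ORF, upstream of its first in-frame stop,
and returns the best-scoring candidate, 5′-most on ties; candidates
with fewer than 10 nt of upstream sequence are skipped with a warning.

## The synthetic generator

`simulate_history()` emits a rooted tree, per-taxon gene models, a
protein alignment and the full ground truth (event ledger, site-column
map, presence matrix). Sites are gained once on a random branch
(ancestral sites on the root) and lost independently downstream —
Dollo-consistent by construction; gains and losses are Poisson per
branch (defaults 0.2 and 0.3, moderate rates that leave most site
histories identifiable while exercising multi-loss cases). Proteins
evolve by independent substitutions with no indels by default, so the
site-to-column map is exact; an optional deletion mode adds gaps at
site-free residues to stress gap handling in projection while keeping
the map exact. Intron lengths are log-normal with optional per-clade
scales, emulating the order-of-magnitude spread between, say,
lepidopteran (tens of kb) and culicid (~160 bp total) architectures.

What the generator does *not* emulate — alignment error, rate
heterogeneity, intron sliding, convergent gain at hotspots — bounds what
green tests mean: they certify the algorithms against their own model,
not robustness to misalignment. Real analyses should treat the
column-tolerance and scaffold-species options as the knobs for alignment
noise.

## Numerical and design choices

* Coordinates are 0-based half-open on the coding strand internally;
  GFF3 input (1-based, stranded) is converted and minus-strand genes are
  re-ordered, with the GFF3 `phase` column cross-checked against
  computed phases (mismatches warn, computed phases win).
* The stop codon is included in `cds_length`, matching conventional CDS
  feature spans.
* Printed comparative tables are shipped verbatim as fixtures, including
  two internal inconsistencies, which are flagged rather than corrected:
  one hymenopteran total differs from the sum of its listed intron
  lengths (457 vs 602), and one formicid cell prints phase 0 where every
  congener has phase 2.
* The packaged gene-model fixture places exon boundaries at synthetic
  offsets chosen to satisfy every printed constraint (12 exons within
  75–216 bp, exon 3 of 71 codons, exon 8 `1-51-0`, exon 9 `0-58-0`,
  exons 6+7 splitting a 232-nt `2-78-2` ancestor, the published phase
  series and intron lengths); totals and phases are
  boundary-independent, so any consistent choice gives the same results.
* Test problem sizes: the exhaustive Dollo check runs all presence
  patterns on four tree shapes per leaf count up to 7; recovery runs 200
  sites on 6- and 12-leaf trees; NJ recovery runs 100 random trees up to
  8 leaves. These sizes make the combinatorial checks complete at small
  n rather than sampled at large n.

## Limitations

Alternative splicing, UTR structure, non-canonical splice-site classes
(beyond a boolean flag), probabilistic gain/loss models and alignment
inference are out of scope. The Dollo ledger is a parsimony statement,
not a rate estimate; branches with no extant descendants in the sample
are invisible to it.
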