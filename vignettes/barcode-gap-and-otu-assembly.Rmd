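---
title: "Barcode gaps and de novo OTU assembly: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Barcode gaps and de novo OTU assembly: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodegap)
```

`barcodegap` implements two connected analyses for bacterial marker
genes. The first asks whether a candidate locus behaves as a DNA
barcode: whether the distribution of pairwise distances *within*
species is separated from the distribution *between* species. The
second asks whether amplicons of such a locus can be assembled *de
novo* into full-length operational taxonomic units (OTUs), and how to
score the quality of such an assembly objectively. This vignette
records the models, the tunable parameters and the design decisions
behind both, including the points where the design was genuinely open.

## The barcode-gap model

For a set of marker sequences labelled by species, all unordered pairs
are compared on a common alignment and partitioned into intra-specific
pairs (same species label; paralogous copies within one genome count
as intra-specific) and inter-specific pairs. The **barcode gap** is
defined as

$$\mathrm{gap} = \mathrm{median}(d_{\mathrm{inter}}) -
\mathrm{median}(d_{\mathrm{intra}}),$$

the difference of the two median distances. Medians rather than means
or minima are used because the intra-specific distributions are far
from normal and can carry long right tails — divergent paralogs of the
chaperonin gene, and mis-annotated relatives swept in by keyword-based
extraction, both inflate the tail without representing typical
within-species divergence. A median-based gap is insensitive to such
extremes, which the test suite checks directly by spiking distance
sets with outliers.

### Distance models

Distances are expressed in substitutions per site. The default model
is F84 (the default of PHYLIP's DNADIST), which distinguishes
transitions from transversions and allows unequal base frequencies.
With base frequencies $\pi_A,\pi_C,\pi_G,\pi_T$, purine/pyrimidine
sums $\pi_R,\pi_Y$, and

$$A = \frac{\pi_C\pi_T}{\pi_Y} + \frac{\pi_A\pi_G}{\pi_R},\qquad
B = \pi_C\pi_T + \pi_A\pi_G,\qquad C = \pi_R\pi_Y,$$

the distance for observed transition and transversion proportions $P$
and $Q$ is

$$d = -2A\,\ln\!\Big(1 - \frac{P}{2A} - \frac{(A-B)\,Q}{2AC}\Big)
      + 2(A-B-C)\,\ln\!\Big(1 - \frac{Q}{2C}\Big).$$

Kimura's two-parameter model and the Jukes–Cantor model are available
as alternatives; at equal base frequencies F84 reduces to K2P
analytically, which the tests assert numerically.

Three numerical decisions were open and are fixed as follows:

* **Frequency estimation is pairwise**: $\pi$ is estimated from the
  two sequences being compared, not from the whole alignment. The
  reference tooling documents both variants; the pairwise variant is
  pinned here by an oracle test against an independent implementation
  (`ape::dist.dna`), which agrees to well below $10^{-6}$.
* **Pairwise deletion**: any site with a gap or ambiguity symbol in
  either sequence of a pair is excluded from that pair only.
* **Saturation**: when a logarithm argument reaches zero or below the
  distance is reported as `Inf`, counted and flagged separately, and
  excluded from medians and extrema. Reported maxima therefore refer
  to finite distances. (Very large finite distances — several
  substitutions per site — are legitimate outputs for divergent
  paralog pairs and are retained.)

Histograms of the two partitions are normalised to percent of
comparisons per relation over *all* finite distances; an optional
display cap (e.g. 1.0 substitutions/site) restricts plotting only and
never the normalisation.

## Barcode region delineation

Regions are defined by PCR primer pairs (shipped in `primer_table()`:
the 16S rRNA V1–V3, V2–V4, V3–V5, V6 and V6-alternate amplicons and
the cpn60 universal target, the region corresponding to nucleotides
274–828 of the *E. coli* chaperonin gene). Matching is a
degeneracy-aware Hamming scan: IUPAC codes expand per the standard
code and inosine matches any base, since the cpn60 broad-range primers
carry many inosines. The default tolerance is 3 mismatches per primer
— primer sites on reference loci are traditionally located by manual
curation, so no tolerance is canonical; 3 is permissive enough for broad-range primers on
their intended targets while rejecting random placements, and it is
configurable. Ambiguous placements (multiple qualifying sites) are
reported in the output for review rather than resolved silently.

The extracted barcode is the **amplicon interior**: the sequence
strictly between the two annealing footprints, excluding the primer
sequences themselves. Two observations force this reading: the
commonly cited average length of the cpn60 universal target (556 bp)
matches
the inter-primer interior, not the primer-inclusive amplicon; and the
post-assembly cleanup stage removes primer sequence from consensus
ends, implying primers are not part of the barcode.

## Window diversity profiles

The sliding-window profile summarises *where* along a target the
discriminating signal lives. For each 120 bp window (in reference
coordinates; default reference is the longest sequence) and each
sequence covering the window, the percent identity to its **nearest
neighbour** — the best-matching other sequence from a different genome
— is computed over the window's alignment columns, with every column
that is not an identical unambiguous base (including gaps) counted as
a mismatch. The profile reports the median over sequences.

The nearest neighbour is chosen *per window*, not once globally: only
the per-window reading produces the expected plateaus at 100% identity
across conserved regions, because within such a region every sequence
has some other sequence it matches perfectly even if their
full-length best matches differ. Same-genome paralogs are excluded as
neighbours (a gene should not be its own closest relative), while
conspecific genomes are allowed. Windows are emitted only where at
least 95% of sequences have full coverage, so ragged alignment ends do
not masquerade as diversity; the step between windows defaults to 1
and is configurable, as no step is prescribed. No smoothing is
applied.

## The synthetic community generator

The generator emulates the study system: a panel of cloned cpn60
universal-target templates with pairwise identities inside a 56–96%
envelope, amplified with the degenerate universal primers and
pyrosequenced from both amplicon ends.

* **Templates** are built by mutating a random ancestor along a star
  tree; per-branch substitution counts are drawn so that all pairwise
  identities land inside `[lo, hi]`, with violating pairs
  rejection-adjusted. Lengths vary by at most one codon around 555 bp
  (552–558), matching the length class of the universal target.
  Default branch divergences are drawn on $[0.05, (1-\mathrm{lo})/2]$:
  realized pairwise identities then span roughly 0.57–0.90, inside the
  envelope, and distinct templates stay separated by at least about
  10%. The envelope bounds are treated as constraints to satisfy, not
  extremes to attain, because the greedy consensus assembler below
  merges any two contigs whose overlap identity clears the `mi`
  threshold: a panel carrying a pair above `mi` cannot be resolved by
  *any* overlap-identity criterion at that setting, only by
  isoform-aware heuristics that are out of scope here. Deliberately
  close pairs — e.g. two templates at 96%, mirroring closely related
  *Lactobacillus* species — are constructed explicitly with
  `mutate_to_identity()` and are separated by setting `mi` between
  their identity and 100.
* **Amplicons** are the templates flanked by the universal primers,
  with degenerate positions concretised once per template (a clone has
  one fixed amplicon sequence).
* **Reads** are drawn alternately from the 5′ end (forward) and the 3′
  end (reverse complement), emulating sequencing from both ends of the
  amplicon. Lengths follow a normal distribution with the requested
  median (default 394) truncated to
  $[80, \text{amplicon length}]$, with sd $= 0.15 \times$ median — the
  length distribution's shape is not prescribed anywhere, only its
  median, so a single-parameter family anchored on that median is
  used. Substitution errors are applied per base at `error_rate`, and
  homopolymer runs of length ≥ 3 can gain or lose one base with
  probability `homopolymer_bias`, the dominant pyrosequencing error
  mode. The default read set is error-free: the headline question —
  does every template come back as a consensus 100% identical to it? —
  is about assembly behaviour, not error correction, and an error-free
  read set isolates exactly that. Quality strings are
  uniform placeholders; flowgram-level noise modelling is out of
  scope.
* **Genome fixtures** for the extraction-and-gap pipeline evolve a
  root marker to species ancestors (inter-species divergence `b`) and
  on to genomes (intra-species divergence `a`) under a Poisson
  substitution process, embed the markers (a 16S-like rRNA and a
  cpn60-like CDS, some copies on the minus strand, divergent paralogs
  optional) in random flanking sequence, and emit annotated flat-file
  records plus a taxonomy table. Model-corrected distances recover the
  designed divergences, so the pipeline's gap estimate approaches
  $b - a$; the acceptance test demands agreement within ±0.03 at the
  default sizes (5 species × 3 genomes, 555 bp markers).

What the generator deliberately does **not** emulate: real 454
flowgram noise, chimera formation during PCR (chimeric consensi are
constructed directly in tests instead), abundance skew (the cloned
community was mixed equimolar, so equal template depth is the
default), and real cpn60 sequence composition (templates are uniform
random under the identity constraints). A green test suite therefore
demonstrates the correctness of the algorithms under controlled
conditions, not performance on real pyrosequencing data.

## The greedy overlap-consensus assembler

The assembler is a deliberately minimal, deterministic stand-in for a
production overlap assembler, exposing exactly the two swept
parameters: minimum overlap length `ml` (nucleotides) and minimum
overlap identity `mi` (percent).

* **Overlap detection** is maximal-scoring semiglobal alignment (free
  end gaps, match +1, mismatch −1, gap −2) over both orientations;
  percent identity is computed over the aligned overlap columns with
  internal gaps counted as mismatches, end overhangs excluded.
* **Greedy order** is globally best-first: among all qualifying pairs
  (identity ≥ `mi` and overlap ≥ `ml`), the pair with the highest
  identity merges first, ties broken by longer overlap, then by the
  lexicographically smallest member read ids. Production assemblers
  rarely document their internal order; determinism and testability
  won this choice, and the partition, monotonicity and discrimination
  properties in the test suite pin the resulting behaviour.
* **Consensus** is recomputed after every merge by per-column majority
  vote over the member reads' aligned columns; base ties break in the
  fixed order A<C<G<T (never IUPAC codes, which would poison
  downstream identity arithmetic), and a deletion wins a column only
  with a strict majority. Coverage is recorded per column for
  diagnostics only; there is no quality weighting.
* **Contigs with a single read are singletons**, reported separately
  from OTUs (which require ≥ 2 members) as a data-loss figure.

At scale the assembler prescreens candidate pairs by shared 12-mers
and aligns in a band (half-width 16) around the most-voted diagonal; a
pair whose shared-k-mer density over the estimated overlap falls far
below $(\mathrm{mi}/100)^k$ cannot qualify and is skipped without
alignment. Inputs of up to 150 reads instead use the exact full
dynamic program for every pair (`exhaustive = TRUE`), and a dedicated
test asserts that the two paths agree on mid-sized communities. The
banded path assumes substitution-dominated divergence, which holds for
the simulated data; heavily indel-divergent reads would need a wider
band.

## Evaluating an assembly

Every assembled read and every OTU consensus is matched to its best
reference by semiglobal percent identity over both orientations, ties
to the lexicographically smallest reference id, with a 55% identity
floor (configurable) below which a query is "unmatched". The overlap
must additionally span at least half of the shorter sequence: without
this guard, the maximal-score free-end alignment of two unrelated
sequences can be a trivial 20-column dovetail at high nominal
identity, and the floor would never trigger. Exhaustive pairwise
matching is used instead of a heuristic similarity-search tool: at
desk scale the exhaustive search is exact, which is preferable for a
scoring primitive.

For each OTU, with the consensus matched to reference $R$:

* **TP** — reads in the OTU whose best reference is $R$;
* **FP** — reads in the OTU whose best reference differs;
* **FN** — reads in *other* OTUs whose best reference is $R$;
* **TN** — reads in other OTUs that match their own OTU's consensus
  reference, when that reference differs from $R$.

Then $\mathrm{Sp} = \mathrm{TN}/(\mathrm{TN+FP})$,
$\mathrm{Sn} = \mathrm{TP}/(\mathrm{TP+FN})$, the residual error of
the OTU is the Euclidean distance from $(\mathrm{Sp}, \mathrm{Sn})$ to
the perfect corner $(1,1)$,
$E = \sqrt{(1-\mathrm{Sp})^2 + (1-\mathrm{Sn})^2} \in [0, \sqrt 2]$,
and the **total error** of an assembly is $\sum E$ over its OTUs.
Reads — not base pairs — are the unit of counting, and singletons are
excluded from the confusion counts (they are reported separately as
the singleton percentage). Two definitional edge cases were open:

* *Degenerate denominators.* A single-OTU assembly has
  $\mathrm{TN+FP} = 0$; the affected ratio is defined as 1.0 and
  flagged (`sp_degenerate`/`sn_degenerate`), so $E$ degrades
  gracefully instead of dividing by zero.
* *The TN reading.* "Correctly placed into other OTUs" is read as
  matching the *other OTU's own* consensus reference, not merely being
  elsewhere. A read that matches neither its own OTU's reference nor
  the target's is consequently counted in neither TN nor FN — which
  also means TP+FP+TN+FN can fall short of the evaluated reads on
  messy assemblies. The brute-force enumeration oracle in the test
  suite encodes this decision explicitly so it can be flipped in one
  place if the other reading is ever preferred.

### Post-assembly cleanup

Three stages are evaluated, mirroring standard post-assembly
practice: the raw
assembly; after **primer trimming** (degenerate-aware primer matches
within 5 bp of either consensus end, either orientation, ≤ 3
mismatches, removed iteratively) and **100% clustering** (OTUs whose
trimmed consensi are identical or exact substrings merge into the
longer, members unioned); and after **chimera removal** (a consensus
whose 5′-most and 3′-most 150 bp best-match different references is
chimeric; consensi under 300 bp are not evaluable and are left
unflagged). A removed chimera's reads are excluded from further
evaluation rather than re-assigned — re-assignment would require a
placement rule of its own and has no obvious justification. The test suite asserts on every
fixture that cleanup never increases total error, stage by stage.

The sweep driver runs assemble → evaluate over a grid of `(ml, mi)`
and tabulates total error per stage, OTU count and singleton
percentage — the machine-readable twin of the usual error trade-off
figure, plotted by `autoplot()`.

## Marker extraction from annotated genomes

Annotated genome records (GenBank flat files; a minimal parser and
writer ship with the package, covering simple and complemented spans)
are scanned for rRNA features carrying "16S" and CDS features matching
a cpn60 keyword set ("cpn60", "groEL", "hsp60", "60 kDa chaperonin",
"chaperonin 60", …). Because genome annotation is inconsistent for
this gene, no single keyword suffices and the shipped set is a
judgment call — it is deliberately user-extensible. Matching is
case-insensitive on **whole tokens**: "groEL" matches "groEL
chaperonin" but neither "groES" nor "groESL", trading a little recall
for testable precision. All annotated copies are extracted
(`copy_index` orders them by position), minus-strand features are
reverse-complemented, and species labels come from a three-column
taxonomy table rather than a full taxonomy dump — absent taxa resolve
to `"unknown"` instead of failing. Coordinates are 1-based inclusive
at the interfaces, 0-based half-open only internally.

## Problem sizes and limitations

The package is desk-scale by design. The shipped analyses run on
synthetic panels of tens of templates, thousands of reads and genome
fixtures of ~15 genomes; survey-scale collections (a thousand-plus
genomes, millions of pairwise comparisons) are out of scope, though
summary tables from such surveys can still be fed through
`gap_statistic()` arithmetic. The test suite exercises the end-to-end community
at its native size (20 templates × 172 reads, median length 394) once
and uses reduced sizes (e.g. 40 reads/template for the
singleton-vs-`ml` profile, which is scale-free) elsewhere. A built-in
star aligner around the longest sequence serves fixture-scale multiple
alignments; real analyses should align with a dedicated multiple
aligner and feed the alignment in. Known limitations: no thermodynamic
primer model, no rate-heterogeneity (gamma) distances, no flowgram
noise model, no de-novo (reference-free) chimera detection, and no
claim to reproduce the internal behaviour of any production
assembler — the shipped assembler is a deterministic stand-in, and the
evaluation framework is the point.
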