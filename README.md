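# barcodegap

Tools for evaluating DNA barcodes for Bacteria and for assessing *de
novo* assembly of barcode amplicons into operational taxonomic units
(OTUs).

Gene-centric surveys of bacterial communities lean on two marker
genes: the 16S rRNA gene and the protein-coding *cpn*60 gene, whose
~555 bp "universal target" (UT) region is amplified by degenerate
broad-range primers. Whether such a locus works as a *barcode* — a
sequence that reliably separates species — comes down to its **barcode
gap**: the separation between the distribution of pairwise distances
within species and the distribution between species, measured here as

```
gap = median(inter-specific distance) − median(intra-specific distance)
```

with distances in substitutions/site under the F84 model (K2P and JC
are available). A locus with a large gap and evenly distributed
diversity also supports a stronger mode of community profiling:
assembling amplicon reads *de novo* into full-length OTU consensus
sequences. `barcodegap` implements both sides of that argument, for
researchers who evaluate marker genes or tune amplicon assemblers:

* **Marker extraction** from annotated genome records (GenBank flat
  files) by keyword matching, keeping all paralogs
  (`read_genbank()`, `extract_markers()`).
* **Barcode delineation** from established primer pairs — the 16S
  V1–V3/V2–V4/V3–V5/V6/V6-alternate regions and the cpn60 UT
  (`primer_table()`, `match_primer()`, `delineate_region()`).
* **Distance analysis**: F84/K2P/JC pairwise distances with pairwise
  deletion, intra/inter-specific partitioning, the gap statistic and
  percent-of-comparisons histograms (`partition_distances()`,
  `gap_statistic()`, `distance_histogram()`).
* **Window diversity profiles**: median nearest-neighbour percent
  identity in sliding 120 bp windows (`window_profile()`).
* **Synthetic data**: template panels with a controlled pairwise
  identity envelope, amplicon reads simulated from both ends, and
  annotated genome fixtures with designed divergences
  (`generate_panel()`, `simulate_reads()`,
  `generate_genome_fixture()`).
* **A greedy overlap-consensus assembler** parameterised by minimum
  overlap length (`ml`) and minimum overlap identity (`mi`)
  (`assemble()`), and an **assembly evaluation** framework: per-OTU
  specificity `Sp = TN/(TN+FP)`, sensitivity `Sn = TP/(TP+FN)`,
  residual error `E = sqrt((1−Sp)² + (1−Sn)²)`, total error `ΣE`,
  post-assembly primer trimming, 100% clustering and chimera
  flagging, and an `(ml, mi)` sweep driver (`evaluate_stages()`,
  `sweep_assembly()`).

Results come back as tibbles; fitted objects support `tidy()`,
`glance()` and `autoplot()`.

## Worked example

Recover a designed barcode gap from synthetic annotated genomes, then
assemble a synthetic amplicon community and score it:

```r
library(barcodegap)

# 5 species x 3 genomes, designed divergence 0.01 within and 0.30
# between species
fx <- generate_genome_fixture(n_species = 5, genomes_per_species = 3,
                              intra = 0.01, inter = 0.30, seed = 33)
markers <- extract_markers(read_genbank(text = fx$genbank), "cpn60",
                           taxonomy = fx$taxonomy)
gap_statistic(partition_distances(markers, model = "f84"))
#>   n_intra n_inter median_intra median_inter barcode_gap
#> 1      15      90      0.00906        0.310       0.301
```

The recovered gap (0.301) sits on the designed value `0.30 − 0.01`:
the medians estimate the within- and between-species divergences, and
their difference is the gap a practitioner would see for this locus.

```r
# a 20-template panel of cpn60-UT-like clones, sequenced error-free
# from both amplicon ends
panel <- generate_panel(seed = 42)
reads <- simulate_reads(panel, reads_per_template = 20,
                        median_length = 394, seed = 7)
asm <- assemble(reads, ml = 100, mi = 92)
asm
#> <otu_assembly> ml = 100, mi = 92: 20 OTUs from 400 reads
#>   (0 singletons, 0.0%)

st <- evaluate_stages(asm, reads, panel)
st$summary[, c("stage", "total_error", "n_otus", "pct_singletons")]
#>   stage             total_error n_otus pct_singletons
#> 1 raw                         0     20              0
#> 2 trimmed_clustered           0     20              0
#> 3 chimera_removed             0     20              0

min(tidy(st$chimera_removed)$consensus_identity)
#> [1] 100
```

Every one of the 20 templates is recovered as its own OTU, no reads
are lost as singletons, the total assembly error is 0 at every cleanup
stage, and each consensus is 100% identical to its template — the
operating point `ml = 100`, `mi = 92` reconstructs this community
faithfully. Raising `ml` towards the read length trades error for
data loss as more reads become singletons; `sweep_assembly()`
tabulates that trade-off and `autoplot()` draws it.

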