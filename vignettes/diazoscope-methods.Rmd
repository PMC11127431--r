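---
title: "Quantifying soil diazotrophs from shotgun metagenomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying soil diazotrophs from shotgun metagenomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diazoscope)
```

## The problem and the estimator

Biological nitrogen fixation is catalysed by nitrogenase, whose structural
genes (*nifHDK* for the molybdenum enzyme, *vnfDK* and *anfDK* for the
vanadium and iron-only alternatives) mark prokaryotes capable of fixing
N~2~. PCR amplicon surveys of *nifH* are the traditional way to census
these diazotrophs in soil, but they inherit primer-mismatch and GC biases
and are confounded by *pseudo-nifH* genes — *nifH*-like sequences on
genomes that lack *nifD/K* and therefore cannot fix nitrogen. diazoscope
implements a shotgun-metagenomic alternative built around three choices:

1. **Markers.** Quantification uses the D/K-type genes (*nifD*, *nifK*,
   *vnfD*, *vnfK*, *anfD*, *anfK*). *nifH* is deliberately excluded from
   the abundance estimate because short NifH fragments are easily confused
   with paralogous reductases; it is still tracked for the pseudo-*nifH*
   diagnostic and primer analyses.
2. **Normalisation.** Marker abundance is expressed per prokaryotic
   genome, not per read: the dominance ratio of a sample is

   $$\mathrm{ratio} = \frac{\sum_{f \in \text{nif D/K}} \mathrm{RPKM}(f)}
                           {\sum_{r \in \text{RP}} \mathrm{RPKM}(r)},
   \qquad
   \mathrm{RPKM}(f) = \frac{\sum_{g \in f} c_g / (L_g/1000)}{N_s/10^6},$$

   where $c_g$ is the read count of reference gene $g$, $L_g$ its length,
   $N_s$ the sample's read count, and RP a panel of universal single-copy
   ribosomal protein genes. The RP denominator makes the ratio robust to
   plant or animal DNA in the sample (which dilutes total reads but not
   ribosomal protein reads), and the per-gene length correction removes
   the systematic length differences between marker orthologs. The exact
   membership of the RP panel is configurable;
   `default_rp_families()` ships fifteen near-universally single-copy
   ribosomal protein genes as the default.
3. **Taxonomy by placement.** Reads assigned to *nifD*/*nifK* are
   taxonomically annotated by placing them on fixed per-marker reference
   trees and taking a confidence-weighted LCA, so that short fragments
   with little phylogenetic signal are abandoned as *unreliable* rather
   than mis-annotated by a best hit.

## Read classification

Reads are quality-filtered (length ≥ 100 nt, mean Phred ≥ 20 by default;
both configurable — real studies should match their upstream QC) and then
searched against the reference proteins in all six reading frames. The
default search is **seed-and-extend**: exact amino-acid 8-mers locate the
query/reference diagonal and a gapless BLOSUM62 extension scores it; a
read is assigned to the top-scoring gene when the score reaches
`bits_min` (50 bits) and the identity `id_min` (0.6), with ties broken by
identity and then by lexicographic gene id. Gapless extension is a
deliberate simplification: the bundled read simulator introduces
substitutions only (no indels), so on its output the gapless score equals
the gapped one, and an exhaustive Smith–Waterman path with affine gaps
(`method = "full"`, via Biostrings) is provided both for small real-data
jobs and as the oracle in the agreement tests. 16S rRNA reads are
assigned by nucleotide best hit on either strand at ≥ 0.8 identity.

Two performance notes. The classifier index precomputes dense k-mer
tables once per database and is reused across samples. The pipeline
driver additionally enables an exact nucleotide 16-mer prescreen
(`nt_prefilter`) that skips six-frame translation for reads sharing no
16-mer with any reference gene; at the generator's 0.5% substitution
rate the probability that a marker read evades every seeding window is
below 10^-6^, but the prescreen is **not** appropriate for reads that
diverge substantially from the references, so it is off by default in
the user-facing classifier.

## Sample curation

Three curation stages mirror the funnel of a typical global survey:

* **Contamination.** Samples whose 16S composition exceeds 25%
  Lactobacillales (order level) or 25% chloroplast reads are excluded;
  these signal fermentation/gut or plant-material contamination of a soil
  sample. The thresholds are configurable; samples with no 16S evidence
  are kept with a warning.
* **Geographic redundancy.** Samples taken within 1 km of each other
  (strict inequality, great-circle haversine distance on a sphere of mean
  radius 6371.0088 km) are clustered by single linkage — connected
  components of the under-1-km graph — and merged by summing counts. The
  haversine sphere diverges from an ellipsoidal geodesic by far less than
  1% at the 1-km decision scale. Merged coordinates are the arithmetic
  centroid, adequate at sub-kilometre extents away from the antimeridian.
* **Depth.** Taxonomic analyses use only samples with a combined
  *nifD* + *nifK* read count of at least 50 (inclusive). The combined —
  rather than per-gene — interpretation is a documented choice.

## Pseudo-nifH diagnostic

Reference *nifH*:*nifD*:*nifK* lengths are approximately 3:5:5, so read
counts sampled uniformly along genes should follow the same proportion.
The expected *nifH* count is
$E_H = \bar L_H \, (c_D/\bar L_D + c_K/\bar L_K)/2$
with $\bar L$ the mean reference length per family (this reduces to
$\tfrac{3}{5}\,\mathrm{mean}(c_D, c_K)$ at exact 3:5:5 lengths). A sample
is flagged when it holds 1.5 times or more the expected *nifH* (the
boundary is inclusive), or any *nifH* when none is expected. Whether to
use the 3:5:5 approximation or exact per-ortholog mean lengths is a
configuration choice; the package uses the mean reference lengths.

## Phylogenetic placement

A translated read is mapped onto the marker's reference alignment by
exact 5-mer seeding (the bundled reference packages have terminal-gap-only
alignments, so residue positions map directly to columns), scored against
every leaf over the covered columns (BLOSUM62 half-bits; leaf gaps score
−4), and the leaf scores are converted to a mass distribution by a
softmax with inverse temperature β = 0.5 per bit — calibrated so a 10-bit
score gap concentrates > 99% of the mass on the better leaf, and tending
to the uniform distribution as β → 0. This score softmax is a deliberate,
fully testable surrogate for maximum-likelihood evolutionary placement:
it preserves the contract that matters downstream (a normalised mass
distribution over the tree, LCA annotation, a confidence threshold)
while avoiding a model-based placement engine.

The annotation is the deepest taxonomy node whose leaves hold cumulative
mass ≥ τ (default 0.8; raising τ can only shallow the annotation). Reads
for which no node reaches τ are discarded as unreliable. Annotations
above family rank that fall within Deltaproteobacteria and whose
confidently supported descendant families (≥ 5% of within-clade mass,
the `gamma` parameter) are all Geobacteraceae or Anaeromyxobacteraceae
are tallied in a dedicated *possibly Geobacteraceae or
Anaeromyxobacteraceae* category, since their family-level identity is
constrained even though not resolved.

## Beta-diversity and group statistics

Placement mass (each read contributes 1/n of its sample's mass) feeds a
**normalized weighted UniFrac**:

$$d(A,B) = \frac{\sum_b l_b\,|P_A(b) - P_B(b)|}{\sum_b l_b\,(P_A(b) + P_B(b))},$$

summing over branches $b$ with lengths $l_b$, where $P_S(b)$ is the mass
of sample $S$ descending through $b$. The weighted variant is required
because placements carry read mass, and the normalisation bounds
distances in [0, 1] for NMDS comparability. The community distance is
the element-wise average of the NifD- and NifK-based matrices.

Ordination uses Kruskal's two-dimensional NMDS (stress-1 with monotone
regression), initialised from classical metric scaling and refined from
random restarts, keeping the lowest-stress fit. Group differences are
tested by one-factor **PERMANOVA** ($SS_\mathrm{total} = \sum_{i<j}
d_{ij}^2/n$, within-group analogues, pseudo-F, 999 label permutations,
add-one p-value convention so p is never zero) and per-environment
dominance ratios are compared by pairwise **Brunner–Munzel** tests — the
rank test of stochastic superiority $P(X<Y) + \tfrac12 P(X{=}Y) = \tfrac12$,
robust to unequal variances — with Bonferroni correction and a compact
letter display. Under complete separation the Brunner–Munzel t-form is
undefined and the implementation falls back to a label-permutation
p-value with a warning, which keeps the letter display total. Spearman
correlations use midranks with the t approximation.

## What the synthetic generator does (and does not) emulate

`simulate_reference_set()` / `simulate_community()` / `simulate_reads()`
define the study conditions used by the tests and the acceptance script:

* 40 taxa drawn from a fixed pool of named families (including
  Geobacteraceae and Anaeromyxobacteraceae inside Deltaproteobacteria,
  and Lactobacillaceae / chloroplast contaminant taxa); 30% complete
  diazotrophs, 10% pseudo-*nifH* carriers. Nitrogenase proteins are
  evolved from shared per-family ancestors (30% family-level, 12%
  taxon-level substitution) so placement has realistic signal; ribosomal
  proteins and 16S are taxon-specific.
* Marker lengths 900/1500/1500 nt ± 10% (the 3:5:5 proportion), genomes
  assembled as markers embedded in 10:1 neutral spacer DNA at the taxon's
  GC (0.35–0.70, with Anaeromyxobacteraceae at its distinctly GC-rich
  0.655–0.697), so roughly 91% of reads are non-marker, as in real
  metagenomes.
* Log-normal community abundances (σ = 1); the diazotroph block is
  rescaled to the sample's diazotroph fraction — 1% mean in aerobic
  categories (cropland, forest, grassland), amplified 17.6-fold in
  anaerobic ones (paddy, sediment, tundra) — with log-normal
  between-sample scatter (sd 0.2 on the log scale) and a 4-fold
  within-block preference for oxygen-matched families, which is what
  gives the two groups distinct community composition.
* 150-nt single-end reads from either strand, substitution errors at
  0.5%, optional logistic GC acceptance bias
  $w = \mathrm{logit}^{-1}(-\lambda\,(\mathrm{GC} - 0.5))$ emulating
  depletion of GC-rich fragments, constant Phred 37 qualities, and
  sampling sites ≥ 10 km apart with sub-kilometre replicates.

Passing tests on this generator demonstrate that the estimator recovers
its own generative conditions; they do not certify behaviour on real
soil metagenomes, whose reads carry indels, quality gradients, unknown
taxa diverged far beyond the reference set, paired-end structure and
non-log-normal abundances. Those aspects are explicitly out of the
generator's scope, as are Illumina error profiles and amplicon
error-correction.

## Numerical choices and degenerate inputs

* Annotation coordinates are 1-based inclusive; `-` strand means
  reverse-complement, then translate with the bacterial genetic code
  (table 11). Internal stop codons warn and are stripped.
* GC content concatenates all qualifying copies (16S copies must be
  ≥ 1000 nt) and excludes ambiguous bases from numerator and denominator;
  a genome with no qualifying copy yields `NA`, never 0.
* When several *nifH* copies exist, the copy nearest a *nifD/K*
  annotation is selected; ties break on the smaller start coordinate.
* A sample with nitrogenase signal but no ribosomal protein signal has
  an undefined ratio and is flagged unusable rather than given a value.
* Zero off-diagonal distances are nudged by a relative 10^-9^ before
  NMDS (the monotone-regression fit requires positive dissimilarities);
  configurations with n ≤ dims + 1 fall back to exact classical scaling
  with stress 0.
* All pipeline randomness (simulation, permutations, NMDS restarts,
  separation fallbacks) derives from one root seed recorded in the
  manifest; a rerun with the same seed is numerically identical.

## Problem sizes used by the tests and acceptance script

The full-scale validation study is 20 aerobic + 20 anaerobic samples of
2×10^5^ reads each against the 40-taxon reference set — enough depth for
roughly 40 nifD/K reads per aerobic and 700 per anaerobic sample, so the
fold estimate has a few-percent standard error. Module tests run the
same machinery at 8–10 taxa and 10^4^–10^5^ reads; the
Smith–Waterman agreement check uses 250 reads against a marker-only
database, and statistic calibrations use 2000 Brunner–Munzel null
replicates and 200 PERMANOVA label randomisations at 999 permutations.

## Known limitations

* The placement engine is a score softmax, not likelihood-based
  evolutionary placement; confidence values are calibrated only through
  β and should not be compared with likelihood weight ratios from other
  tools.
* The gapless fast classifier path assumes low-indel reads; use
  `method = "full"` (or an external translated aligner) for real data
  with indels.
* Reference packages built by `build_refpkg()` rely on the generator's
  indel-free proteins; real reference alignments with internal gaps are
  supported by the `refpkg()` container via per-leaf column maps, but
  building them (MSA, tree inference) is out of scope.
* The contamination thresholds and QC defaults are conventional rather
  than derived; real studies should set them from their own controls.
* Compositional effects of the dominance ratio (sum over a configurable
  RP panel) are documented constants, not estimated quantities; group
  fold-comparisons are invariant to the sum-vs-mean choice.
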