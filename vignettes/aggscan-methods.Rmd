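---
title: "Methods: scoring, classifying and cross-validating a saturation-mutagenesis seeding screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, classifying and cross-validating a saturation-mutagenesis seeding screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggscan)
```

# Overview

`aggscan` analyses sort-seq saturation-mutagenesis screens of α-synuclein
(aSyn) seeded aggregation. The experimental design it models is: one library
variant per cell, FRET-based sorting into aggregate-containing
(FRET-positive) and aggregate-free pools, deep sequencing of each pool, and
per-variant enrichment scoring against the unsorted input library.
Companion modules handle the two orthogonal structural readouts usually run
alongside such screens — cross-linking mass spectrometry (XL-MS) contact
maps of the monomer, and NMR chemical shift perturbations between wild type
and a point mutant.

This vignette documents the statistical model of each stage, the tunable
parameters and their defaults, the numerical choices that are not forced by
the method, what the synthetic-data generator does and does not emulate,
and the known limitations.

# The variant library

An NNS codon (N = A/C/G/T at the first two bases, S = G/C at the third)
spans 32 codons encoding all 20 amino acids plus the TAG stop. Substituting
every codon of an L-residue gene therefore yields 32 codon variants per
position, which collapse to 21 protein products (20 amino acids + stop), of
which 20 are non-wild-type. `enumerate_nns()` performs this expansion and
collapse; position 1 (the initiator Met) is excluded by default, so for
aSyn (140 aa) the mutable window 2–140 gives 139 × 32 = 4448 codon variants
and 139 × 20 = 2780 protein variants. Stop variants are carried as a 21st
substitution symbol: they are excluded from the 20-row display matrix and
from residue medians but are essential for the screen's error estimate.

The packaged aSyn coding sequence is the canonical UniProt P37840 protein
reverse-translated with one representative codon per amino acid (third base
A/T wherever the code allows); the DNA is synthetic in that sense, and the
FASTA is named accordingly. Every protein-level quantity in the pipeline is
invariant to the wild-type codon choice; the A/T-third-base convention
additionally keeps every NNS substitution distinguishable from the template
at the nucleotide level (only Met/Trp positions force an NNS wild-type
codon), which makes synonymous-variant bookkeeping unambiguous.

# Counting

Reads are trimmed to the gene region between two constant anchor sequences
(the primer tails flanking the amplicon; reverse-complement reads are
re-oriented via the anchors) and must have exactly the expected length —
indels are not rescued. Counting is by *exact* string match against the
expected-gene database: a read increments the wild-type bucket (if it
equals the template or any synonymous NNS variant — synonymous counts are
combined into the reference), exactly one protein variant, or the unmatched
bucket. No error-tolerant rescue is attempted, because 1-mismatch rescue
would alias neighbouring single-codon variants, the very thing the library
is made of. Base qualities are parsed but unused.

# Relative enrichment

For variant $i$, selected pool $sel$ and input library $inlib$:

$$\mathrm{RE}_i = \log_{10}\frac{f_i^{sel}}{f_i^{inlib}} -
  \log_{10}\frac{f_{WT}^{sel}}{f_{WT}^{inlib}}$$

Frequencies are relative abundances **among recognized alleles** (matched
reads only). The method itself does not dictate the denominator; excluding
unmatched reads makes RE invariant to pool-specific junk rates (chimeras,
error reads), which differ between sorted pools for purely technical
reasons. RE is antisymmetric under exchanging the variant with the
reference and invariant to sequencing depth; both properties are tested.

Zero counts are not imputed: a variant absent from the input is
`missing_absent`, one with fewer than `min_input_count` input reads (or
zero selected reads) is `missing_low_count`, and only `scored` records
carry RE. The default `min_input_count = 10` keeps the Poisson component
of the RE standard error below ≈ 0.15 log10 units
($\sqrt{1/10}/\ln 10 \approx 0.14$); it is configurable and recorded in the
run manifest. A `pseudocount` option exists for sensitivity analysis but
defaults to 0.

# Stop-codon error estimate

A stop codon upstream of the fluorophore tag makes FRET physically
impossible, so stop variants in the positive gate are pure sorting error.
Two readings of a "stop-codon FDR" are implemented, because the verbal
definition is genuinely ambiguous:

* `positive_re` — the fraction of scored stop variants with RE > 0. Under
  strong selection this approaches 0 (stops are heavily depleted in the
  positive pool); it answers "how many stops look like discoveries".
* `gate_leakage` — the pooled stop enrichment ratio
  $\left(\sum_i f_i^{sel} / \sum_i f_i^{inlib}\right)$ times the fraction
  of sorted cells in the positive gate. Because stops cannot FRET, this is
  an unbiased estimator of the per-cell gate misassignment probability
  (the sorter error itself): the expected positive-pool frequency of a
  non-FRET-capable allele is its cell fraction times the error rate,
  renormalized by the gate size. On synthetic screens with a 3.6 % injected
  sorter error this estimator recovers 0.036 within counting noise, while
  `positive_re` sits near zero.

Both are reported by the pipeline; neither is asserted to be *the*
experimental definition.

# Residue classification

Per-residue medians are taken over scored missense cells only (stops and
masked cells excluded; even counts average the two central values). The
inhibitory/neutral split uses Otsu's method: the threshold maximizing
between-class variance. On continuous data Otsu needs a histogram; the
default is 256 equal-width bins over the observed range, the classical
image-processing formulation, with the threshold reported as the bin edge
and ties resolved by averaging the maximizing edges. The binned threshold
is tested for classification equivalence against an exhaustive search over
all candidate cut points. The comparison is inclusive (median ≤ threshold
⇒ inhibitory), and inhibitory residues are merged into maximal consecutive
intervals rendered "a to b". Sensitivity to the bin count can be probed by
passing `bins`; on well-separated bimodal data (the regime in which the
classification is meaningful at all) the inhibitory set is stable over
64–1024 bins.

# Profile embedding

Each scored residue contributes a 20-vector of substitution REs, with
missing and wild-type cells set to zero; residues with no scored cell are
excluded entirely rather than embedded as all-zero points (zero-filling is
a within-profile imputation, not a justification for embedding unobserved
residues). The embedding is exact-gradient t-SNE — at N ≈ 139 points the
O(N²) exact formulation is cheap and avoids approximation noise — with
perplexity 30, Euclidean distances, per-point kernel calibration by
bisection, early exaggeration 12 for 250 of 1000 iterations, learning rate
200, momentum 0.5 → 0.8, and Gaussian initialization (SD 10⁻⁴) under a
recorded seed. Reruns with the same seed are bit-identical. These optimizer
constants are stated here precisely because no convention fixes them;
changing them changes coordinates but not, in our tests, cluster structure.

# XL-MS consensus and structural compatibility

Identification tables (one row per cross-link spectrum match) are filtered
with the standard post-search criteria exactly as stated: score **strictly**
greater than 30, mass error in the **closed** interval [−2.2, +3.8] ppm,
%TIC > 10, both peptides ≥ 6 residues, and per peptide ≥ 4 assigned
fragments *or* ≥ 3 contiguous fragments. Identifications are collapsed to
unordered residue pairs (peptide context discarded — the consensus map is
residue-level), and a pair is kept only if present in at least `required`
replicates (default all, i.e. 5-of-5); its weight is the mean
identification count across all replicates.

Region counts default to requiring **both** endpoints inside the window;
"links within the N-terminal 35 residues" is ambiguous and the
one-endpoint reading is available via `mode = "any"` — both numbers, and
the distinct-pair count, are reported.

Geometric compatibility against a conformer uses Cα–Cα Euclidean distance
with a strict `< 30 Å` rule. The Cα atom is a choice (zero-length
DMTMM chemistry links side chains; a Cβ option exists), and 30 Å is a
deliberately permissive bound for a disordered chain. Ensemble clustering
superposes the chosen residue window of every model pair by least-squares
rigid-body fitting (Kabsch/SVD, reflection-corrected; cross-checked against
bio3d), then partitions models by k-medoids (PAM) on the RMSD matrix with
k = 4. PAM on a precomputed distance matrix is deterministic and its
medoids are actual models, which is why it was preferred over hierarchical
or k-means variants; occupancies are cluster sizes over ensemble size,
reported in decreasing order.

# NMR chemical shift perturbations

With two assigned ¹H-¹⁵N peak lists, per-residue shift changes are
Δδ = δ(reference) − δ(comparison) in each dimension and the combined
perturbation is

$$\mathrm{CSP} = \sqrt{\Delta\delta_{H}^{2} +
  \left(\Delta\delta_{N}/5\right)^{2}}$$

with the conventional factor 5 compressing the wider ¹⁵N dispersion.
Residues missing from either list are excluded; residues flagged
low-confidence in either list are excluded from the mean CSP (confidence is
an input annotation, not computed — assignment confidence criteria are
upstream of this package). The perturbed region is called at
CSP > mean + k·SD (default k = 1 — no standard cutoff exists for
"substantial" perturbation, so the multiplier is exposed and a small
sensitivity sweep is printed by the analysis driver), with runs merged
across single-residue gaps to tolerate prolines and unassigned positions.

# The synthetic-data generator

`simulate_screen()` draws library allele frequencies from a Dirichlet
(concentration 50, mimicking even coverage), assigns each of `n_cells`
cells one allele, lets a cell with variant $i$ aggregate with probability
$\mathrm{logit}^{-1}(\alpha + \beta s_i)$, flips its gate with probability
`sorter_error`, and samples `reads_per_pool` reads per pool multinomially
with independent per-base substitution errors. Defaults define the study
conditions used throughout the tests and analysis scripts: aSyn residues
2–140; four planted core windows (36–42, 47–56, 65–78, 88–95) whose
missense substitutions carry propensity s = −4; proline additionally
inhibitory over residues 30–100; baseline seeding rate 30 %
(α = logit 0.3, β = 1); sorter error 0.036; 5 × 10⁵ cells; 2 × 10⁵ reads
per pool; per-base error 2.5 × 10⁻⁴ (overlap-corrected merged amplicons);
stops FRET-incapable by construction. The logistic link is the simplest
monotone map from a propensity scale to a sorting probability; nothing in
the pipeline depends on its form.

What the generator does **not** emulate: multiple lentiviral integrations
per cell, photoconversion efficiency, PCR jackpotting and chimeras,
position-dependent sequencing error, indels, or real fragment-ion spectra
(XL-MS fields are drawn directly in passing/failing ranges). Passing
recovery tests therefore demonstrates that the pipeline's inference is
correct *given the stated generative model*, not that real screens are free
of these artifacts.

The other generators plant known truth the downstream stage must recover:
`simulate_xlms()` places true pairs in all replicates with passing fields
and decoys in strict replicate subsets or with single failing fields;
`simulate_ensemble()` builds self-avoiding random-walk conformers at 3.8 Å
Cα spacing, replicated per occupancy with Gaussian noise;
`simulate_peaklists()` shifts a contiguous region by a set magnitude
(¹H offset = magnitude, ¹⁵N offset = 5 × magnitude) over a small global
jitter, omitting aSyn's 5 prolines so 135 residues are assignable. All
generators are bit-reproducible under a seed and leave the caller's RNG
stream untouched.

# Problem sizes and determinism

The test suite and analysis drivers use: the full 139-position aSyn screen
at 3 × 2 × 10⁵ reads for end-to-end recovery (≈ 15 s); toy 4-codon genes
for counting semantics; 100-model ensembles for clustering; 200-point
samples for the Otsu oracle; 120–140-point profile sets for t-SNE. These
sizes were chosen so every property is measured in the regime where its
Monte-Carlo error is far below the tested margins while the whole suite
runs in well under a minute. Every stochastic step takes an explicit seed,
and deterministic stages (counting, scoring, classification) rerun
byte-identically, which the pipeline manifest's MD5 sums make checkable.

# Known limitations

* Point estimates only: no replicate-based shrinkage or variance model for
  RE (Enrich2-style); screens with biological replicates need upstream
  aggregation.
* Exact matching discards reads with any error in the gene region
  (≈ 10 % at the default error rate); depth budgeting should account for
  this, and unmatched rates are reported per pool.
* Otsu assumes a genuinely bimodal median distribution; on unimodal data
  it still returns a cut, and the classification is then not meaningful.
  Inspect the median histogram before trusting the inhibitory set.
* The gate-leakage error estimator needs the positive-gate cell fraction
  from the sort statistics; without it only the `positive_re` reading is
  available.
* t-SNE coordinates are seed-dependent up to rotation/reflection and
  convergence; only neighborhood structure should be interpreted.
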