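---
title: "Mining BaiE families from gut metagenomes: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining BaiE families from gut metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baiminer)
```

## The problem

Secondary bile acids (deoxycholic and lithocholic acid) are produced
from the primary bile acids (cholic and chenodeoxycholic acid) by a
small guild of gut bacteria carrying the bile-acid-inducible (*bai*)
operon. The pathway's marker enzyme is the 7α-dehydratase BaiE.
Because most of these organisms are uncultured, their discovery runs
through assembled metagenomes: find BaiE-like proteins, group them
into families, check whether each family's genome neighborhood carries
the *complete* operon (partial neighborhoods are common and
non-functional), quantify the families in read data, and relate them
to host phenotype. `baiminer` implements that chain end to end, with a
synthetic-data module that makes every stage testable offline.

## Discovery model

ORF extraction scans all six frames and reports, per maximal stop-free
stretch, the single ORF opened by the *first* ATG after the previous
stop (no nested ORFs). The default minimum protein length is 100
residues — comfortably below the smallest operon gene modelled here
(barB, 195 aa; BaiE itself is 177 aa) while suppressing spurious short
ORFs. Intervals are 0-based, half-open, include the stop codon, and
are reported in forward-strand coordinates; that convention holds
everywhere in the package.

Homology search is optimal local alignment (Smith–Waterman, affine
gaps) under BLOSUM62 with gap open 11 / extend 1, the conventional
gapped-BLASTP parameterization, with Karlin–Altschul statistics
(λ = 0.267, K = 0.041):

\[ \mathrm{bit} = \frac{\lambda S - \ln K}{\ln 2}, \qquad
   E = m\,n\,2^{-\mathrm{bit}}. \]

Percent identity is counted over alignment columns *including* gap
columns, and query coverage is the aligned fraction of the query
length. The two discovery stages differ only in thresholds: 50%/90%
identity/coverage against curated reference proteins, 30%/90% against
metagenome ORFs, both exposed in `search_params()`.

The iterative expansion alternates search → SSN clustering →
functional acceptance. A cluster is accepted when it contains a
current query, or — when operon verdicts are available — when a member
carries a complete operon; accepted members become next-round queries.
The accepted set grows monotonically inside a finite database, so a
fixed point is guaranteed; a cap of 20 rounds exists purely as a
diagnostic.

## The SSN and its threshold

The network's edge score is the EFI-EST-style alignment score
\(-\log_{10} E\), clamped at 300 against floating-point underflow, with
the pairwise product of sequence lengths as the E-value search space so
the graph does not depend on database size or input order. The
canonical threshold is 70, which for BaiE-scale proteins (~177 aa)
corresponds to roughly 90% amino-acid identity — the suite verifies
this gloss qualitatively rather than assuming it. Families are
connected components; singletons are kept as their own clusters so the
accounting is lossless. Cluster numbering (1..k by descending size,
ties by smallest member id) replaces the arbitrary naming such networks
usually carry. The within-cluster identity summary is the *minimum*
pairwise percent identity among members; that reading of the
"within-cluster identity" headline is an interpretation, chosen because
it is the only summary that bounds every pair.

## Operon completeness

Neighborhood annotation aligns every ORF within 15 kb of the *baiE*
anchor against reference profiles of the operon genes and assigns the
best bit score subject to ≥30% identity and ≥50% reference coverage —
looser than the discovery filter because neighborhood genes diverge
more than the marker (transporters in real operons drop below 50%
identity to their references). The window default of 15 kb covers the
~12 kb span of known *bai* operons with margin; no authoritative value
exists, so it is configurable.

The completeness rule judges only the seven operon-local genes
(baiA, baiB, baiCD, baiE, baiF, baiG, baiH). The regulators barA/barB
and the distally encoded baiN/baiK are reported but deliberately
excluded from the verdict: regulators are not catalytic, and the
distal genes are not expected inside the neighborhood window at all,
so requiring them would misclassify genuinely complete operons. A
cluster verdict is existential — one complete member makes the cluster
a candidate — and clusters whose members all sit on anchor-only
contigs are `indeterminate` rather than negative, mirroring how short
metagenome contigs limit neighborhood analysis in practice.

## Quantification

Reads are trimmed with a Sickle-style sliding window (window = 10% of
read length) from both ends at mean quality < Q30, followed by a
per-base strip of sub-threshold end bases; the strip makes trimming
idempotent even though the window width tracks the read length. Reads
shorter than 50 bp are dropped. The CPM denominator is the post-trim
high-quality read count: the pipeline order (trim, then map) implies
the trimmed count is the sequencing effort that could have produced a
match.

Read-to-family matching is a banded nucleotide Smith–Waterman
(match +1, mismatch −1, gap −2, both strands) around the most-voted
shared 11-mer diagonal, band ±16. Acceptance is best match with ≥90%
identity over ≥20 alignment columns, one count per read, ties to the
lexicographically smallest cluster. Under the package's
substitution-only error model a read that can pass the 90% criterion
against its source gene always retains long exact runs, so the 11-mer
anchor and the band lose nothing in practice; `prefilter_k = 0`
switches to the exhaustive aligner, and the test suite checks the two
engines agree. The exhaustive pairwise aligner is also the engine for
OrthoANI fragments, where no anchor assumption is warranted.

## Association statistics

The two-group test is a two-sided Mann–Whitney U: the star notation on
skewed CPM distributions never names its test in the tradition this
package follows, and U is the standard nonparametric choice, so the
choice is documented here as an assumption. Exact enumeration is used
when both arms together hold ≤12 tie-free observations, otherwise the
normal approximation with tie and continuity correction. Stars map
p < 0.05/0.01/0.001 to \*/\*\*/\*\*\*. No multiple-testing correction
is applied by default (matching the raw-star reporting convention);
Benjamini–Hochberg is available behind `p_adjust = TRUE`. Spearman's ρ
is the Pearson correlation of midranks with a t-approximation p-value
(n−2 df); samples with an undefined bile-acid ratio (zero primary-BA
denominator) are excluded pairwise, never imputed.

## Comparative genomics

ANI follows the OrthoANI construction: non-overlapping 1020-bp
fragments, reciprocal best-hit pairs by nucleotide local alignment
(admission ≥35% identity over ≥35% of the fragment, the published
OrthoANI defaults), ANI = mean identity over reciprocal pairs. The
same-species call uses 95%, the midpoint of the conventional 94–96%
band, and is configurable. Neighbor joining is the classical
Saitou–Nei algorithm with the Q criterion; ties break to the lowest
index pair, and a negative branch length is clamped to zero with the
deficit moved to its sibling, preserving the joined taxa's path
length. p-distances use pairwise deletion for gap columns — the gap
treatment for concatenated marker alignments is not standardized, and
pairwise deletion wastes no columns on complete rows.

## Mass arithmetic

Monoisotopic masses use NIST most-abundant-isotope values to ≥6
decimals; adducts add or subtract the proton mass 1.007276 Da
(electron mass neglected — the proton-mass convention, stated
explicitly). Printed instrument m/z values carry calibration offsets,
so agreement with computed values is judged in ppm; the package's
computed [M+H]⁺ for cholyl-CoA and 3-oxo-cholyl-CoA land within ~3 ppm
of the published chromatogram annotations, inside the 10 ppm
acceptance band.

## The synthetic-data module

The generators emulate the statistical structure the analysis assumes:

* `mutate_family()` derives family members by i.i.d. residue
  substitution at rate 1 − target identity, BLOSUM62-weighted
  (weight 2^score) so alignment scores stay realistic; the initial
  methionine is fixed. The default target of 0.98 member-to-ancestor
  identity places realized pairwise within-family identity at ~93–96%,
  i.e. inside the >92% within-cluster regime natural BaiE families
  show; 0.97 would let the pairwise minimum dip to ~90%, outside it.
* `build_contig()` reverse-translates proteins with uniform synonymous
  codons (standard bacterial code — codon bias is irrelevant to the
  logic under test) and flanks every gene with a short palindromic
  "stop wall" carrying stop codons in all six frames, so planted ORF
  boundaries are exactly recoverable. Long genes still produce
  occasional reverse-strand ORFs by chance; annotation marks them
  `unassigned` and tests assert recovery *of the planted genes*, not
  absence of extras.
* `simulate_reads()` draws reads with probability ∝ abundance ×
  contig length, substitution errors only (the mapping criterion is
  identity/length-based; indels would add noise without exercising new
  logic), constant Q40 qualities, and emits per-read truth.
* `simulate_metadata()` plants a Spearman correlation via the
  bivariate-normal identity r = 2 sin(πρ/6) applied to the normal
  scores of the abundance ranks, and plants the disease-group effect
  by scaling disease-sample abundances by e^(−effect): the function
  returns both the metadata and the shifted abundance vector, since a
  location shift cannot be imposed on an input held fixed.

What passing tests on this module show — and what they do not: the
generators produce clean family structure, uniform coverage,
substitution-only errors and honest null distributions, so the tests
demonstrate the *logic* of every stage (thresholds, completeness
rules, normalization, calibration) under its stated assumptions. They
do not demonstrate robustness to indels, strain mixtures, chimeric
assemblies, GC bias or batch effects in real cohorts.

## Problem sizes and numerical choices

The packaged study fixture runs 3 families × 6 members, 3 decoys,
one operon contig per family, and 12 samples of 5,000 100-bp reads at
1% error with 20% of reads from *baiE* genes; the abundance-recovery
check uses a single deep sample of 2×10⁵ reads over six planted
families at fractions 85/9.1/5.4/0.3/0.4/0%. These sizes were chosen
so that planted effects dominate sampling noise (binomial 3σ at 2×10⁵
reads resolves a 0.3% family) while a full pipeline run stays in the
tens of seconds. Tolerances in the tests are derived, not tuned:
binomial 3σ for fractions, ±3 percentage points for realized mutation
rates at length 177, ±0.1 for realized Spearman ρ at n = 140.

Determinism: every generator is a pure function of (spec, seed), all
pipeline randomness derives from one master seed via named per-stage
substreams, RNG state is saved and restored around each generator, and
the run report's hash is an md5 over the written tables — two runs
with one seed are byte-identical.

## Known limitations

Protein search is exhaustive all-vs-all (no heuristic seeding), sized
for desk-scale databases, not UniRef. E-values follow plain
Karlin–Altschul without composition-based adjustment, so they are
internally consistent rather than BLAST-identical. The read model has
no indels, pairing or quality miscalibration; paired reads are treated
as independent single ends. Bootstrap support for NJ trees is provided
only as an optional seeded column-resampling flag and is not part of
the validated surface. Maximum-likelihood phylogenetics, HMM-profile
annotation and metabolic-pathway reconstruction are out of scope.
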