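---
title: "Clone-count small RNA analysis: models, criteria and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clone-count small RNA analysis: models, criteria and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirCloneSeq)
```

mirCloneSeq implements a clone-count small RNA analysis chain for
paired tumour/normal cloning-and-sequencing studies: read annotation,
novel miRNA hairpin discovery, RNA-modification profiling, expression
statistics and survival analysis, together with a synthetic study
generator that makes the whole chain testable without external data.
This vignette explains the models behind each stage, the parameters
that matter, the numerical choices, and what the synthetic data do and
do not establish about real libraries.

## Read annotation

Reads are classified against reference databases in the fixed priority
order miRNA, piRNA, rRNA, tRNA, snRNA, snoRNA, mRNA, then the genome.
Classification is an exhaustive ungapped sliding alignment: at this
scale (18–31 nt reads, desk-sized databases) an exhaustive search is
oracle-grade and avoids any heuristic aligner behaviour. A hit
requires identity **strictly greater than** `threshold = 0.9` (a read
with exactly 90% identity is rejected). Identity is the fraction of
matching bases over the aligned span; up to `maxOverhang = 3`
nucleotides of a read may extend past a reference end and are excluded
from the span, so the 5′/3′ end variation characteristic of cloned
small RNAs is recorded (`end5`, `end3`) but not penalized. Cloning
chemistry produces end variation, not indels, so no gaps are allowed.
`N` matches nothing; T and U are equivalent at parse time.

Priority is by class, never by database file order, and within the
miRNA class mature entries precede precursor entries, so a read
matching both gets the mature id. Reads whose only miRNA hit is a
precursor entry are flagged `precursor_only`: these are opposite-arm
candidates. This matters because a read cloned from the non-annotated
arm of a known precursor matches the precursor database exactly and
therefore never reaches the genome class — the discovery stage
consumes both the genome class and these precursor-only reads.

Normalization is clone count × 1000 / (total clone count in the
matrix for that sample), so each sample's normalized totals sum to
exactly 1 000. The class-composition table is computed over *all*
reads, the expression matrix over mature-assigned miRNA reads; with
one denominator serving both the per-1000 contract and the
sum-to-1000 identity, the matrix denominator is the mature-assigned
total.

## Folding model

The hairpin stage needs secondary structure, but only its *topology*:
the decision criteria count loops, bulges and paired mature
nucleotides. Folding is therefore a maximum-weighted nested-pairing
dynamic program (the classic O(n³) recursion) with pair weights
GC = 3, AU = 2, GU = 1 and a minimum hairpin loop of 3 nt — a
pseudo-energy surrogate, not a thermodynamic nearest-neighbour model.
The traceback is deterministic: among optimal structures the smallest
5′ position is paired first, with its largest admissible partner. For
sequences of length ≤ 12 the DP score is verified against exhaustive
enumeration of all nested pairings; `foldFromPairs()` is the seam for
substituting an externally computed structure.

Two consequences of this surrogate shape the rest of the design:

* **Dense degenerate pairing.** With no loop or stacking penalty, a
  random 110-nt window pairs most of its bases; a window holding a
  genuine compact hairpin does not necessarily out-score one holding
  diffuse junk pairing, and an optimal structure may route pairs away
  from a real stem. Thermodynamic folding does not behave this way —
  stacking cooperativity concentrates energy in long helices.
* **G·U asymmetry.** The reverse complement of a G·U pair is C·A,
  which does not pair, so strand symmetry of folding holds exactly
  only for Watson–Crick weights (tested with GU = 0).

## Window scan and candidate assessment

A candidate locus is extended by `context = 88` nt of genomic sequence
on each side and scanned with 110-nt windows at a step of 5 nt —
dense enough that some window always covers any plantable hairpin with
both arms; ties in score break to the leftmost window (`windowScan()`).
Minus-strand loci are folded on the reverse complement with
coordinates and conservation reversed.

Because of the dense-pairing degeneracy above, *candidate assessment*
(`assessHairpin()`, used by the discovery cascade) does not rely on
the single top-scoring window: it folds every admissible window — at
sizes 110, 85 and 65 nt — and accepts the locus when **some** window's
optimal configuration passes the criteria, reporting the best-scoring
passing window. The smaller, precursor-scale subwindows restore the
locality that thermodynamic folding would impose energetically: inside
a 65-nt window a genuine stem dominates its own optimum, while a junk
window still has to pass the structural criteria and (for novel calls)
the conservation test. On random background this combination is
stringent; on planted hairpins it is reliable.

## Structural criteria

The five criteria are evaluated on the *stem-loop unit containing the
mature span*: the subtree of the innermost base pair enclosing the
mature-span midpoint, extended outward through single-child ancestors
(the rest of the mature's stem). Anchoring at the mature span is
deliberate: under a max-pairing folder the literal connected component
of the fold almost always contains additional spurious terminal loops
formed by flanking sequence, which would reject genuine hairpins; the
unit instead asks whether the cloned sequence itself sits in a
stem-loop. Branching *below* the mature's enclosing pair is still a
multiloop and still fails criterion (a).

* (a) exactly one terminal loop in the unit;
* (b) more than 16 mature nucleotides base-paired (anywhere in the
  fold — the partner's location is not constrained);
* (c) terminal loop smaller than 20 nt;
* (d) every internal loop smaller than 10 nt, counting unpaired
  nucleotides on **both** sides (the standard nomenclature; a
  per-side reading would be laxer);
* (e) every bulge smaller than 5 nt.

All bounds are exposed as parameters; the defaults are the study
thresholds. The boundary behaviour (16 vs 17 paired, 19 vs 20 loop,
9 vs 10 internal, 4 vs 5 bulge) is pinned by constructed pairing-table
fixtures in the test suite.

**Conservation.** A hairpin is conserved when the mean of the
conservation track over some contiguous 15-nt window lying entirely
within consecutive stem (paired) positions is at least 0.8. Bulges
break positional runs; an arm without any 15-nt run is flagged
`stem-too-short` and cannot be conserved. The implementation is a
cumulative-sum scan over runs, verified against a brute-force
all-windows oracle.

## Discovery cascade

Groups are built by single-linkage merging of same-strand read
intervals overlapping by ≥ 1 nt; the representative sequence is the
highest-clone-count sequence (lexicographically smallest on ties), and
groups need `minReads = 2` clones — one clone is indistinguishable
from a sequencing artifact. The cascade assigns exactly one class:

1. same-strand overlap with a known precursor → **opposite** if the
   group lies across the precursor's terminal loop from the annotated
   mature (the loop midpoint comes from folding the precursor;
   opposite candidates are not re-folded, since the precursor
   structure is already accepted by the reference database), else
   rejected;
2. overlap with a known mature locus on the other strand → fold on the
   group's own strand; criteria pass → **antisense** (no conservation
   demanded — the locus sits in an annotated, conserved region by
   construction);
3. no overlap with known loci → criteria **and** conservation →
   **novel**; otherwise rejected with the first failing reason
   (`no-stem-loop`, `mature-pairing<=16`, `terminal-loop>=20`,
   `internal-loop>=10`, `bulge>=5`, `not-conserved`). Structurally
   sound but unconserved candidates are thus visible in the output
   with their own reason rather than silently dropped. Without a
   conservation track, novel calls are disabled and logged.

## Modification profiling

Reads are aligned to their mature reference with a 5′-anchored offset
in [−2, +2]; substitutions are called at reference positions +1..+18,
ignoring everything beyond the shorter 3′ extent (the 1–3 nt 3′
variability of cloned miRNAs is length variation, not editing). Reads
with more than 2 substitutions in the profiled window are excluded as
probable artifacts. Fractions are clone-count weighted: edited clones
over clones covering the position, per tissue group; groups under
`minReads = 10` clones report `NA`, and sites are reported at a
fraction of ≥ 0.05 in some group. A → G is labelled A-to-I (inosine is
read as guanosine by sequencing); other substitutions are reported as
raw from→to in RNA letters (U for T) with no mechanistic claim. SNP
exclusion is by an explicit mask only — a fraction-based SNP heuristic
would silently discard genuinely near-complete editing, which does
occur.

Each miRNA contributes nonmodified, modified and total rows to the
forms matrix (a `SummarizedExperiment`); total = nonmodified +
modified everywhere, and normalized totals sum to 1 000. Keeping the
forms separate can change sample clustering when groups differ in
editing rather than abundance — the package tests exactly that
scenario.

## Expression statistics

Rows expressed in fewer than 25% of samples are dropped (a row at
exactly 25% is kept). Samples are clustered by average-linkage
agglomeration on 1 − Pearson correlation of log2(per-1000 + 1); clone
counts are heavy-tailed, hence the log (the transform can be disabled,
in which case the distance is invariant to library-size rescaling).
Undefined correlations (constant profiles) become distance 1 with a
warning. A flat cluster whose members are all tumours and whose mean
normalized marker expression exceeds 250 is flagged high-risk — the
marker gene is a parameter (a miR-21 equivalent on real data, the
planted marker on synthetic data).

**SAM.** d_i = (mean difference)/(s_i + s0) on log2(per-1000 + 1),
with s0 the 5th percentile of the per-gene standard errors by default
(`s0Method = "grid"` selects the coefficient-of-variation minimizing
percentile instead). The null comes from *balanced* permutations —
each permuted group draws half its members from each true group, and
in the paired design exactly half the pair differences are
sign-flipped (all such patterns enumerated when there are at most
4 096) — so no permutation retains the planted signal. The delta is
the smallest value at which the estimated number of false positives is
zero; the estimate is the **mean** across permutations of permuted
statistics beyond the delta cut points (the median variant is
available as `fpMethod = "median"`, but a median-zero rule admits at
least one call on about half of null datasets — the observed maximum
deviation exceeds the per-permutation maximum that often — whereas the
mean-zero rule makes the null call rate a few per thousand). Under
these choices, global-null simulations yield zero calls in ≥ 95% of
seeds while planted 4-fold effects at 18 vs 18 are recovered with
average sensitivity ≥ 0.9.

Paired t tests use the standard closed form on log2(per-1000 + 1)
differences: zero-variance rows are flagged, with t = 0, p = 1 when
the mean difference is also zero and undefined p otherwise. Enrichment
is a two-sided Fisher exact test per term (summing tables no more
probable than observed), ranked by ascending p.

## Clinical module

ROC tables sweep every distinct marker value, reporting sensitivity,
1 − specificity, predictive values, likelihood ratios
(LR+ = sens/(1 − spec)) and accuracy per cutoff, with trapezoid AUC
(equal to the Mann–Whitney statistic, ties counted half). Markers
carry an orientation flag since a diagnostic marker may be *lost* in
tumours. Survival uses the survival package behind the module surface:
product-limit Kaplan–Meier with right censoring (deaths before
censorings at ties), the log-rank chi-square, and Cox partial
likelihood with Breslow tie handling by default (`ties = "efron"`
available). Perfect separation (monotone likelihood) fails loudly with
the offending covariate named; the pipeline skips the Cox fit with a
message when a small study separates. The high-risk survival contrast
follows the clustering flag, reproducing the design in which an
expression cluster — not any individual marker — predicts recurrence.

## The synthetic study generator

`simConfig()` defaults define the emulated study: 18 HCC/ANL pairs;
2 000 clone reads per sample; 30 known miRNAs, 10 novel hairpins, 50
decoy loci (10 each of tRNA, rRNA, snRNA, snoRNA, piRNA), 5
opposite-arm and 3 antisense plants on a single 100-kb chromosome
(small enough for exhaustive scanning); ~80% miRNA read mass with
0.76% piRNA contamination; log-normal abundances (sdlog 1.5) with
per-sample jitter (sdlog 0.3); 3′ trimming of 0–3 nt (55/25/15/5%);
0.5% per-base sequencing error; editing at four sites with the
reported tissue rates (seed-region +6 A-to-I at 0.31/0.50 and
0.86/0.50, +10 C-to-A at 0.96/1.00, +17 U-to-A at 0.74/0.78); tumour
fold changes of log2 1.5 for the marker, +2 for three planted genes
and −2 for two; a high-risk quarter of tumours with a 2.5× marker
boost and an 8-fold recurrence hazard; 30% censoring on an exponential
baseline with a 24-month median.

Construction details that exist to honour the generator's own
contract ("planted signal is recoverable by the downstream module"):

* **Hairpin loops are A or C homopolymers.** A random-alphabet "loop"
  self-pairs under max-weight folding (directly, or through G/T wobble
  after reverse complement on the minus strand) and branches the
  terminal loop into a multiloop; a homopolymer loop admits no pair on
  either strand, so planted precursors are genuine stem-loops under
  the folding model actually used.
* **Antisense targets carry 3 arm mismatches.** An antisense read is
  the exact reverse complement of the mature, which resembles the
  precursor's other arm; with fewer than 3 mismatches it would exceed
  90% identity to the precursor entry and be annotated miRNA instead
  of reaching the genome class.
* **The high-risk cluster is a profile, not one gene.** High-risk
  tumours share a mass-normalized log-normal perturbation (sd 0.8)
  across non-marker miRNAs in addition to the marker boost;
  correlation-distance clustering cannot isolate a subgroup that
  differs in a single gene, and the emulated cluster is a
  profile-level subgroup with high marker expression.
* Mature lengths are 21–23 nt so a 3-nt trim never leaves the 18–24
  window; piRNA decoy fragments are 26–31 nt, truncated into 18–24
  with probability 0.1. Conservation is banded: ≥ 0.9 over novel
  hairpins, ~0.85 over known precursors, < 0.5 over decoys, ~0.3
  background, with Gaussian jitter (σ = 0.05) so the 15-nt window
  test is meaningful but not fragile.

What the synthetic data do **not** model: ligation/PCR bias,
platform-specific (homopolymer) error structure, multi-chromosome
genomes, genuine phylogenetic conservation tracks, isomiR 5′
heterogeneity beyond the ±2 alignment window, or biological
correlation between editing and expression. Passing tests on this
generator therefore demonstrate the *decision logic* — thresholds,
cascades, accounting identities, statistical calibration — not
performance on real libraries, where annotation completeness and the
thermodynamic accuracy of the folding surrogate would dominate.

## Problem sizes and numerical choices

The test suite and the acceptance script run the default study (36
libraries × 2 000 reads), 500-sequence folding-oracle comparisons,
1 000-track conservation comparisons, 200-seed SAM and log-rank
calibrations (100 permutations per null run; power averaged over 5
simulations at 300–500 permutations) and an n = 2 000 Cox recovery —
sizes chosen to give stable Monte-Carlo estimates on a single CPU in a
few minutes. All simulation entry points take explicit seeds and
restore the caller's RNG state (`withSeed()`); pipeline runs are
byte-deterministic given a configuration, and every run writes its
resolved configuration as YAML next to the outputs.

Floating-point notes: fold scores with the default integer weights are
compared exactly in the traceback; zero-variance flags in the paired t
use a 1e-10 relative tolerance because log transforms leave sub-ulp
noise in genuinely constant differences; dot-bracket parsing and
rendering round-trip exactly.

## Known limitations

* The folding surrogate has no stacking or loop entropies; its
  absolute scores are not free energies, and candidate assessment
  compensates with multi-size window scanning rather than energy
  fidelity.
* Opposite-arm detection requires the precursor database entry to
  extend across both arms; precursors annotated only as mature spans
  would silence that class.
* The SAM false-positive estimate at delta uses the permutation count
  directly, without a π₀ (true-null proportion) correction — at a
  zero-false-positive delta the correction is immaterial.
* Cox fitting inherits the survival package's behaviour for tied
  covariates and near-separation; the package refuses rather than
  reports coefficients beyond |β| > 15.
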