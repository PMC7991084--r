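---
title: "Methods: k-mer kernel similarity and benchmarking of CDR3 metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: k-mer kernel similarity and benchmarking of CDR3 metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TCRMatchR)
```

## The model

A TCR's CDR3β loop is the receptor region most directly in contact with
the presented peptide, so CDR3β similarity is a usable proxy for shared
epitope specificity. TCRMatchR scores that similarity with a string
kernel: for sequences $s$ and $t$,

$$K(s,t) \;=\; \sum_{k=1}^{\min(|s|,|t|)} \;\sum_{x \in \text{k-mers}(s)}
\;\sum_{y \in \text{k-mers}(t)} \;\prod_{i=1}^{k} m(x_i, y_i),$$

where the k-mers are contiguous substrings and $m(a,b)$ is the BLOSUM62
*observed joint-frequency* matrix raised element-wise to an exponent
$\beta$. The reported score is the cosine-style normalization
$K(s,t)/\sqrt{K(s,s)K(t,t)}$, which equals 1 exactly for identical
sequences and lies strictly in $(0,1)$ otherwise (the kernel is positive
definite, so Cauchy–Schwarz applies). Two readings of the normalization
factor are implemented; the geometric mean is the default because it is
the only reading under which a self-comparison scores exactly 1, which is
the defining property of the score. The plain product
$K(s,s)\cdot K(t,t)$ remains available via `norm = "product"` for
comparison.

Every k-mer pair lies on one alignment offset, so the kernel is computed
per diagonal with the recurrence $S_j = m_j(1 + S_{j-1})$, giving
$O(|s|\cdot|t|)$ per pair instead of the quartic literal enumeration. The
test suite proves the two routes identical (relative tolerance $10^{-9}$)
exhaustively on a 4-letter sub-alphabet and on random full-alphabet pairs.

### Why a frequency matrix, and why $\beta = 0.11387$

The kernel multiplies per-position values, so it needs strictly positive
entries — log-odds scores (which change sign) cannot be multiplied
meaningfully. The BLOSUM62 joint frequencies $q_{ab}$ are all positive and
encode substitution affinity. Raw frequencies are heavily dominated by
residue abundance, and products across positions decay geometrically;
raising the matrix element-wise to a small power flattens it toward 1 and
controls that decay. The default $\beta = 0.11387$ is the published
default of the k-mer kernel family this score belongs to; it is exposed as
`buildKernelMatrix(exponent =)` and the resulting matrix is pinned in
`inst/extdata/blosum62_qij.txt` (validated in two independent ways: its
row sums reproduce the published BLOSUM62 background frequencies, and
$\mathrm{round}(2\log_2 q_{ab}/p_ap_b)$ reproduces the integer BLOSUM62
log-odds matrix everywhere except a handful of rarest pairs where the
published four-decimal rounding of $q$ is itself lossy).

## Comparison metrics

Six standard metrics share one contract (`computeMetric()`), each tagged
with an orientation so thresholding code knows whether a match means
score ≥ cutoff (similarity) or ≤ cutoff (distance):

| token | definition | orientation |
|---|---|---|
| `alignment_score` | NW score / alignment columns | similarity |
| `identity_alignment` | exact matches / alignment columns | similarity |
| `identity_long` | exact matches / longer input length | similarity |
| `identity_short` | exact matches / shorter input length | similarity |
| `levenshtein` | unit-cost edit distance | distance |
| `tcrdist` | capped similarity-weighted mismatch distance | distance |

Alignments are global Needleman–Wunsch with affine gaps over the integer
BLOSUM62 log-odds matrix (shipped separately from the kernel's frequency
matrix), with open −7 and extend −1 by default: a gap of length $L$ costs
$7 + (L-1)$. The stricter −50/−20 regime is available through
`alignmentParams()`; making gaps harsher can only remove gap columns, a
property the tests assert. "Length of the alignment" counts all alignment
columns including gap columns — the natural reading for a global
alignment; identity denominators for the long/short variants use the
ungapped input lengths. When co-optimal alignments exist, identity counts
can differ between them, so the traceback tie-break is fixed: diagonal
over gap-in-reference over gap-in-query.

TCRdist here is the CDR3-only reduction of the published receptor
distance: per aligned column, identical residues cost 0 and a mismatch
$(a,b)$ costs $\min(4,\, 4 - \mathrm{blosum62}(a,b))$ floored at 0, with
each gapped column costing 4; the distance is the minimum over global
alignments, by dynamic programming with linear gap cost. The explicit
identity case matters: the capped formula alone would go negative for
high-scoring identical pairs such as (W, W). No CDR1/CDR2 terms or gene
segment weights are included, since only CDR3 sequences are modeled.
Levenshtein distance is delegated to base R's C implementation
(`utils::adist`) and cross-checked against a DP oracle in the tests.

## Flank trimming

Curated CDR3 data are inconsistent about including the IMGT junction's
conserved flanks. `trimFlanks()` removes the N-terminal cysteine and the
C-terminal phenylalanine/tryptophan when — and only when — both are
present; one flank alone is never touched, so the length change is exactly
0 or 2. The rule is applied exactly once per record (it is deliberately
not idempotent: "CCASSFF" trims to "CASSF", which would trim again), and
results shorter than 3 residues are rejected per record so every retained
sequence supports k-mers up to $k = 3$.

## Reference database and assembly filters

A `ReferenceDatabase` holds receptor groups, each defined by a unique
CDR3β with the union of its recorded epitopes. Reading a TSV merges
duplicate CDR3β records; `filterSingletonEpitopes()` removes epitopes
recognized by a single group (iterating to a fixpoint so that afterwards
every epitope is supported by at least two groups — a single pass is
formally sufficient because a removed group's only epitopes were
singletons, but the fixpoint loop makes the guarantee unconditional);
`assemblePaired()` keeps receptors with both chains, drops any chain
sequence occurring in more than one receptor, then singleton-filters.
`shuffleControl()` permutes the epitope calls across group slots while
preserving each group's call count and both multisets, repairing
within-group duplicates by deterministic swaps; it estimates the
chance-level precision of any matching procedure on the same data.

## The synthetic generator

`generateSynthetic()` emulates the statistical shape of curated
TCR–epitope data: a truncated power law over epitope popularity (default
exponent 1.3, concentrating roughly half of all calls in the few most
popular epitopes of a 500-epitope catalog), a planted fraction of
singleton epitopes (default 0.5), a mono-specific share of receptor
groups (default 0.885), and same-epitope receptors generated as point
substitution neighborhoods (Poisson mean 1.5) of one motif per epitope.
Motifs are CDR3-like rather than uniform-random: a V-derived prefix (e.g.
`ASS`) and a J-derived suffix (e.g. `EQY`) from small shared pools flank a
random core, with lengths 6–18. The shared germline flanks matter: they
are what lets short CDR3s align nearly perfectly into longer unrelated
ones, which is the documented failure mode of the shorter-sequence
identity metric; with uniform-random motifs that mechanism cannot occur
at desk scale. Generation is fully seed-deterministic, rejects duplicate
CDR3β by resampling (widening the mutation count when stuck), and refuses
infeasible specifications (fewer groups than the planted singletons plus
two receptors per non-singleton epitope).

What the generator does *not* emulate: V(D)J recombination statistics,
position-dependent substitution preferences, cross-reactivity structure
beyond random extra epitopes, or database curation noise. Passing the
benchmark suites on this generator therefore shows the machinery is
correct and the qualitative metric ordering emerges under realistic
shape, not that real-data headline numbers are reproduced.

## Benchmarking

For a query set against a database (typically the database against
itself, self-comparisons excluded by group identity), a reference group
whose score passes the cutoff (inclusive) contributes one epitope call
per epitope it recognizes; calls shared with the query are true
positives, the rest false positives, pooled over all queries
(micro-pooling — duplicate calls across matches count separately, which
is what makes the worked toy example's arithmetic 2/5). Recall is the
fraction of (query, epitope) pairs recovered by at least one match.
TPR/FPR are pair-level, a positive being a pair of groups sharing at
least one epitope. Threshold sweeps reuse one score matrix and per-row
cumulative counts, so a full curve costs little more than one scoring
pass; the default grid is 201 points over the observed score range with
the web presets 0.84/0.90/0.97 always injected for the kernel score.

The partial AUC integrates precision over recall 0–0.5 by trapezoid with
linear interpolation at the window edges. Points with undefined precision
(no calls) are dropped; duplicate recalls collapse to their best
precision. When the smallest attainable recall lies above the window
floor — routine for integer-valued metrics, whose strictest usable cutoff
can admit a large tied block at once — the first defined precision is
extended to the floor as a constant: sub-thresholding randomly inside a
tied block attains any smaller recall at the same expected precision, so
this is the expected-precision curve under random tie-breaking, and it is
inert for continuous scores. `NA` is returned only when the curve never
reaches the window floor.

`bootstrapCompare()` draws groups with replacement (default 100
resamples), scores each drawn group against the full remaining set,
recomputes each metric's partial AUC per resample from precomputed
per-row curves (the same resample indices for every metric, making the
comparison paired), and reports the fraction of resamples in which a
rival's pAUC strictly exceeds the kernel score's — ties never exceed —
plus 2.5/97.5 percentile intervals. Paired-chain analysis averages the
α–α and β–β scores of a metric, orientation inherited.

## Numerical and interface conventions

- Equality tolerances: kernel oracle equivalence and self-normalization
  at $10^{-9}$ relative; scores printed with 4 decimals in output tables.
- Thresholds are inclusive (score = cutoff matches) for both
  orientations.
- Degenerate inputs: empty sequences and non-standard residues (B, J, O,
  U, X, Z, `*`) are rejected with errors, never silently skipped; inputs
  are upper-cased and whitespace-stripped first. Zero matches is a valid
  result, not an error.
- All stochastic operations (generation, shuffling, bootstrap) take an
  explicit integer seed and are bit-reproducible for a fixed seed; report
  files contain no timestamps.
- Problem sizes in the shipped test suite were chosen for quick,
  convincing statistics: 500-group/60-epitope databases across 20 seeds
  for the shuffled-control and metric-ordering studies, 150-group
  databases for the bootstrap separation study, and exhaustive oracle
  comparisons on short sequences (full enumeration of alignments up to
  length 4–5, full 4-letter k-mer enumeration up to length 3 plus random
  longer pairs).

## Known limitations

- Only CDR3 sequences are modeled; gene usage, CDR1/2, and MHC
  restriction are out of scope, and the CDR3-only TCRdist is accordingly
  a reduction of the published receptor distance.
- The kernel's exponent and the "modified" frequency matrix follow the
  cited kernel method's defaults; other transforms would change absolute
  score scales (and hence the meaning of fixed cutoffs like 0.97).
- Chance precision depends strongly on the epitope popularity skew of the
  reference; absolute precision values from synthetic data should not be
  read as forecasts for any real database.
- The shuffle control preserves per-group call counts but not any
  sequence–epitope correlation structure finer than that.
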