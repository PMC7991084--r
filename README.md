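# TCRMatchR

Epitope-specificity matching of T-cell receptor CDR3 sequences by k-mer
kernel similarity, with a full benchmarking framework for comparing
sequence-similarity metrics.

## The problem

T-cell receptor (TCR) repertoire sequencing yields thousands of CDR3β
amino-acid sequences, but not the epitopes those receptors recognize.
Because receptors with similar CDR3β sequences tend to recognize the same
peptide, a query CDR3β can be assigned a *putative* specificity by finding
highly similar receptors in a reference database of TCRs with
experimentally characterized epitopes. This package is for immunologists
and computational biologists who want to (i) annotate query CDR3β (or
paired CDR3α–CDR3β) sequences against such a reference, and (ii) evaluate
how well different similarity metrics predict shared specificity.

## The score

The core is the TCRMatch similarity: a normalized string kernel over all
contiguous k-mers of two CDR3 sequences. With m(a, b) the BLOSUM62
observed joint-frequency matrix raised element-wise to the power 0.11387,

```
K(s, t) = Σ_{k=1}^{min(|s|,|t|)}  Σ_{x ∈ k-mers(s)}  Σ_{y ∈ k-mers(t)}  Π_{i=1}^{k} m(x_i, y_i)
```

and the reported score is `K(s,t) / sqrt(K(s,s) · K(t,t))`, which is 1
exactly when s = t and in (0, 1) otherwise. The implementation uses a
per-diagonal recurrence (`S_j = m_j (1 + S_{j-1})`) that computes the same
sum in O(|s|·|t|), verified in the tests against a literal enumeration of
every k-mer pair.

Six comparison metrics are provided under one dispatch contract
(`computeMetric()`): Needleman–Wunsch alignment score per column and three
percent-identity variants (per alignment column, per longer, per shorter
sequence; BLOSUM62, gap open −7 / extend −1), Levenshtein distance, and a
CDR3-only TCRdist (capped similarity-weighted mismatch distance). The
benchmark engine computes pooled precision/recall over shared-epitope
calls, pair-level ROC points, partial AUC of the precision–recall curve
over recall 0–0.5, and a paired bootstrap comparison of metrics, plus a
shuffled-pairing control that estimates chance-level precision. A
seed-deterministic synthetic repertoire generator (germline-anchored motif
neighborhoods, power-law epitope popularity, planted singletons) provides
study-shaped data for all of this without any download.

## Worked example

```r
library(TCRMatchR)

tcrmatchScore("ASSLAPGATNEKLF", "ASSLAPGATNEKLY")$normalized
#> 0.9988

db  <- generateSynthetic(n_groups = 200, n_epitopes = 40, seed = 7)
res <- runMatch("CASSWWACDPCKRDLWRQYF", db, threshold = 0.97)
head(res[, c("trimmed_sequence", "match_sequence", "score", "epitopes", "group_id")], 4)
#>    trimmed_sequence     match_sequence  score                      epitopes group_id
#>  ASSWWACDPCKRDLWRQY ASSWWACDPCKRDLWRQY 1.0000                     LWHCRIDIR      G10
#>  ASSWWACDPCKRDLWRQY ASSYWACDPCKRDLLEQY 0.9891                     LWHCRIDIR      G28
#>  ASSWWACDPCKRDLWRQY ASSYWACDPCKRDLNQQY 0.9890                     LWHCRIDIR       G8
#>  ASSWWACDPCKRDLWRQY ASSYWACDPCKRDLQEQY 0.9889 LWHCRIDIR,INWYIVRGS,AMHCAGQIR      G29
```

The input's conserved flanks (leading C, trailing F) are trimmed before
the search; each row is a reference receptor group whose score passes the
cutoff, with the epitopes it is known to recognize. The query's exact
match scores 1.0000; single-substitution neighbors score ≈ 0.989. At the
recommended stringency 0.97 this query returns 70 rows; lowering the
cutoff (0.90, 0.84, or `"all"`) returns more, less confident, matches.

Benchmarking the database against itself:

```r
bench <- runBenchmark(db, metrics = c("tcrmatch", "tcrdist", "identity_short"))
round(bench$pauc, 3)
#>       tcrmatch        tcrdist identity_short
#>          0.466          0.442          0.277
```

`pauc` is the area under each metric's precision–recall curve restricted
to recall 0–0.5; higher is better, and percent identity over the shorter
sequence trails because short CDR3s align spuriously well into longer
ones.

A command-line wrapper over the same functions ships at
`inst/cli/tcrmatch.R` with `match`, `benchmark`, and `generate`
subcommands.

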