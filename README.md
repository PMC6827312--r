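# ssnfam — protein subfamily delineation from sequence similarity networks

`ssnfam` splits a large protein family into subfamilies the scalable way:
instead of a multiple sequence alignment and a phylogenetic tree, it builds
**sequence similarity networks** (SSNs) — graphs whose nodes are sequences
and whose edges are pairwise local alignments more significant than an
E-value cutoff — and watches how connected components split as the cutoff
tightens. Candidate partitions are then validated by a library of
per-subfamily profile HMMs scored with precision and recall. The package is
aimed at curators of large enzyme families (the workflow was designed for
glycoside hydrolase–scale data, ~10⁴–10⁵ sequences via BLAST import) and at
method developers who need a fully testable, self-contained implementation.

## The method in brief

**Edges.** For sequences *i*, *j*, the optimal affine-gap Smith–Waterman
alignment (BLOSUM62, gap open 11, extend 1) gives a raw score *S*,
converted with gapped Karlin–Altschul parameters (λ = 0.267, K = 0.041):

    S' = (λS − ln K) / ln 2,      E = m · n · 2^(−S')

with *m* the query length and *n* the database residue total. An unordered
pair keeps the minimum E over directions; E-values are floored at 1e−180.
Precomputed BLAST tabular files (`-outfmt 6`) can be imported instead.

**Scan.** SSNs are indexed over E ∈ {1e−5, 1e−10, …, 1e−120}. Components
refine monotonically as thresholds tighten; the scan records which looser
cluster each stricter cluster came from. Highly similar nodes (E ≤ 1e−85)
can be contracted into metanodes for display without changing component
structure.

**Subfamilies.** At a chosen threshold (default 1e−55) a component becomes
a subfamily iff it has ≥ 20 members and spans ≥ 2 taxonomic classes (an
explicit override list admits robust monotaxon clusters). Everything else
is nonclassified. Numbering is deterministic: descending size, ties by
smallest member id.

**Validation.** For S subfamilies, an S+1 profile-HMM library (one model
per subfamily plus one for the nonclassified remainder) is built from
75%-redundancy-reduced, realigned training sets. Every sequence is
re-scanned; it is assigned to the best model's subfamily only if (i) its
best E < 1e−30 and (ii) the second-best E is ≥ 1e10-fold greater. Counting
TP (prediction matches the partition), FP (contradicts it, or targets an
unassigned protein) and FN (assigned protein with no prediction) gives
precision = TP/(TP+FP) and recall = TP/(TP+FN) per E-value ceiling.

A synthetic-family generator (`generate_families()`, `synth_preset()`)
produces families with planted subfamily structure, taxonomy labels and
truncated fragments, so the whole pipeline is testable offline.

## Worked example

Two synthetic subfamilies with 10 truncated fragment sequences planted
among 73 records:

```r
library(ssnfam)
bundle <- synth_preset("two_families_with_fragments", seed = 1)
cov    <- setNames(bundle$truth$model_coverage, bundle$truth$id)
flt    <- filter_fragments(bundle$records, cov)
#> [ssnfam] fragment filter: 63 kept, 10 fragments (< 95% coverage)

hits <- all_vs_all(flt$kept)
scan <- threshold_scan(hits, flt$kept$id, thresholds = 10^-seq(5, 60, 5))
summary(scan)
#>    threshold components
#> 1      1e-05          1
#> 2      1e-10          1
#> 3      1e-15          2
#> ...
#> 12     1e-60          2
```

The two families are one connected component at loose thresholds and
separate cleanly from 1e−15 on. Calling subfamilies at 1e−25 (minimum size
scaled to the fixture; cluster 2 is deliberately monotaxon and needs an
override):

```r
call <- delineate(partition_at(scan, 1e-25), flt$kept,
                  min_size = 10, overrides = 2)
#> [ssnfam] delineation: 2 subfamilies, 63/63 classified (100.0%)
call
#>   number size n_distinct override
#> 1      1   35          2    FALSE
#> 2      2   28          1     TRUE
```

Validating the partition with the S+1 HMM library:

```r
lib <- build_hmm_library(flt$kept, call$membership, calib_seed = 1)
asg <- assign_subfamily(flt$kept, lib)
ref <- setNames(as.character(call$membership), names(call$membership))
evaluate_library(asg, ref, cutoffs = 10^-seq(10, 50, 10))
#>   cutoff tp fp fn precision recall vacuous_precision
#> 1  1e-10 63  0  0         1      1             FALSE
#> ...
#> 5  1e-50 63  0  0         1      1             FALSE
```

Every kept sequence is re-assigned to its own subfamily at every ceiling —
the partition is self-consistent under the HMM library, which is the
method's acceptance signal for a good threshold.

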