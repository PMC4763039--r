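---
title: "MSAP band-pattern analysis: model, scoring rules and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MSAP band-pattern analysis: model, scoring rules and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msapkit)
```

## The assay and its information content

Methylation-sensitive amplified polymorphism (MSAP) is an AFLP variant
that probes cytosine methylation at 5'-CCGG-3' sites with the
isoschizomer pair *Hpa*II / *Msp*I. Both enzymes recognise CCGG but react
differently to methylation of the two cytosines:

* *Hpa*II cuts unmethylated and hemi-methylated sites, and is blocked by
  full (double-strand) methylation;
* *Msp*I cuts when the internal cytosine is methylated (C^5m^CGG, hemi or
  full), and is blocked by methylation of the external cytosine
  (^5m^CCGG).

Each locus therefore yields a presence bit in two lanes (EcoRI/HpaII and
EcoRI/MspI), and the pair of bits maps to a band type:

| hpa | msp | type | interpretation |
|----:|----:|:----:|:---------------|
| 1 | 1 | I   | unmethylated |
| 1 | 0 | II  | hemi-methylated (external C on one strand) |
| 0 | 1 | III | internal C methylated on both strands |
| 0 | 0 | IV  | hyper-methylated — *if* the fragment is seen in another sample |

The type-IV rule is relative by construction: a fragment absent from both
lanes of *every* sample never appears on a gel and cannot be scored, so
such loci are excluded from every denominator. `validate_band_matrix()`
flags them; `score_band_matrix()` marks them excluded. The same
convention drives the comparison universe of `summarize_comparison()`:
loci absent from both members of a pair stay in the analysis (class D)
exactly when they are observed in some other sample of the matrix.

Two genuine blind spots of the assay are kept visible rather than hidden:
a hemi-methylated *internal* cytosine is cut by both enzymes and scores
type I, indistinguishable from unmethylated (the simulator's `HM_int`
state exists to demonstrate this and defaults to probability 0); and a
restriction-site sequence polymorphism produces the same (0,0) signature
as hyper-methylation, so type IV conflates the two — a documented
limitation of MSAP itself, which this package follows.

## Summary statistics

For a sample with type counts $n_I, n_{II}, n_{III}, n_{IV}$ and total
$n$:

* total methylation $= 100\,(n_{II}+n_{III}+n_{IV})/n$,
* fully methylated $= 100\,(n_{III}+n_{IV})/n$,
* hemi-methylated $= 100\,n_{II}/n$,

so total = fully + hemi exactly, before any rounding. Percentages are
carried at full precision internally; rendering rounds to 1 decimal
(conventional for MSAP tables), chi-square statistics to 2 and p-values
to 3. Pooling across samples (`pool_summaries()`) sums counts and
recomputes percentages from the pooled counts — it never averages
percentages, which would weight samples incorrectly when totals differ.

## Comparative pattern classes

A control/treatment pair of lane-bit pairs takes one of $2^4 = 16$
patterns, labelled A–P with bit order (MspI, HpaII) within each sample.
A–D are the diagonal (treatment equals control: no change), E–J are band
gains in the treatment (demethylation: the site became cuttable), K–P are
band losses (methylation). Swapping the roles of control and treatment
maps each demethylation class to a methylation class (E↔K, F↔L, G↔N,
H↔M, I↔O, J↔P) and fixes A–D; the test suite asserts this involution on
the bit definitions. Group percentages use the comparison's classified
locus count as denominator.

One subtlety is worth recording: under the universe rule above, the two
members of a pair always share one denominator, and published
comparison totals need not equal either sample's single-sample total.
Count-level data are therefore reproduced from count-level fixtures
(`comparison_summary()` on per-class counts), while matrix-level data go
through `summarize_comparison()`; `pattern_counts_to_band_matrix()`
connects the two and the tests check they agree.

## Association statistics

`pearson_chi_square()` tests independence on band-type × condition (or
event-group × comparison) tables with the uncorrected Pearson statistic
$\sum (O-E)^2/E$; no continuity correction is applied for any table,
because the reference values this package reproduces are uncorrected
statistics. All-zero rows/columns — which small simulated matrices
produce readily — are dropped, reported, and the degrees of freedom
computed on the retained table; a table left with fewer than two
informative rows or columns is an error, not a silent answer.

`permutation_chi_square()` is the validation oracle: it conditions on
both margins (Patefield sampling via `r2dtable`), recomputes the Pearson
statistic *by its definition* for each draw (deliberately not sharing
code with the analytic route), and returns the add-one Monte-Carlo
p-value $(b+1)/(M+1)$. Margin-conditioned sampling, rather than
independent multinomial draws per column, matches the null the analytic
test conditions on. The suite requires analytic and permutation p-values
to agree within $3\sqrt{p(1-p)/M}$ on every packaged table.

## Bisulfite context calling

Bisulfite treatment converts unmethylated cytosines to uracil (read T);
methylated cytosines resist. Comparing a clone of converted DNA with the
unconverted reference calls each reference C: C→C methylated, C→T
unmethylated, anything else ambiguous. Contexts are assigned on the top
strand from the two downstream bases: CG, CHG, CHH (H ∈ {A,C,T});
cytosines whose window runs off the sequence end or contains an N are
undetermined. The reported percentage is
$100 \times \text{methylated} / \text{countable}$, per context and
overall, where countable excludes undetermined contexts and ambiguous
calls from numerator *and* denominator (both exclusions are reported, so
nothing disappears silently).

Design choices: comparison is gap-free on pre-aligned, equal-length
sequences — the data are cloned PCR amplicons of fixed loci, so indel
alignment would add a dependency without adding information; positions
are 0-based in programmatic output; conversion efficiency is not
estimated from the data (the simulator exposes it as a parameter so its
effect can be studied instead).

## What the simulator emulates — and what it does not

`simulate_msap()` draws a methylation state per locus and sample from a
state-probability vector, emits the deterministic digestion pattern of
that state, and flips each presence bit independently with probability
`band_noise`. Defaults are the study conditions the package targets:
the state probabilities default to the high-chill dormant-bud profile
(scored fractions 444/610, 33/610, 0, 50/610, 83/610 over U, HM_ext,
HM_int, FM_int, X) and `band_noise` defaults to 0 because no technical
replicate concordance is available to calibrate an error rate. Noise is
symmetric and independent per lane — the simplest model that exposes
scorer robustness; real gel artefacts (co-migration, intensity
thresholds, lane-wide failures) are correlated and are *not* modelled,
so passing recovery tests demonstrates arithmetic correctness of the
scoring chain, not robustness to real gel pathology. One master seed
governs everything, with per-sample substreams derived from it so adding
samples never perturbs existing draws.

`simulate_bisulfite()` generates a random reference (default 300 bp,
matching the 62–307 bp range of cloned MSAP amplicons; GC 0.45), flags
each classifiable cytosine methylated with its context's probability
(defaults CG 0.8, CHG 0.3, CHH 0.05 — the usual plant gene-body ordering
CG > CHG > CHH), and emits clones in which unmethylated Cs convert with
probability `conversion` (default 1.0). All clones share one truth, as
clones of one molecule population do; per-context estimates therefore
converge to the realised truth fractions, which are binomial around the
injected probabilities — the tolerance the recovery tests use.

## Numerical and reporting conventions

* Percent identities are exact in floating point (single divisions);
  tests assert them on random count vectors.
* Chi-square p-values use the exact distribution function
  (`pchisq(..., lower.tail = FALSE)`), cross-checked in the tests against
  numerical integration of the density.
* Degenerate inputs fail loudly: empty summaries, zero countable
  cytosines, comparisons of a sample with itself, tables with fewer than
  two informative margins, probability vectors that do not sum to 1
  (tolerance 1e-9).
* `run_pipeline()` validates every input and comparison pair before
  writing any file, writes rendered TSVs at reporting precision plus a
  JSON report at full precision, and records input MD5 checksums, seed
  and package version so every number is recomputable from its
  provenance block. Repeated runs are byte-identical.

## Problem sizes used in the test suite

The suite exercises exact recovery on a 10,000-locus noise-free
simulation, bit-flip confusion on 10,000 loci at noise 0.1, permutation
agreement with 10,000 margin-preserving draws per table, and bisulfite
recovery on 200 clones of a 2,000 bp locus — sizes at which the binomial
tolerances are tight enough to be meaningful while the whole suite runs
in seconds.
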