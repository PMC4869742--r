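---
title: "Differential correlation networks: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential correlation networks: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcornet)
```

## The problem

Co-expression-style network methods (WGCNA and relatives) assume one
correlation structure for the whole data set and let treatments move only
the means. In designed metabolomics experiments that assumption can fail
outright: the coupling between two metabolites — say citrate and malate —
may itself depend on genotype or on the agroecosystem the plant grew in.
dcornet works on this *second moment* directly. It partitions the samples
of a designed experiment into two contrasting subsets, computes every
metabolite pair's Pearson correlation separately in each subset, and keeps
the pairs whose correlation *changed*. The result is a differential
correlation network: an edge means "this association responded to the
contrast", not "these metabolites are correlated".

## The statistical model

For a pair with sample correlations $r_A$ (on $n_A$ samples) and $r_B$
(on $n_B$ samples) in two disjoint subsets, the Fisher transformation
$z = \operatorname{atanh}(r)$ makes the sampling distribution of each
estimate approximately normal with variance $1/(n-3)$. The test statistic
for "no change in correlation" is

$$ q = \frac{z_B - z_A}{\sqrt{\dfrac{1}{n_A-3} + \dfrac{1}{n_B-3}}}, \qquad
   p = 2\,(1 - \Phi(|q|)), $$

a two-tailed normal test. `correlation_change_test()` implements exactly
this closed form; there is no simulation or resampling in the test itself.
The approximation needs $n > 3$ per subset and $|r| < 1$; both are enforced
upstream (see *Degenerate pairs* below).

Assumptions worth keeping in mind:

* samples within a subset are treated as independent draws — replicate,
  year and fruit-stage structure is pooled, not modelled;
* the two subsets are independent (they contain disjoint samples);
* the normal approximation for $z$ is a large-sample one; at the subset
  sizes of a typical field trial (50–250 samples) it is accurate.

The *pair tests within one partition are not independent of each other*
(two pairs can share a metabolite), so the count of significant edges in
one network fluctuates more than a binomial at $\alpha$ would suggest,
even under a global null. That is a property of the testing family, not a
miscalibration of the per-pair test; the test suite checks per-pair
calibration on independent pairs.

## Multiplicity

The default keeps the traditional per-pair $P < 0.05$, which is liberal
and deliberately exploratory; `multiplicity = "bh"` switches to
Benjamini–Hochberg adjustment for users who want FDR control. BH can only
shrink the edge set relative to the raw threshold.

## Partitions

Five built-in `partition_scheme`s encode the contrasts of the tomato study
the package models (`builtin_partitions()`): low (genotypes 2, 5, 12)
versus high (4, 8, 10, 20) polyamine fruit; methyl-jasmonate-deficient
(12, 20) versus normal (2, 4, 5, 8, 10); bare soil + black polyethylene
versus hairy vetch + rye mulches; and black plastic versus hairy vetch
nested within each polyamine class. Subset A is always the reference
("from") side, so `direction = "increase"` means the correlation rose from
A to B. Partitions pool every factor they do not split on; in particular
the bare-soil treatment exists in only one year and no year adjustment is
made — a subset simply contains whatever samples match its rule. The
factor registry is extensible through the load schema, but the built-in
schemes require the study's genotype and mulch codes and fail loudly on
anything else.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | two-tailed per-pair significance level |
| `multiplicity` | `"none"` | `"bh"` for Benjamini–Hochberg FDR |
| `n_min` | 4 | minimum pairwise-complete n per pair (the test needs n > 3) |
| `w_min`, `w_max` | 1, 7 | display widths at the \|Δr\| = 0.1 and 0.7 anchors |
| `threshold` | 0.19 | strict sd_z bound defining a "stable" association |
| `min_subsets` | 3 | subsets a pair must be usable in to be stability-scored |

Edge width is a linear, clamped map of $|\Delta r|$ between the 0.1 and
0.7 anchors; only those two anchor points are meaningful, the 1–7 range is
an arbitrary display choice. Edge color follows blue = increase,
red = decrease; `swap_colors` flips the convention for users who prefer
the opposite reading (both conventions circulate for this figure style).

## Missing data and degenerate pairs

Correlations use pairwise-complete observations, and each pair's own $n$
is carried into the test, so a cell missing in one metabolite does not
discard the sample for other pairs. Pairs are excluded — with a recorded
reason, not silently — when $n < n_\text{min}$, when either member has
zero variance on the pairwise-complete subset, or when $|r| = 1$.
Saturated pairs stay visible in the `correlation_set` but get no $z$:
clamping $|r| = 1$ to some $1-\epsilon$ would manufacture an arbitrary
$z$ magnitude, so we refuse to test such pairs instead. Correlations are
computed on raw concentrations; Pearson $r$ is invariant to positive
affine rescaling, so standardizing first would change nothing.

Per-metabolite standardization (`standardize()`) exists for the *mean*
summaries (`group_standardized_means()`), where equal weighting across
metabolites on different concentration scales is the point. The SD uses
the sample ($n-1$) denominator throughout the package.

## Stability across partitions

A pair's stability is the sample SD of its $z$ values across the six
subsets of the three main partitions (both polyamine classes, both meJAS
classes, both mulch classes). The nested mulch-within-polyamine schemes
are excluded from this set so that no stratum of samples is counted
twice; the subset list is an argument, so other choices are possible. Two
conventions are fixed and documented because with only six values they
matter (about 10% each): the SD uses the $n-1$ denominator, and the
companion average is taken on the $r$ scale (the SD is on the $z$ scale).
The five-color binning is: bin 1 (most stable) strictly below 0.19, bin 5
(least stable) strictly above 0.35, and the interior split into three
equal-width bins of [0.19, 0.35] with interior boundaries assigned to the
lower bin. The outer thresholds are the meaningful ones; the interior
edges are unspecified by the convention this reproduces, and equal thirds
were chosen for determinism. Stable-association counts use a strict
`sd_z < threshold` inequality.

A per-subset correlation listing produced elsewhere (for example a
transcribed supplement with columns subset, metabolite_i, metabolite_j,
r, n) can be ingested with `read_correlation_sets()` and fed to the same
differential and stability machinery, so published correlation tables can
be re-analyzed without the raw samples.

## The synthetic generator

`synthetic_spec()` + `simulate_table()` provide ground truth for every
downstream stage. The default spec emulates the structure of the field
study: 31 metabolite codes (30 characterized, in amino acid / organic
acid / sugar / energy / other groups, plus the uncharacterized "B" that
the analysis excludes); genotypes 4, 5, 8, 10, 12, 20 under BP, HV and RY
mulch in year one; genotype 2 and the bare-soil treatment added in year
two; four field replications; pink and red fruit stages (368 samples).
Concentrations are multivariate normal around mean 100, SD 20 (arbitrary
NMR-style units), with compound-symmetric group blocks (r = 0.4 within a
chemical group, 0.1 between) as the base correlation, and 2% of cells
missing completely at random — a realistic fraction for NMR
quantification tables. A log-normal option exists because concentrations
are non-negative, with moments matched on the original scale; planted
correlations then hold on the log scale, so analytic checks run on the
Gaussian path.

Planted changes overwrite one pair's correlation per subset of a named
partition; the per-sample matrix is repaired to positive
semi-definiteness by eigenvalue clipping and rescaling to unit diagonal
(`nearest_correlation_repair()` — a one-step clip, not the full
alternating-projections nearest-matrix iteration, which is unnecessary at
these dimensions) and samples are drawn through the symmetric matrix
square root. One `set.seed()` stream drives the draw in canonical sample
order, so a spec plus seed reproduces a table bit for bit. A per-column
counter-based stream (so that adding a metabolite leaves earlier columns
untouched) was considered and rejected: with correlated draws the mixing
matrix changes whenever the roster does, so the property it promises
cannot hold anyway.

What the generator does *not* emulate: NMR peak fitting and quantification
error, informative (non-MCAR) missingness, year/block/stage random
effects, and non-Gaussian concentration distributions on the default
path. Passing tests therefore show the machinery is correct under the
stated sampling model, not that field data meet that model.

## Determinism and numerical choices

Samples are sorted by id inside `pairwise_correlations()` and pairs by
alphabetical code order everywhere, so pipeline outputs are byte-identical
across re-runs and across row/column permutations of the input file —
not merely equal to floating-point tolerance. All randomness enters
through the generator's seed; the analysis stages are deterministic.
Saturation is detected at $|r| \ge 1 - 10^{-12}$; symmetry of user
matrices is checked at $10^{-10}$; the PSD repair clips eigenvalues below
$10^{-8}$.

The verification suite works at deliberately chosen problem sizes:
closed-form identities at hand-computable inputs; null calibration with
2,000 independent pair tests at n = 40 per subset; power at 1,000
replicates against the closed-form normal approximation (≈ 0.971 at
ρ 0.2 → 0.8, n = 40); planted-edge recovery on 20 metabolites with three
planted |Δρ| = 0.6 changes at n = 100 per subset; and stability against
the Fisher sampling SD $\sqrt{1/(n-3)}$ with six independent subsets of
n = 200. These sizes give Monte-Carlo error small enough for 3-standard-
error bands while keeping the whole suite fast. Note that at six subsets
the expected *sample SD* sits a few percent below the asymptotic sampling
SD (the usual small-sample bias of the SD estimator); the 3-SE band
accommodates this.

## Known limitations

* The change test compares two independent subsets; it does not model
  overlap, repeated measures, or more than two groups at once.
* Stability over six subsets of the *same* samples (three partitions of
  one data set) mixes sampling correlation into the SD; the package
  follows that convention because it is what the heat-map construction
  calls for, but the six values are not independent estimates.
* No graph layout or rendering: networks are exported as edge CSV /
  GraphML for Cytoscape.
* Partial correlations, robust/rank correlations and Gaussian graphical
  models are out of scope.

## A minimal worked run

```{r example, eval = FALSE}
spec <- synthetic_spec(seed = 1, changes = list(
  planted_change("CIT", "MAL", 0.1, 0.8, "polyamine")))
tab <- simulate_table(spec)
cs <- partition_correlations(tab, "polyamine")
net <- build_differential_network(cs$A, cs$B, partition = "polyamine")
net
head(net$edges[order(net$edges$p), ])
map <- stability_from_table(tab)
head(stable_association_counts(map))
```
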