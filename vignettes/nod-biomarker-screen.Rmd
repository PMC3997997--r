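---
title: "Methods: the NOD-based miRNA biomarker screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the NOD-based miRNA biomarker screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirnod)
```

## The model

A miRNA–mRNA interaction network is a bipartite graph from regulators
(miRNAs) to targets (genes). Most network statistics treat all targeting
equally; the statistic at the centre of this package does not. The **novel
out degree** of miRNA $m$,

$$\mathrm{NOD}(m) \;=\; \bigl|\{\, g : \mathrm{regulators}(g) = \{m\} \,\}\bigr|,$$

counts only the genes that $m$ targets *exclusively*. It measures
independent regulation power: a perturbation of a high-NOD miRNA propagates
to a set of genes no other miRNA can compensate for, which is why high-NOD
miRNAs are plausible, robust disease biomarkers. Two structural facts make
NOD pleasant to work with, and both are asserted on every synthetic build in
the test suite: exclusive-target sets are pairwise disjoint across miRNAs,
and $\sum_m \mathrm{NOD}(m)$ equals the number of single-regulator genes in
the database.

The screen combines this network evidence with expression evidence:

1. build the union interaction database;
2. select differentially expressed miRNAs (t-test + fold change);
3. rank the selection by NOD and keep the miRNAs whose NOD significantly
   exceeds the population median level;
4. quantify each retained candidate's diagnostic value by ROC/AUC;
5. characterize the candidates' exclusive targets by gene-set enrichment and
   one-hop protein-interaction subnetworks.

## Union interaction database

Experimentally validated target pairs are trusted as-is; computationally
predicted pairs must occur in at least `min_predicted_support = 2`
**distinct** prediction sources ("distinct" means distinct source names, not
distinct rows). Both readings of a mixed pair were defensible; we include a
pair carried by one validated and one predicted source, because validated
evidence suffices alone, and the provenance string keeps both. Identifiers
are joined lexically — miRNA names lower-cased, gene symbols upper-cased, no
alias resolution, mature-arm/star variants kept distinct — so the merge is
deterministic and needs no external identifier service. The consequence,
verified by property tests, is that raising the support threshold can only
shrink the edge set, and deleting all predicted tables leaves exactly the
union of the validated ones.

## Differential expression

The test is the classic pooled-variance two-sided Student t-test
(deliberately not Welch), at raw $P < 0.05$ with no multiple-testing
correction by default — this is a hypothesis-generating screen whose
downstream stages (NOD significance, ROC) provide orthogonal filtering; a
BH-adjusted column is always written and `adjust = "BH"` switches the
candidate flag to it.

Two scale decisions matter:

* **The t-test runs on $\log_2$ intensities** (`log_transform = TRUE`).
  Microarray intensities are positive and right-skewed with roughly
  multiplicative noise; on the log scale the noise model is approximately
  normal and the t-test is well calibrated — the suite checks that the
  fraction of null rows with $p < 0.05$ lies within binomial 99% bounds of
  0.05 over 200 null matrices. On the linear scale the same test would be
  mildly conservative. Data already on a log or signed scale should set
  `log_transform = FALSE`.
* **Fold change is reported on linear-scale group means** with the signed
  convention: $\mathrm{FC} = \bar{x}_{case}/\bar{x}_{ctrl}$ when the case
  mean is larger, and $-\,\bar{x}_{ctrl}/\bar{x}_{case}$ otherwise, so a
  halving prints as $-2$ and the filter is $|\mathrm{FC}| \ge 2$. This keeps
  down-regulation visible in the report without a separate direction column.

Degenerate rows are never dropped silently: zero pooled variance with equal
means gives $t=0, p=1$; with unequal means $t=\pm\infty, p=0$; both are
flagged in a `zero_variance` column.

## NOD significance

The statement "the NOD of an individual miRNA is significantly greater than
the median level" is underspecified for a single observation — no location
test applies to one number. The adopted construction, flagged prominently
here because it is an interpretation: a one-sided Wilcoxon signed-rank test
on the paired differences $d_j = \mathrm{NOD}(m) - \mathrm{NOD}(j)$ over all
other miRNAs $j$. Under ties-free data this reduces to a percentile test of
the focal value's position, and it reproduces the qualitative pattern one
expects (large NOD $\to$ tiny $P$, monotonically — a property test asserts
that raising the focal NOD never raises $P$).

Numerical conventions: zero differences are dropped (Wilcoxon's convention);
with $\le 25$ non-zero, ties-free differences the exact signed-rank null is
used (`psignrank`), otherwise a normal approximation with the standard tie
correction $\sum(t^3-t)/48$ and a 0.5 continuity correction; if every
difference is zero the test is uninformative and returns $p = 0.5$. The
exact branch is validated against full $2^n$ sign-enumeration, the
approximate branch against `wilcox.test` and against enumeration.

The reference population is a choice the source phrasing leaves genuinely
open ("all miRNAs in the database" vs "all these candidate miRNAs"). The
default is **all miRNAs in the database** — the population the NOD statistic
is defined on — with `reference = "candidates"` available; both are
exercised in tests. Group-level comparisons (e.g. known biomarkers vs all
miRNAs) use the two-sample Kolmogorov–Smirnov test plus medians for boxplot
reporting.

## ROC and AUC

AUC is computed by the Mann–Whitney identity with half-credit ties and is
checked against exhaustive enumeration of all case × control pairs, and
against the trapezoidal area of the threshold curve, to $10^{-12}$. Because
a diagnostic marker can be informative in either direction, each miRNA is
**oriented by its fold-change sign**: scores of down-regulated miRNAs are
negated (recorded as `orientation = "flipped"`), so AUC reads as
discriminatory accuracy and a strong down-regulated marker scores near 1,
not near 0. Confidence intervals default to the classical Hanley–McNeil
standard error, truncated to $[0,1]$; `method = "delong"` gives the DeLong
placement-variance interval (cross-checked against pROC in the suite). With
8 + 8 samples these intervals are wide — the AUC point values, not the
intervals, drive the report.

## Enrichment

Gene sets come from GMT files. The universe defaults to the union of all
collection genes — the annotated-universe convention — and can be overridden
(e.g. with the interaction database's gene namespace); query genes outside
the universe are dropped from the draw and counted in a warning. Per set,
the upper-tail hypergeometric probability $P(X \ge \text{overlap})$ is
computed with `phyper` and verified against exact enumeration of all draws
for universes up to 12. Because candidates' exclusive-target sets are
disjoint, the pooled query's size is exactly the sum of the retained NODs —
a useful cross-check that the report prints.

## Protein-interaction subnetworks

For each candidate: $N_0$ = exclusive targets present in the PPI graph,
$N_1$ = their direct neighbors minus $N_0$, $N_2 = |N_0| + |N_1|$. The
exported subnetwork is a pure one-hop star expansion — PPI edges with at
least one endpoint in $N_0$ — because $N_1$ is defined by direct connection
to $N_0$; `include_n1_edges = TRUE` additionally keeps $N_1$–$N_1$ edges for
denser visualization. Gene identifiers must match the interaction database
verbatim; there is no mapping service, and misses simply reduce $N_0$.

## What the synthetic generator emulates — and what it does not

`sim_bundle()` writes a complete input bundle whose default dimensions
mirror a small clinical microarray study: a 641-miRNA × 7706-gene union
network at mean out-degree 51 emitted as 3 validated + 3 predicted source
tables (plus 200 single-source decoy predictions that the union rule must
reject), a 556 × 16 expression matrix (8 case / 8 control), a PPI graph over
the network's genes, and two 50-set GMT collections. Ten planted biomarkers
receive distinct exclusive-target boosts (60 down to 15, so their NOD rank
order is unambiguous) and 4-fold expression effects in alternating
directions; shared genes are guaranteed a second regulator, so each miRNA's
planted NOD is exactly its private-gene count and `compute_nod` must agree
with the generator's bookkeeping integer-for-integer.

Baseline intensities are log-normal (meanlog $\log 100$, sdlog 1) with
multiplicative log-normal noise, sd 0.5 on the log scale — a noise level at
which an 8-vs-8 t-test detects 4-fold effects reliably but 2-fold chance
fluctuations of group means are rare, which a scientist would call a
realistic microarray regime. The generator does **not** emulate probe
effects, batch effects, inter-sample correlation, normalization artifacts,
or sequence-driven target structure; passing tests therefore demonstrate the
correctness and calibration of the statistics on clean inputs, not
robustness to real-array pathology. Every generator takes a single integer
seed; the bundle derives one stream per artifact and records the seeds in
`truth.json`, so fixtures are bit-reproducible.

## Problem sizes

The test suite exercises small instances by choice — networks of 10–60
miRNAs, expression matrices of 50–200 rows, 20-seed oracle sweeps, a
200-matrix null calibration with 100 rows each, and a 200-miRNA × 2500-gene
end-to-end recovery run — sizes at which brute-force oracles (full
enumeration of signed-rank nulls, hypergeometric draws and case/control
pairs) are feasible and the whole suite runs in well under a minute. The
acceptance script runs the study-scale bundle (641 × 7706, 556 × 16), which
completes in seconds.

## Known limitations

* The NOD significance test is an interpretation of an underspecified
  procedure; its absolute $P$ values should be read as a ranking device, not
  as calibrated tail probabilities for single miRNAs.
* Raw (uncorrected) $P$ thresholds are the default at every stage by design;
  users screening large candidate sets should switch on the BH options.
* ROC is evaluated in-sample on the same 8 + 8 cohort used for selection, so
  AUCs are optimistic; there is no cross-validation, mirroring the
  single-marker, small-cohort setting the screen targets.
* Identifier joins are lexical; data mixing symbol conventions (aliases,
  probe ids) must be harmonized upstream.
* The union database treats all validated sources as equally reliable and
  all predictions as exchangeable votes.
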