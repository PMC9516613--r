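---
title: "Harmonizing dental caries phenotypes across heterogeneous cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing dental caries phenotypes across heterogeneous cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cariesharm)
```

## The problem

Consortium-scale genetic studies of dental caries must combine cohorts
whose clinical examinations differ in depth: some record only whether a
participant has any caries experience, others record the cumulative
DMFT/DMFS indices, and a subset records the status of every individual
tooth surface. `cariesharm` implements a three-tiered harmonization of
these data:

1. **Binary case status** — any decayed, missing or filled tooth or
   surface (DMFT/DMFS > 0). Available everywhere; maximizes sample
   size.
2. **Severity** — the quantitative tooth-morbidity indices. Teeth
   missing due to *all* causes are counted in the M component, because
   cause of loss is rarely recorded and tooth loss is itself an
   endpoint of the disease process.
3. **Precision patterns** — per-subject scores on five predefined
   clusters of tooth surfaces with shared caries susceptibility
   (e.g. molar pits and fissures versus smooth surfaces), which carry
   subtype information a crude index discards.

## The odontogram data model

All computation rests on a fixed surface universe: the 28 permanent
index teeth (third molars excluded) in FDI two-digit notation, with
4 surfaces (M, D, B, L) on anterior teeth and 5 (adding O) on
posterior teeth — 128 surfaces in total. Incisal edges are not separate
surfaces; this is the standard DMFS convention. Each surface carries
one of five statuses: `SOUND`, `DECAYED`, `FILLED`, `MISSING_TOOTH`
(uniform across a tooth — no tooth is partly missing), or `EXCLUDED`
for unerupted/unscorable surfaces.

Design choices worth stating explicitly:

* **ICDAS thresholding.** Cohorts grading lesions on the ICDAS 0–6
  scale are harmonized at the moderate-lesion threshold (ICDAS ≥ 3
  maps to `DECAYED`); the threshold is a loader argument, and raising
  it can only decrease the number of decayed surfaces.
* **Unlisted surfaces.** The loader's default policy is to *error* on
  surfaces with no row, forcing an explicit cohort-level decision;
  `sound` supports compact exports that list only affected surfaces,
  `excluded` supports partial examinations. Silent imputation hides
  data problems.
* **Third molars** appear in raw exports, so their rows are accepted
  and dropped (with a logged count) rather than rejected.
* **EXCLUDED semantics.** How unerupted or unscorable surfaces were
  handled in contributing cohorts is generally not documented, so the
  choice here is the package's own: excluded surfaces are never counted
  as affected and the index denominators stay fixed at 128/28, keeping
  indices comparable across subjects at the cost of a conservative
  bias for subjects with many unscorable surfaces.
* **Mixed-status teeth** (decayed and filled surfaces on one tooth)
  classify the tooth as decayed for DMFT, the usual epidemiologic
  precedence (MISSING > DECAYED > FILLED).

## Cluster scores

A cluster map is a partition of the 128 surfaces into five named
groups. A subject's score on cluster *c* is the number of affected
(decayed/filled/missing) surfaces in *c* divided by the fixed cluster
size, so scores live in [0, 1] and satisfy an exact decomposition:
the size-weighted sum of a subject's five scores equals their DMFS.
The denominator is the fixed cluster size rather than the per-person
count of scorable surfaces — the literal reading of
"cluster-specific DMFS divided by the number of tooth surfaces in the
cluster" — which keeps scores comparable but means edentulous subjects
score 1.0 on every cluster.

The builtin default map is *provisional*: the exact published
surface-to-cluster assignment is not reproduced in any source available
to this package, so the default is constructed from the published
cluster names (cluster sizes 16, 24, 48, 16, 24):

```{r odontogram}
render_odontogram(default_cluster_map())
```

Any published 128-row assignment can be dropped in via
`read_cluster_map()` without code change, and every downstream
computation validates the partition property (each surface exactly
once, no empty cluster).

## Re-deriving clusters from data

`derive_clusters()` checks that a cluster structure is *recoverable*:
it clusters the 128 surface columns of a binary affection matrix by
agglomerative clustering with distance 1 − Pearson correlation and
Ward linkage, cutting at *k* = 5. The original derivation's metric and
linkage are not documented, so these defaults are declared, not
inferred: correlation distance groups surfaces by *pattern* of
co-affection rather than raw prevalence, which matches the scientific
intent. Zero-variance columns carry no correlation signal and are
assigned to their Hamming-nearest informative neighbour; edentulous
subjects (constant rows) are dropped by default.

## The synthetic-cohort generator

No participant-level data can ship with the package, so every
statistical property is exercised on synthetic cohorts with known
ground truth. For subject *i* with age \(a_i\) and frailty
\(u_i \sim N(0, \sigma^2)\):

* each tooth is missing with probability
  \(\mathrm{logit}^{-1}(m_0 + m_1 a_i + u_i)\);
* each surface in cluster *c* of a remaining tooth is affected with
  probability \(\mathrm{logit}^{-1}(\alpha_c + \beta a_i + u_i)\),
  split 50/50 between decayed and filled (the indices treat D and F
  identically, so the split only exercises bookkeeping).

This is the minimal model inducing the two dependencies the analyses
assume: within-person correlation across surfaces (via the shared
frailty, which also links caries to tooth loss) and an age trend
shared across clusters. Defaults describe a middle-aged adult cohort:
age 50 ± 15 years (truncated to 18–100), cluster baselines giving
affection probabilities of roughly 0.55, 0.07, 0.40, 0.25, 0.24 at age
50 (molar pits-and-fissures highest, lower anterior teeth lowest,
matching the ordering reported across real cohorts), age slope 0.035
log-odds/year (chosen so that scores roughly double across the 23–74
year span of cohort mean ages), frailty SD 1.5 (reproducing the heavy
overdispersion visible in published cluster-score SDs), and a
tooth-loss process giving ~10% missing teeth at age 50.

What the generator does *not* emulate: examiner effects, half-mouth
or photograph-based protocols, secular cohort effects, genetic
structure, and cluster-specific age slopes. Passing tests therefore
demonstrate the *machinery* is correct under the stated model, not
that real cohorts satisfy that model.

The strong-separation regime used for cluster-recovery validation
spreads the cluster baselines widely (logits 6, −6, 0, −3, 3) with
frailty SD 3: because the logistic squashes different frailty ranges
for different baselines, between-cluster correlations collapse while
within-cluster correlations stay high, giving a regime where a correct
implementation should recover the generating partition essentially
perfectly (observed median adjusted Rand index 1.0 over 20 replicates
at n = 500).

## Meta-regression of cohort summaries on age

Cohort-level cluster means are regressed on cohort mean age by
fixed-effect weighted least squares. The phrase "inverse standard
error weighted" is ambiguous between weights \(1/\mathrm{SE}^2\) and
\(1/\mathrm{SE}\); the package defaults to inverse-variance weighting
(the standard meta-regression estimator) and offers the literal
`inverse_se` scheme as an option. Coefficient standard errors treat
the per-cohort SEs as known: under inverse-variance weights the
covariance is \((X'WX)^{-1}\); under other weight schemes the sandwich
form \((X'WX)^{-1} X'WVWX (X'WX)^{-1}\) with \(V = \mathrm{diag(SE^2)}\)
is used, which reduces to the former when \(W = V^{-1}\). No
between-cohort heterogeneity variance is estimated — the model is the
simple weighted linear fit, not a random-effects meta-regression.

## Power calculations

All association tests are treated as 1-df chi-square tests; power is
the upper-tail probability of the noncentral chi-square beyond the
central upper-\(\alpha\) quantile. Conventions fixed here:

* **Quantitative traits.** A variant explaining fraction *q* of trait
  variance in *n* samples has \(\mathrm{ncp} = n\,q/(1-q)\) — exact
  for the chi-square limit of the marginal test; at \(q \sim 10^{-4}\)
  the difference from \(nq\) is negligible but the convention must be
  fixed. The minimal detectable *q* at a target power is found by
  monotone root-finding on the log scale (relative tolerance 1e−8),
  and plugging the result back reproduces the target power to 1e−6.
* **Binary traits.** The allelic trend (score) test under
  Hardy–Weinberg equilibrium:
  \(\mathrm{ncp} = (\ln \mathrm{OR})^2 \, 2p(1-p)\,
  n_1 n_0/(n_1+n_0)\). This population-frequency approximation is
  accurate to a few percent of power at modest odds ratios; the test
  suite quantifies the agreement against a retrospective logistic
  simulation.
* **Significance threshold.** Genome-wide \(\alpha = 5\times10^{-8}\)
  by default (the universal GWAS convention), exposed as an argument.
  At \(n = 486{,}514\) (the severity-tier sample), 80% power at this
  threshold corresponds to variants explaining ≈ 0.008% of trait
  variance.

## Problem sizes used in validation

The validation suite runs at desk scale by design: Monte-Carlo power
oracles use 20,000 replicates at n = 500 (quantitative) and
1,000 + 1,000 (binary); cluster recovery uses 20 replicates of n = 500
cohorts; meta-regression coverage uses 200 replicates of 20 cohorts;
moment-matching checks use n = 2,000. These sizes put Monte-Carlo error
well below the effects being checked while keeping the full suite fast.

## Known limitations

* The default cluster map is a reconstruction from published cluster
  names, not the published assignment itself; analyses of real data
  should load the authoritative map.
* Fixed denominators mean partially erupted dentitions are scored
  conservatively; a per-person-denominator variant is deliberately not
  implemented to keep cross-subject comparability.
* Published per-cluster summary statistics of real cohorts cannot be
  reproduced without participant-level data; the registry module
  checks only the arithmetic that the printed tables themselves
  determine (totals, pooled fractions, prevalence recomputation). One
  printed cell (a cluster SD of 0.46 at mean 0.24) exceeds the maximum
  SD possible for a fixed-denominator proportion with that mean, which
  suggests a per-person denominator or a typographic issue in the
  source; no attempt is made to reproduce it.
* The meta-regression is fixed-effect; with strong between-cohort
  heterogeneity its CI is anti-conservative.
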