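---
title: "Estimating binary symptom networks with symptomnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating binary symptom networks with symptomnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symptomnet)
```

## The problem and the model

Informant-rated inventories such as the 12-item NPI-Q record, for each
participant, whether each of twelve neuropsychiatric symptoms was
present in the last month. Symptom networks ask a different question
than prevalence tables: which symptoms are conditionally associated
once all the others are held fixed, and which symptoms are most central
to that web of associations.

`symptomnet` models a vector of binary endorsements
$x \in \{0,1\}^p$ with the Ising model

$$P(x) \;\propto\; \exp\Big(\textstyle\sum_i \tau_i x_i +
\sum_{i<j} \Omega_{ij} x_i x_j\Big),$$

a pairwise Markov random field in which $\tau_i$ is item $i$'s
threshold (its disposition to be present absent any influence from
other symptoms, on the log-odds scale) and $\Omega_{ij}$ the pairwise
coupling. The $\{0,1\}$ coding is used throughout, matching the data;
under it each full conditional is a logistic regression,
$\mathrm{logit}\,P(x_j = 1 \mid x_{-j}) = \tau_j + \sum_k \Omega_{jk} x_k$,
which is what makes nodewise logistic estimation consistent for this
joint. The model assumes the sample is i.i.d. and that dependencies are
pairwise; it does not model severity, time, or informant effects.

## Network estimation (eLasso)

`estimate_network()` fits, for each item $j$, an L1-penalized logistic
regression of $x_j$ on the raw 0/1 columns of all other items:

$$\hat b_j(\lambda) \;=\; \arg\min_b \;-\tfrac1n \ell(b) +
\lambda \lVert b_{-0} \rVert_1,$$

with an unpenalized intercept. Design choices, each exposed as an
argument:

* **Penalty path.** 100 values, log-spaced from
  $\lambda_{\max} = \max_k |\sum_i x_{ik}(y_i - \bar y)|/n$ — the
  smallest penalty with an all-zero slope vector, by the KKT condition
  at the intercept-only fit — down to $0.01\,\lambda_{\max}$, with warm
  starts along the path.
* **No predictor standardization.** All predictors are 0/1 on a common
  scale; standardizing would silently reweight the penalty by item
  prevalence and change the interpretation of $\lambda$.
* **Model selection.** The Extended Bayesian Information Criterion,
  $\mathrm{EBIC} = -2\ell + k \ln n + 2\gamma k \ln p$, evaluated at
  every path point and minimized, with $\gamma = 0.25$ as recommended
  for binary networks. Two documented conventions: $k$ counts nonzero
  slopes only (the always-present intercept carries no penalty, which
  keeps the null model comparable across nodes), and $\ell$ is the
  *unpenalized* log-likelihood evaluated at the penalized estimate.
  Exact ties in the criterion break toward the larger penalty, i.e. the
  sparser model.
* **Edge rule and weights.** Under the default OR-rule the edge
  $(j,k)$ is retained when either $b_{jk}$ or $b_{kj}$ is nonzero;
  under the AND-rule, when both are. A retained edge's weight is the
  mean $(b_{jk}+b_{kj})/2$, including a zero member under OR, so the
  OR-rule network is always a supergraph of the AND-rule network from
  the same fits.
* **Degenerate items.** An item endorsed by everyone or no one has no
  conditional distribution to estimate; the node is flagged
  unestimable, isolated in the network (incident weights 0), listed in
  the result, and announced with a warning rather than an error —
  resampling procedures need estimation to survive such replicates.

### The solver

The penalized fits are computed by a coordinate-descent solver written
for this package (C++ via Rcpp): iteratively reweighted least squares
with cyclic coordinate descent on each working quadratic, in
"covariance mode" — with at most a dozen predictors the Gram matrix of
the weighted design is formed once per reweighting, making each
coordinate sweep $O(p^2)$ rather than $O(np)$. Because the predictors
are binary, duplicate $(x, y)$ rows are first collapsed into case
weights, an exact reformulation that caps the effective row count at
$2^p$ regardless of sample size.

Numerical conventions worth knowing:

* Convergence requires the largest parameter update in a reweighting
  cycle to fall below `tol` (default `1e-7`); a fit that exhausts its
  iteration budget is still accepted if its KKT violation is below
  `1e-6`, and otherwise errors with the achieved violation.
* At $\lambda \approx 0$ on separable data the likelihood has no
  finite optimum; the solver warns and returns coefficients capped by
  the iteration budget.
* A converged slope smaller than `1e-10` in absolute value is set to
  exactly zero. A coefficient sitting on the KKT boundary (most
  importantly at $\lambda_{\max}$) can otherwise surface as $\sim
  10^{-16}$ through summation-order noise, which would corrupt the
  model-size count $k$ and deny EBIC a genuine null model on the path —
  this materially degrades specificity under independence.

The test suite checks the solver against an independently implemented
Newton–Raphson optimizer at $\lambda = 0$ and against `glmnet` along
matched penalty paths.

## Centrality

Strength $s_i = \sum_j |W_{ij}|$ and expected influence
$EI_i = \sum_j W_{ij}$ coincide on all-positive networks and differ
only through negative edges. z-scores standardize each index across the
fixed set of $p$ nodes; the population (divide-by-$p$) standard
deviation is the default, since this is a descriptive rescaling of a
complete node set rather than an inference from a sample of nodes — the
sample-SD convention is available via `sd_type = "sample"`. Rank orders
are descending, with exact ties broken by item-label order. Constant
centrality vectors (e.g. an empty network) yield flagged zeros with a
warning rather than NaNs.

## Accuracy and stability machinery

Three bootstrap procedures, all re-running the full estimator with the
original settings on every replicate, all driven by replicate-indexed
seed substreams so results are reproducible and independent of
evaluation order:

* **Nonparametric bootstrap** (`nonparametric_bootstrap()`, default
  `B = 1000`): resamples participants with replacement;
  `edge_ci_table()` forms percentile confidence intervals (R's default
  type-7 quantiles) around each edge weight. Percentile rather than
  BCa intervals: regularized edge-weight distributions have a point
  mass at zero, where BCa's bias correction is unreliable.
* **Case-dropping bootstrap** (`case_dropping_bootstrap()`, default
  drop proportions 0.10–0.75 in steps of 0.05, `B = 250`): subsamples
  without replacement at each drop proportion and records the Pearson
  correlation (Spearman available) between full-sample and subsample
  strength, expected influence, and edge-weight vectors. Proportions
  leaving fewer than $3p$ rows are refused with a warning.
  `cs_coefficient()` then reports, per index, the largest drop
  proportion at which at least 95% of replicates keep a correlation of
  at least .70, with the conventional interpretive bands (above .50
  stable, below .25 untrustworthy). Replicates with degenerate
  (constant) estimates are kept with NA correlations, excluded
  pairwise, and surfaced as a failure rate.
* **Difference tests** (`difference_tests()`): percentile CIs of the
  replicate-wise difference for each pair of retained edges, strengths,
  or expected influences. A difference is significant when zero lies
  *outside* the interval — the conventional reading; descriptions of
  this procedure sometimes state the inverted rule, so the convention
  is fixed here explicitly. The returned table covers all ordered
  pairs; significance is symmetric and the diagonal non-significant by
  definition.

`B` defaults are package choices (the methodology literature states no
single value); both are arguments.

## The synthetic cohort generator

Real NPI-Q cohort data of the relevant scale are restricted-access, so
the package ships a generator whose presets stand in for them.
`make_preset("npiq_like")` builds a 12-item Ising model that emulates a
large memory-clinic cohort:

* The nine strong within- and between-domain couplings reported for
  such cohorts, e.g. delusions–hallucinations 1.51,
  agitation–irritability 1.31, elation–disinhibition 1.21,
  depression–anxiety 0.72. (A tenth reported edge with an ambiguous
  partner item is deliberately omitted rather than guessed.)
* All remaining pairs carry a small positive filler coupling of 0.15,
  except nine structural zeros, so that 57 of the 66 couplings are
  nonzero — the sparsity level reported for the emulated network. The
  zeros are placed on implausible cross-domain pairs: the rare elation
  item against the psychosis and affect items, and the
  psychosis–affect boundary (e.g. delusions–depression).
  Disinhibition ends up with the largest true absolute coupling sum,
  so centrality-recovery checks have a known answer.
* Thresholds are calibrated by fixed-point root-finding on the logit
  scale against the exact $2^{12}$ enumeration until every marginal is
  within 0.002 of its target; the four affect/behaviour targets are
  46.9% (depression), 46.2% (irritability), 46.1% (anxiety) and 45.8%
  (apathy), and the remaining eight (delusions 20%, hallucinations
  11%, agitation 38%, elation 6%, disinhibition 16%, motor disturbance
  14%, nighttime behaviours 25%, appetite 28%) are fixed at rates
  typical of memory-clinic samples. The intended sample size is
  n = 12,494.

Three further presets support testing: `independent` (all couplings
zero — the null for specificity checks), `two_cluster` (two internally
coupled blocks of four), and `dense_random` (signed couplings on every
pair, drawn once from a fixed stream, exercising negative edges).

Sampling is exact for $p \le 20$: the joint is enumerated in the log
domain and rows are drawn i.i.d. from the normalized distribution. For
larger models `sample_ising(..., method = "gibbs")` runs a single-site
Gibbs sampler over the logistic conditionals, with defaults of 200
burn-in sweeps and one retained row per 5 sweeps; both samplers are
seeded and agree with the enumeration within Monte-Carlo error in the
test suite.

**What the generator does not emulate.** Items are conditionally
exchangeable draws from a single stationary Ising model: there is no
informant bias, no severity or distress dimension, no cohort
heterogeneity (e.g. MCI vs dementia mixtures), no longitudinal
structure, and no missingness mechanism. Tests passing on these
presets therefore demonstrate that the estimation and stability
machinery is correct and well-calibrated for the model class, not that
the pipeline is robust to the measurement artifacts of real informant
data.

**A calibration fact worth stating plainly:** with 48 filler couplings
of 0.15 sitting near the EBIC detection threshold at this sample size
(coefficient sampling error is roughly 0.1), the Spearman rank
agreement between all 66 true couplings and their estimates plateaus
around 0.75–0.78 — the acceptance script reports this quantity as
`coupling_rank_correlation`. This is a property of the
generator-plus-scale, not of the estimator: an unpenalized nodewise fit
with no selection at all achieves the same range, because rank
agreement within the large near-tied filler group is limited by noise
rather than by shrinkage. Identification of the strongest edges, their
signs, and the centrality leader is stable across replicates.

## Cohort construction

`load_participant_table()` reads a CSV through a schema mapping (a
named vector or a JSON/YAML file) so that file column names never need
to match the pipeline's logical names, validates item codes against the
legal set, and preserves unknown/not-available codes rather than
coercing them. `apply_inclusion_filters()` applies the standard funnel
in a fixed, auditable order — cognitive status, etiology, minimum age,
then complete-case removal of rows with any missing-coded item,
followed by the minimum-symptom count — and returns the 0/1 matrix
together with a log of the remaining n after each step. Whether the
minimum-symptom criterion should precede or follow the missing-code
exclusion is not settled by convention; this package fixes
missing-first (the symptom count is only well defined on complete
items) and keeps both the codes treated as missing and every cutoff
configurable in `filter_config()`, since unknown/not-available codings
differ between form versions.

## Layout and reporting

`fruchterman_reingold()` implements the standard force-directed
iteration with absolute edge weights multiplying the attractive force
$|w|\,d^2/k$, all-pairs repulsion $k^2/d$, $k = \sqrt{area/p}$ with
unit area, seeded initial positions, and displacement capped by a
quadratically cooling temperature (initial value $0.1\sqrt{area}$) and
damped by the cooling fraction — the damping makes the layout settle
monotonically instead of oscillating around the energy optimum, and the
per-iteration energy trace (attractive $|w|d^3/3k$ minus repulsive
$k^2 \ln d$ over pairs) is attached to the result so that settling is
checkable. Plotting (`autoplot()`, `plot_centrality()`) is a thin layer
over the tested coordinate and table outputs.

`build_report()` consolidates the network summary, strongest edges,
centrality ranks, CS coefficients and the cohort funnel into one object
with Markdown and JSON renderings; the JSON round-trips byte-for-byte
through `report_from_json()`, and omitted optional sections are noted,
not errors. Networks additionally serialize to edge-list CSV and
GraphML (with layout coordinates as vertex attributes) for use in
external graph tools.

## Problem sizes used for verification

The test suite exercises the full study scale where the property being
checked demands it — network recovery and null specificity run at
n = 12,494 and n = 10,000 over 10 and 25 seeded replicates — and small
scales (n = 300–2,000, bootstrap B of 4–10) where the property is
exact by construction, such as fixture-based CS values, percentile
rules, and byte-identical pipeline determinism. The acceptance script
uses the full n = 12,494 with a case-dropping bootstrap of B = 25 over
six drop proportions; these sizes are the package's choices for a
convincing-yet-routine verification run, and all are arguments to the
underlying functions.

## Known limitations

* Only presence/absence is modelled; severity and distress ratings are
  out of scope, as are ordinal or Gaussian variants of the model.
* The estimator assumes i.i.d. rows; clustered or longitudinal
  sampling designs violate the bootstrap's exchangeability assumptions.
* Rank recovery across *all* coupling pairs degrades when many true
  couplings sit near the selection threshold (see the calibration note
  above); conclusions should rest on the strong-edge order and
  centrality leaders, whose stability the bootstrap machinery
  quantifies directly.
* Symptom clusters are a visual/annotation concern: no community
  detection is performed, by design.
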