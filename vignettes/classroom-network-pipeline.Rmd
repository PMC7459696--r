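---
title: "Methods: a four-stage pipeline for two-wave classroom friendship networks"
author: "classnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a four-stage pipeline for two-wave classroom friendship networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(classnet)
```

# The data model

`classnet` analyses sociometric panels: per classroom, a directed friendship
network at baseline (T0) and follow-up (T1) over the same children, plus a
node attribute table (sex, age, maternal education, household income, BMI
and BMI category, MVPA minutes/day, intervention group, and — for intervened
groups — binary satisfaction indicators). A directed tie (i, j) records that
child i nominated child j as a friend. Nominations are unlimited and elicited
with ranks (best friend = 1, ...), but the pipeline collapses them to
unweighted presence/absence: every stage below is defined on binary directed
ties. Self-nominations are rejected, repeated nominations are deduplicated,
and a panel only contains children observed at both waves; edges naming
off-roster children are dropped with a logged count rather than silently.

Per-node cohesion metrics (`node_metrics()`) follow the conventional
sociometric definitions: in-degree, out-degree, degree (their sum), the local
clustering coefficient, and closeness centrality. Two conventions deserve
explicit statement because the literature varies:

* **Clustering** is computed on the undirected reduction (a tie in either
  direction makes two children "friends"): the coefficient is the fraction
  of a child's neighbour pairs that are themselves tied, 0 when the child
  has fewer than two neighbours.
* **Closeness** uses directed shortest paths. Classroom digraphs are
  routinely disconnected, where mean shortest distance is undefined, so the
  default is the Wasserman–Faust correction
  $C(i) = \frac{r_i}{n-1}\cdot\frac{r_i}{\sum_{j\in R(i)} d(i,j)}$
  with $R(i)$ the set of $r_i$ nodes reachable from $i$ (0 when $r_i = 0$).
  Harmonic closeness is available as an alternative
  (`closeness = "harmonic"`); whether paths should instead be symmetrized is
  genuinely open, and we default to directed paths since nomination
  direction is informative. Every report records the conventions in force.

# Stage 1 — tie turnover (Jaccard index)

Writing $E_{11}$ for ties present at both waves, $E_{10}$ for dissolved and
$E_{01}$ for newly formed ties, the turnover index is

$$J = \frac{E_{11}}{E_{10} + E_{01} + E_{11}},$$

equivalently the Jaccard similarity of the two tie sets. $J < 0.3$ indicates
dissolution-dominated change, $J > 0.6$ formation-dominated change, and the
closed band $[0.3, 0.6]$ a meaningful but analyzable amount of turnover —
the regime in which fitting temporal network models to the transition is
considered appropriate. The band edges are included in the "meaningful"
regime (the inclusive reading of an "acceptable" range); a panel with no
ties at either wave has an undefined index and raises an error rather than
returning 0.

# Stage 2 — dyadic homophily (QAP logistic regression)

For each wave separately, tie presence over all $n(n-1)$ ordered dyads is
regressed on attribute-similarity terms: a categorical attribute $d$
contributes the match indicator $\delta(x_{id}, x_{jd})$, a continuous
attribute the absolute difference $|x_{id} - x_{jd}|$. Coefficients are
log-odds; $e^{\beta_d}$ is the multiplicative change in the odds of a tie
per unit of the regressor. The maximum-likelihood fit uses Newton–Raphson
iterations, converging when the largest score component falls below 1e-8
(at most 100 iterations); coefficient paths escaping beyond ±25 are reported
as separation with advice to remove the offending term, and zero-variance
regressors are dropped with a warning.

Because dyads sharing a node are dependent, nominal logistic standard errors
are invalid; inference is by the quadratic assignment procedure. We permute
the *dependent* adjacency matrix: a uniformly random node relabelling is
applied simultaneously to rows and columns, which preserves every structural
property of the observed network (density, degree sequence, triad census)
while destroying its alignment with the attributes, the design is rebuilt
and the model refit. The two-sided permutation p-value per term is
$(1 + \#\{|\beta^\*| \ge |\beta_{obs}|\})/(n_{perm} + 1)$ — the +1 correction
keeps p-values strictly positive. Defaults: 1000 permutations, a mandatory
run seed, significance flagged at 90% confidence, no multiplicity
correction (per-term reporting is the convention this pipeline mirrors; the
report footer says so). Maternal education is an ordered category; it can be
entered either as a match indicator or as its ordinal level code, and both
codings are left to the caller because neither is canonical.

# Stage 3 — separable temporal ERGM (formation and dissolution)

The T0 → T1 transition is decomposed into two constrained networks: the
formation network $y^+ = y^0 \cup y^1$ (ties may only be added to the
baseline) and the dissolution network $y^- = y^0 \cap y^1$ (baseline ties
may only be deleted), so that $y^1 = (y^+ \setminus y^0) \cup y^-$ exactly.
Formation and dissolution are modelled as *independent* exponential-family
processes on their spaces,

$$P(Y^+ = y^+ \mid y^0; \theta^+) \propto \exp\!\big(\theta^+ \!\cdot g^+(y^+)\big),
\qquad
P(Y^- = y^- \mid y^0; \theta^-) \propto \exp\!\big(\theta^- \!\cdot g^-(y^-)\big),$$

and estimated separately by conditional maximum likelihood. Dissolution
coefficients parameterize *persistence*: positive $\theta^-$ means ties with
the feature are preferentially preserved, negative that they are
preferentially dissolved; `interpret_stergm()` emits exactly these readings
for coefficients significant at the chosen level (default 90%).

Statistics available: `edges`; geometrically weighted in-degree
(`gwidegree`), capturing popularity dispersion with diminishing returns;
geometrically weighted edgewise shared partners (`gwesp`), capturing
transitive closure, with shared partners counted along transitive
(outgoing-two-path) directions — the conventional choice for directed
friendship data; `absdiff(attr)` and `nodematch(attr)`. Decay parameters
are **fixed**, default 0.25, and never estimated: fixed-decay keeps the
family linear, and no canonical decay exists for these data, so the value
is a reporting convention that every output records. Ordered categories
(e.g. a 3-level BMI category) enter `absdiff` through their ordinal codes.

Estimation auto-selects among three routes:

1. **Dyad-independent models** (edges/absdiff/nodematch only): the
   conditional likelihood factorizes over free dyads, so the MLE is an exact
   logistic regression on change statistics (no MCMC error at all).
2. **Small spaces** (≤ 20 free dyads): exact MLE by Gray-code enumeration of
   all configurations.
3. **Otherwise MCMC-MLE**: Metropolis sampling by single-dyad toggles
   restricted to the free dyads (burn-in 10,000 toggles, interval 100,
   1000 draws per iteration by default), Newton updates on the
   importance-sampled likelihood with step-halving and a trust-region cap,
   initialized at the maximum pseudolikelihood estimate, stopping when the
   simulated mean statistic matches the observed one within a Mahalanobis
   tolerance. Standard errors come from the inverse estimated Fisher
   information — the covariance of the sampled statistics; 90% confidence
   intervals are $\hat\theta \pm 1.645\,\mathrm{SE}$.

Model degeneracy is a first-class outcome, not a crash: when sampled
statistics collapse to a boundary or coefficients diverge, the fit raises a
structured `classnet_degeneracy` error naming the offending term and
recommending its removal; `run_study()` records the classroom as degenerate
and continues with the others. This mirrors the practical workflow in which
a problematic covariate (BMI in sparse control classrooms, for instance)
must be excluded before the remaining model converges.

Numerical notes. The convergence tolerance trades accuracy for time: the
stopping rule leaves a coefficient error of roughly `ztol` divided by the
statistic's standard deviation, so precision studies should tighten `ztol`
(the package's exact-vs-MCMC agreement checks use 0.02–0.04 with larger
samples). With strongly correlated statistics (edges and gwesp on dense
networks) the likelihood has a flat ridge: estimates remain valid but have
large, highly correlated standard errors, and finite-sample MLE bias of
order 0.1 on 25-node panels is visible in simulation even at tight
tolerances — an inherent property of the information available, not of the
optimizer.

# Stage 4 — difference-in-differences on cohesion

For a cohesion metric $y$ (closeness, degree, in-/out-degree, clustering),
each node contributes one observation per wave to

$$y_i = \beta_0 + \beta_1 t_i + \beta_2 T_i + \beta_3\, t_i T_i + \gamma' z_i,$$

with $t_i$ the treatment indicator, $T_i$ the wave indicator and optional
covariates $z_i$. $\beta_3$ — the treated group's change net of the control
group's change — is the intervention effect; on a covariate-free balanced
panel it equals the 2×2 difference of group-by-wave means exactly. The
standard grid runs three contrasts (MARA vs control, MARA+SMS vs control,
MARA+SMS vs MARA) by five metrics. Covariate adjustment is a configuration
input (default: none), since which baseline imbalances warrant adjustment
is a per-study judgement.

Standard errors: classical OLS by default, with cluster-robust options on
**node** (a node's two waves are dependent) or **classroom** (nodes sharing
a network are dependent — degrees of classmates covary through their common
ties, with intra-class correlation of order $1/(n-1)$). Simulation shows the
node-level dependence makes classical SEs for $\beta_3$ *conservative*
(differencing removes node effects), while the classroom-level dependence
makes node-clustered SEs *anticonservative* with few classrooms; calibrated
10% error rates in our null simulations require classroom clustering with
adequately many classrooms (we use 12 per arm in the calibration study).
With only a handful of classrooms, $\beta_3$ p-values should be read as
descriptive. The default remains classical (reported in the fit metadata),
matching how such models are usually presented with two waves and few
classrooms.

# The synthetic-data generator

No sociometric study data are distributable, so verification rests on a
generator whose every stage has known ground truth:

* **Attributes** are drawn inside the descriptive envelopes of the study
  population the package emulates — sex ratio 71:54 female:male, age
  uniform on 9–13 years, BMI normal (mean 18.5, sd 2.8 kg/m²) truncated to
  13.3–27.75, MVPA lognormal (median 55 min/day, log-sd 0.45) truncated to
  19.92–143.9, with the ≥60 min/day guideline flag derived from MVPA.
  The distributions *within* the envelopes, the maternal-education and
  income category frequencies, and the BMI category cut points (14.5 and
  21 kg/m²) are the package's own choices, documented here precisely
  because they are inventions; satisfaction indicators exist only for
  intervened groups (Bernoulli 0.8).
* **Baseline networks** are long-run Metropolis draws from an
  exponential-family model, default `edges` −2.2 + `nodematch(sex)` 0.8 +
  `gwesp(0.25)` 0.5 on ~20 children — producing densities, sex homophily
  and transitive closure of realistic classroom magnitude (mean degree
  ~7–9, local clustering ~0.3).
* **Transitions** reuse the same separable sampler the estimator targets
  (formation `edges` −2 + `gwesp(0.25)` 0.8; dissolution `edges` +1), so
  estimation tests are exactly internally consistent; an independent
  uniformity check on an enumerable 3-node space and a closed-form
  Bernoulli check guard the sampler itself against shared-bug circularity.
  These defaults were calibrated once so that default panels land the
  Jaccard index inside the meaningful 0.3–0.6 band, and they do.
* **Intervention effects** are planted additively: an `added_degree` of
  $\delta$ places $\delta n/2$ extra uniformly random ties in the treated
  classroom's T1 network, raising mean degree by exactly $\delta$ (each
  directed tie adds one in-degree and one out-degree). Closeness gains
  emerge from the added ties rather than being planted separately. The
  default study — seven classrooms of 16–19 children (125 in total), two
  MARA+SMS, two MARA, three control — plants 4.3 (MARA+SMS) and 0.5 (MARA),
  so the MARA+SMS-vs-MARA contrast carries a 3.8-friendship effect.

What the generator does *not* emulate: nomination-rank structure, missing
attribute values, attrition between waves, inter-classroom nominations, or
any behavioural feedback between physical activity and friendship choice.
Passing parameter-recovery tests therefore demonstrates the estimators are
correct for data from their own model class at classroom sizes — not that
the substantive findings of any particular study would replicate.

# Verification strategy and problem sizes

The test suite checks, among others: exact agreement of all metrics and
change statistics with brute-force enumeration oracles on 10,000 random
digraphs of ≤ 5 nodes; the decomposition identity on 1,000 random panels;
the set-identity form of the Jaccard index; QAP null calibration (500
datasets of 20 nodes, 999 permutations — rejection at p < 0.10 within
binomial bounds of 0.10) and power ≥ 0.9 against planted sex homophily of
log-odds +2 (200 replicates); STERGM closed-form, exact-enumeration and
MCMC agreement, plus parameter recovery with nominal CI coverage on 100
simulated 25-node panels; the exact 2×2 identity for $\beta_3$, a 10%
type-I rate over 500 null studies, and recovery of a planted 3.8 mean-degree
effect within 5% over 200 replicates; and a deterministic end-to-end run of
the default seven-classroom study. These sizes were chosen to give each
check Monte-Carlo resolution well inside its tolerance while keeping the
full suite runnable in minutes.

# Known limitations

* Two waves only; no multi-wave trajectories or continuous-time models.
* Decays are fixed, never estimated (no curved-family fitting).
* QAP offers the classic Y-permutation; Double-Semi-Partialling for
  multi-term robustness is not implemented.
* STERGM goodness-of-fit is limited to statistic traces and acceptance
  rates.
* DD assumes parallel trends, untestable with two time points, and offers
  no propensity weighting or random effects.
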