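---
title: "Modeling longitudinal psychiatric comorbidity trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling longitudinal psychiatric comorbidity trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`trajmorbid` analyzes how psychiatric comorbidity unfolds over the life
course of a diagnosed cohort. Its input is registry-style data: one row
per person (birth date, censoring date and reason, date of the index
diagnosis) and one row per first diagnosis in each of a small set of
comorbidity categories. Its output is a low-dimensional, clusterable
representation of each person's *comorbidity trajectory*, together with
the epidemiological and association analyses that interpret it.

This vignette explains the model behind each stage, the choices the
package makes where the design was genuinely open, and what the bundled
synthetic-data generator does and does not emulate.

## The state sequence model

Time is discretized on an **age grid**: interval $t$ covers ages
$[t, t+1)$ years (6- and 4-month increments are supported). A person's
state in interval $t$ is the **cumulative set** of diagnosis categories
received *strictly before* age $t$. With $C = 8$ categories the state
space has $2^8 = 256$ elements: one no-diagnosis state, 8 singletons and
247 multi-category combinations. Cumulative states make sequences
monotone (states only grow), which the transition and imputation
machinery exploits.

Two conventions are worth stating because the data do not force them:

* **Age grid, not calendar grid.** Follow-up spans differ by birth year;
  anchoring intervals at birthdays makes sequences comparable across
  birth cohorts, and matches the convention of counting states "from
  birth".
* **Boundary diagnoses count from the next interval.** "Diagnosed before
  the beginning of the interval" is read as a strict inequality, so an
  event exactly on a birthday enters the following interval's state.

The default grid length is 36 intervals, covering birth to age 36.

## Optimal matching with censored tails

The dissimilarity between two trajectories is an edit distance: the
minimal total cost of substitutions, insertions and deletions that turn
one sequence into the other, found by the standard global-alignment
dynamic program (the inner loop is implemented in C++).

**Substitution costs** price the replacement of one diagnosis set by
another through their set overlap:

$$c(a, b) = 1 - \frac{2\,|a \cap b|}{|a| + |b|},$$

the Sørensen–Dice dissimilarity, with $c(\emptyset,\emptyset) = 0$.
Under this scheme a singleton against a disjoint singleton costs 1 and
two two-category sets sharing one category cost $0.5$. We note a naming
subtlety: this quantity is often loosely called a Jaccard distance, but
the set-theoretic Jaccard distance $1 - |a \cap b|/|a \cup b|$ gives
$2/3$, not $0.5$, in the shared-category case. The package treats the
worked values as normative, uses Dice as the default
(`cost_model("paper_overlap")`) and retains `"jaccard"` and
`"constant"` schemes for sensitivity analyses. Indels cost 1 by
default; since all substitution costs are at most 1, substitution is
never dominated by an indel pair.

**Censoring.** Observed follow-up lengths differ (administrative end of
follow-up, death, emigration), and raw edit distances would largely
measure length differences. Every sequence is therefore extended to the
full grid length: a first-order Markov chain is estimated from all
observed year-to-year transitions (maximum likelihood, pooled over
persons and ages, i.e. time-homogeneous), and the censored tail of each
sequence is represented by the chain's predicted state *distributions*,
starting from the one-step transition out of the last observed state.
Positions beyond censoring are thus probability vectors rather than
states, and the position cost becomes an expectation:

* observed vs observed: the plain substitution cost;
* observed vs imputed: the probability-weighted mean cost;
* imputed vs imputed: the double expectation under independence of the
  two chains.

Two consequences of the double expectation deserve emphasis. First, a
distribution paired with itself does not cost zero (two independent
draws from the same distribution usually differ), so a censored
sequence has a *positive* self-distance; the pairwise matrix still has
a zero diagonal by definition, but projecting an exact duplicate of a
censored sequence onto the embedding reproduces its training score only
approximately. Exactness holds whenever no imputation is involved, and
the tests pin the exact identity in that regime. Second, as the
transition model becomes deterministic, imputed tails collapse to point
masses and two sequences with identical observed prefixes but different
censoring times become equivalent — the length-independence the
imputation is designed to deliver.

States that appear in a cohort but never as a transition origin (and
states contributed by a replication cohort that the estimation cohort
never produced) receive a self-loop row: the chain holds them fixed.
This is the least-informative monotone completion and keeps projection
of external cohorts well defined.

**Numerical notes.** The dynamic program breaks floating-point ties in
a fixed order (diagonal, up, left), which affects recovered scripts but
not distances. The pairwise computation imputes each tail once,
pre-multiplies each sequence's position-distribution matrix by the cost
matrix, and reduces each pair to one small matrix product plus the DP
recursion; a 300-sequence matrix takes a few seconds on one core.

## Embedding and projection

Classical (Torgerson) scaling double-centers the squared-distance
matrix, $B = -\tfrac12 J D^{(2)} J$, and takes the leading
eigenvectors scaled by the square roots of their eigenvalues. The
analysis keeps $k = 3$ dimensions.

Optimal-matching distances are metric but not guaranteed Euclidean, so
$B$ can have negative eigenvalues. These are excluded from the scores
and from the variance denominator; their relative mass is reported by
the `embedding` object so the user can judge how non-Euclidean a given
matrix is (about 10–20% of the positive mass on simulated cohorts).

Signs of eigenvectors are arbitrary; each dimension is first oriented
so its largest-magnitude loading is positive (deterministic), and
`orient_embedding()` can then flip dimensions to correlate positively
with interpretable features — by convention dimension 1 with the
comorbidity count, dimension 2 with childhood-onset categories,
dimension 3 with substance abuse.

New individuals are placed by Gower's add-a-point interpolation from
their distances to all training sequences; the centering statistics are
retained in the embedding object for this purpose. Stability is
assessed by a leave-one-out jackknife: each reduced embedding is
Procrustes-aligned (rotation, reflection, scaling, translation — solved
in closed form via the SVD) to the full solution, and the coefficient
$1 - \text{mean squared displacement} / \text{total score variance}$ is
reported, subsampled to 200 deletions for large cohorts. A simple
permutation check of the leading eigenstructure (shuffling the
off-diagonal distances) is also provided; it is a generic reference
test, not a calibrated inferential procedure.

## Clustering

Ward's minimum-variance agglomeration (the squared-Euclidean `Ward.D2`
formulation) is run on the retained MDS scores, not on the raw
dissimilarity matrix. Cluster labels are relabeled by descending size
for stability across runs. The number of clusters is chosen where the
variance-explained profile levels off: scanning $k = 3, 4, \ldots$, the
first $k$ whose *next* marginal $R^2$ gain is at most a quarter of the
gain into $k$ is selected; a profile without such a collapse yields
$k = 1$ with a warning. Cluster robustness is quantified by bootstrap
resampling: each original cluster is matched to its best-Jaccard
counterpart in a re-clustered bootstrap sample, averaging over
resamples. A depth-limited CART tree (Gini) fitted to interpretable
features — per-category indicators split before/after the index
diagnosis, plus ages at first diagnosis — serves as a portable
surrogate for the clustering; the feature set is a documented choice,
as is the reference cluster for odds ratios (the largest,
low-comorbidity cluster).

## Epidemiological layer

Cumulative incidence is one-minus-Kaplan–Meier on the age scale,
censoring at the earliest of death, emigration and end of follow-up
(competing risks are handled by censoring, not by a subdistribution
estimator; with death rates of about 1/1000 person-years the numerical
difference is negligible). The decomposition of incidence into parts
before and after the index diagnosis apportions the estimate by the
observed fraction of first events preceding the index date.

Relative risks compare case and control prevalence at censoring, with
the log-method interval
$\exp(\log \mathrm{RR} \pm z \sqrt{1/a - 1/n_1 + 1/b - 1/n_2})$ — the
simple prevalence ratio reproduces the published register contrasts to
their printed precision, which is why no matched-pair estimator is
used.

Temporal structure between category pairs is tested by Cox models with
age as the time scale: for each ordered pair (A, B), follow-up to the
first B diagnosis is episode-split at the first A date, giving a
time-varying prior-A indicator, with sex the only fixed covariate (age
adjustment is absorbed by the time scale). No third diagnoses enter the
model. With 8 categories this yields 56 tests and a Bonferroni
threshold of $0.05/56$, displayed as $9 \times 10^{-4}$ at two
significant digits. Pairs whose exposure coefficient is inestimable
(no exposed events, non-convergence, exploding standard errors) are
flagged and excluded from significance counts rather than silently
dropped.

## Association layer

Joint association of a single predictor with the three dimension scores
uses MANCOVA with **Pillai's trace** (the most robust of the standard
multivariate statistics to mild assumption violations; the choice is a
package decision, as only "MANCOVA" is conventionally specified) and
its standard F approximation, adjusting for age at censoring and sex;
missing predictor values are removed listwise and the analyzed n
reported per variable. Post-hoc per-dimension ordinary least squares
with one-degree-of-freedom F tests are run only for predictors passing
the Bonferroni threshold (0.05 divided by the number of joint tests).
Cluster membership is analyzed in parallel by multinomial logistic
regression against the reference cluster, at the same conservative
threshold. Hospitalization outcomes are analyzed as average yearly
counts after the index diagnosis (counts divided by post-index
follow-up years).

Replication projects an independent cohort onto the primary embedding
(same cost model, primary transition model) and reruns the association
scan on the projected scores; concordance is summarized as the fraction
of primary-significant post-hoc coefficients (joint test passed,
per-dimension $p < 0.05$) whose sign is reproduced.

## The synthetic registry generator

No individual-level register data can be shipped, so the package
includes a generator whose defaults emulate the study conditions the
analysis assumes: births 1981–2002, follow-up to the end of 2016
(observed lengths roughly 14–36 years), eight comorbidity categories,
two age/sex-matched controls per case (matching by duplicating case
birth dates and sexes), weak yearly death (0.001) and emigration
(0.0005) hazards, and an index-diagnosis age drawn from a truncated
normal around the early twenties. Five default latent classes mirror
the clinically described trajectory profiles — childhood-disorder,
adult-multimorbidity, mood-only, substance, low-comorbidity — with
mixture weights proportional to the reported subgroup sizes and
per-category yearly hazards chosen to land in the plausible range of
register cumulative incidences (a few per mille to a few percent per
year, with dominant categories at 2–6% per year).

Events are generated in continuous time as competing exponential
clocks: a yearly hazard $h$ becomes the rate $-\log(1 - h)$ (so the
one-year marginal survival is exactly $1 - h$), and each realized
diagnosis immediately multiplies the rates of related categories by the
configured pair multipliers. Implementing the interaction on the rate
scale, switching at the realized diagnosis date, makes a planted
multiplier *exactly* the hazard ratio the time-dependent Cox stage
estimates — the property the recovery tests check. Hospitalization
outcomes are drawn from a negative binomial with class-dependent yearly
mean over post-onset follow-up (overdispersed counts being the registry
norm); covariates are Gaussian or Bernoulli with class-dependent mean
or log-odds shifts.

What the generator does **not** emulate: real register prevalences and
their secular trends, diagnostic practice changes (ICD-8 to ICD-10),
incidence-density control matching, within-family correlation, and any
genuine genetic architecture (polygenic-score-like covariates are just
shifted Gaussians). Passing tests therefore demonstrate that the
pipeline recovers structure *of the kind the model assumes* at
realistic sizes and censoring — not that the published register-scale
estimates would be reproduced from real data.

## Problem sizes used by the tests and drivers

The bundled analyses run at desk scale by design: the driver scripts
simulate 300 cases (900 persons), the recovery benchmarks use 10 seeds
at 300 cases and 20 seeds at 2000 cases, the null calibration of the
MANCOVA uses 1000 replicates at n = 500, and the increment-sensitivity
check subsamples 100 sequences. These sizes were chosen so each
property is measured with useful precision while the whole suite stays
in the minutes range on a single core.

## Known limitations

* The transition model is time-homogeneous; diagnosis hazards in real
  registries are strongly age-dependent, and an age-stratified chain
  would impute more realistic tails.
* The double-expectation cost ignores dependence between two imputed
  chains; a coupled imputation would lower censored-censored costs.
* The before/after-index incidence split is an apportionment of the
  marginal estimate, not a competing-risks decomposition.
* The elbow rule for the cluster count is deliberately simple; the
  profile itself is always reported so other rules can be applied.
* Confidence intervals from the Cox stage are Wald intervals —
  first-order approximations whose realized coverage at a few hundred
  events can run a couple of points below nominal; checks of planted
  effects over small fixed seed batches inherit that binomial noise.
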