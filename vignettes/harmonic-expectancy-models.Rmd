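---
title: "Stochastic models of harmonic expectancy: methods and design notes"
author: "chordexpect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic models of harmonic expectancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chordexpect)
```

## The data and the question

A listener hears a short sequence of 2, 3 or 4 major triads and rates, on a
9-point scale, how well the final chord belongs to the preceding context
(the *Degree of Relatedness*, DOR; 1 = least appropriate, 5 = neutral,
9 = most appropriate). All chords are drawn from the 12 major triads, so a
chord is identified by its root pitch class (coded 0..11 internally, with
A = 0; the on-disk CSV dialect uses 1..12). The experimental design is:

* **2-chord condition** — all 144 ordered root pairs;
* **3-chord condition** — all 144 ordered pairs of directed root intervals,
  realised from random initial roots;
* **4-chord condition** — all 64 triples of intervals drawn from
  \{major 2nd, perfect 4th, perfect 5th, minor 7th\} = \{2, 5, 7, 10\}
  semitones, random initial roots.

The scientific question is what computation produces the rating: does the
expectancy for the final chord depend only on local transitions, or on an
internally constructed and updated *tonal reference* (a key-like anchor)?

## The six expectancy models

Each model maps a sequence to an internal fitness
$E(c_t) \in [0, 1]$ for its final chord. $E$ is a free fitness value, not a
normalised probability over the 12 candidates: it is calibrated to ratings
through the linear map $A = 10E$, so a strongly related progression must be
able to reach $E \approx 0.9$.

* **1P** (pitch profile): $E = p(c_t)$, a 12-vector over the final root;
  context-free.
* **2P** (pitch Markov): $E = T_P(c_{t-1}, c_t)$ over raw root pairs.
* **1M** (interval profile): $E = m(c_t - c_{t-1} \bmod 12)$; depends only
  on the final interval.
* **2M** (second-order Markov): $E = T_{2M}(i, j)$ with
  $i = c_t - c_{t-2}$, $j = c_t - c_{t-1}$ (mod 12). For 2-chord input the
  two-back chord is unknown; under a flat prior the matrix column is
  averaged over its 11 defined rows.
* **BU** (Bayesian updating): a hidden reference $X$ ranges over the 12
  triads. Chords are labelled by their interval from $X$, and a 12×12
  expectancy matrix $T$ holds the fitness of label-to-label progressions.
  The belief over $X$ starts from the first chord with weight $\kappa$
  ($P(X = c_1 \mid c_1) = \kappa$, the remaining mass uniform over the other
  11 candidates, $0 < \kappa \le 1$) and is updated by Bayes' rule after
  each transition, the likelihood being the reference-relative $T$ entry.
  The final expectancy marginalises $T$ over the current belief.
* **BS** (updating and switching): as BU, plus a reset: from the third
  chord on, when the maximum of the provisional posterior falls below a
  threshold $\theta$, the prior is re-anchored on the preceding chord (the
  initial-state form with the same $\kappa$) before updating — a "key
  change" move. With $\theta = 0$ the reset never fires and BS is exactly
  BU, which the tests assert extensionally.

Immediate chord repetitions are excluded throughout: the corresponding
matrix cells (the diagonal for the reference-relative and pitch-pair
matrices; additionally the unison column for 2M; the unison entry for 1M)
are undefined, and trials containing a repetition are dropped before
fitting and evaluation, reflecting the instability of behavioral ratings of
repeated chords.

Because the interval-indexed models (1M, 2M, BU, BS) see only root
differences, they are exactly transposition-invariant; the pitch-indexed
models (1P, 2P) are not. This asymmetry is itself a testable prediction and
is verified in the test suite.

## The fitting cost

Ratings are mapped to the probability scale by $A' = A/10$ (so the neutral
rating 5 maps to 0.5). The fitting cost is a rating-weighted *binary*
cross-entropy summed over trials:

$$H = \sum_n -\bigl[A'_n \log E_n + (1 - A'_n)\log(1 - E_n)\bigr].$$

Each term is strictly convex in $E_n$ with its minimum exactly at
$E_n = A'_n$. This choice is deliberate and worth spelling out: a cost with
only the $-A'\log E$ term is monotone decreasing in every $E$, so its
minimiser degenerates to all fitness entries at 1 regardless of the data —
no calibrated estimate could come out of it, and noiseless synthetic data
could never be recovered. The two-sided form is the unique natural cost
under which the calibration $A = 10E$ is identifiable: the optimum
reproduces the rating profile, fitted matrix entries land near mean
ratings / 10, and parameter recovery from noiseless data is exact for the
models without belief updating. $E$ is clamped to
$[10^{-12}, 1 - 10^{-12}]$ inside the cost and the belief-update
likelihoods are floored at $10^{-12}$, so lattice values of exactly 0 and 1
remain admissible without producing infinite logs or all-zero posteriors.

## Estimation: discrete coordinate descent

All parameters live on lattices: matrix entries on steps of 0.1 over
$[0,1]$, $\kappa$ on steps of $1/12$ over $(0,1]$, $\theta$ on steps of
0.05 over $[0,1]$. A fit runs `restarts` independent restarts; each draws
every free parameter uniformly on its grid, then repeatedly sweeps the
parameters in a freshly shuffled order. A parameter moves to the better of
its two grid neighbours only on *strict* cost improvement (ties keep the
current value, guaranteeing termination on the finite lattice); a sweep
with no move ends the restart. The best terminal cost over restarts wins.
The sweep order is reshuffled every sweep by default
(`shuffle_each_sweep = FALSE` switches to a single shuffle per restart).
Free-parameter counts: 1P = 12, 1M = 11, 2P = 132, 2M = 121,
BU = 132 + $\kappa$, BS = BU + $\theta$.

The cost kernel and descent loop are compiled (Rcpp); the pure-R
`expectancy()` path is retained as the documented reference implementation,
and the suite asserts agreement between the two to machine precision. All
randomness flows through R's RNG, so a fit is a deterministic function of
(data, model, restarts, seed).

## Pre-modelling statistics

Analyses run on participant-averaged DORs per stimulus pattern:

* Kruskal–Wallis tests (tie-corrected H, $\chi^2_{11}$ reference) of the
  2-chord factors *interval*, *first pitch*, *second pitch*;
* Friedman tests of the 3-chord interval effects on the complete 12×12
  grid. For the *interval-from-second* effect, treatments are the
  final-interval levels and blocks the first-interval levels; for
  *interval-from-first*, treatments are the levels of the first-to-third
  interval and blocks the final-interval levels. Only complete-block
  structures are available at df = 11, which pins this arrangement.
* Interval-profile vectors: for each of the six preceding-chord positions,
  the mean DOR at the four intervals shared by all conditions
  (2, 5, 7, 10 semitones); their Euclidean distances feed non-metric MDS
  (Kruskal stress-1, metric-scaling start plus random restarts, via
  `vegan::monoMDS`) and complete-link hierarchical clustering.
* The context-gain analysis subtracts, from each averaged 3-chord DOR, the
  averaged 2-chord DOR with the same final interval, tests the
  first-to-third-interval effect by Friedman, and runs Nemenyi-style
  pairwise mean-rank contrasts with Bonferroni correction over the 66
  pairs ($\alpha/66 \approx 0.00076$ at $\alpha = 0.05$).

One structural fact discovered while implementing: with the blocking above,
the matched 2-chord mean is constant within each block, so the gain-grid
Friedman statistic is *necessarily identical* to the interval-from-first
Friedman on the raw 3-chord grid (within-block ranks are invariant to a
block-constant shift). The package therefore reports the gain-grid test as
its own quantity and does not claim it reproduces any particular published
value; an identically zero gain grid is reported as an all-ties result
rather than an error.

## Evaluation and model comparison

Two schemes mirror the behavioral analysis:

* **individual** — per participant, train on the 2- and 3-chord trials
  (288 per complete session) and test on the 64 4-chord trials;
* **kfold** — pool all participants and conditions and run a plain random
  10-fold cross-validation.

Pairwise model differences in held-out cross-entropy are compared by the
exact two-sided sign test (ties excluded,
$p = \min(1,\, 2\min(P(X \le k_{\min}), P(X \ge k_{\max})))$ under
Binomial$(N, 1/2)$) and, for the fold scheme, the classical paired t-test.
Information-criterion corrections are deliberately not offered: the
rating-to-probability calibration makes likelihood scale and parameter
count incommensurable, so held-out prediction is the only comparison used.

A note on $\theta$: with sequences of at most four chords, the reset can
fire only at the third-chord update, i.e. only 4-chord trials distinguish
BS from BU. On training sets without 4-chord trials $\theta$ is
unidentified and its fitted value is arbitrary — the near-tie between BU
and BS in any comparison is expected, not a defect.

## The synthetic generator and the recovery study

`simulate_ratings()` drives the calibration backwards: ratings are
$10E$ under planted parameters, either *continuous* (lossless, real-valued
in $[0,10]$) or *discrete* (rounded with additive Gaussian noise and
clipped to the 9-point scale). `simulate_experiment()` emulates a full
session: the complete three-condition design per participant, discrete
noisy ratings, and noisy neutral ratings (midpoint 5) for the
immediate-repetition stimuli that the models cannot rate — keeping the
2-chord design complete for the pre-modelling statistics while the fitting
stage drops those trials.

The recovery study (`recovery_study()`) repeats plant → simulate → refit on
the 253 repetition-free 2- and 3-chord patterns (all 132 ordered distinct
pairs plus all 121 nonzero-interval 3-chord patterns, canonical initial
root 0; randomised roots for the pitch-indexed models, which are not
transposition-invariant). It uses the continuous channel by default: with
a lossless rating channel and on-lattice truth, the cost term of every
identified parameter is minimised exactly at the planted value, so recovery
is exact for 1P, 2P, 1M and 2M — the suite asserts zero bias and zero SD —
while the updating models carry a finite, reported bias (belief dynamics
make some cells weakly identified, e.g. reference labels carrying
$(1-\kappa)/11$ of the belief mass). Discretisation and noise are opt-in
for realism studies; under them exactness claims no longer hold for any
model.

### Study conditions used by the tests and the acceptance script

Design-enumeration, sign-test and model-identity checks are exact and run
at full size. The stochastic stages are scaled to desk size, chosen once:

* recovery: 2–3 repetitions at 2–5 restarts per model (the separable
  models recover exactly from any single restart; restarts only matter for
  BU/BS);
* model comparison: data planted from a BU model with $\kappa = 0.5$
  (estimated initial-chord weights in behavioral data sit well above the
  uninformative $1/12$), rated by 5 simulated participants in discrete mode
  with noise SD 1 on the 253 patterns, compared across all six models by
  10-fold CV at 5 restarts. A single noiseless replicate is deliberately
  not used here: with 253 trials the lattice-estimation error of BU is the
  same order as its structural advantage over 1M, and the comparison is
  uninformative; pooling replicated noisy participants mirrors the group
  analysis the scheme comes from.
* pre-modelling: 8 simulated participants. Under a planted BU model the
  2-chord expectancy is an exact function of the interval alone, so the
  Kruskal–Wallis interval test is strongly significant while both pitch
  tests stay null — the qualitative signature the behavioral data show.

## Known limitations

* The deposited behavioral ratings are not bundled; analyses of the
  original data require supplying that CSV to `read_dor_csv()`. All
  quantitative claims in the tests are about synthetic data and
  mathematical properties of the estimators.
* $\theta$ is effectively inert for sequences shorter than four chords
  (see above), and the reset criterion ("maximum posterior below
  $\theta$") is one reading of a scalar belief-confidence test; it is
  isolated in `bs_step()` should another criterion be preferred.
* The key-profile uses the column *mean* over the 11 defined cells rather
  than the raw sum, keeping it on the $[0,1]$ fitness scale (readable as an
  ideal DOR via $\times 10$); `reduce = "sum"` exposes the literal
  marginalisation.
* Six-point NMDS configurations embed in two dimensions almost perfectly;
  near-zero stress there is expected and carries little information by
  itself.
* The generator models rating noise as additive Gaussian on the rating
  scale only; participant heterogeneity, drift of the rating criterion,
  and sequence-position effects are not emulated, so passing tests on
  synthetic data do not certify those aspects of real data.
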