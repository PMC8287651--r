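---
title: "Methods: the fused GA/PSO/SA search over SVM hyperparameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the fused GA/PSO/SA search over SVM hyperparameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gspsvm)
```

## The optimisation problem

A C-classification SVM with the radial basis kernel
$K(x, x') = \exp(-g\,\lVert x - x'\rVert^2)$ has two free
hyperparameters: the soft-margin penalty $c > 0$ and the kernel
coefficient $g > 0$. We write $g$ for the multiplicative coefficient
(the libsvm `-g` convention); relative to the bandwidth form
$\exp(-\lVert x - x'\rVert^2 / \sigma^2)$ this is $g = 1/\sigma^2$.
The package maximises a scalar fitness
$f(c, g) \in [0, 1]$ — the training-partition classification accuracy
of the SVM at those parameters — over the box
$c \in [0.1, 100]$, $g \in [0.01, 1000]$.

Two readings of "training accuracy" are offered. Resubstitution accuracy
(`fitness_spec("train_accuracy")`) is the literal one, but it is
maximised by degenerate large-$c$/large-$g$ solutions that memorise the
training set. The default is therefore mean accuracy over 5 stratified
folds of the training partition (`fitness_spec("cv_k", k = 5)`), the
standard way such tuning is done in practice; folds are built from a
seeded permutation, so fitness is deterministic at a fixed seed and
invariant to the order of the training rows (rows are put into a
canonical sort order before folding). An inner-holdout scheme is also
available. The QP itself is delegated to libsvm via `e1071::svm`;
nothing in this package re-derives the dual. Multiclass problems use the
solver's one-vs-one decomposition.

## Search geometry

$g$ spans five decades, so the engines search $\log_{10} g$ internally
while $c$ is searched linearly; every reported value is back-transformed.
Positions are clamped into the box after every move, and swarm
velocities are clamped to $\pm 20\%$ of each internal dimension's span —
a common PSO stabilisation that keeps a particle from crossing the whole
box in one step.

## The three engines and their fusion

**Genetic algorithm.** Chromosomes are real-coded $(c, \log_{10} g)$
pairs. Each generation keeps the single best chromosome (elitism 1) and
refills the population with tournament selection (size 2), arithmetic
blend crossover (probability 0.8, per-gene uniform mixing weight), and
per-gene Gaussian mutation (probability 0.1, standard deviation 10% of
the bound's span). These operators are the standard real-coded choices;
nothing in the method constrains them further, so they are deliberately
unexotic.

**Particle swarm.** The velocity and position updates are
$v \leftarrow \omega_m v + c_1 r_1 (p_i - x) + c_2 r_2 (p_g - x)$,
$x \leftarrow x + v$, with $r_1, r_2 \sim U(0,1)$ drawn per particle per
generation and $c_1 = c_2 = 2$. The inertia weight follows the harmonic
schedule
$\omega_m = \omega_1 - (\omega_1 - \omega_2)\,(m-1)^2/t^2$
with $\omega_1 = 0.9$, $\omega_2 = 0.4$: high inertia early for global
exploration, decaying quadratically to favour exploitation late. At
$m = 1$ it equals $\omega_1$ and at $m = t + 1$ exactly $\omega_2$.

**Simulated-annealing gate.** In the fused engine every particle's
proposed move is Metropolis-gated: a move with fitness change
$\Delta f \ge 0$ is always taken; a worsening move is taken with
probability $\exp(\Delta f / t_{temp})$, compared against a $U(0,1)$
draw. (The comparison variate is uniform because a probability compared
against a standard normal draw is incoherent — the draw can be negative
or exceed 1.) A rejected move reverts the particle entirely, position
*and* velocity, so a rejected excursion leaves no momentum trace; the
alternative of keeping the new velocity mixes an accepted dynamic into a
rejected state and makes the gate leaky. The temperature cools
geometrically, $T_{k+1} = 0.95\,T_k$. The initial temperature is
calibrated from the initial populations: $T_0$ is set so that the median
fitness deficit from the incumbent best is accepted with probability
one half ($T_0 = \mathrm{median}|f_i - f_{best}| / \ln 2$, floored at
$10^{-3}$ to survive degenerate flat initialisations). The Boltzmann-type
constant $K$ multiplies $T$ and defaults to 1 — it is a unit scale, not
a physical constant here. The gate applies to the swarm only; the GA's
moves are already governed by selection pressure, and gating crossover
products as well would make the two engines' acceptance semantics
interfere.

**Migration and fusion.** Each generation runs GA step → PSO sweep →
migration, in that order. Migration compares the swarm's global-best
fitness with the GA's best chromosome: whichever is better overwrites
the *other* population's worst member (the worst particle additionally
has its velocity zeroed and its personal best updated). Exact ties
resolve in the swarm-to-GA direction — the choice is arbitrary, but
fixing it keeps runs bit-reproducible. The global best over both
populations is tracked elitistically, which is what makes every
engine's best-fitness history non-decreasing by construction.

**Termination.** A fixed generation budget (default 50) with an
optional early stop after 10 consecutive generations without
improvement (`patience = NULL` disables it). No criterion beyond a
budget is inherent to the method, so the budget is explicit and
recorded in the result.

## Baselines

Grid search evaluates a log-spaced lattice in both dimensions (default
20 × 20) and returns the lattice argmax, breaking exact ties toward the
smaller $(c, g)$ lexicographically so results are deterministic. GA-only
and PSO-only run the respective engine with the same result contract;
the standalone PSO keeps the harmonic inertia but has no annealing gate
and no migration. The fixed-parameter baseline uses $c = 100$, $g = 4$;
the PCA baseline projects the min-max-scaled features onto the principal
components explaining at least 95% of training variance (the threshold
is a conventional default; the method itself prescribes none) before
fitting the fixed-parameter SVM.

## Preprocessing and evaluation protocol

Raw ordinal clinical tables arrive as comma-delimited text with an ID
column, attribute columns and a class column, with missing fields marked
by a token (`"?"`). Preprocessing drops the ID column, deletes every
record containing the token (no imputation — the evaluation protocol
this package follows deletes such records), parses attributes as
numbers, and recodes labels to 0-based integers in sorted order of the
source values, so both 1/2 and 2/4 codings are accepted and the mapping
is reported.

Min-max scaling to $[0, 1]$ is fitted on the training partition only
and applied to both partitions, with test values outside the training
range clipped into $[0, 1]$; fitting on the pooled data would leak test
information into the scaler. Features constant in training map to 0
(divide-by-zero guard). Splits are stratified by class by default, with
largest-remainder allocation so the train size is exactly
$\mathrm{round}(nf)$ and per-class proportions are preserved to within
one sample.

The comparison harness crosses algorithms × training fractions
(default 0.5–0.9) × repeats (default 10), derives an independent seed
per cell from the base seed by hashing the fraction and repeat indices,
tunes on the training partition only, trains the final model on the full
training partition, and scores the held-out partition. Per-metric means
over repeats form the result table; the per-repeat log, chosen
parameters and a JSON manifest ride along as attributes. Undefined
metrics (zero denominators, e.g. precision when nothing was predicted
positive) raise a typed condition and appear as `NA` in reports — never
as a silent 0, which would bias averages.

The same fraction-based repeated-split protocol is used for binary and
multiclass tasks: one coherent protocol matching how the result tables
are organised. A k-fold evaluation of a fixed parameter pair can be had
through `fitness_spec("cv_k")` directly if wanted.

## Metric conventions

MCC is implemented with the square root over the denominator product,
$\mathrm{MCC} = (TP\cdot TN - FP\cdot FN)/\sqrt{(TP{+}FN)(TP{+}FP)(TN{+}FP)(TN{+}FN)}$
— the form without the root is not bounded by 1 and is dimensionally
wrong as a correlation; the implementation is cross-checked in the tests
against the Pearson correlation of the indicator vectors, to which MCC
is algebraically identical. G-mean is
$\sqrt{\text{sensitivity}\times\text{specificity}}$ and therefore cannot
exceed 1. AUC uses the rank (Mann–Whitney) estimator with ties counting
one half, equal to the trapezoidal ROC area. Micro-averaged
precision/recall/F1 pool per-class TP/FP/FN before the ratio; on any
single-label task all three equal the accuracy, Hamming loss equals
$1 - \text{accuracy}$, and micro Jaccard equals
$\text{accuracy}/(2 - \text{accuracy})$ — these identities are asserted
as tests.

## The synthetic generators

The binary generator emulates ordinal diagnostic tables: two Gaussian
class-mean vectors straddling the scale midpoint at a controllable
separation (in feature units), values rounded and clipped to the 1–10
scale, class balance defaulting to 0.35 (roughly the positive share of
the classic table it mimics), and optional emission of a raw dialect
file with ID column, 2/4 class coding and "?" tokens injected at a
stated rate. The multiclass generator draws labels from stated priors
and each enumerated feature from a class-conditional categorical table;
a concentration parameter moves smoothly between no signal (uniform
tables) and perfect separability (deterministic tables).

What the generators do *not* emulate: the covariance structure,
attribute skew and label noise of real clinical data. Passing the
recovery tests therefore shows the pipeline is correct and the search
effective on problems with known structure — it does not certify
clinical-grade accuracy on real data. The bundled
`inst/extdata/wbc_synthetic.data` is such a generated stand-in (699
records, 16 with missing tokens), labelled synthetic precisely because
it is not the original clinical table.

The injected-fitness surface used in optimizer tests is a deterministic
unimodal bump with its maximum exactly at a stated $(c^*, g^*)$,
measured on the same (linear $c$, log $g$) geometry the engines search;
it makes the true optimum known so engines can be scored against an
exhaustive 200 × 200 grid scan.

## Problem sizes and numerical choices

The test-suite and acceptance runs use sizes chosen to exercise every
code path at desk scale: synthetic datasets of 80–400 samples,
engine budgets of 8–30 generations on injected surfaces, a 200 × 200
oracle grid, $10^5$ draws per Metropolis frequency check, 1000 random
prediction sets for the MCC/Pearson agreement, and 10 repeats of the
tuned pipeline on a 300-sample separable problem (3 repeats on the
signal-free control, where the tuner has nothing to find and each run is
slower because cross-validation accuracy stays mid-range). Tolerances:
exact identities are asserted to machine precision; stochastic
frequencies to three binomial standard errors; engine quality to 95% of
the grid oracle.

Degenerate inputs are handled explicitly: constant features scale to 0;
a class absent from a partition raises a degenerate-split error rather
than silently proceeding; single-class training data is rejected;
stratified splits that would empty a class fail loudly; ragged rows in
dialect files are reported with their line number.

## Known limitations

- Fitness evaluations dominate runtime; no surrogate modelling or
  caching of repeated $(c, g)$ evaluations is attempted.
- The engines are serial; repeats in the harness could be parallelised
  but are kept sequential for exact reproducibility of the per-cell
  seed stream.
- Whether the annealing gate should also govern GA moves is a genuine
  design fork; the swarm-only gate implemented here is one defensible
  reading, and the standalone engines let users measure the difference.
- No statistical significance testing between algorithms is provided;
  the harness reports means and standard deviations only.
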