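---
title: "Stepwise SVM model selection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stepwise SVM model selection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepsvm)
```

## The problem

Clinical prediction models usually want a handful of predictors — five to
ten factors that a clinician can score — rather than everything that was
measured. Wrapper selection strategies pick that subset by the predictive
performance of a fitted classifier instead of by marginal association. This
package implements a forward wrapper built on the support vector machine
(the *stepwise SVM*), together with the two strategies it is conventionally
compared against, and a simulation harness for studying the stability of
all three on clustered clinical data.

## The stepwise SVM

Let $m$ be the number of candidate predictors and let
$\mathrm{acc}_{CV}(S)$ be the 10-fold cross-validated accuracy of an SVM
fitted on variable subset $S$. The search is:

1. **Pair stage.** Score all $\binom{m}{2}$ unordered pairs and keep the
   best one. With $m = 26$ this is 325 candidate models.
2. **Forward stages.** Given the current set $S$, score $S \cup \{v\}$ for
   every remaining $v$ ($m - |S|$ candidates: 24, then 23, then 22 for
   $m = 26$) and add the best variable **only if it strictly increases**
   the criterion.
3. **Stop** when no addition strictly improves the criterion, when a size
   cap is reached (default 5 variables), or when no variables remain.

Starting from pairs rather than singletons lets the first step capture a
two-variable interaction that neither variable shows marginally — the price
is the quadratic pair stage, $\binom{m}{2} + \frac{(m-2)(m-1)}{2}$ model
fits for an uncapped run versus $\frac{m(m+1)}{2}$ for stepwise logistic
regression and $m$ for recursive feature elimination
(`count_total_models()`).

The strict-improvement reading of the stopping rule is a deliberate choice:
a non-strict rule admits indefinite plateaus in which variables are added
without predictive gain. Ties among equally scoring candidates are broken
by canonical roster order (the column order of the candidate list), making
every path reproducible; permuting the columns of the input changes nothing
except through that documented tie-break.

The SVM itself is delegated to libsvm via **e1071**: the soft-margin dual
with cost parameter $C$ bounding the dual coefficients, and either the
linear kernel or the RBF kernel
$K(x, x') = \exp(-\gamma \lVert x - x'\rVert^2)$. Solving that quadratic
program is a solved problem and is deliberately *not* re-implemented here;
this package owns everything around it (the search, the evaluation
protocol, the comparators, the generator).

### Evaluation protocol

Two data-use conventions are combined, and their composition is a design
decision of this package: each SVM strategy first holds out a stratified
20% test partition; the *selection criterion* is 10-fold cross-validated
accuracy computed entirely within the remaining 80%; the *reported
performance* is the accuracy of the final refitted model on the untouched
20%. Selection and reporting therefore never see the same rows, the
standard nested arrangement. Both numbers are kept on the fitted object
(`cv_value`, `test_accuracy`) because either could be meant when a single
"accuracy" is quoted for a wrapper method.

Folds are stratified by outcome and seeded, and fold assignment is keyed on
a canonical (lexicographic) row ordering, so a cross-validated score is a
pure function of the data multiset, the seed and the tuning — not of row
order. Every candidate subset within one run is scored on identical folds.

Hyperparameters are fixed once per run (default RBF, $C = 10$,
$\gamma = 1$, the settings used throughout the stepwise-SVM simulation
study); `tune_svm()` implements the grid search that justifies them,
choosing the grid point minimizing the cross-validated mean squared error
of the 0/1 predictions. For hard binary predictions that MSE is identically
the misclassification rate, so the tuner maximizes CV accuracy; this
0/1-loss identity is the package's interpretation of "minimum MSE" for a
classifier, and it is asserted by a test. A per-candidate re-tuning mode
exists (`retune = TRUE`) but is off by default — re-tuning inside every
candidate evaluation multiplies cost by the grid size and was not part of
the reference protocol.

### Feature preprocessing

Kernels are scale-sensitive, so continuous and ordinal predictors are
standardized to zero mean and unit variance using **training-fold**
statistics only. Categorical predictors and the cluster identifiers are
one-hot encoded over the level set of the supplied data; a variable's
dummy block is treated as a unit by the selectors (selection and RFE
ranking operate on variables, not dummy columns). Binary 0/1 predictors
pass through unscaled. Unseen levels at prediction time map to an all-zero
block.

## The comparators

**SVM-RFE** is backward elimination with a linear SVM: fit on the
survivors, rank each variable by the squared weight of its encoded
column(s) — summed over a one-hot block — and drop the lowest, one variable
per iteration, until none remain. The selected set is the $k$ variables
eliminated last (most important first). The weight vector exists only for
the linear kernel, so an RBF request is refused. Ties in the squared-weight
ranking eliminate the later-roster variable, so earlier-roster variables
survive ties — the mirror image of the forward tie-break. The reported
accuracy refits the top-$k$ model and evaluates it under exactly the same
split and folds as the stepwise SVM, for comparability. Both of the
conventional cost settings ($C = 0.1$ and $C = 10$) are run by the
harness.

**Stepwise logistic regression** is the aggregate-data convention: ordinary
(not mixed-effects) logistic regression, forward selection with backward
checks driven by AIC, capped at the same size. No source names a criterion
for "conventional stepwise selection"; AIC with $k = 2$ is the default of
the standard statistical stack and is used here. Predictors enter as single
numeric columns — integer codes for categorical/ordinal variables and the
raw integer labels for `DID`/`HID`. That last convention matters: for the
logistic model the cluster identifiers are arbitrary integers with no
usable signal, so it essentially never selects them, whereas the one-hot
encoded SVM methods can exploit them. Its performance metric is the
concordance statistic (C-statistic) of the final linear predictor on the
full data, computed by the midrank form of the Mann–Whitney U — the
probability that a random positive scores above a random negative, ties
counting one half; the linear predictor is rank-equivalent to the fitted
probability, so either gives the same value.

## The synthetic generator

`generate_hierarchy()` emulates a three-level clinical hierarchy: 35
hospitals, each with 8–15 doctors, each doctor with 2–40 patients, all
counts drawn uniformly and independently. The binary `remission` outcome
follows a random-intercept logistic model
$$\Pr(y_{ijk} = 1) = \mathrm{logit}^{-1}\!\big(\beta_0 + x_{ijk}^\top\beta
  + u_j + v_k\big), \quad u_j \sim N(0, \sigma_d^2),\;
  v_k \sim N(0, \sigma_h^2),$$
with 26 candidate predictors: 20 patient-level (demographics, labs, tumour
measures, 1–9 clinical scores), 3 doctor-level (`Experience`, `School`,
`Lawsuits`) plus the doctor id `DID`, and one hospital-level (`Medicaid`)
plus the hospital id `HID`. The patient id `ID` is never a candidate.

Two facts about this design are worth stating plainly:

* Under uniform draws the expected sample size is
  $35 \times 11.5 \times 21 = 8452.5$, not the 8525 sometimes quoted for
  this hierarchy; the distribution behind that figure is not public, so the
  uniform convention is kept and documented rather than reverse-engineered.
* The coefficients originally used to simulate from this hierarchy are
  likewise not public. The default `effect_spec()` is this package's own
  parameterization, chosen once for realism and fixed: nonzero logit-scale
  effects on `CancerStage` (−0.55), `Experience` (+0.13), `mobility`
  (−0.35), `FamilyHx` (−1.0), `LengthofStay` (−0.18) and `SmokingHx`
  (−0.5), intercept +2.0, and random-intercept standard deviations
  $\sigma_d = 1.0$, $\sigma_h = 0.5$. This puts marginal remission
  prevalence near one third and makes doctor identity genuinely
  informative — which is why the SVM methods select `DID`/`HID` while the
  logistic model cannot.

Degenerate draws in which the outcome comes out single-class are resampled
with a derived seed (up to 10 attempts, with a warning) or rejected,
per configuration. Identical configuration and seed give a bit-identical
dataset, and the generator restores the caller's RNG state.

What the generator does **not** emulate: longitudinal structure, missing
data, measurement error, informative cluster sizes, or predictors whose
effects enter nonlinearly. Tests passing on these data show the selectors
behave correctly under a clean random-intercept world; they do not certify
behaviour on real registries.

## The replication harness

`run_benchmark()` repeats: derive per-repetition seeds from a master seed
(separate streams for generation and evaluation), generate a dataset, run
all four selector configurations on it (stepwise SVM; SVM-RFE at
$C = 0.1$ and $C = 10$; stepwise logistic), and record the ordered
selections and the per-method performance. Aggregates are
selection-frequency tables by position with a cumulative (at-or-before)
variant, and mean/SD/min/max performance per method. Repetitions can be
checkpointed to per-repetition JSON files; resuming from them reproduces
the identical aggregate, and more than 10% failed repetitions aborts the
run.

### Problem sizes used by the test suite

The packaged tests exercise the harness at a scaled-down profile chosen as
this package's desk-scale default: 10 repetitions of a 10-hospital
hierarchy with 4–6 doctors per hospital and 5–15 patients per doctor
(n ≈ 500 per repetition), 10-fold CV, cap 5. The suite asserts the
**ordinal** pattern that motivates the method at full scale — stepwise SVM
mean held-out accuracy above both SVM-RFE accuracies and the logistic
C-statistic — and that assertion is known **not** to hold at this reduced
scale under the default generator (see the limitation below): the test is
kept at the stated conditions rather than weakened, and documents the
scale-dependence of the wrapper's advantage. The selection-pattern checks
do reproduce at desk scale: SVM-RFE selects `DID` and `HID` first in every
repetition, the logistic model never selects the integer-coded cluster ids
and favours `CancerStage`/`mobility`/`Experience`, and the stepwise SVM
favours doctor-level variables.
`run_benchmark(n_reps = 100, hierarchy = hierarchy_config())` runs the
full-scale profile (100 repetitions of the n ≈ 8500 hierarchy) for anyone
willing to spend the CPU time.
Parameter-recovery tests use planted-signal data (3 informative variables
with logit coefficients 2.5/2.0/1.8 among 7 noise variables, n = 1000, 25
seeds) and require the planted set to be recovered in at least 90% of
runs.

## Numerical and degenerate-input choices

* **Ties.** Candidate enumeration is in canonical roster order with
  strict-greater updates, so the earliest tied candidate wins (forward
  search) and the latest tied variable is eliminated (RFE). Grid ties in
  `tune_svm()` go to the earliest grid point; grids are generated linear
  before RBF, ascending cost, ascending gamma.
* **Folds.** Stratified by outcome so every training fold contains both
  classes at realistic prevalences; an unstratified protocol that produces
  a single-class training fold raises an error advising stratification
  rather than returning a silently undefined accuracy.
* **Splits.** The held-out fraction is exact (`round(n * f)`, largest
  remainder across classes); a split that strands a class in one part is an
  error.
* **Constant columns** standardize with unit scale instead of dividing by
  zero. **Separation** or non-convergence in a logistic candidate fit skips
  that candidate with a warning instead of aborting the path.
* **C-statistic** uses the midrank formula, exactly equal to the all-pairs
  tie-half definition (property-tested against a brute-force double loop).

## Known limitations

* The stepwise SVM cost grows quadratically in $m$ through the pair stage;
  no pre-screening is provided, so very high-dimensional inputs (m ≫ 100)
  are out of intended scope.
* The logistic baseline deliberately ignores the cluster structure
  (aggregate-data convention); it is a comparator, not a recommended
  analysis for hierarchical data.
* Accuracy-driven selection inherits accuracy's insensitivity to class
  imbalance; `criterion = "sensitivity"` or `"specificity"` swaps the
  selection metric when one error type matters more.
* **The wrapper's advantage is scale-dependent.** The stepwise SVM
  maximizes a cross-validated estimate over hundreds of candidate models;
  at a few hundred training rows the per-candidate CV standard error
  (≈ 0.02) is comparable to real between-model differences, so the winning
  subset is partly selected on fold noise (winner's curse) and its
  held-out accuracy can trail a non-adaptive comparator. With the default
  generator's strong doctor-level clustering, SVM-RFE's `DID`/`HID`
  selections are genuinely predictive, and at n ≈ 500 it matches or beats
  the stepwise SVM on average; the wrapper's expected advantage is an
  n ≈ 8500 phenomenon, where CV noise is roughly three times smaller.

## A small worked run

```{r example, eval = FALSE}
d <- generate_hierarchy(
  hierarchy_config(n_hospitals = 10, doctors_per_hospital = c(4, 6),
                   patients_per_doctor = c(5, 15), seed = 5),
  default_effects())
fit <- stepsvm(d, max_size = 5, protocol = eval_protocol(seed = 5))
summary(fit)
rfe <- svm_rfe(d, k = 5, protocol = eval_protocol(seed = 5))
logit <- stepwise_logistic(d, max_size = 5)
```
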