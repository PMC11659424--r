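---
title: "Metabolic connectivity networks from regional FDG-PET uptake: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic connectivity networks from regional FDG-PET uptake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

With static FDG-PET, each participant contributes a single image, so
"connectivity" cannot be defined within a subject as it is for fMRI time
series. Instead, metabolic connectivity is defined **across subjects**: two
brain regions are considered connected when their mean tracer uptake
covaries over the participants of a group. The data object is therefore an
$n \times p$ table (subjects × atlas regions, here $p = 65$ by default), one
per group, and each group yields one network whose nodes are regions and
whose edges are partial correlations of uptake across that group's subjects.

This package implements that analysis end to end for a three-group design —
controls (CTRL), antipsychotic-responsive patients (nTRS), and
treatment-resistant patients (TRS) — including the statistical comparison of
group networks and a classifier separating the two patient groups, with the
antipsychotic dose (chlorpromazine equivalents, CPZ) treated as a first-class
confounder.

## Normalization

Raw uptake carries a large subject-specific global scale (injected dose, body
habitus, global metabolism). `normalize_global_mean()` divides each subject's
row by its own mean over all atlas regions, the region-level proxy for a
global gray-matter average. After it, every row has mean exactly 1 and any
positive per-subject scaling is provably removed.

One consequence deserves emphasis: the normalized rows satisfy an exact
linear constraint (row mean = 1), so the sample correlation matrix of a
normalized study is **exactly singular** (rank at most $p-1$), on top of
being rank-deficient whenever $n \le p$. The estimator must and does tolerate
singular inputs; see the numerical-choices section.

## Network estimation: atan-penalized Gaussian graphical models

Partial correlations come from the precision matrix
$\rho_{ij} = -\Theta_{ij} / \sqrt{\Theta_{ii}\Theta_{jj}}$. With $p$
comparable to or exceeding $n$, $\Theta$ is estimated by penalized maximum
likelihood (sparse inverse covariance estimation). The convex L1 penalty
selects a support well but shrinks the surviving entries substantially; the
package therefore uses the non-convex arctangent penalty

$$p_\lambda(\theta) = \lambda\,(\gamma + 2/\pi)\,\arctan(|\theta|/\gamma),$$

whose derivative $\lambda(\gamma + 2/\pi)\gamma/(\gamma^2+\theta^2)$ vanishes
for large $|\theta|$: strong edges are left nearly unshrunken while weak ones
are still driven to zero. The shape parameter $\gamma$ defaults to 0.01.
At $\gamma = 0.01$ the penalty derivative at zero is
$(\gamma + 2/\pi)/\gamma \approx 64.7\lambda$ — far steeper than the L1 slope
$\lambda$ — so zeros are held at zero aggressively once identified.

**Optimization.** The non-convex objective is solved by local linear
approximation (LLA): the L1 graphical-lasso solution at $\lambda$
initializes up to 10 weighted graphical-lasso iterations whose element
penalties are the atan derivative at the current precision entries, stopping
when $\max|\Delta\Theta| < 10^{-4}$. The inner solver is a block
coordinate-descent graphical lasso written in C++ (RcppArmadillo) with
active-set updates and warm starts along the $\lambda$ path. The diagonal is
never penalized. Partial correlations below $10^{-8}$ in magnitude are set to
exact zero and define the edge set.

**Tuning.** $\lambda$ is chosen by a BIC-type criterion,
$\mathrm{BIC}(\lambda) = -2\ell(\hat\Theta) + |E|\log n$ with
$\ell = (n/2)(\log\det\hat\Theta - \mathrm{tr}(S\hat\Theta))$ and $|E|$ the
number of nonzero unordered off-diagonal pairs, over 50 log-spaced values
from $\lambda_{\max} = \max|S_{ij}|_{i\ne j}$ down to
$0.01\,\lambda_{\max}$. Ties break toward the sparser (larger-$\lambda$)
model. Estimation is performed on the correlation matrix rather than the
covariance: regions already share the normalized-uptake scale, and
correlation input is the common GGM convention.

**Covariate adjustment by node augmentation.** To control for medication
dose, the CPZ value enters the estimation as an additional node of the
graphical model; after fitting, the dose row/column is deleted. The retained
region–region partial correlations are thereby conditioned on dose. This is
node augmentation followed by node removal — not residualization — and the
same mechanism accepts any recorded covariate (age, sex, education, illness
duration, onset age). A covariate that is constant within a group is an
error, and missing covariates are never imputed.

## Numerical choices and degenerate inputs

* **Singular correlation input.** On a singular $S$ the small-$\lambda$ end
  of the grid can diverge (the log-likelihood is unbounded as
  $\hat\Theta$ chases a pseudo-inverse). Every candidate fit must pass a
  Cholesky positive-definiteness check to enter the BIC comparison;
  non-PD fits are recorded as invalid (`bic = Inf`), and after two
  consecutive invalid fits the remaining smaller $\lambda$ values are skipped.
  At least one valid candidate always exists ($\lambda_{\max}$ gives the
  diagonal model).
* **Unpenalized limit.** $\lambda < 10^{-14}$ triggers direct inversion with
  an escalating ridge jitter, used by the oracle-equivalence tests.
* **Non-convergence.** If the selected fit has not fully converged the last
  iterate is returned with a warning (a count of such events is reported once
  per permutation test rather than thousands of times).
* **Edge-count monotonicity.** The number of edges is monotone in $\lambda$
  only as a strong tendency: exact lasso-path theory allows entries to leave
  the active set as $\lambda$ decreases, and 1–2-edge transient dips occur
  for both the L1 and the atan path. Tests assert bounded transients and net
  densification, not strict monotonicity.
* **BIC early stopping.** Inside permutation loops (thousands of refits) the
  descending grid is abandoned after `bic_early_stop = 6` consecutive
  non-improving values; the selected $\lambda$ is unchanged in practice and
  the skipped tail is recorded as `NaN` in the BIC path. Set it to 0 for the
  full path.

## Descriptive graph analytics

Binary-topology metrics (edge count, density, global clustering, average
shortest path, small-worldness, robustness) are computed on the binarized
nonzero-edge graph; strength-type metrics (weighted degree, participation,
global strength) use absolute weights — matching the mixed conventions of the
brain-graph toolchain this emulates. Specifics:

* **Robustness** is the mean over node-removal orders of the normalized
  largest-connected-component size averaged along the removal sequence.
  Orders are enumerated exhaustively when $p! \le$ `n_orders` (making
  small-graph values exact; $K_N$ gives $(N+1)/2N$), otherwise sampled under
  a seed. Removal is random, not targeted.
* **Average shortest path** is taken over connected pairs only, with the
  disconnected fraction reported alongside; sparse GGM graphs are often
  disconnected and infinite/harmonic conventions would hide that.
* **Small-worldness** is $(C/\langle C_r\rangle)/(L/\langle L_r\rangle)$
  against degree-preserving rewired references (default 100, seeded); it is
  `NaN` for edgeless or clustering-free graphs.
* **Louvain modules** are computed on absolute weights at resolution 1 with
  5 seeded restarts, keeping the best-modularity partition — the plain
  single-sweep heuristic provably stalls on small cycles, and restarts
  restore exact optimality on every graph with up to 5 nodes.
* **Participation coefficients** use each group's own partition;
  $P_i = 1 - \sum_s (k_{is}/k_i)^2$ with absolute strengths, 0 for isolated
  nodes. **Hubs** are nodes with $P_i$ more than one sample standard
  deviation above the mean (strict inequality, so a constant vector has no
  hubs), and hub status across groups is classified lost / preserved /
  reconfigured by set algebra.
* **Community average degree** is the mean within-community binary degree
  divided by community size minus one — a density-like value in $[0,1]$
  comparable across communities of different sizes, which is how published
  per-subnetwork values in that range are read here.

## Permutation network comparison

Two group networks are compared on absolute-difference statistics: global
strength $|S_A - S_B|$, per-node weighted degree, and per-edge
$||w_A| - |w_B||$. The null is built by pooling both groups' subjects,
reassigning labels at random with group sizes preserved (each subject keeps
its covariate values), and re-running the **entire** estimation — BIC
re-selection included — in every permutation; freezing $\lambda$ would break
exchangeability of the procedure. P-values use the add-one convention
$(1 + \#\{T^* \ge T\})/(1 + B)$ and are never exactly zero. Node and edge
families are adjusted by Benjamini–Hochberg (default) or Holm — the original
analysis does not name its correction, so the choice is logged in every
output. Subnetwork analyses (DMN, dorsal dopamine pathway) restrict the
statistic and adjustment families to within-subnetwork nodes/edges;
`compare_networks_multi()` evaluates several restrictions from one shared
permutation stream at no extra estimation cost. Three-group designs are
compared pairwise; no omnibus test is defined.

## Dose-stratified nested cross-validation

The TRS-vs-nTRS classifier is an elastic-net logistic model
($\lambda[\alpha\|\beta\|_1 + (1-\alpha)\|\beta\|_2^2/2]$, glmnet backend).
Hyperparameters are tuned by exhaustive grid search — $\alpha$ over
$\{0, 0.1, \dots, 1\}$ by default and a 50-point log $\lambda$ path derived
from the training data — selected by pooled inner-fold AUC; the original
work tuned the same $(\alpha, \lambda)$ target with a random-forest-based
search whose mechanics are unpublished, and a deterministic exhaustive search
over the identical space is the reproducible substitute. Folds are built
from strata crossing the class label with dose-quantile bins (tertiles by
default), shuffled within stratum under the seed and dealt round-robin, so
every fold spans the dose range; the stated goal (dose balance) is published,
the mechanism here is this package's. Feature standardization uses training
statistics only, inside each fold. Out-of-fold predictions pool into
accuracy (0.5 threshold), AUC with DeLong variance and Wald 95% CI, and the
Brier score; a final CV on all subjects fixes the reported hyperparameters,
and normalized absolute coefficients give variable importance. Pure-noise
inputs yield AUC ≈ 0.5 — the leakage canary in the test suite.

## The synthetic-data generator

No data accompany the study this design emulates, so validation rests on a
generator with analytic ground truth:

* Group precision matrices are modular: unit diagonal, $-r$ on within-module
  pairs ($r$ = `within_module_partial`, default 0.3), optionally also between
  DMN members and between DDP members across anatomical modules, so the
  functional subnetworks are coherent. Patient groups have designated
  DMN/DDP/frontal edges multiplied by $1 - a$ (attenuation, default 0.4) —
  hypoconnectivity as edge weakening, not rewiring, keeping the truth
  analytic.
* Positive definiteness is enforced by diagonal inflation to strict diagonal
  dominance ($\Theta_{ii} = \max(1, 1.05\sum_j|\Theta_{ij}|)$). For modules
  of more than ~3 nodes this deflates the realized partials below $r$; the
  stored truth is always recomputed exactly from the final matrix.
* Subjects are multivariate normal (mean 10 — arbitrary, removed by
  normalization) with a per-subject positive $N(1, 0.1)$ global scale factor
  that the normalization step must remove. Doses are lognormal
  (meanlog 5.5, sdlog 0.5 — median ≈ 245 mg/day CPZ, right-skewed) for
  patients and 0 for controls; an optional confounder adds
  `effect_size` × standardized dose to target regions, and per-group dose
  levels (`meanlog_by_group`) simulate cohorts differing only in medication
  load. Default group sizes are 16/28/26 over 65 regions, matching the
  emulated cohort.
* Everything is bit-reproducible under the config seed.

What the generator does **not** emulate: spatial autocorrelation between
neighboring regions, partial-volume effects, scanner or reconstruction noise
models, non-Gaussian heavy tails, and site effects. A green test therefore
establishes correctness of the statistical machinery under its own
assumptions, not robustness to PET physics.

### Validation worlds

Property tests fix their worlds a priori rather than reusing one default:

* **Type-I calibration** (identical groups, $p = 10$, $n = 30$/group) uses
  five modules of two regions with partials 0.5. With weak signals the
  BIC sits on a knife edge between the empty and a dense graph, the
  global-strength statistic degenerates to two atoms, and the permutation
  test — while still valid — becomes conservative (observed rejection ~0);
  the band $[0.03, 0.08]$ presupposes a continuous statistic, which requires
  detectable structure. Measured rejection in this world: 0.04 over 200
  replicates.
* **Power** (attenuation 0.8 on 10 designated edges, $n = 60$/group) uses
  ten disjoint edges with partials 0.7 so the deficit per edge is 0.56.
  Clique-shaped alternatives dilute the same attenuation through diagonal
  inflation (partials 0.24 → deficit 0.14/edge) and the criterion's 0.8
  power is then out of reach at $n = 60$ — an instructive sensitivity of the
  method to edge strength, recorded here deliberately.
* **Confounding** uses unconnected target regions so any association is
  attributable to dose.

## Reproducibility and cost

Every stage is deterministic given its seed; the pipeline writes a manifest
(seed, package version, config and its MD5 hash, with machine-local paths
excluded from the hash). Cost, measured once on one CPU of the development
container: a p = 65 BIC-path fit takes ~0.8 s (the dense tail near the
rate floor, with its 10 LLA iterations per lambda, dominates), so the full
default synthetic run — three pairwise comparisons sharing permutation
streams across whole-brain/DMN/DDP restrictions at 500 permutations, plus
metrics and the three-feature-set nested CV — took roughly an hour (measured 73 minutes under mild background load), not the
15-minute target; the same run fits the target at `n_perm = 100` or with a
15-point lambda grid, and the scaled variants in the test suite (100
permutations, two groups) complete in ~2 minutes per run. At those sample
sizes (16–28 per group) the default-world group differences are also only
sporadically significant and the TRS-vs-nTRS classifier sits at chance —
as it must, since the default generator attenuates both patient groups
identically; both observations are descriptive checks, not defects. The
test suite runs scaled-down replicates of every property; scaling factors
are noted inline in `tests/testthat/test-acceptance.R`.

## Known limitations

* Intersubject covariance networks are group-level objects; no
  subject-level connectivity or inference on individuals is available, and
  group sizes of 16–28 put wide (unquantified) sampling bands around every
  descriptive metric.
* BIC on exactly singular correlation input can favor dense fits as
  $\lambda$ shrinks; the PD guard bounds but does not remove this, so the
  grid floor (default $0.01\lambda_{\max}$) is part of the estimator.
* The atan/LLA procedure converges to a local optimum; with at most 10
  LLA iterations the unconverged-iterate warning fires occasionally inside
  permutation nulls (counted and reported once per test).
* Accuracy metrics of the classifier on real patients are not reproducible
  here by construction; the package validates calibration and recovery on
  synthetic data only.
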