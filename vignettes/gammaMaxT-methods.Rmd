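---
title: "Methods: MB-MDR interaction scanning with gammaMAXT multiple-testing correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MB-MDR interaction scanning with gammaMAXT multiple-testing correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A genome-wide interaction scan tests every unordered pair of SNPs for
joint association with a trait.  With $s$ SNPs there are
$m = s(s-1)/2$ pairs — $\approx 5 \times 10^{11}$ for a million SNPs —
and the family-wise error rate (FWER) must be controlled across all of
them.  The MB-MDR statistic (below) has no usable closed-form null
distribution, and the pairs are not independent, so permutation-based
step-down maxT is the method of choice.  Its classical form needs the
full $B \times m$ matrix of permuted statistics; the memory-bounded
variant needs only the $n$ best observed statistics plus, per
permutation, the maximum over the remaining $m - n$ pairs — but that
maximum still costs an $O(m)$ scan per permutation.  gammaMAXT replaces
it with a draw from a parametric model of the null statistic
distribution, fitted to a random sample of pairs, making the
permutation cost independent of $m$.

This package implements the full stack — statistic, three maxT
backends, the tail model, simulators, file-based parallel workflow and
CLI — with the heavy per-pair kernel in C++ and everything else in R.

# The MB-MDR pairwise statistic

For a pair $(g_1, g_2)$, subjects are cross-tabulated into the nine
two-locus genotype cells (minor-allele counts 0/1/2 at each locus);
subjects missing either genotype are excluded pairwise.

**Stage 1 (labelling).**  Each cell is tested one-vs-rest for
association with the trait: Pearson chi-squared on the 2×2
case/control collapse (binary traits) or a pooled-variance two-sample
$t$ (continuous traits).  Cells significant at `alpha_cell` (default
0.1, the conventional MB-MDR setting) are labelled `H` when the cell's
risk/mean is above the rest and `L` when below; all other cells —
including cells with fewer than `min_cell` (default 10) subjects,
empty cells and cells whose test is incomputable — are `O`.

**Stage 2 (pooling).**  The `H` cells are pooled and tested against
all other subjects with the same test family; likewise the `L` cells;
the statistic is $T = \max(T_H, T_L)$, with an absent category
contributing 0.  When every cell is `O`, $T$ is an *exact* zero — this
point mass is what the null model below exploits.

Two choices deserve justification:

* **Pooled-variance $t$, not Welch.**  The pooled `H`/`L` groups can
  be very small (a single 10-subject cell).  A Welch $t$ on such a
  group uses only the small group's variance, and its square is
  practically unbounded: on null data the statistic tail then fits a
  gamma with $k \approx 0.4,\ \theta \approx 180$, the tail model
  breaks, and the gamma backend loses FWER control (observed ~30%
  in pilots).  The pooled-variance $t^2$ stays on a
  $\chi^2_1$-like scale; fitted null tails on continuous data are then
  $k \approx 1.0$, $\theta \approx 2.0$ — the regime the method was
  designed for and that the published diagnostics for this algorithm
  report.
* **Minimum cell size 10.**  Risk-labelling cells with a handful of
  subjects injects noise statistics whose extreme tail is *lighter*
  than gamma (bounded by the tiny cell counts), which degrades the
  fitted tail's extrapolation.  A minimal cell count for labelling is
  the published MB-MDR convention; we default to 10, configurable.

**Codominant main-effect correction.**  A pair can rank highly because
one SNP has a main effect.  The correction regresses the trait on the
four codominant dummies of the two SNPs of the pair under test
(`correct_main = TRUE`), and analyses the OLS residuals with the
continuous-trait tests; it is re-applied under every permutation.
Correcting within the pair keeps the cost $O(1)$ per pair: because the
fitted values are constant within the nine cells, the residual cell
sums are obtained from the raw cell counts/sums by solving a 5×5
weighted least-squares system — no per-individual pass.  A global
variant (`correct_main_effects()`) regressing on all SNPs at once is
provided for small panels.

# Step-down maxT and the three backends

Let $T_{0,1} \ge \dots \ge T_{0,n}$ be the stored top statistics.  For
each permutation $i = 1 \dots B$ of the trait: recompute the
statistics of the stored pairs, obtain the maximum $M_i$ over the
other $m - n$ pairs, replace the last stored entry by $M_i$ if larger,
and force the vector non-increasing (suffix maximum).  The adjusted
p-value of rank $j$ is $(1 + \#\{i : T_{i,j} \ge T_{0,j}\})/(B+1)$,
then made non-decreasing in $j$.  Consequently every p-value lies in
$[1/(B+1), 1]$.

* `backend = "classical"` recomputes all $m$ statistics per
  permutation and takes successive maxima over the observed ranking —
  the textbook procedure, quadratic memory in SNPs, used as the exact
  oracle on small panels.
* `backend = "exact"` computes $M_i$ exhaustively (memory $O(n)$).
  Its top-$n$ adjusted p-values equal the classical ones *exactly*
  under shared permutation streams (a tested invariant).
* `backend = "gamma"` samples $M_i$ from the tail model below.

Ties in the observed ranking are broken by lexicographic pair index,
making all outputs deterministic.

**RNG discipline.**  One master seed generates a seed per permutation;
each permutation re-seeds the RNG.  Serial runs, block-partitioned
runs (`permute_block()`/`aggregate_counts()`) and different backends
therefore see identical trait permutations.  Permutation blocks are
aligned to the refit schedule so a cached tail fit never has to cross
a worker boundary.

# The point-mass + shifted-gamma null model

Under permutation, a randomly chosen non-top pair statistic
$\mathcal{X}$ is zero with probability $1 - \pi$ (the all-`O` tables)
and otherwise positive with some density.  Only the upper tail
matters for a maximum, so the model fits the top `tail_fraction`
(default 10%) of positive values with a shifted gamma:
$F_Y(y) = \gamma(k, (y - y_0)/\theta)\,/\,\Gamma(k)$, where $y_0$ is
the location (the trimmed sample's minimum), $k$ the shape and
$\theta$ the scale.  The number of statistics expected to fall in the
modelled tail is $q = (m - n)\,\pi \cdot \texttt{tail\_fraction}$, and
the maximum over them has CDF $F_Z(z) = F_Y(z)^q$ ($q$ is used as a
real exponent; $q = 0$ gives the empty-max convention $F_Z \equiv 1$).

Estimation per refit (default every `refit_interval = 20`
permutations, under that permutation's trait):

1. sample pair indices uniformly with replacement from the $m - n$
   non-stored pairs, evaluating statistics on demand, until $S$
   (default $10^6$, capped at $\max(100, m-n)$ on small panels)
   strictly positive values are collected; count zeros in $z$;
2. $\hat\pi = S/(z + S)$;
3. sort, keep the top `tail_fraction`; $\hat y_0 = \min v$;
4. $\hat k$: with
   $s = \ln \bar w - \overline{\ln w}$, $w = v - \hat y_0$
   (values equal to $\hat y_0$ are excluded from both averages — they
   would make the log diverge), start from the closed form
   $k_0 = (3 - s + \sqrt{(s-3)^2 + 24 s})/(12 s)$ (within about 1.5%
   of the MLE, an assertion the test suite checks) and Newton–Raphson
   on $\ln k - \psi(k) = s$ using digamma/trigamma to `precision`
   ($10^{-6}$);
5. $\hat\theta = \bar w / \hat k$.

$M_i$ is then sampled by inverse CDF via bisection: a deliberately
high initial guess (default 1000, doubled if its CDF is still below
the uniform draw) with a step that halves each iteration until it is
below `precision`.

**Degenerate inputs.**  On tiny panels the tail sample can be
(essentially) constant — fewer distinct pairs than the trim needs.
The fit is then flagged degenerate and the sampled maximum is the
constant itself, keeping toy runs well-defined.  An all-zero source
aborts with an explicit "degenerate null" error after `1000 * S`
draws.

# Synthetic data: the stated world

* **Null datasets** (`simulate_null()`): per-SNP minor allele
  frequencies uniform on $[0.05, 0.5]$, Hardy–Weinberg genotypes, and
  a balanced binary trait (exactly $\lfloor n/2 \rfloor$ cases,
  assigned independently of genotypes) or a standard normal trait.
* **Epistasis datasets** (`simulate_epistasis()`): two functional SNPs
  follow a 3×3 penetrance table; the reference model is the
  0/0.1 checkerboard at MAF 0.5 (prevalence $K = 0.05$, heritability
  $h^2 = 0.0025/0.0475 \approx 0.0526$); all other SNPs are null.
  Case/control datasets are balanced by rejection sampling of
  individuals.  The continuous variant sets
  trait $= \mu z + N(0,1)$ with $z$ the standardized penetrance
  deviation of the individual's two-locus cell and
  $\mu = \sqrt{h^2/(1-h^2)}$, so the model explains the target
  variance share.
* **Heritability** is variance explained on the penetrance scale,
  $h^2 = \sum_g p_g (f_g - K)^2 / K(1-K)$, the definition used by the
  standard two-locus epistasis simulators.
  `calibrate_penetrance()` scales the amplitude of a zero-main-effect
  pattern $K + a\,(u \otimes u)$ — $u$ orthogonal to the
  Hardy–Weinberg weights, reducing to the ±1 checkerboard at MAF
  0.5 — by scalar root-finding until the heritability matches to
  $10^{-6}$.  Margins stay flat (no main effects) at any MAF by
  construction.
* **Missingness** (`inject_missing()`): each genotype call is masked
  independently (5% in the reference datasets); the trait is never
  masked.

What the generators do *not* emulate: linkage disequilibrium,
population structure, covariates, genotyping-error patterns, and the
"random architecture" penetrance tables of the GAMETES simulator — our
power curves therefore need not match published power values at low
heritability, where architecture details dominate.  A green test
establishes correctness of the algorithms on this stated world, not
transferability to arbitrary real cohorts.

# Numerical and design choices

* Chi-squared tests are Pearson without continuity correction;
  stage-1 binary significance compares against
  $\chi^2_{1,1-\alpha}$ directly.
* Tail sampling is with replacement (memoryless, $O(1)$ per draw);
  draws hitting stored pairs are redrawn and not counted.
* The refit schedule "permutations $1, 21, 41, \dots$" is kept
  verbatim; intermediate permutations reuse the cached fit.
* `S` auto-caps at $m - n$ so that toy panels run; with replacement
  this only reduces the (already ample) sample.
* p-values are reported at full double precision; SNP indices are
  1-based in all files.
* The experiments in the acceptance suite run with the codominant
  main-effect correction switched on, matching the configuration the
  reference software used for its own FWER/power studies.

# Known limitations

* The sampled $M_i$ inherits the shifted-gamma extrapolation.  With
  the main-effect correction on (the reference configuration) the
  gamma backend is well calibrated in our experiments: 400 null
  datasets at the reduced scale give an overall FWER of about 5%
  (binary) and 3.5% (continuous).  A *single* batch of 100 datasets
  has a standard error of about 2 percentage points, so the
  per-batch Bradley band check [2.5%, 7.5%] is itself a noisy
  instrument — an individual batch can land just outside the band
  while the method is calibrated.  Without the correction the raw
  binary chi-squared statistic has a lighter-than-gamma extreme tail
  and the backend becomes conservative (FWER ~2%), never
  anticonservative.
* The zero-mass $\pi$ of our statistic does not exactly reproduce the
  reference software's published diagnostics (whose stage-1
  internals are not fully documented); location, shape and scale of
  the fitted tail do.
* Only pairwise interactions and a single trait column are supported;
  censored traits and higher-order scans are out of scope.
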