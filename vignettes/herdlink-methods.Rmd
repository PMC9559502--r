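---
title: "Across-herd genetic evaluation with herdlink: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Across-herd genetic evaluation with herdlink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Litter size — here the number of piglets born alive per farrowing (NBA) —
is the central reproductive trait in pig breeding programmes. It has low
heritability (typically 0.05–0.15), is expressed only in females, repeats
over a sow's parities, and is recorded across herds that differ in
management. Estimating breeding values (EBVs) jointly across herds is
attractive because information flows between herds through shared genetics,
but a joint evaluation is only trustworthy if the herds are *connected*:
herd effects and genetic effects must be separable in the data. herdlink
implements the full tool chain for this question: the repeatability animal
model for NBA, EM-REML variance components, BLUP with exact prediction
error variances, the connectedness rating (CR) between herds, gene-flow
(GF) contribution matrices, and a multi-herd breeding-program simulator
that serves as the test bed.

## The model

Each farrowing record is modelled as

$$ y = Xb + Z_l l + Z_p p + Z_a a + e $$

with fixed effects (parity; mating season as year × month; sow genotype;
litter sire; herd, when several herds are analysed together; a
weaning-to-conception interval class; quadratic age-at-farrowing nested
within parity; linear previous-lactation length) and three random terms:

* $l \sim N(0, I\sigma^2_l)$ — the common environment of the litter the
  *sow herself was born in* (shared by full/half sisters reared together);
* $p \sim N(0, I\sigma^2_p)$ — the sow's permanent environment, shared by
  her repeated parities (the repeatability treatment of NBA: one trait,
  repeated records);
* $a \sim N(0, A\sigma^2_a)$ — the additive genetic effect, with $A$ the
  numerator relationship matrix from the pedigree;
* $e \sim N(0, I\sigma^2_e)$ residual.

Ratios on the phenotypic scale ($h^2$, $p^2$, $l^2$, $e^2$) are the
components divided by $\sigma^2_{ph} = \sigma^2_a+\sigma^2_p+\sigma^2_l+\sigma^2_e$.

## Pedigree machinery

`pedigree()` validates (unique ids, no self-parentage, acyclic, sires male,
dams female) and topologically orders records; unknown parents are coded 0
and an animal with both parents unknown is a *base animal*. Inbreeding uses
a Meuwissen–Luo style traversal (exact, $O(n \cdot \text{ancestors})$,
implemented in C++); the dense tabular $A$ (`build_A_tabular()`) is kept as
the brute-force oracle, while `build_A_inverse()` builds the sparse
$A^{-1}$ directly by Henderson's rules with Mendelian-sampling variances
that account for parental inbreeding. A single known parent uses the
standard half-parent rule. The gene-flow decomposition
$A = TWT'$ (`build_T_W()`) shares the same Mendelian variances; the test
suite verifies $A^{-1}A = I$ and $TWT' = A$ against the tabular oracle on
random pedigrees.

## Solving and prediction error

The mixed-model equations are assembled sparsely (Matrix package) and
solved by a direct simplicial Cholesky factorization — no iterative solver,
so solutions are bit-reproducible. Prediction error variances come from
the *exact* diagonal of the inverse coefficient matrix, computed by
Takahashi/Erisman–Tinney selected inversion on the Cholesky pattern
(C++, Davis-style dense-scatter recurrence). Reliability is
$r^2 = 1 - \mathrm{PEV}/\sigma^2_a$, using the population additive variance
(not $(1+F_i)\sigma^2_a$), clipped to $[0,1]$ only against numerical noise.
An animal with no records and no phenotyped relatives has
$\mathrm{PEV} = \sigma^2_a$ and hence reliability exactly 0.

## EM-REML

`em_reml()` iterates the classical EM updates
$\hat\sigma^2_k = (\hat u_k' K_k \hat u_k + \sigma^2_e\,\mathrm{tr}(K_k C^{kk}))/q_k$
and $\hat\sigma^2_e = y'(y - W\hat s)/(n - \mathrm{rank}(X))$, with all
traces taken from the selected inverse — no stochastic trace estimation.
The restricted log-likelihood is evaluated every iteration through the
identity $\log|V| + \log|X'V^{-1}X| = \log|R| + \log|G| + \log|C/\sigma^2_e|$
(verified against a dense computation in the tests) and is monotone
non-decreasing across the recorded trace.

Plain EM crawls when a component is small relative to the residual (the
$l$/$p$ direction of NBA models is notoriously flat), so the default adds
SQUAREM-style extrapolation on the log-variance scale with backtracking:
an accelerated point is accepted only if its restricted likelihood (a cheap
factorize-and-solve, no selected inversion) is at least that of the plain
double-EM alternative. Monotonicity is therefore preserved by construction.
Starting values are 10/10/5/75 % of the raw phenotypic variance for
a/p/l/e; components are floored at $10^{-8}$ with a boundary flag.
Standard errors of components are not estimated (EM provides none); report
tables print `NA` there.

## Connectedness rating

CR between herds $i$ and $j$ is the correlation of the estimation errors of
their herd effects,
$\mathrm{CR}_{ij} = \mathrm{Cov}(\hat h_i, \hat h_j) / \sqrt{\mathrm{Var}(\hat h_i)\mathrm{Var}(\hat h_j)}$,
read off the herd block of the inverse MME coefficient matrix times
$\sigma^2_e$. Identifiability convention: the herd factor keeps **all**
levels and the intercept is dropped, so herd effects are directly
estimable; all other factors are reference coded. CR is reported as a
proportion in $[-1, 1]$ (the reference literature prints values like 0.983
and compares them with a "1.5 %" threshold — internally inconsistent by a
factor 100; we treat the threshold as the proportion 0.015, configurable in
`cr_report()`). Small negative numerical covariances are reported as-is.

**Which fixed effects enter the CR model matters.** Any factor whose levels
span herds (a global parity effect, say) statistically connects herds even
when they share no genetics: the herd-effect estimates then co-vary through
the jointly estimated global levels. That is a real phenomenon — the CR
literature is explicit that unrelated animals can be "connected" through
shared management groups — but it obscures the question the simulated
scenarios ask, namely how *genetic* links (AI boars, traded gilts) create
connectedness. The scenario model (`model_spec_scenario()`) therefore nests
season and parity within herd and keeps the litter-sire fixed effect
global: two simulated herds are then connected only through animals, and a
genetically disconnected population gives an exactly block-diagonal
coefficient matrix and CR = 0. The full model (`model_spec()`) with global
factors remains the default for variance-component estimation.

## Gene flow

The fraction of animal $i$'s genome descending from each base animal is the
$i$-th row of $T$; summing base columns by herd of origin (the $Q$
incidence) and averaging over the phenotyped animals of a herd gives the
herd × origin-herd contribution matrix, rows summing to 1. At scale the
package never forms $T$: contributions follow the pedigree recursion
$M_i = \tfrac12 M_{s(i)} + \tfrac12 M_{d(i)}$. An animal with one unknown
parent contributes that phantom half to its own herd (a documented
convention; the spec of the method leaves it open), which preserves the
row-sum invariant. The herd of origin of a base animal is the herd of its
own pedigree record.

## The simulator: a stated world

`scenario_presets()` fixes three worlds at roughly 1/20 of the reference
population's volume (about 2,900 farrowings over 10 years across herds
A ≈ 80, B ≈ 28, C ≈ 40 sows; `scale` multiplies sizes):

* **disconnected** — no AI sharing, no gilt trade, purebred only;
* **ai_connected** — herd B's AI centre sires 30 % of purebred nucleus
  matings in A and C; 6 % of A/C replacements are B-born gilts;
* **ai_connected_with_crossbreds** — additionally 70 % of purebred matings
  in A and C produce reciprocal F1 litters (LxLW / LWxL), and cross matings
  (as well as the later matings of F1 sows) take their semen from the AI
  centre. This mirrors the mechanism described for the reference
  population, where the AI centre's boars of one breed inseminated sows of
  the other, and it is what makes adding crossbred records *increase* CR.

True variance components default to the purebred three-herd estimates
(0.825, 1.171, 0.189, 10.324 piglets²; crossbred world: 0.970, 0.727,
0.181, 8.754), baseline NBA 16.05 with herd deviations (+0.13, −2.05,
+0.83) matching the reference herd means, small parity/season/genotype
effects (≤ 0.5 piglet; season SD 0.3, drawn per herd-year-month), and
realistic covariate ranges. Breeding values are sampled down the pedigree
with inbreeding-adjusted Mendelian variances; NBA is continuous by default
(the analysis model is Gaussian; integer rounding is a robustness option,
not the correctness mode). Selection is random so the realized components
stay at their configured values. Fixed-effect magnitudes are documented,
deliberately arbitrary choices.

What the simulator does **not** emulate: truncation selection on EBV,
culling on performance, heterogeneous residual variances across herds,
seasonality of litter size, or genotype-specific variance. A green test
therefore establishes that the estimation machinery recovers the stated
world, not that real Serbian farm data would reproduce any particular
number.

## Numerical choices and degenerate inputs

* Reference coding: drop-first per factor; one level per herd for factors
  nested within herd; one sire per home herd for the litter-sire factor
  (keeps the fixed part full rank when sires never cross herds). The
  weaning-interval factor drops both its "not applicable" class (parity 1)
  and one real class, because the real classes jointly equal the
  parity-over-1 indicator.
* Residual stochastic rank deficiencies (a season reached by a single
  parity can disconnect a within-herd two-way table) are repaired by
  dropping the dependent columns, found by LINPACK QR, which pivots only
  negligible columns so earlier blocks — herd first — are always kept.
  `solve_mme()` still fails loudly if the assembled system is singular.
* Covariates are centered on the analysed subset's mean, recomputed per
  dataset variant; first-parity records take the value 0 (the mean) for
  previous-lactation length.
* EM components are floored at $10^{-8}$; convergence is the maximum
  relative parameter change over one EM step (default $10^{-6}$; the
  acceptance suite uses $10^{-4}$ with a 100-step cap purely for runtime,
  which the test file states).
* Zero-variance random terms are dropped from the MME with a warning;
  an all-zero phenotypic variance is an error.

## Known limitations

* EM-REML, even accelerated, is slow on the flat $l$–$p$ ridge typical of
  NBA models; interval estimates of $\sigma^2_l$ at desk scale are wide,
  and early stopping leaves the split between $l$ and $p$ less settled
  than $\sigma^2_a$ and $\sigma^2_e$. AI-REML would fix this and is left
  as an extension.
* Reliabilities in the simulated worlds (≈ 0.15–0.4 for sows with records)
  are lower than the 0.5–0.87 of the reference tables: reliability rises
  with herd size, pedigree depth and progeny counts, all of which are
  ~1/20 of the reference volumes here. The *directional* statements
  (joint evaluation helps the weakest herd; connectedness raises with AI
  sharing and with crossbred records) are scale-robust and are what the
  acceptance suite asserts.
* CR magnitudes under the scenario model (genetics-only connectedness) are
  far below the reference values of 0.8–0.99, which include the
  statistical connectedness of globally shared fixed effects; see the CR
  section above for why the scenario model isolates the genetic channel.
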