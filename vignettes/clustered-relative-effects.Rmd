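---
title: "Rank-based relative effects for clustered data: models, tests and design choices"
author: "nparcluster"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based relative effects for clustered data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nparcluster)
```

## Why clustered rank methods

Many trials observe each subject more than once under the same
condition: both hemispheres of a patient are graded, several teeth of
one mouth are scored, animals in one cage are weighed. The replicates
form a *cluster* — independent across subjects, dependent within — and
the outcome is frequently ordinal or heavily non-normal, so neither the
mean nor a Gaussian mixed model is a defensible basis for a treatment
effect. `nparcluster` instead works with the relative
(Wilcoxon–Mann–Whitney) effect

$$p_i = \int F_\theta \, dF_i
      = P(G < X_{ijk}) + \tfrac12 P(G = X_{ijk}),
      \qquad G \sim F_\theta = \sum_s \theta_s F_s,$$

the probability that a draw from a weighted mixture of all group
distributions is smaller than an observation from group $i$. All
distribution functions are used in their normalized (mid) form
$F = (F^- + F^+)/2$, which is what makes every statement below valid
verbatim for ties, ordinal codes and dichotomous outcomes. Effects are
compared through contrasts $Cp$; `p_i = p_j` means "observations from
the two groups tend neither to be smaller nor larger", without any
location-shift or equal-variance assumption — a genuinely nonparametric
Behrens–Fisher formulation. Pairwise-defined effects
$P(X_i < X_j) + \frac12 P(X_i = X_j)$ are deliberately not used: they
can be non-transitive (paradoxical-dice behaviour), whereas all effects
here are measured against one common reference distribution.

## Estimation

With cluster weights $\omega_{ijk}$ (summing to one within each
cluster), $\psi_{ij}$ (within each group) and reference weights
$\theta_i$, the empirical distribution functions
$\hat F_{i\psi} = \sum_j \psi_{ij} \sum_k \omega_{ijk} \hat F_{ijk}$
plug in to give
$\hat p_i = \int \hat F_\theta \, d\hat F_{i\psi}$, a weighted mean of
the placements $\hat F_\theta(X_{ijk})$. Two presets cover the common
cases:

| preset | $\omega_{ijk}$ | $\psi_{ij}$ | $\theta_i$ | $g(n)$ | computed via |
|---|---|---|---|---|---|
| `unweighted` | $1/m_{ij}$ | $1/n_i$ | $1/d$ | $n$ (clusters) | pseudo-ranks |
| `weighted`   | $1/m_{ij}$ | $m_{ij}/M_i$ | $M_i/M$ | $M$ (observations) | mid-ranks |

The unweighted preset is the default throughout: effects defined
against $M_i/M$-weighted references change with sample-size allocation,
which is rarely what a trial wants to estimate. Variance-based or
hierarchical group weightings enter as custom $\theta$; the package
does not try to estimate a variance-based $\theta$ itself, because for
ordinal data the groupwise variance that would drive it is not a
well-defined target — users who want such weights must supply them.

Internally $\hat p$ is computed from one EDF evaluation per observation
($O(M \log M)$); the exported `relative_effects_oracle()` recomputes it
by the explicit $O(M^2)$ double sum over weighted observation pairs and
is used in the test suite to pin the implementation down to $10^{-12}$.
Ties are resolved by exact value equality, never by tolerance: the
half-mass terms are the whole point of the normalized EDF, and a fuzzy
comparison would silently redefine the estimand.

### Ranks

The global rank representation used for the ANOVA-type denominator df is
$R_{ijk} = M\,\hat F_\theta(X_{ijk}) + \frac12$ with $M$ the total
number of observations: under the weighted preset this reproduces
textbook mid-ranks exactly (the test suite asserts `1, 2.5, 2.5, 4` for
pooled data `1, 2, 2, 4`), under the unweighted preset it gives
pseudo-ranks. Group-internal ranks use the group-restricted EDF, whose
$\psi, \omega$ weights are already normalized within the group.

## Covariance estimation

$\sqrt{g(n)}(\hat p - p)$ is asymptotically a sum of independent
per-cluster influence vectors $A_{ij}$; their observable counterparts
$\hat A_{ij}$ are built from the cluster placements
$\hat Y_{ij}^{(c)} = \sum_k \omega_{ijk} \hat F_{c\psi}(X_{ijk})$. The
estimator

$$\hat\Sigma = g(n) \sum_i \sum_j \frac{\psi_{ij}^2}{\kappa_{ij}}
   (\hat A_{ij} - \bar A_{i\cdot})(\hat A_{ij} - \bar A_{i\cdot})',
   \qquad \kappa_{ij} = 1 - 2\psi_{ij} + \sum_{j'} \psi_{ij'}^2,$$

is symmetric and positive semidefinite by construction; the
$\kappa$-correction removes the bias created by centering at the
weighted cluster mean (for equal weights it is the familiar
$1 - 1/n_i$). It also explains the hard requirement of **at least two
clusters per group** for any variance-based inference: with
$n_i = 1$, $\psi_{ij} = 1$ and $\kappa_{ij} = 0$.

A scaling convention had to be fixed, because the quantity standardized
by $g(n)$ appears in several equivalent-looking but mutually
inconsistent square-root placements. The package uses one convention
everywhere: $\hat\Sigma$ estimates the covariance of
$\sqrt{g(n)}(\hat p - p)$, contrast statistics are
$T_l = \sqrt{g(n)/\hat\Upsilon_{ll}}\; c_l'\hat p$ with
$\hat\Upsilon = C\hat\Sigma C'$, and interval half-widths are
$c^{(m)} \sqrt{\hat\Upsilon_{ll}/g(n)}$. This is the only scaling under
which the covariance formula, the quadratic forms and the confidence
intervals are simultaneously consistent, and under which the simulated
levels recover the nominal $\alpha$; the Monte-Carlo unbiasedness test
in `test-variance.R` checks the convention directly against the
empirical covariance of $\sqrt{g(n)}\,\hat p$.

## Global tests

The Wald-type statistic
$Q_w = g(n)\,\hat p'C'(C\hat\Sigma C')^+ C\hat p$ uses a Moore–Penrose
inverse (singular values below $10^{-8}$ of the largest are treated as
zero; the resulting rank is the χ² df). It ignores the sampling
variability of $\hat\Sigma$ and is liberal in small samples — the
simulation harness reproduces this, and the statistic is reported
mainly as a comparator.

The ANOVA-type statistic $Q_a = g(n)\,\hat p' M \hat p / tr(M\hat\Sigma)$
(with $M$ the projection onto the row space of $C$, so any two contrast
matrices with equal row space give identical results) is referred to
$F(\hat f_1, \hat f_2)$. The numerator df is the Box-type
$\hat f_1 = tr(M\hat\Sigma)^2 / tr(M\hat\Sigma M\hat\Sigma)$; the
denominator df is estimated from groupwise variances of
"global minus internal rank" residuals,

$$S_i^2 = \frac{1}{n_i - 1}\sum_{j,k} \omega_{ijk}
  \bigl(R_{ijk} - R^{(i)}_{ijk} - \bar R_{i\cdot} + \tfrac{M_i+1}{2}\bigr)^2,
  \qquad
  \hat f_2 = \frac{\bigl(\sum_i S_i^2/(n - n_i)\bigr)^2}
                  {\sum_i (S_i^2/(n-n_i))^2 / (n_i - 1)}.$$

The inner sum is weighted by $\omega_{ijk}$ alone (no $\psi$ factor):
this follows the printed definition; for both presets' uniform
within-group weights the question is moot, and for exotic custom
$\psi$ the denominator df is at worst an approximation to an
approximation. A `chi2` variant ($\chi^2_{\hat f_1}/\hat f_1$) is kept
because it is the natural asymptotic reference and demonstrably more
liberal — a useful contrast in teaching and in the simulation harness.
For $d = 2$ with singleton clusters and the weighted preset, $Q_a$,
$\hat f_1 = 1$ and $\hat f_2$ reduce *exactly* to the Brunner–Munzel
test; the acceptance suite checks statistic and df against an
independent textbook implementation at $10^{-10}$ on 100 datasets.

Tests of the strict hypothesis of equal distribution functions reuse
the same quadratic forms with the covariance replaced by its
simplification under that hypothesis,
$g(n)\,\mathrm{diag}(\hat\sigma_1^2, \ldots, \hat\sigma_d^2)$, where
$\hat\sigma_i^2$ is the $\psi^2/\kappa$-weighted variability of the
group-internal cluster placements.

## Multiple contrast test procedures

The vector $T = (T_1, \ldots, T_q)'$ is asymptotically multivariate
normal with correlation
$R = \mathrm{diag}(\Upsilon)^{-1/2}\,\Upsilon\,\mathrm{diag}(\Upsilon)^{-1/2}$;
for small samples it is referred to a central multivariate t with
estimated $\hat R$ and the conservative family df
$\hat\nu = \max\{1, \min_l \hat\nu_l\}$, one scalar for the whole
family as required by the multivariate t. Each $\hat\nu_l$ is a
Welch–Satterthwaite ratio of the groupwise variance components
$\hat v_{li}^2 = \sum_j \psi_{ij}^2 \kappa_{ij}^{-1}
(\hat\Lambda_{lij} - \bar\Lambda_{li\cdot})^2$ of the projected
influence values $\hat\Lambda_{lij} = c_l'\hat A_{ij}$. The
$\psi_{ij}^2$ weighting (rather than $\psi_{ij}$) was a genuine open
choice; it was adopted because it matches the covariance estimator's
weighting, and because it is the unique variant whose two-sample
singleton-cluster reduction equals the Brunner–Munzel/Welch df exactly
(the $\psi^1$ variant reduces to
$(\sum_i \hat\sigma_i^2)^2 / \sum_i \hat\sigma_i^4/(n_i-1)$, which is
not the Welch form). The sensitivity is nil for balanced designs and
small for the presets, whose $\psi_{ij}$ are constant within group.

Rejections use the two-sided equicoordinate quantile of
$N(0, \hat R)$ or $t_{\hat\nu}(\hat R)$; adjusted p-values evaluate the
same central rectangle at the observed $|t_l|$,
$p_l = 1 - P(\max_m |T_m| \le |t_l|)$, and the global max-test p-value
is their minimum — consonance of global and per-contrast decisions is
structural, and the test suite asserts it.

### Range preservation

Raw intervals $c_l'\hat p \mp c^{(m)}\sqrt{\hat\Upsilon_{ll}/g(n)}$ can
escape $[-1, 1]$. The default therefore applies the Fisher
transformation $\zeta(x) = \mathrm{atanh}(x)$ to contrasts of normed
rows ($|c_{li}| \le 1$): the delta method gives
$\Gamma = \eta\,\Upsilon\,\eta'$ with
$\eta = \mathrm{diag}\bigl((1-\delta_l^2)^{-1}\bigr)$, the statistics
$\tilde T_l = \sqrt{g(n)/\hat\Gamma_{ll}}\,\zeta(\hat\delta_l)$ share
the correlation matrix $R$ (the Jacobian is diagonal), and the
back-transformed intervals $\tanh(\zeta(\hat\delta_l) \mp
c^{(m)}\sqrt{\hat\Gamma_{ll}/g(n)})$ are strictly inside $(-1, 1)$.
Estimates at the boundary $\pm 1$ (possible with completely separated
tiny samples) are clipped to $\pm(1 - 10^{-12})$ with a warning before
transforming.

Per-group simultaneous intervals (the descriptive table of
`npc_analyze()`) reuse exactly this machinery on the centered effects
$p_i - \frac12 \in (-\frac12, \frac12)$ with the identity as the
"contrast" family, shifting back by $\frac12$; the reported per-group
standard deviation is $\sqrt{\hat\Sigma_{ii}}$. This construction is a
package design choice — a defensible joint-coverage analogue of the
contrast intervals — rather than a canonical definition.

## Numerical choices

* **Rectangle probabilities.** $P(\max_l |T_l| \le c)$ is computed by
  the randomized quasi-Monte-Carlo algorithm of Genz and Bretz
  (`mvtnorm::pmvnorm`) with a fixed integration seed (default
  `20241111`), so critical values and p-values are reproducible
  bit-for-bit; the ambient RNG stream is saved and restored around each
  call. The multivariate t with *non-integer* df (the Satterthwaite
  $\hat\nu$ is real-valued) is evaluated as a chi-scale mixture of
  normal rectangles, $\int_0^1 P(|Z| \le c\,s(u))\,du$ with
  $s(u) = \sqrt{\chi^{2,-1}_\nu(u)/\nu}$, by 32-node Gauss–Legendre
  quadrature (24 nodes in the simulation fast path); against
  integer-df references this is accurate to about $10^{-5}$.
* **Quantiles** are found by bracketing from the univariate quantile
  (a lower bound) and bisection to a bracket width of $10^{-4}$.
* **Degenerate correlation.** Coordinates that are perfectly
  (anti-)correlated are collapsed before integration — on a symmetric
  rectangle $|T_a| = |T_b|$ when $|r_{ab}| = 1$ — which is exactly the
  situation created by the $d = 2$ centering family. Indefiniteness of
  $\hat R$ from floating point is repaired by eigenvalue clipping at
  zero plus renormalization to unit diagonal; negative eigenvalues of
  $\hat\Sigma$ are never clipped inside test statistics, only inside
  PSD assertions.
* **Pseudo-inverse tolerance** is $10^{-8}$ relative to the largest
  singular value, and the resulting rank is reported as the Wald df.

## The simulation harness, and what it does not show

`sim_model()` + `run_study()` regenerate the package's operating
characteristics: marginals normal / beta(2, 5) / Poisson(5) /
binomial(5, 0.6); within-cluster dependence via a **Gaussian copula**
whose latent correlation matrix is either equicorrelated
(homogeneous, $\rho_{max}$) or a unit-diagonal outer product of
$U(\rho_{min}, \rho_{max})$ draws (heterogeneous); imbalance either
mild (cluster sizes drawn from $\max(m^*-3, 2), \ldots, m^*+3$, group
sizes from $n^*-3, \ldots, n^*+3$) or severe (one cluster of 2 and one
of 15 per group; one group of 8 and one of 25). Alternatives shift the
marginal parameters with a factor $r$ (normal $\mu_i = r\,i$,
$\sigma_i = 0.7 + 0.1\,i$; beta $(2 + r(i-1),\, 4 - r(i-1))$; Poisson
$\lambda_i = 5 + r\,i$).

The copula is a modelling choice: the study design fixes marginals and
a correlation matrix but not the joint law, and no adjustment is made
for the (small) attenuation of Pearson correlation under the marginal
transforms. Consequently the harness demonstrates level and power under
*one* realistic dependence mechanism with *exchangeable-ish* positive
dependence; passing studies do not certify behaviour under negative or
tail-asymmetric dependence, informative cluster sizes (where the
outcome distribution depends on $m_{ij}$ — expressly outside the model,
since all $X_{ijk} \sim F_i$), or covariate-driven heterogeneity, none
of which the methods claim to handle.

Problem sizes were chosen to make the Monte-Carlo evidence meaningful
while keeping the default suite quick: the level studies use 2000
replicates (Monte-Carlo SE $\approx 0.005$ at the 0.05 level, so the
assertion band $0.05 \pm 0.015$ is $\pm 3$ SE), the power-monotonicity
study 1000 replicates at $r \in \{0.05, 0.25, 0.5\}$, and both run at
$d \in \{2, 3\}$, $n_i = 20$, $m = 4$. The simulation fast path
computes the MCTP decision from the global adjusted p-value (one
rectangle integral per replicate) instead of a quantile search; the two
decisions are equivalent by monotonicity of the rectangle probability
in $c$.

## Known limitations

* No covariate adjustment; the design is a pure $d$-sample layout, and
  crossed factorial structures must be flattened into cells by the
  user.
* No missing-data machinery: an "unknown" category is treated as its
  own group (as in the motivating bilateral grading application), not
  imputed.
* The weighted (classical-rank) scheme is known from the package's own
  studies to misbehave under severe imbalance; the unweighted scheme is
  the default for a reason.
* Single-step MCTPs only — no step-down refinement — and no
  permutation or bootstrap alternatives to the asymptotic/t
  approximations.
* The shipped `moyamoya_synthetic.csv` is a structural stand-in
  (matching group sizes, cluster sizes and the ordinal scale of the
  motivating cohort) generated from the package's own copula model; it
  carries no information about any real patients.
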