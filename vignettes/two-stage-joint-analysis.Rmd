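---
title: "Robust joint analysis of two-stage case-control association studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust joint analysis of two-stage case-control association studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointGWAS)
```

## The design and the model

A two-stage genome-wide association study genotypes all $m$ SNPs on a
fraction $\pi$ of the $r$ cases and $s$ controls (stage 1), carries the
SNPs with stage-1 p-value below $\gamma$ into stage 2 on the remaining
subjects, and controls the genome-wide type-I error $\alpha$ by testing
each SNP at the Bonferroni level $\alpha/m$. Rather than analysing stage
2 alone (replication analysis), the joint analysis combines the two
stage statistics,
$$T_J = \sqrt{\pi}\,T_1 + \sqrt{1-\pi}\,T_2,$$
which preserves the stage-1 information: under the null, $T_1$ and $T_2$
are independent and asymptotically standard normal, so $T_J$ is standard
normal with $\mathrm{Corr}(T_1, T_J) = \sqrt{\pi}$.

Each biallelic SNP has alleles g and G, with G the risk allele, and
genotypes gg, Gg, GG. The disease model is parameterized by the
prevalence $K$, the risk-allele frequency (MAF), and the genotype
relative risks $\lambda_1 = f_1/f_0$, $\lambda_2 = f_2/f_0$, where $f_i$
is the penetrance of genotype $i$. Under Hardy--Weinberg equilibrium
(HWE) in the source population, the prevalence constraint fixes
$f_0 = K/\{\Pr(gg) + \lambda_1 \Pr(Gg) + \lambda_2 \Pr(GG)\}$, and Bayes'
rule gives the case and control genotype distributions
$p_i = \Pr(i)\,f_i/K$ and $q_i = \Pr(i)(1-f_i)/(1-K)$. The recessive,
additive and dominant models correspond to
$\lambda_1 = 1 < \lambda_2$, $2\lambda_1 = \lambda_2 + 1$ and
$\lambda_1 = \lambda_2 > 1$.

## The four joint tests

**ALLEJ** compares case and control risk-allele frequency estimates,
standardized by the pooled-sample binomial variance
$\{1/(2r_k) + 1/(2s_k)\}\,\bar p(1-\bar p)$ with
$\bar p = \hat\theta\xi + \hat\varpi(1-\xi)$, $\xi = r/(r+s)$.

**CATAJ** is the Cochran--Armitage trend test with additive scores
$(0, 1, 2)$; **MERT** combines the two extreme trend tests,
$$T^{\mathrm{mert}} = \frac{T^R + T^D}{\sqrt{2(1+\rho_{RD})}},$$
where $T^R$, $T^D$ use the recessive $(0,0,1)$ and dominant $(0,1,1)$
scores and $\rho_{RD}$ is their null correlation; **MAX3** takes
$\max(|T^R|, |T^A|, |T^D|)$. MERT and MAX3 trade a little power under a
known model for robustness when the model is uncertain -- the situation
of essentially every GWAS hit, since tag SNPs rarely coincide with
causal variants.

Because the additive scores are the sum of the recessive and dominant
scores, the three trend statistics satisfy the exact identity
$T^A = \omega_1 T^R + \omega_2 T^D$ with
$\omega_1 = (\rho_{RA} - \rho_{RD}\rho_{AD})/(1-\rho_{RD}^2)$ (and
symmetrically $\omega_2$), provided all variances are estimated from one
common set of genotype frequencies. Algebraically
$\omega_1 = \sigma_R/\sigma_A$, $\omega_2 = \sigma_D/\sigma_A$. The
identity makes the MAX3 null law two-dimensional: the acceptance region
$\{\max(|T^R|,|T^A|,|T^D|) \le v\}$ is a hexagon in the $(T^R, T^D)$
plane, and `max3_null_tail()` integrates the conditional normal band
over it to an absolute accuracy of about $10^{-12}$.

## Thresholds

For the normal-based methods the stage-1 threshold is
$b_1 = \Phi^{-1}(1-\gamma/2)$ and the joint threshold solves
$$\Pr_{H_0}(|Z_1| > b_1,\ |Z_J| > b_J) = \alpha/m$$
for the standard bivariate normal with correlation $\sqrt{\pi}$. The
package evaluates such rectangle probabilities with its own port of
Genz's Gauss--Legendre algorithm for bivariate-normal orthants
(`bvn_upper()`, absolute accuracy about $5\times 10^{-16}$), assembling
two-sided events from one-sided orthants so that deep-tail values keep
their relative structure; `uniroot()` then solves for $b_J$ to machine
precision in the root. At $\alpha/m = 10^{-7}$ the achieved equation
residual is limited by the kernel's $\sim 10^{-15}$ absolute accuracy,
i.e. about $10^{-8}$ in relative terms. A useful check on the geometry:
$b_J$ *increases* with $\gamma$ toward $\Phi^{-1}(1-\alpha/(2m))$ -- a
looser stage-1 gate admits more null SNPs, whereas a severe gate makes
selection itself strong evidence, relaxing the joint threshold.

For MAX3 the stage-1 threshold $v_1$ solves the hexagon tail equation at
$\gamma$. The joint threshold $v_J$ has no closed form; it is estimated
by a three-step Monte Carlo: draw stage-1 pairs $(T^R_1, T^D_1)$, keep
the $B_1$ draws with stage-1 MAX3 above $v_1$, draw independent stage-2
pairs, form the joint MAX3, and take $v_J$ as the smallest simulated
joint value whose exceedance fraction is admissible
($\le \alpha/(m\gamma)$) and closest to it. Ties (several candidates
with the same admissible fraction) resolve to the smallest value, the
most powerful admissible threshold.

At genome-wide selection levels ($\gamma = 10^{-4}$) naive stage-1
sampling wastes a factor $1/\gamma = 10^4$ of draws.
`conditional_stage1_sampler()` instead samples the conditional law
exactly: the selection event is the union of three slabs $|L_i| > v_1$
for the unit-variance linear functionals $L_1 = T^R$, $L_2 = T^A$,
$L_3 = T^D$; a slab is chosen uniformly (they share the marginal
probability $2\Phi(-v_1)$), the functional is drawn from the two-sided
truncated normal, the orthogonal component from its exact conditional
normal, and the draw is accepted with probability one over the number of
slabs containing it. A draw landing in $k$ slabs is proposed with
density proportional to $k$ times the restricted normal density, so the
$1/k$ thinning reproduces the conditional law exactly (this is verified
in the test suite by two-sample comparison against naive rejection). The
acceptance bookkeeping doubles as an unbiased estimate of the selection
probability, which the tests confirm equals the hexagon integral.

## Power

For ALLEJ/CATAJ/MERTJ the power is the rectangle probability
$\Pr_{H_1}(|T_1| > b_1, |T_J| > b_J)$ under a shifted bivariate normal
with mean $(\mu_1, \sqrt{\pi}\mu_1 + \sqrt{1-\pi}\mu_2)$ and covariance
$\Gamma \Delta \Gamma'$, $\Delta = \mathrm{diag}(\delta_1, \delta_2)$,
where $(\mu_k, \delta_k)$ are the stage-$k$ moments of the statistic
under the alternative. For the allele-frequency test these are the
plug-in forms of the statistic with population frequencies.

For the trend-based statistics, whose numerator is a score contrast $U$
between case and control genotype distributions, two delta-method
bookkeepings are implemented (`standardize =` in `catt_moments()` /
`mert_moments()`):

* `"null"`: $\mu = E(U)/\mathrm{sd}_0(U)$ with the pooled (mixture)
  null variance in the denominator -- the plain asymptotic law of the
  textbook pooled-variance statistic;
* `"alternative"` (default): $\mu = E(U)/\mathrm{sd}_1(U)$, the
  noncentrality standardized under $H_1$ (the convention of the
  classical two-proportion power formula, where the alternative-variance
  standard deviation carries the mean term), with the MERT scaling
  correlation $\rho_{RD}$ evaluated at the case genotype distribution --
  the frequencies in which the association signal lives.

Both use $\delta = \mathrm{Var}_1(U)/\mathrm{Var}_0(U)$ and both reduce
to $(0, 1)$ under the null, so thresholds and type-I error are
identical; they differ only in how second-order terms enter the
alternative approximation, and their power values differ by at most a
few percent in the scenarios below. The package's power tables use the
`"alternative"` convention. The simulation cross-checks in the test
suite simulate whichever statistic variant a convention models (pooled
variance estimates for `"null"`, case/control arms separately and
case-estimated $\rho_{RD}$ for `"alternative"`) and confirm the means to
Monte-Carlo precision. The $\delta$'s are first-order: under strong
alternatives the estimated denominator co-varies with the numerator, a
second-order effect that shifts the finite-sample variance by up to
about $0.05$ at the hardest scenario tested (recessive, MAF 0.15,
2500 subjects per arm); the tests document this with an absolute
$\pm 0.07$ band. Power is tail-mean-dominated, so analytic and empirical
power still agree to a few parts per thousand.

MAX3J power is empirical by construction: with $v_1, v_J$ fixed, 10,000
two-stage multinomial data sets are simulated under the alternative and
the double-exceedance fraction reported with its binomial standard
error. The threshold Monte Carlo (default $B_1 = 10^6$ conditional
draws, i.e. about $10^3$ exceedances at $\alpha/(m\gamma) = 10^{-3}$)
and the power replicates use separate seeds, so the two error sources
can be budgeted separately.

## What the generator emulates -- and what it does not

`simulate_two_stage()` draws genotype counts from independent
multinomials with the model's case/control genotype probabilities, the
same subjects split $\lceil\pi r\rfloor / \lceil\pi s\rfloor$ between
stages (nearest-integer rounding, remainder to stage 2), and both stages
sampling the same source population. This matches the idealized design
the power formulas describe: HWE in the source population, no
genotyping error, no missingness, no linkage disequilibrium between
SNPs, no population stratification, and identical stage populations.
Passing tests therefore validate the mathematics of the procedures, not
their robustness to those real-data violations. The analysis path
(`analyze_snp()`) makes the two concessions real tables need: $\pi$ is
recomputed from genotyped totals and $\xi$ per stage from that stage's
counts.

## Analysis of observed tables

For observed count tables the statistics use their textbook forms
(pooled variance estimates; MERT's $\rho_{RD}$ from the pooled genotype
frequencies, so that swapping the case and control rows exactly negates
AFDT, CATT and MERT and leaves MAX3 unchanged). Because the published
record of the motivating diabetes example does not define its p-value
convention, `analyze_snp()` reports three labelled p-values per method:
the marginal two-sided tail of $T_J$; the selection-adjusted tail
$\Pr_{H_0}(\text{stage-1 exceeds its } \gamma \text{ threshold},
|T_J| > |t_J^{obs}|)$; and the one-sided observed-pair tail
$\Pr_{H_0}(T_1 > t_1^{obs}, T_J > t_J^{obs})$. The significance flag
requires stage-1 selection and the selection-adjusted tail below
$\alpha/m$, which is exactly the threshold-pair rule. MAX3J versions of
these tails use the hexagon integral (marginal, with combined-stage
frequency estimates) and conditional Monte Carlo (joint tails, with
stage-specific estimates).

## Numerical choices and degenerate inputs

* Root finding: `uniroot()` on monotone tail equations, bracket
  $[\tfrac12\Phi^{-1}(1-\alpha/(2m)),\,10]$ expanded on failure,
  machine-precision tolerance in the root.
* The hexagon integral uses `integrate()` at `rel.tol = 1e-12`; the
  threshold equation is solved to $10^{-8}$ in probability or better.
* Truncated-normal draws use log-scale quantile inversion
  (`qnorm(log.p = TRUE)`), stable at $v_1 \approx 4$ and beyond.
* Monomorphic or zero-variance tables raise explicit errors rather than
  returning `NaN`, so multi-SNP pipelines can skip degenerate markers
  deliberately; expected cell counts below 5 trigger a warning.
* A SNP failing stage-1 selection still gets joint p-values but is
  flagged unselected and never declared significant.
* MAF above 0.5 is accepted with a warning (the formulas do not require
  the risk allele to be minor).

## Problem sizes

The shipped tests and the acceptance script run the study's own sizes
where they matter: $10^4$ power replicates per MAX3J cell with $10^6$
conditional threshold draws, $10^5$ tables for null calibration, $10^6$
draws for Monte-Carlo threshold oracles, and a reduced-genome error
simulation of 200 null SNPs $\times$ $10^4$ genome replicates at
$\gamma = 0.05$, $\alpha = 0.05$ -- the $\alpha/m$ Bonferroni scheme at
desk scale. Everything is vectorized across replicates, so the full
suite completes in well under a minute on one core.

## Known limitations

* Asymptotic statistics only; no exact or permutation versions, so very
  sparse tables (rare variants) are outside scope.
* Bonferroni multiplicity only, as in the design being modelled; no FDR.
* SNPs are treated as independent (no LD), and there is no modelling of
  covariates, stratification, or differential genotyping error between
  stages.
* The alternative-hypothesis moment approximations are first-order;
  their finite-sample variance error is documented above.
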