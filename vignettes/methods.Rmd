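---
title: "Methods: ZINB normalization and sparse network inference for microbiome counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ZINB normalization and sparse network inference for microbiome counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Microbiome sequencing yields an $n \times p$ count table $Y$ (samples by
taxa) whose entries are noisy proxies of underlying abundances. Three
pathologies make naive correlation networks unreliable: sequencing depth
varies strongly across samples, counts are overdispersed relative to a
Poisson model, and a large fraction of entries are zero — some because a
taxon is truly absent (*structural* zeros), some because sequencing simply
missed it (*sampling* zeros). `zinbnet` infers a sparse microbial
association network in two stages: a Bayesian zero-inflated negative
binomial (ZINB) normalization that handles all three pathologies, followed
by an $\ell_1$-penalized Gaussian graphical model whose penalty is chosen by
stability selection.

## Stage one: the ZINB-DPP normalization model

Each count is modeled as a mixture of a point mass at zero and a negative
binomial:

$$y_{ij} \sim \pi_i\, I(y_{ij}=0) + (1-\pi_i)\, \mathrm{NB}(\lambda_{ij}, \phi_j),$$

with NB mean $\lambda_{ij}$ and variance
$\lambda_{ij} + \lambda_{ij}^2/\phi_j$ (small $\phi_j$ means strong
overdispersion). The mean factorizes as $\lambda_{ij} = s_i\,\alpha_{ij}$:
$s_i$ is a sample-specific size factor capturing sequencing depth, and
$\alpha_{ij}$ the normalized abundance. Zero-inflation is introduced
through indicators $\eta_{ij} \sim \mathrm{Bernoulli}(\pi_i)$, with
$\pi_i \sim \mathrm{Beta}(a_\pi, b_\pi)$ (flat by default) and
$\phi_j \sim \mathrm{Ga}(0.001, 0.001)$.

Rather than fixing the size factors (total-count, median-of-ratios, and
similar rules all impose a hard constraint that can bias everything
downstream), the log size factors carry a truncated Dirichlet-process
mixture prior. Each mixture component is itself a two-point Gaussian
mixture

$$t_m\,N(\nu_m, \sigma_s^2) + (1-t_m)\,N\!\left(-\tfrac{t_m \nu_m}{1-t_m}, \sigma_s^2\right),$$

whose mean is identically zero for every $(t_m,\nu_m)$ — this enforces the
*stochastic* constraint $E(\log s_i)=0$ while leaving the distribution of
size factors free to be multimodal or skewed. Component weights follow a
stick-breaking construction at truncation $M=\lfloor n/2\rfloor$, with the
unit stick's remainder assigned to the last component.

Log abundances get a conjugate hierarchical Gaussian prior:
$\log\alpha_{ij} \sim N(\mu_j, \sigma_j^2)$, with
$\mu_j \mid \sigma_j^2 \sim N(0, h_0\sigma_j^2)$ and
$\sigma_j^2 \sim \mathrm{IG}(a_0, b_0)$. Integrating $(\mu_j,\sigma_j^2)$
out gives a non-standardized multivariate Student-$t$ marginal for each
taxon's column of log abundances; `dlog_abundance_marginal()` implements
that closed form and the test suite verifies it against direct numerical
integration of the hierarchy.

### The sampler

`fit_zinb_dpp()` runs a Metropolis-within-Gibbs sampler (compiled C++, one
chain, driven by R's RNG so a seed fixes the run bitwise):

1. $\eta_{ij}$ at observed zeros from its exact Bernoulli conditional with
   success probability
   $\pi_i / \{\pi_i + (1-\pi_i)\,\mathrm{NB}(0; s_i\alpha_{ij}, \phi_j)\}$;
2. $\pi_i$ from its conjugate Beta conditional
   $\mathrm{Beta}(a_\pi + \sum_j \eta_{ij},\, b_\pi + \sum_j(1-\eta_{ij}))$;
3. $\phi_j$ by adaptive Gaussian random walk on $\log\phi_j$;
4. $\log\alpha_{ij}$ by per-cell random walk at NB cells, and a direct prior
   draw at point-mass cells (where the likelihood carries no information);
5. $(\mu_j, \sigma_j^2)$ by their conjugate Normal-Inverse-Gamma update.
   Keeping these explicit — instead of working under the marginalized
   Student-$t$ column prior — makes the cells of a column conditionally
   independent, so the vectorized per-cell sweep in step 4 is a valid MH
   scheme and mixes well; the two formulations are the same model.
6. $\log s_i$ by random walk against its NB likelihood and assigned DPP
   component;
7. the DPP block by blocked Gibbs: component labels, inner-mixture
   indicators, conjugate $V_m$ and $\nu_m$ updates, and a logit random walk
   for $t_m$;
8. a likelihood-invariant recentering: $\log s$ is shifted to mean zero and
   the offset moved into $\log\alpha$ ($\lambda_{ij}=s_i\alpha_{ij}$ is
   unchanged). This pins the finite-sample location that the stochastic
   constraint fixes only in expectation, preventing slow random-walk drift.

Random-walk steps start at 0.5 and are tuned every 100 burn-in iterations
toward ~35% acceptance; adaptation stops at burn-in so the retained chain
is a valid Markov chain. Defaults are 10,000 iterations with 5,000 burn-in,
which is past the mixing we observe on simulated fixtures of the sizes used
throughout (tens to hundreds of samples, tens of taxa). All mixture
densities are evaluated in log space with log-sum-exp.

### Zero dichotomization and imputation

For each of the $L$ observed zeros the chain yields
$p_l = \Pr(\eta_l = 1 \mid Y)$, the posterior probability that the zero is
a sampling zero (a missing value) rather than a true absence. Zeros with
*high* $p_l$ are selected for imputation, with the threshold chosen so that
the realized Bayesian false discovery rate

$$\mathrm{FDR}(t) = \frac{\sum_l (1-p_l)\, I(1-p_l < t)}{\sum_l I(1-p_l < t)}$$

stays at or below a nominal $c_\eta$ (`bfdr_select()`; the most permissive
qualifying threshold is used, ties included or excluded together). The
direction of the dichotomy is worth stating explicitly, since the two
readings are easy to confuse: the selection formula treats high-$p_l$
zeros — those the chain most often attributed to the point mass — as the
discoveries, i.e. the sampling zeros to impute; low-$p_l$ zeros are left
as structural. Defaults: $c_\eta = 0.05$ for simulation work, $0.01$ for
real data.

Imputed sampling zeros receive the taxon's posterior mean log abundance
averaged over its observed-nonzero cells (the column-level summary; the
cell-level posterior mean is available via `impute = "cell"` — the
column-level default is the natural reading of "the posterior mean of
$\log\alpha_{\cdot j}$" and borrows strength from the cells where the taxon
was actually seen). Structural zeros keep their own cell posterior mean —
small by construction, and flagged in `zero_class` so downstream users can
drop them — because the graphical model needs a finite matrix.

## Stage two: sparse precision estimation

Under a Gaussian graphical model for the normalized log abundances $Z$, a
zero entry $\omega_{mk}$ of the precision matrix
$\Omega = \Sigma^{-1}$ means taxa $m$ and $k$ are conditionally
independent; the signed strength of an edge is the partial correlation
$\rho_{mk} = -\omega_{mk}/\sqrt{\omega_{mm}\omega_{kk}}$. `glasso()`
maximizes the $\ell_1$-penalized log-likelihood
$\log\det\Omega - \mathrm{tr}(S\Omega) - \lambda\lVert\Omega\rVert_1$
(diagonal penalized) by block coordinate descent with warm starts along the
penalty path. The solver is validated in the tests against the unpenalized
MLE at $\lambda=0$ and against brute-force maximization of the objective at
$p=2$.

The penalty is selected by StARS: for each $\lambda$ on a 30-point
log-spaced path from $\lambda_{\max}$ (the smallest penalty giving an empty
graph, $\max_{m\neq k}|S_{mk}|$) down to $0.01\lambda_{\max}$, the graph is
re-estimated on $N=20$ subsamples of size $b=\lfloor 10\sqrt{n}\rfloor$,
capped at $\lfloor 0.8n\rfloor$ so subsamples stay genuinely distinct at
small $n$ (the standard default of the reference StARS implementation),
drawn without replacement; edge selection frequencies
$\hat\theta_{mk}$ give the mean instability
$\overline{2\hat\theta(1-\hat\theta)}$, monotonized from the sparse end,
and $\lambda^\*$ is the smallest penalty whose monotonized instability is
at most $\beta = 0.05$. These are the standard constants of the StARS
method; all are exposed in `stars_config()`. The final $\hat\Omega$ is
refit on the full data at $\lambda^\*$ (StARS is used purely as a tuning
rule), and edge presence is $|\hat\omega_{mk}| > 10^{-8}$ to absorb solver
noise.

By default the graphical lasso runs on the sample *correlation* matrix of
$Z$ rather than the covariance: taxa scales still differ after
normalization, and a scale-free penalty treats edges comparably
(`use_correlation = FALSE` restores the covariance). Subsample row sets are
drawn up front from the configuration seed, so results are identical
whatever `n_threads` is.

## Simulation engines

Two generators provide data with known network truth; both are first-class,
tested code, and both deliberately differ from the analysis model.

**Dirichlet-multinomial.** An Erdős–Rényi graph $ER(p,\rho)$ sets the
adjacency; a precision matrix is built with unit diagonal and edge entries
drawn $\mathrm{Unif}[-0.1, 0.1]$, each off-diagonal divided by 1.5 times
its row's absolute off-diagonal sum, then symmetrized by averaging with the
transpose and the diagonal reset to 1. Dividing by the *off-diagonal* row
mass (rather than a sum including the unit diagonal) is the reading
consistent with the construction this follows: it leaves each row with
off-diagonal mass $2/3$ — guaranteeing diagonal dominance, hence positive
definiteness (still verified, with seed-incremented retries as a safety
net) — and produces a realistic mix of strong and weak partial
correlations rather than uniformly negligible ones. The interval
$[-0.1,0]\cup[0,0.1]$ is implemented as $[-0.1,0.1]$ (they differ by a
measure-zero point). Latent abundances are
$D_{i\cdot} \sim N(\mu, \Sigma = \Omega^{-1})$ with
$\mu_j \sim \mathrm{Unif}[0,10]$; fractions
$\psi_i \sim \mathrm{Dirichlet}(\exp(D_{i\cdot}))$; counts
$\mathrm{Multinomial}(N_i, \psi_i)$ with
$N_i \sim \mathrm{DiscreteUnif}[5\times10^4, 10^5]$; finally exactly
$\mathrm{round}(\pi_0\, n\, p)$ uniformly chosen cells are zeroed (the mask
is recorded; cells that were already zero may be chosen — the mask, not the
count change, is the ground truth). The defaults
($\rho = 0.1$, $\pi_0 = 0.1$) are the standard benchmark conditions used
in the acceptance tests at $n = 200$, $p = 40$ with 10 replicates.

**NorTA.** Given a target covariance $\Sigma_0$ and per-taxon ZINB
marginals, draw $Z_0 \sim N(0, \Sigma_0)$, push each column through the
normal CDF, and apply the ZINB quantile (mass $\pi$ at zero, then the NB
quantile of the rescaled tail). Marginals can be estimated from any count
table by per-taxon maximum likelihood (`fit_zinb_marginals()`); when no
reference data are supplied, a Dirichlet-multinomial simulation serves as
the reference, keeping the pipeline self-contained.

Passing tests on these generators shows the method recovers networks under
zero-inflation, overdispersion and uneven depth with an Erdős–Rényi
dependence structure; it does not certify behavior on real data's
phylogenetically structured correlations, compositional artifacts, or
batch effects.

## Benchmark metrics

`signed_confusion()` scores the $p(p-1)/2$ taxon pairs sign-aware: a true
positive needs a nonzero truth, a nonzero estimate, *and* matching sign.
Each pair receives exactly one label so the counts always partition the
pairs; a wrong-signed detection at a true edge counts as a false positive
by default (a wrong claim was made; `wrong_sign = "fn"` treats it as a
miss instead). MCC, ROC/AUC (path mode: one point per penalty;
score mode: one point per unique absolute score, signs compared against
the true partial correlations) and AUPR (rank-only, for non-negative
confidences such as edge stabilities) follow. One consequence worth
knowing: under sign-aware scoring a randomly signed score matrix cannot
exceed a true-positive rate of about one half, so its AUC is ~0.25, not
0.5; the rank-only mode (`sign_aware = FALSE`) is the one with the
conventional permutation null of 0.5. The Pearson-correlation baseline
(`pearson_baseline()` plus `oracle_threshold()`, which keeps as many edges
as the truth has) is included as the naive comparator.

## Numerical choices and degenerate inputs

* Taxa observed nonzero in fewer than half the samples are filtered before
  fitting (`filter_low_abundance`, threshold `0.5`, kept iff nonzero
  fraction $\geq$ threshold; `0.1` is the relaxed variant). An all-zero
  taxon is a hard error naming the taxon.
* Initialization is moment-based: $\pi_i$ = zero fraction of the sample,
  $\phi_j = 1$, $s_i$ = library size over its geometric mean,
  $\alpha_{ij} = (y_{ij}+0.5)/s_i$.
* A non-finite sampler state aborts with the iteration index.
* `bfdr_select` with nothing selectable returns an empty selection (not an
  error); a table without zeros passes through with every cell `nonzero`.
* Glasso convergence is relative to the mean absolute off-diagonal of $S$;
  non-convergence is an error naming the penalty. If no StARS penalty meets
  the tolerance the largest is returned with `no_lambda_ok = TRUE` and a
  warning.
* Identical columns are legal input to StARS (their edge is perfectly
  stable); constant columns in the Pearson baseline get zero correlation
  with a warning.

## Problem sizes

The shipped tests exercise the sampler at up to $n=200$, $p=40$ with
10,000 iterations, 20-replicate recovery studies at $n=100$, $p=10$, and a
10-replicate benchmark at $n=200$, $p=40$; these sizes characterize the
method well while keeping a full run of the suite at desk scale. Replicate
counts are configurable where larger studies are wanted.

## Known limitations

* The two-group extension (borrowing information across case/control
  groups) is out of scope, as are neighborhood-selection ("mb") inference
  and sparse-correlation comparators.
* $\phi_j$ and $\sigma_j^2$ are only weakly identified from a single
  column of counts: the per-cell lognormal abundance layer can absorb NB
  overdispersion, so posteriors for $\phi_j$ are wide (honestly so — the
  credible intervals reflect it). Normalization quality does not depend on
  how that variance is split.
* MCMC convergence diagnostics beyond acceptance-rate logging and trace
  export are not built in; for publication-grade real-data analyses, run
  multiple seeds and compare.
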