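---
title: "Annotating topics by differential expression with grades of membership"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating topics by differential expression with grades of membership}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topicDE)
```

## The model and its assumptions

A multinomial topic model represents the counts of cell $i$ as
$x_{i1},\dots,x_{im} \sim \mathrm{Multinomial}(s_i; \pi_{i1},\dots,\pi_{im})$
with a rank-$K$ structure $\Pi = \mathbf{L}\mathbf{F}^\top$: each cell has
membership proportions $l_{i1},\dots,l_{iK}$ on the simplex, and each topic
$k$ is a probability vector $f_{\cdot k}$ over features. Because the
multinomial likelihood factorizes (up to proportionality) into independent
Poissons, the model is fit as a Poisson NMF,
$x_{ij}\sim\mathrm{Poisson}(\lambda_{ij})$, $\Lambda=\mathbf{H}\mathbf{W}^\top$,
and `poisson2multinom()` recovers $(\mathbf{L},\mathbf{F},s)$ exactly from
$(\mathbf{H},\mathbf{W})$.

To annotate a topic we need per-feature statements, so the DE model drops
the sum-to-one constraint on $f_{\cdot k}$ and analyzes one feature at a
time:
$$x_{ij}\sim\mathrm{Poisson}(s_i\theta_{ij}),\qquad
  \theta_{ij}=\textstyle\sum_k l_{ik}\,p_{jk},$$
with the memberships $l_{ik}$ treated as known. This approximation is good
when cell totals $s_i$ are large and individual rates $p_{jk}$ small, which
holds for UMI and binarized accessibility data. Treating $\mathbf{L}$ as
known means estimation error in the topic model propagates unacknowledged
into the DE results; with well-separated topics this is minor, but for weak
topics the uncertainty is understated.

The key statistic is the **least extreme LFC**: for topic $k$, the pairwise
$\log_2$ rate ratio against whichever other topic minimizes its absolute
value (ties broken toward the smallest competitor index, so the statistic
is deterministic). A feature must differ from *every* other topic to score;
a feature shared by two topics is distinctive for neither. With $K=2$ this
reduces to the ordinary two-group LFC. It is invariant to rescaling all
rates, and the sign convention makes distinctively *under*-expressed
features as visible as over-expressed ones. Comparison against the
single-rate null model ($\log_2 p_{jk}/p_{j0}$,
$\hat p_{j0}=\sum_i x_{ij}/\sum_i s_i$) and against a fixed reference topic
are provided as complementary modes; the reference topic's own rows are 0
by convention.

## Estimation and uncertainty

**MAP rates.** Each rate gets a Gamma$(1+\varepsilon,1)$ prior, implemented
by augmenting the data with $K$ pseudocount rows of value $\varepsilon$,
identity membership block, and unit size factors. MAP estimation is then
maximum likelihood on the augmented problem, run as 40 monotone
multiplicative (EM) updates; for all features at once this is exactly one
Poisson-NMF factor update with the cell factor held fixed, which is how
`de_analysis()` vectorizes it. Setting $\varepsilon=0$ disables the
augmentation entirely (plain MLE): we read "zero pseudocounts" as "no
prior", so hard-membership fits recover the groupwise Poisson MLE
$\sum x/\sum s$ rather than carrying a residual exponential penalty.

**Posterior sampling.** Normal approximations to this likelihood misbehave
for lowly expressed features, and the least-extreme LFC is not a smooth
function of the rates, so uncertainty is quantified by MCMC on
$g_k=\log p_{jk}$: per step one topic is chosen uniformly, its log rate
perturbed by $N(0,\sigma^2)$ ($\sigma=0.3$ by default), and the move
accepted with probability $\min\{1, \text{likelihood ratio}\times
p^\star_k/p_k\}$ — the last factor is the Jacobian of the log transform
under the flat prior on $p$. The chain starts at the MAP estimate and no
burn-in is discarded (the mode is an excellent starting point, and
discarding samples would only increase Monte-Carlo error). Likelihood
differences are evaluated sparsely: only cells with $x_i>0$ contribute log
terms, and the linear part collapses to a precomputed
$\sum_i s_i l_{ik}$ per topic. A unit test replays the identical RNG stream
through a dense R implementation to pin the sparse kernel down exactly.

The statistic (l.e., null, or pairwise LFC) is evaluated **per sample** —
for the l.e. LFC the competitor topic may change from sample to sample,
which is the point of doing this by simulation — then summarized by the
posterior mean, the shortest interval containing 68% of samples (HPD), and
an asymmetric standard error: $\hat s = b-\hat\beta$ if $\hat\beta<0$,
else $\hat\beta-a$, where $[a,b]$ is the HPD interval. The asymmetric rule
prevents the downstream shrinkage from crushing estimates whose posterior
is wide but bounded away from zero; the 68% level makes $\hat s$ agree
with a conventional standard error when the posterior is normal. HPD
intervals are computed on the transformed per-sample statistic in every
mode, for consistency with the least-extreme treatment.

**Chain length.** The default $n_s=10{,}000$ follows a two-seed consistency
heuristic: two independent chains should give post-shrinkage posterior
means with correlation at least 0.99, which the acceptance suite verifies
on simulated data. Features with near-zero counts have very diffuse
log-gamma posteriors (sd $\approx 2.6$ log2 units at $\varepsilon=0.01$)
that a $\sigma=0.3$ random walk traverses slowly; their posterior means
carry the largest Monte-Carlo error at short chain lengths, which is why
scaled-down test runs restrict exact-oracle comparisons to features with
counts in all groups.

**Reproducibility.** Every feature's chain uses an RNG stream derived from
(seed, feature index), so results are independent of processing order and
any single feature's analysis can be reproduced in isolation. Per-feature
failures are flagged and skipped, not fatal.

## Adaptive shrinkage

The per-feature estimates $(\hat\beta_{jk},\hat s_{jk})$ feed an
empirical-Bayes step: true effects are modeled as a zero-centered scale
mixture (normal components by default; symmetric uniforms as an option,
computed with truncated-normal integrals), with mixture weights fitted by
EM on a $\sqrt2$-geometric grid of scales from $\min(\hat s)/10$ to
$2\max|\hat\beta|$ and a Dirichlet$(1,\dots,1)$ weights prior. Posterior
means, posterior SDs, the local false sign rate
$\mathrm{lfsr}=\min\{P(b\ge 0\mid\text{data}),P(b\le 0\mid\text{data})\}$,
and s-values (running mean of lfsr in significance order, ties shared)
follow in closed form. The default family is normal even though uniform
mixtures are the convention for LFC shrinkage in two-group pipelines:
normal components admit closed-form posteriors and are required anyway by
the enrichment step; the family is recorded in the fitted prior object.

Two calibration facts worth knowing, both verified in the test suite:

- Without a point mass the prior is continuous, so $P(b=0)=0$ and
  $\mathrm{lfsr}\le 0.5$; s-value thresholds control the expected
  *sign-error* rate among calls (average lfsr of calls $\le$ the
  threshold by construction).
- Control of false discoveries against *exact* nulls is a stronger demand:
  in a half-null simulation the continuous families give empirical FDR
  $\approx 0.12$ at s-value $\le 0.05$, while adding the point-mass
  component (`pointmass = TRUE`) restores control ($\le 0.10$). The
  full-pipeline FDR criterion on simulated topic data passes with the
  continuous default because the MCMC standard errors are honest about
  near-null features.

For feature rankings where moderation is unwanted (e.g. exporting peaks
for motif analysis), `de_analysis(..., shrink = FALSE)` reports unshrunk
posterior z-scores and two-sided normal p-values instead.

## The synthetic-data generator

`simulate_dataset()` emulates droplet scRNA-seq UMI data with planted
structure, in a fixed draw order (sizes, memberships, rates, counts; seeded
separately so components are reproducible in isolation):

- size factors $s_i=10^{u_i}$, $u_i\sim N(0, 0.2)$ — median library of 1
  with the right order-of-magnitude spread;
- memberships: the number of nonzero topics $K'$ has
  $P(K'=k')\propto 2^{-k'}$ (normalized over $1..K$ — the stated weights
  do not sum to 1 on their own), topics chosen uniformly without
  replacement, proportions Dirichlet on the chosen topics (exactly one-hot
  when $K'=1$);
- rates $f_{jk}=2^{v_j}$, $v_j\sim N(-4,2)$, shared across topics for half
  the features; otherwise one uniformly chosen topic gets
  $2^{v_j+e_j}$, $e_j\sim N(0,1)$;
- counts $x_{ij}\sim\mathrm{Poisson}(\lambda_{ij})$,
  $\Lambda=(\mathrm{diag}(s)\mathbf{L})\mathbf{F}^\top$.

Presets: `discrete2` ($K=2$, $\alpha=(0.01,0.01)$, $n=200$; memberships
essentially hard — in a 10,000-cell draw $\ge 98\%$ of cells have maximum
membership $\ge 0.99$), `mixed2` ($\alpha=(1,1)$), and `mixed6` ($K=6$,
$n=1000$); $m=10{,}000$ features by default, reducible for scaled-down
runs. All planted differences are truth-flagged however small $|e_j|$, so
measured power includes the burden of undetectably small effects — a green
FDR test therefore says calls are sound, not that most planted effects are
found. What the generator does **not** emulate: overdispersion beyond
Poisson, batch effects, doublets, or ambient contamination; conclusions
about robustness to those features cannot be drawn from these tests. In
rare scaled-down draws a cell can receive zero total counts; its counts
are resampled with a deterministic follow-on seed rather than silently
dropping the cell.

## Evaluation and enrichment

`fdr_power_curve()` sweeps a score threshold over its observed values and
tabulates $\mathrm{FDR}=\mathrm{FP}/(\mathrm{TP}+\mathrm{FP})$ (defined as
0 when nothing is called) and
$\mathrm{power}=\mathrm{TP}/(\mathrm{TP}+\mathrm{FN})$, per
(feature, topic) test. `signed_tests_filter()` restricts the universe to
non-negative true effects when comparing against unsigned rankings;
zero-effect tests count as nulls.

For ATAC data, `gene_enrichment()` aggregates peak-level results to genes
via a precomputed link table: one global ("default") normal-mixture prior
is fitted to all (peak, topic) estimates; then per gene and topic the
mixture weights are refitted on the linked peaks only, on the same scale
grid, under a Dirichlet prior with parameters $1.01 + n_0\hat w^{\rm
default}$ ($n_0=20$), which stabilizes genes with few links while letting
well-linked genes adapt — as $n_0\to\infty$ the per-gene weights converge
to the default weights, a limit the tests pin down. The reported log Bayes
factor compares the refit prior against the point-mass-at-zero null (the
cited EB method's definition; comparing against the default prior instead
would be the other defensible reading, and is trivially recoverable as the
difference of two such log-BFs). The per-gene mean l.e. LFC averages the
per-gene-shrunken posterior means over linked peaks with lfsr $<0.05$. The
DE input for this step should be an *unshrunk* analysis: the per-gene
shrinkage here is the only shrinkage applied, avoiding double-moderation
of genes with strong coherent patterns.

## Numerical choices

- Factor entries are floored at $10^{-15}$ in all NMF updates so zeros are
  never absorbing; rates are floored at $10^{-15}$ before logs when
  initializing chains, and flagged.
- EM (multiplicative) updates are the monotone workhorse — the test suite
  asserts non-decreasing likelihood to $10^{-8}$ relative on random
  instances; coordinate-descent updates are damped Newton steps per topic
  column, faster but without a monotonicity guarantee, used in the
  refinement phase as is conventional.
- `fit_poisson_nmf()` runs: seeded uniform initialization scaled to match
  the total count; 10 CD updates of $\mathbf{H}$ with $\mathbf{W}$ fixed;
  an EM "prefit" phase; a CD "refinement" phase (defaults 1000 + 1000,
  iteration count being the convergence criterion, with an optional
  $10^{-6}n$ early stop). Topic-ordering is arbitrary (label switching);
  compare fits by likelihood, not by factor identity.
- The recovery target for a planted fit is the *likelihood*, not the
  planted parameters: at realistic sparsity the MLE sits 15% or more from
  the truth in Frobenius distance, so tests require the fit to reach at
  least the truth's likelihood.
- The acceptance probability is computed entirely in log space; proposals
  that would make a rate's contribution to any observed cell's mean
  non-positive are rejected outright.
- HPD windows use $\lceil \text{level}\cdot n_s\rceil$ order statistics
  and take the first minimal-width window on ties (deterministic).
- `compute_svalues()` shares the cumulative mean across tied lfsr values,
  so every test averages over all tests at least as significant.

## Known limitations

- Memberships are treated as known; no propagation of topic-model
  uncertainty.
- The Poisson observation model ignores overdispersion; strongly
  overdispersed data will yield overconfident intervals.
- The binomial-with-region-factor view of binarized accessibility is
  approximated by the same Poisson machinery with all region factors equal;
  region-size effects are not modeled.
- Analytical (normal-approximation) standard errors are deliberately not
  offered; MCMC is the only uncertainty path.
- The CLI runs single-threaded; the per-feature independence contract makes
  parallel scheduling safe, but no scheduler is bundled.
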