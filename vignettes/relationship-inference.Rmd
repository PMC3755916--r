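---
title: "Discriminating pedigree relationships from IBD segment sharing"
author: "segshare"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating pedigree relationships from IBD segment sharing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Two individuals related through a common ancestor on one side of each of
their pedigrees (uniparental relatives) share stretches of one haplotype
identical by descent.  `segshare` treats a chromosome as an interval of
map length $l$ Morgans and simulates transmission with the Haldane model:
each meiosis places $X \sim \mathrm{Poisson}(l)$ crossovers at i.i.d.
uniform positions, with no interference and the starting parental
haplotype chosen with probability $\tfrac12$.  Founder haplotypes carry
unique integer labels; a descendant haplotype is an ordered mosaic of
labeled intervals, and the pair's shared segments are the maximal
intervals on which the two individuals carry a common founder label.
Positions are continuous (no grid), so segment endpoints are exact
floating-point values and "touches a chromosome end" is an exact equality
with 0 or $l$.

Three conventions matter and are deliberate:

* **Tracked material.**  Collateral descendants are tracked through the
  single haplotype descending from the shared ancestry; in-marrying mates
  receive fresh labels, so sharing through them is impossible by
  construction.  The uncle in the avuncular pairs and the ancestor in
  lineal pairs are diploid endpoints keeping both haplotypes.  This is
  precisely what makes the avuncular segment-count mean $(5l+2)/4$ differ
  from the cousin-type formula, and the package's simulated means
  reproduce those distinctions.
* **Positional merging.**  A segment shared via one founder haplotype that
  abuts a segment shared via the other founder haplotype of the same
  ancestor counts as one segment: maximality is positional, not
  per-label.  Without this the avuncular and lineal counts would be
  systematically inflated.
* **A shared pedigree instance per replicate.**  All relationships with
  the same family base are scored on one dropped pedigree per replicate.
  Estimates for different relationships are therefore correlated within a
  replicate, but replicates are independent, so every marginal
  distribution is unbiased and standard errors scale as usual.

The per-chromosome observable is $(n_s, p_s, t_s)$: the segment count, the
number of chromosome ends covered (0, 1, 2), and the total shared
proportion discretized into tenths ($t_s = t$ iff
$(t-1)/10 < x \le t/10$; $t_s = 0$ iff nothing is shared).  Conditional on
$(n_s, \text{total})$, the split of the total across individual segments
is uniform and carries no information about the relationship, which is why
only the total enters the outcome key.  To keep multinomial cells
populated at $10^5$ replicates, $t_s$ is used only for $1 \le n_s \le 4$;
beyond that only $(n_s, p_s)$ are kept.

## Likelihood machinery

With $P_{\mathbf R}(k)$ the empirical probability of outcome $k$ under
relationship $\mathbf R$, the per-chromosome contribution to the
log-likelihood ratio is $\ln P_{\mathbf A}(k) - \ln P_{\mathbf B}(k)$, and
chromosomes add.  Moments under the truth $\mathbf A$ are
$\mathrm E_{\mathbf A}[\lambda] = \sum_k P_{\mathbf A}(k)\,
[\ln P_{\mathbf A}(k) - \ln P_{\mathbf B}(k)]$ — the directed
Kullback–Leibler distance — with the variance defined analogously.

Numerical choices:

* **Natural logarithms**; all tabulated values are in nats.
* **Zero cells.**  If $P_{\mathbf B}(k)$ is estimated 0 while
  $P_{\mathbf A}(k) > 0$, it is replaced by $1/(2N_{\mathbf B})$
  (half a replicate), and symmetrically.  The number of substitutions is
  recorded on every moments object (`n_zero_cell`); at $N = 10^5$ it is
  of the order of 100 cells for close-vs-close comparisons and its
  contribution is dominated by cells that already carry large $\lambda$.
  An observed outcome seen under *neither* distribution is uninformative:
  it contributes 0 and is flagged with a warning (classification) or a
  count (bulk experiments).
* **Aggregation by cumulants.**  Means and variances add over independent
  chromosomes; so do the third and fourth cumulants
  ($\kappa_4 = \mu_4 - 3\mu_2^2$), from which genome-level skew
  $\kappa_3/\kappa_2^{3/2}$ and *excess* kurtosis $\kappa_4/\kappa_2^2$
  are reported.  (Where only mean and variance aggregation is classically
  stated, the cumulant identity is the standard extension; the kurtosis
  reported is explicitly excess kurtosis.)
* **Ties.**  In sign-of-$\lambda$ assignment, $\lambda = 0$ counts as half
  correct — unbiased under the symmetric null, and exact: a relationship
  tested against itself scores exactly $0.5$.
* **Held-out evaluation.**  `assignment_experiment()` and `lr_sample()`
  draw fresh genomes from an RNG stream independent of the one that built
  the bank (pass a different seed), avoiding the optimistic bias of
  re-scoring training replicates.

Misclassification probabilities use the normal approximation
$\Phi(-m/s)$; genome-level $\lambda$ is close to normal (22 chromosomes,
central limit theorem), with |skew| typically well below 1.

## Genome models and parameters

| Parameter | Default | Why |
|---|---|---|
| genome model | `human5`: 2×0.75, 8×1.25, 6×1.75, 4×2.1, 2×2.75 M (22 autosomes, 35.9 M) | standard five-class simplification of the human autosomal map |
| `equal22` | 22 × 1.632 M | same mean length; E/SD ratios agree with `human5` within ~2% for pairs worth distinguishing |
| replicates `nrep` | $10^5$ per relationship × length | the replication at which the reference tables were computed; SE of cell probabilities ≲ 0.0016 |
| crossover model | Haldane (Poisson, no interference) | the assumption under which the closed forms hold |
| $t_s$ grid | tenths, exact `<=` boundaries | discrete key; boundary ties are measure-zero, convention fixed for bit-reproducibility |

Chromosome lengths are Morgans internally; centimorgans appear only in
files (bank files, segment files), converted by a factor 100.  Segment
files are 0-based, half-open, in cM; end contact for $p_s$ is judged
against the configured length with a $10^{-9}$ cM snap, because file
coordinates carry decimal rounding while simulation-internal arithmetic
is exact.

## What the generator does and does not emulate

The simulator *is* the stated world of the method: idealized, error-free
IBD detection.  A green test establishes that the machinery reproduces
the sampling theory of segment counts, positions and lengths under
Haldane recombination and fully observed sharing.  It does not establish
robustness to: missed short segments (real detectors lose segments below
~1–1.5 cM), segment-boundary error, background population relatedness,
inbred ancestors, bilateral relationships, sex chromosomes, or
interference/sex-specific maps.  Those are outside the model's scope;
their qualitative effect (bias toward more distant apparent relationship,
little impact on same-$R$ comparisons) is discussed in the source
literature but not modeled here.

## Design decisions taken where the design was open

* **Collateral count-formula coverage.**  The collateral count formula
  $a(dl+1)(\tfrac12)^{d-1}$ is applied to *all* non-avuncular full-sib and
  half-sib based pairs, including asymmetric ones (C1R, 2C1R); simulation
  confirms agreement within 0.003 + 3 SE for every catalog entry, so no
  special-casing is needed beyond UN/GUGN.
* **Lineal expected segment length.**  The finite-chromosome length
  $l/(dl+1)$ is printed for lineal chains as stated in the source theory.
  Note an internal tension: the lineal *count* formula uses $d-1$
  effective meioses, so the product count × length equals the exact total
  $2Rl$ only for collateral (cousin-type) relationships; the
  count-times-length identity is asserted in tests only for those.  Users
  wanting a self-consistent lineal per-segment mean can compute
  $2Rl$ / `expected_num_segments()`.
* **Custom relationship specs.**  Non-catalog uniparental pairs can be
  built from (base, $g_1$, $g_2$); the half-sib-base equivalence (the
  distribution depends only on $R$, e.g. half-cousins vs.
  half-great-uncle–great-nephew) is verified as a property rather than by
  duplicating catalog entries, matching their exclusion from the
  reference tables.
* **Banks are plain text.**  One record per outcome class
  (`relationship, length_cM, n_s, p_s, t_s, count`) with `#` headers
  carrying genome, $N$, seed and version; round-trips are bit-exact, and
  re-running any command with the same configuration reproduces files
  byte-for-byte.

## Known limitations

* Empirical distributions inherit Monte-Carlo noise; comparisons of very
  distant pairs (both $R \le 1/64$) have E(λ) so small that bank noise and
  the zero-cell rule dominate — as in the reference results, such pairs
  are near-indistinguishable anyway.
* The Poisson-approximate likelihood (`poisson_lr_moments()`) is provided
  for comparison, not inference: segment counts of close relatives are
  materially underdispersed relative to Poisson, and the approximation
  understates the KL distance (e.g. ≈0.8 vs ≈1.8 nats for UN:HS from
  counts alone).
* No priors over relationships are supplied; `classify_pair()` reports
  likelihood evidence and normal-approximation error rates, and leaves
  posterior reasoning to the user.

## A minimal session

```{r}
library(segshare)
fit <- ibd_fit("human5", c("C", "HC"), nrep = 1e5, seed = 1)
lr_moments(fit, "C", "HC")            # KL distance and E/SD
assignment_experiment(fit, "C", "HC", M = 1e4, seed = 2)
plot(lr_sample(fit, "C", "HC", M = 1e4, seed = 3))  # near-normal lambda
```
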