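# segshare

Identifying pedigree relationships from shared genome segments.

## The problem

Dense marker or sequence data let us observe the genomic regions two
individuals share identical by descent (IBD).  For *uniparental* relatives
(a common ancestor on only one side of each pedigree), the number of shared
segments per chromosome (*n*<sub>s</sub>), whether they reach the
chromosome ends (*p*<sub>s</sub>), and the total length shared
(discretized into tenths, *t*<sub>s</sub>) carry all the information there
is about the pedigree relationship.  That information can distinguish not
only different degrees of relationship (cousins vs. second cousins) but —
to a degree — pedigrees with the *same* Wright's relationship *R*, such as
half-sibs and uncle–nephew (both *R* = 1/4), which single-locus methods
cannot separate at all.

There is no exact theory for the joint distribution of
(*n*<sub>s</sub>, *p*<sub>s</sub>, *t*<sub>s</sub>) under arbitrary
pedigrees, so `segshare` estimates it by Monte-Carlo gene dropping:
founder haplotypes carry unique integer labels, each meiosis places a
Poisson(*l*) number of crossovers uniformly on a chromosome of map length
*l* Morgans (Haldane model, no interference), and shared segments are the
maximal regions where the two individuals carry a common founder label.
A catalog of 19 relationships is built in, spanning full-sib–based
(uncle–nephew UN, cousins C, … third cousins 3C), half-sib–based
(half-sibs HS, … H2C1R) and lineal (grandparent–grandoffspring GPO, …
G6PO) pedigrees, with *R* from 1/4 down to 1/128.

Relationships **A** and **B** are then compared through the
log-likelihood ratio of an observed outcome *k* per chromosome,

&nbsp;&nbsp;&nbsp;&nbsp;λ(**A** : **B**) = Σ<sub>chromosomes</sub>
[ ln *P*<sub>**A**</sub>(*k*) − ln *P*<sub>**B**</sub>(*k*) ],

with probabilities read off the fitted empirical distributions.  The mean
of λ under **A** is the directed Kullback–Leibler distance between the two
outcome distributions; the ratio E(λ)/SD(λ) acts as a noncentrality
parameter, giving normal-approximation misclassification probabilities
Φ(−m/s) for the sign-of-λ decision rule.  Closed-form approximations are
also provided: E(*n*<sub>s</sub>) = *a*(*dl* + 1)(½)<sup>*d*−1</sup> for
collateral relatives separated by *d* meioses with *a* common ancestors,
[(*d* − 1)*l* + 1](½)<sup>*d*−1</sup> for lineal chains, (5*l* + 2)/4 and
(7*l* + 2)/8 for the avuncular cases, and the finite-chromosome expected
segment length *l*/(*dl* + 1).

## Worked example

```r
library(segshare)

# estimate outcome distributions for uncle-nephew and half-sib on the
# five-length model human genome (22 chromosomes, 35.9 M)
fit <- ibd_fit("human5", c("UN", "HS"), nrep = 1e5, seed = 1)

lr_moments(fit, "UN", "HS")
#> Log-likelihood ratio lambda(UN : HS), nspsts, genome human5 [empirical]
#>   E = 2.097 nats, SD = 2.149, E/SD = 0.976, skew = 0.143, ex.kurt = 0.035
#>   zero-cell substitutions used: 92
```

E(λ) ≈ 2.1 nats is the Kullback–Leibler distance from the uncle–nephew to
the half-sib outcome distribution over a whole genome; E(λ)/SD(λ) ≈ 0.98
means the typical evidence is barely one SD from zero, so these two
*R* = 1/4 pedigrees are intrinsically hard to separate:

```r
misclassification_prob(lr_moments(fit, "UN", "HS"), lr_moments(fit, "HS", "UN"))
#>   truth_A   truth_B
#> 0.1645507 0.1527992

assignment_experiment(fit, "HS", "UN", M = 1e4, seed = 2)
#> Assignment by sign of lambda, HS vs UN (M = 10000 per truth, nspsts)
#>   correct | truth HS: 0.848
#>   correct | truth UN: 0.836
#>   mean correct-assignment rate: 0.842
```

— about 5/6 correct, the theoretical ceiling for this pair.  Closer
comparisons are much easier: cousins vs. half-cousins reach ≈ 98.5%
correct assignment.  Closed forms need no simulation:

```r
expected_num_segments("C", 1.632)   # 1.882 segments on an average chromosome
expected_segment_length("HC", 1.632)  # 0.2168 M (not the naive 1/d = 0.25)
```

To classify a real pair, put its detected segments in a tab-separated file
(`chrom  start_cM  end_cM`, chromosome ids as in
`chromosome_table(genome_model("human5"))`) and run
`classify_pair(fit, "segments.tsv", "C", "HC")`, or use the CLI:

```sh
exec/segshare simulate --genome human5 --reps 100000 --seed 1 --out bank
exec/segshare tables --bank bank --which ratios --out tables
exec/segshare classify --segments segments.tsv --bank bank --pair C,HC
```

## Acceptance script

`scripts/acceptance.R` recomputes the package's reference quantities from
scratch — closed-form segment counts and lengths, single-chromosome
moments of the segment-count distribution, the genome-wide UN:HS
Kullback–Leibler distance and its E/SD ratio, and held-out
correct-assignment rates for C vs. HC and 2C1R vs. 3C — and writes them as
JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
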