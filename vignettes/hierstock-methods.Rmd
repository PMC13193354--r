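---
title: "Models and methods behind hierstock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hierstock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hierstock` analyses diploid multiallelic codominant genotypes
(microsatellites being the canonical case) for nested population
structure in mixed stocks. This vignette records the statistical models,
the defaults and why they were chosen, what the synthetic-data generator
does and does not emulate, and the numerical decisions a maintainer
would want written down.

## The data model

A `geno_matrix` stores, for each individual and locus, an unordered pair
of nominal allele classes or a missing call. Allele classes are opaque
integer labels; when genotypes arrive as raw fragment lengths,
`bin_fragments()` snaps them to the grid `offset + k * motif_len`,
searching the offset over `[0, motif_len)` at 0.1-bp resolution for the
least total squared deviation and reporting per-length residuals so a
human can supervise the binning against the frequency histogram. A call
with exactly one scored allele ("half-missing") is flagged but treated
as fully missing by every statistic: the pipeline is dominated by
genotype-level quantities (heterozygosity, exact HWE arrays, genotype
distances), and a partial call would need its own likelihood treatment
to contribute anything beyond an allele count.

## Diversity and equilibrium

Per (group, locus) cell the package reports `N` (genotyped individuals
only — missingness varies by locus), `N_A`, `H_O`, the plug-in
`H_E = 1 - sum(p^2)` (matching the most widely used desktop tools),
`uH_E = 2N/(2N-1) H_E`, `F = 1 - H_O/H_E` (undefined at monomorphic
loci), Botstein's polymorphic information content, and private alleles.
Rarefaction works on gene copies (`g = 2 x individuals`, so "retain 20
samples" means `g = 40`): richness is a property of sampled gene copies,
not individuals. The first-order jackknife treats individuals as the
sampling units, with the Heltshe-Forrester variance.

The HWE test is the exact conditional probability test: given the
allele counts, the probability of a genotype array is
`n! prod(n_a!) 2^h / (prod(n_ab!) (2n)!)` and the p-value is the total
conditional probability of arrays no more probable than the observed
one. When a cheap bound on the array count (`C(n+g-1, g-1)` with `g`
genotype categories) is below `1e5` the null is enumerated exactly;
otherwise it is sampled by random re-pairings of the `2n` gene copies,
which draw from the conditional null without any Markov-chain burn-in,
and the p-value uses the add-one estimator `(1+hits)/(1+B)` so it is
never zero. The probability test is the package's primary HWE test; the
direction of a deviation is read off the sign of `F`. This choice
trades some power against pure heterozygote deficits for a test that is
easy to verify by enumeration — a one-sided deficit score test would
reject more often under Wahlund pooling.

Genotypic linkage disequilibrium uses a G (log-likelihood-ratio) test on
the genotype-by-genotype contingency table with permutation of one
locus's column. A caveat that matters for calibration experiments: with
very high allele richness nearly every individual carries a unique
genotype class, the table degenerates towards a permutation-invariant
diagonal, and the permutation test becomes extremely conservative. The
package's own null calibration therefore uses moderately polymorphic
loci (4 alleles at `n = 50`), where the table is informative; the HWE
calibration uses 10 equifrequent alleles at `n = 50`. Both tests hold
their size near the nominal 5% there (recomputed by the test suite and
`scripts/acceptance.R`).

Multiple testing uses the sequential Bonferroni (Holm) step-down rule,
implemented directly and cross-checked against `stats::p.adjust`; for a
family of six tests at `alpha = 0.05` the first step threshold is
`0.05/6 ~ 0.008`, the familiar fixed cut-off reported in many empirical
studies.

## Differentiation

For `K` groups with within/total heterozygosity components `H_S`, `H_T`:

* Jost's `D = (K/(K-1)) (H_T - H_S)/(1 - H_S)`;
* Hedrick's `G''ST = K (H_T - H_S) / ((K H_T - H_S)(1 - H_S))`.

The default estimator applies the Nei-Chesser small-sample correction
with the harmonic-mean sample size (`mode = "plugin"` exists for
closed-form checks). Multi-locus values combine across-locus mean `H_S`
and `H_T` rather than averaging per-locus ratios, which is the stable
choice near monomorphic loci. Uncertainty comes from delete-one-locus
jackknife (SE), percentile bootstrap over loci (95% CI, 999 resamples)
and permutation of group labels (999 permutations, add-one p).

AMOVA works from Smouse-Peakall squared genotype distances
(`d2 = 0.5 sum_a (c1_a - c2_a)^2`, the 0/1/2/3/4 codominant table);
pairwise-incomplete loci are handled by rescaling the observed sum by
`L/L_obs`, which is unbiased under missingness completely at random and
avoids an imputation model. The variance components follow the standard
two-level decomposition with `n0 = (N - sum(n_g^2)/N)/(P-1)`; `phi_ST`
is reported raw (it can be negative) and floored at zero only in the
percent display. The implementation is checked to `1e-10` against an
independent group-mean (allele-count-embedding) computation.

## Mixture, admixture and K selection

The strict mixture model assigns each individual to one of `K` demes;
profiling out the cluster allele frequencies (with a Jeffreys
pseudo-count `beta = 0.5` per allele, which keeps empty clusters finite)
leaves a combinatorial objective that is optimised by Metropolis
annealing over single-individual reassignments. The schedule is
scale-free: initial temperature equal to the standard deviation of
per-individual log-likelihood contributions, geometric cooling (x0.95
per sweep), at most 200 sweeps, stopping after 5 acceptance-free
sweeps; the best state visited is returned, so the result never falls
below its initialisation. These numbers are deliberate defaults, not
tuned constants: the temperature scale adapts to the data, and the
sweep budget is generous for samples of a few hundred individuals.

The admixture model gives every gene copy of individual `i` probability
`sum_k q_ik p_kla`; EM updates responsibilities, `Q` and `P` in closed
form, skipping missing calls, and its log-likelihood trace is
non-decreasing (asserted to `1e-8` on random data in the test suite).
Fits are initialised from a mixture solution with one-hot rows softened
to 0.9, or from random Dirichlet rows. Scanning defaults (`tol = 1e-4`,
200 iterations) are looser than single-fit defaults because K selection
consumes log-likelihood *differences* of tens to hundreds of units.

K is chosen by the second-order rate of log-likelihood change,
`D_LK2(K) = |L(K+1) - 2L(K) + L(K-1)| / max(SD(K), 1e-3)`, with `L(K)`
the replicate mean; the `1e-3` floor handles the common case of
replicates with zero variance. Ties break toward smaller K. A
`F_STIS(K) = GST(K)/max(FIS(K), 1e-3)` ratio from the best replicate's
hard assignment is reported alongside but never authoritative: within
coherent clusters `FIS` hovers near (or below) zero, so the ratio grows
with K more or less mechanically — the package surfaces the
disagreement rather than resolving it. When the likelihood curve is
flat (`D_LK2` below `1e-6` everywhere) the selection falls back to K = 1
with a `no_curvature` flag.

Because curvature cannot distinguish K = 1 from K = 2, panmixia gets its
own test: the gain `best logL(K=2) - logL(K=1)` is compared against `B`
refits of data simulated from the fitted one-deme model under
Hardy-Weinberg proportions with the observed missing pattern. The null
datasets are drawn *conditionally on the observed per-locus allele
counts* (random re-pairing of gene copies). An unconditional draw from
the frequency point estimate systematically drops rare alleles of
allele-rich loci, which shrinks the overfitting headroom available to a
two-cluster null fit and makes the test wildly anti-conservative
(empirical size near 0.7 at nominal 0.05 in our calibration); the
conditional draw restores the nominal size, as the test suite verifies.

## Hierarchical decomposition

`decompose_demes()` is the package's defining procedure: analyse the
full sample (first order, K assayed 1-14 by default), hard-assign
individuals to the chosen clusters by maximum ancestry, then re-analyse
each cluster independently (second order, K 1-7; third order, K 1-4),
capping K at `floor(n/5)`. Recursion stops at `max_order`, when a node
has fewer than `n_min = 15` members (a K = 2 split below ~8 individuals
per cluster is unidentifiable with ~15 loci), or when the panmixia test
does not reject at `alpha = 0.05`. Hard assignment between orders
mirrors how rearranged clusters are treated as new samples in practice;
admixed individuals are not split fractionally. The whole tree is
reproducible from one seed.

`order_summary()` reports, per order, cluster sizes, mean within-cluster
`H_O`, `H_E`, `N_A`, `F`, mean pairwise `D` and `G''ST` among that
order's clusters, and Holm-corrected HWE conformity counts.

## The synthetic generator: what it emulates, what it does not

`simulate_demes()` encodes the generative hypothesis the analysis is
built to detect: a balanced binary hierarchy of breeding demes drifting
apart level by level. Drift uses the Balding-Nichols construction —
each child's frequency vector is `Dirichlet(parent_p (1-F)/F)` — which
gives one interpretable parameter per level and closed-form nesting,
instead of explicit Wright-Fisher generations. Defaults mirror a
realistic small-river study design: depth 3 (8 leaf demes),
`F_levels = c(0.12, 0.08, 0.05)`, 15 loci with 13-31 alleles each
(ancestral frequencies symmetric Dirichlet(1), giving expected
heterozygosity near 0.9), 16 individuals per leaf, and 18.6% missing
genotypes injected completely at random. `pool_locations()` mixes
leaves into sampling locations (the Wahlund situation);
`emulate_study()` produces the full 140-fish, four-location design with
locations that carry no information about the demes. Alleles lost by
drift simply reach frequency ~0: there is no mutation model, no null
alleles, no scoring error, no linkage, and no dendritic geometry beyond
the balanced tree — so passing recovery benchmarks says the *method*
works under its own assumptions, not that real data are this kind.

Two structural consequences of these defaults are worth recording.
First, pooling two demes drifted at `F = 0.15` produces a pooled-sample
inbreeding coefficient around `(F/2)/(1-F/2) ~ 0.08` — much milder than
the deficits real studies report when null alleles pile on top of the
Wahlund effect — and at that effect size the probability test rejects
HWE at roughly 55-75% of loci for `n = 80`, with occasional significant
arrays whose deviation is not an aggregate deficit. Second, because the
per-level drift *decreases* toward the leaves, the differentiation
among an order's clusters (pairwise mean or K-group) *decreases* from
order 1 to 3 even under perfect recovery: the deepest sibling pairs are
the least drifted, while within-cluster `H_E` falls monotonically. A
field system in which smaller tributaries harbour more isolated demes
corresponds to drift *increasing* toward the leaves and would show the
opposite, rising trend. The order trends are therefore diagnostics to
be read against the drift profile, not universal signatures.

## Benchmark problem sizes

The packaged benchmarks (test suite and `scripts/acceptance.R`) use:
exhaustive HWE arrays up to `n = 4` and 3 alleles against `B = 1e5`
Monte-Carlo pairings; 1000 null datasets (`n = 50`) for test size; 20
two-deme datasets (`F = 0.10`, 50+50 individuals, 15 loci x 15 alleles,
10 replicate fits, K up to 5) for K recovery; and ten seeds of the
depth-3 design (missing-free variant of the generator defaults — the
recovery ceiling is set by the 16-per-leaf sample size already, and the
18.6%-missing variant lands 10-15 ARI points lower) for nested-structure
recovery. Replicates per K default to 10 in these benchmarks; field
analyses of real data typically use 100.

## Known limitations

* Assignment accuracy at the deepest order is bounded by frequency
  estimation from ~16 individuals per cluster; with true frequencies the
  Bayes-optimal assignment is several points better than any fitted
  model can reach at this sample size.
* The panmixia gate errs at its nominal 5%, so a deep decomposition of a
  truly panmictic sample will occasionally split once before its
  children stop.
* The annealing optimiser is stochastic; replicate fits (`R`) are the
  defence against local optima, and only the best-likelihood replicate
  feeds the hierarchy.
* `F_STIS`-style ratios are reported for transparency but are poor K
  estimators here.
* No support for dominant markers, polyploids, null-allele models or
  spatially explicit priors.
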