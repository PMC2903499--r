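---
title: "Disentangling genetic from family and cage variance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disentangling genetic from family and cage variance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grmvc)
```

# The confounding problem

In a population organised into full-sib families that are also housed
together, three sources of resemblance between sibs are almost
collinear: additive genes (expected relationship 1/2), the shared
family environment, and the shared cage. A pedigree-based mixed model
sees full sibs only through their expected relationship, so the
likelihood over `(s2_f, s2_u)` has a long ridge; which end of the ridge
the REML maximum lands on depends on the realisation of the data. Our
own simulations reproduce this instability: with a purely
family-environmental trait (`f2 = 0.3`, no genetic variance), the
pedigree model on some draws estimates `u2 = 0` and on others attributes
most of the family variance to the polygenic term. Dense SNP data break
the ridge in two ways: the realized relationship matrix captures the
*Mendelian sampling* variation in relatedness between sibs (realized
sharing varies around 1/2), and individual SNPs with large effects can
be fitted explicitly.

# The model ladder

All models share the fixed part (intercept and cage-density covariate)
and the family (`f`) and cage (`c`) random intercepts:

* **model 1**: adds a polygenic term `u` for *all* pedigree members
  with covariance `A s2_u`, the numerator relationship matrix;
  variants **1-u** and **1-f** drop one term to expose the ridge.
* **model 2**: replaces `A` by the SNP-based realized relationship
  matrix `G`.
* **model 3**: keeps model 2's random terms and adds a set of
  individual SNPs with additive (0/1/2) codes, selected by
  reversible-jump MCMC; **model 4** additionally fits a heterozygote
  indicator (dominance) column for every selected SNP that shows all
  three genotypes with heterozygosity above 10% (strict inequality);
  additive and dominance columns of a SNP enter and leave together.

`fit_model()` dispatches the REML models; `run_rjmcmc()` implements
models 3 and 4.

# Relationship matrices

**A** is built by the tabular method; founders are taken unrelated and
non-inbred, so `A` is positive semi-definite by construction and its
diagonal is `1 + F`.

**G** (default `similarity_index`) averages, per locus, the four
cross-individual allele identity indicators, which for alternate-allele
dosages reduces to `s = (g_x g_y + (2-g_x)(2-g_y))/4` with values
0, 1/2, 1. With sample allele frequency `p`, the expected similarity of
an unrelated pair is `s0 = 1 - 2p(1-p)`, and the combined ratio
estimator `2 * sum(s - s0) / sum(1 - s0)` (equivalently: per-locus
ratios weighted by `1 - s0`) is unbiased on the relationship scale —
conditional on one, respectively two, alleles shared identical by
descent, the per-locus expectation of `(s - s0)/(1 - s0)` is 1/4,
respectively 1/2. Sums run over loci observed in both individuals, so
missingness is handled pairwise; a pair with no shared informative
locus is an error, not a silent zero.

One algebraic property matters for practice: writing `x = g - 1`, the
per-locus similarity is `1/2 + x_x x_y / 2`, so the raw similarity
matrix decomposes into a positive semi-definite Gram form plus rank-one
terms that lie entirely in the space spanned by the all-ones vector and
its allele-frequency loading. Those components cannot be distinguished
from the overall mean by any model containing an intercept (the REML
likelihood is invariant to them), yet they are the sole source of
negative eigenvalues of the estimator — on strongly structured samples
the leading negative eigenvalue can be large. We therefore remove them
by double centering, after which rows and columns average zero, the
usual convention for genomic relationship matrices. Residual negativity
(possible under missingness) is bent away by a uniform diagonal shift
recorded as `psd_adjustment`; on complete data the shift is zero, and
the test suite asserts it stays below 0.05 on simulated data. The
`vanraden` alternative (`Z Z' / 2*sum(p q)` on frequency-centered
dosages, missing values imputed at `2p`) is provided as an
estimator-sensitivity cross-check; on complete data the two agree very
closely, by the decomposition above.

**LD pruning** follows the common sliding-window semantics: within each
`window`-SNP window advanced by `step`, the later SNP of any pair with
squared correlation above the threshold (default 0.95) is dropped,
visiting pairs left to right; windows never span chromosomes.
Correlations are computed on mean-imputed dosages. Defaults
(`r2 = 0.95`, `window = 50`, `step = 1`) correspond to the pruning used
to form candidate sets for SNP selection; the aggregate matrix `G` is
always built from *all* SNPs — pruning only shapes the candidate list.

# AI-REML

`reml_fit()` maximises the restricted likelihood
`-1/2 (log|V| + log|X'V^-1X| + y'Py)` — the additive constant
`-1/2 (n-p) log 2pi` is excluded; only likelihood differences are ever
interpreted — by average-information updates with step-halving.
Numerical choices:

* starting values split the phenotypic variance equally across the
  components (on the observation scale) unless `start` is given;
* a component whose update is driven negative is clamped to a floor of
  `1e-8` of the phenotypic variance and the step for the remaining
  components is re-solved with the clamped ones held fixed (an
  active-set Newton step); a component clamped three times is pinned,
  reported as 0 with standard error 0, and — as the tests assert —
  removing it changes the log-likelihood by less than `1e-3`;
* convergence is declared when the largest observation-scale variance
  change falls below `tol` (default `1e-6`) relative to the phenotypic
  variance; 100 iterations are allowed and non-convergence is a
  warning carried in the fit, never silent;
* all algebra is dense: realized relationship matrices have essentially
  no zero entries, so sparse techniques buy nothing at this scale
  (thousands of animals), and one Cholesky per iteration dominates the
  cost.

Reported **ratios** are `scale_j * s2_j / total`, where `scale_j` is
the mean prior variance contributed per observation: 1 for factor
terms, the mean diagonal of the record-level covariance for
relationship terms, and the summed column variance for SNP design
terms (whose per-effect variance is not otherwise comparable). `total`
is the sum over all components plus the residual, so the ratios and
the residual ratio sum to one by construction. Standard errors of
ratios use the delta method on the inverse average-information matrix;
`sampling_correlations()` exposes the correlations between component
estimates, the diagnostic that makes the family/polygenic confounding
visible (strongly negative `(f, u)` correlations under model 1,
near-zero `(f, g)` and `(c, g)` correlations under model 2).

`logLik()` carries `df` equal to the number of non-residual variance
components, so `AIC()` reproduces the convention
`AIC = 2 * parameters - 2 * logL` with parameter counts `{f, c, u} = 3`
for the full pedigree model, 2 for the reduced variants, and
`3 + avg n_q` for the MCMC-averaged models, where `avg n_q` counts
additive and dominance effect terms separately and may be fractional.
This convention reproduces every published AIC cell we use as a worked
example.

# SNP selection by reversible-jump MCMC

Solving dense mixed-model equations inside every MCMC round is
impractical, so selected SNP effects are treated as *fixed* effects:
with the variance components frozen, `V` is factorised once and the
profile restricted log-likelihood of any SNP set is a cheap function of
one precomputed Gram matrix; effects are the GLS solutions. Design
choices, flagged here because the concrete move mechanics are this
package's own:

* moves: add / drop / swap with probability 1/3 each; infeasible moves
  (drop from an empty set) are null rounds, which preserves detailed
  balance at the boundaries;
* prior: Poisson(1) on the *number* of selected SNPs, uniform over sets
  of a given size. For a uniform add kernel the acceptance factors
  reduce to the familiar `lambda/(k+1)` (add) and `k/lambda` (drop);
* the add kernel is an equal mixture of a uniform draw and a draw
  weighted by single-SNP profile evidence computed once at the initial
  variances; the Hastings ratio corrects both add and drop moves
  exactly, so this changes mixing speed only. A test verifies the
  chain's visit frequencies against the exactly enumerated posterior on
  a 3-SNP model space;
* proposals whose design column is numerically collinear (conditional
  sum of squares below `1e-10` of the Gram scale) are auto-rejected;
* the chain starts from a prior-penalised greedy forward selection and
  the conditioning variances are re-estimated there (burn-in applies as
  usual). Without this, a strong QTL absorbed by the genomic term at
  the model-2 variances can take a long time to enter;
* every `reml_every` (default 1000) rounds a REML fit of the base terms
  plus one common variance for the selected additive effects and one
  for the dominance effects is stored; the posterior-mean variance
  ratios come from these stored fits. By default the sampler's
  conditioning variances stay *fixed* for the whole chain — the point
  of fixed-effect treatment is precisely that `V` never needs
  updating, and a fixed target makes the chain standard MCMC.
  `update_conditioning = TRUE` refreshes them at each stored fit; in
  our experiments this buys little and can create hysteresis (a QTL
  that happens to be out of the model at refresh time inflates the
  genomic variance, which then suppresses its own re-entry);
* predictions for held-out animals average, over rounds, the fixed +
  QTL part under the current GLS solutions, plus family/cage/genomic
  BLUPs from the stored fits (weighted by window length) — the
  round-averaged prediction used in validation.

Default chain lengths are the conventional 100,000 rounds after 10,000
burn-in; the tests and the acceptance script use 20,000 after 2,000,
which our mixing diagnostics show is ample at their problem sizes.

# Intra-class correlations of relatives

For each relationship class `k` in {1/16, 1/8, 1/4, 1/2} the candidate
pairs are all phenotyped pairs with `A = k` exactly (tolerance `1e-9`;
inbreeding-perturbed near-misses are excluded, which is why the
pedigree simulator avoids sib matings — otherwise the quarter class
empties). Because pairs must also be mutually unrelated *across* pairs,
not all candidates can be used at once: a random permutation is
scanned greedily, accepting any pair unrelated to every previously
accepted animal. This yields a random *maximal* (not maximum)
independent set — verified in the tests against exhaustive enumeration
of maximal independent sets of the conflict graph. The intra-class
correlation of one accepted set is the one-way ANOVA form for groups of
two, `(MSB - MSW)/(MSB + MSW)`, and the procedure averages over
`replicates` (default 10,000) resampled sets; the reported
`mean_sampled` is far below `candidates` for full sibs in sib-rich
pedigrees, because sibships collide with themselves.

# Validation

`make_split()` implements the two schemes: *within* full-sib families
(half of each family to validation — family and cage effects learned
from estimation-set sibs and cagemates remain usable) and *across*
full-sib families (half of the nuclear families within each top-level
family move wholesale — family effects cannot transfer; unseen family
or cage levels contribute 0 to the prediction, and we apply the same
rule to cages, which are family-confounded). Founders carry no
phenotypes in the default generator (below), and in the across scheme
any record-less or family-less animals stay in the estimation side.
Relationship matrices always span estimation and validation animals:
genotypes and pedigree are not phenotypes, and the polygenic BLUP
vector covers every animal in `A` or `G`. Accuracy is the Pearson
correlation of predicted and observed phenotypes; the regression of
observed on predicted indicates bias (1 = unbiased).

# The synthetic generator

The generator emulates the structure the models assume, at the scale of
a well-known heterogeneous-stock mouse population: 85 unrelated
top-level families, 172 full-sib families with sizes from a normal
(mean 11, SD 8) truncated at 1, four generations (about 2,300 animals),
and cages of 2–7 animals largely confounded with families
(`confounding = 0.85` of animals are housed with full sibs only — the
exact degree is not documented for the real data; we picked a value
that makes cage and family nearly collinear without merging them).
Matings avoid full-sib pairs, outcrossing to a new founder when no
non-sib pair is available, as breeding schemes do.

Genotypes descend from a pool of 16 founder haplotypes (two per
notional progenitor strain), built as thresholded Gaussian AR(1)
chains: `adjacent_ld_rho` (default 0.7) sets short-range LD,
allele frequencies are uniform on [0.05, 0.95], and offspring gametes
recombine with probability 0.01 per adjacent-SNP interval, chromosomes
segregating freely. The small pool reproduces two signatures of real
outbred stocks: long-range LD, and nonzero realized relatedness between
pedigree-unrelated families.

Phenotypes are built generatively as
`y = density*slope + f + c + sum L a + sum D d + u + e`. Each component
is rescaled after simulation so its realized variance among phenotyped
animals matches the architecture target *exactly* — recovery tests need
known truth, and raw draws hit targets only in expectation. QTL get
equal per-QTL variance shares (random sign) with a joint correction for
LD between QTL columns; dominance QTL are drawn only from
dominance-eligible SNPs. The polygenic background defaults to an
infinitesimal marker model (tiny effects at every SNP), which makes the
genomic models correctly specified and the pedigree model approximately
so; a pure pedigree gene-flow option exists for marker-free settings.
Founders carry no phenotypes by default, as purchased breeders are not
part of the experiment — this matters: with phenotyped parents in the
estimation set, pedigree links alone predict across families nearly as
well as markers, and the characteristic advantage of the genomic model
disappears.

What the generator does *not* emulate: real recombination maps and
hotspots, sex chromosomes, genotyping error, selection or non-random
mating beyond sib avoidance, non-Gaussian traits, and
genotype-by-environment interaction. Passing recovery tests on these
simulations therefore shows internal consistency of the estimators
under their own model class, not robustness to those realities.

# Problem sizes used by the tests and the acceptance script

Parameter-recovery checks fit the genomic model on twenty simulated
populations of ~1,500 animals at (f², c², g²) = (0.06, 0.08, 0.50);
QTL-recovery chains use ~1,000–1,200 animals, 500 LD-pruned candidates
and 20,000 + 2,000 rounds; the stationarity check enumerates a 3-SNP
space under a 200,000-round chain; cross-validation patterns are
measured at the full 85-family scale with ten replicates; G-versus-A
calibration uses ~300–350 animals at 5,000 SNPs. These sizes were
chosen so each property is measured with comfortable Monte-Carlo margin
while an entire run stays in the minutes range on one core.

# Known limitations

* The similarity-index coefficients follow the weighted-ratio
  family described above; other members of that family differ in
  weights and diagonal treatment, and `vanraden` is the built-in
  sensitivity check.
* Variance-component uncertainty is asymptotic (inverse average
  information); no profile-likelihood or Bayesian intervals.
* The RJMCMC explores SNP sets conditional on frozen variance
  components; it is not a full joint posterior over components and
  effects, and its per-window variance attribution is an approximation
  documented above.
* Single-trait models only; no epistasis; dominance only at selected
  SNPs, not as a genome-wide dominance relationship matrix.
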