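---
title: "Detecting gene flow from genealogical asymmetry with two genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gene flow from genealogical asymmetry with two genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(twotaxon)
```

## The model and the signal

`twotaxon` tests for post-divergence gene flow between two populations using a
single unphased diploid genome from each, with no outgroup and no
polarization. The demographic frame is the five-parameter isolation-with-
migration (IM) model: populations $A$ and $B$ of diploid effective sizes
$N_A$ and $N_B$ split from an ancestor of size $N_{AB}$ a number $t$ of
generations ago, and after the split lineages migrate (backwards in time)
from $A$ to $B$ at per-generation rate $m_A$, and optionally from $B$ to $A$
at rate $m_B$. The closed-form results use coalescent units: $T = t/2N_e$ and
$M = 2N_e m$, with all three sizes equal.

A sample of two lineages per population has two unrooted topology classes.
When the first coalescence joins lineages from the same population the
genealogy is *congruent* with the population tree; when it joins lineages
from different populations it is *incongruent* and carries an internal $ab$
branch. Writing $\tau_a$ and $\tau_b$ for the total lengths of the external
branches leading to the $A$ and $B$ samples, incongruent genealogies satisfy
a symmetry that congruent ones do not: under strict isolation,

$$\mathbb{E}[\tau_a \mid \text{incongruent}, m=0] =
  \mathbb{E}[\tau_b \mid \text{incongruent}, m=0] = 2t + \tfrac{8}{3}N_{AB},$$

*independently of $N_A$ and $N_B$*, because all four lineages must reach the
ancestral population, where they are exchangeable. Unidirectional gene flow
breaks this symmetry — the recipient population (forwards in time) ends up
with the longer external branches — so, conditional on incongruence, the
scaled difference

$$A_i = \frac{\bar\tau_a - \bar\tau_b}{\bar\tau_a + \bar\tau_b}$$

is zero without gene flow and positive with gene flow into $A$. Genealogies
are not observable, but a mutation on the $ab$ internal branch produces a
site at which *both* diploids are heterozygous for the same two alleles (a
`hetAB` site), which under infinite sites can only arise on an incongruent
genealogy. Conditioning on at least one `hetAB` mutation in a block of
$2l+1$ sites and counting the flanking `hetA`/`hetB` polymorphisms gives the
observable statistic

$$A_m = \frac{\bar\tau_a' - \bar\tau_b'}{\bar\tau_a' + \bar\tau_b'}
  \approx \frac{k'_{hetA} - k'_{hetB}}{k'_{hetA} + k'_{hetB}},$$

pooled as a ratio of summed counts over all `hetAB`-centred windows.

## Exact analytics by path enumeration

The joint branch-length distribution decomposes over *event paths*: ordered
sequences of pairwise coalescences, migrations, and the population split,
from the initial sample configuration to the most recent common ancestor.
`im_paths()` enumerates them: there are exactly 95, of which 33 are
incongruent. Of the incongruent paths 10 are symmetric in expectation, 20
form 10 equiprobable pairs whose combined $a$ and $b$ lengths cancel, and 3
are genuinely asymmetric. The asymmetric histories begin with a migration
followed by an $a+b$ coalescence while the second $a$ lineage is still
isolated in population $A$; they have probability zero when $M = 0$ and are
the entire source of the $A_i$ signal.

```{r}
paths <- im_paths(scaled_im_params(T = 1, M = 1))
table(paths$topology_class, paths$symmetry_class, useNA = "ifany")
subset(paths, symmetry_class == "asymmetric",
       select = c(events, probability, exp_tau_a, exp_tau_b))
```

For one path with pre-split states $i = 1, \dots, j{+}1$ (exit rates
$\Lambda_i$) followed by panmictic states $k$ (pair counts $C_k$), the
transform of the restricted branch-length distribution, with an exponential
"load" $\omega$ on each branch type, is

$$G(\omega) = \prod_i r_i \; I(c_1, \dots, c_{j+1}; T)
  \prod_k \frac{r_k}{C_k + u_k}, \qquad c_i = \Lambda_i + u_i,$$

where $u_i$ weights the branches extant in interval $i$ and
$I(c; T) = \int \prod_i e^{-c_i d_i}\, dd$ over durations summing to the
split time $T$. Two exact identities make this numerically clean:

* $I(c;T)$ equals entry $(1, m)$ of $\exp(TB)$ for the upper-bidiagonal
  matrix $B$ with $-c$ on the diagonal — a phase-type evaluation
  (`Matrix::expm`) that is stable even when several $c_i$ coincide;
* $\partial I / \partial c_i = -I(c \text{ with } c_i \text{ duplicated}; T)$,
  because splitting an interval at the same rate multiplies the integrand by
  its duration.

Expectations of $\tau_a$ and $\tau_b$ are therefore sums of
duplicated-node integrals: no symbolic algebra, no finite differences, and
derivatives remain exact at a nonzero load. $A_m$ uses exactly that: loading
the $ab$ dummy variable with the block mutation rate
$\theta = 2 N_e \mu (2l+1)$ turns $G$ into the joint weight of "this path
and zero `hetAB` mutations", and subtracting it from the marginal moments
leaves the moments conditional on at least one `hetAB` mutation.

```{r}
sp <- scaled_im_params(T = 1, M = 1)
bm <- block_model(mu = 1e-8, block_len = 200, Ne = 1e5)
c(p_incongruence = p_incongruence(sp), Ai = ai_expected(sp),
  Am = am_expected(sp, bm))
```

The closed-form incongruence probability
$(2e^{-2T(1+M)} + 2M)/(3+3M)$ is cross-checked in the test suite against the
summed incongruent path mass on a $(T, M)$ grid to $10^{-9}$; it reduces to
$\tfrac{2}{3}e^{-T}e^{-T}$ at $M=0$ and to $2/3$ at $T = 0$ or $M \to \infty$.

Because the `hetAB` conditioning up-weights genealogies with long internal
branches, $A_m$ differs from $A_i$ in scale (not sign), and its
vanishing-block limit is *not* $A_i$; the package treats the two statistics
as distinct quantities throughout.

## The Monte-Carlo oracle

`sim_genealogies()` is an exact Gillespie sampler for the structured
coalescent of the 2+2 sample under the full model (unequal sizes,
bidirectional migration), written in compiled code. It draws competing
exponentials for pairwise coalescence (rate $1/2N$ per pair) and migration
(rate $m$ per lineage) until the split time, then coalesces panmictically,
accumulating branch lengths by unrooted branch type. External-branch time is
also recorded per occupied population, which is what lets the test suite
verify the strict-isolation mutation-rate-bias formula

$$A_i = \frac{3t(\mu_A - \mu_B)}{3t(\mu_A + \mu_B) + 8 N_{AB}\,\mu_{AB}}$$

(`ai_mutation_bias()`) by dropping segment-specific Poisson mutations.

`mc_ai()` and `mc_am()` estimate the two statistics from simulated
replicates as pooled ratios with a delete-one-group block jackknife:
replicates are cut into $g \ge 25$ contiguous groups,
$\mathrm{SE} = \sqrt{\tfrac{g-1}{g}\sum_i(\theta_{-i} - \bar\theta)^2}$, and
the 95% interval is $\pm 1.96\,\mathrm{SE}$. Grouping is by contiguous
replicate index, which is seed-stable; blocks cut from the same recombining
sequence always share a group. The sampler consumes a single R RNG stream
from one integer seed, so identical seeds reproduce results bit for bit;
per-replicate sub-streams would only matter for parallel execution, which
the package does not attempt.

Recombining sequences are delegated to the msprime coalescent simulator
through a thin adapter (`sim_recomb_profile()`) run with the system
`python`; the adapter returns per-block integrated branch lengths by type
and the package does the conditioning, pooling and jackknifing. When the
interpreter or msprime is absent the adapter raises an explicit error
pointing at the non-recombining path rather than degrading silently.

## The empirical estimator

`am_profile()` reads a VCF once (via `vcfR`), classifies every biallelic SNP
from the two genotype calls (`classify_site()`), and recomputes windows per
block size. Conventions, chosen where the method description leaves room:

* VCF positions are 1-based and windows are closed intervals
  $[pos-l, pos+l]$, matching the block size $2l+1$.
* Every `hetAB` site is a focal site, even inside another `hetAB` window;
  flanking sites shared by overlapping windows count in each window. The
  conditioning is per-`hetAB`-mutation, and the jackknife absorbs the
  induced correlation.
* $A_m$ is the ratio of summed counts, never a mean of per-window ratios
  (most windows are empty).
* Only biallelic SNPs with fully called genotypes in both samples enter;
  indels, multiallelic records, half-calls and malformed fields are
  `excluded`. No quality filtering is attempted — that belongs upstream.
* Monomorphic sites are ignored; the statistic is a ratio of counts and
  needs no callable-sites denominator, so accessibility masks are out of
  scope.
* Jackknife groups default to contigs when there are at least 25, otherwise
  to runs of consecutive windows chosen to give at least 25 groups; both
  conventions are standard for genome-scale resampling.

The classification is invariant to phase separators, haplotype order and
REF/ALT exchange, and the profile is exactly antisymmetric under swapping
the two samples — both properties are asserted in the tests.

Interpretation across block sizes matters because recombination mixes
congruent genealogies into large windows. With gene flow and equal sizes,
$A_m$ is stable and positive at small blocks and rises towards the
unconditional asymmetry at large blocks; under strict isolation with unequal
sizes it is null at small blocks but spuriously positive at large ones; a
continent-island history (gene flow into the smaller population) shows the
one unambiguous pattern: positive at small blocks, decreasing (eventually
negative) at large blocks.

## The synthetic-data generator

`make_fixture()` writes fully synthetic two-sample VCFs from the simulator,
so every estimator path is testable offline. Non-recombining fixtures place
each locus on its own contig (natural for per-contig jackknifing), draw
per-class site counts by Poisson thinning of the simulated branch lengths,
place positions uniformly without collision (infinite-sites emulation), and
randomize REF/ALT polarity per site so the estimator cannot exploit the
encoding. The scenario presets use the reference conditions analysed
throughout the package: $N_e = 10^5$, $t = 2 \times 10^5$ generations
($T = 1$), $\mu = 10^{-8}$, migration $M = 1$ where gene flow is present,
$M_B = M_A/4$ for the bidirectional preset, and a doubled population size
where inequality is the point. These fixtures emulate genotype *patterns*,
not sequencing: there is no genotyping error, no missingness, no coverage
variation and no linkage beyond what the simulated genealogies induce, so
passing tests validate the estimator's arithmetic and sampling theory, not
robustness to bioinformatic artefacts.

## Numerical choices and problem sizes

* Conditional ratios are guarded: when the incongruence probability or the
  probability of observing a `hetAB` mutation falls below $10^{-30}$ the
  analytic functions raise an explicit error instead of returning a ratio of
  denormals.
* Path symmetry classes are assigned by exact numeric comparison (relative
  tolerance $10^{-9}$) at two generic $(T, M)$ reference points, which
  cannot produce accidental coincidences across both points; the
  classification is computed once per session and cached.
* The test suite runs 100,000-replicate simulations for distributional
  checks (3-SE tolerances), 500,000 replicates where a sign must be resolved
  under bidirectional gene flow, a 100,000-locus null fixture for the
  estimator's false-positive check, and 400 recombining sequences of 33 kb
  for the block-size patterns; the acceptance script uses 500,000
  replicates for its Monte-Carlo recovery. These sizes were chosen so each
  check's Monte-Carlo error is several times smaller than the effect it
  measures.

## Limitations

* The closed forms cover the equal-size unidirectional model only;
  bidirectional gene flow and unequal sizes are handled by simulation.
* There is no recombination in the analytic model; the estimator's defence
  is the block-size profile, not an adjustment. When $\rho/\theta$ is large,
  small-block counts are scarce and the profile is the only guide.
* $A_m$ is sensitive to mutation-rate differences *between populations*
  (quantified by `ai_mutation_bias()`), to gene flow from unsampled
  populations that diverged before the $A$–$B$ split, and says nothing
  about the timing of gene flow.
* The package deliberately performs no ancestral-allele polarization, no
  phasing and no genome-scan localization; it is a genome-wide two-taxon
  test.
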