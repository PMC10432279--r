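---
title: "Kinship from mismatch rates: models and design choices"
author: "pmrkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinship from mismatch rates: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmrkin)
```

## The problem

Low-coverage ancient genomes are routinely represented as pseudo-haploid
data: at each SNP one sequencing read is drawn and its allele recorded, so
every individual carries a single haploid call (or a missing value) per
site. Diploid genotypes, genotype likelihoods and phase are unavailable,
which rules out most modern relatedness estimators. What survives is the
**pairwise mismatch rate (PMR)**: the fraction of jointly covered sites at
which two call vectors disagree. Relatives share alleles identical by
descent (IBD), so their PMR is depressed below the population background
in a way that depends only on the kinship coefficient.

`pmrkin` implements a complete analysis chain on this statistic for a
burial-community setting: degree classification with binomial posteriors,
parent–offspring versus sibling discrimination from the genomic
*distribution* of mismatch, rule-based pedigree assembly constrained by
uniparental haplogroups, genetic sex and age class, and the downstream
demographic and spatial statistics. A forward simulator of patrilineal,
female-exogamous communities provides ground truth for every step.

## The mismatch-rate model

Write $p_0$ for the PMR of two unrelated individuals from the same
population. If two pseudo-haploid calls are drawn from individuals with
kinship coefficient $\varphi$, the two sampled alleles are IBD with
probability $\varphi$ (this is the definition of $\varphi$), in which case
they cannot mismatch (absent error); otherwise they mismatch at the
background rate. Hence for degree $d$, with $\varphi = 2^{-(d+2)}$,

$$p_d = p_0\left(1 - 2^{-(d+1)}\right),$$

giving $p_0/2$ for duplicate observations of one genome (or identical
twins), $0.75\,p_0$ for first degree, $0.875\,p_0$ for second degree, and
$p_0$ in the limit. The normalised values $0.5, 0.75, 0.875, 1$ are
independent of $p_0$, which is what makes the statistic portable across
panels and populations. `expected_pmr()` implements the formula and the
test suite verifies it against Monte-Carlo draws from explicit diploid
genotypes.

Given a pair's overlap $n$ and mismatch count $k$, `classify_degree()`
treats $k \sim \mathrm{Binomial}(n, p_d)$ and returns the normalised
posterior over the candidate classes $\{0, 1, 2, \mathrm{UNRELATED}\}$
under a uniform prior (configurable). All likelihoods are evaluated in
log space. Ties are broken towards the more distant class: in this
application a false kin claim is costlier than a missed one. Classes
beyond the second degree can be requested, but summary statistics of
allele sharing genuinely do not resolve them reliably, so the default
stops at degree 2 and treats everything more distant as background.

## Estimating the background rate

$p_0$ must come from the data themselves. The classical approach takes
the median PMR over all pairs, assuming most pairs are unrelated. In a
burial community dominated by one extended family that assumption fails
badly: in our simulations of a four-generation patriline the majority of
pairs can be first- to third-degree relatives, the median lands on a kin
mode, and an estimator that re-thresholds against its own shrinking
median ratchets downward and never recovers.

`estimate_background()` therefore anchors the unrelated mode at a high
quantile (default the 95th percentile) of the pair PMR distribution —
close kin pull PMR *down*, never up, so the top of the distribution is
always background — and then drops pairs below $0.90625$ times the
anchor (the midpoint between the normalised second- and third-degree
expectations) before taking the median of the remainder. Third-degree
and more distant pairs remain in the pool by construction; they can
deflate the estimate by at most a few percent, which the classification
boundaries tolerate (the first-degree call boundary sits at a normalised
rate of about $0.81$, the second-degree boundary at about $0.94$).

## Parent–offspring versus siblings

Both relationships are first degree with identical genome-wide expected
PMR, but their IBD structure along the genome differs: a parent and
child share exactly one haplotype *everywhere* (IBD1 throughout), while
full siblings are IBD0/IBD1/IBD2 on about $1/4$, $1/2$, $1/4$ of the
genome in megabase-scale blocks. `windowed_pmr()` tiles the genome into
20 cM windows (windows with fewer than 50 overlapping sites are
excluded), and `classify_po_vs_sibling()` compares two models of the
per-window counts $k_w$:

- parent–offspring: $k_w \sim \mathrm{Bin}(n_w, 0.75\,p_0)$ in every window;
- siblings: $k_w \sim \tfrac14 \mathrm{Bin}(n_w, p_0) +
  \tfrac12 \mathrm{Bin}(n_w, 0.75\,p_0) +
  \tfrac14 \mathrm{Bin}(n_w, 0.5\,p_0)$.

The decision is the sign of the summed log likelihood ratio; its
magnitude is reported as a log-Bayes factor. Windows are treated as
independent and no hidden-Markov smoothing is attempted — the sibling
mixture deliberately ignores that a 20 cM window can straddle an IBD
breakpoint, which costs a little power but requires no segment model.
Fewer than 10 usable windows yields INDETERMINATE. At 500k overlapping
sites the two hypotheses separate by thousands of log-units; in our
validation 100 of 100 simulated pairs classify correctly, and accuracy
remains high at a quarter of that overlap.

## Pedigree assembly

Degree calls alone do not orient a parent–child pair. `seed_nuclear_units()`
applies, in order of authority:

1. **Transmission rules.** An XX candidate mother whose mitochondrial
   label differs from the other member's is infeasible; an XY–XY pair
   with differing Y labels is infeasible in both directions.
2. **Age classes.** A SUBADULT cannot be anyone's parent.
3. **Triangulation.** For pairs feasible in both directions: if a third
   individual is parent–offspring with one member and UNRELATED to the
   other, the two outer individuals must be the child's two parents
   (two-parent rule); an individual that is parent–offspring with two or
   more members of one sibling set is their parent (sibling-set rule).

Anything still unresolved is flagged AMBIGUOUS and contributes no edge —
reproducibility is preferred over guessing, where the original analyses
of such data resolve residual cases by expert curation and IBD-segment
lineality. Sibling sets are the transitive closure of SIBLING calls,
after removing calls whose mitochondrial labels differ (full siblings
share a mother, so such a call must in fact be parent–offspring; it is
reinterpreted and logged).

`expand_pedigrees()` merges units deterministically (lexicographic
order): the identified father/mother of any sibling-set member becomes
parent of the whole set unless called UNRELATED to another member;
members UNRELATED to a well-supported parent are evicted from the set
and reprocessed; missing parents are completed with placeholder nodes
(prefix `U_`), always as a mother/father pair, inheriting the children's
shared mitochondrial (mother) or Y (father) label. Second-degree calls
are used as cross-checks, not edges: an assembled pair whose graph
distance contradicts its call by more than one degree is reported as a
conflict. `validate_pedigree()` re-checks every structural and
transmission invariant, and assembled output always passes it.

Scoring against simulation truth (`compare_to_truth()`) matches
placeholders to unsampled true parents greedily by child-set overlap and
reports parent-edge precision and recall; on simulated three-generation
communities of about 30 individuals at 100k SNPs and Poisson-1 coverage
both reach 1.0.

## The simulator

`simulate_community()` generates the study conditions the analysis
assumes: a patrilocal, patrilineal community with female exogamy.
Defaults: four generations, Poisson(3) offspring per union, daughters
out-migrate with probability 0.8 (they leave the burial community and
are unsampled), 20% of children die as subadults, every union's mother
is a new unrelated in-migrant carrying a fresh mitochondrial label, one
founder couple (hence a single Y lineage among males, matching the
near-fixation of one Y haplogroup such communities show). Genotypes are
gene-dropped: founder haplotypes are site-wise Bernoulli with ALT
frequencies from Beta(0.5, 0.5) truncated to [0.05, 0.95]; children
receive one recombined gamete per parent under the Haldane model
(Poisson crossover count per chromosome, breakpoints uniform on the
genetic map, no interference). Observation is pseudo-haploid: per-site
coverage Poisson(1) by default (zero reads = missing), one chromosome
copy drawn uniformly, allele flipped with error probability 0.01.
Founder-haplotype ancestry labels are carried alongside the alleles, so
exact IBD states are available as oracle for every pair
(`ibd_states()`); parent–offspring pairs are IBD1 everywhere by
construction, a property the tests check exhaustively.

The desk-scale default panel is 50,000 SNPs over 22 chromosomes of 1.5
Morgans each; validation studies in the tests and the acceptance script
use 100k sites for community analyses and 500k for the
parent–offspring/sibling study, sizes chosen so the whole validation
chain completes in minutes on one core while leaving the statistical
margins wide (at 100k sites and Poisson-1 coverage a pair overlaps at
roughly 40k sites, where the degree classes are separated by more than
ten standard errors).

Grave coordinates cluster by patriline: each generation-2 male line gets
a grid centre (spacing 15 m), members scatter with isotropic Gaussian
noise (3 m), and subadult sons are pulled towards their father's grave
by a shrink factor (0.3). This layout is a stand-in for testing the
spatial statistics — no quantitative model of real necropolis layout is
claimed. Other realism limits worth keeping in mind: founders are
mutually unrelated (no background relatedness from a finite mate pool),
there is no mutation, no ascertainment structure in the panel, no
post-mortem damage beyond a symmetric error rate, and age classes are
assigned by a simple death model. Passing tests therefore demonstrate
correctness of the inference chain under its own assumptions, not
robustness to everything real ancient-DNA data can do.

## Demographic statistics

- `proportion_ci()` is the exact Clopper–Pearson interval from Beta
  quantiles — the conventional report for small osteological counts,
  and the only common interval that is guaranteed conservative. From an
  adult cohort of 27 males vs 6 females it returns 64.5–93.0%, and from
  19 vs 18 subadults 34.4–68.1%; Wilson or Jeffreys intervals give
  visibly different bounds at these sample sizes.
- `occupation_duration()` multiplies a generation-count range by the
  standard 28-year anthropological generation interval.
- `category_distance_test()` tests burial proximity of a relationship
  category (e.g. father–subadult son) by permuting individual identities
  over grave coordinates; the p-value uses the add-one correction and is
  one-sided for proximity.
- `mantel_test()` correlates spatial and genetic distance matrices with
  joint row/column permutation; the genetic distance defaults to
  normalised PMR (`norm_pmr_dist()`), since pair-level normalised
  mismatch is the only genetic distance available at these coverages.
  Which individuals enter the matrices is the caller's choice; the
  pipeline uses all individuals with both coordinates and genotypes.
- `haplogroup_summary()` counts distinct uniparental lineages and
  measures, within assembled pedigrees, how many mother-to-child links
  each mitochondrial label survives. Under strict female exogamy the
  modal depth is one generation — in-migrating mothers bring fresh
  lineages that their children carry but do not pass on within the
  community.

Both permutation tests are validated for null calibration
(super-uniform p-values, Kolmogorov–Smirnov check over 500 replicates)
and the Clopper–Pearson interval for coverage (at least nominal over
2,000 simulated draws at p = 0.3, N = 33).

## Numerical and interface choices

- All binomial likelihood work is in log space via `dbinom(log = TRUE)`
  and a log-sum-exp reduction; posteriors are normalised to $10^{-9}$.
- Pair overlap below `min_overlap` (default 5,000 sites) suppresses
  classification (LOW_OVERLAP); individuals below 20,000 covered sites
  are excluded by `filter_low_coverage()` before any pair statistics.
- EIGENSTRAT digits map 2→REF, 0→ALT, 9→missing; a genuine heterozygote
  digit 1 violates the pseudo-haploid contract and is rejected unless
  explicitly mapped to a random allele (`het = "random"`, logged).
- Genetic sex uses per-target-base read rates relative to the pooled
  autosomal rate; the Y-rate thresholds are 0.05 (below: XX) and 0.4
  (above: XY), with the gap flagged INDETERMINATE. The per-base (rather
  than per-SNP) normalisation is a configuration choice the interface
  exposes through the read-count profile itself.
- `run_pipeline()` derives per-stage seeds from one master seed so a
  stage can be rerun alone; outputs carry a manifest with input hashes.

## Known limitations

Degree resolution stops at the second degree by design; third- to
fifth-degree placement requires IBD-segment methods that need imputed
diploid data. The sibling window model ignores within-window IBD
transitions. The background estimator needs at least a visible
unrelated mode (roughly: the top 5% of pairs must be unrelated), which
a very small, fully related sample set violates. Assembly resolves only
what its deterministic rules can defend; in real data some edges that
expert curation would recover remain AMBIGUOUS here.
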