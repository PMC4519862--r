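---
title: "Inferring invasion histories from multilocus sequence data"
author: "seqABC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring invasion histories from multilocus sequence data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqABC)
```

# The problem

Tracing how an introduced species spread — which source fed which invaded
area, in what order, and through what founder events — is a demographic
inference problem. The data are modest: aligned sequences of one or two
loci (here a mitochondrial control region and an X-linked nuclear intron)
sampled across many populations. seqABC implements the complete analysis
chain used in invasion phylogeography: descriptive population genetics,
haplotype network reconstruction, and likelihood-free (ABC) comparison of
explicit demographic scenarios, together with a synthetic-data generator
that reproduces the sampling design of a 37-population red swamp crayfish
(*Procambarus clarkii*) survey (291 control-region and 196 intron
sequences; populations in China plus one site each in Japan and the USA)
so every stage can be exercised and calibrated without access to field
data.

# Sequence handling and site conventions

All statistics operate under **complete deletion**: any alignment column
containing a gap (`-`) or missing base (`N`) in *any* sequence is excluded
everywhere — haplotype identity, segregating sites, pairwise differences,
AMOVA distances. This makes haplotype and polymorphism counts invariant to
indel placement, at the cost of discarding columns that are only locally
gapped. Whether the original study counted a "site with alignment gaps" as
gapped-in-one or gapped-in-many is not documented; we chose the
conservative complete-deletion reading and treat `N` like a gap. Site
indices in reports are 1-based. Haplotypes are labelled `Hap_1, Hap_2, …`
in order of first occurrence, which makes IDs deterministic.

A site is *variable* when it carries two or more bases; *parsimony
informative* when at least two variants are each carried by at least two
sequences (so the pattern `A,A,G,G,T` is informative with three variants);
otherwise it is a singleton-type site.

# Diversity and neutrality statistics

* Haplotype (gene) diversity uses Nei's sample-corrected estimator
  $H_d = n(1-\sum \hat p_i^2)/(n-1)$ with Nei's (1987) sampling variance.
* Nucleotide diversity is $\pi = k/L_a$ where $k$ is the mean pairwise
  difference count over all $\binom{n}{2}$ pairs and $L_a$ the number of
  analysed (complete-deletion) sites. No extra $n/(n-1)$ factor is
  applied on top of the pair average; this convention differs from some
  software in the third decimal at survey-scale sample sizes and is
  stated here so results are comparable.
* Distances between haplotypes: p-distance, JC69, K2P (from transition
  proportion $P$ and transversion proportion $Q$), and an "MCL" distance —
  a Tamura–Nei (TN93) correction whose substitution pattern (base
  frequencies and the transition/transversion split) is pooled over all
  pairs in the spirit of composite-likelihood estimation, with uniform
  rates. Saturated pairs are flagged `NaN` and dropped from the mean with
  a warning.
* Tajima's $D$ (1989) and Fu & Li's $D^*$ (1993, with the Simonsen et
  al. 1995 variance constants) are computed from the full sequence
  multiset — frequencies matter, so statistics are never computed on the
  collapsed haplotype set. Both are flagged undefined when $S = 0$
  rather than silently reported as zero.
* Fu's $F_s$ evaluates $S' = P(K \ge k_{obs}\,|\,\hat\theta_\pi)$ under
  the Ewens sampling formula, with unsigned Stirling numbers of the first
  kind computed in log space (cached per $n$; survey-scale $n \approx
  300$ would overflow doubles otherwise), and $F_s = \ln(S'/(1-S'))$. The
  p-value is the proportion of seeded neutral constant-size coalescent
  simulations at $\hat\theta_\pi$ (1000 by default; the original tool's
  count is unstated) with $F_s^{sim} \le F_s^{obs}$.

# Population structure and isolation by distance

The two-level AMOVA partitions pairwise difference counts (the
squared-Euclidean convention for haplotypic data) among and within
populations; variance components come from the method of moments and the
$\Phi_{ST}$ p-value from permuting individuals among populations. All
permutation p-values in the package include the observed statistic in
numerator and denominator, so $p = 0$ never occurs.

Isolation by distance correlates a genetic distance matrix — pairwise
$\Phi_{ST}$ from two-population AMOVAs, the common IBD convention; the
original study's "genetic similarity" construction is not specified, so
the sign of $r$ should be interpreted against distances — with great-circle
distances (haversine, Earth radius 6371 km). The Mantel test is two-sided
by default (one-sided by flag), permutes rows and columns of one matrix
jointly, and enumerates all $n!$ permutations exactly for $n \le 7$.

# Statistical parsimony networks

Networks connect haplotypes by single mutational steps within a
**connection limit**: the largest number of steps $j$ for which a
parsimonious (homoplasy-free) interpretation retains probability $\ge
0.95$. The published recursion for this probability leaves implementation
details open, so seqABC computes it from an explicit model stated here:
substitutions follow a finite-sites Jukes–Cantor chain on the $m$ compared
sites (a repeat hit on a currently-different site reverts it with
probability 1/3); the unknown substitution count $M$ receives a Poisson
prior whose mean is the JC-corrected divergence implied by the observation
itself; the reported value is the empirical-Bayes posterior $P(M = j \mid
D = j)$. This is deliberately conservative — limits are one to a few steps
smaller than the classical TCS program reports at the same length (for
example 9 steps at ~950 sites) — and its independent test oracle is a
Monte-Carlo simulation of the same chain.

Step distances between haplotypes use pairwise deletion (sites ungapped in
both sequences), consistent with the identity rule but able to differ from
gap-tolerant programs by ±1 step. Components are assembled as a
minimum-spanning network: candidate edges in increasing step order, keeping
*every* edge that joins two hitherto-separate sub-networks at the current
distance. Alternative equal-length connections therefore survive as loops
— a loop is evidence of homoplasy and is reported, not resolved
arbitrarily. Multi-step edges are expanded through inferred intermediate
nodes carrying zero frequency.

Outgroup (root) weights follow the neutral-coalescent rationale that old
haplotypes are frequent and highly connected. Where the published scheme
leaves constants open we use the documented form: weight
$\propto f_i\,(1 + d_i/\sum_j d_j)$ over observed members of a component
($f$ = frequency, $d$ = degree), normalised to sum to one per component;
inferred nodes are excluded from normalisation. This preserves the
properties the inference relies on — singleton components get weight 1.00,
weight increases with frequency at fixed topology, and a star centre beats
its leaves.

# The coalescent scenario simulator

Scenarios are declarative: populations (sampled or unsampled "ghost"
sources), founding events, priors and ordering constraints, expressible in
YAML. Looking backward in time, an event at time $t$ (generations) merges
the target's lineages into the source, and during $(t-db, t]$ the target
has founder size $Nf$ instead of its stable size $N$ — a founder
bottleneck of duration $db$. Gene-copy numbers scale with inheritance:
$N/2$ (mitochondrial), $3N/2$ (X-linked), $2N$ (autosomal). The
simulator is a standard structured coalescent with piecewise-constant
sizes and exponential waiting times; branch lengths are in generations
throughout (no year conversion). Only pure-divergence events are
expressible; two-source admixture events are flagged as unimplemented in
the scenario DSL.

Mutation is finite-sites K2P: Poisson events at rate $\mu$ per variable
site per generation, transitions with probability $\kappa/(\kappa+2)$,
multiple hits allowed, and $\lfloor p_{inv} L\rfloor$ invariant sites
chosen once per dataset (default $p_{inv} = 0.10$). The study priors are
$1 < t_1 < t_2 < \dots < 100$, $5 < db < 25$, $1000 < N < 10^6$,
$1 < Nf < 10^4$ (uniform, orderings by rejection); the sequence-mutation
priors, numerically unstated in the source study which used its ABC
tool's defaults, are log-uniform $\mu \in [10^{-9}, 10^{-7}]$ and uniform
$\kappa \in [0.05, 20]$ — configurable per locus in the design table.

Calibration (reproduced in the test suite): pairwise TMRCA $\approx G$;
$E[k] = \theta = 2G\mu L_{var}$ and Watterson's $E[S] = \theta\,a_{n-1}$
within 5% over 5000 replicates in the small-$\theta/L$ regime;
mitochondrial diversity a quarter of autosomal at equal $N$; mean
Tajima's $D$ over 2000 neutral replicates within $[-0.3, 0.1]$ (the
statistic is mildly left-skewed at moderate $\theta$).

# The ABC engine

Summary statistics per locus: per deme the number of haplotypes,
segregating sites and mean pairwise differences; per deme pair the pooled
within ($W$) and between ($B$) mean pairwise differences, concatenated in
a fixed order (so two loci and three demes give a length-30 vector).
Demes with fewer than two copies report zero within-type statistics, a
mask convention that keeps observed and simulated vectors comparable.
Statistics are per deme; pooling populations into demes is done by the
design table.

The reference table draws parameters from the priors and simulates one
dataset per row. Distances are Euclidean after dividing each statistic by
its pooled median absolute deviation (robust under the heavy-tailed
statistics these priors produce). Model choice is the **direct
estimate**: scenario frequencies among the `n_closest` rows (default 500,
mirroring the confidence-evaluation convention), with a Wilson binomial
interval per frequency. The original tool's CI construction for direct
estimates is undocumented, so these intervals are labelled for what they
are and are not expected to match published intervals; its logistic
regression step is deliberately omitted — a rough direct estimate is the
documented use-case. Ties at the acceptance cutoff are broken by row
order and logged.

Parameter estimation is rejection plus local-linear regression adjustment
on log-transformed parameters (all parameters here are positive), with
adjusted draws clipped to the range spanned by the prior draws and a
logged fallback to the unadjusted posterior when the regression design is
singular. Confidence evaluation simulates pseudo-observed datasets (PODs)
per scenario: the type I error of a scenario is the proportion of its own
PODs it fails to win; the type II error the proportion of rival PODs it
wins; parameter recovery is scored as relative bias and relative RMSE of
the posterior-median point estimates.

A PCA adequacy check projects the observation onto the leading components
of the (subsampled, normalised) reference table and compares its
standardised radius per scenario against the 99th percentile of the
simulated radii.

# What the synthetic generator does and does not emulate

`table1Design()` carries the survey's populations, per-population sample
sizes for both loci (291/196 sequences in total), coordinates and the
region grouping used by the scenarios (R1–R5 in China plus the Japanese
and US sites; for the cluster-1 analyses the three Nanjing populations
pool into one deme). Two caption-level ambiguities had to be resolved:
one population (JX) is listed in both R2 and R5 in the source figures —
we assign it to R5 — and one (JY) is listed in no region — we assign it
to R2, its geographic neighbourhood. Locus lengths default to desk-scale
surrogates (400 and 250 sites) to keep simulation cheap; field-scale
lengths are one argument away. The generator reproduces the *statistical
design* only: sample sizes, inheritance, mutation model and demography.
It does not attempt to mimic the real haplotype sequences, their GenBank
records, or the empirical per-population haplotype distributions, so
passing tests demonstrate correctness of the machinery and calibration
of the simulator — not agreement with the field study's printed
estimates, which depend on the unreleased 291/196-sequence field
alignments.

# Scenario identifiability under the study priors

A finding worth stating plainly: under the study priors the competing
cluster-1 topologies are close to statistically indistinguishable. With
$t < 100$ generations and stable sizes up to $10^6$, nearly all
coalescence happens in the ancestral population, and a founder bottleneck
is only visible when $Nf$ is within an order of magnitude of $db$ —
roughly 2% of the prior mass. In a direct experiment (10,000-row tables,
50 PODs) the ghost-source scenario was recovered against a USA-origin
serial alternative in only 56% of PODs, and the mean posterior
probability of the true scenario was ~0.51. This mirrors the large
type I error (0.712) reported in the original cluster-1 analysis and is
a property of the design, not a defect of the machinery: the test suite
demonstrates scenario recovery on scenario pairs whose priors make them
separable, and the type I error of ~0.5 on deliberately identical
scenarios confirms the error estimator itself is calibrated.

# Numerical and reproducibility choices

Problem sizes used by the automated checks are chosen for a laptop-class
budget: 5000 replicates for coalescent calibration, 2000 for the
Tajima's-D window, 10,000-row reference tables for scenario recovery, 500
accepted simulations per estimate, 100 PODs for coverage, and 2000-row
per-scenario tables in the end-to-end acceptance script. Every stochastic
stage takes an explicit integer seed; the pipeline derives per-stage seeds
deterministically from one top-level seed, and tables are written with
fixed column order at six significant digits so reruns are diffable.
Degenerate inputs are flagged, not zeroed: $S=0$ neutrality tests,
monomorphic AMOVA ($\Phi_{ST}$ undefined), constant Mantel matrices,
saturated distances, and $K=1$ in Fu's $F_s$ all carry explicit
undefined flags.

# Known limitations

No recombination (both loci are treated as non-recombining blocks), no
admixture events, no microsatellite or SNP locus types, no three-level
AMOVA, no sliding-window or mismatch-distribution analyses, and no
neural-network or sequential ABC variants. The connection-limit model is
a documented stand-in for the classical statistical-parsimony recursion
and is conservative; the outgroup-weight constants are likewise the
package's own documented choice within the published rationale.
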