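---
title: "Genome profiling in silico: models, parameters and design choices"
author: "genoprof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome profiling in silico: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genoprof)
```

## The question and the method

Long-lived modular plants accumulate somatic mutations as they grow: every
cell division copies the genome with finite fidelity, so two cells separated
by many divisions should carry systematically different sequences (the
genetic mosaicism hypothesis). Genome profiling (GP) can probe this without
sequencing. It samples a genome with single-primer, low-stringency
("random") PCR, separates the products by micro temperature-gradient gel
electrophoresis (uTGGE), and reduces each band to the point where its
double-strand to single-strand melting transition begins. After
normalization against two co-migrated internal reference fragments, these
feature points — *spiddos* (species identification dots) — are
gel-independent coordinates. Two genomes are compared by the pattern
similarity score over matched spiddos,

$$\mathrm{PaSS} = 1 - \frac{1}{n}\sum_{i=1}^{n}
  \frac{\lVert \vec p_i - \vec p_i' \rVert}
       {\lVert \vec p_i \rVert + \lVert \vec p_i' \rVert},
\qquad d_G = 1 - \mathrm{PaSS},$$

where each $\vec p_i$ is a (mobility, temperature) vector. `genoprof`
implements the whole chain as a forward simulation: a tree's branch
geometry is converted to cell-generation counts, genomes diverge by
per-generation point substitutions, the measurement is emulated with
explicit gel distortion, and the resulting $d_G$ matrices are clustered
with Ward's method.

## The lineage model

Physical distance is converted to generations by the single-file cell
lineage model: tandem cells of unit length $a$ spanning a distance $B$
imply $g' = B/a$ divisions (`generations_from_distance()`). With the
default $a = 20\,\mu m$, a 2 m trunk segment is $10^5$ generations. This is
deliberately an upper-bound model — real meristems are not single files of
cells — and it is used exactly as stated; edge generation counts are
`ceiling(length / a)` so that short positive edges still register at least
one division.

Mutation accumulation is the constant-rate specialization of the general
load model $\mu(g) = \sum_{i=1}^{g} (\mu(i) + \gamma(i))$: we take
$\mu(i) = \mu_c$ and neglect the repair-dependent term $\gamma$
(`accumulated_mutations()`). Along every edge the simulator draws a Poisson
number of substitution events with mean $\mu_c L g$, places them uniformly,
and substitutes to a uniformly chosen different base — a Jukes–Cantor-like
model with back mutations allowed and no indels. GP observables respond to
any substitution, so a richer substitution model would add parameters
without changing what is being tested.

## The measurement model

* **Binding sites.** The primer (default: HUNT, `TGCTGCTGCTGC`) binds
  wherever at most `max_mismatch` of its bases mismatch and its 3'-terminal
  `anchor3 = 3` bases match exactly — polymerase extension needs a matched
  3' end. The two-round thermal protocol of the real assay is collapsed to
  one site-finding pass: re-amplification does not change fragment
  identity.
* **Amplicons and bands.** Every convergent (+,−) site pair with product
  length in `[200, 2000]` bp is a candidate; the `n_bands = 10` best-primed
  candidates (fewest total mismatches, ties by length then position) form
  the profile, modelling amplification bias. The defaults
  (`max_mismatch = 4` on a 100 kb genome) yield roughly a hundred
  candidates and a profile of about ten bands of roughly a kilobase.
* **Melting temperature.** The observable is the transition *initiation*,
  governed by the fragment's lowest-melting domain. We model it as the
  minimum over 50 bp sliding windows of the Marmur–Doty GC formula
  $T_m(w) = 64.9 + 41\,(\mathrm{GC}(w) - 16.4)/|w|$. The window size
  matters more than it looks: with 50 bp windows a random fragment's
  lowest domain melts at 62–64 °C, right next to the 60.0/61.4 °C internal
  references, whereas whole-fragment GC content would sit near 84 °C —
  twenty degrees of extrapolation that would amplify any reference reading
  error ~15× through the two-point calibration. Keeping spiddos near the
  reference span is what makes the normalization well-conditioned.
* **Mobility.** $1 - \log_{10}(\ell/\ell_{\min}) / \log_{10}(\ell_{\max}/
  \ell_{\min})$, clipped to $[0,1]$ — strictly decreasing in length,
  anchored at the calibration lengths (defaults 100 and 3000 bp).
* **Gel distortion.** Each profile receives one per-axis affine transform
  (scales drawn from ±10 % on mobility, ±5 % on temperature; offsets ±0.05
  and ±1 °C) plus i.i.d. Gaussian jitter (σ = 0.005 per axis). References
  co-migrate, so they receive the same distortion — which is exactly why
  two-point linear normalization (`normalize_profile()`) cancels the affine
  part to machine precision. Linear is the only map two references can
  identify; flipped gels (negative scale) are refused rather than silently
  corrected.

## Correspondence, distance, clustering

The original analysis superimposes spiddo sets visually; `match_spiddos()`
automates this as the minimum-total-displacement one-to-one assignment
(Hungarian algorithm, rectangular-safe). With unequal set sizes the score
runs over the matched pairs and the extras are recorded. The printed form
of PaSS is read literally: the denominator is the sum of the two position
norms, which makes the score origin-dependent; all coordinates live in the
normalized frame where both axes are positive, and this choice is recorded
rather than "improved". $d_G$ is a pseudo-semimetric — symmetric, zero on
identical profiles, bounded by 1; no triangle inequality is claimed.

Replicate gels of the same sample can be combined by matching each
replicate to the first and averaging matched coordinates
(`average_profiles()`), mirroring the averaged-spiddos design of the
original experiments; averaging demonstrably reduces $d_G$ measurement
variance.

`ward_cluster()` applies Ward's method directly to the $d_G$ matrix
(`ward.D` convention; `ward.D2` available — which variant historical GP
analysis software used is not documented, so both are exposed). Labels
are sorted before clustering so ties resolve identically regardless of
input order. Recovery of a planted branch partition is scored by cutting
the dendrogram at the known branch count and computing the adjusted Rand
index (`topology_recovery()`).

## The synthetic study and its conditions

The default configuration (`gp_config()`) describes one tree, three
branches attached 2 m apart (the canonical branch-to-branch distance of
the generation arithmetic), three leaves per branch spaced a few
centimetres apart along a 0.1 m branch, $L = 10^5$ bases and
$\mu_c = 10^{-7}$ per base per generation. Two of these numbers deserve
comment:

* **Genome length.** 100 kb stands in for the amplifiable, informative
  fraction of a plant genome; it keeps a full nine-leaf pipeline run around
  a second while preserving realistic band statistics.
* **Mutation rate.** Replication fidelity estimates span
  $10^{-6}$–$10^{-9}$/base/replication. The rate-bound arithmetic
  (`worked_example()`) uses the conventional $10^{-8}$; the simulation
  default sits at $10^{-7}$, in the upper part of the plausible range,
  because the emulated assay — ten bands, one feature point each — detects
  individual events with lower efficiency than the physical assay it
  abstracts, and at $10^{-8}$ the between-branch signal lands at the
  detection threshold where branch recovery is a coin flip. At the default,
  between-branch separations carry expected substitution loads of
  $\sim 10^{-2}$/base (hundreds of events), well above the $10^{-4}$
  sensitivity limit, while same-branch leaves differ by loads near that
  limit — reproducing the observed regime in which leaves of one branch are
  barely distinguishable but branches separate cleanly.
* **Branch length.** Leaves of one branch sit centimetres apart (cluster
  on short shoots), so their lineage separation is small against the
  between-branch trunk path; spreading leaves over a metre-scale branch
  would give same-branch leaves band-level differences, contradicting the
  observation that within-branch differences stay at experimental-error
  level.

What the generator does **not** emulate: meristem developmental structure,
diploidy and heterozygosity, indels and structural variants, PCR
competition kinetics, melting-curve shape beyond the transition point, and
gel-image artefacts. Passing tests therefore demonstrate the
*computational* chain — geometry → generations → load → profile → distance
→ dendrogram — under a clean substitution process, not the wet-lab
robustness of GP.

## The dose-response experiment

`monotone_signal_experiment()` asks a sharper question: does mean $d_G$
rise monotonically with generational separation near the detection limit
(expected loads of 10–100 substitutions)? At these loads the response is a
staircase of individual detectable events, so the experiment is designed
for event resolution: a ladder of 31 leaves along one lineage (mutation
sets are then nested, so the underlying signal accumulates monotonically),
a 20 kb genome profiled with 60 short amplicons (200–400 bp, mismatch
tolerance 6) so the profile tiles the genome and the 50 bp melting window
covers a fifth of each fragment, and 20 replicate gels per leaf to average
reading noise. Per-base loads stay below $5 \times 10^{-3}$; far above
that, GC changes in a window begin to cancel (the count performs a random
walk) and $d_G$ is no longer monotone. Under this design the Spearman
correlation between separation and mean $d_G$ is typically 0.75–0.96.

## Numerical choices and degenerate inputs

* Edge generation counts use a $10^{-9}$-tolerant ceiling so that exact
  ratios such as $2 / (2\times 10^{-5})$ do not round up.
* Normalization refuses coincident or order-reversed references
  (degenerate / flipped calibration) instead of producing unstable maps.
* `pass_score()` defines $0/0$ pairs (both points at the origin) as zero
  displacement; an empty pairing is an error, not a score.
* Assignment costs must be finite; distance matrices are validated for
  symmetry (tolerance $10^{-9}$) and zero diagonal on read.
* All randomness flows from explicit seeds; a pipeline run writes its
  configuration next to its outputs and is byte-reproducible.

## Sizes used by the shipped checks

The test suite and the acceptance script run the designs above at desk
scale: ten seeded pipeline runs of the 3 × 3 default tree, one 31-leaf
ladder with 20 replicate gels, 100 random affine distortions, 1000 random
profile pairs, and 200 rate-recovery trials — a few minutes in total on
one core, with problem sizes stated in each experiment's documentation.

## Known limitations

* $d_G$ mixes two signal channels of different granularity — continuous
  melting shifts and discrete band turnover — so its variance at fixed
  separation is large; distances should be interpreted through replicate
  averages and clustering, not individually.
* The PaSS denominator makes the score depend on the coordinate origin;
  scores are comparable only within one normalized frame.
* The single-file lineage model upper-bounds generation counts; inferred
  rate bounds inherit that conservatism (`bound_mutation_rate()` returns
  the bound direction explicitly for this reason).
* Detection sensitivity is quoted as $1/(n_\mathrm{bands}\,\ell_\mathrm{band})$;
  a stricter reading based on what a single feature point can register
  would be several-fold less sensitive, which is why the simulation
  operates above the nominal limit.
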