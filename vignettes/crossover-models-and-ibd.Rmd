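---
title: "Crossover models and the distribution of IBD segments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crossover models and the distribution of IBD segments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relsim)
```

# The problem

Identity-by-descent (IBD) segments are the genomic regions two relatives
co-inherit from a recent common ancestor.  Their number, lengths and total
extent carry the signal used to classify relationships, to calibrate
direct-to-consumer relative matching, and to date admixture events.  Most
simulation pipelines place crossovers by a Poisson process on a
sex-averaged genetic map, but two well-characterized features of human
meiosis are thereby ignored:

* **Crossover interference** — crossovers suppress nearby crossovers in
  the same meiosis, making inter-crossover spacings more regular than
  Poisson.
* **Sex-specific maps** — human females average about 1.57 times as many
  autosomal crossovers per meiosis as males, with different fine-scale
  rate landscapes.

`relsim` simulates relatives under all four combinations of these factors
(`ss-intf`, `ss-poisson`, `sa-intf`, `sa-poisson`), tracks founder
haplotype descent exactly, and ships the closed-form renewal-process
theory for IBD segment lengths so that simulation output can be checked
against analytics.

# The meiosis model

Haplotypes are ordered runs of `(founder id, end bp)`.  Founders carry two
chromosome-length runs with globally unique ids; a child haplotype copies
runs from one randomly chosen parental haplotype up to each successive
crossover and switches source at every crossover.  IBD between two
individuals is computed by a sweep over the merged run boundaries of their
four haplotypes: maximal matching of founder ids gives IBD2 where both
haplotypes match distinct partners, IBD1 where exactly one matches.  The
maximal-matching rule matters in inbred corner cases — if three of the
four haplotypes carry one founder id, the pair is IBD1, not IBD2.

## Crossover placement

Under the Poisson model, inter-crossover distances (and the distance from
the chromosome start to the first crossover) are Exponential(1) per
Morgan, on the genetic axis of the transmitting parent's sex (the
sex-averaged axis for `sa-*` models).

Under the Housworth–Stahl two-pathway model, a fraction `p` of crossovers
escapes interference and forms a Poisson process of rate `p`; the
remainder arise from a stationary chiasma renewal process with
gamma(shape `nu`, rate `2 nu (1 - p)`) inter-arrivals, thinned by
independent coin flips of probability 1/2 (each chiasma affects two of the
four chromatids in the tetrad; no chromatid interference).  The two rates
sum to one crossover per Morgan.

Numerical choices:

* **Stationary start.**  The renewal process forgets its origin
  geometrically fast, so instead of inverting the equilibrium first-interval
  density we start the chiasma process at a burn-in offset of
  `max(10, 5 / (2 nu (1 - p)))` Morgans before the chromosome and truncate.
  The test suite verifies stationarity directly (window counts independent
  of offset; the first-event distance follows the equilibrium
  forward-recurrence density).
* **Draw order.**  Within a meiosis the free process is sampled first,
  then the regulated chiasmata, then the thinning coins, from R's RNG —
  one seed reproduces a whole run bit-for-bit, in R and in the compiled
  engine alike.
* **Breakpoint convention.**  Crossovers are sampled in genetic units and
  mapped to physical coordinates by linear interpolation between map
  knots.  A crossover at real-valued position `x` closes the previous run
  at `floor(x)`; two crossovers inside the same bp cancel.  Emitted
  segments are 1-based inclusive `[start, end]`.  On a plateau of the
  genetic map (zero recombination over a physical stretch) the
  genetic-to-physical map resolves to the leftmost knot, so a crossover
  sampled exactly at a knot boundary belongs to the left segment.
* **No extrapolation.**  Chromosomes begin at the first map knot and end
  at the last; the crossover rate is treated as zero outside the mapped
  span.

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `nu` (female, male) | – | 5.0, 7.5 | gamma shape; interference strength, stronger in males, in the range of published human estimates |
| `p` (female, male) | – | 0.02, 0.05 | escape fraction; small in both sexes |
| `female_factor` | – | 1.57 | female:male autosomal map-length ratio |
| genome | cM | 2800 male / 4396 female over 22 chromosomes | human-scale autosomal totals |
| error / missing rates | per site | 1e-3 / 1e-3 | genotype synthesis defaults |

For sex-averaged runs the escape fractions average arithmetically,
`p_a = (p_f + p_m) / 2`, while the shape averages through the variance:
every `nu` gives the same mean inter-chiasma distance, so
`nu_a = (1 / (2 nu_f) + 1 / (2 nu_m))^-1` is chosen to put the *variance*
of the averaged distribution midway between the sexes.  With the defaults
this gives `nu_a = 6`, `p_a = 0.035`.

# The segment-length theory

For a pair separated by `2T` meioses on a sex-averaged map with
interference, the package evaluates, in closed form (series truncated at
`k_max = 50`; raising it to 100 changes nothing above `1e-10`):

* `f_reg(x)` — inter-crossover distance on the regulated pathway: a
  geometric mixture of gamma densities over the number of skipped
  chiasmata;
* `g_reg(x) = (1 - p)(1 - F_reg(x))` — equilibrium distance from a random
  site to the next regulated crossover, via regularized upper incomplete
  gamma functions (avoiding overflow at large `k nu`);
* `h(x) = 2T e^{-2pTx} G̃(x)^{2T-1} (g_reg(x) + p G̃(x))` — distance to
  the nearest crossover over all `2T` meioses, where `G̃` is the upper
  tail of `g_reg`, itself closed-form through the identity
  `∫₀ˣ Q(a, cy) dy = x Q(a, cx) + (a/c) P(a+1, cx)`;
* `phi(x) = -(1/2T) h'(x)` — the length density of a randomly chosen
  inter-crossover interval, the infinite-chromosome IBD segment-length
  density.

A finite chromosome of genetic length `L` redistributes mass: the
continuous part becomes `(2 S(x) + (L - x) phi(x)) / (L + 1/(2T))` with
`S(x) = h(x) / (2T)` the upper tail of `phi`, plus an explicit point mass
at `x = L` for segments spanning the whole chromosome.  The atom is kept
separate from the continuous density precisely so total mass is testable;
the corresponding CDF is also closed-form (`segment_length_cdf_finite()`),
which makes histogram bin probabilities exact in the goodness-of-fit
tests.  At `nu = 1` every expression collapses to its Poisson counterpart
`2T e^{-2Tx}` with atom `e^{-2TL} / (2TL + 1)`.

For sex-specific maps without interference, crossovers form an
inhomogeneous Poisson process along physical coordinates with rate
`lambda(x) = lambda_f(x) n_f + lambda_m(x) n_m`, where `n_f` female
meioses mix as `n_f = Bernoulli(1/2) * 2 + Binomial(2T - 2, 1/2)` — the
transmitting common ancestor contributes two meioses of one random sex.
The inter-event density is evaluated on a piecewise-constant rate grid
(default 10 kb bins), including the left-censored first interval; the
right-censored final interval is excluded, matching the convention used
when comparing against simulation.

## What the tests show — and what they do not

The suite regenerates the central comparisons at desk scale: half-cousin
IBD segment lengths for `T ∈ {1, 2, 4, 6}` on a single 2.8-Morgan
chromosome (10^5 pairs per `T`) agree with `phi_L` by chi-square at the 1%
level, including the whole-chromosome atom, and the `nu = 1` run agrees
with the finite Poisson form.  Directional effects use 10^4 pairs per
cell for full siblings through second cousins and half-siblings, and
3,000 replicates per crossover model for admixture dating at
`T ∈ {2, 6}` (1,000 for the recovery checks); these sizes put each tested
ordering several bootstrap standard errors from its null.

The synthetic genome emulates the human autosomes in scale (22
chromosomes, 28/44 male/female Morgans, 250–50 Mb) and in local rate
variation (log-normal knot-to-knot rates), but it applies one female:male
length ratio to every chromosome and has no hotspot-scale structure.
Consequently statistics that depend on the *shape* of real maps — e.g.
the precise percentage by which sex-specific maps inflate the standard
deviation of IBD proportions — land near, but not on, values estimated
from real human maps, and passing tests demonstrate correctness of the
machinery, not calibration to any particular population.  Runs against
the real downloadable sex-specific maps and interference estimates are
supported (`read_genetic_map()`, `read_interference_params()`) but those
resources are not redistributed here.

# Admixture dating

`simulate_admixed()` builds the two-way admixture pedigree: every
generation-1 couple pairs one member from each source population, and the
focal individual `T` generations later inherits one admixed haplotype
(the spouse side is deliberately not modeled).  Ancestry switches
accumulate at `T/2` per Morgan, so uncensored tract lengths are
approximately exponential and the MLE is `T̂ = 2 (n - m) / Σ x_i` with `m`
censored tracts.

One design choice deserves emphasis: **only the tract cut off by the far
chromosome end is censored**.  The crossover processes start fresh at the
chromosome start, so the first tract is a legitimate waiting-time draw;
counting both end tracts as censored would subtract one event per
chromosome and bias `T̂` low by roughly `2C / L_tot` (about a factor of
two at `T = 2` on a 36-Morgan, 22-chromosome genome).  A tract spanning a
whole chromosome is censored once.  Under this convention the estimator
is unbiased in the package's own recovery tests.

# Scope and known limitations

* The def-file dialect covers symmetric branching pedigrees (the printed
  examples parse exactly); asymmetric branch counts and explicit parent
  assignment are expressed through relationship presets
  (half-siblings, half-cousins, removed cousins, forced-sex lineages)
  rather than grammar extensions.  `n_print` per branch is capped at the
  branch's lineage members (2 for the founder couple, 1 elsewhere).
* Interference parameter files accept per-chromosome rows, but published
  estimates are genome-wide; the `*` default row is the expected usage.
* No sex chromosomes, no chi-square (integer-shape) interference model
  with chromatid interference, no cross-chromosome crossover-count
  correlations, and no inference of IBD from genotypes — genotype output
  is for feeding external detectors.
* The command-line interface (`inst/cli/relsim.R`) is a thin wrapper over
  the exported functions; scripted R use is the primary interface.
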