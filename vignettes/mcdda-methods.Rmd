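---
title: "Monte-Carlo diffusion distribution analysis of CRISPR-Cas target search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte-Carlo diffusion distribution analysis of CRISPR-Cas target search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcdda)
```

## The model

A Cas nuclease searching a bacterial genome for its protospacer cycles
through four states: free **3D diffusion** in the cytoplasm, **1D sliding**
(or hopping) along non-specific DNA, **PAM investigation** when a candidate
motif is probed for a guide match, and — if a complete R-loop forms — a
stable **target-bound** state. The package models this as a linear
continuous-time Markov chain

$$\mathrm{3D} \underset{k_{1D\to 3D}}{\overset{k_{3D\to 1D}}{\rightleftharpoons}}
  \mathrm{1D} \underset{k_{PAM\to 1D}}{\overset{k_{1D\to PAM}}{\rightleftharpoons}}
  \mathrm{PAM} \xrightarrow{\;\text{match}\;} \mathrm{Target},$$

with target binding treated as irreversible ($k_{Target\to 3D}=0$). Each
state carries an apparent diffusion coefficient: $D^*_{3D}$ = 2.0
&mu;m&sup2;/s for Cas9-class and 2.2 &mu;m&sup2;/s for Cas12a-class
nucleases (hydrodynamic constants taken as given), $D^*_{1D} = D^*_{PAM} =
0$ because sliding and PAM probing cover distances far below the
localisation precision at 10 ms framing, and $D^*_{Target}$ = 0.21
&mu;m&sup2;/s, the mobility of the plasmid the bound nuclease rides on.
All of these are configurable (`state_diffusion()`); the zeros are a
modelling default, not an assertion that the true coefficients vanish.

Because sptPALM tracks of photoactivatable fluorophores are short (mean
three steps), state transitions cannot be read off individual tracks.
Instead the package follows the MC-DDA strategy: simulate the full
observation process forward from candidate rates, histogram the resulting
apparent diffusion coefficients, and adjust the rates until the simulated
histogram matches the measured one.

## The forward observation model

`simulate_ensemble()` reproduces the imaging experiment inside a
spherocylindrical cell (cylinder length 2 &mu;m, radius 0.5 &mu;m):

* particles start uniformly in the cell volume and in the stationary state
  mixture of the chain (`steady_state_fractions()`);
* motion advances on a 0.1 ms grid; per sub-step each coordinate moves by
  $\sqrt{2 D\,t_{step}}\,z$ and is reflected specularly at the wall
  (the boundary condition is our choice — it conserves particle number and
  is standard for confined Brownian dynamics);
* state-change times are drawn as $-\ln(u)/k$ from the total exit rate and
  counted down on the grid, switches resolved at sub-step resolution;
* after a 200 ms burn-in, the $(x,y)$ projection is recorded every 10 ms
  with independent Gaussian localisation error ($\sigma$ = 0.035 &mu;m per
  coordinate), for a track length drawn from a truncated exponential law on
  1–8 steps calibrated to a mean of 3;
* the per-track apparent diffusion coefficient is
  $D^* = \frac{1}{L}\sum_i \lVert r_{i+1}-r_i\rVert^2 / (4\Delta t)$, and
  $D^*$ values are collected into 85 logarithmic bins over 0.04–10
  &mu;m&sup2;/s, with out-of-range values clamped into the edge bins so that
  empirical and simulated histograms share one normalisation.

Localisation error inflates $D^*$ by $\sigma^2/\Delta t$ = 0.1225
&mu;m&sup2;/s; an immobile emitter therefore appears at $D^*\!\approx$ 0.12
&mu;m&sup2;/s, which the test suite verifies analytically and by Monte
Carlo.

Two choices deserve emphasis. First, observation is the planar projection
of the 3D position, matching how a camera sees the cell and how the
immobile-emitter equivalence above is defined. Second, because particles
are initialised in the exact stationary law (states *and* positions), the
burn-in changes nothing statistically — the suite checks this by
chi-squared comparison of histograms with and without burn-in — so
speed-sensitive code paths (the fitting forward model, reduced-scale tests)
shorten or drop it. Stroboscopic motion blur is not modelled: positions are
instantaneous, convolved only with localisation error.

Determinism: every particle owns an RNG stream derived from the root seed
(`splitmix64`-scrambled mt19937-64, with an inverse-CDF normal transform),
so ensembles are bit-reproducible, independent of particle order, and — for
the fitting objective — reusable as common random numbers.

## Closed-form kinetics

The non-target interaction time, the mean duration of a DNA-bound excursion
from 1D entry to 3D return, follows from summing geometric trajectory
weights:

$$t_{NTI} \;=\; \sum_{n\ge 0} \tau_n P_n
  \;=\; \frac{k_{1D\to PAM}+k_{PAM\to 1D}}{k_{PAM\to 1D}\,k_{1D\to 3D}},$$

where $P_n$ is the probability of exactly $n$ PAM visits per excursion and
$\tau_n$ its mean duration. `t_nti()` implements the closed form,
`t_nti_series()` the partial sums, and `ctmc_oracle()` an event-exact
jump-chain simulation; the three agree to the tolerances asserted in the
tests. Uncertainty propagation (`t_nti_uncertainty()`) uses hand-derived
partial derivatives under the assumption of uncorrelated rate errors, and
is cross-checked against central finite differences. Stationary fractions
follow detailed balance on the linear chain.

## Fitting rates to diffusion histograms

`fit_rates()` minimises the per-bin difference of density-normalised
histograms between data and the stochastic forward model. Three numerical
devices make this practical, all documented here because they are easy to
get wrong:

1. **Common random numbers.** One frozen seed is reused for every
   objective evaluation, so the objective is a deterministic function of
   the parameters and finite differences are meaningful. The LM jacobian
   uses ~1% relative steps (`epsfcn`), large enough to straddle the
   residual granularity of the frozen realisation.
2. **Conditional Monte Carlo over localisation noise** (`noise_reps`).
   Each simulated path contributes several $D^*$ draws re-convolved with
   fresh localisation error. For immobile-state tracks the conditional
   $D^*$ distribution is entirely noise-driven, so this removes most of the
   histogram variance of the best-populated bins at negligible cost —
   empirically a ~5x variance reduction for ~15% extra time.
3. **A composite search parametrisation.** The histogram constrains
   $k_{3D\to 1D}$ and the composite $t_{NTI}$ strongly, but the split
   between 1D and PAM dwells only weakly (both states are immobile at
   imaging resolution, so they are distinguished only through excursion
   duration statistics). Optimising in
   $(\log k_{3D\to 1D},\ \log t_{NTI},\ \log k_{1D\to PAM}/k_{PAM\to 1D},\
   \log k_{PAM\to 1D})$ — a bijection with the rates that also enforces
   positivity — aligns the well-identified directions with axes. A
   derivative-free Nelder–Mead pre-stage (restarted under fresh seeds until
   the objective reaches an estimated noise floor, from multiple starting
   points bracketing the valley) navigates the sloppy directions; the final
   minimisation is Levenberg–Marquardt. Multistart matters: single-sided
   starts stall a little short of the optimum and bias $t_{NTI}$ toward the
   starting side.

An important empirical property of this objective: it can have
**near-degenerate modes**. Distinct kinetic regimes — for example short 1D
sojourns with long PAM dwells versus the converse — can produce pooled
histograms that differ by less than the sampling noise of a 50,000-track
dataset, because the 1D and PAM states are both immobile at imaging
resolution and are distinguished only through excursion-duration
statistics. The multistart pre-stage surfaces these modes; `fit_rates()`
keeps all polished modes in its result rather than silently discarding the
runners-up.

Bootstrap confidence intervals (`bootstrap_ci()`) resample tracks with
replacement and refit. The default replicate refit is a single damped
Gauss–Newton step from the point estimate (first-order equivalent to a full
refit), with three honesty corrections: each replicate is compared against
a fresh forward-model realisation, so forward Monte-Carlo noise enters the
replicate spread; each replicate takes its step at every retained mode and
keeps the mode with the smaller post-step residual, so mode ambiguity
widens the interval; and the spread of the independently polished fits of
the best mode is convolved into the replicates along its measured
direction. Full refits per replicate remain available (`method = "full"`).

At the suite's reduced scale (observed histograms of 50,000 tracks, forward
models of 6,000–20,000 particles with 8 noise replicates) the recovery
benchmark typically returns $t_{NTI}$ within ~5–10% of truth. The one-step
intervals are honest about every noise source they can see but remain
somewhat anti-conservative when a mode decision is confidently wrong for a
particular data realisation — the acceptance suite measures their coverage
rather than assuming it, and the full-refit bootstrap (which captures mode
hopping by construction) is the recommendation when its cost is
acceptable. Production analyses should use the 50,000-particle forward
model of the original protocol (`fit_config()` defaults).

## Two-species mixtures

With a targeting guide, the histogram is modelled as a mixture of the
three-state searcher (rates fixed from the scrambled-guide fit) and a
static bound species at $D^*_{Target}$. Because the species are
independent, the mixture density is linear in the bound fraction, so
`fit_bound_fraction()` simulates each species once and grid-searches the
fraction in steps of 0.01, breaking ties toward the smaller fraction. This
replaces visual inspection of overlays — the original protocol — with a
reproducible least-squares criterion; the deviation is deliberate.

## Target-search prediction

`simulate_search()` predicts how long a nuclease population needs to find
a target. PAM density comes from an i.i.d. base-composition model
(`pam_density_from_gc()`): $P(G)=P(C)=\mathrm{GC}/2$, motif probability the
product over IUPAC positions, summed over a non-overlapping motif set, and
scaled by both strands and all genome (4,641,652 bp at copy 2.3, GC 50.5%)
and plasmid (2,500 bp — a pSC101-class size chosen here, as the reference
background does not print one — at copy 64) copies. `scan_pams()` provides
the exact sequence-scan oracle for this expectation and accepts FASTA
input. Note that expected counts under this model are what the package
uses throughout; counts quoted elsewhere for specific PAM sets depend on
counting conventions this model does not attempt to reproduce.

Per 1D episode the nuclease encounters the target with probability

$$P_{target} = \frac{\#\,\mathrm{targets}-\#\,\mathrm{bound}}{\#\,\mathrm{PAMs}}
  \cdot n_{1D_{PAM}},$$

applied once per 3D→1D entry by default (`trial_mode = "per-episode"`;
`"per-pam-visit"` applies it at each PAM entry instead — the exact
application point is not fixed by the main protocol, so it is a switch).
On success the unit binds at the end of that 1D sojourn, irreversibly.
$n_{1D_{PAM}}$ defaults to 1 and is exposed as configuration; its
derivation from the dissociation probability $P_{dis}$ = 0.144 (itself from
the ~3 bp sliding length) is not reconstructed here — the constant is
carried in `search_params()` as the hook for that derivation.

Because positions never enter the encounter probability, the chain is
sampled event-exactly rather than on the 0.1 ms grid: with a single
target, the number of failed episodes is geometric, the PAM-visit counts
are negative binomial, and the binding time is a sum of three gamma
variates — a draw costs microseconds regardless of how long the search
takes, so the full 2,000-cell × 10-repeat ensembles are cheap.
`search_spatial()` keeps a position-resolved grid-stepped implementation
purely as a cross-check; the suite verifies the two agree on mean
first-binding times within sampling error, and
`analytic_search_oracle()` gives the exact mean
$(1/k_{3D\to 1D}+t_{NTI})/P_{target}-t_{NTI}+\tau_{1D}$ for constant
$P_{target}$. With several targets, unbound units are restarted
memorylessly at each binding event (the encounter probability changes
there); the error is of the order of one search cycle, negligible against
binding times of minutes to hours.

`t50_from_curve()` interpolates the time to 50% finding probability, and
`gc_sweep()` recomputes the PAM census and $t_{50\%}$ over GC 30–70% in
steps of 10: a degenerate NNN motif is GC-invariant, G-rich motifs slow
down with GC (more decoy PAMs to interrogate), T-rich motifs speed up.

## Synthetic experiments

`generate_experiment()` builds complete localisation tables with known
ground truth: per-cell track counts drawn log-uniformly on 7–200
(heterogeneous expression is reported for such populations but no law is,
so log-uniform across the analysed copy-number ranges is our choice, and
any roster can be injected), tracks simulated by the forward model, and
frames staggered so at most one emitter is active per cell at a time —
the sparse-photoactivation regime in which greedy nearest-neighbour
linking (`link_localisations()`) is well-posed. Tables round-trip through
a ThunderSTORM-like CSV dialect (nm on disk, &mu;m in memory, constant
per-row uncertainty column equal to $\sigma$).

What the generator deliberately does *not* emulate: photophysics beyond
track-length truncation (no blinking or variable emission), z-dependent
detection efficiency, chromosome structure, drift, or localisation
ambiguity between overlapping emitters. Passing the recovery tests
therefore demonstrates correctness of the estimation machinery under the
model's own assumptions, not robustness to every artefact of real
microscopy data.

## Problem sizes and numerical choices

Reduced scales used by the test-suite and the acceptance script, chosen to
exercise every claim at useful statistical resolution: observed ensembles
of 50,000 tracks for recovery (the production fit size), forward models of
6,000–20,000 particles with 8 localisation-noise replicates during
fitting, 10^5–10^6 draws for Monte-Carlo anchors, 200–2,000 cells for
search ensembles, and a 10 ms burn-in in place of 200 ms wherever the
stationary-start equivalence applies. Degenerate inputs are defined, not
accidental: zero exit rates give infinite dwells (`Inf`, never overflow),
empty histograms refuse normalisation, curves that never reach 0.5 return
`NA` with a warning, and ties in the mixture grid resolve toward the
smaller fraction.

## Known limitations

* The 1D/PAM split ($k_{1D\to PAM}$ vs $k_{PAM\to 1D}$ individually) is
  weakly identified from pooled histograms; treat the composite $t_{NTI}$
  and the stationary fractions as the robust outputs.
* Off-target binding is not modelled, and replication-fork displacement of
  bound nucleases is out of scope.
* The expected-PAM model assumes i.i.d. bases; real genomes deviate
  (dinucleotide bias), which `scan_pams()` on a real FASTA quantifies.
* Linking thresholds reproduce a standard greedy pipeline, not any
  specific legacy implementation.
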