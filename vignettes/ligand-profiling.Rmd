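---
title: "Ligand-binding profiling of amyloid fibril polymorphs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ligand-binding profiling of amyloid fibril polymorphs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilprofiler)
```

## The two-site competition model

A fibril polymorph is modelled as a set of independent binding-site
populations (`site_population()`), each with a concentration (nM) and a map
of dissociation constants per ligand; a missing entry means no binding. In a
competition assay the fluorescent reporter L0 binds site classes BS1 and
BS2, while the dark competitor L1 binds only BS1. Occupancy within a
population is competitive (mutually exclusive): the displacement observed
when a competitor is titrated in is most simply explained by the two ligands
contesting the same site, and nothing in the titration shapes requires an
allosteric mechanism. There is no cooperativity — every titration is treated
as a sum of 1:1 isotherms, which is also the model used for fitting.

For one ligand and one site class, the bound complex is the physical root of
$b^2 - (L + S + K_d)\,b + L S = 0$, evaluated in the cancellation-safe form
$b = 2LS/(p + \sqrt{p^2 - 4LS})$ with $p = L+S+K_d$. For a
reporter/competitor mixture, `solve_competition_equilibrium()` solves the
coupled mass balances for the two free concentrations with a damped Newton
iteration on log-transformed free concentrations (analytic Jacobian,
deterministic start at free = total), converging when the relative
mass-balance residual falls below 1e-10; if Newton fails, a nested bisection
(outer in free L1, inner in free L0 — both residuals are monotone) is used
instead, so the solver cannot silently return an unconverged state.

Observed signals follow from the solved state. Fluorescence intensity is
$\sum(\text{brightness}_\text{bound} \cdot b + \text{brightness}_\text{free}
\cdot f)$ over intensity-mode reporters — dark competitors contribute
nothing. Bound-state brightness is taken to be the same at BS1 and BS2. This
equal-brightness assumption is what makes the start/end-fluorescence
calculation of %BS1 valid: the fraction of signal lost on full displacement
then equals the fraction of bound reporter sitting on competitor-accessible
sites. The simulator can violate it (unequal per-population brightness) only
as an explicit stress configuration, never by default. Anisotropy follows
the equal-quantum-yield mixing rule $r = r_\text{free} + (r_\text{bound} -
r_\text{free}) f_\text{bound}$.

## Titration design

Two design choices were genuinely open and are fixed as follows:

* **Direct assays titrate fibril sites into fixed reporter** (default 100
  nM). Both readouts (intensity from bound reporter, anisotropy from the
  bound fraction) then sweep the reporter's bound fraction from 0 towards 1,
  and the 1:1 fit needs no unknown site concentration — the fixed reporter
  concentration is known metadata. The titrant axis is the
  reporter-accessible site concentration, proportional to the fibril mass
  added.
* **Competition assays titrate the dark competitor into fixed fibril (500 nM
  monomer) plus reporter (1000 nM ThT)**, the standard displacement format.

Titrant grids are a zero-titrant start point plus 12 points log-spaced from
$K_d/30$ to $30\,K_d$ of the relevant ligand's design affinity. The zero
point is not cosmetic: it anchors the start fluorescence, without which a
flat (no-displacement) titration admits fits that place an invisible
displacement below the first measured concentration.

## Fitting

`fit_direct()` fits `baseline + amplitude * theta` and `fit_competition()`
fits `f_end + (f_start - f_end) * (1 - theta)` by trust-region least squares
(minpack.lm) from three deterministic starts on a log-K_d grid (0.1x, 1x,
10x the geometric mean titrant), lowest RMSE winning. `theta` is always the
exact depletion-aware quadratic bound fraction, not the free-ligand
hyperbola; for titrant far in excess of sites the two coincide.

For competition curves the accessible-site concentration entering `theta` is
itself weakly identified whenever depletion is mild, so two nested variants
are fitted: the depletion-aware model and its hyperbola limit. The extra
parameter is kept only when an F-test (5%) supports it; on noise-free data
the depletion variant wins and recovery is exact, on noisy data the
hyperbola usually suffices. Three numerical consequences are worth stating
explicitly:

* The two variants report the apparent K_d on slightly different scales.
  Replicates of one assay are therefore fitted with a single variant chosen
  by a pooled F-test across all replicates (`fit_panel()`), and the K_d used
  for cross-fibril comparisons is always the half-displacement point of the
  plain 1:1 isotherm, which is far more stable replicate-to-replicate than
  the depletion-variant K_d (whose estimate is strongly correlated with the
  fitted site concentration).
* Plateau parameters `f_start`/`f_end` are bounded to the observed signal
  range plus one range-width of margin: on an unidentifiable flat curve an
  unbounded plateau can run away along the `amplitude x theta` ridge.
* When the information matrix is singular the fit reports infinite (not
  `NA`, not spuriously small) parameter uncertainty.

The shared-site fraction is
`percent_bs1 = 100 (f_start - f_end) / (f_start - f_background)`, clamped to
[0, 100]. `f_background`, the free-reporter signal, defaults to the measured
no-fibril blank carried on the curve and to 0 otherwise (the simulator's
reporters are dark when free; whether a real instrument's free-ThT signal is
subtracted or fitted is exposed through this argument and through the
baseline parameter of the direct fit). A competition assay whose start
fluorescence does not exceed the background by three residual SDs is
rejected as degenerate — the reporter never bound. A fit whose K_d exceeds
twice the largest titrant concentration is flagged low-confidence rather
than silently reported.

## Replicate statistics and binding calls

Parameters are estimated per replicate and pooled as
`mean +/- t(0.975, n-1) sd / sqrt(n)` (`aggregate_replicates()`), mirroring
reporting of titration parameters as averages of at least three
measurements with 95% confidence intervals; per-replicate fitting followed
by t-aggregation was chosen over a global multi-curve fit because it is what
the replicate-based confidence intervals describe.

A ligand is called bound when the pooled evidence has a 95% CI excluding
zero *and* magnitude at least three pooled residual SDs. For competition
assays the evidence is the displacement realised over the measured titrant
range (`(f_start - f_end) * theta(x_max)`), not the extrapolated limiting
displacement: when the fitted K_d lies beyond the titration range the
limiting plateau is pure extrapolation, and using it would let a flat curve
manufacture displacement evidence. For a well-designed titration (max
titrant ~30 K_d) the two differ by ~3%.

Pairwise K_d and %BS1 comparisons use two-sided paired t-tests
(`paired_t_test()`, pairing by replicate index — which experimental
dimension the pairing follows is an assumption, recorded here), at alpha =
0.05; raw p-values are the default decision basis and a Holm adjustment is
available but off by default (`adjust_tests_holm()`). Zero-variance paired
differences with nonzero mean are flagged degenerate with the p-value
floored at 1e-12, never NaN.

Ordinal profile features assert only significance-backed orderings: a
fibril's K_d class is "lowest" within its binary-profile group only when its
replicate estimates are significantly lower than every other group member's;
otherwise the members are recorded as indistinguishable. The %BS1 high/low
classes are assigned by splitting the panel's pooled %BS1 values at the
largest gap, provided the fibrils adjacent to the gap differ significantly.

## The synthetic reference panel

`make_reference_panel()` encodes the eight-polymorph ground truth as
two site populations per fibril (a competitor-accessible BS1 class and a
reporter-only BS2 class) whose parameters reproduce the qualitative profile:
AAR binds all but R and f91; S5H displaces ThT only from f91, PD, MSA and
DLB; BTA displaces ThT from all but F and R; the OXI-shared site fraction is
low (~35–40%) for R and f110 and high (~85–95%) otherwise with f65 above
f110; S5H binds PD most tightly; AAR binds MSA more tightly than DLB or PD.

Exact affinities below the binary level are not pinned down by the published
profile, only their orderings, so the generator draws each K_d log-normally
(sdlog 0.1) around fixed bases in the 0.1–10 µM window — the typical range
for amyloid-binding dyes — chosen so the jitter can never invert a
constrained ordering. Site concentrations (~100 nM sites per 500 nM monomer,
i.e. one site per five monomers — stoichiometry is a free model parameter,
not a measured quantity) get 5% jitter. Replicate noise is Gaussian,
`signal*(1 + N(0, 0.02)) + N(0, 0.5)` in intensity units (plate-reader noise
at these signal levels is near-Gaussian; Poisson counting statistics are not
modelled), with an anisotropy-scaled absolute floor of 0.002. RNG streams
are derived per (seed, fibril, assay), so panels are byte-reproducible and
assays independent.

What the simulator does *not* emulate: instrument drift and plate-position
effects, inner-filter effects at high dye concentrations, fibril
polydispersity and batch-to-batch site-density variation, aggregation
kinetics or the PMCA amplification process itself, and ligand photophysics
beyond the two-state brightness/anisotropy description. Passing round-trip
tests therefore demonstrates correctness of the estimation and
classification machinery under the stated statistical model, not robustness
of the assay to every laboratory failure mode.

## Classification and the minimal panel

The decision trees are fixed, not learned. The binary tree splits on AAR
binding, then S5H, then BTA, reaching the five binary categories; the %BS1
tree separates f65 from f110; the K_d tree identifies PD by the lowest S5H
K_d and then splits MSA from DLB on the AAR K_d. `classify()` traverses
deterministically and, when a tested feature is missing, returns the union
of labels reachable from that node — partial profiles give ambiguity sets,
matching the two-stage binary-then-quantitative protocol, and are never
errors.

The shipped reference profile table records only evidence-backed
discriminations, with per-cell provenance (`observed`, `implied`,
`not_reported`, `significant_difference`): BTA binding for f91 and the PMCA
fibrils is implied by the displacement pattern rather than individually
asserted, and the ThT/ThR and AAR/ThT assays are registered as candidates
with no recorded separations, since no discriminating result is reported for
them. Under that evidence rule two fibrils are separated by an assay iff
their binary calls differ or the fixture lists a significance-backed
quantitative difference. `minimal_assay_search()` enumerates candidate
subsets by increasing size (lexicographic in registry order, AAR-direct
first — the documented tie-break) and returns the first feasible subset with
a per-assay separation certificate; the exhaustive enumeration itself is the
minimality proof, and infeasibility returns the finest achievable partition
instead of an error.

## Validation problem sizes

The test suite and `scripts/acceptance.R` exercise: solver-versus-bisection
agreement on 1000 random instances spanning 1e-3–1e6 nM (tolerance 1e-9
relative, the solver's design accuracy); noiseless K_d recovery on a
10 nM–10 µM grid (within 1%) and %BS1 recovery at shares 20–95% (within 2
points); 50-seed end-to-end strain typing at default noise (requiring ≥95%
of panels fully labelled); and the paired-test type-I rate over 1000
identical-fibril panels (3–8% at alpha = 0.05, bracketing the nominal 5%).
These sizes were chosen to make the checks statistically meaningful while
keeping a full validation run around two minutes on a single core.

## Known limitations

* Two-ligand mixtures only; ternary competition or reporter pairs are out of
  scope, as are binding kinetics (everything is equilibrium).
* The apparent competitor K_d is conditional on the assay design (reporter
  concentration and its K_d); it is comparable across fibrils measured under
  the same design, which is all the classification uses, but it is not the
  intrinsic site affinity.
* The %BS1 endpoint calculation inherits the equal-brightness assumption;
  strongly solvatochromic site-dependent emission would bias it.
* With three replicates the paired t-test has limited power; orderings that
  fail significance are deliberately reported as indistinguishable rather
  than guessed, so under-replicated panels degrade to ambiguity sets.
* The reference decision tree is specific to this eight-polymorph panel and
  ligand toolkit; new polymorphs require re-deriving the profile table and
  re-running the panel search.
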