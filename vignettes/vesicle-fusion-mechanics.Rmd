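---
title: "Mechanics of optically driven vesicle and domain fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanics of optically driven vesicle and domain fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesifuse)
```

vesifuse models the mesoscale mechanics at play when an optical trap is
used to adhere, fuse and remodel giant unilamellar vesicles (GUVs) and the
lipid domains on them. This vignette is the package's account of those
models: what is assumed, which parameters matter, what the synthetic-data
generators do and do not emulate, and where the design was genuinely open.

## Adhesion geometry and membrane tension

Two identical spherical vesicles that adhere "zip up" into truncated
spheres sharing a flat adhesion patch. The patch is parameterised by the
contact angle $\vartheta$, defined as the arcsine of the patch diameter
normalised by the vesicle diameter. Holding the encapsulated volume fixed
while the shape deviates from a sphere *increases* the membrane area; the
closed form is

$$f(\vartheta) = \frac{3-\cos\vartheta}
  {2^{2/3}(1+\cos\vartheta)^{1/3}(2-\cos\vartheta)^{2/3}} - 1 .$$

```{r}
f40 <- area_increase_fraction(deg_to_rad(40))
100 * f40
```

Contact angles in trap experiments range from a few degrees up to about
40°, i.e. area strains from $\sim 10^{-4}$ up to $\sim 10^{-2}$. The test
suite validates the closed form against an independent quadrature oracle
(truncated-sphere volume and area with a numerical root solve for the
deformed radius) to $10^{-9}$ relative tolerance.

Assumptions and deliberate restrictions:

- **Identical vesicles only.** The closed form is derived for the
  symmetric case; `adhesion_pair()` rejects unequal radii rather than
  silently approximating.
- **Patch at most equatorial**, $\vartheta \in [0, \pi/2]$; angles outside
  that range are domain errors.
- **The flat patch disc counts toward each vesicle's membrane area.** This
  convention is required for the brute-force geometry to reproduce the
  closed form, and we verified the equivalence algebraically as well as
  numerically.
- **Linear elasticity.** The tension response is
  $\Delta\tau = K_A f(\vartheta)$ with the area expansion modulus
  $K_A$ defaulting to 200 mJ/m² (typical of fluid phosphatidylcholine
  bilayers). The low-tension entropic (logarithmic) regime is not
  implemented. Note the scales this law implies: strains of $10^{-4}$ (a
  few degrees of contact) give tens of µN/m, while the full 1.2 % strain
  at 40° gives $\sim$2.4 mN/m. Both are reported as the linear law
  dictates; the package makes no attempt to blend regimes.

Angles are radians everywhere in the API; `deg_to_rad()` / `rad_to_deg()`
convert at the boundary, matching how experimental angles are quoted in
degrees.

## Fusion bookkeeping and osmotic state

Fusion conserves the encapsulated volume, so two vesicles of radii
$r_1, r_2$ merge into one of radius $(r_1^3+r_2^3)^{1/3}$, and the
membrane-area deficit

$$1 - \frac{(r_1^3+r_2^3)^{2/3}}{r_1^2+r_2^2}$$

is largest for equal sizes, where it equals $1-2^{-1/3} \approx 20.6\,\%$:
a fifth of the bilayer becomes surplus the instant two equal vesicles
merge, which is the budget available for internal daughter structures.

Osmotic state uses van't Hoff bookkeeping, $\sum_j i_j c_j$, with sugars
counting once and NaCl twice. The standard preparation (0.75 M sucrose
inside; 0.35 M glucose + 0.2 M NaCl outside) is exactly balanced at
0.75 Osm/L; raising the glucose to 0.4 M gives 0.8 Osm/L outside and an
ideal-osmometer equilibrium volume ratio of 0.9375. The ideal-osmometer
rule (water-permeable, solute-impermeable membrane) is the simplest model
consistent with osmotic deflation; permeation kinetics are not modelled.

### Outcome classification

`classify_fusion()` is a deliberately minimal two-regime Bernoulli model
of what the experiments observe:

- laser power at the trap must exceed a threshold (default 150 mW, with
  20–100 mW the non-fusing trapping range) or the attempt is rejected;
- osmotically deflated pairs (volume ratio below $1-10^{-6}$; the
  tolerance only guards floating arithmetic, since the study's two
  conditions are discretely separated) fuse disorderly with probability 1
  — pearling generates tens of internal vesicles;
- balanced pairs fuse cleanly with probability 0.82, the observed clean
  fraction over 50 events, and disorderly otherwise.

No graded curve links osmotic ratio (or tension, power, size, or
nanoparticle count) to the clean probability: the data underlying the
model are two discrete conditions, so a single Bernoulli parameter per
condition is all the evidence supports. Disorderly outcomes record only
the class and the freed-area budget; the daughter-vesicle size
distribution has no governing mechanism to implement. Events carry an
exact volume audit and, when given a seed, are bit-reproducible.

## Composition mixing and phase lookup

Fusing a gel/liquid 1:1:0 DOPC/EggSM/Chol vesicle with a uniformly liquid
1:1:3 vesicle of the same size is expected to yield a 2:2:3 membrane in
the liquid-ordered/liquid-disordered coexistence region. Two mixing
conventions are exposed because the 2:2:3 arithmetic is ambiguous about
what the ratio parts denote:

- `mix_amounts()` sums ratio parts componentwise (equal weights give
  2:2:3). This reproduces the expected composition and is the default,
  but it is not mole-conserving if the parts are read as mole fractions
  of equal-sized membranes.
- `mix_fractions()` takes the area-weighted average of mole fractions
  (assuming equal area per molecule), which is physically conservative
  and gives 7:7:6 for the same inputs.

Neither is asserted as "correct"; the discrepancy is the point, and both
land in the same phase region of the shipped diagram.

```{r}
mixed <- mix_amounts(ternary_composition(1, 1, 0), 1,
                     ternary_composition(1, 1, 3), 1)
to_integer_ratio(mixed)
phase_lookup(mixed)
```

Phase lookup embeds barycentric (DOPC, EggSM, Chol) fractions into the
unit-edge ternary triangle — DOPC bottom-left, EggSM bottom-right, Chol
top; $x = (2\,\mathrm{EggSM}+\mathrm{Chol})/2$,
$y = (\sqrt3/2)\,\mathrm{Chol}$ — and classifies the point against the
diagram's polygons in file order, so a point on a shared boundary goes
deterministically to the first-listed region, and a point in no region is
labelled `"unassigned"` rather than silently defaulted.

**The shipped diagram is schematic.** Its regions are simple
cholesterol-fraction bands (gel/liquid below 10 mol% Chol, Lo/Ld
coexistence between 10 and 50 mol%, uniform liquid above) chosen to
reproduce the qualitative assignments of the four study compositions
(1:1:0, 1:1:3, 2:2:3, 1:1:1). Its provenance string says so; supply a
measured diagram for real compositional work.

## Nanoparticle heating

A membrane-bound gold nanoparticle absorbing power $P$ in a medium of
thermal conductivity $k$ reaches a steady-state surface temperature rise
$\Delta T_s = P/(4\pi k a)$, flat inside the (effectively isothermal)
metal and decaying as $a/r$ outside. Defaults: $a = 75$ nm (150 nm
particles), $k = 0.6$ W/(m·K) (water).

The absorbed power is an *input*, not derived from laser power: that
would require the particle's absorption cross-section at the trapping
wavelength, which is outside this package's scope. Likewise the 4–6 °C
bulk temperature rise near the laser focus is a configured constant
(`ambient_rise_c`, default 5), never computed.

The $1/r$ decay is what makes nanoparticle-mediated fusion compatible
with intact cargo: heating above half the surface rise extends only to
$2a$. Whether the surface can exceed 100 °C while a point half a vesicle
diameter (2.5 µm) away stays below 1 °C depends on the particle size —
$\Delta T(2.5\,\mu m) = \Delta T_s \cdot a/2500\,\mathrm{nm}$, so for
$a = 75$ nm a >100 °C surface implies >3 °C at 2.5 µm, and the sub-degree
regime requires $a \lesssim 25$ nm. The test suite demonstrates the
regime with a 20 nm absorber driven hard; for the default 75 nm particle
the correct statement is "a few degrees at cargo distances", not
"sub-degree".

`hot_zone_extent()` inverts the field in closed form and is cross-checked
against bisection on the field itself to $10^{-9}$ relative tolerance.

## Domain coalescence

Coexisting-phase domains are modelled as in-plane spherical caps on the
host vesicle of radius $R$: area $A = 2\pi R^2(1-\cos\alpha)$, boundary
length $L = 2\pi R \sin\alpha$, capped at a hemisphere
($\alpha \le 90^\circ$). Line energy is $\gamma \sum_i L_i$. Because $L$
is concave in $A$ and vanishes at zero area, merging two same-phase caps
(area exactly additive) never lengthens the total boundary, so every
commanded merge lowers the line energy; in the flat-disc limit two equal
caps merge to $1/\sqrt2$ of their summed boundary.

Design choices where the experiments give no equations to implement:

- The experimentally observed *bulged* out-of-plane domain geometry — and
  the inter-domain repulsion that kinetically traps many-domain states —
  is represented only by the configuration flag `kinetically_trapped`:
  domains never merge spontaneously; merges happen only when commanded.
- The optical trap is an abstract actuator: `sequential_merge()` consumes
  a user-specified order (defaulting to left-to-right), computing no trap
  forces.
- Cross-phase merges are rejected, not modelled.
- Heating-assisted coalescence enters through `line_tension_at()`, a
  linear ramp $\gamma(T) = \gamma_{ref}\max\{0,(T_c-T)/(T_c-T_{ref})\}$
  vanishing at the miscibility temperature. The linear form is the
  simplest monotone interpolation between the two facts available
  (heating lowers line tension; tension vanishes at miscibility); no
  measured $\gamma(T)$ underlies it.

Nine domains fuse to one in exactly eight events under any merge order,
with exact area conservation — the scheduler invariant the tests exercise
at every order permutation.

## Synthetic-data generators

The generators make every pipeline stage testable without measured data.
They emulate the preparation and study conditions:

- **Diameters** are log-normal with median 5 µm and shape 0.25. The
  median matches the reported "c. 5 µm"; log-normal was chosen for
  positivity and right skew typical of electroformed batches, and the
  shape parameter is a one-time realism choice (the study reports no
  dispersion). Shape 0 degenerates to all-equal diameters.
- **Compositions** are assigned from a user list of ratios with
  probabilities; solutions default to the iso-osmotic recipe.
- **Fusion campaigns** pair vesicles consecutively and classify each
  event under the campaign conditions (200 mW, clean probability 0.82 by
  default); a campaign is one seeded RNG stream, and the seed is logged
  into every table.
- **Domain configurations** partition a requested total Ld area — at most
  half the vesicle surface, so all caps and any of their merges stay
  within a hemisphere — by a flat Dirichlet(1,...,1) draw, the uniform
  simplex distribution, since no measured size distribution exists.

What the generators do *not* emulate: image-derived morphology (tubules,
pores, pearling structures, daughter-vesicle counts), correlations
between vesicle size, nanoparticle load and outcome (none are reported),
and any temperature dependence of the fusion statistics. Passing tests
therefore validate the bookkeeping, geometry and outcome *statistics* of
the models — not the morphological realism of any individual event.

## Numerical choices

- Exactness: volume audits are checked to $10^{-12}$ relative; Dirichlet
  partitions set the last area by subtraction so totals conserve exactly.
- The closed-form/oracle comparisons run at $10^{-9}$ relative tolerance
  with `uniroot` solves at tightened tolerances.
- Integer-ratio recovery searches denominators to 1000 at $10^{-6}$
  relative tolerance, then falls back to rounded fractions.
- Boundary ties in phase lookup go to the first-listed region;
  degenerate inputs (zero compositions, both-zero radii, zero external
  osmolarity, oversized caps) are rejected with explicit errors, never
  clamped.
- Study problem sizes are used throughout the analyses: 50-event
  campaigns over 100-vesicle populations, nine-domain configurations,
  and a 10,000-trial outcome check in the test suite (binomial standard
  error $\approx 0.4\,\%$).

## Known limitations

Pore dynamics, pearling kinetics, tubule retraction and trap-force
magnitudes are out of scope (no governing equations to implement);
adhesion is geometric, with no adhesion-energy minimisation (the contact
angle is an input, not a prediction); the phase diagram is schematic; and
the heating model is a steady-state single-particle point-absorber —
no Mie theory, transients, or collective heating.
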