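---
title: "Deriving composite small-angle scattering models with scatterkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving composite small-angle scattering models with scatterkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scatterkit)
```

## The model

scatterkit derives the orientationally averaged scattering of composite
structures assembled from sub-units joined at reference points.  The
factorization it exploits rests on three assumptions:

1. **acyclic connectivity** — no set of sub-units is linked into a closed
   loop (loop closure would correlate the conformations of every member);
2. **completely flexible links** — a joint imposes co-location of two
   reference points but no orientational constraint;
3. **non-interacting sub-units** — no excluded volume or other interaction
   between different sub-units.

Under these assumptions the internal conformation and orientation of every
sub-unit are statistically independent, and the pair-distance distribution
between scatterers in different sub-units is a convolution of per-sub-unit
steps along the unique tree path connecting them.  In Fourier space the
convolution becomes a product: the interference term of sub-units $I$ and
$J$ is

$$\beta_I \beta_J \, A_{I\alpha}(q)\;\prod_{k}\Psi_{k\delta\sigma}(q)\;A_{J\omega}(q),$$

an amplitude out of $I$, a phase factor across every intermediate sub-unit,
and an amplitude into $J$.  Summing $\beta_I^2F_I$ once per sub-unit and the
interference term over ordered pairs, and dividing by $(\sum_I\beta_I)^2$,
gives the normalized composite form factor; the analogous sums give the
composite amplitude relative to any reference point and the composite phase
factor between any two reference points.  Because a wrapped structure again
has an $F$, a set of $A$s and $\Psi$s, hierarchical structures are derived
by recursion, terminating at the sub-unit factor table.

The factor table itself holds closed forms in the dimensionless products
$x = q^2R_g^2$, $u = qL$, $y = qR$: the Debye function
$2(e^{-x}+x-1)/x^2$ for the Gaussian chain, $\mathrm{Si}$-based factors
for the rod, spherical Bessel forms for spheres and shells, a Dawson-function
form for the Gaussian loop, and Bessel/Struve-type forms for circle and
disk.  Two families have no practical closed form — the disk rim against its
face, and the cylinder factors involving hull, ends or combined surface —
and are evaluated as seeded pair-distance Monte Carlo averages of
$\langle\mathrm{sinc}(qr)\rangle$ (the orientational average of a fixed
displacement $r$ is exactly $\mathrm{sinc}(qr)$).  These numeric-tier
factors are memoized at $2^{16}$ pairs with a fixed seed, evaluate like any
other factor, and refuse symbolic export with a pointer to numeric
evaluation.

## Parameters and symbols

Structural parameters are named `<stem>_<tag>`: `Rg2` (squared radius of
gyration, length²), `L` (rod/cylinder length), `R`, `Ri`, `Ro` (radii), and
`beta` (excess scattering length, arbitrary units).  The tag defaults to
the unit name; tagging several units identically declares them identical in
scattering terms, which is also how all instances of a wrapped structure
type share one parameter set.  Distinguishing two instances of a type is
therefore done by tagging the template differently before wrapping — a
deliberate design choice that mirrors how identical repeat units are
actually modeled, and keeps the derived expressions compact.  No units are
enforced: every expression depends on products of $q$ with a length, so any
consistent unit choice cancels.

Interference terms are enumerated over unordered pairs and carried with an
explicit factor 2 (the $I,J$ and $J,I$ paths contribute identical terms);
the term metadata still reports $n$ form-factor terms and $n(n-1)$
interference terms for an $n$-unit tree, which is the bookkeeping the
diagrammatic expansion prescribes.

## Sizes and double counting

Sizes are read off the assembled expressions, not tracked in a parallel
table: $R_g^2=-3\,c_2$ where $c_2$ is the $q^2$ coefficient of the
normalized composite $F$, and the sigma mean-square distances are $-6c_2$
of a composite $A$ or $\Psi$.  Computing them by series expansion of the
same expressions that are evaluated numerically guarantees the two can
never disagree.  The $\sigma$ factor is *not* divided out automatically:
when the reference distribution coincides with the scatterer distribution
(a contour point against its own chain), every distance is counted twice
and the undivided result is twice the radius of gyration.  The tool cannot
deduce coincidence from the graph, so `smsd_ref2scat()` and
`smsd_ref2ref()` return the raw value and offer an explicit
`assume_coincident_distributions` flag.

## Numerical choices

- **Limit safety.**  Every factor implementation switches to its Maclaurin
  series for small arguments (thresholds $10^{-2}$–$10^{-4}$ by function,
  where the series is accurate to machine precision), so $q = 0$ evaluates
  to exactly 1 without special casing, and `expm1` is used where naive
  evaluation would cancel.
- **Series engine.**  Small-$q$ expansions are computed structurally on the
  expression tree with constant folding.  Explicit divisions with removable
  singularities are handled by shifting through shared leading zeros; a
  zero that folding cannot see (symbolic cancellation) is detected by
  evaluating the coefficient at two fixed irrational parameter assignments.
  Coefficients beyond the computed order are marked invalid and the
  expansion retried at higher order only when one is actually requested.
- **Dawson function.**  Evaluated through `pracma::erfi` for $t\le 3$,
  direct quadrature of $\int_0^t e^{s^2-t^2}ds$ for $3<t\le 6$, and the
  asymptotic series beyond — accurate to ~$10^{-12}$ across the switchovers.
- **Circle factor.**  $(1/a)\int_0^a J_0$ by Maclaurin series for $a<8$ and
  adaptive quadrature above; the Python export uses the Struve-function
  closed form.
- **Cylinder.**  $F$ and $A_\mathrm{center}$ by 64-point Gauss–Legendre
  quadrature over the orientation angle; their Guinier coefficients use the
  exact second moment $R^2/2+L^2/12$.
- **No automatic simplification.**  Expressions are emitted as assembled;
  `sk_simplify()` is an explicit constant-folding pass.  Exact results such
  as integer radii of gyration therefore come out of numeric evaluation of
  the expanded coefficient, to machine precision.

## The Monte Carlo oracle

`debye_estimate()` is a brute-force validator: it samples explicit bead
conformations of the assembled structure — polymers as discrete random
walks (step variance $6R_g^2/(n-1)$ per bond, three components), loops as
Brownian bridges, rigid bodies as uniformly sampled point clouds with
independent random orientations — places sub-units so that each link's two
realized points coincide exactly, redraws distributed reference points on
every conformation, and averages the normalized Debye double sum
$\sum_{ij}\beta_i\beta_j\,\mathrm{sinc}(qr_{ij})/(\sum\beta)^2$ (an
Rcpp kernel; $O(n_\mathrm{beads}^2)$ per conformation by design).  Within a
curve-like sub-unit the discrete chain's diagonal is part of its form
factor and is kept; within an iid point cloud (solids, and rigid curves
sampled as iid points) the diagonal is a discretization artifact and the
distinct-pair average is used, which is unbiased for the continuous body.

What passing these tests shows — and does not.  The oracle realizes exactly
the statistical model of the formalism: ideal chains, flexible joints, no
interactions.  Agreement therefore validates the symbolic derivation, not
the physics of any real sample; excluded volume, chain stiffness,
polydispersity and inter-particle structure factors are all outside both
the generator and the derivation.

Default problem sizes used by the validation suite: $10^4$ conformations
and 50–100 beads per sub-unit for composite fixtures (diblock, micelle,
ten-rod chain, 21-arm dendrimer), $2\times10^5$ pairs for per-factor
distance checks.  Tolerances are stated as z-scores against the Monte Carlo
standard error — scale-free, so the same tests run at any contrast or size.
Batches of ~150 simultaneous z comparisons use a 4σ cut (a Bonferroni-style
allowance; at raw 3σ one spurious excursion per run would be expected),
single designated comparisons use 3σ.

## Design choices where the design was open

- **Wrapping consumes the graph.**  A wrapped structure type is immutable
  and its template units are no longer growable; re-opening a type would
  invalidate every cached composite factor derived from it.
- **Both-sides-existing links are rejected.**  A link is only created
  together with the unit it attaches, which makes cycles unrepresentable
  rather than merely checked for.
- **Rod/polymer "middle"** is the contour midpoint, so each half
  contributes a half-length amplitude.
- **Cylinder "surface"** is the area-weighted union of hull and both end
  disks; the spherical shell's combined "surface" weights its two surfaces
  by area fraction.
- **Config front end.**  A YAML schema (`subunits`, `links`, `structures`,
  `parameters`, `qgrid`, `requests`) mirrors the four builder methods; the
  q-grid size field is called `points` because YAML 1.1 parses a bare `n`
  key as a boolean.

## Known limitations

Cyclic structures are excluded by the formalism itself; excluded-volume or
semiflexible chain statistics, polydispersity, inter-structure correlations
(decoupling approximation, RPA, PRISM) and fitting to experimental data are
out of scope — though the composite amplitude that structure-factor
approximations consume is exported.  Numeric-tier factors cannot be
exported symbolically.  The Monte Carlo oracle is quadratic in bead count
and meant for validation, not production evaluation of large structures.
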