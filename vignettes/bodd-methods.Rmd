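---
title: "Gaussian deformation density on top of the IAM: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaussian deformation density on top of the IAM: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Conventional small-molecule refinement uses the independent atom model
(IAM): the unit-cell density is a superposition of spherically averaged
free atoms, each scattering as a four-Gaussian form factor
`f(s) = sum a_i exp(-b_i s^2) + c` with `s = sin(theta)/lambda`,
attenuated by its Debye–Waller factor. Chemical bonding redistributes
electron density into bonds and lone pairs; the IAM cannot represent
this, and the misfit surfaces as bond-centered residual density,
inflated non-hydrogen ADPs and foreshortened X–H bonds.

`boddr` models that redistribution additively with Gaussian lobes while
keeping every atom neutral:

* A **BEDE** instruction on the bond `atom1 -> atom2` adds a lobe of
  amplitude `+A` electrons at distance `r` (Å) from `atom1` along the
  bond and a compensating lobe `-A` at `atom1`. Naively this is two
  Gaussians with three parameters each (position, amplitude, spread);
  forcing amplitude negation and pinning the `-A` lobe to the atom
  reduces the six raw parameters to four free ones: `r`, `A`, `B1`,
  `B2`.
* A **LONE** instruction places `n(m)` lobes of amplitude `+A` at
  distance `r` along directions fixed by the geometry code `m`, plus one
  compensating lobe of amplitude `-(sum of added amplitudes)` at the
  atom: `-2A` for `m = 2`, `-3A` for `m = 3`, and `-6A` for the twelve
  half-occupied lobes of `m = 12`. Codes 6, 7 and 9 serve pi density
  (two lobes perpendicular to, or in, a bonding plane); 12 is the
  disordered-methyl analogue (twelve lobes on a cone, successive
  azimuths 30°, the two half-sets staggered by 60°); 15 completes a 4–5
  coordinate polyhedron. Lobe directions follow the same logic used to
  place riding hydrogens from the remaining bonds; where the text source
  of the m-catalog is incomplete, codes outside
  {1, 2, 3, 6, 7, 9, 12, 15} are rejected with a clear error rather than
  guessed.

In reciprocal space a lobe scatters as
`A exp(-B * 8 pi^2 U_eq(host) * s^2) * exp(2 pi i h . x_lobe)`: the
dimensionless spread `B` *multiplies* the host atom's isotropic
displacement exponent, so lobes ride both the position and the thermal
motion of their host. The coupling is stated in the underlying model
only as "multiplied by the displacement parameters"; we take the
multiplicative reading as the default and expose the additive
alternative (`B + 8 pi^2 U_eq`) behind `b_coupling = "additive"`,
because the one-sentence specification admits both. Lobes use the
isotropic equivalent `U_eq` rather than the full anisotropic tensor: the
card grammar provides one spread scalar per lobe, so a tensor coupling
would be unconstrained.

Card values are *never* refined against experimental data — they come
from a database and stay fixed. Refinable are atomic positions, ADPs,
the overall scale factor and exactly three global asphericity scales
`k_A`, `k_B1`, `k_B2` multiplying all `A`, `B1`, `B2` values (the
absolute scale of database parameters is unknown for a new data set).
With `k_A = 0` the structure factors, Jacobian and refinement trajectory
are bit-identical to the pure-IAM path — downward compatibility is a
design requirement, tested at `identical()` strictness.

## Atom typing and the archetype database

A database entry is keyed by the atom's two-shell environment graph.
Node colors are `(r, g, b, a)` tuples: the root carries
`(0, sum of its bond lengths, 0, 1)`; first-shell nodes
`(distance to root, own bond-length sum, 1, 1)`; second-shell nodes
`(distance to root, 0, 2, a)`. The second-shell alpha entry is
unreadable in the source material; it is implemented as the constant 1,
isolated in one helper (`level2_alpha()`) so the convention can be
revised in a single place. Colors are quantized (default 0.01 Å —
refined bond lengths are not exact, and the hash must be stable against
sub-picometre noise) and the graph is canonicalized by iterative
Weisfeiler–Lehman color refinement with lexicographic tie-breaking; the
digest of the canonical serialization is the database key. This is not a
complete graph-isomorphism canonicalization, but it is deterministic,
invariant under relabeling (property-tested over random permutations),
and collisions are implausible at the size of chemical environment
graphs.

Assignment is automatic: exact hash match instantiates the record's
templates with the actual neighbor labels; a missing archetype falls
back to the nearest record of the same element under a level-wise
color-overlap score (the fraction of matching quantized colors,
level by level) and is flagged; elements with no record at all scatter
as plain IAM — deliberately, since mixing aspherical light atoms with
IAM heavy atoms is a supported use case. The similarity metric is this
package's own choice; the source material only promises that "suitable
alternatives are identified".

Reference card values are obtained by fitting against intensities
computed from a target density. The production-scale version of that
process (DFT model compounds, large metaheuristic searches) is out of
scope; `fit_archetype()` implements a faithful toy-scale analogue — a
seeded differential-evolution search over each card's `(r, A, B1, B2)`
within physical bounds, polished by L-BFGS-B — and is validated by
recovering known card values from oracle-generated data.

## Refinement

The target is intensities: minimize `sum w (Fo^2 - |Fc|^2)^2` with the
SHELX weighting scheme `w = 1/(sigma^2 + (aP)^2 + bP)`,
`P = (max(Fo^2,0) + 2 Fc^2)/3`. Steps are Levenberg–Marquardt with a
forward-difference Jacobian. The original plan called for analytic
derivatives for positions/ADPs/scale; because BEDE and LONE lobe
geometry is itself a function of the atomic positions (a lobe moves when
either bonded atom moves), the chain rule through the geometry
construction adds real complexity for no measurable gain at this problem
size, so the package differentiates numerically throughout. Two
numerical safeguards matter:

* **Floating origin.** In P1 the intensities are exactly invariant under
  a uniform translation, so the normal matrix has three exact null
  directions. The mean fractional coordinate along each axis is
  restrained to its starting value (a rank-3 restraint term added to the
  normal matrix, plus re-centering after each accepted step).
* **Soft directions.** When `k_A` refines toward 0, the spread-scale
  columns vanish and the normal matrix becomes numerically singular.
  Marquardt damping uses a scaled identity floor, and esds come from an
  SVD pseudo-inverse, so flat directions get large-but-finite esds
  instead of a failed solve. A step that cannot reduce the cost at any
  damping is reported as converged ("stalled"); an unsolvable system is
  not.

Convergence: max |shift|/esd < 0.01 (default) or 50 cycles; the damped
step contract (cost never increases across accepted steps) is
property-tested. Riding hydrogens sit at
`elongation x ideal X–H length` along the current parent-to-H direction
and follow their parent rigidly; the deformation-mode default elongation
is 1.14 (1.0 in IAM mode), compensating the foreshortening that
spherical H scattering factors cause.

## Quality metrics and maps

`R1` uses the conventional `Fo^2 > 2 sigma` cut (the source material
does not state its cut; 2 sigma is the field default). `R_complete`
partitions the data into k seeded folds (default k = 10), re-refines
with each fold excluded after a small seeded coordinate shake (default
0.005 Å — large enough to decorrelate from the full-data minimum, two
orders below a bond length), and assembles each reflection's residual
from the model that never saw it. The bias statistic defaults to
`b = (Rc_IAM - R1_IAM) - (Rc_BODD - R1_BODD)`; the printed formula in
the source material is unrecoverable (rendered as an image) and its
tabulated values are not reproducible from the other columns, so this
gap-difference definition is explicitly this package's choice, kept
behind a pluggable `definition` argument. Its sign convention — positive
when the deformation model shrinks the cross-validation gap — is what
the accompanying text states.

ADP comparisons report the mean difference MD (reference minus
comparison) and its population standard deviation (divisor N), six
components per anisotropic atom and one per isotropic atom.

Residual maps are FFT syntheses with coefficients
`(|Fo| - |Fc|) exp(i phi_c)` on a default 0.1 Å grid (spacings coarser
than half the resolution are refused as aliasing); deformation maps are
direct real-space sums of the placed lobes, whose cell integral is zero
by construction (quadrature-tested). Grids are written in CCP4 format
and as plain-text dumps; Parseval consistency between map norm and
coefficient norm is tested exactly on P1 toys.

## The synthetic world

Five P1 fixtures (≤ 12 atoms, orthorhombic cells, isotropic ADPs,
seeded sub-picometre jitter emulating refinement scatter) cover the
instruction vocabulary: ethane (pure BEDE), formaldehyde (carbonyl with
in-plane LONE m = 9), water (m = 2), methylamine (m = 1 on N) and an
Fe–O toy keeping the metal IAM-only. Simulated data carry multiplicative
Gaussian noise on Fo² (2% default — a realistic precision for a good
modern room-temperature data set) with sigmas set consistently with the
noise model, and truth overall scales of 1.0–1.2 matching the magnitude
of experimentally reported scale factors.

The independent oracle samples the analytic real-space density (each
reciprocal Gaussian term mapped to its exact real-space Gaussian,
including Debye–Waller smearing) on a grid and obtains structure factors
by FFT; analytic and numerical F agree to well below the 0.5% acceptance
band. The oracle is restricted to P1, orthogonal cells and isotropic
ADPs — exactly the fixture world — so its separable Gaussian
accumulation stays exact; symmetry correctness is tested separately by
expanding a screw-axis toy to P1 and comparing structure factors.

A green fixture suite establishes that the machinery is internally
consistent and reproduces the *directional* claims (R1 drop,
smaller non-H ADPs, reduced residual extrema, bias-sign arithmetic) on
data whose truth contains bond density. It does not establish agreement
with any experimental dataset: the published headline numbers were
measured on deposited data this package does not ship.

## Known limitations

* Fits with many hydrogen hosts can stall in nearly flat
  `k_B2`–U(H) valleys (seen with the methylamine fixture): the
  refinement converges by shift/esd with R1 at a few tenths of a percent
  rather than machine zero. Exact parameter recovery is demonstrated on
  the carbonyl fixture; the flat-valley behavior is inherent to the
  strong correlation between subtracted-lobe spreads and host ADPs.
* Lattice centering and inversion are supported through LATT; anomalous
  dispersion, extinction, and twinning are parsed-and-ignored.
* The archetype hash quantization makes near-bucket-boundary geometries
  hash-unstable by construction; assignment then degrades gracefully to
  the flagged nearest-match path.
* `m = 15` with four exactly planar bonds has an undefined lobe
  direction and errors; this mirrors the chemistry (no lone-pair site is
  defined by such a geometry).
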