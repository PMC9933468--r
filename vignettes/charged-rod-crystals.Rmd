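---
title: "Ground states and stability of screened charged-rod crystals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ground states and stability of screened charged-rod crystals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`rodlattice` studies suspensions of identical rigid, volumeless, linear
rods of length $a$ carrying $Z$ effective elementary charges, immersed in
a screening electrolyte. Each rod is discretised into $M$ collinear
segments of length $a/M$ and charge $Z/M$. Two segments $i$, $j$ at
separation $r_{ij}$ interact through the far-field anisotropic
screened-Coulomb (Yukawa) potential

$$\beta u_{ij} \;=\; \Big(\tfrac{Z}{M}\Big)^{2} \lambda\,
  S(x_i)\, S(x_j)\, \frac{e^{-\kappa r_{ij}}}{r_{ij}},
  \qquad
  S(x) = \frac{\sinh x}{x},\quad
  x_n = \tfrac{1}{2}\kappa \tfrac{a}{M} (\hat v_n \cdot \hat r_{ij}),$$

the large-separation interaction of two uniformly charged line segments
in Debye–Hückel screening: the $S$ factors are the exact angular
form factors of a finite line charge, and the expression converges to the
double line-charge integral as $\kappa r_{ij} \gg 1$ and
$r_{ij} \gg a/M$. The test suite verifies this against an independent
Gauss–Legendre quadrature of the two-segment integral on randomised
geometries. Rod–rod energies (`rod_pair_energy()`) sum all $M \times M$
segment pairs; self-energies are excluded. Everything is reduced by the
rod length ($a = 1$, $\kappa^* = \kappa a$, $\rho^* = \rho a^3$) and
energies are reported in units of $Z^2 l_B / a$ — multiply by
$Z^2 l_B/a$ to get $k_BT$.

Because the interaction is purely repulsive and strongly screened, no
hard core is needed: close approaches are penalised exponentially. The
model has no excluded volume, no polydispersity and linear screening
only; what passing tests show is therefore a statement about
electrostatic many-body selection between candidate phases, not a full
free-energy phase diagram.

## Crystal candidates and their energies

Candidate phases are stacked triangular (hexagonal) layers:

* **AAA** — layers in registry; **ABA** — hcp registry alternation;
  **ABC** — fcc-like three-registry cycle; square-based variants
  (`cubicAAA`, `cubicABA`) are kept only as a cross-check and always lose
  to their hexagonal counterparts.
* Layer spacing follows from the fixed density,
  $l_z^* = 2/(\sqrt3 \rho^* l_{xy}^{*2})$, so one in-plane parameter
  $l_{xy}^*$ spans the lattice family.
* Orientations are uniform per layer, with polar tilt $\phi$ and
  azimuth $\psi_k = \Theta_2 + k\Theta_1$ for layer $k$: $\Theta_1$ is
  the twist per layer (heliconical/cholesteric order), $\Theta_2$ the
  start angle.

A convention worth stating explicitly: the in-plane basis is oriented so
nearest-neighbour directions lie at $30^\circ + k\,60^\circ$ from the
$x$-axis, i.e. $\psi = 0$ points along a *second*-neighbour direction.
The favourable twist angles $\Theta_1 \in \{0, 60, 120, 180\}$ are tied
to the lattice this way: rods tilted into the layer run between their
nearest neighbours, and their closest on-axis contacts are the second
neighbours "in front" and "behind". With the azimuth origin on a
nearest-neighbour direction instead, tilted rods collide head-on and the
heliconical minima disappear — energies are $60^\circ$-periodic in
$\Theta_2$, which the suite checks.

`energy_per_particle()` evaluates a central rod's interaction with every
rod inside the cutoff radius and reports intra-/interplane and
neighbour-shell decompositions. Following the truncation rule, segment
interactions vanish beyond $n_{trunc}/\kappa^* + 1.5 \rho^{*-1/3}$ and
whole rod pairs beyond $1$ plus that; the second term keeps enough
neighbour shells at strong screening, the first at weak screening. The
cluster is the sphere of all rods within the rod cutoff (not a fixed
shell count), which is also the minimal system size. No $\tfrac12$
double-counting factor is applied; at equal density the convention
cancels from every comparison.

Defaults for lattice work are $M = 15$ and $n_{trunc} = 10$; sensitivity
checks in the suite confirm the *relative* ordering of competing minima
is stable down to $M = 3$, which is why the cheaper discretisations
($M = 7$, $n_{trunc} = 6$) are used for the wide categorical sweeps and
the Monte Carlo runs.

## Scans, minima, barriers

`scan_lxy()` scans $l_{xy}^*$ on a coarse grid (60 points by default —
enough to resolve double-minimum curves) and refines each interior local
minimum by golden-section search to a relative tolerance of $10^{-4}$.
Minima are classified primary/secondary by energy rank; the barrier
between adjacent minima is the maximum of the curve between them minus
the shallower minimum. Because the cutoff makes the rod count jump as
the geometry changes, the steep flanks carry small discontinuities; grid
minima with relative prominence below $0.5\%$ are discarded as
truncation noise (`min_prominence`). If the global grid minimum lands on
a bracket end the scan warns instead of extrapolating.

`scan_tilt()` re-optimises $l_{xy}^*$ at every tilt angle (nested
coarse grid + refinement, 48 points by default) for each
(stacking, $\Theta_1$) candidate on a $2.5^\circ$ grid, and assembles the
lower envelope across candidates. `find_ground_state()` runs the same
machinery over the full candidate set
$\{AAA, ABA, ABC\} \times \Theta_1 \in \{0,60,120,180\} \times \phi$-grid
and reports ties within a relative tolerance ($10^{-3}$ by default),
since ABA and ABC are near-degenerate at $\phi = 0$. $\Theta_2$ is fixed
at 0 throughout (its own scan utility exists via
`orientation_field(theta2 =)`); the grid resolutions are this package's
choices — the method is insensitive to them beyond the stated
refinement tolerances.

At $\rho^* = 10$ these scans give: two ABC $\phi = 0$ minima at
$l^*_{xy} \approx 1/3$ (primary) and $\approx 1/2$ (secondary,
interdigitated/"piercing" geometry), a single heliconical AAA
($\phi = 80^\circ$, $\Theta_1 = 120^\circ$) minimum at $\approx 2/3$,
a $+15\%$/$+145\%$ energy excess of the secondary/heliconical minima at
$\kappa^* = 50$, and tilt-scan local minima near $10^\circ$ and at the
$90^\circ$ end for close-packed stacks (with a shallow one near
$40$–$45^\circ$ at low $\kappa^*$) and near $20$–$25^\circ$ and
$75$–$80^\circ$ for AAA at $\Theta_1 = 120^\circ$. The ground state is
unidirectional close-packed ($\phi = 0$, ABA/ABC) across
$\rho^* \in [1, 20]$, $\kappa^* \in [5, 50]$.

One caveat on absolute numbers: every quantity above is a *relative*
energy or a location, and those are pinned by the quadrature oracle.
The test suite also carries one check of the absolute ground-state
energy magnitude against an external order-of-magnitude figure that the
oracle-normalised potential does not reproduce (it is off by orders of
magnitude while all relative energies agree to a percent); that check
is kept, honestly failing, rather than rescaling the model to it.

## Monte Carlo

`run_mc()` is NVT Metropolis with single-rod displacement, rotation and
combined displacement–rotation trials plus isochoric box-dimension
moves (one box length scaled within $\pm 0.5\%$, a second rescaled to
conserve volume exactly, the third untouched; rod centres map
affinely). One MC step is $N$ single-rod trials or 9 box trials; box
steps run every 10th step by default (the interleaving ratio is a free
choice of this package, logged in the config). At $T = 0$ only strictly
downhill moves are accepted (greedy stochastic minimisation); at finite
$T$ the standard $\min(1, e^{-\Delta u/T})$ rule applies with symmetric
proposals. Step sizes adapt multiplicatively toward a 20–50%
acceptance during the first 300 steps of every 1000-step block
(adjusting every 10th step) and freeze for the block's remainder.

Two implementation details matter for correctness at this scale:

* **Periodic images.** Supercells commensurate with the twist can be
  smaller than twice the interaction cutoff, so energies sum over *all*
  periodic images within the cutoff (including a rod with its own
  images) rather than assuming minimum-image. The compiled engine keeps
  a symmetric rod-pair energy cache so a trial costs one row
  recomputation; the suite cross-checks the cache against naive
  recomputation (`debug_check`) and an all-images R loop.
* **Seeding instabilities.** An ideal lattice is a stationary point of
  the energy by symmetry: from a perfect crystal *every* single-rod
  move is uphill and a greedy run is frozen. Stability tests therefore
  start from `perturb_configuration()` (position jitter
  $\pm 0.02$, orientation kicks $\le 5^\circ$). A metastable structure
  relaxes back; an unstable one escapes.

The flagship relaxation: an optimised AAA crystal with in-plane
cholesteric twist ($\phi = 90^\circ$, $\Theta_1 = 60^\circ$) at
$\rho^* = 10$, $\kappa^* = 20$ is unstable even at $T = 0$ and slides
into a heliconical state with mean tilt $\approx 75^\circ$ and a
three-layer pitch ($\Theta_1 = 120^\circ$), with the box distorting to
accommodate the new layer spacing. The desk-scale protocol uses a
$2 \times 4 \times 12$-cell supercell (192 rods, commensurate with both
$\Theta_1 = 60$ and $120$), $M = 7$, $n_{trunc} = 6$ and 1200–1500 MC
steps (about two minutes per run). Greedy descent can arrest in a
shallow neighbouring basin (a heliconical state at $\approx 85^\circ$
tilt, $\approx 4.6\%$ higher in energy), so the reproduction script runs
it as minimisation with restarts — each restart perturbs the ideal
crystal afresh, anneals 300 steps at a reduced temperature of
$2\times10^{-5}$ (a fraction of a percent of the per-rod energy, far
below the lattice-scan barriers) and quenches to $T = 0$ — and reports
the lowest-energy end state. Full-size melting/quench protocols (tens
of thousands of rods and of steps) are out of desk scale here and are
represented qualitatively by the heating/quench property tests.

Order parameters come from the Maier–Saupe tensor
$Q = (3\langle \hat v \otimes \hat v\rangle - I)/2$: $S$ is the largest
eigenvalue, $B$ the difference of the two others ($(S, B) = (1/4, 3/4)$
for an ideal planar three-fold twist, $(0.20, 0.60)$ at
$\phi = 75^\circ$ — the relaxed state reproduces both). `pair_correlation()`
gives the standard minimum-image $g(r)$ over rod centres (bin width
0.02 by default).

## Mapping to cellulose-nanocrystal suspensions

With counterion-only screening the evaporation of a suspension traces
$\kappa^* = \sqrt{4\pi l_B\, \xi\, \rho^*}$ at fixed line valency
density $\xi = Z/a$ (`evaporation_kappa()`, `evaporation_curve()`);
proton counterions give $pH = -\log_{10} c$ (`ph_from_state()`), which
pins the worked example $\xi = 2\,\mathrm{nm}^{-1}$, $a = 150$ nm,
$\rho^* = 17 \to$ pH 2.6. `line_valency_from_material()` estimates
$\xi$ from surface-site or per-mass charge densities (the most direct
arithmetic gives $\approx 3.2$ and $\approx 5.5\ \mathrm{nm^{-1}}$ for
the two standard CNC preparations). `effective_aspect_ratio()`
implements the swollen-rod picture $a' = a + 2\kappa^{-1}$,
$d' = d + 2\kappa^{-1}$; `barrier_to_line_charge()` inverts a reduced
lattice barrier into the valency at which it equals $k_BT$. Because the
package declines to pick one coupling-parameter convention,
`coupling_parameters()` reports all three length choices side by side;
each scales as $\xi^2 a$ at a fixed reduced state point.

## Numerical choices and limitations

* $\sinh(x)/x$ is evaluated by series below $|x| = 2$ (absolute error
  $<10^{-12}$), avoiding cancellation and libm cost in the hot loop.
* Golden-section refinement assumes single minima within a bracket of
  one grid spacing; the coarse grid density is what guarantees that.
* The running MC energy is refreshed from scratch every 200 steps (and
  on demand) to bound floating-point drift of the cached updates.
* Degenerate geometries (exactly coincident segment centres) raise
  errors rather than being regularised; they are measure-zero and
  excluded by construction in lattice scans.
* Finite clusters make absolute energies depend on $n_{trunc}$
  monotonically from below; comparisons are always made at matched
  truncation.
* The $T = 0$ relaxation endpoint is a local minimum selected by the
  perturbation seed; different seeds can land in different nearby
  basins (the mean tilt is reproducible to a few degrees, the pitch
  robustly three layers).

```{r, eval = FALSE}
library(rodlattice)
p <- potential_params(kappa_star = 50, M = 15, n_trunc = 10)
scan_lxy("ABC", orientation_field(0), p, rho_star = 10)
```
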