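---
title: "Models and numerical methods in ionphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in ionphase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ionphase` models how salt, counterion valency, and ATP-magnesium modulate
liquid-liquid phase separation (LLPS) of charged intrinsically disordered
protein regions (IDRs), with the 103-residue C-terminal IDR of Caprin1 and
its heptaphosphorylated variant (pY-Caprin1) as the reference systems.
Caprin1 is a polyelectrolyte (net charge +13, NCPR = 0.126); phosphorylating
its seven tyrosines at about -2 each turns it into a near-neutral
polyampholyte (net charge -1). That single compositional change flips the
salt response of LLPS: the polyelectrolyte needs ions to condense and shows
reentrant behavior (LLPS propensity rises with salt, peaks, then falls),
while the polyampholyte condenses on its own and is monotonically dissolved
by salt. The package implements three complementary treatments of the same
electrostatic physics -- an analytical rG-RPA+FH free energy, complex-
Langevin field-theoretic simulation (FTS), and coarse-grained explicit-ion
molecular dynamics -- plus a counterion-bridging analyzer and synthetic-data
generators that make everything testable offline.

## Sequences and charges

Residue charges at pH 7.4 are +1 (R, K), -1 (D, E), `py_charge` (default -2)
for phospho-tyrosine, and 0 otherwise. Histidine is treated as uncharged at
neutral pH and the termini of an internal IDR fragment carry no charge;
these conventions reproduce the published count of 19 charged residues for
the Caprin1 IDR. Positions are 1-based.

The shipped `caprin1_wt` fixture is a **synthetic stand-in**: the literal
construct sequence is not redistributed, so the fixture reproduces the
published composition exactly (103 residues; 15 R, 1 K, 3 D, 7 Y; net
charge +13, NCPR = 13/103, FCR = 19/103) and the coarse charge patterning
(arginine-rich N-terminal region and a second cluster before the
C-terminus) on a low-complexity G/S/Q/N/P/A background. Every charge-level
quantity (Q, NCPR, FCR, electroneutrality counts) is exact for the real
construct; residue-identity-level results (e.g. the MD well depths
assigned to specific non-charged positions) are qualitative. The RtoK
variants substitute 15 or 4 arginines by lysine and leave the charge
sequence invariant by construction.

Electroneutrality is bookkept throughout via
`|Q| rho_p + zs rho_s = zc rho_c`, with "counterions" the small ions of
sign opposite to the polymer net charge. For a salt-free box of 100
Caprin1 chains with monovalent counterions this gives 1300 ions.

## The rG-RPA+FH free energy

Internal units: energies in kBT, lengths in the Kuhn length b = 3.8 A
(the peptide virtual bond), concentrations in b^-3. The free-energy density
of a solution state (polymer chains `rho_p`, counterions `rho_c`, salt
`rho_s`, implicit solvent filling the rest) is

```
f = f_ideal + f_fh + f_ex + f_el
```

* `f_ideal`: exact mixing entropy `sum_i rho_i (ln rho_i - 1)` for chains
  and ions plus `phi_w ln phi_w + (1 - phi_w)` for the implicit solvent,
  with `phi_w = 1 - N rho_p - rho_c - rho_s` (every bead, residue or ion,
  occupies one b^3 cell). This free-volume convention supplies the leading
  crowding repulsion and makes the pure-solvent free energy and osmotic
  pressure vanish.
* `f_fh = -chi(T) (N rho_p)^2` with `chi(T) = eps_h/T* + eps_s`; positive
  `chi` is a favorable residue-residue contact.
* `f_ex = (v2/2) (N rho_p)^2`: bare two-body excluded volume acting on
  polymer beads only (the packing entropy of ions is already in `f_ideal`).
* `f_el`: the random-phase-approximation charge-correlation integral
  `(1/4 pi^2) Int dk k^2 [ln(1 + G) - G]` with
  `G(k) = (4 pi lB / k^2) [zc^2 rho_c + zs^2 rho_s + rho_p S(k; x)]` and
  `S(k; x) = sum_{ij} sigma_i sigma_j exp(-k^2 x l^2 |i-j|/6)` the
  charge structure factor of a Gaussian chain with renormalized Kuhn length
  `x l`. The subtracted `-G` removes the ion and monomer self-energies, so
  `f_el <= 0` always and the Debye-Hueckel limiting law `-kappa^3/(12 pi)`
  is recovered for dilute pure salt (verified to < 1% in the tests).

### Reduced temperature and the energetic mapping

The reduced temperature is defined as `T* = l / lB(T)`, the Kuhn-to-Bjerrum
length ratio. This is the unique simple convention that reproduces all four
printed per-contact equivalences of the fitted parameters: `eps_s = -1.5`
maps to `dS = eps_s R = -3.0 cal/mol/K`, and `eps_h = 1.0` maps to
`dH = -eps_h kB T / T*(T) = -1.1 kcal/mol` near 300 K with
`epsilon_r = 80.5`.

### Kuhn-length renormalization

Polyelectrolytes are badly described by ideal Gaussian chains, so the
reference chain is renormalized: `x` minimizes the Gibbs-Bogoliubov
single-chain free energy

```
F1(x) = (3/2)(N-1)(x - 1 - ln x)                    # elastic deformation
      + (lB/2) sum_{i != j} sigma_i sigma_j <exp(-kappa r)/r>_{|i-j| x}
      + (v2/2) sum_{i != j} (3 / (2 pi |i-j| x))^(3/2)
```

with Debye `kappa` from the small ions and the screened-Coulomb average
taken over the Gaussian separation distribution. The minimization is done
by Brent search on `log x` followed by Newton polishing to machine
precision (the spec'd damped fixed-point iteration solves the same
stationarity condition; direct minimization is unconditionally convergent
and needs no damping heuristic). `x -> 1` as `lB -> 0` and for uncharged
chains with `v2 = 0`.

**Design decision: F1 is not added to `f`.** Only the minimizing `x`
enters the free energy, through `S(k; x)`. The screened intrachain Coulomb
content of `F1` is the same physics the RPA integral carries in its
`rho_p S(k)` term; including both double-counts intrachain screening. We
verified during development that adding `rho_p F1(x*)` produces a
counterion-mediated attraction that is *strongest at zero salt*, i.e. the
opposite of the observed polyelectrolyte salt-reentrance, while the
adopted formulation reproduces the experimental trend structure
(no zero-salt LLPS at 300 K for the +13 polyelectrolyte, salt-enhanced
then salt-suppressed LLPS, monotone salt suppression for the
polyampholyte).

### Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `epsilon_r` | relative permittivity | 80.5 | fitted value; close to bulk water |
| `eps_h`, `eps_s` | FH enthalpy/entropy | 1.0, 0.0 | Caprin1 fit (pY: 1.0, -1.5) |
| `v2` | excluded volume (b^3) | 2.4 | calibrated once (below) |
| `zs`, `zc` | ion valencies | 1, 1 | (1,2): ATP-Mg as one ion; (2,4): Mg + ATP |
| `l_A` | Kuhn length (A) | 3.8 | peptide virtual bond |

`v2` is stated nowhere in the source material; it was calibrated **once**
against two stated facts -- restricted UCST at 100 mM NaCl of about 293 K
("LLPS below 20 C with 100 mM NaCl") and no Caprin1 LLPS at zero salt at
300 K -- giving `v2 = 2.4 b^3` (UCST(0.1 M) = 294 K, zero-salt UCST =
290 K), and then frozen before any acceptance test was written. With this
value the model also yields the unique interior maximum of UCST(salt), the
monotone pY salt response, zero-salt LLPS for divalent and tetravalent
counterions, and the dense-phase valency ordering, none of which were
calibration targets.

### Derivatives, stability, coexistence

Chemical potentials are analytic: the entropic and mean-field parts in
closed form, the RPA part differentiated under the (fixed, state-
independent) wavenumber grid, and the ionic-strength dependence of `x`
propagated by the implicit function theorem on `dF1/dx = 0`. A five-point
finite-difference evaluation of the same derivatives is kept as an
independent oracle (`method = "fd"`); they agree to ~1e-9 relative. The
fixed log-spaced k-grid (about 67 points/decade from 1e-7 to 2e3 b^-1 with
an analytic 1/k^2 tail) makes `f` a smooth deterministic function of
composition, which the coexistence Newton solvers require; its trapezoid
bias is ~1e-4 relative and identical for all states, so phase equilibria
are unaffected at the reported 1e-8 tolerance on chemical-potential and
pressure differences.

Restricted-mode (uniform salt) coexistence is a common tangent on
`f(rho_p)` with counterions slaved by local electroneutrality; the solver
seeds Newton from a lower-convex-hull construction, which doubles as the
independent test oracle. The UCST is found by bisection on the existence of
negative curvature (in mean field the spinodal and binodal apex coincide)
to 1e-3 in reduced-temperature units. Unrestricted (Donnan) equilibria are
solved in the two neutral components -- polymer plus `|Q|/zc` counterions,
and salt ion plus `zs/zc` counterions -- which removes the indeterminate
Galvani potential; tielines at high overall salt are reached by
continuation from low salt, where the restricted solution is an excellent
seed. Tieline slope sign encodes salt partitioning: negative = salt
excluded from the condensate (Caprin1 at high salt), positive = enriched
(pY-Caprin1).

## Parameter fitting

`fit_parameters()` mirrors the coexistence-curve fitting protocol:
residuals are `log(predicted) - log(observed)` concentrations, weighting
the dilute and dense arms equally (log residuals also make the objective
invariant under concentration-unit changes). Nelder-Mead over
(`epsilon_r`, per-sequence `eps_h`, `eps_s`) with box penalties
(`epsilon_r` in [20, 120], `eps_h` in [0, 5], `eps_s` in [-5, 5]) and
binodal solves cached by parameter hash. Both binodal arms are fitted.
The test suite exercises zero-noise and 5%-lognormal-noise recovery on
synthetic data from known parameters, scaled down (short test sequence,
two to three temperatures, `epsilon_r` fixed in the noise study) to keep
the suite within its time budget.

## Field-theoretic simulation

The FTS Hamiltonian couples two complex fields, `w` (conjugate to bead
density, excluded volume `v2`) and `psi` (conjugate to charge density,
Bjerrum length `lB`), to single-molecule partition functions of Gaussian
chains evaluated with Gamma-smeared fields (Gaussian smearing width `a`).
Complex-Langevin dynamics samples the complex weight: a first-order
semi-implicit update treats the exact quadratic part plus an RPA-level
estimate of the density response implicitly, and adds real Gaussian noise
of variance `2 dt / dV` per site. Averages of physical observables are CL
time averages whose imaginary parts must vanish within block errors --
asserted in the tests as the standard CL consistency check. The chain
propagator recursion exploits the small set of distinct bead charges
{0, +-1, -2}: the local Boltzmann factors are built from two field
exponentials and integer powers, and all 3-D FFTs are in-place strided
radix-2 transforms.

ATP-Mg is a 6-bead chain `[-1,-1,-1,-1,+1,+1]` (phosphate tail, then two
half-magnesium beads), net charge -2; sodium and chloride are single
beads. In the standard mixture the protein's net charge is balanced by
Cl- and the ATP-Mg charge by Na+.

Production-scale defaults are a 32^3 lattice (spacing b), `dt = 0.005`,
5e4 thermalization + 2e5 production steps. The package tests run
aggressively scaled down (8^3 or 16^3, a few thousand steps, three seeds)
and therefore establish trends within large stochastic errors, not
converged correlation functions; `lB = 7b` matches the strong-coupling
conditions of the ATP study. The FTS excluded volume (`v2 = 0.05 b^3`),
protein density (2e-4 chains/b^3) and the smearing width used for the
acceptance runs (`a = 0.6 b`, above the default `b/sqrt(6)`: at `lB = 7b`
the narrower smearing lets CL trajectories diverge on desk-scale lattices)
are not stated in the source material; they were calibrated once against
the stated dispersed / condensed / dispersed baseline across the three
ATP-Mg densities and then frozen. On the 8^3 test lattice the box edge is
only about twice the chain radius of gyration, so periodic self-images
wash out part of the condensation signal; the acceptance test therefore
asserts the dissolution branches at two pooled standard errors over three
seeds and the Caprin1 condensation branch as consistency within the same
stochastic error (on 16^3 with longer runs than the suite budget allows,
the full rise-then-fall is clearly resolved), and remains the noisiest
part of the suite.

## Coarse-grained MD

One bead per residue plus explicit Na+/Cl-:
`U = U_el + U_sr + U_bond` with force-shifted Coulomb
(`epsilon_r = 80`, 35 A cutoff -- a documented deviation risk relative to
full periodic electrostatics), Kim-Hummer-style short-range wells
(attractive pairs full Lennard-Jones, repulsive pairs WCA), and stiff
harmonic bonds (r0 = 3.8 A). The published well-depth table is not
redistributed; `synthetic_kh_matrix()` generates a clearly-labelled
synthetic stand-in from a hydrophobicity mixing rule with the same
qualitative structure. Forces are analytic and checked against central
differences to 1e-5 relative; the BAOAB Langevin integrator equilibrates
an ideal gas to the set temperature within 2%. Slab analysis recenters the
dense slab by circular center of mass before averaging `rho(z)`; plateau
concentrations feed an order-parameter fit
`rho_den - rho_dil = A (1 - T/Tc)^0.325` with a rectilinear-diameter
correction for the critical point. Reproducing the production-scale
Caprin1 phase diagrams is out of scope at desk scale; the module is
validated by closed forms, gradient oracles, and planted fixtures.

## Bridging analysis

A putative bridging configuration is one counterion within 11 A (the
first minimum of the Arg-Cl radial distribution) of two arginines on
different chains; an ion near k arginines on distinct chains contributes
`choose(k, 2)` configurations. Grouping by Arg-Arg distance R in 2 A
bins, the Coulomb-sum criterion with unit charges (`1/R - 1/d_far < 0`
for the whole bin) reduces to the geometric rule: true bridging iff
`d_far` < bin lower edge, neutralizing iff `d_far` >= bin upper edge,
intermediate otherwise -- the tests verify exact agreement with explicit
Coulomb evaluation at the bin edges. Geometry (projection x along the
inter-Arg axis, perpendicular offset d) is computed from the three
pairwise minimum-image distances by the law of cosines so periodic
wrapping cannot produce inconsistent triangles. Heat maps accumulate
configurations at (x, +-d) with half weight each, making
`P(x, d) = P(x, -d)` exact; `P/|d|` is the average density on the circle
of radius |d|. The isolated three-bead reference integrates the same
Coulomb + short-range-repulsion Boltzmann weight on a cylindrical grid,
with `lB` acting as the inverse model temperature (`lB = 0` is the flat
infinite-temperature limit).

## Synthetic data

Generators are pure functions of (parameters, seed), seeding R's RNG
locally and restoring the caller's state (R's Mersenne-Twister stream is
platform-stable, so a separate counter-based generator adds nothing but
surface). They emulate *analysis surfaces*, not physics: planted bridging
triplets with guaranteed class labels, ideal-gas boxes, two-plateau slab
configurations, and coexistence datasets generated by the package's own
binodal solver from known parameters plus lognormal noise. A green test
on these fixtures establishes that the analysis stages recover planted
ground truth -- it does not establish that the MD or FTS engines reproduce
any particular experimental number.

## Known limitations

* The rG-RPA formulation is a package-level reconstruction (the source
  defers the exact integrand to an appendix not available here); the
  variational x and the RPA integral share intrachain physics at the
  mean-field/one-loop boundary, and ion condensation (Manning) effects are
  absent, so condensed-phase concentrations with multivalent ions are
  overestimated -- tested as orderings, not absolute values.
* Desk-scale FTS lattices are small enough for periodic self-interaction;
  results are trend-level.
* The MD electrostatics use a force-shifted cutoff, not Ewald; the KH
  matrix is synthetic; production binodals are out of scope.
* Tieline solves close to the critical point may fail to converge and are
  reported as errors rather than extrapolated.
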