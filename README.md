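# ionphase

Sequence-specific electrostatics of liquid–liquid phase separation (LLPS)
for charged intrinsically disordered protein regions (IDRs), with salt,
counterion-valency, and ATP–magnesium effects. The package is built around
the Caprin1 C-terminal IDR and its phosphorylated variant as reference
systems: Caprin1 is a polyelectrolyte (net charge +13 over 103 residues,
NCPR = 0.126, FCR = 0.184) whose LLPS requires ions and is *reentrant* in
salt; phosphorylating its 7 tyrosines (≈ −2 each) yields a near-neutral
polyampholyte (Q = −1) that condenses on its own and is monotonically
dissolved by salt.

For quantitative modellers of biomolecular condensates, it provides three
complementary engines over one charge bookkeeping layer:

* **rG-RPA+FH analytical theory** — free energy
  `f = f_ideal + f_fh + f_ex + f_el` (kBT/b³, b = 3.8 Å) with
  χ(T) = ε_h/T\* + ε_s, T\* = l/l_B(T), a variationally renormalized Kuhn
  length `x·l` for polyelectrolyte conformations, and an RPA
  charge-correlation integral with self-energy subtracted (Debye–Hückel
  `−κ³/12π` limit for dilute salt). Analytic chemical potentials,
  stability, fixed-salt binodals, UCSTs, and two-dimensional salt–polymer
  phase diagrams with Donnan-consistent tielines.
* **Field-theoretic simulation (FTS)** — complex-Langevin dynamics of two
  complex lattice fields with Gaussian-chain propagators, a 6-bead
  ATP–Mg model `[−1,−1,−1,−1,+1,+1]`, density–density correlation
  functions with block errors, and residue-resolved ion-contact profiles
  (compiled radix-2 FFT kernel).
* **Coarse-grained explicit-ion MD** — one bead per residue plus Na⁺/Cl⁻,
  `U = U_el + U_sr + U_bond`, analytic forces, BAOAB Langevin dynamics,
  slab density profiles, and binodal/critical-point extraction from
  plateaus. Includes a counterion-bridging analyzer (putative /
  true-bridging / neutralizing Arg⁺–Cl⁻–Arg⁺ configurations, P(x, d)
  heat maps, isolated three-bead Boltzmann reference).

Synthetic-data generators (planted bridges, ideal gases, two-plateau
slabs, model-generated coexistence tables) make every analysis stage
testable without downloads. See `vignette("ionphase-methods")` for models,
conventions, calibration decisions, and limitations — including that the
shipped Caprin1 sequence fixture is a **synthetic stand-in** matching the
published composition (15 R, 1 K, 3 D, 7 Y) and charge patterning, and
that the MD well-depth matrix is synthetic.

## Worked example

```r
library(ionphase)

wt <- charge_sequence(builtin_sequence("caprin1_wt"))
sequence_metrics(wt)
#> $Q
#> [1] 13
#> $NCPR
#> [1] 0.1262136
#> $FCR
#> [1] 0.184466

# counterions needed for a salt-free box of 100 chains
neutralize(wt$Q, 100, zc = 1, count = TRUE)
#> [1] 1300

# per-contact energetics implied by the fitted FH parameters
contact_energetics(eps_h = 1.0, eps_s = -1.5, T_ref = 300)
#> $dH_kcal_mol
#> [1] -1.08553
#> $dS_cal_mol_K
#> [1] -2.980806

# restricted binodal at 100 mM salt (concentrations in chains / b^3)
p <- energy_params(v2 = 2.4)                  # Caprin1 parameter set
binodal_fixed_salt(wt, p, salt = 0.1, T_grid = c(280, 290), salt_unit = "M")
#>   T_K      rho_dil     rho_den   rho_c_dil  rho_c_den       rho_s
#> 1 280 6.001138e-07 0.003584755 0.003312271 0.04990628 0.003304469
#> 2 290 2.168225e-04 0.002393308 0.006123161 0.03441748 0.003304469
ucst(wt, p, salt = 0.1, salt_unit = "M")
#> [1] 294.2432
```

The binodal rows are the coexisting dilute/dense polymer concentrations at
uniform salt (with slaved counterion concentrations); the UCST is the
temperature where the two-phase region closes — here ≈ 294 K at 100 mM,
i.e. LLPS just below room temperature, rising with salt up to ~1 M and
falling again at high salt (the reentrance signature; see the acceptance
tests).

Command-line interface (same operations as the API):

```sh
Rscript -e 'ionphase::ionphase_cli()' seq --raw caprin1_wt
Rscript -e 'ionphase::ionphase_cli()' binodal --salt 0.1 --T-grid 280,290
```

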