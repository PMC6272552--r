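# auxqmmm

A desk-scale QM/MM engine in R for simulating a small quantum-mechanical
region — described by auxiliary density functional theory (ADFT) — embedded
in a classical molecular-mechanics environment. It is aimed at method
developers and students who want a compact, fully testable implementation
of the machinery found in large QM/MM codes: Gaussian integral evaluation,
electrostatic embedding with near/far-field screening, density-fitted SCF,
force-field coupling, flexible solvent boundaries, and free-energy
sampling.

## The model

**ADFT SCF.** The electronic energy of the QM region is

E_SCF = Σ_ab P_ab H_ab + Σ_ab Σ_c̄ P_ab ⟨ab‖c̄⟩ x_c̄ − ½ Σ_c̄d̄ x_c̄ x_d̄ ⟨c̄‖d̄⟩ + E_xc[ρ̃]

where P is the density matrix over contracted Cartesian Gaussians, c̄, d̄
are primitive Hermite Gaussian auxiliary functions, x solves the
variational Coulomb fit G x = J (so the fitted Coulomb energy approaches
the exact one from below), and the exchange-correlation term (Dirac
exchange + VWN correlation) is evaluated on the fitted density
ρ̃ = Σ x_c̄ c̄(r). The Kohn–Sham matrix is the exact derivative of this
energy with respect to P, which the test suite verifies by finite
differences.

**Electrostatic embedding and far fields.** MM point charges enter the
core Hamiltonian as one-electron operators. Each charge is classified
near- or far-field against numerically solved orbital extent radii at an
accuracy threshold τ (default 1e-10 a.u.): near charges get exact
nuclear-attraction integrals via Hermite/Boys recursion; far charges use
the multipolar asymptotic expansion

⟨ab|1/|r−D|⟩ ≈ Σ_m [(−1)^m / (m_x! m_y! m_z!)] T_AD(m) ⟨a+m|b⟩

truncated at order 8, where T_AD(m) are derivative tensors of 1/R and
⟨a+m|b⟩ are overlaps with raised angular momentum. The far-field charge
sums Σ_D Q_D T_AD(m) are accumulated once per QM atom outside the orbital
loops. A double asymptotic expansion handles far-field three-center
repulsion integrals, and the **mixed SCF scheme** stores near-field ERIs
in memory while recomputing far-field ERIs from the expansion every
cycle; conventional, direct and mixed schemes agree to well below
1e-8 hartree.

**QM/MM coupling.** Additive coupling: E = E_QM (embedded SCF +
charge-augmented nuclear repulsion) + E_QMMM (12-6 Lennard-Jones in
ε/R_min form) + E_MM (bonds, angles, Urey-Bradley, dihedrals, LJ,
Coulomb). Subtractive (ONIOM-style) coupling:
E = E_MM(system) − E_MM(model) + E_QM(model), with the extracted charge
field entering both model calculations identically. Boundary bonds are
capped by hydrogen link atoms at R_LA = R_QBA + α (R_MBA − R_QBA), with
link forces projected back by the chain rule. The FIRES restraint keeps a
fixed set of solvent molecules nearest to a solute by harmonic penalties
on intruders, with the reaction force on the boundary molecule so the
restraint force sums to zero. Drude oscillators provide polarizable MM
sites (α = q′²/k_d).

**Sampling.** Velocity-Verlet Born–Oppenheimer MD with an optional
Langevin (BAOAB) thermostat; dual-topology free energy perturbation
H(λ) = λH_A + (1−λ)H_B with exponential averaging and 3-block standard
errors; Hamiltonian replica exchange with Metropolis swaps on the
alternating odd/even neighbor schedule.

## Worked example

One water molecule of a 21-water droplet treated quantum mechanically
(minimal basis, mixed SCF scheme), the remaining 20 waters as SPC point
charges with Lennard-Jones coupling:

```r
library(auxqmmm)
droplet <- make_fixture("water_droplet", list(n = 21), seed = 1)
part    <- partition_by_selection(droplet, 1:3)   # first water is QM
ff      <- load_ff_params("water-spc")
res <- additive_qmmm(droplet, part, ff, basis = "sto3g",
                     settings = scf_settings(scheme = "mixed"))
print(res)
#> <additive_energy> E_QM -74.74107104 + E_QMMM -0.00060430 + E_MM -0.01154914 = -74.75322449
print(res$scf)
#> <scf_result> E = -74.7410710436 hartree (converged after 8 cycles)
#>   core -122.71488578  J(fit) 47.40246088  xc -8.88241301  NN(embedded) 9.45376686
```

`E_QM` is the embedded electronic energy plus the charge-augmented
nuclear repulsion; `E_QMMM` the QM–MM dispersion/repulsion; `E_MM` the
internal energy of the classical waters. For this compact droplet every
embedding site is inside the orbital extents and is treated exactly; with
environments extending tens of bohr (e.g. 2000 random charges out to
30 Å) most sites fall in the far field and are handled by the order-8
expansion at no loss of accuracy (max deviation ~1e-13 hartree per matrix
element against the all-exact reference).

A thin command-line front end is shipped in `inst/cli/auxqmmm.R`:

```sh
Rscript inst/cli/auxqmmm.R scf --xyz water.xyz --basis sto3g --scheme mixed
Rscript inst/cli/auxqmmm.R fep --kA 1 --kB 4 --windows 11
```

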