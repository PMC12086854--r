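# vcdpt

Vibrational circular dichroism (VCD) and infrared (IR) spectra for small
closed-shell molecules from an atomic-orbital-based linear-response
formalism, implemented as an R package with an Rcpp integral core.

VCD measures the differential absorption of left- and right-circularly
polarized IR light by a chiral molecule's vibrational transitions; it is
the standard optical route to absolute configuration.  Within the double
harmonic approximation the observables per normal mode `i` are the
rotational and dipole strengths

    R_i = sum_a [sum_{lb} P^l_{ab} S_i^{lb}] [sum_{lb} M^l_{ab} S_i^{lb}]
    D_i = (1 / 2 w_i) sum_a [sum_{lb} P^l_{ab} S_i^{lb}]^2

built from the atomic polar tensors `P` (electric-dipole derivatives with
respect to nuclear displacement or velocity), atomic axial tensors `M`
(magnetic-dipole derivatives with respect to nuclear velocity) and the
mass-weighted normal-mode transformation `S`.  The tensors come from
first-order response theory over an all-electron restricted Hartree-Fock
mean field in three flavors:

* **NDPT** — nuclear displacement perturbations (real, symmetric; fully
  coupled): length-form polar tensors, IR spectra.
* **NVPT** — nuclear velocity perturbations with velocity-gauge atomic
  orbitals (imaginary, antisymmetric factors; exchange-only coupling at
  Hartree-Fock): velocity-form polar tensors and axial tensors.
* **MFPT** — magnetic-field perturbations with gauge-including atomic
  orbitals (three channels total): axial tensors paired with NDPT polar
  tensors.

Every channel can be solved by two independent engines — a density-matrix
solver working entirely in the AO basis (exponential parametrization,
occupied-virtual projection, preconditioned conjugate gradients in the
Löwdin basis) and a molecular-orbital Sternheimer solver — and their
agreement to 1e-8 on densities, tensors and rotational strengths is the
package's central validation.

## Worked example

```r
library(vcdpt)

mol   <- fixture_molecule("h2o2_P")          # chiral H2O2, dihedral 112 deg
bset  <- builtin_basis("sto-3g")
basis <- build_ao_basis(mol, bset)
scf   <- run_scf(mol, basis)
scf
#> scf_state: E_total = -148.7645286081 Eh (15 iterations, 9 occupied)

ndpt <- solve_channel_set(scf, build_ndpt_channels(scf), "ao")
nvpt <- solve_channel_set(scf, build_nvpt_channels(scf, ndpt), "ao")
vib  <- numeric_hessian(mol, bset)
tab  <- strengths(apt_velocity(scf, nvpt), aat_nvpt(scf, nvpt), vib)
tab[, c("mode", "wavenumber_cm1", "D_1e40esu2cm2", "R_1e44esu2cm2")]
#>   mode wavenumber_cm1 D_1e40esu2cm2 R_1e44esu2cm2
#> 1    7         220.87        247.12         16.21
#> 2    8        1463.37          0.00          0.00
#> 3    9        1629.91        139.95         42.77
#> 4   10        1735.74         17.04        -41.28
#> 5   11        4166.62          4.21        -10.88
#> 6   12        4170.95         12.28         11.01

vcd <- broaden(tab, "R_au", w = 12)          # Lorentzian, FWHM 12 cm-1
ir  <- broaden(tab, "D_au", w = 12)
```

The table lists the six vibrational modes of the chiral structure with
their harmonic wavenumbers, IR dipole strengths (10^-40 esu^2 cm^2) and
signed VCD rotational strengths (10^-44 esu^2 cm^2); the mirror-image
fixture `"h2o2_M"` reproduces the same `D_i` with all `R_i` signs
flipped.  (The numbers above are what the code prints for the frozen
fixture geometry; regenerate them with the snippet.)

A thin command-line driver wraps the same functions:

```sh
Rscript inst/cli/vcdpt.R fixtures --name h2o2_P --out work
Rscript inst/cli/vcdpt.R compute --xyz work/h2o2_P.xyz --unit bohr \
    --basis sto-3g --theory nvpt --solver both --out work/results
Rscript inst/cli/vcdpt.R oracles --out work/oracles.json
```

`compute --solver both` runs every response channel through both solvers
and writes a comparison report with the maximum absolute deviations of
densities, tensors and rotational strengths.

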