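---
title: "Sample-based quantum diagonalization with an IEF-PCM reaction field: models, algorithms and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SQD IEF-PCM methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Solvation shifts the electronic energies of molecules by several kcal/mol —
comparable to reaction barriers and binding energies — so any ground-state
method intended for solution chemistry needs a solvent model.  This package
implements a quantum-centric selected-CI workflow for small closed-shell
solutes in a dielectric continuum: electron configurations are drawn from a
(simulated) local unitary cluster Jastrow state, noise-broken symmetries are
repaired by self-consistent configuration recovery, and the molecular
Hamiltonian is diagonalized in the sampled determinant subspace under an
IEF-PCM reaction field.  A full-sector CASCI IEF-PCM mode provides the
classical reference every sampled run is judged against.

Everything is self-contained: the package carries its own Gaussian-integral
engine (McMurchie–Davidson), restricted Hartree–Fock, spin-orbital CCSD,
AVAS orbital selection, a boundary-element IEF-PCM solver, and a
string-based determinant CI with Davidson diagonalization.

## Electronic-structure model

For a solute with vacuum Hamiltonian $\hat H_0$ embedded in a polarizable
continuum, the Schrödinger equation becomes
$[\hat H_0 + \hat V_\mathrm{int}]\Psi = E\Psi$, where
$\hat V_\mathrm{int}$ is the solute–solvent interaction.  Because the
solvent degrees of freedom are thermally averaged, the eigenvalue plays the
role of a free energy.  The part of $\hat V_\mathrm{int}$ induced by the
solute's own charge density must be counted with a factor $\tfrac12$ in the
free energy (half of the induction work is spent polarizing the dielectric),

$$
G(\Psi) \;=\; \big\langle \Psi \big|\, \hat H_0 \,\big\rangle
  + \tfrac12\, \mathbf q(\Psi)\cdot \boldsymbol\varphi(\Psi),
$$

with $\mathbf q$ the apparent surface charges and $\boldsymbol\varphi$ the
solute electrostatic potential on the cavity surface.  The charge density
both polarizes and is polarized by the continuum, so $G$ is made stationary
by a self-consistent reaction field (SCRF) iteration.

### IEF-PCM boundary elements

The cavity surface $\Gamma$ is a union of atom-centered spheres.  On the
discretized surface the single- and double-layer operators are

$$
(\hat S\sigma)(s) = \int_\Gamma \frac{\sigma(s')}{\|s'-s\|}\,ds', \qquad
(\hat D\sigma)(s) = \int_\Gamma \sigma(s')\,
  \frac{\partial}{\partial n_{s'}}\frac{1}{\|s'-s\|}\,ds',
$$

and the apparent surface charge solves the integral-equation-formalism
system

$$
\big[(2\pi f_\varepsilon)\hat I-\hat D\big]\,\hat S\,\sigma(s)
 \;=\; \big(-2\pi \hat I+\hat D\big)\,\varphi^\rho(s),
\qquad f_\varepsilon = \frac{\varepsilon+1}{\varepsilon-1}.
$$

Discretization choices (each configurable through `pcm_config()`):

* **Spheres.** Van der Waals radii scaled by 1.2.  The default radii table
  is the *modified Bondi* set — Bondi radii with the Rowland–Taylor
  hydrogen radius of 1.10 Å — which is what mainstream IEF-PCM
  implementations use; the plain Bondi table (H = 1.20 Å) is selectable.
  The hydrogen radius is the single most influential parameter for the
  solvation free energy of the small polar solutes treated here (about
  0.5 kcal/mol between the two tables for methanol).
* **Quadrature.** Each sphere carries a deterministic golden-spiral
  (Fibonacci) point set, 302 points per sphere by default.  Points buried
  inside another sphere are removed; points within 10% (relative) of a
  sphere seam get smoothly switched area weights, so energies are smooth
  under geometry changes.  The spiral grid is not symmetric under molecular
  point-group operations, so symmetry holds only to quadrature resolution
  (about $10^{-5}$ Hartree in operator matrix elements at 302 points); the
  Born-ion error decreases monotonically through 110/302/590 points and is
  below 0.5% of the analytic $-\frac12(1-1/\varepsilon)q^2/a$ at 590.
* **Diagonal regularization.** The singular diagonal of $\hat S$ uses the
  classic $S_{kk}=1.0694\sqrt{4\pi/a_k}$ rule; the diagonal of $\hat D$ is
  fixed row-wise by the Gauss solid-angle sum rule
  $\sum_j D_{kj}a_j=-2\pi$.
* **Linear algebra.** The IEF system is solved by direct factorization and
  cached as a response matrix, so each SCRF iteration costs one
  matrix–vector product.

Nuclear charges contribute to $\varphi^\rho$ alongside the electronic
density; the nuclei–charge interaction is carried as a scalar.
Nonelectrostatic terms (cavitation, dispersion, repulsion) are outside the
model.

### Solvation free energies

Reference tabulations differ in what they call $G_\mathrm{solv}$.  The
package computes, and `gsolv()` returns, both

* the thermodynamic difference $G(\text{solution}) - E(\text{gas})$ with
  both energies from the same method, subspace and geometry (the default
  return value), and
* the solvent interaction component $\tfrac12\,\mathbf q\cdot
  \boldsymbol\varphi$ at SCRF convergence (`gsolv_polarization`), the
  quantity a solvent module reports internally.

For the bundled benchmark solutes the interaction component is the
convention that matches the published CASCI IEF-PCM tabulation, and it is
what `scripts/acceptance.R` reports.

## The sampled subspace method

A run proceeds through five stages (`run_sqd_pcm()`):

1. **Chemistry.** Solvated RHF/cc-pVDZ, AVAS active-space selection (see
   below), active-space integrals $(h_1, h_2, E_\mathrm{core})$.
2. **State preparation.** Gas-phase closed-shell CCSD amplitudes *in the
   same active orbitals* parametrize the truncated LUCJ ansatz
   $|\Phi\rangle = e^{-\hat K_2}e^{\hat K_1}e^{i\hat J_1}e^{-\hat K_1}
   |x_\mathrm{RHF}\rangle$.  The opposite-spin doubles tensor, reshaped as
   the symmetric matrix $M_{(ia),(jb)} = t_{ij}^{ab}$, is eigendecomposed;
   the leading eigenpair defines one squared-one-body factor
   $i\lambda\hat X^2$ whose eigenbasis gives $\hat K_1$ and whose
   eigenvalues give the density–density coupling $\hat J_1$ (one Jastrow
   layer; the orbital connectivity of $\hat J_1$ is unrestricted since no
   hardware topology is involved).  The singles amplitudes enter the final
   rotation $\hat K_2$ by the Thouless construction.  Keeping a single
   layer is an approximation: it reproduces two-electron systems
   essentially exactly and degrades gracefully with correlation strength.
3. **Sampling and noise.** The state is simulated exactly in the fixed
   $(n_\alpha, n_\beta)$ determinant sector — orbital rotations become
   sequences of adjacent-pair Givens rotations acting on the amplitude
   matrix, the Jastrow factor is a diagonal phase — and bitstrings are
   drawn multinomially.  Hardware noise is emulated by independent bit
   flips with probability `p_flip` per bit, which breaks particle number
   and spin-z exactly as often as the binomial model predicts.  Real-device
   noise is correlated and gate-dependent; this emulator reproduces only
   the symmetry-breaking phenomenology that the recovery stage consumes,
   so passing tests say nothing about any specific device.
4. **S-CORE recovery.** Broken shots are repaired toward the target
   particle numbers: while a spin sector is off target, one eligible bit
   (occupied bits when in surplus, virtual when in deficit) is flipped,
   chosen with probability proportional to its distance $|x_p - n_p|$ from
   the current average occupancy.  Each flip moves the count monotonically,
   so the procedure terminates; correct shots pass through untouched.  The
   flip law is isolated behind this one function because only its
   ingredients, not its functional form, are standardized; the results are
   sensitive to the sampling budget, not to this law.  Batches are drawn
   frequency-weighted without replacement within a batch, independently
   across batches, and closed under spin inversion: the half-string union
   $U$ defines the determinant set $S = U\times U$ with $d = |U|^2$, so
   $(b,a)$ accompanies every $(a,b)$.
5. **Solve and iterate.** The Hamiltonian is projected into each batch
   subspace — matrix elements between subspace determinants are the exact
   full-space Slater–Condon values, no renormalization — and each batch is
   its own SCRF problem.  The lowest batch energy is the reported ground
   state; the average diagonal density of the batch wavefunctions
   (computed in the presence of the reaction field) updates the occupancy
   distribution for the next of the 3 (default) S-CORE iterations.

### AVAS

Occupied and virtual orbitals are rotated separately to diagonalize their
projection onto the span of chosen atomic orbitals; eigenvalues above a
0.2 threshold (configurable; the value is this package's default, chosen to
split cleanly for the bundled solutes) mark active orbitals.  Labels such
as `"C 2s"` address shells on every matching atom.  Exclusion labels
(`"!O 1s"`) switch to the complementary construction used for the
all-orbital water space: the occupied orbitals with the largest projection
onto the excluded core functions are frozen (one per excluded function) and
everything else, all virtuals included, is active.  No virtual-space
canonicalization is applied; CASCI energies are invariant to it, and the
CCSD stage handles non-canonical references explicitly.

### Subspace diagonalization

CI vectors live on the $N\times N$ grid of (beta string, alpha string)
pairs over the shared half-string set.  The sigma build splits into
same-spin singles/doubles column operations and an opposite-spin term
assembled as dense (string × orbital-pair) intermediates contracted with
BLAS; subspaces below $d = 4\times10^4$ are built densely and solved
directly.  Davidson iterations use the determinant diagonal as
preconditioner, a unit start vector on the lowest diagonal element (or the
previous SCRF iterate — macro-iterations are warm-started), residual
tolerance $10^{-8}$, and a 20-vector cap with restart.  SCRF macro-
iterations alternate converged Davidson solves with charge re-solves and
stop when $|\Delta G| < 10^{-8}$ Hartree and $\max|\Delta q| < 10^{-6}$;
optional linear damping (0.5) on the charges is available for oscillatory
cases but has not been needed for the bundled systems.  Ties between batch
energies break toward the lower batch index.

## Geometry optimization

`optimize_geometry()` minimizes the RHF (optionally IEF-PCM) energy by BFGS
over Cartesians with central-difference gradients (displacement
$2\times10^{-3}$ Bohr), net translation projected out, convergence at
max-gradient $3\times10^{-4}$ Hartree/Bohr and energy change $10^{-6}$
Hartree — common optimizer defaults.  The packaged solute geometries were
produced by this optimizer at RHF/cc-pVDZ IEF-PCM ($\varepsilon=78.3553$),
so re-running the optimizer on them terminates after one gradient
verification.

## Synthetic data and what the tests show

The toy ladder (`h2` (2e,2o), `h2o-mini` (6e,5o), `h6` (6e,6o)) is sized so
that full sectors are exactly diagonalizable, which turns the central
claims into sharp identities: noiseless samples covering a sector must
reproduce CASCI IEF-PCM to solver tolerance, $\varepsilon = 1$ must
reproduce the gas phase bit-for-bit, and subspace energies must nest
variationally.  The noisy-convergence study (bit-flip probability 0.02,
$5\times10^4$ shots, 3 S-CORE iterations, 10 batches, batch sizes 15–240,
ten seeds) emulates the published convergence phenomenology — median error
versus the reference decreasing with batch size through chemical accuracy —
under this package's noise model, which again is a statement about the
algorithm, not about hardware.  Default production settings mirror the
reference study: $2\times10^5$ shots, 3 S-CORE iterations, $K = 10$
batches, $\varepsilon = 78.3553$.

Problem sizes used by the shipped validation runs: methanol's (14e,12o)
sector ($d = 627{,}264$) and methylamine's (14e,13o) sector
($d = 2{,}944{,}656$) are solved in full as CASCI IEF-PCM references;
ethanol (20e,18o) and water (8e,23o) exceed the configured in-memory
sector cap ($10^7$ determinants) and ship as geometries plus
configurations only.

## Known limitations

* Neutral closed-shell solutes only; charged or open-shell species are
  rejected at construction (the gas-phase ansatz approximation is untested
  for ions).
* Electrostatics-only solvation; no cavitation/dispersion/repulsion, no
  SMx-style corrections.
* The LUCJ layer is single-repetition; strongly correlated systems would
  need more layers than the parametrization provides.
* Basis sets ship for H/C/N/O in cc-pVDZ and STO-3G.
* The noise emulator is a symmetry-breaking stand-in, not a device model.
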