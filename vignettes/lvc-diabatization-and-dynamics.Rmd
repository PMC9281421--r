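---
title: "Fragment-diabatized linear vibronic coupling models: construction and dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-diabatized linear vibronic coupling models: construction and dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvcdyn)
```

## The model

`lvcdyn` works with linear vibronic coupling (LVC) Hamiltonians for a set of
$N$ coupled diabatic electronic states $|d_i\rangle$ over $F$ dimensionless
ground-state normal coordinates $\mathbf q$ with conjugate momenta
$\mathbf p$:

$$
H = K + V,\qquad
K = \tfrac12\,\mathbf p^\top \Omega\, \mathbf p,\qquad
V_{ii}(\mathbf q) = E^D_{ii}(0) + \tfrac12 \mathbf q^\top \Omega\, \mathbf q
  + \boldsymbol\lambda_{ii}\cdot\mathbf q,\qquad
V_{ij}(\mathbf q) = E^D_{ij}(0) + \boldsymbol\lambda_{ij}\cdot\mathbf q .
$$

Every diabatic surface is a paraboloid with the *ground-state* curvature
$\Omega$ (the diagonal matrix of frequencies $\omega_\alpha$), displaced by
the gradients $\boldsymbol\lambda_{ii}$; interstate couplings are constant
plus linear. The constant couplings $E^D_{ij}(0)$ vanish only when the
diabatic states coincide with the adiabatic states at the reference geometry;
for fragment-based diabatic states they are an essential part of the model.
Closed forms follow for the minima,
$q^{min}_{ii,\alpha} = -\lambda_{ii,\alpha}/\omega_\alpha$, and the
reorganization energies
$\tfrac12\sum_\alpha \lambda_{ii,\alpha}^2/\omega_\alpha$
(`diabatic_minimum()`, `reorganization_energy()`).

Units are fixed package-wide: energies and vibrational quanta in eV,
dimensionless coordinates, time in fs with $\hbar$ = `hbar_ev_fs` =
0.6582119569 eV·fs. Published tables for systems of this kind print energies
in eV, so the couplings are kept in eV as well.

The intended application is a hydrogen-bonded multichromophoric system such
as the adenine–thymine Watson–Crick pair: local $\pi\pi^*$ and $n\pi^*$
excitations on each base plus an inter-base charge-transfer (CT) state, in
C$_s$ symmetry where A′ ($\pi\pi^*$, CT) and A″ ($n\pi^*$) blocks decouple
along totally symmetric modes. When state and mode irreps are supplied, the
constructor audits the selection rule (a coupling may be nonzero only when
irrep$(i)\otimes$irrep$(j)\otimes$irrep$(\alpha)$ is totally symmetric); the
audit is a validation layer, not a requirement, so models of systems without
symmetry load unchanged.

## Overlap-based diabatization

Given reference states $|R_i\rangle$ (what the diabatic states *should* look
like) and $M \ge N$ adiabatic states $|a_m\rangle$ of the full system at some
geometry, the overlap matrix $S_{im} = \langle R_i | a_m\rangle$ is
symmetrically (Löwdin) orthonormalized,

$$ D = (S S^\top)^{-1/2} S, $$

the unique row-orthonormal matrix closest to $S$ in Frobenius norm — the
combination of adiabatic states that resembles the references as much as
possible. The diabatic Hamiltonian at that geometry is
$H^D = D\,\mathrm{diag}(E^A)\,D^\top$. Three reference conventions are
supported through the data, not through code branches:

* **St** (standard): references are the adiabatic states at the reference
  geometry itself. At that point $S$ is the identity block on the lowest $N$
  states, so $E^D_{ij}(0) = 0$ exactly; `build_lvc_model(strategy = "St")`
  enforces the identity block at the reference point and uses the records'
  overlaps at displaced geometries.
* **FrD** (fragment diabatization): references are excited states of the
  isolated fragments (or inter-fragment orbital transitions for CT states).
* **FrD(MM_ref)**: fragment references computed with the electrostatic field
  of the surrounding fragments included as point charges. The records carry
  the convention as a provenance tag; the diabatization itself is agnostic.

Numerical choices: the inverse square root goes through the
eigen-decomposition of $SS^\top$ with a floor of $10^{-10}$ on its
eigenvalues; below the floor the transform *errors*, naming the reference
state that is not spanned, rather than regularizing silently. Degenerate
adiabatic states need no special handling — $H^D$ is invariant under
orthogonal mixing within a degenerate subspace and under adiabatic sign
flips — but a rank check still guards $SS^\top$.

Two diagnostics accompany every diabatization: the weights
$W_m = \max_i S_{im}^2$ (how cleanly adiabatic state $m$ maps onto one
reference character) and the completenesses $\sum_m S_{im}^2$ (how much of
reference $i$ the adiabatic set captures; below 1 when the set is
truncated).

## Extracting the couplings

`displacement_grid()` builds the $2F+1$ geometries $\{0, \pm\Delta_\alpha
e_\alpha\}$ and `build_lvc_model()` runs the diabatization at each of them,
aligns diabatic-state signs against the reference-point result (always
against the reference point, never the neighbouring geometry, so sign drift
cannot accumulate), and takes central differences

$$
\lambda_{ij,\alpha} =
\frac{H^D_{ij}(+\Delta_\alpha) - H^D_{ij}(-\Delta_\alpha)}{2\Delta_\alpha}.
$$

On an exactly linear-plus-harmonic surface the central difference is exact:
the even harmonic contribution cancels. The default step is
$\Delta_\alpha = 0.1$ (dimensionless), configurable globally or per mode; it
is a compromise between truncation bias (which grows as $\Delta^2$ for cubic
contamination) and the noise floor of the electronic-structure energies
driving a real backend. A per-mode validity diagnostic reports the central
*second* difference, which must equal $\omega_\alpha$ on the diagonal and
vanish off it; deviations flag anharmonicity. Note an intrinsic blind spot:
odd (e.g. cubic) anharmonicity cancels in the second difference and shows up
instead as a $\Delta^2$ bias of the extracted couplings — the test suite
checks exactly this Richardson behaviour.

Sign alignment deserves a design note. Reference-state wavefunctions from
separate electronic-structure runs carry arbitrary global phases; a flipped
reference flips one row of $S$ and hence one row/column of off-diagonal
signs in $H^D$, which would wreck the differences. The obvious fix —
flipping rows of $D$ to match the reference-point $D$ (`phase_align()`) —
is *unsound across geometries*: row coordinates of $D$ live in each
geometry's own adiabatic basis, and near-degenerate adiabatic pairs rotate
strongly under small displacements, producing spurious flips. The pipeline
therefore aligns on the basis-invariant object itself: it chooses row signs
of $H^D(\pm\Delta)$ to maximize agreement of the off-diagonal pattern with
$H^D(0)$ (`align_hamiltonian_signs()`). States connected to the rest only
through symmetry-forbidden (zero) constant couplings carry no sign evidence
and are left alone — their phases can only be pinned by cross-geometry
wavefunction overlaps, which the record schema deliberately does not
require. `phase_align()` remains available for transformations that share a
geometry or basis.

## The synthetic electronic-structure backend

TD-DFT is outside this package's scope. To make the whole pipeline testable,
`make_truth_model()` draws a seeded ground-truth LVC model with the structure
of the target systems — with defaults: 12 states whose labels, characters,
irreps, vertical energies and oscillator strengths follow published
CAM-B3LYP values for the adenine–thymine pair; 10 modes with frequencies in
0.01–0.4 eV; reorganization energies drawn per character ($\pi\pi^*$
0.25–0.40, $n\pi^*$ 0.40–0.60, CT 1.1–1.3 eV, so the CT state always
relaxes the most); couplings only where symmetry allows. Ten modes keeps
every test exact-diagonalization-friendly while preserving the full coupling
topology; the published systems use all 102 dimer modes, which changes scale,
not structure.

`generate_record()` then emulates one excited-state calculation:
diagonalize the truth potential at $\mathbf q$, report the lowest $M$
eigenvalues and the overlaps of the reference set with those eigenvectors.
Imperfections are explicit, seeded knobs:

* truncation of the adiabatic set ($M < N$) — completenesses drop below 1;
* a seeded orthogonal rotation of the references within same-irrep blocks
  by a controlled angle $\theta$ — the simplest stand-in for references that
  are not eigenstates of the full system (fragment states); weights drop
  like $\cos^2\theta$, verified against the two-state closed form;
* per-state embedding shifts applied to the *reference definition* only
  (re-diagonalizing the shifted constant matrix), emulating the MM-embedded
  fragment convention without touching the truth surfaces.

With perfect references and $M = N$ the backend and the parametrization
pipeline are exact inverses — constants recover to $10^{-10}$ eV and
couplings to $10^{-8}$ eV in the tests — and the recovery error grows
monotonically with $\theta$. What the backend does *not* emulate: root
flipping, SCF failures, basis-set effects, or any anharmonicity of the true
surfaces; a passing round trip therefore validates the algebra and the
pipeline, not the physics of a particular electronic-structure method.

## Wavepacket dynamics

Observables of interest are diabatic populations, the expectation values of
the diabatic potential surfaces, and autocorrelation functions after placing
the ground-state vibrational vacuum on one bright diabatic state (vertical
excitation in the sudden approximation). Multilayer tensor-tree methods used
for the full 102-mode problem are deliberately not reimplemented; instead the
package is *numerically exact on reduced models*: the wavepacket lives on a
truncated harmonic-oscillator product basis (levels $0..n_{max,\alpha}$ per
mode), where every LVC matrix element is analytic —
$q = (a + a^\dagger)/\sqrt2$ is tridiagonal, the vibrational energy is
diagonal — so truncation is the only approximation, and doubling $n_{max}$
is the convergence check (the contract tested: converged populations move by
less than $10^{-6}$). `reduce_modes()` keeps the $k$ modes with the largest
total squared coupling $\sum_{ij}\lambda_{ij,\alpha}^2$, mirroring how
propagation effort is normally allocated to strongly coupled modes.

Three propagators compute $\psi(t) = e^{-iHt/\hbar}\psi(0)$:

* `expm` — one dense diagonalization of the (real symmetric) Hamiltonian;
  exact on the basis, the default below 4000 basis states;
* `lanczos` — short-iterative Krylov steps (subspace 40, full
  reorthogonalization) with adaptive substepping to a $10^{-12}$ local
  tolerance;
* `chebyshev` — polynomial expansion per output step with spectral bounds
  from a preliminary Lanczos sweep, truncated at $|J_k| < 10^{-15}$.

All three agree with an independently assembled dense-matrix oracle to
better than $10^{-8}$ in the tests, with norm and energy conserved at the
same level over 250 fs, the default window (output sampling 0.25 fs).

The expectation of a diabatic potential surface is ambiguous when a state is
fractionally populated: the package defaults to the *conditional* value
$\langle\psi_i|V_{ii}|\psi_i\rangle / \langle\psi_i|\psi_i\rangle$ (the
surface energy seen by the part of the wavepacket on state $i$), with the
unconditional matrix element available via
`pes_convention = "unconditional"`; the choice is recorded in the result
metadata, and values are masked (`NA`) when the population is below
$10^{-8}$ instead of dividing by ~0.

## Absorption spectra

Each bright state $b$ contributes

$$
I_b(E) \propto f_b \,\mathrm{Re}\!\int_0^T
C_b(t)\, e^{-\sigma^2 t^2/2\hbar^2}\, e^{i(E + E_{ZPE})t/\hbar}\, dt ,
$$

with $C_b(t)$ the autocorrelation of the propagation started on $b$, $f_b$
its oscillator strength, and $E_{ZPE} = \tfrac12\sum_\alpha\omega_\alpha$
referencing the energy axis to the ground vibrational level. The Gaussian
damping is parametrized directly by the energy-domain half width at half
maximum (default 0.04 eV, $\sigma = \mathrm{hwhm}/\sqrt{2\ln 2}$), so a
stick line becomes a Gaussian of exactly that HWHM — verified to $10^{-6}$
— and a displaced oscillator yields the Huang–Rhys Poisson progression
$e^{-S}S^n/n!$ with $S = \lambda^2/2\omega^2$. The total spectrum is the
pointwise sum of the contributions, normalized to unit maximum (tiny
negative transform ringing is clamped at zero before the final rescale). An
optional photon-energy prefactor (transition-dipole vs oscillator-strength
weighting conventions differ across codes) is off by default and recorded in
the metadata, as is any rigid shift applied for comparison with experiment.
A time grid shorter than four damping times $\hbar/\sigma$ cannot resolve
the requested broadening and is rejected with the required `t_final`.

## Worked example data and its limits

`inst/extdata/frd_12state_fc_diagonal_only.json` transcribes the published
*diagonal* fragment-diabatic energies of the 12-state adenine–thymine model
at the reference geometry. The off-diagonal constant couplings of that
Hamiltonian appear only in supplementary material that is not publicly
printed alongside the main tables, so they are zero in the file (the
filename and the data README say so). Diagonalizing the diagonal-only model
reproduces the published adiabatic column only within ~0.08 eV — the
residual *is* the effect of the missing couplings, and the corresponding
test documents that gap rather than hiding it.

## Problem sizes and limitations

The test-suite and acceptance problem sizes — 12 states × 10 modes for
parametrization round trips, 2 states × 2 modes × $n_{max}=12$ over 250 fs
for propagator oracles, 200 random overlap matrices up to 12 × 40 — were
chosen so each check runs in seconds on one core while exercising the full
coupling topology. Known limitations: no quadratic or anharmonic vibronic
terms, no spin–orbit coupling, no finite-temperature initial conditions, no
monomer-like decay to the ground state (so predictions for real
photophysics degrade beyond ~100 fs), and full-dimensional (≳ 6-mode)
propagation is out of reach of the exact propagators by design — that is
the domain of the tensor-tree codes this package can export models to via
`write_mctdh_operator()`.
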