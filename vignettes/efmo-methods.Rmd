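---
title: "Fragment energies, frozen domains and reaction paths: the methods behind efmo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment energies, frozen domains and reaction paths: the methods behind efmo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efmo)
```

## The model

The effective fragment molecular orbital (EFMO) method approximates the
energy of a large molecular system by partitioning it into fragments
(here: one amino-acid residue or one water per fragment) and combining
three ingredients:

* **monomer energies** $E_I$ of every fragment, evaluated in the gas phase
  by a fragment backend;
* **dimer corrections** for *near* fragment pairs,
  $\Delta E_{IJ} = (E_{IJ} - E_I - E_J) - E^{\mathrm{pol}}_{IJ}$, where
  $E_{IJ}$ is the backend energy of the pair's union roster and
  $E^{\mathrm{pol}}_{IJ}$ removes the classical pair-induction energy that
  the many-body polarization term would otherwise double count;
* **classical terms** for everything else: atom-centered distributed
  multipole electrostatics (charges, dipoles, traceless Buckingham
  quadrupoles) for *far* pairs, plus one self-consistent induced-dipole
  polarization energy $E^{\mathrm{pol}}_{\mathrm{tot}}$ spanning the whole
  system.

The total is
$$
E = \sum_I E_I + \sum_{R_{IJ} < R_{\mathrm{resdim}}} \Delta E_{IJ}
  + \sum_{R_{IJ} \ge R_{\mathrm{resdim}}} E^{\mathrm{es}}_{IJ}
  + E^{\mathrm{pol}}_{\mathrm{tot}},
$$
with pairs classified by the unitless interfragment distance
$R_{IJ} = \min_{i \in I, j \in J} r_{ij} / (R^{\mathrm{vdw}}_i +
R^{\mathrm{vdw}}_j)$ (shared boundary atoms excluded; Bondi radii frozen
into the package).  Covalently bonded neighbor fragments share a boundary
atom and are always treated as near pairs regardless of $R_{IJ}$.

Assumptions worth making explicit: monomer energies are plain gas-phase
energies with no self-polarization removal; the classical electrostatic
term switches on abruptly at $R_{\mathrm{resdim}}$ with no damping or
switching function, so the model energy is discontinuous as a pair crosses
the threshold (on the mock backend the jump equals the neglected
Lennard-Jones tail, which the tests quantify); and multipole moments are
treated as geometry-independent within a step, so electrostatic gradients
are "frozen-moment" gradients without response terms.

## Fragmentation and bond detachment

Covalent bonds between fragments are not cut.  Fragmentation at residue
granularity shares one boundary atom per inter-fragment bond: for peptides
the boundary sits at the C$\alpha$–C(carbonyl) bond with C$\alpha$ shared
(the backbone carbonyl rides with the next residue's amide), and for
generic residues the bond atom in the lower-numbered fragment is shared.
Charge bookkeeping assigns a shared atom to its owning fragment only, so
no classical site is double counted.

When a fragment (or dimer union) is evaluated in isolation, each severed
bond is terminated by a hydrogen **link atom** placed on the bond axis at
1.09 Å from the inside atom.  A cap position is a function of the two
bond-end positions, so cap gradients are chain-ruled exactly onto those
atoms; this is why analytic gradients agree with finite differences even
across fragment boundaries.  A frozen-orbital treatment of the detached
bond would need access to the electronic-structure internals of a real
backend; the backend contract leaves room for such an engine, and the
link-atom construction is the package's default realization.

## Polarization

Each polarizable site carries an induced dipole
$\mu_i = \alpha_i (F^{\mathrm{static}}_i + \sum_{j \ne i} T_{ij} \mu_j)$.
A site is *not* polarized by its own fragment's permanent moments
(standard exclusion in the induced-dipole model), while mutual
dipole–dipole coupling spans all sites.  The equations are solved by a
direct dense (Cholesky) solve up to 300 sites and by fixed-point iteration
beyond, to a residual max-norm of $10^{-8}$ e·bohr by default; both routes
are deterministic.  The interaction tensor is the bare point-dipole tensor
with no Thole damping — a polarization catastrophe (loss of positive
definiteness) is detected and reported with the closest site pair rather
than silently damped.  $E^{\mathrm{pol}}_{IJ}$ uses the isolated-pair
convention: only the dimer's own sites and moments enter.  Polarization
*gradients* are computed by central finite differences of the polarization
energy ($h = 10^{-4}$ bohr); analytic response gradients are out of scope,
and this term dominates gradient cost when many polarizable sites are
present.

## Frozen domains

For geometry optimization of an active site, fragments are partitioned
into an **active** region A (all fragments within `R_active` of the
target fragment, default 2.0 Å), a **buffer** b (fragments within
`R_buffer` = 2.5 Å of A), and a **frozen** remainder F.  Only A atoms
move; a shared boundary atom is mobile only when both owning fragments
are active.  The frozen region's internal energy is constant and dropped;
every coupling touching F is classical; monomers and QM dimers are
evaluated only inside A ∪ b.  The FDD variant also skips QM dimers with
both fragments in b — they cannot contribute to the energy or gradient of
A, which the test suite verifies as an exact identity (FDD − FD equals
minus the buffer-internal dimer sum) and by auditing backend calls.
Frozen-region multipoles and polarizabilities are evaluated once per
session and cached by fragment id; an active fragment covalently bonded
to a frozen fragment is refused, because the classical treatment of
A–F couplings presumes the two regions are well separated.  The distance
predicate uses all atoms (hydrogens included) — the minimum interatomic
distance, with no heavy-atom filtering.

A single engine implements the full and frozen-domain energies, so a
degenerate assignment (everything active) reproduces the full EFMO energy
bit-for-bit rather than merely to a tolerance.

## Reaction-path scanning

The reaction coordinate is $R = r_1 - r_2$, breaking-bond length minus
forming-bond length: negative at the reactant, positive at the product.
A scan steps $R$ in 0.1 Å increments, each step minimizing
$E_{\mathrm{FD(D)}} + \tfrac12 k \sum_m (r_m - r_m^{\mathrm{target}})^2$
over the mobile Cartesian coordinates with $k = 500$ kcal mol⁻¹ Å⁻²,
starting from the previous optimized geometry (adiabatic continuation).
Since only the combined step of $R$ is prescribed, the two bond targets
advance symmetrically by $\pm \Delta R / 2$, linearly interpolated between
the endpoint values — a documented interpretation, configurable through
the per-step targets of `restrained_minimize()`.  Convergence follows the
OPTTOL semantics: maximum absolute component of the objective gradient on
mobile atoms below $5 \times 10^{-4}$ hartree/bohr, with at most 200
L-BFGS iterations per frame; an unconverged frame is flagged, never
silently accepted.  Reported profile energies exclude the restraint
penalty (both are stored, and a bookkeeping identity test reconstructs
the optimizer's objective from them).  Line-search probes that reach a
singular geometry return a large finite value so the optimizer
backtracks instead of crashing.

Path energies can be refined per frame by subtractive two-layer ONIOM,
$E = E^{\mathrm{low}}_{\mathrm{total}} + E^{\mathrm{high}}_{\mathrm{model}}
- E^{\mathrm{low}}_{\mathrm{model}}$, with the model region extracted by
the same capping rule and computed in the gas phase (no environment
multipoles).  Relative energies are invariant under constant shifts of
either level, which the tests assert numerically.

## Ensemble activation enthalpies

Over an ensemble of adiabatic paths, two estimators are reported: the
mean of per-path barriers (highest energy minus lowest energy at negative
$R$, averaged over paths) and the barrier of the averaged profile
(profiles averaged at each grid point first).  Because max/min do not
commute with averaging, the per-path estimator always dominates; the gap
is reported as a transition-state-alignment diagnostic.  Both subtract a
ZPE/thermal correction, default 1.6 kcal/mol, applied to the electronic
barrier; the sign convention (subtraction, reducing the barrier toward an
enthalpy) is exposed as a signed configurable value.  The uncertainty of
the mean is $\mathrm{sd}/\sqrt{N}$.  Paths scanned on the package's
common 0.1 Å grid align exactly; differing grids are linearly
interpolated onto the shared range and flagged.

## The mock backend and what passing tests mean

Real electronic structure is out of scope: the backend contract (energy,
gradient, multipoles, polarizabilities for a capped roster) is filled by a
deterministic analytic potential — harmonic bonds (k = 0.5 hartree/bohr²,
equilibrium at covalent-radius sums), harmonic angles (k = 0.1
hartree/rad², equilibrium 104.52°), and Lennard-Jones (ε = 3·10⁻⁴
hartree, σ = 3 bohr) plus Coulomb terms over all pairs excluding 1-2 and
1-3 neighbors.  Element charges (O −0.8, H +0.4, N −0.4, C 0.0 e) are
neutralized per residue to the residue's net charge; caps carry zero
charge.  Reported multipoles are exactly these point charges, so the
classical far-pair electrostatics is exactly consistent with the mock
dimer Coulomb term — by construction, the only full-versus-fragment
discrepancy on neutral clusters is the neglected far-pair Lennard-Jones
tail.  The `mock-pol` variant adds small isotropic site polarizabilities
(H 0.4, O 1.2, N 1.5, C 1.8 bohr³), chosen once from the stability
condition of the undamped point-dipole model at bonded distances
($\alpha_i \alpha_j < r^6/4$).

The synthetic generators produce the study systems:

* `make_water_cluster()` — rigid equilibrium waters placed in a sphere
  with minimum O–O separation 2.6 Å.  The general default radius is
  density-based (1.93 · n^⅓ Å, bulk-water-like, so placement stays
  feasible at any n).  The supermolecule-identity checks use a compact
  droplet (radius 2.2 Å, hydrogen-bond-scale spacing) so that the default
  dimer cutoff of 1.5 captures every pair: with the frozen mock constants,
  any pair classified far at 3.6–7.6 Å minimum distance would contribute
  more Lennard-Jones tail than the 10⁻⁶ hartree bound being demonstrated,
  so the compact droplet is the geometry on which that identity is a
  meaningful statement about truncation rather than about cluster size.
* `make_bonded_chain()` — a zig-zag C/N chain of four-atom units with one
  shared atom per junction, exercising the cross-region shared-atom
  machinery and cap gradients.
* `make_toy_reaction()` — a proton shuttling between two anionic oxygen
  sites 3.70 Å apart inside a frozen solvent shell (6 waters at 5.0–6.4 Å),
  giving a symmetric double-well with a barrier near 33 kcal/mol over a
  reaction coordinate spanning ±1.35 Å.  The donor and acceptor sit in the
  buffer (their QM dimers with the proton provide the repulsive wall), the
  solvent in the frozen region.  An independent reference profile comes
  from direct constrained minimization of the proton position over an
  $(r_1, \varphi)$ parameterization at fixed $R$ — no restraints, no
  adiabatic continuation — against which the scan agrees to well under
  0.1 kcal/mol.

What passing tests do **not** show: the mock potential has no
charge-transfer, exchange repulsion, anisotropic multipoles or
geometry-dependent moments, so agreement here validates the *formalism*
(assembly, bookkeeping, gradients, region logic, scanning, statistics),
not the accuracy of EFMO with a real electronic-structure backend on real
enzymes.

## Numerical choices

* Units: Å and kcal/mol at the user surface, bohr and hartree internally;
  CODATA 2018 conversion constants in one place (`efmo_units`).
* Atom indexing is 1-based throughout, matching both R and the chemistry
  convention for reports.
* Deterministic pair ordering (I < J) and a single accumulation pass make
  energies bit-reproducible run to run; generator randomness is local to
  an explicit seed and restores the caller's RNG state.
* Monomer/dimer results are cached per session keyed by roster,
  coordinates and level, so a geometry step only recomputes fragments
  that moved; the backend-call log in the session is the audit trail for
  the frozen-domain claims.
* Interaction tensors $T^{(n)} = \nabla^n (1/r)$ are built explicitly
  through rank 5 (quadrupole–quadrupole gradients); charge-only sets take
  a vectorized Coulomb fast path.
* Degenerate inputs fail loudly: coincident multipole sites, polarization
  catastrophes, restraints on fully frozen bonds, paths without a
  negative-coordinate frame, non-overlapping ensemble grids.

Problem sizes in the test and acceptance runs — clusters of 3–20 waters,
chains of up to 5 units, a 21-atom reactive system, ensembles of 7
scanned paths — were chosen as the smallest systems that exercise every
term of the energy with all identities non-trivial.

## Known limitations

* Polarization gradients are finite-difference; analytic response terms
  are absent.
* No Ewald or periodic electrostatics; no charge-penetration corrections.
* The restrained scan requires each restrained bond to have at least one
  mobile atom; it does not require all four restraint atoms to be active,
  which permits scans (like the toy) where a frozen partner anchors one
  end of a restrained bond.
* No true transition-state refinement (eigenvector following) or
  free-energy methods along the path; the barrier estimators work on the
  adiabatic profiles alone.
* Multi-frame restart assumes identical scan settings, enforced through
  a provenance hash.
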