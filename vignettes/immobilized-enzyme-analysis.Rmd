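---
title: "Methods: adsorption, correlation-network and binding-energy analysis of enzyme-nanotube trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adsorption, correlation-network and binding-energy analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immopsn)
```

`immopsn` analyses molecular-dynamics trajectories of an enzyme adsorbed
on a carbon nanotube (or any receptor-ligand system with a rigid
surface). This vignette is the package's account of the models it
implements, the tunable parameters, the numerical choices, and what the
synthetic-data tests do and do not demonstrate.

## Data model

A `structure_model` is an ordered atom table plus coordinates; residues
are assembled from contiguous (chain, residue-number) runs. Internal
residue indices are 0-based and contiguous, while the original PDB
residue numbers survive as *labels*, so subtilisin-literature names
(Gly100, Ser221) remain meaningful after parsing. A `trajectory` binds a
frame list to a model with a frame interval in ps (default 2 ps, a
common coordinate-saving interval). Multi-model PDB is the one trajectory
format every component reads and writes; alternate locations keep the
highest-occupancy conformer; crystal waters are parsed but excluded from
the default `"enzyme"` group, since no analysis here treats them as part
of the protein.

## Surface adsorption

**Adsorbed-atom count.** A protein heavy atom is adsorbed when its
minimum distance to any surface atom is at most the criterion distance
(default 6.0 Å, the customary hydrophobic-contact criterion). Hydrogens
are excluded by default; the count is monotone in the cutoff by
construction.

**SASA.** Shrake–Rupley quadrature: per-atom area is the exposed
fraction of `n_points` test points on the probe-expanded sphere times
$4\pi (r+p)^2$. Defaults: probe 1.4 Å for every solvent (no
solvent-specific probes are attempted; the same probe feeds the
nonpolar solvation term), Bondi-style radii (C 1.70, N 1.55, O 1.52,
S 1.80, H 1.20, P 1.80 Å; nanotube carbon uses the C radius), 960
points. The point set is a deterministic Fibonacci lattice rather than a
random sphere sampling, so results are exactly reproducible. The lattice
is oriented in a molecule-fixed principal-axes frame with canonical
signs taken from the third coordinate moment; this makes SASA invariant
under rigid motion of the system. Where SASA *differences* are formed
(contact areas, nonpolar solvation differences, per-atom burial), all
component calculations share the complex's frame so quadrature
orientation cancels exactly; an isolated pair of groups then buries
exactly zero area.

**Contact area.** The buried-surface convention
$(\mathrm{SAS}_a + \mathrm{SAS}_b - \mathrm{SAS}_{ab})/2$ is the
default; both halved and unhalved conventions exist in the literature
and the `halved` switch selects between them. Small negative quadrature
residues are clamped to zero.

**Density grids.** Frames (optionally strided; the stride must be a
multiple of the frame interval) are least-squares superposed onto the
first used frame over a fit selection, then target atoms are binned into
cubic voxels (default 0.5 Å edge). The reference is the first used frame
because a density grid needs *a* fixed frame and the choice does not
affect occupancy statistics. Counts are conserved by construction;
probability normalization divides by the total observation count.

## Conformation

Superposition is the Kabsch least-squares rotation via SVD with the
reflection excluded; fewer than three atoms or rank-deficient
coordinates are rejected. RMSD series superpose each frame on the
reference over the analysis selection before measuring; the default
reference is the topology coordinates (the crystal structure when read
from one). Both Cα and heavy-backbone selections are supported because
both conventions appear in practice; each analysis takes its selection
explicitly.

RMSF uses three fit-to-mean iterations from a first-frame reference
(the mean structure is not known before fitting; three iterations are
ample for convergence on equilibrated data) and reports per-residue
values through the residue's Cα. A single-frame trajectory has no
defined fluctuation and errors.

The inter-strand distance of the binding pocket defaults to the distance
between geometric centers of heavy backbone atoms of residues 100–103
and 125–128. The metric is not standardized in the literature, so
minimum heavy-atom distance and Cα-centroid distance are selectable
alternatives; distances are instantaneous per frame (no reference
structure enters). Histograms use 0.5 Å bins and conserve the frame
count.

## Dynamical cross-correlation

$$C(i,j) = \frac{\langle \Delta r_i \cdot \Delta r_j\rangle}
{\left(\langle|\Delta r_i|^2\rangle \langle|\Delta r_j|^2\rangle\right)^{1/2}}$$

with $\Delta r$ the deviation from the time-mean position, computed
after (optional, default on) iterated superposition onto the mean
structure — three iterations starting from the first frame, the same
convention as the RMSF. A residue with zero positional variance would
produce NaN rows; instead its off-diagonal entries are set to 0 with a
warning, keeping downstream masking well-defined. Values are clamped to
[−1, 1] and symmetrized against floating-point drift; the diagonal is
exactly 1.

Averaging across windows or replicas is element-wise and unweighted;
the cutoff mask marks $|\bar C| \ge 0.4$ by default. To check that
averaging loses no relevant structure, a consistency statistic is
reported per input: the fraction of masked off-diagonal entries whose
sign agrees with the mean's. The default analysis window is the trailing
10 % of frames — the equilibrated-tail convention (a 20 ns tail of a
200 ns run); it is a fraction, not an absolute time, so it scales with
the data.

## Protein structure network

Edges carry the interaction strength
$I_{ij} = 100\, n_{ij} / \sqrt{N_i N_j}$ (percent), where $n_{ij}$
counts distinct side-chain heavy-atom pairs within 5.0 Å and $N$ are
per-residue-type normalization constants from the PSN literature
(packaged defaults, replaceable via TSV; unknown types fall back to
99.9). Conventions, all configurable:

- Glycine has no side chain and contributes its Cα as proxy; this is
  the standard PSN convention.
- Sequence-adjacent residues (|i−j| = 1 on a chain) are excluded: they
  are covalently linked, and the network is about non-covalent
  interaction.
- The edge-inclusion threshold `i_min` defaults to 3.0 % — a typical
  working value in PSN practice; it is printed wherever used because
  path counts depend on it.
- Only amino-acid residues are nodes; normalization values for the
  nanotube or ligands are undefined.

Communication paths are all minimum-hop paths between a source and
target on the retained (unweighted) edges. A path is kept only if at
least one *intermediate* node is correlated (|C| ≥ 0.4 by default) with
an endpoint; a direct two-node path has no intermediate and is
discarded as trivial self-communication. Per-frame path sets are
accumulated with fractional tie weighting — a frame with $k$ tied
shortest paths contributes $1/k$ to each — making frequencies
deterministic and order-independent, and bounding the per-pair frequency
sum by 1. Paths above the dominance threshold (default 0.30, strictly
greater) are flagged dominant. Because the literature is ambiguous about
whether path counts enumerate (pair, path) combinations or unique paths,
both counts are reported. Desorption analysis marks a residue adsorbed
when any heavy atom is within the criterion distance, and desorbed when
it was adsorbed in the reference frame but is not now.

## MM-GB(SA) binding energy

Single-trajectory protocol: receptor and ligand coordinates are
extracted from complex frames, so the internal (bond/angle/dihedral)
difference is identically zero, and

$$\Delta G_\mathrm{bind} = \Delta E_\mathrm{ele} + \Delta E_\mathrm{vdw}
+ \Delta E_\mathrm{int} + \Delta G_\mathrm{npsolv} + \Delta G_\mathrm{psolv}.$$

No entropy term is computed. Kernels:

- Coulomb: $k\,q_i q_j / (\varepsilon_\mathrm{in} r_{ij})$ with
  $k = 332.0637$ kcal Å mol⁻¹ e⁻²; no distance cutoff (cutoffs belong
  to the MD engine, not to end-state analysis).
- Lennard-Jones: $\varepsilon_{ij}[(R_{min,ij}/r)^{12} -
  2(R_{min,ij}/r)^6]$, $R_{min,ij} = R_i + R_j$,
  $\varepsilon_{ij} = \sqrt{\varepsilon_i \varepsilon_j}$.
- Polar solvation: a pairwise-descreening generalized-Born model,
  $-\tfrac{k}{2}(1/\varepsilon_\mathrm{in} -
  1/\varepsilon_\mathrm{ext})\sum_{ij} q_i q_j / f_\mathrm{GB}$ with
  $f_\mathrm{GB} = \sqrt{r^2 + B_iB_j e^{-r^2/4B_iB_j}}$ and effective
  Born radii from HCT-style descreening integrals. The Born-radius
  offset defaults to 0 so an isolated ion reduces exactly to the Born
  equation with its tabulated GB radius. The polar backend is a plain
  function of coordinates and parameters, so a Poisson–Boltzmann solver
  could be substituted; GB preserves all the identities and limits the
  tests rely on (Born limit, zero at no dielectric contrast, additivity
  at separation, magnitude decreasing from water ε = 80 to heptane
  ε = 1.92).
- Nonpolar solvation: $\gamma \cdot \mathrm{SASA}$ with
  γ = 0.0072 kcal mol⁻¹ Å⁻², probe 1.4 Å.

Solvent presets: water ε = 80, acetonitrile 37.5, heptane 1.92; interior
dielectric 1 (configurable). Per-atom parameters (charge, R_min/2, LJ ε,
GB radius, screening factor) come from a TSV rather than binary topology
files, keeping inputs desk-auditable; an sp² aromatic-carbon preset with
zero charge covers nanotube atoms. Reported uncertainties are standard
errors (sample SD / √n over snapshots) and are labelled as such, since
"±" columns in the literature are often ambiguous between SD and SE.

All derived components are computed from the primitives, so the
additivity identities
($\Delta E_\mathrm{gas} = \Delta E_\mathrm{ele} + \Delta E_\mathrm{vdw} +
\Delta E_\mathrm{int}$,
$\Delta G_\mathrm{solv} = \Delta G_\mathrm{npsolv} + \Delta G_\mathrm{psolv}$,
$\Delta G_\mathrm{ele} = \Delta E_\mathrm{ele} + \Delta G_\mathrm{psolv}$,
$\Delta G_\mathrm{bind} = \Delta E_\mathrm{gas} + \Delta G_\mathrm{solv}$)
hold to machine precision on every run.

The per-residue decomposition splits each inter-group pairwise term half
to each partner atom's residue, assigns GB and SASA shares per atom, and
sums per residue (ligand rows included), so every component column sums
to the corresponding system total; the conventional report filter flags
residues with |total| > 1.0 kcal/mol.

## Synthetic generators

Every analysis stage has a generator producing trajectories whose
ground truth is known exactly: staged adsorption (scheduled counts
placed inside cutoff − 0.5 Å / outside cutoff + 0.5 Å of a pseudo-tube),
Gaussian fluctuations with prescribed block covariance, two-state
contact switching with hand-computable path frequencies, strand-opening
distance schedules, and charged/LJ toys whose reference energies come
from an explicit scalar double loop. Generators are bit-reproducible
from their seed and write standard multi-model PDB so they exercise the
real I/O path.

What they emulate is the *statistical structure the estimators assume* —
prescribed contact counts, covariances, state populations. What they do
not emulate: force-field physics, solvent structure, anharmonic or
correlated-in-time dynamics, conformational drift. A passing recovery
test therefore certifies the estimator, not the biology: it shows the
pipeline returns the right answer when the modelled structure is
actually present in the data.

## Problem sizes and tolerances

The test suite runs at sizes chosen to make sampling error predictable:
correlation recovery uses 5000 frames (SE of a correlation estimate
≈ 0.014, against a ±0.05 band), RMSD/RMSF noise checks use 200–2000
frames against 5 % bands, SASA quadrature at 960 points is checked
against two-sphere closed forms within 1 %, kernels against analytic
values at 10⁻⁶ relative, conservation identities at 10⁻⁶ kcal/mol or
machine precision, and graph algorithms against exhaustive enumeration
on 50 random graphs of up to 12 nodes. The whole suite completes in
well under a minute on one CPU.

## Known limitations

- Only armchair (n,n) nanotubes are generated; zigzag/chiral and capped
  tubes are out of scope.
- The polar solvation term is GB, not a finite-difference
  Poisson–Boltzmann solution; absolute polar energies for irregular
  shapes will differ from PB, though limits and identities agree.
- No entropy estimate; reported binding energies are enthalpy-like
  end-state values.
- mmCIF parsing, protonation assignment and bond-topology inference are
  not provided; inputs are expected to be analysis-ready PDB.
- PSN nodes are amino-acid residues only; ligand- or nanotube-mediated
  paths are not represented.
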