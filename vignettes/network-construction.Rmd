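---
title: "Building surface-accessibility and hydrogen-bond elastic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building surface-accessibility and hydrogen-bond elastic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sahbnet)
```

## The problem and the model

MARTINI-style coarse-grained forcefields map roughly four heavy atoms to
one bead and hold secondary structure with bonded terms, but they do not
maintain tertiary structure on their own. The usual remedy is an elastic
network: harmonic springs between bead pairs, with rest lengths taken
from the experimental structure. A uniform distance-cutoff network
(ELNEDYN: all backbone-bead pairs within $R_c$, at least three positions
apart in sequence, $k = 500\ \mathrm{kJ\,mol^{-1}\,nm^{-2}}$) is very
stable but stiffens everything, loops included.

The SAHBNET recipe implemented here is more selective. It combines two
sources of springs, both read off the atomistic structure:

1. **Hydrogen-bond network.** Backbone beads of two residues are linked
   when their atomistic counterparts share a backbone hydrogen bond.
   These springs trace α-helical ladders and β-sheet rungs and also pick
   up structured loops.
2. **Surface-accessibility network.** A residue whose relative solvent
   accessibility is below $SA_c$ is treated as buried, on the rationale
   that a buried residue's packing interactions matter for global
   stability. Its beads (backbone beads in BB mode, side-chain beads in
   SC mode) are linked to all beads of the same kind within $R_c$ and at
   least five sequence positions away. Partner residues need not be
   buried; pairs on different chains always pass the separation filter,
   which is what makes multimer interfaces work.

The merge drops duplicate pairs, keeping the hydrogen-bond label — a
doubled harmonic would silently double the effective force constant.
Springs store the bead pair, the rest length $b_0$ (the bead distance in
the input structure) and $k$.

### Parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| $SA_c$ | burial cutoff, % relative accessibility | 30 | small proteins may need more; large ones network already at 5 |
| $R_c$ | distance cutoff, nm | 0.9 (BB), 0.5 (SC) | SC networks link interacting side chains, hence shorter reach |
| $K_\mathrm{SPRING}$ | force constant, kJ mol⁻¹ nm⁻² | 1000 | membership of springs never depends on it |
| min. separation (surface) | ordinal $\lvert i-j\rvert$ | 5 | "separated by five positions" read as $\ge 5$ |
| min. separation (ELNEDYN) | ordinal $\lvert i-j\rvert$ | 3 | $i,i{+}1$ and $i,i{+}2$ are covered by explicit bonded terms |

`sweep_parameters()` tabulates spring counts over grids of the three
main dials; spring sets are nested as $SA_c$ or $R_c$ grows, which the
test suite asserts as an invariant.

## Relative accessibility and its reference constants

Absolute per-residue areas come from a Shrake–Rupley engine: test points
on each atom's probe-expanded sphere (probe 0.14 nm, 960 points, Chothia
heavy-atom radii; hydrogens excluded), occluded by neighboring expanded
spheres. Each atom's point grid is oriented in a frame derived from its
nearest neighbors, so computed areas are invariant under rigid-body
motion of the input rather than merely convergent; an isolated atom
reproduces $4\pi(r+p)^2$ to machine precision by construction.

Relative accessibility divides a residue's area by the mean area of the
same residue type as the central residue of the 400 extended
G-X₁-R-X₂-G pentapeptides (X over the 20 standard residues). The 20
reference means ship as immutable constants (`reference_sa()`); they
were produced by a different engine than ours, so
`regenerate_reference_table()` can rebuild the construction with the
local engine as a *diagnostic* — regenerated means land within a few
percent of the constants (glycine ≈ 78 vs 80.8 Å² at default settings)
but never silently replace them. Values above 100 % are legitimate
(chain termini) and are not clamped. Residue types without a reference
value (modified amino acids) are excluded from burial eligibility with a
warning.

Extended-form torsions for the pentapeptides default to
$\varphi = -139^\circ, \psi = +135^\circ$ (antiparallel-β extended);
they are arguments, since "extended" admits variants, and the fully
extended $180^\circ/180^\circ$ form is available for comparison.

## Hydrogen-bond detection

The package places missing amide hydrogens geometrically (1.0 Å from N,
in the C(i−1)–N–CA plane opposite the bisector; prolines and chain-first
residues get none) and scores donor→acceptor pairs with the DSSP-style
electrostatic energy

$$E = 0.084 \cdot 332 \left(\frac{1}{r_{ON}} + \frac{1}{r_{CH}}
      - \frac{1}{r_{OH}} - \frac{1}{r_{CN}}\right)\ \mathrm{kcal/mol},$$

bonding below −0.5 kcal/mol. A geometric criterion
($r_{N\cdots O} \le 0.35$ nm, N–H⋯O angle ≥ 120°) is available and
agrees with the energy form on the ideal-helix fixture. Design choices
worth knowing:

* Only backbone–backbone bonds are considered — the network rule
  attaches springs to backbone beads.
* $i,i{\pm}1$ pairs are excluded as artifacts of backbone covalency;
  $i,i{+}2$ and beyond are allowed so the helical $i,i{+}4$ ladder and
  sheet contacts survive.
* Each donor keeps only its best acceptor, so bifurcated bonds cannot
  create duplicate springs. On the ideal 10-residue helix this yields
  exactly the six $i \to i+4$ bonds; the competing $i \to i+3$ geometry
  scores ≈ +0.2 kcal/mol and is correctly rejected.

A Stride report can replace both engines (`parse_stride()`): its ASG
areas feed the same normalization and its DNR/ACC pairs feed the same
spring builder, so externally computed inputs and the self-contained
path are interchangeable downstream.

## Bead mapping

`map_structure()` implements the MARTINI 2.1 amino-acid mapping: one
backbone bead per residue (center of mass of N, CA, C, O by default, or
the CA position in `ca` mode, which ELNEDYN construction uses) and zero
to four side-chain beads per residue type at mass-weighted centers of
the mapped atom groups (e.g. Lys two, His/Phe/Tyr three, Trp four).
Masses are used only for bead placement; dynamics is out of scope.
Missing side-chain atoms degrade gracefully (bead from available atoms,
with a warning); unknown residue types are an error.

## The normal-mode flexibility proxy

To compare how networks restrain motion without running simulations, the
package builds the standard anisotropic-network Hessian over the spring
set: each spring contributes $-k\,\hat r\hat r^{\mathsf T}$ off-diagonal
super-elements, diagonal blocks balance the rows, eigenmodes give
per-bead mean-square fluctuations $\propto k_BT \sum_m \lambda_m^{-1}
v_{m}^2$ over non-rigid modes (T = 300 K, near-zero threshold
$10^{-8}\lambda_{max}$).

The network alone is not a mechanical model of the protein — in a real
system the parent forcefield's bonded terms carry the chain. Stand-in
springs are therefore added for the proxy only: backbone $i,i{+}1$
springs (k = 1250 kJ mol⁻¹ nm⁻², roughly a MARTINI bond), weaker
$i,i{+}2$ and $i,i{+}3$ springs (k/5, k/25, standing in for angle and
dihedral stiffness), and anchors tying each side-chain bead to its
backbone bead, the preceding side-chain bead and the two nearest
backbone beads along the chain (a single-spring pendant bead would
otherwise contribute spurious zero modes). These stand-ins never appear
in exported topologies.

A connected, sufficiently constrained network has exactly six near-zero
modes; more than six raises an error that distinguishes a disconnected
bead graph (components are listed) from an under-constrained one. RMSF
magnitudes from this proxy are not calibrated against simulation — only
orderings and profile shapes are meaningful, and that is all the tests
assert: on a packed helix–loop–helix fixture the dense uniform ELNEDYN
network yields a flatter, uniformly low RMSF profile, while SAHBNET
keeps the loop beads mobile. `rmsd_series()` (Kabsch superposition) and
`delta_profile()` support comparing profiles from external ensembles in
the same container.

## What the synthetic fixtures do and do not show

Fixtures are built from internal coordinates: ideal α-helices
($\varphi=-57^\circ,\psi=-47^\circ$; 1.0 Å amide hydrogens; CA–CA
0.38 nm, rise ≈ 0.15 nm), extended pentapeptides with side chains in a
fixed canonical rotamer, a 24-residue poly-leucine helix–loop–helix
whose helices pack closely enough to bury core residues, and random-walk
toy bead clouds for rule-enumeration oracles. They exercise every code
path — detection thresholds, burial, separation and distance filters,
multimer interfaces via two-chain variants — at sizes where brute-force
enumeration is feasible (≤ 30 residues, 20 random cases per run).

They are not crystal structures: side-chain rotamers are idealized, no
waters or ligands are present, and burial patterns are simpler than in
real folds. Passing tests therefore demonstrate that the rules are
implemented exactly as stated and behave monotonically, not that any
particular protein will be stable in simulation. Likewise the packaged
reference constants are trusted as given rather than reproduced exactly,
because the engine that produced them (Stride) computes areas
differently; the regeneration diagnostic quantifies that gap instead of
hiding it.

## Numerical choices and limitations

* Lengths are held in nm internally (GROMACS convention); PDB I/O
  converts from/to Å, and SASA is reported in Å² as is customary.
* Topology output writes $b_0$ to 5 decimals (0.01 pm) and integral
  force constants as integers; the parser tolerates comments, blank
  lines, `#ifdef` guards and foreign function types (kept, with a
  warning).
* `lipid_count()` returns a per-leaflet count (floor of
  $x\,y \cdot 256/100$ lipids for an XY surface in nm²); callers double
  it for bilayers.
* Eigen-decomposition is dense (`eigen()`), fine for the hundreds of
  beads this package targets; very large complexes would want sparse
  solvers.
* Residue identity is (chain, author number, insertion code); all
  separation filters use ordinal positions within the chain, so author
  numbering gaps cannot silently shrink separations.
* Out of scope by design: running dynamics, MARTINI's own bonded and
  nonbonded terms, lipid topologies, secondary-structure assignment, and
  filtering the redundancy between hydrogen-bond springs and the
  forcefield's secondary-structure network (deliberately left
  unfiltered, matching the published recipe).
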