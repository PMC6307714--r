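---
title: "The cgfold model: energies, sampling and training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cgfold model: energies, sampling and training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgfold)
```

## Degrees of freedom

`cgfold` represents a protein by the Cartesian coordinates of three atoms
per residue — N, Cα and C — and integrates only those. Everything else is
a deterministic or marginalized function of the backbone:

* the carbonyl **O** of residue *i* is placed from (Cα, C)\_i and
  N\_{i+1}; the amide **H** of residue *i* from C\_{i-1} and (N, Cα)\_i;
  **Cβ** from (N, Cα, C)\_i along the ideal tetrahedral direction, on the
  side that gives the improper dihedral Cβ–Cα–N–C near −123°, as in
  experimental L-amino-acid structures;
* each residue's **side chain** is an oriented bead (a position and a unit
  orientation in the residue frame) with a small discrete set of rotamer
  states from a library, marginalized at every force call (next section).

Energy terms that act on virtual sites produce forces on those sites; the
forces are pulled back onto the N/Cα/C coordinates through the placement
Jacobians. Jacobians are computed by complex-step differentiation
(step 1e-20), which is exact to machine precision and needs no
hand-derived formulas, at the cost of evaluating the placement functions
on complex inputs. The placement functions are therefore written to be
holomorphic in a neighbourhood of real inputs; for example the Cβ
out-of-plane component uses a smooth floor instead of a hard `max(0, .)`.

## Side chains by belief propagation

The rotamer states of nearby residues interact through oriented pair
potentials, giving a pairwise Markov random field whose graph follows the
spatial proximity of the beads. At every force evaluation the package:

1. builds node energies (rotamer prior `-T log w` plus bead–backbone
   terms) and edge tables of pair energies;
2. runs damped (0.5) synchronous sum-product belief propagation in the
   log domain to convergence (tolerance 1e-12, at most 200 sweeps),
   warm-started from the previous call's messages whenever the edge set
   is unchanged;
3. adds the Bethe free energy to the total energy, and adds
   belief-weighted expectations of the stored per-state gradients to the
   forces. Because the beliefs are a stationary point of the Bethe free
   energy, the derivative through the beliefs vanishes (an envelope
   argument) and the belief-weighted force is exact at convergence.

On trees this is exact; on the loopy graphs of dense proteins it is the
standard Bethe approximation. The tight tolerance and generous sweep
budget cost little because warm starts typically converge in a few sweeps.
One consequence of folding the normalized prior into the node energies as
`-T log w` is that the side-chain free energy is non-decreasing in
temperature (its temperature derivative is a sum of Kullback–Leibler-like
terms); the test suite checks this identity.

## Energy terms and parameters

All trainable curves are uniform cubic B-splines, linear in their
coefficients, so exact parameter derivatives are just basis values.

* **Oriented pairs**:
  `V = kappa * (V_radial(r) + ang1(-n1·n12) ang2(n2·n12) V_angular(r))`.
  Side-chain pairs use 62 coefficients on [0, 10] Å, backbone pairs 54 on
  [0, 8] Å; radial curves end with three zero phantom coefficients so both
  value and derivative vanish at and beyond the cutoff. With 20 amino
  acids there are 210 unordered side-chain pairs (13 020 coefficients) and
  5 400 backbone-pair coefficients.
* **Burial**: per-residue-type splines in a smooth logistic neighbour
  count of surrounding Cβ sites (Cβ is the most type-independent proxy
  for side-chain density available from the backbone alone; using the
  packed beads here would make the burial term depend on the rotamer
  solution and double its cost).
* **Ramachandran**: a periodic bicubic (Catmull–Rom) table per residue
  class — general, glycine, proline, pre-proline — plus a Gaussian bump
  in the β-sheet basin whose height is the trainable `sheet_bias`.
* **Hydrogen bonds**: a product of smooth Gaussian/logistic factors in
  the H…O distance and the donor/acceptor collinearity, scaled by the
  trainable `hbond_magnitude`. The geometric constants (distance center
  2.4 Å, width 0.6 Å; angular centers 0.55/0.45, widths 0.35/0.40;
  minimum sequence separation 2) were set a priori so that an ideal
  α-helix scores ≈ 0.85 per i→i+4 bond: a 19-residue ideal helix counts
  15 hydrogen bonds at the default 0.5 threshold.
* **Sterics and bonded terms**: a quadratic ramp below 3.2 Å between
  non-bonded heavy sites, and harmonic bond/angle/ω terms that keep the
  peptide geometry near ideal values.

The bookkeeping total is 18 932 trainable numbers: 310 kappas, 13 020 +
5 400 pair coefficients, 200 burial coefficients and the 2 scalars.

## Sampling

* **Langevin dynamics** uses the BAOAB splitting, which samples
  configurations with second-order accuracy and tolerates large steps.
* **Pivot Monte Carlo** rotates the C-terminal segment about a randomly
  chosen φ or ψ axis by a uniform angle and accepts by Metropolis; these
  moves decorrelate global shape far faster than dynamics alone.
* **Replica exchange** holds one trajectory per ladder temperature and
  proposes neighbour swaps with alternating parity. The ladder is
  arithmetic with spacing proportional to 1/N<sub>res</sub> (a 100-residue
  reference), reflecting the 1/sqrt(N) narrowing of relative energy
  fluctuations.

## Training

Parameters are fit by contrastive divergence. For each native structure
two ensembles are sampled from the current model: a *restrained* one,
confined by a flat-bottom RMSD restraint (zero inside 1 Å, harmonic with
k = 50 outside) to stay near the native, and a *free* one. The update
moves every parameter by the step size times the difference between the
free-ensemble and restrained-ensemble means of the exact energy
derivatives, which raises the energy of what the model samples away from
the native and lowers it near the native. Systems are shuffled once into
fixed minibatches (456 systems at size 12 give 38 updates per pass), the
step size is divided by 4 after every 2 full passes, the first third of
every trajectory is discarded as burn-in, and every sampling run draws
its seed deterministically from the base seed and the global update
counter — so an interrupted run resumed from a checkpoint reproduces the
uninterrupted run bit-exactly.

## Analysis

Cα-RMSD uses the optimal (Kabsch) superposition and by default excludes
three residues at each terminus, which are flexible even in well-folded
ensembles. The radius of gyration is compared against the expanded-coil
reference `1.9 * nres^0.6` Å. Heat capacity is `var(E)/T²`, hydrogen
bonds are counted by thresholding the smooth geometric score, and
ensembles are summarized by greedy leader clustering on pairwise RMSD
with size-ordered clusters.

## Fixtures and toys

The package ships generators instead of data files:

* `make_backbone()` builds idealized helices (φ, ψ = −57°, −47°), strands
  (−120°, 130°) and Ramachandran-sampled coils with ideal bond geometry;
* `make_toy_parameters()` draws a small smooth random parameter set with
  every trainable block populated — useful for gradient checks because
  nothing is zero;
* `make_two_basin_toy()` is a one-dimensional double well with
  quadrature-exact occupancies and energy moments, used to validate the
  samplers against closed-form references.

## Limitations

The Bethe free energy is approximate on loopy graphs; side-chain beads
are single oriented points, so rotamer detail beyond the library is lost;
the solvent is implicit in the trained potentials; and the default
(untrained) parameter set only contains the fixed terms, so folding
behaviour requires training first. Performance is adequate for the small
systems the test-suite exercises (tens of milliseconds per force call
for ~10 residues) but the pure-R implementation is not tuned for large
proteins.
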