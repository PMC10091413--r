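---
title: "Refining GPCR binding-site models with ligand and mutagenesis data"
author: "pocketforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining GPCR binding-site models with ligand and mutagenesis data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketforge)
```

## The problem

Odorant receptors are the largest class A GPCR subfamily and have no
experimental structures; models of them come either from remote-homology
templates or from AlphaFold, which models most class A receptors in an
inactive, apo state. Either way the orthosteric pocket — the
extracellular-facing cavity lined by TM3/TM5/TM6/TM7 side chains — is
usually not in a ligand-competent conformation: known agonists dock
poorly or not at all, and a virtual screen cannot tell actives from
inactives. The working assumption of this package is that two
information sources that *are* available can drive the pocket into
shape:

1. **Pharmacology.** A small panel of confirmed agonists and a much
   larger panel of compounds that elicited no response. A good pocket
   conformation should rank the former above the latter.
2. **Mutagenesis.** Residues whose mutation to alanine abolishes
   activation. A plausible agonist pose should sit close to those
   residues.

The protocol alternates conformational sampling (delegated to a docking
engine) with selection on those two signals, shrinking the sampled
degrees of freedom each round.

## Evaluation statistics

Candidate models are ranked by docking score (kcal/mol, lower is
better). Compounds the engine fails to dock are appended after all
scored compounds, in stable input order: a model that cannot dock an
agonist must not get credit for it. Two tie policies are provided;
`average_rank` (default) gives fractional credit so the trapezoidal AUC
equals the tie-corrected Mann–Whitney statistic, `worst_case` orders
inactives before actives within a tie. The screening experiments the
defaults are calibrated for rarely produce exact score ties, so the
policies agree in practice.

The enrichment factor used here is the *actives-to-inactives ratio
within the top selection*, not the more common hit-rate ratio:

$$\mathrm{EF}_{15\%} = \frac{N_{\text{actives}(15\%)}}{N_{\text{inactives}(15\%)}},
\qquad n_{\text{sel}} = \lfloor 0.15\,N \rfloor .$$

This definition is what makes the reference values of a 13-active /
131-inactive library internally consistent: the selection is 21
compounds, the ideal ranking gives $13/8 = 1.625 \to 1.63$, and
rankings with 2, 4 and 7 actives in the selection give $2/19 \to 0.11$,
$4/17 \to 0.24$ and $7/14 \to 0.50$. Selection size uses `floor`
(21, not 22 — $13/8$ matches the printed maximum only at 21), a
selection with no inactives returns `Inf` rather than an error, and
displayed values are rounded half-up to two decimals
(`round_half_up()`; base `round()` is half-to-even and would print
1.62).

## Geometry

All internal lengths are Å; the 0.4 nm literature threshold enters the
API as 4.0 Å. Superposition is Kabsch via SVD with the determinant
correction (no reflections); pairing of atoms between models is always
explicit (`per_residue_ca_distance()` takes a pairing, defaulting to
the residues common to both models), because published cross-model RMSD
values rarely state their pairing and that choice measurably moves the
number — the acceptance suite demonstrates this sensitivity directly.

Conventions that matter for reproducibility:

- Residue selections (`select_within`, `binding_shell`,
  flexible-residue shells) use *closed* balls (≤), and results are
  sorted by chain then residue number.
- The pose filter is *strict* (<), following "below 0.4 nm": a pose at
  exactly 4.0 Å is discarded.
- Ligand centroids are unweighted heavy-atom means (no mass weighting).
- RMSF superposes every frame onto frame 1, takes the coordinate mean,
  and fits each frame to that mean once (a single iteration of the
  mean-fit loop). Fitting to the raw mean of unaligned frames would be
  degenerate under large rigid motions; this order makes RMSF exactly
  zero for rigid-body ensembles while keeping the computation
  deterministic. The superposition necessarily absorbs a share
  $O(1/n_{\text{atoms}})$ of a single residue's fluctuation, which is
  why the isotropic-noise calibration ($\mathrm{RMSF} \to \sigma\sqrt3$)
  is tested on a 100-residue system.
- Alanine truncation keeps N, CA, C, O, CB (and OXT); a glycine target
  gets a CB at 1.522 Å from CA placed to make both backbone angles
  exactly tetrahedral, on the L-amino-acid side of the backbone plane.
  A collinear backbone (only possible for artificial inputs) is an
  error, not a silent guess.

## Pose clustering and level selection

Complexes surviving the monitor-distance filter are compared by
heavy-atom RMSD over the ligand plus the binding shell (residues with
any heavy atom within 7 Å of the ligand centroid). By default the RMSD
is computed in the shared receptor frame without refitting — complexes
from one refinement lineage share that frame, and refitting would
discard exactly the side-chain rearrangement being clustered;
`refit = TRUE` is available for cross-lineage comparisons. Hydrogens
are excluded throughout (pose formats frequently omit them).

Agglomeration is unweighted average linkage (`stats::hclust`). The
dendrogram level is chosen by the Kelley–Gardner–Sutcliffe penalty: for
each level $k$ the mean within-cluster spread (mean pairwise distance,
clusters of size ≥ 2) is min–max normalised across levels onto
$[1, N-1]$ and added to $k$; the chosen level is the **second local
minimum** of this profile scanning $k$ upward. "Second minimum" is read
as second *local* minimum: the second-smallest value would almost
always be a neighbour of the global minimum and could never select the
several-dozen-cluster levels this criterion is known to produce on
sharp profiles. When the profile has fewer than two local minima — the
usual case for cleanly separated data, where the penalty descends
monotonically to the natural level — the global minimum is used. The
normalisation makes the selection invariant under uniform scaling of
the distance matrix. Ties for cluster representatives (equal key
metric) break lexicographically on pose id.

## The refinement protocol

A round is defined by which side chains the engine may move:

| round | flexible set                     | default radius |
|-------|----------------------------------|----------------|
| IFD1  | residues near pocket points      | 3.0 Å          |
| IFD2  | residues near the current ligand | 4.0 Å          |
| IFD3  | a named residue list (key pair)  | —              |

The gate keeps complexes with AUC strictly above 0.8 (the threshold and
strictness are configurable — the literature phrasing oscillates
between "higher than" and "greater than", so the choice is surfaced
rather than buried) and monitor distance strictly below 4.0 Å. Parents
stay in the candidate pool, so the maximum pool AUC is non-decreasing
by construction; a round in which nothing passes warns and leaves an
empty survivor set instead of failing, since a dead end is a result.
Pocket detection is out of scope: a pocket is user-supplied points or a
reference-ligand centroid plus a box edge.

The engine contract (`docking_engine()`) is three deterministic
functions — `dock`, `refine`, `score_in_place` — with the invariants
that scores are finite and `refine` moves only the ligand and the
declared flexible residues. How many poses a refinement retains is not
fixed by any reference we know of; it is exposed as `n_poses`/
`max_poses` (defaults 5/20).

## Synthetic systems and the mock engine

The generators define the study conditions for every test:

- `make_toy_receptor()` (50 residues, pocket radius 6 Å, seed 7 in the
  tests): residues on a cylindrical shell, side chains pointing inward,
  two full leucines placed diametrically so their Cα midpoint is
  *exactly* the pocket centre. This makes the monitor distance of a
  centred pose near zero by construction, mimicking the geometry the
  filter assumes.
- `make_screen_scores()`: binormal score model, actives
  $\mathcal N(-\delta, 1)$, inactives $\mathcal N(0, 1)$, with
  $\delta = \sqrt2\,\Phi^{-1}(\mathrm{AUC}_{\text{target}})$, so the
  population AUC is exactly the target. Library sizes in tests follow
  the screening set (13/131) or scale up to $10^4$ per class for the
  calibration checks.
- `make_pose_cloud()`: cluster centres on a lattice of spacing
  `between_sep` (10 Å in tests) with isotropic within-cluster jitter
  (0.5 Å) — a separation/spread ratio of 20, at which average linkage
  must recover the planted labels exactly.
- `make_loop_families()`: parametric backbone templates (extended
  strand, hairpin, helical arc) plus Gaussian noise, 3 × 10 segments at
  0.3 Å noise for the embedding tests.
- `mock_engine()`: contact-count scoring
  ($-$contacts $+\,10\times$clashes at 4.0 / 1.5 Å), chosen precisely
  because it is *not* physical: it is exactly invertible, so mutant
  rescoring can be asserted equal to the lost-contact count, and
  locality (mutations 20 Å away change nothing) holds exactly.

What these generators deliberately do **not** emulate: real docking
score distributions and their correlation structure, solvation and
protonation effects, backbone plasticity during induced fit, hydrogen
atoms, and the conformational heterogeneity of real agonist series. A
green test suite therefore certifies the *statistical and geometric
machinery* — it does not certify that any particular receptor model is
right, and the headline numbers of the motivating study that depend on
a commercial conformational search (per-model AUCs, pose and cluster
counts, docking scores) are not reproduction targets here.

All generators are bit-deterministic: one master seed fans out through
`split_seed()` (a Lehmer-style 31-bit step), so any single fixture can
be regenerated in isolation, and two runs of the full protocol under
one seed serialise identically.

## Loop shape space

Backbone segments must be pre-superposed to a common reference frame
before voxelisation — this module deliberately does not superpose,
because the choice of reference (e.g. a shared template receptor) is an
analysis decision, not a property of a loop. Voxels live on a lattice
anchored at a fixed origin (default the coordinate origin), spacing
1.0 Å, atom radius 2.0 Å: backbone-scale resolution at negligible cost,
and an anchored lattice makes grids of different segments directly
intersectable. The overlap of two grids is normalised by the *smaller*
volume, so self-overlap and containment are exactly 1 and the
$1-n$ dissimilarity spans $[0, 1]$; the normalisation used by the
vendor tool this mirrors is undocumented, so a Tanimoto variant is
provided behind a flag. Embedding uses an exact-gradient t-SNE
(perplexity 25, 1000 iterations, fixed seed; perplexity is reduced to
$\lfloor (N-1)/3 \rfloor$ with a warning when the ensemble is small,
and the value actually used is recorded with the result). Exact
gradients are the correct tool at these ensemble sizes (tens to a few
hundred segments); no tree approximation is implemented.

## Known limitations

- PDB only (via bio3d); no mmCIF, no trajectory formats — frame
  ensembles enter as multi-model PDB.
- Ballesteros–Weinstein labels are taken from a user CSV, never
  inferred: deriving them needs curated cross-receptor alignments.
- No hydrogens, protonation states, or physical energy model anywhere;
  scoring realism is the engine backend's job.
- The shipped mock engine explores conformations by Gaussian jitter; it
  exercises the protocol's control flow and bookkeeping, not docking
  accuracy.
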