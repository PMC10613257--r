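---
title: "Methods: active-site annotation, interaction networks and domain dynamics in pappalysins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: active-site annotation, interaction networks and domain dynamics in pappalysins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pappadyn)
```

## Scope

`pappadyn` implements the structural-analysis workflow used to characterise
pappalysin metalloproteases (PAPP-A and PAPP-A2) and how a distal patient
mutation can silence their activity: residue-numbering conversion, metzincin
active-site annotation, typed residue-interaction networks with path
analysis, rigid-body superposition, and molecular-dynamics trajectory
statistics for open/closed domain motion. Everything upstream of these
analyses — cryo-EM reconstruction, structure prediction, running the MD
engine — is out of scope; the package consumes coordinates (PDB/mmCIF,
multi-model PDB for trajectories) and produces statistics and reports.

Because the deposited inputs are large external files, the package ships
generators for synthetic structures and trajectories whose ground truth is
known exactly. Every stage is validated against those generators and against
independent brute-force oracles.

## Residue numbering

Pappalysins are synthesised with a signal peptide and pro-peptide that are
absent from the circulating enzyme. Mature numbering therefore differs from
precursor (UniProt-style) numbering by a constant offset — 234 residues for
PAPP-A2 — so the patient mutation written A1033V in precursor coordinates is
A799V in the mature protein. `convert_numbering()` performs this shift in
either direction and refuses indices that fall inside the pro-peptide; the
round trip is the identity. The offset is configuration, not a constant:
other entities (PAPP-A itself, whose pro-domain length is not part of this
package's inputs) supply their own offset in the run configuration.

## Active-site annotation

Metzincins carry the zinc-binding signature `HEXXHXXGXXH`.
`scan_metzincin_motif()` reports all non-overlapping matches of
`H-[EQ]-x-x-H-x-x-G-x-x-H`, left to right. Glutamine is accepted at the
glutamate position because catalytically dead E-to-Q constructs are common
in structural work; such hits are flagged rather than rejected.

`validate_zinc_site()` turns a sequence hit into a geometric statement. It
selects the zinc nearest the centroid of the motif histidines' C-beta atoms,
lists all atoms within the coordination cutoff, and calls the site
*validated* only if each of the three motif histidines contributes a
side-chain nitrogen inside the cutoff. Defaults, chosen from coordination
chemistry rather than fitted to any structure:

* `coordination_cutoff = 2.8` Å. Zn–N(His) bonds are typically 2.0–2.2 Å;
  2.8 leaves slack for coordinate error without reaching the second shell.
* `water_cutoff = 2.8` Å for the zinc-bound catalytic water, and a 3.5 Å
  heavy-atom criterion for its hydrogen bond to the nearest tyrosine
  hydroxyl. Structures analysed here carry no hydrogens, so all hydrogen
  bonding in the package is heavy-atom N/O–N/O distance only, with no
  angular term.
* The water check degrades to "absent" when no water is deposited; absence
  is reported, not an error.

The Met-turn — the conserved methionine packed beneath the zinc — is named
in the literature by residue, not by a rule. `find_met_turn()` defines it
operationally: the methionine whose side-chain sulfur is nearest the zinc
among methionines within 100 residues downstream of the motif's third
histidine. The window excludes upstream methionines that could sit near the
site by fold accident.

## Residue-interaction networks

`build_graph()` assembles a typed, undirected residue graph from three
detectors, plus metal edges from coordinating residues to a `"zinc"`
pseudo-node:

| kind        | criterion                                   | default |
|-------------|---------------------------------------------|---------|
| hbond       | any N/O–N/O heavy-atom pair                 | 3.5 Å   |
| hydrophobic | apolar side-chain carbon pair               | 4.5 Å   |
| pipi        | aromatic ring centroid pair                 | 6.0 Å   |
| metal       | side-chain atom within coordination cutoff  | 2.8 Å   |

Conventions worth stating:

* Backbone–backbone contacts between sequence neighbours are excluded from
  hydrogen bonds, and sequence-adjacent pairs are excluded from hydrophobic
  edges entirely: both are covalent-geometry trivia that would otherwise
  connect every residue to its neighbours and trivialise path analysis.
  Hydrogen bonds from i to i+2 and beyond are kept.
* Apolar carbons are the side-chain carbons of Ala, Val, Leu, Ile, Pro,
  Phe, Met, Trp, Tyr plus the Lys CB–CD aliphatic stem.
* π-π uses ring centroids only (six-membered ring for Trp), with no
  plane-angle filter — parallel and T-shaped stacks both count — but the
  inter-plane angle is recorded per edge for inspection.
* Duplicate (pair, kind) detections merge keeping the shortest distance.
* Detectors run on one chain at a time. The question they serve — how a
  distal mutation site couples to the catalytic zinc — is intra-chain;
  waters and ions are excluded from the residue graph (the catalytic water
  is handled by the zinc-site validator instead).

`shortest_path()` returns the minimum-hop path; among equal-length paths it
picks the lexicographically smallest residue-index sequence, so reports are
deterministic. Disconnection is an explicit no-path result. On the synthetic
enzyme the planted five-link chain plus the metal edge — six hops from the
distal residue to the zinc — is recovered exactly, which is the package's
analogue of tracing a patient mutation's patch-by-patch connection to the
active site.

## Superposition and domain RMSD

`kabsch()` is the standard SVD solution restricted to proper rotations
(the reflection branch is sign-corrected), with explicit errors for fewer
than three pairs or collinear sets. It is tested against a rotation-grid +
simplex oracle and an established fitting routine.

Residue pairing between paralogs uses global alignment with an identity
substitution matrix and linear gap penalty 1 (`pair_by_alignment()`). For
domain-scale comparisons between ~46%-identical paralogs this is adequate
and, importantly, deterministic.

`domain_rmsd()` runs a single Kabsch pass over all paired C-alphas by
default. Interactive viewers' "align" commands iteratively discard badly
fitting pairs, and published RMSDs often reflect that; an optional
outlier-rejection mode (drop pairs deviating more than 2 SD above the mean,
at most 5 cycles) reproduces the behaviour, and both the all-pair and final
RMSD are always reported so neither convention hides the other. When an
"active site RMSD" is wanted, the operational selection is the eleven motif
residues plus the Met-turn residue (twelve C-alphas); published values of
that kind rarely enumerate their atoms, so comparisons should allow a few
tenths of an Ångström either way.

## Trajectory statistics

Trajectories are multi-model PDB files with a uniform frame spacing
(configuration; the synthetic generator uses 0.1 ns). The centre of mass of
a domain is the *unweighted mean of its C-alpha coordinates* — the
convention used for the M1 (610–927) / M2 (953–1160) / anchor-peptide
(120–143) analysis — and `com_distance_series()` measures the distance
between two such means per frame.

* **Exponential moving average** (`exponential_moving_average()`):
  α = 2/(span_in_frames + 1), first output equal to the first input. The
  span is display smoothing only; 10 ns is the default and it is a flag,
  since no analysis result depends on it.
* **Block averaging** (`block_average()`): the final 400 ns are split into
  eight contiguous 50-ns blocks; the mean and sample SD of the block means
  are reported. Blocking absorbs autocorrelation that would corrupt a naive
  SD; dropping the head removes equilibration transients. Partitions must
  divide exactly — a partial trailing block is rejected, never silently
  truncated.
* **Replicates** (`aggregate_replicates()`): block means are pooled across
  replicates and the pooled mean/SD reported. Whether an "overall" SD pools
  block means or averages per-replicate SDs is ambiguous in the wild, so
  the mean of per-replicate SDs is reported alongside.
* **KDE** (`kde_density()`): fixed-bandwidth Gaussian KDE, bandwidth 3 Å by
  default, evaluated exactly on the grid (no binned FFT approximation) and
  renormalised to integrate to 1 over the grid. "Covariance factor"
  phrasing in the field is estimator-dialect-dependent; here it means the
  kernel standard deviation, in Ångström.
* **Classification** (`classify_states()`): cutoff =
  `reference_distance + 0.5 × reference_sd`; frames above it are open. The
  intended use anchors the reference at the closed-state model distance
  (54 Å for M1–M2) with the distribution SD as the spread term, capturing
  a region extending beyond the closed reference.
* **RMSD vs start** (`rmsd_vs_start()`): per-frame Kabsch-superposed
  C-alpha RMSD against frame 1, so rigid tumbling does not register.

## The synthetic generators, and what passing tests mean

`make_enzyme()` builds a single-chain toy enzyme: a backbone trace with 6 Å
C-alpha spacing (outside every detector cutoff), the planted motif with His
side-chain nitrogens 2.1 Å from a zinc, optionally a catalytic water
(2.3 Å) hydrogen-bonded to a tyrosine hydroxyl (2.9 Å) and a Met-turn
sulfur (5 Å), and one spatially isolated interaction site per planted edge,
placed to satisfy exactly the intended detector at default cutoffs
(H-bond 2.9 Å, hydrophobic 4.0 Å, ring centroids 4.8 Å). Generation
self-verifies: it fails unless the detectors see precisely the planted
edges and nothing else, and unless no cross-residue pair clashes below
1.5 Å. These structures are *geometric, not stereochemical* — side chains
sit wherever the planted interaction requires. They validate distance-based
detection logic; they say nothing about detector behaviour on real packing
densities, where edge counts are far higher and cutoff choices matter more.

`make_dumbbell_trajectory()` emits two rigid C-alpha blobs whose separation
follows a hidden two-state Markov chain (defaults: closed 54 Å, open 63 Å,
jitter SD 2 Å, transition probabilities 0.04 closed→open and 0.01
open→closed, i.e. stationary open occupancy 0.8, 5000 frames at 0.1 ns)
plus an independent random rigid-body transform per frame, on by default so
that any statistic that is not rigid-motion invariant fails immediately.
The jitter is white; real inter-domain distances are strongly
autocorrelated, which is exactly why block averaging exists. Consequently
the *block SD* of synthetic runs is small (the blocks are nearly
independent), and tests assert sampling-theory bounds rather than any
particular SD magnitude.

One consequence of the prescribed smoothing is worth recording. With a 3 Å
kernel on states at 54 and 63 Å with 2 Å jitter, the effective component
width is √(3² + 2²) ≈ 3.6 Å, and at 80% open occupancy the mixture density
is *unimodal*: the closed state survives only as a shoulder (direct
evaluation of the mixture; the single mode sits near 62.9 Å). Mode-recovery
tests therefore run at balanced occupancy, where both modes exist (exact
mixture modes near 54.5 and 62.5 Å); occupancy-recovery tests run at the
80%-open default. For occupancy validation against the hidden chain the
classification cutoff is placed at the inter-mean midpoint — expressed in
the cutoff rule's own form as `reference_sd = open − closed`, giving
(54+63)/2 = 58.5 Å — because with known state means the midpoint is the
equal-variance optimal classifier and keeps per-frame misclassification
(~1% net) inside the binomial comparison band. That is a *validation*
convention for synthetic data; for real trajectories, where only the closed
reference is known, the closed-anchored rule above is the one to use.

## Numerical and design choices

* Residue numbering is 1-based; ranges inclusive on both ends.
* Altloc: highest occupancy wins, ties by altloc letter — deterministic.
* Insertion codes are rejected outright; the targets have none, and silent
  renumbering would corrupt the mature-numbering bookkeeping.
* mmCIF is read-only; the writer emits PDB (including MODEL/ENDMDL blocks).
* Kabsch refuses collinear sets rather than returning an arbitrary member
  of the degenerate solution family.
* KDE mode extraction reports the midpoint of flat-topped plateaus, which
  occur when a symmetric peak falls exactly between grid points.
* Problem sizes in the shipped tests — 1000 random 2000-mers for the motif
  oracle, 50 random structures for the detector oracles, 10000-frame
  trajectories for state recovery — were chosen as the smallest scales at
  which the stochastic bounds are comfortably sharp.

## Limitations

* No energetics anywhere: the network argues geometry and connectivity,
  not ΔΔG; the A799V mechanism is reproduced as a connectivity statement.
* Heavy-atom hydrogen bonds without angles over-count weak contacts; at
  3.5 Å this is the standard trade-off for hydrogen-free models.
* The detectors are per-chain; inter-chain interfaces need per-chain runs
  and manual merging.
* DCD/XTC trajectories must be converted to multi-model PDB upstream.
* The synthetic trajectory's white jitter under-represents autocorrelation;
  block-SD magnitudes from it do not emulate production-simulation values.
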