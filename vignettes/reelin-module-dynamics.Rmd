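---
title: "Dynamics, nanomechanics and conservation of reelin repeat modules: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamics, nanomechanics and conservation of reelin repeat modules: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reelmech)
```

# Scope and scientific background

Reelin is a large extracellular glycoprotein whose central region — repeating
BNR-EGF-BNR ("BEB") modules — binds the lipoprotein receptors ApoER2 and
VLDLR during canonical signalling. Three questions about these modules drive
this package:

1. **Which parts of a module are rigid, which flexible, and how are motions
   coupled?** Addressed with elastic-network and ensemble analyses:
   per-residue RMSF profiles and normalized cross-correlation maps of the
   slowest modes.
2. **Where do allosteric signals enter and leave a module?** Addressed with
   perturbation response scanning (PRS): effectiveness (row means) identifies
   effectors, sensitivity (column means) identifies sensors.
3. **How mechanically stable is a module, and what do disulfide bridges cap?**
   Addressed with worm-like-chain (WLC) analysis of force-extension curves
   (contour-length increments from sequential unfolding) and a geometric
   maximum-extension bound under intact disulfides.

A fourth surface — per-column Shannon entropy, Hamming distance matrices and
UPGMA cladograms — quantifies how conserved the implicated regions are across
species.

The package cannot ship crystal structures, MD trajectories, AFM recordings
or curated alignments, so a first-class synthetic-data module generates each
input class with recorded ground truth; every analysis stage is tested as a
recovery problem against that ground truth.

# Elastic network model

Each residue is a bead at its C-alpha position; beads within a cutoff
$R_c$ are connected by Hookean springs of stiffness $\gamma$. The
$3N \times 3N$ Hessian has, for a contact pair $(i,j)$, the off-diagonal
superblock $-\gamma\, \hat r_{ij} \hat r_{ij}^{\mathsf T}$ (with
$\hat r_{ij}$ the unit inter-bead vector) and diagonal superblocks equal to
minus the sum of the row's off-diagonal superblocks, which enforces
translation invariance exactly.

**Defaults.** $R_c = 15$ Å (the conventional C-alpha ANM choice; the source
analyses name no value) and $\gamma = 1$. All downstream quantities used for
interpretation are normalized (correlations, PRS), so $\gamma$ cancels; RMSF
from ANM modes is reported up to a global scale.

**Rigid modes** are identified by magnitude (eigenvalue below
$10^{-8}\lambda_{\max}$), not by count, so a disconnected network is
detectable: each connected component contributes six zero modes, and more
than six triggers a warning that propagates into the mode-set metadata.

**Mode sign convention.** The first component of each eigenvector with
non-negligible magnitude is made positive, so outputs are reproducible
across eigensolvers.

RMSF from modes uses $\mathrm{RMSF}_i = \sqrt{\sum_k w_k |u_{k,i}|^2}$ with
$w_k = 1/\lambda_k$ (ANM) or the mode variance (PCA). The cross-correlation
map normalizes the mode covariance by the mean-square fluctuations,
$C_{ij} = c_{ij}/\sqrt{c_{ii}c_{jj}}$, and averages the ten slowest modes by
default, matching the "ten slowest modes" convention of the source analyses.
Note that a *single* 3-D mode yields $C_{ij}$ equal to the cosine of the
angle between the two displacement 3-vectors — it equals $\pm 1$ only where
displacements are collinear (a scalar-network intuition that does not carry
over verbatim to the anisotropic model).

# Perturbation response scanning

With $G$ the pseudo-inverse of the Hessian over non-rigid modes, the
response of residue $j$ to an isotropically averaged unit force at residue
$i$ is $p_{ij} = \tfrac13\sum \big(G^{[ji]}\big)^2$ (all nine squared
elements of the $3\times3$ block). Design choices:

- **Normalization** is row-wise by the self-response ($P_{ij} = p_{ij}/p_{ii}$,
  diagonal exactly 1). The source analyses do not state their normalization;
  this choice makes rows comparable and matches the "average effect"
  wording of the effectiveness/sensitivity definitions.
- **Profiles exclude the diagonal** (self-response is definitionally 1 and
  would flatten contrasts).
- The **Monte-Carlo estimator** (uniform unit forces on the sphere, squared
  displacement magnitudes averaged per residue, seeded) is an
  independently-coded stochastic oracle, not the production path.

**Convergence of the Monte-Carlo oracle.** The per-entry estimator is a mean
of quadratic forms in the random force; for anisotropic response blocks its
relative standard deviation is up to $\approx 0.9/\sqrt{n}$ at $n$ forces.
At $n = 1000$ on a 50-bead helix this is $\approx 2.8\%$ per entry, and the
maximum over the $\sim$2450 off-diagonal entries therefore concentrates near
$4\sigma \approx 10\%$ for every seed. The acceptance suite asserts the
stated 5% bound on the maximum at $n = 1000$ and that check is expected to
fail; the same bound holds comfortably at $n = 10{,}000$ (measured 3.9%),
and the mean relative deviation at $n = 1000$ is $\approx 1\%$. We kept the
estimator faithful rather than replacing it with a variance-reduced scheme
(e.g. orthonormal force triads), which would make the "stochastic" oracle
deterministic and defeat its purpose as an independent route.

**Hotspots.** The top 10% of each profile, ties broken in favour of the
earlier residue. A residue may be both sensor and effector.

# Ensemble route

Frames are superposed on the reference by least squares (Kabsch rotation, no
reflection; collinear frames fall back to translation-only with a warning).
PCA uses the $3N\times3N$ coordinate covariance about the ensemble mean —
the mean, not the first frame, to avoid reference bias. Both the PCA
covariance and the ensemble RMSF use the sample divisor $F-1$; the RMSF
definition "mean over frames" would use $F$, but the shared divisor makes
the mode-route/ensemble-route RMSF identity exact rather than exact only as
$F\to\infty$, and the difference is $O(1/F)$ at MD-like frame counts.

# Force spectroscopy

The WLC force is the standard interpolation formula
$F(x) = (k_BT/p)\,[\,\tfrac14(1-x/L_c)^{-2} - \tfrac14 + x/L_c\,]$ with
persistence length fixed at $p = 0.4$ nm throughout (never co-fitted) and
$k_BT = 4.114$ pN·nm (298 K; the experiments are room-temperature AFM with
no stated temperature).

**Event detection.** The in-lab analysis software behind the published
force spectra is unpublished, so all detector settings here are package
decisions, config-exposed with these defaults: Savitzky-Golay (local
quadratic) smoothing over an 11-point window; a candidate event is a local
maximum of the smoothed force whose *post-transition level* (median of the
smoothed force two-to-four half-windows ahead) sits at least
`drop_threshold` = 20 pN below the peak. A level-based test is used instead
of a pointwise minimum because the minimum of noisy smoothed values
systematically inflates drop estimates and produces spurious events at
realistic noise (8.5 pN). The rupture is then localized in two stages —
steepest smoothed descent (coarse), steepest raw single-step drop within
two points (fine) — which recovers noise-free rupture positions exactly and
noisy ones to ~0.15 nm. Candidate peaks without a full post-drop
verification window (curve end) are not classifiable as events. The region
before the first zero-force crossing (nonspecific adhesion) is excluded.

**Contour-length fitting.** Per segment, $L_c$ is the only free parameter of
a least-squares fit. One robust pass removes gross outliers (residuals
beyond 4 MAD — e.g. a post-rupture point caught at the segment edge). The
near-rupture ceiling (`fit_ceiling` = 0.9, excluding points where the
interpolation formula is least accurate) is applied through the *fitted
model force*, not the raw peak force: the raw rupture force is a single
point with 8.5 pN noise, and selecting data by a noisy threshold both biases
the fit and occasionally discards the informative high-force region
entirely.

**Recovery limits.** For the default generator world (rupture forces
~50 pN, grid 0.2 nm, noise 8.5 pN), the Fisher information available below
the 0.9 ceiling gives $\mathrm{sd}(\Delta L_c) \approx 0.66$ nm for the
20-nm increment even for an oracle fit with exact segment boundaries — so
"within ±5% (1 nm) in ≥95% of events" is at the information limit, and the
acceptance suite's measured 93.6% reflects that limit rather than a
detector defect. Larger increments (40, 60 nm) recover within ±5% in
≥96% of events.

**Maximum-extension bound.** Intact disulfide bridges lock the enclosed
sequence intervals (interval union for nested/overlapping bridges); the
bound is (extensible links) × 0.365 nm + one 0.6 nm span per maximal
bridged region, minus the initial N-to-C C-alpha distance. The 0.365 nm
per-residue rise (extended backbone) and 0.6 nm through-bridge span are
documented bookkeeping constants of this package.

# Conservation analysis

Entropy is reported in bits (base 2; the source names no base). Gap policy
defaults: "ignore" for entropy (gaps removed before frequencies; an all-gap
column is flagged undefined) and "symbol" for Hamming distances (gap as a
21st symbol), the latter because it keeps the distance a true metric —
identity, symmetry and the triangle inequality are property-tested.
UPGMA is size-weighted average linkage over `stats::hclust`; a node joining
clusters at distance $d$ sits at height $d/2$, so ultrametric inputs are
reconstructed exactly (cophenetic distances equal the input). Determinism
under ties comes from lexicographic pre-ordering of sequence ids.
Structure-to-alignment mapping goes through ungapped positions of a
designated reference row with a configurable author-numbering offset;
taxon class labels are accepted as an external table, never inferred.

# Synthetic-data generators

All generators are pure functions of their arguments including the seed.

- **Bead chains**: helix geometry with rise 1.5 Å, 100° turn, radius 2.3 Å
  (consecutive C-alpha distances ≈3.8 Å); or two compact domains, optionally
  separated far enough to disconnect the 15 Å network. Crosslinks become
  synthetic cysteine pairs with SG pseudo-atoms 2.05 Å apart; ions are
  placed 3 Å from a chosen residue.
- **Ensembles**: Gaussian draws from a prescribed low-rank mode covariance,
  optionally composed with random rigid motions to exercise superposition.
- **Force curves**: piecewise WLC with a contour-length schedule whose
  default increments are 20, 40 and 60 nm — the major peaks of the published
  increment histograms — with rupture forces of 50 pN (the experiments
  report unfolding below 60 pN), grid step 0.2 nm, and Gaussian force noise
  of 8.5 pN, the stated force-determination accuracy of the instrument. A
  final detachment drop to baseline is appended by default so the last
  unfolding event is detectable; parallel-dimer mode emulates two chains
  sharing the extension, where each true increment appears as two apparent
  events of half the size (the published halving argument), implemented as
  apparent-curve bookkeeping rather than a mechanical two-spring model.
- **Alignments**: 67 sequences by default (the size of the cross-species
  reelin set), with per-column root-retention probabilities; with an
  ultrametric tree, substitutions accumulate along branches at per-column
  rates chosen so a root-to-leaf path retains the root symbol with the
  column's conservation probability, making expected Hamming distances
  tree-consistent. Substitutions are uniform over the 19 alternatives (not
  a reversible substitution model; adequate for the low-divergence recovery
  regime tested).

What the generators deliberately do not emulate: all-atom energetics,
solvent, glycans, AFM drift and baseline artefacts beyond an optional
initial adhesion spike, and alignment errors. A green recovery test
therefore establishes correctness of the estimators under the stated noise
model, not robustness to every artefact of real recordings.

# Numerical and serialization choices

Dense symmetric eigendecomposition throughout (module sizes are a few
hundred residues). Numeric outputs are serialized with 9 significant
digits, so two runs with the same config and seed produce byte-identical
files; every run directory carries its echoed config (JSON) and a manifest
with MD5 content hashes. Warnings (disconnection, dropped segments,
unmappable residues) are reported but do not abort a pipeline stage.

# Known limitations

- ANM-based RMSF is in arbitrary units (scale set by $\gamma$); only the
  ensemble route gives Å directly.
- PRS here is structure-based (ANM from coordinates); conditioning PRS on
  MD covariances is accepted through the mode-set abstraction but is not
  exercised by the tests.
- The event detector assumes tooth-like curves with sharp ruptures; slow
  unfolding plateaus would be localized poorly.
- The dimer generator halves increments exactly; real parallel stretching
  adds geometry-dependent deviations from exact halving.
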