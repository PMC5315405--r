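---
title: "Mechanical bridging scores from conformational ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanical bridging scores from conformational ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechbridge)
```

## The model

Proteins that switch between functional states — the motivating case being
class A G protein-coupled receptors (GPCRs) moving between inactive and
active conformations — do so through collective motions of quasi-rigid
groups of residues. `mechbridge` locates the residues that hold this
mechanical network together, starting from nothing more than a set of
conformers (crystal structures of the same receptor, or frames of a
molecular-dynamics trajectory) reduced to their C\(\alpha\) traces.

The pipeline has three stages.

**1. Distance-fluctuation statistics.** For residues \(a, b\) the
fluctuation is the population standard deviation of their
C\(\alpha\)–C\(\alpha\) distance over the \(M\) ensemble members,

\[ f_{a,b} = \sqrt{\langle d_{a,b}^2\rangle - \langle d_{a,b}\rangle^2}, \]

with \(\langle\cdot\rangle\) the equal-weight mean over members (divisor
\(M\), not \(M-1\): the definition is a moment of the observed set, not an
estimator of a hypothetical population). Pairwise distances are invariant
under rigid-body motion, so no superposition of the conformers is needed —
a deliberate strength of the approach when conformers differ by large
collective rearrangements that would make least-squares fitting ambiguous.

**2. The coupling network.** Fluctuations are mapped to coupling strengths
by a Gaussian weighting restricted to spatial neighbors:

\[ \sigma_{a,b} = \exp\left(-f_{a,b}^2 / 2\bar f^2\right), \qquad
   \sigma_{a,b} = 0 \text{ when } \langle d_{a,b}\rangle \ge 12\,\text{Å}. \]

The sensitivity \(\bar f\) is the mean of \(f_{a,b}\) over the unordered
non-self pairs inside the cutoff. Rigidly coupled neighbors get
\(\sigma \approx 1\); neighbors whose separation fluctuates strongly get
\(\sigma \approx 0\).

**3. The bridging score.** On the coupling matrix \(\sigma\) we form the
symmetric normalized Laplacian
\(L = I - D^{-1/2}\sigma D^{-1/2}\) with degree matrix
\(D_{aa} = \sum_c \sigma_{ac}\), whose eigenvalues
\(0 = \lambda_0 \le \dots \le \lambda_{N-1}\) describe how close the
network is to decomposing into independent pieces. The network *softness*
\(\Omega = \widetilde\sum_i 1/\lambda_i\) sums the inverse eigenvalues,
omitting one zero per connected component. Each residue \(k\) is then
scored by virtual deletion: all its couplings except the covalent-chain
(bonded) ones are removed, the spectrum is recomputed, and

\[ \Delta_k = \Omega_k - \Omega_0 . \]

A large \(\Delta_k\) means residue \(k\)'s non-bonded couplings are
load-bearing for the global connectivity of the mechanical network — the
signature of hinge and interface residues between quasi-rigid domains.
\(\Delta_k\) can be mildly negative: because \(L\) is degree-normalized,
removing couplings rebalances the remaining spectrum and occasionally
stiffens it, which is expected behavior rather than an error. Scores are
invariant under uniform rescaling \(\sigma \to c\sigma\) (the normalization
cancels \(c\)), which the test suite asserts to \(10^{-10}\).

## Assumptions

* Conformers are informative: with fewer than two members nothing
  fluctuates, and with members that sample only one state the profile
  reflects that state's vibrations, not the functional transition. The
  package supports error estimation from all active–inactive structure
  pairs (`pair_error_profile()`) precisely to quantify how much a
  two-structure profile can be trusted.
* Residue correspondence *within* a receptor comes from author numbering
  plus residue identity; correspondence *across* receptors comes only from
  a generic-numbering map (the `AxBB` helix-position scheme in which the
  most conserved residue of each helix is position 50). No sequence
  alignment is ever attempted, avoiding silent misalignment.
* Only C\(\alpha\) atoms are read; the fluctuation definition is a
  C\(\alpha\)-distance statistic, so side chains are irrelevant at parse
  time.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `cutoff` | 12 | Å | mean-distance radius of the local network; pairs at or beyond it are uncoupled (strict `<`) |
| `zero_tol` | 1e-9 | relative | eigenvalue \(\lambda\) counts as zero iff \(\lambda < \text{tol}\cdot\max(\lambda_{max}, 1)\) |
| `stride` | 1 | frames | thinning for multi-MODEL (trajectory) input |
| `mask_disconnecting` | FALSE | — | score network-splitting residues as `NA` instead of flag-and-compute |
| `hinge_width` (generator) | 1 | residues | residues per side of a body boundary labelled as hinge |

The 12 Å cutoff defines "local" physical coupling; the whitelist of
transmembrane generic positions (`default_whitelist()`, bands
1x36–1x56 … 7x45–7x55, deliberately skipping 7x44) restricts
cross-receptor averaging to positions in one-to-one correspondence. Both
ship as editable text files under `inst/extdata/`.

## Numerical choices

* **Two-pass variance.** The fluctuation is computed as the mean squared
  deviation from the mean distance, not as
  \(\langle d^2\rangle - \langle d\rangle^2\) literally: at
  \(d \sim 10^2\) Å the raw-moment form loses ten digits to cancellation,
  while the two-pass form leaves a rigid ensemble with
  \(f < 10^{-13}\) Å. The two expressions are mathematically identical.
* **Degenerate rigid limit.** When \(\bar f \le 10^{-10}\) Å (an ensemble
  rigid up to roundoff) the Gaussian weight is taken in its continuous
  limit \(\sigma = 1\) for every within-cutoff pair, rather than dividing
  two vanishing numbers.
* **Zero eigenvalues.** The count of eigenvalues below the relative
  tolerance must equal the number of connected components of the
  \(\sigma > 0\) graph; the suite checks this against an independent
  graph-traversal count on every tested network. Isolated nodes get their
  \(D^{-1/2}\) entry set to 0 and contribute one exact zero.
* **Disconnecting deletions.** If deleting a residue's couplings splits
  the network, the extra zeros are omitted from \(\Omega_k\) exactly as
  the tilde rule prescribes for \(\Omega_0\), and the residue is flagged.
  `mask_disconnecting = TRUE` reports `NA` there instead, for workflows
  that exclude disconnection-prone termini from the scored set. Both are
  exact behaviors; the default keeps \(N\) constant so all \(\Omega_k\)
  are comparable.
* **Ties.** Rankings (`top_k()`) break ties by residue/position order
  (stable sort). ROC curves group tied scores at one threshold, which
  makes the trapezoidal area equal the Mann–Whitney U estimate of the
  AUC; fully tied scores give exactly 0.5.
* **Eigensolver.** Full dense symmetric eigendecomposition (`eigen`,
  LAPACK). A profile costs \(N\) decompositions of an \(N \times N\)
  matrix; at the \(N \approx 150\text{–}300\) of a transmembrane bundle
  this is seconds on one core, so no iterative solver is warranted.

## The domain decomposition

`partition_domains()` embeds residues in the eigenvectors of the \(k\)
smallest Laplacian eigenvalues (rows renormalized to unit length) and
clusters with k-medoids: the deterministic PAM build-and-swap start plus
`restarts` seeded random medoid initializations, keeping the lowest
within-cluster cost. Medoids keep representative residues interpretable,
and the seeded restarts make runs bit-reproducible. Quality is the mean
silhouette width in the embedding. This is a deliberately simple spectral
decomposition in the spirit of quasi-rigid domain servers; it is *not* a
reimplementation of any published server pipeline (which may add
nearest-neighbor sparsification and bespoke quality scores), so claims
tied to such servers are validated qualitatively, not numerically.
`membership_fraction()` quantifies, across partitions at \(k = 2..k_{max}\),
how often a residue shares a domain with the majority of an anchor set —
the statistic behind "residue X is recruited into the neighboring helix's
dynamical domain in a fraction of subdivisions".

## What the synthetic generator does and does not emulate

`make_hinge_ensemble()` plants the ground truth the pipeline is supposed
to recover: consecutive rigid bodies of C\(\alpha\) beads (3.8 Å virtual
bonds, persistent self-avoiding random-walk geometry), joined at hinge
pivots, each member rotating downstream bodies about a fixed per-hinge
axis by an independent angle \(\le\) `max_angle`, plus isotropic Gaussian
noise added after the rigid motion (so within-body fluctuations sit at a
known \(\sqrt2\,\times\)`noise_sd` scale). Base geometries in which two
bodies come within coupling range *away* from the designated hinge are
rejected during generation — scanned across the hinge-angle range —
because a fixture with a second, unplanted interface would contradict its
own ground truth: the secondary contact residues would be genuine
mechanical bridges the labels know nothing about. Noisy members are
quantized to the 0.001 Å precision of the PDB format so that writing an
ensemble to PDB and re-ingesting it reproduces pipeline results exactly;
noiseless fixtures stay at full precision so that rigid ensembles have
identically zero fluctuation.

The reference fixture used throughout the tests is two 30-residue bodies,
20 members, 25° maximum hinge angle, and 0.2 Å noise — ensemble sizes and
noise chosen to resemble a well-covered receptor's crystal-structure
ensemble with sub-Å coordinate uncertainty. Under those conditions a
planted hinge residue reaches the top-5 bridging scores in \(\ge 90\%\) of
seeds and \(k=2\) clustering recovers the bodies at \(\ge 95\%\) label
agreement (both recomputed by `scripts/acceptance.R` on every run).

What the generator does **not** emulate: real secondary structure,
side-chain packing, membrane anisotropy, correlated (non-isotropic)
experimental noise, state-dependent loop remodelling, or the broad,
many-residue interfaces of real helix bundles. Passing the synthetic
recovery tests therefore shows the machinery is faithful to its
definitions and can recover planted mechanics from noisy ensembles; it
does not by itself certify performance on crystallographic datasets,
which is what the dataset-dependent checks (requiring the user to supply
annotated receptor structures) are for.

## Two-state fixtures and error bars

`make_state_ensemble()` reuses a hinge fixture's geometry, sampling
"inactive" members around hinge angle 0 and "active" members around
`state_angle_offset` (default 30°, comfortably above the 10° jitter used
in the paired-profile tests so that the states are genuinely distinct
conformations). `pair_error_profile()` then scores every active–inactive
pair as a two-member ensemble; the per-residue population standard
deviation across pair-profiles is the error bar, and the mean pair-profile
is returned for comparison with the full-ensemble profile via
`pearson_correlation()`. Partially active structures are excluded from
pairing by default — how such intermediates should enter two-state
pairings is genuinely ambiguous — and can be grouped with the active set
by flag.

Population (not sample) standard deviation is used for both kinds of
error bar — across receptors and across structure pairs — matching the
moment convention of the fluctuation statistic itself.

## Known limitations

* Cross-receptor aggregation requires an externally supplied
  generic-numbering map; the package does not assign generic numbers from
  sequence.
* The coordination-number baseline defines a contact as mean C\(\alpha\)
  distance under the same 12 Å cutoff as the network (self excluded,
  bonded included). Other contact definitions (all-atom, heavy-atom, 4.5 Å)
  would shift the counts; the cutoff is exposed for exactly that reason.
* Residues whose deletion disconnects the network sit at an inherent
  ambiguity of the softness difference; both supported conventions are
  documented above, and profiles record the flag either way.
* `mmCIF` input is out of scope; multi-MODEL PDB is the trajectory
  interchange format.
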