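---
title: "Deconvoluting (un)folding ensembles from S/WAXS data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvoluting (un)folding ensembles from S/WAXS data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A small protein near its thermal midpoint is not one structure but a
mixture of interconverting species — native, partially (un)folded
intermediates, and denatured chains. Solution X-ray scattering measures a
population-weighted average over that mixture: the observed intensity
$I_{\mathrm{exp}}(q)$ is (to a very good approximation) the weighted sum of
the single-conformer intensities. `saxsens` inverts this average: given a
pool of candidate conformers (for the original application, snapshots from
high-temperature MD simulations of the 61-residue Engrailed homeodomain, a
three-helix bundle), it selects a small weighted sub-ensemble whose average
scattering reproduces the measured S/WAXS curve, classifies the selected
conformers into native (N), intermediate (I) and unfolded (U) groups by
radius of gyration, and cross-validates the result against NMR observables
(residual dipolar couplings and NOE distance restraints) that were not
used in the fit.

## Scattering model

Single-conformer profiles come from the Debye equation,

$$I(q) = \sum_{i}\sum_{j} g_i(q)\, g_j(q)\,
  \frac{\sin(q d_{ij})}{q d_{ij}},$$

with $g_i(q) = f_i(q) - \rho_s V_i e^{-\pi V_i^{2/3} q^2}$ the
solvent-corrected effective form factor of the dummy-atom excluded-volume
convention: $f_i(q)$ is the sum-of-Gaussians vacuum form factor,
$\rho_s$ the bulk solvent electron density (default 0.340 e/Å³, i.e.
340 e/nm³), and $V_i$ the per-atom displaced volume. The hydration-shell
contrast is zero by default — for a protein this small with fast
side-chain dynamics the shell term is dropped. The Debye sum is exact at
these momentum transfers; it is the converged limit of spherical-harmonic
expansions, so no harmonic-order parameter exists. The double sum is
evaluated by pair-distance binning (bin width 0.02 Å, contributions taken
at per-bin mean distances), which agrees with the direct sum to better
than 0.1% RMS while reducing cost from $n_{\mathrm{pairs}} \times n_q$ to
$n_{\mathrm{bins}} \times n_q$; `method = "direct"` retains the exact sum
as an internal reference. When a structure carries no explicit hydrogens,
hydrogen electrons and volumes are folded into the bonded heavy atoms
(united-atom mode). Coordinates are always Å and $q$ always Å⁻¹
internally; the profile container rejects $q > 1$ to catch nm⁻¹ input.

Profiles are stored on the grid 0.01–0.7 Å⁻¹ (step 0.005; the measured
S/WAXS range), but fitting uses the window **0.07–0.7 Å⁻¹**: below
0.07 Å⁻¹ aggregation-sensitive particle scattering dominates and is
excluded, the 0.01–0.1 Å⁻¹ region remaining available for Guinier
analysis ($\ln I \approx \ln I_0 - q^2 R_g^2/3$, warning beyond
$q R_g > 1.3$).

## The fit target and the genetic algorithm

An ensemble is encoded as a fixed-length multiset of pool indices — a
*chromosome* of capacity $L = 20$. All members carry equal weight, but
repetition is allowed, so a conformer's weight is its multiplicity divided
by $L$ (granularity 0.05). The model curve is the multiplicity-weighted
mean of pool intensities *in intensity space*, and the target is the
squared difference in log intensity after a closed-form scale,

$$\chi^2 = \sum_q \left[\ln I_{\mathrm{exp}}(q) - \ln c -
  \ln \bar I_{\mathrm{model}}(q)\right]^2,\qquad
  \ln c = \overline{\ln I_{\mathrm{exp}} - \ln \bar I_{\mathrm{model}}},$$

making the fit independent of concentration and absolute calibration. The
residuals are unweighted by default (σ-weighting is available).

Each generation holds 20 elite chromosomes; crossover produces 20
children (uniform gene-wise mixing of a random elite pair) and mutation 40
children (each gene hit independently with probability $2/L$); survivors
are the best 20 *distinct* multisets among elites plus offspring
(μ+λ selection), so the best score never increases. The optimization is
repeated (default 50 repeats of 10000 iterations; the desk-scale profile
used throughout the tests is 2000 iterations × 10–50 repeats with plateau
early-stopping after 500 unimproved generations) and per-structure weights
are reported as the mean ± standard deviation of gene fractions across
repeats.

Two operator-internal choices deserve a note, because the naive versions
fail. First, a mutated gene draws its new value *from the chromosome's own
genes* with probability 0.5 (`mutation_reinforce`), and uniformly from the
pool otherwise. The repetition-as-weight encoding needs moves that
concentrate multiplicity — reaching a weight of 0.6 means accumulating 12
copies of one index, which uniform resets essentially never do. Second,
survivor selection suppresses duplicate multisets; without this the elite
set collapses to copies of one genotype and crossover stops contributing.
On a planted 3-component benchmark (0.60/0.30/0.10 mixture, 1%
multiplicative noise), the plain kernel left every repeat trapped above
the planted optimum and recovered weights of roughly 0.44/0.25/0.08 with
0.22 spurious weight; with reinforcement and deduplication all 20 repeats
reached the planted optimum exactly. `mutation_reinforce = 0` restores
the plain kernel.

Initialization draws every gene uniformly with replacement; repeat $r$
is seeded `seed + r`, so repeats are independent but the whole fit is a
pure function of its configuration.

## Pool preparation: clustering

Conformer pools are optionally reduced by GROMOS-style neighbor-count
(Daura) clustering on the pairwise RMSD matrix of main-chain + Cβ atoms
(glycine contributes no Cβ; matched-pair resolution skips it on both
sides). At each step the unassigned structure with the most unassigned
neighbors within the cutoff founds a cluster (ties to the smallest index);
cutoffs 1.0, 2.5 and 3.5 Å are the conventional series, and only clusters
with ≥ 10 members are retained for fitting. "Center of the cluster in RMSD
space" is operationalized as the medoid — the member minimizing summed
RMSD to all other members. Filtering marks clusters rather than deleting
them, so the partition stays exhaustive. Per-cutoff results are kept
separate; a config option selects which cutoff feeds the fit.

## Population analysis

Fitted weight is classified by radius of gyration with half-open
boundaries: native $R_g <$ 14.25 Å, intermediate 14.25–17.0 Å, unfolded
above. The defaults interpolate the observed group ranges for this fold
(native structures cluster at 13–14 Å, intermediates at roughly
14.5–17 Å); both are configurable since they are cut lines through ranges,
not sharp physical edges. Group standard deviations combine member sds in
quadrature — an upper-bound heuristic, since repeat-level correlations
between structures are discarded at aggregation.

## NMR cross-validation

**RDCs.** Amide H–N unit vectors (reconstructed in the C′–N–CA plane at
1.01 Å when no amide proton is present; residue 1 and prolines skipped)
predict couplings through a traceless symmetric alignment tensor,
$D = \sum_{kl} S_{kl} u_k u_l$, with the dipolar prefactor absorbed into
$S$. The 5 independent components are fitted by linear least squares
(SVD); windows with fewer than 5 usable pairs or rank-deficient designs
are rejected. Agreement is the Cornilescu Q factor
$Q = \mathrm{rms}(D_{\mathrm{calc}} - D_{\mathrm{obs}}) /
\mathrm{rms}(D_{\mathrm{obs}})$, with $Q < 0.25$ the customary
"high-resolution" cutoff. The sliding-window map refits the tensor on
every residue window of ≥ 7 residues (comfortably above the 5 unknowns)
and localizes agreement: a rigidly displaced helix leaves windows inside
the intact core self-consistent (the refitted tensor absorbs the rigid
rotation) while windows spanning the hinge cannot be fit by any single
tensor and show $Q > 0.25$. Per-window refitting is the default; a flag
reuses one global tensor instead. Steric alignment prediction from
structure is out of scope — best-fit tensors are the deterministic,
testable substitute.

**NOEs.** Ensemble distances are power-averaged,
$\bar d = \left(\tfrac1N \sum_i d_i^{-n}\right)^{-1/n}$ with $n = 3$,
dominated by the shortest member distances as NOE physics requires. Note
the $1/N$ normalization: without it $N$ identical distances $d$ would
average to $d\,N^{-1/n} \ne d$; the literal un-normalized form is
available behind `normalized = FALSE`. A restraint is violated when
$\bar d$ exceeds its upper bound (plus an optional tolerance); pseudo-atom
$r^{-6}$ summation is deliberately not implemented.

## The synthetic-data generator

The generator replaces everything the experimental study supplied, with
stored ground truth. Backbones (N, CA, C, O, Cβ, amide H) are built by
internal-coordinate extension with idealized geometry (N–CA 1.458, CA–C
1.525, C–N 1.329 Å, ω = 180°). The default chain is 61 residues with
helical segments 10–22, 28–38 and 42–55 — poly-alanine with glycine at
the turns. Helical residues take (φ, ψ) = (−57°, −47°); with probability
$u$ (the unfolding degree) a helical residue is resampled from a coil
model, a 3-basin mixture over β (−120°, 130°), PPII (−75°, 145°) and αR
(−60°, −45°) with weights 0.4/0.4/0.2 and 20° spread. Turn and terminal
residues always draw from the coil model. Chains with CA–CA clashes
(< 3.5 Å at sequence separation ≥ 4) are resampled. The
undocked-intermediate mode displaces the first helix (with its N-terminal
tail) rigidly by 10–20 Å with a random rotation, leaving the remaining
helix-turn-helix unit intact — the structural hypothesis for this fold's
folding intermediate. Native draws ($u = 0$, no undock) are additionally
accepted only below $R_g$ = 15.5 Å: random turn dihedrals do not encode
tertiary docking, so the acceptance bound is what confines "native"
sampling to the compact basin, emulating what native-temperature MD does
by energetics. The resulting bands (native ≈ 12.5–15.5 Å, unfolded
median ≈ 25 Å, spanning up to ≈ 35 Å) reproduce the compact-to-extended
spread the fit must resolve.

Synthetic experiments are mixtures of pool profiles with i.i.d.
multiplicative Gaussian noise (default 1% — a realistic relative error
for well-exposed solution scattering) and carry their generating weights;
synthetic RDC sets are generated from a known tensor plus coupling noise;
NOE-style restraints harvest all inter-residue heavy-atom pairs within
5 Å of a reference structure, with a 0.5 Å margin, subsampled to 735 (a
typical experimental set size for a protein of this length).

What the generator does *not* emulate: side chains beyond Cβ, force-field
energetics, sequence-specific structure, aggregation, and
instrument-specific error structure. Passing recovery tests therefore
demonstrates that the estimator inverts its own forward model under
realistic noise and pool degeneracy — not that any particular experimental
dataset is reproduced.

## Problem sizes and numerical choices

The test and acceptance runs use desk-scale sizes chosen to exercise every
claim: pools of 50 (three levels) and 200 (four levels) conformers,
50-repeat planted-structure recovery, 20-repeat mixture recovery at 1%
noise, a 4-condition population series (native fraction sweeping 0.9 →
0.2, mirroring a thermal unfolding series), 500 random matrices for the
clustering oracle, and a 2000-bead Monte-Carlo sphere for the Debye
oracle. Ties are broken deterministically everywhere (smallest index;
insertion order in survivor selection), all randomness flows from
user-supplied seeds, and reruns are bit-identical. Degenerate inputs
(empty selections, flat profiles, rank-deficient tensor fits,
all-zero couplings) raise typed errors rather than returning NaN.

## Known limitations

- Weight granularity is $1/L = 0.05$; populations below 5% are invisible
  by construction.
- With near-duplicate pool profiles the per-structure weights are only
  identifiable up to swaps among lookalikes; group-level populations are
  the robust quantity. This limit is pool-size dependent and measurable
  with the package's own recovery tests: for a 50-conformer pool a planted
  0.60/0.30/0.10 mixture at 1% noise is recovered essentially exactly
  (spurious weight ≈ 0.02), while for a 200-conformer pool — even planting
  the most profile-isolated member of each group — the fit landscape
  acquires many quasi-degenerate optima in which a handful of single-copy
  structures absorb noise, leaving the planted weights accurate to better
  than ±0.10 but ≈ 0.2 of spurious weight spread thinly across the pool.
  Exhaustive single-move hill climbing confirms these competitors are
  genuine local optima, not optimizer artifacts: at that dictionary size
  and noise level the data themselves no longer exclude the hangers-on.
  Practical advice: reduce pools by clustering before fitting, and read
  small (single-multiplicity, ≈ 0.05) weights as noise absorption, not
  populations.
- The group sd (quadrature) overstates uncertainty when structure weights
  co-vary across repeats.
- The excluded-volume correction uses fixed per-atom displaced volumes and
  no shell term; absolute intensities are arbitrary units throughout.
- The coil model is a crude dihedral mixture; it produces realistic sizes
  and scattering, not realistic Ramachandran statistics.
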