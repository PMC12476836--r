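---
title: "Screening for short linear motifs with AlphaFold interface confidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for short linear motifs with AlphaFold interface confidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slimpae)
```

## The problem

Short linear motifs (SLiMs) are 3–10 residue interaction modules embedded
in intrinsically disordered regions. They bind folded domains with modest
(typically micromolar) affinity, which makes them hard to detect both
experimentally and computationally. Structure predictors such as AlphaFold,
run on a binary complex of a bait domain and a candidate partner, leave a
usable fingerprint of SLiM binding in their confidence outputs: if the
network places a candidate peptide confidently against the bait, the
predicted aligned error (PAE) between the two chains collapses locally,
and the candidate's per-residue pLDDT rises where a disordered segment
becomes ordered on binding.

`slimpae` turns those fingerprints into a screening workflow: parse the
predictor's outputs, score each bait–candidate pair, localize the motif,
decide which calls survive a screen-size-aware threshold, and quantify how
well any of this works under the severe class imbalance of a real screen.

## Scores

For a two-chain prediction with an $L \times L$ PAE matrix $E$ (row $i$ =
residue the prediction is aligned on, column $j$ = scored residue) and
chain partition $A \cup B$:

* **Model Confidence**: $\mathrm{MC} = 0.2\,\mathrm{pTM} +
  0.8\,\mathrm{ipTM}$, the standard interface-weighted blend of the global
  TM-score estimates. Higher is better.
* **MiniPAE**: $\min \{ E_{ij} : i, j \text{ in different chains} \}$,
  over both off-diagonal blocks of the (asymmetric) matrix. One confident
  inter-chain contact suffices to pull it down; lower is better. The
  per-residue variant (`min_inter_pae_profile()`) assigns each candidate
  residue the minimum PAE over all its pairings with the bait, in either
  orientation; the profile minimum equals MiniPAE.
* **AlphaSLiM**: per residue, $N \cdot (\mathrm{pLDDT}_{bound} -
  \mathrm{pLDDT}_{unbound})$, where $N$ counts that residue's interface
  interactions, the bound track comes from the complex and the unbound
  track from a monomer prediction of the candidate alone. The product
  suppresses the classic pLDDT confounder — pre-structured regions that
  score high without touching the interface have $N = 0$. Values can be
  negative where binding lowers confidence. $N$ is evaluated per residue
  (the per-residue profile requires it). This package computes $N$ as the
  number of bait heavy atoms within a cutoff (default 4.0 Å) of any heavy
  atom of the residue — a deterministic geometric count; externally
  computed interaction-profiler counts can be substituted through
  `contact_counts_from()`.

Two normalizations are provided for cross-metric display. Higher-is-better
scores divide by the dataset maximum. Lower-is-better scores are inverted
and shifted: $(s^{-1} - \min s^{-1}) / \max s^{-1}$. Note the denominator
is the maximum inverse, not the inverse range, so the best original score
maps to $(\max s^{-1} - \min s^{-1})/\max s^{-1} < 1$ in general while the
worst always maps to 0. The form is applied exactly as defined — fidelity
to the published definition is preferred over rescaling it to span [0, 1].

## Motif localization

For MiniPAE calls, the anchor is the arg-min of the candidate chain's
min-inter-PAE profile (first occurrence on ties, for determinism), and the
motif is the maximal contiguous run containing the anchor whose profile
values lie within `delta` (default 3.0 Å) of the global minimum. The
delta-band rule is this package's design choice for the window rule: it
yields one contiguous motif per prediction, consistent with roughly one
passing motif per positive pair in screening practice. Secondary low-PAE
islands are available behind `all_islands = TRUE` but are not part of the
default contract, because MiniPAE is defined by a single global minimum.

For AlphaSLiM calls, motif regions are the maximal contiguous runs of
strictly positive values, each scored by its maximum.

## The adaptive threshold

The minimum of $n$ non-binder MiniPAE scores drifts downward as $n$ grows:
the more candidates you screen, the better the best-scoring non-binder
looks by chance. The calibration procedure quantifies this by repeated
subsampling (default 100 iterations per size) of a non-binder score pool,
recording the minimum per draw and averaging. Fitting

$$y = a\,x^{-b} + c$$

to the (size, average minimum) curve by nonlinear least squares
(Levenberg–Marquardt via `minpack.lm::nlsLM`; starts $a = \max y - \min y$,
$b = 0.3$, $c = \min y$, chosen so curves of this shape converge robustly)
gives a screen-size-dependent cutoff. With the published constants
$(a, b, c) = (30.29, 0.2803, -3.82)$, `adaptive_threshold(220)` ≈ 2.86 Å —
the cutoff for a 220-candidate screen. Comparison is inclusive
(score ≤ threshold passes). Subsampling is without replacement (a
subsample of a finite dataset is a subset); `replace = TRUE` is available.
Each subsample size draws from its own RNG stream derived from the master
seed, so adding sizes never perturbs existing points.

Degenerate inputs are handled explicitly: a flat minima curve
short-circuits to $a = 0$, $c = \bar y$ rather than entering the optimizer
with a singular gradient.

## Benchmark evaluation

Score orientation is an explicit flag everywhere (`lower_is_better`),
never inferred from the data — silent inference is the classic source of
inverted AUCs. ROC curves sweep all thresholds; the trapezoidal AUC gives
tied scores half credit and therefore equals the Mann–Whitney rank
formulation. Precision–recall curves use
$\mathrm{Precision} = TP/(TP+FP)$, $\mathrm{Recall} = TP/(TP+FN)$ with a
conventional (recall 0, precision 1) starting point and trapezoidal
integration over recall, in strictest-to-loosest threshold order so score
ties form zero-width segments.

`tpr_at_zero_fdr()` reports the percentage of binders scoring strictly
better than the best non-binder: FDR = 0 tolerates no false discovery, so
a non-binder tying the best binder already breaks it — hence strict
inequality.

`unbalanced_pr()` emulates screens where non-binders outnumber binders
$r$:1 by drawing $r \cdot n_{pos}$ negatives per iteration (without
replacement), averaging AUCs over iterations and averaging curves on a
fixed 101-point recall grid (per-draw PR points don't align, so each
iteration's precision is interpolated onto the grid; duplicate recalls
collapse to their best precision first). On separated synthetic pools the
mean PR-AUC declines strictly across ratios 1:1 → 1:5 → 1:25, the
qualitative signature of precision collapse under imbalance.

`build_shuffled_negatives()` constructs presumed non-binders by re-pairing
motif proteins with other partners, excluding (i) pairs present in the
positive set, (ii) pairs where the motif matches any motif regex
associated with the new partner (unanchored matching, as ELM patterns are
used), and (iii) pairs whose combined length reaches 1000 residues.

## What the synthetic fixtures emulate — and what they don't

`fixture_spec()` defaults define the package's study conditions, chosen
once: a 100-residue bait against a 60-residue disordered candidate with an
8-residue motif; stripe PAE 2 Å against a 25 Å background (screen-scale
thresholds sit near 3 Å, so planted binders pass and non-binders fail by a
wide margin); PAE noise 0.5 Å, clipped to AlphaFold's practical output
range [0.2, 31.75]; candidate pLDDT 45 (disordered) gaining 25 on the
motif when bound; pTM 0.5, ipTM 0.6. Score pools default to 26 binders and
1100 non-binders — the scale of a structure-independent benchmark with a
large shuffled-negative excess. The CA-only fixture structures place motif
residues 3 Å from a bait atom so the same bundle exercises both the PAE
path and the geometric contact counter.

These fixtures are statistical stand-ins, not physical models: real PAE
matrices have long-range covariance, rank-dependent model quality, and
partial-occupancy interfaces that the generator does not attempt. Passing
tests therefore demonstrate that the *machinery* is correct (parsers,
scores, localization, calibration, evaluation — each checked against
brute-force oracles), not that AlphaFold itself detects any particular
motif. Benchmarks against real predictions require the deposited archives
(hundreds of GB) and are out of scope here.

Problem sizes used in the test suite — oracle checks on matrices up to
L = 200, 100-draw property loops, a 220-record synthetic screen with
50-residue complexes, 20-replicate noisy refits — were picked as the
smallest sizes at which each property is meaningfully exercised.

## Numerical and interface choices

* Coordinates are 1-based inclusive within a chain everywhere a user sees
  them; the concatenated residue axis is 0-offset internally.
* The PAE matrix is kept asymmetric as emitted; MiniPAE and the profiles
  minimize over both orientations, so symmetrizing would change nothing
  and discard information.
* AlphaFold2 score JSON carries no chain boundaries, so the reader demands
  explicit chain lengths or a structure file rather than guessing.
* Multi-model predictions default to the top-ranked model (the community
  default; which model the original analysis scored is not stated);
  rank is parsed from ColabFold file names.
* AlphaFold3 token-level PAE reduces to residue level by the minimum over
  a residue pair's token pairs — conservative toward detecting contacts,
  and the identity for standard one-token-per-residue proteins. Server
  full-data JSON lacks an atom→residue map; the reader accepts an
  `atom_res_ids` array when present and otherwise requires one atom per
  token.
* All stochastic operations take a single integer seed and are
  bit-reproducible; derived per-stream seeds stay within 32-bit range.

## Known limitations

* The contact count $N$ is a heavy-atom distance proxy, not a typed
  interaction profile (no hydrogen bonds vs salt bridges vs hydrophobic
  classification); substitute external counts where that matters.
* MinD, average-model, interface area and solvation energy are ingested as
  precomputed columns only and never recomputed.
* The PR-AUC of a worse-than-random classifier can fall below the
  prevalence floor suggested by the full-recall endpoint; trapezoidal
  integration of the standard sweep makes no guarantee there.
* Motif window extraction uses the delta-band rule described above; other
  window rules (fixed width, PAE-gradient) are deliberate non-goals.
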