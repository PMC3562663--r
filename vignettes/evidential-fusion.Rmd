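---
title: "Evidential fusion of transmembrane topology predictors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidential fusion of transmembrane topology predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topper)
```

## The model

Topology prediction of α-helical membrane proteins assigns each residue one
of three classes — `i` (intracellular), `M` (membrane-spanning), `o`
(extracellular) — and summarizes the sequence as an ordered list of
transmembrane helices plus the membrane side of the N-terminus. `topper`
does not predict from sequence itself; it fuses the label tracks of several
existing predictors into a consensus, treating each predictor's output as a
piece of evidence whose reliability is known from its confusion matrix.

The fusion lives in Dempster–Shafer theory on the frame Ω = {i, M, o}.
A predictor φ with confusion matrix counts $n_{pq}$ (rows = truth, columns
= prediction) has overall recognition rate $Rc_φ$, the trace over the grand
total. When φ emits class $p$ at a residue, that observation contributes the
two-focal mass function

$$m_p^φ(\{p\}) = Rc_φ, \qquad m_p^φ(Ω \setminus \{p\}) = 1 - Rc_φ.$$

Two modelling choices here deserve emphasis, because both are deliberate:

* **The residual mass goes to the complementary doubleton**, not to the
  whole frame. "The predictor is wrong" is treated as positive evidence for
  the *other two* classes jointly. This follows the classical abstract-level
  ensemble construction of Xu, Krzyżak and Suen and has real consequences
  for the combination (see *Behaviour at low recognition rates* below). The
  variant that assigns $1 - Rc$ to Ω (pure ignorance) is not implemented.
* **A single global recognition rate** conditions all three per-class BPAs.
  Per-class recognition and substitution rates would use more of the
  confusion matrix; the simpler global-rate form is the method implemented
  here, and the full matrix still drives evaluation.

Per residue, the $N$ matched BPAs are folded with Dempster's rule of
combination; the fused mass is turned into probabilities with the pignistic
transformation $BetP(x) = \sum_{A \ni x} m(A)/|A|$ and the residue takes
the class with maximal $BetP$. Residues are combined independently: no
positional smoothing or HMM grammar is applied at fusion time, so any
run-length structure must come from the inputs, and the only grammatical
cleanup is the minimum-helix-length rule at decoding time.

## Parameters that matter

| Parameter | Default | Where | Meaning |
|---|---|---|---|
| `min_tm_length` | 5 residues | `decode_labels()` | shortest M-run reported as a helix; shorter runs are absorbed into the flanking loop. The threshold is inclusive (a run of exactly 5 survives). |
| `min_overlap` | 9 residues | `match_regions()`, `same_topology()` | minimum intersection for a predicted and an observed helix to count as the same segment; 9 is the standard segment-overlap convention. The boundary is inclusive: overlap 9 matches, 8 does not. |
| `pseudocount` | 0 | `smooth_matrix()` | optional Laplace smoothing of a confusion matrix. Off by default; only needed when a recognition rate of exactly 0 or 1 would produce categorical BPAs, which can make Dempster's rule inapplicable (total conflict). |
| `n_folds` | 10 | `crossvalidate()` | cross-validation folds; confusion matrices and profiles are estimated on training folds only. |
| `seed` | — | everywhere random | all randomness (fold shuffle, synthetic data) is seeded; identical seeds give identical results. |

Sub-threshold M-runs are *relabelled* to the preceding loop class (the
following one at the N-terminus) rather than deleted, so decoding never
changes the residue count. The N-terminal side is read from the first non-M
label; for a sequence that begins inside the membrane this is the nearest
always-defined reading of "the location of the first residue", and an all-M
track is flagged as having undefined orientation rather than guessed.

## Numerical choices

* Masses must sum to 1 within `1e-9` at construction; after every pairwise
  combination the result is renormalized to absorb floating-point drift.
  Renormalizing per step or once at the end is mathematically equivalent;
  per-step is used so intermediate objects are always valid mass functions.
* Total conflict ($K \ge 1 - 10^{-12}$) raises an error naming the
  offending combination step rather than returning NaN, matching the rule's
  applicability condition $K < 1$.
* Subsets of Ω are represented as 3-bit masks with a fixed canonical class
  order i < M < o, used for every matrix layout, serialization and
  tie-break, so proposition equality is exact and outputs are
  bit-reproducible.
* The argmax over $BetP$ treats values within `1e-9` of the maximum as
  tied and takes the canonically first class. Exactly symmetric label
  patterns (e.g. two equally reliable predictors saying `i` and `o`) tie in
  real arithmetic but differ in the last bits depending on summation order;
  the tolerance makes the decision independent of that order.
* Report percentages are rounded half away from zero (`round_half_up()`),
  2 decimals for percentages and 4 for F scores, matching how such tables
  are conventionally printed. The bundled ensemble confusion matrix yields
  a residue accuracy of 79.99% at that precision (its trace is 23918 of
  29902 residues); summaries that quote 80% are rounding once more.

## Behaviour at low recognition rates

Because the complement of the emitted class receives $1 - Rc$ as a
*doubleton*, repeated agreeing evidence only reinforces the emitted class
when $Rc > 1/2$. Below that, the complement masses dominate the orthogonal
sum: with two predictors of $Rc = 0.4$ both saying `o`, the combination
gives $m(\{o\}) = 0.16/0.52$ and $m(\{i,M\}) = 0.36/0.52$, so
$BetP(i) = BetP(M) = 0.346 > BetP(o) = 0.308$ and the fusion decides
*against* the unanimous label. This is a genuine property of the
construction, pinned by a test, not a defect: a predictor wrong more often
than right really is evidence for the other classes. Unanimity and
plurality dominance (the majority label wins under equal rates) hold for
$Rc > 1/2$ and are verified exhaustively, against an independent
brute-force implementation of the rule, for all label patterns of up to
five predictors. Practical predictors sit far inside the safe region
(recognition rates near 0.78).

## The synthetic benchmark

`sim_spec()` defaults describe the scale of the classical 125-protein
MPtopo-derived evaluation set: 125 proteins, 1–14 helices of 15–30
residues, loops of 1–60 residues, N-terminal side uniform, and five
conditionally independent simulated predictors, each corrupting the true
labels with a row-stochastic confusion matrix with 0.78 on the diagonal and
the remainder split evenly. The 0.78 matches the residue accuracy of real
individual predictors on that benchmark; the uniform error split is a
simplification (real predictors confuse `i`/`o` with `M` asymmetrically).
Amino-acid content is uniform random, since nothing downstream reads the
sequence itself. Structural error modes — whole-helix deletion and
boundary jitter — are available but off by default.

What the generator deliberately does **not** emulate: real predictors emit
grammatically coherent tracks (long clean runs), whereas independent
per-residue noise fragments helices. Fused tracks built from such noise
therefore score high at residue level but poorly at segment and topology
level, because spurious short M-runs survive the length filter. Passing
tests on synthetic data consequently demonstrate the fusion's
residue-level gain and the harness's correctness, not segment-level
performance on real predictor outputs, which depends on their run-length
structure.

Tests and the cross-validation property checks run the generator at its
defaults (125 proteins, five predictors, ~50,000 residues), which keeps the
whole suite under a minute while leaving Monte-Carlo standard errors small
(about 0.2 percentage points on an accuracy), with smaller configurations
for unit-level checks.

## Evaluation conventions

Residue metrics come from the pooled confusion matrix: per-class recall
$n_{pp}/\text{row}_p$, precision $n_{pp}/\text{col}_p$, $F = 2PR/(P+R)$,
accuracy = trace/total. A zero row or column makes the affected metric
undefined (`NA`), which is reported distinctly from 0. At segment level the
overall prediction power is the geometric mean $Q = \sqrt{M \cdot C}$, the
Tusnády–Simon definition; being a geometric mean it always lies between
$M$ and $C$. Segment matching is greedy, in order from the N-terminus and
one-to-one — each helix is consumed by at most one match — which prevents
one long predicted helix spanning two observed ones from counting twice.
Topology correctness takes the strict reading: equal helix counts, every
in-order pair overlapping by at least `min_overlap`, and the same
N-terminal side.

Cross-validation shuffles protein identifiers with a seeded
Mersenne–Twister permutation and cuts the shuffled order into contiguous
blocks whose sizes differ by at most one (125 proteins in 10 folds gives
sizes 12 and 13). Profiles are re-estimated per fold on training data only;
all reported metrics pool the held-out predictions.

## Known limitations

* Only the three-class frame is supported publicly; the internals would
  generalize, but nothing beyond {i, M, o} is tested.
* No alternative combination rules (Yager, PCR5), no reliability
  discounting, and no measurement-level (posterior probability) inputs:
  predictors contribute hard labels only, and abstentions are rejected
  rather than skipped.
* No re-entrant loops, signal peptides, or helix-length upper bounds in the
  topology grammar.
* Native output formats of the individual predictors are not parsed;
  label tracks must be supplied in the package's FASTA-like format, with
  dialect mapping (e.g. `H` → `M`) available at read time.
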