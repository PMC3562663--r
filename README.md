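# topper

Evidential fusion of transmembrane protein topology predictors.

## The problem

Predicting the topology of an α-helical membrane protein — the number and
position of its membrane-spanning helices and whether the N-terminus sits
inside or outside the cell — is a per-residue three-class labelling problem
over the alphabet {i, M, o} (intracellular, transmembrane, extracellular).
Many individual predictors exist (OCTOPUS, PRO-TMHMM, PRODIV-TMHMM,
SCAMPI-msa, SCAMPI-seq, ...), each built on different principles, and no
single one dominates. `topper` implements the TOPPER method: an ensemble
that fuses the label tracks of several predictors with Dempster–Shafer
evidential reasoning, for bioinformaticians who have per-residue predictions
from two or more tools and want a consensus topology that is more accurate
than any input.

## The method

Work on the frame of discernment Ω = {i, M, o}. For a predictor φ with
confusion matrix C<sub>φ</sub> = (n<sub>pq</sub>) (rows = true class,
columns = predicted class), the overall recognition rate is

    Rc_φ = Σ_p n_pp / Σ_pq n_pq .

When φ labels a residue as class p, that output is represented as the basic
probability assignment (BPA)

    m_p^φ({p}) = Rc_φ ,   m_p^φ(Ω \ {p}) = 1 − Rc_φ ,

i.e. the residual mass goes to the *complementary pair of classes*, not to
full ignorance. At each residue the N predictors' matched BPAs are combined
with Dempster's rule of combination (the orthogonal sum)

    m(A) = (1 / (1 − K)) Σ_{B ∩ C = A} m1(B) m2(C) ,   K = Σ_{B ∩ C = ∅} m1(B) m2(C) ,

and the fused mass function is converted to a probability distribution with
the pignistic transformation BetP(x) = Σ_{A ∋ x} m(A)/|A|; the residue's
class is the argmax (ties broken i < M < o). The fused label track is then
decoded into a topology: maximal M-runs of at least `min_tm_length`
(default 5) residues become helices, and the N-terminal side is read off
the first non-M label.

Evaluation follows the field's conventions: per-class recall/precision/F
and accuracy at residue level; at segment level the Tusnády–Simon counts
N<sub>obs</sub>/N<sub>prd</sub>/N<sub>cor</sub> (a predicted and an
observed helix match when they overlap by ≥ 9 residues) with
M = N<sub>cor</sub>/N<sub>obs</sub>, C = N<sub>cor</sub>/N<sub>prd</sub>
and the overall prediction power Q = √(M·C); and at topology level the
fraction of proteins with every helix matched and the orientation correct.
A seeded tenfold cross-validation harness estimates each predictor's
confusion matrix on training folds only.

## Worked example

Fuse three predictors at one residue, using their published benchmark
confusion matrices (bundled under `inst/extdata/mptopo125/`):

```r
library(topper)

cm <- mptopo_confusion("OCTOPUS")
recognition_rate(cm)
#> [1] 0.7869373

profiles <- lapply(mptopo_confusion()[c("OCTOPUS", "PRO", "PRODIV")],
                   build_profile)
res <- combine_residue(c(OCTOPUS = "M", PRO = "M", PRODIV = "i"), profiles)
res$mass
#> Mass function on {i, M, o}
#>   m({i}) = 0.198389
#>   m({M}) = 0.744455
#>   m({o}) = 0.0571562
round(res$betp, 4)
#>      i      M      o
#> 0.1984 0.7445 0.0572
res$decided
#> [1] "M"
```

Two predictors saying "M" (each with ~78–79% recognition rate) outweigh one
saying "i": the fused pignistic probability of M is 0.74 and the residue is
labelled M. Scoring the bundled ensemble confusion matrix and segment
counts reproduces the benchmark tables:

```r
as.data.frame(residue_metrics(mptopo_confusion("TOPPER")))
#>   class recall_pct precision_pct f_score accuracy_pct
#> 1     i      85.96         73.77  0.7940        79.99
#> 2     M      74.82         91.81  0.8245        79.99
#> 3     o      81.85         72.98  0.7716        79.99

region_score_from_counts(515, 507, 500)
#> TM segments: N_obs=515 N_prd=507 N_cor=500 | M=97.09% C=98.62% Q=97.85%
```

Whole-dataset workflows (`combine_dataset()`, `crossvalidate()`,
`simulate_dataset()`) and the file formats (FASTA, FASTA-like label files,
confusion TSVs, YAML run configs) are described in the vignette
`vignettes/evidential-fusion.Rmd`. A thin command-line front end with
`combine` / `eval` / `crossval` / `simulate` subcommands is installed at
`inst/exec/topper`.

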