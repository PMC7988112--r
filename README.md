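# adsig

Cross-species discovery and validation of an atopic-dermatitis (AD) gene
signature, and severity scoring of skin transcriptomes.

AD is diagnosed clinically and scored with instruments such as SCORAD; this
package implements a molecular alternative: differentially expressed genes
(DEGs) that respond with the *same direction* in two mouse models (hapten
contact hypersensitivity, CHS, and brush skin-scratching stimulation, SSS)
and in human lesional-skin cohorts are assembled into a ±1-weighted gene
signature, and each sample is scored with the **AD index**

    AD = Σᵢ wᵢ (eᵢ − μᵢ) / τᵢ

where `wᵢ ∈ {+1, −1}` is the gene's direction weight, `eᵢ` its expression in
the sample, and `μᵢ`, `τᵢ` the mean and standard deviation of the gene across
the scored cohort. A higher index means more severe disease. The package
covers the whole chain:

* **Mouse DEGs** — TPM expression filter, TMM normalization, two-group
  negative-binomial exact test with common dispersion (conditional-likelihood
  estimate), BH FDR; calls at FDR < 5%, FC > 2.
* **Human DEGs** — probe-to-gene collapse by geometric mean, SAM permutation
  statistic with Tusher's automatic fudge constant, Storey q-values; calls at
  FDR < 10%, FC > 1.5.
* **Pathway concordance** — FAIME rank-weighted single-sample pathway scores,
  per-pathway Student t contrasts, Pearson correlation of t-statistics
  between species.
* **Signature & severity** — direction-concordant ortholog intersection
  (`build_signature`), AD index (`ad_index`), SCORAD correlation, paired
  treatment-response tests. The published 36-gene signature ships as a
  fixture (`ad36_signature()`).
* **Resampling benchmarks** — severity correlations of random size-matched
  signatures drawn from direction-weighted gene pools (Human, Human+CHS,
  Human+SSS), add-one tail p-values, pool-vs-pool t-tests.
* **Synthetic studies** — a ground-truthed generator (`sim_config`,
  `simulate_*`) emulating the full study design, so every stage is testable
  without external downloads.

## Worked example

The numbered scripts under `analysis/` run the whole study on a simulated
dataset (seed 17). From the repository root:

```sh
Rscript analysis/01_simulate.R          # generate the synthetic study
Rscript analysis/02_mouse_deg.R         # NB exact tests, CHS vs VT and SSS vs NT
Rscript analysis/03_human_deg.R         # SAM tests on both human cohorts
Rscript analysis/04_pathways.R          # FAIME scores + cross-species concordance
Rscript analysis/05_signature_adindex.R # signature, AD index, severity tests
Rscript analysis/06_resampling.R        # random-signature benchmarks
```

which prints, among other things:

```
CHS vs VT: 62 up, 57 down
SSS vs NT: 66 up, 54 down
DE cohort: 49 up, 48 down
SE cohort: 48 up, 47 down
pathway t-statistic concordance CHS vs DE: r = 0.849 (p = 1.9e-15, n = 52)
signature: 31 genes (18 up, 13 down); recovers 31/36 planted, 0 sign errors
AD index vs SCORAD, lesional: r = 0.837 (p = 5e-16, n = 57)
AD index vs SCORAD, nonlesional: r = 0.481 (p = 0.00015, n = 57)
paired baseline -> week2, lesional: mean change -27.07 (p = 1.9e-09, 19 pairs)
Human      pool ( 95 genes): mean resampled r = 0.848, signature r = 0.837, right-tail p = 0.774
```

Reading this: the two mouse contrasts and two human cohorts yield ~50-60
DEGs per direction (the planted truth is 30 shared per direction plus
model-specific and human-only genes); pathway dysregulation is strongly
concordant across species; the assembled signature recovers 31 of the 36
planted genes with no direction errors; and its AD index tracks SCORAD at
r ≈ 0.84 in lesional skin, dropping sharply after two weeks of simulated
treatment. Intermediate tables land under `results/`.

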