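# relapseEvo

Tools for analyzing how acute myeloid leukemia (AML) evolves between
diagnosis and relapse, aimed at researchers with paired diagnosis/relapse
samples — mutation panels, bulk or single-cell ATAC-seq, and mitochondrial
single-cell ATAC-seq.

A striking feature of relapsed AML is that many patients relapse with the
*same* driver mutations they had at diagnosis. `relapseEvo` implements the
analysis stack for studying that observation end to end:

* **Mutation dynamics.** Each mutation with paired variant allele
  frequencies (VAFs) is classified as *gained* (VAF < 0.05 at diagnosis and
  > 0.1 at relapse), *lost* (VAF > 0.1 then < 0.05), or *stable*
  (everything else; strict inequalities). Patients are binned as
  `stable` / `gain` / `loss` / `gain_and_loss`, per-gene dynamics are
  summarized as ternary fractions, and relapse-free survival of stable vs
  unstable patients is compared by Kaplan–Meier, log-rank, and a Cox model
  `h(t) = h0(t) exp(β·stable + β_a·age + β_s·sex)`.
* **Chromatin accessibility.** Fixed-width (500 bp) consensus peaks by
  score-ranked iterative overlap removal with a ≥2-sample support rule;
  Tn5 cut-site counting (0-based, half-open); CPM normalization;
  per-patient diagnosis–relapse similarity; gene accessibility scores from
  a 5-kb tile matrix with weights `1 + e⁻¹` inside [TSS−5 kb, TTS],
  `e^(−d/5000) + e⁻¹` in flanks, and 0 beyond 20 kb or past an adjacent
  gene; paired negative-binomial differential testing (`~ patient +
  condition`, Wald, BH); a relapse signature (top/bottom 500 genes by
  relapse-vs-diagnosis log2FC in mutationally stable patients) and a
  per-cell relapse score (Σ top − Σ bottom of depth-normalized scores);
  locus-level enrichment scans and compartment-overlap fractions.
* **Reference projection.** Latent semantic indexing (TF-IDF + truncated
  SVD) of a labeled healthy hematopoietic reference, exact projection of
  query cells (including 250 multinomial pseudo-single cells per bulk
  sample), and closest-normal classification by the 10 nearest reference
  cells in LSI space.
* **Mitochondrial clones.** Per-cell heteroplasmy (`alt/(alt+ref)`, pooled
  strands, missing where coverage is zero); strict variant filtering
  (> 3 cells, strand correlation > 0.65, mean coverage > 10); clone
  clustering on binarized heteroplasmy via a shared-nearest-neighbor
  Jaccard graph and Louvain modularity; clone trees from shared/exclusive
  variants with explicit conflict reporting; per-timepoint clone
  frequencies (fishplot-ready); clone pseudobulks; and a convergent-
  evolution test comparing inter-clone Pearson correlations at diagnosis
  vs relapse with an unpaired Student's t-test.

Every pipeline input can be generated synthetically (`gen_*` functions)
with planted, recorded ground truth, so the full stack is testable with no
external data.

## Worked example

```r
library(relapseEvo)

co <- gen_vaf_cohort(n_patients = 200, planted_hr = 1.5, seed = 7)
classes <- classify_mutations(co$mutations)
table(classes)
#> classes
#> gained   lost stable
#>    132    113    535

bins <- bin_patients(co$mutations)
table(bins$clonal_bin)
#>          gain gain_and_loss          loss        stable
#>            42            48            32            78

clinical <- merge(co$clinical, bins, by = "patient_id")
rfs <- relapse_free_survival(clinical)
sprintf("HR (stable vs unstable) = %.2f [%.2f, %.2f], Wald p = %.3g",
        rfs$hr, rfs$hr_ci[1], rfs$hr_ci[2], rfs$wald_p)
#> "HR (stable vs unstable) = 1.28 [0.93, 1.78], Wald p = 0.132"

head(ternary_coordinates(co$mutations, min_events = 20), 3)
#>   gene n_events frac_gained  frac_lost frac_stable
#> 9 NRAS       63   0.1746032 0.17460317   0.6507937
#> 7 KRAS       61   0.1311475 0.09836066   0.7704918
#> 5 IDH1       57   0.1228070 0.15789474   0.7192982
```

The mutation classes agree with the generator's planted truth by
construction (the cohort is built so that classifying its VAF pairs
reproduces the planted labels), the binned patients split roughly
40/20/15/25 across the four categories, and the fitted hazard ratio
estimates the planted 1.5 — at n = 200 the 95% CI [0.93, 1.78] covers it.
Larger cohorts tighten the interval (see the acceptance script below).

Two orchestration functions run the headline analyses end to end on
synthetic cohorts and persist every intermediate plus a checksum manifest:

```r
report <- run_stable_relapse_analysis(pipeline_config("stable", seed = 1L))
report$recovery$bin_recovery        # 1 — planted bins recovered exactly
mito <- run_mitoclone_analysis(pipeline_config("mito", seed = 1L))
mito$convergence$converged          # TRUE — planted convergence declared
```

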