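# brainprotmap

Region-resolved proteomic mapping of the human brain: a tested, reusable R
pipeline for calling region-specific proteins from a label-free (DIA)
protein-abundance matrix measured across 13 gross neuroanatomical divisions
(FL, TL, PL, OL, CB, BS, THA/HT, OC, CC, VT, HIP, AN, OB/OT) in multiple
donors, together with the surrounding analyses such a map needs: abundance
quartile structure, region-correlation modules, and concordance with
transcriptome-level (nTPM) specificity.

It is aimed at proteomics analysts who have a quantified protein × sample
intensity matrix (e.g. Spectronaut output) and a donor/region design, and
who want the downstream statistics reproducible and testable. Raw
mass-spectrometry processing is out of scope; the pipeline starts at the
quantified matrix.

## The model

Intensities are normalized per sample to parts per million
(v → v / Σv × 10⁶, observed values only) and log2 transformed. For protein
*g* in sample *i* of donor *j* and region *r* the working model is

    y_gij = μ_g + β_gr + d_gj + ε_gij ,   d_gj ~ N(0, σ_d²),  ε ~ N(0, σ_e²)

so samples from the same donor share an intra-donor correlation
ρ = σ_d² / (σ_d² + σ_e²). A single consensus ρ is pooled across proteins
(method-of-moments per-protein estimates, Fisher-z trimmed mean, with a
finite-block correction for the donor signal absorbed by region means) and
enters a one-way region ANOVA through compound-symmetry whitening of each
donor block, giving an exact F test at the estimated ρ. P values are
Benjamini–Hochberg adjusted across testable proteins.

A protein is **region-specific** when its top region has the highest mean
normalized intensity, that mean is at least 1.5× the pooled mean of the
remaining regions (linear fold change on geometric means), and the
BH-adjusted p value is below 0.01.

Around the core call: per-region cumulative-abundance quartiles (Q1 = the
most abundant proteins making up the first 25% of a region's signal),
region–region Pearson correlation with complete-linkage clustering and a
comparison against the expected cortical / limbic / midline groupings, and
an HPA-style RNA rule (nTPM < 1 → missing; specific iff max log2 nTPM ≥ 2×
the mean log2 nTPM of the rest) for proteome–transcriptome concordance
classes (both / protein-only / RNA-only / unmapped / background).

A synthetic-data generator emulates the study design (13 regions × 8 donors
≈ 99 samples, ~4,660 proteins, ~16% missingness as MCAR plus
intensity-dependent left-censoring, donor random effects, per-sample depth
factors, planted markers) and provides planted ground truth, so every stage
is covered by parameter-recovery tests.

## Worked example

```r
library(brainprotmap)

p  <- generator_params(n_proteins = 1000, markers_per_region = 10, seed = 42)
ds <- generate_proteome_dataset(p)
lg <- log2_transform(to_ppm(ds$matrix))
print(ds$matrix)
#> abundance_matrix [raw]: 1000 proteins x 99 samples, 16.6% missing

tab  <- call_region_specific(lg, ds$annotations)
cons <- attr(tab, "consensus")
cat("consensus intra-donor correlation:", round(cons$rho_consensus, 3), "\n")
#> consensus intra-donor correlation: 0.248
cat("region-specific calls:", sum(tab$call), "of", nrow(tab), "\n")
#> region-specific calls: 126 of 1000

rec <- recovery_metrics(tab, ds$truth)
cat("sensitivity:", round(rec$sensitivity, 3),
    " FDR:", round(rec$empirical_fdr, 3),
    " region accuracy:", round(rec$region_accuracy, 3), "\n")
#> sensitivity: 0.969  FDR: 0  region accuracy: 1

head(top_k_per_region(tab, k = 3), 6)
#>   region rank protein_id fc_vs_rest        p_adj
#> 1     FL    1     P00839   4.836932 8.968326e-11
#> 2     FL    2     P00146   4.519526 9.241015e-05
#> 3     FL    3     P00601   4.327359 4.261330e-08
#> 4     TL    1     P00882   4.602609 2.524473e-10
#> 5     TL    2     P00532   4.137001 1.039074e-09
#> 6     TL    3     P00283   3.955969 6.137155e-07
```

The generator planted 130 markers (10 per region) with a log2 effect of 2;
the calling rule recovers 97% of them with no false calls, each assigned to
its true region, and the consensus correlation estimate (0.248) is close to
the simulated σ_d²/(σ_d²+σ_e²) = 0.265. The signature table ranks called
proteins per region by fold change versus the pooled remaining regions.

A command-line wrapper with subcommands (`simulate`, `normalize`, `qc`,
`specificity`, `quartiles`, `modules`, `crossomics`, `evaluate`, `run-all`)
is installed at `inst/cli/brainprot.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "brainprot.R", package = "brainprotmap"))')" \
  simulate --out sim --seed 7 --n-proteins 200
```

## Layout

- `R/` — implementation (I/O, generator, preprocessing, specificity
  statistics, quartiles, region modules, cross-omics, evaluation, pipeline)
- `tests/testthat/` — unit, property and end-to-end tests with independent
  brute-force oracles
- `vignettes/region-specific-proteomics.Rmd` — methods notes: model,
  estimators, parameter defaults, numerical conventions, limitations
- `inst/extdata/` — small plain-text fixtures
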