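# pathomics

Deep pathomics for post-transplant hepatocellular carcinoma (HCC):
tile-level histology classification, per-tissue survival risk networks, a
weighted **deep pathomics score (DPS)** for recurrence risk stratification,
and quantitative spatial analysis of multiplex-immunofluorescence (mIF)
immune-cell tables.

The package is aimed at computational pathology researchers who want a
tested, fully reproducible implementation of this pipeline that runs end to
end on synthetic data — every input (labelled tissue tiles, survival
cohorts with known hazard structure, spatial point patterns) is generated
by code, so every stage is exercisable and verifiable without access to
clinical slides.

## What it implements

**Tissue classification.** Whole-slide images are masked with Otsu's
threshold (tissue = dark side of the maximal between-class-variance split),
tiled into patches, and classified into six categories — tumor region (TR),
normal liver tissue (NLT), portal area (PA), fibrous tissue (FT),
hemorrhagic/necrotic tissue (HNT) and immune cells (IC) — by a residual
convolutional network with squeeze-and-excitation (SE) channel attention.
Evaluation follows the usual one-vs-rest ROC/AUC (micro and macro) and
row-normalized confusion matrix.

**Per-tissue prognostic networks.** For each tissue category a scoring
network maps that category's tiles to a patient-level risk score
(mean-pooled over tiles), trained with the joint loss

```
L = -log PL(Cox) + lambda * BCE(sigmoid(score), recurrence)
```

where `-log PL` is the negative Cox partial log-likelihood of the scores
against time-to-recurrence (TTR) with Breslow (default) or Efron ties, and
BCE is binary cross-entropy against the recurrence label. Training stops
when the validation loss starts to rise.

**DPS.** The six per-tissue scores s_t enter a multivariate Cox model
(excluding NLT); the DPS is the fitted linear predictor
`sum_t beta_t * s_t`, min-max normalized on the training cohort. The
immune score (IS) is the normalized immune-cell score alone. The optimal
cutoff is the maximally selected log-rank threshold; patients with
`DPS > cutoff` form the high-risk group (a boundary value is low risk).

**Survival statistics.** Harrell's C-index with bootstrap CI,
time-dependent ROC (cumulative cases / dynamic controls), calibration
curves against Kaplan–Meier observed risk, KM and two-group log-rank, and
univariate/multivariate Cox fits for covariate tables.

**mIF spatial analysis.** Phenotypes are called from boolean marker
colocalization (Treg CD3+CD4+FOXP3+, NK CD3−CD16+CD56+, NKT CD3+CD56+,
CD8+T CD3+CD8+, CD4+T CD3+CD4+, memory T CD45RO+, B CD20+, cDC CD11c+,
monocyte CD11b+, macrophage CD68+, CD11b+CD68+, neutrophil MPO+; most
specific rule first). A tumor-border annotation partitions cells into tumor
nest (TN), invasive margin (IM; within 500 µm of the border on either
side) and normal tissue (NLT). The package computes per-region densities,
Dunn's multiple comparisons, nearest-neighbor proximity between phenotypes
(distances over 300 µm eliminated) and inter-phenotype density
correlations.

## Worked example

```r
library(pathomics)

# --- six-class classifier on synthetic tiles ---------------------------
tiles <- list(); labels <- character(); pids <- character(); k <- 0
for (cls in TISSUE_CLASSES) for (i in 1:50) {
  k <- k + 1
  tiles[[k]] <- generate_tissue_tile(cls, 64, k)
  labels[k] <- cls; pids[k] <- paste0("pt", (i - 1) %/% 5)
}
clf <- train_classifier(tiles, labels, pids,
                        classifier_config(epochs = 5, seed = 1))
# evaluate on fresh tiles -> macro AUC: 1  accuracy: 1

# --- cohort, per-tissue risk networks, DPS -----------------------------
co <- generate_cohort(cohort_spec(n_patients = 120,
                                  tiles_per_patient_per_class = 2,
                                  true_beta = c(IC = 1.2), seed = 2))
profiles <- data.frame(patient_id = co$patients$patient_id)
for (cl in TISSUE_CLASSES)
  profiles[[cl]] <- train_tissue_risk(co, cl, seed = 3)$scores$score
w <- fit_dps_weights(profiles, co$patients$ttr_months,
                     co$patients$recurrence_event)
round(data.frame(beta = w$beta, HR = w$hr, z = w$z), 2)
#>      beta    HR     z
#> TR  -0.51  0.60 -0.63
#> PA   0.58  1.78  0.67
#> FT   0.25  1.29  0.28
#> HNT  1.65  5.19  1.31
#> IC   3.43 30.95  5.33
```

The immune-cell category — the only tissue with a nonzero simulated
effect — dominates the multivariate model, mirroring how the method singles
out the prognostic tissue. Stratifying at the maximally selected cutoff:

```r
d <- compute_dps(profiles, w)
ct <- optimal_cutoff(d$dps, co$patients$ttr_months,
                     co$patients$recurrence_event)
grp <- assign_groups(d$dps, as.numeric(ct))
#> cutoff: 0.7092  high-risk: 27  log-rank chi2: 40.3  p: 2.22e-10
```

and the spatial immune contrast between outcome groups:

```r
f_none  <- generate_mif_field(mif_spec("none_recurrence",  seed = 4))
f_early <- generate_mif_field(mif_spec("early_recurrence", seed = 4))
nearest_neighbor(f_none$cells,  "CD8T", "NK")$mean_distance   # 89.1 um
nearest_neighbor(f_early$cells, "CD8T", "NK")$mean_distance   # 155.9 um
```

CD8+T cells sit closer to NK cells in the non-recurrence group — the
generator's emulation of the cooperative innate/adaptive pattern the
pipeline is designed to quantify.

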