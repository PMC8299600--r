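# neodl

Survival stratification of IDH wild-type glioblastoma from the intrinsic
sequence features of predicted neoantigens.

Missense mutational load, neoantigen count and the differential
agretopicity index (DAI = IC50_WT − IC50_MT) fail to separate long- from
short-surviving IDH wild-type GBM patients. `neodl` implements the
alternative: encode each patient's called neoantigens (mutant 9-mers with
IC50 < 500 nM whose wild-type counterpart has IC50 > 500 nM) by
position-, dipeptide-, tripeptide- and whole-sequence-level intrinsic
features over ten published amino-acid descriptor scales (Cruciani,
Kidera, Z-scales, FASGAI, T-scales, VHSE, ProtFP, ST-scales, BLOSUM
indices, MS-WHIM; 66 components), screen the per-patient feature averages
by univariate Cox regression (valid features: Wald p ≤ 0.05), derive
survival labels by hierarchical k-means on the z-scored valid features,
and train the neoDL stratifier — an LSTM(128) → LSTM(32) → dense(8,
sigmoid) → sigmoid network reading the ordered valid-feature vector as a
scalar sequence, trained with MSE loss and Adam — validated by repeated
stratified 60/40 split trials with log-rank evaluation:

```
h_i(t) = h_0(t) · exp(β · x_i)        (per-feature screening)
valid  = { features with Wald p ≤ 0.05 }
labels = hkmeans(z-scored valid features, k = 2), long-term = 1
p̂_i    = σ(W_o · σ(W_d · LSTM₂(LSTM₁(z_i)) + b_d) + b_o)
```

The package also ships the three baseline stratifiers (mean-split missense
load, neoantigen count, mean DAI with Kaplan–Meier/log-rank evaluation)
and a synthetic-cohort generator with planted positional residue
enrichments and proportional-hazards survival, so the full pipeline is
testable without patient data.

## Worked example

```r
library(neodl)

# a synthetic cohort: 200 patients, planted hazard ratio 3 between a
# long-term group (R/S-enriched at peptide positions 3-4) and a short-term
# group (L/G-enriched)
sim <- generate_cohort(sim_config(seed = 101))

cfg <- neodl_config(hidden = c(32, 16, 8), epochs = 25,
                    max_features = 48, n_trials = 5, seed = 303)
fit <- neodl(sim$cohort, cfg)
print(fit)
#> neoDL fit on 'synthetic': 200 patients with called neoantigens
#>   valid features: 48 / 4348 screened (p <= 0.05)
#>   clusters: long-term (n = 99), short-term (n = 101)
#>   split trials: 5 / 5 significant (log-rank p < 0.05)
#>   full-cohort AUC vs cluster labels: 1; log-rank p = 3.64e-10
```

The fitted object reports that 48 intrinsic features (capped smallest-p)
passed Cox screening, that hierarchical k-means split the cohort into a
99-patient long-term and a 101-patient short-term group, that the LSTM
stratifier separated the survival curves of every held-out test split
(log-rank p < 0.05 in 5/5 trials), and that the selected model reproduces
the cluster labels on the full cohort with AUC 1.0. Against the planted
truth:

```r
truth <- sim$truth[match(fit$patients, sim$truth$patient_id), ]
adjusted_rand_index(fit$cluster, truth$group)
#> [1] 0.8272319

baseline_stratifiers(sim$cohort)        # load / count / DAI baselines
predict(fit, generate_cohort(sim_config(seed = 202))$cohort)$logrank$p
                                        # external-cohort validation
```

A command-line interface wraps the same functions
(`inst/cli/neodl simulate|featurize|screen|label|train|validate|apply|baseline`).

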