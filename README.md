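# fatnet

Dual-stream attention networks for next-day health forecasting from
wearable and music-listening data.

## What problem this solves, and for whom

Digital-health studies of older adults increasingly collect two kinds of
data at once: minute-resolution wearable streams (heart rate, music
on/off state) and once-daily summaries (PANAS positive affect, sleep
efficiency, resting RMSSD/SDNN, resting heart rate, WASO, total sleep
time, listening duration, mean tempo, valence/arousal, demographics).
This package is for methodologists and digital-health researchers who
want to (a) build and validate a day-level composite wellbeing index
from such data, and (b) test whether minute-level music–physiology
interactions carry next-day predictive signal that daily summaries
miss — using an attention-based fusion model whose decisions can be
inspected through its attention maps.

The regression target is the composite **Health Score**. With
cohort-standardized components
`Z_M` (PANAS positive affect), `Z_S` (sleep efficiency) and `Z_H`
(resting RMSSD):

    Health_i = (Z_M,i + Z_S,i + Z_H,i) / 3          (equal weight)
    Health_i = PC1(Z_M,i, Z_S,i, Z_H,i)             (PCA variant)

validated by Cronbach's α (> 0.7), PC1 variance share (≥ 60%),
distributional checks, responsiveness of day-to-day changes against a
1–10 global rating (Spearman ρ > 0.6), and an optional binary
"Good/Not-Good" label at the 75th percentile.

The forecasting model, the **Fusion-Attentive Temporal Network
(FAT-Net)**, encodes the T×2 minute matrix with a Conv1D stack
(32→64→128, kernels 5/3/3, LayerNorm+GELU+dropout), a BiLSTM (h/2 per
direction) and multi-head self-attention pooled by the time mean;
encodes the daily summary vector with a three-layer MLP
(d_ds→64→128→h, BatchNorm+ReLU+dropout); fuses the streams with
bidirectional cross-modal attention over per-feature summary tokens;
and predicts the next-day score with a 2h→256→1 head. Training
minimizes `MSE + λ‖θ‖²` (λ = 1e-5) with AdamW (lr 3e-4, batch 16),
early-stopping on validation MAE. The backend is hand-written,
gradient-checked RcppArmadillo — no deep-learning framework required.

Everything is testable offline: `generate_cohort()` simulates a seeded
cohort with a latent daily-wellness AR(1) factor driving correlated
PANAS/sleep/HRV components and a planted minute-level music→heart-rate
interaction (a rise-then-dip response during some high-tempo listening
sessions) that feeds next-day wellness but is invisible to daily
summaries. Baselines (Random Forest, XGBoost, LSTM, TCN), a
participant-grouped split, a four-technique training-set augmentation
suite (jitter, time warp, magnitude scale, SMOTE; exactly fourfold) and
a multi-run comparison harness complete the pipeline.

## Worked example

```r
library(fatnet)

cfg    <- cohort_config(n_participants = 20, days_mean = 20, T = 240, seed = 42)
cohort <- generate_cohort(cfg)
qc     <- impute_and_exclude(cohort)
daily  <- engineer_features(qc$cohort$daily)

hs <- health_score(daily, rating = cohort$truth$rating)
hs
#> Composite Health Score (equal-weight target)
#>   days scored: 316
#>   Cronbach's alpha: 0.734
#>   PC1 variance fraction: 65.3%
#>   skewness -0.01, excess kurtosis -0.18, Shapiro p 0.428
#>   responsiveness (Spearman rho of daily changes): 0.750
#>   'Good' days (above 75th percentile): 79
```

The reliability numbers say the three components cohere well enough to
average (α above the 0.7 adequacy bar; two thirds of their variance on
one axis), the score is close to normal, and its day-to-day changes
track the self-reported rating changes (ρ = 0.75 here).

```r
pairs  <- build_pairs(daily, qc$cohort$minutes, hs$score)
splits <- split_data(pairs, seed = 42)        # grouped by participant
fit <- fat_net(splits$train, splits$val,
               fatnet_config(T = 240, h = 32, max_epochs = 12,
                             patience = 12, seed = 42))
fit
#> Dual-stream fusion (FAT-Net) regressor (423841 parameters)
#>   T = 240 min x 2 channels, 19 summary features, h = 32
#>   trained 12 epochs; best epoch 9, validation MAE 0.4830

round(compute_metrics(predict(fit, splits$test), splits$test$y), 3)
#>      rmse       mae        r2 pearson_r
#>     0.734     0.605     0.177     0.458

att <- extract_attention(fit, splits$test, sample = 1)
dim(att$cross)       # summary-feature queries x minutes
#> [1]  19 240
```

(A 20-participant, 12-epoch demonstration; the evaluation protocol in
`hypothesis_benchmark()` uses 60 participants and longer training.)
The test RMSE/MAE are in units of the standardized composite score;
`att$cross` is the cross-modal attention map (one row per summary
feature, one column per minute) and `att$self` the per-head T×T
self-attention — the interpretability layer of the model.

A command-line front-end over the same functions lives in
`inst/cli/fatnet.R`
(`generate / preprocess / score / augment / train / evaluate /
attn-export`).

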