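# grfcast

Predicting continuous **normal ground reaction force (GRF) waveforms** during
uphill, level, and downhill running from a single biaxial accelerometer taped
over the sacrum.

## The problem

The normal GRF — the force component perpendicular to the running surface,
in bodyweights (BW) — underlies most kinetic variables that researchers,
clinicians and coaches monitor: vertical impulse, loading rate, contact
time, active peak, step frequency. It is only measurable directly on
force-instrumented treadmills. `grfcast` predicts it frame by frame at
500 Hz from wearable-sensor data across speeds of 2.5–4.17 m/s and slopes of
−10° to +10°, with no stance-phase segmentation or temporal normalization —
so time-dependent variables survive the prediction.

## The model

A sequence-to-sequence recurrent network maps a 13-feature frame sequence to
one GRF value per frame:

* per-frame features: mean, population SD, and range of vertical and
  anteroposterior sacral acceleration in a 6-frame (12 ms) window spanning
  frames *t*−3…*t*+2, plus body mass, height, speed, slope, and the trial's
  rearfoot/midfoot/forefoot strike percentages (all min–max scaled with
  training-set parameters);
* a bidirectional LSTM (tanh) whose forward and time-reversed output
  sequences are averaged elementwise, then a per-frame MLP (128/384/320,
  rectifier) with a linear scalar head;
* dropout 20% (input) and 40% (post-LSTM); Adam (lr 0.001, batch 32,
  MSE loss), ≤ 1,000 epochs with early stopping (min Δ 0.001, patience 30).

The BiLSTM, backpropagation through time, dropout and Adam are implemented
in RcppArmadillo (no deep-learning framework is required) and validated by
finite-difference gradient checks. Stance kinetics use a 5% BW threshold;
predictions must satisfy two biomechanical boundaries (contact count equal
to measured; step frequency ≤ 4 Hz) before entering any aggregate.

Validation machinery: leave-one-subject-out (LOSO) cross-validation with
per-fold, leak-free feature normalization; single-subject slope-split
validation (train 0°/±10°, test ±5°); foot-strike feature ablation; and
permutation feature importance (PFI). Because the study data behind the
method are not publicly deposited, the package ships a physically
consistent synthetic gait simulator (half-sine active GRF + slope- and
foot-strike-dependent impact transient, acceleration derived from
whole-body dynamics `a = g(F − cos θ)`) with analytic ground truth for
every step — see the methods vignette (`vignettes/grfcast-methods.Rmd`).

## Worked example

```r
library(grfcast)

# simulate a small cohort: 8 subjects x 15 conditions (5 slopes x 3 speeds),
# 2.5 s trials at 2,000 Hz
cohort <- simulate_cohort(sim_config(n_subjects = 8, duration = 2.5,
                                     sf_conditions = character(0), seed = 1301))

# leave-one-subject-out cross-validation with a desk-scale network
# (dropout and learning rate scaled with the network; see the vignette)
cfg <- model_config(lstm_units = 32, mlp_sizes = c(32, 32, 32),
                    batch_size = 8, max_epochs = 40, patience = 10,
                    min_delta = 1e-5, learning_rate = 0.002,
                    input_dropout = 0.1, post_lstm_dropout = 0.1, seed = 17)
report <- loso(cohort, cfg)   # 8 folds, ~10 min on one CPU
print(report)
#> <eval_report> 120 trials, 8/8 subjects with metrics | RMSE 0.122 +/- 0.025 BW | rRMSE 5.25 +/- 1.14 % | failure rate 3.3%
#>   MAPE [%]: step_freq 0.00, contact_time 2.64, impulse 7.50, active_peak 8.40, loading_rate 12.11
```

Per-trial waveform errors (`report$per_trial`), per-subject means
(`report$per_subject`), discrete-variable MAPE and the boundary failure rate
are all in the report. RMSE is in bodyweights over the full waveform; rRMSE
normalizes by the average range of the compared waveforms; the failure rate
counts trials whose predicted waveform violated a biomechanical boundary
(those are excluded from the error aggregates).

Discrete kinetics from any waveform:

```r
trial <- preprocess_trial(cohort[[1]])      # 500 Hz, filtered, clipped
kin <- discrete_variables(trial$grf, segment_stance(trial$grf))
print(kin)
#> <step_kinetics> 7 contacts, step frequency 2.80 Hz
#>   start end contact_time active_peak   impulse loading_rate
#> 1     2 117          230    2.271080 0.3509938     46.91200
#> 2   180 296          232    2.271000 0.3510031     46.17166
#> ...
```

Contact time is in ms, impulse in BW·s, loading rate in BW/s (secant slope
over the first 25 ms of stance), active peak in BW (maximum within 40–60%
of stance).

## Command line

```sh
grfcast simulate --config sim.yaml --out data/
grfcast train    --data data/ --out model.json --config cfg.yaml
grfcast predict  --model model.json --trial data/trial_001.csv --out pred.csv
grfcast kinetics --grf pred.csv --out vars.csv
grfcast loso     --data data/ --out report/
```

The launcher lives at `exec/grfcast` inside the installed package; all
commands accept `--config` (YAML, defaults match the published pipeline
values) and `--seed`.

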