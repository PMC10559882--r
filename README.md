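# btsforecast

Hybrid ensemble forecasting of DNA-derived biological time sequences.

## What problem this solves

A DNA sequence S₁S₂…Sₙ over {A, C, G, T} can be mapped to numbers and
treated as a time series — a *biological time sequence* (BTS). Forecasting
such series (predicting the next windowed value from its history) is a
building block for sequence analysis, splicing and computational-biology
pipelines. This package is for bioinformaticians and time-series
researchers who want a complete, reproducible implementation of a hybrid
statistical/neural ensemble forecaster for BTS data, testable end to end on
synthetic sequences without any downloads.

## The method

1. **Encode** the sequence three ways: spectral (a→1, g→2, c→3, t→4), chaos
   game representation (iterative midpoint map into the square [−1, 1]²,
   collapsed to one channel by the Euclidean norm), and Z-curve
   (signed root of X_i + Y_i + Z_i, the purine/amino/weak disparities of
   each prefix).
2. **Window** each encoding into data points (mean of 60 consecutive bases;
   floor(L/60) points), **split** chronologically 70/15/15
   (validation = test = floor(0.15·n)), and carry each encoding under
   min–max and variance normalization fitted on training data only — six
   channels per sequence.
3. **Single-sequence branch**: ARFIMA(p, d, q) per channel — fractional
   differencing (1 − B)^d by its binomial expansion, then conditional
   sum-of-squares ARMA estimation — with (p, d, q) found by particle swarm
   optimization against rolling one-step validation MAPE; per-channel
   forecasts are calibrated to the target scale and fused with
   inverse-validation-MAPE weights into O_AR.
4. **Multi-sequence branch**: a 1-D cross-channel convolution feeding an
   LSTM and a linear head, trained by SGD with backpropagation through
   time written out in R; hyperparameters (epochs N_tr, hidden units N_hn,
   learning rate D_tr) are PSO-searched, and the network is warm-started by
   self-adaptive per-channel pre-training (SaPt) with early stopping.
5. **Fuse**: C_t = w·O_AR + (1 − w)·O_LSTM with w learned on the validation
   segment by exact grid search.
6. **Evaluate**: MAPE, squared correlation R², accuracy growth rate P_MAPE,
   Diebold–Mariano test (critical values 1.645/1.96/2.58 at 90/95/99%), and
   residual-variance stability VAR, against naive-persistence and
   fixed-order ARIMA baselines.

## Worked example

```r
library(btsforecast)

# two synthetic 6,000-base genomes with drifting composition
seqs <- synthetic_benchmark(n_seqs = 2, length = 6000, seed = 42)

encode_spectral("AGCT")$values
#> [1] 1 2 3 4

encode_cgr("AC")$values          # midpoints toward A = (1,1), then C = (-1,-1)
#>          x     y
#> [1,]  0.50  0.50
#> [2,] -0.25 -0.25

round(encode_z("ACGT")$values, 4)
#> [1] 1.7321 1.4142 1.0000 0.0000

# ARFIMA recovery on simulated long memory
x <- generate_arfima_series(2000, d = 0.3, ar = 0.6, seed = 1)
fit_arfima(x, p = 1, d = 0.3, q = 0)
#> <arfima_fit> ARFIMA(1, 0.3, 0) mean=-0.04158 sigma2=1.077
#>   ar: 0.5896

# full pipeline
rep <- run_pipeline(seqs, pipeline_config(seed = 7))
```

The per-sequence report prints (this exact output, seed 7):

```
synth01: test MAPE 4.4780 | R2 0.0643 | VAR 0.019661 | naive MAPE 6.7023 | P_MAPE vs naive 33.2% | w_AR 0.42
synth02: test MAPE 6.3005 | R2 0.0560 | VAR 0.031528 | naive MAPE 9.3494 | P_MAPE vs naive 32.6% | w_AR 1.00
```

Reading it: the fused one-step test forecasts of the windowed spectral
series err by 4.5–6.3% on average, a ~33% accuracy gain (P_MAPE) over naive
persistence; `w_AR` is the learned convex weight on the ARFIMA branch, and
VAR is the residual variance (stability). R² is modest by design — the
benchmark's forecastable compositional drift sits on top of irreducible
binomial window noise.

A command-line front end ships in `inst/cli/btsforecast`:

```sh
Rscript inst/cli/btsforecast run --synthetic 6x6000 --seed 1 --out run1
Rscript inst/cli/btsforecast encode --fasta genome.fa --encoding cgr --out cgr.csv
Rscript inst/cli/btsforecast run --fasta genome.fa --drop ar   # ablation
```

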