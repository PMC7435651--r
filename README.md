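# fallsense

Tools for studying an energy-efficient, wearable fall-detection
workflow: a sample-accurate simulator of the interrupt-driven
transmission scheduler of a waist-worn six-axis IMU module, the
server-side signal-conditioning chain, a CNN-LSTM activity classifier
with a framework-independent shape/parameter auditor and a
self-contained training engine, and a synthetic labelled IMU generator
so every stage runs with no external data.

## Who this is for

Researchers and engineers prototyping wearable fall detection who want
to reason quantitatively about the two halves of such a system before
touching hardware:

1. **When does the radio need to be on?** An MPU6050-class sensor
   buffers 0.5 s of data (600-byte FIFO, six 16-bit channels at 100 Hz)
   and exposes free-fall, motion and zero-motion interrupts. A two-state
   scheduler transmits only after a free-fall or motion event — including
   the buffered pre-trigger history — and stops once the signal has been
   quiet for a second. The fraction of samples transmitted (the duty
   cycle) is the package's energy proxy.
2. **Can the server tell a fall from daily activities?** Transmitted
   data are normalized to the sensor ranges, smoothed with a causal
   moving average, cut into 2-s sliding windows (200 samples × 6
   channels) and classified into eight activities by a CNN-LSTM: four
   SAME-padded 1-D convolution + max-pool blocks (32/64/128/200 filters,
   kernels 3/5/7/9), two 200-unit LSTM layers (dropout 0.5, forget-gate
   bias 1.0), and a softmax layer.

The interrupt thresholds are principled: the free-fall threshold
0.563 g sits just below 1/√3 ≈ 0.57735 g, the worst-case largest axis
component of static gravity, so a resting sensor can never satisfy the
free-fall condition in any orientation.

The network's arithmetic is auditable by hand, with the standard
parameter formulas — conv: `f·(k·c) + f`, LSTM: `4u(d + u + 1)`, dense:
`u·d + u` — giving 608 parameters for the first convolution,
320,800 per LSTM layer, and a temporal contraction
200 → 100 → 50 → 25 → 13 across the four pools.

## Worked example

```r
library(fallsense)

## a synthetic fall: quasi-static, free-fall, impact, rest
fall <- generate_trace("falling", seed = 8)
fall
#> <imu_trace> 400 samples @ 100 Hz (4.00 s)
#> segments:
#>   [1, 400] falling

## what the duty-cycled scheduler transmits
log <- run_fsm(fall)
log
#> <transmission_log> 150/400 samples transmitted (duty cycle 0.375)
#>   3 transmitted range(s), 2 event(s), MCU awake 120 samples
log$events
#>          kind sample_index time_s
#> 1   free_fall          128   1.28
#> 2 zero_motion          247   2.47
```

The weightless phase fires the free-fall interrupt at 0-based sample
128 (the sample completing the 20 ms duration); the scheduler transmits
the 0.5 s FIFO history before that instant and keeps flushing until the
post-impact rest trips the zero-motion interrupt at 2.47 s, after which
the radio sleeps again. On a rest-dominated day the duty cycle is a few
per mille, against 1.0 for an always-transmit design.

```r
## auditable architecture
default_model_spec()
#> <fdnn_model_spec> input 200 x 6, 8 classes
#>    layer          kind timesteps features params
#>       C1        conv1d       200       32    608
#>       S1     maxpool1d       100       32      0
#>       C2        conv1d       100       64  10304
#>       S2     maxpool1d        50       64      0
#>       C3        conv1d        50      128  57472
#>       S3     maxpool1d        25      128      0
#>       C4        conv1d        25      200 230600
#>       S4     maxpool1d        13      200      0
#>  reshape reshape_split        13      200      0
#>       L1          lstm        13      200 320800
#>       L2          lstm        13      200 320800
#>       Fc         dense         1      8   1608
#> total trainable parameters: 942,192

## train a reduced network on synthetic windows and evaluate it
ds  <- generate_dataset(per_class = 80, seed = 2024)
tr  <- ds$split == "train"; va <- ds$split == "validation"
te  <- ds$split == "test"
fit <- fdnn(ds$x[tr, , ], ds$label[tr],
            spec       = default_model_spec(4),
            control    = fdnn_control(epochs = 30),
            validation = list(x = ds$x[va, , ], y = ds$label[va]),
            seed = 2024)
pred <- predict(fit, ds$x[te, , ], type = "code")
print(metrics_report(confusion(ds$label[te], pred)))
#> accuracy:     92.19 %
#> sensitivity: 100.00 %  (falls detected as falls)
#> specificity: 100.00 %  (ADLs not flagged as falls)
#> per-class recall (%):
#>          walking          jogging          jumping   going_upstairs
#>            100.0            100.0            100.0            100.0
#> going_downstairs      standing_up     sitting_down          falling
#>            100.0            100.0             37.5            100.0
```

On this synthetic task the epoch-reduced run of the full network
clears 90 % held-out accuracy in a few minutes on one CPU, with every
fall detected and no false fall alarms; the residual confusion sits
between sitting down and standing up, the two most similar transients.
`summary()`, `plot()`, `coef()` and `write_history_csv()` expose the
fit. The 300-epoch budget is the default of `fdnn_control()`.

Synthetic traces are stylised (sinusoidal gait, four-phase falls):
results on them validate the pipeline and the training engine, not
real-world accuracy. See the vignette
(`vignettes/fall-detection-workflow.Rmd`) for the model, its
assumptions, and every numerical convention.

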