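# pupilfreq

Decoding the contents of visual awareness from the pupil. In binocular
rivalry, two incompatible images — classically a face and a house — are
shown one to each eye, and perception alternates between them every few
seconds while the stimulation itself never changes. `pupilfreq`
implements *pupil frequency tagging* for this situation: both images are
luminance-modulated sinusoidally at the same frequency (1.7 Hz) but with
a phase offset between the eyes (180°, 90°, or 0° as a control), and the
phase of the entrained pupil oscillation is used to infer, cycle by
cycle, which image the observer is currently aware of.

The package is aimed at visual psychophysicists and pupillometry users:
it covers the full chain from raw pupil traces and button-report events
to group statistics, plus a synthetic-data generator that produces
complete rivalry sessions with known ground truth, so the entire
pipeline is testable without any recorded data.

## The model at the core

The pupil tracks luminance with inverted sign and a latency of a few
hundred milliseconds. If the dominant percept drives the pupil
oscillation with weight *w* and the suppressed percept with 1 − *w*, the
summed oscillation has amplitude

    A(w, Δφ) = | w + (1 − w) · exp(i·Δφ) |

relative to a single source (`mixture_amplitude()`): 91% for w = 0.9 at
Δφ = 90°, 80% at 180°; for w = 0.5, 71% at 90° and 0 at 180°. Amplitudes
are therefore not comparable across conditions — the percept signal is
in the **phase**. Each 588 ms presentation cycle (1/1.7 Hz) of the
z-standardized trace yields a complex F1 Fourier coefficient

    Z = (2/N) · Σₙ xₙ · ( cos(2πn/N) + i·sin(2πn/N) ),

whose imaginary part is the sine-phase (reference-aligned) content.
Cycles wholly covered by an exclusive percept report are labelled by
eye; percept dependence is tested with paired t-tests on Im(Z) across
subjects, and single-cycle decodability is quantified by ROC/AUC —
either along Im(Z) or along the optimal projection angle found in 1°
steps in the complex plane.

Preprocessing follows standard pupillometry practice: samples whose
change to the next sample exceeds 5 SD of the block's change rate are
removed, 50 ms around every detected gap is discarded, gaps are filled
by cubic-spline interpolation, and each block is z-standardized.

## Worked example

Simulate one 300 s counterphase block, clean it, extract cycles and
decode the percept:

```r
library(pupilfreq)

params <- simulation_params()                   # w_dom = 0.9, 2.7 s median dominance
sch    <- stimulus_schedule(phase_diff_deg = 180, condition = "mod180_naive")
blk    <- simulate_block(params, sch, seed = 42)

pp <- preprocess(blk$trace)
pp$report
#> cleaning_report: 9059 rate rejections, 7547 removed by padding,
#>                  26632 interpolated (diff SD 235.3)

cy <- extract_cycles(pp$trace, blk$reported, sch)
table(cy$label)
#> excluded     left    right
#>      181      139      190

cy$subject <- "s01"; cy$condition <- "mod180_naive"
res <- decode_session(cy)
res$by_subject[, c("n_left", "n_right", "auc_im", "theta_opt", "auc_opt")]
#>   n_left n_right auc_im theta_opt auc_opt
#> 1    139     190  0.897       133   0.936
```

Of the 510 presentation cycles, 329 were covered by an exclusive report
(the rest were mixed, unreported, or contained a switch). From the phase
of the pupil oscillation alone, the reported eye is predicted for single
cycles with AUC ≈ 0.90 along the sine-phase axis and ≈ 0.94 along the
per-subject optimal rotation — far above the 0.5 chance level, as it
should be for a strongly percept-weighted (w = 0.9) counterphase
simulation. The in-phase control condition carries no phase information
and decodes at chance, which the test suite verifies on 12-subject
synthetic studies.

Design-level quantities:

```r
round(100 * mixture_amplitude(c(0.9, 0.9, 0.5, 0.5), c(90, 180, 90, 180)))
#> 91 80 71  0
sensitivity_min_d(12, alpha = 0.05, power = 0.80)   # 0.889
sensitivity_min_d(12, alpha = 0.05, power = 0.95)   # 1.146
```

A seven-block session fixture (two static blocks, 180°/90° naive and
attention-instruction blocks, 0° control, alternating eye–image
assignment) with a ground-truth manifest is written by
`make_fixture_session()`; `summarize_behavior()`, `rm_anova_2x7()` and
`attention_proportions()` cover the behavioral side. A thin command-line
front end with `simulate` / `preprocess` / `cycles` / `decode` / `stats`
/ `run-all` subcommands is installed at `inst/cli/pupiltag`.

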