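---
title: "A physiologic model of oscillometric blood pressure measurement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A physiologic model of oscillometric blood pressure measurement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscillobp)
```

## The problem

Automatic blood pressure cuffs measure the small pulse-synchronous
oscillations superimposed on the cuff pressure as it is slowly deflated.
The envelope of those oscillations peaks near mean arterial pressure, but
the systolic and diastolic endpoints are conventionally read off with fixed
*characteristic ratios* (about 50% of peak height on the rising side for
systolic, 70% on the falling side for diastolic) that are empirical and
break down when pulse pressure or arterial stiffness deviate from normal.
`oscillobp` implements a physics-based alternative: a forward model of how
the artery under the cuff generates the oscillations, and an inverse
algorithm that fits an individualized artery model to each recorded
envelope and then finds the systolic/diastolic pair whose predicted
envelope best matches the observed one.

## The forward model

**Artery.** The compressed artery segment follows a bi-exponential
pressure-volume law in transmural pressure $P_t$ (arterial minus cuff
pressure). On the collapse branch ($P_t < 0$), $V_a = V_{a0} e^{a P_t}$;
on the distension branch ($P_t \ge 0$),
$V_a = V_{a0}\left(1 + \frac{a}{b}(1 - e^{-b P_t})\right)$, which
saturates at $V_{a0}(1 + a/b)$. Volume and compliance are continuous at
$P_t = 0$; the branch point itself is assigned to the distension branch.
The stiffness constants have physiologic anchors: $a = \ln(0.1)/P_c$ from
the collapse pressure $P_c$ (the transmural pressure at which volume falls
to 10% of $V_{a0}$; about $-20$ mmHg gives $a \approx 0.115$, quoted as
0.11 /mmHg), and $b = -\ln(C_n/(a V_{a0}))/P_{mid}$ from the measured
compliance $C_n$ at mid-level pressure $P_{mid}$ (0.0016 ml/mmHg at
100 mmHg gives $b \approx 0.030$ /mmHg). We store full precision and round
only for display. Note that scaling $a$ and $b$ together rescales the
compliance at every pressure, so a proportional increase represents a more
compliant artery; the ratio $a/b$ sets the maximal distension.

**Cuff.** After inflation the outer wrap is rigid and the cuff's
compliance is that of its sealed air, which Boyle's law gives as
$C_{cuff} = V_0/(P + 760)$ for gauge pressure $P$ in mmHg: the cuff
softens as it deflates. The air volume default $V_0 = 300$ ml corresponds
to a 30 cm × 10 cm × 1 cm adult cuff; since the estimator normalizes
envelope amplitudes, $V_0$ sets the oscillation amplitude scale (tenths of
a mmHg to a few mmHg) but not the recovered pressures.

**Forcing.** Arterial pressure is a three-harmonic Fourier series,
$P_a(t) = DBP + 0.5\,PP + 0.36\,PP\,(\sin\omega t + \tfrac12 \sin 2\omega t
+ \tfrac14 \sin 3\omega t)$, whose mean is the mid-level pressure and
whose extremes land within 0.05 mmHg of nominal SBP and DBP for a 40 mmHg
pulse pressure. Its time derivative is taken analytically, with the pulse
pressure factor applied to the derivative as well so that the derivative
is exact — required for the chain rule in the artery filling-rate term.

**Coupling.** During deflation at bleed rate $r$,
$$\frac{dP}{dt} = -r + \frac{P_0 + 760 - r t}{V_0}\,\frac{dV_a}{dt},
\qquad \frac{dV_a}{dt} = C_a(P_t)\left(\frac{dP_a}{dt} + r\right),$$
with the compliance branch selected by the sign of $P_t$. The transmural
pressure driving the artery uses the smooth deflation ramp $P_0 - rt$: the
sub-mmHg oscillations the artery itself creates are negligible against the
tens of mmHg the ramp sweeps through. Integration is forward Euler at an
internal step of 0.5 ms — small enough that halving it moves no stored
sample by more than 0.01 mmHg — with output decimated to 100 Hz.

One subtlety deserves record. The integrated artery term contains, besides
the pulsatile oscillations, a secular component: the artery steadily fills
as the cuff deflates, which would re-pressurize a sealed cuff by roughly
3 mmHg over a 40 s run and shift the apparent pressure axis of the
envelope by 2–3 mmHg near the diastolic knee (enough to bias recovered
diastolic pressure by +2 mmHg and distort the characteristic ratios). We
model the bleed valve as rate-controlled — automatic devices regulate
deflation so the smooth cuff pressure falls at the nominal rate — so the
stored recording is the ramp plus the *pulsatile* part of the artery
contribution (its one-beat moving average removed). With a volume-free
artery (`Va0 = 0`) the output is exactly the ramp. We also implemented the
fully self-consistent alternative in which the artery responds to the
simulated cuff pressure itself; it rounds the envelope knees through
oscillation feedback and degrades wide-pulse-pressure recovery (systolic
error 3 mmHg rather than 2), so the rate-controlled valve is the default
and only mode.

## Signal processing

The high-pass filter emulates an instrument's analog filter by
moving-average subtraction: the oscillation at time $t$ is the mean
pressure over the centred one-beat window minus the pressure at $t$
(slowly varying baselines cancel; the cardiac component survives,
sign-inverted). Samples within half a beat of either end are undefined.
The window length is rounded to an odd number of samples so it is
symmetric; at 100 Hz and 80 beats/min it covers exactly one beat
(75 samples), which makes ramps cancel identically. The envelope is then
beat-wise peak-to-trough: the record is segmented into consecutive
one-beat windows (known phase for simulated data; ascending zero crossings
with a half-beat minimum separation for external recordings), and each
complete beat contributes its oscillation range and its mean cuff
pressure. Beats touching unfiltered samples are dropped. A 40 s run at
80 beats/min yields 51 usable beats.

## The inverse algorithm

In the envelope head (cuff pressure above systolic, the whole pulse on the
collapse branch) the beat amplitude is proportional to $e^{-aP}$, so
ordinary least squares of $\ln(\text{amp})$ on beat pressure has slope
$-a$; in the tail (below diastolic) the amplitude is proportional to
$e^{bP}$ and the slope is $+b$. The head range runs from the envelope
onset to the first beat reaching one third of the peak amplitude, and the
tail from the last beat above two thirds of the peak to the end. The
*onset* is the first rising-side beat reaching 10% of the peak: beats
below that threshold are at or below the amplitude resolution of a real
recording (a few hundredths of a mmHg here), and with even 0.02 mmHg of
measurement noise their peak-to-trough values are dominated by the noise
range, which would flatten the fitted slope systematically. On noise-free
runs the onset floor changes the recovered constants by well under 1%;
`onset_frac = 0` restores a literal start-at-the-first-beat range, and an
inflection-point range rule is available behind `ranges = "inflection"`.

With $\hat a, \hat b$ fixed, the predicted envelope for a candidate pair
is $\hat y(P) = [V_a(SBP - P) - V_a(DBP - P)]\,(P + 760)/V_0$, and the
misfit is $SS = \sum_{\text{beats}} (y/y_{max} - \hat y/\hat y_{max})^2$,
both envelopes normalized by their own peak *over the observed beat
pressures* so that $V_{a0}$ and $V_0$ drop out. $SS$ is evaluated on a
grid of 1 mmHg steps — diastolic candidates from 10 mmHg below the lowest
beat pressure up to the envelope peak pressure, systolic from the peak
pressure to 10 mmHg above the highest beat pressure — and the minimizer is
the estimate. Ties break deterministically toward the smallest pulse
pressure, then the smallest systolic value. On clean data the surface has
a single basin; a degenerate predicted envelope scores `Inf` rather than
erroring so the grid search can continue.

## Validation scenarios and what they show

`builtin_scenarios()` fixes the five stress conditions used throughout:
normal (120/80 mmHg, $a = 0.11$, $b = 0.03$), stiffness doubled or halved
(both constants scaled by 1.44, the factor consistent with the quoted
scenario constants 0.076 and 0.158), and pulse pressure halved (110/90) or
doubled (140/60), all with the standard cuff (150 mmHg start, 3 mmHg/s,
300 ml) and 80 beats/min. `run_validation()` runs the full pipeline
noise-free on each and also computes the classical 50%/70% fixed-ratio
baseline. Across the suite the grid search recovers systolic pressure
within 2 mmHg and diastolic within 1 mmHg, and the recovered stiffness
constants sit within 0.003 of truth; the summary reports the root mean
squared pressure error under both conventions
($\sqrt{\text{SSE}/n} \approx 0.89$ mmHg and $\sqrt{\text{SSE}}/n
\approx 0.28$ mmHg over the ten recovered values). The diastolic
characteristic ratio measured on the simulated envelopes falls from about
91% (stiff) through 88% (normal) to 84% (compliant) — the closed-form
envelope shape itself bounds this spread (91.5/89.0/86.1), so
substantially wider spreads sometimes quoted for this model cannot arise
from the stated equations — while the fixed 70% diastolic rule drifts by
several mmHg across the same sweep. That contrast, not the absolute ratio
values, is the robust finding.

## What the generator does and does not emulate

The simulator produces exactly the conditions above: a memoryless
bi-exponential artery, a deterministic three-harmonic waveform with fixed
rate and pulse pressure, a rigid-wrap cuff, constant-rate deflation, and
optional additive white Gaussian measurement noise (default off, seeded
when used). Real recordings add respiration and movement artefact,
beat-to-beat variability and arrhythmia, viscoelastic artery behaviour,
and cuff-tissue coupling losses — none of which are modelled. Passing
tests therefore demonstrate internal consistency of the method under the
stated physiology, not clinical accuracy; the estimator's interfaces
(`read_recording()`, `extract_envelope(align = "zero_crossing")`) accept
external data so that question can be pursued separately.

## Numerical choices

Euler at 0.5 ms internal step (first-order, safe for the stiff collapse
exponential); 100 Hz stored rate chosen so the beat period is an odd
integer number of samples at the default heart rate; runs that would reach
zero cuff pressure truncate with a warning; non-finite pressures abort.
Regression requires at least three usable beats per range and drops
non-positive amplitudes with a logged count. The grid aligns candidates to
integer multiples of the step so that integer true pressures are exactly
representable. All randomness flows through the single `seed` argument of
`simulate_run()`; noise-free runs are bit-reproducible.
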