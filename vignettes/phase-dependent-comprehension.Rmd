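---
title: "Modelling phase-dependent speech comprehension under envelope tACS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling phase-dependent speech comprehension under envelope tACS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tacsphase)
```

## The scientific problem

Cortical activity tracks the slow amplitude modulations (the *envelope*)
of speech, particularly in the theta band (4–8 Hz) that carries the
syllabic rhythm. Transcranial alternating current stimulation (tACS)
with a current waveform derived from a speech envelope can perturb this
tracking, and the behavioural consequence — a change in how many
keywords of a sentence a listener understands — depends on the phase
shift between the current and the acoustics. `tacsphase` implements the
full computational chain for such experiments: synthesis of the
stimulation waveforms from audio, the harmonic regression model of
comprehension versus stimulation phase, circular statistics for
per-subject best phases, the adaptive staircase that finds each
listener's 50% sentence reception threshold (SRT), and a synthetic
cohort generator that ties everything together for validation.

## Waveform synthesis

The stimulation waveform is built from audio in a fixed, deterministic
order:

1. **Envelope extraction** — the magnitude of the analytic signal
   (Hilbert envelope) of the broadband audio. The precise envelope
   estimator is not critical here because the next stage keeps only the
   4–8 Hz band; the analytic-signal magnitude is the standard choice.
   The envelope is resampled (FFT-domain, exact for band-limited
   signals) to 250 Hz by default: designing a 4–8 Hz IIR filter
   directly at 44.1 kHz places its poles so close to the unit circle
   that double-precision filtering becomes unreliable, while 250 Hz
   leaves more than a decade of headroom above the band and is
   numerically comfortable.
2. **Theta bandpass** — a Butterworth bandpass of single-pass order 6
   (design order 3 on the band edges), applied forward–backward
   (`signal::filtfilt`) so the output has zero phase and features stay
   aligned with the acoustics. Forward–backward filtering doubles the
   effective attenuation; the package's tests therefore compare
   measured gains against the *squared* magnitude response of the
   designed filter. The signal is padded by odd reflection before
   filtering to suppress start/end transients.
3. **Extrema equalization** — the band-limited envelope is rescaled so
   that every interior local maximum equals +1 and every minimum −1.
   The signal is divided by a piecewise-linear amplitude profile
   interpolated through the magnitudes of its detected extrema. One
   pass leaves residual deviations of order $10^{-3}$ because a
   time-varying gain shifts extrema slightly, so the rescaling is
   iterated to a fixed point (tolerance $10^{-6}$, at most 50 passes).
   The iteration is continuous, preserves the number and order of
   extrema and zero crossings, and is idempotent.
4. **Phase shift** — rotation of the analytic signal:
   $y(t) = x(t)\cos\theta - \mathcal{H}\{x\}(t)\sin\theta$. A positive
   shift advances phase (`sin` → `cos` at +90°). The trigonometric
   factors are computed with `cospi`/`sinpi`, so a 180° shift is a
   *bitwise* negation — an algebraic identity of the rotation, not an
   approximation — and the instantaneous amplitude is preserved for
   any angle.
5. **Current scaling** — peak-referenced: the waveform is scaled so its
   largest absolute value equals the subject's calibrated maximum
   current (study range 0.1–1.5 mA in 0.1 mA steps; population mean
   0.67 mA, which is the package default). Peak referencing (rather
   than RMS) is assumed because the calibration procedure itself is a
   peak-sensation threshold.

The sham control is a 500 ms pulse with 100 ms linear on/off ramps.
Linear ramps are one of several "smooth onset" choices; nothing
downstream depends on the ramp shape.

## The harmonic model of comprehension versus phase

Each subject contributes a comprehension score $CS(\phi_n)$ (percent of
130 keywords correct) at the four phase shifts
$\phi_n = 0°, 90°, 180°, 270°$. Scores are mean-centered per subject,
$\Delta CS(\phi_n) = CS(\phi_n) - \overline{CS}$, which removes
between-subject level differences, and pooled into one regression over
all subject × phase observations (72 rows at study scale):

$$\Delta CS(\phi_n) = A_0 + B_1 \sin\phi_n + B_2 \cos\phi_n
  + A_2 \cos 2\phi_n.$$

With four equally spaced phases this regression is exactly the discrete
Fourier decomposition of the per-phase means: $A_0 = a_0$,
$B_2 = 2\,\mathrm{Re}\,a_1$, $B_1 = -2\,\mathrm{Im}\,a_1$, $A_2 = a_2$,
an identity the test suite verifies to $10^{-8}$ on random cohorts. The
first-harmonic amplitude and best phase follow as

$$A_1 = \sqrt{B_1^2 + B_2^2}, \qquad
  \varphi_1 = \operatorname{atan2}(B_1, B_2),$$

so that $B_1\sin\phi + B_2\cos\phi = A_1\cos(\phi - \varphi_1)$ holds
identically. We note that the conventions in this area are easy to get
inconsistent: the mapping above is the unique one under which a pure
$\cos\phi$ profile gives $\varphi_1 = 0$ and a pure $-\cos\phi$ profile
gives $\varphi_1 = 180°$, matching the equivalent definition
$\varphi_1 = -\arg a_1$ under the forward transform
$a_k = \tfrac14\sum_n \Delta CS(\phi_n) e^{-ik\pi\phi_n/180°}$.

Mean-centering makes the intercept of a balanced cohort vanish to
floating-point noise (|A0| < 1e−10); a reported intercept of order
$10^{-16}$ in such an analysis is numerical zero, not a small effect.

### Standard and robust estimation

The model is fitted by ordinary least squares and by robust regression
(iteratively reweighted least squares with Tukey's bisquare weights,
tuning constant 4.685 for 95% Gaussian efficiency, MAD scale,
convergence at a relative change of $10^{-8}$ or 200 iterations, via
`MASS::rlm`). Per-coefficient p values are corrected with the
Benjamini–Hochberg FDR procedure *within* each model (4 coefficients
unaligned, 3 aligned). On data with no outliers the two estimators
agree to well under 0.1 percentage points at study scale.

**The r² used to compare the estimators.** If the fit quality of both
methods is measured by the plain squared correlation between fitted and
observed values, OLS wins by construction — it maximizes exactly that
quantity — and a comparison is vacuous. The package therefore scores
the robust fit by the squared correlation *weighted by its final IRLS
weights*: observations the estimator has rejected as outliers do not
count against it. With unit weights the definition reduces to the
ordinary $r^2$, which is what the OLS fit reports. This is the only
definition under which "robust fits better than standard on
outlier-contaminated data" is a falsifiable statement, and it is the
behaviour the bootstrap comparison (`bootstrap_r2_compare`) tests: both
estimators are refitted on each bootstrap sample (resampling whole
subjects, preserving the within-subject phase block; row resampling is
available behind a flag) and the paired one-tailed t test asks whether
the robust $r^2$ exceeds the OLS $r^2$. The unweighted definition
remains available (`r2_method = "correlation"`). One caveat is
inherent: across thousands of bootstrap replicates a paired t test
detects even the small systematic advantage that weighting confers on
clean data, so the comparison is informative about *magnitude* (is the
robust gain large?) rather than bare significance.

### Inference on the derived amplitude

Centering couples the four residuals of a subject (they must sum to
zero), so the model-based OLS covariance underestimates the sampling
variance of phase contrasts by a factor of about $\sqrt{3}/2$. The
coefficient tables keep the model-based covariance to stay comparable
with the classical presentation, but for inference on $A_1$ the package
recommends (and its recovery tests use) a by-subject cluster-robust
covariance (`vcov = "cluster"`, `sandwich::vcovCL`, t quantile with
subjects − 1 degrees of freedom) propagated through the delta method
$\operatorname{se}(A_1) = \sqrt{g^\top V g}$ with
$g = (B_1, B_2)/A_1$.

The between-source amplitude difference (target versus distractor
envelope stimulation) is tested by resampling subjects *jointly* for
both sources, re-estimating both amplitudes on every bootstrap sample,
and referring the observed difference to the bootstrap standard error
with a normal approximation. A t test across bootstrap replicates
would be wrong — its standard error shrinks with the number of
replicates, which is an analyst's choice.

### Best-phase alignment

For each subject the phase with the highest score is found (ties broken
toward the lowest phase and counted), the remaining three phases are
re-indexed relative to it, and the three-parameter model (no
180°-period term, which the three remaining points cannot identify
together with the rest) is refitted. The centered deviations keep their
values from the four-phase centering; only the labels change. Because
alignment selects each subject's maximum, it induces a negative
expected intercept and, when the population truly shares one best
phase, *adds* selection noise rather than removing variance — the
package's simulations reproduce this: aligned refits on cohorts with a
common true phase are usually non-significant.

## Circular statistics of best phases

Per-subject best phases live on the circle. The package computes the
mean direction, the resultant vector length $R$ and the angular
deviation $\sqrt{2(1-R)}$ (radians); tests uniformity with the Rayleigh
statistic $Z = nR^2$ using the standard finite-$n$ corrected p value
(cross-checked against a 50,000-draw Monte-Carlo null in the test
suite, and replaced by a Monte-Carlo p below $n = 4$); and fits a von
Mises distribution by maximum likelihood — $\hat\mu$ is the circular
mean and $\hat\kappa$ inverts $A(\kappa) = I_1(\kappa)/I_0(\kappa) = R$
numerically to $10^{-10}$, capped and flagged at $R = 1$.

Goodness of fit uses Watson's one-sample $U^2$ on the fitted
distribution's probability integral transform. Because $\mu$ and
$\kappa$ are estimated from the same data, textbook critical values do
not apply; the p value comes from a parametric bootstrap that refits on
every simulated sample (999 replicates by default). Two caveats are
deliberate design choices:

- The study design discretizes best phases to four values. A
  continuous von Mises can still be fitted (the likelihood only needs
  the angles), but any continuous goodness-of-fit test will eventually
  reject pure four-point data as sample size grows. The package fits
  the raw angles by default; an optional jitter flag exists for
  sensitivity analyses but is off, because silently perturbing data is
  worse than documenting the approximation.
- The two-sample concentration comparison is a permutation test: each
  sample is centered on its own mean direction, the centered angles are
  pooled and permuted, and the statistic is the larger ratio of the two
  circular variances. This avoids the regime-dependent approximations
  of the classical transformation-based test and is exact up to
  permutation noise.

## The adaptive SRT staircase

The virtual listener has a logistic psychometric function
$p(\text{snr}) = \text{guess} + (1-\text{guess}-\text{lapse})
\operatorname{logit}^{-1}\!\big(4s\,(\text{snr}-\text{SRT})\big)$ with
slope $s$ in probability/dB at threshold; keyword counts are binomial
draws of 5 keywords per sentence. The staircase starts uniformly in
$[-3, 0]$ dB, moves up 1 dB when at most 2 of 5 keywords are correct
and down 1 dB otherwise, and stops at 7 reversals or 17 trials. Because
$P(\ge 3 \text{ of } 5)\,=\,0.5$ exactly when the keyword probability
is 0.5, this 1-up/1-down rule converges to the 50% keyword SNR — the
defined SRT — for any symmetric psychometric function.

The estimator phrase "average of the last three SNR values during the
last three repetitions" admits two readings; the package's default
averages, within each of the last three runs, that run's final three
presented SNRs and then averages across runs (`rule = "last3_mean"`),
with the final-SNR-per-run reading behind a flag. Both use presented
SNRs, not reversal SNRs. Simulations with steep listeners
(slope ≥ 0.15/dB) put the residual bias well under 1 dB; at the default
cohort parameters (true SRT $\sim N(-6.9, 1.6^2)$ dB) the mean estimate
is within a few tenths of a dB of truth.

## What the synthetic cohort emulates — and what it does not

`generate_cohort()` reproduces the study design: 18 subjects, 26
sentences × 5 keywords = 130 keywords per condition, scores near 50%
(the point of running at the SRT), a cosine phase modulation with
amplitude 3.0 percentage points peaking at 0° for target-envelope
stimulation and 1.6 points peaking at 180° for the distractor envelope,
sham scores with no modulation, and a Gaussian between-subject offset
(SD 5 points — the study reports no subject-level variance, so this is
a placeholder chosen to produce scatter comparable to published
per-subject score plots, exposed as a parameter and not a claim about
the data). Keyword outcomes are independent Bernoulli draws; real
keywords within a sentence are correlated, which would *inflate* the
effective noise relative to this generator, so the generator is, if
anything, optimistic about attainable precision.

This matters for interpreting the validation suite. With 130
independent keywords at 50%, one condition score has a binomial SD of
$100\sqrt{0.25/130} \approx 4.4$ points, and the sampling SD of $B_2$
across 18 subjects is $\approx 0.73$ points. A true distractor
amplitude of 1.6 points is therefore a $z \approx 2.2$ effect: amplitude
and phase are recovered well (median circular error of the fitted
$\varphi_1$ under 20°, CI coverage at the nominal level), but the
*FDR-corrected significance* of the distractor $B_2$ replicates only in
roughly half of simulated cohorts. The published human data show
smaller standard errors than independent-binomial noise predicts, so a
full significance-pattern replication is not something this generator
can promise — a fact the package documents rather than papers over by
quietly reducing the noise.

Surrogate envelope pairs are theta-band-filtered $1/f$-shaped noise,
offset to non-negativity, generated from distinct seeded substreams;
they reproduce the statistical independence and theta-dominated
modulation spectrum of unrelated sentence envelopes, but none of the
linguistic structure of real speech.

## Numerical and reproducibility choices

- Every stochastic function takes an explicit seed and restores the
  caller's RNG state; generators are pure functions of (parameters,
  seed). The pipeline is byte-reproducible given its configuration.
- Angle I/O is in degrees, internal computation in radians; angles are
  reduced to $[0, 360)$.
- Degenerate inputs are first-class: exact-fit data short-circuit the
  IRLS (whose MAD scale would be zero) to the OLS solution; all-zero
  waveforms scale to all-zero currents; identical circular samples give
  a concentration p of 1; four-balanced-phase samples give $R = 0$
  within machine precision.
- Problem sizes in the validation suite — 200 simulated cohorts for
  recovery and robustness checks, 2,000 bootstrap samples for the r²
  comparison, 50,000 Monte-Carlo draws for the Rayleigh calibration,
  100 staircase procedures, 100 envelope pairs — were chosen so each
  check has comfortable statistical resolution while the whole suite
  runs in about a minute on one core.

## Known limitations

- No sentence-level or keyword-correlation structure in the score
  generator, and no SNR covariate in the comprehension model.
- The robust fit's coefficient covariance is the large-sample IRLS
  approximation; no cluster-robust variant is offered for it.
- The Watson bootstrap refits only $(\mu, \kappa)$; it does not model
  the four-point discretization of the study design, so its p values
  under discretized data should be read as approximate.
- Waveform synthesis assumes mono audio and does not model electrode
  montage, current spread, or hardware constraints.
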