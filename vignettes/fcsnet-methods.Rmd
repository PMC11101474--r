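---
title: "Decision bias and directed beta-band connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision bias and directed beta-band connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcsnet)
```

`fcsnet` implements an analysis pipeline for approach-avoidance (Ap-Av)
decision experiments with simultaneous multi-region local field potential
(LFP) recordings, together with a synthetic-data generator that reproduces
the statistical structure the analysis assumes. In the Ap-Av task a subject
is offered, on every trial, a reward of size $x$ together with an aversive
airpuff of strength $y$ (both varied independently over a fine grid);
choosing *approach* (Ap) accepts both outcomes, choosing *avoidance* (Av)
declines both. Microstimulation of the subgenual cingulate during such a
task can bias choices toward avoidance, and the pipeline quantifies both
that behavioural shift and the accompanying change in directed beta-band
(13–30 Hz) influence within the fronto-cingulo-striatal (FCS) network:
dorsolateral prefrontal cortex (dlPFC), pregenual and subgenual anterior
cingulate (pACC, sgACC) and dorsal striatum.

# The behavioural model

Choices are modelled by a conditional logit,
$$
P(\mathrm{Ap}) \;=\; \frac{1}{1 + e^{-(a x + b y + c)}},
$$
with offers on a canonical $[0,1]$ scale (physical units such as ml of
reward or psi of airpuff are presentation metadata only; the logit is
covariant under axis rescaling, so one canonical scale avoids double
bookkeeping). The approach and avoidance utilities are $U_{AP} = ax + by$
and $U_{AV} = -c$. Two derived quantities matter downstream:

* the **cost-benefit ratio** $\mathrm{CBR} = -b/a$, the sensitivity to
  punishment relative to reward — an increase in CBR is the quantitative
  signature of a negative decision bias; the decision-boundary slope
  $-a/b$ is its reciprocal;
* the **chosen value** $\mathrm{ChV} = p\,U_{AP} + (1-p)\,U_{AV}$, the
  expected utility of the decision, used as the expected-utility (Eutil)
  regressor and to rank task conditions. Note that ChV is *not* globally
  monotone in the reward offer: $\partial\,\mathrm{ChV}/\partial x =
  a\,p\,(1 + (1-p)f)$ with $f = ax+by+c$, which is negative deep in the
  avoidance region ($f < -1/(1-p)$) — raising the reward offer there mostly
  raises the value of the option the subject will still decline to take.

`fit_conditional_logit()` is a binomial GLM on the non-omitted trials, with
quasi-separation detected and flagged; omission trials are excluded from
all choice analyses.

# Decision matrices and stimulation effects

Per-trial quantities (choice, reaction time, beta power) are stacked on a
$100\times100$ grid over offer space and smoothed with a $25\times25$-point
square window. The 101-step offer grid maps to the 100-cell axis by
$\mathrm{cell} = \min(100, \lfloor 100v \rfloor + 1)$, so the two largest
offer steps share the top cell. The window is truncated at matrix borders
and renormalised by the in-bounds trial count, which keeps the edge
estimates unbiased; points whose window holds no trials are undefined.

A stimulation effect is quantified by comparing two blocks
(`stim_effect()`): at each grid point the window's Ap/Av counts in the two
blocks form a $2\times2$ table tested with a two-sided Fisher exact test at
$\alpha = 0.05$, uncorrected. `%dAv` is the percentage of the matrix area
where avoidance increased significantly; a session is *negative effective*
when `%dAv` exceeds 5% of the matrix. The pointwise tests are deliberately
left uncorrected — the 5% area threshold is the multiplicity control, and
its calibration is verified directly: on simulated no-change sessions (two
blocks generated from identical coefficients, 250 trials each) about 2% are
mislabelled effective, comfortably below 5%. If both `%dAv` and `%dAp`
exceed threshold the larger area wins; an exact tie falls back to
non-effective with a warning. Because the grid holds $10^4$ points and the
calibration runs hundreds of sessions, the Fisher p-values are computed by
a vectorised hypergeometric routine with memoisation of repeated tables; it
reproduces `stats::fisher.test()` exactly and is verified against it (and
against a brute-force per-point enumeration) in the test suite.

Group-level summaries (`block_summary()`) compare `%dAv` and `%dCBR`
between effective and non-effective sessions with two-sample t-tests;
`proportion_test()` reports the Fisher exact test one- and two-sided along
with the uncorrected Pearson chi-square, since published proportion
comparisons quote either convention.

# Beta-band LFP processing

The spectral chain mirrors standard practice for stimulation-contaminated
multichannel LFP:

1. **Artifact removal** — samples between 1.5 ms and 50 ms after each
   stimulation trigger are replaced by linear interpolation between the
   boundary samples; overlapping windows merge. Channels that saturate are
   excluded rather than repaired.
2. **Local-average re-referencing** — each channel minus the mean of its
   electrode group, removing shared noise and volume conduction.
3. **Downsampling** — zero-phase 4th-order Butterworth low-pass at 0.45
   times the target rate, then decimation (factor 32 for 32 kHz
   acquisition).

Instantaneous beta power has two extractors (`beta_power_timecourse()`).
The *envelope* method band-passes at 13–30 Hz (zero-phase) and takes the
difference between the upper and lower signal envelopes; "envelope" is
implemented as $\pm$ the analytic-signal modulus, so the difference is
twice the instantaneous amplitude — a deterministic, edge-stable choice
(peak interpolation would give the same value on band-limited signals with
more edge variance). The *squared* method filters forward-only at 13–28 Hz,
squares, and smooths with a Hanning kernel 77 ms wide at half height. The
two beta bands are kept as stated, each attached to its stage, and both are
configurable; the two extractors agree in rank to better than
$\rho = 0.8$ on band-limited signals.

Power spectra use DPSS multitapers with $\pm 2$ Hz smoothing and 4 tapers
on a 1.5 s cue-period window, DC removed per window, reported on a 1-Hz
grid with a one-sided Parseval-consistent normalisation. The tapers come
from the tridiagonal eigenproblem; for windows beyond 1024 samples they are
spline-interpolated from the 1024-point solution and re-orthonormalised,
which is numerically indistinguishable for PSD purposes and avoids a dense
$O(N^3)$ eigendecomposition.

The $1/f$ background is fit as $p = a f^b$ by ordinary least squares in
log–log coordinates over 1–100 Hz **excluding 13–30 Hz**: the exclusion
keeps a genuine beta peak from inflating the baseline. (The functional form
is given; the exclusion band is this package's choice and is configurable.)
A channel *has beta* when cue- or precue-period power exceeds the baseline
in 13–28 Hz (one-sided t-tests across trials per 1-Hz bin, Bonferroni
$n = 25$ over 5–30 Hz) and is *task-related* when cue and precue spectra
differ under the same correction. Both flags are exposed separately because
either criterion alone may be wanted. The Ap-Av tuning index of a channel
is the Ap-minus-Av mean spectrum with the same per-bin testing.

# Beta-response clustering

Each task-related channel's *beta response* is its per-trial mean
decision-period power mapped onto the decision matrix. The population of
responses is embedded by classical (Torgerson) multidimensional scaling of
the correlation-distance matrix $d_{ij} = 1 - r_{ij}$, keeping ten
dimensions, and clustered in that space with a diagonal-covariance Gaussian
mixture fit by EM, the number of components selected by BIC (the scan range
includes 8, the count reported for primate FCS data). The mixture machinery
is mclust's; in its convention the reported BIC is $2\ln\hat L - k\ln n$
and is maximised — equivalent to minimising the textbook
$k\ln n - 2\ln\hat L$. Assignments are maximum-posterior, and the fraction
of assignments with posterior above 0.75 is reported as a confidence
benchmark.

Cluster identity is anchored behaviourally: the $\pm$ChV surfaces of the
session's fitted logit (positive and negative expected utility) are
appended to the distance matrix before embedding — but excluded from
clustering — and the first coordinate (the principal component value, PCV)
is sign-oriented so the positive-utility anchor sits at the minimum. The
two clusters with the lowest mean PCV form the **P group** (power rising
with utility), the two highest the **N group**; the construction of the
anchors as $\pm$ChV is an assumption this package documents, the natural
reading of "positive and negative expected utility" under the fitted model.
Stimulation-induced shifts are tracked channel-wise in a joint embedding
across blocks: mean change in PCV per block (t-tests) and per-group count
tables (Fisher tests of proportion change).

Representational similarity analysis discretises offers into $8\times8$
bins (64 conditions), forms each region's condition patterns from channel
mean powers, ranks conditions by fitted utility, and compares regional
$1 - r$ dissimilarity matrices by Kendall and Spearman rank correlation of
the lower triangles. All-possible-subsets regression explains per-trial
beta power from five standardised regressors (offered reward, offered
airpuff, expected utility, reaction time, omission frequency): all 31
subsets are fit, the winner must pass the overall F-test ($p<0.05$) and
have the most favourable BIC, AIC and Mallows $C_p$ are reported as
cross-checks, and Belsley condition indices (threshold 30) flag collinear
subsets. Among numerically exact fits BIC differences reflect rounding
noise only, so the smallest exact subset wins.

# Coherence, Granger causality and the DAI

Interareal coupling is estimated on cue-period windows at a 250 Hz analysis
rate (ample for 5–30 Hz and keeps VAR orders tractable). Coherence is the
multitaper magnitude-squared coherence with the same taper settings as the
spectra. Directed influence is Geweke's frequency-domain Granger causality
(GC). The primary estimator is parametric: a bivariate VAR pooled across
trials, order selected by per-observation BIC
($\ln\det\hat\Sigma + p\,d^2 \ln N/N$, comparable across orders with
different effective sample sizes) up to order 20, then
$$
GC_{y \to x}(f) \;=\; \ln\frac{S_{xx}(f)}
{S_{xx}(f) - \left(\Sigma_{yy} - \Sigma_{xy}^2/\Sigma_{xx}\right)\,|H_{xy}(f)|^2},
$$
with $H = (I - \sum_j A_j e^{-2\pi i f j/f_s})^{-1}$ and $\Sigma$ the
innovation covariance. The parametric path admits closed-form oracles: for
a known bivariate VAR(1) the frequency-averaged GC equals the time-domain
value obtained from Kolmogorov's formula applied to the driven series'
spectrum, and the estimator reproduces it to within a few percent, with the
Geweke integral identity (frequency average equals time-domain GC) holding
to well under 5%. A nonparametric estimator — multitaper cross-spectral
matrices factorised by Wilson's algorithm into $H$ and $\Sigma$ — is
provided as a cross-check and agrees with the parametric one at the
band-average level. Numerically negative GC values are clipped to zero and
counted.

The **directional asymmetry index**
$$
\mathrm{DAI}_{y\to x} = \frac{GC_{y\to x} - GC_{x\to y}}
{GC_{y\to x} + GC_{x\to y}} \in [-1, 1]
$$
is antisymmetric under pair swap and undefined (flagged) when both GCs are
zero. Band averages use alpha $= [5, 13)$ Hz and beta $= [13, 30]$ Hz,
half-open at 13 to avoid double counting. `network_summary()` aggregates
DAI across channel pairs per ordered region pair (mean, SEM, t-test against
zero, per-frequency tests Bonferroni-corrected over the 26 analysis bins);
`block_contrast()` gives the distribution of per-pair changes in the 5–30
Hz mean DAI between blocks. GC is computed per channel pair and then
averaged within region pairs, not on region-averaged signals, matching how
the channel-pair distributions are reported.

`behavior_granger_test()` links network change to behavioural change:
both series are windowed into non-overlapping 50-trial bins referenced to
the Stim-off mean (the bin width is this package's documented default; it
is configurable), and a bivariate time-domain Granger F-test is run in both
directions with the lag chosen by BIC.

# The synthetic-data generator

No public raw recordings accompany the study conditions this pipeline
targets, so the generator is a first-class, tested module that produces
data with the properties the analysis assumes — with known ground truth, so
recovery can be asserted rather than eyeballed.

**Behaviour.** Offers are uniform over the 101-point grid; a block flagged
as a repeat reuses its reference block's cue sequence element-wise (as
stimulation-on blocks repeat the preceding block's sequence). Choices
follow the logit with per-block coefficients; the default session has
$(a, b, c) = (6, -8, -1)$ in Stim-off and the airpuff weight scaled to
$b = -12$ in Stim-on and Follow-up — a ground-truth CBR increase of 50%,
within the range where the area-based classifier sits near its detection
threshold (across seeds, `%dAv` for this shift spans roughly 3–10%, which
is realistic for a moderately effective site). Omissions are independent at
3%; reaction times are a baseline plus a Gaussian conflict bump peaking at
the decision boundary plus noise, giving the characteristic RT ridge.

**LFP network.** Each region is a beta-resonant AR(2) process (poles at
20 Hz, modulus 0.85) embedded in a VAR with lag-1 directed coupling, plus
$1/f$ noise generated by spectral shaping of white noise (exponent $-1$).
Configurations are validated by the spectral radius of the companion matrix
(non-stationary settings are rejected by name). The default network is the
hierarchy dlPFC → pACC → sgACC → striatum (chain gains 0.2, a direct
dlPFC → striatum edge 0.12) with weak bottom-up feedback (adjacent 0.05,
striatum → dlPFC 0.03). The feedback is not decorative: in a purely
feed-forward chain the DAI saturates at $\pm1$ *independent of the
top-down gain*, so no stimulation effect on directional asymmetry could
exist in the model at all. Reciprocal coupling between identically resonant
nodes is strongly destabilising, which bounds how large the feedback can be
at this pole radius — the defaults sit comfortably inside the stability
region (companion radius ≈ 0.89). Stimulated blocks halve the top-down
gains and multiply the bottom-up gains by 1.5, reproducing the combination
the analysis is designed to detect: reduced top-down influence together
with strengthened bottom-up influence. Per-trial beta amplitude on each
channel is scaled by $g_0 + g_u \cdot \mathrm{Eutil}(\mathrm{trial})$
(standardised), creating utility-tuned P/N-type beta responses. All
randomness flows from one integer seed through documented per-trial and
per-channel sub-streams, so identical seeds give identical arrays.

**What the generator does not emulate.** Real LFPs are not VAR processes:
the generator has no cross-frequency coupling, no nonstationarity within
trials, no volume conduction, no spiking, and its $1/f$ background is
exactly a power law. Passing recovery tests on this model demonstrates that
the estimators are correct and calibrated under the assumed statistical
structure — it does not validate the biological conclusions on real data.
Archetype matrices for clustering tests are noise-corrupted copies of five
prototype surfaces (utility-positive, utility-negative, low-airpuff band,
decision-boundary band, reward-extremes band) with labels retained.

# Numerical choices and problem sizes

Degenerate inputs fail loudly: all-one-choice data raise a separation
error, constant matrices make the correlation distance undefined by name,
constant series flag the Granger test as degenerate instead of returning a
p-value, and zero-variance groups return `NaN` with a flag rather than a
fabricated p-value. Windows with no trials are excluded from both masks of
a stimulation contrast. The test suite and the acceptance script size their
simulations to finish in minutes on one core: sessions of 250 trials per
block for behavioural calibration (200 no-change replicates), 10,000 trials
for coefficient recovery, 200 × 1.5 s trials for the GC oracle, 100 seeded
network realisations of 30 trials for direction recovery, and 20 channel
pairs per region pair for the block contrast. These sizes are the package's
choices; every one of them can be scaled up by the corresponding argument.

# Limitations

Granger estimates are pairwise (no conditioning on the remaining regions),
so indirect influence appears as direct edges; direction signs are still
recovered reliably on the default network, but individual DAI magnitudes
fold in proxy effects — visible, for instance, as a narrow sign dip near
the resonance for the weakly coupled dlPFC–striatum pair. Time-varying
coupling within trials, conditional GC and non-classical MDS are out of
scope. The P/N labelling rule assigns the two extreme clusters per side by
construction, which is only meaningful when the mixture has enough
components to leave middle clusters unlabelled.
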