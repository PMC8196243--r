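---
title: "Models and methods behind fefattn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fefattn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fefattn` analyses how local blockade of ionotropic glutamate receptors
(NMDA- and AMPA-type) changes the excitability and the attentional
modulation of frontal eye field (FEF) neurons recorded during a covert
spatial-attention task. Because raw recordings of this kind are not
publicly available, the package is built around a synthetic-session
generator with explicit ground truth: every analysis stage is exercised,
and validated, against data whose generative parameters are known.

This vignette documents the generative model, the estimators, the
parameters that matter (with defaults and reasons), the numerical
choices, and what a green test does and does not establish.

## The task world

A trial: the animal fixates, three moving gratings appear (one inside the
recorded neuron's receptive field, RF), a colour cue 300-1400 ms later
marks the behaviourally relevant grating, and up to three sequential
luminance dimmings follow at 600-1750 ms intervals; the cued (target)
dimming must be reported within 600 ms. Drug application alternates in
blocks of at least 36 scheduled trials (2 repeats of 3 attention locations
x 2 motion directions x 3 dimming orders); error trials are re-queued
within their block. The first six trials of each block are flagged because
iontophoretic drug onset and washout lag by roughly half a minute; the
filter stage (`filter_trials()`), not the generator, removes them, along
with error trials, and flags conditions left with fewer than 10 trials.

Analysis windows are half-open, in ms relative to their anchor:
`post_stim` = [100, 400) after stimulus onset, `post_cue` = [100, 400)
after cue onset, `pre_dim` = [-500, 0) before the first dimming (target or
distractor), plus a `baseline` window [-300, 0) before stimulus onset used
only for response typing. The half-open convention and the baseline window
are package choices; the other three windows follow the emulated study.

## The spike-count model

Spiking is inhomogeneous Poisson with piecewise-constant epoch rates.
For unit $i$ on trial $t$ the rate in epoch $e$ is

$$\lambda_{ite} = G_{it}\; b_i\; g_{ie}\; a_{it}\; d_{it},$$

where $b_i$ is the baseline rate, $g_{ie}$ the epoch gain (stimulus
transient over [stim, stim+400), post-cue sustained, pre-dimming level),
$a_{it}$ the attention factor (applied from cue onset onward on attend-RF
trials), $d_{it}$ the drug factor (drug-on blocks only), and $G_{it}$ a
trial-wise excitability gain, gamma distributed with mean 1 and variance
$\sigma^2_G$. Counts in a window of expectation $\mu$ are then negative
binomial with

$$\mathrm{Var} = \mu + \sigma^2_G\,\mu^2,$$

which is exactly the model the gain-variance stage fits; $\sigma^2_G = 0$
recovers Poisson counts. The gamma law for $G$ is a package choice (the
fitted model determines only the first two moments).

### Defaults, and why

| parameter | default | reason |
|---|---|---|
| baseline rate | log-normal, median 20 spikes/s (sdlog 0.5) | sustained FEF rates; 10 expected counts in the 0.5 s pre-dim window, the regime in which the gain term dominates Poisson noise |
| attention effect (central) | 1.4 | population AUROCs around 0.65-0.75 |
| attention spread (sdlog) | 0.6 | per-unit effects spanning roughly 1.1-2.0, giving the recorded AUROC spread (~0.55-0.9) |
| drug gain (central) | 0.75 | central drug modulation index (1-g)/(1+g) = 0.143, the recorded population regime |
| DrugMI relative spread | 1.0 | MI SD ~ 0.15 across units, i.e. Cohen's D near 0.9, including a minority of drug-enhanced cells |
| attention x drug interaction (sdlog) | 0.25 | single cells whose attentional modulation is individually altered by the drug while the population mean change is ~0 |
| gain variance $\sigma^2_G$ | 0.2 | Fano factors of 2-4 at pre-dim rates, typical of frontal recordings |
| error rates | 0.002 each (miss, false alarm, break) | hit and correct-rejection rates of 0.998 |
| trials/condition | 60 | the recorded median |

The heterogeneity components deserve emphasis. With *identical* units the
paired no-drug/drug AUROC comparison across 100 units has a standard
error of ~0.004, and a genuine property of finite counts becomes
statistically visible: scaling the rate by $g<1$ scales the gain-variance
term of the count variance by $g^2$ but the Poisson term only by $g$, so
the drug condition is relatively noisier and its true AUROC is attenuated
by roughly 0.005-0.012 at 10 expected counts. Real populations never
occupy this homogeneous regime — their between-cell spread (of attention
effects, drug effects, and genuine per-cell interactions) dominates the
paired SE — so the generator's defaults include all three spreads. With
spreads disabled the attenuation is measurable and significant; the
package documents rather than hides this.

All generator entry points require an explicit integer seed and derive
independent substreams per purpose (trials, spikes, waveforms, eyes), so
identical (config, seed) pairs reproduce byte-identical sessions.

## Waveforms and the narrow/broad divide

Ground-truth peak-to-trough (P2T) widths are drawn from a two-component
mixture straddling 240 us (narrow ~ N(160, 25), broad ~ N(380, 55),
mixing 0.39/0.61). Waveforms are emitted on the 30.72 us acquisition grid
(32 556 Hz) as two Gaussian lobes — a dominant negative trough and a
slower positive afterpotential — with the peak-lobe centre calibrated by
root finding so the continuous template's trough-to-peak distance equals
the planted value exactly.

The classifier spline-interpolates (cubic, natural boundary) to 5.4 us,
normalises polarity so the larger extremum is the trough (a peak
preceding the trough after normalisation is reported as a polarity error,
never silently flipped), measures trough-to-subsequent-peak, and applies
the 240 us cutoff (narrow iff P2T <= 240, boundary inclusive). The cutoff
is adopted verbatim, not re-derived, because its placement relative to
the bimodal dip is dataset-specific.

Bimodality is checked with Hartigan & Hartigan's dip statistic,
implemented from scratch in C++ (the iterative greatest-convex-minorant /
least-concave-majorant algorithm) because no dip implementation is
available in the target environment. It was validated against the
reference CRAN implementation on thousands of fuzzed samples during
development; frozen reference values live in the test suite. One
deliberate divergence: an all-identical sample returns dip 0 (degenerate,
trivially unimodal) rather than 1/(2n). The p-value is calibrated by
Monte Carlo against uniform null samples of the same size (default
10 000 draws; fewer than 1000 warns), with the add-one estimator, and
bimodality is declared at p < 0.01.

## Cell-class clustering

Candidate features per unit: P2T, firing rate, Fano factor, ISI
irregularity (CV, CV2, Lv; ISIs pooled across trials and never spanning
trial boundaries; fewer than 3 ISIs marks the features missing), and
attentional AUROC. Features are min-max standardised to [0, 1].

The dissimilarity pre-screen is greedy forward selection: repeatedly keep
the feature explaining the most residual variance of the full
standardised matrix (least-squares projection) until >= 90% is explained.
This is an approximation of the cited procedure, which the source does
not restate; it is deterministic and drops near-duplicate features (CV2
tracking CV) by construction.

K-means (via `stats::kmeans` behind a seeded-replicate contract) runs
`realizations` seeded realizations x `replicas` random centroid
initialisations per k in 3..8, keeping the best replicate by
within-cluster sum of squares. Information criteria use the
classification likelihood of a diagonal-covariance Gaussian mixture with
hard assignments and mixing proportions ($k(2d+1)-1$ parameters); AIC
and BIC are minimised (ties to smaller k). The often-quoted spherical
equal-variance correspondence was rejected during development because it
provably over-splits well-separated Gaussian clusters at these sample
sizes: splitting an m-point cluster gains about $0.64\,m$ in deviance
against a fixed $2d$ AIC penalty, independent of cluster separation. The
per-cluster per-dimension variances plus the proportion term make
pure-noise splits pay for themselves, and the 2d-per-cluster parameter
count matches how published FEF clustering analyses of this kind space
their AIC and BIC values. "Realizations" re-seed initialisations only
(no unit subsampling).
Stability thresholding reports, per unit, the fraction of realizations in
which it co-clusters with the majority of its final cluster; units below
0.9 are flagged unstable.

Printed information-criterion values from the recorded dataset are
data-bound and are not reproduction targets; the recovery tests instead
plant well-separated feature clusters and require AIC/BIC to select the
planted k with adjusted Rand >= 0.95.

## Attention and drug metrics

* **AUROC**: $P(r_{RF} > r_{away}) + \tfrac12 P(=)$ over all trial pairs
  (Mann-Whitney correspondence; midranks). Both attend-away locations are
  pooled. Computed per drug state on pre-dim rates (and per epoch).
* **Flip convention**: units with no-drug AUROC < 0.5 (attention
  suppresses firing) have both drug states transformed $x \to 1-x$; the
  decision uses the no-drug value only, strict inequality.
* **DrugMI** = (activity_no-drug - activity_drug)/(sum), computed per
  stimulus condition (3 attention x 2 motion) and averaged, per epoch.
* **Cohen's D'** = mean-rate difference over pooled SD (n-1 weighting).
* **ANOVA gate**: three-factor fixed-effects ANOVA (attention x drug x
  motion) on single-trial pre-dim rates; attention-modulated = significant
  attention main effect OR any interaction involving attention (p < 0.05),
  drug-modulated analogously. Sums of squares are Type II via model
  comparison; the synthetic design is balanced up to error re-queueing, so
  the SS types essentially coincide. Note the OR-combination over four
  terms has a null flag rate of $1 - 0.95^4 \approx 18.5\%$ by
  construction; the 5% calibration applies to each component p-value.
* **Response typing** (order: visuo-attention, visual, attention, other)
  uses the 20% rules on baseline, post-stimulus transient and attend-RF
  pre-dim rates. The "attention" class requires pre-dim >= 1.2 x baseline
  and >= the transient (the source's wording "20% larger than baseline and
  stimulus-induced activity" is ambiguous; this reading satisfies its
  worked examples). Zero baselines are floored at 0.5 spikes/s
  (configurable) before computing percentages.
* **Population summaries**: peak-normalised PSTHs averaged with SEM;
  paired t on no-drug vs drug AUROC per group with Cohen's Dz; one-sample
  t on DrugMI with Cohen's D; mixed between-within (split-plot) ANOVA via
  `aov` error strata with partial eta squared; Benjamini-Hochberg FDR for
  post hocs.

## Variability

Fano factor = count variance / count mean (pre-dim window). The
gain-variance fit estimates $\sigma^2_G$ by profile maximum likelihood in
the $(\mu, \sigma^2_G)$ parameterisation ($\mu$ = sample mean, its MLE),
falling back to the moment estimator $(v - m)/m^2$ with a flag if
optimisation fails. Fits are per stimulus condition; fitted terms are
averaged across the 2 attend-RF conditions and, separately, the 4
attend-away conditions, per drug state. The fit is not attempted when the
sample variance is below the mean (the model cannot represent
under-dispersion): with truly Poisson data this gate triggers in about
half of finite samples, which is expected behaviour, not an error.
Under the generative model FF = $1 + \sigma^2_G\mu$, so a drug that only
scales $\mu$ lowers FF while leaving $\sigma^2_G$ unchanged — the
dissociation the variability stage is designed to expose.

## Behaviour

d' = $\Phi^{-1}(hit) - \Phi^{-1}(fa)$, with rates of exactly 0/1 clipped
to 1/(2N) when a trial count is supplied. The 3-dimming guessing model
gives a chance hit rate of 1/3. RTs are divided by their session's grand
mean (all conditions pooled); attention x drug effects are tested on
single-trial normalised RTs with a two-factor ANOVA and rank-sum post
hocs. Error rates use Pearson chi-square (1 df, no continuity correction)
on drug x correct/incorrect counts with fixation breaks discarded.

Microsaccades: 250 Hz x/y traces over [fixation + 300 ms, first dimming);
velocity by 5-point moving-window differentiation; per-axis median-based
SD estimate; elliptic threshold at lambda = 6 SDs; minimum duration 3
samples (12 ms). These detector constants follow the cited
velocity-threshold method's conventions (the source does not restate
them) and are configurable. The generator injects minimum-jerk
displacement steps (default 12 ms duration, log-normal amplitudes with
median 0.4 deg, direction uniform, 0.02 deg sensor noise) and stores
ground truth; at these defaults the detector's first suprathreshold
sample coincides with the injected onset, which is what makes the
+-1-sample onset criterion meaningful.

## The two-stage network

A proof-of-concept, not a fitted model: can neurons whose NMDA
conductance is locally reduced retain attentional modulation because the
surrounding intact population keeps driving them? The architecture is a
desk-scale two-stage attractor circuit: two sensory populations (40 LIF
neurons each) feed two integration ("decision") populations (60 each)
that compete through a shared inhibitory pool (50), with
integration-to-sensory feedback. Synapses are conductance-based AMPA
(tau 2 ms), NMDA (two-variable gating with saturation, tau 100 ms, Mg2+
voltage dependence $1/(1 + [Mg]/3.57\,e^{-0.062V})$) and GABA (tau 5 ms);
all-to-all uniform connectivity within blocks lets the simulator track
population-aggregated gating, and the C++ core integrates 2 s at
dt = 0.05 ms in well under a second.

Attention is a bias on the feedback: the D2 ("attend away") branch's
feedback weight is weakened by 60%, so D1 wins the competition in ~93% of
runs. Cross-excitation between the assemblies and moderate inhibition
keep the winner-take-all *soft* — the original architecture's hard
competition had to be relaxed for exactly the reason the source
describes, and it is what produces attentional AUROCs spanning ~0.78 to
1 rather than sitting uniformly at ceiling. Static per-neuron drive
heterogeneity (SD 1 mV) spreads rates within subgroups so the paired
affected-vs-unaffected AUROC test has non-degenerate variance.

In each decision population, three subgroups of 10 neurons have their
incoming NMDA conductances scaled by 0.60, 0.75 and 0.90 (40/25/10%
reductions); the remaining 30 are unaffected, with the first 10 serving
as the matched benchmark. Per run, stimulus-period rates (excluding the
first 200 ms of transient) give: the attentional AUROC per scaling level
(D1 subgroup vs matched D2 subgroup, 10 vs 10 neurons) and the rate
modulation index (unaffected vs reduced subgroup within D1). Across 100
seeded runs the package's tests require: best unaffected AUROC > 0.99; no
significant paired affected-vs-unaffected AUROC difference; median MI > 0
at every reduction, ordered 40% > 25% > 10%.

Every constant lives in `network_config()` — none are published by the
source, which points to its own code repository for details — and the
tuning procedure was: balance the operating point analytically
(steady-state gating, Mg factor at -55 mV), then adjust feedback bias
and inhibition so the qualitative claims above hold robustly across
seeds, *before* freezing the acceptance tests.

## What a green test establishes

The synthetic world emulates the study's trial structure, count
statistics, waveform bimodality, behavioural error regime and
fixational-eye-movement statistics. It does not emulate: non-Poisson
spike-history structure (refractoriness, bursting) beyond the gain model;
drift and nonstationarity within sessions; correlated variability across
simultaneously recorded units; real waveform shape diversity; or saccade
kinematics beyond a minimum-jerk step. Green pipeline tests therefore
establish estimator correctness and internal consistency (parameter
recovery, calibration, invariances) — not that the estimators would
behave identically on the recorded data, whose statistics are only
approximated here.

## Known limitations

* The Type II ANOVA helper refits nested models per term; it is exact but
  not fast, and is intended for per-unit trial tables, not large designs.
* The NB profile MLE constrains $\sigma^2_G$ to a bracket scaled by the
  moment estimate; pathological samples fall back to moments (flagged).
* The network is a demonstration circuit: sizes, conductances and the
  bias are package choices validated against qualitative claims only.
* The dip test's Monte-Carlo calibration assumes exchangeable draws from
  a uniform null; it calibrates the test size, not its power.
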