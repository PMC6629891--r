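---
title: "Methods: decomposing sleep EEG into concurrent vigilance states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decomposing sleep EEG into concurrent vigilance states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Conventional sleep scoring assigns each 30-s polysomnography epoch a single
stage (W, N1, N2, N3, REM), presuming that the brain occupies one global
vigilance state at a time. Yet wake-like and sleep-like activity can be
present concurrently, and such concomitance is a candidate substrate for the
mismatch between objective and subjective sleep in insomnia disorder.
`sleeptopics` implements a fully data-driven alternative: every epoch is
expressed as a *mixture* of six latent vigilance states ("topics"), and the
mixtures are summarized into dominance, co-occurrence and transition
statistics that can be compared between groups.

## The pipeline

1. **Preprocessing** (`preprocess_recording()`). Four derivations (C3-A2,
   O1-A2, EOGL-A2, EOGR-A1) are band-pass filtered forward and reverse in
   time with 4th-order Butterworth designs (-3 dB per pass at 0.3–35 Hz for
   EEG, 0.3–10 Hz for EOG), optionally after downsampling to the 250 Hz
   analysis rate with an 80 Hz antialiasing low-pass. Epoch quality is
   screened with three statistics per channel — standard deviation, range,
   and range of the first difference — and an epoch is rejected when the
   channel-mean of any statistic exceeds `median + 4 * MAD` over the night
   (unscaled MAD, upper one-sided; a zero MAD is floored at 1e-12 so exact
   ties survive). Rejected epochs are excluded downstream and break temporal
   adjacency.
2. **Symbolization** (`symbolize_recording()`). Each 1-s bin of each stream
   gets a band power (rectangular-window FFT, two-sided bins inside the
   half-open band, normalized to estimate the band's variance contribution)
   or, for the third EOG stream, the zero-lag Pearson correlation of the two
   EOG leads within the bin. Per stream, values are mapped to quantile
   categories computed from the participant's own distribution (quintiles
   V/L/M/H/E for the 8 EEG streams; quartiles V/L/H/E for the 3 EOG
   streams). Moving 3-s windows with 1-s steps, confined to the epoch, turn
   30 letters into 28 three-letter words; counting words yields one document
   per epoch over a 1,192-word namespaced vocabulary
   (8 x 5^3 + 3 x 4^3).
3. **Topic model** (`train_lda()`, `infer_mixtures()`). A K = 6 Latent
   Dirichlet Allocation model is estimated by collapsed Gibbs sampling;
   applying a trained model to new epochs uses fold-in Gibbs with the
   topic-word distributions held fixed. Posterior means over retained sweeps
   give the per-epoch 6-vector of topic probabilities (summing to 1).
   Topics are ranked T1..T6 by a depth score — the expected C3-A2 delta
   quantile level minus the expected beta level under each topic — so T1 is
   deep-sleep-related and the last topic wake-related; near-ties are broken
   by the expected EOG cross-correlation level (eye movements rank later).
4. **Vigilance metrics** (`analyze_cohort()` and friends). The dominant
   topic is the argmax (ties to the lower index). Epochs in runs of at
   least three consecutive epochs with the same dominant topic are *stable*;
   runs never span artifact gaps. For stable epochs the dominant probability
   is the *dominance* and the remaining five probabilities, renormalized to
   1, the *co-occurrence*. Transition probabilities count, per source topic,
   the dominant topic of the epoch immediately following each stable epoch,
   normalized by the number of such stable epochs (the diagonal continuation
   term is retained, so rows sum to 1; rows without observations are
   missing). Per participant we also report the overall mean mixture and the
   percentage of kept epochs that are stable, per type and in total.
5. **Cohort statistics** (`compare_cohort_groups()` and friends).
   Participant-level measures (overall probabilities, stable-time
   percentages, transition probabilities) are compared with a Wilcoxon
   rank-sum test (mid-ranks; tie-corrected normal approximation with
   continuity correction; exact enumeration when n + m <= 10). Dominance
   and co-occurrence vary epoch-wise with unequal counts per participant,
   so they are modeled with linear mixed-effects models (maximum
   likelihood): outcome ~ group + centered age + sex indicator + (1 |
   participant), with t and p from residual degrees of freedom
   (observations minus fixed parameters), matching epoch-scale inference.
   Severity analyses replace group by the ISI total, or by the seven ISI
   items; partial correlations (residual Pearson, t transform with
   n - k - 2 df) relate transition probabilities to the ISI controlling for
   age and sex. Alpha is 0.05 with no multiplicity correction by default
   (a Benjamini–Hochberg switch exists but is off).

## The synthetic-data generator

Raw study recordings of this kind are generally not shareable, so the
package ships a generator that produces cohorts with *known* ground truth.

**Hypnograms** follow a 5-state Markov chain at the 30-s epoch scale; the
default matrix yields roughly 10% W, 5% N1, 45% N2, 20% N3, 20% REM with
consolidated deep-sleep and REM runs, and nights start predominantly awake.

**Signals.** Each EEG channel is, per epoch, a sum of four independent
band-limited Gaussian noise components (delta/theta/alpha/beta) whose SDs
come from the epoch's stage profile; EOG channels carry low-frequency
(0.3–5 Hz) noise plus ~1-s smoothed eye-movement deflections with opposite
polarity on the two leads (negative cross-correlation), frequent in REM/W,
absent in N3. Band-limiting uses the squared-magnitude (zero-phase,
two-pass) response of the same Butterworth designs the analyzer uses,
applied spectrally: each epoch is drawn as a Hermitian white spectrum shaped
by the envelope, which is distributionally identical to zero-phase-filtering
white noise and about four times cheaper. A lognormal per-epoch, per-band
variance jitter (`epoch_jitter_sd = 0.3`) emulates the natural
epoch-to-epoch power variability within a stage.

**Stage profiles.** The defaults encode the qualitative stage semantics
(N3: high, consistent delta/theta, EOG delta spill; N1: low delta,
intermediate alpha, intermediate-to-high beta, slow eye movements; W: high
alpha — occipital-dominant — and beta; REM: globally low power with rapid
eye movements) while keeping the *total* variance of the five stages in a
compressed range. Real N3 has substantially larger overall amplitude than
REM; we deliberately compress that contrast because the 4-MAD artifact
screen is a pure outlier rule: against a discrete mixture of stage clusters
with literal amplitude contrasts it rejected 15–25% of perfectly clean
epochs, whereas the compressed profiles give the realistic 5–8%. Stage
discrimination is carried almost entirely by band composition, which is
what the symbolization consumes; absolute per-stage power levels are
consequently not calibrated to clinical microvolt values.

**Slow-wave depth.** Within N3 runs a slowly varying two-state factor
(default deep/light multipliers 1.5/0.6 on the delta variance and the EOG
delta spill, persistence 0.9 per epoch) emulates the waxing and waning of
slow-wave activity. Besides realism, this is structurally important: with
six topics and five homogeneous stage archetypes, the model's sixth topic
would land haphazardly; genuine depth gradation inside deep sleep
reproducibly yields the two deep-sleep-related topics (T1, T2) that the
vigilance-topic literature describes, with the remaining topics for N2,
N1, REM and W.

**Concomitance.** The construct under study — light-sleep signatures inside
deep sleep — is injected at the sub-epoch level: in a configurable
fraction (`placement`) of N3 epochs, each 1-s bin independently carries
the N1 variance profile with probability `w` (EOG noise variance, burst
rate and burst duration blend at the epoch level). The temporal
formulation is essential, not cosmetic: we initially blended the spectra
uniformly across the epoch and found the effect largely invisible — a
stationary variance blend of two states is a *different single spectrum*,
which a bag-of-words mixture model attributes to the nearest single
topic, whereas a mixture of intruder-state seconds and base-state seconds
produces a genuine mixture of word types, which is exactly what the
topic mixture and the co-occurrence measure are built to detect. It also
matches the construct's definition as simultaneous *and sequential*
expression of two vigilance states within one epoch. Each affected epoch
draws its own intrusion fraction from a Beta with mean `w`
(`heterogeneity` = concentration, default 3): most affected epochs are
partially touched (raising N1-topic co-occurrence while deep-sleep
dominance persists) and a minority are predominantly intruded (flipping
dominance and generating deep-to-light transitions). The per-epoch
fractions use a quantile transform of common uniforms, so increasing `w`
increases every epoch's intrusion monotonically under a fixed seed.
Defaults (ID mean weight 0.45 vs control 0.05, `placement` 0.55,
`heterogeneity` 3) were calibrated once so that, at study-like scale, the
simulated case-control contrast reproduces the order of magnitude of the
published effects (co-occurrence of the light-sleep topic inside stable
deep-sleep epochs elevated by roughly a third to a half, and a
several-fold higher deep-to-light transition probability); they were
fixed before the acceptance checks were frozen and are not revisited.

**Cohorts** (`make_cohort()`). Group sizes default to 64 controls / 55
cases; cases draw the intrusion weight from a Beta with mean 0.30 versus
0.05 for controls; ISI totals (controls 3.8 +/- 3.7, cases 16.5 +/- 4.3,
truncated to 0..28) share a latent Gaussian with the weight (default
correlation 0.6), so the co-occurrence/severity association is recoverable;
ISI items allocate the total over 7 bounded (0–4) items one point at a
time. Ages and sex ratios mirror a typical middle-aged insomnia cohort. A
default full-scale night is ~230 MB of signal, so `signals = FALSE` plus
`realize_recording()` streams nights one at a time.

**The reference model is trained on good sleepers, stage-balanced.** The
published procedure applies a topic model trained once on an independent
dataset of normal sleep. We found this detail to be load-bearing twice
over. First, trained on a mixed case-control cohort, the LDA dedicates a
topic to the intrusion pattern itself and the N1-topic co-occurrence
signal dilutes; trained on intrusion-free sleepers, contaminated epochs
can only be explained as mixtures of pure-state topics — exactly what the
co-occurrence measures are designed to detect. Second, under realistic
stage prevalences N1 occupies only a few percent of epochs, too few for
the model to allocate it a topic (it splits an abundant stage instead);
`train_reference_model()` therefore trains on nights in which every stage
is equally represented in consolidated runs, and then identifies each
stage's topic from the training mixtures. `match_topics_to_stages()` does
the same for any analyzed cohort.

## What the synthetic tests do and do not show

Passing the suite demonstrates that the chain — symbolization, topic
estimation and inference, stable-epoch metrics, group statistics — is
internally correct, recovers known parameters, respects its normalization
contracts, and detects an injected concomitance effect in the right
direction with calibrated type-I error under the null. It does *not* show
that real sleep EEG is described by stage-pure band-limited Gaussian noise:
the generator has no spindles, K-complexes, sawtooth waves, 1/f background,
movement or electrode artifacts, and no within-stage autocorrelation beyond
the hypnogram. Conclusions about real recordings require real recordings.

## Numerical and design choices

- Band edges (unstated in the source conventions): delta [0.5, 4), theta
  [4, 8), alpha [8, 13), beta [13, 35) Hz; EOG power [0.3, 5) Hz. With 1-s
  windows the FFT resolution is 1 Hz, so delta maps to bins 1–3 Hz.
- 1-s FFT windows are rectangular and non-overlapping; quantile cutoffs are
  inverse-ECDF (type 1) with ties assigned to the lower category; cutoffs
  are computed over artifact-free bins by default (`cutoff_scope = "all"`
  switches to the whole recording).
- The EOG cross-correlation is zero-lag Pearson within the bin (a single
  value per bin is required by the letter scheme).
- LDA hyperparameters default to alpha = 0.8 (admits mixed epochs without
  forcing uniformity — dominance would be flattened by a large alpha) and
  eta = 0.1; estimation is collapsed Gibbs (500 burn-in + 100 averaged
  sweeps for training, 50 + 20 for fold-in by default). Per-epoch
  probabilities are posterior means, not single samples.
- Dominance ties break to the lower topic index; the degenerate case
  dominance = 1 defines co-occurrence as uniform 1/5.
- The transition denominator is per source topic (stable epochs of that
  topic with a successor); the tiny published switch probabilities are only
  consistent with a per-stable-epoch denominator. A pooled normalization is
  available via the counts matrix.
- Mixed models use ML (not REML) and residual-df p values; Satterthwaite
  approximations are out of scope.
- The problem sizes used by the acceptance checks (e.g. nights of 300
  epochs at 100 Hz, 20 + 20 participants per replicate cohort, training
  corpora of 5,000 documents) are the package's reduced-scale study
  conditions, chosen to keep full end-to-end replication cheap while
  leaving every mechanism — including artifact gaps and stage mixing —
  exercised.

## Known limitations

- K = 6 is fixed; the original model-order selection (SVM agreement with
  manual scoring) is out of scope, as is any variational inference path.
- The generator's stage profiles are calibrated to qualitative
  descriptions, not to quantitative spectra of real cohorts; absolute
  microvolt levels are intentionally compressed (see above).
- Sleep-cycle structure and within-night temporal dynamics of topics are
  not modeled or measured.
- With very short or heavily rejected nights, transition rows and
  stable-type summaries are frequently missing; downstream comparisons
  drop missing rows, mirroring the unequal-expression handling of the
  published tables.
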