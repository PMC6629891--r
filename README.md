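# sleeptopics

Sleep EEG as a mixture of concurrent vigilance states.

Standard sleep scoring forces every 30-s polysomnography epoch into a single
stage, hiding moments where wake-like and sleep-like activity coexist —
a phenomenon of particular interest in insomnia disorder, where patients
report wakefulness that conventional scoring cannot see. `sleeptopics`
implements a data-driven decomposition: band-pass-filtered EEG/EOG is cut
into 1-s bins, each bin's band power is mapped to a participant-specific
quantile letter (V/L/M/H/E), moving 3-s windows form spectral "words", and
each epoch becomes a word-count document over a 1,192-word vocabulary
(2 EEG channels x 4 bands x 5^3 words + 2 EOG power streams x 4^3 + an EOG
cross-correlation stream x 4^3). A six-topic Latent Dirichlet Allocation
model (collapsed Gibbs sampling, Rcpp) then expresses each epoch as a
probability mixture over latent vigilance states ranked from
deep-sleep-related (T1) to wake-related (T6):

- **dominance** — the probability of the most likely topic in a *stable*
  epoch (a run of >= 3 epochs sharing a dominant topic),
- **co-occurrence** — the remaining topics' probabilities renormalized to 1,
- **transition probabilities** p(Ti -> Tj) from stable epochs to their
  successors,

plus overall topic means and stable-time percentages. Cohort comparisons
use Wilcoxon rank-sum tests (tie-corrected, exact for small samples),
epoch-level linear mixed-effects models (`outcome ~ group + age + sex +
(1 | participant)`, via lme4), partial correlations with the Insomnia
Severity Index (ISI), and ISI-item regressions.

Because raw clinical EEG of this kind is not distributable, the package
includes a first-class synthetic polysomnography generator: Markov-chain
hypnograms, stage-dependent band-limited noise on two EEG derivations with
slowly varying slow-wave depth inside N3, eye-movement bursts on two EOG
derivations, and an injectable, intermittent "light-sleep-inside-deep-sleep"
intrusion whose strength is higher in the simulated insomnia group and
correlated with ISI — so the entire pipeline can be validated against known
ground truth.

## Worked example

The study design the package mirrors: a topic model is trained once on
good sleepers and then applied to every night of a case-control cohort.

```r
library(sleeptopics)

# reference model: 8 stage-balanced good-sleeper nights at 100 Hz
ref <- train_reference_model(seed = 101)
ref$stage_map                      # which topic plays which stage's role
#>   W  N1  N2  N3 REM
#>   6   5   2   1   4

# a small synthetic case-control cohort: 6 controls, 6 insomnia cases,
# 240 epochs (2 h) per night; cases carry the light-sleep intrusion
spec <- cohort_spec(n_control = 6, n_id = 6, n_epochs = 240, fs = 100)
cohort <- make_cohort(spec, seed = 5, signals = FALSE)
an <- analyze_cohort(cohort, model = ref$model, seed = 9)

# co-occurrence of the N1-related topic (T5 here) inside stable epochs
# dominated by the deep-sleep topic (T1), by group
rec <- an$records
sel <- rec$stable_type == "T1"
tapply(rec$cooc_T5[sel], rec$group[sel], mean, na.rm = TRUE)
#> control      ID
#>  0.1122  0.1528

# probability of switching from a stable T1 epoch to a T5-dominated epoch
tapply(an$transitions[, 1, 5], an$summary$group, mean, na.rm = TRUE)
#> control      ID
#>  0.0085  0.1407
```

The printed numbers come from an actual run of the above (R 4.3): the
simulated insomnia group shows more light-sleep probability inside its
deepest sleep (0.15 vs 0.11) and a much higher deep-to-light transition
probability (0.14 vs 0.01) — the directions the method is designed to
detect, because the generator injected a stronger N1 intrusion into the ID
group's N3 epochs. `compare_cohort_groups(an)` runs the full statistical
battery (rank-sum tests for participant-level measures, mixed-effects
models for dominance and co-occurrence) over all measures.

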