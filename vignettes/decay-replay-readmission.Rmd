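---
title: "Careflow models, decay replay and readmission risk: the methods behind dreamHF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Careflow models, decay replay and readmission risk: the methods behind dreamHF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The prediction problem

Heart-failure (HF) patients discharged from an ICU stay face a high risk of
returning to hospital unplanned within 30 days. dreamHF models that risk
from the *shape and timing* of a patient's hospital history rather than
from a flat snapshot of variables: each patient's admissions become an
ordered, timestamped event log; a Petri-net careflow model is mined from
the training logs; replaying a patient's log on the net with per-place
decay functions yields a Timed State Sample (TSS) at the moment of the
index discharge; and a three-branch neural network combines the TSS with
demographics and Charlson/Elixhauser severity scores into a readmission
probability.

The prediction target is binary: the next admission after the index
discharge is unplanned (emergency or urgent) *and* begins within 30 days
(boundary inclusive -- "within 30 days" is read as $\le 30$, and the
inclusive convention is pinned by a unit test at gaps of 29, 30 and 31
days).

# Cohort construction

A patient enters the cohort when four conditions hold simultaneously:

1. the *index admission* -- the most recent admission that still has at
   least one later admission -- carries an HF ICD-9 diagnosis
   (398.91, 402.01, 402.11, 402.91, 404.01, 404.03, 404.11, 404.13,
   404.91, 404.93, or any 428.xx; the 428 family is matched by prefix,
   all others exactly, after stripping the decimal point);
2. at least one admission precedes the index admission (the careflow
   model needs history to replay);
3. at least one admission follows it (evidence the patient is alive and
   still in the system);
4. the patient carries no death flag.

Patients whose HF codes appear only in earlier admissions are excluded.
When several HF admissions could serve as the index, we take the latest
one that leaves a successor; the alternative of treating every qualifying
HF admission as its own instance is deliberately not implemented, keeping
one prediction per patient.

The cohort splits randomly into train/validation/test at 73.1/12.9/14.0%.
Sizes are computed by largest-remainder rounding so they always sum to
the cohort size exactly, and the shuffle is seeded.

# From tables to event logs

Every admission of every member (prior admissions plus the index
admission) emits a fixed repertoire of event types. Millisecond offsets
impose a strict, deterministic order on events that share a clock second;
because replay measures time in days, a millisecond carries essentially
zero decay and changes no information -- it only fixes the order.

| event | timestamp rule |
|---|---|
| admission type | admit time |
| insurance type | admit time + 1 ms |
| lab Mean (per analyte) | first measurement time |
| lab Std, single measurement | Mean event + 1 ms |
| lab Std, repeated measurements | last measurement time |
| Elixhauser group events | discharge − (m−i+1) ms for the i-th of m groups, canonical group order |
| artificial event | first code observation + 1 ms, clipped to discharge − 1 ms |
| discharge | discharge time |

Notes on the open points we had to fix:

* *Comorbidity placement.* The groups scored for an admission are placed
  "very close to" the discharge with +1 ms steps; we anchor the block so
  its last event lands exactly 1 ms before the discharge and order groups
  by their canonical Elixhauser index. This is deterministic and keeps
  every comorbidity event strictly pre-discharge.
* *Artificial events.* Each admission's ordered ICD-9-procedure + CPT
  code sequence is vectorized (hashed bag of 1-grams and 2-grams,
  dimension 256) and clustered by k-means into k = 30 clusters; the
  cluster label becomes one synthetic event per admission. The clustering
  is fitted on training admissions only and is deliberately pluggable --
  any map from code sequence to one of k names fits the interface, since
  the literature this abstraction follows does not pin the vectorizer.
  Procedure codes carry no timestamp of their own, so a sequence
  containing procedures anchors at the admit time; otherwise at the first
  CPT chart time. The timestamp is clipped to 1 ms before discharge on a
  strict 1 ms grid (a half-millisecond offset could not survive
  millisecond-resolution XES round trips), with a priority-ordered bump
  pass resolving any residual tie deterministically.
* *Lab std with one measurement.* The standard deviation of a single
  measurement is taken as 0 and its event emitted 1 ms after the Mean
  event, so presence/timing information is never silently dropped.
* A column records the TSS-collection marker: the index admission's
  discharge event. Nothing after the marker may influence any feature;
  property tests edit post-marker events at random and assert the TSS is
  bit-identical.

# Process discovery and decay replay

The miner is a deterministic directly-follows construction: traces are
padded with START/END; every directly-follows pair (a, b) seen at least
`frequency_threshold` times becomes a place connecting the labeled
transitions a and b, plus a marked source place feeding START and a sink
fed by END. Two guard rails keep the net well-formed at any threshold:

* *orphan rescue* -- a transition whose every incoming (or outgoing) pair
  fell below the threshold keeps its single highest-count pair, so every
  transition always has at least one input and one output place;
* an OTHER transition with a self-loop place absorbs event names outside
  the training vocabulary at replay time, preventing silent model growth
  on validation/test data.

Replay semantics are the package's own, documented choice (the source
method defers to its replay reference and any replayable net can be
substituted through PNML): firing the transition of an event consumes one
token -- from the place of the directly preceding pair when it is marked,
else from the first marked input place -- and produces one token into
*every* output place. When no input place is marked, a missing token is
inserted, counted, and consumed; an insertion is itself a token arrival.
Under this rule a training log replays with zero insertions at threshold
1, which a strict AND-join firing rule could not guarantee on logs with
alternative predecessors. The marking vector can retain tokens produced
into alternatives that were never consumed; it is read as an activity
footprint rather than a reachable Petri-net marking, and a configuration
flag can restrict the TSS to decay values only.

Each place carries a linear decay function
$v_p(t) = \max(0,\ \beta - \alpha_p\,(t - t^{\mathrm{last}}_p))$
with $\beta = 1$ for every place, reset to $\beta$ on token arrival.
Fixing $\beta$ makes decay values directly comparable across places and
bounded in [0, 1] without normalization. Rates are fitted on the training
replay as $\alpha_p = \beta / D_p$, where $D_p$ is the largest
within-trace token inter-arrival time observed at place p (in days; the
records' native resolution); places never re-activated fall back to the
maximum trace duration. The TSS at the marker concatenates decay values,
cumulative token-arrival counts and the marking, one entry per place.

# The classifier

Three branches -- TSS, demographics (standardized age, gender and
ethnicity one-hots), severity scores (Charlson, Elixhauser) -- each pass
through three fully connected ReLU layers, with batch normalization after
the first hidden layer of each branch and dropout 0.2 after hidden layers
one to three. Branch outputs are concatenated, pass one post-concatenation
hidden layer, and a 2-unit softmax emits class probabilities. Training is
Adam on categorical cross-entropy for 100 epochs at batch size 10;
validation AUROC is recorded each epoch and the weights of the best epoch
are kept. The network is implemented natively on BLAS matrix operations
with hand-derived gradients; the test suite validates every gradient
(including the batch-norm backward pass) against central finite
differences, and validates eval-mode determinism (dropout off, running
batch-norm statistics).

Hidden widths (128/64/32 per branch, 64 post-concatenation) and the Adam
step size (1e-3) are configuration defaults, since the source
architecture fixes depth, batch size, epochs, dropout and normalization
but not widths or learning rate. Branch depth and the presence of the
post-concatenation layer are themselves configurable, which is what the
layer-ablation driver varies (1-4 branch layers; removing the
post-concatenation layer).

The classification threshold for precision/sensitivity/accuracy/F-score
defaults to 0.5 on the positive-class softmax output and is exposed in
configuration -- the operating point behind the published headline
metrics is not recoverable, so we state ours.

Severity scoring uses the Quan ICD-9-CM mappings for both indices,
shipped as versioned CSVs. The Elixhauser score is the unweighted group
count by default -- the natural reading of an index contrasted with
Charlson's "higher weights" -- with van Walraven weights behind a flag.
Charlson applies its three canonical hierarchy rules (complicated
diabetes over uncomplicated, moderate/severe liver over mild, metastasis
over malignancy). Scores pool diagnosis codes from all admissions up to
and including the index admission: the discharge-anchored reading is the
one stated with an explicit leakage rationale, and it is asserted by
tests that add post-index admissions and expect unchanged scores.

# Baselines

Six classical learners -- SVM (RBF), k-nearest neighbours, decision tree,
random forest and two gradient-boosted tree variants (depthwise and DART
boosting) -- are each grid-searched over small published-default grids,
the winner chosen by validation AUROC. Two input modes exist. In
*tabular* mode the models see the variables in their original flat
per-admission form: the index admission's type, insurance, per-analyte
lab mean/std and Elixhauser indicators, plus demographics and the
severity scores. Prior-visit history reaches this mode only through the
severity scores -- the multi-admission record is precisely what the
event-log representation adds, and keeping it out of the flat table is
what the comparison is about. In *tss* mode the baselines receive exactly
the NN's concatenated inputs, isolating the contribution of the network
architecture from that of the representation.

# The synthetic EHR generator

Real ICU records of this shape are credential-restricted, so the package
carries a generator that emulates the source schema: patients with
repeated admissions, elective/emergency/urgent admission types, five
insurance categories, repeated measurements of four HF-relevant analytes
(BUN, serum creatinine, sodium, NT-proBNP, with the published cohort
means/sds as defaults), ICD-9 diagnosis codes drawn from the Quan
Elixhauser families, procedure/CPT code sequences, a 10% death-flag rate,
and ISO-8601 second-resolution timestamps on a synthetic calendar
starting 2100-01-01 (de-identified-style future dates). 90% of patients
are structurally guaranteed eligible (a prior admission, a future
admission, an HF code in the index admission); the remainder violate one
criterion each so the exclusion rules are exercised. Inter-admission gaps
are drawn from a mixture with both short (2-25 day) and long (35-300 day)
components, so the 30-day label boundary sees traffic from both sides.

The latent mechanism: each patient draws a standard-normal severity z.
The probability that the admission following the index discharge is
unplanned-within-30-days is
`plogis(qlogis(readmit_base_rate) + signal_strength * z)` with a default
base rate of 0.235, the published cohort's readmission level. Severity
shifts the observable data in three ways, each chosen once to make the
signal recoverable through both the event route and the tabular route at
realistic strength: Elixhauser group prevalences shift by +0.15 per sd of
z (clipped to probabilities), the emergency-admission log-odds by +0.8
per sd, and the BUN/creatinine/NT-proBNP means by +0.1 single-measurement
sd per sd of z. The lab shift is deliberately the weakest: patient
histories pool roughly ten repeated measurements, which multiplies the
effective lab signal by about sqrt(10), and the lab family is meant to be
informative but the least important one, matching the attribution
ordering the method reports on real data. At `signal_strength = 2` the
latent Bayes AUROC is about 0.865 and logistic regression on the
observable features recovers about 0.83.

What the generator does *not* emulate: realistic marginal value
distributions (labs are Gaussian), chart events and notes, coding noise
beyond a flat 80% per-admission re-coding rate of chronic conditions,
transfers and same-hospital ward moves, and any correlation structure
between comorbidity groups beyond the shared latent severity. Passing
tests therefore demonstrate that the pipeline recovers a known latent
mechanism through the full representation stack -- they say nothing about
performance on real clinical data.

# Evaluation machinery

AUROC confidence intervals use DeLong's structural-components variance
(via pROC behind the package's interface); the test suite checks the
point estimate against an exhaustive pairwise U-statistic, the interval
against a 2000-replicate bootstrap, and its empirical coverage over 500
Gaussian-shift simulations (accepting 93-97%). Cohort comparison runs
chi-square tests for categorical variables and two-sided t-tests for
continuous ones at p < 0.05, with zero-variance variables reported as
p = 1 with a note.

Grouped Shapley attribution works at the level of the six variable
families (severity, admission events, demographics, artificial events,
comorbidity events, lab events): Monte-Carlo permutations over groups,
masked groups imputed with training means. Because masking is
mean-imputation, contributions telescope and per-instance efficiency
holds exactly for every sampled permutation -- the tests verify the
closed form on a linear surrogate and the dummy-player property on a
model that ignores a group. TSS columns map to families by the event that
refreshes the place (its source transition); careflow-skeleton places
(START/END/OTHER, source/sink, discharge-fed pairs) count as admission
events.

# Problem sizes and numerical choices

The test suite runs the full pipeline at ~3000 cohort members (the scale
of the published cohort) for the signal-recovery checks, with the network
trained for 20 epochs there; the null-signal band is asserted on each
model's mean test AUROC over three replicate seeded cohorts, because a
single ~420-patient test split measures a null AUROC with a standard
error of ~0.027 and a band of ±0.05 around chance would otherwise be a
coin flip over seven models. Base-rate calibration uses 20000 patients
against a three-standard-error binomial band. Oracle-equivalence replay
checks run >1000 randomized cases on toy nets. Timestamps live on a
strict 1 ms grid (doubles are exact there); decay uses days; k-means uses
10 restarts under a fixed seed; ties in event ordering resolve by a fixed
event-type priority followed by +1 ms bumps.

One practical numerical observation: with batch-size-10 Adam over
thousands of minibatch steps, the trained network is sensitive to
floating-point summation order at the level of the third decimal of
AUROC — bitwise-identical inputs and seeds can reach different local
optima across processes. Wherever a *ranking* is asserted (e.g., which
variable family dominates the attribution), the package's tests therefore
use means over repeated retrainings, the same repeated-run protocol used
for the ablation studies.

# Known limitations

* The discovery algorithm is a directly-follows net, not a
  behaviourally minimal model; any externally mined PNML net can be
  dropped in, which is the intended escape hatch.
* The marking component of the TSS reflects the single-consume replay
  semantics (an activity footprint), not classical reachability.
* The artificial-event vectorizer is one defensible instantiation of an
  underspecified abstraction; treat cluster identities as arbitrary
  labels.
* Elixhauser group detection applies no between-group hierarchy, by
  contract; only Charlson applies its canonical hierarchy rules.
* The generator's independence assumptions (conditional on one latent
  severity) are far simpler than real comorbidity structure; external
  validity claims require real data.
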