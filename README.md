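# dreamHF

Predicting unplanned 30-day readmission of ICU heart-failure (HF)
patients from the *shape and timing* of their hospital history.

Flat tabular snapshots of a patient (one row of labs, codes and
demographics) discard the longitudinal structure that clinicians actually
reason about: how often the patient has been admitted, how acutely, how
recently, and what happened each time. dreamHF treats the electronic
health record as a **clinical event log** — for every hospital admission
it emits timestamped events for the admission type, insurance, HF-relevant
lab measurements (BUN, serum creatinine, sodium, NT-proBNP), Elixhauser
comorbidity groups, abstracted procedure/CPT code sequences and the
discharge — mines a **Petri-net careflow model** from the training logs,
and replays each patient's history on the net with **per-place decay
functions**

&nbsp;&nbsp;&nbsp;&nbsp; v_p(t) = max(0, β − α_p · (t − t_p^last)),&nbsp;&nbsp; β = 1,&nbsp; α_p = β / D_p,

where t_p^last is the last token arrival at place p and D_p the largest
within-trace inter-arrival time seen at p during training replay (in
days). The vector of all places' decay values, cumulative token counts
and marking, captured at the **index discharge** (the Timed State Sample,
TSS), is a leakage-safe numeric summary of the patient's careflow up to
the moment of prediction. A **three-branch neural network** (TSS /
demographics / Charlson + Elixhauser severity scores; three ReLU layers
per branch, batch normalization after each branch's first layer, dropout
0.2, one post-concatenation layer, 2-unit softmax; Adam, batch size 10)
turns it into a readmission probability:

&nbsp;&nbsp;&nbsp;&nbsp; P(unplanned readmission ≤ 30 d) = softmax(NN(TSS, demographics, severity))

The label is TRUE iff the first admission after the index discharge is of
emergency/urgent type and begins within 30 days (inclusive).

Because the clinical source data of this shape is credential-restricted,
the package ships a **synthetic EHR generator** with a configurable
latent-severity mechanism — readmission probability
`plogis(qlogis(0.235) + signal_strength · z)` for a standard-normal
per-patient severity z that also shifts comorbidity prevalences, admission
acuity and lab means — so every stage is testable end to end, from CSV
tables through XES event logs, PNML nets, decay replay, training and
evaluation (DeLong AUROC intervals, grouped Shapley attribution,
variable/layer ablation). Classical baselines (SVM, kNN, decision tree,
random forest, two gradient-boosted variants) run in both a flat tabular
input mode and the TSS input mode for comparison.

Who this is for: researchers in clinical process mining and readmission
modelling who want a complete, inspectable, dependency-light reference
implementation of the event-log → decay-replay → multi-branch-classifier
pipeline, with the simulation harness needed to validate each stage.

## Worked example

```r
library(dreamHF)

cfg    <- synthetic_config(n_patients = 500, seed = 7, signal_strength = 2)
tables <- generate_ehr(cfg)                 # 7 MIMIC-shaped relational tables
cohort <- select_cohort(tables)             # HF inclusion/exclusion + label
#> <hf_cohort> 411 members, 131 (31.9%) readmitted unplanned
split  <- split_cohort(cohort, seed = 7)    # 73.1 / 12.9 / 14.0 %

art    <- fit_artificial_events(tables, split$train, k = 30, seed = 7)
log    <- build_event_log(tables, split$train, art)
#> <hf_event_log> 300 cases, 11825 events, 78 event names
net    <- discover_petri_net(log)
#> <petri_net> 774 places, 81 transitions, 1546 arcs
alphas <- estimate_decay_rates(net, log)

bundles <- assemble_features(tables, split, net, alphas, art)
model <- build_network(ncol(bundles$train$tss),
                       ncol(bundles$train$demographics),
                       ncol(bundles$train$severity),
                       nn_config(epochs = 20, seed = 7))
model <- train_network(model, bundles$train, bundles$validation)
#> <dream_nn> branches 128-64-32, post-concat 64; inputs 2322/8/2; best epoch 1 (val AUROC 0.766)

classification_metrics(predict(model, bundles$test), bundles$test$label)
#> AUROC 0.862 [0.762-0.963]  precision 0.556  sensitivity 0.833  accuracy 0.828  F 0.667  (n=58, 12 positive)
```

Reading the output: 411 of 500 simulated patients meet the inclusion
rules (an HF code in the index admission, at least one prior and one
later admission, alive); at `signal_strength = 2` the latent mechanism
raises the readmission fraction above the 23.5% base rate (31.9% here).
The training logs span 78 distinct event names, whose directly-follows
relations become the 774 places of the careflow net; each patient is then
a 2322-dimensional TSS plus 8 demographic and 2 severity features. On the
58 held-out test patients the network reaches AUROC 0.862 with a wide
DeLong interval — this is a deliberately small demonstration cohort; the
test suite runs the same pipeline at ~3000 members, where the network
recovers AUROC ≈ 0.84 against a latent Bayes ceiling of 0.865.

One call runs all of it with artifacts and manifests on disk
(`run_pipeline(pipeline_config(), "run-dir")`), and
`inst/scripts/dreamhf.R` wraps that for the shell. `model_shapley()`
attributes predictions to the six variable families; `ablation_run()`
re-executes the pipeline with one family or network layer removed.

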