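# notemia

Membership-inference auditing of multilabel clinical-note classifiers —
with a key-phrase-driven synthetic-note generation pipeline for testing
whether synthetic training data changes what a model leaks.

## What problem this addresses

A diagnosis-coding model trained on clinical notes exposes per-code
probability vectors.  A membership-inference attack (MIA) uses only
those vectors to decide whether a given note was in the model's
training set — a serious privacy breach wherever training-set
membership is itself sensitive.  Two common mitigations are
de-identification (stripping PHI tokens before training) and replacing
the training notes with LLM-generated synthetic notes.  `notemia`
provides the full experimental machinery to measure both, end to end,
on a built-in synthetic corpus, for:

- **privacy researchers** auditing text classifiers with a calibrated,
  protocol-exact attack suite;
- **clinical-NLP engineers** quantifying the privacy–utility trade-off
  of training-set size, note truncation and synthetic-data generation.

## The core quantities

The victim is a bidirectional-LSTM ICD coder with per-label attention
(hidden states *H*, per-label attention `A_l = softmax(U_l' tanh(W H))`,
label vector `v_l = H A_l`, one sigmoid output per code).  Utility is
reported as micro/macro AUC, precision, recall, F1 and P@k.  The
attacker scores every note once via the balanced, stratified two-fold
protocol (larger class subsampled; leftovers scored by the final fold's
attacker) using five attack models (threshold margin, logistic, k-NN,
random forest, MLP), and reports

- **attacker advantage** = max over score thresholds of (TPR − FPR),
  0 = no leakage, 1 = total leakage;
- **attack AUC** over the membership ROC.

## Worked example

```r
library(notemia)

u    <- build_code_universe(n_codes = 20, seed = 11)
corp <- generate_corpus(u, corpus_config(
  n_notes = 800, seed = 11, note_length_tokens = c(60, 100),
  signature_injection_rate = 1, label_noise_rate = 0.5))

res <- run_real_experiment(
  corp, u,
  classifier_config(epochs = 100, max_note_tokens = 64, patience = 0,
                    seed = 5),
  attack_config(seed = 3))
print(res$attack)
```

```
membership-inference attack report
  threshold     advantage 0.7598  AUC 0.9076  <- best
  logistic      advantage 0.1214  AUC 0.5390
  knn           advantage 0.1357  AUC 0.5883
  random_forest advantage 0.3625  AUC 0.7219
  mlp           advantage 0.0902  AUC 0.5048
```

The fixture is deliberately half-learnable (`label_noise_rate = 0.5`),
so 100 epochs of training memorize the 560 training notes while test
performance stays capped: the victim's confidence gap between member
and non-member notes is large, and the best attacker separates members
with advantage ≈ 0.76.  Train the same victim for 1 epoch instead and
the advantage collapses toward the null noise floor — that gradient,
not any single number, is the audit's finding.  Scrubbing the PHI
sentinel tokens before training (`scrub_phi`) leaves the advantage
essentially unchanged: de-identification does not defeat membership
inference.

The synthetic path replaces training text before the victim ever sees
it:

```r
syn <- run_synthetic_experiment(
  corp, u, extractor_config(top_n = 60),
  classifier_cfg = classifier_config(epochs = 15, max_note_tokens = 512,
                                     patience = 0, seed = 5),
  attack_cfg = attack_config(seed = 3))
```

Key phrases are extracted from each real train/val note (two
statistical scorers, fuzzy de-duplication, ordered by appearance),
packed into a generation prompt, and rendered by a deterministic
offline stub backend; the victim trains on the synthetic notes only and
is evaluated on real test notes, with the attack mounted on its
real-note prediction vectors.

## Command line

```sh
Rscript inst/cli/notemia.R generate-corpus --n-notes 800 --n-codes 20 \
    --seed 11 --out corpus.jsonl
Rscript inst/cli/notemia.R keyphrases --in corpus.jsonl --top-n 60 \
    --out phrases.jsonl
Rscript inst/cli/notemia.R gen-notes  --in corpus.jsonl --top-n 60 \
    --seed 11 --out synth.jsonl
Rscript inst/cli/notemia.R train --train corpus.jsonl --val corpus.jsonl \
    --n-codes 20 --seed 11 --out model.rds
Rscript inst/cli/notemia.R predict --model model.rds --notes corpus.jsonl \
    --out preds.tsv
Rscript inst/cli/notemia.R attack --member-preds train_preds.tsv \
    --nonmember-preds test_preds.tsv --seed 3 --out attack.json
```

Every stage is byte-identical under a fixed `--seed`.

## Scope

The built-in corpus emulates the statistical structure the pipeline
needs (skewed code prevalence, code-conditional signature phrases,
PHI sentinels, idiosyncratic filler) — it is not clinically realistic
text, and absolute numbers here do not transfer to real data.  See the
methods vignette (`vignettes/privacy-audit.Rmd`) for the models,
protocol details, fixture design rationale and limitations.
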