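---
title: "Auditing membership leakage of clinical-note classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing membership leakage of clinical-note classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A classifier that assigns diagnosis codes to free-text clinical notes can
leak whether a particular person's note was in its training set: a
membership-inference attack (MIA) feeds the victim model a note, observes
the per-code probability vector, and classifies the note as *member* or
*non-member* from the shape of that vector alone.  Two mitigation ideas
recur in practice: de-identification (removing the HIPAA PHI token
categories before training) and replacing the training notes with
LLM-generated synthetic notes.  `notemia` packages the machinery to test
both ideas quantitatively: a seeded synthetic corpus, a label-attention
BiLSTM victim classifier, a key-phrase-driven synthetic-note generator
with a deterministic offline backend, and a shadow-model attack suite
with calibrated metrics.

Everything runs at desk scale on one CPU; no protected data, network
access or credentials are involved anywhere.

## The synthetic corpus

Real discharge summaries are gated behind data-use agreements, so the
package ships a generator that emulates the statistical structure the
pipeline relies on rather than any real corpus:

* **Skewed label prevalence.** Code `j` of `L` receives Zipf weight
  `1/j` (normalized); label sets are drawn by per-code independent
  Bernoulli trials with rates scaled to a target mean cardinality
  (default 3) and resampled when empty.  This mirrors the dominance of a
  few frequent codes in hospital data.
* **Code-conditional signal.** Each code owns a few multi-token
  *signature phrases* drawn from a reserved vocabulary disjoint from the
  background filler.  With injection rate `r`, each phrase of each
  assigned code is embedded in the note with probability `r` (twice by
  default — clinical findings tend to be restated).  At `r = 1` the task
  is fully learnable; at `r = 0` the text carries exactly zero label
  information, which gives a clean null for classifier calibration.
* **Idiosyncratic surface form.** Filler tokens are sampled from a fixed
  embedded vocabulary of ~1700 morpheme-composed clinical-sounding words
  plus common connectives, chunked into sentences.  Per-note filler is
  what an over-trained victim memorizes, as the idiosyncratic phrasing
  of real notes would be.
* **PHI surrogates.** Bracketed sentinel tokens (`[name-…]`, `[date-…]`,
  `[loc-…]`, `[id-…]`) are inserted at token boundaries at a Poisson
  rate.  Real de-identified corpora use bracketed placeholders too; the
  sentinel syntax makes scrubbing exact, hence testable
  (`scrub_phi(inject_phi(x)) == x`).
* **A partial-learnability knob.** `label_noise_rate` leaves a code in a
  note's label set but suppresses its phrases, capping achievable test
  performance while leaving train-set memorization unconstrained.  The
  overfitting fixtures below are built with this knob.

What the generator does **not** emulate: clinical semantics, real ICD
co-occurrence structure, negation, abbreviation noise, section headers,
or inter-note duplication.  A green test suite therefore demonstrates
that the *machinery* behaves as specified under controlled signal and
leakage conditions — not that any particular real-world corpus is safe
or unsafe.

## Key-phrase extraction

The generation pipeline condenses each note into an ordered phrase list.
Text is preprocessed (lowercase; numeric tokens removed; characters
other than letters, sentence enders and newlines stripped), and all
1–3-gram candidates that stay inside one sentence and do not begin or
end with a stopword are enumerated.  Two scorers rank them:

* **Frequency–position scorer:**
  `score = tf × 1/(1 + first_offset/doc_length) × B^(len−1)` with boost
  `B = 2` — frequent, early, multi-word phrases win.  Candidates below
  the least-allowable-seen-frequency (`lasf`, default 1) are discarded.
* **Multi-feature scorer:** each term gets a multiplicative badness from
  position (later is worse), normalized frequency (rarer is worse) and
  sentence dispersion (concentrated is worse); phrase badness is
  `∏ term_badness / (tf × (1 + Σ term_badness))` and the exposed score
  is its negation, so "larger = better" holds module-wide.

Both scorers are specification-level statistical extractors in the
spirit of the classic frequency/position and context-statistics
families; exact parity with any particular library is not a goal.  Ties
are always broken by earlier first offset, then lexicographically, so
rankings are deterministic.

Each ranking is de-duplicated by a similarity threshold (default 0.70):
the matching-blocks ratio `2M/(|a|+|b|)` for one scorer, the Levenshtein
ratio `(|a|+|b|−d)/(|a|+|b|)` for the other, matching the two fuzzy
de-duplication conventions in common use.  The merge step takes the top
`⌈top_n/2⌉` from each ranking, scans them **interleaved** (a1, b1, a2,
b2, …), drops ratio-duplicates plus token-level containment duplicates,
sorts the survivors by first occurrence in the note, and truncates to
`top_n`.  Two consequences were design goals: shrinking `top_n` selects
a prefix of the larger selection (the phrase-count sweep is monotone by
construction), and no phrase in a prompt is a sub-phrase of another
(without the containment rule, short sub-phrases slip past the ratio
threshold and later make in-order coverage measurement ambiguous).

The default `top_n` of 60 is half the default corpus's mean note length
in tokens, the same proportion the phrase-count experiments use as their
anchor.

## Prompt construction and the offline backend

Two instruction templates are supported, differing only in wording
(variants `v0301` and `v0613`); both name a word budget (default 2250)
and append the comma-separated ordered phrase list with the requirement
that phrases appear *sequentially*.  Generation backends are a small
contract: `generate(prompt, max_completion_tokens, seed)` plus a
determinism flag, with outputs capped at 3000 whitespace tokens by
default.  The shipped stub backend embeds every phrase verbatim, in
order, inside seeded connective sentences; seeds vary only the
connective filler, never phrase tokens.  The stub's connective
vocabulary is disjoint from the corpus filler vocabulary so a stub
sentence can never pre-empt a phrase's first occurrence — in-order
coverage of stub output is 1 by construction and the coverage metric
(`present fraction`, and longest-increasing-subsequence order fraction)
measures real deviations only.  Whitespace tokens stand in for model
tokenizer counts throughout; the budgets are proxies, documented as
such.  A live-LLM adapter can implement the same contract but is
deliberately outside the test surface.

## The victim classifier

The utility model is a bidirectional LSTM over learned word embeddings
with a per-label attention head and `L` independent sigmoid outputs:

```
H  = BiLSTM(E[tokens])          # T x 2u
Z  = tanh(W H)                  # da x T
A_l = softmax_t(U_l' Z)         # attention of label l over tokens
v_l = H A_l ; logit_l = O_l' v_l + b_l
```

Training minimizes summed per-label binary cross-entropy with Adam
(learning rate 0.01, batch 16), optional early stopping on validation
micro-F1, and full seeding of initialization and epoch order.  Forward
and backward passes are compiled (RcppArmadillo) with analytically
derived gradients; the test suite checks every parameter block against
central finite differences at `1e-5` relative tolerance, and checks that
the standalone R attention head reproduces the compiled prediction path
to `1e-12`.

Desk defaults are embedding 32, hidden 16 per direction, attention 16:
small enough that the 1/10/100-epoch overfitting ladders run in minutes
on one CPU, and demonstrably large enough to drive the fully-injected
fixture above 0.85 micro-F1 and to memorize an 800-note training split.
The tokenizer is plain whitespace with a frequency-capped vocabulary
built from the training split only; the attack protocol is
representation-agnostic, so sub-word refinements are out of scope.

## Metrics

* **Micro averaging** pools all `n × L` (note, code) pairs into one
  binary problem; **macro** averages per-label metrics.  Precision,
  recall and F1 binarize at a configurable threshold (default 0.5, with
  the 0/0 → 0 convention); AUC is threshold-free with grouped-tie
  handling (a constant score column scores exactly 0.5).  Labels with a
  single class in the truth have no defined AUC and are excluded from
  the macro AUC mean, with the exclusion count reported.
* **Precision@k** is the fraction of the k highest-probability codes
  that are true, averaged over notes, with probability ties broken by
  label index.
* **Attack metrics**: the ROC over all score thresholds yields the
  attacker advantage `max(TPR − FPR)` — never negative, since the
  degenerate threshold achieves 0 — and the trapezoid AUC.

One calibration subtlety is worth stating explicitly.  On a *no-signal*
corpus the pooled micro AUC does **not** sit at 0.5: skewed prevalence
is itself an informative prior across labels (frequent codes get high
constant scores and are more often positive), and the package's null
test observed pooled values near 0.78 with zero text signal.  The
prevalence-blind macro AUC is the correct near-chance null statistic,
and that is what the calibration test asserts.

## The attack protocol

The shadow-model construction uses the victim itself as its own shadow
(the worst-case, owner-side audit): prediction vectors of the training
split are labelled *member*, those of the held-out split *non-member*.
Score assignment follows the balanced stratified-fold protocol exactly:

1. **Balance**: keep `min(m, k)` samples per class; subsample the larger
   class uniformly without replacement; record the leftovers.  For the
   canonical worked sizes m = 4033, k = 1729 this yields 1729 per class
   and 2304 leftover members.
2. **Stratified unshuffled folds** (default 2): fold membership is by
   position within each class in original input order (contiguous
   blocks), so the protocol is deterministic given the balance draw.
3. For each fold, an attacker is trained on the remaining folds and
   scores the held-out fold; **leftover** samples are scored by the
   final fold's attacker.  Every sample is scored exactly once —
   1729 + 1729 + 2304 scores in the worked example.

Five attackers are implemented: a model-free *threshold* attack scoring
the mean confidence margin `mean(|p − 0.5|)` (the attacker sees only
prediction vectors, never true labels, so margin rather than loss),
plus logistic regression, 5-NN, a 100-tree random forest and a
one-hidden-layer MLP (8 units, weight decay `1e-3`), all emitting
member-class probabilities.  With `multilabel = TRUE` the feature map is
the identity on the probability vector; otherwise vectors are sorted
descending so the attacker sees confidence shape only.  The suite
reports per-model advantage/AUC and selects the best by advantage with
ties broken in a fixed model order.

Null calibration is part of the deliverable: on exchangeable member and
non-member vectors (both i.i.d. uniform, 1000 per class) the best-model
advantage stays within the max-over-thresholds noise floor (asserted
≤ 0.10 as a 10-seed mean) and AUC within 0.5 ± 0.05.  Note that a
maximum over ROC points is biased upward at finite n, which is why the
null bound is not 0.

## Experiment designs

* **Real-victim audit** (`run_real_experiment`): train on the train
  split, evaluate utility on the test split, attack with train-vs-test
  prediction vectors.
* **Synthetic-victim audit** (`run_synthetic_experiment`): extract
  phrases from the real train+val notes, generate synthetic
  replacements (ids, labels, splits preserved), train the victim purely
  on synthetic text, evaluate utility on the *real* test notes, and
  attack with the victim's prediction vectors for the *real* train
  (member) versus *real* test (non-member) notes.  The structural point
  — the membership dataset is built from real-note vectors on both
  sides even though the victim never saw real training text — is
  asserted in the tests.
* **Trade-off sweeps** (`run_tradeoff_sweep`): training-size ×
  note-length for real victims, training-size × phrase-count for
  synthetic ones, with seed replicates and mean/sd summary rows,
  emitted as a delimited table sorted by size then second axis
  descending.  Desk-scale defaults (sizes 800/600/400, caps 256/128/64
  tokens, phrase counts 60/30/15) preserve the 1 : 0.75 : 0.5 and
  4 : 1 shape of the reference sweeps at reachable sizes.  Seed
  replication is an engineering addition — single-value-per-cell
  reporting hides Monte-Carlo spread.

The overfitting fixtures deserve a note.  The epoch ladder (1/10/100)
and the PHI comparison both use an 800-note corpus with full signature
injection and `label_noise_rate = 0.5`: half the assigned codes are
text-silent, capping generalization, while the idiosyncratic filler
lets long training memorize the training split.  This is a *designed*
leakage gradient — the fixture exists to produce a controllable
generalization gap, and the tests assert the qualitative ordering
(advantage non-decreasing in training epochs; scrubbing PHI sentinels
moves the overfit victim's advantage by less than the seed noise while
leakage stays high).

## Numerical and reproducibility choices

* All randomness flows from one integer master seed through named child
  seeds (`child_seed(seed, "stage")`, a small deterministic hash into
  `[1, 2^31−2]`), so each stage is independently reproducible and
  re-running one stage does not disturb another.
* Softmax rows are max-shifted before exponentiation; BCE probabilities
  are clamped to `[1e-12, 1 − 1e-12]`.
* LSTM forget-gate biases initialize at 1; other parameters are
  Glorot-uniform from the seeded R stream (never the C++ RNG, for
  cross-platform determinism; epoch permutations are likewise drawn in
  R and passed down).
* Serialization: corpora as JSON-lines with fixed key order; prediction
  matrices as tab-delimited text at 17 significant digits (round-trips
  beyond 12 significant digits); models via RDS with bit-identical
  reloaded predictions.
* Degenerate inputs: empty notes vectorize to a single padding id;
  single-token attention reduces to the identity; empty phrase lists
  are an error at prompt construction; a training fold that loses a
  class is a protocol error rather than a silent skip.

## Problem sizes

The shipped test-and-audit configurations use 20-code universes with
300–800-note corpora, 64–128-token caps for real victims (512 for
synthetic ones, whose stub notes are longer), 15-epoch utility
training, and 1/10/100-epoch ladders over 3–5 seeds — sizes chosen so
the full audit cycle completes in minutes on a single CPU while leaving
all qualitative contrasts (learnability, overfitting gradient,
phrase-count trade-off) comfortably outside noise.

## Known limitations

* The corpus is a statistical emulation; absolute utility or leakage
  numbers here do not transfer to any real dataset.
* The stub backend cannot exhibit LLM failure modes (hallucinated
  codes, phrase paraphrasing, refusal); the backend contract is where a
  live adapter would plug in, untested here by design.
* Attacks are black-box over prediction vectors only; white-box attacks
  (gradients, attention maps) and multi-shadow constructions are out of
  scope.
* Token budgets count whitespace tokens, not model-tokenizer tokens.
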