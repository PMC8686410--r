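---
title: "Radical-augmented Bi-LSTM-CRF tagging of Chinese ADE narratives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radical-augmented Bi-LSTM-CRF tagging of Chinese ADE narratives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Chinese adverse drug event (ADE) reports carry a free-text narrative —
the story of why a drug was given, what was given, and what went wrong —
that structured report fields do not capture. `radner` extracts that
information as typed character spans with three entity types:

* **Reason** — the disease, symptom, or treatment motivating drug use;
* **Drug** — generic names, trade names, and mixed-script abbreviations
  such as `10% GS`;
* **ADR** — the adverse reaction itself.

Because the confidential pharmacovigilance corpora this task is defined on
cannot be shipped, the package pairs the tagger with a synthetic narrative
generator so that the entire pipeline — corpus I/O, training, decoding,
and evaluation — is exercisable and testable end to end from a fresh
install.

## The model

Input is character-level: each Chinese character is a token. Every
position receives the concatenation

$$x_t = [\,w_t \,\|\, r_t\,]$$

of a token vector $w_t$ and a radical vector $r_t$. The radical vector is
looked up through the character's canonical Kangxi radical (1–214, with 0
as the sentinel for non-CJK characters), so characters that share a
semantic class marker — 痛, 疹, 病 all carry the sickness radical 疒 —
share a feature even when the characters themselves are rare. Variant
surface forms normalize to the canonical radical (the three-dot water in
液 counts as 水, 85).

The sequence of $x_t$ is encoded by a bidirectional LSTM (one cell per
direction, hidden states concatenated per position), projected by a single
affine map to per-tag emission scores, and decoded by a linear-chain CRF
over the 7-tag BIO alphabet (`O`, `B-`/`I-` per type). A path
$y_1 \ldots y_T$ is scored

$$s(y) = \mathrm{start}_{y_1} + \sum_t e_{t,y_t} +
  \sum_{t>1} A_{y_{t-1},y_t} + \mathrm{end}_{y_T},$$

training maximizes the path log-likelihood $s(y) - \log Z$ with the exact
log-partition computed by the forward recursion in log space, and
prediction uses Viterbi decoding. All of this — the LSTM with
backpropagation through time, the CRF forward/backward recursions and
their gradients, and the Adam optimizer — is implemented in vectorized
base R and verified against brute-force path enumeration and
finite-difference gradients in the test suite.

### Token features are a pluggable contract

The architecture does not care where $w_t$ comes from. The default
provider is a trainable character-lookup table (width 64) with an `<UNK>`
row; a `contextual_adapter` provider accepts any external function that
maps a character sequence to fixed-width vectors, which is where a
fine-tuned transformer encoder plugs in when one is available. Training a
transformer is explicitly out of scope here: at package scale the lookup
provider is what trains, and the adapter is a prediction-time contract
checked by a stub in the tests. Swapping providers changes vector content
only, never shapes.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `batch_size` | 16 | sequences per Adam update |
| `lstm_hidden` | 128 | hidden units per direction |
| `token_dim` | 64 | lookup-provider vector width |
| `radical_dim` | 20 | radical vector width |
| `learning_rate` | 5e-5 | Adam step size |
| `max_len` | 512 | sequence length incl. `[CLS]`/`[SEP]`/`[PAD]` |
| `epochs` | 20 | training passes |
| `dropout` | 0.1 | on the Bi-LSTM output, training only |
| `clip` | 5 | global gradient-norm ceiling |

The headline defaults (batch 16, hidden 128, radical width 20, learning
rate 5e-5, length 512) are the reference experimental settings for this
architecture. One deserves a warning: **5e-5 is a fine-tuning rate.** It
is the right order of magnitude when the token provider is a pretrained
contextual encoder and the tagger only needs adjustment. When the lookup
provider is trained from random initialization, roughly 260 Adam updates
(200 documents, batch 16, 20 epochs) at 5e-5 move each parameter by at
most ~0.013 — the model cannot leave its random regime, and measured
held-out F1 stays at 0. The package therefore trains its synthetic-corpus
models at `learning_rate = 1e-3`, the standard Adam rate for from-scratch
LSTM-CRF taggers; the default is left at 5e-5 so that the configuration
surface matches the reference settings it documents.

Epoch count, dropout and clipping have no stated reference values and are
set to conventional ones (20, 0.1, 5.0); all are configurable. Illegal BIO
transitions (e.g. `O → I-Drug`) are learned rather than forbidden by
default; `mask_illegal = TRUE` hard-masks them to $-\infty$.

## Sequence handling

Documents longer than `max_len − 2` are split before encoding. The split
point prefers the last sentence-final punctuation mark (。？！；) inside
the window and otherwise falls back to a hard cut at the limit; in either
case the cut moves left until no entity span is bisected, so every entity
survives intact in exactly one fragment (an entity longer than the window
is rejected). Fragment predictions are mapped back to whole-document
offsets before evaluation, so splitting can never manufacture or destroy
strict matches. Model sequences are `[CLS] text [SEP] [PAD]…` with a mask
that is true exactly on real characters; control tokens never reach the
encoder, contribute nothing to the likelihood, and cannot appear inside
decoded spans.

BIO tag sequences decode totally: a stray `I-T` without a compatible
predecessor starts a new entity (the conlleval repair), so prediction
never fails on an ill-formed path. Viterbi ties break toward the lowest
tag index — `O` first — which makes decoding deterministic and testable.

## Evaluation

Scoring is strict entity-level matching: a predicted span counts only if
its (type, start, end) triple exactly equals a gold span of the same
document. Counts are pooled over types for micro precision/recall/F1
($F_1 = 2PR/(P+R)$); per-type scores use the same pooled-count definition
within each type. Conventions for degenerate cases are fixed: precision
(or recall) over an empty prediction (or gold) set is 0, and F1 is 0 when
$P + R = 0$. Repeated runs aggregate as mean and sample standard deviation
($n-1$ denominator), formatted `mean (SD)`. The man-machine harness
(`compare_candidates()`) scores any number of candidate annotation sets —
model predictions, human extractions — against the same gold standard
with the same metric, side by side, with per-document disagreement
listings.

## The radical table

The shipped table (`inst/extdata/kangxi_radicals.tsv`) maps ~850
characters to canonical Kangxi radical numbers. It is hand-curated to
cover the synthetic corpus and common clinical Chinese; it is not an
exhaustive Unihan extract, and CJK characters outside it fall back to the
sentinel 0 (reported once per index). A 176-character audit list —
dominated by the radical characters themselves, whose assignment is
definitionally certain — is kept separately in the test suite and checked
against the table. Characters with genuinely ambiguous traditional
classifications (e.g. 匹/医 between the box radicals 匚 and 匸) are kept
out of the audit list.

## What the synthetic generator does and does not show

The generator fills slotted narrative skeletons (reason → drug
administration → ADR onset → outcome) from closed lexicons, optionally
interleaving distractor snippets (noise rate 0.1 by default), and records
every placement as a gold span whose text slice equals the lexicon surface
form exactly. Identical configuration and seed regenerate a byte-identical
corpus. The working scale — 250 documents split 200 train / 50 test — is
large enough for the tagger to exceed held-out micro-F1 0.90 within 20
epochs and small enough for minutes-scale single-CPU runs; at that scale a
training run takes on the order of 1–2 minutes.

A deliberate limitation: entity surfaces come from closed lexicons
embedded in templated context, so the synthetic task measures whether the
architecture, gradients, decoding, offset bookkeeping and scorer work —
not whether the model generalizes to unseen entity surfaces, colloquial
symptom descriptions, or the annotation ambiguities of real
pharmacovigilance narratives. Passing the synthetic end-to-end check is a
correctness statement about the implementation, not a clinical performance
claim. `corrupt_annotations()` similarly simulates an imperfect annotator
(span drops, one-character boundary shifts, type swaps at stated
sub-probabilities) to exercise the man-machine harness, not to model human
error realistically.

## Numerical choices

* Log-space forward/backward recursions with log-sum-exp throughout; the
  partition function matches full-path enumeration within 1e-8 on
  enumerable instances.
* Embedding tables initialize uniformly on $[-0.5/d, 0.5/d]$; LSTM weights
  on $[-1/\sqrt{H}, 1/\sqrt{H}]$ with forget-gate bias 1; the emission
  projection on $[-1/\sqrt{2H}, 1/\sqrt{2H}]$; CRF scores start at 0.
* Gradients accumulate over the batch, are averaged, clipped at global
  norm 5, and applied by Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
  $\epsilon = 10^{-8}$).
* Every stochastic step (initialization, shuffling, dropout, generation,
  corruption) runs under a locally scoped seed, so runs are bit-for-bit
  reproducible and never disturb the caller's RNG stream.
* Degenerate inputs are rejected loudly: empty fragments, fragments above
  the length limit, overlapping spans, unknown tags or types, corrupted
  checkpoints, non-finite training losses.

## Known limitations

* No transformer encoder and no WordPiece tokenization; character-level
  input only.
* One radical per character — no stroke counts, structure decomposition,
  or glyph features.
* The CRF is first-order; no semi-Markov or higher-order variants, no
  beam search.
* Training requires the lookup provider; contextual adapters are
  prediction-time only.
* The radical table covers common clinical usage, not the full CJK
  inventory; unmapped characters share one sentinel vector.
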