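---
title: "Graph representations of clinical interviews: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph representations of clinical interviews: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dialograph)
```

## The problem and the model

A semi-structured clinical interview is a dialogue between a therapist and
a patient; the screening target is the patient's PHQ-8 score (0–24), with
the conventional threshold of 10 separating depressed from non-depressed.
`dialograph` classifies interviews by first turning each transcript into a
graph and then running a graph neural classifier on it. Two families of
graphs are supported, each in a single-graph *baseline* form and a
*multi-view* form that treats therapist and patient contributions as
interacting perspectives.

### Sentence-similarity graphs

Every utterance is a node carrying its sentence embedding; nodes $i, j$
are connected iff $\cos(e_i, e_j) \ge \tau$, and retained edges carry the
cosine as their weight (we keep the weights rather than binarizing, so the
GCN's adjacency reflects similarity magnitude). The threshold $\tau$
controls sparsity and is a tuned hyper-parameter; `train_config()` carries
a default search grid of $\{0.3, 0.4, 0.5, 0.6, 0.7\}$ which
`run_protocol()` resolves by best mean dev macro-F1.

In the multi-view form each view gets its own similarity graph over its
own utterances, and the views are joined by **cross edges** derived from
dialogue structure: question–answer correspondence is defined at the level
of maximal same-speaker turns (a therapist turn paired with the
immediately following patient turn — a definition that is deterministic
and robust to back-to-back utterances by one speaker), then expanded to
utterance level: every utterance of the question turn connects to every
utterance of the answer turn. Cross edges are *not* thresholded — they
encode discourse structure, not similarity, and thresholding them would
sever the views — and they carry weight 1. A cosine-weighted alternative
would be a one-line change; we keep the binary convention because the
correspondence relation itself is binary. Unpaired turns (a leading
patient turn, a trailing therapist turn) remain nodes in their view graph
but contribute no cross edges.

### Keyword-correlation graphs

An NMF topic model is fitted on the training-split sentences, each
sentence treated as an individual document, over a TF-IDF sentence–term
matrix (smooth idf, English stop-word removal, minimum document frequency
2 — standard topic-modelling practice). Word importance within a
transcript is computed by projecting the transcript's aggregated term
vector non-negatively onto the fixed topic–word basis (non-negative least
squares) and scoring each word present in the transcript by the inner
product of that loading vector with the word's topic column; this is our
reconstruction of "importance inferred from the topic model", with ties
broken by corpus document frequency and then lexicographically. The top 50
words become nodes. Each utterance is assigned to exactly one keyword
node: containment first (the highest-scored keyword the utterance
contains), embedding-similarity fallback otherwise; the sentence sets thus
partition the transcript. Edge weights are the average pairwise cosine
similarity between two nodes' sentence-embedding sets; nodes with empty
sentence sets are dropped because their edge weights would be means over
empty sets. The KCG edge threshold defaults to 0 (keep all non-negative
correlations) and is deliberately not tuned.

The multi-view form fits two separate topic models, one per view, and adds
a cross edge between a therapist node and a patient node whenever some
question–answer pair has its question utterance in the one node's set and
its answer utterance in the other's.

Transcript-level topic loadings could alternatively be aggregated from
per-sentence NMF transforms; we use the single aggregated-vector
projection because it is cheaper and the two agree in the regime where
sentences are short. The number of topics defaults to 10 per model,
matching the convention of reporting topics indexed 0–9; it is exposed as
a parameter.

## The neural models

All four variants share the same building blocks, implemented on a small
reverse-mode autodiff tape over dense matrices (gradients are verified
against finite differences in the test suite):

- **GCN layers** with symmetric normalization,
  $H \leftarrow \mathrm{ReLU}(D^{-1/2}(A+I)D^{-1/2} H W + b)$, edge
  weights as adjacency entries, self-loops added inside the layer (they
  are never stored in the graph objects). Default 2 layers, hidden width
  128, ReLU between layers, dropout 0.2 on node features during training.
- **Node encoder** (KCG variants): single-block multi-head self-attention
  over a node's sentence-embedding set, mean-pooled — a permutation-
  invariant set encoder producing the node's input feature.
- **Attention-pool readout** (baseline variants): multi-head
  self-attention over nodes, mean-pooled to a graph embedding.
- **Cross-attention fusion** (multi-view variants): per-view
  self-attention, then cross-attention in both directions with the views
  swapping query against key/value roles, each direction mean-pooled, the
  two summaries combined by element-wise mean. The precise fusion formula
  of the prior multi-view work is not restated in our sources; the
  element-wise mean of the two cross-attended summaries is our
  reconstruction of its "mean" configuration. Attention blocks are single
  depth with no positional encoding (graphs are unordered), 4 heads by
  default.
- **Classification head**: logistic regression on the graph embedding,
  decision threshold 0.5.

In the multi-view pipelines the GCN runs over the block graph containing
both views' intra-edges *and* the cross edges (so message passing crosses
the views), after which the node features are split by view and fused.
An empty view (e.g. an all-therapist transcript) contributes a zero
summary and fusion degrades to half the surviving view's self-attended
mean; this case is unaddressed by the underlying method description but
required for degenerate inputs.

## Training and evaluation protocol

Training minimizes class-weighted binary cross entropy
($w_c = N / 2N_c$, equalizing the total loss mass of the two classes —
with a 76/31 split this yields weights 107/152 and 107/62) with Adam at
learning rate $5\times10^{-4}$. Transcripts are processed in shuffled
batches of 8 with gradients averaged over the batch. After each epoch dev
macro-F1 is computed; the best-dev checkpoint is restored at the end
(early stop patience 20, epoch cap 100 by default). The multi-seed
protocol trains once per seed (default seeds 0–4, matching the
five-random-initializations convention), tunes the similarity threshold
once on mean dev macro-F1 over the grid, and reports per-seed and
mean ± sd metrics: macro-F1, UAR, accuracy, macro precision — macro/
unweighted averages are the right summary under the ~70/30 class
imbalance. A class absent from the true labels contributes 0 to its
per-class terms.

No information flows from dev/test into any fitted artifact: topic models
see only training-split sentences, graphs are built per transcript from
its own content, and the test suite checks bit-identity of all artifacts
when dev/test transcripts are deleted.

## The synthetic corpus

The reference corpus for this task is access-restricted, so the package
generates synthetic interviews reproducing the structure the method
exploits: a finite set of eight disjoint topic vocabularies standing in
for life domains; per topic a therapist question (stop-word glue plus
topic words) answered with topic words; PHQ-8 sampled from
class-conditional ranges (0–9 / 10–24) so the ≥ 10 rule reproduces the
class; positive rate 0.3 (the ~70/30 imbalance of the reference data);
and three class-dependent signals — shorter patient answers (2–5 tokens
vs 7–14), more therapist follow-up questioning (rate 0.6 vs 0.15 per
topic), and marker keywords ("therapy", "depression", "p_t_s_d",
"medication", "diagnosis") injected with probability 0.95 into positive
and 0.05 into negative transcripts. When markers are injected the patient
answers a few topics with marker-dominated responses; this is what makes
marker keywords surface as nodes (with multi-utterance sentence sets) in
keyword graphs of depressed-class transcripts, mirroring the
marker-cluster phenomenon the visualizations target. The default corpus
size is 100 transcripts with a stratified 60/20/20 split, echoing the
reference corpus scale (107/35/47) while staying desk-fast.

Text is template-based token sequences, not natural language. Together
with the deterministic encoder below, this means passing tests certify
the *pipeline* — graph construction, learning dynamics, protocol
correctness — not natural-language understanding; absolute metric values
on synthetic data say nothing about performance on real interviews.

## The deterministic encoder

The production encoder hook accepts any user function (e.g. a
sentence-transformer such as all-mpnet-base-v2, whose 768 dimensions the
default mirrors), but no test or offline path requires it. All offline
work uses a deterministic encoder: each token maps to a unit vector drawn
from an RNG seeded by a hash of (token, seed); a text's embedding is the
L2-normalized token-vector sum. Identical texts embed identically and
token overlap increases expected cosine similarity — exactly the property
the similarity graphs and KCG edge weights need. Its known limitation is
the absence of semantics: synonyms and related concepts ("therapy" /
"depression") are orthogonal in expectation, so cross-token semantic
similarity visible to a real encoder is invisible here. Embeddings are
L2-normalized by default so cosine similarity is a plain dot product.

## Numerical choices and degenerate inputs

- NMF uses multiplicative updates (Frobenius loss) with seeded uniform
  initialization, 200 iteration cap and a relative-error stopping rule;
  fits are deterministic given the seed.
- Keyword score ties break by corpus document frequency then
  lexicographic order; assignment ties break by keyword rank.
- Checkpoint selection ties (equal dev macro-F1, common on a 20-transcript
  dev split) break by lower dev loss, so an early barely-trained epoch
  that happens to hit the same dev score as a converged one is never the
  restored model.
- Degree normalization clamps degrees at $10^{-12}$; probabilities are
  clamped at $10^{-7}$ inside the loss.
- Empty keyword graphs (a transcript sharing no vocabulary with the
  topic model) predict probability 0.5 and are skipped during training.
- Graph exports order nodes by id and edges lexicographically, making
  DOT/GraphML output byte-stable.
- "Cluster" in the visual summaries is operationalized as a connected
  component of the strong-edge subgraph (weight ≥ cutoff); community
  detection would be a finer alternative but components match the visual
  reading of the rendered figures. A cluster is annotated "filler" when
  at least half its member utterances are in the filler vocabulary or are
  single-token back-channels. A marker cluster is flagged when a marker
  node gathers two or more utterances, two marker nodes share a strong
  component, or a marker node sits in a strong component of two or more
  nodes — in a keyword graph a node already *is* a cluster of sentences.

## Problem sizes used in checks

The shipped tests and the acceptance script run the full protocol at
desk scale, chosen as the package's own defaults: 100-transcript corpora,
64-dimensional deterministic embeddings, hidden width 64, 15–30 epochs,
and 2-seed protocol runs at reduced epochs where only reproducibility
(not performance) is being checked. Oracle-equivalence checks use
hundreds of random instances with $n \le 20$ nodes.

## Known limitations

- The deterministic encoder has no semantics (see above); KCG edge
  weights between topically related but token-disjoint sentence sets are
  near zero, which real encoders would not produce.
- Turn-level QA pairing assumes the interview alternates question and
  answer at the turn level; interjected patient questions are paired as
  answers.
- The GCN/attention stack is intentionally small and CPU-bound; it is a
  faithful, testable implementation of the architecture, not a
  performance-tuned production trainer.
- The similarity threshold is tuned once on mean dev macro-F1 across
  seeds, not per seed.
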