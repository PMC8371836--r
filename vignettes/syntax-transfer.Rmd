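---
title: "Syntax-aware relation extraction and multi-corpus transfer: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Syntax-aware relation extraction and multi-corpus transfer: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synre)
```

## The problem

Biomedical relation extraction asks, for a pair of entity mentions in a
sentence (a SNP and a phenotype, two drugs, a drug and an adverse effect),
whether a typed relationship holds between them and which one. Annotated
corpora for any specific relation type are small — often a few hundred
sentences — which makes the task a natural candidate for *transfer learning*:
training the model jointly on a larger corpus annotated for a *different*
relation type and hoping the shared parts of the model benefit. Whether that
hope is justified depends on what the shared encoder can transfer; `synre`
implements both the models and the diagnostic metrics that explain when
joint training helps and when it degenerates into negative transfer.

## The models

Every token $w_i$ of a parsed sentence is mapped to an input vector
$x_i \in \mathbb{R}^{d_w + d_e}$ by concatenating a word embedding (a
lookup-table row, with a trained unknown-word row absorbing out-of-vocabulary
forms) and one of three *entity-role* embeddings marking the token as part of
the first entity, the second entity, or neither. The roles are what lets a
single sentence with several entity pairs produce a distinct representation
per pair.

Two encoders turn $x_1 \dots x_N$ into a fixed-size sentence representation
$r_s$:

**Child-Sum TreeLSTM.** The dependency tree is processed bottom-up; node $j$
with children $C(j)$ updates

$$\tilde h_j = \textstyle\sum_{k \in C(j)} h_k, \qquad
  i_j = \sigma(W^{(i)} x_j + U^{(i)} \tilde h_j + b^{(i)}),$$
$$f_{jk} = \sigma(W^{(f)} x_j + U^{(f)} h_k + b^{(f)}), \qquad
  o_j = \sigma(W^{(o)} x_j + U^{(o)} \tilde h_j + b^{(o)}),$$
$$u_j = \tanh(W^{(u)} x_j + U^{(u)} \tilde h_j + b^{(u)}), \qquad
  c_j = i_j \odot u_j + \textstyle\sum_k f_{jk} \odot c_k, \qquad
  h_j = o_j \odot \tanh(c_j).$$

Summing over children makes the update invariant to sibling order and
applicable to arbitrary branching. The readout is the root's hidden state
$h_{\text{root}}$ ($d_s = d_h$). The update is sometimes described as reading
out the root's *output state*; since $o_{\text{root}}$ and $h_{\text{root}}$
have the same dimension and $h = o \odot \tanh(c)$ is the quantity an LSTM
conventionally exports, `synre` defaults to $h$ and exposes `readout = "o"`
as a switch. On a linear-chain tree the model reduces exactly to a
sequential LSTM — a property the test suite exploits as an oracle.

**MCCNN.** A multichannel CNN: each channel carries its own copy of the word
embeddings (all initialized identically; gradients flow into only one, the
others stay frozen, following the multichannel trick from image models). For
a kernel of width $k$, window $i$ scores
$\tanh\bigl(\sum_{c} W_c\,[x_i \dots x_{i+k-1}]^{c} + b\bigr)$, a max over
window positions gives $r_h \in \mathbb{R}^{d_h}$, and the $K$ kernels'
outputs concatenate into $r_s$ ($d_s = K d_h$). Sentences shorter than $k$
are zero-padded (split between left and right) so at least one window
exists. A note on the window score: one published rendering of the formula
sums over window positions while describing the index as ranging over
channels; `synre` sums over channels at each window position, which is the
standard multichannel convolution and the only reading consistent with
max-pooling *over* positions.

**Scorer and loss.** A per-corpus affine layer $s(r_s) = W^{(s)} r_s +
b^{(s)}$ produces one score per relation type of *that corpus's* label set;
training minimizes the softmax negative log-likelihood.

**Transfer training.** All corpora share the embedding tables and encoder;
only the scorers are per-corpus. Each SGD step (batch size 1) draws one
instance uniformly from the pooled target + source training instances, so a
10x larger source receives 10x the updates — the literal mixed-corpus
reading. An optional `target_oversample` knob re-balances; it is off by
default. Dropout (inverted, disabled at evaluation) is applied after the
embedding layers and, for the TreeLSTM, to every unit's outgoing hidden
state. A validation slice of the target picks the best epoch snapshot.

Because no automatic-differentiation framework is involved, both encoders'
backward passes are derived by hand (backpropagation through structure for
the tree; backpropagation through the argmax for the max-pool) and
implemented in C++ alongside the forward passes. Their correctness is not
taken on faith: the test suite compares every parameter tensor's analytic
gradient against central finite differences in double precision.

## Syntactic transfer-compatibility metrics

Whether a source corpus helps depends, empirically, far more on *syntactic*
similarity than on vocabulary overlap. `synre` quantifies this with the
shortest dependency path (SDP) between the two entities: the unique path in
the undirected view of the tree, whose node closest to the root is the
lowest common ancestor (LCA). Each path is rendered in three dialects —
POS tags + dependency labels (`NN nsubj *JJ* nmod NN nmod NN`), POS only
(`NN *JJ* NN NN`), dependency labels only (`nsubj ** nmod nmod`) — with the
LCA marked by asterisks. Per corpus and dialect, pattern counts over
true-relation instances (an auto-generated FALSE class is excluded: the
patterns describe *related* entity pairs) are normalized into a
distribution; the *syntactic similarity* of two corpora is the cosine of
their distributions. Alongside it the package reports *dictionary coverage*
(percent of target word types present in the source) and the most frequent
LCA terms (with heads inside an entity span masked as `entity`), so a user
can see, before training, whether a candidate source corpus resembles the
target syntactically, lexically, both, or neither.

Two conventions are worth stating because the printed examples do not force
them: multi-token entities anchor the path at their syntactic head (the
leftmost span token whose head escapes the span), and patterns are read from
the left entity to the right one without arrows, so a pattern and its mirror
stay distinct. A config flag can canonicalize mirrored readings; it is off
by default to match the printed left-to-right example.

## The synthetic generator

Everything above is testable offline because the generator produces parsed,
annotated corpora from weighted *templates*: tree skeletons with POS and
dependency labels, two entity slots, and a label. Forms are drawn per POS
from vocabulary pools; the empirical pattern distribution converges to the
template weights, so pattern-distribution properties have analytic
expectations. `generate_transfer_pair()` builds the transfer setting
directly: the source shares a fraction `overlap` of its weight mass with the
target's skeletons while vocabularies and label sets stay disjoint — lexical
coverage is pinned at 0 while syntactic cosine sweeps 0 to 1, isolating
exactly the variable the transfer analysis is about. Skeleton linear order
is fixed inside each template (the generator writes tokens in skeleton
order), entities default to single tokens, and a template may declare a
multi-token span to exercise the head-anchoring rule.

What the generator does *not* emulate: real parser errors, non-projective
or long sentences, unbalanced label frequencies, cross-sentence relations,
or naturalistic vocabulary distributions (a non-goal by design). Passing
the synthetic experiments therefore demonstrates that the machinery behaves
as specified under controlled conditions, not that any particular F-score
carries over to SNPPhenA-scale data.

## Study conditions and numerical choices

The desk-scale experiments run on one CPU in minutes, so the defaults are
deliberately small and are stated here as the package's chosen conditions:

* **Transfer experiment** (`transfer_experiment()`): target n = 60, source
  n = 600 (the 10x ratio of the motivating setting), test n = 240, overlap
  grid {0, .25, .5, .75, 1}, 5 seeds; encoder d_w = 16, d_e = 8, d_h = 32;
  30 epochs of SGD at learning rate 0.1, dropout 0 (regularization off at
  this scale; dropout's 0.25 default matters at the 100-200-dimensional
  full scale). The measured quantities are macro-F with and without the
  source, their difference (the transfer gain), the POS+DT pattern cosine,
  and the Spearman correlation between cosine and gain across the grid.
* **Learnability** (`learnability_experiment()`): 200 training instances of
  a noiseless trigger-word corpus, 50 epochs, learning rate 0.1, 3 seeds.
* **Full-scale defaults** mirror the published configuration: MCCNN
  d_w = 100, d_e = 10, d_h = 100 per kernel, kernels (3, 5), 2 channels;
  TreeLSTM d_h = 200; dropout 0.25; 10-fold cross-validation with a 10%
  validation slice, 10 restarts per fold, and 5-best-by-validation
  score-averaging ensembles.

Other numerical choices: parameters initialize uniformly in
$(-\sqrt{1/\text{fan-in}}, +\sqrt{1/\text{fan-in}})$; embeddings initialize
the same way unless pre-trained vectors are supplied, and the unknown-word
row trains like any other row. Learning rate and epoch count are not pinned
by the published description ("standard stochastic gradient descent"), so
the package exposes them with defaults lr = 0.05, epochs = 100 and
best-validation-epoch snapshotting. Argmax ties break toward the lowest
label index; max-pool argmax ties break toward the earliest window; both
for determinism. Probabilities in the loss are floored at 1e-12. The
experiment summary reports the *population* standard deviation of macro-F
(reading "average over experiments" literally); `cross_validate()` uses the
same convention.

Indexing is 1-based throughout the R API with closed entity spans
`c(start, end)` — the native R convention — while the JSONL interchange
format keeps 0-based token indices, half-open spans and `head = -1` for the
root, converted at the I/O boundary. CoNLL-U input maps its 1-based IDs
directly and `HEAD = 0` to the root marker.

## Known limitations

* The published headline scores (macro-F in the 60s-80s on SNPPhenA and
  EU-ADR subtasks) require the original corpora, the Charniak-Johnson
  biomedical parses and PubMed-pretrained vectors; none ship here, so the
  package reproduces the *phenomena* (transfer gain tracking syntactic
  cosine; TreeLSTM benefiting where syntax matches) rather than those
  numbers.
* Mixed-corpus sampling is proportional to corpus size; with a very large
  source the target can be swamped — the oversampling knob exists but is
  off to keep the literal uniform-mixing semantics.
* No shortest-path-only TreeLSTM variant, no adversarial domain adaptation,
  and no automatic source-selection policy: the similarity metrics inform
  the user, they do not gate training.
* Single-threaded CPU implementation; practical corpus sizes are
  thousands, not millions, of instances.
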