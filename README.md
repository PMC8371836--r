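# synre

Syntax-aware neural relation extraction with multi-corpus transfer learning,
in R.

Biomedical relation extraction (RE) classifies, for a pair of entity mentions
in a sentence — a SNP and a phenotype, two drugs, a drug and an adverse
effect — whether a typed relationship holds and which one. Corpora annotated
for any one relation type are small, so `synre` is built around *transfer*:
train one shared sentence encoder jointly on a small target corpus and a
larger source corpus annotated for a different task, with only the final
scoring layer specialized per corpus, and use *syntactic* similarity metrics
to anticipate when that helps and when it backfires.

## What is inside

**Encoders.** Both map a dependency-parsed sentence with a marked entity pair
to a fixed-size representation `r_s`, from shared word embeddings
concatenated with 3-way entity-role embeddings (first entity / second entity
/ other):

* a **Child-Sum TreeLSTM** over the dependency tree, whose node update sums
  the children's hidden states

  `h̃_j = Σ_k h_k`,  `i_j = σ(W⁽ⁱ⁾x_j + U⁽ⁱ⁾h̃_j + b⁽ⁱ⁾)`,
  `f_jk = σ(W⁽ᶠ⁾x_j + U⁽ᶠ⁾h_k + b⁽ᶠ⁾)`, `o_j`, `u_j` likewise,
  `c_j = i_j ⊙ u_j + Σ_k f_jk ⊙ c_k`, `h_j = o_j ⊙ tanh(c_j)`,

  read out at the root (`r_s = h_root`);
* a **multichannel CNN (MCCNN)**: per kernel width `k`,
  `tanh(Σ_c W_c [x_i … x_{i+k−1}]^c + b)` over windows, max-pooled over
  positions, kernels concatenated (`d_s = K·d_h`); gradients reach the word
  embeddings through one trainable channel, the others stay frozen.

A per-corpus affine scorer `s(r_s) = W⁽ˢ⁾ r_s + b⁽ˢ⁾` feeds a softmax
negative log-likelihood, minimized by SGD (batch size 1) over instances
drawn uniformly from the mixed target + source pool. Both encoders' backward
passes — backpropagation through structure for the tree — are hand-derived
and implemented in C++ (RcppArmadillo), verified against finite differences
in the tests. Cross-validation, score-averaging ensembles, and macro
precision/recall/F evaluation are included.

**Transfer-compatibility metrics.** Shortest-dependency-path patterns between
the two entities in three dialects — POS + dependency labels
(`NN nsubj *JJ* nmod NN nmod NN`), POS only (`NN *JJ* NN NN`), labels only
(`nsubj ** nmod nmod`), with the lowest common ancestor starred — plus
per-corpus pattern distributions, their cosine similarity, dictionary
coverage, and top LCA-term tables.

**Synthetic generator.** Template-based corpora with controllable pattern
distributions, vocabularies and label functions, including
`generate_transfer_pair()` whose syntactic overlap is a dial while lexical
overlap is pinned to zero — so the whole package is testable offline.

**I/O.** CoNLL-U parses, a self-contained JSONL corpus dialect (header +
one sentence object per line), word2vec text vectors, and bit-exact model
serialization. A thin CLI lives in `inst/cli/synre.R`.

## Worked example

```r
library(synre)

pair <- generate_transfer_pair(overlap = 1, n_target = 60, n_source = 600, seed = 7)
pair$target
#> <re_corpus 'syn_target': 60 instances, 4 labels (t_rel_1, t_rel_2, t_rel_3, t_rel_4), 113 vocabulary types>

similarity_report(pair$target, pair$source)
#> <similarity_report: target 'syn_target' vs source 'syn_source'>
#> # A tibble: 3 × 2
#>   dialect cosine
#>   <chr>    <dbl>
#> 1 POS_DT   0.987
#> 2 POS      0.987
#> 3 DT       0.987
#> dictionary coverage: 0.0%

cfg <- train_config(learning_rate = 0.1, epochs = 30, seed = 7, dropout_p = 0,
                    d_w = 16, d_e = 8, d_h = 32)
baseline <- train_transfer(pair$target, list(), "treelstm", cfg)
joint <- train_transfer(pair$target, list(pair$source), "treelstm", cfg)

test <- generate_transfer_pair(1, 240, 1, seed = 99)$target
f <- function(m) { p <- predict(m, test)
  glance(evaluate(p$gold, p$.pred, test$label_set))$macro_f }
f(baseline)  #> 31.4
f(joint)     #> 100
```

The source shares the target's tree shapes (pattern cosine 0.99) but not a
single word (coverage 0%): with only 54 training sentences the baseline
barely beats chance on the 4-way task (macro-F 31.4), while joint training
with the syntactically matched source lets the shared encoder separate the
structures and the target scorer reaches macro-F 100 on held-out data. Drop
`overlap` toward 0 and the gain shrinks — the negative-transfer diagnostic
in action.

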