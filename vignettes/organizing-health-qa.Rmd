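---
title: "Organizing health QA corpora into profiled topic hierarchies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Organizing health QA corpora into profiled topic hierarchies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qatopics)
```

## The problem

Community health services accumulate large corpora of question-answering (QA)
records: a free-text health question, zero or more answers from clinicians,
and short tags. These corpora are unstructured, grow continuously, and suffer
from a wide *vocabulary gap* — two people describe the same complaint with
almost disjoint words. `qatopics` organizes such a corpus into a rooted,
directed topic hierarchy whose nodes are (possibly overlapping) subsets of
the records, labels every node with standard medical terminologies, and
searches the corpus by routing a query down the hierarchy and reranking the
reached records with a graph random walk.

## The organization scheme

**First layer from prior knowledge.** High-level health categories are hard
to induce but easy to name. The builder takes a *domain prior*: an ordered
list of category names, each with seed example records. For every category a
linear support-vector classifier is trained on its seeds (positives) against
an equal-size seeded sample of the other categories' seeds (negatives), over
the l2-normalized weighted-term representation. Every corpus record joins
each category whose classifier fires; a record firing none goes to its
best-scoring category so the first layer always covers the corpus. Multiple
memberships are allowed throughout: health questions routinely touch several
topics at once.

**Expansion.** Each node's records are assumed to be explained by a small
number of latent subtopics. A node is expanded by fitting latent Dirichlet
allocation (LDA) on its member token sequences, with the child count `k`
chosen to minimize held-out perplexity

$$\mathrm{perplexity} = \exp\!\left\{-\frac{\sum_i \log p(d_i)}{\sum_i l_i}\right\},$$

over a seeded hold-out split, searching `k` in a configurable range (default
2–12) and breaking ties toward the smaller `k`. Two estimator choices matter
and are deliberate:

* The held-out likelihood $p(d_i)$ is estimated by **document completion**:
  the document's topic mixture is inferred from its odd-position tokens and
  the likelihood is evaluated on its even-position tokens. Full-document
  fold-in re-fits the mixture to the very tokens being scored, which makes
  held-out perplexity decrease monotonically in `k` (the argmin then always
  sits at the top of the search range); completion restores a minimum at the
  planted child count on synthetic corpora. Both the likelihood and the
  length normalizer $l_i$ count in-vocabulary tokens, so out-of-vocabulary
  tokens cannot swamp the statistic through the $10^{-12}$ probability
  floor.
* The fitted model's document mixtures are the **inferred posteriors** under
  the fitted topic-word distributions (a vectorized fixed-point pass), not
  the raw Gibbs topic-count proportions. Sampled counts over-smooth short
  records — a pure 30-token document ends up near (0.85, 0.15) — which
  blunts every downstream consumer of the mixtures (the topical kernel, the
  leading-gap assignment, query routing).

The sampler itself is a collapsed Gibbs sampler (Rcpp) with an internal
Mersenne-Twister stream, so a fit is reproduced bit-for-bit by its seed on
any platform, independently of R's RNG state.

**Shrinkage.** Before expanding, the builder asks whether the node is
already specific enough. The node is trial-split into two children `A` and
`B` (a 2-topic model, argmax side), the average pairwise similarity

$$R(A,B) = \frac{1}{|A||B|}\sum_{x_i \in A, x_j \in B} S(x_i, x_j)$$

is computed with the fused kernel as `S` (identity pairs count 1 per the
literal double sum), and the normalized inter-node relation
$\mathrm{inter}(A,B) = R(A,B)/R(A,V) + R(A,B)/R(B,V)$ is compared against
the termination threshold `delta`: expansion stops when `inter > delta`
(strictly). The statistic ranges from 0 (perfectly separated trial children)
to 2 (indistinguishable ones). Because the topical component of the fused
kernel is a two-dimensional Jensen-Shannon similarity during the trial
split, cross-side pairs retain a similarity floor of roughly 0.3–0.4, so on
synthetic corpora cleanly separable nodes score about 1.0–1.4 while
homogeneous nodes score 1.85–2.0. The default `delta = 1.6` sits between the
two regimes with margin on both sides; it is a configuration entry, and on a
real corpus it should be re-examined the same way (the statistic's scale
depends on the kernel weights). On nodes larger than `shrink_sample_max`
(default 300) the relations are estimated on a seeded uniform subsample —
they are plain averages, so a subsample estimates them without bias while
keeping each node's cost quadratic in the sample, not the node.

**Assignment.** Each record of an expanded node is represented by its
posterior mixture over the `k` children and assigned to its *leading*
children: sort the probabilities, find the largest gap between adjacent
values, and keep everything before it (earliest gap on ties, so a flat
posterior keeps only the top child). This yields one membership for pure
records and several for genuinely mixed ones; empty children are dropped.
The builder proceeds breadth-first, treating nodes below `min_node_size`
(default 20) or at the safety `depth_cap` (default 6) as leaves.

**Profiling.** Every node is labeled with ranked terminologies. Member texts
are split into sentences, tokens are POS-tagged, and maximal spans matching

```
(Adj | Noun)* (Noun Prep)? (Adj | Noun)* Noun
```

are collected as noun phrases (greedy left-to-right matching), singularized
tokenwise by a rule table, and merged. The top `profile_k` (default 20)
frequent phrases are normalized through the concept lexicon — a
phrase-to-terminology table with semantic groups standing in for a UMLS
concept-mapping service — and each terminology's score is the number of
distinct candidate phrases normalizing to it (binary votes). Ties break by
summed phrase frequency, then terminology id; the top `profile_top_n`
(default 5) terminologies become the node's labels. This extraction runs on
its own tokenization that keeps stop words: the retrieval stoplist would
delete the prepositions the pattern needs.

## Similarity kernels

Three kernels compare two records, fused linearly with weights
$\beta_1 + \beta_2 + \beta_3 = 1$:

* $\Phi_1$, **weighted term kernel**: cosine over bags of words in which
  tokens mapping to a boosted semantic group of the lexicon (defaults:
  disease or syndrome; body part, organ or organ component; sign or symptom;
  neoplasm) count twice.
* $\Phi_2$, **syntactic tree kernel**: the subset-tree kernel (pure fragment
  counting, no decay) summed over all cross pairs of sentence parse trees
  and divided by the product of sentence counts; min-max scaled to [0, 1]
  over the current record set before fusion since its raw range is
  unbounded. The bundled parser builds a trivial right-branching tree over
  POS tags so the kernel is exercisable offline; any
  `function(tokens) -> parse_tree` plugs in.
* $\Phi_3$, **latent topic kernel**: the Jensen-Shannon divergence between
  the records' topic mixtures (natural log, bounded by $\ln 2$). Since the
  other two kernels are similarities, the divergence is converted to
  $1 - \mathrm{JS}/\ln 2$ before fusion (the raw-divergence polarity is
  selectable via `phi3_polarity`). Two records' mixtures are only comparable
  under a shared model, so in retrieval the pair's topical term is computed
  under the deepest common ancestor node that carries a fitted model and
  contributes 0 when none exists.

The default weights are $\beta = (0.5, 0, 0.5)$: lexical and topical
evidence weighted equally, the syntactic kernel off. In the original
formulation the weights are tuned by a 0.05-step grid search on the simplex
(`beta_grid()` enumerates it) against held-out relevance labels, which a
fresh unlabeled corpus does not have; the lexical and topical kernels carry
the organization scheme, while $\Phi_2$ with the bundled right-branching
parser adds sentence-length structure but no constituency information, so it
is off until a real parser and tuning labels justify it.

## Retrieval

A query is treated as a QA record with only a question part. It is routed
through the first-layer classifiers (all fired categories; best-scoring when
none fires; all branches with a warning when the query shares no vocabulary
with the classifiers), then down the tree: at each node with a model the
query's mixture is inferred and the leading children are descended. The
members of all reached leaves form the candidate pool. Each candidate's
initial score $\bar y_i$ is its fused similarity to the query, and the final
relevance scores solve

$$\mathbf{y} = \frac{1}{1+\lambda}\,\mathbf{W}\mathbf{D}^{-1}\mathbf{y}
  + \frac{\lambda}{1+\lambda}\,\bar{\mathbf{y}},$$

iterated from $\mathbf{y} = \bar{\mathbf{y}}$; `W` is the candidates' fused
similarity matrix with zero diagonal (no self-loops) and `D` its row-sum
diagonal. The iteration is a contraction for $\lambda > 0$ (the
column-normalized walk matrix has unit norm), and the tests check it against
the direct linear solve. Candidates with zero degree bypass the walk and
keep their initial score. The default `lambda = 1` weights the smoothness
and fidelity terms of the underlying objective equally; pushing `lambda`
well below 1 makes the fixed point centrality-dominated — in calibration
sweeps (0.1, 0.5, 1, 2, 10) values below 0.5 broke self-retrieval (an
indexed record issued as its own query no longer ranked first) while values
of 1 and above preserved it, so the neutral equal-weight default is used.

## Evaluation metrics

Against a reference taxonomy (a rooted terminology tree standing in for
MeSH): **tuple accuracy** forms one (parent label, child label) tuple per
hierarchy edge from the nodes' top labels and counts the fraction that are
direct edges of the reference; **cohesiveness** averages the ancestry weight
$1/2^p$ (path length `p`, 0 for non-ancestor pairs, reversed direction
counts 0) over all label pairs of adjacent nodes, pooled globally over edges
(per-edge averaging is available via a flag). Label quality uses **S@K**
(a relevant terminology appears in the top K) and **P@K** (fraction of the
top K that is relevant); retrieval uses **NDCG@n** with exponential gains
$2^{rel}-1$, a $\log_2(\mathrm{rank}+1)$ discount, and graded relevances
0/1/2.

## The synthetic study corpus

Everything above is exercised end-to-end on generated data; no external
resource is needed. `generate_topic_tree()` builds a known topic tree
(default branching 3 then 3); every topic owns a private vocabulary block
(default 40 words) plus a share of a common block (`shared_fraction`, 0.1),
and each child topic draws 80% of its non-shared mass from its own block and
20% from its parent's, so children genuinely specialize their parents while
siblings remain separable. Records are sampled per leaf (default 120;
negative-binomial lengths around 30 tokens, matching the shortness of real
health questions) and split into question, answers and tags; a
`mixture_rate` fraction (0.2) are 50/50 blends of two sibling leaves and
carry two true memberships. Every topic has a planted concept with several
surface variants (bare noun, adjective+noun, noun+noun, plural) injected as
their own clause into that topic's records (leaf concept at rate 0.8, the
first-level category's concept at 0.4), a toy lexicon maps the variants to
one terminology id each, and a reference taxonomy mirrors the true tree.
Queries paraphrase sampled questions by swapping a configured fraction
(default 0.5) of tokens for same-topic synonyms — the generator pairs the
private vocabulary into synonym pairs — emulating the vocabulary gap:
relevance gains are 2 for the source record, 1 for records sharing a true
leaf, 0 otherwise. Seed exemplars for the domain prior are fresh pure
records per category (default 50, a desk-scale stand-in for the hundred
exemplars per category a live service would supply). The bundled POS "tag
dictionary" alternates noun/other tags over the topic vocabulary so that
noun-phrase spans stay short, as in natural text.

What the generator does *not* emulate — natural grammar, misspellings,
polysemy, concept mentions outside the planted variants, and topic counts
far beyond a dozen — bounds what green tests mean: they show the machinery
is correct and recovers planted structure under its stated assumptions, not
that the defaults are tuned for any particular real corpus.

## Numerical and degenerate-input choices

Dirichlet priors default to `alpha = 1/k`, `eta = 0.01`; Gibbs runs 150
sweeps. The random walk iterates to a max-norm tolerance of `1e-8` (cap 500;
it converges in far fewer). Probability floors: `1e-12` per token in
perplexity. Degenerate cases are defined rather than left to chance: a
record with no in-vocabulary token gets the uniform mixture; an all-equal
posterior keeps only its top child; empty children are dropped; a node whose
trial split has a zero-relation side stays a leaf; a query with no
classifier vocabulary routes to every first-layer branch with a warning; an
all-zero candidate graph degrades ranking to the initial scores. Ties are
always broken deterministically (smaller `k`, earliest gap, record id), and
every source of randomness flows from one global seed through per-stage
derived seeds, so a rebuild is byte-identical.

## Problem sizes used in the tests

The bundled suites run on corpora of roughly 360–2,000 records: the shared
fixture uses the default (3, 3) tree at 40 documents per leaf; child-count
recovery uses 4 planted topics at 500 documents per leaf over ten seeds; the
retrieval comparison and the pipeline determinism check run at the full
default conditions (1,080 records, 50 queries). These sizes were chosen so
that every planted effect is comfortably detectable while the whole suite
stays quick on a laptop.

## Known limitations

The first layer is only as good as the domain prior's seed examples; with
few or noisy seeds the margin classifiers misroute records and every later
stage inherits the error. The shrinkage threshold's scale depends on the
kernel weights, so changing `betas` calls for re-examining `delta`.
Perplexity-based selection inherits LDA's variance on small nodes (below a
few hundred records the chosen `k` wobbles by one or two). The bundled
tagger, parser and singularizer are deliberately minimal stand-ins;
replacing them with real components is a one-function plug-in each. Labels
are only as complete as the lexicon: phrases without an entry cast no vote.
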