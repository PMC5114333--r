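# qatopics

Organizes an unstructured corpus of community health question-answering (QA)
records — questions with their answers and tags, as posted on
community-based health services — into a terminology-profiled topic
hierarchy, and searches it.

Health QA corpora grow too fast to curate by hand, carry no topic structure,
and suffer a wide *vocabulary gap*: the same complaint is phrased with
almost disjoint words by different people. `qatopics` addresses this with a
top-down organization scheme and a hierarchy-routed retrieval engine:

* **Prior-knowledge first layer** — per-category linear SVM classifiers
  trained on seed example records route every record into the high-level
  health categories (multiple memberships allowed).
* **Expansion** — each node is split into child topics by LDA (collapsed
  Gibbs, Rcpp), with the child count *k* chosen to minimize held-out
  perplexity, `exp{-Σ log p(d_i) / Σ l_i}`, estimated by document
  completion.
* **Shrinkage** — before expanding, a trial bipartition `V = A ∪ B` is
  scored by the normalized inter-node relation
  `inter(A,B) = R(A,B)/R(A,V) + R(A,B)/R(B,V)`, where
  `R(A,B) = (1/|A||B|) Σ S(x_i, x_j)`; the node stays a leaf when
  `inter > δ`, so each branch finds its own depth.
* **Multi-leaf assignment** — a record joins the *leading* child topics of
  its posterior mixture: everything before the largest gap in the sorted
  probabilities.
* **Profiling** — frequent noun phrases (POS pattern
  `(Adj|Noun)* (Noun Prep)? (Adj|Noun)* Noun`) are normalized through a
  concept lexicon (a UMLS/MetaMap stand-in) and vote for terminologies;
  the top-ranked terminologies label the node.
* **Retrieval** — a query is routed to leaves through the classifiers and
  per-node topic models, and the pooled candidates are reranked by the
  graph random walk `y = WD⁻¹y/(1+λ) + λȳ/(1+λ)` over the fused similarity
  kernel `Φ = β₁Φ₁ + β₂Φ₂ + β₃Φ₃` (weighted-term cosine, subset-tree
  kernel, Jensen-Shannon topic kernel).
* **Evaluation** — parent-child tuple accuracy and cohesiveness
  (`Σ 1/2^p` ancestry weights) against a reference taxonomy, S@K / P@K for
  labels, NDCG@n for retrieval.

A seeded synthetic-data module generates a corpus from a known topic tree —
with an aligned toy lexicon, reference taxonomy and paraphrased queries — so
the whole pipeline runs and is tested offline. See the methods vignette
(`vignettes/organizing-health-qa.Rmd`) for the model details and design
choices.

## Worked example

```r
library(qatopics)

## a synthetic study corpus from a known 3 x 3 topic tree
gen_cfg <- generator_config(docs_per_leaf = 60L, seed = 42L)
tree    <- generate_topic_tree(gen_cfg)
planted <- generate_lexicon_and_reference(tree)
gen     <- generate_corpus(tree, planted, gen_cfg)
corpus  <- contextualize_corpus(gen$corpus)
corpus
#> <qa_corpus> 540 records (0 held out)

## build + label the hierarchy
cfg  <- run_config(k_range = c(2L, 6L), seed = 7L)
hier <- build_hierarchy(corpus, gen$prior, cfg,
                        lexicon = planted$lexicon,
                        tagger  = dictionary_tagger(planted$tag_dict))
hier
#> <qa_hierarchy> 17 nodes (13 leaves), depth 2

hier$nodes[["root.2"]]$model$k     # perplexity chose 4 children (3 planted)
#> [1] 4
head(hier$nodes[["root.2"]]$labels, 3)
#>   term_id      term_name score
#> 1    T_t2   condition t2     3
#> 2  T_t2.1 condition t2.1     3
#> 3  T_t2.2 condition t2.2     2

## hierarchy quality against the planted reference taxonomy
tuple_accuracy(hier, planted$taxonomy)[c("total", "correct", "accuracy")]
#> $total    [1] 16
#> $correct  [1] 6
#> $accuracy [1] 0.375
cohesiveness(hier, planted$taxonomy)
#> [1] 0.07653061

## search with a paraphrased query (half the tokens swapped for synonyms)
q <- generate_queries(corpus, gen$truth, tree, gen_cfg, n_queries = 1L)[[1L]]
res <- search_hierarchy(hier, corpus, q$text, n = 5, lexicon = planted$lexicon)
res
#>       id     score
#> 1 r00401 0.7013464
#> 2 r00402 0.6724957
#> 3 r00419 0.6638424
#> 4 r00388 0.6621092
#> 5 r00367 0.6594333
match(q$source_id, res$id)   # the paraphrased record is retrieved first
#> [1] 1
```

The hierarchy found the three planted categories (routed perfectly by the
seed-trained classifiers), split each into three or four subtopics, and
labeled `root.2` with the planted category concept `T_t2` first, its
subtopic concepts next. Tuple accuracy counts how many (parent label, child
label) pairs are direct edges of the reference taxonomy; cohesiveness
averages `1/2^p` ancestry weights over all adjacent label pairs (0.5 would
mean every labeled edge mirrors a reference edge). The paraphrased query —
whose surface tokens were half replaced — still retrieves its source record
at rank 1 through topic-level routing and the random-walk reranking.

## Command line

A thin dispatcher over the same functions ships at `inst/cli/qatopics.R`:

```sh
Rscript inst/cli/qatopics.R simulate --out-dir data --seed 1
Rscript inst/cli/qatopics.R build   --corpus data/corpus.jsonl --prior data/prior.json \
        --lexicon data/lexicon.tsv --tags data/tags.tsv --seed 2 --out data/hier.json
Rscript inst/cli/qatopics.R search  --hierarchy data/hier.json --corpus data/corpus.jsonl \
        --lexicon data/lexicon.tsv --query "..." --n 10
Rscript inst/cli/qatopics.R eval    --hierarchy data/hier.json --reference data/reference.tsv
```

All artifacts are plain JSON / JSONL / TSV.

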