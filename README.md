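# figlink

Figures carry much of the evidence in a full-text life-science article, but
they are invisible to search tools that only read text. `figlink` predicts
which figures (and tables) in an article's body *support* which sentences of
its abstract, so that a literature-browsing system can jump from a claim in
the abstract straight to the figure behind it. It is aimed at text-mining
and BioNLP researchers who want supervised, probabilistic models of
sentence–figure association together with the ranking-oriented evaluation
machinery that goes with them.

## The models

For an article with sentences *j = 1..n_s* and figures *k = 1..n_f*, the
gold annotation is a binary linkage matrix **L** with L[j,k] = 1 when
sentence *j* and figure *k* are associated. Three sources of evidence are
modelled:

**Text.** Each figure gets a term distribution p_F(t) built from its caption
and/or the paragraphs that cite it (`caption_only`, `referencing_only`,
`pooled`, or a `mixture` with caption weight β). Sentences are treated as
queries against these "documents": the score of an instance is the
query-likelihood log-odds

    S[j,k] = Σ_{t ∈ sentence j} log[ (λ p_B(t) + (1−λ) p_F(t)) / p_B(t) ]

where p_B is an article-level background distribution (add-one smoothed
pooled counts) and λ the background mixing proportion. The background
vocabulary is either the article's own distinct-term count (`variable_size`)
or a corpus-level constant V (`fixed_size`); the fixed size corrects a bias
against long sentences. λ, β and V are learned by grid search (99 λ values,
120 points on the (λ, β) simplex, V minimizing the |correlation| between
sentence length and score).

**Position.** The distance feature j/n_s − k/n_f is discretized into ten
equal-frequency bins; Laplace-smoothed bin probabilities for linked and
unlinked instances give a log-odds matrix **D**, and **Z = S + D** combines
the two under conditional independence.

**Linkage flow.** Links tend to preserve relative order across an article.
A sentences-in-states HMM walks over figures with one state per sentence
plus a non-linked state; transitions are learned with Dirichlet-1 MAP
counts, emissions calibrate the Z scores through class-conditional
Gaussians, and forward–backward posterior decoding turns state occupancies
into linkage scores. A linear-chain CRF generalizes the HMM with one state
per sentence *subset* (size ≤ 2), eight shared transition features (figure
degree one-hots, crossed edges, neighbourhood patterns) and weights trained
by maximizing the conditional likelihood of gold paths.

Evaluation covers AROC, per-article and whole-corpus maximum F1,
precision at the reference operating point, mean "clicks saved", paired
t-tests, article permutation tests, Cohen's kappa agreement statistics, and
a leave-one-article-out cross-validation harness. A synthetic-corpus
generator with controllable text, position and flow signal makes the whole
stack testable without access to an annotated corpus.

## Worked example

```r
library(figlink)

train <- generate_corpus(16, seed = 11)   # annotated synthetic articles
test  <- generate_corpus(8,  seed = 12)

fit <- fl_fit(train, sequence_models = c("hmm_sis", "crf_sis"))
#> <fl_lm (fixed_size, mixture): lambda=0.07142857, beta=0.99, V=8640>

scores <- fl_score_corpus(test, fit, "crf_sis")
eval_report(scores, test)
#> $whole_corpus:  aroc 0.93   max_f1 0.748  precision 0.688
#> $per_article:   aroc 0.928  max_f1 0.809  precision 0.677
#> $clicks: 1.67
```

The fitted language model chose a small background weight (λ ≈ 0.07, the
synthetic text here is strongly figure-specific), an almost caption-only
mixture (β = 0.99), and a large fixed vocabulary. On the held-out articles
the CRF ranks instances with AROC ≈ 0.93; thresholding per article yields a
mean maximum F1 of 0.81, and following the CRF's ranking instead of reading
figures in document order saves 1.67 clicks per sentence on average. The
first article's score matrix shows the posteriors concentrating on the gold
links, e.g. sentence 1 → figure 1 scores 1.000 (gold 1) while sentence 4,
which links nothing, scores at most 0.30:

```r
round(unclass(scores[[1]])[1:4, 1:5], 3)
#>       [,1]  [,2]  [,3]  [,4]  [,5]
#> [1,] 1.000 0.057 0.013 0.015 0.000
#> [2,] 0.034 0.014 0.002 0.011 0.000
#> [3,] 0.006 0.047 0.082 0.548 0.027
#> [4,] 0.303 0.059 0.049 0.041 0.002
```

Corpora are read and written as JSON (`read_corpus()`, `write_corpus()`;
schema in `?read_corpus`). A thin command-line front end lives at
`inst/cli/figlink` (`stats`, `simulate`, `features`, `evaluate`).

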