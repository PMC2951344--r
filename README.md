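# figrank

Automatic ranking of figures in full-text bioscience articles by their
centrality to the article's main findings.

## The problem

Figures carry the experimental evidence of a bioscience article, but they
are not equally important: some report the key knowledge discovery, others
play a supporting role (controls, protocol steps). Authors can rank their
own figures by biological importance, and an article's figures can then be
ordered automatically by how *central* each figure's associated text is to
the article. figrank implements two unsupervised families of centrality
rankers over the structured text of an article, their linear combination,
and the specialised rank-error metrics needed to evaluate figure rankings
against an author's gold order.

## Methods at a glance

**Similarity-based centrality.** A figure is represented by its legend
(*FIGlegend*) or by its legend plus every body sentence that mentions it
(*FIGtext*); the article is represented by its title, abstract, or full
text (*ATCtitle*, *ATCabstract*, *ATCtext*). Each of the 2 × 3 pairings is
a ranking system: score(f) = cos(**v**(fig text), **v**(article text)),
with **v** the TF·IDF term vector (tf × ln((N+1)/(df+1)) by default)
under a pluggable background document-frequency model.

**Frequency-based centrality.** Figures referred to more often are more
central. Six strategies: raw mention counts in the full text or restricted
to Results & Discussion (R&D) sections; the count in each figure's most
topic-relevant mentioning R&D paragraph times that paragraph's relevancy;
and the interpolation Σ_p count(f, p) · rel(p) over all R&D paragraphs,
where rel(p) is the cosine of paragraph p to the title or abstract.

**Linear combination.** After per-article normalization,
score(f) = λ · sim(f) + (1 − λ) · freq(f), with λ = 1 the pure similarity
system and λ = 0 the pure frequency system; `sweep_lambda()` traces all
five metrics over a λ grid.

**Metrics.** For gold ranks r and system ranks R over an article's figure
pairs (i, j):

- **MER** — fraction of pairs with sign(rᵢ−rⱼ) ≠ sign(Rᵢ−Rⱼ);
- **MWER** — wrong pairs weighted by |rᵢ−rⱼ|, normalized by Σ|rᵢ−rⱼ|;
- **MWER-RK** — MWER with a logistic weight L(m) = 4/(1+eᵐ),
  m = min(rᵢ, rⱼ), so mistakes on important figures cost more;
- **ER-HR / WER-HR** — error rate on the single most important figure, and
  its displacement (SysRank − 1)/(numFig − 1), averaged over a collection.

A synthetic-article generator (`generate_collection()`) produces IMRaD-
shaped articles with planted gold rankings — legend topicality and R&D
mention counts both decay with gold rank at controllable strengths — so the
whole pipeline is testable end to end without any external corpus.

## Worked example

```r
library(figrank)
cfg  <- synth_config(n_articles = 20, sim_signal = 0.7, freq_signal = 0.6,
                     noise = 0.25, seed = 404)
coll <- generate_collection(cfg)
idf  <- collection_idf(coll)

a <- coll[[1]]
a
#> <fig_article> id=synth-1204456889 figures=6 sections=5 gold=4,2,3,5,1,6

round(score_similarity(a, "figtext-abstract", idf), 3)
#>     1     2     3     4     5     6
#> 0.173 0.757 0.613 0.740 0.438 0.009

combine_linear(a, idf, lambda = 0.8)
#> <fig_ranking> combined(lambda=0.8): 4 > 2 > 3 > 5 > 1 > 6

evaluate_collection(coll, c("figtext-abstract", "freq-fulltext",
                            "wfreq-rd-abs", "combined"), idf, lambda = 0.8)
#>          method_id    mer   mwer mwer_rk er_hr wer_hr
#> 1 figtext-abstract 0.0769 0.0351  0.0254  0.55 0.1191
#> 2    freq-fulltext 0.0854 0.0463  0.0318  0.45 0.1026
#> 3     wfreq-rd-abs 0.0645 0.0346  0.0244  0.20 0.0546
#> 4         combined 0.0532 0.0238  0.0164  0.35 0.0770
```

The similarity scores track the planted gold order (figure 4 first, figure
6 last); on this article the combined ranking recovers the gold order
exactly. Over the 20-article collection the combined system's pairwise
error rates (MER 0.053, MWER-RK 0.016) improve on both member systems,
the typical benefit of fusing the two complementary centrality signals.

Articles can also be read from structured-article JSON
(`parse_article_json()`, schema in the function documentation) or stripped
from generic article HTML (`strip_html()`), and a command-line front end
(`inst/cli/figrank.R`) exposes `rank`, `eval`, `sweep`, `synth` and `idf`
subcommands:

```sh
Rscript inst/cli/figrank.R synth --out coll/ --n-articles 10 --seed 7
Rscript inst/cli/figrank.R eval  --input coll/ --out report.tsv
Rscript inst/cli/figrank.R sweep --input coll/ --grid 0:1:0.1 --out sweep.tsv
```

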