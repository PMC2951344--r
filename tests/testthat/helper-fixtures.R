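# Shared fixtures, built in code.

options(figrank.verbose = FALSE)

# Hand-built IMRaD article with known mention counts:
#   figure 1: 4 fulltext mentions (1 intro + 2 results + 1 discussion), 3 in R&D
#   figure 2: 2 fulltext mentions (1 results + 1 discussion), 2 in R&D
# The reference-list mention of figures 9 and 1 must never be counted.
make_test_article <- function(gold = c(1, 2)) {
  fig_article(
    id = "fixture-1",
    title = "alpha beta signaling",
    abstract = "alpha beta signaling controls gamma expression",
    sections = list(
      list(heading = "Introduction",
           paragraphs = "We study alpha beta. Overview in Fig. 1."),
      list(heading = "Results",
           paragraphs = c(
             "Strong alpha beta effect. As shown in Fig. 1, and confirmed in Fig. 1 again.",
             "Figure 2 shows gamma controls.")),
      list(heading = "Discussion",
           paragraphs = "Figs. 1 and 2 summarize the pathway."),
      list(heading = "References",
           paragraphs = "See Fig. 9 and Fig. 1 in earlier work.")
    ),
    figures = list(
      list(label = 1, legend = "Alpha beta overview diagram"),
      list(label = 2, legend = "Gamma control experiment")
    ),
    gold = gold
  )
}

# IDF model in which every term is out-of-corpus: with smoothing
# ln((1+1)/(0+1)) = ln 2, every token weighs tf * ln 2, so cosines reduce to
# closed-form token-overlap arithmetic.
uniform_idf <- function() build_idf("placeholderterm", stopwords = FALSE)

# Independent MER oracle: Kendall tau distance via stats::cor on the two
# rank vectors, D = C(n,2) (1 - tau) / 2.
mer_oracle <- function(ref, sys) {
  rr <- match(ref, ref)          # 1..n by construction
  sr <- match(ref, sys)          # system rank of each label, gold order
  n <- length(ref)
  tau <- stats::cor(rr, sr, method = "kendall")
  (1 - tau) / 2
}

# All permutations of 1..n (n small).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (i in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = i)
    }
  }
  out
}
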