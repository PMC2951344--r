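Package: figrank
Title: Automatic Ranking of Figures in Full-Text Bioscience Articles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks the figures of a full-text bioscience article by their
    centrality to the article's main findings. Implements similarity-based
    centrality (TF*IDF cosine similarity between a figure's legend or
    associated text and the article title, abstract or full text),
    frequency-based centrality (raw and relevancy-weighted mention counts in
    Results and Discussion sections), and their linear combination, together
    with pairwise rank-error evaluation metrics (MER, MWER, MWER-RK, ER-HR,
    WER-HR), a structured-article JSON reader with lenient HTML stripping, a
    pluggable inverse-document-frequency model, and a synthetic-article
    generator with planted gold rankings for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
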