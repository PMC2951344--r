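# Article model: JSON round trip, section classification, mention grammar,
# text representations, sentence segmentation.

test_that("structured-article JSON parses, validates gold, and round-trips", {
  json <- '{
    "id": "a1", "title": "alpha study", "abstract": "alpha beta results",
    "sections": [{"heading": "Results", "paragraphs": ["Fig. 1 shows alpha."]}],
    "figures": [{"label": 1, "legend": "first"}, {"label": 2, "legend": "second"}],
    "gold": [2, 1]
  }'
  a <- parse_article_json(json)
  expect_s3_class(a, "fig_article")
  expect_length(a$figures, 2)
  expect_identical(a$gold, c(2L, 1L))

  # round trip through serialization preserves everything observable
  b <- parse_article_json(write_article_json(a))
  expect_identical(write_article_json(a), write_article_json(b))
  expect_identical(b$gold, a$gold)
  expect_identical(count_mentions(b, "fulltext"), count_mentions(a, "fulltext"))

  # gold must be a permutation of the declared labels
  bad <- '{"title": "t", "abstract": "a",
           "figures": [{"label": 1, "legend": "x"}, {"label": 2, "legend": "y"}],
           "gold": [3]}'
  expect_error(parse_article_json(bad), "permutation")
  expect_error(parse_article_json('{"title": "t"}'), "abstract")
  expect_error(parse_article_json("not json {"), "invalid JSON")
})

test_that("Results/Discussion and reference headings are classified by their core", {
  secs <- list(
    list(heading = "RESULTS AND DISCUSSION", paragraphs = "x"),
    list(heading = "3. Discussion", paragraphs = "x"),
    list(heading = "Materials and Methods", paragraphs = "x"),
    list(heading = "IV. Results", paragraphs = "x"),
    list(heading = "References", paragraphs = "x"),
    list(heading = "Literature Cited", paragraphs = "x")
  )
  a <- fig_article(sections = secs, figures = list(list(label = 1, legend = "l")))
  expect_identical(vapply(a$sections, `[[`, TRUE, "is_rd"),
                   c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_identical(vapply(a$sections, `[[`, TRUE, "is_references"),
                   c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  # idempotent
  expect_identical(detect_rd_sections(a), a)
})

test_that("mention grammar handles panels, ranges, conjunctions, and repeats", {
  mk <- function(text, n_figs = 5) {
    fig_article(sections = list(list(heading = "Results", paragraphs = text)),
                figures = lapply(seq_len(n_figs),
                                 function(i) list(label = i, legend = paste("legend", i))))
  }
  counts <- function(text, n_figs = 5) unname(count_mentions(mk(text, n_figs), "fulltext"))

  expect_identical(counts("as shown in Fig. 3A and B"), c(0L, 0L, 1L, 0L, 0L))
  expect_identical(counts("Figures 2–4 show the effect"), c(0L, 1L, 1L, 1L, 0L))
  expect_identical(counts("Figure 1 is key. Later, Fig. 1 again."), c(2L, 0L, 0L, 0L, 0L))
  expect_identical(counts("Figs. 2 and 3 agree"), c(0L, 1L, 1L, 0L, 0L))
  expect_identical(counts("FIG. 4, Fig. 5A–C, and figure 1"), c(1L, 0L, 0L, 1L, 1L))
  # a mention of an undeclared figure is dropped, others kept
  expect_identical(counts("Fig. 7 and Fig. 2", n_figs = 3), c(0L, 1L, 0L))
  # plain words never fire the grammar
  expect_identical(counts("The figure of merit was 3 and configurations varied."),
                   rep(0L, 5))
})

test_that("mention extraction is idempotent and counts match located mentions", {
  a <- make_test_article()
  b <- extract_figure_mentions(a)
  expect_identical(a, b)

  expect_identical(count_mentions(a, "fulltext"), c(`1` = 4L, `2` = 2L))
  expect_identical(count_mentions(a, "rd"), c(`1` = 3L, `2` = 2L))
  total_rows <- sum(vapply(a$figures, function(f) nrow(f$mentions), 0L))
  expect_identical(sum(count_mentions(a, "fulltext")), total_rows)

  # mentions are ordered by document position with valid spans
  for (f in a$figures) {
    m <- f$mentions
    expect_false(is.unsorted(order(m$section_index, m$paragraph_index, m$start)))
    expect_true(all(m$start >= 0 & m$end > m$start))
  }
})

test_that("figure_text builds legend and figtext representations", {
  a <- make_test_article()
  expect_identical(figure_text(a, 1, "legend"), "Alpha beta overview diagram")
  # legend is always a prefix of figtext
  for (lab in 1:2) {
    expect_true(startsWith(figure_text(a, lab, "figtext"),
                           figure_text(a, lab, "legend")))
  }
  # figtext gathers each mentioning sentence once, in document order
  ft1 <- figure_text(a, 1, "figtext")
  expect_match(ft1, "Overview in Fig. 1.", fixed = TRUE)
  expect_match(ft1, "As shown in Fig. 1, and confirmed in Fig. 1 again.", fixed = TRUE)
  expect_length(gregexpr("confirmed", ft1, fixed = TRUE)[[1]], 1)
  # a sentence naming two figures appears in both figtexts
  shared <- "Figs. 1 and 2 summarize the pathway."
  expect_match(ft1, shared, fixed = TRUE)
  expect_match(figure_text(a, 2, "figtext"), shared, fixed = TRUE)
  # mention-free figure: figtext is the bare legend
  b <- fig_article(title = "t", abstract = "a", figures = list(list(label = 1, legend = "L")))
  expect_identical(figure_text(b, 1, "figtext"), "L")
  expect_error(figure_text(a, 99), "unknown figure label")
})

test_that("article_text representations include the right material", {
  a <- make_test_article()
  expect_identical(article_text(a, "title"), "alpha beta signaling")
  expect_identical(article_text(a, "abstract"),
                   "alpha beta signaling controls gamma expression")
  ft <- article_text(a, "fulltext")
  expect_match(ft, "Gamma control experiment", fixed = TRUE)  # legends included
  expect_match(ft, "Figure 2 shows gamma", fixed = TRUE)      # body included
  expect_no_match(ft, "earlier work")                         # references excluded
  # degenerate abstract warns but returns empty text
  d <- fig_article(title = "t", abstract = "", figures = list(list(label = 1, legend = "L")))
  expect_message(val <- withr::with_options(list(figrank.verbose = TRUE),
                                            article_text(d, "abstract")),
                 "empty abstract")
  expect_identical(val, "")
})

test_that("sentence segmentation guards abbreviations and preserves content", {
  expect_identical(segment_sentences("A B. C D."), c("A B.", "C D."))
  expect_identical(segment_sentences("See Fig. 3. Next."), c("See Fig. 3.", "Next."))
  expect_identical(segment_sentences(""), character(0))
  expect_identical(segment_sentences("Smith et al. found 3.5 mM. We disagree!"),
                   c("Smith et al. found 3.5 mM.", "We disagree!"))
  # concatenation reproduces the input modulo whitespace
  paras <- c("One. Two? Three!", "Only one sentence", "e.g. nothing splits here")
  for (p in paras) {
    expect_identical(gsub("\\s+", "", paste(segment_sentences(p), collapse = " ")),
                     gsub("\\s+", "", p))
  }
})

test_that("HTML stripping recovers title, abstract, sections and legends", {
  html <- paste0(
    "<html><head><title>Gamma pathway analysis</title></head><body>",
    "<div class='abstract'><p>Abstract about gamma.</p></div>",
    "<h2>Results</h2><p>Fig. 1 shows the gamma effect.</p>",
    "<div class='figure-legend'>Figure 1. <b>Gamma</b> <i>levels</i> over time.</div>",
    "</body></html>")
  a <- strip_html(html)
  expect_identical(a$title, "Gamma pathway analysis")
  expect_identical(a$abstract, "Abstract about gamma.")
  expect_length(a$sections, 1)
  expect_true(a$sections[[1]]$is_rd)
  expect_identical(a$sections[[1]]$paragraphs, "Fig. 1 shows the gamma effect.")
  # nested markup: legend equals the visible text with tags removed
  expect_identical(a$figures[["1"]]$legend, "Figure 1. Gamma levels over time.")
  expect_identical(count_mentions(a, "fulltext"), c(`1` = 1L))

  # missing abstract is a degenerate warning, not a failure
  expect_message(withr::with_options(list(figrank.verbose = TRUE),
                                     b <- strip_html("<html><body><p>Body only.</p></body></html>")),
                 "no title|no abstract")
  expect_identical(b$abstract, "")
})
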