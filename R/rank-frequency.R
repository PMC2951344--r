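# Frequency-based centrality ranking.
#
# Figures that are referred to more often are taken to be more central. Six
# strategies: raw counts in the full text or in Results & Discussion (R&D)
# sections only, and four relevancy-weighted variants in which each R&D
# paragraph's weight is its cosine similarity to the article title or
# abstract.

.FREQ_METHODS <- c("freq-fulltext", "freq-rd",
                   "wfreq-rd-para-title", "wfreq-rd-para-abs",
                   "wfreq-rd-title", "wfreq-rd-abs")

#' Frequency method identifiers
#'
#' @return Character vector of the six frequency strategy ids.
#' @export
frequency_methods <- function() .FREQ_METHODS

#' Count figure mentions
#'
#' Number of mention occurrences per figure, over the whole body
#' (`"fulltext"`) or restricted to Results & Discussion sections (`"rd"`).
#' Reference-list sections are never counted (mention extraction skips
#' them); legends are not mentions. Figures never mentioned score 0.
#'
#' @param article a `fig_article` with mentions extracted and R&D flags set.
#' @param scope `"fulltext"` or `"rd"`.
#' @return Named integer vector, one count per figure label.
#' @export
count_mentions <- function(article, scope = c("fulltext", "rd")) {
  scope <- match.arg(scope)
  stopifnot(inherits(article, "fig_article"))
  rd_sections <- which(vapply(article$sections, `[[`, TRUE, "is_rd")) - 1L
  if (scope == "rd" && !length(rd_sections))
    .warn("article ", article$id, ": no Results/Discussion sections; all rd counts 0")
  counts <- vapply(article$figures, function(f) {
    m <- f$mentions
    if (scope == "rd") m <- m[m$section_index %in% rd_sections, , drop = FALSE]
    nrow(m)
  }, 0L)
  setNames(counts, names(article$figures))
}

#' Topical relevancy of each Results & Discussion paragraph
#'
#' Cosine similarity between each R&D paragraph and an anchor text (the
#' article title or abstract), under the shared tokenizer and IDF model. An
#' empty anchor yields all-zero relevancies with a warning.
#'
#' @param article a `fig_article`.
#' @param anchor `"title"` or `"abstract"`.
#' @param idf a `fig_idf`.
#' @return data.frame with columns `section_index`, `paragraph_index`
#'   (0-based) and `relevancy` in \[0, 1\]; one row per R&D paragraph.
#' @export
paragraph_relevancy <- function(article, anchor = c("abstract", "title"), idf) {
  anchor <- match.arg(anchor)
  stopifnot(inherits(article, "fig_article"))
  anchor_text <- if (anchor == "title") article$title else article$abstract
  avec <- vectorize(anchor_text, idf)
  if (avec$norm == 0)
    .warn("article ", article$id, ": empty ", anchor, " anchor; relevancies all 0")
  rows <- list()
  for (si in seq_along(article$sections)) {
    sec <- article$sections[[si]]
    if (!isTRUE(sec$is_rd)) next
    for (pi in seq_along(sec$paragraphs)) {
      rel <- if (avec$norm == 0) 0 else cosine(vectorize(sec$paragraphs[[pi]], idf), avec)
      rows[[length(rows) + 1L]] <- data.frame(section_index = si - 1L,
                                              paragraph_index = pi - 1L,
                                              relevancy = rel)
    }
  }
  if (!length(rows))
    return(data.frame(section_index = integer(0), paragraph_index = integer(0),
                      relevancy = numeric(0)))
  do.call(rbind, rows)
}

# Per-figure mention counts within each R&D paragraph, joined to that
# paragraph's relevancy.
.rd_paragraph_counts <- function(article, relevancy) {
  key <- paste(relevancy$section_index, relevancy$paragraph_index)
  lapply(article$figures, function(f) {
    m <- f$mentions
    mk <- paste(m$section_index, m$paragraph_index)
    idx <- match(mk, key)
    idx <- idx[!is.na(idx)]
    if (!length(idx)) return(data.frame(row = integer(0), count = integer(0)))
    tab <- table(idx)
    data.frame(row = as.integer(names(tab)), count = as.integer(tab))
  })
}

#' Frequency-based centrality scores
#'
#' * `freq-fulltext`, `freq-rd`: raw mention counts ([count_mentions()]).
#' * `wfreq-rd-para-title`, `wfreq-rd-para-abs`: for each figure, take the
#'   most topic-relevant R&D paragraph *that mentions it* (ties: earliest
#'   paragraph) and score `count in that paragraph x its relevancy`;
#'   figures with no mentioning R&D paragraph score 0.
#' * `wfreq-rd-title`, `wfreq-rd-abs`: interpolate over all R&D paragraphs,
#'   `sum(count in paragraph x paragraph relevancy)`.
#'
#' @param article a `fig_article` with mentions extracted.
#' @param method_id one of [frequency_methods()].
#' @param idf a `fig_idf`; needed by the weighted strategies.
#' @return Named numeric vector of scores, one per figure label.
#' @export
score_frequency <- function(article, method_id, idf = NULL) {
  if (!(method_id %in% .FREQ_METHODS))
    stop("unknown frequency method: ", method_id,
         " (expected one of ", paste(.FREQ_METHODS, collapse = ", "), ")")
  if (method_id == "freq-fulltext")
    return(setNames(as.numeric(count_mentions(article, "fulltext")),
                    names(article$figures)))
  if (method_id == "freq-rd")
    return(setNames(as.numeric(count_mentions(article, "rd")),
                    names(article$figures)))
  if (is.null(idf)) stop("score_frequency: weighted strategies need an idf model")
  anchor <- if (grepl("title$", method_id)) "title" else "abstract"
  rel <- paragraph_relevancy(article, anchor, idf)
  per_fig <- .rd_paragraph_counts(article, rel)
  best_para <- grepl("^wfreq-rd-para-", method_id)
  scores <- vapply(per_fig, function(pf) {
    if (!nrow(pf)) return(0)
    r <- rel$relevancy[pf$row]
    if (best_para) {
      # maximal relevancy among mentioning paragraphs; ties -> earliest,
      # i.e. the first row in document order
      i <- which(r == max(r))[1]
      pf$count[i] * r[i]
    } else {
      sum(pf$count * r)
    }
  }, 0)
  setNames(scores, names(article$figures))
}
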