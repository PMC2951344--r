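# Similarity-based centrality ranking.
#
# A figure's centrality is modeled as the TF*IDF cosine similarity between a
# figure representation and an article summary representation. The 2 x 3
# grid {legend, figtext} x {title, abstract, fulltext} yields six systems.

.SIM_METHODS <- c("figlegend-title", "figlegend-abstract", "figlegend-fulltext",
                  "figtext-title", "figtext-abstract", "figtext-fulltext")

#' Similarity method identifiers
#'
#' @return Character vector of the six similarity system ids,
#'   `<figure rep>-<article rep>`.
#' @export
similarity_methods <- function() .SIM_METHODS

.parse_sim_method <- function(method_id) {
  if (!(method_id %in% .SIM_METHODS))
    stop("unknown similarity method: ", method_id,
         " (expected one of ", paste(.SIM_METHODS, collapse = ", "), ")")
  parts <- strsplit(method_id, "-", fixed = TRUE)[[1]]
  list(figure_rep = if (parts[1] == "figlegend") "legend" else "figtext",
       article_rep = switch(parts[2], title = "title", abstract = "abstract",
                            fulltext = "fulltext"))
}

#' Similarity-based centrality scores
#'
#' For each figure, `score = cosine(tfidf(figure text), tfidf(article
#' text))` where the figure text is its legend (`figlegend-*`) or legend
#' plus mentioning sentences (`figtext-*`), and the article text is the
#' title, abstract or full text. An empty article representation yields all
#' zero scores with a warning.
#'
#' @param article a `fig_article` with mentions extracted.
#' @param method_id one of [similarity_methods()].
#' @param idf a `fig_idf` background model (see [build_idf()],
#'   [collection_idf()]).
#' @return Named numeric vector of scores, one per figure label.
#' @export
score_similarity <- function(article, method_id, idf) {
  cfg <- .parse_sim_method(method_id)
  labels <- .figure_labels(article)
  atext <- article_text(article, cfg$article_rep)
  avec <- vectorize(atext, idf)
  if (avec$norm == 0) {
    .warn("article ", article$id, ": empty '", cfg$article_rep,
          "' representation; all similarity scores 0")
    return(setNames(numeric(length(labels)), as.character(labels)))
  }
  scores <- vapply(labels, function(lab) {
    fvec <- vectorize(figure_text(article, lab, cfg$figure_rep), idf)
    cosine(fvec, avec)
  }, 0)
  setNames(scores, as.character(labels))
}

#' Induce a strict ranking from scores
#'
#' Sorts descending; exact score ties are broken by earlier document
#' appearance (lower figure label first), so the induced order is always a
#' strict permutation. Rank 1 is the most important figure.
#'
#' @param scores named numeric vector (names are figure labels).
#' @param method_id method identifier recorded in the result.
#' @return A `fig_ranking`: list with `method_id`, `scores`, `order`
#'   (integer labels, rank 1 first) and `tie_breaks_applied` (number of
#'   tied score pairs resolved by the document-order rule).
#' @export
rank_from_scores <- function(scores, method_id = "scores") {
  stopifnot(is.numeric(scores), length(scores) >= 1, !is.null(names(scores)))
  labels <- as.integer(names(scores))
  ord <- order(-scores, labels)
  tab <- table(scores)
  ties <- sum(choose(tab[tab > 1], 2))
  structure(list(method_id = method_id,
                 scores = scores,
                 order = labels[ord],
                 tie_breaks_applied = as.integer(ties)),
            class = "fig_ranking")
}

#' @export
print.fig_ranking <- function(x, ...) {
  cat(sprintf("<fig_ranking> %s: %s%s\n", x$method_id,
              paste(x$order, collapse = " > "),
              if (x$tie_breaks_applied) sprintf(" (%d tie(s) broken)", x$tie_breaks_applied)
              else ""))
  invisible(x)
}

#' System rank of each figure
#'
#' @param ranking a `fig_ranking`.
#' @return Named integer vector mapping figure label to rank (1 = most
#'   important).
#' @export
ranks_of <- function(ranking) {
  stopifnot(inherits(ranking, "fig_ranking"))
  setNames(seq_along(ranking$order), as.character(ranking$order))
}

#' Collection IDF model
#'
#' Builds the default background model for desk-scale use: one document per
#' article, each being the article's full text. An externally supplied IDF
#' file (see [read_idf()]) can stand in for a larger background corpus.
#'
#' @param collection list of `fig_article`s.
#' @param ... passed to [build_idf()].
#' @return A `fig_idf`.
#' @export
collection_idf <- function(collection, ...) {
  stopifnot(length(collection) >= 1)
  build_idf(vapply(collection, article_text, "", representation = "fulltext"), ...)
}
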