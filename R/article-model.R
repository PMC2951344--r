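# Structured-article data model: JSON ingestion, lenient HTML stripping,
# Results/Discussion detection, figure-mention location, and assembly of the
# figure and article text representations used by every ranker.
#
# An article is an S3 list (class "fig_article"):
#   id        opaque string
#   title     character scalar (may be empty -> degenerate)
#   abstract  character scalar (may be empty -> degenerate)
#   sections  list of list(heading, paragraphs, is_rd, is_references)
#   figures   list of list(label (int), display, legend, mentions)
#   gold      integer vector of labels, most important first, or NULL
# Mentions are a data.frame with 0-based section/paragraph/sentence indices
# and a half-open character span within the paragraph.

.EMPTY_MENTIONS <- function() {
  data.frame(section_index = integer(0), paragraph_index = integer(0),
             sentence_index = integer(0), start = integer(0), end = integer(0))
}

#' Construct an article
#'
#' Builds a `fig_article` from its parts, flags Results/Discussion and
#' reference-list sections from their headings, and (unless `mentions` are
#' supplied) locates every figure mention in the body text.
#'
#' @param id opaque article identifier.
#' @param title,abstract character scalars; empty values are legal but mark
#'   the article degenerate for the representations that need them.
#' @param sections list of `list(heading =, paragraphs = character())`.
#' @param figures list of `list(label = <positive int>, legend =, display =)`;
#'   labels must be unique.
#' @param gold optional vector of figure labels, most important first; must
#'   be a permutation of the declared labels.
#' @param mentions optional explicit mention table (data.frame with columns
#'   `label, section_index, paragraph_index, start, end`) overriding
#'   automatic extraction.
#' @return A `fig_article`.
#' @export
fig_article <- function(id = "article", title = "", abstract = "",
                        sections = list(), figures = list(), gold = NULL,
                        mentions = NULL) {
  sections <- lapply(sections, function(s) {
    list(heading = as.character(s$heading %||% ""),
         paragraphs = as.character(unlist(s$paragraphs)),
         is_rd = FALSE, is_references = FALSE)
  })
  labels <- vapply(figures, function(f) {
    lab <- suppressWarnings(as.integer(f$label))
    if (is.na(lab) || lab < 1) stop("fig_article: figure label must be a positive integer, got: ",
                                    deparse(f$label))
    lab
  }, 0L)
  if (anyDuplicated(labels)) stop("fig_article: duplicate figure labels: ",
                                  paste(labels[duplicated(labels)], collapse = ", "))
  figures <- Map(function(f, lab) {
    list(label = lab,
         display = as.character(f$display %||% paste("Figure", lab)),
         legend = as.character(f$legend %||% ""),
         mentions = .EMPTY_MENTIONS())
  }, figures, labels)
  names(figures) <- as.character(labels)
  if (!is.null(gold)) {
    gold <- suppressWarnings(as.integer(gold))
    if (anyNA(gold) || !.is_permutation(gold, labels))
      stop("fig_article: gold ranking is not a permutation of the figure labels")
  }
  art <- structure(
    list(id = as.character(id), title = as.character(title),
         abstract = as.character(abstract), sections = sections,
         figures = figures, gold = gold),
    class = "fig_article"
  )
  art <- detect_rd_sections(art)
  if (is.null(mentions)) {
    art <- extract_figure_mentions(art)
  } else {
    art <- .attach_explicit_mentions(art, mentions)
  }
  art
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fig_article <- function(x, ...) {
  cat(sprintf("<fig_article> id=%s figures=%d sections=%d gold=%s\n",
              x$id, length(x$figures), length(x$sections),
              if (is.null(x$gold)) "no" else paste(x$gold, collapse = ",")))
  invisible(x)
}

.figure_labels <- function(article) {
  vapply(article$figures, `[[`, 0L, "label")
}

# ---------------------------------------------------------------------------
# JSON ingestion

#' Parse a structured-article JSON document
#'
#' Schema: `{id, title, abstract, sections: [{heading, paragraphs: [...]}],
#' figures: [{label, legend, display?}], gold: [labels]?, mentions?:
#' [{label, section_index, paragraph_index, start, end}]}`. Mentions are
#' recomputed from the text unless the optional `mentions` override is
#' present; a `gold` entry must be a permutation of the figure labels.
#'
#' @param source a file path or a JSON string.
#' @return A `fig_article`.
#' @seealso [write_article_json()] for the inverse.
#' @export
parse_article_json <- function(source) {
  obj <- tryCatch(jsonlite::fromJSON(source, simplifyVector = FALSE),
                  error = function(e) stop("parse_article_json: invalid JSON: ",
                                           conditionMessage(e), call. = FALSE))
  if (!is.list(obj)) stop("parse_article_json: top level must be a JSON object")
  for (field in c("title", "abstract", "figures")) {
    if (is.null(obj[[field]]))
      stop("parse_article_json: missing required field '", field, "'")
  }
  mentions <- NULL
  if (!is.null(obj$mentions)) {
    mentions <- do.call(rbind, lapply(obj$mentions, function(m) {
      for (k in c("label", "section_index", "paragraph_index", "start", "end"))
        if (is.null(m[[k]])) stop("parse_article_json: mention missing field '", k, "'")
      data.frame(label = as.integer(m$label),
                 section_index = as.integer(m$section_index),
                 paragraph_index = as.integer(m$paragraph_index),
                 start = as.integer(m$start), end = as.integer(m$end))
    }))
  }
  fig_article(id = obj$id %||% "article",
              title = obj$title, abstract = obj$abstract,
              sections = obj$sections %||% list(),
              figures = obj$figures,
              gold = if (length(obj$gold)) unlist(obj$gold) else NULL,
              mentions = mentions)
}

#' Serialize an article to structured-article JSON
#'
#' @param article a `fig_article`.
#' @param path optional file path; when `NULL` the JSON text is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
write_article_json <- function(article, path = NULL) {
  stopifnot(inherits(article, "fig_article"))
  obj <- list(
    id = article$id, title = article$title, abstract = article$abstract,
    sections = lapply(article$sections, function(s)
      list(heading = s$heading, paragraphs = as.list(s$paragraphs))),
    figures = lapply(unname(article$figures), function(f)
      list(label = f$label, display = f$display, legend = f$legend))
  )
  if (!is.null(article$gold)) obj$gold <- as.list(article$gold)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (is.null(path)) return(as.character(txt))
  writeLines(as.character(txt), path, useBytes = TRUE)
  invisible(path)
}

.attach_explicit_mentions <- function(article, mentions) {
  labels <- .figure_labels(article)
  for (i in seq_len(nrow(mentions))) {
    row <- mentions[i, ]
    if (!(row$label %in% labels)) {
      .warn("explicit mention of undeclared figure ", row$label, " dropped")
      next
    }
    key <- as.character(row$label)
    sent <- 0L
    para <- tryCatch(article$sections[[row$section_index + 1L]]$paragraphs[[row$paragraph_index + 1L]],
                     error = function(e) NULL)
    if (!is.null(para)) {
      spans <- .sentence_spans(para)
      hit <- which(spans$start <= row$start & row$start < spans$end)
      if (length(hit)) sent <- hit[1] - 1L
    }
    article$figures[[key]]$mentions <- rbind(
      article$figures[[key]]$mentions,
      data.frame(section_index = row$section_index,
                 paragraph_index = row$paragraph_index,
                 sentence_index = sent, start = row$start, end = row$end))
  }
  for (key in names(article$figures)) {
    m <- article$figures[[key]]$mentions
    article$figures[[key]]$mentions <-
      m[order(m$section_index, m$paragraph_index, m$start), , drop = FALSE]
  }
  article
}

# ---------------------------------------------------------------------------
# Section classification

# Heading "core": lowercase, with leading enumeration (arabic or roman
# numerals, punctuation, whitespace) stripped.
.heading_core <- function(heading) {
  h <- tolower(trimws(heading))
  h <- sub("^(?:[0-9]+|[ivxlc]+(?=[[:punct:][:space:]]))?[[:punct:][:space:]]*", "", h,
           perl = TRUE)
  h
}

#' Flag Results and Discussion (and reference-list) sections
#'
#' A section is Results-or-Discussion iff its heading core — lowercased,
#' with leading numbering and punctuation stripped — begins with "results"
#' or "discussion" (covers "RESULTS", "3. Discussion", "Results and
#' Discussion"). Headings beginning with "references" or "literature cited"
#' mark reference lists, which are excluded from full-text assembly and
#' mention counting. Idempotent; zero R&D sections is legal.
#'
#' @param article a `fig_article`.
#' @return The article with `is_rd` / `is_references` flags set.
#' @export
detect_rd_sections <- function(article) {
  stopifnot(inherits(article, "fig_article"))
  article$sections <- lapply(article$sections, function(s) {
    core <- .heading_core(s$heading)
    s$is_rd <- grepl("^(results|discussion)", core)
    s$is_references <- grepl("^(references|literature cited)", core)
    s
  })
  article
}

# ---------------------------------------------------------------------------
# Sentence segmentation

.ABBREVIATIONS <- c("Fig.", "Figs.", "FIG.", "FIGS.", "fig.", "figs.",
                    "et al.", "e.g.", "i.e.", "vs.", "cf.", "ca.",
                    "No.", "no.", "Dr.", "approx.", "Ref.", "ref.")

# Replace the period of each guarded abbreviation (and decimal points) with
# \x01, preserving string length so character offsets survive.
.protect_abbrev <- function(text) {
  for (ab in .ABBREVIATIONS) {
    text <- gsub(ab, gsub(".", "\x01", ab, fixed = TRUE), text, fixed = TRUE)
  }
  gsub("(?<=[0-9])\\.(?=[0-9])", "\x01", text, perl = TRUE)
}

# 0-based half-open sentence spans within a paragraph (whitespace-trimmed).
.sentence_spans <- function(paragraph) {
  empty <- data.frame(start = integer(0), end = integer(0), text = character(0))
  if (is.na(paragraph) || !nzchar(trimws(paragraph))) return(empty)
  prot <- .protect_abbrev(paragraph)
  m <- gregexpr("(?<=[.!?])\\s+", prot, perl = TRUE)[[1]]
  n <- nchar(paragraph)
  if (m[1] == -1) {
    starts <- 1L; ends <- n
  } else {
    lens <- attr(m, "match.length")
    starts <- c(1L, as.integer(m) + lens)
    ends <- c(as.integer(m) - 1L, n)
  }
  txt <- substring(paragraph, starts, ends)
  # trim spans to the non-whitespace extent
  lead <- nchar(sub("^(\\s*).*$", "\\1", txt))
  trail <- nchar(sub("^.*?(\\s*)$", "\\1", txt))
  starts <- starts + lead; ends <- ends - trail
  keep <- starts <= ends
  data.frame(start = starts[keep] - 1L, end = ends[keep],
             text = substring(paragraph, starts[keep], ends[keep]))
}

#' Split a paragraph into sentences
#'
#' Rule-based: splits after `.`, `!` or `?` followed by whitespace, with an
#' abbreviation guard list (including "Fig.", "et al.", "e.g.") and a
#' decimal-point guard. Concatenating the output reproduces the input up to
#' whitespace.
#'
#' @param paragraph character scalar.
#' @return Character vector of sentences (empty for blank input).
#' @export
#' @examples
#' segment_sentences("See Fig. 3. Next sentence.")
segment_sentences <- function(paragraph) {
  .sentence_spans(paragraph)$text
}

# ---------------------------------------------------------------------------
# Figure-mention extraction

# One regex finds a figure keyword plus its whole reference-list expression,
# e.g. "Fig. 3A and B", "Figures 2-4", "FIGS. 1, 2 and 5".
.MENTION_PATTERN <- paste0(
  "(?i)\\bfig(?:ure)?s?\\.?\\s*(",
  "[0-9]+[A-Za-z]*(?:\\s*[-–—]\\s*(?:[0-9]+[A-Za-z]*|[A-Za-z]\\b))?",
  "(?:\\s*(?:,|;|&|and)\\s*",
  "(?:[0-9]+[A-Za-z]*(?:\\s*[-–—]\\s*(?:[0-9]+[A-Za-z]*|[A-Za-z]\\b))?|[A-Za-z]\\b)",
  ")*)"
)

# Parse one captured reference expression into the set of figure numbers it
# names. Panels collapse to the parent figure; numeric ranges expand; a
# letter-only item ("and B") is a panel of the preceding figure.
.parse_mention_expr <- function(expr) {
  items <- strsplit(expr, "(?i)\\s*(?:,|;|&|\\band\\b)\\s*", perl = TRUE)[[1]]
  items <- trimws(items[nzchar(trimws(items))])
  out <- integer(0)
  for (item in items) {
    if (!grepl("^[0-9]", item)) next  # letter-only panel item
    parts <- strsplit(item, "\\s*[-–—]\\s*", perl = TRUE)[[1]]
    lo <- as.integer(sub("^([0-9]+).*$", "\\1", parts[1]))
    if (length(parts) >= 2 && grepl("^[0-9]", parts[2])) {
      hi <- as.integer(sub("^([0-9]+).*$", "\\1", parts[2]))
      if (!is.na(hi) && hi >= lo && hi - lo <= 30L) {
        out <- c(out, lo:hi)
        next
      }
    }
    out <- c(out, lo)
  }
  unique(out[!is.na(out)])
}

# All figure-reference expressions in one paragraph: data.frame(label,
# start, end) with 0-based half-open spans; one row per (expression, figure).
.find_mentions_in_text <- function(paragraph) {
  m <- gregexpr(.MENTION_PATTERN, paragraph, perl = TRUE)[[1]]
  empty <- data.frame(label = integer(0), start = integer(0), end = integer(0))
  if (m[1] == -1) return(empty)
  cs <- attr(m, "capture.start")[, 1]
  cl <- attr(m, "capture.length")[, 1]
  rows <- lapply(seq_along(m), function(i) {
    expr <- substring(paragraph, cs[i], cs[i] + cl[i] - 1L)
    labs <- .parse_mention_expr(expr)
    if (!length(labs)) return(empty)
    data.frame(label = labs, start = as.integer(m[i]) - 1L,
               end = as.integer(m[i]) + attr(m, "match.length")[i] - 1L)
  })
  do.call(rbind, rows)
}

#' Locate every figure mention in an article's body text
#'
#' Scans each paragraph of each non-reference section for figure references
#' ("Fig. 3", "Figure 2", "Figs. 2 and 3", "Figures 2–4", panel forms
#' "3A", "3A–C") and attaches one mention per (reference expression,
#' figure) to the matching `FigureRecord`. Ranges and conjunctions expand to
#' every figure they name; panel suffixes collapse to the parent figure, so
#' "Fig. 3A and B" is a single mention of figure 3. References to undeclared
#' figure numbers are dropped with a warning. Legends are not scanned: a
#' legend is the figure itself, not a referral. Re-running replaces (never
#' accumulates) mentions, so extraction is idempotent.
#'
#' @param article a `fig_article`.
#' @return The article with per-figure mention tables populated, sorted by
#'   (section, paragraph, character offset).
#' @export
extract_figure_mentions <- function(article) {
  stopifnot(inherits(article, "fig_article"))
  labels <- .figure_labels(article)
  for (key in names(article$figures)) article$figures[[key]]$mentions <- .EMPTY_MENTIONS()
  for (si in seq_along(article$sections)) {
    sec <- article$sections[[si]]
    if (isTRUE(sec$is_references)) next
    for (pi in seq_along(sec$paragraphs)) {
      para <- sec$paragraphs[[pi]]
      found <- .find_mentions_in_text(para)
      if (!nrow(found)) next
      spans <- .sentence_spans(para)
      for (r in seq_len(nrow(found))) {
        lab <- found$label[r]
        if (!(lab %in% labels)) {
          .warn(sprintf("article %s: mention of undeclared figure %d dropped (section %d)",
                        article$id, lab, si - 1L))
          next
        }
        hit <- which(spans$start <= found$start[r] & found$start[r] < spans$end)
        sent <- if (length(hit)) hit[1] - 1L else 0L
        key <- as.character(lab)
        article$figures[[key]]$mentions <- rbind(
          article$figures[[key]]$mentions,
          data.frame(section_index = si - 1L, paragraph_index = pi - 1L,
                     sentence_index = sent,
                     start = found$start[r], end = found$end[r]))
      }
    }
  }
  for (key in names(article$figures)) {
    m <- article$figures[[key]]$mentions
    article$figures[[key]]$mentions <-
      m[order(m$section_index, m$paragraph_index, m$start), , drop = FALSE]
    rownames(article$figures[[key]]$mentions) <- NULL
  }
  article
}

# ---------------------------------------------------------------------------
# Text representations

#' Text representation of one figure
#'
#' `"legend"` returns the legend string. `"figtext"` returns the legend
#' followed by every body sentence containing a mention of the figure, in
#' document order, each sentence at most once. A sentence mentioning several
#' figures contributes to each of their figtexts.
#'
#' @param article a `fig_article` with mentions extracted.
#' @param label figure label (positive integer).
#' @param representation `"legend"` or `"figtext"`.
#' @return Character scalar.
#' @export
figure_text <- function(article, label, representation = c("figtext", "legend")) {
  representation <- match.arg(representation)
  stopifnot(inherits(article, "fig_article"))
  key <- as.character(as.integer(label))
  fig <- article$figures[[key]]
  if (is.null(fig)) stop("figure_text: unknown figure label: ", label)
  if (representation == "legend") return(fig$legend)
  m <- fig$mentions
  if (!nrow(m)) return(fig$legend)
  keys <- unique(m[, c("section_index", "paragraph_index", "sentence_index")])
  keys <- keys[order(keys$section_index, keys$paragraph_index, keys$sentence_index), ,
               drop = FALSE]
  sents <- vapply(seq_len(nrow(keys)), function(i) {
    para <- article$sections[[keys$section_index[i] + 1L]]$paragraphs[[keys$paragraph_index[i] + 1L]]
    spans <- .sentence_spans(para)
    idx <- keys$sentence_index[i] + 1L
    if (idx <= nrow(spans)) spans$text[idx] else ""
  }, "")
  paste(c(fig$legend, sents[nzchar(sents)]), collapse = " ")
}

#' Summary representation of the article
#'
#' `"title"` and `"abstract"` return those fields (an empty value triggers a
#' degenerate-article warning). `"fulltext"` concatenates title, abstract,
#' every paragraph of every non-reference section, and every figure legend.
#'
#' @param article a `fig_article`.
#' @param representation `"title"`, `"abstract"` or `"fulltext"`.
#' @return Character scalar.
#' @export
article_text <- function(article, representation = c("fulltext", "title", "abstract")) {
  representation <- match.arg(representation)
  stopifnot(inherits(article, "fig_article"))
  if (representation == "title") {
    if (!nzchar(article$title)) .warn("article ", article$id, ": empty title representation")
    return(article$title)
  }
  if (representation == "abstract") {
    if (!nzchar(article$abstract)) .warn("article ", article$id, ": empty abstract representation")
    return(article$abstract)
  }
  paras <- unlist(lapply(article$sections, function(s) {
    if (isTRUE(s$is_references)) character(0) else s$paragraphs
  }))
  legends <- vapply(article$figures, `[[`, "", "legend")
  paste(c(article$title, article$abstract, paras, legends), collapse = " ")
}
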