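# Lenient HTML -> fig_article conversion.
#
# Best-effort stripping of generic article HTML into the structured-article
# model. Landmarks are located with configurable XPath selectors; anything
# not claimed by a selector is concatenated into a "Body" section. Lossy
# steps are logged, never silent.

.DEFAULT_SELECTORS <- list(
  title = "//h1 | //head/title",
  abstract = "//*[contains(concat(' ', normalize-space(@class), ' '), ' abstract ')] | //abstract",
  legend = paste0("//figcaption",
                  " | //*[contains(concat(' ', normalize-space(@class), ' '), ' figure-legend ')]",
                  " | //*[contains(concat(' ', normalize-space(@class), ' '), ' fig-caption ')]"),
  heading = "//h2",
  paragraph = "//p"
)

.node_text <- function(nodes) {
  if (length(nodes) == 0) return(character(0))
  trimws(gsub("\\s+", " ", xml2::xml_text(nodes)))
}

#' Strip article HTML into a structured article
#'
#' Best-effort conversion of generic article HTML: the title, abstract and
#' figure legends are located with XPath selectors (overridable through
#' `selectors`), `<h2>` headings open sections, and every other `<p>` falls
#' into the section opened by the preceding heading (or a catch-all "Body"
#' section). Figure labels are read from the leading "Figure N" of each
#' legend when present, otherwise assigned sequentially. A missing title or
#' abstract yields a degenerate article plus a warning, not a failure.
#'
#' @param html a file path or an HTML string.
#' @param selectors named list overriding any of the XPath selectors
#'   `title`, `abstract`, `legend`, `heading`, `paragraph`.
#' @return A `fig_article` (without gold ranking).
#' @export
strip_html <- function(html, selectors = list()) {
  sel <- utils::modifyList(.DEFAULT_SELECTORS, selectors)
  doc <- xml2::read_html(html)

  title <- .node_text(xml2::xml_find_first(doc, sel$title))
  if (!length(title) || is.na(title) || !nzchar(title)) {
    .warn("strip_html: no title found; article is degenerate")
    title <- ""
  }
  abstract_nodes <- xml2::xml_find_all(doc, sel$abstract)
  abstract <- paste(.node_text(abstract_nodes), collapse = " ")
  if (!nzchar(abstract)) .warn("strip_html: no abstract found")

  legend_nodes <- xml2::xml_find_all(doc, sel$legend)
  legends <- .node_text(legend_nodes)
  figures <- list()
  next_label <- 1L
  for (leg in legends) {
    m <- regmatches(leg, regexec("(?i)^fig(?:ure)?s?\\.?\\s*([0-9]+)", leg, perl = TRUE))[[1]]
    lab <- if (length(m) == 2) as.integer(m[2]) else next_label
    next_label <- max(next_label, lab) + 1L
    figures[[length(figures) + 1L]] <- list(label = lab, legend = leg)
  }

  # Sections: paragraphs grouped under the nearest preceding heading; text
  # already claimed as abstract or legend is excluded; the rest pools into
  # a catch-all "Body" section. A combined XPath yields document order.
  claimed_paths <- vapply(c(abstract_nodes, legend_nodes), xml2::xml_path, "")
  heading_paths <- vapply(xml2::xml_find_all(doc, sel$heading), xml2::xml_path, "")
  all_nodes <- xml2::xml_find_all(doc, paste(sel$heading, sel$paragraph, sep = " | "))
  paths <- vapply(all_nodes, xml2::xml_path, "")
  under_claimed <- vapply(paths, function(p)
    any(startsWith(p, claimed_paths)), TRUE, USE.NAMES = FALSE)
  keep <- !under_claimed | paths %in% heading_paths
  all_nodes <- all_nodes[keep]
  kinds <- ifelse(paths[keep] %in% heading_paths, "h", "p")

  sections <- list(); cur_heading <- "Body"; cur_paras <- character(0)
  flush <- function() {
    if (length(cur_paras))
      sections[[length(sections) + 1L]] <<- list(heading = cur_heading,
                                                 paragraphs = cur_paras)
  }
  for (i in seq_along(all_nodes)) {
    if (kinds[i] == "h") {
      flush()
      cur_heading <- .node_text(all_nodes[[i]])
      cur_paras <- character(0)
    } else {
      txt <- .node_text(all_nodes[[i]])
      if (nzchar(txt)) cur_paras <- c(cur_paras, txt)
    }
  }
  flush()
  if (!length(sections)) .warn("strip_html: no body paragraphs found")

  fig_article(id = "html-article", title = title, abstract = abstract,
              sections = sections, figures = figures)
}
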