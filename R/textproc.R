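# Tokenization, IDF model, sparse TF*IDF vectors, cosine similarity.
#
# This is the shared numerical substrate of every similarity and relevancy
# computation in the package: all rankers call tokenize() -> vectorize() ->
# cosine() with one IdfModel, so a single configuration governs every score.

#' Tokenize text
#'
#' Deterministic rule-based tokenizer: lowercases, splits on every
#' non-alphanumeric character (so hyphenated forms split), keeps tokens of
#' length >= 2, and removes stopwords when `stopwords = TRUE` (default; see
#' [figrank_stopwords()]). No stemming or lemmatization is applied.
#'
#' @param text a character scalar (vectors are concatenated with spaces).
#' @param stopwords logical; remove the built-in stopword list.
#' @return Character vector of tokens (possibly empty).
#' @export
#' @examples
#' tokenize("The p75 receptor binds.")
tokenize <- function(text, stopwords = TRUE) {
  if (length(text) == 0) return(character(0))
  text <- paste(text, collapse = " ")
  if (is.na(text) || !nzchar(text)) return(character(0))
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks <- toks[nchar(toks) >= 2]
  if (isTRUE(stopwords)) toks <- toks[!(toks %in% .STOPWORDS)]
  toks
}

#' Build an inverse-document-frequency model from a document collection
#'
#' Counts, for each term, the number of documents containing it at least
#' once. The resulting model stands in for a large background corpus (the
#' original approach weighted terms against MEDLINE-scale document
#' frequencies); any collection — e.g. the full texts of the articles under
#' evaluation — can serve as the background.
#'
#' @param documents character vector of document texts (length >= 1).
#' @param stopwords passed to [tokenize()].
#' @param smoothing `"smooth"` (default) for idf = ln((N+1)/(df+1)), which
#'   keeps out-of-corpus terms finite, or `"raw"` for ln(N/df).
#' @return An object of class `fig_idf` with fields `corpus_size`, `df`
#'   (named integer vector), `smoothing`, `stopwords`.
#' @export
#' @examples
#' m <- build_idf(c("a b", "b c"))
#' m$df           # a=1, b=2, c=1 (after stopword filtering of "a")
build_idf <- function(documents, stopwords = TRUE, smoothing = c("smooth", "raw")) {
  smoothing <- match.arg(smoothing)
  if (length(documents) < 1) stop("build_idf: need at least one document")
  per_doc <- lapply(documents, function(d) unique(tokenize(d, stopwords = stopwords)))
  all_terms <- unlist(per_doc, use.names = FALSE)
  df <- if (length(all_terms)) table(all_terms) else table(character(0))
  df <- setNames(as.integer(df), names(df))
  structure(
    list(corpus_size = length(documents), df = df,
         smoothing = smoothing, stopwords = isTRUE(stopwords)),
    class = "fig_idf"
  )
}

#' @export
print.fig_idf <- function(x, ...) {
  cat(sprintf("<fig_idf> corpus_size=%d terms=%d smoothing=%s\n",
              x$corpus_size, length(x$df), x$smoothing))
  invisible(x)
}

.idf_factor <- function(terms, idf) {
  df <- idf$df[terms]
  df[is.na(df)] <- 0L
  if (idf$smoothing == "smooth") {
    log((idf$corpus_size + 1) / (df + 1))
  } else {
    # raw ln(N/df); unseen terms get the maximal finite weight ln(N/1)
    df[df == 0L] <- 1L
    log(idf$corpus_size / df)
  }
}

#' Write / read an IDF model as TSV
#'
#' Plain-text interchange format: a header line `#corpus_size=<int>`
#' (plus `#smoothing=` and `#stopwords=` header lines), then one
#' `term<TAB>df` row per term, UTF-8.
#'
#' @param idf a `fig_idf` model.
#' @param path file path.
#' @return `write_idf` returns `path` invisibly; `read_idf` returns a
#'   `fig_idf`.
#' @export
write_idf <- function(idf, path) {
  stopifnot(inherits(idf, "fig_idf"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("#corpus_size=%d", idf$corpus_size),
               sprintf("#smoothing=%s", idf$smoothing),
               sprintf("#stopwords=%s", tolower(as.character(idf$stopwords)))), con)
  if (length(idf$df)) {
    writeLines(paste(names(idf$df), idf$df, sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_idf
#' @export
read_idf <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  get_hdr <- function(key, default = NULL) {
    m <- grep(paste0("^#", key, "="), hdr, value = TRUE)
    if (length(m)) sub(paste0("^#", key, "="), "", m[1]) else default
  }
  n <- get_hdr("corpus_size")
  if (is.null(n)) stop("read_idf: missing #corpus_size= header in ", path)
  df <- integer(0)
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    bad <- vapply(parts, length, 0L) != 2L
    if (any(bad)) stop("read_idf: malformed row(s): ", paste(body[bad][1], collapse = ", "))
    df <- setNames(as.integer(vapply(parts, `[[`, "", 2L)),
                   vapply(parts, `[[`, "", 1L))
  }
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("read_idf: corpus_size must be a positive integer")
  if (length(df) && (any(df < 1) || any(df > n)))
    stop("read_idf: document frequencies must lie in [1, corpus_size]")
  structure(
    list(corpus_size = n, df = df,
         smoothing = get_hdr("smoothing", "smooth"),
         stopwords = identical(get_hdr("stopwords", "true"), "true")),
    class = "fig_idf"
  )
}

#' TF*IDF term vector of a text
#'
#' Builds a sparse term vector with weight `tf(t) * idf(t)`, where `tf` is
#' the raw token count in `text` and `idf` comes from the model's smoothing
#' rule (default `ln((N+1)/(df+1))`, with df = 0 for terms absent from the
#' background corpus). Zero-weight entries are dropped; the Euclidean norm
#' is cached.
#'
#' @param text character scalar.
#' @param idf a `fig_idf` model.
#' @return A `fig_tv` object: list with `weights` (named non-negative
#'   numeric, no zeros) and `norm`.
#' @export
vectorize <- function(text, idf) {
  stopifnot(inherits(idf, "fig_idf"))
  toks <- tokenize(text, stopwords = idf$stopwords)
  if (!length(toks)) {
    return(structure(list(weights = setNames(numeric(0), character(0)), norm = 0),
                     class = "fig_tv"))
  }
  tf <- table(toks)
  terms <- names(tf)
  w <- as.numeric(tf) * .idf_factor(terms, idf)
  keep <- w > 0
  w <- setNames(w[keep], terms[keep])
  structure(list(weights = w, norm = sqrt(sum(w^2))), class = "fig_tv")
}

#' @export
print.fig_tv <- function(x, ...) {
  cat(sprintf("<fig_tv> %d terms, norm=%.4g\n", length(x$weights), x$norm))
  invisible(x)
}

#' Cosine similarity of two term vectors
#'
#' `dot(u, v) / (|u| |v|)`, defined as 0 when either norm is 0. For
#' non-negative weights the value lies in \[0, 1\].
#'
#' @param u,v `fig_tv` objects from [vectorize()].
#' @return numeric scalar in \[0, 1\].
#' @export
cosine <- function(u, v) {
  stopifnot(inherits(u, "fig_tv"), inherits(v, "fig_tv"))
  if (u$norm == 0 || v$norm == 0) return(0)
  common <- intersect(names(u$weights), names(v$weights))
  if (!length(common)) return(0)
  min(1, sum(u$weights[common] * v$weights[common]) / (u$norm * v$norm))
}
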