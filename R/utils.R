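# Internal helpers: logging and config hashing.

.log_msg <- function(..., level = "INFO", verbose = getOption("figrank.verbose", TRUE)) {
  if (isTRUE(verbose)) {
    message(sprintf("[figrank %s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

.warn <- function(...) .log_msg(..., level = "WARN")

#' Hash a configuration object
#'
#' Serializes a configuration (any list of atomic options) to canonical JSON
#' and returns the MD5 of that text. The hash is embedded in every report so
#' that two reports are comparable iff they were produced under identical
#' tokenizer/IDF/ranker settings.
#'
#' @param cfg a named list of configuration values.
#' @return A length-one character MD5 hex digest.
#' @export
#' @examples
#' config_hash(list(stopwords = TRUE, idf = "smooth"))
config_hash <- function(cfg) {
  stopifnot(is.list(cfg))
  cfg <- cfg[order(names(cfg))]
  txt <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  writeLines(as.character(txt), tf)
  unname(tools::md5sum(tf))
}

# Strict-order check: x is a permutation of labels.
.is_permutation <- function(x, labels) {
  length(x) == length(labels) && setequal(x, labels) && !anyDuplicated(x)
}
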