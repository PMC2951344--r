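# Built-in English stopword list, version 1.
#
# A compact general-English function-word list (SMART-style core). Shipped
# in-source and versioned so that tokenization is reproducible across
# installations; the tokenizer records the list version via the config hash.

.STOPWORDS_VERSION <- "en-core-1"

.STOPWORDS <- c(
  "a", "about", "above", "after", "again", "against", "all", "also", "am",
  "an", "and", "any", "are", "as", "at", "be", "because", "been", "before",
  "being", "below", "between", "both", "but", "by", "can", "cannot", "could",
  "did", "do", "does", "doing", "down", "during", "each", "few", "for",
  "from", "further", "had", "has", "have", "having", "he", "her", "here",
  "hers", "him", "his", "how", "however", "i", "if", "in", "into", "is",
  "it", "its", "itself", "just", "may", "me", "might", "more", "most",
  "must", "my", "no", "nor", "not", "of", "off", "on", "once", "only", "or",
  "other", "our", "ours", "out", "over", "own", "per", "same", "shall",
  "she", "should", "so", "some", "such", "than", "that", "the", "their",
  "theirs", "them", "then", "there", "these", "they", "this", "those",
  "through", "thus", "to", "too", "under", "until", "up", "upon", "us",
  "very", "was", "we", "were", "what", "when", "where", "which", "while",
  "who", "whom", "why", "will", "with", "within", "without", "would", "you",
  "your", "yours"
)

#' Built-in stopword list
#'
#' Returns the versioned English stopword list used by [tokenize()] when
#' stopword removal is enabled (the default).
#'
#' @return Character vector of lowercase stopwords.
#' @export
figrank_stopwords <- function() .STOPWORDS
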