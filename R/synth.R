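# Synthetic article collections with planted gold rankings.
#
# Each article gets a topic vocabulary that defines its title and abstract.
# Importance signals are planted in two *disjoint channels* so that the
# similarity and frequency rankers are complementary and their linear
# combination can beat either alone:
#   * similarity channel — the legend of the figure at gold rank k mixes
#     topic words with weight sim_signal * (1 - (k-1)/(n-1)), the rest
#     drawn from a background vocabulary;
#   * frequency channel — the number of Results/Discussion mentions of the
#     rank-k figure decreases in k with strength freq_signal.
# `noise` corrupts both channels (background words in topic slots, jitter
# on mention counts). All randomness flows from one seed.

#' Synthetic-collection configuration
#'
#' The figure-count sampler defaults emulate a real annotated corpus of
#' full-text bioscience articles: mean 5.9 figures per article, sd 1.75,
#' clipped to the observed range 2–13.
#'
#' @param n_articles number of articles.
#' @param fig_mean,fig_sd,fig_range figure-count sampler (normal, rounded,
#'   clipped).
#' @param vocab_size background vocabulary size.
#' @param topic_size topic words per article.
#' @param sim_signal,freq_signal planted signal strengths in \[0, 1\].
#' @param noise corruption level in \[0, 1\].
#' @param seed master seed; fully determines the collection.
#' @return A `fig_synth_config` list.
#' @export
synth_config <- function(n_articles = 100, fig_mean = 5.9, fig_sd = 1.75,
                         fig_range = c(2L, 13L), vocab_size = 400L,
                         topic_size = 30L, sim_signal = 0.9,
                         freq_signal = 0.9, noise = 0.1, seed = 1L) {
  for (p in c(sim_signal, freq_signal, noise))
    if (!is.numeric(p) || p < 0 || p > 1)
      stop("synth_config: sim_signal, freq_signal and noise must lie in [0, 1]")
  stopifnot(n_articles >= 1, vocab_size >= 10, topic_size >= 3,
            fig_range[1] >= 1, fig_range[2] >= fig_range[1])
  structure(list(n_articles = as.integer(n_articles), fig_mean = fig_mean,
                 fig_sd = fig_sd, fig_range = as.integer(fig_range),
                 vocab_size = as.integer(vocab_size),
                 topic_size = as.integer(topic_size),
                 sim_signal = sim_signal, freq_signal = freq_signal,
                 noise = noise, seed = as.integer(seed)),
            class = "fig_synth_config")
}

.bg_pool <- function(cfg) sprintf("bgw%04d", seq_len(cfg$vocab_size))
.topic_pool <- function(cfg) sprintf("topw%04d", seq_len(cfg$vocab_size))

.words <- function(pool, n) {
  if (n <= 0) return(character(0))
  sample(pool, n, replace = TRUE)
}

# topic mixture weight of the figure at gold rank k among n
.sim_weight <- function(cfg, k, n) {
  if (n == 1) return(cfg$sim_signal)
  cfg$sim_signal * (1 - (k - 1) / (n - 1))
}

# planted R&D mention count of the figure at gold rank k among n
.freq_count <- function(cfg, k, n) {
  1L + as.integer(round(cfg$freq_signal * 2 * (n - k))) +
    stats::rpois(1, cfg$noise * 2)
}

#' Generate one synthetic article
#'
#' Builds an IMRaD-shaped article (Introduction, Methods, Results,
#' Discussion) whose figures carry a planted gold ranking: legend topic
#' content decays with gold rank (similarity channel) and R&D mention
#' counts decay with gold rank (frequency channel). All topic tokens outside
#' the title are drawn from the abstract's realized word distribution, so
#' text about central figures echoes the abstract's vocabulary.
#'
#' @param cfg a [synth_config()].
#' @param seed per-article seed (defaults to `cfg$seed`).
#' @return A `fig_article` with gold ranking.
#' @export
generate_article <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "fig_synth_config"))
  set.seed(as.integer(seed))
  bg <- .bg_pool(cfg)
  topic <- sample(.topic_pool(cfg), cfg$topic_size)

  n <- as.integer(round(stats::rnorm(1, cfg$fig_mean, cfg$fig_sd)))
  n <- max(cfg$fig_range[1], min(cfg$fig_range[2], n))
  gold <- sample.int(n)                      # labels, most important first
  rank_of <- match(seq_len(n), gold)         # gold rank of each label

  title <- paste(sample(topic, min(6L, cfg$topic_size)), collapse = " ")
  abs_topic <- .words(topic, 120L)
  abs_words <- c(abs_topic, .words(bg, round(120 * cfg$noise)))
  abstract <- paste(sample(abs_words), collapse = " ")

  # Topic tokens elsewhere are drawn from the abstract's realized word
  # distribution, not the latent pool: text about the article's findings
  # echoes the abstract's vocabulary, which anchors the similarity channel.
  legends <- vapply(seq_len(n), function(lab) {
    w <- .sim_weight(cfg, rank_of[lab], n)
    n_topic <- round(30 * w * (1 - cfg$noise))
    words <- c(.words(abs_topic, n_topic), .words(bg, 30L - n_topic))
    paste0("Figure ", lab, " legend: ", paste(sample(words), collapse = " "), ".")
  }, "")

  figures <- lapply(seq_len(n), function(lab) list(label = lab, legend = legends[lab]))

  # A sentence discussing figure `lab` mixes topic words with the same
  # rank-dependent weight as the figure's legend: text about an important
  # figure talks about the article's main topic. This keeps the similarity
  # signal coherent across legend and associated text, while the frequency
  # signal lives only in how many such sentences exist.
  mention_sentence <- function(lab) {
    w <- .sim_weight(cfg, rank_of[lab], n)
    n_topic <- round(4 * w * (1 - cfg$noise))
    words <- c(.words(abs_topic, n_topic), .words(bg, 4L - n_topic))
    paste0("We observed ", paste(sample(words), collapse = " "),
           " as shown in Fig. ", lab, ".")
  }
  para_preamble <- function()
    paste0(paste(c(.words(abs_topic, 4L), .words(bg, 6L)), collapse = " "), ".")

  # Results/Discussion paragraphs receive the planted mention counts.
  counts <- vapply(seq_len(n), function(lab) .freq_count(cfg, rank_of[lab], n), 0L)
  n_rd <- max(3L, ceiling(sum(counts) / 6))
  rd_sentences <- vector("list", n_rd)
  for (lab in seq_len(n)) {
    for (i in seq_len(counts[lab])) {
      p <- sample.int(n_rd, 1)
      rd_sentences[[p]] <- c(rd_sentences[[p]], mention_sentence(lab))
    }
  }
  rd_paras <- vapply(rd_sentences, function(s)
    paste(c(para_preamble(), s), collapse = " "), "")
  n_results <- max(1L, n_rd - 1L)

  # a little full-text-only mention noise in the Introduction
  intro_mentions <- vapply(seq_len(n), function(lab)
    if (stats::runif(1) < cfg$noise) mention_sentence(lab) else "", "")
  intro <- paste(c(para_preamble(), para_preamble(),
                   intro_mentions[nzchar(intro_mentions)]), collapse = " ")
  methods <- paste(c(para_preamble(), paste(.words(bg, 20L), collapse = " ")),
                   collapse = " ")

  sections <- list(
    list(heading = "Introduction", paragraphs = intro),
    list(heading = "Materials and Methods", paragraphs = methods),
    list(heading = "Results", paragraphs = rd_paras[seq_len(n_results)]),
    list(heading = "Discussion",
         paragraphs = if (n_rd > n_results) rd_paras[(n_results + 1L):n_rd]
                      else para_preamble()),
    list(heading = "References",
         paragraphs = paste(.words(bg, 15L), collapse = " "))
  )

  fig_article(id = sprintf("synth-%d", as.integer(seed)),
              title = title, abstract = abstract, sections = sections,
              figures = figures, gold = gold)
}

#' Generate a synthetic collection
#'
#' Derives one seed per article deterministically from the master seed and
#' calls [generate_article()] for each. With `dir` given, writes one
#' structured-article JSON file per article plus a `manifest.json` echoing
#' the configuration and per-article seeds; an existing non-empty directory
#' is refused unless `force = TRUE`.
#'
#' @param cfg a [synth_config()].
#' @param dir optional output directory.
#' @param force overwrite into a non-empty directory.
#' @return List of `fig_article`s (invisibly when writing to `dir`).
#' @export
generate_collection <- function(cfg, dir = NULL, force = FALSE) {
  stopifnot(inherits(cfg, "fig_synth_config"))
  set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max, cfg$n_articles)
  articles <- lapply(seeds, function(s) generate_article(cfg, seed = s))
  if (is.null(dir)) return(articles)
  if (dir.exists(dir) && length(list.files(dir)) && !isTRUE(force))
    stop("generate_collection: output directory ", dir,
         " is not empty (use force = TRUE to overwrite)")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(articles), function(i) {
    p <- file.path(dir, sprintf("article-%03d.json", i))
    write_article_json(articles[[i]], p)
    p
  }, "")
  manifest <- list(config = unclass(cfg), article_seeds = seeds,
                   files = basename(paths))
  writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE)),
             file.path(dir, "manifest.json"))
  invisible(articles)
}

#' Read a collection directory
#'
#' Parses every `*.json` structured-article file in `dir` (ignoring
#' `manifest.json`).
#'
#' @param dir directory of article JSON files.
#' @return List of `fig_article`s.
#' @export
read_collection <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  if (!length(files)) stop("read_collection: no article JSON files in ", dir)
  lapply(files, parse_article_json)
}
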