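# Linear combination of a similarity system and a frequency system.
#
# combined(f) = lambda * sim(f) + (1 - lambda) * freq(f), after per-article
# normalization: cosine scores live in [0,1] but weighted mention counts are
# unbounded, so raw scores are not commensurate. lambda = 1 reproduces the
# similarity ranking, lambda = 0 the frequency ranking, for every
# normalization mode.

#' Normalize an article's scores
#'
#' * `"minmax"`: affine map onto \[0, 1\]; constant score vectors map to 0.5.
#' * `"rank"`: `1 - (rank - 1)/(n - 1)` from the induced strict ranking
#'   (1 for the top figure, 0 for the bottom; 1 for a single figure).
#' * `"none"`: identity.
#'
#' @param scores named numeric vector.
#' @param normalization `"minmax"`, `"rank"` or `"none"`.
#' @return Named numeric vector on the same labels.
#' @export
normalize_scores <- function(scores, normalization = c("minmax", "rank", "none")) {
  normalization <- match.arg(normalization)
  if (normalization == "none") return(scores)
  if (normalization == "minmax") {
    rng <- range(scores)
    if (rng[1] == rng[2]) return(setNames(rep(0.5, length(scores)), names(scores)))
    return((scores - rng[1]) / (rng[2] - rng[1]))
  }
  ranking <- rank_from_scores(scores)
  r <- ranks_of(ranking)[names(scores)]
  n <- length(scores)
  if (n == 1) return(setNames(1, names(scores)))
  setNames(1 - (r - 1) / (n - 1), names(scores))
}

#' Linearly combine a similarity and a frequency ranking
#'
#' Computes both member systems' scores, normalizes each within the
#' article, and ranks figures by
#' `lambda * sim + (1 - lambda) * freq`. The defaults pair the best
#' similarity system (`figtext-abstract`) with the best frequency system
#' (`wfreq-rd-abs`).
#'
#' @param article a `fig_article` with mentions extracted.
#' @param idf a `fig_idf`.
#' @param lambda mixing weight in \[0, 1\]; 1 = pure similarity, 0 = pure
#'   frequency.
#' @param sim_method,freq_method member system ids.
#' @param normalization see [normalize_scores()].
#' @return A `fig_ranking` with `method_id` `"combined"`.
#' @export
combine_linear <- function(article, idf, lambda = 0.8,
                           sim_method = "figtext-abstract",
                           freq_method = "wfreq-rd-abs",
                           normalization = c("minmax", "rank", "none")) {
  normalization <- match.arg(normalization)
  stopifnot(is.numeric(lambda), length(lambda) == 1, lambda >= 0, lambda <= 1)
  m <- .member_scores(article, idf, sim_method, freq_method, normalization)
  .combine_members(m, lambda)
}

.member_scores <- function(article, idf, sim_method, freq_method, normalization) {
  sim <- normalize_scores(score_similarity(article, sim_method, idf), normalization)
  freq <- normalize_scores(score_frequency(article, freq_method, idf), normalization)
  list(sim = sim, freq = freq[names(sim)])
}

.combine_members <- function(m, lambda) {
  rank_from_scores(lambda * m$sim + (1 - lambda) * m$freq,
                   method_id = sprintf("combined(lambda=%g)", lambda))
}

#' Sweep the combination weight over a grid
#'
#' For each lambda on the grid, ranks every article in the collection with
#' [combine_linear()] and evaluates all five metrics against the gold
#' rankings. Grid endpoints 0 and 1 reproduce the member systems' rows
#' exactly. Articles without a gold ranking are excluded and logged.
#'
#' @param collection list of `fig_article`s with gold rankings.
#' @param idf a `fig_idf`; defaults to [collection_idf()] of the collection.
#' @param grid numeric vector of lambdas in \[0, 1\].
#' @param sim_method,freq_method,normalization passed to [combine_linear()].
#' @return data.frame with one row per lambda and columns `lambda, mer,
#'   mwer, mwer_rk, er_hr, wer_hr, n_articles, n_excluded`.
#' @export
sweep_lambda <- function(collection, idf = NULL, grid = seq(0, 1, by = 0.1),
                         sim_method = "figtext-abstract",
                         freq_method = "wfreq-rd-abs",
                         normalization = "minmax") {
  stopifnot(length(collection) >= 1, all(grid >= 0 & grid <= 1))
  if (is.null(idf)) idf <- collection_idf(collection)
  has_gold <- vapply(collection, function(a) !is.null(a$gold), TRUE)
  if (any(!has_gold)) {
    .warn(sum(!has_gold), " article(s) without gold ranking excluded from sweep")
    collection <- collection[has_gold]
  }
  if (!length(collection)) stop("sweep_lambda: no article has a gold ranking")
  # member scores are lambda-independent: compute them once per article
  members <- lapply(collection, .member_scores, idf = idf,
                    sim_method = sim_method, freq_method = freq_method,
                    normalization = normalization)
  rows <- lapply(grid, function(lam) {
    pairs <- Map(function(a, m) list(ref = a$gold, sys = .combine_members(m, lam)$order),
                 collection, members)
    s <- .collection_metrics(pairs)
    cbind(data.frame(lambda = lam), s)
  })
  do.call(rbind, rows)
}
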