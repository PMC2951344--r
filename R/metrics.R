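# Rank-error evaluation metrics.
#
# A ranking is evaluated against the author's gold order with five metrics:
#   MER      fraction of figure pairs whose relative order is wrong
#   MWER     wrong pairs weighted by their reference-rank distance
#   MWER-RK  MWER with an additional logistic penalty favouring pairs that
#            involve highly ranked (more important) figures
#   ER-HR    error rate on identifying the single most important figure
#   WER-HR   how far down the system placed the reference-top figure
# All rankings here are strict orders: label sequences, rank 1 first.

# Reference rank of each label under an order vector.
.rank_map <- function(order) setNames(seq_along(order), as.character(order))

.check_pairwise_input <- function(ref, sys) {
  ref <- as.integer(ref); sys <- as.integer(sys)
  if (!.is_permutation(sys, ref))
    stop("system order must be a strict permutation of the reference labels")
  if (length(ref) < 2)
    stop("pairwise metrics are undefined for fewer than 2 figures")
  list(ref = ref, sys = sys)
}

# All unordered pairs with reference distance and wrongness flag.
.pair_table <- function(ref, sys) {
  rr <- .rank_map(ref); sr <- .rank_map(sys)
  idx <- utils::combn(as.character(ref), 2)
  ri <- rr[idx[1, ]]; rj <- rr[idx[2, ]]
  si <- sr[idx[1, ]]; sj <- sr[idx[2, ]]
  data.frame(d = abs(ri - rj),
             min_ref = pmin(ri, rj),
             wrong = sign(ri - rj) != sign(si - sj))
}

#' Pairwise error rate of a figure ranking (MER)
#'
#' Fraction of figure pairs whose relative order in the system output
#' disagrees with the reference — the Kendall tau distance normalized by
#' the number of pairs.
#'
#' @param ref reference (gold) order: labels, most important first.
#' @param sys system order, same labels.
#' @return numeric in \[0, 1\].
#' @export
#' @examples
#' mer(1:4, c(2, 1, 3, 4))   # 1 wrong pair of 6 -> 0.1667
mer <- function(ref, sys) {
  x <- .check_pairwise_input(ref, sys)
  p <- .pair_table(x$ref, x$sys)
  sum(p$wrong) / nrow(p)
}

#' Distance-weighted pairwise error rate (MWER)
#'
#' Each wrong pair is weighted by the distance between the two figures'
#' reference ranks; normalized by the total distance over all pairs, so a
#' full reversal scores 1.
#'
#' @inheritParams mer
#' @return numeric in \[0, 1\].
#' @export
#' @examples
#' mwer(1:4, c(2, 1, 3, 4))  # 0.1
mwer <- function(ref, sys) {
  x <- .check_pairwise_input(ref, sys)
  p <- .pair_table(x$ref, x$sys)
  sum(p$d[p$wrong]) / sum(p$d)
}

# Logistic pair weight: a wrong pair whose better-ranked member has
# reference rank m contributes weight L(m) = 4 / (1 + e^m), so errors on
# important figures (small m) cost more.
.logistic_weight <- function(m) 4 / (1 + exp(m))

#' Rank-sensitive weighted error rate (MWER-RK)
#'
#' MWER with an additional logistic weight on each wrong pair: pairs
#' involving more important figures (smaller best reference rank m) are
#' penalized more, via `L(m) = 4 / (1 + exp(m))`. Normalization is by the
#' unweighted total pair distance, as in [mwer()].
#'
#' @inheritParams mer
#' @return numeric >= 0; 0 iff no pair is wrong.
#' @export
#' @examples
#' mwer_rk(1:4, c(2, 1, 3, 4))  # 0.108: the error involves the top figure
#' mwer_rk(1:4, c(1, 2, 4, 3))  # 0.019: same distance, unimportant figures
mwer_rk <- function(ref, sys) {
  x <- .check_pairwise_input(ref, sys)
  p <- .pair_table(x$ref, x$sys)
  sum(p$d[p$wrong] * .logistic_weight(p$min_ref[p$wrong])) / sum(p$d)
}

#' Highest-rank error rate over a collection (ER-HR)
#'
#' Fraction of articles whose system rank-1 figure differs from the
#' reference rank-1 figure. Single-figure articles always agree.
#'
#' @param pairs list of `list(ref =, sys =)` order vectors, one per article.
#' @return numeric in \[0, 1\].
#' @export
er_hr <- function(pairs) {
  stopifnot(length(pairs) >= 1)
  mean(vapply(pairs, function(p) p$ref[1] != p$sys[1], TRUE))
}

#' Weighted highest-rank error rate over a collection (WER-HR)
#'
#' Mean over articles of `(SysRank(reference-top figure) - 1) / (numFig -
#' 1)`: 0 when the system also ranks that figure first, 1 when it ranks it
#' last; defined as 0 for single-figure articles.
#'
#' @inheritParams er_hr
#' @return numeric in \[0, 1\].
#' @export
wer_hr <- function(pairs) {
  stopifnot(length(pairs) >= 1)
  mean(vapply(pairs, function(p) {
    n <- length(p$ref)
    if (n == 1) return(0)
    sys_rank <- match(p$ref[1], p$sys)
    (sys_rank - 1) / (n - 1)
  }, 0))
}

# Shared collection summary: pairwise metrics skip <2-figure articles (the
# exclusion count is reported); ER-HR/WER-HR include every article.
.collection_metrics <- function(pairs) {
  ok <- vapply(pairs, function(p) length(p$ref) >= 2, TRUE)
  pw <- pairs[ok]
  mean_or_na <- function(f) if (length(pw)) mean(vapply(pw, function(p) f(p$ref, p$sys), 0)) else NA_real_
  data.frame(mer = mean_or_na(mer),
             mwer = mean_or_na(mwer),
             mwer_rk = mean_or_na(mwer_rk),
             er_hr = er_hr(pairs),
             wer_hr = wer_hr(pairs),
             n_articles = length(pairs),
             n_excluded = sum(!ok))
}

#' Evaluate ranking methods over an article collection
#'
#' Runs each requested method on every article carrying a gold ranking and
#' reports the collection mean of all five metrics per method. Method ids
#' are any of [similarity_methods()], [frequency_methods()], or
#' `"combined"` (using `lambda` and the default member systems). Articles
#' without gold are excluded and logged; articles with fewer than 2 figures
#' are excluded from the pairwise metrics only, and the exclusion count is
#' reported.
#'
#' @param collection list of `fig_article`s.
#' @param methods character vector of method ids.
#' @param idf a `fig_idf`; defaults to [collection_idf()] of the collection.
#' @param lambda,normalization settings for the `"combined"` method.
#' @return data.frame: one row per method with columns `method_id, mer,
#'   mwer, mwer_rk, er_hr, wer_hr, n_articles, n_excluded, config_hash`.
#' @export
evaluate_collection <- function(collection,
                                methods = c(similarity_methods(), frequency_methods()),
                                idf = NULL, lambda = 0.8, normalization = "minmax") {
  stopifnot(length(collection) >= 1, length(methods) >= 1)
  has_gold <- vapply(collection, function(a) !is.null(a$gold), TRUE)
  if (any(!has_gold))
    .warn(sum(!has_gold), " article(s) without gold ranking excluded from evaluation")
  collection <- collection[has_gold]
  if (!length(collection)) stop("evaluate_collection: no article has a gold ranking")
  if (is.null(idf)) idf <- collection_idf(collection)
  hash <- config_hash(list(idf_smoothing = idf$smoothing, stopwords = idf$stopwords,
                           stopword_list = .STOPWORDS_VERSION,
                           lambda = lambda, normalization = normalization))
  rows <- lapply(methods, function(mid) {
    pairs <- lapply(collection, function(a) {
      sys <- if (mid %in% similarity_methods()) {
        rank_from_scores(score_similarity(a, mid, idf), mid)
      } else if (mid %in% frequency_methods()) {
        rank_from_scores(score_frequency(a, mid, idf), mid)
      } else if (identical(mid, "combined")) {
        combine_linear(a, idf, lambda = lambda, normalization = normalization)
      } else {
        stop("evaluate_collection: unknown method id: ", mid)
      }
      list(ref = a$gold, sys = sys$order)
    })
    cbind(data.frame(method_id = mid), .collection_metrics(pairs))
  })
  out <- do.call(rbind, rows)
  out$config_hash <- hash
  out
}

#' Paired two-sided t test between per-article metric values
#'
#' Compares two methods' per-article values (paired by article) with the
#' standard paired t test. With zero variance of the differences the t
#' statistic is undefined: equal means report p = 1, unequal means report
#' the limit p = 0 with a warning.
#'
#' @param a,b numeric vectors of equal length >= 2, paired by article.
#' @return list with `t` and `p`.
#' @export
paired_t_test <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, p = 1))
    .warn("paired_t_test: zero variance with nonzero mean difference; p -> 0")
    return(list(t = sign(mean(d)) * Inf, p = 0))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value)
}
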