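# Rank-error metrics: exact values, oracle equivalence, and the design
# properties (distance weighting, rank-sensitive penalty, top-figure
# identification).

test_that("pairwise metrics reproduce the canonical four-figure examples", {
  ref <- 1:4
  expect_equal(mer(ref, c(2, 1, 3, 4)), 1 / 6, tolerance = 1e-12)
  expect_equal(round(mer(ref, c(2, 1, 3, 4)), 3), 0.167)
  expect_equal(mwer(ref, c(2, 1, 3, 4)), 0.1, tolerance = 1e-12)
  expect_equal(mwer(ref, c(1, 2, 4, 3)), 0.1, tolerance = 1e-12)  # same distance, same MWER
  expect_equal(round(mwer_rk(ref, c(2, 1, 3, 4)), 3), 0.108)
  expect_equal(round(mwer_rk(ref, c(1, 2, 4, 3)), 3), 0.019)
})

test_that("pairwise metrics are 0 on identity and 1 (or 0) on reversal", {
  for (n in 2:6) {
    ref <- seq_len(n)
    expect_equal(mer(ref, ref), 0)
    expect_equal(mwer(ref, ref), 0)
    expect_equal(mwer_rk(ref, ref), 0)
    expect_equal(mer(ref, rev(ref)), 1)
    expect_equal(mwer(ref, rev(ref)), 1)   # sum wrong = sum all
  }
  expect_error(mer(1L, 1L), "fewer than 2")
  expect_error(mer(1:3, c(1, 2, 4)), "permutation")
})

test_that("MER equals the Kendall-tau pair-inversion distance on all permutations", {
  for (n in 2:5) {
    perms <- all_perms(n)
    ref <- seq_len(n)
    for (sys in perms) {
      expect_equal(mer(ref, sys), mer_oracle(ref, sys), tolerance = 1e-12)
    }
    # non-identity references too (relabelled gold orders)
    set.seed(n)
    for (ref2 in list(sample(n), sample(n))) {
      for (sys in perms[seq(1, length(perms), by = max(1, n - 2))]) {
        expect_equal(mer(ref2, sys), mer_oracle(ref2, sys), tolerance = 1e-12)
      }
    }
  }
})

test_that("MWER weights errors by reference distance; bounds hold everywhere", {
  for (sys in all_perms(4)) {
    m <- mer(1:4, sys); w <- mwer(1:4, sys); rk <- mwer_rk(1:4, sys)
    expect_gte(m, 0); expect_lte(m, 1)
    expect_gte(w, 0); expect_lte(w, 1)
    expect_gte(rk, 0)
    # the three agree on the no-error case
    expect_identical(m == 0, w == 0)
    expect_identical(m == 0, rk == 0)
  }
  # a distant wrong pair costs more than an adjacent one
  expect_gt(mwer(1:4, c(4, 2, 3, 1)), mwer(1:4, c(1, 3, 2, 4)))
})

test_that("MWER-RK penalizes errors on important figures more", {
  # the same adjacent transposition, applied higher in the reference order,
  # must cost strictly more (fixed pair distance d = 1)
  n <- 6
  costs <- vapply(seq_len(n - 1), function(m) {
    sys <- seq_len(n)
    sys[c(m, m + 1)] <- sys[c(m + 1, m)]
    mwer_rk(seq_len(n), sys)
  }, 0)
  expect_true(all(diff(costs) < 0))
})

test_that("top-figure metrics score agreement and displacement", {
  agree <- list(ref = c(3, 1, 2), sys = c(3, 2, 1))
  miss_last <- list(ref = c(1, 2, 3, 4), sys = c(2, 3, 4, 1))  # top ranked last
  miss_mid <- list(ref = c(1, 2, 3, 4), sys = c(2, 1, 3, 4))   # top at rank 2
  single <- list(ref = 1, sys = 1)

  expect_equal(er_hr(list(agree, agree)), 0)
  expect_equal(er_hr(list(miss_last, miss_mid)), 1)
  expect_equal(er_hr(list(agree, miss_mid)), 0.5)
  expect_equal(wer_hr(list(agree)), 0)
  expect_equal(wer_hr(list(miss_last)), 1)
  expect_equal(wer_hr(list(miss_mid)), 1 / 3)
  expect_equal(wer_hr(list(single)), 0)       # single-figure convention
  # ER-HR = 0 implies WER-HR = 0 on the same collection
  expect_equal(wer_hr(list(agree, single)), 0)

  # brute force over all 24 orders of 4: WER-HR is (sys rank of top - 1)/3
  # and increases monotonically with that rank
  for (sys in all_perms(4)) {
    expect_equal(wer_hr(list(list(ref = 1:4, sys = sys))),
                 (match(1, sys) - 1) / 3)
  }
})

test_that("collection evaluation averages per-article metrics per method", {
  # two articles with hand-known outcomes under a perfect and a reversed system
  a1 <- list(ref = 1:3, sys = 1:3)
  a2 <- list(ref = 1:3, sys = c(2, 1, 3))
  expected_mer <- mean(c(0, mer(1:3, c(2, 1, 3))))

  # via the full pipeline: build articles whose similarity ranking is forced
  idf <- uniform_idf()
  mk <- function(legends, gold) fig_article(
    title = "tt", abstract = "aa bb cc",
    sections = list(list(heading = "Results", paragraphs = "body only")),
    figures = lapply(seq_along(legends),
                     function(i) list(label = i, legend = legends[i])),
    gold = gold)
  # legend overlap with abstract decreasing in document order -> order 1,2,3
  art1 <- mk(c("aa bb cc", "aa bb", "aa"), gold = 1:3)       # perfect
  art2 <- mk(c("aa bb", "aa bb cc", "aa"), gold = 1:3)       # swaps 1 and 2
  rep <- evaluate_collection(list(art1, art2), "figlegend-abstract", idf)
  expect_equal(rep$mer, expected_mer, tolerance = 1e-12)
  expect_equal(rep$er_hr, 0.5)
  expect_identical(rep$n_articles, 2L)
  expect_identical(rep$n_excluded, 0L)
  expect_true(nzchar(rep$config_hash))

  # all methods on one perfectly-ranked article give an all-zero row
  rep2 <- evaluate_collection(list(art1), c("figlegend-abstract", "figtext-abstract"), idf)
  expect_equal(rep2$mer, c(0, 0))
  expect_equal(rep2$wer_hr, c(0, 0))

  expect_error(evaluate_collection(list(), "figlegend-abstract"), "length")
})

test_that("single-figure articles are excluded from pairwise means but not ER-HR", {
  idf <- uniform_idf()
  one_fig <- fig_article(title = "tt", abstract = "aa",
                         sections = list(list(heading = "Results", paragraphs = "x")),
                         figures = list(list(label = 1, legend = "aa")), gold = 1)
  two_fig <- fig_article(title = "tt", abstract = "aa bb",
                         sections = list(list(heading = "Results", paragraphs = "x")),
                         figures = list(list(label = 1, legend = "aa bb"),
                                        list(label = 2, legend = "zz")), gold = c(1, 2))
  rep <- evaluate_collection(list(one_fig, two_fig), "figlegend-abstract", idf)
  expect_identical(rep$n_excluded, 1L)
  expect_identical(rep$n_articles, 2L)
  expect_equal(rep$mer, 0)      # mean over the one eligible article
  expect_equal(rep$er_hr, 0)    # single-figure article always agrees
})

test_that("paired t test matches the direct formula and handles degeneracy", {
  expect_identical(paired_t_test(c(1, 2, 3), c(1, 2, 3)), list(t = 0, p = 1))
  # constant nonzero difference: zero variance, p reported as the limit 0
  res <- paired_t_test(c(2, 3, 4), c(1, 2, 3))
  expect_equal(res$p, 0)
  # fixture vectors against the direct formula t = mean(d)/(sd(d)/sqrt(n))
  set.seed(1)
  a <- rnorm(12); b <- rnorm(12)
  d <- a - b
  t_direct <- mean(d) / (sd(d) / sqrt(length(d)))
  p_direct <- 2 * stats::pt(-abs(t_direct), df = length(d) - 1)
  res2 <- paired_t_test(a, b)
  expect_equal(res2$t, t_direct, tolerance = 1e-12)
  expect_equal(res2$p, p_direct, tolerance = 1e-12)
})
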