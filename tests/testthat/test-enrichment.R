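# exhaustive hypergeometric pmf by direct binomial-coefficient enumeration:
# the independent oracle for the tail probabilities
enum_tails <- function(k, n, K, N) {
  xs <- max(0, n + K - N):min(n, K)
  pmf <- choose(K, xs) * choose(N - K, n - xs) / choose(N, n)
  list(p_enrich = sum(pmf[xs >= k]), p_deplete = sum(pmf[xs <= k]))
}

test_that("tail probabilities match exhaustive enumeration for N <= 30", {
  for (N in c(5L, 12L, 20L, 30L)) {
    for (K in 0:N) {
      for (n in 0:N) {
        for (k in unique(c(max(0, n + K - N), min(n, K),
                           round(n * K / N)))) {
          got <- hypergeom_test(k, n, K, N)
          want <- enum_tails(k, n, K, N)
          expect_equal(got$p_enrich, want$p_enrich, tolerance = 1e-12)
          expect_equal(got$p_deplete, want$p_deplete, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("worked small-case tails and conventions are exact", {
  got <- hypergeom_test(4, 6, 5, 20)
  expect_equal(got$p_enrich, (choose(5, 4) * choose(15, 2) +
                                choose(5, 5) * choose(15, 1)) / choose(20, 6))
  expect_equal(got$p_enrich, 0.01393, tolerance = 1e-3)
  # query == background: k = K always, two-sided p = 1
  expect_equal(hypergeom_test(5, 20, 5, 20)$p_two_sided, 1)
  expect_error(hypergeom_test(6, 6, 5, 20), "k <= ")
})

test_that("both tails include k: p_enrich + p_deplete = 1 + P(X = k)", {
  set.seed(61)
  for (i in 1:200) {
    N <- sample(10:60, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    ks <- max(0, n + K - N):min(n, K)
    k <- if (length(ks) == 1L) ks else sample(ks, 1)
    got <- hypergeom_test(k, n, K, N)
    expect_equal(got$p_enrich + got$p_deplete,
                 1 + stats::dhyper(k, K, N - K, n), tolerance = 1e-12)
    expect_gt(got$p_two_sided, 0); expect_lte(got$p_two_sided, 1)
  }
})

test_that("enrichment p-values are super-uniform under the null", {
  set.seed(62)
  N <- 200L; K <- 40L; n <- 25L
  background <- paste0("g", 1:N)
  term <- background[1:K]
  p <- replicate(2000, {
    q <- sample(background, n)
    hypergeom_test(length(intersect(q, term)), n, K, N)$p_enrich
  })
  expect_lte(mean(p <= 0.05), 0.06)
})

test_that("enrich ranks a planted term first and applies BH correctly", {
  set.seed(63)
  background <- paste0("g", 1:300)
  query <- sample(background, 20)
  first <- 0L
  for (rep in 1:200) {
    cfg <- synth_config(seed = 7000L + rep)
    terms <- gen_annotations(cfg, background, planted_query = query,
                             planted_fraction = 0.8)
    res <- enrich(query, terms, background)
    if (res$term_id[1] == "TERM001") first <- first + 1L
  }
  expect_gte(first / 200, 0.95)
  # BH is monotone in p and bounded by 1
  res <- enrich(query, gen_annotations(synth_config(1L), background),
                background)
  ord <- order(res$p_two_sided)
  expect_true(all(diff(res$p_adjust[ord]) >= -1e-12))
  expect_true(all(res$p_adjust <= 1))
  # disjoint small term activates the depletion side with k = 0
  res0 <- enrich(background[1:50],
                 list(list(term_id = "D", term_name = "d",
                           genes = background[251:300])),
                 background)
  expect_equal(res0$k, 0L)
  expect_lt(res0$p_deplete, 1)
  # a term equal to the query is the most significant
  res1 <- enrich(query, list(list(term_id = "EQ", term_name = "eq",
                                  genes = query),
                             list(term_id = "R", term_name = "r",
                                  genes = background[1:30])),
                 background)
  expect_equal(res1$term_id[1], "EQ")
  expect_error(enrich(c(query, "NOT_THERE"),
                      list(list(term_id = "X", term_name = "x",
                                genes = query)), background),
               "outside background")
})

test_that("GMT files round-trip", {
  terms <- list(list(term_id = "T1", term_name = "one", genes = c("a", "b")),
                list(term_id = "T2", term_name = "two", genes = c("c")))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(terms, path)
  expect_equal(read_gmt(path), terms)
})
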