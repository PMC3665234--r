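test_that("ATC validation and level prefixes follow the 7-character format", {
  expect_true(is_valid_atc("N02BA01"))
  expect_false(is_valid_atc("N02BA1"))
  expect_false(is_valid_atc("n02ba01"))
  expect_equal(atc_prefixes("A01AA01"), c("A", "A01", "A01A", "A01AA",
                                          "A01AA01"))
  expect_equal(longest_matched_prefix("A01AA01", "A01AB02"), "A01A")
  expect_equal(longest_matched_prefix("A01AA01", "A01AA01"), "A01AA01")
  expect_equal(longest_matched_prefix("A01AA01", "B01AA03"), "")
  expect_error(atc_prefixes("XYZ"), "invalid ATC")
})

test_that("code similarity matches the hand-computed worked example", {
  codes <- c(rep("A01AA01", 4), rep("A01AB02", 2), rep("B01AA03", 2))
  model <- atc_frequency_model(codes)
  # 2 ln(6/8) / (ln(4/8) + ln(2/8))
  expect_equal(code_similarity("A01AA01", "A01AB02", model),
               2 * log(6 / 8) / (log(4 / 8) + log(2 / 8)))
  expect_equal(code_similarity("A01AA01", "A01AB02", model), 0.2767,
               tolerance = 1e-4)
  expect_equal(code_similarity("A01AA01", "A01AA01", model), 1)
  expect_equal(code_similarity("A01AA01", "B01AA03", model), 0)
  expect_error(code_similarity("A01AA01", "C01AA01", model),
               "not observed")
})

test_that("code similarity is symmetric, bounded and monotone in prefix depth", {
  set.seed(41)
  cfg <- synth_config(seed = 41L, n_drugs = 80L)
  gl <- gen_library(cfg)
  model <- atc_frequency_model(gl$library)
  codes <- unique(unlist(gl$library$drugs$atc_codes))
  for (i in 1:200) {
    ab <- sample(codes, 2, replace = TRUE)
    s <- code_similarity(ab[1], ab[2], model)
    expect_equal(s, code_similarity(ab[2], ab[1], model))
    expect_gte(s, 0); expect_lte(s, 1)
    if (ab[1] == ab[2]) expect_equal(s, 1)
  }
})

test_that("Jaccard TST follows the printed set-overlap formula", {
  expect_equal(tst_jaccard(c("A01AA01", "B01AA03"),
                           c("B01AA03", "N02BA01")), 1 / 3)
  expect_equal(tst_jaccard(c("A01AA01"), c("A01AA01")), 1)
  expect_equal(tst_jaccard(c("A01AA01"), c("B01AA03")), 0)
  expect_error(tst_jaccard(character(0), "A01AA01"), "empty")
})

test_that("max-similarity TST reduces to code similarity and is bounded", {
  codes <- c(rep("A01AA01", 4), rep("A01AB02", 2), rep("B01AA03", 2))
  model <- atc_frequency_model(codes)
  expect_equal(tst_max_similarity("A01AA01", "A01AB02", model),
               code_similarity("A01AA01", "A01AB02", model))
  # a shared identical code dominates
  expect_equal(tst_max_similarity(c("A01AA01", "B01AA03"),
                                  c("B01AA03", "A01AB02"), model), 1)
  expect_equal(tst_max_similarity("A01AA01", "B01AA03", model), 0)
})

test_that("all-pairs TST matrix equals a naive double loop", {
  set.seed(42)
  cfg <- synth_config(seed = 42L, n_drugs = 150L, n_targets = 60L)
  gl <- gen_library(cfg)
  model <- atc_frequency_model(gl$library)
  profiles <- target_atc_profiles(gl$library)
  profiles <- profiles[seq_len(min(50, length(profiles)))]
  for (method in c("jaccard", "max_similarity")) {
    M <- tst_matrix(profiles, method = method, model = model)
    expect_true(isSymmetric(M))
    expect_true(all(M >= 0 & M <= 1))
    naive <- matrix(NA_real_, length(profiles), length(profiles))
    for (i in seq_along(profiles)) {
      for (j in seq_along(profiles)) {
        naive[i, j] <- if (method == "jaccard") {
          tst_jaccard(profiles[[i]], profiles[[j]])
        } else if (i == j) 1 else {
          tst_max_similarity(profiles[[i]], profiles[[j]], model)
        }
      }
    }
    expect_equal(unname(M), naive)
  }
})

test_that("targets group by shared prefix at the requested level", {
  profiles <- list(T1 = c("N02BA01"), T2 = c("N02BE01"),
                   T3 = c("A01AA01"), T4 = c("N02BA01", "A01AA01"))
  g2 <- group_targets(profiles, level = 2)
  expect_setequal(g2$N02, c("T1", "T2", "T4"))
  expect_setequal(g2$A01, c("T3", "T4"))
  expect_equal(attr(g2, "overlapping"), "T4")
  expect_equal(length(group_targets(list(), level = 1)), 0L)
  # three disjoint level-1 subtrees give exactly three groups
  p3 <- list(a = "A01AA01", b = "B01AA01", c = "C01AA01")
  expect_equal(length(group_targets(p3, level = 1)), 3L)
})

test_that("ATC model serialization round-trips", {
  codes <- c(rep("A01AA01", 4), rep("A01AB02", 2), rep("B01AA03", 2))
  model <- atc_frequency_model(codes)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_atc_model(model, path)
  back <- read_atc_model(path)
  expect_equal(back$counts, model$counts)
  expect_equal(back$p, model$p)
  expect_equal(back$total, model$total)
})
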