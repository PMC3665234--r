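test_that("generation is a pure function of (config, seed)", {
  cfg <- synth_config(seed = 71L, n_drugs = 60L, n_bits = 256L)
  a <- gen_library(cfg); b <- gen_library(cfg)
  expect_identical(a$library$fp, b$library$fp)
  expect_identical(a$library$drugs, b$library$drugs)
  expect_identical(a$truth, b$truth)
  qa <- gen_queries(cfg, a$library, a$truth)
  qb <- gen_queries(cfg, b$library, b$truth)
  expect_identical(qa, qb)
  cons <- yzp_constituents()
  parents <- cons[cons$kind == "prototype", c("id", "formula")][1:4, ]
  expect_identical(gen_features(parents, default_rules(), cfg),
                   gen_features(parents, default_rules(), cfg))
  pairs <- data.frame(compound = "c1", gene = paste0("T", 1:20))
  expect_identical(gen_docking(pairs, cfg), gen_docking(pairs, cfg))
  expect_error(synth_config(), "seed")
})

test_that("library matches the configured shape and schema", {
  cfg <- synth_config(seed = 72L, n_drugs = 1447L, n_bits = 128L,
                      n_queries = 0L)
  gl <- gen_library(cfg)
  expect_equal(nrow(gl$library$drugs), 1447L)
  expect_equal(dim(gl$library$fp), c(1447L, 128L))
  expect_true(all(is_valid_atc(unlist(gl$library$drugs$atc_codes))))
  # generated artifacts pass through the same reader as real inputs
  path <- withr::local_tempfile(fileext = ".tsv")
  write_drug_library(gl$library, path)
  back <- read_drug_library(path, 128L)
  expect_identical(unname(back$fp), unname(gl$library$fp))
  expect_identical(back$drugs$targets, gl$library$drugs$targets)
})

test_that("random fingerprints almost never screen as high-similarity hits", {
  cfg <- synth_config(seed = 73L, n_drugs = 200L, n_queries = 0L)
  gl <- gen_library(cfg)
  set.seed(74)
  Q <- matrix(rand_bits(5 * cfg$n_bits, cfg$fp_density), 5, cfg$n_bits)
  rownames(Q) <- paste0("q", 1:5)
  hits <- screen(list(info = NULL, fp = Q), gl$library, threshold = 0.85)
  expect_lt(nrow(hits) / (5 * 200), 0.01)
})

test_that("planted neighbors sit in the expected similarity band", {
  sims <- numeric(0)
  for (s in 1:100) {
    cfg <- synth_config(seed = 8000L + s, n_drugs = 30L, n_queries = 1L)
    gl <- gen_library(cfg)
    qs <- gen_queries(cfg, gl$library, gl$truth)
    for (d in gl$truth$planted$Q01) {
      sims <- c(sims, tanimoto(fingerprint(qs$fp["Q01", ]),
                               fingerprint(gl$library$fp[d, ])))
    }
  }
  expect_gt(mean(sims), 0.5)
  expect_lt(mean(sims), 0.85)
  # zero flip rate: queries coincide with their archetype neighbors
  cfg0 <- synth_config(seed = 75L, n_drugs = 30L, n_queries = 1L,
                       flip_rate = 0)
  gl0 <- gen_library(cfg0)
  qs0 <- gen_queries(cfg0, gl0$library, gl0$truth)
  d0 <- gl0$truth$planted$Q01[1]
  expect_equal(tanimoto(fingerprint(qs0$fp["Q01", ]),
                        fingerprint(gl0$library$fp[d0, ])), 1)
})

test_that("a 21-compound query schema mirrors the prescription layout", {
  cfg <- synth_config(seed = 76L, n_drugs = 150L, n_bits = 256L,
                      n_queries = 21L, n_neighbors = 3L)
  gl <- gen_library(cfg)
  qs <- gen_queries(cfg, gl$library, gl$truth)
  expect_equal(nrow(qs$info), 21L)
  expect_equal(nrow(qs$fp), 21L)
  expect_true(all(nzchar(qs$info$planted_drugs)))
})

test_that("docking mixture separates binders at the -5 threshold", {
  sens <- spec <- numeric(0)
  pairs <- expand.grid(compound = paste0("c", 1:5),
                       gene = paste0("T", 1:20),
                       stringsAsFactors = FALSE)
  for (s in 1:200) {
    cfg <- synth_config(seed = 9000L + s)
    dock <- gen_docking(pairs, cfg)
    kept <- filter_docking(dock, -5.0)
    called <- rownames(dock) %in% rownames(kept)
    sens <- c(sens, mean(called[dock$is_binder]))
    spec <- c(spec, mean(!called[!dock$is_binder]))
  }
  expect_gte(mean(sens, na.rm = TRUE), 0.9)
  expect_gte(mean(spec, na.rm = TRUE), 0.9)
  expect_equal(nrow(gen_docking(pairs[0, ], synth_config(1L))), 0L)
})

test_that("generated features carry ppm-scale noise around theory", {
  cons <- yzp_constituents()
  parents <- cons[cons$kind == "prototype", c("id", "formula")][1:4, ]
  cfg <- synth_config(seed = 77L, mz_noise_ppm = 3)
  feats <- gen_features(parents, default_rules(), cfg)
  ppm <- ppm_error(feats$mz, feats$theoretical_mh)
  expect_true(all(abs(ppm) < 20))
  expect_gt(stats::sd(ppm), 0)
})
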