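#' Configuration for the synthetic-data generator
#'
#' The generator emulates every input the pipeline consumes — an ATC- and
#' target-annotated drug library with planted structural neighbors of the
#' query compounds, noisy metabolite m/z observations, bimodal docking
#' scores, and annotation term sets — with ground truth retained for
#' recovery benchmarking.
#'
#' Defaults mirror the study conditions where stated (200-drug recovery
#' libraries with 5 planted neighbors per query at 5\% bit-flip noise;
#' 3 ppm mass noise against a 10 ppm matching window; binder/non-binder
#' docking score modes at -6.0 and -3.5) and conventional values
#' elsewhere; see the methods vignette.
#'
#' @param seed Integer seed; mandatory — every generator output is a pure
#'   function of (config, seed).
#' @param n_drugs Library size.
#' @param n_bits Fingerprint length.
#' @param fp_density Probability a background fingerprint bit is set.
#' @param n_targets Size of the target gene universe.
#' @param targets_per_drug Integer range (min, max) of targets per drug.
#' @param atc_branching Children per ATC level (5 levels).
#' @param zipf_s Zipf exponent for branch weights; > 0 keeps prefix
#'   frequencies non-degenerate so the information-content model has
#'   contrast.
#' @param n_queries Number of query compounds.
#' @param n_neighbors Planted structural neighbors per query.
#' @param flip_rate Per-bit flip probability used to derive each planted
#'   neighbor from its query archetype (in [0, 0.5)).
#' @param query_flip_rate Extra per-bit noise on the emitted query
#'   fingerprint relative to its archetype (default 0).
#' @param targets_per_neighbor Targets drawn per planted neighbor from
#'   its query's target pool.
#' @param pool_size Target-pool size per query.
#' @param mz_noise_ppm Gaussian m/z noise (ppm) for observed features.
#' @param binder_mean,binder_sd Docking score mode for true binders.
#' @param nonbinder_mean,nonbinder_sd Docking score mode for non-binders.
#' @param binder_fraction Probability a pair is a true binder.
#' @param n_terms Annotation terms generated.
#' @param term_size Integer range (min, max) of genes per term.
#' @return A validated \code{synth_config}.
#' @export
synth_config <- function(seed,
                         n_drugs = 200L,
                         n_bits = 2048L,
                         fp_density = 0.1,
                         n_targets = 100L,
                         targets_per_drug = c(1L, 4L),
                         atc_branching = c(5L, 4L, 3L, 3L, 4L),
                         zipf_s = 1,
                         n_queries = 3L,
                         n_neighbors = 5L,
                         flip_rate = 0.05,
                         query_flip_rate = 0,
                         targets_per_neighbor = 3L,
                         pool_size = 8L,
                         mz_noise_ppm = 3,
                         binder_mean = -6.0, binder_sd = 0.5,
                         nonbinder_mean = -3.5, nonbinder_sd = 0.8,
                         binder_fraction = 0.3,
                         n_terms = 50L,
                         term_size = c(5L, 30L)) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    stop("synth_config requires an explicit seed", call. = FALSE)
  }
  cfg <- list(seed = as.integer(seed), n_drugs = as.integer(n_drugs),
              n_bits = as.integer(n_bits), fp_density = fp_density,
              n_targets = as.integer(n_targets),
              targets_per_drug = as.integer(targets_per_drug),
              atc_branching = as.integer(atc_branching), zipf_s = zipf_s,
              n_queries = as.integer(n_queries),
              n_neighbors = as.integer(n_neighbors),
              flip_rate = flip_rate, query_flip_rate = query_flip_rate,
              targets_per_neighbor = as.integer(targets_per_neighbor),
              pool_size = as.integer(pool_size),
              mz_noise_ppm = mz_noise_ppm,
              binder_mean = binder_mean, binder_sd = binder_sd,
              nonbinder_mean = nonbinder_mean, nonbinder_sd = nonbinder_sd,
              binder_fraction = binder_fraction,
              n_terms = as.integer(n_terms),
              term_size = as.integer(term_size))
  stopifnot(cfg$n_drugs > 0, cfg$n_bits > 0, cfg$n_targets > 0,
            cfg$fp_density > 0, cfg$fp_density < 1,
            cfg$flip_rate >= 0, cfg$flip_rate < 0.5,
            cfg$query_flip_rate >= 0, cfg$query_flip_rate < 0.5,
            length(cfg$atc_branching) == 5L, all(cfg$atc_branching >= 1L),
            cfg$binder_fraction >= 0, cfg$binder_fraction <= 1,
            cfg$n_queries >= 0, cfg$n_neighbors >= 0)
  structure(cfg, class = "synth_config")
}

.zipf_weights <- function(n, s) {
  w <- 1 / seq_len(n)^s
  w / sum(w)
}

.gen_atc_code <- function(branching, s) {
  pick <- function(n) sample.int(n, 1L, prob = .zipf_weights(n, s))
  paste0(LETTERS[pick(branching[1])],
         sprintf("%02d", pick(branching[2])),
         LETTERS[pick(branching[3])],
         LETTERS[pick(branching[4])],
         sprintf("%02d", pick(branching[5])))
}

.flip_bits <- function(bits, rate) {
  if (rate <= 0) return(bits)
  flip <- stats::runif(length(bits)) < rate
  as.integer(xor(bits == 1L, flip))
}

#' Generate a synthetic drug library with planted query neighborhoods
#'
#' Background drugs get independent Bernoulli fingerprints; for each
#' future query, a hidden archetype fingerprint is drawn and
#' \code{n_neighbors} library drugs are planted as per-bit flips of it at
#' \code{flip_rate}. ATC codes are sampled root-to-leaf down a synthetic
#' 5-level tree with Zipf-weighted branches; planted neighbors share a
#' per-query target pool so the query's true target set is recoverable.
#'
#' @param cfg A \code{synth_config}.
#' @return list(library = \code{drug_library}, truth = list with
#'   \code{archetypes} (bit matrix), \code{planted} (per query: drug ids),
#'   \code{true_targets} (per query: union of planted drugs' targets),
#'   \code{drug_role} (named: "background" or the query id)).
#' @export
gen_library <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n_planted <- cfg$n_queries * cfg$n_neighbors
  if (n_planted > cfg$n_drugs) {
    stop("more planted neighbors than drugs in the library", call. = FALSE)
  }
  ids <- sprintf("D%04d", seq_len(cfg$n_drugs))
  universe <- sprintf("T%03d", seq_len(cfg$n_targets))
  fp <- matrix(0L, cfg$n_drugs, cfg$n_bits)
  targets <- vector("list", cfg$n_drugs)
  role <- rep("background", cfg$n_drugs)

  slots <- if (n_planted > 0) sample.int(cfg$n_drugs, n_planted) else integer(0)
  archetypes <- matrix(0L, cfg$n_queries, cfg$n_bits)
  planted <- vector("list", cfg$n_queries)
  pools <- vector("list", cfg$n_queries)
  qids <- if (cfg$n_queries > 0) sprintf("Q%02d", seq_len(cfg$n_queries))
          else character(0)
  k <- 0L
  for (q in seq_len(cfg$n_queries)) {
    archetypes[q, ] <- as.integer(stats::runif(cfg$n_bits) < cfg$fp_density)
    pools[[q]] <- sample(universe, cfg$pool_size)
    idx <- slots[(k + 1L):(k + cfg$n_neighbors)]
    k <- k + cfg$n_neighbors
    for (i in idx) {
      fp[i, ] <- .flip_bits(archetypes[q, ], cfg$flip_rate)
      targets[[i]] <- sort(sample(pools[[q]],
                                  min(cfg$targets_per_neighbor,
                                      cfg$pool_size)))
      role[i] <- qids[q]
    }
    planted[[q]] <- ids[sort(idx)]
  }
  bg <- which(role == "background")
  for (i in bg) {
    fp[i, ] <- as.integer(stats::runif(cfg$n_bits) < cfg$fp_density)
    nt <- sample(seq(cfg$targets_per_drug[1], cfg$targets_per_drug[2]), 1L)
    targets[[i]] <- sort(sample(universe, nt))
  }
  atc <- lapply(seq_len(cfg$n_drugs), function(i) {
    n_codes <- 1L + stats::rpois(1L, 0.5)
    unique(replicate(n_codes, .gen_atc_code(cfg$atc_branching, cfg$zipf_s)))
  })
  drugs <- data.frame(drug_id = ids, name = paste0("drug_", ids),
                      stringsAsFactors = FALSE)
  drugs$atc_codes <- atc
  drugs$targets <- targets
  rownames(fp) <- ids
  if (cfg$n_queries > 0) {
    names(planted) <- qids
    rownames(archetypes) <- qids
  }
  true_targets <- lapply(planted, function(p) {
    sort(unique(unlist(targets[match(p, ids)])))
  })
  list(library = drug_library(drugs, fp),
       truth = list(archetypes = archetypes, planted = planted,
                    true_targets = true_targets,
                    drug_role = stats::setNames(role, ids)))
}

#' Generate query compounds from planted archetypes
#'
#' Each query fingerprint is its hidden archetype, optionally perturbed
#' by \code{query_flip_rate}; the attached truth records the planted
#' neighbor drugs and their pooled targets (the recoverable ground
#' truth).
#'
#' @param cfg The \code{synth_config} used for \code{\link{gen_library}}.
#' @param library The generated \code{drug_library} (unused beyond
#'   dimension checks; present so callers keep the triple together).
#' @param truth The truth object from \code{\link{gen_library}}.
#' @return A compound set: list(info = data.frame(id, planted_drugs,
#'   true_targets), fp = bit matrix), class \code{compound_set}.
#' @export
gen_queries <- function(cfg, library, truth) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 1L)
  qids <- rownames(truth$archetypes)
  fp <- truth$archetypes
  if (cfg$query_flip_rate > 0) {
    for (i in seq_len(nrow(fp))) {
      fp[i, ] <- .flip_bits(fp[i, ], cfg$query_flip_rate)
    }
  }
  info <- data.frame(
    id = qids,
    planted_drugs = vapply(truth$planted, paste, character(1),
                           collapse = ";"),
    true_targets = vapply(truth$true_targets, paste, character(1),
                          collapse = ";"),
    stringsAsFactors = FALSE)
  structure(list(info = info, fp = fp), class = "compound_set")
}

#' Generate noisy observed metabolite features
#'
#' For every feasible (parent, rule) candidate, emits an observed feature
#' whose m/z is the theoretical protonated mass perturbed by Gaussian
#' ppm-scale noise, with the true formula and provenance attached.
#'
#' @param parents data.frame with columns id, formula.
#' @param rules Rule catalogue (default \code{\link{default_rules}}).
#' @param cfg A \code{synth_config} (uses seed and mz_noise_ppm).
#' @return data.frame: id, rt_min, mz, formula, parent (truth), rule
#'   (truth), theoretical_mh (truth).
#' @export
gen_features <- function(parents, rules = default_rules(), cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 2L)
  cand <- enumerate_candidates(parents, rules)
  if (nrow(cand) == 0L) {
    return(data.frame(id = character(), rt_min = numeric(), mz = numeric(),
                      formula = character(), parent = character(),
                      rule = character(), theoretical_mh = numeric(),
                      stringsAsFactors = FALSE))
  }
  eps <- stats::rnorm(nrow(cand), 0, cfg$mz_noise_ppm * 1e-6)
  data.frame(id = sprintf("M%d", seq_len(nrow(cand))),
             rt_min = round(stats::runif(nrow(cand), 1, 30), 3),
             mz = cand$theoretical_mh * (1 + eps),
             formula = cand$formula,
             parent = cand$parent_id,
             rule = cand$rule,
             theoretical_mh = cand$theoretical_mh,
             stringsAsFactors = FALSE)
}

#' Generate a docking-score table with a binder/non-binder mixture
#'
#' Each (compound, gene) pair is a true binder with probability
#' \code{binder_fraction}; binders draw scores from the binder mode,
#' non-binders from the weaker mode. The truth label is attached.
#'
#' @param pairs data.frame with columns compound, gene.
#' @param cfg A \code{synth_config}.
#' @return data.frame: gene, pdb, protein_name, compound, score,
#'   is_binder (truth).
#' @export
gen_docking <- function(pairs, cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 3L)
  n <- nrow(pairs)
  if (n == 0L) {
    return(data.frame(gene = character(), pdb = character(),
                      protein_name = character(), compound = character(),
                      score = numeric(), is_binder = logical(),
                      stringsAsFactors = FALSE))
  }
  is_binder <- stats::runif(n) < cfg$binder_fraction
  score <- ifelse(is_binder,
                  stats::rnorm(n, cfg$binder_mean, cfg$binder_sd),
                  stats::rnorm(n, cfg$nonbinder_mean, cfg$nonbinder_sd))
  pdb <- vapply(seq_len(n), function(i) {
    paste0(sample(c(0:9), 1), paste(sample(LETTERS, 3, replace = TRUE),
                                    collapse = ""))
  }, character(1))
  data.frame(gene = pairs$gene, pdb = pdb,
             protein_name = paste0("protein_", pairs$gene),
             compound = pairs$compound,
             score = score, is_binder = is_binder,
             stringsAsFactors = FALSE)
}

#' Generate annotation term sets, optionally with a planted signal term
#'
#' Random terms over the background gene universe; when
#' \code{planted_query} is given, the first term is built to contain
#' \code{planted_fraction} of the query (plus random fillers), so rank
#' recovery can be benchmarked.
#'
#' @param cfg A \code{synth_config}.
#' @param background Character vector: gene universe.
#' @param planted_query Optional query gene set to plant.
#' @param planted_fraction Fraction of the query placed in the planted
#'   term (default 0.8).
#' @return List of annotation sets (term_id, term_name, genes).
#' @export
gen_annotations <- function(cfg, background, planted_query = NULL,
                            planted_fraction = 0.8) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 4L)
  terms <- vector("list", cfg$n_terms)
  for (i in seq_len(cfg$n_terms)) {
    sz <- sample(seq(cfg$term_size[1], cfg$term_size[2]), 1L)
    terms[[i]] <- list(term_id = sprintf("TERM%03d", i),
                       term_name = sprintf("synthetic term %d", i),
                       genes = sort(sample(background,
                                           min(sz, length(background)))))
  }
  if (!is.null(planted_query) && length(planted_query) > 0) {
    core <- sample(planted_query,
                   max(1L, round(planted_fraction * length(planted_query))))
    filler <- sample(setdiff(background, core),
                     max(0L, cfg$term_size[1]))
    terms[[1]]$genes <- sort(unique(c(core, filler)))
    terms[[1]]$term_name <- "planted signal term"
  }
  terms
}

#' Write a complete synthetic input directory
#'
#' Emits, in the exact formats the pipeline readers consume: the drug
#' library TSV, query fingerprints TSV, observed features TSV, a docking
#' table TSV over the planted queries' targets, an annotation GMT, and a
#' truth JSON.
#'
#' @param cfg A \code{synth_config}.
#' @param dir Output directory (created if needed).
#' @param parents Optional parent compound table for feature generation;
#'   defaults to the packaged prototype constituents.
#' @return Invisibly, the named list of written paths.
#' @export
write_synthetic_inputs <- function(cfg, dir, parents = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gl <- gen_library(cfg)
  qs <- gen_queries(cfg, gl$library, gl$truth)
  if (is.null(parents)) {
    cons <- yzp_constituents()
    parents <- cons[cons$kind == "prototype", c("id", "formula")]
  }
  feats <- gen_features(parents, default_rules(), cfg)
  qt <- unique(unlist(gl$truth$true_targets))
  pairs <- if (length(qt)) {
    expand.grid(compound = qs$info$id, gene = qt[seq_len(min(6, length(qt)))],
                stringsAsFactors = FALSE)
  } else {
    data.frame(compound = character(), gene = character())
  }
  dock <- gen_docking(pairs, cfg)
  bg <- sort(unique(unlist(gl$library$drugs$targets)))
  terms <- gen_annotations(cfg, bg, planted_query = qt)
  paths <- list(
    library = file.path(dir, "library.tsv"),
    queries = file.path(dir, "queries.tsv"),
    features = file.path(dir, "features.tsv"),
    docking = file.path(dir, "docking.tsv"),
    annotations = file.path(dir, "annotations.gmt"),
    truth = file.path(dir, "truth.json"))
  write_drug_library(gl$library, paths$library)
  qtab <- qs$info
  qtab$fingerprint <- apply(qs$fp, 1, fp_to_hex)
  utils::write.table(qtab, paths$queries, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(feats, paths$features, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dock, paths$docking, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_gmt(terms, paths$annotations)
  jsonlite::write_json(
    list(planted = gl$truth$planted, true_targets = gl$truth$true_targets),
    paths$truth, auto_unbox = FALSE)
  invisible(paths)
}
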