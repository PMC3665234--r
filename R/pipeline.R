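#' Read a query-compound fingerprint table
#'
#' TSV with columns \code{id} and \code{fingerprint} (hex), as written by
#' \code{\link{write_synthetic_inputs}}.
#'
#' @param path TSV file.
#' @param n_bits Fingerprint length for hex decoding.
#' @return A \code{compound_set}.
#' @export
read_compound_set <- function(path, n_bits) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  stopifnot(all(c("id", "fingerprint") %in% names(d)))
  nb <- as.integer(n_bits)
  fp <- t(vapply(d$fingerprint, function(h) hex_to_fp(h, nb)$bits,
                 integer(nb)))
  rownames(fp) <- d$id
  structure(list(info = d[, setdiff(names(d), "fingerprint"), drop = FALSE],
                 fp = fp), class = "compound_set")
}

#' Assemble and validate a pipeline run configuration
#'
#' Checks that every referenced input exists and every threshold is in
#' its documented range before any stage runs.
#'
#' @param library Path to the drug-library TSV.
#' @param queries Path to the query fingerprint TSV.
#' @param out_dir Output directory for all artifacts.
#' @param constituents Path to a constituent table (default: the packaged
#'   prescription fixture).
#' @param features Optional path to an observed-feature TSV.
#' @param docking Optional path to a docking-score TSV.
#' @param annotations Optional path to a GMT file.
#' @param truth Optional path to a truth JSON (from the synthetic
#'   generator); enables recovered-target precision/recall in the report.
#' @param threshold Screening Tanimoto threshold.
#' @param top_k Optional per-compound rank cutoff.
#' @param tol_ppm Feature-matching tolerance in ppm.
#' @param docking_threshold Docking score cutoff.
#' @param tst_mode \code{"jaccard"} or \code{"max_similarity"}.
#' @param cluster_cut Compound clustering cut (Tanimoto distance).
#' @param atc_level ATC level for target grouping.
#' @param correction Multiple-testing correction for enrichment.
#' @param n_bits Fingerprint length of the library/queries.
#' @param seed Seed recorded in the report (stages are deterministic).
#' @return A validated \code{run_config}.
#' @export
run_config <- function(library, queries, out_dir,
                       constituents = NULL,
                       features = NULL, docking = NULL,
                       annotations = NULL, truth = NULL,
                       threshold = 0.85, top_k = NULL, tol_ppm = 10,
                       docking_threshold = -5.0,
                       tst_mode = c("jaccard", "max_similarity"),
                       cluster_cut = 0.4, atc_level = 2L,
                       correction = c("BH", "none"),
                       n_bits = 2048L, seed = 1L) {
  tst_mode <- match.arg(tst_mode)
  correction <- match.arg(correction)
  if (is.null(constituents)) {
    constituents <- .extdata("yzp_constituents.tsv")
  }
  paths <- list(library = library, queries = queries,
                constituents = constituents, features = features,
                docking = docking, annotations = annotations,
                truth = truth)
  for (nm in names(paths)) {
    p <- paths[[nm]]
    if (!is.null(p) && !file.exists(p)) {
      stop(sprintf("validation error: %s file '%s' does not exist", nm, p),
           call. = FALSE)
    }
  }
  stopifnot(threshold > 0, threshold <= 1, tol_ppm > 0,
            is.finite(docking_threshold),
            cluster_cut > 0, cluster_cut < 1, atc_level %in% 1:5)
  structure(c(paths, list(out_dir = out_dir, threshold = threshold,
                          top_k = top_k, tol_ppm = tol_ppm,
                          docking_threshold = docking_threshold,
                          tst_mode = tst_mode, cluster_cut = cluster_cut,
                          atc_level = atc_level, correction = correction,
                          n_bits = as.integer(n_bits),
                          seed = as.integer(seed))),
            class = "run_config")
}

#' Run the full compound-target inference pipeline
#'
#' Executes metabolite prediction, similarity screening, target
#' collection, ATC similarity, network construction and clustering,
#' enrichment and docking triage; writes every intermediate artifact
#' under \code{out_dir} and returns a run report (also written as JSON
#' and text). Re-running with identical inputs and config reproduces
#' identical outputs.
#'
#' @param cfg A \code{run_config}.
#' @return The report, invisibly a list.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  report <- list(seed = cfg$seed,
                 params = cfg[c("threshold", "tol_ppm", "docking_threshold",
                                "tst_mode", "cluster_cut", "atc_level",
                                "correction")])

  # -- metabolite prediction ------------------------------------------------
  cons <- utils::read.delim(cfg$constituents, stringsAsFactors = FALSE,
                            colClasses = "character")
  parents <- cons[cons$kind == "prototype", c("id", "formula"), drop = FALSE]
  cand <- enumerate_candidates(parents, default_rules())
  utils::write.table(cand, out("metabolite_candidates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  report$n_candidates <- nrow(cand)
  if (!is.null(cfg$features)) {
    feats <- utils::read.delim(cfg$features, stringsAsFactors = FALSE)
    feats$mz <- as.numeric(feats$mz)
    asg <- match_features(cand, feats, cfg$tol_ppm)
    utils::write.table(asg, out("feature_assignments.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$n_features <- nrow(feats)
    report$n_matched_features <- length(unique(asg$feature_id))
  }

  # -- target inference -----------------------------------------------------
  lib <- read_drug_library(cfg$library, cfg$n_bits)
  queries <- read_compound_set(cfg$queries, cfg$n_bits)
  hits <- screen(queries, lib, threshold = cfg$threshold, top_k = cfg$top_k)
  utils::write.table(hits, out("similarity_hits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cand_sets <- collect_targets(hits, lib, compound_ids = queries$info$id)
  report$n_hits <- nrow(hits)
  all_targets <- sort(unique(unlist(lapply(cand_sets, `[[`, "targets"))))
  report$n_candidate_targets <- length(all_targets)

  if (!is.null(cfg$truth)) {
    truth <- jsonlite::read_json(cfg$truth, simplifyVector = TRUE)
    pr <- .target_recovery(cand_sets, truth$true_targets)
    report$target_precision <- pr$precision
    report$target_recall <- pr$recall
  }

  # -- ATC similarity -------------------------------------------------------
  model <- atc_frequency_model(lib)
  write_atc_model(model, out("atc_model.tsv"))
  profiles <- target_atc_profiles(lib)
  profiles <- profiles[names(profiles) %in% all_targets]
  profiles <- profiles[vapply(profiles, length, integer(1)) > 0]
  if (length(profiles) >= 2) {
    tst <- tst_matrix(profiles, method = cfg$tst_mode, model = model)
    utils::write.table(tst, out("tst_matrix.tsv"), sep = "\t", quote = FALSE,
                       col.names = NA)
    groups <- group_targets(profiles, level = cfg$atc_level)
    report$n_target_groups <- length(groups)
  }

  # -- network --------------------------------------------------------------
  net <- build_network(cand_sets, hits = hits)
  write_sif(net, out("ctn.sif"))
  write_graphml(net, out("ctn.graphml"))
  write_node_table(net, out("ctn_nodes.tsv"))
  deg <- degree_summary(net)
  report$n_nodes <- nrow(net$nodes)
  report$n_edges <- nrow(net$edges)
  report$max_degree <- attr(deg, "max_degree")
  report$min_degree <- attr(deg, "min_degree")
  report$zero_degree_compounds <- attr(deg, "zero_degree_compounds")
  part <- cluster_compounds(queries, cut = cfg$cluster_cut)
  report$n_compound_clusters <- length(part$clusters)

  # -- enrichment -----------------------------------------------------------
  if (!is.null(cfg$annotations) && length(all_targets) > 0) {
    terms <- read_gmt(cfg$annotations)
    background <- sort(unique(c(unlist(lib$drugs$targets), all_targets)))
    enr <- enrich(all_targets, terms, background,
                  correction = cfg$correction)
    utils::write.table(enr, out("enrichment.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    report$top_terms <- utils::head(enr$term_id, 5)
  }

  # -- docking triage -------------------------------------------------------
  if (!is.null(cfg$docking)) {
    dock <- read_docking_table(cfg$docking)
    kept <- filter_docking(dock, cfg$docking_threshold)
    summ <- summarize_docking(kept)
    utils::write.table(kept, out("docking_filtered.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(summ, out("docking_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$n_docking_records <- nrow(dock)
    report$n_docking_retained <- nrow(kept)
    gb <- attr(summ, "global_best")
    if (!is.null(gb)) report$docking_global_best <- gb
  }

  # Published DrugBank-scale context, for side-by-side reading only: these
  # counts depend on an external proprietary library snapshot and are not
  # reproducible from packaged or synthetic inputs.
  report$reference_context <- list(
    note = paste("DrugBank-scale analysis context (not reproducible",
                 "without the external drug library snapshot)"),
    nodes = 143, edges = 1049, candidate_targets = 122,
    top_compound_degrees = c(73, 42, 34, 19, 0))

  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  writeLines(.report_text(report), out("report.txt"))
  invisible(report)
}

.target_recovery <- function(cand_sets, true_targets) {
  qids <- intersect(names(cand_sets), names(true_targets))
  prec <- rec <- numeric(0)
  for (q in qids) {
    pred <- cand_sets[[q]]$targets
    truth <- unlist(true_targets[[q]])
    tp <- length(intersect(pred, truth))
    prec <- c(prec, if (length(pred)) tp / length(pred) else 0)
    rec <- c(rec, if (length(truth)) tp / length(truth) else 1)
  }
  list(precision = mean(prec), recall = mean(rec))
}

.report_text <- function(r) {
  fmt <- function(x) paste(format(x), collapse = ", ")
  c("compound-target inference run report",
    "------------------------------------",
    vapply(setdiff(names(r), c("params", "reference_context")),
           function(nm) sprintf("%s: %s", nm, fmt(r[[nm]])), character(1)),
    "",
    sprintf("[context] %s", r$reference_context$note),
    sprintf("[context] nodes=%d edges=%d candidate_targets=%d",
            r$reference_context$nodes, r$reference_context$edges,
            r$reference_context$candidate_targets))
}
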