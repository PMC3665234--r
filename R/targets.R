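#' Construct a drug library
#'
#' The library is the screening reference: one record per drug with a
#' fingerprint, zero or more ATC codes, and zero or more target gene
#' symbols. Internally the fingerprints are kept as a 0/1 matrix (rows =
#' drugs) so screening is a single matrix product.
#'
#' @param drugs data.frame with columns \code{drug_id}, \code{name},
#'   and list-columns (or ";"-separated strings) \code{atc_codes} and
#'   \code{targets}.
#' @param fp 0/1 matrix of fingerprints, one row per drug, rownames =
#'   drug_id.
#' @return A \code{drug_library}.
#' @export
drug_library <- function(drugs, fp) {
  stopifnot(is.data.frame(drugs), "drug_id" %in% names(drugs))
  if (anyDuplicated(drugs$drug_id)) {
    stop("duplicate drug_id in library", call. = FALSE)
  }
  fp <- as.matrix(fp)
  if (nrow(fp) != nrow(drugs)) {
    stop("fingerprint matrix and drug table sizes differ", call. = FALSE)
  }
  rownames(fp) <- drugs$drug_id
  drugs$atc_codes <- .as_setcol(drugs$atc_codes, nrow(drugs))
  drugs$targets <- .as_setcol(drugs$targets, nrow(drugs))
  structure(list(drugs = drugs, fp = fp), class = "drug_library")
}

.as_setcol <- function(x, n) {
  if (is.null(x)) return(replicate(n, character(0), simplify = FALSE))
  if (is.list(x)) return(lapply(x, as.character))
  lapply(strsplit(as.character(x), ";", fixed = TRUE), function(v) {
    v <- trimws(v)
    v[nzchar(v) & !is.na(v)]
  })
}

#' @export
print.drug_library <- function(x, ...) {
  cat(sprintf("<drug_library> %d drugs, %d-bit fingerprints\n",
              nrow(x$drugs), ncol(x$fp)))
  invisible(x)
}

#' Read a drug library from TSV
#'
#' Expected columns: drug_id, name, one of smiles / fingerprint (hex),
#' atc_codes (";"-separated), targets (";"-separated gene symbols).
#' SMILES are converted through \code{\link{fingerprint_of}}.
#'
#' @param path TSV file.
#' @param n_bits Fingerprint length used to decode hex fingerprints
#'   (and passed to the structure backend).
#' @return A \code{drug_library}.
#' @export
read_drug_library <- function(path, n_bits = 1024L) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  stopifnot(all(c("drug_id", "name") %in% names(d)))
  if ("fingerprint" %in% names(d) && any(nzchar(d$fingerprint))) {
    nb <- as.integer(n_bits)
    fp <- t(vapply(d$fingerprint, function(h) hex_to_fp(h, nb)$bits,
                   integer(nb)))
  } else if ("smiles" %in% names(d)) {
    fp <- t(vapply(d$smiles, function(s) fingerprint_of(s, n_bits)$bits,
                   integer(n_bits)))
  } else {
    stop("library needs a 'fingerprint' (hex) or 'smiles' column",
         call. = FALSE)
  }
  drug_library(d[, intersect(c("drug_id", "name", "atc_codes", "targets"),
                             names(d))], fp)
}

#' Write a drug library to TSV
#'
#' @param lib A \code{drug_library}.
#' @param path Output TSV; fingerprints serialized as hex.
#' @export
write_drug_library <- function(lib, path) {
  stopifnot(inherits(lib, "drug_library"))
  d <- data.frame(
    drug_id = lib$drugs$drug_id,
    name = lib$drugs$name,
    fingerprint = apply(lib$fp, 1, fp_to_hex),
    atc_codes = vapply(lib$drugs$atc_codes, paste, character(1),
                       collapse = ";"),
    targets = vapply(lib$drugs$targets, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.query_fp_matrix <- function(compounds, n_bits) {
  # accepts a compound_set (list(info, fp)) or a plain matrix
  if (is.list(compounds) && !is.data.frame(compounds) &&
      !is.null(compounds$fp)) {
    fp <- as.matrix(compounds$fp)
    if (is.null(rownames(fp)) && !is.null(compounds$info$id)) {
      rownames(fp) <- compounds$info$id
    }
    return(fp)
  }
  if (is.matrix(compounds)) return(compounds)
  stop("compounds must carry fingerprints (a fingerprint matrix or a ",
       "compound set with an $fp matrix); compounds without structures ",
       "or fingerprints cannot be screened", call. = FALSE)
}

#' Screen compounds against the drug library by Tanimoto similarity
#'
#' Returns every (compound, drug) pair at or above \code{threshold},
#' optionally truncated to the \code{top_k} most similar drugs per
#' compound (ties broken by drug_id), sorted per compound by descending
#' score.
#'
#' @param compounds A compound set: list with \code{$info} (data.frame
#'   with \code{id}) and \code{$fp} (0/1 matrix, one row per compound),
#'   or a bare fingerprint matrix with rownames.
#' @param library A \code{drug_library}.
#' @param threshold Minimum Tanimoto similarity (0 < threshold <= 1).
#'   The default 0.85 is the conventional "likely same activity"
#'   heuristic; the screening cutoff the original analysis used is not
#'   published, so this is an explicit knob.
#' @param top_k Optional per-compound rank cutoff applied after the
#'   threshold.
#' @return data.frame: compound_id, drug_id, score.
#' @export
screen <- function(compounds, library, threshold = 0.85, top_k = NULL) {
  stopifnot(inherits(library, "drug_library"),
            threshold > 0, threshold <= 1)
  Q <- .query_fp_matrix(compounds, ncol(library$fp))
  if (ncol(Q) != ncol(library$fp)) {
    stop(sprintf("fingerprint length mismatch: queries %d, library %d",
                 ncol(Q), ncol(library$fp)), call. = FALSE)
  }
  sim <- tanimoto_matrix(Q, library$fp)
  rows <- list()
  for (i in seq_len(nrow(Q))) {
    ok <- which(sim[i, ] >= threshold)
    if (length(ok) == 0L) next
    sc <- sim[i, ok]
    ids <- library$drugs$drug_id[ok]
    ord <- order(-sc, ids)
    if (!is.null(top_k)) ord <- utils::head(ord, top_k)
    rows[[length(rows) + 1L]] <- data.frame(
      compound_id = rownames(Q)[i],
      drug_id = ids[ord],
      score = unname(sc[ord]),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(compound_id = character(), drug_id = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Collect candidate targets from screening hits
#'
#' Per compound, the union of the hit drugs' annotated targets, with
#' provenance recording which drugs support each target. Compounds with
#' no hits are kept with empty target sets (so downstream network
#' statistics can report them) when listed in \code{compound_ids}.
#'
#' @param hits Output of \code{\link{screen}}.
#' @param library The \code{drug_library} the hits refer to.
#' @param compound_ids Optional character vector of all screened compound
#'   ids; defaults to the compounds appearing in \code{hits}.
#' @return A \code{candidate_targets}: named list (by compound id) of
#'   lists with elements \code{targets} (character vector) and
#'   \code{provenance} (named list target -> supporting drug ids).
#' @export
collect_targets <- function(hits, library, compound_ids = NULL) {
  stopifnot(inherits(library, "drug_library"))
  if (nrow(hits) > 0) {
    dangling <- setdiff(hits$drug_id, library$drugs$drug_id)
    if (length(dangling)) {
      stop(sprintf("hit refers to drug id(s) absent from library: %s",
                   paste(dangling, collapse = ", ")), call. = FALSE)
    }
  }
  if (is.null(compound_ids)) compound_ids <- unique(hits$compound_id)
  tgt_by_drug <- stats::setNames(library$drugs$targets,
                                 library$drugs$drug_id)
  out <- lapply(compound_ids, function(cid) {
    h <- hits[hits$compound_id == cid, , drop = FALSE]
    prov <- list()
    for (j in seq_len(nrow(h))) {
      for (tg in tgt_by_drug[[h$drug_id[j]]]) {
        prov[[tg]] <- c(prov[[tg]], h$drug_id[j])
      }
    }
    tg <- if (length(prov)) sort(names(prov)) else character(0)
    list(targets = tg, provenance = prov[tg])
  })
  names(out) <- compound_ids
  structure(out, class = "candidate_targets")
}

#' @export
print.candidate_targets <- function(x, ...) {
  nt <- vapply(x, function(e) length(e$targets), integer(1))
  cat(sprintf("<candidate_targets> %d compounds, %d distinct targets\n",
              length(x), length(unique(unlist(lapply(x, `[[`, "targets"))))))
  if (length(nt)) {
    cat("  targets per compound:",
        paste(sprintf("%s:%d", names(nt), nt), collapse = " "), "\n")
  }
  invisible(x)
}
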