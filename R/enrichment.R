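#' Two-sided hypergeometric test
#'
#' For an overlap of k query genes with a K-gene term inside an N-gene
#' background, with query size n: the enrichment tail is P(X >= k), the
#' depletion tail P(X <= k) for X ~ Hypergeometric(N, K, n), and the
#' two-sided p doubles the smaller tail (capped at 1). Both tails include
#' the observed k, so p_enrich + p_deplete = 1 + P(X = k).
#'
#' @param k Observed overlap.
#' @param n Query size.
#' @param K Term size.
#' @param N Background size.
#' @return list(p_enrich, p_deplete, p_two_sided).
#' @export
hypergeom_test <- function(k, n, K, N) {
  stopifnot(k >= 0, n >= 0, K >= 0, N >= 1, n <= N, K <= N, k <= min(n, K))
  if (k < n + K - N) {
    stop("inconsistent counts: k below the minimum possible overlap",
         call. = FALSE)
  }
  p_enrich <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p_deplete <- stats::phyper(k, K, N - K, n)
  list(p_enrich = p_enrich,
       p_deplete = p_deplete,
       p_two_sided = min(1, 2 * min(p_enrich, p_deplete)))
}

#' Read annotation sets in GMT format
#'
#' One term per line: term_id, description, then member genes, all
#' tab-separated.
#'
#' @param path GMT file.
#' @return List of lists with term_id, term_name, genes.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lapply(strsplit(lines, "\t", fixed = TRUE), function(p) {
    list(term_id = p[1], term_name = p[2],
         genes = unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  })
}

#' Write annotation sets in GMT format
#'
#' @param terms List of lists with term_id, term_name, genes.
#' @param path Output file.
#' @export
write_gmt <- function(terms, path) {
  writeLines(vapply(terms, function(t) {
    paste(c(t$term_id, t$term_name, t$genes), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Hypergeometric enrichment of a gene set against annotation terms
#'
#' Runs the two-sided hypergeometric test of \code{query} against every
#' term, relative to \code{background}. Term genes outside the background
#' are ignored; query genes outside the background are an error.
#'
#' @param query Character vector of gene symbols (subset of background).
#' @param terms List of annotation sets as from \code{\link{read_gmt}},
#'   or a named list of gene vectors.
#' @param background Character vector: the gene universe.
#' @param correction \code{"BH"} (default) for Benjamini-Hochberg
#'   adjustment of the two-sided p across terms, or \code{"none"}.
#' @return data.frame sorted by p_two_sided (ties by term_id): term_id,
#'   term_name, k, n, K, N, p_enrich, p_deplete, p_two_sided, p_adjust.
#' @export
enrich <- function(query, terms, background, correction = c("BH", "none")) {
  correction <- match.arg(correction)
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  outside <- setdiff(query, background)
  if (length(outside)) {
    stop(sprintf("query gene(s) outside background: %s",
                 paste(outside, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(names(terms)) && !is.list(terms[[1]])) {
    terms <- lapply(names(terms), function(nm) {
      list(term_id = nm, term_name = nm, genes = terms[[nm]])
    })
  }
  N <- length(background)
  n <- length(query)
  rows <- lapply(terms, function(t) {
    genes <- intersect(unique(t$genes), background)
    K <- length(genes)
    k <- length(intersect(query, genes))
    p <- hypergeom_test(k, n, K, N)
    data.frame(term_id = t$term_id, term_name = t$term_name,
               k = k, n = n, K = K, N = N,
               p_enrich = p$p_enrich, p_deplete = p$p_deplete,
               p_two_sided = p$p_two_sided, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$p_adjust <- if (correction == "BH") {
    stats::p.adjust(out$p_two_sided, method = "BH")
  } else {
    out$p_two_sided
  }
  out <- out[order(out$p_two_sided, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
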