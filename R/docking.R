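#' Read a docking-score table
#'
#' Expected TSV columns: gene, pdb, protein_name, compound, score.
#' Scores must parse as finite numbers; a non-numeric score is reported
#' with its row number.
#'
#' @param path TSV file.
#' @return data.frame of docking records.
#' @export
read_docking_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  stopifnot(all(c("gene", "pdb", "compound", "score") %in% names(d)))
  sc <- suppressWarnings(as.numeric(d$score))
  bad <- which(is.na(sc) | !is.finite(sc))
  if (length(bad)) {
    stop(sprintf("non-numeric docking score at row %d ('%s')",
                 bad[1], d$score[bad[1]]), call. = FALSE)
  }
  d$score <- sc
  d
}

#' Filter docking records by score threshold
#'
#' More negative docking scores indicate stronger predicted binding;
#' records with score at or below the threshold are retained (the
#' boundary is inclusive), in stable input order. The default -5.0 is
#' the published cutoff for nominating candidate effector molecules.
#'
#' @param records data.frame with a numeric \code{score} column.
#' @param threshold Finite score cutoff, default -5.0.
#' @return The retained records.
#' @export
filter_docking <- function(records, threshold = -5.0) {
  stopifnot(is.data.frame(records), is.finite(threshold))
  if (!is.numeric(records$score)) {
    bad <- which(is.na(suppressWarnings(as.numeric(records$score))))
    if (length(bad)) {
      stop(sprintf("non-numeric docking score at row %d", bad[1]),
           call. = FALSE)
    }
    records$score <- as.numeric(records$score)
  }
  records[records$score <= threshold, , drop = FALSE]
}

#' Per-compound summary of docking records
#'
#' For each compound: the number of distinct target genes, the target
#' list, and the best (most negative) score. Multiple PDB structures of
#' the same gene count once. The global best pair is attached as an
#' attribute.
#'
#' @param records Filtered docking records.
#' @return data.frame: compound, n_targets, targets (";"-joined),
#'   best_score; sorted by descending target count then compound.
#'   Attribute \code{global_best} is a list(score, gene, compound).
#' @export
summarize_docking <- function(records) {
  if (nrow(records) == 0L) {
    out <- data.frame(compound = character(), n_targets = integer(),
                      targets = character(), best_score = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "global_best") <- NULL
    return(out)
  }
  sp <- split(records, records$compound)
  out <- do.call(rbind, c(lapply(names(sp), function(cp) {
    r <- sp[[cp]]
    data.frame(compound = cp,
               n_targets = length(unique(r$gene)),
               targets = paste(sort(unique(r$gene)), collapse = ";"),
               best_score = min(r$score),
               stringsAsFactors = FALSE)
  }), list(make.row.names = FALSE)))
  out <- out[order(-out$n_targets, out$compound), , drop = FALSE]
  rownames(out) <- NULL
  i <- which.min(records$score)
  attr(out, "global_best") <- list(score = records$score[i],
                                   gene = records$gene[i],
                                   compound = records$compound[i])
  out
}
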