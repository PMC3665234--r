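#' Validate ATC codes
#'
#' A full ATC code is 7 characters over 5 nested levels: anatomical main
#' group (1 letter), therapeutic subgroup (2 digits), pharmacological
#' subgroup (1 letter), chemical subgroup (1 letter), chemical substance
#' (2 digits) — e.g. \code{N02BA01}.
#'
#' @param code Character vector of codes.
#' @return Logical vector.
#' @export
is_valid_atc <- function(code) {
  grepl("^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$", code)
}

.check_atc <- function(code) {
  bad <- code[!is_valid_atc(code)]
  if (length(bad)) {
    stop(sprintf("invalid ATC code(s): %s",
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  }
  invisible(code)
}

#' The five official level prefixes of an ATC code
#'
#' @param code A single valid ATC code.
#' @return Character vector of the 1-, 3-, 4-, 5- and 7-character prefixes.
#' @export
atc_prefixes <- function(code) {
  .check_atc(code)
  substring(code, 1L, c(1L, 3L, 4L, 5L, 7L))
}

#' Longest matched level prefix of two ATC codes
#'
#' The deepest official level prefix (1, 3, 4, 5 or 7 characters) shared
#' by both codes; the empty string when even the anatomical letters
#' differ.
#'
#' @param a,b Valid ATC codes.
#' @return The shared prefix, possibly \code{""}.
#' @export
#' @examples
#' longest_matched_prefix("A01AA01", "A01AB02")  # "A01A"
longest_matched_prefix <- function(a, b) {
  pa <- atc_prefixes(a); pb <- atc_prefixes(b)
  shared <- pa[pa == pb]
  if (length(shared) == 0L) "" else shared[length(shared)]
}

#' Fit an ATC frequency / information-content model
#'
#' Counts, over the code occurrences of a drug library, how often each
#' level prefix appears (a drug contributing one occurrence per annotated
#' code), and derives prefix probabilities p = count / total and
#' information content IC = -ln p. Rarer prefixes carry more information;
#' these probabilities drive the Lin-style code similarity.
#'
#' @param codes Character vector of full ATC codes, one element per code
#'   occurrence (not deduplicated), or a \code{drug_library} whose codes
#'   are pooled.
#' @return An \code{atc_model}: list with \code{counts}, \code{p},
#'   \code{ic} (all named by prefix) and \code{total}.
#' @export
atc_frequency_model <- function(codes) {
  if (inherits(codes, "drug_library")) {
    codes <- unlist(codes$drugs$atc_codes, use.names = FALSE)
  }
  codes <- as.character(codes)
  if (length(codes) == 0L) stop("no ATC codes to model", call. = FALSE)
  .check_atc(codes)
  pref <- unlist(lapply(codes, atc_prefixes), use.names = FALSE)
  counts <- table(pref)
  total <- length(codes)
  p <- as.numeric(counts) / total
  out <- list(counts = stats::setNames(as.integer(counts), names(counts)),
              p = stats::setNames(p, names(counts)),
              ic = stats::setNames(-log(p), names(counts)),
              total = total)
  structure(out, class = "atc_model")
}

#' @export
print.atc_model <- function(x, ...) {
  cat(sprintf("<atc_model> %d code occurrences, %d distinct prefixes\n",
              x$total, length(x$counts)))
  invisible(x)
}

.model_p <- function(model, prefix) {
  if (!prefix %in% names(model$p)) {
    stop(sprintf("ATC code or prefix '%s' not observed in the frequency model",
                 prefix), call. = FALSE)
  }
  model$p[[prefix]]
}

#' Information-content similarity of two ATC codes
#'
#' Lin-form semantic similarity driven by prefix frequencies:
#' \deqn{S(a, b) = \frac{2 \ln p(\mathrm{prefix}(a, b))}{\ln p(a) + \ln p(b)}}
#' where prefix(a, b) is the longest matched level prefix and p(.) the
#' occurrence probability under \code{model}. Identical codes score 1
#' (identity takes precedence even when p = 1); an empty matched prefix,
#' or a matched prefix with p = 1 (ln p = 0), scores 0.
#'
#' @param a,b Valid ATC codes, both observed in the model.
#' @param model An \code{atc_model}.
#' @return Similarity in [0, 1].
#' @export
code_similarity <- function(a, b, model) {
  stopifnot(inherits(model, "atc_model"))
  .check_atc(c(a, b))
  pa <- .model_p(model, a)
  pb <- .model_p(model, b)
  if (a == b) return(1)
  pref <- longest_matched_prefix(a, b)
  if (!nzchar(pref)) return(0)
  pp <- .model_p(model, pref)
  if (pp >= 1) return(0)
  2 * log(pp) / (log(pa) + log(pb))
}

#' ATC profiles of targets from a drug library
#'
#' For each target gene symbol, the set of ATC codes of all library drugs
#' annotated to that target. These profiles are the inputs to target
#' therapeutic similarity.
#'
#' @param library A \code{drug_library}.
#' @return Named list target -> character vector of unique ATC codes;
#'   targets whose drugs carry no codes get empty profiles.
#' @export
target_atc_profiles <- function(library) {
  stopifnot(inherits(library, "drug_library"))
  prof <- list()
  for (i in seq_len(nrow(library$drugs))) {
    codes <- library$drugs$atc_codes[[i]]
    for (tg in library$drugs$targets[[i]]) {
      prof[[tg]] <- union(prof[[tg]], codes)
    }
  }
  prof[sort(names(prof))]
}

.check_profile <- function(x, who) {
  if (length(x) == 0L) {
    stop(sprintf("target %s has an empty ATC profile", who), call. = FALSE)
  }
  .check_atc(x)
}

#' Target therapeutic similarity: Jaccard form
#'
#' TST as the set overlap of the two targets' ATC code sets:
#' |ATC(T1) n ATC(T2)| / |ATC(T1) u ATC(T2)|, on exact full-code matches.
#'
#' @param t1,t2 Character vectors of ATC codes (a target's profile).
#' @return TST in [0, 1].
#' @export
tst_jaccard <- function(t1, t2) {
  .check_profile(t1, "t1"); .check_profile(t2, "t2")
  t1 <- unique(t1); t2 <- unique(t2)
  length(intersect(t1, t2)) / length(union(t1, t2))
}

#' Target therapeutic similarity: maximum code similarity form
#'
#' TST as the maximum information-content similarity over all code pairs
#' drawn from the two profiles. This is the "maximum ATC code similarity"
#' reading; the Jaccard form is the package's pipeline default (see the
#' methods vignette for the rationale — the two definitions coexist in
#' the method's description and are different scales).
#'
#' @param t1,t2 Character vectors of ATC codes.
#' @param model An \code{atc_model} covering every code in both profiles.
#' @return TST in [0, 1].
#' @export
tst_max_similarity <- function(t1, t2, model) {
  .check_profile(t1, "t1"); .check_profile(t2, "t2")
  best <- 0
  for (a in unique(t1)) {
    for (b in unique(t2)) {
      s <- code_similarity(a, b, model)
      if (s > best) best <- s
    }
  }
  best
}

#' All-pairs target therapeutic similarity matrix
#'
#' @param profiles Named list target -> ATC code set.
#' @param method \code{"jaccard"} (default) or \code{"max_similarity"}.
#' @param model Required for \code{method = "max_similarity"}.
#' @return Symmetric matrix with target symbols as dimnames.
#' @export
tst_matrix <- function(profiles, method = c("jaccard", "max_similarity"),
                       model = NULL) {
  method <- match.arg(method)
  n <- length(profiles)
  out <- matrix(1, n, n, dimnames = list(names(profiles), names(profiles)))
  if (n < 2L) return(out)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- if (method == "jaccard") {
        tst_jaccard(profiles[[i]], profiles[[j]])
      } else {
        tst_max_similarity(profiles[[i]], profiles[[j]], model)
      }
      out[i, j] <- s
      out[j, i] <- s
    }
  }
  out
}

#' Group targets by shared ATC prefix
#'
#' Groups targets by their codes' prefix at the given ATC level. A target
#' whose codes fall under several prefixes joins every matching group
#' (overlap is allowed and flagged).
#'
#' @param profiles Named list target -> ATC code set.
#' @param level ATC level 1-5 (prefix lengths 1, 3, 4, 5, 7).
#' @return Named list prefix -> character vector of targets, with
#'   attribute \code{"overlapping"} listing targets present in more than
#'   one group.
#' @export
group_targets <- function(profiles, level = 2L) {
  stopifnot(level %in% 1:5)
  len <- c(1L, 3L, 4L, 5L, 7L)[level]
  groups <- list()
  for (tg in names(profiles)) {
    codes <- profiles[[tg]]
    if (length(codes) == 0L) next
    .check_atc(codes)
    for (pref in unique(substr(codes, 1L, len))) {
      groups[[pref]] <- union(groups[[pref]], tg)
    }
  }
  groups <- groups[sort(names(groups))]
  members <- unlist(groups, use.names = FALSE)
  attr(groups, "overlapping") <- sort(unique(members[duplicated(members)]))
  groups
}

#' Serialize an ATC frequency model as TSV
#'
#' @param model An \code{atc_model}.
#' @param path Output path (columns prefix, count, p, ic).
#' @export
write_atc_model <- function(model, path) {
  stopifnot(inherits(model, "atc_model"))
  d <- data.frame(prefix = names(model$counts),
                  count = unname(model$counts),
                  p = unname(model$p),
                  ic = unname(model$ic),
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a serialized ATC frequency model
#'
#' @param path TSV written by \code{\link{write_atc_model}}.
#' @param total Total code occurrences; recovered from the deepest-level
#'   counts when omitted.
#' @return An \code{atc_model}.
#' @export
read_atc_model <- function(path, total = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(total)) total <- sum(d$count[nchar(d$prefix) == 7L])
  structure(list(counts = stats::setNames(as.integer(d$count), d$prefix),
                 p = stats::setNames(d$count / total, d$prefix),
                 ic = stats::setNames(-log(d$count / total), d$prefix),
                 total = total),
            class = "atc_model")
}
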