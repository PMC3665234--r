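#' Construct a binary fingerprint
#'
#' The package-wide fingerprint representation is a plain 0/1 integer
#' vector wrapped in a light class. Fingerprints can come from a chemistry
#' backend (\code{\link{fingerprint_of}}) or be injected directly as bit
#' vectors, which is how the synthetic generator and most tests bypass
#' structure parsing entirely.
#'
#' @param bits Logical or 0/1 integer vector.
#' @return A \code{fingerprint} object.
#' @export
fingerprint <- function(bits) {
  bits <- as.integer(bits)
  if (length(bits) == 0L) stop("fingerprint length must be > 0", call. = FALSE)
  if (any(is.na(bits)) || any(!bits %in% c(0L, 1L))) {
    stop("fingerprint bits must be 0/1", call. = FALSE)
  }
  structure(list(bits = bits, n_set = sum(bits)), class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint> %d bits, %d set\n", length(x$bits), x$n_set))
  invisible(x)
}

#' @export
length.fingerprint <- function(x) length(x$bits)

#' Fingerprint from a structure string
#'
#' Computes a deterministic hashed atom-pair fingerprint from a SMILES
#' string via ChemmineR/ChemmineOB. The backend is deliberately pluggable:
#' everything downstream consumes plain bit vectors, so any fingerprint
#' source (including raw vectors) can be substituted.
#'
#' @param structure SMILES string for a small molecule.
#' @param length Number of bits (default 1024, the atom-pair descriptor
#'   basis set size).
#' @return A \code{fingerprint}.
#' @export
fingerprint_of <- function(structure, length = 1024L) {
  stopifnot(is.character(structure), base::length(structure) == 1L)
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("fingerprint_of() needs the ChemmineR and ChemmineOB packages",
         call. = FALSE)
  }
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(c(q = structure))),
    error = function(e) {
      stop(sprintf("cannot parse structure '%s': %s",
                   structure, conditionMessage(e)), call. = FALSE)
    })
  ap <- suppressWarnings(ChemmineR::sdf2ap(sdf))
  e <- new.env()
  utils::data("apfp", package = "ChemmineR", envir = e)
  descnames <- as.character(e$apfp$AP)[seq_len(length)]
  fpma <- ChemmineR::desc2fp(ap, descnames = descnames, type = "matrix")
  fingerprint(as.integer(fpma[1, ]))
}

.fp_bits <- function(x) {
  if (inherits(x, "fingerprint")) x$bits else as.integer(x)
}

#' Tanimoto similarity of two fingerprints
#'
#' |a AND b| / |a OR b| on the bit sets. Two all-zero fingerprints carry no
#' similarity evidence, so that case is defined as 0 rather than 0/0.
#'
#' @param a,b \code{fingerprint} objects (or 0/1 vectors) of equal length.
#' @return Similarity in [0, 1].
#' @export
tanimoto <- function(a, b) {
  a <- .fp_bits(a); b <- .fp_bits(b)
  if (length(a) != length(b)) {
    stop(sprintf("fingerprint length mismatch: %d vs %d",
                 length(a), length(b)), call. = FALSE)
  }
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0L) return(0)
  inter / uni
}

# All-pairs Tanimoto between the rows of two 0/1 matrices.
# Used by screening and clustering; crossprod keeps it O(n m bits) in C.
tanimoto_matrix <- function(A, B = A) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(ncol(A) == ncol(B))
  inter <- tcrossprod(A, B)
  na <- rowSums(A); nb <- rowSums(B)
  uni <- outer(na, nb, "+") - inter
  out <- ifelse(uni == 0, 0, inter / uni)
  dimnames(out) <- list(rownames(A), rownames(B))
  out
}

# hex serialization so libraries can round-trip through TSV
fp_to_hex <- function(bits) {
  bits <- .fp_bits(bits)
  pad <- (8L - length(bits) %% 8L) %% 8L
  bits <- c(bits, integer(pad))
  bytes <- vapply(seq_len(length(bits) / 8L), function(i) {
    b <- bits[(8L * (i - 1L) + 1L):(8L * i)]
    sum(b * 2L^(7:0))
  }, numeric(1))
  paste(sprintf("%02x", as.integer(bytes)), collapse = "")
}

hex_to_fp <- function(hex, n_bits) {
  bytes <- strtoi(substring(hex, seq(1, nchar(hex), 2),
                            seq(2, nchar(hex), 2)), 16L)
  bits <- unlist(lapply(bytes, function(b) as.integer(intToBits(b)[8:1])))
  fingerprint(bits[seq_len(n_bits)])
}
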