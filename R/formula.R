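#' Monoisotopic masses of the elements handled by the package
#'
#' Masses of the most abundant isotope, in Da, for the elements that occur
#' in small-molecule drug metabolism work (CHNOPS plus the halogens).
#' Values are the conventional high-resolution MS constants; carbon is
#' exactly 12 by definition.
#'
#' @return Named numeric vector of monoisotopic masses (Da).
#' @export
#' @examples
#' isotope_masses()[["C"]]
isotope_masses <- function() {
  c(
    C  = 12.000000,
    H  = 1.0078250,
    N  = 14.0030740,
    O  = 15.9949146,
    S  = 31.9720707,
    P  = 30.9737615,
    F  = 18.9984032,
    Cl = 34.9688527,
    Br = 78.9183376,
    I  = 126.9044730
  )
}

#' Mass of the proton in Da
#'
#' Used for protonated-ion m/z: the [M+H]+ ion carries the mass of a bare
#' proton (1.0072765 Da), not of a hydrogen atom, because the adduct has
#' lost its electron.
#'
#' @return Proton mass in Da.
#' @export
proton_mass <- function() 1.0072765

.hill_order <- function(elements) {
  if ("C" %in% elements) {
    rest <- sort(setdiff(elements, c("C", "H")))
    c("C", intersect("H", elements), rest)
  } else {
    sort(elements)
  }
}

#' Parse a molecular formula string
#'
#' Accepts Hill-order-like formulas such as \code{"C19H19NO4"}; underscores
#' (sometimes used to mark subscripts in extracted tables) are stripped.
#' Repeated element tokens are summed. Unknown element symbols are rejected.
#'
#' @param text A single formula string.
#' @return A \code{molformula}: a named integer vector of element counts,
#'   Hill-ordered, with zero counts removed.
#' @export
#' @examples
#' parse_formula("C19H19NO4")
#' parse_formula("H2O")
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  raw <- gsub("_", "", text, fixed = TRUE)
  if (!nzchar(raw)) {
    stop("empty formula string", call. = FALSE)
  }
  pattern <- "([A-Z][a-z]?)([0-9]*)"
  m <- gregexpr(pattern, raw, perl = TRUE)[[1]]
  tokens <- regmatches(raw, list(m))[[1]]
  covered <- sum(attr(m, "match.length"))
  if (m[1] != 1L || covered != nchar(raw)) {
    bad <- setdiff(seq_len(nchar(raw)),
                   unlist(mapply(function(s, l) seq(s, s + l - 1L),
                                 as.integer(m), attr(m, "match.length"),
                                 SIMPLIFY = FALSE)))
    stop(sprintf("malformed formula '%s': cannot parse at position %d",
                 text, min(bad)), call. = FALSE)
  }
  els <- sub("[0-9]*$", "", tokens)
  cnt <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", tokens)))
  cnt[is.na(cnt)] <- 1L
  known <- names(isotope_masses())
  if (any(!els %in% known)) {
    stop(sprintf("unknown element symbol(s): %s",
                 paste(unique(els[!els %in% known]), collapse = ", ")),
         call. = FALSE)
  }
  counts <- tapply(cnt, els, sum)
  counts <- counts[counts > 0L]
  out <- as.integer(counts[.hill_order(names(counts))])
  names(out) <- .hill_order(names(counts))
  structure(out, class = "molformula")
}

#' Format a molecular formula
#'
#' Inverse of \code{\link{parse_formula}}: Hill order, counts of one
#' implicit, so that \code{parse_formula(format_formula(f))} reproduces
#' \code{f} exactly.
#'
#' @param f A \code{molformula} or named integer vector of counts.
#' @return Formula string.
#' @export
format_formula <- function(f) {
  f <- f[f != 0L]
  if (length(f) == 0L) return("")
  ord <- .hill_order(names(f))
  paste0(vapply(ord, function(el) {
    n <- f[[el]]
    if (n == 1L) el else paste0(el, n)
  }, character(1)), collapse = "")
}

#' @export
format.molformula <- function(x, ...) format_formula(x)

#' @export
print.molformula <- function(x, ...) {
  cat("<molformula>", format_formula(x), "\n")
  invisible(x)
}

.as_formula <- function(f) {
  if (inherits(f, "molformula")) return(f)
  if (is.character(f)) return(parse_formula(f))
  stop("expected a molformula or formula string", call. = FALSE)
}

#' Element-wise formula arithmetic
#'
#' Adds a signed element delta (e.g. the \code{-CH2} of a demethylation) to
#' a formula. Any element driven below zero is an error naming the element,
#' so infeasible biotransformations are caught at the arithmetic level.
#'
#' @param f A \code{molformula}.
#' @param delta Named integer vector, possibly negative.
#' @return A \code{molformula}.
#' @export
formula_add <- function(f, delta) {
  f <- .as_formula(f)
  known <- names(isotope_masses())
  if (length(delta) && any(!names(delta) %in% known)) {
    stop(sprintf("unknown element symbol(s) in delta: %s",
                 paste(setdiff(names(delta), known), collapse = ", ")),
         call. = FALSE)
  }
  els <- union(names(f), names(delta))
  out <- vapply(els, function(el) {
    as.integer(sum(f[el], delta[el], na.rm = TRUE))
  }, integer(1))
  neg <- names(out)[out < 0L]
  if (length(neg)) {
    stop(sprintf("infeasible formula change: element %s would have count %d",
                 neg[1], out[[neg[1]]]), call. = FALSE)
  }
  out <- out[out > 0L]
  res <- as.integer(out[.hill_order(names(out))])
  names(res) <- .hill_order(names(out))
  structure(res, class = "molformula")
}

#' Monoisotopic mass of a formula
#'
#' Sum over elements of count times the most-abundant-isotope mass from
#' \code{\link{isotope_masses}}.
#'
#' @param f A \code{molformula} or formula string.
#' @return Mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("C19H19NO4")
monoisotopic_mass <- function(f) {
  f <- .as_formula(f)
  if (length(f) == 0L) stop("empty formula has no mass", call. = FALSE)
  masses <- isotope_masses()
  missing <- setdiff(names(f), names(masses))
  if (length(missing)) {
    stop(sprintf("no packaged isotope mass for element(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  sum(as.numeric(f) * masses[names(f)])
}

#' Theoretical m/z of the protonated ion [M+H]+
#'
#' Monoisotopic mass plus the proton mass (the adduct is a bare proton).
#'
#' @param f A \code{molformula} or formula string.
#' @return m/z in Th.
#' @export
#' @examples
#' mh_plus("C19H19NO4")  # ~326.1387
mh_plus <- function(f) {
  monoisotopic_mass(f) + proton_mass()
}

#' Relative mass error in parts per million
#'
#' @param observed Observed m/z.
#' @param theoretical Theoretical m/z.
#' @return (observed - theoretical) / theoretical * 1e6.
#' @export
ppm_error <- function(observed, theoretical) {
  (observed - theoretical) / theoretical * 1e6
}
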