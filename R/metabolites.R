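#' Define a biotransformation rule
#'
#' A rule is a signed element delta applied to a parent formula, e.g.
#' demethylation is \code{c(C = -1, H = -2)} ("-CH2"). Rules are data, not
#' code: the default catalogue can be extended or replaced by the user.
#'
#' @param name Rule name, e.g. \code{"demethylation"}.
#' @param delta Named integer vector of signed element changes (non-empty).
#' @param display Human-readable form of the change, e.g. \code{"-CH2"}.
#' @return A \code{reaction_rule}.
#' @export
reaction_rule <- function(name, delta, display = name) {
  stopifnot(is.character(name), length(delta) > 0L, !is.null(names(delta)))
  delta <- vapply(delta, as.integer, integer(1))
  structure(list(name = name, delta = delta, display = display),
            class = "reaction_rule")
}

#' @export
print.reaction_rule <- function(x, ...) {
  cat(sprintf("<reaction_rule> %s (%s)\n", x$name, x$display))
  invisible(x)
}

#' Default biotransformation catalogue
#'
#' The three formula changes observed for this prescription's metabolites:
#' demethylation (-CH2), the composite demethylation plus hydrogenation
#' (-CH2+H2, net -C), and oxidation of a methylene to a ketone (+O-H2).
#'
#' @return List of \code{reaction_rule} objects.
#' @export
default_rules <- function() {
  list(
    reaction_rule("demethylation", c(C = -1L, H = -2L), "-CH2"),
    reaction_rule("demethylation+hydrogenation", c(C = -1L), "-CH2+H2"),
    reaction_rule("methylene_to_ketone", c(O = 1L, H = -2L), "+O-H2")
  )
}

#' Apply a biotransformation rule to a parent formula
#'
#' @param parent \code{molformula} (or formula string) of the parent.
#' @param rule A \code{reaction_rule}.
#' @return The metabolite \code{molformula}; error if any element count
#'   would go negative.
#' @export
#' @examples
#' apply_rule(parse_formula("C21H25NO4"), default_rules()[[1]])  # C20H23NO4
apply_rule <- function(parent, rule) {
  stopifnot(inherits(rule, "reaction_rule"))
  formula_add(.as_formula(parent), rule$delta)
}

.rule_compositions <- function(rules, depth) {
  out <- rules
  if (depth >= 2L) {
    frontier <- rules
    for (d in 2:depth) {
      nxt <- list()
      for (f in frontier) {
        for (r in rules) {
          delta <- f$delta
          for (el in names(r$delta)) {
            delta[el] <- sum(delta[el], r$delta[el], na.rm = TRUE)
          }
          delta <- delta[delta != 0L]
          if (length(delta) == 0L) next
          nxt[[length(nxt) + 1L]] <- reaction_rule(
            paste(f$name, r$name, sep = "+"),
            delta,
            paste(f$display, r$display, sep = " "))
        }
      }
      out <- c(out, nxt)
      frontier <- nxt
    }
  }
  # drop duplicate net deltas, keeping the first (shortest) name
  keys <- vapply(out, function(r) {
    d <- sort(names(r$delta))
    paste(d, r$delta[d], collapse = ";")
  }, character(1))
  out[!duplicated(keys)]
}

#' Enumerate formula-level metabolite candidates
#'
#' Applies every feasible rule (and rule composition up to \code{depth})
#' to every parent, producing one candidate per feasible pair with its
#' theoretical protonated m/z. Infeasible pairs (negative element counts)
#' are skipped silently.
#'
#' @param parents data.frame with columns \code{id} and \code{formula}
#'   (formula strings), e.g. a subset of \code{\link{yzp_constituents}}.
#' @param rules List of \code{reaction_rule}s, default
#'   \code{\link{default_rules}}.
#' @param depth Composition depth; 1 applies single catalogue rules only
#'   (the catalogue already includes the observed composite change).
#' @return data.frame: parent_id, rule, change, formula, theoretical_mh.
#' @export
enumerate_candidates <- function(parents, rules = default_rules(), depth = 1L) {
  stopifnot(is.data.frame(parents), all(c("id", "formula") %in% names(parents)))
  if (length(rules) == 0L) {
    return(data.frame(parent_id = character(), rule = character(),
                      change = character(), formula = character(),
                      theoretical_mh = numeric(), stringsAsFactors = FALSE))
  }
  rules <- .rule_compositions(rules, depth)
  empty <- data.frame(parent_id = character(), rule = character(),
                      change = character(), formula = character(),
                      theoretical_mh = numeric(), stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(parents))) {
    pf <- parse_formula(parents$formula[i])
    for (r in rules) {
      cand <- tryCatch(apply_rule(pf, r), error = function(e) NULL)
      if (is.null(cand) || length(cand) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        parent_id = as.character(parents$id[i]),
        rule = r$name,
        change = r$display,
        formula = format_formula(cand),
        theoretical_mh = mh_plus(cand),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Match observed LC-MS features to metabolite candidates
#'
#' A feature matches a candidate when the observed protonated m/z is within
#' \code{tol_ppm} of the candidate's theoretical value and, when the
#' feature carries an assigned formula, the formulas are identical.
#' Every feature may report zero or several matches (positional isomers
#' share a formula and cannot be distinguished at the formula level).
#'
#' @param candidates Output of \code{\link{enumerate_candidates}}.
#' @param observed data.frame with columns \code{id}, \code{mz} and
#'   optionally \code{formula} (e.g. \code{\link{yzp_features}}).
#' @param tol_ppm Mass tolerance in ppm; default 10, a conventional
#'   Q-TOF window.
#' @return data.frame of assignments, sorted per feature by absolute ppm
#'   error: feature_id, parent_id, rule, formula, theoretical_mh, mz,
#'   ppm_error.
#' @export
match_features <- function(candidates, observed, tol_ppm = 10) {
  stopifnot(tol_ppm > 0)
  empty <- data.frame(feature_id = character(), parent_id = character(),
                      rule = character(), formula = character(),
                      theoretical_mh = numeric(), mz = numeric(),
                      ppm_error = numeric(), stringsAsFactors = FALSE)
  if (is.null(observed) || nrow(observed) == 0L ||
      is.null(candidates) || nrow(candidates) == 0L) {
    return(empty)
  }
  has_formula <- "formula" %in% names(observed)
  rows <- list()
  for (i in seq_len(nrow(observed))) {
    ppm <- ppm_error(observed$mz[i], candidates$theoretical_mh)
    ok <- abs(ppm) <= tol_ppm
    if (has_formula && !is.na(observed$formula[i]) &&
        nzchar(observed$formula[i])) {
      want <- format_formula(parse_formula(observed$formula[i]))
      ok <- ok & candidates$formula == want
    }
    if (!any(ok)) next
    hit <- candidates[ok, , drop = FALSE]
    hit_ppm <- ppm[ok]
    ord <- order(abs(hit_ppm), hit$parent_id, hit$rule)
    rows[[length(rows) + 1L]] <- data.frame(
      feature_id = as.character(observed$id[i]),
      parent_id = hit$parent_id[ord],
      rule = hit$rule[ord],
      formula = hit$formula[ord],
      theoretical_mh = hit$theoretical_mh[ord],
      mz = observed$mz[i],
      ppm_error = hit_ppm[ord],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
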