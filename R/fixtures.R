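.extdata <- function(file) {
  path <- system.file("extdata", file, package = "ctnpharm")
  if (!nzchar(path)) stop(sprintf("fixture %s not found", file), call. = FALSE)
  path
}

#' Constituents of the Yuanhu Zhitong prescription
#'
#' The 21 in-vivo constituents: 15 absorbed prototype compounds (alkaloids
#' from Rhizoma corydalis, coumarins from Radix angelicae dahuricae) and
#' 6 plasma/CSF metabolites with their parent links and molecular
#' formulas.
#'
#' @return data.frame: id, name, source_herb, kind, parent_id, formula.
#' @export
yzp_constituents <- function() {
  utils::read.delim(.extdata("yzp_constituents.tsv"),
                    stringsAsFactors = FALSE,
                    colClasses = "character")
}

#' Observed metabolite features of the prescription
#'
#' The six LC-MS features detected in vivo: retention time, measured
#' protonated m/z, assigned formula, formula change and parent compound.
#'
#' @return data.frame: id, rt_min, mz, formula, change, parent, source.
#' @export
yzp_features <- function() {
  d <- utils::read.delim(.extdata("yzp_features.tsv"),
                         stringsAsFactors = FALSE)
  d$mz <- as.numeric(d$mz)
  d$rt_min <- as.numeric(d$rt_min)
  d
}

#' Docking scores of nominated compound-target pairs
#'
#' The 17 docking-validated pairs (gene, PDB structure, compound, score);
#' more negative scores indicate stronger predicted binding.
#'
#' @return data.frame: gene, pdb, protein_name, compound, score.
#' @export
yzp_docking <- function() {
  read_docking_table(.extdata("yzp_docking.tsv"))
}

#' Structural category labels of the constituents
#'
#' Qualitative expected labels for the three structural classes of the 21
#' constituents (protopine group / other alkaloids / coumarins), shipped
#' for side-by-side comparison with fingerprint clustering — not asserted
#' as ground truth, since the original classing used a proprietary
#' similarity engine.
#'
#' @return data.frame: id, category (I, II, III).
#' @export
yzp_categories <- function() {
  utils::read.delim(.extdata("yzp_categories.tsv"),
                    stringsAsFactors = FALSE,
                    colClasses = "character")
}
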