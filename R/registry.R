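#' Default metabolite registry
#'
#' The built-in roster of NMR-profiled tomato fruit metabolites: 30
#' characterized compounds in five chemical groups (amino acids, organic
#' acids, simple sugars, energy molecules, and choline/nucleic-acid-related
#' "other" compounds) plus the uncharacterized metabolite \code{"B"}, which
#' carries the \code{excluded} flag so that no correlation pair involving it
#' enters any downstream analysis.
#'
#' @return A data frame with columns \code{code}, \code{name}, \code{group}
#'   (one of \code{"amino acid"}, \code{"organic acid"}, \code{"sugar"},
#'   \code{"energy"}, \code{"other"}) and logical \code{excluded}.
#' @export
#' @examples
#' reg <- default_metabolite_registry()
#' table(reg$group)
default_metabolite_registry <- function() {
  aa <- c(ALA = "alanine", ASN = "asparagine", ASP = "aspartate",
          GABA = "gamma-aminobutyrate", GLN = "glutamine", GLU = "glutamate",
          HIS = "histidine", ILE = "isoleucine", PHE = "phenylalanine",
          THR = "threonine", TRP = "tryptophan", TYR = "tyrosine",
          VAL = "valine")
  oa <- c(CIT = "citrate", FOR = "formate", FUM = "fumarate",
          MAL = "malate", SUCC = "succinate")
  su <- c(aGLC = "alpha-glucose", bGLC = "beta-glucose", FRU = "fructose",
          SUCR = "sucrose")
  en <- c(AMP = "adenosine monophosphate", ATP = "adenosine triphosphate")
  ot <- c(ADEN = "adenosine", CHOL = "choline", INOS = "myo-inositol",
          mNAM = "methyl nicotinamide", NU1 = "nucleoside 1",
          NU2 = "nucleoside 2")
  reg <- data.frame(
    code = c(names(aa), names(oa), names(su), names(en), names(ot), "B"),
    name = c(aa, oa, su, en, ot, "uncharacterized B"),
    group = c(rep("amino acid", length(aa)), rep("organic acid", length(oa)),
              rep("sugar", length(su)), rep("energy", length(en)),
              rep("other", length(ot) + 1L)),
    excluded = FALSE,
    stringsAsFactors = FALSE
  )
  reg$excluded[reg$code == "B"] <- TRUE
  rownames(reg) <- NULL
  reg
}

#' Default factor-level registry
#'
#' Declared levels for the design factors of the study the package models:
#' seven genotype codes and four mulch systems (black polyethylene BP, hairy
#' vetch HV, rye RY, bare soil BS). Tables presenting other levels are
#' rejected at load unless the registry is extended via the schema.
#'
#' @return Named list of character vectors of admissible levels.
#' @export
default_factor_registry <- function() {
  list(
    genotype = c("2", "4", "5", "8", "10", "12", "20"),
    mulch = c("BP", "HV", "RY", "BS")
  )
}

#' Build a metabolite registry for a set of codes
#'
#' Codes found in the default registry keep their name/group; unknown codes
#' are admitted with group \code{"other"}. Codes listed in \code{exclude}
#' are flagged so that they never enter pairwise analyses.
#'
#' @param codes Character vector of metabolite codes (case-sensitive, unique).
#' @param exclude Codes to flag as excluded (default the uncharacterized
#'   \code{"B"}).
#' @param registry Optional data frame overriding
#'   \code{\link{default_metabolite_registry}}; must have columns
#'   \code{code}, \code{group} and optionally \code{name}, \code{excluded}.
#' @return Registry data frame restricted to \code{codes}, in their order.
#' @export
resolve_registry <- function(codes, exclude = "B", registry = NULL) {
  if (anyDuplicated(codes)) {
    stop("duplicate metabolite codes: ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "))
  }
  base <- if (is.null(registry)) default_metabolite_registry() else registry
  if (!all(c("code", "group") %in% names(base))) {
    stop("registry must have columns 'code' and 'group'")
  }
  idx <- match(codes, base$code)
  out <- data.frame(
    code = codes,
    name = ifelse(is.na(idx), codes,
                  if ("name" %in% names(base)) base$name[idx] else codes),
    group = ifelse(is.na(idx), "other", base$group[idx]),
    excluded = if ("excluded" %in% names(base)) {
      ifelse(is.na(idx), FALSE, base$excluded[idx])
    } else FALSE,
    stringsAsFactors = FALSE
  )
  out$excluded <- out$excluded | out$code %in% exclude
  rownames(out) <- NULL
  out
}
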