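#' Define a two-subset partition of samples
#'
#' A partition scheme splits samples into exactly two labeled subsets by a
#' predicate on each sample's factor record, optionally restricted to a
#' background stratum (samples outside the stratum belong to neither
#' subset). Subset A is always the reference ("from") side of a differential
#' comparison; subset B is the "to" side.
#'
#' @param name Identifier used in outputs and configs.
#' @param a_label,b_label Display names of the two subsets.
#' @param assign Function taking the factor data frame and returning a
#'   character vector of \code{"A"}, \code{"B"} or \code{NA} per sample.
#' @param stratum Optional function taking the factor data frame and
#'   returning a logical vector; samples where it is \code{FALSE} are
#'   excluded before assignment.
#' @param pooled_factors Factor names deliberately ignored by the split
#'   (documentation only).
#' @return An object of class \code{partition_scheme}.
#' @export
partition_scheme <- function(name, a_label, b_label, assign,
                             stratum = NULL, pooled_factors = character()) {
  stopifnot(is.function(assign), is.null(stratum) || is.function(stratum))
  structure(list(name = name, a_label = a_label, b_label = b_label,
                 assign = assign, stratum = stratum,
                 pooled_factors = pooled_factors),
            class = "partition_scheme")
}

#' @export
print.partition_scheme <- function(x, ...) {
  cat("<partition_scheme> ", x$name, ": A='", x$a_label, "' vs B='",
      x$b_label, "'", if (!is.null(x$stratum)) "  (stratified)" else "",
      "\n", sep = "")
  invisible(x)
}

#' Apply a partition scheme to a table
#'
#' @param table A \code{metabolite_table}.
#' @param scheme A \code{partition_scheme}.
#' @return Character vector (one element per sample, named by sample id) of
#'   \code{"A"}, \code{"B"} or \code{NA} for samples in neither subset.
#'   Errors if either subset comes out empty.
#' @export
apply_partition <- function(table, scheme) {
  stopifnot(inherits(table, "metabolite_table"),
            inherits(scheme, "partition_scheme"))
  fac <- table$factors
  side <- scheme$assign(fac)
  if (!is.null(scheme$stratum)) {
    side[!scheme$stratum(fac)] <- NA_character_
  }
  if (!all(side %in% c("A", "B", NA_character_))) {
    stop("partition '", scheme$name, "' produced labels other than A/B/NA")
  }
  if (sum(side == "A", na.rm = TRUE) == 0L ||
      sum(side == "B", na.rm = TRUE) == 0L) {
    stop("partition '", scheme$name, "' leaves an empty subset on this table")
  }
  names(side) <- rownames(table$values)
  side
}

.genotype_split <- function(a_levels, b_levels) {
  force(a_levels); force(b_levels)
  function(fac) {
    g <- fac$genotype
    ifelse(g %in% a_levels, "A", ifelse(g %in% b_levels, "B", NA_character_))
  }
}

#' Built-in partitions of the tomato field study
#'
#' The five contrasts the package ships with, each a two-subset split of
#' samples by genotype or mulch system. Subset A is the reference side:
#' \describe{
#'   \item{polyamine}{low-polyamine genotypes 2, 5, 12 (A) vs high-polyamine
#'     genotypes 4, 8, 10, 20 (B); mulches pooled.}
#'   \item{mejas}{methyl-jasmonate-deficient genotypes 12, 20 (A) vs normal
#'     genotypes 2, 4, 5, 8, 10 (B); mulches pooled.}
#'   \item{mulch}{bare soil + black polyethylene (A) vs hairy vetch + rye
#'     cover-crop mulches (B); genotypes pooled.}
#'   \item{mulch_within_highPA}{black polyethylene (A) vs hairy vetch (B),
#'     restricted to the high-polyamine genotypes 4, 8, 10, 20.}
#'   \item{mulch_within_lowPA}{the same contrast within the low-polyamine
#'     genotypes 2, 5, 12.}
#' }
#' Genotype and mulch levels must match the declared factor registry; tables
#' from other designs raise an error when the schemes are applied.
#'
#' @return Named list of \code{\link{partition_scheme}} objects.
#' @export
#' @examples
#' names(builtin_partitions())
builtin_partitions <- function() {
  low_pa <- c("2", "5", "12")
  high_pa <- c("4", "8", "10", "20")
  mulch_ab <- function(fac) {
    m <- fac$mulch
    ifelse(m %in% c("BS", "BP"), "A",
           ifelse(m %in% c("HV", "RY"), "B", NA_character_))
  }
  bp_vs_hv <- function(fac) {
    m <- fac$mulch
    ifelse(m == "BP", "A", ifelse(m == "HV", "B", NA_character_))
  }
  list(
    polyamine = partition_scheme(
      "polyamine", "low polyamine", "high polyamine",
      .genotype_split(low_pa, high_pa), pooled_factors = "mulch"),
    mejas = partition_scheme(
      "mejas", "meJAS deficient", "meJAS normal",
      .genotype_split(c("12", "20"), c("2", "4", "5", "8", "10")),
      pooled_factors = "mulch"),
    mulch = partition_scheme(
      "mulch", "bare soil + black plastic", "hairy vetch + rye",
      mulch_ab, pooled_factors = "genotype"),
    mulch_within_highPA = partition_scheme(
      "mulch_within_highPA", "BP (high PA)", "HV (high PA)", bp_vs_hv,
      stratum = function(fac) fac$genotype %in% high_pa),
    mulch_within_lowPA = partition_scheme(
      "mulch_within_lowPA", "BP (low PA)", "HV (low PA)", bp_vs_hv,
      stratum = function(fac) fac$genotype %in% low_pa)
  )
}

#' The six subsets entering the stability calculation
#'
#' Stability is scored across the six subsets of the three main partitions
#' (low/high polyamine, deficient/normal meJAS, bare+BP / HV+RY mulch); the
#' nested mulch-within-polyamine schemes are excluded so no sample stratum
#' is double-counted.
#'
#' @return Named list of lists with elements \code{scheme} (a
#'   \code{partition_scheme}) and \code{side} (\code{"A"} or \code{"B"});
#'   names are the subset labels.
#' @export
stability_subsets <- function() {
  main <- builtin_partitions()[c("polyamine", "mejas", "mulch")]
  out <- list()
  for (p in main) {
    out[[p$a_label]] <- list(scheme = p, side = "A")
    out[[p$b_label]] <- list(scheme = p, side = "B")
  }
  out
}
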