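#' Declare a planted correlation change
#'
#' Ties a metabolite pair to a built-in partition and gives the pair's true
#' correlation in each subset. Samples falling in neither subset keep the
#' base correlation.
#'
#' @param i,j Metabolite codes of the pair.
#' @param r_a,r_b True correlations in subsets A and B; both in (-1, 1).
#' @param partition Name of a built-in partition (see
#'   \code{\link{builtin_partitions}}).
#' @return A \code{planted_change} list.
#' @export
planted_change <- function(i, j, r_a, r_b, partition = "polyamine") {
  if (identical(i, j)) stop("a planted change needs two distinct metabolites")
  if (abs(r_a) >= 1 || abs(r_b) >= 1) stop("planted correlations must be in (-1, 1)")
  structure(list(i = i, j = j, r_a = r_a, r_b = r_b, partition = partition),
            class = "planted_change")
}

#' Default factorial field design
#'
#' One fruit sample per genotype x mulch x year x replicate x fruit-stage
#' cell of the two-year tomato trial the generator emulates: six genotypes
#' under three mulches in the first year; a seventh genotype and the
#' bare-soil treatment added in the second; four field replications; pink
#' and red fruit stages.
#'
#' @param replicates Number of field replications (default 4).
#' @return Data frame with columns genotype, mulch, year, stage, replicate.
#' @export
default_design <- function(replicates = 4L) {
  y1 <- expand.grid(genotype = c("4", "5", "8", "10", "12", "20"),
                    mulch = c("BP", "HV", "RY"),
                    year = "2006",
                    stage = c("pink", "red"),
                    replicate = as.character(seq_len(replicates)),
                    stringsAsFactors = FALSE)
  y2 <- expand.grid(genotype = c("2", "4", "5", "8", "10", "12", "20"),
                    mulch = c("BP", "HV", "RY", "BS"),
                    year = "2007",
                    stage = c("pink", "red"),
                    replicate = as.character(seq_len(replicates)),
                    stringsAsFactors = FALSE)
  rbind(y1, y2)
}

#' Group-block base correlation matrix
#'
#' Compound-symmetric blocks: metabolites of the same chemical group share
#' correlation \code{within}, metabolites of different groups share
#' \code{between}.
#'
#' @param registry Metabolite registry (code + group).
#' @param within,between Block correlations.
#' @return Correlation matrix over \code{registry$code}.
#' @export
group_block_correlation <- function(registry, within = 0.4, between = 0.1) {
  p <- nrow(registry)
  same <- outer(registry$group, registry$group, "==")
  m <- matrix(between, p, p, dimnames = list(registry$code, registry$code))
  m[same] <- within
  diag(m) <- 1
  m
}

#' Specify a synthetic metabolite data set
#'
#' Bundles everything \code{\link{simulate_table}} needs: the metabolite
#' roster and chemical groups, the factorial design, a base correlation
#' matrix, planted between-subset correlation changes, concentration means
#' and SDs, a missingness rate and a seed. Defaults emulate the tomato
#' study: 31 metabolite codes (30 characterized plus the uncharacterized
#' "B"), the two-year genotype-by-mulch design, moderate within-group
#' correlation, and 2\% missing cells.
#'
#' @param metabolites Metabolite codes (default: built-in roster).
#' @param registry Registry resolving the codes (default: built-in).
#' @param design Factor data frame, one row per sample (default:
#'   \code{\link{default_design}}).
#' @param base_correlation Correlation matrix over the codes (default:
#'   \code{\link{group_block_correlation}}).
#' @param changes List of \code{\link{planted_change}} objects.
#' @param means,sds Named or scalar concentration means and SDs.
#' @param missing_rate Probability a cell is missing completely at random.
#' @param lognormal Draw on the log scale so concentrations are positive
#'   (moments matched on the original scale; pair correlations then hold on
#'   the log scale).
#' @param seed Integer seed; identical spec + seed gives identical tables.
#' @return A \code{synthetic_spec} object.
#' @export
#' @examples
#' spec <- synthetic_spec(seed = 42,
#'   changes = list(planted_change("CIT", "MAL", 0.2, 0.8, "polyamine")))
#' tab <- simulate_table(spec)
synthetic_spec <- function(metabolites = NULL, registry = NULL,
                           design = default_design(),
                           base_correlation = NULL,
                           changes = list(),
                           means = 100, sds = 20,
                           missing_rate = 0.02,
                           lognormal = FALSE,
                           seed = 1L) {
  if (is.null(registry)) {
    registry <- if (is.null(metabolites)) default_metabolite_registry() else
      resolve_registry(metabolites)
  }
  metabolites <- registry$code
  p <- length(metabolites)
  if (is.null(base_correlation)) {
    base_correlation <- group_block_correlation(registry)
  }
  base_correlation <- as.matrix(base_correlation)
  if (nrow(base_correlation) != p || ncol(base_correlation) != p) {
    stop("base_correlation must be ", p, " x ", p)
  }
  if (is.null(dimnames(base_correlation))) {
    dimnames(base_correlation) <- list(metabolites, metabolites)
  }
  if (!isSymmetric(base_correlation, tol = 1e-8)) {
    stop("base_correlation must be symmetric")
  }
  if (any(abs(diag(base_correlation) - 1) > 1e-12)) {
    stop("base_correlation must have unit diagonal")
  }
  for (ch in changes) {
    if (!inherits(ch, "planted_change")) stop("changes must be planted_change objects")
    if (!all(c(ch$i, ch$j) %in% metabolites)) {
      stop("planted change references unknown metabolite(s): ", ch$i, ", ", ch$j)
    }
    if (!ch$partition %in% names(builtin_partitions())) {
      stop("unknown partition in planted change: ", ch$partition)
    }
  }
  expand <- function(x, what) {
    if (length(x) == 1L && is.null(names(x))) {
      stats::setNames(rep(as.numeric(x), p), metabolites)
    } else {
      if (!all(metabolites %in% names(x))) stop(what, " must name every metabolite")
      as.numeric(x[metabolites])
    }
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  structure(list(metabolites = metabolites, registry = registry,
                 design = design, base_correlation = base_correlation,
                 changes = changes,
                 means = expand(means, "means"), sds = expand(sds, "sds"),
                 missing_rate = missing_rate, lognormal = lognormal,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Repair a correlation matrix to positive semi-definiteness
#'
#' Eigenvalue clipping followed by rescaling to unit diagonal: negative
#' eigenvalues are raised to a small positive floor, the matrix is
#' reconstructed, and rows/columns are rescaled so the diagonal is exactly
#' one. A matrix that is already positive semi-definite is returned
#' unchanged (diagonal forced to exactly 1).
#'
#' @param m Square, symmetric matrix with unit diagonal.
#' @param eig_floor Floor for clipped eigenvalues.
#' @return A valid correlation matrix.
#' @export
nearest_correlation_repair <- function(m, eig_floor = 1e-8) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || !isSymmetric(unname(m), tol = 1e-10)) {
    stop("input must be a square symmetric matrix")
  }
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= -1e-10) {
    diag(m) <- 1
    return(m)
  }
  lam <- pmax(e$values, eig_floor)
  rep_m <- e$vectors %*% (lam * t(e$vectors))
  d <- 1 / sqrt(diag(rep_m))
  rep_m <- rep_m * tcrossprod(d)
  diag(rep_m) <- 1
  dimnames(rep_m) <- dimnames(m)
  rep_m
}

# Per-sample subset side ("A"/"B"/NA) under each planted change's partition.
.change_sides <- function(spec) {
  parts <- builtin_partitions()
  fac <- spec$design
  vapply(spec$changes, function(ch) {
    sc <- parts[[ch$partition]]
    side <- sc$assign(fac)
    if (!is.null(sc$stratum)) side[!sc$stratum(fac)] <- NA_character_
    side
  }, character(nrow(fac)))
}

#' Simulate a metabolite table from a specification
#'
#' Each sample's metabolite vector is drawn from a multivariate normal whose
#' correlation matrix is the spec's base matrix with the planted pairs
#' overwritten according to the sample's subset under each change's
#' partition, repaired to positive semi-definiteness, then shifted/scaled to
#' the per-metabolite concentration mean and SD. Missing cells are injected
#' completely at random. The same spec and seed reproduce the table exactly.
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @return A \code{\link{metabolite_table}} with a \code{provenance} field
#'   recording the seed and per-change subset sides.
#' @export
simulate_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- nrow(spec$design)
  p <- length(spec$metabolites)
  sides <- if (length(spec$changes) > 0) .change_sides(spec) else
    matrix(character(0), nrow = n, ncol = 0)
  sig <- if (ncol(sides) > 0) {
    apply(sides, 1L, paste, collapse = "|")
  } else rep("", n)
  usig <- unique(sig)
  roots <- vector("list", length(usig))
  for (k_sig in seq_along(usig)) {
    s <- usig[k_sig]
    m <- spec$base_correlation
    if (ncol(sides) > 0) {
      side_vec <- sides[match(s, sig), ]
      for (k in seq_along(spec$changes)) {
        ch <- spec$changes[[k]]
        r <- if (is.na(side_vec[k])) NA_real_ else
          if (side_vec[k] == "A") ch$r_a else ch$r_b
        if (!is.na(r)) m[ch$i, ch$j] <- m[ch$j, ch$i] <- r
      }
    }
    m <- nearest_correlation_repair(m)
    e <- eigen(m, symmetric = TRUE)
    roots[[k_sig]] <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  }
  set.seed(spec$seed)
  z <- matrix(stats::rnorm(n * p), nrow = n, ncol = p)
  x <- matrix(NA_real_, n, p)
  for (k_sig in seq_along(usig)) {
    rows <- sig == usig[k_sig]
    x[rows, ] <- z[rows, , drop = FALSE] %*% roots[[k_sig]]
  }
  if (spec$lognormal) {
    sdlog <- sqrt(log(1 + (spec$sds / spec$means)^2))
    meanlog <- log(spec$means) - sdlog^2 / 2
    x <- exp(sweep(sweep(x, 2L, sdlog, "*"), 2L, meanlog, "+"))
  } else {
    x <- sweep(sweep(x, 2L, spec$sds, "*"), 2L, spec$means, "+")
  }
  if (spec$missing_rate > 0) {
    x[matrix(stats::runif(n * p) < spec$missing_rate, n, p)] <- NA_real_
  }
  ids <- sprintf("S%04d_y%s_g%s_%s_%s_r%s", seq_len(n), spec$design$year,
                 spec$design$genotype, spec$design$mulch, spec$design$stage,
                 spec$design$replicate)
  dimnames(x) <- list(ids, spec$metabolites)
  tab <- metabolite_table(x, spec$design, registry = spec$registry)
  tab$provenance <- list(seed = spec$seed, n_changes = length(spec$changes),
                         sides = sides)
  tab
}

#' Ground-truth differential edges of a synthetic spec
#'
#' The exact pair list recovery tests compare against: planted changes tied
#' to the named partition whose two subset correlations actually differ.
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @param partition Built-in partition name.
#' @return Data frame with columns \code{metabolite_i}, \code{metabolite_j}
#'   (alphabetical within pair), \code{r_a}, \code{r_b}, \code{delta_r}.
#' @export
ground_truth_edges <- function(spec, partition) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!partition %in% names(builtin_partitions())) {
    stop("unknown partition: ", partition)
  }
  keep <- Filter(function(ch) ch$partition == partition && ch$r_a != ch$r_b,
                 spec$changes)
  if (length(keep) == 0L) {
    return(data.frame(metabolite_i = character(), metabolite_j = character(),
                      r_a = numeric(), r_b = numeric(), delta_r = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(keep, function(ch) {
    ij <- sort(c(ch$i, ch$j), method = "radix")
    data.frame(metabolite_i = ij[1L], metabolite_j = ij[2L],
               r_a = ch$r_a, r_b = ch$r_b, delta_r = ch$r_b - ch$r_a,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
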