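#' Fisher r-to-z transformation
#'
#' z = atanh(r) = 0.5 * log((1 + r) / (1 - r)). Stabilizes the sampling
#' variance of a Pearson correlation to approximately 1/(n - 3), which is
#' what makes the two-sample correlation-change test normal-theory exact in
#' the large-sample limit.
#'
#' @param r Correlation(s), each strictly inside (-1, 1).
#' @return z value(s).
#' @export
#' @examples
#' fisher_z(0.5)           # 0.5493
#' fisher_z_inverse(fisher_z(0.42))
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    stop("fisher_z requires |r| < 1")
  }
  atanh(r)
}

#' Inverse Fisher transformation
#'
#' @param z Finite z value(s).
#' @return tanh(z), a correlation in (-1, 1).
#' @export
fisher_z_inverse <- function(z) {
  if (any(!is.finite(z))) stop("fisher_z_inverse requires finite z")
  tanh(z)
}

#' Pairwise Pearson correlations within one sample subset
#'
#' Computes r over pairwise-complete observations for every unordered pair
#' of retained metabolites (registry-excluded codes, such as the
#' uncharacterized "B", are dropped before pairing), together with the
#' pairwise sample count n and the Fisher z value. Pairs with fewer than
#' \code{n_min} complete observations, zero variance in either member, or a
#' saturated |r| = 1 are kept in the set with a reason flag but carry no z
#' and are excluded from all z-based analyses. Samples are canonically
#' sorted by id before computing, so results do not depend on row order.
#'
#' @param table A \code{\link{metabolite_table}}.
#' @param samples Which samples form the subset: logical or integer index,
#'   or character sample ids. \code{NULL} means all samples.
#' @param label Subset label stored with the result.
#' @param n_min Minimum pairwise-complete count for a pair to be retained
#'   (default 4; the change test needs n > 3).
#' @return A \code{correlation_set}: a data frame with columns
#'   \code{metabolite_i}, \code{metabolite_j} (alphabetical within pair),
#'   \code{r}, \code{n}, \code{z}, \code{flag} (\code{"ok"},
#'   \code{"saturated"}, \code{"zero_variance"}, \code{"low_n"}), ordered by
#'   pair; attributes \code{label}, \code{n_min}, \code{roster},
#'   \code{n_samples}.
#' @export
pairwise_correlations <- function(table, samples = NULL, label = "all",
                                  n_min = 4L) {
  stopifnot(inherits(table, "metabolite_table"))
  v <- table$values
  if (!is.null(samples)) {
    v <- v[samples, , drop = FALSE]
  }
  if (nrow(v) < n_min) {
    stop("subset '", label, "' has ", nrow(v),
         " samples; need at least n_min = ", n_min)
  }
  v <- v[order(rownames(v), method = "radix"), , drop = FALSE]
  roster <- retained_metabolites(table)
  v <- v[, roster, drop = FALSE]
  obs <- !is.na(v)
  n_mat <- crossprod(obs)
  r_mat <- suppressWarnings(stats::cor(v, use = "pairwise.complete.obs"))
  idx <- which(upper.tri(r_mat), arr.ind = TRUE)
  r <- r_mat[idx]
  n <- n_mat[idx]
  flag <- rep("ok", length(r))
  flag[is.na(r)] <- "zero_variance"
  flag[!is.na(r) & abs(r) >= 1 - 1e-12] <- "saturated"
  flag[n < n_min] <- "low_n"
  z <- ifelse(flag == "ok", atanh(r), NA_real_)
  out <- data.frame(
    metabolite_i = roster[idx[, 1L]],
    metabolite_j = roster[idx[, 2L]],
    r = r, n = as.integer(n), z = z, flag = flag,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$metabolite_i, out$metabolite_j, method = "radix"), ]
  rownames(out) <- NULL
  structure(out, class = c("correlation_set", "data.frame"),
            label = label, n_min = n_min, roster = roster,
            n_samples = nrow(v))
}

#' Correlation sets for both subsets of a partition
#'
#' @param table A \code{\link{metabolite_table}}.
#' @param scheme A \code{\link{partition_scheme}} or the name of a built-in
#'   partition.
#' @param n_min Passed to \code{\link{pairwise_correlations}}.
#' @return List with elements \code{A} and \code{B}, each a
#'   \code{correlation_set} labeled with the scheme's subset labels.
#' @export
partition_correlations <- function(table, scheme, n_min = 4L) {
  if (is.character(scheme)) {
    parts <- builtin_partitions()
    if (!scheme %in% names(parts)) stop("unknown partition: ", scheme)
    scheme <- parts[[scheme]]
  }
  side <- apply_partition(table, scheme)
  list(
    A = pairwise_correlations(table, which(!is.na(side) & side == "A"),
                              label = scheme$a_label, n_min = n_min),
    B = pairwise_correlations(table, which(!is.na(side) & side == "B"),
                              label = scheme$b_label, n_min = n_min)
  )
}

#' Write correlation sets as one long-format delimited table
#'
#' One row per subset and pair with columns subset, metabolite_i,
#' metabolite_j, r, n, z, flag — the package's analogue of a per-subset
#' pairwise-correlation supplement.
#'
#' @param sets Named list of \code{correlation_set} objects (names override
#'   the sets' own labels when given).
#' @param path Output path.
#' @param delimiter Field separator.
#' @return \code{path}, invisibly.
#' @export
write_correlation_sets <- function(sets, path, delimiter = ",") {
  rows <- lapply(seq_along(sets), function(k) {
    s <- sets[[k]]
    lab <- attr(s, "label")
    if (is.null(lab)) lab <- names(sets)[k]
    data.frame(subset = lab, as.data.frame(s), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read per-subset pairwise correlations from a long-format table
#'
#' Ingests an externally produced listing of the correlation between all
#' metabolite pairs for each data subset (columns: subset, metabolite_i,
#' metabolite_j, r, and optionally n), e.g. a transcription of a published
#' supplement, and reconstitutes one \code{correlation_set} per subset so
#' the differential-network and stability stages can run on it directly.
#'
#' @param path Delimited text file; delimiter auto-detected from the header.
#' @param n_min Minimum n for retention when an n column is present;
#'   when n is absent, every |r| < 1 pair is retained with \code{n = NA}.
#' @return Named list of \code{correlation_set} objects.
#' @export
read_correlation_sets <- function(path, n_min = 4L) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  delim <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
               lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  raw <- utils::read.table(path, sep = delim, header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("subset", "metabolite_i", "metabolite_j", "r")
  if (!all(need %in% names(raw))) {
    stop("correlation table needs columns: ", paste(need, collapse = ", "))
  }
  has_n <- "n" %in% names(raw)
  swap <- raw$metabolite_i > raw$metabolite_j
  tmp <- raw$metabolite_i[swap]
  raw$metabolite_i[swap] <- raw$metabolite_j[swap]
  raw$metabolite_j[swap] <- tmp
  out <- lapply(split(raw, raw$subset), function(d) {
    n <- if (has_n) as.integer(d$n) else rep(NA_integer_, nrow(d))
    flag <- rep("ok", nrow(d))
    flag[is.na(d$r)] <- "zero_variance"
    flag[!is.na(d$r) & abs(d$r) >= 1 - 1e-12] <- "saturated"
    if (has_n) flag[!is.na(n) & n < n_min] <- "low_n"
    set <- data.frame(metabolite_i = d$metabolite_i,
                      metabolite_j = d$metabolite_j,
                      r = d$r, n = n,
                      z = ifelse(flag == "ok", atanh(d$r), NA_real_),
                      flag = flag, stringsAsFactors = FALSE)
    set <- set[order(set$metabolite_i, set$metabolite_j, method = "radix"), ]
    rownames(set) <- NULL
    roster <- sort(unique(c(set$metabolite_i, set$metabolite_j)),
                   method = "radix")
    structure(set, class = c("correlation_set", "data.frame"),
              label = d$subset[1L], n_min = n_min, roster = roster,
              n_samples = NA_integer_)
  })
  out[order(names(out), method = "radix")]
}
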