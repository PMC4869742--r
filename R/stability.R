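#' Five-bin stability classification
#'
#' Maps the cross-partition SD of a pair's z-transformed correlations to
#' the five-color scale of the stability heat map: bin 1 (most stable,
#' yellow) for sd < 0.19, bin 5 (least stable, darkest red) for sd > 0.35,
#' with the interior split into three equal-width bins over [0.19, 0.35]
#' (interior boundaries assigned to the lower bin).
#'
#' @param sd_z Non-negative SD value(s) on the z scale.
#' @return Integer bin(s) in 1..5.
#' @export
#' @examples
#' bin_stability(c(0.109, 0.27, 0.518))  # 1, 3, 5
bin_stability <- function(sd_z) {
  if (any(sd_z < 0, na.rm = TRUE)) stop("sd_z must be >= 0")
  step <- (0.35 - 0.19) / 3
  out <- ifelse(sd_z < 0.19, 1L,
         ifelse(sd_z > 0.35, 5L,
                1L + pmax(1, ceiling((sd_z - 0.19) / step))))
  as.integer(out)
}

.pair_values <- function(sets, col) {
  keys <- lapply(sets, function(s) paste(s$metabolite_i, s$metabolite_j,
                                         sep = "~"))
  all_keys <- sort(unique(unlist(keys)), method = "radix")
  vals <- vapply(seq_along(sets), function(k) {
    s <- sets[[k]]
    v <- ifelse(s$flag == "ok", s[[col]], NA_real_)
    v[match(all_keys, keys[[k]])]
  }, numeric(length(all_keys)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = length(all_keys))
  rownames(vals) <- all_keys
  vals
}

#' Cross-partition stability of every metabolite pair
#'
#' Stability is the sample standard deviation (n - 1 denominator) of a
#' pair's Fisher-z correlations across the subsets in \code{sets} — by
#' default the six subsets of the three main partitions. The companion
#' average is the arithmetic mean of the pair's correlations on the r
#' scale over the same subsets. Pairs with a usable (finite-z) correlation
#' in fewer than \code{min_subsets} subsets are dropped with a reason.
#'
#' @param sets Named list of \code{correlation_set}s, one per subset.
#' @param min_subsets Minimum usable subsets per pair (default 3).
#' @param threshold Stable-association threshold on sd_z (default 0.19,
#'   strict) used by \code{\link{stable_association_counts}}.
#' @return A \code{stability_map}: list with \code{pairs} (metabolite_i,
#'   metabolite_j, sd_z, mean_r, bin, subsets_used), \code{dropped},
#'   \code{subset_labels}, \code{threshold}.
#' @export
build_stability_map <- function(sets, min_subsets = 3L, threshold = 0.19) {
  stopifnot(length(sets) >= min_subsets)
  z <- .pair_values(sets, "z")
  r <- .pair_values(sets, "r")
  used <- rowSums(!is.na(z))
  keep <- used >= min_subsets
  keys <- rownames(z)
  split_keys <- function(k) {
    parts <- strsplit(k, "~", fixed = TRUE)
    data.frame(metabolite_i = vapply(parts, `[`, "", 1L),
               metabolite_j = vapply(parts, `[`, "", 2L),
               stringsAsFactors = FALSE)
  }
  pairs <- split_keys(keys[keep])
  pairs$sd_z <- apply(z[keep, , drop = FALSE], 1L, stats::sd, na.rm = TRUE)
  pairs$mean_r <- rowMeans(r[keep, , drop = FALSE], na.rm = TRUE)
  pairs$bin <- bin_stability(pairs$sd_z)
  pairs$subsets_used <- used[keep]
  rownames(pairs) <- NULL
  dropped <- split_keys(keys[!keep])
  if (nrow(dropped) > 0) {
    dropped$reason <- sprintf("usable in %d < %d subsets", used[!keep],
                              min_subsets)
  } else {
    dropped$reason <- character(0)
  }
  rownames(dropped) <- NULL
  labels <- if (!is.null(names(sets))) names(sets) else
    vapply(sets, attr, "", "label")
  structure(list(pairs = pairs, dropped = dropped, subset_labels = labels,
                 threshold = threshold),
            class = "stability_map")
}

#' @export
print.stability_map <- function(x, ...) {
  cat("<stability_map> ", nrow(x$pairs), " pairs over ",
      length(x$subset_labels), " subsets (", nrow(x$dropped),
      " dropped)\n", sep = "")
  invisible(x)
}

#' Stability map computed from a table and partition schemes
#'
#' Convenience wrapper: applies each scheme (default the three main
#' built-in partitions), computes both subsets' pairwise correlations, and
#' scores stability across the resulting subsets.
#'
#' @param table A \code{\link{metabolite_table}}.
#' @param schemes List of \code{\link{partition_scheme}}s.
#' @param n_min Passed to \code{\link{pairwise_correlations}}.
#' @param ... Passed to \code{\link{build_stability_map}}.
#' @return A \code{stability_map}.
#' @export
stability_from_table <- function(table,
                                 schemes = builtin_partitions()[
                                   c("polyamine", "mejas", "mulch")],
                                 n_min = 4L, ...) {
  sets <- list()
  for (sc in schemes) {
    cs <- partition_correlations(table, sc, n_min = n_min)
    sets[[sc$a_label]] <- cs$A
    sets[[sc$b_label]] <- cs$B
  }
  build_stability_map(sets, ...)
}

#' SD of one pair's z values across subsets
#'
#' @param i,j Metabolite codes of the pair.
#' @param sets Named list of \code{correlation_set}s.
#' @param min_subsets Minimum usable subsets (default 3).
#' @return Sample SD of the pair's z values over the subsets where the
#'   pair is usable.
#' @export
stability_sd <- function(i, j, sets, min_subsets = 3L) {
  .pair_stat(i, j, sets, "z", stats::sd, min_subsets)
}

#' Mean correlation of one pair across subsets
#'
#' @inheritParams stability_sd
#' @return Arithmetic mean of r over the subsets where the pair is usable
#'   (finite z), matching the subsets entering \code{\link{stability_sd}}.
#' @export
mean_correlation <- function(i, j, sets, min_subsets = 3L) {
  .pair_stat(i, j, sets, "r", mean, min_subsets)
}

.pair_stat <- function(i, j, sets, col, fn, min_subsets) {
  ij <- sort(c(i, j), method = "radix")
  vals <- vapply(sets, function(s) {
    hit <- s$metabolite_i == ij[1L] & s$metabolite_j == ij[2L] & s$flag == "ok"
    if (any(hit)) s[[col]][which(hit)[1L]] else NA_real_
  }, numeric(1))
  vals <- vals[!is.na(vals)]
  if (length(vals) < min_subsets) {
    stop("pair ", ij[1L], "~", ij[2L], " usable in only ", length(vals),
         " subsets (need ", min_subsets, ")")
  }
  fn(vals)
}

#' Count each metabolite's stable associations
#'
#' For every metabolite, the number of its retained pairs whose
#' cross-partition sd_z lies strictly below the threshold.
#'
#' @param map A \code{stability_map}.
#' @param threshold Strict upper bound on sd_z (default the map's own,
#'   0.19).
#' @return Data frame with columns \code{metabolite} and \code{count},
#'   sorted by decreasing count then code.
#' @export
stable_association_counts <- function(map, threshold = map$threshold) {
  stopifnot(inherits(map, "stability_map"))
  p <- map$pairs
  stable <- p$sd_z < threshold
  mets <- sort(unique(c(p$metabolite_i, p$metabolite_j)), method = "radix")
  count <- vapply(mets, function(m) {
    sum(stable & (p$metabolite_i == m | p$metabolite_j == m))
  }, integer(1))
  out <- data.frame(metabolite = mets, count = count,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$metabolite, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Two-triangle heat-map matrices
#'
#' Square matrices over an ordered metabolite roster in the layout of the
#' stability figure: the upper-right triangle holds each pair's mean
#' correlation, the lower-left triangle its sd_z; the diagonal is empty.
#' A parallel matrix carries the five-level bin for coloring (mirrored into
#' both triangles' positions of the sd values).
#'
#' @param map A \code{stability_map}.
#' @param order Metabolite display order (default: alphabetical roster of
#'   the map's pairs). Unknown codes are an error.
#' @return List with \code{values} (numeric matrix, upper = mean_r,
#'   lower = sd_z, diagonal NA) and \code{bins} (integer matrix, lower
#'   triangle only).
#' @export
heatmap_matrix <- function(map, order = NULL) {
  stopifnot(inherits(map, "stability_map"))
  p <- map$pairs
  roster <- sort(unique(c(p$metabolite_i, p$metabolite_j)), method = "radix")
  if (is.null(order)) order <- roster
  unknown <- setdiff(order, roster)
  if (length(unknown) > 0) {
    stop("unknown metabolite(s) in order: ", paste(unknown, collapse = ", "))
  }
  k <- length(order)
  vals <- matrix(NA_real_, k, k, dimnames = list(order, order))
  bins <- matrix(NA_integer_, k, k, dimnames = list(order, order))
  for (row in seq_len(nrow(p))) {
    i <- p$metabolite_i[row]; j <- p$metabolite_j[row]
    if (!(i %in% order && j %in% order)) next
    a <- match(i, order); b <- match(j, order)
    up <- c(min(a, b), max(a, b))    # row < col: upper triangle
    vals[up[1L], up[2L]] <- p$mean_r[row]
    vals[up[2L], up[1L]] <- p$sd_z[row]
    bins[up[2L], up[1L]] <- p$bin[row]
  }
  list(values = vals, bins = bins)
}

#' Write heat-map matrices to delimited text
#'
#' @param hm Result of \code{\link{heatmap_matrix}}.
#' @param path_values,path_bins Output paths (bins skipped when
#'   \code{NULL}).
#' @param delimiter Field separator.
#' @return \code{path_values}, invisibly.
#' @export
write_heatmap_matrix <- function(hm, path_values, path_bins = NULL,
                                 delimiter = ",") {
  utils::write.table(hm$values, path_values, sep = delimiter, quote = FALSE,
                     row.names = TRUE, col.names = NA, na = "")
  if (!is.null(path_bins)) {
    utils::write.table(hm$bins, path_bins, sep = delimiter, quote = FALSE,
                       row.names = TRUE, col.names = NA, na = "")
  }
  invisible(path_values)
}
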