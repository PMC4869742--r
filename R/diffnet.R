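#' Two-sample test for a change in correlation
#'
#' Compares a Pearson correlation observed in two independent sample
#' subsets on the Fisher z scale:
#' \deqn{q = (z_b - z_a) / \sqrt{1/(n_a - 3) + 1/(n_b - 3)}}
#' with a two-tailed normal p-value \eqn{p = 2(1 - \Phi(|q|))}. Swapping
#' the subsets negates q and leaves p unchanged.
#'
#' @param r_a,r_b Correlations in subsets A and B, each with |r| < 1.
#' @param n_a,n_b Subset sample sizes, each > 3.
#' @return Data frame with columns \code{q} and \code{p} (vectorized over
#'   the inputs).
#' @export
#' @examples
#' correlation_change_test(0.2, 40, 0.8, 40)  # q = 3.853, p = 1.17e-4
correlation_change_test <- function(r_a, n_a, r_b, n_b) {
  if (any(n_a <= 3) || any(n_b <= 3)) {
    stop("both subsets need n > 3 for the z-based change test")
  }
  if (any(abs(r_a) >= 1) || any(abs(r_b) >= 1)) {
    stop("saturated correlation (|r| >= 1); filter such pairs before testing")
  }
  q <- (atanh(r_b) - atanh(r_a)) / sqrt(1 / (n_a - 3) + 1 / (n_b - 3))
  data.frame(q = q, p = 2 * stats::pnorm(-abs(q)))
}

#' Edge display width from the magnitude of a correlation change
#'
#' Linear map anchored at the conventions of the source figures: a change
#' of about 0.1 in correlation draws the thinnest line and about 0.7 the
#' thickest, clamped outside that range.
#'
#' @param delta_r_magnitude |delta r| values (>= 0).
#' @param w_min,w_max Width at the 0.1 and 0.7 anchors (display units).
#' @return Widths in [w_min, w_max], monotone in the input.
#' @export
display_width <- function(delta_r_magnitude, w_min = 1, w_max = 7) {
  if (any(delta_r_magnitude < 0)) stop("delta_r_magnitude must be >= 0")
  frac <- (delta_r_magnitude - 0.1) / (0.7 - 0.1)
  w_min + pmin(pmax(frac, 0), 1) * (w_max - w_min)
}

#' Build the signed differential-correlation network between two subsets
#'
#' Runs \code{\link{correlation_change_test}} on every metabolite pair
#' retained (finite z) in both correlation sets and keeps the pairs whose
#' correlation changed significantly. Direction is \code{"increase"} when
#' z rose from subset A (the reference, "from" side) to subset B; edge
#' color follows the convention blue = increase, red = decrease, and
#' \code{swap_colors} flips it. Pairs retained in only one set are skipped
#' and reported.
#'
#' @param set_a,set_b \code{correlation_set}s computed on the same
#'   metabolite roster.
#' @param alpha Significance level (default 0.05, two-tailed).
#' @param multiplicity \code{"none"} (raw p < alpha, the default) or
#'   \code{"bh"} (Benjamini-Hochberg adjusted p < alpha).
#' @param partition Partition name recorded in the result.
#' @param swap_colors Swap the blue/red direction coding.
#' @param w_min,w_max Width anchors passed to \code{\link{display_width}}.
#' @return A \code{differential_network}: list with \code{edges} (the
#'   significant pairs with r, n, z per subset, delta_z, delta_r, q, p,
#'   adjusted p, direction, color, width), \code{tests} (all tested pairs),
#'   \code{skipped}, and the settings.
#' @export
build_differential_network <- function(set_a, set_b, alpha = 0.05,
                                       multiplicity = c("none", "bh"),
                                       partition = NA_character_,
                                       swap_colors = FALSE,
                                       w_min = 1, w_max = 7) {
  multiplicity <- match.arg(multiplicity)
  stopifnot(inherits(set_a, "correlation_set"),
            inherits(set_b, "correlation_set"))
  if (!setequal(attr(set_a, "roster"), attr(set_b, "roster"))) {
    stop("correlation sets were computed on different metabolite rosters")
  }
  a <- as.data.frame(set_a)
  b <- as.data.frame(set_b)
  key_a <- paste(a$metabolite_i, a$metabolite_j, sep = "~")
  key_b <- paste(b$metabolite_i, b$metabolite_j, sep = "~")
  m <- match(key_a, key_b)
  if (anyNA(m)) stop("pair rosters of the two sets do not align")
  b <- b[m, ]
  testable <- a$flag == "ok" & b$flag == "ok"
  reason <- paste0("A:", a$flag, "/B:", b$flag)
  skipped <- data.frame(
    metabolite_i = a$metabolite_i[!testable],
    metabolite_j = a$metabolite_j[!testable],
    reason = reason[!testable],
    stringsAsFactors = FALSE
  )
  ta <- a[testable, ]
  tb <- b[testable, ]
  tests <- data.frame(
    metabolite_i = ta$metabolite_i, metabolite_j = ta$metabolite_j,
    r_a = ta$r, n_a = ta$n, z_a = ta$z,
    r_b = tb$r, n_b = tb$n, z_b = tb$z,
    stringsAsFactors = FALSE
  )
  if (nrow(tests) > 0) {
    ct <- correlation_change_test(tests$r_a, tests$n_a, tests$r_b, tests$n_b)
    tests$delta_z <- tests$z_b - tests$z_a
    tests$delta_r <- tests$r_b - tests$r_a
    tests$q <- ct$q
    tests$p <- ct$p
    tests$p_adj <- if (multiplicity == "bh") stats::p.adjust(ct$p, "BH") else ct$p
  } else {
    tests$delta_z <- tests$delta_r <- tests$q <- tests$p <- tests$p_adj <-
      numeric(0)
  }
  sig <- tests$p_adj < alpha
  edges <- tests[sig, , drop = FALSE]
  if (nrow(edges) > 0) {
    edges$direction <- ifelse(edges$delta_z > 0, "increase", "decrease")
    up_color <- if (swap_colors) "red" else "blue"
    down_color <- if (swap_colors) "blue" else "red"
    edges$color <- ifelse(edges$direction == "increase", up_color, down_color)
    edges$width <- display_width(abs(edges$delta_r), w_min, w_max)
  } else {
    edges$direction <- edges$color <- character(0)
    edges$width <- numeric(0)
  }
  rownames(edges) <- NULL
  structure(
    list(partition = partition,
         a_label = attr(set_a, "label"), b_label = attr(set_b, "label"),
         edges = edges, tests = tests, skipped = skipped,
         alpha = alpha, multiplicity = multiplicity,
         swap_colors = swap_colors, w_min = w_min, w_max = w_max),
    class = "differential_network"
  )
}

#' @export
print.differential_network <- function(x, ...) {
  cat("<differential_network> ", x$partition, ": '", x$a_label, "' -> '",
      x$b_label, "'\n  ", nrow(x$tests), " pairs tested, ",
      nrow(x$edges), " significant at alpha = ", x$alpha,
      " (multiplicity: ", x$multiplicity, ")\n", sep = "")
  invisible(x)
}

#' Export a differential network for Cytoscape
#'
#' \code{"edge-csv"} writes a comma-delimited, UTF-8 edge-attribute table
#' with the fixed column order source, target, r_a, r_b, delta_r, delta_z,
#' q, p, direction, color, width (Cytoscape-importable); \code{"graphml"}
#' writes the same attributes as GraphML. Output is byte-identical for
#' identical input and settings.
#'
#' @param net A \code{differential_network}.
#' @param path Output file path.
#' @param format \code{"edge-csv"} (default) or \code{"graphml"}.
#' @return \code{path}, invisibly.
#' @export
export_network <- function(net, path, format = c("edge-csv", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "differential_network"))
  e <- net$edges
  out <- data.frame(source = e$metabolite_i, target = e$metabolite_j,
                    r_a = e$r_a, r_b = e$r_b, delta_r = e$delta_r,
                    delta_z = e$delta_z, q = e$q, p = e$p,
                    direction = e$direction, color = e$color,
                    width = e$width, stringsAsFactors = FALSE)
  if (format == "edge-csv") {
    utils::write.table(out, path, sep = ",", quote = FALSE,
                       row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  } else {
    g <- igraph::graph_from_data_frame(out, directed = FALSE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
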