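test_that("the correlation-change test matches hand arithmetic", {
  # no change: q = 0, p = 1, any valid n
  none <- correlation_change_test(0.4, 12, 0.4, 87)
  expect_equal(none$q, 0)
  expect_equal(none$p, 1)

  # closed form by hand: (atanh(.8) - atanh(.2)) / sqrt(1/37 + 1/37)
  q_hand <- (0.5 * log(1.8 / 0.2) - 0.5 * log(1.2 / 0.8)) / sqrt(2 / 37)
  p_hand <- 2 * pnorm(-abs(q_hand))
  got <- correlation_change_test(0.2, 40, 0.8, 40)
  expect_equal(got$q, 3.853, tolerance = 1e-3)
  expect_equal(got$p, 1.17e-4, tolerance = 1e-2)
  expect_equal(got$q, q_hand, tolerance = 1e-12)
  expect_equal(got$p, p_hand, tolerance = 1e-12)

  # subset swap: q negated, identical p
  swapped <- correlation_change_test(0.8, 40, 0.2, 40)
  expect_equal(swapped$q, -got$q)
  expect_equal(swapped$p, got$p)

  expect_error(correlation_change_test(0.2, 3, 0.5, 40), "n > 3")
  expect_error(correlation_change_test(1, 40, 0.5, 40), "saturated")
})

test_that("display width maps |delta r| linearly between the 0.1 and 0.7 anchors", {
  expect_equal(display_width(0.1), 1)
  expect_equal(display_width(0.7), 7)
  expect_equal(display_width(0.4), 4)          # midpoint
  expect_equal(display_width(0), 1)            # clamped below
  expect_equal(display_width(0.9), 7)          # clamped above
  x <- seq(0, 1, by = 0.01)
  expect_true(all(diff(display_width(x)) >= 0))
  expect_error(display_width(-0.1), ">= 0")
})

test_that("differential networks recover planted edges with calibrated false positives", {
  changes <- list(planted_change("M01", "M02", 0.1, 0.7, "polyamine"),
                  planted_change("M05", "M09", 0.6, 0.0, "polyamine"),
                  planted_change("M12", "M20", -0.3, 0.3, "polyamine"))
  spec <- flat_spec(20, 100, 100, changes = changes, seed = 31)
  tab <- simulate_table(spec)
  cs <- partition_correlations(tab, "polyamine")
  net <- build_differential_network(cs$A, cs$B, partition = "polyamine")

  found <- paste(net$edges$metabolite_i, net$edges$metabolite_j)
  truth <- ground_truth_edges(spec, "polyamine")
  expect_true(all(paste(truth$metabolite_i, truth$metabolite_j) %in% found))

  fp <- sum(!found %in% paste(truth$metabolite_i, truth$metabolite_j))
  bounds <- qbinom(c(0.005, 0.995), 190 - 3, 0.05)
  expect_gte(fp, bounds[1])
  expect_lte(fp, bounds[2])

  # direction encodes the sign of the z change; width matches its own delta_r
  expect_equal(net$edges$direction, ifelse(net$edges$delta_z > 0, "increase", "decrease"))
  expect_equal(net$edges$width, display_width(abs(net$edges$delta_r)))
  expect_equal(net$edges$color, ifelse(net$edges$delta_z > 0, "blue", "red"))

  # BH keeps a subset of the raw-alpha edges
  bh <- build_differential_network(cs$A, cs$B, multiplicity = "bh",
                                   partition = "polyamine")
  expect_true(all(paste(bh$edges$metabolite_i, bh$edges$metabolite_j) %in% found))
  expect_lte(nrow(bh$edges), nrow(net$edges))

  # comparing a subset with itself finds nothing
  self <- build_differential_network(cs$A, cs$A)
  expect_equal(nrow(self$edges), 0L)
})

test_that("swapping subset roles flips directions; edge set ignores input order", {
  spec <- flat_spec(8, 80, 80, seed = 19,
                    changes = list(planted_change("M02", "M07", 0.1, 0.75, "polyamine")))
  tab <- simulate_table(spec)
  cs <- partition_correlations(tab, "polyamine")
  fwd <- build_differential_network(cs$A, cs$B)
  rev <- build_differential_network(cs$B, cs$A)
  key <- function(n) paste(n$edges$metabolite_i, n$edges$metabolite_j)
  expect_setequal(key(fwd), key(rev))
  m <- match(key(fwd), key(rev))
  expect_equal(rev$edges$delta_z[m], -fwd$edges$delta_z)
  expect_equal(rev$edges$p[m], fwd$edges$p)
  expect_equal(rev$edges$direction[m],
               ifelse(fwd$edges$direction == "increase", "decrease", "increase"))

  # permuting metabolite columns and sample rows changes nothing
  perm_tab <- metabolite_table(
    tab$values[rev(seq_len(nrow(tab$values))), sample(ncol(tab$values))],
    tab$factors[rev(seq_len(nrow(tab$values))), ],
    registry = tab$registry)
  cs2 <- partition_correlations(perm_tab, "polyamine")
  fwd2 <- build_differential_network(cs2$A, cs2$B)
  expect_identical(fwd2$edges, fwd$edges)
})

test_that("network export round-trips with internally consistent attributes", {
  spec <- flat_spec(8, 80, 80, seed = 19,
                    changes = list(planted_change("M02", "M07", 0.1, 0.75, "polyamine")))
  tab <- simulate_table(spec)
  cs <- partition_correlations(tab, "polyamine")
  net <- build_differential_network(cs$A, cs$B, partition = "polyamine")
  expect_gte(nrow(net$edges), 1L)

  f <- tempfile(fileext = ".csv")
  export_network(net, f)
  back <- read.csv(f, stringsAsFactors = FALSE)
  expect_equal(names(back),
               c("source", "target", "r_a", "r_b", "delta_r", "delta_z",
                 "q", "p", "direction", "color", "width"))
  expect_equal(nrow(back), nrow(net$edges))
  expect_equal(back$delta_z, net$edges$delta_z, tolerance = 1e-12)
  expect_equal(back$width, display_width(abs(back$delta_r)), tolerance = 1e-12)

  g <- tempfile(fileext = ".graphml")
  export_network(net, g, "graphml")
  gr <- igraph::read_graph(g, format = "graphml")
  expect_equal(igraph::ecount(gr), nrow(net$edges))
  expect_true("delta_z" %in% igraph::edge_attr_names(gr))

  empty <- build_differential_network(cs$A, cs$A)
  fe <- tempfile(fileext = ".csv")
  export_network(empty, fe)
  expect_equal(length(readLines(fe)), 1L)  # header only
})
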