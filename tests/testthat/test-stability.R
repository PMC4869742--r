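test_that("pair stability is the sample SD of z across subsets", {
  sets <- sets_for_pair_z(c(0.1, 0.2, 0.3, 0.1, 0.2, 0.3))
  expect_equal(stability_sd("CIT", "MAL", sets), sqrt(0.04 / 5))  # 0.0894
  # order of the two codes is irrelevant
  expect_equal(stability_sd("MAL", "CIT", sets), sqrt(0.04 / 5))

  const <- sets_for_pair_z(rep(atanh(0.6), 6))
  expect_equal(stability_sd("CIT", "MAL", const), 0)
  expect_equal(mean_correlation("CIT", "MAL", const), 0.6)

  two <- sets_for_pair_z(atanh(c(0.2, -0.2)))
  expect_error(stability_sd("CIT", "MAL", two), "only 2 subsets")
  expect_equal(mean_correlation("CIT", "MAL", two, min_subsets = 2), 0)
  expect_equal(mean_correlation("CIT", "MAL",
                                sets_for_pair_z(atanh(c(0.1, 0.4, 0.7)))), 0.4)
})

test_that("five-bin classification follows the declared thresholds", {
  expect_equal(bin_stability(0.109), 1L)   # most-stable printed extreme
  expect_equal(bin_stability(0.518), 5L)   # least-stable printed extreme
  expect_equal(bin_stability(0.27), 3L)    # interior midpoint
  expect_equal(bin_stability(c(0, 0.1899, 0.19, 0.24, 0.30, 0.35, 0.3501)),
               c(1L, 1L, 2L, 2L, 4L, 4L, 5L))
  # interior boundaries belong to the lower bin
  step <- (0.35 - 0.19) / 3
  expect_equal(bin_stability(0.19 + step), 2L)
  expect_equal(bin_stability(0.19 + 2 * step), 3L)
  # monotone step function
  x <- seq(0, 0.6, by = 0.001)
  expect_true(all(diff(bin_stability(x)) >= 0))
  expect_error(bin_stability(-0.01), ">= 0")
})

test_that("stability maps score pairs, drop sparse ones, and count stable hubs", {
  mk <- function(rs) make_cor_set(data.frame(
    metabolite_i = c("X", "X", "Y"), metabolite_j = c("Y", "Z", "Z"),
    r = rs, n = 50L, stringsAsFactors = FALSE))
  # X~Y varies a lot, X~Z little, Y~Z usable in only 2 subsets
  sets <- list(s1 = mk(c(0.1, 0.50, 0.3)),
               s2 = mk(c(0.6, 0.52, NA)),
               s3 = mk(c(-0.2, 0.48, NA)),
               s4 = mk(c(0.7, 0.51, 0.3)))
  map <- build_stability_map(sets, min_subsets = 3)
  expect_equal(nrow(map$pairs), 2L)
  expect_equal(map$dropped$metabolite_i, "Y")

  xy <- map$pairs[map$pairs$metabolite_i == "X" & map$pairs$metabolite_j == "Y", ]
  expect_equal(xy$sd_z, sd(atanh(c(0.1, 0.6, -0.2, 0.7))))
  expect_equal(xy$mean_r, mean(c(0.1, 0.6, -0.2, 0.7)))
  expect_equal(xy$subsets_used, 4)
  expect_equal(xy$bin, bin_stability(xy$sd_z))

  # strict threshold: sd_z below, not at, the cutoff counts
  mk2 <- function(i, j, sd_target) {
    # six z values with exactly the requested sample SD
    z <- 0.5 + sd_target / sd(1:6) * (1:6 - 3.5)
    sets_for_pair_z(z, i, j)
  }
  sets2 <- Map(function(a, b, c) {
    make_cor_set(rbind(as.data.frame(a), as.data.frame(b), as.data.frame(c))[
      c("metabolite_i", "metabolite_j", "r", "n")])
  }, mk2("X", "Y", 0.10), mk2("X", "Z", 0.18), mk2("X", "W", 0.20))
  map2 <- build_stability_map(sets2, min_subsets = 3)
  counts <- stable_association_counts(map2, threshold = 0.19)
  expect_equal(counts$count[counts$metabolite == "X"], 2L)
  expect_equal(counts$count[counts$metabolite == "W"], 0L)
  all_high <- stable_association_counts(map2, threshold = 0.05)
  expect_true(all(all_high$count == 0L))
})

test_that("heat-map matrices carry mean r upper-right and sd_z lower-left", {
  mk <- function(rs) make_cor_set(data.frame(
    metabolite_i = c("A", "A", "C"), metabolite_j = c("C", "T", "T"),
    r = rs, n = 50L, stringsAsFactors = FALSE))
  sets <- list(mk(c(0.1, 0.4, 0.6)), mk(c(0.2, 0.5, 0.55)),
               mk(c(0.3, 0.6, 0.65)))
  map <- build_stability_map(sets, min_subsets = 3)
  hm <- heatmap_matrix(map)
  expect_equal(dim(hm$values), c(3, 3))
  expect_equal(sum(!is.na(hm$values[upper.tri(hm$values)])), 3)
  expect_equal(sum(!is.na(hm$values[lower.tri(hm$values)])), 3)
  expect_true(all(is.na(diag(hm$values))))
  expect_equal(hm$values["A", "C"], mean_correlation("A", "C", sets))
  expect_equal(hm$values["C", "A"], stability_sd("A", "C", sets))
  expect_equal(hm$bins["C", "A"], bin_stability(stability_sd("A", "C", sets)))

  # reversing the display order transposes the triangle roles
  hm_rev <- heatmap_matrix(map, order = c("T", "C", "A"))
  expect_equal(hm_rev$values["C", "A"], hm$values["A", "C"])
  expect_equal(hm_rev$values["A", "C"], hm$values["C", "A"])
  expect_error(heatmap_matrix(map, order = c("A", "QQ")), "unknown metabolite")

  f <- tempfile(fileext = ".csv")
  write_heatmap_matrix(hm, f)
  back <- as.matrix(read.csv(f, row.names = 1, check.names = FALSE))
  expect_equal(unname(back), unname(hm$values))
})

test_that("with one shared correlation structure, pair SD shrinks as n grows", {
  base <- group_block_correlation(resolve_registry(sprintf("M%02d", 1:6)))
  sim_sets <- function(n, seed) {
    lapply(1:6, function(k) {
      tab <- simulate_table(synthetic_spec(
        metabolites = sprintf("M%02d", 1:6),
        design = two_group_design(n, 4)[1:n, ],
        base_correlation = base, missing_rate = 0, seed = seed + k))
      pairwise_correlations(tab, label = paste0("s", k))
    })
  }
  small <- build_stability_map(sim_sets(30, 100))
  large <- build_stability_map(sim_sets(400, 200))
  expect_lt(mean(large$pairs$sd_z), mean(small$pairs$sd_z))
  # at n = 400 the Fisher sampling SD is ~0.050
  expect_lt(abs(mean(large$pairs$sd_z) - sqrt(1 / 397)), 0.02)
})
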