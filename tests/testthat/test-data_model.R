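test_that("reading a wide table validates, counts missing cells, and round-trips", {
  path <- write_toy_table()
  expect_message(tab <- read_metabolite_table(path), "6 samples, 4 metabolites, 1 missing")
  expect_s3_class(tab, "metabolite_table")
  expect_equal(dim(tab), c(6L, 4L))
  expect_equal(sum(is.na(tab$values)), 1L)
  expect_true(is.na(tab$values["s2", "MAL"]))
  expect_true(tab$registry$excluded[tab$registry$code == "B"])

  # generator output survives a write/read round trip exactly
  gen <- simulate_table(flat_spec(4, 10, 10, seed = 3, missing_rate = 0.1))
  out <- tempfile(fileext = ".csv")
  write_metabolite_table(gen, out)
  back <- read_metabolite_table(out, quiet = TRUE)
  expect_equal(back$values, gen$values)
  expect_equal(back$factors, gen$factors)
})

test_that("malformed tables are rejected loudly", {
  dup_col <- sub("SUCR", "MAL", toy_table_text())
  f <- tempfile(); writeLines(dup_col, f)
  expect_error(read_metabolite_table(f, quiet = TRUE), "duplicate metabolite")

  dup_id <- c(toy_table_text(), "s6,5,BP,2006,red,3,1,1,1,1")
  f <- tempfile(); writeLines(dup_id, f)
  expect_error(read_metabolite_table(f, quiet = TRUE), "duplicate sample id")

  bad_num <- write_toy_table(na_cell = "oops")
  expect_error(read_metabolite_table(bad_num, quiet = TRUE),
               "non-numeric concentration 'oops' at sample 's2', metabolite 'MAL'")

  bad_level <- sub("s5,12", "s5,99", toy_table_text())
  f <- tempfile(); writeLines(bad_level, f)
  expect_error(read_metabolite_table(f, quiet = TRUE), "unknown genotype level")
})

test_that("standardize gives mean 0 / sample SD 1, is idempotent, and rejects constants", {
  v <- cbind(A = c(1, 2, 3), X = c(10, 20, 30))
  rownames(v) <- paste0("s", 1:3)
  tab <- metabolite_table(v, data.frame(year = rep("2006", 3)))
  std <- standardize(tab)
  expect_equal(unname(colMeans(std$values)), c(0, 0))
  expect_equal(unname(apply(std$values, 2, sd)), c(1, 1))

  # n-1 SD convention: [10, 20] -> +/- 1/sqrt(2)
  v2 <- cbind(A = c(10, 20), X = c(1, 5))
  rownames(v2) <- c("s1", "s2")
  tab2 <- standardize(metabolite_table(v2, data.frame(year = c("2006", "2006"))))
  expect_equal(unname(tab2$values[, "A"]), c(-1, 1) / sqrt(2), tolerance = 1e-12)

  twice <- standardize(std)
  expect_equal(twice$values, std$values, tolerance = 1e-12)

  vc <- cbind(A = c(1, 2, 3), FLAT = c(7, 7, 7))
  rownames(vc) <- paste0("s", 1:3)
  expect_error(standardize(metabolite_table(vc, data.frame(year = rep("2006", 3)))),
               "'FLAT' has zero variance")
})

test_that("group means of standardized data behave and recover a planted shift", {
  # sign symmetry: flipping all values flips every group mean
  spec <- flat_spec(6, 12, 12, seed = 11)
  tab <- standardize(simulate_table(spec))
  gm <- group_standardized_means(tab, "genotype")
  flipped <- tab
  flipped$values <- -flipped$values
  gm2 <- group_standardized_means(flipped, "genotype")
  expect_equal(gm2$mean, -gm$mean, tolerance = 1e-12)

  # count-weighted means over all levels cancel exactly per group
  w <- tapply(gm$mean * gm$n_values, gm$group, sum)
  expect_equal(as.numeric(w), rep(0, length(w)), tolerance = 1e-9)

  # planted +0.5 SD shift in amino acids under HV is recovered at the
  # analytically expected size after re-standardization
  spec2 <- synthetic_spec(seed = 21, missing_rate = 0,
                          design = default_design(replicates = 16L))
  tab2 <- simulate_table(spec2)
  aa <- tab2$registry$code[tab2$registry$group == "amino acid"]
  hv <- tab2$factors$mulch == "HV"
  shift <- 0.5 * 20  # 0.5 concentration SDs
  tab2$values[hv, aa] <- tab2$values[hv, aa] + shift
  gm3 <- group_standardized_means(standardize(tab2), "mulch")
  got <- gm3$mean[gm3$level == "HV" & gm3$group == "amino acid"]
  f <- mean(hv)
  expected <- (1 - f) * shift / sqrt(20^2 + f * (1 - f) * shift^2)
  expect_lt(abs(got - expected), 0.09)  # ~3 Monte-Carlo SEs at this size
})

test_that("built-in partitions assign study samples as documented", {
  parts <- builtin_partitions()
  fac <- data.frame(genotype = c("5", "20", "8", "2"),
                    mulch = c("HV", "BP", "RY", "BS"),
                    stringsAsFactors = FALSE)
  expect_equal(parts$polyamine$assign(fac), c("A", "B", "B", "A"))
  expect_equal(parts$mejas$assign(fac), c("B", "A", "B", "B"))
  expect_equal(parts$mulch$assign(fac), c("B", "A", "B", "A"))
  # genotype 20 sits in polyamine B and mejas A simultaneously
  expect_equal(parts$polyamine$assign(fac)[2], "B")
  expect_equal(parts$mejas$assign(fac)[2], "A")

  tab <- simulate_table(synthetic_spec(seed = 5))
  side <- apply_partition(tab, parts$mulch_within_highPA)
  ry_high <- tab$factors$mulch == "RY" & tab$factors$genotype %in% c("4", "8", "10", "20")
  expect_true(all(is.na(side[ry_high])))
  low <- tab$factors$genotype %in% c("2", "5", "12")
  expect_true(all(is.na(side[low])))

  # subsets are disjoint and reproducible by direct factor filtering
  for (nm in names(parts)) {
    s <- apply_partition(tab, parts[[nm]])
    expect_true(all(s %in% c("A", "B", NA_character_)))
    expect_gt(sum(s == "A", na.rm = TRUE), 0)
    expect_gt(sum(s == "B", na.rm = TRUE), 0)
  }
  s <- apply_partition(tab, parts$polyamine)
  expect_equal(unname(s == "A"), tab$factors$genotype %in% c("2", "5", "12"))
})
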