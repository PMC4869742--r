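# Shared in-code fixtures: tiny tables, hand-built correlation sets, and a
# small two-group design for recovery simulations.

# A correlation_set built directly from per-pair values (codes sorted within
# each pair), mirroring what pairwise_correlations() produces.
make_cor_set <- function(df, label = "set", n_min = 4L) {
  swap <- df$metabolite_i > df$metabolite_j
  tmp <- df$metabolite_i[swap]
  df$metabolite_i[swap] <- df$metabolite_j[swap]
  df$metabolite_j[swap] <- tmp
  if (is.null(df$n)) df$n <- NA_integer_
  df$flag <- ifelse(is.na(df$r), "zero_variance",
                    ifelse(abs(df$r) >= 1 - 1e-12, "saturated", "ok"))
  df$z <- ifelse(df$flag == "ok", atanh(df$r), NA_real_)
  df <- df[order(df$metabolite_i, df$metabolite_j, method = "radix"),
           c("metabolite_i", "metabolite_j", "r", "n", "z", "flag")]
  rownames(df) <- NULL
  structure(df, class = c("correlation_set", "data.frame"),
            label = label, n_min = n_min,
            roster = sort(unique(c(df$metabolite_i, df$metabolite_j)),
                          method = "radix"),
            n_samples = NA_integer_)
}

# Six correlation sets holding given z-vectors for a single pair.
sets_for_pair_z <- function(z_values, i = "CIT", j = "MAL") {
  lapply(seq_along(z_values), function(k) {
    make_cor_set(data.frame(metabolite_i = i, metabolite_j = j,
                            r = tanh(z_values[k]), n = 50L,
                            stringsAsFactors = FALSE),
                 label = paste0("subset", k))
  })
}

# Flat design: n_a samples of a low-polyamine genotype and n_b of a
# high-polyamine genotype, so the "polyamine" partition splits them n_a/n_b.
two_group_design <- function(n_a, n_b) {
  data.frame(
    genotype = rep(c("5", "8"), c(n_a, n_b)),
    mulch = "BP", year = "2007", stage = "red",
    replicate = as.character(seq_len(n_a + n_b)),
    stringsAsFactors = FALSE
  )
}

# Spec over generic metabolite codes M01..Mp with independent base structure.
flat_spec <- function(p, n_a, n_b, changes = list(), seed = 1L,
                      missing_rate = 0, base = NULL) {
  codes <- sprintf("M%02d", seq_len(p))
  if (is.null(base)) base <- diag(p)
  synthetic_spec(metabolites = codes, design = two_group_design(n_a, n_b),
                 base_correlation = base, changes = changes,
                 missing_rate = missing_rate, seed = seed)
}

# Tiny literal table: 6 samples x 4 metabolites, one missing cell.
toy_table_text <- function(na_cell = "NA") {
  c("sample_id,genotype,mulch,year,stage,replicate,CIT,MAL,SUCR,B",
    "s1,5,BP,2006,red,1,1.0,2.0,3.0,4.0",
    paste0("s2,5,HV,2006,red,2,1.5,", na_cell, ",3.5,4.5"),
    "s3,8,BP,2006,pink,1,2.0,2.5,4.0,5.0",
    "s4,8,HV,2006,pink,2,2.5,3.0,4.5,5.5",
    "s5,12,RY,2007,red,1,3.0,3.5,5.0,6.0",
    "s6,20,BS,2007,red,2,3.5,4.0,5.5,6.5")
}

write_toy_table <- function(path = tempfile(fileext = ".csv"), ...) {
  writeLines(toy_table_text(...), path)
  path
}
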