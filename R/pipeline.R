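#' Default pipeline configuration
#'
#' @return Nested list with the documented defaults; user configs (YAML)
#'   are merged over it key by key.
#' @export
default_config <- function() {
  list(
    io = list(delimiter = NULL),
    columns = list(sample_id = "sample_id", factors = NULL),
    metabolites = list(exclude = "B"),
    analysis = list(alpha = 0.05, multiplicity = "none",
                    partitions = c("polyamine", "mejas", "mulch"),
                    n_min = 4L, swap_colors = FALSE,
                    standardize = FALSE),
    stability = list(threshold = 0.19, min_subsets = 3L)
  )
}

.merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]])) {
      base[[k]] <- .merge_config(base[[k]], user[[k]])
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Load a pipeline configuration
#'
#' Reads a YAML config file and merges it over
#' \code{\link{default_config}}. The file must name the input table under
#' \code{input: table:}.
#'
#' @param path YAML file, or a list already in config shape.
#' @return Validated config list.
#' @export
load_config <- function(path) {
  user <- if (is.list(path)) path else yaml::read_yaml(path)
  cfg <- .merge_config(default_config(), user)
  if (is.null(cfg$input$table)) stop("config must set input: table: <path>")
  if (!cfg$analysis$multiplicity %in% c("none", "bh")) {
    stop("analysis: multiplicity must be 'none' or 'bh'")
  }
  bad <- setdiff(cfg$analysis$partitions, names(builtin_partitions()))
  if (length(bad) > 0) stop("unknown partition(s): ", paste(bad, collapse = ", "))
  cfg
}

.log <- function(level, stage, fmt, ..., min_level = "info") {
  levels <- c(debug = 1L, info = 2L, warn = 3L)
  if (levels[[level]] >= levels[[min_level]]) {
    message(sprintf("[%s] [%s] %s", level, stage, sprintf(fmt, ...)))
  }
}

#' Run the full differential-correlation pipeline
#'
#' Load and validate the table, compute per-subset pairwise correlations,
#' build one differential network per configured partition, and score
#' cross-partition stability; write every artifact under \code{out_dir}
#' and a JSON run manifest recording config/table hashes, package version,
#' and per-output md5 sums. Re-running with identical inputs reproduces
#' byte-identical outputs (the manifest differs only in its timestamp).
#'
#' @param config Path to a YAML config, or a config list (see
#'   \code{\link{load_config}}).
#' @param out_dir Output directory (created if needed); inputs are never
#'   modified.
#' @param log_level \code{"debug"}, \code{"info"} or \code{"warn"}.
#' @return The manifest, invisibly; also written as
#'   \code{manifest.json} in \code{out_dir}.
#' @export
run_pipeline <- function(config, out_dir, log_level = "info") {
  cfg <- load_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  schema <- list(delimiter = cfg$io$delimiter,
                 sample_id = cfg$columns$sample_id,
                 factors = cfg$columns$factors,
                 exclude = cfg$metabolites$exclude)
  table <- read_metabolite_table(cfg$input$table, schema,
                                 quiet = log_level == "warn")
  if (isTRUE(cfg$analysis$standardize)) table <- standardize(table)
  parts <- builtin_partitions()[cfg$analysis$partitions]
  outputs <- character()

  sets <- list()
  for (sc in parts) {
    cs <- partition_correlations(table, sc, n_min = cfg$analysis$n_min)
    sets[[sc$a_label]] <- cs$A
    sets[[sc$b_label]] <- cs$B
    .log("info", "correlate", "%s: %d/%d samples, %d pairs", sc$name,
         attr(cs$A, "n_samples"), attr(cs$B, "n_samples"), nrow(cs$A),
         min_level = log_level)
  }
  cor_path <- file.path(out_dir, "correlations.csv")
  write_correlation_sets(sets, cor_path)
  outputs["correlations"] <- cor_path

  edge_files <- character()
  for (sc in parts) {
    net <- build_differential_network(
      sets[[sc$a_label]], sets[[sc$b_label]],
      alpha = cfg$analysis$alpha, multiplicity = cfg$analysis$multiplicity,
      partition = sc$name, swap_colors = cfg$analysis$swap_colors)
    f <- file.path(out_dir, paste0("diffnet_", sc$name, ".csv"))
    export_network(net, f, "edge-csv")
    outputs[paste0("diffnet_", sc$name)] <- f
    edge_files[sc$name] <- f
    .log("info", "diffnet", "%s: %d tested, %d significant", sc$name,
         nrow(net$tests), nrow(net$edges), min_level = log_level)
  }

  stab_sets <- sets[unlist(lapply(parts, function(p) c(p$a_label, p$b_label)))]
  map <- build_stability_map(stab_sets,
                             min_subsets = cfg$stability$min_subsets,
                             threshold = cfg$stability$threshold)
  stab_path <- file.path(out_dir, "stability_pairs.csv")
  utils::write.table(map$pairs, stab_path, sep = ",", quote = FALSE,
                     row.names = FALSE, na = "NA")
  outputs["stability_pairs"] <- stab_path
  counts_path <- file.path(out_dir, "stability_counts.csv")
  utils::write.table(stable_association_counts(map), counts_path, sep = ",",
                     quote = FALSE, row.names = FALSE)
  outputs["stability_counts"] <- counts_path
  hm <- heatmap_matrix(map)
  hm_path <- file.path(out_dir, "stability_heatmap.csv")
  write_heatmap_matrix(hm, hm_path, file.path(out_dir, "stability_bins.csv"))
  outputs["stability_heatmap"] <- hm_path
  outputs["stability_bins"] <- file.path(out_dir, "stability_bins.csv")
  .log("info", "stability", "%d pairs scored, %d dropped", nrow(map$pairs),
       nrow(map$dropped), min_level = log_level)

  manifest <- list(
    package_version = as.character(utils::packageVersion("dcornet")),
    config_hash = if (is.character(config)) unname(tools::md5sum(config))
                  else NA_character_,
    table = cfg$input$table,
    table_hash = unname(tools::md5sum(cfg$input$table)),
    partitions = vapply(parts, `[[`, "", "name"),
    alpha = cfg$analysis$alpha,
    multiplicity = cfg$analysis$multiplicity,
    outputs = as.list(outputs),
    output_hashes = as.list(vapply(outputs, function(f)
      unname(tools::md5sum(f)), character(1))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Summarize a pipeline run
#'
#' Reads a manifest (or takes one returned by \code{\link{run_pipeline}})
#' and prints per-partition counts of tested and significant edges, the
#' extreme correlation changes, and the most/least stable pairs.
#'
#' @param manifest Manifest list or path to \code{manifest.json}.
#' @param top Number of extreme stability pairs to show.
#' @return Character vector of report lines, invisibly (also printed).
#' @export
report <- function(manifest, top = 5L) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest)
  for (f in unlist(manifest$outputs)) {
    if (!file.exists(f)) stop("missing output file: ", f)
  }
  lines <- c(sprintf("dcornet run (package %s, alpha = %s, multiplicity = %s)",
                     manifest$package_version, manifest$alpha,
                     manifest$multiplicity))
  for (pname in unlist(manifest$partitions)) {
    f <- manifest$outputs[[paste0("diffnet_", pname)]]
    e <- utils::read.csv(f, stringsAsFactors = FALSE)
    line <- sprintf("  %s: %d significant edge(s)", pname, nrow(e))
    if (nrow(e) > 0) {
      line <- paste0(line, sprintf("; delta_r in [%.3f, %.3f]",
                                   min(e$delta_r), max(e$delta_r)))
    }
    lines <- c(lines, line)
  }
  stab <- utils::read.csv(manifest$outputs$stability_pairs,
                          stringsAsFactors = FALSE)
  if (nrow(stab) > 0) {
    stab <- stab[order(stab$sd_z), ]
    fmt_pair <- function(d) sprintf("%s~%s (sd_z = %.3f)", d$metabolite_i,
                                    d$metabolite_j, d$sd_z)
    lines <- c(lines,
               sprintf("  most stable: %s",
                       paste(fmt_pair(utils::head(stab, top)), collapse = ", ")),
               sprintf("  least stable: %s",
                       paste(fmt_pair(utils::tail(stab, top)), collapse = ", ")))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
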