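#' Construct a metabolite table
#'
#' The package's single input container: a samples-by-metabolites matrix of
#' non-negative concentrations with per-sample design factors and a
#' metabolite registry assigning each code to a chemical group.
#'
#' @param values Numeric matrix, one row per sample and one column per
#'   metabolite; row names are sample ids, column names metabolite codes.
#'   Missing entries (\code{NA}) are permitted.
#' @param factors Data frame of categorical design factors, one row per
#'   sample, same order as \code{values}.
#' @param registry Metabolite registry as returned by
#'   \code{\link{resolve_registry}}; defaults to resolving the column names
#'   against the built-in roster.
#' @param factor_registry Named list of admissible levels per factor (only
#'   factors named here are checked); defaults to
#'   \code{\link{default_factor_registry}}.
#' @param standardized Logical flag recording whether columns have been
#'   standardized.
#' @return An object of class \code{metabolite_table}.
#' @export
metabolite_table <- function(values, factors,
                             registry = resolve_registry(colnames(values)),
                             factor_registry = default_factor_registry(),
                             standardized = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values))) stop("values must have metabolite column names")
  if (is.null(rownames(values))) stop("values must have sample-id row names")
  if (anyDuplicated(rownames(values))) {
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate metabolite codes: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  }
  factors <- as.data.frame(factors, stringsAsFactors = FALSE)
  if (nrow(factors) != nrow(values)) {
    stop("every sample needs a complete factor record (",
         nrow(values), " value rows vs ", nrow(factors), " factor rows)")
  }
  factors[] <- lapply(factors, as.character)
  rownames(factors) <- rownames(values)
  for (f in intersect(names(factor_registry), names(factors))) {
    bad <- setdiff(unique(factors[[f]][!is.na(factors[[f]])]),
                   factor_registry[[f]])
    if (length(bad) > 0) {
      stop("unknown ", f, " level(s): ", paste(bad, collapse = ", "),
           " (declared levels: ", paste(factor_registry[[f]], collapse = ", "),
           ")")
    }
  }
  if (!setequal(registry$code, colnames(values))) {
    stop("registry codes must match the table's metabolite columns exactly")
  }
  structure(
    list(values = values, factors = factors, registry = registry,
         factor_registry = factor_registry, standardized = standardized),
    class = "metabolite_table"
  )
}

#' @export
print.metabolite_table <- function(x, ...) {
  cat("<metabolite_table> ", nrow(x$values), " samples x ",
      ncol(x$values), " metabolites\n", sep = "")
  cat("  factors: ", paste(names(x$factors), collapse = ", "), "\n", sep = "")
  cat("  missing cells: ", sum(is.na(x$values)),
      if (isTRUE(x$standardized)) "  (standardized)" else "", "\n", sep = "")
  invisible(x)
}

#' @export
dim.metabolite_table <- function(x) dim(x$values)

#' Codes of metabolites retained for pairwise analysis
#'
#' All metabolite codes minus those flagged excluded in the registry (the
#' uncharacterized "B" by default), in alphabetical order — the canonical
#' roster used by every correlation stage.
#'
#' @param table A \code{metabolite_table}.
#' @return Character vector of retained codes, sorted.
#' @export
retained_metabolites <- function(table) {
  stopifnot(inherits(table, "metabolite_table"))
  sort(table$registry$code[!table$registry$excluded], method = "radix")
}

.missing_tokens <- c("", "NA", "NaN")

#' Read a wide metabolite table from delimited text
#'
#' Parses a wide table (one row per fruit sample, one column per metabolite)
#' with a header row, validates factor levels against the registry, converts
#' blank/"NA"/"NaN" cells to missing, and reports load counts. Any other
#' non-numeric concentration cell is an error naming the offending
#' row and column.
#'
#' @param path Path to a comma- or tab-delimited text file.
#' @param schema List configuring the parse:
#'   \describe{
#'     \item{delimiter}{\code{","} or \code{"\t"}; \code{NULL} auto-detects
#'       from the header row.}
#'     \item{sample_id}{Name of the sample-id column (default
#'       \code{"sample_id"}).}
#'     \item{factors}{Character vector of factor column names; default is
#'       whichever of genotype, mulch, year, stage, replicate are present.}
#'     \item{metabolites}{Metabolite column names, or \code{"all"} for every
#'       remaining column (default).}
#'     \item{exclude}{Metabolite codes flagged excluded (default
#'       \code{"B"}).}
#'     \item{registry}{Optional registry override data frame.}
#'     \item{factor_registry}{Optional named list of admissible levels.}
#'   }
#' @param quiet Suppress the load report message.
#' @return A validated \code{\link{metabolite_table}}.
#' @export
read_metabolite_table <- function(path, schema = list(), quiet = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  delim <- schema$delimiter
  header <- readLines(path, n = 1L)
  if (is.null(delim)) {
    delim <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
                 lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  }
  raw <- utils::read.table(path, sep = delim, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  id_col <- if (is.null(schema$sample_id)) "sample_id" else schema$sample_id
  if (!id_col %in% names(raw)) stop("sample-id column '", id_col, "' not found")
  factor_cols <- schema$factors
  if (is.null(factor_cols)) {
    factor_cols <- intersect(c("genotype", "mulch", "year", "stage", "replicate"),
                             names(raw))
  }
  missing_fac <- setdiff(factor_cols, names(raw))
  if (length(missing_fac) > 0) {
    stop("factor column(s) not found: ", paste(missing_fac, collapse = ", "))
  }
  met_cols <- schema$metabolites
  if (is.null(met_cols) || identical(met_cols, "all")) {
    met_cols <- names(raw)[!names(raw) %in% c(id_col, factor_cols)]
  }
  if (anyDuplicated(met_cols)) {
    stop("duplicate metabolite column name(s): ",
         paste(unique(met_cols[duplicated(met_cols)]), collapse = ", "))
  }
  ids <- raw[[id_col]]
  if (anyDuplicated(ids)) {
    stop("duplicate sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(met_cols),
                 dimnames = list(ids, met_cols))
  for (m in met_cols) {
    cell <- trimws(raw[[m]])
    is_missing <- cell %in% .missing_tokens
    num <- suppressWarnings(as.numeric(cell))
    bad <- !is_missing & is.na(num)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop("non-numeric concentration '", cell[i], "' at sample '", ids[i],
           "', metabolite '", m, "'")
    }
    vals[, m] <- ifelse(is_missing, NA_real_, num)
  }
  exclude <- if (is.null(schema$exclude)) "B" else schema$exclude
  freg <- if (is.null(schema$factor_registry)) default_factor_registry() else
    schema$factor_registry
  tab <- metabolite_table(
    vals, raw[factor_cols],
    registry = resolve_registry(met_cols, exclude = exclude,
                                registry = schema$registry),
    factor_registry = freg
  )
  if (!quiet) {
    message(sprintf("[load] %d samples, %d metabolites, %d missing cell(s)",
                    nrow(vals), ncol(vals), sum(is.na(vals))))
  }
  tab
}

#' Write a metabolite table to delimited text
#'
#' Inverse of \code{\link{read_metabolite_table}}: sample-id column, factor
#' columns, then metabolite columns; missing cells written as \code{NA}.
#'
#' @param table A \code{metabolite_table}.
#' @param path Output path.
#' @param delimiter Field separator (default comma).
#' @return \code{path}, invisibly.
#' @export
write_metabolite_table <- function(table, path, delimiter = ",") {
  stopifnot(inherits(table, "metabolite_table"))
  out <- data.frame(sample_id = rownames(table$values),
                    table$factors,
                    as.data.frame(table$values, check.names = FALSE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Standardize each metabolite to mean 0, SD 1
#'
#' Column-wise (x - mean) / SD over non-missing entries, with the sample SD
#' (n - 1 denominator), so that every metabolite carries equal weight in
#' group summaries. Missing entries stay missing. Idempotent up to floating
#' point.
#'
#' @param table A \code{metabolite_table}.
#' @return A \code{metabolite_table} with \code{standardized = TRUE}.
#' @export
#' @examples
#' tab <- simulate_table(synthetic_spec(seed = 1))
#' std <- standardize(tab)
#' colMeans(std$values, na.rm = TRUE)  # all ~0
standardize <- function(table) {
  stopifnot(inherits(table, "metabolite_table"))
  v <- table$values
  for (j in seq_len(ncol(v))) {
    x <- v[, j]
    ok <- !is.na(x)
    if (sum(ok) < 2L) {
      stop("metabolite '", colnames(v)[j], "' has fewer than 2 observed values")
    }
    s <- stats::sd(x[ok])
    if (!is.finite(s) || s == 0) {
      stop("metabolite '", colnames(v)[j], "' has zero variance")
    }
    v[, j] <- (x - mean(x[ok])) / s
  }
  table$values <- v
  table$standardized <- TRUE
  table
}

#' Mean standardized value per factor level and chemical group
#'
#' Summarizes a standardized table the way grouped treatment-response bar
#' charts are built: for every level of a design factor and every chemical
#' group, the mean over all standardized values of the group's member
#' metabolites across the samples at that level.
#'
#' @param table A standardized \code{metabolite_table}.
#' @param factor_name Name of a factor column (e.g. \code{"mulch"}).
#' @return Data frame with columns \code{level}, \code{group}, \code{mean},
#'   \code{n_values}.
#' @export
group_standardized_means <- function(table, factor_name) {
  stopifnot(inherits(table, "metabolite_table"))
  if (!isTRUE(table$standardized)) {
    stop("table must be standardized first (see standardize())")
  }
  if (!factor_name %in% names(table$factors)) {
    stop("unknown factor: ", factor_name)
  }
  lev <- table$factors[[factor_name]]
  groups <- sort(unique(table$registry$group), method = "radix")
  out <- list()
  for (g in groups) {
    members <- table$registry$code[table$registry$group == g]
    if (length(members) == 0L) stop("empty metabolite group: ", g)
    sub <- table$values[, members, drop = FALSE]
    for (l in sort(unique(lev), method = "radix")) {
      x <- sub[lev == l, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        level = l, group = g,
        mean = mean(x, na.rm = TRUE),
        n_values = sum(!is.na(x)),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
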