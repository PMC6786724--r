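#' Construct and validate a genus abundance table
#'
#' A genus abundance table is a numeric matrix of relative abundances with
#' samples in rows and genera in columns. Each row is a composition: values
#' are non-negative fractions summing to 1 (within `tol`). This is the common
#' currency of taxon-panel scoring and the power simulation.
#'
#' @param values numeric matrix (samples x genera) of relative abundances.
#' @param sample_ids,genus_names optional identifier vectors; default to the
#'   dimnames of `values`.
#' @param normalize if `TRUE`, rows are divided by their sums before
#'   validation (rows summing to zero are an error either way). By default
#'   rows that do not already sum to 1 are rejected rather than silently
#'   rescaled.
#' @param tol tolerance on the per-row deviation from a unit sum.
#' @return a matrix of class `genus_table` with sample ids as rownames and
#'   genus names as colnames.
#' @export
genus_table <- function(values, sample_ids = rownames(values),
                        genus_names = colnames(values),
                        normalize = FALSE, tol = 1e-6) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop_fmt("abundance values must be numeric")
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(genus_names)) stop_fmt("genus names are required")
  sample_ids <- as.character(sample_ids)
  genus_names <- as.character(genus_names)
  if (length(sample_ids) != nrow(values))
    stop_fmt("length of sample ids (%d) != number of rows (%d)",
             length(sample_ids), nrow(values))
  if (length(genus_names) != ncol(values))
    stop_fmt("length of genus names (%d) != number of columns (%d)",
             length(genus_names), ncol(values))
  if (anyDuplicated(sample_ids))
    stop_fmt("duplicate sample ids: %s",
             paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(genus_names))
    stop_fmt("duplicate genus names: %s",
             paste(unique(genus_names[duplicated(genus_names)]), collapse = ", "))
  dimnames(values) <- list(sample_ids, genus_names)
  if (anyNA(values)) stop_fmt("abundance table contains missing values")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop_fmt("negative abundance at sample '%s', genus '%s'",
             sample_ids[bad[1]], genus_names[bad[2]])
  }
  rs <- rowSums(values)
  if (any(rs == 0))
    stop_fmt("sample(s) with all-zero abundance: %s",
             paste(sample_ids[rs == 0], collapse = ", "))
  if (normalize) {
    values <- values / rs
    rs <- rowSums(values)
  }
  off <- abs(rs - 1)
  if (any(off > tol))
    stop_fmt(paste0("row sums deviate from 1 beyond tolerance %g ",
                    "(worst: sample '%s', sum %.8f); pass normalize = TRUE ",
                    "to rescale"),
             tol, sample_ids[which.max(off)], rs[which.max(off)])
  structure(values, class = c("genus_table", class(values)))
}

#' @export
print.genus_table <- function(x, ...) {
  cat(sprintf("Genus abundance table: %d samples x %d genera\n",
              nrow(x), ncol(x)))
  cat(sprintf("  samples: %s%s\n",
              paste(utils::head(rownames(x), 5), collapse = ", "),
              if (nrow(x) > 5) ", ..." else ""))
  cat(sprintf("  genera:  %s%s\n",
              paste(utils::head(colnames(x), 5), collapse = ", "),
              if (ncol(x) > 5) ", ..." else ""))
  invisible(x)
}

#' Read a genus abundance table from TSV
#'
#' Expects a UTF-8 tab-delimited file with a header row of genus names and a
#' first column named `sample_id`. The body must be numeric; each row must be
#' a relative-abundance composition (see [genus_table()]).
#'
#' @param path file path.
#' @param normalize divide rows by their sums instead of rejecting rows that
#'   do not sum to 1.
#' @param tol row-sum tolerance.
#' @return a `genus_table`.
#' @export
read_abundance_table <- function(path, normalize = FALSE, tol = 1e-6) {
  df <- read_tsv_checked(path, id_col = "sample_id")
  m <- tsv_numeric_body(df, path)
  genus_table(m, normalize = normalize, tol = tol)
}

#' Write a genus abundance table to TSV
#'
#' Inverse of [read_abundance_table()]: values are written at full double
#' precision so a write-then-read round trip reproduces the table.
#'
#' @param table a `genus_table` (or numeric matrix with dimnames).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path) {
  write_matrix_tsv(unclass(table), path, id_col = "sample_id")
}

read_tsv_checked <- function(path, id_col) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          fileEncoding = "UTF-8")
  if (ncol(df) < 2) stop_fmt("%s: expected an id column plus data columns", path)
  if (names(df)[1] != id_col)
    stop_fmt("%s: first column must be '%s' (found '%s')",
             path, id_col, names(df)[1])
  df
}

# Convert the character body of a TSV data.frame to a numeric matrix with the
# first column as rownames; names the offending cell on failure.
tsv_numeric_body <- function(df, path) {
  ids <- df[[1]]
  body <- df[, -1, drop = FALSE]
  m <- matrix(NA_real_, nrow(body), ncol(body),
              dimnames = list(ids, names(body)))
  for (j in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) & !(body[[j]] %in% c("NA", "")))
    if (length(bad))
      stop_fmt("%s: cannot parse value '%s' (row '%s', column '%s') as numeric",
               path, body[[j]][bad[1]], ids[bad[1]], names(body)[j])
    m[, j] <- v
  }
  m
}

write_matrix_tsv <- function(m, path, id_col) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c(id_col, colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i], format_num(m[i, ])), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' Construct a feature-level table (ASV/OTU) with taxonomy
#'
#' @param values numeric matrix (samples x features) of counts or relative
#'   abundances.
#' @param taxonomy named character vector mapping every feature id to a
#'   lineage string (GreenGenes-style `k__...;g__Genus;s__...` or plain
#'   semicolon-delimited ranks). The genus field may be empty.
#' @param type `"counts"` (non-negative integers) or `"relabund"`.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values, taxonomy, type = c("counts", "relabund")) {
  type <- match.arg(type)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_fmt("feature table needs sample rownames and feature colnames")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop_fmt("duplicate sample or feature ids in feature table")
  if (anyNA(values) || any(values < 0))
    stop_fmt("feature values must be non-negative and non-missing")
  if (type == "counts" && any(values != round(values)))
    stop_fmt("count-typed feature table contains non-integer values")
  missing_tax <- setdiff(colnames(values), names(taxonomy))
  if (length(missing_tax))
    stop_fmt("missing taxonomy entry for feature(s): %s",
             paste(utils::head(missing_tax, 5), collapse = ", "))
  structure(list(values = values,
                 taxonomy = taxonomy[colnames(values)],
                 type = type),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table (%s): %d samples x %d features\n",
              x$type, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read a feature table and its taxonomy from TSV
#'
#' The feature TSV has a `sample_id` first column and one column per feature;
#' the taxonomy TSV has two columns, `feature_id` and `lineage`.
#'
#' @param counts_path path to the feature abundance TSV.
#' @param taxonomy_path path to the two-column taxonomy TSV.
#' @inheritParams feature_table
#' @return a `feature_table`.
#' @export
read_feature_table <- function(counts_path, taxonomy_path,
                               type = c("counts", "relabund")) {
  df <- read_tsv_checked(counts_path, id_col = "sample_id")
  m <- tsv_numeric_body(df, counts_path)
  tax <- utils::read.delim(taxonomy_path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           fileEncoding = "UTF-8")
  if (ncol(tax) < 2)
    stop_fmt("%s: expected columns feature_id, lineage", taxonomy_path)
  lineages <- stats::setNames(tax[[2]], tax[[1]])
  feature_table(m, lineages, type = match.arg(type))
}

#' Convert a count-typed feature table to relative abundances
#'
#' Divides each sample row by its total reads. Idempotent on tables already on
#' the relative-abundance scale.
#'
#' @param table a `feature_table`.
#' @return a `feature_table` of type `"relabund"` whose rows sum to 1.
#' @export
to_relative_abundance <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  totals <- rowSums(table$values)
  if (any(totals == 0))
    stop_fmt("sample(s) with zero total reads: %s",
             paste(rownames(table$values)[totals == 0], collapse = ", "))
  feature_table(table$values / totals, table$taxonomy, type = "relabund")
}

#' Extract the genus from a taxonomy lineage string
#'
#' Accepts GreenGenes-dialect lineages (`k__Bacteria;...;g__Roseburia;s__`)
#' and plain semicolon-delimited rank lists (genus = 6th token). Empty or
#' ambiguous genus fields (`g__`, `uncultured`, missing) yield `NA`.
#'
#' @param lineage character vector of lineage strings.
#' @return character vector of genus names, `NA` where unassigned.
#' @export
genus_from_lineage <- function(lineage) {
  vapply(as.character(lineage), function(s) {
    toks <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    g <- toks[startsWith(toks, "g__")]
    if (length(g)) {
      g <- sub("^g__", "", g[1])
    } else if (length(toks) >= 6) {
      g <- toks[6]
    } else {
      return(NA_character_)
    }
    g <- gsub("^\\[|\\]$", "", trimws(g))
    if (g == "" || tolower(g) == "uncultured") NA_character_ else g
  }, character(1), USE.NAMES = FALSE)
}

#' Collapse a feature table to genus level
#'
#' Sums the relative abundances of all features assigned to the same genus.
#' Features whose lineage has no usable genus are pooled into a reserved
#' `"unclassified"` column. Per-sample total abundance is conserved.
#'
#' @param table a relative-abundance-typed `feature_table`.
#' @param tol row-sum tolerance passed to [genus_table()].
#' @return a `genus_table` with one column per distinct genus.
#' @export
collapse_to_genus <- function(table, tol = 1e-6) {
  stopifnot(inherits(table, "feature_table"))
  if (table$type != "relabund")
    stop_fmt("collapse_to_genus expects relative abundances; call to_relative_abundance() first")
  genus <- genus_from_lineage(table$taxonomy)
  genus[is.na(genus)] <- "unclassified"
  levels <- unique(genus)
  out <- matrix(0, nrow(table$values), length(levels),
                dimnames = list(rownames(table$values), levels))
  for (g in levels) {
    out[, g] <- rowSums(table$values[, genus == g, drop = FALSE])
  }
  genus_table(out, tol = tol)
}

#' Read sample metadata from TSV
#'
#' Columns: `sample_id`, `role` (donor/patient), `study`, `response`
#' (response/no_response or NA), `linked_donor` (for patients, the donor
#' sample used for their FMT; NA otherwise).
#'
#' @param path TSV file path.
#' @return a validated data.frame of class `sample_metadata`.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          fileEncoding = "UTF-8",
                          na.strings = c("NA", ""))
  sample_metadata(df)
}

#' Validate sample metadata
#'
#' @param df data.frame with columns `sample_id`, `role`, `study`,
#'   `response`, `linked_donor`.
#' @return `df` with class `sample_metadata`.
#' @export
sample_metadata <- function(df) {
  need <- c("sample_id", "role", "study", "response", "linked_donor")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_fmt("metadata missing column(s): %s", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[need]
  if (anyDuplicated(df$sample_id))
    stop_fmt("duplicate sample ids in metadata")
  if (!all(df$role %in% c("donor", "patient")))
    stop_fmt("role must be 'donor' or 'patient'")
  ok_resp <- is.na(df$response) | df$response %in% c("response", "no_response")
  if (!all(ok_resp))
    stop_fmt("response must be 'response', 'no_response' or NA")
  links <- df$linked_donor[!is.na(df$linked_donor)]
  donors <- df$sample_id[df$role == "donor"]
  bad <- setdiff(links, donors)
  if (length(bad))
    stop_fmt("linked_donor id(s) not present as donor samples: %s",
             paste(unique(bad), collapse = ", "))
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Write sample metadata to TSV
#' @param meta a `sample_metadata` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  cols <- c("sample_id", "role", "study", "response", "linked_donor")
  writeLines(paste(cols, collapse = "\t"), con)
  for (i in seq_len(nrow(meta))) {
    row <- vapply(cols, function(cl) {
      v <- meta[[cl]][i]
      if (is.na(v)) "NA" else as.character(v)
    }, character(1))
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(path)
}
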