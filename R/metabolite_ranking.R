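#' Construct and validate a donor metabolome table
#'
#' Long-format table of stool metabolite abundances: one row per (donor,
#' timepoint), one column per metabolite, in platform units (non-negative).
#' Metabolite columns may carry a chromatography-mode suffix of the form
#' `"metabolite|mode"` (e.g. `"lithocholate|C18neg"`); see
#' [resolve_metabolite_modes()].
#'
#' @param df data.frame with columns `donor_id`, `timepoint`, then metabolite
#'   columns.
#' @return `df` with class `donor_metabolome`.
#' @export
donor_metabolome <- function(df) {
  df <- as.data.frame(df, check.names = FALSE)
  if (!all(c("donor_id", "timepoint") %in% names(df)[1:2]))
    stop_fmt("first two columns must be donor_id, timepoint")
  mets <- setdiff(names(df), c("donor_id", "timepoint"))
  if (length(mets) == 0) stop_fmt("no metabolite columns found")
  key <- paste(df$donor_id, df$timepoint)
  if (anyDuplicated(key))
    stop_fmt("duplicate (donor, timepoint) row(s): %s",
             paste(unique(key[duplicated(key)]), collapse = ", "))
  for (m in mets) {
    v <- df[[m]]
    if (!is.numeric(v)) stop_fmt("metabolite column '%s' is not numeric", m)
    if (any(v < 0, na.rm = TRUE))
      stop_fmt("negative abundance in metabolite '%s'", m)
  }
  class(df) <- c("donor_metabolome", "data.frame")
  df
}

#' Read a donor metabolome table from TSV
#'
#' @param path TSV with columns `donor_id`, `timepoint`, then metabolite
#'   columns (mode suffixes like `"lithocholate|C18neg"` allowed).
#' @return a `donor_metabolome` data.frame.
#' @export
read_metabolome <- function(path) {
  df <- read_tsv_checked(path, id_col = "donor_id")
  if (names(df)[2] != "timepoint")
    stop_fmt("%s: second column must be 'timepoint'", path)
  out <- data.frame(donor_id = df[[1]],
                    timepoint = suppressWarnings(as.numeric(df[[2]])),
                    check.names = FALSE)
  for (j in seq.int(3, ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !(df[[j]] %in% c("NA", "")))
    if (length(bad))
      stop_fmt("%s: cannot parse value '%s' (row %d, column '%s') as numeric",
               path, df[[j]][bad[1]], bad[1], names(df)[j])
    out[[names(df)[j]]] <- v
  }
  donor_metabolome(out)
}

#' Write a donor metabolome table to TSV
#' @param table a `donor_metabolome`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metabolome <- function(table, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(table), collapse = "\t"), con)
  mets <- setdiff(names(table), c("donor_id", "timepoint"))
  for (i in seq_len(nrow(table))) {
    writeLines(paste(c(table$donor_id[i], format_num(table$timepoint[i]),
                       format_num(unlist(table[i, mets]))), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' Resolve multi-mode metabolite columns
#'
#' When a metabolite was measured in several chromatography modes the table
#' carries columns `"name|mode"`. For each base metabolite this keeps exactly
#' one column: a bare (unsuffixed) column wins; otherwise the first mode in
#' `mode_preference` that is present; otherwise the alphabetically first
#' mode. The kept column is renamed to the bare metabolite name.
#'
#' @param table a `donor_metabolome`.
#' @param mode_preference character vector of mode labels in preference
#'   order, or a named list mapping metabolite names to per-metabolite
#'   preference vectors.
#' @return a `donor_metabolome` with one column per metabolite.
#' @export
resolve_metabolite_modes <- function(table,
                                     mode_preference = c("C18neg", "HILICneg")) {
  mets <- setdiff(names(table), c("donor_id", "timepoint"))
  base <- sub("\\|.*$", "", mets)
  mode <- ifelse(grepl("|", mets, fixed = TRUE), sub("^[^|]*\\|", "", mets), "")
  keep <- character(0)
  for (b in unique(base)) {
    cand <- mets[base == b]
    cand_mode <- mode[base == b]
    pref <- if (is.list(mode_preference)) {
      mode_preference[[b]] %||% character(0)
    } else mode_preference
    pick <- if (any(cand_mode == "")) {
      cand[cand_mode == ""][1]
    } else {
      hit <- pref[pref %in% cand_mode]
      if (length(hit)) cand[cand_mode == hit[1]] else cand[order(cand_mode)][1]
    }
    keep[b] <- pick
  }
  out <- table[, c("donor_id", "timepoint", unname(keep)), drop = FALSE]
  names(out) <- c("donor_id", "timepoint", names(keep))
  donor_metabolome(out)
}

#' Per-donor mean metabolite profile
#'
#' For donors with multiple sampled timepoints, takes the arithmetic mean of
#' each metabolite across that donor's timepoints; missing values are
#' excluded from that metabolite's mean.
#'
#' @param table a `donor_metabolome`.
#' @param required metabolites that must have at least one non-missing value
#'   per donor; a donor with all values missing for a required metabolite is
#'   an error naming both.
#' @return numeric matrix, donors x metabolites, rownames = donor ids.
#' @export
donor_mean_profile <- function(table, required = character(0)) {
  stopifnot(inherits(table, "donor_metabolome"))
  mets <- setdiff(names(table), c("donor_id", "timepoint"))
  donors <- unique(table$donor_id)
  prof <- matrix(NA_real_, length(donors), length(mets),
                 dimnames = list(donors, mets))
  for (d in donors) {
    sub <- table[table$donor_id == d, mets, drop = FALSE]
    prof[d, ] <- vapply(sub, function(v) {
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
  }
  for (m in intersect(required, mets)) {
    bad <- rownames(prof)[is.na(prof[, m])]
    if (length(bad))
      stop_fmt("donor '%s' has no non-missing values for required metabolite '%s'",
               bad[1], m)
  }
  miss <- setdiff(required, mets)
  if (length(miss))
    stop_fmt("required metabolite(s) absent from table: %s",
             paste(miss, collapse = ", "))
  prof
}

#' Per-donor SCFA score
#'
#' Arithmetic mean of the three stool short-chain fatty acids (butyrate,
#' isovalerate, propionate), in raw platform units by default. Because
#' platform units can differ in scale across metabolites, a per-metabolite
#' z-score variant is available behind `standardize = TRUE`.
#'
#' @param profile donors x metabolites matrix from [donor_mean_profile()].
#' @param scfas the SCFA column names.
#' @param standardize z-score each SCFA across donors before averaging.
#' @return named numeric vector of per-donor scores.
#' @export
scfa_score <- function(profile,
                       scfas = c("butyrate", "isovalerate", "propionate"),
                       standardize = FALSE) {
  miss <- setdiff(scfas, colnames(profile))
  if (length(miss))
    stop_fmt("SCFA(s) missing from profile: %s", paste(miss, collapse = ", "))
  m <- profile[, scfas, drop = FALSE]
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop_fmt("missing SCFA value: donor '%s', metabolite '%s'",
             rownames(m)[bad[1]], scfas[bad[2]])
  }
  if (standardize) m <- scale(m)
  stats::setNames(rowMeans(m), rownames(profile))
}

#' Bile-acid panel: primary vs. secondary
#'
#' The major primary bile acids, cholate (C) and chenodeoxycholate (CDC), are
#' host-made; the secondary bile acids deoxycholate (DC) and lithocholate
#' (LC) are their microbial conversion products.
#'
#' @param primary,secondary metabolite names of each class.
#' @return list of class `bile_acid_panel`.
#' @export
bile_acid_panel <- function(primary = c("cholate", "chenodeoxycholate"),
                            secondary = c("deoxycholate", "lithocholate")) {
  if (length(primary) == 0 || length(secondary) == 0)
    stop_fmt("both bile-acid classes must be non-empty")
  if (length(intersect(primary, secondary)))
    stop_fmt("primary and secondary bile-acid sets must be disjoint")
  structure(list(primary = primary, secondary = secondary),
            class = "bile_acid_panel")
}

#' Per-donor bile-acid conversion ratio
#'
#' The community's capacity to convert primary to secondary bile acids,
#' approximated as (lithocholate + deoxycholate) / (chenodeoxycholate +
#' cholate). A zero denominator with a positive numerator is reported as
#' `Inf` and flagged (attribute `"infinite"`); 0/0 is an error naming the
#' donor.
#'
#' @param profile donors x metabolites matrix from [donor_mean_profile()].
#' @param panel a [bile_acid_panel()].
#' @return named numeric vector of ratios with a logical attribute
#'   `"infinite"` marking donors with a zero denominator.
#' @export
bile_conversion_ratio <- function(profile, panel = bile_acid_panel()) {
  stopifnot(inherits(panel, "bile_acid_panel"))
  need <- c(panel$primary, panel$secondary)
  miss <- setdiff(need, colnames(profile))
  if (length(miss))
    stop_fmt("bile acid(s) missing from profile: %s",
             paste(miss, collapse = ", "))
  m <- profile[, need, drop = FALSE]
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop_fmt("missing bile-acid value: donor '%s', metabolite '%s'",
             rownames(m)[bad[1]], need[bad[2]])
  }
  num <- rowSums(m[, panel$secondary, drop = FALSE])
  den <- rowSums(m[, panel$primary, drop = FALSE])
  zz <- den == 0 & num == 0
  if (any(zz))
    stop_fmt("0/0 bile-acid conversion ratio for donor '%s'",
             rownames(m)[zz][1])
  ratio <- ifelse(den == 0, Inf, num / den)
  structure(stats::setNames(ratio, rownames(profile)),
            infinite = stats::setNames(den == 0, rownames(profile)))
}

#' Rank donors on SCFA score and bile-acid conversion and select the top
#' quantile of both
#'
#' Donors are ranked descending (rank 1 = best) separately on SCFA score and
#' conversion ratio; exact ties are broken by donor id in lexicographic
#' order. A donor is selected when both ranks fall within the top-`q`
#' cutoff `ceiling(q * n)`.
#'
#' @param scfa named numeric vector of per-donor SCFA scores.
#' @param conversion named numeric vector of per-donor conversion ratios (the
#'   same donors).
#' @param q top-quantile fraction in (0, 1]; default 0.25 (top quartile).
#' @return data.frame of class `donor_ranking`: `donor_id`, `scfa_score`,
#'   `conversion_ratio`, `scfa_rank`, `conversion_rank`, `selected`, ordered
#'   by the sum of ranks; the cutoff is attached as attribute `"cutoff"`.
#' @export
rank_and_select <- function(scfa, conversion, q = 0.25) {
  if (length(scfa) < 2) stop_fmt("need >= 2 donors to rank")
  if (q <= 0 || q > 1) stop_fmt("q must be in (0, 1]")
  if (!setequal(names(scfa), names(conversion)))
    stop_fmt("scfa and conversion vectors must cover the same donors")
  donors <- sort(names(scfa))
  scfa <- scfa[donors]
  conversion <- conversion[donors]
  rank_desc <- function(x) {
    r <- integer(length(x))
    r[order(-x, donors)] <- seq_along(x)
    r
  }
  scfa_rank <- rank_desc(scfa)
  conv_rank <- rank_desc(as.numeric(conversion))
  cutoff <- ceiling(q * length(donors))
  out <- data.frame(donor_id = donors,
                    scfa_score = as.numeric(scfa),
                    conversion_ratio = as.numeric(conversion),
                    scfa_rank = scfa_rank,
                    conversion_rank = conv_rank,
                    selected = scfa_rank <= cutoff & conv_rank <= cutoff,
                    stringsAsFactors = FALSE)
  out <- out[order(out$scfa_rank + out$conversion_rank, out$donor_id), ]
  rownames(out) <- NULL
  structure(out, cutoff = cutoff, q = q,
            class = c("donor_ranking", "data.frame"))
}

#' Rank donors from a metabolome table
#'
#' Convenience pipeline: resolve chromatography modes, average timepoints per
#' donor, compute the SCFA score and bile-acid conversion ratio, and rank and
#' select the top quantile of both ([rank_and_select()]).
#'
#' @param table a `donor_metabolome`.
#' @param q top-quantile fraction, default 0.25.
#' @param mode_preference see [resolve_metabolite_modes()].
#' @param standardize_scfa z-score SCFAs before averaging (see
#'   [scfa_score()]).
#' @return a `donor_ranking` data.frame.
#' @export
rank_donors <- function(table, q = 0.25,
                        mode_preference = c("C18neg", "HILICneg"),
                        standardize_scfa = FALSE) {
  table <- resolve_metabolite_modes(table, mode_preference)
  panel <- bile_acid_panel()
  scfas <- c("butyrate", "isovalerate", "propionate")
  profile <- donor_mean_profile(table,
                                required = c(scfas, panel$primary,
                                             panel$secondary))
  rank_and_select(scfa_score(profile, scfas, standardize = standardize_scfa),
                  bile_conversion_ratio(profile, panel), q = q)
}

#' @export
print.donor_ranking <- function(x, ...) {
  cat(sprintf("Donor ranking: %d donors, top-quantile cutoff rank %d (q = %g)\n",
              nrow(x), attr(x, "cutoff"), attr(x, "q")))
  cat(sprintf("Selected (top quantile of both metrics): %s\n",
              paste(x$donor_id[x$selected], collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... %d more donors\n", nrow(x) - 10))
  invisible(x)
}

#' @export
plot.donor_ranking <- function(x, ...) {
  graphics::plot(x$scfa_rank, x$conversion_rank,
                 pch = ifelse(x$selected, 19, 1),
                 col = ifelse(x$selected, "firebrick", "grey40"),
                 xlab = "SCFA rank (1 = highest)",
                 ylab = "Bile-acid conversion rank (1 = highest)",
                 main = "Donor ranking: SCFA production vs. bile-acid conversion",
                 ...)
  graphics::abline(v = attr(x, "cutoff") + 0.5, h = attr(x, "cutoff") + 0.5,
                   lty = 2, col = "grey60")
  invisible(x)
}

#' Write a donor ranking to TSV
#' @param ranking a `donor_ranking`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_donor_ranking <- function(ranking, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  cols <- c("donor_id", "scfa_score", "conversion_ratio", "scfa_rank",
            "conversion_rank", "selected")
  writeLines(paste(cols, collapse = "\t"), con)
  for (i in seq_len(nrow(ranking))) {
    writeLines(paste(c(ranking$donor_id[i],
                       format_num(ranking$scfa_score[i]),
                       format_num(ranking$conversion_ratio[i]),
                       ranking$scfa_rank[i], ranking$conversion_rank[i],
                       tolower(ranking$selected[i])), collapse = "\t"), con)
  }
  invisible(path)
}
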