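#' Define a taxon panel
#'
#' A taxon panel is a named set of genera whose summed relative abundance is
#' used as a per-sample score — e.g. the butyrate-producer panel used to rank
#' FMT donors.
#'
#' @param name panel label.
#' @param genera character vector of genus names.
#' @return list of class `taxon_panel`.
#' @export
taxon_panel <- function(name, genera) {
  genera <- unique(as.character(genera))
  genera <- genera[genera != ""]
  structure(list(name = as.character(name)[1], genera = genera),
            class = "taxon_panel")
}

#' @export
print.taxon_panel <- function(x, ...) {
  cat(sprintf("Taxon panel '%s': %d genera\n  %s\n", x$name,
              length(x$genera), paste(x$genera, collapse = ", ")))
  invisible(x)
}

#' Read a taxon panel from a JSON config
#'
#' Expects `{"name": ..., "genera": [...]}`.
#'
#' @param path JSON file path.
#' @return a [taxon_panel()].
#' @export
read_taxon_panel <- function(path) {
  if (!file.exists(path)) stop_fmt("panel file not found: %s", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$name) || is.null(cfg$genera))
    stop_fmt("%s: panel JSON needs fields 'name' and 'genera'", path)
  taxon_panel(cfg$name, cfg$genera)
}

#' Default butyrate-producer genus panel
#'
#' Genus-level heuristic panel of dominant gut butyrate producers: genera
#' prevalent across healthy individuals whose representative genomes carry
#' known butyrate-production pathways. Species-level butyrogenic taxa within
#' otherwise heterogeneous genera (the *Eubacterium* species *E. ventriosum*,
#' *E. hallii*, *E. rectale*) are deliberately not represented, since genus
#' membership does not imply conserved butyrate production there. The panel
#' is a config file and can be replaced wholesale with [read_taxon_panel()].
#'
#' @return a [taxon_panel()].
#' @export
default_butyrate_panel <- function() {
  read_taxon_panel(system.file("extdata", "butyrate_panel.json",
                               package = "fmtselect", mustWork = TRUE))
}

#' Per-sample summed abundance of a taxon panel
#'
#' Sums relative abundances over the panel genera present in the table.
#' Matching is performed on normalized genus labels (rank prefix stripped,
#' case-folded); panel genera absent from the table contribute 0. The
#' reserved `"unclassified"` column never matches a panel.
#'
#' @param table a [genus_table()].
#' @param panel a [taxon_panel()]; must be non-empty.
#' @return named numeric vector of per-sample panel abundances in [0, 1].
#' @export
panel_abundance <- function(table, panel) {
  stopifnot(inherits(panel, "taxon_panel"))
  if (length(panel$genera) == 0) stop_fmt("panel is empty")
  cols <- colnames(table)
  keep <- normalize_genus(cols) %in% normalize_genus(panel$genera) &
    cols != "unclassified"
  if (!any(keep))
    return(stats::setNames(rep(0, nrow(table)), rownames(table)))
  rowSums(unclass(table)[, keep, drop = FALSE])
}

#' Test association between donor panel abundance and patient response
#'
#' Maps each patient with a clinical outcome to the panel abundance of their
#' linked donor sample, then compares donor scores between responder and
#' non-responder groups with a two-sided two-sample t-test (equal-variance
#' Student test by default; Welch behind `var_equal = FALSE`).
#'
#' If the pooled variance is exactly zero the t-test is degenerate: equal
#' group means give t = 0, p = 1; unequal means are reported as p = 0 with
#' `degenerate_variance = TRUE`.
#'
#' @param donor_scores named numeric vector of per-donor-sample panel
#'   abundances (names are donor sample ids), e.g. from [panel_abundance()].
#' @param links a `sample_metadata` data.frame carrying patient response
#'   labels and `linked_donor` ids.
#' @param var_equal use the pooled-variance Student t-test (default) rather
#'   than Welch.
#' @return object of class `panel_assoc`: `group_means`, `t_statistic`,
#'   `p_value`, `n_per_group`, `df`, `degenerate_variance`.
#' @export
response_association <- function(donor_scores, links, var_equal = TRUE) {
  stopifnot(inherits(links, "sample_metadata"))
  pats <- links[links$role == "patient" & !is.na(links$response), , drop = FALSE]
  if (any(is.na(pats$linked_donor)))
    stop_fmt("patient(s) with a response but no linked donor: %s",
             paste(pats$sample_id[is.na(pats$linked_donor)], collapse = ", "))
  miss <- setdiff(pats$linked_donor, names(donor_scores))
  if (length(miss))
    stop_fmt("no donor score for linked donor(s): %s",
             paste(unique(miss), collapse = ", "))
  x <- donor_scores[pats$linked_donor[pats$response == "response"]]
  y <- donor_scores[pats$linked_donor[pats$response == "no_response"]]
  if (length(x) < 2 || length(y) < 2)
    stop_fmt("need >= 2 patients per response group (got %d response, %d no_response)",
             length(x), length(y))
  n1 <- length(x); n2 <- length(y)
  pooled_var <- if (var_equal) {
    ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  } else {
    stats::var(x) / n1 + stats::var(y) / n2  # just for the degeneracy check
  }
  degenerate <- pooled_var == 0
  if (degenerate) {
    delta <- mean(x) - mean(y)
    t_stat <- if (delta == 0) 0 else sign(delta) * Inf
    p <- if (delta == 0) 1 else 0
    df <- n1 + n2 - 2
  } else {
    ht <- stats::t.test(x, y, var.equal = var_equal)
    t_stat <- unname(ht$statistic)
    p <- ht$p.value
    df <- unname(ht$parameter)
  }
  structure(list(group_means = c(response = mean(x), no_response = mean(y)),
                 t_statistic = t_stat, p_value = p,
                 n_per_group = c(response = n1, no_response = n2),
                 df = df, var_equal = var_equal,
                 degenerate_variance = degenerate),
            class = "panel_assoc")
}

#' @export
print.panel_assoc <- function(x, ...) {
  cat("Donor panel abundance vs. patient response\n")
  cat(sprintf("  mean (response):    %.4f  (n = %d)\n",
              x$group_means[["response"]], x$n_per_group[["response"]]))
  cat(sprintf("  mean (no response): %.4f  (n = %d)\n",
              x$group_means[["no_response"]], x$n_per_group[["no_response"]]))
  cat(sprintf("  %s t = %.4f, df = %g, p = %.4g%s\n",
              if (x$var_equal) "Student" else "Welch",
              x$t_statistic, x$df, x$p_value,
              if (x$degenerate_variance) "  [degenerate variance]" else ""))
  invisible(x)
}

#' Donor-minus-patient panel abundance differences
#'
#' For every patient with a baseline sample in `table` and a linked donor,
#' computes (donor panel abundance) - (patient baseline panel abundance).
#'
#' @inheritParams panel_abundance
#' @param links a `sample_metadata` data.frame.
#' @return named numeric vector (per patient sample id) of differences in
#'   [-1, 1].
#' @export
donor_patient_difference <- function(table, panel, links) {
  stopifnot(inherits(links, "sample_metadata"))
  scores <- panel_abundance(table, panel)
  pats <- links[links$role == "patient" &
                  links$sample_id %in% rownames(table), , drop = FALSE]
  if (nrow(pats) == 0) stop_fmt("no patient samples found in table")
  no_link <- pats$sample_id[is.na(pats$linked_donor)]
  if (length(no_link))
    stop_fmt("patient(s) without a linked donor: %s",
             paste(no_link, collapse = ", "))
  miss <- pats$sample_id[!(pats$linked_donor %in% names(scores))]
  if (length(miss))
    stop_fmt("linked donor sample missing from table for patient(s): %s",
             paste(miss, collapse = ", "))
  stats::setNames(scores[pats$linked_donor] - scores[pats$sample_id],
                  pats$sample_id)
}
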