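#' Bundle a genus table with case/control labels
#'
#' A case-control dataset serves as the effect-size model for the FMT power
#' simulation: cases stand in for FMT responders, controls for
#' non-responders.
#'
#' @param table a [genus_table()].
#' @param labels character vector (`"case"`/`"control"`), either named by
#'   sample id or in row order of `table`; must cover all samples with at
#'   least 2 per class.
#' @return list of class `case_control_dataset`.
#' @export
case_control_dataset <- function(table, labels) {
  if (is.null(names(labels))) {
    if (length(labels) != nrow(table))
      stop_fmt("labels length (%d) != number of samples (%d)",
               length(labels), nrow(table))
    names(labels) <- rownames(table)
  }
  miss <- setdiff(rownames(table), names(labels))
  if (length(miss))
    stop_fmt("samples without a label: %s",
             paste(utils::head(miss, 5), collapse = ", "))
  labels <- labels[rownames(table)]
  if (!all(labels %in% c("case", "control")))
    stop_fmt("labels must be 'case' or 'control'")
  if (sum(labels == "case") < 2 || sum(labels == "control") < 2)
    stop_fmt("need >= 2 samples per class")
  structure(list(table = table, labels = labels),
            class = "case_control_dataset")
}

#' Log-transform configuration for the signal-to-noise statistic
#'
#' Relative abundances are mapped through `log(a + pseudocount)` (natural
#' log) before computing the signal-to-noise ratio. The pseudocount keeps the
#' statistic defined on sparse tables; its value is carried through to output
#' provenance.
#'
#' @param pseudocount small positive fraction added before the log; default
#'   `1e-6`.
#' @return list of class `transform_config`.
#' @export
transform_config <- function(pseudocount = 1e-6) {
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop_fmt("pseudocount must be > 0")
  structure(list(pseudocount = pseudocount, log_base = "natural"),
            class = "transform_config")
}

#' Signal-to-noise ranking of genera in a case-control dataset
#'
#' Per genus, SNR = (mean log abundance in cases - mean log abundance in
#' controls) / (sample standard deviation of log abundance over all
#' samples), with `log(a + pseudocount)`. Genera with zero variance across
#' all samples are excluded from the ranking and reported. The ranking
#' orders genera by |SNR| descending, ties broken by genus name.
#'
#' @param dataset a [case_control_dataset()].
#' @param cfg a [transform_config()].
#' @return data.frame of class `snr_ranking` (`genus`, `snr`), ordered by
#'   |SNR| descending, with attributes `excluded` (zero-variance genera) and
#'   `pseudocount`.
#' @export
signal_to_noise <- function(dataset, cfg = transform_config()) {
  stopifnot(inherits(dataset, "case_control_dataset"),
            inherits(cfg, "transform_config"))
  is_case <- dataset$labels == "case"
  if (sum(is_case) < 2 || sum(!is_case) < 2)
    stop_fmt("need >= 2 samples per class")
  L <- log(unclass(dataset$table) + cfg$pseudocount)
  mdiff <- colMeans(L[is_case, , drop = FALSE]) -
    colMeans(L[!is_case, , drop = FALSE])
  sds <- apply(L, 2, stats::sd)
  zero_var <- sds == 0
  snr <- mdiff[!zero_var] / sds[!zero_var]
  out <- data.frame(genus = names(snr), snr = unname(snr),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$snr), out$genus), ]
  rownames(out) <- NULL
  structure(out, excluded = names(sds)[zero_var],
            pseudocount = cfg$pseudocount,
            class = c("snr_ranking", "data.frame"))
}

#' Top-k genera by absolute signal-to-noise ratio
#'
#' @param ranking an `snr_ranking` from [signal_to_noise()].
#' @param k number of genera to keep (default 10); if fewer genera are
#'   ranked, all are returned.
#' @return character vector of genus names, ordered by |SNR| descending.
#' @export
top_k_genera <- function(ranking, k = 10) {
  stopifnot(inherits(ranking, "snr_ranking"))
  if (!is_count(k) || k <= 0) stop_fmt("k must be a positive integer")
  if (nrow(ranking) == 0) stop_fmt("ranking is empty")
  utils::head(ranking$genus, k)
}

#' Define a simulated FMT trial design
#'
#' A grid point of the power simulation: an FMT arm of `n_fmt` patients of
#' whom a fraction `response_rate` respond. Responders are subsampled from
#' the dataset's cases and non-responders from its controls. The number of
#' responders is `round(n_fmt * response_rate)` (ties to even).
#'
#' @param n_fmt total patients in the FMT arm.
#' @param response_rate fraction of responders, in (0, 1].
#' @param top_k number of top SNR genera counted as "true" hits (default 10).
#' @param q_threshold Benjamini-Hochberg FDR level (default 0.05).
#' @param n_reps Monte-Carlo replicates for this design.
#' @return list of class `trial_design`.
#' @export
trial_design <- function(n_fmt, response_rate, top_k = 10, q_threshold = 0.05,
                         n_reps = 100) {
  stopifnot(is_count(n_fmt), is_count(top_k), is_count(n_reps))
  if (response_rate <= 0 || response_rate > 1)
    stop_fmt("response_rate must be in (0, 1]")
  n_resp <- round(n_fmt * response_rate)
  if (n_resp < 1)
    stop_fmt("design yields %d responders; need >= 1", n_resp)
  if (response_rate < 1 && n_fmt - n_resp < 1)
    stop_fmt("design yields 0 non-responders at response_rate < 1")
  if (q_threshold <= 0 || q_threshold >= 1)
    stop_fmt("q_threshold must be in (0, 1)")
  structure(list(n_fmt = as.integer(n_fmt), response_rate = response_rate,
                 n_responders = as.integer(n_resp),
                 n_nonresponders = as.integer(n_fmt - n_resp),
                 top_k = as.integer(top_k), q_threshold = q_threshold,
                 n_reps = as.integer(n_reps)),
            class = "trial_design")
}

#' Subsample a simulated FMT trial from a case-control dataset
#'
#' Draws the design's responder count uniformly without replacement from the
#' case samples and its non-responder count from the control samples.
#'
#' @param dataset a [case_control_dataset()].
#' @param design a [trial_design()].
#' @param seed optional integer seed set before sampling; leave `NULL` to
#'   use the current RNG state (as [run_grid()] does via its sub-streams).
#' @return list with `table` (subsampled rows, a `genus_table` matrix slice)
#'   and `labels` (named `"responder"`/`"non_responder"`).
#' @export
simulate_trial <- function(dataset, design, seed = NULL) {
  stopifnot(inherits(dataset, "case_control_dataset"),
            inherits(design, "trial_design"))
  cases <- names(dataset$labels)[dataset$labels == "case"]
  controls <- names(dataset$labels)[dataset$labels == "control"]
  if (design$n_responders > length(cases))
    stop_fmt("design needs %d responders but only %d case samples available",
             design$n_responders, length(cases))
  if (design$n_nonresponders > length(controls))
    stop_fmt("design needs %d non-responders but only %d control samples available",
             design$n_nonresponders, length(controls))
  if (!is.null(seed)) set.seed(seed)
  resp <- sample(cases, design$n_responders)
  nonresp <- sample(controls, design$n_nonresponders)
  ids <- c(resp, nonresp)
  labels <- stats::setNames(rep(c("responder", "non_responder"),
                                c(length(resp), length(nonresp))), ids)
  list(table = unclass(dataset$table)[ids, , drop = FALSE], labels = labels)
}

#' Differentially abundant genera by Kruskal-Wallis + Benjamini-Hochberg
#'
#' Tests each genus between the two groups with the tie-corrected
#' Kruskal-Wallis rank test (chi-square reference, df = 1) on relative
#' abundances, then applies Benjamini-Hochberg step-up correction across all
#' tested genera. Genera with zero variance in the subsample (including
#' all-zero genera) cannot be tested; they are skipped, excluded from the BH
#' family, and reported.
#'
#' @param table numeric matrix (samples x genera) of relative abundances.
#' @param labels two-level grouping vector, named by sample id or in row
#'   order.
#' @param q_threshold FDR level; genera with q below it are significant.
#' @return list: `significant` (genus names with q < `q_threshold`), `stats`
#'   (data.frame genus/p/q for tested genera), `skipped` (zero-variance
#'   genus names).
#' @export
differential_genera <- function(table, labels, q_threshold = 0.05) {
  table <- unclass(table)
  if (!is.null(names(labels))) labels <- labels[rownames(table)]
  g <- factor(labels)
  if (nlevels(g) != 2 || any(table(g) == 0))
    stop_fmt("need exactly 2 non-empty groups (got %d)", nlevels(g))
  sds <- apply(table, 2, stats::sd)
  testable <- which(sds > 0)
  skipped <- colnames(table)[sds == 0]
  p <- vapply(testable, function(j)
    stats::kruskal.test(table[, j], g)$p.value, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  stats_df <- data.frame(genus = colnames(table)[testable], p = unname(p),
                         q = unname(q), stringsAsFactors = FALSE)
  list(significant = stats_df$genus[stats_df$q < q_threshold],
       stats = stats_df, skipped = skipped)
}

#' Count recovered top genera
#'
#' How many of the dataset-level top-SNR genera were declared significant in
#' a simulated trial: the size of the intersection.
#'
#' @param significant character vector of significant genus names.
#' @param top character vector of top-SNR genus names.
#' @return integer count.
#' @export
recovery_count <- function(significant, top) {
  length(intersect(significant, top))
}

#' Run the FMT retrospective-discovery power simulation over a design grid
#'
#' For each design: `n_reps` independent replicates of subsample
#' ([simulate_trial()]) -> test ([differential_genera()]) -> count recovered
#' top hits ([recovery_count()]) against the top-`top_k` genera of the full
#' dataset's signal-to-noise ranking. Replicate r of design d uses an RNG
#' sub-stream derived deterministically from `master_seed`, so any replicate
#' is reproducible in isolation and results are identical across runs.
#'
#' @param dataset a [case_control_dataset()].
#' @param designs a [trial_design()] or list of them (see [trial_grid()]).
#' @param master_seed integer seed governing all subsampling.
#' @param cfg a [transform_config()] for the SNR ranking.
#' @return object of class `fmt_power_sim`: `results` (one row per design x
#'   replicate: design parameters, `rep`, `recovered`, `n_significant`,
#'   `n_tested`, `n_skipped`), `summary` (per-design mean/sd/quartiles of
#'   the recovered count), `top_genera` (per design), `snr` (the full-data
#'   ranking) and `provenance` (seed, pseudocount, dataset hash).
#' @export
run_grid <- function(dataset, designs, master_seed, cfg = transform_config()) {
  stopifnot(inherits(dataset, "case_control_dataset"))
  if (inherits(designs, "trial_design")) designs <- list(designs)
  stopifnot(length(designs) > 0,
            all(vapply(designs, inherits, logical(1), "trial_design")))
  n_cases <- sum(dataset$labels == "case")
  n_controls <- sum(dataset$labels == "control")
  for (d in designs) {
    if (d$n_responders > n_cases)
      stop_fmt("infeasible design (n_fmt=%d, rate=%g): %d responders > %d cases",
               d$n_fmt, d$response_rate, d$n_responders, n_cases)
    if (d$n_nonresponders > n_controls)
      stop_fmt("infeasible design (n_fmt=%d, rate=%g): %d non-responders > %d controls",
               d$n_fmt, d$response_rate, d$n_nonresponders, n_controls)
  }
  ranking <- signal_to_noise(dataset, cfg)
  res <- vector("list", length(designs))
  tops <- vector("list", length(designs))
  for (di in seq_along(designs)) {
    d <- designs[[di]]
    top <- top_k_genera(ranking, d$top_k)
    tops[[di]] <- top
    rec <- integer(d$n_reps)
    nsig <- integer(d$n_reps)
    ntest <- integer(d$n_reps)
    nskip <- integer(d$n_reps)
    for (r in seq_len(d$n_reps)) {
      sub <- simulate_trial(dataset, d,
                            seed = derive_seed(master_seed, di, r))
      dg <- differential_genera(sub$table, sub$labels, d$q_threshold)
      rec[r] <- recovery_count(dg$significant, top)
      nsig[r] <- length(dg$significant)
      ntest[r] <- nrow(dg$stats)
      nskip[r] <- length(dg$skipped)
    }
    res[[di]] <- data.frame(design = di, n_fmt = d$n_fmt,
                            response_rate = d$response_rate,
                            top_k = d$top_k, q_threshold = d$q_threshold,
                            rep = seq_len(d$n_reps), recovered = rec,
                            n_significant = nsig, n_tested = ntest,
                            n_skipped = nskip)
  }
  results <- do.call(rbind, res)
  summ <- do.call(rbind, lapply(seq_along(designs), function(di) {
    r <- res[[di]]$recovered
    data.frame(design = di, n_fmt = designs[[di]]$n_fmt,
               response_rate = designs[[di]]$response_rate,
               n_reps = designs[[di]]$n_reps,
               mean_recovered = mean(r), sd_recovered = stats::sd(r),
               q25 = unname(stats::quantile(r, 0.25)),
               median = stats::median(r),
               q75 = unname(stats::quantile(r, 0.75)))
  }))
  structure(list(results = results, summary = summ, top_genera = tops,
                 snr = ranking, designs = designs,
                 provenance = list(master_seed = master_seed,
                                   pseudocount = cfg$pseudocount,
                                   sd_flavor = "sample (n-1)",
                                   dataset_hash = dataset_hash(dataset),
                                   n_cases = n_cases,
                                   n_controls = n_controls)),
            class = "fmt_power_sim")
}

#' Build a grid of trial designs
#'
#' Crosses `n_fmt` with `response_rate` and returns one [trial_design()] per
#' combination.
#'
#' @inheritParams trial_design
#' @return list of `trial_design` objects.
#' @export
trial_grid <- function(n_fmt, response_rate, top_k = 10, q_threshold = 0.05,
                       n_reps = 100) {
  grid <- expand.grid(n_fmt = n_fmt, response_rate = response_rate)
  lapply(seq_len(nrow(grid)), function(i)
    trial_design(grid$n_fmt[i], grid$response_rate[i], top_k = top_k,
                 q_threshold = q_threshold, n_reps = n_reps))
}

# md5 of a canonical text serialization of the dataset, for provenance
dataset_hash <- function(dataset) {
  tf <- tempfile()
  on.exit(unlink(tf))
  con <- file(tf, "wb")
  writeLines(c(colnames(dataset$table),
               rownames(dataset$table),
               dataset$labels,
               format_num(as.numeric(dataset$table))), con)
  close(con)
  unname(tools::md5sum(tf))
}

#' @export
print.fmt_power_sim <- function(x, ...) {
  cat(sprintf("FMT retrospective-discovery power simulation (%d designs, seed %d)\n",
              length(x$designs), x$provenance$master_seed))
  cat(sprintf("  dataset: %d cases, %d controls, %d genera ranked (pseudocount %g)\n",
              x$provenance$n_cases, x$provenance$n_controls, nrow(x$snr),
              x$provenance$pseudocount))
  cat("  mean recovered top hits per design:\n")
  print.data.frame(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
summary.fmt_power_sim <- function(object, ...) object$summary

#' @export
plot.fmt_power_sim <- function(x, ...) {
  s <- x$summary
  rates <- sort(unique(s$response_rate))
  cols <- grDevices::hcl.colors(max(length(rates), 2), "Dark 2")
  graphics::plot(range(s$n_fmt), c(0, max(s$mean_recovered, 1)), type = "n",
                 xlab = "Patients in FMT arm", ylab = "Mean recovered top hits",
                 main = "Power to recover top differentially abundant genera",
                 ...)
  for (i in seq_along(rates)) {
    ss <- s[s$response_rate == rates[i], ]
    ss <- ss[order(ss$n_fmt), ]
    graphics::lines(ss$n_fmt, ss$mean_recovered, type = "b", pch = 19,
                    col = cols[i])
  }
  graphics::legend("topleft", legend = sprintf("response rate %g", rates),
                   col = cols[seq_along(rates)], lty = 1, pch = 19, bty = "n")
  invisible(x)
}

#' Write power-simulation results to TSV
#'
#' Writes the long-format per-replicate table; with `summary = TRUE` writes
#' the per-design summary instead.
#'
#' @param sim an `fmt_power_sim`.
#' @param path output path.
#' @param summary write the per-design summary table instead of the
#'   per-replicate results.
#' @return `path`, invisibly.
#' @export
write_power_sim <- function(sim, path, summary = FALSE) {
  df <- if (summary) sim$summary else sim$results
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  for (i in seq_len(nrow(df))) {
    vals <- vapply(df[i, ], function(v)
      if (is.numeric(v)) format_num(v) else as.character(v), character(1))
    writeLines(paste(vals, collapse = "\t"), con)
  }
  invisible(path)
}
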