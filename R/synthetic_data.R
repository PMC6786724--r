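#' Specification for a synthetic case-control dataset
#'
#' Parameters of the lognormal compositional model used to generate
#' case-control genus tables with planted differential abundance. Each genus
#' gets a baseline log-mean drawn once; the `n_affected` affected genera are
#' shifted by `effect_delta` on the natural-log scale in case samples;
#' per-entry lognormal noise of scale `sigma` and zero inflation with
#' probability `zero_prob` are applied before per-sample renormalization.
#'
#' @param n_cases,n_controls sample counts per group.
#' @param n_genera number of genera.
#' @param n_affected number of differentially abundant (planted) genera.
#' @param effect_delta case-group shift on the natural-log abundance scale
#'   (>= 0).
#' @param sigma lognormal noise scale on the log abundance.
#' @param zero_prob per-entry zero-inflation probability in [0, 1).
#' @param seed RNG seed; identical seeds give byte-identical datasets.
#' @return a list of class `case_control_spec`.
#' @export
case_control_spec <- function(n_cases, n_controls, n_genera, n_affected,
                              effect_delta, sigma = 1, zero_prob = 0.1,
                              seed = 1L) {
  stopifnot(is_count(n_cases), is_count(n_controls), is_count(n_genera),
            is_count(n_affected), is_count(seed))
  if (n_cases < 2 || n_controls < 2)
    stop_fmt("need at least 2 cases and 2 controls")
  if (n_affected > n_genera)
    stop_fmt("n_affected (%d) exceeds n_genera (%d)", n_affected, n_genera)
  if (effect_delta < 0) stop_fmt("effect_delta must be >= 0")
  if (sigma < 0) stop_fmt("sigma must be >= 0")
  if (zero_prob < 0 || zero_prob >= 1)
    stop_fmt("zero_prob must be in [0, 1)")
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 n_genera = n_genera, n_affected = n_affected,
                 effect_delta = effect_delta, sigma = sigma,
                 zero_prob = zero_prob, seed = as.integer(seed)),
            class = "case_control_spec")
}

#' Generate a synthetic case-control genus abundance dataset
#'
#' Draws from the lognormal compositional model of [case_control_spec()] and
#' returns the table, the case/control labels and the planted ground truth.
#' The RNG stream is split deterministically into sub-streams per stage
#' (baseline means / noise / zero mask), so the same seed always reproduces
#' the same dataset.
#'
#' @param spec a `case_control_spec`.
#' @return list with elements `table` (a [genus_table()]), `labels` (named
#'   character, `"case"`/`"control"` per sample), `affected` (genus names of
#'   the planted differentially abundant genera) and `spec`.
#' @export
make_case_control <- function(spec) {
  stopifnot(inherits(spec, "case_control_spec"))
  n <- spec$n_cases + spec$n_controls
  genera <- sprintf("genus_%03d", seq_len(spec$n_genera))
  samples <- c(sprintf("case_%03d", seq_len(spec$n_cases)),
               sprintf("control_%03d", seq_len(spec$n_controls)))
  labels <- stats::setNames(rep(c("case", "control"),
                                c(spec$n_cases, spec$n_controls)), samples)

  set.seed(derive_seed(spec$seed, 1L))
  mu <- stats::rnorm(spec$n_genera, 0, 1)
  affected <- sort(sample(genera, spec$n_affected))

  set.seed(derive_seed(spec$seed, 2L))
  logx <- matrix(stats::rnorm(n * spec$n_genera, 0, spec$sigma),
                 nrow = n, dimnames = list(samples, genera))
  logx <- sweep(logx, 2, mu, "+")
  logx[labels == "case", affected] <- logx[labels == "case", affected] +
    spec$effect_delta
  x <- exp(logx)

  set.seed(derive_seed(spec$seed, 3L))
  if (spec$zero_prob > 0) {
    mask <- matrix(stats::runif(n * spec$n_genera) < spec$zero_prob, nrow = n)
    x[mask] <- 0
    # a fully zeroed sample would break the composition; redraw its mask
    while (any(rowSums(x) == 0)) {
      i <- which(rowSums(x) == 0)[1]
      xi <- exp(logx[i, ])
      xi[stats::runif(spec$n_genera) < spec$zero_prob] <- 0
      x[i, ] <- xi
    }
  }
  x <- x / rowSums(x)
  list(table = genus_table(x), labels = labels, affected = affected,
       spec = spec)
}

#' Specification for a synthetic donor metabolome
#'
#' Each donor gets latent short-chain fatty acid (SCFA) levels and a latent
#' bile-acid conversion propensity; observed timepoints multiply the latents
#' by lognormal noise `exp(N(0, sigma))`. The metabolites are the three stool
#' SCFAs (butyrate, isovalerate, propionate) and the four major bile acids:
#' primary cholate (C) and chenodeoxycholate (CDC), secondary deoxycholate
#' (DC) and lithocholate (LC).
#'
#' @param n_donors number of donors (>= 2).
#' @param n_timepoints_range integer min/max of sampled timepoints per donor.
#' @param sigma lognormal observation-noise scale (0 = noiseless).
#' @param seed RNG seed.
#' @return list of class `metabolome_spec`.
#' @export
metabolome_spec <- function(n_donors, n_timepoints_range = c(1L, 3L),
                            sigma = 0.3, seed = 1L) {
  stopifnot(is_count(n_donors), is_count(seed), length(n_timepoints_range) == 2)
  if (n_donors < 2) stop_fmt("need at least 2 donors")
  if (sigma < 0) stop_fmt("sigma must be >= 0")
  if (n_timepoints_range[1] < 1 ||
      n_timepoints_range[2] < n_timepoints_range[1])
    stop_fmt("invalid n_timepoints_range")
  structure(list(n_donors = n_donors,
                 n_timepoints_range = as.integer(n_timepoints_range),
                 scfa_names = c("butyrate", "isovalerate", "propionate"),
                 bile_primary = c("cholate", "chenodeoxycholate"),
                 bile_secondary = c("deoxycholate", "lithocholate"),
                 sigma = sigma, seed = as.integer(seed)),
            class = "metabolome_spec")
}

#' Generate a synthetic donor stool metabolome with known ground truth
#'
#' Latent per-donor SCFA levels are lognormal around metabolite-specific base
#' levels; latent bile-acid conversion is generated so that the noiseless
#' conversion ratio (LC + DC) / (CDC + C) equals the latent propensity
#' exactly. Ground truth (latent SCFA score and conversion ratio per donor)
#' is returned alongside the observed table.
#'
#' @param spec a `metabolome_spec`.
#' @return list with `table` (a `donor_metabolome` data.frame: `donor_id`,
#'   `timepoint`, one column per metabolite) and `truth` (data.frame
#'   `donor_id`, `scfa_score`, `conversion_ratio` on the latent scale).
#' @export
make_metabolome <- function(spec) {
  stopifnot(inherits(spec, "metabolome_spec"))
  donors <- sprintf("donor_%03d", seq_len(spec$n_donors))

  set.seed(derive_seed(spec$seed, 1L))
  # latent SCFA levels: platform-unit base levels differ per metabolite,
  # donor-to-donor spread of 1 on the log scale
  base <- c(butyrate = 2, isovalerate = 0, propionate = 2)
  scfa_latent <- sapply(spec$scfa_names, function(m)
    exp(base[[m]] + stats::rnorm(spec$n_donors, 0, 1)))
  rownames(scfa_latent) <- donors
  # latent bile acids: primary levels, conversion propensity r, and the
  # DC/LC split; secondary total = r * primary total so the noiseless ratio
  # recovers r exactly
  cholate <- exp(3 + stats::rnorm(spec$n_donors, 0, 1))
  cdca <- exp(2.5 + stats::rnorm(spec$n_donors, 0, 1))
  ratio <- exp(stats::rnorm(spec$n_donors, 0, 1))
  split_dc <- stats::runif(spec$n_donors, 0.3, 0.7)
  secondary <- ratio * (cholate + cdca)
  bile_latent <- cbind(cholate = cholate, chenodeoxycholate = cdca,
                       deoxycholate = split_dc * secondary,
                       lithocholate = (1 - split_dc) * secondary)
  rownames(bile_latent) <- donors
  latent <- cbind(scfa_latent, bile_latent)

  set.seed(derive_seed(spec$seed, 2L))
  n_tp <- if (spec$n_timepoints_range[1] == spec$n_timepoints_range[2]) {
    rep(spec$n_timepoints_range[1], spec$n_donors)
  } else {
    sample(seq(spec$n_timepoints_range[1], spec$n_timepoints_range[2]),
           spec$n_donors, replace = TRUE)
  }

  set.seed(derive_seed(spec$seed, 3L))
  rows <- vector("list", spec$n_donors)
  for (d in seq_len(spec$n_donors)) {
    noise <- matrix(exp(stats::rnorm(n_tp[d] * ncol(latent), 0, spec$sigma)),
                    nrow = n_tp[d])
    obs <- sweep(noise, 2, latent[d, ], "*")
    colnames(obs) <- colnames(latent)
    rows[[d]] <- data.frame(donor_id = donors[d], timepoint = seq_len(n_tp[d]),
                            obs, check.names = FALSE)
  }
  table <- donor_metabolome(do.call(rbind, rows))
  truth <- data.frame(donor_id = donors,
                      scfa_score = rowMeans(scfa_latent),
                      conversion_ratio = ratio)
  list(table = table, truth = truth, spec = spec)
}

#' Specification for a synthetic FMT trial cohort
#'
#' Donors receive panel abundances spanning (0, 1); each patient is linked to
#' one donor (round-robin) and responds with probability
#' `plogis(qlogis(baseline_response_prob) + panel_effect * (donor panel
#' abundance - cohort mean))`. `panel_effect = 0` is the null of no
#' donor-quality effect.
#'
#' @param n_donors,n_patients cohort sizes.
#' @param panel_effect log-odds coefficient linking donor panel abundance to
#'   patient response.
#' @param baseline_response_prob response probability at the cohort-mean
#'   donor, in (0, 1).
#' @param seed RNG seed.
#' @return list of class `trial_cohort_spec`.
#' @export
trial_cohort_spec <- function(n_donors, n_patients, panel_effect = 0,
                              baseline_response_prob = 0.5, seed = 1L) {
  stopifnot(is_count(n_donors), is_count(n_patients), is_count(seed))
  if (n_donors < 1 || n_patients < 1)
    stop_fmt("need at least 1 donor and 1 patient")
  if (baseline_response_prob <= 0 || baseline_response_prob >= 1)
    stop_fmt("baseline_response_prob must be in (0, 1)")
  structure(list(n_donors = n_donors, n_patients = n_patients,
                 panel_effect = panel_effect,
                 baseline_response_prob = baseline_response_prob,
                 seed = as.integer(seed)),
            class = "trial_cohort_spec")
}

#' Generate a synthetic donor/patient FMT cohort
#'
#' @param spec a `trial_cohort_spec`.
#' @param panel a [taxon_panel()]; its genera carry the donor "quality"
#'   signal. Must be non-empty.
#' @return list with `table` (a [genus_table()] holding donor and patient
#'   baseline samples), `metadata` (a `sample_metadata` data.frame with
#'   donor-patient links and response labels) and `truth` (per-donor panel
#'   abundance and per-patient response probability).
#' @export
make_trial_cohort <- function(spec, panel) {
  stopifnot(inherits(spec, "trial_cohort_spec"), inherits(panel, "taxon_panel"))
  if (length(panel$genera) == 0) stop_fmt("panel must be non-empty")
  donors <- sprintf("donor_%03d", seq_len(spec$n_donors))
  patients <- sprintf("patient_%03d", seq_len(spec$n_patients))
  fillers <- sprintf("other_%02d", 1:5)
  genera <- c(panel$genera, fillers)

  set.seed(derive_seed(spec$seed, 1L))
  donor_panel <- stats::runif(spec$n_donors, 0.05, 0.95)
  set.seed(derive_seed(spec$seed, 2L))
  patient_panel <- stats::runif(spec$n_patients, 0.01, 0.30)

  build_rows <- function(panel_ab, ids) {
    m <- cbind(matrix(panel_ab / length(panel$genera), length(ids),
                      length(panel$genera)),
               matrix((1 - panel_ab) / length(fillers), length(ids),
                      length(fillers)))
    dimnames(m) <- list(ids, genera)
    m
  }
  table <- genus_table(rbind(build_rows(donor_panel, donors),
                             build_rows(patient_panel, patients)))

  link_idx <- ((seq_len(spec$n_patients) - 1L) %% spec$n_donors) + 1L
  eta <- stats::qlogis(spec$baseline_response_prob) +
    spec$panel_effect * (donor_panel[link_idx] - mean(donor_panel[link_idx]))
  set.seed(derive_seed(spec$seed, 3L))
  responded <- stats::rbinom(spec$n_patients, 1, stats::plogis(eta)) == 1

  metadata <- sample_metadata(data.frame(
    sample_id = c(donors, patients),
    role = rep(c("donor", "patient"), c(spec$n_donors, spec$n_patients)),
    study = "synthetic",
    response = c(rep(NA_character_, spec$n_donors),
                 ifelse(responded, "response", "no_response")),
    linked_donor = c(rep(NA_character_, spec$n_donors), donors[link_idx]),
    stringsAsFactors = FALSE))
  truth <- list(donor_panel_abundance = stats::setNames(donor_panel, donors),
                response_prob = stats::setNames(stats::plogis(eta), patients))
  list(table = table, metadata = metadata, truth = truth, spec = spec)
}
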