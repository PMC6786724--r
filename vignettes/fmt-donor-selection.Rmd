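---
title: "Rational FMT donor selection: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rational FMT donor selection: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmtselect)
```

# The problem

Fecal microbiota transplantation (FMT) trials transfer whole stool from
healthy donors to patients, and donors differ: in which taxa they carry, in
how much butyrate their communities produce, in how completely they convert
primary to secondary bile acids. When donor quality affects patient
response, a trial that picks donors arbitrarily can fail even though it
would have succeeded with better donors — and a trial that succeeded may
still be unable to say *which* donor features mattered. `fmtselect`
implements the quantitative side of both questions: scoring and ranking
donors prospectively, and simulating how much statistical power a completed
trial has for retrospective taxon discovery.

# Taxon-panel scoring

A *taxon panel* is a named set of genera whose summed relative abundance in
a sample is used as a score. The shipped default is a genus-level
butyrate-producer panel: genera prevalent across healthy guts whose
representative genomes carry known butyrate-production pathways. Butyrogenic
*Eubacterium* species (*E. ventriosum*, *E. hallii*, *E. rectale*) are
deliberately not represented, because the genus as a whole is not uniformly
butyrogenic and 16S genus-level data cannot resolve the species. The panel
is a JSON config and is expected to be overridden to match the user's
taxonomy; matching is performed on normalized labels (the GreenGenes `g__`
prefix is stripped and names are case-folded), and the reserved
`unclassified` column — where features with empty or ambiguous genus
assignments are pooled during genus collapse — never matches a panel.

The association test maps each patient with a clinical outcome to the panel
abundance of their *linked donor's* sample and compares donor scores between
responder and non-responder groups with a two-sided, equal-variance
(Student) two-sample *t*-test; Welch's test is available behind a flag. Two
degenerate situations are handled explicitly rather than erroring out of a
library routine: zero pooled variance with equal group means reports t = 0,
p = 1, and zero pooled variance with unequal means reports p = 0 with a
`degenerate_variance` flag, since the observed separation is infinite on
the test's own scale. Groups with fewer than two observations are an error —
no test is meaningful there.

One modeling caveat is inherent to the design: when several patients share a
donor, their mapped scores are identical and not independent. The test is
the field-standard first-pass analysis, and with the default synthetic
cohorts (one donor per patient at the calibration sizes) its null p-value
distribution is uniform, which the test suite verifies; with heavy donor
reuse the nominal level should be interpreted cautiously.

# Metabolomics-based donor ranking

Donors with several sampled timepoints are summarized by the arithmetic mean
of each metabolite across their timepoints (missing values excluded from
that metabolite's mean). Two functional metrics are computed per donor:

* **SCFA score** — the mean of the three stool short-chain fatty acids
  (butyrate, isovalerate, propionate) in raw platform units. Raw averaging
  is the primary definition; because platform units can differ in scale
  across metabolites, a per-metabolite z-score variant is available behind
  `standardize = TRUE`.
* **Bile-acid conversion ratio** — (lithocholate + deoxycholate) /
  (chenodeoxycholate + cholate), i.e. total secondary over total primary
  bile acids, a unitless proxy for the community's conversion capacity. The
  ratio is scale-invariant. A zero denominator with a positive numerator is
  reported as `Inf` with a flag (such a donor ranks at the top, which is the
  only consistent placement); 0/0 is an error naming the donor.

When a metabolite was measured in several chromatography modes, columns are
suffixed `"metabolite|mode"` and exactly one mode is kept per metabolite: a
bare column wins, otherwise the first hit in a configurable preference list
(default `C18neg` then `HILICneg`, so lithocholate measured in both modes is
taken from C-18 negative, matching the other bile acids' mode).

Donors are ranked descending on each metric (rank 1 = best); exact ties are
broken by donor id in lexicographic order so that selection lists are
reproducible. The selection rule takes the top quantile *of both metrics*
with an inclusive cutoff `ceiling(q * n)`: for 83 donors at q = 0.25 the
cutoff is rank 21. The ceiling rule was chosen because "top 25%" needs a
concrete integer rule; ceiling is inclusive at the boundary and monotone in
q (raising q never deselects a donor, which the test suite checks as an
invariant).

# The power simulation

The simulation asks: if an FMT trial's responders and non-responders really
differed in donor-derived genus abundances as strongly as cases and controls
differ in a reference case-control dataset, how many of the truly
differential genera would the trial's retrospective analysis find?

1. **Ground truth by signal-to-noise.** Each genus's SNR is the difference
   in mean log abundance between cases and controls divided by the sample
   (n−1) standard deviation of log abundance over all samples. Abundances
   pass through `log(a + pseudocount)` with a default pseudocount of 1e-6;
   the pseudocount and SD flavor are recorded in the result's provenance
   because both are conventions, not forced choices. The `top_k` (default
   10) genera by |SNR| are the "true hits"; ties in |SNR| break
   lexicographically so top-k sets are deterministic. Genera with zero
   variance are excluded and reported.
2. **Trial subsampling.** A design is (n_fmt, response_rate): the number of
   responders is `round(n_fmt * response_rate)` with R's ties-to-even
   rounding, drawn uniformly without replacement from the cases; the
   remainder are non-responders drawn from the controls. Designs infeasible
   against the class sizes fail before any simulation runs.
3. **Testing.** Every genus is tested between the two subsampled groups
   with the tie-corrected Kruskal–Wallis rank test (chi-square reference,
   df = 1; `stats::kruskal.test`), and Benjamini–Hochberg step-up control is
   applied across the genera actually tested. Genera with zero variance in
   the subsample are untestable — the tie-corrected H statistic is 0/0 on
   any constant vector, so the skip applies to all constant genera, not only
   all-zero ones. Skipped genera are excluded from the BH family and can
   never be recovered; both facts are reported in the per-replicate output.
4. **Recovery.** The replicate's recovered count is the size of the
   intersection between the significant set (q < 0.05) and the dataset-level
   top-k. Averaged over replicates this is the design's discovery power.

Replicate r of design d uses an RNG sub-stream derived deterministically
from the master seed via an integer mixing function, so a single replicate
can be reproduced in isolation and adding designs never perturbs earlier
ones. Results carry full provenance: master seed, pseudocount, SD flavor
and an md5 hash of the input dataset.

# Synthetic data: what it emulates and what it does not

The generators exist so that every stage has a testable ground truth.

**Case-control tables** follow a lognormal compositional model: per-genus
baseline log-means are drawn once from N(0, 1); affected genera get
`effect_delta` added on the natural-log scale in case samples; entries are
`exp(N(mean, sigma))`, zeroed with probability `zero_prob`, and each sample
is renormalized to sum to 1. The log-scale shift was chosen because the SNR
statistic operates on log abundances, so planted effects map directly onto
the statistic being tested. Zero inflation is applied *before*
renormalization so zeros interact with the log transform exactly as real
sparse tables do. A sample whose entries all zero out would be an invalid
composition, so its zero mask is redrawn (deterministically, within the
same stream).

Renormalization has one consequence worth knowing: boosting the affected
genera raises case samples' row totals, which depresses every *other*
genus's relative abundance in cases — a common-mode negative offset in the
null genera's SNR. The size of the offset scales with the affected genera's
share of total community mass. The package's reference condition for
recovery experiments therefore uses 200 genera with 10 affected (affected
mass fraction ≈ 5%), which matches the scale of genus-collapsed 16S
case-control tables and keeps the planted signal well separated from the
compositional leakage; with far fewer genera the leakage becomes a real
confound — as it would in real data where a large fraction of the community
shifts.

**Donor metabolomes** draw latent per-donor SCFA levels (lognormal around
metabolite-specific base levels, donor spread of 1 log unit) and a latent
conversion propensity; secondary bile-acid totals are constructed as
propensity × primary totals, so at zero observation noise the empirical
conversion ratio equals the latent propensity exactly and recovered
rankings equal latent rankings exactly — the identity the test suite
asserts. Observed timepoints multiply latents by `exp(N(0, sigma))` noise.

**Trial cohorts** give donors panel abundances spanning (0, 1), link each
patient to a donor round-robin, and draw responses from a logistic model
whose log-odds are `logit(baseline) + panel_effect × (donor panel abundance
− cohort mean)`; `panel_effect = 0` is an exact null used for calibration.

What passing tests on these generators do **not** show: real 16S tables
have phylum-level covariance structure, sequencing-depth artifacts and
taxonomy mis-assignment that the independent-lognormal model lacks; real
metabolomics has batch effects and detection limits; and real donor-patient
cohorts have confounded study effects. The generators validate the
*machinery* — statistics, ranking logic, FDR control, determinism — not
field performance on any particular dataset.

# Numerical choices and degenerate inputs

* Row-sum validation tolerance 1e-6; renormalization only behind an
  explicit flag, so silently rescaling bad data is impossible.
* Pseudocount 1e-6 before the natural log (configurable); sample (n−1) SD
  in the SNR. Both recorded in provenance.
* `round()` (ties-to-even) for responder counts.
* All table writers emit full-precision (`%.15g`) values, so write→read
  round trips are lossless at double precision and identical inputs give
  byte-identical files — the property behind the CLI determinism guarantee.
* Genus lineage parsing accepts GreenGenes-style `g__` prefixes and plain
  semicolon-delimited ranks (genus = 6th field); empty, `g__`-only and
  `uncultured` genus fields pool into `unclassified`.

# Problem sizes in the test suite

The statistical checks use: 200+200 samples × 200 genera with 10 planted
genera (delta = 2, sigma = 1, 10% zeros) for recovery experiments; 50
replicate null datasets of 50+50 × 50 for FDR calibration (200 replicates)
and 500 null cohorts of 50 donors/50 patients for p-value uniformity; 50
donors × 3 timepoints at noise sigma = 0.3 (20 replicates) for metabolome
rank recovery; exact-permutation Kruskal–Wallis oracles on groups of total
size ≤ 8. These sizes make every Monte-Carlo bound tight enough to be
meaningful while keeping the full suite around a minute on one CPU.

# Known limitations

* Genus-level taxonomy cannot see strain- or species-level function; a
  donor can carry a butyrate-producing genus without producing butyrate.
  The metabolomics ranking exists precisely because of this gap.
* The power simulation inherits the effect-size structure of whatever
  case-control dataset it is given; power estimates at genus level likely
  overstate power for finer-grained (OTU/ASV/strain) discovery.
* The association test treats donor scores mapped through patients as
  independent observations (see above).
* `scfa_score` in raw platform units implicitly weights metabolites by
  their unit scale; use `standardize = TRUE` when units are incomparable.
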