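# fmtselect

Quantitative machinery for **rational donor selection in fecal microbiota
transplantation (FMT) trials**, and for asking how much a completed trial can
teach us about *which* donor taxa mattered.

FMT trials often fail or succeed for reasons hidden in donor heterogeneity.
`fmtselect` implements three complementary analyses a trial team can run
before and after an FMT study:

1. **Taxon-panel scoring** — quantify a named genus panel (by default, the
   dominant butyrate-producing genera) in donor stool as a summed relative
   abundance, and test whether donor panel abundance is associated with
   patient clinical response (two-sample *t*-test on donor scores grouped by
   the linked patient's outcome).
2. **Metabolomics-based donor ranking** — rank stool-bank donors on
   community *function* rather than taxonomy: mean short-chain fatty acid
   (SCFA) abundance (butyrate, isovalerate, propionate) and the bile-acid
   conversion ratio

   ratio = (lithocholate + deoxycholate) / (chenodeoxycholate + cholate),

   selecting donors in the top quantile (default top 25%, cutoff
   `ceiling(q·n)`) of **both** metrics.
3. **Retrospective-discovery power simulation** — given a case-control genus
   abundance dataset as an effect-size model, rank genera by signal-to-noise

   SNR_g = (mean log(a_g + ε) in cases − mean log(a_g + ε) in controls) / SD(log(a_g + ε), all samples),

   take the top-10 |SNR| genera as "true" hits, then repeatedly subsample
   simulated FMT arms (responders from cases, non-responders from controls),
   test every genus with a Kruskal–Wallis rank test, apply Benjamini–Hochberg
   FDR control, and count how many true hits are recovered at q < 0.05. The
   mean recovered count across replicates is the trial design's discovery
   power.

Synthetic-data generators with known ground truth (`make_case_control()`,
`make_metabolome()`, `make_trial_cohort()`) make every stage testable
end-to-end without any external downloads.

## Worked example

Simulate a case-control dataset with 10 planted differentially abundant
genera (a strong, diarrhea-like effect) and ask which FMT trial designs could
rediscover them:

```r
library(fmtselect)

gen <- make_case_control(case_control_spec(
  n_cases = 200, n_controls = 200, n_genera = 200, n_affected = 10,
  effect_delta = 2, sigma = 1, zero_prob = 0.1, seed = 42))
ds <- case_control_dataset(gen$table, gen$labels)

rk <- signal_to_noise(ds)
length(intersect(top_k_genera(rk, 10), gen$affected))
#> [1] 10        # all 10 planted genera top the SNR ranking

sim <- run_grid(ds,
                trial_grid(n_fmt = c(30, 100, 200),
                           response_rate = c(0.5, 0.9), n_reps = 25),
                master_seed = 42)
sim
#> FMT retrospective-discovery power simulation (6 designs, seed 42)
#>   dataset: 200 cases, 200 controls, 200 genera ranked (pseudocount 1e-06)
#>   mean recovered top hits per design:
#>  design n_fmt response_rate n_reps mean_recovered sd_recovered q25 median q75
#>       1    30           0.5     25           4.56         2.33   3      4   6
#>       2   100           0.5     25           9.96         0.20  10     10  10
#>       3   200           0.5     25          10.00         0.00  10     10  10
#>       4    30           0.9     25           0.00         0.00   0      0   0
#>       5   100           0.9     25           7.40         1.71   6      8   9
#>       6   200           0.9     25          10.00         0.00  10     10  10
```

Reading the summary: a 30-patient FMT arm recovers under half of the truly
differential genera even at a balanced 50% response rate, and essentially
nothing when 90% of patients respond (only 3 non-responders to compare
against); arms of 100–200 patients recover nearly all 10. Unbalanced
response rates cost real power at every arm size.

Ranking a synthetic 83-donor stool bank on community function:

```r
bank <- make_metabolome(metabolome_spec(n_donors = 83,
                                        n_timepoints_range = c(1, 3),
                                        sigma = 0.3, seed = 42))
ranking <- rank_donors(bank$table, q = 0.25)
ranking
#> Donor ranking: 83 donors, top-quantile cutoff rank 21 (q = 0.25)
#> Selected (top quantile of both metrics): donor_058, donor_001, donor_037,
#>   donor_062, donor_068, donor_046, donor_044
#>     donor_id scfa_score conversion_ratio scfa_rank conversion_rank selected
#> 1  donor_058   42.81728        12.127336         1               2     TRUE
#> 2  donor_001   18.76760        17.758937         7               1     TRUE
#> ...
```

The seven flagged donors sit in the top quartile of both SCFA production and
bile-acid conversion — the shortlist a trial team would take to their stool
bank.

A shell interface mirrors the R functions
(`inst/scripts/fmtselect convert|make-synthetic|score-taxa|rank-donors|simulate-power`);
all of its outputs are byte-identical across runs at a fixed seed.

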