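make_table <- function(rows, genera) {
  genus_table(matrix(rows, ncol = length(genera), byrow = TRUE,
                     dimnames = list(sprintf("s%d", seq_len(length(rows) /
                                                              length(genera))),
                                     genera)))
}

test_that("panel abundance sums panel genera, absent genera contribute 0", {
  gt <- make_table(c(0.2, 0.1, 0.7), c("Faecalibacterium", "Roseburia",
                                       "Bacteroides"))
  panel <- taxon_panel("bp", c("Faecalibacterium", "Roseburia"))
  expect_equal(unname(panel_abundance(gt, panel)), 0.3)

  # a panel genus absent from every sample contributes nothing
  panel2 <- taxon_panel("bp", c("Faecalibacterium", "Butyricicoccus"))
  expect_equal(unname(panel_abundance(gt, panel2)), 0.2)

  # matching is prefix/case-insensitive; "unclassified" never matches
  gt2 <- make_table(c(0.25, 0.35, 0.4), c("g__Roseburia", "UNCLASSIFIED",
                                          "unclassified"))
  expect_equal(unname(panel_abundance(gt2, taxon_panel("bp", "roseburia"))),
               0.25)

  expect_error(panel_abundance(gt, taxon_panel("none", character(0))),
               "empty")
})

test_that("panel abundance matches the loop-and-sum oracle and is monotone", {
  gt <- random_genus_table(20, 50, seed = 77)
  genera <- colnames(gt)
  set.seed(78)
  panel_genera <- sample(genera, 12)
  got <- panel_abundance(gt, taxon_panel("p", panel_genera))
  want <- vapply(rownames(gt), function(s)
    sum(vapply(panel_genera, function(g) unclass(gt)[s, g], numeric(1))),
    numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
  expect_true(all(got >= 0 & got <= 1))

  # adding a genus never decreases any sample's score
  for (extra in sample(setdiff(genera, panel_genera), 5)) {
    grown <- panel_abundance(gt, taxon_panel("p", c(panel_genera, extra)))
    expect_true(all(grown >= got - 1e-15))
  }
})

cohort_meta <- function(responses, donors) {
  sample_metadata(data.frame(
    sample_id = c(donors, sprintf("p%d", seq_along(responses))),
    role = rep(c("donor", "patient"), c(length(donors), length(responses))),
    study = "s",
    response = c(rep(NA, length(donors)), responses),
    linked_donor = c(rep(NA, length(donors)),
                     donors[seq_along(responses)])))
}

test_that("response association reproduces the pooled t-test", {
  donors <- sprintf("d%d", 1:6)
  meta <- cohort_meta(rep(c("response", "no_response"), each = 3), donors)
  scores <- setNames(c(0.1, 0.2, 0.3, 0.2, 0.3, 0.4), donors)
  res <- response_association(scores, meta)
  oracle <- pooled_t_oracle(c(0.1, 0.2, 0.3), c(0.2, 0.3, 0.4))
  expect_equal(res$t_statistic, oracle$t, tolerance = 1e-12)
  expect_equal(res$p_value, oracle$p, tolerance = 1e-12)
  expect_equal(unname(res$n_per_group), c(3L, 3L))

  # identical distributions: t = 0, p = 1
  same <- setNames(c(0.1, 0.2, 0.3, 0.1, 0.2, 0.3), donors)
  res0 <- response_association(same, meta)
  expect_equal(res0$t_statistic, 0)
  expect_equal(res0$p_value, 1)

  # label symmetry: swapping group labels negates t, preserves p
  flipped <- cohort_meta(rep(c("no_response", "response"), each = 3), donors)
  res_f <- response_association(scores, flipped)
  expect_equal(res_f$t_statistic, -res$t_statistic, tolerance = 1e-12)
  expect_equal(res_f$p_value, res$p_value, tolerance = 1e-12)
})

test_that("response association handles degenerate inputs as specified", {
  donors <- sprintf("d%d", 1:5)
  # one group with a single observation -> error
  meta_small <- cohort_meta(c("response", rep("no_response", 2)), donors[1:3])
  expect_error(response_association(setNames(c(0.1, 0.2, 0.3), donors[1:3]),
                                    meta_small), ">= 2")

  # zero pooled variance with unequal means -> p = 0 with a flag
  meta4 <- cohort_meta(rep(c("response", "no_response"), each = 2), donors[1:4])
  res <- response_association(setNames(c(0.4, 0.4, 0.1, 0.1), donors[1:4]),
                              meta4)
  expect_true(res$degenerate_variance)
  expect_equal(res$p_value, 0)

  # zero variance with equal means -> t = 0, p = 1
  res_eq <- response_association(setNames(rep(0.2, 4), donors[1:4]), meta4)
  expect_true(res_eq$degenerate_variance)
  expect_equal(res_eq$p_value, 1)
})

test_that("donor-patient differences subtract patient baseline from donor", {
  genera <- c("Faecalibacterium", "Other")
  gt <- genus_table(matrix(c(0.3, 0.7,
                             0.1, 0.9,
                             0.25, 0.75), 3, 2, byrow = TRUE,
                           dimnames = list(c("d1", "p1", "p2"), genera)))
  meta <- sample_metadata(data.frame(
    sample_id = c("d1", "p1", "p2"), role = c("donor", "patient", "patient"),
    study = "s", response = c(NA, "response", "no_response"),
    linked_donor = c(NA, "d1", "d1")))
  panel <- taxon_panel("bp", "Faecalibacterium")
  d <- donor_patient_difference(gt, panel, meta)
  expect_equal(d, c(p1 = 0.2, p2 = 0.05), tolerance = 1e-12)
  expect_true(all(d >= -1 & d <= 1))

  # donor equals patient -> 0
  gt_eq <- genus_table(matrix(c(0.3, 0.7, 0.3, 0.7), 2, 2, byrow = TRUE,
                              dimnames = list(c("d1", "p1"), genera)))
  meta_eq <- sample_metadata(data.frame(
    sample_id = c("d1", "p1"), role = c("donor", "patient"), study = "s",
    response = c(NA, "response"), linked_donor = c(NA, "d1")))
  expect_equal(unname(donor_patient_difference(gt_eq, panel, meta_eq)), 0)

  # missing link -> error naming the patient
  meta_bad <- sample_metadata(data.frame(
    sample_id = c("d1", "p1"), role = c("donor", "patient"), study = "s",
    response = c(NA, "response"), linked_donor = c(NA, NA)))
  expect_error(donor_patient_difference(gt_eq, panel, meta_bad), "p1")
})

test_that("donor-patient differences match the per-pair oracle on a random cohort", {
  panel <- default_butyrate_panel()
  gen <- make_trial_cohort(trial_cohort_spec(6, 18, panel_effect = 1,
                                             seed = 21), panel)
  d <- donor_patient_difference(gen$table, panel, gen$metadata)
  scores <- panel_abundance(gen$table, panel)
  pats <- gen$metadata[gen$metadata$role == "patient", ]
  for (i in seq_len(nrow(pats))) {
    expect_equal(d[[pats$sample_id[i]]],
                 scores[[pats$linked_donor[i]]] - scores[[pats$sample_id[i]]],
                 tolerance = 1e-12)
  }
})
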