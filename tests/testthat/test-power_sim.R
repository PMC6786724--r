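two_genus_dataset <- function(case_vals, control_vals, genus = "A") {
  # one genus of interest plus a filler genus absorbing the rest of each row
  vals <- c(case_vals, control_vals)
  ids <- sprintf("s%02d", seq_along(vals))
  m <- cbind(vals, 1 - vals)
  dimnames(m) <- list(ids, c(genus, "filler"))
  labels <- setNames(rep(c("case", "control"),
                         c(length(case_vals), length(control_vals))), ids)
  case_control_dataset(genus_table(m), labels)
}

test_that("signal-to-noise follows its closed-form definition", {
  pc <- 1e-6
  # abundances chosen so log(a + pc) hits -1, -1, -3, -3 exactly
  ds <- two_genus_dataset(exp(-1) - pc + c(0, 0), exp(-3) - pc + c(0, 0))
  rk <- signal_to_noise(ds, transform_config(pseudocount = pc))
  want <- (-1 - (-3)) / sd(c(-1, -1, -3, -3))
  expect_equal(rk$snr[rk$genus == "A"], want, tolerance = 1e-10)

  # identical case and control abundances -> snr 0 everywhere
  ds0 <- two_genus_dataset(c(0.2, 0.3), c(0.2, 0.3))
  rk0 <- signal_to_noise(ds0)
  expect_equal(rk0$snr, rep(0, nrow(rk0)))

  # a constant genus is excluded and reported
  m <- cbind(A = c(0.5, 0.5, 0.5, 0.5), B = c(0.2, 0.3, 0.25, 0.4))
  m <- cbind(m, filler = 1 - rowSums(m))
  rownames(m) <- sprintf("s%d", 1:4)
  dsc <- case_control_dataset(genus_table(m),
                              rep(c("case", "control"), each = 2))
  rkc <- signal_to_noise(dsc)
  expect_identical(attr(rkc, "excluded"), "A")
  expect_false("A" %in% rkc$genus)
})

test_that("signal-to-noise matches the per-genus oracle on a random dataset", {
  gen <- make_case_control(case_control_spec(25, 20, 30, 5, effect_delta = 1,
                                             sigma = 1, zero_prob = 0.15,
                                             seed = 44))
  ds <- case_control_dataset(gen$table, gen$labels)
  rk <- signal_to_noise(ds)
  for (g in sample(rk$genus, 10)) {
    expect_equal(rk$snr[rk$genus == g],
                 snr_oracle(unclass(gen$table)[, g], gen$labels),
                 tolerance = 1e-12)
  }
  # ordering is by |snr| descending
  expect_true(all(diff(abs(rk$snr)) <= 1e-15))
})

test_that("top-k selection takes the largest absolute SNR values", {
  gen <- make_case_control(case_control_spec(10, 10, 20, 3, effect_delta = 1,
                                             seed = 45))
  rk <- signal_to_noise(case_control_dataset(gen$table, gen$labels))
  # full-sort oracle
  want <- rk$genus[order(-abs(rk$snr), rk$genus)][1:7]
  expect_identical(top_k_genera(rk, 7), want)
  # fewer genera than k -> all returned
  expect_length(top_k_genera(rk, 100), nrow(rk))
  expect_error(top_k_genera(rk, 0), "positive")

  # signed magnitudes: A = -5 beats B = 3
  rk2 <- structure(data.frame(genus = c("A", "B"), snr = c(-5, 3)),
                   class = c("snr_ranking", "data.frame"))
  rk2 <- rk2[order(-abs(rk2$snr), rk2$genus), ]
  class(rk2) <- c("snr_ranking", "data.frame")
  expect_identical(top_k_genera(rk2, 1), "A")
})

test_that("trial subsampling draws the design's counts from the right classes", {
  gen <- make_case_control(case_control_spec(30, 25, 15, 3, effect_delta = 1,
                                             seed = 46))
  ds <- case_control_dataset(gen$table, gen$labels)

  # response_rate 1 -> all responders, no controls
  sub1 <- simulate_trial(ds, trial_design(10, 1), seed = 1)
  expect_equal(sum(sub1$labels == "responder"), 10L)
  expect_equal(sum(sub1$labels == "non_responder"), 0L)

  # infeasible requests error naming the class
  expect_error(simulate_trial(ds, trial_design(80, 0.5), seed = 1),
               "case|control")
  expect_error(simulate_trial(ds, trial_design(60, 0.9), seed = 1),
               "responders")

  # sampled ids are distinct and label-consistent across many draws
  d <- trial_design(20, 0.6)
  for (r in 1:200) {
    sub <- simulate_trial(ds, d, seed = r)
    ids <- names(sub$labels)
    expect_false(anyDuplicated(ids) > 0)
    resp <- ids[sub$labels == "responder"]
    nonresp <- ids[sub$labels == "non_responder"]
    expect_true(all(gen$labels[resp] == "case"))
    expect_true(all(gen$labels[nonresp] == "control"))
    expect_length(resp, d$n_responders)
    expect_length(nonresp, d$n_nonresponders)
  }
})

test_that("trial design arithmetic rounds responders ties-to-even", {
  d <- trial_design(10, 0.45)
  expect_equal(d$n_responders, 4L)  # round(4.5) ties to even
  d2 <- trial_design(10, 0.55)
  expect_equal(d2$n_responders, 6L)
  expect_error(trial_design(10, 0), "response_rate")
  expect_error(trial_design(1, 0.5), "non-responders|responders")
})

test_that("differential testing applies BH step-up over tested genera", {
  # module-level q-values equal the independent step-up oracle
  gen <- make_case_control(case_control_spec(20, 20, 25, 5, effect_delta = 1.5,
                                             zero_prob = 0.2, seed = 47))
  sub <- simulate_trial(case_control_dataset(gen$table, gen$labels),
                        trial_design(30, 0.5), seed = 2)
  dg <- differential_genera(sub$table, sub$labels)
  expect_equal(dg$stats$q, bh_oracle(dg$stats$p), tolerance = 1e-12)
  expect_setequal(dg$significant, dg$stats$genus[dg$stats$q < 0.05])

  # the worked step-up example
  expect_equal(bh_oracle(c(0.001, 0.02, 0.03, 0.9)),
               c(0.004, 0.04, 0.04, 0.9), tolerance = 1e-12)
  expect_equal(p.adjust(c(0.001, 0.02, 0.03, 0.9), method = "BH"),
               c(0.004, 0.04, 0.04, 0.9), tolerance = 1e-12)

  # both groups identical constant values -> nothing testable, nothing found
  m <- matrix(c(rep(0.4, 6), rep(0.6, 6)), 6, 2,
              dimnames = list(sprintf("s%d", 1:6), c("A", "B")))
  dg0 <- differential_genera(m, rep(c("responder", "non_responder"), each = 3))
  expect_length(dg0$significant, 0)
  expect_setequal(dg0$skipped, c("A", "B"))
})

test_that("Kruskal-Wallis p-values agree with the exact permutation oracle", {
  set.seed(48)
  for (i in 1:25) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    x <- round(runif(n1 + n2), sample(1:2, 1))  # rounding induces ties
    if (sd(x) == 0) next
    labels <- rep(c("responder", "non_responder"), c(n1, n2))
    m <- cbind(A = x / 2, filler = 1 - x / 2)
    rownames(m) <- sprintf("s%d", seq_along(x))
    dg <- differential_genera(m, labels, q_threshold = 0.05)
    oracle <- kw_exact_perm(x, labels)
    # the chi-square reference is asymptotic; agreement is bounded by the
    # discreteness of the exact null plus small-sample approximation slack
    expect_lt(abs(dg$stats$p[dg$stats$genus == "A"] - oracle$p),
              oracle$max_atom + 0.05)
  }
})

test_that("recovery count is the intersection size", {
  expect_equal(recovery_count(c("A", "B"), c("C", "D")), 0L)
  top <- sprintf("g%d", 1:10)
  expect_equal(recovery_count(c(top, "extra"), top), 10L)
  set.seed(49)
  for (i in 1:20) {
    sig <- sample(letters, sample(0:15, 1))
    top <- sample(letters, sample(1:10, 1))
    expect_equal(recovery_count(sig, top), sum(top %in% sig))
  }
})

test_that("run_grid is deterministic and validates feasibility up front", {
  gen <- make_case_control(case_control_spec(40, 40, 30, 5, effect_delta = 2,
                                             zero_prob = 0.1, seed = 50))
  ds <- case_control_dataset(gen$table, gen$labels)
  designs <- trial_grid(n_fmt = c(10, 20), response_rate = 0.5, n_reps = 5)
  a <- run_grid(ds, designs, master_seed = 7)
  b <- run_grid(ds, designs, master_seed = 7)
  expect_identical(a$results, b$results)
  expect_identical(a$provenance$dataset_hash, b$provenance$dataset_hash)
  expect_true(all(a$results$recovered <=
                    pmin(a$results$n_significant, a$results$top_k)))

  # infeasible designs fail before any simulation runs
  expect_error(run_grid(ds, trial_grid(n_fmt = c(10, 500),
                                       response_rate = 0.5, n_reps = 5),
                        master_seed = 7), "infeasible")
})
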