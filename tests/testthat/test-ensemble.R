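test_that("Fisher combination matches the chi-square oracle", {
  all_one <- fisher_combine(rep(1, 6))
  expect_equal(all_one$chi2, 0)
  expect_equal(all_one$p, 1)

  six <- fisher_combine(rep(0.05, 6))
  expect_equal(six$chi2, -12 * log(0.05), tolerance = 1e-12)
  expect_equal(six$df, 12L)
  expect_equal(six$p, pchisq(-12 * log(0.05), 12, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(six$p, 3.4e-4, tolerance = 0.02)

  single <- fisher_combine(0.37)
  expect_equal(single$p, 0.37, tolerance = 1e-12)

  set.seed(2)
  p <- runif(6)
  expect_equal(fisher_combine(p)$p, fisher_combine(rev(p))$p)
  expect_error(fisher_combine(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH adjustment reproduces the hand step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  set.seed(14)
  for (i in 1:20) {
    p <- runif(sample(3:30, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_equal(order(q[order(p)]), seq_along(p))  # monotone in p
  }
})

test_that("the ensemble flags a strongly rhythmic gene and returns one row per gene", {
  sim <- small_sim()
  study <- sim$study
  calls <- cached("small_calls_C", {
    call_rhythmic_genes(study, "C", n_perm = 400, seed = 5)
  })
  expect_equal(nrow(calls), nrow(study$values))
  expect_setequal(calls$gene_id, rownames(study$values))
  expect_true(all(calls$combined_p >= 0 & calls$combined_p <= 1))
  expect_true(all(calls$q >= calls$combined_p - 1e-12))
  # planted rhythmic genes at rel amplitude 0.5, cv 0.15: the clear
  # majority must be recovered
  planted <- sim$truth$gene_id[sim$truth$rhythmic_C]
  expect_gt(mean(planted %in% calls$gene_id[calls$rhythmic]), 0.8)
})

test_that("an all-flat study stays essentially unflagged", {
  cfg <- study_config(n_genes = 300, frac_rhythmic = c(C = 0, W = 0, WRF = 0),
                      n_de_genes = 0, noise_cv = 0.2, seed = 61)
  sim <- generate_study(cfg)
  calls <- call_rhythmic_genes(sim$study, "C", n_perm = 300, seed = 6)
  frac <- mean(calls$rhythmic)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / 300))
})

test_that("the Brown-style correction restores combined-p calibration on null data", {
  cfg <- study_config(n_genes = 800, frac_rhythmic = c(C = 0, W = 0, WRF = 0),
                      n_de_genes = 0, noise_cv = 0.2, seed = 73)
  sim <- generate_study(cfg)
  plain <- call_rhythmic_genes(sim$study, "C", n_perm = 300, seed = 7)
  brown <- call_rhythmic_genes(sim$study, "C", n_perm = 300, seed = 7,
                               brown = TRUE)
  # the six detectors are correlated, so plain Fisher over-rejects at
  # the nominal level while the moment-matched version stays close
  expect_gt(mean(plain$combined_p < 0.05), 0.09)
  expect_lt(abs(mean(brown$combined_p < 0.05) - 0.05), 0.04)
  expect_lte(sum(brown$rhythmic), 2)
})

test_that("missing groups are rejected", {
  sim <- small_sim()
  keep <- sim$study$samples$group != "W"
  crippled <- expr_study(sim$study$values[, keep],
                        sim$study$samples[keep, ])
  expect_error(call_rhythmic_genes(crippled, "W"), "W")
})

test_that("Venn regions agree with direct set algebra", {
  sets <- list(C = c("a"), W = c("b"), WRF = c("c"))
  ov <- overlap_rhythmic_sets(sets)
  expect_equal(sum(ov$n), 3L)
  expect_equal(ov$n[ov$region == "C&W"], 0L)

  same <- list(C = c("x", "y"), W = c("x", "y"), WRF = c("x", "y"))
  ov2 <- overlap_rhythmic_sets(same)
  expect_equal(ov2$n[ov2$region == "C&W&WRF"], 2L)
  expect_equal(sum(ov2$n), 2L)

  set.seed(20)
  for (i in 1:10) {
    u <- sprintf("g%02d", 1:40)
    sets <- list(C = sample(u, 15), W = sample(u, 10), WRF = sample(u, 20))
    ov <- overlap_rhythmic_sets(sets)
    expect_equal(sum(ov$n), length(unique(unlist(sets))))
    # inclusion-exclusion oracle for the triple region
    expect_equal(
      ov$n[ov$region == "C&W&WRF"],
      length(Reduce(intersect, sets))
    )
    # pairwise C&W exclusive region
    expect_equal(
      ov$n[ov$region == "C&W"],
      length(setdiff(intersect(sets$C, sets$W), sets$WRF))
    )
  }
})

test_that("phase histograms bin phases and preserve counts", {
  calls <- tibble::tibble(
    gene_id = sprintf("g%d", 1:10),
    group = factor("C", levels = c("C", "W", "WRF")),
    rhythmic = c(rep(TRUE, 7), rep(FALSE, 3)),
    phase = c(rep(12.0, 5), 3.2, 23.9, 1, 2, 3)
  )
  h <- phase_histogram(calls)
  expect_equal(sum(h$n), 7L)
  expect_equal(h$n[h$bin_start == 12], 5L)
  expect_equal(h$n[h$bin_start == 23], 1L)
  expect_error(phase_histogram(calls, n_bins = 7), "divide")
  h2 <- phase_histogram(calls, n_bins = 12)
  expect_equal(sum(h2$n), 7L)
})
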