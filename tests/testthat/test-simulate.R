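test_that("gene profiles follow the cosinor formula without noise", {
  truth <- flat_truth_row(baseline = 10)
  truth$amplitude_C <- 3
  truth$phase_C <- 9
  samples <- parse_sample_label(c("C1ZT9", "C2ZT21", "C3ZT3"))
  vals <- generate_gene_profile(truth, samples)
  expect_equal(vals[1], 13)  # cosine peak
  expect_equal(vals[2], 7)   # trough
  expect_equal(vals[3], 10 + 3 * cos(2 * pi * (3 - 9) / 24))
})

test_that("zero amplitude gives a constant profile scaled by the fold", {
  truth <- flat_truth_row(baseline = 8)
  truth$de_mult_WRF <- 2
  samples <- study_design()
  vals <- generate_gene_profile(truth, samples)
  expect_equal(unique(vals[samples$group == "C"]), 8)
  expect_equal(unique(vals[samples$group == "WRF"]), 16)
})

test_that("profiles are reproducible and reject invalid amplitudes", {
  truth <- flat_truth_row(baseline = 5, noise_cv = 0.3)
  truth$amplitude_W <- 2
  samples <- study_design()
  v1 <- withr::with_seed(9, generate_gene_profile(truth, samples))
  v2 <- withr::with_seed(9, generate_gene_profile(truth, samples))
  expect_identical(v1, v2)
  expect_true(all(v1 > 0))
  truth$amplitude_W <- 6
  expect_error(generate_gene_profile(truth, samples), "baseline")
})

test_that("generate_study builds the 54-sample design with ground truth", {
  cfg <- study_config(n_genes = 200, seed = 1)
  sim <- generate_study(cfg)
  expect_equal(dim(sim$study$values), c(200L, 54L))
  expect_equal(sort(unique(sim$study$samples$zt)), c(1, 5, 9, 13, 17, 21))
  expect_equal(as.integer(table(sim$study$samples$group)), c(18L, 18L, 18L))
  expect_equal(nrow(sim$truth), 200)
  sim2 <- generate_study(cfg)
  expect_identical(sim$study$values, sim2$study$values)
  expect_identical(sim$truth, sim2$truth)
})

test_that("zero rhythmic fractions plant only flat genes", {
  cfg <- study_config(n_genes = 50, frac_rhythmic = c(C = 0, W = 0, WRF = 0),
                      n_de_genes = 0, seed = 3)
  sim <- generate_study(cfg)
  expect_false(any(sim$truth$rhythmic_C | sim$truth$rhythmic_W |
                     sim$truth$rhythmic_WRF))
  expect_true(all(sim$truth$amplitude_C == 0))
})

test_that("noise-free group means equal the planted cosinor exactly", {
  cfg <- study_config(n_genes = 10, noise_cv = 0, n_de_genes = 0,
                      frac_rhythmic = c(C = 1, W = 1, WRF = 1),
                      replicate_phase_shift = 0, seed = 8)
  sim <- generate_study(cfg)
  samp <- sim$study$samples
  for (i in 1:5) {
    tr <- sim$truth[i, ]
    for (g in c("C", "WRF")) {
      idx <- samp$group == g
      expected <- tr$baseline +
        tr[[paste0("amplitude_", g)]] *
          cos(2 * pi * (samp$zt[idx] - tr[[paste0("phase_", g)]]) / 24)
      expect_equal(unname(sim$study$values[i, idx]), expected,
                   tolerance = 1e-12)
    }
  }
})

test_that("the shifted W replicate series runs out of phase", {
  cfg <- study_config(n_genes = 5, noise_cv = 0, n_de_genes = 0,
                      frac_rhythmic = c(C = 0, W = 1, WRF = 0),
                      replicate_phase_shift = 8, seed = 12)
  sim <- generate_study(cfg)
  samp <- sim$study$samples
  tr <- sim$truth[which(sim$truth$rhythmic_W)[1], ]
  i <- which(sim$truth$gene_id == tr$gene_id)
  shifted <- samp$group == "W" & samp$replicate_index == 2
  expected <- tr$baseline + tr$amplitude_W *
    cos(2 * pi * (samp$zt[shifted] - tr$phase_W - 8) / 24)
  expect_equal(unname(sim$study$values[i, shifted]), expected,
               tolerance = 1e-12)
})

test_that("responder gating confines the DE block to responder animals", {
  cfg <- study_config(n_genes = 60, noise_cv = 0, n_de_genes = 20,
                      de_up_fraction = 1, de_fold = 2,
                      frac_rhythmic = c(C = 0, W = 0, WRF = 0),
                      responder_fraction = 0.5, seed = 21)
  sim <- generate_study(cfg)
  samp <- sim$study$samples
  de_gene <- which(sim$truth$de_mult_WRF == 2)[1]
  wrf <- samp$group == "WRF"
  is_resp <- samp$animal_id %in% sim$responders
  base <- sim$truth$baseline[de_gene]
  expect_equal(unique(sim$study$values[de_gene, wrf & is_resp]), 2 * base)
  expect_equal(unique(sim$study$values[de_gene, wrf & !is_resp]), base)
})

test_that("module catalogs plant the requested enrichment", {
  genes <- sprintf("g%03d", 1:400)
  up <- genes[1:80]
  ms <- withr::with_seed(5, generate_module_catalog(
    genes, sizes = c(50, 60),
    planted_enrichment = list(M1 = 0.4), up_gene_set = up
  ))
  expect_equal(sum(ms$modules$M1 %in% up), 20)
  expect_setequal(names(ms$modules), c("M0", "M1", "M2"))
  expect_equal(length(ms$modules$M0), 400 - 110)
  expect_error(withr::with_seed(5, generate_module_catalog(
    genes, sizes = 50, planted_enrichment = list(M1 = 1),
    up_gene_set = genes[1:10]
  )), "up set")
})

test_that("unenriched modules match the background up-rate on average", {
  genes <- sprintf("g%03d", 1:300)
  up <- genes[1:60]  # background rate 0.2
  fracs <- vapply(1:100, function(s) {
    ms <- withr::with_seed(s, generate_module_catalog(
      genes, sizes = 50, up_gene_set = character()
    ))
    mean(ms$modules$M1 %in% up)
  }, 0)
  # binomial sampling: mean within 4 SEs of 0.2
  se <- sqrt(0.2 * 0.8 / (50 * 100))
  expect_lt(abs(mean(fracs) - 0.2), 4 * se)
})

test_that("disease gene sets respect the planted fold-change threshold", {
  cfg <- study_config(n_genes = 100, n_de_genes = 20, de_up_fraction = 0.5,
                      de_fold = 2, seed = 31)
  sim <- generate_study(cfg)
  planted_up <- sim$truth$gene_id[sim$truth$de_mult_WRF > 1]
  planted_down <- sim$truth$gene_id[sim$truth$de_mult_WRF < 1]
  pair <- withr::with_seed(1, generate_disease_gene_sets(
    sim$truth, n_up = length(planted_up), n_down = length(planted_down),
    shift_log2 = 0.5
  ))
  expect_setequal(pair$up_genes, planted_up)
  expect_setequal(pair$down_genes, planted_down)
  expect_length(intersect(pair$up_genes, pair$down_genes), 0)
  expect_error(withr::with_seed(1, generate_disease_gene_sets(
    sim$truth, n_up = 50, n_down = 0, shift_log2 = 0.5
  )), "qualify")
  # threshold zero: unrestricted draws
  pair0 <- withr::with_seed(2, generate_disease_gene_sets(
    sim$truth, n_up = 40, n_down = 40, shift_log2 = 0
  ))
  expect_length(pair0$up_genes, 40)
  expect_length(intersect(pair0$up_genes, pair0$down_genes), 0)
})
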