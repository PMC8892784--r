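test_that("module filtering crosses with the universe before sizing", {
  universe <- sprintf("u%03d", 1:500)
  ms <- module_set(list(
    M0 = universe[1:300],
    M1 = universe[301:349],                      # 49 in universe
    M2 = universe[351:400],                      # 50 in universe
    M3 = c(universe[401:430], sprintf("x%d", 1:40))  # 30 in universe
  ))
  filtered <- filter_modules(ms, universe, min_size = 50)
  expect_setequal(names(filtered$modules), c("M0", "M2"))
  expect_equal(length(filtered$modules$M2), 50)
  expect_error(filter_modules(ms, universe[1:40], min_size = 50), "M0")
})

test_that("module enrichment matches the hypergeometric tail", {
  universe <- sprintf("u%04d", 1:5050)
  m0 <- universe[1:5000]
  m1 <- universe[5001:5050]
  up <- c(sample(m0, 400), sample(m1, 20))
  ms <- module_set(list(M0 = m0, M1 = m1))
  stats <- module_enrichment(up, ms, universe)
  row <- stats[stats$module_id == "M1", ]
  expect_equal(row$percent_up, 40)
  expect_equal(row$fisher_p,
               oracle_hypergeom_tail(20, 50, sum(m0 %in% up), 5000),
               tolerance = 1e-12)
  expect_true(row$flagged)
})

test_that("Fisher's exact enrichment agrees with the tail sum on random tables", {
  set.seed(23)
  for (i in 1:100) {
    size <- sample(5:200, 1)
    m0_size <- sample(50:200, 1)
    universe <- sprintf("g%d", seq_len(size + m0_size))
    mod <- universe[seq_len(size)]
    m0 <- universe[size + seq_len(m0_size)]
    up <- sample(universe, sample.int(length(universe) - 1, 1))
    ms <- module_set(list(M0 = m0, M1 = mod))
    p <- module_enrichment(up, ms, universe)$fisher_p[2]
    expect_equal(p, oracle_hypergeom_tail(sum(mod %in% up), size,
                                          sum(m0 %in% up), m0_size),
                 tolerance = 1e-12)
  }
})

test_that("a module matching the background rate is not flagged", {
  set.seed(31)
  universe <- sprintf("u%04d", 1:2050)
  m0 <- universe[1:2000]
  m1 <- universe[2001:2050]
  up <- c(sample(m0, 200), sample(m1, 5))  # both at 10%
  ms <- module_set(list(M0 = m0, M1 = m1))
  stats <- module_enrichment(up, ms, universe)
  expect_false(stats$flagged[stats$module_id == "M1"])
  empty <- module_enrichment(character(), ms, universe)
  expect_equal(empty$percent_up, c(0, 0))
  expect_equal(empty$fisher_p[2], 1)
})

test_that("expression shifts are log2 median ratios with zero-median exclusion", {
  design <- study_design()
  vals <- matrix(3, 4, 54, dimnames = list(sprintf("g%d", 1:4),
                                           design$label))
  vals[1, design$group == "WRF"] <- 4
  vals[1, design$group == "C"] <- 2
  vals[2, design$group == "C"] <- 0  # zero median in C
  study <- expr_study(vals, design)
  ms <- module_set(list(M0 = c("g1", "g3", "g4")))
  shift <- module_expression_shift(study, ms, "WRF", "C")
  expect_equal(shift$ratios$log2_ratio[shift$ratios$gene_id == "g1"], 1)
  expect_equal(shift$n_excluded, 1L)
  expect_false("g2" %in% shift$ratios$gene_id)
})

test_that("a shifted module is flagged against M0 and a null module is not", {
  set.seed(55)
  design <- study_design()
  n <- 400
  base <- stats::rlnorm(n, log(10), 0.3)
  vals <- matrix(rep(base, 54), n, 54,
                 dimnames = list(sprintf("g%04d", 1:n), design$label))
  vals <- vals * exp(matrix(rnorm(n * 54, 0, 0.15), n, 54))
  shifted_genes <- 301:400
  vals[shifted_genes, design$group == "WRF"] <-
    vals[shifted_genes, design$group == "WRF"] * 2^0.5
  study <- expr_study(vals, design)
  genes <- rownames(vals)
  ms <- module_set(list(M0 = genes[1:200], M_null = genes[201:280],
                        M_shift = genes[shifted_genes]))
  shift <- module_expression_shift(study, ms, "WRF", "C")
  stats <- shift$stats
  expect_true(stats$flagged[stats$module_id == "M_shift"])
  expect_gt(stats$median_log2_ratio[stats$module_id == "M_shift"], 0.3)
  expect_false(stats$flagged[stats$module_id == "M_null"])
})

test_that("quantile normalization interpolates the empirical quantile function", {
  sorted <- sort(rnorm(500))
  expect_equal(quantile_normalize_distribution(sorted, 500), sorted,
               tolerance = 1e-12)
  expect_equal(quantile_normalize_distribution(rep(7, 10), 500),
               rep(7, 500))
  set.seed(77)
  big <- rnorm(1e6)
  q <- quantile_normalize_distribution(big, 500)
  expect_lt(max(abs(q - qnorm((1:500 - 0.5) / 500))), 0.02)
  expect_true(all(diff(q) >= 0))
  expect_error(quantile_normalize_distribution(3), "2")
})

test_that("the KS shift test sees shifts and ignores monotone transforms", {
  set.seed(88)
  bg <- rnorm(5000, 0, 1)
  same <- ks_shift_test(bg, bg)
  expect_equal(same$D, 0)
  expect_equal(same$ks_p, 1)
  shifted <- ks_shift_test(bg, rnorm(200, 0.25, 1))
  expect_lt(shifted$ks_p, 0.01)
  sub <- sample(bg, 300)
  d1 <- ks_shift_test(bg, sub)$D
  d2 <- ks_shift_test(exp(bg), exp(sub))$D
  expect_equal(d1, d2, tolerance = 1e-9)
  expect_error(ks_shift_test(bg, 1), "2")
})

test_that("null KS flag rates stay near nominal for adequately sized subsets", {
  set.seed(91)
  bg <- rnorm(3000)
  # subsets near the quantile count: calibrated to conservative
  ps <- vapply(1:200, function(i) {
    ks_shift_test(bg, sample(bg, 500))$ks_p
  }, 0)
  expect_lte(mean(ps < 0.05), 0.07)
  # well below the quantile count the fixed effective n inflates the
  # rate somewhat; it must stay bounded (see methods vignette)
  ps_small <- vapply(1:200, function(i) {
    ks_shift_test(bg, sample(bg, 150))$ks_p
  }, 0)
  expect_lte(mean(ps_small < 0.05), 0.3)
})

test_that("disease signature scoring labels up and down sets", {
  sim <- small_sim()
  ms <- module_set(list(M0 = sim$truth$gene_id[1:80]))
  shift <- module_expression_shift(sim$study, ms, "WRF", "C")
  pair <- gene_set_pair(sim$truth$gene_id[81:100],
                        sim$truth$gene_id[101:120], label = "ICM")
  res <- disease_signature_shift(shift, pair)
  expect_equal(res$label, c("ICM_up", "ICM_down"))
  expect_true(all(lengths(res$quantiles) == 500))
})
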