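test_that("pearson panel matches the closed-form oracle and flags degeneracy", {
  p <- lactodim:::pearson_r_p(1:5, c(2, 1, 4, 3, 6))
  expect_equal(p$r, 0.8219949, tolerance = 1e-6)
  expect_equal(p$p_value, 0.08770665, tolerance = 1e-6)
  # brute-force covariance/variance agreement and cor.test cross-check
  withr::with_seed(21, {
    for (i in 1:10) {
      x <- rnorm(12); y <- rnorm(12)
      r <- lactodim:::pearson_r_p(x, y)
      expect_equal(r$r, cov(x, y) / sqrt(var(x) * var(y)), tolerance = 1e-12)
      ct <- cor.test(x, y)
      expect_equal(r$r, unname(ct$estimate), tolerance = 1e-12)
      expect_equal(r$p_value, ct$p.value, tolerance = 1e-12)
    }
  })
  degen <- lactodim:::pearson_r_p(rep(1, 5), rnorm(5))
  expect_true(degen$degenerate)
  expect_true(is.na(degen$r))
  expect_error(lactodim:::pearson_r_p(1:2, 1:2), "at least 3")
})

test_that("group-stratified panels recover planted male-only correlations", {
  ds <- sim_small_dataset(seed = 8)
  lg <- log2_transform(median_normalize(ds$em))
  panel <- c("ADAMTS6", "AURKB", "CCNB1", "CENPE", "PTTG1")
  male <- pearson_panel(lg, ds$cohort, "CTAG2", panel,
                        group = function(s) s$sex == "M")
  female <- pearson_panel(lg, ds$cohort, "CTAG2", panel,
                          group = function(s) s$sex == "F")
  expect_gt(mean(male$pearson_r), 0.5)      # planted target r = 0.8 in men
  expect_lt(mean(abs(female$pearson_r)), 0.5)
  # the pairwise latent coupling hits the target r in expectation
  est <- vapply(1:100, function(s) {
    withr::with_seed(s, {
      z <- rnorm(20)
      a <- lactodim:::latent_coupling_pair(z, 0.8, 0.25) + rnorm(20, 0, 0.25)
      b <- lactodim:::latent_coupling_pair(z, 0.8, 0.25) + rnorm(20, 0, 0.25)
    })
    cor(a, b)
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.8), 0.05)
  self <- pearson_panel(lg, ds$cohort, "CTAG2", "CTAG2")
  expect_equal(self$pearson_r, 1)
  expect_equal(self$p_value, 0)
  expect_error(pearson_panel(lg, ds$cohort, "CTAG2", "NOPE"), "not in matrix")
})

test_that("gained-region integration recovers exactly the planted 19p panel", {
  cfg <- noise_free_config()
  co <- simulate_cohort(cfg)
  ann <- simulate_annotation(cfg)
  em <- simulate_expression(cfg, co, ann)
  lg <- log2_transform(median_normalize(em))
  de <- select_deregulated(lg, co)
  cp <- simulate_cna_profiles(cfg, co)
  segs <- call_segments(segment_profiles(cp, co))
  cand <- gained_region_candidates(de, segs, ann, co, aggressive_male)
  planted_truth <- c("CRB3", "FAM138F", "MATK", "STAP2")
  expect_setequal(cand$symbol, planted_truth)
  expect_true(all(cand$fold_change >= 2 & cand$p_value <= 0.05))
  expect_true(all(cand$n_supporting == sum(aggressive_male(co))))
  # invariance to segment and sample order
  perm <- segs[sample(nrow(segs)), ]
  cand2 <- gained_region_candidates(de, perm, ann, co, aggressive_male)
  expect_equal(cand2, cand)
  # raising min_samples never grows the list
  cand_hi <- gained_region_candidates(de, segs, ann, co, aggressive_male,
                                      min_samples = sum(aggressive_male(co)) + 1)
  expect_equal(nrow(cand_hi), 0)
})

test_that("integration excludes genes outside gains or above alpha", {
  ann <- validate_annotation(data.frame(
    symbol = c("IN_GAIN", "OUT_GAIN", "HIGH_P"),
    chromosome = c("19", "2", "19"), arm = c("p", "q", "p"),
    start = c(1e6, 1e6, 2e6), end = c(1.1e6, 1.1e6, 2.1e6),
    stringsAsFactors = FALSE))
  de <- data.frame(symbol = c("IN_GAIN", "OUT_GAIN", "HIGH_P"),
                   fold_change = c(3, 3, 3), p_value = c(0.01, 0.01, 0.2),
                   stringsAsFactors = FALSE)
  samples <- validate_sample_sheet(data.frame(
    sample_id = "S1", sex = "M", grade = "2b", invasive = TRUE,
    era_ir_score = NA_integer_, tumor_size_mm = NA_real_,
    clinical_behavior = "recurrence", stringsAsFactors = FALSE))
  segs <- data.frame(sample_id = "S1", chromosome = "19", arm_label = "p",
                     start = 5e5, end = 3e6, n_probes = 10, mean_copies = 3.3,
                     baseline = 2, call = "gain", stringsAsFactors = FALSE)
  cand <- gained_region_candidates(de, segs, ann, samples, rep(TRUE, 1))
  expect_equal(cand$symbol, "IN_GAIN")
})

test_that("category cross-tabulation marks memberships and the cross subset", {
  genes <- data.frame(symbol = c("A", "B", "C"), fold_change = c(2, 3, -2),
                      p_value = c(0.01, 0.02, 0.03), stringsAsFactors = FALSE)
  onc <- data.frame(symbol = c("A", "B"),
                    category = c("cell movement", "cell growth"))
  pit <- data.frame(symbol = c("A"), category = c("estrogen signaling"))
  tab <- category_crosstab(genes, onc, pit)
  expect_true(tab$in_cross_subset[tab$symbol == "A"])
  expect_false(tab$in_cross_subset[tab$symbol == "B"])  # oncology only
  expect_false(tab$in_cross_subset[tab$symbol == "C"])  # unmapped, empty marks

  maps <- curated_category_maps()
  cur <- category_crosstab(curated_gene_categories()[, 1:4],
                           maps$oncology, maps$pituitary)
  expect_true(cur$in_cross_subset[cur$symbol == "STAP2"])
  expect_true(all(cur$in_cross_subset))  # the published 32 are all cross-list
})
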