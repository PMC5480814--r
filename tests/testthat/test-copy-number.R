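test_that("region means and background medians match hand arithmetic and oracles", {
  ann <- toy_annotation()
  prof <- coverage_profile("s1", c(10, 10, 10, 20, rep(0, 996)),
                           c(e1 = 8, e2 = 10, e3 = 12))
  small <- repeat_annotation(data.frame(name = "r", start = 0, end = 4,
                                        transcribed = TRUE),
                             unit_length = 1000)
  expect_equal(region_mean_coverage(prof, small, "r"), 12.5)
  zero <- coverage_profile("z", rep(0, 1000), c(e1 = 1))
  expect_equal(region_mean_coverage(zero, ann, "18S"), 0)
  expect_error(region_mean_coverage(prof, ann, "nope"), "unknown region")

  # random profile against a direct-summation oracle
  set.seed(1)
  rp <- coverage_profile("r", runif(1000, 0, 50), c(e1 = 1))
  i <- which(ann$name == "28S")
  acc <- 0
  for (p in (ann$start[i] + 1):ann$end[i]) acc <- acc + rp$depth[p]
  expect_equal(region_mean_coverage(rp, ann, "28S"),
               acc / (ann$end[i] - ann$start[i]))

  # median conventions: odd, even (midpoint), and a sort-based oracle
  cat3 <- toy_catalog(c(e1 = 8, e2 = 10, e3 = 12))
  expect_equal(background_coverage(prof, cat3), 10)
  prof4 <- coverage_profile("s4", rep(1, 1000),
                            c(e1 = 8, e2 = 10, e3 = 12, e4 = 14))
  expect_equal(background_coverage(prof4, toy_catalog(prof4$exon_means)), 11)
  set.seed(2)
  em <- setNames(runif(1001, 5, 50), paste0("e", 1:1001))
  profn <- coverage_profile("sn", rep(1, 1000), em)
  expect_equal(background_coverage(profn, toy_catalog(em)),
               unname(sort(em)[501]))
})

test_that("copy number estimation is exact on noiseless input and scale invariant", {
  ann <- toy_annotation()
  # region mean 1000, background 10, factor 2 -> CN 200
  prof <- coverage_profile("s", rep(1000, 1000),
                           setNames(rep(10, 5), paste0("e", 1:5)))
  est <- estimate_copy_number(prof, ann, toy_catalog(prof$exon_means))
  expect_equal(unname(est$cn), c(200, 200, 200))

  # zero region coverage gives CN 0
  prof0 <- coverage_profile("s0", rep(0, 1000),
                            setNames(rep(10, 3), paste0("e", 1:3)))
  est0 <- estimate_copy_number(prof0, ann, toy_catalog(prof0$exon_means))
  expect_equal(unname(est0$cn), c(0, 0, 0))

  # background 0 is an error
  profb <- coverage_profile("sb", rep(5, 1000),
                            setNames(rep(0, 3), paste0("e", 1:3)))
  expect_error(estimate_copy_number(profb, ann, toy_catalog(profb$exon_means)),
               "background")

  # scale invariance: depth * constant leaves the estimate unchanged
  set.seed(3)
  d <- runif(1000, 10, 100)
  em <- setNames(runif(7, 20, 40), paste0("e", 1:7))
  cat7 <- toy_catalog(em)
  e1 <- estimate_copy_number(coverage_profile("a", d, em), ann, cat7)
  e2 <- estimate_copy_number(coverage_profile("a", 3.7 * d, 3.7 * em),
                             ann, cat7)
  expect_equal(e1$cn, e2$cn)
})

test_that("copy number recovery from simulated truth is accurate at depth 30", {
  cfg <- small_config(projects = "p1", n_pairs = 1,
                      positive_projects = character(0),
                      normal_cn_mean = 156, normal_cn_sd = 0, loss = 0,
                      depth = 30, dispersion = 0.1, n_exons = 300,
                      annotation = scaled_annotation(4300L))
  ests <- vapply(1:20, function(s) {
    cfg$seed <- s
    truth <- simulate_truth(cfg)
    prof <- simulate_coverage(truth, cfg)[["pair001_N"]]
    estimate_copy_number(prof, cfg$annotation, truth$catalog)$cn[["18S"]]
  }, numeric(1))
  expect_lt(abs(mean(ests) / 156 - 1), 0.05)
})

test_that("paired deltas subtract exactly and are antisymmetric", {
  ann <- toy_annotation()
  mk <- function(id, level) {
    em <- setNames(rep(10, 5), paste0("e", 1:5))
    estimate_copy_number(coverage_profile(id, rep(level, 1000), em),
                         ann, toy_catalog(em))
  }
  tum <- mk("t", 1600); nor <- mk("n", 2000)  # CN 320 vs 400
  d <- paired_normalized_cn(tum, nor, "pr1")
  expect_equal(d$delta_18S, -80)
  expect_equal(d$delta_28S, -80)
  d0 <- paired_normalized_cn(nor, nor)
  expect_equal(d0$delta_18S, 0)
  # antisymmetry
  rev <- paired_normalized_cn(nor, tum)
  expect_equal(rev$delta_18S, -d$delta_18S)
  # mismatched ploidy convention is rejected
  nor2 <- nor; nor2$ploidy_factor <- 4
  expect_error(paired_normalized_cn(tum, nor2), "ploidy")
})

test_that("cohort loss test handles degenerate inputs and has calibrated error rates", {
  zeros <- data.frame(delta_18S = rep(0, 5))
  r0 <- cohort_loss_test(zeros, "18S")
  expect_equal(r0$p_value, 1)
  expect_equal(r0$statistic, 0)
  const <- data.frame(delta_18S = rep(-5, 5))
  rc <- cohort_loss_test(const, "18S")
  expect_equal(rc$p_value, 0)
  expect_true(rc$degenerate)

  # power: N(-80, 20^2), n = 13 rejects at 0.01 nearly always
  set.seed(4)
  rej <- vapply(1:100, function(i) {
    cohort_loss_test(rnorm(13, -80, 20))$p_value < 0.01
  }, logical(1))
  expect_gte(mean(rej), 0.95)

  # type-I error at alpha = 0.05 under the null
  set.seed(5)
  rej0 <- vapply(1:1000, function(i) {
    cohort_loss_test(rnorm(10, 0, 20))$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej0), 0.03)
  expect_lt(mean(rej0), 0.07)

  # wilcoxon alternative runs and agrees on the obvious case
  expect_lt(cohort_loss_test(rnorm(20, -80, 5), method = "wilcoxon")$p_value,
            0.01)
})

test_that("region correlations reflect shared copy-number structure", {
  ann <- toy_annotation()
  em <- setNames(rep(10, 5), paste0("e", 1:5))
  cat5 <- toy_catalog(em)
  # one truth CN drives all three regions: all correlations 1
  ests <- lapply(seq(100, 500, by = 100), function(cn) {
    estimate_copy_number(coverage_profile(paste0("s", cn),
                                          rep(cn * 5, 1000), em),
                         ann, cat5)
  })
  r <- region_correlation(ests)
  expect_equal(unname(r), matrix(1, 3, 3))

  # independent random region values: off-diagonals near 0
  set.seed(6)
  ests2 <- lapply(1:1000, function(i) {
    structure(list(sample_id = i,
                   cn = setNames(runif(3, 100, 500), c("18S", "5.8S", "28S")),
                   background = 1, ploidy_factor = 2), class = "cn_estimate")
  })
  r2 <- region_correlation(ests2)
  expect_true(all(abs(r2[upper.tri(r2)]) < 0.1))
})

test_that("chromosome coverage matrix recovers euploidy and planted trisomy", {
  n <- 200
  ids <- sprintf("e%03d", 1:n)
  cat_df <- exon_catalog(data.frame(
    exon_id = ids, chromosome = paste0("chr", rep_len(1:4, n)),
    start = seq_len(n) * 1000L, end = seq_len(n) * 1000L + 500L,
    gene = paste0("g", 1:n)))
  set.seed(7)
  base <- setNames(rnorm(n, 30, 0.5), ids)
  eu <- coverage_profile("eu", rep(30, 10), base)
  m <- chromosome_coverage_matrix(list(eu), cat_df)
  expect_true(all(abs(m - 2) < 0.2))

  tri_means <- base
  tri_means[cat_df$exon_id[cat_df$chromosome == "chr3"]] <-
    base[cat_df$exon_id[cat_df$chromosome == "chr3"]] * 1.5
  tri <- coverage_profile("tri", rep(30, 10), tri_means)
  m2 <- chromosome_coverage_matrix(list(tri), cat_df)
  expect_equal(unname(m2["tri", "chr3"]), 3, tolerance = 0.05)
  expect_true(all(abs(m2[, c("chr1", "chr2", "chr4")] - 2) < 0.2))
})
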