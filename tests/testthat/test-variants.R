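test_that("SNV calling follows the majority rule and the strict >20 quality filter", {
  ref <- toy_reference(1000, "A")
  # match: no SNV
  expect_equal(nrow(call_snvs(toy_pileup(10, "A", A = 30), ref)), 0)
  # forced call at quality 30
  s <- call_snvs(toy_pileup(10, "A", G = 30, qual = 30), ref)
  expect_equal(s$alt, "G")
  expect_true(s$pass)
  # quality exactly 20 is filtered (strictly greater than 20 required)
  s20 <- call_snvs(toy_pileup(10, "A", G = 30, qual = 20), ref)
  expect_false(s20$pass)
  s21 <- call_snvs(toy_pileup(10, "A", G = 30, qual = 21), ref)
  expect_true(s21$pass)
  # depth below the floor fails
  s_thin <- call_snvs(toy_pileup(10, "A", G = 5, qual = 30), ref)
  expect_false(s_thin$pass)
  # tie between ref and alt resolves to ref: no call
  expect_equal(nrow(call_snvs(toy_pileup(10, "A", A = 15, G = 15), ref)), 0)
  # tie between two alts resolves alphabetically
  s_tie <- call_snvs(toy_pileup(10, "A", C = 12, G = 12, A = 6), ref)
  expect_equal(s_tie$alt, "C")
  # positions outside the reference are an error
  expect_error(call_snvs(toy_pileup(5000, "A", G = 30), ref), "outside")
})

test_that("pair classification separates shared and unique SNVs by alt identity", {
  ref <- toy_reference()
  mk <- function(pos, alt) {
    p <- toy_pileup(pos, "A")
    for (i in seq_along(pos)) p[i, alt[i]] <- 30
    call_snvs(p, ref)
  }
  t_calls <- mk(c(10, 20, 30, 40), c("G", "G", "C", "T"))
  n_calls <- mk(c(10, 20, 50, 40), c("G", "G", "C", "G"))
  cl <- classify_pair(t_calls, n_calls)
  expect_equal(cl$shared, c(10, 20))
  expect_equal(cl$tumor_unique, c(30, 40))  # 40: different alt in both
  expect_equal(cl$normal_unique, c(40, 50))
  # disjoint within each genome and symmetric under role swap
  expect_length(intersect(cl$shared, cl$tumor_unique), 0)
  sw <- classify_pair(n_calls, t_calls)
  expect_equal(sw$shared, cl$shared)
  expect_equal(sw$tumor_unique, cl$normal_unique)
  expect_equal(sw$normal_unique, cl$tumor_unique)
  # identical call sets: all shared
  cli <- classify_pair(t_calls, t_calls)
  expect_length(cli$tumor_unique, 0)
  expect_equal(cli$shared, sort(t_calls$position))
})

test_that("planted SNVs are recovered exactly with zero error rate", {
  cfg <- small_config(error_rate = 0, n_shared = 10, n_tumor_unique = 3,
                      n_normal_unique = 2, seed = 17)
  truth <- simulate_truth(cfg)
  for (pid in c("pair001", "pair004")) {
    pt <- simulate_pileup(truth, pid, "tumor", cfg)
    pn <- simulate_pileup(truth, pid, "normal", cfg)
    st <- call_snvs(pt, truth$reference)
    sn <- call_snvs(pn, truth$reference)
    cl <- classify_pair(st, sn)
    plant <- truth$snvs[truth$snvs$pair_id == pid, ]
    expect_equal(cl$shared, sort(plant$position[plant$class == "shared"]))
    expect_equal(cl$tumor_unique,
                 sort(plant$position[plant$class == "tumor_unique"]))
    expect_equal(cl$normal_unique,
                 sort(plant$position[plant$class == "normal_unique"]))
    # sensitivity 1, false calls 0
    expect_equal(sum(st$pass), sum(plant$fraction_tumor > 0))
  }
})

test_that("per-region densities match hand arithmetic and sum to the total", {
  ann <- repeat_annotation(data.frame(name = c("A", "B"),
                                      start = c(0, 2000),
                                      end = c(2000, 3000),
                                      transcribed = c(TRUE, FALSE)))
  d <- snv_density_by_region(c(10, 20, 30, 40, 50), ann)
  expect_equal(d$snvs_per_kb[d$region == "A"], 2.5)
  expect_equal(d$snvs_per_kb[d$region == "B"], 0)
  d0 <- snv_density_by_region(numeric(0), ann)
  expect_true(all(d0$snvs_per_kb == 0))
  # sum over regions of density * kb equals the SNV count
  set.seed(18)
  pos <- sample(0:2999, 120)
  dr <- snv_density_by_region(pos, ann)
  expect_equal(sum(dr$snvs_per_kb * dr$length_bp / 1000), 120)
  # uniform plant gives comparable densities across regions
  expect_lt(abs(dr$snvs_per_kb[1] - dr$snvs_per_kb[2]),
            5 * sqrt(120 / 3))
})

test_that("hotspot summaries count recurrence across genomes", {
  hs <- hotspot_positions(list(g1 = c(100), g2 = c(100), g3 = c(200)))
  expect_equal(hs$counts, c(`100` = 2L, `200` = 1L))
  expect_equal(hs$total_snvs, 3L)
  expect_equal(hs$n_positions, 2L)
  empty <- hotspot_positions(list())
  expect_equal(empty$total_snvs, 0L)
  # planted recurrence: 189 SNVs over 22 positions
  set.seed(19)
  positions <- sample(7000:12000, 22)
  sets <- split(sample(positions, 189, replace = TRUE), rep(1:27, 7))
  hs2 <- hotspot_positions(sets)
  expect_equal(hs2$total_snvs, 189L)
  expect_lte(hs2$n_positions, 22L)
})

test_that("allele counting applies the support rule and its invariances", {
  expect_equal(allele_count(c(50, 0, 0, 0)), 1L)
  expect_equal(allele_count(c(50, 0, 50, 0)), 2L)
  expect_equal(allele_count(c(97, 0, 2, 1)), 1L)
  expect_error(allele_count(c(0, 0, 0, 0)), "zero depth")
  # scaling all counts by a positive integer leaves the count unchanged
  # (support rule held fixed relative to depth via min_reads = 0)
  set.seed(20)
  for (i in 1:20) {
    cnt <- rmultinom(1, 60, runif(4))[, 1]
    if (sum(cnt) == 0) next
    expect_equal(allele_count(cnt, min_reads = 0),
                 allele_count(cnt * 7L, min_reads = 0))
  }
  # enumeration oracle over modest-depth tables
  for (i in 1:200) {
    cnt <- rmultinom(1, sample(1:20, 1), runif(4))[, 1]
    if (sum(cnt) == 0) next
    expect_equal(allele_count(cnt), allele_count_oracle(cnt))
  }
})

test_that("allele differences average the shared-position allele numbers", {
  # tumor has 2 alleles at each of 10 shared positions, normal has 1
  pos <- seq(10, 100, by = 10)
  pt <- toy_pileup(pos, "A", A = 30, G = 70)
  pn <- toy_pileup(pos, "A", G = 100)
  ad <- allele_difference(pt, pn, pos)
  expect_equal(ad$abar_tumor, 2)
  expect_equal(ad$abar_normal, 1)
  expect_equal(ad$delta, 1.0)
  # identical pileups give delta 0
  ad0 <- allele_difference(pt, pt, pos)
  expect_equal(ad0$delta, 0)
  # empty shared set warns and returns NA
  expect_warning(adN <- allele_difference(pt, pn, integer(0)), "empty")
  expect_true(is.na(adN$delta))
})

test_that("project-level allele tests are calibrated", {
  expect_equal(project_allele_test(rep(0, 6))$p_value, 1)
  set.seed(21)
  rej <- vapply(1:200, function(i) {
    project_allele_test(rnorm(14, 0.3, 0.1))$p_value < 0.01
  }, logical(1))
  expect_gte(mean(rej), 0.95)
  rej0 <- vapply(1:1000, function(i) {
    project_allele_test(rnorm(14, 0, 0.1))$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej0), 0.03)
  expect_lt(mean(rej0), 0.07)
})
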