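# helper: build an exon_copy_matrix directly from a samples x exons
# matrix of normalized copy numbers
ecm_from_matrix <- function(cn, samples) {
  structure(list(cn = cn, samples = samples), class = "exon_copy_matrix")
}

null_samples <- function(n_pairs, project = "p1") {
  data.frame(sample_id = c(paste0("pr", seq_len(n_pairs), "_T"),
                           paste0("pr", seq_len(n_pairs), "_N")),
             pair_id = rep(paste0("pr", seq_len(n_pairs)), 2),
             project = project,
             role = rep(c("tumor", "normal"), each = n_pairs))
}

test_that("per-exon paired tests are exact under the null and powered on planted effects", {
  n_pairs <- 20; n_exons <- 50
  s <- null_samples(n_pairs)
  set.seed(10)
  normal <- matrix(2 + rnorm(n_pairs * n_exons, 0, 0.1), n_pairs, n_exons)
  # tumor identical to normal: every p is exactly 1
  cn_id <- rbind(normal, normal)
  dimnames(cn_id) <- list(s$sample_id, sprintf("x%02d", 1:n_exons))
  tt <- per_exon_paired_test(ecm_from_matrix(cn_id, s))
  expect_true(all(tt$p == 1))
  expect_true(all(tt$t == 0))

  # +1 copy planted in one exon across all tumors: p < 1e-6 there
  tumor <- normal + matrix(rnorm(n_pairs * n_exons, 0, 0.1), n_pairs)
  tumor[, 1] <- tumor[, 1] + 1
  cn <- rbind(tumor, normal)
  dimnames(cn) <- dimnames(cn_id)
  tt2 <- per_exon_paired_test(ecm_from_matrix(cn, s))
  expect_lt(tt2$p[tt2$exon_id == "x01"], 1e-6)
  expect_gt(tt2$mean_delta[tt2$exon_id == "x01"], 0.5)

  # agreement with stats::t.test on each exon
  for (j in c(1, 7, 23)) {
    ht <- t.test(tumor[, j], normal[, j], paired = TRUE)
    row <- tt2[tt2$exon_id == sprintf("x%02d", j), ]
    expect_equal(row$t, unname(ht$statistic))
    expect_equal(row$p, ht$p.value)
  }
})

test_that("null paired-test p values are approximately uniform", {
  n_pairs <- 10; n_exons <- 1000
  s <- null_samples(n_pairs)
  set.seed(11)
  cn <- matrix(2 + rnorm(2 * n_pairs * n_exons, 0, 0.1), 2 * n_pairs)
  dimnames(cn) <- list(s$sample_id, sprintf("x%04d", 1:n_exons))
  tt <- per_exon_paired_test(ecm_from_matrix(cn, s))
  expect_gt(stats::ks.test(tt$p, "punif")$p.value, 0.01)
})

test_that("bh_fdr matches the brute-force step-up definition", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(12)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_fdr(p), bh_brute_force(p))
  }
  # order invariance: permute and unpermute
  p <- runif(100)
  perm <- sample(100)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
})

test_that("significant-exon selection is monotone in the threshold", {
  tab <- structure(data.frame(exon_id = sprintf("x%02d", 1:20),
                              project = "p1", t = 0,
                              p = seq(0.001, 0.999, length.out = 20),
                              q = seq(0.001, 0.999, length.out = 20),
                              mean_delta = 0, n_pairs = 5),
                   class = c("exon_test_table", "data.frame"))
  expect_equal(select_significant(tab, 0), character(0))
  all_q1 <- tab; all_q1$q <- 1
  expect_equal(select_significant(all_q1, 0.05), character(0))
  sets <- lapply(c(0.05, 0.2, 0.5, 1), function(th) {
    select_significant(tab, th)
  })
  for (i in 1:3) expect_true(all(sets[[i]] %in% sets[[i + 1]]))
})

test_that("FDR is controlled empirically over null cohorts", {
  n_pairs <- 6; n_exons <- 200
  s <- null_samples(n_pairs)
  set.seed(13)
  frac <- vapply(1:200, function(i) {
    cn <- matrix(2 + rnorm(2 * n_pairs * n_exons, 0, 0.1), 2 * n_pairs)
    dimnames(cn) <- list(s$sample_id, sprintf("x%04d", 1:n_exons))
    tt <- per_exon_paired_test(ecm_from_matrix(cn, s))
    length(select_significant(tt, 0.05)) / n_exons
  }, numeric(1))
  expect_lte(mean(frac), 0.05)
})

test_that("clustering separates planted patterns and finds the gain cluster", {
  # all rows identical: one cluster
  same <- matrix(1, nrow = 5, ncol = 3,
                 dimnames = list(paste0("e", 1:5), paste0("p", 1:3)))
  cl <- cluster_exons(same, k = 4)
  expect_equal(length(unique(cl$assignments)), 1L)

  # two orthogonal planted patterns separate exactly at k = 2
  pat <- rbind(matrix(rep(c(1, 0), each = 10), 10, 2),
               matrix(rep(c(0, 1), each = 10), 10, 2))
  dimnames(pat) <- list(sprintf("e%02d", 1:20), c("pos", "neg"))
  cl2 <- cluster_exons(pat, k = 2, positive_projects = "pos")
  expect_equal(length(unique(cl2$assignments)), 2L)
  expect_equal(gain_cluster_exons(cl2), sprintf("e%02d", 1:10))

  # determinism given input order
  cl3 <- cluster_exons(pat, k = 2, positive_projects = "pos")
  expect_identical(cl2$assignments, cl3$assignments)
})

test_that("planted gain exons are recovered by the select-and-cluster path", {
  # small cohort: 60 gain exons among 600, 4 projects of which 2 positive
  cfg <- small_config(projects = paste0("p", 1:4), n_pairs = 8,
                      positive_projects = c("p1", "p2"),
                      n_exons = 600, n_gain_exons = 60, gain = 1,
                      seed = 14)
  truth <- simulate_truth(cfg)
  profiles <- simulate_coverage(truth, cfg)
  ecm <- exon_copy_matrix(profiles, truth$catalog, truth$samples)
  tt <- per_exon_paired_test(ecm)
  sig <- select_significant(tt, 0.05, projects = c("p1", "p2"),
                            mode = "all")
  dm <- delta_matrix(tt, sig)
  cl <- cluster_exons(dm, k = 4, positive_projects = c("p1", "p2"))
  got <- gain_cluster_exons(cl)
  jac <- length(intersect(got, truth$gain_exons)) /
    length(union(got, truth$gain_exons))
  expect_gte(jac, 0.9)
})

test_that("hypergeometric enrichment matches closed form and enumeration", {
  universe <- paste0("g", 1:10)
  ann <- data.frame(gene = c(paste0("g", 1:5), paste0("g", 1:10)),
                    term = c(rep("small", 5), rep("all", 10)))
  res <- hypergeometric_enrichment(paste0("g", 1:3), universe, ann)
  # term covering the whole universe: p = 1
  expect_equal(res$p[res$term == "all"], 1)
  # overlap 3 of term size 5 in a set of 3: C(5,3)/C(10,3) = 10/120
  expect_equal(res$p[res$term == "small"], 10 / 120)

  # exhaustive enumeration oracle on small universes
  set.seed(15)
  for (i in 1:10) {
    N <- sample(6:12, 1)
    uni <- paste0("u", 1:N)
    term_genes <- sample(uni, sample(1:(N - 1), 1))
    n <- sample(1:(N - 1), 1)
    gs <- sample(uni, n)
    ann_i <- data.frame(gene = term_genes, term = "T")
    p_pkg <- hypergeometric_enrichment(gs, uni, ann_i)$p
    k <- length(intersect(gs, term_genes))
    expect_equal(p_pkg, hyper_enumeration(k, term_genes, uni, n))
  }

  # terms absent from the universe are skipped with a warning
  ann2 <- rbind(ann, data.frame(gene = "zz", term = "orphan"))
  expect_warning(hypergeometric_enrichment(paste0("g", 1:3), universe, ann2),
                 "orphan")
  expect_error(hypergeometric_enrichment("zz", universe, ann), "subset")
})
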