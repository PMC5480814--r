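# Independent oracles and small fixtures used across tests.

# step-up FDR adjustment straight from the definition:
# q(i) = min over ranks j >= rank(i) of p(j) * m / j
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- vapply(seq_len(m), function(k) {
    min(ps[k:m] * m / (k:m))
  }, numeric(1))
  out <- numeric(m)
  out[ord] <- pmin(q, 1)
  out
}

# exhaustive hypergeometric tail: fraction of all n-subsets of the
# universe containing at least k term genes
hyper_enumeration <- function(k, term_genes, universe, n) {
  subsets <- utils::combn(universe, n, simplify = FALSE)
  mean(vapply(subsets, function(s) {
    length(intersect(s, term_genes)) >= k
  }, logical(1)))
}

# allele counting straight from the support rule, one base at a time
allele_count_oracle <- function(counts, min_fraction = 0.1, min_reads = 5) {
  depth <- sum(counts)
  n <- 0L
  for (b in 1:4) {
    if (counts[b] >= min_reads && counts[b] / depth >= min_fraction) {
      n <- n + 1L
    }
  }
  if (n < 1L) n <- 1L
  n
}

# toy annotation: [0,300) transcribed coding block, [300,1000) IGS
toy_annotation <- function() {
  repeat_annotation(data.frame(name = c("18S", "5.8S", "28S"),
                               start = c(0, 100, 200),
                               end = c(100, 200, 300),
                               transcribed = TRUE),
                    unit_length = 1000)
}

# hand-built profile with constant depth over the unit and given exon means
toy_profile <- function(id, unit_depth, exon_means) {
  coverage_profile(id, rep(unit_depth, 1000), exon_means)
}

toy_catalog <- function(exon_means) {
  n <- length(exon_means)
  exon_catalog(data.frame(exon_id = names(exon_means),
                          chromosome = paste0("chr", rep_len(1:2, n)),
                          start = seq_len(n) * 1000L,
                          end = seq_len(n) * 1000L + 500L,
                          gene = paste0("g", seq_len(n))))
}

# tiny pileup around a hand-chosen set of columns
toy_pileup <- function(position, ref, A = 0, C = 0, G = 0, T = 0,
                       qual = 30) {
  structure(data.frame(position = position, ref = ref, A = A, C = C,
                       G = G, T = T, qual = qual,
                       stringsAsFactors = FALSE),
            class = c("pileup_table", "data.frame"))
}

toy_reference <- function(n = 1000, base = "A") {
  structure(list(sequence = paste(rep(base, n), collapse = ""),
                 accession_label = "toy"),
            class = "reference_unit")
}

small_config <- function(...) {
  args <- list(...)
  defaults <- list(projects = paste0("p", 1:2), n_pairs = 3,
                   positive_projects = "p1", n_exons = 100,
                   n_gain_exons = 10, depth = 20,
                   normal_cn_mean = 200, normal_cn_sd = 20, loss = 50,
                   annotation = scaled_annotation(1000L), seed = 11L)
  defaults[names(args)] <- args
  do.call(cohort_config, defaults)
}
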