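# Exons whose copy number co-varies with rDNA loss: per-exon paired
# tumor-vs-normal tests within each project, Benjamini-Hochberg FDR
# selection, hierarchical clustering of per-project mean deltas, and
# hypergeometric enrichment against a user-supplied gene-to-term map.

#' Build a samples x exons matrix of normalized exon copy numbers
#'
#' Each cell is `ploidy_factor * exon mean depth / background` for the
#' sample, i.e. the exon's copy number on the same scale as the rDNA
#' estimates (single-copy exons sit near 2).
#'
#' @param profiles list of `coverage_profile` objects.
#' @param catalog an `exon_catalog`.
#' @param samples data frame with `sample_id`, `pair_id`, `project`,
#'   `role` ("tumor"/"normal") covering every profile; every tumor row
#'   must have a matching normal row sharing `pair_id`.
#' @param ploidy_factor copies per background unit.
#' @return an `exon_copy_matrix`: list with `cn` (matrix) and
#'   `samples` (row metadata in matrix row order).
#' @export
exon_copy_matrix <- function(profiles, catalog, samples,
                             ploidy_factor = 2) {
  stopifnot(all(c("sample_id", "pair_id", "project", "role") %in%
                  names(samples)))
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  stopifnot(all(ids %in% samples$sample_id))
  samples <- samples[match(ids, samples$sample_id), , drop = FALSE]
  if (any(is.na(samples$project))) stop("missing project labels")
  tn <- table(samples$pair_id, samples$role)
  if (!all(tn[, "tumor"] == 1 & tn[, "normal"] == 1)) {
    stop("every pair_id needs exactly one tumor and one normal sample")
  }
  m <- t(vapply(profiles, function(p) {
    bg <- background_coverage(p, catalog)
    vals <- p$exon_means[catalog$exon_id]
    unname(ploidy_factor * vals / bg)
  }, numeric(nrow(catalog))))
  dimnames(m) <- list(ids, catalog$exon_id)
  structure(list(cn = m, samples = samples), class = "exon_copy_matrix")
}

# vectorized paired t over matrix columns; returns t, p, mean delta
paired_t_columns <- function(d) {
  n <- nrow(d)
  m <- colMeans(d)
  s2 <- (colSums(d^2) - n * m^2) / (n - 1)
  s2 <- pmax(s2, 0)
  t_stat <- ifelse(s2 == 0, ifelse(m == 0, 0, sign(m) * Inf),
                   m / sqrt(s2 / n))
  p <- ifelse(is.infinite(t_stat), 0,
              ifelse(s2 == 0 & m == 0, 1, 2 * pt(-abs(t_stat), n - 1)))
  list(t = t_stat, p = p, mean_delta = m, n = n)
}

#' Per-exon paired tumor-vs-normal tests by project
#'
#' For every exon and project, a paired t test of tumor vs normal
#' normalized exon copy number across that project's pairs, with
#' Benjamini-Hochberg adjusted q values computed within each project.
#' All paired differences zero gives statistic 0 and p = 1.
#'
#' @param ecm an [exon_copy_matrix()].
#' @return an `exon_test_table` data frame: `exon_id`, `project`,
#'   `t`, `p`, `q`, `mean_delta`, `n_pairs`.
#' @export
per_exon_paired_test <- function(ecm) {
  stopifnot(inherits(ecm, "exon_copy_matrix"))
  s <- ecm$samples
  out <- lapply(unique(s$project), function(pr) {
    pairs <- unique(s$pair_id[s$project == pr])
    if (length(pairs) < 2) stop("project ", pr, " has fewer than 2 pairs")
    ti <- match(paste0(pairs, ".tumor"),
                paste0(s$pair_id, ".", s$role))
    ni <- match(paste0(pairs, ".normal"),
                paste0(s$pair_id, ".", s$role))
    d <- ecm$cn[ti, , drop = FALSE] - ecm$cn[ni, , drop = FALSE]
    r <- paired_t_columns(d)
    data.frame(exon_id = colnames(ecm$cn), project = pr,
               t = r$t, p = r$p, q = bh_fdr(r$p),
               mean_delta = r$mean_delta, n_pairs = r$n,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, out),
            class = c("exon_test_table", "data.frame"))
}

#' Benjamini-Hochberg adjusted q values
#'
#' Step-up false discovery rate adjustment; output is invariant to
#' input order and monotone in p rank.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return q values of the same length.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Select exons significant at an FDR threshold
#'
#' With `mode = "any"` (default), exons with `q <= threshold` in at
#' least one of the designated projects.  With `mode = "all"`, the
#' exon must reach the threshold in every designated project -- the
#' appropriate rule when asking which exons co-vary with a group of
#' projects, since it suppresses the per-project false discoveries
#' that a union would accumulate.
#'
#' @param table an `exon_test_table`.
#' @param threshold FDR threshold (default 0.05).
#' @param projects project group to consider (default: all projects in
#'   the table).
#' @param mode `"any"` or `"all"` (see above).
#' @return sorted character vector of exon ids.
#' @export
select_significant <- function(table, threshold = 0.05, projects = NULL,
                               mode = c("any", "all")) {
  stopifnot(inherits(table, "exon_test_table"))
  mode <- match.arg(mode)
  projects <- projects %||% unique(table$project)
  sub <- table[table$project %in% projects, , drop = FALSE]
  hit <- tapply(sub$q <= threshold, sub$exon_id,
                if (mode == "any") any else all)
  sort(names(hit)[hit])
}

#' Mean-delta matrix for a set of exons
#'
#' Pivots an `exon_test_table` into an exons x projects matrix of mean
#' tumor-normal deltas, the clustering input.
#'
#' @param table an `exon_test_table`.
#' @param exons exon ids to keep (default all).
#' @return numeric matrix, rows in lexicographic exon order.
#' @export
delta_matrix <- function(table, exons = NULL) {
  exons <- sort(exons %||% unique(table$exon_id))
  projects <- unique(table$project)
  m <- matrix(NA_real_, nrow = length(exons), ncol = length(projects),
              dimnames = list(exons, projects))
  sub <- table[table$exon_id %in% exons, , drop = FALSE]
  m[cbind(match(sub$exon_id, exons), match(sub$project, projects))] <-
    sub$mean_delta
  m
}

#' Hierarchical clustering of exon copy-number trends
#'
#' Agglomerative clustering of per-project mean deltas (Euclidean
#' distance, average linkage by default), cut to `k` clusters.  The
#' gain cluster is anchored at the cluster whose mean delta is most
#' positive in the positive projects while staying nearest zero in
#' the negative projects (score: positive-project mean minus the
#' absolute negative-project mean); clusters whose profile lies
#' closer to that anchor than to the all-zero profile are included in
#' the gain set, so a tight gain block that the cut splits is
#' reunited.  Rows are ordered by exon id first so the result is
#' deterministic.
#'
#' @param deltas exons x projects matrix from [delta_matrix()].
#' @param k number of clusters (default 4).
#' @param positive_projects columns regarded as rDNA-loss positive;
#'   default: all columns (gain cluster then maximizes overall mean).
#' @param metric distance metric for [stats::dist()].
#' @param linkage agglomeration method for [stats::hclust()].
#' @return a `cluster_result` list: `assignments` (named integer
#'   vector), `profiles` (cluster x project mean-delta matrix),
#'   `gain_cluster` (anchor id), `gain_clusters` (ids in the gain
#'   set), `tree` (the hclust object).
#' @export
cluster_exons <- function(deltas, k = 4, positive_projects = NULL,
                          metric = "euclidean", linkage = "average") {
  stopifnot(is.matrix(deltas))
  deltas <- deltas[order(rownames(deltas)), , drop = FALSE]
  if (nrow(deltas) < 2) {
    assignments <- setNames(rep(1L, nrow(deltas)), rownames(deltas))
    profiles <- matrix(colMeans(deltas), nrow = 1,
                       dimnames = list("1", colnames(deltas)))
    return(structure(list(assignments = assignments, profiles = profiles,
                          gain_cluster = 1L, gain_clusters = 1L,
                          tree = NULL),
                     class = "cluster_result"))
  }
  k <- min(k, nrow(unique(deltas)))
  tree <- hclust(dist(deltas, method = metric), method = linkage)
  assignments <- cutree(tree, k = k)
  profiles <- do.call(rbind, lapply(sort(unique(assignments)), function(cl) {
    colMeans(deltas[assignments == cl, , drop = FALSE])
  }))
  rownames(profiles) <- sort(unique(assignments))
  pos <- positive_projects %||% colnames(deltas)
  neg <- setdiff(colnames(deltas), pos)
  score <- rowMeans(profiles[, pos, drop = FALSE]) -
    if (length(neg)) abs(rowMeans(profiles[, neg, drop = FALSE])) else 0
  b <- which.max(score)
  # gain set: clusters whose profile sits closer to the best gain
  # profile than to the null (all-zero) profile, so that a tight gain
  # block split across sub-clusters by the cut is reunited
  d_to_b <- sqrt(rowSums((profiles - rep(profiles[b, ],
                                         each = nrow(profiles)))^2))
  d_to_0 <- sqrt(rowSums(profiles^2))
  gain_set <- as.integer(rownames(profiles)[d_to_b < d_to_0 |
                                              seq_len(nrow(profiles)) == b])
  structure(list(assignments = assignments, profiles = profiles,
                 gain_cluster = as.integer(rownames(profiles)[b]),
                 gain_clusters = gain_set, tree = tree),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("hierarchical clustering: %d exons in %d clusters; gain set {%s} (%d exons)\n",
              length(x$assignments), nrow(x$profiles),
              paste(x$gain_clusters, collapse = ","),
              sum(x$assignments %in% x$gain_clusters)))
  invisible(x)
}

#' Exon ids assigned to the gain cluster
#'
#' Members of every cluster in the gain set (the best-scoring cluster
#' plus clusters profile-closer to it than to zero).
#'
#' @param result a `cluster_result`.
#' @return character vector of exon ids.
#' @export
gain_cluster_exons <- function(result) {
  gain <- result$gain_clusters %||% result$gain_cluster
  sort(names(result$assignments)[result$assignments %in% gain])
}

#' Hypergeometric term enrichment for a gene set
#'
#' For each term, the upper-tail hypergeometric probability of drawing
#' at least the observed number of term-annotated genes when sampling
#' `|gene_set|` genes from the universe without replacement.  Terms
#' with no annotated gene in the universe are skipped with a warning.
#' No ontology graph propagation and no multiplicity adjustment are
#' applied; the raw per-term p values are reported.
#'
#' @param gene_set character vector, a subset of `universe`.
#' @param universe character vector of all candidate genes.
#' @param term_annotation data frame with columns `gene`, `term`.
#' @return data frame: `term`, `term_size` (in universe), `overlap`,
#'   `expected`, `p`, sorted by `p`.
#' @export
hypergeometric_enrichment <- function(gene_set, universe, term_annotation) {
  stopifnot(all(c("gene", "term") %in% names(term_annotation)))
  gene_set <- unique(gene_set)
  universe <- unique(universe)
  if (!all(gene_set %in% universe)) stop("gene_set must be a subset of universe")
  ann <- term_annotation[term_annotation$gene %in% universe, , drop = FALSE]
  skipped <- setdiff(unique(term_annotation$term), unique(ann$term))
  if (length(skipped)) {
    warning("terms with no universe genes skipped: ",
            paste(skipped, collapse = ", "))
  }
  N <- length(universe); n <- length(gene_set)
  out <- do.call(rbind, lapply(unique(ann$term), function(tm) {
    genes <- unique(ann$gene[ann$term == tm])
    K <- length(genes)
    k <- length(intersect(genes, gene_set))
    data.frame(term = tm, term_size = K, overlap = k,
               expected = n * K / N,
               p = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  out[order(out$p, out$term), , drop = FALSE]
}
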