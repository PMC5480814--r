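# End-to-end cohort orchestration: simulate (or ingest) -> copy number
# -> paired deltas -> cohort loss tests -> exon covariation -> SNV and
# allele analysis -> report bundle with a machine-readable manifest.
# All randomness flows from the single config seed via fixed per-stage
# offsets, so identical config + seed gives identical outputs.

#' Load a run configuration from YAML
#'
#' The YAML must contain a `simulate:` block (fields of
#' [cohort_config()]); thresholds and the seed live at the top level.
#'
#' @param path YAML file.
#' @return a list suitable for [run_cohort()].
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$simulate)) {
    stop("run config needs a `simulate:` block")
  }
  sim <- cfg$simulate
  if (!is.null(cfg$seed)) sim$seed <- cfg$seed
  if (!is.null(sim$unit_length)) {
    sim$annotation <- scaled_annotation(as.integer(sim$unit_length))
    sim$unit_length <- NULL
  }
  list(simulate = do.call(cohort_config, sim),
       fdr_threshold = cfg$fdr_threshold %||% 0.05,
       alpha = cfg$alpha %||% 0.05,
       min_qual = cfg$min_qual %||% 20,
       min_depth = cfg$min_depth %||% 10,
       allele_min_fraction = cfg$allele_min_fraction %||% 0.1,
       allele_min_reads = cfg$allele_min_reads %||% 5,
       loss_region = cfg$loss_region %||% "18S",
       n_clusters = cfg$n_clusters %||% 4)
}

#' Run the full cohort analysis
#'
#' Simulates a cohort from the configuration, estimates per-sample
#' rDNA copy number, forms tumor-normal deltas, tests each project for
#' copy loss, runs the exon covariation analysis (paired tests, FDR
#' selection in the loss-significant projects, clustering, gain
#' cluster), and runs the SNV/allele analysis per pair.  Writes TSV
#' tables, JSON summaries and a run manifest under `out_dir` when
#' given.
#'
#' @param config a [cohort_config()], or a list from
#'   [load_run_config()].
#' @param out_dir optional output directory; created if missing.
#' @param fdr_threshold FDR threshold for exon selection.
#' @param alpha significance level for the project loss flags and
#'   allele tests.
#' @param loss_region region whose delta drives the loss flag.
#' @param n_clusters clusters for the exon dendrogram cut.
#' @param min_qual,min_depth SNV calling filters.
#' @param allele_min_fraction,allele_min_reads allele support rule.
#' @param snv_pairs_per_project pairs per project carried through the
#'   (per-base, hence slower) pileup stage; default 3.
#' @return a `cohort_report` list; see Details.
#' @details The report contains `cn_table`, `deltas`, `loss_tests`,
#'   `loss_significant` (flagged projects), `exon_tests` summary,
#'   `significant_exons`, `clusters`, `gain_exons`, `snv`, `alleles`,
#'   and `manifest`.
#' @export
run_cohort <- function(config, out_dir = NULL,
                       fdr_threshold = 0.05, alpha = 0.05,
                       loss_region = "18S", n_clusters = 4,
                       min_qual = 20, min_depth = 10,
                       allele_min_fraction = 0.1, allele_min_reads = 5,
                       snv_pairs_per_project = 3) {
  if (!inherits(config, "cohort_config") && !is.null(config$simulate)) {
    rc <- config
    config <- rc$simulate
    fdr_threshold <- rc$fdr_threshold; alpha <- rc$alpha
    loss_region <- rc$loss_region; n_clusters <- rc$n_clusters
    min_qual <- rc$min_qual; min_depth <- rc$min_depth
    allele_min_fraction <- rc$allele_min_fraction
    allele_min_reads <- rc$allele_min_reads
  }
  stopifnot(inherits(config, "cohort_config"))

  truth <- simulate_truth(config)
  profiles <- simulate_coverage(truth, config)
  ann <- config$annotation
  catalog <- truth$catalog
  samples <- truth$samples
  message(sprintf("cohort: %d samples (%d pairs, %d projects)",
                  nrow(samples), nrow(samples) / 2,
                  length(config$projects)))

  # stage 1: per-sample copy number
  estimates <- lapply(profiles, estimate_copy_number,
                      annotation = ann, catalog = catalog)
  cn_table <- do.call(rbind, lapply(estimates, function(e) {
    data.frame(sample_id = e$sample_id, cn_18S = e$cn[["18S"]],
               cn_5.8S = e$cn[["5.8S"]], cn_28S = e$cn[["28S"]],
               background = e$background, check.names = FALSE)
  }))
  cn_table <- merge(samples[, c("sample_id", "pair_id", "project", "role")],
                    cn_table, by = "sample_id")

  # stage 2: paired deltas
  pair_ids <- unique(samples$pair_id)
  deltas <- do.call(rbind, lapply(pair_ids, function(pid) {
    tum <- estimates[[samples$sample_id[samples$pair_id == pid &
                                          samples$role == "tumor"]]]
    nor <- estimates[[samples$sample_id[samples$pair_id == pid &
                                          samples$role == "normal"]]]
    cbind(paired_normalized_cn(tum, nor, pair_id = pid),
          project = samples$project[samples$pair_id == pid][1])
  }))

  # stage 3: per-project loss tests
  loss_tests <- lapply(setNames(nm = config$projects), function(pr) {
    lapply(setNames(nm = c("18S", "5.8S", "28S")), function(r) {
      cohort_loss_test(deltas[deltas$project == pr, ], region = r)
    })
  })
  loss_significant <- names(Filter(function(tl) {
    tl[[loss_region]]$p_value < alpha && tl[[loss_region]]$mean_delta < 0
  }, loss_tests))
  message(sprintf("loss tests: %d of %d projects flagged (%s)",
                  length(loss_significant), length(config$projects),
                  paste(loss_significant, collapse = ", ")))

  # stage 4: exon covariation
  ecm <- exon_copy_matrix(profiles, catalog, samples)
  exon_tests <- per_exon_paired_test(ecm)
  sig_group <- if (length(loss_significant)) loss_significant else
    config$projects
  significant_exons <- select_significant(exon_tests, fdr_threshold,
                                          projects = sig_group,
                                          mode = "all")
  message(sprintf("covariation: %d exons at FDR <= %g in %d project(s)",
                  length(significant_exons), fdr_threshold,
                  length(sig_group)))
  clusters <- NULL; gain_exons <- character()
  if (length(significant_exons) >= 2) {
    dm <- delta_matrix(exon_tests, significant_exons)
    clusters <- cluster_exons(dm, k = n_clusters,
                              positive_projects = intersect(sig_group,
                                                            colnames(dm)))
    gain_exons <- gain_cluster_exons(clusters)
  }

  # stage 5: SNV and allele analysis on a subset of pairs per project
  snv_pairs <- unlist(lapply(config$projects, function(pr) {
    head(pair_ids[samples$project[match(pair_ids, samples$pair_id)] == pr],
         snv_pairs_per_project)
  }))
  pair_class <- list(); allele_deltas <- numeric(); unique_sets <- list()
  for (pid in snv_pairs) {
    pt <- simulate_pileup(truth, pid, "tumor", config)
    pn <- simulate_pileup(truth, pid, "normal", config)
    st <- call_snvs(pt, truth$reference, min_qual, min_depth)
    sn <- call_snvs(pn, truth$reference, min_qual, min_depth)
    cl <- classify_pair(st, sn)
    pair_class[[pid]] <- cl
    unique_sets[[paste0(pid, "_T")]] <- cl$tumor_unique
    unique_sets[[paste0(pid, "_N")]] <- cl$normal_unique
    ad <- if (length(cl$shared)) {
      allele_difference(pt, pn, cl$shared, allele_min_fraction,
                        allele_min_reads)$delta
    } else NA_real_
    allele_deltas[pid] <- ad
  }
  hotspots <- hotspot_positions(unique_sets)
  all_unique <- unlist(unique_sets, use.names = FALSE)
  density <- snv_density_by_region(all_unique, ann)
  snv_project <- samples$project[match(snv_pairs, samples$pair_id)]
  allele_tests <- lapply(setNames(nm = unique(snv_project)), function(pr) {
    x <- allele_deltas[snv_project == pr]
    x <- x[!is.na(x)]
    if (length(x) >= 2) project_allele_test(x) else NULL
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("rdnacn")),
    seed = config$seed,
    thresholds = list(fdr = fdr_threshold, alpha = alpha,
                      snv_min_qual = min_qual, snv_min_depth = min_depth,
                      allele_min_fraction = allele_min_fraction,
                      allele_min_reads = allele_min_reads),
    n_samples = nrow(samples), n_pairs = length(pair_ids),
    n_exons = nrow(catalog), unit_length = unit_length(ann),
    projects = config$projects,
    loss_significant = loss_significant,
    n_significant_exons = length(significant_exons),
    n_gain_exons = length(gain_exons),
    snv_pairs = snv_pairs)

  report <- structure(list(
    cn_table = cn_table, deltas = deltas, loss_tests = loss_tests,
    loss_significant = loss_significant, exon_tests = exon_tests,
    significant_exons = significant_exons, clusters = clusters,
    gain_exons = gain_exons,
    snv = list(classifications = pair_class, hotspots = hotspots,
               density = density),
    alleles = list(deltas = allele_deltas, tests = allele_tests),
    truth = truth, manifest = manifest), class = "cohort_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(paste0(
    "cohort report: %d pairs, %d projects\n",
    "  loss-significant projects: %s\n",
    "  significant exons (FDR <= %g): %d; gain cluster: %d exons\n",
    "  unique SNVs: %d at %d positions\n"),
    m$n_pairs, length(m$projects),
    if (length(x$loss_significant)) paste(x$loss_significant, collapse = ", ")
    else "none",
    m$thresholds$fdr, m$n_significant_exons, m$n_gain_exons,
    x$snv$hotspots$total_snvs, x$snv$hotspots$n_positions))
  invisible(x)
}

# write the report bundle: TSVs per stage plus JSON summaries
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(d, f) write.table(d, file.path(out_dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  tsv(report$cn_table, "copy_number.tsv")
  tsv(report$deltas, "paired_deltas.tsv")
  tsv(report$exon_tests, "exon_tests.tsv")
  tsv(report$snv$density, "snv_density.tsv")
  if (!is.null(report$clusters)) {
    tsv(data.frame(exon_id = names(report$clusters$assignments),
                   cluster = unname(report$clusters$assignments)),
        "exon_clusters.tsv")
  }
  loss <- lapply(report$loss_tests, function(tl) {
    lapply(tl, function(t) list(statistic = t$statistic,
                                p_value = t$p_value, n = t$n,
                                mean_delta = t$mean_delta))
  })
  jsonlite::write_json(loss, file.path(out_dir, "loss_tests.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
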