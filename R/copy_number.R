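# Coverage-based rDNA copy-number estimation and cohort loss tests.
#
# The copy number of each coding region (18S, 5.8S, 28S) is the mean
# per-base depth over the region, scaled by the background genome
# coverage -- the median of per-exon mean depths over a catalog of
# single-copy exons.  One background unit represents ploidy_factor
# copies (default 2: a single-copy exon contributes two copies per
# diploid genome), so
#   CN_r = ploidy_factor * mean(depth over region r) / background.

#' Construct a coverage profile
#'
#' @param sample_id sample label.
#' @param depth numeric vector of per-base depth over the repeat unit.
#' @param exon_means named numeric vector of per-exon mean depths.
#' @return a `coverage_profile`.
#' @export
coverage_profile <- function(sample_id, depth, exon_means) {
  stopifnot(is.numeric(depth), all(depth >= 0),
            is.numeric(exon_means), all(exon_means >= 0),
            !is.null(names(exon_means)))
  structure(list(sample_id = sample_id, depth = as.numeric(depth),
                 exon_means = exon_means),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("coverage profile %s: %d bp repeat unit, %d exons\n",
              x$sample_id, length(x$depth), length(x$exon_means)))
  invisible(x)
}

#' Write / read a coverage profile as TSV
#'
#' Two files: per-base `(position, depth)` over the repeat unit and
#' per-exon `(exon_id, mean_depth)`.  Positions are 0-based.
#'
#' @param profile a `coverage_profile`.
#' @param depth_path,exon_path TSV paths.
#' @return `write_coverage_profile` returns the paths invisibly;
#'   `read_coverage_profile` returns a `coverage_profile`.
#' @export
write_coverage_profile <- function(profile, depth_path, exon_path) {
  write.table(data.frame(position = seq_along(profile$depth) - 1L,
                         depth = profile$depth),
              depth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(exon_id = names(profile$exon_means),
                         mean_depth = unname(profile$exon_means)),
              exon_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(depth_path, exon_path))
}

#' @rdname write_coverage_profile
#' @param sample_id sample label for the profile read back.
#' @export
read_coverage_profile <- function(depth_path, exon_path, sample_id) {
  d <- read.table(depth_path, header = TRUE, sep = "\t")
  e <- read.table(exon_path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  coverage_profile(sample_id, d$depth[order(d$position)],
                   setNames(e$mean_depth, e$exon_id))
}

#' Mean coverage over one annotated region
#'
#' @param profile a `coverage_profile`.
#' @param annotation a `repeat_annotation`.
#' @param region region name.
#' @return arithmetic mean of per-base depth over `[start, end)`.
#' @export
region_mean_coverage <- function(profile, annotation, region) {
  stopifnot(inherits(profile, "coverage_profile"),
            inherits(annotation, "repeat_annotation"))
  i <- match(region, annotation$name)
  if (is.na(i)) stop("unknown region: ", region)
  if (annotation$end[i] <= annotation$start[i]) {
    stop("zero-length region: ", region)
  }
  if (length(profile$depth) < annotation$end[i]) {
    stop("profile shorter than region ", region)
  }
  mean(profile$depth[(annotation$start[i] + 1L):annotation$end[i]])
}

#' Background genome coverage of a sample
#'
#' The median of per-exon mean depths over the single-copy exon
#' catalog.  With an even number of exons the midpoint of the central
#' pair is used (this value feeds a division, so the convention
#' matters).
#'
#' @param profile a `coverage_profile`.
#' @param catalog an `exon_catalog`; only cataloged exons contribute.
#' @return the median exon depth.
#' @export
background_coverage <- function(profile, catalog) {
  stopifnot(inherits(profile, "coverage_profile"))
  vals <- profile$exon_means[names(profile$exon_means) %in% catalog$exon_id]
  if (length(vals) == 0) stop("no cataloged exon means in profile")
  median(vals)
}

#' Estimate rDNA copy number from coverage
#'
#' @param profile a `coverage_profile`.
#' @param annotation a `repeat_annotation` containing regions 18S,
#'   5.8S and 28S.
#' @param catalog an `exon_catalog` for the background.
#' @param ploidy_factor copies represented by one background unit
#'   (default 2, reporting copies per diploid genome).
#' @return a `cn_estimate` list with `sample_id`, `cn` (named vector
#'   for 18S, 5.8S, 28S), `background`, `ploidy_factor`.
#' @export
estimate_copy_number <- function(profile, annotation, catalog,
                                 ploidy_factor = 2) {
  bg <- background_coverage(profile, catalog)
  if (bg <= 0) stop("background coverage is zero; exon catalog uncovered")
  regions <- c("18S", "5.8S", "28S")
  cn <- vapply(regions, function(r) {
    ploidy_factor * region_mean_coverage(profile, annotation, r) / bg
  }, numeric(1))
  structure(list(sample_id = profile$sample_id, cn = cn,
                 background = bg, ploidy_factor = ploidy_factor),
            class = "cn_estimate")
}

#' @export
print.cn_estimate <- function(x, ...) {
  cat(sprintf("copy number [%s]: 18S %.1f, 5.8S %.1f, 28S %.1f (background %.2f)\n",
              x$sample_id, x$cn["18S"], x$cn["5.8S"], x$cn["28S"],
              x$background))
  invisible(x)
}

#' Tumor minus normal copy number for one matched pair
#'
#' @param tumor,normal `cn_estimate` objects for the two members of a
#'   pair; they must share the ploidy convention.
#' @param pair_id label for the pair.
#' @return one-row data frame with `delta_18S`, `delta_5.8S`,
#'   `delta_28S`.
#' @export
paired_normalized_cn <- function(tumor, normal, pair_id = NULL) {
  stopifnot(inherits(tumor, "cn_estimate"), inherits(normal, "cn_estimate"))
  if (tumor$ploidy_factor != normal$ploidy_factor) {
    stop("tumor and normal estimates use different ploidy factors")
  }
  d <- tumor$cn - normal$cn
  data.frame(pair_id = pair_id %||% paste0(tumor$sample_id, "-",
                                           normal$sample_id),
             delta_18S = d[["18S"]], delta_5.8S = d[["5.8S"]],
             delta_28S = d[["28S"]], stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Cohort-level test for rDNA copy loss
#'
#' Two-sided one-sample t test of the per-pair copy-number differences
#' against zero (equivalently, a paired t test of tumor vs normal).  A
#' Wilcoxon signed-rank alternative is available.  Degenerate inputs:
#' all differences zero gives statistic 0 and p = 1; zero variance
#' about a nonzero mean is reported as p = 0 with a `degenerate` flag.
#'
#' @param deltas data frame of per-pair differences from
#'   [paired_normalized_cn()] (rows bound together), or a numeric
#'   vector.
#' @param region which region's delta column to test (ignored for a
#'   numeric vector).
#' @param method `"t"` (default) or `"wilcoxon"`.
#' @return a `test_result` list: `statistic`, `p_value`, `n`,
#'   `method`, `mean_delta`, `degenerate`.
#' @export
cohort_loss_test <- function(deltas, region = "18S",
                             method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  x <- if (is.numeric(deltas)) deltas else {
    col <- paste0("delta_", region)
    if (!col %in% names(deltas)) stop("no column ", col, " in deltas")
    deltas[[col]]
  }
  x <- x[!is.na(x)]
  if (length(x) < 2) stop("need at least 2 paired differences")
  one_sample_test(x, method = method)
}

# shared degenerate-aware one-sample test against 0
one_sample_test <- function(x, method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  degenerate <- FALSE
  if (sd(x) == 0) {
    degenerate <- TRUE
    if (mean(x) == 0) {
      stat <- 0; p <- 1
    } else {
      stat <- sign(mean(x)) * Inf; p <- 0
    }
  } else if (method == "t") {
    ht <- t.test(x, mu = 0)
    stat <- unname(ht$statistic); p <- ht$p.value
  } else {
    ht <- wilcox.test(x, mu = 0, exact = FALSE)
    stat <- unname(ht$statistic); p <- ht$p.value
  }
  structure(list(statistic = stat, p_value = p, n = length(x),
                 method = if (method == "t") "one-sample t" else
                   "Wilcoxon signed-rank",
                 mean_delta = mean(x), degenerate = degenerate),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, p = %.4g (n = %d, mean %.3g)%s\n",
              x$method, x$statistic, x$p_value, x$n, x$mean_delta,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Pairwise correlation of region copy numbers across samples
#'
#' Pearson correlations between the 18S, 5.8S and 28S copy-number
#' estimates across a set of samples.  A constant region vector gives
#' undefined correlations, reported as `NA`.
#'
#' @param estimates list of `cn_estimate` objects (n >= 3).
#' @return 3x3 correlation matrix with unit diagonal.
#' @export
region_correlation <- function(estimates) {
  stopifnot(length(estimates) >= 3)
  m <- t(vapply(estimates, function(e) e$cn, numeric(3)))
  colnames(m) <- c("18S", "5.8S", "28S")
  suppressWarnings(r <- cor(m))
  diag(r) <- 1
  r
}

#' Chromosome-level normalized coverage matrix
#'
#' For each sample and chromosome, the mean over cataloged exons of
#' `ploidy_factor * exon depth / background`.  Euploid samples sit
#' near 2 everywhere; a trisomic chromosome near 3.  Chromosomes with
#' no cataloged exons get `NA`.
#'
#' @param profiles list of `coverage_profile` objects.
#' @param catalog an `exon_catalog` mapping exons to chromosomes.
#' @param ploidy_factor copies per background unit.
#' @return samples x chromosomes numeric matrix.
#' @export
chromosome_coverage_matrix <- function(profiles, catalog,
                                       ploidy_factor = 2) {
  chroms <- unique(catalog$chromosome)
  out <- t(vapply(profiles, function(p) {
    bg <- background_coverage(p, catalog)
    if (bg <= 0) stop("background coverage is zero for sample ", p$sample_id)
    vapply(chroms, function(ch) {
      ids <- catalog$exon_id[catalog$chromosome == ch]
      vals <- p$exon_means[names(p$exon_means) %in% ids]
      if (length(vals) == 0) return(NA_real_)
      mean(ploidy_factor * vals / bg)
    }, numeric(1))
  }, numeric(length(chroms))))
  rownames(out) <- vapply(profiles, function(p) p$sample_id, character(1))
  colnames(out) <- chroms
  out
}
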