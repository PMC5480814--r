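# Droplet digital PCR quantitation.  The positive-droplet fraction p
# is Poisson-corrected to a per-droplet concentration
# lambda = -ln(1 - p); the target-to-reference concentration ratio,
# scaled by the reference's copies per genome (2 for a single-copy
# autosomal gene), gives the target copy number per diploid genome.
# Droplet volume cancels in the ratio.

#' Construct a droplet assay record
#'
#' @param sample_id assay label.
#' @param n_droplets accepted droplets.
#' @param positives_target,positives_reference positive droplets in
#'   the target and single-copy reference channels.
#' @param droplet_volume_nl droplet volume in nanolitres (QX200
#'   nominal 0.85); used only for optional absolute concentrations.
#' @return a `droplet_assay`.
#' @export
droplet_assay <- function(sample_id, n_droplets, positives_target,
                          positives_reference, droplet_volume_nl = 0.85) {
  stopifnot(n_droplets > 0,
            positives_target >= 0, positives_target <= n_droplets,
            positives_reference >= 0, positives_reference <= n_droplets)
  structure(list(sample_id = sample_id,
                 n_droplets = as.integer(n_droplets),
                 positives_target = as.integer(positives_target),
                 positives_reference = as.integer(positives_reference),
                 droplet_volume_nl = droplet_volume_nl),
            class = "droplet_assay")
}

#' Poisson-corrected droplet concentration
#'
#' Inverts the positive fraction of a partitioned assay:
#' `lambda = -ln(1 - positives / n_droplets)` copies per droplet.
#' Saturated assays (every droplet positive) carry no concentration
#' information and raise an error.
#'
#' @param positives positive droplets.
#' @param n_droplets total droplets.
#' @return copies per droplet.
#' @export
droplet_concentration <- function(positives, n_droplets) {
  if (n_droplets <= 0) stop("n_droplets must be positive")
  if (positives < 0 || positives > n_droplets) {
    stop("positives must lie in [0, n_droplets]")
  }
  if (positives == n_droplets) {
    stop("assay saturated: every droplet positive")
  }
  -log(1 - positives / n_droplets)
}

#' Copy number per genome from a droplet assay
#'
#' The target concentration divided by the single-copy reference
#' concentration, scaled by the reference's copies per genome.
#'
#' @param assay a [droplet_assay()].
#' @param reference_copies_per_genome copies of the reference locus
#'   per genome (default 2).
#' @return an `assay_estimate` list: `sample_id`, `lambda_target`,
#'   `lambda_reference`, `copy_number`, `ci` (95% delta-method
#'   interval on the copy number).
#' @export
assay_copy_number <- function(assay, reference_copies_per_genome = 2) {
  stopifnot(inherits(assay, "droplet_assay"))
  if (assay$positives_reference == 0) {
    stop("no positive reference droplets: normalizer undefined")
  }
  lt <- droplet_concentration(assay$positives_target, assay$n_droplets)
  lr <- droplet_concentration(assay$positives_reference, assay$n_droplets)
  cn <- reference_copies_per_genome * lt / lr
  # delta method on the two binomial fractions:
  # var(log lambda) ~= p / (n (1-p) lambda^2)
  vlog <- function(pos) {
    p <- pos / assay$n_droplets
    lam <- -log(1 - p)
    if (pos == 0) return(Inf)
    p / (assay$n_droplets * (1 - p) * lam^2)
  }
  se_log <- sqrt(vlog(assay$positives_target) +
                   vlog(assay$positives_reference))
  structure(list(sample_id = assay$sample_id, lambda_target = lt,
                 lambda_reference = lr, copy_number = cn,
                 ci = cn * exp(c(-1.96, 1.96) * se_log)),
            class = "assay_estimate")
}

#' @export
print.assay_estimate <- function(x, ...) {
  cat(sprintf("ddPCR [%s]: %.1f copies/genome (95%% CI %.1f-%.1f)\n",
              x$sample_id, x$copy_number, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Summarize replicate copy-number estimates by group
#'
#' @param estimates list of `assay_estimate` objects, or a numeric
#'   vector of copy numbers.
#' @param groups grouping labels (tissue, strain), one per estimate.
#' @return data frame: `group`, `n`, `mean`, `sd` (n-1 denominator),
#'   `cv`.
#' @export
replicate_summary <- function(estimates, groups) {
  cn <- if (is.numeric(estimates)) estimates else
    vapply(estimates, function(e) e$copy_number, numeric(1))
  stopifnot(length(groups) == length(cn), length(cn) >= 1)
  out <- do.call(rbind, lapply(unique(groups), function(g) {
    v <- cn[groups == g]
    s <- if (length(v) > 1) sd(v) else 0
    data.frame(group = g, n = length(v), mean = mean(v), sd = s,
               cv = if (mean(v) > 0) s / mean(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read droplet assays from CSV
#'
#' Expected columns: `sample_id`, `group`, `n_droplets`,
#' `positives_target`, `positives_reference`.
#'
#' @param path CSV file.
#' @return list with `assays` (list of `droplet_assay`) and `groups`.
#' @export
read_droplet_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "n_droplets", "positives_target",
                  "positives_reference") %in% names(d)))
  assays <- lapply(seq_len(nrow(d)), function(i) {
    droplet_assay(d$sample_id[i], d$n_droplets[i],
                  d$positives_target[i], d$positives_reference[i])
  })
  list(assays = assays, groups = d$group %||% rep("all", nrow(d)))
}
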