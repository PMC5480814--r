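# SNV calling within the repeat against the consensus, shared/unique
# classification across tumor-normal pairs, per-region densities,
# recurrence hotspots, and the allele-number difference statistic.

.bases <- c("A", "C", "G", "T")

#' Read / write the pileup TSV dialect
#'
#' Columns: `position` (0-based), `ref`, `A`, `C`, `G`, `T` (read
#' counts), `qual` (representative phred base quality).
#'
#' @param path TSV path.
#' @return `read_pileup` returns a `pileup_table`;
#'   `write_pileup` returns `path` invisibly.
#' @export
read_pileup <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  stopifnot(all(c("position", "ref", .bases, "qual") %in% names(d)))
  structure(d, class = c("pileup_table", "data.frame"))
}

#' @rdname read_pileup
#' @param pileup a `pileup_table`.
#' @export
write_pileup <- function(pileup, path) {
  write.table(pileup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Call SNVs from a pileup against the reference unit
#'
#' At each position the predominant (majority) base is compared to the
#' reference.  A tie that includes the reference resolves to the
#' reference (conservative no-call); a tie between two alternative
#' bases resolves to the alphabetically first.  A mismatch passes when
#' its quality is strictly greater than `min_qual` and its depth is at
#' least `min_depth`; failing mismatches are returned with
#' `pass = FALSE`.
#'
#' @param pileup a `pileup_table`.
#' @param reference a `reference_unit` covering every pileup position.
#' @param min_qual phred quality that a passing call must exceed
#'   (default 20, i.e. quality must be > 20).
#' @param min_depth minimum read depth for a passing call.
#' @return an `snv_calls` data frame: `position`, `ref`, `alt`,
#'   `qual`, `depth`, `pass`.
#' @export
call_snvs <- function(pileup, reference, min_qual = 20, min_depth = 10) {
  stopifnot(inherits(pileup, "pileup_table"),
            inherits(reference, "reference_unit"))
  if (any(pileup$position < 0 |
            pileup$position >= nchar(reference$sequence))) {
    stop("pileup position outside the reference unit")
  }
  cnt <- as.matrix(pileup[, .bases])
  depth <- rowSums(cnt)
  ref_idx <- match(pileup$ref, .bases)
  ref_cnt <- cnt[cbind(seq_len(nrow(cnt)), ref_idx)]
  max_cnt <- do.call(pmax, as.data.frame(cnt))
  # majority != ref only when some base strictly exceeds the ref count
  is_var <- depth > 0 & ref_cnt < max_cnt
  idx <- which(is_var)
  if (!length(idx)) {
    return(structure(data.frame(position = integer(), ref = character(),
                                alt = character(), qual = numeric(),
                                depth = numeric(), pass = logical(),
                                stringsAsFactors = FALSE),
                     class = c("snv_calls", "data.frame")))
  }
  alt <- vapply(idx, function(i) {
    .bases[which(cnt[i, ] == max_cnt[i])[1]]  # alphabetic tie-break
  }, character(1))
  structure(data.frame(position = pileup$position[idx],
                       ref = pileup$ref[idx], alt = alt,
                       qual = pileup$qual[idx], depth = depth[idx],
                       pass = pileup$qual[idx] > min_qual &
                         depth[idx] >= min_depth,
                       stringsAsFactors = FALSE),
            class = c("snv_calls", "data.frame"))
}

#' Classify SNVs of a tumor-normal pair as shared or unique
#'
#' A position is shared when both genomes carry a passing SNV with the
#' same alternative base; otherwise it is unique to the genome
#' carrying it.  A position called with different alternative bases in
#' the two genomes is unique in both.
#'
#' @param tumor_snvs,normal_snvs `snv_calls` from the two genomes;
#'   only passing records are considered.
#' @return a `pair_classification` list of disjoint position sets:
#'   `shared`, `tumor_unique`, `normal_unique`.
#' @export
classify_pair <- function(tumor_snvs, normal_snvs) {
  tu <- tumor_snvs[tumor_snvs$pass, c("position", "alt")]
  no <- normal_snvs[normal_snvs$pass, c("position", "alt")]
  key_t <- paste(tu$position, tu$alt)
  key_n <- paste(no$position, no$alt)
  shared <- sort(tu$position[key_t %in% key_n])
  structure(list(shared = shared,
                 tumor_unique = sort(setdiff(tu$position, shared)),
                 normal_unique = sort(setdiff(no$position, shared))),
            class = "pair_classification")
}

#' @export
print.pair_classification <- function(x, ...) {
  cat(sprintf("pair classification: %d shared, %d tumor-unique, %d normal-unique SNVs\n",
              length(x$shared), length(x$tumor_unique),
              length(x$normal_unique)))
  invisible(x)
}

#' SNVs per kilobase by repeat region
#'
#' @param snvs an `snv_calls` table (passing records counted) or a
#'   vector of 0-based positions.
#' @param annotation a `repeat_annotation`.
#' @return data frame: `region`, `length_bp`, `n_snvs`,
#'   `snvs_per_kb`.
#' @export
snv_density_by_region <- function(snvs, annotation) {
  stopifnot(inherits(annotation, "repeat_annotation"))
  pos <- if (is.numeric(snvs)) snvs else snvs$position[snvs$pass]
  data.frame(region = annotation$name,
             length_bp = annotation$end - annotation$start,
             n_snvs = vapply(seq_len(nrow(annotation)), function(i) {
               sum(pos >= annotation$start[i] & pos < annotation$end[i])
             }, numeric(1)),
             stringsAsFactors = FALSE) |>
    transform(snvs_per_kb = n_snvs / (length_bp / 1000))
}

#' Recurrence of unique SNV positions across genomes
#'
#' Counts, at each position, how many genomes carry a unique SNV
#' there; recurrently hit positions are variation hotspots.
#'
#' @param unique_sets list of per-genome unique-SNV position vectors.
#' @return a `hotspot_summary` list: `counts` (named vector, positions
#'   sorted by descending recurrence), `total_snvs`, `n_positions`.
#' @export
hotspot_positions <- function(unique_sets) {
  pos <- unlist(unique_sets, use.names = FALSE)
  if (!length(pos)) {
    return(structure(list(counts = setNames(integer(), character()),
                          total_snvs = 0L, n_positions = 0L),
                     class = "hotspot_summary"))
  }
  tab <- table(pos)
  counts <- sort(setNames(as.integer(tab), names(tab)),
                 decreasing = TRUE)
  structure(list(counts = counts, total_snvs = length(pos),
                 n_positions = length(counts)),
            class = "hotspot_summary")
}

#' @export
print.hotspot_summary <- function(x, ...) {
  cat(sprintf("hotspots: %d unique SNVs at %d distinct positions\n",
              x$total_snvs, x$n_positions))
  if (x$n_positions) print(head(x$counts, 10))
  invisible(x)
}

#' Number of alleles supported at one pileup position
#'
#' Counts the bases with read support of at least `min_reads` reads
#' and `min_fraction` of the depth; the majority base always counts,
#' so the result lies in 1..4.
#'
#' @param counts numeric vector of A/C/G/T read counts, or a one-row
#'   `pileup_table`.
#' @param min_fraction minimum fraction of depth per supported allele.
#' @param min_reads minimum reads per supported allele.
#' @return integer in 1..4.
#' @export
allele_count <- function(counts, min_fraction = 0.1, min_reads = 5) {
  if (is.data.frame(counts)) counts <- as.numeric(counts[1, .bases])
  stopifnot(length(counts) == 4, all(counts >= 0))
  depth <- sum(counts)
  if (depth == 0) stop("allele count undefined at zero depth")
  max(1L, sum(counts >= min_reads & counts / depth >= min_fraction))
}

#' Allele-number difference of a tumor-normal pair
#'
#' At each shared SNV position the number of supported alleles (1-4)
#' is computed for each genome; the per-genome averages give the mean
#' allele number, and their difference (tumor minus normal) is the
#' pair's allele-difference statistic.
#'
#' @param tumor_pileup,normal_pileup `pileup_table`s of the pair.
#' @param shared_positions 0-based positions of shared SNVs.
#' @param min_fraction,min_reads allele support rule, as in
#'   [allele_count()].
#' @return an `allele_summary` list: `per_position` (data frame of
#'   counts), `abar_tumor`, `abar_normal`, `delta`.
#' @export
allele_difference <- function(tumor_pileup, normal_pileup,
                              shared_positions, min_fraction = 0.1,
                              min_reads = 5) {
  if (!length(shared_positions)) {
    warning("empty shared SNV set; allele difference undefined")
    return(structure(list(per_position = NULL, abar_tumor = NA_real_,
                          abar_normal = NA_real_, delta = NA_real_),
                     class = "allele_summary"))
  }
  count_at <- function(pileup, pos) {
    i <- match(pos, pileup$position)
    if (any(is.na(i))) stop("shared position absent from pileup")
    vapply(i, function(j) {
      allele_count(as.numeric(pileup[j, .bases]), min_fraction, min_reads)
    }, integer(1))
  }
  at <- count_at(tumor_pileup, shared_positions)
  an <- count_at(normal_pileup, shared_positions)
  structure(list(per_position = data.frame(position = shared_positions,
                                           tumor = at, normal = an),
                 abar_tumor = mean(at), abar_normal = mean(an),
                 delta = mean(at) - mean(an)),
            class = "allele_summary")
}

#' Test per-project allele differences against zero
#'
#' Two-sided one-sample t test of the per-pair allele-difference
#' statistics of one project against 0, with the same degenerate
#' handling as [cohort_loss_test()].
#'
#' @param deltas numeric vector of per-pair allele differences.
#' @return a `test_result`.
#' @export
project_allele_test <- function(deltas) {
  deltas <- deltas[!is.na(deltas)]
  if (length(deltas) < 2) stop("need at least 2 pairs")
  one_sample_test(deltas, method = "t")
}
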