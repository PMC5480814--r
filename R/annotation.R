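# Repeat annotation, reference unit and single-copy exon catalog.
# Coordinates are 0-based, half-open (BED convention) throughout; the
# GenBank-style 1-based coordinates of published records are converted
# on ingest.

# U13369.1 feature coordinates (0-based, half-open) for the 42,999 bp
# human 45S repeat unit.  Everything downstream of the 3'ETS is IGS.
.u13369_regions <- data.frame(
  name = c("5ETS", "18S", "ITS1", "5.8S", "ITS2", "28S", "3ETS", "IGS"),
  start = c(0L, 3656L, 5527L, 6622L, 6779L, 7934L, 12969L, 13314L),
  end = c(3656L, 5527L, 6622L, 6779L, 7934L, 12969L, 13314L, 42999L),
  transcribed = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
  stringsAsFactors = FALSE
)

#' Construct and validate a repeat annotation
#'
#' A repeat annotation partitions the 45S repeat unit into named,
#' non-overlapping regions (ETS/ITS spacers, the 18S/5.8S/28S coding
#' sequences, and the intergenic spacer), each flagged as transcribed
#' or not.  Gaps between the supplied regions are auto-assigned to the
#' (non-transcribed) IGS, since the intergenic spacer is everything in
#' the unit not otherwise annotated.
#'
#' @param regions data frame with columns `name`, `start`, `end`
#'   (0-based, half-open) and `transcribed` (logical).
#' @param unit_length total length of the repeat unit in bases;
#'   defaults to the maximum `end`.
#' @return An object of class `repeat_annotation`: a data frame of
#'   regions sorted by `start`, covering `[0, unit_length)` with no
#'   gaps, with attribute `unit_length`.
#' @export
repeat_annotation <- function(regions, unit_length = NULL) {
  stopifnot(is.data.frame(regions),
            all(c("name", "start", "end") %in% names(regions)))
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  if (is.null(regions$transcribed)) {
    regions$transcribed <- regions$name != "IGS"
  }
  regions$transcribed <- as.logical(regions$transcribed)
  if (is.null(unit_length)) unit_length <- max(regions$end)
  unit_length <- as.integer(unit_length)

  bad <- regions$start < 0L | regions$end > unit_length |
    regions$start >= regions$end
  if (any(bad)) {
    stop("invalid interval for region(s): ",
         paste(regions$name[bad], collapse = ", "))
  }
  regions <- regions[order(regions$start), , drop = FALSE]
  ov <- which(regions$start[-1] < regions$end[-nrow(regions)])
  if (length(ov)) {
    stop("overlapping regions: ",
         paste(regions$name[ov + 1], collapse = ", "))
  }

  # fill gaps with IGS segments
  bounds <- c(0L, regions$start, regions$end, unit_length)
  gaps_start <- c(0L, regions$end)
  gaps_end <- c(regions$start, unit_length)
  keep <- gaps_start < gaps_end
  if (any(keep)) {
    igs_names <- if (sum(keep) == 1L && !"IGS" %in% regions$name) "IGS" else
      make.unique(c(regions$name, rep("IGS", sum(keep))))[nrow(regions) + seq_len(sum(keep))]
    fill <- data.frame(name = igs_names,
                       start = gaps_start[keep], end = gaps_end[keep],
                       transcribed = FALSE, stringsAsFactors = FALSE)
    regions <- rbind(regions[, c("name", "start", "end", "transcribed")], fill)
    regions <- regions[order(regions$start), , drop = FALSE]
  } else {
    regions <- regions[, c("name", "start", "end", "transcribed")]
  }
  if (anyDuplicated(regions$name)) {
    stop("duplicate region names: ",
         paste(unique(regions$name[duplicated(regions$name)]), collapse = ", "))
  }
  rownames(regions) <- NULL
  structure(regions, unit_length = unit_length,
            class = c("repeat_annotation", "data.frame"))
}

#' @export
print.repeat_annotation <- function(x, ...) {
  cat(sprintf("45S repeat annotation: %d regions, unit length %d bp\n",
              nrow(x), unit_length(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Unit length of a repeat annotation
#' @param annotation a `repeat_annotation`.
#' @return integer length of the repeat unit in bases.
#' @export
unit_length <- function(annotation) attr(annotation, "unit_length")

#' Load a repeat annotation from a BED file
#'
#' Expects BED4+1: chrom, start, end, name, and optionally a fifth
#' column with the transcribed flag (0/1).  When the flag column is
#' absent, every region except `IGS` is taken as transcribed.  Gaps are
#' auto-assigned to IGS.
#'
#' @param path BED file.
#' @param unit_length unit length; defaults to the maximum interval end.
#' @return a validated [repeat_annotation].
#' @export
load_repeat_annotation <- function(path, unit_length = NULL) {
  stopifnot(file.exists(path))
  bed <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(bed) < 4) stop("annotation BED needs chrom, start, end, name")
  regions <- data.frame(name = as.character(bed[[4]]),
                        start = bed[[2]], end = bed[[3]],
                        stringsAsFactors = FALSE)
  if (ncol(bed) >= 5) regions$transcribed <- bed[[5]] != 0
  repeat_annotation(regions, unit_length = unit_length)
}

#' Write a repeat annotation to a BED file
#'
#' Inverse of [load_repeat_annotation()]: the written file reloads to
#' an identical annotation.
#'
#' @param annotation a `repeat_annotation`.
#' @param path output BED path.
#' @param chrom chromosome label used for the single reference unit.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path, chrom = "45S") {
  bed <- data.frame(chrom = chrom, start = annotation$start,
                    end = annotation$end, name = annotation$name,
                    transcribed = as.integer(annotation$transcribed))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' The U13369-derived annotation of the human 45S repeat unit
#'
#' Region coordinates of the canonical 42,999 bp human ribosomal DNA
#' repeat consensus (GenBank U13369.1): 5'ETS, 18S, ITS1, 5.8S, ITS2,
#' 28S, 3'ETS and the intergenic spacer.
#'
#' @return a [repeat_annotation] with 8 regions and unit length 42,999.
#' @export
u13369_annotation <- function() {
  repeat_annotation(.u13369_regions, unit_length = 42999L)
}

#' A scaled-down repeat annotation for simulation
#'
#' Scales the human 45S region structure to a shorter unit, preserving
#' region proportions (about 31% transcribed).  Useful for fast
#' synthetic cohorts where per-base simulation over the full 43 kb unit
#' is unnecessary.
#'
#' @param unit_length target unit length in bases (default 4300).
#' @return a [repeat_annotation].
#' @export
scaled_annotation <- function(unit_length = 4300L) {
  f <- unit_length / 42999
  b <- unique(round(c(.u13369_regions$start, 42999L) * f))
  regions <- data.frame(name = .u13369_regions$name,
                        start = b[-length(b)], end = b[-1],
                        transcribed = .u13369_regions$transcribed)
  repeat_annotation(regions, unit_length = as.integer(unit_length))
}

#' Transcribed fraction of the repeat unit
#'
#' The proportion of the unit covered by transcribed regions (ETS, ITS,
#' 18S, 5.8S, 28S); the remainder is the non-transcribed IGS.  For the
#' human U13369 unit this is about 0.31.
#'
#' @param annotation a `repeat_annotation`.
#' @return a proportion in `[0, 1]`.
#' @export
transcribed_fraction <- function(annotation) {
  stopifnot(inherits(annotation, "repeat_annotation"))
  sum((annotation$end - annotation$start)[annotation$transcribed]) /
    unit_length(annotation)
}

#' Load and filter a single-copy exon catalog
#'
#' Reads a BED-like file (chrom, start, end, exon_id, gene) and applies
#' the catalog admission rule: each exon must be at least `min_length`
#' bases (the largest exon of a single gene, 300 bp or larger), and at
#' most one exon is kept per gene (the longest; ties broken by exon
#' id).  The number of dropped records is reported.
#'
#' @param path BED-like file with 5 columns.
#' @param min_length minimum admissible exon length in bases.
#' @return an `exon_catalog` data frame with columns `exon_id`,
#'   `chromosome`, `start`, `end`, `gene`.
#' @export
load_exon_catalog <- function(path, min_length = 300L) {
  stopifnot(file.exists(path))
  bed <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(bed) < 5) stop("exon catalog needs chrom, start, end, exon_id, gene")
  cat_df <- data.frame(exon_id = as.character(bed[[4]]),
                       chromosome = as.character(bed[[1]]),
                       start = as.integer(bed[[2]]),
                       end = as.integer(bed[[3]]),
                       gene = as.character(bed[[5]]),
                       stringsAsFactors = FALSE)
  exon_catalog(cat_df, min_length = min_length)
}

#' Apply the exon catalog admission rule
#'
#' @param exons data frame with `exon_id`, `chromosome`, `start`,
#'   `end`, `gene`.
#' @param min_length minimum exon length.
#' @return a filtered `exon_catalog`; filtering is idempotent.
#' @export
exon_catalog <- function(exons, min_length = 300L) {
  stopifnot(is.data.frame(exons),
            all(c("exon_id", "chromosome", "start", "end", "gene") %in%
                  names(exons)))
  n0 <- nrow(exons)
  len <- exons$end - exons$start
  exons <- exons[len >= min_length, , drop = FALSE]
  # one exon per gene: keep the longest, ties to the smallest exon_id
  ord <- order(exons$gene, -(exons$end - exons$start), exons$exon_id)
  exons <- exons[ord, , drop = FALSE]
  exons <- exons[!duplicated(exons$gene), , drop = FALSE]
  if (anyDuplicated(exons$exon_id)) {
    stop("duplicate exon_ids after filtering: ",
         paste(unique(exons$exon_id[duplicated(exons$exon_id)]), collapse = ", "))
  }
  exons <- exons[order(exons$exon_id), , drop = FALSE]
  rownames(exons) <- NULL
  dropped <- n0 - nrow(exons)
  if (dropped > 0) {
    message(sprintf("exon catalog: %d of %d records dropped by admission rule",
                    dropped, n0))
  }
  if (nrow(exons) == 0) {
    stop("exon catalog is empty after filtering; background coverage undefined")
  }
  structure(exons, class = c("exon_catalog", "data.frame"))
}

#' Load a reference repeat unit from FASTA
#'
#' The consensus must contain only A/C/G/T/N; any other ambiguity code
#' is rejected because SNV calling assumes a four-letter reference.
#'
#' @param path FASTA file containing a single sequence.
#' @param annotation optional `repeat_annotation`; when given, the
#'   sequence length must equal the annotation's unit length.
#' @return a `reference_unit` list with `sequence` (character string)
#'   and `accession_label`.
#' @export
load_reference_unit <- function(path, annotation = NULL) {
  stopifnot(file.exists(path))
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) != 1) stop("reference FASTA must contain exactly one sequence")
  s <- toupper(as.character(seqs[[1]]))
  if (grepl("[^ACGTN]", s)) {
    stop("reference contains ambiguity characters other than N")
  }
  if (!is.null(annotation) && nchar(s) != unit_length(annotation)) {
    stop(sprintf("reference length %d != annotation unit length %d",
                 nchar(s), unit_length(annotation)))
  }
  structure(list(sequence = s,
                 accession_label = sub("\\s.*$", "", names(seqs)[1])),
            class = "reference_unit")
}

#' @export
print.reference_unit <- function(x, ...) {
  cat(sprintf("reference unit %s: %d bp\n", x$accession_label,
              nchar(x$sequence)))
  invisible(x)
}
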