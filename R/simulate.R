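# Synthetic cohort generator: paired tumor-normal coverage with known
# rDNA copy number, exon copy states with a planted co-gain cluster,
# pileups with planted shared/unique SNVs, droplet assays, and
# nucleolus images.  Every generator is a pure function of
# (config, seed) and writes enough truth for downstream recovery tests.

# run expr with a fixed RNG state, restoring the caller's stream
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration for a synthetic tumor-normal cohort
#'
#' Describes the study design the generator emulates: several genome
#' projects of matched tumor-normal pairs, a subset of which carry a
#' planted loss of rDNA copies in the tumor (tens of copies against a
#' baseline of several hundred per diploid genome), and a small set of
#' exons planted with a copy gain in the tumors of those same
#' projects.
#'
#' @param projects character vector of project identifiers.
#' @param n_pairs pairs per project; scalar or one value per project.
#' @param positive_projects projects carrying the planted rDNA loss
#'   (and the exon gain cluster).
#' @param normal_cn_mean,normal_cn_sd population distribution of the
#'   germline rDNA copy number (copies per diploid genome).
#' @param loss planted tumor copy loss, in copies.
#' @param n_exons size of the single-copy exon catalog.
#' @param n_gain_exons number of exons in the planted gain cluster.
#' @param gain copies added to gain-cluster exons in positive-project
#'   tumors (baseline exon state is 2).
#' @param depth mean sequencing coverage contributed by one two-copy
#'   (diploid single-copy) locus.
#' @param dispersion negative-binomial overdispersion of per-base
#'   counts (0 gives Poisson).
#' @param error_rate per-base sequencing error rate, in `[0, 0.1]`.
#' @param annotation repeat annotation used for per-base simulation.
#' @param n_shared,n_tumor_unique,n_normal_unique planted SNVs per
#'   pair by class.
#' @param snv_fraction alt allele fraction of planted SNVs.
#' @param tumor_two_allele_prob probability that a shared SNV position
#'   carries residual reference evidence in the tumor (a second
#'   allele, alt fraction `two_allele_fraction`), producing a positive
#'   mean allele-number difference.
#' @param two_allele_fraction alt fraction at two-allele positions.
#' @param seed integer seed; every generator is deterministic given it.
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(projects = paste0("proj", 1:8),
                          n_pairs = c(19, 36, 16, 40, 12, 12, 14, 13),
                          positive_projects = projects[c(5, 7, 8)],
                          normal_cn_mean = 400,
                          normal_cn_sd = 50,
                          loss = 80,
                          n_exons = 16022,
                          n_gain_exons = 100,
                          gain = 1,
                          depth = 30,
                          dispersion = 0.1,
                          error_rate = 0.001,
                          annotation = scaled_annotation(4300L),
                          n_shared = 10,
                          n_tumor_unique = 3,
                          n_normal_unique = 2,
                          snv_fraction = 1.0,
                          tumor_two_allele_prob = 0,
                          two_allele_fraction = 0.7,
                          seed = 1L) {
  n_pairs <- rep_len(as.integer(n_pairs), length(projects))
  stopifnot(length(projects) >= 1, all(n_pairs > 0),
            all(positive_projects %in% projects),
            normal_cn_mean > 0, normal_cn_sd >= 0, loss >= 0,
            n_exons > 0, n_gain_exons >= 0, n_gain_exons <= n_exons,
            gain >= 0, depth >= 0, dispersion >= 0,
            error_rate >= 0, error_rate <= 0.1,
            inherits(annotation, "repeat_annotation"),
            snv_fraction > 0, snv_fraction <= 1,
            tumor_two_allele_prob >= 0, tumor_two_allele_prob <= 1)
  structure(list(projects = projects, n_pairs = n_pairs,
                 positive_projects = positive_projects,
                 normal_cn_mean = normal_cn_mean,
                 normal_cn_sd = normal_cn_sd, loss = loss,
                 n_exons = as.integer(n_exons),
                 n_gain_exons = as.integer(n_gain_exons), gain = gain,
                 depth = depth, dispersion = dispersion,
                 error_rate = error_rate, annotation = annotation,
                 n_shared = as.integer(n_shared),
                 n_tumor_unique = as.integer(n_tumor_unique),
                 n_normal_unique = as.integer(n_normal_unique),
                 snv_fraction = snv_fraction,
                 tumor_two_allele_prob = tumor_two_allele_prob,
                 two_allele_fraction = two_allele_fraction,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a compliant synthetic single-copy exon catalog
#'
#' Exons with unique ids, one per gene, lengths drawn in
#' `[min_length, max_length]`, assigned round-robin to 22 autosomes.
#'
#' @param n_exons number of exons.
#' @param seed RNG seed.
#' @param min_length,max_length exon length range in bases.
#' @return an `exon_catalog`.
#' @export
synth_exon_catalog <- function(n_exons, seed = 1L,
                               min_length = 300L, max_length = 2000L) {
  with_seed(seed, {
    len <- sample(min_length:max_length, n_exons, replace = TRUE)
    start <- as.integer(seq_len(n_exons)) * 10000L
    exon_catalog(data.frame(
      exon_id = sprintf("exon%05d", seq_len(n_exons)),
      chromosome = paste0("chr", rep_len(1:22, n_exons)),
      start = start, end = start + len,
      gene = sprintf("gene%05d", seq_len(n_exons)),
      stringsAsFactors = FALSE))
  })
}

# random four-letter reference over the repeat unit
synth_reference <- function(annotation, seed = 1L) {
  s <- with_seed(seed, paste(sample(c("A", "C", "G", "T"),
                                    unit_length(annotation),
                                    replace = TRUE), collapse = ""))
  structure(list(sequence = s, accession_label = "synthetic45S"),
            class = "reference_unit")
}

#' Draw the ground truth for a synthetic cohort
#'
#' Deterministic given `config$seed`.  Normal rDNA copy numbers are
#' drawn per pair from the configured population distribution; tumors
#' in positive projects carry `normal - loss` copies.  Gain-cluster
#' exons receive `+gain` copies in positive-project tumors only.
#' Planted SNVs are drawn per pair: shared SNVs identical in both
#' genomes, unique SNVs in one genome only.
#'
#' @param config a [cohort_config()].
#' @return a `truth_set` list: `samples` (sample table with true copy
#'   numbers), `catalog`, `gain_exons`, `reference`, `snvs`,
#'   `annotation`, `config`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  ann <- config$annotation
  L <- unit_length(ann)
  catalog <- synth_exon_catalog(config$n_exons, seed = config$seed + 1L)
  reference <- synth_reference(ann, seed = config$seed + 2L)
  with_seed(config$seed, {
    pair_project <- rep(config$projects, config$n_pairs)
    n <- length(pair_project)
    pair_id <- sprintf("pair%03d", seq_len(n))
    normal_cn <- rnorm(n, config$normal_cn_mean, config$normal_cn_sd)
    normal_cn <- pmax(normal_cn, 1)
    if (any(config$loss >= normal_cn)) {
      stop("planted loss magnitude >= drawn normal copy number")
    }
    positive <- pair_project %in% config$positive_projects
    tumor_cn <- normal_cn - ifelse(positive, config$loss, 0)
    samples <- data.frame(
      sample_id = c(paste0(pair_id, "_T"), paste0(pair_id, "_N")),
      pair_id = rep(pair_id, 2),
      project = rep(pair_project, 2),
      role = rep(c("tumor", "normal"), each = n),
      rdna_cn = c(tumor_cn, normal_cn),
      positive_project = rep(positive, 2),
      stringsAsFactors = FALSE)
    gain_exons <- if (config$n_gain_exons > 0)
      sort(sample(catalog$exon_id, config$n_gain_exons)) else character()

    ref_chars <- strsplit(reference$sequence, "")[[1]]
    snvs <- do.call(rbind, lapply(seq_len(n), function(i) {
      k <- config$n_shared + config$n_tumor_unique + config$n_normal_unique
      if (k == 0) return(NULL)
      pos <- sample.int(L, k) - 1L  # 0-based
      cls <- rep(c("shared", "tumor_unique", "normal_unique"),
                 c(config$n_shared, config$n_tumor_unique,
                   config$n_normal_unique))
      alt <- vapply(pos, function(p) {
        sample(setdiff(c("A", "C", "G", "T"), ref_chars[p + 1L]), 1)
      }, character(1))
      two_allele <- cls == "shared" &
        runif(k) < config$tumor_two_allele_prob
      ft <- ifelse(cls == "normal_unique", 0,
                   ifelse(two_allele, config$two_allele_fraction,
                          config$snv_fraction))
      fn <- ifelse(cls == "tumor_unique", 0, config$snv_fraction)
      data.frame(pair_id = pair_id[i], position = pos, alt = alt,
                 fraction_tumor = ft, fraction_normal = fn,
                 class = cls, stringsAsFactors = FALSE)
    }))
    if (is.null(snvs)) {
      snvs <- data.frame(pair_id = character(), position = integer(),
                         alt = character(), fraction_tumor = numeric(),
                         fraction_normal = numeric(), class = character(),
                         stringsAsFactors = FALSE)
    }
    structure(list(samples = samples, catalog = catalog,
                   gain_exons = gain_exons, reference = reference,
                   snvs = snvs, annotation = ann, config = config),
              class = "truth_set")
  })
}

# NB draw with mean mu and overdispersion d (var = mu + d*mu^2);
# d = 0 falls back to Poisson.
rnb <- function(n, mu, dispersion) {
  if (all(mu == 0)) return(numeric(n))
  if (dispersion <= 0) rpois(n, mu) else rnbinom(n, size = 1 / dispersion, mu = mu)
}

# mean of `len` iid NB per-base counts, drawn in closed form
# (sum of len iid NB(mu, size) is NB(len*mu, len*size))
rnb_mean <- function(n, mu, len, dispersion) {
  if (all(mu * len == 0)) return(numeric(n))
  if (dispersion <= 0) rpois(n, len * mu) / len
  else rnbinom(n, size = len / dispersion, mu = len * mu) / len
}

#' Exon copy state for every sample in a truth set
#'
#' Baseline 2 copies; gain-cluster exons carry `2 + gain` in
#' positive-project tumors.
#'
#' @param truth a `truth_set`.
#' @return samples x exons integer matrix of copy states.
#' @export
exon_copy_states <- function(truth) {
  cfg <- truth$config
  m <- matrix(2, nrow = nrow(truth$samples), ncol = nrow(truth$catalog),
              dimnames = list(truth$samples$sample_id,
                              truth$catalog$exon_id))
  gained <- truth$samples$role == "tumor" & truth$samples$positive_project
  if (length(truth$gain_exons) && any(gained)) {
    m[gained, truth$gain_exons] <- 2 + cfg$gain
  }
  m
}

#' Simulate coverage for a cohort
#'
#' Per-base counts over the repeat unit are drawn from a negative
#' binomial with mean `depth * copies / 2` and the configured
#' overdispersion (Poisson when the dispersion is 0); per-exon mean
#' depths are drawn as the average of per-base counts over the exon
#' length, with copies given by each exon's copy state.
#'
#' @param truth a `truth_set` from [simulate_truth()].
#' @param config the same [cohort_config()].
#' @return list of `coverage_profile` objects, one per sample, each
#'   with `sample_id`, per-base `depth`, and named `exon_means`.
#' @export
simulate_coverage <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "truth_set"))
  L <- unit_length(truth$annotation)
  states <- exon_copy_states(truth)
  exon_len <- truth$catalog$end - truth$catalog$start
  with_seed(config$seed + 10L, {
    profiles <- lapply(seq_len(nrow(truth$samples)), function(i) {
      cn <- truth$samples$rdna_cn[i]
      depth <- rnb(L, config$depth * cn / 2, config$dispersion)
      em <- rnb_mean(ncol(states), config$depth * states[i, ] / 2,
                     exon_len, config$dispersion)
      names(em) <- colnames(states)
      coverage_profile(truth$samples$sample_id[i], depth, em)
    })
    names(profiles) <- truth$samples$sample_id
    profiles
  })
}

#' Simulate a pileup table for one genome
#'
#' At planted SNV positions the alt-base read count is
#' `Binomial(depth, fraction)`; elsewhere reads are reference except
#' for sequencing errors at `error_rate`, spread over the three
#' non-reference bases.  Base qualities are 30 at clean and planted
#' columns; error-carrying columns get quality 15, with 10% at 25, so
#' that error noise straddles the >20 calling filter.
#'
#' @param truth a `truth_set`.
#' @param pair_id which pair.
#' @param role `"tumor"` or `"normal"`.
#' @param config the cohort config.
#' @return a `pileup_table` data frame: `position` (0-based), `ref`,
#'   `A`, `C`, `G`, `T`, `qual`.
#' @export
simulate_pileup <- function(truth, pair_id, role = c("tumor", "normal"),
                            config = truth$config) {
  role <- match.arg(role)
  stopifnot(inherits(truth, "truth_set"),
            pair_id %in% truth$samples$pair_id)
  L <- unit_length(truth$annotation)
  ref_chars <- strsplit(truth$reference$sequence, "")[[1]]
  cn <- truth$samples$rdna_cn[truth$samples$pair_id == pair_id &
                                truth$samples$role == role]
  plant <- truth$snvs[truth$snvs$pair_id == pair_id, , drop = FALSE]
  frac <- if (role == "tumor") plant$fraction_tumor else plant$fraction_normal
  plant <- plant[frac > 0 | plant$class == "shared", , drop = FALSE]
  frac <- if (role == "tumor") plant$fraction_tumor else plant$fraction_normal
  if (any(frac <= 0)) stop("planted SNV with allele fraction 0 is undetectable")

  seed <- config$seed + 20L +
    match(pair_id, unique(truth$samples$pair_id)) * 2L +
    (role == "tumor")
  with_seed(seed, {
    depth <- rnb(L, config$depth * cn / 2, config$dispersion)
    bases <- c("A", "C", "G", "T")
    counts <- matrix(0, nrow = L, ncol = 4, dimnames = list(NULL, bases))
    ref_idx <- match(ref_chars, bases)
    # errors: per-position error count, spread over the 3 non-ref bases
    n_err <- rbinom(L, size = depth, prob = config$error_rate)
    counts[cbind(seq_len(L), ref_idx)] <- depth - n_err
    err_pos <- which(n_err > 0)
    for (p in err_pos) {
      alt_idx <- setdiff(1:4, ref_idx[p])
      split <- tabulate(sample(alt_idx, n_err[p], replace = TRUE), nbins = 4)
      counts[p, ] <- counts[p, ] + split
    }
    qual <- rep(30, L)
    if (length(err_pos)) {
      qual[err_pos] <- ifelse(runif(length(err_pos)) < 0.1, 25, 15)
    }
    # planted SNVs override the error model at their positions
    if (nrow(plant)) {
      for (j in seq_len(nrow(plant))) {
        p <- plant$position[j] + 1L
        alt_n <- rbinom(1, size = depth[p], prob = frac[j])
        counts[p, ] <- 0
        counts[p, plant$alt[j]] <- alt_n
        counts[p, ref_chars[p]] <- counts[p, ref_chars[p]] + depth[p] - alt_n
        qual[p] <- 30
      }
    }
    structure(data.frame(position = 0:(L - 1L), ref = ref_chars,
                         A = counts[, "A"], C = counts[, "C"],
                         G = counts[, "G"], T = counts[, "T"],
                         qual = qual, stringsAsFactors = FALSE),
              class = c("pileup_table", "data.frame"))
  })
}

#' Simulate a droplet digital PCR assay
#'
#' Positive-droplet counts for the target and the single-copy
#' reference channel are independent binomials with success
#' probability `1 - exp(-lambda)` per droplet.
#'
#' @param lambda_target,lambda_reference mean copies per droplet.
#' @param n_droplets droplets read.
#' @param seed RNG seed.
#' @param sample_id label for the assay.
#' @return a `droplet_assay` list with `n_droplets`,
#'   `positives_target`, `positives_reference`.
#' @export
simulate_droplet_assay <- function(lambda_target, lambda_reference,
                                   n_droplets, seed = 1L,
                                   sample_id = "assay") {
  stopifnot(lambda_target >= 0, lambda_reference >= 0, n_droplets > 0)
  with_seed(seed, {
    structure(list(
      sample_id = sample_id,
      n_droplets = as.integer(n_droplets),
      positives_target = rbinom(1, n_droplets, 1 - exp(-lambda_target)),
      positives_reference = rbinom(1, n_droplets, 1 - exp(-lambda_reference))),
      class = "droplet_assay")
  })
}

#' Simulate a nucleolus image with disks of known area
#'
#' Renders each disk as a spherical-cap intensity profile (peak
#' `intensity` at the center, falling to zero at the radius edge),
#' emulating the smooth blobs of fluorescent nucleolar staining, and
#' adds Gaussian noise.  The truth area of each disk is the exact
#' count of pixel centers within its radius; overlapping disks are
#' flagged in the truth table.
#'
#' @param disks data frame with columns `x`, `y`, `r`, `intensity`
#'   (pixel coordinates, 1-based centers).
#' @param shape image dimensions `c(rows, cols)`.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed RNG seed.
#' @return list with `image` (matrix) and `truth` (data frame of disk
#'   areas and an `overlaps` flag).
#' @export
simulate_nucleolus_image <- function(disks, shape = c(128L, 128L),
                                     noise_sd = 0, seed = 1L) {
  img <- matrix(0, nrow = shape[1], ncol = shape[2])
  truth <- NULL
  if (!is.null(disks) && nrow(disks)) {
    stopifnot(all(disks$x - disks$r >= 1), all(disks$x + disks$r <= shape[1]),
              all(disks$y - disks$r >= 1), all(disks$y + disks$r <= shape[2]))
    xs <- row(img); ys <- col(img)
    area <- numeric(nrow(disks))
    for (i in seq_len(nrow(disks))) {
      d2 <- (xs - disks$x[i])^2 + (ys - disks$y[i])^2
      inside <- d2 <= disks$r[i]^2
      cap <- disks$intensity[i] * sqrt(1 - d2[inside] / disks$r[i]^2)
      img[inside] <- pmax(img[inside], cap)
      area[i] <- sum(inside)
    }
    overlaps <- vapply(seq_len(nrow(disks)), function(i) {
      any(sqrt((disks$x[-i] - disks$x[i])^2 + (disks$y[-i] - disks$y[i])^2) <
            disks$r[-i] + disks$r[i])
    }, logical(1))
    truth <- data.frame(disk = seq_len(nrow(disks)), area = area,
                        overlaps = overlaps)
  } else {
    truth <- data.frame(disk = integer(), area = numeric(),
                        overlaps = logical())
  }
  if (noise_sd > 0) {
    img <- img + with_seed(seed, matrix(rnorm(length(img), 0, noise_sd),
                                        nrow = shape[1]))
  }
  list(image = img, truth = truth)
}
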