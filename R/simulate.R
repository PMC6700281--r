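#' Construct a repeat-region structure of a given class
#'
#' Builds the run-length structure of an *HTT* repeat region with the
#' stated uninterrupted CAG length and the 3' flank characteristic of each
#' allele class: canonical chromosomes carry
#' `CAA_1 CAG_1 CCG_1 CCA_1 CCG_7 CCT_2` after the CAG run, CAA-loss
#' chromosomes `CCG_12 CCT_2`, and CAACAG-duplication chromosomes
#' `CAA_1 CAG_1 CAA_1 CAG_1 CCG_1 CCA_1 CCG_7 CCT_3`.
#'
#' @param cag uninterrupted CAG length (>= 3 so the profiling anchor
#'   exists).
#' @param class `"canonical"`, `"caa_loss"`, or `"caacag_dup"`.
#' @return A `repeat_structure`.
#' @export
hd_structure <- function(cag, class = "canonical") {
  stopifnot(cag >= 3L)
  head <- sprintf("CAG_%d", as.integer(cag))
  flank <- switch(class,
    canonical = "CAA_1 CAG_1 CCG_1 CCA_1 CCG_7 CCT_2",
    caa_loss = "CCG_12 CCT_2",
    caacag_dup = "CAA_1 CAG_1 CAA_1 CAG_1 CCG_1 CCA_1 CCG_7 CCT_3",
    stop("unknown class: ", class))
  parse_structure(paste(head, flank))
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic cohort, read, and trace
#' generators with validated defaults. Defaults describe a plausible HD GWAS
#' cohort: disease-allele CAG lengths 40-55 with a geometric-like decay,
#' >95% canonical repeat structures with rare CAA-loss and
#' CAACAG-duplication chromosomes, a log-linear CAG-onset expectation, an
#' 8-year Gaussian onset residual, 2x300 bp reads at 100 pairs per allele
#' with 0.5% per-base error, and fragment traces whose expansion-tail mass
#' grows with inherited CAG length.
#'
#' @param seed integer seed; mandatory, drives every generator.
#' @param n_subjects cohort size.
#' @param cag_range inclusive disease-allele CAG range.
#' @param cag_weights sampling weights over `cag_range` (default decaying).
#' @param class_mix named proportions for
#'   canonical/caa_loss/caacag_dup; must sum to 1.
#' @param misprime_prob Bernoulli probability that a duplication chromosome
#'   mis-primes in the fragment assay (+1 rather than +2).
#' @param onset_model truth [onset_model()] for expected onset.
#' @param residual_sd SD (years) of the Gaussian onset residual.
#' @param snps data.frame of modifier SNPs: columns `id`, `maf`, `effect`
#'   (years per minor allele; negative = hastening), optional `tags_class`
#'   (a structure class whose carriers all bear one minor allele,
#'   emulating a rare tag SNP in perfect LD with a non-canonical
#'   structure).
#' @param coverage read pairs per allele.
#' @param read_length read length in bases (default 300).
#' @param base_error per-base substitution error rate.
#' @param stutter_ratio,stutter_decay height of the first left stutter peak
#'   relative to the main peak and its per-step decay.
#' @param propensity_base,propensity_slope mean somatic-expansion propensity
#'   at CAG 40 and its increase per CAG.
#' @param propensity_phi Beta precision of the per-subject propensity.
#' @param coupling_snp,coupling_coef optional SNP id whose dosage shifts
#'   the mean propensity by `coupling_coef` per minor allele.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_subjects = 500L,
                       cag_range = c(40L, 55L),
                       cag_weights = NULL,
                       class_mix = c(canonical = 0.96, caa_loss = 0.025,
                                     caacag_dup = 0.015),
                       misprime_prob = 0.5,
                       onset_model = cagtract::onset_model(
                         "loglinear", c(a = 6.5, b = -0.063)),
                       residual_sd = 8,
                       snps = NULL,
                       coverage = 100L,
                       read_length = 300L,
                       base_error = 0.005,
                       stutter_ratio = 0.35,
                       stutter_decay = 0.5,
                       propensity_base = 0.05,
                       propensity_slope = 0.012,
                       propensity_phi = 50,
                       coupling_snp = NULL,
                       coupling_coef = 0) {
  if (missing(seed)) stop("seed is mandatory")
  cag_range <- as.integer(cag_range)
  k <- cag_range[2L] - cag_range[1L] + 1L
  if (is.null(cag_weights)) cag_weights <- 0.8^seq_len(k)
  stopifnot(length(cag_weights) == k, all(cag_weights > 0))
  if (abs(sum(class_mix) - 1) > 1e-8 || any(class_mix < 0)) {
    stop("class_mix proportions must be non-negative and sum to 1")
  }
  stopifnot(misprime_prob >= 0, misprime_prob <= 1,
            base_error >= 0, base_error <= 1,
            residual_sd > 0, coverage >= 1, read_length >= 30)
  structure(list(
    seed = as.integer(seed), n_subjects = as.integer(n_subjects),
    cag_range = cag_range, cag_weights = cag_weights / sum(cag_weights),
    class_mix = class_mix, misprime_prob = misprime_prob,
    onset_model = onset_model, residual_sd = residual_sd, snps = snps,
    coverage = as.integer(coverage), read_length = as.integer(read_length),
    base_error = base_error,
    stutter_ratio = stutter_ratio, stutter_decay = stutter_decay,
    propensity_base = propensity_base, propensity_slope = propensity_slope,
    propensity_phi = propensity_phi,
    coupling_snp = coupling_snp, coupling_coef = coupling_coef
  ), class = "sim_config")
}

draw_class <- function(n, mix) {
  sample(names(mix), n, replace = TRUE, prob = mix)
}

#' Simulate per-subject repeat-structure allele pairs
#'
#' Disease-allele CAG lengths are drawn from the configured distribution
#' and classes from the configured mix; the normal allele is a canonical
#' structure of 15-25 CAGs.
#'
#' @param config a [sim_config()]; its seed is set on entry, so a fixed
#'   config reproduces identical output.
#' @param n number of subjects (default `config$n_subjects`).
#' @return List of length `n`; each element has `disease` and `normal`
#'   (`repeat_structure`), `class`, and `misprime`.
#' @export
simulate_alleles <- function(config, n = config$n_subjects) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  cags <- sample(seq(config$cag_range[1L], config$cag_range[2L]), n,
                 replace = TRUE, prob = config$cag_weights)
  classes <- draw_class(n, config$class_mix)
  misprime <- classes == "caacag_dup" &
    stats::runif(n) < config$misprime_prob
  normal_cags <- sample(15:25, n, replace = TRUE)
  lapply(seq_len(n), function(i) {
    list(disease = hd_structure(cags[i], classes[i]),
         normal = hd_structure(normal_cags[i], "canonical"),
         class = classes[i],
         misprime = misprime[i])
  })
}

# upstream amplicon context (primer-proximal exon-1 sequence; contains no
# CAGCAGCAG) and downstream proline-rich filler after the tract terminator
sim_upstream <- "ATGAAGGCCTTCGAGTCCCTCAAGTCCTTC"
sim_downstream <- "CCTCCTCAGCCGCCACCGCCG"

# inject independent per-base substitution errors into n copies of a
# template; each error replaces the base by one of the other three
mutate_batch <- function(template, n, error) {
  if (error <= 0) return(rep(template, n))
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(template, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  M <- matrix(rep(chars, each = n), nrow = n)
  hits <- which(stats::runif(n * L) < error)
  if (length(hits)) {
    k <- match(M[hits], bases)
    r <- sample.int(3L, length(hits), replace = TRUE)
    M[hits] <- bases[((k - 1L + r) %% 4L) + 1L]
  }
  apply(M, 1L, paste, collapse = "")
}

#' Simulate paired-end reads from repeat structures
#'
#' Builds the amplicon (upstream context, repeat region, `CAGCTTCCT`
#' terminator, downstream filler) for each structure and emits
#' `config$coverage` read pairs per structure: the forward read is the
#' amplicon 5' prefix, the mate the reverse complement of its 3' suffix,
#' each carrying independent per-base substitution errors. Pairs whose read
#' length is shorter than the amplicon are flagged truncated (and still
#' emitted).
#'
#' @param structures list of `repeat_structure` (e.g. the two alleles of a
#'   sample, or any library).
#' @param config a [sim_config()].
#' @param seed optional integer; when given, set on entry (use distinct
#'   seeds for distinct samples). Defaults to `config$seed + 2`.
#' @return data.frame with columns `allele` (index into `structures`),
#'   `fwd`, `rev`, `truncated`.
#' @export
simulate_reads <- function(structures, config, seed = config$seed + 2L) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", length(structures))
  for (a in seq_along(structures)) {
    amplicon <- paste0(sim_upstream,
                       structure_to_dna(structures[[a]],
                                        with_terminator = TRUE),
                       sim_downstream)
    len <- nchar(amplicon)
    rl <- min(config$read_length, len)
    truncated <- config$read_length < len
    fwd_t <- substring(amplicon, 1L, rl)
    rev_t <- reverse_complement(substring(amplicon, len - rl + 1L, len))
    fwd <- mutate_batch(fwd_t, config$coverage, config$base_error)
    rev <- mutate_batch(rev_t, config$coverage, config$base_error)
    out[[a]] <- data.frame(allele = a, fwd = fwd, rev = rev,
                           truncated = truncated,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write simulated read pairs to a pair of FASTQ files
#'
#' @param reads data.frame from [simulate_reads()].
#' @param fastq1,fastq2 output paths (forward reads and mates).
#' @param sample id used in read names.
#' @export
write_fastq_pair <- function(reads, fastq1, fastq2, sample = "sim") {
  ids <- sprintf("@%s:%d/%%d", sample, seq_len(nrow(reads)))
  q <- function(s) strrep("I", nchar(s))
  writeLines(rbind(sprintf(ids, 1L), reads$fwd, "+", q(reads$fwd)), fastq1)
  writeLines(rbind(sprintf(ids, 2L), reads$rev, "+", q(reads$rev)), fastq2)
  invisible(c(fastq1, fastq2))
}

# mean somatic-expansion propensity as a function of CAG (and optional
# modifier dosage), clamped into (0, 1)
propensity_mean <- function(config, cag, dosage = 0) {
  mu <- config$propensity_base +
    config$propensity_slope * (cag - config$cag_range[1L]) +
    config$coupling_coef * dosage
  pmin(pmax(mu, 0.005), 0.8)
}

#' Simulate one sample's fragment-analysis peak records
#'
#' Emits a main peak at the called CAG allele, left-of-main PCR stutter
#' peaks with geometrically decaying heights, and right-of-main expansion
#' peaks whose summed height equals `propensity` times the main peak
#' height, split over peaks of at least `min_peak_height` RFU each.
#' Fragment sizes follow `size = plate_offset + 3 * cag`.
#'
#' @param sample sample id.
#' @param main_cag inherited (called) main CAG allele.
#' @param propensity expansion height fraction for this sample.
#' @param config a [sim_config()].
#' @param plate plate id.
#' @param plate_offset intercept (bp) of the plate's size model.
#' @param main_height main peak height in RFU.
#' @param min_peak_height smallest expansion peak the generator will emit.
#' @return data.frame of peak records (columns as [read_peak_table()]).
#' @export
simulate_trace <- function(sample, main_cag, propensity, config,
                           plate = "P1", plate_offset = 88,
                           main_height = 4000, min_peak_height = 60) {
  stopifnot(propensity >= 0)
  cags <- main_cag
  heights <- main_height
  n_stutter <- 3L
  for (k in seq_len(n_stutter)) {
    cags <- c(cags, main_cag - k)
    heights <- c(heights,
                 main_height * config$stutter_ratio *
                   config$stutter_decay^(k - 1L))
  }
  if (propensity > 0) {
    total <- propensity * main_height
    # equal split over as many peaks as stay above the detection filter
    n_exp <- max(1L, min(4L, floor(total / min_peak_height)))
    cags <- c(cags, main_cag + seq_len(n_exp))
    heights <- c(heights, rep(total / n_exp, n_exp))
  }
  size <- plate_offset + 3 * cags
  data.frame(sample = sample, plate = plate, called_cag = main_cag,
             size_bp = size, height_rfu = heights, area = heights * 2,
             scan = as.integer(round(size * 10)),
             stringsAsFactors = FALSE)
}

#' Simulate a cohort's fragment traces
#'
#' Draws a per-subject Beta-distributed expansion propensity whose mean
#' increases with inherited CAG length (and optionally with the dosage of a
#' designated modifier SNP) and emits one trace per subject, grouped onto
#' 96-sample plates with slightly different size-calibration intercepts.
#'
#' @param cohort data.frame with `id` and a CAG column (`true_cag` or
#'   `est_cag`).
#' @param config a [sim_config()]; its seed (+3) is set on entry.
#' @param dosages optional named-row dosage matrix for propensity coupling.
#' @return List with `peaks` (full peak table) and `propensity` (named
#'   vector of generating propensities).
#' @export
simulate_trace_cohort <- function(cohort, config, dosages = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  cag <- if (!is.null(cohort$true_cag)) cohort$true_cag else cohort$est_cag
  dose <- rep(0, nrow(cohort))
  if (!is.null(config$coupling_snp) && !is.null(dosages)) {
    dose <- dosages[cohort$id, config$coupling_snp]
  }
  mu <- propensity_mean(config, cag, dose)
  phi <- config$propensity_phi
  prop <- stats::rbeta(nrow(cohort), mu * phi, (1 - mu) * phi)
  plate_ids <- paste0("P", (seq_len(nrow(cohort)) - 1L) %/% 96L + 1L)
  offsets <- stats::runif(length(unique(plate_ids)), 87, 89)
  names(offsets) <- unique(plate_ids)
  main_heights <- stats::runif(nrow(cohort), 3000, 5000)
  peaks <- do.call(rbind, lapply(seq_len(nrow(cohort)), function(i) {
    simulate_trace(cohort$id[i], cag[i], prop[i], config,
                   plate = plate_ids[i],
                   plate_offset = offsets[plate_ids[i]],
                   main_height = main_heights[i])
  }))
  list(peaks = peaks, propensity = stats::setNames(prop, cohort$id))
}

#' Simulate a full cohort: phenotypes, mis-estimated CAG, SNP dosages
#'
#' Onset is generated as
#' `expected(true CAG) + sum(dosage * effect) + N(0, residual_sd)` with the
#' truth onset model from the config; the estimated CAG is distorted per
#' structure class exactly as the fragment assay distorts it (CAA-loss -2,
#' duplication +2 or +1 with mis-priming); SNP genotypes are drawn under
#' Hardy-Weinberg equilibrium at the configured minor allele frequencies.
#' A SNP with `tags_class` set instead marks every carrier of that
#' structure class with one minor allele (a perfect tag of the
#' non-canonical haplotype).
#'
#' @param config a [sim_config()]; seed (+4) set on entry.
#' @return List with `cohort` (data.frame: `id`, `sex`, `onset_years`,
#'   `est_cag`, `true_cag`, `class`, `misprime`), `dosages` (n x SNP
#'   matrix, rownames = ids), and `truth` (generating model, effects,
#'   classes).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 4L)
  n <- config$n_subjects
  cags <- sample(seq(config$cag_range[1L], config$cag_range[2L]), n,
                 replace = TRUE, prob = config$cag_weights)
  classes <- draw_class(n, config$class_mix)
  misprime <- classes == "caacag_dup" &
    stats::runif(n) < config$misprime_prob
  est <- fragment_assay_estimate(cags, classes, misprime)
  ids <- sprintf("S%05d", seq_len(n))
  snps <- config$snps
  dosages <- NULL
  genetic <- rep(0, n)
  if (!is.null(snps) && nrow(snps) > 0L) {
    dosages <- matrix(0L, n, nrow(snps),
                      dimnames = list(ids, snps$id))
    for (j in seq_len(nrow(snps))) {
      if (!is.null(snps$tags_class) && !is.na(snps$tags_class[j]) &&
          nzchar(snps$tags_class[j])) {
        dosages[, j] <- as.integer(classes == snps$tags_class[j])
      } else {
        dosages[, j] <- stats::rbinom(n, 2L, snps$maf[j])
      }
      genetic <- genetic + dosages[, j] * snps$effect[j]
    }
  }
  onset <- expected_onset(cags, config$onset_model) + genetic +
    stats::rnorm(n, 0, config$residual_sd)
  onset <- pmax(onset, 1)
  cohort <- data.frame(
    id = ids,
    sex = sample(c("F", "M"), n, replace = TRUE),
    onset_years = onset,
    est_cag = est,
    true_cag = cags,
    class = classes,
    misprime = misprime,
    stringsAsFactors = FALSE
  )
  list(cohort = cohort, dosages = dosages,
       truth = list(onset_model = config$onset_model,
                    residual_sd = config$residual_sd,
                    snps = snps))
}

#' Write a simulated cohort to disk
#'
#' Writes the cohort TSV, the dosage TSV (samples x SNPs), and a JSON truth
#' summary alongside.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisible character vector of written paths.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort_path <- file.path(dir, "cohort.tsv")
  utils::write.table(sim$cohort, cohort_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- cohort_path
  if (!is.null(sim$dosages)) {
    dosage_path <- file.path(dir, "dosages.tsv")
    utils::write.table(
      data.frame(id = rownames(sim$dosages), sim$dosages,
                 check.names = FALSE),
      dosage_path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, dosage_path)
  }
  invisible(paths)
}
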