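#' Hardy-Weinberg expected genotype counts from an external allele frequency
#'
#' Expected counts for (major homozygote, heterozygote, minor homozygote)
#' in a subgroup of size `n`, computed from a minor allele frequency fixed
#' externally (e.g. in the full cohort the subgroup was drawn from):
#' `n(1-q)^2, 2nq(1-q), nq^2`.
#'
#' @param n subgroup size.
#' @param maf minor allele frequency in (0, 1).
#' @return Named numeric vector `c(major_hom, het, minor_hom)`; rounds to
#'   the conventional integer display via `round()`.
#' @examples
#' round(hwe_expected_counts(1753, 0.257))  # 968 669 116
#' @export
hwe_expected_counts <- function(n, maf) {
  stopifnot(n > 0, maf > 0, maf < 1)
  q <- maf
  c(major_hom = n * (1 - q)^2, het = 2 * n * q * (1 - q),
    minor_hom = n * q^2)
}

#' Chi-square test of genotype counts against external HWE expectations
#'
#' `sum((obs - exp)^2 / exp)` over the three genotype classes, with the
#' upper-tail p-value on 2 degrees of freedom. The degrees of freedom stay
#' at 2 (not the conventional 1) because the expected counts derive from an
#' externally fixed allele frequency rather than one estimated from the
#' observed table.
#'
#' @param observed integer vector of observed counts
#'   (major hom, het, minor hom).
#' @param expected expected counts, e.g. from [hwe_expected_counts()]; all
#'   must be positive.
#' @return List with `statistic`, `df` (2), and `p`.
#' @examples
#' hwe_chisq(c(915, 684, 154), hwe_expected_counts(1753, 0.257))
#' @export
hwe_chisq <- function(observed, expected) {
  stopifnot(length(observed) == 3L, length(expected) == 3L)
  if (any(expected <= 0)) stop("expected counts must all be positive")
  stat <- sum((observed - expected)^2 / expected)
  list(statistic = stat, df = 2L,
       p = stats::pchisq(stat, df = 2L, lower.tail = FALSE))
}

#' Marginal association of a SNP with the residual onset phenotype
#'
#' Fixed-effects least squares of the residual age at onset on the minor
#' allele count of the test SNP, with optional covariates (sex, principal
#' components, ...). The dosage coefficient is the modifier effect in years
#' per minor allele: negative = hastened onset, positive = delayed.
#'
#' @param dosage numeric vector of minor allele counts (0/1/2 or imputed
#'   dosages); must vary.
#' @param phenotype numeric residual-onset vector.
#' @param covariates optional numeric matrix or data.frame of covariates.
#' @return List with `beta` (years/allele), `se`, `p` (two-sided), `n`.
#' @export
marginal_association <- function(dosage, phenotype, covariates = NULL) {
  conditional_association(dosage, phenotype, covariates,
                          conditioning = NULL)
}

#' Conditional association given the dosage of conditioning SNPs
#'
#' Re-runs the fixed-effects association with the minor allele counts of
#' one or more conditioning SNPs (typically the top SNP of the locus) added
#' as covariates, testing whether the test SNP carries signal independent
#' of them.
#'
#' @inheritParams marginal_association
#' @param conditioning numeric vector or matrix of conditioning-SNP
#'   dosages; `NULL` reduces to [marginal_association()].
#' @return List with `beta`, `se`, `p`, `n` for the test dosage.
#' @export
conditional_association <- function(dosage, phenotype, covariates = NULL,
                                    conditioning = NULL) {
  if (stats::var(dosage) == 0) stop("test dosage has zero variance")
  X <- data.frame(.dosage = dosage)
  if (!is.null(conditioning)) {
    conditioning <- as.matrix(conditioning)
    colnames(conditioning) <- paste0(".cond", seq_len(ncol(conditioning)))
    X <- cbind(X, conditioning)
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    names(covariates) <- paste0(".cov", seq_len(ncol(covariates)))
    X <- cbind(X, covariates)
  }
  if (nrow(X) <= ncol(X) + 2L) stop("too few observations for the model")
  fit <- stats::lm(phenotype ~ ., data = cbind(phenotype = phenotype, X))
  aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  if (length(aliased)) {
    stop("collinear terms in the design (aliased: ",
         paste(aliased, collapse = ", "),
         "); the test dosage must be linearly independent of the ",
         "conditioning/covariate set")
  }
  co <- stats::coef(summary(fit))
  list(beta = co[".dosage", "Estimate"],
       se = co[".dosage", "Std. Error"],
       p = co[".dosage", "Pr(>|t|)"],
       n = length(phenotype))
}

#' Logistic association with the dichotomous onset phenotype
#'
#' Plain fixed-effects logistic regression of the late/early group label on
#' the test dosage plus covariates; provided as plumbing for dichotomous
#' analyses.
#'
#' @param dosage minor allele counts.
#' @param group character or factor with levels `"early"` and `"late"`
#'   (late is modelled as the event).
#' @param covariates optional covariates.
#' @return List with `beta` (log odds per allele), `se`, `p`, `n`.
#' @export
dichotomous_association <- function(dosage, group, covariates = NULL) {
  y <- as.integer(as.character(group) == "late")
  X <- data.frame(.dosage = dosage)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    names(covariates) <- paste0(".cov", seq_len(ncol(covariates)))
    X <- cbind(X, covariates)
  }
  fit <- stats::glm(y ~ ., data = cbind(y = y, X), family = stats::binomial())
  co <- stats::coef(summary(fit))
  list(beta = co[".dosage", "Estimate"], se = co[".dosage", "Std. Error"],
       p = co[".dosage", "Pr(>|z|)"], n = length(y))
}

#' Hardy-Weinberg enrichment report for the top somatic-expansion quartile
#'
#' Composes the expansion-index quartiling with the externally-fixed-MAF
#' HWE test: samples are ranked by peak proportional sum (pooled by
#' default, or within each main CAG length with
#' `stratify_by_cag = TRUE`), the top quartile's genotype counts at the
#' test SNP are tabulated, and they are compared with Hardy-Weinberg
#' expectations at the full-cohort minor allele frequency.
#'
#' @param idx data.frame from [expansion_index()].
#' @param genotypes named integer vector of minor-allele counts (0/1/2) per
#'   sample (names = sample ids).
#' @param maf minor allele frequency fixed from the full cohort; defaults
#'   to the frequency computed from `genotypes`.
#' @param stratify_by_cag rank within each main CAG length instead of
#'   pooled.
#' @return List with `n_top`, `observed`, `expected`, `statistic`, `df`,
#'   `p`, and `top_samples`.
#' @export
top_quartile_hwe_report <- function(idx, genotypes, maf = NULL,
                                    stratify_by_cag = FALSE) {
  idx <- idx[idx$sample %in% names(genotypes), , drop = FALSE]
  if (is.null(maf)) {
    g <- genotypes[idx$sample]
    maf <- sum(g) / (2 * length(g))
  }
  if (stratify_by_cag) {
    top <- unlist(lapply(split(idx, idx$main_cag), function(part) {
      if (nrow(part) < 4L) return(character(0))
      ranked <- rank_top_quartile(part)
      ranked$sample[ranked$quartile == 1L]
    }), use.names = FALSE)
  } else {
    ranked <- rank_top_quartile(idx)
    top <- ranked$sample[ranked$quartile == 1L]
  }
  g_top <- genotypes[top]
  observed <- c(major_hom = sum(g_top == 0L), het = sum(g_top == 1L),
                minor_hom = sum(g_top == 2L))
  expected <- hwe_expected_counts(length(g_top), maf)
  test <- hwe_chisq(observed, expected)
  list(n_top = length(g_top), maf = maf, observed = observed,
       expected = expected, statistic = test$statistic, df = test$df,
       p = test$p, top_samples = top)
}
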