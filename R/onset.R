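#' CAG-onset phenotype model
#'
#' Encapsulates the expectation of age at motor onset as a function of the
#' expanded allele's uninterrupted CAG length. Two functional forms are
#' supported:
#' \describe{
#'   \item{`loglinear`}{`E[AO] = exp(a + b * CAG)` with `b < 0`
#'     (coefficients `a`, `b`).}
#'   \item{`expshift`}{`E[AO] = c + exp(a + b * CAG)` with `b < 0` and
#'     `c >= 0` (coefficients `a`, `b`, `c`), the shifted-exponential form
#'     used by several published onset formulas.}
#' }
#' Expected onset must be strictly decreasing and positive over the stated
#' valid CAG range; this is checked at construction.
#'
#' @param form `"loglinear"` or `"expshift"`.
#' @param coef named numeric coefficients (see above).
#' @param range length-2 integer vector, the valid CAG range (inclusive).
#' @return An object of class `onset_model`.
#' @examples
#' m <- onset_model("loglinear", c(a = 6, b = -0.05), range = c(36, 62))
#' expected_onset(42, m)
#' @export
onset_model <- function(form = c("loglinear", "expshift"), coef,
                        range = c(36L, 62L)) {
  form <- match.arg(form)
  needed <- if (form == "loglinear") c("a", "b") else c("a", "b", "c")
  if (!all(needed %in% names(coef))) {
    stop("coef must contain: ", paste(needed, collapse = ", "))
  }
  range <- as.integer(range)
  stopifnot(length(range) == 2L, range[1L] < range[2L])
  m <- structure(list(form = form, coef = coef[needed], range = range),
                 class = "onset_model")
  grid <- seq(range[1L], range[2L])
  eo <- expected_onset(grid, m, .check_range = FALSE)
  if (any(!is.finite(eo)) || any(eo <= 0)) {
    stop("expected onset must be finite and positive over the valid range")
  }
  if (any(diff(eo) >= 0)) {
    stop("expected onset must be strictly decreasing in CAG")
  }
  m
}

#' @export
print.onset_model <- function(x, ...) {
  cat("<onset_model> form ", x$form, ", valid CAG ", x$range[1L], "-",
      x$range[2L], "\n  coef: ",
      paste(sprintf("%s = %.5g", names(x$coef), x$coef), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Expected age at onset for a CAG length
#'
#' @param cag integer vector of uninterrupted CAG lengths within the model's
#'   valid range.
#' @param model an [onset_model()].
#' @param .check_range internal.
#' @return Numeric vector of expected onset ages in years.
#' @export
expected_onset <- function(cag, model, .check_range = TRUE) {
  stopifnot(inherits(model, "onset_model"))
  if (.check_range &&
      (any(cag < model$range[1L]) || any(cag > model$range[2L]))) {
    stop("CAG outside the model's valid range [",
         model$range[1L], ", ", model$range[2L], "]")
  }
  co <- model$coef
  switch(model$form,
         loglinear = exp(co[["a"]] + co[["b"]] * cag),
         expshift = co[["c"]] + exp(co[["a"]] + co[["b"]] * cag))
}

#' Residual age at onset
#'
#' Observed age at motor onset minus the onset expected from CAG length, in
#' natural-scale years; +5 means motor symptoms emerged 5 years later than
#' expected for that CAG length.
#'
#' @param observed observed onset ages (years, > 0).
#' @param expected expected onset ages (years, > 0).
#' @return Numeric vector of residuals in years.
#' @export
residual_onset <- function(observed, expected) {
  if (any(observed <= 0) || any(expected <= 0)) {
    stop("onset ages must be positive")
  }
  observed - expected
}

#' Default log-linear onset model fit to the shipped reference cohort
#'
#' Fits `log(onset) ~ cag` by least squares on the synthetic reference
#' cohort in `inst/extdata/synthetic_reference_cohort.tsv` and returns the
#' resulting `loglinear` [onset_model()]. The reference cohort is synthetic
#' (generated by this package's cohort simulator) and exists to pin down a
#' concrete, reproducible default; any study should substitute a model fit
#' to its own data via [fit_onset_model()] or [onset_model()].
#'
#' @param range valid CAG range for the returned model.
#' @return An `onset_model`.
#' @export
default_onset_model <- function(range = c(36L, 62L)) {
  path <- system.file("extdata", "synthetic_reference_cohort.tsv",
                      package = "cagtract", mustWork = TRUE)
  ref <- utils::read.delim(path)
  fit_onset_model(ref$cag, ref$onset_years, range = range)
}

#' Fit a log-linear onset model to observed (CAG, onset) pairs
#'
#' @param cag integer vector of expanded-allele CAG lengths.
#' @param onset_years observed onset ages.
#' @param range valid CAG range for the returned model.
#' @return An `onset_model` with `form = "loglinear"`.
#' @export
fit_onset_model <- function(cag, onset_years, range = c(36L, 62L)) {
  fit <- stats::lm(log(onset_years) ~ cag)
  onset_model("loglinear",
              c(a = unname(stats::coef(fit)[1L]),
                b = unname(stats::coef(fit)[2L])),
              range = range)
}

#' Read a cohort table
#'
#' Tab-separated with columns `id`, `sex`, `onset_years`, `est_cag`, and
#' optionally `true_cag`, `class`, `misprime`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("id", "onset_years", "est_cag")
  missing <- setdiff(required, names(cohort))
  if (length(missing)) {
    stop("cohort table lacks column(s): ", paste(missing, collapse = ", "))
  }
  cohort
}

#' Compute residual age at onset for a cohort
#'
#' Adds `expected_onset` and `residual` columns based on the estimated CAG;
#' when `use_true_cag = TRUE` and a `true_cag` column is present, also adds
#' `expected_onset_true` and `residual_true` (the estimated-CAG residual is
#' retained for comparison).
#'
#' @param cohort cohort data.frame (see [read_cohort()]).
#' @param model an [onset_model()].
#' @param use_true_cag also compute the true-CAG residual where available.
#' @return The augmented cohort data.frame.
#' @export
phenotype_cohort <- function(cohort, model, use_true_cag = FALSE) {
  cohort$expected_onset <- expected_onset(cohort$est_cag, model)
  cohort$residual <- residual_onset(cohort$onset_years,
                                    cohort$expected_onset)
  if (use_true_cag) cohort <- recompute_with_true_cag(cohort, model)
  cohort
}

#' Recompute residuals from the true uninterrupted CAG length
#'
#' For subjects whose non-canonical repeat structure led the fragment assay
#' to mis-estimate the CAG length, the residual is recomputed from the true
#' length (see [correct_estimated_cag()]); subjects without a `true_cag`
#' keep their estimated-CAG residual as the true-CAG residual. Idempotent.
#'
#' @param cohort cohort data.frame with `residual` already computed (or it
#'   is computed here from `est_cag`).
#' @param model an [onset_model()].
#' @return Cohort with `expected_onset_true` and `residual_true` columns.
#' @export
recompute_with_true_cag <- function(cohort, model) {
  if (is.null(cohort$residual)) {
    cohort$expected_onset <- expected_onset(cohort$est_cag, model)
    cohort$residual <- residual_onset(cohort$onset_years,
                                      cohort$expected_onset)
  }
  if (is.null(cohort$true_cag)) {
    warning("no true_cag column; residuals unchanged")
    cohort$expected_onset_true <- cohort$expected_onset
    cohort$residual_true <- cohort$residual
    return(cohort)
  }
  cag <- ifelse(is.na(cohort$true_cag), cohort$est_cag, cohort$true_cag)
  cohort$expected_onset_true <- expected_onset(cag, model)
  cohort$residual_true <- residual_onset(cohort$onset_years,
                                         cohort$expected_onset_true)
  cohort
}

#' Restrict a cohort to the primary analysis CAG range
#'
#' Keeps subjects whose expanded-allele CAG length (true where available,
#' otherwise estimated) lies in 40-55, the range analysed to minimise
#' inaccuracy in the residual phenotype.
#'
#' @param cohort cohort data.frame.
#' @param min_cag,max_cag inclusive bounds (defaults 40 and 55).
#' @return Filtered cohort.
#' @export
filter_cohort <- function(cohort, min_cag = 40L, max_cag = 55L) {
  cag <- if (!is.null(cohort$true_cag)) {
    ifelse(is.na(cohort$true_cag), cohort$est_cag, cohort$true_cag)
  } else {
    cohort$est_cag
  }
  cohort[cag >= min_cag & cag <= max_cag, , drop = FALSE]
}

#' Dichotomize a cohort into late- and early-onset groups
#'
#' Subjects are sorted by residual age at onset; the top `fraction` form the
#' late-onset group and the bottom `fraction` the early-onset group, each of
#' exactly `floor(fraction * n)` subjects. Ties at a boundary are broken by
#' subject id.
#'
#' @param cohort cohort data.frame with a `residual` column (use
#'   `residual_col` to dichotomize on another column, e.g.
#'   `"residual_true"`).
#' @param fraction group fraction in (0, 0.5] (default 0.30).
#' @param residual_col residual column name.
#' @return Cohort with an added `onset_group` column (`"late"`, `"early"`,
#'   or `NA` for the middle).
#' @export
dichotomize <- function(cohort, fraction = 0.30, residual_col = "residual") {
  stopifnot(fraction > 0, fraction <= 0.5)
  r <- cohort[[residual_col]]
  if (is.null(r)) stop("no '", residual_col, "' column; run phenotype_cohort")
  n <- nrow(cohort)
  k <- floor(fraction * n)
  ord <- order(-r, cohort$id)
  cohort$onset_group <- NA_character_
  if (k > 0L) {
    cohort$onset_group[ord[seq_len(k)]] <- "late"
    cohort$onset_group[ord[seq.int(n - k + 1L, n)]] <- "early"
  }
  cohort
}
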