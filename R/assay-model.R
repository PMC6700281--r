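#' Fragment-sizing assay estimate of the uninterrupted CAG length
#'
#' The PCR fragment-sizing genotyping assay is calibrated against sequenced
#' canonical standards, so it reports the uninterrupted CAG length correctly
#' on canonical chromosomes but systematically mis-estimates it on
#' non-canonical ones: CAA-loss alleles are underestimated by 2 CAGs, and
#' CAACAG-duplication alleles are overestimated by 2 CAGs, or by only 1 when
#' the genotyping primer mis-primes on the duplicated interruption.
#'
#' @param true_cag integer vector of true uninterrupted CAG lengths (>= 1).
#' @param cls structure class, one of `"canonical"`, `"caa_loss"`,
#'   `"caacag_dup"` (recycled against `true_cag`). `"other"` structures have
#'   no estimation model and raise an error.
#' @param misprime logical; for duplication alleles, whether the assay primer
#'   mis-primed (+1 instead of +2). Ignored for other classes.
#' @return Integer vector of assay-estimated CAG lengths.
#' @examples
#' fragment_assay_estimate(44, "caa_loss")    # 42: underestimated by 2
#' fragment_assay_estimate(40, "caacag_dup")  # 42: overestimated by 2
#' @export
fragment_assay_estimate <- function(true_cag, cls, misprime = FALSE) {
  assay_shift(true_cag, cls, misprime, invert = FALSE)
}

#' Correct an assay-estimated CAG length to the true length
#'
#' Exact inverse of [fragment_assay_estimate()] for each structure class and
#' mis-priming state; used to recompute residual age at onset from the true
#' uninterrupted CAG length on non-canonical chromosomes.
#'
#' @param estimated integer vector of assay-estimated CAG lengths.
#' @inheritParams fragment_assay_estimate
#' @return Integer vector of true uninterrupted CAG lengths.
#' @examples
#' correct_estimated_cag(42, "caa_loss")  # 44
#' @export
correct_estimated_cag <- function(estimated, cls, misprime = FALSE) {
  assay_shift(estimated, cls, misprime, invert = TRUE)
}

assay_shift <- function(cag, cls, misprime, invert) {
  cag <- as.integer(cag)
  n <- max(length(cag), length(cls), length(misprime))
  cag <- rep_len(cag, n)
  cls <- rep_len(as.character(cls), n)
  misprime <- rep_len(as.logical(misprime), n)
  if (any(is.na(cag)) || any(cag < 1L)) stop("CAG lengths must be >= 1")
  bad <- !cls %in% c("canonical", "caa_loss", "caacag_dup")
  if (any(bad)) {
    stop("no assay model for structure class: ",
         paste(unique(cls[bad]), collapse = ", "))
  }
  shift <- integer(n)
  shift[cls == "caa_loss"] <- -2L
  shift[cls == "caacag_dup"] <- ifelse(misprime[cls == "caacag_dup"], 1L, 2L)
  if (invert) cag - shift else cag + shift
}
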