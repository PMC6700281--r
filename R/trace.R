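#' Read a fragment-analysis peak table
#'
#' Expects a tab-separated export with columns `sample`, `plate`,
#' `called_cag` (the main expanded CAG allele assigned to the sample),
#' `size_bp`, `height_rfu`, `area`, `scan`.
#'
#' @param path TSV path.
#' @return data.frame of peak records.
#' @export
read_peak_table <- function(path) {
  peaks <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample", "plate", "called_cag", "size_bp", "height_rfu")
  missing <- setdiff(required, names(peaks))
  if (length(missing)) {
    stop("peak table lacks column(s): ", paste(missing, collapse = ", "))
  }
  peaks
}

#' Filter fragment-analysis peaks
#'
#' Applies the bulk-assay quality filters: an upper fragment-size threshold
#' and a minimum peak height. Boundaries: a peak of exactly `max_size` bp is
#' kept, a peak of exactly `min_height` RFU is kept.
#'
#' @param peaks peak-record data.frame (see [read_peak_table()]).
#' @param max_size upper size threshold in bp (default 500).
#' @param min_height minimum peak height in RFU (default 50).
#' @return Filtered data.frame.
#' @export
filter_peaks <- function(peaks, max_size = 500, min_height = 50) {
  peaks[peaks$size_bp <= max_size & peaks$height_rfu >= min_height, ,
        drop = FALSE]
}

# Main peak of each sample: the record with the largest height (the called
# allele is by convention the highest peak in the expanded range).
main_peaks <- function(peaks) {
  idx <- unlist(lapply(split(seq_len(nrow(peaks)), peaks$sample),
                       function(i) i[which.max(peaks$height_rfu[i])]),
                use.names = FALSE)
  peaks[idx, , drop = FALSE]
}

#' Fit a per-plate fragment-size to CAG calibration
#'
#' Ordinary least squares of the called main CAG allele on the main peak's
#' measured fragment size, `cag = b0 + b1 * size`, fit per plate across the
#' samples run on it; the fitted line then assigns CAG lengths to all peaks
#' on that plate.
#'
#' @param peaks peak records of one plate (all peaks; the main peak of each
#'   sample is selected internally as its highest peak).
#' @return An object of class `plate_calibration`: list with `intercept`,
#'   `slope` (CAG per bp), `n`, `sigma` (residual SD), `plate`.
#' @export
fit_plate_calibration <- function(peaks) {
  mp <- main_peaks(peaks)
  if (length(unique(mp$size_bp)) < 2L) {
    stop("plate calibration needs >= 2 distinct main-peak sizes")
  }
  fit <- stats::lm(called_cag ~ size_bp, data = mp)
  cal <- list(
    intercept = unname(stats::coef(fit)[1L]),
    slope = unname(stats::coef(fit)[2L]),
    n = nrow(mp),
    sigma = sqrt(sum(stats::resid(fit)^2) / max(1L, fit$df.residual)),
    plate = if (length(unique(mp$plate)) == 1L) mp$plate[1L] else NA
  )
  if (!is.finite(cal$slope) || cal$slope <= 0) {
    stop("invalid plate calibration: non-positive slope")
  }
  class(cal) <- "plate_calibration"
  cal
}

#' @export
print.plate_calibration <- function(x, ...) {
  cat(sprintf(
    "<plate_calibration> plate %s: cag = %.4f + %.4f * size_bp (n = %d, sigma = %.3g)\n",
    as.character(x$plate), x$intercept, x$slope, x$n, x$sigma))
  invisible(x)
}

# Round half away from zero (round() rounds half to even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Assign CAG lengths to peaks from a plate calibration
#'
#' Transforms each peak's fragment size to an integer CAG length via the
#' fitted line (nearest integer, half away from zero). Within a sample,
#' peaks whose sizes transform to the same CAG length collide; only the
#' record with the larger peak height is kept.
#'
#' @param peaks peak records (one plate).
#' @param cal a `plate_calibration` for that plate.
#' @param resolve_collisions drop same-sample records mapping to a CAG
#'   length already held by a taller peak (default `TRUE`).
#' @return `peaks` with an added integer column `assigned_cag`.
#' @export
assign_peak_cag <- function(peaks, cal, resolve_collisions = TRUE) {
  stopifnot(inherits(cal, "plate_calibration"))
  peaks$assigned_cag <- as.integer(
    round_half_away(cal$intercept + cal$slope * peaks$size_bp))
  if (resolve_collisions && nrow(peaks) > 1L) {
    ord <- order(peaks$sample, peaks$assigned_cag, -peaks$height_rfu)
    peaks <- peaks[ord, , drop = FALSE]
    dup <- duplicated(peaks[, c("sample", "assigned_cag")])
    peaks <- peaks[!dup, , drop = FALSE]
    row.names(peaks) <- NULL
  }
  peaks
}

#' Peak proportional sum: a bulk somatic-expansion index
#'
#' For each sample, peaks assigned a CAG length strictly greater than the
#' sample's main CAG allele are taken as somatically expanded products; each
#' expanded peak's height is divided by the main peak's height and the
#' proportions are summed. Peaks at or to the left of the main allele
#' (PCR stutter) contribute nothing.
#'
#' @param peaks peak records of one sample with `assigned_cag` set
#'   (see [assign_peak_cag()]).
#' @return A list with `sample`, `main_cag`, `pps` (the peak proportional
#'   sum), and `n_expansion_peaks`; or `NULL` (with a warning) when the main
#'   peak is absent after filtering.
#' @export
peak_proportional_sum <- function(peaks) {
  main_cag <- unique(peaks$called_cag)
  if (length(main_cag) != 1L) stop("peaks must belong to a single sample")
  main <- peaks[peaks$assigned_cag == main_cag, , drop = FALSE]
  if (nrow(main) == 0L || max(main$height_rfu) <= 0) {
    warning("sample ", peaks$sample[1L],
            ": main peak missing after filtering; skipped")
    return(NULL)
  }
  main_height <- max(main$height_rfu)
  exp_peaks <- peaks[peaks$assigned_cag > main_cag, , drop = FALSE]
  list(sample = peaks$sample[1L],
       main_cag = as.integer(main_cag),
       pps = sum(exp_peaks$height_rfu) / main_height,
       n_expansion_peaks = nrow(exp_peaks))
}

#' Somatic-expansion indices for a whole peak table
#'
#' Runs the full trace pipeline: size/height filtering, per-plate
#' calibration, CAG assignment with collision resolution, and the peak
#' proportional sum per sample.
#'
#' @param peaks full peak-record data.frame (any number of plates).
#' @param max_size,min_height filters, see [filter_peaks()].
#' @return data.frame with columns `sample`, `main_cag`, `pps`,
#'   `n_expansion_peaks`, one row per scorable sample.
#' @export
expansion_index <- function(peaks, max_size = 500, min_height = 50) {
  peaks <- filter_peaks(peaks, max_size = max_size, min_height = min_height)
  out <- list()
  for (plate in unique(peaks$plate)) {
    pp <- peaks[peaks$plate == plate, , drop = FALSE]
    cal <- fit_plate_calibration(pp)
    pp <- assign_peak_cag(pp, cal)
    for (s in unique(pp$sample)) {
      res <- peak_proportional_sum(pp[pp$sample == s, , drop = FALSE])
      if (!is.null(res)) out[[length(out) + 1L]] <- res
    }
  }
  do.call(rbind, lapply(out, as.data.frame))
}

#' Rank samples and mark the top somatic-expansion quartile
#'
#' Samples are rank-sorted in descending order of peak proportional sum and
#' divided into quartiles: the top quartile holds `floor(n / 4)` samples and
#' the remainder is distributed to the lower quartiles (every quartile size
#' is within 1 of n/4). Ties across a boundary are broken by sample id.
#'
#' @param idx data.frame from [expansion_index()] (needs `sample`, `pps`).
#' @return `idx` with added `quartile` (1 = highest expansion) sorted in
#'   ranking order.
#' @export
rank_top_quartile <- function(idx) {
  n <- nrow(idx)
  if (n < 4L) stop("quartile ranking needs at least 4 samples")
  idx <- idx[order(-idx$pps, idx$sample), , drop = FALSE]
  base <- n %/% 4L
  sizes <- rep(base, 4L)
  extra <- n - 4L * base
  if (extra > 0L) sizes[(4L - extra + 1L):4L] <- base + 1L
  idx$quartile <- rep(1:4, times = sizes)
  row.names(idx) <- NULL
  idx
}

#' Write per-sample expansion indices with quartile labels
#'
#' @param idx data.frame from [rank_top_quartile()].
#' @param path output TSV path.
#' @export
write_expansion_table <- function(idx, path) {
  utils::write.table(idx, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(idx)
}
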