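#' Run-length model of the HTT exon-1 repeat region
#'
#' A `repeat_structure` describes the polymorphic triplet-repeat tract of
#' *HTT* exon 1 as an ordered sequence of trinucleotide runs, e.g. the most
#' common disease-chromosome arrangement
#' `CAG_42 CAA_1 CAG_1 CCG_1 CCA_1 CCG_7 CCT_2`: a pure (uninterrupted) CAG
#' run, a glutamine-encoding CAACAG interruption, and a proline-rich flank,
#' up to (but not including) the `CAGCTTCCT` 9-mer that terminates the tract.
#'
#' @param codons character vector of trinucleotides over A/C/G/T.
#' @param counts integer vector of run lengths, all >= 1.
#' @param terminator_found logical; whether the downstream `CAGCTTCCT`
#'   terminator was actually observed when this structure was read from
#'   sequence. Structures built from notation default to `TRUE`.
#' @return An object of class `repeat_structure` with elements `runs`
#'   (data.frame with columns `codon`, `count`) and `terminator_found`.
#' @examples
#' s <- repeat_structure(c("CAG", "CAA", "CAG"), c(42, 1, 1))
#' uninterrupted_cag_length(s)
#' @export
repeat_structure <- function(codons, counts, terminator_found = TRUE) {
  codons <- toupper(as.character(codons))
  counts <- as.integer(counts)
  if (length(codons) != length(counts)) {
    stop("codons and counts must have equal length")
  }
  if (length(codons) == 0L) stop("a repeat structure needs at least one run")
  if (any(nchar(codons) != 3L) || any(!grepl("^[ACGT]{3}$", codons))) {
    stop("codons must be trinucleotides over A/C/G/T")
  }
  if (any(is.na(counts)) || any(counts < 1L)) {
    stop("run counts must be positive integers")
  }
  runs <- data.frame(codon = codons, count = counts,
                     stringsAsFactors = FALSE)
  runs <- normalize_runs(runs)
  structure(list(runs = runs,
                 terminator_found = isTRUE(terminator_found)),
            class = "repeat_structure")
}

# cheap data.frame constructor for the profiling hot path
run_frame <- function(codon, count) {
  structure(list(codon = codon, count = as.integer(count)),
            class = "data.frame",
            row.names = .set_row_names(length(codon)))
}

# fast internal constructor: runs already validated and normalized
new_repeat_structure <- function(codon, count, terminator_found) {
  structure(list(runs = run_frame(codon, count),
                 terminator_found = terminator_found),
            class = "repeat_structure")
}

# Merge adjacent runs sharing a codon; classification must not depend on how
# a caller happened to split runs.
normalize_runs <- function(runs) {
  if (nrow(runs) <= 1L) return(runs)
  grp <- cumsum(c(TRUE, runs$codon[-1L] != runs$codon[-nrow(runs)]))
  data.frame(
    codon = runs$codon[!duplicated(grp)],
    count = as.integer(tapply(runs$count, grp, sum)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Parse run notation into a repeat structure
#'
#' Accepts whitespace-separated `CODON_COUNT` tokens, e.g.
#' `"CAG_42 CAA_1 CAG_1 CCG_1 CCA_1 CCG_7 CCT_2"`. `format()` of the result
#' round-trips to the normalized notation.
#'
#' @param text a single run-notation string.
#' @param terminator_found passed through to [repeat_structure()].
#' @return A `repeat_structure`.
#' @examples
#' parse_structure("CAG_44 CCG_12 CCT_2")
#' @export
parse_structure <- function(text, terminator_found = TRUE) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("text must be a single string")
  }
  tokens <- strsplit(trimws(text), "[[:space:]]+")[[1L]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) stop("empty structure notation")
  ok <- grepl("^[ACGTacgt]{3}_[0-9]+$", tokens)
  if (any(!ok)) {
    stop("malformed token(s): ", paste(tokens[!ok], collapse = ", "))
  }
  codons <- toupper(sub("_.*$", "", tokens))
  counts <- as.integer(sub("^.*_", "", tokens))
  if (any(counts == 0L)) stop("zero run count in structure notation")
  repeat_structure(codons, counts, terminator_found = terminator_found)
}

#' @export
format.repeat_structure <- function(x, ...) {
  paste(sprintf("%s_%d", x$runs$codon, x$runs$count), collapse = " ")
}

#' @export
as.character.repeat_structure <- function(x, ...) format(x)

#' @export
print.repeat_structure <- function(x, ...) {
  cat("<repeat_structure> ", format(x), "\n", sep = "")
  cat("  uninterrupted CAG: ",
      tryCatch(uninterrupted_cag_length(x), error = function(e) NA),
      "; class: ", classify_structure(x),
      "; terminator ", if (x$terminator_found) "found" else "not found",
      "\n", sep = "")
  invisible(x)
}

#' Build a repeat structure from a DNA string
#'
#' Chops `seq` into successive in-frame trinucleotides starting at its first
#' base and run-length encodes them; a trailing partial codon is an error.
#' This is the constructor for sequence already known to start at the CAG
#' tract and end at the tract boundary; to locate the tract inside a read use
#' [profile_forward()].
#'
#' @param seq a single DNA string over A/C/G/T with length a multiple of 3.
#' @param terminator_found passed through to [repeat_structure()].
#' @return A `repeat_structure`.
#' @export
structure_from_dna <- function(seq, terminator_found = TRUE) {
  seq <- toupper(seq)
  if (!grepl("^[ACGT]+$", seq)) stop("seq must be non-empty DNA over A/C/G/T")
  if (nchar(seq) %% 3L != 0L) stop("seq length must be a multiple of 3")
  starts <- seq.int(1L, nchar(seq), by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  repeat_structure(codons, rep(1L, length(codons)),
                   terminator_found = terminator_found)
}

#' DNA sequence of a repeat structure
#'
#' @param x a `repeat_structure`.
#' @param with_terminator append the `CAGCTTCCT` tract terminator.
#' @return A single DNA string.
#' @export
structure_to_dna <- function(x, with_terminator = FALSE) {
  stopifnot(inherits(x, "repeat_structure"))
  body <- paste(strrep(x$runs$codon, x$runs$count), collapse = "")
  if (with_terminator) paste0(body, "CAGCTTCCT") else body
}

#' Uninterrupted CAG repeat length
#'
#' Length of the leading pure CAG run, the quantity the fragment-sizing
#' genotyping assay estimates and the quantity that times HD onset.
#'
#' @param x a `repeat_structure` whose first run is CAG.
#' @return Integer run length.
#' @export
uninterrupted_cag_length <- function(x) {
  stopifnot(inherits(x, "repeat_structure"))
  if (x$runs$codon[1L] != "CAG") {
    stop("structure does not start with a CAG run")
  }
  x$runs$count[1L]
}

# Indices of the runs forming the glutamine-coding segment: the maximal
# contiguous block of CAG/CAA runs starting at the first run.
glutamine_segment <- function(x) {
  is_q <- x$runs$codon %in% c("CAG", "CAA")
  if (!is_q[1L]) return(integer(0))
  end <- if (any(!is_q)) which(!is_q)[1L] - 1L else nrow(x$runs)
  seq_len(end)
}

#' Encoded polyglutamine length
#'
#' Number of glutamine residues encoded by the contiguous CAG/CAA segment
#' beginning at the uninterrupted CAG run. Canonical alleles
#' (CAG_n + CAACAG) encode n + 2 glutamines, CAA-loss alleles n, and
#' CAACAG-duplication alleles n + 4.
#'
#' @param x a `repeat_structure` whose first run is CAG.
#' @return Integer residue count.
#' @export
polyglutamine_length <- function(x) {
  stopifnot(inherits(x, "repeat_structure"))
  if (x$runs$codon[1L] != "CAG") {
    stop("structure does not start with a CAG run")
  }
  sum(x$runs$count[glutamine_segment(x)])
}

#' Classify a repeat structure
#'
#' Assigns one of the mutually exclusive allele classes observed on HD
#' chromosomes:
#' \describe{
#'   \item{`canonical`}{glutamine segment CAG_n CAA_1 CAG_1 — the single
#'     CAACAG interruption carried by the vast majority of chromosomes.}
#'   \item{`caa_loss`}{no CAA after the CAG run (glutamine segment is the
#'     pure CAG run).}
#'   \item{`caacag_dup`}{glutamine segment CAG_n CAA_1 CAG_1 CAA_1 CAG_1 —
#'     a tandem duplication of the CAACAG unit.}
#'   \item{`other`}{any other arrangement (rare variants).}
#' }
#'
#' @param x a `repeat_structure`.
#' @return A single string, one of `"canonical"`, `"caa_loss"`,
#'   `"caacag_dup"`, `"other"`.
#' @export
classify_structure <- function(x) {
  stopifnot(inherits(x, "repeat_structure"))
  if (x$runs$codon[1L] != "CAG") return("other")
  seg <- glutamine_segment(x)
  codons <- x$runs$codon[seg]
  counts <- x$runs$count[seg]
  if (identical(codons, "CAG")) return("caa_loss")
  if (identical(codons, c("CAG", "CAA", "CAG")) &&
      identical(counts[2:3], c(1L, 1L))) {
    return("canonical")
  }
  if (identical(codons, c("CAG", "CAA", "CAG", "CAA", "CAG")) &&
      identical(counts[2:5], c(1L, 1L, 1L, 1L))) {
    return("caacag_dup")
  }
  "other"
}

#' Structure classes recognised by the assay model
#' @return Character vector of class labels.
#' @export
structure_classes <- function() {
  c("canonical", "caa_loss", "caacag_dup", "other")
}

#' An allele call
#'
#' Couples an uninterrupted CAG length with the supporting repeat structure,
#' its class, and the number of supporting read pairs.
#'
#' @param structure a `repeat_structure` (may be `NULL` when no
#'   terminator-complete structure was available for a called CAG peak).
#' @param cag integer uninterrupted CAG length.
#' @param support supporting read-pair count.
#' @return An object of class `allele_call`.
#' @export
allele_call <- function(structure, cag = uninterrupted_cag_length(structure),
                        support = NA_integer_) {
  if (!is.null(structure)) {
    stopifnot(inherits(structure, "repeat_structure"))
    if (uninterrupted_cag_length(structure) != cag) {
      stop("cag does not match the structure's leading CAG run")
    }
  }
  structure(list(cag = as.integer(cag),
                 structure = structure,
                 cls = if (is.null(structure)) NA_character_
                       else classify_structure(structure),
                 support = as.integer(support)),
            class = "allele_call")
}

#' @export
print.allele_call <- function(x, ...) {
  cat("<allele_call> CAG ", x$cag, " (", x$cls, "), support ", x$support,
      if (is.null(x$structure)) " [no complete structure]" else
        paste0(": ", format(x$structure)),
      "\n", sep = "")
  invisible(x)
}
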