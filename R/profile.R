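#' Profile a forward-strand read into a repeat structure
#'
#' Scanning starts at the first occurrence of the `CAGCAGCAG` 9-mer (the 5'
#' end of the uninterrupted CAG tract), which fixes the reading frame, and
#' consumes successive in-frame trinucleotides into run-length-encoded runs.
#' Scanning stops when the next nine bases equal the `CAGCTTCCT` tract
#' terminator (`terminator_found = TRUE`) or at the end of the read
#' (`terminator_found = FALSE`).
#'
#' @param seq a single read sequence (A/C/G/T/N).
#' @return A `repeat_structure`, or `NULL` when the read has no `CAGCAGCAG`
#'   anchor, when a non-ACGT base falls inside the profiled window, or when
#'   fewer than three in-frame triplets precede the read end.
#' @export
profile_forward <- function(seq) {
  seq <- toupper(seq)
  anchor <- regexpr("CAGCAGCAG", seq, fixed = TRUE)
  if (anchor == -1L) return(NULL)
  window <- substring(seq, anchor)
  n_tri <- nchar(window) %/% 3L
  if (n_tri < 3L) return(NULL)
  starts <- seq.int(1L, by = 3L, length.out = n_tri)
  tri <- substring(window, starts, starts + 2L)
  # terminator = in-frame CAG CTT CCT; stop *before* consuming it
  is_term <- tri == "CAG" &
    c(tri[-1L], "") == "CTT" &
    c(tri[-(1:2)], "", "") == "CCT"
  if (any(is_term)) {
    stop_at <- which(is_term)[1L] - 1L
    terminator_found <- TRUE
  } else {
    stop_at <- n_tri
    terminator_found <- FALSE
  }
  if (stop_at < 1L) return(NULL)
  consumed <- tri[seq_len(stop_at)]
  if (any(!grepl("^[ACGT]{3}$", consumed))) return(NULL)
  runs <- rle(consumed)
  new_repeat_structure(runs$values, runs$lengths, terminator_found)
}

#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, NULL), function(ch) paste(rev(ch), collapse = ""),
         "", USE.NAMES = FALSE)
}

#' Profile a read pair
#'
#' The antisense mate is reverse-complemented and profiled like the forward
#' read; the pair is retained only when both mates yield identical run
#' lists, otherwise it is discarded (the normal fate of pairs carrying a
#' sequencing error inside the tract).
#'
#' @param fwd forward-strand read sequence.
#' @param rev mate sequence in antisense orientation.
#' @return A `repeat_structure` (with `terminator_found` true only when both
#'   mates saw the terminator), or `NULL` when the pair is discarded.
#' @export
profile_pair <- function(fwd, rev) {
  profile_pair_rc(fwd, reverse_complement(rev))
}

# mate already reverse-complemented (lets callers batch the complement)
profile_pair_rc <- function(fwd, rev_rc) {
  pf <- profile_forward(fwd)
  if (is.null(pf)) return(NULL)
  pr <- profile_forward(rev_rc)
  if (is.null(pr)) return(NULL)
  if (!identical(pf$runs, pr$runs)) return(NULL)
  pf$terminator_found <- pf$terminator_found && pr$terminator_found
  pf
}

# A profile's CAG length is usable only if the leading CAG run demonstrably
# ended inside the read: either a later run follows it or the terminator was
# seen. A lone CAG run without terminator is only a lower bound.
cag_complete <- function(structure) {
  nrow(structure$runs) > 1L || structure$terminator_found
}

#' Aggregate profiled read pairs into a structure histogram
#'
#' @param fwd character vector of forward-strand reads.
#' @param rev character vector of antisense mates (same length).
#' @return A `profile_histogram`: data.frame with one row per distinct
#'   retained structure (`structure` serialized run notation, `cag`,
#'   `cag_complete`, `terminator_found`, `count`), sorted by decreasing
#'   count, with attributes `n_pairs` (input pairs) and `n_discarded`.
#' @export
aggregate_profiles <- function(fwd, rev) {
  stopifnot(length(fwd) == length(rev))
  keys <- character(0); cags <- integer(0)
  compl <- logical(0); term <- logical(0)
  counts <- integer(0)
  discarded <- 0L
  rev_rc <- if (length(rev)) reverse_complement(rev) else character(0)
  # profile each distinct pair once; error-free data collapses heavily
  pair_key <- paste(fwd, rev_rc, sep = "\r")
  uniq <- !duplicated(pair_key)
  mult <- as.integer(table(factor(pair_key, levels = pair_key[uniq])))
  for (i in seq_along(which(uniq))) {
    u <- which(uniq)[i]
    m <- mult[i]
    p <- profile_pair_rc(fwd[u], rev_rc[u])
    if (is.null(p)) { discarded <- discarded + m; next }
    key <- paste0(format(p), if (p$terminator_found) " +" else " -")
    j <- match(key, keys)
    if (is.na(j)) {
      keys <- c(keys, key)
      cags <- c(cags, if (p$runs$codon[1L] == "CAG") p$runs$count[1L]
                      else NA_integer_)
      compl <- c(compl, cag_complete(p))
      term <- c(term, p$terminator_found)
      counts <- c(counts, m)
    } else {
      counts[j] <- counts[j] + m
    }
  }
  hist <- data.frame(
    structure = sub(" [+-]$", "", keys),
    cag = cags,
    cag_complete = compl,
    terminator_found = term,
    count = counts,
    stringsAsFactors = FALSE
  )
  hist <- hist[order(-hist$count, hist$structure), , drop = FALSE]
  row.names(hist) <- NULL
  attr(hist, "n_pairs") <- length(fwd)
  attr(hist, "n_discarded") <- discarded
  class(hist) <- c("profile_histogram", "data.frame")
  hist
}

#' @export
print.profile_histogram <- function(x, ...) {
  cat("<profile_histogram> ", attr(x, "n_pairs"), " pairs, ",
      attr(x, "n_discarded"), " discarded\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' Call a two-allele repeat genotype from a profile histogram
#'
#' Projects the histogram onto uninterrupted CAG length using only profiles
#' whose CAG run is complete, picks the two most frequent CAG lengths (one
#' for a homozygote), and attaches to each the highest-count
#' terminator-complete structure carrying that length. Equally frequent CAG
#' peaks are broken deterministically in favour of the longer CAG and the
#' genotype is flagged with `tie = TRUE`.
#'
#' @param hist a `profile_histogram` from [aggregate_profiles()].
#' @param min_support minimum supporting pair count for a CAG peak.
#' @return An object of class `genotype`: list with `alleles` (list of one
#'   or two [allele_call()]s, shorter CAG first), `tie`, and `incomplete`
#'   (`TRUE` when a called peak had no terminator-complete structure).
#' @export
call_genotype_miseq <- function(hist, min_support = 1L) {
  stopifnot(inherits(hist, "profile_histogram"))
  usable <- hist[hist$cag_complete & !is.na(hist$cag), , drop = FALSE]
  if (nrow(usable) == 0L) stop("no CAG-complete profiles in histogram")
  peak <- tapply(usable$count, usable$cag, sum)
  peak_cag <- as.integer(names(peak))
  peak_n <- as.integer(peak)
  keep <- peak_n >= min_support
  peak_cag <- peak_cag[keep]; peak_n <- peak_n[keep]
  if (length(peak_cag) == 0L) stop("no CAG peak reaches min_support")
  ord <- order(-peak_n, -peak_cag)  # ties: longer CAG first
  top <- ord[seq_len(min(2L, length(ord)))]
  tie <- length(ord) > 2L && peak_n[ord[2L]] == peak_n[ord[3L]]
  if (length(top) == 2L && peak_n[top[1L]] == peak_n[top[2L]]) tie <- TRUE

  make_call <- function(cag, support) {
    cand <- hist[!is.na(hist$cag) & hist$cag == cag & hist$terminator_found, ,
                 drop = FALSE]
    if (nrow(cand) == 0L) {
      return(allele_call(NULL, cag = cag, support = support))
    }
    best <- cand[order(-cand$count, cand$structure)[1L], ]
    s <- parse_structure(best$structure)
    allele_call(s, cag = cag, support = support)
  }
  alleles <- lapply(top, function(i) make_call(peak_cag[i], peak_n[i]))
  alleles <- alleles[order(vapply(alleles, `[[`, 0L, "cag"))]
  structure(list(
    alleles = alleles,
    tie = tie,
    incomplete = any(vapply(alleles, function(a) is.null(a$structure), TRUE))
  ), class = "genotype")
}

#' @export
print.genotype <- function(x, ...) {
  cat("<genotype>", if (length(x$alleles) == 1L) " homozygous" else "",
      if (x$tie) " [tie]" else "",
      if (x$incomplete) " [incomplete]" else "", "\n", sep = "")
  for (a in x$alleles) print(a)
  invisible(x)
}

#' Genotype repeat structures from whole-genome-sequencing reads
#'
#' Each read is searched (relative to the forward strand) for the
#' `CAGCTTCCT` tract terminator, then read 3' to 5' in the frame fixed by
#' the terminator until three consecutive CAG triplets are found. A
#' recovered sequence is complete when it carries `CAGCAGCAG` at its 5' end
#' and the terminator 9-mer at its 3' end; complete sequences are aggregated
#' and those representing 14% or less of the aggregated complete reads are
#' filtered out. One surviving sequence means a homozygote, two a
#' heterozygote.
#'
#' @param reads character vector of read sequences (forward-strand
#'   orientation).
#' @param completeness_filter share at or below which an aggregated sequence
#'   is dropped (default 0.14).
#' @return A list with `status` (`"homozygote"`, `"heterozygote"`,
#'   `"no_call"`, or `"ambiguous"`), `structures` (list of
#'   `repeat_structure` for the surviving sequences, most frequent first),
#'   `counts` (named supporting-read counts for all complete sequences), and
#'   `n_complete`.
#' @export
profile_reverse_wgs <- function(reads, completeness_filter = 0.14) {
  recovered <- character(0)
  for (seq in toupper(reads)) {
    t_pos <- regexpr("CAGCTTCCT", seq, fixed = TRUE)
    if (t_pos == -1L) next
    # walk 3'->5' in the terminator's frame looking for CAGCAGCAG
    p <- t_pos - 3L
    found <- NA_integer_
    while (p >= 1L) {
      if (substring(seq, p, p + 8L) == "CAGCAGCAG") { found <- p; break }
      p <- p - 3L
    }
    if (is.na(found)) next
    s <- substring(seq, found, t_pos + 8L)
    if (!grepl("^[ACGT]+$", s)) next
    recovered <- c(recovered, s)
  }
  if (length(recovered) == 0L) {
    return(list(status = "no_call", structures = list(),
                counts = integer(0), n_complete = 0L))
  }
  counts <- sort(table(recovered), decreasing = TRUE)
  counts <- stats::setNames(as.integer(counts), names(counts))
  total <- sum(counts)
  surviving <- counts[counts / total > completeness_filter]
  status <- switch(as.character(min(length(surviving), 3L)),
                   "0" = "no_call",
                   "1" = "homozygote",
                   "2" = "heterozygote",
                   "3" = "ambiguous")
  structures <- lapply(names(surviving), function(s) {
    # strip the terminator before run-length encoding
    profile_forward(s)
  })
  list(status = status, structures = structures,
       counts = counts, n_complete = total)
}

#' Profile paired FASTQ files and call a genotype
#'
#' Convenience wrapper: reads two FASTQ files (mate order must match),
#' aggregates profiles, and calls the MiSeq-style genotype.
#'
#' @param fastq1,fastq2 paths to the forward and antisense FASTQ files.
#' @param min_support passed to [call_genotype_miseq()].
#' @return A list with `genotype` and `histogram`.
#' @export
profile_fastq_sample <- function(fastq1, fastq2, min_support = 1L) {
  fwd <- as.character(Biostrings::readDNAStringSet(fastq1, format = "fastq"))
  rev <- as.character(Biostrings::readDNAStringSet(fastq2, format = "fastq"))
  if (length(fwd) != length(rev)) stop("FASTQ mate counts differ")
  hist <- aggregate_profiles(unname(fwd), unname(rev))
  list(genotype = call_genotype_miseq(hist, min_support = min_support),
       histogram = hist)
}

#' Write a genotype table for profiled samples
#'
#' @param genotypes named list of `genotype` objects (names are sample ids).
#' @param path output TSV path.
#' @return The written data.frame, invisibly.
#' @export
write_genotype_table <- function(genotypes, path) {
  rows <- lapply(names(genotypes), function(id) {
    g <- genotypes[[id]]
    a <- g$alleles
    a2 <- if (length(a) >= 2L) a[[2L]] else a[[1L]]
    data.frame(
      sample = id,
      allele1_cag = a[[1L]]$cag, allele1_class = a[[1L]]$cls,
      allele1_structure = if (is.null(a[[1L]]$structure)) NA_character_
                          else format(a[[1L]]$structure),
      allele1_support = a[[1L]]$support,
      allele2_cag = a2$cag, allele2_class = a2$cls,
      allele2_structure = if (is.null(a2$structure)) NA_character_
                          else format(a2$structure),
      allele2_support = a2$support,
      tie = g$tie, incomplete = g$incomplete,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
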