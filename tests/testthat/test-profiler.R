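test_that("forward profiling traces the scan rule on a constructed read", {
  read <- paste0("TT", strrep("CAG", 10), "CAACAG", "CCG", "CCA",
                 strrep("CCG", 7), strrep("CCT", 2),
                 "CAGCTTCCT", "CCGCCACCG")
  s <- profile_forward(read)
  expect_equal(format(s), "CAG_10 CAA_1 CAG_1 CCG_1 CCA_1 CCG_7 CCT_2")
  expect_true(s$terminator_found)
})

test_that("forward profiling handles missing anchor, truncation, and Ns", {
  expect_null(profile_forward("TTTTCCGCCGCCGCCG"))
  # read ends inside the CAG run: lone CAG run, terminator not found
  s <- profile_forward(paste0("AA", strrep("CAG", 8)))
  expect_equal(format(s), "CAG_8")
  expect_false(s$terminator_found)
  # N inside the profiled window rejects the profile
  expect_null(profile_forward(paste0(strrep("CAG", 5), "CNG", "CCGCCG")))
  # but an N before the anchor is harmless
  s2 <- profile_forward(paste0("NNT", strrep("CAG", 5), "CAGCTTCCT"))
  expect_equal(format(s2), "CAG_5")
  expect_true(s2$terminator_found)
})

test_that("profiling starts at the leftmost anchor in its frame", {
  # CCAGCAGCAGCAG...: leftmost CAGCAGCAG starts at position 2
  read <- paste0("C", strrep("CAG", 6), "CAACAGCAGCTTCCT")
  s <- profile_forward(read)
  expect_equal(s$runs$codon[1L], "CAG")
  expect_equal(s$runs$count[1L], 6L)
})

test_that("pair profiling keeps matched mates and discards errors", {
  s <- canonical42()
  pair <- perfect_pair(s)
  got <- profile_pair(pair$fwd, pair$rev)
  expect_identical(format(got), format(s))

  # substitution inside the tract on one mate -> run lists differ -> discard
  bad_rev <- pair$rev
  substr(bad_rev, 150, 150) <- if (substr(bad_rev, 150, 150) == "A") "C" else "A"
  expect_null(profile_pair(pair$fwd, bad_rev))
})

test_that("profiling is invariant to which mate is sense", {
  s <- hd_structure(30L, "caacag_dup")
  pair <- perfect_pair(s)
  # swap roles: the antisense of the mate is a sense read and vice versa
  swapped <- profile_pair(reverse_complement(pair$rev),
                          reverse_complement(pair$fwd))
  expect_identical(format(swapped), format(s))
})

test_that("aggregation counts structures and discards separately", {
  a <- hd_structure(42L, "canonical")
  b <- hd_structure(17L, "canonical")
  pa <- perfect_pair(a); pb <- perfect_pair(b)
  fwd <- c(rep(pa$fwd, 60), rep(pb$fwd, 40), "TTTTTTTTTTTT")
  rev <- c(rep(pa$rev, 60), rep(pb$rev, 40), "ACACACACACAC")
  hist <- aggregate_profiles(fwd, rev)
  expect_equal(nrow(hist), 2L)
  expect_equal(hist$count, c(60L, 40L))
  expect_equal(attr(hist, "n_discarded"), 1L)
  expect_equal(attr(hist, "n_pairs"), 101L)

  empty <- aggregate_profiles(character(0), character(0))
  expect_equal(nrow(empty), 0L)
})

test_that("genotype calling picks the two most frequent complete CAG peaks", {
  a <- hd_structure(42L, "canonical")
  b <- hd_structure(17L, "canonical")
  pa <- perfect_pair(a); pb <- perfect_pair(b)
  hist <- aggregate_profiles(c(rep(pa$fwd, 80), rep(pb$fwd, 90)),
                             c(rep(pa$rev, 80), rep(pb$rev, 90)))
  g <- call_genotype_miseq(hist)
  expect_equal(vapply(g$alleles, `[[`, 0L, "cag"), c(17L, 42L))
  expect_equal(vapply(g$alleles, `[[`, "", "cls"),
               c("canonical", "canonical"))
  expect_false(g$tie)
  expect_false(g$incomplete)

  # single structure -> homozygous call
  hom <- call_genotype_miseq(aggregate_profiles(rep(pa$fwd, 50),
                                                rep(pa$rev, 50)))
  expect_length(hom$alleles, 1L)
  expect_equal(hom$alleles[[1L]]$cag, 42L)

  # tied peaks -> deterministic, flagged
  tied <- call_genotype_miseq(aggregate_profiles(
    c(rep(pa$fwd, 50), rep(pb$fwd, 50)),
    c(rep(pa$rev, 50), rep(pb$rev, 50))))
  expect_true(tied$tie)
  expect_equal(vapply(tied$alleles, `[[`, 0L, "cag"), c(17L, 42L))
})

test_that("truncated lone-CAG profiles do not form genotype peaks", {
  a <- hd_structure(42L, "canonical")
  pa <- perfect_pair(a)
  # reads that end inside the CAG run: lower bounds only
  trunc_fwd <- paste0("TT", strrep("CAG", 20))
  trunc_rev <- reverse_complement(trunc_fwd)
  hist <- aggregate_profiles(c(rep(pa$fwd, 10), rep(trunc_fwd, 90)),
                             c(rep(pa$rev, 10), rep(trunc_rev, 90)))
  g <- call_genotype_miseq(hist)
  expect_length(g$alleles, 1L)
  expect_equal(g$alleles[[1L]]$cag, 42L)
})

test_that("forward profiling recovers every library structure exactly", {
  for (s in structure_library()) {
    pair <- perfect_pair(s)
    got <- profile_pair(pair$fwd, pair$rev)
    expect_identical(format(got), format(s))
    expect_true(got$terminator_found)
  }
})

test_that("WGS reverse profiling aggregates and applies the 14% filter", {
  # adjacent-sequence fragments: canonical vs dup (CAG run collapses to the
  # anchor 3 CAGs closest to the first interruption)
  region <- function(cls) {
    paste0("GTTC", structure_to_dna(hd_structure(12L, cls),
                                    with_terminator = TRUE), "CCGCCA")
  }
  reads <- c(rep(region("canonical"), 80), rep(region("caacag_dup"), 70),
             rep(region("caa_loss"), 10))
  res <- profile_reverse_wgs(reads)
  # caa_loss share 10/160 = 6.25% <= 14% -> filtered; heterozygote remains
  expect_equal(res$status, "heterozygote")
  expect_equal(res$n_complete, 160L)
  expect_length(res$structures, 2L)

  # boundary: share exactly 14% is removed ("14% or less")
  reads2 <- c(rep(region("canonical"), 86), rep(region("caa_loss"), 14))
  res2 <- profile_reverse_wgs(reads2)
  expect_equal(res2$status, "homozygote")

  # single sequence -> homozygote; none -> no call; >2 -> ambiguous
  expect_equal(profile_reverse_wgs(rep(region("canonical"), 5))$status,
               "homozygote")
  expect_equal(profile_reverse_wgs("TTTTTT")$status, "no_call")
  res3 <- profile_reverse_wgs(c(rep(region("canonical"), 50),
                                rep(region("caa_loss"), 49),
                                rep(region("caacag_dup"), 48)))
  expect_equal(res3$status, "ambiguous")
})

test_that("WGS path needs both anchors within the read", {
  # terminator but no 3 consecutive CAGs upstream
  expect_equal(profile_reverse_wgs("CCGCCGCCGCAGCTTCCT")$status, "no_call")
  # in-frame anchor reachable walking back from the terminator
  # the walk stops at the first in-frame CAGCAGCAG nearest the terminator,
  # so the recovered fragment carries a 3-CAG head regardless of run length
  read <- paste0(strrep("CAG", 4), "CCGCCACAGCTTCCT")
  res <- profile_reverse_wgs(read)
  expect_equal(res$status, "homozygote")
  expect_equal(format(res$structures[[1L]]), "CAG_3 CCG_1 CCA_1")
})

test_that("FASTQ round trip profiles back to the generating genotype", {
  cfg <- sim_config(seed = 7, coverage = 30L, base_error = 0)
  alleles <- list(hd_structure(44L, "caa_loss"),
                  hd_structure(18L, "canonical"))
  reads <- simulate_reads(alleles, cfg)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq_pair(reads, f1, f2, sample = "S1")
  res <- profile_fastq_sample(f1, f2)
  cags <- vapply(res$genotype$alleles, `[[`, 0L, "cag")
  expect_equal(cags, c(18L, 44L))
  expect_equal(vapply(res$genotype$alleles, `[[`, "", "cls"),
               c("canonical", "caa_loss"))
  tab <- write_genotype_table(list(S1 = res$genotype), tempfile())
  expect_equal(tab$allele1_cag, 18L)
  expect_equal(tab$allele2_cag, 44L)
  unlink(c(f1, f2))
})
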