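test_that("HWE expected counts follow n(1-q)^2, 2nq(1-q), nq^2", {
  e <- hwe_expected_counts(1753, 0.257)
  expect_equal(unname(e), c(967.74, 669.47, 115.78), tolerance = 1e-4)
  expect_equal(unname(round(e)), c(968, 669, 116))
  expect_equal(sum(e), 1753)
  # limit maf -> 0: everyone major homozygote
  e0 <- hwe_expected_counts(100, 1e-9)
  expect_equal(unname(e0), c(100, 0, 0), tolerance = 1e-6)
  # always sums to n
  for (q in c(0.01, 0.257, 0.5, 0.9)) {
    expect_equal(sum(hwe_expected_counts(537, q)), 537)
  }
})

test_that("HWE chi-square equals a hand-summed oracle", {
  # textbook hand computation: observed (10, 20, 10) vs HWE at q = 0.5,
  # n = 40 -> expected (10, 20, 10) -> statistic 0
  expect_equal(hwe_chisq(c(10, 20, 10),
                         hwe_expected_counts(40, 0.5))$statistic, 0)
  # hand-summed: observed (30, 8, 2) vs expected (25.6, 12.8, 1.6) at
  # q = 0.2, n = 40: 4.4^2/25.6 + 4.8^2/12.8 + 0.4^2/1.6
  got <- hwe_chisq(c(30, 8, 2), hwe_expected_counts(40, 0.2))
  expect_equal(got$statistic, 4.4^2 / 25.6 + 4.8^2 / 12.8 + 0.4^2 / 1.6)
  expect_equal(got$df, 2L)
  expect_error(hwe_chisq(c(1, 2, 3), c(1, 0, 3)), "positive")

  # property: equality with an independently coded oracle on random tables
  oracle <- function(obs, exp) {
    obs <- unname(obs); exp <- unname(exp)
    s <- 0
    for (i in 1:3) s <- s + (obs[i] - exp[i])^2 / exp[i]
    s
  }
  set.seed(99)
  for (rep in 1:1000) {
    n <- sample(50:500, 1)
    q <- stats::runif(1, 0.05, 0.5)
    obs <- as.vector(stats::rmultinom(1, n, c((1 - q)^2, 2 * q * (1 - q), q^2)))
    exp <- hwe_expected_counts(n, q)
    expect_equal(hwe_chisq(obs, exp)$statistic, oracle(obs, exp))
  }
})

test_that("marginal association reduces to the textbook simple slope", {
  set.seed(5)
  dosage <- stats::rbinom(200, 2, 0.3)
  y <- 1.5 * dosage + stats::rnorm(200)
  got <- marginal_association(dosage, y)
  expect_equal(got$beta, stats::cov(dosage, y) / stats::var(dosage),
               tolerance = 1e-10)
  expect_equal(got$n, 200L)
  expect_error(marginal_association(rep(1, 50), stats::rnorm(50)),
               "zero variance")
})

test_that("injected modifier effects are recovered with covariates", {
  set.seed(6)
  n <- 3000
  dosage <- stats::rbinom(n, 2, 0.1)
  sex <- stats::rbinom(n, 1, 0.5)
  y <- -4.4 * dosage + 0.5 * sex + stats::rnorm(n, 0, 8)
  got <- marginal_association(dosage, y, covariates = data.frame(sex))
  expect_equal(got$beta, -4.4, tolerance = 0.5)
  expect_lt(got$p, 1e-10)
})

test_that("conditional association removes LD-borne signal", {
  set.seed(7)
  n <- 2000
  causal <- stats::rbinom(n, 2, 0.3)
  # tightly linked proxy: copy with a little recombination noise
  flip <- stats::runif(n) < 0.05
  proxy <- ifelse(flip, stats::rbinom(n, 2, 0.3), causal)
  y <- -3 * causal + stats::rnorm(n, 0, 6)
  marg <- marginal_association(proxy, y)
  expect_lt(marg$p, 1e-6)
  cond <- conditional_association(proxy, y, conditioning = causal)
  expect_gt(cond$p, 0.05)

  # conditioning on an independent SNP leaves beta within 2 SE of marginal
  indep <- stats::rbinom(n, 2, 0.4)
  cond2 <- conditional_association(proxy, y, conditioning = indep)
  expect_lt(abs(cond2$beta - marg$beta), 2 * marg$se)

  # empty conditioning set is exactly marginal
  expect_equal(conditional_association(proxy, y, conditioning = NULL),
               marg)
  # perfect collinearity is diagnosed
  expect_error(conditional_association(proxy, y, conditioning = proxy),
               "collinear")
})

test_that("type-I error is nominal under the null", {
  set.seed(8)
  rejections <- 0L
  for (rep in 1:400) {
    dosage <- stats::rbinom(150, 2, 0.3)
    if (stats::var(dosage) == 0) next
    y <- stats::rnorm(150, 0, 8)
    if (marginal_association(dosage, y)$p < 0.05) {
      rejections <- rejections + 1L
    }
  }
  expect_lt(abs(rejections / 400 - 0.05), 0.02)
})

test_that("tag rules classify the documented examples", {
  rules <- hd_tag_rules()
  expect_equal(vapply(rules, `[[`, "", "label")[1:3],
               c("5AM1", "5AM2", "5AM3"))
  stats <- data.frame(
    snp = c("a", "b", "c", "d", "e"),
    maf = c(0.25, 0.02, 0.25, 0.25, 0.02),
    effect = c(-1.2, 0.9, -1.2, 0.8, 0.9),
    p_marginal = c(1e-6, 5e-4, 1e-5, 5e-4, 5e-4),
    cond_rs701383 = c(0.01, 5e-4, 0.01, 5e-3, NA),
    stringsAsFactors = FALSE
  )
  expect_warning(out <- classify_tag_snps(stats, rules), "skipped")
  # hastening, marginal 1e-6, conditional 0.01 -> 5AM1
  expect_equal(out$tag[1L], "5AM1")
  # delaying, both p 5e-4 < 1e-3, maf 2% < 5% -> 5AM2
  expect_equal(out$tag[2L], "5AM2")
  # boundary: marginal exactly 1e-5 fails the strict 5AM1 cut
  expect_true(is.na(out$tag[3L]))
  # delaying, maf in [0.20, 0.35], marginal < 1e-3, conditional > 1e-3 -> 5AM3
  expect_equal(out$tag[4L], "5AM3")
  # missing required conditional p -> skipped
  expect_true(is.na(out$tag[5L]))
})

test_that("chr15 and chr19 rule sets honour their thresholds in order", {
  stats <- data.frame(
    snp = c("f15am1", "f15am2", "f15am3", "f15am4", "l19am1", "l19am2",
            "l19am3"),
    maf = c(0.02, 0.30, 0.01, 0.40, 0.10, 0.40, 0.01),
    effect = c(-2, 1, -3, 1, 1, -0.5, 2),
    p_marginal = c(1e-9, 1e-9, 1e-7, 1e-6, 1e-5, 1e-6, 1e-3),
    # all far below the chr5 conditional cuts so no chr5 rule fires first
    cond_rs701383 = rep(1e-9, 7),
    cond_rs150393409 = c(1e-3, 1e-10, 1e-7, 1e-9, NA, 0.5, NA),
    cond_rs35811129 = c(1e-9, 1e-3, 1e-7, NA, NA, NA, NA),
    cond_rs274883 = c(NA, NA, NA, NA, 0.5, NA, 0.5),
    cond_rs3730945 = c(NA, NA, NA, NA, NA, 0.1, NA),
    cond_rs145821638 = c(NA, NA, NA, NA, NA, NA, 0.8),
    stringsAsFactors = FALSE
  )
  out <- suppressWarnings(classify_tag_snps(stats))
  expect_equal(out$tag,
               c("15AM1", "15AM2", "15AM3", "15AM4", "19AM1", "19AM2",
                 "19AM3"))
})

test_that("the rule engine is order-stable and total", {
  rules <- hd_tag_rules()
  set.seed(10)
  conds <- unique(unlist(lapply(rules, function(r) {
    vapply(r$conditional, `[[`, "", "snp")
  })))
  n <- 300
  stats <- data.frame(snp = sprintf("s%03d", 1:n),
                      maf = stats::runif(n, 0.001, 0.5),
                      effect = stats::rnorm(n),
                      p_marginal = 10^stats::runif(n, -10, 0))
  for (cc in conds) stats[[paste0("cond_", cc)]] <- 10^stats::runif(n, -10, 0)
  out1 <- classify_tag_snps(stats, rules)
  out2 <- classify_tag_snps(stats, rules)
  expect_identical(out1$tag, out2$tag)       # deterministic
  expect_length(out1$tag, n)                 # total: one label or NA each
  # a label, when assigned, is the first matching rule
  labels <- vapply(rules, `[[`, "", "label")
  for (i in seq_len(n)) {
    matches <- vapply(rules, function(r) {
      isTRUE(cagtract:::rule_matches(r, out1[i, , drop = FALSE]))
    }, TRUE)
    expected <- if (any(matches)) labels[which(matches)[1L]] else NA_character_
    expect_identical(out1$tag[i], expected)
  }
})

test_that("top-quartile HWE report reproduces composed arithmetic", {
  set.seed(12)
  n <- 400
  idx <- data.frame(sample = sprintf("S%04d", 1:n),
                    main_cag = sample(40:55, n, replace = TRUE),
                    pps = stats::runif(n))
  g <- stats::setNames(stats::rbinom(n, 2, 0.257), idx$sample)
  rep_pooled <- top_quartile_hwe_report(idx, g, maf = 0.257)
  expect_equal(rep_pooled$n_top, 100L)
  expect_equal(sum(rep_pooled$observed), 100L)
  expect_equal(sum(rep_pooled$expected), 100)
  # the statistic equals hwe_chisq of the tabulated top quartile
  manual <- hwe_chisq(rep_pooled$observed,
                      hwe_expected_counts(100, 0.257))
  expect_equal(rep_pooled$statistic, manual$statistic)

  # stratified mode ranks within each CAG length
  rep_strat <- top_quartile_hwe_report(idx, g, maf = 0.257,
                                       stratify_by_cag = TRUE)
  sizes <- table(idx$main_cag)
  expect_equal(rep_strat$n_top, sum(sizes %/% 4L))
})

test_that("expansion-coupled genotypes enrich the top quartile", {
  set.seed(13)
  n <- 600
  g <- stats::rbinom(n, 2, 0.3)
  # minor-allele dosage raises expansion propensity
  pps <- stats::rbeta(n, (0.05 + 0.1 * g) * 40, (1 - 0.05 - 0.1 * g) * 40)
  idx <- data.frame(sample = sprintf("S%04d", 1:n),
                    main_cag = 42L, pps = pps)
  names(g) <- idx$sample
  coupled <- top_quartile_hwe_report(idx, g, maf = 0.3)
  expect_lt(coupled$p, 0.05)
  # minor-allele excess relative to HWE expectation
  expect_gt(coupled$observed[["minor_hom"]], coupled$expected[["minor_hom"]])

  # independence -> p behaves like a null draw most of the time; check the
  # statistic is small on average over a few replicates
  ps <- replicate(20, {
    pps0 <- stats::rbeta(n, 2, 20)
    idx0 <- data.frame(sample = idx$sample, main_cag = 42L, pps = pps0)
    top_quartile_hwe_report(idx0, g, maf = 0.3)$p
  })
  expect_gt(mean(ps > 0.05), 0.7)
})

test_that("dichotomous logistic plumbing detects a group-modifier link", {
  set.seed(14)
  n <- 1000
  dosage <- stats::rbinom(n, 2, 0.3)
  p_late <- stats::plogis(-0.8 * dosage + 0.2)
  group <- ifelse(stats::runif(n) < p_late, "late", "early")
  got <- dichotomous_association(dosage, group)
  expect_lt(got$p, 1e-4)
  expect_lt(got$beta, 0)
})
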