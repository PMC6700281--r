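#' Load tag-SNP classification rules from YAML
#'
#' A rule set is an ordered list of declarative rules, each with a `label`,
#' an optional onset `direction` (`hastened` / `delayed`), an optional
#' minor-allele-frequency window (`maf:` with any of `gt`, `ge`, `lt`,
#' `le`), a `marginal` p-value condition (`cmp` of `"<"` or `">"` plus
#' `p`), and zero or more `conditional` conditions, each naming the
#' conditioning SNP whose conditional p-value the condition applies to.
#' All p-value and frequency comparisons are strict unless `ge`/`le` is
#' used.
#'
#' @param path YAML file; defaults to the modifier-haplotype rule sets
#'   shipped with the package (5AM1-3 at MSH3/DHFR, 15AM1-4 at FAN1,
#'   19AM1-3 at LIG1).
#' @return List of rules (class `tag_rules`), in declared order.
#' @export
read_tag_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "tag_rules.yaml", package = "cagtract",
                        mustWork = TRUE)
  }
  rules <- yaml::read_yaml(path)
  for (r in rules) {
    if (is.null(r$label) || is.null(r$marginal)) {
      stop("each rule needs at least a label and a marginal condition")
    }
  }
  structure(rules, class = "tag_rules")
}

#' Built-in modifier-haplotype tag rules
#'
#' @return The shipped `tag_rules` object (see [read_tag_rules()]).
#' @export
hd_tag_rules <- function() read_tag_rules()

cmp_apply <- function(value, cmp, threshold) {
  switch(cmp,
         "<" = value < threshold,
         ">" = value > threshold,
         "<=" = value <= threshold,
         ">=" = value >= threshold,
         stop("unknown comparator: ", cmp))
}

maf_in_window <- function(maf, w) {
  ok <- TRUE
  if (!is.null(w$gt)) ok <- ok && maf > w$gt
  if (!is.null(w$ge)) ok <- ok && maf >= w$ge
  if (!is.null(w$lt)) ok <- ok && maf < w$lt
  if (!is.null(w$le)) ok <- ok && maf <= w$le
  ok
}

# Evaluate one rule against one SNP's statistics row. Returns TRUE/FALSE,
# or NA when a referenced conditional p-value is absent.
rule_matches <- function(rule, row) {
  if (!is.null(rule$direction) && rule$direction != row$direction) {
    return(FALSE)
  }
  if (!is.null(rule$maf) && !maf_in_window(row$maf, rule$maf)) return(FALSE)
  if (!cmp_apply(row$p_marginal, rule$marginal$cmp, rule$marginal$p)) {
    return(FALSE)
  }
  for (cond in rule$conditional) {
    col <- paste0("cond_", cond$snp)
    if (is.null(row[[col]]) || is.na(row[[col]])) return(NA)
    if (!cmp_apply(row[[col]], cond$cmp, cond$p)) return(FALSE)
  }
  TRUE
}

#' Classify SNPs into modifier-haplotype tag sets
#'
#' Evaluates an ordered rule set against per-SNP statistics; each SNP takes
#' the label of the first matching rule, or no label. A SNP lacking a
#' conditional p-value a candidate rule requires is skipped (label `NA`)
#' with a warning.
#'
#' @param stats data.frame with one row per SNP and columns `snp`, `maf`,
#'   `effect` (years per minor allele; its sign defines the direction
#'   unless a `direction` column with values `"hastened"`/`"delayed"` is
#'   supplied), `p_marginal`, and one `cond_<rsid>` column per conditioning
#'   SNP the rules reference.
#' @param rules a `tag_rules` object (default [hd_tag_rules()]).
#' @return `stats` with an added `tag` column (label or `NA`).
#' @export
classify_tag_snps <- function(stats, rules = hd_tag_rules()) {
  if (is.null(stats$direction)) {
    stats$direction <- ifelse(stats$effect < 0, "hastened", "delayed")
  }
  stats$tag <- NA_character_
  for (i in seq_len(nrow(stats))) {
    row <- stats[i, , drop = FALSE]
    for (rule in rules) {
      m <- rule_matches(rule, row)
      if (is.na(m)) {
        warning("SNP ", row$snp, ": missing conditional p-value required ",
                "by rule ", rule$label, "; SNP skipped")
        break
      }
      if (m) { stats$tag[i] <- rule$label; break }
    }
  }
  stats
}
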