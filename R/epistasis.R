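# Two-locus genetics of sex reversal and offspring sex-ratio testing.
#
# Locus 1 (Cyn_Z_6676874) is hemizygous in ZW genetic females, so its
# "genotype" is a single allele A or T; locus 2 (Cyn_Z_8564889) admits
# GG, AG and AA (heterozygotes arise from a rare Dmrt1 duplication).

#' Two-locus reversal classification
#'
#' Deterministic penetrance rule: a ZW genetic female reverses into a
#' pseudomale iff it carries the T allele at the first locus and at least
#' one A allele at the second locus; otherwise it stays female.
#'
#' @param g1 Character vector of hemizygous first-locus alleles
#'   (`"A"`/`"T"`).
#' @param g2 Character vector of second-locus genotypes (`"GG"`, `"AG"`,
#'   `"GA"`, `"AA"`).
#' @return Character vector `"pseudomale"`/`"female"`.
#' @examples
#' classify_reversal("T", "AA")   # pseudomale
#' classify_reversal("A", "AG")   # female
#' @export
classify_reversal <- function(g1, g2) {
  g1 <- as.character(g1)
  g2 <- as.character(g2)
  if (!all(g1 %in% c("A", "T")))
    stop("g1 alleles must be A or T")
  g2n <- vapply(strsplit(g2, ""), function(a)
    paste(sort(a), collapse = ""), character(1))
  if (!all(g2n %in% c("GG", "AG", "AA")))
    stop("g2 genotypes must be GG, AG/GA or AA")
  ifelse(g1 == "T" & grepl("A", g2n, fixed = TRUE),
         "pseudomale", "female")
}

#' Two-locus genotype-by-phenotype table
#'
#' Tabulates individuals by second-locus genotype (rows GG/AA/AG),
#' first-locus allele (columns A/T) and observed phenotype, and counts
#' how many observed phenotypes disagree with [classify_reversal()].
#'
#' @param g1,g2 Genotypes as in [classify_reversal()].
#' @param phenotype Observed phenotype, `"female"`/`"pseudomale"`.
#' @return Object of class `two_locus_table`: `counts` (3 x 2 x 2 array),
#'   `misclassified` (count), `predicted` (the rule's calls), `n`.
#' @export
build_two_locus_table <- function(g1, g2, phenotype) {
  stopifnot(length(g1) == length(g2), length(g1) == length(phenotype))
  phenotype <- as.character(phenotype)
  if (length(g1) &&
      !all(phenotype %in% c("female", "pseudomale")))
    stop("phenotype must be female or pseudomale")
  predicted <- classify_reversal(g1, g2)
  g2n <- vapply(strsplit(as.character(g2), ""), function(a)
    paste(sort(a), collapse = ""), character(1))
  counts <- table(
    factor(g2n, levels = c("GG", "AA", "AG")),
    factor(as.character(g1), levels = c("A", "T")),
    factor(phenotype, levels = c("female", "pseudomale")))
  counts <- array(counts, dim = c(3, 2, 2),
                  dimnames = list(g2 = c("GG", "AA", "AG"),
                                  g1 = c("A", "T"),
                                  phenotype = c("female", "pseudomale")))
  structure(list(counts = counts,
                 misclassified = sum(predicted != phenotype),
                 predicted = predicted, n = length(g1)),
            class = "two_locus_table")
}

#' @export
print.two_locus_table <- function(x, ...) {
  cat("two-locus genotype x phenotype table (n =", x$n, ")\n")
  print(stats::ftable(x$counts, row.vars = c("g2", "g1")))
  cat("misclassified by the T&A rule:", x$misclassified, "\n")
  invisible(x)
}

#' Offspring sex-ratio test under the no-W-sperm model
#'
#' If a pseudomale sire produced W sperm, ZW x ZW crosses would yield
#' ZW:ZZ offspring at 2:1 (WW zygotes die); if it produces only Z sperm
#' the expectation is 1:1. Tests observed (ZW, ZZ) counts against the
#' expected ratio by a chi-square goodness-of-fit test with one degree of
#' freedom (default), or by an exact binomial test.
#'
#' @param n_zw,n_zz Observed offspring counts.
#' @param expected_ratio Numeric length-2 expected ZW:ZZ ratio (default
#'   `c(2, 1)`); only its proportions matter.
#' @param method `"chisq"` (default) or `"binomial"` (exact, one-sided
#'   toward the observed deviation).
#' @return Object of class `ratio_test`: `statistic`, `df`, `p_value`,
#'   `observed`, `expected_ratio`, `method`.
#' @examples
#' offspring_ratio_test(24, 22)   # P = 0.037
#' @export
offspring_ratio_test <- function(n_zw, n_zz, expected_ratio = c(2, 1),
                                 method = c("chisq", "binomial")) {
  method <- match.arg(method)
  if (n_zw < 0 || n_zz < 0) stop("counts must be non-negative")
  n <- n_zw + n_zz
  if (n == 0) stop("no offspring")
  pr <- expected_ratio / sum(expected_ratio)
  if (method == "chisq") {
    e <- n * pr
    stat <- sum((c(n_zw, n_zz) - e)^2 / e)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    side <- if (n_zw / n <= pr[1]) "less" else "greater"
    p <- stats::binom.test(n_zw, n, pr[1], alternative = side)$p.value
    stat <- NA_real_
  }
  structure(list(statistic = stat, df = 1L, p_value = p,
                 observed = c(ZW = n_zw, ZZ = n_zz),
                 expected_ratio = expected_ratio, method = method),
            class = "ratio_test")
}

#' @export
print.ratio_test <- function(x, ...) {
  cat(sprintf("offspring ZW:ZZ ratio test (%s) vs %g:%g\n", x$method,
              x$expected_ratio[1], x$expected_ratio[2]))
  cat(sprintf("observed ZW = %d, ZZ = %d\n", x$observed["ZW"],
              x$observed["ZZ"]))
  if (!is.na(x$statistic))
    cat(sprintf("X-squared = %.4f, df = %d, ", x$statistic, x$df))
  cat(sprintf("P = %.4g\n", x$p_value))
  invisible(x)
}
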