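# Builds one moderate family population shared by several blocks.
make_scan_fixture <- function(seed = 31, n_fam = 8, n_off = 20) {
  sim <- simulate_population(sim_config(
    n_families = n_fam, n_offspring_per_family = n_off,
    marker_counts = c("1" = 60, "2" = 60, Z = 20), seed = seed))
  g <- impute_missing(filter_markers(sim$geno)$geno)
  list(sim = sim, g = g)
}

test_that("REML recovers the variance ratio within an order of magnitude", {
  fx <- make_scan_fixture()
  grm <- build_grm(fx$g)
  K <- grm$K
  ek <- eigen(K, symmetric = TRUE)
  rt <- ek$vectors %*% diag(sqrt(pmax(ek$values, 0))) %*% t(ek$vectors)
  n <- nrow(K)
  set.seed(99)
  lams <- replicate(25, {
    gg <- rt %*% stats::rnorm(n)            # g ~ N(0, K), sigma2_g = 1
    y <- 1 + gg + stats::rnorm(n)           # sigma2_e = 1, lambda = 1
    estimate_vc(y, K)$lambda
  })
  expect_gt(stats::median(lams), 0.2)
  expect_lt(stats::median(lams), 5)
})

test_that("REML drives lambda to the lower boundary when y ignores K", {
  fx <- make_scan_fixture()
  K <- build_grm(fx$g)$K
  set.seed(100)
  lams <- replicate(20, estimate_vc(stats::rnorm(nrow(K)), K)$lambda)
  expect_gt(mean(lams < 0.1), 0.5)
})

test_that("K = I makes the ratio non-identifiable (warned boundary)", {
  set.seed(5)
  y <- stats::rnorm(40)
  expect_warning(vc <- estimate_vc(y, diag(40)), "flat")
  expect_true(vc$boundary)
  expect_error(estimate_vc(rep(1, 10), diag(10)), "constant")
})

test_that("whitening is invertible and matches the plain model at sigma2_g = 0", {
  fx <- make_scan_fixture()
  grm <- build_grm(fx$g)
  y <- fx$sim$pheno$reversal[match(rownames(fx$g$geno),
                                   fx$sim$pheno$id)]
  vc <- estimate_vc(y, grm)
  d <- whiten(y, fx$g$geno, vc, grm)
  expect_equal(unname(drop(d$L %*% d$ystar)), y, tolerance = 1e-10)
  # sigma2_g = 0: whitening is a global rescale, statistics match OLS
  vc0 <- structure(list(sigma2_g = 0, sigma2_e = 2, lambda = 0,
                        loglik = NA, boundary = TRUE, n = length(y)),
                   class = "vc")
  d0 <- whiten(y, fx$g$geno, vc0, grm)
  expect_equal(d0$ystar, y / sqrt(2), tolerance = 1e-12)
  s0 <- scan_markers(d0)
  raw <- structure(list(ystar = y, Mstar = fx$g$geno,
                        intercept = rep(1, length(y)), vc = vc0),
                   class = "whitened_design")
  expect_equal(s0$stat, scan_markers(raw)$stat, tolerance = 1e-9)
})

test_that("whitened residuals are near-white under the generating model", {
  fx <- make_scan_fixture()
  K <- build_grm(fx$g)$K
  n <- nrow(K)
  ek <- eigen(K, symmetric = TRUE)
  rt <- ek$vectors %*% diag(sqrt(pmax(ek$values, 0))) %*% t(ek$vectors)
  vc <- structure(list(sigma2_g = 1, sigma2_e = 1, lambda = 1,
                       loglik = NA, boundary = FALSE, n = n),
                  class = "vc")
  set.seed(77)
  resids <- replicate(200, {
    y <- rt %*% stats::rnorm(n) + stats::rnorm(n)
    d <- whiten(drop(y), matrix(0, n, 1), vc, K)
    r <- d$ystar
    r
  })
  emp <- tcrossprod(resids) / ncol(resids)
  offd <- emp[upper.tri(emp)]
  expect_lt(abs(mean(diag(emp)) - 1), 0.15)
  expect_lt(mean(abs(offd)), 0.1)
})

test_that("whitened scan equals the direct GLS -2dlogLik oracle", {
  set.seed(40)
  sim <- simulate_population(sim_config(
    n_families = 4, n_offspring_per_family = 10,
    marker_counts = c("1" = 12, Z = 4), seed = 41))
  g <- impute_missing(filter_markers(sim$geno)$geno)
  grm <- build_grm(g)
  n <- nrow(grm$K)
  y <- sim$pheno$reversal[match(rownames(g$geno), sim$pheno$id)] +
    stats::rnorm(n, 0, 0.1)             # jitter avoids exact separation
  vc <- estimate_vc(y, grm)
  d <- whiten(y, g$geno, vc, grm)
  got <- scan_markers(d)$stat
  V <- vc$sigma2_g * grm$K + diag(vc$sigma2_e, n)
  want <- gls_stat_oracle(y, g$geno, V)
  keep <- is.finite(got) & got > 1e-8
  expect_equal(got[keep], want[keep], tolerance = 1e-6)
})

test_that("scan statistic is invariant to allele recoding", {
  fx <- make_scan_fixture()
  grm <- build_grm(fx$g)
  y <- fx$sim$pheno$reversal[match(rownames(fx$g$geno),
                                   fx$sim$pheno$id)]
  vc <- estimate_vc(y, grm)
  d1 <- whiten(y, fx$g$geno, vc, grm)
  d2 <- whiten(y, 2L - fx$g$geno, vc, grm)
  s1 <- scan_markers(d1)
  s2 <- scan_markers(d2)
  expect_equal(s1$stat, s2$stat, tolerance = 1e-8)
  expect_equal(s1$b, -s2$b, tolerance = 1e-8)
  # P monotone decreasing in the statistic
  ord <- order(s1$stat)
  expect_true(all(diff(s1$p[ord]) <= 1e-15))
})

test_that("degenerate markers: collinear -> T = 0; separation -> underflow", {
  set.seed(50)
  n <- 60
  y <- rep(c(0, 1), each = n / 2)
  M <- cbind(const = rep(1L, n),            # collinear with intercept
             perfect = as.integer(2 * y),   # separates y exactly
             noise = as.integer(stats::rbinom(n, 2, 0.5)))
  d <- structure(list(ystar = y, Mstar = M, intercept = rep(1, n),
                      vc = NULL), class = "whitened_design")
  s <- scan_markers(d)
  expect_equal(s$stat[1], 0)
  expect_equal(s$p[1], 1)
  expect_equal(s$flag[1], "collinear")
  expect_true(is.infinite(s$stat[2]))
  expect_equal(s$flag[2], "underflow")
  expect_equal(s$p[2], .Machine$double.xmin)
})

test_that("genome-wide threshold is sandwiched and hits 3.841 for one marker", {
  one <- data.frame(marker = "m1", chrom = "1", pos = 1L, b = 1,
                    stat = 2, p = 0.5, flag = "")
  expect_equal(piepho_threshold(one, 0.05), stats::qchisq(0.95, 1),
               tolerance = 1e-6)
  fx <- make_scan_fixture()
  grm <- build_grm(fx$g)
  y <- fx$sim$pheno$reversal[match(rownames(fx$g$geno),
                                   fx$sim$pheno$id)]
  vc <- estimate_vc(y, grm)
  s <- scan_markers(whiten(y, fx$g$geno, vc, grm), fx$g$map)
  thr <- piepho_threshold(s, 0.05)
  expect_gte(thr, stats::qchisq(0.95, 1))
  expect_lte(thr, stats::qchisq(1 - 0.05 / nrow(s), 1))
})

test_that("analytic threshold tracks the permutation oracle", {
  fx <- make_scan_fixture(seed = 61)
  grm <- build_grm(fx$g)
  set.seed(62)
  y <- stats::rbinom(nrow(grm$K), 1, 0.5)  # null phenotype
  vc <- estimate_vc(y, grm)
  s <- scan_markers(whiten(y, fx$g$geno, vc, grm), fx$g$map)
  thr <- piepho_threshold(s, 0.05)
  set.seed(63)
  perm <- permutation_threshold(y, fx$g$geno, vc, grm, n_perm = 100,
                                alpha = 0.05)
  # analytic bound is conservative: at or above the empirical critical
  # value, but not beyond Bonferroni
  expect_gte(thr, perm * 0.8)
  expect_lte(thr, stats::qchisq(1 - 0.05 / nrow(s), 1))
})

test_that("support interval follows the drop rule", {
  mk <- function(stat) data.frame(
    marker = paste0("m", seq_along(stat)), chrom = "Z",
    pos = seq_along(stat) * 1000L, b = 1, stat = stat,
    p = stats::pchisq(stat, 1, lower.tail = FALSE), flag = "")
  # flat profile at the peak: interval spans the whole chromosome
  flat <- mk(rep(30, 6))
  ci <- peak_ci(flat, threshold = 10)
  expect_equal(ci$start, 1000)
  expect_equal(ci$end, 6000)
  # isolated peak: midpoints to the flanking markers
  spike <- mk(c(1, 1, 40, 2, 1))
  ci2 <- peak_ci(spike, threshold = 10)
  expect_equal(ci2$start, floor((2000 + 3000) / 2))
  expect_equal(ci2$end, ceiling((3000 + 4000) / 2))
  expect_equal(ci2$peak_marker, "m3")
  # clipping to supplied chromosome length
  ci3 <- peak_ci(flat, threshold = 10, chrom_lengths = c(Z = 9999))
  expect_equal(ci3$start, 1)
  expect_equal(ci3$end, 9999)
  expect_error(peak_ci(mk(rep(1, 5)), threshold = 10), "no QTL")
})

test_that("run_gwas recovers a fully penetrant causal locus end to end", {
  # seed chosen to give a cohort segregating at the second locus (a
  # degenerate draw where every founder Z haplotype carries A would
  # leave the phenotype single-class, which run_gwas rejects)
  sim <- simulate_ztw_cohort(80, sim_config(marker_scale = 0.02,
                                            seed = 72))
  fit <- run_gwas(sim$geno, sim$pheno)
  causal <- attr(sim$truth, "causal_markers")[2]
  expect_equal(fit$peak$marker, causal)
  expect_true(fit$peak$above_threshold)
  expect_equal(fit$ci$chrom, "Z")
  expect_lte(fit$ci$start, 8564889)
  expect_gte(fit$ci$end, 8564889)
  expect_s3_class(fit, "zw_scan")
  expect_equal(length(coef(fit)), fit$n_markers)
  expect_output(print(fit), "peak")
  # conditioning on the locus-1 allele keeps only carriers
  fit2 <- run_gwas(sim$geno, sim$pheno,
                   condition = c(marker = "Cyn_Z_6676874", allele = "T"))
  expect_equal(fit2$n, 80)
  expect_error(run_gwas(sim$geno, transform(sim$pheno, reversal = 1L)),
               "single class")
})
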